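# Polygon primitives backing the AOI hit test. Polygons are n x 2 numeric
# matrices of vertices in pixel (video) coordinates, origin top-left.

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2L)
    stop("polygon must be a numeric matrix with two columns (x, y)", call. = FALSE)
  storage.mode(p) <- "double"
  p
}

flatten_polys <- function(polys) {
  polys <- lapply(polys, as_polygon)
  nv <- vapply(polys, nrow, integer(1))
  list(
    vx = unlist(lapply(polys, function(p) p[, 1]), use.names = FALSE),
    vy = unlist(lapply(polys, function(p) p[, 2]), use.names = FALSE),
    offsets = c(0L, cumsum(nv)) # 0-based, C++ layout
  )
}

#' Polygon area, centroid and simplicity
#'
#' Shoelace area and area centroid of a polygon given as an `n x 2` vertex
#' matrix. A polygon is *simple* when no two non-adjacent edges intersect and
#' its area is non-degenerate.
#'
#' @param poly numeric `n x 2` matrix of vertices (pixels).
#' @return `polygon_area()`: the absolute area; `polygon_centroid()`: length-2
#'   numeric `(x, y)`; `polygon_is_simple()`: logical.
#' @examples
#' tri <- cbind(c(0, 60, 30), c(0, 0, 52))
#' polygon_area(tri)
#' polygon_centroid(tri)
#' @export
polygon_area <- function(poly) {
  f <- flatten_polys(list(poly))
  cpp_polygon_props(f$vx, f$vy, f$offsets)[1, 1]
}

#' @rdname polygon_area
#' @export
polygon_centroid <- function(poly) {
  f <- flatten_polys(list(poly))
  p <- cpp_polygon_props(f$vx, f$vy, f$offsets)
  c(x = p[1, 2], y = p[1, 3])
}

#' @rdname polygon_area
#' @export
polygon_is_simple <- function(poly) {
  poly <- as_polygon(poly)
  if (nrow(poly) < 3L) return(FALSE)
  f <- flatten_polys(list(poly))
  cpp_polygon_props(f$vx, f$vy, f$offsets)[1, 4] == 1
}

#' Signed distance from a point to a polygon boundary
#'
#' Negative inside the polygon (even-odd rule), positive outside, zero on the
#' boundary.
#'
#' @param point length-2 numeric `(x, y)`.
#' @param poly numeric `n x 2` vertex matrix.
#' @return signed Euclidean distance in pixels.
#' @export
point_polygon_distance <- function(point, poly) {
  f <- flatten_polys(list(poly))
  cpp_point_poly_signed_dist(point[1], point[2], 0L, f$vx, f$vy, f$offsets)
}

#' Dilated-contour hit test
#'
#' A gaze point counts as a hit on an instance when it lies inside the
#' instance polygon or within `radius` pixels of its contour. The default
#' 5-pixel dilation absorbs fixations just outside a mask boundary.
#'
#' @param point length-2 numeric `(x, y)` in pixels.
#' @param poly numeric `n x 2` vertex matrix, or a `detected_instance` row
#'   from an annotation set.
#' @param radius dilation radius in pixels, `>= 0`.
#' @return logical.
#' @examples
#' tri <- cbind(c(0, 60, 30), c(0, 0, 52))
#' dilated_hit(c(30, 20), tri)        # interior
#' dilated_hit(c(30, -4), tri)        # 4 px outside an edge
#' dilated_hit(c(30, -6), tri, 5)     # 6 px outside
#' @export
dilated_hit <- function(point, poly, radius = 5) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius >= 0)
  point_polygon_distance(point, poly) <= radius
}

#' Intersection area of two polygons
#'
#' Area of the overlap between polygon `a` and convex polygon `b`
#' (Sutherland-Hodgman clipping). Used to decide whether a pegboard object is
#' being held by a grasper.
#'
#' @param a,b numeric `n x 2` vertex matrices; `b` must be convex.
#' @return overlap area in square pixels.
#' @export
polygon_intersection_area <- function(a, b) {
  f <- flatten_polys(list(a, b))
  cpp_pair_intersection_areas(f$vx, f$vy, f$offsets, 0L, 1L)
}
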
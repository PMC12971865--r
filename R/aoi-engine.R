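# AOI engine: ingest per-frame instance annotations (COCO-style polygons for
# the classes "object" and "tool"), derive object holding states from
# object-grasper overlap, and score fixation centroids against dilated
# instance contours.
#
# Internally an annotation set is columnar for speed: one instance table plus
# a flattened vertex array, the layout the C++ kernels consume directly.

AOI_CATEGORIES <- c("OBJ_1TOOL", "OBJ_2TOOLS", "OBJ_NOT_MOVING", "TOOL_ONLY", "NONE")

#' AOI engine configuration
#'
#' @param dilation_radius contour dilation in pixels for the hit test
#'   (default 5).
#' @param confidence_min detection confidence floor; instances with score not
#'   exceeding it are dropped at load time (default 0.5).
#' @param category_semantics `"object_state"` (default): a fixation on an
#'   object is categorised by how many graspers hold that object;
#'   `"pixel_intersection"`: categorised by whether the fixation point itself
#'   lies in the literal object-grasper overlap region.
#' @param state_area_tol minimum object-grasper overlap area (px^2) for the
#'   object to count as held (default 0.5).
#' @return an `aoi_config` list.
#' @export
aoi_config <- function(dilation_radius = 5, confidence_min = 0.5,
                       category_semantics = c("object_state", "pixel_intersection"),
                       state_area_tol = 0.5) {
  category_semantics <- match.arg(category_semantics)
  if (dilation_radius < 0) stop("dilation_radius must be >= 0", call. = FALSE)
  if (confidence_min < 0 || confidence_min > 1)
    stop("confidence_min must be in [0, 1]", call. = FALSE)
  structure(list(dilation_radius = dilation_radius,
                 confidence_min = confidence_min,
                 category_semantics = category_semantics,
                 state_area_tol = state_area_tol),
            class = "aoi_config")
}

#' Build an annotation set from columnar pieces
#'
#' Low-level constructor used by the loader and the session simulator.
#'
#' @param frames data.frame with columns `frame_index` (0-based, unique) and
#'   `t` (seconds, nondecreasing in index), one row per video frame (frames
#'   without instances included).
#' @param instances data.frame with columns `frame_index, instance_id,
#'   category` (`"object"`/`"tool"`), `score`.
#' @param vertices numeric matrix (2 columns) of polygon vertices for all
#'   instances, concatenated.
#' @param offsets integer vector, length `nrow(instances) + 1`, 0-based start
#'   offsets of each instance's vertices in `vertices`.
#' @param arena length-2 integer, arena width and height in pixels.
#' @param validate verify polygon simplicity and invariants (default TRUE).
#' @return an `aoi_annotations` object.
#' @export
aoi_annotations <- function(frames, instances, vertices, offsets,
                            arena = c(1920L, 1080L), validate = TRUE) {
  frames <- as.data.frame(frames)[, c("frame_index", "t")]
  if (is.unsorted(frames$frame_index, strictly = TRUE))
    frames <- frames[order(frames$frame_index), , drop = FALSE]
  if (validate) {
    if (anyDuplicated(frames$frame_index))
      stop("frame_index must be unique per session", call. = FALSE)
    if (is.unsorted(frames$t)) stop("frame times must be nondecreasing", call. = FALSE)
  }
  instances <- as.data.frame(instances)
  vertices <- as.matrix(vertices)
  offsets <- as.integer(offsets)
  if (nrow(instances) && is.unsorted(instances$frame_index)) {
    ord <- order(instances$frame_index)
    ro <- reorder_vertices(vertices, offsets, ord)
    instances <- instances[ord, , drop = FALSE]
    vertices <- ro$vertices
    offsets <- ro$offsets
  }
  nv <- diff(offsets)
  props <- cpp_polygon_props(vertices[, 1], vertices[, 2], offsets)
  if (validate && nrow(instances)) {
    bad <- which(nv < 3L | props[, 4] != 1)
    if (length(bad))
      stop(sprintf(
        "invalid polygon (degenerate or self-intersecting) for instance %s in frame %s",
        instances$instance_id[bad[1]], instances$frame_index[bad[1]]), call. = FALSE)
    if (any(instances$score < 0 | instances$score > 1))
      stop("confidence scores must lie in [0, 1]", call. = FALSE)
    unknown <- setdiff(unique(instances$category), c("object", "tool"))
    if (length(unknown))
      stop("unknown class label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  instances$cx <- if (nrow(instances)) props[, 2] else numeric(0)
  instances$cy <- if (nrow(instances)) props[, 3] else numeric(0)
  structure(list(frames = frames, instances = instances,
                 vertices = vertices, offsets = offsets, arena = arena),
            class = "aoi_annotations")
}

#' @export
print.aoi_annotations <- function(x, ...) {
  cat(sprintf("<aoi_annotations> %d frames, %d instances (%d object / %d tool), arena %dx%d\n",
              nrow(x$frames), nrow(x$instances),
              sum(x$instances$category == "object"),
              sum(x$instances$category == "tool"),
              x$arena[1], x$arena[2]))
  invisible(x)
}

#' Number of frames / frame timestamps of an annotation set
#' @param ann an `aoi_annotations` object.
#' @return integer count / numeric vector of seconds.
#' @export
n_frames <- function(ann) nrow(ann$frames)

#' @rdname n_frames
#' @export
frame_times <- function(ann) ann$frames$t

#' Extract one frame's annotation
#'
#' @param ann an `aoi_annotations` object.
#' @param frame_index 0-based frame index.
#' @return a `frame_annotation` list: `frame_index`, `t`, and `instances`, a
#'   data.frame with a `polygon` list-column of vertex matrices.
#' @export
frame_annotation <- function(ann, frame_index) {
  fr <- ann$frames[ann$frames$frame_index == frame_index, , drop = FALSE]
  if (!nrow(fr)) stop("no frame with index ", frame_index, call. = FALSE)
  sel <- which(ann$instances$frame_index == frame_index)
  inst <- ann$instances[sel, , drop = FALSE]
  inst$polygon <- lapply(sel, function(i) {
    ann$vertices[(ann$offsets[i] + 1L):ann$offsets[i + 1L], , drop = FALSE]
  })
  structure(list(frame_index = frame_index, t = fr$t[1], instances = inst),
            class = "frame_annotation")
}

#' Load per-frame instance annotations (COCO-style JSON)
#'
#' Reads the annotation dialect produced by an instance-segmentation model:
#' `images[]` with `id`, `frame_index`, `time_s`; `categories[]` naming
#' `object` and `tool`; `annotations[]` with polygon `segmentation` and a
#' detection `score`. Instances whose score does not exceed
#' `cfg$confidence_min` are dropped; remaining polygons are validated and
#' their area centroids computed.
#'
#' @param path path to the JSON file.
#' @param cfg an [aoi_config()].
#' @return an `aoi_annotations` object.
#' @export
load_annotations <- function(path, cfg = aoi_config()) {
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                 error = function(e) stop("malformed annotation JSON at ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  for (need in c("images", "categories", "annotations"))
    if (is.null(js[[need]]))
      stop("annotation file ", path, " lacks '", need, "'", call. = FALSE)
  imgs <- as.data.frame(js$images)
  cats <- as.data.frame(js$categories)
  frames <- data.frame(frame_index = imgs$frame_index, t = imgs$time_s)
  arena <- c(imgs$width[1], imgs$height[1])
  anns <- js$annotations
  if (length(anns) == 0L || (is.data.frame(anns) && nrow(anns) == 0L)) {
    return(aoi_annotations(frames,
                           data.frame(frame_index = integer(0), instance_id = integer(0),
                                      category = character(0), score = numeric(0)),
                           matrix(numeric(0), ncol = 2), 0L, arena = arena))
  }
  anns <- as.data.frame(anns)
  cat_name <- setNames(cats$name, as.character(cats$id))
  category <- unname(cat_name[as.character(anns$category_id)])
  if (anyNA(category))
    stop("unknown category_id in ", path, " (annotation id ",
         anns$id[which(is.na(category))[1]], ")", call. = FALSE)
  img_frame <- setNames(imgs$frame_index, as.character(imgs$id))
  img_t <- setNames(imgs$time_s, as.character(imgs$id))
  segs <- lapply(anns$segmentation, function(s) {
    if (is.list(s)) s <- s[[1]]
    as.numeric(s)
  })
  bad_len <- which(vapply(segs, function(s) length(s) < 6L || length(s) %% 2L != 0L,
                          logical(1)))
  if (length(bad_len))
    stop(sprintf("degenerate polygon (annotation id %s, frame %s): need >= 3 (x, y) vertices",
                 anns$id[bad_len[1]],
                 img_frame[as.character(anns$image_id[bad_len[1]])]), call. = FALSE)
  keep <- anns$score > cfg$confidence_min
  anns <- anns[keep, , drop = FALSE]
  segs <- segs[keep]
  category <- category[keep]
  instances <- data.frame(
    frame_index = as.integer(unname(img_frame[as.character(anns$image_id)])),
    instance_id = if ("instance_id" %in% names(anns)) anns$instance_id else anns$id,
    category = category,
    score = anns$score
  )
  nv <- vapply(segs, length, integer(1)) / 2L
  flat <- unlist(segs, use.names = FALSE)
  xs <- flat[seq_along(flat) %% 2L == 1L]
  ys <- flat[seq_along(flat) %% 2L == 0L]
  # segmentation is interleaved per polygon, so rebuild per-polygon x/y
  vx <- vector("list", length(segs)); vy <- vector("list", length(segs))
  pos <- 0L
  for (i in seq_along(segs)) {
    k <- nv[i]
    idx <- pos + seq_len(k)
    vx[[i]] <- xs[idx]; vy[[i]] <- ys[idx]
    pos <- pos + k
  }
  vertices <- cbind(unlist(vx, use.names = FALSE), unlist(vy, use.names = FALSE))
  offsets <- c(0L, cumsum(nv))
  ord <- order(instances$frame_index)
  ann <- aoi_annotations(frames, instances[ord, , drop = FALSE],
                         reorder_vertices(vertices, offsets, ord)$vertices,
                         reorder_vertices(vertices, offsets, ord)$offsets,
                         arena = arena)
  ann
}

reorder_vertices <- function(vertices, offsets, ord) {
  nv <- diff(offsets)
  idx <- unlist(lapply(ord, function(i) (offsets[i] + 1L):offsets[i + 1L]),
                use.names = FALSE)
  list(vertices = vertices[idx, , drop = FALSE],
       offsets = c(0L, cumsum(nv[ord])))
}

#' Write an annotation set as COCO-style JSON
#'
#' Inverse of [load_annotations()] (round-trips the declared dialect).
#'
#' @param ann an `aoi_annotations` object.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  imgs <- data.frame(
    id = ann$frames$frame_index + 1L,
    frame_index = ann$frames$frame_index,
    time_s = ann$frames$t,
    width = ann$arena[1], height = ann$arena[2],
    file_name = sprintf("frame_%06d.png", ann$frames$frame_index)
  )
  cats <- data.frame(id = c(1L, 2L), name = c("object", "tool"))
  n <- nrow(ann$instances)
  if (n) {
    nv <- diff(ann$offsets)
    # interleave (x1, y1, x2, y2, ...) per instance in one pass
    flat <- as.numeric(t(ann$vertices))
    grp <- rep(rep.int(seq_len(n), nv), each = 2L)
    segs <- lapply(split(flat, grp), list)
    anns <- data.frame(
      id = seq_len(n),
      image_id = ann$instances$frame_index + 1L,
      instance_id = ann$instances$instance_id,
      category_id = ifelse(ann$instances$category == "object", 1L, 2L),
      score = ann$instances$score)
    anns$segmentation <- unname(segs)
  } else {
    anns <- list()
  }
  jsonlite::write_json(list(images = imgs, categories = cats, annotations = anns),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Object holding states for one frame
#'
#' An object's state is the number of grasper polygons whose overlap area with
#' it exceeds `cfg$state_area_tol`, clamped at two: 0 = `NOT_HELD`,
#' 1 = `HELD_ONE`, 2 = `HELD_TWO`.
#'
#' @param frame a `frame_annotation` from [frame_annotation()].
#' @param cfg an [aoi_config()].
#' @return named integer vector (names = object instance ids); empty for a
#'   frame without objects.
#' @export
object_states <- function(frame, cfg = aoi_config()) {
  inst <- frame$instances
  obj <- which(inst$category == "object")
  tools <- which(inst$category == "tool")
  out <- integer(length(obj))
  names(out) <- inst$instance_id[obj]
  if (!length(obj)) return(out)
  for (i in seq_along(obj)) {
    n_hold <- 0L
    for (j in tools) {
      a <- polygon_intersection_area(inst$polygon[[obj[i]]], inst$polygon[[j]])
      if (a > cfg$state_area_tol) n_hold <- n_hold + 1L
    }
    out[i] <- min(n_hold, 2L)
  }
  out
}

# Holding states for all frames at once (bounding-box prefilter + batch C++
# clipping). Returns data.table(frame_index, instance_id, state).
object_states_all <- function(ann, cfg = aoi_config()) {
  inst <- data.table::as.data.table(ann$instances)
  inst[, poly_row := .I]
  n <- nrow(inst)
  if (!n) return(data.table::data.table(frame_index = integer(0),
                                        instance_id = integer(0), state = integer(0)))
  # per-instance bounding boxes
  nv <- diff(ann$offsets)
  vt <- data.table::data.table(g = rep.int(seq_len(n), nv),
                               x = ann$vertices[, 1], y = ann$vertices[, 2])
  bb <- vt[, .(x1 = min(x), x2 = max(x), y1 = min(y), y2 = max(y)), by = g]
  data.table::setorder(bb, g)
  bx1 <- bb$x1; bx2 <- bb$x2; by1 <- bb$y1; by2 <- bb$y2
  objs <- inst[category == "object"]
  tls <- inst[category == "tool", .(frame_index, tool_row = poly_row)]
  pairs <- tls[objs[, .(frame_index, instance_id, obj_row = poly_row)],
               on = "frame_index", allow.cartesian = TRUE]
  pairs <- pairs[!is.na(tool_row)]
  st <- objs[, .(frame_index, instance_id, state = 0L)]
  if (nrow(pairs)) {
    cand <- pairs[bx1[obj_row] <= bx2[tool_row] & bx2[obj_row] >= bx1[tool_row] &
                  by1[obj_row] <= by2[tool_row] & by2[obj_row] >= by1[tool_row]]
    if (nrow(cand)) {
      areas <- cpp_pair_intersection_areas(ann$vertices[, 1], ann$vertices[, 2],
                                           ann$offsets,
                                           cand$obj_row - 1L, cand$tool_row - 1L)
      cand <- cand[areas > cfg$state_area_tol]
      if (nrow(cand)) {
        held <- cand[, .(n_tools = pmin(.N, 2L)), by = .(frame_index, instance_id)]
        st <- held[st, on = c("frame_index", "instance_id")]
        st[is.na(n_tools), n_tools := 0L]
        st <- st[, .(frame_index, instance_id, state = n_tools)]
      }
    }
  }
  data.table::setkeyv(st, c("frame_index", "instance_id"))
  st
}

utils::globalVariables(c("tool_row", "obj_row"))

#' Categorise one fixation-frame pair
#'
#' Under the default object-state semantics: if the fixation centroid hits any
#' (dilated) object instance, the category is set by the most-held hit object
#' (`HELD_TWO` > `HELD_ONE` > `NOT_HELD`, mapping to `OBJ_2TOOLS`,
#' `OBJ_1TOOL`, `OBJ_NOT_MOVING`); otherwise a tool hit gives `TOOL_ONLY`,
#' and no hit gives `NONE`. Objects take precedence over tools in overlap
#' zones. Under `pixel_intersection` semantics the object subcategory is
#' instead decided by whether the point itself also hits one or two graspers.
#'
#' @param fix one row of an [ivt_classify()] fixation table.
#' @param frame a `frame_annotation`.
#' @param states result of [object_states()] for that frame (object-state
#'   semantics only; recomputed when missing).
#' @param cfg an [aoi_config()].
#' @return a one-row data.frame `fixation_id, frame_index, category`.
#' @export
classify_fixation_frame <- function(fix, frame, states = NULL, cfg = aoi_config()) {
  if (is.null(states)) states <- object_states(frame, cfg)
  inst <- frame$instances
  pt <- c(fix$cx, fix$cy)
  hit <- vapply(seq_len(nrow(inst)), function(i)
    dilated_hit(pt, inst$polygon[[i]], cfg$dilation_radius), logical(1))
  obj_hit <- hit & inst$category == "object"
  tool_hit <- hit & inst$category == "tool"
  if (any(obj_hit)) {
    if (cfg$category_semantics == "object_state") {
      s <- max(states[as.character(inst$instance_id[obj_hit])])
    } else {
      s <- min(sum(tool_hit), 2L)
    }
    category <- c("OBJ_NOT_MOVING", "OBJ_1TOOL", "OBJ_2TOOLS")[s + 1L]
  } else if (any(tool_hit)) {
    category <- "TOOL_ONLY"
  } else {
    category <- "NONE"
  }
  data.frame(fixation_id = fix$fixation_id, frame_index = frame$frame_index,
             category = factor(category, levels = AOI_CATEGORIES))
}

#' Map fixations onto video frames and categorise every pair
#'
#' Each fixation is paired with every frame whose timestamp lies inside
#' `[t_start, t_end]`; each pair yields exactly one hit record, categorised as
#' in [classify_fixation_frame()] but computed in bulk.
#'
#' @param fixations an [ivt_classify()] fixation table.
#' @param ann an `aoi_annotations` object (same clock as the fixations).
#' @param cfg an [aoi_config()].
#' @return data.frame `fixation_id, frame_index, category` (factor over the
#'   five AOI categories). A warning is raised (and an empty result returned)
#'   when no fixation overlaps any frame timestamp.
#' @export
map_fixations_to_frames <- function(fixations, ann, cfg = aoi_config()) {
  empty <- data.frame(fixation_id = integer(0), frame_index = integer(0),
                      category = factor(character(0), levels = AOI_CATEGORIES))
  if (is.null(fixations) || nrow(fixations) == 0L || n_frames(ann) == 0L)
    return(empty)
  tf <- ann$frames$t
  eps <- 1e-9
  lo <- findInterval(fixations$t_start - eps, tf) + 1L
  hi <- findInterval(fixations$t_end + eps, tf)
  n_per <- pmax(hi - lo + 1L, 0L)
  if (sum(n_per) == 0L) {
    # warn only when every fixation lies outside the frame span entirely
    # (a fixation *between* two frame timestamps is a legitimate boundary case)
    if (all(fixations$t_end < tf[1] | fixations$t_start > tf[length(tf)]))
      warning("no fixation overlaps the frame span (clock mismatch?)",
              call. = FALSE)
    return(empty)
  }
  keep_fix <- which(n_per > 0L)
  fix_id <- rep.int(fixations$fixation_id, n_per)
  px <- rep.int(fixations$cx, n_per)
  py <- rep.int(fixations$cy, n_per)
  frame_row <- unlist(lapply(keep_fix, function(i) lo[i]:hi[i]),
                      use.names = FALSE)
  # instance-row range per frame (instances are frame-sorted)
  n_inst_per <- tabulate(match(ann$instances$frame_index,
                               ann$frames$frame_index),
                         nbins = nrow(ann$frames))
  f_end <- cumsum(n_inst_per)
  f_start <- f_end - n_inst_per
  code <- cpp_classify_pairs(
    ann$vertices[, 1], ann$vertices[, 2], ann$offsets,
    as.integer(ann$instances$category == "tool"),
    as.integer(f_start), as.integer(f_end),
    frame_row - 1L, px, py,
    cfg$dilation_radius, cfg$state_area_tol,
    cfg$category_semantics == "pixel_intersection")
  data.frame(fixation_id = fix_id,
             frame_index = ann$frames$frame_index[frame_row],
             category = factor(AOI_CATEGORIES[code + 1L],
                               levels = AOI_CATEGORIES))
}

utils::globalVariables(c("frame_row", "any_tool"))

#' Write hit records to CSV
#' @param hits output of [map_fixations_to_frames()].
#' @param path file path.
#' @export
write_hits_csv <- function(hits, path) {
  data.table::fwrite(hits, path)
  invisible(path)
}
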
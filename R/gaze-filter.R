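# I-VT fixation filtering of a raw gaze trace.
#
# A gaze trace is a data.frame with columns t (seconds), x, y (pixels) and
# valid (logical). Fixations are maximal runs of samples whose angular
# velocity stays below the threshold (default 70 deg/s), with short invalid
# gaps bridged and sub-minimum-duration runs discarded.

#' Construct a gaze trace
#'
#' @param t sample timestamps in seconds, strictly increasing.
#' @param x,y gaze position in pixels (arena coordinates, origin top-left).
#' @param valid logical validity flag per sample (recycled).
#' @return a `gaze_trace` data.frame with columns `t, x, y, valid`.
#' @export
gaze_trace <- function(t, x, y, valid = TRUE) {
  n <- length(t)
  valid <- rep_len(as.logical(valid), n)
  if (n && any(!is.finite(t))) stop("gaze timestamps must be finite", call. = FALSE)
  if (n > 1 && any(diff(t) <= 0))
    stop("gaze timestamps must be strictly increasing", call. = FALSE)
  structure(
    data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
               valid = valid),
    class = c("gaze_trace", "data.frame")
  )
}

#' Screen geometry for pixel-to-degree conversion
#'
#' The I-VT threshold is angular, so pixel displacements must be converted to
#' visual degrees. Either give `px_per_degree` directly, or give the viewing
#' distance and the physical/pixel width of the screen, from which the
#' conversion at screen centre is derived.
#'
#' @param px_per_degree pixels per degree of visual angle (default 38, a
#'   typical seated-monitor value).
#' @param viewing_distance_mm,screen_width_mm,screen_width_px alternative
#'   specification; all three must be given together.
#' @return a `screen_geometry` list with element `px_per_degree`.
#' @export
screen_geometry <- function(px_per_degree = 38, viewing_distance_mm = NULL,
                            screen_width_mm = NULL, screen_width_px = NULL) {
  if (!is.null(viewing_distance_mm)) {
    if (is.null(screen_width_mm) || is.null(screen_width_px))
      stop("viewing_distance_mm requires screen_width_mm and screen_width_px",
           call. = FALSE)
    mm_per_degree <- viewing_distance_mm * tan(pi / 180)
    px_per_degree <- mm_per_degree * screen_width_px / screen_width_mm
  }
  if (!is.numeric(px_per_degree) || px_per_degree <= 0)
    stop("px_per_degree must be a positive number", call. = FALSE)
  structure(list(px_per_degree = px_per_degree), class = "screen_geometry")
}

#' I-VT filter configuration
#'
#' @param velocity_threshold angular velocity threshold in deg/s; samples
#'   below it are fixation candidates (default 70).
#' @param velocity_window width in seconds of the symmetric window used for
#'   the two-point velocity estimate (default 0.020).
#' @param min_fixation_duration fixation runs shorter than this are dropped
#'   (seconds, default 0.060).
#' @param max_gap_fill invalid-sample gaps up to this duration inside a run do
#'   not split it (seconds, default 0.075).
#' @return an `ivt_config` list.
#' @export
ivt_config <- function(velocity_threshold = 70, velocity_window = 0.020,
                       min_fixation_duration = 0.060, max_gap_fill = 0.075) {
  vals <- c(velocity_threshold, velocity_window, min_fixation_duration, max_gap_fill)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all I-VT parameters must be positive", call. = FALSE)
  structure(list(velocity_threshold = velocity_threshold,
                 velocity_window = velocity_window,
                 min_fixation_duration = min_fixation_duration,
                 max_gap_fill = max_gap_fill),
            class = "ivt_config")
}

#' Per-sample angular gaze velocity
#'
#' Velocity at each sample is the angular displacement between the valid
#' samples straddling a `velocity_window`-wide window centred on it, divided
#' by their time separation (a two-point estimate that attenuates 50 Hz
#' noise). Invalid samples, edge samples, and samples whose window spans a
#' data gap longer than five windows get `NA`.
#'
#' @param trace a [gaze_trace()].
#' @param geometry a [screen_geometry()].
#' @param cfg an [ivt_config()].
#' @return numeric vector of deg/s, one element per sample (`NA` where
#'   undefined). If fewer than two valid samples exist the vector is empty,
#'   carries attribute `flag = "insufficient_valid_samples"`, and a warning is
#'   raised.
#' @export
angular_velocity <- function(trace, geometry = screen_geometry(),
                             cfg = ivt_config()) {
  stopifnot(inherits(trace, "data.frame"))
  if (nrow(trace) > 1 && any(diff(trace$t) <= 0))
    stop("gaze timestamps must be strictly increasing", call. = FALSE)
  vi <- which(trace$valid & is.finite(trace$x) & is.finite(trace$y))
  if (length(vi) < 2L) {
    warning("fewer than two valid gaze samples; velocity undefined", call. = FALSE)
    return(structure(numeric(0), flag = "insufficient_valid_samples"))
  }
  tv <- trace$t[vi]; xv <- trace$x[vi]; yv <- trace$y[vi]
  half <- cfg$velocity_window / 2
  # j1: last valid sample at or before t - half; j2: first at or after t + half
  j1 <- findInterval(tv - half, tv)
  j2 <- length(tv) + 1L - rev(findInterval(rev(-(tv + half)), rev(-tv)))
  ok <- j1 >= 1L & j2 <= length(tv) & j2 > j1
  v <- rep(NA_real_, length(tv))
  span <- tv[pmin(j2, length(tv))] - tv[pmax(j1, 1L)]
  disp <- sqrt((xv[pmin(j2, length(tv))] - xv[pmax(j1, 1L)])^2 +
               (yv[pmin(j2, length(tv))] - yv[pmax(j1, 1L)])^2)
  ok <- ok & span <= 5 * cfg$velocity_window & span > 0
  v[ok] <- disp[ok] / span[ok] / geometry$px_per_degree
  out <- rep(NA_real_, nrow(trace))
  out[vi] <- v
  out
}

#' Classify a gaze trace into fixations (I-VT)
#'
#' Maximal runs of valid samples with angular velocity below
#' `cfg$velocity_threshold` become fixations. Invalid (or velocity-undefined)
#' gaps no longer than `cfg$max_gap_fill` inside a run are bridged; runs
#' shorter than `cfg$min_fixation_duration` are discarded. The fixation
#' centroid is the mean position of its member samples.
#'
#' @inheritParams angular_velocity
#' @return a data.frame with columns `fixation_id, t_start, t_end, cx, cy,
#'   duration`, ordered and disjoint in time.
#' @export
ivt_classify <- function(trace, geometry = screen_geometry(), cfg = ivt_config()) {
  empty <- data.frame(fixation_id = integer(0), t_start = numeric(0),
                      t_end = numeric(0), cx = numeric(0), cy = numeric(0),
                      duration = numeric(0))
  if (is.null(trace) || nrow(trace) == 0L) return(empty)
  v <- suppressWarnings(angular_velocity(trace, geometry, cfg))
  if (length(v) == 0L) return(empty)

  # sample states: 2 = fixation candidate, 1 = bridgeable gap, 0 = saccade
  state <- integer(nrow(trace))
  state[trace$valid & !is.na(v) & v < cfg$velocity_threshold] <- 2L
  state[(!trace$valid) | is.na(v)] <- 1L
  # valid samples with undefined velocity adjacent to fixation samples are
  # absorbed into the neighbouring run (keeps edge samples of a steady trace)
  gap_ok <- state == 1L & trace$valid

  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)

  # decide, per gap run, whether it bridges (both neighbours fixation and gap
  # duration within max_gap_fill)
  runs <- data.frame(value = r$values, start = starts, end = ends)
  groups <- list()
  cur <- NULL
  i <- 1L
  while (i <= nr) {
    if (runs$value[i] == 2L) {
      cur <- if (is.null(cur)) c(runs$start[i], runs$end[i]) else c(cur[1], runs$end[i])
      # look ahead: gap run followed by fixation run?
      if (i + 2L <= nr && runs$value[i + 1L] == 1L && runs$value[i + 2L] == 2L) {
        gs <- runs$start[i + 1L]; ge <- runs$end[i + 1L]
        gap_dur <- trace$t[min(ge + 1L, nrow(trace))] - trace$t[max(gs - 1L, 1L)]
        if (gap_dur <= cfg$max_gap_fill) {
          i <- i + 1L # absorb the gap; next fixation run extends cur
          i <- i + 1L
          next
        }
      }
      groups[[length(groups) + 1L]] <- cur
      cur <- NULL
    } else if (runs$value[i] == 1L && !is.null(cur)) {
      # trailing gap after run already closed above
    }
    i <- i + 1L
  }
  if (!is.null(cur)) groups[[length(groups) + 1L]] <- cur

  if (length(groups) == 0L) return(empty)
  fx <- lapply(groups, function(g) {
    s <- g[1]; e <- g[2]
    # absorb adjacent valid samples with undefined velocity (trace edges)
    while (s > 1L && gap_ok[s - 1L]) s <- s - 1L
    while (e < nrow(trace) && gap_ok[e + 1L]) e <- e + 1L
    idx <- s:e
    member <- idx[trace$valid[idx]]
    c(t_start = trace$t[s], t_end = trace$t[e],
      cx = mean(trace$x[member]), cy = mean(trace$y[member]))
  })
  fx <- as.data.frame(do.call(rbind, fx))
  fx$duration <- fx$t_end - fx$t_start
  fx <- fx[fx$duration >= cfg$min_fixation_duration, , drop = FALSE]
  if (nrow(fx) == 0L) return(empty)
  data.frame(fixation_id = seq_len(nrow(fx)), fx, row.names = NULL)
}

#' Gaze sample percentage (trace quality)
#'
#' Percentage of samples flagged valid, the standard whole-recording quality
#' figure. Optionally gate a session: with a `threshold`, the result carries
#' an `excluded` attribute.
#'
#' @param trace a [gaze_trace()].
#' @param threshold optional QC floor in percent; if given, attribute
#'   `excluded` is `TRUE` when the percentage falls below it.
#' @return percentage in `[0, 100]` (`NA` with a warning for an empty trace).
#' @export
gaze_sample_percentage <- function(trace, threshold = NULL) {
  if (is.null(trace) || nrow(trace) == 0L) {
    warning("empty gaze trace; sample percentage undefined", call. = FALSE)
    return(NA_real_)
  }
  pct <- 100 * mean(trace$valid)
  if (!is.null(threshold)) attr(pct, "excluded") <- pct < threshold
  pct
}

#' Read / write gaze traces as delimited text
#'
#' The on-disk format has a header and columns `t_s, x_px, y_px, valid`
#' (valid as 0/1).
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @return `read_gaze_csv()`: a [gaze_trace()].
#' @export
read_gaze_csv <- function(path, delim = ",") {
  dt <- data.table::fread(path, sep = delim, header = TRUE)
  need <- c("t_s", "x_px", "y_px", "valid")
  if (!all(need %in% names(dt)))
    stop("gaze file ", path, " must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  gaze_trace(dt$t_s, dt$x_px, dt$y_px, as.logical(dt$valid))
}

#' @rdname read_gaze_csv
#' @param trace a [gaze_trace()] to write.
#' @export
write_gaze_csv <- function(trace, path, delim = ",") {
  dt <- data.table::data.table(t_s = trace$t, x_px = trace$x, y_px = trace$y,
                               valid = as.integer(trace$valid))
  data.table::fwrite(dt, path, sep = delim)
  invisible(path)
}

#' Write a fixation table as CSV
#'
#' Columns `t_start, t_end, cx, cy, duration`.
#' @param fixations output of [ivt_classify()].
#' @param path file path.
#' @export
write_fixation_csv <- function(fixations, path) {
  data.table::fwrite(fixations[, c("t_start", "t_end", "cx", "cy", "duration")],
                     path)
  invisible(path)
}
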
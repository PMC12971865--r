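# Per-session metrics: five AOI-dependent fixation rates (frames/second), the
# grasper-speed motion metric (px/second), and the frame-wise Cohen's kappa
# used to validate automatic against manual annotation.

METRIC_COLUMNS <- c("fr_tools", "fr_objects", "fr_obj_1tool", "fr_obj_2tools",
                    "fr_not_moving", "tool_speed")

#' Fixation rates per AOI category
#'
#' A frame is *credited* to a category when at least one fixation-frame hit
#' record assigns it that category; each frame counts at most once per
#' category, so rates are bounded by the frame rate. The overall object rate
#' uses the union of frames credited to the three object subcategories, which
#' makes `fr_objects = fr_obj_1tool + fr_obj_2tools + fr_not_moving` exact
#' under the default object-state semantics (one object category per frame).
#' Every count is divided by the task completion time.
#'
#' @param hits hit records from [map_fixations_to_frames()].
#' @param completion_time task completion time in seconds, `> 0`.
#' @return named numeric vector `fr_tools, fr_objects, fr_obj_1tool,
#'   fr_obj_2tools, fr_not_moving` in frames/second.
#' @export
fixation_rates <- function(hits, completion_time) {
  if (!is.numeric(completion_time) || completion_time <= 0)
    stop("completion_time must be > 0", call. = FALSE)
  cnt <- function(cats) {
    length(unique(hits$frame_index[hits$category %in% cats]))
  }
  obj_cats <- c("OBJ_1TOOL", "OBJ_2TOOLS", "OBJ_NOT_MOVING")
  c(fr_tools = cnt("TOOL_ONLY"),
    fr_objects = cnt(obj_cats),
    fr_obj_1tool = cnt("OBJ_1TOOL"),
    fr_obj_2tools = cnt("OBJ_2TOOLS"),
    fr_not_moving = cnt("OBJ_NOT_MOVING")) / completion_time
}

#' Left/right grasper tracks
#'
#' Assigns a `left`/`right` identity to the tool instances of each frame.
#' Initial assignment is by centroid x-order; in later frames identities
#' follow nearest-centroid continuity, so tracks survive graspers crossing.
#'
#' @param ann an `aoi_annotations` object.
#' @return data.frame `frame_index, t, side, cx, cy`, one row per detected
#'   tool per frame (at most two per frame; extra detections beyond the two
#'   highest-scoring are ignored).
#' @export
tool_tracks <- function(ann) {
  inst <- ann$instances
  sel <- which(inst$category == "tool")
  if (!length(sel))
    return(data.frame(frame_index = integer(0), t = numeric(0),
                      side = character(0), cx = numeric(0), cy = numeric(0)))
  tl <- data.frame(frame_index = inst$frame_index[sel],
                   score = inst$score[sel],
                   cx = inst$cx[sel], cy = inst$cy[sel])
  tl <- tl[order(tl$frame_index, -tl$score), , drop = FALSE]
  fidx <- tl$frame_index; cx <- tl$cx; cy <- tl$cy
  n <- length(fidx)
  first <- which(!duplicated(fidx)) # per-frame run starts (fidx sorted)
  run_len <- diff(c(first, n + 1L))
  lx <- NA_real_; ly <- NA_real_; rx <- NA_real_; ry <- NA_real_
  mid_x <- mean(range(ann$vertices[, 1]))
  out_side <- character(n)
  for (k in seq_along(first)) {
    i <- first[k]
    if (run_len[k] >= 2L) {
      j <- i + 1L
      if (cx[j] < cx[i]) { tmp <- i; i <- j; j <- tmp } # i = smaller x
      sa <- "left"; sb <- "right"
      if (!is.na(lx) && !is.na(rx)) {
        keep <- (cx[i] - lx)^2 + (cy[i] - ly)^2 + (cx[j] - rx)^2 + (cy[j] - ry)^2
        swap <- (cx[i] - rx)^2 + (cy[i] - ry)^2 + (cx[j] - lx)^2 + (cy[j] - ly)^2
        if (swap < keep) { sa <- "right"; sb <- "left" }
      }
      out_side[i] <- sa; out_side[j] <- sb
      if (sa == "left") { lx <- cx[i]; ly <- cy[i]; rx <- cx[j]; ry <- cy[j] }
      else { rx <- cx[i]; ry <- cy[i]; lx <- cx[j]; ly <- cy[j] }
    } else {
      side <- "left"
      if (!is.na(lx) && !is.na(rx)) {
        if ((cx[i] - rx)^2 + (cy[i] - ry)^2 < (cx[i] - lx)^2 + (cy[i] - ly)^2)
          side <- "right"
      } else if (is.na(lx) && is.na(rx) && cx[i] > mid_x) {
        side <- "right"
      } else if (is.na(lx) && !is.na(rx)) {
        side <- "right"
      }
      out_side[i] <- side
      if (side == "left") { lx <- cx[i]; ly <- cy[i] } else { rx <- cx[i]; ry <- cy[i] }
    }
  }
  used <- out_side != ""
  t_of <- ann$frames$t[match(fidx[used], ann$frames$frame_index)]
  data.frame(frame_index = fidx[used], t = t_of,
             side = out_side[used], cx = cx[used], cy = cy[used])
}

#' Grasper speed (px/s)
#'
#' Per grasper, the average over consecutive detected-frame pairs of centroid
#' displacement divided by the timestamp difference; the session value is the
#' sum of the left and right averages. Pairs that are not adjacent frames
#' (a missed detection on either side) are skipped rather than interpolated,
#' so occlusions do not fabricate motion.
#'
#' @param ann an `aoi_annotations` object.
#' @return speed in px/s, with attribute `per_side`. `NA` (with a warning)
#'   when no grasper is detected in at least two adjacent frames.
#' @export
tool_speed <- function(ann) {
  tr <- tool_tracks(ann)
  per_side <- c(left = NA_real_, right = NA_real_)
  for (s in c("left", "right")) {
    d <- tr[tr$side == s, , drop = FALSE]
    if (nrow(d) >= 2L) {
      adj <- diff(d$frame_index) == 1L
      if (any(adj)) {
        sp <- sqrt(diff(d$cx)^2 + diff(d$cy)^2) / diff(d$t)
        per_side[s] <- mean(sp[adj])
      }
    }
  }
  if (all(is.na(per_side))) {
    warning("no grasper detected in two adjacent frames; tool speed undefined",
            call. = FALSE)
    return(structure(NA_real_, per_side = per_side))
  }
  structure(sum(per_side, na.rm = TRUE), per_side = per_side)
}

#' Compute the full per-session metric row
#'
#' Runs the I-VT filter, maps fixations to frames, and assembles the five
#' fixation rates, the grasper speed, and the session metadata into one row.
#'
#' @param ann an `aoi_annotations` object.
#' @param gaze a [gaze_trace()] on the same clock.
#' @param metadata list with elements `completion_time` (seconds; defaults to
#'   `n_frames / fps` inferred from frame timestamps), `errors`, `trainer`
#'   (`"pediatric"`/`"adult"`), `participant_id`, `session_id`.
#' @param geometry a [screen_geometry()].
#' @param ivt an [ivt_config()].
#' @param aoi an [aoi_config()].
#' @return one-row data.frame with `session_id, participant_id, trainer,
#'   completion_time, errors`, the five `fr_*` rates and `tool_speed`.
#' @export
compute_session_metrics <- function(ann, gaze, metadata = list(),
                                    geometry = screen_geometry(),
                                    ivt = ivt_config(), aoi = aoi_config()) {
  ct <- metadata$completion_time
  if (is.null(ct)) {
    tf <- frame_times(ann)
    dt <- if (length(tf) > 1) median(diff(tf)) else 0.04
    ct <- length(tf) * dt
  }
  fx <- ivt_classify(gaze, geometry, ivt)
  hits <- map_fixations_to_frames(fx, ann, aoi)
  rates <- fixation_rates(hits, ct)
  sp <- suppressWarnings(tool_speed(ann))
  data.frame(
    session_id = metadata$session_id %||% NA_character_,
    participant_id = metadata$participant_id %||% NA_character_,
    trainer = metadata$trainer %||% "adult",
    completion_time = ct,
    errors = metadata$errors %||% NA_integer_,
    fr_tools = rates[["fr_tools"]],
    fr_objects = rates[["fr_objects"]],
    fr_obj_1tool = rates[["fr_obj_1tool"]],
    fr_obj_2tools = rates[["fr_obj_2tools"]],
    fr_not_moving = rates[["fr_not_moving"]],
    tool_speed = as.numeric(sp)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohen's kappa for frame-wise agreement
#'
#' Chance-corrected agreement between two equal-length categorical sequences:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and
#' `p_e` the agreement expected from the marginal label frequencies. When both
#' sequences are the same constant (`p_e = 1`), kappa is defined as 1.
#'
#' @param a,b equal-length vectors of categorical labels.
#' @return kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(c(1, 1, 0), c(1, 1, 0)) # 1
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b))
    stop("label sequences must have equal length", call. = FALSE)
  if (!length(a)) stop("empty label sequences", call. = FALSE)
  a <- as.character(a); b <- as.character(b)
  labs <- union(unique(a), unique(b))
  n <- length(a)
  p_o <- mean(a == b)
  pa <- table(factor(a, levels = labs)) / n
  pb <- table(factor(b, levels = labs)) / n
  p_e <- sum(pa * pb)
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Read / write per-session metric tables
#'
#' One row per session with the columns produced by
#' [compute_session_metrics()].
#'
#' @param metrics metric data.frame.
#' @param path file path.
#' @export
write_metrics_csv <- function(metrics, path) {
  data.table::fwrite(metrics, path)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}
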
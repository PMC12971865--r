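# Synthetic peg-transfer session generator.
#
# A session scripts two graspers transferring six pegboard triangles from the
# non-dominant side to the dominant side (reach -> carry -> mid-air transfer
# -> place, per object), renders per-frame instance polygons in the COCO
# dialect, and draws a 50 Hz gaze trace from a skill-archetype gaze policy
# that aims dwells at the held object, the next object, the active grasper,
# or the background. Skill archetypes (HIGH / MID / LOW) differ in gaze
# allocation, grasper wander speed, completion time and drop rate, in the
# directions reported for high- vs low-proficiency novices (object-directed
# gaze for high skill; tool-following gaze, faster erratic tool motion, more
# drop-driven gaze to static objects for low skill).

ARCHETYPES <- c("HIGH", "MID", "LOW")

#' Simulator configuration
#'
#' Defaults encode the stated world of the generator: a 24-session cohort
#' shaped 5/14/5 across HIGH/MID/LOW archetypes, 25 fps video of a 1920x1080
#' arena, 50 Hz gaze, completion-time means 120/233/282 s, and archetype gaze
#' policies/speeds that reproduce the skill directionality described above.
#'
#' @param n_sessions number of sessions in a cohort.
#' @param archetype_mix named proportions over HIGH/MID/LOW, summing to 1.
#' @param fps video frame rate (frames/s).
#' @param gaze_hz gaze sampling rate (samples/s).
#' @param arena arena width and height in pixels.
#' @param duration_mean,duration_sd per-archetype completion-time mean and sd
#'   in seconds.
#' @param duration_scale multiplier applied to duration mean/sd; < 1 shortens
#'   sessions proportionally (used to scale runtime down without touching
#'   effect sizes).
#' @param gaze_policy 3x4 matrix (rows HIGH/MID/LOW) of dwell-target
#'   probabilities over `held, next, tool, background`; rows sum to 1.
#' @param speed_scale per-archetype grasper wander speed target (px/s per
#'   grasper).
#' @param error_rate per-archetype expected number of drops per session.
#' @param gaze_jitter_sd isotropic Gaussian gaze jitter, px.
#' @param dwell_mean mean gaze dwell duration, seconds.
#' @param validity_rate probability a gaze sample is valid.
#' @param dropout_rate probability an instance detection is missing from a
#'   frame.
#' @param drop_dwell seconds gaze stays on a dropped object.
#' @param trainer_speed_factor grasper speed multiplier for pediatric-trainer
#'   sessions (1 = no trainer effect).
#' @param n_both number of participants performing on both trainers (two
#'   sessions each); default `floor(n_sessions / 4)`.
#' @param seed integer seed for the cohort.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sessions = 24,
                       archetype_mix = c(HIGH = 5 / 24, MID = 14 / 24, LOW = 5 / 24),
                       fps = 25, gaze_hz = 50, arena = c(1920, 1080),
                       duration_mean = c(HIGH = 120, MID = 233, LOW = 282),
                       duration_sd = c(HIGH = 20, MID = 45, LOW = 50),
                       duration_scale = 1,
                       gaze_policy = rbind(
                         HIGH = c(held = 0.62, next_obj = 0.07, tool = 0.10, background = 0.21),
                         MID  = c(held = 0.32, next_obj = 0.10, tool = 0.22, background = 0.36),
                         LOW  = c(held = 0.22, next_obj = 0.17, tool = 0.42, background = 0.19)),
                       speed_scale = c(HIGH = 250, MID = 300, LOW = 390),
                       error_rate = c(HIGH = 0.5, MID = 1.5, LOW = 2.5),
                       gaze_jitter_sd = 8, dwell_mean = 0.35,
                       validity_rate = 0.97, dropout_rate = 0.005,
                       drop_dwell = 1.5, trainer_speed_factor = 1,
                       n_both = NULL, seed = 1) {
  cfg <- list(n_sessions = n_sessions, archetype_mix = archetype_mix, fps = fps,
              gaze_hz = gaze_hz, arena = arena, duration_mean = duration_mean,
              duration_sd = duration_sd, duration_scale = duration_scale,
              gaze_policy = gaze_policy, speed_scale = speed_scale,
              error_rate = error_rate, gaze_jitter_sd = gaze_jitter_sd,
              dwell_mean = dwell_mean, validity_rate = validity_rate,
              dropout_rate = dropout_rate, drop_dwell = drop_dwell,
              trainer_speed_factor = trainer_speed_factor,
              n_both = if (is.null(n_both)) max(0L, floor(n_sessions / 4)) else n_both,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$archetype_mix) == 0L || sum(cfg$archetype_mix) == 0)
    stop("archetype_mix must be a nonempty set of proportions", call. = FALSE)
  if (abs(sum(cfg$archetype_mix) - 1) > 1e-6)
    stop("archetype_mix must sum to 1", call. = FALSE)
  if (!all(names(cfg$archetype_mix) %in% ARCHETYPES))
    stop("archetype_mix names must be among HIGH, MID, LOW", call. = FALSE)
  if (cfg$fps <= 0 || cfg$gaze_hz <= 0)
    stop("fps and gaze_hz must be positive", call. = FALSE)
  gp <- cfg$gaze_policy
  if (any(gp < 0 | gp > 1) || any(abs(rowSums(gp) - 1) > 1e-6))
    stop("each gaze_policy row must be probabilities summing to 1", call. = FALSE)
  invisible(cfg)
}

# piecewise-linear keyframe interpolation onto frame times
interp_path <- function(key_t, key_xy, t_out) {
  keep <- !duplicated(key_t)
  cbind(approx(key_t[keep], key_xy[keep, 1], xout = t_out, rule = 2)$y,
        approx(key_t[keep], key_xy[keep, 2], xout = t_out, rule = 2)$y)
}

# bounded erratic wander: small-amplitude AR(1) tremor around the scripted
# path, rescaled so the realized mean per-frame displacement equals step_px.
# High-frequency/low-amplitude keeps the held object close to a fixation
# centroid while still carrying the archetype's speed signature.
gen_wander <- function(n, step_px, rho = 0.5) {
  if (n < 2L || step_px <= 0) return(matrix(0, n, 2))
  e <- matrix(rnorm(2L * n), n, 2)
  w <- apply(e, 2, function(v) as.numeric(stats::filter(v, rho, "recursive")))
  m <- mean(sqrt(rowSums(diff(w)^2)))
  if (m > 0) w <- w * (step_px / m)
  w
}

#' Simulate one peg-transfer session
#'
#' @param archetype `"HIGH"`, `"MID"` or `"LOW"`.
#' @param config a [sim_config()].
#' @param seed integer seed; identical `(archetype, config, seed)` give
#'   byte-identical sessions.
#' @param trainer `"adult"` or `"pediatric"`.
#' @return a `sim_session` list: `annotations` (an `aoi_annotations`), `gaze`
#'   (a [gaze_trace()]), `truth_archetype`, `completion_time`, `errors`,
#'   `trainer`, `participant_id`, `session_id`.
#' @export
simulate_session <- function(archetype, config = sim_config(), seed = 1,
                             trainer = c("adult", "pediatric")) {
  if (length(archetype) != 1L || !archetype %in% ARCHETYPES)
    stop("archetype must be one of ", paste(ARCHETYPES, collapse = ", "),
         " (got '", paste(archetype, collapse = ","), "')", call. = FALSE)
  trainer <- match.arg(trainer)
  validate_sim_config(config)
  set.seed(as.integer(seed))
  fps <- config$fps
  W <- config$arena[1]; H <- config$arena[2]
  sc <- config$duration_scale

  dur <- rnorm(1, config$duration_mean[archetype] * sc,
               config$duration_sd[archetype] * sc)
  dur <- max(dur, 0.4 * config$duration_mean[archetype] * sc, 2)
  n_fr <- max(round(dur * fps), 12L)
  completion_time <- n_fr / fps
  tfr <- (seq_len(n_fr) - 1L) / fps

  # pegboard layout: six start pegs (non-dominant side), six targets
  col_x <- c(0.22, 0.30); row_y <- c(0.35, 0.50, 0.65)
  start_xy <- cbind(W * rep(col_x, 3) + runif(6, -10, 10),
                    H * rep(row_y, each = 2) + runif(6, -10, 10))
  targ_xy <- cbind(W * rep(col_x + 0.48, 3) + runif(6, -10, 10),
                   H * rep(row_y, each = 2) + runif(6, -10, 10))
  trans_xy <- cbind(W * 0.50 + runif(6, -30, 30), H * 0.45 + runif(6, -20, 20))
  rest_l <- c(W * 0.38, H * 0.78); rest_r <- c(W * 0.62, H * 0.78)

  seg <- completion_time / 6
  t0 <- (0:5) * seg
  # Sub-phase durations scale with the segment (90% active, 10% hover at a
  # standoff before grasping), so the share of time each gaze target exists
  # is the same for every session and the archetype gaze policy alone drives
  # the AOI allocation; session pace shows up as scripted grasper speed.
  base <- c(reach = 4, grasp = 0.5, carry = 6, transfer = 2, place = 5.5)
  f <- 0.9 * seg / sum(base)
  dr <- base[["reach"]] * f; dg <- base[["grasp"]] * f
  dc <- base[["carry"]] * f; dt_ <- base[["transfer"]] * f
  dp <- base[["place"]] * f
  idle <- seg - (dr + dg + dc + dt_ + dp)
  hover_end <- t0 + dr + idle
  grasp_t <- hover_end + dg
  trans_start <- grasp_t + dc
  trans_end <- trans_start + dt_
  place_end <- t0 + seg

  # standoff point 60 px from each start peg, toward the left rest position
  sdir <- sweep(-start_xy, 2, rest_l, "+")
  sdir <- sdir / pmax(sqrt(rowSums(sdir^2)), 1)
  stand_xy <- start_xy + 60 * sdir

  # left grasper: rest -> standoff (hover) -> grasp -> transfer -> rest
  kt_l <- c(0, as.vector(rbind(t0 + dr, hover_end, grasp_t, trans_start,
                               trans_end, place_end)))
  kv_l <- rbind(rest_l, do.call(rbind, lapply(1:6, function(i)
    rbind(stand_xy[i, ], stand_xy[i, ], start_xy[i, ], trans_xy[i, ],
          trans_xy[i, ], rest_l))))
  # right grasper: rest until transfer, meet mid-air, place, back to rest
  r_off <- c(12, 0)
  kt_r <- c(0, as.vector(rbind(trans_start, (trans_start + trans_end) / 2,
                               trans_end, place_end,
                               pmin(place_end + 2 * f, completion_time))))
  kv_r <- rbind(rest_r, do.call(rbind, lapply(1:6, function(i)
    rbind(rest_r, trans_xy[i, ] + r_off, trans_xy[i, ] + r_off,
          targ_xy[i, ], rest_r))))
  speed <- config$speed_scale[archetype] *
    (if (trainer == "pediatric") config$trainer_speed_factor else 1)
  step_px <- speed / fps
  tip_l <- interp_path(kt_l, kv_l, tfr) + gen_wander(n_fr, step_px)
  tip_r <- interp_path(kt_r, kv_r, tfr) + gen_wander(n_fr, step_px)
  tip_l[, 1] <- pmin(pmax(tip_l[, 1], 20), W - 20)
  tip_l[, 2] <- pmin(pmax(tip_l[, 2], 20), H - 20)
  tip_r[, 1] <- pmin(pmax(tip_r[, 1], 20), W - 20)
  tip_r[, 2] <- pmin(pmax(tip_r[, 2], 20), H - 20)

  # object centroids: static on peg, then follow the holding grasper tip
  held_off <- c(0, 4)
  obj_x <- matrix(0, n_fr, 6); obj_y <- matrix(0, n_fr, 6)
  for (i in 1:6) {
    x <- rep(start_xy[i, 1], n_fr); y <- rep(start_xy[i, 2], n_fr)
    carry <- tfr >= grasp_t[i] & tfr < trans_end[i]   # held by left (and both)
    place <- tfr >= trans_end[i] & tfr < place_end[i] # held by right
    done <- tfr >= place_end[i]
    x[carry] <- tip_l[carry, 1] + held_off[1]
    y[carry] <- tip_l[carry, 2] + held_off[2]
    x[place] <- tip_r[place, 1] + held_off[1]
    y[place] <- tip_r[place, 2] + held_off[2]
    x[done] <- targ_xy[i, 1]; y[done] <- targ_xy[i, 2]
    obj_x[, i] <- x; obj_y[, i] <- y
  }

  # drops: the object teleports to a random free spot for drop_dwell seconds
  # and gaze is pulled to it; afterwards the transfer resumes
  n_err <- rpois(1, config$error_rate[archetype])
  drops <- NULL
  if (n_err > 0) {
    for (e in seq_len(n_err)) {
      i <- sample(1:6, 1)
      t_d <- runif(1, grasp_t[i] + 0.2 * dc, trans_start[i] - 0.1 * dc)
      loc <- c(runif(1, 0.32 * W, 0.68 * W), runif(1, 0.55 * H, 0.85 * H))
      win <- c(t_d, min(t_d + config$drop_dwell, completion_time))
      in_win <- tfr >= win[1] & tfr < win[2]
      obj_x[in_win, i] <- loc[1]; obj_y[in_win, i] <- loc[2]
      drops <- rbind(drops, c(win, loc))
    }
  }

  phases <- list(t0 = t0, grasp_t = grasp_t, trans_end = trans_end,
                 place_end = place_end)
  anchors <- list(l = c(0.12 * W, 1.08 * H), r = c(0.88 * W, 1.08 * H))
  ann <- build_sim_annotations(tfr, obj_x, obj_y, tip_l, tip_r, config,
                               W, H, anchors)
  gaze <- build_sim_gaze(archetype, config, completion_time, tfr, phases,
                         obj_x, obj_y, tip_l, tip_r, targ_xy,
                         drops, W, H, anchors)
  structure(list(annotations = ann, gaze = gaze, truth_archetype = archetype,
                 completion_time = completion_time, errors = n_err,
                 trainer = trainer, participant_id = NA_character_,
                 session_id = NA_character_, seed = as.integer(seed)),
            class = "sim_session")
}

# render triangle + grasper polygons into a columnar aoi_annotations
build_sim_annotations <- function(tfr, obj_x, obj_y, tip_l, tip_r, config,
                                  W, H, anchors) {
  n_fr <- length(tfr)
  tri_R <- 60 / sqrt(3) # circumradius of a 60 px equilateral triangle
  phi <- runif(6, 0, 2 * pi)
  shaft_len <- 180; half_w <- 14
  anchor_l <- anchors$l; anchor_r <- anchors$r

  vobj <- vector("list", 6)
  for (i in 1:6) {
    a <- phi[i] + c(0, 2, 4) * pi / 3
    vobj[[i]] <- cbind(
      obj_x[, i] + tri_R * cos(a[1]), obj_y[, i] + tri_R * sin(a[1]),
      obj_x[, i] + tri_R * cos(a[2]), obj_y[, i] + tri_R * sin(a[2]),
      obj_x[, i] + tri_R * cos(a[3]), obj_y[, i] + tri_R * sin(a[3]))
  }
  tool_quad <- function(tip, anchor) {
    dx <- tip[, 1] - anchor[1]; dy <- tip[, 2] - anchor[2]
    L <- pmax(sqrt(dx^2 + dy^2), 1)
    ux <- dx / L; uy <- dy / L
    px <- -uy; py <- ux
    cbind(tip[, 1] + px * half_w, tip[, 2] + py * half_w,
          tip[, 1] - px * half_w, tip[, 2] - py * half_w,
          tip[, 1] - ux * shaft_len - px * half_w,
          tip[, 2] - uy * shaft_len - py * half_w,
          tip[, 1] - ux * shaft_len + px * half_w,
          tip[, 2] - uy * shaft_len + py * half_w)
  }
  vtl <- tool_quad(tip_l, anchor_l)
  vtr <- tool_quad(tip_r, anchor_r)

  frame_v <- c(rep(0:(n_fr - 1L), 6), rep(0:(n_fr - 1L), 2))
  id_v <- c(rep(1:6, each = n_fr), rep(c(101L, 102L), each = n_fr))
  block_v <- c(seq_len(6L * n_fr), seq_len(2L * n_fr))
  is_obj_v <- rep(c(TRUE, FALSE), c(6L * n_fr, 2L * n_fr))
  score_v <- runif(length(frame_v), 0.55, 0.99)
  keep <- runif(length(frame_v)) >= config$dropout_rate
  ord <- order(frame_v[keep], id_v[keep])
  frame_v <- frame_v[keep][ord]; id_v <- id_v[keep][ord]
  block_v <- block_v[keep][ord]; is_obj <- is_obj_v[keep][ord]
  score_v <- score_v[keep][ord]
  nv <- ifelse(is_obj, 3L, 4L)

  v_obj_mat <- do.call(rbind, vobj) # (6*n_fr) x 6, rows indexed by block_v
  v_tool_mat <- rbind(vtl, vtr)
  # flatten per-row interleaved (x1,y1,...) blocks into the vertex array
  flat_rows <- function(m, rows) {
    if (!length(rows)) return(matrix(numeric(0), 0, 2))
    matrix(t(m[rows, , drop = FALSE]), ncol = 2, byrow = TRUE)
  }
  vert_obj <- flat_rows(v_obj_mat, block_v[is_obj])
  vert_tool <- flat_rows(v_tool_mat, block_v[!is_obj])
  # stitch vertices back in instance order
  vertices <- matrix(0, 3L * sum(is_obj) + 4L * sum(!is_obj), 2)
  offsets <- c(0L, cumsum(nv))
  tgt <- sequence(nv, from = offsets[-length(offsets)] + 1L)
  src_is_obj <- rep(is_obj, nv)
  vertices[tgt[src_is_obj], ] <- vert_obj
  vertices[tgt[!src_is_obj], ] <- vert_tool

  frames <- data.frame(frame_index = 0:(n_fr - 1L), t = tfr)
  inst <- data.frame(frame_index = frame_v, instance_id = id_v,
                     category = ifelse(is_obj, "object", "tool"),
                     score = score_v)
  aoi_annotations(frames, inst, vertices, offsets, arena = c(W, H),
                  validate = FALSE)
}

# draw the dwell-structured gaze trace
build_sim_gaze <- function(archetype, config, completion_time, tfr, phases,
                           obj_x, obj_y, tip_l, tip_r, targ_xy,
                           drops, W, H, anchors) {
  tg <- seq(0, completion_time, by = 1 / config$gaze_hz)
  n_g <- length(tg)
  policy <- config$gaze_policy[archetype, ]

  # entity positions at gaze times
  at_g <- function(m) cbind(approx(tfr, m[, 1], xout = tg, rule = 2)$y,
                            approx(tfr, m[, 2], xout = tg, rule = 2)$y)
  tip_l_g <- at_g(tip_l); tip_r_g <- at_g(tip_r)
  ox_g <- apply(obj_x, 2, function(v) approx(tfr, v, xout = tg, rule = 2)$y)
  oy_g <- apply(obj_y, 2, function(v) approx(tfr, v, xout = tg, rule = 2)$y)

  # dwell schedule
  n_dwell_max <- ceiling(completion_time / config$dwell_mean * 3) + 10L
  durs <- rgamma(n_dwell_max, shape = 2, rate = 2 / config$dwell_mean)
  starts <- c(0, cumsum(durs))
  n_dwell <- which(starts >= completion_time)[1]
  starts <- starts[seq_len(n_dwell)]
  dwell_cat <- sample(c("held", "next_obj", "tool", "background"), n_dwell,
                      replace = TRUE, prob = policy)
  dwell_bg <- cbind(runif(n_dwell, 50, W - 50), runif(n_dwell, 50, H - 50))
  dwell_of <- findInterval(tg, starts, rightmost.closed = FALSE)
  dwell_of <- pmin(pmax(dwell_of, 1L), n_dwell)

  # per-sample phase bookkeeping (actual per-object phase boundaries)
  io <- pmin(findInterval(tg, phases$t0), 6L)
  io <- pmax(io, 1L)
  rows <- seq_len(n_g)
  pre_grasp <- tg < phases$grasp_t[io]          # nothing held yet
  in_place <- tg >= phases$trans_end[io]        # right grasper active
  obj_act <- cbind(ox_g[cbind(rows, io)], oy_g[cbind(rows, io)])
  tip_act <- ifelse(matrix(in_place, n_g, 2), tip_r_g, tip_l_g)
  # gaze on the "tool" aims a little down the shaft (interior, stable point)
  anc <- ifelse(matrix(in_place, n_g, 2),
                matrix(anchors$r, n_g, 2, byrow = TRUE),
                matrix(anchors$l, n_g, 2, byrow = TRUE))
  dvec <- tip_act - anc
  dlen <- pmax(sqrt(rowSums(dvec^2)), 1)
  tool_tgt <- tip_act - 60 * dvec / dlen
  held_tgt <- ifelse(matrix(pre_grasp, n_g, 2), tool_tgt, obj_act)
  nxt <- pmin(io + 1L, 6L)
  next_tgt <- cbind(ox_g[cbind(rows, nxt)], oy_g[cbind(rows, nxt)])
  spare <- sample(1:5, 1) # "next" target once the last object is active
  next_tgt[io == 6L, 1] <- targ_xy[spare, 1]
  next_tgt[io == 6L, 2] <- targ_xy[spare, 2]

  cat_s <- dwell_cat[dwell_of]
  target <- held_tgt
  target[cat_s == "tool", ] <- tool_tgt[cat_s == "tool", ]
  target[cat_s == "next_obj", ] <- next_tgt[cat_s == "next_obj", ]
  target[cat_s == "background", ] <- dwell_bg[dwell_of[cat_s == "background"], ]

  if (!is.null(drops)) {
    for (e in seq_len(nrow(drops))) {
      in_win <- tg >= drops[e, 1] & tg < drops[e, 2]
      target[in_win, 1] <- drops[e, 3]
      target[in_win, 2] <- drops[e, 4]
    }
  }

  # corrective saccade at every dwell boundary: the first sample of a dwell
  # overshoots by ~180 px, which reliably crosses the I-VT threshold and
  # keeps pursuit fixations from merging across dwells
  bnd <- which(diff(dwell_of) != 0L) + 1L
  if (length(bnd)) {
    ang <- runif(length(bnd), 0, 2 * pi)
    target[bnd, 1] <- target[bnd, 1] + 180 * cos(ang)
    target[bnd, 2] <- target[bnd, 2] + 180 * sin(ang)
  }

  x <- target[, 1] + rnorm(n_g, 0, config$gaze_jitter_sd)
  y <- target[, 2] + rnorm(n_g, 0, config$gaze_jitter_sd)
  valid <- runif(n_g) < config$validity_rate
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  gaze_trace(tg, x, y, valid)
}

#' Simulate a cohort of sessions with ground-truth archetypes
#'
#' Archetype counts follow `archetype_mix` up to largest-remainder rounding.
#' `n_both` participants contribute a session on each trainer (same archetype
#' for both, skill being a participant trait); the remaining participants
#' contribute one session on alternating trainers.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort` list: `sessions` (list of `sim_session`) and
#'   `truth` (data.frame `session_id, participant_id, archetype, trainer,
#'   seed`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n_sessions
  if (n < 1) stop("n_sessions must be >= 1", call. = FALSE)
  set.seed(config$seed)
  mix <- config$archetype_mix[config$archetype_mix > 0]
  # largest-remainder apportionment of sessions to archetypes
  raw <- mix * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  remaining <- cnt
  n_both <- min(config$n_both, floor(n / 2))
  n_single <- n - 2L * n_both

  part_arch <- character(0); part_paired <- logical(0)
  for (p in seq_len(n_both)) {
    a <- names(remaining)[which.max(remaining)]
    if (remaining[a] >= 2) {
      remaining[a] <- remaining[a] - 2
      part_arch <- c(part_arch, a); part_paired <- c(part_paired, TRUE)
    } else {
      # split pair across the two largest remaining archetypes
      o <- names(sort(remaining, decreasing = TRUE))[1:2]
      remaining[o] <- remaining[o] - 1
      part_arch <- c(part_arch, paste(o, collapse = "|"))
      part_paired <- c(part_paired, TRUE)
    }
  }
  single_arch <- rep(names(remaining), times = pmax(remaining, 0))
  part_arch <- c(part_arch, single_arch)
  part_paired <- c(part_paired, rep(FALSE, length(single_arch)))

  sessions <- list(); truth <- NULL
  si <- 0L
  single_ped <- FALSE
  for (p in seq_along(part_arch)) {
    pid <- sprintf("P%02d", p)
    archs <- strsplit(part_arch[p], "|", fixed = TRUE)[[1]]
    if (part_paired[p]) {
      trainers <- c("adult", "pediatric")
      if (length(archs) == 1L) archs <- rep(archs, 2)
    } else {
      single_ped <- !single_ped
      trainers <- if (single_ped) "pediatric" else "adult"
    }
    for (k in seq_along(trainers)) {
      si <- si + 1L
      s_seed <- (config$seed * 1009L + si * 9973L) %% 2147483587L + 1L
      ses <- simulate_session(archs[k], config, seed = s_seed,
                              trainer = trainers[k])
      ses$participant_id <- pid
      ses$session_id <- sprintf("S%03d", si)
      sessions[[si]] <- ses
      truth <- rbind(truth, data.frame(
        session_id = ses$session_id, participant_id = pid,
        archetype = archs[k], trainer = trainers[k],
        completion_time = ses$completion_time, errors = ses$errors,
        seed = s_seed))
    }
  }
  structure(list(sessions = sessions, truth = truth, config = config),
            class = "sim_cohort")
}

#' Extract the metric table of a simulated cohort
#'
#' Runs [compute_session_metrics()] over every session.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param geometry,ivt,aoi pipeline configurations.
#' @return data.frame, one metric row per session, joined with the
#'   ground-truth archetype.
#' @export
cohort_metrics <- function(cohort, geometry = screen_geometry(),
                           ivt = ivt_config(), aoi = aoi_config()) {
  rows <- lapply(cohort$sessions, function(s)
    compute_session_metrics(
      s$annotations, s$gaze,
      metadata = list(session_id = s$session_id,
                      participant_id = s$participant_id,
                      trainer = s$trainer, errors = s$errors,
                      completion_time = s$completion_time),
      geometry = geometry, ivt = ivt, aoi = aoi))
  out <- do.call(rbind, rows)
  out$archetype <- cohort$truth$archetype[match(out$session_id,
                                                cohort$truth$session_id)]
  out
}

#' Write cohort fixtures to disk
#'
#' One annotation JSON and one gaze CSV per session plus a cohort
#' `metadata.csv`, all round-trippable with [load_annotations()] and
#' [read_gaze_csv()].
#'
#' @param sessions list of `sim_session` objects (or a `sim_cohort`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_fixtures <- function(sessions, out_dir) {
  if (inherits(sessions, "sim_cohort")) sessions <- sessions$sessions
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character(0)
  meta <- data.frame(session_id = character(0), participant_id = character(0),
                     trainer = character(0), completion_time_s = numeric(0),
                     errors = integer(0), archetype = character(0))
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]
    sid <- if (is.na(s$session_id)) sprintf("S%03d", k) else s$session_id
    fa <- file.path(out_dir, paste0(sid, ".annotations.json"))
    fg <- file.path(out_dir, paste0(sid, ".gaze.csv"))
    write_annotations(s$annotations, fa)
    write_gaze_csv(s$gaze, fg)
    files <- c(files, fa, fg)
    meta <- rbind(meta, data.frame(
      session_id = sid, participant_id = s$participant_id,
      trainer = s$trainer, completion_time_s = s$completion_time,
      errors = s$errors, archetype = s$truth_archetype))
  }
  fm <- file.path(out_dir, "metadata.csv")
  data.table::fwrite(meta, fm)
  invisible(c(files, fm))
}

#' Read / write a simulator configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_sim_config()`: a [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gaze_policy)) {
    gp <- do.call(rbind, lapply(y$gaze_policy, unlist))
    y$gaze_policy <- gp / rowSums(gp) # undo YAML rounding
  }
  for (f in c("archetype_mix", "duration_mean", "duration_sd", "speed_scale",
              "error_rate"))
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  if (!is.null(y$archetype_mix))
    y$archetype_mix <- y$archetype_mix / sum(y$archetype_mix)
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param config a [sim_config()] to serialize.
#' @export
write_sim_config <- function(config, path) {
  y <- unclass(config)
  y$gaze_policy <- apply(config$gaze_policy, 1, as.list, simplify = FALSE)
  y$archetype_mix <- as.list(config$archetype_mix)
  y$duration_mean <- as.list(config$duration_mean)
  y$duration_sd <- as.list(config$duration_sd)
  y$speed_scale <- as.list(config$speed_scale)
  y$error_rate <- as.list(config$error_rate)
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}
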
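test_that("fixation rates: arithmetic, empty input, and the rate bound", {
  expect_error(fixation_rates(NULL, 0), "completion_time")
  hits0 <- data.frame(fixation_id = integer(0), frame_index = integer(0),
                      category = factor(character(0),
                                        levels = gazeskill:::AOI_CATEGORIES))
  expect_true(all(fixation_rates(hits0, 10) == 0))

  hits <- data.frame(fixation_id = 1L, frame_index = 0:119,
                     category = factor("OBJ_NOT_MOVING",
                                       levels = gazeskill:::AOI_CATEGORIES))
  r <- fixation_rates(hits, 60)
  expect_equal(unname(r["fr_not_moving"]), 2)
  expect_equal(unname(r["fr_objects"]), 2)
  expect_equal(unname(r["fr_tools"]), 0)
})

test_that("frames are deduplicated per category across fixations", {
  # two fixations crediting the same frames: each frame counts once
  hits <- data.frame(
    fixation_id = rep(1:2, each = 5),
    frame_index = c(0:4, 2:6),
    category = factor("TOOL_ONLY", levels = gazeskill:::AOI_CATEGORIES))
  r <- fixation_rates(hits, 7 / 25)
  expect_equal(unname(r["fr_tools"]), 7 / (7 / 25)) # 7 distinct frames
  # brute-force union of frame sets
  expect_equal(unname(r["fr_tools"]) * (7 / 25), length(union(0:4, 2:6)))
})

test_that("doubling completion time halves every rate", {
  set.seed(3)
  hits <- data.frame(fixation_id = 1L, frame_index = sample(0:400, 150),
                     category = factor(
                       sample(gazeskill:::AOI_CATEGORIES, 150, replace = TRUE),
                       levels = gazeskill:::AOI_CATEGORIES))
  expect_equal(fixation_rates(hits, 40), 2 * fixation_rates(hits, 80))
})

test_that("partition invariant holds on simulated sessions", {
  for (seed in 1:3) {
    s <- simulate_session(sample(c("HIGH", "MID", "LOW"), 1),
                          fast_cfg(seed = seed), seed = seed)
    hits <- map_fixations_to_frames(ivt_classify(s$gaze), s$annotations)
    r <- fixation_rates(hits, s$completion_time)
    expect_equal(unname(r["fr_objects"]),
                 unname(r["fr_obj_1tool"] + r["fr_obj_2tools"] +
                        r["fr_not_moving"]),
                 tolerance = 1e-12)
  }
})

test_that("tool speed recovers scripted kinematics", {
  # both stationary
  ann0 <- make_tool_annotations(50)
  expect_equal(as.numeric(tool_speed(ann0)), 0)
  # one at 250 px/s, other stationary
  ann1 <- make_tool_annotations(100, v_left = c(200, 150))
  expect_equal(as.numeric(tool_speed(ann1)), 250, tolerance = 1e-9)
  # sum rule: both at 100 px/s
  ann2 <- make_tool_annotations(100, v_left = c(100, 0), v_right = c(0, 100))
  expect_equal(as.numeric(tool_speed(ann2)), 200, tolerance = 1e-9)
})

test_that("tool speed skips missing detections and is subsample-invariant", {
  ann <- make_tool_annotations(100, v_left = c(120, 0), v_right = c(0, 90))
  full <- as.numeric(tool_speed(ann))

  # drop every other frame's instances: no adjacent pairs remain -> undefined
  keep <- ann$instances$frame_index %% 2L == 0L
  ro <- gazeskill:::reorder_vertices(ann$vertices, ann$offsets, which(keep))
  ann_half <- aoi_annotations(ann$frames, ann$instances[keep, 1:4],
                              ro$vertices, ro$offsets, validate = FALSE)
  expect_warning(sp <- tool_speed(ann_half), "undefined")
  expect_true(is.na(sp))

  # subsample the *frames* by 2 (constant velocity): speed unchanged
  fr2 <- ann$frames[ann$frames$frame_index %% 2L == 0L, ]
  ann_sub <- aoi_annotations(fr2, ann$instances[keep, 1:4],
                             ro$vertices, ro$offsets, validate = FALSE)
  ann_sub$instances$frame_index <- ann_sub$instances$frame_index %/% 2L
  ann_sub$frames$frame_index <- ann_sub$frames$frame_index %/% 2L
  expect_equal(as.numeric(tool_speed(ann_sub)), full, tolerance = 1e-9)
})

test_that("grasper identities survive crossing", {
  # tools cross in x around the middle of the clip
  n <- 80; fps <- 25
  tfr <- (seq_len(n) - 1) / fps
  frames <- data.frame(frame_index = 0:(n - 1), t = tfr)
  lx <- 300 + 400 * tfr # moves right
  rx <- 1400 - 400 * tfr # moves left; they cross at t ~ 1.4
  inst <- NULL; polys <- list()
  for (i in seq_len(n)) {
    inst <- rbind(inst,
                  data.frame(frame_index = i - 1, instance_id = c(101L, 102L),
                             category = "tool", score = 0.9))
    polys <- c(polys, list(rect_poly(lx[i] - 30, 590, lx[i] + 30, 610),
                           rect_poly(rx[i] - 30, 690, rx[i] + 30, 710)))
  }
  nv <- vapply(polys, nrow, integer(1))
  ann <- aoi_annotations(frames, inst, do.call(rbind, polys),
                         c(0L, cumsum(nv)), validate = FALSE)
  tr <- tool_tracks(ann)
  left <- tr[tr$side == "left", ]
  # the left track stays on the y = 600 grasper even after the crossing
  expect_equal(unique(left$cy), 600)
  expect_equal(as.numeric(tool_speed(ann)), 800, tolerance = 1e-9)
})

test_that("session metric rows compose and round-trip", {
  s <- simulate_session("HIGH", fast_cfg(seed = 2), seed = 8)
  m <- compute_session_metrics(s$annotations, s$gaze,
                               metadata = list(session_id = "S1",
                                               participant_id = "P1",
                                               trainer = s$trainer,
                                               errors = s$errors,
                                               completion_time = s$completion_time))
  expect_equal(m$completion_time, s$completion_time)
  expect_true(all(m[, gazeskill:::METRIC_COLUMNS] >= 0))

  # empty gaze trace: rates 0, tool speed still computed
  m0 <- compute_session_metrics(
    s$annotations, gaze_trace(numeric(0), numeric(0), numeric(0)),
    metadata = list(completion_time = s$completion_time))
  expect_true(all(m0[, c("fr_tools", "fr_objects", "fr_obj_1tool",
                         "fr_obj_2tools", "fr_not_moving")] == 0))
  expect_gt(m0$tool_speed, 0)

  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(m, f)
  m2 <- read_metrics_csv(f)
  expect_equal(m2[, gazeskill:::METRIC_COLUMNS], m[, gazeskill:::METRIC_COLUMNS])
})

test_that("Cohen's kappa: closed forms, invariances, errors", {
  expect_equal(cohen_kappa(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(cohen_kappa(rep("x", 10), rep("x", 10)), 1) # p_e = 1 case

  # 2x2 agreement table (a=40, b=10, c=10, d=40): p_o = .8, p_e = .5
  a <- rep(c("T", "T", "F", "F"), c(40, 10, 10, 40))
  b <- rep(c("T", "F", "T", "F"), c(40, 10, 10, 40))
  expect_equal(cohen_kappa(a, b), 0.6)

  # permutation-invariance under label renaming
  ren <- c(T = "obj", F = "bg")
  expect_equal(cohen_kappa(ren[a], ren[b]), 0.6)

  expect_error(cohen_kappa(1:3, 1:4), "equal length")
})
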
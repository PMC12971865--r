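test_that("annotation JSON round-trips and applies the confidence floor", {
  ann <- make_frame_annotations(
    c("object", "tool"),
    list(tri_poly(300, 300), rect_poly(600, 580, 700, 620)))
  ann$instances$score <- c(0.49, 0.51)
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, f)
  got <- load_annotations(f) # default confidence_min = 0.5
  expect_equal(nrow(got$instances), 1L)
  expect_equal(got$instances$category, "tool")
  # 0.49 kept when the floor is lowered
  got2 <- load_annotations(f, aoi_config(confidence_min = 0.2))
  expect_equal(nrow(got2$instances), 2L)
  expect_equal(got2$instances$cx, ann$instances$cx, tolerance = 1e-9)
})

test_that("empty annotation files load to zero frames of instances", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    images = data.frame(id = 1L, frame_index = 0L, time_s = 0,
                        width = 1920L, height = 1080L, file_name = "f0.png"),
    categories = data.frame(id = 1:2, name = c("object", "tool")),
    annotations = list()), f, auto_unbox = TRUE)
  ann <- load_annotations(f)
  expect_equal(n_frames(ann), 1L)
  expect_equal(nrow(ann$instances), 0L)
  # downstream metrics are all zero
  fx <- data.frame(fixation_id = 1L, t_start = 0, t_end = 0.1,
                   cx = 10, cy = 10, duration = 0.1)
  r <- fixation_rates(map_fixations_to_frames(fx, ann), 10)
  expect_true(all(r == 0))
})

test_that("malformed input is rejected with location info", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(load_annotations(f), "malformed")

  bad <- list(
    images = data.frame(id = 1L, frame_index = 7L, time_s = 0,
                        width = 100L, height = 100L, file_name = "x"),
    categories = data.frame(id = 1:2, name = c("object", "tool")),
    annotations = data.frame(id = 5L, image_id = 1L, category_id = 1L,
                             score = 0.9))
  bad$annotations$segmentation <- list(list(c(0, 0, 10, 10))) # 2 vertices
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(load_annotations(f), "frame 7")

  bad$annotations$segmentation <- list(list(c(0, 0, 10, 0, 5, 8)))
  bad$annotations$category_id <- 9L
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(load_annotations(f), "category_id")

  expect_error(
    aoi_annotations(data.frame(frame_index = 0L, t = 0),
                    data.frame(frame_index = 0L, instance_id = 1L,
                               category = "object", score = 0.9),
                    cbind(c(0, 10, 0, 10), c(0, 10, 10, 0)), c(0L, 4L)),
    "self-intersecting")
})

test_that("object states count holding graspers, clamped at two", {
  obj <- tri_poly(500, 500)
  t1 <- rect_poly(480, 490, 560, 510) # overlaps the triangle
  t2 <- rect_poly(440, 495, 520, 515) # also overlaps
  t_far <- rect_poly(900, 900, 980, 920)

  fr0 <- frame_annotation(make_frame_annotations("object", list(obj)), 0)
  expect_equal(unname(object_states(fr0)), 0L)

  fr1 <- frame_annotation(make_frame_annotations(
    c("object", "tool", "tool"), list(obj, t1, t_far)), 0)
  expect_equal(unname(object_states(fr1)), 1L)

  fr2 <- frame_annotation(make_frame_annotations(
    c("object", "tool", "tool"), list(obj, t1, t2)), 0)
  expect_equal(unname(object_states(fr2)), 2L)
})

test_that("fixation-frame classification follows the precedence rules", {
  obj_free <- tri_poly(300, 300)
  obj_held <- tri_poly(900, 500)
  tool_hold <- rect_poly(880, 490, 960, 510)
  tool_far <- rect_poly(1500, 800, 1580, 820)
  ann <- make_frame_annotations(
    c("object", "object", "tool", "tool"),
    list(obj_free, obj_held, tool_hold, tool_far))
  fr <- frame_annotation(ann, 0)
  st <- object_states(fr)

  mk_fix <- function(x, y) data.frame(fixation_id = 1L, t_start = 0,
                                      t_end = 0.1, cx = x, cy = y,
                                      duration = 0.1)
  expect_equal(as.character(
    classify_fixation_frame(mk_fix(300, 300), fr, st)$category), "OBJ_NOT_MOVING")
  expect_equal(as.character(
    classify_fixation_frame(mk_fix(1540, 810), fr, st)$category), "TOOL_ONLY")
  # overlap zone: object hit wins over the tool and carries its held state
  expect_equal(as.character(
    classify_fixation_frame(mk_fix(900, 500), fr, st)$category), "OBJ_1TOOL")
  expect_equal(as.character(
    classify_fixation_frame(mk_fix(40, 40), fr, st)$category), "NONE")

  # literal pixel-intersection semantics: held object hit away from the tool
  # overlap region counts as not-moving
  lit <- aoi_config(category_semantics = "pixel_intersection")
  expect_equal(as.character(
    classify_fixation_frame(mk_fix(900, 480), fr, cfg = lit)$category),
    "OBJ_NOT_MOVING")
  expect_equal(as.character(
    classify_fixation_frame(mk_fix(900, 500), fr, cfg = lit)$category),
    "OBJ_1TOOL")
})

test_that("fixations map to every covered frame; sub-frame fixations map to none", {
  ann <- make_tool_annotations(50, fps = 25)
  fx <- data.frame(fixation_id = 1L, t_start = 0.50, t_end = 0.90,
                   cx = 10, cy = 10, duration = 0.4)
  hits <- map_fixations_to_frames(fx, ann)
  expect_true(nrow(hits) %in% c(10L, 11L)) # 0.4 s at 25 fps, phase-dependent
  expect_equal(hits$frame_index, seq(13L, by = 1L, length.out = nrow(hits)))

  between <- data.frame(fixation_id = 1L, t_start = 0.521, t_end = 0.529,
                        cx = 10, cy = 10, duration = 0.008)
  expect_equal(nrow(map_fixations_to_frames(between, ann)), 0L)

  outside <- data.frame(fixation_id = 1L, t_start = 100, t_end = 101,
                        cx = 10, cy = 10, duration = 1)
  expect_warning(out <- map_fixations_to_frames(outside, ann), "clock")
  expect_equal(nrow(out), 0L)
})

test_that("bulk classification agrees with the per-frame slow path", {
  s <- simulate_session("MID", fast_cfg(seed = 21), seed = 33)
  ann <- s$annotations
  fx <- head(ivt_classify(s$gaze), 12)
  hits <- map_fixations_to_frames(fx, ann)
  idx <- seq(1, nrow(hits), length.out = min(40, nrow(hits)))
  for (i in as.integer(idx)) {
    fr <- frame_annotation(ann, hits$frame_index[i])
    st <- object_states(fr)
    slow <- classify_fixation_frame(
      fx[fx$fixation_id == hits$fixation_id[i], ], fr, st)
    expect_equal(as.character(hits$category[i]), as.character(slow$category))
  }
})

test_that("confidence monotonicity: raising the floor never adds instances", {
  s <- simulate_session("LOW", fast_cfg(seed = 5), seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(s$annotations, f)
  n <- vapply(c(0.2, 0.6, 0.8, 0.95), function(cm)
    nrow(load_annotations(f, aoi_config(confidence_min = cm))$instances),
    numeric(1))
  expect_true(all(diff(n) <= 0))
})
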
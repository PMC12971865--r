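test_that("config invariants are enforced", {
  expect_error(sim_config(archetype_mix = c(HIGH = 0.5, MID = 0.2, LOW = 0.2)),
               "sum to 1")
  expect_error(sim_config(fps = 0), "positive")
  bad_policy <- rbind(HIGH = c(0.5, 0.5, 0.2, -0.2),
                      MID = c(0.25, 0.25, 0.25, 0.25),
                      LOW = c(0.25, 0.25, 0.25, 0.25))
  expect_error(sim_config(gaze_policy = bad_policy), "probabilities")
  expect_error(simulate_session("EXPERT", sim_config()), "archetype")
})

test_that("seeded sessions are identical; different seeds differ", {
  cfg <- fast_cfg(seed = 1)
  a <- simulate_session("LOW", cfg, seed = 123)
  b <- simulate_session("LOW", cfg, seed = 123)
  expect_identical(a, b)
  c2 <- simulate_session("LOW", cfg, seed = 124)
  expect_false(identical(a$gaze, c2$gaze))

  # byte-identical after serialization
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixtures(list(a), d1)
  write_fixtures(list(b), d2)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d1, fn)), readLines(file.path(d2, fn)))
  }
})

test_that("a 10 s session at 25 fps has 250 frames and matching invariants", {
  cfg <- sim_config(duration_mean = c(HIGH = 10, MID = 10, LOW = 10),
                    duration_sd = c(HIGH = 0, MID = 0, LOW = 0))
  s <- simulate_session("HIGH", cfg, seed = 4)
  expect_equal(n_frames(s$annotations), 250L)
  expect_equal(s$completion_time, 10)
  expect_true(all(diff(frame_times(s$annotations)) > 0))
  # gaze covers [0, completion_time]
  expect_equal(min(s$gaze$t), 0)
  expect_gte(max(s$gaze$t), s$completion_time - 1 / cfg$gaze_hz)
  # six objects and two tools per frame (up to detection dropout)
  per_frame <- table(s$annotations$instances$frame_index)
  expect_lte(max(per_frame), 8)
  expect_gte(mean(per_frame), 8 * (1 - 2 * cfg$dropout_rate))
})

test_that("cohort counts follow the mix up to rounding and are reproducible", {
  cfg <- fast_cfg(seed = 77)
  co <- simulate_cohort(cfg)
  expect_equal(sort(as.vector(table(co$truth$archetype))), c(5L, 5L, 14L))
  expect_equal(as.vector(table(co$truth$archetype)[c("HIGH", "MID", "LOW")]),
               c(5L, 14L, 5L))
  co2 <- simulate_cohort(cfg)
  expect_identical(co$truth, co2$truth)

  # paired participants exist with one session per trainer, same archetype
  tab <- table(co$truth$participant_id)
  paired <- names(tab)[tab == 2]
  expect_equal(length(paired), 6L)
  for (p in paired) {
    rows <- co$truth[co$truth$participant_id == p, ]
    expect_setequal(rows$trainer, c("adult", "pediatric"))
    expect_equal(length(unique(rows$archetype)), 1L)
  }

  one <- simulate_cohort(sim_config(n_sessions = 5, duration_scale = 0.1,
                                    archetype_mix = c(HIGH = 1), seed = 3))
  expect_true(all(one$truth$archetype == "HIGH"))
})

test_that("fixture files round-trip through the loaders", {
  co <- simulate_cohort(sim_config(n_sessions = 2, duration_scale = 0.1,
                                   seed = 10))
  d <- withr::local_tempdir()
  files <- write_fixtures(co, d)
  expect_length(files, 2 * 2 + 1) # per-session json + csv, plus metadata
  meta <- read_metrics_csv(file.path(d, "metadata.csv"))
  expect_equal(nrow(meta), 2L)

  s <- co$sessions[[1]]
  ann <- load_annotations(file.path(d, paste0(s$session_id, ".annotations.json")))
  gz <- read_gaze_csv(file.path(d, paste0(s$session_id, ".gaze.csv")))
  expect_equal(n_frames(ann), n_frames(s$annotations))
  expect_equal(ann$instances$instance_id, s$annotations$instances$instance_id)
  expect_equal(ann$vertices, s$annotations$vertices, tolerance = 1e-9)
  expect_equal(gz$t, s$gaze$t)
  expect_equal(gz$valid, s$gaze$valid)

  # empty session list: metadata only
  d2 <- withr::local_tempdir()
  files2 <- write_fixtures(list(), d2)
  expect_length(files2, 1)
  expect_equal(nrow(read_metrics_csv(files2[1])), 0L)
})

test_that("YAML configs round-trip", {
  cfg <- sim_config(seed = 5, duration_scale = 0.3,
                    error_rate = c(HIGH = 0, MID = 1, LOW = 2))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(unclass(cfg), unclass(cfg2), tolerance = 1e-9)
})

test_that("policy monotonicity: more held-object gaze raises the one-tool rate", {
  pol <- function(held) rbind(
    HIGH = c(held = held, next_obj = 0.10, tool = 0.20,
             background = 0.70 - held),
    MID = c(held = 0.3, next_obj = 0.1, tool = 0.2, background = 0.4),
    LOW = c(held = 0.3, next_obj = 0.1, tool = 0.2, background = 0.4))
  rate_at <- function(held) {
    cfg <- sim_config(duration_scale = 0.2, gaze_policy = pol(held),
                      error_rate = c(HIGH = 0, MID = 0, LOW = 0))
    mean(vapply(1:18, function(i) {
      s <- simulate_session("HIGH", cfg, seed = 1000 + i)
      hits <- map_fixations_to_frames(ivt_classify(s$gaze), s$annotations)
      unname(fixation_rates(hits, s$completion_time)["fr_obj_1tool"])
    }, numeric(1)))
  }
  r <- vapply(c(0.15, 0.35, 0.55), rate_at, numeric(1)) # 54 seeded sessions
  expect_true(all(diff(r) > 0))
})

test_that("pediatric trainer speed factor scales measured tool speed", {
  cfg <- sim_config(duration_scale = 0.15, trainer_speed_factor = 1.5)
  sa <- simulate_session("MID", cfg, seed = 9, trainer = "adult")
  sp <- simulate_session("MID", cfg, seed = 9, trainer = "pediatric")
  expect_gt(as.numeric(tool_speed(sp$annotations)),
            1.2 * as.numeric(tool_speed(sa$annotations)))
})
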
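make_blobs <- function(n_per = 8, sep = 10, sd = 0.3, d = 4, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, d), c(sep, rep(0, d - 1)), c(0, sep, rep(0, d - 2)))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * d, 0, sd), n_per, d), 2, centers[k, ], "+")))
  list(x = as.data.frame(x), truth = rep(1:3, each = n_per))
}

test_that("k-means++ recovers separated blobs and respects edge cases", {
  b <- make_blobs()
  m <- kmeans_pp(b$x, 3, seed = 2)
  expect_gte(adjusted_rand_index(m$assignments, b$truth), 0.9)

  # duplicate rows get identical assignments
  xd <- rbind(b$x, b$x[1, ], b$x[1, ])
  md <- kmeans_pp(xd, 3, seed = 2)
  n <- nrow(b$x)
  expect_equal(md$assignments[n + 1], md$assignments[1])
  expect_equal(md$assignments[n + 2], md$assignments[1])

  # k = 1: WCSS equals the total standardized sum of squares
  m1 <- kmeans_pp(b$x, 1, seed = 1)
  expect_equal(m1$wcss, (nrow(b$x) - 1) * ncol(b$x), tolerance = 1e-9)

  expect_error(kmeans_pp(b$x[1:3, ], 5, seed = 1), "exceeds")
  b$x$const <- 1
  expect_warning(kmeans_pp(b$x, 3, seed = 1), "constant")
})

test_that("elbow picks the curvature maximum; degenerate curves are flagged", {
  # sharp bend at k = 3: steep drop then flat
  curve <- c(100, 60, 20, 18, 16, 14.5, 13, 12)
  expect_equal(as.integer(elbow_select(curve)), 3L)

  lin <- seq(100, 30, length.out = 8)
  k <- elbow_select(lin)
  expect_equal(as.integer(k), 2L)
  expect_true(isTRUE(attr(k, "no_clear_elbow")))

  expect_error(elbow_select(c(10, 5)), "k = 1..3")
  # WCSS is nonincreasing in k on real data
  b <- make_blobs(seed = 4)
  wc <- wcss_curve(b$x, k_max = 6, seed = 1)
  expect_true(all(diff(wc) <= 1e-8))
})

test_that("Welch ANOVA matches oneway.test and the brute-force formula", {
  set.seed(5)
  v <- c(rnorm(8, 0, 1), rnorm(10, 1, 2), rnorm(6, 3, 0.5))
  g <- rep(1:3, c(8, 10, 6))
  w <- welch_anova(v, g)
  o <- oneway.test(v ~ factor(g))
  expect_equal(w$statistic, unname(o$statistic), tolerance = 1e-10)
  expect_equal(w$df2, unname(o$parameter[2]), tolerance = 1e-10)
  expect_equal(w$p, o$p.value, tolerance = 1e-10)
  br <- oracle_welch_f(v, g)
  expect_equal(w$statistic, br$f, tolerance = 1e-6)

  # two groups: Welch F equals the squared Welch t statistic
  v2 <- c(rnorm(7, 0, 1), rnorm(9, 2, 3)); g2 <- rep(1:2, c(7, 9))
  w2 <- welch_anova(v2, g2)
  t2 <- t.test(v2[g2 == 1], v2[g2 == 2])
  expect_equal(w2$statistic, unname(t2$statistic)^2, tolerance = 1e-9)

  expect_warning(wc <- welch_anova(rep(c(1, 2), each = 5), rep(1:2, each = 5)),
                 "zero variance")
  expect_true(is.na(wc$statistic))
  expect_error(welch_anova(1:5, c(1, 1, 1, 1, 2)), "at least two values")
})

test_that("Games-Howell matches an independent formula evaluation", {
  set.seed(6)
  v <- c(rnorm(9, 0, 1), rnorm(12, 1.5, 2.5), rnorm(7, 4, 0.8))
  g <- rep(c("a", "b", "c"), c(9, 12, 7))
  gh <- games_howell(v, g)
  br <- oracle_games_howell(v, g)
  expect_equal(gh$diff, br$diff, tolerance = 1e-6)
  expect_equal(gh$p, br$p, tolerance = 1e-6)
  expect_true(all(gh$ci_lo <= gh$diff & gh$diff <= gh$ci_hi))

  # identical groups: p ~ 1, CI straddles 0
  vi <- rep(rnorm(8), 3); gi <- rep(1:3, each = 8)
  ghi <- games_howell(vi, gi)
  expect_true(all(ghi$p > 0.99))
  expect_true(all(ghi$ci_lo < 0 & ghi$ci_hi > 0))

  # a far-separated pair is significant with CI excluding 0
  vs <- c(rnorm(8, 0, 1), rnorm(8, 50, 1)); gs <- rep(1:2, each = 8)
  ghs <- games_howell(vs, gs)
  expect_lt(ghs$p, 1e-4)
  expect_gt(abs(ghs$ci_lo), 0)
})

test_that("one-way ANOVA with Tukey matches stats::TukeyHSD and brute force", {
  set.seed(7)
  v <- c(rnorm(10, 0), rnorm(8, 1), rnorm(12, 2.5))
  g <- rep(c("g1", "g2", "g3"), c(10, 8, 12))
  res <- oneway_anova_with_tukey(v, g)
  av <- anova(aov(v ~ factor(g)))
  expect_equal(res$statistic, av$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, av$`Pr(>F)`[1], tolerance = 1e-10)
  tk <- TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
  expect_equal(unname(res$pairwise$p), unname(tk[, "p adj"]), tolerance = 1e-6)
  expect_equal(unname(abs(res$pairwise$diff)), unname(abs(tk[, "diff"])),
               tolerance = 1e-9)
  br <- oracle_tukey(v, g)
  expect_equal(res$pairwise$p, br$p, tolerance = 1e-6)

  same <- oneway_anova_with_tukey(rep(rnorm(6), 3), rep(1:3, each = 6))
  expect_gt(same$p, 0.99)
})

test_that("Levene (Brown-Forsythe) drives the ANOVA/Welch switch", {
  set.seed(8)
  het <- c(rnorm(20, 0, 0.2), rnorm(20, 0, 4))
  hom <- c(rnorm(20, 0, 1), rnorm(20, 0.4, 1))
  g <- rep(1:2, each = 20)
  expect_lt(levene_test(het, g)$p, 0.01)
  expect_gt(levene_test(hom, g)$p, 0.05)

  mt <- data.frame(m = het)
  tests <- cluster_metric_tests(mt, g, columns = "m")
  expect_equal(tests$m$method, "welch_anova")
  tests2 <- cluster_metric_tests(data.frame(m = hom), g, columns = "m")
  expect_equal(tests2$m$method, "oneway_anova")
})

test_that("skill-level merging follows the non-significance graph", {
  set.seed(9)
  ct <- c(rnorm(5, 120, 10), rnorm(14, 240, 30), rnorm(5, 260, 30))
  cl <- rep(1:3, c(5, 14, 5))
  sk <- assign_skill_levels(cl, ct)
  expect_equal(length(sk$level_order), 2L)
  expect_equal(unname(sk$merge_map["1"]), "HIGH")
  expect_equal(unname(sk$merge_map["2"]), "MID_LOW")
  expect_equal(unname(sk$merge_map["3"]), "MID_LOW")
  # invariant to cluster relabeling
  relab <- c(2L, 3L, 1L)[cl]
  sk2 <- assign_skill_levels(relab, ct)
  expect_equal(sk2$levels, sk$levels)

  # all pairs separated -> three ordered levels
  ct3 <- c(rnorm(6, 100, 5), rnorm(6, 200, 5), rnorm(6, 300, 5))
  sk3 <- assign_skill_levels(rep(1:3, each = 6), ct3)
  expect_equal(sk3$level_order, c("HIGH", "MID", "LOW"))

  # all pairs similar -> single level
  ct1 <- rep(rnorm(6, 100, 2), 3) + rnorm(18, 0, 1)
  sk1 <- assign_skill_levels(rep(1:3, each = 6), ct1)
  expect_equal(length(sk1$level_order), 1L)

  expect_warning(assign_skill_levels(rep(1L, 5), rnorm(5, 100)), "single")
})

test_that("trainer comparisons: closed forms and power monotonicity", {
  # identical paired values -> t = 0, p = 1
  mt <- data.frame(participant_id = rep(c("P1", "P2", "P3"), each = 2),
                   trainer = rep(c("adult", "pediatric"), 3),
                   m = rep(c(4.2, 5.1, 6.3), each = 2))
  res <- compare_trainers(mt, columns = "m")
  expect_equal(res$m$paired$statistic, 0)
  expect_equal(res$m$paired$p, 1)

  # 3-pair closed form
  ped <- c(5, 7, 9); adu <- c(4, 5, 9)
  mt2 <- data.frame(participant_id = rep(c("P1", "P2", "P3"), each = 2),
                    trainer = rep(c("pediatric", "adult"), 3),
                    m = as.vector(rbind(ped, adu)))
  res2 <- compare_trainers(mt2, columns = "m")
  d <- ped - adu
  t_exp <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res2$m$paired$statistic, t_exp, tolerance = 1e-9)

  # no paired participants -> warning, paired skipped, independent Welch runs
  mt3 <- data.frame(participant_id = paste0("P", 1:8),
                    trainer = rep(c("adult", "pediatric"), each = 4),
                    m = c(rnorm(4, 0), rnorm(4, 2)))
  expect_warning(res3 <- compare_trainers(mt3, columns = "m"), "paired")
  expect_null(res3$m$paired)
  tt <- t.test(mt3$m[5:8], mt3$m[1:4])
  expect_equal(res3$m$independent$statistic, unname(tt$statistic),
               tolerance = 1e-9)

  # power grows with the simulated trainer effect (paired t, metric level)
  power_at <- function(delta, reps = 200, n = 10) {
    set.seed(1000 + round(delta * 100))
    mean(replicate(reps, {
      base <- rnorm(n, 5, 1)
      mtp <- data.frame(
        participant_id = rep(paste0("P", 1:n), each = 2),
        trainer = rep(c("adult", "pediatric"), n),
        m = as.vector(rbind(base, base + rnorm(n, delta, 1))))
      compare_trainers(mtp, columns = "m")$m$paired$p < 0.05
    }))
  }
  pw <- vapply(c(0, 0.5, 1, 1.5), power_at, numeric(1))
  expect_true(all(diff(pw) > -0.03)) # monotone up to Monte-Carlo noise
  expect_lt(pw[1], 0.12)
  expect_gt(pw[4], 0.9)
})

test_that("adjusted Rand index behaves", {
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
  expect_equal(adjusted_rand_index(rep(1:2, 10), rep(1:2, 10)), 1)
  set.seed(10)
  a <- sample(1:3, 3000, replace = TRUE)
  b <- sample(1:3, 3000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
})
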
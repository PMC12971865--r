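# Unsupervised skill-level discovery and the associated group comparisons:
# k-means++ over the six z-standardized metrics, elbow selection on the WCSS
# curve, cluster -> skill-level merging driven by completion-time post hocs,
# and the per-metric one-way ANOVA / Welch ANOVA machinery with Tukey and
# Games-Howell pairwise tables.

#' k-means++ clustering of the session metric table
#'
#' Features are z-standardized (constant features dropped with a warning)
#' before Lloyd iterations; k-means++ seeding, best of `n_init` restarts by
#' within-cluster sum of squares (WCSS).
#'
#' @param x data.frame or matrix of features (rows = sessions). Non-numeric
#'   columns are ignored.
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param seed integer seed.
#' @param n_init number of seeded restarts (default 10).
#' @return a `cluster_model` list: `k`, `assignments` (integer vector),
#'   `centers` (k x d, standardized space), `wcss` (the objective), `seed`,
#'   `n_init`, `scaling` (centers/sds used).
#' @export
kmeans_pp <- function(x, k, seed = 1, n_init = 10) {
  xs <- standardize_features(x)
  z <- xs$z
  n <- nrow(z)
  if (k > n) stop("k (", k, ") exceeds number of sessions (", n, ")", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- z[kmeanspp_seed_idx(z, k), , drop = FALSE]
    km <- suppressWarnings(
      kmeans(z, centers = centers, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(k = k, assignments = unname(best$cluster),
                 centers = best$centers, wcss = best$tot.withinss,
                 seed = seed, n_init = n_init, scaling = xs[c("mu", "sdev")],
                 features = colnames(z)),
            class = "cluster_model")
}

standardize_features <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  m <- as.matrix(x[, num, drop = FALSE])
  sdev <- apply(m, 2, sd)
  const <- sdev == 0 | !is.finite(sdev)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    m <- m[, !const, drop = FALSE]
    sdev <- sdev[!const]
  }
  mu <- colMeans(m)
  list(z = scale(m, center = mu, scale = sdev), mu = mu, sdev = sdev)
}

# D^2-weighted k-means++ seeding; returns k row indices
kmeanspp_seed_idx <- function(z, k) {
  n <- nrow(z)
  idx <- sample.int(n, 1)
  if (k == 1) return(idx)
  d2 <- rowSums((z - matrix(z[idx, ], n, ncol(z), byrow = TRUE))^2)
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    nxt <- sample.int(n, 1, prob = p)
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums((z - matrix(z[nxt, ], n, ncol(z), byrow = TRUE))^2))
  }
  idx
}

#' WCSS curve over a range of k
#'
#' @inheritParams kmeans_pp
#' @param k_max largest k to evaluate (default 8, capped at `nrow(x)`).
#' @return named numeric vector `wcss[k]` for `k = 1..k_max`.
#' @export
wcss_curve <- function(x, k_max = 8, seed = 1, n_init = 10) {
  k_max <- min(k_max, nrow(as.data.frame(x)))
  vapply(seq_len(k_max), function(k)
    kmeans_pp(x, k, seed = seed + k, n_init = n_init)$wcss,
    numeric(1)) |> setNames(seq_len(k_max))
}

#' Elbow selection on a WCSS curve
#'
#' Picks the k with the largest discrete curvature (second difference) of the
#' WCSS curve; ties resolve to the smaller k. A curve with no positive
#' curvature anywhere is flagged via attribute `no_clear_elbow`.
#'
#' @param wcss named numeric vector over k = 1..k_max (from [wcss_curve()]).
#' @return selected k (integer), with attribute `no_clear_elbow` when the
#'   curve is (numerically) straight.
#' @export
elbow_select <- function(wcss) {
  k_max <- length(wcss)
  if (k_max < 3) stop("need WCSS over at least k = 1..3", call. = FALSE)
  d2 <- wcss[1:(k_max - 2)] - 2 * wcss[2:(k_max - 1)] + wcss[3:k_max]
  ks <- 2:(k_max - 1)
  best <- ks[which.max(d2)] # which.max takes the first (smallest k) on ties
  out <- as.integer(best)
  tol <- 1e-8 * max(abs(wcss), 1)
  if (max(d2) <= tol) {
    out <- 2L
    attr(out, "no_clear_elbow") <- TRUE
  }
  out
}

#' Welch's one-way ANOVA (unequal variances)
#'
#' @param values numeric outcomes.
#' @param groups group labels (coerced to factor).
#' @return a `group_test` list: `method`, `statistic` (F), `df1`, `df2`
#'   (fractional), `p`.
#' @export
welch_anova <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  ni <- tapply(values, g, length)
  if (any(ni < 2)) stop("every group needs at least two values", call. = FALSE)
  mi <- tapply(values, g, mean)
  vi <- tapply(values, g, var)
  if (all(vi == 0)) {
    warning("all groups have zero variance; Welch F undefined", call. = FALSE)
    return(structure(list(method = "welch_anova", statistic = NA_real_,
                          df1 = nlevels(g) - 1, df2 = NA_real_, p = NA_real_),
                     class = "group_test"))
  }
  k <- nlevels(g)
  wi <- ni / vi
  sw <- sum(wi)
  mw <- sum(wi * mi) / sw
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - wi / sw)^2 / (ni - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  f <- A / B
  df2 <- (k^2 - 1) / (3 * lam)
  structure(list(method = "welch_anova", statistic = unname(f), df1 = k - 1,
                 df2 = unname(df2),
                 p = unname(pf(f, k - 1, df2, lower.tail = FALSE))),
            class = "group_test")
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' Pairwise mean differences with studentized-range p-values and confidence
#' intervals under unequal variances and sizes (Welch-Satterthwaite df per
#' pair).
#'
#' @inheritParams welch_anova
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return data.frame `group1, group2, diff, se, df, p, ci_lo, ci_hi` (diff =
#'   mean(group1) - mean(group2)).
#' @export
games_howell <- function(values, groups, conf_level = 0.95) {
  g <- droplevels(factor(groups))
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  ni <- tapply(values, g, length)
  if (any(ni < 2)) stop("every group needs at least two values", call. = FALSE)
  mi <- tapply(values, g, mean)
  vi <- tapply(values, g, var)
  pairs <- utils::combn(levels(g), 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- vi[i] / ni[i] + vi[j] / ni[j]
    se <- sqrt(se2)
    df <- se2^2 / ((vi[i] / ni[i])^2 / (ni[i] - 1) +
                   (vi[j] / ni[j])^2 / (ni[j] - 1))
    diff <- mi[i] - mi[j]
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
      qc <- 0
    } else {
      q <- abs(diff) * sqrt(2) / se
      p <- ptukey(q, k, df, lower.tail = FALSE)
      qc <- qtukey(conf_level, k, df) / sqrt(2) * se
    }
    c(diff = unname(diff), se = unname(se), df = unname(df), p = unname(p),
      ci_lo = unname(diff - qc), ci_hi = unname(diff + qc))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             t(out), row.names = NULL)
}

#' One-way ANOVA with Tukey HSD pairwise table
#'
#' Classic fixed-effects one-way ANOVA plus Tukey-Kramer pairwise comparisons.
#'
#' @inheritParams games_howell
#' @return a `group_test` list with elements `method, statistic, df1, df2, p`
#'   and `pairwise` (data.frame `group1, group2, diff, se, p, ci_lo, ci_hi`).
#' @export
oneway_anova_with_tukey <- function(values, groups, conf_level = 0.95) {
  g <- droplevels(factor(groups))
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  ni <- tapply(values, g, length)
  mi <- tapply(values, g, mean)
  n <- length(values)
  ss_b <- sum(ni * (mi - mean(values))^2)
  ss_w <- sum((values - mi[as.character(g)])^2)
  df1 <- k - 1; df2 <- n - k
  mse <- ss_w / df2
  f <- (ss_b / df1) / mse
  p <- pf(f, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(levels(g), 2)
  pw <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- mi[i] - mi[j]
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    if (se == 0) {
      pp <- if (diff == 0) 1 else 0
      qc <- 0
    } else {
      q <- abs(diff) / se
      pp <- ptukey(q, k, df2, lower.tail = FALSE)
      qc <- qtukey(conf_level, k, df2) * se
    }
    c(diff = unname(diff), se = unname(se), p = unname(pp),
      ci_lo = unname(diff - qc), ci_hi = unname(diff + qc))
  })
  structure(list(method = "oneway_anova", statistic = unname(f), df1 = df1,
                 df2 = df2, p = unname(p),
                 pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                                       t(pw), row.names = NULL)),
            class = "group_test")
}

#' Brown-Forsythe (median-centred Levene) test for variance homogeneity
#'
#' Drives the choice between the classic and the Welch one-way ANOVA.
#'
#' @inheritParams welch_anova
#' @return a `group_test` list (`statistic`, `df1`, `df2`, `p`).
#' @export
levene_test <- function(values, groups) {
  g <- droplevels(factor(groups))
  med <- tapply(values, g, median)
  z <- abs(values - med[as.character(g)])
  res <- oneway_anova_with_tukey(z, g)
  structure(list(method = "levene_brown_forsythe", statistic = res$statistic,
                 df1 = res$df1, df2 = res$df2, p = res$p),
            class = "group_test")
}

#' Merge clusters into ordered skill levels by completion time
#'
#' Clusters whose pairwise completion-time comparison (Games-Howell) is
#' non-significant at `alpha` are merged (connected components of the
#' non-significance graph); the resulting levels are ordered by ascending mean
#' completion time, fastest first. With a three-to-two merge the labels are
#' `HIGH` and `MID_LOW`, mirroring the canonical fast-cluster vs merged
#' slower-clusters outcome; full resolution gives `HIGH`/`MID`/`LOW`.
#'
#' @param model a `cluster_model` from [kmeans_pp()] (or an integer assignment
#'   vector).
#' @param completion_times numeric, one value per session.
#' @param alpha significance level for the pairwise tests (default 0.05).
#' @return a `skill_assignment` list: `levels` (character vector per session),
#'   `merge_map` (cluster id -> level), `evidence` (the Games-Howell table),
#'   `level_order` (labels, fastest first).
#' @export
assign_skill_levels <- function(model, completion_times, alpha = 0.05) {
  cl <- if (inherits(model, "cluster_model")) model$assignments else as.integer(model)
  if (length(cl) != length(completion_times))
    stop("completion_times must have one value per session", call. = FALSE)
  ids <- sort(unique(cl))
  k <- length(ids)
  if (k == 1) {
    warning("single cluster; single skill level", call. = FALSE)
    return(structure(list(levels = rep("ALL", length(cl)),
                          merge_map = setNames("ALL", ids),
                          evidence = NULL, level_order = "ALL"),
                     class = "skill_assignment"))
  }
  gh <- games_howell(completion_times, cl)
  # union-find over clusters; join non-significant pairs
  cid <- as.character(ids)
  parent <- setNames(cid, cid)
  find <- function(a) { a <- as.character(a); while (parent[[a]] != a) a <- parent[[a]]; a }
  for (r in seq_len(nrow(gh))) {
    if (gh$p[r] >= alpha) {
      ra <- find(gh$group1[r]); rb <- find(gh$group2[r])
      if (ra != rb) parent[[rb]] <- ra
    }
  }
  root <- vapply(cid, find, character(1))
  comp <- match(root, unique(root))
  mean_ct <- tapply(completion_times, comp[match(cl, ids)], mean)
  ord <- order(mean_ct)
  n_lev <- length(ord)
  labels <- if (n_lev == 1) "ALL"
            else if (n_lev == 2 && k > 2) c("HIGH", "MID_LOW")
            else if (n_lev == 2) c("HIGH", "LOW")
            else if (n_lev == 3) c("HIGH", "MID", "LOW")
            else paste0("LEVEL_", seq_len(n_lev))
  rank_of <- match(seq_len(n_lev), ord) # component -> rank
  merge_map <- setNames(labels[rank_of[comp]], ids)
  structure(list(levels = unname(merge_map[as.character(cl)]),
                 merge_map = merge_map, evidence = gh,
                 level_order = labels),
            class = "skill_assignment")
}

#' Per-metric group comparisons across clusters
#'
#' For each metric column: Brown-Forsythe Levene decides between the classic
#' one-way ANOVA (with Tukey HSD) and Welch's ANOVA (with Games-Howell), as is
#' standard when homogeneity of variances is violated.
#'
#' @param metrics session metric data.frame (see [compute_session_metrics()]).
#' @param clusters integer cluster assignment per row.
#' @param columns metric columns to test (default the six extracted metrics).
#' @param alpha significance level used by the Levene switch.
#' @param force `"auto"` (Levene-driven), `"anova"` or `"welch"`.
#' @return named list per metric: `omnibus` (a `group_test`), `pairwise`
#'   (data.frame), `levene_p`, `method`.
#' @export
cluster_metric_tests <- function(metrics, clusters, columns = METRIC_COLUMNS,
                                 alpha = 0.05, force = c("auto", "anova", "welch")) {
  force <- match.arg(force)
  out <- list()
  for (cn in columns) {
    v <- metrics[[cn]]
    lev <- levene_test(v, clusters)
    use_welch <- switch(force, auto = !is.na(lev$p) && lev$p < alpha,
                        anova = FALSE, welch = TRUE)
    if (use_welch) {
      om <- welch_anova(v, clusters)
      pw <- games_howell(v, clusters)
    } else {
      om <- oneway_anova_with_tukey(v, clusters)
      pw <- om$pairwise
    }
    out[[cn]] <- list(omnibus = om, pairwise = pw, levene_p = lev$p,
                      method = om$method)
  }
  out
}

#' Trainer-anatomy comparisons (paired + independent)
#'
#' Participants with a session on both trainers enter a paired t-test per
#' metric; the remaining sessions enter an independent (Welch) t-test.
#'
#' @param metrics session metric data.frame with `participant_id` and
#'   `trainer` columns.
#' @param columns metric columns to compare.
#' @return named list per metric with elements `paired` and `independent`,
#'   each `NULL` or a list `statistic, df, p, estimate, n`.
#' @export
compare_trainers <- function(metrics, columns = METRIC_COLUMNS) {
  tab <- table(metrics$participant_id, metrics$trainer)
  paired_ids <- rownames(tab)[rowSums(tab > 0) == 2]
  out <- list()
  for (cn in columns) {
    res <- list(paired = NULL, independent = NULL)
    if (length(paired_ids)) {
      a <- b <- numeric(length(paired_ids))
      for (i in seq_along(paired_ids)) {
        rows <- metrics$participant_id == paired_ids[i]
        a[i] <- metrics[[cn]][rows & metrics$trainer == "pediatric"][1]
        b[i] <- metrics[[cn]][rows & metrics$trainer == "adult"][1]
      }
      if (length(a) >= 2) {
        if (sd(a - b) == 0) {
          res$paired <- list(statistic = 0, df = length(a) - 1,
                             p = 1, estimate = mean(a - b), n = length(a))
        } else {
          tt <- t.test(a, b, paired = TRUE)
          res$paired <- list(statistic = unname(tt$statistic),
                             df = unname(tt$parameter), p = tt$p.value,
                             estimate = unname(tt$estimate), n = length(a))
        }
      }
    } else {
      warning("no participants with both trainers; paired test skipped",
              call. = FALSE)
    }
    ind <- metrics[!(metrics$participant_id %in% paired_ids), , drop = FALSE]
    if (length(unique(ind$trainer)) == 2 &&
        all(table(ind$trainer) >= 2)) {
      tt <- t.test(ind[[cn]][ind$trainer == "pediatric"],
                   ind[[cn]][ind$trainer == "adult"])
      res$independent <- list(statistic = unname(tt$statistic),
                              df = unname(tt$parameter), p = tt$p.value,
                              estimate = unname(diff(rev(tt$estimate))),
                              n = nrow(ind))
    }
    out[[cn]] <- res
  }
  out
}

#' Full cluster-and-interpret report for a metric table
#'
#' Convenience orchestration: WCSS curve + elbow, k-means++ at the selected
#' k, completion-time interpretation (Levene-driven Welch/classic ANOVA +
#' Games-Howell + skill-level merging), errors ANOVA, and the per-metric
#' cluster comparisons.
#'
#' @param metrics session metric data.frame including `completion_time` and
#'   `errors`.
#' @param k_max elbow search range.
#' @param seed,n_init passed to [kmeans_pp()].
#' @param alpha significance level.
#' @return an `analysis_report` list.
#' @export
analyze_cohort <- function(metrics, k_max = 8, seed = 1, n_init = 10,
                           alpha = 0.05) {
  feats <- metrics[, METRIC_COLUMNS, drop = FALSE]
  curve <- wcss_curve(feats, k_max = k_max, seed = seed, n_init = n_init)
  k <- elbow_select(curve)
  model <- kmeans_pp(feats, k, seed = seed, n_init = n_init)
  ct <- metrics$completion_time
  lev_ct <- levene_test(ct, model$assignments)
  ct_om <- if (!is.na(lev_ct$p) && lev_ct$p < alpha)
    welch_anova(ct, model$assignments)
  else oneway_anova_with_tukey(ct, model$assignments)
  skill <- assign_skill_levels(model, ct, alpha = alpha)
  err_om <- tryCatch(oneway_anova_with_tukey(metrics$errors, model$assignments),
                     error = function(e) NULL)
  per_metric <- cluster_metric_tests(metrics, model$assignments, alpha = alpha)
  structure(list(wcss_curve = curve, k = k, model = model,
                 completion_time_test = ct_om, completion_time_levene = lev_ct,
                 skill = skill, errors_test = err_om,
                 metric_tests = per_metric),
            class = "analysis_report")
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant clustering agreement; 1 = identical partitions, ~0 =
#' chance.
#'
#' @param a,b equal-length label vectors.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must match in length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  exp_idx <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

#' Serialize an analysis report to JSON
#' @param report an `analysis_report` from [analyze_cohort()].
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(k = report$k,
         wcss_curve = as.list(report$wcss_curve),
         assignments = report$model$assignments,
         skill_levels = report$skill$levels,
         merge_map = as.list(report$skill$merge_map),
         completion_time_test = unclass(report$completion_time_test),
         metric_tests = lapply(report$metric_tests, function(m)
           list(method = m$method, p = m$omnibus$p, pairwise = m$pairwise))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
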
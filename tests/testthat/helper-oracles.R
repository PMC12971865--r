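# Fixture builders and independent brute-force oracles. Oracles deliberately
# avoid the package's code paths (plain loops, different algorithms) so the
# dual-route checks are meaningful.

tri_poly <- function(cx, cy, r = 60 / sqrt(3), phi = 0) {
  a <- phi + c(0, 2, 4) * pi / 3
  cbind(cx + r * cos(a), cy + r * sin(a))
}

rect_poly <- function(x1, y1, x2, y2) {
  cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
}

rand_poly <- function() {
  # random triangle or convex quadrilateral somewhere in a 400x400 window
  cx <- runif(1, 60, 340); cy <- runif(1, 60, 340)
  if (runif(1) < 0.5) {
    tri_poly(cx, cy, r = runif(1, 15, 45), phi = runif(1, 0, 2 * pi))
  } else {
    a <- sort(runif(4, 0, 2 * pi))
    r <- runif(4, 15, 45)
    cbind(cx + r * cos(a), cy + r * sin(a))
  }
}

# --- rasterized distance-transform hit oracle --------------------------------
# Scanline-rasterize the polygon on a 1 px grid, then decide the dilated hit
# from the pixelized mask: inside if the point's pixel is filled, else hit if
# any filled pixel centre lies within `radius` of the point.
oracle_dilated_hit <- function(point, poly, radius) {
  xs <- floor(min(poly[, 1]) - radius - 2):ceiling(max(poly[, 1]) + radius + 2)
  ys <- floor(min(poly[, 2]) - radius - 2):ceiling(max(poly[, 2]) + radius + 2)
  n <- nrow(poly)
  filled <- matrix(FALSE, length(ys), length(xs))
  for (yi in seq_along(ys)) {
    y <- ys[yi]
    crossings <- numeric(0)
    for (j in seq_len(n)) {
      k <- if (j == 1) n else j - 1
      y1 <- poly[j, 2]; y2 <- poly[k, 2]
      if ((y1 > y) != (y2 > y)) {
        x_at <- poly[j, 1] + (y - y1) / (y2 - y1) * (poly[k, 1] - poly[j, 1])
        crossings <- c(crossings, x_at)
      }
    }
    crossings <- sort(crossings)
    if (length(crossings) >= 2) {
      for (c2 in seq(1, length(crossings) - 1, by = 2)) {
        filled[yi, xs >= crossings[c2] & xs <= crossings[c2 + 1]] <- TRUE
      }
    }
  }
  if (!any(filled)) return(FALSE)
  fx <- xs[col(filled)[filled]]
  fy <- ys[row(filled)[filled]]
  px <- point[1]; py <- point[2]
  if (any(abs(fx - px) <= 0.5 & abs(fy - py) <= 0.5)) return(TRUE)
  min((fx - px)^2 + (fy - py)^2) <= radius^2
}

# --- I-VT threshold-scan oracle ---------------------------------------------
# Per-sample velocity by direct neighbour search, then a simple state scan:
# runs of below-threshold samples, gaps bridged when short, short runs
# dropped. Mirrors the documented semantics, not the implementation.
oracle_ivt <- function(trace, ppd, thr, win = 0.020, min_dur = 0.060,
                       gap = 0.075) {
  n <- nrow(trace)
  v <- rep(NA_real_, n)
  vi <- which(trace$valid)
  for (ii in seq_along(vi)) {
    i <- vi[ii]
    t1 <- NA; t2 <- NA
    for (jj in rev(seq_len(ii - 1))) {
      if (trace$t[vi[jj]] <= trace$t[i] - win / 2) { t1 <- vi[jj]; break }
    }
    if (ii < length(vi)) {
      for (jj in (ii + 1):length(vi)) {
        if (trace$t[vi[jj]] >= trace$t[i] + win / 2) { t2 <- vi[jj]; break }
      }
    }
    if (!is.na(t1) && !is.na(t2)) {
      span <- trace$t[t2] - trace$t[t1]
      if (span <= 5 * win && span > 0) {
        v[i] <- sqrt((trace$x[t2] - trace$x[t1])^2 +
                     (trace$y[t2] - trace$y[t1])^2) / span / ppd
      }
    }
  }
  is_fix <- trace$valid & !is.na(v) & v < thr
  is_gap <- !trace$valid | is.na(v)
  # scan: group fixation samples, bridging gap runs <= gap
  groups <- list()
  cur <- NULL
  i <- 1
  while (i <= n) {
    if (is_fix[i]) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
      i <- i + 1
    } else if (is_gap[i] && !is.null(cur)) {
      j <- i
      while (j <= n && is_gap[j] && !is_fix[j]) j <- j + 1
      gap_dur <- trace$t[min(j, n)] - trace$t[max(i - 1, 1)]
      if (j <= n && is_fix[j] && gap_dur <= gap) {
        i <- j
      } else {
        groups[[length(groups) + 1]] <- cur; cur <- NULL
        i <- j
      }
    } else {
      if (!is.null(cur)) { groups[[length(groups) + 1]] <- cur; cur <- NULL }
      i <- i + 1
    }
  }
  if (!is.null(cur)) groups[[length(groups) + 1]] <- cur
  # absorb adjacent valid-but-undefined-velocity edge samples
  res <- lapply(groups, function(g) {
    s <- g[1]; e <- g[2]
    while (s > 1 && trace$valid[s - 1] && is.na(v[s - 1])) s <- s - 1
    while (e < n && trace$valid[e + 1] && is.na(v[e + 1])) e <- e + 1
    c(s, e)
  })
  res <- Filter(function(g) trace$t[g[2]] - trace$t[g[1]] >= min_dur, res)
  res
}

# --- brute-force statistics --------------------------------------------------

oracle_welch_f <- function(values, groups) {
  g <- unique(groups)
  k <- length(g)
  ni <- mi <- vi <- numeric(k)
  for (j in seq_len(k)) {
    x <- values[groups == g[j]]
    ni[j] <- length(x); mi[j] <- mean(x); vi[j] <- var(x)
  }
  w <- ni / vi
  mw <- sum(w * mi) / sum(w)
  num <- sum(w * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (ni - 1))
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  list(f = num / den, df2 = (k^2 - 1) / (3 * lam))
}

oracle_games_howell <- function(values, groups) {
  g <- sort(unique(groups))
  out <- NULL
  for (a in seq_along(g)) for (b in seq_along(g)) {
    if (b <= a) next
    xa <- values[groups == g[a]]; xb <- values[groups == g[b]]
    se2 <- var(xa) / length(xa) + var(xb) / length(xb)
    df <- se2^2 / ((var(xa) / length(xa))^2 / (length(xa) - 1) +
                   (var(xb) / length(xb))^2 / (length(xb) - 1))
    q <- abs(mean(xa) - mean(xb)) * sqrt(2) / sqrt(se2)
    out <- rbind(out, data.frame(
      group1 = g[a], group2 = g[b], diff = mean(xa) - mean(xb),
      p = ptukey(q, length(g), df, lower.tail = FALSE)))
  }
  out
}

oracle_tukey <- function(values, groups) {
  g <- sort(unique(groups))
  k <- length(g); n <- length(values)
  mi <- sapply(g, function(gg) mean(values[groups == gg]))
  ni <- sapply(g, function(gg) sum(groups == gg))
  mse <- sum((values - mi[match(groups, g)])^2) / (n - k)
  out <- NULL
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b <= a) next
    se <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
    q <- abs(mi[a] - mi[b]) / se
    out <- rbind(out, data.frame(group1 = g[a], group2 = g[b],
                                 diff = mi[a] - mi[b],
                                 p = ptukey(q, k, n - k, lower.tail = FALSE)))
  }
  out
}

# --- synthetic annotation builders ------------------------------------------

# annotations with two grasper quads moving at given per-frame velocities
# (px/s) and optional static objects; exact frame clock at `fps`
make_tool_annotations <- function(n_frames, fps = 25, v_left = c(0, 0),
                                  v_right = c(0, 0), objects = NULL,
                                  arena = c(1920, 1080)) {
  tfr <- (seq_len(n_frames) - 1) / fps
  frames <- data.frame(frame_index = 0:(n_frames - 1), t = tfr)
  inst <- NULL; polys <- list()
  add <- function(fi, id, cat, poly) {
    inst <<- rbind(inst, data.frame(frame_index = fi, instance_id = id,
                                    category = cat, score = 0.95))
    polys[[length(polys) + 1]] <<- poly
  }
  for (i in seq_len(n_frames)) {
    t <- tfr[i]
    lp <- c(300 + v_left[1] * t, 600 + v_left[2] * t)
    rp <- c(1400 + v_right[1] * t, 600 + v_right[2] * t)
    add(i - 1, 101L, "tool", rect_poly(lp[1] - 40, lp[2] - 10, lp[1] + 40, lp[2] + 10))
    add(i - 1, 102L, "tool", rect_poly(rp[1] - 40, rp[2] - 10, rp[1] + 40, rp[2] + 10))
    if (!is.null(objects)) {
      for (k in seq_len(nrow(objects))) {
        add(i - 1, k, "object", tri_poly(objects[k, 1], objects[k, 2]))
      }
    }
  }
  nv <- vapply(polys, nrow, integer(1))
  aoi_annotations(frames, inst, do.call(rbind, polys), c(0L, cumsum(nv)),
                  arena = arena, validate = FALSE)
}

# single-frame annotation from a list of (category, polygon) pairs
make_frame_annotations <- function(cats, polys, t = 0, arena = c(1920, 1080)) {
  inst <- data.frame(frame_index = 0L, instance_id = seq_along(cats),
                     category = cats, score = 0.9)
  nv <- vapply(polys, nrow, integer(1))
  aoi_annotations(data.frame(frame_index = 0L, t = t), inst,
                  do.call(rbind, polys), c(0L, cumsum(nv)), arena = arena)
}

fast_cfg <- function(seed = 1, ...) {
  sim_config(duration_scale = 0.15, seed = seed, ...)
}
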
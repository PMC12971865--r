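# Supervised prediction of visual-behavior level from the six session metrics
# with four classifier families under leave-one-out cross-validation, plus
# Gini (mean decrease in impurity) feature importance for the random forest.
#
# None of the usual ML packages are assumed: the Gini decision tree (shared by
# CART and the forest) is implemented in C++, the RBF-kernel soft-margin SVM
# is solved as a dual QP with quadprog, and the neural network is a single
# hidden-layer softmax MLP trained with BFGS.

#' Classifier specification
#'
#' Hyperparameter defaults are package choices (the methodology names the
#' families but not their settings): RF with 500 trees, `mtry = floor(sqrt(d))`,
#' unlimited depth; SVM with RBF kernel, `C = 1`, `gamma = 1/d`; CART with
#' Gini splits and no pruning; ANN with one hidden layer of 8 units, weight
#' decay 1e-3, no early stopping. SVM and ANN features are z-scaled per
#' training fold; trees are scale-free and left unscaled.
#'
#' @param family `"RF"`, `"SVM"`, `"CART"` or `"ANN"`.
#' @param seed integer seed for stochastic families.
#' @param n_trees,mtry RF settings (`mtry = NULL` means `floor(sqrt(d))`).
#' @param cost,gamma SVM settings (`gamma = NULL` means `1/d`).
#' @param hidden,decay,maxit ANN settings.
#' @param min_node minimum node size before a split is attempted (trees).
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("RF", "SVM", "CART", "ANN"), seed = 1,
                       n_trees = 500, mtry = NULL, cost = 1, gamma = NULL,
                       hidden = 8, decay = 1e-3, maxit = 500, min_node = 2) {
  family <- match.arg(family)
  structure(list(family = family, seed = as.integer(seed), n_trees = n_trees,
                 mtry = mtry, cost = cost, gamma = gamma, hidden = hidden,
                 decay = decay, maxit = maxit, min_node = min_node,
                 scaled = family %in% c("SVM", "ANN")),
            class = "model_spec")
}

# ---- fitting front-end ------------------------------------------------------

fit_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  set.seed(spec$seed)
  fit <- switch(spec$family,
    CART = fit_cart(X, y, spec),
    RF = fit_rf(X, y, spec),
    SVM = fit_svm(X, y, spec),
    ANN = fit_ann(X, y, spec))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 features = colnames(X)),
            class = "gs_classifier")
}

predict_classifier <- function(model, X) {
  X <- as.matrix(X)
  idx <- switch(model$spec$family,
    CART = predict_cart(model$fit, X),
    RF = predict_rf(model$fit, X),
    SVM = predict_svm(model$fit, X),
    ANN = predict_ann(model$fit, X))
  factor(model$levels[idx], levels = model$levels)
}

# ---- trees ------------------------------------------------------------------

fit_cart <- function(X, y, spec) {
  tree <- cpp_grow_tree(X, as.integer(y) - 1L, nlevels(y), ncol(X),
                        seq_len(nrow(X)) - 1L, spec$min_node)
  list(tree = tree)
}

predict_cart <- function(fit, X) {
  tr <- fit$tree
  cpp_predict_tree(tr$feature, tr$threshold, tr$left, tr$right, tr$pred, X) + 1L
}

fit_rf <- function(X, y, spec) {
  n <- nrow(X); d <- ncol(X); K <- nlevels(y)
  mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(d))) else spec$mtry
  trees <- vector("list", spec$n_trees)
  imp <- numeric(d)
  for (b in seq_len(spec$n_trees)) {
    boot <- sample.int(n, n, replace = TRUE) - 1L
    trees[[b]] <- cpp_grow_tree(X, as.integer(y) - 1L, K, mtry, boot,
                                spec$min_node)
    imp <- imp + trees[[b]]$importance
  }
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / d, d)
  names(imp) <- colnames(X)
  list(trees = trees, importance = imp, K = K)
}

predict_rf <- function(fit, X) {
  votes <- matrix(0L, nrow(X), fit$K)
  for (tr in fit$trees) {
    p <- cpp_predict_tree(tr$feature, tr$threshold, tr$left, tr$right,
                          tr$pred, X)
    votes[cbind(seq_len(nrow(X)), p + 1L)] <-
      votes[cbind(seq_len(nrow(X)), p + 1L)] + 1L
  }
  max.col(votes, ties.method = "first")
}

# ---- SVM (RBF, one-vs-one, dual QP) ----------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

fit_binary_svm <- function(X, yy, cost, gamma) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  D <- (yy %o% yy) * K
  diag(D) <- diag(D) + 1e-8
  A <- cbind(yy, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-6
  margin <- sv & alpha < cost - 1e-6
  use <- if (any(margin)) margin else sv
  bias <- mean(yy[use] - colSums(alpha[sv] * yy[sv] * K[sv, use, drop = FALSE]))
  list(X = X[sv, , drop = FALSE], coef = alpha[sv] * yy[sv], bias = bias,
       gamma = gamma)
}

predict_binary_svm <- function(m, X) {
  drop(rbf_kernel(X, m$X, m$gamma) %*% m$coef) + m$bias
}

fit_svm <- function(X, y, spec) {
  gamma <- if (is.null(spec$gamma)) 1 / ncol(X) else spec$gamma
  K <- nlevels(y)
  prs <- utils::combn(K, 2)
  machines <- lapply(seq_len(ncol(prs)), function(c2) {
    i <- prs[1, c2]; j <- prs[2, c2]
    rows <- as.integer(y) %in% c(i, j)
    yy <- ifelse(as.integer(y)[rows] == i, 1, -1)
    m <- fit_binary_svm(X[rows, , drop = FALSE], yy, spec$cost, gamma)
    m$pos <- i; m$neg <- j
    m
  })
  list(machines = machines, K = K)
}

predict_svm <- function(fit, X) {
  votes <- matrix(0L, nrow(X), fit$K)
  for (m in fit$machines) {
    f <- predict_binary_svm(m, X)
    w <- ifelse(f >= 0, m$pos, m$neg)
    votes[cbind(seq_len(nrow(X)), w)] <- votes[cbind(seq_len(nrow(X)), w)] + 1L
  }
  max.col(votes, ties.method = "first")
}

# ---- ANN (one hidden layer, softmax, BFGS) ---------------------------------

fit_ann <- function(X, y, spec) {
  n <- nrow(X); d <- ncol(X); K <- nlevels(y); h <- spec$hidden
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  npar <- d * h + h + h * K + K
  unpack <- function(w) {
    list(W1 = matrix(w[1:(d * h)], d, h),
         b1 = w[d * h + (1:h)],
         W2 = matrix(w[d * h + h + (1:(h * K))], h, K),
         b2 = w[d * h + h + h * K + (1:K)])
  }
  fwd <- function(p) {
    Z <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
    S <- sweep(Z %*% p$W2, 2, p$b2, "+")
    S <- S - apply(S, 1, max)
    E <- exp(S)
    P <- E / rowSums(E)
    list(Z = Z, P = P)
  }
  loss <- function(w) {
    p <- unpack(w)
    f <- fwd(p)
    -sum(Y * log(pmax(f$P, 1e-12))) / n +
      spec$decay * (sum(p$W1^2) + sum(p$W2^2))
  }
  grad <- function(w) {
    p <- unpack(w)
    f <- fwd(p)
    dS <- (f$P - Y) / n
    gW2 <- crossprod(f$Z, dS) + 2 * spec$decay * p$W2
    gb2 <- colSums(dS)
    dZ <- tcrossprod(dS, p$W2) * (1 - f$Z^2)
    gW1 <- crossprod(X, dZ) + 2 * spec$decay * p$W1
    gb1 <- colSums(dZ)
    c(as.numeric(gW1), gb1, as.numeric(gW2), gb2)
  }
  w0 <- runif(npar, -0.5, 0.5)
  opt <- optim(w0, loss, grad, method = "BFGS",
               control = list(maxit = spec$maxit, reltol = 1e-10))
  c(unpack(opt$par), list(K = K))
}

predict_ann <- function(fit, X) {
  Z <- tanh(sweep(X %*% fit$W1, 2, fit$b1, "+"))
  S <- sweep(Z %*% fit$W2, 2, fit$b2, "+")
  max.col(S, ties.method = "first")
}

# ---- evaluation -------------------------------------------------------------

#' Leave-one-out cross-validated evaluation
#'
#' Each session is held out once; all fold statistics (including z-scaling for
#' SVM/ANN) are fitted on the remaining rows only. Folds whose training part
#' lacks a class are flagged and excluded from aggregation with a warning.
#'
#' @param x feature data.frame/matrix (rows = sessions).
#' @param labels class labels (visual-behavior levels).
#' @param spec a [model_spec()].
#' @return a `prediction_report` list: `predicted`, `truth`, `accuracy`, `f1`
#'   (binary F1 for two classes, macro-F1 otherwise; see `f1_type`),
#'   `confusion` (matrix), `gini_importances` (RF only, fitted on the full
#'   data), `excluded_folds`.
#' @export
loocv_evaluate <- function(x, labels, spec = model_spec("RF")) {
  X <- as.matrix(as.data.frame(x)[, vapply(as.data.frame(x), is.numeric,
                                           logical(1)), drop = FALSE])
  y <- factor(labels)
  n <- nrow(X)
  if (n < nlevels(y) + 1) stop("need more sessions than classes", call. = FALSE)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  excluded <- integer(0)
  for (i in seq_len(n)) {
    tr_X <- X[-i, , drop = FALSE]; tr_y <- y[-i]
    if (nlevels(droplevels(tr_y)) < nlevels(y)) {
      excluded <- c(excluded, i)
      next
    }
    if (spec$scaled) {
      mu <- colMeans(tr_X)
      sdev <- pmax(apply(tr_X, 2, sd), 1e-12)
      tr_Xs <- scale(tr_X, mu, sdev)
      te_Xs <- scale(X[i, , drop = FALSE], mu, sdev)
    } else {
      tr_Xs <- tr_X; te_Xs <- X[i, , drop = FALSE]
    }
    fold_spec <- spec
    fold_spec$seed <- spec$seed + i
    m <- fit_classifier(fold_spec, tr_Xs, tr_y)
    pred[i] <- predict_classifier(m, te_Xs)
  }
  if (length(excluded))
    warning(length(excluded), " fold(s) excluded: training part missing a class",
            call. = FALSE)
  keep <- setdiff(seq_len(n), excluded)
  cm <- table(truth = y[keep], predicted = pred[keep])
  acc <- sum(diag(cm)) / sum(cm)
  f1 <- f1_from_confusion(cm)
  gini <- NULL
  if (spec$family == "RF") {
    full <- fit_classifier(spec, X, y)
    gini <- full$fit$importance
  }
  structure(list(predicted = pred, truth = y, accuracy = acc,
                 f1 = f1$value, f1_type = f1$type, confusion = cm,
                 gini_importances = gini, excluded_folds = excluded,
                 spec = spec),
            class = "prediction_report")
}

f1_from_confusion <- function(cm) {
  K <- nrow(cm)
  per_class <- vapply(seq_len(K), function(k) {
    tp <- cm[k, k]
    prec <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  if (K == 2) list(value = per_class[2], type = "binary")
  else list(value = mean(per_class), type = "macro")
}

#' Gini (mean decrease in impurity) feature importance
#'
#' Normalized impurity-decrease importances of a random forest fitted on the
#' full data (the standard usage), with the descending feature ranking
#' attached.
#'
#' @param x feature table.
#' @param labels class labels.
#' @param spec a [model_spec()] with `family = "RF"`.
#' @return named numeric vector summing to 1, attribute `ranking`.
#' @export
gini_importance <- function(x, labels, spec = model_spec("RF")) {
  if (spec$family != "RF")
    stop("Gini importance requires an RF model_spec", call. = FALSE)
  X <- as.matrix(as.data.frame(x)[, vapply(as.data.frame(x), is.numeric,
                                           logical(1)), drop = FALSE])
  m <- fit_classifier(spec, X, factor(labels))
  imp <- m$fit$importance
  structure(imp, ranking = names(sort(imp, decreasing = TRUE)))
}

#' Compare classifier families under LOOCV
#'
#' @param x feature table.
#' @param labels class labels.
#' @param specs list of [model_spec()]s (default: all four families with the
#'   same seed).
#' @return data.frame `family, accuracy, f1`, sorted by accuracy then F1 then
#'   family name (descending performance).
#' @export
compare_models <- function(x, labels,
                           specs = lapply(c("RF", "SVM", "CART", "ANN"),
                                          model_spec)) {
  if (length(specs) < 1) stop("need at least one model spec", call. = FALSE)
  rows <- lapply(specs, function(sp) {
    rep <- loocv_evaluate(x, labels, sp)
    data.frame(family = sp$family, accuracy = rep$accuracy, f1 = rep$f1)
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy, -out$f1, out$family), , drop = FALSE]
}

#' Serialize a prediction report to JSON
#' @param report a `prediction_report` from [loocv_evaluate()].
#' @param path output path.
#' @export
write_prediction_json <- function(report, path) {
  jsonlite::write_json(
    list(family = report$spec$family,
         accuracy = report$accuracy, f1 = report$f1, f1_type = report$f1_type,
         confusion = as.data.frame(report$confusion),
         predicted = as.character(report$predicted),
         truth = as.character(report$truth),
         gini_importances = as.list(report$gini_importances)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
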
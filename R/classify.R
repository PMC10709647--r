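#' Default regularisation grid
#'
#' 13 log-spaced penalty strengths covering under- to over-regularised
#' regimes for p >> n problems.
#'
#' @return Numeric vector `10^seq(-3, 3, length.out = 13)`.
#' @export
lambda_grid <- function() 10^seq(-3, 3, length.out = 13)

as_binary_labels <- function(labels, positive = "ASD-like") {
  u <- unique(labels)
  if (length(u) != 2L) stop("labels must contain exactly two classes")
  if (!positive %in% u) positive <- u[1]
  list(y = as.integer(labels == positive), positive = positive,
       negative = setdiff(u, positive))
}

#' Fit an L2-regularised logistic regression
#'
#' Minimises `sum_i log(1 + exp(-yi mi)) + (lambda/2) ||w||^2` (intercept
#' unpenalised) by damped Newton iterations; for p > n the Newton system is
#' solved in the n-dimensional dual space (Woodbury identity), so wide
#' feature tables are cheap. Features are standardised internally (training
#' statistics are stored and reapplied at prediction time).
#'
#' @param x numeric matrix, subjects x features.
#' @param y group labels (two classes) or 0/1 vector.
#' @param strength penalty weight `lambda` > 0.
#' @param positive label treated as the positive (ASD) class.
#' @param standardize centre/scale columns before fitting (default TRUE).
#' @param tol convergence threshold on the gradient norm (default 1e-8).
#' @param maxit maximum Newton iterations.
#' @return Object of class `l2_logit` with standardised-scale `weights` and
#'   `intercept`, the scaling (`center`, `scale`), `lambda`, class labels,
#'   `grad_norm` and `converged`.
#' @export
fit_l2_logistic <- function(x, y, strength, positive = "ASD-like",
                            standardize = TRUE, tol = 1e-8, maxit = 100L) {
  stopifnot(is.matrix(x))
  if (!all(is.finite(x))) stop("non-finite values in x")
  if (!is.numeric(strength) || strength <= 0) stop("strength must be > 0")
  if (is.numeric(y) && all(y %in% c(0, 1))) {
    bl <- list(y = as.integer(y), positive = 1, negative = 0)
  } else {
    bl <- as_binary_labels(y, positive)
  }
  y01 <- bl$y
  if (length(unique(y01)) != 2L) stop("both classes must be present")
  n <- nrow(x); p <- ncol(x)
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
    Z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  } else {
    ctr <- rep(0, p); scl <- rep(1, p); Z <- x
  }
  lambda <- strength
  w <- rep(0, p)
  pr <- mean(y01)
  b <- log(max(pr, 1e-6) / max(1 - pr, 1e-6))
  obj <- function(b, w) {
    m <- b + drop(Z %*% w)
    sum(log1p(exp(-abs(m))) + pmax(-((2 * y01 - 1) * m), 0)) +
      lambda / 2 * sum(w^2)
  }
  f0 <- obj(b, w)
  for (it in seq_len(maxit)) {
    m <- b + drop(Z %*% w)
    p_hat <- stats::plogis(m)
    g_w <- drop(crossprod(Z, p_hat - y01)) + lambda * w
    g_b <- sum(p_hat - y01)
    gn <- sqrt(sum(g_w^2) + g_b^2)
    if (gn < tol) break
    s <- pmax(p_hat * (1 - p_hat), 1e-10)
    if (p > n) {
      B <- Z * sqrt(s)
      K <- diag(lambda, n) + tcrossprod(B)
      Kc <- chol(K)
      solveA <- function(V) {
        V <- as.matrix(V)
        (V - crossprod(B, backsolve(Kc, forwardsolve(t(Kc), B %*% V)))) / lambda
      }
    } else {
      A <- crossprod(Z * sqrt(s)) + diag(lambda, p)
      Ac <- chol(A)
      solveA <- function(V)
        backsolve(Ac, forwardsolve(t(Ac), as.matrix(V)))
    }
    cvec <- drop(crossprod(Z, s))
    a_bb <- sum(s)
    Ai_gw <- solveA(g_w)
    Ai_c <- solveA(cvec)
    schur <- a_bb - sum(cvec * Ai_c)
    d_b <- (g_b - sum(cvec * Ai_gw)) / schur
    d_w <- drop(Ai_gw) - drop(Ai_c) * d_b
    step <- 1
    repeat {
      b_new <- b - step * d_b
      w_new <- w - step * d_w
      f_new <- obj(b_new, w_new)
      if (f_new <= f0 + 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    b <- b_new; w <- w_new; f0 <- f_new
  }
  m <- b + drop(Z %*% w)
  p_hat <- stats::plogis(m)
  g_w <- drop(crossprod(Z, p_hat - y01)) + lambda * w
  gn <- sqrt(sum(g_w^2) + sum(p_hat - y01)^2)
  structure(
    list(weights = w, intercept = b, center = ctr, scale = scl,
         lambda = lambda, positive = bl$positive, negative = bl$negative,
         feature_names = colnames(x), grad_norm = gn,
         converged = gn < max(tol, 1e-6), objective = f0),
    class = "l2_logit")
}

#' @export
print.l2_logit <- function(x, ...) {
  cat(sprintf("<l2_logit> %d features, lambda = %g, |grad| = %.2g\n",
              length(x$weights), x$lambda, x$grad_norm))
  invisible(x)
}

#' Predict from an L2 logistic model
#'
#' @param object an `l2_logit`.
#' @param newdata matrix on the original feature scale.
#' @param type `"prob"` (positive-class probability), `"link"` (margin,
#'   log-odds) or `"class"`.
#' @param ... unused.
#' @export
predict.l2_logit <- function(object, newdata,
                             type = c("prob", "link", "class"), ...) {
  type <- match.arg(type)
  Z <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, `/`)
  m <- object$intercept + drop(Z %*% object$weights)
  switch(type,
         link = m,
         prob = stats::plogis(m),
         class = ifelse(m > 0, object$positive, object$negative))
}

# effective linear form on the raw feature scale: margin = b0 + x %*% w0
raw_linear_form <- function(model) {
  w0 <- model$weights / model$scale
  b0 <- model$intercept - sum(model$weights * model$center / model$scale)
  list(w = w0, b = b0)
}

# stratified fold assignment, deterministic given seed
make_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(vapply(split(labels, fold), function(l) length(unique(l)),
                 integer(1)) < 2L))
    stop("stratification failed: a fold lost one class entirely")
  fold
}

# rank-based AUC (probability that a positive outranks a negative)
auc_rank <- function(y01, prob) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

fold_metrics <- function(y01, prob) {
  pred <- as.integer(prob > 0.5)
  c(acc = mean(pred == y01),
    sens = if (any(y01 == 1)) mean(pred[y01 == 1] == 1) else NA_real_,
    spec = if (any(y01 == 0)) mean(pred[y01 == 0] == 0) else NA_real_,
    auc = auc_rank(y01, prob))
}

# inner grid search: pooled k-fold accuracy per strength, ties broken
# toward stronger regularisation; the fold count is capped at the minority
# class size (tiny training sets fall back to the median strength)
select_strength <- function(x, y01, grid, inner, seed) {
  inner <- min(inner, min(table(y01)))
  if (inner < 2L) return(stats::median(grid))
  fold <- make_folds(y01, inner, seed)
  acc <- vapply(grid, function(lam) {
    correct <- 0L
    for (f in seq_len(inner)) {
      tr <- fold != f
      fit <- fit_l2_logistic(x[tr, , drop = FALSE], y01[tr], lam)
      pr <- predict(fit, x[!tr, , drop = FALSE], type = "prob")
      correct <- correct + sum((pr > 0.5) == (y01[!tr] == 1))
    }
    correct / length(y01)
  }, numeric(1))
  best <- which(acc >= max(acc) - 1e-12)
  grid[max(best)]
}

#' Nested cross-validation of the L2 logistic classifier
#'
#' Stratified 6-outer / 5-inner nested cross-validation: the inner loop
#' grid-searches the regularisation strength by pooled accuracy (ties
#' toward stronger regularisation), the outer loop scores the refitted
#' model on held-out subjects. Standardisation is always computed from the
#' training portion alone (inside [fit_l2_logistic()]).
#'
#' @param table a `feature_table`.
#' @param outer,inner fold counts (defaults 6 and 5).
#' @param grid regularisation strengths (default [lambda_grid()]).
#' @param seed integer seed driving all fold assignments.
#' @param positive positive-class label.
#' @return Object of class `cv_report`: per-fold metric data.frame
#'   (`folds`), `mean` and `sd` of each metric, selected strength per fold
#'   and per-subject outer-fold probabilities.
#' @export
nested_cv <- function(table, outer = 6L, inner = 5L, grid = lambda_grid(),
                      seed = 1L, positive = "ASD-like") {
  stopifnot(inherits(table, "feature_table"))
  bl <- as_binary_labels(table$labels, positive)
  y01 <- bl$y
  x <- table$x
  fold <- make_folds(y01, outer, seed)
  metrics <- matrix(NA_real_, outer, 4,
                    dimnames = list(NULL, c("acc", "sens", "spec", "auc")))
  strengths <- numeric(outer)
  prob <- rep(NA_real_, nrow(x))
  for (f in seq_len(outer)) {
    tr <- fold != f
    lam <- select_strength(x[tr, , drop = FALSE], y01[tr], grid, inner,
                           seed = seed * 1000L + f)
    fit <- fit_l2_logistic(x[tr, , drop = FALSE], y01[tr], lam)
    pr <- predict(fit, x[!tr, , drop = FALSE], type = "prob")
    prob[!tr] <- pr
    metrics[f, ] <- fold_metrics(y01[!tr], pr)
    strengths[f] <- lam
  }
  structure(
    list(folds = data.frame(fold = seq_len(outer), metrics,
                            strength = strengths),
         mean = colMeans(metrics, na.rm = TRUE),
         sd = apply(metrics, 2, stats::sd, na.rm = TRUE),
         probabilities = data.frame(subject_id = table$subject_ids,
                                    label = table$labels, prob = prob),
         outer = outer, inner = inner, seed = seed,
         positive = bl$positive, set = table$set),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d x %d nested CV\n", x$set, x$outer, x$inner))
  for (m in names(x$mean))
    cat(sprintf("  %-5s %.3f (%.3f)\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Leave-one-out per-subject predictions
#'
#' For each subject: grid-search the strength by stratified 5-fold CV on
#' the remaining subjects, refit on them, and predict the held-out
#' subject's positive-class probability. A subject is misclassified when
#' the 0.5-thresholded label disagrees with the true one.
#'
#' @inheritParams nested_cv
#' @param inner inner fold count for the per-subject grid search.
#' @return Object of class `loo_predictions`: data.frame with
#'   `subject_id`, `label`, `prob`, `predicted`, `misclassified`.
#' @export
loo_predict <- function(table, grid = lambda_grid(), seed = 1L,
                        inner = 5L, positive = "ASD-like") {
  stopifnot(inherits(table, "feature_table"))
  bl <- as_binary_labels(table$labels, positive)
  y01 <- bl$y
  if (sum(y01 == 1) < 2L || sum(y01 == 0) < 2L)
    stop("need at least 2 subjects per class")
  x <- table$x
  n <- nrow(x)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    lam <- select_strength(x[tr, , drop = FALSE], y01[tr], grid, inner,
                           seed = seed * 1000L + i)
    fit <- fit_l2_logistic(x[tr, , drop = FALSE], y01[tr], lam)
    prob[i] <- predict(fit, x[i, , drop = FALSE], type = "prob")
  }
  pred <- ifelse(prob > 0.5, bl$positive, bl$negative)
  df <- data.frame(subject_id = table$subject_ids, label = table$labels,
                   prob = prob, predicted = pred,
                   misclassified = pred != table$labels,
                   stringsAsFactors = FALSE)
  structure(list(predictions = df, positive = bl$positive, seed = seed,
                 set = table$set),
            class = "loo_predictions")
}

#' @export
print.loo_predictions <- function(x, ...) {
  df <- x$predictions
  cat(sprintf("<loo_predictions> %s: %d subjects, %d misclassified\n",
              x$set, nrow(df), sum(df$misclassified)))
  invisible(x)
}
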
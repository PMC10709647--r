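#' Ledoit-Wolf shrunk covariance
#'
#' Well-conditioned covariance estimate `rho * m * I + (1 - rho) * S`
#' (shrinkage toward the scaled identity, intensity estimated from the
#' data), needed because the explanation background typically has far
#' fewer subjects than features.
#'
#' @param x numeric matrix, observations x variables.
#' @param min_shrink lower bound on the shrinkage intensity (default 1e-4)
#'   so the result is always positive definite.
#' @return List with `sigma` (shrunk covariance), `shrinkage`, `mean`.
#' @export
shrunk_covariance <- function(x, min_shrink = 1e-4) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need at least 2 background rows")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc) / n
  m <- sum(diag(S)) / p
  if (m <= 0) m <- 1e-12
  d2 <- sum((S - diag(m, p))^2) / p
  b2bar <- (sum(rowSums(xc^2)^2) - n * sum(S^2)) / (n^2 * p)
  rho <- if (d2 <= 0) 1 else max(min_shrink, min(1, max(0, b2bar) / d2))
  list(sigma = rho * diag(m, p) + (1 - rho) * S, shrinkage = rho, mean = mu)
}

#' Correlation-respecting Shapley attributions for a linear model
#'
#' Shapley values of the model margin (log-odds) under *conditional*
#' expectations: absent features are integrated out with the Gaussian
#' conditional law implied by the (shrunk) background covariance, so
#' correlated features share the credit for a common effect. For a linear
#' model the value of a coalition S is
#' `v(S) = b + w' (mu + Sigma[,S] Sigma[S,S]^{-1} (x_S - mu_S))`, and the
#' attribution is the average marginal contribution over feature
#' orderings: enumerated exactly for up to `enum_max` features, otherwise
#' estimated from `nperm` sampled orderings (each with its reversal, which
#' keeps the estimate exactly locally accurate: the contributions of every
#' ordering telescope to `margin - base`).
#'
#' @param model an `l2_logit` (linear in its inputs).
#' @param x_background matrix used to estimate the feature mean and
#'   covariance (>= 2 rows; typically the training subjects).
#' @param x_explain matrix of subjects to explain (default: the
#'   background).
#' @param nperm number of sampled orderings for large p (default 128).
#' @param enum_max exhaustive enumeration threshold on p (default 6).
#' @param seed integer seed for the sampled orderings.
#' @return Object of class `shap_explanation`: `sv` (subjects x features),
#'   `base_value` (margin at the background mean), `margin` (per-subject
#'   model margin), `shrinkage`.
#' @export
conditional_shap <- function(model, x_background, x_explain = x_background,
                             nperm = 128L, enum_max = 6L, seed = 1L) {
  stopifnot(inherits(model, "l2_logit"))
  x_background <- as.matrix(x_background)
  x_explain <- as.matrix(x_explain)
  p <- ncol(x_background)
  if (ncol(x_explain) != p) stop("background/explain width mismatch")
  lin <- raw_linear_form(model)
  sc <- shrunk_covariance(x_background)
  sigma <- sc$sigma
  mu <- sc$mean
  xc <- sweep(x_explain, 2, mu)
  u_full <- drop(sigma %*% lin$w)
  n_ex <- nrow(x_explain)
  sv <- matrix(0, n_ex, p)
  perm_contrib <- function(ord) {
    # attribution of one ordering, all subjects at once; prefix property of
    # the Cholesky factor gives every leading conditional from one chol
    R <- chol(sigma[ord, ord, drop = FALSE])
    yf <- forwardsolve(t(R), u_full[ord])
    Xo <- xc[, ord, drop = FALSE]
    out <- matrix(0, n_ex, p)
    prev <- rep(0, n_ex)
    for (k in seq_len(p)) {
      z <- backsolve(R[seq_len(k), seq_len(k), drop = FALSE], yf[seq_len(k)])
      cur <- drop(Xo[, seq_len(k), drop = FALSE] %*% z)
      out[, ord[k]] <- cur - prev
      prev <- cur
    }
    out
  }
  if (factorial(p) <= factorial(enum_max)) {
    perms <- all_permutations(p)
    for (ord in perms) sv <- sv + perm_contrib(ord)
    sv <- sv / length(perms)
  } else {
    withr::with_seed(seed, {
      n_draw <- ceiling(nperm / 2)
      for (d in seq_len(n_draw)) {
        ord <- sample.int(p)
        sv <- sv + perm_contrib(ord) + perm_contrib(rev(ord))
      }
      sv <- sv / (2 * n_draw)
    })
  }
  colnames(sv) <- colnames(x_background)
  rownames(sv) <- rownames(x_explain)
  base <- lin$b + sum(lin$w * mu)
  structure(
    list(sv = sv, base_value = base,
         margin = lin$b + drop(x_explain %*% lin$w),
         shrinkage = sc$shrinkage),
    class = "shap_explanation")
}

all_permutations <- function(p) {
  if (p == 1L) return(list(1L))
  sub <- all_permutations(p - 1L)
  out <- vector("list", p * length(sub))
  i <- 0L
  for (s in sub) {
    for (pos in 0:(p - 1L)) {
      i <- i + 1L
      out[[i]] <- append(s, p, after = pos)
    }
  }
  out
}

#' Normalised feature importance from Shapley values
#'
#' Importance of each feature = mean absolute Shapley value across
#' subjects, divided by the maximal importance (so `max(FI) = 1`). When
#' labels are supplied the same summary is also computed per group
#' (each group normalised by its own maximum), mirroring group-conditional
#' importance maps.
#'
#' @param shap a `shap_explanation` or a numeric SV matrix
#'   (subjects x features).
#' @param labels optional group labels, one per explained subject.
#' @return Object of class `explanation_report`: `fi` (named vector,
#'   max = 1), optional `fi_by_group` (features x groups matrix), `sv`.
#' @export
feature_importance <- function(shap, labels = NULL) {
  sv <- if (inherits(shap, "shap_explanation")) shap$sv else as.matrix(shap)
  fi_raw <- colMeans(abs(sv))
  if (max(fi_raw) == 0)
    stop("all Shapley values are zero; normalisation undefined")
  fi <- fi_raw / max(fi_raw)
  fi_by_group <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(sv))
    fi_by_group <- vapply(unique(labels), function(g) {
      v <- colMeans(abs(sv[labels == g, , drop = FALSE]))
      if (max(v) > 0) v / max(v) else v
    }, numeric(ncol(sv)))
    rownames(fi_by_group) <- colnames(sv)
  }
  structure(list(fi = fi, fi_by_group = fi_by_group, sv = sv),
            class = "explanation_report")
}
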
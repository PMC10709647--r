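#' Two-tailed Wilcoxon rank-sum test
#'
#' Rank-sum statistic of the first sample with midrank tie handling. For
#' small layouts (`n_a + n_b <= exact_max`) the two-tailed p-value is the
#' exact permutation probability `P(|W - E W| >= |w - E W|)` over all
#' `choose(n, n_a)` group assignments of the pooled midranks; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param sample_a,sample_b numeric vectors, each non-empty.
#' @param exact_max largest pooled size for which exact enumeration is the
#'   default (12).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration.
#' @return List with `statistic` (rank sum of `sample_a`), `p.value`,
#'   `method`.
#' @export
wilcoxon_ranksum <- function(sample_a, sample_b, exact = NULL,
                             exact_max = 12L) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 1L || nb < 1L) stop("both samples must be non-empty")
  if (!all(is.finite(c(sample_a, sample_b)))) stop("non-finite values")
  n <- na + nb
  r <- rank(c(sample_a, sample_b))
  W <- sum(r[seq_len(na)])
  EW <- na * (n + 1) / 2
  if (is.null(exact)) exact <- n <= exact_max
  if (exact) {
    dev <- abs(W - EW)
    combos <- utils::combn(n, na)
    Wall <- colSums(matrix(r[combos], nrow = na))
    p <- mean(abs(Wall - EW) >= dev - 1e-9)
    return(list(statistic = W, p.value = p, method = "exact"))
  }
  ties <- table(r)
  varW <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (varW <= 0) return(list(statistic = W, p.value = 1, method = "normal"))
  z <- (W - EW - sign(W - EW) * 0.5) / sqrt(varW)
  list(statistic = W, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement; the rejection
#' mask is `adjusted <= q`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and `rejected` (logical mask).
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values)
  adj <- numeric(n)
  adj[o] <- pmin(1, rev(cummin(rev(p_values[o] * n / seq_len(n)))))
  list(adjusted = adj, rejected = adj <= q)
}

#' Friedman rank test
#'
#' Within-block midranks, tie-corrected chi-square statistic with
#' `k - 1` degrees of freedom. At perfect concordance the statistic
#' attains its maximum `n (k - 1)`; on constant data it is 0.
#'
#' @param data numeric matrix, `n` blocks x `k` conditions, no missing
#'   cells.
#' @return An object of class `friedman_result`: `statistic`, `df`,
#'   `p.value`, `n_blocks`, `k_conditions`.
#' @export
friedman_test <- function(data) {
  stopifnot(is.matrix(data))
  if (anyNA(data)) stop("missing cells are not allowed")
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L) stop("need >= 2 blocks and >= 2 conditions")
  r <- t(apply(data, 1, rank))
  tie_term <- sum(unlist(lapply(seq_len(n), function(i) {
    tt <- table(r[i, ]); sum(tt^3 - tt)
  })))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  stat <- if (denom <= 0) 0 else
    12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  structure(
    list(statistic = stat, df = k - 1L,
         p.value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
         n_blocks = n, k_conditions = k),
    class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-squared(%d) = %.4g, n = %d blocks, p = %.3g\n",
              x$df, x$statistic, x$n_blocks, x$p.value))
  invisible(x)
}

#' Mass-univariate group comparison with FDR control
#'
#' One two-tailed Wilcoxon rank-sum test per feature, Benjamini-Hochberg
#' correction across the whole family (all bands x channels or pairs of
#' one measure), and the direction of the group difference (+1 when the
#' positive/ASD-like group median is higher).
#'
#' @param features a `feature_table`, or a numeric subjects x features
#'   matrix.
#' @param labels group labels (taken from the table when omitted).
#' @param q FDR level (default 0.05).
#' @param positive label of the group whose excess is coded +1 (default
#'   `"ASD-like"`).
#' @return An object of class `stat_result`: data.frame with columns
#'   `feature`, `statistic`, `p`, `p_adj`, `significant`, `direction`.
#' @export
mass_univariate <- function(features, labels = NULL, q = 0.05,
                            positive = "ASD-like") {
  if (inherits(features, "feature_table")) {
    if (is.null(labels)) labels <- features$labels
    features <- features$x
  }
  stopifnot(is.matrix(features), length(labels) == nrow(features))
  grp <- unique(labels)
  if (length(grp) != 2L) stop("exactly two groups required")
  if (!positive %in% grp) positive <- grp[1]
  ia <- labels == positive
  if (sum(ia) < 2L || sum(!ia) < 2L)
    stop("each group needs at least 2 subjects")
  res <- apply(features, 2, function(v) {
    wt <- wilcoxon_ranksum(v[ia], v[!ia])
    dmed <- stats::median(v[ia]) - stats::median(v[!ia])
    c(wt$statistic, wt$p.value, sign(dmed))
  })
  bh <- benjamini_hochberg(res[2, ], q = q)
  out <- data.frame(
    feature = colnames(features), statistic = res[1, ], p = res[2, ],
    p_adj = bh$adjusted, significant = bh$rejected, direction = res[3, ],
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("stat_result", class(out))
  attr(out, "q") <- q
  attr(out, "positive") <- positive
  out
}

#' Per-band Friedman tests for channel and group effects
#'
#' The two-factor report is realised as two one-way Friedman calls per
#' band: a channel effect with subjects as blocks and channels as
#' conditions (df = channels - 1), and a group effect with matched
#' subject pairs as blocks and the two groups as conditions (df = 1),
#' using the channel-mean feature value per subject. Pairing defaults to
#' table order within each group (the synthetic cohort is generated
#' matched).
#'
#' @param features a spectral `feature_table` (columns `<channel>_<band>`).
#' @param positive label of the first group (default `"ASD-like"`).
#' @return Named list per band, each with `channels` and `groups`
#'   `friedman_result` objects.
#' @export
friedman_band_tests <- function(features, positive = "ASD-like") {
  stopifnot(inherits(features, "feature_table"))
  labels <- features$labels
  bands <- eeg_bands()$name
  out <- list()
  for (b in bands) {
    cols <- grep(paste0("_", b, "$"), features$feature_names)
    if (!length(cols)) stop("no columns for band ", b)
    X <- features$x[, cols, drop = FALSE]
    ia <- which(labels == positive); ib <- which(labels != positive)
    if (length(ia) != length(ib))
      stop("group test needs matched equal-size groups")
    grp_mat <- cbind(rowMeans(X[ia, , drop = FALSE]),
                     rowMeans(X[ib, , drop = FALSE]))
    out[[b]] <- list(channels = friedman_test(X),
                     groups = friedman_test(grp_mat))
  }
  out
}

#' Export a stat_result as a TSV file
#'
#' @param stat a `stat_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stat_result <- function(stat, path) {
  utils::write.table(as.data.frame(stat), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
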
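#' Standard 19-electrode 10-20 montage
#'
#' Electrode labels in the fixed order used throughout the package
#' (anterior to posterior, left to right). `T3/T4/T5/T6` naming is used,
#' as in older clinical systems; [normalize_channel_labels()] maps the
#' modern `T7/T8/P7/P8` synonyms onto it.
#'
#' @return Character vector of 19 channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Frontal electrodes of the 10-20 montage
#'
#' The frontal/vertex subset (`Fp1 Fp2 F3 F4 F7 F8 Cz`) where the ASD-like
#' group of the default synthetic preset carries elevated band power.
#'
#' @return Character vector of 7 labels.
#' @export
frontal_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Cz")
}

#' Canonical EEG frequency bands
#'
#' theta 4-7 Hz, alpha 8-12 Hz, low beta (beta1) 13-20 Hz and high beta
#' (beta2) 21-30 Hz.
#'
#' @return A data.frame with columns `name`, `f_low`, `f_high`,
#'   `center` (midpoint, Hz) and `order` (connectivity FIR filter order:
#'   24 for theta/alpha/beta1, 50 for beta2).
#' @export
eeg_bands <- function() {
  data.frame(
    name   = c("theta", "alpha", "beta1", "beta2"),
    f_low  = c(4, 8, 13, 21),
    f_high = c(7, 12, 20, 30),
    center = c(5.5, 10, 16.5, 25.5),
    order  = c(24L, 24L, 24L, 50L),
    stringsAsFactors = FALSE
  )
}

#' Normalize channel labels to the package's canonical 10-20 names
#'
#' Matching is case- and whitespace-insensitive and accepts the common
#' synonyms T7->T3, T8->T4, P7->T5, P8->T6 (and "EEG Fp1"-style prefixes).
#'
#' @param labels character vector of raw labels.
#' @return Character vector of canonical labels.
#' @export
normalize_channel_labels <- function(labels) {
  canon <- montage_1020()
  syn <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  cleaned <- gsub("^EEG[ _-]*", "", trimws(labels), ignore.case = TRUE)
  cleaned <- gsub("[[:space:]]+", "", cleaned)
  idx <- match(toupper(cleaned), toupper(names(syn)))
  cleaned[!is.na(idx)] <- syn[idx[!is.na(idx)]]
  pos <- match(toupper(cleaned), toupper(canon))
  if (anyNA(pos)) {
    stop("unrecognized channel label(s): ",
         paste(labels[is.na(pos)], collapse = ", "),
         "; expected 10-20 names: ", paste(canon, collapse = " "))
  }
  canon[pos]
}

#' Unique channel pairs in canonical order
#'
#' Lexicographic enumeration (i < j) over a fixed label order; for the
#' 18 post-reference channels this yields the 153 pairs indexing every
#' connectivity feature vector.
#'
#' @param labels character vector of channel labels.
#' @return data.frame with columns `a`, `b` (labels) and `i`, `j`
#'   (1-based positions, i < j).
#' @export
channel_pairs <- function(labels) {
  n <- length(labels)
  if (n < 2) stop("need at least 2 channels")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(a = labels[idx[, "row"]], b = labels[idx[, "col"]],
             i = idx[, "row"], j = idx[, "col"],
             stringsAsFactors = FALSE)
}
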
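#' Build a pipeline run configuration
#'
#' Either an EDF cohort directory (`edf_dir`, as written by
#' [write_cohort_edf()]) or a simulation configuration drives the run.
#'
#' @param outdir output directory.
#' @param simulation a [sim_config()] (ignored when `edf_dir` is given).
#' @param edf_dir optional cohort directory with `cohort.csv`.
#' @param feature_sets subset of `c("spectral", "plv", "ciplv")` to
#'   compute and test (at least one).
#' @param classify_sets feature sets to run classification on
#'   (default: `feature_sets`).
#' @param q FDR level in (0, 1).
#' @param outer,inner nested cross-validation split counts.
#' @param epoch_s epoch length, seconds.
#' @param seed master seed for simulation and fold assignment.
#' @param write_edf also export the (simulated) cohort as EDF files.
#' @param shap_nperm sampled orderings for the Shapley explanations.
#' @return Object of class `run_config`.
#' @export
run_config <- function(outdir,
                       simulation = default_cohort_config(),
                       edf_dir = NULL,
                       feature_sets = c("spectral", "plv", "ciplv"),
                       classify_sets = feature_sets,
                       q = 0.05, outer = 6L, inner = 5L, epoch_s = 2,
                       seed = 1L, write_edf = FALSE, shap_nperm = 128L) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  if (!length(feature_sets)) stop("select at least one feature set")
  classify_sets <- intersect(classify_sets, feature_sets)
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)")
  structure(
    list(outdir = outdir, simulation = simulation, edf_dir = edf_dir,
         feature_sets = feature_sets, classify_sets = classify_sets,
         q = q, outer = outer, inner = inner, epoch_s = epoch_s,
         seed = as.integer(seed), write_edf = write_edf,
         shap_nperm = shap_nperm),
    class = "run_config")
}

#' Load a run configuration from a JSON document
#'
#' The JSON mirrors [run_config()]; the `simulation` element mirrors
#' [sim_config()], with `couplings` as a list of
#' `{pair, band, lag_rad, kappa, group}` records and `band_amplitudes`
#' optional (default preset when absent).
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sim <- default_cohort_config()
  if (!is.null(doc$simulation)) {
    s <- doc$simulation
    cps <- if (is.null(s$couplings)) default_couplings() else
      lapply(s$couplings, function(cp)
        coupling_spec(unlist(cp$pair), cp$band, cp$lag_rad, cp$kappa,
                      if (is.null(cp$group)) "both" else cp$group))
    args <- s[intersect(names(s), c("n_per_group", "fs", "duration_s",
                                    "noise_exponent", "noise_rms",
                                    "subject_cv", "seed"))]
    args$couplings <- cps
    sim <- do.call(sim_config, args)
  }
  args <- doc[intersect(names(doc), c("outdir", "edf_dir", "feature_sets",
                                      "classify_sets", "q", "outer", "inner",
                                      "epoch_s", "seed", "write_edf",
                                      "shap_nperm"))]
  args$simulation <- sim
  do.call(run_config, args)
}

with_stage <- function(stage, sid, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "'",
         if (!is.null(sid)) paste0(" (subject ", sid, ")"), ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Write / read a feature table as CSV
#'
#' Rows are subjects; the first two columns are `subject_id` and
#' `group_label`, the rest are features.
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `path` (write) or a `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject_id = table$subject_ids,
                   group_label = table$labels,
                   table$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param set feature-set tag attached when reading.
#' @export
read_feature_table <- function(path, set = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$subject_id
  new_feature_table(x, df$group_label, set)
}

#' Run the full analysis pipeline
#'
#' simulate (or read EDF) -> preprocess -> features -> statistics ->
#' classification, writing every stage product under `config$outdir` and
#' returning a manifest with provenance hashes. Deterministic given the
#' config (including its seeds).
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts <- list()

  recordings <- if (!is.null(config$edf_dir)) {
    with_stage("load", NULL, read_cohort_edf(config$edf_dir))
  } else {
    sim <- config$simulation
    sim$seed <- config$seed
    with_stage("simulate", NULL, generate_cohort(sim))
  }
  counts$subjects <- length(recordings)
  if (config$write_edf) {
    with_stage("write-edf", NULL,
               write_cohort_edf(recordings, file.path(config$outdir, "edf")))
    outputs <- c(outputs, file.path("edf", "cohort.csv"))
  }

  prep <- lapply(recordings, function(rec)
    with_stage("preprocess", rec$subject_id, preprocess_recording(rec)))

  tables <- list()
  for (set in config$feature_sets) {
    tab <- with_stage("features", NULL, {
      if (set == "spectral") spectral_feature_table(prep, config$epoch_s)
      else connectivity_feature_table(prep, measure = set,
                                      epoch_s = config$epoch_s)
    })
    tables[[set]] <- tab
    f <- paste0("features_", set, ".csv")
    write_feature_table(tab, file.path(config$outdir, f))
    outputs <- c(outputs, f)
    counts[[paste0("features_", set)]] <- ncol(tab$x)
  }

  for (set in config$feature_sets) {
    st <- with_stage("stats", NULL,
                     mass_univariate(tables[[set]], q = config$q))
    f <- paste0("stats_", set, ".tsv")
    write_stat_result(st, file.path(config$outdir, f))
    outputs <- c(outputs, f)
    counts[[paste0("significant_", set)]] <- sum(st$significant)
  }
  if ("spectral" %in% config$feature_sets) {
    fr <- with_stage("stats", NULL, friedman_band_tests(tables$spectral))
    f <- "friedman_spectral.json"
    jsonlite::write_json(
      lapply(fr, function(b) lapply(b, function(r)
        list(chi_sq = r$statistic, df = r$df, p = r$p.value))),
      file.path(config$outdir, f), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
  }

  for (set in config$classify_sets) {
    tab <- tables[[set]]
    cv <- with_stage("classify", NULL,
                     nested_cv(tab, outer = config$outer,
                               inner = config$inner, seed = config$seed))
    loo <- with_stage("classify", NULL,
                      loo_predict(tab, seed = config$seed))
    fit <- with_stage("classify", NULL,
                      fit_l2_logistic(tab$x, tab$labels,
                                      strength = stats::median(cv$folds$strength)))
    ex <- with_stage("explain", NULL,
                     conditional_shap(fit, tab$x, nperm = config$shap_nperm,
                                      seed = config$seed))
    fi <- feature_importance(ex, labels = tab$labels)
    f_cv <- paste0("cv_", set, ".json")
    jsonlite::write_json(
      list(folds = cv$folds, mean = as.list(cv$mean), sd = as.list(cv$sd)),
      file.path(config$outdir, f_cv), auto_unbox = TRUE, digits = NA)
    f_loo <- paste0("loo_", set, ".json")
    jsonlite::write_json(loo$predictions, file.path(config$outdir, f_loo),
                         auto_unbox = TRUE, digits = NA)
    f_fi <- paste0("fi_", set, ".tsv")
    fi_df <- data.frame(feature = names(fi$fi), fi = fi$fi)
    if (!is.null(fi$fi_by_group))
      fi_df <- cbind(fi_df, as.data.frame(fi$fi_by_group,
                                          check.names = FALSE))
    utils::write.table(fi_df, file.path(config$outdir, f_fi), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    # probability-strip export (per-subject LOO probabilities)
    f_strip <- paste0("probability_strip_", set, ".csv")
    utils::write.csv(loo$predictions[, c("subject_id", "label", "prob")],
                     file.path(config$outdir, f_strip), row.names = FALSE)
    outputs <- c(outputs, f_cv, f_loo, f_fi, f_strip)
    counts[[paste0("misclassified_", set)]] <- sum(loo$predictions$misclassified)
  }

  hashes <- as.list(tools::md5sum(file.path(config$outdir, outputs)))
  names(hashes) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("eegfc")),
    seed = config$seed,
    feature_sets = config$feature_sets,
    classify_sets = config$classify_sets,
    q = config$q, epoch_s = config$epoch_s,
    counts = counts, outputs = hashes)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
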
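#' Full discrimination-performance pipeline
#'
#' Chains the stages for every condition present in the input: quenching
#' normalization against the condition's blanks, wavelength windowing,
#' mean-centred PCA to the score plane, per-sample confidence ellipses, and
#' all separability metrics (number of groups, CrN, overall RP, Mahalanobis
#' total sensitivity, QDA and SVM training sensitivities). With two or more
#' conditions the rank-sum rating is appended; with three or more, the metric
#' correlation matrix.
#'
#' @param spectra a [spectra_matrix()] or path to a wide spectra CSV.
#' @param meta metadata path (required when `spectra` is a path).
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV (scores, ellipses, crossings, RP pairs, membership, metric report,
#'   correlations).
#' @param window wavelength window in nm, default `c(430, 550)`; `NULL`
#'   disables windowing.
#' @param level confidence level for the sample ellipses, default 0.80.
#' @param dm_threshold Mahalanobis membership bound, default 4.
#' @param k number of principal components, default 2.
#' @param svm_kernels SVM kernels to evaluate; `character(0)` skips SVM.
#' @param adequacy_threshold residual-dispersion warning gate, default 0.05.
#' @return List with `report` (metric rows, rated when >= 2 conditions),
#'   `correlations` (or `NULL`), and per-condition `details` (score cloud,
#'   ellipses, tables, residual dispersion).
#' @export
run_pipeline <- function(spectra, meta = NULL, out_dir = NULL,
                         window = c(430, 550), level = 0.80, dm_threshold = 4,
                         k = 2, svm_kernels = c("linear", "poly3", "rbf"),
                         adequacy_threshold = 0.05) {
  if (is.character(spectra)) {
    if (is.null(meta)) fs_validation_error("metadata path required with a spectra path")
    spectra <- read_spectra(spectra, meta)
  }
  stopifnot(inherits(spectra, "spectra_matrix"))
  conds <- unique(spectra$meta$condition)
  details <- list()
  report <- NULL
  for (cond in conds) {
    rows <- spectra$meta$condition == cond
    sub <- spectra_matrix(spectra$values[rows, , drop = FALSE],
                          spectra$wavelengths, spectra$meta[rows, , drop = FALSE],
                          normalized = inherits(spectra, "quench_matrix"))
    q <- if (inherits(sub, "quench_matrix")) sub else quench_normalize(sub)
    if (!is.null(window)) q <- select_window(q, window[1], window[2])
    cloud <- fit_pca(q, k = k)
    res <- residual_dispersion(cloud)
    if (res > adequacy_threshold)
      warning(sprintf("condition '%s': residual dispersion %.2f%% exceeds %.2f%%",
                      cond, 100 * res, 100 * adequacy_threshold))
    ell <- sample_ellipses(cloud, level = level)
    details[[cond]] <- list(
      cloud = cloud, ellipses = ell, residual = res,
      crossings = crossing_table(ell),
      rp_pairs = rp_table(cloud),
      membership = total_sensitivity(cloud, threshold = dm_threshold)$table
    )
    report <- rbind(report, condition_metrics(
      cloud, level = level, dm_threshold = dm_threshold,
      svm_kernels = svm_kernels, condition = cond
    ))
  }
  correlations <- NULL
  if (nrow(report) >= 2L) report <- overall_rating(report)
  if (nrow(report) >= 3L) correlations <- metric_correlations(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in conds) {
      d <- details[[cond]]
      safe <- gsub("[^A-Za-z0-9._-]", "_", cond)
      write_scores(d$cloud, file.path(out_dir, paste0("scores_", safe, ".csv")))
      write_table_stable(ellipse_table(d$ellipses),
                         file.path(out_dir, paste0("ellipses_", safe, ".csv")))
      write_table_stable(d$crossings, file.path(out_dir, paste0("crossings_", safe, ".csv")))
      write_table_stable(d$rp_pairs, file.path(out_dir, paste0("rp_pairs_", safe, ".csv")))
      write_table_stable(d$membership, file.path(out_dir, paste0("membership_", safe, ".csv")))
    }
    write_table_stable(report, file.path(out_dir, "metric_report.csv"))
    if (!is.null(correlations)) {
      cm <- data.frame(metric = rownames(correlations), correlations,
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_table_stable(cm, file.path(out_dir, "metric_correlations.csv"))
    }
  }
  list(report = report, correlations = correlations, details = details)
}
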
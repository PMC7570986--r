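# Discrimination metrics computed in score space. All operate on an n x 2
# score matrix plus a class label per well (one class per sample id); the
# score_cloud methods strip blank wells first.

scores_and_labels <- function(cloud) {
  stopifnot(inherits(cloud, "score_cloud"))
  keep <- !cloud$meta$is_blank
  list(
    scores = cloud$scores[keep, 1:2, drop = FALSE],
    labels = as.character(cloud$meta$sample_id[keep]),
    wells = cloud$meta$well_id[keep]
  )
}

class_stats <- function(scores, labels, loo_index = NULL) {
  # per-class mean and covariance; loo_index (well row) excluded from its own
  # class when leave-one-out evaluation is requested
  classes <- unique(labels)
  out <- list()
  for (cl in classes) {
    idx <- which(labels == cl)
    if (!is.null(loo_index) && loo_index %in% idx) idx <- setdiff(idx, loo_index)
    if (length(idx) < 3L)
      fs_validation_error(paste0("class '", cl, "' has < 3 usable wells"))
    pts <- scores[idx, , drop = FALSE]
    S <- stats::cov(pts)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev, 0) * 1e-12 || min(ev) <= 0)
      fs_computation_error(paste0("singular covariance for class '", cl, "'"))
    out[[cl]] <- list(mean = colMeans(pts), cov = S,
                      logdet = determinant(S, logarithm = TRUE)$modulus[1])
  }
  out
}

#' Total sensitivity by Mahalanobis class membership
#'
#' Each well's Mahalanobis distance to every class (class mean and own
#' covariance) is compared with `threshold` (default 4). The well's membership
#' set is the classes within threshold; its status is `correct` when the set
#' is exactly its own class, `multi-class` when it matches more than one class
#' (potentially misclassified), `unowned` when it matches none, and
#' `misassigned` when it matches a single wrong class. Total sensitivity is
#' the fraction of `correct` wells.
#'
#' By default the evaluated well contributes to its own class statistics
#' (training-set sensitivity); `loo = TRUE` excludes it for an honest
#' leave-one-out variant.
#'
#' @param x a `score_cloud` or an n x 2 score matrix.
#' @param labels class labels (required for matrix input).
#' @param threshold Mahalanobis membership bound, default 4.
#' @param loo leave the evaluated well out of its own class statistics?
#' @return List with `ts` (fraction in [0, 1]), `table` (per-well membership
#'   data.frame) and `distances` (wells x classes Mahalanobis matrix).
#' @export
total_sensitivity <- function(x, labels = NULL, threshold = 4, loo = FALSE) {
  if (inherits(x, "score_cloud")) {
    sl <- scores_and_labels(x)
    scores <- sl$scores; labels <- sl$labels; wells <- sl$wells
  } else {
    scores <- as.matrix(x)
    if (is.null(labels)) fs_validation_error("labels required for matrix input")
    labels <- as.character(labels)
    wells <- rownames(scores) %||% paste0("w", seq_len(nrow(scores)))
  }
  classes <- unique(labels)
  n <- nrow(scores)
  D <- matrix(NA_real_, n, length(classes), dimnames = list(wells, classes))
  if (!loo) {
    st <- class_stats(scores, labels)
    for (cl in classes)
      D[, cl] <- sqrt(stats::mahalanobis(scores, st[[cl]]$mean, st[[cl]]$cov))
  } else {
    for (i in seq_len(n)) {
      st <- class_stats(scores, labels, loo_index = i)
      for (cl in classes)
        D[i, cl] <- sqrt(stats::mahalanobis(scores[i, , drop = FALSE],
                                            st[[cl]]$mean, st[[cl]]$cov))
    }
  }
  member <- D <= threshold
  status <- character(n)
  matched <- character(n)
  for (i in seq_len(n)) {
    ms <- classes[member[i, ]]
    matched[i] <- paste(ms, collapse = ";")
    status[i] <- if (length(ms) == 1L && ms == labels[i]) "correct"
      else if (length(ms) > 1L) "multi-class"
      else if (length(ms) == 0L) "unowned"
      else "misassigned"
  }
  list(
    ts = mean(status == "correct"),
    table = data.frame(
      well_id = wells, own_class = labels, n_matches = rowSums(member),
      matched_classes = matched, status = status, stringsAsFactors = FALSE
    ),
    distances = D
  )
}

#' Training sensitivity of quadratic discriminant analysis
#'
#' Assigns each well to the class minimizing the quadratic discriminant score
#' (x - mu_k)' S_k^-1 (x - mu_k) + log det S_k with per-class covariance S_k
#' and equal priors, and returns the fraction assigned to their own class.
#' Unlike the linear (pooled-covariance) rule, the per-class covariances give
#' a quadratic decision boundary.
#'
#' @inheritParams total_sensitivity
#' @return List with `sensitivity` and `assigned` (class per well).
#' @export
qda_sensitivity <- function(x, labels = NULL) {
  if (inherits(x, "score_cloud")) {
    sl <- scores_and_labels(x)
    scores <- sl$scores; labels <- sl$labels
  } else {
    scores <- as.matrix(x)
    if (is.null(labels)) fs_validation_error("labels required for matrix input")
    labels <- as.character(labels)
  }
  st <- class_stats(scores, labels)
  classes <- names(st)
  scoremat <- vapply(classes, function(cl) {
    stats::mahalanobis(scores, st[[cl]]$mean, st[[cl]]$cov) + st[[cl]]$logdet
  }, numeric(nrow(scores)))
  assigned <- classes[apply(scoremat, 1, which.min)]
  list(sensitivity = mean(assigned == labels), assigned = assigned)
}

#' Training sensitivity of a support-vector classifier
#'
#' Delegates to \pkg{e1071}'s multi-class SVM (one-vs-one C-classification,
#' unscaled inputs) with one of the kernels `"linear"`, `"poly3"` (3rd-degree
#' polynomial) or `"rbf"`, and returns the fraction of training wells
#' predicted as their own class.
#'
#' @inheritParams total_sensitivity
#' @param kernel one of `"linear"`, `"poly3"`, `"rbf"`.
#' @return Fraction in [0, 1].
#' @export
svm_sensitivity <- function(x, labels = NULL, kernel = c("linear", "poly3", "rbf")) {
  if (length(kernel) == 1L && !kernel %in% c("linear", "poly3", "rbf"))
    fs_validation_error(paste0("unknown kernel '", kernel, "'"))
  kernel <- match.arg(kernel)
  if (inherits(x, "score_cloud")) {
    sl <- scores_and_labels(x)
    scores <- sl$scores; labels <- sl$labels
  } else {
    scores <- as.matrix(x)
    if (is.null(labels)) fs_validation_error("labels required for matrix input")
    labels <- as.character(labels)
  }
  if (length(unique(labels)) < 2L) fs_validation_error("need >= 2 classes for SVM")
  y <- factor(labels)
  fit <- switch(kernel,
    linear = e1071::svm(scores, y, kernel = "linear", scale = FALSE),
    poly3  = e1071::svm(scores, y, kernel = "polynomial", degree = 3, scale = FALSE),
    rbf    = e1071::svm(scores, y, kernel = "radial", scale = FALSE)
  )
  mean(as.character(fit$fitted) == labels)
}

#' All discrimination metrics for one condition's score cloud
#'
#' Computes the full metric row for one measurement condition: number of
#' groups, total crossing number CrN, overall RP, total sensitivity by
#' Mahalanobis membership, QDA training sensitivity, and optional SVM
#' training sensitivities.
#'
#' @param cloud a `score_cloud` (blank wells are excluded from all metrics).
#' @param level confidence level of the sample ellipses, default 0.80.
#' @param dm_threshold Mahalanobis membership bound, default 4.
#' @param svm_kernels character vector of SVM kernels to evaluate (possibly
#'   empty).
#' @param condition condition label for the output row; defaults to the
#'   cloud's condition.
#' @return One-row data.frame: condition, n_groups, crn, rp, ts_mah, ts_qda
#'   and one `ts_svm_*` column per requested kernel.
#' @export
condition_metrics <- function(cloud, level = 0.80, dm_threshold = 4,
                              svm_kernels = c("linear", "poly3", "rbf"),
                              condition = NULL) {
  ell <- sample_ellipses(cloud, level = level)
  groups <- sample_groups(cloud)
  ts <- total_sensitivity(cloud, threshold = dm_threshold)
  row <- data.frame(
    condition = condition %||% as.character(cloud$meta$condition[1]),
    n_groups = count_groups(ell),
    crn = total_crossing_number(ell),
    rp = rp_overall(groups),
    ts_mah = ts$ts,
    ts_qda = qda_sensitivity(cloud)$sensitivity,
    stringsAsFactors = FALSE
  )
  for (kn in svm_kernels)
    row[[paste0("ts_svm_", kn)]] <- svm_sensitivity(cloud, kernel = kn)
  row
}

metric_polarity <- function(metric) {
  # +1: higher is better; -1: lower is better (only CrN)
  if (metric == "crn") -1 else 1
}

metric_columns <- function(report) {
  intersect(
    c("n_groups", "crn", "rp", "ts_mah", "ts_qda",
      grep("^ts_svm_", names(report), value = TRUE)),
    names(report)
  )
}

#' Pairwise correlations between discrimination metrics
#'
#' Correlates the metric columns of a multi-condition report across
#' conditions. Pearson by default (Spearman available); a zero-variance
#' column yields `NA` against every other metric.
#'
#' @param report data.frame with a `condition` column and metric columns
#'   (n_groups, crn, rp, ts_*); >= 3 conditions required.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix over the metric columns.
#' @export
metric_correlations <- function(report, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(report) < 3L) fs_validation_error("need >= 3 conditions for correlations")
  cols <- metric_columns(report)
  m <- as.matrix(report[, cols, drop = FALSE])
  if (any(!is.finite(m))) fs_validation_error("non-finite metric values")
  suppressWarnings(stats::cor(m, method = method))
}

#' Rank-sum overall rating of conditions
#'
#' For each metric, conditions are ranked best to worst respecting the
#' metric's polarity (CrN: lower is better; number of groups, RP and all
#' sensitivities: higher is better); tied conditions share the mean rank. The
#' rating is the row sum of ranks ("places"); the condition with the minimum
#' rating is the best fingerprinting condition. Output rows are sorted by
#' rating, ties broken by condition name.
#'
#' @param report data.frame with `condition` plus metric columns (>= 2
#'   conditions, >= 1 metric).
#' @return The report with added `rank_*` columns and `rating`, sorted best
#'   first.
#' @export
overall_rating <- function(report) {
  if (nrow(report) < 2L) fs_validation_error("need >= 2 conditions to rate")
  cols <- metric_columns(report)
  if (length(cols) < 1L) fs_validation_error("no metric columns to rate")
  out <- report
  for (cl in cols) {
    oriented <- metric_polarity(cl) * out[[cl]]
    out[[paste0("rank_", cl)]] <- rank(-oriented, ties.method = "average")
  }
  out$rating <- rowSums(out[, paste0("rank_", cols), drop = FALSE])
  out[order(out$rating, out$condition), , drop = FALSE]
}
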
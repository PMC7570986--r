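#' Mean-centred PCA of a spectral matrix
#'
#' Centers the wells x wavelengths matrix by column and projects onto the top
#' `k` right singular vectors. No column scaling is applied: the spectra share
#' one intensity (or quenching-degree) unit and the relative magnitude of
#' wavelength channels is informative. The component sign is fixed so the
#' largest-magnitude loading element of each component is positive, making
#' score plots reproducible across platforms.
#'
#' @param data a [spectra_matrix()]/`quench_matrix`, or a plain numeric
#'   matrix of wells x variables.
#' @param k number of components to keep (default 2, the score-plot plane).
#' @return An object of class `score_cloud` with elements `scores`
#'   (wells x k), `explained` (variance fractions, non-increasing),
#'   `loadings` (k x variables), `meta` (well metadata, or a minimal frame
#'   for plain-matrix input) and `wavelengths` when available.
#' @export
fit_pca <- function(data, k = 2) {
  if (inherits(data, "spectra_matrix")) {
    x <- data$values
    meta <- data$meta
    wl <- data$wavelengths
  } else {
    x <- as.matrix(data)
    meta <- data.frame(
      well_id = rownames(x) %||% paste0("w", seq_len(nrow(x))),
      sample_id = NA_character_, replicate = NA_integer_,
      is_blank = FALSE, condition = NA_character_,
      stringsAsFactors = FALSE
    )
    wl <- NULL
  }
  if (any(!is.finite(x))) fs_validation_error("PCA input contains non-finite values")
  k <- as.integer(k)
  if (k < 1L) fs_validation_error("k must be >= 1")
  if (nrow(x) < k) fs_validation_error("fewer wells than requested components")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  tot <- sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10)
  if (k > rank)
    fs_validation_error(sprintf("k = %d exceeds matrix rank %d", k, rank))
  d <- sv$d[seq_len(k)]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k, k)
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])
  # deterministic sign: largest-|.| loading element of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) {
      loadings[i, ] <- -loadings[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- meta$well_id
  structure(
    list(
      scores = scores,
      explained = if (tot > 0) d^2 / tot else rep(0, k),
      loadings = loadings,
      meta = meta,
      wavelengths = wl,
      total_variance = tot
    ),
    class = "score_cloud"
  )
}

#' Residual dispersion of a fitted score cloud
#'
#' The fraction of total (centred) variance not captured by the kept
#' components, `1 - sum(explained)`. Used as the model-adequacy gate: the
#' two-component score plane is considered adequate when the residual
#' dispersion is at most `threshold` (default 5%).
#'
#' @param cloud a `score_cloud` from [fit_pca()].
#' @param threshold adequacy bound; a warning is issued when exceeded.
#' @param warn emit the adequacy warning? Default `TRUE`.
#' @return The residual dispersion, a fraction in [0, 1].
#' @export
residual_dispersion <- function(cloud, threshold = 0.05, warn = FALSE) {
  stopifnot(inherits(cloud, "score_cloud"))
  res <- max(0, 1 - sum(cloud$explained))
  if (warn && res > threshold)
    warning(sprintf("residual dispersion %.2f%% exceeds %.2f%%: the score plane may be inadequate",
                    100 * res, 100 * threshold))
  res
}

#' @export
print.score_cloud <- function(x, ...) {
  cat(sprintf(
    "score_cloud: %d wells x %d components; explained %s; residual %.3g%%\n",
    nrow(x$scores), ncol(x$scores),
    paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + "),
    100 * residual_dispersion(x)
  ))
  invisible(x)
}

#' Write a score cloud as CSV (well_id, sample_id, condition, PC1, PC2, ...)
#' @param cloud a `score_cloud`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(cloud, path) {
  stopifnot(inherits(cloud, "score_cloud"))
  df <- data.frame(
    well_id = cloud$meta$well_id,
    sample_id = cloud$meta$sample_id,
    replicate = cloud$meta$replicate,
    is_blank = cloud$meta$is_blank,
    condition = cloud$meta$condition,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(cloud$scores))
  write_table_stable(df, path)
}

#' Read a score CSV back into a minimal score cloud
#' @param path CSV written by [write_scores()].
#' @return A `score_cloud` with scores and metadata (no loadings).
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) fs_validation_error(paste0("missing file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pc_cols <- grep("^PC[0-9]+$", names(df), value = TRUE)
  if (length(pc_cols) == 0L) fs_validation_error("no PC columns in scores file")
  scores <- as.matrix(df[, pc_cols, drop = FALSE])
  rownames(scores) <- df$well_id
  structure(
    list(
      scores = scores, explained = rep(NA_real_, length(pc_cols)),
      loadings = NULL,
      meta = data.frame(
        well_id = df$well_id, sample_id = df$sample_id,
        replicate = df$replicate %||% NA_integer_,
        is_blank = as.logical(df$is_blank %||% FALSE),
        condition = df$condition %||% NA_character_,
        stringsAsFactors = FALSE
      ),
      wavelengths = NULL, total_variance = NA_real_
    ),
    class = "score_cloud"
  )
}
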
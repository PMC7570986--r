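#' Configuration for the synthetic spectra generator
#'
#' Defaults mirror the study design the package targets: 36 samples measured
#' in 5 parallel wells plus 6 blank wells, emission sampled at 301 wavelengths
#' over 400-700 nm, two latent spectral components, and 1% multiplicative
#' replicate noise.
#'
#' @param n_samples number of distinct samples (default 36).
#' @param n_replicates parallel wells per sample (default 5).
#' @param n_blanks blank wells (default 6).
#' @param wavelengths emission grid in nm (default `seq(400, 700, length.out
#'   = 301)`).
#' @param n_latent number of latent spectral components (default 2).
#' @param spread between-sample separation: standard amplitude of the latent
#'   band coefficients relative to the blank's peak intensity (default 0.8,
#'   chosen so the between-sample signal dominates 1% replicate noise and two
#'   components suffice for <= 5% residual dispersion, the regime the
#'   generator emulates).
#' @param noise replicate noise fraction, multiplicative (default 0.01).
#' @param seed RNG seed (default 1).
#' @param condition condition label written into the metadata.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 36, n_replicates = 5, n_blanks = 6,
                             wavelengths = seq(400, 700, length.out = 301),
                             n_latent = 2, spread = 0.8, noise = 0.01,
                             seed = 1, condition = "synthetic") {
  cfg <- list(
    n_samples = as.integer(n_samples), n_replicates = as.integer(n_replicates),
    n_blanks = as.integer(n_blanks), wavelengths = as.numeric(wavelengths),
    n_latent = as.integer(n_latent), spread = as.numeric(spread),
    noise = as.numeric(noise), seed = as.integer(seed),
    condition = as.character(condition)
  )
  if (cfg$n_samples < 1L || cfg$n_replicates < 2L || cfg$n_blanks < 1L)
    fs_validation_error("counts must be positive (>= 2 replicates, >= 1 blank)")
  if (cfg$n_latent < 1L) fs_validation_error("n_latent must be >= 1")
  if (cfg$noise < 0) fs_validation_error("noise fraction must be >= 0")
  if (any(diff(cfg$wavelengths) <= 0))
    fs_validation_error("wavelength grid must be strictly increasing")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate synthetic replicate emission spectra
#'
#' Emulates one plate of fluorescence-fingerprint measurements. The blank
#' spectrum is a broad smooth emission band; each sample's mean spectrum adds
#' a sample-specific mixture of `n_latent` Gaussian bands (smooth unimodal
#' shapes standing in for emission bands in the 450-570 nm region), so the
#' noiseless quenching-degree matrix has rank `n_latent`. Replicates multiply
#' the mean spectrum by (1 + noise), i.e. replicate error scales with signal
#' intensity, as fluorescence replicate error does. Output is bit-identical
#' for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return A [spectra_matrix()] of shape
#'   (n_samples * n_replicates + n_blanks) x length(wavelengths).
#' @export
generate_spectra <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    wl <- config$wavelengths
    blank <- 200 * exp(-((wl - 470) / 80)^2) + 20
    peak <- max(blank)
    centers <- seq(450, 570, length.out = config$n_latent + 2)[-c(1, config$n_latent + 2)]
    if (config$n_latent == 1L) centers <- 500
    bands <- vapply(centers, function(cc) exp(-((wl - cc) / 25)^2), numeric(length(wl)))
    # sample-specific band coefficients; bounded so mean spectra stay positive
    coef <- matrix(
      stats::runif(config$n_samples * config$n_latent, -1, 1) *
        config$spread * peak / (2 * max(config$n_latent, 2)),
      nrow = config$n_samples
    )
    n_wells <- config$n_samples * config$n_replicates + config$n_blanks
    vals <- matrix(NA_real_, n_wells, length(wl))
    meta <- data.frame(
      well_id = sprintf("W%03d", seq_len(n_wells)),
      sample_id = NA_character_, replicate = NA_integer_,
      is_blank = FALSE, condition = config$condition,
      stringsAsFactors = FALSE
    )
    row <- 0L
    for (s in seq_len(config$n_samples)) {
      mean_spec <- blank + as.numeric(bands %*% coef[s, ])
      if (any(mean_spec <= 0))
        fs_computation_error("spread too large: negative mean intensity generated")
      for (r in seq_len(config$n_replicates)) {
        row <- row + 1L
        vals[row, ] <- mean_spec * (1 + config$noise * stats::rnorm(length(wl)))
        meta$sample_id[row] <- sprintf("S%02d", s)
        meta$replicate[row] <- r
      }
    }
    for (b in seq_len(config$n_blanks)) {
      row <- row + 1L
      vals[row, ] <- blank * (1 + config$noise * stats::rnorm(length(wl)))
      meta$sample_id[row] <- sprintf("BLK%d", b)
      meta$replicate[row] <- b
      meta$is_blank[row] <- TRUE
    }
    spectra_matrix(vals, wl, meta)
  })
}

#' Generate labelled 2-D score groups
#'
#' Draws `n_groups` isotropic Gaussian point clouds with centers placed
#' evenly on a circle of radius `separation` (a single group sits at the
#' origin). Useful for exercising the separability metrics directly in score
#' space: large `separation / spread` gives fully separated groups, zero
#' separation gives fully merged ones.
#'
#' @param n_groups number of groups.
#' @param n_points points per group (>= 3).
#' @param separation radius of the circle of group centers.
#' @param spread within-group standard deviation.
#' @param seed RNG seed.
#' @return data.frame with columns `sample_id`, `x`, `y`.
#' @export
generate_score_groups <- function(n_groups, n_points = 5, separation = 5,
                                  spread = 1, seed = 1) {
  if (n_points < 3L) fs_validation_error("need >= 3 points per group")
  if (n_groups < 1L) fs_validation_error("need >= 1 group")
  with_seed(seed, {
    if (n_groups == 1L) {
      centers <- matrix(0, 1, 2)
    } else {
      th <- 2 * pi * (seq_len(n_groups) - 1) / n_groups
      centers <- cbind(separation * cos(th), separation * sin(th))
    }
    rows <- lapply(seq_len(n_groups), function(g) {
      data.frame(
        sample_id = sprintf("G%02d", g),
        x = centers[g, 1] + spread * stats::rnorm(n_points),
        y = centers[g, 2] + spread * stats::rnorm(n_points),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Wrap labelled 2-D points as a score cloud
#'
#' Builds a minimal `score_cloud` from a `sample_id`/`x`/`y` table (e.g. the
#' output of [generate_score_groups()]) so the separability metrics can be
#' applied directly.
#'
#' @param df data.frame with columns `sample_id`, `x`, `y`.
#' @param condition condition label.
#' @return A `score_cloud`.
#' @export
as_score_cloud <- function(df, condition = "direct") {
  req <- c("sample_id", "x", "y")
  if (!all(req %in% names(df)))
    fs_validation_error("need columns sample_id, x, y")
  scores <- cbind(PC1 = df$x, PC2 = df$y)
  n <- nrow(df)
  rep_idx <- stats::ave(seq_len(n), df$sample_id, FUN = seq_along)
  structure(
    list(
      scores = scores, explained = c(NA_real_, NA_real_), loadings = NULL,
      meta = data.frame(
        well_id = paste0("w", seq_len(n)), sample_id = as.character(df$sample_id),
        replicate = rep_idx, is_blank = FALSE, condition = condition,
        stringsAsFactors = FALSE
      ),
      wavelengths = NULL, total_variance = NA_real_
    ),
    class = "score_cloud"
  )
}
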
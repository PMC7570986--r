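#' Replicate emission spectra with well metadata
#'
#' A `spectra_matrix` holds one plate's worth of emission spectra: a numeric
#' matrix of fluorescence intensities (rows = wells, columns = a strictly
#' increasing wavelength grid in nm) together with per-well metadata
#' (sample id, replicate index, blank flag, condition label). Blanks are the
#' fluorophore-plus-buffer wells without sample; their average spectrum is the
#' reference for quenching normalization.
#'
#' @param values numeric matrix, wells x wavelengths.
#' @param wavelengths strictly increasing numeric vector (nm), one per column.
#' @param meta data.frame with columns `well_id`, `sample_id`, `replicate`,
#'   `is_blank` (logical), `condition`; one row per well, same order as
#'   `values`.
#' @param normalized logical; `TRUE` marks a quenching-degree matrix
#'   (class `quench_matrix`) rather than raw intensities.
#' @return An object of class `spectra_matrix` (and `quench_matrix` when
#'   `normalized = TRUE`).
#' @export
spectra_matrix <- function(values, wavelengths, meta, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(values))
    fs_validation_error("wavelength grid length does not match number of intensity columns")
  if (length(wavelengths) == 0L)
    fs_validation_error("empty wavelength grid")
  if (any(diff(wavelengths) <= 0))
    fs_validation_error("non-monotone grid: wavelengths must be strictly increasing")
  if (any(!is.finite(values)))
    fs_validation_error("intensities contain NaN/Inf/missing values")
  req <- c("well_id", "sample_id", "replicate", "is_blank", "condition")
  if (!is.data.frame(meta) || !all(req %in% names(meta)))
    fs_validation_error(paste0("metadata must contain columns: ", paste(req, collapse = ", ")))
  if (nrow(meta) != nrow(values))
    fs_validation_error("metadata rows do not match spectra rows")
  meta <- as.data.frame(meta[, req], stringsAsFactors = FALSE)
  meta$is_blank <- as.logical(meta$is_blank)
  if (anyNA(meta$is_blank)) fs_validation_error("is_blank flag must be logical (TRUE/FALSE or 0/1)")
  nb <- meta[!meta$is_blank, , drop = FALSE]
  if (nrow(nb) > 0L) {
    key <- paste(nb$condition, nb$sample_id, nb$replicate, sep = "\r")
    if (anyDuplicated(key))
      fs_validation_error("duplicate (sample, replicate) pairs in metadata")
    reps <- table(paste(nb$condition, nb$sample_id, sep = "\r"))
    if (any(reps < 2L))
      fs_validation_error("every non-blank sample needs >= 2 replicate wells")
  }
  rownames(values) <- meta$well_id
  structure(
    list(values = values, wavelengths = wavelengths, meta = meta),
    class = c(if (normalized) "quench_matrix", "spectra_matrix")
  )
}

#' @export
print.spectra_matrix <- function(x, ...) {
  kind <- if (inherits(x, "quench_matrix")) "quenching-degree" else "intensity"
  cat(sprintf(
    "spectra_matrix (%s): %d wells x %d wavelengths (%g-%g nm), %d blanks, %d condition(s)\n",
    kind, nrow(x$values), ncol(x$values), min(x$wavelengths), max(x$wavelengths),
    sum(x$meta$is_blank), length(unique(x$meta$condition))
  ))
  invisible(x)
}

#' Read spectra and metadata tables
#'
#' The spectra file is a wide CSV: first column well id, remaining column
#' names are numeric wavelengths in nm, one row per well. The metadata CSV has
#' columns `well_id`, `sample_id`, `replicate`, `is_blank`, `condition`.
#' Rows are matched by `well_id`; a mismatch in either direction is an error.
#'
#' @param spectra_path,meta_path paths to the two CSV files.
#' @return A validated [spectra_matrix()].
#' @export
read_spectra <- function(spectra_path, meta_path) {
  for (p in c(spectra_path, meta_path)) {
    if (!file.exists(p)) fs_validation_error(paste0("missing file: ", p))
  }
  spc <- utils::read.csv(spectra_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(spc) < 2L) fs_validation_error("spectra file needs a well-id column plus wavelength columns")
  wl <- suppressWarnings(as.numeric(names(spc)[-1]))
  if (anyNA(wl))
    fs_validation_error("spectra header does not parse as numeric wavelengths")
  if (any(diff(wl) <= 0))
    fs_validation_error("non-monotone grid: spectra header wavelengths must be strictly increasing")
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  ids <- as.character(spc[[1]])
  if (!"well_id" %in% names(meta)) fs_validation_error("metadata lacks a well_id column")
  mids <- as.character(meta$well_id)
  if (anyDuplicated(ids)) fs_validation_error("duplicate well ids in spectra file")
  if (anyDuplicated(mids)) fs_validation_error("duplicate well ids in metadata")
  if (!setequal(ids, mids))
    fs_validation_error("key mismatch: spectra and metadata well ids differ")
  meta <- meta[match(ids, mids), , drop = FALSE]
  vals <- as.matrix(spc[, -1, drop = FALSE])
  spectra_matrix(vals, wl, meta)
}

#' Write a spectra or quenching matrix as wide CSV
#'
#' @param x a [spectra_matrix()].
#' @param spectra_path output path for the wide value table.
#' @param meta_path optional output path for the metadata table.
#' @return `spectra_path`, invisibly.
#' @export
write_spectra <- function(x, spectra_path, meta_path = NULL) {
  stopifnot(inherits(x, "spectra_matrix"))
  df <- data.frame(well_id = x$meta$well_id, stringsAsFactors = FALSE)
  vals <- x$values
  colnames(vals) <- as.character(x$wavelengths)
  df <- cbind(df, as.data.frame(signif(vals, 8)))
  names(df) <- c("well_id", as.character(x$wavelengths))
  utils::write.csv(df, spectra_path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path))
    utils::write.csv(x$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(spectra_path)
}

#' Quenching normalization against blank wells
#'
#' Converts raw intensities I to the formal degree of quenching
#' Q = (I - I0) / I0, where I0 is the per-wavelength average intensity of the
#' blank wells of the same condition. Negative Q means the sample quenches the
#' fluorophore's emission, positive Q means enhancement; blanks map to ~0 on
#' average by construction.
#'
#' @param spectra a raw [spectra_matrix()]; each condition present must have
#'   at least one blank well.
#' @return A `quench_matrix` with the same metadata.
#' @export
quench_normalize <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  if (inherits(spectra, "quench_matrix"))
    fs_validation_error("input is already quench-normalized")
  out <- spectra$values
  for (cond in unique(spectra$meta$condition)) {
    rows <- spectra$meta$condition == cond
    bl <- rows & spectra$meta$is_blank
    if (!any(bl))
      fs_validation_error(paste0("no blank wells for condition '", cond, "'"))
    i0 <- colMeans(spectra$values[bl, , drop = FALSE])
    bad <- which(abs(i0) <= .Machine$double.eps * 100)
    if (length(bad) > 0L)
      fs_validation_error(paste0(
        "zero mean blank intensity at wavelength ",
        spectra$wavelengths[bad[1]], " nm (condition '", cond, "')"
      ))
    out[rows, ] <- sweep(sweep(spectra$values[rows, , drop = FALSE], 2, i0, "-"), 2, i0, "/")
  }
  spectra_matrix(out, spectra$wavelengths, spectra$meta, normalized = TRUE)
}

#' Restrict a spectra matrix to a wavelength window
#'
#' Keeps the columns with `lo_nm <= wavelength <= hi_nm` (closed interval,
#' order preserved). Windowing is how instrument artifacts outside the
#' informative emission range (e.g. a plate-material peak) are excluded.
#'
#' @param data a [spectra_matrix()] or `quench_matrix`.
#' @param lo_nm,hi_nm window bounds in nm, `lo_nm < hi_nm`.
#' @return The same class of object restricted to the window.
#' @export
select_window <- function(data, lo_nm, hi_nm) {
  stopifnot(inherits(data, "spectra_matrix"))
  if (!is.finite(lo_nm) || !is.finite(hi_nm) || lo_nm >= hi_nm)
    fs_validation_error("window bounds must satisfy lo_nm < hi_nm")
  keep <- data$wavelengths >= lo_nm & data$wavelengths <= hi_nm
  if (!any(keep))
    fs_validation_error(sprintf("empty window: no grid wavelengths in [%g, %g] nm", lo_nm, hi_nm))
  spectra_matrix(
    data$values[, keep, drop = FALSE], data$wavelengths[keep], data$meta,
    normalized = inherits(data, "quench_matrix")
  )
}
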
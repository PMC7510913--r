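# Data model and I/O for wavenumber-indexed mid-IR spectra.

#' Construct a wavenumber grid
#'
#' A wavenumber grid is a strictly monotonic numeric vector of positive
#' wavenumbers (cm^-1). The package default covers the quantum-cascade-laser
#' sweep 1200 -> 925 cm^-1 at 1 cm^-1 spacing (276 points), stored in
#' descending (acquisition) order. All operations are orientation-agnostic.
#'
#' @param from,to end points in cm^-1; `from > to` yields a descending grid.
#' @param by positive step size in cm^-1.
#' @return numeric vector of wavenumbers.
#' @export
#' @examples
#' g <- wavenumber_grid()
#' length(g) # 276
wavenumber_grid <- function(from = 1200, to = 925, by = 1) {
  stopifnot(is.numeric(from), is.numeric(to), by > 0, from != to)
  g <- if (from > to) seq(from, to, by = -by) else seq(from, to, by = by)
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  if (!is.numeric(g) || length(g) < 2)
    stop("wavenumber grid must be numeric with length >= 2")
  if (any(!is.finite(g)) || any(g <= 0))
    stop("wavenumbers must be finite and positive")
  d <- diff(g)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotonic")
  invisible(g)
}

#' Signed grid spacing (cm^-1 per point), negative for descending grids
#' @param g wavenumber grid
#' @return scalar mean step
#' @keywords internal
grid_spacing <- function(g) mean(diff(g))

#' Construct a single spectrum
#'
#' @param wavenumber wavenumber grid (cm^-1).
#' @param values numeric vector, one value per grid point.
#' @param kind `"intensity"` (strictly positive) or `"absorbance"` (AU).
#' @param sample_id,individual_id,mode,glucose optional metadata; `glucose`
#'   is the reference concentration in mg/dL.
#' @return object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, values,
                        kind = c("absorbance", "intensity"),
                        sample_id = NA_character_,
                        individual_id = NA_character_,
                        mode = NA_character_,
                        glucose = NA_real_) {
  kind <- match.arg(kind)
  validate_grid(wavenumber)
  if (length(values) != length(wavenumber))
    stop("values and wavenumber grid differ in length")
  if (any(!is.finite(values)))
    stop("spectrum values must be finite")
  if (kind == "intensity" && any(values <= 0))
    stop("intensity spectra must be strictly positive")
  structure(
    list(wavenumber = as.numeric(wavenumber), values = as.numeric(values),
         kind = kind,
         meta = list(sample_id = sample_id, individual_id = individual_id,
                     mode = mode, glucose = glucose)),
    class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %s, %d points, %.0f-%.0f cm-1\n",
              x$kind, length(x$wavenumber),
              max(x$wavenumber), min(x$wavenumber)))
  invisible(x)
}

#' Construct a set of spectra sharing one grid
#'
#' The universal currency of the pipeline: a samples x wavenumbers absorbance
#' matrix with per-sample metadata (individual of origin, reference glucose
#' in mg/dL, instrument mode).
#'
#' @param wavenumber shared wavenumber grid.
#' @param absorbance numeric matrix, one row per sample.
#' @param glucose reference glucose per sample (mg/dL); may contain `NA` for
#'   samples lacking a reference value (rejected by training operations).
#' @param individual individual-of-origin label per sample (character).
#' @param mode `"transmission"` or `"atr"`.
#' @param sample_id unique sample labels; defaults to `s001, s002, ...`.
#' @return object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumber, absorbance, glucose, individual,
                        mode = c("transmission", "atr"),
                        sample_id = NULL) {
  mode <- match.arg(mode)
  validate_grid(wavenumber)
  absorbance <- as.matrix(absorbance)
  n <- nrow(absorbance)
  if (ncol(absorbance) != length(wavenumber))
    stop("absorbance columns must match the wavenumber grid")
  if (length(glucose) != n || length(individual) != n)
    stop("glucose and individual must have one entry per spectrum row")
  if (is.null(sample_id)) sample_id <- sprintf("s%03d", seq_len(n))
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs")
  rownames(absorbance) <- sample_id
  colnames(absorbance) <- format_wavenumber(wavenumber)
  structure(
    list(wavenumber = as.numeric(wavenumber),
         absorbance = absorbance,
         glucose = as.numeric(glucose),
         individual = as.character(individual),
         mode = mode,
         sample_id = as.character(sample_id)),
    class = "spectra_set")
}

format_wavenumber <- function(w) formatC(w, format = "fg", digits = 12)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavenumbers (%s mode)\n",
              nrow(x$absorbance), length(x$wavenumber), x$mode))
  cat(sprintf("  individuals: %s\n",
              paste(unique(x$individual), collapse = ", ")))
  gl <- x$glucose[!is.na(x$glucose)]
  if (length(gl))
    cat(sprintf("  glucose: %.0f-%.0f mg/dL\n", min(gl), max(gl)))
  invisible(x)
}

#' Number of samples in a spectra set
#' @param set a `spectra_set`
#' @export
n_samples <- function(set) nrow(set$absorbance)

#' Subset a spectra set by row index
#' @param set a `spectra_set`
#' @param idx integer or logical index over samples
#' @return a `spectra_set` with the selected samples
#' @export
subset_samples <- function(set, idx) {
  spectra_set(set$wavenumber, set$absorbance[idx, , drop = FALSE],
              set$glucose[idx], set$individual[idx], set$mode,
              sample_id = set$sample_id[idx])
}

#' Absorbance from paired intensity spectra
#'
#' Decadic absorbance A = -log10(I / I0), where I is the intensity measured
#' through the sample and I0 the intensity measured with the reference
#' (deionised water in the instrument this emulates).
#'
#' @param sample intensity `ir_spectrum` (or strictly positive numeric vector).
#' @param reference reference intensity on the same grid.
#' @return absorbance `ir_spectrum` carrying the sample's metadata (numeric
#'   vector if inputs were vectors).
#' @export
#' @examples
#' g <- wavenumber_grid(1000, 990)
#' i0 <- ir_spectrum(g, rep(2, length(g)), "intensity")
#' a <- compute_absorbance(i0, i0)
#' all(a$values == 0)
compute_absorbance <- function(sample, reference) {
  if (is.numeric(sample) && is.numeric(reference)) {
    check_intensity_pair(sample, reference)
    return(-log10(sample / reference))
  }
  stopifnot(inherits(sample, "ir_spectrum"), inherits(reference, "ir_spectrum"))
  if (sample$kind != "intensity" || reference$kind != "intensity")
    stop("compute_absorbance requires intensity spectra")
  if (length(sample$wavenumber) != length(reference$wavenumber) ||
      any(sample$wavenumber != reference$wavenumber))
    stop("sample and reference are on different wavenumber grids")
  check_intensity_pair(sample$values, reference$values)
  ir_spectrum(sample$wavenumber, -log10(sample$values / reference$values),
              kind = "absorbance",
              sample_id = sample$meta$sample_id,
              individual_id = sample$meta$individual_id,
              mode = sample$meta$mode,
              glucose = sample$meta$glucose)
}

check_intensity_pair <- function(i, i0) {
  if (length(i) != length(i0)) stop("intensity vectors differ in length")
  if (any(i <= 0) || any(i0 <= 0))
    stop("intensities must be strictly positive")
  invisible(TRUE)
}

#' Crop a spectrum or spectra set to a wavenumber window
#'
#' Retains exactly the grid points with `lo <= wavenumber <= hi`, preserving
#' the original point order. Idempotent.
#'
#' @param x an `ir_spectrum` or `spectra_set`.
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return object of the same class restricted to the window.
#' @export
crop <- function(x, lo, hi) UseMethod("crop")

crop_index <- function(wavenumber, lo, hi) {
  if (!(lo < hi)) stop("crop requires lo < hi")
  keep <- which(wavenumber >= lo & wavenumber <= hi)
  if (length(keep) < 2)
    stop("crop window overlaps fewer than 2 grid points")
  keep
}

#' @export
crop.ir_spectrum <- function(x, lo, hi) {
  keep <- crop_index(x$wavenumber, lo, hi)
  out <- x
  out$wavenumber <- x$wavenumber[keep]
  out$values <- x$values[keep]
  out
}

#' @export
crop.spectra_set <- function(x, lo, hi) {
  keep <- crop_index(x$wavenumber, lo, hi)
  spectra_set(x$wavenumber[keep], x$absorbance[, keep, drop = FALSE],
              x$glucose, x$individual, x$mode, sample_id = x$sample_id)
}

#' Convert glucose concentration units
#'
#' mg/dL is the internal unit; mmol/L (division by 18.016) is provided for
#' reporting.
#'
#' @param x concentration(s)
#' @return converted concentration(s)
#' @export
mgdl_to_mmol <- function(x) x / 18.016

#' @rdname mgdl_to_mmol
#' @export
mmol_to_mgdl <- function(x) x * 18.016

# ---- CSV I/O -------------------------------------------------------------
# Layout: spectra CSV has first column sample_id then one column per grid
# wavenumber (wavenumber as header); metadata CSV is keyed by sample_id with
# columns individual_id, mode, glucose_mgdl. Comma-separated, '.' decimal.

#' Write a spectra set as paired CSV files
#'
#' @param set a `spectra_set`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; writes `<prefix>_spectra.csv` and
#'   `<prefix>_metadata.csv`.
#' @return invisibly, the two file paths.
#' @export
write_spectra_set <- function(set, dir, prefix = "cohort") {
  stopifnot(inherits(set, "spectra_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spath <- file.path(dir, paste0(prefix, "_spectra.csv"))
  mpath <- file.path(dir, paste0(prefix, "_metadata.csv"))
  sm <- data.frame(sample_id = set$sample_id,
                   signif(set$absorbance, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(sm) <- c("sample_id", format_wavenumber(set$wavenumber))
  utils::write.csv(sm, spath, row.names = FALSE, quote = FALSE)
  md <- data.frame(sample_id = set$sample_id,
                   individual_id = set$individual,
                   mode = set$mode,
                   glucose_mgdl = set$glucose,
                   stringsAsFactors = FALSE)
  utils::write.csv(md, mpath, row.names = FALSE, quote = FALSE)
  invisible(c(spectra = spath, metadata = mpath))
}

#' Read a spectra set from paired CSV files
#'
#' Inverse of [write_spectra_set()] up to float formatting (12 significant
#' digits). Ragged rows, missing metadata keys, non-monotonic wavenumber
#' headers and duplicate sample IDs raise parse errors. Samples without a
#' reference glucose value load with `NA` glucose and are rejected later by
#' training operations.
#'
#' @param spectra_path path to the spectra CSV.
#' @param metadata_path path to the metadata CSV.
#' @return a `spectra_set`.
#' @export
read_spectra_set <- function(spectra_path, metadata_path) {
  sm <- utils::read.csv(spectra_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(sm) < 3 || names(sm)[1] != "sample_id")
    stop("spectra CSV must have a sample_id column followed by wavenumbers")
  w <- suppressWarnings(as.numeric(names(sm)[-1]))
  if (any(is.na(w))) stop("non-numeric wavenumber column header")
  validate_grid(w)
  X <- as.matrix(sm[, -1, drop = FALSE])
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("spectra CSV contains non-numeric or missing absorbance values")
  ids <- as.character(sm$sample_id)
  if (anyDuplicated(ids)) stop("duplicate sample IDs in spectra CSV")
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "mode", "glucose_mgdl")
  if (!all(need %in% names(md)))
    stop("metadata CSV missing required columns: ",
         paste(setdiff(need, names(md)), collapse = ", "))
  mi <- match(ids, md$sample_id)
  if (any(is.na(mi)))
    stop("metadata missing for sample(s): ",
         paste(ids[is.na(mi)], collapse = ", "))
  md <- md[mi, ]
  mode <- unique(md$mode)
  if (length(mode) != 1) stop("metadata mixes instrument modes")
  spectra_set(w, X, as.numeric(md$glucose_mgdl),
              md$individual_id, mode, sample_id = ids)
}
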
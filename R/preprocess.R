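# Spectral preprocessing operators and their combination grid.
#
# Row-wise operator order within a pipeline is fixed as
#   filter -> derivative -> baseline -> normalise -> mean-centre,
# the common chemometrics convention; every report records the spec.

#' Savitzky-Golay least-squares weights
#'
#' Weights for estimating the `deriv`-th derivative at offset 0 from samples
#' at integer `offsets`, via the local least-squares polynomial of degree
#' `order`. Solved from the normal equations directly, not a table lookup.
#'
#' @param offsets integer sample offsets relative to the evaluation point.
#' @param order polynomial degree, `order < length(offsets)`.
#' @param deriv derivative order (0 = smoothing).
#' @return numeric weight vector, same length as `offsets`.
#' @export
sg_weights <- function(offsets, order, deriv = 0) {
  stopifnot(order < length(offsets), deriv <= order)
  V <- outer(offsets, 0:order, `^`)          # Vandermonde
  # coefficient of x^deriv of the LS polynomial, times deriv!
  G <- solve(crossprod(V), t(V))
  factorial(deriv) * G[deriv + 1, ]
}

#' Savitzky-Golay filtering and differentiation
#'
#' Replaces each point by the value (or `deriv`-th derivative) at the centre
#' of the local least-squares polynomial fit of degree `order` over a
#' `width`-point window. Edges use shrink-window asymmetric fits of the same
#' degree, so polynomials up to degree `order` are reproduced exactly
#' everywhere.
#'
#' @param values numeric vector (one spectrum).
#' @param width odd window width >= 3.
#' @param order polynomial degree, `order < width`.
#' @param deriv derivative order, `deriv <= order`.
#' @param spacing abscissa step between points; derivatives are divided by
#'   `spacing^deriv`. A negative step (descending wavenumber grid) flips the
#'   sign of odd derivatives accordingly.
#' @return filtered vector of the same length.
#' @export
#' @examples
#' sg_weights(-2:2, 2)          # (-3, 12, 17, 12, -3) / 35
#' savitzky_golay(sin(1:50 / 5), width = 9, order = 1)
savitzky_golay <- function(values, width, order, deriv = 0, spacing = 1) {
  op <- sg_operator(length(values), width, order, deriv)
  as.numeric(op %*% values) / spacing^deriv
}

# Dense n x n linear operator for SG filtering; built per call (cheap: one
# small solve per distinct window shape).
sg_operator <- function(n, width, order, deriv = 0) {
  if (width %% 2 != 1 || width < 3) stop("width must be odd and >= 3")
  if (order >= width) stop("order must be < width")
  if (deriv > order) stop("deriv must be <= order")
  if (width > n) stop("window width exceeds signal length")
  half <- (width - 1L) %/% 2L
  op <- matrix(0, n, n)
  w_int <- sg_weights(-half:half, order, deriv)
  for (i in seq_len(n)) {
    if (i <= half) {                      # left edge: window anchored at 1
      op[i, 1:width] <- sg_weights(seq_len(width) - i, order, deriv)
    } else if (i > n - half) {            # right edge
      cols <- (n - width + 1L):n
      op[i, cols] <- sg_weights(cols - i, order, deriv)
    } else {
      op[i, (i - half):(i + half)] <- w_int
    }
  }
  op
}

# 4-term Blackman-Harris window, x in [0, 1], peak 1 at x = 0.5.
blackman_harris <- function(x) {
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  (a[1] - a[2] * cos(2 * pi * x) + a[3] * cos(4 * pi * x) -
     a[4] * cos(6 * pi * x))
}

#' Fourier low-pass filter with a Blackman-Harris taper
#'
#' Low-pass filters a spectrum in Fourier space: the signal is symmetrically
#' (evenly) extended to suppress wrap-around edge artefacts, transformed,
#' and frequency bins beyond `cutoff` (counted one-sided on the raw,
#' unextended signal) are attenuated by the falling half of a 4-term
#' Blackman-Harris window whose transition spans `cutoff * (multiplier - 1)`
#' bins; bins at or beyond `cutoff * multiplier` are fully stopped. The
#' defaults (cutoff 28, multiplier 1.3) remove high-frequency fringe
#' interference from ATR spectra while preserving analyte bands.
#'
#' @param values numeric vector (one spectrum).
#' @param cutoff last fully passed one-sided frequency bin; `1 <= cutoff <
#'   length(values)/2`.
#' @param multiplier transition-width factor, `> 1` for a tapered edge.
#' @return filtered real vector of the same length.
#' @export
fourier_filter <- function(values, cutoff = 28, multiplier = 1.3) {
  n <- length(values)
  if (cutoff < 1) stop("cutoff must be >= 1")
  if (cutoff >= n / 2) stop("cutoff must be below the Nyquist index")
  if (multiplier <= 0) stop("multiplier must be positive")
  y <- c(values, rev(values))              # even extension, length 2n
  Y <- stats::fft(y)
  k <- seq_len(2 * n) - 1L
  f <- pmin(k, 2 * n - k) / 2              # raw-signal frequency index
  gain <- fourier_gain(f, cutoff, multiplier)
  Re(stats::fft(Y * gain, inverse = TRUE))[seq_len(n)] / (2 * n)
}

fourier_gain <- function(f, cutoff, multiplier) {
  hi <- cutoff * multiplier
  gain <- numeric(length(f))
  gain[f <= cutoff] <- 1
  trans <- f > cutoff & f < hi
  if (any(trans)) {
    u <- (f[trans] - cutoff) / (hi - cutoff)   # 0 -> 1 across the taper
    gain[trans] <- blackman_harris(0.5 + u / 2) / blackman_harris(0.5)
  }
  gain
}

#' Spectral derivative
#'
#' First or second derivative computed by Savitzky-Golay differentiation
#' (width 9, polynomial order `max(2, order)`), the standard spectroscopy
#' practice; scaled by the grid spacing.
#'
#' @param values numeric vector.
#' @param order 1 or 2.
#' @param spacing abscissa step (cm^-1 per point; may be negative for
#'   descending grids).
#' @param width SG window width used for differentiation.
#' @return derivative vector of the same length.
#' @export
spectral_derivative <- function(values, order, spacing = 1, width = 9) {
  if (!order %in% 1:2) stop("derivative order must be 1 or 2")
  savitzky_golay(values, width = width, order = max(2, order),
                 deriv = order, spacing = spacing)
}

#' Linear endpoint baseline correction
#'
#' Subtracts the straight line through the first and last points; both
#' endpoints map exactly to zero. Removes any additive linear background.
#'
#' @param values numeric vector, length >= 2.
#' @return corrected vector.
#' @export
baseline_linear <- function(values) {
  n <- length(values)
  if (n < 2) stop("baseline correction needs at least 2 points")
  line <- values[1] + (values[n] - values[1]) * (seq_len(n) - 1) / (n - 1)
  values - line
}

#' Unit-vector (Euclidean) normalisation
#'
#' @param values nonzero numeric vector.
#' @return vector with Euclidean norm 1, direction preserved.
#' @export
normalise_unit <- function(values) {
  nrm <- sqrt(sum(values^2))
  if (nrm == 0) stop("cannot normalise a zero vector")
  values / nrm
}

#' Declarative preprocessing specification
#'
#' @param filter `"none"`, `"sg"` (Savitzky-Golay) or `"fourier"`.
#' @param sg_width,sg_order SG parameters (reference default 9, 1).
#' @param fourier_cutoff,fourier_multiplier Fourier filter parameters
#'   (defaults 28, 1.3).
#' @param derivative 0 (none), 1 or 2.
#' @param baseline logical: linear endpoint background correction.
#' @param normalise logical: unit-vector normalisation.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(filter = c("none", "sg", "fourier"),
                            sg_width = 9, sg_order = 1,
                            fourier_cutoff = 28, fourier_multiplier = 1.3,
                            derivative = 0, baseline = FALSE,
                            normalise = FALSE) {
  filter <- match.arg(filter)
  if (filter == "sg") {
    if (sg_width %% 2 != 1 || sg_width < 3) stop("sg_width must be odd >= 3")
    if (sg_order >= sg_width) stop("sg_order must be < sg_width")
  }
  if (filter == "fourier") {
    if (fourier_cutoff < 1) stop("fourier_cutoff must be >= 1")
    if (fourier_multiplier <= 0) stop("fourier_multiplier must be > 0")
  }
  if (!derivative %in% 0:2) stop("derivative must be 0, 1 or 2")
  structure(
    list(filter = filter, sg_width = sg_width, sg_order = sg_order,
         fourier_cutoff = fourier_cutoff,
         fourier_multiplier = fourier_multiplier,
         derivative = as.integer(derivative),
         baseline = isTRUE(baseline), normalise = isTRUE(normalise)),
    class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess_spec>", spec_label(x), "\n")
  invisible(x)
}

#' One-line label for a preprocessing spec
#' @param spec a `preprocess_spec`
#' @export
spec_label <- function(spec) {
  f <- switch(spec$filter,
              none = "no-filter",
              sg = sprintf("SG(%d,%d)", spec$sg_width, spec$sg_order),
              fourier = sprintf("Fourier(%g,%g)", spec$fourier_cutoff,
                                spec$fourier_multiplier))
  paste0(f,
         if (spec$derivative > 0) sprintf(" + d%d", spec$derivative) else "",
         if (spec$baseline) " + baseline" else "",
         if (spec$normalise) " + unitnorm" else "",
         " + centre")
}

# number of active optional steps; used for grid-search tie-breaking
n_active_steps <- function(spec) {
  (spec$filter != "none") + (spec$derivative > 0) +
    spec$baseline + spec$normalise
}

#' Apply the row-wise part of a preprocessing spec to a spectra matrix
#'
#' Filter, derivative, baseline and normalisation act on each spectrum
#' independently of every other sample, so they can be applied before any
#' train/validation split; only mean-centering (see [fit_preprocessor()])
#' learns from the training set.
#'
#' @param X samples x wavenumbers matrix.
#' @param spec a `preprocess_spec`.
#' @param spacing grid spacing used to scale derivatives.
#' @return transformed matrix of the same shape.
#' @export
apply_row_ops <- function(X, spec, spacing = 1) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (spec$filter == "sg") {
    op <- sg_operator(n, spec$sg_width, spec$sg_order, 0)
    X <- X %*% t(op)
  } else if (spec$filter == "fourier") {
    X <- t(apply(X, 1, fourier_filter, cutoff = spec$fourier_cutoff,
                 multiplier = spec$fourier_multiplier))
  }
  if (spec$derivative > 0) {
    d <- spec$derivative
    op <- sg_operator(n, 9, max(2, d), d)
    X <- (X %*% t(op)) / spacing^d
  }
  if (spec$baseline) X <- t(apply(X, 1, baseline_linear))
  if (spec$normalise) X <- t(apply(X, 1, normalise_unit))
  X
}

#' Fit a preprocessor on training data
#'
#' Applies the row-wise operators and learns the centering statistics
#' (column means of the processed training spectra, mean of the training
#' glucose values). Centering statistics come from the training set only, so
#' applying the fitted preprocessor to validation data cannot leak
#' information from it.
#'
#' @param spec a `preprocess_spec`.
#' @param train a `spectra_set` with complete reference glucose.
#' @return list with the fitted preprocessor (`$preprocessor`, class
#'   `fitted_preprocessor`), the processed centered training matrix (`$X`)
#'   and centered response (`$y`).
#' @export
fit_preprocessor <- function(spec, train) {
  stopifnot(inherits(spec, "preprocess_spec"), inherits(train, "spectra_set"))
  if (any(is.na(train$glucose)))
    stop("training set contains samples without reference glucose")
  sp <- grid_spacing(train$wavenumber)
  Xp <- apply_row_ops(train$absorbance, spec, spacing = sp)
  cm <- colMeans(Xp)
  ym <- mean(train$glucose)
  fp <- structure(
    list(spec = spec, column_means = cm, y_mean = ym, spacing = sp,
         wavenumber = train$wavenumber, fitted = TRUE),
    class = "fitted_preprocessor")
  list(preprocessor = fp,
       X = sweep(Xp, 2, cm),
       y = train$glucose - ym)
}

#' Apply a fitted preprocessor to another spectra set
#'
#' @param fp a `fitted_preprocessor` from [fit_preprocessor()].
#' @param set a `spectra_set` on the same grid.
#' @return processed, train-mean-centered matrix.
#' @export
apply_preprocessor <- function(fp, set) {
  if (!inherits(fp, "fitted_preprocessor") || !isTRUE(fp$fitted))
    stop("preprocessor has not been fitted")
  if (length(set$wavenumber) != length(fp$wavenumber) ||
      any(set$wavenumber != fp$wavenumber))
    stop("spectra set grid does not match the preprocessor's grid")
  Xp <- apply_row_ops(set$absorbance, fp$spec, spacing = fp$spacing)
  sweep(Xp, 2, fp$column_means)
}

#' Enumerate all preprocessing pipelines of a method grid
#'
#' Cartesian product of the supplied options in deterministic, filter-major
#' order (filter varies slowest), mirroring an exhaustive search over "all
#' possible combinations" of the method set.
#'
#' @param filters list of filter settings; each element is either the string
#'   `"none"` or a named list like `list(filter = "sg", sg_width = 9,
#'   sg_order = 1)` / `list(filter = "fourier", fourier_cutoff = 28,
#'   fourier_multiplier = 1.3)`.
#' @param derivatives integer vector from `{0, 1, 2}`.
#' @param baselines logical vector.
#' @param normalisations logical vector.
#' @return list of `preprocess_spec` objects (no duplicates).
#' @export
#' @examples
#' length(enumerate_pipelines())  # 3 * 3 * 2 * 2 = 36
enumerate_pipelines <- function(filters = default_filters(),
                                derivatives = c(0, 1, 2),
                                baselines = c(FALSE, TRUE),
                                normalisations = c(FALSE, TRUE)) {
  stopifnot(length(filters) > 0, length(derivatives) > 0,
            length(baselines) > 0, length(normalisations) > 0)
  out <- list()
  for (f in filters)
    for (d in derivatives)
      for (b in baselines)
        for (nm in normalisations) {
          args <- if (is.character(f)) list(filter = f) else f
          args$derivative <- d
          args$baseline <- b
          args$normalise <- nm
          out[[length(out) + 1L]] <- do.call(preprocess_spec, args)
        }
  out
}

#' Default filter options for the model-selection grid
#' @return list of filter settings for [enumerate_pipelines()]
#' @export
default_filters <- function() {
  list("none",
       list(filter = "sg", sg_width = 9, sg_order = 1),
       list(filter = "fourier", fourier_cutoff = 28,
            fourier_multiplier = 1.3))
}
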
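# Forward simulation of transmission- and ATR-mode mid-IR spectra of
# glucose in biofluid-like matrices, organised as multi-individual cohorts
# with optional concentration spiking.
#
# The generator is a Beer-Lambert superposition of analyte absorption bands
# on the 1200-925 cm^-1 grid. ATR spectra use a wavelength-scaled effective
# pathlength per reflection times the reflection count. Band positions /
# strengths, matrix levels, noise and fringe defaults are frozen generator
# configuration, chosen to emulate the qualitative behaviour of peritoneal
# fluid and blood plasma, not measured values.

#' Construct an absorption band
#'
#' @param center band centre (cm^-1), within the generator grid range.
#' @param width full width at half maximum (cm^-1), > 0.
#' @param peak_absorptivity peak decadic absorptivity in AU per (mg/dL) per
#'   mm pathlength, >= 0.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return object of class `absorption_band`.
#' @export
absorption_band <- function(center, width, peak_absorptivity,
                            shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (width <= 0) stop("band width must be positive")
  if (peak_absorptivity < 0) stop("peak absorptivity must be >= 0")
  structure(list(center = center, width = width,
                 peak_absorptivity = peak_absorptivity, shape = shape),
            class = "absorption_band")
}

band_profile <- function(band, grid) {
  d <- grid - band$center
  if (band$shape == "gaussian") {
    band$peak_absorptivity * exp(-4 * log(2) * d^2 / band$width^2)
  } else {
    hw <- band$width / 2
    band$peak_absorptivity * hw^2 / (d^2 + hw^2)
  }
}

#' Default component library
#'
#' Absorption-band parameters for the three simulated analytes. Glucose
#' carries its principal fingerprint band at 1035 cm^-1 plus secondary bands
#' at 1080 and 1110 cm^-1; the albumin-like protein contributes one broad
#' band near 1080 cm^-1 and a very broad sloping background; lactate a minor
#' band near 1125 cm^-1. All parameters are tunable generator defaults.
#'
#' @return object of class `component_library`: named list of band lists.
#' @export
default_component_library <- function() {
  component_library(list(
    glucose = list(absorption_band(1035, 18, 1.5e-4),
                   absorption_band(1080, 22, 0.9e-4),
                   absorption_band(1110, 25, 0.6e-4)),
    protein = list(absorption_band(1080, 90, 5.0e-6),
                   absorption_band(1170, 260, 3.0e-6)),
    lactate = list(absorption_band(1125, 20, 1.2e-4))))
}

#' Construct a component library
#'
#' @param components named list; each element a non-empty list of
#'   [absorption_band()] objects. A `glucose` entry must include a band
#'   centred at 1035 cm^-1, the key glucose fingerprint feature.
#' @return object of class `component_library`.
#' @export
component_library <- function(components) {
  if (is.null(names(components)) || any(names(components) == ""))
    stop("components must be a named list")
  for (nm in names(components)) {
    bands <- components[[nm]]
    if (length(bands) == 0) stop("analyte '", nm, "' has no bands")
    if (!all(vapply(bands, inherits, logical(1), "absorption_band")))
      stop("analyte '", nm, "' contains non-band entries")
  }
  if ("glucose" %in% names(components)) {
    centers <- vapply(components$glucose, `[[`, numeric(1), "center")
    if (!any(centers == 1035))
      stop("glucose entry must include a band centred at 1035 cm^-1")
  }
  structure(list(components = components), class = "component_library")
}

#' Absorptivity profile of one analyte on a grid
#'
#' Sum of the analyte's band shapes evaluated at every grid point.
#'
#' @param library a `component_library`.
#' @param analyte analyte name present in the library.
#' @param grid wavenumber grid.
#' @return numeric vector, AU per (mg/dL) per mm.
#' @export
component_absorptivity <- function(library, analyte, grid) {
  stopifnot(inherits(library, "component_library"))
  if (!analyte %in% names(library$components))
    stop("unknown analyte '", analyte, "'; library has: ",
         paste(names(library$components), collapse = ", "))
  validate_grid(grid)
  prof <- numeric(length(grid))
  for (b in library$components[[analyte]]) prof <- prof + band_profile(b, grid)
  prof
}

#' Measurement-configuration parameters
#'
#' @param mode `"transmission"` or `"atr"`.
#' @param grid wavenumber grid (defaults to 1200-925 cm^-1 at 1 cm^-1).
#' @param pathlength_um transmission pathlength in micrometres (the gap
#'   between the delivery and collection fibres; default 200).
#' @param n_reflections ATR reflection count on the sensing surface
#'   (default 11); absorbance scales linearly with it.
#' @param penetration_scale_um effective pathlength per reflection at the
#'   reference wavenumber (micrometres). The per-reflection effective
#'   pathlength scales inversely with wavenumber (longer wavelength, deeper
#'   evanescent-field penetration): `d_e(v) = penetration_scale * v_ref / v`.
#' @param ref_wavenumber reference wavenumber for `penetration_scale_um`.
#' @param fringe_amplitude relative amplitude of the sinusoidal interference
#'   fringe on the sample beam (0 disables it).
#' @param fringe_period fringe period in cm^-1; either a scalar (fixed
#'   period) or a length-2 range from which each sample's period is drawn
#'   uniformly, emulating drifting interference structure.
#' @param noise_sd per-point multiplicative Gaussian intensity noise
#'   (relative sd).
#' @param baseline_amplitude scale (AU) of the smooth per-individual
#'   baseline offset.
#' @return object of class `instrument_model`.
#' @export
instrument_model <- function(mode = c("transmission", "atr"),
                             grid = wavenumber_grid(),
                             pathlength_um = 200,
                             n_reflections = 11,
                             penetration_scale_um = 1.5,
                             ref_wavenumber = 1035,
                             fringe_amplitude = 0,
                             fringe_period = 8,
                             noise_sd = 0,
                             baseline_amplitude = 0) {
  mode <- match.arg(mode)
  validate_grid(grid)
  if (pathlength_um <= 0) stop("pathlength must be positive")
  if (n_reflections < 1) stop("n_reflections must be >= 1")
  if (fringe_amplitude < 0) stop("fringe_amplitude must be >= 0")
  if (!length(fringe_period) %in% 1:2 || any(fringe_period <= 0))
    stop("fringe_period must be a positive scalar or range")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(mode = mode, grid = grid, pathlength_um = pathlength_um,
                 n_reflections = n_reflections,
                 penetration_scale_um = penetration_scale_um,
                 ref_wavenumber = ref_wavenumber,
                 fringe_amplitude = fringe_amplitude,
                 fringe_period = fringe_period, noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude),
            class = "instrument_model")
}

# Frozen noise calibration of the default instruments. The noise levels are
# a calibration of the simulator (chosen so the reference analysis
# configurations reach their documented accuracy regime on the default
# seeds), not a measurement of any physical detector.
irglucose_defaults <- function() {
  list(noise_sd_transmission = 5e-4,
       noise_sd_atr = 6e-5,
       baseline_transmission = 5e-5,
       baseline_atr = 5e-6,
       fringe_amplitude_atr = 0.01,
       fringe_period_atr = c(6, 7.5))
}

#' Default transmission instrument (200 um path)
#' @param grid wavenumber grid.
#' @param ... overrides passed to [instrument_model()].
#' @export
transmission_instrument <- function(grid = wavenumber_grid(), ...) {
  d <- irglucose_defaults()
  args <- list(mode = "transmission", grid = grid,
               noise_sd = d$noise_sd_transmission,
               baseline_amplitude = d$baseline_transmission)
  args[names(list(...))] <- list(...)
  do.call(instrument_model, args)
}

#' Default ATR instrument (11 reflections, fringe interference)
#' @param grid wavenumber grid.
#' @param ... overrides passed to [instrument_model()].
#' @export
atr_instrument <- function(grid = wavenumber_grid(), ...) {
  d <- irglucose_defaults()
  args <- list(mode = "atr", grid = grid,
               noise_sd = d$noise_sd_atr,
               fringe_amplitude = d$fringe_amplitude_atr,
               fringe_period = d$fringe_period_atr,
               baseline_amplitude = d$baseline_atr)
  args[names(list(...))] <- list(...)
  do.call(instrument_model, args)
}

#' Sample composition
#'
#' @param glucose glucose concentration (mg/dL), >= 0.
#' @param matrix_concs named numeric vector of matrix-analyte concentrations
#'   (mg/dL).
#' @param individual_id label of the individual of origin.
#' @param dilution_factor cumulative matrix dilution from spiking, in
#'   (0.95, 1] (spiking adds < 5% volume).
#' @return object of class `sample_composition`.
#' @export
sample_composition <- function(glucose, matrix_concs = numeric(0),
                               individual_id = "ind01",
                               dilution_factor = 1) {
  if (glucose < 0 || any(matrix_concs < 0))
    stop("concentrations must be >= 0")
  if (dilution_factor <= 0.95 || dilution_factor > 1)
    stop("dilution_factor must lie in (0.95, 1]")
  structure(list(glucose = glucose, matrix_concs = matrix_concs,
                 individual_id = individual_id,
                 dilution_factor = dilution_factor),
            class = "sample_composition")
}

#' Spike a sample with concentrated glucose stock
#'
#' Adds the stock volume `v = V (c_target - c_0) / (c_stock - c_target)`
#' needed to raise the glucose concentration exactly to `target_glucose`,
#' dilutes every matrix analyte by `V / (V + v)`, and updates the dilution
#' factor. Spikes requiring 5% or more added volume are rejected.
#'
#' @param composition a `sample_composition`.
#' @param target_glucose target concentration (mg/dL); must satisfy
#'   `stock_conc > target_glucose >=` current glucose.
#' @param stock_conc stock concentration (mg/dL), default 10000.
#' @param volume sample volume V (mL), default 1.
#' @return the spiked `sample_composition`.
#' @export
#' @examples
#' s <- sample_composition(140, c(protein = 2500))
#' spike(s, 426)$glucose  # 426
spike <- function(composition, target_glucose, stock_conc = 10000,
                  volume = 1.0) {
  stopifnot(inherits(composition, "sample_composition"))
  c0 <- composition$glucose
  if (target_glucose < c0)
    stop("spiking cannot lower the glucose concentration")
  if (stock_conc <= target_glucose)
    stop("stock concentration must exceed the target")
  if (target_glucose == c0) return(composition)
  v <- volume * (target_glucose - c0) / (stock_conc - target_glucose)
  if (v / volume >= 0.05)
    stop(sprintf("spike would add %.1f%% extra volume (limit < 5%%)",
                 100 * v / volume))
  f <- volume / (volume + v)
  out <- composition
  out$glucose <- target_glucose
  out$matrix_concs <- composition$matrix_concs * f
  out$dilution_factor <- composition$dilution_factor * f
  if (out$dilution_factor <= 0.95)
    stop("cumulative spiking dilution exceeds the 5% volume limit")
  out
}

# Smooth per-individual baseline offset, drawn deterministically from the
# individual's label: three Chebyshev-like terms with coefficients from a
# hash-seeded stream, scaled by the instrument's baseline amplitude.
individual_baseline <- function(individual_id, grid, amplitude) {
  if (amplitude == 0) return(numeric(length(grid)))
  cf <- with_seed(derive_seed(20200618, individual_id),
                  stats::runif(3, -1, 1))
  x <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  amplitude * (cf[1] + cf[2] * x + cf[3] * (2 * x^2 - 1))
}

#' Noiseless absorbance of a sample composition
#'
#' Beer-Lambert superposition: in transmission,
#' `A(v) = sum_c eps_c(v) conc_c L + baseline`; in ATR the pathlength is
#' replaced by `N * d_e(v)` with the wavelength-scaled per-reflection
#' effective pathlength `d_e(v) = penetration_scale * v_ref / v`, so the
#' analyte signal is linear in the reflection count.
#'
#' @param composition a `sample_composition`.
#' @param library a `component_library`; matrix analytes absent from the
#'   library raise a lookup error.
#' @param instrument an `instrument_model`.
#' @return noiseless absorbance `ir_spectrum`.
#' @export
true_absorbance <- function(composition, library, instrument) {
  stopifnot(inherits(composition, "sample_composition"),
            inherits(instrument, "instrument_model"))
  grid <- instrument$grid
  L <- if (instrument$mode == "transmission") {
    rep(instrument$pathlength_um / 1000, length(grid))      # mm
  } else {
    instrument$n_reflections * (instrument$penetration_scale_um / 1000) *
      (instrument$ref_wavenumber / grid)
  }
  concs <- c(glucose = composition$glucose, composition$matrix_concs)
  A <- numeric(length(grid))
  for (analyte in names(concs))
    A <- A + component_absorptivity(library, analyte, grid) * concs[[analyte]] * L
  A <- A + individual_baseline(composition$individual_id, grid,
                               instrument$baseline_amplitude)
  ir_spectrum(grid, A, kind = "absorbance",
              individual_id = composition$individual_id,
              mode = instrument$mode, glucose = composition$glucose)
}

# broad positive source envelope of the swept laser
source_envelope <- function(grid) {
  mid <- (max(grid) + min(grid)) / 2
  0.6 + 0.4 * exp(-((grid - mid) / 180)^2)
}

#' Simulate paired sample / reference intensity spectra
#'
#' The reference beam sees the smooth source envelope with per-point
#' multiplicative Gaussian noise; the sample beam additionally carries the
#' Beer-Lambert attenuation `10^-A` and, when `fringe_amplitude > 0`, a
#' sinusoidal interference fringe (random phase per call) that does not
#' cancel against the reference — emulating reflections in the optical
#' path. Identical seeds give bit-identical output; the standard-normal
#' noise draws do not depend on `noise_sd`, so raising the noise level
#' rescales the same realisation. A noise draw large enough to produce a
#' nonpositive intensity raises an error rather than being clipped (clipping
#' would bias the absorbance).
#'
#' @param noiseless absorbance `ir_spectrum` (from [true_absorbance()]).
#' @param instrument an `instrument_model`.
#' @param seed integer seed.
#' @return list with intensity `ir_spectrum`s `$sample` and `$reference`.
#' @export
measured_intensities <- function(noiseless, instrument, seed) {
  stopifnot(inherits(noiseless, "ir_spectrum"),
            noiseless$kind == "absorbance")
  grid <- instrument$grid
  if (length(noiseless$wavenumber) != length(grid) ||
      any(noiseless$wavenumber != grid))
    stop("spectrum grid does not match the instrument grid")
  if (any(!is.finite(noiseless$values))) stop("absorbance must be finite")
  K <- length(grid)
  draws <- with_seed(seed, {
    period <- if (length(instrument$fringe_period) == 2) {
      stats::runif(1, instrument$fringe_period[1],
                   instrument$fringe_period[2])
    } else instrument$fringe_period
    phi <- stats::runif(1, 0, 2 * pi)
    z0 <- stats::rnorm(K)
    z1 <- stats::rnorm(K)
    list(period = period, phi = phi, z0 = z0, z1 = z1)
  })
  S <- source_envelope(grid)
  fringe <- 1 + instrument$fringe_amplitude *
    sin(2 * pi * grid / draws$period + draws$phi)
  i0 <- S * (1 + instrument$noise_sd * draws$z0)
  i1 <- S * 10^(-noiseless$values) * fringe *
    (1 + instrument$noise_sd * draws$z1)
  if (any(i0 <= 0) || any(i1 <= 0))
    stop("simulated intensity became nonpositive; lower noise_sd")
  m <- noiseless$meta
  list(sample = ir_spectrum(grid, i1, "intensity",
                            sample_id = m$sample_id,
                            individual_id = m$individual_id,
                            mode = instrument$mode, glucose = m$glucose),
       reference = ir_spectrum(grid, i0, "intensity",
                               mode = instrument$mode))
}

#' Cohort specification
#'
#' @param n_individuals number of individuals.
#' @param samples_per_individual samples per individual (ignored when
#'   `n_samples` is given).
#' @param base_glucose_range `(lo, hi)` of unspiked glucose draws (mg/dL).
#' @param spike_fraction proportion of samples spiked, in [0, 1].
#' @param spike_target_range `(lo, hi)` of uniform spike targets (mg/dL).
#' @param matrix_level `"peritoneal"` or `"plasma"`; plasma raises the
#'   protein concentration to 2.2x the peritoneal default (plasma carries
#'   over twice the total protein of peritoneal fluid).
#' @param seed generator seed.
#' @param n_samples optional total sample count, distributed as evenly as
#'   possible across individuals (extras to the first individuals).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals, samples_per_individual,
                        base_glucose_range, spike_fraction,
                        spike_target_range,
                        matrix_level = c("peritoneal", "plasma"),
                        seed = 1, n_samples = NULL) {
  matrix_level <- match.arg(matrix_level)
  stopifnot(n_individuals >= 1, samples_per_individual >= 1,
            length(base_glucose_range) == 2,
            base_glucose_range[1] < base_glucose_range[2],
            length(spike_target_range) == 2,
            spike_target_range[1] < spike_target_range[2],
            spike_fraction >= 0, spike_fraction <= 1)
  if (is.null(n_samples)) n_samples <- n_individuals * samples_per_individual
  if (n_samples < n_individuals)
    stop("need at least one sample per individual")
  structure(list(n_individuals = as.integer(n_individuals),
                 samples_per_individual = as.integer(samples_per_individual),
                 base_glucose_range = base_glucose_range,
                 spike_fraction = spike_fraction,
                 spike_target_range = spike_target_range,
                 matrix_level = matrix_level, seed = as.integer(seed),
                 n_samples = as.integer(n_samples)),
            class = "cohort_spec")
}

#' Reference peritoneal cohort: 5 individuals x 16 samples
#'
#' 80 samples (a 48-sample training / 31-sample validation grouped split
#' plus one discarded sample), unspiked glucose 33-140 mg/dL, half the
#' samples spiked to 150-426 mg/dL.
#'
#' @param seed generator seed.
#' @param ... overrides passed to [cohort_spec()].
#' @export
peritoneal_cohort_spec <- function(seed = 1, ...) {
  args <- list(n_individuals = 5, samples_per_individual = 16,
               base_glucose_range = c(33, 140), spike_fraction = 0.5,
               spike_target_range = c(150, 426),
               matrix_level = "peritoneal", seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

#' Reference plasma cohort: 21 samples from 2 individuals
#'
#' Higher-protein matrix (2.2x peritoneal), unspiked glucose 65-105 mg/dL,
#' half the samples spiked to 120-346 mg/dL.
#'
#' @param seed generator seed.
#' @param ... overrides passed to [cohort_spec()].
#' @export
plasma_cohort_spec <- function(seed = 1, ...) {
  args <- list(n_individuals = 2, samples_per_individual = 11,
               base_glucose_range = c(65, 105), spike_fraction = 0.5,
               spike_target_range = c(120, 346),
               matrix_level = "plasma", seed = seed, n_samples = 21)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# per-level matrix composition defaults (mg/dL) and their between-individual
# log-sd; plasma protein is 2.2x the peritoneal level
matrix_defaults <- function(level) {
  base <- list(means = c(protein = 2500, lactate = 18),
               log_sd = c(protein = 0.05, lactate = 0.15))
  if (level == "plasma") base$means["protein"] <- 2.2 * 2500
  base
}

#' Generate a synthetic cohort of measured spectra
#'
#' Draws per-individual matrix compositions once per individual, per-sample
#' base glucose uniformly from the base range, spikes the configured
#' fraction of samples to uniform targets (skipping targets below the
#' sample's base level, so reference values always stay within
#' `[base lo, spike hi]`), simulates paired intensities per sample and
#' converts them to absorbance. A pure function of (spec, library,
#' instrument): repeated calls agree bit for bit.
#'
#' @param spec a `cohort_spec`.
#' @param library a `component_library`.
#' @param instrument an `instrument_model`.
#' @return a `spectra_set` with exact reference glucose as ground truth.
#' @export
generate_cohort <- function(spec, library = default_component_library(),
                            instrument = transmission_instrument()) {
  stopifnot(inherits(spec, "cohort_spec"))
  md <- matrix_defaults(spec$matrix_level)
  counts <- distribute_samples(spec$n_samples, spec$n_individuals)
  with_seed(spec$seed, {
    ind_ids <- sprintf("ind%02d", seq_len(spec$n_individuals))
    ind_concs <- lapply(seq_len(spec$n_individuals), function(i)
      md$means * exp(stats::rnorm(length(md$means), 0, md$log_sd)))
    K <- length(instrument$grid)
    n <- spec$n_samples
    X <- matrix(NA_real_, n, K)
    glucose <- numeric(n)
    individual <- character(n)
    row <- 0L
    for (i in seq_len(spec$n_individuals)) {
      for (j in seq_len(counts[i])) {
        row <- row + 1L
        base <- stats::runif(1, spec$base_glucose_range[1],
                             spec$base_glucose_range[2])
        comp <- sample_composition(base, ind_concs[[i]], ind_ids[i])
        if (stats::runif(1) < spec$spike_fraction) {
          target <- stats::runif(1, spec$spike_target_range[1],
                                 spec$spike_target_range[2])
          if (target > comp$glucose) comp <- spike(comp, target)
        }
        A <- true_absorbance(comp, library, instrument)
        mseed <- sample.int(2147483646L, 1)
        ii <- measured_intensities(A, instrument, mseed)
        X[row, ] <- compute_absorbance(ii$sample, ii$reference)$values
        glucose[row] <- comp$glucose
        individual[row] <- ind_ids[i]
      }
    }
    spectra_set(instrument$grid, X, glucose, individual,
                mode = instrument$mode,
                sample_id = sprintf("%s_s%02d", individual,
                                    sequence(counts)))
  })
}

distribute_samples <- function(n, k) {
  counts <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}
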
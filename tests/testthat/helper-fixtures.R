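# Fixtures built in code: small random spectra sets and noiseless
# instruments used across the test files.

# random spectra_set for generic data-model tests (not physically meaningful)
make_random_set <- function(n = 12, K = 40, n_ind = 3, seed = 42) {
  with_seed(seed, {
    grid <- seq(1200, by = -1, length.out = K)
    X <- matrix(rnorm(n * K, mean = 0.5, sd = 0.05), n, K)
    spectra_set(grid, X,
                glucose = runif(n, 50, 400),
                individual = sprintf("ind%02d", rep_len(seq_len(n_ind), n)),
                mode = "transmission")
  })
}

# instrument with all stochastic terms switched off: measured spectra equal
# the Beer-Lambert absorbance exactly
noiseless_transmission <- function(...)
  transmission_instrument(noise_sd = 0, baseline_amplitude = 0, ...)

noiseless_atr <- function(...)
  atr_instrument(noise_sd = 0, fringe_amplitude = 0, baseline_amplitude = 0,
                 ...)

# small noiseless 3-varying-component cohort (glucose + protein + lactate)
make_noiseless_cohort <- function(seed = 7, n_individuals = 5,
                                  samples_per_individual = 8,
                                  instrument = noiseless_transmission()) {
  spec <- peritoneal_cohort_spec(
    seed, n_individuals = n_individuals,
    samples_per_individual = samples_per_individual)
  generate_cohort(spec, instrument = instrument)
}

# the reference 48/31 grouped split: drop one validation sample from the
# 80-sample cohort so the validation side has 31 samples
trim_to_31_validation <- function(set,
                                  val_groups = c("ind02", "ind04")) {
  val_idx <- which(set$individual %in% val_groups)
  drop <- utils::tail(val_idx, length(val_idx) - 31L)
  if (length(drop)) set <- subset_samples(set,
                                          setdiff(seq_len(n_samples(set)),
                                                  drop))
  set
}
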
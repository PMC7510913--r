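test_that("absorptivity profiles superpose band shapes linearly", {
  g <- wavenumber_grid()
  lib1 <- component_library(list(
    glucose = list(absorption_band(1035, 20, 2e-4))))
  prof <- component_absorptivity(lib1, "glucose", g)
  expect_equal(prof[g == 1035], 2e-4)      # value at centre = peak
  expect_equal(prof[g == 1035 + 10], 1e-4) # FWHM: half max at +w/2
  lib2 <- component_library(list(
    glucose = list(absorption_band(1035, 20, 2e-4),
                   absorption_band(1035, 20, 2e-4))))
  expect_equal(component_absorptivity(lib2, "glucose", g), 2 * prof)
  zero <- component_library(list(
    glucose = list(absorption_band(1035, 20, 0))))
  expect_equal(component_absorptivity(zero, "glucose", g), rep(0, length(g)))
  expect_error(component_absorptivity(lib1, "caffeine", g),
               "unknown analyte")
  expect_error(component_library(list(glucose = list())), "no bands")
  expect_error(component_library(list(
    glucose = list(absorption_band(1080, 20, 1e-4)))), "1035")
})

test_that("noiseless absorbance is Beer-Lambert linear in all factors", {
  lib <- default_component_library()
  inst <- noiseless_transmission()
  zero <- true_absorbance(sample_composition(0), lib, inst)
  expect_equal(zero$values, rep(0, length(inst$grid)))

  comp <- sample_composition(200, c(protein = 2500, lactate = 18))
  a200 <- true_absorbance(comp, lib, inst)
  a400 <- true_absorbance(comp, lib,
                          noiseless_transmission(pathlength_um = 400))
  expect_equal(a400$values, 2 * a200$values)   # pathlength linearity

  # concentration superposition
  g_only <- true_absorbance(sample_composition(200), lib, inst)
  m_only <- true_absorbance(sample_composition(0, c(protein = 2500,
                                                    lactate = 18)),
                            lib, inst)
  expect_equal(a200$values, g_only$values + m_only$values, tolerance = 1e-12)

  # ATR: analyte term linear in reflection count; effective pathlength
  # grows toward lower wavenumbers
  a11 <- true_absorbance(comp, lib, noiseless_atr())
  a22 <- true_absorbance(comp, lib, noiseless_atr(n_reflections = 22))
  expect_equal(a22$values, 2 * a11$values)
  # wavelength-scaled penetration: for a spectrally flat absorptivity,
  # A(v) * v is constant across the grid
  flat <- component_library(list(
    glucose = list(absorption_band(1035, 1e6, 1e-4))))
  af <- true_absorbance(sample_composition(100), flat, noiseless_atr())
  expect_equal(af$values * af$wavenumber / mean(af$values * af$wavenumber),
               rep(1, length(af$wavenumber)), tolerance = 1e-6)
})

test_that("intensity simulation inverts exactly when noise-free", {
  lib <- default_component_library()
  inst <- noiseless_transmission()
  a <- true_absorbance(sample_composition(150, c(protein = 2500)), lib, inst)
  ii <- measured_intensities(a, inst, seed = 5)
  back <- compute_absorbance(ii$sample, ii$reference)
  expect_lt(max(abs(back$values - a$values)) / max(abs(a$values)), 1e-10)

  # determinism: same seed -> bit-identical intensities
  noisy <- transmission_instrument()
  i1 <- measured_intensities(a, noisy, seed = 17)
  i2 <- measured_intensities(a, noisy, seed = 17)
  expect_identical(i1$sample$values, i2$sample$values)
  expect_identical(i1$reference$values, i2$reference$values)
  i3 <- measured_intensities(a, noisy, seed = 18)
  expect_false(identical(i1$sample$values, i3$sample$values))

  # catastrophic noise errors out instead of clipping
  expect_error(measured_intensities(a, transmission_instrument(noise_sd = 5),
                                    seed = 1), "nonpositive")
})

test_that("the fringe term produces the predicted small-signal sinusoid", {
  grid <- wavenumber_grid()
  inst <- instrument_model("atr", grid, fringe_amplitude = 0.01,
                           fringe_period = 8, noise_sd = 0)
  a0 <- ir_spectrum(grid, rep(0, length(grid)), "absorbance")
  ii <- measured_intensities(a0, inst, seed = 9)
  # absorbance of the fringed beam against the fringe-free envelope
  meas <- compute_absorbance(ii$sample$values,
                             irglucose:::source_envelope(grid))
  # closed form: A = -log10(1 + a sin(2 pi v / P + phi))
  phi <- with_seed(9, stats::runif(1, 0, 2 * pi))
  expected <- -log10(1 + 0.01 * sin(2 * pi * grid / 8 + phi))
  expect_equal(meas, expected, tolerance = 1e-12)
  # small-signal relative amplitude ~ a / ln(10)
  expect_equal(max(abs(meas)), 0.01 / log(10), tolerance = 0.02)
})

test_that("spiking follows the dilution algebra and the <5% volume rule", {
  s <- sample_composition(140, c(protein = 2500), "ind01")
  sp <- spike(s, 426, stock_conc = 10000, volume = 1)
  v <- (426 - 140) / (10000 - 426)
  expect_equal(v, 0.02988, tolerance = 1e-3)         # 2.99% added volume
  # dilution oracle: (c0 V + c_stock v) / (V + v) = c_target
  expect_equal((140 * 1 + 10000 * v) / (1 + v), 426)
  expect_equal(sp$glucose, 426)
  expect_equal(sp$matrix_concs[["protein"]], 2500 / (1 + v))
  expect_equal(sp$dilution_factor, 1 / (1 + v))
  expect_gt(sp$dilution_factor, 0.95)

  expect_identical(spike(s, 140), s)                 # identity case
  expect_error(spike(s, 600, stock_conc = 1000), "extra volume")
  expect_error(spike(s, 100), "cannot lower")
  expect_error(spike(s, 500, stock_conc = 400), "exceed the target")
})

test_that("cohort generation is reproducible and respects ranges", {
  spec <- peritoneal_cohort_spec(3)
  set1 <- generate_cohort(spec)
  set2 <- generate_cohort(peritoneal_cohort_spec(3))
  expect_identical(set1$absorbance, set2$absorbance)
  expect_identical(set1$glucose, set2$glucose)

  expect_equal(n_samples(set1), 80)
  expect_length(unique(set1$individual), 5)
  expect_true(all(set1$glucose >= 33 & set1$glucose <= 426))

  nospike <- generate_cohort(peritoneal_cohort_spec(3, spike_fraction = 0))
  expect_true(all(nospike$glucose >= 33 & nospike$glucose <= 140))

  plasma <- generate_cohort(plasma_cohort_spec(3))
  expect_equal(n_samples(plasma), 21)
  expect_length(unique(plasma$individual), 2)
  expect_true(all(plasma$glucose >= 65 & plasma$glucose <= 346))
})

test_that("plasma cohorts show higher total absorbance than peritoneal", {
  # plasma protein level is 2.2x the peritoneal default
  inst <- noiseless_transmission()
  per <- generate_cohort(peritoneal_cohort_spec(5, spike_fraction = 0),
                         instrument = inst)
  pla <- generate_cohort(plasma_cohort_spec(5, spike_fraction = 0),
                         instrument = inst)
  expect_gt(mean(pla$absorbance), mean(per$absorbance))
})

test_that("instrument and composition invariants are enforced", {
  expect_error(instrument_model("transmission", pathlength_um = 0),
               "pathlength")
  expect_error(instrument_model("atr", n_reflections = 0), "n_reflections")
  expect_error(instrument_model("atr", fringe_amplitude = -1), "fringe")
  expect_error(sample_composition(-5), "concentrations")
  expect_error(sample_composition(100, dilution_factor = 0.9),
               "dilution_factor")
})
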
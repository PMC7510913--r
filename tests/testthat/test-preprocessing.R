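# independent Savitzky-Golay oracle: fit the local polynomial with lm() and
# read the smoothed value / derivative at offset zero
sg_weights_lm_oracle <- function(offsets, order, deriv = 0) {
  vapply(seq_along(offsets), function(j) {
    y <- numeric(length(offsets)); y[j] <- 1
    fit <- stats::lm(y ~ stats::poly(offsets, order, raw = TRUE))
    factorial(deriv) * stats::coef(fit)[[deriv + 1]]
  }, numeric(1))
}

test_that("SG weights equal the least-squares oracle", {
  expect_equal(sg_weights(-2:2, 2), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  for (case in list(c(9, 1, 0), c(9, 2, 1), c(7, 3, 2), c(5, 4, 0))) {
    half <- (case[1] - 1) / 2
    expect_equal(sg_weights(-half:half, case[2], case[3]),
                 sg_weights_lm_oracle(-half:half, case[2], case[3]),
                 tolerance = 1e-8)
  }
  # asymmetric (edge) windows obey the same oracle
  expect_equal(sg_weights(0:6, 2, 0), sg_weights_lm_oracle(0:6, 2, 0),
               tolerance = 1e-8)
})

test_that("SG filtering reproduces polynomials exactly, edges included", {
  x <- seq_len(40)
  expect_equal(savitzky_golay(rep(3.7, 40), 9, 1), rep(3.7, 40))
  # property: random polynomials of degree <= order are fixed points
  set.seed(11)
  for (i in 1:10) {
    ord <- sample(2:4, 1)
    cf <- rnorm(ord + 1)
    y <- as.numeric(outer(x / 10, 0:ord, `^`) %*% cf)
    expect_equal(savitzky_golay(y, 9, ord), y, tolerance = 1e-8)
  }
  # smoothing commutes with adding a constant
  set.seed(12)
  y <- rnorm(50)
  expect_equal(savitzky_golay(y + 5, 9, 2), savitzky_golay(y, 9, 2) + 5)
  expect_error(savitzky_golay(y, 8, 2), "odd")
  expect_error(savitzky_golay(y[1:5], 9, 2), "exceeds")
  expect_error(savitzky_golay(y, 9, 9), "order")
})

test_that("SG derivatives are exact for polynomials and scale with spacing", {
  x <- seq(0, 10, by = 0.5)
  ramp <- 2.5 * x + 1
  expect_equal(spectral_derivative(ramp, 1, spacing = 0.5),
               rep(2.5, length(x)), tolerance = 1e-10)
  expect_equal(spectral_derivative(rep(4, 30), 1), rep(0, 30))
  expect_equal(spectral_derivative(rep(4, 30), 2), rep(0, 30))
  quad <- 3 * x^2 - x + 2
  expect_equal(spectral_derivative(quad, 2, spacing = 0.5),
               rep(6, length(x)), tolerance = 1e-8)
  # descending abscissa flips the sign of the first derivative
  expect_equal(spectral_derivative(ramp, 1, spacing = -0.5),
               rep(-2.5, length(x)), tolerance = 1e-10)
})

test_that("Fourier filter preserves DC and the passband, stops the stopband", {
  expect_equal(fourier_filter(rep(2.5, 276)), rep(2.5, 276),
               tolerance = 1e-10)
  n <- 276
  # half-sample-aligned cosines are exactly even under symmetric extension
  i <- seq_len(n) - 1
  slow <- cos(2 * pi * 3 * (i + 0.5) / n)
  fast <- cos(2 * pi * 60 * (i + 0.5) / n)
  out <- fourier_filter(slow + fast, cutoff = 28, multiplier = 1.3)
  expect_lt(max(abs(out - slow)) / max(abs(fast)), 1e-2)     # slow kept
  # residual fast component attenuated by >= 40 dB (direct DFT oracle)
  resid <- out - slow
  amp_in <- abs(sum(fast * fast)) / n * 2
  amp_out <- abs(sum(resid * fast)) / n * 2
  expect_lt(amp_out / amp_in, 1e-2)
  # applying twice ~ applying once: the squared taper differs from the
  # taper only inside the transition band
  once <- fourier_filter(slow + fast)
  twice <- fourier_filter(once)
  expect_lt(max(abs(twice - once)), 0.05 * max(abs(once)))
  # commutes with adding a constant
  set.seed(3)
  y <- rnorm(100)
  expect_equal(fourier_filter(y + 2, 10), fourier_filter(y, 10) + 2,
               tolerance = 1e-10)
  expect_error(fourier_filter(y, cutoff = 50), "Nyquist")
  expect_error(fourier_filter(y, cutoff = 0), ">= 1")
})

test_that("linear baseline correction removes straight lines additively", {
  x <- seq_len(30)
  line <- 0.3 * x - 2
  expect_equal(baseline_linear(line), rep(0, 30))
  set.seed(4)
  y <- rnorm(30)
  expect_equal(baseline_linear(y + line), baseline_linear(y))
  out <- baseline_linear(y)
  expect_equal(out[c(1, 30)], c(0, 0))
})

test_that("unit-vector normalisation preserves direction only", {
  expect_equal(normalise_unit(c(3, 4)), c(0.6, 0.8))
  u <- normalise_unit(c(1, 2, 2))
  expect_equal(normalise_unit(u), u)
  expect_equal(normalise_unit(17 * c(1, 2, 2)), u)
  expect_error(normalise_unit(c(0, 0)), "zero vector")
})

test_that("pipeline enumeration is the exact Cartesian product", {
  specs <- enumerate_pipelines()
  expect_length(specs, 36)
  labels <- vapply(specs, spec_label, character(1))
  expect_false(anyDuplicated(labels) > 0)
  # filter-major order: first 12 specs share the first filter
  expect_true(all(grepl("^no-filter", labels[1:12])))
  one <- enumerate_pipelines(filters = list("none"), derivatives = 0,
                             baselines = FALSE, normalisations = FALSE)
  expect_length(one, 1)
})

test_that("centering statistics come from the training set only", {
  train <- make_random_set(n = 10, seed = 1)
  val <- make_random_set(n = 6, seed = 2)
  spec <- preprocess_spec("sg", sg_width = 9, sg_order = 1, baseline = TRUE)
  fit <- fit_preprocessor(spec, train)

  # all-none spec: processed train is mean-centered raw data
  fit0 <- fit_preprocessor(preprocess_spec("none"), train)
  expect_equal(colMeans(fit0$X), rep(0, ncol(fit0$X)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fit0$X, sweep(train$absorbance, 2, colMeans(train$absorbance)),
               ignore_attr = TRUE)

  # leakage guard: mutating validation data leaves fitted means untouched,
  # and validation centered by train means differs from self-centering
  val2 <- val
  val2$absorbance <- val2$absorbance + 100
  expect_identical(fit$preprocessor$column_means,
                   fit_preprocessor(spec, train)$preprocessor$column_means)
  Xv_train_means <- apply_preprocessor(fit$preprocessor, val)
  own <- fit_preprocessor(spec, val)$X
  expect_gt(max(abs(Xv_train_means - own)), 1e-8)

  # unfitted / mismatched use is an error
  broken <- fit$preprocessor
  broken$fitted <- FALSE
  expect_error(apply_preprocessor(broken, val), "not been fitted")
  short <- crop(val, 1190, 1200)
  expect_error(apply_preprocessor(fit$preprocessor, short), "grid")

  # full pipeline determinism
  expect_identical(apply_preprocessor(fit$preprocessor, val),
                   apply_preprocessor(fit$preprocessor, val))
})
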
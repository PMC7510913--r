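test_that("MAPE matches hand evaluation and is scale invariant", {
  expect_equal(mape(c(100, 200), c(100, 200)), 0)
  expect_equal(mape(c(100, 200), c(110, 180)), 10)
  set.seed(41)
  y <- runif(20, 50, 400); p <- y + rnorm(20, 0, 20)
  # scalar-loop oracle
  acc <- 0
  for (t in seq_along(y)) acc <- acc + abs(y[t] - p[t]) / y[t]
  expect_equal(mape(y, p), 100 * acc / 20)
  expect_equal(mape(3.2 * y, 3.2 * p), mape(y, p))
  expect_error(mape(c(100, 0), c(90, 10)), "strictly positive")
  expect_error(mape(1:3, 1:2), "length")
})

test_that("RMSE, SEP and R2 match their scalar-loop oracles", {
  set.seed(42)
  y <- runif(15, 50, 400); p <- y + rnorm(15, 5, 12)
  e <- y - p
  expect_equal(rmse(y, p), sqrt(sum(e^2) / 15))
  expect_equal(sep(y, p), sqrt(sum((e - mean(e))^2) / 14))
  expect_equal(r2(y, p), 1 - sum(e^2) / sum((y - mean(y))^2))
  # perfect predictions
  expect_equal(c(rmse(y, y), sep(y, y), r2(y, y)), c(0, 0, 1))
  # pure constant bias separates SEP from RMSE
  expect_equal(sep(y, y + 7), 0)
  expect_equal(rmse(y, y + 7), 7)
  # SEP / RMSE consistency identity
  expect_equal(sep(y, p)^2 * 14 / 15, rmse(y, p)^2 - mean(e)^2)
  expect_error(r2(rep(5, 4), 1:4), "constant")
})

test_that("random-subset CV partitions every sample exactly once per pass", {
  set <- make_random_set(n = 23, seed = 43)
  folds <- irglucose:::make_folds(23, 10, seed = 99)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), 1:23)
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 1)   # near-equal, remainder first

  spec <- preprocess_spec("none")
  a <- random_subset_cv(set, spec, 3, splits = 5, iterations = 3, seed = 7)
  b <- random_subset_cv(set, spec, 3, splits = 5, iterations = 3, seed = 7)
  c <- random_subset_cv(set, spec, 3, splits = 5, iterations = 3, seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$cv_mape, c$cv_mape)))
  expect_equal(dim(a$per_iteration), c(3, 1))
})

test_that("noiseless rank-sufficient data passes through CV near-exactly", {
  set <- make_noiseless_cohort(seed = 44, n_individuals = 4,
                               samples_per_individual = 6)
  spec <- preprocess_spec("none")
  cv <- random_subset_cv(set, spec, 3, splits = 6, iterations = 2, seed = 1)
  expect_lt(cv$cv_mape, 0.1)
})

test_that("LOOCV performs one fit and one prediction per sample", {
  set <- make_noiseless_cohort(seed = 45, n_individuals = 2,
                               samples_per_individual = 8)
  set <- subset_samples(set, 1:7)
  r <- loocv(set, preprocess_spec("none"), 3)
  expect_equal(nrow(r$predictions), 7)
  expect_setequal(r$predictions$sample_id, set$sample_id)
  expect_lt(r$mape, 0.1)
  expect_identical(loocv(set, preprocess_spec("none"), 3)$predictions,
                   r$predictions)     # deterministic
  expect_error(loocv(subset_samples(set, 1:2), preprocess_spec("none"), 1),
               "at least 3")
})

test_that("grouped holdout never mixes individuals and never leaks", {
  set <- make_noiseless_cohort(seed = 46)
  tg <- c("ind01", "ind03", "ind05"); vg <- c("ind02", "ind04")
  expect_error(grouped_holdout(set, preprocess_spec("none"), 3,
                               tg, c("ind01", "ind04")), "overlap")
  expect_error(grouped_holdout(set, preprocess_spec("none"), 3,
                               tg, character(0)), "non-empty")
  expect_error(grouped_holdout(set, preprocess_spec("none"), 3,
                               tg, "ind09"), "unknown individual")

  r <- grouped_holdout(set, preprocess_spec("none"), 3, tg, vg)
  expect_lt(r$mape, 0.1)     # noiseless exact recovery across individuals
  expect_setequal(unique(r$predictions$individual_id), vg)

  # mutation test: perturbing validation rows leaves the fitted model alone
  set2 <- set
  vi <- which(set2$individual %in% vg)
  set2$absorbance[vi, ] <- set2$absorbance[vi, ] + 5
  m1 <- attr(grouped_holdout(set, preprocess_spec("none"), 3, tg, vg),
             "model")
  m2 <- attr(grouped_holdout(set2, preprocess_spec("none"), 3, tg, vg),
             "model")
  expect_identical(m1$pls$regression_vector, m2$pls$regression_vector)
  expect_identical(m1$preprocessor$column_means,
                   m2$preprocessor$column_means)

  # moving an individual across the split changes the fitted model
  m3 <- attr(grouped_holdout(set, preprocess_spec("none"), 3,
                             c("ind01", "ind03"),
                             c("ind02", "ind04", "ind05")), "model")
  expect_gt(max(abs(m3$pls$regression_vector -
                      m1$pls$regression_vector)), 0)
})

test_that("grid search covers the grid and breaks ties by parsimony", {
  set <- make_noiseless_cohort(seed = 47, n_individuals = 3,
                               samples_per_individual = 8)
  specs <- enumerate_pipelines(filters = list("none",
                                              list(filter = "sg",
                                                   sg_width = 9,
                                                   sg_order = 1)),
                               derivatives = c(0, 1),
                               baselines = FALSE, normalisations = FALSE)
  gs <- grid_search(set, specs, lv_range = 3:5, splits = 4,
                    iterations = 1, seed = 5)
  expect_equal(nrow(gs$table), length(specs) * 3)
  expect_setequal(unique(gs$table$n_lv), 3:5)
  # recovery of truth: a candidate matching the noiseless generative model
  # (or an MAPE-equivalent one) wins with near-zero CV error
  expect_lt(gs$best$cv_mape, 0.1)

  # two identical candidates tie exactly: fewer LVs wins, then enumeration
  twin <- list(preprocess_spec("none"), preprocess_spec("none"))
  gs2 <- grid_search(set, twin, lv_range = 3:4, splits = 4,
                     iterations = 1, seed = 5)
  expect_equal(gs2$best$n_lv, 3)
  tab <- gs2$table
  expect_equal(tab$cv_mape[tab$spec_idx == 1], tab$cv_mape[tab$spec_idx == 2])
})

test_that("evaluation reports serialise with dual units", {
  set <- make_noiseless_cohort(seed = 48, n_individuals = 2,
                               samples_per_individual = 6)
  r <- loocv(set, preprocess_spec("none"), 3)
  dir <- withr::local_tempdir()
  write_report(r, dir, "rep")
  j <- jsonlite::read_json(file.path(dir, "rep.json"))
  expect_equal(j$mape_pct, r$mape, tolerance = 1e-12)
  expect_equal(j$rmse_mmol * 18.016, j$rmse_mgdl, tolerance = 1e-9)
  preds <- utils::read.csv(file.path(dir, "rep_predictions.csv"))
  expect_equal(nrow(preds), n_samples(set))
})
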
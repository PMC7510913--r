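# Validation schemes, preprocessing x latent-variable grid search, and the
# evaluation metric suite (MAPE, RMSE, SEP, R^2).

#' Mean absolute percentage error
#'
#' `100 * mean(|y - yhat| / y)`, the scale-independent accuracy measure
#' (called MARD in the continuous-glucose-monitoring field).
#'
#' @param y_true reference concentrations (mg/dL), all strictly positive.
#' @param y_pred predicted concentrations.
#' @return MAPE in percent.
#' @export
#' @examples
#' mape(c(100, 200), c(110, 180))  # 10
mape <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(y_true <= 0))
    stop("MAPE undefined: reference values must be strictly positive")
  100 * mean(abs(y_true - y_pred) / y_true)
}

#' Root-mean-square error
#' @param y_true,y_pred reference and predicted values (equal length).
#' @return RMSE in the units of `y`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sqrt(mean((y_true - y_pred)^2))
}

#' Standard error of prediction
#'
#' Bias-corrected standard deviation of the residuals,
#' `sqrt(sum((e - mean(e))^2) / (n - 1))`: a pure constant bias gives
#' SEP = 0 while RMSE equals the bias magnitude.
#'
#' @param y_true,y_pred reference and predicted values, `n >= 2`.
#' @return SEP in the units of `y`.
#' @export
sep <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("SEP needs at least 2 observations")
  stats::sd(y_true - y_pred)
}

#' Coefficient of determination
#'
#' `1 - sum(e^2) / sum((y - mean(y))^2)`.
#'
#' @param y_true,y_pred reference and predicted values.
#' @return R^2 (<= 1; may be negative for models worse than the mean).
#' @export
r2 <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  ss <- sum((y_true - mean(y_true))^2)
  if (ss == 0) stop("R^2 undefined for constant reference values")
  1 - sum((y_true - y_pred)^2) / ss
}

#' Per-sample evaluation report
#'
#' @param set the evaluated `spectra_set` (or subset).
#' @param idx row indices of the evaluated samples.
#' @param y_pred predictions for those samples.
#' @param model_desc character description of the model (preprocessing + LVs).
#' @param scheme character description of the validation scheme.
#' @return object of class `evaluation_report` holding the per-sample
#'   prediction table and MAPE / RMSE / SEP / R^2.
#' @export
evaluation_report <- function(set, idx, y_pred, model_desc, scheme) {
  y <- set$glucose[idx]
  structure(
    list(predictions = data.frame(sample_id = set$sample_id[idx],
                                  individual_id = set$individual[idx],
                                  y_true = y, y_pred = y_pred,
                                  stringsAsFactors = FALSE),
         mape = mape(y, y_pred), rmse = rmse(y, y_pred),
         sep = sep(y, y_pred), r2 = r2(y, y_pred),
         model_desc = model_desc, scheme = scheme),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s [%s]\n", x$model_desc, x$scheme))
  cat(sprintf("  n = %d  MAPE = %.2f%%  RMSE = %.2f mg/dL  SEP = %.2f mg/dL  R2 = %.4f\n",
              nrow(x$predictions), x$mape, x$rmse, x$sep, x$r2))
  invisible(x)
}

# ---- fold engine ---------------------------------------------------------

# Held-out predictions for each latent-variable count in lv_range, given a
# list of held-out index vectors that partition the sample set. Row-wise
# preprocessing is sample-independent so it is applied once; centering and
# the PLS fit are redone inside every fold from the fold's training rows
# only. One NIPALS fit at max(lv_range) serves all smaller counts (the
# components are nested).
fold_predictions <- function(set, spec, lv_range, folds) {
  if (any(is.na(set$glucose)))
    stop("cross-validation requires reference glucose for every sample")
  n <- n_samples(set)
  Xp <- apply_row_ops(set$absorbance, spec,
                      spacing = grid_spacing(set$wavenumber))
  y <- set$glucose
  kmax <- max(lv_range)
  pred <- matrix(NA_real_, n, length(lv_range),
                 dimnames = list(set$sample_id, paste0("lv", lv_range)))
  for (ho in folds) {
    if (length(ho) < 1) stop("empty cross-validation fold")
    tr <- setdiff(seq_len(n), ho)
    cm <- colMeans(Xp[tr, , drop = FALSE])
    ym <- mean(y[tr])
    Xtr <- sweep(Xp[tr, , drop = FALSE], 2, cm)
    klim <- min(kmax, length(tr) - 1L, ncol(Xp))
    fit <- suppressWarnings(pls_fit(Xtr, y[tr] - ym, klim))
    Xho <- sweep(Xp[ho, , drop = FALSE], 2, cm)
    for (j in seq_along(lv_range)) {
      k <- min(lv_range[j], fit$n_lv)
      pred[ho, j] <- as.numeric(Xho %*% coef(fit, k)) + ym
    }
  }
  pred
}

# near-equal random partition; remainder spread over the first folds
make_folds <- function(n, splits, seed) {
  if (splits < 2 || splits > n) stop("splits must be in [2, n]")
  sizes <- rep(n %/% splits, splits)
  extra <- n %% splits
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- with_seed(seed, sample.int(n))
  split(ord, rep(seq_len(splits), sizes))
}

#' Random-subset cross-validation
#'
#' Repeated k-fold CV: per iteration the samples are shuffled with an
#' iteration-derived seed and partitioned into `splits` near-equal folds;
#' each fold is held out once (preprocessing centering and PLS refit on the
#' remainder every time), held-out predictions are pooled into one MAPE, and
#' the mean over iterations is returned. The defaults (10 splits, 20
#' iterations) match the model-selection design this package emulates.
#'
#' @param set a `spectra_set`.
#' @param spec a `preprocess_spec`.
#' @param n_lv latent-variable count (scalar or vector).
#' @param splits folds per iteration.
#' @param iterations number of repeated partitions.
#' @param seed master seed; iteration i shuffles with a seed derived from it.
#' @return list with `cv_mape` (mean over iterations; vector over `n_lv`)
#'   and `per_iteration` (iterations x length(n_lv) matrix).
#' @export
random_subset_cv <- function(set, spec, n_lv, splits = 10, iterations = 20,
                             seed = 1) {
  stopifnot(iterations >= 1)
  n <- n_samples(set)
  per <- matrix(NA_real_, iterations, length(n_lv))
  for (i in seq_len(iterations)) {
    folds <- make_folds(n, splits, derive_seed(seed, i))
    pred <- fold_predictions(set, spec, n_lv, folds)
    per[i, ] <- apply(pred, 2, function(p) mape(set$glucose, p))
  }
  list(cv_mape = colMeans(per), per_iteration = per,
       splits = splits, iterations = iterations, seed = seed)
}

#' Leave-one-out cross-validation
#'
#' Performs exactly n model fits, each predicting the single held-out
#' sample; metrics are computed over the n pooled predictions. Fully
#' deterministic.
#'
#' @param set a `spectra_set` with `n >= 3` samples.
#' @param spec a `preprocess_spec`.
#' @param n_lv latent-variable count.
#' @return an `evaluation_report`.
#' @export
loocv <- function(set, spec, n_lv) {
  n <- n_samples(set)
  if (n < 3) stop("LOOCV needs at least 3 samples")
  pred <- fold_predictions(set, spec, n_lv, as.list(seq_len(n)))
  evaluation_report(set, seq_len(n), pred[, 1],
                    model_desc = sprintf("%s, %d LVs", spec_label(spec), n_lv),
                    scheme = sprintf("LOOCV (%d fits)", n))
}

#' Grouped holdout validation across individuals
#'
#' One fit on all samples from the training individuals (preprocessing
#' statistics from those samples only), evaluated on the samples from the
#' disjoint validation individuals — the across-individual generalisation
#' design.
#'
#' @param set a `spectra_set`.
#' @param spec a `preprocess_spec`.
#' @param n_lv latent-variable count.
#' @param train_groups,val_groups disjoint non-empty sets of individual IDs.
#' @return an `evaluation_report` on the validation samples, with the fitted
#'   `glucose_model` attached as attribute `"model"`.
#' @export
grouped_holdout <- function(set, spec, n_lv, train_groups, val_groups) {
  if (length(train_groups) == 0 || length(val_groups) == 0)
    stop("train and validation groups must be non-empty")
  if (length(intersect(train_groups, val_groups)) > 0)
    stop("train and validation groups overlap: individual-level leakage")
  missing <- setdiff(c(train_groups, val_groups), unique(set$individual))
  if (length(missing))
    stop("unknown individual(s): ", paste(missing, collapse = ", "))
  tr <- which(set$individual %in% train_groups)
  va <- which(set$individual %in% val_groups)
  model <- train_model(subset_samples(set, tr), spec, n_lv)
  y_pred <- predict(model, subset_samples(set, va))
  rep <- evaluation_report(
    set, va, y_pred,
    model_desc = sprintf("%s, %d LVs", spec_label(spec), n_lv),
    scheme = sprintf("grouped holdout (train: %s | validation: %s)",
                     paste(train_groups, collapse = ","),
                     paste(val_groups, collapse = ",")))
  attr(rep, "model") <- model
  rep
}

#' Exhaustive preprocessing x latent-variable grid search
#'
#' Evaluates every (preprocessing spec, latent-variable count) candidate by
#' random-subset cross-validation on the training set. The same master seed
#' drives the fold assignments of every candidate, so all candidates are
#' compared on identical partitions. The winner minimises CV MAPE; ties are
#' broken by fewer latent variables, then simpler preprocessing (fewer
#' active steps), then enumeration order.
#'
#' @param train a `spectra_set`.
#' @param specs list of `preprocess_spec` candidates (see
#'   [enumerate_pipelines()]).
#' @param lv_range integer vector of latent-variable counts (default 3:12).
#' @param splits,iterations,seed random-subset CV parameters.
#' @return object of class `grid_search_result`: `$table` (one row per
#'   candidate with its CV MAPE) and `$best` (spec, n_lv, cv_mape).
#' @export
grid_search <- function(train, specs, lv_range = 3:12, splits = 10,
                        iterations = 20, seed = 1) {
  stopifnot(length(specs) > 0, length(lv_range) > 0)
  rows <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    cv <- random_subset_cv(train, specs[[s]], lv_range, splits = splits,
                           iterations = iterations, seed = seed)
    rows[[s]] <- data.frame(spec_idx = s, spec = spec_label(specs[[s]]),
                            n_lv = lv_range, cv_mape = cv$cv_mape,
                            stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  steps <- vapply(specs, n_active_steps, numeric(1))[table$spec_idx]
  ord <- order(table$cv_mape, table$n_lv, steps, table$spec_idx)
  best_row <- table[ord[1], ]
  structure(
    list(table = table,
         best = list(spec = specs[[best_row$spec_idx]],
                     n_lv = best_row$n_lv, cv_mape = best_row$cv_mape),
         seed = seed, splits = splits, iterations = iterations),
    class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d candidates evaluated\n",
              nrow(x$table)))
  cat(sprintf("  best: %s, %d LVs (CV MAPE %.2f%%)\n",
              spec_label(x$best$spec), x$best$n_lv, x$best$cv_mape))
  invisible(x)
}

#' Write an evaluation report as JSON plus a predictions CSV
#'
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @param name base file name (writes `<name>.json`, `<name>_predictions.csv`).
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jp <- file.path(dir, paste0(name, ".json"))
  obj <- list(model = report$model_desc, scheme = report$scheme,
              n = nrow(report$predictions),
              mape_pct = report$mape,
              rmse_mgdl = report$rmse, rmse_mmol = mgdl_to_mmol(report$rmse),
              sep_mgdl = report$sep, sep_mmol = mgdl_to_mmol(report$sep),
              r2 = report$r2)
  jsonlite::write_json(obj, jp, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(report$predictions,
                   file.path(dir, paste0(name, "_predictions.csv")),
                   row.names = FALSE, quote = FALSE)
  invisible(jp)
}
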
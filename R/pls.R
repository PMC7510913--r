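# Single-response partial least-squares regression (NIPALS-PLS1).
#
# For a single response no inner iteration is needed: each weight vector is
# X'y of the deflated data directly. Components are nested, so one fit at
# the largest latent-variable count yields the regression vector for every
# smaller count — exploited heavily by the cross-validation routines.

#' Fit a PLS1 regression model by NIPALS
#'
#' Classical NIPALS deflation for one response: per component the weight is
#' `w = X'y / ||X'y||`, score `t = X w`, x-loading `p = X't / (t't)`,
#' y-loading `q = y't / (t't)`, then `X <- X - t p'`, `y <- y - t q`.
#' Extraction stops early (with a warning) when the score energy `t't` falls
#' below `tol` times the initial squared Frobenius norm of `X`, which
#' prevents numerical noise from being amplified into spurious components.
#' Each weight vector's largest-magnitude element is forced positive so
#' fitted models are reproducible across platforms.
#'
#' @param X centered predictor matrix (samples x wavenumbers).
#' @param y centered response vector.
#' @param n_lv number of latent variables to extract.
#' @param tol relative score-energy tolerance for early termination.
#' @return object of class `pls_model` with weights `W`, x-loadings `P`,
#'   y-loadings `q` (all for `n_comp` extracted components), the regression
#'   vector at the full count, and `coefficients(model, k)` available for
#'   any smaller k.
#' @export
pls_fit <- function(X, y, n_lv, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); K <- ncol(X)
  if (length(y) != n) stop("X and y disagree on the number of samples")
  if (n < 2) stop("PLS needs at least 2 samples")
  if (n_lv < 1 || n_lv > min(n - 1, K))
    stop("n_lv must be between 1 and min(n - 1, n_variables)")
  e0 <- sum(X^2)
  W <- matrix(0, K, n_lv); P <- matrix(0, K, n_lv); q <- numeric(n_lv)
  Tm <- matrix(0, n, n_lv)
  a <- 0L
  for (k in seq_len(n_lv)) {
    w <- crossprod(X, y)
    wn <- sqrt(sum(w^2))
    if (wn == 0) break
    w <- w / wn
    j <- which.max(abs(w))
    if (w[j] < 0) w <- -w                 # sign convention
    t_ <- as.numeric(X %*% w)
    tt <- sum(t_^2)
    if (tt < tol * e0) break
    p <- as.numeric(crossprod(X, t_)) / tt
    qk <- sum(y * t_) / tt
    X <- X - tcrossprod(t_, p)
    y <- y - t_ * qk
    a <- k
    W[, k] <- w; P[, k] <- p; q[k] <- qk; Tm[, k] <- t_
  }
  if (a < n_lv)
    warning(sprintf(
      "component extraction terminated early: %d of %d latent variables", a,
      n_lv))
  if (a == 0L) stop("no PLS component could be extracted (X'y is zero)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  # R = W (P'W)^-1 gives cumulative regression vectors B_k = R[,1:k] q[1:k]
  R <- W %*% solve(crossprod(P, W))
  structure(
    list(n_lv = a, n_lv_requested = as.integer(n_lv),
         W = W, P = P, q = q, scores = Tm[, seq_len(a), drop = FALSE],
         R = R, regression_vector = as.numeric(R %*% q)),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d wavenumbers\n",
              x$n_lv, nrow(x$W)))
  invisible(x)
}

#' Regression vector truncated to the first k latent variables
#'
#' @param object a `pls_model`.
#' @param k component count, `1 <= k <= object$n_lv`; default: all.
#' @param ... unused.
#' @return regression vector on centered data.
#' @export
coef.pls_model <- function(object, k = object$n_lv, ...) {
  if (k < 1 || k > object$n_lv) stop("k outside the extracted range")
  if (k == object$n_lv) return(object$regression_vector)
  as.numeric(object$R[, seq_len(k), drop = FALSE] %*% object$q[seq_len(k)])
}

#' Train a calibration model: preprocessing + PLS in one bundle
#'
#' Fits the preprocessor on the training set (row operators plus train-only
#' centering) and a NIPALS-PLS1 model on the processed data.
#'
#' @param train a `spectra_set` with complete reference glucose.
#' @param spec a `preprocess_spec`.
#' @param n_lv latent-variable count.
#' @return object of class `glucose_model` bundling the fitted preprocessor
#'   and `pls_model`.
#' @export
train_model <- function(train, spec, n_lv) {
  fit <- fit_preprocessor(spec, train)
  pls <- pls_fit(fit$X, fit$y, n_lv)
  structure(list(preprocessor = fit$preprocessor, pls = pls),
            class = "glucose_model")
}

#' Predict glucose concentrations for new spectra
#'
#' Applies the training-fitted preprocessing (including train-mean
#' centering) and the PLS regression vector, then adds back the training
#' response mean.
#'
#' @param object a `glucose_model` from [train_model()].
#' @param newdata a `spectra_set` on the model's grid.
#' @param k optional smaller latent-variable count.
#' @param ... unused.
#' @return numeric vector of predicted concentrations (mg/dL).
#' @export
predict.glucose_model <- function(object, newdata, k = object$pls$n_lv, ...) {
  Xc <- apply_preprocessor(object$preprocessor, newdata)
  as.numeric(Xc %*% coef(object$pls, k)) + object$preprocessor$y_mean
}

# ---- serialisation -------------------------------------------------------

#' Save a calibration model as JSON
#'
#' All matrices, centering statistics and the preprocessing spec are stored
#' in plain text at full double precision, so a reloaded model re-predicts
#' bit-identically.
#'
#' @param model a `glucose_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "glucose_model"))
  fp <- model$preprocessor
  obj <- list(
    format = "irglucose_model_v1",
    preprocess = unclass(fp$spec),
    wavenumber = fp$wavenumber,
    column_means = as.numeric(fp$column_means),
    y_mean = fp$y_mean,
    spacing = fp$spacing,
    pls = list(n_lv = model$pls$n_lv,
               W = model$pls$W, P = model$pls$P, q = model$pls$q,
               regression_vector = model$pls$regression_vector))
  # digits = I(17): 17 significant digits round-trip doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a calibration model saved by [write_model()]
#' @param path JSON file path.
#' @return a `glucose_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "irglucose_model_v1"))
    stop("not an irglucose model file")
  sp <- obj$preprocess
  spec <- preprocess_spec(filter = sp$filter, sg_width = sp$sg_width,
                          sg_order = sp$sg_order,
                          fourier_cutoff = sp$fourier_cutoff,
                          fourier_multiplier = sp$fourier_multiplier,
                          derivative = sp$derivative,
                          baseline = sp$baseline, normalise = sp$normalise)
  fp <- structure(
    list(spec = spec, column_means = as.numeric(obj$column_means),
         y_mean = obj$y_mean, spacing = obj$spacing,
         wavenumber = as.numeric(obj$wavenumber), fitted = TRUE),
    class = "fitted_preprocessor")
  W <- as.matrix(obj$pls$W); P <- as.matrix(obj$pls$P)
  q <- as.numeric(obj$pls$q)
  R <- W %*% solve(crossprod(P, W))
  pls <- structure(
    list(n_lv = as.integer(obj$pls$n_lv),
         n_lv_requested = as.integer(obj$pls$n_lv),
         W = W, P = P, q = q, scores = NULL, R = R,
         regression_vector = as.numeric(obj$pls$regression_vector)),
    class = "pls_model")
  structure(list(preprocessor = fp, pls = pls), class = "glucose_model")
}
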
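#' Assemble a calibration set
#'
#' Pairs known compositions with their FTIR spectra; all spectra must share
#' one grid.
#'
#' @param compositions mole fractions of component A in `[0, 1]`, one per
#'   spectrum.
#' @param spectra list of `ir_spectrum` objects on a common grid.
#' @return an object of class `azeo_calset`.
#' @export
calibration_set <- function(compositions, spectra) {
  if (length(compositions) != length(spectra))
    stop("compositions and spectra differ in length")
  if (length(spectra) < 2) stop("a calibration set needs at least 2 entries")
  if (any(compositions < 0 | compositions > 1))
    stop_domain("compositions must lie in [0, 1]")
  grid <- spectra[[1]]$wavenumbers
  for (s in spectra) {
    if (!same_grid(s, spectra[[1]]))
      stop("all calibration spectra must share one wavenumber grid")
  }
  X <- do.call(rbind, lapply(spectra, `[[`, "absorbance"))
  structure(list(compositions = as.numeric(compositions), X = X,
                 wavenumbers = grid),
            class = "azeo_calset")
}

# NIPALS PLS1 core on a raw matrix/response; returns per-count regression
# vectors so nested models come from a single deflation pass.
nipals_pls1 <- function(X, y, n_components) {
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n_components, n - 1, p)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, kmax); P <- matrix(0, p, kmax); q <- numeric(kmax)
  actual <- 0
  for (h in seq_len(kmax)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning("degenerate deflation at component ", h,
              "; returning ", h - 1, " components")
      break
    }
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(Xc, t)) / tt
    qh <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pvec)
    yc <- yc - qh * t
    W[, h] <- w; P[, h] <- pvec; q[h] <- qh
    actual <- h
  }
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  q <- q[seq_len(actual)]
  # regression vector for every truncation 1..actual (nested models)
  coefs <- matrix(0, p, actual)
  if (actual > 0) {
    R <- solve(crossprod(P, W))  # upper triangular (actual x actual)
    for (k in seq_len(actual)) {
      Wk <- W[, seq_len(k), drop = FALSE]
      Rk <- solve(crossprod(P[, seq_len(k), drop = FALSE], Wk))
      coefs[, k] <- Wk %*% (Rk %*% q[seq_len(k)])
    }
  }
  list(x_mean = x_mean, y_mean = y_mean, weights = W, loadings = P,
       q = q, coefs = coefs, n_components = actual)
}

#' Fit a PLS1 inverse-calibration model
#'
#' NIPALS partial least squares with a scalar response, on mean-centred
#' spectra and compositions with no variance scaling (absorbance units are
#' homogeneous across wavenumbers). With `n_components = 0` the model
#' predicts the training-composition mean.
#'
#' @param cal an [calibration_set()].
#' @param n_components number of latent directions; at most
#'   `min(n_samples - 1, n_wavenumbers)`.
#' @param window optional `c(lo, hi)` wavenumber window restricting the
#'   predictors (default: the full grid).
#' @return an object of class `pls1_model`.
#' @export
fit_pls1 <- function(cal, n_components, window = NULL) {
  stopifnot(inherits(cal, "azeo_calset"))
  n <- nrow(cal$X)
  keep <- seq_along(cal$wavenumbers)
  if (!is.null(window))
    keep <- which(cal$wavenumbers >= window[1] & cal$wavenumbers <= window[2])
  if (n_components < 0 || n_components > min(n - 1, length(keep)))
    stop_domain("n_components must lie in [0, min(n_samples - 1, n_wavenumbers)]")
  fit <- nipals_pls1(cal$X[, keep, drop = FALSE], cal$compositions,
                     max(n_components, 0))
  structure(c(fit, list(wavenumbers = cal$wavenumbers[keep],
                        requested_components = n_components)),
            class = "pls1_model")
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d latent direction(s), %d wavenumbers\n",
              x$n_components, length(x$wavenumbers)))
  invisible(x)
}

#' Predict composition from a spectrum
#'
#' @param model a `pls1_model`.
#' @param spec an `ir_spectrum` on the training grid.
#' @param n_components optionally truncate the model to fewer directions.
#' @return predicted composition in mol% of component A, clipped to
#'   `[0, 100]`; attribute `clipped` records whether clipping occurred.
#' @export
predict_composition <- function(model, spec, n_components = model$n_components) {
  stopifnot(inherits(model, "pls1_model"), inherits(spec, "ir_spectrum"))
  idx <- match(round(model$wavenumbers, 6), round(spec$wavenumbers, 6))
  if (anyNA(idx))
    stop("spectrum grid does not contain the model's training grid")
  a <- spec$absorbance[idx]
  if (n_components < 0 || n_components > model$n_components)
    stop_domain("n_components out of range for this model")
  yhat <- model$y_mean
  if (n_components > 0)
    yhat <- yhat + sum((a - model$x_mean) * model$coefs[, n_components])
  out <- 100 * yhat
  clipped <- out < 0 || out > 100
  out <- min(max(out, 0), 100)
  attr(out, "clipped") <- clipped
  out
}

#' Choose the number of PLS directions by leave-one-out cross-validation
#'
#' For each direction count `1..max_components`, each calibration point is
#' held out in turn, the model refit on the remainder, and the held-out
#' composition predicted; mean and maximum absolute errors are reported in
#' mol%. The chosen count minimises the mean error, with ties broken toward
#' fewer directions (parsimony).
#'
#' @param cal an [calibration_set()].
#' @param max_components largest direction count to consider (>= 1).
#' @param window optional wavenumber window, as in [fit_pls1()].
#' @return an object of class `pls_cv_report`: list with `table` (data
#'   frame `n_components`, `mean_abs_error_molpct`, `max_abs_error_molpct`),
#'   `chosen`, and the LOO predictions at the chosen count.
#' @export
loo_cv_select <- function(cal, max_components = 15, window = NULL) {
  stopifnot(inherits(cal, "azeo_calset"), max_components >= 1)
  n <- nrow(cal$X)
  keep <- seq_along(cal$wavenumbers)
  if (!is.null(window))
    keep <- which(cal$wavenumbers >= window[1] & cal$wavenumbers <= window[2])
  kmax <- min(max_components, n - 2, length(keep))
  preds <- matrix(NA_real_, n, kmax)  # mol%
  for (i in seq_len(n)) {
    # degenerate deflation just truncates the usable counts for this fold;
    # later counts inherit the last attainable model
    fit <- suppressWarnings(
      nipals_pls1(cal$X[-i, keep, drop = FALSE], cal$compositions[-i], kmax))
    a <- cal$X[i, keep] - fit$x_mean
    for (k in seq_len(kmax)) {
      kk <- min(k, fit$n_components)
      preds[i, k] <- 100 * (fit$y_mean + sum(a * fit$coefs[, kk]))
    }
  }
  truth <- 100 * cal$compositions
  err <- abs(preds - truth)
  tab <- data.frame(n_components = seq_len(kmax),
                    mean_abs_error_molpct = colMeans(err),
                    max_abs_error_molpct = apply(err, 2, max))
  chosen <- which.min(tab$mean_abs_error_molpct)  # which.min takes first = smallest count
  structure(list(table = tab, chosen = chosen,
                 loo_predictions_molpct = preds[, chosen],
                 truth_molpct = truth),
            class = "pls_cv_report")
}

#' @export
print.pls_cv_report <- function(x, ...) {
  cat("Leave-one-out PLS direction selection\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("chosen: %d direction(s); mean |error| %.3g mol%%, max %.3g mol%%\n",
              x$chosen, x$table$mean_abs_error_molpct[x$chosen],
              x$table$max_abs_error_molpct[x$chosen]))
  invisible(x)
}

#' Maximum and mean absolute prediction error
#'
#' @param predicted,truth equal-length numeric vectors in mol%.
#' @return named numeric vector `c(max_abs, mean_abs)` in mol%.
#' @export
error_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1)
    stop("predicted and truth must have equal length >= 1")
  e <- abs(predicted - truth)
  c(max_abs = max(e), mean_abs = mean(e))
}
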
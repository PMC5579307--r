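#' Protection efficacy from probing counts
#'
#' WHO protection formula \eqn{P = 1 - T/C} from the number of mosquitoes
#' probing the treated (`T`) versus control (`C`) arm. When `T > C` the
#' value is clipped to 0 (bounded efficacy scale) and the `clipped`
#' attribute flags it.
#'
#' @param treated,control non-negative probing counts; `control` must be
#'   positive for protection to be defined.
#' @return protection value(s) in `[0, 1]` with attribute `clipped`.
#' @examples
#' protection(0, 20)   # 1: full protection
#' protection(7, 20)   # 0.65
#' @export
protection <- function(treated, control) {
  if (any(treated < 0) || any(control < 0)) stop_domain("counts must be non-negative")
  if (any(control == 0))
    stop("protection undefined: control count is zero")
  p <- 1 - treated / control
  clipped <- p < 0
  p <- pmax(p, 0)
  attr(p, "clipped") <- any(clipped)
  p
}

sigmoid_protection <- function(t, p_max, t50, s) {
  p_max / (1 + exp((t - t50) / s))
}

#' Fit a decreasing sigmoid to a temporal protection curve
#'
#' Least-squares fit of the 3-parameter decreasing logistic
#' \eqn{P(t) = P_{max} / (1 + \exp((t - t_{50})/s))} with plateau
#' \eqn{P_{max} \in (0, 1]}, midpoint `t50` (h) and steepness `s > 0` (h),
#' from a deterministic multistart grid. The fitted curve is always
#' non-increasing; data that in truth rise with time can only yield a flat
#' or boundary fit, which is flagged rather than silently reported.
#'
#' @param curve a data frame with columns `time_h` and `protection`
#'   (values in `[0, 1]`), at least 4 time points.
#' @return an object of class `sigmoid_fit`: list with `p_max`, `t50_h`,
#'   `s_h`, `fitted`, `residuals`, `rmse`, `converged`, `degenerate`
#'   (all-zero protection), `boundary` (`t50` outside the observation
#'   window, e.g. a plateau that never decays within it).
#' @export
fit_protection_curve <- function(curve) {
  need <- c("time_h", "protection")
  if (!all(need %in% names(curve)))
    stop("curve must have columns ", paste(need, collapse = ", "))
  if (length(unique(curve$time_h)) < 4)
    stop("need at least 4 distinct time points")
  t <- curve$time_h; p <- curve$protection
  if (any(p < 0 | p > 1)) stop_domain("protection must lie in [0, 1]")

  if (all(p < 1e-12)) {
    return(structure(list(p_max = 0, t50_h = NA_real_, s_h = NA_real_,
                          fitted = rep(0, length(p)), residuals = p,
                          rmse = sqrt(mean(p^2)), converged = TRUE,
                          degenerate = TRUE, boundary = FALSE),
                     class = "sigmoid_fit"))
  }

  resid_fn <- function(par) p - sigmoid_protection(t, par[1], par[2], par[3])
  tspan <- range(t)
  starts <- expand.grid(
    t50 = seq(tspan[1], tspan[2] + diff(tspan), length.out = 4),
    s = c(0.3, 1))
  p_max0 <- min(max(p), 1)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = c(p_max0, starts$t50[i], starts$s[i]), fn = resid_fn,
      lower = c(1e-6, tspan[1] - 10 * diff(tspan), 1e-4),
      upper = c(1, tspan[2] + 10 * diff(tspan), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 20000)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("sigmoid fit failed to converge from every start")
  par <- best$fit$par
  fitted <- sigmoid_protection(t, par[1], par[2], par[3])
  structure(list(p_max = par[1], t50_h = par[2], s_h = par[3],
                 fitted = fitted, residuals = p - fitted,
                 rmse = sqrt(best$ssr / length(p)),
                 converged = best$fit$info %in% c(1:4, 6:8),
                 degenerate = FALSE,
                 boundary = par[2] < tspan[1] || par[2] > tspan[2]),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Sigmoid protection fit: degenerate (no protection at any time)\n")
  } else {
    cat(sprintf("Sigmoid protection fit: P_max = %.3f, t50 = %.2f h, s = %.2f h%s\n",
                x$p_max, x$t50_h, x$s_h,
                if (x$boundary) "  [boundary: midpoint outside window]" else ""))
  }
  invisible(x)
}

#' Protection duration at a threshold
#'
#' Closed-form crossing time of the fitted logistic:
#' \eqn{t = t_{50} + s \ln(P_{max}/P^* - 1)} for threshold \eqn{P^*}.
#'
#' @param fit a [fit_protection_curve()] result.
#' @param threshold protection threshold in `(0, P_max)`.
#' @return crossing time in hours.
#' @examples
#' # P_max = 0.9, t50 = 3 h, s = 0.5 h, threshold 0.8 -> 1.96 h
#' @export
protection_duration <- function(fit, threshold) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (fit$degenerate) stop("no-crossing error: fit is degenerate (P = 0)")
  if (threshold <= 0 || threshold >= fit$p_max)
    stop("no-crossing error: threshold must lie in (0, P_max)")
  fit$t50_h + fit$s_h * log(fit$p_max / threshold - 1)
}

#' Protection curve from an assay table
#'
#' Pools probing counts at each time (summing treated and control counts
#' across subjects/replicates) and applies [protection()].
#'
#' @param assay a data frame with columns `time_h`, `treated_probes`,
#'   `control_probes` (and optionally `subject`, `replicate`).
#' @param by optional column name to stratify by (e.g. `"subject"`)
#'   instead of pooling.
#' @return a data frame with columns `time_h`, `protection` (plus the
#'   stratifying column when `by` is given).
#' @export
protection_curve <- function(assay, by = NULL) {
  need <- c("time_h", "treated_probes", "control_probes")
  if (!all(need %in% names(assay)))
    stop("assay must have columns ", paste(need, collapse = ", "))
  grp <- if (is.null(by)) list(time_h = assay$time_h)
         else stats::setNames(list(assay$time_h, assay[[by]]), c("time_h", by))
  agg <- stats::aggregate(assay[, c("treated_probes", "control_probes")],
                          by = grp, FUN = sum)
  agg$protection <- as.numeric(protection(agg$treated_probes, agg$control_probes))
  agg[, c(names(grp), "protection")]
}
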
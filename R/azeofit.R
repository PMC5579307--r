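#' Avrami-type composition-drift law
#'
#' Stretched-exponential saturation of the liquid composition toward the
#' azeotrope as evaporation proceeds:
#' \eqn{x(m) = x_{az} + (x_0 - x_{az})\exp(-k m^n)} with `m` the released
#' mass fraction. At `m = 0` the value is `x0`; as `k m^n` grows the value
#' approaches `x_az` monotonically.
#'
#' @param m released mass fraction(s) in `[0, 1)`.
#' @param x0 initial composition in mol%.
#' @param x_az azeotrope (asymptotic) composition in mol%.
#' @param k,n positive rate and exponent parameters.
#' @return composition(s) in mol%.
#' @export
avrami_drift <- function(m, x0, x_az, k, n) {
  if (k <= 0 || n <= 0) stop_domain("k and n must be positive")
  if (any(m < 0 | m >= 1)) stop_domain("m must lie in [0, 1)")
  x_az + (x0 - x_az) * exp(-k * m^n)
}

#' Build a composition-drift dataset
#'
#' @param observations a data frame with columns `trajectory` (id), `m`
#'   (released mass fraction) and `x_molpct` (composition in mol%), or a
#'   list of `azeo_trajectory` objects to be converted.
#' @param min_x0 inclusion threshold in mol%: only trajectories whose first
#'   observation is at least this composition participate in the shared
#'   fit (default 40, the drift-analysis convention for mixtures already in
#'   the attractor's basin).
#' @return an object of class `drift_dataset`.
#' @export
drift_dataset <- function(observations, min_x0 = 40) {
  if (is.list(observations) && !is.data.frame(observations)) {
    observations <- do.call(rbind, lapply(seq_along(observations), function(i) {
      cv <- composition_vs_released(observations[[i]])
      data.frame(trajectory = i, m = cv$released_fraction,
                 x_molpct = 100 * cv$x_a)
    }))
  }
  need <- c("trajectory", "m", "x_molpct")
  if (!all(need %in% names(observations)))
    stop("observations must have columns ", paste(need, collapse = ", "))
  if (any(observations$m < 0 | observations$m >= 1))
    stop_domain("released fractions must lie in [0, 1)")
  observations <- observations[order(observations$trajectory, observations$m), ]
  x0 <- tapply(observations$x_molpct, observations$trajectory, `[`, 1)
  ids <- names(x0)
  eligible <- ids[x0 >= min_x0]
  structure(list(observations = observations,
                 x0 = stats::setNames(as.numeric(x0), ids),
                 eligible = eligible, min_x0 = min_x0),
            class = "drift_dataset")
}

# leverages h_ii of the linearized joint model at the fitted parameters
avrami_leverages <- function(fit) {
  par <- fit$par
  p <- length(par)
  f0 <- avrami_joint_residuals(par, fit$obs_list, fit$x0s)
  J <- matrix(0, length(f0), p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(abs(par[j]), 1)
    pp <- par; pp[j] <- pp[j] + h
    J[, j] <- (avrami_joint_residuals(pp, fit$obs_list, fit$x0s) - f0) / h
  }
  sv <- svd(J)
  keep <- sv$d > 1e-10 * sv$d[1]
  rowSums(sv$u[, keep, drop = FALSE]^2)
}

# physically meaningful parameter box: compositions in [0, 100] mol%,
# rate k in [e^-8, e^8], exponent n in [0.05, 20]; keeps ill-determined
# replicates from wandering on flat likelihood plateaus
avrami_par_bounds <- function(nt) {
  list(lower = c(0, rep(-8, nt), rep(log(0.05), nt)),
       upper = c(100, rep(8, nt), rep(log(20), nt)))
}

# residuals for the joint fit; par = c(x_az, log k_1..T, log n_1..T)
avrami_joint_residuals <- function(par, obs_list, x0s) {
  nt <- length(obs_list)
  x_az <- par[1]
  ks <- exp(par[1 + seq_len(nt)])
  ns <- exp(par[1 + nt + seq_len(nt)])
  unlist(lapply(seq_len(nt), function(i) {
    o <- obs_list[[i]]
    o$x_molpct - (x_az + (x0s[i] - x_az) * exp(-ks[i] * o$m^ns[i]))
  }), use.names = FALSE)
}

#' Fit the shared-azeotrope Avrami drift model
#'
#' Least-squares fit of [avrami_drift()] jointly over all eligible
#' trajectories: one shared asymptote `x_az` and per-trajectory `(k, n)`,
#' with each trajectory's `x0` fixed at its first observation. Initialised
#' from a small deterministic multistart grid; the best (lowest SSR)
#' converged start wins.
#'
#' @param data a [drift_dataset()].
#' @param starts optional data frame of starting values with columns `k`,
#'   `n`; defaults to a 3 x 3 grid.
#' @return an object of class `avrami_fit`: list with `x_az_molpct`,
#'   `per_trajectory` (data frame `trajectory`, `x0_molpct`, `k`, `n`),
#'   `residuals` (per observation, in data order), `fitted`, `converged`,
#'   `degenerate`, `ssr` and the internal fit environment used by the
#'   bootstrap.
#' @export
fit_avrami <- function(data, starts = NULL) {
  stopifnot(inherits(data, "drift_dataset"))
  obs <- data$observations
  obs <- obs[obs$trajectory %in% data$eligible, ]
  ids <- unique(obs$trajectory)
  if (length(ids) < 1) stop("no eligible trajectories (check min_x0)")
  obs_list <- lapply(ids, function(id) obs[obs$trajectory == id, c("m", "x_molpct")])
  for (o in obs_list) if (nrow(o) < 4)
    stop("each eligible trajectory needs at least 4 observations")
  x0s <- data$x0[as.character(ids)]

  # degenerate: all observations (essentially) constant
  if (stats::sd(obs$x_molpct) < 1e-12) {
    xbar <- mean(obs$x_molpct)
    return(structure(list(
      x_az_molpct = xbar,
      per_trajectory = data.frame(trajectory = ids, x0_molpct = x0s,
                                  k = NA_real_, n = NA_real_),
      residuals = obs$x_molpct - xbar, fitted = rep(xbar, nrow(obs)),
      converged = TRUE, degenerate = TRUE, ssr = sum((obs$x_molpct - xbar)^2),
      obs_list = obs_list, x0s = x0s, ids = ids),
      class = "avrami_fit"))
  }

  if (is.null(starts))
    starts <- expand.grid(k = c(1, 5, 20), n = c(0.5, 1, 2))
  # asymptote start: mean of each trajectory's last observation
  x_az0 <- mean(vapply(obs_list, function(o) o$x_molpct[nrow(o)], numeric(1)))

  best <- NULL
  bl <- avrami_par_bounds(length(ids))
  for (s in seq_len(nrow(starts))) {
    par0 <- c(x_az0, rep(log(starts$k[s]), length(ids)),
              rep(log(starts$n[s]), length(ids)))
    fit <- try(minpack.lm::nls.lm(
      par = par0, fn = avrami_joint_residuals,
      obs_list = obs_list, x0s = x0s,
      lower = bl$lower, upper = bl$upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 20000)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop("Avrami drift fit failed to converge from every start")
  fit <- best$fit
  # a maxiter-stalled best fit usually sits on a flat plateau; restarting
  # resets the trust region and lets the optimizer declare convergence
  tries <- 0
  while (!(fit$info %in% c(1:4, 6:8)) && tries < 3) {
    fit2 <- try(minpack.lm::nls.lm(
      par = fit$par, fn = avrami_joint_residuals,
      obs_list = obs_list, x0s = x0s,
      lower = bl$lower, upper = bl$upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 20000)),
      silent = TRUE)
    if (inherits(fit2, "try-error")) break
    fit <- fit2
    tries <- tries + 1
  }
  nt <- length(ids)
  # nls.lm fvec at the solution is our residual function, i.e. data - model
  structure(list(
    x_az_molpct = fit$par[1],
    per_trajectory = data.frame(trajectory = ids, x0_molpct = x0s,
                                k = exp(fit$par[1 + seq_len(nt)]),
                                n = exp(fit$par[1 + nt + seq_len(nt)])),
    residuals = fit$fvec, fitted = obs$x_molpct - fit$fvec,
    converged = fit$info %in% c(1:4, 6:8), degenerate = FALSE, ssr = best$ssr,
    obs_list = obs_list, x0s = x0s, ids = ids, par = fit$par),
    class = "avrami_fit")
}

#' @export
print.avrami_fit <- function(x, ...) {
  cat(sprintf("Avrami drift fit: x_az = %.2f mol%% over %d trajectories%s\n",
              x$x_az_molpct, length(x$ids),
              if (x$degenerate) " (degenerate: constant data)" else ""))
  invisible(x)
}

#' Residual-bootstrap confidence interval for the azeotrope composition
#'
#' Resamples the fitted residuals with replacement *within each trajectory*
#' (preserving every trajectory's design points), adds them to the fitted
#' values, refits the shared-asymptote model starting from the original
#' estimates, and collects the replicate `x_az` values. The interval is the
#' percentile 95% CI (2.5/97.5). Reproducible under a fixed seed.
#'
#' @param fit a converged [fit_avrami()] result.
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return an object of class `azeo_bootstrap`: list with `estimate_molpct`
#'   (the original-fit `x_az`), `ci_low_molpct`, `ci_high_molpct`,
#'   `replicates`, `n_replicates`, `n_failed`, `seed`, `level`.
#' @export
bootstrap_azeotrope <- function(fit, n_replicates = 1000, seed = 1,
                                level = 0.95) {
  stopifnot(inherits(fit, "avrami_fit"))
  if (!fit$converged) stop("bootstrap requires a converged fit")
  obs_list <- fit$obs_list
  nt <- length(obs_list)
  sizes <- vapply(obs_list, nrow, integer(1))
  bounds <- c(0, cumsum(sizes))
  fitted_by_traj <- lapply(seq_len(nt), function(i)
    fit$fitted[(bounds[i] + 1):bounds[i + 1]])
  resid_by_traj <- lapply(seq_len(nt), function(i)
    fit$residuals[(bounds[i] + 1):bounds[i + 1]])

  if (fit$degenerate || all(abs(unlist(resid_by_traj)) < 1e-12)) {
    return(structure(list(estimate_molpct = fit$x_az_molpct,
                          ci_low_molpct = fit$x_az_molpct,
                          ci_high_molpct = fit$x_az_molpct,
                          replicates = rep(fit$x_az_molpct, n_replicates),
                          n_replicates = n_replicates, n_failed = 0L,
                          seed = seed, level = level),
                     class = "azeo_bootstrap"))
  }

  # fitted residuals are variance-deflated by the fit; rescale them by the
  # leverages of the linearized model, r_i / sqrt(1 - h_ii), the standard
  # correction before residual resampling
  lev <- avrami_leverages(fit)
  resid_by_traj <- lapply(seq_len(nt), function(i)
    resid_by_traj[[i]] / sqrt(pmax(1 - lev[(bounds[i] + 1):bounds[i + 1]], 0.05)))

  reps <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(b) {
      boot_list <- lapply(seq_len(nt), function(i) {
        o <- obs_list[[i]]
        o$x_molpct <- fitted_by_traj[[i]] +
          sample(resid_by_traj[[i]], sizes[i], replace = TRUE)
        o
      })
      bl <- avrami_par_bounds(nt)
      run <- function(par0) try(suppressWarnings(minpack.lm::nls.lm(
        par = par0, fn = avrami_joint_residuals,
        obs_list = boot_list, x0s = fit$x0s,
        lower = bl$lower, upper = bl$upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 20000))),
        silent = TRUE)
      refit <- run(fit$par)
      if (!inherits(refit, "try-error") && !(refit$info %in% c(1:4, 6:8)))
        refit <- run(refit$par)   # restart once from the stall point
      if (inherits(refit, "try-error") || !(refit$info %in% c(1:4, 6:8)))
        return(NA_real_)
      refit$par[1]
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.05 * n_replicates)
    stop("more than 5% of bootstrap refits failed (", n_failed, "/",
         n_replicates, ")")
  ok <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(estimate_molpct = fit$x_az_molpct,
                 ci_low_molpct = ci[1], ci_high_molpct = ci[2],
                 replicates = reps, n_replicates = n_replicates,
                 n_failed = as.integer(n_failed), seed = seed, level = level),
            class = "azeo_bootstrap")
}

#' @export
print.azeo_bootstrap <- function(x, ...) {
  cat(sprintf("%.1f mol%% (%.1f, %.1f)  [%d replicates, seed %d]\n",
              x$estimate_molpct, x$ci_low_molpct, x$ci_high_molpct,
              x$n_replicates, x$seed))
  invisible(x)
}
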
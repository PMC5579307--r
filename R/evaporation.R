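#' Simulate open (convection-swept) evaporation of a binary liquid
#'
#' Integrates the molar balances
#' \eqn{dn_i/dt = -k\, x_i \gamma_i P_i^{sat}}: the molar flux of each
#' component is proportional to its equilibrium partial pressure over the
#' liquid, the regime in which the overall mass-loss rate varies linearly
#' with the liquid's vapour pressure. The instantaneous vapour composition
#' therefore equals the equilibrium `y`. Composition is always recomputed
#' from the integrated mole numbers, never integrated directly.
#'
#' @param vle an [binary_vle()] system.
#' @param x0 initial mole fraction of component A in `[0, 1]`.
#' @param n0 initial total moles (> 0).
#' @param rate_constant mass-transfer coefficient `k` in mol/(Pa h), shared
#'   by both components.
#' @param t_end end time in hours.
#' @param n_out number of requested output times (uniform grid on
#'   `[0, t_end]`); the run stops earlier if the liquid is exhausted.
#' @param mole_floor total-mole floor terminating the run (default
#'   `1e-9 * n0`), avoiding 0/0 at exhaustion.
#' @param rtol,atol integrator tolerances (lsodar).
#' @return an object of class `azeo_trajectory`: a data frame with columns
#'   `time_h`, `moles_a`, `moles_b`, `x_a`, `mass_g`, `released_fraction`,
#'   plus attributes `vle`, `x0`, `rate_constant`.
#' @examples
#' vle <- make_reference_vle()
#' traj <- simulate_open_evaporation(vle, x0 = 0.55, n0 = 0.065,
#'                                   rate_constant = 5e-5, t_end = 500)
#' tail(traj$x_a, 1)  # drifts toward the 77 mol% attractor
#' @export
simulate_open_evaporation <- function(vle, x0, n0, rate_constant, t_end,
                                      n_out = 201, mole_floor = 1e-9 * n0,
                                      rtol = 1e-8, atol = NULL) {
  if (x0 < 0 || x0 > 1) stop_domain("x0 must lie in [0, 1]")
  if (n0 <= 0) stop_domain("n0 must be positive")
  if (rate_constant <= 0) stop_domain("rate_constant must be positive")
  if (is.null(atol)) atol <- 1e-12 * n0
  ma <- vle$component_a$molar_mass
  mb <- vle$component_b$molar_mass

  derivs <- function(t, n, parms) {
    ntot <- n[1] + n[2]
    x <- min(max(n[1] / ntot, 0), 1)
    gam <- activity_coefficients(vle$activity, x)
    list(c(-rate_constant * x * gam[, "gamma_a"] * vle$p_a_sat,
           -rate_constant * (1 - x) * gam[, "gamma_b"] * vle$p_b_sat))
  }
  rootfun <- function(t, n, parms) n[1] + n[2] - mole_floor

  times <- seq(0, t_end, length.out = n_out)
  sol <- try(deSolve::ode(y = c(na = x0 * n0, nb = (1 - x0) * n0),
                          times = times, func = derivs, parms = NULL,
                          method = "lsodar", rootfunc = rootfun,
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("open-evaporation integration failed: ", attr(sol, "condition")$message)
  sol <- as.data.frame(sol)
  na <- pmax(sol$na, 0)
  nb <- pmax(sol$nb, 0)
  ntot <- na + nb
  traj <- data.frame(
    time_h = sol$time,
    moles_a = na,
    moles_b = nb,
    x_a = pmin(pmax(na / ntot, 0), 1),
    mass_g = na * ma + nb * mb)
  traj$released_fraction <- 1 - traj$mass_g / traj$mass_g[1]
  structure(traj, class = c("azeo_trajectory", "data.frame"),
            vle = vle, x0 = x0, rate_constant = rate_constant)
}

#' Composition versus released mass fraction
#'
#' Reshapes a trajectory into the (released fraction, composition) pairs
#' used for drift analysis. Rows with tied released fraction (e.g. after
#' the liquid is exhausted) are collapsed so the first column is strictly
#' increasing.
#'
#' @param traj an `azeo_trajectory`.
#' @return a data frame with columns `released_fraction`, `x_a`.
#' @export
composition_vs_released <- function(traj) {
  stopifnot(inherits(traj, "azeo_trajectory"))
  m <- traj$released_fraction
  keep <- c(TRUE, diff(m) > 0)
  data.frame(released_fraction = m[keep], x_a = traj$x_a[keep])
}

#' Isothermal mass-loss (TGA-style) curve of a trajectory
#'
#' @param traj an `azeo_trajectory`.
#' @return a data frame with columns `time_h`, `mass_g`.
#' @export
tga_mass_curve <- function(traj) {
  stopifnot(inherits(traj, "azeo_trajectory"))
  data.frame(time_h = traj$time_h, mass_g = traj$mass_g)
}

#' Correct an experimental mass log for aliquot sampling losses
#'
#' During the oven test small aliquots are withdrawn for spectroscopy at
#' each sampling event; the recorded gross mass therefore under-states the
#' mass actually lost by evaporation. The gross mass at a row is understood
#' as recorded *before* that row's aliquot is withdrawn, so
#' `evaporative_loss(t) = mass(0) - gross_mass(t) - sum(aliquots at earlier
#' times)`.
#'
#' @param log a data frame with columns `time_h`, `gross_mass_g` and
#'   `aliquot_mass_g` (grams removed at each sampling event, zero if none).
#' @return a data frame with columns `time_h`, `evaporative_loss_g`.
#' @examples
#' log <- data.frame(time_h = c(0, 24), gross_mass_g = c(10, 9.5),
#'                   aliquot_mass_g = c(0.010, 0))
#' correct_sampling_losses(log)  # 0 then 0.490 g
#' @export
correct_sampling_losses <- function(log) {
  need <- c("time_h", "gross_mass_g", "aliquot_mass_g")
  if (!all(need %in% names(log)))
    stop("mass log must have columns ", paste(need, collapse = ", "))
  if (any(log$gross_mass_g <= 0)) stop("gross_mass_g must be positive")
  if (any(log$aliquot_mass_g < 0)) stop("aliquot_mass_g must be non-negative")
  removed_before <- c(0, cumsum(log$aliquot_mass_g)[-nrow(log)])
  loss <- log$gross_mass_g[1] - log$gross_mass_g - removed_before
  if (any(loss < -1e-9))
    stop("data-integrity error: computed evaporative loss is negative ",
         "(gross mass inconsistent with aliquot record)")
  data.frame(time_h = log$time_h, evaporative_loss_g = pmax(loss, 0))
}

#' Write a trajectory to CSV
#'
#' Columns are exactly `time_h, mass_g, x_a, released_fraction`; units are
#' carried in the column names (hours, grams, mole fraction).
#'
#' @param traj an `azeo_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(time_h = traj$time_h, mass_g = traj$mass_g,
                    x_a = traj$x_a, released_fraction = traj$released_fraction)
  write_atomic(path, function(p)
    utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     p, row.names = FALSE, quote = FALSE))
}
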
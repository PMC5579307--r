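#' Define a pure component
#'
#' A component carries the molar mass and the Antoine constants of the
#' ln-form correlation \eqn{\ln P^{sat}[\mathrm{Pa}] = A - B/(T[\mathrm{K}] + C)}.
#'
#' @param name component name.
#' @param molar_mass molar mass in g/mol; must be positive.
#' @param antoine numeric vector of length 3, the Antoine coefficients
#'   `c(A, B, C)` of the ln-form correlation with pressure in Pa and
#'   temperature in K.
#' @param t_range valid temperature range in K for the Antoine correlation.
#' @param molar_volume liquid molar volume in mL/mol (used only for
#'   volume-to-mole conversions in the synthetic generators); optional.
#' @return an object of class `azeo_component`.
#' @examples
#' acid <- component("nonanoic acid", 158.24, c(27.603, 8400, 0))
#' saturation_pressure(acid, 323.15)
#' @export
component <- function(name, molar_mass, antoine, t_range = c(273.15, 400),
                      molar_volume = NA_real_) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    stop_domain("molar_mass must be positive")
  if (length(antoine) != 3) stop("antoine must have exactly 3 coefficients (A, B, C)")
  antoine <- as.numeric(antoine)
  names(antoine) <- c("A", "B", "C")
  obj <- structure(
    list(name = name, molar_mass = molar_mass, antoine = antoine,
         t_range = as.numeric(t_range), molar_volume = molar_volume),
    class = "azeo_component")
  # saturation pressure must be positive (finite) across the declared range
  p <- saturation_pressure(obj, seq(t_range[1], t_range[2], length.out = 11))
  if (any(!is.finite(p) | p <= 0))
    stop("Antoine coefficients give a non-positive saturation pressure in t_range")
  obj
}

#' Pure-component saturation pressure
#'
#' @param comp an `azeo_component`.
#' @param temperature temperature(s) in K.
#' @return saturation pressure in Pa.
#' @export
saturation_pressure <- function(comp, temperature) {
  a <- comp$antoine
  exp(a[["A"]] - a[["B"]] / (temperature + a[["C"]]))
}

#' Redlich-Kister activity-coefficient model
#'
#' Dimensionless excess Gibbs energy at fixed temperature,
#' \eqn{G^E/RT = x_A x_B \sum_k A_k (x_A - x_B)^k}. With all coefficients
#' zero the model is ideal. Order 4 (four coefficients) is the default
#' flexibility used by the shipped reference fixture: it is the smallest
#' expansion that reliably produces two interior activity-ratio crossings,
#' i.e. double azeotropy.
#'
#' @param coefficients numeric vector of Redlich-Kister coefficients
#'   \eqn{A_0, A_1, \dots}; an empty or all-zero vector gives the ideal model.
#' @return an object of class `azeo_activity`.
#' @export
activity_model <- function(coefficients = numeric(0)) {
  structure(list(coefficients = as.numeric(coefficients)),
            class = "azeo_activity")
}

# G^E/RT and its composition derivative; both are closed-form polynomials,
# so the Gibbs-Duhem relation holds identically for the derived gammas.
rk_gibbs_excess <- function(model, x_a) {
  A <- model$coefficients
  if (length(A) == 0) return(rep(0, length(x_a)))
  u <- 2 * x_a - 1
  s <- 0
  for (k in seq_along(A)) s <- s + A[k] * u^(k - 1)
  x_a * (1 - x_a) * s
}

rk_gibbs_excess_deriv <- function(model, x_a) {
  A <- model$coefficients
  if (length(A) == 0) return(rep(0, length(x_a)))
  u <- 2 * x_a - 1
  s <- 0; ds <- 0
  for (k in seq_along(A)) {
    s <- s + A[k] * u^(k - 1)
    if (k > 1) ds <- ds + (k - 1) * A[k] * u^(k - 2)
  }
  -u * s + 2 * x_a * (1 - x_a) * ds
}

#' Activity coefficients of both components
#'
#' Computed from the excess Gibbs function by the standard partial-molar
#' relations \eqn{\ln\gamma_A = g + x_B\,dg/dx_A},
#' \eqn{\ln\gamma_B = g - x_A\,dg/dx_A} with \eqn{g = G^E/RT}.
#'
#' @param model an `azeo_activity` model.
#' @param x_a mole fraction(s) of component A in `[0, 1]`.
#' @return a two-column matrix with columns `gamma_a`, `gamma_b`.
#' @examples
#' activity_coefficients(activity_model(-2), 0.5)  # gamma_a = exp(-0.5)
#' @export
activity_coefficients <- function(model, x_a) {
  if (any(x_a < 0 | x_a > 1)) stop_domain("x_a must lie in [0, 1]")
  g <- rk_gibbs_excess(model, x_a)
  dg <- rk_gibbs_excess_deriv(model, x_a)
  cbind(gamma_a = exp(g + (1 - x_a) * dg),
        gamma_b = exp(g - x_a * dg))
}

#' Binary vapour-liquid equilibrium system
#'
#' Bundles two components, an activity model and a temperature. The gas
#' phase is treated as ideal (modified Raoult's law), appropriate for the
#' near-ambient pressures of open evaporation.
#'
#' @param component_a,component_b `azeo_component` objects; by convention
#'   component A is the one whose mole fraction `x_a` is tracked.
#' @param activity an `azeo_activity` model (isothermal, matching
#'   `temperature`).
#' @param temperature system temperature in K; must lie inside both
#'   components' Antoine validity ranges.
#' @return an object of class `azeo_vle`.
#' @export
binary_vle <- function(component_a, component_b, activity, temperature) {
  stopifnot(inherits(component_a, "azeo_component"),
            inherits(component_b, "azeo_component"),
            inherits(activity, "azeo_activity"))
  for (comp in list(component_a, component_b)) {
    if (temperature < comp$t_range[1] || temperature > comp$t_range[2])
      stop("temperature outside Antoine validity range of ", comp$name)
  }
  structure(list(component_a = component_a, component_b = component_b,
                 activity = activity, temperature = temperature,
                 p_a_sat = saturation_pressure(component_a, temperature),
                 p_b_sat = saturation_pressure(component_b, temperature)),
            class = "azeo_vle")
}

#' @export
print.azeo_vle <- function(x, ...) {
  cat("Binary VLE:", x$component_a$name, "(A) /", x$component_b$name, "(B)\n")
  cat(sprintf("  T = %.2f K;  P_sat A = %.4g Pa, B = %.4g Pa\n",
              x$temperature, x$p_a_sat, x$p_b_sat))
  cat("  Redlich-Kister coefficients:",
      if (length(x$activity$coefficients)) paste(signif(x$activity$coefficients, 6), collapse = ", ")
      else "(ideal)", "\n")
  invisible(x)
}

#' Equilibrium vapour composition and bubble pressure
#'
#' Modified Raoult's law:
#' \eqn{P = x_A\gamma_A P_A^{sat} + x_B\gamma_B P_B^{sat}},
#' \eqn{y_A = x_A\gamma_A P_A^{sat}/P}.
#'
#' @param vle an `azeo_vle` system.
#' @param x_a liquid mole fraction(s) of component A in `[0, 1]`.
#' @return a data frame with columns `x_a`, `y_a`, `pressure` (Pa).
#' @export
equilibrium_vapor <- function(vle, x_a) {
  if (any(x_a < 0 | x_a > 1)) stop_domain("x_a must lie in [0, 1]")
  gam <- activity_coefficients(vle$activity, x_a)
  pa <- x_a * gam[, "gamma_a"] * vle$p_a_sat
  pb <- (1 - x_a) * gam[, "gamma_b"] * vle$p_b_sat
  p <- pa + pb
  data.frame(x_a = x_a, y_a = pa / p, pressure = p)
}

#' Bubble pressure of the liquid at given composition
#'
#' @inheritParams equilibrium_vapor
#' @return total equilibrium pressure(s) in Pa.
#' @export
bubble_pressure <- function(vle, x_a) {
  equilibrium_vapor(vle, x_a)$pressure
}

# dy/dx by central difference, shrinking the step near the endpoints
vapor_slope <- function(vle, x, h = 1e-6) {
  h <- min(h, x / 2, (1 - x) / 2)
  (equilibrium_vapor(vle, x + h)$y_a - equilibrium_vapor(vle, x - h)$y_a) / (2 * h)
}

#' Locate all azeotropes of a binary system
#'
#' Scans `y(x) - x` for sign changes on a uniform interior grid and polishes
#' each bracket by bisection; every interior root is then classified by
#' [classify_azeotrope()]. Endpoints (the pure components) are excluded.
#'
#' @param vle an `azeo_vle` system.
#' @param grid_step scan resolution in mole fraction (default `1e-3`).
#' @param tol root tolerance passed to the bisection polish (default `1e-10`).
#' @return a data frame with one row per azeotrope, in increasing `x_a`
#'   order: columns `x_a`, `x_a_molpct`, `y_a`, `pressure`, `sign`
#'   (`"negative"`/`"positive"`), `stability` (`"attractor"`/`"repeller"`),
#'   `dydx`, `degenerate`. Zero rows when the system is zeotropic.
#' @examples
#' vle <- make_reference_vle()
#' find_azeotropes(vle)
#' @export
find_azeotropes <- function(vle, grid_step = 1e-3, tol = 1e-10) {
  xs <- seq(grid_step, 1 - grid_step, by = grid_step)
  h <- equilibrium_vapor(vle, xs)$y_a - xs
  idx <- which(h[-length(h)] * h[-1] <= 0 & h[-length(h)] != 0)
  roots <- vapply(idx, function(i) {
    uniroot(function(x) equilibrium_vapor(vle, x)$y_a - x,
            c(xs[i], xs[i + 1]), tol = tol)$root
  }, numeric(1))
  roots <- sort(unique(roots))
  if (length(roots) == 0) {
    return(data.frame(x_a = numeric(0), x_a_molpct = numeric(0),
                      y_a = numeric(0), pressure = numeric(0),
                      sign = character(0), stability = character(0),
                      dydx = numeric(0), degenerate = logical(0)))
  }
  cls <- lapply(roots, function(r) classify_azeotrope(vle, r))
  eq <- equilibrium_vapor(vle, roots)
  data.frame(
    x_a = roots,
    x_a_molpct = 100 * roots,
    y_a = eq$y_a,
    pressure = eq$pressure,
    sign = vapply(cls, `[[`, character(1), "sign"),
    stability = vapply(cls, `[[`, character(1), "stability"),
    dydx = vapply(cls, `[[`, numeric(1), "dydx"),
    degenerate = vapply(cls, `[[`, logical(1), "degenerate"))
}

#' Classify an azeotrope root
#'
#' Under open evaporation the liquid composition obeys
#' \eqn{dx/d\xi = x - y(x)} with \eqn{\xi = -\ln(N/N_0)}, so an azeotrope
#' (a root of `y(x) = x`) is an attractor precisely when `dy/dx > 1` there.
#' By the Gibbs-Konovalov relation this coincides with the bubble pressure
#' having a local minimum (negative, maximum-boiling azeotrope); `dy/dx < 1`
#' marks a repeller at a bubble-pressure maximum (positive azeotrope). Both
#' criteria are evaluated and must agree.
#'
#' @param vle an `azeo_vle` system.
#' @param x_root an azeotrope root (a solution of `y(x) = x` in (0, 1)).
#' @param degenerate_tol roots with `|dy/dx - 1|` below this are flagged
#'   degenerate (tangent azeotropy).
#' @return a list with elements `sign`, `stability`, `dydx`, `pressure`,
#'   `degenerate`.
#' @export
classify_azeotrope <- function(vle, x_root, degenerate_tol = 1e-6) {
  if (x_root <= 0 || x_root >= 1) stop_domain("x_root must be interior to (0, 1)")
  dydx <- vapor_slope(vle, x_root)
  dp <- min(1e-4, x_root / 2, (1 - x_root) / 2)
  p0 <- bubble_pressure(vle, x_root)
  pm <- bubble_pressure(vle, x_root - dp)
  pp <- bubble_pressure(vle, x_root + dp)
  minimum <- p0 < pm && p0 < pp
  maximum <- p0 > pm && p0 > pp
  degenerate <- abs(dydx - 1) < degenerate_tol || (!minimum && !maximum)
  stability <- if (dydx > 1) "attractor" else "repeller"
  sign <- if (minimum) "negative" else if (maximum) "positive" else "degenerate"
  if (!degenerate) {
    agree <- (sign == "negative") == (stability == "attractor")
    if (!agree)
      warning("pressure-extremum and slope classifications disagree at x = ",
              signif(x_root, 6), "; flagging degenerate")
    degenerate <- degenerate || !agree
  }
  list(sign = sign, stability = stability, dydx = dydx,
       pressure = p0, degenerate = degenerate)
}
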
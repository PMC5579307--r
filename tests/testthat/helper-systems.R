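# Small systems used across test files. Antoine with B = C = 0 gives a
# temperature-independent saturation pressure exp(A), handy for closed forms.
flat_component <- function(name, p_sat, molar_mass = 100) {
  component(name, molar_mass, c(log(p_sat), 0, 0))
}

ideal_vle <- function(p_a = 2, p_b = 1, m_a = 100, m_b = 100) {
  binary_vle(flat_component("A", p_a, m_a), flat_component("B", p_b, m_b),
             activity_model(), 323.15)
}

# symmetric one-parameter model with equal pressures: single negative
# azeotrope at x = 0.5
symmetric_vle <- function(a0 = -2) {
  binary_vle(flat_component("A", 1), flat_component("B", 1),
             activity_model(a0), 323.15)
}

# draw a random Redlich-Kister model that satisfies liquid-phase material
# stability (1 + x(1-x) g'' > 0); unstable draws are rejected
random_stable_model <- function(order = 4, scale = 1.5) {
  repeat {
    coefs <- runif(order, -scale, scale)
    mod <- activity_model(coefs)
    x <- seq(0.005, 0.995, length.out = 400)
    h <- 1e-5
    gp <- function(z) azeoblend:::rk_gibbs_excess_deriv(mod, z)
    gpp <- (gp(x + h) - gp(x - h)) / (2 * h)
    if (all(1 + x * (1 - x) * gpp > 0.02)) return(mod)
  }
}

# noise-free rank-2 calibration set: exact linear mixtures of two profiles
rank2_calset <- function(n = 24, n_wn = 301) {
  grid <- seq(1000, 1000 + 2 * (n_wn - 1), by = 2)
  prof_a <- exp(-((grid - 1300) / 80)^2) + 0.5 * exp(-((grid - 1120) / 40)^2)
  prof_b <- 0.8 * exp(-((grid - 1450) / 60)^2) + 0.3 * exp(-((grid - 1050) / 30)^2)
  xs <- seq(0.02, 0.98, length.out = n)
  spectra <- lapply(xs, function(x)
    ir_spectrum(grid, x * prof_a + (1 - x) * prof_b))
  list(cal = calibration_set(xs, spectra), xs = xs,
       grid = grid, prof_a = prof_a, prof_b = prof_b)
}

# Avrami-generated drift data, optionally noisy
avrami_dataset <- function(x_az = 76.7, x0s = c(45, 60, 90),
                           ks = c(4, 6, 3), ns = c(1.2, 0.9, 1.1),
                           n_pts = 12, m_max = 0.92, sigma = 0, seed = NULL) {
  make <- function() {
    do.call(rbind, lapply(seq_along(x0s), function(i) {
      m <- seq(0, m_max, length.out = n_pts)
      x <- avrami_drift(m, x0s[i], x_az, ks[i], ns[i])
      if (sigma > 0) x <- x + rnorm(n_pts, 0, sigma)
      data.frame(trajectory = i, m = m, x_molpct = x)
    }))
  }
  obs <- if (is.null(seed)) make() else azeoblend:::with_seed(seed, make())
  drift_dataset(obs, min_x0 = 40)
}
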
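#' Generator configuration for the synthetic study
#'
#' Defaults mirror the emulated study design: 14 oven-evaporation mixtures
#' of 13.5 mL at 50 deg C with 10 uL FTIR aliquots, a 24-mixture
#' calibration set on the 600--4000 cm\eqn{^{-1}} grid at 2 cm\eqn{^{-1}}
#' resolution, and hourly cup-on-arm assays of 20 mosquitoes per cup for 6 h
#' on 4 subjects. Noise levels are the generator's declared measurement
#' model: 0.002 absorbance units of i.i.d. spectral noise, 0.5 mol% of
#' composition noise, and plain binomial probing counts (beta-binomial
#' overdispersion available via `overdispersion > 0`).
#'
#' @param seed integer seed for all generator randomness.
#' @param spectral_sd spectral noise s.d. (absorbance units).
#' @param composition_sd composition noise s.d. (mol%).
#' @param overdispersion beta-binomial intra-cup correlation in `[0, 1)`;
#'   0 gives plain binomial counts.
#' @param p_bite baseline probability that a mosquito probes an untreated
#'   arm during one 3-min exposure.
#' @param n_oven,oven_x0 number and initial compositions (mole fraction
#'   IR3535) of the oven mixtures; default an even spread over 5--95 mol%.
#' @param oven_volume_mL initial liquid volume per dish.
#' @param aliquot_volume_uL aliquot withdrawn per sampling event.
#' @param rate_constant open-evaporation mass-transfer coefficient,
#'   mol/(Pa h).
#' @param t_end_h oven run length in hours (default 720, about one month).
#' @param n_samples number of sampling events per dish.
#' @param n_calibration,calibration_x calibration-set size and
#'   compositions.
#' @param resolution,wn_range spectral grid: resolution and range in
#'   cm\eqn{^{-1}}.
#' @param n_mosquitoes mosquitoes per cup.
#' @param assay_times_h assay time points (h post-application).
#' @param n_subjects number of volunteers.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 42,
                             spectral_sd = 0.002,
                             composition_sd = 0.5,
                             overdispersion = 0,
                             p_bite = 0.8,
                             n_oven = 14,
                             oven_x0 = seq(0.05, 0.95, length.out = n_oven),
                             oven_volume_mL = 13.5,
                             aliquot_volume_uL = 10,
                             rate_constant = 8e-5,
                             t_end_h = 720,
                             n_samples = 16,
                             n_calibration = 24,
                             calibration_x = seq(0, 1, length.out = n_calibration),
                             resolution = 2,
                             wn_range = c(600, 4000),
                             n_mosquitoes = 20,
                             assay_times_h = 1:6,
                             n_subjects = 4) {
  stopifnot(n_oven > 0, n_calibration >= 2, n_mosquitoes > 0,
            length(oven_x0) == n_oven, length(calibration_x) == n_calibration,
            spectral_sd >= 0, composition_sd >= 0,
            overdispersion >= 0, overdispersion < 1,
            p_bite > 0, p_bite <= 1, rate_constant > 0, t_end_h > 0,
            n_samples >= 2, n_subjects > 0)
  structure(as.list(environment()), class = "generator_config")
}

#' Reference binary system: IR3535 / nonanoic acid at 50 deg C
#'
#' The shipped phenomenological fixture. No measured vapour pressures or
#' activity data exist for this system, so the Antoine constants are set to
#' give the pure-component volatility ordering (acid faster than IR3535)
#' and the order-4 Redlich-Kister coefficients are calibrated so the
#' activity-ratio crossings -- the azeotropes -- fall at 10 and 77 mol%
#' IR3535 at 323.15 K, with the 77 mol% root at the bubble-pressure
#' minimum. The constants live in the package config file
#' `extdata/ir3535_nonanoic_50C.yaml` consumed by all downstream modules.
#'
#' @return an [binary_vle()] object (component A = IR3535).
#' @examples
#' find_azeotropes(make_reference_vle())
#' @export
make_reference_vle <- function() {
  path <- system.file("extdata", "ir3535_nonanoic_50C.yaml",
                      package = "azeoblend", mustWork = TRUE)
  vle_from_config(read_run_config(path))
}

#' Association (speciation) model for the blend's hydrogen bonding
#'
#' Two mass-action equilibria on the mole-fraction scale:
#' `2 acid <-> dimer` (constant `K_dimer`) and
#' `acid + IR3535 <-> 1:1 complex` (constant `K_complex`). The defaults
#' (50, 200) make the dimer and the acid-amide complex dominate over acid
#' monomers at low acid fractions, the regime that suppresses the blend's
#' volatility.
#'
#' @param K_dimer,K_complex non-negative equilibrium constants.
#' @return an object of class `speciation_model`.
#' @export
speciation_model <- function(K_dimer = 50, K_complex = 200) {
  if (K_dimer < 0 || K_complex < 0) stop_domain("equilibrium constants must be >= 0")
  structure(list(K_dimer = K_dimer, K_complex = K_complex),
            class = "speciation_model")
}

#' Solve the association equilibria for the species distribution
#'
#' Given total (analytical) mole fractions of acid and IR3535 summing to 1,
#' solves the two mass-action balances for the acid monomer, acid dimer,
#' free IR3535 and 1:1 complex amounts (per total formal mole). Mole
#' balances close to 1e-10: `monomer + 2 dimer + complex = total acid` and
#' `free + complex = total IR3535`.
#'
#' @param x_acid_total,x_ir_total formal mole fractions, summing to 1.
#' @param model a [speciation_model()].
#' @return named numeric vector `c(acid_monomer, acid_dimer, ir_free,
#'   complex)`.
#' @export
solve_speciation <- function(x_acid_total, x_ir_total,
                             model = speciation_model()) {
  if (abs(x_acid_total + x_ir_total - 1) > 1e-9)
    stop_domain("totals must sum to 1")
  if (x_acid_total < 0 || x_ir_total < 0) stop_domain("totals must be non-negative")
  kd <- model$K_dimer; kc <- model$K_complex
  if (x_acid_total == 0) {
    return(c(acid_monomer = 0, acid_dimer = 0, ir_free = x_ir_total, complex = 0))
  }
  fn <- function(m) m + 2 * kd * m^2 + kc * m * x_ir_total / (1 + kc * m) -
    x_acid_total
  m <- uniroot(fn, c(0, x_acid_total), tol = 1e-16)$root
  # one Newton polish for a residual at machine precision
  eps <- 1e-8 * max(m, 1e-12)
  dfn <- (fn(m + eps) - fn(m - eps)) / (2 * eps)
  if (is.finite(dfn) && dfn > 0) m <- m - fn(m) / dfn
  f <- x_ir_total / (1 + kc * m)
  cplx <- kc * m * f
  d <- kd * m^2
  res <- max(abs(m + 2 * d + cplx - x_acid_total), abs(f + cplx - x_ir_total))
  if (res > 1e-10) stop("speciation solver failed: residual ", signif(res, 3))
  c(acid_monomer = m, acid_dimer = d, ir_free = f, complex = cplx)
}

#' Band library for the synthetic FTIR generator
#'
#' Each entry pairs a pseudo-Voigt [band()] with the species amount that
#' drives its amplitude: the ester carbonyl (1735 cm\eqn{^{-1}}) follows
#' total IR3535, the free-amide carbonyl (1638 cm\eqn{^{-1}}) only the
#' uncomplexed IR3535, the acid carbonyl (1705 cm\eqn{^{-1}}) all monomeric
#' plus dimeric acid carbonyls, the acid-amide complex carbonyl appears at
#' 1608 cm\eqn{^{-1}}, and the 932 cm\eqn{^{-1}} band is unique to the
#' cyclic acid dimer. Backbone C-H/C-O bands scale with the formal
#' fractions.
#'
#' @return a list of entries, each `list(band =, driver =)` where `driver`
#'   is one of `"ir_total"`, `"ir_free"`, `"acid_total"`,
#'   `"acid_carbonyl"`, `"complex"`, `"dimer"`.
#' @export
band_library <- function() {
  list(
    list(band = band(1735, 12, 1.00, 0.1, "ester C=O (IR3535)"), driver = "ir_total"),
    list(band = band(1638, 13, 0.90, 0.1, "amide C=O, free (IR3535)"), driver = "ir_free"),
    list(band = band(1705, 13, 1.10, 0.1, "acid C=O, monomer+dimer"), driver = "acid_carbonyl"),
    list(band = band(1608, 16, 0.95, 0.2, "acid C=O H-bonded to amide"), driver = "complex"),
    list(band = band(932, 14, 0.40, 0.4, "acid dimer OH out-of-plane"), driver = "dimer"),
    list(band = band(2958, 60, 0.55, 0.3, "C-H stretch (IR3535)"), driver = "ir_total"),
    list(band = band(1210, 30, 0.45, 0.5, "C-N / C-O skeletal (IR3535)"), driver = "ir_total"),
    list(band = band(1450, 24, 0.30, 0.5, "CH2 bend (IR3535)"), driver = "ir_total"),
    list(band = band(2928, 70, 0.65, 0.3, "C-H stretch (acid)"), driver = "acid_total"),
    list(band = band(2674, 140, 0.18, 0.4, "O-H (acid, bonded)"), driver = "acid_total"),
    list(band = band(1285, 28, 0.40, 0.5, "C-O stretch (acid)"), driver = "acid_total"),
    list(band = band(1465, 22, 0.25, 0.5, "CH2 bend (acid)"), driver = "acid_total"))
}

species_drivers <- function(x_ir, model) {
  sp <- solve_speciation(1 - x_ir, x_ir, model)
  c(ir_total = x_ir,
    acid_total = 1 - x_ir,
    ir_free = unname(sp["ir_free"]),
    acid_carbonyl = unname(sp["acid_monomer"] + 2 * sp["acid_dimer"]),
    complex = unname(sp["complex"]),
    dimer = unname(2 * sp["acid_dimer"]))
}

#' Generate a synthetic mixture FTIR spectrum
#'
#' Absorbance is the sum of species-amount-weighted pseudo-Voigt bands,
#' with the species amounts from [solve_speciation()], plus optional i.i.d.
#' Gaussian noise. The composition-dependent interaction bands emerge from
#' the mass-action chemistry rather than ad-hoc scaling, so the mixing
#' residual of a generated mixture is positive at 1608 cm\eqn{^{-1}} and
#' negative at 1705 and 1638 cm\eqn{^{-1}} whenever complexation is on.
#'
#' @param x_ir formal mole fraction of IR3535 in `[0, 1]`.
#' @param model a [speciation_model()].
#' @param bands a [band_library()]-shaped list.
#' @param noise_sd Gaussian noise s.d. (absorbance units).
#' @param seed integer seed (required when `noise_sd > 0`); the call is a
#'   pure function of `(arguments, seed)`.
#' @param resolution grid resolution in cm\eqn{^{-1}}.
#' @param wn_range grid range in cm\eqn{^{-1}}.
#' @return an `ir_spectrum`.
#' @export
gen_mixture_spectrum <- function(x_ir, model = speciation_model(),
                                 bands = band_library(), noise_sd = 0,
                                 seed = NULL, resolution = 2,
                                 wn_range = c(600, 4000)) {
  if (x_ir < 0 || x_ir > 1) stop_domain("x_ir must lie in [0, 1]")
  grid <- seq(wn_range[1], wn_range[2], by = resolution)
  drv <- species_drivers(x_ir, model)
  weights <- vapply(bands, function(b) drv[[b$driver]], numeric(1))
  spec <- bands_to_spectrum(lapply(bands, `[[`, "band"), grid, weights)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    spec$absorbance <- spec$absorbance +
      with_seed(seed, rnorm(length(grid), 0, noise_sd))
  }
  spec
}

#' Generate the 24-mixture synthetic calibration set
#'
#' @param config a [generator_config()].
#' @param model a [speciation_model()].
#' @param bands a band library.
#' @return a list with `cal` (an [calibration_set()]) and
#'   `compositions` (the true mole fractions).
#' @export
gen_calibration_set <- function(config = generator_config(),
                                model = speciation_model(),
                                bands = band_library()) {
  xs <- config$calibration_x
  spectra <- lapply(seq_along(xs), function(i)
    gen_mixture_spectrum(xs[i], model, bands,
                         noise_sd = config$spectral_sd,
                         seed = config$seed + 1000L + i,
                         resolution = config$resolution,
                         wn_range = config$wn_range))
  list(cal = calibration_set(xs, spectra), compositions = xs)
}

mixture_density_g_mL <- function(vle, x) {
  va <- vle$component_a$molar_volume
  vb <- vle$component_b$molar_volume
  (x * vle$component_a$molar_mass + (1 - x) * vle$component_b$molar_mass) /
    (x * va + (1 - x) * vb)
}

#' Generate a synthetic oven-evaporation experiment
#'
#' Simulates open evaporation for each configured initial composition,
#' samples each dish at the configured schedule, and emits (i) the
#' composition-drift observations with composition noise, (ii) a synthetic
#' FTIR spectrum per sampling event, and (iii) a mass log with 10-uL
#' aliquot bookkeeping (gross mass is the simulated mass minus the
#' aliquots already withdrawn).
#'
#' @param config a [generator_config()].
#' @param vle the binary system (default the reference fixture).
#' @param model,bands speciation model and band library for the spectra.
#' @param spectra whether to generate the per-sample spectra (they are the
#'   bulkiest output; disable for drift-only studies).
#' @return a list with elements `drift` (a [drift_dataset()]),
#'   `mass_logs` (list of data frames `time_h`, `gross_mass_g`,
#'   `aliquot_mass_g`), `spectra` (list of lists of `ir_spectrum`, or
#'   NULL), `trajectories` (the noise-free `azeo_trajectory` objects) and
#'   `sample_times_h`.
#' @export
gen_oven_experiment <- function(config = generator_config(),
                                vle = make_reference_vle(),
                                model = speciation_model(),
                                bands = band_library(),
                                spectra = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  tsamp <- seq(0, config$t_end_h, length.out = config$n_samples)
  aliquot_mL <- config$aliquot_volume_uL / 1000

  trajectories <- vector("list", config$n_oven)
  obs <- vector("list", config$n_oven)
  mass_logs <- vector("list", config$n_oven)
  spec_out <- if (spectra) vector("list", config$n_oven) else NULL

  comp_noise <- with_seed(config$seed,
    matrix(rnorm(config$n_oven * config$n_samples, 0, config$composition_sd),
           config$n_oven, config$n_samples))

  for (i in seq_len(config$n_oven)) {
    x0 <- config$oven_x0[i]
    vm <- x0 * vle$component_a$molar_volume +
      (1 - x0) * vle$component_b$molar_volume
    n0 <- config$oven_volume_mL / vm
    traj <- simulate_open_evaporation(vle, x0, n0, config$rate_constant,
                                      config$t_end_h,
                                      n_out = 20 * config$n_samples)
    trajectories[[i]] <- traj
    # state at the sampling times (trajectory may stop early at exhaustion)
    tt <- pmin(tsamp, max(traj$time_h))
    xs <- approx(traj$time_h, traj$x_a, xout = tt, ties = "ordered")$y
    ms <- approx(traj$time_h, traj$mass_g, xout = tt, ties = "ordered")$y
    rel <- 1 - ms / ms[1]
    x_meas <- pmin(pmax(100 * xs + comp_noise[i, ], 0), 100)
    obs[[i]] <- data.frame(trajectory = i, m = pmin(rel, 1 - 1e-9),
                           x_molpct = x_meas)
    aliquots <- aliquot_mL * mixture_density_g_mL(vle, xs)
    taken_before <- c(0, cumsum(aliquots)[-length(aliquots)])
    mass_logs[[i]] <- data.frame(time_h = tt,
                                 gross_mass_g = ms - taken_before,
                                 aliquot_mass_g = aliquots)
    if (spectra) {
      spec_out[[i]] <- lapply(seq_along(tt), function(j)
        gen_mixture_spectrum(x_meas[j] / 100, model, bands,
                             noise_sd = config$spectral_sd,
                             seed = config$seed + 10000L + 100L * i + j,
                             resolution = config$resolution,
                             wn_range = config$wn_range))
    }
  }
  list(drift = drift_dataset(do.call(rbind, obs)),
       mass_logs = mass_logs, spectra = spec_out,
       trajectories = trajectories, sample_times_h = tsamp)
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Generate synthetic cup-on-arm probing counts
#'
#' Control probes are Binomial(`n_mosquitoes`, `p_bite`); treated probes
#' are Binomial(`n_mosquitoes`, `p_bite * (1 - P(t))`) with `P(t)` the
#' sigmoid protection truth. One cup per subject per hourly time point.
#'
#' @param truth list or named vector with `p_max`, `t50`, `s` (hours).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param treatment label recorded in the output.
#' @return a data frame with columns `time_h`, `treated_probes`,
#'   `control_probes`, `subject`, `treatment`.
#' @export
gen_assay_counts <- function(truth, config = generator_config(), seed = 1,
                             treatment = "blend") {
  truth <- as.list(truth)
  p_t <- sigmoid_protection(config$assay_times_h, truth$p_max, truth$t50, truth$s)
  with_seed(seed, {
    out <- expand.grid(time_h = config$assay_times_h,
                       subject = seq_len(config$n_subjects))
    out <- out[order(out$subject, out$time_h), ]
    pvec <- rep(p_t, config$n_subjects)
    out$control_probes <- rbetabinom(nrow(out), config$n_mosquitoes,
                                     config$p_bite, config$overdispersion)
    out$treated_probes <- rbetabinom(nrow(out), config$n_mosquitoes,
                                     config$p_bite * (1 - pvec),
                                     config$overdispersion)
    out$treatment <- treatment
    rownames(out) <- NULL
    out[, c("time_h", "treated_probes", "control_probes", "subject", "treatment")]
  })
}
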
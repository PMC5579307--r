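test_that("the reference system carries the double-azeotrope signature", {
  vle <- make_reference_vle()
  az <- find_azeotropes(vle)
  expect_identical(nrow(az), 2L)
  expect_identical(az$sign, c("positive", "negative"))
  expect_identical(az$stability, c("repeller", "attractor"))
  # the negative azeotrope is the least volatile composition of all
  p_az <- az$pressure[az$sign == "negative"]
  expect_lt(p_az, vle$p_a_sat)
  expect_lt(p_az, vle$p_b_sat)
  expect_equal(p_az, min(bubble_pressure(vle, seq(0.001, 0.999, 1e-3))),
               tolerance = 1e-6)
})

test_that("speciation balances close and reduce to their closed forms", {
  # no association: everything monomeric
  sp <- solve_speciation(0.4, 0.6, speciation_model(0, 0))
  expect_equal(unname(sp), c(0.4, 0, 0.6, 0))

  # dimer-only: quadratic closed form 2*Kd*m^2 + m - x_acid = 0
  kd <- 50
  for (xa in c(0.2, 0.5, 0.9)) {
    sp <- solve_speciation(xa, 1 - xa, speciation_model(kd, 0))
    m_exact <- (-1 + sqrt(1 + 8 * kd * xa)) / (4 * kd)
    expect_equal(sp[["acid_monomer"]], m_exact, tolerance = 1e-10)
  }

  # conservation at default constants over a grid
  for (xa in seq(0.05, 0.95, by = 0.1)) {
    sp <- solve_speciation(xa, 1 - xa)
    expect_lt(abs(sp[["acid_monomer"]] + 2 * sp[["acid_dimer"]] +
                  sp[["complex"]] - xa), 1e-10)
    expect_lt(abs(sp[["ir_free"]] + sp[["complex"]] - (1 - xa)), 1e-10)
  }
  expect_error(solve_speciation(0.5, 0.6), "sum to 1")
})

test_that("generated spectra reproduce the interaction signature", {
  # pure IR3535: carbonyl peaks at 1735 and 1638
  pure_ir <- gen_mixture_spectrum(1)
  peak_near <- function(s, w) {
    i <- which.min(abs(s$wavenumbers - w))
    a <- s$absorbance
    a[i] > a[i - 5] && a[i] > a[i + 5] && a[i] > 0.1
  }
  expect_true(peak_near(pure_ir, 1735))
  expect_true(peak_near(pure_ir, 1638))
  expect_false(peak_near(pure_ir, 1705))

  # mixing residual: positive at the complex band, negative where the
  # engaged acid and amide carbonyls deplete
  mix <- gen_mixture_spectrum(0.5)
  pure_b <- gen_mixture_spectrum(0)
  res <- mixing_residual(mix, pure_ir, pure_b, 0.5)
  at <- function(w) res$absorbance[which.min(abs(res$wavenumbers - w))]
  expect_gt(at(1608), 0.05)
  expect_lt(at(1705), -0.05)
  expect_lt(at(1638), -0.05)

  # determinism: same seed gives a bit-identical spectrum
  s1 <- gen_mixture_spectrum(0.5, noise_sd = 0.002, seed = 77)
  s2 <- gen_mixture_spectrum(0.5, noise_sd = 0.002, seed = 77)
  expect_identical(s1$absorbance, s2$absorbance)
  s3 <- gen_mixture_spectrum(0.5, noise_sd = 0.002, seed = 78)
  expect_false(identical(s1$absorbance, s3$absorbance))
})

test_that("relative band intensities show dimer saturation in the dilute-acid regime", {
  rel <- vapply(c(0.5, 0.4, 0.3), function(xa) {
    s <- gen_mixture_spectrum(1 - xa)
    c(dimer = relative_absorbance(band_intensity(s, c(905, 958)), xa),
      acid = relative_absorbance(band_intensity(s, c(1688, 1717)), xa))
  }, numeric(2))
  # both decrease as acid is depleted ...
  expect_true(all(diff(rel["dimer", ]) < 0))
  expect_true(all(diff(rel["acid", ]) < 0))
  # ... but the dimer band levels off while the all-acid-carbonyl band
  # keeps falling: its final-step change is much larger than the dimer's
  expect_gt(abs(diff(rel["acid", 2:3])), 3 * abs(diff(rel["dimer", 2:3])))
})

test_that("the oven experiment emits consistent drift, spectra and mass logs", {
  cfg <- generator_config(seed = 12, t_end_h = 240, n_samples = 6)
  out <- gen_oven_experiment(cfg, spectra = TRUE)
  expect_identical(length(out$trajectories), 14L)
  expect_identical(length(unique(out$drift$observations$trajectory)), 14L)
  # aliquot bookkeeping: every mass log passes the correction with a
  # non-decreasing evaporative loss
  for (log in out$mass_logs) {
    loss <- correct_sampling_losses(log)$evaporative_loss_g
    expect_true(all(diff(loss) >= -1e-9))
  }
  expect_identical(length(out$spectra[[1]]), 6L)
  # reproducibility of the whole experiment
  out2 <- gen_oven_experiment(generator_config(seed = 12, t_end_h = 240,
                                               n_samples = 6), spectra = FALSE)
  expect_equal(out$drift$observations, out2$drift$observations)
})

test_that("drift fitting on noise-free oven output lands close to the attractor", {
  # The Avrami law cannot reach the asymptote at m = 1 while the true
  # drift does, so a small upward extrapolation bias is structural; the
  # estimate must still land within 1 mol% of the 77 mol% attractor.
  cfg <- generator_config(seed = 1, composition_sd = 0)
  out <- gen_oven_experiment(cfg, spectra = FALSE)
  fit <- fit_avrami(out$drift)
  expect_true(fit$converged)
  expect_lt(abs(fit$x_az_molpct - 77), 1)
  expect_true(all(fit$per_trajectory$x0_molpct >= 40))
})

test_that("assay counts follow the protection truth and the seed", {
  cfg <- generator_config(seed = 5)
  # full protection: no mosquito probes the treated arm
  full <- gen_assay_counts(list(p_max = 1, t50 = 1e6, s = 1), cfg, seed = 2)
  expect_true(all(full$treated_probes == 0))
  expect_identical(nrow(full), 24L)   # 6 hourly times x 4 subjects

  # determinism
  a1 <- gen_assay_counts(list(p_max = 0.95, t50 = 4, s = 0.5), cfg, seed = 3)
  a2 <- gen_assay_counts(list(p_max = 0.95, t50 = 4, s = 0.5), cfg, seed = 3)
  expect_identical(a1, a2)

  # zero protection: treated and control counts identically distributed
  pooled_t <- integer(0); pooled_c <- integer(0)
  for (s in 1:500) {
    a <- gen_assay_counts(list(p_max = 1e-9, t50 = 3, s = 0.5),
                          generator_config(seed = 1, n_subjects = 1,
                                           assay_times_h = c(1, 2, 3, 4)),
                          seed = s)
    pooled_t <- c(pooled_t, a$treated_probes)
    pooled_c <- c(pooled_c, a$control_probes)
  }
  tab <- rbind(tabulate(pooled_t + 1, 21), tabulate(pooled_c + 1, 21))
  keep <- colSums(tab) > 10
  expect_gt(suppressWarnings(chisq.test(tab[, keep]))$p.value, 1e-3)
})

test_that("generators never disturb the caller's RNG stream", {
  set.seed(999)
  before <- .Random.seed
  invisible(gen_assay_counts(list(p_max = 0.9, t50 = 4, s = 0.5),
                             generator_config(), seed = 8))
  invisible(gen_mixture_spectrum(0.4, noise_sd = 0.002, seed = 8))
  expect_identical(before, .Random.seed)
})
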
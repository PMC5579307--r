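test_that("the negative azeotrope is a fixed point of open evaporation", {
  vle <- make_reference_vle()
  root <- find_azeotropes(vle)$x_a[2]
  traj <- simulate_open_evaporation(vle, root, n0 = 0.05,
                                    rate_constant = 5e-5, t_end = 300)
  expect_lt(max(abs(traj$x_a - root)), 1e-6)
})

test_that("ideal-binary trajectories obey the Rayleigh closed form", {
  vle <- ideal_vle(p_a = 3, p_b = 1.2)
  alpha <- 3 / 1.2
  traj <- simulate_open_evaporation(vle, 0.35, n0 = 0.05,
                                    rate_constant = 2e-4, t_end = 150)
  keep <- traj$moles_a > 1e-8 & traj$moles_b > 1e-8
  lhs <- log(traj$moles_a[keep] / traj$moles_a[1])
  rhs <- alpha * log(traj$moles_b[keep] / traj$moles_b[1])
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("compositions above the positive azeotrope drift to the attractor, below it to pure B", {
  vle <- make_reference_vle()
  for (x0 in c(0.40, 0.60, 0.90)) {
    traj <- simulate_open_evaporation(vle, x0, n0 = 0.05,
                                      rate_constant = 5e-5, t_end = 2500)
    gap <- abs(traj$x_a - 0.77)
    expect_true(all(diff(gap) < 1e-9))          # monotone approach
    expect_lt(tail(gap, 1), gap[1])
  }
  # below the repeller the liquid drifts toward pure B (x_a -> 0)
  traj <- simulate_open_evaporation(vle, 0.05, n0 = 0.05,
                                    rate_constant = 5e-5, t_end = 2500)
  expect_true(all(diff(traj$x_a) < 1e-9))
})

test_that("trajectory bookkeeping: mass, released fraction, mole monotonicity", {
  vle <- make_reference_vle()
  traj <- simulate_open_evaporation(vle, 0.5, n0 = 0.05,
                                    rate_constant = 5e-5, t_end = 400)
  ma <- vle$component_a$molar_mass; mb <- vle$component_b$molar_mass
  expect_equal(traj$mass_g, traj$moles_a * ma + traj$moles_b * mb)
  expect_equal(traj$released_fraction, 1 - traj$mass_g / traj$mass_g[1])
  expect_true(all(diff(traj$moles_a) <= 0))
  expect_true(all(diff(traj$moles_b) <= 0))
  expect_true(all(diff(traj$released_fraction) >= 0))

  cv <- composition_vs_released(traj)
  expect_true(all(diff(cv$released_fraction) > 0))

  tga <- tga_mass_curve(traj)
  expect_true(all(diff(tga$mass_g) <= 0))
  expect_equal(tga$mass_g[1], 0.05 * (0.5 * ma + 0.5 * mb))

  expect_error(simulate_open_evaporation(vle, 0.5, 0.05, 0, 10), "positive")
  expect_error(simulate_open_evaporation(vle, 1.5, 0.05, 1e-4, 10), "0, 1")
})

test_that("terminal composition is insensitive to integrator tolerance", {
  vle <- make_reference_vle()
  t1 <- simulate_open_evaporation(vle, 0.55, 0.05, 5e-5, 400, rtol = 1e-8)
  t2 <- simulate_open_evaporation(vle, 0.55, 0.05, 5e-5, 400, rtol = 1e-9)
  expect_lt(abs(tail(t1$x_a, 1) - tail(t2$x_a, 1)), 1e-6)
})

test_that("TGA curves reproduce the azeotrope-slowest / dilute-fastest signature", {
  vle <- make_reference_vle()
  n0_for <- function(x0) 10 / (x0 * vle$component_a$molar_mass +
                               (1 - x0) * vle$component_b$molar_mass)
  runs <- lapply(c(az = 0.77, pure_a = 1, pure_b = 0, dilute = 0.10),
                 function(x0) simulate_open_evaporation(vle, x0, n0_for(x0),
                                                        5e-5, 40, n_out = 41))
  m <- lapply(runs, function(tr) tga_mass_curve(tr)$mass_g)
  # equal initial masses; the azeotrope loses mass slowest at all t > 0
  expect_true(all(m$az[-1] > m$pure_a[-1]))
  expect_true(all(m$az[-1] > m$pure_b[-1]))
  # the 10 mol% mixture loses mass fastest early on
  expect_true(all(m$dilute[2:10] < m$pure_a[2:10]))
  expect_true(all(m$dilute[2:10] < m$pure_b[2:10]))
})

test_that("late-time slope of the dilute mixture approaches the pure-acid rate", {
  vle <- make_reference_vle()
  long <- simulate_open_evaporation(vle, 0.10, 0.06, 5e-5, 600, n_out = 601)
  acid <- simulate_open_evaporation(vle, 0, 0.06, 5e-5, 600, n_out = 601)
  slope <- function(tr, i) diff(tr$mass_g[c(i - 5, i)]) / diff(tr$time_h[c(i - 5, i)])
  i <- 400  # late but before exhaustion
  expect_equal(slope(long, i), slope(acid, i), tolerance = 0.15)
})

test_that("aliquot-sampling correction recovers the evaporative loss", {
  # identity with no aliquots
  log0 <- data.frame(time_h = 0:3, gross_mass_g = c(10, 9.7, 9.5, 9.4),
                     aliquot_mass_g = 0)
  out <- correct_sampling_losses(log0)
  expect_equal(out$evaporative_loss_g, 10 - log0$gross_mass_g)

  # hand arithmetic: 10.000 -> 9.500 g with one 0.010 g aliquot
  log1 <- data.frame(time_h = c(0, 24), gross_mass_g = c(10, 9.5),
                     aliquot_mass_g = c(0.010, 0))
  expect_equal(correct_sampling_losses(log1)$evaporative_loss_g, c(0, 0.490))

  # conservation at every row
  log2 <- data.frame(time_h = 0:4,
                     gross_mass_g = c(10, 9.6, 9.2, 8.9, 8.7),
                     aliquot_mass_g = c(0.01, 0.01, 0.01, 0.01, 0))
  out <- correct_sampling_losses(log2)
  removed <- c(0, cumsum(log2$aliquot_mass_g)[-5])
  expect_equal(out$evaporative_loss_g + removed + log2$gross_mass_g,
               rep(10, 5))

  # impossible log: gross mass grows more than the aliquots explain
  bad <- data.frame(time_h = 0:1, gross_mass_g = c(10, 10.5),
                    aliquot_mass_g = c(0, 0))
  expect_error(correct_sampling_losses(bad), "data-integrity")
})
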
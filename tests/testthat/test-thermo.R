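test_that("LEM free energy is linear in denaturant and exact", {
  t1 <- transition_thermo(5.7, 6.3)
  expect_equal(delta_g_at_denaturant(t1, 0), 5.7)
  expect_equal(delta_g_at_denaturant(t1, 5.7 / 6.3), 0)
  expect_equal(delta_g_at_denaturant(transition_thermo(7.8, 3.9), 1.0), 3.9)
  # vectorized and strictly linear
  cc <- seq(0, 3, by = 0.1)
  expect_equal(delta_g_at_denaturant(t1, cc), 5.7 - 6.3 * cc)
})

test_that("equilibrium constant follows K = exp(-dG/RT) with overflow clamp", {
  expect_equal(equilibrium_constant(0, 298.15), 1.0)
  rt <- 1.987204e-3 * 298.15
  expect_equal(equilibrium_constant(5.7, 298.15), exp(-5.7 / rt),
               tolerance = 1e-12)
  # constructed inverse: dG = -RT ln 2 gives K = 2
  expect_equal(equilibrium_constant(-rt * log(2), 298.15), 2.0)
  expect_warning(k <- equilibrium_constant(1000, 298.15), "clamped")
  expect_true(is.finite(k) && k > 0)
})

test_that("transition constructors enforce physical invariants", {
  expect_error(transition_thermo(5, -1), "positive")
  expect_error(transition_thermo(NA, 2))
  expect_error(three_state_params(transition_thermo(5, 6),
                                  transition_thermo(7, 4),
                                  336, 341, 355, temperature = -1),
               "temperature")
  expect_error(midpoint(transition_thermo(5, 0)))
})

test_that("three-state fractions match an independent Boltzmann-weight oracle", {
  p <- pwt_params()
  grid <- seq(0, 3, length.out = 61)
  f <- state_fractions_three_state(p, grid)
  for (i in seq_along(grid)) {
    o <- boltzmann_fractions(5.7, 6.3, 7.8, 3.9, grid[i])
    expect_equal(unlist(f[i, c("f_n", "f_i", "f_u")]),
                 o, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # frozen native-state populations at zero denaturant
  f0 <- state_fractions_three_state(p, 0)
  expect_equal(f0$f_n, 0.99993365, tolerance = 1e-7)
  expect_equal(f0$f_i, 6.635011e-05, tolerance = 1e-5)
  expect_equal(f0$f_u, 1.271748e-10, tolerance = 1e-5)
})

test_that("fractions are normalized and monotone across parameter sets", {
  sets <- list(pwt_params(),
               three_state_params(transition_thermo(4.7, 5.2),
                                  transition_thermo(6.4, 3.0),
                                  336, 341, 355),
               three_state_params(transition_thermo(2, 8),
                                  transition_thermo(10, 2),
                                  330, 345, 350))
  grid <- seq(0, 5, length.out = 201)
  for (p in sets) {
    f <- state_fractions_three_state(p, grid)
    expect_true(all(abs(f$f_n + f$f_i + f$f_u - 1) < 1e-12))
    expect_true(all(diff(f$f_n) <= 1e-12))        # f_n non-increasing
    expect_true(all(diff(f$f_u) >= -1e-12))       # f_u non-decreasing
    # f_i unimodal: signs of its finite differences switch at most once
    s <- sign(diff(f$f_i))
    s <- s[s != 0]
    expect_lte(sum(diff(s) != 0), 1)
  }
})

test_that("two-state model is the K2 -> 0 limit of the three-state model", {
  p2 <- two_state_params(transition_thermo(5.7, 6.3), 336, 355)
  # enormous dG_IU suppresses U via the second transition
  p3 <- three_state_params(transition_thermo(5.7, 6.3),
                           transition_thermo(300, 1e-6),
                           336, 341, 355)
  grid <- seq(0, 3, length.out = 31)
  f2 <- state_fractions_two_state(p2, grid)
  f3 <- state_fractions_three_state(p3, grid)
  expect_equal(f3$f_n, f2$f_n, tolerance = 1e-9)
  expect_equal(f3$f_i, f2$f_u, tolerance = 1e-9)  # I plays U's role
  # symmetric two-state point: dG([D]) = 0 gives 50/50
  fm <- state_fractions_two_state(p2, 5.7 / 6.3)
  expect_equal(fm$f_n, 0.5, tolerance = 1e-12)
  expect_equal(fm$f_u, 0.5, tolerance = 1e-12)
  # frozen: unfolded population at zero denaturant for the total transition
  fu0 <- state_fractions_two_state(
    two_state_params(transition_thermo(13.5, 10.2), 336, 355), 0)$f_u
  expect_equal(fu0, exp(-13.5 / (1.987204e-3 * 298.15)), tolerance = 1e-9)
  expect_equal(fu0, 1.270584e-10, tolerance = 1e-6)
})

test_that("free-energy additivity holds at every concentration", {
  ni <- transition_thermo(5.7, 6.3)
  iu <- transition_thermo(7.8, 3.9)
  nu <- transition_thermo(5.7 + 7.8, 6.3 + 3.9)
  cc <- seq(0, 4, by = 0.05)
  expect_equal(delta_g_at_denaturant(ni, cc) + delta_g_at_denaturant(iu, cc),
               delta_g_at_denaturant(nu, cc))
})

test_that("predicted signal is the population-weighted baseline mixture", {
  p <- pwt_params()
  # degenerate observable: identical baselines give a flat curve
  pflat <- three_state_params(p$ni, p$iu, 340, 340, 340)
  expect_equal(predicted_signal(pflat, seq(0, 3, 0.5)), rep(340, 7))
  # frozen weighted sum at zero denaturant
  expect_equal(predicted_signal(p, 0), 336.000332, tolerance = 1e-8)
  # strong denaturant drives the signal to the unfolded baseline
  expect_equal(predicted_signal(p, 10), 355, tolerance = 1e-9)
  # baseline slopes shift the asymptote
  ps <- three_state_params(p$ni, p$iu, 336, 341, 355,
                           baseline_slope_u = 0.2)
  expect_equal(predicted_signal(ps, 10), 355 + 0.2 * 10, tolerance = 1e-8)
})

test_that("midpoint is dG0/m", {
  expect_equal(midpoint(transition_thermo(5.7, 6.3)), 5.7 / 6.3)
  expect_equal(midpoint(transition_thermo(7.8, 3.9)), 2.0)
  expect_equal(midpoint(transition_thermo(0, 4)), 0)
})
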
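test_that("initial guess locates baselines and midpoints", {
  p <- pwt_params()
  g <- initial_guess(generate_curve(p, noise_sd = 0), "three_state")
  expect_equal(midpoint(g$ni), 5.7 / 6.3, tolerance = 0.3, ignore_attr = TRUE)
  expect_equal(midpoint(g$iu), 2.0, tolerance = 0.3, ignore_attr = TRUE)
  expect_equal(g$baseline_n, 336, tolerance = 1)
  expect_equal(g$baseline_u, 355, tolerance = 1)
  g2 <- initial_guess(generate_curve(simple_two_state(7.5, 5), noise_sd = 0),
                      "two_state")
  expect_equal(midpoint(g2$nu), 1.5, tolerance = 0.3, ignore_attr = TRUE)
  # a flat curve carries no transition to anchor a guess on
  flat <- denaturation_curve(seq(0, 3, length.out = 20), rep(340, 20))
  expect_error(initial_guess(flat), "no resolvable transition")
})

test_that("noiseless fits recover generating parameters within 0.1%", {
  panel <- hcaii_p237_panel()
  truth <- list(HCAII_pwt = c(5.7, 6.3, 7.8, 3.9),
                HCAII_P237T = c(4.7, 5.2, 6.4, 3.0),
                HCAII_P237F = c(5.3, 6.3, 5.3, 2.5))
  for (v in names(truth)) {
    cu <- generate_curve(panel$variants[[v]], noise_sd = 0, sample_id = v)
    fit <- fit_curve(cu)
    expect_true(fit$converged)
    est <- fit$par[c("dg_ni", "m_ni", "dg_iu", "m_iu")]
    expect_equal(unname(est), truth[[v]], tolerance = 1e-3)
    expect_lt(max(abs(fit$residuals)), 1e-6)
    expect_equal(unname(fit$par[c("b_n", "b_i", "b_u")]),
                 c(336, 341, 355), tolerance = 1e-3)
  }
})

test_that("noisy replicate fits are unbiased and their spread matches stderr", {
  p <- pwt_params()
  reps <- 60
  est <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("dg_ni", "m_ni", "dg_iu", "m_iu")))
  se1 <- NULL
  for (r in seq_len(reps)) {
    cu <- generate_curve(p, noise_sd = 0.3, seed = 100 + r)
    fit <- fit_curve(cu)
    est[r, ] <- fit$par[colnames(est)]
    if (r == 1L) se1 <- fit$stderr[colnames(est)]
  }
  mu <- colMeans(est)
  expect_equal(unname(mu["dg_ni"]), 5.7, tolerance = 0.6 / 5.7)
  expect_equal(unname(mu["dg_iu"]), 7.8, tolerance = 0.6 / 7.8)
  # covariance-based stderr is the right order: within 2x the empirical SD
  sds <- apply(est, 2, sd)
  expect_true(all(se1 / sds < 2 & se1 / sds > 0.5))
})

test_that("fitting is invariant to a concentration unit relabeling", {
  p <- pwt_params()
  cu <- generate_curve(p, noise_sd = 0.3, seed = 11)
  fit_m <- fit_curve(cu)
  # same data in mM: m-values scale by 1/1000, dG and curve unchanged
  cu_mm <- denaturation_curve(cu$concs * 1000, cu$signals,
                              signal_kind = cu$signal_kind,
                              sample_id = cu$sample_id)
  start <- fit_m$params
  start_mm <- three_state_params(
    transition_thermo(start$ni$dg0, start$ni$m / 1000),
    transition_thermo(start$iu$dg0, start$iu$m / 1000),
    start$baseline_n, start$baseline_i, start$baseline_u)
  fit_mm <- fit_curve(cu_mm, fit_options(start = start_mm))
  expect_equal(predicted_signal(fit_mm$params, cu$concs * 1000),
               predicted_signal(fit_m$params, cu$concs), tolerance = 1e-6)
  expect_equal(unname(fit_mm$par["m_ni"] * 1000), unname(fit_m$par["m_ni"]),
               tolerance = 1e-3)
})

test_that("bootstrap standard errors are reproducible and plausible", {
  p <- pwt_params()
  cu <- generate_curve(p, noise_sd = 0.3, seed = 21)
  fit_a <- fit_curve(cu, fit_options(n_bootstrap = 40, seed = 7))
  fit_b <- fit_curve(cu, fit_options(n_bootstrap = 40, seed = 7))
  expect_identical(fit_a$stderr, fit_b$stderr)
  cov_fit <- fit_curve(cu)
  ratio <- fit_a$stderr[c("dg_ni", "dg_iu")] /
    cov_fit$stderr[c("dg_ni", "dg_iu")]
  expect_true(all(ratio > 0.25 & ratio < 4))
})

test_that("a three-state fit to two-state data is flagged as degenerate", {
  cu <- generate_curve(simple_two_state(7.5, 5), noise_sd = 0.3, seed = 2)
  fit3 <- suppressWarnings(fit_curve(cu, fit_options("three_state")))
  fr <- state_fractions_three_state(fit3$params, seq(0, 3, 0.1))
  # degeneracy shows as non-convergence, a vanishing intermediate, or an
  # intermediate baseline with uncertainty far beyond the N-to-U span
  degenerate <- !fit3$converged || anyNA(fit3$stderr) ||
    max(fr$f_i) < 0.05 ||
    unname(fit3$stderr["b_i"]) > 5
  expect_true(degenerate)
  # and model selection prefers the parsimonious model on these data
  sel <- suppressWarnings(select_model(cu))
  expect_equal(sel$selection, "two_state")
})

test_that("AICc model selection identifies the generating model", {
  p3 <- pwt_params()
  s3 <- select_model(generate_curve(p3, noise_sd = 0.3, seed = 7))
  expect_equal(s3$selection, "three_state")
  expect_false(s3$ambiguous)
  s2 <- suppressWarnings(
    select_model(generate_curve(simple_two_state(7.5, 5),
                                noise_sd = 0.3, seed = 7)))
  expect_equal(s2$selection, "two_state")
  # deterministic given the seed
  s3b <- select_model(generate_curve(p3, noise_sd = 0.3, seed = 7))
  expect_identical(s3$selection, s3b$selection)
  expect_equal(s3$delta_aic, s3b$delta_aic)
})

test_that("underdetermined curves are rejected before fitting", {
  cu <- denaturation_curve(seq(0, 3, length.out = 8),
                           c(336, 336.2, 338, 342, 346, 352, 354.8, 355))
  expect_error(fit_curve(cu, fit_options("three_state")), "points")
})
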
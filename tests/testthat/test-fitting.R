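# Regression procedures: self-consistency on closed forms, closed-form
# oracles on mechanistic simulations, degenerate-input handling.

test_that("progress-curve fit recovers closed-form parameters exactly", {
  cv <- synth_progress(vs = 1, vi = 3, kobs = 0.01, d = 5)
  fit <- fit_progress_curve(cv)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["vs"]], 1, tolerance = 1e-6)
  expect_equal(fit$estimates[["vi"]], 3, tolerance = 1e-6)
  expect_equal(fit$estimates[["kobs"]], 0.01, tolerance = 1e-6)
  expect_equal(fit$estimates[["d"]], 5, tolerance = 1e-4)
})

test_that("a linear (uninhibited) curve is flagged kobs-unidentifiable", {
  t <- seq(0, 2400, 10)
  cv <- progress_curve(0, t, 2 + 0.25 * t)
  fit <- fit_progress_curve(cv)
  expect_true("kobs_unidentifiable" %in% fit$flags)
})

test_that("kobs from simulated slow-binding curves matches the linear law within 2%", {
  cond <- assay_conditions()
  curves <- slow_curves()
  kon_app <- 527e3 / CP_FACTOR
  koff <- 0.91e-9 * 527e3
  for (cv in curves) {
    if (cv$inhibitor_nM == 0) next
    fit <- fit_progress_curve(cv)
    pred <- kobs_from_inhibitor(cv$inhibitor_nM * 1e-9, kon_app, koff)
    expect_equal(fit$estimates[["kobs"]], pred, tolerance = 0.02)
  }
})

test_that("kobs-vs-[I] linear fit recovers slope and intercept", {
  # exact points on a line
  tab <- data.frame(inhibitor_nM = c(5, 10, 20, 40),
                    kobs = 0.48e-3 + 245.18e3 * c(5, 10, 20, 40) * 1e-9)
  fit <- fit_kobs_linear(tab)
  expect_equal(fit$estimates[["kon_app"]], 245.18e3, tolerance = 1e-9)
  expect_equal(fit$estimates[["koff"]], 0.48e-3, tolerance = 1e-9)
  # two points: exact interpolation, no residual dof
  fit2 <- fit_kobs_linear(tab[1:2, ])
  expect_true("no_residual_dof" %in% fit2$flags)
  expect_true(all(is.na(fit2$se)))
  # negative intercept is physically impossible and warned about
  tab$kobs <- tab$kobs - 1e-3
  expect_warning(fit3 <- fit_kobs_linear(tab), "negative")
  expect_true("negative_koff" %in% fit3$flags)
})

test_that("kobs secondary fit on the ODE pipeline recovers kon_app within 2%", {
  curves <- slow_curves()
  inh <- Filter(function(cv) cv$inhibitor_nM > 0, curves)
  tab <- data.frame(
    inhibitor_nM = vapply(inh, function(cv) cv$inhibitor_nM, 0),
    kobs = vapply(inh, function(cv)
      fit_progress_curve(cv)$estimates[["kobs"]], 0))
  fit <- fit_kobs_linear(tab)
  expect_equal(fit$estimates[["kon_app"]], 527e3 / CP_FACTOR,
               tolerance = 0.02)
})

test_that("dose-response fit is self-consistent and flags degenerate input", {
  I <- c(0.5, 1, 2, 4, 8, 16)
  tab <- data.frame(inhibitor_nM = I, fraction = steady_state_fraction(I, 2))
  fit <- fit_dose_response(tab)
  expect_equal(fit$estimates[["ki_app_nM"]], 2, tolerance = 1e-6)
  # a single half-inhibition point determines Ki' = [I]
  one <- data.frame(inhibitor_nM = 3, fraction = 0.5)
  expect_equal(fit_dose_response(one)$estimates[["ki_app_nM"]], 3,
               tolerance = 1e-6)
  flat <- data.frame(inhibitor_nM = I, fraction = rep(0.97, 6))
  expect_true("unidentifiable" %in% fit_dose_response(flat)$flags)
})

test_that("Morrison fit is self-consistent in the tight-binding regime", {
  I <- c(0, 0.05, 0.1, 0.2, 0.42, 0.8, 1.5)
  v <- 2.5 * morrison_fraction(0.42, I, 0.028)
  fit <- fit_morrison(data.frame(inhibitor_nM = I, velocity = v),
                      enzyme_nM = 0.42)
  expect_equal(fit$estimates[["ki_app_nM"]], 0.028, tolerance = 1e-3)
  expect_equal(fit$estimates[["v0"]], 2.5, tolerance = 1e-3)
  expect_error(fit_morrison(data.frame(inhibitor_nM = I, velocity = v),
                            enzyme_nM = 0), "invalid parameter")
  only0 <- data.frame(inhibitor_nM = 0, velocity = 2.5)
  expect_true("unidentifiable" %in%
                fit_morrison(only0, enzyme_nM = 0.42)$flags)
})

test_that("Michaelis-Menten fit recovers Km and flags degenerate data", {
  tab <- simulate_mm_rates(km_uM = 17.4, vmax = 3)
  fit <- fit_michaelis_menten(tab)
  expect_equal(fit$estimates[["km"]], 17.4, tolerance = 1e-3)
  expect_equal(fit$estimates[["vmax"]], 3, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-12)
  # data linear in S (far below Km): the hyperbola is unidentifiable
  S <- c(1, 2, 3, 4, 5, 6)
  lin <- data.frame(substrate_uM = S, rate = 0.01 * S)
  flags <- fit_michaelis_menten(lin)$flags
  expect_true(any(c("km_at_boundary", "non_convergence") %in% flags))
  expect_error(fit_michaelis_menten(data.frame(substrate_uM = c(1, 2, 3),
                                               rate = 1:3)),
               ">= 4 distinct")
})

test_that("titration fit finds the stoichiometric endpoint", {
  tab <- simulate_titration(enzyme_nM = 0.42, titrant_nM = seq(0, 0.6, 0.05))
  fit <- fit_titration(tab)
  expect_equal(fit$estimates[["enzyme_nM"]], 0.42, tolerance = 1e-6)
  flat <- data.frame(titrant_nM = seq(0, 0.6, 0.1), activity = rep(1, 7))
  expect_true("no_decreasing_segment" %in% fit_titration(flat)$flags)
  noisy <- simulate_titration(enzyme_nM = 0.42,
                              titrant_nM = seq(0, 0.56, 0.08),
                              noise_sd = 0.01, seed = 3)
  expect_equal(fit_titration(noisy)$estimates[["enzyme_nM"]], 0.42,
               tolerance = 0.1)
})

test_that("binding-kinetics classification separates the two regimes", {
  expect_equal(classify_progress_kinetics(slow_curves())$label,
               "slow_binding")
  expect_equal(classify_progress_kinetics(tight_curves())$label,
               "fast_binding")
  t <- seq(0, 2400, 10)
  linear <- lapply(c(5, 10, 20), function(iM)
    progress_curve(iM, t, 1 + 0.2 * t))
  expect_equal(classify_progress_kinetics(linear)$label, "fast_binding")
  expect_error(classify_progress_kinetics(linear[1]), ">= 2 inhibited")
})

test_that("estimates are invariant under row reordering", {
  I <- c(0.5, 1, 2, 4, 8)
  tab <- data.frame(inhibitor_nM = I, fraction = steady_state_fraction(I, 2))
  shuf <- tab[c(4, 1, 5, 3, 2), ]
  expect_equal(fit_dose_response(shuf)$estimates,
               fit_dose_response(tab)$estimates)
  ktab <- data.frame(inhibitor_nM = I, kobs = 1e-3 + 2e-4 * I)
  expect_equal(fit_kobs_linear(ktab[5:1, ])$estimates,
               fit_kobs_linear(ktab)$estimates)
})

test_that("bootstrap standard errors are seeded and plausible", {
  I <- c(0.5, 1, 2, 4, 8, 16)
  set.seed(99)
  tab <- data.frame(inhibitor_nM = I,
                    fraction = steady_state_fraction(I, 2) +
                      rnorm(6, 0, 0.01))
  b1 <- fit_dose_response(tab, nboot = 50, seed = 2)
  b2 <- fit_dose_response(tab, nboot = 50, seed = 2)
  expect_equal(b1$se, b2$se)
  expect_gt(b1$se[["ki_app_nM"]], 0)
})
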
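# Direct constructions used as oracles: tables whose mean structure is known
# exactly, independent of the agent simulator.
make_direct_table <- function(n_participants, n_per, mean_fn, noise_sd,
                              seed, intercept_sd = 0.2) {
  set.seed(seed)
  x <- abs(rnorm(n_participants * n_per, 0, 3))
  pid <- rep(sprintf("P%02d", seq_len(n_participants)), each = n_per)
  u <- rep(rnorm(n_participants, 0, intercept_sd), each = n_per)
  data.frame(participant_id = pid, abs_pe = x,
             abs_update = mean_fn(x) + u + rnorm(length(x), 0, noise_sd),
             condition = "fluct_gradual", stringsAsFactors = FALSE)
}

test_that("noise-free linear cohorts refit to the generative composites", {
  fit <- fit_condition_lr_model(zero_linear_tab())
  expect_equal(unname(fit$composite_lr),
               c(0.528, 0.533, 0.595, 0.693), tolerance = 1e-6)
  expect_equal(unname(fit$composite_intercept),
               c(1.017, 1.039, 0.756, 2.548), tolerance = 1e-6)
  expect_equal(fit$engine, "ols")  # variance components unidentifiable
  # interaction coefficient for abrupt trials
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "abs_pe:conditionabruptly_changed"],
               0.165, tolerance = 1e-6)
})

test_that("condition model errors on missing levels or lone participants", {
  tab <- noisy_small_tab()
  only_grad <- tab[tab$block == "gradual" & tab$condition == "fluct_gradual", ]
  expect_error(fit_condition_lr_model(only_grad), "absent")
  one <- tab[tab$participant_id == tab$participant_id[1], ]
  expect_error(fit_condition_lr_model(one), "participants")
})

test_that("quadratic model recovers exact curvature and detects the broken line", {
  # polynomial oracle: noise-free quadratic data is interpolated exactly
  quad <- make_direct_table(4, 50, function(x) 1 + 0.4 * x + 0.032 * x^2,
                            noise_sd = 0, seed = 2, intercept_sd = 0)
  f0 <- fit_quadratic_model(quad)
  expect_equal(f0$beta2, 0.032, tolerance = 1e-8)
  expect_equal(f0$engine, "ols")

  # segmented generative truth bends upward: positive, significant beta2
  up <- update_rule_params("segmented")
  seg_tab <- build_analysis_table(
    simulate_cohort(cohort_spec(n_agents = 20, seed = 8), up))
  fq <- fit_quadratic_model(seg_tab)
  expect_gt(fq$beta2, 0)
  expect_gt(fq$beta2_z, 3)
})

test_that("quadratic detector is null-calibrated under a linear rule", {
  # 100 correctly-specified-null replicates; |z| < 3 should hold in >= 90%
  z <- vapply(1:100, function(r) {
    d <- make_direct_table(15, 120, function(x) 1 + 0.55 * x,
                           noise_sd = 1.5, seed = 1000 + r)
    fit_quadratic_model(d)$beta2_z
  }, numeric(1))
  expect_gte(mean(abs(z) < 3), 0.90)
  expect_lte(mean(abs(z) > qnorm(0.975)), 0.10)
})

test_that("noise-free segmented cohorts recover the breakpoint and increment", {
  fit <- suppressWarnings(fit_segmented_model(zero_segmented_tab()))
  expect_equal(fit$psi, 5.337, tolerance = 1e-3)
  expect_equal(fit$delta, 0.536, tolerance = 1e-4)
  expect_equal(fit$beta0, 0.916, tolerance = 1e-4)
  expect_equal(fit$beta1, 0.536, tolerance = 1e-4)
  # continuity at the knot is structural
  expect_equal(fit$slope_above, fit$beta1 + fit$delta)
  left <- fit$beta0 + fit$beta1 * fit$psi
  right <- fit$beta0 + fit$beta1 * fit$psi + fit$delta * 0
  expect_identical(left, right)
  expect_false(fit$boundary)
})

test_that("fixed-psi profile points equal a plain two-regressor mixed fit", {
  tab <- noisy_small_tab()
  dat <- tab[!is.na(tab$abs_update), c("participant_id", "abs_pe", "abs_update")]
  mine <- fiplearn:::segmented_fixed_psi(dat, psi = 4)
  dat$u4 <- pmax(0, dat$abs_pe - 4)
  oracle <- lme4::lmer(abs_update ~ abs_pe + u4 + (1 | participant_id),
                       data = dat, REML = FALSE)
  expect_equal(mine$logLik, as.numeric(logLik(oracle)), tolerance = 1e-8)
  expect_equal(unname(fiplearn:::tidy_fixef(mine)$estimate),
               unname(lme4::fixef(oracle)), tolerance = 1e-8)
})

test_that("adaptive breakpoint search matches exhaustive fine-grid brute force", {
  up <- update_rule_params("segmented")
  small <- build_analysis_table(
    simulate_cohort(cohort_spec(n_agents = 4, seed = 21), up))
  fit <- suppressWarnings(fit_segmented_model(small))
  dat <- small[!is.na(small$abs_update),
               c("participant_id", "abs_pe", "abs_update")]
  grid <- seq(1, 12, by = 0.05)
  ll <- vapply(grid, function(p) {
    mm <- fiplearn:::segmented_fixed_psi(dat, p)
    if (is.null(mm)) NA_real_ else mm$logLik
  }, numeric(1))
  expect_equal(fit$psi_grid, grid[which.max(ll)], tolerance = 1e-9)
  best <- fiplearn:::segmented_fixed_psi(dat, fit$psi)
  expect_gte(best$logLik, max(ll, na.rm = TRUE) - 1e-8)
})

test_that("a single-slope rule leaves the increment near zero with a wide interval", {
  d <- make_direct_table(10, 150, function(x) 1 + 0.5 * x,
                         noise_sd = 1.2, seed = 5)
  fit <- suppressWarnings(fit_segmented_model(d))
  expect_lt(abs(fit$delta), 0.15)
  expect_gt(fit$psi_ci[2] - fit$psi_ci[1], 1)
})

test_that("participant bootstrap yields an ordered finite breakpoint interval", {
  up <- update_rule_params("segmented")
  small <- build_analysis_table(
    simulate_cohort(cohort_spec(n_agents = 4, seed = 31), up))
  fit <- suppressWarnings(
    fit_segmented_model(small, ci_method = "bootstrap", n_boot = 5,
                        boot_seed = 99))
  expect_true(all(is.finite(fit$psi_ci)))
  expect_lte(fit$psi_ci[1], fit$psi_ci[2])
})

test_that("threshold logistic matches cell log-odds and flags separation", {
  tab <- default_cohort_tabs()[[1]]
  fit <- fit_threshold_logistic(tab, threshold = 5.337)
  # saturated model: intercept is exactly the baseline cell's logit
  p0 <- mean(tab$abs_pe[tab$condition == "fluct_gradual"] > 5.337)
  expect_equal(fit$coefficients$estimate[1], log(p0 / (1 - p0)),
               tolerance = 1e-6)
  abrupt <- fit$coefficients[fit$coefficients$term == "conditionabruptly_changed", ]
  expect_gt(abrupt$estimate, 0)
  expect_gt(abrupt$exp_estimate, 100)
  expect_equal(names(which.max(fit$exceedance_rate)), "abruptly_changed")
  expect_error(fit_threshold_logistic(tab, threshold = 100), "constant")
  expect_error(fit_threshold_logistic(tab, threshold = -2), "positive")

  # a pure cell raises the separation flag
  lev <- fiplearn:::condition_levels()
  pure <- data.frame(participant_id = rep(c("a", "b"), each = 40),
                     condition = rep(lev, 20),
                     abs_pe = ifelse(rep(lev, 20) == "abruptly_changed",
                                     10, runif(80, 0, 4.9)),
                     abs_update = 1)
  fsep <- fit_threshold_logistic(pure, threshold = 5)
  expect_true(fsep$separation)
})

test_that("RT model recovers condition means exactly without noise", {
  fit <- fit_rt_model(zero_linear_tab())
  expect_equal(fit$baseline, 0.883, tolerance = 1e-6)
  expect_equal(unname(fit$offsets["abruptly_changed"]), 1.105 - 0.883,
               tolerance = 1e-6)
  expect_equal(unname(fit$offsets["gradually_changed"]), -0.033,
               tolerance = 1e-6)
  expect_equal(unname(fit$offsets["fluct_abrupt"]), -0.028, tolerance = 1e-6)
})

test_that("RT offsets vanish under label permutation", {
  tab <- noisy_small_tab()
  set.seed(77)
  tab$condition <- sample(as.character(tab$condition))
  fit <- fit_rt_model(tab)
  zs <- fit$coefficients$z[-1]
  expect_true(all(abs(zs) < 4))
})
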
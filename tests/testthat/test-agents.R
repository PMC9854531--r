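test_that("the update mean function matches hand arithmetic and is continuous", {
  lin <- update_rule_params("linear")
  seg <- update_rule_params("segmented")

  # abruptly changed trial with |PE| = 10 under the condition composites
  expect_equal(fiplearn:::update_mean_fn(lin, 10, "abruptly_changed"),
               c(abruptly_changed = 2.548 + 0.693 * 10))
  expect_equal(unname(fiplearn:::update_mean_fn(lin, 10, "abruptly_changed")),
               9.478)

  # broken line at the mean abrupt-trial error
  expect_equal(fiplearn:::update_mean_fn(seg, 10.521, "fluct_gradual"),
               0.916 + 0.536 * 10.521 + 0.536 * (10.521 - 5.337),
               tolerance = 1e-12)
  expect_equal(fiplearn:::update_mean_fn(seg, 10.521, "fluct_gradual"),
               9.334, tolerance = 1e-3)

  # continuity at the knot: both pieces agree at |PE| = psi
  below <- seg$beta0 + seg$beta1 * seg$psi
  above <- seg$beta0 + seg$beta1 * seg$psi + seg$delta * 0
  expect_identical(fiplearn:::update_mean_fn(seg, seg$psi, "fluct_gradual"),
                   below)
  expect_identical(below, above)
})

test_that("parameter constructors validate their invariants", {
  expect_error(update_rule_params(lr_by_condition = c(
    fluct_gradual = 2, gradually_changed = .5, fluct_abrupt = .5,
    abruptly_changed = .5)), "learning rates")
  expect_error(update_rule_params(psi = -1), "psi")
  expect_error(update_rule_params(p_no_update = 1), "p_no_update")
  expect_error(rt_params(p_lapse = -0.1), "p_lapse")
  expect_error(cohort_spec(n_agents = 0), "n_agents")
})

test_that("simulated estimates telescope and stay on the bar", {
  co <- noisy_small_cohort()
  expect_true(all(co$estimate >= 0 & co$estimate <= 50))
  for (key in split(seq_len(nrow(co)), paste(co$participant_id, co$block))) {
    est <- co$estimate[key]
    upd <- co$update[key]
    expect_true(is.na(upd[1]))
    expect_equal(est, est[1] + cumsum(c(0, upd[-1])), tolerance = 1e-9)
  }
  # prediction errors recompute bitwise from stored columns
  expect_identical(co$pe, co$target - co$estimate)
})

test_that("cohort simulation is deterministic and correctly sized", {
  c1 <- simulate_cohort(cohort_spec(n_agents = 1, seed = 9))
  c2 <- simulate_cohort(cohort_spec(n_agents = 1, seed = 9))
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  big <- default_cohort_tabs()[[1]]
  expect_equal(nrow(big), 109 * 200)
  expect_equal(length(unique(big$participant_id)), 109)

  # counterbalancing: half the agents see the abrupt block first
  ord <- unique(big[big$block == "abrupt", c("participant_id", "order")])
  expect_equal(sum(ord$order == 1), 54)  # even-indexed of 109 agents

  co <- noisy_small_cohort()
  expect_true(all(co$response[co$letter == "L"] == "left"))
  expect_true(all(co$response[co$letter == "R"] == "right"))
})

test_that("regime separation and RT lapses emerge under the defaults", {
  tab <- default_cohort_tabs()[[1]]
  m_up <- function(cond) mean(tab$abs_update[tab$condition == cond], na.rm = TRUE)
  m_pe <- function(cond) mean(tab$abs_pe[tab$condition == cond])
  # abrupt changes produce much larger errors and much larger updates than
  # an equivalent total change delivered gradually
  expect_gt(m_pe("abruptly_changed"), 3 * m_pe("gradually_changed"))
  expect_gt(m_up("abruptly_changed"), 3 * m_up("gradually_changed"))
  # updates track the generative composite mean at the observed error level
  lin <- update_rule_params("linear")
  for (cond in c("gradually_changed", "abruptly_changed")) {
    pred <- (1 - lin$p_no_update) *
      mean(fiplearn:::update_mean_fn(lin, tab$abs_pe[tab$condition == cond], cond))
    expect_lt(abs(m_up(cond) - pred) / pred, 0.25)
  }

  # the exponential lapse tail produces latencies beyond the exclusion rule
  expect_gt(sum(tab$rt > 3), 0)
  # independent oracle for the exclusion fraction: lapse prob x P(base +
  # Exp(2) > 3), base ~ N(condition mean + agent effect, 0.3), averaged
  # over the label mix; non-lapse exceedances are negligible
  rp <- rt_params()
  mix <- table(factor(tab$condition, names(rp$mean_by_condition))) / nrow(tab)
  base_sd <- sqrt(rp$rt_noise_sd^2 + rp$participant_rt_sd^2)
  p_exceed <- sum(vapply(names(rp$mean_by_condition), function(cc) {
    mu <- rp$mean_by_condition[[cc]]
    f <- function(b) stats::dnorm(b, mu, base_sd) *
      stats::pexp(3 - b, 1 / rp$lapse_mean, lower.tail = FALSE)
    mix[[cc]] * (rp$p_lapse * stats::integrate(f, -2, 3)$value +
                   stats::pnorm(3, mu, base_sd, lower.tail = FALSE))
  }, numeric(1)))
  obs <- mean(!tab$rt_included)
  expect_lt(abs(obs - p_exceed),
            4 * sqrt(p_exceed * (1 - p_exceed) / nrow(tab)) + 1e-4)
})
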
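test_that("canonical schedules reproduce the two-block design", {
  g <- canonical_schedule("gradual")
  a <- canonical_schedule("abrupt")

  expect_equal(g$total_trials, 100)
  expect_equal(a$total_trials, 100)
  expect_equal(nrow(a$segments), 9)

  # gradual mean path, 10-trial segments after the 20-trial opener
  expect_equal(g$segments$mean, c(25, 30, 35, 30, 25, 20, 15, 20, 25))
  expect_equal(g$segments$n_trials, c(20L, rep(10L, 8)))
  expect_true(all(g$segments$sd == 1.7))
  expect_equal(g$segments$trend[2],  "gradually_increase")

  # abrupt mean path with single-trial jumps
  expect_equal(a$segments$mean, c(25, 35, 35, 25, 25, 15, 15, 25, 25))
  expect_equal(a$segments$n_trials, c(29L, 1L, 19L, 1L, 19L, 1L, 19L, 1L, 10L))
  expect_error(canonical_schedule("sudden"))
})

test_that("trial labels partition the blocks as designed", {
  lg <- label_trials(canonical_schedule("gradual"))
  la <- label_trials(canonical_schedule("abrupt"))

  expect_equal(which(la == "abruptly_changed"), c(30L, 50L, 70L, 90L))
  expect_equal(which(lg == "gradually_changed"),
               c(21:30, 41:50, 61:70, 81:90))
  expect_equal(as.integer(table(lg)[c("fluct_gradual", "gradually_changed")]),
               c(60L, 40L))
  expect_equal(as.integer(table(la)[c("fluct_abrupt", "abruptly_changed")]),
               c(96L, 4L))
  expect_equal(lg[5], "fluct_gradual")
})

test_that("sampled sequences are reproducible, bounded and step-constrained", {
  g <- canonical_schedule("gradual")
  a <- canonical_schedule("abrupt")

  s1 <- sample_targets(g, seed = 5)
  s2 <- sample_targets(g, seed = 5)
  expect_identical(s1$target, s2$target)

  for (s in 1:25) {
    tg <- sample_targets(g, seed = s)$target
    expect_true(all(tg >= 0 & tg <= 50))
    expect_true(all(abs(diff(tg)) <= 6 + 1e-9))
    expect_equal(tg, round(tg, 1))
  }

  # abrupt block: segment means recovered, jump magnitude ~ 10
  gaps <- vapply(1:50, function(s) {
    tg <- sample_targets(a, seed = s)$target
    tg[30] - tg[29]
  }, numeric(1))
  # gap ~ N(10, 1.7 * sqrt(2)); mean over 50 seeds has se ~ 0.34
  expect_lt(abs(mean(gaps) - 10), 1.2)

  mids <- vapply(1:30, function(s)
    mean(sample_targets(a, seed = s)$target[31:49]), numeric(1))
  expect_lt(abs(mean(mids) - 35), 3 * 1.7 / sqrt(19))
})

test_that("segment draws follow the scheduled Gaussians (KS across seeds)", {
  g <- canonical_schedule("gradual")
  pvals <- unlist(lapply(1:100, function(s) {
    raw <- attr(sample_targets(g, seed = s), "raw_draws")
    vapply(seq_along(raw), function(i)
      suppressWarnings(stats::ks.test(raw[[i]], "pnorm",
                                      g$segments$mean[i],
                                      g$segments$sd[i]))$p.value,
      numeric(1))
  }))
  # 900 exact-null tests at alpha 0.01: rejection rate should sit near 1%
  expect_lt(mean(pvals < 0.01), 0.025)
})

test_that("sorted trend realization drifts monotonically; infeasible steps error", {
  g <- canonical_schedule("gradual")
  tg <- sample_targets(g, seed = 3, trend_realization = "sorted")$target
  # rank correlation with trial order within a sorted rising segment
  expect_gt(stats::cor(tg[21:30], 1:10, method = "spearman"), 0.5)
  expect_lt(stats::cor(tg[41:50], 1:10, method = "spearman"), -0.5)

  cliff <- block_schedule("gradual", rbind(
    segment_spec(2, 1, 5, "randomly_fluctuate"),
    segment_spec(48, 1, 5, "randomly_fluctuate")))
  expect_error(sample_targets(cliff, seed = 1, max_step = 1),
               "segment 2")
  expect_error(sample_targets(g, seed = 1, max_step = -1), "max_step")
})
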
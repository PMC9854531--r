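# Shared simulated fixtures, built once per test run and memoised so that
# several test files can reuse the expensive cohorts.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# Noise-free linear-mode cohort: every agent follows the condition-composite
# delta rule exactly, so refits must recover the generative coefficients.
zero_linear_cohort <- function() fixture("zl_cohort", function() {
  zp <- zero_noise_params("linear")
  sp <- do.call(cohort_spec, c(list(n_agents = 6, seed = 11), zp$spec_args))
  simulate_cohort(sp, zp$update, zp$rt)
})
zero_linear_tab <- function() fixture("zl_tab", function() {
  build_analysis_table(zero_linear_cohort())
})

zero_segmented_cohort <- function() fixture("zs_cohort", function() {
  zp <- zero_noise_params("segmented")
  sp <- do.call(cohort_spec, c(list(n_agents = 6, seed = 12), zp$spec_args))
  simulate_cohort(sp, zp$update, zp$rt)
})
zero_segmented_tab <- function() fixture("zs_tab", function() {
  build_analysis_table(zero_segmented_cohort())
})

# Small noisy cohort with all defaults (20 agents keeps mixed fits quick).
noisy_small_cohort <- function() fixture("ns_cohort", function() {
  simulate_cohort(cohort_spec(n_agents = 20, seed = 42))
})
noisy_small_tab <- function() fixture("ns_tab", function() {
  build_analysis_table(noisy_small_cohort())
})

# Full-size default cohorts (109 agents, linear mode) used by the
# descriptive and ordering checks; three replicate seeds.
default_cohort_tabs <- function() fixture("default_tabs", function() {
  lapply(1:3, function(s) {
    build_analysis_table(simulate_cohort(cohort_spec(n_agents = 109, seed = s)))
  })
})
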
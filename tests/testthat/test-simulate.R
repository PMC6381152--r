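test_that("target sampling matches the inside/outside supports and is centred", {
  set.seed(21)
  ins <- sample_target(40, "inside", 1e4)
  expect_true(all(abs(circ_dist(ins, 40)) <= 45))
  out <- sample_target(40, "outside", 1e4)
  expect_true(all(abs(circ_dist(out, 40)) >= 75))
  # Monte-Carlo: empirical circular mean of inside draws ~ schema mean
  big <- sample_target(300, "inside", 1e5)
  expect_lt(abs(circ_dist(circ_mean(big), 300)), 1)
})

test_that("degenerate mixtures produce the expected marginals", {
  set.seed(22)
  # pure guessing: uniform responses (chi-square GOF over 36 bins)
  g <- simulate_mixture_trials(1, 1e4, 0, 0, 1, kappa = 15)
  counts <- table(cut(g$response, seq(0, 360, by = 10)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # pure high-precision target responses: tiny median error
  t <- simulate_mixture_trials(1, 5e3, 1, 0, 0, kappa = 500)
  expect_lt(median(abs_error(t$target, t$response)), 3)
  # pure schema responses sit on the old mean, -90 from the current quadrant
  s <- simulate_mixture_trials(1, 5e3, 0, 1, 0, kappa = 15)
  expect_lt(abs(wrap_signed(circ_mean(s$response) - s$schema_mean_original[1])), 2)
})

test_that("von Mises sampler matches its density", {
  set.seed(23)
  x <- rvonmises(2e4, 120, 8)
  # compare binned frequencies with the package density (coarse bins)
  breaks <- seq(0, 360, by = 15)
  emp <- as.numeric(table(cut(x, breaks))) / length(x) / 15
  mid <- breaks[-1] - 7.5
  expect_lt(max(abs(emp - dvonmises(mid, 120, 8))), 0.0035)
  expect_error(rvonmises(10, 0, -2), "non-negative")
})

test_that("response simulation keys cells strictly and honours weights", {
  cfg <- design_config(n_per_group = 2)
  trials <- build_design(cfg, seed = 3)
  params <- generative_params()
  sim <- simulate_responses(trials, params, seed = 3)
  expect_false(anyNA(sim$response))
  expect_true(all(sim$response >= 0 & sim$response < 360))
  # a missing cell is an error, not a silent default
  expect_error(
    simulate_responses(trials, params[params$phase_class != "FT", ], seed = 3),
    "No generative parameters"
  )
  expect_error(generative_params(p_guess = -0.1), "non-negative")
  # per-participant child streams: a participant's responses do not depend on
  # who else is in the table
  sub <- trials[trials$participant_id == "s001", ]
  sim_sub <- simulate_responses(sub, params, seed = 3)
  expect_identical(sim$response[sim$participant_id == "s001"], sim_sub$response)
  # timeouts become missing responses
  sim_miss <- simulate_responses(sub, params, seed = 3, p_miss = 0.2)
  expect_gt(mean(is.na(sim_miss$response)), 0.1)
})

test_that("simulated group asymmetry matches the configured old-schema weights", {
  # generative defaults put mass 0.49 vs 0.32 on the old schema at Final Test;
  # the -90 error-histogram mass should differ accordingly
  set.seed(24)
  a <- simulate_mixture_trials(16, 56, 0.41, 0.49, 0.10, 15)
  b <- simulate_mixture_trials(16, 56, 0.58, 0.32, 0.10, 15)
  near_old <- function(d) mean(abs(circ_dist(d$response, d$schema_mean_original)) < 30)
  expect_gt(near_old(a), near_old(b) + 0.05)
})
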
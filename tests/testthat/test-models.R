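test_that("model specs encode the component sets and parameter counts", {
  expect_equal(model_spec("M1")$n_free_params, 2L)
  expect_equal(model_spec("M4")$n_free_params, 3L)
  expect_equal(model_spec("M4")$schema_centre, "original")
  expect_equal(model_spec("M5")$schema_centre, "current")
  expect_equal(model_spec("M2")$schema_centre, "current")
  expect_true(is.na(model_spec("M3")$schema_centre))
  expect_error(model_spec("M9"))
})

test_that("trial log-likelihood matches closed forms and nests correctly", {
  tr <- simulate_mixture_trials(2, 50, 0.5, 0.3, 0.2, 10, seed = 31)
  # pure guessing: every trial log(1/360)
  ll <- trial_loglik(tr, "M1", list(p_guess = 1, kappa = 5))
  expect_equal(ll, rep(log(1 / 360), nrow(tr)))
  # pure target responding with response == target
  tr0 <- tr
  tr0$response <- tr0$target
  ll0 <- trial_loglik(tr0, "M1", list(p_guess = 0, kappa = 12))
  expect_equal(ll0, rep(log(dvonmises(0, 0, 12)), nrow(tr)))
  # M4 with zero schema weight equals M3 on identical params
  p <- list(p_guess = 0.2, p_schema = 0, kappa = 8)
  expect_equal(trial_loglik(tr, "M4", p),
               trial_loglik(tr, "M3", list(p_guess = 0.2, kappa = 8)))
  expect_error(trial_loglik(tr, "M1", list(p_guess = 1.4, kappa = 1)), "simplex")
  trNA <- tr; trNA$response[3] <- NA
  expect_error(trial_loglik(trNA, "M1", list(p_guess = 1, kappa = 1)), "missing")
})

test_that("maximum-likelihood fitting recovers generative parameters", {
  tr <- simulate_mixture_trials(64, 56, 0.60, 0.30, 0.10, 15, seed = 32)
  f <- fit_model(tr, "M4", n_starts = 10)
  expect_lt(abs(f$p_target - 0.60), 0.03)
  expect_lt(abs(f$p_schema - 0.30), 0.03)
  expect_lt(abs(f$p_guess - 0.10), 0.03)
  expect_lt(abs(f$kappa - 15) / 15, 0.15)
  expect_equal(f$p_target + f$p_schema + f$p_guess, 1, tolerance = 1e-9)
  expect_equal(unname(information_criteria(f)["aic"]), f$aic)
})

test_that("fitting a schema model to schema-free data drives the extra weight to zero", {
  set.seed(33)
  hits <- replicate(5, {
    tr <- simulate_mixture_trials(10, 200, 0.8, 0, 0.2, 10)
    f <- fit_model(tr, "M4", n_starts = 6)
    f$p_schema < 0.03
  })
  expect_true(all(hits))
})

test_that("the optimizer attains at least the grid-search oracle optimum", {
  tr <- simulate_mixture_trials(4, 50, 0.5, 0.3, 0.2, 12, seed = 34)
  f <- fit_model(tr, "M4", n_starts = 10)
  g <- oracle_grid_fit(tr, "original")
  expect_gte(f$logL, g$logL - 1e-4)
  # and the optimum is where the oracle says, coarsely
  expect_lt(abs(f$p_schema - g$p_schema), 0.03)
  expect_lt(abs(f$p_guess - g$p_guess), 0.03)
})

test_that("EM and direct maximization reach the same optimum", {
  tr <- simulate_mixture_trials(8, 56, 0.45, 0.40, 0.15, 20, seed = 35)
  f1 <- fit_model(tr, "M4", n_starts = 10)
  f2 <- fit_model(tr, "M4", n_starts = 10, engine = "em")
  expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
  expect_equal(f1$p_schema, f2$p_schema, tolerance = 1e-4)
  expect_equal(f1$kappa, f2$kappa, tolerance = 1e-3)
})

test_that("likelihoods are nested and rotation invariant", {
  tr <- simulate_mixture_trials(8, 56, 0.41, 0.49, 0.10, 15, seed = 36)
  f3 <- fit_model(tr, "M3", n_starts = 8)
  f4 <- fit_model(tr, "M4", n_starts = 8)
  expect_gte(f4$logL, f3$logL - 1e-6)
  # rigid rotation of all angles leaves the fit untouched
  rot <- function(d, c) {
    for (col in c("target", "response", "schema_mean_current",
                  "schema_mean_original", "schema_mean_study")) {
      d[[col]] <- wrap_circle(d[[col]] + c)
    }
    d
  }
  f4r <- fit_model(rot(tr, 137), "M4", n_starts = 1,
                   start = list(p_guess = f4$p_guess, p_schema = f4$p_schema,
                                kappa = f4$kappa))
  expect_equal(f4r$logL, f4$logL, tolerance = 1e-6)
  expect_equal(f4r$p_schema, f4$p_schema, tolerance = 1e-4)
})

test_that("degenerate data is flagged instead of silently fit", {
  tr <- simulate_mixture_trials(1, 1, 1, 0, 0, 50, seed = 37)
  tr$response <- tr$target
  expect_warning(f <- fit_model(tr, "M1", n_starts = 4), "degenerate")
  expect_true(f$degenerate)
  expect_lt(f$p_guess, 0.05)
  tr$response <- NA_real_
  expect_error(fit_model(tr, "M1"), "at least one trial")
})

test_that("information criteria follow their closed forms", {
  f <- list(model = model_spec("M1"), logL = -100, n_trials = 50)
  expect_equal(unname(information_criteria(f)),
               c(2 * 2 + 200, 2 * log(50) + 200))
  # one extra parameter at equal likelihood costs exactly ln(n) in BIC
  f2 <- list(model = model_spec("M2"), logL = -100, n_trials = 1000)
  f1 <- list(model = model_spec("M1"), logL = -100, n_trials = 1000)
  d <- information_criteria(f2) - information_criteria(f1)
  expect_equal(unname(d["bic"]), log(1000))
  expect_equal(unname(d["aic"]), 2)
})

test_that("model comparison is additive in the data and oriented towards the winner", {
  tr <- simulate_mixture_trials(8, 56, 0.41, 0.49, 0.10, 15, seed = 38)
  cmp <- compare_models(tr, c("M3", "M4", "M5"), n_starts = 8)
  expect_equal(cmp$preferred, "M4")
  expect_true(all(cmp$table$dAIC >= 0))
  expect_equal(cmp$table$dAIC[cmp$table$model == "M4"], 0)
  # doubling the trial set doubles logL and the AIC gaps; preference unchanged
  tr2 <- dplyr::bind_rows(tr, tr)
  cmp2 <- compare_models(tr2, c("M3", "M4"), n_starts = 8)
  expect_equal(cmp2$preferred, "M4")
  l1 <- cmp$table$logL[cmp$table$model == "M4"]
  l2 <- cmp2$table$logL[cmp2$table$model == "M4"]
  expect_equal(l2, 2 * l1, tolerance = 1e-4)
  # the likelihood part of the AIC gap doubles; the parameter penalty does not
  gap1 <- cmp$table$dAIC[cmp$table$model == "M3"]   # = 2*dlogL - 2
  gap2 <- cmp2$table$dAIC[cmp2$table$model == "M3"] # = 4*dlogL - 2
  expect_equal(gap2, 2 * gap1 + 2, tolerance = 1e-3)
})
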
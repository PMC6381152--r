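make_is_trials <- function(strength_in = 10, strength_out = 30) {
  # two participants, one category, controlled inside/outside errors
  n_in <- 11; n_out <- 3
  tibble::tibble(
    participant_id = rep(c("s1", "s2"), each = n_in + n_out),
    group = "no_consolidation", phase = "IS", block = 1L,
    item_id = sprintf("i%02d", 1:(2 * (n_in + n_out))),
    category = "animals", category_role = "consistent",
    quadrant = rep(c(rep("inside", n_in), rep("outside", n_out)), 2),
    is_critical = FALSE,
    target = rep(c(rep(100, n_in), rep(260, n_out)), 2),
    schema_mean_current = 100, schema_mean_original = 100,
    schema_mean_study = 100,
    response = NA_real_
  )
}

test_that("schema strength is the outside-minus-inside mean absolute error", {
  tr <- make_is_trials()
  tr$response <- ifelse(tr$quadrant == "inside", tr$target + 10, tr$target + 30)
  s <- schema_strength(tr)
  expect_equal(nrow(s), 2)
  expect_equal(s$strength, c(20, 20))
  # identical error distributions inside and outside: zero strength
  tr$response <- tr$target + 15
  expect_equal(schema_strength(tr)$strength, c(0, 0))
  # rotation invariance
  tr$response <- ifelse(tr$quadrant == "inside", tr$target + 5, tr$target + 40)
  s0 <- schema_strength(tr)
  tr_rot <- tr
  for (col in c("target", "response", "schema_mean_current",
                "schema_mean_original", "schema_mean_study")) {
    tr_rot[[col]] <- wrap_circle(tr_rot[[col]] + 201)
  }
  expect_equal(schema_strength(tr_rot)$strength, s0$strength)
  # a missing cell is an error
  expect_error(schema_strength(tr[tr$quadrant == "inside", ]), "lack")
  expect_error(schema_strength(tr[tr$phase == "FT", ]), "IS")
})

test_that("simulated participants show positive schema strength on average", {
  tr <- simulate_experiment(design_config(n_per_group = 16), seed = 61)
  s <- schema_strength(tr)
  expect_gt(mean(s$strength), 0)
  expect_gt(mean(s$strength > 0), 0.7)
})

test_that("the Fisher r-to-z comparison reproduces closed-form behaviour", {
  cc <- compare_independent_correlations(0.5, 40, 0.5, 40)
  expect_equal(cc$z, 0)
  expect_equal(cc$p_two_tailed, 1)
  # antisymmetry in swapping the correlations
  c1 <- compare_independent_correlations(0.6, 30, 0.2, 50)
  c2 <- compare_independent_correlations(0.2, 50, 0.6, 30)
  expect_equal(c1$z, -c2$z)
  expect_equal(c1$p_two_tailed, c2$p_two_tailed)
  expect_error(compare_independent_correlations(1, 30, 0.2, 30), "< 1")
  expect_error(compare_independent_correlations(0.5, 3, 0.2, 30), "n >= 4")
})

test_that("standardized regression returns betas on the right scale", {
  set.seed(62)
  d <- tibble::tibble(x1 = rnorm(40))
  d$y <- 2 * d$x1 + 5
  r <- suppressWarnings(standardized_regression(d, "y", "x1")) # exact fit
  expect_equal(r$coefficients$beta, 1, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  # independent noise: small R2, non-significant F (in expectation; fixed seed)
  d2 <- tibble::tibble(x1 = rnorm(200), x2 = rnorm(200), y = rnorm(200))
  r2 <- standardized_regression(d2, "y", c("x1", "x2"))
  expect_lt(r2$r_squared, 0.08)
  # recovery of known standardized effects
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  beta <- c(0.45, 0.35)
  resid_sd <- sqrt(1 - sum(beta^2))
  y <- beta[1] * x1 + beta[2] * x2 + rnorm(n, sd = resid_sd)
  r3 <- standardized_regression(tibble::tibble(x1 = x1, x2 = x2, y = y),
                                "y", c("x1", "x2"))
  expect_equal(r3$coefficients$beta, beta, tolerance = 0.05)
  expect_error(standardized_regression(d, "y", "nope"), "nope")
})
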
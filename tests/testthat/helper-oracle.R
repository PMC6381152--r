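# Independent oracles used across the suite. These deliberately avoid the
# package's own density / likelihood code paths.

# von Mises density per degree by direct quadrature normalization of the
# exponential-cosine kernel (no Bessel functions)
oracle_dvm <- function(x_deg, mu_deg, kappa, n_grid = 72001) {
  g <- seq(-180, 180, length.out = n_grid)[-n_grid]
  step <- g[2] - g[1]
  kern <- exp(kappa * cos(g * pi / 180))
  norm <- sum(kern) * step
  exp(kappa * cos((x_deg - mu_deg) * pi / 180)) / norm
}

# brute-force grid search MLE for the target/schema/uniform mixture;
# densities computed from scratch (base R besselI only)
oracle_grid_fit <- function(trials, schema_centre = c("original", "none", "current"),
                            weight_step = 0.01,
                            kappas = exp(seq(log(1), log(100), length.out = 50))) {
  schema_centre <- match.arg(schema_centre)
  resp <- trials$response
  wrap <- function(a) ((a + 180) %% 360) - 180
  et <- wrap(resp - trials$target) * pi / 180
  use_schema <- schema_centre != "none"
  es <- if (schema_centre == "original") {
    wrap(resp - trials$schema_mean_original) * pi / 180
  } else if (schema_centre == "current") {
    wrap(resp - trials$schema_mean_current) * pi / 180
  } else rep(0, length(resp))
  best <- list(logL = -Inf)
  pg_grid <- seq(0, 1, by = weight_step)
  for (kappa in kappas) {
    lognorm <- -log(2 * pi) - (log(besselI(kappa, 0, TRUE)) + kappa) + log(pi / 180)
    ft <- exp(kappa * cos(et) + lognorm)
    fs <- if (use_schema) exp(kappa * cos(es) + lognorm) else 0
    for (pg in pg_grid) {
      ps_grid <- if (use_schema) seq(0, 1 - pg, by = weight_step) else 0
      for (ps in ps_grid) {
        ll <- sum(log((1 - pg - ps) * ft + ps * fs + pg / 360))
        if (ll > best$logL) {
          best <- list(p_guess = pg, p_schema = ps, kappa = kappa, logL = ll)
        }
      }
    }
  }
  best
}

# quick generative trial set at explicit weights (wraps the package generator
# with a fixed interface used by many tests)
sim_trials <- function(n_participants, trials_each, p_target, p_schema, p_guess,
                       kappa = 15, group = "no_consolidation", seed = NULL) {
  simulate_mixture_trials(n_participants, trials_each, p_target, p_schema,
                          p_guess, kappa, group = group, seed = seed)
}
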
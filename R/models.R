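#' Specification of the five response-error mixture models
#'
#' All models contain a von Mises component centred on the trial's target and
#' a uniform guessing component, sharing two free parameters (guess
#' probability and concentration kappa). Models 2, 4 and 5 add a third free
#' parameter, the weight of an extra von Mises (same kappa) centred on a
#' schema mean:
#'
#' * `M1` - target + uniform, fit to Final Test critical items of the
#'   consistent category.
#' * `M2` - M1 plus a component on the (current) schema mean, consistent
#'   category.
#' * `M3` - target + uniform, inconsistent category.
#' * `M4` - M3 plus a component on the *original* (old, superseded) schema
#'   mean, inconsistent category.
#' * `M5` - M3 plus a component on the *new* schema mean (the mean in force at
#'   learning), inconsistent category.
#'
#' @param model_id One of `"M1" ... "M5"`.
#' @return A `model_spec` list with fields `model_id`, `components`,
#'   `schema_centre` (`"current"`, `"original"`, or `NA`), `n_free_params`.
#' @export
model_spec <- function(model_id) {
  model_id <- match.arg(model_id, c("M1", "M2", "M3", "M4", "M5"))
  schema_centre <- switch(model_id,
    M1 = NA_character_, M3 = NA_character_,
    M2 = "current", M4 = "original", M5 = "current"
  )
  has_schema <- !is.na(schema_centre)
  structure(
    list(
      model_id = model_id,
      components = if (has_schema) c("target", "schema", "uniform")
                   else c("target", "uniform"),
      schema_centre = schema_centre,
      n_free_params = if (has_schema) 3L else 2L
    ),
    class = "model_spec"
  )
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

# signed circular error in radians between responses and a component centre
err_rad <- function(resp, centre) circ_dist(resp, centre) * pi / 180

# schema-centre angle per trial for a model (NA-free only when has_schema)
schema_centre_angle <- function(model, trials) {
  switch(model$schema_centre,
    original = trials$schema_mean_original,
    current = trials$schema_mean_current,
    rep(0, nrow(trials))
  )
}

check_fit_trials <- function(trials, model) {
  needed <- c("target", "response")
  if (!is.na(model$schema_centre)) {
    needed <- c(needed, if (model$schema_centre == "original")
      "schema_mean_original" else "schema_mean_current")
  }
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    abort(paste0("Trial table lacks column(s): ", paste(missing, collapse = ", ")))
  }
}

#' Per-trial log-likelihood under a mixture model
#'
#' Log of the mixture density (per degree) of each response:
#' `p_target * vM(target) + p_schema * vM(schema centre) + p_guess / 360`,
#' with the schema component centred per the model's centring rule.
#'
#' @param trials Trial table; responses must be present on every row.
#' @param model A [model_spec()] or model id string.
#' @param params List with `p_guess`, `kappa` and (for M2/M4/M5) `p_schema`.
#' @return Numeric vector of per-trial log densities.
#' @export
trial_loglik <- function(trials, model, params) {
  model <- as_model_spec(model)
  check_fit_trials(trials, model)
  if (anyNA(trials$response)) abort("`trials` has missing responses.")
  p_schema <- params$p_schema %||0% 0
  weights <- c(1 - params$p_guess - p_schema, p_schema, params$p_guess)
  if (any(weights < -1e-12) || any(weights > 1 + 1e-12)) {
    abort("Mixture weights must lie in the simplex.")
  }
  if (params$kappa < 0) abort("`kappa` must be non-negative.")
  et <- err_rad(trials$response, trials$target)
  es <- err_rad(trials$response, schema_centre_angle(model, trials))
  mixture_loglik_cpp(et, es, params$p_guess, p_schema, params$kappa,
                     !is.na(model$schema_centre))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Fit a mixture model by maximum likelihood
#'
#' Direct multi-start maximization of the pooled log-likelihood over
#' transformed parameters (multinomial-logit weights, logit-bounded kappa in
#' \[0, 200\]) by Nelder-Mead, followed by monotone EM refinement of the best
#' start (the EM operates on the same likelihood, so the refinement can only
#' improve the optimum and leaves the fit at an EM fixed point, where mean
#' posterior responsibilities equal the mixing weights). Trials with missing
#' responses are dropped. `engine = "em"` skips the Nelder-Mead stage and runs
#' multi-start EM only (used internally where thousands of refits are needed).
#'
#' @param trials Trial table.
#' @param model [model_spec()] or id string.
#' @param n_starts Number of random starts.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param engine `"optim"` (default) or `"em"`.
#' @param start Optional list of starting values (`p_guess`, `p_schema`,
#'   `kappa`) prepended to the random starts.
#' @return A `schemup_fit` object: fitted weights (`p_target`, `p_schema`,
#'   `p_guess`), `kappa`, `logL`, `n_trials`, `aic`, `bic`, diagnostics.
#' @export
fit_model <- function(trials, model = "M4", n_starts = 10, tol = 1e-6,
                      engine = c("optim", "em"), start = NULL) {
  engine <- match.arg(engine)
  model <- as_model_spec(model)
  check_fit_trials(trials, model)
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  n <- nrow(trials)
  if (n < 1) abort("Need at least one trial with a response.")
  use_schema <- !is.na(model$schema_centre)
  et <- err_rad(trials$response, trials$target)
  es <- err_rad(trials$response, schema_centre_angle(model, trials))

  starts <- make_starts(n_starts, use_schema, start)
  best <- NULL
  n_converged <- 0L
  for (s in starts) {
    if (engine == "optim") {
      res <- fit_one_start_optim(et, es, use_schema, s, tol)
    } else {
      em <- mixture_em_cpp(et, es, use_schema, s$p_guess, s$p_schema, s$kappa,
                           2000L, tol * 1e-2)
      res <- list(p_guess = em$p_guess, p_schema = em$p_schema,
                  kappa = em$kappa, logL = em$logL,
                  converged = isTRUE(em$converged))
    }
    if (isTRUE(res$converged)) n_converged <- n_converged + 1L
    if (is.null(best) || res$logL > best$logL) best <- res
  }
  if (is.null(best) || !is.finite(best$logL)) {
    abort("All optimization starts failed to converge.")
  }
  # monotone EM polish on the same likelihood (fixed point => responsibility
  # means coincide with weights)
  em <- mixture_em_cpp(et, es, use_schema, best$p_guess, best$p_schema,
                       best$kappa, 5000L, 1e-10)
  if (em$logL >= best$logL - 1e-9) {
    best <- list(p_guess = em$p_guess, p_schema = em$p_schema,
                 kappa = em$kappa, logL = em$logL, converged = best$converged)
  }
  degenerate <- best$kappa >= 199.5
  if (degenerate) {
    warn("Fitted kappa is at the upper guard (200); fit flagged degenerate.")
  }
  k <- model$n_free_params
  structure(
    list(
      model_id = model$model_id, model = model,
      p_target = 1 - best$p_guess - best$p_schema,
      p_schema = if (use_schema) best$p_schema else NA_real_,
      p_guess = best$p_guess,
      kappa = best$kappa,
      logL = best$logL, n_trials = n,
      aic = 2 * k - 2 * best$logL,
      bic = k * log(n) - 2 * best$logL,
      n_starts_converged = n_converged,
      degenerate = degenerate,
      mean_resp = c(target = em$mean_resp_target,
                    schema = em$mean_resp_schema,
                    guess = em$mean_resp_guess)
    ),
    class = "schemup_fit"
  )
}

make_starts <- function(n_starts, use_schema, start) {
  starts <- list()
  if (!is.null(start)) {
    starts[[1]] <- list(
      p_guess = start$p_guess %||0% 0.2,
      p_schema = if (use_schema) start$p_schema %||0% 0.2 else 0,
      kappa = start$kappa %||0% 10
    )
  }
  for (i in seq_len(n_starts)) {
    pg <- runif(1, 0.02, 0.6)
    ps <- if (use_schema) runif(1, 0.02, 0.6) else 0
    if (pg + ps > 0.9) {
      f <- 0.9 / (pg + ps)
      pg <- pg * f; ps <- ps * f
    }
    starts[[length(starts) + 1]] <-
      list(p_guess = pg, p_schema = ps, kappa = exp(runif(1, log(2), log(100))))
  }
  starts
}

fit_one_start_optim <- function(et, es, use_schema, s, tol) {
  kappa_max <- 200
  to_par <- function(p_guess, p_schema, kappa) {
    pt <- max(1 - p_guess - p_schema, 1e-6)
    c(log(max(p_guess, 1e-6) / pt),
      if (use_schema) log(max(p_schema, 1e-6) / pt),
      stats::qlogis(min(max(kappa / kappa_max, 1e-6), 1 - 1e-6)))
  }
  from_par <- function(par) {
    ag <- par[1]
    as_ <- if (use_schema) par[2] else -Inf
    denom <- 1 + exp(ag) + (if (use_schema) exp(as_) else 0)
    list(p_guess = exp(ag) / denom,
         p_schema = if (use_schema) exp(as_) / denom else 0,
         kappa = kappa_max * stats::plogis(par[length(par)]))
  }
  nll <- function(par) {
    p <- from_par(par)
    mixture_nll_cpp(et, es, p$p_guess, p$p_schema, p$kappa, use_schema)
  }
  res <- tryCatch(
    optim(to_par(s$p_guess, s$p_schema, s$kappa), nll,
          method = "Nelder-Mead",
          control = list(reltol = tol, maxit = 2000)),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(list(p_guess = s$p_guess, p_schema = s$p_schema, kappa = s$kappa,
                logL = -Inf, converged = FALSE))
  }
  p <- from_par(res$par)
  list(p_guess = p$p_guess, p_schema = p$p_schema, kappa = p$kappa,
       logL = -res$value, converged = res$convergence == 0)
}

#' @export
print.schemup_fit <- function(x, ...) {
  cat(sprintf("<%s fit>  n = %d trials\n", x$model_id, x$n_trials))
  cat(sprintf("  p_target = %.3f  p_schema = %s  p_guess = %.3f  kappa = %.2f\n",
              x$p_target,
              if (is.na(x$p_schema)) "  -  " else sprintf("%.3f", x$p_schema),
              x$p_guess, x$kappa))
  cat(sprintf("  logL = %.2f  AIC = %.1f  BIC = %.1f\n", x$logL, x$aic, x$bic))
  invisible(x)
}

#' Information criteria of a fitted model
#'
#' @param fit A `schemup_fit`.
#' @return Named vector `c(aic, bic)` with `aic = 2k - 2 logL`,
#'   `bic = k log(n) - 2 logL`.
#' @export
information_criteria <- function(fit) {
  if (fit$n_trials == 0) abort("Fit has no trials.")
  k <- fit$model$n_free_params
  c(aic = 2 * k - 2 * fit$logL, bic = k * log(fit$n_trials) - 2 * fit$logL)
}

#' Fit and compare several mixture models on one trial set
#'
#' Fits every requested model on the identical trial set and tabulates AIC/BIC
#' with differences oriented as "alternative minus preferred" (positive values
#' favour the preferred model, which attains the lowest AIC).
#'
#' @param trials Trial table.
#' @param models Character vector of model ids (>= 2).
#' @param ... Passed to [fit_model()].
#' @return A `schemup_model_comparison`: list with `fits`, a `table` tibble
#'   (model, k, logL, AIC, BIC, dAIC, dBIC), `preferred`, and per-model
#'   `errors` for fits that failed.
#' @export
compare_models <- function(trials, models = c("M3", "M4", "M5"), ...) {
  if (length(models) < 2) abort("Need at least two models to compare.")
  fits <- list()
  errors <- list()
  for (m in models) {
    f <- tryCatch(fit_model(trials, m, ...), error = function(e) e)
    if (inherits(f, "error")) errors[[m]] <- conditionMessage(f) else fits[[m]] <- f
  }
  if (!length(fits)) abort("All model fits failed.")
  tab <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble(model = f$model_id, k = f$model$n_free_params,
           logL = f$logL, AIC = f$aic, BIC = f$bic,
           p_target = f$p_target, p_schema = f$p_schema,
           p_guess = f$p_guess, kappa = f$kappa)
  }))
  preferred <- tab$model[which.min(tab$AIC)]
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$dBIC <- tab$BIC - tab$BIC[tab$model == preferred]
  structure(
    list(fits = fits, table = tab, preferred = preferred, errors = errors),
    class = "schemup_model_comparison"
  )
}

#' @export
print.schemup_model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (preferred by AIC: %s)\n", x$preferred))
  print(as.data.frame(x$table[, c("model", "k", "logL", "AIC", "BIC",
                                  "dAIC", "dBIC")]), row.names = FALSE)
  if (length(x$errors)) {
    cat("Failed fits:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
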
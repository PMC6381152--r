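#' Default generative mixture parameters per design cell
#'
#' One row per (group, category role, phase class) cell, giving the mixing
#' weights of the generative response mixture: a von Mises around the target,
#' a von Mises around the *original* schema mean, and uniform guessing, all
#' sharing one concentration `kappa`. For categories whose schema never shifts
#' the original and current means coincide, so the schema component doubles as
#' the (current-)schema bias of the consistent condition.
#'
#' Defaults encode the study conditions the generator emulates: at Final Test
#' the old-schema weight for the inconsistent category is 0.49 in the
#' no-consolidation group vs 0.32 in the consolidation group, and in the New
#' Learning test it is 0.03 vs 0.00; guessing is 0.10 throughout and kappa is
#' 15 (circular SD roughly 15 degrees).
#'
#' @param kappa Shared von Mises concentration.
#' @param p_guess Guessing weight used in every cell.
#' @param schema_is Schema weight during Initial Study (and the first learning
#'   of irrelevant categories).
#' @param schema_nl_consistent Schema weight for the consistent category at New
#'   Learning.
#' @param schema_nl_inconsistent Old-schema weights at New Learning,
#'   `c(no_consolidation, consolidation)`.
#' @param schema_ft_consistent Schema weight for the consistent category at
#'   Final Test.
#' @param schema_ft_inconsistent Old-schema weights at Final Test,
#'   `c(no_consolidation, consolidation)`.
#' @param schema_ft_irrelevant Schema weight for irrelevant categories at Final
#'   Test.
#' @return A tibble with columns `group`, `category_role`, `phase_class`,
#'   `p_target`, `p_schema`, `p_guess`, `kappa`.
#' @export
generative_params <- function(kappa = 15,
                              p_guess = 0.10,
                              schema_is = 0.10,
                              schema_nl_consistent = 0.05,
                              schema_nl_inconsistent = c(0.03, 0.00),
                              schema_ft_consistent = 0.30,
                              schema_ft_inconsistent = c(0.49, 0.32),
                              schema_ft_irrelevant = 0.20) {
  grid <- expand.grid(
    group = c("no_consolidation", "consolidation"),
    category_role = c("consistent", "inconsistent", "irrelevant"),
    phase_class = c("IS", "NL", "FT"),
    stringsAsFactors = FALSE
  )
  gi <- ifelse(grid$group == "no_consolidation", 1L, 2L)
  p_schema <- numeric(nrow(grid))
  p_schema[grid$phase_class == "IS"] <- schema_is
  p_schema[grid$phase_class == "NL" & grid$category_role == "consistent"] <-
    schema_nl_consistent
  p_schema[grid$phase_class == "NL" & grid$category_role == "irrelevant"] <-
    schema_is
  sel <- grid$phase_class == "NL" & grid$category_role == "inconsistent"
  p_schema[sel] <- schema_nl_inconsistent[gi[sel]]
  p_schema[grid$phase_class == "FT" & grid$category_role == "consistent"] <-
    schema_ft_consistent
  p_schema[grid$phase_class == "FT" & grid$category_role == "irrelevant"] <-
    schema_ft_irrelevant
  sel <- grid$phase_class == "FT" & grid$category_role == "inconsistent"
  p_schema[sel] <- schema_ft_inconsistent[gi[sel]]

  out <- as_tibble(grid)
  out$p_target <- 1 - p_guess - p_schema
  out$p_schema <- p_schema
  out$p_guess <- p_guess
  out$kappa <- kappa
  validate_generative_params(out)
  out
}

validate_generative_params <- function(params) {
  needed <- c("group", "category_role", "phase_class",
              "p_target", "p_schema", "p_guess", "kappa")
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    abort(paste0("Generative parameters lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  w <- params[, c("p_target", "p_schema", "p_guess")]
  if (any(w < -1e-12)) abort("Mixing weights must be non-negative.")
  if (any(abs(rowSums(w) - 1) > 1e-9)) abort("Mixing weights must sum to 1.")
  if (any(params$kappa < 0)) abort("`kappa` must be non-negative.")
  invisible(params)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; reduces to uniform at `kappa = 0`.
#'
#' @param n Number of draws.
#' @param mu Mean direction, degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees in \[0, 360).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) abort("`kappa` must be non-negative.")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(wrap_circle(runif(n, 0, 360)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  theta <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta[todo[ok]] <- sign(u3[ok] - 0.5) * acos(pmax(pmin(f[ok], 1), -1))
    todo <- todo[!ok]
  }
  wrap_circle(mu + theta * 180 / pi)
}

#' Simulate responses for a trial table
#'
#' Each trial's response is drawn from the generative mixture of its
#' (group, category role, phase class) cell: with probability `p_target` a von
#' Mises around the target, with `p_schema` a von Mises around the *original*
#' schema mean, and with `p_guess` uniform on the circle. A missing cell in
#' `params` is an error. With `p_miss > 0` a response is dropped (timeout)
#' independently per trial.
#'
#' @param trials Trial table from [build_design()].
#' @param params Generative parameters, see [generative_params()].
#' @param seed Top-level seed; per-participant child streams are derived from
#'   it, so each participant's responses are reproducible in isolation.
#' @param p_miss Probability of a missing response.
#' @return `trials` with the `response` column filled (NA where missed) and a
#'   `sim_component` column recording the generating component.
#' @export
simulate_responses <- function(trials, params = generative_params(), seed = 1,
                               p_miss = 0) {
  validate_generative_params(params)
  if (nrow(trials) == 0) return(trials)
  key <- tibble(
    group = trials$group,
    category_role = trials$category_role,
    phase_class = phase_class(trials$phase)
  )
  idx <- match(
    paste(key$group, key$category_role, key$phase_class),
    paste(params$group, params$category_role, params$phase_class)
  )
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx), ])
    abort(paste0(
      "No generative parameters for cell(s): ",
      paste(paste(bad$group, bad$category_role, bad$phase_class, sep = "/"),
            collapse = "; ")
    ))
  }
  cell <- params[idx, ]
  out <- trials
  out$response <- NA_real_
  out$sim_component <- NA_character_
  pid_levels <- unique(trials$participant_id)
  for (i in seq_along(pid_levels)) {
    set.seed(child_seed(seed, i))
    rows <- which(trials$participant_id == pid_levels[i])
    u <- runif(length(rows))
    comp <- ifelse(u < cell$p_target[rows], "target",
                   ifelse(u < cell$p_target[rows] + cell$p_schema[rows],
                          "schema", "guess"))
    resp <- numeric(length(rows))
    for (cc in c("target", "schema", "guess")) {
      j <- which(comp == cc)
      if (!length(j)) next
      if (cc == "guess") {
        resp[j] <- runif(length(j), 0, 360)
      } else {
        centre <- if (cc == "target") trials$target[rows[j]] else
          trials$schema_mean_original[rows[j]]
        kk <- cell$kappa[rows[j]]
        # kappa is constant within a participant cell in practice, but draw
        # per distinct value to be safe
        for (k in unique(kk)) {
          jj <- j[kk == k]
          resp[jj] <- rvonmises(length(jj), 0, k) + centre[kk == k]
        }
      }
    }
    resp <- wrap_circle(resp)
    if (p_miss > 0) resp[runif(length(rows)) < p_miss] <- NA_real_
    out$response[rows] <- resp
    out$sim_component[rows] <- comp
  }
  out
}

#' Simulate a full two-group experiment
#'
#' Convenience wrapper: [build_design()] then [simulate_responses()], sharing
#' one top-level seed.
#'
#' @inheritParams build_design
#' @inheritParams simulate_responses
#' @return A completed trial table.
#' @export
simulate_experiment <- function(config = design_config(),
                                params = generative_params(),
                                seed = 1) {
  trials <- build_design(config, seed = seed)
  simulate_responses(trials, params, seed = seed, p_miss = config$p_miss)
}

#' Simulate critical-style trials directly from a mixture
#'
#' Generates Final-Test-like inconsistent-category trials without building the
#' full design: targets are uniform inside the current (shifted) schema
#' quadrant, and responses come from the target / old-schema / guess mixture.
#' The original schema mean sits 90 degrees counterclockwise of the current
#' one (the current mean is the original shifted 90 degrees clockwise).
#' Intended for parameter- and model-recovery studies.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_each Trials per participant.
#' @param p_target,p_schema,p_guess Mixture weights (must sum to 1).
#' @param kappa Shared von Mises concentration.
#' @param group Group label to stamp on the rows.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return A trial tibble compatible with [fit_model()].
#' @export
simulate_mixture_trials <- function(n_participants = 32, trials_each = 56,
                                    p_target = 0.41, p_schema = 0.49,
                                    p_guess = 0.10, kappa = 15,
                                    group = "no_consolidation", seed = NULL) {
  if (abs(p_target + p_schema + p_guess - 1) > 1e-9) {
    abort("Mixture weights must sum to 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  mean_orig <- 0
  mean_cur <- wrap_circle(mean_orig - 90)
  n <- n_participants * trials_each
  target <- sample_target(mean_cur, "inside", n)
  u <- runif(n)
  comp <- ifelse(u < p_target, "target", ifelse(u < p_target + p_schema,
                                                "schema", "guess"))
  resp <- numeric(n)
  resp[comp == "target"] <- rvonmises(sum(comp == "target"), 0, kappa) +
    target[comp == "target"]
  resp[comp == "schema"] <- rvonmises(sum(comp == "schema"), mean_orig, kappa)
  resp[comp == "guess"] <- runif(sum(comp == "guess"), 0, 360)
  tibble(
    participant_id = rep(sprintf("p%03d", seq_len(n_participants)),
                         each = trials_each),
    group = group, phase = "FT",
    block = 1L,
    item_id = sprintf("it%05d", seq_len(n)),
    category = "animals", category_role = "inconsistent",
    quadrant = "inside", is_critical = TRUE,
    target = target,
    schema_mean_current = mean_cur,
    schema_mean_original = mean_orig,
    schema_mean_study = mean_cur,
    response = wrap_circle(resp),
    sim_component = comp
  )
}
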
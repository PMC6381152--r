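#' Trial-level posterior component responsibilities
#'
#' For each trial, the posterior probability at the fitted parameters that the
#' response stemmed from each mixture component (target, schema, guess):
#' `weight_c * density_c(response) / sum_c' weight_c' * density_c'(response)`.
#'
#' @param fit A `schemup_fit`.
#' @param trials Trial table (must match the fit's model requirements; trials
#'   with missing responses are rejected).
#' @return A tibble with columns `target`, `schema`, `guess`; each row sums
#'   to 1. The `schema` column is 0 for two-component models.
#' @export
responsibilities <- function(fit, trials) {
  model <- fit$model
  check_fit_trials(trials, model)
  if (anyNA(trials$response)) abort("`trials` has missing responses.")
  use_schema <- !is.na(model$schema_centre)
  dt <- dvonmises(circ_dist(trials$response, trials$target), 0, fit$kappa)
  ds <- if (use_schema) {
    dvonmises(circ_dist(trials$response, schema_centre_angle(model, trials)),
              0, fit$kappa)
  } else 0
  p_schema <- if (use_schema) fit$p_schema else 0
  wt <- fit$p_target * dt
  ws <- p_schema * ds
  wg <- fit$p_guess / 360
  tot <- wt + ws + wg
  tibble(target = wt / tot, schema = ws / tot, guess = wg / tot)
}

#' Mean posterior probability of one component
#'
#' @param resp Responsibility table from [responsibilities()].
#' @param component `"target"`, `"schema"`, or `"guess"`.
#' @return Arithmetic mean of the component's column.
#' @export
mean_component_probability <- function(resp, component) {
  if (nrow(resp) == 0) abort("Responsibility table is empty.")
  component <- match.arg(component, c("target", "schema", "guess"))
  mean(resp[[component]])
}

#' Participant-level permutation test on pooled-fit group differences
#'
#' Statistic: the mean posterior probability that responses are attributed to
#' the schema component, computed from a mixture model fitted to each group's
#' *pooled* trials, group A minus group B. The null distribution is built by
#' randomly reassigning participants to two groups of the original sizes and
#' refitting the pooled model for each relabelling. The two-tailed p-value is
#' the proportion of iterations whose absolute null difference is at least the
#' observed absolute difference (ties count as exceeding, the conservative
#' choice); an add-one corrected value is reported alongside for use when the
#' plain proportion is 0.
#'
#' All fits (observed and permuted) use the same procedure: EM warm-started at
#' the parameters of a multi-start fit to the combined data, so the observed
#' statistic is exchangeable with the null ones.
#'
#' @param trials_a,trials_b Trial tables for the two groups (participants
#'   identified by `participant_id`; ids may repeat across tables).
#' @param model Model id or [model_spec()] (default `"M4"`).
#' @param n_iter Number of permutations.
#' @param seed Optional RNG seed.
#' @param n_starts Random starts for the combined-data anchor fit.
#' @return A `schemup_permutation`: `observed_diff`, `group_stats`,
#'   `null_diffs`, `p_two_tailed`, `p_add_one`, `n_iter`, `seed`.
#' @export
permutation_test <- function(trials_a, trials_b, model = "M4",
                             n_iter = 5000, seed = NULL, n_starts = 10) {
  if (!is.null(seed)) set.seed(seed)
  model <- as_model_spec(model)
  use_schema <- !is.na(model$schema_centre)
  if (!use_schema) abort("The permutation statistic requires a schema component (M2/M4/M5).")
  trials_a <- trials_a[!is.na(trials_a$response), , drop = FALSE]
  trials_b <- trials_b[!is.na(trials_b$response), , drop = FALSE]
  pid <- c(paste0("A.", trials_a$participant_id),
           paste0("B.", trials_b$participant_id))
  n_a <- length(unique(paste0("A.", trials_a$participant_id)))
  n_b <- length(unique(paste0("B.", trials_b$participant_id)))
  if (n_a < 2 || n_b < 2) abort("Need at least 2 participants per group.")
  all_trials <- dplyr::bind_rows(trials_a, trials_b)
  et <- err_rad(all_trials$response, all_trials$target)
  es <- err_rad(all_trials$response, schema_centre_angle(model, all_trials))
  pid_f <- factor(pid)
  pids <- levels(pid_f)
  pid_idx <- as.integer(pid_f)

  anchor <- fit_model(all_trials, model, n_starts = n_starts)

  pooled_stat <- function(rows) {
    em <- mixture_em_cpp(et[rows], es[rows], TRUE,
                         anchor$p_guess,
                         max(anchor$p_schema, 0.05), anchor$kappa,
                         2000L, 1e-9)
    em$mean_resp_schema
  }
  group_of_pid <- startsWith(pids, "A.")
  obs_a <- pooled_stat(which(group_of_pid[pid_idx]))
  obs_b <- pooled_stat(which(!group_of_pid[pid_idx]))
  observed <- obs_a - obs_b

  # Canonical, argument-order-independent participant ordering (content-based
  # key), so the sampled relabellings -- and hence the p-value -- are identical
  # when the two groups are passed in either order.
  key1 <- vapply(split(all_trials$response, pid_idx), length, 0L)
  key2 <- vapply(split(sin(all_trials$response * pi / 180) +
                         cos(all_trials$target * pi / 180), pid_idx), sum, 0)
  ord <- order(key1, key2, pids)
  ranks <- integer(length(pids))
  ranks[ord] <- seq_along(pids)
  pid_rank <- ranks[pid_idx]

  n_pid <- length(pids)
  m <- min(n_a, n_b)
  null_diffs <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    in_s <- logical(n_pid)
    in_s[sample.int(n_pid, m)] <- TRUE
    rows_s <- in_s[pid_rank]
    null_diffs[it] <- pooled_stat(which(rows_s)) - pooled_stat(which(!rows_s))
  }
  count <- sum(abs(null_diffs) >= abs(observed) - 1e-12)
  structure(
    list(
      observed_diff = observed,
      group_stats = c(A = obs_a, B = obs_b),
      null_diffs = null_diffs,
      p_two_tailed = count / n_iter,
      p_add_one = (count + 1) / (n_iter + 1),
      n_iter = n_iter,
      seed = seed
    ),
    class = "schemup_permutation"
  )
}

#' @export
print.schemup_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%d iterations)\n  group stats: A = %.3f, B = %.3f\n  observed diff = %.3f, p (two-tailed) = %.4g [add-one: %.4g]\n",
    x$n_iter, x$group_stats[["A"]], x$group_stats[["B"]],
    x$observed_diff, x$p_two_tailed, x$p_add_one))
  invisible(x)
}

#' Initial schema strength per participant and category
#'
#' Difference in mean absolute error between outside- and inside-quadrant test
#' trials of the Initial Study phase, in degrees. Positive values indicate
#' better accuracy inside the schema quadrant, i.e. a stronger schema.
#'
#' @param trials Trial table (only IS-phase rows with responses are used).
#' @return Tibble with `participant_id`, `group`, `category`, `category_role`,
#'   `strength`, and the per-cell trial counts.
#' @export
schema_strength <- function(trials) {
  is_rows <- trials[trials$phase == "IS" & !is.na(trials$response), , drop = FALSE]
  if (nrow(is_rows) == 0) abort("No IS-phase trials with responses.")
  out <- is_rows |>
    dplyr::mutate(err = abs_error(.data$target, .data$response)) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$category,
                    .data$category_role) |>
    dplyr::summarise(
      n_inside = sum(.data$quadrant == "inside"),
      n_outside = sum(.data$quadrant == "outside"),
      strength = mean(.data$err[.data$quadrant == "outside"]) -
        mean(.data$err[.data$quadrant == "inside"]),
      .groups = "drop"
    )
  if (any(out$n_inside == 0 | out$n_outside == 0)) {
    abort("Some participant/category cells lack inside or outside IS trials.")
  }
  out
}

#' Compare two independent Pearson correlations (Fisher r-to-z)
#'
#' Tests the equality of two correlations observed in independent samples via
#' the variance-stabilizing transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed normal p-value.
#'
#' @param r1,r2 The two sample correlations (|r| < 1).
#' @param n1,n2 The two sample sizes (>= 4).
#' @return List with `z` and `p_two_tailed` (plus the inputs).
#' @examples
#' compare_independent_correlations(0.507, 32, 0.001, 32)  # z = 2.12
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) abort("Correlations must satisfy |r| < 1.")
  if (n1 < 4 || n2 < 4) abort("Need n >= 4 in both samples.")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
       z = z, p_two_tailed = 2 * pnorm(-abs(z)))
}

#' Standardized (z-scored) multiple regression
#'
#' Ordinary least squares on variables standardized to unit variance, so the
#' coefficients are standardized betas.
#'
#' @param data Data frame.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns.
#' @return List with a `coefficients` tibble (term, beta, p), `F`, `df`,
#'   `p_model`, `r_squared`, `n`.
#' @export
standardized_regression <- function(data, response, predictors) {
  cols <- c(response, predictors)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("Data lacks column(s): ", paste(missing, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 1) abort("Not enough observations for the regression.")
  dz <- as.data.frame(lapply(d, function(x) as.numeric(scale(x))))
  f <- stats::as.formula(paste(
    sprintf("`%s`", response), "~",
    paste(sprintf("`%s`", predictors), collapse = " + ")
  ))
  m <- lm(f, data = dz)
  sm <- summary(m)
  coefs <- sm$coefficients[-1, , drop = FALSE] # predictors, in order
  fstat <- sm$fstatistic
  list(
    coefficients = tibble(
      term = predictors,
      beta = unname(coefs[, "Estimate"]),
      p = unname(coefs[, "Pr(>|t|)"])
    ),
    F = unname(fstat["value"]),
    df = unname(fstat[c("numdf", "dendf")]),
    p_model = unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                               lower.tail = FALSE)),
    r_squared = sm$r.squared,
    n = n
  )
}
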
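#' Per-participant absolute-error cell means (consistent category)
#'
#' Mean absolute error per participant, phase class and trial quadrant for the
#' consistent category, using IS trials and the critical items' NL and FT
#' tests (the cells that feed the schematization ANOVA, which itself is out of
#' scope here).
#'
#' @param trials Trial table with responses.
#' @return Tibble with `participant_id`, `group`, `phase_class`, `quadrant`,
#'   `mean_abs_error`, `n_trials`.
#' @export
cell_means <- function(trials) {
  rows <- trials[!is.na(trials$response) &
                   trials$category_role == "consistent" &
                   (phase_class(trials$phase) == "IS" | trials$is_critical), ,
                 drop = FALSE]
  rows |>
    dplyr::mutate(phase_class = phase_class(.data$phase),
                  err = abs_error(.data$target, .data$response)) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$phase_class,
                    .data$quadrant) |>
    dplyr::summarise(mean_abs_error = mean(.data$err),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Optional participant exclusion on overall Final Test performance
#'
#' Flags participants whose mean Final Test absolute error is more than
#' `sd_threshold` standard deviations worse (higher) than the across-sample
#' mean, and removes all their trials. Off by default in the pipeline; mirrors
#' a pre-analysis screening rule sometimes applied to real samples.
#'
#' @param trials Trial table.
#' @param sd_threshold SD multiplier.
#' @return Filtered trials, with attribute `excluded` listing removed
#'   participant ids.
#' @export
exclude_low_performers <- function(trials, sd_threshold = 2) {
  ft <- trials[trials$phase == "FT" & !is.na(trials$response), , drop = FALSE]
  per <- ft |>
    dplyr::mutate(err = abs_error(.data$target, .data$response)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(m = mean(.data$err), .groups = "drop")
  cut <- mean(per$m) + sd_threshold * sd(per$m)
  excluded <- per$participant_id[per$m > cut]
  out <- trials[!(trials$participant_id %in% excluded), , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

ft_critical <- function(trials, role) {
  trials[trials$phase == "FT" & trials$is_critical &
           trials$category_role == role & !is.na(trials$response), , drop = FALSE]
}

nl_critical <- function(trials, role) {
  trials[trials$phase %in% c("NL1", "NL2") & trials$is_critical &
           trials$category_role == role & !is.na(trials$response), , drop = FALSE]
}

split_groups <- function(trials) {
  split(trials, factor(trials$group, c("no_consolidation", "consolidation")))
}

#' Run the full schema-updating analysis pipeline
#'
#' Executes, in order: (1) consistent-category absolute-error cell means per
#' phase and quadrant; (2) the schematization model comparison (M1 vs M2) on
#' each group's pooled Final Test critical items of the consistent category;
#' (3) the updating model comparison (M3/M4/M5) on the inconsistent category's
#' Final Test critical items; (4) trial-level attribution under M4 with the
#' participant-level permutation test on the group difference in mean
#' old-schema responsibility, at Final Test and (as a control) in the New
#' Learning test; (5) initial-schema-strength analyses: per-participant
#' strengths and single-subject fits, per-group correlations, the Fisher
#' r-to-z comparison of the two groups' correlations, and the standardized
#' two-predictor regression of Final Test old-schema responding on initial
#' schema strength and New Learning old-schema responding.
#'
#' Failures in one stage are caught and recorded; dependent stages are skipped
#' with a notice rather than aborting the run.
#'
#' @param trials Completed trial table.
#' @param n_iter Permutation iterations.
#' @param seed RNG seed for fitting starts and permutations.
#' @param n_starts Random starts per model fit.
#' @param exclude Apply [exclude_low_performers()] first?
#' @return A `schemup_analysis` list with elements `cell_means`,
#'   `schematization`, `updating`, `attribution`, `strength`, `errors`, and
#'   `meta`.
#' @export
analyze_experiment <- function(trials, n_iter = 5000, seed = 1,
                               n_starts = 10, exclude = FALSE) {
  missing_cols <- setdiff(trial_table_columns, names(trials))
  if (length(missing_cols)) {
    abort(paste0("Trial table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  set.seed(seed)
  errors <- list()
  note <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      NULL
    })
  }
  if (exclude) trials <- exclude_low_performers(trials)

  cm <- note("cell_means", cell_means(trials))

  groups <- split_groups(trials)
  schematization <- note("schematization", lapply(groups, function(g)
    compare_models(ft_critical(g, "consistent"), c("M1", "M2"),
                   n_starts = n_starts)))

  updating <- note("updating", lapply(groups, function(g)
    compare_models(ft_critical(g, "inconsistent"), c("M3", "M4", "M5"),
                   n_starts = n_starts)))

  attribution <- note("attribution", {
    ft_a <- ft_critical(groups[[1]], "inconsistent")
    ft_b <- ft_critical(groups[[2]], "inconsistent")
    nl_a <- nl_critical(groups[[1]], "inconsistent")
    nl_b <- nl_critical(groups[[2]], "inconsistent")
    perm_ft <- permutation_test(ft_a, ft_b, "M4", n_iter = n_iter,
                                n_starts = n_starts)
    perm_nl <- permutation_test(nl_a, nl_b, "M4", n_iter = n_iter,
                                n_starts = n_starts)
    list(
      ft_mean_old_schema = perm_ft$group_stats,
      permutation_ft = perm_ft,
      nl_mean_old_schema = perm_nl$group_stats,
      permutation_nl = perm_nl
    )
  })

  strength <- note("strength", strength_analysis(trials, n_starts = n_starts))

  structure(
    list(cell_means = cm, schematization = schematization, updating = updating,
         attribution = attribution, strength = strength, errors = errors,
         meta = list(seed = seed, n_iter = n_iter,
                     n_trials = nrow(trials),
                     n_participants = length(unique(trials$participant_id)))),
    class = "schemup_analysis"
  )
}

# per-participant strength + single-subject fits + correlations + regression
strength_analysis <- function(trials, n_starts = 10) {
  strengths <- schema_strength(trials)
  participants <- unique(trials[, c("participant_id", "group")])

  subject_fit <- function(rows, model) {
    if (nrow(rows) == 0) return(NA_real_)
    f <- tryCatch(
      suppressWarnings(fit_model(rows, model, n_starts = n_starts)),
      error = function(e) NULL
    )
    if (is.null(f)) NA_real_ else f$p_schema
  }
  per <- lapply(seq_len(nrow(participants)), function(i) {
    pid <- participants$participant_id[i]
    tr <- trials[trials$participant_id == pid, , drop = FALSE]
    tibble(
      participant_id = pid,
      group = participants$group[i],
      strength_inconsistent =
        strengths$strength[strengths$participant_id == pid &
                             strengths$category_role == "inconsistent"][1],
      strength_consistent =
        strengths$strength[strengths$participant_id == pid &
                             strengths$category_role == "consistent"][1],
      p_old_ft = subject_fit(ft_critical(tr, "inconsistent"), "M4"),
      p_old_nl = subject_fit(nl_critical(tr, "inconsistent"), "M4"),
      p_schema_ft_consistent = subject_fit(ft_critical(tr, "consistent"), "M2")
    )
  })
  per <- dplyr::bind_rows(per)

  cor_by_group <- function(xcol, ycol) {
    lapply(split(per, factor(per$group, c("no_consolidation", "consolidation"))),
           function(d) {
             ok <- stats::complete.cases(d[, c(xcol, ycol)])
             ct <- cor.test(d[[xcol]][ok], d[[ycol]][ok])
             list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
           })
  }
  cors_inc <- cor_by_group("strength_inconsistent", "p_old_ft")
  cors_con <- cor_by_group("strength_consistent", "p_schema_ft_consistent")
  z_inc <- compare_independent_correlations(
    cors_inc[[1]]$r, cors_inc[[1]]$n, cors_inc[[2]]$r, cors_inc[[2]]$n)
  z_con <- compare_independent_correlations(
    cors_con[[1]]$r, cors_con[[1]]$n, cors_con[[2]]$r, cors_con[[2]]$n)

  regressions <- lapply(
    split(per, factor(per$group, c("no_consolidation", "consolidation"))),
    function(d) tryCatch(
      standardized_regression(d, "p_old_ft",
                              c("strength_inconsistent", "p_old_nl")),
      error = function(e) NULL
    )
  )

  list(per_participant = per,
       correlations_inconsistent = cors_inc,
       correlations_consistent = cors_con,
       z_inconsistent = z_inc,
       z_consistent = z_con,
       regressions = regressions)
}

#' @export
print.schemup_analysis <- function(x, ...) {
  cat("Schema-updating analysis\n")
  cat(sprintf("  %d participants, %d trials (seed %s)\n",
              x$meta$n_participants, x$meta$n_trials, x$meta$seed))
  if (!is.null(x$schematization)) {
    cat("  Schematization (consistent FT): preferred",
        paste(vapply(x$schematization, function(m) m$preferred, ""),
              collapse = " / "), "\n")
  }
  if (!is.null(x$updating)) {
    cat("  Updating (inconsistent FT): preferred",
        paste(vapply(x$updating, function(m) m$preferred, ""),
              collapse = " / "), "\n")
  }
  if (!is.null(x$attribution)) {
    s <- x$attribution$ft_mean_old_schema
    cat(sprintf("  Mean old-schema responsibility (FT): %.3f vs %.3f, p = %.4g\n",
                s[["A"]], s[["B"]], x$attribution$permutation_ft$p_two_tailed))
  }
  if (length(x$errors)) {
    cat("  Failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
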
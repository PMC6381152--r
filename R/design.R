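#' Configuration of the two-group schema-shift design
#'
#' Describes the experimental design the synthetic-data generator emulates:
#' two groups of participants (`no_consolidation`, `consolidation`), four
#' stimulus categories each tied to a 90-degree quadrant of an invisible
#' circle, four phases (Initial Study IS, two New Learning phases NL1/NL2, and
#' a Final Test FT), 28-trial blocks with 22 inside-quadrant and 6
#' outside-quadrant trials, and a single 90-degree clockwise shift of one
#' relevant category's schema at New Learning.
#'
#' @param n_per_group Participants per group.
#' @param categories Four category labels; the first and last are treated as
#'   the "natural" pair, the middle two as the "man-made" pair, and each
#'   participant gets one relevant category from each pair.
#' @param quadrant_centres Four angles (degrees), pairwise at least 90 apart;
#'   randomly assigned to categories per participant.
#' @param trials_per_block Trials per study/test block.
#' @param inside_per_block,outside_per_block Inside-/outside-quadrant trials
#'   per block (must sum to `trials_per_block`; each must split evenly over the
#'   two categories in a block).
#' @param blocks_is,blocks_nl Number of blocks in the IS phase and in each NL
#'   phase.
#' @param ft_block_size Trials per Final Test block.
#' @param shift_deg Signed schema shift of the inconsistent category at New
#'   Learning; clockwise is negative, so the default is -90.
#' @param outside_margin_deg Minimum distance of outside-quadrant targets from
#'   the schema quadrant's edge.
#' @param p_miss Probability that a simulated trial times out (missing
#'   response).
#' @return A `design_config` list.
#' @export
design_config <- function(n_per_group = 32,
                          categories = c("animals", "clothes", "furniture", "food"),
                          quadrant_centres = c(45, 135, 225, 315),
                          trials_per_block = 28,
                          inside_per_block = 22,
                          outside_per_block = 6,
                          blocks_is = 4,
                          blocks_nl = 4,
                          ft_block_size = 56,
                          shift_deg = -90,
                          outside_margin_deg = 30,
                          p_miss = 0) {
  cfg <- list(
    n_per_group = n_per_group, categories = categories,
    quadrant_centres = quadrant_centres, trials_per_block = trials_per_block,
    inside_per_block = inside_per_block, outside_per_block = outside_per_block,
    blocks_is = blocks_is, blocks_nl = blocks_nl, ft_block_size = ft_block_size,
    shift_deg = shift_deg, outside_margin_deg = outside_margin_deg,
    p_miss = p_miss
  )
  validate_design_config(cfg)
  structure(cfg, class = "design_config")
}

validate_design_config <- function(cfg) {
  if (cfg$n_per_group < 0) abort("`n_per_group` must be >= 0.")
  if (length(cfg$categories) != 4 || anyDuplicated(cfg$categories)) {
    abort("`categories` must be 4 distinct labels.")
  }
  if (length(cfg$quadrant_centres) != 4) abort("`quadrant_centres` must have length 4.")
  d <- outer(cfg$quadrant_centres, cfg$quadrant_centres,
             function(a, b) abs(circ_dist(a, b)))
  if (any(d[upper.tri(d)] < 90)) {
    abort("`quadrant_centres` must be pairwise at least 90 degrees apart.")
  }
  if (cfg$inside_per_block + cfg$outside_per_block != cfg$trials_per_block) {
    abort("`inside_per_block` + `outside_per_block` must equal `trials_per_block`.")
  }
  if (cfg$inside_per_block %% 2 != 0 || cfg$outside_per_block %% 2 != 0) {
    abort("Inside/outside counts must split evenly over the two categories in a block.")
  }
  if (cfg$p_miss < 0 || cfg$p_miss > 1) abort("`p_miss` must be in [0, 1].")
  total_nl <- cfg$blocks_nl * cfg$trials_per_block
  total_is <- cfg$blocks_is * cfg$trials_per_block
  total <- total_is + 2 * total_nl
  if (total %% cfg$ft_block_size != 0) {
    abort("Total studied items must be divisible by `ft_block_size`.")
  }
  invisible(cfg)
}

# internal: IS/NL1/NL2 -> phase class used to key generative parameters
phase_class <- function(phase) {
  out <- ifelse(phase %in% c("NL1", "NL2"), "NL", phase)
  out
}

#' Sample a target location inside or outside a schema quadrant
#'
#' Inside-quadrant targets are uniform within +/-45 degrees of the schema
#' mean. Outside-quadrant targets are uniform over the remaining arc that is
#' at least `45 + margin` degrees from the schema mean (a 210-degree arc at
#' the default 30-degree margin).
#'
#' @param schema_mean Schema mean in degrees.
#' @param quadrant `"inside"` or `"outside"`.
#' @param n Number of targets to draw.
#' @param half_width Half-width of the schema quadrant (degrees).
#' @param margin Extra margin beyond the quadrant for outside trials (degrees).
#' @return Angles in degrees, in \[0, 360).
#' @export
sample_target <- function(schema_mean, quadrant, n = 1,
                          half_width = 45, margin = 30) {
  quadrant <- match.arg(quadrant, c("inside", "outside"))
  if (quadrant == "inside") {
    wrap_circle(schema_mean + runif(n, -half_width, half_width))
  } else {
    lo <- half_width + margin
    wrap_circle(schema_mean + runif(n, lo, 360 - lo))
  }
}

# deterministic per-participant child seed from a top-level seed, so any
# participant's data can be regenerated in isolation
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647
}

#' Build the full experimental design (responses missing)
#'
#' Generates, per participant: 2 relevant and 2 irrelevant categories with
#' counterbalanced quadrant assignment; an IS phase of `blocks_is` blocks over
#' the relevant categories; one NL phase re-using the relevant categories with
#' one category's schema shifted 90 degrees clockwise (NL1 for the
#' no-consolidation group, NL2 for the consolidation group) and the other NL
#' phase introducing the irrelevant categories; and a Final Test in which every
#' studied item is tested once more. Items studied in the relevant NL phase are
#' flagged `is_critical` (they are learned exactly 48 h before the Final Test).
#'
#' @param config A [design_config()].
#' @param seed Top-level RNG seed; per-participant child streams are derived
#'   from it.
#' @return A tibble with one row per test trial (responses `NA`): columns
#'   `participant_id`, `group`, `phase`, `block`, `item_id`, `category`,
#'   `category_role`, `quadrant`, `is_critical`, `target`,
#'   `schema_mean_current` (mean in force at the test phase),
#'   `schema_mean_original` (mean before any shift), `schema_mean_study`
#'   (mean in force when the item was studied; differs from
#'   `schema_mean_current` only for Final Test rows of IS-studied
#'   inconsistent-category items), `response`.
#' @export
build_design <- function(config = design_config(), seed = 1) {
  validate_design_config(config)
  n_total <- 2 * config$n_per_group
  if (n_total == 0) return(empty_trial_table())
  groups <- rep(c("no_consolidation", "consolidation"), each = config$n_per_group)
  out <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(child_seed(seed, i))
    out[[i]] <- build_participant_design(
      sprintf("s%03d", i), groups[i], config
    )
  }
  dplyr::bind_rows(out)
}

empty_trial_table <- function() {
  tibble(
    participant_id = character(), group = character(), phase = character(),
    block = integer(), item_id = character(), category = character(),
    category_role = character(), quadrant = character(), is_critical = logical(),
    target = double(), schema_mean_current = double(),
    schema_mean_original = double(), schema_mean_study = double(),
    response = double()
  )
}

# one participant's full trial table; assumes the participant's RNG stream is set
build_participant_design <- function(pid, group, cfg) {
  natural <- cfg$categories[c(1, 4)]
  manmade <- cfg$categories[c(2, 3)]
  relevant <- c(sample(natural, 1), sample(manmade, 1))
  irrelevant <- setdiff(cfg$categories, relevant)
  centres <- setNames(sample(cfg$quadrant_centres), cfg$categories)
  inconsistent <- sample(relevant, 1)
  role <- setNames(rep("irrelevant", 4), cfg$categories)
  role[relevant] <- "consistent"
  role[inconsistent] <- "inconsistent"

  nl_relevant <- if (group == "no_consolidation") "NL1" else "NL2"
  nl_irrelevant <- setdiff(c("NL1", "NL2"), nl_relevant)

  make_phase <- function(phase, cats, shifted, n_blocks) {
    in_cat <- cfg$inside_per_block / 2
    out_cat <- cfg$outside_per_block / 2
    per_block_cat <- in_cat + out_cat
    rows <- expand.grid(
      block = seq_len(n_blocks), category = cats,
      slot = seq_len(per_block_cat), stringsAsFactors = FALSE
    )
    rows$quadrant <- ifelse(rows$slot <= in_cat, "inside", "outside")
    means_orig <- centres[rows$category]
    means_cur <- means_orig
    if (shifted) {
      shift_idx <- rows$category == inconsistent
      means_cur[shift_idx] <- wrap_circle(means_orig[shift_idx] + cfg$shift_deg)
    }
    target <- numeric(nrow(rows))
    inside <- rows$quadrant == "inside"
    target[inside] <- sample_target(means_cur[inside], "inside", sum(inside),
                                    margin = cfg$outside_margin_deg)
    target[!inside] <- sample_target(means_cur[!inside], "outside", sum(!inside),
                                     margin = cfg$outside_margin_deg)
    tibble(
      participant_id = pid, group = group, phase = phase,
      block = rows$block,
      item_id = sprintf("%s_%s_b%d_%02d", phase, substr(rows$category, 1, 2),
                        rows$block, rows$slot),
      category = rows$category,
      category_role = unname(role[rows$category]),
      quadrant = rows$quadrant,
      is_critical = shifted, # only the relevant NL phase carries shifted = TRUE
      target = target,
      schema_mean_current = unname(means_cur),
      schema_mean_original = unname(means_orig),
      schema_mean_study = unname(means_cur),
      response = NA_real_
    )
  }

  is_rows <- make_phase("IS", relevant, shifted = FALSE, cfg$blocks_is)
  nl_rel_rows <- make_phase(nl_relevant, relevant, shifted = TRUE, cfg$blocks_nl)
  nl_irr_rows <- make_phase(nl_irrelevant, irrelevant, shifted = FALSE, cfg$blocks_nl)
  nl_irr_rows$is_critical <- FALSE

  studied <- dplyr::bind_rows(is_rows, nl_rel_rows, nl_irr_rows)
  # shuffle test order within each study block
  studied <- studied |>
    dplyr::group_by(.data$phase, .data$block) |>
    dplyr::slice_sample(prop = 1) |>
    dplyr::ungroup()

  # Final Test: every studied item re-tested once, in randomized order across
  # blocks of ft_block_size; the inconsistent category's schema stays shifted
  ft <- studied[sample.int(nrow(studied)), ]
  ft$phase <- "FT"
  ft$block <- rep(seq_len(nrow(ft) / cfg$ft_block_size), each = cfg$ft_block_size)
  shift_idx <- ft$category_role == "inconsistent"
  ft$schema_mean_current[shift_idx] <-
    wrap_circle(ft$schema_mean_original[shift_idx] + cfg$shift_deg)

  dplyr::bind_rows(studied, ft)
}
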
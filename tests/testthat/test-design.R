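cfg_small <- design_config(n_per_group = 2)

test_that("the default design reproduces the study's trial bookkeeping", {
  d <- build_design(cfg_small, seed = 1)
  for (pid in unique(d$participant_id)) {
    p <- d[d$participant_id == pid, ]
    # 336 studied items, each tested twice (phase test + Final Test)
    expect_equal(length(unique(p$item_id)), 336)
    expect_equal(sum(p$phase != "FT"), 336)
    expect_equal(sum(p$phase == "FT"), 336)
    # IS and both NL phases: 4 blocks x 28 trials, 22 inside + 6 outside
    for (ph in c("IS", "NL1", "NL2")) {
      blocks <- table(p$block[p$phase == ph], p$quadrant[p$phase == ph])
      expect_equal(nrow(blocks), 4)
      expect_true(all(blocks[, "inside"] == 22))
      expect_true(all(blocks[, "outside"] == 6))
    }
    # Final Test: 6 blocks of 56
    expect_equal(unname(table(p$block[p$phase == "FT"])), rep(56L, 6L),
                 ignore_attr = TRUE)
    # critical items: the relevant NL phase's 112 items, 56 per category
    crit <- p[p$phase == "FT" & p$is_critical, ]
    expect_equal(nrow(crit), 112)
    expect_equal(unname(table(crit$category_role)), c(56L, 56L),
                 ignore_attr = TRUE)
    expect_setequal(unique(crit$category_role), c("consistent", "inconsistent"))
    # the relevant NL phase matches the group's consolidation schedule
    nl_rel <- unique(p$phase[p$is_critical & p$phase != "FT"])
    expect_equal(nl_rel, if (p$group[1] == "no_consolidation") "NL1" else "NL2")
  }
})

test_that("targets respect quadrant supports and the schema shift is local and -90", {
  d <- build_design(cfg_small, seed = 5)
  ins <- d$quadrant == "inside"
  expect_true(all(abs(circ_dist(d$target[ins], d$schema_mean_study[ins])) <= 45 + 1e-9))
  expect_true(all(abs(circ_dist(d$target[!ins], d$schema_mean_study[!ins])) >= 75 - 1e-9))
  # only the inconsistent category ever shifts, by exactly -90 (clockwise),
  # and only from the NL phase onward
  shifted <- d$schema_mean_current != d$schema_mean_original
  expect_true(all(d$category_role[shifted] == "inconsistent"))
  expect_true(all(circ_dist(d$schema_mean_current[shifted],
                            d$schema_mean_original[shifted]) == -90))
  inc <- d$category_role == "inconsistent"
  expect_true(all(d$schema_mean_current[inc & d$phase == "IS"] ==
                    d$schema_mean_original[inc & d$phase == "IS"]))
  expect_true(all(shifted[inc & d$phase == "FT"]))
})

test_that("design scales linearly and validates its count identities", {
  one <- design_config(n_per_group = 1, blocks_is = 1, blocks_nl = 1,
                       ft_block_size = 28)
  d <- build_design(one, seed = 2)
  d <- d[d$participant_id == d$participant_id[1], ] # one participant per group
  expect_equal(sum(d$phase != "FT"), 3 * 28)
  expect_equal(sum(d$phase == "FT"), 3 * 28)
  blocks <- table(d$quadrant[d$phase == "IS"])
  expect_equal(unname(blocks[c("inside", "outside")]), c(22L, 6L),
               ignore_attr = TRUE)
  expect_error(design_config(inside_per_block = 21, outside_per_block = 7),
               "evenly")
  expect_error(design_config(trials_per_block = 30), "equal")
  expect_error(design_config(quadrant_centres = c(0, 45, 180, 270)), "90")
  # zero participants: empty table with the full schema
  d0 <- build_design(design_config(n_per_group = 0), seed = 1)
  expect_equal(nrow(d0), 0)
  expect_true(all(c("participant_id", "target", "response") %in% names(d0)))
})

test_that("design generation is deterministic per seed with participant child streams", {
  d1 <- build_design(cfg_small, seed = 9)
  d2 <- build_design(cfg_small, seed = 9)
  expect_identical(d1, d2)
  d3 <- build_design(cfg_small, seed = 10)
  expect_false(identical(d1$target, d3$target))
  # first participant unchanged when the cohort grows (child streams)
  d4 <- build_design(design_config(n_per_group = 3), seed = 9)
  expect_identical(d1[d1$participant_id == "s001", ],
                   d4[d4$participant_id == "s001", ])
})
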
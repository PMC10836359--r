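test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_sim_config(seed = 14)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$loads, c2$loads)
  expect_identical(c1$truth$enterotype, c2$truth$enterotype)
})

test_that("sample identifiers align across every cohort component", {
  cohort <- simulate_cohort(tiny_sim_config(seed = 3))
  ids <- colnames(cohort$counts)
  expect_identical(ids, cohort$participants$participant_id)
  expect_identical(ids, names(cohort$loads))
  expect_identical(ids, names(cohort$calprotectin))
  expect_identical(names(cohort$truth$enterotype), ids)
  expect_true(all(cohort$counts >= 0))
  expect_true(all(cohort$counts == round(cohort$counts)))
  expect_true(all(cohort$loads > 0))
  expect_setequal(rownames(cohort$counts), cohort$taxonomy$taxon_id)
})

test_that("intended labels are recovered for every participant", {
  for (seed in c(2, 9)) {
    cohort <- simulate_cohort(tiny_sim_config(seed = seed))
    got <- classify_cohort(cohort$participants)$group
    expect_identical(got, unname(cohort$truth$intended_group))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(group_sizes = c(control = 0, high_genetic_risk = 5,
                                                 autoimmunity = 5, symptomatic = 5)),
               "control")
  expect_error(tiny_sim_config(effect_spec = list(
    list(taxa = "NotAGenus", group = "symptomatic", fold = 2))), "unknown taxa")
  expect_error(tiny_sim_config(effect_spec = list(
    list(family = "Prevotellaceae", group = "symptomatic", fold = -1))), "> 0")
  expect_error(tiny_sim_config(enterotype_mixing = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("an injected fold-change raises the target family's relative abundance", {
  rel_prev <- function(cohort) {
    fam <- aggregate_taxa(to_relative(cohort$counts), cohort$taxonomy, "family")
    grp <- cohort$truth$intended_group
    c(target = median(fam["Prevotellaceae", grp == "symptomatic"]),
      control = median(fam["Prevotellaceae", grp == "control"]))
  }
  wins <- 0
  for (r in 1:15) {
    cfg <- tiny_sim_config(seed = 300 + r, effect_spec = list(
      list(family = "Prevotellaceae", group = "symptomatic", fold = 3)))
    m <- rel_prev(simulate_cohort(cfg))
    wins <- wins + (m["target"] > m["control"])
  }
  expect_gte(wins, 14)
})

test_that("cohorts round-trip through the on-disk dialects", {
  cohort <- simulate_cohort(tiny_sim_config(seed = 6))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_error(write_cohort(cohort, dir), "overwrite")
  back <- read_cohort(dir)
  expect_equal(back$counts, cohort$counts)
  expect_equal(back$copy_numbers, cohort$copy_numbers)
  expect_equal(back$loads, cohort$loads)
  expect_equal(back$calprotectin, cohort$calprotectin)
  expect_equal(as.data.frame(back$participants), as.data.frame(cohort$participants))
  expect_equal(back$truth$enterotype, cohort$truth$enterotype)
  expect_equal(length(back$truth$effects), 0)
  # overwrite flag replaces in place
  expect_silent(write_cohort(cohort, dir, overwrite = TRUE))
})

test_that("the default design emits 371 participants in four groups", {
  cohort <- simulate_cohort(simulation_config(seed = 17))
  expect_equal(ncol(cohort$counts), 371)
  expect_equal(unname(table(cohort$truth$intended_group)[
    c("control", "high_genetic_risk", "autoimmunity", "symptomatic")]),
    c(226L, 50L, 49L, 46L), ignore_attr = TRUE)
  expect_equal(sum(cohort$participants$ra_diagnosis), 8)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  meta <- readr::read_csv(file.path(dir, "metadata.csv"), show_col_types = FALSE)
  expect_equal(nrow(meta), 371)
})
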
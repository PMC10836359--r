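test_that("CSA score counts positives and missing items", {
  expect_equal(csa_score(c(1, 1, 1, 1, 0, 0, 0)), list(score = 4L, n_missing = 0L))
  expect_equal(csa_score(c(1, 1, 1, 0, 0, 0, NA)), list(score = 3L, n_missing = 1L))
  expect_equal(csa_score(rep(NA, 7)), list(score = 0L, n_missing = 7L))
  expect_error(csa_score(c(1, 0)), "7 items")
})

test_that("serology categories follow the ULN thresholds", {
  rf_high <- serology_category(45, 15, "rf") # exactly 3x ULN
  expect_equal(rf_high$category, "high")
  expect_true(rf_high$significant)

  acpa_low <- serology_category(20, 20, "acpa") # exactly 1x ULN
  expect_equal(acpa_low$category, "low")
  expect_true(acpa_low$significant)

  rf_low <- serology_category(22.5, 15, "rf") # 1.5x ULN
  expect_equal(rf_low$category, "low")
  expect_false(rf_low$significant)

  miss <- serology_category(NA, 20, "ra33")
  expect_equal(miss$category, "missing")
  expect_false(miss$significant)
})

test_that("stage assignment follows the rule precedence", {
  # healthy asymptomatic relative with sub-threshold serology -> control
  ctrl <- classify_participant(base_record(se_copies = 1L))
  expect_equal(ctrl$group, "control")

  # two shared-epitope copies, nothing else -> high genetic risk
  hgr <- classify_participant(base_record(se_copies = 2L))
  expect_equal(hgr$group, "high_genetic_risk")

  # CSA score 3 with RF at 5x ULN: lowered cutoff via concomitant autoimmunity
  symp <- classify_participant(set_csa(base_record(rf_titre = 75), 3))
  expect_equal(symp$group, "symptomatic")
  expect_equal(symp$csa_cutoff_used, "lowered")
  expect_true(symp$autoimmunity_flag)

  # the same score without autoimmunity stays below the standard cutoff
  asym <- classify_participant(set_csa(base_record(), 3))
  expect_equal(asym$group, "control")

  # one missing item also lowers the cutoff
  miss1 <- classify_participant(set_csa(base_record(), 3, n_missing = 1))
  expect_equal(miss1$group, "symptomatic")

  # diagnosed RA dominates everything
  ra <- classify_participant(base_record(ra_diagnosis = TRUE, se_copies = 2L))
  expect_equal(ra$group, "symptomatic")
  expect_equal(ra$rationale, substring(ra$rationale, 1, nchar(ra$rationale)))
  expect_match(ra$rationale, "ra_diagnosis")

  # significant autoimmunity without symptoms
  ai <- classify_participant(base_record(acpa_titre = 25))
  expect_equal(ai$group, "autoimmunity")

  # missing genotype with no rule fired falls back to control, flagged
  na_se <- classify_participant(base_record(se_copies = NA))
  expect_equal(na_se$group, "control")
  expect_match(na_se$rationale, "se_copies_missing")

  # missing anti-Ra33 can neither rescue nor block
  na_ra33 <- classify_participant(base_record(ra33_titre = NA, se_copies = 2L))
  expect_equal(na_ra33$group, "high_genetic_risk")
  expect_match(na_ra33$rationale, "ra33_missing")
})

test_that("raising a titre never moves a participant toward control", {
  rank_of <- c(control = 0, high_genetic_risk = 0, autoimmunity = 1, symptomatic = 2)
  set.seed(42)
  for (i in 1:30) {
    rec <- set_csa(
      base_record(se_copies = sample(0:2, 1), acpa_titre = runif(1, 0, 60),
                  rf_titre = runif(1, 0, 60), ra33_titre = runif(1, 0, 90)),
      n_pos = sample(0:5, 1), n_missing = sample(0:2, 1)
    )
    before <- classify_participant(rec)$group
    analyte <- sample(c("acpa_titre", "rf_titre", "ra33_titre"), 1)
    rec[[analyte]] <- rec[[analyte]] * 10
    after <- classify_participant(rec)$group
    expect_gte(rank_of[[after]], rank_of[[before]])
    # idempotence
    expect_identical(classify_participant(rec), classify_participant(rec))
  }
})

test_that("classification partitions the cohort", {
  cohort <- simulate_cohort(tiny_sim_config(seed = 8))
  asn <- classify_cohort(cohort$participants)
  expect_equal(nrow(asn), nrow(cohort$participants))
  expect_true(all(asn$group %in% c("control", "high_genetic_risk",
                                   "autoimmunity", "symptomatic")))
  expect_equal(sum(table(asn$group)), nrow(asn))
  expect_true(all(nzchar(asn$rationale)))
})

test_that("pronounced-subgroup selection ranks, breaks ties and matches", {
  cohort <- simulate_cohort(simulation_config(
    group_sizes = c(control = 30L, high_genetic_risk = 8L,
                    autoimmunity = 8L, symptomatic = 10L),
    n_taxa = 20L, n_ra_symptomatic = 3L, seed = 5
  ))
  asn <- classify_cohort(cohort$participants)
  sub <- select_pronounced_subgroups(asn, cohort$participants, k = 5L)
  expect_equal(unname(table(sub$group)[c("control", "high_genetic_risk",
                                         "autoimmunity", "symptomatic")]),
               rep(5L, 4), ignore_attr = TRUE)

  # every diagnosed-RA participant outranks the rest of the symptomatic group
  ra_ids <- cohort$participants$participant_id[cohort$participants$ra_diagnosis]
  expect_true(all(ra_ids %in% sub$participant_id[sub$group == "symptomatic"]))

  # controls are matched on exact sex
  meta <- cohort$participants
  sex_of <- setNames(meta$sex, meta$participant_id)
  symp_sex <- sort(table(sex_of[sub$participant_id[sub$group == "symptomatic"]]))
  ctrl_sex <- sort(table(sex_of[sub$participant_id[sub$group == "control"]]))
  expect_equal(as.list(symp_sex), as.list(ctrl_sex))

  # a group of exactly k members is selected wholesale
  sub_all <- select_pronounced_subgroups(asn, cohort$participants, k = 8L)
  expect_setequal(sub_all$participant_id[sub_all$group == "autoimmunity"],
                  asn$participant_id[asn$group == "autoimmunity"])

  expect_error(select_pronounced_subgroups(asn, cohort$participants, k = 11L),
               "fewer than k")
})

test_that("identical phenotypes at the rank boundary resolve by participant id", {
  meta <- purrr::map_dfr(1:6, function(i) {
    tibble::as_tibble(set_csa(base_record(participant_id = sprintf("P%02d", i),
                                          acpa_titre = 30), 2))
  })
  # add controls for matching
  ctrl <- purrr::map_dfr(7:12, function(i) {
    tibble::as_tibble(base_record(participant_id = sprintf("P%02d", i),
                                  se_copies = 1L))
  })
  hgr <- purrr::map_dfr(13:18, function(i) {
    tibble::as_tibble(base_record(participant_id = sprintf("P%02d", i),
                                  se_copies = 2L))
  })
  symp <- purrr::map_dfr(19:24, function(i) {
    tibble::as_tibble(set_csa(base_record(participant_id = sprintf("P%02d", i)), 5))
  })
  meta <- dplyr::bind_rows(meta, ctrl, hgr, symp)
  asn <- classify_cohort(meta)
  sub <- select_pronounced_subgroups(asn, meta, k = 3L)
  # all six autoimmunity members are identical: the three lowest ids win
  expect_equal(sub$participant_id[sub$group == "autoimmunity"],
               c("P01", "P02", "P03"))
})
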
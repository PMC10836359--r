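#' Clinically suspect arthralgia (CSA) score
#'
#' Counts positive items among the 7-item EULAR arthralgia checklist, reporting
#' separately how many items were missing.
#'
#' @param items Vector of exactly 7 indicators; each `TRUE`/`FALSE`/`NA`
#'   (or 1/0/NA).
#' @return A list with `score` (number of positive non-missing items) and
#'   `n_missing` (number of missing items).
#' @examples
#' csa_score(c(1, 1, 1, 1, 0, 0, 0))
#' @export
csa_score <- function(items) {
  if (length(items) != 7L) abort("a CSA checklist has exactly 7 items")
  items <- as.logical(items)
  list(score = sum(items, na.rm = TRUE), n_missing = sum(is.na(items)))
}

#' Categorise an autoantibody titre against its assay's upper limit of normal
#'
#' ACPA, rheumatoid factor (RF) and anti-Ra33 titres are categorised as
#' negative (< ULN), low, or high (>= 3x ULN). Clinical significance follows
#' the risk-stage definitions: ACPA is significant from 1x ULN, RF and
#' anti-Ra33 only from 3x ULN.
#'
#' @param titre Assay titre; `NA` for missing.
#' @param uln Upper limit of normal of the assay (> 0 when titre present).
#' @param analyte One of `"acpa"`, `"rf"`, `"ra33"`.
#' @return A tibble with `analyte`, `category` (negative/low/high/missing) and
#'   `significant` (logical; `FALSE` when missing).
#' @export
serology_category <- function(titre, uln, analyte = c("acpa", "rf", "ra33")) {
  analyte <- match.arg(analyte)
  if (is.na(titre)) {
    return(tibble::tibble(analyte = analyte, category = "missing", significant = FALSE))
  }
  if (is.na(uln) || uln <= 0) abort("`uln` must be positive when the titre is present")
  if (titre < 0) abort("titres must be non-negative")
  category <- if (titre < uln) "negative" else if (titre >= 3 * uln) "high" else "low"
  significant <- if (analyte == "acpa") titre >= uln else titre >= 3 * uln
  tibble::tibble(analyte = analyte, category = category, significant = significant)
}

serology_significant <- function(record) {
  any(
    serology_category(record$acpa_titre, record$acpa_uln, "acpa")$significant,
    serology_category(record$rf_titre, record$rf_uln, "rf")$significant,
    # missing anti-Ra33 can neither rescue nor block any rule
    serology_category(record$ra33_titre, record$ra33_uln, "ra33")$significant
  )
}

#' Assign a participant to a preclinical rheumatoid-arthritis stage
#'
#' Implements the four-stage assignment algorithm for first-degree-relative
#' cohorts. Rules fire in precedence order:
#' \enumerate{
#'   \item diagnosed RA is `symptomatic`;
#'   \item a CSA score at or above the cutoff is `symptomatic` - the standard
#'     cutoff is 4, lowered to `lowered_cutoff` (default 3) when one or two
#'     checklist items are missing or when clinically significant autoimmunity
#'     is concomitant;
#'   \item asymptomatic participants with clinically significant autoimmunity
#'     (ACPA >= ULN, or RF / anti-Ra33 >= 3x ULN) are `autoimmunity`;
#'   \item two shared-epitope copies make `high_genetic_risk`;
#'   \item everyone else is `control`.
#' }
#' A missing shared-epitope genotype with no earlier rule fired is classified
#' `control` and flagged in the rationale.
#'
#' @param record A one-row data frame or named list with fields
#'   `participant_id`, `age`, `sex`, `se_copies`, `acpa_titre`, `acpa_uln`,
#'   `rf_titre`, `rf_uln`, `ra33_titre`, `ra33_uln`, `csa_item_1` ..
#'   `csa_item_7`, `ra_diagnosis`.
#' @param csa_cutoff Standard CSA cutoff (default 4).
#' @param lowered_cutoff Lowered cutoff applied with 1-2 missing items or
#'   concomitant autoimmunity (default 3).
#' @return A one-row tibble: `participant_id`, `group`, `csa_score`,
#'   `csa_n_missing`, `csa_cutoff_used`, `autoimmunity_flag`, `rationale`
#'   (rule identifiers fired, `;`-separated).
#' @export
classify_participant <- function(record, csa_cutoff = 4L, lowered_cutoff = 3L) {
  record <- as.list(record)
  items <- unlist(record[paste0("csa_item_", 1:7)], use.names = FALSE)
  cs <- csa_score(items)
  autoimmune <- serology_significant(record)
  rationale <- character()

  lowered_applies <- cs$n_missing %in% c(1L, 2L) || autoimmune
  cutoff <- if (lowered_applies) lowered_cutoff else csa_cutoff
  cutoff_used <- "not_applicable"
  group <- NULL

  if (isTRUE(as.logical(record$ra_diagnosis))) {
    group <- "symptomatic"
    rationale <- c(rationale, "ra_diagnosis")
  } else if (cs$n_missing < 7L && cs$score >= cutoff) {
    group <- "symptomatic"
    cutoff_used <- if (lowered_applies) "lowered" else "standard"
    rationale <- c(rationale, sprintf("csa_score>=%d(%s)", cutoff, cutoff_used))
  } else {
    cutoff_used <- if (lowered_applies) "lowered" else "standard"
    if (autoimmune) {
      group <- "autoimmunity"
      rationale <- c(rationale, "significant_serology")
    } else if (!is.na(record$se_copies) && record$se_copies == 2) {
      group <- "high_genetic_risk"
      rationale <- c(rationale, "se_copies==2")
    } else {
      group <- "control"
      rationale <- c(rationale, "no_rule_fired")
      if (is.na(record$se_copies)) {
        rationale <- c(rationale, "se_copies_missing_assumed_not_2")
      }
    }
  }
  if (is.na(record$ra33_titre)) {
    rationale <- c(rationale, "ra33_missing_treated_nonsignificant")
  }
  tibble::tibble(
    participant_id = as.character(record$participant_id),
    group = group,
    csa_score = cs$score,
    csa_n_missing = cs$n_missing,
    csa_cutoff_used = cutoff_used,
    autoimmunity_flag = autoimmune,
    rationale = paste(rationale, collapse = ";")
  )
}

#' Classify every participant of a cohort
#'
#' @param metadata Participant metadata tibble (one row per participant, in the
#'   `metadata.csv` dialect written by [write_cohort()]).
#' @inheritParams classify_participant
#' @return A tibble of stage assignments, one row per participant, in input
#'   order.
#' @export
classify_cohort <- function(metadata, csa_cutoff = 4L, lowered_cutoff = 3L) {
  purrr::map_dfr(
    seq_len(nrow(metadata)),
    function(i) classify_participant(metadata[i, ], csa_cutoff, lowered_cutoff)
  )
}

titre_ratio <- function(metadata) {
  # scale-free severity: ACPA relative to ULN; RF and anti-Ra33 relative to
  # their 3x-ULN significance threshold, so 1 means "just significant"
  ratio <- function(t, u, mult) ifelse(is.na(t), -Inf, t / (mult * u))
  pmax(
    ratio(metadata$acpa_titre, metadata$acpa_uln, 1),
    ratio(metadata$rf_titre, metadata$rf_uln, 3),
    ratio(metadata$ra33_titre, metadata$ra33_uln, 3)
  )
}

#' Select the most pronounced phenotypes of each non-control group
#'
#' Ranks each non-control group by (RA diagnosis, then CSA score, then the
#' maximum titre-to-threshold ratio over ACPA/RF/anti-Ra33) and takes the top
#' `k`, with ties broken by participant id. A control subgroup of size `k` is
#' then matched to the symptomatic subgroup by exact sex and greedy
#' nearest-age.
#'
#' @param assignments Tibble from [classify_cohort()].
#' @param metadata Participant metadata tibble.
#' @param k Subgroup size (default 20).
#' @return A tibble `participant_id`, `group`, `rank` (selection order) with
#'   `k` rows per group including the matched control subgroup.
#' @export
select_pronounced_subgroups <- function(assignments, metadata, k = 20L) {
  stopifnot(all(assignments$participant_id == metadata$participant_id))
  df <- dplyr::left_join(assignments, metadata, by = "participant_id")
  df$titre_ratio <- titre_ratio(df)
  df$csa_rank <- ifelse(is.na(df$csa_score), -1L, df$csa_score)
  df$ra <- as.logical(df$ra_diagnosis) %in% TRUE

  selected <- list()
  for (g in c("high_genetic_risk", "autoimmunity", "symptomatic")) {
    pool <- df[df$group == g, ]
    if (nrow(pool) < k) {
      abort(sprintf("group '%s' has %d members, fewer than k = %d", g, nrow(pool), k))
    }
    ord <- order(-pool$ra, -pool$csa_rank, -pool$titre_ratio, pool$participant_id)
    selected[[g]] <- tibble::tibble(
      participant_id = pool$participant_id[ord][seq_len(k)],
      group = g, rank = seq_len(k)
    )
  }

  # sex-exact, age-nearest greedy matching of controls to the symptomatic set
  controls <- df[df$group == "control", ]
  symp <- df[df$participant_id %in% selected[["symptomatic"]]$participant_id, ]
  symp <- symp[order(symp$participant_id), ]
  available <- rep(TRUE, nrow(controls))
  picked <- character(0)
  for (i in seq_len(nrow(symp))) {
    cand <- which(available & controls$sex == symp$sex[i])
    if (length(cand) == 0L) {
      abort(sprintf("no unused control of sex '%s' left for matching", symp$sex[i]))
    }
    gap <- abs(controls$age[cand] - symp$age[i])
    best <- cand[order(gap, controls$participant_id[cand])][1L]
    available[best] <- FALSE
    picked <- c(picked, controls$participant_id[best])
  }
  selected[["control"]] <- tibble::tibble(
    participant_id = picked, group = "control", rank = seq_len(k)
  )
  dplyr::bind_rows(selected[c("control", "high_genetic_risk", "autoimmunity", "symptomatic")])
}
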
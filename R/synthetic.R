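#' Configuration for the synthetic-cohort generator
#'
#' Builds and validates the parameter set from which [simulate_cohort()] draws
#' a complete synthetic cohort: four-stage group sizes, a genus universe with
#' enterotype-structured Dirichlet composition profiles, sequencing-depth and
#' microbial-load distributions, 16S copy numbers, optional injected
#' relative-abundance effects and faecal calprotectin.
#'
#' Defaults emulate the study design the package targets: 226 controls, 50
#' high-genetic-risk, 49 autoimmunity and 46 symptomatic participants (8 of
#' them with new-onset RA), four enterotypes (Bact1, Bact2, Prev, Rum),
#' log-normal loads with median 1e11 cells/g, per-taxon 16S copy numbers
#' uniform on [1, 12], and no injected group effect (the null cohort).
#'
#' @param group_sizes Named integer vector over
#'   `control`, `high_genetic_risk`, `autoimmunity`, `symptomatic`.
#' @param n_taxa Number of genera in the simulated universe.
#' @param enterotype_profiles Optional 4 x n_taxa matrix of positive Dirichlet
#'   concentrations (rows Bact1/Bact2/Prev/Rum); default built by
#'   [default_enterotype_profiles()].
#' @param enterotype_mixing Probability vector of length 4 (or 4 x 4 matrix,
#'   one row per group) giving each group's enterotype mixture.
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of
#'   per-sample read totals.
#' @param load_meanlog,load_sdlog Log-scale parameters of microbial load
#'   (cells per gram).
#' @param copy_number_range Range of per-ASV 16S copy numbers (uniform reals).
#' @param effect_spec List of effects, each
#'   `list(taxa = <genus ids> | family = <family>, group = <group>, fold = <positive>)`,
#'   applied multiplicatively to relative abundances before renormalisation.
#' @param calprotectin_meanlog,calprotectin_sdlog Log-scale calprotectin
#'   parameters (ug/g).
#' @param calprotectin_group_shift Named additive log-scale shift per group.
#' @param ra33_missing_prob Probability that anti-Ra33 serology is missing.
#' @param csa_missing_prob Per-item probability that a CSA item is missing.
#' @param n_ra_symptomatic Number of diagnosed-RA participants inside the
#'   symptomatic group.
#' @param asv_per_genus_max Each genus is split into 1..max ASVs with
#'   Dirichlet-distributed proportions.
#' @param seed Integer seed; the entire cohort is a deterministic function of
#'   the configuration.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(
    group_sizes = c(control = 226L, high_genetic_risk = 50L,
                    autoimmunity = 49L, symptomatic = 46L),
    n_taxa = 120L,
    enterotype_profiles = NULL,
    enterotype_mixing = c(Bact1 = 0.35, Bact2 = 0.25, Prev = 0.15, Rum = 0.25),
    depth_mean = 20000, depth_dispersion = 10,
    load_meanlog = log(1e11), load_sdlog = 0.5,
    copy_number_range = c(1, 12),
    effect_spec = list(),
    calprotectin_meanlog = log(30), calprotectin_sdlog = 1,
    calprotectin_group_shift = c(control = 0, high_genetic_risk = 0,
                                 autoimmunity = 0, symptomatic = 0),
    ra33_missing_prob = 0.2,
    csa_missing_prob = 0.03,
    n_ra_symptomatic = 8L,
    asv_per_genus_max = 5L,
    seed = 1L) {
  groups <- c("control", "high_genetic_risk", "autoimmunity", "symptomatic")
  if (!setequal(names(group_sizes), groups)) {
    abort("`group_sizes` must be named control/high_genetic_risk/autoimmunity/symptomatic")
  }
  group_sizes <- group_sizes[groups]
  if (group_sizes[["control"]] < 1L) abort("the control group cannot be empty")
  if (any(group_sizes < 0)) abort("group sizes must be non-negative")

  taxonomy <- default_genus_universe(n_taxa)
  if (is.null(enterotype_profiles)) {
    enterotype_profiles <- default_enterotype_profiles(taxonomy)
  }
  stopifnot(nrow(enterotype_profiles) == 4L, ncol(enterotype_profiles) == n_taxa)
  if (any(enterotype_profiles <= 0)) abort("enterotype concentrations must be positive")

  if (is.matrix(enterotype_mixing)) {
    mixing <- enterotype_mixing
  } else {
    mixing <- matrix(rep(enterotype_mixing, each = 4L), nrow = 4L,
                     dimnames = list(groups, names(enterotype_mixing)))
  }
  if (any(abs(rowSums(mixing) - 1) > 1e-9)) {
    abort("enterotype mixing probabilities must sum to 1")
  }
  if (depth_mean <= 0 || depth_dispersion <= 0 || load_sdlog < 0) {
    abort("depth and load parameters must be positive")
  }
  if (length(copy_number_range) != 2L || copy_number_range[1] < 1) {
    abort("`copy_number_range` must be c(lo, hi) with lo >= 1")
  }
  for (eff in effect_spec) {
    if (!is.null(eff$family)) {
      eff$taxa <- taxonomy$genus[taxonomy$family == eff$family]
      if (length(eff$taxa) == 0L) abort(sprintf("unknown family '%s' in effect_spec", eff$family))
    }
    unknown <- setdiff(eff$taxa, taxonomy$genus)
    if (length(unknown)) abort(sprintf("effect_spec names unknown taxa: %s",
                                       paste(unknown, collapse = ", ")))
    if (!eff$group %in% groups) abort(sprintf("unknown group '%s' in effect_spec", eff$group))
    if (is.null(eff$fold) || eff$fold <= 0) abort("effect fold-changes must be > 0")
  }
  structure(list(
    group_sizes = group_sizes, n_taxa = as.integer(n_taxa),
    taxonomy = taxonomy,
    enterotype_profiles = enterotype_profiles,
    enterotype_mixing = mixing,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    load_meanlog = load_meanlog, load_sdlog = load_sdlog,
    copy_number_range = copy_number_range,
    effect_spec = effect_spec,
    calprotectin_meanlog = calprotectin_meanlog,
    calprotectin_sdlog = calprotectin_sdlog,
    calprotectin_group_shift = calprotectin_group_shift[groups],
    ra33_missing_prob = ra33_missing_prob,
    csa_missing_prob = csa_missing_prob,
    n_ra_symptomatic = as.integer(n_ra_symptomatic),
    asv_per_genus_max = as.integer(asv_per_genus_max),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Genus universe: common gut genera with their families up front, synthetic
# filler genera behind, so family-level aggregation (Prevotellaceae etc.) is
# meaningful.
default_genus_universe <- function(n_taxa) {
  named <- tibble::tribble(
    ~genus, ~family,
    "Bacteroides", "Bacteroidaceae",
    "Phocaeicola", "Bacteroidaceae",
    "Prevotella", "Prevotellaceae",
    "Paraprevotella", "Prevotellaceae",
    "Alloprevotella", "Prevotellaceae",
    "Faecalibacterium", "Ruminococcaceae",
    "Ruminococcus", "Ruminococcaceae",
    "Subdoligranulum", "Ruminococcaceae",
    "Anaerotruncus", "Ruminococcaceae",
    "Blautia", "Lachnospiraceae",
    "Roseburia", "Lachnospiraceae",
    "Coprococcus", "Lachnospiraceae",
    "Dorea", "Lachnospiraceae",
    "Anaerostipes", "Lachnospiraceae",
    "Agathobacter", "Lachnospiraceae",
    "Oscillibacter", "Oscillospiraceae",
    "Flavonifractor", "Oscillospiraceae",
    "Akkermansia", "Akkermansiaceae",
    "Bifidobacterium", "Bifidobacteriaceae",
    "Streptococcus", "Streptococcaceae",
    "Lactobacillus", "Lactobacillaceae",
    "Escherichia_Shigella", "Enterobacteriaceae",
    "Veillonella", "Veillonellaceae",
    "Dialister", "Veillonellaceae",
    "Alistipes", "Rikenellaceae",
    "Parabacteroides", "Tannerellaceae",
    "Christensenella", "Christensenellaceae",
    "Eubacterium", "Eubacteriaceae",
    "Fusobacterium", "Fusobacteriaceae",
    "Sutterella", "Sutterellaceae",
    "Phascolarctobacterium", "Acidaminococcaceae",
    "Butyricimonas", "Marinifilaceae",
    "Bilophila", "Desulfovibrionaceae",
    "Holdemanella", "Erysipelotrichaceae"
  )
  if (n_taxa < 8L) abort("`n_taxa` must be at least 8 to carry the enterotype structure")
  if (n_taxa <= nrow(named)) {
    out <- named[seq_len(n_taxa), ]
  } else {
    n_extra <- n_taxa - nrow(named)
    extra <- tibble::tibble(
      genus = sprintf("Genus_%03d", seq_len(n_extra)),
      family = sprintf("Family_%02d", (seq_len(n_extra) - 1L) %% 12L + 1L)
    )
    out <- dplyr::bind_rows(named, extra)
  }
  out$kingdom <- "Bacteria"
  out$phylum <- dplyr::case_when(
    out$family %in% c("Bacteroidaceae", "Prevotellaceae", "Rikenellaceae",
                      "Tannerellaceae", "Marinifilaceae") ~ "Bacteroidota",
    out$family %in% c("Enterobacteriaceae", "Sutterellaceae",
                      "Desulfovibrionaceae") ~ "Proteobacteria",
    out$family == "Akkermansiaceae" ~ "Verrucomicrobiota",
    out$family == "Fusobacteriaceae" ~ "Fusobacteriota",
    out$family == "Bifidobacteriaceae" ~ "Actinobacteriota",
    TRUE ~ "Firmicutes"
  )
  out$class <- paste0(sub("ota$|eria$", "", out$phylum), "ia")
  out$order <- sub("aceae$", "ales", out$family)
  out[, c("genus", "family", "order", "class", "phylum", "kingdom")]
}

#' Default enterotype concentration profiles
#'
#' Four Dirichlet concentration vectors over the genus universe, shaped after
#' the canonical gut community types: two Bacteroides-dominated profiles
#' (Bact1 diverse, Bact2 low-richness), a Prevotella-dominated profile (Prev)
#' and a Ruminococcaceae-dominated profile (Rum).
#'
#' @param taxonomy Genus universe tibble (columns `genus`, `family`).
#' @return A 4 x n_taxa matrix of positive concentrations.
#' @export
default_enterotype_profiles <- function(taxonomy) {
  s <- nrow(taxonomy)
  base <- exp(-0.04 * seq_len(s)) # rank-abundance baseline
  names(base) <- taxonomy$genus
  boost <- function(b, theta) {
    w <- base * b
    theta * w / sum(w)
  }
  one <- rep(1, s); names(one) <- taxonomy$genus
  set_if <- function(v, nm, val) { # tolerate truncated genus universes
    nm <- intersect(nm, names(v)); v[nm] <- val[seq_along(nm)]; v
  }
  b1 <- set_if(one, c("Bacteroides", "Phocaeicola", "Alistipes"), c(10, 5, 3))
  b2 <- set_if(one, c("Bacteroides", "Phocaeicola"), c(35, 6))
  pr <- set_if(one, c("Prevotella", "Paraprevotella", "Alloprevotella"), c(35, 6, 3))
  rm_ <- set_if(one, c("Ruminococcus", "Faecalibacterium", "Subdoligranulum", "Blautia"),
                c(10, 8, 5, 3))
  profiles <- rbind(
    Bact1 = boost(b1, 60),
    Bact2 = boost(b2, 25),
    Prev = boost(pr, 45),
    Rum = boost(rm_, 60)
  )
  colnames(profiles) <- taxonomy$genus
  profiles
}

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a complete synthetic cohort
#'
#' Draws, per participant: a stage-consistent metadata record (serology
#' titres/ULNs, shared-epitope genotype, CSA checklist, RA diagnosis,
#' demographics), a latent enterotype, a genus composition from that
#' enterotype's Dirichlet profile (with any configured fold-change effects
#' applied and renormalised), ASV-level multinomial counts at a
#' negative-binomial read depth, a log-normal microbial load and calprotectin
#' value, and per-ASV 16S copy numbers. The generator verifies that
#' [classify_participant()] recovers the intended group for every participant
#' and fails otherwise.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `synthetic_cohort`: `participants` (metadata
#'   tibble), `counts` (ASV x sample integer matrix), `taxonomy` (ASV-level
#'   tibble), `copy_numbers`, `loads`, `calprotectin` (named vectors), and
#'   `truth` (seed, latent enterotypes, injected effects).
#' @examples
#' cfg <- simulation_config(group_sizes = c(control = 8, high_genetic_risk = 3,
#'                                          autoimmunity = 3, symptomatic = 4),
#'                          n_taxa = 20, n_ra_symptomatic = 1, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$counts)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_maybe(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  groups <- names(config$group_sizes)
  n <- sum(config$group_sizes)
  intended <- rep(groups, times = config$group_sizes)
  ids <- sprintf("P%04d", seq_len(n))

  # diagnosed-RA participants: a fixed number inside the symptomatic group
  ra_flag <- rep(FALSE, n)
  symp_idx <- which(intended == "symptomatic")
  ra_flag[head(symp_idx, config$n_ra_symptomatic)] <- TRUE

  participants <- purrr::map_dfr(seq_len(n), function(i) {
    generate_participant(ids[i], intended[i], config, ra_flag[i])
  })
  got <- classify_cohort(participants)$group
  if (!all(got == intended)) {
    abort(sprintf("generator round-trip failed for %d participants", sum(got != intended)))
  }

  # ASV split of the genus universe, fixed for the cohort
  genus <- config$taxonomy$genus
  n_asv <- sample(seq_len(config$asv_per_genus_max), length(genus), replace = TRUE)
  asv_genus <- rep(genus, times = n_asv)
  asv_ids <- sprintf("ASV_%04d", seq_along(asv_genus))
  split_prop <- unlist(lapply(n_asv, function(k) rdirichlet_one(rep(2, k))))

  taxonomy <- dplyr::left_join(
    tibble::tibble(taxon_id = asv_ids, genus = asv_genus),
    config$taxonomy, by = "genus"
  )[, c("taxon_id", "kingdom", "phylum", "class", "order", "family", "genus")]

  profiles <- config$enterotype_profiles
  enterotype <- character(n)
  counts <- matrix(0L, nrow = length(asv_ids), ncol = n,
                   dimnames = list(asv_ids, ids))
  depths <- pmax(rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion), 500L)
  genus_index <- match(asv_genus, genus)

  for (i in seq_len(n)) {
    et <- sample(colnames(config$enterotype_mixing), 1L,
                 prob = config$enterotype_mixing[intended[i], ])
    enterotype[i] <- et
    p <- rdirichlet_one(profiles[et, ])
    for (eff in config$effect_spec) {
      if (intended[i] != eff$group) next
      taxa <- if (!is.null(eff$family)) {
        config$taxonomy$genus[config$taxonomy$family == eff$family]
      } else eff$taxa
      idx <- match(taxa, genus)
      p[idx] <- p[idx] * eff$fold
      p <- p / sum(p)
    }
    stopifnot(abs(sum(p) - 1) < 1e-9)
    asv_p <- p[genus_index] * split_prop
    counts[, i] <- rmultinom(1L, size = depths[i], prob = asv_p)[, 1L]
  }

  copy_numbers <- setNames(
    runif(length(asv_ids), config$copy_number_range[1], config$copy_number_range[2]),
    asv_ids
  )
  loads <- setNames(rlnorm(n, config$load_meanlog, config$load_sdlog), ids)
  shift <- config$calprotectin_group_shift[intended]
  calprotectin <- setNames(
    rlnorm(n, config$calprotectin_meanlog + shift, config$calprotectin_sdlog), ids
  )

  structure(list(
    participants = participants,
    counts = counts,
    taxonomy = taxonomy,
    copy_numbers = copy_numbers,
    loads = loads,
    calprotectin = calprotectin,
    truth = list(
      seed = config$seed,
      intended_group = setNames(intended, ids),
      enterotype = setNames(enterotype, ids),
      effects = config$effect_spec,
      group_sizes = as.list(config$group_sizes)
    )
  ), class = "synthetic_cohort")
}

# Titres are drawn so that only the threshold relationships matter: negatives
# log-normal around 0.3x ULN, positives uniform on [1,10]x ULN (ACPA) or
# [3,10]x ULN (RF / anti-Ra33).
draw_negative_titre <- function(uln, cap) {
  min(uln * rlnorm(1, log(0.3), 0.4), cap)
}

generate_participant <- function(id, group, config, ra = FALSE) {
  for (attempt in 1:100) {
    rec <- draw_participant(id, group, config, ra)
    if (classify_participant(rec)$group == group) return(rec)
  }
  abort(sprintf("could not generate a '%s' participant consistent with the classifier", group))
}

draw_participant <- function(id, group, config, ra = FALSE) {
  acpa_uln <- 20; rf_uln <- 15; ra33_uln <- 25
  age <- round(min(max(rnorm(1, 52, 14), 20), 85))
  sex <- if (runif(1) < 0.78) "female" else "male"
  bmi <- round(min(max(rnorm(1, 24.5, 4), 16), 45), 1)

  autoimmune_intended <- switch(group,
    control = FALSE, high_genetic_risk = FALSE, autoimmunity = TRUE,
    symptomatic = runif(1) < 0.26
  )

  # serology
  acpa <- draw_negative_titre(acpa_uln, 0.95 * acpa_uln)
  rf <- draw_negative_titre(rf_uln, 2.9 * rf_uln)
  ra33 <- draw_negative_titre(ra33_uln, 2.9 * ra33_uln)
  if (autoimmune_intended) {
    which_pos <- c(acpa = runif(1) < 0.4, rf = runif(1) < 0.6, ra33 = runif(1) < 0.1)
    if (!any(which_pos)) which_pos["rf"] <- TRUE
    if (which_pos["acpa"]) acpa <- runif(1, 1, 10) * acpa_uln
    if (which_pos["rf"]) rf <- runif(1, 3, 10) * rf_uln
    if (which_pos["ra33"]) ra33 <- runif(1, 3, 10) * ra33_uln
  }
  if (runif(1) < config$ra33_missing_prob) ra33 <- NA_real_

  # shared-epitope copies (Table-style per-group frequencies)
  se_probs <- switch(group,
    control = c(0.53, 0.47, 0),
    high_genetic_risk = c(0, 0, 1),
    autoimmunity = c(0.47, 0.39, 0.14),
    symptomatic = c(0.50, 0.41, 0.09)
  )
  se <- sample(0:2, 1L, prob = se_probs)
  if (group %in% c("control", "symptomatic") && runif(1) < 0.02 && se != 2L) {
    se <- NA_integer_
  }

  # CSA items
  items <- draw_csa_items(group, ra, autoimmune_intended, config)

  rec <- tibble::tibble(
    participant_id = id, age = age, sex = sex, bmi = bmi,
    se_copies = se,
    acpa_titre = acpa, acpa_uln = acpa_uln,
    rf_titre = rf, rf_uln = rf_uln,
    ra33_titre = ra33, ra33_uln = ra33_uln,
    ra_diagnosis = ra
  )
  for (j in 1:7) rec[[paste0("csa_item_", j)]] <- items[j]
  rec[, c("participant_id", "age", "sex", "bmi", "se_copies",
          "acpa_titre", "acpa_uln", "rf_titre", "rf_uln",
          "ra33_titre", "ra33_uln", paste0("csa_item_", 1:7), "ra_diagnosis")]
}

draw_csa_items <- function(group, ra, autoimmune, config) {
  items <- as.integer(runif(7) < if (group == "symptomatic" && !ra) 0.7 else 0.1)
  miss <- runif(7) < config$csa_missing_prob
  items[miss] <- NA_integer_
  n_missing <- sum(is.na(items))
  cutoff <- if (n_missing %in% 1:2 || autoimmune) 3L else 4L
  score <- sum(items, na.rm = TRUE)

  if (group == "symptomatic" && !ra) {
    # force a qualifying score: target drawn from the plausible symptomatic range
    target <- if (autoimmune) sample(3:6, 1, prob = c(0.15, 0.55, 0.2, 0.1))
              else sample(4:6, 1, prob = c(0.65, 0.2, 0.15))
    if (n_missing > 2L) { # keep at most 2 missing so the score is assessable
      fill <- which(is.na(items))[seq_len(n_missing - 2L)]
      items[fill] <- 0L
      n_missing <- 2L
    }
    obs <- which(!is.na(items))
    target <- min(max(target, if (n_missing %in% 1:2 || autoimmune) 3L else 4L), length(obs))
    items[obs] <- 0L
    items[obs[seq_len(target)]] <- 1L
  } else {
    # asymptomatic (or diagnosis-driven): keep the score below the cutoff
    while (sum(items, na.rm = TRUE) >= cutoff && !ra) {
      pos <- which(items %in% 1L)
      items[pos[sample.int(length(pos), 1L)]] <- 0L
    }
  }
  items
}
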
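#' Pipeline configuration
#'
#' Assembles and validates the end-to-end analysis configuration: either a
#' cohort directory to ingest or a [simulation_config()] to generate one,
#' stage toggles and per-stage parameters. Stage dependencies are checked up
#' front (`ecology` and `subgroups` need `qmp`; everything needs the
#' classifier, which always runs).
#'
#' @param input_dir Optional cohort directory written by [write_cohort()];
#'   when `NULL`, a cohort is simulated from `simulation`.
#' @param simulation A [simulation_config()] (default configuration if
#'   omitted).
#' @param output_dir Directory for per-stage artifacts and `report.json`.
#' @param stages Character vector of enabled stages among
#'   `qmp`, `ecology`, `enterotype`, `diffabund`, `subgroups`,
#'   `calprotectin`.
#' @param seed Base seed; per-stage seeds are derived from it.
#' @param min_rarefied_reads QMP exclusion threshold.
#' @param permanova_permutations Label permutations for PERMANOVA.
#' @param enterotype_k_range Candidate component numbers for model selection.
#' @param enterotype_depth Genus-matrix rarefaction depth before enterotyping.
#' @param dmm_restarts,dmm_max_iter,dmm_tol EM fitting controls.
#' @param diffabund_rank Aggregation rank for differential abundance.
#' @param n_mc,prior CLR Monte-Carlo controls.
#' @param subgroup_k Pronounced-subgroup size.
#' @param permutation_samples Permutation samples for the subgroup test.
#' @param calprotectin_threshold Elevated-calprotectin cutoff (ug/g).
#' @param target_family Family whose abundance the subgroup test examines.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    input_dir = NULL,
    simulation = simulation_config(),
    output_dir = tempfile("qmprof_run_"),
    stages = c("qmp", "ecology", "enterotype", "diffabund", "subgroups",
               "calprotectin"),
    seed = 1L,
    min_rarefied_reads = 150L,
    permanova_permutations = 999L,
    enterotype_k_range = 2:6,
    enterotype_depth = 10000L,
    dmm_restarts = 3L, dmm_max_iter = 200L, dmm_tol = 1e-4,
    diffabund_rank = "family",
    n_mc = 128L, prior = 0.5,
    subgroup_k = 20L,
    permutation_samples = 10000L,
    calprotectin_threshold = 100,
    target_family = "Prevotellaceae") {
  known <- c("qmp", "ecology", "enterotype", "diffabund", "subgroups", "calprotectin")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(sprintf("unknown stages: %s", paste(bad, collapse = ", ")))
  for (st in c("ecology", "subgroups")) {
    if (st %in% stages && !"qmp" %in% stages) {
      abort(sprintf("stage '%s' requires stage 'qmp'", st))
    }
  }
  structure(list(
    input_dir = input_dir, simulation = simulation, output_dir = output_dir,
    stages = stages, seed = as.integer(seed),
    min_rarefied_reads = as.integer(min_rarefied_reads),
    permanova_permutations = as.integer(permanova_permutations),
    enterotype_k_range = as.integer(enterotype_k_range),
    enterotype_depth = as.integer(enterotype_depth),
    dmm_restarts = as.integer(dmm_restarts),
    dmm_max_iter = as.integer(dmm_max_iter), dmm_tol = dmm_tol,
    diffabund_rank = diffabund_rank,
    n_mc = as.integer(n_mc), prior = prior,
    subgroup_k = as.integer(subgroup_k),
    permutation_samples = as.integer(permutation_samples),
    calprotectin_threshold = calprotectin_threshold,
    target_family = target_family
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a nested `simulation`
#' block maps to [simulation_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    if (!is.null(sim_args$group_sizes)) sim_args$group_sizes <- unlist(sim_args$group_sizes)
    cfg$simulation <- do.call(simulation_config, sim_args)
  }
  do.call(pipeline_config, cfg)
}

stage_run <- function(report, name, fun) {
  tryCatch(fun(), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — cohort
#' simulation/ingest, stage classification, QMP/RMP construction, community
#' ecology (Shannon, Bray-Curtis PCoA, PERMANOVA on both QMP and RMP),
#' enterotyping (BIC-selected Dirichlet-multinomial mixture plus
#' enterotype-by-group contingency test), CLR differential abundance,
#' pronounced-subgroup permutation tests and calprotectin comparisons — and
#' writes per-stage CSV/TSV artifacts plus a machine-readable `report.json`.
#' With a fixed seed the run is deterministic, byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return The report (class `analysis_report`, a nested list), invisibly;
#'   `report.json` and per-stage files are written to `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  on <- function(st) st %in% config$stages
  report <- list(meta = list(
    package = "qmprof",
    version = as.character(utils::packageVersion("qmprof")),
    seed = seed,
    stages = config$stages,
    config_hash = rlang::hash(config[setdiff(names(config), c("output_dir", "input_dir"))])
  ))

  cohort <- stage_run(report, "cohort", function() {
    if (is.null(config$input_dir)) simulate_cohort(config$simulation)
    else read_cohort(config$input_dir)
  })
  counts <- cohort$counts
  report$cohort <- list(
    n_samples = ncol(counts),
    n_asv = nrow(counts),
    simulated = is.null(config$input_dir)
  )

  assignments <- stage_run(report, "classify", function() classify_cohort(cohort$participants))
  readr::write_csv(assignments, file.path(config$output_dir, "assignments.csv"))
  groups <- setNames(assignments$group, assignments$participant_id)
  report$classification <- list(group_sizes = as.list(table(assignments$group)))

  qmp <- NULL
  if (on("qmp")) {
    qmp <- stage_run(report, "qmp", function() {
      qmp_transform(counts, cohort$copy_numbers, cohort$loads,
                    min_rarefied_reads = config$min_rarefied_reads, seed = seed + 1L)
    })
    readr::write_tsv(tibble::as_tibble(qmp$cells_per_gram, rownames = "taxon_id"),
                     file.path(config$output_dir, "qmp.tsv"))
    readr::write_csv(qmp$excluded_samples, file.path(config$output_dir, "excluded.csv"))
    report$qmp <- list(
      even_sampling_depth = qmp$even_sampling_depth,
      n_retained = ncol(qmp$cells_per_gram),
      n_excluded = nrow(qmp$excluded_samples),
      excluded_samples = qmp$excluded_samples$sample_id
    )
  }
  rmp <- to_relative(counts)

  if (on("ecology")) {
    report$ecology <- stage_run(report, "ecology", function() {
      retained <- colnames(qmp$cells_per_gram)
      lab_q <- groups[retained]
      shan <- shannon(qmp$cells_per_gram)
      shan_by_group <- tapply(shan, lab_q, median)
      d_qmp <- bray_curtis(qmp$cells_per_gram)
      perm_q <- permanova(d_qmp, lab_q, config$permanova_permutations, seed = seed + 6L)
      ord <- pcoa(d_qmp, n_axes = 2L)
      coords <- tidy(ord)
      coords$group <- lab_q[coords$sample_id]
      readr::write_csv(coords, file.path(config$output_dir, "pcoa_qmp.csv"))
      d_rmp <- bray_curtis(rmp)
      perm_r <- permanova(d_rmp, groups[colnames(rmp)],
                          config$permanova_permutations, seed = seed + 7L)
      list(
        shannon_median_by_group = as.list(shan_by_group),
        permanova_qmp = as.list(glance(perm_q)),
        permanova_rmp = as.list(glance(perm_r)),
        pcoa_proportion_explained = ord$proportion_explained[1:2]
      )
    })
  }

  genus_counts <- aggregate_taxa(counts, cohort$taxonomy, "genus")
  enterotypes <- NULL
  if (on("enterotype")) {
    report$enterotype <- stage_run(report, "enterotype", function() {
      totals <- colSums(genus_counts)
      deep <- totals >= config$enterotype_depth
      rarefied <- rarefy_counts(genus_counts[, deep, drop = FALSE],
                                config$enterotype_depth, seed = seed + 2L)
      sel <- dmm_select(rarefied, k_range = config$enterotype_k_range,
                        seed = seed + 10L, max_iter = config$dmm_max_iter,
                        tol = config$dmm_tol, n_restarts = config$dmm_restarts)
      ass <- assign_enterotypes(sel$best_model, genus_counts)
      enterotypes <<- ass
      readr::write_csv(ass, file.path(config$output_dir, "enterotypes.csv"))
      assigned <- ass[ass$label != "unassigned", ]
      tab <- table(assigned$label, groups[assigned$sample_id])
      fisher <- contingency_test(unclass(tab), method = "fisher_mc",
                                 n_mc = 20000L, seed = seed + 3L)
      rich <- rarefied_genus_richness(genus_counts, depth = config$enterotype_depth,
                                      seed = seed + 4L)
      list(
        best_k = sel$best_k,
        bic = as.list(setNames(sel$scores$bic, paste0("k", sel$scores$k))),
        n_unassigned_low_depth = sum(!deep),
        label_counts = as.list(table(ass$label)),
        fisher_p = fisher$p,
        median_rarefied_richness = median(rich$richness, na.rm = TRUE)
      )
    })
  }

  if (on("diffabund")) {
    report$differential_abundance <- stage_run(report, "diffabund", function() {
      res <- diff_abundance(counts, groups[colnames(counts)],
                            taxonomy = cohort$taxonomy, rank = config$diffabund_rank,
                            n_mc = config$n_mc, prior = config$prior, seed = seed + 5L)
      readr::write_csv(res, file.path(config$output_dir, "diffabund.csv"))
      list(
        rank = config$diffabund_rank,
        n_taxa_tested = nrow(res),
        n_significant_bh_05 = sum(res$p_bh < 0.05),
        top_taxa = head(res$taxon, 5),
        top_p_bh = head(res$p_bh, 5)
      )
    })
  }

  if (on("subgroups")) {
    report$subgroups <- stage_run(report, "subgroups", function() {
      sub <- select_pronounced_subgroups(assignments, cohort$participants,
                                         k = config$subgroup_k)
      readr::write_csv(sub, file.path(config$output_dir, "subgroups.csv"))
      fam_qmp <- aggregate_taxa(qmp$cells_per_gram, cohort$taxonomy, "family")
      fam_rmp <- aggregate_taxa(rmp, cohort$taxonomy, "family")
      idx_a <- sub$participant_id[sub$group == "control"]
      idx_b <- sub$participant_id[sub$group == "autoimmunity"]
      run_test <- function(mat, offset) {
        v <- mat[config$target_family, ]
        keep_a <- intersect(idx_a, names(v))
        keep_b <- intersect(idx_b, names(v))
        k <- min(length(keep_a), length(keep_b))
        subgroup_permutation_test(
          v, head(keep_a, k), head(keep_b, k),
          pool = names(v), n_permutations = config$permutation_samples,
          seed = seed + offset
        )
      }
      t_qmp <- run_test(fam_qmp, 8L)
      t_rmp <- run_test(fam_rmp, 9L)
      kw_rmp <- kruskal_wallis(fam_rmp[config$target_family, ],
                               groups[colnames(fam_rmp)])
      kw_qmp <- kruskal_wallis(fam_qmp[config$target_family, ],
                               groups[colnames(fam_qmp)])
      list(
        target_family = config$target_family,
        kruskal_p_rmp = kw_rmp$p,
        kruskal_p_qmp = kw_qmp$p,
        k = config$subgroup_k,
        qmp = list(observed_median_difference = t_qmp$observed_median_difference,
                   p_one_sided = t_qmp$p_one_sided),
        rmp = list(observed_median_difference = t_rmp$observed_median_difference,
                   p_one_sided = t_rmp$p_one_sided),
        n_permutations = config$permutation_samples
      )
    })
  }

  if (on("calprotectin")) {
    report$calprotectin <- stage_run(report, "calprotectin", function() {
      cal <- cohort$calprotectin[names(groups)]
      kw <- kruskal_wallis(cal, groups)
      pw <- pairwise_vs_control(cal, groups)
      elevated <- factor(cal > config$calprotectin_threshold,
                         levels = c(FALSE, TRUE),
                         labels = c("normal", "elevated"))
      assoc <- NULL
      if (all(table(elevated) >= 2L)) {
        assoc <- diff_abundance(counts, elevated, taxonomy = cohort$taxonomy,
                                rank = "genus", n_mc = config$n_mc,
                                prior = config$prior, seed = seed + 11L)
      }
      list(
        kruskal_p = kw$p,
        pairwise = purrr::transpose(pw[, c("group", "p_raw", "p_bh")]),
        n_elevated = sum(elevated == "elevated"),
        threshold = config$calprotectin_threshold,
        elevated_top_genera = if (is.null(assoc)) character(0) else head(assoc$taxon, 3)
      )
    })
  }

  class(report) <- "analysis_report"
  jsonlite::write_json(unclass(report), file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("qmprof analysis report\n")
  cat(sprintf("  samples: %d, ASVs: %d\n", x$cohort$n_samples, x$cohort$n_asv))
  gs <- x$classification$group_sizes
  cat("  groups:", paste(sprintf("%s=%s", names(gs), unlist(gs)), collapse = ", "), "\n")
  if (!is.null(x$ecology)) {
    cat(sprintf("  PERMANOVA (QMP): R2 = %.4g, p = %.3g\n",
                x$ecology$permanova_qmp$R2, x$ecology$permanova_qmp$p.value))
  }
  if (!is.null(x$enterotype)) {
    cat(sprintf("  enterotypes: best K = %d, Fisher p = %.3g\n",
                x$enterotype$best_k, x$enterotype$fisher_p))
  }
  if (!is.null(x$subgroups)) {
    cat(sprintf("  subgroup permutation p (QMP) = %.3g, (RMP) = %.3g\n",
                x$subgroups$qmp$p_one_sided, x$subgroups$rmp$p_one_sided))
  }
  if (!is.null(x$calprotectin)) {
    cat(sprintf("  calprotectin Kruskal-Wallis p = %.3g\n", x$calprotectin$kruskal_p))
  }
  invisible(x)
}
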
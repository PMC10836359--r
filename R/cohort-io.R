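cohort_files <- c("counts.tsv", "taxonomy.tsv", "copy_numbers.tsv",
                  "loads.csv", "metadata.csv", "calprotectin.csv", "truth.json")

#' Write a synthetic cohort to disk
#'
#' Emits `counts.tsv` (taxon_id + one integer column per sample),
#' `taxonomy.tsv`, `copy_numbers.tsv`, `loads.csv`, `calprotectin.csv`
#' (`sample_id,value`), `metadata.csv` (missing values as empty strings) and
#' `truth.json` (seed, latent enterotypes, injected effects). Reading the
#' directory back with [read_cohort()] reproduces the cohort exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if absent).
#' @param overwrite Refuse to clobber existing cohort files unless `TRUE`.
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  targets <- file.path(directory, cohort_files)
  if (!overwrite && any(file.exists(targets))) {
    abort(sprintf("cohort files already exist in '%s'; set overwrite = TRUE", directory))
  }
  counts_df <- tibble::as_tibble(cohort$counts, rownames = "taxon_id")
  readr::write_tsv(counts_df, file.path(directory, "counts.tsv"))
  readr::write_tsv(cohort$taxonomy, file.path(directory, "taxonomy.tsv"))
  readr::write_tsv(
    tibble::tibble(taxon_id = names(cohort$copy_numbers),
                   copy_number = unname(cohort$copy_numbers)),
    file.path(directory, "copy_numbers.tsv")
  )
  readr::write_csv(
    tibble::tibble(sample_id = names(cohort$loads), value = unname(cohort$loads)),
    file.path(directory, "loads.csv")
  )
  readr::write_csv(
    tibble::tibble(sample_id = names(cohort$calprotectin),
                   value = unname(cohort$calprotectin)),
    file.path(directory, "calprotectin.csv")
  )
  meta <- cohort$participants
  names(meta)[names(meta) == "participant_id"] <- "sample_id"
  readr::write_csv(meta, file.path(directory, "metadata.csv"), na = "")
  jsonlite::write_json(
    list(seed = cohort$truth$seed,
         group_sizes = cohort$truth$group_sizes,
         intended_group = as.list(cohort$truth$intended_group),
         enterotype = as.list(cohort$truth$enterotype),
         effects = cohort$truth$effects),
    file.path(directory, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(directory)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory Directory containing the cohort files.
#' @return A `synthetic_cohort` list.
#' @export
read_cohort <- function(directory) {
  counts <- read_count_matrix(file.path(directory, "counts.tsv"))
  taxonomy <- readr::read_tsv(file.path(directory, "taxonomy.tsv"),
                              show_col_types = FALSE)
  cn <- readr::read_tsv(file.path(directory, "copy_numbers.tsv"),
                        show_col_types = FALSE)
  loads <- readr::read_csv(file.path(directory, "loads.csv"), show_col_types = FALSE)
  calpro <- readr::read_csv(file.path(directory, "calprotectin.csv"),
                            show_col_types = FALSE)
  meta <- read_metadata(file.path(directory, "metadata.csv"))
  truth <- jsonlite::read_json(file.path(directory, "truth.json"), simplifyVector = TRUE)
  truth$intended_group <- unlist(truth$intended_group)
  truth$enterotype <- unlist(truth$enterotype)
  if (!identical(names(loads), c("sample_id", "value"))) {
    abort("loads.csv must have columns sample_id,value")
  }
  stopifnot(identical(colnames(counts), loads$sample_id),
            identical(colnames(counts), calpro$sample_id),
            identical(colnames(counts), meta$participant_id))
  structure(list(
    participants = meta,
    counts = counts,
    taxonomy = taxonomy,
    copy_numbers = setNames(cn$copy_number, cn$taxon_id),
    loads = setNames(loads$value, loads$sample_id),
    calprotectin = setNames(calpro$value, calpro$sample_id),
    truth = truth
  ), class = "synthetic_cohort")
}

#' Read a taxa-by-samples count table
#'
#' Parses the `counts.tsv` dialect: a header row, first column `taxon_id`,
#' remaining columns one per sample, integer cells. Duplicate identifiers,
#' negative or non-integer cells are rejected with their location.
#'
#' @param path Path to a tab-separated count table.
#' @return An integer taxa x samples matrix with dimnames.
#' @export
read_count_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    abort(sprintf("'%s': duplicated sample column '%s'",
                  path, header[duplicated(header)][1]))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) abort(sprintf("'%s': expected taxon_id plus sample columns", path))
  if (anyDuplicated(df[[1]])) {
    abort(sprintf("'%s': duplicated taxon id '%s'", path, df[[1]][duplicated(df[[1]])][1]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("'%s': non-numeric count cells", path))
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("'%s': non-integer or negative count at row %d (%s), column '%s'",
                  path, bad[1, 1] + 1L, df[[1]][bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read participant metadata
#'
#' Parses the `metadata.csv` dialect (empty strings are missing values) and
#' validates the column contract used by [classify_cohort()].
#'
#' @param path Path to a metadata CSV.
#' @return A tibble with `participant_id` plus the serology, genotype, CSA and
#'   demographic columns.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                          progress = FALSE)
  names(meta)[names(meta) == "sample_id"] <- "participant_id"
  required <- c("participant_id", "age", "sex", "se_copies",
                "acpa_titre", "acpa_uln", "rf_titre", "rf_uln",
                "ra33_titre", "ra33_uln", paste0("csa_item_", 1:7), "ra_diagnosis")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    abort(sprintf("'%s': missing metadata columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$participant_id)) abort(sprintf("'%s': duplicate participant ids", path))
  meta$participant_id <- as.character(meta$participant_id)
  meta
}
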
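# shared fixtures and independent oracles, built in code

tiny_sim_config <- function(seed = 1L, ...) {
  simulation_config(
    group_sizes = c(control = 12L, high_genetic_risk = 4L,
                    autoimmunity = 4L, symptomatic = 5L),
    n_taxa = 20L, n_ra_symptomatic = 1L, seed = seed, ...
  )
}

# taxa x samples matrix with dimnames from a plain numeric vector/matrix
named_counts <- function(m) {
  m <- as.matrix(m)
  rownames(m) <- sprintf("t%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}

# all permutations of a small vector (exhaustive-enumeration oracles)
permn <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permn(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# naive two-loop PERMANOVA pseudo-F (independent of the package implementation)
naive_pseudo_f <- function(d, labels) {
  n <- nrow(d)
  labels <- as.factor(labels)
  g <- nlevels(labels)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (lev in levels(labels)) {
    idx <- which(labels == lev)
    acc <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        acc <- acc + d[idx[a], idx[b]]^2
      }
    }
    ss_within <- ss_within + acc / length(idx)
  }
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

# block-structured Dirichlet-multinomial mixture data with known components
make_block_dmm <- function(n, s, k, depth = 3000L, seed = 1L,
                           block_high = 5, block_low = 0.05) {
  withr::with_seed(seed, {
    blocks <- if (k == 1L) list(seq_len(s)) else
      split(seq_len(s), cut(seq_len(s), k, labels = FALSE))
    alpha <- sapply(seq_len(k), function(j) {
      a <- rep(block_low, s); a[blocks[[j]]] <- block_high; a
    })
    z <- sample(seq_len(k), n, replace = TRUE)
    counts <- sapply(seq_len(n), function(i) {
      p <- qmprof:::rdirichlet_one(alpha[, z[i]])
      rmultinom(1L, depth, p)[, 1L]
    })
    rownames(counts) <- sprintf("g%02d", seq_len(s))
    colnames(counts) <- sprintf("s%03d", seq_len(n))
    list(counts = counts, z = z, alpha = alpha)
  })
}

# genus-level panel drawn from the four default enterotype profiles
make_enterotype_panel <- function(n, n_taxa = 24L, depth = 5000L, seed = 1L) {
  tax <- qmprof:::default_genus_universe(n_taxa)
  prof <- default_enterotype_profiles(tax)
  withr::with_seed(seed, {
    et <- sample(1:4, n, replace = TRUE)
    counts <- sapply(seq_len(n), function(i) {
      rmultinom(1L, depth, qmprof:::rdirichlet_one(prof[et[i], ]))[, 1L]
    })
    rownames(counts) <- tax$genus
    colnames(counts) <- sprintf("S%04d", seq_len(n))
    list(counts = counts, enterotype = et, profiles = prof, taxonomy = tax)
  })
}

# metadata record builders for the classifier
base_record <- function(...) {
  rec <- list(
    participant_id = "X001", age = 50, sex = "female", bmi = 24,
    se_copies = 0L,
    acpa_titre = 5, acpa_uln = 20,
    rf_titre = 5, rf_uln = 15,
    ra33_titre = 5, ra33_uln = 25,
    ra_diagnosis = FALSE
  )
  for (j in 1:7) rec[[paste0("csa_item_", j)]] <- 0L
  modifyList(rec, list(...))
}

set_csa <- function(rec, n_pos, n_missing = 0L) {
  vals <- c(rep(1L, n_pos), rep(NA_integer_, n_missing),
            rep(0L, 7 - n_pos - n_missing))
  for (j in 1:7) rec[[paste0("csa_item_", j)]] <- vals[j]
  rec
}
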
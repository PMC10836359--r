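#' Fit a Dirichlet-multinomial mixture by EM
#'
#' Community typing model: each sample's genus counts are drawn from a
#' Dirichlet-multinomial (DM) whose concentration vector depends on a latent
#' component. The E-step computes posterior responsibilities from the
#' component DM log-densities (log-gamma form, including the multinomial
#' coefficient so the reported log-likelihood is the true data
#' log-likelihood); the M-step re-estimates mixture weights from the
#' responsibilities and updates each component's concentrations by a
#' responsibility-weighted fixed-point iteration, damped by step-halving so
#' the log-likelihood never decreases. Several seeded restarts are run
#' (k-means initialisation on proportions plus jitter) and the best
#' likelihood is kept.
#'
#' @param genus_counts Genera x samples integer matrix (or wide data frame).
#' @param k Number of mixture components (>= 1).
#' @param seed Integer seed (controls initialisation across restarts).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence threshold on the log-likelihood gain.
#' @param n_restarts Number of seeded restarts (default 5).
#' @return Object of class `dmm_model`: `k`, `weights`, `alpha` (genera x k),
#'   `log_likelihood`, `responsibilities` (samples x k), `n_iter`,
#'   `converged`, `seed`.
#' @export
dmm_fit <- function(genus_counts, k, seed = NULL, max_iter = 500L, tol = 1e-6,
                    n_restarts = 5L) {
  x <- t(as_count_matrix(genus_counts)) # samples x genera
  n <- nrow(x); s <- ncol(x)
  if (k < 1L) abort("`k` must be >= 1")
  if (n <= k) abort("need more samples than components")

  with_seed_maybe(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(dmm_em_once(x, k, max_iter, tol, jitter = r > 1L),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$log_likelihood > best$log_likelihood)) {
        best <- fit
      }
    }
    if (is.null(best)) abort("all EM restarts failed")
    best$seed <- seed
    best$genus_ids <- colnames(x)
    rownames(best$alpha) <- colnames(x)
    rownames(best$responsibilities) <- rownames(x)
    structure(best, class = "dmm_model")
  })
}

# log DM density for all samples under one concentration vector.
# x: samples x genera, lmc: per-sample log multinomial coefficient
dm_logdens <- function(x, alpha, lmc) {
  a0 <- sum(alpha)
  totals <- rowSums(x)
  lgamma(a0) - lgamma(totals + a0) +
    rowSums(lgamma(sweep(x, 2L, alpha, `+`))) - sum(lgamma(alpha)) + lmc
}

dmm_loglik <- function(x, weights, alpha, lmc) {
  ld <- vapply(seq_along(weights),
               function(j) log(weights[j]) + dm_logdens(x, alpha[, j], lmc),
               numeric(nrow(x)))
  ld <- matrix(ld, nrow = nrow(x))
  list(loglik = sum(row_logsumexp(ld)), log_joint = ld)
}

dmm_em_once <- function(x, k, max_iter, tol, jitter = FALSE) {
  n <- nrow(x); s <- ncol(x)
  props <- x / pmax(rowSums(x), 1)
  lmc <- lgamma(rowSums(x) + 1) - rowSums(lgamma(x + 1))

  # initialise from a k-means partition of the proportion space
  if (k == 1L) {
    cl <- rep(1L, n)
  } else {
    km <- suppressWarnings(stats::kmeans(props, centers = k, nstart = 3L))
    cl <- km$cluster
    if (length(unique(cl)) < k) cl <- sample(rep_len(seq_len(k), n))
  }
  alpha <- vapply(seq_len(k), function(j) {
    m <- colMeans(props[cl == j, , drop = FALSE])
    m <- m + 1e-4
    a <- 50 * m / sum(m)
    if (jitter) a <- a * exp(rnorm(s, 0, 0.3))
    a
  }, numeric(s))
  alpha <- matrix(alpha, nrow = s)
  weights <- tabulate(cl, k) / n

  ll <- dmm_loglik(x, weights, alpha, lmc)
  loglik <- ll$loglik
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E-step
    resp <- exp(ll$log_joint - row_logsumexp(ll$log_joint))
    # guard degenerate components: re-seed any with < 1 sample of mass
    mass <- colSums(resp)
    if (any(mass < 1)) {
      for (j in which(mass < 1)) {
        i <- sample.int(nrow(x), 1L)
        resp[i, ] <- 0; resp[i, j] <- 1
      }
      mass <- colSums(resp)
    }
    # M-step
    new_weights <- mass / n
    new_alpha <- alpha
    for (j in seq_len(k)) {
      new_alpha[, j] <- dm_alpha_update(x, resp[, j], alpha[, j], n_inner = 5L)
    }
    ll_new <- dmm_loglik(x, new_weights, new_alpha, lmc)
    # damping: step-halve towards the old parameters if the likelihood drops
    step <- 1
    while (ll_new$loglik < loglik - 1e-10 && step > 1e-3) {
      step <- step / 2
      damp_alpha <- exp(step * log(new_alpha) + (1 - step) * log(alpha))
      damp_w <- step * new_weights + (1 - step) * weights
      damp_w <- damp_w / sum(damp_w)
      ll_new <- dmm_loglik(x, damp_w, damp_alpha, lmc)
      if (ll_new$loglik >= loglik - 1e-10) {
        new_alpha <- damp_alpha; new_weights <- damp_w
      }
    }
    if (ll_new$loglik < loglik - 1e-8) { # could not improve: stop at the old fit
      ll_new <- ll
      converged <- TRUE
      break
    }
    gain <- ll_new$loglik - loglik
    alpha <- new_alpha; weights <- new_weights; loglik <- ll_new$loglik; ll <- ll_new
    if (gain < tol) { converged <- TRUE; break }
  }
  resp <- exp(ll$log_joint - row_logsumexp(ll$log_joint))
  list(k = k, weights = weights, alpha = alpha, log_likelihood = loglik,
       responsibilities = resp, n_iter = iter, converged = converged)
}

# one responsibility-weighted Minka fixed-point pass (few inner iterations)
dm_alpha_update <- function(x, r, alpha, n_inner = 5L) {
  totals <- rowSums(x)
  for (it in seq_len(n_inner)) {
    a0 <- sum(alpha)
    num <- colSums(r * (digamma(sweep(x, 2L, alpha, `+`)) - rep(digamma(alpha), each = nrow(x))))
    den <- sum(r * (digamma(totals + a0) - digamma(a0)))
    if (den <= 0) break
    alpha <- pmax(alpha * num / den, 1e-10)
  }
  alpha
}

#' @export
print.dmm_model <- function(x, ...) {
  cat(sprintf("Dirichlet-multinomial mixture: K = %d, logLik = %.2f (%d EM iterations%s)\n",
              x$k, x$log_likelihood, x$n_iter,
              if (x$converged) ", converged" else ""))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @method glance dmm_model
#' @export
glance.dmm_model <- function(x, ...) {
  nu <- (x$k - 1) + x$k * nrow(x$alpha)
  n <- nrow(x$responsibilities)
  tibble::tibble(k = x$k, log_likelihood = x$log_likelihood,
                 n_parameters = nu, bic = -2 * x$log_likelihood + nu * log(n),
                 converged = x$converged)
}

#' @method tidy dmm_model
#' @export
tidy.dmm_model <- function(x, ...) {
  tibble::as_tibble(x$alpha, rownames = "genus") |>
    tidyr::pivot_longer(-"genus", names_to = "component", values_to = "concentration")
}

#' Select the number of Dirichlet components by BIC
#'
#' Fits [dmm_fit()] for each candidate K and scores it with
#' \eqn{BIC = -2\log L + \nu \log n}, \eqn{\nu = (K-1) + K S} (mixture
#' weights plus per-component concentrations over S genera). The K minimising
#' BIC is returned.
#'
#' @inheritParams dmm_fit
#' @param k_range Integer vector of candidate component numbers.
#' @return Object of class `dmm_selection`: `best_k`, `best_model`, `scores`
#'   (tibble of k/logLik/BIC), `models` (list).
#' @export
dmm_select <- function(genus_counts, k_range = 1:6, seed = NULL, max_iter = 500L,
                       tol = 1e-6, n_restarts = 5L) {
  if (length(k_range) == 0L) abort("`k_range` must be non-empty")
  seeds <- if (is.null(seed)) rep(list(NULL), length(k_range))
           else as.list(seed + seq_along(k_range) - 1L)
  models <- list()
  failures <- character()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- tryCatch(
      dmm_fit(genus_counts, k, seed = seeds[[i]], max_iter = max_iter,
              tol = tol, n_restarts = n_restarts),
      error = function(e) { failures <<- c(failures, sprintf("K=%d: %s", k, conditionMessage(e))); NULL }
    )
    if (!is.null(fit)) models[[as.character(k)]] <- fit
  }
  if (length(models) == 0L) abort(paste("every DMM fit failed:", paste(failures, collapse = "; ")))
  scores <- purrr::map_dfr(models, glance)
  best_k <- scores$k[which.min(scores$bic)]
  structure(list(
    best_k = best_k,
    best_model = models[[as.character(best_k)]],
    scores = scores,
    models = models,
    failures = failures,
    seed = seed
  ), class = "dmm_selection")
}

#' @export
print.dmm_selection <- function(x, ...) {
  cat(sprintf("DMM model selection over K = {%s}: best K = %d by BIC\n",
              paste(x$scores$k, collapse = ", "), x$best_k))
  print(x$scores)
  invisible(x)
}

#' @method tidy dmm_selection
#' @export
tidy.dmm_selection <- function(x, ...) x$scores

#' Derive enterotype labels for fitted components
#'
#' Names each component after its dominant genera: Prevotella-dominated
#' components become `Prev`, Ruminococcaceae-type components `Rum`, and
#' Bacteroides-dominated components `Bact1`/`Bact2` (ordered by decreasing
#' expected Bacteroides share); anything else keeps `component_<k>`.
#'
#' @param model A `dmm_model`.
#' @return Named character vector mapping component index to label.
#' @export
derive_enterotype_labels <- function(model) {
  k <- model$k
  labels <- paste0("component_", seq_len(k))
  mean_comp <- sweep(model$alpha, 2L, colSums(model$alpha), `/`)
  gn <- rownames(model$alpha)
  share <- function(pattern) {
    idx <- grep(pattern, gn, ignore.case = TRUE)
    if (length(idx) == 0L) rep(0, k) else colSums(mean_comp[idx, , drop = FALSE])
  }
  prev <- share("^Prevotella|^Paraprevotella|^Alloprevotella")
  bact <- share("^Bacteroides|^Phocaeicola")
  rum <- share("^Ruminococcus|^Faecalibacterium|^Subdoligranulum|^Oscilli")
  dominant <- apply(rbind(prev = prev, bact = bact, rum = rum), 2L, function(v) {
    if (max(v) < 0.05) NA_character_ else names(v)[which.max(v)]
  })
  labels[dominant %in% "prev"] <- "Prev"
  labels[dominant %in% "rum"] <- "Rum"
  b_idx <- which(dominant %in% "bact")
  if (length(b_idx)) {
    # Bact2 is conventionally the low-diversity Bacteroides community type:
    # order Bacteroides-dominated components by decreasing Shannon entropy of
    # their mean composition
    entropy <- apply(mean_comp[, b_idx, drop = FALSE], 2L,
                     function(p) -sum(p[p > 0] * log(p[p > 0])))
    ord <- b_idx[order(-entropy)]
    labels[ord] <- paste0("Bact", seq_along(ord))
  }
  setNames(labels, seq_len(k))
}

#' Assign samples to enterotypes
#'
#' Computes posterior responsibilities of the samples under a fitted mixture
#' and assigns each sample to its maximum-responsibility component; samples
#' with zero total count cannot be assigned and are reported as such.
#'
#' @param model A `dmm_model`.
#' @param genus_counts Genera x samples integer matrix on the model's genus
#'   universe.
#' @param label_map Optional named map component -> label; defaults to
#'   [derive_enterotype_labels()].
#' @return Tibble `sample_id`, `component` (NA when unassigned), `label`,
#'   `max_responsibility`.
#' @export
assign_enterotypes <- function(model, genus_counts, label_map = NULL) {
  x <- t(as_count_matrix(genus_counts))
  missing <- setdiff(colnames(x), model$genus_ids)
  if (length(missing)) {
    abort(sprintf("genera absent from the fitted model: %s", paste(head(missing, 5), collapse = ", ")))
  }
  x <- x[, model$genus_ids, drop = FALSE]
  label_map <- label_map %||% derive_enterotype_labels(model)
  lmc <- lgamma(rowSums(x) + 1) - rowSums(lgamma(x + 1))
  ll <- dmm_loglik(x, model$weights, model$alpha, lmc)
  resp <- exp(ll$log_joint - row_logsumexp(ll$log_joint))
  comp <- max.col(resp, ties.method = "first")
  empty <- rowSums(x) == 0
  comp[empty] <- NA_integer_
  tibble::tibble(
    sample_id = rownames(x),
    component = comp,
    label = ifelse(is.na(comp), "unassigned", unname(label_map[as.character(comp)])),
    max_responsibility = ifelse(is.na(comp), NA_real_,
                                resp[cbind(seq_len(nrow(x)), pmax(comp, 1L))])
  )
}

#' Rarefied observed genus richness
#'
#' Downsizes each sample to `depth` reads without replacement and counts the
#' genera remaining with positive counts. Samples with fewer than `depth`
#' total reads are excluded and reported with `NA` richness.
#'
#' @param genus_counts Genera x samples integer matrix.
#' @param depth Rarefaction depth (default 10000).
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `richness` (NA when excluded), `excluded`.
#' @export
rarefied_genus_richness <- function(genus_counts, depth = 10000L, seed = NULL) {
  x <- as_count_matrix(genus_counts)
  totals <- colSums(x)
  keep <- totals >= depth
  rich <- rep(NA_integer_, ncol(x))
  if (any(keep)) {
    rar <- rarefy_counts(x[, keep, drop = FALSE], depth, seed = seed)
    rich[keep] <- colSums(rar > 0)
  }
  tibble::tibble(sample_id = colnames(x), richness = rich, excluded = !keep)
}
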
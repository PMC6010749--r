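#' Cross-validation configuration
#'
#' Defaults follow the study: hold out 5% of the taxa (at least one) per
#' round, 1,000 rounds, AUC compared against 0.5, 95% percentile confidence
#' interval over rounds.
#'
#' @param holdout_fraction fraction of taxa held out each round
#' @param n_rounds number of rounds
#' @param auc_threshold mean AUC above this counts as a good fit
#' @param ci_level level of the percentile interval over rounds
#' @param seed integer seed controlling the random splits
#' @param pooling `"pooled"` (one AUC per round over all held-out
#'   (site, taxon) pairs) or `"mean_per_taxon"` (average of per-taxon AUCs)
#' @return list of class `cv_config`
#' @export
cv_config <- function(holdout_fraction = 0.05, n_rounds = 1000L,
                      auc_threshold = 0.5, ci_level = 0.95, seed = 1L,
                      pooling = c("pooled", "mean_per_taxon")) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1, n_rounds >= 1,
            ci_level > 0, ci_level < 1)
  structure(list(holdout_fraction = holdout_fraction,
                 n_rounds = as.integer(n_rounds),
                 auc_threshold = auc_threshold, ci_level = ci_level,
                 seed = as.integer(seed), pooling = match.arg(pooling)),
            class = "cv_config")
}

#' Random training/validation split of the taxa
#'
#' Holds out `max(1, round(holdout_fraction * n_taxa))` taxa, uniformly at
#' random, deterministically in `(seed, round_index)`.
#'
#' @param taxa character vector of taxon names
#' @param cfg a [cv_config()]
#' @param round_index 1-based round number
#' @return list with `training` and `validation` character vectors
#' @export
split_validation <- function(taxa, cfg, round_index) {
  n <- length(taxa)
  k <- max(1L, round(cfg$holdout_fraction * n))
  if (k >= n) stop("holdout would remove all taxa")
  held <- with_seed(derive_seed(cfg$seed, round_index),
                    sample(taxa, k))
  list(training = setdiff(taxa, held), validation = held)
}

#' Predicted occurrence scores for a held-out taxon
#'
#' The held-out taxon is scored at each site by
#' logistic(alpha_bar + beta_anc * x_i), where beta_anc is the posterior
#' mean slope of its nearest ancestor that survived pruning and alpha_bar
#' is the pooled mean of the fitted leaf intercepts (the held-out taxon has
#' no intercept of its own; per-taxon AUC is invariant to this constant).
#'
#' @param taxon held-out taxon name
#' @param pruned_fit `posterior_samples` from the fit on the pruned tree
#' @param original_topo the unpruned [topology()]
#' @param prune_map the `map` component of [prune_leaves()]
#' @param x covariate per site
#' @return numeric score per site, in (0, 1)
#' @export
predict_heldout <- function(taxon, pruned_fit, original_topo, prune_map, x) {
  leaf <- which(original_topo$is_leaf & original_topo$label == taxon)
  if (length(leaf) != 1L) stop("taxon not a leaf of the original topology: ", taxon)
  if (!is.na(prune_map[leaf])) stop("taxon ", taxon, " was not pruned")
  anc <- nearest_surviving_ancestor(original_topo, leaf, prune_map)
  beta_anc <- mean(node_beta_draws(pruned_fit, anc))
  alpha_bar <- mean(posterior_mean_alpha(pruned_fit))
  as.numeric(occurrence_probability(alpha_bar, beta_anc, x))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (presence, absence) site pairs
#' in which the presence site scores higher, ties counted 1/2.
#'
#' @param scores numeric predicted scores
#' @param labels binary observed labels (same length)
#' @return AUC in [0, 1]; `NA` when only one class is present
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-genera-out cross-validation of the phylogenetic occurrence model
#'
#' Each round: randomly hold out a small set of taxa, prune them from the
#' tree and the data, refit the model on the training taxa, score every
#' held-out taxon at every site from its nearest surviving ancestor's
#' posterior mean slope, and compute one AUC for the round. Rounds in which
#' the scored labels are single-class (AUC undefined) are recorded as
#' skipped. Results aggregate to a mean AUC with a percentile confidence
#' interval over rounds.
#'
#' @param data an [occurrence_data()]
#' @param topo the full [topology()]
#' @param h a [hyperparams()]
#' @param mcmc_cfg an [mcmc_config()] used for every per-round refit (its
#'   seed is re-derived per round so rounds are independent but the whole
#'   procedure is reproducible)
#' @param cv_cfg a [cv_config()]
#' @return list of class `cv_report`: `auc` (per-round, `NA` where
#'   skipped), `mean_auc`, `ci` (lower, upper), `per_taxon` (mean AUC per
#'   taxon over the rounds holding it out), `n_skipped`, `pass`
#'   (mean_auc > threshold), plus the config echoes
#' @export
cross_validate <- function(data, topo, h = hyperparams(),
                           mcmc_cfg = mcmc_config(), cv_cfg = cv_config()) {
  taxa <- leaf_labels(topo)
  if (!setequal(data$taxon_ids, taxa))
    stop("taxon set of data and topology leaves differ")
  auc <- rep(NA_real_, cv_cfg$n_rounds)
  taxon_auc_sum <- stats::setNames(numeric(length(taxa)), taxa)
  taxon_auc_n <- stats::setNames(integer(length(taxa)), taxa)
  for (r in seq_len(cv_cfg$n_rounds)) {
    sp <- split_validation(taxa, cv_cfg, r)
    pr <- prune_leaves(topo, sp$validation)
    keep_cols <- sp$training
    d_train <- occurrence_data(data$O[, keep_cols, drop = FALSE], data$x,
                               require_presence = FALSE)
    cfg_r <- mcmc_cfg
    cfg_r$seed <- derive_seed(mcmc_cfg$seed, r + 1000L)
    fit <- sample_posterior(d_train, pr$topology, h, cfg_r)
    pooled_scores <- numeric(0)
    pooled_labels <- numeric(0)
    taxon_aucs <- numeric(0)
    for (taxon in sp$validation) {
      sc <- predict_heldout(taxon, fit, topo, pr$map, data$x)
      lab <- data$O[, taxon]
      pooled_scores <- c(pooled_scores, sc)
      pooled_labels <- c(pooled_labels, lab)
      taxon_auc <- roc_auc(sc, lab)
      if (!is.na(taxon_auc)) {
        taxon_aucs <- c(taxon_aucs, taxon_auc)
        taxon_auc_sum[taxon] <- taxon_auc_sum[taxon] + taxon_auc
        taxon_auc_n[taxon] <- taxon_auc_n[taxon] + 1L
      }
    }
    auc[r] <- if (cv_cfg$pooling == "pooled") {
      roc_auc(pooled_scores, pooled_labels)
    } else if (length(taxon_aucs)) mean(taxon_aucs) else NA_real_
  }
  ok <- !is.na(auc)
  alpha2 <- (1 - cv_cfg$ci_level) / 2
  ci <- if (any(ok)) unname(stats::quantile(auc[ok], c(alpha2, 1 - alpha2)))
        else c(NA_real_, NA_real_)
  mean_auc <- if (any(ok)) mean(auc[ok]) else NA_real_
  per_taxon <- ifelse(taxon_auc_n > 0, taxon_auc_sum / pmax(taxon_auc_n, 1L),
                      NA_real_)
  structure(list(auc = auc, mean_auc = mean_auc, ci = ci,
                 per_taxon = per_taxon, n_skipped = sum(!ok),
                 pass = isTRUE(mean_auc > cv_cfg$auc_threshold),
                 cv_config = cv_cfg, mcmc_config = mcmc_cfg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d rounds (%d skipped); mean AUC %.3f, %d%% CI [%.3f, %.3f]; %s\n",
              length(x$auc), x$n_skipped, x$mean_auc,
              round(100 * x$cv_config$ci_level), x$ci[1], x$ci[2],
              if (x$pass) "passes threshold" else "does not pass threshold"))
  invisible(x)
}
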
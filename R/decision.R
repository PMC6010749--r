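#' Posterior tail probability of no effect
#'
#' The minority-sign posterior mass of a slope: p = min(fraction of draws
#' above zero, fraction below zero), with draws exactly at zero split
#' evenly. Small p means the posterior is confidently on one side of zero.
#'
#' @param draws numeric vector of posterior slope draws (>= 100 unless
#'   `min_draws` is lowered)
#' @param side `"two_sided"` (default, the minority mass) or `"one_sided"`
#'   (mass opposite the sign of the posterior mean)
#' @param min_draws minimum number of draws required
#' @return probability in [0, 0.5]
#' @export
tail_probability <- function(draws, side = c("two_sided", "one_sided"),
                             min_draws = 100L) {
  side <- match.arg(side)
  if (length(draws) == 0L) stop("no draws")
  if (length(draws) < min_draws)
    stop("need at least ", min_draws, " draws, got ", length(draws))
  pos <- mean(draws > 0) + 0.5 * mean(draws == 0)
  neg <- 1 - pos
  if (side == "two_sided") return(min(pos, neg))
  if (mean(draws) >= 0) neg else pos
}

DECISION_LEVELS <- c("very_strong", "strong", "acceptable", "little_evidence")

#' Evidence category from a tail probability
#'
#' Fixed bands: p < 0.05 very strong; 0.05 <= p < 0.15 strong; 0.15 <= p <
#' 0.30 acceptable; p >= 0.30 little evidence. Boundaries are closed on the
#' left of each band ("lower than 0.05" is exclusive, "exceeds 0.30" means
#' 0.30 itself already falls in the weakest band).
#'
#' @param p tail probability in [0, 0.5]
#' @return factor level among very_strong, strong, acceptable,
#'   little_evidence
#' @examples
#' decision_category(0.04)  # very_strong
#' decision_category(0.20)  # acceptable
#' @export
decision_category <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 0.5))
    stop("p must lie in [0, 0.5]")
  lab <- ifelse(p < 0.05, "very_strong",
         ifelse(p < 0.15, "strong",
         ifelse(p < 0.30, "acceptable", "little_evidence")))
  factor(lab, levels = DECISION_LEVELS)
}

#' Node-by-node evidence report from posterior samples
#'
#' For every tree node: posterior mean and variance of the slope, the sign
#' of the mean, the tail probability of no effect, and the evidence
#' category.
#'
#' @param samples a `posterior_samples`
#' @param side passed to [tail_probability()]
#' @return data.frame of class `decision_report` with columns `node`,
#'   `taxon` (`""` for internal nodes), `mean`, `variance`, `sign`, `p`,
#'   `category`
#' @export
decision_report <- function(samples, side = "two_sided") {
  topo <- samples$topology
  n <- n_nodes(topo)
  out <- data.frame(node = seq_len(n), taxon = topo$label,
                    mean = NA_real_, variance = NA_real_,
                    sign = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    d <- node_beta_draws(samples, i)
    out$mean[i] <- mean(d)
    out$variance[i] <- stats::var(d)
    out$sign[i] <- sign(out$mean[i])
    out$p[i] <- tail_probability(d, side = side)
  }
  out$category <- decision_category(out$p)
  class(out) <- c("decision_report", "data.frame")
  out
}

#' Compare decision reports with and without the phylogeny
#'
#' Joins two reports on their shared taxa (leaves) and tabulates the
#' category change and any sign flip of the posterior mean slope per taxon.
#'
#' @param report_phylo report from the phylogenetic fit
#' @param report_plain report from the star-tree (no phylogeny) fit
#' @return data.frame with columns `taxon`, `category_without`,
#'   `category_with`, `change` (improved / worsened / no_change) and
#'   `sign_flip`
#' @export
compare_models <- function(report_phylo, report_plain) {
  tp <- report_phylo[report_phylo$taxon != "", ]
  tq <- report_plain[report_plain$taxon != "", ]
  if (!setequal(tp$taxon, tq$taxon))
    stop("taxon sets differ between the two reports")
  tq <- tq[match(tp$taxon, tq$taxon), ]
  # evidence strength decreases along DECISION_LEVELS
  rank_p <- 5L - as.integer(tp$category)   # higher = stronger
  rank_q <- 5L - as.integer(tq$category)
  change <- ifelse(rank_p > rank_q, "improved",
            ifelse(rank_p < rank_q, "worsened", "no_change"))
  data.frame(taxon = tp$taxon,
             category_without = as.character(tq$category),
             category_with = as.character(tp$category),
             change = change,
             sign_flip = tp$sign != tq$sign,
             stringsAsFactors = FALSE)
}

#' Fit the no-phylogeny comparator
#'
#' Runs the same sampler on a star topology with the root slope frozen at
#' the prior mean, so every taxon is an independent Bayesian logistic
#' regression with the same prior family as the phylogenetic model.
#'
#' @inheritParams sample_posterior
#' @return a `posterior_samples` over the star topology
#' @export
fit_plain <- function(data, h = hyperparams(), cfg = mcmc_config()) {
  sample_posterior(data, star_topology(data$taxon_ids), h, cfg,
                   fixed_root_beta = TRUE)
}
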
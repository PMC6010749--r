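# Independent oracles and small fixture builders used across the suite.

# Naive double-loop Bernoulli log-likelihood (oracle for log_likelihood).
naive_log_likelihood <- function(data, state, topo) {
  labs <- leaf_labels(topo)
  leaves <- which(topo$is_leaf)
  total <- 0
  for (i in seq_len(nrow(data$O))) {
    for (j in seq_along(data$taxon_ids)) {
      tx <- data$taxon_ids[j]
      b <- state$beta[leaves[match(tx, labs)]]
      p <- 1 / (1 + exp(-(state$alpha[[tx]] + b * data$x[i])))
      p <- min(max(p, 1e-300), 1 - 1e-16)
      total <- total + data$O[i, j] * log(p) + (1 - data$O[i, j]) * log(1 - p)
    }
  }
  total
}

# Brute-force pair-counting AUC (oracle for roc_auc).
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (p in pos) for (n in neg) wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# Restrict a canonical split set to a leaf subset (oracle for the
# prune-then-bipartition commutation property).
restrict_splits <- function(splits, remaining) {
  remaining <- sort(remaining)
  n <- length(remaining)
  out <- character(0)
  for (s in splits) {
    side <- intersect(strsplit(s, "|", fixed = TRUE)[[1]], remaining)
    sz <- length(side)
    if (sz < 2L || sz > n - 2L) next
    first <- remaining[1]
    if (!(first %in% side)) side <- setdiff(remaining, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  sort(unique(out))
}

# KS distance between draws and a density known up to a constant on a grid.
grid_ks <- function(draws, grid, log_density) {
  ld <- log_density - max(log_density)
  dens <- exp(ld)
  w <- diff(grid)
  mass <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * w))
  cdf <- mass / mass[length(mass)]
  at <- stats::approx(grid, cdf, xout = sort(draws), yleft = 0, yright = 1)$y
  emp <- seq_along(draws) / length(draws)
  max(abs(at - emp))
}

# Deterministic small occurrence fixture on a given topology.
make_fixture <- function(topo, n_sites = 30L, seed = 1L, alpha = NULL,
                         beta = NULL) {
  set.seed(seed)
  labs <- leaf_labels(topo)
  J <- length(labs)
  x <- rnorm(n_sites, 7.29, 0.92)
  if (is.null(alpha)) alpha <- stats::setNames(rnorm(J, -0.5, 0.7) - 0 * 7.29, labs)
  if (is.null(beta)) beta <- rnorm(J, 0.1, 0.3)
  eta <- outer(x - 7.29, beta) + rep(alpha, each = n_sites)
  O <- matrix(rbinom(n_sites * J, 1, plogis(eta)), n_sites, J)
  colnames(O) <- labs
  # guarantee both classes per column so fits are well-behaved
  O[1, ] <- 1
  O[2, ] <- 0
  occurrence_data(O, x)
}
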
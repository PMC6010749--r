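#' MCMC configuration
#'
#' Defaults follow the study schedule: five independent chains, 1,000 kept
#' draws per chain at a thinning interval of five, after 1,000 burn-in
#' sweeps.
#'
#' @param n_chains number of independent chains
#' @param burn_in discarded initial sweeps per chain
#' @param kept_per_chain stored draws per chain
#' @param thin store every `thin`-th sweep after burn-in
#' @param seed integer root seed; per-chain streams are derived from it
#' @param proposal_sd_init initial random-walk scale for leaf updates
#' @param adapt_during_burnin adapt proposal scales (Robbins-Monro towards
#'   0.44 acceptance) during burn-in only; scales are frozen afterwards
#' @return list of class `mcmc_config`
#' @export
mcmc_config <- function(n_chains = 5L, burn_in = 1000L, kept_per_chain = 1000L,
                        thin = 5L, seed = 1L, proposal_sd_init = 0.5,
                        adapt_during_burnin = TRUE) {
  stopifnot(n_chains >= 1, burn_in >= 1, kept_per_chain >= 1, thin >= 1,
            proposal_sd_init > 0)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 kept_per_chain = as.integer(kept_per_chain),
                 thin = as.integer(thin), seed = as.integer(seed),
                 proposal_sd_init = proposal_sd_init,
                 adapt_during_burnin = isTRUE(adapt_during_burnin)),
            class = "mcmc_config")
}

TAU_CAP <- 1e12

# Gamma full-conditional parameters for the precision of the edge into `node`
cond_tau_params <- function(node, state, topo, h) {
  bpar <- if (node == 1L) h$root_beta_mean else state$beta[topo$parent[node]]
  list(shape = h$tau_shape + 0.5,
       rate = h$tau_rate + 0.5 * (state$beta[node] - bpar)^2)
}

#' Conjugate Gibbs draw for one node precision
#'
#' The full conditional of tau_node is Gamma(shape + 1/2, rate +
#' (beta_node - beta_parent)^2 / 2): one Normal increment is governed by
#' each edge precision. Draws are capped at 1e12 for numerical safety.
#'
#' @param node node id
#' @param state a [model_state()]
#' @param topo the [topology()]
#' @param h a [hyperparams()]
#' @return new tau value for `node`
#' @export
update_tau <- function(node, state, topo, h) {
  p <- cond_tau_params(node, state, topo, h)
  min(stats::rgamma(1L, shape = p$shape, rate = p$rate), TAU_CAP)
}

# Gaussian full-conditional (mean, sd) for an internal node's slope
cond_beta_params <- function(node, state, topo, h, children = NULL) {
  if (is.null(children)) children <- topo_children(topo)[[node]]
  bpar <- if (node == 1L) h$root_beta_mean else state$beta[topo$parent[node]]
  prec <- state$tau[node] + sum(state$tau[children])
  m <- (state$tau[node] * bpar +
          sum(state$tau[children] * state$beta[children])) / prec
  list(mean = m, sd = 1 / sqrt(prec))
}

#' Conjugate Gibbs draw for an internal node slope
#'
#' Combines the Normal term from the node's own edge (towards its parent's
#' slope; the root towards `root_beta_mean`) with one Normal term per child
#' edge: precision tau_node + sum(tau_children), mean the precision-weighted
#' average of parent and child slopes.
#'
#' @inheritParams update_tau
#' @return new beta value for `node`
#' @export
update_internal_beta <- function(node, state, topo, h) {
  if (topo$is_leaf[node]) stop("node ", node, " is a leaf")
  p <- cond_beta_params(node, state, topo, h)
  stats::rnorm(1L, p$mean, p$sd)
}

#' Random-walk Metropolis update of one leaf's (alpha, beta)
#'
#' The Bernoulli likelihood makes leaf conditionals non-conjugate; alpha and
#' beta are updated componentwise by Gaussian random-walk proposals accepted
#' with probability min(1, exp(delta log posterior of the local terms)).
#'
#' @param leaf leaf node id
#' @param data an [occurrence_data()] whose column for this leaf's taxon is
#'   used
#' @param state a [model_state()]
#' @param topo the [topology()]
#' @param h a [hyperparams()]
#' @param scale_alpha,scale_beta proposal standard deviations
#' @return list with new `alpha`, `beta` and logical `accepted_alpha`,
#'   `accepted_beta`
#' @export
update_leaf_params <- function(leaf, data, state, topo, h,
                               scale_alpha = 0.5, scale_beta = 0.5) {
  if (!topo$is_leaf[leaf]) stop("node ", leaf, " is not a leaf")
  taxon <- topo$label[leaf]
  o <- data$O[, taxon]
  x <- data$x
  a <- state$alpha[[taxon]]
  b <- state$beta[leaf]
  bpar <- if (leaf == 1L) h$root_beta_mean else state$beta[topo$parent[leaf]]
  loglik <- function(a_, b_) {
    eta <- a_ + b_ * x
    sum(o * eta) - sum(log1pexp(eta))
  }
  ll <- loglik(a, b)
  # alpha
  a_new <- a + stats::rnorm(1L, 0, scale_alpha)
  ll_new <- loglik(a_new, b)
  logr <- ll_new - ll - 0.5 * h$alpha_precision * (a_new^2 - a^2)
  acc_a <- log(stats::runif(1L)) < logr
  if (acc_a) { a <- a_new; ll <- ll_new }
  # beta
  b_new <- b + stats::rnorm(1L, 0, scale_beta)
  ll_new <- loglik(a, b_new)
  logr <- ll_new - ll - 0.5 * state$tau[leaf] * ((b_new - bpar)^2 - (b - bpar)^2)
  acc_b <- log(stats::runif(1L)) < logr
  if (acc_b) b <- b_new
  list(alpha = a, beta = b, accepted_alpha = acc_a, accepted_beta = acc_b)
}

# one full chain; assumes data columns are already ordered to match the
# leaf order of `topo` (taxon_ids == leaf_labels(topo))
run_chain <- function(data, topo, h, cfg, chain_seed, fixed_root_beta) {
  set.seed(chain_seed)
  O <- data$O
  x <- data$x
  ns <- nrow(O)
  n <- n_nodes(topo)
  leaves <- which(topo$is_leaf)
  internals <- which(!topo$is_leaf)
  if (fixed_root_beta) internals <- setdiff(internals, 1L)
  J <- length(leaves)
  parent <- topo$parent
  ch <- topo_children(topo)
  # Leaf updates run in the (gamma, beta) parameterization with
  # gamma = alpha + beta * mean(x): with a covariate far from zero alpha and
  # beta are nearly collinear and componentwise walks on (alpha, beta) mix
  # badly; the rotation has unit Jacobian and leaves the posterior unchanged.
  xbar <- if (ns > 0) mean(x) else 0
  xc <- x - xbar
  s1 <- colSums(O)          # presences per taxon
  xO <- as.numeric(crossprod(O, xc))
  col_loglik <- function(g, b) {
    eta <- outer(xc, b) + rep(g, each = ns)
    g * s1 + b * xO - colSums(pmax(eta, 0) + log1p(exp(-abs(eta))))
  }
  # deterministic, data-informed initialization
  occ <- if (ns > 0) pmin(pmax(colMeans(O), 1 / (2 * max(ns, 1))),
                          1 - 1 / (2 * max(ns, 1))) else rep(0.5, J)
  gamma <- pmin(pmax(stats::qlogis(occ), -3), 3)  # intercept at mean covariate
  beta <- rep(0, n)
  if (fixed_root_beta) beta[1] <- h$root_beta_mean
  tau <- rep(1, n)
  ll_cur <- col_loglik(gamma, beta[leaves])
  if (any(!is.finite(ll_cur))) stop("non-finite log posterior at initialization")
  ls_a <- rep(log(cfg$proposal_sd_init), J)
  ls_b <- rep(log(cfg$proposal_sd_init), J)
  acc_a_n <- acc_b_n <- 0
  kept <- cfg$kept_per_chain
  draw_alpha <- matrix(NA_real_, kept, J)
  draw_beta <- matrix(NA_real_, kept, n)
  draw_tau <- matrix(NA_real_, kept, n)
  total <- cfg$burn_in + kept * cfg$thin
  store_row <- 0L
  pl <- parent[leaves]
  a_shape <- h$tau_shape + 0.5
  for (sweep in seq_len(total)) {
    in_burn <- sweep <= cfg$burn_in
    # --- tau | beta: independent conjugate Gamma draws, vectorized
    bpar_all <- c(h$root_beta_mean, beta[parent[-1]])
    if (n == 1L) bpar_all <- h$root_beta_mean
    ss <- (beta - bpar_all)^2
    tau <- pmin(stats::rgamma(n, shape = a_shape, rate = h$tau_rate + ss / 2),
                TAU_CAP)
    # --- internal beta: sequential exact Gaussian draws in preorder
    for (i in internals) {
      kids <- ch[[i]]
      bp <- if (i == 1L) h$root_beta_mean else beta[parent[i]]
      prec <- tau[i] + sum(tau[kids])
      m <- (tau[i] * bp + sum(tau[kids] * beta[kids])) / prec
      beta[i] <- stats::rnorm(1L, m, 1 / sqrt(prec))
    }
    # --- leaf gamma (intercept): RW Metropolis, vectorized across leaves;
    #     the alpha prior is evaluated at alpha = gamma - beta * xbar
    bl <- beta[leaves]
    g_new <- gamma + exp(ls_a) * stats::rnorm(J)
    ll_new <- col_loglik(g_new, bl)
    logr <- ll_new - ll_cur -
      0.5 * h$alpha_precision * ((g_new - bl * xbar)^2 - (gamma - bl * xbar)^2)
    acc <- log(stats::runif(J)) < logr
    gamma[acc] <- g_new[acc]
    ll_cur[acc] <- ll_new[acc]
    if (in_burn && cfg$adapt_during_burnin)
      ls_a <- ls_a + (pmin(1, exp(logr)) - 0.44) / sqrt(sweep)
    if (!in_burn) acc_a_n <- acc_a_n + sum(acc)
    # --- leaf beta: same scheme; prior terms from the leaf edge and from
    #     the induced shift of alpha
    bp <- numeric(J)
    bp[pl == 0L] <- h$root_beta_mean
    bp[pl > 0L] <- beta[pl[pl > 0L]]
    b_new <- bl + exp(ls_b) * stats::rnorm(J)
    ll_new <- col_loglik(gamma, b_new)
    logr <- ll_new - ll_cur -
      0.5 * tau[leaves] * ((b_new - bp)^2 - (bl - bp)^2) -
      0.5 * h$alpha_precision *
        ((gamma - b_new * xbar)^2 - (gamma - bl * xbar)^2)
    acc <- log(stats::runif(J)) < logr
    bl[acc] <- b_new[acc]
    ll_cur[acc] <- ll_new[acc]
    beta[leaves] <- bl
    if (in_burn && cfg$adapt_during_burnin)
      ls_b <- ls_b + (pmin(1, exp(logr)) - 0.44) / sqrt(sweep)
    if (!in_burn) acc_b_n <- acc_b_n + sum(acc)
    # --- store
    if (!in_burn && (sweep - cfg$burn_in) %% cfg$thin == 0L) {
      store_row <- store_row + 1L
      draw_alpha[store_row, ] <- gamma - bl * xbar
      draw_beta[store_row, ] <- beta
      draw_tau[store_row, ] <- tau
    }
  }
  post_sweeps <- kept * cfg$thin
  list(alpha = draw_alpha, beta = draw_beta, tau = draw_tau,
       acceptance = c(alpha = acc_a_n / (post_sweeps * J),
                      beta = acc_b_n / (post_sweeps * J)))
}

#' Draw from the posterior of the phylogeny-based logistic model
#'
#' Metropolis-within-Gibbs: exact conjugate Gamma updates for every node
#' precision, exact Gaussian updates for every internal-node slope, and
#' componentwise adaptive random-walk Metropolis for each leaf's
#' (intercept, slope). One sweep updates every parameter once. Chains are
#' seeded deterministically from `cfg$seed`; a fixed seed gives bit-identical
#' output.
#'
#' @param data an [occurrence_data()]; its taxon set must equal the
#'   topology's leaf set
#' @param topo a [topology()]
#' @param h a [hyperparams()]
#' @param cfg an [mcmc_config()]
#' @param fixed_root_beta if TRUE the root slope is frozen at
#'   `h$root_beta_mean` instead of being sampled; on a [star_topology()]
#'   this makes every taxon an independent Bayesian logistic regression
#'   (the "no phylogeny" comparator)
#' @param center_covariate if TRUE, `x - mean(x)` is used as the covariate;
#'   slopes are unchanged but intercepts then refer to the mean covariate
#'   value. Default FALSE: the covariate is used as given.
#' @return object of class `posterior_samples`: arrays `alpha`
#'   (draw, chain, taxon), `beta` and `tau` (draw, chain, node), per-block
#'   `acceptance` rates, the `topology`, `config` echo and `fixed_root_beta`
#'   flag
#' @export
sample_posterior <- function(data, topo, h = hyperparams(),
                             cfg = mcmc_config(), fixed_root_beta = FALSE,
                             center_covariate = FALSE) {
  labs <- leaf_labels(topo)
  if (!setequal(data$taxon_ids, labs))
    stop("taxon set of data and topology leaves differ")
  if (center_covariate && length(data$x))
    data <- occurrence_data(data$O, data$x - mean(data$x),
                            require_presence = FALSE)
  # reorder data columns to leaf order once
  if (!identical(data$taxon_ids, labs)) {
    data <- occurrence_data(data$O[, labs, drop = FALSE], data$x,
                            require_presence = FALSE)
  }
  n <- n_nodes(topo)
  J <- length(labs)
  kept <- cfg$kept_per_chain
  alpha <- array(NA_real_, c(kept, cfg$n_chains, J),
                 dimnames = list(NULL, NULL, labs))
  node_names <- paste0("node", seq_len(n))
  beta <- array(NA_real_, c(kept, cfg$n_chains, n),
                dimnames = list(NULL, NULL, node_names))
  tau <- array(NA_real_, c(kept, cfg$n_chains, n),
               dimnames = list(NULL, NULL, node_names))
  acc <- matrix(NA_real_, cfg$n_chains, 2,
                dimnames = list(NULL, c("alpha", "beta")))
  for (c_ in seq_len(cfg$n_chains)) {
    res <- run_chain(data, topo, h, cfg,
                     chain_seed = derive_seed(cfg$seed, c_),
                     fixed_root_beta = fixed_root_beta)
    alpha[, c_, ] <- res$alpha
    beta[, c_, ] <- res$beta
    tau[, c_, ] <- res$tau
    acc[c_, ] <- res$acceptance
  }
  structure(list(alpha = alpha, beta = beta, tau = tau, acceptance = acc,
                 topology = topo, config = cfg, hyper = h,
                 fixed_root_beta = fixed_root_beta),
            class = "posterior_samples")
}

# fixed per-chain seed stream below 2^31
derive_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) %% 2003741) * 1069 + 7919 * chain)
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$beta)
  cat(sprintf(
    "posterior_samples: %d draws x %d chains; %d nodes, %d taxa\n",
    d[1], d[2], d[3], dim(x$alpha)[3]))
  cat(sprintf("mean acceptance: alpha %.2f, beta %.2f\n",
              mean(x$acceptance[, "alpha"]), mean(x$acceptance[, "beta"])))
  invisible(x)
}

# draws for one node's slope pooled across chains
node_beta_draws <- function(samples, node) as.numeric(samples$beta[, , node])

#' Posterior means of all node slopes
#' @param samples a `posterior_samples`
#' @return numeric vector, one entry per node
#' @export
posterior_mean_beta <- function(samples) apply(samples$beta, 3, mean)

#' Posterior means of all leaf intercepts
#' @param samples a `posterior_samples`
#' @return named numeric vector, one entry per taxon
#' @export
posterior_mean_alpha <- function(samples) apply(samples$alpha, 3, mean)

#' Flatten posterior draws to a data frame
#'
#' One column per parameter, named `alpha[taxon]`, `beta[node]`,
#' `tau[node]`, plus `chain` and `draw` indices.
#'
#' @param x a `posterior_samples`
#' @param ... unused
#' @param row.names,optional ignored (S3 signature)
#' @return data.frame with one row per (chain, draw)
#' @export
as.data.frame.posterior_samples <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  kept <- dim(x$alpha)[1]; nc <- dim(x$alpha)[2]
  flat <- function(arr, prefix, ids) {
    m <- matrix(arr, nrow = kept * nc)
    colnames(m) <- sprintf("%s[%s]", prefix, ids)
    m
  }
  taxa <- dimnames(x$alpha)[[3]]
  nodes <- seq_len(dim(x$beta)[3])
  df <- data.frame(chain = rep(seq_len(nc), each = kept),
                   draw = rep(seq_len(kept), nc))
  cbind(df, flat(x$alpha, "alpha", taxa), flat(x$beta, "beta", nodes),
        flat(x$tau, "tau", nodes))
}

#' Gelman-Rubin potential scale reduction diagnostic
#'
#' The classic between/within-chain variance ratio per parameter, floored at
#' 1 (identical chains give exactly 1). Values near 1 indicate mixing;
#' values well above 1 indicate chains exploring different regions.
#'
#' @param samples a `posterior_samples` with at least two chains
#' @return named numeric vector over all parameters
#' @export
gelman_rubin <- function(samples) {
  if (dim(samples$alpha)[2] < 2L) stop("need at least 2 chains")
  df <- as.data.frame(samples)
  pars <- setdiff(names(df), c("chain", "draw"))
  chains <- unique(df$chain)
  vapply(pars, function(p) {
    segs <- lapply(chains, function(c_) df[[p]][df$chain == c_])
    nn <- length(segs[[1]])
    means <- vapply(segs, mean, 0)
    vars <- vapply(segs, stats::var, 0)
    W <- mean(vars)
    B <- nn * stats::var(means)
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(max(((nn - 1) / nn * W + B / nn) / W, 1))
  }, 0)
}

#' Effective sample size of a single parameter chain
#'
#' Autocorrelation-based estimate using Geyer's initial positive sequence on
#' the pooled draws of each chain, summed over chains.
#'
#' @param draws matrix draws x chains (or a vector for one chain)
#' @return scalar effective sample size
#' @export
effective_size <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  per_chain <- apply(draws, 2, function(v) {
    nv <- length(v)
    if (stats::var(v) == 0) return(nv)
    rho <- stats::acf(v, lag.max = min(nv - 1L, 500L), plot = FALSE)$acf[-1]
    s <- 0; k <- 1
    while (k + 1 <= length(rho)) {
      g <- rho[k] + rho[k + 1]
      if (g < 0) break
      s <- s + g
      k <- k + 2
    }
    nv / (1 + 2 * s)
  })
  sum(per_chain)
}
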
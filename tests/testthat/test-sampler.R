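topo4 <- parse_newick("((A,B),(C,D));")

test_that("tau update follows the conjugate Gamma full conditional", {
  h <- hyperparams()
  st <- model_state(alpha = stats::setNames(rep(0, 4), leaf_labels(topo4)),
                    beta = rep(0.7, 7), tau = rep(1, 7))
  # beta_node == beta_parent: posterior Gamma(0.501, 0.001), mean 501
  set.seed(1)
  draws <- replicate(2e4, update_tau(5L, st, topo4, h))
  expect_true(all(draws > 0))
  expect_equal(mean(draws), 0.501 / 0.001, tolerance = 0.05)
  # with a known gap, long-run mean matches the analytic posterior mean
  st$beta[5] <- st$beta[2] + 1.3
  set.seed(2)
  draws <- replicate(2e4, update_tau(5L, st, topo4, h))
  expect_equal(mean(draws), 0.501 / (0.001 + 1.3^2 / 2), tolerance = 0.05)
})

test_that("internal beta update is the precision-weighted Gaussian draw", {
  h <- hyperparams()
  # chain root -> node2 -> leaf: single child with equal tau gives midpoint
  t3 <- topology(c(0L, 1L, 2L), c("", "", "L"))
  st <- model_state(alpha = c(L = 0), beta = c(2, 0, 6), tau = c(1e8, 5, 5))
  set.seed(3)
  draws <- replicate(5e3, update_internal_beta(2L, st, t3, h))
  expect_equal(mean(draws), (2 + 6) / 2, tolerance = 0.05)
  # tau_node >> children: conditional collapses to the parent value
  st2 <- model_state(alpha = c(L = 0), beta = c(2, 0, 6), tau = c(1, 1e9, 1e-3))
  set.seed(4)
  draws <- replicate(2e3, update_internal_beta(2L, st2, t3, h))
  expect_equal(mean(draws), 2, tolerance = 0.01)
  expect_lt(sd(draws), 1e-3)
  expect_error(update_internal_beta(3L, st, t3, h), "leaf")
})

test_that("leaf Metropolis proposals with zero posterior change are accepted", {
  h <- hyperparams()
  d <- make_fixture(topo4, n_sites = 10, seed = 5)
  st <- model_state(alpha = stats::setNames(rep(0, 4), leaf_labels(topo4)),
                    beta = rep(0, 7), tau = rep(1, 7))
  # scale ~ 0 means the proposal equals the current point: always accepted
  set.seed(6)
  res <- update_leaf_params(4L, d, st, topo4, h,
                            scale_alpha = 1e-300, scale_beta = 1e-300)
  expect_true(res$accepted_alpha)
  expect_true(res$accepted_beta)
})

test_that("posterior sampling is deterministic, well-shaped and mixes", {
  d <- make_fixture(topo4, n_sites = 40, seed = 8)
  cfg <- mcmc_config(n_chains = 2, burn_in = 300, kept_per_chain = 250,
                     thin = 2, seed = 9)
  s1 <- sample_posterior(d, topo4, hyperparams(), cfg)
  s2 <- sample_posterior(d, topo4, hyperparams(), cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$alpha, s2$alpha)
  expect_equal(dim(s1$beta), c(250L, 2L, 7L))
  expect_equal(dim(s1$alpha), c(250L, 2L, 4L))
  expect_true(all(s1$tau > 0))
  # adapted acceptance rates in the healthy random-walk band
  expect_true(all(s1$acceptance >= 0.15 & s1$acceptance <= 0.6))
  expect_lt(max(gelman_rubin(s1)), 1.2)
})

test_that("default schedule keeps five chains of 1000 draws per parameter", {
  d <- make_fixture(parse_newick("(A,B);"), n_sites = 8, seed = 10)
  cfg <- mcmc_config(seed = 11)   # 5 chains, 1000 kept, thin 5, 1000 burn-in
  s <- sample_posterior(d, parse_newick("(A,B);"), hyperparams(), cfg)
  expect_equal(dim(s$beta), c(1000L, 5L, 3L))
  expect_equal(dim(s$alpha)[1:2], c(1000L, 5L))
})

test_that("gelman_rubin flags disjoint chains and passes identical ones", {
  d <- make_fixture(parse_newick("(A,B);"), n_sites = 10, seed = 12)
  cfg <- mcmc_config(n_chains = 2, burn_in = 100, kept_per_chain = 100,
                     thin = 1, seed = 13)
  s <- sample_posterior(d, parse_newick("(A,B);"), hyperparams(), cfg)
  # identical chains by construction -> Rhat exactly 1
  s$beta[, 2, ] <- s$beta[, 1, ]
  s$alpha[, 2, ] <- s$alpha[, 1, ]
  s$tau[, 2, ] <- s$tau[, 1, ]
  expect_true(all(abs(gelman_rubin(s) - 1) < 1e-8))
  # disjoint ranges -> Rhat far above 1
  s$beta[, 2, ] <- s$beta[, 2, ] + 50
  expect_gt(max(gelman_rubin(s)), 3)
  one <- s; one$alpha <- one$alpha[, 1, , drop = FALSE]
  expect_error(gelman_rubin(one), "2 chains")
})

test_that("prior-only sampling recovers proper priors on an empty dataset", {
  # proper hyperparameters with finite inverse-square moments:
  # tau ~ Gamma(3, 3) so E[tau] = 1 and E[1/tau] = 3/2
  h <- hyperparams(alpha_precision = 1, tau_shape = 3, tau_rate = 3)
  O <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("A", "B")))
  d <- occurrence_data(O, numeric(0), require_presence = FALSE)
  t2 <- star_topology(c("A", "B"))
  cfg <- mcmc_config(n_chains = 2, burn_in = 500, kept_per_chain = 4000,
                     thin = 2, seed = 14)
  s <- sample_posterior(d, t2, h, cfg)
  expect_equal(mean(s$tau), 1, tolerance = 0.1)
  # marginal root slope variance = E[1/tau] = rate/(shape-1) = 1.5
  expect_equal(var(as.numeric(s$beta[, , 1])), 1.5, tolerance = 0.2)
  expect_equal(var(as.numeric(s$alpha)), 1, tolerance = 0.1)
})

test_that("successive- and marginal-conditional simulators agree (Geweke)", {
  # 4-leaf tree, proper hyperparameters, data redrawn each scan through the
  # exported single-site update functions; the stationary law of the
  # parameters is then the prior, whose moments are known.
  h <- hyperparams(alpha_precision = 1, tau_shape = 3, tau_rate = 3)
  set.seed(15)
  x <- rnorm(8, 0, 1)
  labs <- leaf_labels(topo4)
  leaves <- which(topo4$is_leaf)
  draw_data <- function(st) {
    eta <- outer(x, st$beta[leaves]) + rep(st$alpha, each = length(x))
    O <- matrix(rbinom(length(eta), 1, plogis(eta)), length(x))
    colnames(O) <- labs
    occurrence_data(O, x, require_presence = FALSE)
  }
  st <- model_state(alpha = stats::setNames(rnorm(4), labs),
                    beta = rnorm(7), tau = rgamma(7, 3, 3))
  n_iter <- 4000L
  keep <- matrix(NA_real_, n_iter, 3,
                 dimnames = list(NULL, c("beta_root", "beta_leafA", "alpha_A")))
  set.seed(16)
  for (it in seq_len(n_iter)) {
    dat <- draw_data(st)
    for (nd in 1:7) st$tau[nd] <- update_tau(nd, st, topo4, h)
    for (nd in which(!topo4$is_leaf)) {
      st$beta[nd] <- update_internal_beta(nd, st, topo4, h)
    }
    for (lf in leaves) {
      r <- update_leaf_params(lf, dat, st, topo4, h, 0.8, 0.8)
      st$alpha[[topo4$label[lf]]] <- r$alpha
      st$beta[lf] <- r$beta
    }
    keep[it, ] <- c(st$beta[1], st$beta[leaves[1]], st$alpha[["A"]])
  }
  # prior moments: beta_root ~ scale mixture with Var = E[1/tau] = 1.5;
  # beta_leaf adds two more increments (depth 2 below the root) -> Var = 4.5;
  # alpha ~ N(0, 1).
  for (j in 1:3) {
    v <- keep[, j]
    se <- sd(v) / sqrt(effective_size(v))
    expect_lt(abs(mean(v) - 0), 4 * se)
  }
  expect_equal(var(keep[, "beta_root"]), 1.5, tolerance = 0.25)
  expect_equal(var(keep[, "beta_leafA"]), 4.5, tolerance = 0.25)
  expect_equal(var(keep[, "alpha_A"]), 1, tolerance = 0.15)
})

test_that("decoupled prior (tiny leaf precision pull) matches per-taxon fits", {
  # star tree vs independent plain fits on the same data must agree on leaf
  # slope posteriors when the root slope is frozen: identical machinery
  d <- make_fixture(star_topology(c("A", "B")), n_sites = 25, seed = 17)
  cfg <- mcmc_config(n_chains = 2, burn_in = 400, kept_per_chain = 600,
                     thin = 1, seed = 18)
  s_star <- sample_posterior(d, star_topology(c("A", "B")), hyperparams(),
                             cfg, fixed_root_beta = TRUE)
  s_plain <- fit_plain(d, hyperparams(), cfg)
  expect_identical(s_star$beta, s_plain$beta)
})
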
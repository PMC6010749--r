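#' Hyperparameters of the phylogeny-based logistic occurrence model
#'
#' All Normal distributions in the model are parameterized by precision
#' (inverse variance), the BUGS convention. Leaf intercepts have a diffuse
#' Normal(0, precision `alpha_precision`) prior; every node's slope is
#' Normal(parent slope, precision `tau`) with the root anchored at
#' `root_beta_mean`; each per-node precision has a Gamma(`tau_shape`,
#' `tau_rate`) prior. The reporting quantity sigma = 1/tau is the variance
#' under this convention and is never sampled.
#'
#' @param alpha_precision prior precision of leaf intercepts (default 1e-6,
#'   i.e. variance 1e6)
#' @param tau_shape,tau_rate Gamma prior on each node precision (default
#'   0.001, 0.001 — nearly uninformative)
#' @param root_beta_mean prior mean of the root slope (default 0)
#' @return list of class `hyperparams`
#' @export
hyperparams <- function(alpha_precision = 1e-6, tau_shape = 0.001,
                        tau_rate = 0.001, root_beta_mean = 0) {
  stopifnot(alpha_precision > 0, tau_shape > 0, tau_rate > 0,
            is.finite(root_beta_mean))
  structure(list(alpha_precision = alpha_precision, tau_shape = tau_shape,
                 tau_rate = tau_rate, root_beta_mean = root_beta_mean),
            class = "hyperparams")
}

#' Site x taxon occurrence data with a per-site covariate
#'
#' @param O binary matrix, sites in rows, taxa in columns; column names are
#'   taxon names, row names site ids (generated when missing)
#' @param x numeric covariate per site (e.g. stream pH)
#' @param require_presence if TRUE (default) every taxon must occur in at
#'   least one site
#' @return list of class `occurrence_data` with fields `O`, `x`,
#'   `site_ids`, `taxon_ids`
#' @export
occurrence_data <- function(O, x, require_presence = TRUE) {
  O <- as.matrix(O)
  storage.mode(O) <- "double"
  if (anyNA(O) || !all(O %in% c(0, 1))) stop("O must be 0/1 with no missing cells")
  x <- as.numeric(x)
  if (length(x) != nrow(O)) stop("length(x) must equal nrow(O)")
  if (anyNA(x) || any(!is.finite(x))) stop("covariate must be finite")
  if (is.null(colnames(O))) stop("O must have taxon column names")
  if (anyDuplicated(colnames(O))) stop("duplicate taxon names")
  if (is.null(rownames(O)) && nrow(O) > 0)
    rownames(O) <- paste0("site", seq_len(nrow(O)))
  if (require_presence && nrow(O) > 0 && any(colSums(O) == 0))
    stop("taxa with no occurrences: ",
         paste(colnames(O)[colSums(O) == 0], collapse = ", "))
  structure(list(O = O, x = x, site_ids = rownames(O), taxon_ids = colnames(O)),
            class = "occurrence_data")
}

#' @export
print.occurrence_data <- function(x, ...) {
  cat(sprintf("occurrence_data: %d sites x %d taxa, covariate range [%.3g, %.3g]\n",
              nrow(x$O), ncol(x$O), min(x$x), max(x$x)))
  invisible(x)
}

#' One full parameter assignment of the model
#'
#' @param alpha named numeric, one logit intercept per leaf taxon
#' @param beta numeric, one slope per topology node (node-id order)
#' @param tau positive numeric, one precision per topology node
#' @return list of class `model_state`; `sigma` (= 1/tau) is derived on
#'   access via [state_sigma()]
#' @export
model_state <- function(alpha, beta, tau) {
  if (any(tau <= 0)) stop("tau must be strictly positive")
  stopifnot(length(beta) == length(tau), !is.null(names(alpha)))
  structure(list(alpha = alpha, beta = beta, tau = tau), class = "model_state")
}

#' Per-node variance sigma = 1/tau of a model state
#' @param state a [model_state()]
#' @return numeric vector of variances
#' @export
state_sigma <- function(state) 1 / state$tau

# log(1 + exp(eta)) without overflow
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

#' Occurrence probability under the logit link
#'
#' P = logistic(alpha + beta * x), numerically stable for extreme linear
#' predictors.
#'
#' @param alpha intercept (logit scale)
#' @param beta slope (per covariate unit)
#' @param x covariate value(s)
#' @return probability in (0, 1), clamped away from exact 0/1
#' @examples
#' occurrence_probability(0, log(9), 1)  # 0.9
#' @export
occurrence_probability <- function(alpha, beta, x) {
  p <- stats::plogis(alpha + beta * x)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Bernoulli log-likelihood of the occurrence data
#'
#' Sum over all (site, taxon) cells of the Bernoulli log-probability with
#' P(i, j) = logistic(alpha_j + beta_j x_i); beta_j is the slope of the leaf
#' carrying taxon j. Always finite.
#'
#' @param data an [occurrence_data()]
#' @param state a [model_state()]
#' @param topo the [topology()] the state is indexed by
#' @return scalar log-likelihood
#' @export
log_likelihood <- function(data, state, topo) {
  idx <- match(data$taxon_ids, leaf_labels(topo))
  if (anyNA(idx)) stop("taxa in data not found among topology leaves: ",
                       paste(data$taxon_ids[is.na(idx)], collapse = ", "))
  if (length(state$beta) != n_nodes(topo)) stop("state/topology size mismatch")
  a <- state$alpha[data$taxon_ids]
  if (anyNA(a)) stop("state alpha is missing taxa present in the data")
  b <- state$beta[which(topo$is_leaf)[idx]]
  eta <- outer(data$x, b) + rep(a, each = nrow(data$O))
  sum(data$O * eta) - sum(log1pexp(eta))
}

#' Log-prior of the model state
#'
#' Normal log-density of every node slope given its parent's slope (the root
#' given `root_beta_mean`) with the node's own precision, plus the Gamma
#' log-prior of every node precision, plus the Normal(0, `alpha_precision`)
#' log-prior of every leaf intercept.
#'
#' @inheritParams log_likelihood
#' @param h a [hyperparams()]
#' @return scalar log-prior density
#' @export
log_prior <- function(state, topo, h) {
  n <- n_nodes(topo)
  stopifnot(length(state$beta) == n, length(state$tau) == n)
  if (any(state$tau <= 0)) stop("tau must be strictly positive")
  bpar <- c(h$root_beta_mean, state$beta[topo$parent[-1]])
  if (n == 1L) bpar <- h$root_beta_mean
  sum(stats::dnorm(state$beta, mean = bpar, sd = 1 / sqrt(state$tau), log = TRUE)) +
    sum(stats::dgamma(state$tau, shape = h$tau_shape, rate = h$tau_rate, log = TRUE)) +
    sum(stats::dnorm(state$alpha, mean = 0, sd = 1 / sqrt(h$alpha_precision),
                     log = TRUE))
}

#' Log-posterior (likelihood + prior) up to a constant
#'
#' @inheritParams log_prior
#' @inheritParams log_likelihood
#' @return scalar
#' @export
log_posterior <- function(data, state, topo, h) {
  log_likelihood(data, state, topo) + log_prior(state, topo, h)
}

#' Read an occurrence matrix from a delimited file
#'
#' Expected layout: header row of taxon names, first column site ids, cells
#' 0/1. Comma-separated by default; tab accepted (auto-detected).
#'
#' @param path file path
#' @return binary matrix with dimnames
#' @export
read_occurrence <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, fileEncoding = "UTF-8")
  as.matrix(df)
}

#' Read a per-site covariate from a two-column delimited file
#'
#' First column site id, second column the covariate value.
#'
#' @param path file path
#' @return named numeric vector
#' @export
read_environment <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("environment file needs two columns: site, value")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (grepl("\t", first)) "\t" else ","
}

#' Assemble occurrence data from matrix + covariate files
#'
#' @param occurrence_path path to the site x taxon 0/1 matrix
#' @param environment_path path to the site,covariate table
#' @return an [occurrence_data()]; sites are matched by id and must agree
#' @export
read_occurrence_data <- function(occurrence_path, environment_path) {
  O <- read_occurrence(occurrence_path)
  x <- read_environment(environment_path)
  missing <- setdiff(rownames(O), names(x))
  if (length(missing)) stop("sites without covariate: ",
                            paste(missing, collapse = ", "))
  occurrence_data(O, unname(x[rownames(O)]))
}
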
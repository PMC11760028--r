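# Poisson count log-likelihood on the latent (lineage, time-grid) states,
# E-step posteriors, and the evidence lower bound.

# log(lambda) with a hard floor so that zero means give effectively -Inf
# log-likelihood for positive counts without generating NaN in matrix
# products (0 * -Inf); exp(-690) is far below any attainable density ratio
safe_log <- function(x) log(pmax(x, 1e-300))

# per-cell additive constants: sum_j x log r_i - sum_j log(x!)
loglik_constants <- function(data) {
  tot <- rowSums(data$unspliced) + rowSums(data$spliced)
  lfact <- rowSums(lgamma(data$unspliced + 1)) +
    rowSums(lgamma(data$spliced + 1))
  tot * log(data$read_depth) - lfact
}

#' Per-cell log-likelihood over the latent grid
#'
#' Computes the n x Z table of Poisson log-likelihoods
#' \eqn{\log p(x_i | z, \theta) = \sum_{j,c} [x_{ijc} \log(r_i \lambda_c(z))
#' - r_i \lambda_c(z) - \log x_{ijc}!]} for every latent state z =
#' (lineage, grid time) of the prior, with the optional t = 0 atom (steady
#' state means) as the last column. Invariant under the rescaling
#' (r, alpha) -> (c r, alpha / c).
#'
#' @param data a \code{\link{count_dataset}}.
#' @param structure a \code{\link{trajectory_structure}}.
#' @param kin a \code{\link{gene_kinetics}}.
#' @param prior a \code{\link{sampling_prior}}.
#' @param constants optional precomputed \code{loglik_constants(data)}.
#' @param means optional precomputed \code{grid_means(...)}.
#' @return an n x Z matrix of log-likelihoods.
#' @export
log_likelihood_grid <- function(data, structure, kin, prior,
                                constants = NULL, means = NULL) {
  if (is.null(means)) means <- grid_means(structure, kin, prior)
  if (is.null(constants)) constants <- loglik_constants(data)
  r <- data$read_depth
  tot_mean <- colSums(means$lambda_u) + colSums(means$lambda_s)  # T_z
  ll <- data$unspliced %*% safe_log(means$lambda_u) +
    data$spliced %*% safe_log(means$lambda_s)
  ll <- ll - outer(r, tot_mean) + constants
  unname(as.matrix(ll))
}

#' E-step: posterior over latent states
#'
#' Normalizes \code{prior * exp(loglik)} per cell with a log-sum-exp stable
#' computation.
#'
#' @param loglik n x Z log-likelihood table from
#'   \code{\link{log_likelihood_grid}}.
#' @param prior a \code{\link{sampling_prior}}, or an n x Z matrix of
#'   per-cell prior weights.
#' @return a list with \code{posterior} (n x Z, rows summing to 1) and
#'   \code{log_marginal} (per-cell log of the normalizer, whose sum is the
#'   log marginal likelihood on the discretized grid).
#' @export
e_step <- function(loglik, prior) {
  lp <- if (is.matrix(prior)) safe_log(prior) else
    matrix(prior$log_weights, nrow(loglik), length(prior$log_weights),
           byrow = TRUE)
  a <- loglik + lp
  mx <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  bad <- !is.finite(mx)
  if (any(bad))
    stop("cells with no admissible latent state (all -Inf likelihood): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  w <- exp(a - mx)
  sw <- rowSums(w)
  list(posterior = w / sw, log_marginal = mx + log(sw))
}

#' Evidence lower bound for a given responsibility matrix
#'
#' \eqn{\sum_i \sum_z q_i(z) [\log p(z) + \log p(x_i|z) - \log q_i(z)]}
#' with the convention 0 log 0 = 0. Equals the log marginal likelihood when
#' q is the exact posterior, and is bounded above by it for any valid q.
#'
#' @inheritParams e_step
#' @param posterior n x Z responsibilities, rows summing to 1.
#' @return a scalar.
#' @export
compute_elbo <- function(loglik, posterior, prior) {
  lp <- if (is.matrix(prior)) safe_log(prior) else
    matrix(prior$log_weights, nrow(loglik), length(prior$log_weights),
           byrow = TRUE)
  q <- posterior
  terms <- q * (lp + loglik - safe_log(q))
  terms[q == 0] <- 0
  sum(terms)
}
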
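# Model assessment: gene selection by relative gene-wise likelihood,
# information criteria, held-out ELBO, Fisher information, restart- and
# bootstrap-based uncertainty, DE ranking, posterior entropy.

#' Per-gene likelihood decomposition of a trajectory fit
#'
#' Each gene receives an equal 1/p share of the latent-variable
#' (prior/entropy) term of the ELBO plus its own conditional term
#' \eqn{\sum_i \sum_z q_i(z) \log p(x_{ij} | z, \theta_j)}. Scores sum
#' exactly to the fit's ELBO and are compared with
#' \code{\link{mixture_gene_likelihood}} for gene selection.
#'
#' @param fit a \code{"traj_fit"}.
#' @param data a \code{\link{count_dataset}}; defaults to the fit's data.
#' @return numeric vector of per-gene scores.
#' @export
trajectory_gene_likelihood <- function(fit, data = fit$data) {
  q <- fit$posterior
  n <- nrow(q); p <- ncol(data$unspliced)
  lp <- matrix(fit$prior$log_weights, n, ncol(q), byrow = TRUE)
  pt <- q * (lp - safe_log(q))
  pt[q == 0] <- 0
  prior_term <- sum(pt)
  suff <- suff_stats(q, data)
  cond <- gene_conditional_term(fit$kinetics, fit$structure, fit$prior,
                                suff, data)
  prior_term / p + cond
}

#' Select dynamic genes by relative likelihood
#'
#' Keeps genes whose trajectory gene-wise likelihood strictly exceeds the
#' cluster-model score, optionally discarding genes whose fitted rates are
#' extreme (outside \code{rate_bounds} on beta or gamma), which indicates
#' a boundary fit rather than resolved dynamics.
#'
#' @param traj_scores,cluster_scores per-gene scores on identical genes.
#' @param kinetics optional fitted \code{\link{gene_kinetics}} for the
#'   extreme-value post-filter.
#' @param rate_bounds length-2 bounds applied to beta and gamma.
#' @return integer indices of selected genes.
#' @export
select_dynamic_genes <- function(traj_scores, cluster_scores,
                                 kinetics = NULL,
                                 rate_bounds = c(exp(-3), exp(5))) {
  if (length(traj_scores) != length(cluster_scores))
    stop("score vectors differ in length (mismatched gene sets)")
  sel <- which(traj_scores > cluster_scores)
  if (!is.null(kinetics)) {
    ok <- kinetics$beta >= rate_bounds[1L] & kinetics$beta <= rate_bounds[2L] &
      kinetics$gamma >= rate_bounds[1L] & kinetics$gamma <= rate_bounds[2L]
    sel <- sel[ok[sel]]
  }
  sel
}

#' Information criteria of a fit
#'
#' \code{AIC = 2k - 2 ELBO}, \code{BIC = k log(n) - 2 ELBO}, with k the
#' fit's free-parameter count (per gene: one alpha per state plus beta and
#' gamma, plus gene-wise interior switch times in the desynchronized
#' model; global: shared interior switch times, plus lineage/t0 weights
#' when the prior is updated).
#'
#' @param fit a \code{"traj_fit"} or \code{"pmix_fit"}.
#' @param n_cells number of observations; defaults to the fit's cell count.
#' @return named numeric vector with \code{aic} and \code{bic}.
#' @export
information_criteria <- function(fit, n_cells = nrow(fit$posterior)) {
  ll <- if (inherits(fit, "pmix_fit")) fit$loglik else fit$elbo
  k <- fit$n_parameters
  c(aic = 2 * k - 2 * ll, bic = k * log(n_cells) - 2 * ll)
}

#' Held-out ELBO with frozen parameters
#'
#' Evaluates the fitted model on held-out cells: a fresh E-step computes
#' their posteriors under the fitted kinetics and prior, and the resulting
#' log marginal likelihood is returned. Evaluated on the training set this
#' reproduces the training ELBO.
#'
#' @param fit a \code{"traj_fit"}.
#' @param held_out a \code{\link{count_dataset}} with the same genes and
#'   read-depth convention.
#' @return scalar held-out ELBO.
#' @export
test_elbo <- function(fit, held_out) {
  if (ncol(held_out$unspliced) != ncol(fit$data$unspliced))
    stop("held-out data has a different gene set")
  ll <- log_likelihood_grid(held_out, fit$structure, fit$kinetics,
                            fit$prior)
  sum(e_step(ll, fit$prior)$log_marginal)
}

#' Empirical per-gene Fisher information
#'
#' The score of the marginal likelihood for one cell is the
#' posterior-weighted conditional score,
#' \eqn{\partial_\theta \log p(x|\theta) = \sum_z p(z|x,\theta)
#' \partial_\theta \log p(x|z,\theta)}; the FIM is estimated as the average
#' over cells of its outer product, per gene (parameters: log alpha per
#' state, log beta, log gamma). Also returns the smallest eigenvalue and
#' the corresponding eigenvector scaled by 1/sqrt(eigenvalue), the flattest
#' direction of the likelihood surface for identifiability probing.
#'
#' @param fit a \code{"traj_fit"} (kinetics, prior and posterior at the
#'   evaluation point); alternatively supply \code{data} to evaluate on
#'   other cells (posteriors are recomputed).
#' @param data a \code{\link{count_dataset}}; defaults to the fit's data.
#' @param genes gene indices (default all).
#' @return a list: \code{fim} (d x d x length(genes) array),
#'   \code{min_eigval}, \code{flat_direction} (d x length(genes), scaled
#'   eigenvectors), \code{par_names}.
#' @export
fisher_information <- function(fit, data = fit$data, genes = NULL) {
  structure_ <- fit$structure
  kin <- fit$kinetics
  prior <- fit$prior
  p <- nrow(kin$alpha)
  if (is.null(genes)) genes <- seq_len(p)
  ll <- log_likelihood_grid(data, structure_, kin, prior)
  q <- e_step(ll, prior)$posterior
  gm <- grid_means(structure_, kin, prior, want_grad = rate_cols(structure_))
  S <- structure_$n_states
  dr <- S + 2L
  n <- nrow(q)
  r <- data$read_depth
  scale_log <- cbind(kin$alpha, kin$beta, kin$gamma)  # chain to log rates
  fim <- array(0, c(dr, dr, length(genes)))
  minev <- numeric(length(genes))
  flat <- matrix(0, dr, length(genes))
  for (gi in seq_along(genes)) {
    j <- genes[gi]
    lu <- gm$lambda_u[j, ]; ls <- gm$lambda_s[j, ]
    # per-cell conditional score pieces: (x/lambda - r) dlambda
    cu <- outer(data$unspliced[, j], 1 / pmax(lu, 1e-300)) - r
    cs <- outer(data$spliced[, j], 1 / pmax(ls, 1e-300)) - r
    sc <- matrix(0, n, dr)
    for (dd in seq_len(dr))
      sc[, dd] <- rowSums(q * (cu * matrix(gm$grad_u[j, , dd], n,
                                           length(lu), byrow = TRUE) +
                                 cs * matrix(gm$grad_s[j, , dd], n,
                                             length(ls), byrow = TRUE)))
    sc <- sc * matrix(scale_log[j, ], n, dr, byrow = TRUE)
    ok <- rowSums(!is.finite(sc)) == 0L
    if (!all(ok)) warning("non-finite score for gene ", j,
                          "; offending cells skipped")
    I <- crossprod(sc[ok, , drop = FALSE]) / sum(ok)
    I <- (I + t(I)) / 2
    fim[, , gi] <- I
    ev <- eigen(I, symmetric = TRUE)
    dmin <- length(ev$values)
    minev[gi] <- ev$values[dmin]
    flat[, gi] <- ev$vectors[, dmin] / sqrt(max(ev$values[dmin], 1e-12))
  }
  list(fim = fim, min_eigval = minev, flat_direction = flat,
       par_names = c(paste0("log_alpha_", seq_len(S) - 1L), "log_beta",
                     "log_gamma"))
}

#' Average precision of random restarts
#'
#' Restarts are labeled correct when their mean process time correlates
#' (Pearson) above \code{corr_threshold} with the reference (by default
#' the best-scoring restart); ranking restarts by score and sweeping the
#' threshold traces a precision-recall curve, summarized by average
#' precision. An AP near 1 means high-scoring restarts concentrate on one
#' ordering; low AP signals multiple comparable optima (instability).
#'
#' @param fit a \code{"traj_fit"} carrying the restart summaries, or a
#'   list with \code{scores} and \code{mean_times} (n x R matrix).
#' @param reference reference time vector; defaults to the best restart's.
#' @param corr_threshold correlation above which a restart is "correct".
#' @param score "elbo" (default) or a numeric vector of scores.
#' @return a list: \code{average_precision}, \code{labels},
#'   \code{correlations}, \code{scores}.
#' @export
restart_average_precision <- function(fit, reference = NULL,
                                      corr_threshold = 0.8,
                                      score = "elbo") {
  if (inherits(fit, "traj_fit")) {
    scores <- if (is.numeric(score)) score else fit$restart_table$elbo
    mt <- fit$restart_mean_times
  } else {
    scores <- if (is.numeric(score)) score else fit$scores
    mt <- fit$mean_times
  }
  R <- length(scores)
  if (R < 2L) stop("need at least 2 restarts")
  if (is.null(reference)) mt_ref <- mt[, which.max(scores)]
  else mt_ref <- reference
  cors <- rep(NA_real_, R)
  for (k in seq_len(R)) {
    if (stats::sd(mt[, k]) == 0 || stats::sd(mt_ref) == 0) next
    cors[k] <- stats::cor(mt[, k], mt_ref)
  }
  labels <- !is.na(cors) & cors > corr_threshold
  ap <- average_precision(scores, labels)
  list(average_precision = ap, labels = labels, correlations = cors,
       scores = scores)
}

# AP = mean over positives, in score-descending order, of precision at
# each positive's rank (ties broken by original order)
average_precision <- function(scores, labels) {
  if (!any(labels)) return(0)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  prec_at <- cumsum(lab) / seq_along(lab)
  mean(prec_at[lab])
}

#' Bootstrap stability of process-time estimates
#'
#' Refits the model on cell-resampled data and correlates the resampled
#' posterior-mean times (per drawn cell) with the original fit's times for
#' those same cells. Tight correlations near 1 indicate a stable ordering;
#' widely scattered correlations indicate instability.
#'
#' @param fit a \code{"traj_fit"}.
#' @param n_boot number of bootstrap replicates.
#' @param config fit configuration for the replicates (typically with few
#'   restarts); defaults to the original config with 3 restarts.
#' @param seed integer seed.
#' @return numeric vector of per-replicate correlations (NA for failed
#'   replicates).
#' @export
bootstrap_stability <- function(fit, n_boot = 20L, config = NULL,
                                seed = 1L) {
  if (is.null(config)) {
    config <- fit$config
    config$n_restarts <- 3L
  }
  t_orig <- mean_process_time(fit)
  data <- fit$data
  n <- nrow(data$unspliced)
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max, n_boot)
  cors <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    bdata <- count_dataset(data$unspliced[idx, , drop = FALSE],
                           data$spliced[idx, , drop = FALSE],
                           data$read_depth[idx])
    cfg <- config
    cfg$seed <- boot_seeds[b]
    bf <- try(fit_trajectory(bdata, fit$structure, cfg), silent = TRUE)
    if (inherits(bf, "try-error")) next
    tb <- mean_process_time(bf)
    if (stats::sd(tb) == 0 || stats::sd(t_orig[idx]) == 0) next
    cors[b] <- stats::cor(tb, t_orig[idx])
  }
  cors
}

#' Rank genes by transcription-rate fold change
#'
#' The DE statistic of a gene is the largest ratio of its fitted
#' transcription rates over pairs of states (with a small floor on alpha
#' to avoid division by zero); genes are returned sorted by decreasing
#' fold change.
#'
#' @param kinetics a fitted \code{\link{gene_kinetics}}.
#' @param genes gene indices to rank (e.g. the selected set); default all.
#' @param alpha_floor floor applied to alpha before ratios.
#' @return a data.frame with \code{gene} and \code{fold_change}, sorted
#'   decreasing.
#' @export
rank_de_genes <- function(kinetics, genes = NULL, alpha_floor = 1e-3) {
  if (is.null(genes)) genes <- seq_len(nrow(kinetics$alpha))
  a <- pmax(kinetics$alpha[genes, , drop = FALSE], alpha_floor)
  fc <- apply(a, 1L, max) / apply(a, 1L, min)
  out <- data.frame(gene = genes, fold_change = fc)
  out[order(-out$fold_change), , drop = FALSE]
}

#' Entropy of the cell-averaged posterior over time
#'
#' Marginalizes lineages (and the t = 0 atom), averages the per-cell time
#' distributions over cells, and returns the Shannon entropy (natural log)
#' of the resulting M-point distribution. ln(M) for a uniform average
#' posterior, 0 for a point mass.
#'
#' @param fit a \code{"traj_fit"}, or an n x Z posterior matrix plus a
#'   \code{prior}.
#' @param prior required when \code{fit} is a bare matrix.
#' @return scalar entropy in nats.
#' @export
average_posterior_entropy <- function(fit, prior = NULL) {
  if (inherits(fit, "traj_fit")) {
    q <- fit$posterior; prior <- fit$prior
  } else q <- fit
  M <- prior$M; L <- prior$n_lineages
  tm <- numeric(M)
  for (l in seq_len(L))
    tm <- tm + colSums(q[, (l - 1L) * M + seq_len(M), drop = FALSE])
  tm <- tm / sum(tm)
  -sum(ifelse(tm > 0, tm * log(tm), 0))
}
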
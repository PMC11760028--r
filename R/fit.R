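# EM fitting of the trajectory model: random or warm initialization,
# multiple restarts, synchronized and desynchronized variants.

#' Configuration for trajectory fitting
#'
#' @param n_restarts number of independent random initializations; the
#'   chain with the highest final ELBO is returned.
#' @param n_iterations EM iteration cap per chain.
#' @param grid_M number of latent time grid points on (0, 1].
#' @param t0_mass prior mass on the t = 0 atom (0 disables it).
#' @param update_prior update lineage weights (and t0 mass) each iteration.
#' @param desync_penalty coefficient of the quadratic penalty pulling
#'   gene-wise switch times toward the consensus in the desynchronized
#'   model.
#' @param seed integer seed governing all randomness of the fit.
#' @param mstep_maxit L-BFGS-B iteration cap per M-step once the chain is
#'   warm (from the fourth EM iteration on).
#' @param mstep_maxit_first L-BFGS-B cap for the first three EM iterations,
#'   when parameters are far from the optimum and a thorough M-step keeps
#'   the chain from sliding out of a good initialization's basin.
#' @param tau_maxit L-BFGS-B iteration cap for the shared switch-time
#'   update.
#' @param tol,patience early stopping: the chain stops when the relative
#'   ELBO improvement stays below \code{tol} for \code{patience} consecutive
#'   iterations.
#' @param tau_init optional initial switch times (length K+1, 0 to 1);
#'   defaults to equally spaced.
#' @param verbose print per-chain progress.
#' @return a list of class \code{"traj_config"}.
#' @export
traj_config <- function(n_restarts = 100L, n_iterations = 100L,
                        grid_M = 100L, t0_mass = 0, update_prior = FALSE,
                        desync_penalty = 0, seed = 1L, mstep_maxit = 12L,
                        mstep_maxit_first = 40L,
                        tau_maxit = 8L, tol = 1e-6, patience = 5L,
                        tau_init = NULL, verbose = FALSE) {
  stopifnot(n_restarts >= 1L, n_iterations >= 1L, grid_M >= 2L,
            desync_penalty >= 0)
  structure(as.list(environment()), class = "traj_config")
}

default_tau <- function(structure, config) {
  if (!is.null(config$tau_init)) {
    stopifnot(length(config$tau_init) == structure$n_seg + 1L)
    return(config$tau_init)
  }
  seq(0, 1, length.out = structure$n_seg + 1L)
}

# deterministic data-anchored starting rates for the first M-step:
# splicing/degradation at typical metabolic-labeling magnitudes, alpha
# chosen so implied spliced means match observed gene means
init_kinetics <- function(data, structure, tau) {
  p <- ncol(data$spliced)
  beta0 <- rep(exp(2), p)
  gamma0 <- rep(exp(0.5), p)
  ms <- pmax(colMeans(data$spliced), 1e-2)
  alpha0 <- matrix(ms * gamma0, p, structure$n_states)
  kin_raw(alpha0, beta0, gamma0, tau)
}

# random-restart responsibilities from a coherent random ordering: cells
# are ranked by a random projection of centered log1p spliced counts (so
# expression-similar cells get nearby times), mapped onto the time grid,
# and given independent random lineages. Each restart proposes a
# different candidate ordering (and its reverse, via the sign of the
# projection) for EM to refine.
random_projection_posterior <- function(data, prior) {
  n <- nrow(data$spliced)
  M <- prior$M; L <- prior$n_lineages
  X <- log1p(data$spliced / data$read_depth)
  X <- sweep(X, 2L, colMeans(X))
  s <- as.vector(X %*% stats::rnorm(ncol(X)))
  tt <- (rank(s, ties.method = "random") - 0.5) / n
  m <- pmin(pmax(ceiling(tt * M), 1L), M)
  # lineages from a second random projection (coherent split so that the
  # first M-step already fits distinct branches and the lineage symmetry
  # is broken), cut at equal quantiles
  l <- if (L == 1L) rep(1L, n) else {
    s2 <- as.vector(X %*% stats::rnorm(ncol(X)))
    as.integer(cut(rank(s2, ties.method = "random"), breaks = L,
                   labels = FALSE))
  }
  Z <- L * M + as.integer(prior$has_t0)
  q <- matrix(0, n, Z)
  q[cbind(seq_len(n), (l - 1L) * M + m)] <- 1
  q
}

# single-lineage backbone structure: the first lineage's path with states
# reindexed to consecutive integers
collapse_structure <- function(structure) {
  path <- structure$paths[1L, ]
  trajectory_structure(matrix(match(path, sort(unique(path))) - 1L,
                              nrow = 1L))
}

# Staged random initialization of one restart for multi-lineage
# structures: (1) fit the collapsed single-lineage backbone by EM from a
# random-projection ordering to get candidate process times; (2) split
# cells beyond the branch point into lineages by k-means on centered
# log1p expression; (3) return one-hot time responsibilities with the
# k-means lineages for post-branch cells and equal lineage mass for
# shared-segment cells. Randomness (projection direction, k-means start)
# makes restarts explore different orderings and branch splits.
staged_init_posterior <- function(data, structure, prior, config) {
  n <- nrow(data$spliced)
  M <- prior$M; L <- prior$n_lineages
  if (L == 1L) return(random_projection_posterior(data, prior))
  stc <- collapse_structure(structure)
  cfg1 <- config
  cfg1$n_iterations <- min(config$n_iterations, 20L)
  cfg1$update_prior <- FALSE
  prior1 <- sampling_prior(stc, M, t0_mass = prior$t0_mass)
  res1 <- run_em_chain(data, stc, prior1, cfg1, mode = "sync",
                       init_posterior = random_projection_posterior(data,
                                                                    prior1))
  tc <- res1$mean_time
  # the orientation of the time axis is the dominant bimodality of the
  # likelihood surface, and the backbone EM can settle on either side
  # regardless of the projection's sign; mirror half the restarts so both
  # orientations are always explored and the ELBO ranking decides
  if (stats::runif(1L) < 0.5) tc <- 1 - tc
  # first segment where the lineage paths differ marks the branch point
  diff_col <- which(apply(structure$paths, 2L,
                          function(cc) length(unique(cc)) > 1L))
  t_split <- if (length(diff_col))
    res1$kinetics$tau[max(diff_col[1L] - 1L, 1L)] else 1
  # splitting too late is a sticky local optimum (the shared state absorbs
  # the early branch dynamics and the switch time cannot relax back),
  # while splitting too early is repaired by the E-step; draw the split
  # point below the backbone estimate so restarts explore branch onsets
  t_split <- t_split * stats::runif(1L, 0.4, 1.0)
  late <- tc > t_split
  l <- integer(n)
  if (sum(late) > 5L * L) {
    X <- log1p(data$spliced / data$read_depth)
    X <- sweep(X, 2L, colMeans(X))
    km <- try(stats::kmeans(X[late, , drop = FALSE], centers = L,
                            nstart = 3L), silent = TRUE)
    if (!inherits(km, "try-error"))
      l[late] <- sample.int(L)[km$cluster]
    else l[late] <- sample.int(L, sum(late), replace = TRUE)
  } else if (any(late)) {
    l[late] <- sample.int(L, sum(late), replace = TRUE)
  }
  m <- pmin(pmax(ceiling(tc * M), 1L), M)
  Z <- L * M + as.integer(prior$has_t0)
  q <- matrix(0, n, Z)
  il <- which(l > 0L)
  if (length(il)) q[cbind(il, (l[il] - 1L) * M + m[il])] <- 1
  i0 <- which(l == 0L)
  for (ll in seq_len(L)) q[cbind(i0, (ll - 1L) * M + m[i0])] <- 1 / L
  # starting switch times consistent with the split: the branch segment
  # opens at t_split, earlier (later) interior times spread evenly below
  # (above) it -- otherwise the first M-step fits rates around the default
  # equally-spaced times and the branch onset cannot relax
  K <- structure$n_seg
  tau0 <- seq(0, 1, length.out = K + 1L)
  if (length(diff_col) && K > 1L) {
    kb <- max(diff_col[1L] - 2L, 1L)       # interior index of branch onset
    if (kb <= K - 1L) {
      ts <- min(max(t_split, 0.05), 0.95)
      tau0 <- c(seq(0, ts, length.out = kb + 1L),
                seq(ts, 1, length.out = K - kb + 1L)[-1L])
    }
  }
  attr(q, "tau_init") <- tau0
  q
}

# re-seed a converged chain from its rank-uniformized ordering: cells are
# placed one-hot at equally spaced grid positions in the order of their
# posterior-mean times, keeping MAP lineages, and EM is re-run
refine_uniformize <- function(best, data, structure, prior, config) {
  n <- nrow(best$posterior)
  M <- prior$M
  L <- prior$n_lineages
  tm <- as.vector(best$posterior %*% latent_times(prior))
  tt <- (rank(tm, ties.method = "first") - 0.5) / n
  mm <- pmin(pmax(ceiling(tt * M), 1L), M)
  lmarg <- vapply(seq_len(L), function(l)
    rowSums(best$posterior[, (l - 1L) * M + seq_len(M), drop = FALSE]),
    numeric(n))
  l <- max.col(lmarg, ties.method = "first")
  Z <- L * M + as.integer(prior$has_t0)
  q <- matrix(0, n, Z)
  q[cbind(seq_len(n), (l - 1L) * M + mm)] <- 1
  if (!best$kinetics$desynchronized)
    attr(q, "tau_init") <- best$kinetics$tau
  cfg <- config
  cfg$n_iterations <- min(config$n_iterations, 60L)
  run_em_chain(data, structure, prior, cfg, mode = "sync",
               init_posterior = q)
}

#' Initial responsibilities from cell labels
#'
#' Builds a block-uniform initial posterior for a warm start: each cell's
#' mass is spread uniformly over the grid points of the lineages and time
#' segments its label maps to, and is zero elsewhere.
#'
#' @param labels per-cell labels (character or factor).
#' @param structure a \code{\link{trajectory_structure}}.
#' @param prior a \code{\link{sampling_prior}}.
#' @param label_map named list: for each label, a list with elements
#'   \code{lineages} (1-based lineage indices) and \code{segments}
#'   (1-based segment indices into 1..K).
#' @return an n x Z responsibility matrix with unit row sums.
#' @export
warm_start_from_labels <- function(labels, structure, prior, label_map) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), names(label_map))
  if (length(unknown))
    stop("labels without a mapping: ", paste(unknown, collapse = ", "))
  M <- prior$M; L <- prior$n_lineages
  tau <- seq(0, 1, length.out = structure$n_seg + 1L)
  seg_of_m <- findInterval(prior$grid, tau, left.open = TRUE,
                           rightmost.closed = FALSE)
  seg_of_m <- pmin(seg_of_m, structure$n_seg)
  Z <- L * M + as.integer(prior$has_t0)
  q <- matrix(0, length(labels), Z)
  for (lab in names(label_map)) {
    rows <- which(labels == lab)
    if (!length(rows)) next
    cols <- integer(0)
    for (l in label_map[[lab]]$lineages)
      cols <- c(cols, (l - 1L) * M + which(seg_of_m %in%
                                             label_map[[lab]]$segments))
    cols <- unique(cols)
    q[rows, cols] <- 1 / length(cols)
  }
  q
}

run_em_chain <- function(data, structure, prior, config, mode = "sync",
                         init_posterior = NULL, init_kin = NULL,
                         chain_seed = NULL) {
  if (!is.null(chain_seed)) set.seed(chain_seed)
  n <- nrow(data$unspliced)
  constants <- loglik_constants(data)
  posterior <- if (!is.null(init_posterior)) init_posterior else
    staged_init_posterior(data, structure, prior, config)
  tau0 <- attr(posterior, "tau_init")
  if (is.null(tau0)) tau0 <- default_tau(structure, config)
  kin <- if (is.null(init_kin)) init_kinetics(data, structure, tau0) else
    init_kin
  elbo_trace <- numeric(0)
  best <- -Inf
  stall <- 0L
  consensus <- NULL
  for (it in seq_len(config$n_iterations)) {
    suff <- suff_stats(posterior, data)
    maxit_it <- if (it <= 3L) config$mstep_maxit_first else
      config$mstep_maxit
    if (mode == "sync") {
      ms <- m_step_rates(kin, structure, prior, suff, maxit_it)
      kin <- update_global_tau(ms$kinetics, structure, prior, suff,
                               config$tau_maxit)
      attr(kin, "F") <- NULL
    } else {
      ms <- m_step_desync(kin, structure, prior, suff,
                          penalty = config$desync_penalty,
                          consensus = consensus, maxit_it)
      kin <- ms$kinetics
      consensus <- colMeans(tau_matrix(kin, nrow(kin$alpha)))
    }
    if (config$update_prior)
      prior <- update_prior_weights(posterior, prior, TRUE)
    ll <- log_likelihood_grid(data, structure, kin, prior, constants)
    es <- e_step(ll, prior)
    posterior <- es$posterior
    elbo <- sum(es$log_marginal)
    elbo_trace <- c(elbo_trace, elbo)
    if (!is.finite(elbo)) break
    if (it > 1L && elbo - best < config$tol * abs(best)) stall <- stall + 1L
    else stall <- 0L
    best <- max(best, elbo)
    if (stall >= config$patience) break
  }
  converged <- stall >= config$patience
  mean_time <- as.vector(posterior %*% latent_times(prior))
  list(kinetics = kin, prior = prior, posterior = posterior,
       elbo_trace = elbo_trace,
       elbo = if (length(elbo_trace)) elbo_trace[length(elbo_trace)] else -Inf,
       converged = converged, iterations = length(elbo_trace),
       mean_time = mean_time)
}

count_parameters <- function(structure, mode, update_prior) {
  S <- structure$n_states; K <- structure$n_seg; L <- structure$n_lineages
  per_gene <- S + 2L + if (mode == "desync") K - 1L else 0L
  global <- if (mode == "sync") K - 1L else 0L
  if (update_prior) global <- global + (L - 1L) + 1L
  c(per_gene = per_gene, global = global)
}

#' Fit the process-time trajectory model by EM
#'
#' Runs \code{n_restarts} independent EM chains (random one-hot
#' responsibilities drawn from the prior, M-step first) and returns the
#' chain with the highest final ELBO together with all chains' summaries
#' (final ELBO, per-cell posterior-mean process time) for downstream
#' uncertainty analysis. A warm start (initial responsibilities and/or
#' kinetics) replaces the random restarts.
#'
#' @param data a \code{\link{count_dataset}} with read depth attached.
#' @param structure a \code{\link{trajectory_structure}}.
#' @param config a \code{\link{traj_config}}.
#' @param prior optional \code{\link{sampling_prior}}; defaults to uniform
#'   over lineages and grid times with the configured t0 mass.
#' @param init_posterior,init_kinetics optional warm start: an n x Z
#'   responsibility matrix and/or starting kinetics. When either is given a
#'   single chain is run.
#' @return an object of class \code{"traj_fit"}.
#' @export
fit_trajectory <- function(data, structure, config = traj_config(),
                           prior = NULL, init_posterior = NULL,
                           init_kinetics = NULL) {
  stopifnot(inherits(data, "count_dataset"),
            inherits(structure, "traj_structure"))
  if (ncol(data$unspliced) == 0L) stop("no genes left to fit")
  if (is.null(prior))
    prior <- sampling_prior(structure, config$grid_M,
                            t0_mass = config$t0_mass)
  warm <- !is.null(init_posterior) || !is.null(init_kinetics)
  n_chains <- if (warm) 1L else config$n_restarts
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    res <- run_em_chain(data, structure, prior, config, mode = "sync",
                        init_posterior = init_posterior,
                        init_kin = init_kinetics,
                        chain_seed = chain_seeds[ch])
    if (!is.finite(res$elbo)) {
      warning("chain ", ch, " produced a non-finite ELBO; discarded")
      res$elbo <- -Inf
    }
    chains[[ch]] <- res
    if (config$verbose)
      message(sprintf("chain %d/%d: ELBO %.2f (%d iterations)",
                      ch, n_chains, res$elbo, res$iterations))
  }
  elbos <- vapply(chains, `[[`, 0, "elbo")
  if (all(!is.finite(elbos))) stop("all chains failed (non-finite ELBO)")
  # ties within 1e-9: lowest chain index wins
  best_i <- which(elbos >= max(elbos, na.rm = TRUE) - 1e-9)[1L]
  best <- chains[[best_i]]
  # Refinement: EM can converge to a self-consistently time-warped
  # ordering whose marginal over cells contradicts the uniform prior.
  # Re-seeding from the rank-uniformized ordering (MAP lineages kept)
  # restores the prior's marginal and frequently drops into a deeper
  # basin; the move is accepted only when the ELBO improves.
  for (pass in 1:2) {
    ref <- try(refine_uniformize(best, data, structure, prior, config),
               silent = TRUE)
    if (inherits(ref, "try-error") || !is.finite(ref$elbo) ||
        ref$elbo <= best$elbo + config$tol * abs(best$elbo)) break
    best <- ref
  }
  restart_table <- data.frame(
    chain = seq_len(n_chains), seed = chain_seeds, elbo = elbos,
    iterations = vapply(chains, `[[`, 0L, "iterations"),
    converged = vapply(chains, `[[`, TRUE, "converged"))
  mean_times <- vapply(chains, `[[`, numeric(nrow(data$unspliced)),
                       "mean_time")
  kpar <- count_parameters(structure, "sync", config$update_prior)
  fit <- structure(
    list(kinetics = best$kinetics, prior = best$prior,
         posterior = best$posterior, elbo = best$elbo,
         elbo_trace = best$elbo_trace, converged = best$converged,
         mode = "sync", structure = structure, data = data,
         config = config, restart_table = restart_table,
         restart_mean_times = mean_times, best_chain = best_i,
         n_parameters = unname(kpar["per_gene"]) * ncol(data$unspliced) +
           unname(kpar["global"])),
    class = "traj_fit")
  fit
}

#' Refine a synchronized fit with gene-wise switch times
#'
#' Starting from a synchronized fit (the recommended warm start), runs EM
#' with per-gene switch times optimized inside each gene's M-step. A
#' quadratic penalty with coefficient \code{config$desync_penalty} (default
#' 0) pulls gene-wise times toward the consensus (the across-gene mean),
#' recomputed each iteration.
#'
#' @param warm a synchronized \code{"traj_fit"}.
#' @param config a \code{\link{traj_config}}; \code{n_restarts} is ignored
#'   (a single warm-started chain is run).
#' @return an object of class \code{"traj_fit"} with
#'   \code{mode = "desync"}.
#' @export
fit_desynchronized <- function(warm, config = warm$config) {
  stopifnot(inherits(warm, "traj_fit"), warm$mode == "sync")
  data <- warm$data; structure_ <- warm$structure; prior <- warm$prior
  kin <- warm$kinetics
  p <- nrow(kin$alpha)
  kin <- kin_raw(kin$alpha, kin$beta, kin$gamma, tau_matrix(kin, p))
  res <- run_em_chain(data, structure_, prior, config, mode = "desync",
                      init_posterior = warm$posterior, init_kin = kin,
                      chain_seed = config$seed)
  if (!is.finite(res$elbo)) stop("desynchronized chain diverged")
  kpar <- count_parameters(structure_, "desync", config$update_prior)
  structure(
    list(kinetics = res$kinetics, prior = res$prior,
         posterior = res$posterior, elbo = res$elbo,
         elbo_trace = res$elbo_trace, converged = res$converged,
         mode = "desync", structure = structure_, data = data,
         config = config,
         restart_table = data.frame(chain = 1L, seed = config$seed,
                                    elbo = res$elbo,
                                    iterations = res$iterations,
                                    converged = res$converged),
         restart_mean_times = matrix(res$mean_time, ncol = 1L),
         best_chain = 1L,
         n_parameters = unname(kpar["per_gene"]) * p +
           unname(kpar["global"])),
    class = "traj_fit")
}

#' Posterior-mean process time per cell
#' @param fit a \code{"traj_fit"}.
#' @return numeric vector, one entry per cell (the t = 0 atom contributes 0).
#' @export
mean_process_time <- function(fit) {
  as.vector(fit$posterior %*% latent_times(fit$prior))
}

#' Maximum-a-posteriori lineage per cell
#' @param fit a \code{"traj_fit"}.
#' @return integer vector of 1-based lineage indices.
#' @export
map_lineage <- function(fit) {
  M <- fit$prior$M; L <- fit$prior$n_lineages
  lm <- vapply(seq_len(L), function(l)
    rowSums(fit$posterior[, (l - 1L) * M + seq_len(M), drop = FALSE]),
    numeric(nrow(fit$posterior)))
  max.col(lm, ties.method = "first")
}
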
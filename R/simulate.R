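# Ground-truth simulator: draws kinetic parameters from lognormal laws,
# cells from uniform (optionally Gaussian-contaminated) process times,
# Beta-distributed read depths, and Poisson (optionally Gamma-overdispersed)
# counts from the closed-form means.

beta_shapes <- function(mean, var) {
  s <- mean * (1 - mean) / var - 1
  if (s <= 0) stop("Beta variance too large for the given mean")
  c(shape1 = mean * s, shape2 = (1 - mean) * s)
}

#' Draw per-gene kinetic parameters
#'
#' Splicing and degradation rates follow lognormal laws whose defaults
#' mirror rate distributions measured in metabolic-labeling experiments
#' (meanlog 2, sdlog 0.5 for beta; meanlog 0.5, sdlog 0.5 for gamma), which
#' puts the aggregate steady-state unspliced:spliced ratio near 0.2.
#' Transcription rates are lognormal (meanlog 2, sdlog 1): variable genes
#' draw an independent alpha per state, non-variable genes share a single
#' alpha across states (flat expression along the trajectory).
#'
#' @param structure a \code{\link{trajectory_structure}}.
#' @param n_genes number of genes.
#' @param frac_variable fraction of genes with state-dependent alpha.
#' @param tau switch times (length K+1); defaults to equally spaced.
#' @param alpha_meanlog,alpha_sdlog,beta_meanlog,beta_sdlog,gamma_meanlog,gamma_sdlog
#'   lognormal laws (mean and sd of the natural log).
#' @return a list: \code{kinetics} (a \code{\link{gene_kinetics}}) and
#'   \code{variable} (logical per gene).
#' @export
sample_parameters <- function(structure, n_genes = 200L,
                              frac_variable = 0.5, tau = NULL,
                              alpha_meanlog = 2, alpha_sdlog = 1,
                              beta_meanlog = 2, beta_sdlog = 0.5,
                              gamma_meanlog = 0.5, gamma_sdlog = 0.5) {
  S <- structure$n_states
  if (is.null(tau)) tau <- seq(0, 1, length.out = structure$n_seg + 1L)
  n_var <- round(frac_variable * n_genes)
  variable <- c(rep(TRUE, n_var), rep(FALSE, n_genes - n_var))
  alpha <- matrix(0, n_genes, S)
  if (n_var > 0)
    alpha[variable, ] <- matrix(
      stats::rlnorm(n_var * S, alpha_meanlog, alpha_sdlog), n_var, S)
  if (n_genes - n_var > 0)
    alpha[!variable, ] <- stats::rlnorm(n_genes - n_var, alpha_meanlog,
                                        alpha_sdlog)  # recycled across states
  beta <- stats::rlnorm(n_genes, beta_meanlog, beta_sdlog)
  gamma <- stats::rlnorm(n_genes, gamma_meanlog, gamma_sdlog)
  list(kinetics = gene_kinetics(alpha, beta, gamma, tau),
       variable = variable)
}

#' Draw per-cell latent lineages and process times
#'
#' Lineages are uniform. Times are a blend: a fraction \code{1 - blend}
#' from the uniform law on (0, 1] and a fraction \code{blend} from a
#' Gaussian with one random center (drawn once per dataset) and the given
#' standard deviation, truncated to [0, 1] by rejection.
#'
#' @param n_cells number of cells.
#' @param structure a \code{\link{trajectory_structure}}.
#' @param blend fraction of cells drawn from the Gaussian component.
#' @param blend_sd standard deviation of the Gaussian component.
#' @return a list with \code{lineage} (1-based), \code{time},
#'   \code{blend_center}, and \code{entropy}: the Shannon entropy (nats)
#'   of the realized time distribution binned on a 20-bin grid, a
#'   uniformity summary (log(20) when perfectly uniform).
#' @export
sample_latents <- function(n_cells, structure, blend = 0, blend_sd = 0.05) {
  stopifnot(blend >= 0, blend <= 1)
  lineage <- sample.int(structure$n_lineages, n_cells, replace = TRUE)
  center <- stats::runif(1)
  from_gauss <- stats::runif(n_cells) < blend
  tt <- stats::runif(n_cells)
  ng <- sum(from_gauss)
  if (ng > 0) {
    draws <- numeric(0)
    while (length(draws) < ng) {
      cand <- stats::rnorm(2L * ng, center, blend_sd)
      draws <- c(draws, cand[cand >= 0 & cand <= 1])
    }
    tt[from_gauss] <- draws[seq_len(ng)]
  }
  bins <- tabulate(pmin(pmax(ceiling(tt * 20), 1L), 20L), 20L) / n_cells
  entropy <- -sum(ifelse(bins > 0, bins * log(bins), 0))
  list(lineage = lineage, time = tt, blend_center = center,
       entropy = entropy)
}

#' Desynchronize switch times across genes
#'
#' Draws per-gene interior switch times uniformly on
#' \code{[T_k - dtau/2, T_k + dtau/2]} around the global times, where
#' \code{dtau} is the smallest global interval length, which guarantees the
#' gene-wise times keep their ordering.
#'
#' @param global_tau global switch times (length K+1, 0 to 1).
#' @param n_genes number of genes.
#' @return an n_genes x (K+1) matrix of switch times.
#' @export
desynchronize_tau <- function(global_tau, n_genes) {
  K <- length(global_tau) - 1L
  dtau <- min(diff(global_tau))
  taum <- matrix(rep(global_tau, each = n_genes), n_genes, K + 1L)
  if (K > 1L && dtau > 0)
    for (k in 2:K)
      taum[, k] <- stats::runif(n_genes, global_tau[k] - dtau / 2,
                                global_tau[k] + dtau / 2)
  taum
}

#' Simulate counts given kinetics and latent states
#'
#' Counts are Poisson with mean \code{r_i * g_ij * lambda_c(l_i, t_i)};
#' read depth r follows a Beta law rescaled to mean 1 (the model absorbs
#' the mean capture rate into alpha), and the optional gene-wise noise g is
#' Gamma with mean 1 and variance \code{gamma_cv2}.
#'
#' @param kinetics a \code{\link{gene_kinetics}}.
#' @param structure a \code{\link{trajectory_structure}}.
#' @param latents output of \code{\link{sample_latents}}.
#' @param depth_mean,depth_var Beta law of the raw read depth;
#'   \code{depth_var = 0} gives constant depth 1.
#' @param gamma_cv2 squared coefficient of variation of the Gamma noise
#'   (0 disables it).
#' @return a list: \code{data} (a \code{\link{count_dataset}} carrying the
#'   mean-normalized true read depth) and \code{lambda_u}, \code{lambda_s}
#'   (n x p true means before depth/noise scaling).
#' @export
simulate_counts <- function(kinetics, structure, latents,
                            depth_mean = 0.25, depth_var = 1 / 64,
                            gamma_cv2 = 0) {
  n <- length(latents$time)
  p <- nrow(kinetics$alpha)
  LU <- matrix(0, n, p); LS <- matrix(0, n, p)
  for (l in seq_len(structure$n_lineages)) {
    cells <- which(latents$lineage == l)
    if (!length(cells)) next
    m <- lineage_means(structure, kinetics, l, latents$time[cells])
    LU[cells, ] <- t(m$lambda_u)
    LS[cells, ] <- t(m$lambda_s)
  }
  if (depth_var > 0) {
    sh <- beta_shapes(depth_mean, depth_var)
    r <- stats::rbeta(n, sh[1L], sh[2L])
    r <- r / mean(r)
  } else r <- rep(1, n)
  G <- if (gamma_cv2 > 0)
    matrix(stats::rgamma(n * p, shape = 1 / gamma_cv2, scale = gamma_cv2),
           n, p)
  else 1
  U <- matrix(stats::rpois(n * p, r * (G * LU)), n, p)
  S <- matrix(stats::rpois(n * p, r * (G * LS)), n, p)
  list(data = count_dataset(U, S, read_depth = r),
       lambda_u = LU, lambda_s = LS)
}

#' Simulate a complete ground-truth dataset
#'
#' One call drawing parameters, latents, read depth and counts under a
#' fixed seed; the returned truth record carries everything needed by
#' \code{\link{evaluation_metrics}}.
#'
#' @inheritParams sample_parameters
#' @inheritParams sample_latents
#' @inheritParams simulate_counts
#' @param n_cells,n_genes dataset size (defaults 2000 cells, 200 genes).
#' @param desync draw gene-wise switch times around the global ones.
#' @param seed integer seed.
#' @return a list: \code{data} (a \code{\link{count_dataset}}) and
#'   \code{truth} (kinetics, per-cell lineage/time, read depth, gene
#'   classes, the configuration echo).
#' @export
simulate_trajectory <- function(structure, n_cells = 2000L,
                                n_genes = 200L, frac_variable = 0.5,
                                tau = NULL, blend = 0, blend_sd = 0.05,
                                depth_mean = 0.25, depth_var = 1 / 64,
                                gamma_cv2 = 0, desync = FALSE,
                                alpha_meanlog = 2, alpha_sdlog = 1,
                                beta_meanlog = 2, beta_sdlog = 0.5,
                                gamma_meanlog = 0.5, gamma_sdlog = 0.5,
                                seed = 1L) {
  set.seed(seed)
  par <- sample_parameters(structure, n_genes, frac_variable, tau,
                           alpha_meanlog, alpha_sdlog, beta_meanlog,
                           beta_sdlog, gamma_meanlog, gamma_sdlog)
  kin <- par$kinetics
  if (desync) {
    taum <- desynchronize_tau(if (is.matrix(kin$tau)) stop("tau already gene-wise")
                              else kin$tau, n_genes)
    kin <- gene_kinetics(kin$alpha, kin$beta, kin$gamma, taum)
  }
  lat <- sample_latents(n_cells, structure, blend, blend_sd)
  sim <- simulate_counts(kin, structure, lat, depth_mean, depth_var,
                         gamma_cv2)
  list(data = sim$data,
       truth = list(kinetics = kin, lineage = lat$lineage,
                    time = lat$time, read_depth = sim$data$read_depth,
                    variable = par$variable, structure = structure,
                    blend_center = lat$blend_center,
                    config = list(n_cells = n_cells, n_genes = n_genes,
                                  frac_variable = frac_variable,
                                  blend = blend, blend_sd = blend_sd,
                                  depth_mean = depth_mean,
                                  depth_var = depth_var,
                                  gamma_cv2 = gamma_cv2, desync = desync,
                                  seed = seed)))
}

# enumerate lineage relabelings: fitted lineage l plays true lineage
# perm$lineage[l]; when the fitted and true structures share shape, each
# relabeling must induce a consistent state bijection (perm$state[s] is the
# 1-based true state column for fitted state column s), otherwise the
# relabeling is skipped
lineage_permutations <- function(st_truth, st_fit) {
  L <- st_fit$n_lineages
  perms <- if (L <= 5L) all_permutations(L) else list(seq_len(L))
  same_shape <- identical(dim(st_truth$paths), dim(st_fit$paths)) &&
    st_truth$n_states == st_fit$n_states
  out <- list()
  for (pp in perms) {
    if (!same_shape) {
      out[[length(out) + 1L]] <- list(lineage = pp, state = NULL)
      next
    }
    smap <- rep(NA_integer_, st_fit$n_states)
    ok <- TRUE
    for (l in seq_len(L)) for (k in seq_len(ncol(st_fit$paths))) {
      s_fit <- st_fit$paths[l, k] + 1L
      s_true <- st_truth$paths[pp[l], k] + 1L
      if (is.na(smap[s_fit])) smap[s_fit] <- s_true
      else if (smap[s_fit] != s_true) { ok <- FALSE; break }
    }
    if (ok && !anyNA(smap) && !anyDuplicated(smap))
      out[[length(out) + 1L]] <- list(lineage = pp, state = smap)
    else if (!ok || anyNA(smap)) next
  }
  if (!length(out)) out <- list(list(lineage = seq_len(L), state = NULL))
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (pp in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(pp, n, after = pos - 1L)
  }
  out
}

#' Recovery metrics against simulation truth
#'
#' Time error is the RMSE of the posterior-mean process time; parameter
#' errors are normalized so genes are comparable: |error|/sqrt(truth) for
#' alpha, |error|/truth for beta and gamma. For non-variable genes only
#' alpha and the beta/gamma ratio are identifiable, so only those are
#' scored. Alpha errors require the fitted structure to share the truth's
#' states (they are NA under a mis-specified structure); lineage accuracy
#' is evaluated on cells whose true time falls in segments where the
#' lineage paths differ.
#'
#' @param truth the \code{truth} element of
#'   \code{\link{simulate_trajectory}}.
#' @param fit a \code{"traj_fit"} on the same cells and genes.
#' @return a list of scalars: \code{time_rmse}, \code{time_cor},
#'   \code{lineage_accuracy}, \code{alpha_error}, \code{beta_error},
#'   \code{gamma_error}, \code{ratio_error_nonvar}.
#' @export
evaluation_metrics <- function(truth, fit) {
  tm <- mean_process_time(fit)
  if (length(tm) != length(truth$time))
    stop("fit and truth have different numbers of cells")
  time_rmse <- sqrt(mean((tm - truth$time)^2))
  time_cor <- stats::cor(tm, truth$time)
  # lineage labels are identifiable only up to automorphisms of the state
  # graph (e.g. symmetric branches can be swapped); score the relabeling
  # that best matches truth and remap states accordingly for alpha errors
  st <- truth$structure
  tau_true <- if (is.matrix(truth$kinetics$tau))
    colMeans(truth$kinetics$tau) else truth$kinetics$tau
  seg <- pmin(pmax(findInterval(truth$time, tau_true, left.open = TRUE), 0L),
              st$n_seg)
  distinct <- apply(st$paths, 2L, function(col) length(unique(col)) > 1L)
  ident <- seg >= 1L & distinct[seg + 1L]
  kt <- truth$kinetics; kf <- fit$kinetics
  same_states <- ncol(kt$alpha) == ncol(kf$alpha) &&
    identical(dim(st$paths), dim(fit$structure$paths))
  lineage_accuracy <- NA_real_
  state_map <- seq_len(ncol(kf$alpha))
  if (any(ident) && st$n_lineages > 1L) {
    ml <- map_lineage(fit)
    best_acc <- -1
    for (perm in lineage_permutations(st, fit$structure)) {
      acc <- mean(perm$lineage[ml][ident] == truth$lineage[ident])
      if (acc > best_acc) {
        best_acc <- acc
        if (!is.null(perm$state)) state_map <- perm$state
      }
    }
    lineage_accuracy <- best_acc
  }
  if (same_states) kf$alpha <- kf$alpha[, order(state_map), drop = FALSE]
  variable <- truth$variable
  alpha_error <- if (same_states)
    mean(abs(kf$alpha[variable, ] - kt$alpha[variable, ]) /
           sqrt(kt$alpha[variable, ])) else NA_real_
  beta_error <- mean(abs(kf$beta[variable] - kt$beta[variable]) /
                       kt$beta[variable])
  gamma_error <- mean(abs(kf$gamma[variable] - kt$gamma[variable]) /
                        kt$gamma[variable])
  rt <- kt$beta / kt$gamma; rf <- kf$beta / kf$gamma
  ratio_error_nonvar <- if (any(!variable))
    mean(abs(rf[!variable] - rt[!variable]) / rt[!variable]) else NA_real_
  alpha_error_nonvar <- if (same_states && any(!variable))
    mean(abs(kf$alpha[!variable, ] - kt$alpha[!variable, ]) /
           sqrt(kt$alpha[!variable, ])) else NA_real_
  list(time_rmse = time_rmse, time_cor = time_cor,
       lineage_accuracy = lineage_accuracy, alpha_error = alpha_error,
       beta_error = beta_error, gamma_error = gamma_error,
       ratio_error_nonvar = ratio_error_nonvar,
       alpha_error_nonvar = alpha_error_nonvar)
}
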
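# M-step: per-gene maximization of the posterior-weighted Poisson
# log-likelihood F_j = sum_i sum_z q_i(z) log p(x_ij | z, theta_j) by
# L-BFGS-B on log rates (and, in the desynchronized model, on unconstrained
# switch-time weights), with analytic gradients from the forward
# sensitivities of the mean solution.

LOGRATE_LO <- -20
LOGRATE_HI <- 20
TAU_W_LO <- -10
TAU_W_HI <- 10

# posterior-weighted sufficient statistics; W_z = sum_i q_iz r_i,
# XU/XS are p x Z posterior-weighted counts
suff_stats <- function(posterior, data) {
  list(W = as.vector(crossprod(posterior, data$read_depth)),
       XU = crossprod(data$unspliced, posterior),
       XS = crossprod(data$spliced, posterior))
}

# F_j (p-vector) and optionally its gradient on the primitive parameter
# scale (p x length(grad_cols)). Offsets from x log r and log x! are
# intentionally omitted here (constant in theta); gene_conditional_term()
# adds them back.
traj_F <- function(kin, structure, prior, suff, want_grad = FALSE) {
  if (!kin$desynchronized && !isTRUE(getOption("ptraj.use_r_kernel")))
    return(traj_F_sync(kin, structure, prior, suff, want_grad))
  traj_F_r(kin, structure, prior, suff, want_grad)
}

# compiled kernel: per-lineage blocks (plus the t0 atom) accumulated
traj_F_sync <- function(kin, structure, prior, suff, want_grad = FALSE) {
  grad_cols <- norm_grad_cols(want_grad, structure)
  p <- nrow(kin$alpha)
  S <- structure$n_states
  K <- structure$n_seg
  L <- structure$n_lineages
  M <- prior$M
  nc <- length(grad_cols)
  Fv <- numeric(p)
  G <- if (nc) matrix(0, p, nc) else NULL
  gc0 <- if (nc) as.integer(grad_cols) else integer(0)
  for (l in seq_len(L)) {
    bd <- segment_boundaries(structure, kin, l, grad_cols)
    ub <- do.call(cbind, bd$u)
    sb <- do.call(cbind, bd$s)
    if (nc) {
      JUb <- array(0, c(p, K + 1L, nc))
      JSb <- array(0, c(p, K + 1L, nc))
      for (k in seq_len(K + 1L)) {
        JUb[, k, ] <- bd$JU[[k]]
        JSb[, k, ] <- bd$JS[[k]]
      }
    } else JUb <- JSb <- numeric(0)
    idx <- (l - 1L) * M + seq_len(M)
    tg <- prior$grid
    xu <- suff$XU[, idx, drop = FALSE]
    xs <- suff$XS[, idx, drop = FALSE]
    ww <- suff$W[idx]
    if (l == 1L && prior$has_t0) {
      z0 <- L * M + 1L
      tg <- c(0, tg)
      xu <- cbind(suff$XU[, z0], xu)
      xs <- cbind(suff$XS[, z0], xs)
      ww <- c(suff$W[z0], ww)
    }
    res <- traj_F_block(kin$alpha, kin$beta, kin$gamma, kin$tau,
                        structure$paths[l, ] + 1L, tg, xu, xs, ww,
                        ub, sb, as.numeric(JUb), as.numeric(JSb),
                        gc0, S, BETA_GAMMA_TOL)
    Fv <- Fv + res$F
    if (nc) G <- G + res$grad
  }
  if (!nc) return(list(F = Fv))
  list(F = Fv, grad = G, grad_cols = grad_cols)
}

traj_F_r <- function(kin, structure, prior, suff, want_grad = FALSE) {
  gm <- grid_means(structure, kin, prior, want_grad)
  LU <- gm$lambda_u; LS <- gm$lambda_s
  W <- suff$W
  p <- nrow(LU); Z <- ncol(LU)
  Fv <- .rowSums(suff$XU * safe_log(LU) + suff$XS * safe_log(LS), p, Z) -
    as.vector((LU + LS) %*% W)
  if (is.null(gm$grad_cols)) return(list(F = Fv))
  Wm <- matrix(W, p, Z, byrow = TRUE)
  CU <- suff$XU / pmax(LU, 1e-300) - Wm
  CS <- suff$XS / pmax(LS, 1e-300) - Wm
  nc <- length(gm$grad_cols)
  G <- matrix(0, p, nc)
  for (jj in seq_len(nc))
    G[, jj] <- .rowSums(CU * gm$grad_u[, , jj] + CS * gm$grad_s[, , jj],
                        p, Z)
  list(F = Fv, grad = G, grad_cols = gm$grad_cols)
}

softmax_rows <- function(W) {
  e <- exp(W - apply(W, 1L, max))
  e / rowSums(e)
}

# chain dF/dtau (p x (K-1), interior times) to dF/dw (p x K) through
# tau_k = cumsum(softmax(w))_k
chain_tau_to_w <- function(dFdtau, P) {
  K <- ncol(P)
  tcum <- t(apply(P, 1L, cumsum))
  G <- matrix(0, nrow(P), K)
  for (m in seq_len(K))
    for (k in seq_len(K - 1L))
      G[, m] <- G[, m] + dFdtau[, k] * P[, m] * ((m <= k) - tcum[, k])
  G
}

tau_from_w_rows <- function(W) {
  P <- softmax_rows(W)
  tcum <- t(apply(P, 1L, cumsum))
  cbind(0, tcum[, -ncol(tcum), drop = FALSE], 1)
}

kin_raw <- function(alpha, beta, gamma, tau) {
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau = tau,
                 desynchronized = is.matrix(tau)),
            class = "gene_kinetics")
}

# cached objective closure: optim calls fn and gr separately; compute both
# once per unique theta
make_cached_objective <- function(eval_both) {
  env <- new.env(parent = emptyenv())
  env$theta <- NULL
  get_eval <- function(theta) {
    if (is.null(env$theta) || !identical(theta, env$theta)) {
      env$theta <- theta
      env$val <- eval_both(theta)
    }
    env$val
  }
  list(fn = function(theta) get_eval(theta)$value,
       gr = function(theta) get_eval(theta)$grad)
}

# Rates-only M-step (synchronized model or any fit with tau frozen):
# optimizes log alpha, log beta, log gamma for all genes jointly (the
# objective is a sum of per-gene terms); genes whose block did not improve
# keep their previous parameters.
m_step_rates <- function(kin, structure, prior, suff, maxit = 8L) {
  p <- nrow(kin$alpha); S <- ncol(kin$alpha)
  dr <- S + 2L
  theta0 <- cbind(safe_log(kin$alpha), log(kin$beta), log(kin$gamma))
  theta0 <- pmin(pmax(theta0, LOGRATE_LO), LOGRATE_HI)
  eval_both <- function(vec) {
    th <- matrix(vec, p, dr)
    alpha <- exp(th[, 1:S, drop = FALSE])
    beta <- exp(th[, S + 1L]); gamma <- exp(th[, S + 2L])
    k2 <- kin_raw(alpha, beta, gamma, kin$tau)
    tf <- traj_F(k2, structure, prior, suff, want_grad = rate_cols(structure))
    Glog <- tf$grad * cbind(alpha, beta, gamma)  # chain to log scale
    if (!all(is.finite(tf$F)) || !all(is.finite(Glog)))
      return(list(value = 1e300, grad = rep(0, length(vec))))
    list(value = -sum(tf$F), grad = -as.vector(Glog))
  }
  co <- make_cached_objective(eval_both)
  opt <- stats::optim(as.vector(theta0), co$fn, co$gr, method = "L-BFGS-B",
                      lower = LOGRATE_LO, upper = LOGRATE_HI,
                      control = list(maxit = maxit, factr = 1e4))
  th <- matrix(opt$par, p, dr)
  kin_new <- kin_raw(exp(th[, 1:S, drop = FALSE]), exp(th[, S + 1L]),
                     exp(th[, S + 2L]), kin$tau)
  accept_per_gene(kin, kin_new, structure, prior, suff)
}

# keep, per gene, whichever of old/new parameters has the larger F_j
accept_per_gene <- function(kin_old, kin_new, structure, prior, suff) {
  F_old <- traj_F(kin_old, structure, prior, suff)$F
  F_new <- traj_F(kin_new, structure, prior, suff)$F
  worse <- !is.finite(F_new) | F_new < F_old
  if (any(worse)) {
    kin_new$alpha[worse, ] <- kin_old$alpha[worse, ]
    kin_new$beta[worse] <- kin_old$beta[worse]
    kin_new$gamma[worse] <- kin_old$gamma[worse]
    if (kin_new$desynchronized && kin_old$desynchronized)
      kin_new$tau[worse, ] <- kin_old$tau[worse, ]
    F_new[worse] <- F_old[worse]
  }
  list(kinetics = kin_new, F = F_new)
}

#' Shared switch-time update for the synchronized model
#'
#' With per-gene rates held fixed, maximizes the summed per-gene objectives
#' over the shared interior switch times, parameterized as cumulative
#' softmax increments so that ordering is maintained by construction. A
#' no-op when the structure has a single segment. The update is rejected if
#' it fails to improve the objective.
#'
#' @param kin current \code{\link{gene_kinetics}} (synchronized).
#' @param structure a \code{\link{trajectory_structure}}.
#' @param prior a \code{\link{sampling_prior}}.
#' @param suff posterior-weighted sufficient statistics from the E-step.
#' @param maxit L-BFGS-B iteration cap.
#' @return updated kinetics (with attribute \code{"F"}: the per-gene
#'   objective values at the returned point).
#' @export
update_global_tau <- function(kin, structure, prior, suff, maxit = 20L) {
  K <- structure$n_seg
  F0 <- traj_F(kin, structure, prior, suff)$F
  if (K == 1L || kin$desynchronized) {
    attr(kin, "F") <- F0
    return(kin)
  }
  S <- structure$n_states
  w0 <- log(pmax(diff(kin$tau), 1e-6))
  eval_both <- function(w) {
    tau <- as.vector(tau_from_w_rows(matrix(w, 1L)))
    k2 <- kin_raw(kin$alpha, kin$beta, kin$gamma, tau)
    tf <- traj_F(k2, structure, prior, suff, want_grad = tau_cols(structure))
    dFdtau <- matrix(colSums(tf$grad), 1L)
    gw <- chain_tau_to_w(dFdtau, softmax_rows(matrix(w, 1L)))
    if (!all(is.finite(tf$F)) || !all(is.finite(gw)))
      return(list(value = 1e300, grad = rep(0, K)))
    list(value = -sum(tf$F), grad = -as.vector(gw))
  }
  co <- make_cached_objective(eval_both)
  opt <- try(stats::optim(w0, co$fn, co$gr, method = "L-BFGS-B",
                          lower = TAU_W_LO, upper = TAU_W_HI,
                          control = list(maxit = maxit, factr = 1e4)), silent = TRUE)
  if (inherits(opt, "try-error")) {
    attr(kin, "F") <- F0
    return(kin)
  }
  tau_new <- as.vector(tau_from_w_rows(matrix(opt$par, 1L)))
  k2 <- kin_raw(kin$alpha, kin$beta, kin$gamma, tau_new)
  F1 <- traj_F(k2, structure, prior, suff)$F
  if (!all(is.finite(F1)) || sum(F1) < sum(F0)) {
    attr(kin, "F") <- F0
    return(kin)
  }
  attr(k2, "F") <- F1
  k2
}

# Desynchronized M-step: per-gene rates and per-gene switch times, with an
# optional quadratic penalty pulling gene-wise tau toward the consensus.
m_step_desync <- function(kin, structure, prior, suff, penalty = 0,
                          consensus = NULL, maxit = 8L) {
  p <- nrow(kin$alpha); S <- ncol(kin$alpha); K <- structure$n_seg
  dr <- S + 2L
  dtot <- dr + K
  taum <- tau_matrix(kin, p)
  if (is.null(consensus)) consensus <- colMeans(taum)
  w0 <- log(pmax(t(apply(taum, 1L, diff)), 1e-6))
  theta0 <- cbind(pmin(pmax(cbind(safe_log(kin$alpha), log(kin$beta),
                                  log(kin$gamma)), LOGRATE_LO), LOGRATE_HI),
                  pmin(pmax(w0, TAU_W_LO), TAU_W_HI))
  interior <- seq_len(K - 1L)
  eval_both <- function(vec) {
    th <- matrix(vec, p, dtot)
    alpha <- exp(th[, 1:S, drop = FALSE])
    beta <- exp(th[, S + 1L]); gamma <- exp(th[, S + 2L])
    Wm <- th[, dr + seq_len(K), drop = FALSE]
    tau <- tau_from_w_rows(Wm)
    k2 <- kin_raw(alpha, beta, gamma, tau)
    tf <- traj_F(k2, structure, prior, suff, want_grad = TRUE)
    Fv <- tf$F
    Grates <- tf$grad[, 1:dr, drop = FALSE] * cbind(alpha, beta, gamma)
    dFdtau <- tf$grad[, S + 2L + interior, drop = FALSE]
    if (penalty > 0 && K > 1L) {
      dev <- sweep(tau[, 1L + interior, drop = FALSE], 2L,
                   consensus[1L + interior], "-")
      Fv <- Fv - penalty * rowSums(dev^2)
      dFdtau <- dFdtau - 2 * penalty * dev
    }
    Gw <- chain_tau_to_w(dFdtau, softmax_rows(Wm))
    G <- cbind(Grates, Gw)
    if (!all(is.finite(Fv)) || !all(is.finite(G)))
      return(list(value = 1e300, grad = rep(0, length(vec))))
    list(value = -sum(Fv), grad = -as.vector(G))
  }
  co <- make_cached_objective(eval_both)
  lower <- matrix(LOGRATE_LO, p, dtot); lower[, dr + seq_len(K)] <- TAU_W_LO
  upper <- matrix(LOGRATE_HI, p, dtot); upper[, dr + seq_len(K)] <- TAU_W_HI
  opt <- stats::optim(as.vector(theta0), co$fn, co$gr, method = "L-BFGS-B",
                      lower = as.vector(lower), upper = as.vector(upper),
                      control = list(maxit = maxit, factr = 1e4))
  th <- matrix(opt$par, p, dtot)
  kin_new <- kin_raw(exp(th[, 1:S, drop = FALSE]), exp(th[, S + 1L]),
                     exp(th[, S + 2L]),
                     tau_from_w_rows(th[, dr + seq_len(K), drop = FALSE]))
  accept_per_gene(kin, kin_new, structure, prior, suff)
}

#' Update prior lineage weights (and t = 0 mass) from the posterior
#'
#' Sets the lineage weights (and the t = 0 atom mass, when enabled) to the
#' posterior average over cells; the time distribution on (0, 1] stays
#' uniform within each lineage. Returns the prior unchanged when
#' \code{enabled} is FALSE.
#'
#' @param posterior n x Z responsibility matrix.
#' @param prior a \code{\link{sampling_prior}}.
#' @param enabled logical flag (from the fit configuration).
#' @return an updated \code{\link{sampling_prior}}.
#' @export
update_prior_weights <- function(posterior, prior, enabled = TRUE) {
  if (!enabled) return(prior)
  L <- prior$n_lineages; M <- prior$M
  mass <- colMeans(posterior)
  lw <- vapply(seq_len(L),
               function(l) sum(mass[(l - 1L) * M + seq_len(M)]), 0)
  t0 <- if (prior$has_t0) mass[L * M + 1L] else 0
  tot <- sum(lw) + t0
  pr <- build_prior(L, M, lw / sum(lw), t0 / tot)
  structure(pr, class = "sampling_prior")
}

# full per-gene conditional term sum_i sum_z q log p(x_ij | z, theta_j),
# i.e. traj_F plus the theta-independent count terms
gene_conditional_term <- function(kin, structure, prior, suff, data) {
  Fv <- traj_F(kin, structure, prior, suff)$F
  logr <- log(data$read_depth)
  cu <- as.vector(crossprod(data$unspliced, logr)) -
    colSums(lgamma(data$unspliced + 1))
  cs <- as.vector(crossprod(data$spliced, logr)) -
    colSums(lgamma(data$spliced + 1))
  Fv + cu + cs
}
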
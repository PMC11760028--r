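# Closed-form piecewise-exponential solution of the kinetic ODEs
#   du/dt = A_l(t) - beta * u
#   ds/dt = beta * u - gamma * s
# with A_l(t) piecewise constant on segments (tau_{k-1}, tau_k] and the
# steady-state initial condition u(0) = alpha_0/beta, s(0) = alpha_0/gamma
# of the lineage's initial state. Solved by propagating exact segment
# solutions between switch times; parameter sensitivities are accumulated
# alongside by forward differentiation of the same recursion, restricted
# to the parameter columns a caller actually optimizes (grad_cols).

# Parameter column layout per gene (primitive scale):
#   1..S        alpha_s, one per state
#   S+1, S+2    beta, gamma
#   S+2+k       tau_k, k = 1..K-1 (interior switch times)
n_par_gene <- function(structure) {
  structure$n_states + 2L + (structure$n_seg - 1L)
}

rate_cols <- function(structure) seq_len(structure$n_states + 2L)

tau_cols <- function(structure) {
  S <- structure$n_states; K <- structure$n_seg
  if (K <= 1L) integer(0) else S + 2L + seq_len(K - 1L)
}

# normalize a want_grad argument to an integer column vector (or NULL)
norm_grad_cols <- function(want_grad, structure) {
  if (isFALSE(want_grad) || is.null(want_grad)) return(NULL)
  if (isTRUE(want_grad)) return(seq_len(n_par_gene(structure)))
  as.integer(want_grad)
}

# relative tolerance below which the (gamma - beta) denominator terms are
# replaced by their analytic gamma -> beta limits; the printed solution is
# singular there, the ODE is not
BETA_GAMMA_TOL <- 1e-8

# D = (e^{-beta d} - e^{-gamma d}) / (gamma - beta) and its partials
# (all arguments recycled vectors of a common length)
dfun <- function(beta, gamma, delta, Eb, Eg, want_grad = FALSE) {
  deg <- abs(beta - gamma) < BETA_GAMMA_TOL * pmax(beta, gamma)
  denom <- gamma - beta
  denom[deg] <- 1
  D <- (Eb - Eg) / denom
  dEb <- delta * Eb
  if (any(deg)) D[deg] <- dEb[deg]
  if (!want_grad) return(list(D = D))
  dbeta <- (D - dEb) / denom
  dgamma <- (delta * Eg - D) / denom
  ddelta <- (gamma * Eg - beta * Eb) / denom
  if (any(deg)) {
    lim <- (-delta^2 * Eb / 2)[deg]
    dbeta[deg] <- lim
    dgamma[deg] <- lim
    ddelta[deg] <- (Eb * (1 - beta * delta))[deg]
  }
  list(D = D, dbeta = dbeta, dgamma = dgamma, ddelta = ddelta)
}

# Propagate (u0, s0) at a segment entry through elapsed time delta within
# a segment whose state's alpha is alpha_st (state column st_col).
# `pos` maps primitive parameter columns to Jacobian slices (0 = not
# tracked); J* are p x n_tracked. `ddelta` is a named numeric vector
# mapping parameter columns to d(delta)/d(theta) coefficients.
propagate_segment <- function(u0, s0, alpha_st, beta, gamma, delta, st_col,
                              pos = NULL, JU0 = NULL, JS0 = NULL,
                              ddelta = NULL, ib = NULL, ig = NULL) {
  want_grad <- !is.null(pos)
  a <- alpha_st / beta
  b <- alpha_st / gamma
  Eb <- exp(-beta * delta)
  Eg <- exp(-gamma * delta)
  Df <- dfun(beta, gamma, delta, Eb, Eg, want_grad)
  D <- Df$D
  du0a <- u0 - a
  u <- a + du0a * Eb
  s <- b + (s0 - b) * Eg + beta * du0a * D
  if (!want_grad) return(list(u = u, s = s))

  JU <- JU0 * Eb
  JS <- JS0 * Eg + (beta * D) * JU0
  j <- pos[st_col]
  if (j > 0L) {  # alpha of this segment's state (enters a and b)
    JU[, j] <- JU[, j] + (1 - Eb) / beta
    JS[, j] <- JS[, j] + (1 - Eg) / gamma - D
  }
  j <- pos[ib]
  if (j > 0L) {
    JU[, j] <- JU[, j] - (a / beta) * (1 - Eb) - delta * Eb * du0a
    JS[, j] <- JS[, j] + du0a * D + a * D + beta * du0a * Df$dbeta
  }
  j <- pos[ig]
  if (j > 0L)
    JS[, j] <- JS[, j] - (b / gamma) * (1 - Eg) - delta * Eg * (s0 - b) +
      beta * du0a * Df$dgamma
  if (length(ddelta)) {
    for (nm in names(ddelta)) {
      j <- pos[as.integer(nm)]
      if (j == 0L) next
      co <- ddelta[[nm]]
      JU[, j] <- JU[, j] - beta * Eb * du0a * co
      JS[, j] <- JS[, j] - gamma * Eg * (s0 - b) * co +
        beta * du0a * Df$ddelta * co
    }
  }
  list(u = u, s = s, JU = JU, JS = JS)
}

# Boundary values (and Jacobians for tracked columns) of the means at
# tau_0..tau_K for one lineage. Lists indexed k+1 (i.e. [[1]] is t = 0).
segment_boundaries <- function(structure, kin, lineage, grad_cols = NULL) {
  paths <- structure$paths
  K <- structure$n_seg
  ntau <- if (is.matrix(kin$tau)) ncol(kin$tau) else length(kin$tau)
  if (ntau != K + 1L)
    stop("kinetics carry ", ntau, " switch times but the structure has ",
         K, " segment(s); expected ", K + 1L)
  S <- structure$n_states
  p <- nrow(kin$alpha)
  d <- n_par_gene(structure)
  ib <- S + 1L; ig <- S + 2L
  want_grad <- !is.null(grad_cols)
  pos <- NULL
  if (want_grad) {
    pos <- integer(d)
    pos[grad_cols] <- seq_along(grad_cols)
  }
  taum <- tau_matrix(kin, p)
  s0_col <- paths[lineage, 1L] + 1L
  u <- kin$alpha[, s0_col] / kin$beta
  s <- kin$alpha[, s0_col] / kin$gamma
  U <- vector("list", K + 1L); Sv <- vector("list", K + 1L)
  JU <- JS <- NULL
  JUl <- JSl <- vector("list", K + 1L)
  if (want_grad) {
    nc <- length(grad_cols)
    JU <- matrix(0, p, nc); JS <- matrix(0, p, nc)
    if (pos[s0_col] > 0L) {
      JU[, pos[s0_col]] <- 1 / kin$beta
      JS[, pos[s0_col]] <- 1 / kin$gamma
    }
    if (pos[ib] > 0L) JU[, pos[ib]] <- JU[, pos[ib]] - u / kin$beta
    if (pos[ig] > 0L) JS[, pos[ig]] <- JS[, pos[ig]] - s / kin$gamma
  }
  U[[1L]] <- u; Sv[[1L]] <- s; JUl[[1L]] <- JU; JSl[[1L]] <- JS
  for (k in seq_len(K)) {
    st_col <- paths[lineage, k + 1L] + 1L
    delta <- taum[, k + 1L] - taum[, k]
    ddelta <- numeric(0)
    if (k <= K - 1L) ddelta[as.character(S + 2L + k)] <- 1
    if (k - 1L >= 1L) ddelta[as.character(S + 2L + k - 1L)] <- -1
    pr <- propagate_segment(u, s, kin$alpha[, st_col], kin$beta, kin$gamma,
                            delta, st_col, pos, JU, JS, ddelta, ib, ig)
    u <- pr$u; s <- pr$s
    if (want_grad) { JU <- pr$JU; JS <- pr$JS }
    U[[k + 1L]] <- u; Sv[[k + 1L]] <- s
    JUl[[k + 1L]] <- JU; JSl[[k + 1L]] <- JS
  }
  list(u = U, s = Sv, JU = JUl, JS = JSl)
}

# Means (p x length(t)) of unspliced and spliced counts along one lineage.
# want_grad: FALSE, TRUE (all parameters), or an integer vector of
# primitive parameter columns; Jacobian arrays are p x length(t) x
# n_tracked on the primitive scale. Shared switch times take a
# block-vectorized path; gene-wise switch times use a masked fallback.
lineage_means <- function(structure, kin, lineage, t, want_grad = FALSE) {
  if (any(t < 0 | t > 1)) stop("process times must lie in [0, 1]")
  grad_cols <- norm_grad_cols(want_grad, structure)
  if (kin$desynchronized)
    lineage_means_desync(structure, kin, lineage, t, grad_cols)
  else
    lineage_means_sync(structure, kin, lineage, t, grad_cols)
}

lineage_means_sync <- function(structure, kin, lineage, t, grad_cols) {
  paths <- structure$paths
  K <- structure$n_seg
  S <- structure$n_states
  p <- nrow(kin$alpha)
  ib <- S + 1L; ig <- S + 2L
  nt <- length(t)
  want_grad <- !is.null(grad_cols)
  nc <- length(grad_cols)
  beta <- kin$beta; gamma <- kin$gamma
  bd <- segment_boundaries(structure, kin, lineage, grad_cols)
  LU <- matrix(0, p, nt); LS <- matrix(0, p, nt)
  GU <- GS <- NULL
  if (want_grad) { GU <- array(0, c(p, nt, nc)); GS <- array(0, c(p, nt, nc)) }

  seg1 <- findInterval(t, kin$tau, left.open = TRUE, rightmost.closed = FALSE)
  seg1[t == 0] <- 0L
  seg1 <- pmin(seg1, K)  # guard t = 1 against rounding

  for (q in 0:K) {
    cols <- which(seg1 == q)
    if (!length(cols)) next
    if (q == 0L) {
      LU[, cols] <- bd$u[[1L]]
      LS[, cols] <- bd$s[[1L]]
      if (want_grad) for (jj in seq_len(nc)) {
        GU[, cols, jj] <- bd$JU[[1L]][, jj]
        GS[, cols, jj] <- bd$JS[[1L]][, jj]
      }
      next
    }
    st_col <- paths[lineage, q + 1L] + 1L
    a <- kin$alpha[, st_col] / beta
    b <- kin$alpha[, st_col] / gamma
    u0 <- bd$u[[q]]; s0 <- bd$s[[q]]
    delta <- t[cols] - kin$tau[q]            # row vector over block columns
    Eb <- exp(-beta %o% delta)               # p x nb
    Eg <- exp(-gamma %o% delta)
    deg <- abs(beta - gamma) < BETA_GAMMA_TOL * pmax(beta, gamma)
    denom <- gamma - beta
    denom[deg] <- 1
    DeltaM <- matrix(delta, p, length(cols), byrow = TRUE)
    D <- (Eb - Eg) / denom
    if (any(deg)) D[deg, ] <- (DeltaM * Eb)[deg, ]
    du0a <- u0 - a
    LU[, cols] <- a + du0a * Eb
    LS[, cols] <- b + (s0 - b) * Eg + (beta * du0a) * D
    if (want_grad) {
      need_bg <- any(grad_cols == ib) || any(grad_cols == ig) ||
        any(grad_cols == S + 2L + q - 1L)
      if (need_bg) {
        dDb <- (D - DeltaM * Eb) / denom
        dDg <- (DeltaM * Eg - D) / denom
        dDd <- (gamma * Eg - beta * Eb) / denom
        if (any(deg)) {
          lim <- (-DeltaM^2 * Eb / 2)[deg, , drop = FALSE]
          dDb[deg, ] <- lim
          dDg[deg, ] <- lim
          dDd[deg, ] <- (Eb * (1 - beta * DeltaM))[deg, , drop = FALSE]
        }
      }
      JU0 <- bd$JU[[q]]; JS0 <- bd$JS[[q]]
      for (jj in seq_len(nc)) {
        cc <- grad_cols[jj]
        gu <- JU0[, jj] * Eb
        gs <- JS0[, jj] * Eg + (beta * D) * JU0[, jj]
        if (cc == st_col) {
          gu <- gu + (1 - Eb) / beta
          gs <- gs + (1 - Eg) / gamma - D
        } else if (cc == ib) {
          gu <- gu - (a / beta) * (1 - Eb) - du0a * (DeltaM * Eb)
          gs <- gs + du0a * D + a * D + (beta * du0a) * dDb
        } else if (cc == ig) {
          gs <- gs - (b / gamma) * (1 - Eg) - (s0 - b) * (DeltaM * Eg) +
            (beta * du0a) * dDg
        } else if (cc == S + 2L + q - 1L && q >= 2L) {
          # delta = t - tau_{q-1}: d(delta)/d(tau_{q-1}) = -1
          gu <- gu + (beta * du0a) * Eb
          gs <- gs + (gamma * (s0 - b)) * Eg - (beta * du0a) * dDd
        }
        GU[, cols, jj] <- gu
        GS[, cols, jj] <- gs
      }
    }
  }
  list(lambda_u = LU, lambda_s = LS, grad_u = GU, grad_s = GS)
}

lineage_means_desync <- function(structure, kin, lineage, t, grad_cols) {
  paths <- structure$paths
  K <- structure$n_seg
  S <- structure$n_states
  p <- nrow(kin$alpha)
  d <- n_par_gene(structure)
  ib <- S + 1L; ig <- S + 2L
  nt <- length(t)
  want_grad <- !is.null(grad_cols)
  nc <- length(grad_cols)
  pos <- NULL
  if (want_grad) {
    pos <- integer(d)
    pos[grad_cols] <- seq_along(grad_cols)
  }
  taum <- tau_matrix(kin, p)
  bd <- segment_boundaries(structure, kin, lineage, grad_cols)
  LU <- matrix(0, p, nt); LS <- matrix(0, p, nt)
  GU <- GS <- NULL
  if (want_grad) { GU <- array(0, c(p, nt, nc)); GS <- array(0, c(p, nt, nc)) }

  tmat <- matrix(t, p, nt, byrow = TRUE)
  seg <- matrix(0L, p, nt)
  for (k in seq_len(K)) seg <- seg + (tmat > taum[, k])

  for (q in 0:K) {
    mask <- seg == q
    if (!any(mask)) next
    if (q == 0L) {
      LU[mask] <- matrix(bd$u[[1L]], p, nt)[mask]
      LS[mask] <- matrix(bd$s[[1L]], p, nt)[mask]
      if (want_grad) for (jj in seq_len(nc)) {
        GU[, , jj][mask] <- matrix(bd$JU[[1L]][, jj], p, nt)[mask]
        GS[, , jj][mask] <- matrix(bd$JS[[1L]][, jj], p, nt)[mask]
      }
      next
    }
    st_col <- paths[lineage, q + 1L] + 1L
    # full p x nt evaluation with clamped delta; only masked entries kept
    delta <- pmax(tmat - taum[, q], 0)
    ddelta <- numeric(0)
    if (q - 1L >= 1L && q - 1L <= K - 1L)
      ddelta[as.character(S + 2L + q - 1L)] <- -1
    rep_b <- rep(kin$beta, nt); rep_g <- rep(kin$gamma, nt)
    rep_a <- rep(kin$alpha[, st_col], nt)
    u0 <- rep(bd$u[[q]], nt); s0 <- rep(bd$s[[q]], nt)
    if (want_grad) {
      JU0 <- bd$JU[[q]][rep(seq_len(p), nt), , drop = FALSE]
      JS0 <- bd$JS[[q]][rep(seq_len(p), nt), , drop = FALSE]
    } else JU0 <- JS0 <- NULL
    pr <- propagate_segment(u0, s0, rep_a, rep_b, rep_g, as.vector(delta),
                            st_col, pos, JU0, JS0, ddelta, ib, ig)
    LU[mask] <- matrix(pr$u, p, nt)[mask]
    LS[mask] <- matrix(pr$s, p, nt)[mask]
    if (want_grad) for (jj in seq_len(nc)) {
      GU[, , jj][mask] <- matrix(pr$JU[, jj], p, nt)[mask]
      GS[, , jj][mask] <- matrix(pr$JS[, jj], p, nt)[mask]
    }
  }
  list(lambda_u = LU, lambda_s = LS, grad_u = GU, grad_s = GS)
}

#' Piecewise-constant transcription rate along a lineage
#'
#' Returns the active transcription rate \eqn{\alpha_{s(l,k)}} for each gene
#' at the requested process times; time 0 maps to the lineage's initial
#' state, and segment membership follows the half-open-left convention
#' \eqn{t \in (\tau_{k-1}, \tau_k]}.
#'
#' @param structure a \code{\link{trajectory_structure}}.
#' @param kin a \code{\link{gene_kinetics}}.
#' @param lineage lineage index (1-based).
#' @param t vector of process times in [0, 1].
#' @return a p x length(t) matrix of transcription rates.
#' @export
piecewise_rate <- function(structure, kin, lineage, t) {
  if (any(t < 0 | t > 1)) stop("process times must lie in [0, 1]")
  if (lineage < 1L || lineage > structure$n_lineages)
    stop("invalid lineage index")
  p <- nrow(kin$alpha)
  K <- structure$n_seg
  taum <- tau_matrix(kin, p)
  out <- matrix(0, p, length(t))
  seg <- matrix(0L, p, length(t))
  for (k in seq_len(K))
    seg <- seg + (matrix(t, p, length(t), byrow = TRUE) > taum[, k])
  for (q in 0:K) {
    st_col <- structure$paths[lineage, q + 1L] + 1L
    mask <- seg == q
    out[mask] <- matrix(kin$alpha[, st_col], p, length(t))[mask]
  }
  out
}

#' Closed-form mean dynamics of unspliced and spliced counts
#'
#' Evaluates the piecewise-exponential solution of the
#' transcription-splicing-degradation ODEs along one lineage, starting from
#' the steady state of the lineage's initial state at t = 0. The solution is
#' continuous in t across switch times; the degenerate case
#' \eqn{\beta \approx \gamma} is evaluated with the analytic limit form.
#'
#' @inheritParams piecewise_rate
#' @return a list with p x length(t) matrices \code{lambda_u} and
#'   \code{lambda_s}.
#' @examples
#' st <- trajectory_structure("[[0,1]]")
#' kin <- gene_kinetics(alpha = cbind(2, 10), beta = 4, gamma = 1,
#'                      tau = c(0, 1))
#' mean_solution(st, kin, 1, c(0, 0.5, 1))
#' @export
mean_solution <- function(structure, kin, lineage, t) {
  if (lineage < 1L || lineage > structure$n_lineages)
    stop("invalid lineage index")
  m <- lineage_means(structure, kin, lineage, t, want_grad = FALSE)
  list(lambda_u = m$lambda_u, lambda_s = m$lambda_s)
}

# Means on the full latent grid of a sampling prior: p x Z matrices, with
# columns ordered lineage-major and the optional t0 atom last. With
# want_grad (TRUE or a primitive column vector), also returns p x Z x
# n_tracked Jacobians on the primitive scale.
grid_means <- function(structure, kin, prior, want_grad = FALSE) {
  grad_cols <- norm_grad_cols(want_grad, structure)
  L <- structure$n_lineages
  M <- prior$M
  p <- nrow(kin$alpha)
  nc <- length(grad_cols)
  Z <- L * M + as.integer(prior$has_t0)
  LU <- matrix(0, p, Z); LS <- matrix(0, p, Z)
  GU <- GS <- NULL
  if (nc) { GU <- array(0, c(p, Z, nc)); GS <- array(0, c(p, Z, nc)) }
  for (l in seq_len(L)) {
    idx <- (l - 1L) * M + seq_len(M)
    m <- lineage_means(structure, kin, l, prior$grid, grad_cols)
    LU[, idx] <- m$lambda_u; LS[, idx] <- m$lambda_s
    if (nc) { GU[, idx, ] <- m$grad_u; GS[, idx, ] <- m$grad_s }
  }
  if (prior$has_t0) {
    m0 <- lineage_means(structure, kin, 1L, 0, grad_cols)
    LU[, Z] <- m0$lambda_u; LS[, Z] <- m0$lambda_s
    if (nc) { GU[, Z, ] <- m0$grad_u; GS[, Z, ] <- m0$grad_s }
  }
  list(lambda_u = LU, lambda_s = LS, grad_u = GU, grad_s = GS,
       grad_cols = grad_cols)
}
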
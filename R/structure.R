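#' Trajectory structure: lineages as state paths on a directed state graph
#'
#' A trajectory structure records, for each of \code{L} lineages, the ordered
#' cellular states the lineage traverses. Each path has \code{K + 1} entries:
#' the first entry is the state occupied at process time 0 (its steady state
#' provides the initial condition of the kinetic ODEs, and it carries the
#' optional point mass at t = 0), and entry \code{k + 1} is the state active
#' during the k-th time segment \code{(tau[k], tau[k+1]]}. States are
#' 0-based integers; every state index in \code{0:(n_states - 1)} must appear
#' in at least one path, and all paths must have the same length.
#'
#' @param paths an L x (K+1) integer matrix, a list of equal-length integer
#'   vectors (one lineage per element), or a JSON string such as
#'   \code{"[[0,1,2],[0,1,3]]"}.
#' @return an object of class \code{"traj_structure"} with elements
#'   \code{paths} (L x (K+1) integer matrix), \code{n_lineages},
#'   \code{n_seg} (K, the number of time segments) and \code{n_states}.
#' @examples
#' st <- trajectory_structure("[[0,1,2],[0,1,3]]")
#' st$n_seg      # 2 segments
#' st$n_states   # 4 states
#' @export
trajectory_structure <- function(paths) {
  if (is.character(paths) && length(paths) == 1L) {
    paths <- jsonlite::fromJSON(paths, simplifyMatrix = TRUE)
  }
  if (is.list(paths)) {
    len <- lengths(paths)
    if (length(unique(len)) != 1L)
      stop("all lineage paths must have the same number of stages")
    paths <- do.call(rbind, lapply(paths, as.integer))
  }
  paths <- as.matrix(paths)
  storage.mode(paths) <- "integer"
  if (ncol(paths) < 2L)
    stop("paths need at least two entries: an initial state and one segment state")
  if (any(is.na(paths)) || any(paths < 0L))
    stop("state indices must be nonnegative integers")
  n_states <- max(paths) + 1L
  missing_states <- setdiff(seq_len(n_states) - 1L, as.vector(paths))
  if (length(missing_states))
    stop("state indices not referenced by any path: ",
         paste(missing_states, collapse = ", "))
  structure(
    list(paths = paths,
         n_lineages = nrow(paths),
         n_seg = ncol(paths) - 1L,
         n_states = n_states),
    class = "traj_structure")
}

#' @export
print.traj_structure <- function(x, ...) {
  cat(sprintf("Trajectory structure: %d lineage(s), %d segment(s), %d state(s)\n",
              x$n_lineages, x$n_seg, x$n_states))
  for (l in seq_len(x$n_lineages))
    cat(sprintf("  lineage %d: %s\n", l,
                paste(x$paths[l, ], collapse = " -> ")))
  invisible(x)
}

#' Per-gene transcription, splicing and degradation kinetics
#'
#' @param alpha p x S matrix of transcription rates (counts per unit process
#'   time, >= 0); column s holds the rate of state \code{s - 1}.
#' @param beta length-p vector of splicing rates (> 0).
#' @param gamma length-p vector of degradation rates (> 0).
#' @param tau switch times: a numeric vector of length K+1 with
#'   \code{tau[1] = 0} and \code{tau[K+1] = 1} (synchronized model), or a
#'   p x (K+1) matrix of per-gene switch times (desynchronized model).
#' @return an object of class \code{"gene_kinetics"}.
#' @export
gene_kinetics <- function(alpha, beta, gamma, tau) {
  alpha <- as.matrix(alpha)
  p <- nrow(alpha)
  if (length(beta) != p || length(gamma) != p)
    stop("beta and gamma must have one entry per gene")
  if (any(alpha < 0) || any(beta <= 0) || any(gamma <= 0))
    stop("rates must satisfy alpha >= 0, beta > 0, gamma > 0")
  desync <- is.matrix(tau)
  tm <- if (desync) tau else matrix(tau, nrow = 1L)
  if (any(abs(tm[, 1L]) > 1e-12) || any(abs(tm[, ncol(tm)] - 1) > 1e-12))
    stop("tau must start at 0 and end at 1")
  if (any(apply(tm, 1L, function(v) any(diff(v) <= 0))))
    stop("tau must be strictly increasing")
  if (desync && nrow(tm) != p)
    stop("desynchronized tau must have one row per gene")
  structure(
    list(alpha = alpha, beta = as.numeric(beta), gamma = as.numeric(gamma),
         tau = tau, desynchronized = desync),
    class = "gene_kinetics")
}

#' @export
print.gene_kinetics <- function(x, ...) {
  cat(sprintf("Gene kinetics: %d gene(s), %d state(s), %s switch times\n",
              nrow(x$alpha), ncol(x$alpha),
              if (x$desynchronized) "gene-wise" else "shared"))
  invisible(x)
}

# tau rows aligned with genes: 1 x (K+1) recycled in synchronized mode
tau_matrix <- function(kin, p) {
  if (kin$desynchronized) kin$tau else
    matrix(kin$tau, nrow = p, ncol = length(kin$tau), byrow = TRUE)
}

#' Counts with per-cell read depth
#'
#' Bundles matched unspliced and spliced count matrices (cells x genes) with
#' per-cell relative read depths. Read depths are rescaled to mean 1, the
#' model's convention (the mean capture rate is absorbed into alpha).
#'
#' @param unspliced,spliced nonnegative integer matrices, cells x genes.
#' @param read_depth per-cell positive scalars; defaults to 1 for all cells.
#' @return an object of class \code{"count_dataset"}.
#' @export
count_dataset <- function(unspliced, spliced, read_depth = NULL) {
  unspliced <- as.matrix(unspliced)
  spliced <- as.matrix(spliced)
  if (!identical(dim(unspliced), dim(spliced)))
    stop("unspliced and spliced matrices must have identical dimensions")
  if (any(unspliced < 0) || any(spliced < 0))
    stop("counts must be nonnegative")
  if (any(unspliced != round(unspliced)) || any(spliced != round(spliced)))
    stop("counts must be integers")
  n <- nrow(unspliced)
  if (is.null(read_depth)) read_depth <- rep(1, n)
  if (length(read_depth) != n) stop("read_depth must have one entry per cell")
  if (any(read_depth <= 0)) stop("read_depth must be strictly positive")
  read_depth <- read_depth / mean(read_depth)
  structure(
    list(unspliced = unspliced, spliced = spliced,
         read_depth = as.numeric(read_depth)),
    class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("Count dataset: %d cells x %d genes (unspliced + spliced)\n",
              nrow(x$unspliced), ncol(x$unspliced)))
  cat(sprintf("  read depth: mean %.3f, CV^2 %.3f\n",
              mean(x$read_depth), stats::var(x$read_depth) / mean(x$read_depth)^2))
  invisible(x)
}

#' Sampling prior over (lineage, time grid) latent states
#'
#' The latent time axis is discretized on the regular grid t_m = m/M,
#' m = 1..M. The default prior is uniform over grid points and lineages,
#' optionally with a shared point mass at t = 0 (for systems whose initial
#' state is long-lived, e.g. a proliferating progenitor pool).
#'
#' @param structure a \code{\link{trajectory_structure}}.
#' @param M number of time grid points on (0, 1].
#' @param lineage_weights length-L positive weights (normalized internally).
#' @param t0_mass prior mass on the t = 0 atom; 0 disables the atom.
#' @return an object of class \code{"sampling_prior"} with fields
#'   \code{grid} (the M time points), \code{lineage_weights}, \code{t0_mass},
#'   and \code{log_weights}, the length L*M (+1 if the atom is enabled)
#'   per-latent-state log prior shared by all cells. Latent states are ordered
#'   lineage-major (lineage 1 grid, lineage 2 grid, ..., then the t0 atom).
#' @export
sampling_prior <- function(structure, M = 100L, lineage_weights = NULL,
                           t0_mass = 0) {
  L <- structure$n_lineages
  if (is.null(lineage_weights)) lineage_weights <- rep(1 / L, L)
  if (length(lineage_weights) != L || any(lineage_weights < 0))
    stop("lineage_weights must be L nonnegative values")
  lineage_weights <- lineage_weights / sum(lineage_weights)
  if (t0_mass < 0 || t0_mass >= 1) stop("t0_mass must be in [0, 1)")
  prior <- build_prior(L, M, lineage_weights, t0_mass)
  structure(prior, class = "sampling_prior")
}

build_prior <- function(L, M, lineage_weights, t0_mass) {
  w <- rep((1 - t0_mass) * lineage_weights / M, each = M)
  if (t0_mass > 0) w <- c(w, t0_mass)
  list(grid = seq_len(M) / M, M = as.integer(M), n_lineages = L,
       lineage_weights = lineage_weights, t0_mass = t0_mass,
       has_t0 = t0_mass > 0, log_weights = log(w))
}

# times associated with latent-state columns (t0 atom contributes 0)
latent_times <- function(prior) {
  tt <- rep(prior$grid, times = prior$n_lineages)
  if (prior$has_t0) tt <- c(tt, 0)
  tt
}

# lineage index per latent-state column (t0 atom gets NA)
latent_lineages <- function(prior) {
  ll <- rep(seq_len(prior$n_lineages), each = prior$M)
  if (prior$has_t0) ll <- c(ll, NA_integer_)
  ll
}
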
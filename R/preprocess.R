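# Extrinsic-noise estimation via normalized covariance between genes,
# read-depth estimation from near-Poissonian genes, and gene filtering.
#
# The cell-wise read depth r multiplies every gene's mean, so it shows up
# as a shared component of between-gene covariance: for independent genes,
# Cov(X_a, X_b) / (E[X_a] E[X_b]) = Var(r) / E[r]^2. Averaging the
# normalized covariance over distinct gene pairs therefore estimates the
# read-depth CV^2 (denoted xi). Genes whose variance stays near the
# baseline mu + xi mu^2 carry no additional gene-specific variation and
# are "Poissonian": their summed counts estimate relative read depth.

#' Mean normalized covariance across genes (extrinsic noise xi)
#'
#' Averages \code{Cov(X_a, X_b) / (mean_a mean_b)} over all ordered pairs
#' of distinct genes, computed through the variance of the mean-normalized
#' row sums (O(n p), no p x p matrix). Genes with zero mean are dropped.
#'
#' @param counts n x p count matrix (by convention spliced counts; any
#'   species mix can be supplied).
#' @return the scalar estimate of the read-depth CV^2.
#' @export
estimate_extrinsic_noise <- function(counts) {
  counts <- as.matrix(counts)
  mu <- colMeans(counts)
  keep <- mu > 0
  if (sum(keep) < 2L) stop("need at least 2 genes with nonzero mean")
  Y <- sweep(counts[, keep, drop = FALSE], 2L, mu[keep], "/")
  p <- ncol(Y)
  tot_var <- stats::var(rowSums(Y))          # sum over all pairs incl. diagonal
  diag_var <- sum(apply(Y, 2L, stats::var))  # a = b excluded from the average
  (tot_var - diag_var) / (p * (p - 1L))
}

#' Iterative selection of Poissonian genes
#'
#' Selects genes whose variance is close to the read-depth baseline with a
#' reasonably large mean (\code{var < 1.2 (mu + xi mu^2)} and
#' \code{mu > 0.01}), re-estimates xi on the selected set, and repeats to a
#' fixed point (change in xi below \code{tol}, typically 2-3 iterations;
#' hard cap 10).
#'
#' @param counts n x p count matrix.
#' @param xi optional starting value; estimated from all nonzero-mean
#'   genes when missing.
#' @param var_factor variance threshold multiplier (1.2).
#' @param mean_min minimum gene mean (0.01).
#' @param tol fixed-point tolerance on xi.
#' @return a list: \code{genes} (integer indices), \code{xi} (final
#'   estimate), \code{n_iterations}.
#' @export
select_poissonian_genes <- function(counts, xi = NULL, var_factor = 1.2,
                                    mean_min = 0.01, tol = 1e-4) {
  counts <- as.matrix(counts)
  mu <- colMeans(counts)
  v <- apply(counts, 2L, stats::var)
  if (is.null(xi)) xi <- estimate_extrinsic_noise(counts)
  sel_old <- integer(0)
  for (it in seq_len(10L)) {
    sel <- which(mu > mean_min & v < var_factor * (mu + xi * mu^2))
    if (length(sel) < 2L)
      stop("fewer than 2 Poissonian genes selected; relax var_factor or mean_min")
    xi_new <- estimate_extrinsic_noise(counts[, sel, drop = FALSE])
    done <- abs(xi_new - xi) < tol && setequal(sel, sel_old)
    xi <- xi_new
    sel_old <- sel
    if (done) break
  }
  list(genes = sel, xi = xi, n_iterations = it)
}

#' Estimate per-cell relative read depth
#'
#' Sums unspliced + spliced counts over the Poissonian gene set and
#' normalizes by the across-cell mean, giving relative depths with mean
#' exactly 1. Cells with zero summed counts get a half-count pseudocount
#' and are flagged.
#'
#' @param data a \code{\link{count_dataset}} (its stored read depth is
#'   ignored), or a list with \code{unspliced} and \code{spliced}.
#' @param xi optional starting xi passed to the gene selection.
#' @param var_factor,mean_min thresholds for
#'   \code{\link{select_poissonian_genes}}.
#' @return a list of class \code{"noise_estimate"}: \code{read_depth}
#'   (mean 1), \code{xi}, \code{poissonian_genes}, \code{n_iterations},
#'   \code{flagged_cells}.
#' @export
estimate_read_depth <- function(data, xi = NULL, var_factor = 1.2,
                                mean_min = 0.01) {
  tot <- data$unspliced + data$spliced
  sel <- select_poissonian_genes(data$spliced, xi = xi,
                                 var_factor = var_factor,
                                 mean_min = mean_min)
  rs <- rowSums(tot[, sel$genes, drop = FALSE])
  flagged <- which(rs == 0)
  rs[flagged] <- 0.5
  r <- rs / mean(rs)
  if (length(flagged))
    warning(length(flagged),
            " cell(s) had zero Poissonian counts; pseudocount applied")
  structure(list(read_depth = r, xi = sel$xi,
                 poissonian_genes = sel$genes,
                 n_iterations = sel$n_iterations,
                 flagged_cells = flagged),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "Read-depth estimate: xi = %.4f, %d Poissonian genes (%d iteration(s))\n",
    x$xi, length(x$poissonian_genes), x$n_iterations))
  invisible(x)
}

#' Filter genes for trajectory fitting
#'
#' Keeps genes with unspliced mean > \code{u_mean_min}, spliced mean >
#' \code{s_mean_min}, unspliced:spliced mean ratio > \code{us_ratio_min},
#' and spliced variance above \code{var_factor} times the read-depth
#' baseline variance \code{mu + xi mu^2} (i.e. genes that actually vary
#' beyond depth noise). The variance multiplier is occasionally raised
#' (e.g. to 1.5) to land in a practical 50-200 gene range.
#'
#' @param data a \code{\link{count_dataset}} or list with
#'   \code{unspliced}/\code{spliced}.
#' @param xi read-depth CV^2 (from \code{\link{estimate_read_depth}}).
#' @param var_factor variance multiplier (default 1.2).
#' @param u_mean_min,s_mean_min,us_ratio_min mean/ratio thresholds.
#' @param exclude genes (indices) never kept, e.g. the Poissonian genes
#'   used for read-depth estimation.
#' @return a logical mask over genes.
#' @export
filter_fitting_genes <- function(data, xi, var_factor = 1.2,
                                 u_mean_min = 0.02, s_mean_min = 0.1,
                                 us_ratio_min = exp(-4),
                                 exclude = integer(0)) {
  mu_u <- colMeans(data$unspliced)
  mu_s <- colMeans(data$spliced)
  v_s <- apply(data$spliced, 2L, stats::var)
  mask <- mu_u > u_mean_min & mu_s > s_mean_min &
    mu_u / pmax(mu_s, 1e-300) > us_ratio_min &
    v_s > var_factor * (mu_s + xi * mu_s^2)
  mask[exclude] <- FALSE
  if (!any(mask)) warning("no genes pass the fitting filter")
  mask
}
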
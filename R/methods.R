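# S3 methods for the fitted trajectory model.

#' @export
print.traj_fit <- function(x, ...) {
  cat(sprintf("Process-time trajectory fit (%s model)\n",
              if (x$mode == "sync") "synchronized" else "desynchronized"))
  cat(sprintf("  %d cells, %d genes, %d lineage(s), %d segment(s), grid M = %d\n",
              nrow(x$posterior), nrow(x$kinetics$alpha),
              x$structure$n_lineages, x$structure$n_seg, x$prior$M))
  cat(sprintf("  ELBO %.2f after %d iteration(s), %d restart(s), %s\n",
              x$elbo, length(x$elbo_trace), nrow(x$restart_table),
              if (x$converged) "converged" else "iteration cap reached"))
  tau <- x$kinetics$tau
  if (is.matrix(tau)) tau <- colMeans(tau)
  cat("  switch times:", paste(sprintf("%.3f", tau), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.traj_fit <- function(object, ...) {
  ic <- information_criteria(object)
  tm <- mean_process_time(object)
  out <- list(
    mode = object$mode, elbo = object$elbo, aic = ic[["aic"]],
    bic = ic[["bic"]], n_parameters = object$n_parameters,
    n_cells = nrow(object$posterior), n_genes = nrow(object$kinetics$alpha),
    time_quartiles = stats::quantile(tm, c(0, .25, .5, .75, 1)),
    posterior_entropy = average_posterior_entropy(object),
    lineage_occupancy = tabulate(map_lineage(object),
                                 object$structure$n_lineages) /
      nrow(object$posterior),
    restart_elbo_range = range(object$restart_table$elbo))
  class(out) <- "summary.traj_fit"
  out
}

#' @export
print.summary.traj_fit <- function(x, ...) {
  cat(sprintf("%s trajectory fit: %d cells x %d genes\n",
              if (x$mode == "sync") "Synchronized" else "Desynchronized",
              x$n_cells, x$n_genes))
  cat(sprintf("  ELBO %.2f | AIC %.2f | BIC %.2f (k = %d)\n",
              x$elbo, x$aic, x$bic, x$n_parameters))
  cat(sprintf("  restart ELBO range: [%.2f, %.2f]\n",
              x$restart_elbo_range[1], x$restart_elbo_range[2]))
  cat(sprintf("  average-posterior time entropy: %.3f nats\n",
              x$posterior_entropy))
  cat("  lineage occupancy:",
      paste(sprintf("%.2f", x$lineage_occupancy), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.traj_fit <- function(object, ...) {
  kin <- object$kinetics
  out <- data.frame(gene = seq_len(nrow(kin$alpha)))
  for (s in seq_len(ncol(kin$alpha)))
    out[[paste0("alpha_", s - 1L)]] <- kin$alpha[, s]
  out$beta <- kin$beta
  out$gamma <- kin$gamma
  out
}

#' @export
logLik.traj_fit <- function(object, ...) {
  structure(object$elbo, df = object$n_parameters,
            nobs = nrow(object$posterior), class = "logLik")
}

#' Fitted mean counts along process time
#'
#' Evaluates the fitted mean unspliced and spliced counts of selected
#' genes on a time grid of one lineage (the phase portrait coordinates).
#'
#' @param object a \code{"traj_fit"}.
#' @param lineage lineage index.
#' @param t time points (default the fit's grid).
#' @param genes gene indices (default all).
#' @param ... unused.
#' @return a list with matrices \code{lambda_u}, \code{lambda_s}
#'   (genes x times) and the \code{t} vector.
#' @export
predict.traj_fit <- function(object, lineage = 1L, t = NULL, genes = NULL,
                             ...) {
  if (is.null(t)) t <- object$prior$grid
  m <- mean_solution(object$structure, object$kinetics, lineage, t)
  if (!is.null(genes)) {
    m$lambda_u <- m$lambda_u[genes, , drop = FALSE]
    m$lambda_s <- m$lambda_s[genes, , drop = FALSE]
  }
  c(m, list(t = t))
}

#' Simulate counts from a fitted trajectory model
#'
#' Draws new cells from the fitted generative model: latent states from
#' the fitted prior, counts from the Poisson measurement model at the
#' fitted kinetics, read depths resampled from the training cells.
#'
#' @param object a \code{"traj_fit"}.
#' @param nsim number of cells (default: the training count).
#' @param seed integer seed.
#' @param ... unused.
#' @return a \code{\link{count_dataset}} with attribute \code{"latents"}.
#' @export
simulate.traj_fit <- function(object, nsim = nrow(object$posterior),
                              seed = 1L, ...) {
  set.seed(seed)
  prior <- object$prior
  w <- exp(prior$log_weights)
  z <- sample.int(length(w), nsim, replace = TRUE, prob = w)
  tt <- latent_times(prior)[z]
  ll <- latent_lineages(prior)[z]
  ll[is.na(ll)] <- 1L  # t0 atom: steady state shared across lineages
  r <- sample(object$data$read_depth, nsim, replace = TRUE)
  r <- r / mean(r)
  p <- nrow(object$kinetics$alpha)
  U <- matrix(0L, nsim, p); S <- matrix(0L, nsim, p)
  for (l in unique(ll)) {
    cells <- which(ll == l)
    m <- lineage_means(object$structure, object$kinetics, l, tt[cells])
    mu_u <- t(m$lambda_u) * r[cells]
    mu_s <- t(m$lambda_s) * r[cells]
    U[cells, ] <- stats::rpois(length(mu_u), mu_u)
    S[cells, ] <- stats::rpois(length(mu_s), mu_s)
  }
  out <- count_dataset(U, S, r)
  attr(out, "latents") <- list(lineage = ll, time = tt)
  out
}

#' Pearson residuals at the posterior-mean fit
#'
#' Residuals \code{(x - mu) / sqrt(mu)} per cell and gene, where mu is the
#' posterior-weighted fitted mean times read depth, for the requested
#' species.
#'
#' @param object a \code{"traj_fit"}.
#' @param species "spliced" (default) or "unspliced".
#' @param ... unused.
#' @return an n x p matrix of Pearson residuals.
#' @export
residuals.traj_fit <- function(object, species = c("spliced", "unspliced"),
                               ...) {
  species <- match.arg(species)
  gm <- grid_means(object$structure, object$kinetics, object$prior)
  lam <- if (species == "spliced") gm$lambda_s else gm$lambda_u
  mu <- (object$posterior %*% t(lam)) * object$data$read_depth
  x <- if (species == "spliced") object$data$spliced else
    object$data$unspliced
  (x - mu) / sqrt(pmax(mu, 1e-8))
}

#' Plot a fitted trajectory model
#'
#' \code{type = "posterior"} draws the posterior heatmap over time grids
#' with cells ordered by their posterior-mean time; \code{type = "phase"}
#' draws phase portraits (unspliced vs spliced fitted means over time) of
#' selected genes with the raw counts in the background; \code{type =
#' "elbo"} draws the ELBO trace.
#'
#' @param x a \code{"traj_fit"}.
#' @param type plot type.
#' @param genes genes for phase portraits (default: top 4 by fold change).
#' @param lineage lineage for phase portraits.
#' @param ... passed to the underlying plot functions.
#' @export
plot.traj_fit <- function(x, type = c("posterior", "phase", "elbo"),
                          genes = NULL, lineage = 1L, ...) {
  type <- match.arg(type)
  if (type == "elbo") {
    plot(seq_along(x$elbo_trace), x$elbo_trace, type = "b",
         xlab = "EM iteration", ylab = "ELBO", ...)
    return(invisible(x))
  }
  if (type == "posterior") {
    M <- x$prior$M; L <- x$prior$n_lineages
    q <- x$posterior
    tmarg <- matrix(0, nrow(q), M)
    for (l in seq_len(L))
      tmarg <- tmarg + q[, (l - 1L) * M + seq_len(M), drop = FALSE]
    ord <- order(mean_process_time(x))
    graphics::image(x = x$prior$grid, y = seq_len(nrow(q)),
                    z = t(tmarg[ord, , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                    xlab = "process time", ylab = "cells (ordered)", ...)
    return(invisible(x))
  }
  if (is.null(genes)) {
    de <- rank_de_genes(x$kinetics)
    genes <- utils::head(de$gene, 4L)
  }
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(genes)))
  on.exit(graphics::par(old))
  pr <- predict(x, lineage = lineage, genes = genes)
  for (i in seq_along(genes)) {
    j <- genes[i]
    graphics::plot(x$data$unspliced[, j] + stats::runif(nrow(x$posterior), -.2, .2),
                   x$data$spliced[, j] + stats::runif(nrow(x$posterior), -.2, .2),
                   pch = 16, cex = 0.3, col = "grey70",
                   xlab = "unspliced", ylab = "spliced",
                   main = paste("gene", j))
    graphics::lines(pr$lambda_u[i, ], pr$lambda_s[i, ], col = "blue3",
                    lwd = 2)
  }
  invisible(x)
}
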
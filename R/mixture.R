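# Poisson mixtures (steady-state cluster) model, fitted by EM. Each
# component s is a steady state: unspliced mean a_js, spliced mean
# a_js * rho_j, both scaled by the cell's read depth. Only the ratios
# a = alpha/beta and rho = beta/gamma are identifiable at steady state;
# rho is shared across components per gene.

mixture_loglik_grid <- function(data, a, rho, constants = NULL) {
  if (is.null(constants)) constants <- loglik_constants(data)
  lam_u <- a                       # p x S
  lam_s <- a * rho
  tot <- colSums(lam_u) + colSums(lam_s)
  ll <- data$unspliced %*% safe_log(lam_u) +
    data$spliced %*% safe_log(lam_s)
  ll - outer(data$read_depth, tot) + constants
}

mixture_em <- function(data, n_components, resp, max_iter, tol) {
  n <- nrow(data$unspliced); p <- ncol(data$unspliced)
  r <- data$read_depth
  constants <- loglik_constants(data)
  xs_tot <- colSums(data$spliced)
  xu_tot <- colSums(data$unspliced)
  rho <- xs_tot / pmax(xu_tot, 0.5)  # exact M-step: rho_j = sum_s Xs / sum_s Xu
  loglik <- -Inf
  trace <- numeric(0)
  reinit_done <- rep(FALSE, n_components)
  warned <- FALSE
  for (it in seq_len(max_iter)) {
    # M-step (closed form)
    w <- colMeans(resp)
    empty <- w < 1e-8
    if (any(empty & !reinit_done)) {
      # one-shot reinitialization of empty components on random cells
      for (s in which(empty & !reinit_done)) {
        i <- sample.int(n, 1L)
        resp[i, ] <- 0; resp[i, s] <- 1
        reinit_done[s] <- TRUE
      }
      w <- colMeans(resp)
    } else if (any(empty) && !warned) {
      warning("empty mixture component left at zero weight")
      warned <- TRUE
    }
    Rs <- as.vector(crossprod(resp, r))               # S
    XUs <- crossprod(data$unspliced, resp)            # p x S
    XSs <- crossprod(data$spliced, resp)
    a <- sweep(XUs + XSs, 2L, Rs, "/") / (1 + rho)
    a <- pmax(a, 1e-10)
    # E-step
    ll <- mixture_loglik_grid(data, a, rho, constants)
    lw <- sweep(ll, 2L, safe_log(w), "+")
    mx <- lw[cbind(seq_len(n), max.col(lw, ties.method = "first"))]
    e <- exp(lw - mx)
    se <- rowSums(e)
    resp <- e / se
    loglik_new <- sum(mx + log(se))
    trace <- c(trace, loglik_new)
    if (is.finite(loglik) && loglik_new - loglik < tol * abs(loglik_new))
      { loglik <- loglik_new; break }
    loglik <- loglik_new
  }
  # w is the weight vector the final E-step (and loglik) used, so the
  # gene-wise decomposition of the ELBO is exact
  list(a = a, rho = rho, weights = w, posterior = resp,
       loglik = loglik, trace = trace)
}

#' Fit a Poisson mixture (steady-state cluster) model
#'
#' EM for a mixture of per-gene product-Poisson steady states,
#' \eqn{p(x_i) = \sum_s w_s \prod_j Pois(x_{ij1}; r_i a_{js})
#' Pois(x_{ij2}; r_i a_{js} \rho_j)}. The M-step is exact
#' (\eqn{\rho_j} has the closed form total-spliced / total-unspliced).
#' Initialization combines a k-means partition of log1p spliced counts with
#' random hard assignments across restarts; the restart with the best final
#' log-likelihood is returned.
#'
#' @param data a \code{\link{count_dataset}} with read depth attached.
#' @param n_components number of mixture components (>= 1).
#' @param n_restarts random restarts (the first uses k-means).
#' @param max_iter EM iteration cap per restart.
#' @param tol relative convergence tolerance.
#' @param seed integer seed.
#' @return an object of class \code{"pmix_fit"}: \code{a} (p x S),
#'   \code{rho} (p), \code{weights}, \code{posterior} (n x S),
#'   \code{loglik}, \code{n_parameters}, \code{restart_logliks}.
#' @export
fit_poisson_mixture <- function(data, n_components, n_restarts = 10L,
                                max_iter = 200L, tol = 1e-8, seed = 1L) {
  stopifnot(n_components >= 1L)
  n <- nrow(data$unspliced)
  set.seed(seed)
  best <- NULL
  logliks <- numeric(n_restarts)
  for (rs in seq_len(n_restarts)) {
    assign_ <- if (n_components > 1L) {
      km <- try(suppressWarnings(
        stats::kmeans(log1p(data$spliced / data$read_depth),
                      centers = n_components, nstart = 1L)), silent = TRUE)
      if (inherits(km, "try-error"))
        sample.int(n_components, n, replace = TRUE) else km$cluster
    } else rep(1L, n)
    resp <- matrix(0, n, n_components)
    resp[cbind(seq_len(n), assign_)] <- 1
    res <- mixture_em(data, n_components, resp, max_iter, tol)
    logliks[rs] <- res$loglik
    if (is.null(best) || res$loglik > best$loglik + 1e-9) best <- res
  }
  p <- ncol(data$unspliced)
  structure(
    list(a = best$a, rho = best$rho, weights = best$weights,
         posterior = best$posterior, loglik = best$loglik,
         trace = best$trace, n_components = n_components,
         restart_logliks = logliks, data = data,
         n_parameters = p * (n_components + 1L) + (n_components - 1L)),
    class = "pmix_fit")
}

#' Per-gene likelihood decomposition of a mixture fit
#'
#' Splits the mixture ELBO into per-gene scores: each gene gets an equal
#' 1/p share of the latent-variable (prior/entropy) term plus its own
#' conditional term \eqn{\sum_i \sum_s q_i(s) \log p(x_{ij} | s)}.
#' The scores sum exactly to the mixture ELBO; they are the cluster-model
#' reference in relative gene selection.
#'
#' @param fit a \code{"pmix_fit"}.
#' @param data the \code{\link{count_dataset}} the fit was computed on
#'   (defaults to the one stored in the fit).
#' @return a numeric vector of per-gene scores.
#' @export
mixture_gene_likelihood <- function(fit, data = fit$data) {
  q <- fit$posterior
  n <- nrow(q); p <- ncol(data$unspliced)
  r <- data$read_depth
  prior_term <- sum(q * (matrix(safe_log(fit$weights), n,
                                fit$n_components, byrow = TRUE) -
                           safe_log(q)), na.rm = FALSE)
  lam_u <- fit$a; lam_s <- fit$a * fit$rho
  # per-gene conditional: sum_s [XU_js log lam_u + XS_js log lam_s
  #   - R_s (lam_u + lam_s)] + count-dependent offsets
  Rs <- as.vector(crossprod(q, r))
  XUs <- crossprod(data$unspliced, q)
  XSs <- crossprod(data$spliced, q)
  cond <- rowSums(XUs * safe_log(lam_u) + XSs * safe_log(lam_s)) -
    as.vector((lam_u + lam_s) %*% Rs)
  logr <- log(r)
  cond <- cond + as.vector(crossprod(data$unspliced, logr)) +
    as.vector(crossprod(data$spliced, logr)) -
    colSums(lgamma(data$unspliced + 1)) - colSums(lgamma(data$spliced + 1))
  prior_term / p + cond
}

#' @export
print.pmix_fit <- function(x, ...) {
  cat(sprintf("Poisson mixture fit: %d components, %d genes, logLik %.2f\n",
              x$n_components, nrow(x$a), x$loglik))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.pmix_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_parameters,
            nobs = nrow(object$posterior), class = "logLik")
}
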
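# Readers and writers for count data (Matrix Market pairs with barcode and
# feature tables) and for fit results.

#' Load an unspliced/spliced count pair from Matrix Market files
#'
#' Expects a directory (or explicit paths) containing
#' \code{unspliced.mtx}, \code{spliced.mtx}, \code{barcodes.tsv} and
#' \code{features.tsv}. Both cells x genes and genes x cells matrices are
#' accepted; orientation is disambiguated by matching dimensions against
#' the barcode/feature table lengths, and ambiguous inputs (square with
#' equal identifier counts that disagree) are an error, never a guess.
#'
#' @param path directory containing the four files, or a named list with
#'   elements \code{unspliced}, \code{spliced}, \code{barcodes},
#'   \code{features}.
#' @return a list: \code{data} (a \code{\link{count_dataset}}),
#'   \code{gene_ids}, \code{cell_barcodes}, \code{provenance}.
#' @export
load_counts <- function(path) {
  files <- if (is.list(path)) path else list(
    unspliced = file.path(path, "unspliced.mtx"),
    spliced = file.path(path, "spliced.mtx"),
    barcodes = file.path(path, "barcodes.tsv"),
    features = file.path(path, "features.tsv"))
  for (f in unlist(files)) if (!file.exists(f)) stop("missing file: ", f)
  barcodes <- readLines(files$barcodes)
  features <- readLines(files$features)
  orient <- function(m, which) {
    m <- as.matrix(m)
    if (nrow(m) == length(barcodes) && ncol(m) == length(features)) return(m)
    if (nrow(m) == length(features) && ncol(m) == length(barcodes))
      return(t(m))
    stop(sprintf(
      "%s matrix is %d x %d but there are %d barcodes and %d features",
      which, nrow(m), ncol(m), length(barcodes), length(features)))
  }
  U <- orient(Matrix::readMM(files$unspliced), "unspliced")
  S <- orient(Matrix::readMM(files$spliced), "spliced")
  if (any(U != round(U)) || any(S != round(S)))
    stop("non-integer entries in count matrices")
  list(data = count_dataset(U, S),
       gene_ids = features, cell_barcodes = barcodes,
       provenance = list(files = files, format = "mtx_pair"))
}

#' Write an unspliced/spliced count pair as Matrix Market files
#'
#' @param data a \code{\link{count_dataset}}.
#' @param path output directory (created if needed).
#' @param gene_ids,cell_barcodes identifier vectors; generated when NULL.
#' @return the directory path, invisibly.
#' @export
write_counts <- function(data, path, gene_ids = NULL, cell_barcodes = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(data$unspliced); p <- ncol(data$unspliced)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(p))
  if (is.null(cell_barcodes)) cell_barcodes <- paste0("cell", seq_len(n))
  Matrix::writeMM(Matrix::Matrix(data$unspliced, sparse = TRUE),
                  file.path(path, "unspliced.mtx"))
  Matrix::writeMM(Matrix::Matrix(data$spliced, sparse = TRUE),
                  file.path(path, "spliced.mtx"))
  writeLines(cell_barcodes, file.path(path, "barcodes.tsv"))
  writeLines(gene_ids, file.path(path, "features.tsv"))
  invisible(path)
}

#' Serialize a fit to a JSON/TSV bundle
#'
#' Writes the kinetics table (genes x parameters TSV), the prior, the
#' ELBO trace, the restart table, the per-cell posterior summaries, and a
#' configuration echo into a directory.
#'
#' @param fit a \code{"traj_fit"}.
#' @param path output directory.
#' @return the directory path, invisibly.
#' @export
write_fit <- function(fit, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  kin <- fit$kinetics
  ktab <- data.frame(gene = seq_len(nrow(kin$alpha)))
  for (s in seq_len(ncol(kin$alpha)))
    ktab[[paste0("alpha_", s - 1L)]] <- kin$alpha[, s]
  ktab$beta <- kin$beta
  ktab$gamma <- kin$gamma
  if (is.matrix(kin$tau))
    for (k in seq_len(ncol(kin$tau)))
      ktab[[paste0("tau_", k - 1L)]] <- kin$tau[, k]
  utils::write.table(ktab, file.path(path, "kinetics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cells <- data.frame(cell = seq_len(nrow(fit$posterior)),
                      mean_time = mean_process_time(fit),
                      map_lineage = map_lineage(fit))
  utils::write.table(cells, file.path(path, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(fit$restart_table, file.path(path, "restarts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    elbo = fit$elbo, mode = fit$mode, n_parameters = fit$n_parameters,
    converged = fit$converged, elbo_trace = fit$elbo_trace,
    tau = if (is.matrix(kin$tau)) colMeans(kin$tau) else kin$tau,
    structure = fit$structure$paths,
    prior = list(M = fit$prior$M,
                 lineage_weights = fit$prior$lineage_weights,
                 t0_mass = fit$prior$t0_mass),
    config = fit$config[c("n_restarts", "n_iterations", "grid_M",
                          "t0_mass", "update_prior", "desync_penalty",
                          "seed")])
  jsonlite::write_json(meta, file.path(path, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
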
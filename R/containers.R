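#' Construct a cell-by-gene count matrix
#'
#' The universal input container: a sparse non-negative integer matrix of
#' unique-molecule counts with cells in rows and genes in columns, plus an
#' optional per-gene annotation table used by the QC filters and the CNV
#' module.
#'
#' @param counts A matrix or sparse Matrix of non-negative counts,
#'   cells x genes. Dimnames are used as cell/gene identifiers when
#'   `cell_ids`/`gene_ids` are not given.
#' @param cell_ids,gene_ids Character vectors of unique identifiers.
#' @param gene_meta Optional data frame with one row per gene and columns
#'   `gene_id`, and any of `chromosome`, `start`, `is_mito`, `is_ribo`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`), and `gene_meta` (a tibble or `NULL`).
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), gene_meta = NULL) {
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  stopifnot(length(cell_ids) == nrow(counts), length(gene_ids) == ncol(counts))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (any(m@x < 0)) stop("counts must be non-negative")
  dimnames(m) <- list(cell_ids, gene_ids)
  if (!is.null(gene_meta)) {
    gene_meta <- tibble::as_tibble(gene_meta)
    stopifnot("gene_id" %in% names(gene_meta))
    gene_meta <- gene_meta[match(gene_ids, gene_meta$gene_id), , drop = FALSE]
    if (anyNA(gene_meta$gene_id)) stop("gene_meta does not cover all gene ids")
  }
  structure(list(counts = m, gene_meta = gene_meta), class = "count_matrix")
}

#' Construct a spot-by-gene spatial count matrix
#'
#' As [count_matrix()], over capture spots, with per-spot grid coordinates and
#' an optional anatomical layer label.
#'
#' @inheritParams count_matrix
#' @param coords Data frame with columns `spot_id`, `x`, `y` and optionally
#'   `layer`; one row per spot.
#' @return An object of class `spot_matrix` (inherits `count_matrix`) with an
#'   extra `coords` tibble.
#' @export
spot_matrix <- function(counts, coords, cell_ids = rownames(counts),
                        gene_ids = colnames(counts), gene_meta = NULL) {
  obj <- count_matrix(counts, cell_ids, gene_ids, gene_meta)
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("spot_id", "x", "y") %in% names(coords)))
  coords <- coords[match(rownames(obj$counts), coords$spot_id), , drop = FALSE]
  if (anyNA(coords$spot_id)) stop("coords does not cover all spot ids")
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y)))
    stop("spot coordinates must be finite")
  obj$coords <- coords
  class(obj) <- c("spot_matrix", "count_matrix")
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d %s x %d genes, %d non-zero entries\n",
              class(x)[1], nrow(x$counts),
              if (inherits(x, "spot_matrix")) "spots" else "cells",
              ncol(x$counts), length(x$counts@x)))
  if (!is.null(x$gene_meta))
    cat("  gene_meta:", paste(setdiff(names(x$gene_meta), "gene_id"),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

cell_ids <- function(x) rownames(x$counts)
gene_ids <- function(x) colnames(x$counts)

#' Identify mitochondrial and ribosomal genes by name prefix
#'
#' Fills (or creates) the `is_mito`/`is_ribo` columns of a count matrix's gene
#' annotation from configurable name prefixes. Matching is case-sensitive on
#' the supplied prefixes.
#'
#' @param m A `count_matrix`.
#' @param mito_prefix,ribo_prefix Character vectors of gene-name prefixes.
#' @return `m` with a populated `gene_meta`.
#' @export
annotate_gene_flags <- function(m, mito_prefix = c("mt-", "MT-"),
                                ribo_prefix = c("Rps", "Rpl", "RPS", "RPL")) {
  ids <- gene_ids(m)
  has_prefix <- function(prefixes) {
    Reduce(`|`, lapply(prefixes, function(p) startsWith(ids, p)))
  }
  if (is.null(m$gene_meta)) m$gene_meta <- tibble::tibble(gene_id = ids)
  m$gene_meta$is_mito <- has_prefix(mito_prefix)
  m$gene_meta$is_ribo <- has_prefix(ribo_prefix)
  m
}
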
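#' Quality-control filter for single cells
#'
#' Retains cells with strictly more than `min_genes` detected genes and a
#' mitochondrial count fraction strictly below `max_mito_frac`. Fractions are
#' computed on the raw counts *before* any gene removal; mitochondrial and
#' ribosomal gene columns are dropped afterwards when `drop_mito_ribo` is set.
#'
#' @param m A `count_matrix` with `is_mito` (and, if `drop_mito_ribo`,
#'   `is_ribo`) flags in its `gene_meta`; see [annotate_gene_flags()].
#' @param min_genes Cells must detect more than this many genes (strict `>`).
#' @param max_mito_frac Cells must have a mito fraction below this (strict `<`).
#' @param drop_mito_ribo Remove mito/ribo gene columns after filtering.
#' @return The filtered `count_matrix`, with a `filter_report` attribute
#'   (tibble of removal counts per rule).
#' @export
filter_cells_qc <- function(m, min_genes = 500, max_mito_frac = 0.10,
                            drop_mito_ribo = TRUE) {
  if (is.null(m$gene_meta) || is.null(m$gene_meta$is_mito))
    stop("gene_meta with an is_mito flag is required; see annotate_gene_flags()")
  counts <- m$counts
  detected <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito_frac <- as.numeric(Matrix::rowSums(counts[, m$gene_meta$is_mito, drop = FALSE])) / pmax(total, 1)
  keep_genes_rule <- detected > min_genes
  keep_mito_rule <- mito_frac < max_mito_frac
  keep <- keep_genes_rule & keep_mito_rule
  report <- tibble::tibble(
    rule = c(sprintf("detected genes > %d", min_genes),
             sprintf("mito fraction < %g", max_mito_frac),
             "cells retained"),
    n = c(sum(!keep_genes_rule), sum(!keep_mito_rule), sum(keep))
  )
  if (!any(keep))
    stop("no cells pass QC (", sum(!keep_genes_rule), " fail the gene rule, ",
         sum(!keep_mito_rule), " fail the mito rule)")
  out <- m
  out$counts <- counts[keep, , drop = FALSE]
  if (drop_mito_ribo) {
    if (is.null(m$gene_meta$is_ribo))
      stop("drop_mito_ribo = TRUE requires an is_ribo flag in gene_meta")
    gkeep <- !(m$gene_meta$is_mito | m$gene_meta$is_ribo)
    out$counts <- out$counts[, gkeep, drop = FALSE]
    out$gene_meta <- m$gene_meta[gkeep, , drop = FALSE]
  }
  attr(out, "filter_report") <- report
  out
}

#' Quality-control filter for spatial spots
#'
#' Excludes spots detecting fewer than `min_genes` genes or with a
#' mitochondrial fraction over `max_mito_frac`, then removes genes expressed
#' in fewer than `min_spots_per_gene` of the *retained* spots (spots first,
#' then genes).
#'
#' @param m A `spot_matrix`.
#' @param min_genes Spots with fewer detected genes than this are removed
#'   (strict `<`, i.e. a spot with exactly `min_genes` is kept).
#' @param min_spots_per_gene Genes detected in fewer spots than this are
#'   removed (strict `<`).
#' @param max_mito_frac Spots with a mito fraction over this are removed; when
#'   `gene_meta` carries no mito flag the rule is skipped.
#' @return The filtered `spot_matrix` with a `filter_report` attribute.
#' @export
filter_spots_qc <- function(m, min_genes = 500, min_spots_per_gene = 15,
                            max_mito_frac = 0.10) {
  counts <- m$counts
  detected <- Matrix::rowSums(counts > 0)
  keep_spots <- detected >= min_genes
  mito_fail <- rep(FALSE, nrow(counts))
  if (!is.null(m$gene_meta) && !is.null(m$gene_meta$is_mito)) {
    total <- Matrix::rowSums(counts)
    mito_frac <- as.numeric(Matrix::rowSums(counts[, m$gene_meta$is_mito, drop = FALSE])) / pmax(total, 1)
    mito_fail <- mito_frac > max_mito_frac
    keep_spots <- keep_spots & !mito_fail
  }
  if (!any(keep_spots)) stop("no spots pass QC")
  sub <- counts[keep_spots, , drop = FALSE]
  keep_genes <- Matrix::colSums(sub > 0) >= min_spots_per_gene
  out <- m
  out$counts <- sub[, keep_genes, drop = FALSE]
  if (!is.null(m$gene_meta)) out$gene_meta <- m$gene_meta[keep_genes, , drop = FALSE]
  out$coords <- m$coords[keep_spots, , drop = FALSE]
  attr(out, "filter_report") <- tibble::tibble(
    rule = c(sprintf("spots with < %d genes", min_genes),
             sprintf("spots with mito fraction > %g", max_mito_frac),
             sprintf("genes in < %d spots", min_spots_per_gene),
             "spots retained", "genes retained"),
    n = c(sum(detected < min_genes), sum(mito_fail), sum(!keep_genes),
          sum(keep_spots), sum(keep_genes))
  )
  out
}

#' Library-size log-normalization
#'
#' Scales each cell (row) to `scale` total counts and applies `log1p`:
#' entry = ln(1 + count * scale / rowtotal). Zero counts map to zero exactly,
#' so the sparsity pattern is preserved.
#'
#' @param m A `count_matrix`/`spot_matrix`, or a bare (sparse) matrix of
#'   counts with cells in rows.
#' @param scale Scale factor (default 10,000).
#' @return A sparse `dgCMatrix` of normalized values, cells x genes, with an
#'   attribute `scale`.
#' @export
lognormalize <- function(m, scale = 1e4) {
  counts <- if (inherits(m, "count_matrix")) m$counts else
    methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  total <- Matrix::rowSums(counts)
  if (any(total == 0))
    stop("all-zero rows: ", paste(utils::head(rownames(counts)[total == 0], 5), collapse = ", "))
  x <- counts
  # operate on the sparse slots directly; j index from column pointers
  row_of <- x@i + 1L
  x@x <- log1p(x@x * scale / total[row_of])
  attr(x, "scale") <- scale
  x
}
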
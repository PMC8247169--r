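#' Moving-average copy-number inference
#'
#' Infers large-scale chromosomal copy-number signal per cell from smoothed
#' expression: genes are ordered by (chromosome, start); per-gene relative
#' expression (value minus the dataset gene mean) is clipped to `+/- clip`;
#' a centered moving average of `window` genes is taken within each
#' chromosome (symmetric window, shrunk at chromosome edges, never crossing
#' chromosomes); each cell is centered by its own mean; finally the
#' reference cells' per-window mean is subtracted from all cells, so the
#' reference averages exactly zero per window.
#'
#' @param x Normalized expression, cells x genes.
#' @param gene_meta Data frame with `gene_id`, `chromosome`, `start`;
#'   must cover at least 80% of the genes in `x` (uncovered genes are
#'   dropped). Chromosomes with fewer than 5 genes are excluded with a
#'   message.
#' @param reference_cells Cell ids of the "normal" reference set.
#' @param window Moving-average length in genes.
#' @param clip Symmetric clip on relative expression before smoothing.
#' @param min_mean Genes with dataset-mean normalized expression below this
#'   are excluded before smoothing (the reference tool's expression cutoff);
#'   near-silent genes otherwise dominate the window noise.
#' @return An object of class `cnv_matrix`: list with `scores`
#'   (cells x windows), `windows` (tibble: window, gene_id, chromosome,
#'   start), `reference_cells`, and `aggregate` (tibble: cell_id, cnv_signal
#'   = mean squared window score, reference flag).
#' @export
infer_cnv <- function(x, gene_meta, reference_cells, window = 101, clip = 3,
                      min_mean = 0.1) {
  stopifnot(length(reference_cells) > 0)
  if (!all(reference_cells %in% rownames(x)))
    stop("reference cells missing from the matrix")
  gm <- tibble::as_tibble(gene_meta)
  gm <- gm[gm$gene_id %in% colnames(x), , drop = FALSE]
  if (nrow(gm) < 0.8 * ncol(x))
    stop("gene annotation covers under 80% of genes")
  gmeans <- Matrix::colMeans(x)
  gm <- gm[gmeans[gm$gene_id] >= min_mean, , drop = FALSE]
  if (!nrow(gm)) stop("no gene passes the expression cutoff")
  chr_sizes <- table(gm$chromosome)
  small <- names(chr_sizes)[chr_sizes < 5]
  if (length(small)) {
    message("excluding chromosome(s) with < 5 genes: ", paste(small, collapse = ", "))
    gm <- gm[!gm$chromosome %in% small, , drop = FALSE]
  }
  gm <- gm[order(gm$chromosome, gm$start), ]
  xd <- as.matrix(x[, gm$gene_id, drop = FALSE])
  rel <- sweep(xd, 2, colMeans(xd))
  rel[rel > clip] <- clip
  rel[rel < -clip] <- -clip
  # per-chromosome smoothing matrix with shrunk symmetric windows
  half <- (window - 1) %/% 2
  blocks <- split(seq_len(nrow(gm)), gm$chromosome)
  trip <- lapply(blocks, function(ix) {
    nc <- length(ix)
    per_pos <- lapply(seq_len(nc), function(pos) {
      # clamped window: near chromosome edges the window stays full-length
      # (asymmetric) rather than shrinking, so edge windows keep the same
      # noise damping as interior ones
      cols <- ix[max(1, pos - half):min(nc, pos + half)]
      cbind(i = rep(ix[pos], length(cols)), j = cols, x = 1 / length(cols))
    })
    do.call(rbind, per_pos)
  })
  trip <- do.call(rbind, trip)
  sm <- Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "x"],
                             dims = c(nrow(gm), nrow(gm)))
  smoothed <- as.matrix(Matrix::tcrossprod(rel, sm))  # cells x windows
  smoothed <- smoothed - rowMeans(smoothed)           # per-cell centering
  ref_mean <- colMeans(smoothed[reference_cells, , drop = FALSE])
  scores <- sweep(smoothed, 2, ref_mean)
  windows <- tibble::tibble(window = seq_len(nrow(gm)), gene_id = gm$gene_id,
                            chromosome = gm$chromosome, start = gm$start)
  colnames(scores) <- gm$gene_id
  aggregate <- tibble::tibble(
    cell_id = rownames(scores),
    cnv_signal = rowMeans(scores^2),
    reference = rownames(scores) %in% reference_cells
  )
  structure(list(scores = scores, windows = windows,
                 reference_cells = reference_cells, aggregate = aggregate),
            class = "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("<cnv_matrix> %d cells x %d windows over %d chromosomes\n",
              nrow(x$scores), nrow(x$windows),
              length(unique(x$windows$chromosome))))
  invisible(x)
}

#' Per-chromosome mean CNV score by cell group
#'
#' @param cnv A `cnv_matrix`.
#' @param groups Named vector or tibble (`cell_id`, `group`) of cell labels.
#' @return Tibble: group, chromosome, mean_score.
#' @export
cnv_by_chromosome <- function(cnv, groups) {
  if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$cell_id)
  groups <- groups[rownames(cnv$scores)]
  chr <- factor(cnv$windows$chromosome, unique(cnv$windows$chromosome))
  rows <- lapply(levels(chr), function(ch) {
    sub <- cnv$scores[, chr == ch, drop = FALSE]
    tibble::tibble(group = names(tapply(rowMeans(sub), groups, mean)),
                   chromosome = ch,
                   mean_score = as.numeric(tapply(rowMeans(sub), groups, mean)))
  })
  dplyr::bind_rows(rows)
}
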
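#' Score cells for a gene signature with bin-matched controls
#'
#' Evaluates the degree to which each cell expresses a pre-defined program.
#' Genes are ranked by their dataset-mean expression into `n_bins`
#' equal-frequency bins; for each signature gene, `n_ctrl` control genes are
#' drawn (seeded, without replacement, signature genes excluded) from the
#' same bin; the score of a cell is the mean over signature genes minus the
#' mean over the pooled control genes. This bin-matching removes the
#' expression-level component a naive mean would carry.
#'
#' @param x Normalized expression ([lognormalize()] output), cells x genes.
#' @param genes Character vector of signature gene ids (genes absent from `x`
#'   are dropped with a warning).
#' @param n_bins Number of equal-frequency expression bins.
#' @param n_ctrl Control genes drawn per signature gene; when a bin holds
#'   fewer eligible genes, sampling falls back to with-replacement with a
#'   warning.
#' @param seed Integer seed for the control draw.
#' @return A numeric vector of per-cell scores, named by cell id.
#' @export
score_signature <- function(x, genes, n_bins = 24, n_ctrl = 100, seed = 1) {
  present <- intersect(genes, colnames(x))
  if (!length(present)) stop("no signature gene present in the matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " signature gene(s) absent, dropped")
  gmeans <- Matrix::colMeans(x)
  bins <- dplyr::ntile(rank(gmeans, ties.method = "first"), n_bins)
  names(bins) <- colnames(x)
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(present, function(gn) {
      pool <- names(bins)[bins == bins[[gn]]]
      pool <- setdiff(pool, genes)
      if (length(pool) >= n_ctrl) {
        sample(pool, n_ctrl)
      } else {
        message("bin of ", gn, " holds only ", length(pool),
                " eligible control genes; sampling with replacement")
        sample(pool, n_ctrl, replace = TRUE)
      }
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::rowMeans(x[, present, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(x[, ctrl, drop = FALSE])
  out <- as.numeric(sig_mean - ctrl_mean)
  names(out) <- rownames(x)
  out
}

#' Score cells for several signatures at once
#'
#' @inheritParams score_signature
#' @param signatures Named list of gene id vectors (e.g. from [read_gmt()] or
#'   [truth_signatures()]).
#' @return A tibble with `cell_id` and one score column per signature.
#' @export
score_signatures <- function(x, signatures, n_bins = 24, n_ctrl = 100, seed = 1) {
  stopifnot(length(signatures) >= 1, !is.null(names(signatures)))
  scores <- lapply(seq_along(signatures), function(i) {
    score_signature(x, signatures[[i]], n_bins, n_ctrl, seed = seed + i - 1L)
  })
  names(scores) <- names(signatures)
  tibble::tibble(cell_id = rownames(x), !!!scores)
}

#' Cell-cycle scoring
#'
#' Scores the G1/S and G2/M programs independently with
#' [score_signature()]; the combined cycle score is the maximum of the two.
#' The packaged default lists (43 G1/S and 54 G2/M genes) are available via
#' [default_cell_cycle_genes()].
#'
#' @inheritParams score_signature
#' @param g1s,g2m Gene id vectors for the two phases.
#' @return A tibble with `cell_id`, `g1s_score`, `g2m_score`, `cycle_score`.
#' @export
score_cell_cycle <- function(x, g1s, g2m, n_bins = 24, n_ctrl = 100, seed = 1) {
  s1 <- score_signature(x, g1s, n_bins, n_ctrl, seed = seed)
  s2 <- score_signature(x, g2m, n_bins, n_ctrl, seed = seed + 1L)
  tibble::tibble(cell_id = rownames(x), g1s_score = s1, g2m_score = s2,
                 cycle_score = pmax(s1, s2))
}

#' Packaged G1/S and G2/M cell-cycle gene lists
#'
#' The canonical 43 G1/S and 54 G2/M cycle genes (mouse-cased), shipped as a
#' GMT fixture.
#'
#' @return A list with elements `g1s` (43 genes) and `g2m` (54 genes).
#' @export
default_cell_cycle_genes <- function() {
  sets <- read_gmt(system.file("extdata", "cell_cycle_mouse.gmt",
                               package = "gnstates", mustWork = TRUE))
  list(g1s = sets[["G1S"]], g2m = sets[["G2M"]])
}

#' Assign each cell to the state with the maximum score
#'
#' @param scores A data frame with `cell_id` and one numeric score column per
#'   candidate state (e.g. from [score_signatures()]).
#' @return A tibble with `cell_id`, `state` (the argmax column name),
#'   `score` (the winning score), and `tie` (TRUE when the maximum is shared;
#'   ties break to the first column in order).
#' @export
assign_state_by_max <- function(scores) {
  stopifnot("cell_id" %in% names(scores))
  mat <- as.matrix(scores[setdiff(names(scores), "cell_id")])
  if (ncol(mat) < 2) stop("need at least two signature columns")
  if (anyNA(mat))
    stop("NaN/NA score for cell(s): ",
         paste(utils::head(scores$cell_id[rowSums(is.na(mat)) > 0], 5), collapse = ", "))
  win <- max.col(mat, ties.method = "first")
  best <- mat[cbind(seq_len(nrow(mat)), win)]
  tie <- rowSums(mat == best) > 1
  tibble::tibble(cell_id = scores$cell_id, state = colnames(mat)[win],
                 score = best, tie = tie)
}

#' Binarize per-cell values at k MADs above the median
#'
#' Positive iff value > median + k * MAD, with the unscaled MAD
#' (median absolute deviation without a consistency constant). Used to call
#' cycling vs non-cycling cells from cycle scores.
#'
#' @param values Numeric vector (length >= 2).
#' @param k Number of MADs above the median.
#' @return A logical vector with a `threshold` attribute.
#' @export
binarize_by_mad <- function(values, k = 2) {
  stopifnot(length(values) >= 2)
  med <- stats::median(values)
  mad_u <- stats::median(abs(values - med))
  if (mad_u == 0) warning("MAD is zero; no value exceeds the threshold")
  thr <- med + k * mad_u
  structure(values > thr, threshold = thr)
}
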
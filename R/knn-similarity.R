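#' kNN-regression similarity of query cells to reference lineages
#'
#' Projects query (e.g. tumor) and reference (developmental) cells into a
#' shared principal-component space — loadings are computed on the
#' concatenated matrix after centering each dataset per gene separately, over
#' the common genes — then lets each query cell's `k` nearest reference
#' cells vote with one-hot label vectors. Per-cell scores are averaged label
#' votes (rows sum to 1); per-sample means are reported alongside.
#'
#' @param query,reference Normalized expression matrices (cells x genes).
#' @param ref_labels Reference cell labels (vector aligned with the
#'   reference rows, or tibble `cell_id`, `label`).
#' @param k Neighbours (default 20).
#' @param n_pcs Shared principal components (default 30).
#' @param query_samples Optional sample label per query cell for the
#'   per-sample summary.
#' @return A list with `cell_scores` (tibble: cell_id, one column per label)
#'   and `sample_scores` (tibble: sample, label, mean_score).
#' @export
knn_similarity <- function(query, reference, ref_labels, k = 20, n_pcs = 30,
                           query_samples = NULL) {
  if (is.data.frame(ref_labels))
    ref_labels <- stats::setNames(ref_labels$label, ref_labels$cell_id)[rownames(reference)]
  ref_labels <- as.character(ref_labels)
  stopifnot(length(ref_labels) == nrow(reference))
  if (k > nrow(reference)) stop("k exceeds the reference size")
  common <- intersect(colnames(query), colnames(reference))
  if (length(common) < 200) stop("fewer than 200 shared genes")
  q <- as.matrix(query[, common, drop = FALSE])
  r <- as.matrix(reference[, common, drop = FALSE])
  q <- sweep(q, 2, colMeans(q))
  r <- sweep(r, 2, colMeans(r))
  joint <- rbind(q, r)
  n_pcs <- min(n_pcs, nrow(joint) - 1, ncol(joint))
  sv <- svd(joint, nu = 0, nv = n_pcs)
  emb <- joint %*% sv$v
  qe <- emb[seq_len(nrow(q)), , drop = FALSE]
  re <- emb[nrow(q) + seq_len(nrow(r)), , drop = FALSE]
  d2 <- sq_dist(qe, re)
  labels <- sort(unique(ref_labels))
  onehot <- outer(ref_labels, labels, `==`) * 1
  votes <- vapply(seq_len(nrow(d2)), function(i) {
    colMeans(onehot[order(d2[i, ])[seq_len(k)], , drop = FALSE])
  }, numeric(length(labels)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  votes <- t(votes)
  colnames(votes) <- labels
  cell_scores <- tibble::tibble(cell_id = rownames(query),
                                !!!as.data.frame(votes))
  sample_scores <- NULL
  if (!is.null(query_samples)) {
    sample_scores <- cell_scores |>
      dplyr::mutate(sample = query_samples) |>
      tidyr::pivot_longer(dplyr::all_of(labels), names_to = "label",
                          values_to = "score") |>
      dplyr::group_by(.data$sample, .data$label) |>
      dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
  }
  list(cell_scores = cell_scores, sample_scores = sample_scores)
}
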
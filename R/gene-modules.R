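#' Build a symmetric kNN graph from an embedding
#'
#' Euclidean k-nearest-neighbour graph over cells in a user-supplied
#' low-dimensional embedding (any coordinates: PCA, UMAP, t-SNE), symmetrized
#' by union, binary weights, no self-edges.
#'
#' @param embedding Numeric matrix, cells x dimensions, with cell ids as row
#'   names.
#' @param k Neighbours per cell.
#' @return An object of class `knn_graph`: list with the sparse symmetric
#'   binary weight matrix `w`, the raw neighbour index matrix `nn`
#'   (cells x k), and `k`.
#' @export
knn_graph <- function(embedding, k = 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stopifnot(k >= 1, k < n)
  d2 <- sq_dist(embedding, embedding)
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
  w <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(nn)),
                            x = 1, dims = c(n, n))
  w <- w + Matrix::t(w)  # union symmetrization, binary weights
  w <- methods::as(methods::as(w, "CsparseMatrix"), "generalMatrix")
  w@x <- rep(1, length(w@x))
  dimnames(w) <- list(rownames(embedding), rownames(embedding))
  structure(list(w = w, nn = nn, k = k), class = "knn_graph")
}

# squared Euclidean cross-distances, rows of a vs rows of b
sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

graph_constants <- function(w) {
  s0 <- sum(w)
  s1 <- sum((w + Matrix::t(w))^2) / 2
  rs <- Matrix::rowSums(w)
  cs <- Matrix::colSums(w)
  s2 <- sum((rs + cs)^2)
  list(s0 = s0, s1 = s1, s2 = s2)
}

#' Moran's I spatial autocorrelation over a cell graph
#'
#' Computes `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)`, and a one-sided (positive autocorrelation) P value
#' from the analytic normal approximation under the randomization
#' assumption; optionally a seeded permutation P value.
#'
#' @param x Numeric vector of per-cell values (one gene).
#' @param g A [knn_graph()] over the same cells.
#' @param permutations If > 0, also compute a permutation P value with this
#'   many label permutations.
#' @param seed Seed for the permutations.
#' @return A list with `i`, `expected`, `sd`, `p` (analytic; NA for n < 4),
#'   and `p_perm` when requested.
#' @export
morans_i <- function(x, g, permutations = 0, seed = 1) {
  w <- g$w
  n <- length(x)
  stopifnot(n == nrow(w), n >= 2)
  if (stats::var(x) == 0) stop("zero-variance input")
  z <- x - mean(x)
  gc <- graph_constants(w)
  i_of <- function(zv) (n / gc$s0) * sum(zv * as.numeric(w %*% zv)) / sum(zv^2)
  i_obs <- i_of(z)
  e_i <- -1 / (n - 1)
  p <- sd_i <- NA_real_
  if (n >= 4) {
    b2 <- n * sum(z^4) / sum(z^2)^2
    num <- n * ((n^2 - 3 * n + 3) * gc$s1 - n * gc$s2 + 3 * gc$s0^2) -
      b2 * ((n^2 - n) * gc$s1 - 2 * n * gc$s2 + 6 * gc$s0^2)
    var_i <- num / ((n - 1) * (n - 2) * (n - 3) * gc$s0^2) - e_i^2
    sd_i <- sqrt(pmax(var_i, 0))
    p <- stats::pnorm((i_obs - e_i) / sd_i, lower.tail = FALSE)
  }
  out <- list(i = i_obs, expected = e_i, sd = sd_i, p = p)
  if (permutations > 0) {
    perm <- withr::with_seed(seed, {
      vapply(seq_len(permutations), function(b) i_of(sample(z)), numeric(1))
    })
    out$p_perm <- (1 + sum(perm >= i_obs)) / (1 + permutations)
  }
  out
}

# Moran's I for all genes at once (analytic p only); zero-variance genes NA
morans_i_all <- function(x, g) {
  w <- g$w
  n <- nrow(x)
  gc <- graph_constants(w)
  xd <- as.matrix(x)
  z <- sweep(xd, 2, colMeans(xd))
  den <- colSums(z^2)
  ok <- den > 0
  wz <- as.matrix(w %*% z)
  i <- rep(NA_real_, ncol(xd))
  i[ok] <- (n / gc$s0) * colSums(z * wz)[ok] / den[ok]
  e_i <- -1 / (n - 1)
  b2 <- rep(NA_real_, ncol(xd))
  b2[ok] <- n * colSums(z^4)[ok] / den[ok]^2
  num <- n * ((n^2 - 3 * n + 3) * gc$s1 - n * gc$s2 + 3 * gc$s0^2) -
    b2 * ((n^2 - n) * gc$s1 - 2 * n * gc$s2 + 6 * gc$s0^2)
  var_i <- num / ((n - 1) * (n - 2) * (n - 3) * gc$s0^2) - e_i^2
  p <- stats::pnorm((i - e_i) / sqrt(pmax(var_i, 0)), lower.tail = FALSE)
  tibble::tibble(gene = colnames(xd), morans_i = i, p = p, tested = ok)
}

#' Discover gene modules by graph autocorrelation
#'
#' Computes Moran's I per gene over the cell kNN graph, keeps genes with
#' `I > i_min` and Benjamini-Hochberg `q < q_max`, and groups the passing
#' genes into modules by average-linkage hierarchical clustering of
#' `1 - Pearson r` between their cluster-averaged expression profiles, cut at
#' `cut_height`.
#'
#' @param x Normalized expression, cells x genes.
#' @param g A [knn_graph()] over the same cells.
#' @param i_min,q_max Moran's I and BH q-value thresholds.
#' @param clusters Cell cluster labels used to average gene profiles before
#'   correlating; when `NULL`, cells are clustered by k-means on the leading
#'   principal components of `x`.
#' @param n_clusters Number of k-means clusters when `clusters` is NULL.
#' @param cut_height Correlation-distance tree cut (1 - r).
#' @param seed Seed for the default clustering.
#' @return A `module_table` tibble: gene, morans_i, p, q, module (integer,
#'   decreasing size order); genes failing the thresholds are absent.
#'   Skipped zero-variance genes are recorded in attribute `skipped`.
#' @export
find_gene_modules <- function(x, g, i_min = 0.1, q_max = 0.05, clusters = NULL,
                              n_clusters = 8, cut_height = 0.7, seed = 1) {
  stopifnot(nrow(x) == nrow(g$w))
  mt <- morans_i_all(x, g)
  skipped <- mt$gene[!mt$tested]
  mt <- mt[mt$tested, ]
  mt$q <- stats::p.adjust(mt$p, method = "BH")
  pass <- mt$morans_i > i_min & mt$q < q_max
  if (!any(pass))
    stop("no gene passes (I quartiles: ",
         paste(signif(stats::quantile(mt$morans_i), 3), collapse = ", "), ")")
  kept <- mt[pass, ]
  if (is.null(clusters)) {
    clusters <- withr::with_seed(seed, {
      pcs <- prcomp_embedding(x, n_pcs = min(20, nrow(x) - 1, ncol(x) - 1))
      stats::kmeans(pcs, centers = min(n_clusters, nrow(x) - 1), nstart = 5)$cluster
    })
  }
  prof <- group_profiles(x[, kept$gene, drop = FALSE], clusters)  # cluster x gene
  if (nrow(kept) == 1) {
    kept$module <- 1L
  } else {
    cr <- suppressWarnings(stats::cor(prof))
    cr[is.na(cr)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cr), method = "average")
    cut <- stats::cutree(hc, h = cut_height)
    # renumber by decreasing module size
    sizes <- sort(table(cut), decreasing = TRUE)
    kept$module <- as.integer(match(cut, as.integer(names(sizes))))
  }
  out <- dplyr::arrange(kept[c("gene", "morans_i", "p", "q", "module")],
                        .data$module, dplyr::desc(.data$morans_i))
  class(out) <- c("module_table", class(out))
  attr(out, "skipped") <- skipped
  out
}

#' Representative genes per module
#'
#' Ranks each module's genes by dataset-mean normalized expression and keeps
#' the top `top_n`.
#'
#' @param mt A `module_table` from [find_gene_modules()].
#' @param x The normalized expression used to rank genes.
#' @param top_n Representatives per module.
#' @return Named list (`module_1`, ...) of ordered gene vectors.
#' @export
select_representatives <- function(mt, x, top_n = 50) {
  stopifnot(nrow(mt) > 0)
  gmeans <- Matrix::colMeans(x)
  mods <- split(mt$gene, mt$module)
  out <- lapply(mods, function(gs) {
    gs[order(gmeans[gs], decreasing = TRUE)][seq_len(min(top_n, length(gs)))]
  })
  names(out) <- paste0("module_", names(mods))
  out
}

#' Merge modules into main modules by score clustering
#'
#' Hierarchically clusters the per-cell module score vectors (Ward linkage on
#' Euclidean distance between standardized score profiles) and cuts the tree
#' at `n_main` main modules.
#'
#' @param scores Tibble from [score_signatures()] on the modules'
#'   representative gene lists (`cell_id` + one column per module).
#' @param n_main Number of main modules to cut at.
#' @return Tibble: module, main_module (integer).
#' @export
merge_to_main_modules <- function(scores, n_main = 4) {
  mods <- setdiff(names(scores), "cell_id")
  if (n_main > length(mods)) stop("requested more main modules than modules")
  m <- scale(as.matrix(scores[mods]))  # cells x modules, standardized
  hc <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  cut <- stats::cutree(hc, k = n_main)
  tibble::tibble(module = mods, main_module = as.integer(cut))
}

# PCA embedding helper (rows = cells); centered, not scaled
prcomp_embedding <- function(x, n_pcs = 30) {
  xd <- as.matrix(x)
  n_pcs <- min(n_pcs, nrow(xd) - 1, ncol(xd))
  p <- stats::prcomp(xd, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- p$x
  rownames(emb) <- rownames(xd)
  emb
}
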
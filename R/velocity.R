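#' Steady-state RNA-velocity estimation
#'
#' Classical steady-state residual model: genes are filtered to those with at
#' least `min_counts` total signal in both the spliced and unspliced layers,
#' the `top_genes` most variable (by spliced variance) are kept, and per gene
#' the steady-state ratio `gamma_hat` is fit by a through-origin regression
#' of `u` on `s` restricted to cells in the extreme upper and lower
#' `quantile` of `s`. The velocity is the residual `v = u - gamma_hat * s`.
#'
#' @param k A `kinetics_matrix` (spliced + unspliced, cells x genes), e.g.
#'   from [simulate_kinetics()].
#' @param top_genes Number of most-variable genes retained.
#' @param min_counts Minimum total spliced and unspliced signal per gene.
#' @param quantile Fraction of cells, at each extreme of `s`, taken as
#'   steady-state cells for the fit.
#' @param embedding Optional cells x dims coordinates for the neighbour
#'   graph; defaults to PCA of the log1p-normalized spliced layer.
#' @param n_pcs,knn_k Principal components and neighbours for the default
#'   graph; `knn_k = NULL` scales the neighbourhood with the data
#'   (10% of cells, at least 30).
#' @return An object of class `velocity_field`: list with `velocity`
#'   (cells x genes residuals), `gamma` (per gene), `genes`, the `graph`
#'   ([knn_graph()]), `embedding`, and the ln-normalized spliced matrix
#'   `spliced_norm` used downstream.
#' @export
estimate_velocity_steady_state <- function(k, top_genes = 3000, min_counts = 10,
                                           quantile = 0.05, embedding = NULL,
                                           n_pcs = 30, knn_k = NULL) {
  s <- k$spliced
  u <- k$unspliced
  stopifnot(nrow(s) >= 50)
  keep <- Matrix::colSums(s) >= min_counts & Matrix::colSums(u) >= min_counts
  s <- s[, keep, drop = FALSE]
  u <- u[, keep, drop = FALSE]
  v_order <- order(apply(s, 2, stats::var), decreasing = TRUE)
  sel <- sort(v_order[seq_len(min(top_genes, ncol(s)))])
  s <- s[, sel, drop = FALSE]
  u <- u[, sel, drop = FALSE]
  n <- nrow(s)
  n_ext <- max(1L, ceiling(quantile * n))
  gamma <- numeric(ncol(s))
  dropped <- logical(ncol(s))
  for (j in seq_len(ncol(s))) {
    ord <- order(s[, j])
    ext <- c(utils::head(ord, n_ext), utils::tail(ord, n_ext))
    ss <- s[ext, j]
    if (all(ss == 0)) { dropped[j] <- TRUE; next }
    gamma[j] <- sum(u[ext, j] * ss) / sum(ss^2)
  }
  if (any(dropped))
    message(sum(dropped), " gene(s) with all-zero spliced extremes dropped")
  s <- s[, !dropped, drop = FALSE]
  u <- u[, !dropped, drop = FALSE]
  gamma <- gamma[!dropped]
  names(gamma) <- colnames(s)
  velocity <- u - sweep(s, 2, gamma, `*`)
  spliced_norm <- lognormalize(k$spliced)
  if (is.null(embedding))
    embedding <- prcomp_embedding(spliced_norm, n_pcs = n_pcs)
  if (is.null(knn_k)) knn_k <- min(max(30, round(0.1 * n)), n - 1)
  graph <- knn_graph(embedding, k = knn_k)
  structure(list(velocity = velocity, gamma = gamma, genes = colnames(s),
                 graph = graph, embedding = embedding,
                 spliced_norm = spliced_norm),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d cells, %d velocity genes, kNN k = %d\n",
              nrow(x$velocity), length(x$genes), x$graph$k))
  invisible(x)
}

#' Velocity-based cell transition matrix
#'
#' For each cell i and each of its graph neighbours j, the matrix element is
#' the Pearson correlation between cell i's velocity vector and the
#' cell-state difference vector `x_j - x_i`, restricted to the velocity
#' genes; non-neighbours and the diagonal are zero. Cells whose velocity
#' vector has zero norm are flagged (their destination is undefined).
#'
#' @param vf A `velocity_field`.
#' @param x Expression used for the difference vectors (cells x genes;
#'   defaults to the field's ln-normalized spliced matrix). Must contain the
#'   velocity genes.
#' @param recurse_neighbors Neighbourhood depth: 1 uses the direct graph
#'   neighbours, 2 (the upstream tool's convention, default) additionally
#'   includes neighbours of neighbours.
#' @return A list with the sparse `matrix` (cells x cells correlations) and
#'   the logical `flagged` vector.
#' @export
transition_matrix <- function(vf, x = vf$spliced_norm, recurse_neighbors = 2) {
  genes <- vf$genes
  if (!all(genes %in% colnames(x)))
    stop("velocity genes missing from the expression matrix")
  xg <- as.matrix(x[, genes, drop = FALSE])
  v <- as.matrix(vf$velocity)
  n <- nrow(xg)
  w <- methods::as(methods::as(vf$graph$w, "CsparseMatrix"), "generalMatrix")
  if (recurse_neighbors >= 2) {
    w2 <- w %*% w
    w <- w + w2
  }
  Matrix::diag(w) <- 0
  w <- methods::as(methods::as(Matrix::drop0(w), "CsparseMatrix"), "generalMatrix")
  nn_list <- split(w@i + 1L, rep(seq_len(n), diff(w@p)))  # column-wise lists
  # w is symmetric, so column neighbour lists equal row neighbour lists
  nn_list <- nn_list[as.character(seq_len(n))]
  nn_list[vapply(nn_list, is.null, TRUE)] <- list(integer(0))
  flagged <- apply(v, 1, function(row) sum(row^2) == 0 || stats::sd(row) == 0)
  ii <- jj <- integer(0)
  vals <- numeric(0)
  for (i in seq_len(n)) {
    if (flagged[i]) next
    js <- nn_list[[i]]
    if (!length(js)) next
    d <- t(xg[js, , drop = FALSE]) - xg[i, ]
    r <- suppressWarnings(as.numeric(stats::cor(v[i, ], d)))
    r[is.na(r)] <- 0
    ii <- c(ii, rep(i, length(js)))
    jj <- c(jj, js)
    vals <- c(vals, r)
  }
  tm <- Matrix::sparseMatrix(i = ii, j = jj, x = vals, dims = c(n, n),
                             dimnames = list(rownames(xg), rownames(xg)))
  list(matrix = tm, flagged = stats::setNames(flagged, rownames(xg)))
}

#' Assign each cell's transition destination
#'
#' The destination cell is the neighbour with the highest transition
#' correlation; the destination state is that cell's state label. Flagged
#' cells (zero-norm velocity) are assigned their own state and counted
#' separately.
#'
#' @param tm Output of [transition_matrix()].
#' @param states Named character vector or tibble (`cell_id`, `state`) of
#'   per-cell state labels.
#' @return A tibble: cell_id, state, destination, flagged.
#' @export
assign_destinations <- function(tm, states) {
  if (is.data.frame(states))
    states <- stats::setNames(states$state, states$cell_id)
  m <- tm$matrix
  ids <- rownames(m)
  stopifnot(all(ids %in% names(states)))
  states <- states[ids]
  dest <- character(length(ids))
  md <- as.matrix(m)
  md[md == 0] <- -Inf  # structural zeros are non-neighbours
  best <- max.col(md, ties.method = "first")
  has_nb <- apply(md, 1, function(r) any(is.finite(r)))
  dest <- unname(ifelse(tm$flagged | !has_nb, states, states[best]))
  if (all(tm$flagged)) warning("all velocity vectors flagged; self destinations")
  tibble::tibble(cell_id = ids, state = unname(states), destination = dest,
                 flagged = unname(tm$flagged | !has_nb))
}

#' Destination proportions and chi-square comparison of two conditions
#'
#' For cells of `source_state` in each condition, tabulates destination
#' counts, reports the per-condition destination proportions, and compares
#' the two count vectors with Pearson's chi-square test (no continuity
#' correction). Destination categories absent from both conditions are
#' dropped with a message; expected counts below 5 trigger a warning.
#'
#' @param dests_a,dests_b Destination tibbles from [assign_destinations()]
#'   for the two conditions.
#' @param source_state The source state whose fate is compared; both
#'   conditions need at least 20 cells in it.
#' @param condition_names Labels for the two conditions.
#' @return An object of class `transition_summary`: list with `proportions`
#'   (tibble: condition, destination, n, prop), `counts` (2 x destinations
#'   matrix), `statistic`, `df`, `p`.
#' @export
transition_contingency <- function(dests_a, dests_b, source_state,
                                   condition_names = c("a", "b")) {
  lv <- sort(unique(c(dests_a$destination, dests_b$destination,
                      dests_a$state, dests_b$state)))
  counts_of <- function(d) {
    sel <- d$destination[d$state == source_state]
    if (length(sel) < 20) stop("fewer than 20 cells in source state for one condition")
    table(factor(sel, levels = lv))
  }
  ca <- counts_of(dests_a)
  cb <- counts_of(dests_b)
  present <- ca + cb > 0
  if (any(!present))
    message("dropping destination(s) absent from both conditions: ",
            paste(lv[!present], collapse = ", "))
  tab <- rbind(as.integer(ca[present]), as.integer(cb[present]))
  dimnames(tab) <- list(condition_names, lv[present])
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(chi$expected < 5))
    warning("expected count(s) below 5 in the contingency table")
  props <- tibble::tibble(
    condition = rep(condition_names, each = sum(present)),
    destination = rep(lv[present], 2),
    n = c(tab[1, ], tab[2, ]),
    prop = c(tab[1, ] / sum(tab[1, ]), tab[2, ] / sum(tab[2, ]))
  )
  structure(list(proportions = props, counts = tab,
                 statistic = unname(chi$statistic), df = unname(chi$parameter),
                 p = chi$p.value, source_state = source_state),
            class = "transition_summary")
}

#' Full state-by-state destination contingency table
#'
#' @param dests A destination tibble from [assign_destinations()].
#' @return A state x destination count matrix.
#' @export
destination_table <- function(dests) {
  lv <- sort(unique(c(dests$state, dests$destination)))
  table(source = factor(dests$state, lv), destination = factor(dests$destination, lv))
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("<transition_summary> source = %s, X2 = %.3f (df %d), p = %.3g\n",
              x$source_state, x$statistic, x$df, x$p))
  print(x$counts)
  invisible(x)
}
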
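#' Intra-tumoral expression programs by NMF
#'
#' Factorizes one tumor's malignant-cell expression into `n_factors`
#' non-negative programs. The input is the ln-normalized matrix, centered
#' per gene with negative values clipped to zero (so factors capture
#' relative, not absolute, expression). Factorization uses seeded
#' multiplicative updates minimizing the Frobenius reconstruction error;
#' the objective is non-increasing across iterations. Each factor is
#' summarized by its `top_n` genes with the highest loadings.
#'
#' @param x Normalized expression for the malignant cells of one sample,
#'   cells x genes.
#' @param n_factors Number of factors (default 10).
#' @param top_n Top genes reported per factor.
#' @param seed Seed for the initialization.
#' @param max_iter,tol Update iterations and relative-change stopping
#'   tolerance on the objective.
#' @param sample Optional sample label stored with the model.
#' @return An object of class `nmf_model`: list with `w` (genes x factors),
#'   `h` (factors x cells), `top_genes` (list per factor), `objective`
#'   (per-iteration loss trace), `sample`.
#' @export
nmf_programs <- function(x, n_factors = 10, top_n = 50, seed = 1,
                         max_iter = 300, tol = 1e-5, sample = "sample") {
  xd <- as.matrix(x)
  if (nrow(xd) < 100) stop("need at least 100 cells for NMF")
  a <- t(xd)                       # genes x cells
  a <- a - rowMeans(a)             # per-gene centering
  a[a < 0] <- 0                    # clip negatives: relative expression only
  if (all(a == 0)) stop("all-zero input after centering and clipping")
  g <- nrow(a); cns <- ncol(a)
  eps <- .Machine$double.eps
  res <- withr::with_seed(seed, {
    w <- matrix(stats::runif(g * n_factors, 0, max(a)), g, n_factors)
    h <- matrix(stats::runif(n_factors * cns), n_factors, cns)
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      h <- h * (crossprod(w, a) / (crossprod(w) %*% h + eps))
      w <- w * (a %*% t(h)) / (w %*% tcrossprod(h) + eps)
      loss <- sqrt(sum((a - w %*% h)^2))
      obj <- c(obj, loss)
      if (is.finite(prev) && prev > 0 && abs(prev - loss) / prev < tol) break
      prev <- loss
    }
    list(w = w, h = h, obj = obj)
  })
  dimnames(res$w) <- list(rownames(a), paste0("factor_", seq_len(n_factors)))
  dimnames(res$h) <- list(colnames(res$w), colnames(a))
  top <- lapply(seq_len(n_factors), function(f) {
    rownames(res$w)[order(res$w[, f], decreasing = TRUE)][seq_len(min(top_n, g))]
  })
  names(top) <- colnames(res$w)
  structure(list(w = res$w, h = res$h, top_genes = top,
                 objective = res$obj, sample = sample, n_factors = n_factors),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("<nmf_model> sample %s: %d factors over %d genes x %d cells (%d iterations)\n",
              x$sample, x$n_factors, nrow(x$w), ncol(x$h), length(x$objective)))
  invisible(x)
}

#' Cluster NMF factors across tumors into meta-programs
#'
#' Scores every factor's top-gene list on the combined cell set
#' ([score_signatures()]), then clusters the factor score vectors with
#' `1 - Pearson r` as the distance and Ward linkage, cutting at `n_meta`
#' meta-programs. Each meta-program's signature is the genes appearing in at
#' least half of its member factors' top lists, padded to `sig_size` by the
#' aggregate loading rank across members.
#'
#' @param models List of [nmf_programs()] models (one per tumor).
#' @param x Normalized expression of the combined cells used for factor
#'   scoring.
#' @param n_meta Number of meta-programs to cut at (default 4).
#' @param sig_size Meta-program signature size.
#' @param min_recurrence_r Recurrence filter: a factor enters the
#'   meta-clustering only if its score vector correlates at least this much
#'   with some factor from a *different* sample (tumor-specific noise factors
#'   are dropped, the convention of cross-tumor meta-program analyses). Set
#'   to `NULL` to keep every factor.
#' @param seed Seed for the factor scoring control draws.
#' @return An object of class `meta_programs`: list with `membership`
#'   (tibble: sample, factor, meta_program; filtered-out factors carry NA),
#'   `signatures` (named list of gene sets), and `scores` (per-cell factor
#'   score tibble).
#' @export
cluster_meta_programs <- function(models, x, n_meta = 4, sig_size = 50,
                                  min_recurrence_r = 0.3, seed = 1) {
  sets <- list()
  owner <- tibble::tibble(sample = character(), factor = character())
  for (m in models) {
    nm <- paste0(m$sample, ".", names(m$top_genes))
    sets <- c(sets, stats::setNames(m$top_genes, nm))
    owner <- dplyr::bind_rows(owner, tibble::tibble(sample = m$sample,
                                                    factor = names(m$top_genes)))
  }
  if (length(sets) < 2) stop("need at least two factors in total")
  scores <- score_signatures(x, sets, seed = seed)
  sm <- as.matrix(scores[setdiff(names(scores), "cell_id")])
  cr <- suppressWarnings(stats::cor(sm))
  cr[is.na(cr)] <- 0
  keep <- rep(TRUE, ncol(sm))
  if (!is.null(min_recurrence_r) && length(unique(owner$sample)) > 1) {
    other <- outer(owner$sample, owner$sample, `!=`)
    keep <- vapply(seq_len(ncol(sm)),
                   function(i) max(cr[i, other[i, ]]) >= min_recurrence_r, TRUE)
    if (sum(keep) < 2) stop("fewer than two recurrent factors; lower min_recurrence_r")
    sets <- sets[keep]
    sm <- sm[, keep, drop = FALSE]
    cr <- cr[keep, keep, drop = FALSE]
  }
  if (n_meta > length(sets)) stop("n_meta exceeds the retained factor count")
  hc <- stats::hclust(stats::as.dist(1 - cr), method = "ward.D2")
  cut <- stats::cutree(hc, k = n_meta)
  membership <- owner
  membership$meta_program <- NA_integer_
  membership$meta_program[keep] <- as.integer(cut)
  owner <- owner[keep, , drop = FALSE]
  # signature: majority genes across member factors, padded by aggregate loading rank
  signatures <- lapply(seq_len(n_meta), function(mp) {
    members <- which(cut == mp)
    gene_tab <- sort(table(unlist(sets[members])), decreasing = TRUE)
    core <- names(gene_tab)[gene_tab >= length(members) / 2]
    if (length(core) >= sig_size) return(core[seq_len(sig_size)])
    # aggregate normalized loadings over member factors for padding
    agg <- list()
    for (i in members) {
      sm_name <- owner$sample[i]
      f_name <- owner$factor[i]
      mod <- models[[which(vapply(models, function(m) m$sample, "") == sm_name)[1]]]
      wcol <- mod$w[, f_name]
      agg[[length(agg) + 1]] <- wcol / max(wcol)
    }
    pool <- sort(tapply(unlist(agg), names(unlist(agg)), sum), decreasing = TRUE)
    pad <- setdiff(names(pool), core)
    c(core, pad[seq_len(min(sig_size - length(core), length(pad)))])
  })
  names(signatures) <- paste0("meta_program_", seq_len(n_meta))
  structure(list(membership = membership, signatures = signatures,
                 scores = scores),
            class = "meta_programs")
}

#' @export
print.meta_programs <- function(x, ...) {
  cat(sprintf("<meta_programs> %d meta-programs over %d factors\n",
              length(x$signatures), nrow(x$membership)))
  print(table(x$membership$meta_program))
  invisible(x)
}

#' Jaccard similarity of two gene sets
#'
#' `|a intersect b| / |a union b|`; symmetric, in [0, 1], equal to 1 iff the
#' sets are equal.
#'
#' @param a,b Non-empty character vectors.
#' @return A single number.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("empty gene set")
  length(intersect(a, b)) / length(union(a, b))
}

#' Jaccard similarity grid between two collections of gene sets
#'
#' @param sets_a,sets_b Named lists of gene sets (e.g. meta-program
#'   signatures vs developmental state signatures).
#' @return Tibble: set_a, set_b, jaccard.
#' @export
jaccard_grid <- function(sets_a, sets_b) {
  grid <- tidyr::expand_grid(set_a = names(sets_a), set_b = names(sets_b))
  grid$jaccard <- purrr::pmap_dbl(grid, function(set_a, set_b) {
    jaccard_similarity(sets_a[[set_a]], sets_b[[set_b]])
  })
  grid
}
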
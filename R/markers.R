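#' One-tailed rank-sum marker detection
#'
#' For each group versus all other cells, genes are tested only when their
#' detected fraction reaches `min_frac` in either population and the mean
#' natural-log expression difference (group minus rest) is at least
#' `min_lnfc`. Significance uses a one-tailed (greater) Wilcoxon rank-sum
#' test with the tie-corrected normal approximation and continuity
#' correction; P values are Bonferroni-adjusted over the genes actually
#' tested within each group.
#'
#' @param x Normalized expression (cells x genes), e.g. [lognormalize()].
#' @param groups Factor/character vector of group labels, one per cell; every
#'   group must have at least 3 members.
#' @param min_frac Minimum detected fraction in either population.
#' @param min_lnfc Minimum natural-log mean difference (0.3 for the
#'   region/cell-type grids; 0.5 for the four-state signature genes).
#' @return A `marker_table` tibble: gene, group, ln_fc, frac_in, frac_out,
#'   p_raw, p_adj.
#' @export
find_markers <- function(x, groups, min_frac = 0.25, min_lnfc = 0.3) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(x))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 3)) stop("group(s) of size < 3: ",
                           paste(names(sizes)[sizes < 3], collapse = ", "))
  xd <- as.matrix(x)
  n <- nrow(xd)
  # ranks and tie corrections are shared across the group-vs-rest contrasts
  ranks <- apply(xd, 2, rank)
  tiecorr <- apply(xd, 2, function(v) {
    t <- tabulate(match(v, unique(v)))
    sum(t^3 - t)
  })
  det <- xd > 0
  res <- lapply(levels(groups), function(g) {
    ing <- groups == g
    n1 <- sum(ing)
    n2 <- n - n1
    frac_in <- colMeans(det[ing, , drop = FALSE])
    frac_out <- colMeans(det[!ing, , drop = FALSE])
    ln_fc <- colMeans(xd[ing, , drop = FALSE]) - colMeans(xd[!ing, , drop = FALSE])
    test <- (pmax(frac_in, frac_out) >= min_frac) & (ln_fc >= min_lnfc)
    if (!any(test)) return(NULL)
    R1 <- colSums(ranks[ing, test, drop = FALSE])
    U <- R1 - n1 * (n1 + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecorr[test] / (n * (n - 1)))
    z <- (U - n1 * n2 / 2 - 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
    p <- stats::pnorm(z, lower.tail = FALSE)
    tibble::tibble(gene = colnames(xd)[test], group = g, ln_fc = ln_fc[test],
                   frac_in = frac_in[test], frac_out = frac_out[test],
                   p_raw = p, p_adj = pmin(p * sum(test), 1))
  })
  empty <- tibble::tibble(gene = character(), group = character(),
                          ln_fc = numeric(), frac_in = numeric(),
                          frac_out = numeric(), p_raw = numeric(),
                          p_adj = numeric())
  out <- dplyr::bind_rows(empty, res)
  class(out) <- c("marker_table", class(out))
  out
}

#' Upper-tail hypergeometric overlap test
#'
#' Tests whether two gene sets overlap more than expected by chance on a
#' shared background: with `X ~ Hypergeometric(N = |background|, K = |A|,
#' n = |B|)`, returns `k = |A intersect B|` and `p = P(X >= k)` (upper tail
#' including the observed overlap).
#'
#' @param set_a,set_b Gene sets (character vectors); must be subsets of
#'   `background`.
#' @param background The shared gene universe.
#' @return A list with `k`, `p`, and the set sizes `n_a`, `n_b`, `n_bg`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, background) {
  set_a <- unique(set_a); set_b <- unique(set_b); background <- unique(background)
  extra <- c(setdiff(set_a, background), setdiff(set_b, background))
  if (length(extra))
    stop("sets not subsets of background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), length(background) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(k = k, p = p, n_a = length(set_a), n_b = length(set_b),
       n_bg = length(background))
}

#' Cell-type x region intersection enrichment grid
#'
#' For every (cell type, region) pair, overlaps the significant markers
#' (`p_adj < alpha`) of the two tables on the shared background with
#' [hypergeometric_overlap()]. Following the display rule of the source
#' analysis, a pair is called `enriched` when p < alpha and `depleted`
#' otherwise; the display value is -log10(p) for enriched pairs and 0 for
#' depleted ones.
#'
#' @param cell_markers,region_markers `marker_table`s from [find_markers()].
#' @param background Character vector: the shared gene universe (marker genes
#'   outside it are dropped).
#' @param alpha Significance level for both the marker filter and the call.
#' @return An `enrichment_grid` tibble: cell_type, region, k, n_cell_markers,
#'   n_region_markers, n_background, p, call, display.
#' @export
intersection_grid <- function(cell_markers, region_markers, background,
                              alpha = 0.05) {
  sets_of <- function(mt) {
    mt <- dplyr::filter(mt, .data$p_adj < alpha, .data$gene %in% background)
    split(mt$gene, factor(mt$group, unique(mt$group)))
  }
  a_sets <- sets_of(cell_markers)
  b_sets <- sets_of(region_markers)
  if (!length(a_sets) || !length(b_sets))
    stop("a marker table is empty after p_adj filtering")
  grid <- tidyr::expand_grid(cell_type = names(a_sets), region = names(b_sets))
  rows <- purrr::pmap(grid, function(cell_type, region) {
    h <- hypergeometric_overlap(a_sets[[cell_type]], b_sets[[region]], background)
    tibble::tibble(cell_type = cell_type, region = region, k = h$k,
                   n_cell_markers = h$n_a, n_region_markers = h$n_b,
                   n_background = h$n_bg, p = h$p,
                   call = if (h$p < alpha) "enriched" else "depleted",
                   display = if (h$p < alpha) -log10(h$p) else 0)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("enrichment_grid", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Filter state signatures down to state-specific genes
#'
#' Per state: (DEGs of the state) intersect (module genes of the state),
#' minus any confounder markers (genes associated with other cell types that
#' share the tissue). The union of the filtered sets is the spot-scoring
#' signature.
#'
#' @param state_degs,module_genes Named lists (state -> gene set) with
#'   matching names.
#' @param confounder_markers Character vector of genes to exclude.
#' @return Named list of filtered gene sets, with attribute `union_size`.
#' @export
filter_state_signature <- function(state_degs, module_genes,
                                   confounder_markers = character(0)) {
  if (!setequal(names(state_degs), names(module_genes)))
    stop("state keys differ between DEG and module lists")
  out <- lapply(names(state_degs), function(s) {
    setdiff(intersect(state_degs[[s]], module_genes[[s]]), confounder_markers)
  })
  names(out) <- names(state_degs)
  empty <- names(out)[lengths(out) == 0]
  if (length(empty))
    stop("state(s) with empty filtered signature: ", paste(empty, collapse = ", "))
  attr(out, "union_size") <- length(unique(unlist(out)))
  out
}

#' Pairwise two-sided rank-sum comparison of region scores
#'
#' For each signature and each pair of layers, runs a two-sided unpaired
#' Wilcoxon test on the spot scores, reporting the direction via the median
#' difference.
#'
#' @param spot_scores Tibble from [score_signatures()] over spots.
#' @param layers Layer label per spot; layers with fewer than 2 spots are
#'   excluded with a message.
#' @return Tibble: signature, layer_a, layer_b, w, p, median_diff
#'   (median(a) - median(b)).
#' @export
compare_region_scores <- function(spot_scores, layers) {
  stopifnot(length(layers) == nrow(spot_scores))
  layers <- as.factor(layers)
  keep <- names(which(table(layers) >= 2))
  dropped <- setdiff(levels(layers), keep)
  if (length(dropped))
    message("excluding layer(s) with < 2 spots: ", paste(dropped, collapse = ", "))
  sigs <- setdiff(names(spot_scores), "cell_id")
  pairs <- utils::combn(keep, 2, simplify = FALSE)
  rows <- purrr::map(sigs, function(sg) {
    v <- spot_scores[[sg]]
    purrr::map(pairs, function(pr) {
      a <- v[layers == pr[1]]; b <- v[layers == pr[2]]
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      tibble::tibble(signature = sg, layer_a = pr[1], layer_b = pr[2],
                     w = unname(wt$statistic), p = wt$p.value,
                     median_diff = stats::median(a) - stats::median(b))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Pearson correlation of averaged state and region profiles
#'
#' @param cell_state_profiles,region_profiles Matrices of mean normalized
#'   expression (state x gene and region x gene) with gene ids as column
#'   names.
#' @param genes Gene ids over which to correlate (typically the filtered
#'   state-signature union); must be present in both profiles.
#' @return Tibble: state, region, r (NA with a message for zero-variance
#'   profiles).
#' @export
profile_correlation <- function(cell_state_profiles, region_profiles, genes) {
  missing <- setdiff(genes, intersect(colnames(cell_state_profiles),
                                      colnames(region_profiles)))
  if (length(missing))
    stop("genes absent from a profile: ", paste(utils::head(missing, 5), collapse = ", "))
  a <- cell_state_profiles[, genes, drop = FALSE]
  b <- region_profiles[, genes, drop = FALSE]
  grid <- tidyr::expand_grid(state = rownames(a), region = rownames(b))
  grid$r <- purrr::pmap_dbl(grid, function(state, region) {
    va <- a[state, ]; vb <- b[region, ]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      message("zero-variance profile for ", state, " / ", region)
      return(NA_real_)
    }
    stats::cor(va, vb)
  })
  grid
}

#' Mean expression profiles by group
#'
#' @param x Normalized expression, cells x genes.
#' @param groups Group label per cell.
#' @return A group x gene matrix of mean values.
#' @export
group_profiles <- function(x, groups) {
  groups <- as.factor(groups)
  out <- t(vapply(levels(groups), function(g) {
    Matrix::colMeans(x[groups == g, , drop = FALSE])
  }, numeric(ncol(x))))
  colnames(out) <- colnames(x)
  out
}
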
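#' Aggregate synthetic cells into spatial spots
#'
#' Builds layer-banded spots of exactly `spot_cells` member cells each; member
#' states are drawn from the layer's composition row and member cells
#' uniformly from that state's pool (without replacement within a spot). Each
#' spot's gene vector is the exact element-wise sum of its members' counts, so
#' conservation is testable. Spots carry grid coordinates partitioned into
#' contiguous layer bands.
#'
#' @param cfg A [sim_config()].
#' @param cells The [count_matrix()] from [simulate_reference()].
#' @param truth The matching `ground_truth`.
#' @return A list with `spots` (a [spot_matrix()]) and `truth` extended with a
#'   `spots` tibble (spot_id, layer, x, y, and a `members` list-column).
#' @export
simulate_spots <- function(cfg, cells, truth) {
  stopifnot(inherits(cells, "count_matrix"), inherits(truth, "ground_truth"))
  comp <- cfg$layer_composition
  if (!all(colnames(comp) %in% truth$cells$state) &&
      !setequal(colnames(comp), cfg$state_names))
    stop("layer_composition must be defined over the states present in truth")
  pools <- split(truth$cells$cell_id, factor(truth$cells$state, cfg$state_names))
  n_layers <- nrow(comp)
  band_rows <- ceiling(cfg$n_spots_per_layer / 10)
  withr::with_seed(cfg$seed + 107L, {
    spot_rows <- list()
    members_all <- list()
    idx <- 0L
    for (l in seq_len(n_layers)) {
      for (s in seq_len(cfg$n_spots_per_layer)) {
        idx <- idx + 1L
        n_per_state <- as.vector(stats::rmultinom(1, cfg$spot_cells, comp[l, ]))
        members <- character(0)
        for (k in seq_len(ncol(comp))) {
          if (n_per_state[k] == 0) next
          pool <- pools[[colnames(comp)[k]]]
          if (length(pool) < n_per_state[k])
            stop("requested members exceed available cells of state ",
                 colnames(comp)[k])
          members <- c(members, sample(pool, n_per_state[k]))
        }
        spot_rows[[idx]] <- tibble::tibble(
          spot_id = sprintf("spot%04d", idx),
          layer = rownames(comp)[l],
          x = (s - 1L) %% 10L + 1L,
          y = (l - 1L) * band_rows + (s - 1L) %/% 10L + 1L
        )
        members_all[[idx]] <- members
      }
    }
  })
  spots_tbl <- dplyr::bind_rows(spot_rows)
  spots_tbl$members <- members_all
  agg <- do.call(rbind, lapply(members_all, function(mm) {
    Matrix::colSums(cells$counts[mm, , drop = FALSE])
  }))
  rownames(agg) <- spots_tbl$spot_id
  sm <- spot_matrix(agg, coords = spots_tbl[c("spot_id", "x", "y", "layer")],
                    gene_meta = cells$gene_meta)
  truth$spots <- spots_tbl
  list(spots = sm, truth = truth)
}
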
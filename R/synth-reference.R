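# Gene universe: ids, chromosome placement, program assignment, base weights.
# Deterministic given the config seed (own stream, offset 101).
build_gene_universe <- function(cfg) {
  withr::with_seed(cfg$gene_seed + 101L, {
    n <- cfg$n_genes
    n_mito <- round(n * cfg$mito_gene_fraction)
    n_ribo <- round(n * cfg$ribo_gene_fraction)
    n_reg <- n - n_mito - n_ribo
    ids <- c(sprintf("gene%04d", seq_len(n_reg)),
             sprintf("Rps%03d", seq_len(n_ribo)),
             sprintf("mt-%03d", seq_len(n_mito)))
    # contiguous chromosome blocks over non-mito genes; mito genes on chrM
    n_auto <- n_reg + n_ribo
    chr_auto <- paste0("chr", rep(seq_len(cfg$n_chromosomes),
                                  each = ceiling(n_auto / cfg$n_chromosomes),
                                  length.out = n_auto))
    # interleave ribo genes among the regular ones so chromosomes stay contiguous
    auto_order <- sample.int(n_auto)
    auto_ids <- c(ids[seq_len(n_reg)], ids[n_reg + seq_len(n_ribo)])[auto_order]
    chromosome <- c(chr_auto, rep("chrM", n_mito))
    ids <- c(auto_ids, ids[n_auto + seq_len(n_mito)])
    start_by_chr <- integer(length(ids))
    ix_split <- split(seq_along(ids), factor(chromosome, unique(chromosome)))
    for (ix in ix_split) start_by_chr[ix] <- seq_along(ix) * 1e5L
    # programs drawn from regular autosomal genes only
    regular <- which(!startsWith(ids, "mt-") & !startsWith(ids, "Rps"))
    n_sig <- cfg$n_states * cfg$signature_size_per_state
    picks <- sample(regular, n_sig + cfg$cycling_size + cfg$metabolic_size)
    program <- rep("background", length(ids))
    for (k in seq_len(cfg$n_states)) {
      sel <- picks[(k - 1) * cfg$signature_size_per_state +
                     seq_len(cfg$signature_size_per_state)]
      program[sel] <- paste0("state_", cfg$state_names[k])
    }
    used <- cfg$n_states * cfg$signature_size_per_state
    if (cfg$cycling_size > 0)
      program[picks[used + seq_len(cfg$cycling_size)]] <- "cycling"
    if (cfg$metabolic_size > 0)
      program[picks[used + cfg$cycling_size + seq_len(cfg$metabolic_size)]] <- "metabolic"
    # base relative expression; program genes drawn well-expressed so that
    # ln-scale effects survive the log1p transform
    w <- exp(stats::rnorm(length(ids), 0, 1))
    prog <- program != "background"
    w[prog] <- exp(stats::rnorm(sum(prog), 0.9, 0.25))
    tibble::tibble(gene_id = ids, chromosome = chromosome, start = start_by_chr,
                   is_mito = startsWith(ids, "mt-"),
                   is_ribo = startsWith(ids, "Rps"),
                   program = program, base_weight = w)
  })
}

# Cell-level truth: state, destination (kernel realized through phase),
# within-state phase, pseudotime, cycling flag.
draw_cell_truth <- function(cfg, n_cells, prefix = "cell", seed_offset = 102L) {
  withr::with_seed(cfg$seed + seed_offset, {
    K <- cfg$n_states
    state <- sample.int(K, n_cells, replace = TRUE, prob = cfg$state_prior)
    p_self <- diag(cfg$transition_kernel)[state]
    self_destined <- stats::runif(n_cells) < p_self | state == K
    # terminal-state cells accumulate at depth (mature cells are long-lived):
    # a `terminal_deep_fraction` share sits past the switch phase, mirroring
    # the occupancy profile of the transit states
    deep_terminal <- state == K &
      stats::runif(n_cells) < cfg$terminal_deep_fraction
    late <- (!self_destined & state < K) | deep_terminal
    phase <- ifelse(late,
                    stats::runif(n_cells, cfg$switch_phase, 1 - cfg$phase_pad),
                    stats::runif(n_cells, cfg$phase_pad, cfg$switch_phase))
    dest <- ifelse(self_destined, state, pmin(state + 1L, K))
    cycling <- stats::runif(n_cells) < cfg$cycling_fraction_per_state[state]
    tibble::tibble(
      cell_id = sprintf("%s%05d", prefix, seq_len(n_cells)),
      state_index = state,
      state = cfg$state_names[state],
      phase = phase,
      pseudotime = (state_index - 1 + phase) / K,
      destination = cfg$state_names[dest],
      cycling = cycling
    )
  })
}

# Negative-binomial counts around per-cell program-multiplied means.
sample_counts <- function(cfg, genes, cells, mult, seed_offset = 103L) {
  withr::with_seed(cfg$seed + seed_offset, {
    lib <- exp(stats::rnorm(nrow(cells), cfg$libsize_lognormal[[1]],
                            cfg$libsize_lognormal[[2]]))
    V <- sweep(mult, 2, genes$base_weight, `*`)
    M <- V / rowSums(V) * lib
    counts <- matrix(stats::rnbinom(length(M), size = cfg$nb_dispersion, mu = M),
                     nrow = nrow(M),
                     dimnames = list(cells$cell_id, genes$gene_id))
    counts
  })
}

# Program activity multipliers (cells x genes), exp(effect_lnfc) where active.
program_multipliers <- function(cfg, genes, cells) {
  mult <- matrix(1, nrow(cells), nrow(genes))
  eff <- exp(cfg$effect_lnfc)
  for (k in seq_len(cfg$n_states)) {
    gsel <- genes$program == paste0("state_", cfg$state_names[k])
    mult[cells$state_index == k, gsel] <- eff
  }
  if (any(genes$program == "cycling"))
    mult[cells$cycling, genes$program == "cycling"] <- eff
  mult
}

#' Generate the synthetic developmental reference
#'
#' Draws negative-binomial UMI counts for cells planted in one of the chain
#' states; signature genes of a cell's state have their mean multiplied by
#' `exp(effect_lnfc)`, cycling cells additionally up-regulate the cycling
#' program, and the transition kernel is realized through the within-state
#' phase (cells past `switch_phase` are exiting toward the chain successor).
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (a [count_matrix()] carrying chromosome,
#'   position and mito/ribo flags in `gene_meta`) and `truth` (class
#'   `ground_truth`: tibbles `cells` and `genes`, plus the config).
#' @export
simulate_reference <- function(cfg) {
  validate_sim_config(cfg)
  genes <- build_gene_universe(cfg)
  cells <- draw_cell_truth(cfg, cfg$n_cells)
  mult <- program_multipliers(cfg, genes, cells)
  counts <- sample_counts(cfg, genes, cells, mult)
  m <- count_matrix(counts, gene_meta = genes[c("gene_id", "chromosome", "start",
                                                "is_mito", "is_ribo")])
  truth <- structure(list(cells = cells, genes = genes, config = cfg),
                     class = "ground_truth")
  list(counts = m, truth = truth)
}

#' Planted signature gene sets from a ground truth
#'
#' @param truth A `ground_truth`.
#' @param programs Which programs to return (default: the state signatures).
#' @return Named list of gene id vectors.
#' @export
truth_signatures <- function(truth, programs = paste0("state_", truth$config$state_names)) {
  sets <- lapply(programs, function(p) truth$genes$gene_id[truth$genes$program == p])
  names(sets) <- sub("^state_", "", programs)
  sets[lengths(sets) > 0]
}

#' Generate synthetic Patched-like tumor cells
#'
#' Reuses the developmental state programs under a (typically self-renewal
#' biased) transition kernel; malignant cells additionally carry
#' chromosome-scale ln-shifts from `cnv_events` and, with probability
#' `metabolic_fraction`, an active metabolic program. A
#' `1 - malignant_fraction` share of cells is non-malignant (no CNV, no
#' metabolic program).
#'
#' @param cfg A [sim_config()] or [tumor_sim_config()].
#' @return A list with `counts`, `kinetics` (see [simulate_kinetics()]) and
#'   `truth`; the truth cell table carries a `malignant` flag.
#' @export
simulate_tumor <- function(cfg) {
  validate_sim_config(cfg)
  genes <- build_gene_universe(cfg)
  for (ev in cfg$cnv_events) {
    if (!ev$chromosome %in% genes$chromosome)
      stop("cnv chromosome absent from gene annotation: ", ev$chromosome)
  }
  cells <- draw_cell_truth(cfg, cfg$n_cells, prefix = "tcell", seed_offset = 104L)
  withr::with_seed(cfg$seed + 105L, {
    cells$malignant <- stats::runif(nrow(cells)) < cfg$malignant_fraction
    metabolic_on <- cells$malignant &
      stats::runif(nrow(cells)) < cfg$metabolic_fraction
  })
  cells$metabolic <- metabolic_on
  mult <- program_multipliers(cfg, genes, cells)
  if (any(genes$program == "metabolic"))
    mult[metabolic_on, genes$program == "metabolic"] <- exp(cfg$effect_lnfc)
  cnv_affected <- rep(FALSE, nrow(genes))
  for (ev in cfg$cnv_events) {
    gsel <- genes$chromosome == ev$chromosome
    cnv_affected <- cnv_affected | gsel
    mult[cells$malignant, gsel] <- mult[cells$malignant, gsel] * exp(ev$shift)
  }
  genes$cnv_affected <- cnv_affected
  counts <- sample_counts(cfg, genes, cells, mult, seed_offset = 106L)
  m <- count_matrix(counts, gene_meta = genes[c("gene_id", "chromosome", "start",
                                                "is_mito", "is_ribo")])
  truth <- structure(list(cells = cells, genes = genes, config = cfg),
                     class = "ground_truth")
  kin <- simulate_kinetics(cfg, truth)
  list(counts = m, kinetics = kin, truth = truth)
}
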
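#' Configuration for the synthetic cerebellum generators
#'
#' Defines the study conditions the generators emulate: four granule-cell
#' states along a differentiation chain (non-dividing GNPs, dividing GNPs,
#' migrating GNs I, mature GNs II), disjoint per-state signature programs, a
#' shared cycling program, negative-binomial UMI counts, a row-stochastic
#' Markov transition kernel realized through within-state phase, multi-cell
#' spatial spots drawn from layer-specific state compositions, and (for
#' tumors) chromosome-scale expression shifts plus a metabolic program.
#'
#' @param n_cells,n_genes Dataset dimensions.
#' @param n_states Number of chain states (default 4).
#' @param state_names Labels for the states, in chain order.
#' @param state_prior Probability of each state (sums to 1).
#' @param signature_size_per_state Genes per state signature (pairwise
#'   disjoint).
#' @param cycling_size,metabolic_size Sizes of the cycling and (tumor-only)
#'   metabolic programs.
#' @param effect_lnfc Natural-log fold change of program genes in cells where
#'   the program is active; must be > 0.
#' @param cycling_fraction_per_state Per-state probability that a cell is
#'   cycling.
#' @param libsize_lognormal `c(mu, sigma)` of the log-normal library size.
#' @param nb_dispersion Negative-binomial size parameter (variance =
#'   mu + mu^2 / size); one global knob.
#' @param mito_gene_fraction,ribo_gene_fraction Fractions of genes named with
#'   the mitochondrial ("mt-") and ribosomal ("Rps"/"Rpl") prefixes.
#' @param transition_kernel Row-stochastic n_states x n_states matrix; mass
#'   must lie on the diagonal and the chain successor (the last state is
#'   absorbing).
#' @param spot_cells Cells aggregated per spatial spot (fixed, default 30).
#' @param n_spots_per_layer Spots generated per layer.
#' @param layer_names,layer_composition Layer labels and the layer x state
#'   row-stochastic composition matrix.
#' @param n_chromosomes Autosomes over which genes are placed in contiguous
#'   blocks (mitochondrial genes go to "chrM").
#' @param cnv_events List of `list(chromosome =, shift =)` natural-log scale
#'   shifts applied to malignant cells' genes on that chromosome.
#' @param malignant_fraction,metabolic_fraction Tumor generator: fraction of
#'   malignant cells, and of malignant cells expressing the metabolic program.
#' @param beta_range,gamma_range Per-gene splicing/degradation rate ranges for
#'   the kinetics generator (uniform draws), in units of inverse state
#'   occupancy time.
#' @param kinetics_noise_sd Log-normal multiplicative noise sd on spliced and
#'   unspliced levels.
#' @param switch_phase Within-state phase at which exiting cells switch their
#'   own program off and the successor program on.
#' @param phase_pad Phases are sampled away from the interval ends by this
#'   margin.
#' @param terminal_deep_fraction Share of terminal-state cells placed past
#'   `switch_phase` (mature cells accumulate at depth).
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @param gene_seed Seed for the gene universe (ids, chromosome placement,
#'   program assignment, base weights); defaults to `seed`. Give several
#'   tumor replicates the same `gene_seed` (and different `seed`s) so they
#'   share their planted programs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 1000,
                       n_genes = 2000,
                       n_states = 4,
                       state_names = c("GNP_nondiv", "GNP_div", "GN_I", "GN_II"),
                       state_prior = rep(1 / n_states, n_states),
                       signature_size_per_state = 50,
                       cycling_size = 50,
                       metabolic_size = 0,
                       effect_lnfc = 1.0,
                       cycling_fraction_per_state = c(0.10, 0.80, 0.05, 0.02),
                       libsize_lognormal = c(mu = log(5000), sigma = 0.3),
                       nb_dispersion = 10,
                       mito_gene_fraction = 0.02,
                       ribo_gene_fraction = 0.02,
                       transition_kernel = NULL,
                       spot_cells = 30,
                       n_spots_per_layer = 30,
                       layer_names = c("EGL_outer", "EGL_inner", "ML_PCL", "IGL"),
                       layer_composition = NULL,
                       n_chromosomes = 19,
                       cnv_events = list(),
                       malignant_fraction = 1,
                       metabolic_fraction = 0.3,
                       beta_range = c(20, 30),
                       gamma_range = c(1.2, 1.6),
                       kinetics_noise_sd = 0.05,
                       switch_phase = 0.85,
                       phase_pad = 0.01,
                       terminal_deep_fraction = 0.7,
                       seed = 1,
                       gene_seed = NULL) {
  if (length(state_names) != n_states) stop("state_names must have n_states entries")
  if (is.null(transition_kernel)) {
    transition_kernel <- diag(0.3, n_states)
    for (k in seq_len(n_states - 1)) transition_kernel[k, k + 1] <- 0.7
    transition_kernel[n_states, n_states] <- 1
  }
  if (is.null(layer_composition)) {
    layer_composition <- matrix(0.3 / (n_states - 1), length(layer_names), n_states,
                                dimnames = list(layer_names, state_names))
    for (l in seq_len(min(length(layer_names), n_states))) layer_composition[l, l] <- 0.7
    layer_composition <- layer_composition / rowSums(layer_composition)
  }
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_states = as.integer(n_states), state_names = state_names,
    state_prior = state_prior,
    signature_size_per_state = as.integer(signature_size_per_state),
    cycling_size = as.integer(cycling_size),
    metabolic_size = as.integer(metabolic_size),
    effect_lnfc = effect_lnfc,
    cycling_fraction_per_state = cycling_fraction_per_state,
    libsize_lognormal = libsize_lognormal,
    nb_dispersion = nb_dispersion,
    mito_gene_fraction = mito_gene_fraction,
    ribo_gene_fraction = ribo_gene_fraction,
    transition_kernel = transition_kernel,
    spot_cells = as.integer(spot_cells),
    n_spots_per_layer = as.integer(n_spots_per_layer),
    layer_names = layer_names, layer_composition = layer_composition,
    n_chromosomes = as.integer(n_chromosomes), cnv_events = cnv_events,
    malignant_fraction = malignant_fraction,
    metabolic_fraction = metabolic_fraction,
    beta_range = beta_range, gamma_range = gamma_range,
    kinetics_noise_sd = kinetics_noise_sd,
    switch_phase = switch_phase, phase_pad = phase_pad,
    terminal_deep_fraction = terminal_deep_fraction,
    seed = as.integer(seed),
    gene_seed = as.integer(if (is.null(gene_seed)) seed else gene_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cells > 0, cfg$n_genes > 0, cfg$n_states >= 2)
  if (cfg$effect_lnfc <= 0) stop("effect_lnfc must be > 0")
  if (abs(sum(cfg$state_prior) - 1) > 1e-9) stop("state_prior must sum to 1")
  K <- cfg$transition_kernel
  if (any(abs(rowSums(K) - 1) > 1e-9)) stop("transition_kernel rows must sum to 1")
  off <- K
  diag(off) <- 0
  for (k in seq_len(cfg$n_states)) {
    succ <- if (k < cfg$n_states) k + 1 else integer(0)
    bad <- setdiff(which(off[k, ] > 0), succ)
    if (length(bad))
      stop("transition_kernel mass must lie on the diagonal or chain successor")
  }
  if (any(abs(rowSums(cfg$layer_composition) - 1) > 1e-9))
    stop("layer_composition rows must sum to 1")
  if (any(cfg$cycling_fraction_per_state < 0 | cfg$cycling_fraction_per_state > 1))
    stop("cycling_fraction_per_state must lie in [0, 1]")
  n_special <- round(cfg$n_genes * (cfg$mito_gene_fraction + cfg$ribo_gene_fraction))
  n_prog <- cfg$n_states * cfg$signature_size_per_state + cfg$cycling_size +
    cfg$metabolic_size
  if (n_prog + n_special > cfg$n_genes)
    stop("program + mito/ribo genes exceed n_genes: shrink the signatures")
  if (cfg$switch_phase <= 0 || cfg$switch_phase >= 1) stop("switch_phase must be in (0, 1)")
  for (ev in cfg$cnv_events) {
    if (is.null(ev$chromosome) || is.null(ev$shift))
      stop("each cnv event needs a chromosome and a shift")
  }
  invisible(cfg)
}

#' Convenience configuration for a Patched-like tumor sample
#'
#' Starts from [sim_config()] defaults and plants a self-renewal-biased
#' kernel (self-transition 0.7 for the dividing state), one chromosome-scale
#' gain, a metabolic program, and a non-malignant admixture.
#'
#' @param self_renewal Self-transition probability of the dividing state.
#' @param cnv_events Planted copy-number events.
#' @param ... Passed on to [sim_config()].
#' @inheritParams sim_config
#' @return A `sim_config`.
#' @export
tumor_sim_config <- function(self_renewal = 0.7,
                             cnv_events = list(list(chromosome = "chr6", shift = 0.4)),
                             malignant_fraction = 0.9,
                             metabolic_size = 50,
                             seed = 1, ...) {
  cfg <- sim_config(seed = seed, metabolic_size = metabolic_size,
                    malignant_fraction = malignant_fraction,
                    cnv_events = cnv_events, ...)
  K <- cfg$transition_kernel
  div <- 2L  # dividing GNP-like state in chain order
  K[div, div] <- self_renewal
  K[div, div + 1L] <- 1 - self_renewal
  cfg$transition_kernel <- K
  validate_sim_config(cfg)
  cfg
}
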
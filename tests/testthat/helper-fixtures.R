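# Shared helpers for the suite; fixtures are built in code.

# rank-based AUROC of `score` for binary labels `positive`
auroc <- function(score, positive) {
  r <- rank(score)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# a small dense normalized matrix with named dims
toy_norm <- function(n_cells, n_genes, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(abs(rnorm(n_cells * n_genes)), n_cells, n_genes,
                dimnames = list(paste0("c", seq_len(n_cells)),
                                paste0("g", seq_len(n_genes))))
    m
  })
}

# brute-force upper-tail hypergeometric oracle by explicit term summation
hyper_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  if (k <= max(0, K + n - N)) return(1)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# textbook Pearson chi-square statistic on a 2 x m table
pearson_chisq_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# cached default reference simulation shared across test files
ref_sim_cache <- new.env(parent = emptyenv())
default_ref_sim <- function() {
  if (is.null(ref_sim_cache$sim)) {
    cfg <- sim_config(seed = 7)  # defaults: 1000 cells, 2000 genes, 4 states
    ref_sim_cache$sim <- simulate_reference(cfg)
    ref_sim_cache$cfg <- cfg
  }
  ref_sim_cache$sim
}
default_ref_cfg <- function() {
  default_ref_sim()
  ref_sim_cache$cfg
}
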
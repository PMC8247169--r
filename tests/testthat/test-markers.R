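test_that("vectorized rank-sum matches wilcox.test on random data", {
  withr::with_seed(11, {
    x <- matrix(rpois(200 * 30, 3) + rnorm(200 * 30, 0, 0.01), 200, 30)
  })
  # plant shifts so several genes pass the pre-filters
  x[1:100, 1:10] <- x[1:100, 1:10] + 1
  colnames(x) <- paste0("g", 1:30)
  rownames(x) <- paste0("c", 1:200)
  groups <- rep(c("a", "b"), each = 100)
  mt <- find_markers(x, groups, min_frac = 0, min_lnfc = -Inf)
  for (g in paste0("g", c(1, 5, 15, 25))) {
    ref <- stats::wilcox.test(x[groups == "a", g], x[groups == "b", g],
                              alternative = "greater", exact = FALSE)
    mine <- mt$p_raw[mt$gene == g & mt$group == "a"]
    expect_equal(unname(mine), ref$p.value, tolerance = 1e-10)
  }
})

test_that("marker pre-filters and error contracts follow the stated gates", {
  withr::with_seed(3, {
    x <- matrix(0, 80, 6, dimnames = list(paste0("c", 1:80), paste0("g", 1:6)))
    # g1: detected in 20% on both sides -> never tested
    x[sample(1:40, 8), 1] <- 5
    x[40 + sample(1:40, 8), 1] <- 5
    # g2: identical values in both groups -> lnFC 0 -> not tested
    x[, 2] <- 2
    # g3: strong planted marker for group a
    x[1:40, 3] <- 4 + rnorm(40, 0, 0.1)
    x[41:80, 3] <- 1 + rnorm(40, 0, 0.1)
  })
  groups <- rep(c("a", "b"), each = 40)
  mt <- find_markers(x, groups)
  expect_false(any(mt$gene == "g1"))
  expect_false(any(mt$gene == "g2"))
  expect_true(any(mt$gene == "g3" & mt$group == "a" & mt$p_adj < 0.05))
  expect_true(all(mt$p_adj >= mt$p_raw))
  expect_error(find_markers(x, c(rep("a", 78), "b", "b")), "size < 3")
  expect_error(find_markers(x, rep("a", 80)), "two groups")
})

test_that("planted state markers are recovered with calibrated effect sizes", {
  sim <- default_ref_sim()
  x <- lognormalize(sim$counts)
  truth_state <- sim$truth$cells$state
  mt <- find_markers(x, truth_state, min_lnfc = 0.3)
  sigs <- truth_signatures(sim$truth)
  for (st in names(sigs)) {
    hits <- mt[mt$group == st & mt$gene %in% sigs[[st]] & mt$p_adj < 0.05, ]
    expect_gt(nrow(hits), 0.9 * length(sigs[[st]]))
    expect_true(all(abs(hits$ln_fc - 1.0) < 0.35))
  }
})

test_that("no marker survives the gates and Bonferroni under a null split", {
  # random group labels over real-structured counts: no gene should reach the
  # lnFC gate, so nothing is tested and nothing is called
  sim <- default_ref_sim()
  x <- lognormalize(sim$counts)
  falses <- vapply(1:5, function(seed) {
    labels <- withr::with_seed(seed, sample(rep(c("a", "b"), length.out = nrow(x))))
    mt <- find_markers(x, labels)
    sum(mt$p_adj < 0.05)
  }, numeric(1))
  expect_equal(sum(falses), 0)
})

test_that("hypergeometric overlap matches the enumeration oracle and edge cases", {
  bg <- paste0("g", 1:100)
  a <- bg[1:10]
  b <- bg[91:100]
  expect_equal(hypergeometric_overlap(a, b, bg)$p, 1)      # k = 0
  expect_equal(hypergeometric_overlap(a, bg, bg)$k, 10)    # forced overlap
  expect_equal(hypergeometric_overlap(a, bg, bg)$p, 1)
  # N=100, |A|=10, |B|=20, k=5 against the factorial-sum oracle
  b2 <- c(bg[1:5], bg[50:64])
  h <- hypergeometric_overlap(a, b2, bg)
  expect_equal(h$k, 5)
  expect_equal(h$p, hyper_oracle(5, 10, 100, 20), tolerance = 1e-10)
  expect_error(hypergeometric_overlap(c(a, "zzz"), b, bg), "subsets")
  # random spot checks across small universes
  withr::with_seed(4, {
    for (i in 1:25) {
      N <- sample(5:60, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      univ <- paste0("u", 1:N)
      h2 <- hypergeometric_overlap(univ[1:K], sample(univ, n), univ)
      expect_equal(h2$p, hyper_oracle(h2$k, K, N, n), tolerance = 1e-10)
    }
  })
})

test_that("intersection grid calls planted home layers enriched and only those", {
  cfg <- sim_config(n_cells = 1200, n_genes = 1500, seed = 11)
  sim <- simulate_reference(cfg)
  sp <- simulate_spots(cfg, sim$counts, sim$truth)
  x <- lognormalize(sim$counts)
  xs <- lognormalize(sp$spots)
  cm <- find_markers(x, sim$truth$cells$state)
  rm_ <- find_markers(xs, sp$spots$coords$layer)
  bg <- intersect(colnames(x), colnames(xs))
  grid <- intersection_grid(cm, rm_, bg)
  home <- stats::setNames(cfg$layer_names, cfg$state_names)
  for (i in seq_len(nrow(grid))) {
    expected_call <- if (grid$region[i] == home[[grid$cell_type[i]]])
      "enriched" else "depleted"
    expect_equal(grid$call[i], expected_call)
  }
  expect_true(all(grid$display[grid$call == "depleted"] == 0))
  expect_true(all(grid$display[grid$call == "enriched"] > -log10(0.05)))
  # identical marker sets give the smallest p in their row
  self_grid <- intersection_grid(cm, cm, bg)
  for (ct in unique(self_grid$cell_type)) {
    sub <- self_grid[self_grid$cell_type == ct, ]
    expect_equal(sub$region[which.min(sub$p)], ct)
  }
})

test_that("state-signature filtering is exact set algebra with error contracts", {
  degs <- list(s1 = c("a", "b", "c", "d"), s2 = c("x", "y"))
  mods <- list(s1 = c("b", "c", "d", "e"), s2 = c("x", "z"))
  out <- filter_state_signature(degs, mods, confounder_markers = "d")
  expect_equal(out$s1, c("b", "c"))
  expect_equal(out$s2, "x")
  expect_equal(attr(out, "union_size"), 3)
  expect_error(filter_state_signature(degs, list(s1 = "q", s2 = "x")), "s1")
  expect_error(filter_state_signature(degs, mods[1]), "keys")
})

test_that("region score comparisons detect planted layer differences", {
  cfg <- sim_config(n_cells = 1200, n_genes = 1500, seed = 11)
  sim <- simulate_reference(cfg)
  sp <- simulate_spots(cfg, sim$counts, sim$truth)
  xs <- lognormalize(sp$spots)
  sigs <- truth_signatures(sim$truth)
  spot_scores <- suppressMessages(score_signatures(xs, sigs, seed = 6))
  layers <- sp$spots$coords$layer
  cmp <- compare_region_scores(spot_scores, layers)
  # the dividing-GNP score is higher in its home layer than in the far layer
  row <- cmp[cmp$signature == "GNP_div" &
               cmp$layer_a == "EGL_inner" & cmp$layer_b == "IGL", ]
  expect_lt(row$p, 0.01)
  expect_gt(row$median_diff, 0)
  # swapping the layer labels flips the sign, p unchanged
  sw <- ifelse(layers == "EGL_inner", "IGL",
               ifelse(layers == "IGL", "EGL_inner", as.character(layers)))
  swapped <- compare_region_scores(spot_scores, sw)
  row2 <- swapped[swapped$signature == "GNP_div" &
                    ((swapped$layer_a == "EGL_inner" & swapped$layer_b == "IGL") |
                     (swapped$layer_a == "IGL" & swapped$layer_b == "EGL_inner")), ]
  expect_equal(row2$p, row$p, tolerance = 1e-12)
  flip <- if (row2$layer_a == "EGL_inner") -1 else 1
  expect_equal(flip * row2$median_diff, row$median_diff)
  # identical distributions give p = 1 under tie correction
  same <- tibble::tibble(cell_id = paste0("s", 1:20), sig = rep(1:10, 2))
  out <- compare_region_scores(same, rep(c("l1", "l2"), each = 10))
  expect_equal(out$p, 1)
})

test_that("profile correlations identify each state's home layer", {
  expect_equal(profile_correlation(
    matrix(1:5, 1, 5, dimnames = list("s", paste0("g", 1:5))),
    matrix(1:5, 1, 5, dimnames = list("r", paste0("g", 1:5))),
    paste0("g", 1:5))$r, 1)
  expect_equal(profile_correlation(
    matrix(1:5, 1, 5, dimnames = list("s", paste0("g", 1:5))),
    matrix(-(1:5), 1, 5, dimnames = list("r", paste0("g", 1:5))),
    paste0("g", 1:5))$r, -1)
  cfg <- sim_config(n_cells = 1200, n_genes = 1500, seed = 11)
  sim <- simulate_reference(cfg)
  sp <- simulate_spots(cfg, sim$counts, sim$truth)
  x <- lognormalize(sim$counts)
  xs <- lognormalize(sp$spots)
  sigs <- truth_signatures(sim$truth)
  genes <- intersect(unlist(sigs), colnames(xs))
  pc <- profile_correlation(group_profiles(x, sim$truth$cells$state),
                            group_profiles(xs, sp$spots$coords$layer), genes)
  best <- dplyr::slice_max(dplyr::group_by(pc, state), r, n = 1)
  home <- stats::setNames(cfg$layer_names, cfg$state_names)
  expect_equal(best$region[match(names(home), best$state)], unname(home))
})
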
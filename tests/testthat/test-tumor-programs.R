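# three tumors sharing one planted gene universe, cached for this file
tumor_trio <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      out <- list(models = list(), xs = list(), truths = list())
      for (i in 1:3) {
        cfg <- tumor_sim_config(seed = 30 + i, gene_seed = 77, n_cells = 400,
                                n_genes = 1200, malignant_fraction = 1,
                                cycling_fraction_per_state = rep(0, 4),
                                metabolic_size = 0)
        tum <- simulate_tumor(cfg)
        x <- lognormalize(tum$counts)
        out$models[[i]] <- nmf_programs(x, sample = paste0("MB", i), seed = i)
        out$xs[[i]] <- x
        out$truths[[i]] <- tum$truth
      }
      common <- Reduce(intersect, lapply(out$xs, colnames))
      comb <- do.call(rbind, lapply(out$xs, function(m) as.matrix(m[, common])))
      rownames(comb) <- paste0(rep(c("t1.", "t2.", "t3."), each = 400),
                               rownames(comb))
      out$combined <- comb
      cache <<- out
    }
    cache
  }
})

test_that("NMF reconstructs a rank-1 matrix and behaves deterministically", {
  withr::with_seed(5, {
    w0 <- runif(60)
    h0 <- runif(120)
  })
  a <- outer(h0, w0)  # cells x genes, exactly rank 1
  dimnames(a) <- list(paste0("c", seq_along(h0)), paste0("g", seq_along(w0)))
  # bypass the centering path: a rank-1 non-negative input stays rank 1 after
  # clipping only if it is fed as already-centered; test the factorization core
  # through a one-factor fit on the raw input shifted to dodge the centering
  m1 <- nmf_programs(a + 0, n_factors = 1, seed = 3)
  centered <- t(a) - rowMeans(t(a))
  centered[centered < 0] <- 0
  rec <- m1$w %*% m1$h
  expect_lt(sqrt(sum((centered - rec)^2)) / sqrt(sum(centered^2)), 1e-3)
  # objective is non-increasing across multiplicative updates
  expect_true(all(diff(m1$objective) <= 1e-8))
  m2 <- nmf_programs(a, n_factors = 1, seed = 3)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$h, m2$h)
  expect_error(nmf_programs(a[1:20, ], n_factors = 2), "at least 100 cells")
})

test_that("NMF factors recover the planted tumor programs", {
  trio <- tumor_trio()
  prog <- stats::setNames(trio$truths[[1]]$genes$program,
                          trio$truths[[1]]$genes$gene_id)
  planted <- truth_signatures(trio$truths[[1]])
  for (m in trio$models) {
    expect_true(all(diff(m$objective) <= 1e-8))
    hits <- vapply(planted, function(sig) {
      max(vapply(m$top_genes, function(tg) jaccard_similarity(tg, sig), 0))
    }, numeric(1))
    expect_gte(sum(hits >= 0.6), 4)
  }
})

test_that("meta-program clustering groups cross-sample factors by planted program", {
  trio <- tumor_trio()
  mp <- suppressMessages(cluster_meta_programs(trio$models, trio$combined,
                                               n_meta = 4, seed = 9))
  memb <- dplyr::filter(tidy(mp), !is.na(meta_program))
  prog <- stats::setNames(trio$truths[[1]]$genes$program,
                          trio$truths[[1]]$genes$gene_id)
  lab <- vapply(seq_len(nrow(memb)), function(i) {
    m <- trio$models[[match(memb$sample[i], vapply(trio$models, `[[`, "", "sample"))]]
    names(sort(table(prog[m$top_genes[[memb$factor[i]]]]), decreasing = TRUE))[1]
  }, "")
  keep <- startsWith(lab, "state_")
  expect_gte(adjusted_rand(memb$meta_program[keep], lab[keep]), 0.9)
  # each meta-program signature matches one planted program closely
  jg <- jaccard_grid(mp$signatures, truth_signatures(trio$truths[[1]]))
  best <- tapply(jg$jaccard, jg$set_a, max)
  expect_true(all(best >= 0.6))
  expect_error(cluster_meta_programs(trio$models, trio$combined, n_meta = 40),
               "n_meta")
})

test_that("duplicated factors co-cluster and the full cut yields singletons", {
  x <- toy_norm(150, 400, seed = 21)
  m <- nmf_programs(x, n_factors = 3, seed = 2, sample = "s1")
  m2 <- m
  m2$sample <- "s2"
  mp <- suppressMessages(cluster_meta_programs(
    list(m, m2), x, n_meta = 3, min_recurrence_r = NULL, seed = 4))
  memb <- tidy(mp)
  # identical factors from the two copies always share a meta-program
  for (f in unique(memb$factor)) {
    expect_length(unique(memb$meta_program[memb$factor == f]), 1)
  }
  mp_full <- suppressMessages(cluster_meta_programs(
    list(m, m2), x, n_meta = 6, min_recurrence_r = NULL, seed = 4))
  expect_length(unique(tidy(mp_full)$meta_program), 6)
})

test_that("Jaccard similarity is exact set arithmetic with its invariants", {
  expect_equal(jaccard_similarity(letters[1:5], letters[1:5]), 1)
  expect_equal(jaccard_similarity(letters[1:5], letters[6:10]), 0)
  a <- paste0("g", 1:50)
  b <- paste0("g", 26:75)
  expect_equal(jaccard_similarity(a, b), 25 / 75)
  expect_error(jaccard_similarity(character(0), "a"), "empty")
  withr::with_seed(2, {
    for (i in 1:20) {
      s1 <- sample(letters, sample(3:15, 1))
      s2 <- sample(letters, sample(3:15, 1))
      j <- jaccard_similarity(s1, s2)
      expect_identical(j, jaccard_similarity(s2, s1))
      expect_gte(j, 0)
      expect_lte(j, 1)
      expect_identical(j == 1, setequal(s1, s2))
    }
  })
})

test_that("meta-programs map onto developmental states like the planted structure", {
  # cycling program -> dividing-GNP signature; metabolic -> nothing above 0.2
  cfg <- tumor_sim_config(seed = 51, n_cells = 400, n_genes = 1500,
                          malignant_fraction = 1)
  tum <- simulate_tumor(cfg)
  planted_meta <- truth_signatures(
    tum$truth, programs = c("cycling", "metabolic",
                            paste0("state_", cfg$state_names[2:3])))
  dev_sigs <- truth_signatures(tum$truth)
  jg <- jaccard_grid(planted_meta, dev_sigs)
  # the metabolic program matches no developmental state
  expect_lt(max(jg$jaccard[jg$set_a == "metabolic"]), 0.2)
  # each state-derived program matches exactly its own state
  expect_equal(jg$set_b[jg$set_a == "GNP_div"][which.max(jg$jaccard[jg$set_a == "GNP_div"])],
               "GNP_div")
})

test_that("CNV inference zeroes the reference and flags the planted gain", {
  cfg <- tumor_sim_config(seed = 41, n_cells = 600, n_genes = 3000,
                          malignant_fraction = 0.8)
  tum <- simulate_tumor(cfg)
  x <- lognormalize(tum$counts)
  ref <- tum$truth$cells$cell_id[!tum$truth$cells$malignant]
  cnv <- suppressMessages(infer_cnv(x, tum$counts$gene_meta, ref))
  # reference per-window means are exactly zero after subtraction
  expect_lt(max(abs(colMeans(cnv$scores[ref, ]))), 1e-12)
  mal <- tum$truth$cells$malignant[match(rownames(cnv$scores),
                                         tum$truth$cells$cell_id)]
  # the gained chromosome stands out in malignant cells only
  bych <- cnv_by_chromosome(cnv, stats::setNames(ifelse(mal, "mal", "norm"),
                                                 rownames(cnv$scores)))
  chr6 <- bych[bych$chromosome == "chr6", ]
  expect_gt(chr6$mean_score[chr6$group == "mal"], 0.2)
  expect_lt(abs(chr6$mean_score[chr6$group == "norm"]), 0.02)
  expect_gt(auroc(tidy(cnv)$cnv_signal, mal), 0.9)
})

test_that("CNV smoothing handles small chromosomes and is shift-invariant", {
  # window larger than the chromosome: every window is the full-chromosome mean
  withr::with_seed(3, {
    x <- matrix(rnorm(20 * 30), 20, 30,
                dimnames = list(paste0("c", 1:20), paste0("g", 1:30)))
  })
  gm <- tibble::tibble(gene_id = paste0("g", 1:30),
                       chromosome = rep(c("chrA", "chrB"), each = 15),
                       start = rep(1:15, 2) * 10)
  cnv <- infer_cnv(x, gm, reference_cells = paste0("c", 1:5), window = 101,
                   min_mean = -Inf)
  sub <- cnv$scores[, cnv$windows$chromosome == "chrA"]
  expect_lt(max(apply(sub, 1, stats::sd)), 1e-12)  # constant per chromosome
  # chromosomes with fewer than 5 genes are excluded with a message
  gm2 <- gm
  gm2$chromosome[1:3] <- "chrTiny"
  expect_message(infer_cnv(x, gm2, paste0("c", 1:5), min_mean = -Inf), "chrTiny")
  # adding a per-cell constant is removed by the per-cell centering (with the
  # clip wide open the pipeline is linear, so the identity is exact)
  wide <- infer_cnv(x, gm, reference_cells = paste0("c", 1:5), window = 101,
                    clip = 100, min_mean = -Inf)
  shifted <- x + matrix(rnorm(20), 20, 30)
  cnv2 <- infer_cnv(shifted, gm, reference_cells = paste0("c", 1:5),
                    window = 101, clip = 100, min_mean = -Inf)
  expect_equal(cnv2$scores, wide$scores, tolerance = 1e-10)
  expect_error(infer_cnv(x, gm, "nope", min_mean = -Inf), "missing")
})

test_that("kNN similarity votes sum to one and rank the true lineage first", {
  # reference: GN cells (with their internal state structure) plus three
  # unrelated lineages built from disjoint background programs
  cfgR <- sim_config(seed = 61, gene_seed = 60, n_cells = 500, n_genes = 1500)
  ref <- simulate_reference(cfgR)
  gn <- ref$truth$genes
  bg <- gn$gene_id[gn$program == "background"]
  withr::with_seed(33, {
    other_programs <- split(sample(bg, 150), rep(c("astro", "oligo", "GABA"), each = 50))
    w <- gn$base_weight
    other <- lapply(names(other_programs), function(lin) {
      mult <- rep(1, nrow(gn))
      mult[gn$gene_id %in% other_programs[[lin]]] <- exp(1)
      mu <- outer(rep(5000, 120), w * mult / sum(w * mult) * 1)
      m <- matrix(rnbinom(length(mu), size = 2, mu = mu * 5000 / rowSums(mu)[1] * 0 + mu * 1), 120, nrow(gn))
      m
    })
  })
  other_counts <- do.call(rbind, other)
  rownames(other_counts) <- paste0("o", seq_len(nrow(other_counts)))
  colnames(other_counts) <- gn$gene_id
  refx <- rbind(as.matrix(lognormalize(ref$counts)),
                as.matrix(lognormalize(other_counts)))
  labels <- c(rep("GN", 500), rep(c("astro", "oligo", "GABA"), each = 120))
  # query: tumor cells sharing the GN gene universe
  tum <- simulate_tumor(tumor_sim_config(seed = 62, gene_seed = 60,
                                         n_cells = 300, n_genes = 1500))
  qx <- as.matrix(lognormalize(tum$counts))
  ks <- knn_similarity(qx, refx, labels, k = 20,
                       query_samples = rep(c("MB1", "MB2"), length.out = 300))
  mat <- as.matrix(ks$cell_scores[setdiff(names(ks$cell_scores), "cell_id")])
  expect_equal(unname(rowSums(mat)), rep(1, 300))
  best <- ks$sample_scores |>
    dplyr::group_by(sample) |>
    dplyr::slice_max(mean_score, n = 1)
  expect_true(all(best$label == "GN"))
  # a query whose k neighbours all share one label scores exactly 1 for it:
  # with a single-label reference this holds for every query cell
  ones <- knn_similarity(qx[1:20, ], refx, rep("L", nrow(refx)), k = 20)
  expect_true(all(ones$cell_scores$L == 1))
  # mixed queries drawn from the reference rows recover their own label
  mix <- c(1:10, 501:510, 621:630, 741:750)
  pure <- knn_similarity(refx[mix, ], refx, labels, k = 5)
  own_best <- vapply(seq_along(mix), function(i) {
    row <- pure$cell_scores[i, setdiff(names(pure$cell_scores), "cell_id")]
    names(row)[which.max(as.numeric(row))] == labels[mix[i]]
  }, TRUE)
  expect_gte(mean(own_best), 0.9)
  expect_error(knn_similarity(qx, refx, labels, k = 5000), "k exceeds")
  expect_error(knn_similarity(qx[, 1:100], refx[, 1:100], labels), "200 shared")
})
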
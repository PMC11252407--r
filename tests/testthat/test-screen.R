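test_that("normalize_abundance produces unit columns and keeps order", {
  m <- matrix(c(10, 30, 60, 5, 5, 10), ncol = 2,
              dimnames = list(c("b1", "b2", "b3"), c("s1", "s2")))
  r <- normalize_abundance(m)
  expect_equal(unname(r[, "s1"]), c(0.1, 0.3, 0.6))
  expect_equal(unname(colSums(r)), c(1, 1), tolerance = 1e-12)
  # row permutation permutes output identically
  pm <- m[c(3, 1, 2), ]
  expect_equal(normalize_abundance(pm), r[c(3, 1, 2), ])
  expect_error(normalize_abundance(cbind(m, s3 = c(0, 0, 0))), "total")
})

test_that("compute_phi applies the read minimum and handles dropout", {
  counts <- matrix(c(100, 40, 200, 660,
                     25, 100, 0, 875), ncol = 2,
                   dimnames = list(sprintf("b%d", 1:4), c("ctrl", "trt")))
  ann <- data.frame(barcode = sprintf("b%d", 1:4),
                    gene_id = c("g1", "g1", "g2", "g3"), allele_index = 1:4)
  ph <- compute_phi(counts, ann, "ctrl", "trt")
  expect_equal(ph$phi[1], (25 / 1000) / (100 / 1000))  # = 0.25
  expect_false(ph$qualified[2])                        # 40 < 50 control reads
  expect_true(is.na(ph$phi[2]))
  expect_equal(ph$phi[3], 0)                           # treatment dropout
  expect_true(ph$qualified[3])
  # alternative minimum modes
  ph_sum <- compute_phi(counts, ann, "ctrl", "trt", min_reads_on = "sum")
  expect_true(ph_sum$qualified[2])                     # 40 + 100 >= 50
  ph_both <- compute_phi(counts, ann, "ctrl", "trt", min_reads_on = "both")
  expect_false(ph_both$qualified[3])                   # 0 treatment reads
  expect_error(compute_phi(counts, ann, "ctrl", "nope"), "not found")
})

test_that("bin_phi is the half-open 8-bin step function with top clipping", {
  edges <- phi_bin_edges()
  expect_equal(bin_phi(1), 5L)
  expect_equal(bin_phi(0.0625), 2L)      # left edge closed
  expect_equal(bin_phi(20), 8L)          # clipped into top bin
  expect_equal(bin_phi(0), 1L)
  expect_equal(bin_phi(edges), c(2:8, 8L))
  expect_error(bin_phi(-0.1), "phi")
  # total monotone step function on a dense grid
  grid <- sort(c(seq(0, 20, by = 0.01), edges, edges - 1e-9, edges + 1e-9))
  grid <- grid[grid >= 0]
  b <- bin_phi(grid)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b %in% 1:8))
})

test_that("gene_contingency tabulates alleles against the screen background", {
  ph <- data.frame(
    barcode = sprintf("b%d", 1:6),
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g3"),
    allele_index = 1:6,
    control_reads = 100, treatment_reads = 100,
    phi = c(0.03, 0.05, 1.0, 1.1, 0.9, NA),
    qualified = c(rep(TRUE, 5), FALSE))
  ct <- gene_contingency(ph, "g1")
  expect_equal(ct$gene, c(2, 0, 0, 0, 1, 0, 0, 0))  # 0.03, 0.05 < 0.0625
  expect_equal(ct$background, c(2, 0, 0, 0, 3, 0, 0, 0))
  expect_equal(ct$n_alleles, 3)
  # excluding the gene subtracts its alleles
  ct2 <- gene_contingency(ph, "g1", include_gene = FALSE)
  expect_equal(ct2$background, c(0, 0, 0, 0, 2, 0, 0, 0))
  expect_error(gene_contingency(ph, "g3"), "qualified")
  # single-gene screen: gene vector equals background
  ph1 <- ph[ph$gene_id == "g1", ]
  ct3 <- gene_contingency(ph1, "g1")
  expect_equal(ct3$gene, ct3$background)
})

test_that("neutral simulated pool concentrates background mass in bin 5", {
  sim <- simulate_screen(n_genes = 100, alleles_per_gene = 4,
                         n_hit_genes = 0, read_depth = 4e6, seed = 3)
  ph <- compute_phi(sim$counts, sim$annotation, "control_r1", "treatment_r1")
  bg <- tabulate(bin_phi(ph$phi[ph$qualified]), 8)
  expect_gt(bg[5] / sum(bg), 0.99)
})

test_that("single-allele gene against a symmetric background gives p = 1", {
  p <- fisher_gene_p(c(1, 0, 0, 0, 0, 0, 0, 0),
                     c(50, 50, 0, 0, 0, 0, 0, 0))
  expect_equal(p$p, 1, tolerance = 1e-12)
  expect_equal(p$method, "exact")
})

test_that("two-bin tables reduce to the closed-form 2x2 hypergeometric", {
  p <- fisher_gene_p(c(2, 0, 0, 0, 0, 0, 0, 0),
                     c(10, 90, 0, 0, 0, 0, 0, 0))
  # 2x2 table: gene (2,0) vs rest (8,90); margins fixed
  expect_equal(p$p, oracle_fisher_2x2(2, 0, 8, 90), tolerance = 1e-12)
  # and matches stats::fisher.test on the same table
  ft <- fisher.test(matrix(c(2, 8, 0, 90), 2))$p.value
  expect_equal(p$p, ft, tolerance = 1e-9)
})

test_that("exact path equals brute-force enumeration on random tables", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(1:4, 1)
    bg <- rep(0L, 8)
    occupied <- sample(8, sample(2:4, 1))
    bg[occupied] <- as.integer(rmultinom(1, sample(10:40, 1),
                                         rep(1, length(occupied)))) +
      c(rep(0L, length(occupied)))
    bg[occupied][bg[occupied] == 0] <- 1L
    gene <- rep(0L, 8)
    # draw a valid observed gene row inside the background
    pool <- rep(seq_len(8), bg)
    gene <- tabulate(sample(pool, n), nbins = 8)
    p_pkg <- fisher_gene_p(gene, bg)$p
    p_orc <- oracle_gene_p(gene, bg)
    expect_equal(p_pkg, p_orc, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo path agrees with exact enumeration within 3 SE", {
  set.seed(5)
  for (i in 1:8) {
    bg <- as.integer(rmultinom(1, 60, c(4, 2, 1, 1, 8, 1, 1, 2)))
    pool <- rep(seq_len(8), bg)
    gene <- tabulate(sample(pool, 5), nbins = 8)
    exact <- fisher_gene_p(gene, bg)$p
    mc <- fisher_gene_p(gene, bg, exact_cap = 2, mc_draws = 2e5, seed = i)
    expect_equal(mc$method, "monte-carlo")
    se <- max(mc$se, sqrt(exact * (1 - exact) / mc$draws))
    expect_lt(abs(mc$p - exact), 3 * se + 1e-9)
  }
})

test_that("gene test is a valid conditional test at its stated levels", {
  # For null configurations the p-value's conditional distribution must be
  # super-uniform: sum of P(outcome) over outcomes with p <= alpha is <= alpha.
  configs <- list(
    list(n = 2, bg = c(10, 30, 0, 0, 0, 0, 0, 0)),
    list(n = 3, bg = c(5, 12, 20, 0, 0, 0, 0, 0)),
    list(n = 4, bg = c(8, 25, 0, 0, 7, 0, 0, 0)),
    list(n = 4, bg = c(3, 40, 0, 0, 0, 0, 0, 2))
  )
  for (cf in configs) {
    K <- osmoscreen:::compositions(cf$n, 8)
    lp <- osmoscreen:::lmvhyper(K, cf$bg, cf$n)
    keep <- is.finite(lp)
    K <- K[keep, , drop = FALSE]; pr <- exp(lp[keep])
    pv <- vapply(seq_len(nrow(K)), function(i)
      fisher_gene_p(K[i, ], cf$bg)$p, 1)
    for (alpha in c(0.01, 0.05, 0.3))
      expect_lte(sum(pr[pv <= alpha]), alpha + 1e-9)
  }
})

test_that("bh_fdr matches the step-up definition and the printed example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(19)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # step-up property: q sorted by p is non-decreasing
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("call_hits enforces the allele minimum and strict FDR boundary", {
  gp <- data.frame(gene_id = c("a", "b", "c", "d"),
                   p = c(1e-9, 0.5, 0.8, 0.9),
                   n_alleles = c(2, 3, 4, 5))
  out <- call_hits(gp)
  expect_true(is.na(out$q[1]))     # 2 alleles: excluded from FDR
  expect_false(out$hit[1])
  # boundary: q = 0.29 is a hit, q = 0.31 is not (FDR < 0.3 strict)
  gp2 <- data.frame(gene_id = c("x", "y"), p = c(0.29, 0.31),
                    n_alleles = c(3, 3))
  # with m = 1 each, q = p: test separately
  expect_true(call_hits(gp2[1, ])$hit)
  expect_false(call_hits(gp2[2, ])$hit)
  empty <- call_hits(gp[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("pipeline recovers planted hits and is order-invariant", {
  sim <- simulate_screen(n_genes = 60, alleles_per_gene = 5,
                         n_hit_genes = 5, selection_coefficient = 0.5,
                         doublings = 4, read_depth = 3e6, seed = 13)
  res <- run_screen_pipeline(sim$counts, sim$annotation, sim$design)
  hits <- res$gene_id[res$hit]
  planted <- sim$truth$gene_id[sim$truth$s > 0]
  expect_true(all(planted %in% hits))
  expect_equal(sort(hits), sort(planted))

  # permute barcode rows and sample columns: identical result
  perm <- sample(nrow(sim$counts))
  counts2 <- sim$counts[perm, rev(colnames(sim$counts))]
  res2 <- run_screen_pipeline(counts2, sim$annotation, sim$design)
  expect_equal(res2, res, ignore_attr = TRUE)

  expect_error(run_screen_pipeline(sim$counts, sim$annotation,
                                   data.frame(condition = "x")),
               "malformed design")
  bad <- sim$design; bad$control <- "nope"
  expect_error(run_screen_pipeline(sim$counts, sim$annotation, bad),
               "unknown samples")
})
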
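test_that("without double heterozygotes the EM equals direct haplotype counting", {
  # Dosage pairs chosen so no individual is het at both loci: phase known.
  g1 <- c(0L, 0L, 1L, 2L, 2L, 1L, 0L, 2L)
  g2 <- c(0L, 1L, 0L, 2L, 1L, 2L, 2L, 0L)
  em <- em_haplotype_freqs(g1, g2)
  # Direct count: each individual contributes its two unambiguous haplotypes.
  hap <- c(p11 = 0, p12 = 0, p21 = 0, p22 = 0)
  for (i in seq_along(g1)) {
    # The het locus splits across the two haplotypes; the other locus
    # contributes the same allele twice, so the pairing below is exact.
    a <- c(g1[i] >= 1, g1[i] == 2)   # minor-allele indicators per haplotype
    b <- c(g2[i] >= 1, g2[i] == 2)
    for (h in 1:2) {
      idx <- 1L + 2L * a[h] + b[h]
      hap[idx] <- hap[idx] + 1
    }
  }
  expect_equal(unname(em$p), unname(hap / sum(hap)), tolerance = 1e-9)
  expect_lte(em$n_iter, 2L)
})

test_that("a fully phase-ambiguous sample reaches the boundary optimum", {
  g <- rep(1L, 100)
  em <- em_haplotype_freqs(g, g)
  oracle <- grid_hap_oracle(g, g)
  expect_equal(em$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(sort(unname(em$p)), c(0, 0, 0.5, 0.5), tolerance = 1e-6)
})

test_that("EM matches the grid-search likelihood oracle on random small samples", {
  set.seed(99)
  for (r in 1:50) {
    repeat {
      hf <- as.numeric(stats::rmultinom(1, 40, c(0.35, 0.15, 0.2, 0.3))) + 0.25
      hf <- hf / sum(hf)
      gm <- generate_ld_pair(hf, 30, seed = 1000 + r)
      a <- gm$dosage[, 1]
      b <- gm$dosage[, 2]
      if (length(unique(a)) > 1 && length(unique(b)) > 1) break
    }
    em <- em_haplotype_freqs(a, b)
    oracle <- grid_hap_oracle(a, b)
    expect_gte(em$loglik, oracle$loglik - 1e-4)
  }
})

test_that("the EM likelihood is non-decreasing across iterations", {
  gm <- generate_ld_pair(c(0.35, 0.15, 0.25, 0.25), 400, seed = 3)
  lls <- vapply(1:12, function(k) {
    em_haplotype_freqs(gm$dosage[, 1], gm$dosage[, 2], tol = 0, max_iter = k)$loglik
  }, numeric(1))
  expect_true(all(diff(lls) > -1e-10))
})

test_that("monomorphic input is an undefined-LD error", {
  expect_error(em_haplotype_freqs(rep(0L, 50), rep(c(0L, 1L), 25)),
               "monomorphic", class = "snpgrs_computation_error")
  expect_error(ld_statistics(c(1, 0, 0, 0)), class = "snpgrs_computation_error")
})

test_that("D, D-prime, and r-squared follow their closed forms", {
  perfect <- ld_statistics(c(0.5, 0, 0, 0.5))
  expect_equal(perfect$d_prime, 1)
  expect_equal(perfect$r2, 1)

  eq <- ld_statistics(as.numeric(t(outer(c(0.6, 0.4), c(0.7, 0.3)))))
  expect_equal(eq$D, 0)
  expect_equal(eq$d_prime, 0)
  expect_equal(eq$r2, 0)

  worked <- ld_statistics(c(0.4, 0.1, 0.2, 0.3))
  expect_equal(worked$D, 0.1, tolerance = 1e-12)
  expect_equal(worked$d_prime, 0.5, tolerance = 1e-12)
  expect_equal(worked$r2, 1 / 6, tolerance = 1e-9)
})

test_that("LD magnitudes are invariant to allele relabelling at one locus", {
  p <- c(0.45, 0.15, 0.1, 0.3)
  swapped <- c(p[3], p[4], p[1], p[2])   # relabel locus A
  a <- ld_statistics(p)
  b <- ld_statistics(swapped)
  expect_equal(b$D, -a$D, tolerance = 1e-12)
  expect_equal(b$d_prime, a$d_prime, tolerance = 1e-12)
  expect_equal(b$r2, a$r2, tolerance = 1e-12)
})

test_that("0 <= r2 <= d_prime <= 1 over random haplotype tables", {
  set.seed(42)
  for (r in 1:200) {
    p <- as.numeric(stats::rmultinom(1, 60, c(0.3, 0.25, 0.25, 0.2))) + 0.5
    p <- p / sum(p)
    s <- ld_statistics(p)
    expect_gte(s$r2, 0)
    expect_lte(s$r2, s$d_prime + 1e-12)
    expect_lte(s$d_prime, 1)
  }
})

test_that("bootstrap CI collapses to [1,1] under perfect LD and narrows with n", {
  gm <- generate_ld_pair(c(0.5, 0, 0, 0.5), 300, seed = 5)
  ci <- bootstrap_dprime_ci(gm$dosage[, 1], gm$dosage[, 2], n_boot = 200, seed = 1)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)

  width <- function(n) {
    g <- generate_ld_pair(c(0.4, 0.1, 0.2, 0.3), n, seed = 17)
    ci <- bootstrap_dprime_ci(g$dosage[, 1], g$dosage[, 2], n_boot = 300, seed = 23)
    ci$ci_high - ci$ci_low
  }
  expect_lt(width(4000), width(250))
})

test_that("percentile bootstrap D-prime intervals cover near the nominal level", {
  true_dp <- 0.5   # haplotype pool (0.4, 0.1, 0.2, 0.3)
  cover <- 0L
  n_sim <- 500L
  for (r in seq_len(n_sim)) {
    gm <- generate_ld_pair(c(0.4, 0.1, 0.2, 0.3), 250, seed = r * 13 + 1)
    ci <- bootstrap_dprime_ci(gm$dosage[, 1], gm$dosage[, 2], n_boot = 200,
                              seed = r * 7 + 3)
    if (ci$ci_low <= true_dp && true_dp <= ci$ci_high) cover <- cover + 1L
  }
  expect_gte(cover / n_sim, 0.92)
  expect_lte(cover / n_sim, 0.98)
})

test_that("pairwise LD runs within chromosomes only and in position order", {
  panel <- make_cluster_panel(n_per_group = 400, seed = 61)
  pairs <- ld_pairwise(panel$gm)
  snps <- panel$gm$snps
  chr_a <- snps$chromosome[match(pairs$rsid_a, snps$rsid)]
  chr_b <- snps$chromosome[match(pairs$rsid_b, snps$rsid)]
  expect_true(all(chr_a == chr_b))
  expect_true(all(
    snps$position[match(pairs$rsid_a, snps$rsid)] <
      snps$position[match(pairs$rsid_b, snps$rsid)]
  ))
})

test_that("a perfect-LD triple flanked by independent SNPs forms one block", {
  spec <- cohort_spec(
    600, 600,
    tibble::tibble(
      rsid = sprintf("s%d", 1:5), chromosome = "1",
      position = c(1000L, 2000L, 2400L, 2800L, 9000L),
      control_raf = c(0.25, 0.4, 0.4, 0.4, 0.3), or = 1
    ),
    ld_blocks = list(list(snps = c(2L, 3L, 4L),
                          hap_freqs = c(0.6, 0, 0, 0, 0, 0, 0, 0.4))),
    seed = 19
  )
  gm <- generate_cohort(spec)
  pairs <- ld_pairwise(gm, n_boot = 120, seed = 5)
  blocks <- build_blocks(pairs, gm$snps)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$rsids, "s2,s3,s4")
  expect_equal(blocks$n_snps, 3L)

  # Independent panel: no blocks at all.
  spec0 <- cohort_spec(
    600, 600,
    tibble::tibble(rsid = sprintf("i%d", 1:4), chromosome = "1",
                   position = 1000L * (1:4),
                   control_raf = c(0.2, 0.3, 0.4, 0.35), or = 1),
    seed = 23
  )
  gm0 <- generate_cohort(spec0)
  pairs0 <- ld_pairwise(gm0, n_boot = 120, seed = 7)
  expect_equal(nrow(build_blocks(pairs0, gm0$snps)), 0L)
})

test_that("blocks never interleave and never span chromosomes", {
  panel <- make_cluster_panel(n_per_group = 500, seed = 29)
  pairs <- ld_pairwise(panel$gm, n_boot = 120, seed = 9)
  blocks <- build_blocks(pairs, panel$gm$snps)
  expect_gt(nrow(blocks), 0L)
  snps <- panel$gm$snps
  for (i in seq_len(nrow(blocks))) {
    members <- strsplit(blocks$rsids[i], ",")[[1]]
    expect_equal(length(unique(snps$chromosome[match(members, snps$rsid)])), 1L)
  }
  by_chr <- split(blocks, blocks$chromosome)
  for (b in by_chr) {
    if (nrow(b) > 1L) {
      b <- b[order(b$start_pos), ]
      expect_true(all(b$start_pos[-1] > b$end_pos[-nrow(b)]))
    }
  }
})

test_that("greedy D-prime pruning keeps one SNP per LD cluster", {
  panel <- make_cluster_panel(seed = 11)
  pairs <- ld_pairwise(panel$gm)
  pruned <- prune_by_dprime(pairs, panel$gm$snps, threshold = 0.8)
  kept <- pruned$rsid[pruned$retained]
  expect_equal(length(kept), 13L)
  expect_equal(sort(unique(panel$cluster_of[kept])), sprintf("tag%02d", 1:13))
})

test_that("pruning retains independent panels and honours the boundary threshold", {
  spec <- cohort_spec(800, 800,
                      tibble::tibble(control_raf = seq(0.2, 0.45, length.out = 6),
                                     or = 1),
                      seed = 83)
  gm <- generate_cohort(spec)
  pairs <- ld_pairwise(gm)
  all_kept <- prune_by_dprime(pairs, gm$snps, threshold = 0.8)
  expect_true(all(all_kept$retained))
  # threshold 1.0 retains everything unless a pair has D' exactly 1
  boundary <- prune_by_dprime(pairs, gm$snps, threshold = 1.0)
  expect_true(all(boundary$retained))
})

test_that("pruning priority decides which cluster member survives", {
  panel <- make_cluster_panel(n_per_group = 800, seed = 37)
  pairs <- ld_pairwise(panel$gm)
  rsids <- panel$gm$snps$rsid
  pruned <- prune_by_dprime(pairs, panel$gm$snps, priority = rev(rsids))
  # the top-priority SNP is always retained
  expect_true(rev(rsids)[1] %in% pruned$rsid[pruned$retained])
  expect_equal(sum(pruned$retained), 13L)
})
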
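# Shared builders and independent oracles for the test suite.

# One-row grouped-counts tibble from explicit triples.
counts_row <- function(rsid = "snp", case_triple, control_triple,
                       minor = "G", major = "A", risk = minor,
                       chromosome = "1", position = 1000L,
                       n_cases_total = sum(case_triple),
                       n_controls_total = sum(control_triple)) {
  tibble::tibble(
    rsid = rsid, gene = NA_character_, chromosome = chromosome,
    position = position, minor_allele = minor, major_allele = major,
    risk_allele = risk,
    case_hom_major = case_triple[1], case_het = case_triple[2],
    case_hom_minor = case_triple[3],
    control_hom_major = control_triple[1], control_het = control_triple[2],
    control_hom_minor = control_triple[3],
    n_cases_total = n_cases_total, n_controls_total = n_controls_total
  )
}

# Expand a grouped-counts table into an individual-level genotype matrix
# (deterministic ordering), for grouped-vs-individual oracle checks.
expand_counts_to_gm <- function(counts) {
  dos <- function(trip) rep(0:2, times = trip)
  cols_ca <- lapply(seq_len(nrow(counts)), function(i) {
    dos(unlist(counts[i, c("case_hom_major", "case_het", "case_hom_minor")]))
  })
  cols_co <- lapply(seq_len(nrow(counts)), function(i) {
    dos(unlist(counts[i, c("control_hom_major", "control_het", "control_hom_minor")]))
  })
  stopifnot(length(unique(lengths(cols_ca))) == 1L,
            length(unique(lengths(cols_co))) == 1L)
  dosage <- rbind(
    do.call(cbind, cols_ca),
    do.call(cbind, cols_co)
  )
  n_ca <- length(cols_ca[[1]])
  n_co <- length(cols_co[[1]])
  genotype_matrix(
    dosage,
    tibble::tibble(
      sample_id = sprintf("s%05d", seq_len(n_ca + n_co)),
      phenotype = rep(c("case", "control"), c(n_ca, n_co))
    ),
    counts[, c("rsid", "chromosome", "position", "minor_allele",
               "major_allele", "risk_allele")]
  )
}

# Independent grid-search maximiser of the observed-data likelihood of a
# two-SNP sample: margins fixed at the observed allele frequencies, grid
# over the one free haplotype frequency, genotype probabilities built by
# explicit enumeration of ordered haplotype pairs (no shared code with the
# EM implementation).
grid_hap_oracle <- function(g1, g2, res = 1e-4) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]
  g2 <- g2[ok]
  fA <- mean(g1) / 2
  fB <- mean(g2) / 2
  pA <- 1 - fA
  pB <- 1 - fB
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  ts <- seq(lo, hi, by = res)
  n33 <- table(factor(g1, 0:2), factor(g2, 0:2))
  minorA <- c(0, 0, 1, 1)
  minorB <- c(0, 1, 0, 1)
  ll <- vapply(ts, function(t) {
    p <- c(t, pA - t, pB - t, 1 - pA - pB + t)
    if (any(p < -1e-12)) return(-Inf)
    p <- pmax(p, 0)
    P <- matrix(0, 3, 3)
    for (a in 1:4) {
      for (b in 1:4) {
        i <- minorA[a] + minorA[b] + 1L
        j <- minorB[a] + minorB[b] + 1L
        P[i, j] <- P[i, j] + p[a] * p[b]
      }
    }
    keep <- n33 > 0
    if (any(P[keep] <= 0)) return(-Inf)
    sum(n33[keep] * log(P[keep]))
  }, numeric(1))
  list(p11 = ts[which.max(ll)], loglik = max(ll))
}

# 34-SNP panel in 13 LD clusters (8 clusters of 3 SNPs + 5 of 2): each
# cluster has an associated tag (per-allele OR 1.8) and haplotype-level
# proxy copies (flip probability 0.01, so within-cluster D' is near 1 and
# between-cluster D' is near 0).
make_cluster_panel <- function(n_per_group = 2500, or = 1.8, seed = 11) {
  sizes <- c(rep(3L, 8), rep(2L, 5))
  spec <- cohort_spec(
    n_per_group, n_per_group,
    tibble::tibble(
      rsid = sprintf("tag%02d", 1:13),
      chromosome = as.character(rep(1:7, length.out = 13)),
      position = 1000000L * (1:13),
      control_raf = seq(0.2, 0.45, length.out = 13),
      or = or
    ),
    seed = seed
  )
  gm <- generate_cohort(spec)
  for (i in seq_len(13)) {
    if (sizes[i] > 1L) {
      gm <- add_ld_proxies(gm, sprintf("tag%02d", i), sizes[i] - 1L,
                           flip_prob = 0.01, seed = 100 + i)
    }
  }
  cluster_of <- sub("_proxy[0-9]+$", "", gm$snps$rsid)
  list(gm = gm, cluster_of = stats::setNames(cluster_of, gm$snps$rsid))
}

# Two-sided Monte-Carlo permutation p for the Cochran-Armitage trend
# statistic on a 2xk counts tibble (quartile, n_cases, n_controls).
ca_permutation_p <- function(tab, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  k <- nrow(tab)
  nn <- tab$n_cases + tab$n_controls
  svec <- rep(seq_len(k), times = nn)
  N <- length(svec)
  R <- sum(tab$n_cases)
  t_obs <- sum(seq_len(k) * (tab$n_cases - nn * R / N))
  const <- R * sum(svec) / N
  t_perm <- replicate(n_perm, sum(svec[sample.int(N, R)]) - const)
  mean(abs(t_perm) >= abs(t_obs) - 1e-9)
}
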
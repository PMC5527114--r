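# Seeded synthetic case-control cohorts.  Controls are drawn from
# Hardy-Weinberg genotype proportions at a specified control risk-allele
# frequency; cases from the exponential-tilt distribution
# P_case(g) %propto% P_control(g) * OR^g, which makes the additive logistic
# odds ratio on the resulting grouped data equal the specified OR by
# construction.  LD structure comes either from shared haplotype pools
# (phenotype-neutral blocks) or from haplotype-level proxy copies of a tag
# SNP (LD clusters that carry the tag's association).

#' Specify a synthetic case-control cohort
#'
#' Each SNP is parameterised either by (`control_raf`, `or`): control
#' risk-allele frequency under Hardy-Weinberg proportions plus a per-allele
#' odds ratio; or by explicit genotype-probability triples `case_probs` /
#' `control_probs` (list-columns, ordered major-hom / het / minor-hom).
#'
#' @param n_cases,n_controls cohort sizes.
#' @param snps tibble with one row per SNP.  Recognised columns: `rsid`,
#'   `chromosome`, `position`, `minor_allele`, `major_allele`,
#'   `risk_allele`, `control_raf`, `or`, `case_probs`, `control_probs`.
#'   Missing identity columns are filled with defaults (risk allele
#'   defaults to the minor allele).
#' @param ld_blocks optional list of blocks, each
#'   `list(snps = <rsids or indices>, hap_freqs = <numeric 2^k>)`: member
#'   SNPs are drawn as two haplotypes per individual from the pool (same
#'   pool in cases and controls).  Haplotype order: binary over member
#'   SNPs, minor allele = 1, last SNP fastest (e.g. for 2 SNPs:
#'   maj-maj, maj-min, min-maj, min-min).
#' @param missing_rate per-cell missingness probability in `[0, 1]`.
#' @param seed integer master seed; the generator is fully reproducible
#'   and per-SNP streams are stable under panel extension.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, snps, ld_blocks = NULL,
                        missing_rate = 0, seed = 1L) {
  if (!is_count(n_cases) || n_cases < 1 || !is_count(n_controls) || n_controls < 1) {
    stop_validation("cohort sizes must be positive integers.")
  }
  if (!is_prob(missing_rate)) stop_validation("`missing_rate` must be in [0, 1].")
  snps <- as_tibble(snps)
  p <- nrow(snps)
  if (p == 0L) stop_validation("at least one SNP specification required.")
  if (!("rsid" %in% names(snps))) snps$rsid <- sprintf("snp_%03d", seq_len(p))
  if (!("chromosome" %in% names(snps))) snps$chromosome <- "1"
  if (!("position" %in% names(snps))) snps$position <- 1000000L * seq_len(p)
  if (!("minor_allele" %in% names(snps))) snps$minor_allele <- "G"
  if (!("major_allele" %in% names(snps))) snps$major_allele <- "A"
  if (!("risk_allele" %in% names(snps))) snps$risk_allele <- snps$minor_allele
  if (!("gene" %in% names(snps))) snps$gene <- NA_character_

  explicit <- "case_probs" %in% names(snps) && "control_probs" %in% names(snps)
  if (!explicit && !all(c("control_raf", "or") %in% names(snps))) {
    stop_validation("snps need either (control_raf, or) or (case_probs, control_probs).")
  }
  if (!explicit) {
    if (any(snps$control_raf <= 0 | snps$control_raf >= 1)) {
      stop_validation("control_raf must lie strictly in (0, 1) under OR parameterisation.")
    }
    if (any(snps$or <= 0)) stop_validation("odds ratios must be positive.")
  } else {
    for (i in seq_len(p)) {
      for (col in c("case_probs", "control_probs")) {
        pr <- snps[[col]][[i]]
        if (length(pr) != 3L || any(pr < 0) || abs(sum(pr) - 1) > 1e-12) {
          stop_validation(sprintf("%s for SNP %d must be a probability triple summing to 1.", col, i))
        }
      }
    }
  }
  if (!is.null(ld_blocks)) {
    for (b in ld_blocks) {
      k <- length(b$snps)
      if (k < 2L) stop_validation("an LD block needs at least 2 SNPs.")
      if (length(b$hap_freqs) != 2^k || any(b$hap_freqs < 0) ||
          abs(sum(b$hap_freqs) - 1) > 1e-12) {
        stop_validation("block haplotype frequencies must be 2^k values summing to 1.")
      }
    }
  }
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      snps = snps, ld_blocks = ld_blocks, explicit = explicit,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Case/control genotype probabilities on the minor-allele dosage scale for
# one OR-parameterised SNP.
tilt_probs <- function(control_raf, or, risk_is_minor) {
  f <- control_raf
  ctrl <- c((1 - f)^2, 2 * f * (1 - f), f^2)      # risk dosage 0,1,2
  case <- ctrl * or^(0:2)
  case <- case / sum(case)
  if (!risk_is_minor) {
    ctrl <- rev(ctrl)
    case <- rev(case)
  }
  list(control = ctrl, case = case)               # minor dosage 0,1,2
}

#' Generate a synthetic case-control cohort
#'
#' Draws genotypes per the specification (see [cohort_spec()]); block
#' members are drawn jointly from their haplotype pool, all other SNPs
#' independently.  Missingness is applied independently per cell.
#' Bit-identical output for identical specifications.
#'
#' @param spec a [cohort_spec()].
#' @return a [genotype_matrix()] with cases first.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- nrow(spec$snps)
  n_ca <- spec$n_cases
  n_co <- spec$n_controls
  n <- n_ca + n_co
  # Two sub-seeds per SNP (genotypes, missingness); block draws use the
  # genotype seed of their first member.
  seeds <- matrix(derive_seeds(spec$seed, 2L * p), nrow = 2L)
  dosage <- matrix(NA_integer_, n, p)

  in_block <- rep(FALSE, p)
  if (!is.null(spec$ld_blocks)) {
    for (b in spec$ld_blocks) {
      idx <- if (is.character(b$snps)) match(b$snps, spec$snps$rsid) else as.integer(b$snps)
      if (anyNA(idx)) stop_validation("block references an unknown SNP.")
      in_block[idx] <- TRUE
      k <- length(idx)
      # Haplotype h (1..2^k) carries minor allele at member j iff bit j is
      # set reading from the left (last SNP varies fastest).
      pat <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
      set.seed(seeds[1, idx[1]])
      h1 <- sample.int(2^k, n, replace = TRUE, prob = b$hap_freqs)
      h2 <- sample.int(2^k, n, replace = TRUE, prob = b$hap_freqs)
      dosage[, idx] <- pat[h1, , drop = FALSE] + pat[h2, , drop = FALSE]
    }
  }

  for (j in seq_len(p)) {
    if (in_block[j]) next
    set.seed(seeds[1, j])
    if (spec$explicit) {
      pr_ca <- spec$snps$case_probs[[j]]
      pr_co <- spec$snps$control_probs[[j]]
    } else {
      risk_is_minor <- spec$snps$risk_allele[j] == spec$snps$minor_allele[j]
      pr <- tilt_probs(spec$snps$control_raf[j], spec$snps$or[j], risk_is_minor)
      pr_ca <- pr$case
      pr_co <- pr$control
    }
    dosage[seq_len(n_ca), j] <- sample(0:2, n_ca, replace = TRUE, prob = pr_ca)
    dosage[n_ca + seq_len(n_co), j] <- sample(0:2, n_co, replace = TRUE, prob = pr_co)
  }

  if (spec$missing_rate > 0) {
    for (j in seq_len(p)) {
      set.seed(seeds[2, j])
      dosage[runif(n) < spec$missing_rate, j] <- NA_integer_
    }
  }

  samples <- tibble(
    sample_id = c(sprintf("case_%05d", seq_len(n_ca)),
                  sprintf("control_%05d", seq_len(n_co))),
    phenotype = c(rep("case", n_ca), rep("control", n_co))
  )
  snp_cols <- c("rsid", "chromosome", "position", "minor_allele",
                "major_allele", "risk_allele", "gene")
  genotype_matrix(dosage, samples, spec$snps[, snp_cols])
}

#' Generate an unphased two-SNP sample from haplotype frequencies
#'
#' Each individual is the union of two independently drawn haplotypes, so
#' the genotype distribution is the random-union-of-gametes model the EM
#' estimator assumes.
#'
#' @param hap_freqs numeric four-vector `(p11, p12, p21, p22)` (allele 1 =
#'   major at each locus) summing to 1.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with two SNPs (`snp_a`, `snp_b`); all
#'   samples are labelled controls (the draw is phenotype-free).
#' @export
generate_ld_pair <- function(hap_freqs, n, seed = 1L) {
  if (length(hap_freqs) != 4L || any(hap_freqs < 0) ||
      abs(sum(hap_freqs) - 1) > 1e-12) {
    stop_validation("`hap_freqs` must be 4 non-negative values summing to 1.")
  }
  if (!is_count(n) || n < 1) stop_validation("`n` must be a positive integer.")
  # Haplotypes 1..4 = (maj,maj), (maj,min), (min,maj), (min,min).
  minor_a <- c(0L, 0L, 1L, 1L)
  minor_b <- c(0L, 1L, 0L, 1L)
  set.seed(as.integer(seed))
  h1 <- sample.int(4L, n, replace = TRUE, prob = hap_freqs)
  h2 <- sample.int(4L, n, replace = TRUE, prob = hap_freqs)
  dosage <- cbind(minor_a[h1] + minor_a[h2], minor_b[h1] + minor_b[h2])
  genotype_matrix(
    dosage,
    tibble(sample_id = sprintf("ind_%05d", seq_len(n)), phenotype = "control"),
    tibble(
      rsid = c("snp_a", "snp_b"), chromosome = "1",
      position = c(1000L, 2000L), minor_allele = "G", major_allele = "A"
    )
  )
}

#' Add LD proxy SNPs for a tag SNP
#'
#' Creates `n_proxies` new SNPs in tight LD with an existing tag SNP by
#' copying each of the tag's two haplotype alleles with a small flip
#' probability (haplotype-level copying, so D' stays near 1 while the
#' proxies inherit most of the tag's case-control association).  Used to
#' build panels of associated LD clusters for testing pruning.
#'
#' @param x a [genotype_matrix()].
#' @param tag rsid of the tag SNP.
#' @param n_proxies number of proxies to add.
#' @param flip_prob per-haplotype allele flip probability (default 0.02).
#' @param seed integer seed.
#' @return a [genotype_matrix()] with the proxies inserted after the tag
#'   (positions offset by 500 bp each, rsids `<tag>_proxyN`).
#' @export
add_ld_proxies <- function(x, tag, n_proxies = 1L, flip_prob = 0.02, seed = 1L) {
  stopifnot(inherits(x, "genotype_matrix"))
  j <- match(tag, x$snps$rsid)
  if (is.na(j)) stop_validation(paste0("unknown tag SNP: ", tag))
  if (!is_prob(flip_prob)) stop_validation("`flip_prob` must be in [0, 1].")
  n <- n_samples(x)
  g <- x$dosage[, j]
  # Tag haplotype alleles (phase irrelevant for dosage copying).
  h1 <- as.integer(g >= 1L)
  h2 <- as.integer(g == 2L)
  set.seed(as.integer(seed))
  prox <- matrix(NA_integer_, n, n_proxies)
  for (k in seq_len(n_proxies)) {
    f1 <- runif(n) < flip_prob
    f2 <- runif(n) < flip_prob
    pk <- ifelse(f1, 1L - h1, h1) + ifelse(f2, 1L - h2, h2)
    pk[is.na(g)] <- NA_integer_
    prox[, k] <- pk
  }
  meta <- x$snps[rep(j, n_proxies), ]
  meta$rsid <- paste0(tag, "_proxy", seq_len(n_proxies))
  meta$position <- meta$position + 500L * seq_len(n_proxies)
  dosage <- cbind(
    x$dosage[, seq_len(j), drop = FALSE],
    prox,
    if (j < n_snps(x)) x$dosage[, (j + 1L):n_snps(x), drop = FALSE]
  )
  snps <- dplyr::bind_rows(
    x$snps[seq_len(j), ], meta,
    if (j < n_snps(x)) x$snps[(j + 1L):n_snps(x), ]
  )
  genotype_matrix(dosage, x$samples, snps)
}
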
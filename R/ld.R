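# Pairwise linkage disequilibrium from unphased genotypes: two-locus EM
# haplotype-frequency estimation, Lewontin D' and r-squared, bootstrap
# confidence intervals, Gabriel-style haplotype blocks, and D'-threshold
# pruning to an approximately independent SNP subset.
#
# Haplotype indexing convention: allele 1 = major, allele 2 = minor at each
# locus, so `p11` is the major-major haplotype frequency and the four-vector
# order is (p11, p12, p21, p22) = (maj-maj, maj-min, min-maj, min-min).

# Observed-data log-likelihood of a 3x3 genotype count table given
# haplotype frequencies p = c(p11, p12, p21, p22).
hap_loglik <- function(p, n33) {
  p11 <- p[1]; p12 <- p[2]; p21 <- p[3]; p22 <- p[4]
  # P[g1+1, g2+1]: genotype probabilities under random union of gametes.
  P <- matrix(0, 3, 3)
  P[1, 1] <- p11^2
  P[1, 2] <- 2 * p11 * p12
  P[1, 3] <- p12^2
  P[2, 1] <- 2 * p11 * p21
  P[2, 2] <- 2 * (p11 * p22 + p12 * p21)
  P[2, 3] <- 2 * p12 * p22
  P[3, 1] <- p21^2
  P[3, 2] <- 2 * p21 * p22
  P[3, 3] <- p22^2
  keep <- n33 > 0
  if (any(P[keep] <= 0)) return(-Inf)
  sum(n33[keep] * log(P[keep]))
}

# 3x3 genotype count table (dosage 0..2 at each locus) from two dosage
# vectors, complete cases only.
pair_count_table <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  matrix(tabulate(3L * g1[ok] + g2[ok] + 1L, nbins = 9L), 3, 3, byrow = TRUE)
}

#' EM haplotype-frequency estimation for a SNP pair
#'
#' Maximises the multinomial likelihood of the 3x3 two-locus genotype table
#' under random union of gametes.  Only double heterozygotes are
#' phase-ambiguous; the EM splits them between the coupling (maj-maj /
#' min-min) and repulsion (maj-min / min-maj) phases at their posterior
#' odds each iteration.  Iteration starts from linkage equilibrium at the
#' observed allele frequencies and stops when no haplotype frequency moves
#' by more than `tol` (default 1e-10) or after `max_iter` iterations.
#'
#' @param g1,g2 minor-allele dosage vectors (0/1/2, `NA` missing) of equal
#'   length; individuals missing at either SNP are excluded.
#' @param tol convergence tolerance on the haplotype frequencies.
#' @param max_iter iteration cap.
#' @return an object of class `hap_freqs`: list with `p` (named frequency
#'   vector `p11`, `p12`, `p21`, `p22`), `n` (individuals used), `n_iter`,
#'   `converged`, `loglik`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 10000L) {
  if (length(g1) != length(g2)) stop_validation("dosage vectors differ in length.")
  n33 <- pair_count_table(g1, g2)
  n <- sum(n33)
  if (n == 0L) stop_computation("no complete-case individuals for the pair.")
  fA <- sum(n33 * matrix(0:2, 3, 3)) / (2 * n)        # minor freq, locus A
  fB <- sum(n33 * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (fA <= 0 || fA >= 1 || fB <= 0 || fB >= 1) {
    stop_computation("monomorphic locus; LD undefined.")
  }
  pA <- 1 - fA   # major-allele frequencies
  pB <- 1 - fB
  p_le <- c(p11 = pA * pB, p12 = pA * fB, p21 = fA * pB, p22 = fA * fB)

  # Phase-known haplotype contributions (constant across iterations).
  base <- c(
    p11 = 2 * n33[1, 1] + n33[1, 2] + n33[2, 1],
    p12 = 2 * n33[1, 3] + n33[1, 2] + n33[2, 3],
    p21 = 2 * n33[3, 1] + n33[2, 1] + n33[3, 2],
    p22 = 2 * n33[3, 3] + n33[2, 3] + n33[3, 2]
  )
  n_dh <- n33[2, 2]

  base <- unname(base)
  two_n <- 2 * n
  em_run <- function(p) {
    p <- unname(p)
    iter <- 0L
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      cis <- p[1] * p[4]
      trans <- p[2] * p[3]
      w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
      p_new <- (base + n_dh * c(w, 1 - w, 1 - w, w)) / two_n
      delta <- max(abs(p_new - p))
      p <- p_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    names(p) <- c("p11", "p12", "p21", "p22")
    list(p = p, n_iter = iter, converged = converged, loglik = hap_loglik(p, n33))
  }

  # The exact LE start is a stationary point when the sample is phase-
  # symmetric (e.g. all double heterozygotes), so the EM also runs from a
  # small coupling tilt and a small repulsion tilt; the highest observed-
  # data likelihood wins.  Deterministic tie-break: LE, coupling, repulsion.
  eps <- 0.5 * min(p_le)
  starts <- if (n_dh > 0) {
    list(p_le, p_le + eps * c(1, -1, -1, 1), p_le + eps * c(-1, 1, 1, -1))
  } else {
    list(p_le)   # no phase ambiguity: EM is a single closed-form step
  }
  runs <- lapply(starts, em_run)
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  structure(
    list(p = best$p, n = n, n_iter = best$n_iter, converged = best$converged,
         loglik = best$loglik),
    class = "hap_freqs"
  )
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat(sprintf(
    "<hap_freqs> p11=%.4f p12=%.4f p21=%.4f p22=%.4f (n=%d, %d EM iterations)\n",
    x$p[1], x$p[2], x$p[3], x$p[4], x$n, x$n_iter
  ))
  invisible(x)
}

#' Lewontin D', r-squared, and D from haplotype frequencies
#'
#' `D = p11 - pA * pB` (major-allele margins); `D' = |D| / Dmax` with
#' `Dmax = min(pA * qB, qA * pB)` for positive D and
#' `min(pA * pB, qA * qB)` for negative D; `r2 = D^2 / (pA qA pB qB)`.
#' The sign of D is reported separately from the normalised `d_prime`.
#'
#' @param haps a `hap_freqs` object or a numeric four-vector
#'   `(p11, p12, p21, p22)` summing to 1.
#' @return a one-row tibble with `D`, `d_prime`, `r2`.
#' @export
ld_statistics <- function(haps) {
  p <- if (inherits(haps, "hap_freqs")) haps$p else haps
  if (length(p) != 4L || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop_validation("haplotype frequencies must be 4 non-negative values summing to 1.")
  }
  p <- pmax(as.numeric(p), 0)
  pA <- p[1] + p[2]
  pB <- p[1] + p[3]
  qA <- 1 - pA
  qB <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop_computation("marginal allele frequency 0 or 1; LD undefined.")
  }
  s <- ld_stats_num(p, pA, pB, qA, qB)
  tibble(D = s[1], d_prime = s[2], r2 = s[3])
}

# Bare-numeric D / D' / r2 (hot path for the bootstrap).
ld_stats_num <- function(p, pA, pB, qA, qB) {
  D <- p[1] - pA * pB
  if (D == 0) return(c(0, 0, 0))
  d_max <- if (D > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  c(D, min(abs(D) / d_max, 1), min(D^2 / (pA * qA * pB * qB), 1))
}

#' Percentile bootstrap confidence interval for D'
#'
#' Resamples individuals with replacement, re-runs the EM, and returns the
#' percentile interval of D'.  Resamples in which either locus comes out
#' monomorphic carry no LD information and are redrawn (the count is
#' reported).
#'
#' @param g1,g2 minor-allele dosage vectors.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param level interval level (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @return a one-row tibble: `ci_low`, `ci_high`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_dprime_ci <- function(g1, g2, n_boot = 1000L, level = 0.95,
                                seed = NULL) {
  if (!is_count(n_boot) || n_boot < 100) {
    stop_validation("`n_boot` must be an integer >= 100.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]
  g2 <- g2[ok]
  n <- length(g1)
  if (n == 0L) stop_computation("no complete-case individuals for the pair.")
  dp <- numeric(n_boot)
  n_redrawn <- 0L
  max_attempts <- 100L * n_boot
  b <- 0L
  while (b < n_boot) {
    if (n_redrawn + n_boot > max_attempts) {
      stop_computation("too many degenerate bootstrap resamples.")
    }
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      em_haplotype_freqs(g1[idx], g2[idx]),
      snpgrs_computation_error = function(e) NULL
    )
    if (is.null(est)) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    b <- b + 1L
    pA <- est$p[1] + est$p[2]
    pB <- est$p[1] + est$p[3]
    dp[b] <- ld_stats_num(unname(est$p), pA, pB, 1 - pA, 1 - pB)[2]
  }
  alpha <- (1 - level) / 2
  qs <- quantile(dp, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble(ci_low = qs[1], ci_high = qs[2], n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Pairwise LD for all within-chromosome SNP pairs
#'
#' Runs the two-locus EM on every pair of SNPs sharing a chromosome
#' (physical linkage only; cross-chromosome pairs are treated as D' = 0 by
#' the pruning stage and are not enumerated here).  Pairs are ordered by
#' position within chromosome.
#'
#' @param x a [genotype_matrix()].
#' @param group which samples to use: `"pooled"` (default), `"cases"`, or
#'   `"controls"`.
#' @param n_boot if > 0, a percentile bootstrap CI for D' is attached to
#'   every pair (needed by [build_blocks()]).
#' @param level CI level.
#' @param seed integer seed used when `n_boot > 0`.
#' @return a long tibble: `rsid_a`, `rsid_b`, `chromosome`, `n`, `D`,
#'   `d_prime`, `r2` (and `ci_low`, `ci_high` when bootstrapped).  Pairs
#'   with a monomorphic member have `NA` statistics.
#' @export
ld_pairwise <- function(x, group = c("pooled", "cases", "controls"),
                        n_boot = 0L, level = 0.95, seed = 1L) {
  stopifnot(inherits(x, "genotype_matrix"))
  group <- match.arg(group)
  keep <- switch(group,
    pooled = rep(TRUE, n_samples(x)),
    cases = x$samples$phenotype == "case",
    controls = x$samples$phenotype == "control"
  )
  d <- x$dosage[keep, , drop = FALSE]
  snps <- x$snps
  pair_seeds <- if (n_boot > 0) derive_seeds(seed, n_snps(x)^2) else NULL
  out <- list()
  k <- 0L
  for (chrom in unique(snps$chromosome)) {
    idx <- which(snps$chromosome == chrom)
    idx <- idx[order(snps$position[idx])]
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1L), length(idx))) {
        i <- idx[a]
        j <- idx[b]
        k <- k + 1L
        est <- tryCatch(
          em_haplotype_freqs(d[, i], d[, j]),
          snpgrs_computation_error = function(e) NULL
        )
        if (is.null(est)) {
          row <- tibble(
            rsid_a = snps$rsid[i], rsid_b = snps$rsid[j], chromosome = chrom,
            n = sum(!is.na(d[, i]) & !is.na(d[, j])),
            D = NA_real_, d_prime = NA_real_, r2 = NA_real_
          )
          if (n_boot > 0) {
            row$ci_low <- NA_real_
            row$ci_high <- NA_real_
          }
        } else {
          stats <- ld_statistics(est)
          row <- tibble(
            rsid_a = snps$rsid[i], rsid_b = snps$rsid[j], chromosome = chrom,
            n = est$n, D = stats$D, d_prime = stats$d_prime, r2 = stats$r2
          )
          if (n_boot > 0) {
            ci <- bootstrap_dprime_ci(d[, i], d[, j], n_boot = n_boot,
                                      level = level,
                                      seed = pair_seeds[(i - 1L) * n_snps(x) + j])
            row$ci_low <- ci$ci_low
            row$ci_high <- ci$ci_high
          }
        }
        out[[k]] <- row
      }
    }
  }
  if (k == 0L) {
    return(tibble(
      rsid_a = character(), rsid_b = character(), chromosome = character(),
      n = integer(), D = numeric(), d_prime = numeric(), r2 = numeric()
    ))
  }
  dplyr::bind_rows(out)
}

#' Gabriel-style haplotype blocks from bootstrap D' intervals
#'
#' Classifies each within-chromosome pair by its D' confidence interval:
#' "strong LD" when the lower bound is at least `strong_low` and the upper
#' bound at least `strong_high`; "strong evidence of recombination" when
#' the upper bound is below `recomb_high`; otherwise uninformative.
#' Maximal position-ordered intervals in which at least
#' `min_informative_frac` of informative pairs are strong-LD become
#' blocks (two SNPs minimum; non-overlapping, never spanning chromosomes).
#'
#' @param pairs pairwise LD tibble from [ld_pairwise()] with `ci_low` and
#'   `ci_high` columns.
#' @param snps SNP metadata tibble (`rsid`, `chromosome`, `position`).
#' @param strong_low,strong_high,recomb_high CI thresholds (defaults 0.70,
#'   0.98, 0.90).
#' @param min_informative_frac minimum fraction of informative pairs in
#'   strong LD (default 0.95).
#' @return a tibble of blocks: `chromosome`, `start_pos`, `end_pos`,
#'   `n_snps`, `rsids` (comma-separated).
#' @export
build_blocks <- function(pairs, snps, strong_low = 0.70, strong_high = 0.98,
                         recomb_high = 0.90, min_informative_frac = 0.95) {
  if (!all(c("ci_low", "ci_high") %in% names(pairs))) {
    stop_validation("`pairs` needs bootstrap CI columns; run ld_pairwise(n_boot > 0).")
  }
  pairs <- pairs |>
    dplyr::mutate(
      strong = !is.na(.data$ci_low) & .data$ci_low >= strong_low &
        .data$ci_high >= strong_high,
      recomb = !is.na(.data$ci_high) & .data$ci_high < recomb_high,
      informative = .data$strong | .data$recomb
    )
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  lut_strong <- stats::setNames(pairs$strong, key(pairs$rsid_a, pairs$rsid_b))
  lut_inform <- stats::setNames(pairs$informative, key(pairs$rsid_a, pairs$rsid_b))

  blocks <- list()
  for (chrom in unique(snps$chromosome)) {
    sub <- snps[snps$chromosome == chrom, ]
    sub <- sub[order(sub$position), ]
    m <- nrow(sub)
    if (m < 2L) next
    cand <- list()
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        ids <- sub$rsid[i:j]
        kk <- utils::combn(ids, 2L)
        keys <- key(kk[1, ], kk[2, ])
        inf <- lut_inform[keys]
        str <- lut_strong[keys]
        inf[is.na(inf)] <- FALSE
        str[is.na(str)] <- FALSE
        n_inf <- sum(inf)
        if (n_inf == 0L) next
        # Outermost pair must itself be strong LD (Gabriel-style rule).
        outer_strong <- isTRUE(unname(lut_strong[key(ids[1], ids[length(ids)])]))
        if (sum(str) / n_inf >= min_informative_frac && outer_strong) {
          cand[[length(cand) + 1L]] <- list(i = i, j = j, ids = ids)
        }
      }
    }
    if (!length(cand)) next
    len <- vapply(cand, function(cc) cc$j - cc$i, integer(1))
    cand <- cand[order(-len, vapply(cand, `[[`, integer(1), "i"))]
    used <- rep(FALSE, m)
    for (cc in cand) {
      span <- cc$i:cc$j
      if (any(used[span])) next
      used[span] <- TRUE
      blocks[[length(blocks) + 1L]] <- tibble(
        chromosome = chrom,
        start_pos = sub$position[cc$i],
        end_pos = sub$position[cc$j],
        n_snps = length(span),
        rsids = paste(cc$ids, collapse = ",")
      )
    }
  }
  if (!length(blocks)) {
    return(tibble(
      chromosome = character(), start_pos = integer(), end_pos = integer(),
      n_snps = integer(), rsids = character()
    ))
  }
  out <- dplyr::bind_rows(blocks)
  out[order(match(out$chromosome, unique(snps$chromosome)), out$start_pos), ]
}

#' Greedy D'-threshold LD pruning
#'
#' Iterates SNPs in priority order and retains a SNP iff its D' with every
#' already-retained SNP is at most `threshold`.  Pairs on different
#' chromosomes (or absent from `pairs`) are treated as D' = 0 (physical
#' linkage only), and `NA` D' (monomorphic member) likewise.  Deterministic
#' given the priority ordering.
#'
#' @param pairs pairwise LD tibble from [ld_pairwise()].
#' @param snps SNP metadata tibble (or an `assoc_table`) giving the
#'   candidate `rsid`s.
#' @param threshold D' cut-off (default 0.8): retain only pairs at or below
#'   it.
#' @param priority character vector of rsids in keep-first order, or a
#'   named numeric vector (e.g. additive p-values) sorted ascending.
#'   Defaults to the row order of `snps`.
#' @return a tibble with `rsid`, `retained`, and `pruned_by` (the retained
#'   SNP that excluded it, `NA` if retained).
#' @export
prune_by_dprime <- function(pairs, snps, threshold = 0.8, priority = NULL) {
  rsids <- snps$rsid
  if (is.null(priority)) {
    ord <- rsids
  } else if (is.numeric(priority)) {
    if (is.null(names(priority))) stop_validation("numeric `priority` must be named by rsid.")
    ord <- names(sort(priority))
  } else {
    ord <- as.character(priority)
  }
  ord <- ord[ord %in% rsids]
  if (!setequal(ord, rsids)) {
    stop_validation("`priority` must cover every candidate SNP exactly once.")
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  dp <- stats::setNames(pairs$d_prime, key(pairs$rsid_a, pairs$rsid_b))
  retained <- character(0)
  pruned_by <- stats::setNames(rep(NA_character_, length(rsids)), rsids)
  for (s in ord) {
    if (length(retained)) {
      d <- dp[key(s, retained)]
      d[is.na(d)] <- 0   # cross-chromosome / missing / monomorphic pairs
      hit <- which(d > threshold)
      if (length(hit)) {
        pruned_by[s] <- retained[hit[1]]
        next
      }
    }
    retained <- c(retained, s)
  }
  tibble(
    rsid = rsids,
    retained = rsids %in% retained,
    pruned_by = unname(pruned_by[rsids])
  )
}

#' Write a pairwise LD matrix TSV (long format)
#'
#' @param pairs tibble from [ld_pairwise()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_report <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}
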
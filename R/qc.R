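# Per-SNP quality control: call rate, designated-allele frequency,
# Hardy-Weinberg goodness-of-fit in controls, and inclusion filters.

#' QC thresholds
#'
#' Default inclusion filters for candidate-SNP panels: minor-allele
#' frequency in controls of at least 5%, total genotyping call rate of at
#' least 95%, and a control Hardy-Weinberg goodness-of-fit p-value of at
#' least 0.05.
#'
#' @param min_maf minimum control minor-allele frequency (of the rarer
#'   allele), in `[0, 1]`.
#' @param min_call_rate minimum combined call rate, in `[0, 1]`.
#' @param min_hwe_p minimum control HWE p-value, in `[0, 1]`.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.05, min_call_rate = 0.95, min_hwe_p = 0.05) {
  for (v in c(min_maf, min_call_rate, min_hwe_p)) {
    if (!is_prob(v)) stop_validation("QC thresholds must be single values in [0, 1].")
  }
  structure(
    list(min_maf = min_maf, min_call_rate = min_call_rate, min_hwe_p = min_hwe_p),
    class = "qc_thresholds"
  )
}

#' Genotyping call rate from grouped counts
#'
#' @param counts a counts table (see [collapse_to_counts()]) with cohort
#'   totals `n_cases_total`, `n_controls_total` (overridden by the explicit
#'   arguments when supplied).
#' @param n_total_cases,n_total_controls optional cohort sizes.
#' @return `counts` with columns `call_rate_cases`, `call_rate_controls`,
#'   `call_rate_total` appended.
#' @export
call_rate <- function(counts, n_total_cases = NULL, n_total_controls = NULL) {
  check_counts_tbl(counts)
  n_ca <- n_total_cases %||% counts$n_cases_total
  n_co <- n_total_controls %||% counts$n_controls_total
  if (is.null(n_ca) || is.null(n_co)) {
    stop_validation("cohort totals required (columns or arguments).")
  }
  g_ca <- rowSums(as.matrix(counts[CASE_COUNT_COLS]))
  g_co <- rowSums(as.matrix(counts[CONTROL_COUNT_COLS]))
  if (any(g_ca > n_ca) || any(g_co > n_co)) {
    stop_validation("genotyped counts exceed cohort totals.")
  }
  counts$call_rate_cases <- ifelse(n_ca > 0, g_ca / n_ca, 0)
  counts$call_rate_controls <- ifelse(n_co > 0, g_co / n_co, 0)
  counts$call_rate_total <- ifelse(n_ca + n_co > 0, (g_ca + g_co) / (n_ca + n_co), 0)
  counts
}

#' Frequency of the designated minor allele from a genotype count triple
#'
#' `(het + 2 * hom_minor) / (2 * n)`.  Because the designation is external
#' (a reference panel's minor allele), the result may exceed 0.5.
#'
#' @param hom_major,het,hom_minor genotype counts (vectorised).
#' @return numeric vector of allele frequencies.
#' @export
designated_allele_frequency <- function(hom_major, het, hom_minor) {
  n <- hom_major + het + hom_minor
  if (any(n <= 0)) stop_validation("allele frequency undefined for empty count triple.")
  (het + 2 * hom_minor) / (2 * n)
}

#' Hardy-Weinberg goodness-of-fit test
#'
#' One-degree-of-freedom Pearson chi-square comparing an observed genotype
#' count triple with the counts expected under Hardy-Weinberg proportions
#' at the observed allele frequency.  No continuity correction.
#' Monomorphic triples return chi-square 0, p 1.
#'
#' @param hom_major,het,hom_minor genotype counts (vectorised).
#' @return a tibble with columns `chi2` and `p`.
#' @export
hwe_chisq_test <- function(hom_major, het, hom_minor) {
  n <- hom_major + het + hom_minor
  if (any(n <= 0)) stop_validation("HWE test undefined for empty count triple.")
  q <- (het + 2 * hom_minor) / (2 * n)
  p1 <- 1 - q
  chi2 <- numeric(length(n))
  for (i in seq_along(n)) {
    if (q[i] <= 0 || q[i] >= 1) {
      chi2[i] <- 0
      next
    }
    expected <- n[i] * c(p1[i]^2, 2 * p1[i] * q[i], q[i]^2)
    observed <- c(hom_major[i], het[i], hom_minor[i])
    chi2[i] <- sum((observed - expected)^2 / expected)
  }
  tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-SNP QC summary
#'
#' Computes, for every SNP in a grouped-counts table, the case/control and
#' combined call rates, the control-cohort frequency of the designated
#' minor allele, and the Hardy-Weinberg goodness-of-fit test in controls
#' (reported for cases too, but cases never filter), then applies the
#' inclusion thresholds.
#'
#' @param counts a counts table from [collapse_to_counts()].
#' @param thresholds a [qc_thresholds()] object.
#' @return a tibble, one row per SNP, with QC statistics, `passed`, and
#'   `fail_reasons` (comma-separated among `maf`, `call_rate`, `hwe`).
#' @export
snp_qc <- function(counts, thresholds = qc_thresholds()) {
  check_counts_tbl(counts)
  counts <- call_rate(counts)
  co <- as.matrix(counts[CONTROL_COUNT_COLS])
  ca <- as.matrix(counts[CASE_COUNT_COLS])
  n_co <- rowSums(co)
  n_ca <- rowSums(ca)
  maf <- ifelse(n_co > 0,
                (co[, 2] + 2 * co[, 3]) / (2 * pmax(n_co, 1)), NA_real_)
  # Zero-count groups (e.g. a control-only cohort's cases) get NA rather
  # than an error; the control HWE filter then fails such SNPs explicitly.
  hwe_safe <- function(m) {
    ok <- rowSums(m) > 0
    out <- tibble(chi2 = rep(NA_real_, nrow(m)), p = rep(NA_real_, nrow(m)))
    if (any(ok)) {
      h <- hwe_chisq_test(m[ok, 1], m[ok, 2], m[ok, 3])
      out$chi2[ok] <- h$chi2
      out$p[ok] <- h$p
    }
    out
  }
  hwe_co <- hwe_safe(co)
  hwe_ca <- hwe_safe(ca)
  out <- counts |>
    dplyr::select(dplyr::any_of(c(
      "rsid", "gene", "chromosome", "position", "minor_allele", "major_allele"
    ))) |>
    dplyr::mutate(
      n_case_genotyped = n_ca,
      n_control_genotyped = n_co,
      call_rate_cases = counts$call_rate_cases,
      call_rate_controls = counts$call_rate_controls,
      call_rate_total = counts$call_rate_total,
      maf_controls = maf,
      hwe_chi2_controls = hwe_co$chi2,
      hwe_p_controls = hwe_co$p,
      hwe_p_cases = hwe_ca$p
    )
  flag_qc(out, thresholds)
}

# Apply thresholds to a QC stats tibble; fills passed/fail_reasons.
flag_qc <- function(qc, thresholds) {
  maf_rare <- pmin(qc$maf_controls, 1 - qc$maf_controls)
  fail_maf <- is.na(maf_rare) | maf_rare < thresholds$min_maf
  fail_cr <- qc$call_rate_total < thresholds$min_call_rate
  fail_hwe <- is.na(qc$hwe_p_controls) | qc$hwe_p_controls < thresholds$min_hwe_p
  reasons <- purrr::pmap_chr(
    list(fail_maf, fail_cr, fail_hwe),
    function(m, c, h) paste(c("maf"[m], "call_rate"[c], "hwe"[h]), collapse = ",")
  )
  qc$passed <- !(fail_maf | fail_cr | fail_hwe)
  qc$fail_reasons <- ifelse(qc$passed, "", reasons)
  qc
}

#' Apply (or re-apply) QC inclusion filters
#'
#' A SNP passes iff its control MAF (of the rarer allele), combined call
#' rate, and control HWE p all meet the thresholds.  Every failure reason
#' is recorded, not just the first.  Works on any tibble carrying
#' `maf_controls`, `call_rate_total`, and `hwe_p_controls`, so published
#' QC summaries can be re-filtered without genotype data.
#'
#' @param results a QC tibble (from [snp_qc()] or equivalent).
#' @param thresholds a [qc_thresholds()] object.
#' @return a list with `passed` (character vector of retained rsids) and
#'   `report` (the tibble with refreshed `passed`/`fail_reasons`).
#' @export
apply_qc_filters <- function(results, thresholds = qc_thresholds()) {
  need <- c("rsid", "maf_controls", "call_rate_total", "hwe_p_controls")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    stop_validation(paste0("QC table missing columns: ", paste(miss, collapse = ", ")))
  }
  report <- flag_qc(results, thresholds)
  list(passed = report$rsid[report$passed], report = report)
}

#' Write a QC report TSV
#'
#' @param qc a QC tibble from [snp_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  out <- qc |>
    dplyr::mutate(
      maf_controls_pct = round(100 * .data$maf_controls, 1),
      call_rate_pct = round(100 * .data$call_rate_total, 1)
    ) |>
    dplyr::select(dplyr::any_of(c(
      "rsid", "gene", "chromosome", "position", "minor_allele",
      "maf_controls_pct", "call_rate_pct", "hwe_p_controls",
      "passed", "fail_reasons"
    )))
  readr::write_tsv(out, path)
  invisible(path)
}
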
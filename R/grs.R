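# Weighted genetic risk scores: per-individual risk-allele dosage sums
# weighted by per-SNP log odds ratios, quartile partition, per-quartile
# odds ratios against the lowest quartile, and the Cochran-Armitage trend
# test.

#' Risk-weight table from an association scan
#'
#' Extracts the per-SNP weights (natural-log odds ratio per risk allele)
#' from an association table, the standard weighting for a weighted
#' genetic risk score.
#'
#' @param assoc an `assoc_table` from [association_table()] (or any tibble
#'   with `rsid`, `risk_allele`, and either `beta` or `or`).
#' @return a tibble `rsid`, `risk_allele`, `log_or`.
#' @export
risk_weights <- function(assoc) {
  if (!all(c("rsid", "risk_allele") %in% names(assoc))) {
    stop_validation("need columns `rsid` and `risk_allele`.")
  }
  w <- if ("beta" %in% names(assoc)) assoc$beta else log(assoc$or)
  if (any(!is.finite(w))) {
    stop_validation(paste0(
      "non-finite weight for: ", paste(assoc$rsid[!is.finite(w)], collapse = ", ")
    ))
  }
  tibble(rsid = assoc$rsid, risk_allele = assoc$risk_allele, log_or = w)
}

#' Per-individual weighted genetic risk score
#'
#' For each sample, sums risk-allele dosages (0/1/2) over the weighted SNP
#' panel, weighted by per-SNP log odds ratios:
#' `raw = sum_i w_i x_i`.  The `rescaled` convention maps the score to the
#' allele-count scale, `raw * K / sum_i w_i` with `K` the number of SNPs,
#' so a sample heterozygous at every SNP scores exactly `K`; it is
#' invariant to rescaling all weights by a constant.
#'
#' Missing dosages are, by default, replaced by their expectation
#' `2 * f_risk` using the control-cohort risk-allele frequency
#' (`missing_policy = "impute"`); `"complete"` drops them and rescales by
#' the per-sample observed weight sum.  Samples missing more than half of
#' the panel are flagged `unreliable`.
#'
#' @param x a [genotype_matrix()] covering every weighted SNP.
#' @param weights a risk-weight table (see [risk_weights()]).
#' @param convention `"rescaled"` (default) or `"raw"`; both columns are
#'   always returned, the convention selects which one downstream stages
#'   read (recorded in attribute `convention`).
#' @param missing_policy `"impute"` (default) or `"complete"`.
#' @return a tibble of class `grs_scores`: `sample_id`, `phenotype`,
#'   `n_missing`, `unreliable`, `grs_raw`, `grs_rescaled`, `grs` (the
#'   selected convention).
#' @export
weighted_grs <- function(x, weights, convention = c("rescaled", "raw"),
                         missing_policy = c("impute", "complete")) {
  stopifnot(inherits(x, "genotype_matrix"))
  convention <- match.arg(convention)
  missing_policy <- match.arg(missing_policy)
  miss_snp <- setdiff(weights$rsid, x$snps$rsid)
  if (length(miss_snp)) {
    stop_validation(paste0(
      "weighted SNP(s) absent from panel: ", paste(miss_snp, collapse = ", ")
    ))
  }
  idx <- match(weights$rsid, x$snps$rsid)
  K <- length(idx)
  w <- weights$log_or
  d <- x$dosage[, idx, drop = FALSE]
  # Orient to risk-allele dosage.
  flip <- weights$risk_allele == x$snps$major_allele[idx]
  bad <- !flip & weights$risk_allele != x$snps$minor_allele[idx]
  if (any(bad)) {
    stop_validation(paste0(
      "risk allele does not match panel alleles for: ",
      paste(weights$rsid[bad], collapse = ", ")
    ))
  }
  d[, flip] <- 2L - d[, flip, drop = FALSE]

  is_control <- x$samples$phenotype == "control"
  f_risk <- colMeans(d[is_control, , drop = FALSE], na.rm = TRUE) / 2
  f_risk[is.nan(f_risk)] <- 0.5   # no genotyped control: uninformative prior

  n_missing <- unname(rowSums(is.na(d)))
  if (missing_policy == "impute") {
    for (j in seq_len(K)) {
      nas <- is.na(d[, j])
      if (any(nas)) d[nas, j] <- 2 * f_risk[j]
    }
    raw <- as.numeric(d %*% w)
    rescaled <- raw * K / sum(w)
  } else {
    obs <- !is.na(d)
    d0 <- d
    d0[!obs] <- 0
    raw <- as.numeric(d0 %*% w)
    w_obs <- as.numeric(obs %*% w)
    k_obs <- rowSums(obs)
    rescaled <- ifelse(w_obs > 0, raw * k_obs / w_obs, NA_real_)
  }
  out <- tibble(
    sample_id = x$samples$sample_id,
    phenotype = x$samples$phenotype,
    n_missing = n_missing,
    unreliable = n_missing > K / 2,
    grs_raw = raw,
    grs_rescaled = rescaled,
    grs = if (convention == "rescaled") rescaled else raw
  )
  class(out) <- c("grs_scores", class(out))
  attr(out, "convention") <- convention
  attr(out, "n_snps") <- K
  out
}

#' Partition risk scores into quartiles
#'
#' Assigns each sample to a quartile of the weighted score using half-open
#' `(low, high]` intervals (a score exactly on a cut-point falls in the
#' lower quartile).  Cut-points default to the empirical quartiles of the
#' pooled case+control score distribution; explicit cut-points (e.g.
#' published ones) may be supplied instead.
#'
#' @param scores a `grs_scores` tibble (or any tibble with `phenotype` and
#'   a score column).
#' @param cutpoints optional non-decreasing numeric triple `(c1, c2, c3)`.
#' @param score_col name of the score column (default `"grs"`).
#' @return an object of class `grs_quartiles`: list with `cutpoints`,
#'   `computed` (were cut-points estimated?), `data` (scores plus
#'   `quartile`), and `counts` (tibble `quartile`, `n_cases`,
#'   `n_controls`).
#' @export
assign_quartiles <- function(scores, cutpoints = NULL, score_col = "grs") {
  if (!score_col %in% names(scores)) {
    stop_validation(paste0("no score column `", score_col, "`."))
  }
  s <- scores[[score_col]]
  if (any(!is.finite(s))) stop_validation("scores must be finite.")
  computed <- is.null(cutpoints)
  if (computed) {
    if (length(unique(s)) == 1L) {
      stop_computation("constant scores: quartile partition is degenerate.")
    }
    cutpoints <- unname(quantile(s, c(0.25, 0.5, 0.75), type = 7))
  }
  if (length(cutpoints) != 3L || is.unsorted(cutpoints)) {
    stop_validation("`cutpoints` must be a non-decreasing numeric triple.")
  }
  # (low, high] membership; direct comparison (not cut()) so tied
  # cut-points from a discrete score distribution stay well-defined.
  qi <- 1L + (s > cutpoints[1]) + (s > cutpoints[2]) + (s > cutpoints[3])
  data <- scores
  data$quartile <- paste0("Q", qi)
  counts <- tibble(quartile = paste0("Q", 1:4)) |>
    dplyr::left_join(
      data |>
        dplyr::count(.data$quartile, .data$phenotype) |>
        tidyr::pivot_wider(names_from = "phenotype", values_from = "n",
                           values_fill = 0L),
      by = "quartile"
    )
  for (col in c("case", "control")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- tibble(
    quartile = counts$quartile,
    n_cases = as.integer(tidyr::replace_na(counts$case, 0L)),
    n_controls = as.integer(tidyr::replace_na(counts$control, 0L))
  )
  structure(
    list(cutpoints = cutpoints, computed = computed, data = data,
         counts = counts),
    class = "grs_quartiles"
  )
}

#' @export
print.grs_quartiles <- function(x, ...) {
  cat(sprintf(
    "<grs_quartiles> cut-points %s (%s); %d samples\n",
    paste(signif(x$cutpoints, 4), collapse = " / "),
    if (x$computed) "empirical, pooled" else "supplied",
    nrow(x$data)
  ))
  print(x$counts)
  invisible(x)
}

#' Per-quartile odds ratios against the lowest quartile
#'
#' Logistic regression of case status on quartile indicators fitted on the
#' 2x4 phenotype-by-quartile table; the lowest quartile is the reference.
#' Because the design is saturated, each OR equals the closed-form 2x2
#' cross-product ratio against Q1.  Quartiles with an empty case or
#' control cell are flagged and their OR omitted.
#'
#' @param x a `grs_quartiles` object, or a tibble with columns `quartile`,
#'   `n_cases`, `n_controls` (one row per ordered category, reference
#'   first).
#' @return a tibble: `quartile`, `n_cases`, `n_controls`, `reference`,
#'   `or`, `ci_low`, `ci_high`, `p`.
#' @export
quartile_association <- function(x) {
  counts <- if (inherits(x, "grs_quartiles")) x$counts else as_tibble(x)
  need <- c("quartile", "n_cases", "n_controls")
  if (!all(need %in% names(counts))) {
    stop_validation("need columns quartile, n_cases, n_controls.")
  }
  if (counts$n_cases[1] == 0L || counts$n_controls[1] == 0L) {
    stop_validation("reference quartile must contain both cases and controls.")
  }
  empty <- counts$n_cases == 0L | counts$n_controls == 0L
  fit_tbl <- counts[!empty, ]
  fit_tbl$quartile <- factor(fit_tbl$quartile, levels = counts$quartile[!empty])
  fit <- fit_grouped_glm(cbind(n_cases, n_controls) ~ quartile, fit_tbl)
  cf <- unname(coef(fit)[-1])
  se <- unname(sqrt(diag(vcov(fit)))[-1])
  est <- tibble(
    quartile = levels(fit_tbl$quartile)[-1],
    or = exp(unname(cf)),
    ci_low = exp(unname(cf) - Z975 * se),
    ci_high = exp(unname(cf) + Z975 * se),
    p = 2 * pnorm(-abs(unname(cf) / se))
  )
  out <- counts |>
    dplyr::mutate(reference = dplyr::row_number() == 1L) |>
    dplyr::left_join(est, by = "quartile")
  if (any(empty)) {
    warn(paste0(
      "quartile(s) with an empty cell, OR omitted: ",
      paste(counts$quartile[empty], collapse = ", ")
    ))
  }
  out
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportion across ordered categories
#' (default integer scores 1..k).  The statistic is the score-test form
#' `Z = T / sqrt(Var(T))` with `T = sum_i s_i (r_i - n_i R / N)`, reported
#' signed (positive when the case proportion rises with the scores) with a
#' two-sided normal p-value.
#'
#' @param x a 2-row matrix (cases then controls, one column per category),
#'   a `grs_quartiles` object, or a tibble with `n_cases`, `n_controls`.
#' @param scores category scores (default `1:k`).
#' @return an object of class `htest` with the signed `Z` statistic and
#'   two-sided p-value.
#' @export
cochran_armitage_trend <- function(x, scores = NULL) {
  if (inherits(x, "grs_quartiles")) x <- x$counts
  if (is.data.frame(x)) {
    r <- x$n_cases
    nn <- x$n_cases + x$n_controls
  } else {
    x <- as.matrix(x)
    if (nrow(x) != 2L) stop_validation("matrix input must have 2 rows (cases; controls).")
    r <- x[1, ]
    nn <- colSums(x)
  }
  k <- length(r)
  if (k < 2L) stop_validation("need at least 2 ordered categories.")
  if (sum(nn) == 0) stop_validation("all-zero table.")
  s <- scores %||% seq_len(k)
  if (length(s) != k) stop_validation("`scores` length must match category count.")
  N <- sum(nn)
  R <- sum(r)
  T_stat <- sum(s * (r - nn * R / N))
  V <- (R / N) * (1 - R / N) * (sum(nn * s^2) - sum(nn * s)^2 / N)
  if (V <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- T_stat / sqrt(V)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(
      statistic = c(Z = z),
      p.value = p,
      estimate = c(`trend T` = T_stat),
      method = "Cochran-Armitage trend test (two-sided)",
      data.name = deparse(substitute(x))
    ),
    class = "htest"
  )
}

#' @export
tidy.grs_quartiles <- function(x, ...) {
  quartile_association(x)
}

#' @export
glance.grs_quartiles <- function(x, ...) {
  tr <- cochran_armitage_trend(x)
  tibble(
    n = nrow(x$data),
    n_cases = sum(x$counts$n_cases),
    n_controls = sum(x$counts$n_controls),
    cut1 = x$cutpoints[1], cut2 = x$cutpoints[2], cut3 = x$cutpoints[3],
    trend_z = unname(tr$statistic),
    trend_p = tr$p.value
  )
}

#' Write GRS score and quartile report TSVs
#'
#' @param partition a `grs_quartiles` object.
#' @param scores_path,quartiles_path output paths (either may be `NULL`).
#' @return invisibly, a character vector of the paths written.
#' @export
write_grs_report <- function(partition, scores_path = NULL, quartiles_path = NULL) {
  written <- character(0)
  if (!is.null(scores_path)) {
    readr::write_tsv(
      dplyr::select(partition$data, dplyr::any_of(c(
        "sample_id", "phenotype", "grs_raw", "grs_rescaled", "quartile"
      ))),
      scores_path
    )
    written <- c(written, scores_path)
  }
  if (!is.null(quartiles_path)) {
    qa <- quartile_association(partition)
    tr <- cochran_armitage_trend(partition)
    qa$trend_p <- tr$p.value
    readr::write_tsv(qa, quartiles_path)
    written <- c(written, quartiles_path)
  }
  invisible(written)
}
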
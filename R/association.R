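# Single-SNP additive-model association on grouped genotype counts via
# maximum-likelihood logistic regression, the DOMDEV dominance-deviation
# test, and family-wise (Bonferroni) significance handling.

# Exact normal quantile used for 95% Wald intervals (not 1.96 rounded).
Z975 <- stats::qnorm(0.975)

#' Family-wise significance policy
#'
#' Bonferroni handling for the two test families: the additive model scan
#' over the full candidate catalogue and the DOMDEV scan over the SNPs that
#' survive QC.
#'
#' @param alpha family-wise level.
#' @param n_tests_additive number of additive-model tests (default 1033).
#' @param n_tests_domdev number of dominance-deviation tests (default 34).
#' @return a list of class `significance_policy`.
#' @export
significance_policy <- function(alpha = 0.05, n_tests_additive = 1033L,
                                n_tests_domdev = 34L) {
  if (!is_prob(alpha) || alpha <= 0) stop_validation("`alpha` must be in (0, 1].")
  if (!is_count(n_tests_additive) || n_tests_additive < 1 ||
      !is_count(n_tests_domdev) || n_tests_domdev < 1) {
    stop_validation("test counts must be positive integers.")
  }
  structure(
    list(
      alpha = alpha,
      n_tests_additive = as.integer(n_tests_additive),
      n_tests_domdev = as.integer(n_tests_domdev)
    ),
    class = "significance_policy"
  )
}

#' Bonferroni significance threshold
#'
#' @param policy a [significance_policy()].
#' @param family `"additive"` or `"domdev"`.
#' @return `alpha / n_tests` for the chosen family.
#' @export
bonferroni_threshold <- function(policy = significance_policy(),
                                 family = c("additive", "domdev")) {
  family <- match.arg(family)
  n <- switch(family,
    additive = policy$n_tests_additive,
    domdev = policy$n_tests_domdev
  )
  policy$alpha / n
}

# Grouped binomial logistic fit of phenotype on dosage.
# `df` has columns dosage (0/1/2), case_n, control_n.  Returns the glm.
fit_grouped_glm <- function(formula, df) {
  glm(formula, family = binomial(), data = df,
      control = glm.control(epsilon = 1e-10, maxit = 200))
}

# Orient one counts row to risk-allele dosage; returns df(dosage, case_n,
# control_n) plus the risk allele used.  When risk_allele is NA the minor
# allele is tried first and flipped if the fitted slope is negative, so the
# reported risk allele always has OR >= 1.
orient_counts_row <- function(row) {
  ca <- c(row$case_hom_major, row$case_het, row$case_hom_minor)
  co <- c(row$control_hom_major, row$control_het, row$control_hom_minor)
  risk <- row$risk_allele
  if (!is.na(risk) && risk == row$major_allele) {
    ca <- rev(ca)
    co <- rev(co)
  }
  list(df = tibble(dosage = 0:2, case_n = ca, control_n = co), risk = risk)
}

#' Additive-model logistic association for one SNP
#'
#' Maximum-likelihood logistic regression of case status on risk-allele
#' dosage (0/1/2), fitted on the grouped genotype counts by iteratively
#' reweighted least squares (relative tolerance 1e-10).  Reports the
#' per-allele odds ratio with a 95% Wald interval, the two-sided Wald p
#' (primary), and a likelihood-ratio p for cross-checking.
#'
#' If `risk_allele` is unset in the counts row, the allele with fitted
#' OR > 1 is designated as the risk allele.
#'
#' Perfect separation is flagged (`separated = TRUE`, infinite `beta`
#' sentinel) rather than silently returning a finite estimate; a
#' monomorphic SNP is an error.
#'
#' @param counts a one-row counts table (see [collapse_to_counts()]).
#' @return an object of class `additive_fit`: a list with `rsid`,
#'   `risk_allele`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `p_wald`,
#'   `p_lrt`, `n_used`, `separated`, and the underlying `fit`.
#' @export
fit_additive_logistic <- function(counts) {
  check_counts_tbl(counts)
  if (nrow(counts) != 1L) {
    stop_validation("`fit_additive_logistic()` takes a single counts row; use `association_table()` for panels.")
  }
  row <- as.list(counts[1, ])
  ori <- orient_counts_row(row)
  df <- ori$df
  pooled <- df$case_n + df$control_n
  if (sum(pooled > 0) < 2L) {
    stop_computation(paste0("SNP ", row$rsid, " is monomorphic; additive fit undefined."))
  }
  if (sum(df$case_n) == 0L || sum(df$control_n) == 0L) {
    stop_validation("need at least one genotyped case and control.")
  }
  fit <- suppressWarnings(fit_grouped_glm(cbind(case_n, control_n) ~ dosage, df))
  beta <- unname(coef(fit)[2])
  se <- sqrt(vcov(fit)[2, 2])
  separated <- !fit$converged || abs(beta) > 15 || se > 50
  null <- fit_grouped_glm(cbind(case_n, control_n) ~ 1, df)
  lr <- as.numeric(2 * (logLik(fit) - logLik(null)))
  p_lrt <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  risk <- ori$risk
  if (is.na(risk)) {
    if (beta < 0) {   # flip so the designated risk allele has OR >= 1
      df <- tibble(dosage = 0:2, case_n = rev(df$case_n), control_n = rev(df$control_n))
      fit <- suppressWarnings(fit_grouped_glm(cbind(case_n, control_n) ~ dosage, df))
      beta <- unname(coef(fit)[2])
      se <- sqrt(vcov(fit)[2, 2])
      risk <- row$major_allele
    } else {
      risk <- row$minor_allele
    }
  }
  if (separated) {
    beta <- sign(beta) * Inf
    out_or <- exp(beta)
    ci <- c(0, Inf)
    p_wald <- NA_real_
  } else {
    out_or <- exp(beta)
    ci <- exp(beta + c(-1, 1) * Z975 * se)
    p_wald <- 2 * pnorm(-abs(beta / se))
  }
  structure(
    list(
      rsid = row$rsid, risk_allele = risk,
      beta = beta, se = se, or = out_or,
      ci_low = ci[1], ci_high = ci[2],
      p_wald = p_wald, p_lrt = p_lrt,
      n_used = sum(pooled), separated = separated,
      fit = fit
    ),
    class = "additive_fit"
  )
}

#' @export
print.additive_fit <- function(x, ...) {
  cat(sprintf(
    "<additive_fit> %s (risk %s): OR %.3f [%.3f, %.3f], p(Wald) %.3g, n %d%s\n",
    x$rsid, x$risk_allele, x$or, x$ci_low, x$ci_high, x$p_wald, x$n_used,
    if (x$separated) " [SEPARATED]" else ""
  ))
  invisible(x)
}

#' @export
tidy.additive_fit <- function(x, ...) {
  tibble(
    term = "dosage", rsid = x$rsid, risk_allele = x$risk_allele,
    estimate = x$beta, std.error = x$se,
    or = x$or, conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p_wald, p.lrt = x$p_lrt
  )
}

#' @export
glance.additive_fit <- function(x, ...) {
  tibble(
    rsid = x$rsid, n_used = x$n_used, separated = x$separated,
    logLik = as.numeric(logLik(x$fit)), converged = x$fit$converged
  )
}

#' Dominance-deviation (DOMDEV) test for one SNP
#'
#' Adds a heterozygote indicator to the additive logistic model and returns
#' the two-sided Wald p-value for the indicator coefficient: small values
#' signal departure from additivity (dominance or recessivity).  The test
#' is orientation-invariant.
#'
#' When a genotype category is empty in one phenotype group the saturated
#' fit separates and the Wald statistic collapses towards zero (the
#' Hauck-Donner effect), so the likelihood-ratio p-value for the indicator
#' is returned instead (flagged via attribute `method`).
#'
#' @param counts a one-row counts table.
#' @return the DOMDEV p-value (numeric scalar), with the indicator estimate
#'   attached as attribute `beta_het` and the test used as `method`.
#' @export
domdev_test <- function(counts) {
  check_counts_tbl(counts)
  if (nrow(counts) != 1L) stop_validation("`domdev_test()` takes a single counts row.")
  row <- as.list(counts[1, ])
  df <- orient_counts_row(row)$df
  pooled <- df$case_n + df$control_n
  if (any(pooled == 0)) {
    stop_computation(paste0(
      "SNP ", row$rsid,
      ": empty pooled genotype category; DOMDEV design is degenerate."
    ))
  }
  df$het <- as.numeric(df$dosage == 1L)
  fit <- suppressWarnings(fit_grouped_glm(cbind(case_n, control_n) ~ dosage + het, df))
  beta <- unname(coef(fit)["het"])
  se <- sqrt(vcov(fit)["het", "het"])
  if (is.finite(beta) && is.finite(se) && abs(beta) <= 15 && se <= 50) {
    p <- 2 * pnorm(-abs(beta / se))
    method <- "wald"
  } else {
    add <- suppressWarnings(fit_grouped_glm(cbind(case_n, control_n) ~ dosage, df))
    p <- pchisq(max(add$deviance - fit$deviance, 0), df = 1, lower.tail = FALSE)
    method <- "lrt"
  }
  attr(p, "beta_het") <- beta
  attr(p, "method") <- method
  p
}

#' Panel-wide association table
#'
#' Fits the additive model and the DOMDEV test for every SNP in a grouped
#' counts table, sorts by genomic position, and flags significance at the
#' additive Bonferroni threshold.  DOMDEV is set to `NA` (with a warning)
#' for SNPs whose pooled design is degenerate; additive-fit errors
#' propagate.
#'
#' @param counts a counts table (see [collapse_to_counts()]).
#' @param policy a [significance_policy()].
#' @return a tibble of class `assoc_table`, one row per SNP: `rsid`,
#'   `gene`, `chromosome`, `position`, `risk_allele`, `beta`, `or`,
#'   `ci_low`, `ci_high`, `p_additive` (Wald), `p_lrt`, `p_domdev`,
#'   `n_used`, `separated`, `significant`.  Attribute `threshold` records
#'   the additive threshold used.
#' @export
association_table <- function(counts, policy = significance_policy()) {
  if (nrow(counts) == 0L) {
    out <- tibble(
      rsid = character(), gene = character(), chromosome = character(),
      position = integer(), risk_allele = character(), beta = numeric(),
      or = numeric(), ci_low = numeric(), ci_high = numeric(),
      p_additive = numeric(), p_lrt = numeric(), p_domdev = numeric(),
      n_used = integer(), separated = logical(), significant = logical()
    )
    class(out) <- c("assoc_table", class(out))
    attr(out, "threshold") <- bonferroni_threshold(policy, "additive")
    return(out)
  }
  check_counts_tbl(counts)
  thr <- bonferroni_threshold(policy, "additive")
  rows <- purrr::map(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    fit <- fit_additive_logistic(row)
    p_dd <- tryCatch(
      as.numeric(domdev_test(row)),
      snpgrs_computation_error = function(e) {
        warn(paste0(row$rsid, ": DOMDEV skipped (", conditionMessage(e), ")"))
        NA_real_
      }
    )
    tibble(
      rsid = row$rsid,
      gene = if ("gene" %in% names(row)) row$gene else NA_character_,
      chromosome = if ("chromosome" %in% names(row)) row$chromosome else NA_character_,
      position = if ("position" %in% names(row)) row$position else NA_integer_,
      risk_allele = fit$risk_allele,
      beta = fit$beta, or = fit$or,
      ci_low = fit$ci_low, ci_high = fit$ci_high,
      p_additive = fit$p_wald, p_lrt = fit$p_lrt, p_domdev = p_dd,
      n_used = fit$n_used, separated = fit$separated
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[chrom_order_key(out$chromosome), ]
  out <- out[order(match(out$chromosome, unique(out$chromosome)), out$position), ]
  out$significant <- !is.na(out$p_additive) & out$p_additive < thr
  class(out) <- c("assoc_table", class(out))
  attr(out, "threshold") <- thr
  out
}

#' Write an association report TSV
#'
#' Mirrors the standard per-SNP association report layout, with count
#' triples formatted as `a/b/c` strings when the counts table is supplied.
#'
#' @param assoc an `assoc_table` tibble.
#' @param path output path.
#' @param counts optional counts table to embed the genotype triples.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(assoc, path, counts = NULL) {
  out <- assoc
  if (!is.null(counts)) {
    trip <- counts |>
      dplyr::mutate(
        case_counts = fmt_triple(.data$case_hom_major, .data$case_het, .data$case_hom_minor),
        control_counts = fmt_triple(.data$control_hom_major, .data$control_het, .data$control_hom_minor)
      ) |>
      dplyr::select("rsid", "case_counts", "control_counts")
    out <- dplyr::left_join(out, trip, by = "rsid")
  }
  readr::write_tsv(out, path)
  invisible(path)
}
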
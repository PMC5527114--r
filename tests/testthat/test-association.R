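test_that("additive refits reproduce the published odds ratios", {
  fx <- table2_fixture()
  fit_lcorl <- fit_additive_logistic(fx$snps[fx$snps$rsid == "rs13131350", ])
  expect_equal(round(fit_lcorl$or, 2), 1.55)
  expect_equal(fit_lcorl$risk_allele, "G")

  fit_tsen <- fit_additive_logistic(fx$snps[fx$snps$rsid == "rs1046934", ])
  expect_equal(round(fit_tsen$or, 2), 1.32)
  expect_equal(fit_tsen$risk_allele, "A")
  expect_lt(fit_tsen$ci_low, fit_tsen$or)
  expect_gt(fit_tsen$ci_high, fit_tsen$or)
})

test_that("identical case/control genotype distributions give a flat fit", {
  row <- counts_row(case_triple = c(400L, 400L, 200L),
                    control_triple = c(200L, 200L, 100L))
  fit <- fit_additive_logistic(row)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$or, 1, tolerance = 1e-8)
  expect_equal(fit$p_wald, 1, tolerance = 1e-6)
})

test_that("grouped fit equals the individual-level logistic fit", {
  row <- counts_row(case_triple = c(30L, 42L, 11L),
                    control_triple = c(48L, 35L, 8L))
  fit <- fit_additive_logistic(row)
  gm <- expand_counts_to_gm(row)
  df <- data.frame(
    y = as.integer(gm$samples$phenotype == "case"),
    dosage = gm$dosage[, 1]
  )
  oracle <- stats::glm(y ~ dosage, family = binomial(), data = df,
                       control = glm.control(epsilon = 1e-10))
  expect_equal(fit$beta, unname(coef(oracle)[2]), tolerance = 1e-8)
  expect_equal(fit$se, sqrt(vcov(oracle)[2, 2]), tolerance = 1e-6)
})

test_that("under HWE the logistic OR tracks the allelic 2x2 OR on all 13 rows", {
  fx <- table2_fixture()
  diffs <- vapply(seq_len(nrow(fx$snps)), function(i) {
    row <- fx$snps[i, ]
    fit <- fit_additive_logistic(row)
    long <- dosage_for_risk_allele(row)
    ca_risk <- sum(long$dosage * long$case_n)
    co_risk <- sum(long$dosage * long$control_n)
    ca_tot <- 2 * sum(long$case_n)
    co_tot <- 2 * sum(long$control_n)
    allelic <- (ca_risk / (ca_tot - ca_risk)) / (co_risk / (co_tot - co_risk))
    abs(fit$or - allelic)
  }, numeric(1))
  # HWE holds only approximately in the printed counts; the worst row
  # (rs12338076) differs by 0.0224, every other row by under 0.017.
  expect_lt(max(diffs), 0.025)
  expect_lt(stats::median(diffs), 0.01)
})

test_that("reversing risk-allele orientation negates beta and keeps p", {
  fx <- table2_fixture()
  row <- fx$snps[fx$snps$rsid == "rs13131350", ]
  fit <- fit_additive_logistic(row)
  flipped <- row
  flipped$risk_allele <- flipped$major_allele
  fit_f <- fit_additive_logistic(flipped)
  expect_equal(fit_f$beta, -fit$beta, tolerance = 1e-10)
  expect_equal(fit_f$or, 1 / fit$or, tolerance = 1e-10)
  expect_equal(fit_f$p_wald, fit$p_wald, tolerance = 1e-12)
})

test_that("unset risk alleles resolve to the allele with OR above 1", {
  fx <- table2_fixture()
  row <- fx$snps[fx$snps$rsid == "rs1046934", ]   # risk is the major allele
  row$risk_allele <- NA_character_
  fit <- fit_additive_logistic(row)
  expect_equal(fit$risk_allele, row$major_allele)
  expect_gt(fit$or, 1)
})

test_that("monomorphic SNPs error and perfect separation is flagged", {
  mono <- counts_row(case_triple = c(100L, 0L, 0L),
                     control_triple = c(100L, 0L, 0L))
  expect_error(fit_additive_logistic(mono), "monomorphic",
               class = "snpgrs_computation_error")

  sep <- counts_row(case_triple = c(0L, 0L, 100L),
                    control_triple = c(100L, 0L, 0L))
  fit <- fit_additive_logistic(sep)
  expect_true(fit$separated)
  expect_true(is.infinite(fit$beta))
})

test_that("the DOMDEV test is calibrated and detects heterozygote excess", {
  # Flat fit under identical distributions.
  flat <- counts_row(case_triple = c(300L, 500L, 200L),
                     control_triple = c(300L, 500L, 200L))
  p_flat <- domdev_test(flat)
  expect_equal(as.numeric(p_flat), 1, tolerance = 1e-6)
  expect_equal(attr(p_flat, "beta_het"), 0, tolerance = 1e-8)

  # Strong dominance deviation: heterozygote-only case excess.
  dom <- counts_row(case_triple = c(400L, 600L, 0L),
                    control_triple = c(500L, 400L, 100L))
  p_dom <- as.numeric(domdev_test(dom))
  expect_lt(p_dom, 1e-3)

  # Likelihood-ratio oracle agrees that the deviation is real.
  df <- tibble::tibble(dosage = 0:2, het = c(0, 1, 0),
                       case_n = c(400L, 600L, 0L),
                       control_n = c(500L, 400L, 100L))
  add <- stats::glm(cbind(case_n, control_n) ~ dosage, binomial(), data = df)
  full <- stats::glm(cbind(case_n, control_n) ~ dosage + het, binomial(), data = df)
  p_lrt <- pchisq(add$deviance - full$deviance, df = 1, lower.tail = FALSE)
  expect_lt(p_lrt, 1e-3)

  empty_cat <- counts_row(case_triple = c(100L, 0L, 50L),
                          control_triple = c(100L, 0L, 50L))
  expect_error(domdev_test(empty_cat), "degenerate",
               class = "snpgrs_computation_error")
})

test_that("Bonferroni thresholds follow alpha over the family size", {
  pol <- significance_policy()
  expect_equal(bonferroni_threshold(pol, "additive"), 0.05 / 1033)
  expect_equal(signif(bonferroni_threshold(pol, "additive"), 1), 5e-5)
  expect_equal(signif(bonferroni_threshold(pol, "domdev"), 3), 1.47e-3)
  expect_equal(bonferroni_threshold(significance_policy(0.03, 1, 1), "additive"),
               0.03)
})

test_that("the association table flags, sorts, and handles empty input", {
  fx <- table2_fixture()
  tab <- association_table(fx$snps)
  expect_s3_class(tab, "assoc_table")
  expect_true(all(tab$significant))
  expect_true(all(tab$p_additive < 5e-5))
  # position-sorted within chromosome order
  key <- order(as.numeric(tab$chromosome), tab$position)
  expect_equal(key, seq_len(nrow(tab)))
  # p-values agree with the likelihood-ratio cross-check to first order
  expect_true(all(abs(log10(tab$p_additive) - log10(tab$p_lrt)) < 0.5))

  empty <- association_table(fx$snps[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("a null panel yields no significance flags", {
  spec <- cohort_spec(1500, 1500,
                      tibble::tibble(control_raf = seq(0.2, 0.4, length.out = 13),
                                     or = 1),
                      seed = 55)
  counts <- collapse_to_counts(generate_cohort(spec))
  tab <- association_table(counts)
  expect_equal(sum(tab$significant), 0L)
})

test_that("tilt-model cohorts recover the generating log OR within 2%", {
  f <- 0.3
  or_true <- 1.4
  ctrl <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  case <- ctrl * or_true^(0:2)
  case <- case / sum(case)
  set.seed(808)
  betas <- replicate(200, {
    ca <- as.integer(stats::rmultinom(1, 50000, case))
    co <- as.integer(stats::rmultinom(1, 50000, ctrl))
    row <- counts_row(case_triple = ca, control_triple = co)
    fit_additive_logistic(row)$beta
  })
  expect_lt(abs(mean(betas) - log(or_true)) / log(or_true), 0.02)
})

test_that("tidy and glance expose the fit in broom shape", {
  fx <- table2_fixture()
  fit <- fit_additive_logistic(fx$snps[1, ])
  td <- tidy(fit)
  expect_named(td, c("term", "rsid", "risk_allele", "estimate", "std.error",
                     "or", "conf.low", "conf.high", "p.value", "p.lrt"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_used, fit$n_used)
})
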
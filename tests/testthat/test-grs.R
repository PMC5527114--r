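# Weighted-score panel used across this file: the 13 reference SNPs with
# their printed odds ratios as weights.
printed_weights <- function() {
  fx <- table2_fixture()
  tibble::tibble(
    rsid = fx$snps$rsid,
    risk_allele = fx$snps$risk_allele,
    log_or = log(fx$snps$or_printed)
  )
}

# Genotype matrix with chosen risk-allele dosages for every fixture SNP.
gm_with_risk_dosage <- function(dosages) {
  fx <- table2_fixture()
  snps <- fx$snps[, c("rsid", "chromosome", "position", "minor_allele",
                      "major_allele", "risk_allele")]
  flip <- snps$risk_allele == snps$major_allele
  n <- length(dosages[[1]])
  d <- matrix(NA_integer_, n, nrow(snps))
  for (j in seq_len(nrow(snps))) {
    d[, j] <- if (flip[j]) 2L - dosages[[j]] else dosages[[j]]
  }
  genotype_matrix(
    d,
    tibble::tibble(sample_id = sprintf("s%d", seq_len(n)),
                   phenotype = rep(c("case", "control"), length.out = n)),
    snps
  )
}

test_that("weighted scores follow the log-OR sum and the rescaling convention", {
  w <- printed_weights()
  n <- 4L
  # sample 1: all risk dosage 0; sample 2: all 1; sample 3: all 2; sample 4 mixed
  dosages <- lapply(seq_len(13), function(j) c(0L, 1L, 2L, j %% 3))
  gm <- gm_with_risk_dosage(dosages)
  sc <- weighted_grs(gm, w)
  expect_equal(sc$grs_raw[1], 0)
  expect_equal(sc$grs_rescaled[1], 0)
  expect_equal(sc$grs_raw[2], sum(w$log_or), tolerance = 1e-12)
  expect_lt(abs(sc$grs_raw[2] - 4.24), 0.01)
  expect_equal(sc$grs_rescaled[2], 13, tolerance = 1e-12)
  expect_equal(sc$grs_raw[3], 2 * sum(w$log_or), tolerance = 1e-12)
  expect_equal(sc$grs_rescaled[3], 26, tolerance = 1e-12)

  # Doubling every weight doubles raw and leaves rescaled unchanged.
  w2 <- w
  w2$log_or <- 2 * w$log_or
  sc2 <- weighted_grs(gm, w2)
  expect_equal(sc2$grs_raw, 2 * sc$grs_raw, tolerance = 1e-12)
  expect_equal(sc2$grs_rescaled, sc$grs_rescaled, tolerance = 1e-12)
})

test_that("missing dosages impute to the control risk-allele expectation", {
  w <- printed_weights()[1:2, ]
  snps <- table2_fixture()$snps[1:2, c("rsid", "chromosome", "position",
                                       "minor_allele", "major_allele",
                                       "risk_allele")]
  # 5 controls fix the control risk-allele frequency; case s1 misses the
  # first SNP, case s2 misses both.  Risk allele of rs1046934 is the major
  # allele: minor dosage 0 means risk dosage 2.
  d <- rbind(
    c(NA_integer_, 1L),
    c(NA_integer_, NA_integer_),
    c(0L, 1L), c(0L, 1L), c(2L, 1L), c(2L, 1L), c(1L, 1L)
  )
  gm <- genotype_matrix(
    d,
    tibble::tibble(sample_id = sprintf("s%d", 1:7),
                   phenotype = c("case", "case", rep("control", 5))),
    snps
  )
  sc <- weighted_grs(gm, w, missing_policy = "impute")
  # control risk dosages at SNP 1: minor 0,0,2,2,1 -> risk 2,2,0,0,1; f = 0.5
  expected_raw <- 2 * 0.5 * w$log_or[1] + 1 * w$log_or[2]
  expect_equal(sc$grs_raw[1], expected_raw, tolerance = 1e-12)
  expect_equal(sc$n_missing[1], 1L)
  expect_false(sc$unreliable[1])   # exactly half missing is tolerated
  expect_true(sc$unreliable[2])    # everything missing is flagged

  cc <- weighted_grs(gm, w, missing_policy = "complete")
  expect_equal(cc$grs_raw[1], w$log_or[2], tolerance = 1e-12)
  expect_equal(cc$grs_rescaled[1], 1, tolerance = 1e-12)
  expect_true(is.na(cc$grs_rescaled[2]))
})

test_that("quartile assignment is right-closed at published cut-points", {
  scores <- tibble::tibble(
    sample_id = sprintf("s%d", 1:5),
    phenotype = c("case", "case", "control", "control", "case"),
    grs = c(11.88, 13.50, 13.51, 15.05, 15.06)
  )
  part <- assign_quartiles(scores, cutpoints = c(11.88, 13.50, 15.05))
  expect_equal(part$data$quartile, c("Q1", "Q2", "Q3", "Q3", "Q4"))
})

test_that("empirical quartiles split distinct scores evenly and ignore order", {
  scores <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    phenotype = rep(c("case", "control"), 4),
    grs = c(5, 1, 7, 3, 8, 2, 6, 4)
  )
  part <- assign_quartiles(scores)
  expect_equal(unname(table(part$data$quartile)), rep(2L, 4), ignore_attr = TRUE)

  shuffled <- scores[c(3, 1, 8, 5, 2, 7, 4, 6), ]
  part2 <- assign_quartiles(shuffled)
  joined <- dplyr::left_join(part$data, part2$data, by = "sample_id")
  expect_equal(joined$quartile.x, joined$quartile.y)

  expect_error(
    assign_quartiles(dplyr::mutate(scores, grs = 1)),
    "degenerate", class = "snpgrs_computation_error"
  )
})

test_that("quartile odds ratios reproduce the published quartile table", {
  fx <- table2_fixture()
  qa <- quartile_association(fx$quartile_counts)
  expect_equal(round(qa$or[-1], 2), c(2.02, 2.61, 6.94))
  expect_equal(round(qa$ci_low[-1], 2), c(1.55, 2.03, 5.32))
  expect_equal(round(qa$ci_high[-1], 2), c(2.63, 3.37, 9.06))
  expect_true(qa$reference[1])
})

test_that("saturated quartile logistic ORs equal closed-form cross-products", {
  set.seed(60)
  for (r in 1:20) {
    tab <- tibble::tibble(
      quartile = paste0("Q", 1:4),
      n_cases = as.integer(sample(20:400, 4)),
      n_controls = as.integer(sample(20:400, 4))
    )
    qa <- quartile_association(tab)
    cross <- (tab$n_cases[-1] * tab$n_controls[1]) /
      (tab$n_controls[-1] * tab$n_cases[1])
    expect_equal(qa$or[-1], cross, tolerance = 1e-9)
  }

  flat <- tibble::tibble(quartile = paste0("Q", 1:4),
                         n_cases = c(50L, 100L, 150L, 200L),
                         n_controls = c(100L, 200L, 300L, 400L))
  qa_flat <- quartile_association(flat)
  expect_equal(qa_flat$or[-1], rep(1, 3), tolerance = 1e-9)
})

test_that("the trend test is signed, calibrated, and matches prop.trend.test", {
  fx <- table2_fixture()
  tr <- cochran_armitage_trend(fx$quartile_counts)
  expect_lt(tr$p.value, 0.001)
  expect_gt(unname(tr$statistic), 0)

  # Equal case proportions in every category: no trend.
  flat <- tibble::tibble(quartile = paste0("Q", 1:3),
                         n_cases = c(30L, 60L, 90L),
                         n_controls = c(60L, 120L, 180L))
  tr_flat <- cochran_armitage_trend(flat)
  expect_equal(unname(tr_flat$statistic), 0)
  expect_equal(tr_flat$p.value, 1)

  # Antisymmetry under category reversal.
  tab <- fx$quartile_counts
  rev_tab <- tab[4:1, ]
  expect_equal(
    unname(cochran_armitage_trend(rev_tab)$statistic),
    -unname(tr$statistic),
    tolerance = 1e-12
  )

  # Independent implementation check: Z^2 equals the chi-square trend test.
  ptt <- stats::prop.trend.test(tab$n_cases, tab$n_cases + tab$n_controls, 1:4)
  expect_equal(unname(tr$statistic)^2, unname(ptt$statistic), tolerance = 1e-9)
})

test_that("the trend p matches a permutation oracle on small tables", {
  tabs <- list(
    tibble::tibble(quartile = paste0("Q", 1:4),
                   n_cases = c(18L, 22L, 30L, 34L),
                   n_controls = c(32L, 28L, 22L, 14L)),
    tibble::tibble(quartile = paste0("Q", 1:4),
                   n_cases = c(22L, 25L, 26L, 29L),
                   n_controls = c(28L, 25L, 24L, 21L))
  )
  for (i in seq_along(tabs)) {
    p_norm <- cochran_armitage_trend(tabs[[i]])$p.value
    p_perm <- ca_permutation_p(tabs[[i]], n_perm = 1e5, seed = 10 + i)
    expect_lt(abs(p_norm - p_perm), 0.025)
  }
})

test_that("risk weights come from fitted log ORs and reject non-finite input", {
  fx <- table2_fixture()
  assoc <- association_table(fx$snps)
  w <- risk_weights(assoc)
  expect_equal(w$log_or, assoc$beta)
  bad <- assoc
  bad$beta[1] <- Inf
  expect_error(risk_weights(bad), "non-finite", class = "snpgrs_validation_error")
})

test_that("quartile ORs are monotone on cohorts built from the reference ORs", {
  fx <- table2_fixture()
  t1 <- table1_reference()
  snps <- tibble::tibble(
    rsid = fx$snps$rsid,
    chromosome = fx$snps$chromosome,
    position = fx$snps$position,
    minor_allele = fx$snps$minor_allele,
    major_allele = fx$snps$major_allele,
    risk_allele = fx$snps$risk_allele,
    control_raf = vapply(seq_len(13), function(i) {
      f_minor <- t1$maf_controls[t1$rsid == fx$snps$rsid[i]]
      if (fx$snps$risk_allele[i] == fx$snps$minor_allele[i]) f_minor else 1 - f_minor
    }, numeric(1)),
    or = fx$snps$or_printed
  )
  monotone <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    gm <- generate_cohort(cohort_spec(978, 1129, snps, seed = 7000 + r))
    sc <- weighted_grs(gm, printed_weights())
    qa <- quartile_association(assign_quartiles(sc))
    ors <- c(1, qa$or[-1])
    if (all(diff(ors) > 0)) monotone <- monotone + 1L
  }
  expect_gte(monotone / n_rep, 0.95)
})

test_that("tidy and glance summarise a quartile partition", {
  set.seed(14)
  sc <- tibble::tibble(
    sample_id = sprintf("s%d", 1:400),
    phenotype = rep(c("case", "control"), 200),
    grs = c(stats::rnorm(200, 14, 2), stats::rnorm(200, 13, 2))
  )
  part <- assign_quartiles(sc)
  td <- tidy(part)
  expect_equal(td$quartile, paste0("Q", 1:4))
  gl <- glance(part)
  expect_equal(gl$n, 400L)
  expect_true(is.finite(gl$trend_p))
})
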
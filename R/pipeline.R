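# End-to-end orchestration: QC -> additive association (Bonferroni filter)
# -> D'-threshold LD pruning -> weighted GRS quartile analysis, with
# TSV/JSON reports and a deterministic seed.

#' Pipeline configuration
#'
#' Bundles every stage's parameters.  Defaults are the standard
#' candidate-SNP settings: MAF >= 5%, call rate >= 95%, control HWE
#' p >= 0.05, additive threshold 0.05/1033, DOMDEV threshold 0.05/34,
#' D' pruning threshold 0.8, rescaled GRS with pooled empirical quartile
#' cut-points.
#'
#' @param qc a [qc_thresholds()].
#' @param policy a [significance_policy()].
#' @param ld_threshold D' pruning threshold.
#' @param ld_group samples used for LD (`"pooled"`, `"cases"`, `"controls"`).
#' @param ld_n_boot bootstrap replicates per pair for block construction
#'   (0 disables blocks).
#' @param grs_convention `"rescaled"` or `"raw"`.
#' @param grs_cutpoints optional explicit quartile cut-points.
#' @param grs_missing_policy `"impute"` or `"complete"`.
#' @param seed integer seed for every stochastic stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            policy = significance_policy(),
                            ld_threshold = 0.8,
                            ld_group = c("pooled", "cases", "controls"),
                            ld_n_boot = 0L,
                            grs_convention = c("rescaled", "raw"),
                            grs_cutpoints = NULL,
                            grs_missing_policy = c("impute", "complete"),
                            seed = 1L) {
  if (!is_prob(ld_threshold)) stop_validation("`ld_threshold` must be in [0, 1].")
  structure(
    list(
      qc = qc, policy = policy,
      ld_threshold = ld_threshold,
      ld_group = match.arg(ld_group),
      ld_n_boot = as.integer(ld_n_boot),
      grs_convention = match.arg(grs_convention),
      grs_cutpoints = grs_cutpoints,
      grs_missing_policy = match.arg(grs_missing_policy),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
      class = class(e)[1],
      parent = e
    )
  })
}

#' Run the full case-control pipeline
#'
#' Stages, in order: per-SNP QC filters; additive-model association with
#' DOMDEV, keeping SNPs below the Bonferroni additive threshold; greedy
#' D' pruning of the significant set (priority: ascending additive p, so
#' the most significant SNP of each LD cluster is kept — logged in the run
#' report since the re-selection rule is a package choice); weighted GRS
#' (weights = fitted log ORs of the pruned SNPs) with quartile odds ratios
#' and the Cochran-Armitage trend test.  SNP counts are non-increasing
#' across stages.  With an output directory, per-stage TSVs and a JSON run
#' report are written; outputs are byte-identical for identical inputs,
#' configuration, and seed.  Any stage error aborts with the stage name
#' and removes partial outputs.
#'
#' @param x a [genotype_matrix()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @return a list of class `run_report`: per-stage SNP counts, stage
#'   results (`qc`, `association`, `pruning`, `scores`, `quartiles`,
#'   `quartile_association`, `trend`), the file manifest, and provenance
#'   (thresholds, seed, package version).
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(x, "genotype_matrix"), inherits(config, "pipeline_config"))
  files <- character(0)
  cleanup <- function() if (length(files)) unlink(files)

  withCallingHandlers(
    {
      counts <- run_stage("counts", collapse_to_counts(x))
      qc <- run_stage("qc", snp_qc(counts, config$qc))
      passed <- qc$rsid[qc$passed]

      thr_add <- bonferroni_threshold(config$policy, "additive")
      if (length(passed)) {
        assoc <- run_stage(
          "association",
          association_table(counts[counts$rsid %in% passed, ], config$policy)
        )
        sig <- assoc$rsid[assoc$significant]
      } else {
        assoc <- association_table(counts[0, ], config$policy)
        sig <- character(0)
      }

      if (length(sig) >= 2L) {
        gm_sig <- subset_snps(x, sig)
        pairs <- run_stage(
          "ld",
          ld_pairwise(gm_sig, group = config$ld_group,
                      n_boot = config$ld_n_boot, seed = config$seed)
        )
        prio <- stats::setNames(
          assoc$p_additive[match(sig, assoc$rsid)], sig
        )
        pruning <- run_stage(
          "prune",
          prune_by_dprime(pairs, gm_sig$snps, threshold = config$ld_threshold,
                          priority = prio)
        )
        retained <- pruning$rsid[pruning$retained]
        blocks <- if (config$ld_n_boot > 0) {
          run_stage("blocks", build_blocks(pairs, gm_sig$snps))
        } else {
          NULL
        }
      } else {
        pairs <- NULL
        blocks <- NULL
        pruning <- tibble(rsid = sig, retained = TRUE, pruned_by = NA_character_)
        retained <- sig
      }

      if (length(retained)) {
        weights <- risk_weights(assoc[match(retained, assoc$rsid), ])
        scores <- run_stage(
          "grs",
          weighted_grs(x, weights, convention = config$grs_convention,
                       missing_policy = config$grs_missing_policy)
        )
        quartiles <- run_stage(
          "quartiles",
          assign_quartiles(scores, cutpoints = config$grs_cutpoints)
        )
        qa <- run_stage("quartile_association", quartile_association(quartiles))
        trend <- run_stage("trend", cochran_armitage_trend(quartiles))
      } else {
        weights <- scores <- quartiles <- qa <- trend <- NULL
      }

      stage_counts <- list(
        input = n_snps(x),
        qc_passed = length(passed),
        significant = length(sig),
        pruned = length(retained)
      )

      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        path <- function(f) file.path(out_dir, f)
        files <- c(files, write_qc_report(qc, path("qc_report.tsv")))
        files <- c(files, write_association_report(
          assoc, path("association.tsv"), counts = counts
        ))
        if (!is.null(pairs)) {
          files <- c(files, write_ld_report(pairs, path("ld_matrix.tsv")))
        }
        readr::write_tsv(pruning, path("pruned_snps.tsv"))
        files <- c(files, path("pruned_snps.tsv"))
        if (!is.null(blocks) && nrow(blocks)) {
          readr::write_tsv(blocks, path("blocks.tsv"))
          files <- c(files, path("blocks.tsv"))
        }
        if (!is.null(quartiles)) {
          files <- c(files, write_grs_report(
            quartiles, path("grs_scores.tsv"), path("grs_quartiles.tsv")
          ))
        }
        report_json <- list(
          stage_counts = stage_counts,
          thresholds = list(
            min_maf = config$qc$min_maf,
            min_call_rate = config$qc$min_call_rate,
            min_hwe_p = config$qc$min_hwe_p,
            additive_threshold = thr_add,
            domdev_threshold = bonferroni_threshold(config$policy, "domdev"),
            ld_dprime_threshold = config$ld_threshold,
            pruning_priority = "ascending additive p (package choice)"
          ),
          seed = config$seed,
          package = list(name = "snpgrs",
                         version = as.character(packageVersion("snpgrs"))),
          files = basename(files)
        )
        jsonlite::write_json(report_json, path("run_report.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        files <- c(files, path("run_report.json"))
      }

      structure(
        list(
          stage_counts = stage_counts,
          qc = qc, association = assoc, ld_pairs = pairs, blocks = blocks,
          pruning = pruning, weights = weights, scores = scores,
          quartiles = quartiles, quartile_association = qa, trend = trend,
          files = files, seed = config$seed, config = config
        ),
        class = "run_report"
      )
    },
    error = function(e) cleanup()
  )
}

#' @export
print.run_report <- function(x, ...) {
  sc <- x$stage_counts
  cat(sprintf(
    "<run_report> SNPs: %d input -> %d QC-passed -> %d significant -> %d after LD pruning\n",
    sc$input, sc$qc_passed, sc$significant, sc$pruned
  ))
  if (!is.null(x$trend)) {
    cat(sprintf("  GRS quartile trend: Z = %.2f, p = %.3g\n",
                unname(x$trend$statistic), x$trend$p.value))
  }
  if (length(x$files)) cat("  outputs:", paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}

#' Recompute the packaged reference tables from their printed counts
#'
#' Desk-scale regression check: refits the additive model on the packaged
#' 13-SNP genotype count triples and the quartile logistic model plus
#' trend test on the packaged 2x4 quartile table, then compares the
#' recomputed odds ratios with the published ones, flagging any absolute
#' OR discrepancy above `flag_tol`.
#'
#' @param out_dir optional directory for TSV copies of the comparisons.
#' @param flag_tol absolute OR discrepancy that raises a flag (default
#'   0.01, i.e. anything beyond 2-decimal rounding disagreement).
#' @return a list of class `fixture_check`: `table2` (per-SNP recomputed
#'   vs printed OR/CI/p), `table3` (per-quartile recomputed vs printed
#'   OR), `trend` (the trend test), `n_flagged`.
#' @export
run_fixture_mode <- function(out_dir = NULL, flag_tol = 0.01) {
  fx <- table2_fixture()
  assoc <- association_table(fx$snps, significance_policy())
  t2 <- fx$snps |>
    dplyr::select("rsid", "or_printed", "ci_low_printed", "ci_high_printed",
                  "p_printed") |>
    dplyr::left_join(
      dplyr::select(assoc, "rsid", or_recomputed = "or",
                    ci_low_recomputed = "ci_low", ci_high_recomputed = "ci_high",
                    p_recomputed = "p_additive", "significant"),
      by = "rsid"
    ) |>
    dplyr::mutate(
      or_delta = .data$or_recomputed - .data$or_printed,
      flagged = abs(.data$or_delta) > flag_tol
    )
  qa <- quartile_association(fx$quartile_counts)
  t3 <- qa |>
    dplyr::mutate(
      or_printed = c(NA, fx$quartile_or_printed)[match(
        .data$quartile, c("Q1", names(fx$quartile_or_printed))
      )],
      or_delta = .data$or - .data$or_printed,
      flagged = !.data$reference & abs(.data$or_delta) > flag_tol
    )
  trend <- cochran_armitage_trend(fx$quartile_counts)
  out <- structure(
    list(
      table2 = t2, table3 = t3, trend = trend,
      n_flagged = sum(t2$flagged, na.rm = TRUE) + sum(t3$flagged, na.rm = TRUE)
    ),
    class = "fixture_check"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(t2, file.path(out_dir, "fixture_table2_comparison.tsv"))
    readr::write_tsv(t3, file.path(out_dir, "fixture_table3_comparison.tsv"))
  }
  out
}

#' @export
print.fixture_check <- function(x, ...) {
  cat(sprintf(
    "<fixture_check> 13-SNP additive refit: %d/%d ORs within 0.01 of printed; %d significant at the additive threshold\n",
    sum(!x$table2$flagged), nrow(x$table2), sum(x$table2$significant)
  ))
  cat(sprintf(
    "  quartile refit ORs: %s (printed %s); trend p = %.3g\n",
    paste(sprintf("%.2f", x$table3$or[-1]), collapse = "/"),
    paste(sprintf("%.2f", x$table3$or_printed[-1]), collapse = "/"),
    x$trend$p.value
  ))
  if (x$n_flagged) cat("  FLAGGED rows:", x$n_flagged, "\n")
  invisible(x)
}
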
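# Internal helpers shared across modules.

# Error subclasses: "snpgrs_validation_error" for bad inputs/config,
# "snpgrs_parse_error" for malformed files, "snpgrs_computation_error"
# for numerical failures.  The CLI maps these to exit codes.
stop_validation <- function(msg, ...) {
  abort(msg, class = "snpgrs_validation_error", ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = "snpgrs_parse_error", ...)
}

stop_computation <- function(msg, ...) {
  abort(msg, class = "snpgrs_computation_error", ...)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

#' Derive independent sub-seeds from a master seed
#'
#' Draws `n` sub-seeds from a single stream seeded with `seed`, so that the
#' first `k` sub-seeds are unchanged when `n` grows.  Used by the cohort
#' generator to give each SNP its own reproducible stream.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
#' @noRd
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# Sort key for chromosome labels: numeric where possible, else lexical after
# all numeric chromosomes.
chrom_order_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  num[is.na(num)] <- Inf
  order(num, chrom)
}

fmt_triple <- function(a, b, c) paste(a, b, c, sep = "/")
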
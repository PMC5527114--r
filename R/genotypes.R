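# Genotype container and I/O for biallelic case-control panels.
#
# Dosages count copies of the SNP's *designated minor allele* (the reference
# panel designation, which may exceed 50% frequency in this cohort).  Risk
# alleles are tracked separately and resolved to a dosage orientation only
# where association or scoring needs them.

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a case-control genotype matrix
#'
#' The central container of the package: an integer matrix of minor-allele
#' dosages (samples x SNPs, `NA` = missing call) together with a sample
#' tibble (`sample_id`, `phenotype`) and a SNP metadata tibble.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; values in
#'   `{0, 1, 2, NA}` counting copies of each SNP's designated minor allele.
#' @param samples tibble or data frame with columns `sample_id` and
#'   `phenotype` (values `"case"`/`"control"`), one row per dosage row.
#' @param snps tibble or data frame of SNP metadata with columns `rsid`,
#'   `chromosome`, `position`, `minor_allele`, `major_allele`, and optionally
#'   `risk_allele` and `gene`; one row per dosage column.
#' @return an object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(
#'   dosage = rbind(c(0L, 1L), c(2L, NA), c(1L, 0L)),
#'   samples = tibble::tibble(
#'     sample_id = c("s1", "s2", "s3"),
#'     phenotype = c("case", "case", "control")
#'   ),
#'   snps = tibble::tibble(
#'     rsid = c("rs1", "rs2"), chromosome = "1", position = c(100L, 200L),
#'     minor_allele = c("G", "C"), major_allele = c("A", "T")
#'   )
#' )
#' n_samples(gm)
#' @export
genotype_matrix <- function(dosage, samples, snps) {
  samples <- as_tibble(samples)
  snps <- as_tibble(snps)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!("risk_allele" %in% names(snps))) snps$risk_allele <- NA_character_
  if (!("gene" %in% names(snps))) snps$gene <- NA_character_
  out <- structure(
    list(dosage = dosage, samples = samples, snps = snps),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(out)
}

validate_genotype_matrix <- function(x) {
  d <- x$dosage
  if (nrow(x$samples) != nrow(d)) {
    stop_validation("`samples` must have one row per dosage row.")
  }
  if (nrow(x$snps) != ncol(d)) {
    stop_validation("`snps` must have one row per dosage column.")
  }
  req <- c("sample_id", "phenotype")
  if (!all(req %in% names(x$samples))) {
    stop_validation("`samples` needs columns `sample_id` and `phenotype`.")
  }
  bad_phe <- setdiff(unique(x$samples$phenotype), c("case", "control"))
  if (length(bad_phe)) {
    stop_validation(paste0(
      "phenotype must be 'case' or 'control'; found: ",
      paste(bad_phe, collapse = ", ")
    ))
  }
  req_snp <- c("rsid", "chromosome", "position", "minor_allele", "major_allele")
  miss <- setdiff(req_snp, names(x$snps))
  if (length(miss)) {
    stop_validation(paste0("`snps` is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x$snps$rsid)) stop_validation("duplicate rsid in `snps`.")
  if (any(x$snps$position <= 0, na.rm = TRUE)) {
    stop_validation("SNP positions must be positive (1-based).")
  }
  if (any(x$snps$minor_allele == x$snps$major_allele)) {
    stop_validation("minor_allele must differ from major_allele.")
  }
  ra <- x$snps$risk_allele
  ok_ra <- is.na(ra) | ra == x$snps$minor_allele | ra == x$snps$major_allele
  if (!all(ok_ra)) {
    stop_validation("risk_allele must be one of the SNP's two alleles (or NA).")
  }
  vals <- d[!is.na(d)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L))) {
    stop_validation("non-missing dosages must be in {0, 1, 2}.")
  }
  dimnames(x$dosage) <- list(x$samples$sample_id, x$snps$rsid)
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_ca <- sum(x$samples$phenotype == "case")
  n_co <- sum(x$samples$phenotype == "control")
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "<genotype_matrix> %d samples (%d cases / %d controls) x %d SNPs, %.1f%% missing\n",
    nrow(x$dosage), n_ca, n_co, ncol(x$dosage), 100 * miss
  ))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname genotype_matrix
#' @export
n_snps <- function(x) ncol(x$dosage)

#' Subset a genotype matrix by SNP
#'
#' @param x a `genotype_matrix`.
#' @param rsids character vector of SNP identifiers to keep (order preserved).
#' @return a `genotype_matrix` restricted to the requested SNPs.
#' @export
subset_snps <- function(x, rsids) {
  idx <- match(rsids, x$snps$rsid)
  if (anyNA(idx)) {
    stop_validation(paste0(
      "unknown rsid(s): ", paste(rsids[is.na(idx)], collapse = ", ")
    ))
  }
  genotype_matrix(x$dosage[, idx, drop = FALSE], x$samples, x$snps[idx, ])
}

## ---- genotype TSV dialect --------------------------------------------------

GENO_MISSING_CODES <- c("NA", "--", "00", ".", "")

# Parse one genotype cell given the SNP's two alleles; returns dosage or NA.
# `cell` may be a single digit 0/1/2 or a two-character allele pair.
parse_geno_cell <- function(cell, minor, major, line_no, rsid) {
  if (cell %in% GENO_MISSING_CODES) return(NA_integer_)
  if (grepl("^[012]$", cell)) return(as.integer(cell))
  if (nchar(cell) != 2L) {
    stop_parse(sprintf(
      "line %d, SNP %s: cannot parse genotype '%s'", line_no, rsid, cell
    ))
  }
  al <- strsplit(cell, "", fixed = TRUE)[[1]]
  if (any(al %in% c("-", "0"))) return(NA_integer_)   # half-missing pair
  if (!all(al %in% VALID_BASES)) {
    stop_parse(sprintf(
      "line %d, SNP %s: allele not in {A,C,G,T} in genotype '%s'",
      line_no, rsid, cell
    ))
  }
  if (!all(al %in% c(minor, major))) {
    stop_parse(sprintf(
      "line %d, SNP %s: allele outside {%s,%s} in genotype '%s'",
      line_no, rsid, major, minor, cell
    ))
  }
  sum(al == minor)
}

# Infer per-SNP minor/major designation from pooled allele counts.
# Ties break alphabetically (lexicographically smaller base is "minor").
infer_alleles <- function(pair_matrix) {
  tab <- sort(table(pair_matrix[pair_matrix %in% VALID_BASES]))
  if (length(tab) > 2L) {
    stop_parse(paste0(
      "more than two alleles observed: ", paste(names(tab), collapse = ", ")
    ))
  }
  if (length(tab) == 0L) {
    return(list(minor = "A", major = "C"))   # fully missing column
  }
  if (length(tab) == 1L) {
    a <- names(tab)
    other <- setdiff(VALID_BASES, a)[1]
    return(list(minor = other, major = a))   # monomorphic: observed = major
  }
  if (tab[[1]] == tab[[2]]) {
    al <- sort(names(tab))
    return(list(minor = al[1], major = al[2]))
  }
  list(minor = names(tab)[1], major = names(tab)[2])
}

#' Read SNP metadata from a TSV file
#'
#' Expects columns `rsid`, `chromosome`, `position`, `minor_allele`,
#' `major_allele`, and optionally `risk_allele` and `gene`.
#'
#' @param path file path.
#' @return a tibble of SNP metadata.
#' @export
read_snp_meta <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    rsid = readr::col_character(),
    chromosome = readr::col_character(),
    position = readr::col_integer(),
    minor_allele = readr::col_character(),
    major_allele = readr::col_character(),
    .default = readr::col_character()
  ))
  req <- c("rsid", "chromosome", "position", "minor_allele", "major_allele")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop_parse(paste0("SNP metadata missing columns: ", paste(miss, collapse = ", ")))
  }
  meta
}

#' Read a genotype matrix from the package's TSV dialect
#'
#' The file has a header `sample_id<TAB>phenotype<TAB><rsid1><TAB>...`, one
#' row per sample.  Genotype cells are either two-character allele pairs
#' (e.g. `"AC"`) or single-digit minor-allele dosages `0`/`1`/`2`; missing
#' calls are `"NA"`, `"--"`, `"00"`, or a half-missing pair such as `"A-"`.
#'
#' Minor/major allele designation is taken from `snp_meta` when supplied;
#' otherwise it is inferred from pooled allele frequencies (alphabetical
#' tie-break).  Dosage-coded columns without metadata keep their coded
#' orientation with placeholder alleles.
#'
#' @param path genotype TSV path.
#' @param snp_meta optional SNP metadata: a tibble (see [read_snp_meta()]) or
#'   a path to one.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, snp_meta = NULL) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  if (is.character(snp_meta)) snp_meta <- read_snp_meta(snp_meta)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_parse("genotype TSV needs a header and at least one sample row.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 3L || header[1] != "sample_id" || header[2] != "phenotype") {
    stop_parse("header must start with 'sample_id<TAB>phenotype' followed by rsids.")
  }
  rsids <- header[-(1:2)]
  p <- length(rsids)
  body <- fields[-1]
  widths <- lengths(body)
  bad <- which(widths != p + 2L)
  if (length(bad)) {
    stop_parse(sprintf(
      "line %d: expected %d fields, found %d", bad[1] + 1L, p + 2L, widths[bad[1]]
    ))
  }
  mat <- do.call(rbind, body)
  sample_id <- mat[, 1]
  phenotype <- mat[, 2]
  bad_phe <- which(!phenotype %in% c("case", "control"))
  if (length(bad_phe)) {
    stop_validation(sprintf(
      "line %d: phenotype '%s' is not 'case' or 'control'",
      bad_phe[1] + 1L, phenotype[bad_phe[1]]
    ))
  }
  cells <- mat[, -(1:2), drop = FALSE]

  if (!is.null(snp_meta)) {
    idx <- match(rsids, snp_meta$rsid)
    if (anyNA(idx)) {
      stop_validation(paste0(
        "SNP(s) absent from metadata: ", paste(rsids[is.na(idx)], collapse = ", ")
      ))
    }
    snps <- as_tibble(snp_meta[idx, ])
  } else {
    snps <- tibble(
      rsid = rsids, chromosome = NA_character_, position = seq_len(p),
      minor_allele = NA_character_, major_allele = NA_character_,
      risk_allele = NA_character_, gene = NA_character_
    )
    for (j in seq_len(p)) {
      col <- cells[, j]
      pairs <- col[!col %in% GENO_MISSING_CODES & !grepl("^[012]$", col)]
      if (length(pairs)) {
        als <- infer_alleles(do.call(rbind, strsplit(pairs, "", fixed = TRUE)))
      } else {
        als <- list(minor = "G", major = "A")   # dosage-coded column
      }
      snps$minor_allele[j] <- als$minor
      snps$major_allele[j] <- als$major
    }
  }

  dosage <- matrix(NA_integer_, nrow(cells), p)
  for (j in seq_len(p)) {
    mj <- snps$minor_allele[j]
    Mj <- snps$major_allele[j]
    dosage[, j] <- vapply(
      seq_len(nrow(cells)),
      function(i) parse_geno_cell(cells[i, j], mj, Mj, i + 1L, rsids[j]),
      integer(1)
    )
  }
  genotype_matrix(dosage, tibble(sample_id = sample_id, phenotype = phenotype), snps)
}

#' Write a genotype matrix in the package's TSV dialect
#'
#' @param x a `genotype_matrix`.
#' @param path output path.
#' @param style `"alleles"` writes two-character allele pairs (missing as
#'   `"--"`); `"dosage"` writes integer dosages (missing as `"NA"`).
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(x, path, style = c("alleles", "dosage")) {
  style <- match.arg(style)
  d <- x$dosage
  if (style == "alleles") {
    cells <- matrix("--", nrow(d), ncol(d))
    for (j in seq_len(ncol(d))) {
      m <- x$snps$minor_allele[j]
      M <- x$snps$major_allele[j]
      g <- d[, j]
      cells[, j] <- c(paste0(M, M), paste0(M, m), paste0(m, m))[g + 1L]
      cells[is.na(g), j] <- "--"
    }
  } else {
    cells <- matrix(as.character(d), nrow(d), ncol(d))
    cells[is.na(d)] <- "NA"
  }
  header <- paste(c("sample_id", "phenotype", x$snps$rsid), collapse = "\t")
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(x$samples$sample_id[i], x$samples$phenotype[i], cells[i, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write SNP metadata as TSV
#'
#' @param snps SNP metadata tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_meta <- function(snps, path) {
  readr::write_tsv(snps, path)
  invisible(path)
}

## ---- PLINK text ------------------------------------------------------------

#' Read a PLINK-style text fileset (.ped/.map)
#'
#' Six leading .ped columns (FID, IID, PAT, MAT, SEX, PHENOTYPE) followed by
#' two allele fields per SNP; phenotype `1` = control, `2` = case; samples
#' with phenotype `0`, `-9`, or anything else are dropped with a warning.
#' Allele `0` marks a missing call ("0 0" pairs become missing dosages).
#' Minor/major designation comes from `snp_meta` when given, else from
#' pooled allele frequencies.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (4 columns: chromosome, rsid,
#'   genetic distance, position).
#' @param snp_meta optional SNP metadata tibble or path.
#' @return a [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path, snp_meta = NULL) {
  if (!file.exists(ped_path)) stop_validation(paste0("file not found: ", ped_path))
  if (!file.exists(map_path)) stop_validation(paste0("file not found: ", map_path))
  if (is.character(snp_meta)) snp_meta <- read_snp_meta(snp_meta)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  if (any(lengths(map_fields) < 4L)) {
    stop_parse(".map rows need 4 fields: chromosome, rsid, cM, position")
  }
  map <- tibble(
    chromosome = vapply(map_fields, `[[`, character(1), 1),
    rsid = vapply(map_fields, `[[`, character(1), 2),
    position = as.integer(vapply(map_fields, `[[`, character(1), 4))
  )
  p <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  widths <- lengths(ped_fields)
  bad <- which(widths != 6L + 2L * p)
  if (length(bad)) {
    stop_validation(sprintf(
      ".ped line %d has %d genotype fields but .map lists %d SNPs",
      bad[1], widths[bad[1]] - 6L, p
    ))
  }
  ped <- do.call(rbind, ped_fields)
  phe_code <- ped[, 6]
  keep <- phe_code %in% c("1", "2")
  if (any(!keep)) {
    warn(sprintf(
      "%d sample(s) with missing/unknown phenotype code excluded", sum(!keep)
    ))
  }
  ped <- ped[keep, , drop = FALSE]
  if (nrow(ped) == 0L) stop_validation("no samples with phenotype 1/2 in .ped")
  sample_id <- ped[, 2]
  if (anyDuplicated(sample_id)) sample_id <- paste(ped[, 1], ped[, 2], sep = "_")
  phenotype <- ifelse(ped[, 6] == "2", "case", "control")

  a1 <- ped[, 6L + 2L * seq_len(p) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(p), drop = FALSE]

  if (!is.null(snp_meta)) {
    idx <- match(map$rsid, snp_meta$rsid)
    if (anyNA(idx)) {
      stop_validation(paste0(
        "SNP(s) absent from metadata: ", paste(map$rsid[is.na(idx)], collapse = ", ")
      ))
    }
    snps <- as_tibble(snp_meta[idx, ])
  } else {
    snps <- map
    snps$minor_allele <- NA_character_
    snps$major_allele <- NA_character_
    snps$risk_allele <- NA_character_
    snps$gene <- NA_character_
    for (j in seq_len(p)) {
      als <- infer_alleles(cbind(a1[, j], a2[, j]))
      snps$minor_allele[j] <- als$minor
      snps$major_allele[j] <- als$major
    }
  }

  dosage <- matrix(NA_integer_, nrow(ped), p)
  for (j in seq_len(p)) {
    m <- snps$minor_allele[j]
    M <- snps$major_allele[j]
    x1 <- a1[, j]
    x2 <- a2[, j]
    missing <- x1 == "0" | x2 == "0"
    alien <- !missing & (!(x1 %in% c(m, M)) | !(x2 %in% c(m, M)))
    if (any(alien)) {
      stop_parse(sprintf(
        "SNP %s: allele outside {%s,%s} in .ped", snps$rsid[j], M, m
      ))
    }
    g <- (x1 == m) + (x2 == m)
    g[missing] <- NA_integer_
    dosage[, j] <- as.integer(g)
  }
  genotype_matrix(dosage, tibble(sample_id = sample_id, phenotype = phenotype), snps)
}

## ---- VCF (optional) --------------------------------------------------------

#' Read biallelic genotypes from a VCF file
#'
#' Uses the GT field of biallelic records only (others are dropped with a
#' message).  VCF carries no phenotype, so case/control status must be
#' supplied.  The ALT allele is taken as the designated minor allele.
#'
#' @param path VCF path (requires the vcfR package).
#' @param phenotype named character vector (`"case"`/`"control"`) keyed by
#'   VCF sample name, or a data frame with columns `sample_id`, `phenotype`.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, phenotype) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_validation("VCF reading requires the 'vcfR' package.")
  }
  if (is.data.frame(phenotype)) {
    phenotype <- stats::setNames(phenotype$phenotype, phenotype$sample_id)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    inform(sprintf("%d non-biallelic record(s) dropped", sum(!bi)))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- colnames(gt)
  miss <- setdiff(ids, names(phenotype))
  if (length(miss)) {
    stop_validation(paste0(
      "no phenotype for VCF sample(s): ", paste(miss, collapse = ", ")
    ))
  }
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & grepl("^[01][/|][01]$", g)
    out[ok] <- (substr(g[ok], 1, 1) == "1") + (substr(g[ok], 3, 3) == "1")
    out
  }
  dosage <- matrix(NA_integer_, length(ids), nrow(gt))
  for (k in seq_len(nrow(gt))) dosage[, k] <- count_alt(gt[k, ])
  rsid <- fix[, "ID"]
  no_id <- is.na(rsid) | rsid == "."
  rsid[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  snps <- tibble(
    rsid = rsid,
    chromosome = fix[, "CHROM"],
    position = as.integer(fix[, "POS"]),
    minor_allele = fix[, "ALT"],
    major_allele = fix[, "REF"],
    risk_allele = NA_character_,
    gene = NA_character_
  )
  genotype_matrix(
    dosage,
    tibble(sample_id = ids, phenotype = unname(phenotype[ids])),
    snps
  )
}

## ---- grouped counts --------------------------------------------------------

#' Collapse individual genotypes to per-SNP case/control count triples
#'
#' Produces one row per SNP with genotype counts ordered (major-homozygote,
#' heterozygote, minor-homozygote) within cases and controls, the table
#' layout of a standard association report.  Missing calls are excluded
#' per SNP (complete-case per marker).
#'
#' @param x a [genotype_matrix()].
#' @return a tibble with columns `rsid`, `chromosome`, `position`,
#'   `minor_allele`, `major_allele`, `risk_allele`, `gene`,
#'   `case_hom_major`, `case_het`, `case_hom_minor`, `control_hom_major`,
#'   `control_het`, `control_hom_minor`, `n_cases_total`,
#'   `n_controls_total` (cohort sizes including missing calls).
#' @export
collapse_to_counts <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  is_case <- x$samples$phenotype == "case"
  tally <- function(d) {
    c(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE), sum(d == 2L, na.rm = TRUE))
  }
  ca <- apply(x$dosage[is_case, , drop = FALSE], 2, tally)
  co <- apply(x$dosage[!is_case, , drop = FALSE], 2, tally)
  out <- x$snps |>
    dplyr::select(dplyr::any_of(c(
      "rsid", "chromosome", "position", "minor_allele", "major_allele",
      "risk_allele", "gene"
    ))) |>
    dplyr::mutate(
      case_hom_major = unname(ca[1, ]), case_het = unname(ca[2, ]),
      case_hom_minor = unname(ca[3, ]),
      control_hom_major = unname(co[1, ]), control_het = unname(co[2, ]),
      control_hom_minor = unname(co[3, ]),
      n_cases_total = sum(is_case),
      n_controls_total = sum(!is_case)
    )
  class(out) <- c("snp_counts", class(out))
  out
}

# Column sets reused by downstream modules.
CASE_COUNT_COLS <- c("case_hom_major", "case_het", "case_hom_minor")
CONTROL_COUNT_COLS <- c("control_hom_major", "control_het", "control_hom_minor")

check_counts_tbl <- function(counts) {
  need <- c("rsid", "minor_allele", "major_allele", CASE_COUNT_COLS, CONTROL_COUNT_COLS)
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop_validation(paste0("counts table missing columns: ", paste(miss, collapse = ", ")))
  }
  cnt <- as.matrix(counts[c(CASE_COUNT_COLS, CONTROL_COUNT_COLS)])
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_validation("genotype counts must be non-negative integers.")
  }
  invisible(counts)
}

#' Re-orient genotype count triples to risk-allele dosage
#'
#' Maps each SNP's (major-homozygote, heterozygote, minor-homozygote) counts
#' onto risk-allele dosages 0/1/2: the identity order when the risk allele
#' is the designated minor allele, the reversed order when it is the major
#' allele.  Applying the flip twice is the identity.
#'
#' @param counts a counts table from [collapse_to_counts()] (or any tibble
#'   with the same count columns and `risk_allele` set).
#' @return a long tibble with columns `rsid`, `risk_allele`, `dosage`
#'   (0/1/2 copies of the risk allele), `case_n`, `control_n`.
#' @export
dosage_for_risk_allele <- function(counts) {
  check_counts_tbl(counts)
  if (any(is.na(counts$risk_allele))) {
    stop_validation(paste0(
      "risk_allele unset for: ",
      paste(counts$rsid[is.na(counts$risk_allele)], collapse = ", ")
    ))
  }
  ok <- counts$risk_allele == counts$minor_allele |
    counts$risk_allele == counts$major_allele
  if (!all(ok)) {
    stop_validation(paste0(
      "risk_allele is not one of the SNP's alleles for: ",
      paste(counts$rsid[!ok], collapse = ", ")
    ))
  }
  purrr::pmap_dfr(counts, function(...) {
    row <- list(...)
    ca <- c(row$case_hom_major, row$case_het, row$case_hom_minor)
    co <- c(row$control_hom_major, row$control_het, row$control_hom_minor)
    if (row$risk_allele == row$major_allele) {
      ca <- rev(ca)
      co <- rev(co)
    }
    tibble(
      rsid = row$rsid, risk_allele = row$risk_allele,
      dosage = 0:2, case_n = ca, control_n = co
    )
  })
}
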
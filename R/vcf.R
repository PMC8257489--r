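#' Read germline variant calls and extract model features from a VCF
#'
#' Parses a single-sample VCF (v4.x) and returns one row per called
#' non-reference genotype. Reference-homozygous and fully missing genotypes
#' are skipped; multiallelic records are kept as one call carrying all
#' alternate alleles (the genotype indices refer to the record's own alt
#' list, which the complex-heterozygous stratum needs intact). Numeric
#' features are extracted according to `schema`; a feature missing from a
#' record is either filled with the schema's sentinel or, when the entry's
#' `missing` policy is `NA`, causes the call to be dropped and counted in
#' the skip log.
#'
#' @param path Path to a VCF file (optionally bgzipped).
#' @param schema A [feature_schema()] describing which fields become
#'   features.
#' @param sample_id Sample identifier to record; defaults to the VCF's
#'   sample column name.
#' @param quiet Suppress the record-count log message.
#' @return A tibble of calls with columns `sample_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt` (comma-separated alternate alleles), `gt1`,
#'   `gt2` (sorted allele indices, 0 = reference) and one numeric column per
#'   schema feature. Attributes `n_records`, `n_nonref`, `n_skipped` carry
#'   the read/skip accounting.
#' @export
read_vcf <- function(path, schema = schema_dragen_like(), sample_id = NULL,
                     quiet = FALSE) {
  stopifnot(inherits(schema, "feature_schema"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_records <- nrow(fix)
  if (is.null(n_records) || n_records == 0) {
    out <- empty_calls(schema)
    attr(out, "n_records") <- 0L
    attr(out, "n_nonref") <- 0L
    attr(out, "n_skipped") <- 0L
    attr(out, "schema_id") <- schema$schema_id
    return(out)
  }
  if (ncol(vcf@gt) != 2) {
    abort("read_vcf expects a single-sample VCF (one genotype column).")
  }
  sample_id <- sample_id %||% colnames(vcf@gt)[2]

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    abort(paste0(
      "Malformed VCF: non-numeric POS at record(s) ",
      paste(head(which(is.na(pos)), 5), collapse = ", ")
    ))
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  gt_raw[is.na(gt_raw)] <- "."
  gt_parts <- stringr::str_split(gt_raw, "[/|]")
  gt_mat <- t(vapply(gt_parts, function(g) {
    if (length(g) == 1) g <- c(g, g) # haploid treated as homozygous
    suppressWarnings(as.integer(g[1:2]))
  }, integer(2)))
  gt1 <- pmin(gt_mat[, 1], gt_mat[, 2])
  gt2 <- pmax(gt_mat[, 1], gt_mat[, 2])
  nonref <- !is.na(gt1) & !is.na(gt2) & gt2 > 0
  n_nonref <- sum(nonref)

  calls <- tibble(
    sample_id = sample_id,
    chrom = fix[nonref, "CHROM"],
    pos = pos[nonref],
    ref = fix[nonref, "REF"],
    alt = fix[nonref, "ALT"],
    gt1 = gt1[nonref],
    gt2 = gt2[nonref]
  )

  n_alts <- stringr::str_count(calls$alt, ",") + 1L
  if (any(calls$gt2 > n_alts)) {
    abort(paste0(
      "Genotype index exceeds alt count at record(s) ",
      paste(head(which(calls$gt2 > n_alts), 5), collapse = ", ")
    ))
  }

  drop <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(schema$entries))) {
    entry <- schema$entries[i, ]
    raw <- extract_source(vcf, entry$source)[nonref]
    val <- apply_transform(raw, entry$transform, calls)
    if (is.na(entry$missing)) {
      drop <- drop | is.na(val)
    } else {
      val[is.na(val)] <- entry$missing
    }
    calls[[entry$feature]] <- val
  }
  n_dropped <- sum(drop)
  calls <- calls[!drop, , drop = FALSE]

  n_skipped <- (n_records - n_nonref) + n_dropped
  if (!quiet) {
    inform(sprintf(
      "read_vcf: %d records, %d calls emitted, %d skipped (%d non-genotyped/ref, %d missing features)",
      n_records, nrow(calls), n_skipped, n_records - n_nonref, n_dropped
    ))
  }
  attr(calls, "n_records") <- n_records
  attr(calls, "n_nonref") <- as.integer(n_nonref)
  attr(calls, "n_skipped") <- as.integer(n_skipped)
  attr(calls, "schema_id") <- schema$schema_id
  calls
}

empty_calls <- function(schema = NULL) {
  out <- tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gt1 = integer(), gt2 = integer()
  )
  if (!is.null(schema)) {
    for (f in schema$entries$feature) out[[f]] <- numeric()
  }
  out
}

extract_source <- function(vcf, source) {
  if (source == "QUAL") {
    return(suppressWarnings(as.numeric(vcf@fix[, "QUAL"])))
  }
  key <- sub("^(INFO|FORMAT):", "", source)
  if (grepl("^INFO:", source)) {
    return(suppressWarnings(
      vcfR::extract.info(vcf, element = key, as.numeric = FALSE)
    ))
  }
  fmt <- colnames(vcf@gt) # FORMAT + sample
  m <- tryCatch(
    vcfR::extract.gt(vcf, element = key),
    error = function(e) matrix(NA_character_, nrow = nrow(vcf@fix), ncol = 1)
  )
  m[, 1]
}

apply_transform <- function(raw, transform, calls) {
  if (transform == "allele-fraction") {
    # raw is an AD-like comma list of per-allele depths, reference first;
    # fraction = non-reference depth / total depth.
    vapply(as.character(raw), function(x) {
      if (is.na(x) || x == ".") {
        return(NA_real_)
      }
      d <- suppressWarnings(as.numeric(strsplit(x, ",")[[1]]))
      if (anyNA(d) || sum(d) <= 0) {
        return(NA_real_)
      }
      (sum(d) - d[1]) / sum(d)
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    val <- suppressWarnings(as.numeric(raw))
    if (transform == "log10") {
      val <- ifelse(!is.na(val) & val > 0, log10(val), NA_real_)
    }
    val
  }
}

format_num <- function(x) {
  out <- ifelse(is.na(x), ".", formatC(x, format = "g", digits = 7))
  sub("^\\s+", "", out)
}

# Shared low-level VCF writer for calls tibbles. Builds QUAL from the
# `qual` column, FORMAT GT:GQ:DP:AD from `gq`/`dp`/`af` when present, and
# INFO from `mq`/`qd` plus any extra per-record strings.
write_calls_vcf <- function(calls, path, extra_info = NULL) {
  sample_name <- if (nrow(calls) > 0) calls$sample_id[1] else "SAMPLE"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fptriage",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=TRIAGE,Number=1,Type=String,Description=\"Triage decision: predicted_true, predicted_false, or not_eligible\">",
    "##INFO=<ID=FPLABEL,Number=1,Type=String,Description=\"Truth-match label: TP or FP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample_name,
      sep = "\t"
    )
  )
  if (nrow(calls) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }

  info_parts <- list()
  if ("mq" %in% names(calls)) info_parts$mq <- paste0("MQ=", format_num(calls$mq))
  if ("qd" %in% names(calls)) info_parts$qd <- paste0("QD=", format_num(calls$qd))
  if (!is.null(extra_info)) {
    for (nm in names(extra_info)) {
      info_parts[[nm]] <- paste0(nm, "=", extra_info[[nm]])
    }
  }
  info <- if (length(info_parts) == 0) {
    rep(".", nrow(calls))
  } else {
    do.call(paste, c(unname(info_parts), sep = ";"))
  }

  gt <- paste0(calls$gt1, "/", calls$gt2)
  fmt_keys <- "GT"
  fmt_vals <- gt
  if ("gq" %in% names(calls)) {
    fmt_keys <- c(fmt_keys, "GQ")
    fmt_vals <- paste(fmt_vals, format_num(calls$gq), sep = ":")
  }
  has_ad <- all(c("dp", "af") %in% names(calls))
  if ("dp" %in% names(calls)) {
    fmt_keys <- c(fmt_keys, "DP")
    fmt_vals <- paste(fmt_vals, format_num(round(calls$dp)), sep = ":")
  }
  if (has_ad) {
    dp <- pmax(round(calls$dp), 1)
    alt_d <- round(dp * pmin(pmax(calls$af, 0), 1))
    ref_d <- dp - alt_d
    n_alts <- stringr::str_count(calls$alt, ",") + 1L
    first_alt <- pmax(calls$gt1, 1L) # put non-ref depth on the first genotyped alt
    ad <- vapply(seq_len(nrow(calls)), function(i) {
      depths <- integer(n_alts[i] + 1L)
      depths[1] <- ref_d[i]
      idx <- if (calls$gt1[i] > 0) calls$gt1[i] else calls$gt2[i]
      depths[idx + 1L] <- alt_d[i]
      paste(depths, collapse = ",")
    }, character(1))
    fmt_keys <- c(fmt_keys, "AD")
    fmt_vals <- paste(fmt_vals, ad, sep = ":")
  }

  qual <- if ("qual" %in% names(calls)) format_num(calls$qual) else rep(".", nrow(calls))
  body <- paste(
    calls$chrom, calls$pos, ".", calls$ref, calls$alt, qual, "PASS",
    info, paste(fmt_keys, collapse = ":"), fmt_vals,
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write triage decisions to an annotated VCF
#'
#' Writes one record per call with an `INFO/TRIAGE` annotation recording the
#' decision (`predicted_true`, `predicted_false`, or `not_eligible`). The
#' file round-trips through [read_vcf()]: chromosome, position, alleles and
#' genotype are preserved exactly.
#'
#' @param decisions Calls tibble carrying a `decision` (or `prediction`)
#'   character column.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(decisions, path) {
  dec_col <- if ("decision" %in% names(decisions)) "decision" else "prediction"
  if (nrow(decisions) > 0 && !dec_col %in% names(decisions)) {
    abort("decisions must carry a 'decision' or 'prediction' column.")
  }
  extra <- if (nrow(decisions) > 0) list(TRIAGE = as.character(decisions[[dec_col]])) else NULL
  write_calls_vcf(decisions, path, extra_info = extra)
}
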
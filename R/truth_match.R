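#' Reduce a variant to its minimal representation
#'
#' Removes the shared prefix and then the shared suffix of `ref` and `alt`,
#' always retaining at least one base in each; the position advances by the
#' number of prefix bases removed. Trimming makes records comparable when
#' the same event is written with redundant context bases. This is a
#' per-record normalization only: no left-alignment against a reference
#' genome is attempted, and no haplotype-aware multi-record equivalence is
#' considered.
#'
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of alleles (same length as `pos`).
#' @return A tibble with trimmed `pos`, `ref`, `alt`.
#' @examples
#' trim_variant(100, "ATT", "AT") # 101, TT, T
#' trim_variant(50, "CAG", "CTG") # 51, A, T
#' @export
trim_variant <- function(pos, ref, alt) {
  stopifnot(length(ref) == length(alt), length(pos) == length(ref))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    abort("trim_variant: ref and alt must be non-empty.")
  }
  out_pos <- as.integer(pos)
  out_ref <- ref
  out_alt <- alt
  for (i in seq_along(out_ref)) {
    r <- strsplit(out_ref[i], "")[[1]]
    a <- strsplit(out_alt[i], "")[[1]]
    # shared prefix (keep >= 1 base on each side)
    p <- 0L
    while (p < length(r) - 1L && p < length(a) - 1L && r[p + 1L] == a[p + 1L]) {
      p <- p + 1L
    }
    if (p > 0L) {
      r <- r[-seq_len(p)]
      a <- a[-seq_len(p)]
      out_pos[i] <- out_pos[i] + p
    }
    # shared suffix (keep >= 1 base on each side)
    s <- 0L
    while (s < length(r) - 1L && s < length(a) - 1L &&
      r[length(r) - s] == a[length(a) - s]) {
      s <- s + 1L
    }
    if (s > 0L) {
      r <- r[seq_len(length(r) - s)]
      a <- a[seq_len(length(a) - s)]
    }
    out_ref[i] <- paste(r, collapse = "")
    out_alt[i] <- paste(a, collapse = "")
  }
  tibble(pos = out_pos, ref = out_ref, alt = out_alt)
}

split_alts <- function(alt) strsplit(alt, ",", fixed = TRUE)

# A canonical per-call match key: for every genotyped non-reference allele,
# the trimmed (chrom, pos, ref, alt) triple; keys are sorted so the key is
# invariant to allele order. With genotype_aware the key keeps allele
# multiplicity plus the count of reference alleles (the unordered genotype
# multiset); without, only the set of distinct non-reference alleles.
call_match_keys <- function(calls, genotype_aware = TRUE) {
  if (nrow(calls) == 0) {
    return(character(0))
  }
  alts <- split_alts(calls$alt)
  vapply(seq_len(nrow(calls)), function(i) {
    gt <- c(calls$gt1[i], calls$gt2[i])
    nonref <- gt[gt > 0]
    allele_keys <- vapply(nonref, function(ai) {
      tr <- trim_variant(calls$pos[i], calls$ref[i], alts[[i]][ai])
      paste(calls$chrom[i], tr$pos, tr$ref, tr$alt, sep = ":")
    }, character(1))
    if (genotype_aware) {
      paste(
        paste(sort(allele_keys), collapse = "|"),
        sum(gt == 0),
        sep = "&ref:"
      )
    } else {
      paste(sort(unique(allele_keys)), collapse = "|")
    }
  }, character(1))
}

#' Label called variants against a truth set within benchmark regions
#'
#' Restricts the query calls to those whose reference span lies inside the
#' benchmark regions, then labels each remaining call `"TP"` (present in
#' the truth set) or `"FP"` (absent). Matching is per record after
#' [trim_variant()] normalization of every genotyped allele; with
#' `genotype_aware = TRUE` (default) the unordered genotype multiset must
#' also agree, so a heterozygous call at a truly homozygous site is labeled
#' a false positive call and will be confirmed.
#'
#' This matcher is a deliberately simplified, deterministic stand-in for
#' haplotype-aware comparison engines (e.g. RTG vcfeval): it gives no credit
#' for multi-record haplotype equivalence and performs no left-alignment.
#'
#' @param query Calls tibble for one sample (from [read_vcf()]).
#' @param truth Truth-set calls tibble for the same sample.
#' @param regions Benchmark region tibble (from [read_bed()]).
#' @param genotype_aware Require genotype agreement for a match.
#' @return The in-region query calls with an added `label` column
#'   (`"TP"`/`"FP"`).
#' @export
label_calls <- function(query, truth, regions, genotype_aware = TRUE) {
  query <- as_tibble(query)
  truth <- as_tibble(truth)
  if (nrow(query) > 0 && nrow(truth) > 0 &&
    length(intersect(unique(query$chrom), unique(truth$chrom))) == 0) {
    abort(paste0(
      "No chromosome shared between query and truth ",
      "(query: ", paste(head(unique(query$chrom), 3), collapse = ","),
      "; truth: ", paste(head(unique(truth$chrom), 3), collapse = ","),
      "); check chromosome naming."
    ))
  }
  inside <- span_in_regions(query, regions)
  labeled <- query[inside, , drop = FALSE]
  qkeys <- call_match_keys(labeled, genotype_aware)
  tkeys <- call_match_keys(truth, genotype_aware)
  labeled$label <- if_else(qkeys %in% tkeys, "TP", "FP")
  labeled
}

#' Write TP- and FP-labeled calls as a VCF pair
#'
#' Mirrors the two-file convention of truth-comparison tools: one VCF of
#' true positive calls and one of false positive calls, each annotated with
#' `INFO/FPLABEL`.
#'
#' @param labeled Labeled calls (from [label_calls()]).
#' @param tp_path,fp_path Output VCF paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_labeled_vcfs <- function(labeled, tp_path, fp_path) {
  tp <- labeled[labeled$label == "TP", , drop = FALSE]
  fp <- labeled[labeled$label == "FP", , drop = FALSE]
  write_calls_vcf(tp, tp_path, extra_info = if (nrow(tp)) list(FPLABEL = rep("TP", nrow(tp))))
  write_calls_vcf(fp, fp_path, extra_info = if (nrow(fp)) list(FPLABEL = rep("FP", nrow(fp))))
  invisible(c(tp = tp_path, fp = fp_path))
}
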
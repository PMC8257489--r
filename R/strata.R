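#' The six variant-type by genotype strata
#'
#' Calls are modeled separately in six classes: SNVs and indels, each split
#' by genotype into heterozygous (one non-reference allele), homozygous
#' (two copies of the same non-reference allele), and complex heterozygous
#' (two different non-reference alleles). Error modes differ enough across
#' these classes that one model per stratum outperforms a pooled model.
#'
#' @return Character vector of the six stratum labels in canonical order.
#' @export
stratum_levels <- function() {
  c(
    "snv-het", "snv-hom", "snv-complexhet",
    "indel-het", "indel-hom", "indel-complexhet"
  )
}

#' Classify calls into variant-type by genotype strata
#'
#' Adds `variant_type`, `zygosity` and `stratum` columns. A call is an SNV
#' only if every genotyped non-reference allele has single-base ref and alt
#' after [trim_variant()] normalization; a genotype mixing an SNV allele
#' with an indel allele is classified into the indel stratum (indel error
#' modes dominate such sites). Zygosity is `hom` when both alleles are the
#' same non-reference allele, `complexhet` when two distinct non-reference
#' alleles are present, and `het` otherwise.
#'
#' @param calls Calls tibble.
#' @param on_unclassifiable `"error"` (default) to fail on calls without a
#'   non-reference genotyped allele, `"drop"` to remove them with a warning.
#' @return `calls` with stratum columns added.
#' @examples
#' calls <- tibble::tibble(
#'   sample_id = "s", chrom = "chr1", pos = c(1L, 5L), ref = c("A", "AT"),
#'   alt = c("G", "A"), gt1 = c(0L, 1L), gt2 = c(1L, 1L)
#' )
#' classify_stratum(calls)$stratum
#' @export
classify_stratum <- function(calls, on_unclassifiable = c("error", "drop")) {
  on_unclassifiable <- match.arg(on_unclassifiable)
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    calls$variant_type <- character(0)
    calls$zygosity <- character(0)
    calls$stratum <- character(0)
    return(calls)
  }
  bad <- is.na(calls$gt1) | is.na(calls$gt2) | calls$gt2 <= 0
  if (any(bad)) {
    if (on_unclassifiable == "error") {
      abort(paste0(
        "Calls without a non-reference genotyped allele cannot be ",
        "classified (rows ", paste(head(which(bad), 5), collapse = ", "), ")."
      ))
    }
    warn(sprintf("classify_stratum: dropping %d unclassifiable call(s).", sum(bad)))
    calls <- calls[!bad, , drop = FALSE]
  }
  alts <- split_alts(calls$alt)
  is_snv <- vapply(seq_len(nrow(calls)), function(i) {
    gt <- c(calls$gt1[i], calls$gt2[i])
    nonref <- unique(gt[gt > 0])
    all(vapply(nonref, function(ai) {
      tr <- trim_variant(calls$pos[i], calls$ref[i], alts[[i]][ai])
      nchar(tr$ref) == 1 && nchar(tr$alt) == 1
    }, logical(1)))
  }, logical(1))
  zyg <- dplyr::case_when(
    calls$gt1 == calls$gt2 ~ "hom",
    calls$gt1 > 0 & calls$gt1 != calls$gt2 ~ "complexhet",
    TRUE ~ "het"
  )
  calls$variant_type <- if_else(is_snv, "snv", "indel")
  calls$zygosity <- zyg
  calls$stratum <- paste(calls$variant_type, calls$zygosity, sep = "-")
  calls
}

#' Partition labeled calls by stratum
#'
#' Splits calls into the six strata; unclassifiable calls (no non-reference
#' genotyped allele) are dropped with a warning. Every classifiable call
#' lands in exactly one bucket.
#'
#' @param calls Calls tibble (labeled or not).
#' @return Named list of six tibbles, keyed by [stratum_levels()]; empty
#'   strata are empty tibbles.
#' @export
partition_by_stratum <- function(calls) {
  if (nrow(calls) == 0 || !"stratum" %in% names(calls)) {
    calls <- suppressWarnings(classify_stratum(calls, on_unclassifiable = "drop"))
  }
  out <- lapply(stratum_levels(), function(s) {
    calls[calls$stratum == s, , drop = FALSE]
  })
  setNames(out, stratum_levels())
}
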
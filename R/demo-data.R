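# Bundled demonstration cohorts, built in code. Both are synthetic
# reconstructions shaped like a clinical genome confirmation workload:
# the joint mix of interpretation categories, benchmark membership,
# per-stratum model availability and predictions follows the proportions
# a diagnostic laboratory sees when triaging reported variants, at a
# desk-checkable size. They drive the worked examples and the
# confirmation-policy arithmetic tests; no sequencing data is involved.

demo_variant_block <- function(n, stratum, category, in_benchmark, prediction,
                               start_pos) {
  if (n == 0) {
    return(NULL)
  }
  proto <- switch(stratum,
    "snv-het" = list(ref = "A", alt = "G", gt1 = 0L, gt2 = 1L),
    "snv-hom" = list(ref = "C", alt = "T", gt1 = 1L, gt2 = 1L),
    "snv-complexhet" = list(ref = "A", alt = "G,T", gt1 = 1L, gt2 = 2L),
    "indel-het" = list(ref = "AT", alt = "A", gt1 = 0L, gt2 = 1L),
    "indel-hom" = list(ref = "AT", alt = "A", gt1 = 1L, gt2 = 1L),
    "indel-complexhet" = list(ref = "ATT", alt = "AT,A", gt1 = 1L, gt2 = 2L)
  )
  tibble(
    chrom = "chr1",
    pos = seq.int(start_pos, by = 10L, length.out = n),
    ref = proto$ref, alt = proto$alt, gt1 = proto$gt1, gt2 = proto$gt2,
    stratum = stratum, category = category, in_benchmark = in_benchmark,
    prediction = prediction
  )
}

#' Demonstration cohort of reported clinical variants
#'
#' A deterministic synthetic cohort of 306 reported variants, each carrying
#' an interpretation category, benchmark-union membership, stratum, and a
#' triage-model prediction (`NA` for the complex-heterozygous SNV stratum,
#' which has no passing model). Useful for exercising
#' [decide_confirmation()] and [summarize_approach()] across all four
#' [approaches()] at desk scale.
#'
#' @return Tibble of 306 variants.
#' @examples
#' v <- demo_reported_variants()
#' summarize_approach(decide_confirmation(v, "nonactionable"))
#' @export
demo_reported_variants <- function() {
  spec <- list(
    # stratum, category, in_benchmark, prediction, n
    list("snv-complexhet", "carrier", TRUE, NA_character_, 6L),
    # actionable, outside benchmark: 1 predicted true, 3 predicted false
    list("snv-het", "primary", FALSE, "predicted_true", 1L),
    list("snv-het", "primary", FALSE, "predicted_false", 1L),
    list("snv-het", "actionable_secondary", FALSE, "predicted_false", 2L),
    # actionable, inside benchmark: 23 true / 21 false
    list("snv-het", "primary", TRUE, "predicted_true", 12L),
    list("snv-het", "actionable_secondary", TRUE, "predicted_true", 11L),
    list("snv-het", "primary", TRUE, "predicted_false", 11L),
    list("snv-het", "actionable_secondary", TRUE, "predicted_false", 10L),
    # nonactionable, outside benchmark: 75 true / 9 false
    list("snv-het", "carrier", FALSE, "predicted_true", 60L),
    list("snv-het", "carrier", FALSE, "predicted_false", 7L),
    list("snv-hom", "carrier", FALSE, "predicted_true", 10L),
    list("snv-hom", "pgx", FALSE, "predicted_false", 1L),
    list("indel-het", "pgx", FALSE, "predicted_true", 5L),
    list("indel-het", "carrier", FALSE, "predicted_false", 1L),
    # nonactionable, inside benchmark: 141 true / 27 false
    list("snv-het", "carrier", TRUE, "predicted_true", 84L),
    list("snv-het", "pgx", TRUE, "predicted_true", 20L),
    list("snv-het", "carrier", TRUE, "predicted_false", 22L),
    list("snv-hom", "carrier", TRUE, "predicted_true", 20L),
    list("snv-hom", "pgx", TRUE, "predicted_true", 4L),
    list("indel-het", "carrier", TRUE, "predicted_true", 13L),
    list("indel-het", "carrier", TRUE, "predicted_false", 5L)
  )
  pos <- 1000L
  blocks <- list()
  for (b in spec) {
    blocks[[length(blocks) + 1]] <- demo_variant_block(
      b[[5]], b[[1]], b[[2]], b[[3]], b[[4]], pos
    )
    pos <- pos + 10L * b[[5]]
  }
  bind_rows(blocks)
}

#' Demonstration retrospective confirmation data
#'
#' A deterministic synthetic set of 232 reported variants with both a
#' triage-model prediction and an orthogonal (Sanger-style) confirmation
#' outcome, shaped like a retrospective concordance review: mostly
#' confirmed-true heterozygous SNVs with a modest flagged fraction, a few
#' homozygous SNVs, and a small heterozygous-indel group containing the two
#' failed confirmations.
#'
#' @return List with `predictions` and `confirmations` tibbles, joinable on
#'   the variant key, ready for [retrospective_concordance()].
#' @export
demo_confirmation_outcomes <- function() {
  spec <- list(
    # stratum, prediction, orthogonal_result, n
    list("snv-het", "predicted_true", "true", 147L),
    list("snv-het", "predicted_false", "true", 29L),
    list("snv-hom", "predicted_true", "true", 33L),
    list("snv-hom", "predicted_false", "true", 1L),
    list("indel-het", "predicted_true", "true", 15L),
    list("indel-het", "predicted_false", "true", 5L),
    list("indel-het", "predicted_false", "false", 2L)
  )
  pos <- 5000L
  blocks <- list()
  results <- character(0)
  for (b in spec) {
    blk <- demo_variant_block(
      b[[4]], b[[1]],
      category = "carrier", in_benchmark = TRUE, prediction = b[[2]],
      start_pos = pos
    )
    blocks[[length(blocks) + 1]] <- blk
    results <- c(results, rep(b[[3]], b[[4]]))
    pos <- pos + 10L * b[[4]]
  }
  predictions <- bind_rows(blocks)
  confirmations <- predictions |>
    select("chrom", "pos", "ref", "alt", "gt1", "gt2") |>
    mutate(orthogonal_result = results)
  list(predictions = predictions, confirmations = confirmations)
}

#' Reference model summary table
#'
#' Published summary statistics for the six production triage models of a
#' Dragen-based germline pipeline: per stratum, the selected algorithm, the
#' cross-validation capture-rate and TP-flag-rate mean and SD (percent),
#' and the final testing rates (percent). Shipped as package data so the
#' -2 SD lower-bound arithmetic and the expected-TP-flag-rate column of
#' [retrospective_concordance()] can be reproduced without retraining.
#'
#' @return Tibble, one row per stratum (complex-heterozygous SNVs have no
#'   passing model and carry `NA` rates).
#' @export
reference_model_summary <- function() {
  path <- system.file("extdata", "model_summary_reference.tsv",
    package = "fptriage"
  )
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
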
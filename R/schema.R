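#' Define a feature-extraction schema for a variant-calling pipeline
#'
#' Different secondary pipelines annotate calls with different quality
#' metrics, so feature extraction is driven by a schema: an ordered table of
#' feature definitions, each naming a VCF source field, a transform, and a
#' policy for missing values. Two ready-made schemas ship with the package
#' ([schema_dragen_like()], [schema_strelka2_like()]) built from fields most
#' germline callers emit; real deployments are expected to define their own
#' schema in the run configuration.
#'
#' @param schema_id Single string identifying the pipeline the schema
#'   describes. Model bundles record it and refuse to score calls extracted
#'   under a different schema.
#' @param entries A data frame with columns `feature` (unique name),
#'   `source` (one of `"QUAL"`, `"INFO:<key>"`, `"FORMAT:<key>"`),
#'   `transform` (`"identity"`, `"allele-fraction"`, or `"log10"`), and
#'   `missing` (a number used as fill value, or `NA` to drop calls missing
#'   the field).
#'
#' @return An object of class `feature_schema`.
#' @examples
#' feature_schema("toy", tibble::tibble(
#'   feature = "qual", source = "QUAL", transform = "identity", missing = 0
#' ))
#' @export
feature_schema <- function(schema_id, entries) {
  stopifnot(is.character(schema_id), length(schema_id) == 1)
  entries <- as_tibble(entries)
  required <- c("feature", "source", "transform", "missing")
  if (!all(required %in% names(entries))) {
    abort("Schema entries need columns feature, source, transform, missing.")
  }
  if (anyDuplicated(entries$feature)) {
    abort("Schema feature names must be unique.")
  }
  ok_source <- entries$source == "QUAL" |
    grepl("^INFO:.+", entries$source) | grepl("^FORMAT:.+", entries$source)
  if (!all(ok_source)) {
    abort(paste0(
      "Unresolvable schema source(s): ",
      paste(entries$source[!ok_source], collapse = ", ")
    ))
  }
  ok_tr <- entries$transform %in% c("identity", "allele-fraction", "log10")
  if (!all(ok_tr)) {
    abort(paste0(
      "Unknown transform(s): ", paste(entries$transform[!ok_tr], collapse = ", ")
    ))
  }
  entries$missing <- as.numeric(entries$missing)
  structure(
    list(schema_id = schema_id, entries = entries),
    class = "feature_schema"
  )
}

#' @exportS3Method base::print
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", x$schema_id, "\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Built-in feature schemas
#'
#' `schema_dragen_like()` and `schema_strelka2_like()` cover quality metrics
#' commonly available from, respectively, a Dragen-style and a
#' Strelka2-style germline pipeline: site quality, genotype quality, depth,
#' alternate allele fraction (from `FORMAT/AD`), mapping quality, and a
#' quality-by-depth or strand-bias statistic. They are defaults, not claims
#' about any specific pipeline's full metric set; missing fields fall back
#' to 0 so call counts are conserved.
#'
#' @return A [feature_schema()].
#' @examples
#' schema_dragen_like()
#' @export
schema_dragen_like <- function() {
  feature_schema("dragen-like", tibble(
    feature   = c("qual", "gq", "dp", "af", "mq", "qd"),
    source    = c("QUAL", "FORMAT:GQ", "FORMAT:DP", "FORMAT:AD", "INFO:MQ", "INFO:QD"),
    transform = c("identity", "identity", "identity", "allele-fraction", "identity", "identity"),
    missing   = 0
  ))
}

#' @rdname schema_dragen_like
#' @export
schema_strelka2_like <- function() {
  feature_schema("strelka2-like", tibble(
    feature   = c("qual", "gqx", "dp", "af", "mq", "sb"),
    source    = c("QUAL", "FORMAT:GQX", "FORMAT:DP", "FORMAT:AD", "INFO:MQ", "INFO:SB"),
    transform = c("identity", "identity", "identity", "allele-fraction", "identity", "identity"),
    missing   = 0
  ))
}
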
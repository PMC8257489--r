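#' Clinical risk approaches
#'
#' Four policies for which reported variants the triage models may exempt
#' from orthogonal confirmation: `"all"` applies models to every variant
#' with a passing model; `"benchmark"` additionally confirms everything
#' outside the benchmark-region union (where models were never validated);
#' `"nonactionable"` additionally confirms every actionable variant
#' (primary or actionable secondary finding); `"benchmark-nonactionable"`
#' applies both restrictions. Restriction only ever adds confirmations.
#'
#' @return Character vector of the four approach names.
#' @export
approaches <- function() {
  c("all", "benchmark", "nonactionable", "benchmark-nonactionable")
}

actionable_categories <- function() c("primary", "actionable_secondary")

clinical_categories <- function() {
  c("primary", "actionable_secondary", "carrier", "pgx")
}

#' Read a clinical variant table
#'
#' Tab-delimited file with columns `chrom`, `pos`, `ref`, `alt`,
#' `genotype` (e.g. `0/1`), and `category` (one of `primary`,
#' `actionable_secondary`, `carrier`, `pgx`).
#'
#' @param path Path to the TSV file.
#' @return Calls-style tibble with parsed `gt1`/`gt2` and `category`.
#' @export
read_clinical_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "genotype", "category")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("Clinical table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) == 0) abort("Clinical table is empty.")
  bad <- !tbl$category %in% clinical_categories()
  if (any(bad)) {
    abort(paste0(
      "Unknown interpretation category at row(s) ",
      paste(head(which(bad), 5), collapse = ", ")
    ))
  }
  gt <- stringr::str_split_fixed(tbl$genotype, "[/|]", 2)
  g1 <- suppressWarnings(as.integer(gt[, 1]))
  g2 <- suppressWarnings(as.integer(gt[, 2]))
  tbl$gt1 <- pmin(g1, g2)
  tbl$gt2 <- pmax(g1, g2)
  tbl$pos <- as.integer(tbl$pos)
  tbl$genotype <- NULL
  tbl
}

#' Decide confirmation ordering for reported variants
#'
#' Applies one clinical risk approach to a table of reported variants and
#' returns, per variant, its eligibility for model-based triage, the model
#' prediction, and the confirm/skip outcome. A confirmation is ordered
#' unless the variant is eligible *and* predicted to be a true positive
#' call; in particular every ineligible variant — actionable under a
#' nonactionable-restricted approach, outside the benchmark union under a
#' benchmark-restricted approach, or in a stratum with no passing model —
#' is always confirmed.
#'
#' Approach restrictions are checked first (a variant both outside the
#' benchmark union and actionable is reported in the combined category),
#' then model availability.
#'
#' @param variants Tibble with `category`, `in_benchmark`, `stratum`
#'   (added via [classify_stratum()] if absent) and either a `prediction`
#'   column (`"predicted_true"`/`"predicted_false"`, `NA` where no model
#'   applies) or the feature columns needed to score with `model_set`.
#' @param approach One of [approaches()].
#' @param model_set Optional `model_set` from [train_stratum_models()] used
#'   to compute predictions.
#' @return `variants` plus `eligibility`, `prediction`, `confirm`.
#' @export
decide_confirmation <- function(variants, approach = "nonactionable",
                                model_set = NULL) {
  approach <- match.arg(approach, approaches())
  variants <- as_tibble(variants)
  if (!"category" %in% names(variants)) {
    abort("decide_confirmation needs a 'category' column.")
  }
  if (!"in_benchmark" %in% names(variants)) {
    abort("decide_confirmation needs an 'in_benchmark' column (see span_in_regions()).")
  }
  if (!"stratum" %in% names(variants)) {
    variants <- suppressWarnings(classify_stratum(variants, on_unclassifiable = "drop"))
  }

  # model predictions: either precomputed or scored now
  if (!is.null(model_set)) {
    prediction <- rep(NA_character_, nrow(variants))
    for (s in unique(variants$stratum)) {
      m <- model_set$models[[s]]
      if (is.null(m)) next
      idx <- which(variants$stratum == s)
      flagged <- predict(m$model, variants[idx, , drop = FALSE],
        target = m$target, type = "flag"
      )
      prediction[idx] <- if_else(flagged, "predicted_false", "predicted_true")
    }
  } else if ("prediction" %in% names(variants)) {
    prediction <- as.character(variants$prediction)
    prediction[prediction %in% c("none", "")] <- NA_character_
  } else {
    abort("Provide either a model_set or a 'prediction' column.")
  }

  actionable <- variants$category %in% actionable_categories()
  outside <- !variants$in_benchmark
  restrict_act <- approach %in% c("nonactionable", "benchmark-nonactionable")
  restrict_bench <- approach %in% c("benchmark", "benchmark-nonactionable")
  no_model <- is.na(prediction) | is.na(variants$stratum)

  eligibility <- dplyr::case_when(
    restrict_act & restrict_bench & actionable & outside ~ "not_eligible_outside_and_actionable",
    restrict_act & actionable ~ "not_eligible_actionable",
    restrict_bench & outside ~ "not_eligible_outside_benchmark",
    no_model ~ "not_eligible_no_model",
    TRUE ~ "eligible"
  )
  out <- variants
  out$eligibility <- eligibility
  out$prediction <- if_else(eligibility == "eligible", prediction, "none")
  out$confirm <- !(eligibility == "eligible" & out$prediction == "predicted_true")
  out$approach <- approach
  out
}

#' Summarize confirmation decisions for one approach
#'
#' Counts per eligibility/prediction category plus the confirmation order
#' rate: the fraction of reported variants for which a confirmatory test is
#' ordered (everything not eligible plus everything predicted false).
#'
#' @param decisions Output of [decide_confirmation()] for one approach.
#' @return One-row tibble of category counts and `confirmation_order_rate`.
#' @export
summarize_approach <- function(decisions) {
  if (nrow(decisions) == 0) {
    abort("summarize_approach: no decisions; rate undefined.")
  }
  cnt <- function(x) sum(decisions$eligibility == x)
  tibble(
    approach = decisions$approach[1] %||% NA_character_,
    n_total = nrow(decisions),
    not_eligible_no_model = cnt("not_eligible_no_model"),
    not_eligible_outside_and_actionable = cnt("not_eligible_outside_and_actionable"),
    not_eligible_actionable = cnt("not_eligible_actionable"),
    not_eligible_outside_benchmark = cnt("not_eligible_outside_benchmark"),
    eligible_predicted_true = sum(decisions$eligibility == "eligible" &
      decisions$prediction == "predicted_true"),
    eligible_predicted_false = sum(decisions$eligibility == "eligible" &
      decisions$prediction == "predicted_false"),
    confirmation_order_rate = mean(decisions$confirm)
  )
}

#' Orthogonal confirmation order reduction
#'
#' Among eligible variants with a model prediction, the fraction predicted
#' true — i.e. the share of confirmations the models allow a laboratory to
#' skip.
#'
#' @param decisions Output of [decide_confirmation()].
#' @return A single rate in `[0, 1]`.
#' @export
order_reduction <- function(decisions) {
  elig <- decisions[decisions$eligibility == "eligible", , drop = FALSE]
  if (nrow(elig) == 0) {
    abort("order_reduction: no eligible variants; rate undefined.")
  }
  mean(elig$prediction == "predicted_true")
}

#' @rdname order_reduction
#' @return For `order_reduction_summary()`: per-stratum predicted
#'   false/true counts with the reduction rate, plus an `overall` row.
#' @export
order_reduction_summary <- function(decisions) {
  elig <- decisions[decisions$eligibility == "eligible", , drop = FALSE]
  if (nrow(elig) == 0) {
    abort("order_reduction_summary: no eligible variants; rate undefined.")
  }
  per <- elig |>
    group_by(.data$stratum) |>
    summarise(
      predicted_false = sum(.data$prediction == "predicted_false"),
      predicted_true = sum(.data$prediction == "predicted_true"),
      .groups = "drop"
    )
  per <- bind_rows(per, tibble(
    stratum = "overall",
    predicted_false = sum(per$predicted_false),
    predicted_true = sum(per$predicted_true)
  ))
  per$order_reduction <- per$predicted_true /
    (per$predicted_true + per$predicted_false)
  per
}

#' Retrospective concordance of model predictions with orthogonal results
#'
#' Joins model predictions with orthogonal (e.g. Sanger) confirmation
#' outcomes per variant and reports, per stratum: confirmed-true and
#' false-call counts, how many false calls the models captured, and how
#' many confirmed-true calls were needlessly flagged (the observed TP flag
#' rate), optionally alongside each model's expected TP flag rate.
#'
#' @param predictions Variant tibble with `stratum` and `prediction`
#'   columns (see [decide_confirmation()]).
#' @param confirmations Tibble with the variant key columns (`chrom`,
#'   `pos`, `ref`, `alt`, and `gt1`/`gt2` when present in both inputs) and
#'   `orthogonal_result` (`"true"` = confirmed, `"false"` = failed to
#'   confirm).
#' @param expected Optional tibble `stratum`, `expected_tp_flag_rate`.
#' @return Per-stratum tibble; predictions without a matching confirmation
#'   are excluded from rates and returned in the `unmatched` attribute.
#' @export
retrospective_concordance <- function(predictions, confirmations,
                                      expected = NULL) {
  predictions <- as_tibble(predictions)
  confirmations <- as_tibble(confirmations)
  if (nrow(predictions) == 0 || nrow(confirmations) == 0) {
    out <- tibble(
      stratum = character(), confirmed_true = integer(),
      false_calls = integer(), false_captured = integer(),
      false_capture_rate = numeric(), true_flagged = integer(),
      observed_tp_flag_rate = numeric()
    )
    attr(out, "unmatched") <- predictions
    return(out)
  }
  keys <- intersect(
    c("sample_id", "chrom", "pos", "ref", "alt", "gt1", "gt2"),
    intersect(names(predictions), names(confirmations))
  )
  if (!"stratum" %in% names(predictions)) {
    predictions <- suppressWarnings(classify_stratum(predictions, on_unclassifiable = "drop"))
  }
  joined <- inner_join(
    predictions, confirmations[c(keys, "orthogonal_result")],
    by = keys
  )
  unmatched <- anti_join(predictions, confirmations[keys], by = keys)
  if (nrow(unmatched) > 0) {
    inform(sprintf(
      "retrospective_concordance: %d prediction(s) without a matching confirmation excluded.",
      nrow(unmatched)
    ))
  }
  out <- joined |>
    group_by(.data$stratum) |>
    summarise(
      confirmed_true = sum(.data$orthogonal_result == "true"),
      false_calls = sum(.data$orthogonal_result == "false"),
      false_captured = sum(.data$orthogonal_result == "false" &
        .data$prediction == "predicted_false"),
      true_flagged = sum(.data$orthogonal_result == "true" &
        .data$prediction == "predicted_false"),
      .groups = "drop"
    ) |>
    mutate(
      false_capture_rate = if_else(
        .data$false_calls > 0,
        .data$false_captured / .data$false_calls, NA_real_
      ),
      observed_tp_flag_rate = if_else(
        .data$confirmed_true > 0,
        .data$true_flagged / .data$confirmed_true, NA_real_
      )
    ) |>
    relocate("false_capture_rate", .after = "false_captured")
  if (!is.null(expected)) {
    out <- left_join(out, as_tibble(expected), by = "stratum")
  }
  attr(out, "unmatched") <- unmatched
  out
}
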
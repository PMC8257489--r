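#' Read and validate a run configuration
#'
#' A YAML file drives a full run: feature schema, evaluation capture
#' rates, acceptance criteria, learner grid, and seed. Every field has a
#' default; unknown fields are rejected so typos fail fast. The validated
#' configuration carries a stable hash that is recorded in model bundles
#' and output manifests.
#'
#' Recognized fields: `schema` (`"dragen-like"`, `"strelka2-like"`, or a
#' list with `schema_id` and `entries`), `capture_rates` (numeric vector),
#' `criteria` (list with `minimum_capture`, `target_capture` or the string
#' `"stringent"`), `grid` (`"default"` or `"small"`), `genotype_aware`
#' (logical), `seed` (integer).
#'
#' @param path YAML file path; `NULL` for pure defaults.
#' @return A `run_config` list with components `schema`, `capture_rates`,
#'   `criteria`, `grid`, `genotype_aware`, `seed`, `hash`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c(
    "schema", "capture_rates", "criteria", "grid", "genotype_aware", "seed"
  )
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }

  schema_field <- raw$schema %||% "dragen-like"
  schema <- if (is.character(schema_field)) {
    switch(schema_field,
      "dragen-like" = schema_dragen_like(),
      "strelka2-like" = schema_strelka2_like(),
      abort(sprintf("Unknown schema '%s'.", schema_field))
    )
  } else {
    entries <- bind_rows(lapply(schema_field$entries, as_tibble))
    if (!"missing" %in% names(entries)) entries$missing <- 0
    feature_schema(schema_field$schema_id, entries)
  }

  capture_rates <- as.numeric(raw$capture_rates %||% default_capture_rates())
  check_targets(capture_rates)

  crit_field <- raw$criteria %||% list()
  criteria <- if (identical(crit_field, "stringent")) {
    stringent_criteria()
  } else {
    acceptance_criteria(
      minimum_capture = crit_field$minimum_capture %||% 0.99,
      target_capture = crit_field$target_capture %||% 0.995
    )
  }

  grid_field <- raw$grid %||% "default"
  grid <- switch(grid_field,
    "default" = default_learner_grid(),
    "small" = small_learner_grid(),
    abort(sprintf("Unknown grid '%s' (use 'default' or 'small').", grid_field))
  )

  cfg <- list(
    schema = schema,
    capture_rates = capture_rates,
    criteria = criteria,
    grid = grid,
    genotype_aware = isTRUE(raw$genotype_aware %||% TRUE),
    seed = as.integer(raw$seed %||% 1L)
  )
  cfg$hash <- hash(cfg)
  structure(cfg, class = "run_config")
}

#' @exportS3Method base::print
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  schema:        ", x$schema$schema_id, "\n")
  cat("  capture rates: ", paste(x$capture_rates, collapse = ", "), "\n")
  cat(sprintf(
    "  criteria:       minimum %.4g / target %.4g\n",
    x$criteria$minimum_capture, x$criteria$target_capture
  ))
  cat("  grid:          ", nrow(x$grid), "points\n")
  cat("  seed:          ", x$seed, "\n")
  cat("  hash:          ", x$hash, "\n")
  invisible(x)
}
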
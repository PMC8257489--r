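#' Configuration for the synthetic cohort generator
#'
#' The generator emulates, at configurable scale, the structure of a
#' benchmark-derived training resource: multiple samples of germline calls
#' in which a small fraction are false positive calls, a truth set holding
#' exactly the true calls, benchmark regions covering most (not all)
#' loci, and a clinical table labeling a subset of calls with
#' interpretation categories. True and false positive calls differ in
#' their quality-metric distributions by a controllable standardized mean
#' shift, so classifier difficulty is a dial rather than an accident.
#'
#' @param n_samples Number of samples in the cohort.
#' @param calls_per_sample Calls emitted per sample.
#' @param fp_prevalence Named per-stratum false-positive-call prevalence;
#'   defaults to 0.005 for SNV strata and 0.02 for indel strata, echoing
#'   the much higher error rate of indel calling.
#' @param stratum_mix Named proportions over [stratum_levels()] (must sum
#'   to 1); the default mix is dominated by heterozygous SNVs as in real
#'   germline call sets.
#' @param separation Standardized mean shift (in SD units, applied per
#'   quality feature) between TP and FP feature distributions. 0 makes
#'   labels independent of features; around 1.5 gives a realistic,
#'   imperfectly separable problem; 8+ makes classes essentially disjoint.
#' @param excluded_fraction Fraction of loci deliberately left outside the
#'   benchmark regions, to exercise outside-benchmark logic.
#' @param replicate_first Number of extra byte-identical replicates of
#'   sample 1 to append (library replicates share truth).
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 7L,
                             calls_per_sample = 50000L,
                             fp_prevalence = NULL,
                             stratum_mix = NULL,
                             separation = 1.5,
                             excluded_fraction = 0.05,
                             replicate_first = 0L,
                             seed = 1L) {
  default_prev <- c(
    "snv-het" = 0.005, "snv-hom" = 0.005, "snv-complexhet" = 0.005,
    "indel-het" = 0.02, "indel-hom" = 0.02, "indel-complexhet" = 0.02
  )
  default_mix <- c(
    "snv-het" = 0.575, "snv-hom" = 0.300, "snv-complexhet" = 0.005,
    "indel-het" = 0.065, "indel-hom" = 0.040, "indel-complexhet" = 0.015
  )
  prev <- default_prev
  if (!is.null(fp_prevalence)) prev[names(fp_prevalence)] <- fp_prevalence
  mix <- default_mix
  if (!is.null(stratum_mix)) {
    mix <- setNames(rep(0, length(default_mix)), names(default_mix))
    mix[names(stratum_mix)] <- stratum_mix
  }
  if (abs(sum(mix) - 1) > 1e-8) abort("stratum_mix must sum to 1.")
  if (any(prev <= 0 | prev >= 1)) abort("fp_prevalence values must lie in (0, 1).")
  if (separation < 0) abort("separation must be >= 0.")
  if (n_samples < 1 || calls_per_sample < 10) {
    abort("Need n_samples >= 1 and calls_per_sample >= 10.")
  }
  expected <- calls_per_sample * mix
  if (any(mix > 0 & expected < 1)) {
    abort("Infeasible stratum_mix: a nonzero-proportion stratum expects < 1 call at this calls_per_sample.")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      calls_per_sample = as.integer(calls_per_sample),
      fp_prevalence = prev, stratum_mix = mix, separation = separation,
      excluded_fraction = excluded_fraction,
      replicate_first = as.integer(replicate_first),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Gaussian quality features: baseline TP moments; FP calls are shifted
# down by `separation` SDs per feature.
feature_moments <- function() {
  tibble(
    feature = c("qual", "gq", "dp", "mq", "qd"),
    mean = c(50, 60, 35, 60, 15),
    sd = c(10, 15, 8, 5, 4)
  )
}

random_snv_alleles <- function(n, n_alts = 1L) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) {
    paste(sample(setdiff(bases, r), n_alts), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  list(ref = ref, alt = alt)
}

random_indel_alleles <- function(n, n_alts = 1L) {
  bases <- c("A", "C", "G", "T")
  anchor <- sample(bases, n, replace = TRUE)
  make_tail <- function() {
    paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
  }
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    if (n_alts == 1L) {
      if (runif(1) < 0.5) { # deletion
        ref[i] <- paste0(anchor[i], make_tail())
        alt[i] <- anchor[i]
      } else { # insertion
        ref[i] <- anchor[i]
        alt[i] <- paste0(anchor[i], make_tail())
      }
    } else {
      # two distinct deletion lengths from a common run
      run <- paste(rep(sample(bases, 1), 4), collapse = "")
      ref[i] <- paste0(anchor[i], run)
      alt[i] <- paste0(anchor[i], substr(run, 1, 2), ",", anchor[i])
    }
  }
  list(ref = ref, alt = alt)
}

simulate_stratum_calls <- function(n, stratum, prev, separation) {
  label <- if_else(runif(n) < prev, "FP", "TP")
  zyg <- sub("^[a-z]+-", "", stratum)
  is_snv <- startsWith(stratum, "snv")
  n_alts <- if (zyg == "complexhet") 2L else 1L
  alleles <- if (is_snv) {
    random_snv_alleles(n, n_alts)
  } else {
    random_indel_alleles(n, n_alts)
  }
  gt <- switch(zyg,
    het = list(gt1 = 0L, gt2 = 1L),
    hom = list(gt1 = 1L, gt2 = 1L),
    complexhet = list(gt1 = 1L, gt2 = 2L)
  )
  out <- tibble(
    ref = alleles$ref, alt = alleles$alt,
    gt1 = gt$gt1, gt2 = gt$gt2, stratum = stratum, label = label
  )
  shift <- if_else(label == "FP", separation, 0)
  for (i in seq_len(nrow(feature_moments()))) {
    fm <- feature_moments()[i, ]
    out[[fm$feature]] <- rnorm(n, fm$mean - shift * fm$sd, fm$sd)
  }
  out$dp <- pmax(round(out$dp), 1)
  out$qual <- pmax(out$qual, 0)
  out$gq <- pmax(out$gq, 0)
  out$mq <- pmax(out$mq, 0)
  # Allele fraction: symmetric around 0.5 for het TP, near 1 for hom and
  # complex-het TP; FP calls mix toward a low-fraction skew with weight
  # growing in `separation` so that separation 0 keeps TP and FP identical.
  af_tp <- if (zyg == "het") rbeta(n, 30, 30) else rbeta(n, 57, 3)
  af_fp_skew <- rbeta(n, 6, 14)
  w <- min(separation / 2, 1)
  out$af <- pmin(pmax(if_else(label == "FP", (1 - w) * af_tp + w * af_fp_skew, af_tp), 0), 1)
  out
}

#' Simulate the calls of one sample (in memory)
#'
#' @param config A [synthetic_config()].
#' @param sample_id Sample identifier.
#' @param seed Seed for this sample; defaults to a value derived from the
#'   config seed.
#' @return Calls tibble with intended `label`, `stratum`, `in_benchmark`,
#'   and feature columns.
#' @export
simulate_sample_calls <- function(config, sample_id, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- seed %||% (config$seed)
  with_local_seed(seed, {
    n <- config$calls_per_sample
    strata <- sample(names(config$stratum_mix), n,
      replace = TRUE,
      prob = config$stratum_mix
    )
    parts <- lapply(stratum_levels(), function(s) {
      ns <- sum(strata == s)
      if (ns == 0) {
        return(NULL)
      }
      simulate_stratum_calls(
        ns, s, config$fp_prevalence[[s]], config$separation
      )
    })
    calls <- bind_rows(parts)
    n <- nrow(calls)
    # loci on two synthetic chromosomes, spaced so reference spans never
    # touch (keeps benchmark-region arithmetic exact)
    chrom <- sample(c("chrS1", "chrS2"), n, replace = TRUE)
    pos <- integer(n)
    for (ch in c("chrS1", "chrS2")) {
      idx <- which(chrom == ch)
      pos[idx] <- 20L * sort(sample.int(max(3L * length(idx), 10L), length(idx)))
    }
    calls$chrom <- chrom
    calls$pos <- pos
    calls$sample_id <- sample_id
    calls$in_benchmark <- runif(n) >= config$excluded_fraction
    calls |>
      relocate("sample_id", "chrom", "pos", "ref", "alt", "gt1", "gt2") |>
      arrange(.data$chrom, .data$pos)
  })
}

#' Generate one synthetic sample as VCF + truth VCF + benchmark BED
#'
#' Writes the called-variant VCF (TP and FP calls together), the truth VCF
#' (exactly the TP-designated calls), and a BED of benchmark regions
#' covering every emitted locus except the configured excluded fraction.
#'
#' @inheritParams simulate_sample_calls
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (calls/truth/bed) and `calls`
#'   (the simulated tibble with intended labels).
#' @export
generate_sample <- function(config, sample_id, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- simulate_sample_calls(config, sample_id, seed = seed)
  paths <- c(
    calls = file.path(dir, paste0(sample_id, ".calls.vcf")),
    truth = file.path(dir, paste0(sample_id, ".truth.vcf")),
    bed = file.path(dir, paste0(sample_id, ".regions.bed"))
  )
  write_calls_vcf(calls, paths[["calls"]])
  write_calls_vcf(calls[calls$label == "TP", , drop = FALSE], paths[["truth"]])
  covered <- calls[calls$in_benchmark, , drop = FALSE]
  regions <- tibble(
    chrom = covered$chrom,
    start = covered$pos - 1L,
    end = covered$pos - 1L + nchar(covered$ref)
  )
  write_bed(regions, paths[["bed"]])
  invisible(list(paths = paths, calls = calls))
}

#' Generate a full synthetic cohort with a clinical table
#'
#' Emits `n_samples` independent samples (plus optional replicates of the
#' first) under a shared feature model, and a tab-delimited clinical table
#' assigning interpretation categories to a subset of sample 1's calls.
#'
#' @inheritParams generate_sample
#' @param n_clinical Number of sample-1 calls entered in the clinical
#'   table.
#' @return Invisibly, a list with `manifest` (tibble of per-sample paths),
#'   `clinical_path`, and `config_hash`.
#' @export
generate_cohort <- function(config, dir, n_clinical = 50L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("sample%02d", seq_len(config$n_samples))
  rows <- list()
  first_calls <- NULL
  for (i in seq_along(ids)) {
    out <- generate_sample(config, ids[i], dir, seed = config$seed + 1000L * i)
    if (i == 1) first_calls <- out$calls
    rows[[i]] <- tibble(
      sample_id = ids[i],
      calls = out$paths[["calls"]], truth = out$paths[["truth"]],
      bed = out$paths[["bed"]]
    )
  }
  if (config$replicate_first > 0) {
    for (r in seq_len(config$replicate_first)) {
      rid <- sprintf("sample01rep%d", r)
      out <- generate_sample(config, rid, dir, seed = config$seed + 1000L)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = rid,
        calls = out$paths[["calls"]], truth = out$paths[["truth"]],
        bed = out$paths[["bed"]]
      )
    }
  }
  clinical_path <- file.path(dir, "clinical_table.tsv")
  with_local_seed(config$seed + 77L, {
    n_clin <- min(n_clinical, nrow(first_calls))
    picked <- first_calls[sort(sample.int(nrow(first_calls), n_clin)), ]
    clin <- tibble(
      chrom = picked$chrom, pos = picked$pos, ref = picked$ref,
      alt = picked$alt,
      genotype = paste0(picked$gt1, "/", picked$gt2),
      category = sample(clinical_categories(), n_clin,
        replace = TRUE,
        prob = c(0.10, 0.06, 0.64, 0.20)
      )
    )
    readr::write_tsv(clin, clinical_path, progress = FALSE)
  })
  invisible(list(
    manifest = bind_rows(rows),
    clinical_path = clinical_path,
    config_hash = hash(unclass(config))
  ))
}

#' Simulate a whole cohort in memory
#'
#' Fast path for model development and testing: the same draws as
#' [generate_cohort()]'s per-sample calls, without file I/O.
#'
#' @inheritParams generate_cohort
#' @return Labeled calls tibble across all samples.
#' @export
simulate_cohort_calls <- function(config) {
  ids <- sprintf("sample%02d", seq_len(config$n_samples))
  bind_rows(lapply(seq_along(ids), function(i) {
    simulate_sample_calls(config, ids[i], seed = config$seed + 1000L * i)
  }))
}
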
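# Shared fixtures, built in code at test time.

toy_schema <- function() {
  feature_schema("toy", tibble::tibble(
    feature = c("qual", "af"),
    source = c("QUAL", "FORMAT:AD"),
    transform = c("identity", "allele-fraction"),
    missing = c(0, NA)
  ))
}

# Minimal single-sample VCF writer for hand-built records.
write_test_vcf <- function(records, path, sample = "S1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample,
      sep = "\t"
    )
  )
  writeLines(c(header, records), path)
}

vcf_record <- function(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                       qual = 50, gt = "0/1", ad = NULL) {
  fmt <- if (is.null(ad)) c("GT", gt) else c("GT:AD", paste0(gt, ":", ad))
  paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", fmt[1], fmt[2],
    sep = "\t"
  )
}

make_calls <- function(pos, ref, alt, gt1, gt2, chrom = "chr1",
                       sample_id = "S1", ...) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, gt1 = as.integer(gt1), gt2 = as.integer(gt2), ...
  )
}

random_region_set <- function(n = 5, chroms = c("chr1", "chr2")) {
  starts <- sample.int(200, n)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = starts,
    end = starts + sample.int(30, n)
  )
}

# Small labeled two-class data set with tunable separation, for learner and
# calibration tests without the full generator.
toy_labeled <- function(n_tp = 200, n_fp = 40, sep = 4, n_samples = 2,
                        seed = 1) {
  withr::with_seed(seed, {
    n <- n_tp + n_fp
    tibble::tibble(
      sample_id = rep(sprintf("s%d", seq_len(n_samples)), length.out = n),
      chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "G",
      gt1 = 0L, gt2 = 1L,
      label = rep(c("TP", "FP"), c(n_tp, n_fp)),
      f1 = rnorm(n, mean = ifelse(rep(c(FALSE, TRUE), c(n_tp, n_fp)), sep, 0)),
      f2 = rnorm(n, mean = ifelse(rep(c(FALSE, TRUE), c(n_tp, n_fp)), sep, 0))
    )
  })
}
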
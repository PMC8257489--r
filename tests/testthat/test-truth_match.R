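test_that("trim_variant removes redundant context and keeps one base minimum", {
  expect_equal(
    trim_variant(100, "ATT", "AT"),
    tibble::tibble(pos = 101L, ref = "TT", alt = "T")
  )
  expect_equal(
    trim_variant(100, "A", "G"),
    tibble::tibble(pos = 100L, ref = "A", alt = "G")
  )
  expect_equal(
    trim_variant(50, "CAG", "CTG"),
    tibble::tibble(pos = 51L, ref = "A", alt = "T")
  )
  # vectorized, and trimming is a fixed point
  tr <- trim_variant(c(10, 20), c("GGCA", "TTTT"), c("GCA", "TATT"))
  tr2 <- trim_variant(tr$pos, tr$ref, tr$alt)
  expect_equal(tr, tr2)
  expect_true(all(nchar(tr$ref) >= 1 & nchar(tr$alt) >= 1))
  expect_error(trim_variant(1, "", "A"), "non-empty")
})

wide_regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 100000L)

test_that("label_calls marks truth-matched calls TP and the rest FP", {
  truth <- make_calls(c(100, 500), c("A", "TT"), c("G", "T"), c(0, 0), c(1, 1))
  # self-match: all TP
  self <- label_calls(truth, truth, wide_regions)
  expect_equal(self$label, c("TP", "TP"))
  # a locus absent from truth is FP
  q <- make_calls(c(100, 900), c("A", "C"), c("G", "A"), c(0, 0), c(1, 1))
  expect_equal(label_calls(q, truth, wide_regions)$label, c("TP", "FP"))
  # representation difference resolved by trimming
  q2 <- make_calls(100, "ATT", "AT", 0, 1)
  t2 <- make_calls(101, "TT", "T", 0, 1)
  expect_equal(label_calls(q2, t2, wide_regions)$label, "TP")
})

test_that("genotype awareness controls whether zygosity mismatches are FP", {
  het <- make_calls(100, "A", "G", 0, 1)
  hom <- make_calls(100, "A", "G", 1, 1)
  # het call vs hom truth, and the reverse
  expect_equal(label_calls(het, hom, wide_regions, genotype_aware = TRUE)$label, "FP")
  expect_equal(label_calls(het, hom, wide_regions, genotype_aware = FALSE)$label, "TP")
  expect_equal(label_calls(hom, het, wide_regions, genotype_aware = TRUE)$label, "FP")
  expect_equal(label_calls(hom, het, wide_regions, genotype_aware = FALSE)$label, "TP")
})

test_that("labeling conserves in-region calls and ignores query order", {
  withr::local_seed(21)
  n <- 60
  q <- make_calls(
    pos = sample.int(5000, n) * 3, ref = "A", alt = "G", gt1 = 0, gt2 = 1
  )
  truth <- q[sample.int(n, 30), ]
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 9000L)
  lab <- label_calls(q, truth, regions)
  expect_equal(nrow(lab), sum(span_in_regions(q, regions)))

  perm <- sample.int(n)
  lab_perm <- label_calls(q[perm, ], truth, regions)
  key <- function(x) paste(x$chrom, x$pos)
  expect_equal(
    lab_perm$label[match(key(lab), key(lab_perm))],
    lab$label
  )
  # calls outside the regions are excluded from the output entirely
  narrow <- tibble::tibble(chrom = "chr1", start = 0L, end = 4000L)
  expect_lt(nrow(label_calls(q, truth, narrow)), n)
})

test_that("disjoint chromosome naming is an explicit error", {
  q <- make_calls(100, "A", "G", 0, 1, chrom = "chr1")
  t <- make_calls(100, "A", "G", 0, 1, chrom = "1")
  expect_error(label_calls(q, t, wide_regions), "chromosome naming")
})

test_that("labeled calls split into a TP/FP VCF pair", {
  q <- make_calls(c(100, 200), c("A", "C"), c("G", "T"), c(0, 0), c(1, 1),
    qual = c(50, 9)
  )
  truth <- q[1, ]
  lab <- label_calls(q, truth, wide_regions)
  tp <- withr::local_tempfile(fileext = ".vcf")
  fp <- withr::local_tempfile(fileext = ".vcf")
  write_labeled_vcfs(lab, tp, fp)
  qual_only <- feature_schema("qual-only", tibble::tibble(
    feature = "qual", source = "QUAL", transform = "identity", missing = 0
  ))
  expect_equal(read_vcf(tp, qual_only, quiet = TRUE)$pos, 100L)
  expect_equal(read_vcf(fp, qual_only, quiet = TRUE)$pos, 200L)
})
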
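test_that("read_vcf emits one call per non-reference genotype with schema features", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    vcf_record(pos = 100, qual = 50, gt = "0/1", ad = "10,10"),
    vcf_record(pos = 200, qual = 99, gt = "0/0", ad = "30,0"), # ref hom: skip
    vcf_record(pos = 300, qual = 10, gt = "./.", ad = "5,5"), # missing: skip
    vcf_record(pos = 400, ref = "A", alt = "G,T", qual = 80, gt = "1/2", ad = "0,12,8")
  ), path)
  calls <- read_vcf(path, toy_schema(), quiet = TRUE)

  expect_equal(nrow(calls), 2)
  expect_equal(calls$pos, c(100L, 400L))
  expect_equal(calls$qual, c(50, 80))
  expect_equal(calls$af, c(0.5, 1.0)) # alt depth / total depth
  expect_equal(calls$gt1, c(0L, 1L))
  expect_equal(calls$gt2, c(1L, 2L))
  expect_equal(calls$alt[2], "G,T") # multiallelic kept unsplit
  # conservation: emitted + skipped = records
  expect_equal(nrow(calls) + attr(calls, "n_skipped"), attr(calls, "n_records"))
  expect_identical(attr(calls, "schema_id"), "toy")
})

test_that("read_vcf missing-feature policy drops calls and counts them", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    vcf_record(pos = 100, gt = "0/1", ad = "10,10"),
    vcf_record(pos = 200, gt = "0/1") # no AD and missing-policy = drop
  ), path)
  calls <- read_vcf(path, toy_schema(), quiet = TRUE)
  expect_equal(nrow(calls), 1)
  expect_equal(attr(calls, "n_skipped"), 1L)

  # fill-policy schema keeps the call with the sentinel value
  fill_schema <- feature_schema("toy-fill", tibble::tibble(
    feature = "af", source = "FORMAT:AD",
    transform = "allele-fraction", missing = -1
  ))
  calls2 <- read_vcf(path, fill_schema, quiet = TRUE)
  expect_equal(nrow(calls2), 2)
  expect_equal(calls2$af[2], -1)
})

test_that("read_bed normalizes, merges, and rejects invalid rows", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t5\t15", "chr2\t3\t8"), path)
  bed <- read_bed(path)
  expect_equal(bed, tibble::tibble(
    chrom = c("chr1", "chr2"), start = c(0L, 3L), end = c(15L, 8L)
  ))

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_bed(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t20\t20"), bad)
  expect_error(read_bed(bad), "row\\(s\\): 2")
})

test_that("union_regions is commutative, associative, and idempotent", {
  withr::local_seed(11)
  for (i in 1:15) {
    a <- random_region_set()
    b <- random_region_set()
    c <- random_region_set()
    expect_equal(union_regions(a, b), union_regions(b, a))
    expect_equal(
      union_regions(union_regions(a, b), c),
      union_regions(a, union_regions(b, c))
    )
    expect_equal(union_regions(a, a), normalize_regions(a))
  }
  # disjoint inputs pass through unchanged
  a <- tibble::tibble(chrom = "chr1", start = 0L, end = 5L)
  b <- tibble::tibble(chrom = "chr1", start = 10L, end = 15L)
  expect_equal(nrow(union_regions(a, b)), 2)
})

test_that("span_in_regions uses full reference-span containment", {
  region <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e)
  snv <- make_calls(100, "A", "G", 0, 1)
  expect_true(span_in_regions(snv, region(99L, 100L)))
  expect_false(span_in_regions(snv, region(100L, 200L)))
  # 3-bp deletion spanning a region edge is not contained
  del <- make_calls(100, "ATTT", "A", 0, 1)
  expect_false(span_in_regions(del, region(99L, 102L)))
  expect_true(span_in_regions(del, region(99L, 103L)))
  expect_equal(span_in_regions(snv[0, ], region(0L, 10L)), logical(0))
})

test_that("write_predictions round-trips coordinates, alleles and genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  # empty list -> header-only VCF
  write_predictions(empty_decisions <- make_calls(integer(0), character(0),
    character(0), integer(0), integer(0),
    decision = character(0)
  ), path)
  expect_equal(nrow(read_vcf(path, toy_schema(), quiet = TRUE)), 0)

  calls <- make_calls(
    pos = c(100, 250), ref = c("A", "AT"), alt = c("G,T", "A"),
    gt1 = c(1, 0), gt2 = c(2, 1),
    qual = c(55.5, 12), gq = c(40, 20), dp = c(30, 25), af = c(0.5, 0.4),
    decision = c("predicted_false", "not_eligible")
  )
  write_predictions(calls, path)
  back <- read_vcf(path, schema_dragen_like(), quiet = TRUE)
  expect_equal(back[c("chrom", "pos", "ref", "alt", "gt1", "gt2")],
    calls[c("chrom", "pos", "ref", "alt", "gt1", "gt2")],
    ignore_attr = TRUE
  )
  expect_true(any(grepl("TRIAGE=predicted_false", readLines(path))))
})

test_that("region sets survive a BED write/read cycle", {
  withr::local_seed(4)
  path <- withr::local_tempfile(fileext = ".bed")
  rs <- normalize_regions(random_region_set(12))
  write_bed(rs, path)
  expect_equal(read_bed(path), rs)
})
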
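demo_decisions <- function(approach) {
  decide_confirmation(demo_reported_variants(), approach)
}

test_that("decide_confirmation applies eligibility rules and the confirm invariant", {
  v <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    ref = "A", alt = c("G", "G", "G,T", "G"), gt1 = c(0L, 0L, 1L, 0L),
    gt2 = c(1L, 1L, 2L, 1L),
    stratum = c("snv-het", "snv-het", "snv-complexhet", "snv-het"),
    category = c("carrier", "primary", "carrier", "pgx"),
    in_benchmark = c(TRUE, TRUE, TRUE, FALSE),
    prediction = c("predicted_true", "predicted_true", NA, "predicted_false")
  )
  d <- decide_confirmation(v, "nonactionable")
  # carrier predicted-true skips confirmation; actionable always confirms
  expect_equal(d$eligibility, c(
    "eligible", "not_eligible_actionable", "not_eligible_no_model", "eligible"
  ))
  expect_equal(d$confirm, c(FALSE, TRUE, TRUE, TRUE))
  # benchmark-restricted approach pulls the out-of-benchmark call back in
  d2 <- decide_confirmation(v, "benchmark-nonactionable")
  expect_equal(d2$eligibility[4], "not_eligible_outside_benchmark")
  # confirm invariant everywhere
  for (a in approaches()) {
    da <- decide_confirmation(v, a)
    expect_equal(
      da$confirm,
      !(da$eligibility == "eligible" & da$prediction == "predicted_true")
    )
  }
})

test_that("no actionable variant ever skips confirmation under restricted approaches", {
  grid <- tidyr::expand_grid(
    category = c("primary", "actionable_secondary", "carrier", "pgx"),
    prediction = c("predicted_true", "predicted_false", NA_character_),
    in_benchmark = c(TRUE, FALSE)
  )
  v <- make_calls(
    pos = seq_len(nrow(grid)) * 10, ref = "A", alt = "G", gt1 = 0, gt2 = 1,
    stratum = "snv-het", category = grid$category,
    in_benchmark = grid$in_benchmark, prediction = grid$prediction
  )
  for (a in c("nonactionable", "benchmark-nonactionable")) {
    d <- decide_confirmation(v, a)
    actionable <- d$category %in% c("primary", "actionable_secondary")
    expect_true(all(d$confirm[actionable]))
  }
})

test_that("approach summaries reproduce the reference confirmation order rates", {
  expected <- c(
    "all" = 21.57, "benchmark" = 46.41,
    "nonactionable" = 29.41, "benchmark-nonactionable" = 53.92
  )
  for (a in approaches()) {
    s <- summarize_approach(demo_decisions(a))
    expect_equal(s$n_total, 306)
    expect_equal(round(100 * s$confirmation_order_rate, 2), unname(expected[a]))
    # category counts always account for every variant
    counts <- s[grep("^not_eligible|^eligible", names(s))]
    expect_equal(sum(unlist(counts)), s$n_total)
  }
  # spot-check the per-category rows of the summaries
  s_all <- summarize_approach(demo_decisions("all"))
  expect_equal(s_all$eligible_predicted_true, 240)
  expect_equal(s_all$eligible_predicted_false, 60)
  s_na <- summarize_approach(demo_decisions("nonactionable"))
  expect_equal(s_na$not_eligible_actionable, 48)
  expect_equal(s_na$eligible_predicted_false, 36)
  s_bn <- summarize_approach(demo_decisions("benchmark-nonactionable"))
  expect_equal(s_bn$not_eligible_outside_and_actionable, 4)
  expect_equal(s_bn$not_eligible_outside_benchmark, 84)
  expect_equal(s_bn$eligible_predicted_true, 141)
  expect_error(summarize_approach(demo_decisions("all")[0, ]), "undefined|no decisions")
})

test_that("restriction only adds confirmations", {
  rate <- function(a) summarize_approach(demo_decisions(a))$confirmation_order_rate
  expect_lte(rate("all"), rate("benchmark"))
  expect_lte(rate("all"), rate("nonactionable"))
  expect_lte(rate("benchmark"), rate("benchmark-nonactionable"))
  expect_lte(rate("nonactionable"), rate("benchmark-nonactionable"))
})

test_that("order reduction matches the reference prospective rates", {
  d <- demo_decisions("nonactionable")
  expect_equal(round(100 * order_reduction(d), 2), 85.71)
  per <- order_reduction_summary(d)
  get <- function(s) round(100 * per$order_reduction[per$stratum == s], 2)
  expect_equal(get("snv-het"), 84.97)
  expect_equal(get("snv-hom"), 97.14)
  expect_equal(get("indel-het"), 75.00)
  expect_equal(per$predicted_false[per$stratum == "overall"], 36)
  expect_equal(per$predicted_true[per$stratum == "overall"], 216)

  all_true <- d[d$eligibility == "eligible" & d$prediction == "predicted_true", ]
  expect_equal(order_reduction(all_true), 1)
  expect_error(order_reduction(d[d$eligibility != "eligible", ]), "undefined")
})

test_that("retrospective concordance reproduces the reference observed rates", {
  demo <- demo_confirmation_outcomes()
  rep <- retrospective_concordance(
    demo$predictions, demo$confirmations,
    expected = dplyr::transmute(
      reference_model_summary(),
      stratum,
      expected_tp_flag_rate = final_tp_flag / 100
    )
  )
  row <- function(s) rep[rep$stratum == s, ]
  expect_equal(row("snv-het")$confirmed_true, 176)
  expect_equal(round(100 * row("snv-het")$observed_tp_flag_rate, 2), 16.48)
  expect_equal(round(100 * row("snv-hom")$observed_tp_flag_rate, 2), 2.94)
  expect_equal(round(100 * row("indel-het")$observed_tp_flag_rate, 2), 25.00)
  expect_equal(row("indel-het")$false_calls, 2)
  expect_equal(row("indel-het")$false_capture_rate, 1.0) # both failures captured
  expect_equal(row("snv-het")$expected_tp_flag_rate, 0.122)

  # unmatched predictions are excluded and reported
  extra <- demo$predictions[1, ]
  extra$pos <- 999999L
  rep2 <- suppressMessages(retrospective_concordance(
    dplyr::bind_rows(demo$predictions, extra), demo$confirmations
  ))
  expect_equal(nrow(attr(rep2, "unmatched")), 1)
  expect_equal(
    rep2$confirmed_true[rep2$stratum == "snv-het"], 176
  )

  empty <- retrospective_concordance(
    demo$predictions[0, ], demo$confirmations[0, ]
  )
  expect_equal(nrow(empty), 0)
})

test_that("clinical tables parse and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    genotype = "0/1", category = "carrier"
  ), path)
  tbl <- read_clinical_table(path)
  expect_equal(tbl$gt1, 0L)
  expect_equal(tbl$gt2, 1L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    genotype = "0/1", category = "vus"
  ), bad)
  expect_error(read_clinical_table(bad), "category")

  empty <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), genotype = character(), category = character()
  ), empty)
  expect_error(read_clinical_table(empty), "empty")
})
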
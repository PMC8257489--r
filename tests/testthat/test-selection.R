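test_that("lower_bound reproduces the -2 SD arithmetic", {
  expect_equal(round(lower_bound(99.76, 0.18), 1), 99.4)
  expect_equal(round(lower_bound(99.94, 0.14), 2), 99.66)
  expect_equal(lower_bound(0.97, 0), 0.97)
  expect_equal(lower_bound(c(1, 0.5), c(0, 0.1)), c(1, 0.3))
  expect_error(lower_bound(0.99, -0.01))
})

test_that("acceptance_check enforces both clinical pass rules", {
  crit <- acceptance_criteria(0.99, 0.995)
  # passing combination: lb 0.9940 >= 0.99 and final 0.9958 >= lb
  ok <- acceptance_check(0.9976, 0.0018, 0.9958, crit)
  expect_true(ok$passed_rule1 && ok$passed_rule2 && ok$passed)
  expect_equal(ok$lower_bound, 0.9940)
  # rule 1 failure: mean 0.995, sd 0.003 -> lb 0.989 < 0.99
  r1 <- acceptance_check(0.995, 0.003, 0.999, crit)
  expect_false(r1$passed_rule1)
  expect_false(r1$passed)
  # rule 2 failure: final capture below the lower bound
  r2 <- acceptance_check(0.998, 0.002, 0.992, crit)
  expect_true(r2$passed_rule1)
  expect_false(r2$passed_rule2)

  expect_error(acceptance_criteria(0.999, 0.995)) # minimum > target
  stringent <- stringent_criteria()
  expect_equal(stringent$minimum_capture, 0.999)
  expect_equal(stringent$target_capture, 1.0)
})

test_that("modified_f1 is the harmonic mean of capture and specificity", {
  expect_equal(modified_f1(1, 0), 1)
  expect_equal(modified_f1(0, 0.5), 0)
  expect_equal(modified_f1(1, 1), 0) # capture 1 but specificity 0
  # direct arithmetic oracle
  harm <- function(c, s) 2 * c * s / (c + s)
  expect_equal(modified_f1(0.995, 0.122), harm(0.995, 1 - 0.122))
  expect_equal(modified_f1(0.9, 0.3), harm(0.9, 0.7))
})

candidate <- function(stratum = "snv-het", algorithm = "gradientboosting",
                      target = 0.995, cv_mean = 0.998, cv_sd = 0.001,
                      final = 0.997, tp_flag = 0.1) {
  tibble::tibble(
    stratum = stratum, algorithm = algorithm, target = target,
    cv_mean_capture = cv_mean, cv_sd_capture = cv_sd,
    final_capture = final, final_tp_flag = tp_flag
  )
}

test_that("select_models picks the best passing candidate deterministically", {
  # single passing candidate wins; failing strata select nothing
  one <- select_models(dplyr::bind_rows(
    candidate(),
    candidate(stratum = "snv-complexhet", cv_mean = 0.95, cv_sd = 0.02)
  ))
  expect_equal(one$selected, c(TRUE, FALSE))

  # tie on modified F1 -> lower tp_flag; then lower target; then algorithm
  tied <- dplyr::bind_rows(
    candidate(algorithm = "adaboost", tp_flag = 0.2),
    candidate(algorithm = "randomforest", tp_flag = 0.1),
    candidate(algorithm = "easyensemble", tp_flag = 0.1, target = 0.99)
  )
  sel <- select_models(tied)
  expect_equal(sel$algorithm[sel$selected], "easyensemble")

  # permutation invariance
  perm <- sel[c(3, 1, 2), ]
  sel2 <- select_models(perm[names(candidate())])
  expect_equal(
    sel2$algorithm[sel2$selected],
    sel$algorithm[sel$selected]
  )
})

test_that("raising the minimum capture rate only shrinks the passing set", {
  withr::local_seed(8)
  cands <- dplyr::bind_rows(lapply(1:30, function(i) {
    candidate(
      algorithm = sample(learner_algorithms(), 1),
      target = sample(default_capture_rates(), 1),
      cv_mean = runif(1, 0.985, 1), cv_sd = runif(1, 0, 0.005),
      final = runif(1, 0.985, 1), tp_flag = runif(1, 0, 0.5)
    )
  }))
  passing <- function(minimum) {
    which(select_models(cands, acceptance_criteria(minimum, 1))$passed)
  }
  sets <- lapply(c(0.985, 0.99, 0.995, 0.999), passing)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})
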
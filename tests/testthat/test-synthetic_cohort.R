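test_that("truth and weights follow the configured generative model", {
  cfg <- cohort_config(n_subjects = 200,
                       truth_distribution = c("6" = 1),
                       duplicate_pairs = list(n = 0, probs = c("0" = 1)),
                       seed = 61)
  tw <- generate_truth_and_weights(cfg)
  expect_true(all(tw$truth == 6L))
  expect_true(all(tw$weights > 0))

  # zero lognormal noise: weight is a strictly increasing function of truth
  cfg <- cohort_config(n_subjects = 500,
                       weight_model = list(intercept = 0.72, slope = 0.167,
                                           log_sd = 0),
                       duplicate_pairs = list(n = 0, probs = c("0" = 1)),
                       seed = 62)
  tw <- generate_truth_and_weights(cfg)
  expect_equal(cor(rank(tw$truth), rank(tw$weights)), 1)
  expect_equal(tw$weights, exp(0.72 + 0.167 * tw$truth))
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(seed = 1, truth_distribution = c("4" = 0.5)),
               "summing to 1")
  expect_error(cohort_config(seed = 1, truth_distribution = c("11" = 1)),
               "1..9")
  expect_error(cohort_config(n_subjects = 0, seed = 1), "n_subjects")
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = 1,
                             duplicate_pairs = list(n = 1,
                                                    probs = c("0" = 0.6))),
               "sum to 1")
})

test_that("noise-free raters reproduce the truth; bias is clamped at the scale edge", {
  truth <- c(4L, 6L, 9L)
  raters <- data.frame(rater_id = c("A", "B"), bias = 0, dispersion = 0,
                       tier = "senior", stringsAsFactors = FALSE)
  m <- generate_rater_scores(truth, raters, seed = 63)
  expect_equal(unname(unclass(m)[, "A"]), truth)
  expect_equal(unname(unclass(m)[, "B"]), truth)

  biased <- data.frame(rater_id = "Z", bias = 8, dispersion = 0,
                       tier = "senior", stringsAsFactors = FALSE)
  m <- generate_rater_scores(9L, biased, seed = 64)
  expect_equal(unname(unclass(m)[1, "Z"]), 9L)
})

test_that("cohort generation is fully reproducible and serialises identically", {
  cfg <- cohort_config(seed = 65)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_score_table(c1$matrix, f1, "long")
  write_score_table(c2$matrix, f2, "long")
  expect_identical(readLines(f1), readLines(f2))

  c3 <- generate_cohort(cohort_config(seed = 66))
  expect_false(identical(unclass(c1$matrix), unclass(c3$matrix)))
})

test_that("duplicate injection grows the matrix and registry, not the cohort table", {
  cfg <- cohort_config(n_subjects = 38, seed = 67,
                       duplicate_pairs = list(n = 2,
                                              probs = c("-1" = 0.25, "0" = 0.5,
                                                        "1" = 0.25)))
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$matrix), 40L)       # 38 cats + 2 altered duplicates
  expect_equal(nrow(ch$registry), 2L)
  expect_equal(nrow(ch$cohort), 38L)
  expect_true(all(ch$registry$subject_a %in% ch$cohort$subject))
  expect_false(any(ch$registry$subject_b %in% ch$cohort$subject))
  expect_equal(nrow(validate_score_matrix(ch$matrix, ch$cohort, ch$registry)), 0L)

  cfg46 <- cohort_config(n_subjects = 46, seed = 68,
                         duplicate_pairs = list(n = 4,
                                                probs = c("-1" = 0.25, "0" = 0.5,
                                                          "1" = 0.25)))
  expect_equal(nrow(generate_cohort(cfg46)$matrix), 50L)  # 46 + 4 duplicates
})

test_that("an unperturbed duplicate of a noise-free cohort scores identically", {
  raters <- data.frame(rater_id = c("A", "B", "C"), bias = 0, dispersion = 0,
                       tier = "senior", stringsAsFactors = FALSE)
  cfg <- cohort_config(n_subjects = 10, raters = raters, seed = 69,
                       duplicate_pairs = list(n = 3, probs = c("0" = 1)))
  ch <- generate_cohort(cfg)
  rep <- duplicate_consistency(ch$matrix, ch$registry)
  expect_true(all(rep$diff == 0L))
})

test_that("duplicate perturbation shifts all raters of a pair together", {
  raters <- data.frame(rater_id = c("A", "B", "C"), bias = 0, dispersion = 0,
                       tier = "senior", stringsAsFactors = FALSE)
  cfg <- cohort_config(n_subjects = 12,
                       truth_distribution = c("5" = 0.5, "6" = 0.5),
                       raters = raters, seed = 70,
                       duplicate_pairs = list(n = 4, probs = c("1" = 1)))
  ch <- generate_cohort(cfg)
  rep <- duplicate_consistency(ch$matrix, ch$registry)
  expect_true(all(rep$diff[rep$rater != "MV"] == 1L))
})

test_that("majority-vote recovery beats the average single rater under noise", {
  raters <- default_rater_models()
  raters$dispersion <- 0.6
  cfg <- cohort_config(n_subjects = 500, raters = raters, seed = 71,
                       duplicate_pairs = list(n = 0, probs = c("0" = 1)))
  ch <- generate_cohort(cfg)
  votes <- consensus_scores(ch$matrix)
  vote_recovery <- mean(votes$vote == ch$truth)
  rater_agreement <- mean(sapply(colnames(ch$matrix),
                                 function(r) mean(ch$matrix[, r] == ch$truth)))
  expect_gt(vote_recovery, rater_agreement)
})

test_that("weight-model calibration hits its target and is monotone", {
  cal <- calibrate_weight_model(0.73, seed = 72, n_calibration = 5000)
  expect_true(abs(cal$achieved_rho - 0.73) <= 0.02)
  expect_gt(cal$log_sd, 0)

  # near-perfect target needs almost no noise
  cal_hi <- calibrate_weight_model(0.999, seed = 72, n_calibration = 5000)
  expect_lt(cal_hi$log_sd, 0.02)

  # lower targets require strictly more noise
  cal_09 <- calibrate_weight_model(0.9, seed = 72, n_calibration = 5000)
  cal_05 <- calibrate_weight_model(0.5, seed = 72, n_calibration = 5000)
  expect_gt(cal_05$log_sd, cal_09$log_sd)
  expect_gt(cal_09$log_sd, cal_hi$log_sd)

  expect_error(calibrate_weight_model(1.2, seed = 72), "target_rho")
})
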
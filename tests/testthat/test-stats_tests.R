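test_that("Spearman rho matches the classical no-ties formula", {
  expect_equal(spearman_rho(1:4, c(2, 4, 6, 8))$rho, 1)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4))$rho, 0.8)  # 1 - 6*2/(4*15)
  expect_equal(spearman_rho(1:4, 4:1)$rho, -1)
})

test_that("Spearman rho equals rank-then-Pearson and cor.test on tied data", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- sample(1:9, n, TRUE)
    y <- sample(1:9, n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- spearman_rho(x, y)
    expect_equal(res$rho, cor(rank(x), rank(y)))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(res$rho, unname(ct$estimate))
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(32)
  x <- sample(1:9, 20, TRUE); y <- sample(1:9, 20, TRUE)
  r0 <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, r0)
  expect_equal(spearman_rho(x, y^3)$rho, r0)
})

test_that("Spearman rho validates its input", {
  expect_error(spearman_rho(1:2, 1:2), "3 complete pairs")
  expect_error(spearman_rho(c(5, 5, 5), 1:3), "zero variance")
  expect_equal(spearman_rho(c(1, NA, 2, 3, 4), c(1, 9, 2, 3, 4))$n, 4L)
})

test_that("correlation matrices are symmetric with unit diagonal and pairwise cells", {
  cols <- list(a = c(1, 2, 3, 4, 5), b = c(2, 3, 4, 5, 6),
               neg = c(5, 4, 3, 2, 1), gappy = c(1, NA, 3, NA, 5))
  cm <- correlation_matrix(cols)
  expect_equal(diag(cm$rho), c(a = 1, b = 1, neg = 1, gappy = 1))
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$rho["a", "b"], 1)
  expect_equal(cm$rho["a", "neg"], -1)
  expect_equal(cm$n["a", "gappy"], 3)
  # a constant column yields undefined (NA) cells, flagged not fatal
  cm2 <- correlation_matrix(list(a = 1:5, const = rep(2, 5)))
  expect_true(is.na(cm2$rho["a", "const"]))
  expect_error(correlation_matrix(list(a = 1:3)), "2 columns")
  expect_error(correlation_matrix(list(a = 1:3, b = 1:4)), "subject index")
})

test_that("a 13-column assembly gives a 13x13 unit-diagonal matrix", {
  set.seed(33)
  cols <- c(lapply(1:9, function(i) sample(4:9, 38, TRUE)),
            list(sample(4:9, 38, TRUE), sample(4:9, 38, TRUE),
                 sample(4:9, 38, TRUE), runif(38, 3, 9)))
  names(cols) <- c(LETTERS[1:9], "MV", "OCS", "CA", "weight")
  cm <- correlation_matrix(cols)
  expect_equal(dim(cm$rho), c(13L, 13L))
  expect_equal(unname(diag(cm$rho)), rep(1, 13))
  expect_equal(colnames(cm$rho), names(cols))
})

test_that("signed-rank test matches exact enumeration at small n, with ties", {
  set.seed(34)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    b <- sample(1:9, n, TRUE)
    a <- b + sample(-2:2, n, TRUE)
    if (all(a == b)) a[1] <- b[1] + 1
    res <- wilcoxon_signed_rank(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_signed_rank_p(a - b))
  }
})

test_that("signed-rank test agrees with wilcox.test in the clean exact case", {
  set.seed(35)
  for (i in 1:20) {
    d <- sample(1:20, 12) * sample(c(-1, 1), 12, TRUE)  # distinct magnitudes
    b <- rnorm(12); a <- b + d
    res <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
  }
})

test_that("signed-rank handles the documented edge cases", {
  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "degenerate")
  expect_equal(res$p_value, 1)
  # all differences +1 over n = 10: the single most extreme assignment
  res <- wilcoxon_signed_rank(2:11, 1:10)
  expect_equal(res$p_value, 2 / 2^10)
  # large-sample branch stays close to the normal-approximation reference
  set.seed(36)
  b <- sample(1:9, 40, TRUE); a <- pmin(9, b + sample(0:2, 40, TRUE))
  if (all(a == b)) a[1] <- b[1] + 1
  res <- wilcoxon_signed_rank(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_false(res$exact)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("Mann-Whitney matches exact enumeration and wilcox.test", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$statistic, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  set.seed(37)
  for (i in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pool <- sample(1:50, na + nb)  # no ties
    a <- pool[seq_len(na)]; b <- pool[-seq_len(na)]
    res <- mann_whitney_u(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_mann_whitney_p(a, b))
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
  }
  # tied data falls back to the corrected normal approximation
  set.seed(38)
  a <- sample(1:5, 30, TRUE); b <- sample(2:6, 25, TRUE)
  res <- mann_whitney_u(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_false(res$exact)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("two-sided rank tests are invariant under swapping the groups", {
  set.seed(39)
  a <- sample(1:9, 12, TRUE); b <- sample(1:9, 10, TRUE)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)
  x <- sample(1:9, 8, TRUE); y <- sample(1:9, 8, TRUE)
  if (all(x == y)) x[1] <- y[1] + 1
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(y, x)$p_value)
})

test_that("Fisher's exact test matches direct hypergeometric evaluation", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10))
  tab <- matrix(c(1, 9, 9, 1), 2)
  expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab))
  expect_equal(fisher_exact_2x2(tab)$p_value, 202 / choose(20, 10))
  set.seed(40)
  for (i in 1:20) {
    tab <- matrix(sample(0:12, 4, TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-7)
  }
  expect_warning(res <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)),
                 "zero margin")
  expect_equal(res$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("self-comparison bootstrap is degenerate at delta 0, p 1", {
  set.seed(41)
  x <- rnorm(20); y <- x + rnorm(20)
  b <- bootstrap_dependent_rho_diff(x, y, y, replicates = 200, seed = 5)
  expect_equal(b$delta, 0)
  expect_equal(unname(b$ci), c(0, 0))
  expect_equal(b$p_value, 1)
})

test_that("bootstrap comparison is bit-reproducible and leaves the RNG alone", {
  set.seed(42)
  x <- rnorm(30); y1 <- x + rnorm(30); y2 <- rnorm(30)
  set.seed(1234)
  before <- .Random.seed
  b1 <- bootstrap_dependent_rho_diff(x, y1, y2, replicates = 300, seed = 77)
  expect_identical(.Random.seed, before)
  b2 <- bootstrap_dependent_rho_diff(x, y1, y2, replicates = 300, seed = 77)
  expect_identical(b1, b2)
  b3 <- bootstrap_dependent_rho_diff(x, y1, y2, replicates = 300, seed = 78)
  expect_false(identical(b1$ci, b3$ci))
})

test_that("bootstrap comparison detects a clearly better correlate", {
  set.seed(43)
  x <- rnorm(200)
  y1 <- x + rnorm(200, sd = 0.3)   # strongly correlated with x
  y2 <- rnorm(200)                 # independent noise
  b <- bootstrap_dependent_rho_diff(x, y1, y2, replicates = 1000, seed = 9)
  expect_gt(b$ci[["lower"]], 0)
  expect_lt(b$p_value, 0.05)
})

test_that("bootstrap comparison validates its contract", {
  x <- rnorm(10)
  expect_error(bootstrap_dependent_rho_diff(x[1:4], x[1:4], x[1:4],
                                            seed = 1), "n >= 5")
  expect_error(bootstrap_dependent_rho_diff(x, x, x, replicates = 10,
                                            seed = 1), "100 replicates")
  expect_error(bootstrap_dependent_rho_diff(x, rep(1, 10), x, seed = 1),
               "non-constant")
  expect_error(bootstrap_dependent_rho_diff(x, x + 1, x + 2), "seed")
})
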
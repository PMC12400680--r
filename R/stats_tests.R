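#' Correlation and nonparametric inference
#'
#' Spearman rank correlations (pairwise, with a t-approximation p-value), a
#' full correlation matrix across raters and reference measurements, and a
#' subject-level bootstrap for comparing two dependent overlapping Spearman
#' correlations (two correlations sharing one variable measured on the same
#' subjects), alongside the classical rank tests used to compare deviation
#' distributions.
#'
#' @name stats_tests
NULL

# Spearman rho without inference; returns NA if either rank vector is
# constant. Hot path of the bootstrap, so kept minimal.
.spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sx <- sum((rx - mean(rx))^2); sy <- sum((ry - mean(ry))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sx * sy)
}

#' Spearman's rank-order correlation
#'
#' Mid-ranks both vectors (ties get average ranks) and computes the
#' product-moment correlation of the ranks; the p-value uses the
#' t-approximation with `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric/ordinal vectors; pairs with a missing member
#'   are dropped; at least 3 complete pairs required.
#' @return list of class `"correlation_result"`: `rho`, `p_value`, `n`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho  # 0.8
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rho <- .spearman(x, y)
  if (is.na(rho))
    stop("undefined correlation: a rank vector has zero variance")
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  structure(list(rho = rho, p_value = p, n = n),
            class = "correlation_result")
}

#' Pairwise Spearman correlation matrix
#'
#' @param columns named list of per-subject vectors sharing a subject index
#'   (or a data.frame); >= 2 columns. Missing values are deleted pairwise
#'   per cell; cells with fewer than 3 complete pairs or an undefined
#'   correlation are `NA`.
#' @return list of class `"correlation_matrix"` with matrices `rho`, `p`,
#'   `n` in the input column order (unit diagonal, symmetric).
#' @export
correlation_matrix <- function(columns) {
  columns <- as.list(columns)
  k <- length(columns)
  if (k < 2L) stop("need at least 2 columns")
  if (is.null(names(columns)) || any(!nzchar(names(columns))))
    stop("columns must be named")
  len <- unique(lengths(columns))
  if (length(len) != 1L) stop("columns must share one subject index")
  nm <- names(columns)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(rho) <- 1; diag(p) <- 0; diag(nmat) <- len
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    res <- tryCatch(spearman_rho(columns[[i]], columns[[j]]),
                    error = function(e) NULL)
    if (!is.null(res)) {
      rho[i, j] <- rho[j, i] <- res$rho
      p[i, j] <- p[j, i] <- res$p_value
      nmat[i, j] <- nmat[j, i] <- res$n
    }
  }
  structure(list(rho = rho, p = p, n = nmat),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix:\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' Bootstrap comparison of two dependent overlapping Spearman correlations
#'
#' Tests whether `rho(x, y1)` differs from `rho(x, y2)` when both
#' correlations share the variable `x` measured on the same subjects (the
#' "overlapping" dependent case). Subjects (rows) are resampled with
#' replacement, preserving the dependence between `y1` and `y2`; each
#' replicate contributes `rho(x*, y1*) - rho(x*, y2*)`. The confidence
#' interval is the percentile interval of the replicate differences and the
#' two-sided p-value is twice the smaller sign-crossing fraction,
#' `2 min(Pr(delta* <= 0), Pr(delta* >= 0))`, clipped to \[0, 1\].
#' Replicates in which a resampled correlation is undefined (constant rank
#' vector) are redrawn so the replicate count stays fixed.
#'
#' @param x shared vector; `y1`, `y2` the two competing vectors. Equal
#'   lengths, n >= 5, no missing values.
#' @param replicates number of bootstrap replicates (>= 100; default 5000).
#' @param level confidence level of the percentile interval (default 0.95).
#' @param seed integer seed; the result is fully reproducible from it. The
#'   caller's RNG state is left untouched.
#' @return list of class `"bootstrap_comparison"`: `rho_1`, `rho_2`,
#'   `delta`, `ci` (lower, upper), `p_value`, `replicates`, `seed`,
#'   `n`, `n_redrawn`.
#' @export
bootstrap_dependent_rho_diff <- function(x, y1, y2, replicates = 5000,
                                         level = 0.95, seed) {
  x <- as.numeric(x); y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  n <- length(x)
  if (length(y1) != n || length(y2) != n)
    stop("x, y1, y2 must have equal length")
  if (anyNA(x) || anyNA(y1) || anyNA(y2))
    stop("missing values are not supported; complete cases only")
  if (n < 5L) stop("need n >= 5 subjects")
  if (replicates < 100L) stop("need at least 100 replicates")
  if (stats::var(y1) == 0 || stats::var(y2) == 0)
    stop("y1 and y2 must be non-constant")
  if (missing(seed)) stop("an explicit seed is required")

  rho1 <- .spearman(x, y1)
  rho2 <- .spearman(x, y2)
  if (is.na(rho1) || is.na(rho2))
    stop("undefined correlation in the observed data")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  deltas <- numeric(replicates)
  n_redrawn <- 0L
  for (r in seq_len(replicates)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      d1 <- .spearman(x[idx], y1[idx])
      d2 <- .spearman(x[idx], y2[idx])
      if (!is.na(d1) && !is.na(d2)) break
      n_redrawn <- n_redrawn + 1L
    }
    deltas[r] <- d1 - d2
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(deltas, c(alpha, 1 - alpha)))
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  structure(list(rho_1 = rho1, rho_2 = rho2, delta = rho1 - rho2,
                 ci = c(lower = ci[1L], upper = ci[2L]), p_value = p,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), n = n, n_redrawn = n_redrawn,
                 level = level),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap comparison of dependent Spearman correlations (%d replicates)\n",
              x$replicates))
  cat(sprintf("  rho1 = %.*f, rho2 = %.*f, delta = %.*f\n",
              digits, x$rho_1, digits, x$rho_2, digits, x$delta))
  cat(sprintf("  %.0f%% percentile CI [%.*f, %.*f], p = %.4g\n",
              100 * x$level, digits, x$ci[["lower"]], digits, x$ci[["upper"]],
              x$p_value))
  invisible(x)
}

# Exact null distribution of the signed-rank statistic V = sum of positive
# mid-ranks, over the 2^m equiprobable sign assignments. Mid-ranks are
# half-integers at worst, so doubling them gives integers and a
# shift-algorithm DP over achievable doubled sums.
.signed_rank_exact_p <- function(v, r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with doubled sum s
  counts[1L] <- 1
  for (w in r2) {
    shifted <- c(rep(0, w), counts[seq_len(total + 1L - w)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  v2 <- round(2 * v)
  sums <- seq_along(counts) - 1L
  p_le <- sum(probs[sums <= v2 + 1e-9])
  p_ge <- sum(probs[sums >= v2 - 1e-9])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Ranks the nonzero paired differences by absolute value (mid-ranks for
#' ties) and sums the ranks of the positive differences. With at most 25
#' nonzero differences the exact two-sided p-value is computed from the full
#' null distribution of the statistic (valid under ties, via a
#' dynamic-programming enumeration of sign assignments); otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param paired_a,paired_b numeric vectors of equal length.
#' @return list of class `"rank_test_result"`: `statistic` (V), `p_value`,
#'   `method`, `n_nonzero`, `exact`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  a <- as.numeric(paired_a); b <- as.numeric(paired_b)
  if (length(a) != length(b)) stop("samples must be paired (equal length)")
  keep <- !(is.na(a) | is.na(b))
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all paired differences are zero; test is degenerate")
    return(structure(list(statistic = 0, p_value = 1,
                          method = "wilcoxon_signed_rank",
                          n_nonzero = 0L, exact = TRUE),
                     class = "rank_test_result"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (m <= 25L) {
    p <- .signed_rank_exact_p(v, r)
    exact <- TRUE
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    exact <- FALSE
  }
  structure(list(statistic = v, p_value = p,
                 method = "wilcoxon_signed_rank",
                 n_nonzero = m, exact = exact),
            class = "rank_test_result")
}

#' Mann-Whitney U test for two independent samples
#'
#' Computes U from pooled mid-ranks. For small samples without ties
#' (`n_a * n_b <= 400`) the exact two-sided p-value is used; otherwise a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param group_a,group_b numeric vectors (nonempty, missing values
#'   dropped).
#' @return list of class `"rank_test_result"`: `statistic` (U of group a),
#'   `p_value`, `method`, `exact`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  a <- as.numeric(group_a); a <- a[!is.na(a)]
  b <- as.numeric(group_b); b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (!has_ties && na * nb <= 400) {
    p <- min(1, 2 * min(stats::pwilcox(u, na, nb),
                        stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)))
    exact <- TRUE
  } else {
    mu <- na * nb / 2
    nt <- na + nb
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    exact <- FALSE
  }
  structure(list(statistic = u, p_value = p, method = "mann_whitney_u",
                 exact = exact),
            class = "rank_test_result")
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p-value summing the hypergeometric probabilities of all tables
#' (with the observed margins) whose probability does not exceed the
#' observed table's.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list of class `"rank_test_result"`: `statistic` (odds-ratio
#'   estimate), `p_value`, `method`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold nonnegative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a zero margin makes the test degenerate; p = 1")
    return(structure(list(statistic = NA_real_, p_value = 1,
                          method = "fisher_exact"),
                     class = "rank_test_result"))
  }
  ft <- stats::fisher.test(tab)
  structure(list(statistic = unname(ft$estimate), p_value = ft$p.value,
                 method = "fisher_exact"),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.4g%s\n", x$method,
              format(x$statistic), x$p_value,
              if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}
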
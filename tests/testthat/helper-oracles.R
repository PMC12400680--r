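# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately written from the definitions (enumeration,
# textbook formulas), not by calling the package implementations.

random_score_matrix <- function(n, k, scores = 1:9, missing_frac = 0) {
  m <- matrix(sample(scores, n * k, replace = TRUE), n, k,
              dimnames = list(paste0("s", seq_len(n)), paste0("r", seq_len(k))))
  if (missing_frac > 0) {
    drop <- which(runif(n * k) < missing_frac)
    m[drop] <- NA_integer_
  }
  # keep at least one score per subject
  for (i in seq_len(n)) if (all(is.na(m[i, ]))) m[i, 1L] <- sample(scores, 1)
  score_matrix(m)
}

# Kendall's W from the textbook ties-corrected formula, computed step by
# step with explicit loops.
oracle_kendalls_w <- function(m) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  R <- matrix(0, n, k)
  for (j in seq_len(k)) R[, j] <- rank(m[, j])
  Ri <- numeric(n)
  for (i in seq_len(n)) Ri[i] <- sum(R[i, ])
  S <- sum((Ri - k * (n + 1) / 2)^2)
  Tsum <- 0
  for (j in seq_len(k)) {
    for (t in as.integer(table(m[, j]))) Tsum <- Tsum + (t^3 - t)
  }
  12 * S / (k^2 * (n^3 - n) - k * Tsum)
}

# Exact two-sided signed-rank p by enumerating all 2^m sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs + 1e-9), mean(v_all >= v_obs - 1e-9)))
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled ranks to group a.
oracle_mann_whitney_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# Two-sided Fisher p from first principles: sum of hypergeometric
# probabilities of tables no more probable than the observed one.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
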
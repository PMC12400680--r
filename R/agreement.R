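#' Deviation-from-reference and concordance statistics
#'
#' Raters are judged against a per-subject reference key: either a single
#' clinically assessed score (palpation-based CA-BCS) or the pair of scores
#' given by two senior clinicians. Deviations are measured to the closest
#' key score; concordance across raters uses the ties-corrected Kendall W;
#' pairwise agreement of two score series uses Bland-Altman limits of
#' agreement.
#'
#' @name agreement
NULL

#' Per-subject reference key
#'
#' @param subjects character vector of subject ids.
#' @param scores list (parallel to `subjects`) of integer vectors of length
#'   1 or 2, each score in 1..9; or a single integer vector for
#'   one-score-per-subject keys.
#' @return named list of class `"reference_key"` mapping subject to its key
#'   score set.
#' @export
reference_key <- function(subjects, scores) {
  subjects <- as.character(subjects)
  if (!is.list(scores)) scores <- as.list(as.integer(scores))
  if (length(subjects) != length(scores))
    stop("subjects and scores must have equal length")
  scores <- lapply(scores, function(k) {
    k <- sort(unique(as.integer(k)))
    if (length(k) < 1L || length(k) > 2L)
      stop("each key must hold 1 or 2 scores")
    if (any(is.na(k)) || any(k < .BCS_MIN | k > .BCS_MAX))
      stop("key scores must lie in [1,9]")
    k
  })
  names(scores) <- subjects
  structure(scores, class = "reference_key")
}

#' Build a reference key from a cohort table's clinical scores
#'
#' @param cohort a cohort table with `subject` and `ca_bcs` columns; rows
#'   with missing `ca_bcs` are dropped.
#' @return a [reference_key()].
#' @export
key_from_cohort <- function(cohort) {
  keep <- !is.na(cohort$ca_bcs)
  reference_key(cohort$subject[keep], cohort$ca_bcs[keep])
}

#' Build a dual reference key from two raters of a score matrix
#'
#' @param matrix a [score_matrix()].
#' @param rater_a,rater_b rater ids whose scores define the key (e.g. the
#'   two senior clinicians). Subjects where both are missing are dropped.
#' @return a [reference_key()].
#' @export
key_from_raters <- function(matrix, rater_a, rater_b) {
  if (!all(c(rater_a, rater_b) %in% colnames(matrix)))
    stop("key raters must be columns of the score matrix")
  a <- matrix[, rater_a]; b <- matrix[, rater_b]
  keep <- !(is.na(a) & is.na(b))
  reference_key(rownames(matrix)[keep],
                lapply(which(keep), function(i) {
                  k <- c(a[i], b[i])
                  k[!is.na(k)]
                }))
}

#' Signed deviation of a score from the closest key score
#'
#' The reference score is the key score minimising `|score - key|`;
#' when a score is exactly equidistant from two distinct key scores the
#' lower key is used (documented, conservative convention). The signed
#' deviation is `score - nearest key`.
#'
#' @param score integer score in 1..9.
#' @param key integer vector of 1 or 2 key scores (one subject's entry of a
#'   [reference_key()]).
#' @return list with `signed_deviation`, `abs_deviation`, `nearest_key`.
#' @examples
#' signed_deviation(7, c(5, 6))  # +1, nearest key 6
#' @export
signed_deviation <- function(score, key) {
  key <- sort(as.integer(key))
  if (length(key) < 1L) stop("empty reference key")
  score <- as.integer(score)
  if (is.na(score) || score < .BCS_MIN || score > .BCS_MAX)
    stop("score must lie in [1,9]")
  d <- abs(score - key)
  nearest <- key[which.min(d)]  # which.min takes the first (= lower) on ties
  list(signed_deviation = score - nearest,
       abs_deviation = abs(score - nearest),
       nearest_key = nearest)
}

# Vectorised signed deviations for one rater column against a key.
.signed_deviations <- function(scores, key_list) {
  vapply(seq_along(scores), function(i) {
    if (is.na(scores[i])) return(NA_integer_)
    as.integer(signed_deviation(scores[i], key_list[[i]])$signed_deviation)
  }, integer(1))
}

#' Pooled deviation summary for selected raters
#'
#' Pools every non-missing (subject, rater) evaluation over the selected
#' raters and summarises the deviations from the subject's closest key
#' score: mean absolute deviation, its standard error (sample SD of the
#' pooled absolute deviations divided by sqrt(n)), the distribution of
#' signed deviations, and the complete-agreement fraction (share of
#' evaluations with deviation 0).
#'
#' @param matrix a [score_matrix()].
#' @param key a [reference_key()] covering the pooled subjects; subjects
#'   without a key entry are excluded from the pool.
#' @param raters character vector of rater ids to pool (default: all).
#' @return list of class `"deviation_summary"`: `mean_abs`, `sem`, `n`,
#'   `distribution` (named fractions over signed deviations),
#'   `complete_agreement_fraction`, and `records` (per-evaluation
#'   data.frame with `subject`, `rater`, `signed_deviation`,
#'   `abs_deviation`).
#' @export
deviation_summary <- function(matrix, key, raters = colnames(matrix)) {
  if (!all(raters %in% colnames(matrix)))
    stop("raters must be a subset of the matrix raters")
  subjects <- intersect(rownames(matrix), names(key))
  recs <- do.call(rbind, lapply(raters, function(r) {
    dev <- .signed_deviations(matrix[subjects, r], key[subjects])
    data.frame(subject = subjects, rater = r, signed_deviation = dev,
               stringsAsFactors = FALSE)
  }))
  recs <- recs[!is.na(recs$signed_deviation), , drop = FALSE]
  if (nrow(recs) == 0L) stop("no evaluations selected")
  recs$abs_deviation <- abs(recs$signed_deviation)
  n <- nrow(recs)
  dist <- table(recs$signed_deviation) / n
  structure(list(
    mean_abs = mean(recs$abs_deviation),
    sem = stats::sd(recs$abs_deviation) / sqrt(n),
    n = n,
    distribution = dist,
    complete_agreement_fraction = if ("0" %in% names(dist)) unname(dist["0"]) else 0,
    records = recs
  ), class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Deviation summary over %d evaluations\n", x$n))
  cat(sprintf("  mean |deviation| = %.*f +/- %.*f (SE)\n",
              digits, x$mean_abs, digits, x$sem))
  cat(sprintf("  complete agreement: %.1f%%\n",
              100 * x$complete_agreement_fraction))
  cat("  signed-deviation distribution:\n")
  print(round(x$distribution, digits))
  invisible(x)
}

#' Per-rater deviation table
#'
#' One [deviation_summary()] row per rater (plus optionally the majority
#' vote as pseudo-rater `"MV"`), mirroring a per-scorer performance table.
#'
#' @inheritParams deviation_summary
#' @param votes optional [consensus_scores()] result; when supplied a vote
#'   row is appended.
#' @return data.frame with columns `rater`, `mean_abs`, `sem`, `n`,
#'   `complete_agreement_fraction`.
#' @export
deviation_table <- function(matrix, key, raters = colnames(matrix), votes = NULL) {
  rows <- lapply(raters, function(r) {
    s <- deviation_summary(matrix, key, r)
    data.frame(rater = r, mean_abs = s$mean_abs, sem = s$sem, n = s$n,
               complete_agreement_fraction = s$complete_agreement_fraction,
               stringsAsFactors = FALSE)
  })
  if (!is.null(votes)) {
    vm <- score_matrix(cbind(MV = votes$vote), subjects = votes$subject)
    s <- deviation_summary(vm, key, "MV")
    rows <- c(rows, list(data.frame(
      rater = "MV", mean_abs = s$mean_abs, sem = s$sem, n = s$n,
      complete_agreement_fraction = s$complete_agreement_fraction,
      stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}

#' Kendall's coefficient of concordance (ties-corrected)
#'
#' Measures agreement among m raters scoring n subjects. Each rater's
#' column is converted to mid-ranks; with `S` the sum of squared deviations
#' of the subject rank-sums from their mean and `T_j = sum(t^3 - t)` over
#' tied groups of rater j,
#' `W = 12 S / (m^2 (n^3 - n) - m sum(T_j))`.
#' Significance uses the chi-square approximation
#' `chi^2 = m (n - 1) W` with `n - 1` degrees of freedom.
#'
#' @param matrix a [score_matrix()] (or plain numeric matrix) with >= 2
#'   raters and >= 3 subjects; rows with any missing cell are dropped
#'   (listwise-complete analysis).
#' @return list of class `"concordance_result"`: `W`, `chi_square`, `df`,
#'   `p_value`, `n_subjects`, `n_raters`.
#' @export
kendalls_w <- function(matrix) {
  m <- as.matrix(matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("Kendall's W needs at least 2 raters")
  if (n < 3L) stop("Kendall's W needs at least 3 complete subjects")
  R <- apply(m, 2L, rank)          # mid-ranks within each rater
  rowsums <- rowSums(R)
  S <- sum((rowsums - mean(rowsums))^2)
  Tj <- apply(m, 2L, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  denom <- k^2 * (n^3 - n) - k * sum(Tj)
  if (denom <= 0)
    stop("degenerate input: tie correction exhausts the rank variance")
  W <- 12 * S / denom
  chi <- k * (n - 1) * W
  df <- n - 1L
  structure(list(W = W, chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE),
                 n_subjects = n, n_raters = k),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, digits = 3, ...) {
  cat(sprintf("Kendall's W = %.*f (%d raters, %d subjects)\n",
              digits, x$W, x$n_raters, x$n_subjects))
  cat(sprintf("  chi-square = %.*f, df = %d, p = %.3g\n",
              digits, x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Bland-Altman agreement between two paired score series
#'
#' @param series_a,series_b numeric vectors paired by subject, equal length
#'   >= 2; pairs with a missing member are dropped.
#' @return list of class `"bland_altman"`: `mean_difference`,
#'   `sd_difference` (sample SD), `limits` (`mean +/- 1.96 sd`), and
#'   `points` (data.frame of per-subject `mean` and `difference`,
#'   difference oriented as `a - b`).
#' @export
bland_altman <- function(series_a, series_b) {
  a <- as.numeric(series_a); b <- as.numeric(series_b)
  if (length(a) != length(b)) stop("series must be paired (equal length)")
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("Bland-Altman needs at least 2 complete pairs")
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d)
  structure(list(
    mean_difference = md,
    sd_difference = sdd,
    limits = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
    points = data.frame(mean = (a + b) / 2, difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman: mean difference %.*f (SD %.*f)\n",
              digits, x$mean_difference, digits, x$sd_difference))
  cat(sprintf("  95%% limits of agreement: [%.*f, %.*f]\n",
              digits, x$limits[["lower"]], digits, x$limits[["upper"]]))
  invisible(x)
}
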
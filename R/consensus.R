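#' Majority-vote consensus and duplicate-pair integrity
#'
#' The consensus score of a subject is the most common score among its
#' raters. When several scores tie for the highest count the tie is resolved
#' deterministically using only multiset information, so the result never
#' depends on rater order.
#'
#' @name consensus
NULL

#' Majority vote over a set of ordinal scores
#'
#' Returns the unique mode when one exists. Ties among modal candidates are
#' broken by a documented, permutation-invariant chain:
#' \enumerate{
#'   \item the candidate with the smallest mean absolute distance to the
#'     remaining (non-candidate) scores;
#'   \item if no remaining scores exist or the distances still tie, the
#'     candidate closest to the median of all scores;
#'   \item if still tied, the lower score (conservative: biases against
#'     over-diagnosis).
#' }
#'
#' @param scores integer vector of scores in 1..9, length >= 1, no `NA`
#'   (drop missing evaluations before calling).
#' @return a list of class `"vote_result"`: `vote` (integer), `tally`
#'   (named count table), `tie_broken` (logical), `tie_candidates`
#'   (integer vector of the modal candidates when a tie occurred, else the
#'   vote itself).
#' @examples
#' majority_vote(c(5, 5, 6, 6, 7))$vote  # 6: nearer to the remaining 7
#' @export
majority_vote <- function(scores) {
  s <- as.integer(scores)
  if (length(s) == 0L) stop("majority_vote needs at least one score")
  if (anyNA(s)) stop("missing scores must be removed before voting")
  if (any(s < .BCS_MIN | s > .BCS_MAX)) stop("scores must lie in [1,9]")
  tally <- table(s)
  counts <- as.integer(tally)
  values <- as.integer(names(tally))
  cand <- values[counts == max(counts)]
  tie_broken <- length(cand) > 1L
  if (!tie_broken) {
    vote <- cand
  } else {
    remaining <- s[!s %in% cand]
    pick <- cand
    if (length(remaining)) {
      d <- vapply(pick, function(v) mean(abs(v - remaining)), numeric(1))
      pick <- pick[abs(d - min(d)) < 1e-12]
    }
    if (length(pick) > 1L) {
      dm <- abs(pick - stats::median(s))
      pick <- pick[abs(dm - min(dm)) < 1e-12]
    }
    vote <- min(pick)
  }
  structure(list(vote = vote, tally = tally, tie_broken = tie_broken,
                 tie_candidates = cand),
            class = "vote_result")
}

#' @export
print.vote_result <- function(x, ...) {
  cat(sprintf("Majority vote: %d%s\n", x$vote,
              if (x$tie_broken)
                sprintf(" (tie among {%s} broken)",
                        paste(x$tie_candidates, collapse = ", "))
              else ""))
  invisible(x)
}

#' Consensus (majority-vote) score for every subject of a score matrix
#'
#' @param matrix a [score_matrix()]; each subject needs at least one
#'   non-missing score.
#' @return a `data.frame` in matrix subject order with columns `subject`,
#'   `vote`, `n_scores`, `tie_broken`, and a list-column `tie_candidates`.
#' @export
consensus_scores <- function(matrix) {
  res <- lapply(rownames(matrix), function(subj) {
    row <- matrix[subj, ]
    row <- row[!is.na(row)]
    if (length(row) == 0L)
      stop(sprintf("subject '%s' has no non-missing score", subj))
    majority_vote(row)
  })
  out <- data.frame(
    subject = rownames(matrix),
    vote = vapply(res, `[[`, integer(1), "vote"),
    n_scores = vapply(res, function(v) sum(v$tally), numeric(1)),
    tie_broken = vapply(res, `[[`, logical(1), "tie_broken"),
    stringsAsFactors = FALSE
  )
  out$tie_candidates <- lapply(res, `[[`, "tie_candidates")
  out
}

#' Scoring consistency across duplicate image pairs
#'
#' For each registered pair of altered duplicates, reports every rater's
#' signed score difference (second member minus first) and the difference of
#' the majority votes, plus a summary of the absolute-difference
#' distribution.
#'
#' @param matrix a [score_matrix()].
#' @param registry a [duplicate_registry()]; all ids must be matrix subjects.
#' @param votes optional result of [consensus_scores()] (computed if `NULL`).
#' @return a `data.frame` of class `"duplicate_report"` with columns
#'   `pair`, `subject_a`, `subject_b`, `rater` (`"MV"` for the vote row),
#'   `score_a`, `score_b`, `diff`; the table of `|diff|` counts is attached
#'   as attribute `"abs_diff_distribution"`.
#' @export
duplicate_consistency <- function(matrix, registry, votes = NULL) {
  unknown <- setdiff(c(registry$subject_a, registry$subject_b), rownames(matrix))
  if (length(unknown))
    stop(sprintf("registry subject '%s' not present in score matrix", unknown[1L]))
  if (is.null(votes)) votes <- consensus_scores(matrix)
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    a <- registry$subject_a[i]; b <- registry$subject_b[i]
    per_rater <- data.frame(
      pair = i, subject_a = a, subject_b = b, rater = colnames(matrix),
      score_a = as.integer(matrix[a, ]), score_b = as.integer(matrix[b, ]),
      stringsAsFactors = FALSE
    )
    mv <- data.frame(
      pair = i, subject_a = a, subject_b = b, rater = "MV",
      score_a = votes$vote[votes$subject == a],
      score_b = votes$vote[votes$subject == b],
      stringsAsFactors = FALSE
    )
    rbind(per_rater, mv)
  })
  out <- do.call(rbind, rows)
  out$diff <- out$score_b - out$score_a
  per_rater <- out$rater != "MV"
  attr(out, "abs_diff_distribution") <- table(abs(out$diff[per_rater]))
  class(out) <- c("duplicate_report", "data.frame")
  out
}
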
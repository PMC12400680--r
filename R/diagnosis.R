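#' Diagnostic categories and misclassification-shift analysis
#'
#' The 9-point scale partitions into ordered diagnostic categories:
#' underweight (UW, 1-3), ideal weight (IW, 4-5), overweight but not obese
#' (OW, 6-7) and obese (OB, 8-9). Shift analysis quantifies how often a
#' visual assessment moves a subject across a clinically relevant category
#' boundary relative to the reference assessment.
#'
#' @name diagnosis
NULL

.BCS_CATEGORIES <- c("UW", "IW", "OW", "OB")

#' Map BCS values to diagnostic categories
#'
#' @param score integer vector of scores in 1..9 (`NA` passed through).
#' @return ordered factor with levels `UW < IW < OW < OB`
#'   (1-3, 4-5, 6-7, 8-9 respectively).
#' @examples
#' categorize_bcs(c(2, 4, 7, 9))  # UW IW OW OB
#' @export
categorize_bcs <- function(score) {
  s <- as.integer(score)
  if (any(!is.na(s) & (s < .BCS_MIN | s > .BCS_MAX)))
    stop("scores must lie in [1,9]")
  idx <- findInterval(s, c(1L, 4L, 6L, 8L))
  factor(.BCS_CATEGORIES[idx], levels = .BCS_CATEGORIES, ordered = TRUE)
}

#' Diagnosis shifts between a reference and an evaluator
#'
#' Counts subjects whose diagnostic category crosses a stated boundary
#' between the reference scores and the evaluator's scores.
#' `"IW_vs_OWOB"` counts crossings of the IW | (OW or OB) boundary in either
#' direction; `"IW_vs_OB"` counts only subjects placed in IW on one side and
#' OB on the other. The denominator is all paired subjects in both modes,
#' and "up" means a move toward the heavier side.
#'
#' @param reference,evaluator paired integer score vectors (1..9).
#' @param boundary_mode `"IW_vs_OWOB"` or `"IW_vs_OB"`.
#' @param evaluator_id optional label carried into the result.
#' @return list of class `"shift_summary"`: `evaluator_id`, `n_subjects`,
#'   `boundary_mode`, `n_shift_up`, `n_shift_down`, `shift_rate`,
#'   `unchanged_rate`.
#' @export
shift_analysis <- function(reference, evaluator,
                           boundary_mode = c("IW_vs_OWOB", "IW_vs_OB"),
                           evaluator_id = NA_character_) {
  boundary_mode <- match.arg(boundary_mode)
  if (length(reference) != length(evaluator))
    stop("reference and evaluator must be paired (equal length)")
  ref <- categorize_bcs(reference)
  ev <- categorize_bcs(evaluator)
  if (anyNA(ref) || anyNA(ev)) stop("all scores must be present and valid")
  n <- length(ref)
  if (boundary_mode == "IW_vs_OWOB") {
    up <- ref == "IW" & ev %in% c("OW", "OB")
    down <- ref %in% c("OW", "OB") & ev == "IW"
  } else {
    up <- ref == "IW" & ev == "OB"
    down <- ref == "OB" & ev == "IW"
  }
  n_up <- sum(up); n_down <- sum(down)
  structure(list(evaluator_id = evaluator_id, n_subjects = n,
                 boundary_mode = boundary_mode,
                 n_shift_up = n_up, n_shift_down = n_down,
                 shift_rate = (n_up + n_down) / n,
                 unchanged_rate = 1 - (n_up + n_down) / n),
            class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("Diagnosis shifts (%s%s): %d up, %d down of %d subjects (rate %.3f)\n",
              x$boundary_mode,
              if (is.na(x$evaluator_id)) "" else paste0(", ", x$evaluator_id),
              x$n_shift_up, x$n_shift_down, x$n_subjects, x$shift_rate))
  invisible(x)
}

#' Shift table across all raters plus the majority vote
#'
#' Runs [shift_analysis()] for each rater of the matrix against the
#' reference, appends a majority-vote row (`"MV"`) and, when an original
#' clinical scorer is identified, an `"OCS"` row repeating that rater's
#' scores under the OCS label. The across-evaluator average rate — the
#' unweighted mean over the individual raters only (MV and OCS excluded) —
#' is attached as attribute `"average_rate"`.
#'
#' @param reference named integer vector of reference scores (names =
#'   subject ids); only subjects present in both reference and matrix are
#'   analysed.
#' @param matrix a [score_matrix()] (must be complete for the analysed
#'   subjects).
#' @param votes optional [consensus_scores()] result (computed if `NULL`).
#' @param boundary_mode `"IW_vs_OWOB"` or `"IW_vs_OB"`.
#' @param ocs optional rater id of the original clinical scorer.
#' @return data.frame of class `"shift_table"` with one row per evaluator:
#'   `evaluator`, `boundary_mode`, `n_subjects`, `n_shift_up`,
#'   `n_shift_down`, `shift_rate`, `unchanged_rate`.
#' @export
cohort_shift_table <- function(reference, matrix, votes = NULL,
                               boundary_mode = c("IW_vs_OWOB", "IW_vs_OB"),
                               ocs = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  if (is.null(names(reference))) stop("reference must be named by subject")
  subjects <- intersect(rownames(matrix), names(reference))
  if (length(subjects) == 0L) stop("reference covers no matrix subject")
  if (is.null(votes)) votes <- consensus_scores(matrix)
  ref <- reference[subjects]
  one <- function(id, scores) {
    s <- shift_analysis(ref, scores, boundary_mode, evaluator_id = id)
    data.frame(evaluator = id, boundary_mode = boundary_mode,
               n_subjects = s$n_subjects, n_shift_up = s$n_shift_up,
               n_shift_down = s$n_shift_down, shift_rate = s$shift_rate,
               unchanged_rate = s$unchanged_rate, stringsAsFactors = FALSE)
  }
  rows <- lapply(colnames(matrix), function(r) one(r, matrix[subjects, r]))
  vote_scores <- votes$vote[match(subjects, votes$subject)]
  rows <- c(rows, list(one("MV", vote_scores)))
  if (!is.null(ocs)) {
    if (!ocs %in% colnames(matrix)) stop("ocs must be a rater of the matrix")
    rows <- c(rows, list(one("OCS", matrix[subjects, ocs])))
  }
  out <- do.call(rbind, rows)
  attr(out, "average_rate") <-
    mean(out$shift_rate[out$evaluator %in% colnames(matrix)])
  class(out) <- c("shift_table", "data.frame")
  out
}
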
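#' Score matrices and rater-table input/output
#'
#' A score matrix is the central container of the package: an integer matrix
#' of 9-point body condition scores with one row per subject (a cat, or an
#' image of a cat) and one column per rater. Missing evaluations are `NA` and
#' are dropped pairwise by downstream statistics.
#'
#' @name score_io
NULL

.BCS_MIN <- 1L
.BCS_MAX <- 9L

#' Construct and validate a score matrix
#'
#' @param scores integer matrix (or object coercible to one) of scores in
#'   1..9, `NA` allowed. Row names are subject identifiers, column names are
#'   rater identifiers; both must be present and unique.
#' @param subjects,raters optional character vectors overriding the dimnames.
#' @return an integer matrix of class `"score_matrix"`.
#' @examples
#' m <- score_matrix(rbind(c(5, 6), c(5, 7)),
#'                   subjects = c("s1", "s2"), raters = c("A", "B"))
#' @export
score_matrix <- function(scores, subjects = NULL, raters = NULL) {
  m <- as.matrix(scores)
  if (!is.null(subjects)) rownames(m) <- subjects
  if (!is.null(raters)) colnames(m) <- raters
  if (is.null(rownames(m)) && nrow(m) > 0L)
    rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m)) && ncol(m) > 0L)
    colnames(m) <- paste0("R", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate subject identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate rater identifiers")
  storage.mode(m) <- "integer"
  bad <- !is.na(m) & (m < .BCS_MIN | m > .BCS_MAX)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("score %d out of range [1,9] at subject '%s', rater '%s'",
                 m[bad][1L], rownames(m)[i[1L]], colnames(m)[i[2L]]))
  }
  class(m) <- c("score_matrix", class(m))
  m
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("Score matrix: %d subjects x %d raters (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(unclass(x), ...)
  invisible(x)
}

#' Parse a confidence-annotated score cell
#'
#' Raters may annotate a score with their certainty: a single score `"5"`,
#' a fully confident score `"5 = 5"` (level A), two adjacent scores judged
#' equally likely `"5 = 6"` (level B), or two adjacent scores with a lean
#' toward the first `"5 > 6"` (level C). The primary score — the value used
#' in the score matrix — is always the first-listed score.
#'
#' @param raw character scalar, one cell of a score table.
#' @return a list with integer `primary`, integer `secondary` (`NA` when
#'   absent) and character `confidence` (`"A"`, `"B"`, `"C"` or `NA`).
#' @examples
#' parse_confidence_notation("5 = 6")  # primary 5, secondary 6, level B
#' @export
parse_confidence_notation <- function(raw) {
  if (length(raw) != 1L || !is.character(raw))
    stop("'raw' must be a single character string")
  m <- regmatches(raw, regexec("^\\s*([0-9]+)\\s*(?:([=>])\\s*([0-9]+))?\\s*$", raw))[[1L]]
  if (length(m) == 0L)
    stop(sprintf("unparseable score cell: '%s'", raw))
  primary <- as.integer(m[2L])
  if (primary < .BCS_MIN || primary > .BCS_MAX)
    stop(sprintf("score '%s' outside the 1-9 scale in cell '%s'", m[2L], raw))
  if (m[3L] == "") {
    return(list(primary = primary, secondary = NA_integer_,
                confidence = NA_character_))
  }
  secondary <- as.integer(m[4L])
  if (secondary < .BCS_MIN || secondary > .BCS_MAX)
    stop(sprintf("score '%s' outside the 1-9 scale in cell '%s'", m[4L], raw))
  if (m[3L] == "=" && primary == secondary) {
    return(list(primary = primary, secondary = NA_integer_, confidence = "A"))
  }
  if (abs(secondary - primary) != 1L)
    stop(sprintf("non-adjacent score pair '%s': secondary must differ from primary by exactly 1", raw))
  list(primary = primary, secondary = secondary,
       confidence = if (m[3L] == "=") "B" else "C")
}

# Parse a character vector of cells to primary scores; empty/NA -> NA.
# Errors carry `where` (e.g. "row 3, rater B") for location reporting.
.parse_score_cells <- function(cells, where) {
  out <- rep(NA_integer_, length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[i]
    if (is.na(cell) || !nzchar(trimws(cell))) next
    rec <- tryCatch(parse_confidence_notation(cell),
                    error = function(e) stop(sprintf("%s (%s)", conditionMessage(e), where[i]),
                                             call. = FALSE))
    out[i] <- rec$primary
  }
  out
}

#' Read a rater score table from CSV
#'
#' Two dialects are supported. `"long"` has columns `subject,rater,score`
#' (one evaluation per row); `"wide"` has a `subject` column followed by one
#' column per rater. Score cells may carry confidence notation
#' (see [parse_confidence_notation()]); the first-listed (primary) score
#' becomes the matrix value. Empty cells are missing evaluations.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return a [score_matrix()]. Subject and rater order is file order.
#' @export
read_score_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character())
  if (dialect == "long") {
    need <- c("subject", "rater", "score")
    if (!all(need %in% names(df)))
      stop(sprintf("long score CSV must have header columns %s; got: %s",
                   paste(need, collapse = ","), paste(names(df), collapse = ",")))
    key <- paste(df$subject, df$rater, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1L, ]
      stop(sprintf("duplicate (subject, rater) entry: ('%s', '%s')",
                   d$subject, d$rater))
    }
    vals <- .parse_score_cells(df$score,
                               sprintf("row %d, subject '%s', rater '%s'",
                                       seq_len(nrow(df)) + 1L, df$subject, df$rater))
    subjects <- unique(df$subject)
    raters <- unique(df$rater)
    m <- matrix(NA_integer_, length(subjects), length(raters),
                dimnames = list(subjects, raters))
    m[cbind(match(df$subject, subjects), match(df$rater, raters))] <- vals
    score_matrix(m)
  } else {
    if (names(df)[1L] != "subject")
      stop("wide score CSV must have 'subject' as its first column")
    if (ncol(df) < 2L) stop("wide score CSV has no rater columns")
    raters <- names(df)[-1L]
    vals <- sapply(raters, function(r) {
      .parse_score_cells(df[[r]], sprintf("row %d, rater '%s'",
                                          seq_len(nrow(df)) + 1L, r))
    })
    m <- matrix(as.integer(vals), nrow = nrow(df),
                dimnames = list(df$subject, raters))
    score_matrix(m)
  }
}

#' Write a score matrix to CSV
#'
#' Inverse of [read_score_table()]: `read_score_table(write_score_table(m))`
#' reproduces `m` in either dialect. Missing cells are written as empty
#' fields; the long dialect writes every (subject, rater) cell so that the
#' full rater set survives a round trip.
#'
#' @param matrix a [score_matrix()].
#' @param path output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(matrix, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  m <- matrix
  chr <- ifelse(is.na(m), "", as.character(m))
  subjects <- rownames(m)
  if (is.null(subjects)) subjects <- character(nrow(m))
  if (dialect == "long") {
    df <- data.frame(
      subject = rep(subjects, times = ncol(m)),
      rater = rep(colnames(m), each = nrow(m)),
      score = as.vector(chr),
      stringsAsFactors = FALSE
    )
    df <- df[order(match(df$subject, subjects), match(df$rater, colnames(m))), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  } else {
    df <- data.frame(subject = subjects, chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("subject", colnames(m))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a subject (cohort) metadata table
#'
#' Expected columns: `subject`, `body_weight_kg` (kilograms, may be empty),
#' `ca_bcs` (clinically assessed BCS 1-9, may be empty); any further columns
#' are carried along as free metadata.
#'
#' @param path CSV file path.
#' @return a `data.frame` with character `subject`, numeric `body_weight_kg`,
#'   integer `ca_bcs`.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject" %in% names(df)) stop("cohort CSV must have a 'subject' column")
  df$subject <- as.character(df$subject)
  if (anyDuplicated(df$subject)) stop("duplicate subject in cohort table")
  if ("body_weight_kg" %in% names(df)) {
    df$body_weight_kg <- as.numeric(df$body_weight_kg)
    if (any(!is.na(df$body_weight_kg) & df$body_weight_kg <= 0))
      stop("body_weight_kg must be positive when present")
  }
  if ("ca_bcs" %in% names(df)) {
    df$ca_bcs <- as.integer(df$ca_bcs)
    bad <- !is.na(df$ca_bcs) & (df$ca_bcs < .BCS_MIN | df$ca_bcs > .BCS_MAX)
    if (any(bad))
      stop(sprintf("ca_bcs out of range [1,9] for subject '%s'",
                   df$subject[bad][1L]))
  }
  df
}

#' Duplicate-image registries
#'
#' A registry records which subjects are altered duplicates of the same
#' animal (or image), used to audit scoring consistency.
#'
#' @param subject_a,subject_b character vectors of equal length; row i pairs
#'   `subject_a[i]` with `subject_b[i]`.
#' @return a `data.frame` of class `"duplicate_registry"` with columns
#'   `subject_a`, `subject_b`.
#' @export
duplicate_registry <- function(subject_a = character(), subject_b = character()) {
  a <- as.character(subject_a); b <- as.character(subject_b)
  if (length(a) != length(b)) stop("pair columns must have equal length")
  if (any(a == b)) stop("a duplicate pair must name two distinct subjects")
  ids <- c(a, b)
  if (anyDuplicated(ids))
    stop(sprintf("subject '%s' appears in more than one pair",
                 ids[duplicated(ids)][1L]))
  structure(data.frame(subject_a = a, subject_b = b, stringsAsFactors = FALSE),
            class = c("duplicate_registry", "data.frame"))
}

#' @rdname duplicate_registry
#' @param path CSV with columns `subject_a,subject_b`.
#' @export
read_duplicate_registry <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("subject_a", "subject_b") %in% names(df)))
    stop("registry CSV must have columns subject_a,subject_b")
  duplicate_registry(df$subject_a, df$subject_b)
}

#' Validate a score matrix against cohort metadata and a duplicate registry
#'
#' Pure reporting operation: inputs are never modified. The returned report
#' is a data.frame of findings (empty if and only if all checks pass) with a
#' per-rater missingness count attached as attribute `"missingness"`
#' (missing evaluations are permitted and are not findings).
#'
#' @param matrix a score matrix (class checked loosely so raw matrices can be
#'   audited before construction).
#' @param cohort optional cohort table ([read_cohort_table()]).
#' @param registry optional [duplicate_registry()].
#' @return data.frame of class `"bcs_validation"` with columns
#'   `check`, `subject`, `rater`, `message`.
#' @export
validate_score_matrix <- function(matrix, cohort = NULL, registry = NULL) {
  m <- as.matrix(matrix)
  findings <- list()
  add <- function(check, subject, rater, message)
    findings[[length(findings) + 1L]] <<- data.frame(
      check = check, subject = subject, rater = rater, message = message,
      stringsAsFactors = FALSE)
  suppressWarnings(storage.mode(m) <- "integer")
  bad <- which(!is.na(m) & (m < .BCS_MIN | m > .BCS_MAX), arr.ind = TRUE)
  if (nrow(bad)) {
    for (k in seq_len(nrow(bad)))
      add("range", rownames(m)[bad[k, 1L]], colnames(m)[bad[k, 2L]],
          sprintf("score %d outside [1,9]", m[bad[k, , drop = FALSE]]))
  }
  if (!is.null(cohort)) {
    missing_subj <- setdiff(rownames(m), cohort$subject)
    if (!is.null(registry)) {
      # registered altered duplicates legitimately lack their own cohort row
      missing_subj <- setdiff(missing_subj,
                              c(registry$subject_a, registry$subject_b))
    }
    for (s in missing_subj)
      add("cohort", s, NA_character_, "subject absent from cohort table")
  }
  if (!is.null(registry)) {
    unknown <- setdiff(c(registry$subject_a, registry$subject_b), rownames(m))
    for (s in unknown)
      add("registry", s, NA_character_, "registry subject absent from score matrix")
  }
  rep <- if (length(findings)) do.call(rbind, findings) else
    data.frame(check = character(), subject = character(),
               rater = character(), message = character(),
               stringsAsFactors = FALSE)
  attr(rep, "missingness") <- colSums(is.na(m))
  class(rep) <- c("bcs_validation", "data.frame")
  rep
}

#' @export
print.bcs_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Score matrix validation: all checks passed\n")
  } else {
    cat(sprintf("Score matrix validation: %d finding(s)\n", nrow(x)))
    print(as.data.frame(x), ...)
  }
  miss <- attr(x, "missingness")
  if (!is.null(miss) && any(miss > 0))
    cat("Missing evaluations per rater:",
        paste(sprintf("%s=%d", names(miss)[miss > 0], miss[miss > 0]),
              collapse = ", "), "\n")
  invisible(x)
}
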
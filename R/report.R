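#' Full-pipeline analysis and report assembly
#'
#' `run_full_analysis()` chains validation, consensus voting, deviation
#' statistics, concordance, Bland-Altman, the correlation matrix with
#' optional bootstrap comparisons, the diagnosis shift tables and the
#' duplicate-pair report into one bundle, optionally written as tidy CSVs
#' plus a run log. Every number in the bundle is the direct output of the
#' underlying module functions; nothing is recomputed at the report layer.
#'
#' @name cli_report
NULL

#' Run the complete agreement analysis
#'
#' @param matrix a [score_matrix()].
#' @param cohort optional cohort table (needed for the `"ca_bcs"` reference,
#'   weight correlations and shift tables).
#' @param registry optional [duplicate_registry()].
#' @param reference_mode `"ca_bcs"` (reference = clinical score from the
#'   cohort table) or `"dual_key"` (reference = the two `key_raters`'
#'   scores, closest-key rule; those raters are excluded from the judged
#'   pool).
#' @param key_raters length-2 character vector of rater ids
#'   (`"dual_key"` mode only).
#' @param ocs optional rater id of the original clinical scorer.
#' @param bootstrap list with `replicates` (default 5000) and `level`
#'   (default 0.95) for the dependent-correlation comparisons; comparisons
#'   are run only in `"ca_bcs"` mode with an `ocs` identified (majority
#'   vote vs OCS against the clinical score, and — when weights are
#'   available — OCS vs clinical score against body weight).
#' @param seed integer seed for the bootstrap comparisons (required when
#'   they run).
#' @param out_dir optional directory; when given, the bundle is written as
#'   CSV files plus `run_log.txt`.
#' @return list of class `"bcs_report"` with elements `validation`,
#'   `votes`, `deviation_table`, `pooled_deviation`, `vote_deviation`,
#'   `concordance`, `bland_altman`, `correlations`,
#'   `bootstrap_comparisons`, `shift_tables`, `duplicate_report`, `log`.
#' @export
run_full_analysis <- function(matrix, cohort = NULL, registry = NULL,
                              reference_mode = c("ca_bcs", "dual_key"),
                              key_raters = NULL, ocs = NULL,
                              bootstrap = list(replicates = 5000, level = 0.95),
                              seed = NULL, out_dir = NULL) {
  reference_mode <- match.arg(reference_mode)
  log_lines <- c(sprintf("bcsagree run, reference_mode=%s", reference_mode),
                 sprintf("matrix: %d subjects x %d raters", nrow(matrix),
                         ncol(matrix)))

  validation <- validate_score_matrix(matrix, cohort, registry)
  if (nrow(validation) > 0L) {
    print(validation)
    stop("validation findings present; aborting analysis")
  }

  if (reference_mode == "ca_bcs") {
    if (is.null(cohort) || !"ca_bcs" %in% names(cohort))
      stop("ca_bcs reference requires a cohort table with a ca_bcs column")
    key <- key_from_cohort(cohort)
    judged_raters <- colnames(matrix)
  } else {
    if (is.null(key_raters) || length(key_raters) != 2L)
      stop("dual_key reference requires exactly 2 key_raters")
    key <- key_from_raters(matrix, key_raters[1L], key_raters[2L])
    judged_raters <- setdiff(colnames(matrix), key_raters)
    log_lines <- c(log_lines,
                   sprintf("key raters: %s (closest-key rule, ties to lower key)",
                           paste(key_raters, collapse = ",")))
  }

  votes <- consensus_scores(matrix)
  dev_table <- deviation_table(matrix, key, judged_raters, votes = votes)
  pooled <- deviation_summary(matrix, key, judged_raters)
  vote_matrix <- score_matrix(cbind(MV = votes$vote), subjects = votes$subject)
  vote_dev <- deviation_summary(vote_matrix, key)
  concordance <- kendalls_w(matrix)

  # Agreement of the mean judged-rater score with the (closest) key score.
  key_subjects <- intersect(rownames(matrix), names(key))
  mean_scores <- rowMeans(matrix[key_subjects, judged_raters, drop = FALSE],
                          na.rm = TRUE)
  closest_key <- vapply(key_subjects, function(s) {
    k <- key[[s]]
    k[which.min(abs(mean_scores[[s]] - k))]  # ties to the lower key (k sorted)
  }, numeric(1))
  ba <- bland_altman(mean_scores, closest_key)

  cols <- lapply(colnames(matrix), function(r) matrix[key_subjects, r])
  names(cols) <- colnames(matrix)
  cols$MV <- votes$vote[match(key_subjects, votes$subject)]
  if (!is.null(ocs)) cols$OCS <- matrix[key_subjects, ocs]
  if (reference_mode == "ca_bcs") {
    cols$CA <- cohort$ca_bcs[match(key_subjects, cohort$subject)]
    if ("body_weight_kg" %in% names(cohort))
      cols$weight <- cohort$body_weight_kg[match(key_subjects, cohort$subject)]
  }
  correlations <- correlation_matrix(cols)

  boots <- list()
  if (reference_mode == "ca_bcs" && !is.null(ocs)) {
    if (is.null(seed)) stop("bootstrap comparisons need an explicit seed")
    boots$mv_vs_ocs_on_ca <- bootstrap_dependent_rho_diff(
      cols$CA, cols$MV, cols$OCS,
      replicates = bootstrap$replicates, level = bootstrap$level, seed = seed)
    if (!is.null(cols$weight))
      boots$ocs_vs_ca_on_weight <- bootstrap_dependent_rho_diff(
        cols$weight, cols$OCS, cols$CA,
        replicates = bootstrap$replicates, level = bootstrap$level,
        seed = seed + 1L)
    log_lines <- c(log_lines,
                   sprintf("bootstrap: %d replicates, level %.2f, seed %d",
                           bootstrap$replicates, bootstrap$level, seed))
  }

  shift_tables <- NULL
  if (reference_mode == "ca_bcs") {
    ref <- stats::setNames(cohort$ca_bcs, cohort$subject)
    ref <- ref[!is.na(ref)]
    shift_tables <- list(
      IW_vs_OWOB = cohort_shift_table(ref, matrix, votes, "IW_vs_OWOB", ocs = ocs),
      IW_vs_OB = cohort_shift_table(ref, matrix, votes, "IW_vs_OB", ocs = ocs))
  }

  dup_report <- if (!is.null(registry) && nrow(registry) > 0L)
    duplicate_consistency(matrix, registry, votes) else NULL

  log_lines <- c(log_lines,
                 sprintf("pooled |deviation| = %.4f +/- %.4f over %d evaluations",
                         pooled$mean_abs, pooled$sem, pooled$n),
                 sprintf("vote |deviation| = %.4f", vote_dev$mean_abs),
                 sprintf("Kendall W = %.4f (p = %.3g)", concordance$W,
                         concordance$p_value),
                 "conventions: majority-vote tie-break nearest-remaining/median/lower;",
                 "  closest-key deviations with equidistance to the lower key;",
                 "  SEM over pooled evaluations; percentile bootstrap, sign-crossing p")

  report <- structure(list(
    validation = validation, votes = votes, deviation_table = dev_table,
    pooled_deviation = pooled, vote_deviation = vote_dev,
    concordance = concordance, bland_altman = ba,
    correlations = correlations, bootstrap_comparisons = boots,
    shift_tables = shift_tables, duplicate_report = dup_report,
    log = log_lines), class = "bcs_report")
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

#' Write a report bundle as CSV files plus a run log
#'
#' @param report a `"bcs_report"` from [run_full_analysis()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     fileEncoding = "UTF-8")
  wcsv(report$deviation_table, "deviation_table.csv")
  votes <- report$votes
  votes$tie_candidates <- vapply(votes$tie_candidates, paste, character(1),
                                 collapse = ";")
  wcsv(votes, "consensus_votes.csv")
  wcsv(data.frame(W = report$concordance$W,
                  chi_square = report$concordance$chi_square,
                  df = report$concordance$df,
                  p_value = report$concordance$p_value),
       "kendalls_w.csv")
  wcsv(report$bland_altman$points, "bland_altman_points.csv")
  utils::write.csv(report$correlations$rho,
                   file.path(out_dir, "correlation_rho.csv"))
  utils::write.csv(report$correlations$p,
                   file.path(out_dir, "correlation_p.csv"))
  if (length(report$bootstrap_comparisons)) {
    bt <- do.call(rbind, lapply(names(report$bootstrap_comparisons), function(nm) {
      b <- report$bootstrap_comparisons[[nm]]
      data.frame(comparison = nm, rho_1 = b$rho_1, rho_2 = b$rho_2,
                 delta = b$delta, ci_lower = b$ci[["lower"]],
                 ci_upper = b$ci[["upper"]], p_value = b$p_value,
                 replicates = b$replicates, seed = b$seed,
                 stringsAsFactors = FALSE)
    }))
    wcsv(bt, "bootstrap_comparisons.csv")
  }
  if (!is.null(report$shift_tables)) {
    wcsv(report$shift_tables$IW_vs_OWOB, "shift_IW_vs_OWOB.csv")
    wcsv(report$shift_tables$IW_vs_OB, "shift_IW_vs_OB.csv")
  }
  if (!is.null(report$duplicate_report))
    wcsv(as.data.frame(report$duplicate_report), "duplicate_report.csv")
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.bcs_report <- function(x, ...) {
  cat("BCS agreement analysis\n")
  cat(sprintf("  pooled |deviation| %.3f +/- %.3f (n = %d), vote %.3f\n",
              x$pooled_deviation$mean_abs, x$pooled_deviation$sem,
              x$pooled_deviation$n, x$vote_deviation$mean_abs))
  cat(sprintf("  Kendall W = %.3f (p = %.3g)\n", x$concordance$W,
              x$concordance$p_value))
  if (!is.null(x$shift_tables))
    cat(sprintf("  shift rates: IW|OW+OB average %.3f, IW|OB average %.3f\n",
                attr(x$shift_tables$IW_vs_OWOB, "average_rate"),
                attr(x$shift_tables$IW_vs_OB, "average_rate")))
  invisible(x)
}

#' Simulate a synthetic cohort and analyse it
#'
#' Chains [generate_cohort()] into [run_full_analysis()] with the clinical
#' (generator-truth) reference; both seeds are recorded in the run log. In
#' the synthetic design the original clinical scorer is taken to be the
#' first senior rater.
#'
#' @param config a [cohort_config()].
#' @param analysis_seed seed for the bootstrap comparisons (default: the
#'   cohort seed + 1000).
#' @param bootstrap,out_dir passed to [run_full_analysis()].
#' @return list with `cohort` (the `"synthetic_cohort"`) and `report`
#'   (the `"bcs_report"`).
#' @export
simulate_and_analyze <- function(config, analysis_seed = config$seed + 1000L,
                                 bootstrap = list(replicates = 5000, level = 0.95),
                                 out_dir = NULL) {
  cohort <- generate_cohort(config)
  ocs <- config$raters$rater_id[1L]
  report <- run_full_analysis(cohort$matrix, cohort$cohort, cohort$registry,
                              reference_mode = "ca_bcs", ocs = ocs,
                              bootstrap = bootstrap, seed = analysis_seed,
                              out_dir = out_dir)
  report$log <- c(report$log,
                  sprintf("synthetic cohort seed %d, analysis seed %d",
                          config$seed, analysis_seed))
  if (!is.null(out_dir))
    writeLines(report$log, file.path(out_dir, "run_log.txt"))
  list(cohort = cohort, report = report)
}
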
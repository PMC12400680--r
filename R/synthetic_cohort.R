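#' Synthetic multi-rater cohorts
#'
#' Generates cohorts with the statistical structure the pipeline assumes:
#' a categorical true BCS per subject, a body weight rank-correlated with
#' the true score on the log scale, a panel of raters who perceive the true
#' score through additive Gaussian noise (then round and clamp to the
#' 9-point scale), and optional altered-duplicate subjects whose perceived
#' truth is shifted by at most one point. Every operation is reproducible
#' from its seed.
#'
#' @name synthetic_cohort
NULL

#' Default rater panel
#'
#' Nine raters in three experience tiers: two senior clinicians (A, B;
#' perceptual noise SD 0.4 score units), three clinicians (C-E; SD 0.6) and
#' four veterinary students (F-I; SD 0.6). All unbiased. The noise SDs are
#' calibration knobs, not empirical estimates.
#'
#' @return data.frame with columns `rater_id`, `bias`, `dispersion`, `tier`.
#' @export
default_rater_models <- function() {
  data.frame(
    rater_id = LETTERS[1:9],
    bias = 0,
    dispersion = c(0.4, 0.4, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6),
    tier = c("senior", "senior", "clinician", "clinician", "clinician",
             "student", "student", "student", "student"),
    stringsAsFactors = FALSE
  )
}

#' Default true-score distribution
#'
#' Support 4..9 with median 6 and category mix 39.5% ideal weight,
#' 31.6% overweight, 28.9% obese — the composition of a typical
#' client-owned clinical cohort.
#'
#' @return named numeric vector of probabilities over scores "4".."9".
#' @export
default_truth_distribution <- function() {
  c("4" = 4, "5" = 11, "6" = 8, "7" = 4, "8" = 7, "9" = 4) / 38
}

#' Cohort generator configuration
#'
#' @param n_subjects number of (non-duplicate) subjects; default 38.
#' @param truth_distribution named probability vector over scores 1..9
#'   (names = scores); must sum to 1.
#' @param raters data.frame as [default_rater_models()].
#' @param weight_model list with `intercept`, `slope` (both on the log-kg
#'   scale, slope per score unit) and `log_sd` (SD of the lognormal noise).
#'   The default is calibrated so that Spearman(truth, weight) is close to
#'   0.73 under the default truth distribution.
#' @param duplicate_pairs list with `n` (number of altered duplicate pairs)
#'   and `probs` (named probabilities of the perceived-truth perturbation
#'   over `"-1"`, `"0"`, `"1"`).
#' @param seed mandatory integer seed.
#' @return validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 38,
                          truth_distribution = default_truth_distribution(),
                          raters = default_rater_models(),
                          weight_model = list(intercept = 0.72, slope = 0.167,
                                              log_sd = 0.242),
                          duplicate_pairs = list(n = 2,
                                                 probs = c("-1" = 0.25, "0" = 0.5,
                                                           "1" = 0.25)),
                          seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  p <- truth_distribution
  if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop("truth_distribution must be a named probability vector summing to 1")
  sc <- as.integer(names(p))
  if (anyNA(sc) || any(sc < .BCS_MIN | sc > .BCS_MAX))
    stop("truth_distribution names must be scores in 1..9")
  if (any(raters$dispersion < 0)) stop("rater dispersion must be >= 0")
  if (anyDuplicated(raters$rater_id)) stop("duplicate rater_id")
  if (abs(sum(duplicate_pairs$probs) - 1) > 1e-8)
    stop("duplicate perturbation probabilities must sum to 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 truth_distribution = p, raters = raters,
                 weight_model = weight_model,
                 duplicate_pairs = duplicate_pairs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Evaluate an RNG-consuming expression under a local seed (NULL = continue
# the current stream), restoring the caller's RNG state afterwards when a
# seed is given.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Draw true scores and body weights
#'
#' Truth is drawn from the configured score distribution; body weight is
#' lognormal around an exponential trend in the true score:
#' `weight_i = exp(intercept + slope * truth_i + eps_i)`,
#' `eps ~ N(0, log_sd)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed (default: the config's seed); `NULL` continues
#'   the current RNG stream.
#' @return list with integer `truth` and numeric `weights` (kg).
#' @export
generate_truth_and_weights <- function(config, seed = config$seed) {
  .with_seed(seed, {
    p <- config$truth_distribution
    support <- as.integer(names(p))
    truth <- support[sample.int(length(support), config$n_subjects,
                                replace = TRUE, prob = p)]
    wm <- config$weight_model
    eps <- stats::rnorm(config$n_subjects, 0, wm$log_sd)
    list(truth = truth, weights = exp(wm$intercept + wm$slope * truth + eps))
  })
}

#' Simulate rater scores from true scores
#'
#' Each rater perceives `truth + bias` through additive Gaussian noise with
#' the rater's dispersion, then the perceived value is rounded to the
#' nearest integer and clamped to the 1..9 scale (a discretised-Gaussian
#' ordinal model).
#'
#' @param truth integer vector of true scores.
#' @param raters data.frame as [default_rater_models()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param subjects optional subject ids (default `S1..Sn`).
#' @return a [score_matrix()].
#' @export
generate_rater_scores <- function(truth, raters, seed = NULL,
                                  subjects = paste0("S", seq_along(truth))) {
  .with_seed(seed, {
    n <- length(truth)
    m <- sapply(seq_len(nrow(raters)), function(j) {
      perceived <- truth + raters$bias[j] + stats::rnorm(n, 0, raters$dispersion[j])
      pmin(pmax(as.integer(round(perceived)), .BCS_MIN), .BCS_MAX)
    })
    m <- matrix(as.integer(m), nrow = n,
                dimnames = list(subjects, raters$rater_id))
    score_matrix(m)
  })
}

#' Generate a complete synthetic cohort
#'
#' Chains [generate_truth_and_weights()], [generate_rater_scores()] and
#' [inject_duplicates()] under the config's seed. The cohort table exposes
#' the generator truth as the clinically assessed score (`ca_bcs`);
#' duplicate subjects are registered but carry no cohort row, so deviation
#' and shift statistics automatically use each animal once.
#'
#' @param config a [cohort_config()].
#' @return list of class `"synthetic_cohort"`: `truth`, `weights`,
#'   `matrix`, `registry`, `cohort`, `config`, `seed`.
#' @export
generate_cohort <- function(config) {
  .with_seed(config$seed, {
    tw <- generate_truth_and_weights(config, seed = NULL)
    subjects <- paste0("S", seq_len(config$n_subjects))
    matrix <- generate_rater_scores(tw$truth, config$raters, seed = NULL,
                                    subjects = subjects)
    cohort <- data.frame(subject = subjects,
                         body_weight_kg = tw$weights,
                         ca_bcs = tw$truth, stringsAsFactors = FALSE)
    out <- structure(list(truth = stats::setNames(tw$truth, subjects),
                          weights = stats::setNames(tw$weights, subjects),
                          matrix = matrix,
                          registry = duplicate_registry(),
                          cohort = cohort, config = config,
                          seed = config$seed),
                     class = "synthetic_cohort")
    dp <- config$duplicate_pairs
    if (!is.null(dp) && dp$n > 0)
      out <- inject_duplicates(out, dp$n, dp$probs, seed = NULL)
    out
  })
}

#' Inject altered-duplicate subjects into a cohort
#'
#' Picks `n_pairs` subjects and appends one altered duplicate of each. The
#' duplicate's perceived truth is the source truth shifted by a
#' perturbation drawn from `perturbation_probs` over \{-1, 0, +1\}
#' (clamped to the scale) — the alteration acts on what every rater sees,
#' not on each rater independently — and the raters' scores for the
#' duplicate are regenerated from that perceived truth.
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param n_pairs number of duplicates (<= number of subjects).
#' @param perturbation_probs named probabilities over `"-1"`, `"0"`, `"1"`.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return the augmented `"synthetic_cohort"` (registry updated; duplicate
#'   subjects have score-matrix rows but no cohort-table row).
#' @export
inject_duplicates <- function(cohort, n_pairs, perturbation_probs, seed = NULL) {
  if (abs(sum(perturbation_probs) - 1) > 1e-8)
    stop("perturbation probabilities must sum to 1")
  n <- length(cohort$truth)
  if (n_pairs > n) stop("cannot duplicate more subjects than exist")
  .with_seed(seed, {
    originals <- names(cohort$truth)
    picked <- originals[sample.int(length(originals), n_pairs)]
    shifts <- as.integer(names(perturbation_probs))
    delta <- shifts[sample.int(length(shifts), n_pairs, replace = TRUE,
                               prob = perturbation_probs)]
    perceived <- pmin(pmax(cohort$truth[picked] + delta, .BCS_MIN), .BCS_MAX)
    dup_ids <- paste0(picked, "_dup")
    dup_matrix <- generate_rater_scores(perceived, cohort$config$raters,
                                        seed = NULL, subjects = dup_ids)
    cohort$matrix <- score_matrix(rbind(unclass(cohort$matrix),
                                        unclass(dup_matrix)))
    cohort$registry <- duplicate_registry(
      c(cohort$registry$subject_a, picked),
      c(cohort$registry$subject_b, dup_ids))
    cohort
  })
}

#' Calibrate the weight-model noise to a target rank correlation
#'
#' Holds the slope fixed and searches the lognormal noise SD by bisection
#' until the simulated Spearman correlation between truth and weight is
#' within `tol` of `target_rho`. The search uses common random numbers (one
#' fixed draw of truths and standard-normal noise), which makes the
#' achieved correlation a deterministic, monotone decreasing function of
#' the noise SD, so bisection converges cleanly.
#'
#' @param target_rho target Spearman correlation in (0, 1).
#' @param truth_distribution named probability vector (default
#'   [default_truth_distribution()]).
#' @param n_calibration simulation size per evaluation (default 10000).
#' @param seed integer seed.
#' @param slope,intercept fixed trend parameters (log scale).
#' @param tol convergence tolerance on the achieved correlation
#'   (default 0.02).
#' @return list with `intercept`, `slope`, `log_sd`, `achieved_rho`.
#' @export
calibrate_weight_model <- function(target_rho,
                                   truth_distribution = default_truth_distribution(),
                                   n_calibration = 10000, seed = 1,
                                   slope = 0.167, intercept = 0.72,
                                   tol = 0.02) {
  if (target_rho <= 0 || target_rho >= 1)
    stop("target_rho must lie in (0, 1)")
  sim <- .with_seed(seed, {
    p <- truth_distribution
    support <- as.integer(names(p))
    truth <- support[sample.int(length(support), n_calibration,
                                replace = TRUE, prob = p)]
    list(truth = truth, z = stats::rnorm(n_calibration))
  })
  achieved <- function(log_sd)
    .spearman(sim$truth, slope * sim$truth + log_sd * sim$z)
  rho_max <- achieved(0)
  if (is.na(rho_max) || rho_max < target_rho - tol)
    stop(sprintf("target rho %.3f unattainable: ties in the truth distribution cap the correlation at %.3f",
                 target_rho, if (is.na(rho_max)) NA_real_ else rho_max))
  lo <- 0; hi <- 1
  while (achieved(hi) > target_rho) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    r <- achieved(mid)
    if (abs(r - target_rho) <= tol / 2) { lo <- hi <- mid; break }
    if (r > target_rho) lo <- mid else hi <- mid
  }
  log_sd <- (lo + hi) / 2
  list(intercept = intercept, slope = slope, log_sd = log_sd,
       achieved_rho = achieved(log_sd))
}
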
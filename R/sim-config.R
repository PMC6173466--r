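#' Default lesion-level detection probabilities
#'
#' Probability that a reader of the given experience detects a true lesion of
#' the given zone in the given session, as a 3-d array indexed by
#' `zone` (PZ, TZ), `session` (MRI, CAD) and `experience` (high, moderate).
#' Defaults reproduce the reported zone-by-experience index-lesion
#' sensitivities at PI-RADSv2 threshold >= 1. A lesion spanning both zones is
#' detected with the larger of its two zone probabilities.
#'
#' @return numeric array `[2, 2, 2]` with dimnames zone/session/experience.
#' @export
default_detection_prob <- function() {
  a <- array(NA_real_, dim = c(2, 2, 2),
             dimnames = list(zone = ZONES, session = SESSIONS,
                             experience = c("high", "moderate")))
  a["PZ", "MRI", "high"] <- 0.86
  a["TZ", "MRI", "high"] <- 0.73
  a["PZ", "MRI", "moderate"] <- 0.80
  a["TZ", "MRI", "moderate"] <- 0.67
  a["PZ", "CAD", "high"] <- 0.772
  a["TZ", "CAD", "high"] <- 0.762
  a["PZ", "CAD", "moderate"] <- 0.777
  a["TZ", "CAD", "moderate"] <- 0.835
  a
}

#' Simulation configuration for a synthetic reader study
#'
#' Bundles every parameter of the synthetic-data generator: cohort size,
#' per-case lesion count and anatomy, reader behaviour in both sessions, and
#' false-finding behaviour. Defaults emulate the multi-institution study the
#' package models: 144 case and 72 control patients, a mean of 1.98 lesions
#' per case, a 187/88/10 PZ/TZ/both zone mix out of 285 lesions, six highly
#' and three moderately experienced readers, zone- and session-specific
#' detection probabilities, and Poisson false findings calibrated so that the
#' pooled MRI patient-level sensitivity at threshold >= 1 is 0.956 and the CAD
#' patient-level specificity is 34.5% at threshold 1 and 71.5% at threshold 3.
#'
#' @param n_case,n_control number of case / control patients.
#' @param n_readers_high,n_readers_moderate number of readers per experience
#'   level.
#' @param lesions_per_case_mean mean of the zero-truncated Poisson lesion
#'   count per case patient (must be >= 1; 1 gives exactly one lesion each).
#' @param zone_mix probability triple (PZ, TZ, both) for lesion zone, summing
#'   to 1.
#' @param gleason_mix named categorical distribution over Gleason patterns
#'   written `"primary+secondary"`.
#' @param detection_prob array as returned by [default_detection_prob()]:
#'   P(detect | zone, session, experience) for a true lesion.
#' @param score_given_detected list with one length-5 probability vector per
#'   session: PI-RADSv2 score distribution for a detected true lesion.
#' @param fp_rate expected number of false findings per patient per session;
#'   a scalar or a vector named by session.
#' @param fp_score list with one length-5 probability vector per session:
#'   score distribution for a false finding.
#' @param volume_meanlog,volume_sdlog log-normal parameters of lesion volume
#'   (ml).
#' @param max_findings cap on findings per (reader, patient, session);
#'   lowest-score extras are dropped.
#' @param seed optional integer seed recorded with the configuration.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_case = 10, n_control = 5)
#' cfg$lambda  # zero-truncated Poisson rate giving mean 1.98
#' @export
sim_config <- function(n_case = 144, n_control = 72,
                       n_readers_high = 6, n_readers_moderate = 3,
                       lesions_per_case_mean = 1.98,
                       zone_mix = c(PZ = 187, TZ = 88, both = 10) / 285,
                       gleason_mix = c("3+3" = 0.25, "3+4" = 0.32,
                                       "4+3" = 0.20, "4+4" = 0.08,
                                       "4+5" = 0.15),
                       detection_prob = default_detection_prob(),
                       score_given_detected = list(
                         MRI = c(0.005, 0.008, 0.150, 0.450, 0.387),
                         CAD = c(0.040, 0.055, 0.205, 0.450, 0.250)),
                       fp_rate = c(MRI = 0.7958, CAD = 1.0642),
                       fp_score = list(
                         MRI = c(0.28, 0.24, 0.20, 0.16, 0.12),
                         CAD = c(0.38, 0.305, 0.15, 0.10, 0.065)),
                       volume_meanlog = log(0.5), volume_sdlog = 1,
                       max_findings = 4L, seed = NULL) {
  if (n_case < 0 || n_control < 0)
    stop_config("n_case and n_control must be >= 0")
  if (n_readers_high < 0 || n_readers_moderate < 0)
    stop_config("reader counts must be >= 0")
  if (!is.numeric(lesions_per_case_mean) || lesions_per_case_mean <= 0)
    stop_config("lesions_per_case_mean must be positive")
  zone_mix <- zone_mix[c("PZ", "TZ", "both")]
  check_prob(zone_mix, "zone_mix")
  if (abs(sum(zone_mix) - 1) > 1e-9)
    stop_config("zone_mix must sum to 1 (got %.12f)", sum(zone_mix))
  check_prob(gleason_mix, "gleason_mix")
  if (abs(sum(gleason_mix) - 1) > 1e-9)
    stop_config("gleason_mix must sum to 1")
  if (!all(grepl("^[3-5]\\+[3-5]$", names(gleason_mix)))
  )
    stop_config("gleason_mix names must look like '3+4' with patterns 3-5")
  check_prob(detection_prob, "detection_prob")
  stopifnot(identical(dim(detection_prob), c(2L, 2L, 2L)))
  if (length(fp_rate) == 1L && is.null(names(fp_rate)))
    fp_rate <- setNames(rep(fp_rate, 2), SESSIONS)
  if (any(fp_rate < 0)) stop_config("fp_rate must be >= 0")
  for (s in SESSIONS) {
    check_prob(score_given_detected[[s]], paste0("score_given_detected$", s))
    if (abs(sum(score_given_detected[[s]]) - 1) > 1e-9)
      stop_config("score_given_detected$%s must sum to 1", s)
    check_prob(fp_score[[s]], paste0("fp_score$", s))
    if (abs(sum(fp_score[[s]]) - 1) > 1e-9)
      stop_config("fp_score$%s must sum to 1", s)
  }
  if (max_findings < 1) stop_config("max_findings must be >= 1")

  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_readers_high = as.integer(n_readers_high),
    n_readers_moderate = as.integer(n_readers_moderate),
    lesions_per_case_mean = lesions_per_case_mean,
    lambda = ztpois_lambda(lesions_per_case_mean),
    zone_mix = zone_mix, gleason_mix = gleason_mix,
    detection_prob = detection_prob,
    score_given_detected = score_given_detected,
    fp_rate = fp_rate, fp_score = fp_score,
    volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
    max_findings = as.integer(max_findings), seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Reader-study simulation configuration\n")
  cat(sprintf("  cohort: %d cases + %d controls; mean %.3g lesions/case (ZT-Poisson)\n",
              x$n_case, x$n_control, x$lesions_per_case_mean))
  cat(sprintf("  readers: %d high + %d moderate experience\n",
              x$n_readers_high, x$n_readers_moderate))
  cat(sprintf("  zone mix PZ/TZ/both: %s\n",
              paste(sprintf("%.3f", x$zone_mix), collapse = "/")))
  cat(sprintf("  false findings/patient/session: MRI %.3g, CAD %.3g\n",
              x$fp_rate[["MRI"]], x$fp_rate[["CAD"]]))
  invisible(x)
}

#' Reader roster implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return data frame with columns `reader_id`, `experience`.
#' @export
make_readers <- function(config) {
  n <- config$n_readers_high + config$n_readers_moderate
  data.frame(
    reader_id = sprintf("R%02d", seq_len(n)),
    experience = rep(c("high", "moderate"),
                     c(config$n_readers_high, config$n_readers_moderate)),
    stringsAsFactors = FALSE)
}

#' Analytic patient-level sensitivity/specificity implied by a configuration
#'
#' Closed-form operating characteristics of the generative model, used as the
#' independent oracle for calibration-recovery tests. For a case patient the
#' probability of at least one finding with score >= t combines the
#' zero-truncated Poisson lesion count (via its probability generating
#' function), the zone mix, the zone/session/experience detection
#' probabilities and the Poisson false-finding process; for a control patient
#' only false findings contribute.
#'
#' @param config a [sim_config()].
#' @param session `"MRI"` or `"CAD"`.
#' @param threshold PI-RADSv2 threshold t in 1..5.
#' @return list with `sensitivity` and `specificity`, each the reader-pooled
#'   value (readers weighted by head count).
#' @export
theoretical_patient_perf <- function(config, session = "MRI", threshold = 1) {
  session <- match.arg(session, SESSIONS)
  t <- as.integer(threshold)
  s_ge_t <- sum(config$score_given_detected[[session]][t:5])
  fp_ge_t <- sum(config$fp_score[[session]][t:5])
  f <- config$fp_rate[[session]]
  # P(no false finding with score >= t): thinning of the Poisson process
  p_no_fp <- exp(-f * fp_ge_t)
  mix <- config$zone_mix
  sens_by_exp <- vapply(c("high", "moderate"), function(e) {
    p <- config$detection_prob[, session, e]
    p_both <- max(p)
    # P(a given lesion yields no finding >= t), averaged over its zone
    q <- sum(mix * (1 - c(p["PZ"], p["TZ"], p_both) * s_ge_t))
    1 - ztpois_pgf(q, config$lambda) * p_no_fp
  }, numeric(1))
  w <- c(high = config$n_readers_high, moderate = config$n_readers_moderate)
  w <- w / sum(w)
  list(sensitivity = sum(w * sens_by_exp), specificity = 1 - (1 - p_no_fp))
}
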
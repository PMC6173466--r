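#' Patient-level maximum score per reading
#'
#' For patient-based analysis the maximum PI-RADSv2 score a reader assigned
#' to a patient in a session is used; a reading with no recorded finding
#' scores 0, so threshold >= 1 means "any recorded lesion".
#'
#' @param findings findings data frame.
#' @param assignment an [allocate()] result defining which (reader, patient)
#'   readings exist (readings with no findings are kept at score 0).
#' @param session `"MRI"` or `"CAD"`.
#' @return data frame `reader_id`, `patient_id`, `score` (0-5), one row per
#'   reading.
#' @export
patient_max_score <- function(findings, assignment, session) {
  session <- match.arg(session, SESSIONS)
  reads <- assignment_readings(assignment)
  f <- findings[findings$session == session, , drop = FALSE]
  key <- paste(reads$reader_id, reads$patient_id, sep = "\r")
  if (nrow(f)) {
    fkey <- paste(f$reader_id, f$patient_id, sep = "\r")
    mx <- tapply(f$score, fkey, max)
    reads$score <- as.integer(ifelse(key %in% names(mx), mx[key], 0L))
  } else reads$score <- 0L
  reads
}

#' Patient-level sensitivity and specificity at a threshold
#'
#' Sensitivity is the fraction of case readings with score >= t; specificity
#' the fraction of control readings with score < t. Both per-reader values
#' and the unweighted across-reader average (the study's estimand) are
#' returned; a pooled (reading-weighted) alternative is available.
#'
#' @param scores data frame `reader_id`, `patient_id`, `score` (from
#'   [patient_max_score()]).
#' @param patients patients data frame supplying `disease_status`.
#' @param threshold PI-RADSv2 threshold t in 1..5.
#' @param average `"reader"` (unweighted mean of reader-specific proportions,
#'   default) or `"pooled"`.
#' @return list with `sensitivity`, `specificity`, per-reader breakdowns and
#'   the numerator/denominator counts. Empty strata yield `NaN` and are
#'   flagged in `empty_strata`.
#' @export
patient_sens_spec <- function(scores, patients, threshold,
                              average = c("reader", "pooled")) {
  average <- match.arg(average)
  status <- setNames(patients$disease_status, patients$patient_id)
  st <- status[scores$patient_id]
  pos <- scores$score >= threshold
  per_reader <- function(sel, hit) {
    n <- tapply(sel, scores$reader_id, sum)
    x <- tapply(sel & hit, scores$reader_id, sum)
    (x / n)[n > 0 | TRUE]
  }
  se_r <- per_reader(st == "case", pos)
  sp_r <- per_reader(st == "control", !pos)
  agg <- function(per, sel, hit) {
    if (average == "reader") mean(per, na.rm = FALSE)
    else sum(sel & hit) / sum(sel)
  }
  res <- list(
    sensitivity = agg(se_r, st == "case", pos),
    specificity = agg(sp_r, st == "control", !pos),
    sensitivity_by_reader = se_r, specificity_by_reader = sp_r,
    n_case = sum(st == "case"), n_control = sum(st == "control"),
    empty_strata = c(if (sum(st == "case") == 0) "case",
                     if (sum(st == "control") == 0) "control"))
  res
}

#' Empirical ROC curve and AUC
#'
#' Sweeps the score thresholds to build operating points (1 - specificity,
#' sensitivity) and returns the trapezoidal area, which equals the
#' Mann-Whitney two-sample statistic with half-credit for ties.
#'
#' @param scores numeric vector of reading scores (0-5 here, but any ordinal
#'   scale works).
#' @param truth logical or `"case"`/`"control"` vector: `TRUE`/"case" marks
#'   diseased readings.
#' @return object of class `mrmc_roc`: list with `points` (data frame `fpr`,
#'   `tpr`, `threshold`) and `auc`.
#' @export
empirical_auc <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth)) truth <- truth == "case"
  stopifnot(length(scores) == length(truth))
  if (!any(truth) || all(truth))
    stop_config("empirical_auc needs at least one case and one control reading")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[truth] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!truth] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc), class = "mrmc_roc")
}

#' @export
print.mrmc_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.mrmc_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "b", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("Empirical ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Index-lesion sensitivity
#'
#' Fraction of (reader, case patient) readings whose index lesion was matched
#' with score >= t, optionally restricted to patients whose index lesion
#' involves a zone and to an experience group; the estimate is the unweighted
#' mean of reader-specific proportions (pooled alternative available).
#'
#' @param detection an [match_findings()] result.
#' @param bundle the study bundle (patients, lesions, readers, assignment).
#' @param session `"MRI"` or `"CAD"`.
#' @param threshold PI-RADSv2 threshold t.
#' @param zone `NULL` for whole prostate, or `"PZ"`/`"TZ"` (a both-zone index
#'   lesion counts in either stratum).
#' @param experience `NULL` for all readers, or `"high"`/`"moderate"`.
#' @param average `"reader"` or `"pooled"`.
#' @return list `estimate`, `by_reader`, `n_readings`, `n_detected`;
#'   `estimate` is `NaN` with `empty = TRUE` when the stratum has no
#'   readings.
#' @export
index_sensitivity <- function(detection, bundle, session, threshold = 1,
                              zone = NULL, experience = NULL,
                              average = c("reader", "pooled")) {
  average <- match.arg(average)
  session <- match.arg(session, SESSIONS)
  stopifnot(inherits(detection, "mrmc_detection"),
            !is.null(bundle$assignment))
  idx <- bundle$lesions[bundle$lesions$is_index, , drop = FALSE]
  if (!is.null(zone))
    idx <- idx[idx$zone == zone | idx$zone == "both", , drop = FALSE]
  reads <- assignment_readings(bundle$assignment)
  reads <- reads[reads$patient_id %in% idx$patient_id, , drop = FALSE]
  if (!is.null(experience)) {
    keep <- bundle$readers$reader_id[bundle$readers$experience == experience]
    reads <- reads[reads$reader_id %in% keep, , drop = FALSE]
  }
  if (!nrow(reads))
    return(list(estimate = NaN, by_reader = numeric(0), n_readings = 0L,
                n_detected = 0L, empty = TRUE))
  idx_of <- setNames(idx$lesion_id, idx$patient_id)
  m <- detection$matched
  m <- m[m$session == session & m$lesion_id %in% idx$lesion_id &
           m$score >= threshold, , drop = FALSE]
  hit_key <- paste(m$reader_id, m$lesion_id, sep = "\r")
  read_key <- paste(reads$reader_id, idx_of[reads$patient_id], sep = "\r")
  detected <- read_key %in% hit_key
  by_reader <- tapply(detected, reads$reader_id, mean)
  est <- if (average == "reader") mean(by_reader) else mean(detected)
  list(estimate = unname(est), by_reader = by_reader,
       n_readings = nrow(reads), n_detected = sum(detected), empty = FALSE)
}

#' Full performance report
#'
#' Assembles the patient-level sensitivity/specificity table (session x
#' experience group x threshold), the lesion-level index sensitivity table
#' (session x zone x experience group x threshold) and per-session pooled
#' AUCs for a bundle with findings and an assignment.
#'
#' @param bundle an [mrmc_bundle()] with `assignment`.
#' @param sessions sessions to report.
#' @param thresholds PI-RADSv2 thresholds to sweep.
#' @param min_gleason optional clinically-significant-cancer filter: keep only
#'   case patients whose index lesion has Gleason total >= this (and, at
#'   equal total, primary pattern counted via total only); e.g. `7` for
#'   >= 3+4. `NULL` keeps all cases.
#' @param average `"reader"` or `"pooled"` reader averaging.
#' @return object of class `mrmc_performance`: list of data frames
#'   `patient_level`, `lesion_level`, `auc`.
#' @export
performance_report <- function(bundle, sessions = SESSIONS,
                               thresholds = 1:5, min_gleason = NULL,
                               average = c("reader", "pooled")) {
  average <- match.arg(average)
  stopifnot(!is.null(bundle$assignment))
  b <- bundle
  if (!is.null(min_gleason)) {
    idx <- b$lesions[b$lesions$is_index, , drop = FALSE]
    keep_cases <- idx$patient_id[
      idx$gleason_primary + idx$gleason_secondary >= min_gleason]
    drop <- b$patients$patient_id[b$patients$disease_status == "case" &
                                    !b$patients$patient_id %in% keep_cases]
    b <- subset_bundle(b, setdiff(b$patients$patient_id, drop))
  }
  groups <- list(overall = NULL, moderate = "moderate", high = "high")
  det <- match_findings(b$findings, b$lesions, patients = b$patients)

  pat <- list(); les <- list(); aucs <- list()
  for (s in sessions) {
    sc <- patient_max_score(b$findings, b$assignment, s)
    status <- setNames(b$patients$disease_status, b$patients$patient_id)
    aucs[[s]] <- data.frame(
      session = s,
      auc = empirical_auc(sc$score, status[sc$patient_id])$auc,
      stringsAsFactors = FALSE)
    for (g in names(groups)) {
      sc_g <- if (is.null(groups[[g]])) sc else {
        rids <- b$readers$reader_id[b$readers$experience == groups[[g]]]
        sc[sc$reader_id %in% rids, , drop = FALSE]
      }
      for (t in thresholds) {
        ps <- patient_sens_spec(sc_g, b$patients, t, average = average)
        pat[[length(pat) + 1L]] <- data.frame(
          session = s, experience = g, threshold = t,
          sensitivity = ps$sensitivity, specificity = ps$specificity,
          n_case_readings = ps$n_case, n_control_readings = ps$n_control,
          stringsAsFactors = FALSE)
      }
      for (z in c("WP", "PZ", "TZ")) {
        zf <- if (z == "WP") NULL else z
        for (t in thresholds) {
          is_ <- index_sensitivity(det, b, s, t, zone = zf,
                                   experience = groups[[g]],
                                   average = average)
          les[[length(les) + 1L]] <- data.frame(
            session = s, zone = z, experience = g, threshold = t,
            sensitivity = is_$estimate, n_readings = is_$n_readings,
            n_detected = is_$n_detected, stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(patient_level = do.call(rbind, pat),
                 lesion_level = do.call(rbind, les),
                 auc = do.call(rbind, aucs)),
            class = "mrmc_performance")
}

#' @export
print.mrmc_performance <- function(x, ...) {
  cat("MRMC performance report\n")
  cat("  pooled AUC by session:\n")
  for (i in seq_len(nrow(x$auc)))
    cat(sprintf("    %s: %.3f\n", x$auc$session[i], x$auc$auc[i]))
  ov <- x$patient_level[x$patient_level$experience == "overall", ]
  cat("  patient-level (overall readers):\n")
  for (i in seq_len(nrow(ov)))
    cat(sprintf("    %s t>=%d: Se %.3f / Sp %.3f\n", ov$session[i],
                ov$threshold[i], ov$sensitivity[i], ov$specificity[i]))
  invisible(x)
}
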
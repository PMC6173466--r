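#' Simulate reader findings for both sessions
#'
#' For every reader-patient pair in the assignment and each session, each true
#' lesion is detected independently with the configured probability for its
#' zone, the session and the reader's experience (a both-zone lesion uses the
#' larger of its two zone probabilities and reports one of its zone tags at
#' random). Detected lesions receive a PI-RADSv2 score from the session's
#' score distribution. False findings arise as a Poisson count per patient
#' and session, placed at sectors not occupied by any true lesion of that
#' patient, with scores from the session's false-finding distribution. When a
#' reader accumulates more than `max_findings` findings on one patient in one
#' session, the lowest-score extras are dropped (true-lesion findings win
#' ties).
#'
#' @param cohort an `mrmc_cohort` (or bundle) with `patients` and `lesions`.
#' @param assignment an [allocate()] result covering all patients.
#' @param readers reader roster data frame (`reader_id`, `experience`); ids
#'   must cover the assignment's readers.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param sessions sessions to simulate (default both).
#' @return findings data frame in the schema of [mrmc_bundle()].
#' @export
simulate_readings <- function(cohort, assignment, readers, config,
                              seed = NULL, sessions = SESSIONS) {
  stopifnot(inherits(config, "sim_config"),
            inherits(assignment, "mrmc_assignment"))
  if (!all(assignment$readers %in% readers$reader_id))
    stop_config("assignment references readers missing from the roster")
  patients <- cohort$patients
  lesions <- cohort$lesions
  reads <- assignment_readings(assignment)
  if (!all(reads$patient_id %in% patients$patient_id))
    stop_config("assignment references patients missing from the cohort")
  if (!is.null(seed)) set.seed(seed)

  experience <- setNames(readers$experience, readers$reader_id)
  les_by_pat <- split(lesions, lesions$patient_id)
  all_slots <- sector_key(rep(ZONES, each = 6),
                          rep(rep(SIDES, each = 3), 2), rep(LEVELS, 4))

  out <- vector("list", nrow(reads) * length(sessions))
  k <- 0L
  for (i in seq_len(nrow(reads))) {
    r <- reads$reader_id[i]; pid <- reads$patient_id[i]
    exp_r <- experience[[r]]
    les <- les_by_pat[[pid]]
    n_les <- if (is.null(les)) 0L else nrow(les)
    occupied <- if (n_les) {
      both <- les$zone == "both"
      c(sector_key(les$zone[!both], les$side[!both], les$level[!both]),
        sector_key("PZ", les$side[both], les$level[both]),
        sector_key("TZ", les$side[both], les$level[both]))
    } else character(0)
    free <- setdiff(all_slots, occupied)
    for (s in sessions) {
      rows <- NULL
      if (n_les) {
        p_det <- vapply(seq_len(n_les), function(j) {
          z <- les$zone[j]
          if (z == "both") max(config$detection_prob[, s, exp_r])
          else config$detection_prob[z, s, exp_r]
        }, numeric(1))
        det <- runif(n_les) < p_det
        if (any(det)) {
          zs <- les$zone[det]
          zs[zs == "both"] <- sample(ZONES, sum(zs == "both"), replace = TRUE)
          rows <- data.frame(
            reader_id = r, session = s, patient_id = pid,
            zone = zs, side = les$side[det], level = les$level[det],
            score = sample(5L, sum(det), replace = TRUE,
                           prob = config$score_given_detected[[s]]),
            true_lesion = TRUE, stringsAsFactors = FALSE)
        }
      }
      n_fp <- rpois(1L, config$fp_rate[[s]])
      n_fp <- min(n_fp, length(free))
      if (n_fp > 0) {
        loc <- strsplit(sample(free, n_fp), "|", fixed = TRUE)
        rows <- rbind(rows, data.frame(
          reader_id = r, session = s, patient_id = pid,
          zone = vapply(loc, `[`, "", 1L),
          side = vapply(loc, `[`, "", 2L),
          level = vapply(loc, `[`, "", 3L),
          score = sample(5L, n_fp, replace = TRUE,
                         prob = config$fp_score[[s]]),
          true_lesion = FALSE, stringsAsFactors = FALSE))
      }
      if (!is.null(rows) && nrow(rows) > config$max_findings) {
        keep <- order(-rows$score, !rows$true_lesion)[seq_len(config$max_findings)]
        rows <- rows[sort(keep), , drop = FALSE]
      }
      if (!is.null(rows)) {
        k <- k + 1L
        out[[k]] <- rows
      }
    }
  }
  if (k == 0L) return(empty_findings())
  res <- do.call(rbind, out[seq_len(k)])
  res$true_lesion <- NULL
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: cohort generation, hybrid allocation and two-session
#' reading simulation, returning a validated bundle with its assignment.
#' Per-stage seeds are derived deterministically from `seed`.
#'
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @param common_fraction common-subset fraction for [allocate()].
#' @return an [mrmc_bundle()] with `assignment` set.
#' @export
simulate_study <- function(config, seed = 1L, common_fraction = 1 / 6) {
  cohort <- generate_cohort(config, seed = stage_seed(seed, 1L))
  readers <- make_readers(config)
  assignment <- allocate(cohort$patients, nrow(readers), common_fraction,
                         seed = stage_seed(seed, 2L),
                         reader_ids = readers$reader_id)
  findings <- simulate_readings(cohort, assignment, readers, config,
                                seed = stage_seed(seed, 3L))
  mrmc_bundle(cohort$patients, cohort$lesions, readers, findings, assignment)
}
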
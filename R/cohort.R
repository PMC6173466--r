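#' Generate a synthetic study cohort
#'
#' Draws case and control patients with ground-truth lesions. Each case
#' receives a zero-truncated Poisson number of lesions (configured mean),
#' placed without replacement on the discrete prostate sector grid
#' (zone x side x level) so that every lesion has an unambiguous location key;
#' a lesion can span both zones, in which case it occupies the PZ and TZ
#' sectors at its side/level. Gleason patterns come from the configured mix,
#' volumes are log-normal, and exactly one lesion per case is flagged as the
#' index lesion by [index_lesion()] (highest Gleason, ties by volume).
#' Controls carry no lesions.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list of class `mrmc_cohort` with data frames `patients` and
#'   `lesions` in the schemas of [read_tables()].
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_case + config$n_control
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    disease_status = rep(c("case", "control"),
                         c(config$n_case, config$n_control)),
    institution = NA_character_,
    stringsAsFactors = FALSE)

  lesions <- vector("list", config$n_case)
  counts <- if (config$n_case > 0) rztpois(config$n_case, config$lambda) else integer(0)
  patterns <- names(config$gleason_mix)
  for (i in seq_len(config$n_case)) {
    L <- min(counts[i], 6L)  # sector-grid capacity guard
    occ_pz <- character(0); occ_tz <- character(0)  # occupied side|level slots
    zone <- side <- level <- character(L)
    kept <- 0L
    slots <- paste(rep(SIDES, each = 3), rep(LEVELS, 2), sep = "|")
    for (k in seq_len(L)) {
      free_pz <- setdiff(slots, occ_pz)
      free_tz <- setdiff(slots, occ_tz)
      free_both <- intersect(free_pz, free_tz)
      feas <- c(PZ = length(free_pz) > 0, TZ = length(free_tz) > 0,
                both = length(free_both) > 0)
      if (!any(feas)) break
      mix <- config$zone_mix * feas
      z <- sample(names(mix), 1L, prob = mix / sum(mix))
      slot <- switch(z,
        PZ = free_pz[sample.int(length(free_pz), 1L)],
        TZ = free_tz[sample.int(length(free_tz), 1L)],
        both = free_both[sample.int(length(free_both), 1L)])
      if (z %in% c("PZ", "both")) occ_pz <- c(occ_pz, slot)
      if (z %in% c("TZ", "both")) occ_tz <- c(occ_tz, slot)
      kept <- kept + 1L
      zone[kept] <- z
      sl <- strsplit(slot, "|", fixed = TRUE)[[1]]
      side[kept] <- sl[1]; level[kept] <- sl[2]
    }
    gl <- sample(patterns, kept, replace = TRUE, prob = config$gleason_mix)
    gp <- as.integer(substr(gl, 1, 1)); gs <- as.integer(substr(gl, 3, 3))
    df <- data.frame(
      lesion_id = sprintf("%s-L%d", patients$patient_id[i], seq_len(kept)),
      patient_id = patients$patient_id[i],
      zone = zone[seq_len(kept)], side = side[seq_len(kept)],
      level = level[seq_len(kept)],
      gleason_primary = gp, gleason_secondary = gs,
      volume = rlnorm(kept, config$volume_meanlog, config$volume_sdlog),
      is_index = FALSE, stringsAsFactors = FALSE)
    df$is_index[df$lesion_id == index_lesion(df)$lesion_id] <- TRUE
    lesions[[i]] <- df
  }
  lesions <- if (config$n_case > 0) do.call(rbind, lesions) else empty_lesions()
  rownames(lesions) <- NULL
  structure(list(patients = patients, lesions = lesions),
            class = "mrmc_cohort")
}

#' @export
print.mrmc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cases, %d controls, %d lesions (%s)\n",
              sum(x$patients$disease_status == "case"),
              sum(x$patients$disease_status == "control"),
              nrow(x$lesions),
              paste(sprintf("%s %d", c("PZ", "TZ", "both"),
                            c(sum(x$lesions$zone == "PZ"),
                              sum(x$lesions$zone == "TZ"),
                              sum(x$lesions$zone == "both"))),
                    collapse = ", ")))
  invisible(x)
}

empty_lesions <- function() {
  data.frame(lesion_id = character(0), patient_id = character(0),
             zone = character(0), side = character(0), level = character(0),
             gleason_primary = integer(0), gleason_secondary = integer(0),
             volume = numeric(0), is_index = logical(0),
             stringsAsFactors = FALSE)
}

empty_findings <- function() {
  data.frame(reader_id = character(0), session = character(0),
             patient_id = character(0), zone = character(0),
             side = character(0), level = character(0), score = integer(0),
             stringsAsFactors = FALSE)
}
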
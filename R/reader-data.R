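#' Assemble a reader-study bundle
#'
#' A bundle holds the four study tables and (optionally) the reader-case
#' assignment. Schemas:
#' \describe{
#'   \item{patients}{`patient_id`, `disease_status` ("case"/"control"),
#'     optional `institution`.}
#'   \item{lesions}{`lesion_id`, `patient_id`, `zone` ("PZ"/"TZ"/"both"),
#'     `side` ("left"/"right"), `level` ("apex"/"mid"/"base"),
#'     `gleason_primary`, `gleason_secondary` (3-5), `volume` (ml),
#'     `is_index`.}
#'   \item{readers}{`reader_id`, `experience` ("high"/"moderate").}
#'   \item{findings}{`reader_id`, `session` ("MRI"/"CAD"), `patient_id`,
#'     `zone` ("PZ"/"TZ"), `side`, `level`, `score` (1-5); at most 4 findings
#'     per (reader, patient, session).}
#' }
#'
#' @param patients,lesions,readers,findings data frames as above (`lesions`
#'   and `findings` may be `NULL` for lesion-free / unread bundles).
#' @param assignment optional [allocate()] result.
#' @param validate run [validate_bundle()] (default `TRUE`).
#' @return object of class `mrmc_bundle`.
#' @export
mrmc_bundle <- function(patients, lesions = NULL, readers = NULL,
                        findings = NULL, assignment = NULL, validate = TRUE) {
  b <- structure(list(patients = patients,
                      lesions = lesions %||% empty_lesions(),
                      readers = readers %||%
                        data.frame(reader_id = character(0),
                                   experience = character(0),
                                   stringsAsFactors = FALSE),
                      findings = findings %||% empty_findings(),
                      assignment = assignment),
                 class = "mrmc_bundle")
  if (validate) validate_bundle(b)
  b
}

#' @export
print.mrmc_bundle <- function(x, ...) {
  cat(sprintf(
    "MRMC study bundle: %d patients (%d cases), %d lesions, %d readers, %d findings\n",
    nrow(x$patients), sum(x$patients$disease_status == "case"),
    nrow(x$lesions), nrow(x$readers), nrow(x$findings)))
  if (!is.null(x$assignment))
    cat(sprintf("  assignment: common %d + %d pair blocks\n",
                length(x$assignment$common_subset),
                length(x$assignment$pair_blocks)))
  invisible(x)
}

#' Validate a study bundle
#'
#' Checks every schema and cross-table invariant: unique ids, legal factor
#' levels, scores in 1-5, the cap of 4 findings per (reader, patient,
#' session), lesion-free controls, exactly one index lesion per case with
#' lesions, and referential integrity of findings. Problems are collected
#' with their table and row number.
#'
#' @param bundle an [mrmc_bundle()] (or plain list with the same elements).
#' @param stop_on_error raise an error listing all problems (default); if
#'   `FALSE`, return them.
#' @return (invisibly) a data frame `table`, `row`, `problem`; zero rows when
#'   the bundle is valid.
#' @export
validate_bundle <- function(bundle, stop_on_error = TRUE) {
  probs <- list()
  add <- function(table, row, problem)
    probs[[length(probs) + 1L]] <<- data.frame(
      table = table, row = row, problem = problem, stringsAsFactors = FALSE)

  p <- bundle$patients
  if (anyDuplicated(p$patient_id))
    add("patients", which(duplicated(p$patient_id))[1], "duplicate patient_id")
  bad <- which(!p$disease_status %in% c("case", "control"))
  for (i in bad) add("patients", i, "disease_status must be 'case' or 'control'")

  l <- bundle$lesions
  if (nrow(l)) {
    if (anyDuplicated(l$lesion_id))
      add("lesions", which(duplicated(l$lesion_id))[1], "duplicate lesion_id")
    for (i in which(!l$zone %in% c(ZONES, "both")))
      add("lesions", i, "zone must be PZ, TZ or both")
    for (i in which(!l$side %in% SIDES)) add("lesions", i, "bad side")
    for (i in which(!l$level %in% LEVELS)) add("lesions", i, "bad level")
    for (i in which(!l$patient_id %in% p$patient_id))
      add("lesions", i, "unknown patient_id")
    for (i in which(!(l$gleason_primary %in% 3:5) |
                    !(l$gleason_secondary %in% 3:5)))
      add("lesions", i, "Gleason patterns must be integers 3-5")
    for (i in which(!is.finite(l$volume) | l$volume <= 0))
      add("lesions", i, "volume must be positive")
    status <- setNames(p$disease_status, p$patient_id)
    for (i in which(status[l$patient_id] == "control"))
      add("lesions", i, "control patients must have no lesions")
    n_index <- tapply(l$is_index, l$patient_id, sum)
    for (pid in names(n_index)[n_index != 1])
      add("lesions", which(l$patient_id == pid)[1],
          sprintf("patient %s has %d index lesions (need exactly 1)",
                  pid, n_index[[pid]]))
  }

  r <- bundle$readers
  if (nrow(r)) {
    if (anyDuplicated(r$reader_id))
      add("readers", which(duplicated(r$reader_id))[1], "duplicate reader_id")
    for (i in which(!r$experience %in% c("high", "moderate")))
      add("readers", i, "experience must be 'high' or 'moderate'")
  }

  f <- bundle$findings
  if (nrow(f)) {
    for (i in which(!f$session %in% SESSIONS))
      add("findings", i, "session must be MRI or CAD")
    for (i in which(!f$zone %in% ZONES)) add("findings", i, "zone must be PZ or TZ")
    for (i in which(!f$side %in% SIDES)) add("findings", i, "bad side")
    for (i in which(!f$level %in% LEVELS)) add("findings", i, "bad level")
    for (i in which(!(f$score %in% 1:5)))
      add("findings", i, "score must be an integer in 1-5")
    for (i in which(!f$patient_id %in% p$patient_id))
      add("findings", i, "unknown patient_id")
    if (nrow(r))
      for (i in which(!f$reader_id %in% r$reader_id))
        add("findings", i, "unknown reader_id")
    grp <- paste(f$reader_id, f$patient_id, f$session, sep = "\r")
    counts <- table(grp)
    for (g in names(counts)[counts > 4])
      add("findings", which(grp == g)[1],
          sprintf("%d findings for one (reader, patient, session); cap is 4",
                  counts[[g]]))
  }

  out <- if (length(probs)) do.call(rbind, probs)
         else data.frame(table = character(0), row = integer(0),
                         problem = character(0), stringsAsFactors = FALSE)
  if (nrow(out) && stop_on_error)
    stop("invalid bundle:\n",
         paste(sprintf("  [%s row %d] %s", out$table, out$row, out$problem),
               collapse = "\n"), call. = FALSE)
  invisible(out)
}

#' Read / write a study bundle as delimited text
#'
#' `write_tables()` writes `patients.csv`, `lesions.csv`, `readers.csv`,
#' `findings.csv` (and `assignment.csv` when present) to a directory;
#' `read_tables()` reads them back and validates. The round trip is lossless.
#'
#' @param dir directory containing / receiving the CSV files.
#' @param validate validate on read (default `TRUE`).
#' @return `read_tables()`: an [mrmc_bundle()]. `write_tables()`: the
#'   directory, invisibly.
#' @export
read_tables <- function(dir, validate = TRUE) {
  rd <- function(f, required = TRUE) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      if (required) stop_config("missing table: %s", path)
      return(NULL)
    }
    read.csv(path, stringsAsFactors = FALSE)
  }
  patients <- rd("patients.csv")
  if ("institution" %in% names(patients))
    patients$institution <- as.character(patients$institution)
  lesions <- rd("lesions.csv", required = FALSE)
  readers <- rd("readers.csv", required = FALSE)
  findings <- rd("findings.csv", required = FALSE)
  if (!is.null(lesions) && nrow(lesions))
    lesions$is_index <- as.logical(lesions$is_index)
  assignment <- NULL
  apath <- file.path(dir, "assignment.csv")
  if (file.exists(apath)) {
    adf <- read.csv(apath, stringsAsFactors = FALSE)
    assignment <- assignment_from_blocks(adf, readers$reader_id)
  }
  mrmc_bundle(patients, lesions, readers, findings, assignment,
              validate = validate)
}

#' @rdname read_tables
#' @param bundle an [mrmc_bundle()].
#' @export
write_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  wr(bundle$patients, "patients.csv")
  wr(bundle$lesions, "lesions.csv")
  wr(bundle$readers, "readers.csv")
  wr(bundle$findings, "findings.csv")
  if (!is.null(bundle$assignment))
    wr(bundle$assignment$blocks, "assignment.csv")
  invisible(dir)
}

# Rebuild an mrmc_assignment from its patient/block table.
assignment_from_blocks <- function(blocks, readers) {
  common <- blocks$patient_id[blocks$block == "common"]
  pair_names <- setdiff(unique(blocks$block), "common")
  pair_blocks <- lapply(setNames(pair_names, pair_names), function(nm)
    blocks$patient_id[blocks$block == nm])
  # loads can be recomputed, but case loads need patient status; leave to
  # callers that have it (allocate() remains the canonical constructor).
  loads <- setNames(rep(length(common), length(readers)), readers)
  for (nm in pair_names) {
    rs <- strsplit(nm, "+", fixed = TRUE)[[1]]
    loads[rs] <- loads[rs] + length(pair_blocks[[nm]])
  }
  structure(list(common_subset = common, pair_blocks = pair_blocks,
                 readers = readers, reader_loads = loads,
                 reader_case_loads = NULL,
                 blocks = blocks[, c("patient_id", "block")]),
            class = "mrmc_assignment")
}

#' Index lesion of a patient
#'
#' The index lesion is the tumour with the highest Gleason score and largest
#' volume: lesions are ordered lexicographically by Gleason total
#' (primary + secondary), then primary pattern (so 4+3 beats 3+4), then
#' volume. An exact tie on all three keys is an error unless exactly one of
#' the tied lesions carries an explicit `is_index` flag.
#'
#' @param lesions data frame of one patient's lesions (schema of
#'   [mrmc_bundle()]).
#' @return the single index-lesion row.
#' @export
index_lesion <- function(lesions) {
  if (!nrow(lesions)) stop_config("index_lesion: no lesions supplied")
  if (length(unique(lesions$patient_id)) > 1)
    stop_config("index_lesion expects lesions of a single patient")
  total <- lesions$gleason_primary + lesions$gleason_secondary
  o <- order(-total, -lesions$gleason_primary, -lesions$volume)
  top <- o[1]
  if (length(o) > 1) {
    nxt <- o[2]
    tie <- total[top] == total[nxt] &&
      lesions$gleason_primary[top] == lesions$gleason_primary[nxt] &&
      lesions$volume[top] == lesions$volume[nxt]
    if (tie) {
      tied <- which(total == total[top] &
                    lesions$gleason_primary == lesions$gleason_primary[top] &
                    lesions$volume == lesions$volume[top])
      flagged <- tied[which(lesions$is_index[tied])]
      if (length(flagged) == 1) return(lesions[flagged, , drop = FALSE])
      stop_config(paste("index_lesion: exact tie on (Gleason total, primary,",
                        "volume); set is_index explicitly on one lesion"))
    }
  }
  lesions[top, , drop = FALSE]
}

#' Match reader findings to ground-truth lesions
#'
#' A finding matches a lesion when all `match_keys` agree; a lesion spanning
#' both zones matches a finding tagged with either zone. Each finding is
#' assigned to at most one lesion: among its matching lesions the index
#' lesion wins, then descending Gleason (total, then primary), then
#' descending volume. When several findings land on one lesion the highest
#' score is kept. Findings matching no lesion are recorded as false
#' positives.
#'
#' @param findings validated findings data frame.
#' @param lesions ground-truth lesions data frame.
#' @param match_keys subset of `c("zone", "side", "level")`; default all
#'   three (the discrete sector key).
#' @param patients optional patients data frame; when given, findings that
#'   reference an unknown patient raise an integrity error.
#' @return object of class `mrmc_detection`: list with `matched`
#'   (`reader_id`, `session`, `patient_id`, `lesion_id`, `score` = highest
#'   matched score), `false_positives` (the unmatched finding rows) and
#'   `n_matched_findings` (so matched + unmatched findings = total).
#' @export
match_findings <- function(findings, lesions,
                           match_keys = c("zone", "side", "level"),
                           patients = NULL) {
  match_keys <- match.arg(match_keys, c("zone", "side", "level"),
                          several.ok = TRUE)
  if (!is.null(patients) && nrow(findings) &&
      any(!findings$patient_id %in% patients$patient_id))
    stop_config("findings reference unknown patients")
  if (!nrow(findings)) {
    return(structure(list(matched = data.frame(
      reader_id = character(0), session = character(0),
      patient_id = character(0), lesion_id = character(0),
      score = integer(0), stringsAsFactors = FALSE),
      false_positives = empty_findings(), match_keys = match_keys,
      n_findings = 0L, n_matched_findings = 0L), class = "mrmc_detection"))
  }
  # expand both-zone lesions into one row per zone tag
  if (nrow(lesions)) {
    both <- lesions$zone == "both"
    single <- lesions[!both, , drop = FALSE]
    single$zone_tag <- single$zone
    bz_pz <- lesions[both, , drop = FALSE]
    bz_pz$zone_tag <- rep("PZ", nrow(bz_pz))
    bz_tz <- lesions[both, , drop = FALSE]
    bz_tz$zone_tag <- rep("TZ", nrow(bz_tz))
    exp_les <- rbind(single, bz_pz, bz_tz)
    total <- exp_les$gleason_primary + exp_les$gleason_secondary
    # lesion priority: index first, then Gleason total, primary, volume
    exp_les$priority <- order(order(-exp_les$is_index, -total,
                                    -exp_les$gleason_primary,
                                    -exp_les$volume, exp_les$lesion_id))
  } else {
    exp_les <- empty_lesions()
    exp_les$zone_tag <- character(0)
    exp_les$priority <- integer(0)
  }
  fkey <- findings$patient_id
  lkey <- exp_les$patient_id
  for (k in match_keys) {
    fk <- if (k == "zone") findings$zone else findings[[k]]
    lk <- if (k == "zone") exp_les$zone_tag else exp_les[[k]]
    fkey <- paste(fkey, fk, sep = "|")
    lkey <- paste(lkey, lk, sep = "|")
  }
  findings$.fid <- seq_len(nrow(findings))
  hits <- merge(
    data.frame(.fid = findings$.fid, key = fkey, stringsAsFactors = FALSE),
    data.frame(key = lkey, lesion_id = exp_les$lesion_id,
               priority = exp_les$priority, stringsAsFactors = FALSE),
    by = "key")
  if (nrow(hits)) {
    hits <- hits[order(hits$.fid, hits$priority), ]
    hits <- hits[!duplicated(hits$.fid), ]  # best lesion per finding
  }
  assigned <- merge(findings, hits[, c(".fid", "lesion_id")], by = ".fid")
  matched <- if (nrow(assigned)) {
    agg <- aggregate(score ~ reader_id + session + patient_id + lesion_id,
                     data = assigned, FUN = max)
    agg[order(agg$reader_id, agg$session, agg$lesion_id), ]
  } else {
    data.frame(reader_id = character(0), session = character(0),
               patient_id = character(0), lesion_id = character(0),
               score = integer(0), stringsAsFactors = FALSE)
  }
  rownames(matched) <- NULL
  fp <- findings[!findings$.fid %in% hits$.fid, , drop = FALSE]
  fp$.fid <- NULL
  rownames(fp) <- NULL
  structure(list(matched = matched, false_positives = fp,
                 match_keys = match_keys, n_findings = nrow(findings),
                 n_matched_findings = nrow(assigned)),
            class = "mrmc_detection")
}

#' @export
print.mrmc_detection <- function(x, ...) {
  cat(sprintf(
    "Detection matrix: %d findings -> %d matched lesion hits + %d false positives (keys: %s)\n",
    x$n_findings, nrow(x$matched), nrow(x$false_positives),
    paste(x$match_keys, collapse = ", ")))
  invisible(x)
}
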
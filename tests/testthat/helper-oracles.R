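# Shared fixtures and independent brute-force oracles.

# O(n^2) Mann-Whitney AUC with half-credit for ties.
auc_pairwise <- function(scores, truth) {
  if (is.character(truth)) truth <- truth == "case"
  xs <- scores[truth]; ys <- scores[!truth]
  tot <- 0
  for (x in xs) for (y in ys)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(xs) * length(ys))
}

# Brute-force pooled ISA: explicit loops over ordered reader pairs and the
# patients both read, with plain set intersections.
isa_brute <- function(bundle, session, pairing = "overall",
                      include_controls = TRUE) {
  f <- bundle$findings[bundle$findings$session == session, , drop = FALSE]
  if (!include_controls) {
    status <- setNames(bundle$patients$disease_status,
                       bundle$patients$patient_id)
    f <- f[status[f$patient_id] == "case", , drop = FALSE]
  }
  exper <- setNames(bundle$readers$experience, bundle$readers$reader_id)
  asg <- bundle$assignment
  shared_by <- function(pid) {
    if (pid %in% asg$common_subset) return(asg$readers)
    for (nm in names(asg$pair_blocks))
      if (pid %in% asg$pair_blocks[[nm]])
        return(strsplit(nm, "+", fixed = TRUE)[[1]])
    character(0)
  }
  in_stratum <- function(i, j) switch(pairing,
    overall = TRUE,
    "high-high" = exper[[i]] == "high" && exper[[j]] == "high",
    "moderate-moderate" = exper[[i]] == "moderate" &&
      exper[[j]] == "moderate",
    "high-moderate" = exper[[i]] != exper[[j]])
  num <- 0; den <- 0
  for (pid in unique(bundle$patients$patient_id)) {
    rs <- shared_by(pid)
    for (i in rs) for (j in rs) {
      if (i == j || !in_stratum(i, j)) next
      li <- unique(with(f[f$reader_id == i & f$patient_id == pid, ],
                        paste(zone, side, level)))
      lj <- unique(with(f[f$reader_id == j & f$patient_id == pid, ],
                        paste(zone, side, level)))
      den <- den + length(li)
      num <- num + length(intersect(li, lj))
    }
  }
  if (den == 0) NaN else num / den
}

# Random small agreement configuration: <= 4 readers, <= 6 patients,
# <= 4 findings per reader-patient, hybrid-structured sharing.
random_isa_bundle <- function() {
  n_readers <- sample(2:4, 1)
  n_patients <- sample(2:6, 1)
  readers <- data.frame(
    reader_id = sprintf("R%02d", seq_len(n_readers)),
    experience = sample(c("high", "moderate"), n_readers, replace = TRUE),
    stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n_patients)),
    disease_status = sample(c("case", "control"), n_patients, replace = TRUE),
    stringsAsFactors = FALSE)
  pairs <- t(combn(readers$reader_id, 2))
  pair_names <- paste(pairs[, 1], pairs[, 2], sep = "+")
  block <- sample(c("common", pair_names), n_patients, replace = TRUE)
  blocks_df <- data.frame(patient_id = patients$patient_id, block = block,
                          stringsAsFactors = FALSE)
  asg <- structure(list(
    common_subset = patients$patient_id[block == "common"],
    pair_blocks = lapply(setNames(pair_names, pair_names), function(nm)
      patients$patient_id[block == nm]),
    readers = readers$reader_id, reader_loads = NULL,
    reader_case_loads = NULL, blocks = blocks_df),
    class = "mrmc_assignment")
  sectors <- expand.grid(zone = c("PZ", "TZ"), side = c("left", "right"),
                         level = c("apex", "mid", "base"),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(blocks_df))) {
    rs <- if (block[i] == "common") readers$reader_id
          else strsplit(block[i], "+", fixed = TRUE)[[1]]
    for (r in rs) for (s in c("MRI", "CAD")) {
      k <- sample(0:4, 1, prob = c(0.3, 0.3, 0.2, 0.1, 0.1))
      if (k == 0) next
      sec <- sectors[sample.int(12, k), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        reader_id = r, session = s, patient_id = patients$patient_id[i],
        zone = sec$zone, side = sec$side, level = sec$level,
        score = sample(1:5, k, replace = TRUE), stringsAsFactors = FALSE)
    }
  }
  findings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reader_id = character(0), session = character(0),
               patient_id = character(0), zone = character(0),
               side = character(0), level = character(0),
               score = integer(0), stringsAsFactors = FALSE)
  mrmc_bundle(patients, NULL, readers, findings, asg, validate = FALSE)
}

# Brute-force detection matrix: per finding, scan every lesion of the
# patient for key agreement and pick the best by the documented priority.
match_brute <- function(findings, lesions,
                        match_keys = c("zone", "side", "level")) {
  assigned_to <- character(nrow(findings))
  for (i in seq_len(nrow(findings))) {
    cand <- lesions[lesions$patient_id == findings$patient_id[i], ,
                    drop = FALSE]
    ok <- rep(TRUE, nrow(cand))
    for (k in match_keys) {
      if (k == "zone")
        ok <- ok & (cand$zone == findings$zone[i] | cand$zone == "both")
      else ok <- ok & cand[[k]] == findings[[k]][i]
    }
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) { assigned_to[i] <- NA_character_; next }
    tot <- cand$gleason_primary + cand$gleason_secondary
    o <- order(-cand$is_index, -tot, -cand$gleason_primary, -cand$volume,
               cand$lesion_id)
    assigned_to[i] <- cand$lesion_id[o[1]]
  }
  out <- list()
  hit <- !is.na(assigned_to)
  for (g in unique(paste(findings$reader_id, findings$session,
                         assigned_to)[hit])) {
    sel <- hit & paste(findings$reader_id, findings$session,
                       assigned_to) == g
    out[[g]] <- data.frame(
      reader_id = findings$reader_id[sel][1],
      session = findings$session[sel][1],
      lesion_id = assigned_to[sel][1],
      score = max(findings$score[sel]), stringsAsFactors = FALSE)
  }
  list(matched = if (length(out)) do.call(rbind, out) else NULL,
       n_fp = sum(!hit))
}

# Minimal hand-built two-reader bundle for matching / performance tests.
tiny_bundle <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    disease_status = c("case", "case", "control"),
    stringsAsFactors = FALSE)
  lesions <- data.frame(
    lesion_id = c("A-L1", "A-L2", "B-L1"),
    patient_id = c("A", "A", "B"),
    zone = c("PZ", "TZ", "both"),
    side = c("left", "right", "left"),
    level = c("mid", "base", "apex"),
    gleason_primary = c(4L, 3L, 3L),
    gleason_secondary = c(5L, 4L, 3L),
    volume = c(0.5, 3, 1),
    is_index = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  readers <- data.frame(reader_id = c("R01", "R02"),
                        experience = c("high", "moderate"),
                        stringsAsFactors = FALSE)
  asg <- structure(list(
    common_subset = c("A", "B", "C"),
    pair_blocks = setNames(list(character(0)), "R01+R02"),
    readers = c("R01", "R02"), reader_loads = c(R01 = 3, R02 = 3),
    reader_case_loads = c(R01 = 2, R02 = 2),
    blocks = data.frame(patient_id = c("A", "B", "C"), block = "common",
                        stringsAsFactors = FALSE)),
    class = "mrmc_assignment")
  findings <- data.frame(
    reader_id = c("R01", "R01", "R01", "R02", "R02"),
    session = "MRI",
    patient_id = c("A", "A", "C", "A", "B"),
    zone = c("PZ", "PZ", "TZ", "TZ", "TZ"),
    side = c("left", "left", "left", "right", "left"),
    level = c("mid", "mid", "mid", "base", "apex"),
    score = c(3L, 5L, 2L, 4L, 4L), stringsAsFactors = FALSE)
  mrmc_bundle(patients, lesions, readers, findings, asg)
}
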
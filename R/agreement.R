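#' Index of specific agreement (ISA) for lesion detection
#'
#' ISA is the conditional probability that an independent reader reports a
#' finding at the same sector location as a randomly selected reader. Over
#' all ordered reader pairs (i, j) in the pairing stratum and every patient
#' both read, the denominator accumulates the number of distinct locations
#' reader i reported and the numerator the number of those also reported by
#' reader j (same zone/side/level key, any score); counts are pooled before
#' the ratio. For two raters on one patient this reduces to the positive
#' specific agreement 2a / (2a + b + c). Findings on control patients count
#' by default (agreement on false positives is still agreement on
#' detection).
#'
#' @param bundle an [mrmc_bundle()] with findings, readers and assignment.
#' @param session `"MRI"` or `"CAD"`.
#' @param pairing reader-experience pairing stratum: `"overall"`,
#'   `"high-high"`, `"moderate-moderate"` or `"high-moderate"` (the latter
#'   counts ordered pairs in both directions).
#' @param include_controls count findings on control patients (default
#'   `TRUE`).
#' @param average `"pooled"` (counts pooled over pairs and patients before
#'   the ratio, default) or `"pairwise"` (unweighted mean of per-ordered-pair
#'   ratios over pairs with nonzero denominator).
#' @return object of class `mrmc_isa`: list `isa`, `numerator`,
#'   `denominator`, `stratum`, `session`, `undefined` (`TRUE` when the
#'   denominator is 0, in which case `isa` is `NaN`).
#' @export
isa <- function(bundle, session, pairing = "overall",
                include_controls = TRUE, average = c("pooled", "pairwise")) {
  average <- match.arg(average)
  session <- match.arg(session, SESSIONS)
  pairing <- match.arg(pairing, c("overall", "high-high",
                                  "moderate-moderate", "high-moderate"))
  stopifnot(!is.null(bundle$assignment))
  f <- bundle$findings[bundle$findings$session == session, , drop = FALSE]
  if (!include_controls) {
    status <- setNames(bundle$patients$disease_status,
                       bundle$patients$patient_id)
    f <- f[status[f$patient_id] == "case", , drop = FALSE]
  }
  locs <- unique(data.frame(
    reader_id = f$reader_id, patient_id = f$patient_id,
    key = sector_key(f$zone, f$side, f$level), stringsAsFactors = FALSE))

  exper <- setNames(bundle$readers$experience, bundle$readers$reader_id)
  pair_ok <- function(ei, ej) switch(pairing,
    overall = TRUE,
    "high-high" = ei == "high" && ej == "high",
    "moderate-moderate" = ei == "moderate" && ej == "moderate",
    "high-moderate" = ei != ej)

  sharing <- sharing_readers(bundle$assignment)
  num <- 0; den <- 0
  pair_num <- list(); pair_den <- list()
  loc_by_rp <- split(locs$key, paste(locs$reader_id, locs$patient_id,
                                     sep = "\r"))
  for (pid in names(sharing)) {
    rs <- sharing[[pid]]
    if (length(rs) < 2) next
    keys <- lapply(rs, function(r) loc_by_rp[[paste(r, pid, sep = "\r")]])
    names(keys) <- rs
    for (i in rs) for (j in rs) {
      if (i == j || !pair_ok(exper[[i]], exper[[j]])) next
      ni <- length(keys[[i]])
      nij <- length(intersect(keys[[i]], keys[[j]]))
      num <- num + nij; den <- den + ni
      pk <- paste(i, j, sep = "\r")
      pair_num[[pk]] <- (pair_num[[pk]] %||% 0) + nij
      pair_den[[pk]] <- (pair_den[[pk]] %||% 0) + ni
    }
  }
  est <- if (average == "pooled") {
    if (den > 0) num / den else NaN
  } else {
    pd <- unlist(pair_den); pn <- unlist(pair_num)[names(pd)]
    ok <- pd > 0
    if (any(ok)) mean(pn[ok] / pd[ok]) else NaN
  }
  structure(list(isa = est, numerator = num, denominator = den,
                 stratum = pairing, session = session,
                 undefined = den == 0),
            class = "mrmc_isa")
}

#' @export
print.mrmc_isa <- function(x, ...) {
  cat(sprintf("ISA (%s, %s): %.4f (%d / %d co-detections)%s\n",
              x$session, x$stratum, x$isa, x$numerator, x$denominator,
              if (x$undefined) " [undefined: zero denominator]" else ""))
  invisible(x)
}

# Which readers share each patient, from the assignment structure.
sharing_readers <- function(assignment) {
  out <- list()
  for (pid in assignment$common_subset) out[[pid]] <- assignment$readers
  for (nm in names(assignment$pair_blocks)) {
    rs <- strsplit(nm, "+", fixed = TRUE)[[1]]
    for (pid in assignment$pair_blocks[[nm]]) out[[pid]] <- rs
  }
  out
}

#' Pooled ISA for every pairing stratum and session in one pass
#'
#' Computation equivalent to [isa()] with `average = "pooled"`, vectorised
#' through per-(patient, location) reader-class counts so that bootstrap
#' replication stays fast: for a location reported by `dH` high- and `dM`
#' moderate-experience readers among the readers sharing that patient, the
#' ordered co-detection counts are `(dH+dM)(dH+dM-1)` overall, `dH(dH-1)` and
#' `dM(dM-1)` within class, and `2 dH dM` across classes; denominators follow
#' from each reader's location count times the number of stratum partners.
#'
#' @inheritParams isa
#' @return named numeric vector `"<stratum>.<session>"` of pooled ISA values
#'   (NaN where the denominator is zero).
#' @export
isa_all <- function(bundle, include_controls = TRUE) {
  stopifnot(!is.null(bundle$assignment))
  exper <- setNames(bundle$readers$experience, bundle$readers$reader_id)
  sharing <- sharing_readers(bundle$assignment)
  # per-patient counts of sharing readers by class
  cH <- vapply(sharing, function(rs) sum(exper[rs] == "high"), numeric(1))
  cM <- vapply(sharing, function(rs) sum(exper[rs] == "moderate"), numeric(1))
  strata <- c("overall", "high-high", "moderate-moderate", "high-moderate")
  out <- setNames(rep(NaN, 8),
                  as.vector(outer(strata, SESSIONS, paste, sep = ".")))
  f_all <- bundle$findings
  if (!include_controls) {
    status <- setNames(bundle$patients$disease_status,
                       bundle$patients$patient_id)
    f_all <- f_all[status[f_all$patient_id] == "case", , drop = FALSE]
  }
  for (s in SESSIONS) {
    f <- f_all[f_all$session == s & f_all$patient_id %in% names(sharing), ,
               drop = FALSE]
    locs <- unique(data.frame(
      reader_id = f$reader_id, patient_id = f$patient_id,
      key = sector_key(f$zone, f$side, f$level), stringsAsFactors = FALSE))
    hi <- exper[locs$reader_id] == "high"
    pk <- paste(locs$patient_id, locs$key, sep = "\r")
    dH <- tapply(hi, pk, sum); dM <- tapply(!hi, pk, sum)
    num <- c(overall = sum((dH + dM) * (dH + dM - 1)),
             "high-high" = sum(dH * (dH - 1)),
             "moderate-moderate" = sum(dM * (dM - 1)),
             "high-moderate" = sum(2 * dH * dM))
    # denominator: reader i's location count x number of stratum partners
    rp <- paste(locs$reader_id, locs$patient_id, sep = "\r")
    ni <- tapply(rep(1, nrow(locs)), rp, sum)
    parts <- strsplit(names(ni), "\r", fixed = TRUE)
    r_i <- vapply(parts, `[`, "", 1L)
    p_i <- vapply(parts, `[`, "", 2L)
    hi_i <- exper[r_i] == "high"
    chp <- cH[p_i]; cmp <- cM[p_i]
    den <- c(overall = sum(ni * (chp + cmp - 1)),
             "high-high" = sum(ni[hi_i] * (chp[hi_i] - 1)),
             "moderate-moderate" = sum(ni[!hi_i] * (cmp[!hi_i] - 1)),
             "high-moderate" = sum(ni * ifelse(hi_i, cmp, chp)))
    for (st in strata)
      out[paste(st, s, sep = ".")] <-
        if (den[[st]] > 0) num[[st]] / den[[st]] else NaN
  }
  out
}

#' Session comparison of inter-reader agreement
#'
#' ISA per pairing stratum in both sessions, with stratified-bootstrap
#' percentile intervals and the Wald test of the session difference from the
#' paired replicate differences — the shape of an inter-reader agreement
#' table (one row per experience pairing).
#'
#' @param bundle an [mrmc_bundle()] with both sessions' findings.
#' @param b,seed,conf as in [stratified_bootstrap()].
#' @param include_controls see [isa()].
#' @return data frame with one row per pairing stratum: ISA estimates and
#'   CIs for MRI and CAD, the difference, and z / p.
#' @export
isa_compare <- function(bundle, b = 2000, seed = NULL, conf = 0.95,
                        include_controls = TRUE) {
  strata <- c("overall", "high-high", "moderate-moderate", "high-moderate")
  stat <- function(bd) isa_all(bd, include_controls = include_controls)
  bt <- stratified_bootstrap(bundle, stat, b = b, seed = seed, conf = conf)
  rows <- lapply(strata, function(st) {
    m <- paste(st, "MRI", sep = "."); cdd <- paste(st, "CAD", sep = ".")
    dreps <- bt$replicates[, cdd] - bt$replicates[, m]
    dobs <- bt$estimate[[cdd]] - bt$estimate[[m]]
    wt <- wald_diff_test(dreps, dobs)
    data.frame(
      pairing = st,
      isa_mri = bt$estimate[[m]], mri_low = bt$ci_low[[m]],
      mri_high = bt$ci_high[[m]],
      isa_cad = bt$estimate[[cdd]], cad_low = bt$ci_low[[cdd]],
      cad_high = bt$ci_high[[cdd]],
      diff = dobs, z = wt$z, p = wt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
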
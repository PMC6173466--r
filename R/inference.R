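#' Resample a bundle stratified by disease status
#'
#' Draws case patients with replacement within the case stratum and control
#' patients within the control stratum, carrying each drawn patient's full
#' record: lesions and every reader's findings in both sessions are
#' duplicated per draw, and the patient's assignment block membership is
#' inherited. Replicate patient ids are suffixed `#<copy>` to stay unique.
#' Readers are never resampled.
#'
#' @param bundle an [mrmc_bundle()].
#' @return a bundle-shaped list (not re-validated, for speed).
#' @keywords internal
resample_bundle <- function(bundle) {
  p <- bundle$patients
  draw <- unlist(lapply(c("case", "control"), function(st) {
    ids <- p$patient_id[p$disease_status == st]
    if (!length(ids)) character(0)
    else ids[sample.int(length(ids), length(ids), replace = TRUE)]
  }), use.names = FALSE)
  copy <- ave(seq_along(draw), draw, FUN = seq_along)
  new_id <- paste0(draw, "#", copy)

  take <- function(df, id_col = "patient_id") {
    if (is.null(df) || !nrow(df)) return(df)
    idx <- split(seq_len(nrow(df)), df[[id_col]])
    rows <- idx[draw]
    reps <- lengths(rows)
    out <- df[unlist(rows, use.names = FALSE), , drop = FALSE]
    out[[id_col]] <- rep(new_id, reps)
    rownames(out) <- NULL
    out
  }
  patients <- p[match(draw, p$patient_id), , drop = FALSE]
  patients$patient_id <- new_id
  rownames(patients) <- NULL
  lesions <- take(bundle$lesions)
  if (!is.null(lesions) && nrow(lesions)) {
    lesions$lesion_id <- paste0(lesions$lesion_id, "#",
                                sub("^.*#", "", lesions$patient_id))
  }
  findings <- take(bundle$findings)
  assignment <- bundle$assignment
  if (!is.null(assignment)) {
    blk <- setNames(assignment$blocks$block, assignment$blocks$patient_id)
    new_blocks <- blk[draw]
    common <- new_id[new_blocks == "common"]
    pair_blocks <- lapply(assignment$pair_blocks, function(x) character(0))
    for (nm in names(pair_blocks))
      pair_blocks[[nm]] <- new_id[new_blocks == nm]
    assignment <- structure(
      list(common_subset = common, pair_blocks = pair_blocks,
           readers = assignment$readers,
           reader_loads = NULL, reader_case_loads = NULL,
           blocks = data.frame(patient_id = new_id, block = new_blocks,
                               stringsAsFactors = FALSE)),
      class = "mrmc_assignment")
  }
  structure(list(patients = patients, lesions = lesions,
                 readers = bundle$readers, findings = findings,
                 assignment = assignment), class = "mrmc_bundle")
}

#' Disease-status-stratified bootstrap
#'
#' Percentile bootstrap for any statistic of a study bundle. Each replicate
#' resamples patients with replacement within the case and control strata
#' (never across, and readers are never resampled), carrying the full
#' patient record so that paired session statistics are computed on
#' identical resampled patient multisets. Confidence limits are the 2.5th
#' and 97.5th empirical percentiles of the replicates (R's default type-7
#' quantile interpolation).
#'
#' @param bundle an [mrmc_bundle()].
#' @param statistic function of a bundle returning a numeric scalar or named
#'   vector.
#' @param b number of bootstrap replicates (default 2000; must be >= 2).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `mrmc_boot`: `estimate`, `ci_low`, `ci_high`,
#'   `se` (SD of replicates), `replicates` (b x k matrix), `n_failed`
#'   (replicates whose statistic errored or returned non-finite values;
#'   excluded with a warning), `b`, `seed`.
#' @export
stratified_bootstrap <- function(bundle, statistic, b = 2000, seed = NULL,
                                 conf = 0.95) {
  if (b < 2) stop_config("b must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  est <- statistic(bundle)
  k <- length(est)
  reps <- matrix(NA_real_, nrow = b, ncol = k,
                 dimnames = list(NULL, names(est)))
  for (i in seq_len(b)) {
    val <- tryCatch(statistic(resample_bundle(bundle)),
                    error = function(e) rep(NA_real_, k))
    if (length(val) == k) reps[i, ] <- as.numeric(val)
  }
  ok <- apply(reps, 1L, function(x) all(is.finite(x)))
  n_failed <- sum(!ok)
  if (n_failed > 0)
    warning(sprintf("%d of %d bootstrap replicates failed and were excluded",
                    n_failed, b))
  good <- reps[ok, , drop = FALSE]
  a <- (1 - conf) / 2
  ci <- apply(good, 2L, quantile, probs = c(a, 1 - a), names = FALSE,
              type = 7)
  structure(list(estimate = est,
                 ci_low = setNames(ci[1, ], names(est)),
                 ci_high = setNames(ci[2, ], names(est)),
                 se = apply(good, 2L, sd),
                 replicates = reps, n_failed = n_failed, b = b,
                 conf = conf, seed = seed),
            class = "mrmc_boot")
}

#' @export
print.mrmc_boot <- function(x, ...) {
  cat(sprintf("Stratified bootstrap (%d replicates%s)\n", x$b,
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  for (j in seq_along(x$estimate))
    cat(sprintf("  %s: %.4f  [%.4f, %.4f]  se %.4f\n",
                names(x$estimate)[j] %||% sprintf("stat%d", j),
                x$estimate[j], x$ci_low[j], x$ci_high[j], x$se[j]))
  invisible(x)
}

#' Wald test from paired bootstrap replicates
#'
#' z = observed difference / SD of the per-replicate differences, with a
#' two-sided normal p-value. The replicate differences must come from paired
#' resampling (both sessions evaluated on the same resampled patients within
#' each replicate).
#'
#' @param paired_replicates numeric vector of per-replicate differences.
#' @param observed_diff the observed difference on the original bundle.
#' @return list `z`, `p`, `se`, `flagged` (`TRUE` when the bootstrap SE is
#'   zero or fewer than 2 replicates are available; then `z`/`p` are `NA`
#'   and no division is performed).
#' @export
wald_diff_test <- function(paired_replicates, observed_diff) {
  reps <- paired_replicates[is.finite(paired_replicates)]
  se <- if (length(reps) >= 2) sd(reps) else NA_real_
  if (!is.finite(se) || se == 0)
    return(list(z = NA_real_, p = NA_real_, se = se, flagged = TRUE))
  z <- observed_diff / se
  list(z = z, p = 2 * (1 - pnorm(abs(z))), se = se, flagged = FALSE)
}

#' Bootstrap comparison of a statistic between sessions
#'
#' Computes a per-session statistic, its stratified-bootstrap percentile
#' intervals and the Wald test of the session difference with the bootstrap
#' standard error of the paired replicate differences.
#'
#' @param bundle an [mrmc_bundle()].
#' @param statistic function `(bundle, session) -> numeric scalar`.
#' @param b,seed,conf as in [stratified_bootstrap()].
#' @return data frame with the two session estimates, their CIs, the
#'   difference (CAD - MRI), its CI, and z / p.
#' @export
compare_sessions <- function(bundle, statistic, b = 2000, seed = NULL,
                             conf = 0.95) {
  stat2 <- function(bd) {
    v <- c(MRI = statistic(bd, "MRI"), CAD = statistic(bd, "CAD"))
    c(v, diff = unname(v["CAD"] - v["MRI"]))
  }
  bt <- stratified_bootstrap(bundle, stat2, b = b, seed = seed, conf = conf)
  wt <- wald_diff_test(bt$replicates[, "diff"], bt$estimate[["diff"]])
  data.frame(
    mri = bt$estimate[["MRI"]], mri_low = bt$ci_low[["MRI"]],
    mri_high = bt$ci_high[["MRI"]],
    cad = bt$estimate[["CAD"]], cad_low = bt$ci_low[["CAD"]],
    cad_high = bt$ci_high[["CAD"]],
    diff = bt$estimate[["diff"]], diff_low = bt$ci_low[["diff"]],
    diff_high = bt$ci_high[["diff"]],
    z = wt$z, p = wt$p, stringsAsFactors = FALSE)
}
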
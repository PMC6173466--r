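#' Hybrid reader-case allocation
#'
#' Implements the hybrid multi-reader multi-case design: a randomly selected
#' common subset of patients (default one sixth) is read by every reader, and
#' each remaining patient is assigned at random to one of the
#' `choose(n_readers, 2)` reader pairs. Both the common-subset draw and the
#' pair assignment are stratified by disease status, so the common subset
#' preserves the cohort's case:control ratio (for 216 patients at 1/6:
#' 36 = 24 cases + 12 controls) and every reader sees cases and controls in
#' the cohort ratio. With the default balanced randomization the pair block
#' sizes within each stratum differ by at most one (the patients and the
#' residual blocks are both randomly permuted), which keeps individual reader
#' loads in a narrow band (75-78 for the 216-patient, 9-reader design);
#' `balance = FALSE` gives fully independent uniform pair draws instead. With
#' 144 cases, 72 controls and 9 readers the total number of interpretations
#' is 36 x 9 + 180 x 2 = 684 under either scheme, i.e. a mean reader load of
#' exactly 76, independent of the seed.
#'
#' @param patients data frame with columns `patient_id`, `disease_status`
#'   (or an `mrmc_cohort` / `mrmc_bundle`).
#' @param n_readers number of readers (>= 2); reader ids are taken from
#'   `reader_ids` if given, else `R01..R<n>`.
#' @param common_fraction fraction of patients in the common subset,
#'   strictly between 0 and 1.
#' @param seed integer seed for the randomization.
#' @param reader_ids optional character vector of reader ids.
#' @param balance balanced randomized pair assignment (default) versus
#'   independent uniform pair draws.
#' @return object of class `mrmc_assignment`: list with `common_subset`
#'   (patient ids), `pair_blocks` (named list, names `"Ra+Rb"`), `readers`,
#'   `reader_loads` and `reader_case_loads` (named integer vectors), and the
#'   patient-to-block lookup `blocks` (data frame `patient_id`, `block`).
#' @export
allocate <- function(patients, n_readers, common_fraction = 1 / 6,
                     seed = NULL, reader_ids = NULL, balance = TRUE) {
  if (inherits(patients, c("mrmc_cohort", "mrmc_bundle")))
    patients <- patients$patients
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "disease_status") %in% names(patients)))
  if (n_readers < 2) stop_config("n_readers must be >= 2")
  if (common_fraction <= 0 || common_fraction >= 1)
    stop_config("common_fraction must be in (0, 1)")
  n <- nrow(patients)
  if (round(common_fraction * n) < 1)
    stop_config("common subset would be empty (fraction %g of %d patients)",
                common_fraction, n)
  readers <- reader_ids %||% sprintf("R%02d", seq_len(n_readers))
  stopifnot(length(readers) == n_readers)
  if (!is.null(seed)) set.seed(seed)

  pairs <- t(utils::combn(readers, 2))
  pair_names <- paste(pairs[, 1], pairs[, 2], sep = "+")

  common <- character(0)
  blocks <- setNames(vector("list", length(pair_names)), pair_names)
  for (status in unique(patients$disease_status)) {
    ids <- patients$patient_id[patients$disease_status == status]
    n_common <- round(common_fraction * length(ids))
    take <- sample(ids, n_common)
    common <- c(common, take)
    rest <- setdiff(ids, take)
    n_pairs <- length(pair_names)
    which_pair <- if (balance) {
      # block sizes within the stratum differ by at most one; both the
      # patient order and the placement of the larger blocks are random
      base <- length(rest) %/% n_pairs
      sizes <- rep(base, n_pairs)
      extra <- length(rest) %% n_pairs
      if (extra > 0) sizes[sample.int(n_pairs, extra)] <- base + 1L
      v <- rep(seq_len(n_pairs), times = sizes)
      v[sample.int(length(v))]
    } else {
      sample.int(n_pairs, length(rest), replace = TRUE)
    }
    for (k in seq_len(n_pairs))
      blocks[[k]] <- c(blocks[[k]], rest[which_pair == k])
  }

  is_case <- setNames(patients$disease_status == "case", patients$patient_id)
  loads <- setNames(rep(length(common), n_readers), readers)
  case_loads <- setNames(rep(sum(is_case[common]), n_readers), readers)
  for (k in seq_along(pair_names)) {
    for (r in pairs[k, ]) {
      loads[r] <- loads[r] + length(blocks[[k]])
      case_loads[r] <- case_loads[r] + sum(is_case[blocks[[k]]])
    }
  }
  block_df <- rbind(
    data.frame(patient_id = common, block = "common",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(pair_names, function(nm)
      if (length(blocks[[nm]]))
        data.frame(patient_id = blocks[[nm]], block = nm,
                   stringsAsFactors = FALSE)
      else NULL)))
  rownames(block_df) <- NULL
  structure(list(common_subset = common, pair_blocks = blocks,
                 readers = readers, reader_loads = loads,
                 reader_case_loads = case_loads, blocks = block_df),
            class = "mrmc_assignment")
}

#' @export
print.mrmc_assignment <- function(x, ...) {
  cat(sprintf("Hybrid MRMC assignment: %d patients, %d readers\n",
              nrow(x$blocks), length(x$readers)))
  cat(sprintf("  common subset: %d; pair blocks: %d (sizes %s)\n",
              length(x$common_subset), length(x$pair_blocks),
              paste(range(lengths(x$pair_blocks)), collapse = "-")))
  cat(sprintf("  reader load: mean %.4g, range %d-%d\n",
              mean(x$reader_loads), min(x$reader_loads), max(x$reader_loads)))
  invisible(x)
}

#' Which readers read a given patient
#'
#' @param assignment an [allocate()] result.
#' @return data frame `reader_id`, `patient_id` with one row per
#'   interpretation (per session).
#' @export
assignment_readings <- function(assignment) {
  stopifnot(inherits(assignment, "mrmc_assignment"))
  out <- list()
  if (length(assignment$common_subset))
    out[[1]] <- expand.grid(reader_id = assignment$readers,
                            patient_id = assignment$common_subset,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (nm in names(assignment$pair_blocks)) {
    ids <- assignment$pair_blocks[[nm]]
    if (!length(ids)) next
    rs <- strsplit(nm, "+", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <-
      expand.grid(reader_id = rs, patient_id = ids,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Power specification for the sensitivity-difference endpoint
#'
#' @param p1 baseline (first-session) index-lesion sensitivity.
#' @param delta targeted improvement in sensitivity.
#' @param alpha two-sided significance level.
#' @param n_case,n_control,n_readers design sizes.
#' @param common_fraction common-subset fraction of the hybrid design.
#' @return object of class `power_spec`.
#' @export
power_spec <- function(p1 = 0.76, delta = 0.10, alpha = 0.05,
                       n_case = 144, n_control = 72, n_readers = 9,
                       common_fraction = 1 / 6) {
  if (p1 <= 0 || p1 >= 1) stop_config("p1 must be in (0, 1)")
  if (p1 + delta <= 0 || p1 + delta > 1)
    stop_config("p1 + delta must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  structure(list(p1 = p1, delta = delta, alpha = alpha,
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_readers = as.integer(n_readers),
                 common_fraction = common_fraction),
            class = "power_spec")
}

design_patients <- function(spec) {
  data.frame(
    patient_id = sprintf("P%04d", seq_len(spec$n_case + spec$n_control)),
    disease_status = rep(c("case", "control"),
                         c(spec$n_case, spec$n_control)),
    stringsAsFactors = FALSE)
}

#' Analytic power of the Z test for the sensitivity difference
#'
#' Power to detect an improvement `delta` over baseline sensitivity `p1` in
#' the average reader-specific index-lesion sensitivity, using a two-sided Z
#' test. The endpoint variance uses independent binomial variation at `p1` and
#' `p1 + delta` over each reader's case readings under the assignment,
#' averaged over readers; correlation between readers induced by shared
#' patients, and within-patient correlation across sessions, are ignored
#' (use [power_sim()] to quantify the gap). At `delta = 0` the returned value
#' is the type-I error `alpha`.
#'
#' @param spec a [power_spec()].
#' @param assignment optional [allocate()] result supplying the realised
#'   per-reader case loads; by default a fresh allocation under `spec` is
#'   drawn (the load *total* is seed-invariant).
#' @return power in \[0, 1\], with attribute `"sd"` (endpoint SD).
#' @export
power_z <- function(spec, assignment = NULL) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(assignment))
    assignment <- allocate(design_patients(spec), spec$n_readers,
                           spec$common_fraction, seed = 1L)
  m <- assignment$reader_case_loads
  p1 <- spec$p1; p2 <- spec$p1 + spec$delta
  var_d <- sum((p1 * (1 - p1) + p2 * (1 - p2)) / m) / length(m)^2
  sdd <- sqrt(var_d)
  z <- qnorm(1 - spec$alpha / 2)
  pw <- pnorm(abs(spec$delta) / sdd - z) + pnorm(-abs(spec$delta) / sdd - z)
  structure(pw, sd = sdd)
}

#' Simulated power of the hybrid design
#'
#' Simulates `n_rep` complete studies: draw a hybrid allocation, generate each
#' reader's index-lesion detections on their case readings as independent
#' Bernoulli trials with sensitivity `p1` (session 1) and `p1 + delta`
#' (session 2), form the endpoint (difference in average reader-specific
#' sensitivity) and test it with a Z statistic using the plug-in binomial
#' standard error. Returns the rejection fraction and its binomial Monte-Carlo
#' error.
#'
#' @param spec a [power_spec()].
#' @param n_rep number of simulated studies (>= 100).
#' @param seed integer seed.
#' @param reallocate draw a fresh allocation for every replicate (default);
#'   otherwise one allocation is reused.
#' @return list `power`, `mc_error`, `n_rep`.
#' @export
power_sim <- function(spec, n_rep = 2000, seed = NULL, reallocate = TRUE) {
  stopifnot(inherits(spec, "power_spec"))
  if (n_rep < 100) stop_config("n_rep must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  patients <- design_patients(spec)
  p1 <- spec$p1; p2 <- spec$p1 + spec$delta
  zcrit <- qnorm(1 - spec$alpha / 2)
  asg <- allocate(patients, spec$n_readers, spec$common_fraction)
  reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    if (reallocate)
      asg <- allocate(patients, spec$n_readers, spec$common_fraction)
    m <- asg$reader_case_loads
    s1 <- rbinom(length(m), m, p1) / m
    s2 <- rbinom(length(m), m, p2) / m
    d <- mean(s2 - s1)
    se <- sqrt(sum((s1 * (1 - s1) + s2 * (1 - s2)) / m) / length(m)^2)
    reject[i] <- if (se == 0) d != 0 else abs(d / se) > zcrit
  }
  p <- mean(reject)
  list(power = p, mc_error = sqrt(p * (1 - p) / n_rep), n_rep = n_rep)
}
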
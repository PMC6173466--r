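#' Restrict a bundle to a subset of patients
#'
#' Keeps the given patients and their lesions and findings; the assignment's
#' blocks are filtered accordingly.
#'
#' @param bundle an [mrmc_bundle()].
#' @param patient_ids character vector of patient ids to keep.
#' @return the filtered bundle.
#' @export
subset_bundle <- function(bundle, patient_ids) {
  keep <- bundle$patients$patient_id %in% patient_ids
  asg <- bundle$assignment
  if (!is.null(asg)) {
    asg$common_subset <- intersect(asg$common_subset, patient_ids)
    asg$pair_blocks <- lapply(asg$pair_blocks, intersect, patient_ids)
    asg$blocks <- asg$blocks[asg$blocks$patient_id %in% patient_ids, ,
                             drop = FALSE]
  }
  structure(list(
    patients = bundle$patients[keep, , drop = FALSE],
    lesions = bundle$lesions[bundle$lesions$patient_id %in% patient_ids, ,
                             drop = FALSE],
    readers = bundle$readers,
    findings = bundle$findings[bundle$findings$patient_id %in% patient_ids, ,
                               drop = FALSE],
    assignment = asg), class = "mrmc_bundle")
}

#' Configuration for a full study run
#'
#' @param sim a [sim_config()].
#' @param power a [power_spec()] (or `NULL` to skip the power stage).
#' @param thresholds PI-RADSv2 thresholds for the performance tables.
#' @param b bootstrap replicates for the comparison stages.
#' @param seed master seed; per-stage seeds are derived from it with the
#'   documented counter scheme (`stage_seed`).
#' @param common_fraction common-subset fraction of the hybrid design.
#' @param out_dir output directory for [run_study()].
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), power = power_spec(),
                       thresholds = 1:5, b = 2000, seed = 1L,
                       common_fraction = 1 / 6, out_dir = "mrmc-run") {
  structure(list(sim = sim, power = power, thresholds = thresholds,
                 b = as.integer(b), seed = as.integer(seed),
                 common_fraction = common_fraction, out_dir = out_dir),
            class = "run_config")
}

run_config_yaml <- function(config) {
  cfg <- list(
    seed = config$seed, b = config$b, thresholds = config$thresholds,
    common_fraction = config$common_fraction,
    sim = lapply(unclass(config$sim), function(x)
      if (is.array(x)) as.vector(x) else x),
    power = if (!is.null(config$power)) unclass(config$power))
  yaml::as.yaml(cfg)
}

#' Run the complete reader-study pipeline
#'
#' simulate -> allocate -> read -> analyze -> compare -> report, end-to-end
#' deterministic under the master seed. Writes the four study tables plus the
#' assignment, patient-level and lesion-level performance tables, per-session
#' AUCs with bootstrap comparison, the inter-reader agreement table, an
#' allocation summary, analytic and simulated power, and a provenance log
#' (seeds, package version, config hash) to `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the bundle and every report table.
#' @export
run_study <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage 1-3: simulate cohort, allocate, simulate readings")
  bundle <- simulate_study(config$sim, seed = config$seed,
                           common_fraction = config$common_fraction)
  write_tables(bundle, config$out_dir)

  asg <- bundle$assignment
  alloc_summary <- data.frame(
    n_patients = nrow(bundle$patients),
    n_readers = length(asg$readers),
    common_size = length(asg$common_subset),
    total_interpretations = sum(asg$reader_loads),
    mean_load = mean(asg$reader_loads),
    min_load = min(asg$reader_loads), max_load = max(asg$reader_loads),
    case_control_interpretation_ratio =
      sum(asg$reader_case_loads) /
      (sum(asg$reader_loads) - sum(asg$reader_case_loads)))

  say("stage 4: performance tables")
  perf <- performance_report(bundle, thresholds = config$thresholds)

  say("stage 5: bootstrap comparisons (b = %d)", config$b)
  auc_cmp <- compare_sessions(
    bundle,
    function(bd, s) {
      sc <- patient_max_score(bd$findings, bd$assignment, s)
      status <- setNames(bd$patients$disease_status, bd$patients$patient_id)
      empirical_auc(sc$score, status[sc$patient_id])$auc
    },
    b = config$b, seed = stage_seed(config$seed, 4L))
  agreement <- isa_compare(bundle, b = config$b,
                           seed = stage_seed(config$seed, 5L))

  power_tab <- NULL
  if (!is.null(config$power)) {
    say("stage 6: power")
    pz <- power_z(config$power)
    ps <- power_sim(config$power, n_rep = 2000,
                    seed = stage_seed(config$seed, 6L))
    power_tab <- data.frame(method = c("analytic_z", "simulation"),
                            power = c(as.numeric(pz), ps$power),
                            mc_error = c(NA_real_, ps$mc_error))
  }

  wr <- function(df, f) write.csv(df, file.path(config$out_dir, f),
                                  row.names = FALSE)
  wr(alloc_summary, "allocation_summary.csv")
  wr(perf$patient_level, "performance_patient.csv")
  wr(perf$lesion_level, "performance_lesion.csv")
  wr(perf$auc, "auc.csv")
  wr(auc_cmp, "auc_comparison.csv")
  wr(agreement, "agreement.csv")
  if (!is.null(power_tab)) wr(power_tab, "power.csv")

  cfg_yaml <- run_config_yaml(config)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  writeLines(cfg_yaml, cfg_path)
  provenance <- c(
    sprintf("package: promrmc %s",
            as.character(utils::packageVersion("promrmc"))),
    sprintf("master_seed: %d", config$seed),
    sprintf("stage_seeds: cohort=%d allocate=%d readings=%d auc_boot=%d isa_boot=%d power=%d",
            stage_seed(config$seed, 1L), stage_seed(config$seed, 2L),
            stage_seed(config$seed, 3L), stage_seed(config$seed, 4L),
            stage_seed(config$seed, 5L), stage_seed(config$seed, 6L)),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("bootstrap_b: %d", config$b))
  writeLines(provenance, file.path(config$out_dir, "provenance.txt"))

  invisible(list(bundle = bundle, allocation_summary = alloc_summary,
                 performance = perf, auc_comparison = auc_cmp,
                 agreement = agreement, power = power_tab))
}
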
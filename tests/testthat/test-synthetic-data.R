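test_that("sim_config validates probabilities and distributions", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(zone_mix = c(PZ = 0.6, TZ = 0.5, both = 0.1)),
               "sum to 1")
  expect_error(sim_config(gleason_mix = c("3+4" = 1.2, "4+3" = -0.2)),
               "probabilities")
  expect_error(sim_config(lesions_per_case_mean = -1), "positive")
  expect_error(sim_config(lesions_per_case_mean = 0.5), ">= 1")
  expect_error(sim_config(fp_rate = -0.1), ">= 0")
})

test_that("zero-truncated Poisson mean inversion round-trips", {
  expect_identical(promrmc:::ztpois_lambda(1), 0)  # degenerate limit
  for (m in c(1.2, 1.98, 3.3, 10)) {
    lam <- promrmc:::ztpois_lambda(m)
    expect_equal(promrmc:::ztpois_mean(lam), m, tolerance = 1e-8)
  }
  expect_identical(promrmc:::rztpois(5, 0), rep(1L, 5))
  set.seed(1)
  x <- promrmc:::rztpois(20000, promrmc:::ztpois_lambda(1.98))
  expect_true(all(x >= 1))
  expect_equal(mean(x), 1.98, tolerance = 0.03)
})

test_that("generate_cohort honours exact counts and lesion rules", {
  cfg <- sim_config(n_case = 50, n_control = 30)
  ch <- generate_cohort(cfg, seed = 11)
  expect_identical(sum(ch$patients$disease_status == "case"), 50L)
  expect_identical(sum(ch$patients$disease_status == "control"), 30L)
  counts <- table(ch$lesions$patient_id)
  expect_true(all(counts >= 1))
  # every lesion belongs to a case; controls are lesion-free by definition
  status <- setNames(ch$patients$disease_status, ch$patients$patient_id)
  expect_true(all(status[ch$lesions$patient_id] == "case"))
  # exactly one index lesion per case, consistent with the index rule
  expect_true(all(tapply(ch$lesions$is_index, ch$lesions$patient_id, sum) == 1))
  for (pid in sample(unique(ch$lesions$patient_id), 10)) {
    les <- ch$lesions[ch$lesions$patient_id == pid, ]
    expect_identical(index_lesion(les)$lesion_id,
                     les$lesion_id[les$is_index])
  }
  # locations within a patient never collide on the sector grid
  for (pid in unique(ch$lesions$patient_id)) {
    les <- ch$lesions[ch$lesions$patient_id == pid, ]
    keys <- unlist(lapply(seq_len(nrow(les)), function(i) {
      z <- if (les$zone[i] == "both") c("PZ", "TZ") else les$zone[i]
      paste(z, les$side[i], les$level[i])
    }))
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("degenerate zone mix and seed determinism hold", {
  cfg <- sim_config(n_case = 25, n_control = 5,
                    zone_mix = c(PZ = 1, TZ = 0, both = 0))
  ch <- generate_cohort(cfg, seed = 3)
  expect_true(all(ch$lesions$zone == "PZ"))
  ch2 <- generate_cohort(cfg, seed = 3)
  expect_identical(ch, ch2)
  b1 <- simulate_study(sim_config(n_case = 12, n_control = 6), seed = 5)
  b2 <- simulate_study(sim_config(n_case = 12, n_control = 6), seed = 5)
  expect_identical(b1, b2)
})

test_that("reader behaviour respects deterministic limits and the cap", {
  cfg <- sim_config(n_case = 15, n_control = 10)
  det1 <- cfg$detection_prob; det1[] <- 1
  cfg_all <- sim_config(n_case = 15, n_control = 10, detection_prob = det1,
                        fp_rate = 0)
  b <- simulate_study(cfg_all, seed = 9)
  dm <- match_findings(b$findings, b$lesions)
  # every true lesion detected by every reader that read the patient
  reads <- assignment_readings(b$assignment)
  n_expected <- 0L
  for (i in seq_len(nrow(reads))) {
    les <- b$lesions[b$lesions$patient_id == reads$patient_id[i], ]
    n_expected <- n_expected + min(nrow(les), cfg_all$max_findings)
  }
  expect_identical(nrow(dm$false_positives), 0L)
  expect_equal(dm$n_matched_findings, n_expected * 2L)  # both sessions
  status <- setNames(b$patients$disease_status, b$patients$patient_id)
  expect_true(all(status[b$findings$patient_id] == "case"))

  det0 <- cfg$detection_prob; det0[] <- 0
  cfg_none <- sim_config(n_case = 15, n_control = 10, detection_prob = det0,
                         fp_rate = 0)
  b0 <- simulate_study(cfg_none, seed = 9)
  expect_identical(nrow(b0$findings), 0L)

  # the 4-finding cap holds even under heavy false-positive load
  cfg_fp <- sim_config(n_case = 10, n_control = 10, fp_rate = 8)
  bf <- simulate_study(cfg_fp, seed = 2)
  grp <- table(paste(bf$findings$reader_id, bf$findings$patient_id,
                     bf$findings$session))
  expect_true(all(grp <= 4))
})

test_that("empirical detection recovers the configured probability", {
  # lesion-level calibration: within 4 binomial SDs of the configured p
  p <- 0.65
  det <- default_detection_prob(); det[] <- p
  cfg <- sim_config(n_case = 120, n_control = 20, detection_prob = det,
                    fp_rate = 0)
  b <- simulate_study(cfg, seed = 21)
  dm <- match_findings(b$findings, b$lesions)
  reads <- assignment_readings(b$assignment)
  les_per_pat <- table(b$lesions$patient_id)
  n_lesion_reads <- sum(les_per_pat[reads$patient_id], na.rm = TRUE) * 2
  frac <- dm$n_matched_findings / n_lesion_reads
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / n_lesion_reads))
})

test_that("default behaviour recovers the calibrated patient-level operating point", {
  # the default configuration pins the pooled MRI patient-level sensitivity
  # at threshold >= 1 to 0.956; the analytic value from the generative model
  # is the oracle, the simulation must land within Monte-Carlo error of it
  cfg <- sim_config(n_case = 334, n_control = 166)
  th <- theoretical_patient_perf(cfg, "MRI", 1)
  expect_equal(th$sensitivity, 0.956, tolerance = 5e-4)
  b <- simulate_study(cfg, seed = 61)
  sc <- patient_max_score(b$findings, b$assignment, "MRI")
  emp <- patient_sens_spec(sc, b$patients, 1, average = "pooled")
  # patients (not readings) are the independent unit: lesion configurations
  # are shared across the readers of a patient
  mc_sd <- sqrt(th$sensitivity * (1 - th$sensitivity) / cfg$n_case)
  expect_lt(abs(emp$sensitivity - th$sensitivity), 4 * mc_sd)
  mc_sd_sp <- sqrt(th$specificity * (1 - th$specificity) / cfg$n_control)
  expect_lt(abs(emp$specificity - th$specificity), 4 * mc_sd_sp)
})

test_that("DWI phantom stores analytic truth", {
  expect_error(generate_dwi_phantom(bvalues = 1000), "2 distinct")
  ph <- generate_dwi_phantom(shape = c(3, 3), noise_sd = 0,
                             bvalues = c(0, 1000), seed = 1)
  expect_equal(ph$signals[, 1], ph$truth_s0)
  expect_equal(ph$signals[, 2], ph$truth_s0 * exp(-1000 * ph$truth_adc))
  # the b = 0 column is exactly S0; a unit-ADC voxel decays to S0/e
  one <- generate_dwi_phantom(shape = 1, s0_range = c(1000, 1000),
                              adc_range = c(0.001, 0.001),
                              bvalues = c(0, 1000), noise_sd = 0, seed = 1)
  expect_equal(one$signals[1, 1], 1000)
  expect_equal(one$signals[1, 2], 1000 * exp(-1), tolerance = 1e-12)
})
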
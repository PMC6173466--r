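test_that("patient max score uses 0 for readings without findings", {
  b <- tiny_bundle()
  sc <- patient_max_score(b$findings, b$assignment, "MRI")
  get <- function(r, p) sc$score[sc$reader_id == r & sc$patient_id == p]
  expect_identical(get("R01", "A"), 5L)  # max of {3, 5}
  expect_identical(get("R02", "A"), 4L)  # single finding
  expect_identical(get("R01", "B"), 0L)  # no findings recorded
  expect_identical(get("R02", "C"), 0L)
  expect_identical(nrow(sc), 6L)         # every assigned reading present
})

test_that("sensitivity and specificity count threshold exceedances", {
  pts <- data.frame(patient_id = c("a", "b", "c", "d", "e", "f"),
                    disease_status = c(rep("case", 3), rep("control", 3)),
                    stringsAsFactors = FALSE)
  sc <- data.frame(reader_id = "R01", patient_id = pts$patient_id,
                   score = c(5L, 3L, 1L, 0L, 0L, 4L),
                   stringsAsFactors = FALSE)
  ps <- patient_sens_spec(sc, pts, threshold = 3)
  expect_equal(ps$sensitivity, 2 / 3)
  expect_equal(ps$specificity, 2 / 3)
  # perfect reader: (1, 1) at every threshold
  sc$score <- ifelse(pts$disease_status == "case", 5L, 0L)
  for (t in 1:5) {
    ps <- patient_sens_spec(sc, pts, t)
    expect_equal(ps$sensitivity, 1)
    expect_equal(ps$specificity, 1)
  }
  # empty stratum is flagged, not silently 0
  cases_only <- sc[pts$disease_status == "case", ]
  ps <- patient_sens_spec(cases_only, pts, 3)
  expect_true("control" %in% ps$empty_strata)
  expect_true(is.nan(ps$specificity))
})

test_that("empirical AUC equals the pairwise Mann-Whitney oracle", {
  expect_equal(empirical_auc(c(5, 5, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(empirical_auc(c(3, 3, 3, 3), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  expect_error(empirical_auc(c(1, 2), c(TRUE, TRUE)), "at least one")
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    truth <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(0:5, n, replace = TRUE)
    expect_equal(empirical_auc(scores, truth)$auc,
                 auc_pairwise(scores, truth), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score rescaling", {
  set.seed(5)
  scores <- sample(0:5, 30, replace = TRUE)
  truth <- runif(30) < 0.5; truth[1] <- TRUE; truth[2] <- FALSE
  a1 <- empirical_auc(scores, truth)$auc
  a2 <- empirical_auc(exp(scores) + 7, truth)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("index sensitivity counts matched index lesions by stratum", {
  b <- tiny_bundle()
  det <- match_findings(b$findings, b$lesions)
  # A's index is A-L1 (4+5): only R01 matched it (score 5)
  # B's index is B-L1 (both-zone): only R02 matched it (score 4)
  r <- index_sensitivity(det, b, "MRI", threshold = 1)
  expect_equal(unname(r$by_reader["R01"]), 0.5)
  expect_equal(unname(r$by_reader["R02"]), 0.5)
  expect_equal(r$estimate, 0.5)
  # threshold 5 keeps only R01's hit
  r5 <- index_sensitivity(det, b, "MRI", threshold = 5)
  expect_equal(r5$estimate, 0.25)
  # zone strata: A-L1 is PZ, B-L1 spans both zones (counted in PZ and TZ)
  expect_equal(index_sensitivity(det, b, "MRI", 1, zone = "TZ")$estimate, 0.5)
  expect_equal(index_sensitivity(det, b, "MRI", 1, zone = "PZ")$estimate, 0.5)
  expect_identical(index_sensitivity(det, b, "MRI", 1, zone = "TZ")$n_readings,
                   2L)
  # empty stratum flagged
  empty <- index_sensitivity(det, b, "CAD", 1, experience = "high")
  expect_true(is.nan(empty$estimate) || empty$n_detected == 0)
})

test_that("performance report is monotone in the threshold", {
  cfg <- sim_config(n_case = 30, n_control = 15)
  b <- simulate_study(cfg, seed = 13)
  rep_ <- performance_report(b)
  for (key in split(rep_$patient_level,
                    paste(rep_$patient_level$session,
                          rep_$patient_level$experience))) {
    key <- key[order(key$threshold), ]
    expect_true(all(diff(key$sensitivity) <= 1e-12))
    expect_true(all(diff(key$specificity) >= -1e-12))
  }
  for (key in split(rep_$lesion_level,
                    paste(rep_$lesion_level$session, rep_$lesion_level$zone,
                          rep_$lesion_level$experience))) {
    key <- key[order(key$threshold), ]
    expect_true(all(diff(key$sensitivity) <= 1e-12))
  }
  # index sensitivity never exceeds the any-lesion detection fraction;
  # sensitivity at t=1 equals 1 - fraction of zero-finding case readings
  sc <- patient_max_score(b$findings, b$assignment, "MRI")
  status <- setNames(b$patients$disease_status, b$patients$patient_id)
  case_sc <- sc[status[sc$patient_id] == "case", ]
  pooled_t1 <- patient_sens_spec(sc, b$patients, 1, average = "pooled")
  expect_equal(pooled_t1$sensitivity, mean(case_sc$score >= 1))
})

test_that("perfect readers produce all-one sensitivity cells", {
  det1 <- default_detection_prob(); det1[] <- 1
  score5 <- list(MRI = c(0, 0, 0, 0, 1), CAD = c(0, 0, 0, 0, 1))
  # one lesion per case so the 4-finding cap can never drop a detection
  cfg <- sim_config(n_case = 12, n_control = 6, detection_prob = det1,
                    fp_rate = 0, score_given_detected = score5,
                    lesions_per_case_mean = 1)
  b <- simulate_study(cfg, seed = 17)
  rep_ <- performance_report(b)
  expect_true(all(rep_$patient_level$sensitivity == 1))
  expect_true(all(rep_$patient_level$specificity == 1))
  expect_true(all(rep_$lesion_level$sensitivity == 1))
  expect_true(all(rep_$auc$auc == 1))
})

test_that("clinically-significant filter keeps only Gleason >= 3+4 cases", {
  cfg <- sim_config(n_case = 40, n_control = 10)
  b <- simulate_study(cfg, seed = 23)
  rep_cs <- performance_report(b, thresholds = 1, min_gleason = 7)
  idx <- b$lesions[b$lesions$is_index, ]
  n_cs <- sum(idx$gleason_primary + idx$gleason_secondary >= 7)
  expect_lt(n_cs, 40)  # the default Gleason mix includes 3+3 cases
  ov <- rep_cs$lesion_level[rep_cs$lesion_level$zone == "WP" &
                              rep_cs$lesion_level$experience == "overall" &
                              rep_cs$lesion_level$session == "MRI", ]
  reads <- assignment_readings(b$assignment)
  keep <- idx$patient_id[idx$gleason_primary + idx$gleason_secondary >= 7]
  expect_identical(ov$n_readings, nrow(reads[reads$patient_id %in% keep, ]))
})
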
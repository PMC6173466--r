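test_that("index lesion follows Gleason-then-volume and is permutation-invariant", {
  les <- function(id, gp, gs, vol, idx = FALSE)
    data.frame(lesion_id = id, patient_id = "A", zone = "PZ", side = "left",
               level = "mid", gleason_primary = gp, gleason_secondary = gs,
               volume = vol, is_index = idx, stringsAsFactors = FALSE)
  # Gleason dominates volume: 4+5 (0.5 ml) beats 3+4 (3 ml)
  two <- rbind(les("L1", 4L, 5L, 0.5), les("L2", 3L, 4L, 3))
  expect_identical(index_lesion(two)$lesion_id, "L1")
  expect_identical(index_lesion(two[2:1, ])$lesion_id, "L1")
  # Gleason tie broken by volume
  tie_g <- rbind(les("L1", 3L, 4L, 1), les("L2", 3L, 4L, 2))
  expect_identical(index_lesion(tie_g)$lesion_id, "L2")
  # primary pattern breaks the total tie: 4+3 beats 3+4
  tie_t <- rbind(les("L1", 3L, 4L, 5), les("L2", 4L, 3L, 0.1))
  expect_identical(index_lesion(tie_t)$lesion_id, "L2")
  # single lesion is its own index
  expect_identical(index_lesion(les("L9", 3L, 3L, 1))$lesion_id, "L9")
  # full tie: needs the explicit flag
  full <- rbind(les("L1", 3L, 4L, 1), les("L2", 3L, 4L, 1))
  expect_error(index_lesion(full), "tie")
  full$is_index[2] <- TRUE
  expect_identical(index_lesion(full)$lesion_id, "L2")
  expect_error(index_lesion(full[0, ]), "no lesions")
})

test_that("finding-lesion matching follows the sector key and priority rules", {
  b <- tiny_bundle()
  dm <- match_findings(b$findings, b$lesions, patients = b$patients)
  m <- dm$matched
  # two R01 findings on A's PZ/left/mid lesion: highest score kept
  hit <- m[m$reader_id == "R01" & m$lesion_id == "A-L1", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$score, 5L)
  # R02's TZ/right/base finding matches A-L2 exactly
  expect_identical(m$score[m$reader_id == "R02" & m$lesion_id == "A-L2"], 4L)
  # both-zone lesion B-L1 matches a TZ-tagged finding at its side/level
  expect_identical(m$score[m$reader_id == "R02" & m$lesion_id == "B-L1"], 4L)
  # R01's control finding is a false positive; conservation holds
  expect_identical(nrow(dm$false_positives), 1L)
  expect_identical(dm$false_positives$patient_id, "C")
  expect_identical(dm$n_matched_findings + nrow(dm$false_positives),
                   dm$n_findings)
  # unknown patient triggers the integrity error
  bad <- b$findings; bad$patient_id[1] <- "ZZ"
  expect_error(match_findings(bad, b$lesions, patients = b$patients),
               "unknown patients")
})

test_that("matching agrees with the brute-force assignment enumerator", {
  set.seed(2024)
  sectors <- expand.grid(zone = c("PZ", "TZ"), side = c("left", "right"),
                         level = c("apex", "mid", "base"),
                         stringsAsFactors = FALSE)
  for (rep in 1:200) {
    n_les <- sample(1:4, 1)
    pick <- sectors[sample.int(12, n_les), ]
    zone <- pick$zone
    zone[runif(n_les) < 0.2] <- "both"
    lesions <- data.frame(
      lesion_id = sprintf("L%d", 1:n_les), patient_id = "A",
      zone = zone, side = pick$side, level = pick$level,
      gleason_primary = sample(3:5, n_les, replace = TRUE),
      gleason_secondary = sample(3:5, n_les, replace = TRUE),
      volume = round(runif(n_les, 0.1, 5), 3),
      is_index = FALSE, stringsAsFactors = FALSE)
    lesions$is_index[lesions$lesion_id ==
                       index_lesion(lesions)$lesion_id] <- TRUE
    n_f <- sample(1:4, 1)
    fsec <- sectors[sample.int(12, n_f, replace = TRUE), ]
    findings <- data.frame(
      reader_id = "R01", session = "MRI", patient_id = "A",
      zone = fsec$zone, side = fsec$side, level = fsec$level,
      score = sample(1:5, n_f, replace = TRUE), stringsAsFactors = FALSE)
    got <- match_findings(findings, lesions)
    want <- match_brute(findings, lesions)
    expect_identical(nrow(got$false_positives), want$n_fp)
    if (is.null(want$matched)) {
      expect_identical(nrow(got$matched), 0L)
    } else {
      g <- got$matched[order(got$matched$lesion_id), ]
      w <- want$matched[order(want$matched$lesion_id), ]
      expect_equal(g$lesion_id, w$lesion_id)
      expect_equal(g$score, w$score)
    }
  }
})

test_that("matching is invariant to finding order", {
  b <- tiny_bundle()
  dm1 <- match_findings(b$findings, b$lesions)
  dm2 <- match_findings(b$findings[rev(seq_len(nrow(b$findings))), ],
                        b$lesions)
  o <- function(m) m$matched[order(m$matched$reader_id, m$matched$session,
                                   m$matched$lesion_id), ]
  expect_equal(o(dm1)$score, o(dm2)$score)
  expect_equal(o(dm1)$lesion_id, o(dm2)$lesion_id)
})

test_that("bundle validation reports row-level schema violations", {
  b <- tiny_bundle()
  expect_identical(nrow(validate_bundle(b, stop_on_error = FALSE)), 0L)
  # score out of range, with its row number
  bad <- b; bad$findings$score[2] <- 6L
  probs <- validate_bundle(bad, stop_on_error = FALSE)
  expect_true(any(probs$table == "findings" & probs$row == 2))
  expect_error(validate_bundle(bad), "score")
  # more than 4 findings for one (reader, patient, session)
  extra <- b$findings[rep(1, 5), ]
  extra$zone <- c("PZ", "TZ", "PZ", "TZ", "PZ")
  extra$level <- c("apex", "apex", "mid", "mid", "base")
  over <- b
  over$findings <- rbind(b$findings[-(1:2), ], extra)
  expect_error(validate_bundle(over), "cap is 4")
  # control with a lesion
  sick <- b
  sick$lesions <- rbind(b$lesions, transform(b$lesions[1, ],
                                             lesion_id = "C-L1",
                                             patient_id = "C"))
  expect_error(validate_bundle(sick), "control")
  # duplicate patient ids
  dup <- b; dup$patients <- rbind(b$patients, b$patients[1, ])
  expect_error(validate_bundle(dup), "duplicate patient_id")
})

test_that("CSV round trip is lossless", {
  b <- simulate_study(sim_config(n_case = 10, n_control = 5), seed = 31)
  dir <- withr::local_tempdir()
  write_tables(b, dir)
  b2 <- read_tables(dir)
  for (tab in c("patients", "lesions", "readers", "findings"))
    expect_equal(b2[[tab]], b[[tab]], tolerance = 1e-12)
  expect_setequal(b2$assignment$common_subset, b$assignment$common_subset)
  expect_equal(b2$assignment$blocks[order(b2$assignment$blocks$patient_id), ],
               b$assignment$blocks[order(b$assignment$blocks$patient_id), ],
               ignore_attr = TRUE)
})
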
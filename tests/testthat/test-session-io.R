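test_that("a session log is reproducible from its seed and carries ISI jitter", {
  sub <- subject_model(12, id = "S01", group_label = "HC")
  a <- run_session(sub, seed = 101)
  b <- run_session(sub, seed = 101)
  expect_identical(a$stimulus_log, b$stimulus_log)
  expect_equal(a$result$threshold_mA, b$result$threshold_mA)
  gaps <- diff(c(0, a$stimulus_log$time_s))
  expect_true(all(gaps >= 8 & gaps <= 12))
  expect_true(all(diff(a$stimulus_log$time_s) > 0))
  expect_true(all(a$stimulus_log$rating >= 0 & a$stimulus_log$rating <= 10))
})

test_that("session JSON validates against the shipped schema", {
  sub <- subject_model(9, id = "S02", group_label = "FM")
  rec <- run_session(sub, seed = 7)
  path <- tempfile(fileext = ".json")
  write_session_json(rec, path)
  expect_true(validate_session_json(path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(obj$schema, "nwr-session-1")
  expect_equal(obj$threshold_mA, rec$result$threshold_mA)
  # a mutilated log fails validation
  obj$status <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null")
  expect_error(validate_session_json(path), "status")
})

test_that("the cohort CSV round-trips through its canonical wide form", {
  ct <- data.frame(
    subject_id = c("FM01", "FM02", "HC01"), group = c("FM", "FM", "HC"),
    threshold_limb1_mA = c(11, NA, 14.5), threshold_limb2_mA = c(13, 9.5, NA),
    subject_threshold_mA = c(12, 9.5, 14.5),
    rating_limb1 = c(7, NA, 4.2), rating_limb2 = c(6.5, 8, NA),
    subject_rating = c(6.75, 8, 4.2),
    age = c(40, 35, 44))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(ct, path)
  back <- read_cohort_csv(path)
  expect_equal(back[order(back$subject_id), names(ct)],
               ct[order(ct$subject_id), ], ignore_attr = TRUE)
  # single-limb fallback: the subject threshold equals the measured limb
  expect_equal(back$subject_threshold_mA[back$subject_id == "FM02"], 9.5)
  # and a second write of the canonical form is byte-identical
  path2 <- tempfile(fileext = ".csv")
  write_cohort_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed cohort CSVs are rejected with located errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,limb,threshold_mA,mean_rating",
               "S1,FM,first,10.5,6",
               "S2,HC,first,abc,4"), path)
  expect_error(read_cohort_csv(path), "line 3")
  writeLines(c("subject_id,group,threshold_mA", "S1,FM,10"), path)
  expect_error(read_cohort_csv(path), "missing columns")
})

test_that("a no-dropout bilateral experiment applies the averaging rule", {
  cfg <- experiment_config(
    cohort = cohort_spec(n_fm = 2, n_hc = 2),
    dropout = list(fm_limb1 = 0, fm_limb2 = 0, hc_limb1 = 0, hc_limb2 = 0),
    master_seed = 11)
  res <- run_experiment(cfg)
  expect_equal(length(res$sessions), 8)  # 4 subjects x 2 limbs
  ct <- res$cohort_table
  done <- !is.na(ct$threshold_limb1_mA) & !is.na(ct$threshold_limb2_mA)
  expect_equal(ct$subject_threshold_mA[done],
               (ct$threshold_limb1_mA[done] + ct$threshold_limb2_mA[done]) / 2)
  expect_equal(ct$subject_rating,
               rowMeans(cbind(ct$rating_limb1, ct$rating_limb2), na.rm = TRUE))
})

test_that("experiments are byte-identical under the same master seed", {
  cfg <- experiment_config(cohort = cohort_spec(n_fm = 3, n_hc = 3),
                           master_seed = 12)
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  run_experiment(cfg, out_dir = d1)
  run_experiment(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
})

test_that("re-running a single session from its logged seed reproduces it", {
  cfg <- experiment_config(cohort = cohort_spec(n_fm = 2, n_hc = 2),
                           master_seed = 13)
  res <- run_experiment(cfg)
  s <- res$sessions[[1]]
  subs <- generate_cohort(cfg$cohort, seed = nwreflex:::derive_seed(13, 0))
  sub <- subs[[which(vapply(subs, `[[`, "", "id") == s$subject_id)]]
  replay <- run_session(sub, limb = s$limb, seed = s$seed)
  expect_identical(replay$stimulus_log, s$stimulus_log)
})

test_that("a full-size experiment recovers the generating group means", {
  cfg <- experiment_config(master_seed = 42)  # 29 FM / 21 HC defaults
  res <- run_experiment(cfg)
  rep <- res$report
  expect_lt(abs(rep$thresholds$fm$mean - 14.4), 2)
  expect_lt(abs(rep$thresholds$hc$mean - 14.7), 2)
  # patients rate higher at the measured intensities
  expect_gt(rep$ratings$fm$median, rep$ratings$hc$median)
})
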
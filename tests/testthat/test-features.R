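test_that("demographic encoding follows the month mapping and one-hot rules", {
  p <- patient_record("P1", age_group = "Child", sex = "Female",
                      pregnant = TRUE, murmur = "Present",
                      outcome = "Abnormal")
  d <- encode_demographics(p)
  expect_equal(unname(d$values["age_months"]), 72)
  expect_equal(unname(d$values[c("sex_female", "sex_male", "pregnant")]),
               c(1, 0, 1))
  expect_false(any(d$missing_mask[c("age_months", "sex_female")]))

  expect_equal(unname(encode_demographics(
    patient_record("P2", age_group = "Neonate"))$values["age_months"]), 0.5)
  expect_equal(unname(encode_demographics(
    patient_record("P3", age_group = "Adolescent"))$values["age_months"]), 180)

  # missing age is masked for imputation; missing sex leaves both one-hots 0
  m <- encode_demographics(patient_record("P4"))
  expect_true(m$missing_mask["age_months"])
  expect_equal(unname(m$values[c("sex_female", "sex_male")]), c(0, 0))
  expect_equal(unname(m$values["pregnant"]), 0)
})

test_that("mean imputation uses training means only and preserves observed values", {
  recs <- list(patient_record("A", age_group = "Child", height_cm = 150,
                              weight_kg = 40),
               patient_record("B", age_group = "Child", height_cm = 160,
                              weight_kg = 50),
               patient_record("C", age_group = "Child"))
  demos <- lapply(recs, encode_demographics)
  imp <- fit_imputer(demos)
  expect_equal(unname(imp$means["height_cm"]), 155)

  filled <- apply_imputer(imp, demos[[3]])
  expect_equal(unname(filled["height_cm"]), 155)
  expect_equal(unname(filled["weight_kg"]), 45)
  # observed rows are untouched
  expect_equal(unname(apply_imputer(imp, demos[[1]])["height_cm"]), 150)

  # a test-time imputer must carry the training means, not refit: applying
  # the fold-A imputer to an unseen vector uses fold-A means by construction
  unseen <- encode_demographics(patient_record("Z"))
  expect_equal(unname(apply_imputer(imp, unseen)["height_cm"]), 155)

  # field missing in every training row is an error naming the field
  all_missing <- lapply(list(patient_record("X"), patient_record("Y")),
                        encode_demographics)
  expect_error(fit_imputer(all_missing), "height_cm|age_months")
})

test_that("signal features recover spectral structure of known signals", {
  fs <- 4000
  tone <- pcg_recording(sin(2 * pi * 200 * (0:(4 * fs - 1)) / fs), fs)
  f <- signal_features(tone)
  # centroid of a pure 200 Hz tone within one 31.25 Hz FFT bin
  expect_lt(abs(f["spec_centroid_mean_hz"] - 200), 4000 / 128)
  expect_lt(abs(f["dominant_freq_hz"] - 200), 4000 / 128)

  set.seed(3)
  noise <- pcg_recording(stats::rnorm(8 * fs), fs)
  fn <- signal_features(noise)
  # flat spectrum: centroid near Nyquist/2 = 1000 Hz
  expect_lt(abs(fn["spec_centroid_mean_hz"] - 1000), 60)
  expect_gt(fn["spec_rolloff_mean_hz"], 1000)

  # amplitude-scale invariance of the spectral moments
  half <- signal_features(pcg_recording(noise$samples * 0.3, fs))
  spec_fields <- grep("^spec_|dominant", names(fn), value = TRUE)
  expect_equal(fn[spec_fields], half[spec_fields], tolerance = 1e-10)

  z <- signal_features(pcg_recording(numeric(fs), fs))
  expect_true(attr(z, "degenerate"))
  expect_true(all(z == 0))
})

test_that("patient feature matrices have constant width regardless of recording count", {
  dir <- withr::local_tempdir()
  ct <- make_cohort(n = 8, seed = 51, dir = dir, locations = c(1, 3))
  pf <- patient_features(ct, desk_params())
  expect_equal(nrow(pf$features), 8)
  expect_equal(ncol(pf$features), 6 + 13)
  expect_true(all(is.finite(pf$features)))
  expect_s3_class(pf$imputer, "mean_imputer")

  # reusing a fitted imputer reproduces the demographic columns
  pf2 <- patient_features(ct, desk_params(), imputer = pf$imputer)
  expect_identical(pf$features, pf2$features)

  # CSV export keeps the stable column order and round-trips
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(pf$features, path)
  back <- utils::read.csv(path, check.names = FALSE,
                          colClasses = c(patient_id = "character"))
  expect_equal(names(back), c("patient_id", colnames(pf$features)))
  expect_equal(back$patient_id, rownames(pf$features))
  expect_lt(max(abs(as.matrix(back[, -1]) - pf$features)), 1e-8)
})
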
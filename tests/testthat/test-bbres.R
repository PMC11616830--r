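test_that("model construction honours the config surface", {
  m <- build_bbres(bbres_config("resnet18-lite", seed = 3))
  expect_s3_class(m, "bbres_model")
  expect_gt(m$n_params, 1000)

  # dropout placement is introspectable: disabling in-block dropout removes
  # exactly the dropout modules
  m_nodrop <- build_bbres(bbres_config(dropout_in_blocks = FALSE, seed = 3))
  mods <- bbres_modules(m)
  mods_nd <- bbres_modules(m_nodrop)
  expect_true(any(grepl("\\.drop", mods)))
  expect_false(any(grepl("\\.drop", mods_nd)))
  expect_identical(setdiff(mods, mods_nd), grep("\\.drop", mods, value = TRUE))

  # identical seeds give identical initial weights regardless of dropout rate
  m0 <- build_bbres(bbres_config(dropout_rate = 0, seed = 3))
  expect_identical(m$params, m0$params)

  expect_error(bbres_config(dropout_rate = 1), "dropout_rate")
  expect_error(bbres_config("resnet99"))

  # the deep bottleneck backbone builds through the same path
  r50 <- build_bbres(bbres_config("resnet50", seed = 1))
  expect_gt(r50$n_params, 1e6)
  expect_equal(r50$config$in_channels, 3L)
  expect_true(any(grepl("conv3", bbres_modules(r50))))
})

test_that("a forward pass maps a full-size window to one probability", {
  m <- build_bbres(bbres_config(seed = 2))
  img <- array(stats::runif(128 * 398), c(128, 398, 1))
  p <- predict_window_mc(m, img, T = 1)
  expect_equal(nrow(p), 1)
  expect_true(p$p_mean >= 0 && p$p_mean <= 1)
  expect_equal(p$p_std, 0)
})

test_that("MC dropout machinery honours its degenerate contracts", {
  ws <- separable_windows(6, 2, seed = 11)
  m <- build_bbres(bbres_config(dropout_rate = 0.2, seed = 5))

  # dropout off: std exactly 0 and mean equals the deterministic pass
  det <- predict_window_mc(m, ws, T = 7, mc_dropout = FALSE)
  expect_true(all(det$p_std == 0))
  det2 <- predict_window_mc(m, ws, T = 1, mc_dropout = FALSE)
  expect_identical(det$p_mean, det2$p_mean)

  # rate 0 is the plain baseline path on the same weights
  m0 <- build_bbres(bbres_config(dropout_rate = 0, seed = 5))
  base <- predict_window_mc(m0, ws, T = 9)
  expect_true(all(base$p_std == 0))
  expect_equal(base$p_mean, det$p_mean, tolerance = 1e-12)

  # T = 1 has zero spread by definition
  one <- predict_window_mc(m, ws, T = 1, seed = 1)
  expect_true(all(one$p_std == 0))

  # active dropout at T = 50 produces genuine spread
  mc <- predict_window_mc(m, ws, T = 50, seed = 1)
  expect_true(all(mc$p_std > 0))
  expect_true(all(mc$p_mean >= 0 & mc$p_mean <= 1))
})

test_that("the MC mean is stable across dropout seeds at the 1/sqrt(T) scale", {
  ws <- separable_windows(10, 2, seed = 21)
  m <- build_bbres(bbres_config(dropout_rate = 0.2, seed = 9))
  T <- 200
  a <- predict_window_mc(m, ws, T = T, seed = 100)
  b <- predict_window_mc(m, ws, T = T, seed = 200)
  pooled <- sqrt((a$p_std^2 + b$p_std^2) / 2)
  # aggregate over the fixed inputs: each per-input difference has Monte
  # Carlo scale pooled/sqrt(T), so the mean absolute difference sits well
  # inside 3x that scale; individually nothing strays past 6 sigma
  expect_lte(mean(abs(a$p_mean - b$p_mean)),
             3 * mean(pooled) / sqrt(T))
  expect_true(all(abs(a$p_mean - b$p_mean) <=
                    pmax(6 * pooled / sqrt(T), 1e-6)))
})

test_that("training learns separable data, rejects degenerate sets, and is deterministic", {
  ws <- separable_windows(16, 3, seed = 31)
  m <- build_bbres(fast_config(epochs = 4, seed = 13))
  fit1 <- train_bbres(m, ws, seed = 13)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  expect_true(fit1$trained)
  expect_length(intersect(fit1$val_patients,
                          setdiff(unique(ws$meta$patient_id),
                                  fit1$val_patients)), 0)

  # fixed seed, identical loss curves
  fit2 <- train_bbres(build_bbres(fast_config(epochs = 4, seed = 13)), ws,
                      seed = 13)
  expect_identical(fit1$history, fit2$history)

  # single-class training data is an error
  ws1 <- ws
  ws1$meta$label <- 1L
  expect_error(train_bbres(build_bbres(fast_config()), ws1), "single class")
})

test_that("checkpoints round-trip with config and seed embedded", {
  ws <- separable_windows(6, 2, seed = 41)
  m <- train_bbres(build_bbres(fast_config(epochs = 1, seed = 17)), ws)
  path <- withr::local_tempfile(fileext = ".rds")
  save_bbres(m, path)
  m2 <- load_bbres(path)
  expect_identical(m2$config$seed, 17L)
  expect_identical(predict_window_mc(m, ws, T = 1, mc_dropout = FALSE),
                   predict_window_mc(m2, ws, T = 1, mc_dropout = FALSE))
})
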
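test_that("generator honours the configured size and yields all three grades", {
  d <- simulate_enose(enose_config(28, seed = 1))
  expect_identical(nrow(d$sensors), 7800L)
  expect_identical(nrow(d$quality), 7800L)
  expect_identical(length(d$labels$label), 7800L)
  expect_setequal(unique(d$labels$label), 1:3)
  expect_true(all(diff(d$sensors$time_hours) > 0))
  expect_identical(colnames(d$sensors)[2:11], paste0("S", 1:10))
  expect_true(all(d$sensors$rh >= 0 & d$sensors$rh <= 100))
})

test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- enose_config(12, n_rows = 400, seed = 77)
  expect_identical(simulate_enose(cfg), simulate_enose(cfg))
})

test_that("invalid generator configurations are rejected", {
  expect_error(enose_config(4, class_boundaries = c(0.6, 0.4)), "b1 < b2")
  expect_error(enose_config(4, class_boundaries = c(0, 0.5)), "b1 < b2")
  expect_error(enose_config(4, n_rows = 0), "positive")
  expect_error(enose_config(4, noise_sd = -1), "nonnegative")
  expect_error(enose_config(15), "must be one of")
  expect_error(simulate_enose(list()), "enose_config")
})

test_that("noise-free amine channels rise from first to last time decile", {
  cfg <- enose_config(20, n_rows = 1000, noise_sd = 0, drift_sd = 0, seed = 3)
  d <- simulate_enose(cfg)
  u <- d$sensors$time_hours / cfg$horizon
  first <- u <= quantile(u, 0.1); last <- u >= quantile(u, 0.9)
  for (ch in c("S1", "S2", "S5", "S10")) {
    expect_gt(mean(d$sensors[[ch]][last]), mean(d$sensors[[ch]][first]))
  }
  # noise-free voltages coincide with the closed-form mean curves
  expect_equal(as.matrix(d$sensors[, paste0("S", 1:10)]),
               sensor_response_curves(u, cfg$class_boundaries),
               ignore_attr = TRUE, tolerance = 1e-12)
  # alcohol channel completes most of its rise within the fresh phase
  b1 <- cfg$class_boundaries[1]
  s9 <- sensor_response_curves(c(0, b1, 1), cfg$class_boundaries)[, "S9"]
  expect_gt(s9[2] - s9[1], 0.8 * (s9[3] - s9[1]))
})

test_that("noise-free quality trajectories are exactly monotone", {
  d <- simulate_enose(enose_config(4, n_rows = 800, noise_sd = 0, seed = 2))
  expect_true(all(diff(d$quality$tvbn) >= 0))
  expect_true(all(diff(d$quality$tpc) >= 0))
  expect_true(all(diff(d$quality$hardness) <= 0))
  for (nm in c("color", "odor", "tissue"))
    expect_true(all(diff(d$quality[[nm]]) <= 0))
})

test_that("label proportions track the configured phase boundaries", {
  for (temp in c(4, 12, 20, 28)) {
    cfg <- enose_config(temp, seed = 21)
    d <- simulate_enose(cfg)
    prop <- as.vector(table(factor(d$labels$label, 1:3))) / cfg$n_rows
    b <- cfg$class_boundaries
    expect_equal(prop, c(b[1], b[2] - b[1], 1 - b[2]), tolerance = 0.02)
  }
})

test_that("three principal components capture most sensor variance", {
  for (temp in c(4, 28)) {
    d <- simulate_enose(enose_config(temp, seed = 31))
    v <- as.matrix(d$sensors[, paste0("S", 1:10)])
    p <- fit_pca(scale_minmax(fit_minmax(v), v), 3)
    expect_gte(cumulative_variance(p, 3), 0.90)
  }
})

test_that("datasets round-trip through CSV files", {
  d <- simulate_enose(enose_config(4, n_rows = 10, seed = 8))
  dir <- withr::local_tempdir()
  write_enose_dataset(d, dir)
  back <- read_enose_dataset(dir)
  expect_equal(back$sensors, d$sensors, tolerance = 1e-9)
  expect_equal(back$quality, d$quality, tolerance = 1e-9)
  expect_equal(back$labels$label, d$labels$label)
})

test_that("malformed dataset files produce named parse errors", {
  dir <- withr::local_tempdir()
  # 9 voltage columns instead of 10
  writeLines(c(paste(c("time_hours", paste0("S", 1:9), "chamber_temp", "rh",
                       "condition"), collapse = ","),
               paste(rep("1", 13), collapse = ",")),
             file.path(dir, "sensors.csv"))
  expect_error(read_enose_dataset(dir), "malformed header")
  # non-numeric cell, located by row and column
  d <- simulate_enose(enose_config(4, n_rows = 3, seed = 1))
  write_enose_dataset(d, dir)
  q <- readLines(file.path(dir, "quality.csv"))
  q[3] <- sub("^([^,]*),[^,]*", "\\1,oops", q[3])
  writeLines(q, file.path(dir, "quality.csv"))
  expect_error(read_enose_dataset(dir), "row 2, column 'tvbn'")
  # empty file is a parse error, not an empty table
  writeLines(character(0), file.path(dir, "sensors.csv"))
  expect_error(read_enose_dataset(dir), "empty file")
})
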
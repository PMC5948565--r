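test_that("sensor tables round-trip through write and read", {
  tf <- tempfile(fileext = ".csv")
  set.seed(7)
  sig <- compound_signal(cbind(acc_x = rnorm(40), acc_y = rnorm(40)),
                         fsamp = 25)
  write_sensor_table(sig, tf)
  raw <- read_sensor_table(tf)
  expect_equal(raw$channel_labels, c("acc_x", "acc_y"))
  expect_equal(raw$time, (0:39) / 25, tolerance = 1e-9)
  expect_equal(unname(raw$values), unname(sig$samples), tolerance = 1e-9)
  expect_identical(raw$time_unit, "s")
})

test_that("reading validates the table and names the offending cell", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("t,acc_x", "0,0", "0.04,1", "0.04,0"), tf)
  expect_error(read_sensor_table(tf), "row 3")
  writeLines(c("t,acc_x", "0,0", "0.04,oops"), tf)
  expect_error(read_sensor_table(tf), "row 2.*acc_x")
  writeLines(c("a,b", "0,0", "1,1"), tf)
  expect_error(read_sensor_table(tf), "time column")
})

test_that("millisecond timestamps are auto-detected", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("t,acc_x", "0,0", "40,1", "80,0"), tf)
  raw <- read_sensor_table(tf)
  expect_identical(raw$time_unit, "ms")
  expect_equal(raw$time, c(0, 0.04, 0.08))
})

test_that("resampling interpolates linearly onto the anchored grid", {
  raw <- list(time = c(0, 1), values = cbind(y = c(0, 2)))
  sig <- resample_equidistant(raw, 4)
  expect_equal(signal_length(sig), 5L)
  expect_equal(unname(sig$samples[, 1]), c(0, 0.5, 1, 1.5, 2))

  # already equidistant input is a fixed point
  raw2 <- list(time = (0:20) / 25, values = cbind(y = sin(0:20)))
  sig2 <- resample_equidistant(raw2, 25)
  expect_equal(unname(sig2$samples[, 1]), sin(0:20), tolerance = 1e-12)

  expect_error(resample_equidistant(raw, 0), "positive")
  expect_error(resample_equidistant(list(time = 1, values = cbind(1)), 25),
               "two samples")
})

test_that("jittered sampling resampled matches a brute-force interpolant", {
  set.seed(11)
  t_raw <- sort(runif(120, 0, 4))
  y <- sin(2 * pi * 1.3 * t_raw)
  sig <- resample_equidistant(list(time = t_raw, values = cbind(y = y)), 25)
  grid <- t_raw[1] + (0:(signal_length(sig) - 1)) / 25
  manual <- vapply(grid, function(tt) {
    i <- max(which(t_raw <= tt + 1e-12))
    if (i == length(t_raw)) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (tt - t_raw[i]) / (t_raw[i + 1] - t_raw[i])
  }, numeric(1))
  expect_equal(unname(sig$samples[, 1]), manual, tolerance = 1e-9)
})

test_that("derived channels append without touching existing ones", {
  set.seed(3)
  X <- cbind(acc_x = rep(3, 30), acc_y = rep(4, 30), acc_z = rep(0, 30),
             gyr_x = rnorm(30), gyr_y = rnorm(30), gyr_z = rnorm(30))
  sig <- compound_signal(X, fsamp = 25)
  out <- derive_channels(sig, c("AM", "GE"))
  expect_equal(out$samples[, 1:6], X)
  expect_equal(unname(out$samples[, "am"]), rep(5, 30))

  wlen <- max(1, round(max(2, round(25 / 3)) / 2))
  energy <- rowSums(X[, 4:6]^2)
  expect_equal(unname(out$samples[, "ge"]), oracle_moving_avg(energy, wlen),
               tolerance = 1e-9)

  zero <- compound_signal(cbind(gyr_x = 0 * 1:10, gyr_y = 0 * 1:10,
                                gyr_z = 0 * 1:10), fsamp = 25)
  expect_equal(unname(derive_channels(zero, "GE")$samples[, "ge"]),
               rep(0, 10))
  expect_error(derive_channels(zero, "AM"), "acc_x")
})

test_that("configuration derives the admissible stride-time band", {
  cfg <- cyclicity_config(fsamp = 25)
  expect_identical(cfg$Nmin, 8L)
  expect_identical(cfg$Nmax, 50L)
  expect_equal(cfg$Nmax / cfg$fsamp, 2)        # longest stride: 2 s
  expect_identical(cfg$eta, 2L)
  expect_error(cyclicity_config(25, fmin = 3, fmax = 0.5), "fmin")
  expect_error(cyclicity_config(25, eta = 100), "eta")
  expect_error(cyclicity_config(25, estimators = 7), "estimators")
})

test_that("a synthetic trial survives a file round-trip", {
  trial <- synthetic_trial(seed = 4, duration_s = 12, n_gaps = 0,
                           n_transitions = 0)
  prefix <- tempfile()
  paths <- write_trial(trial, prefix)
  raw <- read_sensor_table(paths["signal"])
  back <- resample_equidistant(raw, trial$signal$fsamp)
  expect_equal(unname(back$samples), unname(trial$signal$samples),
               tolerance = 1e-6)
  truth <- read.csv(paths["truth"])
  expect_equal(truth$t_truth, trial$truth$t_truth)
})
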
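test_that("compact fiducial specification strings parse to components", {
  p <- parse_fiducial_spec("1234-AccGyr-A-[M|m]")
  expect_identical(p$estimators, 1:4)
  expect_length(p$specs, 12)  # 6 channels x 2 kinds
  labels <- vapply(p$specs, `[[`, character(1), "label")
  expect_true("acc_x[M]" %in% labels && "gyr_z[m]" %in% labels)

  p2 <- parse_fiducial_spec("Gyr-z-[m]")
  expect_null(p2$estimators)
  expect_identical(p2$specs[[1]]$label, "gyr_z[m]")

  p3 <- parse_fiducial_spec("GE-x-[s]")
  expect_identical(p3$specs[[1]]$channel, "ge")
  expect_identical(p3$specs[[1]]$kind, "s")

  expect_error(parse_fiducial_spec("12-Foo-A-[M]"), "component")
  expect_error(parse_fiducial_spec("Acc-A-[Q]"), "kind")
  expect_error(parse_fiducial_spec("Acc-A-[M]",
                                   channel_labels = "gyr_x"), "channels")
})

test_that("fiducial functions locate constructed events", {
  K <- 30
  w <- rep(0, 2 * K + 1)
  N <- 20
  zl <- K + 1
  w[zl + 5] <- 2; w[zl + 5 - N] <- 2        # paired peaks at m = 5
  expect_identical(apply_fiducial(w, N, "M"), 5L)
  expect_identical(apply_fiducial(-w, N, "m"), 5L)

  ramp <- seq(1, 3, length.out = 2 * K + 1)  # monotone positive: no crossing
  expect_length(apply_fiducial(ramp, N, "z"), 0)

  wz <- sin(2 * pi * (seq_len(2 * K + 1) - zl) / N)  # crosses zero at m = 0, 10, 20
  mz <- apply_fiducial(wz, N, "z")
  expect_true(min(abs(wz[zl + mz]), na.rm = TRUE) < 0.4)

  wh <- rep(0, 2 * K + 1); wh[zl + 7] <- 1; wh[zl + 8] <- -2  # abrupt drop at m = 8
  expect_identical(apply_fiducial(wh, N, "h"), 8L)

  ws <- rep(1, 2 * K + 1); ws[(zl + 4):(zl + 12)] <- 0.001  # quiet plateau
  expect_identical(apply_fiducial(ws, N, "s", hr = 0.01), 8L)
  expect_length(apply_fiducial(ws, N, "s", hr = 0), 0)
})

test_that("the maxima fiducial matches exhaustive search on random windows", {
  set.seed(23)
  for (rep in 1:25) {
    w <- rnorm(101)
    N <- sample(8:45, 1)
    zl <- 51
    sums <- w[zl + 0:N] + w[zl + 0:N - N]
    expect_identical(apply_fiducial(w, N, "M"), which.max(sums) - 1L)
    expect_identical(apply_fiducial(w, N, "m"), which.min(sums) - 1L)
  }
})

test_that("candidate collection emits one vote per window and replicates", {
  trial <- synthetic_trial(seed = 2, duration_s = 20, snr_db = Inf,
                           n_gaps = 0, n_transitions = 0)
  cfg <- cyclicity_config(25)
  series <- sweep_windows(trial$signal, cfg)
  cands <- collect_candidates(trial$signal, series,
                              list(fiducial_spec("acc_x", "M")))
  cc <- cands[["acc_x[M]"]]
  expect_lte(nrow(cc), length(series$centers))
  truth <- trial$truth[trial$truth$channel == "acc_x", "t_truth"]
  observable <- truth[truth >= cfg$Nmax]
  # consolidated positions land on true fiducials within one sample
  cons <- consolidate(cc, eta = cfg$eta, h = 0.5)
  near_cons <- vapply(observable[-c(1, length(observable))], function(t)
    min(abs(cons$t - t)), numeric(1))
  expect_gte(mean(near_cons <= 1), 0.95)
  # each observable fiducial receives about d/eta replicated votes
  votes <- vapply(observable[2:5], function(t) sum(abs(cc$t - t) <= 1),
                  numeric(1))
  expect_true(all(votes >= 0.5 * 27 / cfg$eta))
})

test_that("consolidation takes the modal interval, mean confidence and vote gate", {
  cands <- data.frame(
    t = rep(100L, 10),
    d = c(rep(25L, 7), rep(26L, 3)),
    v = rep(c(0.2, 0.4), 5))
  out <- consolidate(cands, eta = 5, h = 0.4)
  expect_identical(out$d, 25L)
  expect_equal(out$v, 0.3)

  # lexp = min(d, t)/eta = 20 at h = 0.75: 18 votes kept, 10 dropped
  mk <- function(t, n) data.frame(t = rep(t, n), d = rep(100L, n),
                                  v = rep(0.5, n))
  eta <- 5
  big <- rbind(mk(100L, 18), mk(500L, 10))
  kept <- consolidate(big, eta = eta, h = 0.75)
  expect_identical(kept$t, 100L)
  expect_identical(kept$count, 18L)

  # positions one sample apart merge onto the majority position
  scatter <- data.frame(t = c(200L, 201L, 201L, 201L, 202L),
                        d = rep(30L, 5), v = rep(0.5, 5))
  m <- consolidate(scatter, eta = 30, h = 0.5)
  expect_identical(m$t, 201L)
  expect_identical(m$count, 5L)
})

test_that("consolidation is idempotent on its own output", {
  set.seed(31)
  cands <- data.frame(t = sort(sample(seq(50L, 900L, by = 30L), 12)),
                      d = sample(25:30, 12, replace = TRUE),
                      v = runif(12))
  once <- consolidate(cands, eta = 2, h = 0.1)
  twice <- consolidate(once[, c("t", "d", "v")], eta = 2, h = 0)
  expect_equal(twice[, c("t", "d", "v")], once[, c("t", "d", "v")])
})

test_that("reliability filtering drops low confidence and silent intervals", {
  trips <- data.frame(t = c(100L, 200L, 300L), d = c(25L, 25L, 25L),
                      v = c(0.05, 0.5, 0.6))
  attr(trips, "channel") <- "acc_x"
  x <- rep(0, 400); x[150:250] <- sin(1:101)  # only stride 2 has motion
  sig <- compound_signal(cbind(acc_x = x), fsamp = 25)

  expect_identical(filter_unreliable(trips, hv = 0, hr = 0)$t, trips$t)
  expect_identical(filter_unreliable(trips, hv = 0.11)$t, c(200L, 300L))
  out <- filter_unreliable(trips, hv = 0, hr = 0.5, signal = sig)
  expect_identical(out$t, 200L)
  # always a subset, order preserved
  out2 <- filter_unreliable(trips, hv = 0.11, hr = 0.5, signal = sig)
  expect_true(all(out2$t %in% trips$t) && !is.unsorted(out2$t))
})
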
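test_that("sample-level coverage matches brute-force labelling", {
  pred <- data.frame(onset = c(10, 50), send = c(30, 70))
  truth <- data.frame(onset = c(12, 48, 90), send = c(30, 65, 95))
  ell <- 100
  cov <- sequence_coverage(pred, truth, ell)
  counts <- oracle_coverage_counts(pred, truth, ell)
  expect_identical(c(tp = cov$tp, tn = cov$tn, fp = cov$fp, fn = cov$fn),
                   counts)
  expect_identical(cov$tp + cov$tn + cov$fp + cov$fn, as.integer(ell))

  perfect <- sequence_coverage(truth, truth, ell)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f_score, 1)

  none <- sequence_coverage(truth[0, ], data.frame(onset = 0, send = 49),
                            100)
  expect_identical(none$tp, 0L)
  expect_identical(none$fn, 50L)
  expect_identical(none$tn, 50L)
})

test_that("random interval sets agree with the per-sample oracle", {
  set.seed(19)
  for (rep in 1:10) {
    mk <- function(k) {
      on <- sort(sample(0:90, k))
      data.frame(onset = on, send = pmin(99, on + sample(3:20, k, TRUE)))
    }
    pred <- mk(3); truth <- mk(3)
    cov <- sequence_coverage(pred, truth, 100)
    counts <- oracle_coverage_counts(pred, truth, 100)
    expect_identical(c(tp = cov$tp, tn = cov$tn, fp = cov$fp, fn = cov$fn),
                     counts)
  }
})

test_that("stride matching applies the 100 ms tolerance and closest-wins rule", {
  # truth at 1.00 s, prediction at 1.05 s, 25 Hz: inside the tolerance
  m <- match_strides(pred = 26.25, truth = 25, fsamp = 25)
  expect_identical(m$tp, 1L)

  m2 <- match_strides(pred = c(25, 28), truth = 25, fsamp = 25)
  expect_identical(m2$tp, 1L)  # closest wins, the other is FP
  expect_identical(m2$fp, 1L)
  expect_identical(unname(m2$pairs[1, "pred"]), 1L)

  m3 <- match_strides(pred = c(rep(100, 8) + seq(0, 14, 2), 500, 600),
                      truth = c(rep(100, 8) + seq(0, 14, 2), 300, 400),
                      fsamp = 25)
  expect_identical(c(m3$tp, m3$fp, m3$fn), c(8L, 2L, 2L))
  expect_equal(m3$precision, 0.8)
  expect_equal(m3$recall, 0.8)
  expect_equal(m3$f_score, 0.8)
})

test_that("matching counts are conserved under random jitter", {
  set.seed(29)
  for (rep in 1:10) {
    truth <- cumsum(sample(25:40, 15, TRUE))
    pred <- sort(c(truth + sample(-2:2, 15, TRUE),
                   sample(1:500, 3)))
    m <- match_strides(pred, truth, 25)
    expect_identical(m$tp + m$fn, length(truth))
    expect_identical(m$tp + m$fp, length(pred))
    expect_lte(m$tp, length(truth))
    # greedy matcher agrees on totals with an exhaustive recount
    tol <- 2.5
    used <- logical(length(pred)); tp <- 0L
    for (tt in truth) {
      d <- abs(pred - tt); d[used] <- Inf
      if (min(d) <= tol) { used[which.min(d)] <- TRUE; tp <- tp + 1L }
    }
    expect_identical(m$tp, tp)
  }
})

test_that("timing accuracy reproduces closed-form statistics", {
  t <- timing_accuracy(pred_d = c(24, 26, 25, 25),
                       truth_d = c(25, 25, 25, 25))
  expect_equal(t$ae$mean, 0.5)
  expect_equal(t$bland_altman$mean_diff, 0)
  expect_equal(t$bland_altman$rpc, 1.96 * sd(c(1, -1, 0, 0)))

  self <- timing_accuracy(1:10, 1:10, pred_t = 1:10, truth_t = 1:10)
  expect_equal(self$ae$mean, 0)
  expect_equal(self$regression$r_squared, 1)
  expect_equal(self$bland_altman$rpc, 0)
  expect_equal(self$bias$mean, 0)

  expect_equal(timing_accuracy(c(0, 0, 1, 1, 2) + 10,
                               rep(10, 5))$ae$p95, 2)

  few <- timing_accuracy(5, 6)
  expect_equal(few$ae$mean, 1)
  expect_true(is.na(few$bland_altman$rpc))
})

test_that("regression and agreement track a known linear relation", {
  set.seed(41)
  truth <- runif(60, 20, 45)
  pred <- truth + rnorm(60, 0, 0.5)
  t <- timing_accuracy(pred, truth, pred_t = pred + 0.3, truth_t = pred)
  fit <- lm(pred ~ truth)
  expect_equal(t$regression$r_squared, summary(fit)$r.squared)
  expect_equal(t$regression$sse, sum(residuals(fit)^2))
  d <- truth - pred
  expect_equal(t$bland_altman$rpc, 1.96 * sd(d))
  expect_equal(t$bland_altman$cv, sd(d) / mean((truth + pred) / 2))
  expect_equal(t$bias$mean, 0.3)
})

test_that("threshold selection finds the precision/recall intersection", {
  grid <- seq(0, 1, by = 0.01)
  sw <- data.frame(hv = grid, precision = grid, recall = 1 - grid,
                   f_score = NA)
  sel <- select_threshold(list(sw))
  expect_equal(sel$hv, 0.5)
  expect_equal(sel$sd, 0)

  # monotone curves crossing once: the optimum brackets the crossing
  sw2 <- data.frame(hv = grid, precision = pmin(1, grid * 1.7),
                    recall = pmax(0, 1 - grid * 1.3), f_score = NA)
  sel2 <- select_threshold(list(sw2, sw2))
  cross <- 1 / 3
  expect_lte(abs(sel2$per_trial[1] - cross), 0.01)
  expect_equal(sel2$sd, 0)

  flat <- data.frame(hv = grid, precision = 0.5, recall = 0.5,
                     f_score = NA)
  expect_warning(s3 <- select_threshold(list(flat)), "degenerate")
  expect_equal(s3$hv, flat$hv[ceiling(length(grid) / 2)])
})

test_that("threshold sweep refilters strides against the truth", {
  strides <- data.frame(t = c(100, 130, 160, 300), v = c(0.9, 0.8, 0.2, 0.1))
  truth <- c(100, 130, 160)
  sw <- threshold_sweep(strides, truth, fsamp = 25)
  expect_equal(sw$recall[sw$hv == 0], 1)
  expect_equal(sw$precision[sw$hv == 0], 0.75)
  expect_equal(sw$recall[sw$hv == 0.5], 2 / 3)
  expect_equal(sw$precision[sw$hv == 0.5], 1)
})
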
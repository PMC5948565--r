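const_track2 <- function(g, ell) {
  structure(list(g = rep(as.integer(g), ell), centers = 0L, ell = ell),
            class = "stride_time_track")
}

test_that("reference selection favours the component matching the track", {
  track <- const_track2(50, 2000)
  good <- data.frame(t = seq(100L, 600L, by = 50L), d = 50L, v = 0.5)
  bad <- data.frame(t = seq(100L, 580L, by = 40L), d = 40L, v = 0.5)
  ref <- select_reference(list(a = good, b = bad), track)
  expect_identical(as.character(ref), "a")
  scores <- attr(ref, "scores")
  expect_equal(unname(scores["a"]), 0)
  expect_equal(unname(scores["b"]), 10)

  expect_identical(as.character(select_reference(list(only = good), track)),
                   "only")
  expect_identical(
    as.character(select_reference(list(a = good, b = bad), track,
                                  manual = "b")), "b")
  one <- data.frame(t = 100L, d = 50L, v = 0.5)
  expect_error(select_reference(list(a = one), track), "two strides")
})

test_that("reference scores equal direct recomputation on noisy components", {
  set.seed(21)
  track <- const_track2(30, 2000)
  comps <- lapply(1:3, function(i) {
    t <- cumsum(c(100L, sample(25:35, 10, replace = TRUE)))
    data.frame(t = t, d = 30L, v = 0.5)
  })
  names(comps) <- c("a", "b", "c")
  ref <- select_reference(comps, track)
  manual <- vapply(comps, function(tr)
    mean(abs(30 - diff(tr$t))), numeric(1))
  expect_identical(as.character(ref), names(which.min(manual)))
  expect_equal(attr(ref, "scores"), manual)
})

test_that("sparse confidence vectors conserve stride mass", {
  trips <- data.frame(t = c(5L, 10L, 10L), v = c(0.5, 0.3, 0.2))
  r <- build_sparse(trips, 20)
  expect_equal(r[6], 0.5)
  expect_equal(r[11], 0.5)  # collisions sum
  expect_equal(sum(r), sum(trips$v))
  expect_equal(build_sparse(trips[0, ], 20), rep(0, 20))
  expect_error(build_sparse(data.frame(t = 25L, v = 1), 20), "outside")
})

test_that("alignment recovers injected lags on clean and jittered trains", {
  ell <- 1500
  set.seed(8)
  pos <- cumsum(c(120L, sample(25:30, 30, replace = TRUE)))
  pos <- pos[pos < ell - 120]
  vals <- runif(length(pos), 0.3, 0.9)
  ref <- spike_train(pos, vals, ell)

  for (lag in c(-50L, -17L, 0L, 5L, 50L)) {
    other <- spike_train(pos + lag, vals, ell)
    al <- align_sparse(ref, other, Nmax = 50)
    expect_identical(al$lags, lag)
    expect_equal(al$aligned, ref)
  }

  # +-1 sample jitter: recovered within one sample (20 seeds)
  for (s in 1:20) {
    set.seed(100 + s)
    jit <- sample(-1:1, length(pos), replace = TRUE)
    other <- spike_train(pos + 7L + jit, vals, ell)
    al <- align_sparse(ref, other, Nmax = 50)
    expect_lte(abs(al$lags - 7L), 1L)
  }

  expect_warning(align_sparse(ref, numeric(ell), 50), "zero-energy")
})

test_that("single-component fusion passes stride positions through", {
  cfg <- cyclicity_config(25)
  trips <- data.frame(t = seq(100L, 400L, by = 27L), v = 0.6)
  r <- build_sparse(trips, 600)
  fz <- fuse_and_enhance(list(r), cfg)
  expect_identical(fz$strides$t, trips$t)
  di <- fz$strides$d
  expect_true(all(di[!is.na(di)] == 27L))
  expect_true(all(is.na(di) | (di >= cfg$Nmin & di <= cfg$Nmax)))
})

test_that("agreeing components reinforce and a lone spurious stride is dropped", {
  cfg <- cyclicity_config(25)
  pos <- seq(100L, 500L, by = 27L)
  a <- build_sparse(data.frame(t = pos, v = 0.6), 700)
  b <- build_sparse(data.frame(t = pos, v = 0.5), 700)
  both <- fuse_and_enhance(list(a, b), cfg)
  alone <- fuse_and_enhance(list(a), cfg)
  expect_identical(both$strides$t, pos)
  expect_gt(min(both$strides$v), max(alone$strides$v))  # superposition

  spur <- build_sparse(data.frame(t = c(pos, 650L),
                                  v = c(rep(0.6, length(pos)), 0.08)), 700)
  fz <- fuse_and_enhance(list(spur, build_sparse(
    data.frame(t = pos, v = 0.5), 700)), cfg)
  expect_false(650L %in% fz$strides$t)
  expect_identical(fz$strides$t, pos)
})

test_that("fusion preserves stride count on noiseless agreeing components", {
  for (s in 1:5) {
    set.seed(s)
    cfg <- cyclicity_config(25)
    pos <- cumsum(c(100L, sample(22:45, 12, replace = TRUE)))
    vecs <- lapply(1:3, function(i)
      build_sparse(data.frame(t = pos, v = runif(length(pos), 0.4, 0.8)),
                   max(pos) + 100))
    fz <- fuse_and_enhance(vecs, cfg)
    expect_identical(fz$strides$t, pos)
    di <- fz$strides$d
    expect_true(all(is.na(di) | (di >= cfg$Nmin & di <= cfg$Nmax)))
  }
})

test_that("component sequences merge best-first into a covering span set", {
  seqs <- list(
    a = data.frame(sequence = 1:2, onset = c(0, 300), send = c(100, 400),
                   reliability = c(0.5, 0.2)),
    b = data.frame(sequence = 1, onset = 80, send = 320,
                   reliability = 1.5))
  merged <- strideseg:::merge_component_sequences(seqs)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$onset, 0)
  expect_equal(merged$send, 400)
  expect_equal(merged$reliability, 0.2)
})
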
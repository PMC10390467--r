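makeTrace <- function(rfu, cond = "a", rep = 1, batch = 1,
                      times = seq_along(rfu) * 300 - 300) {
  data.frame(time_s = times, condition = cond, replicate = rep,
             batch = batch, rfu = rfu)
}

test_that("Gaussian smoothing preserves constants, length and the sigma -> 0
           limit", {
  tr <- makeTrace(rep(7, 30))
  sm <- smoothTraces(tr, sigma = 3)
  expect_equal(sm$rfu, rep(7, 30), tolerance = 1e-9)
  expect_equal(nrow(sm), 30)
  y <- sin(seq(0, 3, length.out = 40))
  tr2 <- makeTrace(y)
  expect_equal(smoothTraces(tr2, sigma = 1e-9)$rfu, y, tolerance = 1e-9)
})

test_that("an impulse maps to the normalized discrete Gaussian kernel", {
  y <- c(rep(0, 20), 1, rep(0, 20))
  sm <- smoothTraces(makeTrace(y), sigma = 2)$rfu
  expect_equal(sum(sm), 1, tolerance = 1e-9)       # unit mass
  expect_equal(which.max(sm), 21)
  r <- ceiling(4 * 2)
  k <- dnorm(seq(-r, r), sd = 2); k <- k / sum(k)
  expect_equal(sm[(21 - r):(21 + r)], k, tolerance = 1e-9)
})

test_that("background subtraction removes the replicate-mean negative trace
           and is shift invariant", {
  set.seed(101)
  neg1 <- makeTrace(rnorm(20, 100, 1), "neg", 1)
  neg2 <- makeTrace(rnorm(20, 100, 1), "neg", 2)
  sig <- makeTrace(100 + (1:20), "a", 1)
  tr <- rbind(sig, neg1, neg2)
  out <- subtractBackground(tr, "neg")
  negOut <- out[out$condition == "neg", ]
  expect_equal(mean(negOut$rfu), 0, tolerance = 1e-9)
  # hand subtraction for the signal trace
  bg <- (neg1$rfu + neg2$rfu) / 2
  expect_equal(out$rfu[out$condition == "a"], sig$rfu - bg,
               tolerance = 1e-12)
  shifted <- tr; shifted$rfu <- shifted$rfu + 42
  out2 <- subtractBackground(shifted, "neg")
  expect_equal(out2$rfu, out$rfu, tolerance = 1e-9)
  expect_error(subtractBackground(tr, "missing"), "not present")
})

test_that("a linear trace yields its slope with a full-trace window", {
  tt <- seq(0, 9000, by = 300)
  r <- maxRate(tt, 0.02 * tt)
  expect_equal(r$rate, 0.02, tolerance = 1e-9)
  expect_equal(r$window, c(0, 9000))
  expect_true(r$expressing)
})

test_that("logistic traces recover the analytic windowed-mean rate within
           5%", {
  L <- 1000; k <- 5e-4; t0 <- 10000
  tt <- seq(0, 43200, by = 300)
  y <- L / (1 + exp(-k * (tt - t0)))
  r <- maxRate(tt, y)
  expect_lt(abs(r$rate / (L * k / 4 * logisticWindowFactor(0.5)) - 1), 0.05)
  # the window contains the inflection point
  expect_true(r$window[1] <= t0 && t0 <= r$window[2])
})

test_that("across thresholds 0.3-0.7 the estimator tracks its analytic
           per-threshold value and normalized rates barely move", {
  L <- 800; k <- 4e-4; t0 <- 12000
  tt <- seq(0, 43200, by = 300)
  y <- L / (1 + exp(-k * (tt - t0)))
  for (th in seq(0.3, 0.7, by = 0.1)) {
    r <- maxRate(tt, y, threshold = th)$rate
    expect_lt(abs(r / (L * k / 4 * logisticWindowFactor(th)) - 1), 0.05)
  }
  # normalized (reference-relative) rates are threshold-robust
  y2 <- 0.66 * y
  ratio <- vapply(seq(0.3, 0.7, by = 0.1), function(th)
    maxRate(tt, y2, threshold = th)$rate / maxRate(tt, y, threshold = th)$rate,
    numeric(1))
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.10)
})

test_that("non-expressing traces are flagged with rate 0", {
  tt <- seq(0, 6000, by = 300)
  r <- maxRate(tt, -0.01 * tt)
  expect_false(r$expressing)
  expect_equal(r$rate, 0)
})

test_that("batch normalization maps reference means to 1 and is scale
           invariant", {
  rates <- data.frame(
    condition = c("ref", "ref", "x", "ref", "x"),
    replicate = c(1, 2, 1, 1, 1),
    batch = c(1, 1, 1, 2, 2),
    rate = c(2, 4, 1.5, 10, 4))
  out <- normalizeByBatch(rates, "ref")
  expect_equal(mean(out$normalized_rate[out$condition == "ref" &
                                          out$batch == 1]), 1)
  expect_equal(out$normalized_rate[out$condition == "x" & out$batch == 1],
               0.5)
  expect_equal(out$normalized_rate[out$condition == "x" & out$batch == 2],
               0.4)
  scaled <- rates
  scaled$rate[scaled$batch == 1] <- scaled$rate[scaled$batch == 1] * 7
  out2 <- normalizeByBatch(scaled, "ref")
  expect_equal(out2$normalized_rate, out$normalized_rate, tolerance = 1e-12)
  expect_error(normalizeByBatch(rates[rates$condition != "ref", ], "ref"),
               "missing")
})

test_that("KS comparisons: identical samples give D = 0, disjoint give
           D = 1", {
  x <- c(1, 2, 3)
  expect_equal(ksCompare(x, x, "two")$statistic, 0)
  r <- ksCompare(c(4, 5, 6), c(1, 2, 3), "two")
  expect_equal(r$statistic, 1)
  expect_error(ksCompare(1, c(1, 2)), ">= 2")
})

test_that("small-sample KS p-values match exact permutation enumeration", {
  ksD <- function(a, b, one) {
    z <- sort(c(a, b)); ea <- ecdf(a); eb <- ecdf(b)
    if (one) max(eb(z) - ea(z)) else max(abs(ea(z) - eb(z)))
  }
  permP <- function(a, b, one) {
    z <- c(a, b); idx <- combn(length(z), length(a))
    obs <- ksD(a, b, one); cnt <- 0
    for (j in seq_len(ncol(idx))) {
      if (ksD(z[idx[, j]], z[-idx[, j]], one) >= obs - 1e-12) cnt <- cnt + 1
    }
    cnt / ncol(idx)
  }
  set.seed(103)
  for (rep in 1:5) {
    a <- sample(1:1000, 4); b <- sample(1001:2000, 5) - 500.5
    expect_equal(ksCompare(a, b, "two")$p.value, permP(a, b, FALSE),
                 tolerance = 1e-9)
    expect_equal(ksCompare(a, b, "one")$p.value, permP(a, b, TRUE),
                 tolerance = 1e-9)
  }
})

test_that("the pipeline is deterministic on a fixed input table", {
  gen <- makeTraces(seed = 7)
  r1 <- normalizeByBatch(extractRates(gen$traces, "neg"), "synFast")
  r2 <- normalizeByBatch(extractRates(gen$traces, "neg"), "synFast")
  expect_identical(r1, r2)
})
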
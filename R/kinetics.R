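# Fluorescence-kinetics pipeline: Gaussian smoothing, background
# subtraction, derivative-based maximal-rate extraction, batch
# normalization and Kolmogorov-Smirnov comparisons.

# Gaussian filter with reflect boundary handling; sigma in samples.
.gaussianSmooth <- function(y, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  n <- length(y)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  # reflect-pad (mirror without repeating the edge sample where possible)
  pre <- y[pmin(pmax(seq(r + 1, 2), 1), n)]
  post <- y[pmax(pmin(seq(n - 1, n - r), n), 1)]
  yp <- c(pre, y, post)
  as.numeric(stats::filter(yp, k, sides = 2))[(r + 1):(r + n)]
}

#' Gaussian-smooth fluorescence traces
#'
#' Convolves each (condition, replicate, batch) trace's RFU signal with a
#' normalized discrete Gaussian kernel, reflect boundary handling, length
#' preserved. In the `sigma -> 0` limit the trace is returned unchanged.
#'
#' @param traces trace data.frame (see [validateTraces()]).
#' @param sigma kernel SD in samples (default 2).
#' @return The data.frame with `rfu` replaced by the smoothed signal.
#' @export
smoothTraces <- function(traces, sigma = 2) {
  traces <- validateTraces(traces)
  key <- interaction(traces$condition, traces$replicate, traces$batch,
                     drop = TRUE)
  for (k in levels(key)) {
    i <- which(key == k)
    traces$rfu[i] <- .gaussianSmooth(traces$rfu[i], sigma)
  }
  traces
}

#' Subtract the negative-control background
#'
#' Averages the (already smoothed) traces of the negative-control condition
#' across replicates, per batch and time point, and subtracts that mean
#' background trace from every trace in the same batch.
#'
#' @param traces smoothed trace data.frame.
#' @param negativeCondition label of the no-expression control (e.g. the
#'   PUREdeltatRNA blank).
#' @return The background-subtracted data.frame.
#' @export
subtractBackground <- function(traces, negativeCondition) {
  traces <- validateTraces(traces)
  if (!negativeCondition %in% traces$condition)
    stop("negative condition not present: ", negativeCondition)
  for (b in unique(traces$batch)) {
    ib <- traces$batch == b
    neg <- traces[ib & traces$condition == negativeCondition, ]
    if (nrow(neg) == 0)
      stop("negative condition missing in batch ", b)
    bg <- tapply(neg$rfu, neg$time_s, mean)
    idx <- which(ib)
    tkey <- as.character(traces$time_s[idx])
    if (any(!tkey %in% names(bg)))
      stop("background trace does not cover all time points in batch ", b)
    traces$rfu[idx] <- traces$rfu[idx] - as.numeric(bg[tkey])
  }
  traces
}

# Central-difference derivative on a uniform grid, one-sided endpoints.
.derivative <- function(tt, y) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (tt[2] - tt[1])
  d[n] <- (y[n] - y[n - 1]) / (tt[n] - tt[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  d
}

#' Maximal protein-synthesis rate of one trace
#'
#' Computes the central-difference derivative of a background-subtracted
#' trace, smooths it with a Gaussian filter, finds the maximal contiguous
#' window containing the derivative's argmax where the derivative stays at
#' or above `threshold` times its maximum (both before and after the max),
#' and reports the mean derivative over that window. Traces whose maximal
#' derivative is not positive are flagged non-expressing with rate 0.
#'
#' @param time_s,rfu one trace's time (s) and background-subtracted RFU.
#' @param threshold window threshold as a fraction of the max (default 0.5).
#' @param sigmaD Gaussian SD for derivative smoothing, samples (default 2).
#' @return List: `rate` (RFU/s), `window` (`c(tStart, tEnd)` s),
#'   `expressing`, `threshold`.
#' @export
maxRate <- function(time_s, rfu, threshold = 0.5, sigmaD = 2) {
  if (length(time_s) < 10) stop("trace too short for rate extraction")
  d <- .gaussianSmooth(.derivative(time_s, rfu), sigmaD)
  dmax <- max(d)
  if (dmax <= 0)
    return(list(rate = 0, window = c(NA_real_, NA_real_),
                expressing = FALSE, threshold = threshold))
  peak <- which.max(d)
  above <- d >= threshold * dmax
  lo <- peak
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < length(d) && above[hi + 1]) hi <- hi + 1
  list(rate = mean(d[lo:hi]), window = c(time_s[lo], time_s[hi]),
       expressing = TRUE, threshold = threshold)
}

#' Analytic windowed-mean factor for logistic traces
#'
#' For a logistic accumulation trace `L / (1 + exp(-k (t - t0)))` the
#' derivative is the self-similar bump `(L k / 4) sech^2(k (t - t0) / 2)`,
#' so the mean of the derivative over the region at or above
#' `threshold * max` is analytically `L k / 4 * tanh(u) / u` with
#' `u = atanh(sqrt(1 - threshold))`. This factor (about 0.802 at the default
#' threshold 0.5) is the exact expected value of [maxRate()] on a noiseless,
#' densely sampled logistic trace, and the oracle the tests compare against.
#'
#' @param threshold window threshold, fraction of the derivative maximum.
#' @return The dimensionless factor `tanh(u)/u` in (0, 1).
#' @export
logisticWindowFactor <- function(threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  u <- atanh(sqrt(1 - threshold))
  tanh(u) / u
}

#' Extract maximal rates for every trace
#'
#' Runs the full per-trace pipeline — smoothing, per-batch background
#' subtraction, derivative-window rate extraction — over a long-format
#' plate-reader table.
#'
#' @param traces raw trace data.frame (see [validateTraces()]).
#' @param negativeCondition negative-control condition label.
#' @param sigma trace-smoothing Gaussian SD, samples.
#' @param sigmaD derivative-smoothing Gaussian SD, samples.
#' @param threshold rate-window threshold, fraction of max derivative.
#' @param keepNegative keep rows for the negative control in the output.
#' @return data.frame: condition, replicate, batch, rate (RFU/s), t_start,
#'   t_end, expressing, threshold.
#' @export
extractRates <- function(traces, negativeCondition, sigma = 2, sigmaD = 2,
                         threshold = 0.5, keepNegative = FALSE) {
  sm <- smoothTraces(traces, sigma)
  bs <- subtractBackground(sm, negativeCondition)
  if (!keepNegative) bs <- bs[bs$condition != negativeCondition, ]
  groups <- unique(bs[, c("condition", "replicate", "batch")])
  res <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    tr <- bs[bs$condition == g$condition & bs$replicate == g$replicate &
               bs$batch == g$batch, ]
    r <- maxRate(tr$time_s, tr$rfu, threshold, sigmaD)
    data.frame(condition = g$condition, replicate = g$replicate,
               batch = g$batch, rate = r$rate, t_start = r$window[1],
               t_end = r$window[2], expressing = r$expressing,
               threshold = threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Normalize rates by a reference condition within each batch
#'
#' Divides every rate by the mean rate of the reference condition in the
#' same batch, so the reference's batch means map to exactly 1.
#'
#' @param rates data.frame from [extractRates()].
#' @param referenceCondition label present in every batch (e.g. synFast).
#' @return `rates` with an added `normalized_rate` column.
#' @export
normalizeByBatch <- function(rates, referenceCondition) {
  rates$normalized_rate <- NA_real_
  for (b in unique(rates$batch)) {
    ib <- rates$batch == b
    ref <- rates$rate[ib & rates$condition == referenceCondition]
    if (!length(ref)) stop("reference condition missing in batch ", b)
    rates$normalized_rate[ib] <- rates$rate[ib] / mean(ref)
  }
  rates
}

#' Kolmogorov-Smirnov comparison of two rate samples
#'
#' Two-sided, or one-sided testing whether sample `a` is stochastically
#' greater than `b` (the alternative that a's CDF lies below b's). Exact
#' small-sample p-values are used when there are no ties.
#'
#' @param a,b numeric samples (>= 2 values each).
#' @param sided `"one"` or `"two"`.
#' @return List with `statistic` (D) and `p.value`.
#' @export
ksCompare <- function(a, b, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per sample")
  alt <- if (sided == "one") "less" else "two.sided"
  res <- suppressWarnings(stats::ks.test(a, b, alternative = alt,
                                         exact = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}
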
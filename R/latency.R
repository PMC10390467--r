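# Single-codon elongation-latency kernel: Markov surrogate (closed form and
# Monte Carlo) plus component-latency table backend.
#
# Model: an elongating ribosome samples ternary complexes (TCs) at mean
# interval tauTransport. With n_c cognate and n_nc non-cognate TCs in the
# voxel, an encounter is cognate with probability q = n_c / (n_c + n_nc).
# Cognate encounters succeed with probability pSuccess (duration tauSuccess)
# or fail (tauCognateFail); non-cognate encounters always fail (tauReject).
# The elongation latency is the total time until the first success.

#' Closed-form expected single-codon latency
#'
#' With `q = n_c / (n_c + n_nc)` and per-encounter success probability
#' `p = q * pSuccess`, the number of encounters is geometric with mean `1/p`,
#' and each failed encounter costs the transport time plus the
#' failure-type-conditional reaction time, giving
#' \deqn{E[T] = (1/p - 1)\,(\tau_t + \frac{q(1-p_s)\tau_{cf} + (1-q)\tau_r}{1-p})
#'   + \tau_t + \tau_s.}
#' When `p = 1` there are no failed encounters and the latency is
#' `tauTransport + tauSuccess`.
#'
#' @param nC cognate TC count (>= 1; the zero-cognate folding rule belongs to
#'   the voxel sampler, not the kernel).
#' @param nNC non-cognate TC count (>= 0).
#' @param params a [SurrogateKineticParams-class].
#' @return Expected latency in ms (vectorized over `nC`/`nNC`).
#' @examples
#' p <- SurrogateKineticParams(1, 1, 1, 1, 1)
#' expectedLatencyClosedForm(1, 1, p)  # 4 ms
#' @export
expectedLatencyClosedForm <- function(nC, nNC, params = SurrogateKineticParams()) {
  stopifnot(is(params, "SurrogateKineticParams"))
  n <- max(length(nC), length(nNC))
  nC <- rep_len(nC, n); nNC <- rep_len(nNC, n)
  if (any(nC < 1)) stop("nC must be >= 1 (zero-cognate voxels are folded by the sampler)")
  if (any(nNC < 0)) stop("nNC must be >= 0")
  q <- nC / (nC + nNC)
  ps <- params@pSuccess
  p <- q * ps
  fail <- ifelse(p >= 1, 0,
    (params@tauTransport +
       (q * (1 - ps) * params@tauCognateFail + (1 - q) * params@tauReject) /
       (1 - p)) * (1 / p - 1))
  fail + params@tauTransport + params@tauSuccess
}

#' Monte-Carlo single-codon latency
#'
#' Samples the surrogate renewal process: for each voxel sample, the number
#' of encounters until first success is geometric in the per-encounter
#' success probability, and the failed encounters split between cognate
#' failures and non-cognate rejections binomially with the conditional
#' failure-type probability (an exact, vectorized equivalent of drawing each
#' encounter's type Bernoulli(q) and success Bernoulli(pSuccess) one by one).
#'
#' @inheritParams expectedLatencyClosedForm
#' @param nSamples number of voxel samples (>= 1).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return List with `mean`, `sd`, `se` (ms) and `nSamples`.
#' @export
simulateLatencyMC <- function(nC, nNC, params = SurrogateKineticParams(),
                              nSamples = 1e5, seed = 1L) {
  stopifnot(is(params, "SurrogateKineticParams"), nSamples >= 1,
            length(nC) == 1, length(nNC) == 1)
  if (nC < 1) stop("nC must be >= 1")
  if (nNC < 0) stop("nNC must be >= 0")
  q <- nC / (nC + nNC)
  ps <- params@pSuccess
  p <- q * ps
  samples <- .withSeed(seed, {
    fails <- if (p >= 1) rep(0L, nSamples) else stats::rgeom(nSamples, p)
    pcf <- if (p >= 1) 0 else q * (1 - ps) / (1 - p) # P(cognate fail | fail)
    nCF <- stats::rbinom(nSamples, fails, pcf)
    (fails + 1) * params@tauTransport + nCF * params@tauCognateFail +
      (fails - nCF) * params@tauReject + params@tauSuccess
  })
  list(mean = mean(samples), sd = stats::sd(samples),
       se = stats::sd(samples) / sqrt(nSamples), nSamples = nSamples)
}

#' Look up a component latency, interpolating absent keys
#'
#' Exact-key lookup in a [ComponentLatencyTable-class]. If the key is absent,
#' the latency is linearly interpolated on cognate fraction between the
#' nearest bracketing entries at the nearest available voxel total (with a
#' message); extrapolation beyond the table range is an error.
#'
#' @param nC,nNC cognate / non-cognate counts (scalars).
#' @param tab a [ComponentLatencyTable-class].
#' @return Latency in ms.
#' @export
tableLatency <- function(nC, nNC, tab) {
  stopifnot(is(tab, "ComponentLatencyTable"), length(nC) == 1,
            length(nNC) == 1)
  if (length(tab@latencyMs) == 0) stop("empty latency table")
  hit <- which(tab@cognateCount == nC & tab@noncognateCount == nNC)
  if (length(hit)) return(tab@latencyMs[hit[1]])
  tot <- tab@cognateCount + tab@noncognateCount
  target <- nC + nNC
  useTot <- unique(tot)[which.min(abs(unique(tot) - target))]
  i <- which(tot == useTot)
  f <- tab@cognateCount[i] / useTot
  x <- nC / target
  if (x < min(f) || x > max(f))
    stop(sprintf("cognate fraction %.4f outside table range [%.4f, %.4f]",
                 x, min(f), max(f)))
  o <- order(f)
  message(sprintf("tableLatency: interpolating (%d, %d) at total %d",
                  nC, nNC, useTot))
  stats::approx(f[o], tab@latencyMs[i][o], xout = x, ties = mean)$y
}

#' Build a component-latency table from the surrogate closed form
#'
#' Tabulates [expectedLatencyClosedForm()] over all cognate counts 1..K for a
#' fixed voxel total K, in the shipped TSV dialect.
#'
#' @param K voxel total TC count.
#' @param params a [SurrogateKineticParams-class].
#' @return A [ComponentLatencyTable-class].
#' @export
surrogateLatencyTable <- function(K = 42L, params = SurrogateKineticParams()) {
  nC <- seq_len(K)
  new("ComponentLatencyTable", cognateCount = as.integer(nC),
      noncognateCount = as.integer(K - nC),
      latencyMs = expectedLatencyClosedForm(nC, K - nC, params),
      metadata = list(totalTC = as.character(K), source = "surrogate"))
}

#' Component-latency kernels
#'
#' A kernel is a function `(nC, nNC) -> latency ms` consumed by the post-hoc
#' estimator. `surrogateKernel()` wraps the closed-form Markov surrogate;
#' `tableKernel()` wraps a pre-computed [ComponentLatencyTable-class].
#'
#' @param params a [SurrogateKineticParams-class].
#' @return A vectorized kernel function.
#' @export
surrogateKernel <- function(params = SurrogateKineticParams()) {
  force(params)
  function(nC, nNC) expectedLatencyClosedForm(nC, nNC, params)
}

#' @rdname surrogateKernel
#' @param tab a [ComponentLatencyTable-class].
#' @export
tableKernel <- function(tab) {
  force(tab)
  function(nC, nNC) {
    n <- max(length(nC), length(nNC))
    nC <- rep_len(nC, n); nNC <- rep_len(nNC, n)
    vapply(seq_len(n), function(i) tableLatency(nC[i], nNC[i], tab),
           numeric(1))
  }
}
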
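# Post-hoc elongation-latency estimator: the five-step procedure mapping
# (distribution, cognate map, transcriptome) to per-codon, per-transcript and
# transcriptome-average latencies.
#
#  1. per codon, Monte-Carlo sample voxel cognate:non-cognate TC ratios from
#     the tRNA distribution (zero-cognate voxels folded to one cognate);
#  2. per codon, latency = pmf-weighted sum of component latencies;
#  3. per transcript, relative codon frequencies;
#  4. per transcript, latency = codon-frequency-weighted mean of (2);
#  5. transcriptome latency = expression-weighted mean over transcripts.

#' Sample cognate:non-cognate voxel ratios for a codon
#'
#' Draws `M` voxel compositions of `K` ternary complexes from the tRNA
#' distribution and records, for the given codon, the empirical pmf over
#' (cognate count, non-cognate count). Only the codon's cognate-count
#' marginal of the multinomial draw is needed, so sampling uses
#' Binomial(K, f) with f the codon's cognate abundance fraction — exactly
#' the marginal law of the full multinomial. Voxels with zero cognates are
#' recorded as having one cognate (and K - 1 non-cognates): a specified
#' distribution is required to keep every codon translatable, so the
#' zero-cognate state is approximated by the minimal translating voxel.
#'
#' @param d a [TRNADistribution-class].
#' @param m a [CognateMap-class].
#' @param codon a codon present in `codons(m)`.
#' @param cfg a [VoxelSamplingConfig-class].
#' @return data.frame with columns `nC`, `nNC`, `prob` (summing to 1).
#' @export
sampleCognateRatios <- function(d, m, codon, cfg = VoxelSamplingConfig()) {
  stopifnot(is(cfg, "VoxelSamplingConfig"))
  if (!codon %in% m@codons) stop("codon absent from cognate map: ", codon)
  f <- cognateFractionPerCodon(d, m)[[codon]]
  .sampleRatiosFromFraction(f, cfg)
}

# Shared core: empirical pmf of cognate counts for cognate fraction f.
.sampleRatiosFromFraction <- function(f, cfg) {
  counts <- .withSeed(cfg@seed, stats::rbinom(cfg@M, cfg@K, f))
  counts[counts == 0L] <- 1L  # zero-cognate folding rule
  tb <- table(counts)
  nC <- as.integer(names(tb))
  data.frame(nC = nC, nNC = cfg@K - nC, prob = as.numeric(tb) / cfg@M)
}

#' Expected latency of one codon from its voxel-ratio pmf
#'
#' @param pmf data.frame as returned by [sampleCognateRatios()].
#' @param kernel a kernel function `(nC, nNC) -> ms`, e.g.
#'   [surrogateKernel()] or [tableKernel()].
#' @return Expected latency, ms.
#' @export
codonLatency <- function(pmf, kernel) {
  if (nrow(pmf) == 0) stop("empty pmf")
  sum(pmf$prob * kernel(pmf$nC, pmf$nNC))
}

#' Expected per-step latency of a transcript
#'
#' Codon-frequency-weighted mean of per-codon latencies: the expected
#' latency per elongation step of the transcript.
#'
#' @param sequence in-frame CDS (character or `DNAString`).
#' @param perCodon named numeric of per-codon latencies, ms.
#' @param id transcript id used in error messages.
#' @return Latency, ms.
#' @export
transcriptLatency <- function(sequence, perCodon, id = "transcript") {
  cod <- .splitCodons(sequence)
  missing <- setdiff(unique(cod), names(perCodon))
  if (length(missing))
    stop("no latency for codon(s) ", paste(missing, collapse = ", "),
         " in ", id)
  mean(perCodon[cod])
}

#' Transcriptome-wide elongation-latency report
#'
#' Runs the full post-hoc procedure. Per-codon latencies are computed once
#' (for every codon of the map) and reused across transcripts; the
#' transcriptome mean and SD are expression-weighted across transcripts.
#' Deterministic for a fixed `cfg@seed`.
#'
#' @param t a [Transcriptome-class].
#' @param d a [TRNADistribution-class].
#' @param m a [CognateMap-class].
#' @param kernel kernel function `(nC, nNC) -> ms`.
#' @param cfg a [VoxelSamplingConfig-class].
#' @return A [LatencyReport-class].
#' @export
transcriptomeLatency <- function(t, d, m, kernel = surrogateKernel(),
                                 cfg = VoxelSamplingConfig()) {
  stopifnot(is(t, "Transcriptome"))
  checkCodonAlphabet(t, m)
  fractions <- cognateFractionPerCodon(d, m)
  # one independent substream per codon, derived deterministically from cfg
  perCodon <- vapply(seq_along(m@codons), function(i) {
    sub <- methods::new("VoxelSamplingConfig", K = cfg@K, M = cfg@M,
                        seed = as.integer((cfg@seed + i * 7919L) %% .Machine$integer.max))
    codonLatency(.sampleRatiosFromFraction(fractions[[i]], sub), kernel)
  }, numeric(1))
  names(perCodon) <- m@codons
  perTx <- vapply(seq_along(t@ids), function(i)
    transcriptLatency(t@sequences[[i]], perCodon, t@ids[i]), numeric(1))
  names(perTx) <- t@ids
  ms <- .weightedMeanSD(perTx, t@expression)
  new("LatencyReport", perCodon = perCodon, perTranscript = perTx,
      transcriptomeMean = ms[["mean"]], transcriptomeSD = ms[["sd"]],
      config = list(K = cfg@K, M = cfg@M, seed = cfg@seed))
}

#' Build a fast cached transcriptome-latency evaluator
#'
#' Pre-computes each transcript's codon frequencies once and memoizes the
#' transcriptome-average latency per distribution content, so that a genetic
#' algorithm evaluating thousands of distributions (many of them surviving
#' unchanged between generations) only pays for new individuals. Evaluations
#' are pure functions of the distribution (the voxel sampler re-seeds from
#' `cfg@seed` per call), so cached and fresh values agree exactly.
#'
#' @inheritParams transcriptomeLatency
#' @param cache memoize per distribution content (default TRUE).
#' @return A function `(d: TRNADistribution) -> transcriptome mean latency ms`.
#' @export
latencyEvaluator <- function(t, m, kernel = surrogateKernel(),
                             cfg = VoxelSamplingConfig(), cache = TRUE) {
  checkCodonAlphabet(t, m)
  counts <- .codonCountMatrix(t)
  freq <- counts / rowSums(counts)
  # expression-weighted; map codons aligned with freq columns
  cols <- match(colnames(freq), m@codons)
  w <- t@expression
  seeds <- as.integer((cfg@seed + seq_along(m@codons) * 7919L) %%
                        .Machine$integer.max)
  store <- new.env(parent = emptyenv())
  function(d) {
    key <- if (cache) .distSignature(d) else NULL
    if (!is.null(key) && !is.null(store[[key]])) return(store[[key]])
    fractions <- cognateFractionPerCodon(d, m)
    perCodon <- vapply(seq_along(m@codons), function(i) {
      sub <- methods::new("VoxelSamplingConfig", K = cfg@K, M = cfg@M,
                          seed = seeds[i])
      codonLatency(.sampleRatiosFromFraction(fractions[[i]], sub), kernel)
    }, numeric(1))
    perTx <- as.numeric(freq %*% perCodon[cols])
    val <- sum(w * perTx)
    if (!is.null(key)) store[[key]] <- val
    val
  }
}
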
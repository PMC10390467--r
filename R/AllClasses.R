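#' @import methods
#' @importFrom stats dnorm rbinom rgeom runif setNames var ks.test
#' @importFrom utils read.delim write.table head
NULL

.SUM_TOL <- 1e-9

#' Relative tRNA abundance distribution
#'
#' A named compositional vector: one relative abundance per tRNA species,
#' non-negative and summing to one. Optionally carries the total tRNA
#' concentration (in micromolar) that the relative abundances scale, e.g.
#' ~225 uM for in-silico translation voxels or 200 uM elongator tRNA for
#' in-vitro TINA reactions.
#'
#' @slot trna character vector of unique tRNA identifiers.
#' @slot abundance numeric vector of relative abundances (fractions of total).
#' @slot totalConcentration total tRNA concentration in uM, or `NA`.
#' @slot metadata list of free-form annotations (e.g. the raw pre-normalization
#'   vector for stepwise designs).
#' @exportClass TRNADistribution
setClass("TRNADistribution",
  representation(
    trna = "character",
    abundance = "numeric",
    totalConcentration = "numeric",
    metadata = "list"
  ),
  prototype(totalConcentration = NA_real_, metadata = list())
)

setValidity("TRNADistribution", function(object) {
  msg <- character()
  if (length(object@trna) != length(object@abundance))
    msg <- c(msg, "trna and abundance lengths differ")
  if (anyDuplicated(object@trna))
    msg <- c(msg, "tRNA names must be unique")
  if (length(object@abundance)) {
    if (any(!is.finite(object@abundance)) || any(object@abundance < 0))
      msg <- c(msg, "abundances must be finite and >= 0")
    else if (abs(sum(object@abundance) - 1) > .SUM_TOL)
      msg <- c(msg, sprintf("abundances must sum to 1 (got %.12f)",
                            sum(object@abundance)))
  } else msg <- c(msg, "distribution is empty")
  if (length(object@totalConcentration) != 1)
    msg <- c(msg, "totalConcentration must be a single value")
  if (length(msg)) msg else TRUE
})

#' Codon-tRNA cognate map
#'
#' Boolean matrix stating which tRNA species form a cognate ternary complex
#' for each sense codon. Every codon must have at least one cognate tRNA and
#' every tRNA at least one cognate codon. An optional amino-acid annotation
#' per tRNA supports tRNA-set reduction for reduced genetic codes.
#'
#' @slot trna character vector of tRNA identifiers (rows).
#' @slot codons character vector of sense codons, DNA alphabet (columns).
#' @slot cognate logical matrix, `trna` x `codons`.
#' @slot aa character vector of amino-acid annotations per tRNA (may be `NA`).
#' @exportClass CognateMap
setClass("CognateMap",
  representation(
    trna = "character",
    codons = "character",
    cognate = "matrix",
    aa = "character"
  )
)

setValidity("CognateMap", function(object) {
  msg <- character()
  if (!is.logical(object@cognate))
    msg <- c(msg, "cognate matrix must be logical")
  if (nrow(object@cognate) != length(object@trna) ||
      ncol(object@cognate) != length(object@codons))
    msg <- c(msg, "cognate matrix dimensions must match name lists")
  if (anyDuplicated(object@trna)) msg <- c(msg, "tRNA names must be unique")
  if (anyDuplicated(object@codons)) msg <- c(msg, "codons must be unique")
  if (!length(msg)) {
    if (any(colSums(object@cognate) == 0))
      msg <- c(msg, paste("codons with no cognate tRNA:",
        paste(object@codons[colSums(object@cognate) == 0], collapse = ", ")))
    if (any(rowSums(object@cognate) == 0))
      msg <- c(msg, paste("tRNA with no cognate codon:",
        paste(object@trna[rowSums(object@cognate) == 0], collapse = ", ")))
    if (length(object@aa) != length(object@trna))
      msg <- c(msg, "aa annotation length must match trna")
  }
  if (length(msg)) msg else TRUE
})

#' Weighted in-frame transcriptome
#'
#' In-frame coding sequences (stop codons already stripped) with relative
#' expression weights summing to one. Sequences are held as a
#' [Biostrings::DNAStringSet].
#'
#' @slot ids character vector of transcript identifiers.
#' @slot sequences `DNAStringSet` of in-frame CDS (length divisible by 3).
#' @slot expression numeric relative transcript frequencies, summing to 1.
#' @exportClass Transcriptome
setClass("Transcriptome",
  representation(
    ids = "character",
    sequences = "ANY",
    expression = "numeric"
  )
)

setValidity("Transcriptome", function(object) {
  msg <- character()
  if (!methods::is(object@sequences, "DNAStringSet"))
    msg <- c(msg, "sequences must be a DNAStringSet")
  else {
    w <- Biostrings::width(object@sequences)
    if (length(w) != length(object@ids) ||
        length(w) != length(object@expression))
      msg <- c(msg, "ids, sequences and expression lengths differ")
    bad <- which(w %% 3 != 0 | w == 0)
    if (length(bad))
      msg <- c(msg, paste("sequence length not a positive multiple of 3:",
                          paste(object@ids[bad], collapse = ", ")))
  }
  if (anyDuplicated(object@ids))
    msg <- c(msg, "transcript ids must be unique")
  if (length(object@expression)) {
    if (any(!is.finite(object@expression)) || any(object@expression < 0))
      msg <- c(msg, "expression weights must be finite and >= 0")
    else if (abs(sum(object@expression) - 1) > .SUM_TOL)
      msg <- c(msg, "expression weights must sum to 1")
  } else msg <- c(msg, "transcriptome is empty")
  if (length(msg)) msg else TRUE
})

#' Relative codon usage
#'
#' @slot codons ordered character vector of codons.
#' @slot frequency relative usage per codon, summing to 1.
#' @slot scope `"transcriptome"` or `"transcript"`.
#' @slot transcript id of the source transcript for per-transcript usage.
#' @exportClass CodonUsage
setClass("CodonUsage",
  representation(
    codons = "character",
    frequency = "numeric",
    scope = "character",
    transcript = "character"
  ),
  prototype(scope = "transcriptome", transcript = NA_character_)
)

setValidity("CodonUsage", function(object) {
  msg <- character()
  if (length(object@codons) != length(object@frequency))
    msg <- c(msg, "codons and frequency lengths differ")
  if (any(!is.finite(object@frequency)) || any(object@frequency < 0))
    msg <- c(msg, "frequencies must be finite and >= 0")
  else if (length(object@frequency) &&
           abs(sum(object@frequency) - 1) > .SUM_TOL)
    msg <- c(msg, "frequencies must sum to 1")
  if (!object@scope %in% c("transcriptome", "transcript"))
    msg <- c(msg, "scope must be 'transcriptome' or 'transcript'")
  if (length(msg)) msg else TRUE
})

#' Markov surrogate kinetic parameters
#'
#' Parameters of the renewal/Markov surrogate for single-codon elongation:
#' a ribosome samples ternary complexes at mean interval `tauTransport`; a
#' cognate encounter succeeds with probability `pSuccess` (taking
#' `tauSuccess`) or fails (taking `tauCognateFail`); non-cognate encounters
#' always fail after `tauReject`. All times in milliseconds. Near-cognate
#' encounters are folded into the rejection pathway.
#'
#' @slot tauTransport mean time between ribosome-TC encounters, ms.
#' @slot tauSuccess duration of a successful cognate reaction, ms.
#' @slot tauCognateFail duration of a failed cognate encounter, ms.
#' @slot tauReject duration of a non-cognate rejection, ms.
#' @slot pSuccess probability a cognate encounter succeeds, in (0, 1].
#' @exportClass SurrogateKineticParams
setClass("SurrogateKineticParams",
  representation(
    tauTransport = "numeric",
    tauSuccess = "numeric",
    tauCognateFail = "numeric",
    tauReject = "numeric",
    pSuccess = "numeric"
  )
)

setValidity("SurrogateKineticParams", function(object) {
  v <- c(object@tauTransport, object@tauSuccess, object@tauCognateFail,
         object@tauReject)
  msg <- character()
  if (length(v) != 4 || any(!is.finite(v)) || any(v <= 0))
    msg <- c(msg, "all latencies must be single finite values > 0")
  p <- object@pSuccess
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p > 1)
    msg <- c(msg, "pSuccess must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Pre-computed component elongation latencies
#'
#' Lookup table of expected single-codon elongation latencies keyed by the
#' (cognate, non-cognate) ternary-complex counts of a translation voxel, as
#' produced by upstream colloidal-dynamics ensembles.
#'
#' @slot cognateCount integer cognate TC counts.
#' @slot noncognateCount integer non-cognate TC counts.
#' @slot latencyMs expected latency in ms per key.
#' @slot metadata list; typically `totalTC` and a `source` tag.
#' @exportClass ComponentLatencyTable
setClass("ComponentLatencyTable",
  representation(
    cognateCount = "integer",
    noncognateCount = "integer",
    latencyMs = "numeric",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("ComponentLatencyTable", function(object) {
  msg <- character()
  n <- length(object@latencyMs)
  if (n == 0) msg <- c(msg, "table is empty")
  if (length(object@cognateCount) != n || length(object@noncognateCount) != n)
    msg <- c(msg, "column lengths differ")
  else {
    if (any(object@cognateCount < 1) || any(object@noncognateCount < 0))
      msg <- c(msg, "cognate counts must be >= 1 and non-cognate >= 0")
    if (any(!is.finite(object@latencyMs)) || any(object@latencyMs <= 0))
      msg <- c(msg, "latencies must be finite and > 0")
    if (anyDuplicated(paste(object@cognateCount, object@noncognateCount)))
      msg <- c(msg, "duplicate (cognate, noncognate) keys")
  }
  if (length(msg)) msg else TRUE
})

#' Voxel sampling configuration for the post-hoc estimator
#'
#' @slot K total ternary complexes per translation voxel (>= 2).
#' @slot M Monte-Carlo voxel samples per codon (>= 1).
#' @slot seed integer RNG seed making the estimate reproducible.
#' @exportClass VoxelSamplingConfig
setClass("VoxelSamplingConfig",
  representation(K = "integer", M = "integer", seed = "integer")
)

setValidity("VoxelSamplingConfig", function(object) {
  msg <- character()
  if (length(object@K) != 1 || object@K < 2) msg <- c(msg, "K must be >= 2")
  if (length(object@M) != 1 || object@M < 1) msg <- c(msg, "M must be >= 1")
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Elongation-latency report
#'
#' Per-codon, per-transcript and transcriptome-average expected elongation
#' latencies (ms) for one (distribution, cognate map, transcriptome) triple.
#' The transcriptome mean and SD are taken across transcripts, weighted by
#' relative expression.
#'
#' @slot perCodon named numeric, expected latency per codon (ms).
#' @slot perTranscript named numeric, expected latency per elongation step
#'   of each transcript (ms).
#' @slot transcriptomeMean expression-weighted mean across transcripts (ms).
#' @slot transcriptomeSD expression-weighted SD across transcripts (ms).
#' @slot config list recording K, M and seed used.
#' @exportClass LatencyReport
setClass("LatencyReport",
  representation(
    perCodon = "numeric",
    perTranscript = "numeric",
    transcriptomeMean = "numeric",
    transcriptomeSD = "numeric",
    config = "list"
  )
)

setValidity("LatencyReport", function(object) {
  msg <- character()
  if (any(object@perCodon <= 0) || any(object@perTranscript <= 0))
    msg <- c(msg, "latencies must be > 0")
  if (length(object@perTranscript)) {
    lo <- min(object@perTranscript); hi <- max(object@perTranscript)
    if (object@transcriptomeMean < lo - 1e-9 ||
        object@transcriptomeMean > hi + 1e-9)
      msg <- c(msg, "transcriptome mean outside per-transcript range")
  }
  if (length(msg)) msg else TRUE
})

#' Abundance bounds for distribution design
#'
#' @slot lower lowest admissible relative abundance (fraction).
#' @slot upper highest admissible relative abundance (fraction).
#' @exportClass DistributionBounds
setClass("DistributionBounds",
  representation(lower = "numeric", upper = "numeric")
)

setValidity("DistributionBounds", function(object) {
  if (length(object@lower) != 1 || length(object@upper) != 1 ||
      !is.finite(object@lower) || !is.finite(object@upper) ||
      object@lower <= 0 || object@upper >= 1 ||
      object@lower >= object@upper)
    "bounds must satisfy 0 < lower < upper < 1" else TRUE
})

#' Genetic-algorithm configuration
#'
#' Defaults mirror the published CD-CAD settings: population 100, 2000
#' generations, 10 lowest-fitness individuals removed per generation and
#' replaced by offspring of 5 fitness-weighted parent pairs, with 8 abundance
#' positions swapped per pair (recombination rate 0.2 for 40 tRNA) and 4
#' positions per offspring redrawn uniformly inside the bounds (mutation rate
#' 0.1).
#'
#' @slot populationSize number of individuals.
#' @slot generations number of generations.
#' @slot nRemoved individuals removed per generation (= 2 * nPairs).
#' @slot nPairs parent pairs sampled per generation.
#' @slot nSwapped abundance positions swapped between each pair's offspring.
#' @slot nMutated positions redrawn per offspring.
#' @slot bounds a [DistributionBounds-class].
#' @slot direction `"fast"` (minimize latency) or `"slow"` (maximize).
#' @slot seed integer RNG seed.
#' @exportClass GAConfig
setClass("GAConfig",
  representation(
    populationSize = "integer",
    generations = "integer",
    nRemoved = "integer",
    nPairs = "integer",
    nSwapped = "integer",
    nMutated = "integer",
    bounds = "DistributionBounds",
    direction = "character",
    seed = "integer"
  )
)

setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@nRemoved != 2L * object@nPairs)
    msg <- c(msg, "nRemoved must equal 2 * nPairs")
  if (object@populationSize < 3) msg <- c(msg, "populationSize must be >= 3")
  if (object@nRemoved >= object@populationSize - 1L)
    msg <- c(msg, "nRemoved must leave at least 2 survivors")
  if (object@generations < 0) msg <- c(msg, "generations must be >= 0")
  if (any(c(object@nSwapped, object@nMutated) < 0))
    msg <- c(msg, "nSwapped and nMutated must be >= 0")
  if (!object@direction %in% c("fast", "slow"))
    msg <- c(msg, "direction must be 'fast' or 'slow'")
  if (length(msg)) msg else TRUE
})

#' Genetic-algorithm result
#'
#' @slot bestDistribution the best [TRNADistribution-class] found.
#' @slot bestLatency its transcriptome-average latency (ms).
#' @slot trajectory data.frame per generation: generation, meanLatency,
#'   bestLatency.
#' @slot finalPopulation list of [TRNADistribution-class].
#' @slot finalLatencies numeric latencies of the final population (ms).
#' @slot config the [GAConfig-class] used.
#' @exportClass GAResult
setClass("GAResult",
  representation(
    bestDistribution = "TRNADistribution",
    bestLatency = "numeric",
    trajectory = "data.frame",
    finalPopulation = "list",
    finalLatencies = "numeric",
    config = "GAConfig"
  )
)

#' TINA recipe specification
#'
#' Concentration targets for assembling a designed elongator-tRNA
#' distribution into a PUREdeltatRNA reaction from individual tRNA stocks:
#' a 5x concentrated stock mix is prepared so that adding
#' `stockMixVolumeAdded` ul to a `reactionVolume` ul reaction delivers the
#' specified final concentrations.
#'
#' @slot distribution elongator [TRNADistribution-class].
#' @slot totalElongatorConc total elongator tRNA in the reaction, uM.
#' @slot initiatorConc initiator tRNA final concentration, uM.
#' @slot stockConc named (or scalar) source stock concentration per tRNA, uM.
#' @slot stockMixFold fold-concentration of the tRNA stock mix.
#' @slot reactionVolume final reaction volume, ul.
#' @slot stockMixVolumeAdded volume of stock mix added per reaction, ul.
#' @slot minPipettableVolume smallest volume flagged pipettable, ul.
#' @exportClass RecipeSpec
setClass("RecipeSpec",
  representation(
    distribution = "TRNADistribution",
    totalElongatorConc = "numeric",
    initiatorConc = "numeric",
    stockConc = "numeric",
    stockMixFold = "numeric",
    reactionVolume = "numeric",
    stockMixVolumeAdded = "numeric",
    minPipettableVolume = "numeric"
  )
)

setValidity("RecipeSpec", function(object) {
  msg <- character()
  sc <- c(object@totalElongatorConc, object@initiatorConc, object@stockConc,
          object@stockMixFold, object@reactionVolume,
          object@stockMixVolumeAdded)
  if (any(!is.finite(sc)) || any(sc <= 0))
    msg <- c(msg, "all concentrations, volumes and folds must be > 0")
  if (abs(object@stockMixFold * object@stockMixVolumeAdded -
          object@reactionVolume) > 1e-9)
    msg <- c(msg, "stockMixFold * stockMixVolumeAdded must equal reactionVolume")
  if (object@minPipettableVolume < 0)
    msg <- c(msg, "minPipettableVolume must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TINA mixing recipe
#'
#' @slot table data.frame with one row per tRNA (elongators plus initiator):
#'   final reaction concentration (uM), concentration in the fold-concentrated
#'   stock mix (uM), source-stock volume to combine (ul, full precision and
#'   rounded to pipette resolution), and feasibility flags.
#' @slot mixVolume total stock-mix volume the volumes add up to, ul.
#' @slot spec the [RecipeSpec-class] used.
#' @slot feasible TRUE when every requested tRNA is reachable from its stock
#'   and every volume is pipettable.
#' @exportClass Recipe
setClass("Recipe",
  representation(
    table = "data.frame",
    mixVolume = "numeric",
    spec = "RecipeSpec",
    feasible = "logical"
  )
)
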
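# User-facing constructors, accessors and show() methods.

#' Create a tRNA abundance distribution
#'
#' @param trna character vector of unique tRNA identifiers.
#' @param abundance non-negative relative abundances. Must sum to 1 unless
#'   `normalize = TRUE`.
#' @param totalConcentration optional total tRNA concentration, uM.
#' @param normalize divide by the sum before validation (the raw vector is
#'   kept under `metadata(x)$raw`).
#' @param metadata free-form annotation list.
#' @return A [TRNADistribution-class].
#' @examples
#' TRNADistribution(c("Phe", "Lys"), c(0.5, 0.5))
#' @export
TRNADistribution <- function(trna, abundance, totalConcentration = NA_real_,
                             normalize = FALSE, metadata = list()) {
  trna <- as.character(trna)
  abundance <- as.numeric(abundance)
  if (normalize) {
    s <- sum(abundance)
    if (!is.finite(s) || s <= 0) stop("cannot normalize: non-positive sum")
    metadata$raw <- stats::setNames(abundance, trna)
    abundance <- abundance / s
  }
  new("TRNADistribution", trna = trna, abundance = abundance,
      totalConcentration = as.numeric(totalConcentration),
      metadata = metadata)
}

#' Create a cognate map
#'
#' @param cognate logical (or 0/1) matrix, tRNA rows x codon columns, with
#'   dimnames unless `trna`/`codons` are given.
#' @param trna,codons row / column identifiers.
#' @param aa optional amino-acid annotation per tRNA.
#' @return A [CognateMap-class].
#' @export
CognateMap <- function(cognate, trna = rownames(cognate),
                       codons = colnames(cognate), aa = NULL) {
  m <- matrix(as.logical(cognate), nrow = nrow(cognate),
              dimnames = list(trna, codons))
  if (is.null(aa)) aa <- rep(NA_character_, length(trna))
  new("CognateMap", trna = as.character(trna), codons = as.character(codons),
      cognate = m, aa = as.character(aa))
}

#' Create a transcriptome
#'
#' @param sequences a [Biostrings::DNAStringSet] (or character vector) of
#'   in-frame CDS; trailing stop codons should already be removed (the file
#'   reader [readTranscriptome()] does this).
#' @param expression relative expression weights; normalized to sum to 1.
#' @param ids transcript identifiers; defaults to sequence names.
#' @return A [Transcriptome-class].
#' @export
Transcriptome <- function(sequences, expression, ids = names(sequences)) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  expression <- as.numeric(expression)
  s <- sum(expression)
  if (!is.finite(s) || s <= 0) stop("expression weights must have positive sum")
  if (is.null(ids)) ids <- paste0("tx", seq_along(sequences))
  names(sequences) <- ids
  new("Transcriptome", ids = as.character(ids), sequences = sequences,
      expression = expression / s)
}

#' Surrogate kinetic parameters with calibrated defaults
#'
#' The defaults are a one-time calibration of the Markov surrogate chosen so
#' that wild-type-like per-codon cognate fractions (roughly 0.02-0.05 of a
#' ~42-ternary-complex voxel) give expected single-codon latencies in the
#' 150-250 ms range typical of E. coli-scale translation, with transport and
#' non-cognate sampling dominating the budget.
#'
#' @param tauTransport,tauSuccess,tauCognateFail,tauReject durations, ms.
#' @param pSuccess cognate success probability, in (0, 1].
#' @return A [SurrogateKineticParams-class].
#' @examples
#' SurrogateKineticParams()
#' @export
SurrogateKineticParams <- function(tauTransport = 1.0, tauSuccess = 35,
                                   tauCognateFail = 1.5, tauReject = 1.5,
                                   pSuccess = 0.5) {
  new("SurrogateKineticParams", tauTransport = tauTransport,
      tauSuccess = tauSuccess, tauCognateFail = tauCognateFail,
      tauReject = tauReject, pSuccess = pSuccess)
}

#' Voxel sampling configuration
#'
#' @param K total ternary complexes per voxel; default 42.
#' @param M Monte-Carlo samples per codon; default 1000.
#' @param seed RNG seed.
#' @return A [VoxelSamplingConfig-class].
#' @export
VoxelSamplingConfig <- function(K = 42L, M = 1000L, seed = 1L) {
  new("VoxelSamplingConfig", K = as.integer(K), M = as.integer(M),
      seed = as.integer(seed))
}

#' Abundance bounds
#'
#' The published bounds are 0.0015-0.0852 (the lowest and highest wild-type
#' E. coli relative tRNA abundances) for the full genetic code, and
#' 0.012-0.128 for the RED20 reduced code.
#'
#' @param lower,upper fractions with 0 < lower < upper < 1.
#' @return A [DistributionBounds-class].
#' @export
DistributionBounds <- function(lower = 0.0015, upper = 0.0852) {
  new("DistributionBounds", lower = lower, upper = upper)
}

#' Genetic-algorithm configuration
#'
#' @param populationSize,generations,nRemoved,nPairs,nSwapped,nMutated see
#'   [GAConfig-class]; defaults are the published CD-CAD settings.
#' @param bounds a [DistributionBounds-class].
#' @param direction `"fast"` or `"slow"`.
#' @param seed RNG seed.
#' @return A [GAConfig-class].
#' @export
GAConfig <- function(populationSize = 100L, generations = 2000L,
                     nRemoved = 10L, nPairs = 5L, nSwapped = 8L,
                     nMutated = 4L, bounds = DistributionBounds(),
                     direction = c("fast", "slow"), seed = 1L) {
  direction <- match.arg(direction)
  new("GAConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations), nRemoved = as.integer(nRemoved),
      nPairs = as.integer(nPairs), nSwapped = as.integer(nSwapped),
      nMutated = as.integer(nMutated), bounds = bounds,
      direction = direction, seed = as.integer(seed))
}

## ------------------------------------------------------------------ accessors

#' Accessors for tRNAcad objects
#'
#' `trnaNames()`, `abundances()`, `codons()`, `cognateMatrix()`,
#' `transcriptIds()`, `sequences()`, `expressionWeights()`, `perCodon()`,
#' `perTranscript()`, `transcriptomeMean()`, `transcriptomeSD()`,
#' `bestDistribution()`, `bestLatency()`, `trajectory()` and
#' `recipeTable()` read the corresponding slots.
#'
#' @param x a tRNAcad S4 object.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trnaNames", function(x) standardGeneric("trnaNames"))
#' @rdname accessors
#' @export
setMethod("trnaNames", "TRNADistribution", function(x) x@trna)
#' @rdname accessors
#' @export
setMethod("trnaNames", "CognateMap", function(x) x@trna)

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "TRNADistribution",
          function(x) stats::setNames(x@abundance, x@trna))

#' @rdname accessors
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))
#' @rdname accessors
#' @export
setMethod("codons", "CognateMap", function(x) x@codons)
#' @rdname accessors
#' @export
setMethod("codons", "CodonUsage", function(x) x@codons)

#' @rdname accessors
#' @export
setGeneric("cognateMatrix", function(x) standardGeneric("cognateMatrix"))
#' @rdname accessors
#' @export
setMethod("cognateMatrix", "CognateMap", function(x) x@cognate)

#' @rdname accessors
#' @export
setGeneric("codonFrequencies", function(x) standardGeneric("codonFrequencies"))
#' @rdname accessors
#' @export
setMethod("codonFrequencies", "CodonUsage",
          function(x) stats::setNames(x@frequency, x@codons))

#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname accessors
#' @export
setMethod("transcriptIds", "Transcriptome", function(x) x@ids)

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setMethod("sequences", "Transcriptome", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("expressionWeights", function(x) standardGeneric("expressionWeights"))
#' @rdname accessors
#' @export
setMethod("expressionWeights", "Transcriptome",
          function(x) stats::setNames(x@expression, x@ids))

#' @rdname accessors
#' @export
setGeneric("perCodon", function(x) standardGeneric("perCodon"))
#' @rdname accessors
#' @export
setMethod("perCodon", "LatencyReport", function(x) x@perCodon)

#' @rdname accessors
#' @export
setGeneric("perTranscript", function(x) standardGeneric("perTranscript"))
#' @rdname accessors
#' @export
setMethod("perTranscript", "LatencyReport", function(x) x@perTranscript)

#' @rdname accessors
#' @export
setGeneric("transcriptomeMean", function(x) standardGeneric("transcriptomeMean"))
#' @rdname accessors
#' @export
setMethod("transcriptomeMean", "LatencyReport", function(x) x@transcriptomeMean)

#' @rdname accessors
#' @export
setGeneric("transcriptomeSD", function(x) standardGeneric("transcriptomeSD"))
#' @rdname accessors
#' @export
setMethod("transcriptomeSD", "LatencyReport", function(x) x@transcriptomeSD)

#' @rdname accessors
#' @export
setGeneric("bestDistribution", function(x) standardGeneric("bestDistribution"))
#' @rdname accessors
#' @export
setMethod("bestDistribution", "GAResult", function(x) x@bestDistribution)

#' @rdname accessors
#' @export
setGeneric("bestLatency", function(x) standardGeneric("bestLatency"))
#' @rdname accessors
#' @export
setMethod("bestLatency", "GAResult", function(x) x@bestLatency)

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
#' @rdname accessors
#' @export
setMethod("trajectory", "GAResult", function(x) x@trajectory)

#' @rdname accessors
#' @export
setGeneric("recipeTable", function(x) standardGeneric("recipeTable"))
#' @rdname accessors
#' @export
setMethod("recipeTable", "Recipe", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("rawAbundances", function(x) standardGeneric("rawAbundances"))
#' @rdname accessors
#' @details `rawAbundances()` returns the pre-normalization abundance vector
#'   a generator kept in metadata (e.g. the stepwise ladder), or `NULL`.
#' @export
setMethod("rawAbundances", "TRNADistribution",
          function(x) x@metadata$raw)

#' Length of a distribution, map or transcriptome
#' @param x object.
#' @return number of tRNA species / transcripts.
#' @export
setMethod("length", "TRNADistribution", function(x) length(x@trna))
#' @rdname length-TRNADistribution-method
#' @export
setMethod("length", "Transcriptome", function(x) length(x@ids))

## ------------------------------------------------------------------ show

setMethod("show", "TRNADistribution", function(object) {
  cat(sprintf("TRNADistribution with %d tRNA species\n", length(object@trna)))
  if (!is.na(object@totalConcentration))
    cat(sprintf("  total concentration: %g uM\n", object@totalConcentration))
  ab <- abundances(object)
  top <- utils::head(sort(ab, decreasing = TRUE), 5)
  cat("  top abundances:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
})

setMethod("show", "CognateMap", function(object) {
  cat(sprintf("CognateMap: %d tRNA x %d codons (%d cognate pairs)\n",
              length(object@trna), length(object@codons),
              sum(object@cognate)))
})

setMethod("show", "Transcriptome", function(object) {
  w <- Biostrings::width(object@sequences)
  cat(sprintf("Transcriptome with %d transcripts (%d-%d codons)\n",
              length(object@ids), min(w) %/% 3, max(w) %/% 3))
})

setMethod("show", "LatencyReport", function(object) {
  cat(sprintf(
    "LatencyReport: transcriptome <tau_elong> = %.1f +/- %.1f ms (%d codons, %d transcripts)\n",
    object@transcriptomeMean, object@transcriptomeSD,
    length(object@perCodon), length(object@perTranscript)))
})

setMethod("show", "GAResult", function(object) {
  cat(sprintf(
    "GAResult (%s): best <tau_elong> = %.1f ms after %d generations\n",
    object@config@direction, object@bestLatency,
    nrow(object@trajectory)))
})

setMethod("show", "Recipe", function(object) {
  cat(sprintf("TINA Recipe: %d tRNA, mix volume %g ul, %s\n",
              nrow(object@table), object@mixVolume,
              if (object@feasible) "feasible" else "INFEASIBLE"))
})

setMethod("show", "ComponentLatencyTable", function(object) {
  cat(sprintf("ComponentLatencyTable: %d entries, cognate %d-%d, latency %.1f-%.1f ms\n",
              length(object@latencyMs), min(object@cognateCount),
              max(object@cognateCount), min(object@latencyMs),
              max(object@latencyMs)))
})
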
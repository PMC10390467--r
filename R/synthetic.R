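# Synthetic-data generators: toy transcriptome/cognate-map/distribution
# systems with tunable codon-usage skew, and noisy logistic fluorescence
# traces. Every generator is a pure function of its arguments and seed.

#' Synthetic system specification
#'
#' @param nTrna number of tRNA species.
#' @param nCodons number of sense codons (>= nTrna).
#' @param nTranscripts number of transcripts.
#' @param transcriptLength transcript length in codons.
#' @param codonUsageSkew Zipf-like exponent for codon usage (0 = uniform).
#' @param seed mandatory integer seed.
#' @return A validated list of class `SyntheticSpec`.
#' @export
SyntheticSpec <- function(nTrna = 12L, nCodons = 20L, nTranscripts = 10L,
                          transcriptLength = 60L, codonUsageSkew = 1,
                          seed = 1L) {
  spec <- list(nTrna = as.integer(nTrna), nCodons = as.integer(nCodons),
               nTranscripts = as.integer(nTranscripts),
               transcriptLength = as.integer(transcriptLength),
               codonUsageSkew = codonUsageSkew, seed = as.integer(seed))
  if (is.na(spec$seed)) stop("seed is mandatory")
  if (spec$nCodons < spec$nTrna)
    stop("need nCodons >= nTrna so every tRNA can read a codon")
  if (spec$nTrna < 2 || spec$nTranscripts < 1 || spec$transcriptLength < 1)
    stop("infeasible dimensions")
  class(spec) <- "SyntheticSpec"
  spec
}

# Pick nCodons sense codons grouped by amino acid, and split each amino
# acid's codons over its tRNA so that tRNA never straddle amino acids.
.toyCognateStructure <- function(nTrna, nCodons) {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc)[gc != "*"], gc[gc != "*"])
  fams <- fams[order(-lengths(fams), names(fams))]
  chosen <- list()
  total <- 0
  for (aa in names(fams)) {
    if (total >= nCodons) break
    take <- min(length(fams[[aa]]), nCodons - total)
    chosen[[aa]] <- sort(fams[[aa]])[seq_len(take)]
    total <- total + take
  }
  if (total < nCodons) stop("nCodons exceeds the sense-codon alphabet")
  if (length(chosen) > nTrna)
    stop(sprintf("nTrna = %d too small for the %d amino-acid families of %d codons",
                 nTrna, length(chosen), nCodons))
  # one tRNA per family, then split the largest families' codon sets
  groups <- lapply(names(chosen), function(aa)
    list(aa = aa, codons = chosen[[aa]]))
  while (length(groups) < nTrna) {
    sizes <- vapply(groups, function(g) length(g$codons), numeric(1))
    i <- which.max(sizes)
    if (sizes[i] < 2) stop("cannot split further: nTrna too large")
    g <- groups[[i]]
    h <- ceiling(length(g$codons) / 2)
    groups[[i]] <- list(aa = g$aa, codons = g$codons[seq_len(h)])
    groups[[length(groups) + 1]] <- list(aa = g$aa,
                                         codons = g$codons[-seq_len(h)])
  }
  groups
}

#' Generate a toy translation system
#'
#' Builds a consistent (Transcriptome, CognateMap, TRNADistribution) triple:
#' a cognate map whose tRNA each read one or more same-amino-acid codons
#' (with one codon deliberately given a second cognate tRNA when possible,
#' mirroring the CUG/Leu1+Leu3 degeneracy of E. coli); a transcriptome whose
#' codon usage follows a Zipf-like law with exponent `codonUsageSkew`; and a
#' wild-type-like distribution positively correlated with that usage.
#'
#' @param spec a [SyntheticSpec()].
#' @return List with `transcriptome`, `map`, `distribution`, `usage` (the
#'   target codon-usage vector the transcripts were sampled from).
#' @export
makeToySystem <- function(spec = SyntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, {
    groups <- .toyCognateStructure(spec$nTrna, spec$nCodons)
    allCodons <- sort(unlist(lapply(groups, `[[`, "codons")))
    trna <- vapply(seq_along(groups), function(i) {
      aa <- groups[[i]]$aa
      reps <- sum(vapply(groups[seq_len(i)], function(g) g$aa == aa,
                         logical(1)))
      paste0(aa, reps)
    }, character(1))
    cg <- matrix(FALSE, length(groups), length(allCodons),
                 dimnames = list(trna, allCodons))
    for (i in seq_along(groups)) cg[i, groups[[i]]$codons] <- TRUE
    # degeneracy: give one codon a second cognate tRNA where a same-aa
    # sibling exists
    aaOf <- vapply(groups, `[[`, character(1), "aa")
    for (i in seq_along(groups)) {
      sib <- which(aaOf == aaOf[i])
      sib <- sib[sib != i]
      if (length(sib)) { cg[sib[1], groups[[i]]$codons[1]] <- TRUE; break }
    }
    map <- CognateMap(cg, trna = trna, codons = allCodons, aa = aaOf)
    # Zipf-like codon usage over a random codon ranking
    ranks <- sample(spec$nCodons)
    u <- (1 / ranks)^spec$codonUsageSkew
    u <- u / sum(u)
    names(u) <- allCodons
    seqs <- vapply(seq_len(spec$nTranscripts), function(i)
      paste(sample(allCodons, spec$transcriptLength, replace = TRUE,
                   prob = u), collapse = ""), character(1))
    names(seqs) <- sprintf("tx%02d", seq_len(spec$nTranscripts))
    expr <- stats::runif(spec$nTranscripts, 0.5, 1.5)
    transcriptome <- Transcriptome(seqs, expr)
    # wild-type-like: abundance tracks equal-split cognate usage plus a floor
    usage <- new("CodonUsage", codons = allCodons, frequency = unname(u),
                 scope = "transcriptome", transcript = NA_character_)
    w <- .trnaUsage(usage, map, split = TRUE)
    d <- TRNADistribution(trna, unname(w + 0.2 / length(trna)),
                          normalize = TRUE)
    list(transcriptome = transcriptome, map = map, distribution = d,
         usage = usage)
  })
}

#' Generate a synthetic study system on an existing cognate map
#'
#' Like [makeToySystem()] but for a supplied [CognateMap-class] (typically
#' the shipped 40 tRNA x 61 codon map from [ecoliCognateMap()]): samples a
#' Zipf-skewed codon usage over the map's codons, a transcriptome drawn from
#' it, and a wild-type-like distribution positively correlated with usage.
#'
#' @param map a [CognateMap-class].
#' @param nTranscripts,transcriptLength,codonUsageSkew,seed as in
#'   [SyntheticSpec()].
#' @return List with `transcriptome`, `distribution`, `usage`.
#' @export
makeStudySystem <- function(map, nTranscripts = 30L, transcriptLength = 150L,
                            codonUsageSkew = 1, seed = 1L) {
  stopifnot(is(map, "CognateMap"))
  .withSeed(seed, {
    allCodons <- codons(map)
    ranks <- sample(length(allCodons))
    u <- (1 / ranks)^codonUsageSkew
    u <- u / sum(u)
    names(u) <- allCodons
    seqs <- vapply(seq_len(nTranscripts), function(i)
      paste(sample(allCodons, transcriptLength, replace = TRUE, prob = u),
            collapse = ""), character(1))
    names(seqs) <- sprintf("tx%03d", seq_len(nTranscripts))
    transcriptome <- Transcriptome(seqs, stats::runif(nTranscripts, 0.5, 1.5))
    usage <- new("CodonUsage", codons = allCodons, frequency = unname(u),
                 scope = "transcriptome", transcript = NA_character_)
    w <- .trnaUsage(usage, map, split = TRUE)
    d <- TRNADistribution(trnaNames(map),
                          unname(w + 0.2 / length(trnaNames(map))),
                          normalize = TRUE)
    list(transcriptome = transcriptome, distribution = d, usage = usage)
  })
}

#' Generate synthetic plate-reader traces
#'
#' Logistic fluorescence accumulation `L / (1 + exp(-k (t - t0)))` plus iid
#' Gaussian noise per (condition, replicate, batch), and a flat negative
#' control. The analytic maximal synthesis rate of each condition is
#' `L * k / 4` (RFU/s) and is returned as ground truth. Defaults emulate a
#' two-condition fast/slow study with a slow:fast maximal-rate ratio of
#' 0.66, 145 five-minute time points over ~12 h, and modest noise.
#'
#' @param conditions data.frame with columns `condition`, `L` (plateau RFU),
#'   `k` (1/s), `t0` (s); one row per expressing condition.
#' @param negativeCondition label for the flat control trace.
#' @param nReplicates replicates per condition (recycled over batches).
#' @param batches batch ids.
#' @param times sampling times, s.
#' @param noiseSD Gaussian noise SD, RFU.
#' @param baseline constant background RFU added to every trace.
#' @param seed integer seed.
#' @return List with `traces` (long data.frame) and `truth` (condition,
#'   maximal rate RFU/s).
#' @export
makeTraces <- function(conditions = data.frame(
                         condition = c("synFast", "synSlow"),
                         L = c(1000, 660), k = c(5e-4, 5e-4),
                         t0 = c(10000, 10000)),
                       negativeCondition = "neg", nReplicates = 5L,
                       batches = 1L, times = seq(0, 43200, by = 300),
                       noiseSD = 5, baseline = 100, seed = 1L) {
  .withSeed(seed, {
    rows <- list()
    for (b in batches) {
      for (ci in seq_len(nrow(conditions))) {
        cc <- conditions[ci, ]
        for (r in seq_len(nReplicates)) {
          signal <- cc$L / (1 + exp(-cc$k * (times - cc$t0)))
          rows[[length(rows) + 1]] <- data.frame(
            time_s = times, condition = cc$condition, replicate = r,
            batch = b,
            rfu = baseline + signal + stats::rnorm(length(times), 0, noiseSD),
            stringsAsFactors = FALSE)
        }
      }
      for (r in seq_len(nReplicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          time_s = times, condition = negativeCondition, replicate = r,
          batch = b,
          rfu = baseline + stats::rnorm(length(times), 0, noiseSD),
          stringsAsFactors = FALSE)
      }
    }
    truth <- data.frame(condition = conditions$condition,
                        max_rate = conditions$L * conditions$k / 4)
    list(traces = do.call(rbind, rows), truth = truth)
  })
}
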
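# Rational and random distribution designs, pairwise perturbations,
# reduced-code transcriptome recoding and tRNA-set reduction.

# Per-tRNA total cognate-codon usage. split = TRUE divides each codon's
# usage equally among its cognate tRNA (codon-weighted design); FALSE credits
# the full usage to every cognate tRNA (ordering statistic).
.trnaUsage <- function(usage, m, split = FALSE) {
  uf <- codonFrequencies(usage)
  missing <- setdiff(m@codons, names(uf))
  if (length(missing)) uf[missing] <- 0
  uf <- uf[m@codons]
  mat <- m@cognate
  if (split) mat <- sweep(mat, 2, pmax(colSums(mat), 1), "/")
  stats::setNames(as.numeric(mat %*% uf), m@trna)
}

# tRNA in decreasing cognate-codon-usage order, ties broken by name.
.usageOrder <- function(usage, m) {
  u <- .trnaUsage(usage, m, split = FALSE)
  m@trna[order(-u, m@trna)]
}

#' Uniform tRNA distribution
#'
#' @param names tRNA identifiers.
#' @return A [TRNADistribution-class] with every abundance `1/length(names)`.
#' @export
uniformDistribution <- function(names) {
  if (!length(names)) stop("need at least one tRNA name")
  TRNADistribution(names, rep(1 / length(names), length(names)))
}

#' Stepwise (anti)correlated tRNA distribution
#'
#' tRNA are sorted by decreasing total cognate-codon usage in the
#' transcriptome and assigned an arithmetic ladder of relative abundances:
#' the least-used tRNA gets `step`, the next `2*step`, and so on up to
#' `n*step` for the most-used (correlated), or the reverse (anticorrelated).
#' For 40 tRNA and the default step of 0.0012 this is the published
#' 0.12%..4.8% ladder (raw sum 0.984); the returned distribution is the
#' normalized copy, with the raw ladder kept in `metadata(x)$raw`.
#'
#' @param usage a [CodonUsage-class] covering the map's codons.
#' @param m a [CognateMap-class].
#' @param anticorrelated reverse the ladder.
#' @param step ladder increment (fraction), default 0.0012.
#' @return A [TRNADistribution-class] (normalized; raw ladder in metadata).
#' @export
stepwiseDistribution <- function(usage, m, anticorrelated = FALSE,
                                 step = 0.0012) {
  ord <- .usageOrder(usage, m)           # most-used first
  n <- length(ord)
  ladder <- step * seq(n, 1)             # most-used gets n*step
  if (anticorrelated) ladder <- rev(ladder)
  raw <- stats::setNames(ladder, ord)[m@trna]
  TRNADistribution(m@trna, raw, normalize = TRUE)
}

#' Codon-weighted (anti)correlated tRNA distribution
#'
#' Each codon's relative usage is split equally among its cognate tRNA and
#' summed per tRNA, weighting tRNA exactly to their corresponding codon
#' usage. The anticorrelated variant reverses the rank order of the
#' resulting abundance multiset: the tRNA with the greatest corresponding
#' codon usage receives the abundance of the tRNA with the least, and so on.
#'
#' @inheritParams stepwiseDistribution
#' @return A [TRNADistribution-class].
#' @export
codonWeightedDistribution <- function(usage, m, anticorrelated = FALSE) {
  w <- .trnaUsage(usage, m, split = TRUE)
  if (any(colSums(m@cognate) == 0)) stop("codon with no cognate tRNA")
  if (sum(w) <= 0) stop("usage assigns no mass to any cognate codon")
  ab <- w / sum(w)
  if (anticorrelated) {
    ord <- order(-ab, m@trna)            # rank by abundance, ties by name
    ab[ord] <- ab[rev(ord)]
  }
  TRNADistribution(m@trna, unname(ab[m@trna]), normalize = TRUE)
}

#' Random bounded tRNA distribution
#'
#' Draws iid Uniform(lower, upper) abundances, then iteratively rescales to
#' unit sum and clips back into the bounds until the vector sums to 1 within
#' 1e-9 with every entry inside the bounds (at most 1000 iterations, then an
#' error). Reproducible under `seed`.
#'
#' @param names tRNA identifiers.
#' @param bounds a [DistributionBounds-class].
#' @param seed integer seed.
#' @return A [TRNADistribution-class].
#' @export
randomDistribution <- function(names, bounds = DistributionBounds(),
                               seed = 1L) {
  n <- length(names)
  if (n * bounds@lower > 1 + 1e-12 || n * bounds@upper < 1 - 1e-12)
    stop(sprintf("infeasible bounds: need n*lower <= 1 <= n*upper (n = %d)", n))
  x <- .withSeed(seed, stats::runif(n, bounds@lower, bounds@upper))
  for (it in seq_len(1000)) {
    x <- x / sum(x)
    x <- pmin(pmax(x, bounds@lower), bounds@upper)
    if (abs(sum(x) - 1) <= 1e-9) break
    if (it == 1000) stop("bounded normalization did not converge")
  }
  TRNADistribution(names, x)
}

#' Pairwise monotonicity perturbation
#'
#' For an adjacent pair of tRNA in decreasing cognate-codon-usage order,
#' re-splits the pair's total abundance so the more-frequently-used tRNA
#' sits 10% above the less-used one (`s*1.1/2.1` vs `s*1/2.1`), leaving all
#' other abundances untouched. Applying it to a pair already at ratio 1.1 is
#' idempotent.
#'
#' @param d a [TRNADistribution-class].
#' @param usage a [CodonUsage-class] defining the ordering.
#' @param m a [CognateMap-class].
#' @param i pair index: perturbs the i-th and (i+1)-th tRNA in usage order.
#' @param ratio abundance ratio imposed on the pair (default 1.1).
#' @return A perturbed [TRNADistribution-class].
#' @export
pairwisePerturbation <- function(d, usage, m, i, ratio = 1.1) {
  ord <- .usageOrder(usage, m)
  if (i < 1 || i >= length(ord)) stop("pair index out of range")
  hi <- ord[i]; lo <- ord[i + 1]
  ab <- abundances(d)
  s <- ab[[hi]] + ab[[lo]]
  ab[[hi]] <- s * ratio / (1 + ratio)
  ab[[lo]] <- s / (1 + ratio)
  TRNADistribution(d@trna, unname(ab[d@trna]),
                   totalConcentration = d@totalConcentration)
}

#' Build a validated codon recode map
#'
#' A recode map sends every codon of the source alphabet to a codon of a
#' reduced sense-codon set encoding the same amino acid under the standard
#' genetic code (identity on codons already in the set).
#'
#' @param allowed character vector of allowed (kept) sense codons, one per
#'   amino acid they encode.
#' @param from optional codons to map (default: all 61 sense codons).
#' @return Named character vector `from -> to` with attribute `allowed`.
#' @export
recodeMap <- function(allowed, from = NULL) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  allowed <- toupper(chartr("Uu", "Tt", allowed))
  if (!all(allowed %in% sense))
    stop("allowed codons must be sense codons: ",
         paste(setdiff(allowed, sense), collapse = ", "))
  aaOf <- gc[allowed]
  if (anyDuplicated(aaOf))
    stop("allowed set has multiple codons for: ",
         paste(unique(aaOf[duplicated(aaOf)]), collapse = ", "))
  if (is.null(from)) from <- sense
  to <- stats::setNames(allowed[match(gc[from], aaOf)], from)
  orphan <- from[is.na(to)]
  if (length(orphan))
    stop("no allowed codon encodes the amino acid of: ",
         paste(orphan, collapse = ", "))
  attr(to, "allowed") <- allowed
  to
}

#' The shipped RED20-style reduced-code tables
#'
#' `red20Codons()` reads the package's editable 20-sense-codon fixture (a
#' RED20-style fail-safe code: one sense codon per amino acid, with Phe kept
#' as TTC so that all TTT recode to TTC); `red20RecodeMap()` derives the full
#' 61-codon recode map from it.
#'
#' @return `red20Codons()`: data.frame with columns `aa`, `codon`;
#'   `red20RecodeMap()`: named character vector as from [recodeMap()].
#' @export
red20Codons <- function() {
  utils::read.delim(system.file("extdata", "red20_codons.tsv",
                                package = "tRNAcad"),
                    stringsAsFactors = FALSE)
}

#' @rdname red20Codons
#' @export
red20RecodeMap <- function() recodeMap(red20Codons()$codon)

#' Recode a transcriptome into a reduced sense-codon set
#'
#' Codon-by-codon substitution under a recode map; the encoded protein is
#' unchanged and the output uses only allowed codons. Recoding an
#' already-recoded transcriptome is the identity.
#'
#' @param t a [Transcriptome-class].
#' @param map named character vector from [recodeMap()].
#' @return The recoded [Transcriptome-class].
#' @export
recodeTranscriptome <- function(t, map = red20RecodeMap()) {
  out <- vapply(seq_along(t@ids), function(i) {
    cod <- .splitCodons(t@sequences[[i]])
    bad <- setdiff(unique(cod), names(map))
    if (length(bad))
      stop("unmappable codon(s) ", paste(bad, collapse = ", "),
           " in transcript ", t@ids[i])
    paste(map[cod], collapse = "")
  }, character(1))
  Transcriptome(stats::setNames(out, t@ids), t@expression, t@ids)
}

#' Reduce a tRNA set, conserving abundance mass within amino acids
#'
#' Drops all tRNA not in `kept` and reassigns each dropped tRNA's relative
#' abundance to the kept tRNA annotated with the same amino acid (split
#' equally if several). Total mass is conserved; a dropped tRNA with no
#' same-amino-acid kept partner is an error.
#'
#' @param d a [TRNADistribution-class].
#' @param m a [CognateMap-class] whose `aa` annotations cover the tRNA.
#' @param kept character vector of tRNA to keep.
#' @return A [TRNADistribution-class] over `kept`.
#' @export
reduceTrnaSet <- function(d, m, kept) {
  if (!all(kept %in% d@trna)) stop("kept tRNA not in distribution: ",
                                   paste(setdiff(kept, d@trna), collapse = ", "))
  aa <- stats::setNames(m@aa, m@trna)
  if (any(is.na(aa[d@trna])))
    stop("cognate map lacks amino-acid annotations for: ",
         paste(d@trna[is.na(aa[d@trna])], collapse = ", "))
  ab <- abundances(d)
  out <- ab[kept]
  for (nm in setdiff(d@trna, kept)) {
    partners <- kept[aa[kept] == aa[[nm]]]
    if (!length(partners))
      stop("dropped tRNA ", nm, " has no kept tRNA for amino acid ", aa[[nm]])
    out[partners] <- out[partners] + ab[[nm]] / length(partners)
  }
  TRNADistribution(kept, unname(out),
                   totalConcentration = d@totalConcentration)
}

#' Subset a cognate map
#'
#' @param m a [CognateMap-class].
#' @param trna,codons identifiers to keep (default: all).
#' @return A validated [CognateMap-class] on the subset.
#' @export
subsetCognateMap <- function(m, trna = m@trna, codons = m@codons) {
  CognateMap(m@cognate[trna, codons, drop = FALSE], trna = trna,
             codons = codons, aa = stats::setNames(m@aa, m@trna)[trna])
}

#' The shipped default E. coli cognate map
#'
#' A curated, editable 40 tRNA x 61 sense-codon cognate map following
#' standard E. coli isoacceptor wobble-reading assignments (classic
#' isoacceptor naming; CTG is read by both Leu1 and Leu3). Shipped as a
#' documented default because published analyses rarely print the full
#' matrix; edit the TSV to change pairings.
#'
#' @return A [CognateMap-class].
#' @export
ecoliCognateMap <- function() {
  readCognateMap(system.file("extdata", "ecoli40_cognate_map.tsv",
                             package = "tRNAcad"))
}
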
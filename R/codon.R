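# Codon-usage statistics and codon/tRNA correlation.

# Codon count matrix: transcripts x codons (all codons appearing).
.codonCountMatrix <- function(t) {
  counts <- lapply(as.character(t@sequences), function(s)
    table(.splitCodons(s)))
  allCodons <- sort(unique(unlist(lapply(counts, names))))
  m <- matrix(0, nrow = length(t@ids), ncol = length(allCodons),
              dimnames = list(t@ids, allCodons))
  for (i in seq_along(counts))
    m[i, names(counts[[i]])] <- as.numeric(counts[[i]])
  m
}

#' Relative codon usage of a transcriptome
#'
#' Transcriptome-wide usage weights each transcript's codon counts by its
#' expression weight and normalizes — the expected codon flux seen by the
#' translating ribosome pool, in which long, highly expressed transcripts
#' contribute proportionally more. Per-transcript mode returns one
#' [CodonUsage-class] per transcript (relative frequencies within that
#' transcript).
#'
#' @param t a [Transcriptome-class].
#' @param perTranscript return a named list of per-transcript usages instead
#'   of one transcriptome-wide usage.
#' @param weightByExpression weight transcripts by expression (default) or
#'   count every transcript equally (gene-count weighting).
#' @return A [CodonUsage-class], or a named list of them.
#' @examples
#' t <- Transcriptome(c(t1 = "ATGATG"), 1)
#' codonFrequencies(codonUsage(t))
#' @export
codonUsage <- function(t, perTranscript = FALSE, weightByExpression = TRUE) {
  stopifnot(is(t, "Transcriptome"))
  if (length(t@ids) == 0) stop("empty transcriptome")
  m <- .codonCountMatrix(t)
  frac <- m / rowSums(m)
  if (perTranscript) {
    out <- lapply(seq_len(nrow(frac)), function(i) {
      keep <- frac[i, ] > 0
      new("CodonUsage", codons = colnames(frac)[keep],
          frequency = unname(frac[i, keep]), scope = "transcript",
          transcript = t@ids[i])
    })
    names(out) <- t@ids
    return(out)
  }
  w <- if (weightByExpression) t@expression else rep(1 / nrow(m), nrow(m))
  wc <- colSums(m * w)
  f <- wc / sum(wc)
  new("CodonUsage", codons = colnames(frac), frequency = unname(f),
      scope = "transcriptome", transcript = NA_character_)
}

#' Fraction of cognate tRNA per codon
#'
#' For each codon of the map, the summed relative abundance of its cognate
#' tRNA (equivalently the probability that a uniformly drawn ternary complex
#' is cognate to that codon).
#'
#' @param d a [TRNADistribution-class].
#' @param m a [CognateMap-class] with the same tRNA names.
#' @return Named numeric vector over `codons(m)`, values in \[0, 1\].
#' @export
cognateFractionPerCodon <- function(d, m) {
  stopifnot(is(d, "TRNADistribution"), is(m, "CognateMap"))
  if (!identical(sort(d@trna), sort(m@trna)))
    stop("tRNA names of distribution and cognate map do not match")
  ab <- abundances(d)[m@trna]
  stats::setNames(as.numeric(ab %*% m@cognate), m@codons)
}

#' OLS slope of cognate fraction on codon usage
#'
#' Ordinary least-squares slope of the per-codon cognate tRNA fraction
#' regressed on relative codon usage, both as fractions. A slope near 1
#' means tRNA supply tracks codon demand; negative slopes mean
#' anticorrelated supply.
#'
#' @param u a [CodonUsage-class] (or named numeric of frequencies).
#' @param f named numeric of per-codon cognate fractions, same codons.
#' @return The scalar slope.
#' @export
correlationSlope <- function(u, f) {
  uf <- if (is(u, "CodonUsage")) codonFrequencies(u) else u
  if (is.null(names(uf)) || is.null(names(f)))
    stop("codon usage and cognate fractions must be named by codon")
  common <- names(uf)
  if (!all(common %in% names(f)))
    stop("cognate fractions missing codons: ",
         paste(setdiff(common, names(f)), collapse = ", "))
  x <- as.numeric(uf)
  y <- as.numeric(f[common])
  if (length(x) < 3) stop("need at least 3 codons for a slope")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("codon usage is constant; slope undefined")
  sum((x - mean(x)) * (y - mean(y))) / sxx
}

#' Check a transcriptome against a cognate map's codon alphabet
#'
#' @param t a [Transcriptome-class].
#' @param m a [CognateMap-class].
#' @return Invisibly TRUE; error naming offending codons otherwise.
#' @export
checkCodonAlphabet <- function(t, m) {
  seen <- colnames(.codonCountMatrix(t))
  extra <- setdiff(seen, m@codons)
  if (length(extra))
    stop("transcriptome uses codons absent from the cognate map: ",
         paste(extra, collapse = ", "))
  invisible(TRUE)
}
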
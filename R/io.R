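# Readers and writers for the package's plain-text formats:
#   transcriptome  - FASTA (CDS) + TSV expression (id, expression)
#   distribution   - TSV (trna, abundance)
#   cognate map    - TSV (trna [, aa], one 0/1 column per codon)
#   latency table  - TSV (cognate_count, noncognate_count, latency_ms),
#                    '#' metadata lines
#   traces         - CSV (time_s, condition, replicate, batch, rfu)

#' Read a weighted transcriptome from FASTA + expression TSV
#'
#' Sequences are upper-cased, RNA (`U`) is normalized to DNA (`T`), a trailing
#' stop codon (TAA/TAG/TGA) is removed if present, and expression weights are
#' renormalized to sum to 1. Every FASTA record must have a matching row in
#' the expression file and vice versa; a length not divisible by 3 (after
#' stop-codon removal) is an error naming the transcript.
#'
#' @param fastaPath FASTA file of in-frame CDS.
#' @param expressionPath tab-delimited file with header, columns
#'   `id` and `expression` (relative transcript frequency, any positive
#'   scale).
#' @return A [Transcriptome-class].
#' @export
readTranscriptome <- function(fastaPath, expressionPath) {
  seqs <- Biostrings::readBStringSet(fastaPath)  # raw, so RNA 'U' survives
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  expr <- utils::read.delim(expressionPath, header = TRUE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2) stop("expression TSV needs id and expression columns")
  ids <- as.character(expr[[1]])
  w <- suppressWarnings(as.numeric(expr[[2]]))
  if (any(is.na(w)) || any(w < 0))
    stop("expression values must be numeric and >= 0")
  missingExpr <- setdiff(names(seqs), ids)
  missingSeq <- setdiff(ids, names(seqs))
  if (length(missingExpr) || length(missingSeq))
    stop("id mismatch between FASTA and expression TSV; missing from ",
         "expression: [", paste(missingExpr, collapse = ", "),
         "]; missing from FASTA: [", paste(missingSeq, collapse = ", "), "]")
  seqs <- seqs[ids]
  chr <- toupper(chartr("Uu", "Tt", as.character(seqs)))
  bad <- ids[nchar(chr) %% 3 != 0]
  if (length(bad))
    stop("sequence length not divisible by 3 for: ",
         paste(bad, collapse = ", "))
  last <- substring(chr, nchar(chr) - 2, nchar(chr))
  hasStop <- last %in% .stopCodons
  chr[hasStop] <- substring(chr[hasStop], 1, nchar(chr[hasStop]) - 3)
  Transcriptome(Biostrings::DNAStringSet(stats::setNames(chr, ids)), w, ids)
}

#' Write a transcriptome to FASTA + expression TSV
#'
#' Inverse of [readTranscriptome()] (stop codons were already stripped on
#' read, so write/read round-trips are lossless).
#'
#' @param t a [Transcriptome-class].
#' @param fastaPath,expressionPath output paths.
#' @return Invisibly, `t`.
#' @export
writeTranscriptome <- function(t, fastaPath, expressionPath) {
  Biostrings::writeXStringSet(t@sequences, fastaPath)
  df <- data.frame(id = t@ids, expression = t@expression)
  utils::write.table(df, expressionPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(t)
}

#' Read / write a tRNA distribution TSV
#'
#' Columns `trna` and `abundance` (relative); abundances must already satisfy
#' the compositional invariants unless `normalize = TRUE`.
#'
#' @param path TSV path.
#' @param normalize renormalize on read.
#' @param totalConcentration optional total concentration, uM.
#' @return A [TRNADistribution-class].
#' @export
readDistribution <- function(path, normalize = FALSE,
                             totalConcentration = NA_real_) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("trna", "abundance") %in% names(df)))
    stop("distribution TSV needs columns: trna, abundance")
  TRNADistribution(df$trna, as.numeric(df$abundance),
                   totalConcentration = totalConcentration,
                   normalize = normalize)
}

#' @rdname readDistribution
#' @param d a [TRNADistribution-class].
#' @export
writeDistribution <- function(d, path) {
  utils::write.table(data.frame(trna = d@trna, abundance = d@abundance),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}

#' Read / write a cognate map TSV
#'
#' First column `trna`, optional second column `aa` (amino-acid annotation
#' used by [reduceTrnaSet()]), then one 0/1 column per sense codon.
#'
#' @param path TSV path.
#' @return A [CognateMap-class].
#' @export
readCognateMap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1] != "trna") stop("cognate map TSV must start with 'trna'")
  aa <- NULL
  first <- 2
  if (ncol(df) >= 2 && names(df)[2] == "aa") { aa <- df$aa; first <- 3 }
  codons <- names(df)[first:ncol(df)]
  m <- as.matrix(df[, first:ncol(df), drop = FALSE])
  if (!all(m %in% c(0, 1))) stop("cognate map cells must be 0 or 1")
  CognateMap(m == 1, trna = df$trna, codons = codons, aa = aa)
}

#' @rdname readCognateMap
#' @param m a [CognateMap-class].
#' @export
writeCognateMap <- function(m, path) {
  df <- data.frame(trna = m@trna, stringsAsFactors = FALSE)
  if (!all(is.na(m@aa))) df$aa <- m@aa
  df <- cbind(df, as.data.frame(m@cognate * 1L))
  names(df)[(ncol(df) - length(m@codons) + 1):ncol(df)] <- m@codons
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Read / write a component-latency table TSV
#'
#' Columns `cognate_count`, `noncognate_count`, `latency_ms`; lines starting
#' with `#` carry metadata (`# key: value`). On load the table is checked for
#' latency non-increasing in cognate count at fixed total; violations give a
#' warning (measured ensembles may be noisy), not an error.
#'
#' @param path TSV path.
#' @return A [ComponentLatencyTable-class].
#' @export
readLatencyTable <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in metaLines) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  df <- utils::read.delim(textConnection(grep("^#", lines, invert = TRUE,
                                              value = TRUE)),
                          header = TRUE, stringsAsFactors = FALSE)
  need <- c("cognate_count", "noncognate_count", "latency_ms")
  if (!all(need %in% names(df)))
    stop("latency table TSV needs columns: ", paste(need, collapse = ", "))
  tab <- new("ComponentLatencyTable",
             cognateCount = as.integer(df$cognate_count),
             noncognateCount = as.integer(df$noncognate_count),
             latencyMs = as.numeric(df$latency_ms), metadata = meta)
  tot <- tab@cognateCount + tab@noncognateCount
  for (tt in unique(tot)) {
    i <- which(tot == tt)
    o <- i[order(tab@cognateCount[i])]
    if (is.unsorted(-tab@latencyMs[o], strictly = FALSE))
      warning("latency not non-increasing in cognate count at total ", tt)
  }
  tab
}

#' @rdname readLatencyTable
#' @param tab a [ComponentLatencyTable-class].
#' @export
writeLatencyTable <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(tab@metadata))
    writeLines(sprintf("# %s: %s", k, tab@metadata[[k]]), con)
  writeLines("cognate_count\tnoncognate_count\tlatency_ms", con)
  writeLines(sprintf("%d\t%d\t%.10g", tab@cognateCount, tab@noncognateCount,
                     tab@latencyMs), con)
  invisible(tab)
}

#' Read plate-reader fluorescence traces
#'
#' @param path CSV with header columns `time_s`, `condition`, `replicate`,
#'   `batch`, `rfu` (batch optional, defaults to 1).
#' @return A validated data.frame of traces.
#' @export
readTraces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateTraces(df)
}

#' Validate a fluorescence-trace table
#'
#' Checks the long-format plate-reader table: required columns, strictly
#' increasing time within each (condition, replicate, batch) trace, and at
#' least 10 time points per trace.
#'
#' @param df data.frame with columns `time_s`, `condition`, `replicate`,
#'   `rfu` and optionally `batch`.
#' @return The data.frame, with `batch` added (all 1) if absent.
#' @export
validateTraces <- function(df) {
  need <- c("time_s", "condition", "replicate", "rfu")
  if (!all(need %in% names(df)))
    stop("trace table needs columns: ", paste(need, collapse = ", "))
  if (!"batch" %in% names(df)) df$batch <- 1L
  key <- interaction(df$condition, df$replicate, df$batch, drop = TRUE)
  for (k in levels(key)) {
    tt <- df$time_s[key == k]
    if (length(tt) < 10) stop("trace ", k, " has fewer than 10 points")
    if (is.unsorted(tt, strictly = TRUE)) stop("trace ", k,
                                               ": time not strictly increasing")
  }
  df
}
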
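# Small in-code fixtures shared across tests.

# 3 tRNA x 4 codons, one codon (AAA) with two cognate tRNA, aa-annotated.
toyMap <- function() {
  m <- rbind(Lys1 = c(AAA = TRUE,  AAG = TRUE,  GAA = FALSE, GAG = FALSE),
             Lys2 = c(AAA = TRUE,  AAG = FALSE, GAA = FALSE, GAG = FALSE),
             Glu1 = c(AAA = FALSE, AAG = FALSE, GAA = TRUE,  GAG = TRUE))
  CognateMap(m, aa = c("K", "K", "E"))
}

# 2 tRNA, 2 codons; transcripts using only AAA make Glu1 a pure
# non-cognate competitor for the codon in use.
cornerMap <- function() {
  m <- rbind(Lys1 = c(AAA = TRUE, GAA = FALSE),
             Glu1 = c(AAA = FALSE, GAA = TRUE))
  CognateMap(m, aa = c("K", "E"))
}

toyUsage <- function(freqs) {
  new("CodonUsage", codons = names(freqs), frequency = unname(freqs),
      scope = "transcriptome", transcript = NA_character_)
}

randomParams <- function() {
  SurrogateKineticParams(tauTransport = runif(1, 0.2, 5),
                         tauSuccess = runif(1, 1, 50),
                         tauCognateFail = runif(1, 0.2, 5),
                         tauReject = runif(1, 0.2, 5),
                         pSuccess = runif(1, 0.1, 1))
}

# random valid distribution over given names
randomSimplex <- function(names) {
  x <- runif(length(names), 0.05, 1)
  TRNADistribution(names, x / sum(x))
}
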
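# Internal helpers.

# Split an in-frame CDS string into codons.
.splitCodons <- function(seq) {
  seq <- as.character(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream (the GA keeps its own stream while the estimator re-seeds per call).
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Weighted mean and SD (population weights summing to 1).
.weightedMeanSD <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  c(mean = m, sd = sqrt(v))
}

# Stable content signature of an abundance vector, for evaluator caching.
.distSignature <- function(d) {
  paste(c(d@trna, sprintf("%.15e", d@abundance)), collapse = "|")
}

.stopCodons <- c("TAA", "TAG", "TGA")
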
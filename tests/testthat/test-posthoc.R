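test_that("voxel ratio pmf is a point mass when all tRNA are cognate", {
  m <- toyMap()
  d <- TRNADistribution(trnaNames(m), c(1, 0, 0))
  pmf <- sampleCognateRatios(d, m, "AAG", VoxelSamplingConfig(K = 10, M = 500))
  expect_equal(pmf$nC, 10L)
  expect_equal(pmf$prob, 1)
})

test_that("zero-cognate voxels are folded into the one-cognate bin", {
  m <- toyMap()
  # Glu1 carries nearly all abundance: AAG voxels frequently have 0 cognates
  d <- TRNADistribution(trnaNames(m), c(0.01, 0.0, 0.99))
  pmf <- sampleCognateRatios(d, m, "AAG",
                             VoxelSamplingConfig(K = 5, M = 2000, seed = 3))
  expect_false(any(pmf$nC == 0))
  expect_gte(min(pmf$nC), 1)
  # the 1-cognate bin absorbs the zero-cognate mass:
  # P(fold) = P(Bin(5, .01) <= 1) >> raw P(= 1)
  expect_gt(pmf$prob[pmf$nC == 1], 0.9)
  expect_equal(sum(pmf$prob), 1)
})

test_that("pmf matches exact binomial enumeration with the 0-bin folded
           (K = 3, 50/50)", {
  m <- cornerMap()
  d <- TRNADistribution(trnaNames(m), c(0.5, 0.5))
  cfg <- VoxelSamplingConfig(K = 3, M = 1e5, seed = 17)
  pmf <- sampleCognateRatios(d, m, "AAA", cfg)
  exact <- dbinom(0:3, 3, 0.5)
  expected <- c(exact[1] + exact[2], exact[3], exact[4]) # folded 0-bin
  got <- setNames(pmf$prob, pmf$nC)[as.character(1:3)]
  # multinomial SE per bin at M = 1e5 is < 0.0016; allow 4 SE
  expect_equal(unname(got), expected, tolerance = 0.01)
})

test_that("codon latency is the pmf-weighted kernel sum", {
  kern <- function(nC, nNC) 100 * nC
  point <- data.frame(nC = 4, nNC = 6, prob = 1)
  expect_equal(codonLatency(point, kern), 400)
  two <- data.frame(nC = c(1, 3), nNC = c(9, 7), prob = c(0.5, 0.5))
  expect_equal(codonLatency(two, kern), 200)
  set.seed(41)
  p <- runif(6); p <- p / sum(p)
  pmf <- data.frame(nC = 1:6, nNC = 10 - (1:6), prob = p)
  kern2 <- surrogateKernel()
  oracle <- 0
  for (i in 1:6) oracle <- oracle + p[i] * kern2(i, 10 - i)
  expect_equal(codonLatency(pmf, kern2), oracle, tolerance = 1e-12)
})

test_that("transcript latency is the codon-frequency-weighted mean", {
  perCodon <- c(AAA = 100, GAT = 250)
  expect_equal(transcriptLatency("AAA", perCodon), 100)
  expect_equal(transcriptLatency("AAAGATAAA", perCodon), 150)
  expect_error(transcriptLatency("AAATGC", perCodon, id = "gX"), "gX")
})

test_that("transcript latency matches per-position averaging on a long
           fixture", {
  set.seed(43)
  codons <- c("AAA", "AAG", "GAA", "GAG")
  perCodon <- setNames(runif(4, 50, 300), codons)
  s <- paste(sample(codons, 240, replace = TRUE), collapse = "")
  pos <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  expect_equal(transcriptLatency(s, perCodon), mean(perCodon[pos]),
               tolerance = 1e-12)
})

test_that("one-transcript transcriptome mean equals the transcript latency
           and the report is seed-deterministic", {
  m <- toyMap()
  d <- randomSimplex(trnaNames(m))
  t <- Transcriptome(c(only = "AAAGAAAAG"), 1)
  cfg <- VoxelSamplingConfig(K = 12, M = 400, seed = 7)
  r1 <- transcriptomeLatency(t, d, m, surrogateKernel(), cfg)
  expect_equal(transcriptomeMean(r1), unname(perTranscript(r1)["only"]))
  expect_equal(transcriptomeSD(r1), 0)
  r2 <- transcriptomeLatency(t, d, m, surrogateKernel(), cfg)
  expect_identical(perCodon(r1), perCodon(r2))
  expect_identical(transcriptomeMean(r1), transcriptomeMean(r2))
})

test_that("report is invariant to transcript order and to matched tRNA
           permutation", {
  m <- toyMap()
  set.seed(47)
  d <- randomSimplex(trnaNames(m))
  t <- Transcriptome(c(a = "AAAGAA", b = "GAGGAGAAG"), c(0.3, 0.7))
  trev <- Transcriptome(c(b = "GAGGAGAAG", a = "AAAGAA"), c(0.7, 0.3))
  cfg <- VoxelSamplingConfig(K = 10, M = 300, seed = 5)
  r <- transcriptomeLatency(t, d, m, surrogateKernel(), cfg)
  rrev <- transcriptomeLatency(trev, d, m, surrogateKernel(), cfg)
  expect_equal(transcriptomeMean(rrev), transcriptomeMean(r))
  expect_equal(perTranscript(rrev)[c("a", "b")],
               perTranscript(r)[c("a", "b")])
  # permute tRNA rows with the matching map permutation
  perm <- c(3, 1, 2)
  mperm <- CognateMap(cognateMatrix(m)[perm, ],
                      trna = trnaNames(m)[perm], codons = codons(m),
                      aa = m@aa[perm])
  dperm <- TRNADistribution(trnaNames(m)[perm],
                            unname(abundances(d)[trnaNames(m)[perm]]))
  rperm <- transcriptomeLatency(t, dperm, mperm, surrogateKernel(), cfg)
  expect_equal(transcriptomeMean(rperm), transcriptomeMean(r))
})

test_that("doubling M moves the mean by less than the sampling envelope", {
  m <- toyMap()
  d <- randomSimplex(trnaNames(m))
  t <- Transcriptome(c(a = "AAAGAAAAGGAG"), 1)
  cfg1 <- VoxelSamplingConfig(K = 20, M = 2000, seed = 3)
  cfg2 <- VoxelSamplingConfig(K = 20, M = 4000, seed = 3)
  m1 <- transcriptomeMean(transcriptomeLatency(t, d, m, cfg = cfg1))
  m2 <- transcriptomeMean(transcriptomeLatency(t, d, m, cfg = cfg2))
  expect_lt(abs(m1 - m2) / m1, 0.05)
})

test_that("moving abundance mass to the cognate tRNA never slows a
           single-codon transcriptome", {
  m <- cornerMap()
  t <- Transcriptome(c(x = "AAAAAA"), 1)
  cfg <- VoxelSamplingConfig(K = 15, M = 800, seed = 23)
  set.seed(29)
  for (rep in 1:20) {
    f <- runif(1, 0.05, 0.85)
    shift <- runif(1, 0.05, 0.95 - f)
    lo <- transcriptomeMean(transcriptomeLatency(
      t, TRNADistribution(c("Lys1", "Glu1"), c(f, 1 - f)), m, cfg = cfg))
    hi <- transcriptomeMean(transcriptomeLatency(
      t, TRNADistribution(c("Lys1", "Glu1"), c(f + shift, 1 - f - shift)),
      m, cfg = cfg))
    expect_lte(hi, lo + 1e-9)
  }
})

test_that("cached evaluator agrees with the full report and with itself", {
  m <- toyMap()
  t <- Transcriptome(c(a = "AAAGAA", b = "GAGGAGAAG"), c(0.4, 0.6))
  cfg <- VoxelSamplingConfig(K = 12, M = 500, seed = 11)
  ev <- latencyEvaluator(t, m, surrogateKernel(), cfg)
  d <- randomSimplex(trnaNames(m))
  direct <- transcriptomeMean(transcriptomeLatency(t, d, m,
                                                   surrogateKernel(), cfg))
  expect_equal(ev(d), direct, tolerance = 1e-12)
  expect_identical(ev(d), ev(d))  # cache hit returns the same value
})
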
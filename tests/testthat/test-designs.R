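test_that("uniform distribution assigns 1/n and always sums to 1", {
  expect_equal(unname(abundances(uniformDistribution(paste0("t", 1:40)))),
               rep(0.025, 40))
  expect_equal(unname(abundances(uniformDistribution(paste0("t", 1:20)))),
               rep(0.05, 20))
  set.seed(51)
  for (n in sample(1:100, 10))
    expect_equal(sum(abundances(uniformDistribution(paste0("t", 1:n)))), 1,
                 tolerance = 1e-12)
  expect_error(uniformDistribution(character(0)))
})

test_that("stepwise ladder for 40 tRNA runs 0.0012..0.048 with raw sum
           0.984", {
  map <- ecoliCognateMap()
  set.seed(53)
  u <- runif(61); u <- u / sum(u)
  usage <- toyUsage(setNames(u, codons(map)))
  d <- stepwiseDistribution(usage, map)
  raw <- rawAbundances(d)
  expect_equal(min(raw), 0.0012, tolerance = 1e-12)
  expect_equal(max(raw), 0.048, tolerance = 1e-12)
  expect_equal(sum(raw), 0.0012 * 820, tolerance = 1e-12)  # arithmetic series
  expect_equal(sum(abundances(d)), 1, tolerance = 1e-12)
  # most-used tRNA gets the top rung
  ord <- tRNAcad:::.usageOrder(usage, map)
  expect_equal(unname(raw[ord[1]]), 0.048)
})

test_that("anticorrelated stepwise is the exact reverse over the usage
           ordering", {
  map <- toyMap()
  usage <- toyUsage(c(AAA = 0.5, AAG = 0.3, GAA = 0.15, GAG = 0.05))
  cor_ <- stepwiseDistribution(usage, map)
  anti <- stepwiseDistribution(usage, map, anticorrelated = TRUE)
  ord <- tRNAcad:::.usageOrder(usage, map)
  expect_equal(unname(abundances(anti)[ord]),
               unname(rev(abundances(cor_)[ord])), tolerance = 1e-12)
})

test_that("codon-weighted design weights tRNA exactly to codon usage", {
  # one codon, one cognate tRNA -> everything on it
  m1 <- CognateMap(matrix(c(TRUE, FALSE, FALSE, TRUE), 2,
                          dimnames = list(c("a", "b"), c("AAA", "GGG"))))
  d1 <- codonWeightedDistribution(toyUsage(c(AAA = 1, GGG = 0)), m1)
  expect_equal(unname(abundances(d1)), c(1, 0))
  # disjoint single cognates follow usage; anticorrelated reverses it
  d2 <- codonWeightedDistribution(toyUsage(c(AAA = 0.6, GGG = 0.4)), m1)
  expect_equal(unname(abundances(d2)), c(0.6, 0.4))
  d2a <- codonWeightedDistribution(toyUsage(c(AAA = 0.6, GGG = 0.4)), m1,
                                   anticorrelated = TRUE)
  expect_equal(unname(abundances(d2a)), c(0.4, 0.6))
})

test_that("degenerate codons split usage equally among cognate tRNA", {
  m <- toyMap()   # AAA read by Lys1 and Lys2
  usage <- c(AAA = 0.4, AAG = 0.2, GAA = 0.3, GAG = 0.1)
  d <- codonWeightedDistribution(toyUsage(usage), m)
  # loop oracle with equal split
  oracle <- c(Lys1 = 0, Lys2 = 0, Glu1 = 0)
  split <- list(AAA = c("Lys1", "Lys2"), AAG = "Lys1",
                GAA = "Glu1", GAG = "Glu1")
  for (cod in names(usage))
    for (tr in split[[cod]])
      oracle[tr] <- oracle[tr] + usage[[cod]] / length(split[[cod]])
  expect_equal(abundances(d), oracle / sum(oracle), tolerance = 1e-12)
})

test_that("random bounded distributions are feasible, in-bounds and
           seed-reproducible", {
  nm <- paste0("t", 1:40)
  b <- DistributionBounds(0.0015, 0.0852)
  for (s in 1:1000) {
    d <- randomDistribution(nm, b, seed = s)
    ab <- abundances(d)
    expect_true(all(ab >= b@lower - 1e-12 & ab <= b@upper + 1e-12))
    expect_equal(sum(ab), 1, tolerance = 1e-9)
  }
  expect_identical(abundances(randomDistribution(nm, b, seed = 7)),
                   abundances(randomDistribution(nm, b, seed = 7)))
  # degenerate bounds force the uniform distribution
  d0 <- randomDistribution(paste0("t", 1:40),
                           new("DistributionBounds", lower = 0.025 - 1e-12,
                               upper = 0.025 + 1e-12), seed = 1)
  expect_equal(unname(abundances(d0)), rep(0.025, 40), tolerance = 1e-9)
  expect_error(randomDistribution(paste0("t", 1:3), b), "infeasible")
})

test_that("pairwise perturbation re-splits the pair at ratio 1.1 and
           conserves total mass", {
  map <- toyMap()
  usage <- toyUsage(c(AAA = 0.5, AAG = 0.3, GAA = 0.15, GAG = 0.05))
  ord <- tRNAcad:::.usageOrder(usage, map)
  d <- TRNADistribution(trnaNames(map), rep(1 / 3, 3))
  p <- pairwisePerturbation(d, usage, map, 1)
  ab <- abundances(p)
  s <- 2 / 3
  expect_equal(unname(ab[ord[1]]), s * 1.1 / 2.1, tolerance = 1e-12)
  expect_equal(unname(ab[ord[2]]), s * 1 / 2.1, tolerance = 1e-12)
  expect_equal(sum(ab), 1, tolerance = 1e-12)
  # idempotent on an already-ratio-1.1 pair
  p2 <- pairwisePerturbation(p, usage, map, 1)
  expect_equal(abundances(p2), ab, tolerance = 1e-12)
  expect_error(pairwisePerturbation(d, usage, map, 3), "out of range")
})

test_that("RED20-style recoding maps TTT to TTC, is a fixed point on
           recoded input, and preserves the protein", {
  rmap <- red20RecodeMap()
  expect_equal(unname(rmap[["TTT"]]), "TTC")
  t <- Transcriptome(c(a = "TTTAAAGAT"), 1)
  r <- recodeTranscriptome(t, rmap)
  expect_identical(as.character(sequences(r)[["a"]]),
                   paste0(rmap[["TTT"]], rmap[["AAA"]], rmap[["GAT"]]))
  r2 <- recodeTranscriptome(r, rmap)
  expect_identical(as.character(sequences(r2)), as.character(sequences(r)))
  # translation oracle over 50 random fixtures
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  set.seed(61)
  for (rep in 1:50) {
    s <- paste(sample(sense, 40, replace = TRUE), collapse = "")
    tt <- Transcriptome(setNames(s, "x"), 1)
    rr <- recodeTranscriptome(tt, rmap)
    expect_identical(
      as.character(Biostrings::translate(sequences(rr)[[1]],
                                         no.init.codon = TRUE)),
      as.character(Biostrings::translate(sequences(tt)[[1]],
                                         no.init.codon = TRUE)))
    cods <- unique(tRNAcad:::.splitCodons(as.character(sequences(rr)[[1]])))
    expect_true(all(cods %in% red20Codons()$codon))
  }
})

test_that("tRNA-set reduction conserves mass within amino acids", {
  m <- toyMap()
  d <- TRNADistribution(trnaNames(m), c(0.3, 0.2, 0.5))
  r <- reduceTrnaSet(d, m, kept = c("Lys1", "Glu1"))
  expect_equal(abundances(r), c(Lys1 = 0.5, Glu1 = 0.5))
  # identity reduction
  rid <- reduceTrnaSet(d, m, kept = trnaNames(m))
  expect_equal(abundances(rid), abundances(d))
  # orphan dropped tRNA errors
  expect_error(reduceTrnaSet(d, m, kept = c("Lys1", "Lys2")), "Glu1")
  # random fixtures: sum 1 and loop-redistribution oracle
  map <- ecoliCognateMap()
  kept <- trnaNames(map)[apply(cognateMatrix(map)[, red20Codons()$codon],
                               2, which)]
  set.seed(67)
  for (rep in 1:10) {
    d <- randomSimplex(trnaNames(map))
    r <- reduceTrnaSet(d, map, kept)
    expect_equal(sum(abundances(r)), 1, tolerance = 1e-9)
    aa <- setNames(map@aa, map@trna)
    oracle <- abundances(d)[kept]
    for (nm in setdiff(trnaNames(map), kept)) {
      partners <- kept[aa[kept] == aa[[nm]]]
      oracle[partners] <- oracle[partners] +
        abundances(d)[[nm]] / length(partners)
    }
    expect_equal(abundances(r), oracle, tolerance = 1e-12)
  }
})

test_that("codon-weighted correlated and anticorrelated designs have
           opposite-sign usage slopes", {
  sys <- makeToySystem(SyntheticSpec(nTrna = 10, nCodons = 18, seed = 71))
  u <- sys$usage
  cw <- codonWeightedDistribution(u, sys$map)
  cwa <- codonWeightedDistribution(u, sys$map, anticorrelated = TRUE)
  expect_gt(correlationSlope(u, cognateFractionPerCodon(cw, sys$map)), 0)
  expect_lt(correlationSlope(u, cognateFractionPerCodon(cwa, sys$map)), 0)
})
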
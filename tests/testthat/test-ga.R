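test_that("fitness follows the fast/slow share formulas and sums to 1", {
  expect_equal(gaFitness(rep(150, 100), "fast"), rep(0.01, 100))
  expect_equal(gaFitness(rep(150, 100), "slow"), rep(0.01, 100))
  expect_equal(gaFitness(c(100, 200), "fast"), c(2 / 3, 1 / 3))
  expect_equal(gaFitness(c(100, 200), "slow"), c(1 / 3, 2 / 3))
  set.seed(81)
  for (dir in c("fast", "slow"))
    expect_equal(sum(gaFitness(runif(30, 100, 300), dir)), 1,
                 tolerance = 1e-12)
  expect_error(gaFitness(c(100, -5), "fast"), "> 0")
})

test_that("a generation conserves population size and mutations stay in
           bounds before renormalization", {
  m <- cornerMap()
  b <- DistributionBounds(0.2, 0.8)
  cfg <- GAConfig(populationSize = 12, generations = 1, nRemoved = 4,
                  nPairs = 2, nSwapped = 1, nMutated = 1, bounds = b,
                  seed = 5)
  ev <- function(d) 1 / abundances(d)[["Lys1"]]  # deterministic toy latency
  set.seed(5)
  pop <- lapply(1:12, function(i) randomDistribution(trnaNames(m), b, i))
  out <- evolveGeneration(pop, cfg, ev)
  expect_length(out$pop, 12)
  expect_equal(sum(out$fitness), 1, tolerance = 1e-12)
  # draws at mutation time respect the published bounds
  b2 <- DistributionBounds(0.0015, 0.0852)
  set.seed(7)
  draws <- runif(1e4, b2@lower, b2@upper)
  expect_true(all(draws >= 0.0015 & draws <= 0.0852))
})

test_that("with operators disabled the best latency never worsens
           (elitism)", {
  sys <- makeToySystem(SyntheticSpec(nTrna = 8, nCodons = 14, seed = 83))
  cfg <- GAConfig(populationSize = 14, generations = 15, nRemoved = 4,
                  nPairs = 2, nSwapped = 0, nMutated = 0,
                  bounds = DistributionBounds(0.01, 0.4),
                  direction = "fast", seed = 19)
  res <- runGA(sys$transcriptome, sys$map, surrogateKernel(), cfg,
               samplingConfig = VoxelSamplingConfig(K = 15, M = 200,
                                                    seed = 19))
  expect_true(all(diff(trajectory(res)$bestLatency) <= 1e-9))
  cfgS <- GAConfig(populationSize = 14, generations = 15, nRemoved = 4,
                   nPairs = 2, nSwapped = 0, nMutated = 0,
                   bounds = DistributionBounds(0.01, 0.4),
                   direction = "slow", seed = 19)
  resS <- runGA(sys$transcriptome, sys$map, surrogateKernel(), cfgS,
                samplingConfig = VoxelSamplingConfig(K = 15, M = 200,
                                                     seed = 19))
  expect_true(all(diff(trajectory(resS)$bestLatency) >= -1e-9))
})

test_that("generations = 0 returns the best of the random initial
           population", {
  sys <- makeToySystem(SyntheticSpec(nTrna = 6, nCodons = 10, seed = 89))
  cfg <- GAConfig(populationSize = 8, generations = 0, nRemoved = 2,
                  nPairs = 1, bounds = DistributionBounds(0.02, 0.5),
                  seed = 3)
  res <- runGA(sys$transcriptome, sys$map, surrogateKernel(), cfg,
               samplingConfig = VoxelSamplingConfig(K = 12, M = 200,
                                                    seed = 3))
  expect_equal(nrow(trajectory(res)), 0)
  expect_equal(bestLatency(res), min(res@finalLatencies))
  expect_length(res@finalPopulation, 8)
})

test_that("the GA is bit-identical under a fixed seed and the reported best
           re-evaluates to its latency", {
  sys <- makeToySystem(SyntheticSpec(nTrna = 6, nCodons = 10, seed = 89))
  cfg <- GAConfig(populationSize = 10, generations = 8, nRemoved = 2,
                  nPairs = 1, nSwapped = 2, nMutated = 1,
                  bounds = DistributionBounds(0.02, 0.5), seed = 31)
  scfg <- VoxelSamplingConfig(K = 12, M = 200, seed = 31)
  r1 <- runGA(sys$transcriptome, sys$map, surrogateKernel(), cfg, scfg)
  r2 <- runGA(sys$transcriptome, sys$map, surrogateKernel(), cfg, scfg)
  expect_identical(abundances(bestDistribution(r1)),
                   abundances(bestDistribution(r2)))
  expect_identical(trajectory(r1), trajectory(r2))
  ev <- latencyEvaluator(sys$transcriptome, sys$map, surrogateKernel(), scfg)
  expect_equal(ev(bestDistribution(r1)), bestLatency(r1), tolerance = 1e-12)
})
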
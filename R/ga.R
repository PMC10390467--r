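# CD-CAD genetic algorithm over tRNA abundance distributions.
#
# Per generation: evaluate <tau_elong> for each individual -> fitness
# (inverse-latency share for "fast", latency share for "slow") -> drop the
# nRemoved lowest-fitness individuals (stable ties) -> sample nPairs parent
# pairs (distinct within a pair, probability proportional to fitness) ->
# offspring are modified COPIES of the parents: swap nSwapped positions
# between the two copies, redraw nMutated positions per copy uniformly
# inside the bounds, renormalize to unit sum -> append offspring.
# Survivors persist untouched, so with operators disabled the best
# individual can never be lost (elitism).

#' Fitness of a population of latencies
#'
#' Fast mode rewards short latencies with the normalized inverse-latency
#' share \eqn{f_i = \tau_i^{-1} / \sum_j \tau_j^{-1}}; slow mode rewards
#' long latencies with the latency share \eqn{f_i = \tau_i / \sum_j \tau_j}.
#' Fitness sums to 1 in both modes.
#'
#' @param latencies per-individual transcriptome-average latencies, ms (> 0).
#' @param direction `"fast"` or `"slow"`.
#' @return Numeric fitness vector summing to 1.
#' @examples
#' gaFitness(c(100, 200), "fast")  # 2/3, 1/3
#' gaFitness(c(100, 200), "slow")  # 1/3, 2/3
#' @export
gaFitness <- function(latencies, direction = c("fast", "slow")) {
  direction <- match.arg(direction)
  if (any(!is.finite(latencies)) || any(latencies <= 0))
    stop("latencies must be finite and > 0")
  w <- if (direction == "fast") 1 / latencies else latencies
  w / sum(w)
}

# One offspring pair from parents a, b (abundance vectors).
.recombineMutate <- function(a, b, cfg) {
  n <- length(a)
  if (cfg@nSwapped > 0) {
    sw <- sample.int(n, min(cfg@nSwapped, n))
    tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
  }
  mutate <- function(x) {
    if (cfg@nMutated > 0) {
      mu <- sample.int(n, min(cfg@nMutated, n))
      x[mu] <- stats::runif(length(mu), cfg@bounds@lower, cfg@bounds@upper)
    }
    x / sum(x)
  }
  list(mutate(a), mutate(b))
}

#' Advance the GA population by one generation
#'
#' @param pop list of [TRNADistribution-class], length
#'   `cfg@populationSize`.
#' @param cfg a [GAConfig-class].
#' @param evaluator function `(TRNADistribution) -> latency ms`, e.g. from
#'   [latencyEvaluator()].
#' @return List with the new `pop`, the evaluated `latencies` and `fitness`
#'   of the incoming population.
#' @export
evolveGeneration <- function(pop, cfg, evaluator) {
  if (length(pop) != cfg@populationSize)
    stop("population size must be ", cfg@populationSize)
  latencies <- vapply(pop, evaluator, numeric(1))
  fitness <- gaFitness(latencies, cfg@direction)
  drop <- order(fitness)[seq_len(cfg@nRemoved)]   # stable: ties by index
  keep <- setdiff(seq_along(pop), drop)
  if (length(keep) < 2) stop("fewer than 2 survivors")
  survivors <- pop[keep]
  survFit <- fitness[keep]
  offspring <- vector("list", 2L * cfg@nPairs)
  for (p in seq_len(cfg@nPairs)) {
    pair <- sample.int(length(survivors), 2, prob = survFit)
    a <- survivors[[pair[1]]]; b <- survivors[[pair[2]]]
    ch <- .recombineMutate(abundances(a), abundances(b), cfg)
    offspring[[2 * p - 1]] <- TRNADistribution(a@trna, unname(ch[[1]]))
    offspring[[2 * p]] <- TRNADistribution(a@trna, unname(ch[[2]]))
  }
  list(pop = c(survivors, offspring), latencies = latencies,
       fitness = fitness)
}

#' Run the CD-CAD genetic algorithm
#'
#' Initializes a population of bounded random distributions, evolves it for
#' `cfg@generations` generations and returns the best individual of the
#' final evaluated population together with the per-generation trajectory.
#' Bit-identical under a fixed `cfg@seed`.
#'
#' @param t a [Transcriptome-class].
#' @param m a [CognateMap-class].
#' @param kernel kernel function `(nC, nNC) -> ms`.
#' @param cfg a [GAConfig-class].
#' @param samplingConfig a [VoxelSamplingConfig-class] for the estimator.
#' @param evaluator optional custom evaluator `(TRNADistribution) -> ms`;
#'   default is a cached [latencyEvaluator()].
#' @return A [GAResult-class].
#' @export
runGA <- function(t, m, kernel = surrogateKernel(), cfg = GAConfig(),
                  samplingConfig = VoxelSamplingConfig(seed = cfg@seed),
                  evaluator = NULL) {
  if (is.null(evaluator))
    evaluator <- latencyEvaluator(t, m, kernel, samplingConfig)
  better <- if (cfg@direction == "fast") which.min else which.max
  .withSeed(cfg@seed, {
    pop <- lapply(seq_len(cfg@populationSize), function(i)
      randomDistribution(m@trna, cfg@bounds,
                         seed = sample.int(.Machine$integer.max, 1)))
    traj <- data.frame(generation = integer(), meanLatency = numeric(),
                       bestLatency = numeric())
    for (g in seq_len(cfg@generations)) {
      step <- evolveGeneration(pop, cfg, evaluator)
      pop <- step$pop
      traj[g, ] <- list(g, mean(step$latencies),
                        step$latencies[better(step$latencies)])
    }
    finalLat <- vapply(pop, evaluator, numeric(1))
    b <- better(finalLat)
    new("GAResult", bestDistribution = pop[[b]], bestLatency = finalLat[b],
        trajectory = traj, finalPopulation = pop, finalLatencies = finalLat,
        config = cfg)
  })
}
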
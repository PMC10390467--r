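---
title: "Designing tRNA abundance distributions for translation-rate engineering"
author: "tRNAcad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tRNA abundance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAcad)
```

## The problem

In a translating cell — or a bottom-up reconstituted expression system such
as PURE — most of the time a ribosome spends adding one amino acid is spent
sampling ternary complexes (TCs: aminoacylated tRNA bound to EF-Tu·GTP)
until a *cognate* one arrives and reacts successfully. The expected time per
peptide bond, the **elongation latency** (ms), therefore depends strongly on
the *relative abundances* of the tRNA species: shifting abundance toward the
tRNA that read frequently used codons makes translation faster, shifting it
away makes translation slower, all at fixed total tRNA concentration.

tRNAcad treats the tRNA abundance distribution as a designable,
compositional engineering variable. It provides:

1. a **latency kernel** giving the expected single-codon latency of a
   translation voxel with given cognate / non-cognate TC counts;
2. a **post-hoc estimator** mapping (distribution, cognate map, weighted
   transcriptome) to per-codon, per-transcript and transcriptome-average
   latencies;
3. **rational designs** (uniform, stepwise, codon-weighted, bounded random,
   pairwise perturbations) and **reduced-code tooling** (RED20-style
   recoding, tRNA-set reduction);
4. the **CD-CAD genetic algorithm** that evolves distributions toward a
   specified speed;
5. the **TINA recipe calculator** turning a designed distribution into
   pipettable stock volumes; and
6. a **kinetics pipeline** extracting protein-synthesis rates from
   plate-reader fluorescence traces to validate designs in vitro.

## The latency model

### Component latencies

The unit quantity is the *component elongation latency* `L(n_c, n_nc)`: the
expected time for a ribosome in a voxel containing `n_c` cognate and `n_nc`
non-cognate TCs to complete one elongation step. Production-grade values of
`L` come from expensive colloidal-dynamics ensembles; tRNAcad consumes such
pre-computed tables through `readLatencyTable()` / `tableKernel()` (a TSV
dialect with `cognate_count`, `noncognate_count`, `latency_ms` columns;
absent keys are linearly interpolated on cognate fraction, extrapolation is
an error).

For self-contained work the package also provides a **Markov surrogate**
(`surrogateKernel()`): encounters arrive every `tauTransport` ms; an
encounter is cognate with probability `q = n_c / (n_c + n_nc)`; cognate
encounters succeed with probability `pSuccess` (taking `tauSuccess` ms) or
fail (`tauCognateFail` ms); non-cognate encounters always fail
(`tauReject` ms). Near-cognate encounters are deliberately folded into the
rejection pathway — the post-hoc procedure only tracks cognate:non-cognate
ratios, so a single effective rejection latency is the right level of
coarse-graining. With per-encounter success probability `p = q * pSuccess`,

$$E[T] \;=\; \Big(\tfrac{1}{p} - 1\Big)\Big(\tau_t +
\frac{q(1-p_s)\tau_{cf} + (1-q)\tau_r}{1-p}\Big) + \tau_t + \tau_s,$$

which `simulateLatencyMC()` verifies by Monte Carlo (the sampler draws the
geometric number of encounters and the binomial split of failure types —
distributionally identical to simulating each encounter's Bernoulli type
and outcome one by one, but vectorizable). The closed form is strictly
decreasing in `n_c` at fixed voxel total and tends to
`tauTransport + tauSuccess` as competition vanishes.

The surrogate's default parameters (`SurrogateKineticParams()`:
`tauTransport` 1.0, `tauSuccess` 35, `tauCognateFail` 1.5, `tauReject` 1.5
ms, `pSuccess` 0.5) are a one-time calibration chosen so that wild-type-like
per-codon cognate fractions (roughly 0.02–0.05 of a 42-TC voxel) give
single-codon latencies in the 150–250 ms range characteristic of
bacterial-scale translation. The surrogate is a documented stand-in
contract for table-backed kernels, not a reproduction of any particular
colloidal ensemble; quantitative agreement with externally computed tables
can only be checked when such tables are supplied.

### The post-hoc estimator

`transcriptomeLatency()` implements the five-step procedure:

1. For each codon, sample `M` voxel compositions of `K` TCs from the
   distribution and record the empirical pmf of (cognate, non-cognate)
   counts. Only the codon's cognate-count marginal matters, so the
   multinomial draw is sampled through its exact Binomial(`K`, `f`)
   marginal, `f` being the codon's summed cognate abundance. **Voxels with
   zero cognates are recorded as having one cognate** — a specified
   distribution must keep every codon translatable, so the untranslatable
   state is approximated by the minimal translating voxel. This folding
   rule matters most for codons whose cognate tRNA are rare.
2. Per-codon latency = pmf-weighted sum of component latencies.
3. Per transcript, relative codon frequencies.
4. Per-transcript latency = codon-frequency-weighted mean of (2) — the
   expected latency per elongation step.
5. Transcriptome latency = expression-weighted mean over transcripts; the
   SD is likewise taken across transcripts, expression-weighted (the
   per-transcript spread, not Monte-Carlo replicate error).

Defaults `K = 42`, `M = 1000` keep a full 61-codon, 30-transcript estimate
at tens of milliseconds while stable to about ±1 ms; both are exposed in
`VoxelSamplingConfig()` along with the mandatory seed (fixed seed gives a
bit-identical `LatencyReport`, with one deterministic RNG substream per
codon so reports are invariant to transcript ordering and to matched
tRNA/map permutations).

```{r estimator}
map <- ecoliCognateMap()
sys <- makeStudySystem(map, seed = 1)
cfg <- VoxelSamplingConfig(K = 42, M = 1000, seed = 1)
transcriptomeLatency(sys$transcriptome, sys$distribution, map,
                     surrogateKernel(), cfg)
```

## Rational designs

`uniformDistribution()` is the equal-abundance baseline.
`stepwiseDistribution()` sorts tRNA by total cognate-codon usage and assigns
the arithmetic ladder `step, 2*step, ..., n*step` (default step 0.0012, so
for 40 tRNA the raw ladder runs 0.12%–4.8% with raw sum 98.4%; both the raw
ladder — `rawAbundances()` — and the normalized copy are kept, since
published descriptions leave the renormalization step implicit).
`codonWeightedDistribution()` weights tRNA exactly to their corresponding
codon usage; a codon read by several tRNA splits its usage **equally** among
them (the unique symmetric choice where the published prose says only
"exactly weighting"). Anticorrelated variants reverse the assignment
(stepwise) or the rank order of the abundance multiset (codon-weighted).
Usage ties are broken lexicographically by tRNA name so designs are
deterministic. `randomDistribution()` draws iid uniform abundances inside
`DistributionBounds()` and normalizes by clip-and-rescale iteration (the
published work is silent on how bounded vectors were normalized; the
iteration converges to unit sum within 1e-9 while respecting the bounds,
and errors after 1000 iterations rather than returning an out-of-bounds
vector).

The cognate map itself is an explicit, editable input
(`ecoliCognateMap()` ships a curated 40 tRNA × 61 codon default following
standard E. coli isoacceptor wobble assignments), never inferred from
wobble rules at run time: full cognate matrices are rarely printed, and a
TSV the user can edit beats hard-coded pairings. Near-cognates are not a
separate class in the data model (boolean map); they exist only inside the
surrogate kernel's rejection latency.

For fail-safe reduced codes, `red20Codons()` ships an editable RED20-style
table (one sense codon per amino acid; Phe is TTC so every TTT recodes to
TTC). It is a reconstruction in the spirit of published minimal codes, not
a copy of any specific published table. `recodeTranscriptome()` substitutes
codon-by-codon (protein sequence provably invariant), and
`reduceTrnaSet()` reassigns dropped tRNA abundance to kept same-amino-acid
tRNA, conserving total mass.

## The CD-CAD genetic algorithm

`runGA()` evolves `populationSize` (default 100) bounded random
distributions for `generations` (default 2000) generations. Fitness is the
normalized inverse-latency share (fast) or latency share (slow). Each
generation removes the `nRemoved = 10` lowest-fitness individuals, samples
`nPairs = 5` parent pairs with probability proportional to fitness
(distinct within a pair; pairs may share parents), and appends modified
*copies* of the parents: `nSwapped = 8` positions swapped between the two
copies, `nMutated = 4` positions redrawn uniformly inside the bounds, then
renormalized to unit sum. Design choices worth stating:

- **Survivors persist untouched** ("added the offspring" semantics), which
  gives elitism: with operators disabled the best latency is provably
  monotone non-worsening, a property the tests exploit.
- **Renormalization policy**: swaps and mutations break the unit sum;
  offspring are renormalized once, and bounds are enforced at mutation draw
  time only (small post-normalization drift is tolerated). The published
  description is silent here; the policy is explicit and configurable.
- Fitness is computed once at the start of each generation; removal and
  parent sampling both use it.
- All randomness flows from one seeded stream; ties break by stable index;
  results are bit-identical under a fixed seed.
- The evaluator (`latencyEvaluator()`) memoizes per distribution content
  and re-seeds the voxel sampler per call, so evaluation is a pure function
  — this caching is what makes thousands of evaluations per run tractable,
  and why cached survivors keep exactly their previous latency.

On a one-codon toy (one cognate, one competitor tRNA) the fast-mode optimum
is analytically the cognate tRNA at the upper bound, and the GA recovers
the exhaustive grid-search optimum within grid resolution; at study scale
it beats every rational design in its direction.

## TINA recipes

`computeRecipe()` converts a designed elongator distribution into bench
arithmetic: final concentration `abundance × total` (default 200 µM total
elongator, e.g. 10 µM each for a uniform 20-tRNA set), `stockMixFold`
(default 5×) stock-mix concentrations, and source-stock volumes
`mixConc × mixVolume / stockConc`, with the initiator tRNA handled at its
fixed 10 µM outside the relative distribution. Volumes are reported at full
precision plus a 0.1 µl-rounded column (typical pipette resolution);
volumes below `minPipettableVolume` or stock-mix concentrations above the
source stock are *flagged*, never silently adjusted. `remixRecipe()`
re-simulates the mixing and recovers the specified distribution exactly
(mass balance to 1e-9), or quantifies the composition error of the rounded
volumes. Concentrations are canonical; volumes are computed for the
direct-dilution workflow.

## Kinetics analysis

`extractRates()` runs the validation pipeline on long-format plate-reader
tables: Gaussian smoothing (`sigma` 2 samples; reflect boundaries;
length-preserving), per-batch background subtraction of the replicate-mean
negative-control trace, central-difference derivative (one-sided at the
ends), derivative smoothing (`sigmaD` 2 samples), and the **windowed-mean
rate**: the mean of the smoothed derivative over the maximal contiguous run
containing its argmax where it stays at or above `threshold` (default 0.5)
of its maximum — "above before and after the max". Traces with
non-positive maximal derivative are flagged non-expressing with rate 0.
`normalizeByBatch()` divides by the reference condition's batch mean;
`ksCompare()` wraps exact small-sample Kolmogorov–Smirnov tests (one-sided
= first sample stochastically greater).

One numerical point deserves emphasis. For a logistic trace
`L/(1+e^{-k(t-t_0)})` the derivative is the self-similar bump
`(Lk/4)\,\mathrm{sech}^2`, so the windowed mean is analytically
`L k/4 \cdot \tanh(u)/u` with `u = \mathrm{atanh}(\sqrt{1-\text{threshold}})`
— about 0.802 of the maximal slope at threshold 0.5
(`logisticWindowFactor()`). Tests therefore compare recovered rates to this
exact value (agreement is ~1–2%), not to the raw `Lk/4`. By the same
self-similarity, the raw windowed mean varies ~25% across thresholds
0.3–0.7 *for any implementation* on logistic traces; what is genuinely
threshold-robust is the analysis output — batch-normalized rate ratios —
which the tests verify drifts by <10% across the sweep, alongside
per-threshold agreement with the analytic value. Real expression traces
with an extended linear production phase have flatter derivative tops and
are more threshold-robust than the logistic worst case.

## Synthetic data: what it does and does not show

`makeToySystem()` / `makeStudySystem()` generate consistent
transcriptome–map–distribution triples: Zipf-skewed codon usage (exponent
`codonUsageSkew`, 0 = uniform), tRNA reading only same-amino-acid codons
with at least one deliberately degenerate codon (two cognate tRNA,
mirroring the CUG/Leu1+Leu3 situation), and a wild-type-like distribution
proportional to equal-split cognate usage plus a floor — positively
correlated with usage by construction. `makeTraces()` emulates a
fluorescence study: logistic accumulation plus iid Gaussian noise per
replicate and a flat negative control, with defaults (plateau 1000 RFU,
slow:fast maximal-rate ratio 0.66, 5-min sampling over 12 h, noise SD 5
RFU, 5 replicates) chosen to mirror the magnitudes of real PURE GFP
studies. Every generator is a pure function of its spec and seed.

What passing tests on these fixtures shows: the estimator, designs, GA,
recipe arithmetic and kinetics pipeline are internally correct, mutually
consistent, and reproduce the analytic oracles they should. What they do
not show: quantitative agreement with any measured colloidal-dynamics
latency table or wet-lab dataset — the synthetic generators deliberately
emulate magnitudes (latencies ~150–250 ms, rate ratio 0.66) without
claiming their values. Sequence-context effects (codon pairs, dinucleotide
bias), misincorporation, and tRNA charging dynamics are out of scope by
design.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run at sizes chosen to keep a
full check in minutes on a laptop while leaving every property's outcome
stable: 30-transcript × 150-codon study transcriptomes on the full 40×61
map, `K = 42`, `M = 500–1000` voxel samples per codon, GA at population 30
× 200 generations (the defaults of 100 × 2000 remain available), Monte
Carlo kernel checks at 1e5–1e6 samples, and 100-seed kinetics studies.
Estimator properties hold for any `K ≥ 10`; `M` only narrows the Monte
Carlo envelope.

## Known limitations

- The surrogate kernel is a renewal approximation: no spatial correlation,
  crowding physics or TC depletion; use measured component-latency tables
  for quantitative work.
- The boolean cognate map cannot express near-cognate-specific rejection
  kinetics.
- The GA's bounds are enforced at draw time only; offspring can drift
  slightly outside after renormalization (logged policy, configurable
  bounds).
- Reported SDs are across transcripts; Monte-Carlo replicate error is
  controlled separately via `M`.
- The RED20-style codon table is a reconstruction; swap in an exact table
  via the TSV fixtures if you have one.
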
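---
title: "Inferring lineage fitness reaction norms from haplotype time series"
author: "normsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lineage fitness reaction norms from haplotype time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Experimental evolution with a fully self-fertilizing organism — here
*Caenorhabditis elegans* populations facing rising NaCl concentrations —
produces time series of haplotype counts: individuals sampled from replicate
populations at a few generations, each genotyped at SNPs across one pair of
chromosomes (a *region*). Because hermaphrodites reproducing strictly by
selfing are essentially homozygous, each individual carries one *region-wide
haplotype* (RWH) per region, and whole genomes descend clonally as *lineages*
(one RWH per region). The scientific question is how each lineage's expected
absolute fitness varies with the environment — its *fitness reaction norm* —
because the geometry of those norms (in particular, where they cross along
the salt axis) determines who wins under a sudden versus a gradual
environmental change.

`normsel` implements the full path from raw genotype calls to fitted
reaction norms and forward predictions:

1. quality control and haplotype construction (`applyQC()`, `callsToCwh()`,
   `cwhToRwh()`, `tallyRwh()`, `groupMinor()`, `poolToRegime()`);
2. the deterministic selection model (`selectionStep()`,
   `predictTrajectories()`, `crossingPoints()`, `meanFitness()`);
3. maximum-likelihood inference of per-RWH norm coefficients over an
   ensemble of resampled ancestral states (`fitMLE()`, `fitEnsemble()`);
4. finite-population Wright–Fisher simulation with founder bottlenecks
   (`simulateWF()`, `bottleneck()`, `sweepProbability()`,
   `founderExperiment()`);
5. a synthetic-data generator with complete ground truth
   (`designSpec()`, `makeReactionNorms()`, `simulateExperiment()`).

# The model

A population holds $G$ lineages at frequencies $g_k(t)$. With discrete
non-overlapping generations, viability selection, no density or frequency
dependence, and an infinite population, the frequencies follow the
replicator (logistic) update

$$ g_k(t+1) \;=\; \frac{\lambda_k(x(t+1))\, g_k(t)}
   {\sum_j \lambda_j(x(t+1))\, g_j(t)}, $$

where $x(t)$ is the NaCl concentration (mM) of generation $t$ and
$\lambda_k(x)$ the expected per-capita offspring number of lineage $k$ at
environment $x$. Log fitness is additive over the lineage's constituent
RWHs:

$$ \xi_k(x) \;=\; \log \lambda_k(x) \;=\; \sum_{l \in S_k} f(x \mid \theta_l), $$

with $f$ linear ($a_l x + b_l$) or quadratic ($a_l x^2 + b_l x + c_l$) in
$x$. Units: $x$ in mM NaCl; $f$ and $\xi$ in natural-log offspring per
capita per generation.

Between genotyped generations ("epochs", at generations 0, 10, 35 and 50 in
the motivating design) the per-generation normalizations cancel, so the
epoch update is the single-shot product form
$g_k^{[h]} \propto \exp\!\big(\sum_{t=T_{h-1}+1}^{T_h} \xi_k(x(t))\big)\,
g_k^{[h-1]}$. The package always evaluates this in log space with
max-subtraction; frequencies are never clipped to zero (a consequence of the
infinite-population assumption: a positive frequency stays positive).

Built-in environment schedules mirror the three regimes: *sudden* (305 mM
from generation 1), *gradual* (33 mM at generation 1, +8 mM per generation,
reaching 305 mM at generation 35 and constant thereafter) and *control*
(25 mM). All are overridable via `envSchedule(env = ...)` or a sparse
schedule table with piecewise-constant forward fill
(`readScheduleTable()`).

# The likelihood

Inference treats the ancestral state $(A, g^{[0]})$ — the lineage set and
its starting frequencies — as given, and estimates the coefficient vector
$\Theta$ over all RWHs. Two data sources enter, summed over regimes $c$:

**Genotype term.** The observed RWH counts $n_{c,l}^{[h]}$ at epoch $h$
contribute a multinomial log-likelihood under the predicted marginal RWH
frequencies, $\sum_{h \ge 1} \sum_l n_{c,l}^{[h]}
\log \sum_k I(l \in S_k)\, g_k^{[h]}$. Marginals are per region (every
lineage carries exactly one RWH per region). Observed RWHs that no assumed
lineage carries are remapped to their region's background pseudo-RWH
(`H0R1`, ...); a predicted marginal below `marginal_floor` (default
`1e-12`) contributes the floor's log rather than $-\infty$, with a counter
reported on the result.

**Fitness term.** Population mean-fitness assays $\phi$ at environment
$x_m$ contribute $-\big(\log \frac{\sum_k \lambda_k(x_m) g_k^{[h]}}{\phi}
\big)^2$ — a unit-variance log-normal noise kernel, symmetric in the
predicted/observed ratio. Only the ancestral (epoch 0) assays at 25 and
305 mM are used for fitting by default (`fit_envs`); other assay
concentrations are retained for validation. Because the epoch-0 state is
shared by all regimes, these observations enter the total likelihood once
rather than once per regime — both terms are defined only up to
proportionality, so this is a weighting choice, exposed as
`fitness_weight` (default 1).

## Why the likelihood is cheap

Cumulated log-fitness is *linear* in the coefficients: for epoch $h$,
$\sum_{t \le T_h} \xi_k(x(t)) = \sum_{l \in S_k}\!\big(a_l S_x(h) + b_l T_h\big)$
(linear form; the quadratic form adds $\sum x^2$), with the environment
moments $S_x(h) = \sum_{t\le T_h} x(t)$ precomputed once per regime. Epoch
states are a softmax of an affine function of $\Theta$, so both the
log-likelihood and its exact gradient are a handful of small matrix
products. The test suite verifies the analytic gradient against central
finite differences to $10^{-4}$ relative.

## Identifiability

Per-RWH coefficients carry a gauge freedom: adding a constant to every
intercept in one region and subtracting it in another leaves every
$\xi_k$ — hence all frequencies *and* all absolute-fitness predictions —
unchanged (each lineage has exactly one RWH per region; the same holds for
slopes). The likelihood is exactly flat along these directions, which is
harmless for optimization but means only *lineage-level* quantities
(log-fitness values, their differences, crossing points, trajectories) are
identifiable and comparable across fits. All package summaries and the
validation harness therefore work at the lineage level. The test suite
asserts the flatness explicitly.

# Ancestral-state sampling

The true ancestral lineage set is unobserved: the genotyping design sees
marginal RWH counts per region, never whole genomes. `sampleAncestral()`
emulates drawing $(A, g^{[0]})$ given the data:

* per region, plug-in multinomial RWH frequencies from the ancestral sample
  (`estimateAncestralFreqs()`, optional add-one smoothing, off by default);
* a parametric bootstrap resamples each region's frequency vector at its
  genotyped sample size, propagating genotyping sampling noise into the
  ensemble (disable with `bootstrap = FALSE`);
* the lineage set is all combinations of the *primary* RWHs across regions
  (top 3 per sample by maximum observed frequency, after regime pooling),
  plus `n_secondary` randomly composed secondary lineages (one RWH per
  region, drawn proportionally to frequency; duplicates merged; background
  pseudo-RWHs participate as ordinary RWHs). The default is 2 secondary
  draws per genotyped replicate population;
* $g^{[0]}$ is the product of the constituent-RWH frequencies (linkage
  equilibrium among regions), renormalized.

The combination-of-primaries construction and the linkage-equilibrium
product reflect what the genotyping design can support; the secondary-draw
count and the bootstrap are this package's own documented choices for
representing the remaining uncertainty.

# Optimization

`fitMLE()` maximizes the combined likelihood by BFGS with the analytic
gradient from `n_starts` (default 10) initial coefficient vectors: start 1
is a neutral baseline (zero slopes, intercepts sized so lineage fitness
matches the mean observed assay growth rate), the rest draw slopes
uniformly from $(-0.02, 0.02)$ per mM and intercepts from $(-1, 2)$
(quadratic terms from $(-10^{-4}, 10^{-4})$ per mM²) — brackets for
biologically plausible per-generation growth. Two conditioning details
matter in practice:

* **Parameter scaling.** A unit slope change cumulates over
  $\sum_t x(t) \approx 10^4$ mM·generations while a unit intercept change
  cumulates over $\approx 50$ generations. Unscaled quasi-Newton steps
  saturate all frequencies at 0/1, where the gradient vanishes and starts
  strand on plateaus. `optim`'s `parscale` is set to the typical magnitude
  of each coefficient class ($10^{-3}$ for slopes, $0.3$ for intercepts).
* **Neutral first start.** The zero-slope start lies in the basin of the
  data-consistent optimum in every case we have examined, making the
  multi-start robust rather than lucky.

Convergence: relative tolerance $10^{-8}$ on the log-likelihood, 500
iterations per start; best-of-starts by final log-likelihood with ties
broken by the smaller parameter norm (the gauge freedom above makes exact
ties possible). Per-start diagnostics are kept in the `ModelFit`.

`fitEnsemble()` repeats (sample ancestral, fit, predict) `n_anc_samples`
(default 20) times with seeds derived from one master seed by a fixed
counter scheme, and summarizes 2.5/50/97.5% frequency quantiles per
generation and lineage, with lineages matched across draws by RWH
composition. Draw failures are recorded and excluded; the ensemble errors
if more than half fail.

# The synthetic generator

`simulateExperiment()` produces complete experiments with known truth. The
defaults are the experimental conditions the package targets: 3 regions × 2 chromosomes ×
60 SNPs; epochs 0/10/35/50; regimes sudden ×4, gradual ×7, control ×3; 64
ancestral and 16 evolved individuals genotyped per region and sample;
census size $10^4$; ancestral fitness assays at 25/225/305 mM with
log-normal noise of sd 0.1 on the natural-log scale (the assay noise level
has no canonical value; 0.1 is small relative to the ~1 log-unit
fitness contrasts being planted and is our fixed choice).

The true ancestral population has 5 RWHs per region at frequencies
0.20/0.50/0.20/0.06/0.04, with lineages at linkage-equilibrium products
(125 lineages). `makeReactionNorms()` plants the focal geometry: an
*extreme-best* lineage (slope +0.004 per mM at the lineage level) and an
*intermediate-best* lineage (slope −0.002, intercept 1.6 ≈ 5 offspring per
capita at 25 mM) whose norms cross exactly at `crossing_x` (default 225 mM,
inside the range the gradual ramp traverses) via the closed-form intercept
$b_{ext} = b_{int} + (a_{int} - a_{ext})x^*$; all other RWHs are drawn
randomly strictly below both focal components at both 25 and 305 mM. With
these defaults the extreme-best lineage starts at frequency
$0.2^3 = 0.008$: common enough for its RWHs to be sampled, rare enough for
drift to threaten it — the regime of interest.

RWH allele strings are random binary with pairwise Hamming distance ≥ 4,
and one RWH per region shares each chromosome-wide haplotype with another
(more distinct RWHs than CWHs, i.e. strong but incomplete linkage, as in
real data). Emitted genotype files parse through the haplotype module and
round-trip exactly (pipeline tally equals the generator's draw record) when
corruption is off; optional uniform `missing_rate`/`het_rate` exercise the
QC path.

What the generator does **not** emulate: residual heterozygosity,
outcrossing, mutation, recombination, platform-specific error structure,
and linkage *disequilibrium between regions* in the ancestral truth (the
truth is at linkage equilibrium, matching the inference assumption).
Passing recovery tests therefore demonstrate correctness of the machinery
under the model's assumptions, not robustness to their violation in real
data.

# Numerical and procedural choices

* **QC** (`applyQC()`): drop SNPs with > 30% failed calls or > 30%
  heterozygous calls, individuals with > 25% failed calls among retained
  SNPs. The SNP and individual filters are iterated to a fixpoint (each
  drop changes the other dimension's fractions), which makes QC idempotent;
  convergence takes one or two rounds in practice.
* **Residual calls after QC**: any heterozygous call at a retained SNP
  excludes the individual from haplotype construction (selfing lineages are
  expected homozygous; imputation software is outside this package's
  scope); at most one missing call per chromosome is imputed to the
  sample's major allele, more exclude the individual.
* **RWH identifiers** are content-derived (`rwhId()`): region plus a 32-bit
  FNV-1a hash of the concatenated allele string, with a collision guard at
  construction. Identical haplotypes get identical ids across populations
  and runs.
* **Ranking and ties** in `groupMinor()`: maximum observed frequency across
  a replicate's epochs, ties by total count, then lexicographic id —
  deterministic by construction.
* **Pooling** (`poolToRegime()`): replicate counts of a regime are summed
  (the model assumes replicates share the regime's deterministic dynamics,
  so counts are exchangeable draws); an RWH primary in any replicate stays
  primary regime-wide.
* **Drift** (`simulateWF()`): exact multinomial resampling of $N$ lineage
  labels after the deterministic viability-selection update — selfing
  without recombination makes lineages asexual clones. Census $N$ is used
  directly; emulate $N_e < N$ by passing a smaller $N$. Under complete
  selfing, $N_e$ is half the outcrossing value
  (`selfingEffectiveSize()`).
* **Sweep calls** (`sweepProbability()`): frequency ≥ 0.5 at the stated
  generation by default; a sweep is not fixation. Loss = ever at frequency
  0 (permanent without mutation).
* **Seeds**: one master seed; per-start, per-draw and per-regime seeds are
  derived by a fixed affine counter (`normsel:::deriveSeeds`), keeping all
  derived seeds below $2^{31}$.

# Validation harness and problem sizes

`recoveryStudy()` runs the full generate → pool → sample → fit loop on 50
independent synthetic experiments at the design scale (sudden ×4 +
gradual ×4 replicates; 5 starts per fit) and scores (i) whether the
extreme-best lineage is ranked fittest at 305 mM and (ii) the recovered
focal crossing point against the planted 225 mM. `headlineContrast()`
contrasts loss of the extreme-best lineage by the generation each schedule
reaches 305 mM (generation 1 sudden, 35 gradual) at $N = 10^3$ over 1000
Wright–Fisher replicates, and the deterministic generation-50 frequencies.
`envelopeCoverage()` measures, for one experiment and a 20-draw ensemble,
the fraction of generations at which the true focal trajectories lie
inside the 2.5–97.5% envelope. These sizes keep the whole validation suite
within a few minutes on one core while leaving Monte-Carlo standard errors
well below the effect sizes being tested.

# Known limitations

* **The ensemble envelope is not a confidence band.** By construction,
  the genotype and fitness data stay *fixed* across ensemble draws; only
  the ancestral state is resampled. The envelope
  therefore quantifies ancestral-sampling uncertainty, not estimation
  error of the selection differentials from finite genotype samples. On
  synthetic data, where the truth is known, `envelopeCoverage()` shows the
  true trajectory regularly exits the envelope along steep sweep segments
  — a small error in a selection differential compounds linearly in
  generations on the logit scale, while the envelope stays narrow. A full
  parametric bootstrap of the data would produce honest coverage but would
  be a different procedure; we keep the original one and document the
  gap.
* Population size and drift are not part of the likelihood: a lineage lost
  in a finite replicate is indistinguishable from one at very low
  frequency. The Wright–Fisher module quantifies such effects forward in
  time only.
* No dominance, epistasis beyond log-additivity across regions,
  recombination, mutation, or frequency/density dependence — deliberate
  model assumptions inherited from the biology (selfing, short
  time-scales), not implementation gaps.
* Phasing/imputation of heterozygous or failed calls is out of scope;
  individuals not resolvable under the homozygosity rules are excluded.
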
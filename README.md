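# normsel

Inference of lineage fitness reaction norms from haplotype-frequency time
series in experimentally evolving, self-fertilizing populations — and
forward prediction of lineage dynamics under deterministic selection or
finite-population drift.

## The problem

In evolve-and-resequence experiments with a strictly selfing organism
(e.g. *C. elegans* populations driven from 25 mM up to 305 mM NaCl),
genomes descend clonally: each homozygous individual carries one
region-wide haplotype (RWH) per genotyped chromosome pair, and a
genome-wide *lineage* is a tuple of RWHs, one per region. Whether a
population adapts to the extreme environment depends on the *fitness
reaction norms* of the standing lineages — each lineage's expected
per-capita offspring number $\lambda_k(x)$ as a function of the
environmental value $x$ — and in particular on where those norms cross
along the environmental axis.

`normsel` estimates the norms from two data sources collected during
evolution under sudden / gradual / control environmental-change regimes:

* **genotype counts** $n_{c,l}^{[h]}$ of each RWH in samples of
  individuals taken at a few generations (epochs 0, 10, 35, 50), and
* **mean population fitness assays** $\phi$ of the ancestor at chosen
  environments.

The model is a deterministic replicator update
$g_k(t{+}1) \propto \lambda_k(x(t{+}1))\, g_k(t)$ with log-additive RWH
effects, $\log \lambda_k(x) = \sum_{l \in S_k} f(x \mid \theta_l)$, where
$f$ is linear ($a x + b$) or quadratic in $x$. Coefficients $\Theta$ are
estimated by multi-start quasi-Newton maximum likelihood combining a
multinomial term for the counts with a squared-log (log-normal) kernel for
the fitness assays, over an ensemble of resampled ancestral states
(lineage sets and starting frequencies are not directly observable). A
Wright–Fisher module adds drift, founder bottlenecks and sweep/loss
probabilities; a synthetic-data generator provides complete experiments
with known ground truth.

## Worked example

Generate a synthetic experiment at the default design scale (the planted
focal norms cross at 225 mM), run the count pipeline, fit the ensemble and
summarize:

```r
library(normsel)

spec  <- designSpec(regimes = c(sudden = 4L, gradual = 4L))
set.seed(11)
truth <- makeReactionNorms(spec, crossing_x = 225)
ex    <- simulateExperiment(spec, truth, seed = 11, emit = "counts")

pooled <- poolToRegime(groupMinor(truthCountsTable(ex)))
data   <- assembleInferenceData(pooled, ex$fitness, ex$schedules,
                                n_replicates = 8L)
ens    <- fitEnsemble(data, n_anc_samples = 20, n_starts = 5, seed = 11)
writeLines(makeReport(ens, data, tempfile()))
```

which prints:

```
normsel ensemble report
draws: 20  master seed: 11

regime gradual: top lineages by median frequency
  R1:f73f386d+R2:6c79b453+R3:a5f348fe  median freq at epochs [0,10,35,50]: 0.188 0.963 0.983 0.729
  R1:3167adfc+R2:e9396c89+R3:b7f30ae1  median freq at epochs [0,10,35,50]: 0.006 0.000 0.000 0.001
  R1:3167adfc+R2:e9396c89+R3:a5f348fe  median freq at epochs [0,10,35,50]: 0.012 0.000 0.000 0.013
  crossing of top-2 lineage norms: median 219.2 mM (20/20 draws)

regime sudden: top lineages by median frequency
  R1:3167adfc+R2:e9396c89+R3:b7f30ae1  median freq at epochs [0,10,35,50]: 0.006 0.355 0.987 0.999
  R1:f73f386d+R2:6c79b453+R3:a5f348fe  median freq at epochs [0,10,35,50]: 0.188 0.023 0.000 0.000
  R1:f73f386d+R2:6c79b453+R3:b7f30ae1  median freq at epochs [0,10,35,50]: 0.102 0.059 0.000 0.000
  crossing of top-2 lineage norms: median 219.2 mM (20/20 draws)
```

Read: lineages are labelled by their RWH composition (region plus a
content-derived haplotype hash). Under the *sudden* regime the
extreme-salt specialist (`R1:3167adfc+R2:e9396c89+R3:b7f30ae1`) sweeps
from <1% to ~99% by generation 50. Under the *gradual* regime the
intermediate-environment specialist rises first (96% by generation 10) and
only starts to be overtaken after the ramp reaches 305 mM — the classic
signature of crossing reaction norms. The fitted norms of the two leading
lineages cross at a median 219 mM across the 20 ancestral draws, close to
the planted 225 mM.

For real data, start from files instead: `runPipeline(list(genotypes =
"genotypes.tsv", fitness = "fitness.tsv", out = "run1", seed = 1))`
performs QC → haplotype construction → tally → grouping → pooling →
ensemble inference → prediction and writes `qc_report.json`,
`rwh_counts.tsv`, `fit.json`, `trajectories.tsv`, `report.txt` and
`run_info.json` into the run directory.

To ask finite-population questions — e.g. how often the best high-salt
lineage is *lost* before the environment gets there:

```r
hc <- headlineContrast(seed = 1, N = 1e3, n_replicates = 1000)
hc$loss_gradual   # 1.00  — lost by arrival at 305 mM (gradual, gen 35)
hc$loss_sudden    # 0.00  — lost by arrival at 305 mM (sudden, gen 1)
```

## Package layout

* `R/` — haplotype processing, selection model, likelihood and fitting,
  Wright–Fisher simulation, synthetic generator, pipeline.
* `tests/testthat/` — unit, property and end-to-end validation suites
  (closed-form oracles, brute-force enumerations, grid-search and
  Monte-Carlo checks).
* `vignettes/reaction-norm-inference.Rmd` — the model, its assumptions,
  all tunable parameters, numerical choices and known limitations.
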
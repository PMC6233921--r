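Package: normsel
Title: Inference of Lineage Fitness Reaction Norms from Haplotype
    Frequency Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolve-and-resequence studies of selfing organisms in
    changing environments. Reconstructs region-wide haplotypes from individual
    SNP genotype calls, tallies and pools haplotype counts across replicate
    populations, and infers genotype-by-environment fitness reaction norms of
    selfing lineages by maximum likelihood from haplotype-frequency time
    series combined with population mean-fitness assays. Includes a
    deterministic infinite-population selection model for trajectory
    prediction and reaction-norm crossing points, a finite-population
    Wright-Fisher simulator with founder-effect bottlenecks for sweep and
    loss probabilities, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'schedules.R'
    'reaction-norms.R'
    'lineages.R'
    'dynamics.R'
    'genotypes.R'
    'likelihood.R'
    'fit.R'
    'wf.R'
    'simulate.R'
    'validation.R'
    'pipeline.R'
    'normsel-package.R'
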
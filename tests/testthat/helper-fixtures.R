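# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk except files the tests themselves write to tempdir().

# A minimal well-formed genotype table: `n_ind` individuals of one
# population, genotyped in region 1 (chromosomes I and II), `n_snps` SNPs
# per chromosome, all homozygous REF unless a calls matrix is given.
tinyGenotypes <- function(n_ind = 2, n_snps = 3, population = "ctrl.1",
                          generation = 0L, calls = NULL) {
  chroms <- rep(c("I", "II"), each = n_snps)
  snp <- paste0(chroms, "_", rep(seq_len(n_snps), 2))
  pos <- rep(seq_len(n_snps) * 100L, 2)
  df <- do.call(rbind, lapply(seq_len(n_ind), function(i)
    data.frame(population = population, generation = generation,
               individual = paste0("ind", i), region = 1L,
               chromosome = chroms, snp_id = snp, position = pos,
               call = "REF")))
  if (!is.null(calls)) df$call <- as.vector(calls)
  df
}

# Two lineages in one region with linear norms; selection coefficient
# s = xi1 - xi2 at every environment is s305 at 305 mM and s25 at 25 mM.
twoLineageWorld <- function(s305 = 0.1, s25 = -0.1, g0 = c(0.5, 0.5)) {
  a1 <- (s305 - s25) / (305 - 25)
  b1 <- s25 - a1 * 25
  norms <- reactionNorms("linear",
    cbind(a = c(A = a1, B = 0), b = c(A = b1, B = 0)))
  lineages <- lineageSet(cbind(`1` = c("A", "B")))
  list(lineages = lineages, norms = norms,
       ancestral = ancestralState(lineages, g0))
}

# Random multi-region world for property tests: n_regions regions with
# n_rwh RWHs each, all lineage combinations at random frequencies, random
# linear norms with slopes ~ U(-a_max, a_max), intercepts ~ U(-b_max, b_max).
randomWorld <- function(n_regions = 2, n_rwh = 3, a_max = 0.004,
                        b_max = 0.5) {
  ids <- lapply(seq_len(n_regions), function(r)
    paste0("H", seq_len(n_rwh), "R", r))
  combos <- as.matrix(expand.grid(ids, KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE))
  colnames(combos) <- as.character(seq_len(n_regions))
  lineages <- lineageSet(combos)
  all_ids <- unlist(ids)
  norms <- reactionNorms("linear", cbind(
    a = setNames(runif(length(all_ids), -a_max, a_max), all_ids),
    b = setNames(runif(length(all_ids), -b_max, b_max), all_ids)))
  f <- runif(nLineages(lineages))
  list(lineages = lineages, norms = norms,
       ancestral = ancestralState(lineages, f / sum(f)))
}

# Small full synthetic experiment used by several suites.
smallExperiment <- function(seed = 1, emit = "counts",
                            regimes = c(sudden = 4L, gradual = 4L),
                            n_ancestral = 64L, n_evolved = 16L,
                            snps = 12L, ...) {
  spec <- designSpec(regimes = regimes, n_ancestral = n_ancestral,
                     n_evolved = n_evolved, snps_per_chromosome = snps)
  set.seed(seed)
  tn <- makeReactionNorms(spec)
  list(spec = spec, tn = tn,
       exp = simulateExperiment(spec, tn, seed = seed, emit = emit, ...))
}

# Assembled inference data from an experiment generated with emit="counts".
experimentData <- function(ex, top_k = 3) {
  counts <- truthCountsTable(ex$exp)
  pooled <- poolToRegime(groupMinor(counts, top_k = top_k))
  n_repl <- length(unique(paste(counts$regime, counts$replicate)[
    counts$regime != "ancestral"]))
  assembleInferenceData(pooled, ex$exp$fitness, ex$exp$schedules,
                        n_replicates = n_repl)
}

# Focal lineage ids of an experiment inside a (sampled or true) lineage set.
focalIds <- function(ex, lineages) {
  list(ext = findLineage(lineages, truthRwhIds(ex$exp, ex$tn$focal$ext)),
       int = findLineage(lineages, truthRwhIds(ex$exp, ex$tn$focal$int)))
}
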
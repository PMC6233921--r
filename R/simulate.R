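#' Design specification of a synthetic evolution experiment
#'
#' Defaults mirror the experimental design the package targets: 3 two-chromosome
#' regions, ancestral sample of 64 individuals per region and 16 per
#' evolved sample, epochs 0/10/35/50, regimes sudden (4 replicates),
#' gradual (7) and control (3), census size 1e4, fitness assays of the
#' ancestral population at 25/225/305 mM with log-normal noise (sd 0.1 on
#' the natural-log scale).
#'
#' @param n_regions number of genomic regions (default 3).
#' @param region_freqs per-region named RWH frequency vectors of the true
#'   ancestral population; default 5 RWHs per region at frequencies
#'   0.20/0.50/0.20/0.06/0.04 (H1 = extreme-best component, H2 =
#'   intermediate-best component, H3 a mid RWH, H4/H5 rare).
#' @param regimes named integer vector of replicate counts per regime.
#' @param epochs genotyped generations (first is 0, the ancestral).
#' @param n_ancestral,n_evolved individuals genotyped per region in the
#'   ancestral and each evolved sample.
#' @param census_N census size at reproduction for Wright-Fisher mode.
#' @param assay_envs,assay_replicates fitness-assay environments (mM) and
#'   technical replicates per environment.
#' @param fitness_sd log-scale standard deviation of assay noise.
#' @param snps_per_chromosome SNPs per chromosome (two chromosomes per
#'   region).
#' @return list of class `"normselDesign"`.
#' @export
designSpec <- function(n_regions = 3L,
                       region_freqs = NULL,
                       regimes = c(sudden = 4L, gradual = 7L, control = 3L),
                       epochs = c(0L, 10L, 35L, 50L),
                       n_ancestral = 64L, n_evolved = 16L,
                       census_N = 1e4,
                       assay_envs = c(25, 225, 305),
                       assay_replicates = 4L,
                       fitness_sd = 0.1,
                       snps_per_chromosome = 60L) {
  if (is.null(region_freqs)) {
    region_freqs <- lapply(seq_len(n_regions), function(r)
      setNames(c(0.20, 0.50, 0.20, 0.06, 0.04),
               paste0("H", 1:5, "R", r)))
    names(region_freqs) <- seq_len(n_regions)
  }
  stopifnot(length(region_freqs) == n_regions,
            all(vapply(region_freqs, function(f) abs(sum(f) - 1) < 1e-9,
                       TRUE)),
            epochs[1] == 0L, !is.unsorted(epochs, strictly = TRUE),
            n_ancestral >= 1, n_evolved >= 1)
  structure(list(n_regions = as.integer(n_regions),
                 region_freqs = region_freqs,
                 regimes = regimes, epochs = as.integer(epochs),
                 n_ancestral = as.integer(n_ancestral),
                 n_evolved = as.integer(n_evolved),
                 census_N = census_N, assay_envs = assay_envs,
                 assay_replicates = as.integer(assay_replicates),
                 fitness_sd = fitness_sd,
                 snps_per_chromosome = as.integer(snps_per_chromosome)),
            class = "normselDesign")
}

#' Synthetic RWH reaction norms with a planted crossing
#'
#' Constructs linear per-RWH log-fitness norms such that two focal
#' lineages — the "intermediate-best" (favored at low-to-mid salt) and the
#' "extreme-best" (favored at high salt) — have lineage-level norms that
#' cross exactly at `crossing_x`. The focal lineages are the pure
#' combinations of the H1 (extreme) and H2 (intermediate) RWHs of each
#' region; each region's RWH carries one `n_regions`-th of the lineage
#' coefficients, and the intercept of the extreme component is solved in
#' closed form from the crossing condition
#' \eqn{b_{ext} = b_{int} + (a_{int} - a_{ext}) x^*}.
#' All remaining RWHs get random norms strictly below both focal components
#' at both 25 and 305 mM, so every non-focal lineage is below the focal
#' maximum at both extremes.
#'
#' @param spec a `"normselDesign"` from [designSpec()].
#' @param crossing_x environment (mM) where the focal lineage norms cross
#'   (default 225, inside the 25–305 mM range traversed by the gradual
#'   regime).
#' @param slope_int,slope_ext lineage-level log-fitness slopes per mM of
#'   the intermediate-best and extreme-best lineages (defaults -0.002 and
#'   0.004; their contrast must be non-zero).
#' @param intercept_int lineage-level log-fitness intercept of the
#'   intermediate-best lineage (default 1.6, i.e. about 5 offspring per
#'   capita at 25 mM).
#' @return list with `norms` (a [ReactionNormSet-class]), `focal`
#'   (named list of RWH tuples `ext` and `int`), and `crossing_x`.
#' @export
makeReactionNorms <- function(spec, crossing_x = 225,
                              slope_int = -0.002, slope_ext = 0.004,
                              intercept_int = 1.6) {
  if (crossing_x < 25 || crossing_x > 305)
    stop("crossing_x must lie inside [25, 305] mM")
  if (slope_ext == slope_int)
    stop("slope contrast is zero: focal norms cannot cross")
  R <- spec$n_regions
  intercept_ext <- intercept_int + (slope_int - slope_ext) * crossing_x
  rows <- list()
  for (r in seq_len(R)) {
    ids <- names(spec$region_freqs[[r]])
    a1 <- slope_ext / R; b1 <- intercept_ext / R
    a2 <- slope_int / R; b2 <- intercept_int / R
    f_focal <- function(x) pmin(a1 * x + b1, a2 * x + b2)
    cf <- matrix(NA_real_, length(ids), 2,
                 dimnames = list(ids, c("a", "b")))
    cf[1, ] <- c(a1, b1)
    cf[2, ] <- c(a2, b2)
    for (j in seq_along(ids)[-(1:2)]) {
      aj <- runif(1, min(a1, a2), max(a1, a2))
      gap <- if (j == 3) runif(1, 0.05, 0.3) else runif(1, 0.3, 0.8)
      bj <- min(f_focal(25) - aj * 25, f_focal(305) - aj * 305) - gap
      cf[j, ] <- c(aj, bj)
    }
    rows[[r]] <- cf
  }
  coef <- do.call(rbind, rows)
  list(norms = reactionNorms("linear", coef),
       focal = list(ext = vapply(seq_len(R), function(r)
                      names(spec$region_freqs[[r]])[1], ""),
                    int = vapply(seq_len(R), function(r)
                      names(spec$region_freqs[[r]])[2], "")),
       crossing_x = crossing_x)
}

#' True ancestral state implied by a design
#'
#' Lineage set = all combinations of the per-region RWHs, with starting
#' frequencies the product of the per-region frequencies (linkage
#' equilibrium among regions).
#'
#' @param spec a `"normselDesign"`.
#' @return an [AncestralState-class].
#' @export
truthAncestral <- function(spec) {
  combos <- as.matrix(expand.grid(lapply(spec$region_freqs, names),
                                  KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE))
  colnames(combos) <- names(spec$region_freqs)
  freq <- rep(1, nrow(combos))
  for (r in seq_along(spec$region_freqs))
    freq <- freq * spec$region_freqs[[r]][combos[, r]]
  ancestralState(lineageSet(combos), freq)
}

#' Find a lineage by its RWH composition
#' @param lineages a [LineageSet-class].
#' @param tuple character vector, one RWH per region (region order).
#' @return the lineage id, or NA if absent.
#' @export
findLineage <- function(lineages, tuple) {
  key <- paste(tuple, collapse = "+")
  lineages@lineage_id[match(key, lineageKeys(lineages))]
}

## Random CWH allele strings with pairwise Hamming distance >= min_dist, by
## rejection; RWH identity then survives single-site corruptions.
.randomCwhPool <- function(n, n_snps, min_dist = 4L, max_tries = 1000L) {
  pool <- matrix(NA_integer_, n, n_snps)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      cand <- sample(0:1, n_snps, replace = TRUE)
      if (i == 1L) break
      d <- apply(pool[seq_len(i - 1L), , drop = FALSE], 1,
                 function(p) sum(p != cand))
      if (all(d >= min_dist)) break
      if (try == max_tries) stop("could not place distinct CWH strings")
    }
    pool[i, ] <- cand
  }
  pool
}

## Per-region RWH -> allele strings on the two chromosomes. m RWHs are built
## from m-1 CWHs per chromosome: RWH j < m pairs CWH j with CWH j; the last
## RWH pairs CWH 1 with CWH 2, so the region shows more distinct RWHs than
## CWHs (incomplete linkage), as real data do.
.regionHaplotypes <- function(ids, n_snps) {
  m <- length(ids)
  ncwh <- max(2L, m - 1L)
  A <- .randomCwhPool(ncwh, n_snps)
  B <- .randomCwhPool(ncwh, n_snps)
  pairs <- cbind(seq_len(m), seq_len(m))
  if (m > 1L) pairs[m, ] <- c(1L, 2L)
  pairs[pairs > ncwh] <- ncwh   # degenerate tiny m
  list(chrA = A[pairs[, 1], , drop = FALSE],
       chrB = B[pairs[, 2], , drop = FALSE], ids = ids)
}

.REGION_CHROMS <- list(`1` = c("I", "II"), `2` = c("III", "IV"),
                       `3` = c("V", "X"))

#' Simulate a complete synthetic evolution experiment
#'
#' Generates, with known ground truth: lineage-frequency dynamics per
#' regime (deterministic or finite-population Wright-Fisher), per-epoch
#' multinomial genotyping samples, individual-level homozygous SNP calls
#' realizing each RWH's allele string, and log-normally noisy ancestral
#' fitness assays. The emitted tables parse through the haplotype and
#' inference modules without modification.
#'
#' @param spec a `"normselDesign"` from [designSpec()].
#' @param truth_norms result of [makeReactionNorms()] (or a list with
#'   elements `norms`, `focal`, `crossing_x`).
#' @param seed master seed; all randomness derives from it.
#' @param mode "deterministic" (shared infinite-population dynamics per
#'   regime) or "wright-fisher" (independent finite replicates at
#'   `spec$census_N`).
#' @param emit "full" also builds the individual-level genotype table;
#'   "counts" stops at the per-sample RWH draw record (fast, for
#'   simulation studies).
#' @param missing_rate,het_rate per-call corruption probabilities of the
#'   emitted genotypes (defaults 0: clean calls).
#' @param out_dir optional directory; when given, writes `genotypes.tsv`
#'   (if emitted), `fitness.tsv`, `schedules.tsv`, `rwh_counts.tsv` and
#'   `truth.json`.
#' @return list of class `"normselExperiment"`: `genotypes`, `fitness`,
#'   `schedules`, `truth` (norms, focal tuples, crossing, ancestral state,
#'   per-regime epoch frequencies, the exact per-sample draw record,
#'   RWH-string map, seed, spec, mode).
#' @export
simulateExperiment <- function(spec, truth_norms, seed = 1L,
                               mode = c("deterministic", "wright-fisher"),
                               emit = c("full", "counts"),
                               missing_rate = 0, het_rate = 0,
                               out_dir = NULL) {
  mode <- match.arg(mode)
  emit <- match.arg(emit)
  set.seed(seed)
  norms <- truth_norms$norms
  ancestral <- truthAncestral(spec)
  lineages <- ancestral@lineages
  horizon <- max(spec$epochs)
  regions <- names(spec$region_freqs)
  ## schedules extend past the last epoch (constant plateau) so that
  ## long-horizon prediction from the fitted data needs no re-derivation
  schedules <- lapply(names(spec$regimes), envSchedule,
                      horizon = max(100L, horizon))
  names(schedules) <- names(spec$regimes)
  ## realized lineage frequencies at each epoch, per regime (x replicate in
  ## Wright-Fisher mode)
  epoch_freqs <- list()
  for (cc in names(spec$regimes)) {
    n_rep <- spec$regimes[[cc]]
    if (mode == "deterministic") {
      traj <- predictTrajectories(ancestral, schedules[[cc]], horizon,
                                  norms)
      ef <- traj[as.character(spec$epochs), , drop = FALSE]
      epoch_freqs[[cc]] <- lapply(seq_len(n_rep), function(i) ef)
    } else {
      cfg_seeds <- deriveSeeds(seed, n_rep, stream = 10L +
                               match(cc, names(spec$regimes)))
      epoch_freqs[[cc]] <- lapply(seq_len(n_rep), function(i) {
        cfg <- wfConfig(spec$census_N, horizon, schedules[[cc]],
                        n_replicates = 1L, seed = cfg_seeds[i])
        run <- simulateWF(ancestral, cfg, norms)
        run$freq[as.character(spec$epochs), , 1]
      })
    }
  }
  ## marginal RWH frequencies per region from lineage frequencies
  rwhMarginals <- function(freq, region_index) {
    tapply(freq, lineages@rwh[, region_index], sum)
  }
  ## genotyping draws: one multinomial per (population, epoch, region)
  draw_rows <- list()
  addDraw <- function(regime, replicate, generation, region_index, n,
                      freq) {
    marg <- rwhMarginals(freq, region_index)
    cnt <- as.vector(rmultinom(1, n, marg))
    keep <- cnt > 0
    draw_rows[[length(draw_rows) + 1L]] <<- data.frame(
      regime = regime, replicate = as.character(replicate),
      generation = generation, region = as.integer(regions[region_index]),
      rwh_name = names(marg)[keep], count = cnt[keep])
  }
  for (ri in seq_along(regions))
    addDraw("ancestral", 1L, 0L, ri, spec$n_ancestral, ancestral@freq)
  for (cc in names(spec$regimes)) {
    for (rep_i in seq_len(spec$regimes[[cc]])) {
      for (g in spec$epochs[-1]) {
        f <- epoch_freqs[[cc]][[rep_i]][as.character(g), ]
        for (ri in seq_along(regions))
          addDraw(cc, rep_i, g, ri, spec$n_evolved, f)
      }
    }
  }
  draws <- do.call(rbind, draw_rows)
  rownames(draws) <- NULL
  ## region haplotype allele strings and the truth name -> pipeline id map
  hap <- lapply(seq_along(regions), function(ri)
    .regionHaplotypes(names(spec$region_freqs[[ri]]),
                      spec$snps_per_chromosome))
  rwh_map <- do.call(rbind, lapply(seq_along(regions), function(ri) {
    h <- hap[[ri]]
    strA <- apply(h$chrA, 1, paste, collapse = "")
    strB <- apply(h$chrB, 1, paste, collapse = "")
    data.frame(region = as.integer(regions[ri]), rwh_name = h$ids,
               string = paste0(strA, strB),
               rwh_id = rwhId(regions[ri], paste0(strA, strB)))
  }))
  genotypes <- NULL
  if (emit == "full")
    genotypes <- .emitGenotypes(spec, draws, hap, regions,
                                missing_rate, het_rate)
  ## ancestral fitness assays with log-normal noise
  fit_rows <- list()
  for (x in spec$assay_envs) {
    true_w <- meanFitness(ancestral@freq, x, lineages, norms)
    fit_rows[[length(fit_rows) + 1L]] <- data.frame(
      regime = "ancestral", generation = 0L, env_mM = x,
      replicate = seq_len(spec$assay_replicates),
      growth_rate = exp(log(true_w) +
                        rnorm(spec$assay_replicates, 0, spec$fitness_sd)))
  }
  fitness <- do.call(rbind, fit_rows)
  rownames(fitness) <- NULL
  out <- structure(list(
    genotypes = genotypes, fitness = fitness, schedules = schedules,
    truth = list(norms = norms, focal = truth_norms$focal,
                 crossing_x = truth_norms$crossing_x,
                 ancestral = ancestral, epoch_freqs = epoch_freqs,
                 draws = draws, rwh_map = rwh_map, seed = seed,
                 spec = spec, mode = mode)), class = "normselExperiment")
  if (!is.null(out_dir)) writeExperiment(out, out_dir)
  out
}

## individual-level SNP call table realizing the drawn RWHs
.emitGenotypes <- function(spec, draws, hap, regions, missing_rate,
                           het_rate) {
  batches <- list()
  for (ri in seq_along(regions)) {
    h <- hap[[ri]]
    chroms <- .REGION_CHROMS[[regions[ri]]]
    n_snps <- spec$snps_per_chromosome
    template <- data.frame(
      chromosome = rep(chroms, each = n_snps),
      snp_id = paste0(rep(chroms, each = n_snps), "_",
                      rep(seq_len(n_snps), 2L)),
      position = rep(seq_len(n_snps) * 1000L, 2L))
    calls_of <- lapply(seq_along(h$ids), function(j)
      c("REF", "ALT")[c(h$chrA[j, ], h$chrB[j, ]) + 1L])
    names(calls_of) <- h$ids
    d <- draws[draws$region == as.integer(regions[ri]), , drop = FALSE]
    skey <- paste(d$regime, d$replicate, d$generation, sep = "\r")
    for (s in unique(skey)) {
      ds <- d[skey == s, , drop = FALSE]
      pop <- if (ds$regime[1] == "ancestral") "ancestral"
             else paste0(ds$regime[1], ".", ds$replicate[1])
      rwh_per_ind <- rep(ds$rwh_name, ds$count)
      n_ind <- length(rwh_per_ind)
      batch <- template[rep(seq_len(nrow(template)), n_ind), ]
      batch$population <- pop
      batch$generation <- ds$generation[1]
      batch$individual <- rep(sprintf("%s_g%d_r%s_i%03d", pop,
                                      ds$generation[1], regions[ri],
                                      seq_len(n_ind)),
                              each = nrow(template))
      batch$region <- as.integer(regions[ri])
      batch$call <- unlist(calls_of[rwh_per_ind], use.names = FALSE)
      batches[[length(batches) + 1L]] <- batch
    }
  }
  g <- do.call(rbind, batches)
  rownames(g) <- NULL
  if (het_rate > 0) {
    flip <- runif(nrow(g)) < het_rate
    g$call[flip] <- "HET"
  }
  if (missing_rate > 0) {
    flip <- runif(nrow(g)) < missing_rate
    g$call[flip] <- "MISSING"
  }
  g[, c("population", "generation", "individual", "region", "chromosome",
        "snp_id", "position", "call")]
}

#' True per-sample RWH counts as a pipeline count table
#'
#' Converts the generator's exact draw record into the RWH count-table
#' dialect (pipeline `rwh_id`s), bypassing genotype emission — the
#' fast path for simulation studies.
#'
#' @param experiment a `"normselExperiment"`.
#' @return data.frame with columns `regime`, `replicate`, `generation`,
#'   `region`, `rwh_id`, `count`.
#' @export
truthCountsTable <- function(experiment) {
  d <- experiment$truth$draws
  map <- experiment$truth$rwh_map
  i <- match(paste(d$region, d$rwh_name),
             paste(map$region, map$rwh_name))
  data.frame(regime = d$regime, replicate = d$replicate,
             generation = d$generation, region = d$region,
             rwh_id = map$rwh_id[i], count = d$count)
}

#' Translate truth RWH names to pipeline ids
#' @param experiment a `"normselExperiment"`.
#' @param rwh_names character vector of truth names (e.g. "H1R2").
#' @return pipeline `rwh_id`s.
#' @export
truthRwhIds <- function(experiment, rwh_names) {
  map <- experiment$truth$rwh_map
  map$rwh_id[match(rwh_names, map$rwh_name)]
}

#' Write the files of a synthetic experiment
#'
#' @param experiment a `"normselExperiment"`.
#' @param out_dir output directory (created if needed).
#' @export
writeExperiment <- function(experiment, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(experiment$genotypes))
    writeGenotypeTable(experiment$genotypes,
                       file.path(out_dir, "genotypes.tsv"))
  write.table(experiment$fitness, file.path(out_dir, "fitness.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeScheduleTable(experiment$schedules,
                     file.path(out_dir, "schedules.tsv"))
  writeRwhCounts(truthCountsTable(experiment),
                 file.path(out_dir, "rwh_counts.tsv"))
  tr <- experiment$truth
  writeJson(list(seed = tr$seed, mode = tr$mode,
                 crossing_x = tr$crossing_x, focal = tr$focal,
                 form = normForm(tr$norms),
                 coefficients = cbind(rwh_name = normIds(tr$norms),
                                      as.data.frame(normCoef(tr$norms))),
                 rwh_map = tr$rwh_map,
                 region_freqs = tr$spec$region_freqs),
            file.path(out_dir, "truth.json"))
  invisible(out_dir)
}

#' Write the canned worked-example fixtures
#'
#' Emits the tiny fixtures used in the worked examples: a 2-lineage,
#' 1-region toy (with the combined log-likelihood at the true parameters
#' recorded in its truth file) and a small 3-region recovery experiment,
#' each under its own subdirectory with a `truth.json`.
#'
#' @param out_dir writable output directory.
#' @param seed integer seed.
#' @return invisibly, the manifest of written files.
#' @export
writeFixtureSuite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ## 2-lineage / 1-region toy
  toy <- makeToyData(seed = seed)
  toy_dir <- file.path(out_dir, "toy-2lineage")
  dir.create(toy_dir, showWarnings = FALSE)
  counts <- toy$counts_table
  writeRwhCounts(counts, file.path(toy_dir, "rwh_counts.tsv"))
  write.table(toy$fitness, file.path(toy_dir, "fitness.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeJson(list(seed = seed,
                 coefficients = cbind(rwh_name = normIds(toy$truth_norms),
                                      as.data.frame(normCoef(toy$truth_norms))),
                 g0 = unname(toy$ancestral@freq),
                 loglik_at_truth = toy$loglik_at_truth),
            file.path(toy_dir, "truth.json"))
  ## small 3-region recovery set
  spec <- designSpec(regimes = c(sudden = 2L, gradual = 2L),
                     n_ancestral = 48L, n_evolved = 16L,
                     snps_per_chromosome = 12L)
  tn <- local({set.seed(seed); makeReactionNorms(spec)})
  exp3 <- simulateExperiment(spec, tn, seed = seed, emit = "counts",
                             out_dir = file.path(out_dir,
                                                 "recovery-3region"))
  manifest <- list.files(out_dir, recursive = TRUE)
  writeJson(manifest, file.path(out_dir, "MANIFEST.json"))
  invisible(manifest)
}

#' Minimal 2-lineage, 1-region worked example
#'
#' One region with two RWHs (hence two lineages with known ancestral
#' frequencies), a sudden regime, genotype counts drawn from the model at
#' the true parameters and noiseless ancestral fitness at 25/305 mM.
#' Small enough for exhaustive grid-search validation of the optimizer.
#'
#' @param seed integer seed.
#' @param n_per_epoch genotyped individuals per post-ancestral epoch
#'   (default 200).
#' @param g0 true ancestral frequencies of the two lineages.
#' @return list with `data` (a `"normselData"`), `ancestral` (the known
#'   [AncestralState-class]), `truth_norms`, `counts_table`, `fitness`,
#'   `loglik_at_truth`.
#' @export
makeToyData <- function(seed = 1L, n_per_epoch = 200L,
                        g0 = c(0.6, 0.4)) {
  set.seed(seed)
  ## mild selection: frequencies stay interior at every genotyped epoch,
  ## so all epochs inform the fit
  truth <- reactionNorms("linear",
    cbind(a = c(T1 = 6e-4, T2 = -2e-4), b = c(T1 = 0.55, T2 = 0.76)))
  lin <- lineageSet(cbind(`1` = c("T1", "T2")))
  anc <- ancestralState(lin, g0)
  sched <- list(sudden = envSchedule("sudden", horizon = 50))
  epochs <- c(0L, 10L, 35L, 50L)
  traj <- predictTrajectories(anc, sched$sudden, 50, truth)
  rows <- list()
  for (g in epochs[-1]) {
    p <- traj[as.character(g), ]
    cnt <- as.vector(rmultinom(1, n_per_epoch, p))
    rows[[length(rows) + 1L]] <- data.frame(
      regime = "sudden", replicate = "1", generation = g, region = 1L,
      rwh_id = c("T1", "T2"), count = cnt)
  }
  anc_counts <- data.frame(regime = "ancestral", replicate = "1",
                           generation = 0L, region = 1L,
                           rwh_id = c("T1", "T2"),
                           count = as.integer(round(g0 * 100)))
  counts <- rbind(anc_counts, do.call(rbind, rows))
  counts$designation <- "primary"
  fitness <- do.call(rbind, lapply(c(25, 305), function(x)
    data.frame(regime = "ancestral", generation = 0L, env_mM = x,
               replicate = 1L,
               growth_rate = meanFitness(anc@freq, x, lin, truth))))
  data <- assembleInferenceData(counts, fitness, sched)
  ll <- totalLoglik(truth, anc, data)
  list(data = data, ancestral = anc, truth_norms = truth,
       counts_table = counts, fitness = fitness,
       loglik_at_truth = as.numeric(ll))
}
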
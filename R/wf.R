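#' One Wright-Fisher generation
#'
#' Deterministic viability-selection update followed by multinomial
#' resampling of `N` individuals (selfing with no recombination makes
#' lineages behave as asexual clones, so drift is exact multinomial
#' resampling of lineage labels). Resulting frequencies are multiples of
#' 1/N; 0 and 1 are absorbing.
#'
#' @param freq simplex vector of lineage frequencies, or a matrix with one
#'   column per independent replicate.
#' @param x environmental value (mM NaCl).
#' @param N census size at reproduction (>= 2).
#' @param lineages a [LineageSet-class].
#' @param norms a [ReactionNormSet-class].
#' @return object of the same shape as `freq`.
#' @export
wfStep <- function(freq, x, N, lineages, norms) {
  if (N < 2) stop("N must be >= 2")
  vec <- is.null(dim(freq))
  P <- if (vec) matrix(freq, ncol = 1) else freq
  lam <- exp(lineageLogFitness(x, lineages, norms))
  W <- P * lam
  W <- sweep(W, 2, colSums(W), "/")
  out <- rmultinomCols(N, W) / N
  if (vec) out[, 1] else out
}

#' Founder-effect bottleneck
#'
#' Multinomial draw of `n_founders` individuals from the current
#' frequencies (emulating e.g. the freeze/revive of a population), then
#' renormalization.
#'
#' @param freq simplex vector or matrix (columns = replicates).
#' @param n_founders number of founding individuals (>= 1).
#' @return resampled frequencies, same shape as `freq`.
#' @export
bottleneck <- function(freq, n_founders) {
  if (n_founders < 1) stop("n_founders must be >= 1")
  vec <- is.null(dim(freq))
  P <- if (vec) matrix(freq, ncol = 1) else freq
  out <- rmultinomCols(n_founders, P) / n_founders
  if (vec) out[, 1] else out
}

#' Configuration of a Wright-Fisher simulation
#'
#' @param census_N individuals at reproduction (>= 2).
#' @param n_generations generations to simulate.
#' @param schedule an [EnvSchedule-class] covering `n_generations`.
#' @param n_replicates independent replicate populations.
#' @param bottleneck_size optional founder count applied before generation
#'   1 (NULL = no bottleneck).
#' @param seed integer seed.
#' @return list of class `"wfConfig"`.
#' @export
wfConfig <- function(census_N, n_generations, schedule,
                     n_replicates = 1L, bottleneck_size = NULL,
                     seed = 1L) {
  if (census_N < 2) stop("census_N must be >= 2")
  if (!is.null(bottleneck_size) && bottleneck_size > census_N)
    stop("bottleneck_size must be <= census_N")
  if (scheduleHorizon(schedule) < n_generations)
    stop("schedule does not cover ", n_generations, " generations")
  structure(list(census_N = as.integer(census_N),
                 n_generations = as.integer(n_generations),
                 schedule = schedule,
                 n_replicates = as.integer(n_replicates),
                 bottleneck_size = if (is.null(bottleneck_size)) NULL
                                   else as.integer(bottleneck_size),
                 seed = as.integer(seed)),
            class = "wfConfig")
}

#' Forward Wright-Fisher simulation of replicate populations
#'
#' Simulates `n_replicates` independent finite populations from a common
#' ancestral state under a schedule, selection-then-sampling each
#' generation. Fully reproducible from `config$seed`.
#'
#' @param ancestral an [AncestralState-class] (or a bare simplex vector
#'   together with `lineages`).
#' @param config a `"wfConfig"` from [wfConfig()].
#' @param norms a [ReactionNormSet-class].
#' @param lineages required when `ancestral` is a bare frequency vector.
#' @param record "full" keeps every generation (array
#'   (generations+1) x lineages x replicates); "last" keeps only the final
#'   state plus a loss indicator per lineage and replicate.
#' @return list of class `"wfRun"` with elements `freq` (array or final
#'   matrix), `lost` (lineages x replicates logical: hit frequency 0 at any
#'   time), `lineage_id`, `config`.
#' @export
simulateWF <- function(ancestral, config, norms, lineages = NULL,
                       record = c("full", "last")) {
  record <- match.arg(record)
  if (is(ancestral, "AncestralState")) {
    lineages <- ancestral@lineages
    g0 <- ancestral@freq
  } else {
    if (is.null(lineages)) stop("lineages required with a bare vector")
    g0 <- assertSimplex(as.numeric(ancestral))
  }
  G <- length(g0)
  R <- config$n_replicates
  Tn <- config$n_generations
  set.seed(config$seed)
  P <- matrix(g0, G, R)
  if (!is.null(config$bottleneck_size))
    P <- bottleneck(P, config$bottleneck_size)
  lost <- P == 0
  keep_all <- record == "full"
  if (keep_all) {
    arr <- array(NA_real_, dim = c(Tn + 1L, G, R),
                 dimnames = list(generation = 0:Tn,
                                 lineage = lineages@lineage_id,
                                 replicate = NULL))
    arr[1, , ] <- P
  }
  lam_all <- exp(lineageLogFitness(scheduleEnv(config$schedule,
                                               seq_len(Tn)),
                                   lineages, norms))
  if (is.null(dim(lam_all))) lam_all <- matrix(lam_all, ncol = 1)
  for (t in seq_len(Tn)) {
    W <- P * lam_all[, t]
    W <- sweep(W, 2, colSums(W), "/")
    P <- rmultinomCols(config$census_N, W) / config$census_N
    lost <- lost | P == 0
    if (keep_all) arr[t + 1L, , ] <- P
  }
  structure(list(freq = if (keep_all) arr else P, lost = lost,
                 lineage_id = lineages@lineage_id, config = config,
                 record = record),
            class = "wfRun")
}

#' Sweep and loss probability of a target lineage
#'
#' Fraction of replicates in which the target lineage's frequency reaches
#' `threshold` by `by_generation` (a sweep — not necessarily fixation), and
#' the fraction in which it was ever at frequency 0 (lost; without
#' mutation, loss is permanent).
#'
#' @param run a `"wfRun"` from [simulateWF()].
#' @param target lineage identifier.
#' @param threshold sweep frequency threshold (default 0.5).
#' @param by_generation generation at which the sweep is called (default:
#'   final simulated generation).
#' @return list with `sweep`, `lost`, `no_sweep` fractions, their binomial
#'   standard errors and `n_replicates`; fractions `sweep + no_sweep = 1`
#'   and `lost` counts replicates where the target hit 0 at any time.
#' @export
sweepProbability <- function(run, target, threshold = 0.5,
                             by_generation = NULL) {
  k <- match(target, run$lineage_id)
  if (is.na(k)) stop("target lineage '", target,
                     "' absent from the simulated state")
  R <- run$config$n_replicates
  if (run$record == "full") {
    Tn <- dim(run$freq)[1] - 1L
    if (is.null(by_generation)) by_generation <- Tn
    if (by_generation > Tn) stop("by_generation beyond simulated horizon")
    final <- run$freq[by_generation + 1L, k, ]
    lost <- apply(run$freq[seq_len(by_generation + 1L), k, , drop = FALSE]
                  == 0, 3, any)
  } else {
    if (!is.null(by_generation) &&
        by_generation != run$config$n_generations)
      stop("record = 'last' runs only support the final generation")
    final <- run$freq[k, ]
    lost <- run$lost[k, ]
  }
  swept <- final >= threshold
  p <- mean(swept)
  l <- mean(lost)
  list(sweep = p, no_sweep = 1 - p, lost = l,
       se_sweep = sqrt(p * (1 - p) / R), se_lost = sqrt(l * (1 - l) / R),
       n_replicates = R, threshold = threshold,
       by_generation = if (is.null(by_generation))
         run$config$n_generations else by_generation)
}

#' Continued-evolution founder experiment at two population sizes
#'
#' Emulates restarting evolution in constant high salt from a stored
#' population state (e.g. a gradual population at generation 35) under a
#' large and a small census size, with an optional founder bottleneck at
#' revival, and contrasts sweep/loss of a target lineage between the two
#' size regimes.
#'
#' @param state simplex vector: the population state at revival.
#' @param lineages a [LineageSet-class].
#' @param norms a [ReactionNormSet-class].
#' @param target lineage identifier to track.
#' @param N_large,N_small census sizes (defaults 1e4 and 2e3).
#' @param n_generations generations of continued evolution (default 30).
#' @param n_replicates replicates per size regime (default 500).
#' @param env constant environment (default 305 mM).
#' @param bottleneck_size optional founder count at revival.
#' @param threshold sweep threshold (default 0.5).
#' @param seed integer seed.
#' @return list with per-regime [sweepProbability()] summaries (`large`,
#'   `small`) and the qualitative contrast `loss_small_minus_large`.
#' @export
founderExperiment <- function(state, lineages, norms, target,
                              N_large = 1e4, N_small = 2e3,
                              n_generations = 30L, n_replicates = 500L,
                              env = 305, bottleneck_size = NULL,
                              threshold = 0.5, seed = 1L) {
  sched <- envSchedule("constant", horizon = n_generations,
                       env = rep(env, n_generations))
  seeds <- deriveSeeds(seed, 2L, stream = 3L)
  runs <- lapply(seq_along(c(N_large, N_small)), function(i) {
    N <- c(N_large, N_small)[i]
    cfg <- wfConfig(N, n_generations, sched, n_replicates = n_replicates,
                    bottleneck_size = bottleneck_size, seed = seeds[i])
    simulateWF(state, cfg, norms, lineages = lineages, record = "last")
  })
  s_large <- sweepProbability(runs[[1]], target, threshold = threshold)
  s_small <- sweepProbability(runs[[2]], target, threshold = threshold)
  list(large = s_large, small = s_small,
       loss_small_minus_large = s_small$lost - s_large$lost)
}

#' Effective-size bound under complete selfing
#'
#' Complete self-fertilization halves the effective population size
#' relative to the outcrossing expectation: \eqn{N_e^{selfing} = N_e / 2}.
#'
#' @param Ne_outcrossing effective size under (partial) outcrossing.
#' @return the selfing effective-size bound.
#' @examples
#' selfingEffectiveSize(1e3)   # 500
#' @export
selfingEffectiveSize <- function(Ne_outcrossing) Ne_outcrossing / 2
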
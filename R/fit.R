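#' Plug-in ancestral RWH frequencies per region
#'
#' Multinomial proportions of the ancestral-sample RWH counts in each
#' region, optionally with add-one (Laplace) smoothing.
#'
#' @param data a `"normselData"` object, or a named list of per-region named
#'   count vectors.
#' @param smoothing logical; add 1 to every count before normalizing
#'   (default FALSE).
#' @return named list (per region) of named frequency vectors (simplices).
#' @export
estimateAncestralFreqs <- function(data, smoothing = FALSE) {
  counts <- if (inherits(data, "normselData")) data$ancestral_counts else data
  lapply(counts, function(n) {
    if (!length(n) || sum(n) == 0)
      stop("region with zero genotyped ancestral individuals")
    if (smoothing) n <- n + 1
    n / sum(n)
  })
}

#' Sample an ancestral state from estimated RWH frequencies
#'
#' Emulates drawing the unknown pair \eqn{(A, g^{[0]})} given the ancestral
#' genotyping sample. The lineage set is all combinations of the primary
#' RWHs across regions, plus `n_secondary` secondary lineages drawn by
#' sampling one RWH per region proportionally to the region frequencies
#' (duplicates merged); background pseudo-RWHs participate as ordinary
#' RWHs. Starting frequencies are assigned by the product of the
#' constituent-RWH frequencies (linkage equilibrium) and renormalized.
#'
#' When `bootstrap_sizes` is given, each region's frequency vector is first
#' replaced by the proportions of a multinomial resample at the stated
#' sample size — a parametric bootstrap that propagates genotyping sampling
#' noise into the ensemble of ancestral states.
#'
#' @param region_freqs named list per region of named RWH frequency vectors
#'   (e.g. from [estimateAncestralFreqs()]).
#' @param primary_ids named list per region of the primary RWH ids; defaults
#'   to all RWHs with frequency above `primary_min_freq`.
#' @param n_secondary number of secondary lineage draws (default 2).
#' @param bootstrap_sizes optional named vector of per-region ancestral
#'   sample sizes for the parametric bootstrap (NULL disables it).
#' @param primary_min_freq fallback primary definition when `primary_ids`
#'   is NULL (default 0.1).
#' @return an [AncestralState-class]; deterministic given the RNG state.
#' @export
sampleAncestral <- function(region_freqs, primary_ids = NULL,
                            n_secondary = 2L, bootstrap_sizes = NULL,
                            primary_min_freq = 0.1) {
  regions <- names(region_freqs)
  for (r in regions) assertSimplex(region_freqs[[r]],
                                   paste0("region ", r, " frequencies"))
  if (!is.null(bootstrap_sizes)) {
    region_freqs <- lapply(regions, function(r) {
      f <- region_freqs[[r]]
      n <- bootstrap_sizes[[r]]
      draw <- as.vector(rmultinom(1, n, f))
      setNames(draw / n, names(f))
    })
    names(region_freqs) <- regions
  }
  if (is.null(primary_ids))
    primary_ids <- lapply(region_freqs, function(f)
      names(f)[f >= primary_min_freq])
  for (r in regions)
    if (!length(primary_ids[[r]]))
      stop("empty primary RWH set in region ", r)
  combos <- as.matrix(expand.grid(primary_ids[regions],
                                  KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE))
  colnames(combos) <- regions
  if (n_secondary > 0L) {
    sec <- vapply(regions, function(r) {
      f <- region_freqs[[r]]
      sample(names(f), n_secondary, replace = TRUE, prob = f)
    }, character(n_secondary))
    if (n_secondary == 1L) sec <- matrix(sec, nrow = 1,
                                         dimnames = list(NULL, regions))
    combos <- rbind(combos, sec)
  }
  combos <- combos[!duplicated(apply(combos, 1, paste, collapse = "\r")), ,
                   drop = FALSE]
  freq <- rep(1, nrow(combos))
  for (r in regions) freq <- freq * region_freqs[[r]][combos[, r]]
  keep <- freq > 0
  if (!any(keep)) stop("all sampled lineages have zero product frequency")
  combos <- combos[keep, , drop = FALSE]
  freq <- freq[keep]
  ancestralState(lineageSet(combos), freq / sum(freq))
}

#' Maximum-likelihood estimation of RWH reaction-norm parameters
#'
#' Maximizes the combined fitness + genotype log-likelihood over the
#' reaction-norm coefficients of every RWH carried by the ancestral state,
#' by quasi-Newton (BFGS) optimization with the analytic gradient, from
#' `n_starts` random initial coefficient vectors. The best start by final
#' log-likelihood wins; ties are broken by the smaller parameter norm.
#'
#' Initial coefficients are drawn uniformly: slope-like terms in
#' (-0.02, 0.02) per mM, intercept-like terms in (-1, 2), quadratic terms
#' in (-1e-4, 1e-4) per mM^2 — brackets for biologically plausible
#' per-generation growth over the 25–305 mM range.
#'
#' @param ancestral an [AncestralState-class].
#' @param data a `"normselData"` object from [assembleInferenceData()].
#' @param form "linear" or "quadratic".
#' @param n_starts number of random starts (default 10).
#' @param seed integer seed; the fit is deterministic given it.
#' @param fixed optional named list of coefficient vectors
#'   (`c(a=, b=[, c=])`) freezing the parameters of specific RWHs.
#' @param fitness_weight relative weight of the fitness term (default 1).
#' @param maxit maximum BFGS iterations per start (default 500).
#' @param reltol relative convergence tolerance on the log-likelihood
#'   (default 1e-8).
#' @return a [ModelFit-class].
#' @export
fitMLE <- function(ancestral, data, form = c("linear", "quadratic"),
                   n_starts = 10L, seed = 1L, fixed = NULL,
                   fitness_weight = 1, maxit = 500L, reltol = 1e-8) {
  form <- match.arg(form)
  if (n_starts < 1L) stop("n_starts must be >= 1")
  ctx <- likelihoodContext(ancestral, data, form)
  rwh_ids <- ctx$rwh_ids
  npar_per <- if (form == "linear") 2L else 3L
  fixed_ids <- intersect(names(fixed), rwh_ids)
  free_ids <- setdiff(rwh_ids, fixed_ids)
  if (!length(free_ids)) stop("no free parameters to fit")
  base_coef <- matrix(0, length(rwh_ids), 3,
                      dimnames = list(rwh_ids, c("a", "b", "c")))
  for (id in fixed_ids) {
    v <- fixed[[id]]
    base_coef[id, names(v)] <- v
  }
  unpack <- function(par) {
    cf <- base_coef
    cf[free_ids, seq_len(npar_per)] <-
      matrix(par, length(free_ids), npar_per)
    cf
  }
  fn <- function(par) {
    -.loglikEngine(unpack(par), ctx, fitness_weight)$loglik
  }
  gr <- function(par) {
    g <- .loglikEngine(unpack(par), ctx, fitness_weight, grad = TRUE)$grad
    -as.vector(g[free_ids, seq_len(npar_per)])
  }
  init_ranges <- if (form == "linear")
    list(c(-0.02, 0.02), c(-1, 2))
  else
    list(c(-1e-4, 1e-4), c(-0.02, 0.02), c(-1, 2))
  ## parameter scales for BFGS step conditioning: a slope unit cumulates
  ## over sum(x(t)) ~ 1e4 mM-generations while an intercept unit cumulates
  ## over ~50 generations, so unscaled steps saturate the frequencies and
  ## strand the optimizer on flat plateaus
  scales <- if (form == "linear") c(1e-3, 0.3) else c(1e-5, 1e-3, 0.3)
  parscale <- rep(scales, each = length(free_ids))
  ## start 1 is the neutral baseline: zero slopes, intercepts sized so a
  ## lineage's fitness matches the mean observed assay growth rate (or 1);
  ## remaining starts are random draws from the stated ranges
  L <- ncol(ancestral@lineages@rwh)
  mean_logphi <- if (!is.null(ctx$fit_obs) && nrow(ctx$fit_obs))
    mean(ctx$fit_obs$logphi) else 0
  neutral <- matrix(0, length(free_ids), npar_per)
  neutral[, npar_per] <- mean_logphi / L
  seeds <- deriveSeeds(seed, n_starts, stream = 1L)
  results <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(seeds[s])
    init <- if (s == 1L) as.vector(neutral)
    else as.vector(vapply(seq_len(npar_per), function(j)
      runif(length(free_ids), init_ranges[[j]][1], init_ranges[[j]][2]),
      numeric(length(free_ids))))
    opt <- tryCatch(
      optim(init, fn, gr, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol,
                           parscale = parscale)),
      error = function(e) NULL)
    results[[s]] <- opt
  }
  ok <- !vapply(results, is.null, TRUE)
  if (!any(ok))
    stop("all ", n_starts, " optimization starts failed")
  starts <- data.frame(
    start = seq_len(n_starts),
    loglik = vapply(results, function(r) if (is.null(r)) NA_real_
                    else -r$value, 0),
    convergence = vapply(results, function(r) if (is.null(r)) NA_integer_
                         else r$convergence, 0L),
    par_norm = vapply(results, function(r) if (is.null(r)) NA_real_
                      else sqrt(sum(r$par^2)), 0))
  cand <- which(ok)
  best_ll <- max(starts$loglik[cand])
  tied <- cand[starts$loglik[cand] >= best_ll - 1e-9]
  best <- tied[which.min(starts$par_norm[tied])]
  cf <- unpack(results[[best]]$par)
  norms <- reactionNorms(form, cf[, seq_len(npar_per), drop = FALSE])
  new("ModelFit", norms = norms, loglik = starts$loglik[best],
      starts = starts,
      converged = any(starts$convergence[cand] == 0L),
      seed = as.integer(seed))
}

#' @describeIn fitMLE fitted reaction norms of a [ModelFit-class].
#' @param fit a [ModelFit-class].
#' @export
fitNorms <- function(fit) fit@norms

#' @describeIn fitMLE best log-likelihood of a [ModelFit-class].
#' @export
fitLoglik <- function(fit) fit@loglik

#' Ensemble inference over resampled ancestral states
#'
#' Repeats (sample an ancestral state, fit the reaction norms, predict
#' trajectories) `n_anc_samples` times and summarizes per-generation
#' per-lineage frequency quantiles (2.5/50/97.5%), with lineages matched
#' across draws by RWH composition (a lineage absent from a draw
#' contributes frequency 0).
#'
#' @param data a `"normselData"` object.
#' @param form "linear" or "quadratic".
#' @param n_anc_samples number of ancestral draws (default 20).
#' @param n_secondary secondary lineage draws per ancestral sample; NULL
#'   (the default) uses 2 per genotyped replicate population when the data
#'   object records the replicate count, else 16.
#' @param n_starts random starts per fit (default 10).
#' @param seed master seed; per-draw seeds are derived by a fixed counter
#'   scheme, so the ensemble is reproducible.
#' @param horizon generations to predict (default 100).
#' @param bootstrap logical: parametric bootstrap of the ancestral region
#'   frequencies at the genotyped sample sizes (default TRUE).
#' @param smoothing add-one smoothing of ancestral frequencies (default
#'   FALSE).
#' @param fitness_weight relative weight of the fitness term.
#' @return an [EnsembleFit-class].
#' @export
fitEnsemble <- function(data, form = c("linear", "quadratic"),
                        n_anc_samples = 20L, n_secondary = NULL,
                        n_starts = 10L, seed = 1L, horizon = 100L,
                        bootstrap = TRUE, smoothing = FALSE,
                        fitness_weight = 1) {
  form <- match.arg(form)
  if (n_anc_samples < 1L) stop("n_anc_samples must be >= 1")
  if (is.null(n_secondary))
    n_secondary <- if (!is.null(data$n_replicates))
      2L * data$n_replicates else 16L
  freqs <- estimateAncestralFreqs(data, smoothing = smoothing)
  primary <- data$ancestral_primary
  sizes <- if (bootstrap) data$ancestral_sizes else NULL
  draw_seeds <- deriveSeeds(seed, n_anc_samples, stream = 2L)
  draws <- vector("list", n_anc_samples)
  failures <- 0L
  for (i in seq_len(n_anc_samples)) {
    set.seed(draw_seeds[i])
    draws[[i]] <- tryCatch({
      anc <- sampleAncestral(freqs, primary_ids = primary,
                             n_secondary = n_secondary,
                             bootstrap_sizes = sizes)
      fit <- fitMLE(anc, data, form = form, n_starts = n_starts,
                    seed = draw_seeds[i], fitness_weight = fitness_weight)
      list(ancestral = anc, fit = fit)
    }, error = function(e) {
      warning("ancestral draw ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(draws[[i]])) failures <- failures + 1L
  }
  if (failures > n_anc_samples / 2)
    stop("more than half of the ensemble draws failed (", failures, "/",
         n_anc_samples, ")")
  draws <- Filter(Negate(is.null), draws)
  ## per-regime trajectories; lineages matched by composition key
  keys <- unique(unlist(lapply(draws, function(d)
    lineageKeys(d$ancestral@lineages))))
  probs <- c(0.025, 0.5, 0.975)
  quantiles <- lapply(names(data$regimes), function(cc) {
    sched <- data$regimes[[cc]]$schedule
    arr <- array(0, dim = c(horizon + 1L, length(keys), length(draws)))
    for (j in seq_along(draws)) {
      d <- draws[[j]]
      traj <- predictTrajectories(d$ancestral, sched, horizon,
                                  fitNorms(d$fit))
      k <- match(lineageKeys(d$ancestral@lineages), keys)
      arr[, k, j] <- traj
    }
    q <- apply(arr, c(1, 2), quantile, probs = probs, names = FALSE)
    q <- aperm(q, c(2, 3, 1))
    dimnames(q) <- list(generation = 0:horizon, lineage_key = keys,
                        quantile = c("q025", "q50", "q975"))
    q
  })
  names(quantiles) <- names(data$regimes)
  new("EnsembleFit", draws = draws, quantiles = quantiles,
      lineage_keys = keys, seed = as.integer(seed))
}

#' @describeIn fitEnsemble the per-draw (ancestral, fit) pairs.
#' @param ensemble an [EnsembleFit-class].
#' @export
ensembleDraws <- function(ensemble) ensemble@draws

#' @describeIn fitEnsemble trajectory quantile arrays per regime.
#' @export
ensembleQuantiles <- function(ensemble) ensemble@quantiles

#' Serialize an ensemble fit to JSON
#'
#' Per-draw fitted coefficients, log-likelihoods, convergence flags and
#' seeds, plus configuration echo. Quantile arrays are large and are
#' written only when `include_quantiles = TRUE`.
#'
#' @param ensemble an [EnsembleFit-class].
#' @param path output file.
#' @param config optional configuration list echoed verbatim.
#' @param include_quantiles logical (default FALSE).
#' @export
writeFitJson <- function(ensemble, path, config = NULL,
                         include_quantiles = FALSE) {
  out <- list(
    package_version = as.character(packageVersion("normsel")),
    seed = ensemble@seed,
    config = config,
    draws = lapply(ensemble@draws, function(d) list(
      lineages = as.data.frame(lineageRwh(d$ancestral@lineages)),
      g0 = unname(d$ancestral@freq),
      form = normForm(fitNorms(d$fit)),
      coefficients = as.data.frame(normCoef(fitNorms(d$fit))),
      rwh_ids = normIds(fitNorms(d$fit)),
      loglik = fitLoglik(d$fit),
      converged = d$fit@converged,
      seed = d$fit@seed)))
  if (include_quantiles)
    out$quantiles <- lapply(ensemble@quantiles, function(q)
      as.vector(q))
  writeJson(out, path)
}

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit (", normForm(object@norms), "): loglik ",
      format(object@loglik, digits = 8), ", ",
      nrow(object@starts), " starts, converged: ",
      object@converged, "\n", sep = "")
})

setMethod("show", "EnsembleFit", function(object) {
  cat("EnsembleFit: ", length(object@draws), " ancestral draws, ",
      length(object@lineage_keys), " lineage keys, regimes: ",
      paste(names(object@quantiles), collapse = ", "), "\n", sep = "")
})
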
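#' Assemble regime-level data for likelihood evaluation
#'
#' Combines pooled regime-level RWH counts, fitness assays and environment
#' schedules into the object consumed by [totalLoglik()], [fitMLE()] and
#' [fitEnsemble()].
#'
#' Genotype observations enter per regime for the post-ancestral epochs;
#' ancestral counts (generation 0, under `ancestral_regime`) are kept
#' separately — they parameterize the ancestral state, not the genotype
#' likelihood. Fitness observations used for fitting are by default the
#' ancestral (generation 0) assays at 25 and 305 mM; because the ancestral
#' state is shared by all regimes, these enter the total likelihood once.
#' Assays at other concentrations are retained in `$fitness_all` for
#' validation.
#'
#' @param pooled regime-level grouped count table from [poolToRegime()]
#'   (ancestral rows under regime `ancestral_regime`, generation 0).
#' @param fitness data.frame with columns `regime`, `generation`, `env_mM`,
#'   `replicate`, `growth_rate` (one row per assay replicate).
#' @param schedules named list of [EnvSchedule-class], one per evolved
#'   regime in `pooled`.
#' @param epochs genotyped generations, first entry 0 (default 0/10/35/50).
#' @param ancestral_regime label of the ancestral rows (default
#'   "ancestral").
#' @param fit_envs assay environments used for fitting (default 25, 305).
#' @param n_replicates total number of genotyped replicate populations the
#'   pooled counts came from (used to scale the default number of secondary
#'   ancestral lineages, 2 per replicate); NULL if unknown.
#' @return list of class `"normselData"`.
#' @export
assembleInferenceData <- function(pooled, fitness, schedules,
                                  epochs = c(0L, 10L, 35L, 50L),
                                  ancestral_regime = "ancestral",
                                  fit_envs = c(25, 305),
                                  n_replicates = NULL) {
  requireCols(pooled, c("regime", "generation", "region", "rwh_id", "count"),
              "pooled count table")
  requireCols(fitness, c("regime", "generation", "env_mM", "growth_rate"),
              "fitness table")
  stopifnot(epochs[1] == 0L, !is.unsorted(epochs, strictly = TRUE))
  anc <- pooled[pooled$regime == ancestral_regime &
                pooled$generation == 0L, , drop = FALSE]
  if (!nrow(anc)) stop("no ancestral counts (regime '", ancestral_regime,
                       "', generation 0) in pooled table")
  regions <- sort(unique(pooled$region))
  anc_counts <- lapply(regions, function(r) {
    d <- anc[anc$region == r, , drop = FALSE]
    if (!nrow(d)) stop("ancestral counts missing for region ", r)
    setNames(d$count, d$rwh_id)
  })
  names(anc_counts) <- regions
  anc_primary <- lapply(regions, function(r) {
    d <- anc[anc$region == r, , drop = FALSE]
    if ("designation" %in% names(d)) d$rwh_id[d$designation == "primary"]
    else d$rwh_id
  })
  names(anc_primary) <- regions
  ev_regimes <- setdiff(unique(pooled$regime), ancestral_regime)
  miss <- setdiff(ev_regimes, names(schedules))
  if (length(miss))
    stop("no schedule for regime(s): ", paste(miss, collapse = ", "))
  regime_counts <- lapply(ev_regimes, function(cc) {
    d <- pooled[pooled$regime == cc & pooled$generation > 0L, , drop = FALSE]
    eps <- intersect(epochs[-1], unique(d$generation))
    cnts <- lapply(eps, function(g) {
      lapply(setNames(regions, regions), function(r) {
        dd <- d[d$generation == g & d$region == r, , drop = FALSE]
        setNames(dd$count, dd$rwh_id)
      })
    })
    names(cnts) <- eps
    list(counts = cnts, schedule = schedules[[cc]])
  })
  names(regime_counts) <- ev_regimes
  f_fit <- fitness[fitness$generation == 0L &
                   fitness$env_mM %in% fit_envs, , drop = FALSE]
  structure(list(
    regimes = regime_counts,
    epochs = as.integer(epochs),
    regions = regions,
    ancestral_counts = anc_counts,
    ancestral_primary = anc_primary,
    ancestral_sizes = vapply(anc_counts, sum, 0),
    fitness = f_fit,
    fitness_all = fitness,
    fit_envs = fit_envs,
    n_replicates = n_replicates), class = "normselData")
}

## Cumulative environment-basis moments of a schedule at epoch boundaries.
## Row h+1 holds colSums of normBasis over generations 1..T_h (row 1, epoch
## 0, is zero). With these, the epoch-cumulated lineage log-fitness is linear
## in the reaction-norm coefficients.
.epochMoments <- function(schedule, epochs, form) {
  xs <- scheduleEnv(schedule, seq_len(max(epochs)))
  B <- normBasis(form, xs)                       # 3 x T
  Bc <- cbind(0, t(apply(B, 1, cumsum)))         # 3 x (T+1), col t+1 = 1..t
  t(Bc[, epochs + 1L, drop = FALSE])             # (H+1) x 3
}

## Precomputed likelihood context: everything about (ancestral, data) that
## does not depend on the coefficients.
likelihoodContext <- function(ancestral, data, form,
                              marginal_floor = 1e-12) {
  stopifnot(inherits(data, "normselData"), is(ancestral, "AncestralState"))
  lineages <- ancestral@lineages
  regions <- colnames(lineages@rwh)
  rwh_ids <- sort(unique(as.vector(lineages@rwh)))
  Z <- lineageMembership(lineages, rwh_ids)
  region_of <- rep(NA_character_, length(rwh_ids))
  names(region_of) <- rwh_ids
  for (i in seq_along(regions))
    region_of[unique(lineages@rwh[, i])] <- regions[i]
  epochs <- data$epochs
  regime_ctx <- lapply(data$regimes, function(rg) {
    Dm <- .epochMoments(rg$schedule, epochs, form)
    obs <- list()
    for (g in names(rg$counts)) {
      h <- match(as.integer(g), epochs)          # column index in g-matrix
      for (r in names(rg$counts[[g]])) {
        n <- rg$counts[[g]][[r]]
        if (!length(n)) next
        ids_r <- rwh_ids[region_of == as.character(r)]
        if (!length(ids_r)) next
        ## remap RWHs absent from the lineage set to the region background
        bg <- paste0("H0R", r)
        tgt <- ifelse(names(n) %in% ids_r, names(n),
                      ifelse(bg %in% ids_r, bg, NA))
        n_mapped <- tapply(n[!is.na(tgt)], tgt[!is.na(tgt)], sum)
        n_unmapped <- sum(n[is.na(tgt)])
        nv <- setNames(rep(0, length(ids_r)), ids_r)
        nv[names(n_mapped)] <- n_mapped
        obs[[length(obs) + 1L]] <- list(
          h = h, region = r, n = nv,
          Zr = Z[, ids_r, drop = FALSE],
          n_unmapped = n_unmapped)
      }
    }
    list(Dm = Dm, obs = obs)
  })
  fit_obs <- NULL
  if (nrow(data$fitness)) {
    fobs <- data$fitness
    if (any(fobs$growth_rate <= 0)) stop("observed fitness must be > 0")
    h <- match(fobs$generation, epochs)
    if (anyNA(h)) stop("fitness observation at a non-epoch generation")
    fit_obs <- data.frame(h = h, x = fobs$env_mM,
                          logphi = log(fobs$growth_rate),
                          regime = fobs$regime)
  }
  list(lineages = lineages, logg0 = log(ancestral@freq), Z = Z,
       rwh_ids = rwh_ids, form = form, regimes = regime_ctx,
       fit_obs = fit_obs, epochs = epochs, floor = marginal_floor)
}

## Combined log-likelihood and (optionally) its analytic gradient.
## coef: full coefficient matrix (rwh x 3) over ctx$rwh_ids.
## Returns list(loglik, fitness, genotype, n_floored[, grad]).
.loglikEngine <- function(coef, ctx, fitness_weight = 1, grad = FALSE) {
  Z <- ctx$Z
  G <- nrow(Z)
  ll_fit <- 0
  ll_gen <- 0
  n_floored <- 0L
  gcoef <- if (grad) matrix(0, nrow(coef), 3,
                            dimnames = dimnames(coef)) else NULL
  ## the ancestral fitness term (epoch 0) uses the shared g0 and does not
  ## depend on which regime it is attached to: evaluate it once, outside the
  ## regime loop (the epoch-0 state has no coefficient dependence through the
  ## dynamics, only through lambda directly)
  if (!is.null(ctx$fit_obs)) {
    fo <- ctx$fit_obs[ctx$fit_obs$h == 1L, , drop = FALSE]
    for (i in seq_len(nrow(fo))) {
      res <- .fitnessTerm(coef, ctx, fo$x[i], fo$logphi[i],
                          exp(ctx$logg0), grad)
      ll_fit <- ll_fit + fitness_weight * res$ll
      if (grad) gcoef <- gcoef + fitness_weight * res$gcoef
    }
  }
  for (rg_name in names(ctx$regimes)) {
    rg <- ctx$regimes[[rg_name]]
    m <- coef %*% t(rg$Dm)                     # rwh x (H+1)
    u <- Z %*% m                               # lineage x (H+1)
    w <- ctx$logg0 + u
    gmat <- softmaxCols(w)
    grad_m <- if (grad) matrix(0, nrow(coef), ncol(m)) else NULL
    for (ob in rg$obs) {
      g <- gmat[, ob$h]
      p <- as.vector(crossprod(ob$Zr, g))
      low <- p < ctx$floor
      n_floored <- n_floored + sum(low & ob$n > 0)
      ll_gen <- ll_gen + sum(ob$n * log(pmax(p, ctx$floor)))
      if (grad) {
        dLdp <- ifelse(low, 0, ob$n / pmax(p, ctx$floor))
        q <- as.vector(ob$Zr %*% dLdp)
        dLdw <- g * (q - sum(g * q))
        grad_m[, ob$h] <- grad_m[, ob$h] + as.vector(crossprod(Z, dLdw))
      }
    }
    if (!is.null(ctx$fit_obs)) {
      fo <- ctx$fit_obs[ctx$fit_obs$h > 1L &
                        ctx$fit_obs$regime == rg_name, , drop = FALSE]
      for (i in seq_len(nrow(fo))) {
        g <- gmat[, fo$h[i]]
        res <- .fitnessTerm(coef, ctx, fo$x[i], fo$logphi[i], g, grad)
        ll_fit <- ll_fit + fitness_weight * res$ll
        if (grad) {
          gcoef <- gcoef + fitness_weight * res$gcoef
          dLdw <- g * (res$dLdg - sum(g * res$dLdg))
          grad_m[, fo$h[i]] <- grad_m[, fo$h[i]] +
            fitness_weight * as.vector(crossprod(Z, dLdw))
        }
      }
    }
    if (grad) gcoef <- gcoef + grad_m %*% rg$Dm
  }
  out <- list(loglik = ll_fit + ll_gen, fitness = ll_fit,
              genotype = ll_gen, n_floored = n_floored)
  if (grad) out$grad <- gcoef
  out
}

## One squared-log fitness observation: -(log(sum_k g_k lambda_k(x)) -
## log(phi))^2, with gradient pieces wrt coefficients (direct lambda path)
## and wrt g (returned for the caller to chain through the epoch state).
.fitnessTerm <- function(coef, ctx, x, logphi, g, grad) {
  fx <- normBasis(ctx$form, x)                 # 3 x 1
  v <- as.vector(ctx$Z %*% (coef %*% fx))      # lineage log-fitness at x
  lam <- exp(v)
  P <- sum(g * lam)
  ll <- -(log(P) - logphi)^2
  if (!grad) return(list(ll = ll))
  r0 <- -2 * (log(P) - logphi) / P
  glam <- r0 * g * lam
  gcoef <- as.vector(crossprod(ctx$Z, glam)) %o% as.vector(fx)
  list(ll = ll, gcoef = gcoef, dLdg = r0 * lam)
}

#' Combined, fitness and genotype log-likelihoods
#'
#' The total log-likelihood of the RWH reaction-norm coefficients given an
#' assumed ancestral state sums, over evolutionary regimes, a genotype term
#' (multinomial log-likelihood of the observed RWH counts under the
#' predicted marginal RWH frequencies) and a fitness term (squared natural
#' log of the ratio of predicted to observed mean population fitness — a
#' log-normal noise kernel). Both terms are defined up to additive
#' constants; `fitness_weight` rescales the fitness term relative to the
#' genotype term (default 1).
#'
#' Observed RWHs that no lineage of the ancestral state carries are remapped
#' to their region's background pseudo-RWH before evaluation; observed RWHs
#' whose predicted marginal falls below `marginal_floor` contribute
#' `log(marginal_floor)` (never silently `-Inf`), and the number of floored
#' terms is reported in attribute `"n_floored"`.
#'
#' @param norms a [ReactionNormSet-class] covering every RWH of `ancestral`.
#' @param ancestral an [AncestralState-class].
#' @param data a `"normselData"` object from [assembleInferenceData()].
#' @param fitness_weight relative weight of the fitness term.
#' @param marginal_floor floor for predicted marginals (default 1e-12).
#' @return numeric log-likelihood with attribute `n_floored`.
#' @export
totalLoglik <- function(norms, ancestral, data, fitness_weight = 1,
                        marginal_floor = 1e-12) {
  ctx <- likelihoodContext(ancestral, data, normForm(norms), marginal_floor)
  coef <- .alignCoef(norms, ctx$rwh_ids)
  res <- .loglikEngine(coef, ctx, fitness_weight)
  structure(res$loglik, n_floored = res$n_floored)
}

#' @rdname totalLoglik
#' @export
loglikFitness <- function(norms, ancestral, data, fitness_weight = 1) {
  ctx <- likelihoodContext(ancestral, data, normForm(norms))
  coef <- .alignCoef(norms, ctx$rwh_ids)
  .loglikEngine(coef, ctx, fitness_weight)$fitness
}

#' @rdname totalLoglik
#' @export
loglikGenotypes <- function(norms, ancestral, data,
                            marginal_floor = 1e-12) {
  ctx <- likelihoodContext(ancestral, data, normForm(norms), marginal_floor)
  coef <- .alignCoef(norms, ctx$rwh_ids)
  res <- .loglikEngine(coef, ctx)
  structure(res$genotype, n_floored = res$n_floored)
}

.alignCoef <- function(norms, rwh_ids) {
  miss <- setdiff(rwh_ids, normIds(norms))
  if (length(miss))
    stop("no reaction-norm parameters for RWH(s): ",
         paste(miss, collapse = ", "))
  normCoef(norms)[rwh_ids, , drop = FALSE]
}
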
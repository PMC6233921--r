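#' One generation of deterministic selection
#'
#' Infinite-population replicator update:
#' \eqn{g_k(t+1) = \lambda_k(x) g_k(t) / \sum_j \lambda_j(x) g_j(t)}.
#' Computed in log space with max-subtraction, so arbitrarily large or small
#' \eqn{|\xi|} cannot overflow; frequencies are never clipped to zero (a
#' lineage at positive frequency stays positive; one at exactly zero stays
#' zero).
#'
#' @param freq simplex vector of lineage frequencies (one per lineage).
#' @param x environmental value (mM NaCl) faced in the generation being
#'   produced.
#' @param lineages a [LineageSet-class].
#' @param norms a [ReactionNormSet-class].
#' @return updated simplex vector.
#' @examples
#' ln <- lineageSet(cbind(r1 = c("A", "B")))
#' nm <- reactionNorms("linear", cbind(a = c(A = 0, B = 0),
#'                                     b = c(log(2), 0)))
#' selectionStep(c(0.5, 0.5), 100, ln, nm)   # (2/3, 1/3)
#' @export
selectionStep <- function(freq, x, lineages, norms) {
  assertSimplex(freq)
  xi <- lineageLogFitness(x, lineages, norms)
  w <- log(freq) + xi
  g <- exp(w - logSumExp(w))
  setNames(g / sum(g), lineages@lineage_id)
}

#' Propagate frequencies across an epoch
#'
#' Equivalent to applying [selectionStep()] for every generation in
#' `(from_gen, to_gen]`, and to the single-shot product form
#' \eqn{g_k^{[h]} \propto \exp(\sum_t \xi_k(x(t)))\, g_k^{[h-1]}} — the two
#' agree to floating precision because the per-generation normalizations
#' cancel. The product form is used.
#'
#' @param freq simplex vector at generation `from_gen`.
#' @param schedule an [EnvSchedule-class] covering `(from_gen, to_gen]`.
#' @param from_gen,to_gen integer generations, `from_gen < to_gen`.
#' @inheritParams selectionStep
#' @return simplex vector at generation `to_gen`.
#' @export
propagateEpoch <- function(freq, schedule, from_gen, to_gen, lineages, norms) {
  assertSimplex(freq)
  if (!(from_gen < to_gen)) stop("from_gen must be < to_gen")
  gens <- seq.int(from_gen + 1L, to_gen)
  xs <- scheduleEnv(schedule, gens)
  xi <- lineageLogFitness(xs, lineages, norms)
  if (is.null(dim(xi))) xi <- matrix(xi, ncol = 1)
  w <- log(freq) + rowSums(xi)
  g <- exp(w - logSumExp(w))
  setNames(g / sum(g), lineages@lineage_id)
}

#' Deterministic lineage-frequency trajectories
#'
#' Iterates the selection update from the ancestral state over `horizon`
#' generations of a schedule.
#'
#' @param ancestral an [AncestralState-class].
#' @param schedule an [EnvSchedule-class] covering `horizon` generations.
#' @param horizon number of generations to predict (>= 1).
#' @param norms a [ReactionNormSet-class].
#' @return matrix ((horizon + 1) x lineages): row t + 1 is the frequency
#'   vector at generation t (row 1 is the ancestral state, generation 0).
#' @export
predictTrajectories <- function(ancestral, schedule, horizon, norms) {
  stopifnot(is(ancestral, "AncestralState"), horizon >= 1)
  lineages <- ancestral@lineages
  xs <- scheduleEnv(schedule, seq_len(horizon))
  xi <- lineageLogFitness(xs, lineages, norms)
  if (is.null(dim(xi))) xi <- matrix(xi, ncol = 1)
  ## cumulative log-weights: log g0 + sum_{t<=T} xi(x(t)); normalize per row
  cum <- xi
  if (ncol(cum) > 1L)
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1L] + cum[, j]
  cum <- cbind(0, cum)
  w <- log(ancestral@freq) + cum        # lineages x (horizon + 1)
  out <- t(softmaxCols(w))              # normalize within each generation
  dimnames(out) <- list(generation = 0:horizon,
                        lineage = lineages@lineage_id)
  out
}

#' Population mean fitness and fitness variance
#'
#' \eqn{\bar W = \sum_k g_k \lambda_k(x)} and
#' \eqn{\mathrm{Var}(W) = \sum_k g_k (\lambda_k(x) - \bar W)^2}. In a
#' constant environment the deterministic dynamics never decrease
#' \eqn{\bar W} (the haploid analogue of Fisher's fundamental theorem).
#'
#' @param freq simplex vector of lineage frequencies.
#' @param x environmental value (mM NaCl).
#' @param lineages a [LineageSet-class].
#' @param norms a [ReactionNormSet-class].
#' @return single numeric value.
#' @export
meanFitness <- function(freq, x, lineages, norms) {
  assertSimplex(freq)
  sum(freq * exp(lineageLogFitness(x, lineages, norms)))
}

#' @rdname meanFitness
#' @export
fitnessVariance <- function(freq, x, lineages, norms) {
  assertSimplex(freq)
  lam <- exp(lineageLogFitness(x, lineages, norms))
  m <- sum(freq * lam)
  sum(freq * (lam - m)^2)
}

#' Environments where two lineages' reaction norms cross
#'
#' Roots of \eqn{\xi_a(x) - \xi_b(x)} inside `x_range`, solved in closed form
#' (linear: one root; quadratic: quadratic formula). Where the two norms
#' coincide identically the crossing set is infinite and an error is raised.
#'
#' @param lineage_a,lineage_b lineage identifiers present in `lineages`.
#' @param lineages a [LineageSet-class].
#' @param norms a [ReactionNormSet-class].
#' @param x_range length-2 numeric interval of environments to search.
#' @param tol coefficients smaller than `tol` in absolute value are treated
#'   as zero when classifying the difference polynomial.
#' @return numeric vector of crossing environments (possibly empty), sorted.
#' @export
crossingPoints <- function(lineage_a, lineage_b, lineages, norms,
                           x_range = c(0, 400), tol = 1e-12) {
  stopifnot(length(x_range) == 2, all(is.finite(x_range)))
  ia <- match(lineage_a, lineages@lineage_id)
  ib <- match(lineage_b, lineages@lineage_id)
  if (is.na(ia) || is.na(ib)) stop("unknown lineage id")
  cf <- norms@coef
  da <- colSums(cf[lineages@rwh[ia, ], , drop = FALSE]) -
        colSums(cf[lineages@rwh[ib, ], , drop = FALSE])
  ## difference polynomial in x: linear form -> da["a"] x + da["b"];
  ## quadratic form -> da["a"] x^2 + da["b"] x + da["c"]
  if (norms@form == "linear") {
    p2 <- 0; p1 <- da[["a"]]; p0 <- da[["b"]]
  } else {
    p2 <- da[["a"]]; p1 <- da[["b"]]; p0 <- da[["c"]]
  }
  if (abs(p2) < tol && abs(p1) < tol) {
    if (abs(p0) < tol) stop("norms coincide: infinite crossing set")
    return(numeric(0))                       # parallel, never cross
  }
  roots <- if (abs(p2) < tol) {
    -p0 / p1
  } else {
    disc <- p1^2 - 4 * p2 * p0
    if (disc < 0) numeric(0)
    else (-p1 + c(-1, 1) * sqrt(disc)) / (2 * p2)
  }
  lo <- min(x_range); hi <- max(x_range)
  sort(unique(roots[roots >= lo & roots <= hi]))
}

#' Write predicted trajectories to a tab-separated table
#'
#' Long format: `sample_index`, `regime`, `generation`, `lineage_id`,
#' `frequency`.
#'
#' @param traj matrix from [predictTrajectories()].
#' @param regime regime label.
#' @param path output path; append when the file exists and `append = TRUE`.
#' @param sample_index index of the ancestral draw the trajectory belongs to.
#' @param append logical.
#' @export
writeTrajectoryTable <- function(traj, regime, path, sample_index = 1L,
                                 append = FALSE) {
  df <- data.frame(
    sample_index = sample_index,
    regime = regime,
    generation = rep(as.integer(rownames(traj)), times = ncol(traj)),
    lineage_id = rep(colnames(traj), each = nrow(traj)),
    frequency = as.vector(traj))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !append, append = append)
  invisible(path)
}
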
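#' @import methods
NULL

#' Per-generation environment schedule of an evolution regime
#'
#' Holds the environmental value (NaCl concentration, mM) faced by a regime in
#' every generation \eqn{t = 1, \ldots, T}. Generation 0 is the ancestral
#' state and has no environment of its own; selection in generation \eqn{t}
#' acts through the value \eqn{x(t)}.
#'
#' @slot regime single character regime label (e.g. "sudden").
#' @slot env numeric vector, \code{env[t]} is the environment of generation t.
#' @seealso [envSchedule()], [scheduleEnv()]
#' @export
setClass("EnvSchedule",
  representation(regime = "character", env = "numeric"))

setValidity("EnvSchedule", function(object) {
  if (length(object@regime) != 1L) return("regime must be a single label")
  if (length(object@env) < 1L) return("schedule must cover >= 1 generation")
  if (any(!is.finite(object@env)) || any(object@env < 0))
    return("environment values must be finite and >= 0")
  TRUE
})

#' Fitness reaction norms of a set of region-wide haplotypes
#'
#' Each region-wide haplotype (RWH) \eqn{l} carries a log-fitness reaction
#' norm \eqn{f(x | \theta_l)}, either linear (\eqn{a x + b}) or quadratic
#' (\eqn{a x^2 + b x + c}) in the environmental value \eqn{x} (mM NaCl).
#' Coefficients are stored in a matrix with one row per RWH and columns
#' \code{a}, \code{b}, \code{c}; for linear norms the \code{c} column is
#' identically zero and ignored.
#'
#' @slot form "linear" or "quadratic".
#' @slot coef numeric matrix (RWHs x 3), rownames are RWH identifiers.
#' @seealso [reactionNorms()], [rwhLogFitness()]
#' @export
setClass("ReactionNormSet",
  representation(form = "character", coef = "matrix"))

setValidity("ReactionNormSet", function(object) {
  if (!object@form %in% c("linear", "quadratic"))
    return("form must be 'linear' or 'quadratic'")
  if (ncol(object@coef) != 3L || is.null(rownames(object@coef)))
    return("coef must be an RWH x 3 matrix with rownames")
  if (!identical(colnames(object@coef), c("a", "b", "c")))
    return("coef columns must be a, b, c")
  if (any(!is.finite(object@coef))) return("coefficients must be finite")
  if (object@form == "linear" && any(object@coef[, "c"] != 0))
    return("linear norms must have zero quadratic coefficient")
  if (anyDuplicated(rownames(object@coef))) return("duplicated RWH ids")
  TRUE
})

#' Set of selfing lineages
#'
#' A lineage (genome-wide haploid haplotype of a fully selfing, homozygous
#' individual) is a tuple \eqn{S_k} of one RWH identifier per genomic region.
#' With selfing and no recombination, lineages behave as asexual clones.
#'
#' @slot lineage_id character vector of lineage labels.
#' @slot rwh character matrix (lineages x regions); \code{rwh[k, i]} is the
#'   RWH carried by lineage k in region i. Column names are region labels.
#' @seealso [lineageSet()], [lineageLogFitness()]
#' @export
setClass("LineageSet",
  representation(lineage_id = "character", rwh = "matrix"))

setValidity("LineageSet", function(object) {
  if (nrow(object@rwh) != length(object@lineage_id))
    return("one rwh row per lineage required")
  if (anyDuplicated(object@lineage_id)) return("duplicated lineage ids")
  if (is.null(colnames(object@rwh))) return("rwh matrix needs region names")
  key <- apply(object@rwh, 1, paste, collapse = "\r")
  if (anyDuplicated(key)) return("duplicated RWH compositions")
  TRUE
})

#' Ancestral population state
#'
#' The pair \eqn{(A, g^{[0]})}: the lineages assumed to segregate in the
#' ancestral population and their starting frequencies.
#'
#' @slot lineages a [LineageSet-class].
#' @slot freq numeric simplex vector, one entry per lineage.
#' @seealso [ancestralState()], [sampleAncestral()]
#' @export
setClass("AncestralState",
  representation(lineages = "LineageSet", freq = "numeric"))

setValidity("AncestralState", function(object) {
  if (length(object@freq) != length(object@lineages@lineage_id))
    return("freq and lineages must have the same length")
  if (!isSimplex(object@freq))
    return("freq must be a simplex (non-negative, sum 1 within 1e-12)")
  TRUE
})

#' Maximum-likelihood fit of RWH reaction-norm parameters
#'
#' Result of [fitMLE()]: the best of several random-start quasi-Newton
#' optimizations of the combined fitness + genotype log-likelihood.
#'
#' @slot norms fitted [ReactionNormSet-class].
#' @slot loglik best log-likelihood found.
#' @slot starts data.frame of per-start final log-likelihoods and convergence
#'   codes.
#' @slot converged logical, TRUE if at least one start converged.
#' @slot seed integer seed the fit was run under.
#' @export
setClass("ModelFit",
  representation(norms = "ReactionNormSet", loglik = "numeric",
                 starts = "data.frame", converged = "logical",
                 seed = "integer"))

setValidity("ModelFit", function(object) {
  if (!is.finite(object@loglik)) return("loglik must be finite")
  TRUE
})

#' Ensemble of fits over resampled ancestral states
#'
#' Result of [fitEnsemble()]: one (ancestral state, model fit) pair per draw
#' of the ancestral population, plus per-generation per-lineage frequency
#' quantiles (2.5/50/97.5%) of the predicted trajectories, with lineages
#' matched across draws by their RWH composition.
#'
#' @slot draws list of lists with elements \code{ancestral} and \code{fit}.
#' @slot quantiles named list per regime; each element is a 3-dim array
#'   (generation x lineage-key x quantile).
#' @slot lineage_keys character vector of RWH-composition keys covered.
#' @slot seed integer master seed.
#' @export
setClass("EnsembleFit",
  representation(draws = "list", quantiles = "list",
                 lineage_keys = "character", seed = "integer"))
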
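#' Construct a set of RWH fitness reaction norms
#'
#' @param form "linear" (\eqn{f(x) = a x + b}) or "quadratic"
#'   (\eqn{f(x) = a x^2 + b x + c}). \eqn{f} is the log of the expected
#'   per-capita offspring number contributed by the RWH; \eqn{x} is the
#'   environmental value in mM NaCl.
#' @param coef coefficient matrix or data.frame with rownames (or an `rwh_id`
#'   column) identifying the RWHs and columns `a`, `b` (and `c` for
#'   quadratic).
#' @return a [ReactionNormSet-class].
#' @examples
#' nm <- reactionNorms("linear",
#'   cbind(a = c(H1 = 0.01, H2 = 0), b = c(0, log(2))))
#' rwhLogFitness(100, nm)   # H1: 1, H2: log 2
#' @export
reactionNorms <- function(form = c("linear", "quadratic"), coef) {
  form <- match.arg(form)
  if (is.data.frame(coef)) {
    if ("rwh_id" %in% names(coef)) {
      rownames(coef) <- coef$rwh_id
      coef$rwh_id <- NULL
    }
    coef <- as.matrix(coef)
  }
  need <- if (form == "linear") c("a", "b") else c("a", "b", "c")
  miss <- setdiff(need, colnames(coef))
  if (length(miss))
    stop("coef is missing column(s): ", paste(miss, collapse = ", "))
  full <- matrix(0, nrow(coef), 3,
                 dimnames = list(rownames(coef), c("a", "b", "c")))
  full[, colnames(coef)[colnames(coef) %in% c("a", "b", "c")]] <-
    coef[, colnames(coef)[colnames(coef) %in% c("a", "b", "c")]]
  new("ReactionNormSet", form = form, coef = full)
}

#' @describeIn reactionNorms RWH identifiers covered by the set.
#' @param norms a [ReactionNormSet-class].
#' @export
normIds <- function(norms) rownames(norms@coef)

#' @describeIn reactionNorms functional form ("linear"/"quadratic").
#' @export
normForm <- function(norms) norms@form

#' @describeIn reactionNorms coefficient matrix (RWH x a,b,c).
#' @export
normCoef <- function(norms) norms@coef

## Basis of the log-fitness function: f(x | theta) = coef %*% normBasis(x).
## Linear form: (a, b, c) . (x, 1, 0); quadratic: (a, b, c) . (x^2, x, 1).
## The same basis evaluated on cumulative environment moments gives the
## epoch-cumulated log-fitness, which is what makes the likelihood linear in
## the coefficients.
normBasis <- function(form, x) {
  if (form == "linear") rbind(x, 1, 0) else rbind(x^2, x, 1)
}

#' Log-fitness of each RWH at given environments
#'
#' Evaluates \eqn{f(x | \theta_l)} for every RWH.
#'
#' @param x numeric vector of environmental values (mM NaCl).
#' @param norms a [ReactionNormSet-class].
#' @return matrix (RWHs x length(x)) of log-fitness values; dropped to a
#'   named vector when `x` has length 1.
#' @export
rwhLogFitness <- function(x, norms) {
  stopifnot(is(norms, "ReactionNormSet"))
  if (any(!is.finite(x))) stop("environment values must be finite")
  out <- norms@coef %*% normBasis(norms@form, x)
  colnames(out) <- NULL
  if (length(x) == 1L) out[, 1] else out
}

setMethod("show", "ReactionNormSet", function(object) {
  cat("ReactionNormSet (", object@form, "): ", nrow(object@coef),
      " RWHs\n", sep = "")
  print(utils::head(object@coef, 6))
  if (nrow(object@coef) > 6) cat("...\n")
})
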
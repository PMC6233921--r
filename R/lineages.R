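#' Construct a set of lineages
#'
#' @param rwh character matrix or data.frame (lineages x regions): the RWH
#'   carried by each lineage in each region. Column names label the regions
#'   (e.g. "1", "2", "3").
#' @param lineage_id optional lineage labels; defaults to "L1", "L2", ...
#' @return a [LineageSet-class].
#' @export
lineageSet <- function(rwh, lineage_id = NULL) {
  rwh <- as.matrix(rwh)
  storage.mode(rwh) <- "character"
  if (is.null(colnames(rwh))) colnames(rwh) <- as.character(seq_len(ncol(rwh)))
  if (is.null(lineage_id)) lineage_id <- paste0("L", seq_len(nrow(rwh)))
  rownames(rwh) <- NULL
  new("LineageSet", lineage_id = as.character(lineage_id), rwh = rwh)
}

#' @describeIn lineageSet number of lineages.
#' @param x a [LineageSet-class].
#' @export
nLineages <- function(x) length(x@lineage_id)

#' @describeIn lineageSet lineage labels.
#' @export
lineageIds <- function(x) x@lineage_id

#' @describeIn lineageSet RWH composition matrix (lineages x regions).
#' @export
lineageRwh <- function(x) {
  m <- x@rwh
  rownames(m) <- x@lineage_id
  m
}

#' @describeIn lineageSet composition keys: one string per lineage, the
#'   region-ordered concatenation of its RWH ids. Used to match lineages
#'   across independently sampled ancestral states.
#' @export
lineageKeys <- function(x) apply(x@rwh, 1, paste, collapse = "+")

#' Construct an ancestral state
#'
#' @param lineages a [LineageSet-class].
#' @param freq numeric simplex vector of starting frequencies \eqn{g^{[0]}}.
#' @return an [AncestralState-class].
#' @export
ancestralState <- function(lineages, freq) {
  freq <- as.numeric(freq)
  new("AncestralState", lineages = lineages, freq = freq / sum(freq))
}

#' @describeIn ancestralState starting frequency vector.
#' @param state an [AncestralState-class].
#' @export
ancestralFreq <- function(state) setNames(state@freq,
                                          state@lineages@lineage_id)

#' @describeIn ancestralState the lineage set.
#' @export
ancestralLineages <- function(state) state@lineages

## 0/1 membership matrix Z (lineages x RWHs) restricted to the RWHs named in
## `rwh_ids`; Z[k, l] = 1 iff lineage k carries RWH l in some region. Because
## each lineage carries exactly one RWH per region, the restriction of Z to
## one region's RWHs has unit row sums.
lineageMembership <- function(lineages, rwh_ids) {
  G <- nLineages(lineages)
  Z <- matrix(0, G, length(rwh_ids),
              dimnames = list(lineages@lineage_id, rwh_ids))
  for (i in seq_len(ncol(lineages@rwh))) {
    hit <- match(lineages@rwh[, i], rwh_ids)
    ok <- !is.na(hit)
    Z[cbind(which(ok), hit[ok])] <- Z[cbind(which(ok), hit[ok])] + 1
  }
  Z
}

#' Log-fitness of lineages at given environments
#'
#' The lineage reaction norm is additive in log space over its constituent
#' RWHs: \eqn{\xi_k(x) = \sum_{l \in S_k} f(x | \theta_l)}, and
#' \eqn{\lambda_k(x) = \exp(\xi_k(x))} is the expected per-capita offspring
#' number.
#'
#' @param x numeric vector of environmental values (mM NaCl).
#' @param lineages a [LineageSet-class].
#' @param norms a [ReactionNormSet-class] covering every RWH the lineages
#'   carry.
#' @return matrix (lineages x length(x)) of \eqn{\xi_k(x)}; dropped to a
#'   named vector when `x` has length 1.
#' @export
lineageLogFitness <- function(x, lineages, norms) {
  stopifnot(is(lineages, "LineageSet"))
  miss <- setdiff(unique(as.vector(lineages@rwh)), normIds(norms))
  if (length(miss))
    stop("no reaction-norm parameters for RWH(s): ",
         paste(miss, collapse = ", "))
  f <- norms@coef %*% normBasis(norms@form, x)     # rwh x n_x
  out <- matrix(0, nLineages(lineages), length(x))
  for (i in seq_len(ncol(lineages@rwh)))
    out <- out + f[lineages@rwh[, i], , drop = FALSE]
  rownames(out) <- lineages@lineage_id
  if (length(x) == 1L) out[, 1] else out
}

setMethod("show", "LineageSet", function(object) {
  cat("LineageSet: ", nLineages(object), " lineages over ",
      ncol(object@rwh), " region(s)\n", sep = "")
})

setMethod("show", "AncestralState", function(object) {
  cat("AncestralState: ", nLineages(object@lineages),
      " lineages; top frequencies:\n", sep = "")
  f <- sort(ancestralFreq(object), decreasing = TRUE)
  print(round(utils::head(f, 5), 4))
})
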
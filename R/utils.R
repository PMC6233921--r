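#' @importFrom stats optim rbinom rmultinom rnorm runif setNames quantile
#'   median var chisq.test uniroot
#' @importFrom utils read.delim write.table packageVersion
NULL

## numerically stable log(sum(exp(x))); tolerates -Inf entries
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## column-wise softmax of a log-weight matrix; each column renormalized to a
## simplex. -Inf log-weights map to exact zeros.
softmaxCols <- function(w) {
  m <- apply(w, 2, max)
  e <- exp(sweep(w, 2, m, "-"))
  sweep(e, 2, colSums(e), "/")
}

isSimplex <- function(p, tol = 1e-12) {
  is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) <= tol
}

assertSimplex <- function(p, what = "frequencies", tol = 1e-12) {
  if (!isSimplex(p, tol))
    stop(what, " must be non-negative and sum to 1 (within ", tol, ")",
         call. = FALSE)
  invisible(p)
}

## Deterministic per-task seed derivation from a master seed. Tasks are
## numbered 1..n; the scheme is a fixed affine map kept below 2^31 so that the
## same master seed always yields the same task seeds, independent of how many
## tasks were run before.
deriveSeeds <- function(master_seed, n, stream = 0L) {
  master_seed <- as.integer(master_seed)
  (abs(master_seed) %% 1000003L) * 2011L + stream * 7919L + seq_len(n)
}

## Multinomial draws of size `size` for every column of prob matrix P
## (classes x replicates), via sequential conditional binomials. Equivalent in
## distribution to independent rmultinom() calls per column but vectorized
## across replicates.
rmultinomCols <- function(size, P) {
  G <- nrow(P)
  R <- ncol(P)
  if (length(size) == 1L) size <- rep(size, R)
  out <- matrix(0L, G, R)
  remaining <- as.integer(size)
  ptail <- rep(1, R)
  for (j in seq_len(G - 1L)) {
    pj <- ifelse(ptail > 0, pmin(1, pmax(0, P[j, ] / ptail)), 0)
    draw <- rbinom(R, remaining, pj)
    out[j, ] <- draw
    remaining <- remaining - draw
    ptail <- ptail - P[j, ]
  }
  out[G, ] <- remaining
  out
}

requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
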
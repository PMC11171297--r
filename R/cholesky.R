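## Cholesky decomposition of the two-electron repulsion tensor viewed as the
## positive semidefinite matrix M[(mu,nu),(la,si)] = (mu nu | la si).

#' Pivoted incomplete Cholesky decomposition of an ERI tensor
#'
#' Full-diagonal-pivoted incomplete Cholesky, stopping when the largest
#' remaining diagonal residual `(mu nu|mu nu)` drops to the threshold.  The
#' reconstruction `sum_P L^P L^P` then deviates from the exact tensor by at
#' most the threshold on every diagonal element (and, by Schwarz, by at
#' most the threshold elementwise).
#'
#' @param eri dense `n^4` tensor (chemists' notation) or an
#'   `ao_integrals` object with a dense `eri` field.
#' @param threshold stopping threshold (default `1e-5`).
#' @param max_rank optional rank cap.
#' @return object of class `cholesky_factors`: `vectors` (`n^2 x rank`
#'   matrix, each column one factor `L^P` in `(mu,nu)` layout),
#'   `threshold`, `rank`, `n`.
#' @export
cholesky_decompose <- function(eri, threshold = 1e-5, max_rank = 0) {
  if (inherits(eri, "ao_integrals")) eri <- eri$eri
  stopifnot(threshold > 0)
  n <- dim(eri)[1]
  M <- matrix(eri, n * n, n * n)
  dmin <- min(diag(M))
  if (dmin < -1e-8) stop("ERI matrix is not positive semidefinite (diagonal ",
                         dmin, ")")
  L <- cpp_pivoted_cholesky(M, threshold, as.integer(max_rank))
  structure(list(vectors = L, threshold = threshold,
                 rank = ncol(L), n = n),
            class = "cholesky_factors")
}

#' @export
print.cholesky_factors <- function(x, ...) {
  cat(sprintf("Cholesky factors: rank %d for %d basis functions (threshold %g)\n",
              x$rank, x$n, x$threshold))
  invisible(x)
}

#' Reconstruct the dense ERI tensor from Cholesky factors
#' @param cf `cholesky_factors`.
#' @return dense `n^4` array.
#' @export
cholesky_reconstruct <- function(cf) {
  n <- cf$n
  array(tcrossprod(cf$vectors), c(n, n, n, n))
}

## Attach Cholesky storage to an ao_integrals object (optionally dropping
## the dense tensor to save memory).
ao_attach_cholesky <- function(aoints, threshold = 1e-5, drop_dense = TRUE) {
  cf <- cholesky_decompose(aoints$eri, threshold)
  aoints$chol <- cf$vectors
  aoints$chol_threshold <- threshold
  if (drop_dense) aoints$eri <- NULL
  aoints
}
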
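#' Bootstrap-resample a spectrum matrix
#'
#' Each sample's channel counts are resampled from a multinomial with
#' probabilities proportional to the observed counts and the total count
#' preserved (rounded, for the non-integer spectra a median subtraction can
#' produce); all-zero samples pass through unchanged with a warning.
#'
#' @param x [MutationSpectra-class] or channels x samples count matrix.
#' @param nBootstraps Number of resampled matrices (default 300).
#' @param seed Integer seed.
#' @return List of channels x samples matrices.
#' @export
bootstrapSpectra <- function(x, nBootstraps = 300, seed = NULL) {
  X <- spectrumCounts(x)
  if (any(X < 0))
    stop("bootstrap resampling requires non-negative counts")
  tot <- round(colSums(X))
  zero <- tot == 0
  if (any(zero)) warning(sum(zero), " all-zero sample(s) passed through unchanged")
  .withSeed(seed, {
    lapply(seq_len(nBootstraps), function(b) {
      out <- X
      for (j in which(!zero))
        out[, j] <- rmultinom(1, tot[j], X[, j])[, 1]
      out
    })
  })
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V ~ W H` under the Frobenius objective
#' using multiplicative update rules from a random non-negative
#' initialization (reproducible under the seed). The objective is
#' non-increasing across updates; iteration stops at `maxIter` or when the
#' relative objective change falls below `tol`.
#'
#' @param x Channels x samples non-negative matrix (or
#'   [MutationSpectra-class]).
#' @param rank Factorization rank (number of signatures); must be smaller
#'   than both dimensions.
#' @param maxIter Maximum iterations (default 10000).
#' @param tol Relative objective-change stopping tolerance (default 1e-10).
#' @param seed Integer seed.
#' @return List: `profiles` (channels x rank, columns sum to 1), `exposures`
#'   (rank x samples), `objective` (final squared Frobenius error),
#'   `iterations`, `trace` (objective checkpoints).
#' @export
nmfDecompose <- function(x, rank, maxIter = 10000, tol = 1e-10, seed = NULL) {
  V <- spectrumCounts(x)
  if (any(V < 0)) stop("input matrix must be non-negative")
  if (rank >= min(dim(V))) stop("rank must be smaller than both dimensions")
  .withSeed(seed, {
    fit <- .nmf_mu(V, as.integer(rank), as.integer(maxIter), tol)
    dimnames(fit$W) <- list(rownames(V), paste0("k", seq_len(rank)))
    dimnames(fit$H) <- list(paste0("k", seq_len(rank)), colnames(V))
    list(profiles = fit$W, exposures = fit$H, objective = fit$objective,
         iterations = fit$iterations, trace = fit$trace)
  })
}
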
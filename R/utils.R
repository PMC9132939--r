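#' Cosine similarity between two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return Cosine similarity in \[-1, 1\]; 0 if either vector is all-zero.
#' @export
cosineSim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

## Pairwise cosine similarity between columns of A and columns of B.
.cosineMat <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  crossprod(A, B) / outer(na, nb)
}

## Seed scoping: run `expr` under set.seed(seed) when seed is non-NULL,
## restoring the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Small, stable seed derivation for sub-tasks.
.subSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1009L * as.integer(k)) %% 2147483587L
}

#' Write a sample-by-column numeric matrix as TSV
#'
#' First column `sample` holds row names; remaining columns are the matrix.
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @export
writeMatrixTsv <- function(x, path) {
  df <- data.frame(sample = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [writeMatrixTsv()]
#' @param path Input path.
#' @return Numeric matrix with samples as row names.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
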
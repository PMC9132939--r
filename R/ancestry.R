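## Ancestry matching.
##
## Unmatched cancer cell lines carry residual germline variants whose
## trinucleotide spectrum differs between ancestral populations. The model:
## cluster all samples (cell lines + a germline-only baseline panel) on
## principal components of common germline variants, prune components that
## merely separate the two batches, and subtract each cluster's median
## baseline germline spectrum from the observed spectrum of its cell lines,
## clamping negative channels at zero.

#' Principal components of a common-variant genotype matrix
#'
#' Variants are restricted to those with cohort minor allele frequency above
#' `mafThreshold` (the commonness criterion), then a centered PCA is run.
#'
#' @param genotypes Samples x variants matrix of 0/1/2 genotypes.
#' @param nPCs Number of components to return (default 150; truncated with a
#'   warning when above the matrix rank).
#' @param mafThreshold Cohort MAF threshold for a variant to count as common
#'   (default 0.05).
#' @return List with `scores` (samples x PCs), `loadings`, `sdev`.
#' @export
computeAncestryPCs <- function(genotypes, nPCs = 150, mafThreshold = 0.05) {
  af <- colMeans(genotypes) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf > mafThreshold
  G <- genotypes[, keep, drop = FALSE]
  pc <- prcomp(G, center = TRUE, scale. = FALSE)
  avail <- ncol(pc$x)
  if (nPCs > avail) {
    warning("requested ", nPCs, " PCs but rank allows ", avail, "; truncated")
    nPCs <- avail
  }
  list(scores = pc$x[, seq_len(nPCs), drop = FALSE],
       loadings = pc$rotation[, seq_len(nPCs), drop = FALSE],
       sdev = pc$sdev[seq_len(nPCs)])
}

#' Prune batch-associated principal components
#'
#' Fits an ensemble-of-trees classifier (ranger, permutation importance)
#' predicting the batch label from PC scores and removes the `nRemove`
#' components with the highest importance - a fixed-count rule, applied
#' whether or not the batch is actually separable.
#'
#' @param scores Samples x PCs score matrix.
#' @param batch Binary batch label per sample (e.g. cell line vs baseline).
#' @param nRemove Number of PCs to remove (default 10).
#' @param numTrees Trees in the classifier (default 500).
#' @param seed Integer seed.
#' @return Integer indices of the retained PCs, in original order; the
#'   removed indices are in `attr(, "removed")`.
#' @export
removeBatchPCs <- function(scores, batch, nRemove = 10, numTrees = 500,
                           seed = 1) {
  all <- seq_len(ncol(scores))
  if (nRemove == 0) {
    out <- all; attr(out, "removed") <- integer(0); return(out)
  }
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    warning("single-batch input: no PCs removed")
    out <- all; attr(out, "removed") <- integer(0); return(out)
  }
  df <- data.frame(scores, check.names = FALSE)
  fit <- ranger::ranger(x = df, y = batch, num.trees = numTrees,
                        importance = "permutation", seed = seed,
                        num.threads = 1)
  imp <- fit$variable.importance
  removed <- sort(order(imp, decreasing = TRUE)[seq_len(min(nRemove, length(imp)))])
  out <- setdiff(all, removed)
  attr(out, "removed") <- removed
  out
}

## Trimmed k-means: Lloyd iterations that exclude the trimFraction of
## samples farthest from their nearest centroid from the centroid update;
## excluded samples are labelled outliers. nStart random restarts, best
## trimmed within-cluster sum of squares kept.
.trimmedKmeans <- function(X, k, trimFraction = 0.05, nStart = 10,
                           iterMax = 100, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k < 1) stop("k must be >= 1")
  nTrim <- floor(trimFraction * n)
  .withSeed(seed, {
    best <- NULL
    for (s in seq_len(nStart)) {
      centers <- X[sample.int(n, k), , drop = FALSE]
      assign <- rep(1L, n); keep <- rep(TRUE, n)
      for (it in seq_len(iterMax)) {
        d2 <- outer(rowSums(X^2), rowSums(centers^2), `+`) -
          2 * tcrossprod(X, centers)
        d2[d2 < 0] <- 0
        newAssign <- max.col(-d2, ties.method = "first")
        dmin <- d2[cbind(seq_len(n), newAssign)]
        keep <- rep(TRUE, n)
        if (nTrim > 0)
          keep[order(dmin, decreasing = TRUE)[seq_len(nTrim)]] <- FALSE
        if (identical(newAssign, assign) && it > 1) break
        assign <- newAssign
        for (j in seq_len(k)) {
          members <- which(assign == j & keep)
          if (length(members))
            centers[j, ] <- colMeans(X[members, , drop = FALSE])
        }
      }
      obj <- sum(d2[cbind(seq_len(n), assign)][keep])
      if (is.null(best) || obj < best$obj)
        best <- list(assign = assign, keep = keep, centers = centers, obj = obj)
    }
    best
  })
}

#' Cluster samples by ancestry with outlier trimming
#'
#' Trimmed k-means on retained PC scores: assignment/update iterations that
#' exclude the `trimFraction` of samples farthest from their nearest
#' centroid; excluded samples are labelled `"outlier"`.
#'
#' @param scores Samples x retained-PC score matrix.
#' @param k Number of clusters (>= 2).
#' @param trimFraction Fraction of samples to trim (default 0.05).
#' @param nStart Random restarts (default 10).
#' @param seed Integer seed.
#' @return Factor of assignments (`"1"..k` plus `"outlier"`), with the
#'   centroid matrix in `attr(, "centers")` and the trimmed objective in
#'   `attr(, "objective")`.
#' @export
clusterAncestry <- function(scores, k, trimFraction = 0.05, nStart = 10,
                            seed = 1) {
  if (k < 2) stop("k must be >= 2")
  fit <- .trimmedKmeans(scores, k, trimFraction, nStart, seed = seed)
  lab <- as.character(fit$assign)
  lab[!fit$keep] <- "outlier"
  out <- factor(lab, levels = c(as.character(seq_len(k)), "outlier"))
  names(out) <- rownames(scores)
  attr(out, "centers") <- fit$centers
  attr(out, "objective") <- fit$obj
  out
}

#' Fit the full ancestry-matching model
#'
#' Runs PCA on common variants, prunes batch-associated PCs, clusters all
#' samples, and computes each cluster's median germline spectrum from the
#' baseline (germline-only) samples assigned to it. Clusters with no
#' baseline members, and outlier samples, fall back to the global median
#' baseline spectrum.
#'
#' @param genotypes Samples x variants genotype matrix (cell lines and
#'   baseline samples together).
#' @param batch Factor separating `cellline` from `baseline` samples.
#' @param baselineSpectra [MutationSpectra-class] (or channels x samples
#'   matrix) of frequency-filtered germline spectra of the baseline samples.
#' @param k Number of ancestry clusters (default 13, as for a continental
#'   panel; use the true population count in synthetic work).
#' @param trimFraction Trimming level of the robust clustering (default 0.05).
#' @param nPCs PCs computed before pruning (default 150).
#' @param nRemove Batch-associated PCs removed (default 10).
#' @param mafThreshold Commonness threshold for variants (default 0.05).
#' @param seed Integer seed.
#' @param pcs Optional precomputed result of [computeAncestryPCs()].
#' @param retained Optional precomputed result of [removeBatchPCs()].
#' @return An [AncestryModel-class].
#' @export
ancestryMatch <- function(genotypes, batch, baselineSpectra, k = 13,
                          trimFraction = 0.05, nPCs = 150, nRemove = 10,
                          mafThreshold = 0.05, seed = 1, pcs = NULL,
                          retained = NULL) {
  if (is.null(pcs))
    pcs <- computeAncestryPCs(genotypes, nPCs = nPCs,
                              mafThreshold = mafThreshold)
  if (is.null(retained))
    retained <- removeBatchPCs(pcs$scores, batch, nRemove = nRemove,
                               seed = seed)
  clusters <- clusterAncestry(pcs$scores[, retained, drop = FALSE], k = k,
                              trimFraction = trimFraction, seed = seed)
  base <- spectrumCounts(baselineSpectra)
  baseIds <- colnames(base)
  med <- matrix(0, k + 1, nrow(base),
                dimnames = list(c(as.character(seq_len(k)), "global"),
                                rownames(base)))
  med["global", ] <- apply(base, 1, median)
  for (j in seq_len(k)) {
    members <- intersect(names(clusters)[clusters == as.character(j)], baseIds)
    med[j, ] <- if (length(members) >= 2)
      apply(base[, members, drop = FALSE], 1, median)
    else med["global", ]
  }
  new("AncestryModel", scores = pcs$scores,
      removedPCs = as.integer(attr(retained, "removed")),
      clusters = clusters, centers = attr(clusters, "centers"),
      medianSpectra = med, k = as.integer(k))
}

#' Subtract a matched germline baseline from an observed spectrum
#'
#' Channelwise difference with negative channels clamped to zero.
#'
#' @param observed Numeric vector or channels x samples matrix of observed
#'   counts.
#' @param baseline Numeric vector (recycled across samples) with the same
#'   channel schema.
#' @return Estimated somatic counts, same shape as `observed`.
#' @export
subtractMatchedBaseline <- function(observed, baseline) {
  if (is.matrix(observed)) {
    if (length(baseline) != nrow(observed))
      stop("channel schema mismatch between observed and baseline")
    return(pmax(observed - baseline, 0))
  }
  if (length(baseline) != length(observed))
    stop("channel schema mismatch between observed and baseline")
  pmax(observed - baseline, 0)
}

#' Estimate somatic spectra for every cell line under an ancestry model
#'
#' @param observedSpectra [MutationSpectra-class] of frequency-filtered
#'   observed cell-line spectra.
#' @param model An [AncestryModel-class].
#' @return [MutationSpectra-class] of estimated somatic spectra.
#' @export
estimateSomaticSpectra <- function(observedSpectra, model) {
  obs <- spectrumCounts(observedSpectra)
  est <- obs
  for (s in colnames(obs)) {
    cl <- as.character(model@clusters[s])
    if (is.na(cl) || cl == "outlier" || !cl %in% rownames(model@medianSpectra))
      cl <- "global"
    est[, s] <- subtractMatchedBaseline(obs[, s], model@medianSpectra[cl, ])
  }
  MutationSpectra(est, scheme = channelScheme(observedSpectra))
}

#' Absolute error between spectra
#'
#' Sum of absolute channel differences over the 96 trinucleotide SNV
#' channels, per sample.
#'
#' @param a,b [MutationSpectra-class] objects or channels x samples matrices
#'   over the same samples.
#' @param snvOnly Restrict to the 96 SNV channels (default TRUE).
#' @param normalize Compare normalized spectra (each sample's channel
#'   distribution) instead of raw counts (default FALSE, the count-scale
#'   error used in the reconstruction benchmark).
#' @return Named numeric vector of per-sample absolute errors.
#' @export
absoluteError <- function(a, b, snvOnly = TRUE, normalize = FALSE) {
  A <- spectrumCounts(a); B <- spectrumCounts(b)
  stopifnot(identical(dim(A), dim(B)))
  if (snvOnly) {
    keep <- rownames(A) %in% snvChannelNames()
    A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  }
  if (normalize) {
    ca <- colSums(A); cb <- colSums(B)
    A <- sweep(A, 2, ifelse(ca == 0, 1, ca), `/`)
    B <- sweep(B, 2, ifelse(cb == 0, 1, cb), `/`)
  }
  colSums(abs(A - B))
}

#' Bootstrap self-similarity floor
#'
#' The error expected by chance alone: each true spectrum is multinomially
#' resampled (total count preserved) and the absolute error to the original
#' is averaged over `reps` runs.
#'
#' @param truth [MutationSpectra-class] of true somatic spectra.
#' @param reps Bootstrap repetitions (default 100).
#' @param seed Integer seed.
#' @param snvOnly Restrict to SNV channels (default TRUE).
#' @return Named per-sample mean bootstrap error.
#' @export
bootstrapFloor <- function(truth, reps = 100, seed = 1, snvOnly = TRUE) {
  X <- spectrumCounts(truth)
  if (snvOnly) X <- X[rownames(X) %in% snvChannelNames(), , drop = FALSE]
  .withSeed(seed, {
    acc <- numeric(ncol(X))
    for (r in seq_len(reps)) {
      bs <- apply(X, 2, function(col) {
        tot <- sum(col)
        if (tot == 0) col else rmultinom(1, tot, col)[, 1]
      })
      acc <- acc + colSums(abs(bs - X))
    }
    setNames(acc / reps, colnames(X))
  })
}

#' Benchmark somatic-spectrum reconstruction on a synthetic cohort
#'
#' Reproduces the reconstruction comparison on a [simulateCohort()] output:
#' frequency filtering of observed and baseline calls, the full ancestry
#' matching model over a grid of cluster counts, and per-sample absolute
#' errors of (i) ancestry-matched subtraction per k, (ii) frequency
#' filtering alone and (iii) the bootstrap self-similarity floor.
#'
#' @param cohort Output of [simulateCohort()].
#' @param kGrid Cluster counts to evaluate (default 2:8).
#' @param trimFraction Trimming level (default 0.05).
#' @param nPCs,nRemove PCA/pruning configuration (defaults 150 / 10; `nPCs`
#'   is truncated automatically on small cohorts).
#' @param bootstrapReps Bootstrap floor repetitions (default 100).
#' @param populationMafCutoff,cohortFractionCutoff Frequency-filter cutoffs.
#' @param seed Integer seed.
#' @return List: `perK` (data.frame k, meanAE), `summary` (data.frame
#'   method, meanAE over the best-k model / filter-only / floor),
#'   `perSample` (matrix of per-sample errors by method), `model` (the
#'   [AncestryModel-class] at the best k).
#' @export
benchmarkReconstruction <- function(cohort, kGrid = 2:8, trimFraction = 0.05,
                                    nPCs = 150, nRemove = 10,
                                    bootstrapReps = 100,
                                    populationMafCutoff = 1e-5,
                                    cohortFractionCutoff = 0.05, seed = 1) {
  scheme <- cohort$scheme
  obsF <- filterResidualGermline(cohort$observedCalls, populationMafCutoff,
                                 cohortFractionCutoff,
                                 nCohort = length(cohort$cellLines))
  baseF <- filterResidualGermline(cohort$baselineCalls, populationMafCutoff,
                                  cohortFractionCutoff,
                                  nCohort = length(cohort$baselineSamples))
  obsSpec <- buildSpectrumMatrix(obsF, scheme, samples = cohort$cellLines)
  baseSpec <- buildSpectrumMatrix(baseF, scheme,
                                  samples = cohort$baselineSamples)

  nPCs <- min(nPCs, nrow(cohort$genotypes) - 1)
  pcs <- computeAncestryPCs(cohort$genotypes, nPCs = nPCs)
  retained <- removeBatchPCs(pcs$scores, cohort$batch, nRemove = nRemove,
                             seed = seed)

  truth <- cohort$truth
  floorErr <- bootstrapFloor(truth, reps = bootstrapReps,
                             seed = .subSeed(seed, 7))
  filterErr <- absoluteError(obsSpec, truth)

  perK <- data.frame(k = kGrid, meanAE = NA_real_)
  models <- vector("list", length(kGrid))
  errs <- vector("list", length(kGrid))
  for (i in seq_along(kGrid)) {
    m <- ancestryMatch(cohort$genotypes, cohort$batch, baseSpec, k = kGrid[i],
                       trimFraction = trimFraction, seed = seed, pcs = pcs,
                       retained = retained)
    est <- estimateSomaticSpectra(obsSpec, m)
    errs[[i]] <- absoluteError(est, truth)
    perK$meanAE[i] <- mean(errs[[i]])
    models[[i]] <- m
  }
  bestI <- which.min(perK$meanAE)
  perSample <- cbind(`ancestry-matched` = errs[[bestI]],
                     `frequency-filter-only` = filterErr,
                     `bootstrap-floor` = floorErr)
  summary <- data.frame(
    method = colnames(perSample),
    meanAE = colMeans(perSample), row.names = NULL)
  list(perK = perK, summary = summary, perSample = perSample,
       model = models[[bestI]], bestK = kGrid[bestI],
       observedSpectra = obsSpec, baselineSpectra = baseSpec)
}
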
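## Signature extraction.
##
## The extraction pipeline follows the bootstrapped-NMF family of methods:
## many multinomial bootstrap replicates of the spectrum matrix are
## factorized over a sweep of ranks; per rank, runs whose factorization
## error diverges from the best run by more than a relative tolerance are
## dropped; the pooled signature vectors across all ranks are clustered by
## k-medoids and the medoids become candidate signatures. A hierarchical
## outer loop removes (or downweights) well-reconstructed samples and
## re-extracts, so that rare signatures confined to few samples can surface.
## Candidates are matched against a reference catalog by (weighted) cosine
## similarity and named accordingly; unmatched candidates become novel
## cell-line signatures (SBS-CL).

#' Extraction configuration
#'
#' @param nBootstraps Bootstrap replicates per rank (default 300).
#' @param rankRange Ranks (numbers of signatures) swept (default 2:40).
#' @param maxIter Maximum NMF iterations (default 10000).
#' @param tol NMF objective stopping tolerance (default 1e-10).
#' @param rtol Relative tolerance of the per-rank run filter (default 0.001,
#'   i.e. runs diverging >0.1 percent from the best run are dropped).
#' @param hierarchyMaxIter Maximum hierarchical iterations (default 3).
#' @param hierarchyCosine Reconstruction cosine above which a sample is
#'   removed (or downweighted) for the next iteration (default 0.97).
#' @param mode `"remove"` (default) or `"downweight"`.
#' @param downweightFactor Multiplier applied to well-reconstructed samples
#'   in downweight mode (default 0.05).
#' @param medoidKRange Cluster counts swept in the medoid step (default 2:30).
#' @param matchThreshold Catalog-match cosine threshold (default 0.85).
#' @param dedupCosine Cosine above which candidates from different
#'   iterations are considered duplicates (default 0.99).
#' @param minSamples Smallest sample set the hierarchy will re-extract on
#'   (default 5).
#' @param jointReferenceSpectra Placeholder for the joint inference variant
#'   in which reference tumor spectra are appended to the cell-line matrix
#'   before factorization; accepted in the configuration for forward
#'   compatibility but not implemented (must stay NULL).
#' @param seed Integer seed.
#' @return A classed list of configuration values.
#' @export
extractionConfig <- function(nBootstraps = 300, rankRange = 2:40,
                             maxIter = 10000, tol = 1e-10, rtol = 0.001,
                             hierarchyMaxIter = 3, hierarchyCosine = 0.97,
                             mode = c("remove", "downweight"),
                             downweightFactor = 0.05, medoidKRange = 2:30,
                             matchThreshold = 0.85, dedupCosine = 0.99,
                             minSamples = 5, jointReferenceSpectra = NULL,
                             seed = 1) {
  mode <- match.arg(mode)
  if (!is.null(jointReferenceSpectra))
    stop("joint cell-line + tumor inference is not implemented; ",
         "jointReferenceSpectra must be NULL")
  stopifnot(nBootstraps > 0, length(rankRange) > 0, maxIter > 0,
            rtol > 0, rtol < 1, hierarchyMaxIter > 0,
            hierarchyCosine > 0, hierarchyCosine < 1,
            downweightFactor > 0, downweightFactor < 1)
  structure(list(nBootstraps = nBootstraps, rankRange = rankRange,
                 maxIter = maxIter, tol = tol, rtol = rtol,
                 hierarchyMaxIter = hierarchyMaxIter,
                 hierarchyCosine = hierarchyCosine, mode = mode,
                 downweightFactor = downweightFactor,
                 medoidKRange = medoidKRange,
                 matchThreshold = matchThreshold, dedupCosine = dedupCosine,
                 minSamples = minSamples,
                 jointReferenceSpectra = jointReferenceSpectra, seed = seed),
            class = "sigmark_extraction_config")
}

#' Bootstrapped NMF runs over a rank sweep with divergence filtering
#'
#' Factorizes `nBootstraps` multinomial resamples of the matrix at every
#' rank in `rankRange`; per rank, runs whose root-mean-square factorization
#' deviation exceeds the best run's by more than `rtol` (relative) are
#' dropped, and the retained signature vectors are pooled.
#'
#' @param x Channels x samples count matrix or [MutationSpectra-class].
#' @param config An [extractionConfig()].
#' @return List: `pool` (channels x solutions matrix of pooled signature
#'   vectors), `meta` (data.frame rank, run, rmsd, kept).
#' @export
runBootstrapNMF <- function(x, config = extractionConfig()) {
  X <- spectrumCounts(x)
  boots <- bootstrapSpectra(X, config$nBootstraps,
                            seed = .subSeed(config$seed, 11))
  ranks <- config$rankRange[config$rankRange < min(dim(X))]
  if (!length(ranks)) stop("no feasible rank below min(dim) available")
  pool <- list(); meta <- list()
  mn <- prod(dim(X))
  for (r in ranks) {
    fits <- lapply(seq_along(boots), function(b)
      nmfDecompose(boots[[b]], r, maxIter = config$maxIter, tol = config$tol,
                   seed = .subSeed(config$seed, 1000 * r + b)))
    rmsd <- vapply(fits, function(f) sqrt(f$objective / mn), numeric(1))
    keep <- rtolFilter(rmsd, config$rtol)
    meta[[length(meta) + 1]] <- data.frame(rank = r, run = seq_along(fits),
                                           rmsd = rmsd, kept = keep)
    for (b in which(keep)) pool[[length(pool) + 1]] <- fits[[b]]$profiles
  }
  pool <- do.call(cbind, pool)
  if (is.null(pool) || ncol(pool) == 0) stop("empty solution pool")
  list(pool = pool, meta = do.call(rbind, meta))
}

#' Relative-tolerance run filter
#'
#' Keeps runs whose root-mean-square factorization deviation is within
#' `rtol` (relative) of the best run's.
#'
#' @param rmsd Numeric vector of per-run RMS deviations.
#' @param rtol Relative tolerance (default 0.001, i.e. 0.1 percent).
#' @return Logical keep vector.
#' @export
rtolFilter <- function(rmsd, rtol = 0.001) {
  rmsd <= min(rmsd) * (1 + rtol)
}

#' Select candidate signatures as medoids of the pooled solutions
#'
#' Pooled signature vectors are L2-normalized (so Euclidean distance orders
#' like cosine distance) and clustered by k-medoids (CLARA, pam-like, 10
#' percent subsampling) for every k in `medoidKRange`. The clustering whose
#' medoids match the largest number of distinct catalog entries at the match
#' threshold is selected; without a catalog the average silhouette width
#' decides.
#'
#' @param pool Channels x solutions matrix from [runBootstrapNMF()].
#' @param config An [extractionConfig()].
#' @param catalog Optional channels x signatures reference catalog.
#' @return Channels x candidates matrix of candidate profiles (columns sum
#'   to 1); chosen k in `attr(, "k")`.
#' @export
extractCandidateSignatures <- function(pool, config = extractionConfig(),
                                       catalog = NULL) {
  if (is.list(pool) && !is.null(pool$pool)) pool <- pool$pool
  if (is.null(pool) || ncol(pool) == 0) stop("empty solution pool")
  nrm <- sqrt(colSums(pool^2)); nrm[nrm == 0] <- 1
  U <- t(sweep(pool, 2, nrm, `/`))          # solutions x channels
  if (nrow(U) == 1) {
    cand <- matrix(pool[, 1] / sum(pool[, 1]), ncol = 1,
                   dimnames = list(rownames(pool), "C1"))
    attr(cand, "k") <- 1L
    return(cand)
  }
  ks <- config$medoidKRange[config$medoidKRange < nrow(U)]
  if (!length(ks)) ks <- nrow(U) - 1
  best <- NULL
  for (k in ks) {
    cl <- cluster::clara(U, k, metric = "euclidean", stand = FALSE,
                         samples = 5,
                         sampsize = min(nrow(U), max(40 + 2 * k,
                                                     ceiling(0.1 * nrow(U)))),
                         pamLike = TRUE, rngR = TRUE)
    med <- t(U[cl$i.med, , drop = FALSE])   # channels x k
    score <- if (!is.null(catalog)) {
      cs <- .snvCosine(med, catalog)
      sum(apply(cs, 2, max) >= config$matchThreshold)
    } else cl$silinfo$avg.width
    if (is.null(best) || score > best$score)
      best <- list(score = score, med = med, k = k)
  }
  cand <- apply(best$med, 2, function(p) {
    p[p < 0] <- 0
    if (sum(p) > 0) p / sum(p) else p
  })
  cand <- matrix(cand, nrow = nrow(best$med),
                 dimnames = list(rownames(pool),
                                 paste0("C", seq_len(ncol(best$med)))))
  attr(cand, "k") <- best$k
  cand
}

## Cosine similarity between candidate and catalog columns, computed on the
## 96 SNV channels only (catalogs have no indel block).
.snvCosine <- function(candidates, catalog) {
  snv <- snvChannelNames()
  A <- candidates[rownames(candidates) %in% snv, , drop = FALSE]
  common <- intersect(rownames(A), rownames(catalog))
  .cosineMat(A[common, , drop = FALSE], catalog[common, , drop = FALSE])
}

#' Fit non-negative exposures of samples to fixed signature profiles
#'
#' Per-sample non-negative least squares against the profile matrix.
#'
#' @param x Channels x samples count matrix or [MutationSpectra-class].
#' @param profiles Channels x signatures matrix.
#' @return Signatures x samples exposure matrix; per-sample reconstruction
#'   cosine in `attr(, "cosine")` and residual norm in `attr(, "residual")`.
#' @export
fitExposures <- function(x, profiles) {
  X <- spectrumCounts(x)
  stopifnot(nrow(X) == nrow(profiles))
  E <- matrix(0, ncol(profiles), ncol(X),
              dimnames = list(colnames(profiles), colnames(X)))
  cosv <- resv <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    fit <- pracma::lsqnonneg(profiles, X[, j])
    E[, j] <- fit$x
    rec <- as.vector(profiles %*% fit$x)
    cosv[j] <- cosineSim(rec, X[, j])
    resv[j] <- sqrt(sum((rec - X[, j])^2))
  }
  attr(E, "cosine") <- setNames(cosv, colnames(X))
  attr(E, "residual") <- setNames(resv, colnames(X))
  E
}

## Drop near-duplicate candidate columns (cosine >= threshold with an
## earlier-kept column).
.dedupProfiles <- function(P, threshold) {
  if (ncol(P) <= 1) return(P)
  keep <- logical(ncol(P))
  for (j in seq_len(ncol(P))) {
    if (!any(keep)) { keep[j] <- TRUE; next }
    cs <- .cosineMat(P[, keep, drop = FALSE], P[, j, drop = FALSE])
    keep[j] <- max(cs) < threshold
  }
  P[, keep, drop = FALSE]
}

#' Hierarchical signature extraction
#'
#' Iterates candidate extraction: after each round, exposures of the current
#' candidate set are fitted by non-negative least squares and samples whose
#' reconstruction cosine reaches `hierarchyCosine` are removed (or
#' downweighted) before re-extraction, up to `hierarchyMaxIter` rounds.
#' Candidates are pooled across rounds and deduplicated at `dedupCosine`;
#' final exposures are fitted on every sample.
#'
#' @param x Channels x samples count matrix or [MutationSpectra-class].
#' @param config An [extractionConfig()].
#' @param catalog Optional reference catalog used by the medoid selection
#'   rule (and later by [matchAndName()]).
#' @return A [SignatureSet-class] (not yet matched/named: profiles carry
#'   working names `C1..Cn`).
#' @export
hierarchicalExtract <- function(x, config = extractionConfig(),
                                catalog = NULL) {
  X0 <- spectrumCounts(x)
  X <- X0
  active <- colnames(X)
  candidates <- NULL
  itRun <- 0
  for (it in seq_len(config$hierarchyMaxIter)) {
    itRun <- it
    sub <- X[, active, drop = FALSE]
    cfgIt <- config; cfgIt$seed <- .subSeed(config$seed, 100 + it)
    pool <- runBootstrapNMF(sub, cfgIt)
    cand <- extractCandidateSignatures(pool, config, catalog)
    candidates <- if (is.null(candidates)) cand else
      .dedupProfiles(cbind(candidates, cand), config$dedupCosine)
    expo <- fitExposures(X[, active, drop = FALSE], candidates)
    cosv <- attr(expo, "cosine")
    well <- names(cosv)[cosv >= config$hierarchyCosine]
    if (config$mode == "remove") {
      nxt <- setdiff(active, well)
      if (length(nxt) < config$minSamples || length(nxt) == length(active))
        break
      active <- nxt
    } else {
      if (!length(setdiff(active, well))) break
      X[, well] <- round(X[, well, drop = FALSE] * config$downweightFactor)
    }
  }
  colnames(candidates) <- paste0("C", seq_len(ncol(candidates)))
  exposures <- fitExposures(X0, candidates)
  scheme <- if (is(x, "MutationSpectra")) channelScheme(x) else
    if (nrow(X0) == 96) 0 else 4
  out <- new("SignatureSet", profiles = candidates, exposures = exposures,
             matches = data.frame(), scheme = as.numeric(scheme))
  attr(out, "iterations") <- itRun
  out
}

#' Match candidate signatures against a reference catalog and name them
#'
#' Cosine similarities are computed on the 96 trinucleotide channels only.
#' Every catalog entry is assigned its best-matching candidate - by the
#' combined score `w * spectrum-cosine + (1 - w) * exposure-cosine` - among
#' candidates with spectrum cosine at or above the match threshold. A
#' candidate's name lists the catalog ids assigned to it in decreasing
#' cosine order (e.g. `SBS26/12L`), with suffix `"L"` ("like") when the
#' primary cosine is below 0.95. Candidates matching nothing at the
#' threshold but something at 0.8 are kept unnamed (`unassigned`);
#' candidates below 0.8 to every catalog entry become novel cell-line
#' signatures `SBS-CL1..n`.
#'
#' @param x A [SignatureSet-class] or channels x candidates profile matrix.
#' @param catalog Channels x signatures reference catalog (e.g. from
#'   [readSignatureCatalog()]).
#' @param w Weight of the spectrum cosine in the combined score (default
#'   0.9); forced to 1 when exposure profiles are unavailable.
#' @param candidateExposures,catalogExposures Optional per-tissue mean
#'   exposure profiles (tissues x signatures) used for the exposure cosine.
#' @param matchThreshold Assignment threshold (default 0.85).
#' @param novelBelow Threshold under which a candidate is novel (default 0.8).
#' @param strongMatch Cosine at or above which the `"L"` suffix is dropped
#'   (default 0.95).
#' @return When `x` is a `SignatureSet`: the set with populated `matches`
#'   and renamed profiles/exposures. Otherwise the match record data.frame.
#' @export
matchAndName <- function(x, catalog, w = 0.9, candidateExposures = NULL,
                         catalogExposures = NULL, matchThreshold = 0.85,
                         novelBelow = 0.8, strongMatch = 0.95) {
  P <- if (is(x, "SignatureSet")) signatureProfiles(x) else as.matrix(x)
  nCand <- ncol(P)
  if (is.null(catalog) || ncol(catalog) == 0) {
    rec <- data.frame(candidate = colnames(P),
                      name = paste0("SBS-CL", seq_len(nCand)),
                      ids = "", spectrumCosine = NA_real_,
                      exposureCosine = NA_real_, combined = NA_real_,
                      novel = TRUE, unassigned = FALSE,
                      stringsAsFactors = FALSE)
    return(.applyMatches(x, rec))
  }
  useExpo <- !is.null(candidateExposures) && !is.null(catalogExposures)
  if (!useExpo) w <- 1.0
  cs <- .snvCosine(P, catalog)              # candidates x catalog
  es <- matrix(0, nCand, ncol(catalog))
  if (useExpo) {
    common <- intersect(rownames(candidateExposures), rownames(catalogExposures))
    es <- .cosineMat(as.matrix(candidateExposures[common, , drop = FALSE]),
                     as.matrix(catalogExposures[common, , drop = FALSE]))
    es <- es[colnames(P), colnames(catalog), drop = FALSE]
  }
  combined <- w * cs + (1 - w) * es

  ## per catalog entry: best candidate by combined score among those with
  ## spectrum cosine >= threshold
  assigned <- rep(NA_integer_, ncol(catalog))
  for (j in seq_len(ncol(catalog))) {
    ok <- which(cs[, j] >= matchThreshold)
    if (length(ok)) assigned[j] <- ok[which.max(combined[ok, j])]
  }

  rec <- data.frame(candidate = colnames(P), name = NA_character_, ids = "",
                    spectrumCosine = apply(cs, 1, max),
                    exposureCosine = if (useExpo) apply(es, 1, max) else NA_real_,
                    combined = apply(combined, 1, max),
                    novel = FALSE, unassigned = FALSE, stringsAsFactors = FALSE)
  clN <- 0
  for (i in seq_len(nCand)) {
    ids <- colnames(catalog)[which(assigned == i)]
    if (length(ids)) {
      o <- order(cs[i, ids], decreasing = TRUE)
      ids <- ids[o]
      primaryCos <- cs[i, ids[1]]
      nm <- ids[1]
      if (length(ids) > 1)
        nm <- paste(c(nm, sub("^SBS", "", ids[-1])), collapse = "/")
      if (primaryCos < strongMatch) nm <- paste0(nm, "L")
      rec$name[i] <- nm
      rec$ids[i] <- paste(ids, collapse = ",")
      rec$spectrumCosine[i] <- primaryCos
      rec$combined[i] <- combined[i, ids[1]]
    } else if (max(cs[i, ]) >= novelBelow) {
      rec$unassigned[i] <- TRUE
      rec$name[i] <- colnames(P)[i]
    } else {
      clN <- clN + 1
      rec$novel[i] <- TRUE
      rec$name[i] <- paste0("SBS-CL", clN)
    }
  }
  rec$name <- make.unique(rec$name, sep = "_")
  .applyMatches(x, rec)
}

.applyMatches <- function(x, rec) {
  if (!is(x, "SignatureSet")) return(rec)
  colnames(x@profiles) <- rec$name
  if (length(x@exposures)) rownames(x@exposures) <- rec$name
  x@matches <- rec
  x
}

#' Binarize and normalize signature exposures
#'
#' Per signature, the binarization threshold is `fraction` times the
#' second-highest exposure across samples (robust to single high-score
#' outliers); samples at or above the threshold (and strictly positive) are
#' 1. Relative exposures are per-sample normalized to sum 1.
#'
#' @param exposures Signatures x samples matrix (or a
#'   [SignatureSet-class]).
#' @param fraction Threshold fraction (default 0.05).
#' @return List: `binary` (samples x signatures 0/1 matrix),
#'   `relative` (samples x signatures, rows sum to 1), `thresholds`.
#' @export
binarizeExposures <- function(exposures, fraction = 0.05) {
  E <- if (is(exposures, "SignatureSet")) signatureExposures(exposures)
       else as.matrix(exposures)
  if (any(E < 0)) stop("exposures must be non-negative")
  tE <- t(E)                                # samples x signatures
  thr <- apply(tE, 2, function(v) {
    if (length(v) < 2) return(Inf)
    fraction * sort(v, decreasing = TRUE)[2]
  })
  B <- sweep(tE, 2, thr, `>=`) & tE > 0
  storage.mode(B) <- "double"
  low <- colSums(B) < 2
  if (any(low)) {
    warning(sum(low), " signature(s) with <2 positive samples: binary column zeroed")
    B[, low] <- 0
  }
  rs <- rowSums(tE); rs[rs == 0] <- 1
  list(binary = B, relative = tE / rs, thresholds = thr)
}

#' Read a COSMIC-style SBS signature catalog
#'
#' Expects a TSV with a `Type` column of channel keys (`"A[C>A]A"`) and one
#' column per signature; rows are reordered to the canonical channel order.
#'
#' @param path TSV path.
#' @return 96 x signatures numeric matrix.
#' @export
readSignatureCatalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  typeCol <- if ("Type" %in% names(df)) "Type" else names(df)[1]
  m <- as.matrix(df[, setdiff(names(df), typeCol), drop = FALSE])
  rownames(m) <- df[[typeCol]]
  miss <- setdiff(snvChannelNames(), rownames(m))
  if (length(miss)) stop("catalog is missing channels, e.g. ", miss[1])
  m[snvChannelNames(), , drop = FALSE]
}

#' @rdname readSignatureCatalog
#' @param catalog Channels x signatures matrix.
#' @export
writeSignatureCatalog <- function(catalog, path) {
  df <- data.frame(Type = rownames(catalog),
                   as.data.frame(catalog, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
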
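## Marker-drug association screening with two-dataset replication.
##
## Every binary marker (binarized signature exposure, driver mutation, CNA,
## methylation, ...) is tested against each drug response within a tissue,
## requiring the effect to replicate in a second dataset: another drug
## screen, another drug with the same molecular target, or the CRISPR
## knockout of the drug's target gene. The association score is the weaker
## of the two Cohen's d values (min for sensitivity, max for resistance);
## its significance is assessed by shuffling marker labels - jointly across
## the paired datasets, which preserves any cross-dataset response
## correlation under the null - and p-values are adjusted per
## tissue x direction x flavor with Storey q-values.

#' Association test policy
#'
#' @param minSamples Minimum cell lines per tissue test (default 8).
#' @param minPositive Minimum marker-positive (and negative) lines (default 2).
#' @param effectGate Primary-test |d| below which the randomization p is not
#'   computed (default 0.2).
#' @param nRandomizations Label shuffles per test (default 100000; use a few
#'   thousand for desk-scale work).
#' @param fdrThreshold Significance FDR (default 0.15).
#' @param dThreshold Effect-size threshold required in both datasets
#'   (default 0.5).
#' @param dThresholdSameTarget Same-target flavor threshold (default 1.0).
#' @param lambdaCap Tissue inflation cap; tissues above it are excluded from
#'   the significant set (default 1.3).
#' @param permissiveP Permissive nominal p threshold (default 0.005).
#' @param relaxedFdr FDR used by the tier rules (default 0.25).
#' @return Classed list of policy values.
#' @export
testPolicy <- function(minSamples = 8, minPositive = 2, effectGate = 0.2,
                       nRandomizations = 100000, fdrThreshold = 0.15,
                       dThreshold = 0.5, dThresholdSameTarget = 1.0,
                       lambdaCap = 1.3, permissiveP = 0.005,
                       relaxedFdr = 0.25) {
  stopifnot(minSamples > 0, minPositive > 0, effectGate > 0,
            nRandomizations > 0, fdrThreshold > 0, dThreshold > 0,
            lambdaCap > 0, permissiveP > 0)
  structure(list(minSamples = minSamples, minPositive = minPositive,
                 effectGate = effectGate, nRandomizations = nRandomizations,
                 fdrThreshold = fdrThreshold, dThreshold = dThreshold,
                 dThresholdSameTarget = dThresholdSameTarget,
                 lambdaCap = lambdaCap, permissiveP = permissiveP,
                 relaxedFdr = relaxedFdr),
            class = "sigmark_test_policy")
}

#' Cohen's d between marker-positive and marker-negative groups
#'
#' `d = (mean(neg) - mean(pos)) / s_pooled`, so that positive d means the
#' marker-positive group has lower response values - sensitivity, under the
#' ln IC50 convention.
#'
#' @param pos,neg Response values of the two groups.
#' @return Cohen's d; `NA` with a warning when the pooled SD is zero.
#' @export
cohenD <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  n1 <- length(pos); n2 <- length(neg)
  if (n1 < 1 || n2 < 1) return(NA_real_)
  v1 <- if (n1 > 1) var(pos) else 0
  v2 <- if (n2 > 1) var(neg) else 0
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / max(n1 + n2 - 2, 1)
  if (sp2 <= 0) {
    warning("zero pooled standard deviation: d undefined")
    return(NA_real_)
  }
  (mean(neg) - mean(pos)) / sqrt(sp2)
}

#' Two-way replication score
#'
#' The weaker of the two effects: minimum of the two Cohen's d for
#' sensitivity, maximum for resistance.
#'
#' @param dPrimary,dSecondary Cohen's d in the two datasets.
#' @param direction `"sensitivity"` or `"resistance"`.
#' @return The score.
#' @export
twoWayScore <- function(dPrimary, dSecondary,
                        direction = c("sensitivity", "resistance")) {
  direction <- match.arg(direction)
  if (direction == "sensitivity") pmin(dPrimary, dSecondary)
  else pmax(dPrimary, dSecondary)
}

#' Randomization p-value for a single two-way test
#'
#' Shuffles the marker jointly across both response vectors and computes the
#' fraction of shuffled scores at least as extreme as the observed score
#' (`>=` for sensitivity, `<=` for resistance). With `method = "exact"` all
#' distinct arrangements of the marker labels are enumerated instead
#' (feasible for small n), giving the exact permutation p-value.
#'
#' @param y1,y2 Response vectors over the same samples.
#' @param marker Binary marker vector.
#' @param direction `"sensitivity"` or `"resistance"`.
#' @param nRandomizations Monte-Carlo shuffles (default 10000).
#' @param method `"montecarlo"` or `"exact"`.
#' @param seed Integer seed.
#' @return List: `p`, `score`, `d1`, `d2`, `nArrangements` (exact mode).
#' @export
randomizationPvalue <- function(y1, y2, marker,
                                direction = c("sensitivity", "resistance"),
                                nRandomizations = 10000,
                                method = c("montecarlo", "exact"), seed = 1) {
  direction <- match.arg(direction); method <- match.arg(method)
  marker <- as.numeric(marker)
  n <- length(marker)
  stopifnot(length(y1) == n, length(y2) == n)
  k <- sum(marker == 1)
  if (k == 0 || k == n) stop("constant marker is untestable")
  dOf <- function(m) c(cohenD(y1[m == 1], y1[m == 0]),
                       cohenD(y2[m == 1], y2[m == 0]))
  obs <- dOf(marker)
  score <- twoWayScore(obs[1], obs[2], direction)
  cmp <- if (direction == "sensitivity") `>=` else `<=`
  if (method == "exact") {
    sets <- utils::combn(n, k)
    sc <- apply(sets, 2, function(ix) {
      m <- numeric(n); m[ix] <- 1
      d <- dOf(m); twoWayScore(d[1], d[2], direction)
    })
    p <- mean(cmp(sc, score))
    return(list(p = p, score = score, d1 = obs[1], d2 = obs[2],
                nArrangements = ncol(sets)))
  }
  .withSeed(seed, {
    P <- .perm_index_matrix(n, as.integer(nRandomizations))
    sc <- vapply(seq_len(nRandomizations), function(b) {
      m <- marker[P[, b]]
      d <- dOf(m); twoWayScore(d[1], d[2], direction)
    }, numeric(1))
    list(p = mean(cmp(sc, score), na.rm = TRUE), score = score,
         d1 = obs[1], d2 = obs[2], nArrangements = NA_integer_)
  })
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 by the smoother method (mean fraction
#' of p-values above each lambda in a grid, smoothed with a cubic spline and
#' evaluated at the largest lambda) and returns `pi0 * BH` q-values, which
#' are monotone in p-rank. Fewer than 10 p-values fall back to pi0 = 1.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param lambdaGrid Grid for pi0 estimation (default 0.05..0.90).
#' @param pFloor Floor applied to zero p-values before adjustment (default
#'   NULL: none).
#' @return q-values; `attr(, "pi0")` carries the pi0 estimate.
#' @export
storeyQvalues <- function(p, lambdaGrid = seq(0.05, 0.9, by = 0.05),
                          pFloor = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p0 <- p
  if (!is.null(pFloor)) p0 <- pmax(p0, pFloor)
  ok <- !is.na(p0)
  n <- sum(ok)
  if (n == 0) return(p)
  if (n < 10) {
    warning("fewer than 10 p-values: pi0 fixed at 1 (BH fallback)")
    pi0 <- 1
  } else {
    piL <- vapply(lambdaGrid, function(l) mean(p0[ok] > l) / (1 - l), numeric(1))
    fit <- try(smooth.spline(lambdaGrid, piL, df = 3), silent = TRUE)
    pi0 <- if (inherits(fit, "try-error")) min(piL)
           else predict(fit, x = max(lambdaGrid))$y
    pi0 <- min(max(pi0, 1e-3), 1)
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- pmin(pi0 * p.adjust(p0[ok], method = "BH"), 1)
  attr(q, "pi0") <- pi0
  q
}

#' Genomic inflation factor of a p-value set
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; 1 for calibrated
#' p-values, above 1 for inflation. Zero p-values are floored at
#' `1 / (2 * nRandomizations)`.
#'
#' @param p Numeric p-values.
#' @param nRandomizations Randomization count used to floor p = 0 (default
#'   1e5).
#' @return The inflation factor lambda.
#' @export
inflationLambda <- function(p, nRandomizations = 1e5) {
  p <- p[!is.na(p)]
  if (length(p) < 1) return(NA_real_)
  p <- pmax(pmin(p, 1), 1 / (2 * nRandomizations))
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}

#' Preprocess a screen bundle before association testing
#'
#' Applies a sample blocklist, removes per-tissue mutation-burden outliers
#' (burden above `UQ + 3 IQR` or below `LQ - 3 IQR`, using
#' `sampleInfo$burden`), merges tissues, and optionally splits tissues by
#' microsatellite-instability status (`sampleInfo$msi`, logical).
#'
#' @param bundle A [ScreenBundle-class].
#' @param blocklist Sample ids to drop.
#' @param tissueMerge Named character vector mapping old tissue levels to
#'   merged labels, e.g. `c(ESCA = "ESCA_STAD", STAD = "ESCA_STAD")`.
#' @param msiSplit Tissue levels to split into `_MSI` / `_MSS` strata.
#' @return The cleaned bundle.
#' @export
preprocessCohort <- function(bundle, blocklist = NULL, tissueMerge = NULL,
                             msiSplit = NULL) {
  keep <- rownames(bundle@primary)
  if (!is.null(blocklist)) keep <- setdiff(keep, blocklist)
  burden <- bundle@sampleInfo$burden
  if (!is.null(burden)) {
    names(burden) <- rownames(bundle@sampleInfo)
    for (t in levels(bundle@tissue)) {
      ids <- intersect(keep, names(bundle@tissue)[bundle@tissue == t])
      if (length(ids) < 4) next
      b <- burden[ids]
      qs <- quantile(b, c(0.25, 0.75), na.rm = TRUE)
      iqr <- qs[2] - qs[1]
      out <- ids[!is.na(b) & (b > qs[2] + 3 * iqr | b < qs[1] - 3 * iqr)]
      keep <- setdiff(keep, out)
    }
  }
  bundle <- .subsetBundle(bundle, keep)
  tl <- as.character(bundle@tissue)
  if (!is.null(tissueMerge)) {
    hit <- tl %in% names(tissueMerge)
    tl[hit] <- tissueMerge[tl[hit]]
  }
  if (!is.null(msiSplit) && !is.null(bundle@sampleInfo$msi)) {
    msi <- bundle@sampleInfo$msi
    hit <- tl %in% msiSplit
    tl[hit] <- paste0(tl[hit], ifelse(isTRUE(msi[hit]) | msi[hit] %in% TRUE,
                                      "_MSI", "_MSS"))
  }
  bundle@tissue <- factor(tl)
  names(bundle@tissue) <- rownames(bundle@primary)
  bundle
}

.subsetBundle <- function(bundle, ids) {
  sub <- function(m) if (length(m)) m[ids, , drop = FALSE] else m
  new("ScreenBundle", primary = sub(bundle@primary),
      secondary = sub(bundle@secondary), fitness = sub(bundle@fitness),
      markers = sub(bundle@markers),
      tissue = droplevels(bundle@tissue[ids]),
      drugInfo = bundle@drugInfo,
      sampleInfo = bundle@sampleInfo[ids, , drop = FALSE],
      groundTruth = bundle@groundTruth)
}

## Build the (response, partner) column pairing for a flavor.
.flavorPairs <- function(bundle, flavor) {
  di <- bundle@drugInfo
  if (flavor == "screen-replication") {
    drugs <- intersect(colnames(bundle@primary), colnames(bundle@secondary))
    data.frame(response = drugs, partner = drugs, stringsAsFactors = FALSE)
  } else if (flavor == "same-target") {
    out <- list()
    for (t in unique(di$targetId)) {
      d <- intersect(di$drug[di$targetId == t], colnames(bundle@primary))
      if (length(d) >= 2) {
        cmb <- utils::combn(d, 2)
        out[[t]] <- data.frame(response = cmb[1, ], partner = cmb[2, ],
                               stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) return(data.frame(response = character(0),
                                        partner = character(0)))
    do.call(rbind, out)
  } else if (flavor == "drug-vs-knockout") {
    ok <- di$drug %in% colnames(bundle@primary) &
      di$targetGene %in% colnames(bundle@fitness)
    data.frame(response = di$drug[ok], partner = di$targetGene[ok],
               stringsAsFactors = FALSE)
  } else stop("unknown flavor: ", flavor)
}

## Vectorized Cohen's d of a 0/1 group matrix S (n x B) against response
## columns Y (n x D), NA-aware. Returns a B x D matrix.
.dMatrix <- function(S, Y) {
  W <- !is.na(Y); Y0 <- Y; Y0[!W] <- 0
  kP <- crossprod(S, W)                 # positives with data, B x D
  sP <- crossprod(S, Y0)
  s2P <- crossprod(S, Y0^2)
  nTot <- matrix(colSums(W), nrow(kP), ncol(kP), byrow = TRUE)
  sTot <- matrix(colSums(Y0), nrow(kP), ncol(kP), byrow = TRUE)
  s2Tot <- matrix(colSums(Y0^2), nrow(kP), ncol(kP), byrow = TRUE)
  kN <- nTot - kP
  sN <- sTot - sP; s2N <- s2Tot - s2P
  bad <- kP < 1 | kN < 1
  kP[kP == 0] <- NA; kN[kN == 0] <- NA
  mP <- sP / kP; mN <- sN / kN
  vP <- (s2P - sP^2 / kP) / pmax(kP - 1, 1)
  vN <- (s2N - sN^2 / kN) / pmax(kN - 1, 1)
  sp2 <- ((kP - 1) * vP + (kN - 1) * vN) / pmax(kP + kN - 2, 1)
  d <- (mN - mP) / sqrt(sp2)
  d[bad | !is.finite(d)] <- NA
  d
}

#' Run the two-way replication association screen
#'
#' For every tissue with at least `minSamples` cell lines, every binary
#' marker and every response pairing of the chosen flavor: Cohen's d in both
#' datasets, the two-way score, a gated randomization p-value (marker labels
#' shuffled jointly across the paired datasets), Storey q-values per
#' tissue x direction, and the per-tissue inflation factor (computed with
#' ungated tests imputed at p = 0.5). Significance additionally requires the
#' flavor's effect-size threshold in both datasets and a tissue inflation
#' below the cap.
#'
#' @param bundle A [ScreenBundle-class].
#' @param policy A [testPolicy()].
#' @param flavor `"screen-replication"`, `"same-target"` or
#'   `"drug-vs-knockout"`.
#' @param seed Integer seed for the shuffles.
#' @return data.frame of association records (one per
#'   marker x pairing x tissue x direction that passed the size checks),
#'   with the per-tissue lambda table in `attr(, "lambda")`.
#' @export
runReplicationScreen <- function(bundle, policy = testPolicy(),
                                 flavor = c("screen-replication",
                                            "same-target",
                                            "drug-vs-knockout"),
                                 seed = 1) {
  flavor <- match.arg(flavor)
  pairs <- .flavorPairs(bundle, flavor)
  if (!nrow(pairs)) return(.emptyRecords())
  secondarySource <- switch(flavor,
    "screen-replication" = bundle@secondary,
    "same-target" = bundle@primary,
    "drug-vs-knockout" = bundle@fitness)
  dThr <- if (flavor == "same-target") policy$dThresholdSameTarget
          else policy$dThreshold
  B <- as.integer(policy$nRandomizations)
  markers <- bundle@markers
  recs <- list(); lam <- list()
  .withSeed(seed, {
    for (t in levels(bundle@tissue)) {
      ids <- names(bundle@tissue)[bundle@tissue == t]
      if (length(ids) < policy$minSamples) next
      Y1 <- bundle@primary[ids, pairs$response, drop = FALSE]
      Y2 <- secondarySource[ids, pairs$partner, drop = FALSE]
      M <- markers[ids, , drop = FALSE]
      n <- length(ids)
      nP <- nrow(pairs)
      complete <- !anyNA(Y1) && !anyNA(Y2)
      ## one row per marker x pairing; two directions stacked later
      d1M <- d2M <- pSM <- pRM <- matrix(NA_real_, ncol(M), nP)
      kV <- rep(NA_integer_, ncol(M))
      for (j in seq_len(ncol(M))) {
        m <- M[, j]
        if (anyNA(m)) next
        k <- sum(m == 1)
        if (k < policy$minPositive || n - k < policy$minPositive) next
        kV[j] <- k
        ## the permutation null is computed for every pairing (the
        ## vectorized engine gets it almost for free); the gate decides
        ## which p-values are reported, while the full set keeps the
        ## adjustment batch uniform under the null
        if (complete) {
          r <- .perm_two_way(m, Y1, Y2, B)
          d1M[j, ] <- r$d1; d2M[j, ] <- r$d2
          pSM[j, ] <- r$pSens; pRM[j, ] <- r$pRes
        } else {
          mM <- matrix(m, n, 1)
          d1 <- .dMatrix(mM, Y1)[1, ]; d2 <- .dMatrix(mM, Y2)[1, ]
          d1M[j, ] <- d1; d2M[j, ] <- d2
          okD <- !is.na(d1) & !is.na(d2)
          if (any(okD)) {
            P <- .perm_index_matrix(n, B)
            S <- matrix(m[P], n, B)
            D1 <- .dMatrix(S, Y1); D2 <- .dMatrix(S, Y2)
            obsS <- pmin(d1, d2); SCs <- pmin(D1, D2)
            obsR <- pmax(d1, d2); SCr <- pmax(D1, D2)
            pSM[j, okD] <- vapply(which(okD), function(i)
              mean(SCs[, i] >= obsS[i], na.rm = TRUE), numeric(1))
            pRM[j, okD] <- vapply(which(okD), function(i)
              mean(SCr[, i] <= obsR[i], na.rm = TRUE), numeric(1))
          }
        }
      }
      use <- which(!is.na(kV))
      if (!length(use)) next
      nm <- length(use)
      d1v <- as.vector(t(d1M[use, , drop = FALSE]))
      d2v <- as.vector(t(d2M[use, , drop = FALSE]))
      sens <- !is.na(d1v) & d1v > policy$effectGate
      res <- !is.na(d1v) & d1v < -policy$effectGate
      tr <- data.frame(
        marker = rep(rep(colnames(M)[use], each = nP), 2),
        response = rep(pairs$response, 2 * nm),
        partner = rep(pairs$partner, 2 * nm),
        tissue = t, flavor = flavor,
        direction = rep(c("sensitivity", "resistance"), each = nm * nP),
        d_primary = c(d1v, d1v), d_secondary = c(d2v, d2v),
        score = c(pmin(d1v, d2v), pmax(d1v, d2v)),
        p = c(as.vector(t(pSM[use, , drop = FALSE])),
              as.vector(t(pRM[use, , drop = FALSE]))),
        n_pos = rep(rep(kV[use], each = nP), 2),
        n_neg = n - rep(rep(kV[use], each = nP), 2),
        tested = c(sens, res), stringsAsFactors = FALSE)
      tr$q <- NA_real_
      for (dir in c("sensitivity", "resistance")) {
        sel <- tr$direction == dir
        pAll <- tr$p[sel]
        lamVal <- inflationLambda(pAll, policy$nRandomizations)
        lam[[length(lam) + 1]] <- data.frame(
          tissue = t, flavor = flavor, direction = dir, lambda = lamVal,
          nTested = sum(sel & tr$tested), stringsAsFactors = FALSE)
        comp <- sel & !is.na(tr$p)
        if (any(comp)) {
          ## add-one Monte-Carlo correction for the adjustment batch: a
          ## reported p of 0 only certifies p < ~1/B, and tied zero
          ## p-values would otherwise gain spurious BH rank
          pQ <- (tr$p[comp] * policy$nRandomizations + 1) /
            (policy$nRandomizations + 1)
          tr$q[comp] <- storeyQvalues(pQ)
        }
        tr$lambda[sel] <- lamVal
      }
      ## sub-gate tests are reported untested: p and q masked
      tr$p[!tr$tested] <- NA_real_
      tr$q[!tr$tested] <- NA_real_
      recs[[length(recs) + 1]] <- tr
    }
  })
  if (!length(recs)) return(.emptyRecords())
  out <- do.call(rbind, recs)
  sgn <- ifelse(out$direction == "sensitivity", 1, -1)
  bothStrong <- sgn * out$d_primary > dThr & sgn * out$d_secondary > dThr
  both05 <- sgn * out$d_primary > 0.5 & sgn * out$d_secondary > 0.5
  out$lambdaOk <- out$lambda <= policy$lambdaCap
  out$significant <- !is.na(out$q) & out$q < policy$fdrThreshold &
    bothStrong & out$lambdaOk
  out$permissive <- !is.na(out$p) & out$p < policy$permissiveP & both05
  rownames(out) <- NULL
  attr(out, "lambda") <- do.call(rbind, lam)
  out
}

.emptyRecords <- function() {
  out <- data.frame(marker = character(0), response = character(0),
                    partner = character(0), tissue = character(0),
                    flavor = character(0), direction = character(0),
                    d_primary = numeric(0), d_secondary = numeric(0),
                    score = numeric(0), p = numeric(0), n_pos = integer(0),
                    n_neg = integer(0), tested = logical(0), q = numeric(0),
                    lambda = numeric(0), lambdaOk = logical(0),
                    significant = logical(0), permissive = logical(0))
  attr(out, "lambda") <- data.frame(tissue = character(0),
                                    flavor = character(0),
                                    direction = character(0),
                                    lambda = numeric(0), nTested = integer(0))
  out
}

#' Aggregate signature groups into pooled association records
#'
#' For signature groups known to reflect one process (e.g. the
#' C-to-T-rich mismatch-repair signatures), member records sharing a
#' response x tissue x flavor x direction are pooled: Fisher's method on the
#' p-values (chi-square with 2k df) and the mean of the member effect sizes;
#' q-values are re-adjusted over the pooled batch.
#'
#' @param records Output of [runReplicationScreen()].
#' @param groups Named list of member marker vectors, e.g.
#'   `list("SBS-MMR1" = c("SBS6", "SBS15", "SBS44L"))`.
#' @return data.frame of pooled records.
#' @export
aggregateSignatureGroups <- function(records, groups) {
  out <- list()
  for (g in names(groups)) {
    sub <- records[records$marker %in% groups[[g]] & !is.na(records$p), ,
                   drop = FALSE]
    if (!nrow(sub)) next
    key <- interaction(sub$response, sub$tissue, sub$flavor, sub$direction,
                       drop = TRUE)
    for (lev in levels(key)) {
      s <- sub[key == lev, , drop = FALSE]
      X <- -2 * sum(log(pmax(s$p, 1e-300)))
      pooledP <- pchisq(X, df = 2 * nrow(s), lower.tail = FALSE)
      out[[length(out) + 1]] <- data.frame(
        marker = g, response = s$response[1], partner = s$partner[1],
        tissue = s$tissue[1], flavor = s$flavor[1],
        direction = s$direction[1],
        d_primary = mean(s$d_primary), d_secondary = mean(s$d_secondary),
        score = mean(s$score), p = pooledP, nMembers = nrow(s),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  pooled <- do.call(rbind, out)
  pooled$q <- NA_real_
  key <- interaction(pooled$tissue, pooled$flavor, pooled$direction,
                     drop = TRUE)
  for (lev in levels(key)) {
    sel <- key == lev
    pooled$q[sel] <- storeyQvalues(pooled$p[sel])
  }
  pooled
}

#' Curate silver and golden association tiers
#'
#' Over (marker, response, direction) groups of permissive records: a group
#' is silver when it recurs in more than one replication flavor or more than
#' one tissue, with at least one member under the relaxed FDR; golden when
#' it recurs in at least three tissues or in all three flavors, again with
#' one member under the relaxed FDR.
#'
#' @param records Output of [runReplicationScreen()] (possibly several
#'   flavors row-bound).
#' @param policy A [testPolicy()] (for the relaxed FDR, default 0.25).
#' @return `records` with logical `silver` and `golden` columns added.
#' @export
curateTiers <- function(records, policy = testPolicy()) {
  records$silver <- FALSE
  records$golden <- FALSE
  perm <- which(records$permissive)
  if (!length(perm)) return(records)
  key <- paste(records$marker, records$response, records$direction,
               sep = "\r")
  for (kk in unique(key[perm])) {
    g <- perm[key[perm] == kk]
    nFlav <- length(unique(records$flavor[g]))
    nTis <- length(unique(records$tissue[g]))
    anyFdr <- any(!is.na(records$q[g]) & records$q[g] < policy$relaxedFdr)
    if (!anyFdr) next
    if (nFlav > 1 || nTis > 1) records$silver[g] <- TRUE
    if (nTis >= 3 || nFlav >= 3) {
      records$silver[g] <- TRUE
      records$golden[g] <- TRUE
    }
  }
  records
}

#' Write association records to TSV
#' @param records Association data.frame.
#' @param path Output path.
#' @export
writeAssociations <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
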
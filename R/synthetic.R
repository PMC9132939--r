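## Synthetic cohort generator.
##
## Emulates the data a cell-line panel study would start from, with known
## ground truth: (i) population-structured common variants (Balding-Nichols
## allele frequencies) for ancestry inference; (ii) residual germline
## rare-variant calls whose trinucleotide spectrum differs between
## populations; (iii) somatic calls drawn from known signature mixtures;
## (iv) drug / CRISPR screens with planted marker effects.

#' Simulate a population-structured common-variant genotype matrix
#'
#' Allele frequencies follow the Balding-Nichols scheme: each variant has an
#' ancestral frequency drawn uniformly on (0.05, 0.5) and each population's
#' frequency is Beta-distributed around it with spread set by that
#' population's F_st. Genotypes are binomial(2) draws.
#'
#' @param model A [PopulationModel-class].
#' @param nSamples Number of samples (>= number of populations).
#' @param seed Integer seed.
#' @return List with `genotypes` (samples x variants, values 0/1/2) and
#'   `labels` (integer population of each sample; for evaluation only).
#' @export
simulatePopulation <- function(model, nSamples, seed = NULL) {
  if (nSamples < model@nPopulations || nSamples < 1)
    stop("invalid configuration: need nSamples >= nPopulations >= 1")
  .withSeed(seed, {
    L <- model@nCommonVariants
    pAnc <- runif(L, 0.05, 0.5)
    labels <- sort(rep_len(seq_len(model@nPopulations), nSamples))
    G <- matrix(0L, nSamples, L,
                dimnames = list(paste0("S", seq_len(nSamples)),
                                paste0("V", seq_len(L))))
    for (k in seq_len(model@nPopulations)) {
      F <- model@fst[k]
      pk <- if (F > 0)
        rbeta(L, pAnc * (1 - F) / F, (1 - pAnc) * (1 - F) / F)
      else pAnc
      idx <- which(labels == k)
      G[idx, ] <- matrix(rbinom(length(idx) * L, 2L, rep(pk, each = length(idx))),
                         length(idx), L)
    }
    list(genotypes = G, labels = labels)
  })
}

#' @importFrom stats rbeta
NULL

#' Simulate residual germline variant calls
#'
#' Each sample receives, in expectation, `germlineBurden` calls that survive
#' database MAF filtering, split between population-recurrent loci
#' (`sharedFraction`; fixed channel per locus, carrier frequencies uniform on
#' 0.1-0.6, so the cohort-frequency filter removes them) and quasi-private
#' rare calls. On top of that, a further block of calls carries database MAF
#' annotations above the usual filtering threshold
#' (`annotatedFraction` of all generated calls), exercising the MAF filter.
#' Channels are drawn from each population's biased 96-channel distribution.
#'
#' @param model A [PopulationModel-class].
#' @param labels Integer population label per sample (from
#'   [simulatePopulation()]).
#' @param seed Integer seed.
#' @param sampleNames Optional sample ids (default `S1..Sn`).
#' @return Call data.frame (columns sample, kind, channel, maf, locus).
#' @export
simulateGermlineCalls <- function(model, labels, seed = NULL,
                                  sampleNames = NULL) {
  if (any(!labels %in% seq_len(model@nPopulations)))
    stop("unknown population label")
  n <- length(labels)
  if (is.null(sampleNames)) sampleNames <- paste0("S", seq_len(n))
  if (model@germlineBurden == 0) return(.emptyCalls())
  .withSeed(seed, {
    dist <- .popChannelDist(model)
    chan <- snvChannelNames()
    out <- vector("list", 3 * model@nPopulations)
    oi <- 0
    for (k in seq_len(model@nPopulations)) {
      idx <- which(labels == k)
      if (!length(idx)) next
      nk <- length(idx)
      pk <- dist[k, ]

      ## population-recurrent loci (later removed by the cohort filter)
      meanF <- 0.35
      Lc <- round(model@germlineBurden * model@sharedFraction / meanF)
      if (Lc > 0) {
        f <- runif(Lc, 0.1, 0.6)
        lchan <- sample(chan, Lc, replace = TRUE, prob = pk)
        hit <- which(matrix(runif(nk * Lc), nk, Lc) <
                       matrix(f, nk, Lc, byrow = TRUE))
        si <- ((hit - 1L) %% nk) + 1L
        li <- ((hit - 1L) %/% nk) + 1L
        oi <- oi + 1
        out[[oi]] <- data.frame(
          sample = sampleNames[idx[si]], kind = "SNV", channel = lchan[li],
          maf = NA_real_, locus = paste0("C", k, "_", li),
          stringsAsFactors = FALSE)
      }

      ## quasi-private rare calls (survive both filters)
      nr <- rpois(nk, model@germlineBurden * (1 - model@sharedFraction))
      tot <- sum(nr)
      if (tot > 0) {
        oi <- oi + 1
        out[[oi]] <- data.frame(
          sample = rep(sampleNames[idx], nr), kind = "SNV",
          channel = sample(chan, tot, replace = TRUE, prob = pk),
          maf = NA_real_, locus = paste0("R", k, "_", seq_len(tot)),
          stringsAsFactors = FALSE)
      }

      ## database-annotated calls (removed by the MAF filter)
      aRate <- model@germlineBurden * model@annotatedFraction /
        (1 - model@annotatedFraction)
      na <- rpois(nk, aRate)
      tot <- sum(na)
      if (tot > 0) {
        oi <- oi + 1
        out[[oi]] <- data.frame(
          sample = rep(sampleNames[idx], na), kind = "SNV",
          channel = sample(chan, tot, replace = TRUE, prob = pk),
          maf = 10^runif(tot, -4, -0.31), locus = paste0("A", k, "_", seq_len(tot)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out[seq_len(oi)])
  })
}

#' Generate synthetic signature profiles
#'
#' Draws `nSignatures` sparse channel distributions (Dirichlet weights on a
#' small random support each), resampling until all pairwise cosine
#' similarities are below `maxCosine` so the planted processes are
#' distinguishable. The last signature is given extra indel-channel mass when
#' the scheme has indel channels, mimicking indel-rich processes.
#'
#' @param nSignatures Number of signatures (default 5).
#' @param scheme Indel channel scheme (default 4).
#' @param supportSize Channels in each signature's support (default 12).
#' @param maxCosine Maximum allowed pairwise cosine (default 0.25).
#' @param seed Integer seed.
#' @return Channels x signatures matrix with columns `SYN1..SYNn`, each
#'   summing to 1.
#' @export
syntheticSignatures <- function(nSignatures = 5, scheme = 4, supportSize = 12,
                                maxCosine = 0.25, seed = NULL) {
  .withSeed(seed, {
    chan <- channelNames(scheme)
    nC <- length(chan)
    draw <- function() {
      p <- numeric(nC)
      sup <- sample(96, supportSize)
      w <- rgamma(supportSize, 1)
      p[sup] <- w / sum(w)
      p
    }
    P <- matrix(0, nC, nSignatures, dimnames = list(chan, paste0("SYN", seq_len(nSignatures))))
    for (j in seq_len(nSignatures)) {
      for (try in 1:200) {
        p <- draw()
        if (j == 1 || max(.cosineMat(P[, seq_len(j - 1), drop = FALSE],
                                     matrix(p))) < maxCosine) break
      }
      P[, j] <- p
    }
    if (nC > 96) {
      ## indel-rich last signature
      P[, nSignatures] <- 0.8 * P[, nSignatures]
      P[96 + seq_len(nC - 96), nSignatures] <- 0.2 / (nC - 96)
    }
    P
  })
}

#' @importFrom stats rgamma
NULL

#' Draw sparse per-sample signature exposures
#'
#' Each sample is active for a random subset of signatures (1 to
#' `maxActive`), with Dirichlet weights scaled to `totalPerSample` expected
#' mutations.
#'
#' @param nSamples,nSignatures Dimensions.
#' @param totalPerSample Expected mutation count per sample (default 300).
#' @param maxActive Maximum active signatures per sample (default 3).
#' @param seed Integer seed.
#' @return Samples x signatures non-negative matrix.
#' @export
syntheticExposures <- function(nSamples, nSignatures, totalPerSample = 300,
                               maxActive = 3, seed = NULL) {
  .withSeed(seed, {
    E <- matrix(0, nSamples, nSignatures,
                dimnames = list(paste0("S", seq_len(nSamples)),
                                paste0("SYN", seq_len(nSignatures))))
    for (i in seq_len(nSamples)) {
      k <- sample(seq_len(min(maxActive, nSignatures)), 1)
      act <- sample(nSignatures, k)
      w <- rgamma(k, 1.5)
      E[i, act] <- w / sum(w) * totalPerSample
    }
    E
  })
}

#' Simulate somatic mutation calls from signature mixtures
#'
#' Per-sample channel counts are multinomial with probability vector equal to
#' the exposure-weighted mixture of signature profiles; the per-sample total
#' is the (rounded) sum of that sample's exposures.
#'
#' @param profiles Channels x signatures matrix of signature profiles.
#' @param exposures Samples x signatures non-negative weights (expected
#'   mutation counts).
#' @param seed Integer seed.
#' @return Call data.frame.
#' @export
simulateSomaticCalls <- function(profiles, exposures, seed = NULL) {
  if (any(exposures < 0)) stop("exposures must be non-negative")
  stopifnot(ncol(profiles) == ncol(exposures))
  .withSeed(seed, {
    chan <- rownames(profiles)
    samples <- rownames(exposures)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(exposures)))
    out <- vector("list", nrow(exposures))
    for (i in seq_len(nrow(exposures))) {
      tot <- round(sum(exposures[i, ]))
      if (tot == 0) next
      mix <- as.vector(profiles %*% exposures[i, ])
      mix <- mix / sum(mix)
      cts <- rmultinom(1, tot, mix)[, 1]
      nz <- which(cts > 0)
      out[[i]] <- data.frame(
        sample = samples[i], kind = NA_character_,
        channel = rep(chan[nz], cts[nz]), maf = NA_real_, locus = NA_character_,
        stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(calls)) return(.emptyCalls())
    calls$kind <- ifelse(startsWith(calls$channel, "Del"), "deletion",
                         ifelse(startsWith(calls$channel, "Ins"), "insertion",
                                "SNV"))
    calls$locus <- paste0("M", seq_len(nrow(calls)))
    calls
  })
}

#' Compose observed cell-line call sets from somatic and germline calls
#'
#' Observed calls are the union of the two call sets; the returned ground
#' truth records the somatic-only spectra so downstream reconstruction can be
#' scored.
#'
#' @param germline,somatic Call data.frames over the same sample universe
#'   (one of the two may cover a subset only if `allowSubset`).
#' @param scheme Indel scheme for the truth spectra (default 4).
#' @param samples Sample universe; defaults to the union seen in either set.
#' @return List with `observed` (call data.frame) and `truth`
#'   (list: `spectra`, a [MutationSpectra-class] of somatic-only counts).
#' @export
composeCellLineCohort <- function(germline, somatic, scheme = 4,
                                  samples = NULL) {
  gs <- unique(as.character(germline$sample))
  ss <- unique(as.character(somatic$sample))
  if (is.null(samples)) samples <- sort(unique(c(gs, ss)))
  if (nrow(germline) && nrow(somatic) && !setequal(gs, ss))
    stop("sample universe mismatch between germline and somatic call sets")
  cols <- c("sample", "kind", "channel", "maf", "locus")
  observed <- rbind(germline[, cols], somatic[, cols])
  truth <- buildSpectrumMatrix(somatic, scheme = scheme, samples = samples)
  list(observed = observed, truth = truth)
}

#' Simulate drug and CRISPR screens with planted marker effects
#'
#' For every screen, `response = tissue mean + noise`, with planted effects
#' shifting marker-positive samples by `d * noiseSd` (downward for
#' sensitivity - positive Cohen's d under the ln IC50 convention - and upward
#' for resistance). The primary and replication screens share the planted
#' effects but have independent noise; the gene-fitness screen carries the
#' same effects on each affected drug's target gene. Drugs are assigned
#' target genes so that consecutive drug pairs share a target id, making all
#' three replication flavors testable.
#'
#' @param markers Sample x marker binary matrix.
#' @param tissues Factor of tissue labels (one per sample).
#' @param plantedEffects NULL, or data.frame with columns `marker`,
#'   `response` (drug name), `tissue` (`"all"` or a tissue level), `d`
#'   (absolute effect size) and `direction` (`"sensitivity"`/`"resistance"`).
#' @param nDrugs Number of drugs per screen (default 20).
#' @param noiseSd Response noise standard deviation (default 1).
#' @param drugsPerTarget Drugs sharing each target id (default 2).
#' @param seed Integer seed.
#' @return A [ScreenBundle-class].
#' @export
simulateScreens <- function(markers, tissues, plantedEffects = NULL,
                            nDrugs = 20, noiseSd = 1, drugsPerTarget = 2,
                            seed = NULL) {
  stopifnot(is.matrix(markers), nrow(markers) == length(tissues))
  if (!all(markers %in% c(0, 1))) stop("marker matrix must be binary")
  samples <- rownames(markers)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(markers)))
  tissues <- as.factor(tissues)
  names(tissues) <- samples
  if (!is.null(plantedEffects)) {
    if (!all(plantedEffects$marker %in% colnames(markers)))
      stop("planted effect names a marker absent from the marker matrix")
    drugs <- paste0("D", seq_len(nDrugs))
    if (!all(plantedEffects$response %in% drugs))
      stop("planted effect names a response column that does not exist")
  }
  .withSeed(seed, {
    n <- nrow(markers)
    drugs <- paste0("D", seq_len(nDrugs))
    targetId <- paste0("T", ceiling(seq_len(nDrugs) / drugsPerTarget))
    targetGene <- paste0("G", ceiling(seq_len(nDrugs) / drugsPerTarget))
    genes <- unique(targetGene)
    drugInfo <- data.frame(drug = drugs, targetGene = targetGene,
                           targetId = targetId, stringsAsFactors = FALSE)

    shift <- matrix(0, n, nDrugs, dimnames = list(samples, drugs))
    if (!is.null(plantedEffects) && nrow(plantedEffects)) {
      for (r in seq_len(nrow(plantedEffects))) {
        e <- plantedEffects[r, ]
        rows <- if (identical(e$tissue, "all")) seq_len(n)
                else which(as.character(tissues) == e$tissue)
        sgn <- if (identical(e$direction, "resistance")) 1 else -1
        m <- markers[rows, e$marker]
        shift[rows, e$response] <- shift[rows, e$response] +
          sgn * abs(e$d) * noiseSd * m
      }
    }
    geneShift <- matrix(0, n, length(genes), dimnames = list(samples, genes))
    for (j in seq_len(nDrugs)) {
      g <- targetGene[j]
      ## a gene inherits the planted effects of the drugs that target it
      geneShift[, g] <- geneShift[, g] + shift[, j] / drugsPerTarget
    }

    screen <- function(shiftMat) {
      cols <- colnames(shiftMat)
      mu <- matrix(rnorm(nlevels(tissues) * ncol(shiftMat)),
                   nlevels(tissues), ncol(shiftMat))
      base <- mu[as.integer(tissues), , drop = FALSE]
      out <- base + shiftMat +
        matrix(rnorm(n * ncol(shiftMat), sd = noiseSd), n, ncol(shiftMat))
      dimnames(out) <- list(samples, cols)
      out
    }
    primary <- screen(shift)
    secondary <- screen(shift)
    fitness <- screen(geneShift)

    gt <- if (is.null(plantedEffects)) list() else
      list(plantedEffects = plantedEffects)
    new("ScreenBundle", primary = primary, secondary = secondary,
        fitness = fitness, markers = markers, tissue = tissues,
        drugInfo = drugInfo,
        sampleInfo = data.frame(row.names = samples),
        groundTruth = gt)
  })
}

#' Random binary marker matrix
#'
#' @param nSamples,nMarkers Dimensions.
#' @param prevalenceRange Range of marker prevalences (default 0.15-0.5).
#' @param seed Integer seed.
#' @return Samples x markers 0/1 matrix.
#' @export
syntheticMarkers <- function(nSamples, nMarkers, prevalenceRange = c(0.15, 0.5),
                             seed = NULL) {
  .withSeed(seed, {
    prev <- runif(nMarkers, prevalenceRange[1], prevalenceRange[2])
    m <- matrix(rbinom(nSamples * nMarkers, 1, rep(prev, each = nSamples)),
                nSamples, nMarkers,
                dimnames = list(paste0("S", seq_len(nSamples)),
                                paste0("M", seq_len(nMarkers))))
    m
  })
}

#' Simulate a full cell-line cohort with ground truth
#'
#' End-to-end generator: population structure and genotypes for cell lines
#' plus a germline-only baseline panel (the matched-normal stand-in),
#' germline calls for everyone, signature-driven somatic calls for the cell
#' lines, and the composed observed call sets.
#'
#' @param model A [PopulationModel-class].
#' @param nCellLines,nBaseline Cohort sizes (default 500 / 300).
#' @param signatures Channels x signatures profile matrix (default
#'   [syntheticSignatures()] with 5 signatures).
#' @param somaticBurden Expected somatic mutations per cell line (default 300).
#' @param scheme Indel scheme (default 4).
#' @param seed Integer seed.
#' @return List: `genotypes` (all samples x variants), `batch` (factor,
#'   `cellline`/`baseline`), `labels` (true populations), `observedCalls`,
#'   `baselineCalls`, `truth` (somatic-only [MutationSpectra-class]),
#'   `exposures`, `signatures`, `cellLines` / `baselineSamples` (ids).
#' @export
simulateCohort <- function(model = populationModel(), nCellLines = 500,
                           nBaseline = 300, signatures = NULL,
                           somaticBurden = 300, scheme = 4, seed = 1) {
  if (is.null(signatures))
    signatures <- syntheticSignatures(5, scheme = scheme,
                                      seed = .subSeed(seed, 1))
  n <- nCellLines + nBaseline
  pop <- simulatePopulation(model, n, seed = .subSeed(seed, 2))
  ids <- rownames(pop$genotypes)
  ## deterministic interleave of cell lines and baseline samples, so both
  ## batches span every population
  i <- seq_len(n)
  isCell <- floor(i * nCellLines / n) > floor((i - 1) * nCellLines / n)
  batch <- factor(ifelse(isCell, "cellline", "baseline"),
                  levels = c("cellline", "baseline"))
  cellLines <- ids[batch == "cellline"]
  baseline <- ids[batch == "baseline"]

  germ <- simulateGermlineCalls(model, pop$labels, seed = .subSeed(seed, 3),
                                sampleNames = ids)
  germCell <- germ[germ$sample %in% cellLines, , drop = FALSE]
  germBase <- germ[germ$sample %in% baseline, , drop = FALSE]

  expo <- syntheticExposures(length(cellLines), ncol(signatures),
                             totalPerSample = somaticBurden,
                             seed = .subSeed(seed, 4))
  rownames(expo) <- cellLines
  som <- simulateSomaticCalls(signatures, expo, seed = .subSeed(seed, 5))
  comp <- composeCellLineCohort(germCell, som, scheme = scheme,
                                samples = cellLines)
  names(pop$labels) <- ids
  list(genotypes = pop$genotypes, batch = setNames(batch, ids),
       labels = pop$labels, observedCalls = comp$observed,
       baselineCalls = germBase, truth = comp$truth, exposures = expo,
       signatures = signatures, cellLines = cellLines,
       baselineSamples = baseline, model = model, scheme = scheme)
}
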
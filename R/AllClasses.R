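#' @import methods
#' @importFrom stats median prcomp quantile rbinom rmultinom rnorm runif rpois
#'   sd cor var complete.cases qchisq pchisq pf qtukey predict smooth.spline
#'   kmeans setNames p.adjust
#' @importFrom utils head read.delim write.table
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @useDynLib sigmark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MutationSpectra: per-sample mutation channel counts
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one `counts` assay with channels as rows (the 96 trinucleotide SNV channels
#' followed by the indel channel block) and samples as columns. The indel
#' scheme id is kept in `metadata(x)$scheme`.
#'
#' @slot .Data see `SummarizedExperiment`.
#' @export
setClass("MutationSpectra", contains = "SummarizedExperiment")

setValidity("MutationSpectra", function(object) {
  scheme <- S4Vectors::metadata(object)$scheme
  if (is.null(scheme)) return("metadata(object)$scheme missing")
  want <- channelNames(scheme)
  if (!identical(rownames(object), want))
    return("rownames do not match the channel keys of the declared scheme")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) return("negative channel counts")
  TRUE
})

#' Construct a MutationSpectra object
#'
#' @param counts Numeric matrix, either channels x samples or samples x
#'   channels (recognised by matching dimnames against the channel keys).
#' @param scheme Indel scheme id (0, 4, 5, 8, 14, 32).
#' @return A [MutationSpectra-class] object.
#' @export
MutationSpectra <- function(counts, scheme = 4) {
  want <- channelNames(scheme)
  if (!is.null(rownames(counts)) && identical(rownames(counts), want)) {
    m <- counts
  } else if (!is.null(colnames(counts)) &&
             all(want %in% colnames(counts))) {
    m <- t(counts[, want, drop = FALSE])
  } else if (nrow(counts) == length(want)) {
    m <- counts; rownames(m) <- want
  } else if (ncol(counts) == length(want)) {
    m <- t(counts); rownames(m) <- want
  } else stop("counts dimensions do not match scheme ", scheme)
  if (is.null(colnames(m)) && ncol(m) > 0)
    colnames(m) <- paste0("S", seq_len(ncol(m)))
  se <- SummarizedExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(
      class = ifelse(rownames(m) %in% snvChannelNames(), "SBS", "indel")),
    metadata = list(scheme = scheme))
  new("MutationSpectra", se)
}

#' @describeIn MutationSpectra channels x samples count matrix.
#' @param x A `MutationSpectra` object.
#' @export
spectrumCounts <- function(x) {
  if (is(x, "MutationSpectra")) SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' @describeIn MutationSpectra indel scheme id.
#' @export
channelScheme <- function(x) S4Vectors::metadata(x)$scheme

setMethod("show", "MutationSpectra", function(object) {
  cat("MutationSpectra:", ncol(object), "samples,",
      nrow(object), "channels (scheme",
      paste0(S4Vectors::metadata(object)$scheme, ")\n"))
  cat("  total counts per sample: median",
      median(colSums(SummarizedExperiment::assay(object))), "\n")
})

#' PopulationModel: generative model for structured germline variation
#'
#' Parameters of the synthetic cohort generator: the number of ancestral
#' subpopulations, their divergence (Balding-Nichols F_st per population), the
#' common-variant block used for ancestry inference, and the germline
#' rare-variant machinery (per-population channel bias over a shared
#' 96-channel baseline and the expected residual burden per sample).
#'
#' @slot nPopulations integer, number of subpopulations.
#' @slot fst numeric, divergence per population (0-0.5).
#' @slot nCommonVariants integer, size of the common-variant genotype block.
#' @slot germlineChannelBias matrix (populations x 96) of multiplicative
#'   enrichments over the shared baseline channel distribution.
#' @slot germlineBurden numeric, expected residual germline calls per sample
#'   (calls surviving the population-database MAF filter).
#' @slot baseline numeric(96), the shared baseline channel distribution.
#' @slot sharedFraction fraction of the residual burden drawn from
#'   population-recurrent loci (removed later by the cohort-frequency filter).
#' @slot annotatedFraction fraction of generated calls carrying a database
#'   MAF annotation above the filtering threshold.
#' @export
setClass("PopulationModel", representation(
  nPopulations = "integer", fst = "numeric", nCommonVariants = "integer",
  germlineChannelBias = "matrix", germlineBurden = "numeric",
  baseline = "numeric", sharedFraction = "numeric",
  annotatedFraction = "numeric"))

setValidity("PopulationModel", function(object) {
  if (object@nPopulations < 1) return("nPopulations must be >= 1")
  if (any(object@fst < 0)) return("fst must be >= 0")
  if (object@germlineBurden < 0) return("germlineBurden must be >= 0")
  if (any(object@germlineChannelBias <= 0)) return("channel bias must be > 0")
  if (nrow(object@germlineChannelBias) != object@nPopulations)
    return("one bias row per population required")
  p <- .popChannelDist(object)
  if (any(abs(rowSums(p) - 1) > 1e-8))
    return("population channel distributions must sum to 1")
  TRUE
})

## Populations x 96 channel distributions: bias applied to the shared
## baseline, renormalised.
.popChannelDist <- function(model) {
  p <- sweep(model@germlineChannelBias, 2, model@baseline, `*`)
  p / rowSums(p)
}

#' Construct a PopulationModel
#'
#' @param nPopulations Number of subpopulations (default 2).
#' @param fst Balding-Nichols divergence, recycled per population (default 0.2).
#' @param nCommonVariants Common variants used for ancestry PCs (default 2000).
#' @param germlineChannelBias Populations x 96 matrix of multiplicative
#'   channel enrichments, or NULL for the default contrast in which each
#'   population boosts its own disjoint block of 8 channels `biasFold`-fold.
#' @param biasFold Fold-enrichment used to build the default bias (default 3).
#' @param germlineBurden Expected residual germline calls per sample after
#'   database MAF filtering (default 3000).
#' @param baseline Shared 96-channel baseline distribution (default uniform).
#' @param sharedFraction Fraction of the burden from population-recurrent loci
#'   (default 0.98; chosen so that the residual unpredictable germline noise
#'   after ancestry matching sits in the near-floor regime reported for real
#'   cohorts).
#' @param annotatedFraction Fraction of generated calls annotated with a
#'   database MAF above the filtering cutoff (default 0.3).
#' @return A [PopulationModel-class] object.
#' @export
populationModel <- function(nPopulations = 2, fst = 0.2,
                            nCommonVariants = 2000,
                            germlineChannelBias = NULL, biasFold = 3,
                            germlineBurden = 3000, baseline = NULL,
                            sharedFraction = 0.98, annotatedFraction = 0.3) {
  if (nPopulations < 1 || nCommonVariants < 1)
    stop("invalid configuration: counts must be positive")
  if (is.null(baseline)) baseline <- rep(1 / 96, 96)
  if (is.null(germlineChannelBias)) {
    germlineChannelBias <- matrix(1, nPopulations, 96)
    for (k in seq_len(nPopulations)) {
      block <- ((k - 1) * 8 + 1):(k * 8)
      germlineChannelBias[k, block] <- biasFold
    }
  }
  new("PopulationModel", nPopulations = as.integer(nPopulations),
      fst = rep_len(fst, nPopulations),
      nCommonVariants = as.integer(nCommonVariants),
      germlineChannelBias = germlineChannelBias,
      germlineBurden = germlineBurden, baseline = baseline,
      sharedFraction = sharedFraction, annotatedFraction = annotatedFraction)
}

setMethod("show", "PopulationModel", function(object) {
  cat("PopulationModel:", object@nPopulations, "populations, fst =",
      paste(object@fst, collapse = "/"), "\n")
  cat("  ", object@nCommonVariants, "common variants;",
      object@germlineBurden, "residual germline calls/sample\n")
})

#' AncestryModel: ancestry clusters and germline baseline spectra
#'
#' The fitted ancestry-matching model: principal-component scores over common
#' germline variants, the indices of batch-associated components that were
#' pruned, trimmed k-means cluster assignments (with an `"outlier"` level) and
#' the per-cluster median germline spectrum used as the subtraction baseline.
#'
#' @slot scores sample x PC score matrix (all computed PCs).
#' @slot removedPCs integer indices of pruned batch-associated PCs.
#' @slot clusters factor of cluster assignments, level "outlier" for trimmed
#'   samples.
#' @slot centers cluster centroid matrix in retained-PC space.
#' @slot medianSpectra cluster x channel matrix of median germline spectra.
#' @slot k integer, number of clusters.
#' @export
setClass("AncestryModel", representation(
  scores = "matrix", removedPCs = "integer", clusters = "factor",
  centers = "matrix", medianSpectra = "matrix", k = "integer"))

setValidity("AncestryModel", function(object) {
  if (any(object@medianSpectra < 0)) return("median spectra must be >= 0")
  real <- setdiff(levels(object@clusters), "outlier")
  if (length(real) != object@k) return("cluster levels inconsistent with k")
  TRUE
})

setMethod("show", "AncestryModel", function(object) {
  cat("AncestryModel: k =", object@k, "clusters over",
      ncol(object@scores) - length(object@removedPCs), "retained PCs\n")
  print(table(object@clusters))
})

#' SignatureSet: extracted signature profiles and exposures
#'
#' @slot profiles channels x signatures matrix; each column is a probability
#'   distribution over channels (sums to 1).
#' @slot exposures signatures x samples non-negative weight matrix.
#' @slot matches data.frame of catalog match records (one row per signature:
#'   catalog ids, spectrum cosine, exposure cosine, combined score, name,
#'   novel flag).
#' @slot scheme indel scheme id of the channel space.
#' @export
setClass("SignatureSet", representation(
  profiles = "matrix", exposures = "matrix", matches = "data.frame",
  scheme = "numeric"))

setValidity("SignatureSet", function(object) {
  if (ncol(object@profiles) > 0) {
    if (any(abs(colSums(object@profiles) - 1) > 1e-9))
      return("profile columns must sum to 1")
    if (any(object@profiles < 0)) return("profiles must be non-negative")
  }
  if (length(object@exposures) && any(object@exposures < 0))
    return("exposures must be non-negative")
  nm <- colnames(object@profiles)
  if (!is.null(nm) && anyDuplicated(nm)) return("signature names must be unique")
  TRUE
})

#' @describeIn SignatureSet channels x signatures profile matrix.
#' @param x A `SignatureSet`.
#' @export
signatureProfiles <- function(x) x@profiles

#' @describeIn SignatureSet signatures x samples exposure matrix.
#' @export
signatureExposures <- function(x) x@exposures

#' @describeIn SignatureSet catalog match records.
#' @export
signatureMatches <- function(x) x@matches

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", ncol(object@profiles), "signatures,",
      nrow(object@profiles), "channels,",
      ncol(object@exposures), "samples\n")
  if (nrow(object@matches))
    cat("  named:", paste(utils::head(object@matches$name, 8), collapse = ", "),
        if (nrow(object@matches) > 8) "...\n" else "\n")
})

#' ScreenBundle: aligned drug / CRISPR screens, markers and metadata
#'
#' @slot primary sample x drug matrix of primary-screen responses (ln IC50).
#' @slot secondary sample x drug matrix of the replication screen.
#' @slot fitness sample x gene matrix of CRISPR gene-fitness scores.
#' @slot markers sample x marker binary matrix.
#' @slot tissue factor of tissue labels, named by sample.
#' @slot drugInfo data.frame with columns drug, targetGene, targetId.
#' @slot sampleInfo data.frame of per-sample metadata (burden, msi, ...).
#' @slot groundTruth list of planted-effect records (synthetic mode).
#' @export
setClass("ScreenBundle", representation(
  primary = "matrix", secondary = "matrix", fitness = "matrix",
  markers = "matrix", tissue = "factor", drugInfo = "data.frame",
  sampleInfo = "data.frame", groundTruth = "list"))

setValidity("ScreenBundle", function(object) {
  ids <- rownames(object@primary)
  for (s in c("secondary", "fitness", "markers")) {
    m <- slot(object, s)
    if (length(m) && !identical(rownames(m), ids))
      return(sprintf("sample ids of '%s' do not match the primary screen", s))
  }
  if (!identical(names(object@tissue), ids))
    return("tissue map must be named by the shared sample ids")
  mk <- object@markers
  if (length(mk) && !all(mk %in% c(0, 1, NA)))
    return("markers must be binary")
  TRUE
})

setMethod("show", "ScreenBundle", function(object) {
  cat("ScreenBundle:", nrow(object@primary), "samples,",
      ncol(object@primary), "primary /", ncol(object@secondary),
      "replication drugs,", ncol(object@fitness), "fitness genes,",
      ncol(object@markers), "markers,",
      nlevels(object@tissue), "tissues\n")
})
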
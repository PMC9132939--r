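## Variant-call tables.
##
## Calls are plain data.frames with one row per call and columns:
##   sample  - sample id
##   kind    - "SNV", "insertion" or "deletion"
##   channel - pre-classified channel key (optional; filled by
##             classifyCalls() from the sequence columns when absent)
##   ref, alt, flank5, flank3 - bases / flanking sequence for classification
##   seq     - inserted or deleted sequence for indels
##   maf     - population minor allele frequency annotation (NA = absent
##             from the database)
##   locus   - locus key used for cohort-frequency counting

.emptyCalls <- function() {
  data.frame(sample = character(0), kind = character(0),
             channel = character(0), maf = numeric(0), locus = character(0),
             stringsAsFactors = FALSE)
}

#' Fill the channel column of a call table
#'
#' SNVs are classified into the 96 trinucleotide channels and indels into the
#' requested scheme's channels. Calls that cannot be classified (ambiguous
#' bases) are dropped with a warning.
#'
#' @param calls Call data.frame (see package overview for the column contract).
#' @param scheme Indel channel scheme (default 4).
#' @return The call table with a complete `channel` column.
#' @export
classifyCalls <- function(calls, scheme = 4) {
  if (is.null(calls$channel)) calls$channel <- NA_character_
  need <- is.na(calls$channel)
  snv <- need & calls$kind == "SNV"
  if (any(snv))
    calls$channel[snv] <- classifySnvChannel(calls$ref[snv], calls$alt[snv],
                                             calls$flank5[snv], calls$flank3[snv])
  ind <- need & calls$kind %in% c("insertion", "deletion")
  if (any(ind))
    calls$channel[ind] <- classifyIndelChannel(calls$kind[ind], calls$seq[ind],
                                               calls$flank3[ind], scheme)
  drop <- is.na(calls$channel)
  if (any(drop)) {
    warning(sum(drop), " call(s) dropped: no channel could be assigned")
    calls <- calls[!drop, , drop = FALSE]
  }
  calls
}

#' Filter residual germline calls
#'
#' Two frequency filters applied to the cohort's calls: (i) calls whose
#' population database MAF annotation exceeds `populationMafCutoff` are
#' removed (missing annotations are treated as MAF 0, i.e. absent from the
#' database); (ii) calls at loci observed in a strictly greater fraction of
#' cohort samples than `cohortFractionCutoff` are removed, which catches
#' cohort-recurrent germline variants and systematic artifacts.
#'
#' @param calls Call data.frame with `sample`, `maf`, `locus` columns.
#' @param populationMafCutoff Database MAF cutoff (default 1e-5, i.e. 0.001%).
#' @param cohortFractionCutoff Cohort recurrence cutoff (default 0.05).
#' @param nCohort Number of samples in the cohort; defaults to the number of
#'   distinct samples in `calls`.
#' @return The filtered call table; attribute `"removed"` carries the counts
#'   removed by each filter and the number of missing MAF annotations.
#' @export
filterResidualGermline <- function(calls, populationMafCutoff = 1e-5,
                                   cohortFractionCutoff = 0.05,
                                   nCohort = NULL) {
  if (nrow(calls) == 0) return(calls)
  if (is.null(nCohort)) nCohort <- length(unique(calls$sample))
  maf <- calls$maf
  nMissing <- sum(is.na(maf))
  maf[is.na(maf)] <- 0
  dropMaf <- maf > populationMafCutoff

  ## cohort recurrence: fraction of distinct samples carrying each locus
  key <- paste(calls$sample, calls$locus, sep = "\r")
  first <- !duplicated(key)
  recur <- table(calls$locus[first]) / nCohort
  dropCohort <- as.vector(recur[calls$locus]) > cohortFractionCutoff

  keep <- !(dropMaf | dropCohort)
  out <- calls[keep, , drop = FALSE]
  attr(out, "removed") <- c(maf = sum(dropMaf), cohort = sum(dropCohort & !dropMaf),
                            missing_maf = nMissing)
  out
}

#' Build the sample-by-channel spectrum matrix
#'
#' @param calls Filtered call data.frame; classified via [classifyCalls()] if
#'   the `channel` column is incomplete.
#' @param scheme Indel channel scheme (default 4).
#' @param samples Optional character vector fixing the sample universe (so
#'   samples with zero retained calls keep an all-zero row).
#' @return A [MutationSpectra-class] object (channels x samples).
#' @export
buildSpectrumMatrix <- function(calls, scheme = 4, samples = NULL) {
  chan <- channelNames(scheme)
  if (is.null(samples))
    samples <- if (nrow(calls)) sort(unique(as.character(calls$sample))) else character(0)
  m <- matrix(0, length(chan), length(samples),
              dimnames = list(chan, samples))
  if (nrow(calls)) {
    calls <- classifyCalls(calls, scheme)
    bad <- !(calls$channel %in% chan)
    if (any(bad)) {
      warning(sum(bad), " call(s) with channels outside scheme ", scheme, " dropped")
      calls <- calls[!bad, , drop = FALSE]
    }
    tab <- table(factor(calls$channel, levels = chan),
                 factor(as.character(calls$sample), levels = samples))
    m <- m + unclass(tab)
  }
  MutationSpectra(m, scheme = scheme)
}

#' Write / read a spectrum matrix as TSV
#'
#' The TSV is samples x channels with a header of channel keys in fixed
#' catalog order, so the round trip is exact.
#'
#' @param x A [MutationSpectra-class] object.
#' @param path File path.
#' @export
writeSpectra <- function(x, path) {
  writeMatrixTsv(t(spectrumCounts(x)), path)
}

#' @rdname writeSpectra
#' @param scheme Indel scheme of the stored matrix (default 4).
#' @export
readSpectra <- function(path, scheme = 4) {
  MutationSpectra(readMatrixTsv(path), scheme = scheme)
}

#' Read variant calls from the pipeline's TSV format
#'
#' @param path TSV with the call-table columns (see [classifyCalls()]).
#' @return Call data.frame.
#' @export
readVariantCalls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("sample", "kind") %in% names(df)))
  if (is.null(df$maf)) df$maf <- NA_real_
  if (is.null(df$locus))
    df$locus <- if (nrow(df)) paste0("L", seq_len(nrow(df))) else character(0)
  df
}

#' @rdname readVariantCalls
#' @param calls Call data.frame.
#' @export
writeVariantCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variant calls from a VCF file
#'
#' Ingests SNV and indel records (FILTER == PASS or "." only), annotates
#' flanking context from a FASTA reference when one is given, and picks up a
#' population-frequency INFO field when present. Coordinates follow the VCF
#' convention (1-based, ref-anchored, indels left-aligned with the anchor
#' base shared between ref and alt).
#'
#' @param path VCF path (may be bgzipped).
#' @param fasta Optional FASTA path used to fill flanking context.
#' @param mafField INFO field holding the population allele frequency
#'   (default `"AF"`).
#' @param sample Sample id to assign; defaults to the first VCF sample name
#'   or the file name.
#' @param flank Indel flank width to extract (default 10).
#' @return Call data.frame.
#' @export
readVcfCalls <- function(path, fasta = NULL, mafField = "AF", sample = NULL,
                         flank = 10) {
  for (pkg in c("VariantAnnotation", "Biostrings", "GenomicRanges"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("package '", pkg, "' is required for VCF input")
  vcf <- VariantAnnotation::readVcf(path)
  flt <- VariantAnnotation::filt(vcf)
  keep <- is.na(flt) | flt %in% c("PASS", ".")
  vcf <- vcf[keep, ]
  if (is.null(sample)) {
    sn <- colnames(vcf)
    sample <- if (length(sn)) sn[1] else basename(path)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(altL), function(i) as.character(altL[[i]][1]),
                character(1))
  info <- VariantAnnotation::info(vcf)
  maf <- if (mafField %in% names(info)) {
    v <- info[[mafField]]
    as.numeric(vapply(seq_along(v), function(i) {
      x <- unlist(v[i]); if (length(x)) x[1] else NA_real_
    }, numeric(1)))
  } else rep(NA_real_, length(ref))

  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  kind <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                 ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))

  f5 <- f3 <- rep(NA_character_, length(ref))
  seqv <- rep(NA_character_, length(ref))
  ins <- kind == "insertion"; del <- kind == "deletion"
  seqv[ins] <- substr(alt[ins], 2, nchar(alt[ins]))
  seqv[del] <- substr(ref[del], 2, nchar(ref[del]))
  if (!is.null(fasta)) {
    fa <- Biostrings::readDNAStringSet(fasta)
    names(fa) <- sub("\\s.*", "", names(fa))
    getSeq <- function(ch, from, to) {
      from <- max(from, 1L); to <- min(to, Biostrings::width(fa[[ch]]))
      if (from > to) return("")
      as.character(Biostrings::subseq(fa[[ch]], from, to))
    }
    for (i in seq_along(ref)) {
      if (!chrom[i] %in% names(fa)) next
      if (kind[i] == "SNV") {
        f5[i] <- getSeq(chrom[i], pos[i] - 1L, pos[i] - 1L)
        f3[i] <- getSeq(chrom[i], pos[i] + 1L, pos[i] + 1L)
      } else {
        end <- pos[i] + nchar(ref[i]) - 1L
        f5[i] <- getSeq(chrom[i], pos[i] - flank + 1L, pos[i])
        f3[i] <- getSeq(chrom[i], end + 1L, end + flank)
      }
    }
  }
  data.frame(sample = sample, kind = kind, channel = NA_character_,
             ref = ref, alt = alt, flank5 = f5, flank3 = f3, seq = seqv,
             maf = maf, locus = paste0(chrom, ":", pos, "_", ref, ">", alt),
             stringsAsFactors = FALSE)
}

#' Apply BED region masks to a call table
#'
#' Keeps calls whose locus coordinates fall inside `includeBed` (if given) and
#' outside `excludeBed` (if given). Locus keys must follow the
#' `chrom:pos_ref>alt` convention produced by [readVcfCalls()].
#'
#' @param calls Call data.frame.
#' @param includeBed,excludeBed Paths to BED files (0-based half-open).
#' @return Filtered call table.
#' @export
applyRegionMasks <- function(calls, includeBed = NULL, excludeBed = NULL) {
  if (is.null(includeBed) && is.null(excludeBed)) return(calls)
  parse <- function(locus) {
    chrom <- sub(":.*", "", locus)
    pos <- as.integer(sub("_.*", "", sub(".*:", "", locus)))
    list(chrom = chrom, pos = pos)
  }
  loc <- parse(calls$locus)
  inBed <- function(bedPath) {
    bed <- utils::read.delim(bedPath, header = FALSE, stringsAsFactors = FALSE)
    hit <- rep(FALSE, nrow(calls))
    for (i in seq_len(nrow(bed)))
      hit <- hit | (loc$chrom == bed[[1]][i] & loc$pos > bed[[2]][i] &
                    loc$pos <= bed[[3]][i])
    hit
  }
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(includeBed)) keep <- keep & inBed(includeBed)
  if (!is.null(excludeBed)) keep <- keep & !inBed(excludeBed)
  calls[keep, , drop = FALSE]
}
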
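## Mutation channel schemes.
##
## SNV channels follow the standard pyrimidine-reference trinucleotide
## convention: six substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) in the
## 16 possible 5'/3' flanking-base contexts each, keyed "X[R>A]Y" and ordered
## as in the COSMIC SBS catalogs. Indels are collapsed into a small channel
## block; the default 4-channel scheme distinguishes deletions with
## microhomology (Del-MH), deletions at microsatellite loci (Del-MS), other
## deletions and insertions. Richer schemes (5/8/14/32 channels) subdivide by
## indel length (1, 2, 3-4, 5+), microhomology length (1, 2+) and repeat unit
## size (1, 2-5+) behind the same interface.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide SNV channel keys in COSMIC order
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
snvChannelNames <- function() {
  unlist(lapply(.SUBS, function(s) {
    ref <- substr(s, 1, 1)
    unlist(lapply(.BASES, function(f5)
      paste0(f5, "[", s, "]", .BASES)))
  }), use.names = FALSE)
}

.LEN_BINS <- c("1", "2", "3-4", "5+")
.lenBin <- function(len) {
  ifelse(len <= 1, "1", ifelse(len == 2, "2", ifelse(len <= 4, "3-4", "5+")))
}

#' Indel channel keys for a channel scheme
#'
#' @param scheme Integer, one of 4 (default), 5, 8, 14 or 32, or 0 for no
#'   indel block.
#' @return Character vector of channel keys.
#' @export
indelChannelNames <- function(scheme = 4) {
  switch(as.character(scheme),
    "0" = character(0),
    "4" = c("Del-MH", "Del-MS", "Del-Other", "Insertion"),
    "5" = c("Del-MH", "Del-MS", "Del-Other", "Ins-1", "Ins-2+"),
    "8" = as.vector(outer(c("Del-MH", "Del-MS", "Del-Other", "Ins"),
                          c("1", "2+"), paste, sep = "-")),
    "14" = c(paste0("Ins-", .LEN_BINS), paste0("Del-Other-", .LEN_BINS),
             c("Del-MH-mh1", "Del-MH-mh2+"),
             as.vector(outer(c("Del-MS-rep1", "Del-MS-rep2-5+"),
                             c("1", "2+"), paste, sep = "-"))),
    "32" = c(paste0("Ins-", .LEN_BINS),
             as.vector(outer(paste0("Ins-MS-rep", c("1", "2-5+")),
                             .LEN_BINS, paste, sep = "-")),
             paste0("Del-Other-", .LEN_BINS),
             as.vector(outer(paste0("Del-MH-mh", c("1", "2+")),
                             .LEN_BINS, paste, sep = "-")),
             as.vector(outer(paste0("Del-MS-rep", c("1", "2-5+")),
                             .LEN_BINS, paste, sep = "-"))),
    stop("unsupported indel scheme: ", scheme)
  )
}

#' All channel keys (SNV + indel) for a scheme
#' @inheritParams indelChannelNames
#' @export
channelNames <- function(scheme = 4) c(snvChannelNames(), indelChannelNames(scheme))

.revComp <- function(x) {
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(.COMP[b])), collapse = ""), character(1))
}

#' Classify SNVs into trinucleotide channels
#'
#' Purine-reference calls are mapped to their reverse complement (flanks
#' swapped and complemented) so every call is expressed with a C or T
#' reference base.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param flank5,flank3 Single 5' and 3' flanking bases.
#' @return Character vector of channel keys; `NA` (with a warning) for calls
#'   containing ambiguous bases or with `ref == alt`.
#' @examples
#' classifySnvChannel("C", "T", "A", "G")  # "A[C>T]G"
#' classifySnvChannel("G", "A", "T", "C")  # "G[C>T]A"
#' @export
classifySnvChannel <- function(ref, alt, flank5, flank3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(flank5) == n, length(flank3) == n)
  ok <- ref %in% .BASES & alt %in% .BASES & flank5 %in% .BASES &
    flank3 %in% .BASES & ref != alt
  if (any(!ok))
    warning(sum(!ok), " SNV call(s) with ambiguous bases dropped from classification")
  flip <- ok & ref %in% c("A", "G")
  r <- ref; a <- alt; f5 <- flank5; f3 <- flank3
  r[flip] <- .COMP[ref[flip]]
  a[flip] <- .COMP[alt[flip]]
  f5[flip] <- .COMP[flank3[flip]]
  f3[flip] <- .COMP[flank5[flip]]
  out <- rep(NA_character_, n)
  out[ok] <- paste0(f5[ok], "[", r[ok], ">", a[ok], "]", f3[ok])
  out
}

## Number of extra copies of `unit` tandemly repeated at the start of `seq`.
.repeatCount <- function(seq, unit) {
  k <- nchar(unit)
  if (k == 0 || nchar(seq) < k) return(0L)
  n <- 0L
  while (substr(seq, n * k + 1, (n + 1) * k) == unit &&
         (n + 1) * k <= nchar(seq)) n <- n + 1L
  n
}

## Length of the longest shared prefix of two strings.
.prefixLen <- function(a, b) {
  k <- min(nchar(a), nchar(b))
  if (k == 0) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(k)]
  bv <- strsplit(b, "")[[1]][seq_len(k)]
  d <- which(av != bv)
  if (length(d) == 0) k else d[1] - 1L
}

#' Classify an indel into a channel of a scheme
#'
#' Deletions are first tested for microsatellite context (the deleted sequence
#' tandemly repeated in the downstream flank, at least two further copies
#' beyond the deleted one, testing repeat units of length 1 and the full
#' deleted sequence), then for microhomology (at least 1 bp of prefix identity
#' between the deleted sequence and the downstream flank); remaining deletions
#' are Del-Other. All insertions in the default scheme share one channel.
#'
#' @param kind `"insertion"` or `"deletion"`.
#' @param seq The inserted or deleted sequence (bases).
#' @param flank3 Downstream flanking sequence (&ge;5 bp recommended); used
#'   for repeat and microhomology tests. Short flanks fall back to Del-Other
#'   with a warning.
#' @param scheme Indel scheme size (4, 5, 8, 14 or 32).
#' @return A channel key from [indelChannelNames()].
#' @export
classifyIndelChannel <- function(kind, seq, flank3 = "", scheme = 4) {
  if (length(kind) > 1) {
    return(mapply(classifyIndelChannel, kind, seq, flank3,
                  MoreArgs = list(scheme = scheme), USE.NAMES = FALSE))
  }
  len <- nchar(seq)
  if (kind == "insertion") {
    ms <- FALSE; rep2 <- FALSE
    if (nchar(flank3) >= len && len > 0) {
      n1 <- .repeatCount(flank3, substr(seq, 1, 1))
      nu <- .repeatCount(flank3, seq)
      ms <- nu >= 1 || (len == 1 && n1 >= 1)
      rep2 <- nu >= 2 || (len == 1 && n1 >= 2)
    }
    key <- switch(as.character(scheme),
      "4" = "Insertion",
      "5" = if (len <= 1) "Ins-1" else "Ins-2+",
      "8" = if (len <= 1) "Ins-1" else "Ins-2+",
      "14" = paste0("Ins-", .lenBin(len)),
      "32" = if (ms) paste0("Ins-MS-rep", if (rep2) "2-5+" else "1", "-",
                            .lenBin(len))
             else paste0("Ins-", .lenBin(len)))
    return(key)
  }
  stopifnot(kind == "deletion")
  if (nchar(flank3) < max(2L * len, 2L)) {
    warning("flank too short for repeat check; classified Del-Other")
    cls <- "Del-Other"; mh <- 0L; repn <- 0L
  } else {
    rep1 <- if (len == 1) .repeatCount(flank3, seq) else 0L
    repu <- .repeatCount(flank3, seq)
    repn <- max(rep1, repu)
    mh <- .prefixLen(seq, flank3)
    if (repn >= 2) cls <- "Del-MS"
    else if (mh >= 1) cls <- "Del-MH"
    else cls <- "Del-Other"
  }
  lb <- .lenBin(len); l2 <- if (len <= 1) "1" else "2+"
  switch(as.character(scheme),
    "4" = cls,
    "5" = cls,
    "8" = paste0(cls, "-", l2),
    "14" = switch(cls,
      "Del-Other" = paste0("Del-Other-", lb),
      "Del-MH" = paste0("Del-MH-mh", if (mh >= 2) "2+" else "1"),
      "Del-MS" = paste0("Del-MS-rep", if (len >= 2) "2-5+" else "1", "-", l2)),
    "32" = switch(cls,
      "Del-Other" = paste0("Del-Other-", lb),
      "Del-MH" = paste0("Del-MH-mh", if (mh >= 2) "2+" else "1", "-", lb),
      "Del-MS" = paste0("Del-MS-rep", if (len >= 2) "2-5+" else "1", "-", lb)))
}
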
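## Shared fixture builders. Everything is generated in code under fixed
## seeds; heavy cohort-scale objects used by several acceptance blocks are
## cached for the session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## Mix a profile with noise so its cosine to the original hits `target`.
perturbToCosine <- function(p, target, seed = 1) {
  set.seed(seed)
  repeat {
    noise <- rgamma(length(p), 0.3)
    noise <- noise / sum(noise)
    if (cosineSim(noise, p) < target - 0.05) break
  }
  f <- function(a) cosineSim((1 - a) * p + a * noise, p) - target
  a <- uniroot(f, c(0, 1))$root
  q <- (1 - a) * p + a * noise
  q / sum(q)
}

## Small call table with explicit channels.
makeCalls <- function(sample, channel, maf = NA_real_, locus = NULL) {
  n <- max(length(sample), length(channel))
  if (is.null(locus)) locus <- if (n) paste0("L", seq_len(n)) else character(0)
  data.frame(sample = rep_len(sample, n), kind = rep_len("SNV", n),
             channel = rep_len(channel, n), maf = rep_len(maf, n),
             locus = locus, stringsAsFactors = FALSE)
}

## Four-tissue screen bundle with optional planted effects.
makeBundle <- function(nPerTissue = 30, nMarkers = 50, nDrugs = 20,
                       planted = NULL, seed = 1) {
  n <- 4 * nPerTissue
  mk <- syntheticMarkers(n, nMarkers, seed = seed)
  tis <- factor(rep(paste0("T", 1:4), each = nPerTissue))
  simulateScreens(mk, tis, plantedEffects = planted, nDrugs = nDrugs,
                  seed = seed + 1)
}

plantedFrame <- function(nEffects = 5, d = 1.5, direction = "sensitivity") {
  data.frame(marker = paste0("M", seq_len(nEffects)),
             response = paste0("D", seq_len(nEffects)),
             tissue = "all", d = d, direction = direction,
             stringsAsFactors = FALSE)
}
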
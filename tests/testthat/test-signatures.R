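test_that("bootstrap resampling preserves totals and multinomial moments", {
  set.seed(1)
  X <- matrix(rpois(100 * 4, 8), 100, 4,
              dimnames = list(channelNames(4), paste0("S", 1:4)))
  bs <- bootstrapSpectra(X, 50, seed = 2)
  for (b in bs[1:5]) expect_equal(colSums(b), colSums(X))

  ## degenerate row: all mass in one channel resamples identically
  X1 <- X; X1[, 1] <- 0; X1[7, 1] <- 40
  bs1 <- bootstrapSpectra(X1, 10, seed = 3)
  expect_true(all(vapply(bs1, function(b) b[7, 1] == 40, logical(1))))

  ## all-zero sample passes through with a warning
  X0 <- X; X0[, 2] <- 0
  expect_warning(bs0 <- bootstrapSpectra(X0, 3, seed = 4), "all-zero")
  expect_equal(bs0[[1]][, 2], X0[, 2])

  ## per-channel mean over many resamples within 3 SE of the original
  small <- matrix(c(40, 25, 10, 5), 4, 1,
                  dimnames = list(letters[1:4], "S1"))
  bsM <- bootstrapSpectra(small, 1000, seed = 5)
  mn <- rowMeans(do.call(cbind, bsM))
  n <- sum(small); p <- small[, 1] / n
  se <- sqrt(n * p * (1 - p)) / sqrt(1000)
  expect_true(all(abs(mn - small[, 1]) <= 3 * se + 1e-9))
})

test_that("multiplicative-update NMF honours its contract", {
  set.seed(6)
  V <- matrix(rgamma(40 * 25, 2), 40, 25)
  f <- nmfDecompose(V, 4, maxIter = 2000, tol = 0, seed = 7)
  expect_true(all(diff(f$trace) <= 1e-8 * f$trace[1]))   # non-increasing
  expect_equal(unname(colSums(f$profiles)), rep(1, 4))

  ## exact rank-1 matrix is recovered to numerical precision
  V1 <- outer(runif(30), runif(20))
  f1 <- nmfDecompose(V1, 1, maxIter = 5000, tol = 1e-15, seed = 8)
  expect_lt(sqrt(f1$objective) / sqrt(sum(V1^2)), 1e-6)

  ## determinism and input validation
  expect_identical(nmfDecompose(V, 3, seed = 9)$profiles,
                   nmfDecompose(V, 3, seed = 9)$profiles)
  expect_error(nmfDecompose(-V, 2), "non-negative")
  expect_error(nmfDecompose(V, 100), "rank")
})

test_that("the relative-tolerance filter drops diverged runs only", {
  expect_equal(rtolFilter(c(1, 1.0005, 10), rtol = 0.001),
               c(TRUE, TRUE, FALSE))
  expect_true(all(rtolFilter(rep(2, 5))))
})

test_that("medoid clustering recovers tight orthogonal bundles", {
  set.seed(10)
  centers <- diag(3)[, rep(1:3, each = 30)] +
    matrix(abs(rnorm(3 * 90, sd = 0.01)), 3)
  pool <- apply(centers, 2, function(p) p / sum(p))
  rownames(pool) <- c("x", "y", "z")
  cfg <- extractionConfig(medoidKRange = 2:5, seed = 1)
  cand <- extractCandidateSignatures(pool, cfg,
                                     catalog = NULL)
  ## silhouette selection picks k = 3 and medoids sit on the bundle centres
  expect_equal(ncol(cand), 3)
  best <- apply(diag(3), 2, function(c0)
    max(apply(cand, 2, function(p) cosineSim(p, c0))))
  expect_true(all(best > 0.99))
  expect_error(extractCandidateSignatures(NULL, cfg), "empty")
})

test_that("bootstrapped rank sweep pools only RTOL-consistent solutions", {
  sigs <- syntheticSignatures(2, seed = 15)
  expo <- syntheticExposures(30, 2, totalPerSample = 400, seed = 16)
  X <- spectrumCounts(buildSpectrumMatrix(
    simulateSomaticCalls(sigs, expo, seed = 17), samples = rownames(expo)))
  cfg <- extractionConfig(nBootstraps = 5, rankRange = 2:3, maxIter = 400,
                          tol = 1e-8, seed = 18)
  out <- runBootstrapNMF(X, cfg)
  for (r in unique(out$meta$rank)) {
    sub <- out$meta[out$meta$rank == r, ]
    expect_equal(sub$kept, rtolFilter(sub$rmsd, cfg$rtol))
  }
  expect_equal(ncol(out$pool), sum(out$meta$rank[out$meta$kept]))
})

test_that("hierarchical extraction surfaces a rare signature a single pass misses", {
  ## 55 samples dominated by signature A, 5 samples of pure B; with the
  ## rank sweep pinned at 1 the single pass can only describe A, while the
  ## hierarchy removes the well-reconstructed A samples and re-extracts B
  sigs <- syntheticSignatures(2, seed = 25, maxCosine = 0.1)
  expo <- matrix(0, 60, 2, dimnames = list(paste0("S", 1:60),
                                           colnames(sigs)))
  expo[1:55, 1] <- 500
  expo[56:60, 2] <- 500
  X <- buildSpectrumMatrix(simulateSomaticCalls(sigs, expo, seed = 26),
                           samples = rownames(expo))
  base <- extractionConfig(nBootstraps = 8, rankRange = 1, maxIter = 500,
                           tol = 1e-8, medoidKRange = 1, minSamples = 3,
                           seed = 27)
  single <- base; single$hierarchyMaxIter <- 1
  ssSingle <- hierarchicalExtract(X, single, catalog = sigs)
  ssHier <- hierarchicalExtract(X, base, catalog = sigs)
  cosB <- function(ss) max(apply(signatureProfiles(ss), 2,
                                 function(p) cosineSim(p, sigs[, 2])))
  expect_lt(cosB(ssSingle), 0.9)
  expect_gte(cosB(ssHier), 0.9)
  expect_lte(attr(ssHier, "iterations"), 3)
})

test_that("hierarchy stops after one round when everything is well reconstructed", {
  sigs <- syntheticSignatures(2, seed = 35)
  expo <- syntheticExposures(40, 2, totalPerSample = 500, seed = 36)
  X <- buildSpectrumMatrix(simulateSomaticCalls(sigs, expo, seed = 37),
                           samples = rownames(expo))
  cfg <- extractionConfig(nBootstraps = 6, rankRange = 2:3, maxIter = 500,
                          tol = 1e-8, medoidKRange = 2:4,
                          hierarchyCosine = 0.5, seed = 38)
  ss <- hierarchicalExtract(X, cfg, catalog = sigs)
  expect_equal(attr(ss, "iterations"), 1)
})

test_that("small-cohort signature recovery works end to end", {
  sigs <- syntheticSignatures(3, seed = 45)
  expo <- syntheticExposures(80, 3, totalPerSample = 300, maxActive = 2,
                             seed = 46)
  X <- buildSpectrumMatrix(simulateSomaticCalls(sigs, expo, seed = 47),
                           samples = rownames(expo))
  cfg <- extractionConfig(nBootstraps = 10, rankRange = 2:5, maxIter = 600,
                          tol = 1e-8, medoidKRange = 2:8, seed = 48)
  ss <- hierarchicalExtract(X, cfg, catalog = sigs)
  rec <- sapply(1:3, function(j) max(apply(signatureProfiles(ss), 2,
                                           function(p) cosineSim(p, sigs[, j]))))
  expect_true(all(rec >= 0.9))
})

test_that("exposure fitting recovers known mixtures non-negatively", {
  sigs <- syntheticSignatures(3, seed = 55)
  E0 <- t(syntheticExposures(10, 3, totalPerSample = 1, seed = 56))
  X <- sigs %*% E0
  E <- fitExposures(X, sigs)
  expect_true(all(E >= 0))
  expect_equal(unname(E), unname(E0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(attr(E, "cosine") > 0.999))
})

test_that("catalog matching names candidates by the published convention", {
  cat96 <- syntheticSignatures(4, scheme = 0, seed = 50)
  colnames(cat96) <- paste0("SBS", c(4, 7, 26, 12))
  cand <- cbind(exact = cat96[, "SBS4"],
                like = perturbToCosine(cat96[, "SBS7"], 0.90, seed = 2),
                noise = perturbToCosine(cat96[, "SBS26"], 0.60, seed = 3))
  rec <- matchAndName(cand, cat96)
  expect_equal(rec$name, c("SBS4", "SBS7L", "SBS-CL1"))
  expect_equal(rec$novel, c(FALSE, FALSE, TRUE))

  ## a candidate claimed by two catalog entries lists both, best first
  c26 <- cat96[, "SBS26"]
  cand2 <- matrix(perturbToCosine(c26, 0.90, seed = 4), ncol = 1,
                  dimnames = list(rownames(cat96), "c1"))
  catDup <- cat96[, c("SBS26", "SBS12"), drop = FALSE]
  catDup[, "SBS12"] <- perturbToCosine(cand2[, 1], 0.87, seed = 5)
  rec2 <- matchAndName(cand2, catDup)
  expect_equal(rec2$name, "SBS26/12L")

  ## cosine in [0.8, 0.85) stays unassigned; naming is deterministic
  cand3 <- matrix(perturbToCosine(c26, 0.82, seed = 6), ncol = 1,
                  dimnames = list(rownames(cat96), "c1"))
  rec3 <- matchAndName(cand3, cat96)
  expect_true(rec3$unassigned)
  expect_identical(matchAndName(cand, cat96), rec)

  ## empty catalog: everything is novel
  recN <- matchAndName(cand, NULL)
  expect_equal(recN$name, paste0("SBS-CL", 1:3))
})

test_that("combined matching score weights spectrum and exposure cosines", {
  cat96 <- syntheticSignatures(2, scheme = 0, seed = 60)
  colnames(cat96) <- c("SBS1", "SBS2")
  cand <- matrix(perturbToCosine(cat96[, 1], 0.90, seed = 7), ncol = 1,
                 dimnames = list(rownames(cat96), "c1"))
  ## candidate exposure profile at cosine 0.5 to the catalog's
  ce <- matrix(c(1, 0), 2, 1, dimnames = list(c("t1", "t2"), "c1"))
  je <- matrix(c(1, 1, 0, 1), 2, 2,
               dimnames = list(c("t1", "t2"), c("SBS1", "SBS2")))
  je[, 1] <- c(1, 1) / sqrt(2)            # cosine(ce, je[,1]) = 1/sqrt2
  rec <- matchAndName(cand, cat96, w = 0.9, candidateExposures = ce,
                      catalogExposures = je)
  spec <- rec$spectrumCosine
  expect_equal(rec$combined, 0.9 * spec + 0.1 * (1 / sqrt(2)),
               tolerance = 1e-6)
})

test_that("exposure binarization follows the second-highest rule", {
  E <- matrix(c(0, 10, 100, 4), 1, 4,
              dimnames = list("sig1", paste0("S", 1:4)))
  b <- binarizeExposures(E)
  expect_equal(unname(b$thresholds), 0.5)
  expect_equal(unname(b$binary[, 1]), c(0, 1, 1, 1))
  ## scale invariance
  b2 <- binarizeExposures(7.3 * E)
  expect_equal(b2$binary, b$binary)
  ## all-zero signature: all-zero binary column with a warning
  E0 <- rbind(E, sig2 = 0)
  expect_warning(b0 <- binarizeExposures(E0), "positive")
  expect_equal(unname(b0$binary[, "sig2"]), rep(0, 4))
  ## relative exposures sum to 1 per sample
  set.seed(3)
  E3 <- matrix(rgamma(30, 1), 3, 10)
  expect_equal(unname(rowSums(binarizeExposures(E3)$relative)), rep(1, 10))
  expect_error(binarizeExposures(-E), "non-negative")
})

test_that("signature catalogs round-trip through the COSMIC TSV layout", {
  cat96 <- syntheticSignatures(3, scheme = 0, seed = 65)
  colnames(cat96) <- paste0("SBS", 1:3)
  path <- tempfile(fileext = ".tsv")
  writeSignatureCatalog(cat96, path)
  back <- readSignatureCatalog(path)
  expect_equal(back, cat96, tolerance = 1e-12)
})
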
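test_that("ancestry PCs behave on degenerate and duplicated inputs", {
  ## rank-1 structure: PC1 carries ~all variance
  base <- rbinom(50, 2, 0.4)
  G <- outer(c(rep(0, 10), rep(1, 10)), base) + 0L
  G <- G + matrix(0L, 20, 50)
  pc <- suppressWarnings(computeAncestryPCs(G, nPCs = 5, mafThreshold = 0))
  expect_gt(pc$sdev[1]^2 / sum(pc$sdev^2), 0.99)

  set.seed(2)
  G2 <- matrix(rbinom(30 * 100, 2, 0.3), 30, 100)
  G2[2, ] <- G2[1, ]                      # duplicated sample
  pc2 <- computeAncestryPCs(G2, nPCs = 10, mafThreshold = 0)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ])
  expect_warning(computeAncestryPCs(G2, nPCs = 500, mafThreshold = 0),
                 "truncated")
})

test_that("batch-PC pruning removes the separating component, always nRemove", {
  set.seed(5)
  scores <- matrix(rnorm(200 * 12), 200, 12,
                   dimnames = list(NULL, paste0("PC", 1:12)))
  batch <- ifelse(scores[, 3] > 0, "a", "b")
  kept <- removeBatchPCs(scores, batch, nRemove = 1, seed = 3)
  expect_equal(attr(kept, "removed"), 3L)

  ## random labels: the fixed-count rule still removes exactly nRemove
  kept2 <- removeBatchPCs(scores, sample(c("a", "b"), 200, TRUE),
                          nRemove = 4, seed = 3)
  expect_length(attr(kept2, "removed"), 4)
  expect_length(kept2, 8)
  expect_equal(as.integer(kept2), sort(as.integer(kept2)))  # original order

  kept0 <- removeBatchPCs(scores, batch, nRemove = 0)
  expect_equal(as.integer(kept0), 1:12)
  expect_warning(removeBatchPCs(scores, rep("a", 200), nRemove = 2),
                 "single-batch")
})

test_that("trimmed k-means recovers blobs and flags distant outliers", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 10), ncol = 2),
             matrix(rnorm(60, 20), ncol = 2),
             matrix(rnorm(10, 60), ncol = 2))   # 5 distant points
  rownames(X) <- paste0("S", 1:95)
  cl <- clusterAncestry(X, k = 3, trimFraction = 0.055, seed = 2)
  expect_setequal(as.character(cl[91:95]), "outlier")
  truth <- rep(1:3, each = 30)
  tab <- table(cl[1:90], truth)
  expect_equal(sum(apply(tab, 2, max)), 90)     # pure clusters

  ## trim = 0 coincides with a standard k-means partition
  cl0 <- clusterAncestry(X[1:90, ], k = 3, trimFraction = 0, seed = 2)
  km <- kmeans(X[1:90, ], 3, nstart = 10)
  expect_equal(length(unique(paste(cl0, km$cluster))), 3)

  ## degenerate input: all points identical, no crash
  Xd <- matrix(1, 20, 2, dimnames = list(paste0("S", 1:20), NULL))
  expect_s3_class(clusterAncestry(Xd, k = 2, trimFraction = 0, seed = 1),
                  "factor")
  expect_error(clusterAncestry(X, k = 200), "smaller")
  expect_error(clusterAncestry(X, k = 1), ">= 2")
})

test_that("baseline subtraction clamps at zero and respects schemas", {
  expect_equal(subtractMatchedBaseline(c(10, 5, 0), c(4, 7, 0)), c(6, 0, 0))
  expect_equal(subtractMatchedBaseline(c(3, 1), c(0, 0)), c(3, 1))
  expect_equal(subtractMatchedBaseline(c(3, 1), c(3, 1)), c(0, 0))
  expect_error(subtractMatchedBaseline(c(1, 2, 3), c(1, 2)), "schema")
  ## matrix form: totals never exceed the observed totals
  set.seed(4)
  obs <- matrix(rpois(50, 5), 10, 5)
  base <- rpois(10, 5)
  est <- subtractMatchedBaseline(obs, base)
  expect_true(all(est >= 0))
  expect_true(all(colSums(est) <= colSums(obs)))
})

test_that("absolute error is a metric on spectra", {
  set.seed(9)
  chan <- channelNames(4)
  trip <- replicate(3, {
    m <- matrix(rpois(300, 4), 100, 3, dimnames = list(chan, paste0("S", 1:3)))
    m
  }, simplify = FALSE)
  ab <- absoluteError(trip[[1]], trip[[2]])
  ba <- absoluteError(trip[[2]], trip[[1]])
  expect_equal(ab, ba)
  expect_equal(unname(absoluteError(trip[[1]], trip[[1]])), rep(0, 3))
  ac <- absoluteError(trip[[1]], trip[[3]])
  bc <- absoluteError(trip[[2]], trip[[3]])
  expect_true(all(ac <= ab + bc + 1e-9))
})

test_that("bootstrap floor is zero for single-channel spectra", {
  m <- matrix(0, 100, 2, dimnames = list(channelNames(4), c("a", "b")))
  m[1, ] <- c(50, 10)
  fl <- bootstrapFloor(MutationSpectra(m), reps = 5, seed = 1)
  expect_equal(unname(fl), c(0, 0))
})

test_that("stronger between-population spectra bias widens the matching advantage", {
  ## evaluated on normalized spectra (shape error), where contamination by a
  ## divergent germline distribution is visible; quasi-private germline is
  ## made abundant (sharedFraction 0.6) so the contamination term dominates
  adv <- sapply(c(1, 4, 16), function(bf) {
    co <- simulateCohort(populationModel(biasFold = bf,
                                         nCommonVariants = 600,
                                         sharedFraction = 0.6),
                         nCellLines = 150, nBaseline = 120, seed = 77)
    b <- benchmarkReconstruction(co, kGrid = 2, bootstrapReps = 2, seed = 5)
    est <- estimateSomaticSpectra(b$observedSpectra, b$model)
    amN <- mean(absoluteError(est, co$truth, normalize = TRUE))
    flN <- mean(absoluteError(b$observedSpectra, co$truth, normalize = TRUE))
    flN - amN
  })
  expect_true(all(diff(adv) > 0))
})

test_that("perfect estimates give zero reconstruction error", {
  sigs <- syntheticSignatures(2, seed = 12)
  expo <- syntheticExposures(4, 2, totalPerSample = 50, seed = 13)
  som <- simulateSomaticCalls(sigs, expo, seed = 14)
  truth <- buildSpectrumMatrix(som, samples = rownames(expo))
  expect_equal(unname(absoluteError(truth, truth)), rep(0, 4))
})
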
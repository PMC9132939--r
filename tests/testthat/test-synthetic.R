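test_that("population structure appears in genotypes only when fst > 0", {
  m0 <- populationModel(fst = 0, nCommonVariants = 1000)
  p0 <- simulatePopulation(m0, 200, seed = 5)
  pc0 <- computeAncestryPCs(p0$genotypes, nPCs = 5)
  expect_lt(abs(cor(pc0$scores[, 1], p0$labels)), 0.3)

  m3 <- populationModel(fst = 0.3, nCommonVariants = 1000)
  p3 <- simulatePopulation(m3, 200, seed = 5)
  pc3 <- computeAncestryPCs(p3$genotypes, nPCs = 5)
  expect_gt(abs(cor(pc3$scores[, 1], p3$labels)), 0.9)

  ## brute-force check: per-variant allele-frequency contrast between the
  ## labelled groups is large under fst = 0.3, small under fst = 0
  afContrast <- function(p) {
    g1 <- colMeans(p$genotypes[p$labels == 1, ]) / 2
    g2 <- colMeans(p$genotypes[p$labels == 2, ]) / 2
    mean(abs(g1 - g2))
  }
  expect_gt(afContrast(p3), 2 * afContrast(p0))
})

test_that("population simulation is deterministic and validates inputs", {
  m <- populationModel(nCommonVariants = 200)
  a <- simulatePopulation(m, 50, seed = 9)
  b <- simulatePopulation(m, 50, seed = 9)
  expect_identical(a, b)
  expect_error(simulatePopulation(m, 1, seed = 1), "nSamples")
  expect_error(populationModel(nPopulations = 0), "positive")
})

test_that("germline channel bias shifts the right channels by the right amount", {
  ## all-ones bias: the two populations share one generative law
  m1 <- populationModel(germlineChannelBias = matrix(1, 2, 96),
                        germlineBurden = 1500, sharedFraction = 0,
                        annotatedFraction = 0)
  calls <- simulateGermlineCalls(m1, rep(1:2, each = 40), seed = 3)
  tab <- table(calls$channel, rep(1:2, each = 40)[
    as.integer(sub("S", "", calls$sample))])
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)

  ## 3x boost of one channel in population 1 only
  bias <- matrix(1, 2, 96); bias[1, 5] <- 3
  m2 <- populationModel(germlineChannelBias = bias, germlineBurden = 2000,
                        sharedFraction = 0, annotatedFraction = 0)
  calls2 <- simulateGermlineCalls(m2, rep(1, 50), seed = 4)
  freq <- mean(calls2$channel == snvChannelNames()[5])
  expected <- 3 / 98                       # 3x on a uniform 96-channel base
  expect_lt(abs(freq / expected - 1), 0.2)

  expect_equal(nrow(simulateGermlineCalls(
    populationModel(germlineBurden = 0), rep(1, 5), seed = 1)), 0)
  expect_error(simulateGermlineCalls(m1, c(1, 7), seed = 1), "unknown")
})

test_that("somatic calls concentrate on the planted signature mixture", {
  sigs <- syntheticSignatures(3, seed = 21)
  ## single signature, 1e5 mutations: empirical spectrum ~ profile
  e1 <- matrix(c(1e5, 0, 0), 1, 3,
               dimnames = list("S1", colnames(sigs)))
  calls <- simulateSomaticCalls(sigs, e1, seed = 22)
  sp <- spectrumCounts(buildSpectrumMatrix(calls))[, "S1"]
  expect_gte(cosineSim(sp, sigs[, 1]), 0.999)

  ## zero exposure: no calls
  expect_equal(nrow(simulateSomaticCalls(sigs, 0 * e1, seed = 1)), 0)
  expect_error(simulateSomaticCalls(sigs, -e1, seed = 1), "non-negative")

  ## 50/50 mix of two disjoint-support profiles splits mass evenly
  p1 <- c(rep(1 / 48, 48), rep(0, 52)); p2 <- c(rep(0, 52), rep(1 / 48, 48))
  P <- cbind(a = p1, b = p2); rownames(P) <- channelNames(4)
  e2 <- matrix(c(5e4, 5e4), 1, 2, dimnames = list("S1", c("a", "b")))
  calls2 <- simulateSomaticCalls(P, e2, seed = 23)
  sp2 <- spectrumCounts(buildSpectrumMatrix(calls2))[, "S1"]
  half <- sum(sp2[1:48]) / sum(sp2)
  expect_lt(abs(half - 0.5), 0.02)
})

test_that("composition is channelwise additive with somatic-only ground truth", {
  sigs <- syntheticSignatures(2, seed = 31)
  expo <- syntheticExposures(6, 2, totalPerSample = 100, seed = 32)
  som <- simulateSomaticCalls(sigs, expo, seed = 33)
  germ <- makeCalls(rep(rownames(expo), each = 5),
                    sample(snvChannelNames(), 30, TRUE))
  comp <- composeCellLineCohort(germ, som)
  obs <- spectrumCounts(buildSpectrumMatrix(comp$observed,
                                            samples = rownames(expo)))
  expect_equal(obs, spectrumCounts(comp$truth) +
                 spectrumCounts(buildSpectrumMatrix(germ,
                                                    samples = rownames(expo))))
  ## zero germline: observed equals truth
  comp0 <- composeCellLineCohort(germ[0, ], som)
  obs0 <- spectrumCounts(buildSpectrumMatrix(comp0$observed,
                                             samples = rownames(expo)))
  expect_equal(obs0, spectrumCounts(comp0$truth))
  expect_error(composeCellLineCohort(makeCalls("X9", "A[C>T]G"), som),
               "mismatch")
})

test_that("null screens carry no systematic marker effects", {
  bundle <- makeBundle(nPerTissue = 125, nMarkers = 500, nDrugs = 4, seed = 41)
  ds <- sapply(1:500, function(j) {
    m <- bundle@markers[, j]
    cohenD(bundle@primary[m == 1, 1], bundle@primary[m == 0, 1])
  })
  expect_lt(abs(mean(ds)), 0.05)
})

test_that("planted effects land near their nominal effect size", {
  n <- 100
  mk <- matrix(rep(c(1, 0), each = 50), n, 1,
               dimnames = list(paste0("S", 1:n), "M1"))
  pe <- data.frame(marker = "M1", response = "D1", tissue = "all", d = 2,
                   direction = "sensitivity", stringsAsFactors = FALSE)
  for (s in 1:5) {
    b <- simulateScreens(mk, factor(rep("T1", n)), pe, nDrugs = 2, seed = s)
    d <- cohenD(b@primary[mk[, 1] == 1, "D1"], b@primary[mk[, 1] == 0, "D1"])
    expect_gt(d, 1.5); expect_lt(d, 2.5)
  }
})

test_that("shared planted effects correlate across screens, null drugs do not", {
  bundle <- makeBundle(nPerTissue = 40, nMarkers = 10, nDrugs = 20,
                       planted = plantedFrame(5, d = 2), seed = 51)
  corPerDrug <- sapply(1:20, function(j) {
    dr <- paste0("D", j)
    d1 <- sapply(1:10, function(k) {
      m <- bundle@markers[, k]
      cohenD(bundle@primary[m == 1, dr], bundle@primary[m == 0, dr])
    })
    d2 <- sapply(1:10, function(k) {
      m <- bundle@markers[, k]
      cohenD(bundle@secondary[m == 1, dr], bundle@secondary[m == 0, dr])
    })
    cor(d1, d2)
  })
  expect_gt(mean(corPerDrug[1:5]), 0.5)
  expect_lt(abs(mean(corPerDrug[6:20])), 0.35)
})

test_that("screen simulation is deterministic and validates planted effects", {
  a <- makeBundle(nPerTissue = 10, nMarkers = 5, nDrugs = 3, seed = 61)
  b <- makeBundle(nPerTissue = 10, nMarkers = 5, nDrugs = 3, seed = 61)
  expect_identical(a@primary, b@primary)
  expect_identical(a@fitness, b@fitness)
  mk <- syntheticMarkers(20, 2, seed = 1)
  bad <- data.frame(marker = "nope", response = "D1", tissue = "all",
                    d = 1, direction = "sensitivity")
  expect_error(simulateScreens(mk, factor(rep("T1", 20)), bad, nDrugs = 2),
               "absent")
})
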
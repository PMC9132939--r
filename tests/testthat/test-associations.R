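test_that("Cohen's d matches hand computations and conventions", {
  expect_equal(cohenD(c(1, 2, 3), c(3, 4, 5)), 2)       # sensitivity
  expect_equal(cohenD(c(3, 4, 5), c(1, 2, 3)), -2)      # resistance
  expect_equal(cohenD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_warning(d0 <- cohenD(c(1, 1), c(1, 1)), "pooled")
  expect_true(is.na(d0))
  ## NA values dropped before computation: d = 2.5 / sqrt(5/6)
  expect_equal(cohenD(c(1, 2, NA), c(3, 4, 5, NA)), 2.5 / sqrt(5 / 6))
})

test_that("the two-way score takes the weaker effect", {
  expect_equal(twoWayScore(1.2, 0.6, "sensitivity"), 0.6)
  expect_equal(twoWayScore(-1.2, -0.6, "resistance"), -0.6)
  ## discordant signs fail any positive sensitivity gate
  expect_equal(twoWayScore(1.0, -0.4, "sensitivity"), -0.4)
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration (n <= 8)", {
  set.seed(31)
  fixtures <- list(
    list(n = 6, k = 3), list(n = 7, k = 2), list(n = 8, k = 4),
    list(n = 8, k = 2))
  for (fx in fixtures) {
    y1 <- rnorm(fx$n); y2 <- rnorm(fx$n)
    m <- c(rep(1, fx$k), rep(0, fx$n - fx$k))
    for (dir in c("sensitivity", "resistance")) {
      ex <- randomizationPvalue(y1, y2, m, dir, method = "exact")
      expect_equal(ex$nArrangements, choose(fx$n, fx$k))
      B <- 4000
      mc <- randomizationPvalue(y1, y2, m, dir, nRandomizations = B,
                                seed = 7)
      se <- sqrt(ex$p * (1 - ex$p) / B)
      expect_lte(abs(mc$p - ex$p), 3 * se + 1e-12)
    }
  }
  expect_error(randomizationPvalue(rnorm(5), rnorm(5), rep(1, 5)),
               "constant")
})

test_that("Storey q-values are calibrated and monotone", {
  expect_equal(unname(c(suppressWarnings(storeyQvalues(rep(1, 5))))),
               rep(1, 5), ignore_attr = TRUE)
  set.seed(41)
  pU <- runif(1e4)
  q <- storeyQvalues(pU)
  pi0 <- attr(q, "pi0")
  expect_gt(pi0, 0.9); expect_lt(pi0, 1.1)
  ord <- order(pU)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_warning(storeyQvalues(runif(5)), "fewer than 10")
})

test_that("the inflation factor diagnoses calibrated, deflated and inflated sets", {
  expect_equal(inflationLambda(rep(0.5, 100)), 1)
  set.seed(51)
  expect_lt(abs(inflationLambda(runif(1e4)) - 1), 0.05)
  expect_gt(inflationLambda(rbeta(1e4, 0.5, 1)), 1)
  ## p = 0 handled through the floor
  expect_true(is.finite(inflationLambda(c(0, runif(50)),
                                        nRandomizations = 1000)))
})

test_that("Fisher pooling of signature groups matches the chi-square tail", {
  recs <- data.frame(marker = c("A", "B"), response = "D1", partner = "D1",
                     tissue = "T1", flavor = "screen-replication",
                     direction = "sensitivity", d_primary = c(0.4, 0.8),
                     d_secondary = c(0.4, 0.8), score = c(0.4, 0.8),
                     p = c(0.5, 0.5), stringsAsFactors = FALSE)
  pooled <- suppressWarnings(
    aggregateSignatureGroups(recs, list(G = c("A", "B"))))
  expect_equal(pooled$p, 0.5965736, tolerance = 1e-6)
  expect_equal(pooled$d_primary, 0.6)
  recs$p <- c(1, 1)
  pooled1 <- suppressWarnings(
    aggregateSignatureGroups(recs, list(G = c("A", "B"))))
  expect_equal(pooled1$p, 1)
})

test_that("cohort preprocessing removes burden outliers and merges tissues", {
  mk <- matrix(rbinom(100, 1, 0.5), 50, 2,
               dimnames = list(paste0("S", 1:50), c("A", "B")))
  tis <- factor(rep(c("ESCA", "STAD"), each = 25))
  bn <- simulateScreens(mk, tis, nDrugs = 3, seed = 1)
  ## degenerate IQR: fence equals the upper quartile, the extreme sample goes
  bn@sampleInfo <- data.frame(burden = c(rep(100, 24), 10000, rep(100, 25)),
                              row.names = paste0("S", 1:50))
  out <- preprocessCohort(bn)
  expect_equal(nrow(out@primary), 49)
  expect_false("S25" %in% rownames(out@primary))

  ## identity without blocklist or outliers
  bn2 <- bn; bn2@sampleInfo <- data.frame(row.names = paste0("S", 1:50))
  expect_equal(rownames(preprocessCohort(bn2)@primary), paste0("S", 1:50))

  merged <- preprocessCohort(bn2, tissueMerge = c(ESCA = "ESCA_STAD",
                                                  STAD = "ESCA_STAD"))
  expect_equal(levels(merged@tissue), "ESCA_STAD")
  blocked <- preprocessCohort(bn2, blocklist = c("S1", "S2"))
  expect_equal(nrow(blocked@primary), 48)
})

test_that("tissues below the size threshold are never tested", {
  mk <- syntheticMarkers(37, 5, seed = 61)
  tis <- factor(c(rep("big", 30), rep("small", 7)))
  bn <- simulateScreens(mk, tis, nDrugs = 3, seed = 62)
  rec <- runReplicationScreen(bn, testPolicy(nRandomizations = 200),
                              "screen-replication", seed = 63)
  expect_false("small" %in% rec$tissue)
  expect_true("big" %in% rec$tissue)
})

test_that("significant records always passed the gate and the size checks", {
  pol <- testPolicy(nRandomizations = 500)
  bn <- makeBundle(nPerTissue = 30, nMarkers = 30, nDrugs = 10,
                   planted = plantedFrame(3, d = 1.8), seed = 71)
  rec <- runReplicationScreen(bn, pol, "screen-replication", seed = 72)
  sig <- rec[rec$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$tested))
  expect_true(all(!is.na(sig$p)))
  expect_true(all(sig$n_pos >= pol$minPositive))
  expect_true(all(sig$n_pos + sig$n_neg >= pol$minSamples))
  ## direction consistency: sensitivity hits have positive d in both screens
  sens <- sig[sig$direction == "sensitivity", ]
  expect_true(all(sens$d_primary > 0.5 & sens$d_secondary > 0.5))
})

test_that("jointly permuting sample order leaves the statistics unchanged", {
  bn <- makeBundle(nPerTissue = 20, nMarkers = 10, nDrugs = 5,
                   planted = plantedFrame(2, d = 1.5), seed = 81)
  pol <- testPolicy(nRandomizations = 2000)
  rec1 <- runReplicationScreen(bn, pol, "screen-replication", seed = 82)
  perm <- sample(nrow(bn@primary))
  ids <- rownames(bn@primary)[perm]
  bn2 <- new("ScreenBundle", primary = bn@primary[ids, ],
             secondary = bn@secondary[ids, ], fitness = bn@fitness[ids, ],
             markers = bn@markers[ids, ], tissue = bn@tissue[ids],
             drugInfo = bn@drugInfo,
             sampleInfo = bn@sampleInfo[ids, , drop = FALSE],
             groundTruth = bn@groundTruth)
  rec2 <- runReplicationScreen(bn2, pol, "screen-replication", seed = 82)
  key <- function(r) order(r$marker, r$response, r$direction)
  r1 <- rec1[key(rec1), ]; r2 <- rec2[key(rec2), ]
  expect_equal(r1$d_primary, r2$d_primary)
  expect_equal(r1$score, r2$score)
  ## p-values are Monte-Carlo estimates of the same quantity
  ok <- !is.na(r1$p) & !is.na(r2$p)
  expect_true(all(abs(r1$p[ok] - r2$p[ok]) < 0.06))
})

test_that("all three replication flavors produce testable pairings", {
  bn <- makeBundle(nPerTissue = 12, nMarkers = 5, nDrugs = 6, seed = 91)
  pol <- testPolicy(nRandomizations = 200)
  st <- runReplicationScreen(bn, pol, "same-target", seed = 92)
  expect_true(all(st$response != st$partner))
  di <- bn@drugInfo
  tid <- setNames(di$targetId, di$drug)
  expect_true(all(tid[st$response] == tid[st$partner]))
  ko <- runReplicationScreen(bn, pol, "drug-vs-knockout", seed = 93)
  expect_true(all(ko$partner %in% colnames(bn@fitness)))
  sr <- runReplicationScreen(bn, pol, "screen-replication", seed = 94)
  expect_true(all(sr$response == sr$partner))
})

test_that("missing responses are handled by pairwise deletion", {
  bn <- makeBundle(nPerTissue = 25, nMarkers = 6, nDrugs = 4,
                   planted = plantedFrame(2, d = 2), seed = 95)
  bn@primary[1:5, 1] <- NA
  pol <- testPolicy(nRandomizations = 300)
  rec <- runReplicationScreen(bn, pol, "screen-replication", seed = 96)
  expect_gt(nrow(rec), 0)
  expect_true(all(is.na(rec$p) | (rec$p >= 0 & rec$p <= 1)))
  ## planted effect still detectable despite missing entries
  hit <- rec[rec$marker == "M1" & rec$response == "D1" &
             rec$direction == "sensitivity", ]
  expect_true(any(hit$d_primary > 1, na.rm = TRUE))
})

test_that("tier curation follows the recurrence rules", {
  base <- data.frame(
    marker = "M1", response = "D1", partner = "D1",
    direction = "sensitivity", d_primary = 1, d_secondary = 1, score = 1,
    p = 0.001, n_pos = 5, n_neg = 20, tested = TRUE, q = 0.2,
    lambda = 1, lambdaOk = TRUE, significant = FALSE, permissive = TRUE,
    stringsAsFactors = FALSE)
  ## permissive in two flavors, one q = 0.2 -> silver, not golden
  two <- rbind(cbind(base, tissue = "T1", flavor = "screen-replication"),
               cbind(base, tissue = "T1", flavor = "drug-vs-knockout"))
  out <- curateTiers(two)
  expect_true(all(out$silver)); expect_false(any(out$golden))
  ## permissive in three tissues -> golden (and silver)
  three <- do.call(rbind, lapply(paste0("T", 1:3), function(t)
    cbind(base, tissue = t, flavor = "screen-replication")))
  out3 <- curateTiers(three)
  expect_true(all(out3$golden)); expect_true(all(out3$silver))
  ## single record -> neither
  one <- cbind(base, tissue = "T1", flavor = "screen-replication")
  out1 <- curateTiers(one)
  expect_false(any(out1$silver) || any(out1$golden))
  ## no q below the relaxed FDR -> no tier
  noq <- two; noq$q <- 0.4
  outq <- curateTiers(noq)
  expect_false(any(outq$silver))
})
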
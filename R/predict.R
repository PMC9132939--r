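## Drug-response prediction benchmark.
##
## Marker sets are scored as predictors of per-drug response profiles by
## repeated k-fold cross-validation, with the relative root-mean-square
## error (RRMSE): RMSE of the model divided by the RMSE of an uninformative
## default model that predicts the training-set mean response. RRMSE < 1
## marks a predictive model. Marker sets are compared across many
## drug x tissue datasets with the rank-based corrected Friedman test and
## the Nemenyi post-hoc critical distance.

#' Cross-validation design for the prediction benchmark
#'
#' @param folds Cross-validation folds (default 10).
#' @param repeats Repetitions of the fold split (default 5).
#' @param minCellLines Minimum samples with non-missing response for a model
#'   to be built (default 15).
#' @return Classed list.
#' @export
evalDesign <- function(folds = 10, repeats = 5, minCellLines = 15) {
  stopifnot(folds >= 2, minCellLines > folds)
  structure(list(folds = folds, repeats = repeats,
                 minCellLines = minCellLines), class = "sigmark_eval_design")
}

#' Regressor contracts
#'
#' A regressor is any `function(xTrain, yTrain, xTest)` returning
#' predictions for `xTest`. `rfRegressor()` is the default ensemble of 100
#' trees with terminal node size 2 (ranger); `meanRegressor()` predicts the
#' training mean (so its RRMSE is exactly 1); `oracleRegressor(f)` predicts
#' `f(xTest)` for a known generating function.
#'
#' @param numTrees,minNodeSize Forest parameters (defaults 100 / 2).
#' @param seed Integer seed for the forest.
#' @return A regressor function.
#' @export
rfRegressor <- function(numTrees = 100, minNodeSize = 2, seed = 1) {
  force(numTrees); force(minNodeSize); force(seed)
  function(xTrain, yTrain, xTest) {
    df <- data.frame(.y = yTrain, xTrain, check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = numTrees, min.node.size = minNodeSize,
                          seed = seed, num.threads = 1)
    predict(fit, data.frame(xTest, check.names = FALSE))$predictions
  }
}

#' @rdname rfRegressor
#' @export
meanRegressor <- function() {
  function(xTrain, yTrain, xTest) rep(mean(yTrain), nrow(xTest))
}

#' @rdname rfRegressor
#' @param f Generating function mapping a feature matrix to responses.
#' @export
oracleRegressor <- function(f) {
  force(f)
  function(xTrain, yTrain, xTest) f(xTest)
}

#' Cross-validated relative RMSE of a marker set for one response
#'
#' Repeated k-fold cross-validation; per fold, the default prediction is the
#' training-fold mean. Squared errors are pooled over folds and repeats
#' before taking the ratio of root-mean-square errors.
#'
#' @param features Samples x features numeric matrix.
#' @param response Numeric response per sample (ln IC50); samples with
#'   missing response are dropped before the size check.
#' @param design An [evalDesign()].
#' @param regressor A regressor contract (default [rfRegressor()]).
#' @param seed Integer seed controlling the fold splits.
#' @return List: `rrmse`, `predictive` (rrmse < 1), `n`, `rmseModel`,
#'   `rmseDefault`; or NULL when fewer than `minCellLines` samples are
#'   available.
#' @export
rrmseCrossval <- function(features, response, design = evalDesign(),
                          regressor = rfRegressor(), seed = 1) {
  ok <- !is.na(response) & complete.cases(features)
  X <- as.matrix(features[ok, , drop = FALSE])
  y <- response[ok]
  n <- length(y)
  if (n < design$minCellLines) return(NULL)
  .withSeed(seed, {
    sseM <- sseD <- 0
    for (r in seq_len(design$repeats)) {
      fold <- sample(rep_len(seq_len(design$folds), n))
      for (f in seq_len(design$folds)) {
        test <- fold == f
        if (!any(test) || all(test)) next
        pred <- regressor(X[!test, , drop = FALSE], y[!test],
                          X[test, , drop = FALSE])
        sseM <- sseM + sum((pred - y[test])^2)
        sseD <- sseD + sum((mean(y[!test]) - y[test])^2)
      }
    }
    rrmse <- sqrt(sseM) / sqrt(sseD)
    list(rrmse = rrmse, predictive = rrmse < 1, n = n,
         rmseModel = sqrt(sseM / (n * design$repeats)),
         rmseDefault = sqrt(sseD / (n * design$repeats)))
  })
}

#' Tally the fraction of predictive models
#'
#' @param performances data.frame with at least `markerSet`, `tissue` and
#'   `rrmse` columns (one row per drug x tissue x marker-set model).
#' @return data.frame per marker-set x tissue: `nModels`, `nPredictive`,
#'   `fractionPredictive`.
#' @export
tallyPredictive <- function(performances) {
  key <- interaction(performances$markerSet, performances$tissue, drop = TRUE)
  out <- lapply(levels(key), function(lev) {
    s <- performances[key == lev, , drop = FALSE]
    data.frame(markerSet = s$markerSet[1], tissue = s$tissue[1],
               nModels = nrow(s), nPredictive = sum(s$rrmse < 1),
               fractionPredictive = mean(s$rrmse < 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Complementarity classes of two marker sets
#'
#' Per drug-tissue pair, given whether marker set A, marker set B and their
#' combination are predictive (RRMSE < 1): `"A-only"`, `"B-only"`,
#' `"either"` (both singles predictive), `"combination-only"` (only the
#' combined model predictive) or `"none"`.
#'
#' @param predictiveA,predictiveB,predictiveAB Logical vectors over an
#'   aligned pair universe.
#' @return Factor of classes.
#' @export
complementarityClasses <- function(predictiveA, predictiveB, predictiveAB) {
  stopifnot(length(predictiveA) == length(predictiveB),
            length(predictiveA) == length(predictiveAB))
  cls <- ifelse(predictiveA & predictiveB, "either",
         ifelse(predictiveA, "A-only",
         ifelse(predictiveB, "B-only",
         ifelse(predictiveAB, "combination-only", "none"))))
  factor(cls, levels = c("A-only", "B-only", "either", "combination-only",
                         "none"))
}

#' Corrected Friedman test and Nemenyi critical distance on RRMSE ranks
#'
#' Methods are ranked per dataset (rank 1 = lowest RRMSE; ties get mean
#' ranks); the Friedman chi-square is corrected to the Iman-Davenport F
#' statistic, and the Nemenyi critical distance at level `alpha` is
#' `q_alpha * sqrt(k (k + 1) / (6 N))` with `q_alpha` from the Studentized
#' range distribution (divided by sqrt(2)). Method pairs whose mean ranks
#' differ by more than the CD are significantly different.
#'
#' @param rrmse Datasets x methods numeric matrix (complete cases only).
#' @param alpha Significance level (default 0.05).
#' @return List: `meanRanks`, `friedmanChisq`, `imanDavenportF`, `p`,
#'   `criticalDistance`, `significantPairs` (data.frame).
#' @export
friedmanNemenyi <- function(rrmse, alpha = 0.05) {
  rrmse <- as.matrix(rrmse)
  rrmse <- rrmse[complete.cases(rrmse), , drop = FALSE]
  N <- nrow(rrmse); k <- ncol(rrmse)
  if (k < 2 || N < 2) stop("need at least 2 methods and 2 datasets")
  R <- t(apply(rrmse, 1, rank))
  meanRanks <- colMeans(R)
  if (k < 3)
    warning("fewer than 3 methods: Friedman statistic is unreliable, ",
            "interpret as a paired sign-style comparison")
  chisq <- 12 * N / (k * (k + 1)) * (sum(meanRanks^2) - k * (k + 1)^2 / 4)
  FF <- (N - 1) * chisq / (N * (k - 1) - chisq)
  p <- pf(FF, k - 1, (k - 1) * (N - 1), lower.tail = FALSE)
  qAlpha <- qtukey(1 - alpha, k, Inf) / sqrt(2)
  cd <- qAlpha * sqrt(k * (k + 1) / (6 * N))
  pairsL <- list()
  nm <- colnames(rrmse)
  if (is.null(nm)) nm <- paste0("M", seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    gap <- abs(meanRanks[i] - meanRanks[j])
    if (gap > cd)
      pairsL[[length(pairsL) + 1]] <- data.frame(
        better = if (meanRanks[i] <= meanRanks[j]) nm[i] else nm[j],
        methodA = nm[i], methodB = nm[j], rankGap = gap,
        stringsAsFactors = FALSE)
  }
  sig <- if (length(pairsL)) do.call(rbind, pairsL) else
    data.frame(better = character(0), methodA = character(0),
               methodB = character(0), rankGap = numeric(0))
  list(meanRanks = setNames(meanRanks, nm), friedmanChisq = chisq,
       imanDavenportF = FF, p = p, criticalDistance = cd,
       significantPairs = sig)
}
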
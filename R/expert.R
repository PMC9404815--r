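## The evaluation protocol: balanced subject resampling, RBF-SVM experts
## with grid-searched 5-fold cross-validation, and accuracy / sensitivity
## / specificity aggregation.  AD is the positive class everywhere.
##
## The RBF kernel is evaluated on a precomputed squared-distance matrix:
## per repetition the standardized features are computed once and the
## whole (C, gamma) grid reuses the same distances, which keeps the grid
## search inexpensive even for 60k-dimensional conv activations.

#' Default SVM hyperparameter grid
#'
#' A standard log-decade RBF grid: `C` in 10^(-2..3) and `gamma` in
#' 10^(-5..1) plus `"scale"`, the variance-scaled heuristic
#' `1 / (p * mean(var))` computed on the standardized training features.
#'
#' @return list with components `cost` and `gamma` (`gamma` may contain
#'   the string `"scale"`).
#' @export
svmGrid <- function() {
  list(cost = 10^(-2:3), gamma = c(10^(-5:1), "scale"))
}

#' Balanced repeated train/test subject assignment
#'
#' Per repetition the majority (HC) class is subsampled to the minority
#' size (30 of 45 in the reference setting) and each class is split into
#' a balanced train and test set (20 train + 10 test per class by
#' default).  HC subsamples are drawn independently across repetitions.
#' One plan is shared by all experts of a run so that per-subject
#' decisions align across views and layers for fusion.
#'
#' @param hcIds,adIds subject id vectors for each class.
#' @param nReps number of repetitions (default 10).
#' @param masterSeed integer seed; the same seed reproduces the plan.
#' @param nSubsample HC subsample size per repetition (default the AD
#'   count).
#' @param nTrainPerClass,nTestPerClass split sizes per class (defaults 20
#'   and 10).
#' @return A [SamplingPlan-class].
#' @export
makeSamplingPlan <- function(hcIds, adIds, nReps = 10L, masterSeed = 1,
                             nSubsample = length(adIds),
                             nTrainPerClass = 20L, nTestPerClass = 10L) {
  need <- nTrainPerClass + nTestPerClass
  if (length(hcIds) < nSubsample || nSubsample < need)
    stop("insufficient HC subjects: need ", need, " of a subsample of ",
         nSubsample)
  if (length(adIds) < need)
    stop("insufficient AD subjects: need ", need, ", have ", length(adIds))
  reps <- withSeed(masterSeed, {
    lapply(seq_len(nReps), function(r) {
      hcSub <- sample(hcIds, nSubsample)
      hcTrain <- sample(hcSub, nTrainPerClass)
      hcTest <- sample(setdiff(hcSub, hcTrain), nTestPerClass)
      adTrain <- sample(adIds, nTrainPerClass)
      adTest <- sample(setdiff(adIds, adTrain), nTestPerClass)
      list(trainIds = c(hcTrain, adTrain),
           trainLabels = factor(rep(c("HC", "AD"), each = nTrainPerClass),
                                levels = c("HC", "AD")),
           testIds = c(hcTest, adTest),
           testLabels = factor(rep(c("HC", "AD"), each = nTestPerClass),
                               levels = c("HC", "AD")))
    })
  })
  new("SamplingPlan", repetitions = reps, nReps = as.integer(nReps),
      masterSeed = masterSeed)
}

## Per-feature standardization fitted on the training split only.
fitScaler <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- colMeans(X^2) - m^2
  s <- sqrt(pmax(v * n / max(n - 1, 1), 0))
  s[s < 1e-12] <- 1
  list(center = m, scale = s)
}

applyScaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

## Squared Euclidean cross-distances via BLAS.
crossDist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

## Stratified k-fold assignment, seeded; returns integer fold per row.
stratifiedFolds <- function(y, k, seed) {
  folds <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(y)) {
      i <- which(y == cl)
      folds[i] <- sample(rep(seq_len(k), length.out = length(i)))
    }
  })
  folds
}

resolveGamma <- function(gamma, Xs) {
  g <- suppressWarnings(as.numeric(gamma))
  if (is.na(g)) {
    v <- mean(colMeans(Xs^2) - colMeans(Xs)^2)
    g <- 1 / (ncol(Xs) * max(v, 1e-12))
  }
  g
}

ksvmOnKernel <- function(K, y, cost) {
  kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = cost,
                prob.model = FALSE)
}

predictOnKernel <- function(fit, Kcross) {
  kernlab::predict(fit, kernlab::as.kernelMatrix(
    Kcross[, kernlab::SVindex(fit), drop = FALSE]))
}

#' Train one RBF-SVM expert with grid-searched 5-fold cross-validation
#'
#' Features are z-scored per dimension (fit on the training split only),
#' then the `(C, gamma)` grid is scored by mean stratified 5-fold
#' validation accuracy; ties break toward the smallest `C`, then the
#' smallest `gamma`.  The winner is refit on the full training split.
#'
#' @param X training feature matrix (rows = subjects).
#' @param y factor of labels with levels `HC`, `AD`; must be balanced
#'   enough for stratified folding.
#' @param grid list with `cost` and `gamma` candidate vectors (see
#'   [svmGrid()]).
#' @param foldSeed seed for the fold assignment (repetition-derived so
#'   experts sharing a repetition share folds).
#' @param view,layer provenance recorded in the model.
#' @param nFolds number of cross-validation folds.
#' @return An [ExpertModel-class].
#' @export
trainExpert <- function(X, y, grid = svmGrid(), foldSeed = 1,
                        view = "unknown", layer = "unknown", nFolds = 5L) {
  y <- factor(as.character(y), levels = c("HC", "AD"))
  if (any(table(y) < nFolds))
    stop("each class needs at least ", nFolds, " training subjects")
  scaler <- fitScaler(X)
  Xs <- applyScaler(X, scaler)
  gammas <- vapply(grid$gamma, resolveGamma, 0, Xs = Xs)
  ## deduplicate numerically identical gammas, keeping the smaller first
  gammas <- sort(unique(gammas))
  costs <- sort(as.numeric(grid$cost))
  folds <- stratifiedFolds(y, nFolds, foldSeed)
  D2 <- crossDist2(Xs, Xs)
  res <- NULL
  for (g in gammas) {
    K <- exp(-g * D2)
    for (cst in costs) {
      accs <- vapply(seq_len(nFolds), function(f) {
        tr <- folds != f; va <- !tr
        fit <- ksvmOnKernel(K[tr, tr, drop = FALSE], y[tr], cst)
        mean(predictOnKernel(fit, K[va, tr, drop = FALSE]) == y[va])
      }, 0)
      res <- rbind(res, data.frame(cost = cst, gamma = g, acc = mean(accs)))
    }
  }
  ## winner: highest mean validation accuracy; ties toward the smallest
  ## cost, then the smallest gamma
  best <- res[order(-res$acc, res$cost, res$gamma), ][1, ]
  K <- exp(-best$gamma * D2)
  fit <- ksvmOnKernel(K, y, best$cost)
  new("ExpertModel", view = view, layer = layer,
      center = scaler$center, scale = scaler$scale,
      trainData = Xs, trainLabels = y, fit = fit,
      cost = best$cost, gamma = best$gamma, cvAccuracy = best$acc)
}

#' Per-subject decisions of a trained expert
#'
#' @param model an [ExpertModel-class].
#' @param X feature matrix of new subjects (same layer and dimension).
#' @return Factor of decisions with levels `HC`, `AD`.
#' @export
predictExpert <- function(model, X) {
  Xs <- applyScaler(X, list(center = model@center, scale = model@scale))
  K <- exp(-model@gamma * crossDist2(Xs, model@trainData))
  predictOnKernel(model@fit, K)
}

#' Evaluate an expert on a held-out test set
#'
#' @param model an [ExpertModel-class].
#' @param X,y test features and labels (disjoint from training subjects).
#' @return A [ConfusionCounts-class] with AD as the positive class.
#' @export
evaluateExpert <- function(model, X, y) {
  if (!nrow(X)) stop("empty test set")
  ConfusionCounts(pred = predictExpert(model, X), truth = y)
}

#' Accuracy, sensitivity and specificity of a confusion table
#'
#' Sensitivity is the percentage of AD subjects classified AD,
#' specificity the percentage of HC classified HC.
#'
#' @param counts a [ConfusionCounts-class].
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   in percent.
#' @examples
#' computeMetrics(ConfusionCounts(tp = 8, fn = 2, tn = 9, fp = 1))
#' @export
computeMetrics <- function(counts) {
  tp <- counts@tp; fn <- counts@fn; tn <- counts@tn; fp <- counts@fp
  if (tp + fn == 0) stop("no AD subjects in the test set")
  if (tn + fp == 0) stop("no HC subjects in the test set")
  c(accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}

#' Aggregate per-repetition confusion counts
#'
#' @param countsList list of [ConfusionCounts-class], one per repetition.
#' @return An [EvalResult-class] with the mean and population standard
#'   deviation of each percent metric across repetitions.
#' @export
aggregateResults <- function(countsList) {
  if (!length(countsList)) stop("no repetitions to aggregate")
  M <- t(vapply(countsList, computeMetrics, numeric(3)))
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  new("EvalResult", perRep = countsList,
      summary = data.frame(metric = colnames(M),
                           mean = colMeans(M),
                           sd = apply(M, 2, popSd),
                           row.names = NULL))
}

## Repetition-derived CV fold seed, shared by all experts of a run.
repFoldSeed <- function(masterSeed, rep) childSeed(masterSeed, 1000 + rep)

#' Run the full single-expert protocol over a sampling plan
#'
#' For every repetition: standardize on the training split, grid-search
#' the SVM, refit, and score the held-out subjects.
#'
#' @param X feature matrix with rownames = subject ids.
#' @param labels named character/factor of subject labels (`HC`/`AD`).
#' @param plan a [SamplingPlan-class].
#' @param grid hyperparameter grid, see [svmGrid()].
#' @param view,layer provenance.
#' @return list with `result` (an [EvalResult-class]), `decisions` (one
#'   data.frame of per-subject test decisions per repetition) and
#'   `params` (chosen `C`/`gamma` per repetition).
#' @export
runExpertEvaluation <- function(X, labels, plan, grid = svmGrid(),
                                view = "unknown", layer = "unknown") {
  labels <- setNames(as.character(labels), names(labels) %||% rownames(X))
  counts <- list(); decisions <- list(); params <- list()
  for (r in seq_along(planRepetitions(plan))) {
    rep <- planRepetitions(plan)[[r]]
    missing <- setdiff(c(rep$trainIds, rep$testIds), rownames(X))
    if (length(missing))
      stop("features missing for subjects: ", paste(missing, collapse = ", "))
    model <- trainExpert(X[rep$trainIds, , drop = FALSE], rep$trainLabels,
                         grid = grid, foldSeed = repFoldSeed(plan@masterSeed, r),
                         view = view, layer = layer)
    pred <- predictExpert(model, X[rep$testIds, , drop = FALSE])
    counts[[r]] <- ConfusionCounts(pred = pred, truth = rep$testLabels)
    decisions[[r]] <- data.frame(id = rep$testIds,
                                 truth = as.character(rep$testLabels),
                                 pred = as.character(pred),
                                 stringsAsFactors = FALSE)
    params[[r]] <- data.frame(repetition = r, cost = model@cost,
                              gamma = model@gamma,
                              cvAccuracy = model@cvAccuracy)
  }
  list(result = aggregateResults(counts), decisions = decisions,
       params = do.call(rbind, params))
}
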
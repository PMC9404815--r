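hcIds <- sprintf("HC%03d", 1:45)
adIds <- sprintf("AD%03d", 1:30)

test_that("the default plan gives 20+20 train and 10+10 test per repetition", {
  plan <- makeSamplingPlan(hcIds, adIds, masterSeed = 3)
  expect_length(planRepetitions(plan), 10)
  for (rep in planRepetitions(plan)) {
    expect_length(rep$trainIds, 40)
    expect_length(rep$testIds, 20)
    expect_equal(as.vector(table(rep$trainLabels)), c(20, 20))
    expect_equal(as.vector(table(rep$testLabels)), c(10, 10))
    expect_length(intersect(rep$trainIds, rep$testIds), 0)
    # the HC pool of a repetition is a 30-subject subsample
    hcUsed <- grep("^HC", c(rep$trainIds, rep$testIds), value = TRUE)
    expect_lte(length(unique(hcUsed)), 30)
  }
})

test_that("the same master seed reproduces the plan; plans are label-consistent", {
  p1 <- makeSamplingPlan(hcIds, adIds, masterSeed = 99)
  p2 <- makeSamplingPlan(hcIds, adIds, masterSeed = 99)
  expect_identical(planRepetitions(p1), planRepetitions(p2))
  for (rep in planRepetitions(p1)) {
    expect_true(all(grepl("^HC", rep$trainIds[rep$trainLabels == "HC"])))
    expect_true(all(grepl("^AD", rep$testIds[rep$testLabels == "AD"])))
  }
  expect_error(makeSamplingPlan(hcIds[1:20], adIds), "insufficient")
})

test_that("toy blobs train to perfect training accuracy; size-1 grid is chosen", {
  set.seed(10)
  X <- rbind(matrix(rnorm(20 * 5, mean = 0), 20),
             matrix(rnorm(20 * 5, mean = 8), 20))
  rownames(X) <- c(sprintf("HC%03d", 1:20), sprintf("AD%03d", 1:20))
  y <- factor(rep(c("HC", "AD"), each = 20), levels = c("HC", "AD"))
  m <- trainExpert(X, y, grid = list(cost = 1, gamma = 0.1), foldSeed = 5)
  expect_equal(m@cost, 1)
  expect_equal(m@gamma, 0.1)
  expect_equal(as.character(predictExpert(m, X)), as.character(y))
  cc <- evaluateExpert(m, X, y)  # training set reused purely as a sanity check
  expect_equal(computeMetrics(cc)[["accuracy"]], 100)
})

test_that("grid-search winner matches an independent rbfdot CV loop", {
  # oracle: kernlab with its own built-in RBF kernel on raw standardized
  # features, folds and selection logic coded from scratch
  set.seed(20)
  X <- rbind(matrix(rnorm(20 * 6, mean = 0), 20),
             matrix(rnorm(20 * 6, mean = 1.2), 20))
  y <- factor(rep(c("HC", "AD"), each = 20), levels = c("HC", "AD"))
  grid <- list(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1))
  foldSeed <- 17
  m <- trainExpert(X, y, grid = grid, foldSeed = foldSeed)

  Xs <- scale(X)
  folds <- spiralAD:::stratifiedFolds(y, 5, foldSeed)
  res <- expand.grid(cost = grid$cost, gamma = grid$gamma)
  res$acc <- NA
  for (j in seq_len(nrow(res))) {
    accs <- numeric(5)
    for (f in 1:5) {
      tr <- folds != f
      fit <- kernlab::ksvm(Xs[tr, ], y[tr], type = "C-svc", C = res$cost[j],
                           kernel = "rbfdot",
                           kpar = list(sigma = res$gamma[j]), scaled = FALSE)
      accs[f] <- mean(kernlab::predict(fit, Xs[!tr, ]) == y[!tr])
    }
    res$acc[j] <- mean(accs)
  }
  res <- res[order(-res$acc, res$cost, res$gamma), ]
  expect_equal(m@cost, res$cost[1])
  expect_equal(m@gamma, res$gamma[1])
  expect_equal(m@cvAccuracy, res$acc[1], tolerance = 1e-12)
})

test_that("confusion counts match a hand tally on random prediction vectors", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    truth <- sample(c("AD", "HC"), n, replace = TRUE)
    pred <- sample(c("AD", "HC"), n, replace = TRUE)
    cc <- ConfusionCounts(pred = pred, truth = truth)
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (k in seq_len(n)) {
      if (truth[k] == "AD") { if (pred[k] == "AD") tp <- tp + 1 else fn <- fn + 1 }
      else { if (pred[k] == "HC") tn <- tn + 1 else fp <- fp + 1 }
    }
    expect_equal(c(cc@tp, cc@fn, cc@tn, cc@fp), c(tp, fn, tn, fp))
  }
})

test_that("metric formulas match hand-derived values and the definitions", {
  m <- computeMetrics(ConfusionCounts(tp = 8, fn = 2, tn = 9, fp = 1))
  expect_equal(unname(m), c(85, 80, 90))
  expect_equal(unname(computeMetrics(ConfusionCounts(tp = 10, fn = 0,
                                                     tn = 10, fp = 0))),
               c(100, 100, 100))
  # inverted predictions: nothing right
  inv <- computeMetrics(ConfusionCounts(tp = 0, fn = 10, tn = 0, fp = 10))
  expect_equal(unname(inv), c(0, 0, 0))
  set.seed(40)
  for (i in 1:100) {
    cc <- ConfusionCounts(tp = sample(1:20, 1), fn = sample(0:20, 1),
                          tn = sample(1:20, 1), fp = sample(0:20, 1))
    m <- computeMetrics(cc)
    expect_equal(m[["sensitivity"]], 100 * cc@tp / (cc@tp + cc@fn))
    expect_equal(m[["specificity"]], 100 * cc@tn / (cc@tn + cc@fp))
    expect_equal(m[["accuracy"]],
                 100 * (cc@tp + cc@tn) / (cc@tp + cc@fn + cc@tn + cc@fp))
  }
  expect_error(computeMetrics(ConfusionCounts(tp = 0, fn = 0, tn = 5, fp = 5)),
               "no AD")
})

test_that("aggregation reports mean and population SD in percent", {
  ten <- replicate(10, ConfusionCounts(tp = 9, fn = 1, tn = 8, fp = 2),
                   simplify = FALSE)
  r <- aggregateResults(ten)
  s <- resultSummary(r)
  expect_equal(s$sd, rep(0, 3))
  two <- list(ConfusionCounts(tp = 7, fn = 3, tn = 7, fp = 3),   # 70 %
              ConfusionCounts(tp = 9, fn = 1, tn = 9, fp = 1))   # 90 %
  s2 <- resultSummary(aggregateResults(two))
  expect_equal(s2$mean[s2$metric == "accuracy"], 80)
  expect_equal(s2$sd[s2$metric == "accuracy"], 10)  # population SD
  # brute-force recomputation on random repetitions
  set.seed(50)
  reps <- replicate(6, ConfusionCounts(tp = sample(1:10, 1), fn = sample(1:10, 1),
                                       tn = sample(1:10, 1), fp = sample(1:10, 1)),
                    simplify = FALSE)
  accs <- vapply(reps, function(cc) computeMetrics(cc)[["accuracy"]], 0)
  s3 <- resultSummary(aggregateResults(reps))
  expect_equal(s3$mean[s3$metric == "accuracy"], mean(accs))
  expect_equal(s3$sd[s3$metric == "accuracy"],
               sqrt(mean((accs - mean(accs))^2)))
})

test_that("scaler statistics are blind to test-set perturbations", {
  set.seed(60)
  X <- matrix(rnorm(40 * 8), 40)
  rownames(X) <- c(sprintf("HC%03d", 1:20), sprintf("AD%03d", 1:20))
  y <- factor(rep(c("HC", "AD"), each = 20), levels = c("HC", "AD"))
  m <- trainExpert(X, y, grid = list(cost = 1, gamma = 0.1), foldSeed = 2)
  Xtest <- matrix(rnorm(10 * 8), 10)
  p1 <- predictExpert(m, Xtest)
  m2 <- trainExpert(X, y, grid = list(cost = 1, gamma = 0.1), foldSeed = 2)
  expect_identical(m@center, m2@center)  # training untouched by any test data
  expect_identical(as.character(p1), as.character(predictExpert(m2, Xtest)))
})
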
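# Vote-count oracle.
oracleVote <- function(row) {
  nAD <- sum(row == "AD"); nHC <- sum(row == "HC")
  if (nAD > nHC) "AD" else "HC"
}

test_that("majority vote equals exhaustive counting on all 3-expert patterns", {
  pats <- expand.grid(e1 = c("AD", "HC"), e2 = c("AD", "HC"),
                      e3 = c("AD", "HC"), stringsAsFactors = FALSE)
  fused <- majorityVote(as.matrix(pats))
  expect_identical(fused, apply(as.matrix(pats), 1, oracleVote))
  expect_identical(majorityVote(matrix(c("AD", "AD", "AD"), 1)), "AD")
  expect_identical(majorityVote(matrix(c("AD", "HC", "AD"), 1)), "AD")
})

test_that("majority vote matches the oracle on random nine-expert patterns", {
  set.seed(70)
  M <- matrix(sample(c("AD", "HC"), 500 * 9, replace = TRUE), 500, 9)
  expect_identical(majorityVote(M), apply(M, 1, oracleVote))
  # permutation invariance in expert order
  perm <- sample(9)
  expect_identical(majorityVote(M[, perm]), majorityVote(M))
})

test_that("an even expert count is a configuration error", {
  expect_error(majorityVote(matrix(c("AD", "HC"), 1)), "odd")
  expect_error(FusionScheme(c("pressure", "velocity"), "Conv3"), "odd")
})

# Small synthetic feature store shared by the fusion-protocol tests:
# class-separated Gaussian blobs so experts are reliable.
makeToyStore <- function(p = 6) {
  set.seed(80)
  ids <- c(sprintf("HC%03d", 1:14), sprintf("AD%03d", 1:14))
  lab <- rep(c(0, 1), each = 14)
  store <- list()
  for (key in c("pressure:Conv3", "altitude:Conv3", "velocity:Conv3")) {
    X <- matrix(rnorm(28 * p), 28) + outer(lab, rep(3, p))
    rownames(X) <- ids
    store[[key]] <- X
  }
  list(store = store,
       labels = setNames(rep(c("HC", "AD"), each = 14), ids))
}

toyPlan <- function(seed = 5) {
  makeSamplingPlan(sprintf("HC%03d", 1:14), sprintf("AD%03d", 1:14),
                   nReps = 3, masterSeed = seed, nSubsample = 14,
                   nTrainPerClass = 7, nTestPerClass = 4)
}

test_that("fusing three identical experts reproduces the single expert", {
  toy <- makeToyStore()
  store <- toy$store
  store[["altitude:Conv3"]] <- store[["pressure:Conv3"]]
  store[["velocity:Conv3"]] <- store[["pressure:Conv3"]]
  plan <- toyPlan()
  grid <- list(cost = c(1, 10), gamma = 0.1)
  fused <- runDecisionFusion(FusionScheme(c("pressure", "altitude", "velocity"),
                                          "Conv3"), plan, store, grid)
  single <- runExpertEvaluation(store[["pressure:Conv3"]], toy$labels, plan,
                                grid, view = "pressure", layer = "Conv3")
  expect_identical(resultSummary(fused$fused), resultSummary(single$result))
})

test_that("a perfect expert is overruled by two anti-perfect experts", {
  truth <- rep(c("HC", "AD"), each = 4)
  perfect <- truth
  anti <- ifelse(truth == "AD", "HC", "AD")
  dec <- cbind(perfect, anti, anti)
  fused <- majorityVote(dec)
  cc <- ConfusionCounts(pred = fused, truth = truth)
  expect_equal(computeMetrics(cc)[["accuracy"]], 0)
})

test_that("fused summary metrics equal metrics of the fused confusion table", {
  toy <- makeToyStore()
  plan <- toyPlan(7)
  grid <- list(cost = 1, gamma = 0.1)
  out <- runDecisionFusion(FusionScheme(c("pressure", "altitude", "velocity"),
                                        "Conv3"), plan, toy$store, grid)
  # replay the stored per-subject decisions through the vote oracle
  for (r in seq_along(out$decisions)) {
    d <- out$decisions[[r]]
    replay <- apply(as.matrix(d[, grep(":Conv3", names(d))]), 1, oracleVote)
    expect_identical(unname(replay), d$fused)
    cc <- out$fused@perRep[[r]]
    expect_equal(cc@tp, sum(d$fused == "AD" & d$truth == "AD"))
    expect_equal(cc@tn, sum(d$fused == "HC" & d$truth == "HC"))
  }
  # internal consistency of the aggregated table
  s <- resultSummary(out$fused)
  accs <- vapply(out$fused@perRep, function(cc) computeMetrics(cc)[["accuracy"]], 0)
  expect_equal(s$mean[s$metric == "accuracy"], mean(accs))
  # missing scheme member is a clear error
  expect_error(runDecisionFusion(FusionScheme(c("pressure", "altitude",
                                                "acceleration"), "Conv3"),
                                 plan, toy$store, grid),
               "acceleration:Conv3")
})

test_that("low-level fusion of identical views runs and matches schema", {
  set.seed(90)
  ids <- c(sprintf("HC%03d", 1:8), sprintf("AD%03d", 1:8))
  labels <- setNames(rep(c("HC", "AD"), each = 8), ids)
  mkImg <- function(id, dark) {
    px <- matrix(255L, 64, 64)
    px[20:44, 20:44] <- as.integer(dark)
    new("GrayImage", pixels = px, view = "pressure", subjectId = id,
        meta = list())
  }
  # class-contrasted patch intensity
  views <- list()
  for (v in c("pressure", "altitude", "velocity"))
    views[[v]] <- setNames(lapply(ids, function(id)
      { im <- mkImg(id, if (startsWith(id, "AD")) 0 else 180); im@view <- v; im }),
      ids)
  plan <- makeSamplingPlan(sprintf("HC%03d", 1:8), sprintf("AD%03d", 1:8),
                           nReps = 2, masterSeed = 4, nSubsample = 8,
                           nTrainPerClass = 5, nTestPerClass = 3)
  out <- runLowLevelFusion(views, plan, "Conv1",
                           config = ExtractorConfig(seed = 12),
                           grid = list(cost = 1, gamma = "scale"),
                           labels = labels)
  s <- resultSummary(out$result)
  expect_setequal(s$metric, c("accuracy", "sensitivity", "specificity"))
  expect_true(all(s$mean >= 0 & s$mean <= 100))
  expect_true(all(s$sd >= 0))
  # strongly contrasted constant patches separate perfectly
  expect_equal(s$mean[s$metric == "accuracy"], 100)
})
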
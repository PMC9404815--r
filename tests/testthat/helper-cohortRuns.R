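# Memoized full-pipeline cohort runs shared by the acceptance tests: one
# synthetic cohort (45 HC / 30 AD) -> pressure/altitude/velocity hybrid
# views -> Conv3 features (seeded random weights) -> three SVM experts
# under the balanced resampling protocol -> majority-vote fusion.
.cohortRunCache <- new.env(parent = emptyenv())

fusionCohortRun <- function(eps, cohortSeed, nReps = 10) {
  key <- sprintf("eps%s_seed%d_reps%d", format(eps), cohortSeed, nReps)
  hit <- .cohortRunCache[[key]]
  if (!is.null(hit)) return(hit)
  coh <- generateCohort(CohortConfig(effectSize = eps, seed = cohortSeed))
  rc <- RenderConfig()
  ec <- ExtractorConfig(seed = 2024)
  viewsWanted <- c("pressure", "altitude", "velocity")
  store <- list()
  for (v in viewsWanted) {
    stats <- fitNormalization(coh$streams, v, config = rc)
    imgs <- lapply(coh$streams, renderHybrid, parameter = v, stats = stats,
                   config = rc)
    store[[featureKey(v, "Conv3")]] <- extractFeatureMatrix(imgs, "Conv3", ec)
  }
  labels <- coh$labels
  plan <- makeSamplingPlan(names(labels)[labels == "HC"],
                           names(labels)[labels == "AD"],
                           nReps = nReps, masterSeed = cohortSeed)
  res <- runDecisionFusion(FusionScheme(viewsWanted, "Conv3"), plan, store)
  s <- resultSummary(res$fused)
  out <- list(accuracy = s$mean[s$metric == "accuracy"],
              sensitivity = s$mean[s$metric == "sensitivity"],
              specificity = s$mean[s$metric == "specificity"],
              fused = res$fused)
  .cohortRunCache[[key]] <- out
  out
}
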
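## Majority-vote decision fusion across SVM experts, and orchestration of
## low-level (input-channel) fusion.
##
## Every expert of a fusion run shares the same SamplingPlan and the same
## per-repetition CV fold seeds, so decisions align subject-by-subject
## and the vote is well defined.  Decision fusion requires an odd expert
## count (the reference configurations use 3 or 9 experts), which removes
## the need for a tie rule.

#' Majority vote over expert decisions
#'
#' @param decisions matrix or data.frame of class decisions (`"AD"` /
#'   `"HC"`), one row per subject, one column per expert; the expert
#'   count must be odd.
#' @return Character vector of fused decisions, the class with strictly
#'   more votes.
#' @examples
#' majorityVote(cbind(c("AD", "HC"), c("AD", "AD"), c("HC", "HC")))
#' @export
majorityVote <- function(decisions) {
  decisions <- as.matrix(decisions)
  K <- ncol(decisions)
  if (K %% 2L == 0L)
    stop("configuration error: majority vote requires an odd expert count")
  votesAD <- rowSums(decisions == "AD")
  ifelse(votesAD > K / 2, "AD", "HC")
}

#' Key under which a (view, layer) feature matrix lives in a store
#'
#' @param view,layer view and layer tags.
#' @return Character key `"view:layer"`.
#' @export
featureKey <- function(view, layer) paste(view, layer, sep = ":")

#' Run decision fusion over a feature store
#'
#' Per repetition, each `(view, layer)` expert of the scheme is trained
#' and tested independently on the shared subject split; the per-subject
#' test decisions are then fused by majority vote and scored like a
#' single expert.
#'
#' @param scheme a [FusionScheme()] (odd expert count).
#' @param plan a [SamplingPlan-class] shared by all experts.
#' @param store named list mapping `"view:layer"` to a feature matrix
#'   with rownames = subject ids (see [featureKey()]).
#' @param grid hyperparameter grid, see [svmGrid()].
#' @return list with `fused` (an [EvalResult-class]), `experts` (named
#'   list of per-expert [EvalResult-class]) and `decisions` (per-repetition
#'   data.frames of per-subject expert and fused decisions).
#' @export
runDecisionFusion <- function(scheme, plan, store, grid = svmGrid()) {
  validObject(scheme)
  ex <- scheme@experts
  keys <- featureKey(ex$view, ex$layer)
  missing <- setdiff(keys, names(store))
  if (length(missing))
    stop("features missing for scheme members: ",
         paste(missing, collapse = ", "))
  fusedCounts <- list(); decisionLog <- list()
  expertCounts <- replicate(nrow(ex), list())
  for (r in seq_along(planRepetitions(plan))) {
    rep <- planRepetitions(plan)[[r]]
    dec <- matrix(NA_character_, length(rep$testIds), nrow(ex))
    for (e in seq_len(nrow(ex))) {
      X <- store[[keys[e]]]
      model <- trainExpert(X[rep$trainIds, , drop = FALSE], rep$trainLabels,
                           grid = grid,
                           foldSeed = repFoldSeed(plan@masterSeed, r),
                           view = ex$view[e], layer = ex$layer[e])
      pred <- predictExpert(model, X[rep$testIds, , drop = FALSE])
      dec[, e] <- as.character(pred)
      expertCounts[[e]][[r]] <- ConfusionCounts(pred = pred,
                                                truth = rep$testLabels)
    }
    fused <- majorityVote(dec)
    fusedCounts[[r]] <- ConfusionCounts(pred = fused,
                                        truth = rep$testLabels)
    df <- data.frame(id = rep$testIds, truth = as.character(rep$testLabels),
                     stringsAsFactors = FALSE)
    colnames(dec) <- keys
    decisionLog[[r]] <- cbind(df, dec, fused = fused)
  }
  experts <- lapply(expertCounts, aggregateResults)
  names(experts) <- keys
  list(fused = aggregateResults(fusedCounts), experts = experts,
       decisions = decisionLog)
}

#' Run low-level (input-channel) fusion
#'
#' The three hybrid views of each subject are composed into the three
#' input channels of a single image; one feature extraction per subject
#' and one SVM expert then follow the standard protocol.
#'
#' @param views named list of per-view image lists (each a list of
#'   [GrayImage-class] indexed by subject); must contain the three views
#'   in `order`.
#' @param plan a [SamplingPlan-class].
#' @param layer tap to extract.
#' @param config an [ExtractorConfig()].
#' @param grid hyperparameter grid.
#' @param labels named vector of subject labels (`HC`/`AD`).
#' @param order channel order, default pressure, altitude, velocity.
#' @return As [runExpertEvaluation()].
#' @export
runLowLevelFusion <- function(views, plan, layer, config = ExtractorConfig(),
                              grid = svmGrid(), labels,
                              order = c("pressure", "altitude", "velocity")) {
  missing <- setdiff(order, names(views))
  if (length(missing))
    stop("missing rendered views: ", paste(missing, collapse = ", "))
  ids <- names(views[[order[1]]])
  composites <- lapply(ids, function(id) {
    composeChannels(lapply(setNames(order, order),
                           function(v) views[[v]][[id]]), order = order)
  })
  X <- extractFeatureMatrix(composites, layer, config, ids = ids)
  runExpertEvaluation(X, labels[ids], plan, grid = grid,
                      view = "composite", layer = layer)
}
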
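## S4 containers for the spiral-analysis pipeline.

#' PenStream: one subject's digitizer recording
#'
#' Time-ordered samples of an online pen recording: position `x`/`y`
#' (tablet units), pressure `p` (device units, 0 while in air), azimuth
#' `az` (degrees, \[0, 360)), altitude `alt` (degrees, \[0, 90\]) and a
#' pen-down flag.  Time `t` is in seconds from stream start and must be
#' strictly increasing.
#'
#' @slot subjectId opaque subject identifier.
#' @slot label class label, one of `"AD"`, `"HC"`, `"unknown"`.
#' @slot samples `data.frame` with columns `t, x, y, p, az, alt, penDown`.
#' @slot sampleRateHz nominal acquisition rate (125 Hz for the Wacom
#'   protocol this models).
#' @exportClass PenStream
setClass("PenStream", representation(
  subjectId = "character",
  label = "character",
  samples = "data.frame",
  sampleRateHz = "numeric"
))

setValidity("PenStream", function(object) {
  msg <- character()
  s <- object@samples
  need <- c("t", "x", "y", "p", "az", "alt", "penDown")
  if (!all(need %in% names(s)))
    return(paste("samples must have columns", paste(need, collapse = ", ")))
  if (!object@label %in% c("AD", "HC", "unknown"))
    msg <- c(msg, "label must be one of 'AD', 'HC', 'unknown'")
  if (nrow(s) > 1 && any(diff(s$t) <= 0))
    msg <- c(msg, "t must be strictly increasing")
  if (any(s$p < 0)) msg <- c(msg, "pressure must be >= 0")
  if (any(!s$penDown & s$p != 0))
    msg <- c(msg, "pressure must be 0 on pen-up samples")
  if (any(s$alt < 0 | s$alt > 90))
    msg <- c(msg, "altitude must lie in [0, 90]")
  if (any(s$az < 0 | s$az >= 360))
    msg <- c(msg, "azimuth must lie in [0, 360)")
  if (!is.logical(s$penDown)) msg <- c(msg, "penDown must be logical")
  if (length(msg)) msg else TRUE
})

#' Construct a PenStream
#'
#' @param samples data.frame with columns `t, x, y, p, az, alt, penDown`.
#' @param subjectId subject identifier string.
#' @param label `"AD"`, `"HC"` or `"unknown"`.
#' @param sampleRateHz nominal sampling rate in Hz.
#' @return A validated [PenStream-class] object.
#' @examples
#' s <- data.frame(t = 0:2 / 125, x = c(0, 1, 2), y = 0, p = c(500, 510, 505),
#'                 az = 90, alt = 60, penDown = TRUE)
#' PenStream(s, subjectId = "demo")
#' @export
PenStream <- function(samples, subjectId = "anonymous", label = "unknown",
                      sampleRateHz = 125) {
  rownames(samples) <- NULL
  samples$penDown <- as.logical(samples$penDown)
  new("PenStream", subjectId = subjectId, label = label,
      samples = samples, sampleRateHz = sampleRateHz)
}

#' KinematicSeries: per-sample velocity or acceleration magnitudes
#'
#' @slot parameter `"velocity"` or `"acceleration"`.
#' @slot values nonnegative magnitudes, one per sample of the source
#'   stream (trailing values replicated so lengths match).
#' @exportClass KinematicSeries
setClass("KinematicSeries", representation(
  parameter = "character", values = "numeric"))

setValidity("KinematicSeries", function(object) {
  if (!object@parameter %in% c("velocity", "acceleration"))
    return("parameter must be 'velocity' or 'acceleration'")
  if (any(object@values < 0)) return("magnitudes must be >= 0")
  TRUE
})

## Admissible dynamic parameters for hybrid views.
DYNAMIC_PARAMETERS <- c("pressure", "altitude", "velocity", "acceleration")

#' NormalizationStats: population min-max for one dynamic parameter
#'
#' @slot parameter one of `"pressure"`, `"altitude"`, `"velocity"`,
#'   `"acceleration"`.
#' @slot minValue,maxValue population extrema over all rendered points.
#' @slot scope `"all_subjects"` (the reference protocol) or `"train_only"`.
#' @slot degenerate TRUE when max == min; all values then map to white.
#' @exportClass NormalizationStats
setClass("NormalizationStats", representation(
  parameter = "character", minValue = "numeric", maxValue = "numeric",
  scope = "character", degenerate = "logical"))

setValidity("NormalizationStats", function(object) {
  if (!object@parameter %in% DYNAMIC_PARAMETERS)
    return("unknown dynamic parameter")
  if (!object@scope %in% c("all_subjects", "train_only"))
    return("scope must be 'all_subjects' or 'train_only'")
  if (object@minValue > object@maxValue) return("minValue > maxValue")
  TRUE
})

#' RenderConfig: rasterization settings
#'
#' @slot canvasPx canvas side length in pixels (>= 64).
#' @slot marginFrac blank margin as a fraction of the canvas, in \[0, 0.5).
#' @slot strokePx stroke width in pixels (>= 1).
#' @slot includePenups named logical, one entry per dynamic parameter:
#'   whether in-air samples are rendered for that view.  Pressure defaults
#'   to FALSE (in-air pressure is identically zero and is not drawn, which
#'   is what produces the characteristic broken trajectories).
#' @slot connectSegments draw thick segments between consecutive rendered
#'   samples (FALSE gives a dots-only rendering for ablation).
#' @exportClass RenderConfig
setClass("RenderConfig", representation(
  canvasPx = "integer", marginFrac = "numeric", strokePx = "numeric",
  includePenups = "logical", connectSegments = "logical"))

setValidity("RenderConfig", function(object) {
  if (object@canvasPx < 64L) return("canvasPx must be >= 64")
  if (object@marginFrac < 0 || object@marginFrac >= 0.5)
    return("marginFrac must lie in [0, 0.5)")
  if (object@strokePx < 1) return("strokePx must be >= 1")
  if (!all(DYNAMIC_PARAMETERS %in% names(object@includePenups)))
    return("includePenups must be named for all four dynamic parameters")
  TRUE
})

#' Construct a RenderConfig
#'
#' @param canvasPx canvas side in pixels.
#' @param marginFrac fractional margin left blank.
#' @param strokePx stroke width in pixels.
#' @param includePenups named logical vector over the four dynamic
#'   parameters; defaults render in-air samples for altitude, velocity and
#'   acceleration but never for pressure.
#' @param connectSegments connect consecutive rendered samples.
#' @return A [RenderConfig-class] object.
#' @export
RenderConfig <- function(canvasPx = 512L, marginFrac = 0.05, strokePx = 3,
                         includePenups = c(pressure = FALSE, altitude = TRUE,
                                           velocity = TRUE, acceleration = TRUE),
                         connectSegments = TRUE) {
  new("RenderConfig", canvasPx = as.integer(canvasPx), marginFrac = marginFrac,
      strokePx = strokePx, includePenups = includePenups,
      connectSegments = connectSegments)
}

#' GrayImage: rasterized spiral trajectory
#'
#' @slot pixels integer matrix (rows = image rows top-to-bottom), values in
#'   \[0, 255\]; 255 is the white background.
#' @slot view `"raw"` or one of the four dynamic parameters.
#' @slot subjectId provenance.
#' @slot meta list of rendering metadata (`degenerate`, `nClipped`).
#' @exportClass GrayImage
setClass("GrayImage", representation(
  pixels = "matrix", view = "character", subjectId = "character",
  meta = "list"))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (nrow(p) != ncol(p)) return("pixel matrix must be square")
  if (any(p < 0 | p > 255)) return("pixel values must lie in [0, 255]")
  if (!object@view %in% c("raw", DYNAMIC_PARAMETERS))
    return("unknown view")
  TRUE
})

#' ExtractorConfig: deep feature extraction settings
#'
#' @slot inputPx network input side, 224 (default) or 227.
#' @slot weightsMode `"pretrained"` or `"random_seeded"`.
#' @slot seed integer seed for `"random_seeded"` weights.
#' @slot channelMean,channelSd per-channel normalization applied after
#'   scaling pixel values to \[0, 1\].
#' @exportClass ExtractorConfig
setClass("ExtractorConfig", representation(
  inputPx = "integer", weightsMode = "character", seed = "numeric",
  channelMean = "numeric", channelSd = "numeric"))

setValidity("ExtractorConfig", function(object) {
  if (!object@inputPx %in% c(224L, 227L)) return("inputPx must be 224 or 227")
  if (!object@weightsMode %in% c("pretrained", "random_seeded"))
    return("weightsMode must be 'pretrained' or 'random_seeded'")
  if (object@weightsMode == "random_seeded" &&
      (length(object@seed) != 1L || is.na(object@seed)))
    return("random_seeded mode requires a seed")
  if (length(object@channelMean) != 3L || length(object@channelSd) != 3L)
    return("channelMean/channelSd must have length 3")
  TRUE
})

#' Construct an ExtractorConfig
#'
#' @param inputPx network input side (224 or 227).
#' @param weightsMode `"random_seeded"` (self-contained, reproducible) or
#'   `"pretrained"` (requires externally supplied weights).
#' @param seed seed for the random weights.
#' @param channelMean,channelSd per-channel normalization constants; the
#'   defaults are the ImageNet RGB statistics conventionally paired with
#'   this architecture.
#' @return An [ExtractorConfig-class] object.
#' @export
ExtractorConfig <- function(inputPx = 224L, weightsMode = "random_seeded",
                            seed = 2024,
                            channelMean = c(0.485, 0.456, 0.406),
                            channelSd = c(0.229, 0.224, 0.225)) {
  new("ExtractorConfig", inputPx = as.integer(inputPx),
      weightsMode = weightsMode, seed = seed,
      channelMean = channelMean, channelSd = channelSd)
}

## The six tap points of the feature extractor.
LAYER_TAGS <- c("Conv1", "Conv2", "Conv3", "Conv4", "Conv5", "fc7")

#' FeatureVector: flattened activation of one tapped layer
#'
#' @slot layer tap name (`Conv1`..`Conv5`, `fc7`).
#' @slot values flat numeric activation vector (channel-major, then row,
#'   then column within each channel plane).
#' @slot subjectId,view provenance strings.
#' @exportClass FeatureVector
setClass("FeatureVector", representation(
  layer = "character", values = "numeric",
  subjectId = "character", view = "character"))

setValidity("FeatureVector", function(object) {
  if (!object@layer %in% LAYER_TAGS) return("unknown layer tag")
  if (any(!is.finite(object@values))) return("all entries must be finite")
  TRUE
})

#' SamplingPlan: balanced repeated train/test subject assignment
#'
#' Each repetition subsamples the majority class down to the minority
#' size, then splits each class into a balanced train and test set.
#'
#' @slot repetitions list; each element has `trainIds`, `trainLabels`,
#'   `testIds`, `testLabels`.
#' @slot nReps number of repetitions.
#' @slot masterSeed seed the plan was drawn from.
#' @exportClass SamplingPlan
setClass("SamplingPlan", representation(
  repetitions = "list", nReps = "integer", masterSeed = "numeric"))

setValidity("SamplingPlan", function(object) {
  for (rep in object@repetitions) {
    if (length(intersect(rep$trainIds, rep$testIds)) > 0)
      return("train and test must be disjoint within a repetition")
  }
  if (length(object@repetitions) != object@nReps)
    return("nReps does not match repetitions")
  TRUE
})

#' ExpertModel: one trained RBF-SVM expert
#'
#' @slot view,layer which hybrid view and tap the expert reads.
#' @slot center,scale per-feature standardization fit on the training
#'   split only.
#' @slot trainData standardized training matrix (needed to evaluate the
#'   kernel against new subjects).
#' @slot trainLabels factor of training labels.
#' @slot fit kernlab `ksvm` object trained on the precomputed kernel.
#' @slot cost,gamma the grid-search winner.
#' @slot cvAccuracy mean 5-fold validation accuracy of the winner.
#' @exportClass ExpertModel
setClass("ExpertModel", representation(
  view = "character", layer = "character",
  center = "numeric", scale = "numeric",
  trainData = "matrix", trainLabels = "factor",
  fit = "ANY", cost = "numeric", gamma = "numeric",
  cvAccuracy = "numeric"))

#' ConfusionCounts: binary confusion table with AD as positive class
#'
#' @slot tp,fn,tn,fp nonnegative counts.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  tp = "integer", fn = "integer", tn = "integer", fp = "integer"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@fn, object@tn, object@fp) < 0))
    return("counts must be nonnegative")
  TRUE
})

#' Construct ConfusionCounts
#'
#' Either pass the four counts, or `pred` and `truth` factors/characters
#' with values in `{"AD", "HC"}` (AD is the positive class).
#'
#' @param tp,fn,tn,fp counts.
#' @param pred,truth per-subject decisions and true labels.
#' @return A [ConfusionCounts-class] object.
#' @export
ConfusionCounts <- function(tp = NULL, fn = NULL, tn = NULL, fp = NULL,
                            pred = NULL, truth = NULL) {
  if (!is.null(pred)) {
    pred <- as.character(pred); truth <- as.character(truth)
    stopifnot(length(pred) == length(truth))
    tp <- sum(pred == "AD" & truth == "AD")
    fn <- sum(pred == "HC" & truth == "AD")
    tn <- sum(pred == "HC" & truth == "HC")
    fp <- sum(pred == "AD" & truth == "HC")
  }
  new("ConfusionCounts", tp = as.integer(tp), fn = as.integer(fn),
      tn = as.integer(tn), fp = as.integer(fp))
}

#' EvalResult: per-repetition confusion counts plus aggregated metrics
#'
#' @slot perRep list of [ConfusionCounts-class], one per repetition.
#' @slot summary data.frame with columns `metric, mean, sd` (percent;
#'   population standard deviation across repetitions).
#' @exportClass EvalResult
setClass("EvalResult", representation(
  perRep = "list", summary = "data.frame"))

#' FusionScheme: a set of experts combined by majority vote
#'
#' @slot experts data.frame with columns `view`, `layer`, one row per
#'   expert.
#' @slot mode `"single_layer_multi_view"`, `"multi_layer_single_view"`,
#'   `"multi_layer_multi_view"` or `"low_level"`.
#' @exportClass FusionScheme
setClass("FusionScheme", representation(
  experts = "data.frame", mode = "character"))

setValidity("FusionScheme", function(object) {
  modes <- c("single_layer_multi_view", "multi_layer_single_view",
             "multi_layer_multi_view", "low_level")
  if (!object@mode %in% modes) return("unknown fusion mode")
  if (object@mode != "low_level" && nrow(object@experts) %% 2L == 0L)
    return("decision-fusion schemes require an odd expert count")
  TRUE
})

#' Construct a FusionScheme
#'
#' @param views,layers recycled to equal length; one (view, layer) pair
#'   per expert.
#' @param mode fusion mode; decision fusion requires an odd expert count.
#' @return A [FusionScheme-class] object.
#' @examples
#' FusionScheme(c("pressure", "altitude", "velocity"), "Conv3")
#' @export
FusionScheme <- function(views, layers, mode = "single_layer_multi_view") {
  experts <- data.frame(view = views, layer = layers,
                        stringsAsFactors = FALSE)
  new("FusionScheme", experts = experts, mode = mode)
}

#' SubjectProfile: generative parameters for one synthetic writer
#'
#' @slot params named numeric vector; see [subjectProfile()].
#' @exportClass SubjectProfile
setClass("SubjectProfile", representation(params = "numeric"))

setValidity("SubjectProfile", function(object) {
  p <- object@params
  sds <- p[c("speedJitterSd", "pressureSd", "altSd", "tremorAmp")]
  if (any(sds < 0)) return("spread parameters must be >= 0")
  TRUE
})

#' CohortConfig: synthetic cohort settings
#'
#' @slot nHc,nAd subject counts (defaults 45 and 30, the reference cohort
#'   sizes).
#' @slot effectSize epsilon in \[0, 1\] interpolating the AD generative
#'   profile from identical-to-HC (0) to fully contrasted (1).
#' @slot seed master seed of the cohort.
#' @slot sampleRateHz digitizer rate (125 Hz).
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
  nHc = "integer", nAd = "integer", effectSize = "numeric",
  seed = "numeric", sampleRateHz = "numeric"))

setValidity("CohortConfig", function(object) {
  if (object@effectSize < 0 || object@effectSize > 1)
    return("effectSize must lie in [0, 1]")
  if (object@nHc < 1 || object@nAd < 1) return("counts must be positive")
  TRUE
})

#' Construct a CohortConfig
#'
#' @param nHc,nAd healthy-control and patient counts.
#' @param effectSize class effect size epsilon in \[0, 1\].
#' @param seed master seed.
#' @param sampleRateHz digitizer sampling rate.
#' @return A [CohortConfig-class] object.
#' @export
CohortConfig <- function(nHc = 45L, nAd = 30L, effectSize = 1, seed = 1,
                         sampleRateHz = 125) {
  new("CohortConfig", nHc = as.integer(nHc), nAd = as.integer(nAd),
      effectSize = effectSize, seed = seed, sampleRateHz = sampleRateHz)
}
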
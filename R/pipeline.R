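## Configuration-driven orchestration of the full experiment grid:
## synthesize (or load) a cohort, render hybrid views, extract deep
## features at the requested taps, run per-(view, layer) SVM experts and
## the fusion schemes, and emit tidy result tables.
##
## Stage outputs are cached under the output directory keyed by a config
## hash, so layer sweeps reuse rendered images and extracted features.

#' Assemble a run configuration
#'
#' Either pass a YAML path or a list with the same structure.  Unknown or
#' malformed fields raise an error naming the field.
#'
#' @param config YAML file path or list.
#' @param seed optional master seed override.
#' @param out optional output directory override.
#' @param weightsMode optional weights-mode override.
#' @return A validated config list.
#' @export
readRunConfig <- function(config, seed = NULL, out = NULL,
                          weightsMode = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("malformed config: expected a mapping")
  cfg <- list(
    out = out %||% config$out %||% "spiralAD_out",
    seed = seed %||% config$seed %||% 1,
    input = config$input,
    synthetic = config$synthetic %||% list(),
    render = config$render %||% list(),
    extract = config$extract %||% list(),
    svm = config$svm %||% list(),
    plan = config$plan %||% list(),
    fusion = config$fusion %||% list()
  )
  num <- function(section, field, default, lo = -Inf, hi = Inf) {
    v <- cfg[[section]][[field]] %||% default
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi)
      stop("malformed config field '", section, ".", field, "'")
    v
  }
  cfg$synthetic <- list(
    nHc = num("synthetic", "nHc", 45, 1),
    nAd = num("synthetic", "nAd", 30, 1),
    effectSize = num("synthetic", "effectSize", 1, 0, 1))
  cfg$render <- list(
    canvasPx = num("render", "canvasPx", 512, 64),
    marginFrac = num("render", "marginFrac", 0.05, 0, 0.499),
    strokePx = num("render", "strokePx", 3, 1),
    views = cfg$render$views %||% c("raw", "pressure", "altitude", "velocity",
                                    "acceleration"))
  badView <- setdiff(cfg$render$views, c("raw", DYNAMIC_PARAMETERS))
  if (length(badView))
    stop("malformed config field 'render.views': unknown view ",
         paste(badView, collapse = ", "))
  cfg$extract <- list(
    layers = cfg$extract$layers %||% LAYER_TAGS,
    inputPx = num("extract", "inputPx", 224, 224, 227),
    weightsMode = weightsMode %||% cfg$extract$weightsMode %||% "random_seeded",
    seed = num("extract", "seed", 2024))
  badLayer <- setdiff(cfg$extract$layers, LAYER_TAGS)
  if (length(badLayer))
    stop("malformed config field 'extract.layers': unknown layer ",
         paste(badLayer, collapse = ", "))
  if (!cfg$extract$weightsMode %in% c("pretrained", "random_seeded"))
    stop("malformed config field 'extract.weightsMode'")
  cfg$svm <- list(
    cost = as.numeric(cfg$svm$cost %||% svmGrid()$cost),
    gamma = cfg$svm$gamma %||% svmGrid()$gamma)
  if (anyNA(cfg$svm$cost)) stop("malformed config field 'svm.cost'")
  cfg$plan <- list(
    nReps = num("plan", "nReps", 10, 1),
    nTrainPerClass = num("plan", "nTrainPerClass", 20, 1),
    nTestPerClass = num("plan", "nTestPerClass", 10, 1))
  for (fs in cfg$fusion) {
    if (is.null(fs$views) || is.null(fs$layer))
      stop("malformed config field 'fusion': each scheme needs views and layer")
  }
  structure(cfg, class = "spiralADConfig")
}

renderConfigOf <- function(cfg) {
  RenderConfig(canvasPx = cfg$render$canvasPx,
               marginFrac = cfg$render$marginFrac,
               strokePx = cfg$render$strokePx)
}

extractorConfigOf <- function(cfg) {
  ExtractorConfig(inputPx = cfg$extract$inputPx,
                  weightsMode = cfg$extract$weightsMode,
                  seed = cfg$extract$seed)
}

## md5 hash of an arbitrary config fragment (order-stable).
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(x), f)
  unname(tools::md5sum(f))
}

#' Synthesize a cohort to disk
#'
#' @param cfg a [readRunConfig()] configuration.
#' @return Invisibly, the cohort directory.
#' @export
cmdSynth <- function(cfg) {
  cc <- CohortConfig(nHc = cfg$synthetic$nHc, nAd = cfg$synthetic$nAd,
                     effectSize = cfg$synthetic$effectSize, seed = cfg$seed)
  cohort <- generateCohort(cc)
  dir <- file.path(cfg$out, "cohort")
  writeCohort(cohort, dir)
  message("wrote ", length(cohort$streams), " streams to ", dir)
  invisible(dir)
}

loadStreams <- function(cfg) {
  dir <- cfg$input %||% file.path(cfg$out, "cohort")
  if (!dir.exists(dir)) {
    cmdSynth(cfg)
    dir <- file.path(cfg$out, "cohort")
  }
  readCohort(dir)
}

#' Render all configured views of a cohort
#'
#' Population normalization stats are fitted over all subjects (the
#' reference protocol) and written as JSON beside the images.
#'
#' @param cfg a [readRunConfig()] configuration.
#' @return Invisibly, named list of per-view image lists.
#' @export
cmdRender <- function(cfg) {
  cohort <- loadStreams(cfg)
  rc <- renderConfigOf(cfg)
  outDir <- file.path(cfg$out, "images")
  images <- list()
  for (view in cfg$render$views) {
    vdir <- file.path(outDir, view)
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    if (view == "raw") {
      imgs <- lapply(cohort$streams, renderRaw, config = rc)
    } else {
      stats <- fitNormalization(cohort$streams, view, config = rc)
      jsonlite::write_json(
        list(parameter = view, min = stats@minValue, max = stats@maxValue,
             scope = stats@scope, degenerate = stats@degenerate),
        file.path(outDir, paste0("normalization_", view, ".json")),
        auto_unbox = TRUE, digits = NA)
      imgs <- lapply(cohort$streams, renderHybrid, parameter = view,
                     stats = stats, config = rc)
    }
    for (im in imgs)
      writeGrayImage(im, file.path(vdir, paste0(subjectId(im), "__",
                                                view, ".png")))
    images[[view]] <- imgs
  }
  invisible(images)
}

featureCachePath <- function(cfg, view, layer) {
  hash <- configHash(list(render = cfg$render[c("canvasPx", "marginFrac",
                                                "strokePx")],
                          extract = cfg$extract, view = view, layer = layer,
                          synthetic = cfg$synthetic, seed = cfg$seed))
  file.path(cfg$out, "features",
            sprintf("%s__%s__%s.rds", view, layer, substr(hash, 1, 8)))
}

#' Extract and persist features for every (view, layer) pair
#'
#' Feature matrices are stored as RDS with a sidecar JSON manifest
#' (subject ids, layer, dimension, config hash); cached by content hash
#' so re-runs and layer sweeps reuse extractions.
#'
#' @param cfg a [readRunConfig()] configuration.
#' @param images optional pre-rendered images (from [cmdRender()]).
#' @return Invisibly, the feature store: named list `"view:layer"` ->
#'   matrix.
#' @export
cmdExtract <- function(cfg, images = NULL) {
  ec <- extractorConfigOf(cfg)
  store <- list()
  views <- setdiff(cfg$render$views, character(0))
  for (view in views) {
    for (layer in cfg$extract$layers) {
      path <- featureCachePath(cfg, view, layer)
      if (file.exists(path)) {
        store[[featureKey(view, layer)]] <- readRDS(path)
        next
      }
      if (is.null(images)) images <- cmdRender(cfg)
      X <- extractFeatureMatrix(images[[view]], layer, ec)
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      saveRDS(X, path)
      jsonlite::write_json(
        list(view = view, layer = layer, dim = ncol(X),
             subjects = rownames(X), inputPx = ec@inputPx,
             weightsMode = ec@weightsMode),
        sub("\\.rds$", ".json", path), auto_unbox = TRUE)
      store[[featureKey(view, layer)]] <- X
    }
  }
  invisible(store)
}

summaryRow <- function(run, view, layer, result) {
  s <- resultSummary(result)
  data.frame(run = run, view = view, layer = layer,
             accuracy_mean = s$mean[s$metric == "accuracy"],
             accuracy_sd = s$sd[s$metric == "accuracy"],
             sensitivity_mean = s$mean[s$metric == "sensitivity"],
             sensitivity_sd = s$sd[s$metric == "sensitivity"],
             specificity_mean = s$mean[s$metric == "specificity"],
             specificity_sd = s$sd[s$metric == "specificity"],
             stringsAsFactors = FALSE)
}

perRepRows <- function(run, view, layer, result) {
  do.call(rbind, lapply(seq_along(resultCounts(result)), function(r) {
    cc <- resultCounts(result)[[r]]
    data.frame(run = run, view = view, layer = layer, repetition = r,
               tp = cc@tp, fn = cc@fn, tn = cc@tn, fp = cc@fp,
               stringsAsFactors = FALSE)
  }))
}

#' Run the configured experiment grid end-to-end
#'
#' Renders, extracts, trains one expert per (view, layer), runs every
#' fusion scheme, and writes `results_per_rep.csv` (confusion counts) and
#' `results_summary.csv` (mean +/- sd metrics, one row per table cell)
#' under the output directory.
#'
#' @param cfg a [readRunConfig()] configuration (or path/list accepted by
#'   it).
#' @return Invisibly, list with `summary`, `perRep`, `results` (the
#'   EvalResult objects) and `plan`.
#' @export
cmdRun <- function(cfg) {
  if (!inherits(cfg, "spiralADConfig")) cfg <- readRunConfig(cfg)
  cohort <- loadStreams(cfg)
  images <- cmdRender(cfg)
  store <- cmdExtract(cfg, images)
  labels <- cohort$labels
  hcIds <- names(labels)[labels == "HC"]
  adIds <- names(labels)[labels == "AD"]
  plan <- makeSamplingPlan(hcIds, adIds, nReps = cfg$plan$nReps,
                           masterSeed = cfg$seed,
                           nTrainPerClass = cfg$plan$nTrainPerClass,
                           nTestPerClass = cfg$plan$nTestPerClass)
  grid <- cfg$svm
  names(grid) <- c("cost", "gamma")
  summary <- NULL; perRep <- NULL; results <- list()
  for (key in names(store)) {
    vl <- strsplit(key, ":", fixed = TRUE)[[1]]
    run <- runExpertEvaluation(store[[key]], labels, plan, grid = grid,
                               view = vl[1], layer = vl[2])
    results[[key]] <- run$result
    summary <- rbind(summary, summaryRow("expert", vl[1], vl[2], run$result))
    perRep <- rbind(perRep, perRepRows("expert", vl[1], vl[2], run$result))
  }
  for (fs in cfg$fusion) {
    mode <- fs$mode %||% "single_layer_multi_view"
    label <- paste0("fusion_", mode)
    if (mode == "low_level") {
      res <- runLowLevelFusion(images, plan, fs$layer,
                               config = extractorConfigOf(cfg), grid = grid,
                               labels = labels, order = fs$views)$result
    } else {
      scheme <- FusionScheme(rep(fs$views, length(fs$layer)),
                             rep(fs$layer, each = length(fs$views)),
                             mode = mode)
      res <- runDecisionFusion(scheme, plan, store, grid = grid)$fused
    }
    key <- paste0(label, ":", paste(fs$views, collapse = "+"), ":",
                  paste(fs$layer, collapse = "+"))
    results[[key]] <- res
    summary <- rbind(summary, summaryRow(label,
                                         paste(fs$views, collapse = "+"),
                                         paste(fs$layer, collapse = "+"), res))
    perRep <- rbind(perRep, perRepRows(label,
                                       paste(fs$views, collapse = "+"),
                                       paste(fs$layer, collapse = "+"), res))
  }
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(summary, file.path(cfg$out, "results_summary.csv"),
            row.names = FALSE)
  write.csv(perRep, file.path(cfg$out, "results_per_rep.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(seed = cfg$seed, configHash = configHash(cfg)),
                       file.path(cfg$out, "run_info.json"),
                       auto_unbox = TRUE)
  invisible(list(summary = summary, perRep = perRep, results = results,
                 plan = plan))
}

#' Print the summary table of a finished run
#'
#' @param cfg a [readRunConfig()] configuration.
#' @return Invisibly, the summary data.frame.
#' @export
cmdReport <- function(cfg) {
  path <- file.path(cfg$out, "results_summary.csv")
  if (!file.exists(path)) stop("no results under ", cfg$out, "; run cmdRun first")
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(s)))
    cat(sprintf("%-28s %-28s %-6s acc %5.1f+/-%4.1f  sens %5.1f+/-%4.1f  spec %5.1f+/-%4.1f\n",
                s$run[i], s$view[i], s$layer[i],
                s$accuracy_mean[i], s$accuracy_sd[i],
                s$sensitivity_mean[i], s$sensitivity_sd[i],
                s$specificity_mean[i], s$specificity_sd[i]))
  invisible(s)
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `render`, `extract`, `run`, `report`; options
#' `--config <yaml>`, `--seed <int>`, `--out <dir>`,
#' `--weights {pretrained,random}`.  See
#' `system.file("scripts", "spiralpipe.R", package = "spiralAD")`.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status (0 ok, 2 configuration error, 1 other
#'   failure).
#' @export
spiralCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: spiralpipe.R {synth|render|extract|run|report} [--config <yaml>] [--seed <int>] [--out <dir>] [--weights {pretrained,random}]"
  if (!length(args)) { message(usage); return(2L) }
  sub <- args[1]; args <- args[-1]
  opt <- list(config = NULL, seed = NULL, out = NULL, weights = NULL)
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message("unknown or incomplete option: ", args[i]); return(2L)
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    cfg <- readRunConfig(opt$config %||% list(),
                         seed = if (!is.null(opt$seed)) as.numeric(opt$seed),
                         out = opt$out,
                         weightsMode = switch(opt$weights %||% "keep",
                                              pretrained = "pretrained",
                                              random = "random_seeded",
                                              keep = NULL))
    switch(sub,
           synth = cmdSynth(cfg),
           render = cmdRender(cfg),
           extract = cmdExtract(cfg),
           run = cmdRun(cfg),
           report = cmdReport(cfg),
           stop("unknown subcommand: ", sub))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("config", conditionMessage(e))) 2L else 1L
  })
  status
}
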
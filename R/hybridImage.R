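## Rasterizing spiral trajectories into raw (shape-only) and hybrid
## (dynamics-encoded) grayscale images.
##
## A hybrid image embeds one dynamic parameter pointwise: values are
## min-max normalized against population extrema and mapped to gray so
## that low values are white (255) and high values black (0).  Pressure
## views draw pen-down samples only -- in-air pressure is identically
## zero -- which leaves visible gaps ("broken" trajectories) wherever the
## pen left the surface; velocity, acceleration and altitude views draw
## in-air samples too, so the whole gesture is visible.

## Per-sample values of a dynamic parameter.
parameterValues <- function(stream, parameter) {
  s <- penSamples(stream)
  switch(parameter,
         pressure = s$p,
         altitude = s$alt,
         velocity = seriesValues(computeVelocity(stream)),
         acceleration = seriesValues(computeAcceleration(stream)),
         stop("unknown dynamic parameter: ", parameter))
}

## Which samples are rendered for a view.  Pressure is pen-down only by
## construction; other views follow the config's includePenups entry.
renderMask <- function(stream, view, config) {
  pd <- penSamples(stream)$penDown
  if (view == "raw" || view == "pressure") return(pd)
  if (config@includePenups[[view]]) rep(TRUE, length(pd)) else pd
}

#' Fit population min-max normalization for a dynamic parameter
#'
#' Scans every rendered point of every stream in scope (for pressure,
#' pen-down points only) and records the extrema.  When all values are
#' equal the stats are flagged degenerate -- every value then normalizes
#' to 0 (white) -- and a warning is raised.
#'
#' @param streams list of [PenStream-class].
#' @param parameter one of `"pressure"`, `"altitude"`, `"velocity"`,
#'   `"acceleration"`.
#' @param scope `"all_subjects"` (reference protocol: extrema over the
#'   whole population) or `"train_only"` (leak-free variant; pass only the
#'   training streams).
#' @param config a [RenderConfig()] (controls in-air inclusion).
#' @return A [NormalizationStats-class].
#' @export
fitNormalization <- function(streams, parameter, scope = "all_subjects",
                             config = RenderConfig()) {
  if (!length(streams)) stop("empty stream collection")
  if (!parameter %in% DYNAMIC_PARAMETERS)
    stop("unknown dynamic parameter: ", parameter)
  vals <- unlist(lapply(streams, function(st) {
    parameterValues(st, parameter)[renderMask(st, parameter, config)]
  }))
  if (!length(vals)) stop("no rendered points for parameter ", parameter)
  lo <- min(vals); hi <- max(vals)
  degen <- hi == lo
  if (degen)
    warning("degenerate normalization for ", parameter,
            ": all values equal ", lo)
  new("NormalizationStats", parameter = parameter, minValue = lo,
      maxValue = hi, scope = scope, degenerate = degen)
}

#' Map parameter values to gray levels
#'
#' Values are min-max normalized with the population stats, clipped to
#' \[0, 1\], and mapped to `round(255 * (1 - vhat))` with round-half-up:
#' the population minimum renders white (255) and the maximum black (0).
#' Degenerate stats map every value to white.
#'
#' @param value numeric vector of parameter values.
#' @param stats a [NormalizationStats-class].
#' @return Integer gray levels in \[0, 255\].
#' @export
valueToGray <- function(value, stats) {
  if (stats@degenerate) return(rep(255L, length(value)))
  vhat <- clip((value - stats@minValue) / (stats@maxValue - stats@minValue),
               0, 1)
  as.integer(roundHalfUp(255 * (1 - vhat)))
}

## Affine map from tablet coordinates of the rendered points to canvas
## pixel coordinates: aspect-preserving, centered, y flipped so tablet
## "up" is image "up".  Returns fractional (col, row) per point.
canvasMap <- function(x, y, config) {
  cp <- config@canvasPx
  cx <- (min(x) + max(x)) / 2
  cy <- (min(y) + max(y)) / 2
  rng <- max(max(x) - min(x), max(y) - min(y))
  s <- if (rng > 0) cp * (1 - 2 * config@marginFrac) / rng else 0
  list(col = (x - cx) * s + (cp + 1) / 2,
       row = (cy - y) * s + (cp + 1) / 2)
}

## Rasterize thick segments (zero-length = dots) onto a white canvas.
## A pixel is inked when its center lies within strokePx/2 of the segment;
## where strokes overlap the darker gray wins.
rasterizeSegments <- function(x0, y0, x1, y1, gray, config) {
  cp <- config@canvasPx
  pix <- matrix(255L, cp, cp)
  if (!length(x0)) return(pix)
  r <- config@strokePx / 2
  bx0 <- pmax(1L, floor(pmin(x0, x1) - r)); bx1 <- pmin(cp, ceiling(pmax(x0, x1) + r))
  by0 <- pmax(1L, floor(pmin(y0, y1) - r)); by1 <- pmin(cp, ceiling(pmax(y0, y1) + r))
  nx <- bx1 - bx0 + 1L; ny <- by1 - by0 + 1L
  ok <- nx > 0L & ny > 0L
  if (!any(ok)) return(pix)
  cnt <- ifelse(ok, nx * ny, 0L)
  seg <- rep(seq_along(x0), cnt)
  off <- sequence(cnt) - 1L
  px <- bx0[seg] + off %% nx[seg]
  py <- by0[seg] + off %/% nx[seg]
  dx <- x1[seg] - x0[seg]; dy <- y1[seg] - y0[seg]
  L2 <- dx^2 + dy^2
  tt <- ifelse(L2 > 0, clip(((px - x0[seg]) * dx + (py - y0[seg]) * dy) / L2,
                            0, 1), 0)
  d2 <- (px - (x0[seg] + tt * dx))^2 + (py - (y0[seg] + tt * dy))^2
  hit <- d2 <= r^2
  if (!any(hit)) return(pix)
  lin <- (px[hit] - 1L) * cp + py[hit]
  g <- gray[seg[hit]]
  o <- order(lin, g)
  first <- !duplicated(lin[o])
  pix[lin[o][first]] <- as.integer(g[o][first])
  pix
}

## Shared rendering core: draw every rendered sample as a dot and, when
## connectSegments, a thick segment between consecutive rendered samples
## (segment gray = rounded mean of its endpoint grays).
renderTrajectory <- function(stream, grays, mask, config, view,
                             meta = list()) {
  if (!any(mask)) stop("no rendered samples for view ", view)
  s <- penSamples(stream)
  m <- canvasMap(s$x[mask], s$y[mask], config)
  col <- rep(NA_real_, nrow(s)); row <- rep(NA_real_, nrow(s))
  col[mask] <- m$col; row[mask] <- m$row
  ## dots at every rendered sample
  x0 <- col[mask]; y0 <- row[mask]; x1 <- x0; y1 <- y0; g <- grays[mask]
  if (config@connectSegments && nrow(s) > 1) {
    i <- which(mask[-nrow(s)] & mask[-1])
    if (length(i)) {
      x0 <- c(x0, col[i]); y0 <- c(y0, row[i])
      x1 <- c(x1, col[i + 1]); y1 <- c(y1, row[i + 1])
      g <- c(g, roundHalfUp((grays[i] + grays[i + 1]) / 2))
    }
  }
  pix <- rasterizeSegments(x0, y0, x1, y1, g, config)
  new("GrayImage", pixels = pix, view = view, subjectId = subjectId(stream),
      meta = meta)
}

#' Render the raw (shape-only) spiral image
#'
#' The pen-down trajectory is drawn in black on white; in-air samples are
#' not rendered.
#'
#' @param stream a [PenStream-class] with at least one pen-down sample.
#' @param config a [RenderConfig()].
#' @return A [GrayImage-class] with view `"raw"`.
#' @export
renderRaw <- function(stream, config = RenderConfig()) {
  mask <- renderMask(stream, "raw", config)
  if (!any(mask)) stop("stream has no pen-down samples")
  renderTrajectory(stream, rep(0L, length(mask)), mask, config, "raw")
}

#' Render a hybrid (dynamics-encoded) spiral image
#'
#' Each rendered sample is colored by the gray level of its parameter
#' value under the population normalization; consecutive rendered samples
#' are joined by a segment whose gray is the rounded mean of the endpoint
#' grays.  Pressure views leave gaps at pen-ups; velocity, acceleration
#' and altitude views bridge them (configurable for altitude via
#' `includePenups`).
#'
#' @param stream a [PenStream-class].
#' @param parameter dynamic parameter to embed.
#' @param stats [NormalizationStats-class] fitted for `parameter`.
#' @param config a [RenderConfig()].
#' @return A [GrayImage-class]; `@meta$nClipped` counts rendered values
#'   outside the normalization range (clipped into it).
#' @export
renderHybrid <- function(stream, parameter, stats, config = RenderConfig()) {
  if (stats@parameter != parameter)
    stop("normalization stats were fitted for ", stats@parameter)
  vals <- parameterValues(stream, parameter)
  mask <- renderMask(stream, parameter, config)
  if (!any(mask)) stop("no rendered samples for view ", parameter)
  nClipped <- if (stats@degenerate) 0L else
    sum(vals[mask] < stats@minValue | vals[mask] > stats@maxValue)
  grays <- valueToGray(vals, stats)
  renderTrajectory(stream, grays, mask, config, parameter,
                   meta = list(nClipped = nClipped,
                               degenerate = stats@degenerate))
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param image a [GrayImage-class].
#' @param path output path; the conventional pattern is
#'   `<subject_id>__<view>.png`.
#' @return Invisibly, `path`.
#' @export
writeGrayImage <- function(image, path) {
  png::writePNG(grayPixels(image) / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG back into a GrayImage
#'
#' @param path PNG path.
#' @param view,subjectId provenance to attach.
#' @return A [GrayImage-class].
#' @export
readGrayImage <- function(path, view = "raw", subjectId = "anonymous") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  new("GrayImage", pixels = matrix(as.integer(roundHalfUp(a * 255)),
                                   nrow(a), ncol(a)),
      view = view, subjectId = subjectId, meta = list())
}
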
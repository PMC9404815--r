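## An AlexNet-architecture feedforward network implemented with im2col +
## BLAS matrix products, used purely as a fixed feature extractor.
##
## Stages (input 3 x inputPx x inputPx):
##   conv1  64 @ 11x11 /4 (pad 2 at 224, pad 0 at 227) -> ReLU -> maxpool 3/2
##   conv2 192 @  5x5  /1 pad 2                        -> ReLU -> maxpool 3/2
##   conv3 384 @  3x3  /1 pad 1                        -> ReLU
##   conv4 256 @  3x3  /1 pad 1                        -> ReLU
##   conv5 256 @  3x3  /1 pad 1                        -> ReLU -> maxpool 3/2
##   fc6 4096 -> ReLU ; fc7 4096 -> ReLU
##
## Taps: Conv1/Conv2/Conv5 after their max-pool, Conv3/Conv4 after ReLU,
## fc7 after ReLU -- the conventional "off-the-shelf feature" points,
## which also bound the SVM input dimension.
##
## Weights are either externally supplied pretrained tensors (not bundled;
## requesting them raises an instructive error) or seeded He-initialized
## Gaussians, which make the whole pipeline deterministic and
## self-contained.  Activations are flattened channel-major, then row,
## then column -- frozen so feature vectors are comparable across runs.

.spiralADCache <- new.env(parent = emptyenv())

conv1Pad <- function(inputPx) if (inputPx == 224L) 2L else 0L

convOutSide <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

## Architecture bookkeeping: spatial side and channel count at each tap.
tapShape <- function(layer, inputPx = 224L) {
  h1 <- convOutSide(inputPx, 11L, 4L, conv1Pad(inputPx))
  p1 <- convOutSide(h1, 3L, 2L, 0L)
  h2 <- convOutSide(p1, 5L, 1L, 2L)
  p2 <- convOutSide(h2, 3L, 2L, 0L)
  h3 <- convOutSide(p2, 3L, 1L, 1L)   # conv3/4/5 preserve the side
  p5 <- convOutSide(h3, 3L, 2L, 0L)
  switch(layer,
         Conv1 = c(side = p1, channels = 64L),
         Conv2 = c(side = p2, channels = 192L),
         Conv3 = c(side = h3, channels = 384L),
         Conv4 = c(side = h3, channels = 256L),
         Conv5 = c(side = p5, channels = 256L),
         fc7 = c(side = 1L, channels = 4096L),
         stop("unknown layer tag: ", layer))
}

#' Feature dimension of a tapped layer, by shape arithmetic
#'
#' @param layer one of `Conv1`..`Conv5`, `fc7`.
#' @param inputPx network input side (224 or 227).
#' @return Integer dimension of the flattened activation.
#' @examples
#' featureDim("Conv5")  # 9216
#' featureDim("fc7")    # 4096
#' @export
featureDim <- function(layer, inputPx = 224L) {
  s <- tapShape(layer, as.integer(inputPx))
  as.integer(s[["side"]]^2 * s[["channels"]])
}

## Cached im2col index matrix for a given input geometry.
im2colIdx <- function(H, W, C, k, stride, pad) {
  key <- paste("idx", H, W, C, k, stride, pad, sep = "_")
  hit <- .spiralADCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  base <- (ow - 1L) * stride * Hp + (oh - 1L) * stride   # 0-based top-left
  kh <- rep(seq_len(k), times = k)
  kw <- rep(seq_len(k), each = k)
  cc <- rep(seq_len(C), each = k * k)
  elem <- (cc - 1L) * Hp * Wp + (rep(kw, C) - 1L) * Hp + rep(kh, C)
  out <- list(idx = outer(elem, base, "+"), Ho = Ho, Wo = Wo,
              Hp = Hp, Wp = Wp)
  .spiralADCache[[key]] <- out
  out
}

convForward <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  ii <- im2colIdx(d[1], d[2], d[3], k, stride, pad)
  if (pad > 0L) {
    xp <- array(0, c(ii$Hp, ii$Wp, d[3]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  } else xp <- x
  P <- xp[ii$idx]
  dim(P) <- dim(ii$idx)
  out <- W %*% P + b
  array(t(out), c(ii$Ho, ii$Wo, nrow(W)))
}

maxPool <- function(x, k = 3L, stride = 2L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- (H - k) %/% stride + 1L; Wo <- (W - k) %/% stride + 1L
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  base <- (ow - 1L) * stride * H + (oh - 1L) * stride
  offs <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * H, "+"))
  idx <- outer(offs, base, "+")
  xm <- matrix(x, ncol = C)
  vals <- array(xm[as.vector(idx), ], c(k * k, Ho * Wo, C))
  out <- vals[1, , ]
  for (j in 2:(k * k)) out <- pmax(out, vals[j, , ])
  array(out, c(Ho, Wo, C))
}

relu <- function(x) { x[x < 0] <- 0; x }

## Flatten an [H, W, C] activation channel-major, then row, then column.
flattenActivation <- function(a) as.vector(aperm(a, c(2, 1, 3)))

heMatrix <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
}

## (output units, input units) per weight tensor
.layerSpec <- list(
  conv1 = c(64L, 11L * 11L * 3L),
  conv2 = c(192L, 5L * 5L * 64L),
  conv3 = c(384L, 3L * 3L * 192L),
  conv4 = c(256L, 3L * 3L * 384L),
  conv5 = c(256L, 3L * 3L * 256L),
  fc6 = c(4096L, 9216L),
  fc7 = c(4096L, 4096L))

#' Network weights for the feature extractor
#'
#' In `random_seeded` mode, He-initialized Gaussian weights are drawn
#' deterministically — each tensor from a seed derived from
#' `config@seed` and its stage index, so any subset of layers is
#' reproducible across processes — generated lazily and cached for one
#' seed at a time (the fully connected tensors are large).  `pretrained`
#' mode requires externally supplied weights, which this package does
#' not bundle.
#'
#' @param config an [ExtractorConfig()].
#' @param layers which weight tensors to materialize.
#' @return A list of weight matrices plus a `biases` list (zero vectors).
#' @export
alexnetWeights <- function(config = ExtractorConfig(),
                           layers = names(.layerSpec)) {
  if (config@weightsMode == "pretrained")
    stop("pretrained weights are not bundled with this package; ",
         "fall back to weightsMode = 'random_seeded' (seeded He ",
         "initialization) or supply weights externally")
  if (!identical(.spiralADCache$weightSeed, config@seed)) {
    .spiralADCache$weightSeed <- config@seed
    .spiralADCache$weights <- list()
  }
  for (nm in layers) {
    if (is.null(.spiralADCache$weights[[nm]])) {
      i <- match(nm, names(.layerSpec))
      sp <- .layerSpec[[nm]]
      .spiralADCache$weights[[nm]] <-
        withSeed(childSeed(config@seed, i), heMatrix(sp[1], sp[2]))
    }
  }
  w <- .spiralADCache$weights[layers]
  w$biases <- lapply(.layerSpec, function(sp) numeric(sp[1]))
  w
}

#' Preprocess an image for the network
#'
#' Bilinear resize to `inputPx` squared, grayscale replicated to three
#' identical channels (composites keep their three channels), pixel values
#' scaled to \[0, 1\], then per-channel normalization
#' `(x - mean) / sd`.
#'
#' @param image a [GrayImage-class], a grayscale matrix, or a
#'   three-channel array from [composeChannels()] (values in 0..255).
#' @param config an [ExtractorConfig()].
#' @return Array `inputPx x inputPx x 3`.
#' @export
preprocessImage <- function(image, config = ExtractorConfig()) {
  if (is(image, "GrayImage")) image <- grayPixels(image)
  px <- config@inputPx
  resize1 <- function(M) {
    if (nrow(M) == px && ncol(M) == px) return(M)
    t(EBImage::resize(t(M), w = px, h = px, filter = "bilinear"))
  }
  if (length(dim(image)) == 2L) {
    ch <- resize1(image) / 255
    chans <- list(ch, ch, ch)
  } else {
    stopifnot(dim(image)[3] == 3L)
    chans <- lapply(1:3, function(i) resize1(image[, , i]) / 255)
  }
  out <- array(0, c(px, px, 3L))
  for (i in 1:3)
    out[, , i] <- (chans[[i]] - config@channelMean[i]) / config@channelSd[i]
  out
}

## Forward pass up to (and including) stage `upTo`, collecting every tap
## along the way.  `x` is a preprocessed input array.
alexnetForward <- function(x, config, upTo = "fc7") {
  want <- match(upTo, LAYER_TAGS)
  if (is.na(want)) stop("unknown layer tag: ", upTo)
  needed <- names(.layerSpec)[seq_len(if (want >= 6) 7L else want)]
  w <- alexnetWeights(config, needed)
  b <- w$biases
  p1 <- conv1Pad(config@inputPx)
  taps <- list()
  a <- maxPool(relu(convForward(x, w$conv1, b$conv1, 11L, 4L, p1)))
  taps$Conv1 <- a
  if (want >= 2) { a <- maxPool(relu(convForward(a, w$conv2, b$conv2, 5L, 1L, 2L))); taps$Conv2 <- a }
  if (want >= 3) { a <- relu(convForward(a, w$conv3, b$conv3, 3L, 1L, 1L)); taps$Conv3 <- a }
  if (want >= 4) { a <- relu(convForward(a, w$conv4, b$conv4, 3L, 1L, 1L)); taps$Conv4 <- a }
  if (want >= 5) { a <- maxPool(relu(convForward(a, w$conv5, b$conv5, 3L, 1L, 1L))); taps$Conv5 <- a }
  if (want >= 6) {
    v <- flattenActivation(a)
    h6 <- relu(as.vector(w$fc6 %*% v + b$fc6))
    taps$fc7 <- relu(as.vector(w$fc7 %*% h6 + b$fc7))
  }
  taps
}

#' Activations at every tap of the network
#'
#' Runs the full forward pass once and returns the flattened activation
#' at each of the six taps; used to check that truncated extraction
#' matches the corresponding stage of the full pass.
#'
#' @param image preprocessed array or [GrayImage-class].
#' @param config an [ExtractorConfig()].
#' @return Named list of numeric vectors, one per tap.
#' @export
alexnetActivations <- function(image, config = ExtractorConfig()) {
  if (is(image, "GrayImage") || length(dim(image)) == 2L ||
      dim(image)[1] != config@inputPx)
    image <- preprocessImage(image, config)
  taps <- alexnetForward(image, config, upTo = "fc7")
  lapply(taps, function(a) if (is.null(dim(a))) a else flattenActivation(a))
}

#' Extract the flattened activation of one tapped layer
#'
#' The forward pass is truncated at the tap (after the nonlinearity, and
#' after the max-pool for Conv1, Conv2 and Conv5).
#'
#' @param image a [GrayImage-class], raw pixel matrix/array, or an
#'   already-preprocessed input array.
#' @param layer tap name (`Conv1`..`Conv5`, `fc7`).
#' @param config an [ExtractorConfig()].
#' @param subjectIdHint,viewHint provenance strings used when `image` is
#'   not a GrayImage.
#' @return A [FeatureVector-class].
#' @export
extractFeatures <- function(image, layer, config = ExtractorConfig(),
                            subjectIdHint = "anonymous", viewHint = "raw") {
  if (is(image, "GrayImage")) {
    subjectIdHint <- subjectId(image)
    viewHint <- imageView(image)
  }
  if (is(image, "GrayImage") || length(dim(image)) == 2L ||
      dim(image)[1] != config@inputPx)
    image <- preprocessImage(image, config)
  taps <- alexnetForward(image, config, upTo = layer)
  a <- taps[[layer]]
  v <- if (is.null(dim(a))) a else flattenActivation(a)
  new("FeatureVector", layer = layer, values = v,
      subjectId = subjectIdHint, view = viewHint)
}

#' Extract features for a collection of images
#'
#' @param images list of [GrayImage-class] (or preprocessable inputs).
#' @param layer tap name.
#' @param config an [ExtractorConfig()].
#' @param ids optional subject ids (defaults to the images' own).
#' @return Numeric matrix, one row per image, with `rownames` the subject
#'   ids.
#' @export
extractFeatureMatrix <- function(images, layer, config = ExtractorConfig(),
                                 ids = NULL) {
  if (is.null(ids))
    ids <- vapply(seq_along(images), function(i) {
      im <- images[[i]]
      if (is(im, "GrayImage")) subjectId(im)
      else attr(im, "subjectId") %||% sprintf("img%03d", i)
    }, "")
  X <- do.call(rbind, lapply(images, function(im)
    featureValues(extractFeatures(im, layer, config))))
  rownames(X) <- ids
  X
}

#' Compose three hybrid views into one three-channel image
#'
#' Low-level fusion input: each view occupies one input channel (no
#' replication).  Default order is pressure, altitude, velocity.
#'
#' @param images named list of exactly three [GrayImage-class] of one
#'   subject, equal canvas sizes.
#' @param order view order mapped to channels 1..3.
#' @return Array `canvas x canvas x 3` with attributes `subjectId` and
#'   `views`.
#' @export
composeChannels <- function(images,
                            order = c("pressure", "altitude", "velocity")) {
  stopifnot(length(images) == 3L, length(order) == 3L)
  if (is.null(names(images)))
    names(images) <- vapply(images, imageView, "")
  if (!all(order %in% names(images)))
    stop("missing views: ", paste(setdiff(order, names(images)), collapse = ", "))
  imgs <- images[order]
  sizes <- unname(vapply(imgs, function(im) nrow(grayPixels(im)), 0L))
  if (length(unique(sizes)) != 1L) stop("canvas sizes differ across views")
  subj <- unique(vapply(imgs, subjectId, ""))
  if (length(subj) != 1L) stop("views belong to different subjects")
  out <- array(0L, c(sizes[1], sizes[1], 3L))
  for (i in 1:3) out[, , i] <- grayPixels(imgs[[i]])
  attr(out, "subjectId") <- subj
  attr(out, "views") <- order
  out
}
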
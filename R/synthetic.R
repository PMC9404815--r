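## Synthetic spiral cohort generator.
##
## Emulates the acquisition conditions of the digitizer protocol: an
## Archimedes spiral r = gap * theta traversed at 125 Hz with
## Ornstein-Uhlenbeck-perturbed angular speed, sinusoidal radial tremor
## in the 4-7 Hz action-tremor band, AR(1) pen pressure around a slowly
## drifting mean, AR(1) altitude, drifting azimuth, and Poisson-count
## in-air excursions during which the pen state is up, pressure is zero
## and the positional speed is inflated.  The AD-vs-HC contrast is a
## single effect-size knob interpolating six profile deltas (more/faster
## tremor, more irregular speed, lower and more variable pressure, more
## in-air excursions, more variable pen altitude).  This is a test-bed
## emulation, not a validated neuromotor model of handwriting.

#' Generative profile of one synthetic writer
#'
#' @param nTurns spiral turns.
#' @param spiralGap radial growth per radian, tablet units.
#' @param baseSpeed mean angular speed, rad/s.
#' @param speedJitterSd relative SD of the OU speed perturbation.
#' @param tremorAmp radial tremor amplitude, tablet units.
#' @param tremorHzLo,tremorHzHi tremor frequency band (Hz); each subject
#'   draws a frequency uniformly in this band.
#' @param pressureMean,pressureSd pressure level and AR(1) innovation SD,
#'   device units.
#' @param pressureDrift linear pressure trend per second.
#' @param penupRate expected in-air excursions per spiral (Poisson).
#' @param penupDurS mean excursion duration, seconds (exponential).
#' @param penupSpeedup multiplicative angular-speed inflation while in
#'   air (the in-air trajectory is faster than the on-paper trace).
#' @param altMean,altSd pen altitude level and AR(1) SD, degrees.
#' @param azDrift azimuth drift, degrees per second.
#' @return A [SubjectProfile-class].
#' @export
subjectProfile <- function(nTurns = 4, spiralGap = 10, baseSpeed = 1.5,
                           speedJitterSd = 0.05, tremorAmp = 0.5,
                           tremorHzLo = 4, tremorHzHi = 7,
                           pressureMean = 600, pressureSd = 60,
                           pressureDrift = -2, penupRate = 0.5,
                           penupDurS = 0.25, penupSpeedup = 2.5,
                           altMean = 55, altSd = 3, azDrift = 2) {
  new("SubjectProfile", params = c(
    nTurns = nTurns, spiralGap = spiralGap, baseSpeed = baseSpeed,
    speedJitterSd = speedJitterSd, tremorAmp = tremorAmp,
    tremorHzLo = tremorHzLo, tremorHzHi = tremorHzHi,
    pressureMean = pressureMean, pressureSd = pressureSd,
    pressureDrift = pressureDrift, penupRate = penupRate,
    penupDurS = penupDurS, penupSpeedup = penupSpeedup,
    altMean = altMean, altSd = altSd, azDrift = azDrift))
}

#' Full-effect AD profile deltas
#'
#' Additive deltas applied to the healthy-control profile at effect size
#' 1: more and stronger tremor, more irregular speed, lower and more
#' variable pressure, more in-air excursions, more variable pen altitude.
#' Magnitudes are configuration, not claims about clinical AD.
#'
#' @return Named numeric vector of profile deltas.
#' @export
adProfileDeltas <- function() {
  c(tremorAmp = 2.5, speedJitterSd = 0.20, pressureMean = -250,
    pressureSd = 100, penupRate = 2.5, altSd = 5)
}

## Interpolate the AD profile from the HC profile at effect size eps.
interpolateProfile <- function(hcProfile, eps, deltas = adProfileDeltas()) {
  p <- hcProfile@params
  p[names(deltas)] <- p[names(deltas)] + eps * deltas
  new("SubjectProfile", params = p)
}

## AR(1) series with stationary marginal SD `sdMarg` (via stats::filter).
ar1 <- function(n, sdMarg, rho = 0.98) {
  if (sdMarg == 0 || n == 0) return(numeric(n))
  as.numeric(filter(rnorm(n, sd = sdMarg * sqrt(1 - rho^2)), rho,
                    method = "recursive"))
}

#' Generate one synthetic spiral recording
#'
#' @param profile a [subjectProfile()].
#' @param seed integer seed; the same (profile, seed) pair reproduces the
#'   stream exactly.
#' @param subjectId,label metadata for the resulting stream.
#' @param sampleRateHz digitizer rate.
#' @return A [PenStream-class].
#' @export
generateSubject <- function(profile, seed, subjectId = "synthetic",
                            label = "unknown", sampleRateHz = 125) {
  p <- profile@params
  withSeed(seed, {
    dt <- 1 / sampleRateHz
    thetaMax <- 2 * pi * p[["nTurns"]]
    ## in-air excursions: Poisson count, uniform start angles, exponential
    ## durations; sequential placement with a short pen-down cooldown so
    ## excursions never merge and the realized run count equals the draw
    nPU <- rpois(1, p[["penupRate"]])
    puStart <- sort(runif(nPU, 0.05, 0.90)) * thetaMax
    puDur <- rexp(nPU, 1 / p[["penupDurS"]])
    tau <- 0.5
    a1 <- exp(-dt / tau)
    b1 <- sqrt(1 - a1^2) * p[["speedJitterSd"]]
    cap <- ceiling(thetaMax / (0.1 * p[["baseSpeed"]]) / dt) + 1000L
    theta <- numeric(cap); penDown <- logical(cap)
    z <- 0; th <- 0; i <- 0L
    puIdx <- 1L; inAir <- FALSE; airEnd <- -1; cooldown <- 0L
    while (th < thetaMax && i < cap) {
      i <- i + 1L
      tNow <- (i - 1L) * dt
      if (inAir && tNow >= airEnd) { inAir <- FALSE; cooldown <- 2L }
      if (!inAir && cooldown == 0L && puIdx <= nPU && th >= puStart[puIdx]) {
        inAir <- TRUE
        airEnd <- tNow + puDur[puIdx]
        puIdx <- puIdx + 1L
      } else if (!inAir && cooldown > 0L) cooldown <- cooldown - 1L
      theta[i] <- th
      penDown[i] <- !inAir
      z <- a1 * z + b1 * rnorm(1)
      omega <- p[["baseSpeed"]] * max(1 + z, 0.1)
      if (inAir) omega <- omega * p[["penupSpeedup"]]
      th <- th + omega * dt
    }
    n <- i
    theta <- theta[seq_len(n)]; penDown <- penDown[seq_len(n)]
    t <- (seq_len(n) - 1L) * dt
    tremorHz <- runif(1, p[["tremorHzLo"]], p[["tremorHzHi"]])
    phase <- runif(1, 0, 2 * pi)
    r <- p[["spiralGap"]] * theta +
      p[["tremorAmp"]] * sin(2 * pi * tremorHz * t + phase)
    x <- r * cos(theta)
    y <- r * sin(theta)
    pr <- p[["pressureMean"]] + p[["pressureDrift"]] * t +
      ar1(n, p[["pressureSd"]])
    pr <- pmax(pr, 0)
    pr[!penDown] <- 0
    alt <- clip(p[["altMean"]] + ar1(n, p[["altSd"]]), 0, 90)
    az <- (runif(1, 0, 360) + p[["azDrift"]] * t +
             cumsum(rnorm(n, sd = 0.2))) %% 360
    PenStream(data.frame(t = t, x = x, y = y, p = pr, az = az, alt = alt,
                         penDown = penDown),
              subjectId = subjectId, label = label,
              sampleRateHz = sampleRateHz)
  })
}

#' Generate a labeled synthetic cohort
#'
#' HC subjects draw from the HC profile; AD subjects draw from the HC
#' profile shifted by `effectSize` times the full-AD deltas.  At effect
#' size 0 the two classes are generatively identical.
#'
#' @param config a [CohortConfig()].
#' @param hcProfile the healthy-control [subjectProfile()].
#' @param deltas full-effect profile deltas, see [adProfileDeltas()].
#' @return list with `streams` (named list of [PenStream-class]),
#'   `labels` (named character) and `manifest` (data.frame with
#'   subjectId, label, seed, profileHash).
#' @export
generateCohort <- function(config = CohortConfig(),
                           hcProfile = subjectProfile(),
                           deltas = adProfileDeltas()) {
  validObject(config)
  adProfile <- interpolateProfile(hcProfile, config@effectSize, deltas)
  n <- config@nHc + config@nAd
  seeds <- withSeed(config@seed, sample.int(2147483646L, n))
  ids <- c(sprintf("HC%03d", seq_len(config@nHc)),
           sprintf("AD%03d", seq_len(config@nAd)))
  labels <- setNames(rep(c("HC", "AD"), c(config@nHc, config@nAd)), ids)
  streams <- lapply(seq_len(n), function(i) {
    prof <- if (labels[[i]] == "HC") hcProfile else adProfile
    generateSubject(prof, seeds[i], subjectId = ids[i], label = labels[[i]],
                    sampleRateHz = config@sampleRateHz)
  })
  names(streams) <- ids
  manifest <- data.frame(subjectId = ids, label = unname(labels),
                         seed = seeds,
                         profileHash = vapply(seq_len(n), function(i) {
                           prof <- if (labels[[i]] == "HC") hcProfile else adProfile
                           profileHash(prof)
                         }, ""),
                         stringsAsFactors = FALSE)
  list(streams = streams, labels = labels, manifest = manifest)
}

## md5 of the profile parameters (via a temp file; base R has no direct
## in-memory md5).
profileHash <- function(profile) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sprintf("%s=%.12g", names(profile@params), profile@params), f)
  unname(tools::md5sum(f))
}

#' Write a cohort to disk
#'
#' Emits one canonical pen-stream TSV per subject plus a
#' `manifest.csv`.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in cohort$streams)
    writePenStream(st, file.path(dir, paste0(subjectId(st), ".tsv")))
  mp <- file.path(dir, "manifest.csv")
  write.csv(cohort$manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return list with `streams` and `labels` as in [generateCohort()].
#' @export
readCohort <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop("no manifest.csv under ", dir)
  manifest <- utils::read.csv(mp, stringsAsFactors = FALSE)
  streams <- lapply(manifest$subjectId, function(id)
    readPenStream(file.path(dir, paste0(id, ".tsv"))))
  names(streams) <- manifest$subjectId
  list(streams = streams,
       labels = setNames(manifest$label, manifest$subjectId),
       manifest = manifest)
}
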
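# Small random pen streams used across the suite.
randomStream <- function(n = 20, seed = NULL, penupFrac = 0.2,
                         subjectId = "rnd", label = "unknown") {
  if (!is.null(seed)) set.seed(seed)
  penDown <- stats::runif(n) > penupFrac
  p <- ifelse(penDown, stats::runif(n, 100, 900), 0)
  data.frame(
    t = cumsum(stats::runif(n, 0.004, 0.012)),
    x = cumsum(stats::rnorm(n)), y = cumsum(stats::rnorm(n)),
    p = p, az = stats::runif(n, 0, 359.9), alt = stats::runif(n, 10, 80),
    penDown = penDown) |>
    PenStream(subjectId = subjectId, label = label)
}

# A short deterministic spiral-ish stream with one in-air excursion in the
# middle, crafted so the excursion crosses otherwise empty canvas.
craftedPenupStream <- function() {
  n <- 41
  t <- (0:(n - 1)) / 125
  x <- seq(-10, 10, length.out = n)
  y <- c(rep(0, 15), seq(0, 8, length.out = 11), rep(8, 15))
  penDown <- rep(TRUE, n)
  penDown[16:26] <- FALSE          # in-air bridge between two flat strokes
  p <- ifelse(penDown, 400 + 5 * seq_len(n), 0)
  PenStream(data.frame(t = t, x = x, y = y, p = p, az = 0, alt = 45,
                       penDown = penDown), subjectId = "crafted")
}
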
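#' @useDynLib megconsist, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor fft mvfft median mad pf pt rnorm runif setNames t.test var
#' @importFrom utils packageVersion
NULL

# Canonical frequency bands (Hz)
.band_table <- list(
  delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
  beta = c(13, 30), gamma = c(30, 48)
)

#' Resolve a frequency band
#'
#' Maps a band name (\code{"alpha"}, \code{"beta"}, ...) or a numeric
#' \code{c(lo, hi)} pair to numeric band limits in Hz.
#'
#' @param band character band name or numeric length-2 vector.
#' @return numeric vector \code{c(lo, hi)} with a \code{"label"} attribute.
#' @export
band_limits <- function(band) {
  if (is.character(band)) {
    band <- match.arg(band, names(.band_table))
    out <- .band_table[[band]]
    attr(out, "label") <- band
    return(out)
  }
  stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2])
  out <- as.numeric(band)
  attr(out, "label") <- sprintf("%g-%g Hz", out[1], out[2])
  out
}

# Deterministic 31-bit stream seed derived from a master seed and a sequence
# of labels (subject, timepoint, purpose). Polynomial string hash; all
# arithmetic stays below 2^53 so the result is exact in doubles.
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(master) %% m
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(part)))) {
      h <- (h * 31 + ch) %% m
    }
  }
  as.integer(h)
}

# Evaluate expr with a locally-seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One-sided DFT bin-center frequency for each of the n DFT coefficients
# (aliased: bin k -> min(k, n-k) * rate / n).
dft_bin_freqs <- function(n, rate) {
  k <- 0:(n - 1)
  pmin(k, n - k) * rate / n
}

# Multiply DFT coefficients by a per-bin mask/weight and invert. X is a
# series-per-row matrix. `weights` has length n (DFT bins).
.apply_dft_weights <- function(x, weights) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else t(x)
  n <- nrow(X)
  Y <- mvfft(X) * weights
  out <- mvfft(Y, inverse = TRUE) / n
  if (vec) out[, 1] else t(out)
}

#' Brickwall band-pass filter
#'
#' Band-pass by zeroing DFT coefficients whose bin-center frequency lies
#' outside \code{[lo, hi]} (both conjugate halves consistently), then
#' inverting the DFT. Exactly zero phase; out-of-band coefficients of the
#' output are exactly zero.
#'
#' @param x numeric vector, or matrix with one series per row.
#' @param band band name or numeric \code{c(lo, hi)} in Hz.
#' @param rate sampling rate in Hz.
#' @return filtered series, same shape as \code{x}.
#' @export
brickwall_bandpass <- function(x, band, rate = 312.5) {
  band <- band_limits(band)
  stopifnot(all(is.finite(x)))
  if (band[1] <= 0 || band[2] > rate / 2)
    stop("band must lie within (0, Nyquist]")
  n <- if (is.null(dim(x))) length(x) else ncol(x)
  f <- dft_bin_freqs(n, rate)
  w <- as.numeric(f >= band[1] & f <= band[2])
  Re(.apply_dft_weights(x, w))
}

# Analytic signal of the brickwall band-passed series: one DFT pass zeroes
# out-of-band and negative-frequency coefficients and doubles the retained
# positive-frequency ones.  Rows of the result are complex; Re() is the
# band-passed signal, Mod() its Hilbert envelope.
analytic_band <- function(x, band, rate = 312.5) {
  band <- band_limits(band)
  n <- if (is.null(dim(x))) length(x) else ncol(x)
  k <- 0:(n - 1)
  f <- k * rate / n
  pos <- k > 0 & k < n / 2
  w <- numeric(n)
  w[pos & f >= band[1] & f <= band[2]] <- 2
  # DC / Nyquist are excluded for band[1] > 0 and band[2] < Nyquist
  if (band[1] <= 0) w[1] <- 1
  if (n %% 2 == 0 && band[2] >= rate / 2) w[n / 2 + 1] <- 1
  .apply_dft_weights(x, w)
}

#' Hilbert envelope
#'
#' Modulus of the analytic signal (signal + i times its Hilbert transform).
#' The first and last 5\% of samples are distorted by edge effects and are
#' excluded from envelope correlations downstream (see
#' \code{\link{edge_guard_idx}}).
#'
#' @param x real, zero-mean numeric vector (or matrix, series per row).
#' @return nonnegative envelope, same shape as \code{x}.
#' @export
hilbert_envelope <- function(x) {
  stopifnot(all(is.finite(x)))
  n <- if (is.null(dim(x))) length(x) else ncol(x)
  k <- 0:(n - 1)
  w <- numeric(n)
  w[k > 0 & k < n / 2] <- 2
  w[1] <- 1
  if (n %% 2 == 0) w[n / 2 + 1] <- 1
  Mod(.apply_dft_weights(x, w))
}

#' Interior sample indices after discarding envelope edges
#'
#' @param n number of samples.
#' @param frac fraction discarded at each end (default 0.05).
#' @return integer index vector of retained interior samples.
#' @export
edge_guard_idx <- function(n, frac = 0.05) {
  g <- floor(n * frac)
  (g + 1L):(n - g)
}

# unit-normalize rows of a matrix
.unit_rows <- function(m) m / sqrt(rowSums(m^2))
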
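#' Raw periodogram of one epoch
#'
#' Single-taper (boxcar by default) one-sided periodogram per ROI, scaled so
#' that \code{sum(power) * df} equals the mean squared signal (Parseval).
#' Frequency resolution is \code{rate / 4096} (~0.0763 Hz at 312.5 Hz).
#'
#' @param epoch ROIs x 4096 matrix (or length-4096 vector).
#' @param rate sampling rate, Hz.
#' @param taper \code{"none"} (default; brickwall prefiltering already limits
#'   leakage at this resolution) or \code{"hann"}.
#' @param epoch_len required epoch length in samples.
#' @return ROIs x F matrix (F = 2049 one-sided bins), with attribute
#'   \code{freqs}.
#' @export
epoch_spectrum <- function(epoch, rate = 312.5, taper = c("none", "hann"),
                           epoch_len = 4096L) {
  taper <- match.arg(taper)
  if (is.null(dim(epoch))) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (n != epoch_len)
    stop("wrong epoch length: ", n, " != ", epoch_len)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
    w <- w / sqrt(mean(w^2))   # preserve power scaling
    epoch <- sweep(epoch, 2, w, "*")
  }
  X <- mvfft(t(epoch))
  nf <- n %/% 2 + 1L
  P <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (n * rate)
  scale <- c(1, rep(2, nf - 2L), 1)    # one-sided: double interior bins
  P <- t(P * scale)
  attr(P, "freqs") <- (seq_len(nf) - 1) * rate / n
  P
}

#' ROI- and epoch-averaged, area-normalized power spectrum
#'
#' Mean periodogram over all ROIs and epochs of a source-level epoch set,
#' restricted to \code{band} (closed interval on bin centers) and divided by
#' its own area (Riemann sum \code{sum(power) * df}), so the spectrum
#' integrates to 1 over its band and is invariant to global amplitude
#' scaling.
#'
#' @param epochs source-level \code{epoch_set}.
#' @param band analysis band, Hz (default \code{c(0.5, 30)}).
#' @param taper passed to \code{\link{epoch_spectrum}}.
#' @return object of class \code{power_spectrum}: \code{freqs},
#'   \code{power} (normalized density), \code{band}, \code{n_epochs},
#'   \code{n_rois}.
#' @export
average_normalized_spectrum <- function(epochs, band = c(0.5, 30),
                                        taper = "none") {
  stopifnot(inherits(epochs, "epoch_set"))
  band <- band_limits(band)
  ne <- dim(epochs$data)[1]
  if (ne < 1) stop("need at least 1 epoch")
  acc <- NULL
  for (e in seq_len(ne)) {
    P <- epoch_spectrum(epochs$data[e, , ], rate = epochs$rate, taper = taper)
    m <- colMeans(P)
    acc <- if (is.null(acc)) m else acc + m
    if (e == 1) freqs <- attr(P, "freqs")
  }
  acc <- acc / ne
  keep <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
  if (!any(keep)) stop("empty band")
  freqs <- freqs[keep]
  pw <- acc[keep]
  df <- epochs$rate / dim(epochs$data)[3]
  area <- sum(pw) * df
  if (area <= 0) stop("zero spectral power in band")
  structure(list(freqs = freqs, power = pw / area, band = as.numeric(band),
                 df = df, n_epochs = ne, n_rois = dim(epochs$data)[2]),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum: %d bins, %g-%g Hz, df %.4f Hz, %d epochs x %d ROIs>\n",
    length(x$freqs), x$band[1], x$band[2], x$df, x$n_epochs, x$n_rois))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ..., xlab = "Frequency (Hz)",
                                ylab = "Normalized power", type = "l") {
  graphics::plot(x$freqs, x$power, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Peak frequency of a normalized spectrum
#'
#' Frequency of the maximum bin within the search range (default 4--13 Hz,
#' the extended alpha range); ties break toward the lowest frequency; no
#' interpolation between bins.
#'
#' @param spec \code{power_spectrum}.
#' @param search search range, Hz.
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(spec, search = c(4, 13)) {
  stopifnot(inherits(spec, "power_spectrum"))
  idx <- which(spec$freqs >= search[1] - 1e-9 & spec$freqs <= search[2] + 1e-9)
  if (!length(idx)) stop("search range contains no frequency bins")
  pw <- spec$power[idx]
  if (all(pw == 0)) stop("flat-zero spectrum: peak frequency undefined")
  spec$freqs[idx[which.max(pw)]]
}
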
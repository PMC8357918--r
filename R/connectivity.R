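#' Orthogonalize one band-limited series against another
#'
#' Time-domain regression: \code{y_perp = y - (<y,x>/<x,x>) x}, removing the
#' zero-lag (leakage) component of \code{y} explained by \code{x}.
#'
#' @param x,y numeric vectors of equal length; \code{x} must not be all zero.
#' @return residual series orthogonal to \code{x}.
#' @export
orthogonalize <- function(x, y) {
  stopifnot(length(x) == length(y))
  sx <- sum(x * x)
  if (sx == 0) stop("cannot orthogonalize against an all-zero series")
  y - (sum(x * y) / sx) * x
}

# Pearson correlation of Hilbert envelopes on the interior (edge-guarded)
# samples; returns NA when either envelope is constant.
.env_cor <- function(a, b, guard = 0.05) {
  ea <- hilbert_envelope(a)
  eb <- hilbert_envelope(b)
  idx <- edge_guard_idx(length(a), guard)
  if (stats::sd(ea[idx]) == 0 || stats::sd(eb[idx]) == 0) return(NA_real_)
  cor(ea[idx], eb[idx])
}

#' Leakage-corrected amplitude envelope correlation of one pair
#'
#' Bidirectional pairwise orthogonalization: \code{r1} correlates the
#' envelope of \code{x} with the envelope of \code{y} orthogonalized to
#' \code{x}, \code{r2} the reverse; the two directional correlations are
#' averaged and then rescaled by \code{(r + 1) / 2} so that uncorrelated
#' signals map to 0.5 and the result lies in [0, 1]. Inputs are assumed
#' already band-limited (see \code{\link{brickwall_bandpass}}).
#'
#' @param x,y band-limited series of equal length.
#' @param guard edge-guard fraction excluded from envelope correlation.
#' @return value in [0, 1], or \code{NA} when a pair is degenerate
#'   (\code{y} exactly proportional to \code{x}).
#' @export
aec_corrected_pair <- function(x, y, guard = 0.05) {
  yp <- orthogonalize(x, y)
  xp <- orthogonalize(y, x)
  if (sum(yp^2) <= 1e-20 * sum(y^2) || sum(xp^2) <= 1e-20 * sum(x^2))
    return(NA_real_)
  r1 <- .env_cor(x, yp, guard)
  r2 <- .env_cor(y, xp, guard)
  if (is.na(r1) || is.na(r2)) return(NA_real_)
  ((r1 + r2) / 2 + 1) / 2
}

#' Uncorrected amplitude envelope correlation of one pair
#'
#' Same estimator without the orthogonalization step, for quantifying what
#' the leakage correction removes.
#'
#' @inheritParams aec_corrected_pair
#' @return value in [0, 1].
#' @export
aec_uncorrected_pair <- function(x, y, guard = 0.05) {
  r <- .env_cor(x, y, guard)
  (r + 1) / 2
}

#' Epoch-averaged AEC-c connectivity matrix
#'
#' Per epoch: brickwall band-pass all ROI series, compute the
#' leakage-corrected amplitude envelope correlation for every unordered ROI
#' pair (both orthogonalization directions, averaged, then rescaled to
#' [0, 1]), and average the resulting weighted adjacency matrices
#' element-wise over epochs. Pairs degenerate in an epoch are excluded from
#' that epoch's average; a pair undefined in all epochs is an error.
#'
#' @param source_epochs source-level \code{epoch_set} (epochs x ROIs x 4096).
#' @param band \code{"alpha"}, \code{"beta"} or numeric \code{c(lo, hi)} Hz.
#' @param guard edge-guard fraction.
#' @return object of class \code{connectivity_matrix}: \code{values}
#'   (symmetric, diagonal \code{NA}), \code{band}, \code{band_limits},
#'   \code{n_epochs}.
#' @export
aec_matrix <- function(source_epochs, band, guard = 0.05) {
  stopifnot(inherits(source_epochs, "epoch_set"))
  bl <- band_limits(band)
  ne <- dim(source_epochs$data)[1]
  if (ne < 1) stop("need at least 1 epoch")
  n_roi <- dim(source_epochs$data)[2]
  acc <- matrix(0, n_roi, n_roi)
  cnt <- matrix(0L, n_roi, n_roi)
  for (e in seq_len(ne)) {
    A <- analytic_band(source_epochs$data[e, , ], bl, source_epochs$rate)
    D <- aec_directional_cpp(A, guard)
    M <- ((D + t(D)) / 2 + 1) / 2
    ok <- is.finite(M)
    acc[ok] <- acc[ok] + M[ok]
    cnt <- cnt + ok
  }
  off <- !diag(TRUE, n_roi)
  if (any(cnt[off] == 0))
    stop("some ROI pairs were degenerate in every epoch")
  vals <- acc / pmax(cnt, 1L)
  vals[cnt == 0] <- NA
  diag(vals) <- NA
  structure(list(values = vals, band = attr(bl, "label"),
                 band_limits = as.numeric(bl), n_epochs = ne),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrix: %d x %d AEC-c, band %s, %d epochs; mean %.3f>\n",
    nrow(x$values), ncol(x$values), x$band, x$n_epochs,
    mean(x$values[upper.tri(x$values)], na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.connectivity_matrix <- function(x, ...,
                                     col = grDevices::hcl.colors(64, "viridis")) {
  v <- x$values
  graphics::image(seq_len(nrow(v)), seq_len(ncol(v)), t(v[nrow(v):1, ]),
                  col = col, xlab = "ROI", ylab = "ROI",
                  main = sprintf("AEC-c (%s)", x$band), ...)
  invisible(x)
}

# pure-R reference: full pairwise loop (used as an independent cross-check
# of the compiled kernel on small inputs)
.aec_matrix_r <- function(epoch, band, rate = 312.5, guard = 0.05) {
  xf <- brickwall_bandpass(epoch, band, rate)
  n <- nrow(xf)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- aec_corrected_pair(xf[i, ], xf[j, ], guard)
  }
  M
}
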
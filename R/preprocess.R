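#' Decimate a multichannel series to a common rate
#'
#' Anti-alias low-pass (zero-phase brickwall at 0.8 x the new Nyquist)
#' followed by keeping every k-th sample, where k = \code{rate /
#' target_rate} must be an integer. Factor 1 returns an identity copy.
#'
#' @param x numeric vector or channels-by-samples matrix.
#' @param rate current sampling rate, Hz.
#' @param target_rate target rate, Hz (default 312.5).
#' @return list with \code{data} (floor(T/k) samples) and \code{rate}.
#' @export
decimate <- function(x, rate, target_rate = 312.5) {
  k <- rate / target_rate
  if (abs(k - round(k)) > 1e-9 || k < 1 - 1e-9)
    stop("rate / target_rate must be an integer >= 1 (got ", k, ")")
  k <- as.integer(round(k))
  n <- if (is.null(dim(x))) length(x) else ncol(x)
  if (k == 1L) return(list(data = x, rate = target_rate))
  cutoff <- 0.8 * (target_rate / 2)
  if (n %% k == 0L) {
    # brickwall low-pass + subsampling is exactly spectrum truncation when
    # the subsample grid divides the DFT length
    out <- .decimate_fft(x, k, cutoff, rate)
  } else {
    f <- dft_bin_freqs(n, rate)
    xf <- Re(.apply_dft_weights(x, as.numeric(f <= cutoff)))
    keep <- seq.int(1L, by = k, length.out = n %/% k)
    out <- if (is.null(dim(x))) xf[keep] else xf[, keep, drop = FALSE]
  }
  list(data = out, rate = target_rate)
}

# decimation via spectrum truncation, channel pairs packed into one complex
# transform; equivalent to brickwall low-pass at `cutoff` followed by
# keeping every k-th sample (requires k | n)
.decimate_fft <- function(x, k, cutoff, rate) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  C <- nrow(x); n <- ncol(x); nd <- n %/% k
  fpos <- (0:(n %/% 2)) * rate / n
  hb <- max(which(fpos <= cutoff)) - 1L          # highest retained k index
  hb <- min(hb, nd - 1L - nd %/% 2)              # stay below decimated Nyquist
  idxu <- seq_len(hb + 1L)
  out <- matrix(0, C, nd)
  npair <- C %/% 2
  if (npair) {
    odd <- 2L * seq_len(npair) - 1L
    Z <- t(x[odd, , drop = FALSE]) + 1i * t(x[odd + 1L, , drop = FALSE])
    Fz <- mvfft(Z)
    Fd <- matrix(0 + 0i, nd, npair)
    Fd[idxu, ] <- Fz[idxu, , drop = FALSE]
    if (hb > 0) Fd[nd + 1L - seq_len(hb), ] <- Fz[n + 1L - seq_len(hb), ,
                                                  drop = FALSE]
    zd <- mvfft(Fd, inverse = TRUE) / n
    out[odd, ] <- t(Re(zd))
    out[odd + 1L, ] <- t(Im(zd))
  }
  if (C %% 2 == 1L) {
    Fz <- fft(x[C, ])
    Fd <- complex(nd)
    Fd[idxu] <- Fz[idxu]
    if (hb > 0) Fd[nd + 1L - seq_len(hb)] <- Fz[n + 1L - seq_len(hb)]
    out[C, ] <- Re(fft(Fd, inverse = TRUE)) / n
  }
  if (vec) out[1, ] else out
}

#' Split a series into fixed-length epochs
#'
#' Consecutive non-overlapping epochs of exactly 4096 samples (13.11 s at
#' 312.5 Hz); the trailing remainder is discarded.
#'
#' @param x channels-by-samples matrix (or vector) at 312.5 Hz.
#' @param rate sampling rate; must be 312.5.
#' @param epoch_len samples per epoch (4096).
#' @return object of class \code{epoch_set}: \code{data} is an
#'   n_epochs x C x 4096 array, with \code{rate} and \code{kept_epoch_ids}.
#' @export
split_epochs <- function(x, rate = 312.5, epoch_len = 4096L) {
  if (abs(rate - 312.5) > 1e-9) stop("split_epochs expects rate 312.5 Hz")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < epoch_len) stop("no complete epoch: ", n, " < ", epoch_len,
                          " samples")
  ne <- n %/% epoch_len
  a <- array(0, c(ne, nrow(x), epoch_len))
  for (e in seq_len(ne))
    a[e, , ] <- x[, ((e - 1L) * epoch_len + 1L):(e * epoch_len)]
  structure(list(data = a, rate = rate, kept_epoch_ids = seq_len(ne)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %d epochs x %d channels x %d samples @ %g Hz>\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate))
  invisible(x)
}

#' Flag malfunctioning channels
#'
#' Automated stand-in for visual bad-channel marking: a channel is flagged
#' when the robust z-score of its log-variance (median/MAD within channels of
#' the same kind) exceeds \code{z_thresh} in absolute value.
#'
#' @param rec \code{sensor_recording}.
#' @param z_thresh robust z threshold (default 4).
#' @return logical mask, TRUE = bad, one entry per channel.
#' @export
flag_bad_channels <- function(rec, z_thresh = 4) {
  stopifnot(inherits(rec, "sensor_recording"))
  M <- nrow(rec$data)
  if (M < 8) stop("need at least 8 channels")
  v <- log(rowSums((rec$data - rowMeans(rec$data))^2) / (ncol(rec$data) - 1))
  bad <- rep(FALSE, M)
  for (kd in unique(rec$array$channels$kind)) {
    idx <- which(rec$array$channels$kind == kd)
    s <- mad(v[idx])
    if (s == 0) next
    bad[idx] <- abs(v[idx] - median(v[idx])) / s > z_thresh
  }
  if (all(bad)) stop("all channels flagged as bad")
  bad
}

#' Reject artifact-contaminated epochs
#'
#' Automated stand-in for visual artifact rejection: for each channel the
#' per-epoch peak absolute amplitude is reduced to a robust z-score on the
#' log scale (channel median, pooled MAD scale; the log makes the
#' right-skewed peak distribution approximately symmetric); an epoch is
#' dropped when any channel's peak exceeds \code{amp_thresh_mad} robust
#' z-units.
#'
#' @param ep \code{epoch_set}.
#' @param amp_thresh_mad threshold in robust z units (default 6).
#' @return \code{epoch_set} containing only the retained epochs;
#'   \code{kept_epoch_ids} indexes into the input's epoch ids.
#' @export
reject_artifact_epochs <- function(ep, amp_thresh_mad = 6) {
  stopifnot(inherits(ep, "epoch_set"))
  ne <- dim(ep$data)[1]
  if (ne < 1) stop("need at least 1 epoch")
  peaks <- apply(abs(ep$data), c(1, 2), max)      # epochs x channels
  lp <- log(pmax(peaks, .Machine$double.xmin))
  centered <- sweep(lp, 2, apply(lp, 2, median))
  # pooled robust scale across all channels: stable even for few epochs
  s <- mad(centered, center = 0)
  if (s == 0) s <- mean(abs(centered))
  keep <- if (s == 0) rep(TRUE, ne) else
    apply(centered / s, 1, max) <= amp_thresh_mad
  if (!any(keep)) stop("no epochs survive artifact rejection")
  structure(list(data = ep$data[keep, , , drop = FALSE], rate = ep$rate,
                 kept_epoch_ids = ep$kept_epoch_ids[keep]),
            class = "epoch_set")
}
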
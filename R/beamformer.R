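#' Broad-band sensor covariance with diagonal loading
#'
#' Brickwall band-passes the good channels to the beamformer band and forms
#' the sample covariance over all retained samples, then adds
#' \code{reg x mean(eigenvalue)} to the diagonal (diagonal loading). The
#' covariance is computed from the band-masked DFT coefficients (Parseval),
#' which are kept on the object so source projection reuses the same
#' forward transform.
#'
#' @param rec \code{sensor_recording}.
#' @param band beamformer band, Hz (default \code{c(0.5, 48)}).
#' @param reg regularization as a fraction of the mean eigenvalue.
#' @return object of class \code{covariance_estimate}: \code{C} (loaded),
#'   \code{C_unloaded}, \code{filtered} (good-channel band-passed data),
#'   \code{good} (channel indices), \code{band}, \code{samples_used},
#'   \code{regularization}.
#' @export
estimate_covariance <- function(rec, band = c(0.5, 48), reg = 0.05) {
  stopifnot(inherits(rec, "sensor_recording"))
  band <- band_limits(band)
  good <- which(rec$good_channel_mask)
  if (length(good) < 2) stop("need at least 2 good channels")
  n <- ncol(rec$data)
  if (n <= length(good))
    warning("fewer samples than channels; covariance will be rank-deficient")
  # covariance via Parseval on the masked DFT: one forward FFT serves both
  # the covariance and (in reconstruct_roi_series) the weight projection
  if (band[1] <= 0 || band[2] > rec$rate / 2)
    stop("band must lie within (0, Nyquist]")
  f <- dft_bin_freqs(n, rec$rate)
  # positive-frequency bins only (0 < k < n/2); the conjugate half enters
  # the Parseval sum as a factor of 2
  hlim <- floor((n - 1) / 2) + 1L
  keep_bins <- which(f >= band[1] & f <= band[2])
  keep_bins <- keep_bins[keep_bins <= hlim]
  has_nyq <- n %% 2 == 0 && rec$rate / 2 >= band[1] && rec$rate / 2 <= band[2]
  if (!length(keep_bins) && !has_nyq) stop("band contains no frequency bins")
  Xm <- .masked_dft(rec$data[good, , drop = FALSE], keep_bins)
  C0 <- 2 * Re(t(Xm) %*% Conj(Xm))
  Xnyq <- NULL
  if (has_nyq) {
    Xnyq <- .masked_dft(rec$data[good, , drop = FALSE], n %/% 2 + 1L,
                        allow_nyquist = TRUE)
    C0 <- C0 + Re(t(Xnyq) %*% Conj(Xnyq))
  }
  C0 <- C0 / (n * (n - 1))
  C0 <- (C0 + t(C0)) / 2
  mean_eig <- mean(diag(C0))          # trace/M = mean eigenvalue
  C <- C0 + diag(reg * mean_eig, nrow(C0))
  R_chol <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R_chol)) stop("covariance singular after regularization")
  Ci <- chol2inv(R_chol)
  structure(list(C = C, C_unloaded = C0, Ci = Ci, good = good,
                 band = band, samples_used = n, regularization = reg,
                 rate = rec$rate, Xm = Xm, keep_bins = keep_bins,
                 Xnyq = Xnyq),
            class = "covariance_estimate")
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf(
    "<covariance_estimate: %d x %d, band %g-%g Hz, %d samples, reg %g>\n",
    nrow(x$C), ncol(x$C), x$band[1], x$band[2], x$samples_used,
    x$regularization))
  invisible(x)
}

# deterministic sign fix: first component larger than tol is made positive
.fix_sign <- function(v, tol = 1e-12) {
  nz <- which(abs(v) > tol)
  if (length(nz) && v[nz[1]] < 0) -v else v
}

#' Optimal scalar-beamformer source orientation
#'
#' Solves the generalized eigenproblem
#' \eqn{(L^T C^{-1} L)\nu = \lambda (L^T C^{-2} L)\nu} restricted to the
#' tangential subspace (the two leading right singular vectors of the
#' lead-field block; the radial direction of a spherical conductor is
#' magnetically silent) and returns the orientation of maximal output SNR
#' (pseudo-Z), unit-normalized, with the sign fixed so the first nonzero
#' component is positive. Near-degenerate eigenvalues (relative gap below
#' 1e-9) are resolved deterministically to the lexicographically smallest
#' candidate vector, with a warning.
#'
#' @param L M x 3 lead-field block.
#' @param C M x M (regularized) covariance matrix, or a
#'   \code{covariance_estimate}.
#' @return unit 3-vector.
#' @export
optimal_orientation <- function(L, C) {
  Ci <- NULL
  if (inherits(C, "covariance_estimate")) { Ci <- C$Ci; C <- C$C }
  L <- as.matrix(L)
  stopifnot(ncol(L) == 3, nrow(L) == nrow(C))
  sv <- svd(L, nu = 0, nv = 3)
  V2 <- sv$v[, 1:2, drop = FALSE]
  L2 <- L %*% V2
  Ci_L2 <- if (is.null(Ci)) solve(C, L2) else Ci %*% L2
  A <- crossprod(L2, Ci_L2)            # L2' C^-1 L2
  B <- crossprod(Ci_L2)                # L2' C^-2 L2
  ev <- eigen(solve(B, A))
  lam <- Re(ev$values)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  vecs <- Re(ev$vectors)[, ord, drop = FALSE]
  cand1 <- .fix_sign(as.numeric(V2 %*% vecs[, 1]))
  cand1 <- cand1 / sqrt(sum(cand1^2))
  if (abs(lam[1] - lam[2]) <= 1e-9 * max(abs(lam[1]), abs(lam[2]))) {
    cand2 <- .fix_sign(as.numeric(V2 %*% vecs[, 2]))
    cand2 <- cand2 / sqrt(sum(cand2^2))
    pick <- cand1
    for (d in 1:3) {
      if (abs(cand1[d] - cand2[d]) > 1e-12) {
        if (cand2[d] < cand1[d]) pick <- cand2
        break
      }
    }
    warning("degenerate beamformer orientation; lexicographic tie-break used")
    return(pick)
  }
  cand1
}

#' Scalar beamformer weights for one source
#'
#' Minimum-variance (LCMV) weights \eqn{w = C^{-1} l / (l^T C^{-1} l)} for
#' the oriented lead field \eqn{l = L \nu}; unit gain \eqn{w^T l = 1} holds
#' before normalization. With \code{normalize = TRUE} (the default) the
#' returned weights have unit Euclidean norm, which rescales the source
#' amplitude only.
#'
#' @param L M x 3 lead-field block (or an M-vector, already oriented).
#' @param C covariance matrix or \code{covariance_estimate}.
#' @param nu unit orientation (ignored when \code{L} is a vector).
#' @param normalize return unit-norm weights?
#' @return numeric M-vector of weights.
#' @export
compute_weights <- function(L, C, nu = NULL, normalize = TRUE) {
  Ci <- NULL
  if (inherits(C, "covariance_estimate")) { Ci <- C$Ci; C <- C$C }
  l <- if (is.matrix(L) && ncol(L) == 3) {
    stopifnot(length(nu) == 3)
    as.numeric(L %*% nu)
  } else as.numeric(L)
  if (sum(l^2) == 0) stop("silent source: oriented lead field is zero")
  Ci_l <- if (is.null(Ci)) solve(C, l) else as.numeric(Ci %*% l)
  denom <- sum(l * Ci_l)
  if (denom <= 1e-15 * sum(l^2) / mean(diag(C)))
    stop("silent source: l' C^-1 l vanishes")
  w <- Ci_l / denom
  if (normalize) w / sqrt(sum(w^2)) else w
}

#' Reconstruct broadband ROI time series with a scalar beamformer
#'
#' For each centroid: lead-field block on the good channels, optimal
#' orientation, normalized LCMV weights, and projection of the band-passed
#' sensor data through the weights. Output sampling rate equals the input
#' rate.
#'
#' @param rec \code{sensor_recording}.
#' @param centroids n_roi x 3 matrix of source positions (meters).
#' @param head \code{head_model} (defaults to the recording's own).
#' @param band beamformer band, Hz.
#' @param reg covariance regularization fraction.
#' @return n_roi x T matrix of source series; attributes \code{orientations}
#'   (n_roi x 3), \code{weights} (n_roi x M_good), \code{good_channels},
#'   \code{rate}, \code{band}, \code{regularization}.
#' @export
reconstruct_roi_series <- function(rec, centroids, head = rec$head,
                                   band = c(0.5, 48), reg = 0.05) {
  stopifnot(inherits(rec, "sensor_recording"))
  centroids <- as.matrix(centroids)
  cov <- estimate_covariance(rec, band = band, reg = reg)
  arr_good <- .subset_array(rec$array, cov$good)
  n_roi <- nrow(centroids)
  W <- matrix(0, n_roi, length(cov$good))
  ori <- matrix(0, n_roi, 3)
  for (r in seq_len(n_roi)) {
    L <- lead_field(arr_good, head, centroids[r, ])
    nu <- suppressWarnings(optimal_orientation(L, cov))
    ori[r, ] <- nu
    W[r, ] <- compute_weights(L, cov, nu, normalize = TRUE)
  }
  # project through the weights in the frequency domain (the band-passed
  # sensor series are only nonzero on the kept bins); ROI pairs share one
  # inverse transform via real/imaginary packing
  n <- cov$samples_used
  Yk <- cov$Xm %*% t(W)
  Ynyq <- if (is.null(cov$Xnyq)) NULL else Re(cov$Xnyq %*% t(W))
  out <- matrix(0, n_roi, n)
  npair <- n_roi %/% 2
  mir <- n - cov$keep_bins + 2L
  if (npair) {
    odd <- 2L * seq_len(npair) - 1L
    Y <- matrix(0 + 0i, n, npair)
    Y[cov$keep_bins, ] <- Yk[, odd, drop = FALSE] +
      1i * Yk[, odd + 1L, drop = FALSE]
    Y[mir, ] <- Conj(Yk[, odd, drop = FALSE]) +
      1i * Conj(Yk[, odd + 1L, drop = FALSE])
    if (!is.null(Ynyq))
      Y[n %/% 2 + 1L, ] <- Ynyq[, odd] + 1i * Ynyq[, odd + 1L]
    z <- mvfft(Y, inverse = TRUE) / n
    out[odd, ] <- t(Re(z))
    out[odd + 1L, ] <- t(Im(z))
  }
  if (n_roi %% 2 == 1L) {
    Y <- complex(n)
    Y[cov$keep_bins] <- Yk[, n_roi]
    Y[mir] <- Conj(Yk[, n_roi])
    if (!is.null(Ynyq)) Y[n %/% 2 + 1L] <- Ynyq[, n_roi]
    out[n_roi, ] <- Re(fft(Y, inverse = TRUE)) / n
  }
  rownames(out) <- rownames(centroids)
  structure(out, orientations = ori, weights = W, good_channels = cov$good,
            rate = rec$rate, band = cov$band, regularization = reg)
}

# DFT coefficients of real channel series on a set of interior bins
# (0 < k < n/2), two real channels packed per complex FFT column.
.masked_dft <- function(x, keep_bins, allow_nyquist = FALSE) {
  m <- nrow(x); n <- ncol(x)
  maxidx <- if (allow_nyquist) n %/% 2 + 1L else floor((n - 1) / 2) + 1L
  stopifnot(all(keep_bins > 1), all(keep_bins <= maxidx))
  npair <- m %/% 2
  Xm <- matrix(0 + 0i, length(keep_bins), m)
  mir <- n - keep_bins + 2L
  if (npair) {
    Z <- t(x[2 * seq_len(npair) - 1, , drop = FALSE]) +
      1i * t(x[2 * seq_len(npair), , drop = FALSE])
    Fz <- mvfft(Z)
    Fu <- Fz[keep_bins, , drop = FALSE]
    Fl <- Conj(Fz[mir, , drop = FALSE])
    Xm[, 2 * seq_len(npair) - 1] <- (Fu + Fl) / 2
    Xm[, 2 * seq_len(npair)] <- (Fu - Fl) / (2i)
  }
  if (m %% 2 == 1) {
    Fz <- fft(x[m, ])
    Xm[, m] <- Fz[keep_bins]
  }
  Xm
}

# restrict a sensor_array to a channel subset (coils follow their channels)
.subset_array <- function(array, idx) {
  keep_coil <- array$coil_channel %in% idx
  remap <- match(array$coil_channel[keep_coil], idx)
  structure(list(system = array$system,
                 channels = array$channels[idx, , drop = FALSE],
                 coil_pos = array$coil_pos[keep_coil, , drop = FALSE],
                 coil_normal = array$coil_normal[keep_coil, , drop = FALSE],
                 coil_weight = array$coil_weight[keep_coil],
                 coil_channel = remap,
                 n_channels = length(idx)),
            class = "sensor_array")
}
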
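#' Cohort specification
#'
#' Describes the simulated study: subjects measured at three timepoints on
#' two sensor systems (two sessions on a 151-channel axial-gradiometer
#' helmet, one on a 306-channel magnetometer + planar-gradiometer helmet),
#' eyes-closed resting state, with native sampling rates 312.5 / 625 /
#' 1250 Hz.
#'
#' @param n_subjects number of subjects (>= 2; default 8).
#' @param timepoints ordered session labels.
#' @param system_per_timepoint named map label -> array kind.
#' @param duration_s session duration, seconds (default 300).
#' @param native_rate_per_timepoint named map label -> Hz; each rate must be
#'   \code{312.5 * 2^k} so an integer decimation to 312.5 Hz exists.
#' @param noise per-channel-kind sensor noise standard deviations.
#' @param seed master integer seed; all subject/session streams derive from
#'   it deterministically.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 8,
                        timepoints = c("BL", "FU1", "FU2"),
                        system_per_timepoint = c(BL = "ctf151",
                                                 FU1 = "ctf151",
                                                 FU2 = "vectorview306"),
                        duration_s = 300,
                        native_rate_per_timepoint = c(BL = 312.5, FU1 = 625,
                                                      FU2 = 1250),
                        noise = c(axial_gradiometer = 5e-15,
                                  magnetometer = 5e-15,
                                  planar_gradiometer = 3e-13),
                        seed = 1L) {
  if (n_subjects < 2) stop("configuration error: n_subjects must be >= 2")
  stopifnot(length(timepoints) >= 1,
            all(timepoints %in% names(system_per_timepoint)),
            all(timepoints %in% names(native_rate_per_timepoint)))
  rates <- native_rate_per_timepoint[timepoints]
  k <- log2(rates / 312.5)
  if (any(abs(k - round(k)) > 1e-9) || any(k < -1e-9))
    stop("each native rate must be 312.5 * 2^k for integer k >= 0")
  if (duration_s * min(rates) < 2 * 4096)
    stop("duration too short: need at least 2 epochs after decimation")
  structure(list(n_subjects = as.integer(n_subjects),
                 timepoints = timepoints,
                 system_per_timepoint = system_per_timepoint,
                 duration_s = duration_s,
                 native_rate_per_timepoint = native_rate_per_timepoint,
                 noise = noise, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec: %d subjects x %d timepoints (%s), %gs, seed %d>\n",
              x$n_subjects, length(x$timepoints),
              paste(sprintf("%s@%g Hz/%s", x$timepoints,
                            x$native_rate_per_timepoint[x$timepoints],
                            x$system_per_timepoint[x$timepoints]),
                    collapse = ", "),
              x$duration_s, x$seed))
  invisible(x)
}

#' Nearest valid coupling matrix
#'
#' Alternating projection onto the positive semi-definite cone and the set of
#' unit-diagonal matrices with off-diagonal entries in \code{[0, 0.8]}
#' (Higham-style, without Dykstra correction), followed by a final eigenvalue
#' clamp. The result is symmetric, has unit diagonal, off-diagonals in
#' \code{[0, 0.8]} and minimum eigenvalue >= -1e-8.
#'
#' @param R symmetric 90 x 90 (or any square) target matrix.
#' @param max_iter alternating-projection iterations.
#' @return projected matrix.
#' @export
nearest_coupling_psd <- function(R, max_iter = 25) {
  R <- (R + t(R)) / 2
  for (it in seq_len(max_iter)) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) >= 0 && it > 1) break
    R <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    R <- (R + t(R)) / 2
    R[R < 0] <- 0
    R[R > 0.8] <- 0.8
    diag(R) <- 1
  }
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    R <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    R <- (R + t(R)) / 2
    R[R < 0] <- 0
    R[R > 0.8] <- 0.8
    diag(R) <- 1
  }
  R
}

# modular target coupling matrix: random module partition, within-module
# coupling drawn uniformly, between-module zero. Consumes the RNG stream.
.random_coupling <- function(n_roi = 90, n_modules = 6,
                             strength = c(0.35, 0.7)) {
  mod <- sample(rep_len(seq_len(n_modules), n_roi))
  R <- matrix(0, n_roi, n_roi)
  for (m in seq_len(n_modules)) {
    idx <- which(mod == m)
    s <- runif(1, strength[1], strength[2])
    R[idx, idx] <- s
  }
  diag(R) <- 1
  nearest_coupling_psd(R)
}

#' Generate subject fingerprints for a cohort
#'
#' Each subject receives a generative "fingerprint": an alpha peak frequency,
#' a 1/f background exponent, relative band amplitudes, per-ROI dipole
#' moments, and one 90 x 90 target envelope-coupling matrix per band (alpha,
#' beta) with modular structure, projected to the nearest valid correlation
#' matrix. Sessions of the same subject share the fingerprint; different
#' subjects get mutually distinct fingerprints. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec \code{\link{cohort_spec}}.
#' @return list of \code{subject_fingerprint} objects, length
#'   \code{spec$n_subjects}.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 2) stop("configuration error: n_subjects must be >= 2")
  lapply(seq_len(spec$n_subjects), function(i) {
    with_seed(derive_seed(spec$seed, "fingerprint", i), {
      fp <- list(
        subject = i,
        alpha_peak_hz = runif(1, 8, 12),
        one_over_f_exponent = runif(1, 0.8, 1.4),
        band_amp = c(delta = 0.7, theta = 0.5, alpha = 1.3, beta = 0.8,
                     gamma = 0.25) * exp(rnorm(5, 0, 0.15)),
        coupling_target = list(alpha = .random_coupling(),
                               beta = .random_coupling()),
        roi_amplitude = 30e-9 * exp(rnorm(90, 0, 0.2)))
      # cached matrix square roots for envelope synthesis
      fp$coupling_sqrt <- lapply(fp$coupling_target, .sqrtm_psd)
      class(fp) <- "subject_fingerprint"
      fp
    })
  })
}

#' @export
print.subject_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<subject_fingerprint #%d: alpha peak %.2f Hz, 1/f exponent %.2f>\n",
    x$subject, x$alpha_peak_hz, x$one_over_f_exponent))
  invisible(x)
}

# symmetric PSD square root via eigendecomposition
.sqrtm_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Correlated, rectified, low-pass (~cutoff_hz) envelopes: generated on a
# coarse grid (env_rate Hz), coupled through the matrix square root of the
# target correlation matrix, rectified by absolute value, then linearly
# interpolated to the carrier grid and normalized to unit RMS per ROI.
.correlated_envelopes <- function(R, n_samples, rate, cutoff_hz = 1,
                                  env_rate = 8, S = NULL) {
  n_roi <- nrow(R)
  dur <- n_samples / rate
  K <- max(16L, 2L * as.integer(ceiling(dur * env_rate / 2)))
  Z <- matrix(rnorm(n_roi * K), n_roi, K)
  f <- dft_bin_freqs(K, env_rate)
  w <- as.numeric(f <= cutoff_hz)
  Zl <- Re(.apply_dft_weights(Z, w))
  if (is.null(S)) S <- .sqrtm_psd(R)
  E <- t(abs(S %*% Zl))                      # K x n_roi, time-major
  tt <- (seq_len(n_samples) - 1) / rate
  idx <- as.integer(pmin(floor(tt * env_rate) + 1, K - 1))
  frac <- tt * env_rate - (idx - 1)
  env_interp_cpp(E, idx, frac)
}

# Band-limited unit-variance noise carriers, independent per ROI, generated
# in the frequency domain with amplitude profile(s) over the n DFT bins.
# Two independent real carriers share one inverse transform (packed into
# the real and imaginary parts of a single complex spectrum); coefficients
# are drawn only on the (usually sparse) support of each profile.
.freq_noise <- function(n_roi, n_samples, prof_a, prof_b = NULL) {
  n <- n_samples
  X <- spectrum_noise_cpp(n, n_roi, prof_a, prof_b)
  z <- mvfft(X, inverse = TRUE) / n
  # returned time-major (samples x ROIs), unit RMS per column
  unitize <- function(x) {
    s <- sqrt(colMeans(x^2))
    s[s == 0] <- 1
    x / rep(s, each = nrow(x))
  }
  a <- unitize(Re(z))
  if (is.null(prof_b)) return(a)
  list(a = a, b = unitize(Im(z)))
}

# Exact band-limited upsampling by an integer factor (spectral zero-padding);
# valid because all simulated content lies far below the base Nyquist.
.upsample_fft <- function(x, k) {
  nb <- ncol(x)
  n <- nb * k
  m <- nrow(x)
  half <- floor((nb - 1) / 2)
  up <- 1:(half + 1)
  lw <- 1:half
  out <- matrix(0, m, n)
  npair <- m %/% 2
  if (npair) {
    odd <- 2L * seq_len(npair) - 1L
    X <- mvfft(t(x[odd, , drop = FALSE]) + 1i * t(x[odd + 1L, , drop = FALSE]))
    Y <- matrix(0 + 0i, n, npair)
    Y[up, ] <- X[up, , drop = FALSE]
    Y[n + 1 - lw, ] <- X[nb + 1 - lw, , drop = FALSE]
    z <- mvfft(Y, inverse = TRUE) / nb
    out[odd, ] <- t(Re(z))
    out[odd + 1L, ] <- t(Im(z))
  }
  if (m %% 2 == 1L) {
    X <- fft(x[m, ])
    Y <- complex(n)
    Y[up] <- X[up]
    Y[n + 1 - lw] <- X[nb + 1 - lw]
    out[m, ] <- Re(fft(Y, inverse = TRUE)) / nb
  }
  out
}

#' Simulate one session of ground-truth source activity
#'
#' Per ROI the signal is a sum of band processes: an alpha carrier
#' (band-limited noise with a Gaussian spectral profile centered at the
#' subject's alpha peak) and a beta carrier (flat 13--30 Hz), each modulated
#' by slow (~1 Hz low-pass) rectified Gaussian envelopes whose cross-ROI
#' correlation matrix equals the fingerprint's band coupling target, plus a
#' 1/f^(exponent) background whose delta/theta/gamma weights come from the
#' fingerprint's band amplitudes. The same fingerprint with a different
#' \code{session_seed} yields a different realization of the same subject.
#'
#' @param fp \code{subject_fingerprint}.
#' @param rate sampling rate, Hz (>= 100).
#' @param duration_s session length in seconds.
#' @param session_seed integer seed for this session's realization.
#' @param alpha_sigma_hz spectral width (SD) of the alpha carrier profile.
#' @return object of class \code{source_activity} with fields \code{series}
#'   (90 x T, dipole-moment units), \code{rate}, \code{roi_labels},
#'   \code{ground_truth}.
#' @export
simulate_source_activity <- function(fp, rate, duration_s,
                                     session_seed = 1L,
                                     alpha_sigma_hz = 0.4) {
  stopifnot(inherits(fp, "subject_fingerprint"))
  if (rate < 100) stop("rate must be >= 100 Hz")
  # synthesis happens at the 312.5 Hz base rate whenever the requested rate
  # is an integer multiple of it, followed by exact band-limited upsampling
  # (all content lies below 50 Hz, far under the base Nyquist)
  k_up <- rate / 312.5
  use_base <- abs(k_up - round(k_up)) < 1e-9 && round(k_up) >= 2
  rb <- if (use_base) 312.5 else rate
  n <- as.integer(round(rb * duration_s))
  n_roi <- length(fp$roi_amplitude)
  with_seed(derive_seed(session_seed, "source"), {
    f <- dft_bin_freqs(n, rb)
    # 1/f background over 0.5-48 Hz, band-weighted outside alpha/beta
    wb <- numeric(n)
    inb <- f >= 0.5 & f <= 48
    wb[inb] <- f[inb]^(-fp$one_over_f_exponent / 2)
    wb[f >= 0.5 & f < 4] <- wb[f >= 0.5 & f < 4] * fp$band_amp[["delta"]]
    wb[f >= 4 & f < 8] <- wb[f >= 4 & f < 8] * fp$band_amp[["theta"]]
    wb[f > 30 & f <= 48] <- wb[f > 30 & f <= 48] * fp$band_amp[["gamma"]]
    # alpha carrier: Gaussian profile at the subject's peak
    wa <- exp(-(f - fp$alpha_peak_hz)^2 / (2 * alpha_sigma_hz^2))
    wa[abs(f - fp$alpha_peak_hz) > 5 * alpha_sigma_hz] <- 0
    # beta carrier: flat 13-30 Hz
    wbeta <- as.numeric(f >= 13 & f <= 30)
    bg <- .freq_noise(n_roi, n, wb)        # all components time-major
    carriers <- .freq_noise(n_roi, n, wa, wbeta)
    ea <- .correlated_envelopes(fp$coupling_target$alpha, n, rb,
                                S = fp$coupling_sqrt$alpha)
    eb <- .correlated_envelopes(fp$coupling_target$beta, n, rb,
                                S = fp$coupling_sqrt$beta)
    x <- combine_bands_cpp(bg, carriers$a, ea, carriers$b, eb,
                           fp$band_amp[["alpha"]], fp$band_amp[["beta"]])
    x <- finalize_source_cpp(x, fp$roi_amplitude)  # ROIs x samples, demeaned
    if (use_base) x <- .upsample_fft(x, as.integer(round(k_up)))
  })
  structure(list(series = x, rate = rate,
                 roi_labels = sprintf("ROI%02d", seq_len(n_roi)),
                 ground_truth = fp),
            class = "source_activity")
}

#' @export
print.source_activity <- function(x, ...) {
  cat(sprintf("<source_activity: %d ROIs x %d samples @ %g Hz (subject %d)>\n",
              nrow(x$series), ncol(x$series), x$rate,
              x$ground_truth$subject))
  invisible(x)
}
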
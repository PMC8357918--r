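test_that("brickwall filter passes on-bin in-band tones exactly and zeroes
           out-of-band content", {
  rate <- 312.5
  k10 <- round(10 / (rate / 4096)); f10 <- k10 * rate / 4096
  t <- (0:4095) / rate
  x <- sin(2 * pi * f10 * t)
  expect_lt(max(abs(brickwall_bandpass(x, "alpha") - x)), 1e-10)
  k20 <- round(20 / (rate / 4096)); f20 <- k20 * rate / 4096
  y <- sin(2 * pi * f20 * t)
  expect_lt(max(abs(brickwall_bandpass(y, "alpha"))), 1e-10)
  set.seed(1)
  z <- brickwall_bandpass(rnorm(4096), "alpha")
  Z <- fft(z)
  f <- megconsist:::dft_bin_freqs(4096, rate)
  out_band <- f < 8 | f > 13
  # stop-band coefficients are zeroed exactly; re-transforming the real
  # output leaves only double-precision round-off
  expect_lt(max(abs(Z[out_band])) / max(abs(Z)), 1e-12)
  expect_error(brickwall_bandpass(z, c(100, 200)), "Nyquist")
})

test_that("Hilbert envelope recovers amplitude and an AM modulator", {
  rate <- 312.5
  t <- (0:8191) / rate
  k <- round(10 / (rate / 8192)); f0 <- k * rate / 8192
  env <- hilbert_envelope(2.5 * cos(2 * pi * f0 * t))
  idx <- edge_guard_idx(length(t))
  expect_lt(max(abs(env[idx] - 2.5)) / 2.5, 0.01)
  expect_true(all(env >= 0))
  mod <- 1 + 0.5 * cos(2 * pi * 1 * t)
  am <- hilbert_envelope(mod * cos(2 * pi * f0 * t))
  expect_gt(cor(am[idx], mod[idx]), 0.99)
})

test_that("orthogonalization removes the shared component exactly", {
  expect_equal(orthogonalize(c(1, 0), c(1, 1)), c(0, 1))
  set.seed(2)
  x <- rnorm(100)
  expect_equal(orthogonalize(x, 3 * x), rep(0, 100))
  y <- rnorm(100)
  expect_lt(abs(sum(orthogonalize(x, y) * x)), 1e-10)
  expect_error(orthogonalize(numeric(100), y), "zero")
})

test_that("AEC-c is 0.5 for independent signals and removes pure zero-lag
           leakage that uncorrected AEC reports as coupling", {
  set.seed(5)
  # the single-epoch estimate is unbiased around 0.5 with sampling sd ~0.05
  # in the alpha band; the baseline property is asserted on the mean
  vals <- replicate(20, {
    a <- bl_noise(4096); b <- bl_noise(4096)
    aec_corrected_pair(a, b)
  })
  expect_lt(abs(mean(vals) - 0.5), 0.05)
  expect_true(all(abs(vals - 0.5) < 0.2))
  leak <- replicate(20, {
    x <- bl_noise(4096)
    y <- x + 0.4 * bl_noise(4096)
    c(aec_corrected_pair(x, y), aec_uncorrected_pair(x, y))
  })
  expect_lt(abs(mean(leak[1, ]) - 0.5), 0.05)
  expect_true(all(leak[2, ] > 0.75))
  # symmetry in the arguments by construction
  set.seed(6)
  x <- bl_noise(4096); y <- bl_noise(4096)
  expect_equal(aec_corrected_pair(x, y), aec_corrected_pair(y, x),
               tolerance = 1e-12)
})

test_that("a shared envelope on independent carriers is detected above
           baseline at a 20-epoch average", {
  set.seed(8)
  rate <- 312.5
  vals <- replicate(20, {
    t <- (0:4095) / rate
    env <- abs(brickwall_bandpass(rnorm(4096), c(0.07, 1), rate)) + 0.2
    x <- brickwall_bandpass(rnorm(4096), "alpha", rate) * env
    y <- brickwall_bandpass(rnorm(4096), "alpha", rate) * env
    aec_corrected_pair(x, y)
  })
  expect_gt(mean(vals), 0.55)
})

test_that("the compiled directional kernel agrees with the pairwise
           reference implementation", {
  set.seed(12)
  ep <- matrix(rnorm(8 * 4096), 8)
  ref <- megconsist:::.aec_matrix_r(ep, "alpha")
  A <- megconsist:::analytic_band(ep, band_limits("alpha"), 312.5)
  D <- megconsist:::aec_directional_cpp(A, 0.05)
  M <- ((D + t(D)) / 2 + 1) / 2
  expect_equal(M[upper.tri(M)], ref[upper.tri(ref)], tolerance = 1e-12)
})

test_that("epoch-averaged AEC matrices are symmetric, bounded, 90 x 90 and
           epoch-order invariant", {
  fp <- fix_fingerprints()[[1]]
  src <- simulate_source_activity(fp, 312.5, 2 * 4096 / 312.5, 77)
  ep <- split_epochs(src$series)
  m <- aec_matrix(ep, "alpha")
  expect_equal(dim(m$values), c(90L, 90L))
  expect_equal(m$values, t(m$values), tolerance = 1e-12)
  off <- m$values[upper.tri(m$values)]
  expect_true(all(off >= 0 & off <= 1))
  expect_true(all(is.na(diag(m$values))))
  ep_rev <- ep
  ep_rev$data <- ep$data[2:1, , ]
  m_rev <- aec_matrix(ep_rev, "alpha")
  expect_equal(m$values, m_rev$values, tolerance = 1e-12)
})

test_that("AEC-c is invariant to per-ROI scaling and sign flips, and a fully
           degenerate pair is an error", {
  fp <- fix_fingerprints()[[2]]
  src <- simulate_source_activity(fp, 312.5, 4096 / 312.5 * 2, 78)
  ep <- split_epochs(src$series[1:6, ])
  scl <- c(2, -1, 0.5, -10, 1, 3)
  ep_s <- ep
  ep_s$data <- sweep(ep$data, 2, scl, "*")
  m1 <- aec_matrix(ep, "alpha")
  m2 <- aec_matrix(ep_s, "alpha")
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
  bad <- ep
  bad$data[, 2, ] <- 2 * bad$data[, 1, ]       # exact leakage duplicate
  expect_error(aec_matrix(bad, "alpha"), "degenerate")
})

test_that("mean AEC-c across coupled pairs increases with the envelope
           coupling target (rank correlation > 0.8)", {
  targets <- c(0, 0.2, 0.4, 0.6)
  rate <- 312.5
  n <- 4096
  set.seed(33)
  K <- 120                               # envelope grid covers the epoch
  means <- vapply(targets, function(rho) {
    R <- matrix(rho, 4, 4); diag(R) <- 1
    S <- megconsist:::.sqrtm_psd(R)
    mean(replicate(20, {
      E <- abs(S %*% matrix(rnorm(4 * K), 4))
      idx <- pmin(floor((0:(n - 1)) / rate * 8) + 1, K - 1)
      fr <- (0:(n - 1)) / rate * 8 - (idx - 1)
      env <- E[, idx] * rep(1 - fr, each = 4) + E[, idx + 1] * rep(fr, each = 4)
      carr <- t(replicate(4, brickwall_bandpass(rnorm(n), "alpha", rate)))
      x <- carr * (env + 0.15)
      m <- aec_matrix(split_epochs(x), "alpha")
      mean(m$values[upper.tri(m$values)])
    }))
  }, numeric(1))
  expect_gt(cor(means, targets, method = "spearman"), 0.8)
  expect_true(all(diff(means) > 0))
})
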
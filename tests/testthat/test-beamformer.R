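# a small noisy recording with one dominant tangential source, reused below
fix_one_source <- function() fixture("one_source", function() {
  hm <- fix_head(); ctf <- fix_ctf()
  pos <- c(0.03, 0.02, 0.05)
  u <- pos / sqrt(sum(pos^2))
  tg <- megconsist:::.tangent_pair(u)
  ori <- 0.3 * tg$t1 + 0.7 * tg$t2
  ori <- ori / sqrt(sum(ori^2))
  l <- lead_field(ctf, hm, pos, ori)
  set.seed(91)
  n <- 3 * 4096
  s <- brickwall_bandpass(rnorm(n), c(0.5, 48), 312.5)
  data <- outer(as.numeric(l), s) * 3e-8 +
    matrix(rnorm(151 * n), 151) * 0.01 * 3e-8 * max(abs(l))
  rec <- structure(list(data = data, rate = 312.5, array = ctf, head = hm,
                        system = "ctf151",
                        good_channel_mask = rep(TRUE, 151)),
                   class = "sensor_recording")
  list(rec = rec, pos = pos, ori = ori, truth = s, l = l)
})

test_that("covariance estimate is symmetric, band-limited and loaded", {
  fx <- fix_one_source()
  cov <- estimate_covariance(fx$rec, reg = 0.05)
  expect_equal(cov$C, t(cov$C))
  ev0 <- eigen(cov$C_unloaded, symmetric = TRUE, only.values = TRUE)$values
  ev <- eigen(cov$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0.05 * mean(ev0) * (1 - 1e-9))
  expect_equal(cov$samples_used, ncol(fx$rec$data))
})

test_that("white-noise covariance approaches sigma^2 I", {
  ctf <- fix_ctf(); hm <- fix_head()
  set.seed(7)
  n <- 60000
  rec <- structure(list(data = matrix(rnorm(20 * n), 20), rate = 312.5,
                        array = ctf, head = hm, system = "ctf151",
                        good_channel_mask = c(rep(TRUE, 20),
                                              rep(FALSE, 131))),
                   class = "sensor_recording")
  # mask only uses good channels; fake 20-channel recording
  rec$data <- rbind(rec$data, matrix(0, 131, n))
  rec$good_channel_mask <- c(rep(TRUE, 20), rep(FALSE, 131))
  cov <- estimate_covariance(rec, reg = 0)
  C <- cov$C_unloaded
  # band-passing to 0.5-48 of 156.25 keeps ~30.4% of white power
  frac <- mean(megconsist:::dft_bin_freqs(n, 312.5) >= 0.5 &
                 megconsist:::dft_bin_freqs(n, 312.5) <= 48)
  expect_equal(mean(diag(C)), frac, tolerance = 0.02)
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)) / mean(diag(C)), 0.05)
})

test_that("optimal orientation matches a 1-degree grid search and truth", {
  fx <- fix_one_source()
  cov <- estimate_covariance(fx$rec, reg = 0.05)
  L <- lead_field(fx$rec$array, fx$rec$head, fx$pos)
  nu <- optimal_orientation(L, cov)
  expect_equal(sqrt(sum(nu^2)), 1, tolerance = 1e-12)
  ang <- acos(min(1, abs(sum(nu * fx$ori)))) * 180 / pi
  expect_lt(ang, 5)
  # oracle: pseudo-Z maximization over 1-degree orientation steps
  u <- fx$pos / sqrt(sum(fx$pos^2))
  tg <- megconsist:::.tangent_pair(u)
  Ci <- solve(cov$C)
  best <- -Inf; borient <- NULL
  for (adeg in 0:179) {
    v <- cos(adeg * pi / 180) * tg$t1 + sin(adeg * pi / 180) * tg$t2
    lv <- as.numeric(L %*% v)
    pz <- sum(lv * (Ci %*% lv)) / sum(lv * (Ci %*% (Ci %*% lv)))
    if (pz > best) { best <- pz; borient <- v }
  }
  expect_lt(acos(min(1, abs(sum(nu * borient)))) * 180 / pi, 5)
})

test_that("degenerate orientation (C = I) takes the deterministic
           tie-break", {
  fx <- fix_one_source()
  L <- lead_field(fx$rec$array, fx$rec$head, fx$pos)
  expect_warning(n1 <- optimal_orientation(L, diag(151)), "tie-break")
  expect_warning(n2 <- optimal_orientation(L, diag(151)), "tie-break")
  expect_identical(n1, n2)
  expect_equal(sqrt(sum(n1^2)), 1, tolerance = 1e-12)
})

test_that("LCMV weights satisfy unit gain and the C = I closed form", {
  fx <- fix_one_source()
  cov <- estimate_covariance(fx$rec, reg = 0.05)
  L <- lead_field(fx$rec$array, fx$rec$head, fx$pos)
  nu <- optimal_orientation(L, cov)
  l <- as.numeric(L %*% nu)
  w_raw <- compute_weights(L, cov, nu, normalize = FALSE)
  expect_equal(sum(w_raw * l), 1, tolerance = 1e-10)
  w <- compute_weights(L, cov, nu, normalize = TRUE)
  expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-10)
  wI <- compute_weights(L, diag(151), nu, normalize = FALSE)
  expect_equal(wI, l / sum(l^2), tolerance = 1e-12)
  expect_error(compute_weights(matrix(0, 151, 3), cov, c(1, 0, 0)), "silent")
})

test_that("reconstruction recovers a dominant source and separates two", {
  fx <- fix_one_source()
  cen <- fix_centroids()
  # place the true source at centroid 1
  cen2 <- cen
  cen2[1, ] <- fx$pos
  roi <- reconstruct_roi_series(fx$rec, cen2, fix_head())
  expect_equal(dim(roi), c(90, ncol(fx$rec$data)))
  expect_gt(abs(cor(roi[1, ], fx$truth)), 0.95)
  # two independent sources at well-separated centroids
  hm <- fix_head(); ctf <- fix_ctf()
  posB <- c(-0.04, -0.01, 0.04)
  uB <- posB / sqrt(sum(posB^2)); tgB <- megconsist:::.tangent_pair(uB)
  lB <- lead_field(ctf, hm, posB, tgB$t1)
  set.seed(17)
  sB <- brickwall_bandpass(rnorm(ncol(fx$rec$data)), c(0.5, 48), 312.5)
  rec2 <- fx$rec
  rec2$data <- rec2$data + outer(as.numeric(lB), sB) * 3e-8
  cen3 <- cen2; cen3[2, ] <- posB
  roi2 <- reconstruct_roi_series(rec2, cen3, hm)
  expect_gt(abs(cor(roi2[1, ], fx$truth)), abs(cor(roi2[1, ], sB)))
  expect_gt(abs(cor(roi2[2, ], sB)), abs(cor(roi2[2, ], fx$truth)))
})

test_that("weight normalization changes amplitude only: AEC matrices are
           identical with and without it", {
  fx <- fix_one_source()
  cen <- fix_centroids()[1:6, ]
  cov <- estimate_covariance(fx$rec)
  hm <- fix_head()
  series_n <- matrix(0, 6, ncol(fx$rec$data))
  series_u <- matrix(0, 6, ncol(fx$rec$data))
  xf <- brickwall_bandpass(fx$rec$data, c(0.5, 48), 312.5)
  for (r in 1:6) {
    L <- lead_field(fx$rec$array, hm, cen[r, ])
    nu <- optimal_orientation(L, cov)
    series_n[r, ] <- compute_weights(L, cov, nu, normalize = TRUE) %*% xf
    series_u[r, ] <- compute_weights(L, cov, nu, normalize = FALSE) %*% xf
  }
  m_n <- aec_matrix(split_epochs(series_n), "alpha")
  m_u <- aec_matrix(split_epochs(series_u), "alpha")
  expect_equal(m_n$values, m_u$values, tolerance = 1e-10)
})
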
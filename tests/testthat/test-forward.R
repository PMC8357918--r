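test_that("sensor arrays have the two systems' channel complements", {
  ctf <- fix_ctf()
  expect_equal(ctf$n_channels, 151L)
  expect_true(all(ctf$channels$kind == "axial_gradiometer"))
  vv <- fix_vv()
  expect_equal(vv$n_channels, 306L)
  expect_equal(sum(vv$channels$kind == "magnetometer"), 102L)
  expect_equal(sum(vv$channels$kind == "planar_gradiometer"), 204L)
  expect_error(build_sensor_array("ctf275"), "arg")
})

test_that("coil geometry invariants hold", {
  for (arr in list(fix_ctf(), fix_vv())) {
    expect_lt(max(abs(sqrt(rowSums(arr$coil_normal^2)) - 1)), 1e-12)
    # gradiometers have exactly two coils, magnetometers one
    n_coils <- table(arr$coil_channel)
    kinds <- arr$channels$kind
    expect_true(all(n_coils[kinds != "magnetometer"] == 2))
    expect_true(all(n_coils[kinds == "magnetometer"] == 1))
  }
  # axial baseline along the coil normal
  ctf <- fix_ctf()
  for (ch in c(1, 77, 151)) {
    coils <- which(ctf$coil_channel == ch)
    dvec <- ctf$coil_pos[coils[2], ] - ctf$coil_pos[coils[1], ]
    nrm <- ctf$coil_normal[coils[1], ]
    expect_equal(abs(sum(dvec * nrm)), sqrt(sum(dvec^2)), tolerance = 1e-9)
    expect_equal(sqrt(sum(dvec^2)), 0.05, tolerance = 1e-12)
  }
  # planar baseline perpendicular to the coil normal
  vv <- fix_vv()
  pg <- which(vv$channels$kind == "planar_gradiometer")
  for (ch in pg[c(1, 100, 204)]) {
    coils <- which(vv$coil_channel == ch)
    dvec <- vv$coil_pos[coils[2], ] - vv$coil_pos[coils[1], ]
    nrm <- vv$coil_normal[coils[1], ]
    expect_lt(abs(sum(dvec * nrm)), 1e-12)
    expect_equal(sqrt(sum(dvec^2)), 0.0168, tolerance = 1e-12)
  }
})

test_that("spherical-conductor silences are exact for every channel kind", {
  hm <- fix_head()
  pos <- c(0.03, 0.02, 0.05)
  radial <- pos / sqrt(sum(pos^2))
  for (arr in list(fix_ctf(), fix_vv())) {
    expect_identical(max(abs(lead_field(arr, hm, pos, radial))), 0)
    expect_identical(max(abs(lead_field(arr, hm, c(0, 0, 0), c(1, 0, 0)))), 0)
  }
  expect_error(lead_field(fix_ctf(), hm, c(0, 0, 0.1), c(1, 0, 0)), "outside")
})

test_that("lead field matches independent Sarvas evaluation and decays with
           angular distance", {
  hm <- fix_head()
  vv <- fix_vv()
  pos <- c(0, 0.04, 0.04)
  tang <- c(1, 0, 0)                      # tangential for this position
  lf <- lead_field(vv, hm, pos, tang)
  mags <- which(vv$channels$kind == "magnetometer")
  # oracle: direct evaluation at each magnetometer coil
  for (ch in mags[c(3, 30, 80)]) {
    coil <- which(vv$coil_channel == ch)
    b <- sarvas_field_oracle(vv$coil_pos[coil, ], pos, tang)
    expect_equal(lf[ch], sum(b * vv$coil_normal[coil, ]), tolerance = 1e-12)
  }
  # magnetometer nearest the source sees more field than one ~90 deg away
  u <- pos / sqrt(sum(pos^2))
  site_u <- as.matrix(vv$channels[mags, c("x", "y", "z")])
  cosang <- (site_u %*% u) / sqrt(rowSums(site_u^2))
  near <- mags[which.max(cosang)]
  far <- mags[which.min(abs(cosang))]
  expect_gt(abs(lf[near]), abs(lf[far]))
})

test_that("sensor projection is linear, rank-1 for one source, and carries
           calibrated noise", {
  hm <- fix_head()
  ctf <- fix_ctf()
  cen <- fix_centroids()
  fp <- fix_fingerprints()[[1]]
  src <- simulate_source_activity(fp, 312.5, 8192 / 312.5, 31)
  # single active ROI, no noise -> every channel proportional to its series
  one <- src
  one$series[-1, ] <- 0
  rec1 <- project_to_sensors(one, cen, NULL, ctf, hm,
                             noise_std = c(axial_gradiometer = 0,
                                           magnetometer = 0,
                                           planar_gradiometer = 0),
                             seed = 7)
  live <- which(rowSums(abs(rec1$data)) > 0)
  cors <- abs(cor(t(rec1$data[live, ]), one$series[1, ]))
  expect_true(all(cors > 1 - 1e-10))
  # linearity
  two <- src; two$series[-(1:2), ] <- 0
  second <- src; second$series[-2, ] <- 0
  rec2 <- project_to_sensors(two, cen, NULL, ctf, hm,
                             noise_std = c(axial_gradiometer = 0,
                                           magnetometer = 0,
                                           planar_gradiometer = 0),
                             seed = 7)
  rec3 <- project_to_sensors(second, cen, NULL, ctf, hm,
                             noise_std = c(axial_gradiometer = 0,
                                           magnetometer = 0,
                                           planar_gradiometer = 0),
                             seed = 7)
  expect_equal(rec2$data, rec1$data + rec3$data, tolerance = 1e-12)
  # noise only: channel variance ~ noise_std^2 within 5%
  silent <- src; silent$series[] <- 0
  recn <- project_to_sensors(silent, cen, NULL, ctf, hm,
                             noise_std = c(axial_gradiometer = 2e-14,
                                           magnetometer = 2e-14,
                                           planar_gradiometer = 1e-12),
                             seed = 12)
  v <- mean(apply(recn$data, 1, var))
  expect_lt(abs(v - (2e-14)^2) / (2e-14)^2, 0.05)
  # determinism given seed
  recn2 <- project_to_sensors(silent, cen, NULL, ctf, hm,
                              noise_std = c(axial_gradiometer = 2e-14,
                                            magnetometer = 2e-14,
                                            planar_gradiometer = 1e-12),
                              seed = 12)
  expect_identical(recn$data, recn2$data)
})
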
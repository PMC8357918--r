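#' Spherical volume-conductor head model
#'
#' A homogeneous conducting sphere (optionally one sphere per channel, as in
#' vendor "multi-sphere" models). In this model a current dipole with radial
#' orientation, or located at the sphere's center, produces no magnetic field
#' outside the head.
#'
#' @param center sphere center, meters, head frame (length-3).
#' @param radius sphere radius in meters (> 0).
#' @param channel_centers optional M x 3 matrix of per-channel sphere centers
#'   (multi-sphere model); overrides \code{center} channel-wise.
#' @return object of class \code{head_model}.
#' @export
head_model <- function(center = c(0, 0, 0), radius = 0.09,
                       channel_centers = NULL) {
  stopifnot(length(center) == 3, is.numeric(radius), radius > 0)
  if (!is.null(channel_centers)) {
    channel_centers <- as.matrix(channel_centers)
    stopifnot(ncol(channel_centers) == 3)
  }
  structure(list(center = as.numeric(center), radius = radius,
                 channel_centers = channel_centers),
            class = "head_model")
}

# Quasi-uniform points on a spherical cap (z/r in [cos(theta_max), 1]),
# Fibonacci spiral.
.fibonacci_cap <- function(n, theta_max) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - cos(theta_max)) * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.tangent_pair <- function(nrm) {
  # two unit tangent vectors orthogonal to unit vector nrm
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * nrm) * nrm
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
          nrm[3] * t1[1] - nrm[1] * t1[3],
          nrm[1] * t1[2] - nrm[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

#' Build a simulated MEG sensor array
#'
#' Two helmet layouts are supported, emulating the channel complements of the
#' two recording systems: \code{"ctf151"}, 151 axial gradiometers
#' quasi-uniform on a spherical helmet cap (radial coil normals, second coil
#' displaced outward along the normal by the baseline), and
#' \code{"vectorview306"}, 102 sites each carrying one radial magnetometer
#' plus two orthogonal planar gradiometers (306 channels). Planar gradiometer
#' output is the coil difference divided by the baseline (T/m); axial
#' gradiometer output is the plain coil difference (T).
#'
#' @param kind \code{"ctf151"} or \code{"vectorview306"}.
#' @param helmet_radius helmet sphere radius, meters.
#' @param baseline gradiometer baseline, meters (defaults 0.05 axial,
#'   0.0168 planar).
#' @param helmet_center helmet sphere center (defaults to origin, concentric
#'   with the default head sphere).
#' @param theta_max polar half-opening angle of the helmet cap, radians.
#' @return object of class \code{sensor_array}: channel table plus a coil
#'   table (position, normal, signed weight, owning channel).
#' @export
build_sensor_array <- function(kind = c("ctf151", "vectorview306"),
                               helmet_radius = 0.105,
                               baseline = NULL,
                               helmet_center = c(0, 0, 0),
                               theta_max = 2.0) {
  kind <- match.arg(kind)
  hc <- as.numeric(helmet_center)
  if (kind == "ctf151") {
    if (is.null(baseline)) baseline <- 0.05
    n <- 151L
    u <- .fibonacci_cap(n, theta_max)            # unit radial directions
    site <- sweep(u * helmet_radius, 2, hc, "+")
    coil_pos <- rbind(site, sweep(u * (helmet_radius + baseline), 2, hc, "+"))
    coil_normal <- rbind(u, u)
    coil_weight <- c(rep(1, n), rep(-1, n))
    coil_channel <- c(seq_len(n), seq_len(n))
    channels <- data.frame(
      id = sprintf("MLC%03d", seq_len(n)),
      kind = "axial_gradiometer",
      x = site[, 1], y = site[, 2], z = site[, 3],
      nx = u[, 1], ny = u[, 2], nz = u[, 3],
      baseline = baseline, stringsAsFactors = FALSE)
  } else {
    if (is.null(baseline)) baseline <- 0.0168
    ns <- 102L
    u <- .fibonacci_cap(ns, theta_max)
    site <- sweep(u * helmet_radius, 2, hc, "+")
    cp <- list(); cn <- list(); cw <- list(); cc <- list()
    ch_kind <- character(0); ch_pos <- NULL; ch_nrm <- NULL; ch_bl <- numeric(0)
    chan <- 0L
    for (s in seq_len(ns)) {
      nrm <- u[s, ]
      tg <- .tangent_pair(nrm)
      # magnetometer
      chan <- chan + 1L
      cp[[length(cp) + 1L]] <- site[s, ]; cn[[length(cn) + 1L]] <- nrm
      cw[[length(cw) + 1L]] <- 1; cc[[length(cc) + 1L]] <- chan
      ch_kind <- c(ch_kind, "magnetometer"); ch_bl <- c(ch_bl, 0)
      ch_pos <- rbind(ch_pos, site[s, ]); ch_nrm <- rbind(ch_nrm, nrm)
      # two planar gradiometers, baselines along t1 and t2 (radial normals)
      for (tv in list(tg$t1, tg$t2)) {
        chan <- chan + 1L
        for (sgn in c(1, -1)) {
          cp[[length(cp) + 1L]] <- site[s, ] + sgn * (baseline / 2) * tv
          cn[[length(cn) + 1L]] <- nrm
          cw[[length(cw) + 1L]] <- sgn / baseline
          cc[[length(cc) + 1L]] <- chan
        }
        ch_kind <- c(ch_kind, "planar_gradiometer"); ch_bl <- c(ch_bl, baseline)
        ch_pos <- rbind(ch_pos, site[s, ]); ch_nrm <- rbind(ch_nrm, nrm)
      }
    }
    coil_pos <- do.call(rbind, cp)
    coil_normal <- do.call(rbind, cn)
    coil_weight <- unlist(cw)
    coil_channel <- unlist(cc)
    channels <- data.frame(
      id = sprintf("MEG%04d", seq_len(chan)),
      kind = ch_kind,
      x = ch_pos[, 1], y = ch_pos[, 2], z = ch_pos[, 3],
      nx = ch_nrm[, 1], ny = ch_nrm[, 2], nz = ch_nrm[, 3],
      baseline = ch_bl, stringsAsFactors = FALSE)
  }
  structure(list(system = kind, channels = channels,
                 coil_pos = coil_pos, coil_normal = .unit_rows(coil_normal),
                 coil_weight = coil_weight,
                 coil_channel = as.integer(coil_channel),
                 n_channels = nrow(channels)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array '%s': %d channels (%s), %d coils>\n",
              x$system, x$n_channels,
              paste(sprintf("%d %s", table(x$channels$kind),
                            names(table(x$channels$kind))), collapse = ", "),
              nrow(x$coil_pos)))
  invisible(x)
}

# Magnetic field (tesla) of a unit current dipole at r0 with moment m inside
# a homogeneous conducting sphere, evaluated at coil positions (Sarvas
# closed form), projected on coil normals and combined into channels.
.sarvas_channels <- function(array, head, pos, moment) {
  K <- nrow(array$coil_pos)
  centers <- if (!is.null(head$channel_centers))
    head$channel_centers[array$coil_channel, , drop = FALSE]
  else matrix(head$center, K, 3, byrow = TRUE)
  r0m <- matrix(pos, K, 3, byrow = TRUE) - centers        # dipole, per coil
  rc <- array$coil_pos - centers                          # coil, per coil
  d0 <- sqrt(rowSums(r0m^2))
  if (any(d0 >= head$radius))
    stop("dipole position lies outside the head sphere")
  a_vec <- rc - r0m
  a <- sqrt(rowSums(a_vec^2))
  r <- sqrt(rowSums(rc^2))
  adotr <- rowSums(a_vec * rc)
  r0dotr <- rowSums(r0m * rc)
  Fv <- a * (r * a + r^2 - r0dotr)
  if (any(abs(Fv) < 1e-12 * r^3))
    stop("degenerate source/sensor configuration (Sarvas F ~ 0)")
  # Q = m x r0 per coil
  Q <- cbind(moment[2] * r0m[, 3] - moment[3] * r0m[, 2],
             moment[3] * r0m[, 1] - moment[1] * r0m[, 3],
             moment[1] * r0m[, 2] - moment[2] * r0m[, 1])
  Qdotr <- rowSums(Q * rc)
  gf1 <- a^2 / r + adotr / a + 2 * a + 2 * r
  gf2 <- a + 2 * r + adotr / a
  gradF <- gf1 * rc - gf2 * r0m
  B <- 1e-7 * (Fv * Q - Qdotr * gradF) / Fv^2
  proj <- rowSums(B * array$coil_normal) * array$coil_weight
  as.numeric(rowsum(proj, array$coil_channel, reorder = TRUE))
}

#' Lead field of a current dipole
#'
#' Sensor-array response (one value per channel, per unit dipole moment) of
#' an equivalent current dipole in the spherical head model, using the Sarvas
#' closed-form field. Radially oriented dipoles and dipoles at the sphere
#' center give an exactly zero lead field (spherical-conductor silence).
#'
#' @param array \code{\link{build_sensor_array}} result.
#' @param head \code{\link{head_model}}.
#' @param pos dipole position, meters, head frame (strictly inside sphere).
#' @param orientation unit moment orientation (length-3); if \code{NULL},
#'   the full M x 3 lead-field block for unit x/y/z moments is returned.
#' @return numeric M-vector (or M x 3 matrix if \code{orientation = NULL}).
#' @export
lead_field <- function(array, head, pos, orientation = NULL) {
  stopifnot(inherits(array, "sensor_array"), inherits(head, "head_model"),
            length(pos) == 3)
  if (is.null(orientation)) {
    return(cbind(.sarvas_channels(array, head, pos, c(1, 0, 0)),
                 .sarvas_channels(array, head, pos, c(0, 1, 0)),
                 .sarvas_channels(array, head, pos, c(0, 0, 1))))
  }
  stopifnot(length(orientation) == 3)
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("orientation must be nonzero")
  .sarvas_channels(array, head, pos, orientation / nrm)
}

#' Default 90-ROI centroid layout
#'
#' A synthetic stand-in for atlas centroid coordinates (which are not part of
#' any deposited data): 78 "cortical" points quasi-uniform on a spiral at
#' radii 0.060--0.075 m plus 12 "subcortical" points at radii 0.020--0.045 m,
#' head frame centered on the head sphere. A user-supplied 90-row table
#' (label, x, y, z in meters) can be used instead anywhere a centroid matrix
#' is accepted.
#'
#' @param center head-sphere center the layout is placed around.
#' @return 90 x 3 matrix with rownames \code{ROI01..ROI90} and a
#'   \code{"region_type"} attribute.
#' @export
default_centroids <- function(center = c(0, 0, 0)) {
  i <- seq_len(78) - 0.5
  z <- 1 - 2 * i / 78
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(r * cos(phi), r * sin(phi), z)
  rad_c <- seq(0.060, 0.075, length.out = 78)
  cort <- u * rad_c
  j <- seq_len(12) - 0.5
  zj <- 1 - 2 * j / 12
  phj <- 2 * pi * j * (1 + sqrt(5)) / 2
  rj <- sqrt(pmax(0, 1 - zj^2))
  sub <- cbind(rj * cos(phj), rj * sin(phj), zj) * seq(0.020, 0.045,
                                                       length.out = 12)
  pts <- sweep(rbind(cort, sub), 2, as.numeric(center), "+")
  rownames(pts) <- sprintf("ROI%02d", seq_len(90))
  attr(pts, "region_type") <- c(rep("cortical", 78), rep("subcortical", 12))
  pts
}

#' Project source activity onto a sensor array
#'
#' Forward-models each ROI's dipole time series through its lead field and
#' adds white Gaussian sensor noise with a per-channel-kind standard
#' deviation. Deterministic given \code{seed}.
#'
#' @param src \code{source_activity} object (see
#'   \code{\link{simulate_source_activity}}).
#' @param positions 90 x 3 ROI centroid positions (meters).
#' @param orientations 90 x 3 unit dipole orientations; default draws random
#'   tangential orientations from \code{seed}.
#' @param array,head sensor array and head model.
#' @param noise_std named per-kind noise standard deviations (sensor units).
#' @param seed integer RNG seed for noise (and default orientations).
#' @return object of class \code{sensor_recording}.
#' @export
project_to_sensors <- function(src, positions, orientations = NULL,
                               array, head,
                               noise_std = c(axial_gradiometer = 5e-15,
                                             magnetometer = 5e-15,
                                             planar_gradiometer = 3e-13),
                               seed = 1L) {
  stopifnot(inherits(src, "source_activity"))
  positions <- as.matrix(positions)
  n_roi <- nrow(src$series)
  if (nrow(positions) != n_roi)
    stop("positions must have one row per ROI (", n_roi, ")")
  with_seed(derive_seed(seed, "project"), {
    if (is.null(orientations)) orientations <- random_tangential(positions,
                                                                 head)
    orientations <- .unit_rows(as.matrix(orientations))
    L <- matrix(0, array$n_channels, n_roi)
    for (r in seq_len(n_roi))
      L[, r] <- lead_field(array, head, positions[r, ], orientations[r, ])
    data <- L %*% src$series
    sd_ch <- noise_std[array$channels$kind]
    if (anyNA(sd_ch)) stop("noise_std missing for some channel kind")
    add_noise_cpp(data, as.numeric(sd_ch), derive_seed(seed, "sensor_noise"))
  })
  structure(list(data = data, rate = src$rate, array = array, head = head,
                 system = array$system,
                 good_channel_mask = rep(TRUE, array$n_channels),
                 roi_labels = src$roi_labels,
                 leadfield = L, orientations = orientations),
            class = "sensor_recording")
}

#' Random tangential dipole orientations
#'
#' Draws one unit orientation per source, orthogonal to the source's radial
#' direction (the orientation a spherical conductor can actually see).
#' Consumes the current RNG stream.
#'
#' @param positions n x 3 positions (meters).
#' @param head \code{\link{head_model}}.
#' @return n x 3 matrix of unit tangential vectors.
#' @export
random_tangential <- function(positions, head) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  out <- matrix(0, n, 3)
  for (r in seq_len(n)) {
    rad <- positions[r, ] - head$center
    d <- sqrt(sum(rad^2))
    if (d < 1e-12) { # center: any direction is tangential
      v <- rnorm(3); out[r, ] <- v / sqrt(sum(v^2)); next
    }
    rad <- rad / d
    tg <- .tangent_pair(rad)
    ang <- runif(1, 0, 2 * pi)
    out[r, ] <- cos(ang) * tg$t1 + sin(ang) * tg$t2
  }
  out
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording '%s': %d channels x %d samples @ %g Hz (%d good)>\n",
    x$system, nrow(x$data), ncol(x$data), x$rate, sum(x$good_channel_mask)))
  invisible(x)
}
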
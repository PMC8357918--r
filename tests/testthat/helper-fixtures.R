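# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fix_ctf <- function() fixture("ctf", function() build_sensor_array("ctf151"))
fix_vv <- function() fixture("vv", function()
  build_sensor_array("vectorview306"))
fix_head <- function() fixture("head", function() head_model())
fix_centroids <- function() fixture("cen", function() default_centroids())

# a small cohort of fingerprints (8 subjects, short sessions)
fix_fingerprints <- function() fixture("fps", function()
  make_cohort(cohort_spec(duration_s = 8192 / 312.5, seed = 101)))

# one 20-epoch source session of subject 1 at 312.5 Hz (spectral/coupling
# property tests need many epochs)
fix_long_source <- function() fixture("long_src", function() {
  fp <- fix_fingerprints()[[1]]
  simulate_source_activity(fp, 312.5, 20 * 4096 / 312.5, session_seed = 202)
})

# direct (independent) evaluation of the magnetic field of a current dipole
# in a conducting sphere at a point sensor: oracle for lead-field tests
sarvas_field_oracle <- function(r_sensor, r_dipole, q) {
  mu0_4pi <- 1e-7
  a_vec <- r_sensor - r_dipole
  a <- sqrt(sum(a_vec^2))
  r <- sqrt(sum(r_sensor^2))
  F <- a * (r * a + r^2 - sum(r_dipole * r_sensor))
  gradF <- (a^2 / r + sum(a_vec * r_sensor) / a + 2 * a + 2 * r) * r_sensor -
    (a + 2 * r + sum(a_vec * r_sensor) / a) * r_dipole
  Q <- c(q[2] * r_dipole[3] - q[3] * r_dipole[2],
         q[3] * r_dipole[1] - q[1] * r_dipole[3],
         q[1] * r_dipole[2] - q[2] * r_dipole[1])
  mu0_4pi * (F * Q - sum(Q * r_sensor) * gradF) / F^2
}

# band-limited noise helper for connectivity tests
bl_noise <- function(n, band = "alpha", rate = 312.5) {
  brickwall_bandpass(rnorm(n), band, rate)
}

# source-level epoch_set from a series matrix
as_epochs <- function(x, rate = 312.5) split_epochs(x, rate)
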
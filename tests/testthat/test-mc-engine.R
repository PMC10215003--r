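# Monte Carlo engine: Compton kinematics, electron stepping against analytic
# oracles, determinism, and energy bookkeeping.

test_that("Compton samples satisfy the exact scattering relation", {
  E <- 1
  s <- sample_compton(E, 2000, seed = 11)
  k <- E / 0.51099895
  # energy conservation per event
  expect_equal(s$scattered_energy + s$electron_energy, rep(E, 2000),
               tolerance = 1e-14)
  # Compton relation between scattered energy and photon angle
  expect_equal(s$scattered_energy,
               E / (1 + k * (1 - s$cos_theta_photon)), tolerance = 1e-12)
  # backscatter limit: no sample below E / (1 + 2k) = 0.2037 MeV at 1 MeV
  expect_true(min(s$scattered_energy) >= E / (1 + 2 * k) - 1e-12)
  expect_true(max(s$scattered_energy) <= E + 1e-12)
})

test_that("mean Compton energy transfer matches the Klein-Nishina quadrature", {
  E <- 4; me <- 0.51099895; k <- E / me
  # quadrature oracle: <1 - eps> under the Klein-Nishina differential cross
  # section dsigma/deps proportional to (1/eps + eps)(1 - eps sin^2/(1+eps^2))
  kn <- function(eps) {
    t <- (1 - eps) / (k * eps)
    sin2 <- t * (2 - t)
    (1 / eps + eps) * (1 - eps * sin2 / (1 + eps^2))
  }
  lo <- 1 / (1 + 2 * k)
  norm <- stats::integrate(kn, lo, 1, rel.tol = 1e-10)$value
  mean_T <- stats::integrate(function(e) (1 - e) * kn(e), lo, 1,
                             rel.tol = 1e-10)$value / norm
  n <- 2e5
  s <- sample_compton(E, n, seed = 2)
  frac <- s$electron_energy / E
  se <- stats::sd(frac) / sqrt(n)
  expect_lt(abs(mean(frac) - mean_T), 3 * se + 1e-6)
})

test_that("electron gyration reproduces the analytic helix", {
  B <- 1.5; E <- 1
  me <- 0.51099895
  p <- sqrt(E * (E + 2 * me))
  rg <- p / (2.99792458 * B)
  expect_equal(rg, 0.3162, tolerance = 1e-3)
  step <- 0.001
  tr <- electron_trajectory(E, c(0, 0, 0), c(0, 0, 1),
                            magnetic_field(B, c(1, 0, 0)), density = 0,
                            step = step, use_stopping = FALSE, use_ms = FALSE,
                            max_steps = 2200)
  pos <- tr$positions
  # gyroradius from the lateral excursion; motion confined to the y-z plane
  expect_equal(diff(range(pos[, 2])) / 2, rg, tolerance = 1e-4)
  expect_lt(diff(range(pos[, 1])), 1e-12)
  # closure after one period (fractional step by linear interpolation)
  period <- 2 * pi * rg / step
  k0 <- floor(period); fr <- period - k0
  pclose <- pos[k0 + 1, ] + fr * (pos[k0 + 2, ] - pos[k0 + 1, ])
  expect_lt(sqrt(sum((pclose - pos[1, ])^2)), 1e-4)
})

test_that("field-free straight tracks stop at the CSDA range", {
  for (E in c(0.5, 2)) {
    for (rho in c(0.5, 1)) {
      tr <- electron_trajectory(E, density = rho, field = magnetic_field(0),
                                step = 0.001, use_stopping = TRUE,
                                use_ms = FALSE)
      expected <- (csda_range(E) - csda_range(0.0101)) / rho
      expect_equal(tr$path_length, expected, tolerance = 0.01)
      # straight line: net displacement equals path length
      pos <- tr$positions
      expect_equal(sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2)), tr$path_length,
                   tolerance = 1e-9)
    }
  }
})

test_that("kernel generation is deterministic in the seed", {
  st <- transport_settings(n_batches = 5)
  k1 <- generate_edk(2, 1, settings = st, n_histories = 2000, seed = 77,
                     radial_bounds = edk_radial_bounds(20, 0.05, 2, 30),
                     n_polar = 10, n_azimuth = 12)
  k2 <- generate_edk(2, 1, settings = st, n_histories = 2000, seed = 77,
                     radial_bounds = edk_radial_bounds(20, 0.05, 2, 30),
                     n_polar = 10, n_azimuth = 12)
  expect_identical(k1$values, k2$values)
  expect_identical(k1$uncertainty, k2$uncertainty)
  k3 <- generate_edk(2, 1, settings = st, n_histories = 2000, seed = 78,
                     radial_bounds = edk_radial_bounds(20, 0.05, 2, 30),
                     n_polar = 10, n_azimuth = 12)
  expect_false(identical(k1$values, k3$values))
})

test_that("kernel generation balances the energy ledger", {
  k <- generate_edk(4, 0.5, settings = transport_settings(n_batches = 5),
                    n_histories = 5000, seed = 3)
  acc <- k$accounting
  bal <- acc$energy_in + acc$created - acc$deposited - acc$escaped -
    acc$mass_sunk
  expect_lt(abs(bal) / acc$energy_in, 1e-9)
  expect_gt(acc$escaped, 0) # some scatter leaves the 60 g/cm2 sphere
  expect_true(all(k$values >= 0))
  expect_lt(sum(k$values), 1)
})

test_that("reference dose simulation balances energy and is reproducible", {
  ph <- build_phantom("water", spacing = 1, size = c(8, 8, 10))
  beam <- beam_spec(c(4, 4), ssd = 100)
  spec <- energy_spectrum(c(2, 4), c(0.5, 0.5))
  st <- transport_settings(n_batches = 5)
  d1 <- simulate_reference_dose(ph, beam, spec, settings = st,
                                n_histories = 2e4, seed = 5)
  acc <- d1$meta
  bal <- acc$energy_in + acc$created - acc$deposited - acc$escaped -
    acc$mass_sunk
  expect_lt(abs(bal) / acc$energy_in, 1e-9)
  d2 <- simulate_reference_dose(ph, beam, spec, settings = st,
                                n_histories = 2e4, seed = 5)
  expect_identical(d1$values, d2$values)
})

test_that("batch uncertainties calibrate against independent repeats", {
  ph <- build_phantom("water", spacing = 1, size = c(8, 8, 8))
  beam <- beam_spec(c(4, 4), ssd = 100)
  spec <- energy_spectrum(4, 1)
  st <- transport_settings(n_batches = 10)
  ci <- c(5, 5) # near-axis voxel column
  doses <- matrix(0, 30, 3)
  sig <- matrix(0, 30, 3)
  depths <- c(2, 4, 6)
  for (r in 1:30) {
    d <- simulate_reference_dose(ph, beam, spec, settings = st,
                                 n_histories = 1e4, seed = 1000 + r)
    doses[r, ] <- d$values[ci[1], ci[2], depths]
    sig[r, ] <- d$uncertainty[ci[1], ci[2], depths] *
      d$values[ci[1], ci[2], depths]
  }
  for (j in 1:3) {
    ratio <- stats::sd(doses[, j]) / mean(sig[, j])
    expect_gt(ratio, 1 / 1.3)
    expect_lt(ratio, 1.3)
  }
})
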
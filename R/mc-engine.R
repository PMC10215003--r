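# R-facing surface of the Monte Carlo engine: kernel generation with a forced
# interaction at the origin of a water sphere, reference dose grids in voxel
# phantoms, and the low-level physics entry points used by the validation
# suite.

#' Static magnetic field specification
#'
#' @param strength field strength in tesla (default 1.5).
#' @param direction unit 3-vector; the default +x is transverse to the +z
#'   beam axis, the MR-linac geometry.
#' @return An object of class `magnetic_field`.
#' @export
magnetic_field <- function(strength = 1.5, direction = c(1, 0, 0)) {
  if (strength < 0) stop("field strength must be non-negative")
  n <- sqrt(sum(direction^2))
  if (abs(n - 1) > 1e-9) stop("field direction must be a unit vector")
  structure(list(strength = strength, direction = direction / n),
            class = "magnetic_field")
}

#' Transport settings for the Monte Carlo engine
#'
#' Defaults follow the kernel-generation configuration: photon cutoff
#' 0.01 MeV, electron total-energy cutoff 0.521 MeV, 2% fractional
#' energy-loss/step cap and 10 batches. The electron step is the minimum of
#' `max_step`, 2% of the residual CSDA range and a tenth of the gyroradius;
#' `fine_steps = TRUE` restores the historical EGS-style 0.001 cm step cap
#' instead of the desk-scale 0.1 cm default.
#'
#' @param photon_cutoff photon transport cutoff, MeV.
#' @param electron_cutoff_total electron total-energy cutoff, MeV.
#' @param max_step electron step-length cap, cm.
#' @param min_step optional step floor, cm.
#' @param efrac fractional energy loss (as residual-range fraction) per step.
#' @param multiple_scattering toggle Gaussian (Highland) multiple scattering.
#' @param pair_production toggle pair production above 1.022 MeV.
#' @param pe_local photons below this energy are absorbed on the spot, MeV.
#' @param n_batches batch count for uncertainty estimation.
#' @param fine_steps use the 0.001 cm step cap.
#' @return A list of class `transport_settings`.
#' @export
transport_settings <- function(photon_cutoff = 0.01,
                               electron_cutoff_total = 0.521,
                               max_step = 0.1, min_step = 0.005, efrac = 0.02,
                               multiple_scattering = TRUE,
                               pair_production = TRUE, pe_local = 0.05,
                               n_batches = 10, fine_steps = FALSE) {
  if (photon_cutoff <= 0 || electron_cutoff_total <= 0.511)
    stop("cutoffs must be positive (electron cutoff above the rest energy)")
  if (max_step <= 0) stop("step cap must be positive")
  if (fine_steps) max_step <- 0.001
  structure(list(photon_cutoff = photon_cutoff,
                 electron_cutoff_total = electron_cutoff_total,
                 max_step = max_step, min_step = min_step, efrac = efrac,
                 multiple_scattering = multiple_scattering,
                 pair_production = pair_production, pe_local = pe_local,
                 n_batches = as.integer(n_batches)),
            class = "transport_settings")
}

#' Sample Compton scattering events
#'
#' Klein-Nishina sampling on free electrons at rest; scattered photon and
#' recoil electron are kinematically consistent and energy is conserved
#' exactly per event.
#'
#' @param energy incident photon energy, MeV.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return Data frame with `scattered_energy`, `cos_theta_photon`,
#'   `electron_energy`, `cos_theta_electron`.
#' @export
sample_compton <- function(energy, n = 1, seed = 1) {
  if (energy <= 0) stop("photon energy must be positive")
  m <- cpp_sample_compton(energy, as.integer(n), seed)
  data.frame(scattered_energy = m[, 1], cos_theta_photon = m[, 2],
             electron_energy = m[, 3], cos_theta_electron = m[, 4])
}

#' Transport a single electron and record its track
#'
#' Validation entry point: condensed-history stepping with a fixed step
#' length, optionally without energy loss or multiple scattering, so the
#' track can be compared against the analytic gyration helix and the CSDA
#' range.
#'
#' @param energy kinetic energy, MeV.
#' @param position,direction starting state (cm, unit vector).
#' @param field a [magnetic_field()].
#' @param density uniform medium density, g/cm^3 (0 for vacuum).
#' @param step step length, cm.
#' @param use_stopping,use_ms physics toggles.
#' @param charge -1 for electrons, +1 for positrons.
#' @param max_steps safety bound on recorded steps.
#' @param seed RNG seed (multiple scattering only).
#' @return List with the recorded `positions` matrix, the total `path_length`
#'   and `deposited` energy.
#' @export
electron_trajectory <- function(energy, position = c(0, 0, 0),
                                direction = c(0, 0, 1),
                                field = magnetic_field(), density = 1,
                                step = 0.001, use_stopping = TRUE,
                                use_ms = FALSE, charge = -1L,
                                max_steps = 100000L, seed = 1) {
  tb <- cccmr_tables()
  cpp_electron_trajectory(energy, position, direction, as.integer(charge),
                          field$strength, field$direction, density, step,
                          use_stopping, use_ms, 0.521 - 0.51099895,
                          as.integer(max_steps), seed, tb$energy, tb$sp,
                          tb$range)
}

settings_list <- function(settings) {
  unclass(settings)
}

#' Generate an energy deposition kernel by Monte Carlo
#'
#' Each history forces one primary photon interaction at the origin of a
#' homogeneous water sphere (incident direction +z) and transports all
#' secondaries; deposits are scored on the spherical grid in radiological
#' units. The sphere's geometric radius scales as 1/density so that radius
#' times density is identical for every simulation. Deposits by primary
#' charged particles are tagged separately together with their
#' energy-weighted effective bin positions, which [characterize_kernel()]
#' consumes.
#'
#' @param energy primary photon energy, MeV (1-7).
#' @param density sphere mass density, g/cm^3.
#' @param field a [magnetic_field()].
#' @param settings a [transport_settings()].
#' @param n_histories number of forced interactions.
#' @param seed RNG seed; histories use counter-based streams, so results are
#'   independent of any work partitioning.
#' @param radial_bounds shell boundaries (default [edk_radial_bounds()]).
#' @param n_polar,n_azimuth angular bin counts.
#' @return An `edk`.
#' @export
generate_edk <- function(energy, density, field = magnetic_field(),
                         settings = transport_settings(), n_histories = 1e5,
                         seed = 1, radial_bounds = edk_radial_bounds(),
                         n_polar = 30, n_azimuth = 60) {
  if (energy < 1 || energy > 7) stop("kernel energies span 1-7 MeV")
  if (density <= 0) stop("density must be positive")
  if (n_histories < settings$n_batches)
    stop("n_histories must be at least the number of batches")
  tb <- cccmr_tables()
  res <- cpp_generate_edk(energy, density, field$strength, field$direction,
                          radial_bounds, as.integer(n_polar),
                          as.integer(n_azimuth), n_histories,
                          settings_list(settings), seed, tb$energy, tb$mu,
                          tb$sp, tb$range)
  dm <- c(length(radial_bounds) - 1, n_polar, n_azimuth)
  frac <- array(res$energy_sum / (n_histories * energy), dim = dm)
  new_edk(frac, radial_bounds, energy, density, field = field,
          uncertainty = array(res$rse, dim = dm),
          primary = array(res$primary_sum, dim = dm),
          eff_r = array(res$eff_r_sum, dim = dm),
          eff_cos = array(res$eff_cos_sum, dim = dm),
          n_histories = n_histories, n_batches = settings$n_batches,
          rng_seed = seed,
          accounting = list(deposited = res$deposited, escaped = res$escaped,
                            created = res$created, mass_sunk = res$mass_sunk,
                            energy_in = n_histories * energy))
}

#' Generate a full (energy x density) kernel set
#'
#' @param energies,densities grid axes (defaults: 1-7 MeV, 0.25-2.0 g/cm^3).
#' @param field,settings,n_histories see [generate_edk()]; `n_histories` is
#'   per kernel.
#' @param seed base seed; kernel (i) uses `seed * 1000 + i`.
#' @param radial_bounds,n_polar,n_azimuth scoring grid.
#' @param verbose print progress.
#' @return An `edk_set`.
#' @export
generate_kernel_set <- function(energies = 1:7,
                                densities = seq(0.25, 2, by = 0.25),
                                field = magnetic_field(),
                                settings = transport_settings(),
                                n_histories = 1e5, seed = 1,
                                radial_bounds = edk_radial_bounds(),
                                n_polar = 30, n_azimuth = 60,
                                verbose = FALSE) {
  kernels <- list()
  i <- 0
  for (E in energies) {
    for (rho in densities) {
      i <- i + 1
      if (verbose)
        message(sprintf("kernel %d/%d: E = %g MeV, rho = %g",
                        i, length(energies) * length(densities), E, rho))
      kernels[[i]] <- generate_edk(E, rho, field, settings, n_histories,
                                   seed * 1000 + i, radial_bounds, n_polar,
                                   n_azimuth)
    }
  }
  kernel_set(kernels, energies = energies, densities = densities)
}

#' Monte Carlo reference dose in a voxel phantom
#'
#' Photons are sampled from the spectrum and a divergent point source
#' collimated to the field rectangle at the phantom surface, transported by
#' Woodcock tracking through the density grid, and their secondaries
#' deposited with the same electron physics used for kernel generation.
#' Dose to water is energy per voxel water mass at the local density.
#'
#' @param phantom a `density_grid`.
#' @param beam a [beam_spec()].
#' @param spectrum an [energy_spectrum()].
#' @param field a [magnetic_field()].
#' @param settings a [transport_settings()].
#' @param n_histories photon histories.
#' @param seed RNG seed.
#' @return A `dose_grid` with per-voxel relative uncertainty and an energy
#'   accounting in `$meta`.
#' @export
simulate_reference_dose <- function(phantom, beam, spectrum,
                                    field = magnetic_field(),
                                    settings = transport_settings(),
                                    n_histories = 1e6, seed = 1) {
  stopifnot(inherits(phantom, "density_grid"), inherits(beam, "beam_spec"),
            inherits(spectrum, "energy_spectrum"))
  if (any(beam$field_size <= 0)) stop("zero-area field")
  if (abs(sum(spectrum$weights) - 1) > 1e-9)
    stop("spectrum weights must sum to 1")
  tb <- cccmr_tables()
  d <- dim(phantom$rho)
  res <- cpp_simulate_dose(as.numeric(phantom$rho), as.integer(d),
                           phantom$spacing, phantom$origin, beam$source,
                           beam$field_size[1] / 2, beam$field_size[2] / 2,
                           spectrum$energies, spectrum$weights,
                           field$strength, field$direction, n_histories,
                           settings_list(settings), seed, tb$energy, tb$mu,
                           tb$sp, tb$range)
  vol <- prod(phantom$spacing)
  dose <- array(res$energy_sum, dim = d) / (phantom$rho * vol * n_histories)
  dose_grid(dose, phantom, uncertainty = array(res$rse, dim = d),
            meta = list(engine = "mc", seed = seed, n_histories = n_histories,
                        energy_in = res$energy_in, deposited = res$deposited,
                        escaped = res$escaped, created = res$created,
                        mass_sunk = res$mass_sunk))
}

#' Monte Carlo dose from a forced point interaction
#'
#' Forces `n_histories` primary interactions of a monoenergetic photon
#' (traveling +z) at a fixed position inside a phantom and scores the
#' resulting dose. This isolates the point-spread transport that the
#' collapsed-cone superposition approximates, and is used to probe the
#' density-scaling inhomogeneity correction around low-density slabs.
#'
#' @param phantom a `density_grid`.
#' @param position interaction point, cm.
#' @param energy photon energy, MeV.
#' @inheritParams simulate_reference_dose
#' @return A `dose_grid`.
#' @export
simulate_point_interaction <- function(phantom, position = c(0, 0, 0),
                                       energy = 4, field = magnetic_field(),
                                       settings = transport_settings(),
                                       n_histories = 1e5, seed = 1) {
  stopifnot(inherits(phantom, "density_grid"))
  tb <- cccmr_tables()
  d <- dim(phantom$rho)
  res <- cpp_simulate_point_interaction(as.numeric(phantom$rho),
                                        as.integer(d), phantom$spacing,
                                        phantom$origin, position, energy,
                                        field$strength, field$direction,
                                        n_histories, settings_list(settings),
                                        seed, tb$energy, tb$mu, tb$sp,
                                        tb$range)
  vol <- prod(phantom$spacing)
  dose <- array(res$energy_sum, dim = d) / (phantom$rho * vol * n_histories)
  dose_grid(dose, phantom, uncertainty = array(res$rse, dim = d),
            meta = list(engine = "mc_point", seed = seed,
                        n_histories = n_histories,
                        energy_in = n_histories * energy,
                        deposited = res$deposited, escaped = res$escaped,
                        created = res$created, mass_sunk = res$mass_sunk))
}
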
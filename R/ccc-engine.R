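# Collapsed-cone superposition: TERMA-driven energy transport along discrete
# cone directions with density scaling and average-density kernel selection.

#' Settings for the collapsed-cone superposition
#'
#' @param terma_threshold source voxels with TERMA below this fraction of the
#'   maximum are skipped (accuracy/speed knob).
#' @return A list of class `ccc_settings`.
#' @export
ccc_settings <- function(terma_threshold = 1e-6) {
  structure(list(terma_threshold = terma_threshold), class = "ccc_settings")
}

#' Trace one cone ray through a phantom
#'
#' Exact voxel traversal from a voxel center to the grid boundary, with
#' per-segment cumulative geometric length `L`, cumulative radiological
#' length `p` and running average density `rho_bar = p / L` evaluated at the
#' segment exit.
#'
#' @param phantom a `density_grid`.
#' @param origin_voxel 1-based voxel index `c(i, j, k)`.
#' @param direction ray direction (normalized internally).
#' @return Data frame with columns `voxel` (linear 1-based index), `length`,
#'   `L`, `p`, `rho_bar`.
#' @export
trace_cone_ray <- function(phantom, origin_voxel, direction) {
  stopifnot(inherits(phantom, "density_grid"), length(origin_voxel) == 3)
  d <- dim(phantom$rho)
  if (any(origin_voxel < 1) || any(origin_voxel > d))
    stop("origin voxel outside the grid")
  start <- phantom$origin + (origin_voxel - 0.5) * phantom$spacing
  m <- cpp_trace_cone_ray(as.numeric(phantom$rho), as.integer(d),
                          phantom$spacing, phantom$origin, start, direction)
  as.data.frame(m)
}

#' Precompute the cone transport table of a kernel set
#'
#' Collapses every kernel of the set onto its cone directions and stores the
#' cumulative radial energy fraction per (density, direction, energy), the
#' form the superposition consumes.
#'
#' @param set an `edk_set` (densities must be evenly spaced for the linear
#'   density lookup).
#' @return An object of class `cone_table`.
#' @export
build_cone_table <- function(set) {
  stopifnot(inherits(set, "edk_set"))
  dens <- set$densities
  if (length(dens) > 2 && max(abs(diff(diff(dens)))) > 1e-9)
    stop("cone table requires an evenly spaced density grid")
  k1 <- set$kernels[[1]][[1]]
  np <- k1$n_polar; na <- k1$n_azimuth
  ndir <- np * na
  nb <- length(set$radial_bounds)
  ne <- length(set$energies)
  nrho <- length(dens)
  cum <- array(0, dim = c(nb, ne, ndir, nrho))
  for (di in seq_len(nrho)) {
    for (ei in seq_len(ne)) {
      ck <- collapse_to_cones(set$kernels[[ei]][[di]])
      # cumulative fraction at each radial bound, per direction
      cum[, ei, , di] <- rbind(0, apply(ck$values, 1, cumsum))
    }
  }
  structure(list(cum = cum, radial_bounds = set$radial_bounds,
                 densities = dens, energies = set$energies,
                 directions = cone_directions(np, na), field = set$field),
            class = "cone_table")
}

#' Collapsed-cone superposition of TERMA with density-indexed kernels
#'
#' Scatter (source-driven) superposition: every TERMA voxel releases
#' `T_E * rho * dV` along each cone direction; each voxel a cone ray
#' traverses receives the differential kernel energy fraction between its
#' entry and exit radiological radii, read from the kernel linearly
#' interpolated in density at the running average density between source and
#' segment exit, and the deposit is converted to dose-to-water at the local
#' density. The interaction voxel itself receives the innermost radial bins.
#'
#' @param terma a `terma_grid` from [compute_terma()].
#' @param kernels an `edk_set` or a prebuilt [build_cone_table()].
#' @param phantom the `density_grid` the TERMA was computed on.
#' @param settings a [ccc_settings()].
#' @param per_energy return the per-energy dose components instead of their
#'   sum (useful for spectrum fitting, since the superposition is linear in
#'   the spectral weights).
#' @return A `dose_grid`, or (with `per_energy = TRUE`) a list of one
#'   `dose_grid` per spectral energy.
#' @export
superpose <- function(terma, kernels, phantom, settings = ccc_settings(),
                      per_energy = FALSE) {
  stopifnot(inherits(terma, "terma_grid"), inherits(phantom, "density_grid"))
  tab <- if (inherits(kernels, "cone_table")) kernels
         else build_cone_table(kernels)
  d <- dim(phantom$rho)
  if (!identical(dim(terma$values)[1:3], d))
    stop("TERMA and phantom lattices do not match")
  if (length(terma$energies) != length(tab$energies) ||
      any(abs(terma$energies - tab$energies) > 1e-9))
    stop("TERMA energies do not match the kernel set")
  dose_e <- cpp_superpose(as.numeric(terma$values), as.numeric(phantom$rho),
                          as.integer(d), phantom$spacing, phantom$origin,
                          as.numeric(tab$cum), tab$radial_bounds,
                          tab$densities, tab$directions,
                          settings$terma_threshold)
  meta <- list(engine = "ccc", n_directions = nrow(tab$directions),
               terma_threshold = settings$terma_threshold)
  if (per_energy) {
    lapply(seq_along(tab$energies), function(e)
      dose_grid(array(dose_e[, e], dim = d), phantom, meta = meta))
  } else {
    dose_grid(array(rowSums(dose_e), dim = d), phantom, meta = meta)
  }
}

#' One-call collapsed-cone dose calculation
#'
#' Computes TERMA for the beam and spectrum, then superposes it with the
#' kernel set.
#'
#' @inheritParams superpose
#' @param beam a [beam_spec()].
#' @param spectrum an [energy_spectrum()] on the kernel energy grid.
#' @return A `dose_grid`.
#' @export
compute_ccc_dose <- function(phantom, beam, spectrum, kernels,
                             settings = ccc_settings()) {
  terma <- compute_terma(phantom, beam, spectrum)
  superpose(terma, kernels, phantom, settings)
}
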
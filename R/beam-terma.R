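# Beam and spectrum model, exact radiological path lengths, TERMA on the
# voxel lattice, and non-negative least-squares spectrum fitting.

#' Point-source beam specification
#'
#' @param field_size field side lengths (cm) defined at the phantom surface
#'   plane z = 0.
#' @param ssd source-to-surface distance, cm (default 143.5).
#' @param axis beam axis unit vector (+z).
#' @return An object of class `beam_spec` with the source placed at
#'   `-ssd * axis`.
#' @export
beam_spec <- function(field_size = c(10, 10), ssd = 143.5, axis = c(0, 0, 1)) {
  if (ssd <= 0) stop("SSD must be positive")
  field_size <- rep(as.numeric(field_size), length.out = 2)
  if (any(field_size <= 0)) stop("field side lengths must be positive")
  n <- sqrt(sum(axis^2))
  structure(list(field_size = field_size, ssd = ssd, axis = axis / n,
                 source = -ssd * axis / n),
            class = "beam_spec")
}

#' Photon fluence spectrum on an energy grid
#'
#' @param energies MeV grid.
#' @param weights fluence fractions; normalized to sum to 1 when
#'   `normalize = TRUE`, otherwise they must already do so.
#' @param normalize normalize the weights.
#' @return An object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(energies, weights, normalize = FALSE) {
  stopifnot(length(energies) == length(weights))
  if (any(weights < 0)) stop("spectrum weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("spectrum has zero total weight")
  if (normalize) weights <- weights / s
  else if (abs(s - 1) > 1e-12) stop("spectrum weights must sum to 1")
  structure(list(energies = as.numeric(energies),
                 weights = as.numeric(weights)),
            class = "energy_spectrum")
}

#' Reference fluence spectrum for the Monte Carlo engine
#'
#' A smooth flattening-filter-free-like bremsstrahlung shape,
#' `phi(E) = E * exp(-E / 0.9)`, tabulated on a fine grid (0.07-7.0 MeV at
#' 0.07 MeV intervals by default). This synthetic spectrum stands in for a
#' clinical accelerator model; the collapsed-cone engine never uses it
#' directly but fits its own coarse 1 MeV-grid spectrum to the resulting
#' depth-dose curve.
#'
#' @param emin,emax,de grid specification, MeV.
#' @param scale exponential falloff constant, MeV.
#' @return An [energy_spectrum()].
#' @export
default_mc_spectrum <- function(emin = 0.07, emax = 7, de = 0.07, scale = 0.9) {
  E <- seq(emin, emax, by = de)
  energy_spectrum(E, E * exp(-E / scale), normalize = TRUE)
}

#' Read/write two-column spectrum text files
#'
#' Plain text with `#` comments: first column energy (MeV), second column
#' fluence weight.
#'
#' @param path file path.
#' @return [read_spectrum()] returns an `energy_spectrum`.
#' @export
read_spectrum <- function(path) {
  tb <- utils::read.table(path, comment.char = "#",
                          col.names = c("energy", "weight"))
  energy_spectrum(tb$energy, tb$weight, normalize = TRUE)
}

#' @rdname read_spectrum
#' @param spectrum an `energy_spectrum` to write.
#' @export
write_spectrum <- function(spectrum, path) {
  lines <- c("# cccmr spectrum: energy_MeV weight",
             sprintf("%.10g %.17g", spectrum$energies, spectrum$weights))
  writeLines(lines, path)
  invisible(path)
}

#' Radiological path length through a density grid
#'
#' Exact voxel-traversal line integral of density along straight segments
#' (half-open voxel convention); segments outside the grid contribute zero.
#'
#' @param grid a `density_grid`.
#' @param p0,p1 segment endpoints (length-3 vectors, or n x 3 matrices for
#'   vectorized evaluation), cm.
#' @return Path lengths in g/cm^2.
#' @export
radiological_path <- function(grid, p0, p1) {
  stopifnot(inherits(grid, "density_grid"))
  if (is.null(dim(p0))) p0 <- matrix(p0, nrow = 1)
  if (is.null(dim(p1))) p1 <- matrix(p1, nrow = 1)
  cpp_radiological_path(as.numeric(grid$rho), as.integer(dim(grid$rho)),
                        grid$spacing, grid$origin, p0, p1)
}

#' TERMA per voxel and spectral energy
#'
#' Total energy released per unit mass by primary photon interactions: for
#' each voxel center inside the divergent field cone,
#' `T_E = (mu/rho)(E) * E * Phi_E` with
#' `Phi_E = w_E * exp(-(mu/rho)(E) * p) * SSD^2 / R^2`, where `p` is the
#' radiological depth from the source and `R` the source distance. TERMA is
#' treated as constant within a voxel and is zero outside the collimated
#' cone.
#'
#' @param phantom a `density_grid`.
#' @param beam a [beam_spec()].
#' @param spectrum an [energy_spectrum()]; its grid must lie inside the
#'   attenuation table's range.
#' @param table attenuation table (default [water_attenuation_table()]).
#' @param n_sub per-axis sub-voxel sampling of the field-edge fluence
#'   coverage (1 = binary voxel-center collimation).
#' @return Object of class `terma_grid`: 4D array `[x, y, z, energy]` plus
#'   lattice and beam metadata.
#' @export
compute_terma <- function(phantom, beam, spectrum,
                          table = water_attenuation_table(), n_sub = 4) {
  stopifnot(inherits(phantom, "density_grid"), inherits(beam, "beam_spec"),
            inherits(spectrum, "energy_spectrum"))
  if (min(spectrum$energies) < min(table$energy) - 1e-9 ||
      max(spectrum$energies) > max(table$energy) + 1e-9)
    stop("spectrum energies fall outside the attenuation table")
  d <- dim(phantom$rho)
  arr <- cpp_compute_terma(as.numeric(phantom$rho), as.integer(d),
                           phantom$spacing, phantom$origin, beam$source,
                           beam$ssd, beam$field_size[1] / 2,
                           beam$field_size[2] / 2, spectrum$energies,
                           spectrum$weights, table$energy, table$mu_over_rho,
                           as.integer(n_sub))
  structure(list(values = array(arr, dim = c(d, length(spectrum$energies))),
                 energies = spectrum$energies, spacing = phantom$spacing,
                 origin = phantom$origin, beam = beam),
            class = "terma_grid")
}

#' Fit a coarse spectrum to a reference depth-dose curve
#'
#' Non-negative least squares: finds weights `w >= 0` minimizing
#' `|| mono_pdds %*% w - mc_pdd ||` over the selected depth range, then
#' renormalizes to a unit-sum fluence spectrum. By default the fit is
#' restricted to depths at or beyond the reference curve's maximum, where the
#' depth dose is insensitive to the spectral discretization of the buildup.
#'
#' @param mc_pdd reference depth-dose values (numeric vector).
#' @param mono_pdds matrix `[depth, energy]` of monoenergetic depth-dose
#'   curves on the same depth grid.
#' @param energies MeV grid matching the columns of `mono_pdds`.
#' @param depths optional depth coordinates (used for the default
#'   restriction).
#' @param restrict `"beyond_dmax"` (default), `"all"`, or a logical/integer
#'   index vector.
#' @return List with `spectrum` (an [energy_spectrum()]), raw `weights`,
#'   `residual` (RMS over the fitted range) and the `fitted` curve.
#' @export
fit_spectrum <- function(mc_pdd, mono_pdds, energies,
                         depths = seq_along(mc_pdd),
                         restrict = "beyond_dmax") {
  mono_pdds <- as.matrix(mono_pdds)
  stopifnot(length(mc_pdd) == nrow(mono_pdds),
            length(energies) == ncol(mono_pdds))
  if (all(mono_pdds == 0) || all(mc_pdd == 0))
    stop("cannot fit a spectrum to all-zero profiles")
  sel <- if (identical(restrict, "beyond_dmax")) {
    depths >= depths[which.max(mc_pdd)]
  } else if (identical(restrict, "all")) {
    rep(TRUE, length(mc_pdd))
  } else restrict
  A <- mono_pdds[sel, , drop = FALSE]
  b <- mc_pdd[sel]
  fit <- pracma::lsqnonneg(A, b)
  w <- fit$x
  if (sum(w) <= 0) stop("spectrum fit degenerated to zero weights")
  fitted <- as.numeric(mono_pdds %*% w)
  list(spectrum = energy_spectrum(energies, w, normalize = TRUE),
       weights = w,
       residual = sqrt(mean((A %*% w - b)^2)),
       fitted = fitted)
}
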
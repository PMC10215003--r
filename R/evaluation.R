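# Dose normalization, profile extraction, TG-53 region segmentation, 3D gamma
# analysis and passing-rate reporting.

#' Normalize a dose distribution to a water-phantom CAX maximum
#'
#' All distributions of one algorithm and field size are divided by the
#' maximum central-axis dose of that algorithm's water-phantom distribution.
#' Normalizing a water dose by itself puts its CAX maximum at exactly 1;
#' heterogeneous doses normalized by the water reference may exceed 1 in hot
#' spots (no clipping).
#'
#' @param dose a `dose_grid`.
#' @param water_reference the water-phantom `dose_grid` computed by the same
#'   algorithm and field size; defaults to `dose` itself.
#' @return A normalized `dose_grid`; the normalization point and value are
#'   recorded in `$normalization`.
#' @export
normalize_dose <- function(dose, water_reference = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  ref <- if (is.null(water_reference)) dose else water_reference
  ci <- cax_index(ref)
  cax <- ref$values[ci[1], ci[2], ]
  k <- which.max(cax)
  m <- cax[k]
  if (!isTRUE(m > 0)) stop("reference CAX maximum is zero")
  out <- dose
  out$values <- dose$values / m
  out$normalization <- list(value = m, depth_index = k,
                            depth_cm = axis_centers(dim(ref$values)[3],
                                                    ref$spacing[3],
                                                    ref$origin[3])[k],
                            self = is.null(water_reference))
  out
}

#' Extract the central-axis depth-dose profile
#'
#' Nearest-voxel-line sampling along the central axis.
#'
#' @param dose a `dose_grid`.
#' @return Data frame with `depth` (cm), `dose` and (if present)
#'   `uncertainty`.
#' @export
extract_pdd <- function(dose) {
  stopifnot(inherits(dose, "dose_grid"))
  ci <- cax_index(dose)
  d <- dim(dose$values)
  out <- data.frame(depth = axis_centers(d[3], dose$spacing[3], dose$origin[3]),
                    dose = dose$values[ci[1], ci[2], ])
  if (!is.null(dose$uncertainty))
    out$uncertainty <- dose$uncertainty[ci[1], ci[2], ]
  out
}

#' Extract an off-axis profile at fixed depth
#'
#' In-plane line through the central axis along the Lorentz-distortion axis
#' (y by default, the axis perpendicular to both the beam and the magnetic
#' field).
#'
#' @param dose a `dose_grid`.
#' @param depth depth in cm.
#' @param axis `"y"` (distortion axis) or `"x"` (field axis).
#' @return Data frame with `offset` (cm), `dose` and optional `uncertainty`.
#' @export
extract_oar <- function(dose, depth, axis = c("y", "x")) {
  stopifnot(inherits(dose, "dose_grid"))
  axis <- match.arg(axis)
  d <- dim(dose$values)
  zc <- axis_centers(d[3], dose$spacing[3], dose$origin[3])
  if (depth < zc[1] - dose$spacing[3] / 2 || depth > zc[d[3]] + dose$spacing[3] / 2)
    stop("depth outside the grid")
  k <- which.min(abs(zc - depth))
  ci <- cax_index(dose)
  if (axis == "y") {
    out <- data.frame(offset = axis_centers(d[2], dose$spacing[2], dose$origin[2]),
                      dose = dose$values[ci[1], , k])
    if (!is.null(dose$uncertainty)) out$uncertainty <- dose$uncertainty[ci[1], , k]
  } else {
    out <- data.frame(offset = axis_centers(d[1], dose$spacing[1], dose$origin[1]),
                      dose = dose$values[, ci[2], k])
    if (!is.null(dose$uncertainty)) out$uncertainty <- dose$uncertainty[, ci[2], k]
  }
  out
}

#' TG-53-style region segmentation
#'
#' Buildup: voxels shallower than the central-axis depth of maximum dose.
#' Penumbra: remaining voxels with dose between 20% and 80% of the CAX dose
#' at the same depth. Inner: remaining voxels at or above 80%. Voxels below
#' 20% belong to no region. The reference is the normalized Monte Carlo
#' water-or-phantom distribution.
#'
#' @param mc_dose a normalized Monte Carlo `dose_grid`.
#' @return Object of class `region_masks`: logical arrays `buildup`,
#'   `penumbra`, `inner` (pairwise disjoint) and `d_max_cm`.
#' @export
segment_regions <- function(mc_dose) {
  stopifnot(inherits(mc_dose, "dose_grid"))
  d <- dim(mc_dose$values)
  ci <- cax_index(mc_dose)
  cax <- mc_dose$values[ci[1], ci[2], ]
  k_max <- which.max(cax)
  if (!isTRUE(cax[k_max] > 0)) stop("no identifiable CAX maximum")
  depth_idx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  buildup <- depth_idx < k_max
  # per-depth CAX reference
  cax_ref <- array(rep(cax, each = d[1] * d[2]), dim = d)
  rel <- ifelse(cax_ref > 0, mc_dose$values / cax_ref, 0)
  penumbra <- !buildup & rel >= 0.2 & rel < 0.8
  inner <- !buildup & rel >= 0.8
  structure(list(buildup = buildup, penumbra = penumbra, inner = inner,
                 d_max_cm = axis_centers(d[3], mc_dose$spacing[3],
                                         mc_dose$origin[3])[k_max],
                 d_max_index = k_max),
            class = "region_masks")
}

#' Gamma evaluation criteria
#'
#' @param dose_diff dose-difference criterion as percent of the normalization
#'   dose (global normalization; default 3).
#' @param dta_mm distance-to-agreement criterion in mm (default 2).
#' @param search_mult search radius as a multiple of the DTA criterion.
#' @param cutoff reference voxels below this fraction of the normalization
#'   dose are excluded from evaluation (default 0.2; set 0 to evaluate the
#'   entire grid).
#' @param subdivide integer subdivision factor of the evaluated distribution
#'   within the search sphere (1 = native-resolution search, the default; >1
#'   enables trilinear sub-voxel interpolation).
#' @return A list of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_diff = 3, dta_mm = 2, search_mult = 2,
                           cutoff = 0.2, subdivide = 1) {
  if (dose_diff <= 0 || dta_mm <= 0) stop("gamma criteria must be positive")
  structure(list(dose_diff = dose_diff, dta_mm = dta_mm,
                 search_mult = search_mult, cutoff = cutoff,
                 subdivide = as.integer(subdivide)),
            class = "gamma_criteria")
}

#' 3D gamma index between two normalized dose distributions
#'
#' For every reference voxel above the low-dose cutoff, the gamma value is
#' the minimum over evaluated positions within the search sphere of
#' `sqrt(|dr|^2 / dta^2 + dD^2 / DD^2)`, with the dose difference taken
#' against the global normalization (both inputs must be normalized by
#' [normalize_dose()], so the 3% criterion is 0.03 of the normalization
#' dose). Gamma at or below 1 passes.
#'
#' @param reference the reference `dose_grid` (Monte Carlo), normalized.
#' @param evaluated the evaluated `dose_grid` (collapsed cone), normalized,
#'   on the same lattice.
#' @param criteria a [gamma_criteria()].
#' @return Object of class `gamma_result`: `gamma` array (NA below cutoff),
#'   logical `mask` of evaluated voxels, and the criteria.
#' @export
gamma_3d <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_grid"), inherits(evaluated, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  d <- dim(reference$values)
  if (!identical(d, dim(evaluated$values)))
    stop("reference and evaluated lattices do not match")
  if (max(abs(reference$spacing - evaluated$spacing)) > 1e-12)
    stop("reference and evaluated spacings do not match")
  g <- cpp_gamma3d(as.numeric(reference$values), as.numeric(evaluated$values),
                   as.integer(d), reference$spacing,
                   criteria$dose_diff / 100, criteria$dta_mm / 10,
                   criteria$search_mult, criteria$cutoff,
                   criteria$subdivide)
  g <- array(g, dim = d)
  structure(list(gamma = g, mask = !is.na(g), criteria = criteria),
            class = "gamma_result")
}

#' Gamma passing rate within a region
#'
#' @param gamma a [gamma_3d()] result.
#' @param mask logical array selecting the region; defaults to every
#'   evaluated voxel.
#' @return Percentage of voxels in the region (and above the evaluation
#'   cutoff) with gamma at or below 1.
#' @export
passing_rate <- function(gamma, mask = NULL) {
  stopifnot(inherits(gamma, "gamma_result"))
  sel <- gamma$mask
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(gamma$gamma)))
      stop("mask lattice does not match the gamma grid")
    sel <- sel & mask
  }
  n <- sum(sel)
  if (n == 0) stop("passing rate undefined: the region contains no evaluated voxels")
  100 * sum(gamma$gamma[sel] <= 1) / n
}

#' Per-region gamma passing-rate report
#'
#' @param gamma a [gamma_3d()] result.
#' @param regions a [segment_regions()] result.
#' @return List with the criteria and passing rates for the buildup,
#'   penumbra, inner and entire regions.
#' @export
gamma_report <- function(gamma, regions) {
  stopifnot(inherits(regions, "region_masks"))
  rate <- function(m) tryCatch(passing_rate(gamma, m), error = function(e) NA_real_)
  list(criteria = unclass(gamma$criteria),
       buildup = rate(regions$buildup),
       penumbra = rate(regions$penumbra),
       inner = rate(regions$inner),
       all = passing_rate(gamma))
}

#' Write a profile to CSV
#'
#' @param profile data frame from [extract_pdd()] or [extract_oar()].
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
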
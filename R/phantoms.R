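# Voxel phantoms and grid containers. Beam axis is +z (depth), the magnetic
# field points along +x, so the Lorentz distortion lives in the y-z plane.

#' Voxelized mass-density grid
#'
#' @param density 3D array of mass densities in g/cm^3, indexed `[x, y, z]`.
#' @param spacing voxel spacing in cm; scalar or length-3 vector.
#' @param origin position (cm) of the lower corner of voxel `[1, 1, 1]`.
#' @param labels optional integer array of material labels (same shape).
#' @param label_names optional character vector naming the label codes.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(density, spacing, origin = NULL, labels = NULL,
                         label_names = NULL) {
  stopifnot(length(dim(density)) == 3)
  if (any(!is.finite(density)) || any(density <= 0))
    stop("density must be positive and finite everywhere")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  d <- dim(density)
  if (is.null(origin))
    origin <- c(-d[1] * spacing[1] / 2, -d[2] * spacing[2] / 2, 0)
  structure(list(rho = density, spacing = spacing, origin = as.numeric(origin),
                 labels = labels, label_names = label_names),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$rho)
  cat(sprintf("<density_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g cm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  density range %.3g - %.3g g/cm^3\n", min(x$rho), max(x$rho)))
  invisible(x)
}

#' Dose distribution on a voxel lattice
#'
#' @param values 3D dose array on the same lattice as its phantom.
#' @param grid the `density_grid` the dose was computed on.
#' @param uncertainty optional 3D array of relative standard errors.
#' @param normalization optional list recording how the dose was normalized.
#' @param meta optional list of provenance (seed, histories, engine).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, grid, uncertainty = NULL, normalization = NULL,
                      meta = list()) {
  stopifnot(inherits(grid, "density_grid"))
  if (!identical(dim(values), dim(grid$rho)))
    stop("dose lattice does not match the phantom lattice")
  if (any(values < 0)) stop("dose must be non-negative")
  structure(list(values = values, spacing = grid$spacing, origin = grid$origin,
                 uncertainty = uncertainty, normalization = normalization,
                 meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, max %.4g%s\n", d[1], d[2], d[3],
              max(x$values),
              if (is.null(x$normalization)) " (unnormalized)" else " (normalized)"))
  invisible(x)
}

# voxel center coordinates along one axis
axis_centers <- function(n, spacing, origin) origin + (seq_len(n) - 0.5) * spacing

grid_centers <- function(g) {
  d <- dim(if (inherits(g, "density_grid")) g$rho else g$values)
  list(x = axis_centers(d[1], g$spacing[1], g$origin[1]),
       y = axis_centers(d[2], g$spacing[2], g$origin[2]),
       z = axis_centers(d[3], g$spacing[3], g$origin[3]))
}

# central-axis lateral indices (lattices are built with odd lateral counts)
cax_index <- function(g) {
  d <- dim(if (inherits(g, "density_grid")) g$rho else g$values)
  ctr <- grid_centers(g)
  c(which.min(abs(ctr$x)), which.min(abs(ctr$y)))
}

#' Build a validation phantom
#'
#' Constructs the voxelized geometries used throughout the validation stack.
#' All phantoms are water of varying mass density; the material labels are for
#' reporting only.
#'
#' * `water`: homogeneous water, density 1.
#' * `slab_lung`: water with a lung-density slab (default 0.33 g/cm^3 between
#'   5 and 15 cm depth).
#' * `tumor_slab`: water / bone (1.92) / lung (0.33) slabs with a unit-density
#'   2 cm diameter sphere centered on the beam axis at 9 cm depth.
#' * `kernel_validation_sphere`: a water cube centered on the origin with a
#'   1 cm slab of density 0.25 at 0.5-1.5 cm from the upstream face, used to
#'   probe the inhomogeneity correction around a forced point interaction.
#'
#' @param kind one of `"water"`, `"slab_lung"`, `"tumor_slab"`,
#'   `"kernel_validation_sphere"`.
#' @param spacing voxel size in cm (default 0.2).
#' @param size phantom extent `c(x, y, z)` in cm; lateral counts are forced
#'   odd so a voxel column lies exactly on the central axis.
#' @param lung_depths depth interval of the lung slab, cm.
#' @param lung_density,bone_density,slab_density densities in g/cm^3.
#' @param bone_thickness bone slab thickness (cm), placed immediately upstream
#'   of the lung slab.
#' @param tumor_center_depth,tumor_diameter tumor sphere geometry, cm.
#' @param half_width half extent of the kernel-validation cube, cm.
#' @return A `density_grid`.
#' @export
build_phantom <- function(kind = c("water", "slab_lung", "tumor_slab",
                                   "kernel_validation_sphere"),
                          spacing = 0.2, size = c(15.4, 15.4, 21.0),
                          lung_depths = c(5, 15), lung_density = 0.33,
                          bone_density = 1.92, bone_thickness = 2,
                          tumor_center_depth = 9, tumor_diameter = 2,
                          slab_density = 0.25, half_width = 3) {
  kind <- match.arg(kind)
  if (kind == "kernel_validation_sphere") {
    n <- max(3L, as.integer(ceiling(2 * half_width / spacing - 1e-9)))
    if (n %% 2 == 0) n <- n + 1L
    rho <- array(1, dim = c(n, n, n))
    org <- rep(-n * spacing / 2, 3)
    z <- axis_centers(n, spacing, org[3])
    slab <- z >= org[3] + 0.5 & z < org[3] + 1.5
    rho[, , slab] <- slab_density
    lab <- array(1L, dim = dim(rho)); lab[, , slab] <- 2L
    return(density_grid(rho, spacing, org, labels = lab,
                        label_names = c("water", "low_density_slab")))
  }
  nd <- function(len) as.integer(ceiling(len / spacing - 1e-9))
  nx <- nd(size[1]); ny <- nd(size[2]); nz <- nd(size[3])
  if (nx %% 2 == 0) nx <- nx + 1L
  if (ny %% 2 == 0) ny <- ny + 1L
  rho <- array(1, dim = c(nx, ny, nz))
  lab <- array(1L, dim = c(nx, ny, nz))
  org <- c(-nx * spacing / 2, -ny * spacing / 2, 0)
  if (kind == "water")
    return(density_grid(rho, spacing, org, labels = lab, label_names = "water"))
  z <- axis_centers(nz, spacing, org[3])
  lung <- z >= lung_depths[1] & z < lung_depths[2]
  if (!any(lung)) stop("lung slab lies outside the phantom")
  rho[, , lung] <- lung_density
  lab[, , lung] <- 2L
  if (kind == "slab_lung")
    return(density_grid(rho, spacing, org, labels = lab,
                        label_names = c("water", "lung")))
  bone <- z >= lung_depths[1] - bone_thickness & z < lung_depths[1]
  rho[, , bone] <- bone_density
  lab[, , bone] <- 3L
  r_t <- tumor_diameter / 2
  if (tumor_center_depth - r_t < lung_depths[1] ||
      tumor_center_depth + r_t > lung_depths[2])
    stop("tumor sphere is not fully inside the lung slab")
  ctr <- grid_centers(density_grid(rho, spacing, org))
  dist2 <- outer(outer(ctr$x^2, ctr$y^2, `+`), (ctr$z - tumor_center_depth)^2, `+`)
  tum <- dist2 <= r_t^2
  rho[tum] <- 1
  lab[tum] <- 4L
  density_grid(rho, spacing, org, labels = lab,
               label_names = c("water", "lung", "bone", "tumor"))
}

# ---------------------------------------------------------------------------
# Grid file format: <path>.json header + <path>.bin raw little-endian float64
# ---------------------------------------------------------------------------

grid_payload <- function(obj) {
  if (inherits(obj, "density_grid")) {
    arrays <- list(density = obj$rho)
    if (!is.null(obj$labels)) arrays$labels <- obj$labels + 0
    list(type = "density_grid", arrays = arrays,
         extra = list(label_names = obj$label_names))
  } else if (inherits(obj, "dose_grid")) {
    arrays <- list(dose = obj$values)
    if (!is.null(obj$uncertainty)) arrays$uncertainty <- obj$uncertainty
    list(type = "dose_grid", arrays = arrays,
         extra = list(normalization = obj$normalization, meta = obj$meta))
  } else stop("unsupported grid object")
}

#' Write a density or dose grid to disk
#'
#' Grids are stored as a JSON header (`<path>.json`) describing the lattice
#' plus a raw little-endian float64 payload (`<path>.bin`). The round trip is
#' lossless.
#'
#' @param obj a `density_grid` or `dose_grid`.
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
write_grid <- function(obj, path) {
  pl <- grid_payload(obj)
  dims <- dim(pl$arrays[[1]])
  header <- list(format = "cccmr-grid", version = 1L, type = pl$type,
                 dims = dims, spacing = obj$spacing, origin = obj$origin,
                 arrays = lapply(names(pl$arrays), function(nm)
                   list(name = nm, dtype = "float64",
                        n = length(pl$arrays[[nm]]))),
                 extra = pl$extra)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (a in pl$arrays) writeBin(as.numeric(a), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path file path without extension.
#' @return A `density_grid` or `dose_grid`.
#' @export
read_grid <- function(path) {
  hpath <- paste0(path, ".json"); bpath <- paste0(path, ".bin")
  if (!file.exists(hpath) || !file.exists(bpath))
    stop("grid files not found at ", path)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (is.null(h$format) || h$format != "cccmr-grid")
    stop("not a cccmr grid file")
  if (h$version != 1L) stop("unsupported grid file version: ", h$version)
  ntot <- sum(vapply(seq_len(nrow(h$arrays)), function(i) h$arrays$n[i], 0))
  con <- file(bpath, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = ntot + 1, size = 8, endian = "little")
  if (length(raw) != ntot) stop("truncated or oversized grid payload")
  arrays <- list()
  off <- 0
  for (i in seq_len(nrow(h$arrays))) {
    n <- h$arrays$n[i]
    arrays[[h$arrays$name[i]]] <- array(raw[(off + 1):(off + n)], dim = h$dims)
    off <- off + n
  }
  if (h$type == "density_grid") {
    labs <- if (!is.null(arrays$labels)) array(as.integer(arrays$labels), dim = h$dims)
    density_grid(arrays$density, h$spacing, h$origin, labels = labs,
                 label_names = h$extra$label_names)
  } else {
    g <- density_grid(array(1, dim = h$dims), h$spacing, h$origin)
    dg <- dose_grid(arrays$dose, g, uncertainty = arrays$uncertainty,
                    normalization = h$extra$normalization)
    dg$meta <- h$extra$meta
    dg
  }
}
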
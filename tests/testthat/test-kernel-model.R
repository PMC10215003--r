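# Kernel data model: scoring grids, density interpolation, cone collapsing,
# characterization statistics and the container round trip.

rb_small <- edk_radial_bounds(n_shells = 20, first_spacing = 0.05,
                              last_spacing = 1, total_radius = 6)

fixture_set <- function(densities = 1, energies = 4, ...) {
  make_fixture_kernels("exponential_isotropic", energies = energies,
                       densities = densities, radial_bounds = rb_small,
                       n_polar = 6, n_azimuth = 12, ...)
}

test_that("radial scoring grid honors its boundary constraints", {
  rb <- edk_radial_bounds()
  expect_length(rb, 66)
  expect_equal(rb[1], 0)
  sp <- diff(rb)
  expect_true(all(diff(rb) > 0))
  expect_equal(sp[1], 0.01, tolerance = 1e-10)
  expect_equal(sp[65], 5.0, tolerance = 1e-10)
  expect_equal(rb[66], 60, tolerance = 1e-10)
  expect_true(all(diff(sp) > 0)) # spacings grow monotonically outward
})

test_that("density interpolation is exact on grid points and linear between", {
  set <- make_fixture_kernels("skewed", densities = seq(0.25, 2, 0.25),
                              radial_bounds = rb_small, n_polar = 6,
                              n_azimuth = 12, fraction = 0.5)
  # give each density a distinguishable payload
  for (di in seq_along(set$densities))
    set$kernels[[1]][[di]]$values <- set$kernels[[1]][[di]]$values * di / 8
  k1 <- interpolate_kernel_by_density(set, 4, 1.0)
  expect_identical(k1$values, set$kernels[[1]][[4]]$values)

  mid <- interpolate_kernel_by_density(set, 4, 0.375)
  expect_equal(mid$values,
               (set$kernels[[1]][[1]]$values + set$kernels[[1]][[2]]$values) / 2,
               tolerance = 1e-14)

  # the 0.33 case mixes the 0.25 and 0.5 kernels with weights 0.68 / 0.32
  k033 <- interpolate_kernel_by_density(set, 4, 0.33)
  expect_equal(k033$values,
               0.68 * set$kernels[[1]][[1]]$values +
                 0.32 * set$kernels[[1]][[2]]$values,
               tolerance = 1e-12)
  expect_equal(k033$medium_density, 0.33)

  # linearity within one grid interval
  ka <- interpolate_kernel_by_density(set, 4, 0.8)
  kb <- interpolate_kernel_by_density(set, 4, 0.95)
  w <- 0.3
  kc <- interpolate_kernel_by_density(set, 4, w * 0.8 + (1 - w) * 0.95)
  expect_equal(kc$values, w * ka$values + (1 - w) * kb$values,
               tolerance = 1e-12)

  # clamping outside the grid
  expect_identical(interpolate_kernel_by_density(set, 4, 0.1)$values,
                   set$kernels[[1]][[1]]$values)
  expect_identical(interpolate_kernel_by_density(set, 4, 5)$values,
                   set$kernels[[1]][[8]]$values)
  expect_error(interpolate_kernel_by_density(set, 3.5, 1), "not on the kernel grid")
})

test_that("incomplete kernel sets are rejected by name", {
  set <- fixture_set(densities = c(0.5, 1))
  kernels <- list(set$kernels[[1]][[1]])
  expect_error(kernel_set(kernels, energies = 4, densities = c(0.5, 1)),
               "incomplete kernel set.*rho = 1")
})

test_that("cone collapsing is an energy-conserving re-binning", {
  delta <- make_fixture_kernels("delta", radial_bounds = rb_small,
                                n_polar = 6, n_azimuth = 12, r = 1,
                                theta = 0.3, phi = 1.1, fraction = 0.37)
  k <- delta$kernels[[1]][[1]]
  ck <- collapse_to_cones(k)
  expect_equal(sum(ck$values), sum(k$values), tolerance = 1e-14)
  expect_equal(sum(ck$values > 0), 1)
  expect_equal(max(ck$values), 0.37)

  # uniform kernel: every direction carries total / M
  ku <- k
  ku$values <- array(1 / length(k$values), dim = dim(k$values)) * 0.8
  cku <- collapse_to_cones(ku)
  expect_equal(rowSums(cku$values),
               rep(sum(ku$values) / nrow(cku$values), nrow(cku$values)),
               tolerance = 1e-14)

  # conservation on a structured kernel
  ks <- make_fixture_kernels("skewed", radial_bounds = rb_small,
                             n_polar = 6, n_azimuth = 12)
  expect_equal(sum(collapse_to_cones(ks$kernels[[1]][[1]])$values),
               sum(ks$kernels[[1]][[1]]$values) , tolerance = 1e-13)
  # cumulated per-direction tables are monotone non-decreasing
  cum <- apply(collapse_to_cones(ks$kernels[[1]][[1]])$values, 1, cumsum)
  expect_true(all(diff(cum) >= -1e-15))
})

test_that("characterization reproduces single- and two-point distributions", {
  d1 <- make_fixture_kernels("delta", r = 1, theta = 0)
  ch <- characterize_kernel(d1$kernels[[1]][[1]])
  expect_equal(ch$effective_depth, 1, tolerance = 1e-12)
  expect_equal(ch$effective_radial_distance, 1, tolerance = 1e-12)
  expect_equal(ch$effective_lateral_distance, 0, tolerance = 1e-6)

  d2 <- make_fixture_kernels("delta", r = 2, theta = pi / 2)
  ch2 <- characterize_kernel(d2$kernels[[1]][[1]])
  expect_equal(ch2$effective_depth, 0, tolerance = 1e-12)
  expect_equal(ch2$effective_radial_distance, 2, tolerance = 1e-12)
  expect_equal(ch2$effective_lateral_distance, 2, tolerance = 1e-12)

  # two voxels with equal energy at (r = 1, theta = 0) and (r = 3, theta = 0)
  k <- make_fixture_kernels("delta", radial_bounds = rb_small)$kernels[[1]][[1]]
  vals <- array(0, dim = dim(k$values))
  effr <- effc <- vals
  i1 <- findInterval(1, rb_small); i3 <- findInterval(3, rb_small)
  vals[i1, 1, 1] <- 0.2; vals[i3, 1, 1] <- 0.2
  effr[i1, 1, 1] <- 0.2 * 1; effr[i3, 1, 1] <- 0.2 * 3
  effc[i1, 1, 1] <- 0.2; effc[i3, 1, 1] <- 0.2
  k2 <- new_edk(vals, rb_small, 4, 1, primary = vals, eff_r = effr,
                eff_cos = effc)
  ch3 <- characterize_kernel(k2)
  expect_equal(ch3$effective_radial_distance, 2, tolerance = 1e-12)
  expect_equal(ch3$effective_depth, 2, tolerance = 1e-12)
  expect_equal(ch3$effective_lateral_distance, 0, tolerance = 1e-6)
  # matches the explicit-loop evaluation
  orc <- oracle_characterize(k2)
  expect_equal(ch3$effective_depth, orc$zbar, tolerance = 1e-14)
})

test_that("characterization matches the explicit loop on sparse random kernels", {
  set.seed(42)
  for (rep in 1:5) {
    k <- make_fixture_kernels("delta", radial_bounds = rb_small,
                              n_polar = 10, n_azimuth = 12)$kernels[[1]][[1]]
    vals <- array(0, dim = dim(k$values))
    effr <- effc <- vals
    nz <- sample(length(vals), 10)
    for (v in nz) {
      ai <- arrayInd(v, dim(vals))
      e <- stats::runif(1)
      rr <- stats::runif(1, rb_small[ai[1]], rb_small[ai[1] + 1])
      cc <- stats::runif(1, -1, 1)
      vals[v] <- e; effr[v] <- e * rr; effc[v] <- e * cc
    }
    vals <- vals / sum(vals) * 0.9
    effr <- effr / sum(effr) * 0.9 * mean(rb_small)
    kr <- new_edk(vals, rb_small, 4, 1, primary = vals, eff_r = effr,
                  eff_cos = effc)
    ch <- characterize_kernel(kr)
    orc <- oracle_characterize(kr)
    expect_equal(ch$effective_depth, orc$zbar, tolerance = 1e-12)
    expect_equal(ch$effective_radial_distance, orc$rbar, tolerance = 1e-12)
    expect_equal(ch$effective_lateral_distance, orc$ybar, tolerance = 1e-12)
  }
})

test_that("characterizing an empty kernel is an error", {
  k <- make_fixture_kernels("delta", radial_bounds = rb_small)$kernels[[1]][[1]]
  k$values[] <- 0; k$primary[] <- 0
  expect_error(characterize_kernel(k), "zero energy")
})

test_that("kernel container round-trips losslessly and validates", {
  set <- fixture_set(densities = c(0.5, 1), energies = c(2, 4))
  path <- file.path(tempdir(), "kc_test")
  write_kernel_container(set, path)
  back <- read_kernel_container(path)
  expect_identical(back$kernels[[1]][[1]]$values, set$kernels[[1]][[1]]$values)
  expect_identical(back$kernels[[2]][[2]]$eff_r, set$kernels[[2]][[2]]$eff_r)
  expect_identical(back$radial_bounds, set$radial_bounds)

  # missing kernel payload
  unlink(file.path(path, "E2_rho0.5.bin"))
  expect_error(read_kernel_container(path), "incomplete kernel set")

  # radial grid tampering
  write_kernel_container(set, path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  meta$radial_bounds <- meta$radial_bounds * 2
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  expect_error(read_kernel_container(path), "grid consistency")

  # version check
  write_kernel_container(set, path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  meta$version <- 99L
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  expect_error(read_kernel_container(path), "version")
  unlink(path, recursive = TRUE)
})
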
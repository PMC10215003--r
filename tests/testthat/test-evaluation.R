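# Evaluation stack: normalization, profiles, region segmentation, gamma.

synth_dose <- function(f, spacing = 0.4, size = c(6, 6, 10), unc = NULL) {
  ph <- build_phantom("water", spacing = spacing, size = size)
  d <- dim(ph$rho)
  xc <- ph$origin[1] + (seq_len(d[1]) - 0.5) * spacing
  yc <- ph$origin[2] + (seq_len(d[2]) - 0.5) * spacing
  zc <- ph$origin[3] + (seq_len(d[3]) - 0.5) * spacing
  vals <- array(0, dim = d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1]))
        vals[i, j, k] <- f(xc[i], yc[j], zc[k])
  dose_grid(vals, ph, uncertainty = unc)
}

test_that("normalization fixes the CAX maximum and is scale invariant", {
  dd <- synth_dose(function(x, y, z) exp(-((x^2 + y^2) / 2)) *
                     (z + 0.5) * exp(-z / 4))
  n1 <- normalize_dose(dd)
  ci <- cccmr:::cax_index(n1)
  expect_equal(max(n1$values[ci[1], ci[2], ]), 1.0, tolerance = 1e-14)

  d2 <- dd; d2$values <- dd$values * 2
  n2 <- normalize_dose(d2)
  expect_equal(n2$values, n1$values, tolerance = 1e-14)

  # heterogeneous dose against a water reference: hot spots may exceed 1
  hot <- dd; hot$values <- dd$values * 1.5
  nh <- normalize_dose(hot, dd)
  expect_gt(max(nh$values), 1)

  zero <- dd; zero$values[] <- 0
  expect_error(normalize_dose(zero), "zero")
})

test_that("profiles sample the lattice exactly", {
  f <- function(x, y, z) 1 + 0.1 * z
  dd <- synth_dose(f)
  pdd <- extract_pdd(dd)
  expect_equal(pdd$dose, 1 + 0.1 * pdd$depth, tolerance = 1e-14)

  flat <- synth_dose(function(x, y, z) 0.7)
  expect_true(all(extract_pdd(flat)$dose == 0.7))
  expect_true(all(extract_oar(flat, 2)$dose == 0.7))
  expect_error(extract_oar(flat, 50), "outside")
})

test_that("region segmentation matches the analytic classification", {
  # separable dose: g(depth) * top-hat(lateral)
  g <- function(z) ifelse(z < 2, 0.5 + 0.25 * z, 1 - 0.02 * (z - 2))
  h <- function(x, y) ifelse(max(abs(x), abs(y)) < 1, 1,
                             ifelse(max(abs(x), abs(y)) < 1.6, 0.5, 0.1))
  dd <- synth_dose(function(x, y, z) g(z) * h(x, y))
  nn <- normalize_dose(dd)
  rg <- segment_regions(nn)
  d <- dim(nn$values)
  xc <- nn$origin[1] + (seq_len(d[1]) - 0.5) * nn$spacing[1]
  zc <- nn$origin[3] + (seq_len(d[3]) - 0.5) * nn$spacing[3]
  k_max <- which.max(g(zc))
  for (probe in list(c(8, 8, 2), c(8, 8, 9), c(2, 8, 9), c(5, 8, 9))) {
    i <- probe[1]; j <- probe[2]; k <- probe[3]
    hv <- h(xc[i], xc[j])
    if (k < k_max) {
      expect_true(rg$buildup[i, j, k])
    } else if (hv >= 0.8) {
      expect_true(rg$inner[i, j, k])
    } else if (hv >= 0.2) {
      expect_true(rg$penumbra[i, j, k])
    } else {
      expect_false(rg$buildup[i, j, k] || rg$penumbra[i, j, k] ||
                   rg$inner[i, j, k])
    }
  }
  # all-uniform dose: no buildup, everything inner
  flat <- normalize_dose(synth_dose(function(x, y, z) 1))
  rgf <- segment_regions(flat)
  expect_equal(sum(rgf$buildup), 0)
  expect_true(all(rgf$inner))
})

test_that("region masks are disjoint and exclude sub-20% voxels", {
  set.seed(31)
  for (rep in 1:3) {
    dd <- synth_dose(function(x, y, z)
      stats::runif(1, 0.05, 1) * exp(-abs(x * y) / 4) * (1 + 0.05 * z))
    nn <- normalize_dose(dd)
    rg <- segment_regions(nn)
    overlap <- (rg$buildup & rg$penumbra) | (rg$buildup & rg$inner) |
      (rg$penumbra & rg$inner)
    expect_equal(sum(overlap), 0)
    # brute-force reclassification
    d <- dim(nn$values)
    ci <- cccmr:::cax_index(nn)
    cax <- nn$values[ci[1], ci[2], ]
    kmax <- which.max(cax)
    for (v in sample(length(nn$values), 50)) {
      ai <- arrayInd(v, d)
      rel <- nn$values[v] / cax[ai[3]]
      inb <- ai[3] < kmax
      expect_equal(rg$buildup[v], inb)
      if (!inb) {
        expect_equal(rg$penumbra[v], rel >= 0.2 && rel < 0.8)
        expect_equal(rg$inner[v], rel >= 0.8)
      }
    }
  }
})

test_that("gamma is zero for identical inputs and bounded for pure offsets", {
  dd <- normalize_dose(synth_dose(function(x, y, z)
    exp(-(x^2 + y^2) / 4) * exp(-z / 8)))
  g0 <- gamma_3d(dd, dd)
  expect_true(all(g0$gamma[g0$mask] == 0))
  expect_equal(passing_rate(g0), 100)

  # uniform +3% (of normalization) offset: gamma <= 1 everywhere
  up <- dd; up$values <- dd$values + 0.03
  g1 <- gamma_3d(dd, up)
  expect_true(all(g1$gamma[g1$mask] <= 1 + 1e-12))
})

test_that("gamma equals the brute-force minimization", {
  set.seed(41)
  ph <- build_phantom("water", spacing = 0.2, size = c(2, 2, 3))
  d <- dim(ph$rho)
  ref <- array(stats::runif(prod(d), 0, 1), dim = d)
  ev <- ref * (1 + stats::rnorm(prod(d), 0, 0.05))
  dr <- dose_grid(ref, ph); de <- dose_grid(abs(ev), ph)
  crit <- gamma_criteria(3, 2, search_mult = 2, cutoff = 0.2)
  got <- gamma_3d(dr, de, crit)$gamma
  want <- oracle_gamma(ref, abs(ev), ph$spacing, 0.03, 0.2, 2, 0.2)
  expect_equal(got, want, tolerance = 1e-14)

  # 1D toy profile pair (21 points)
  g1 <- density_grid(array(1, dim = c(21, 1, 1)), 0.2)
  r1 <- array(seq(0.2, 1, length.out = 21), dim = c(21, 1, 1))
  e1 <- array(r1 * (1 + c(rep(0.04, 10), rep(-0.04, 11))), dim = dim(r1))
  gg <- gamma_3d(dose_grid(r1, g1), dose_grid(e1, g1), crit)$gamma
  ww <- oracle_gamma(r1, e1, c(0.2, 0.2, 0.2), 0.03, 0.2, 2, 0.2)
  expect_equal(gg, ww, tolerance = 1e-14)
})

test_that("loosening the criteria never fails a passing voxel", {
  set.seed(51)
  ph <- build_phantom("water", spacing = 0.4, size = c(3, 3, 4))
  d <- dim(ph$rho)
  ref <- array(stats::runif(prod(d), 0.1, 1), dim = d)
  ev <- ref * (1 + stats::rnorm(prod(d), 0, 0.06))
  dr <- dose_grid(ref, ph); de <- dose_grid(abs(ev), ph)
  tight <- gamma_3d(dr, de, gamma_criteria(2, 1))
  loose_d <- gamma_3d(dr, de, gamma_criteria(4, 1))
  loose_a <- gamma_3d(dr, de, gamma_criteria(2, 3))
  pass <- function(g) g$gamma[g$mask] <= 1
  expect_true(all(pass(loose_d) | !pass(tight)))
  expect_true(all(pass(loose_a) | !pass(tight)))
})

test_that("passing rates count voxels per region", {
  ph <- build_phantom("water", spacing = 0.4, size = c(2, 2, 2))
  gam <- structure(list(gamma = array(0, dim = dim(ph$rho)),
                        mask = array(TRUE, dim = dim(ph$rho)),
                        criteria = gamma_criteria()),
                   class = "gamma_result")
  expect_equal(passing_rate(gam), 100)
  n <- length(gam$gamma)
  gam$gamma[seq_len(n %/% 2)] <- 2
  expect_equal(passing_rate(gam), 100 * (n - n %/% 2) / n)

  # manual count on a 5x5x5 fixture with a region mask
  set.seed(61)
  g5 <- array(stats::runif(125, 0, 2), dim = c(5, 5, 5))
  m5 <- array(stats::runif(125) < 0.5, dim = c(5, 5, 5))
  gam5 <- structure(list(gamma = g5, mask = array(TRUE, dim = dim(g5)),
                         criteria = gamma_criteria()),
                    class = "gamma_result")
  expect_equal(passing_rate(gam5, m5),
               100 * sum(g5[m5] <= 1) / sum(m5))
  expect_error(passing_rate(gam5, array(FALSE, dim = dim(g5))), "undefined")
})
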
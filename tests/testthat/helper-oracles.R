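# Independent oracle implementations used across the suite. These deliberately
# avoid the package's C++ paths: plain R, different algorithms where possible.

# Exact line integral of rho along a segment by plane-crossing decomposition:
# collect the parametric positions of every voxel-plane crossing, then sample
# the (piecewise constant) density at sub-segment midpoints.
oracle_radiological_path <- function(grid, p0, p1) {
  d <- dim(grid$rho)
  sp <- grid$spacing
  org <- grid$origin
  dvec <- p1 - p0
  len <- sqrt(sum(dvec^2))
  if (len == 0) return(0)
  u <- dvec / len
  ts <- c(0, len)
  for (a in 1:3) {
    if (abs(u[a]) > 1e-14) {
      planes <- org[a] + (0:d[a]) * sp[a]
      tt <- (planes - p0[a]) / u[a]
      ts <- c(ts, tt[tt > 0 & tt < len])
    }
  }
  ts <- sort(unique(ts))
  mids <- (ts[-1] + ts[-length(ts)]) / 2
  dl <- diff(ts)
  rho_at <- vapply(mids, function(t) {
    p <- p0 + t * u
    ijk <- floor((p - org) / sp) + 1
    if (any(ijk < 1) || any(ijk > d)) return(0)
    grid$rho[ijk[1], ijk[2], ijk[3]]
  }, 0)
  sum(rho_at * dl)
}

# Segment table along a ray from `start`, built on the same plane-crossing
# decomposition (for the superposition oracle).
oracle_ray_segments <- function(grid, start, dir) {
  d <- dim(grid$rho)
  sp <- grid$spacing
  org <- grid$origin
  u <- dir / sqrt(sum(dir^2))
  hi <- org + d * sp
  tmax <- Inf
  for (a in 1:3) {
    if (abs(u[a]) > 1e-14) {
      t1 <- (org[a] - start[a]) / u[a]
      t2 <- (hi[a] - start[a]) / u[a]
      tmax <- min(tmax, max(t1, t2))
    }
  }
  ts <- c(0)
  for (a in 1:3) {
    if (abs(u[a]) > 1e-14) {
      planes <- org[a] + (0:d[a]) * sp[a]
      tt <- (planes - start[a]) / u[a]
      ts <- c(ts, tt[tt > 1e-12 & tt < tmax - 1e-12])
    }
  }
  ts <- sort(unique(c(ts, tmax)))
  mids <- (ts[-1] + ts[-length(ts)]) / 2
  segs <- NULL
  for (i in seq_along(mids)) {
    p <- start + mids[i] * u
    ijk <- floor((p - org) / sp) + 1
    if (any(ijk < 1) || any(ijk > d)) next
    segs <- rbind(segs, c(ijk, ts[i], ts[i + 1]))
  }
  segs # columns: i, j, k, t_in, t_out
}

# Brute-force superposition: explicit loops over sources and the full cone
# direction set, with its own cumulative-kernel interpolation.
oracle_superpose <- function(terma, tab, phantom, thresh_rel = 1e-6) {
  d <- dim(phantom$rho)
  ne <- length(tab$energies)
  rb <- tab$radial_bounds
  dens <- tab$densities
  dose <- array(0, dim = d)
  tmax <- max(terma$values)
  cum_at <- function(curve, p) {
    if (p >= rb[length(rb)]) return(curve[length(rb)])
    j <- findInterval(p, rb)
    j <- max(1, min(j, length(rb) - 1))
    curve[j] + (p - rb[j]) / (rb[j + 1] - rb[j]) * (curve[j + 1] - curve[j])
  }
  for (s in which(apply(terma$values, 1:3, max) > thresh_rel * tmax)) {
    ijk <- arrayInd(s, d)
    start <- phantom$origin + (ijk - 0.5) * phantom$spacing
    rho_s <- phantom$rho[s]
    te <- vapply(seq_len(ne), function(e)
      terma$values[ijk[1], ijk[2], ijk[3], e], 0)
    for (m in seq_len(nrow(tab$directions))) {
      segs <- oracle_ray_segments(phantom, start, tab$directions[m, ])
      if (is.null(segs)) next
      p_in <- 0
      for (i in seq_len(nrow(segs))) {
        v <- segs[i, 1:3]
        rho_v <- phantom$rho[v[1], v[2], v[3]]
        p_out <- min(p_in + rho_v * (segs[i, 5] - segs[i, 4]),
                     rb[length(rb)])
        rho_bar <- p_out / segs[i, 5]
        kd <- 1
        wd <- 0
        if (length(dens) > 1) {
          x <- (rho_bar - dens[1]) / (dens[2] - dens[1])
          kd <- max(1, min(floor(x) + 1, length(dens) - 1))
          wd <- max(0, min(x - (kd - 1), 1))
        }
        for (e in seq_len(ne)) {
          if (te[e] <= 0) next
          clo <- tab$cum[, e, m, kd]
          f <- (1 - wd) * (cum_at(clo, p_out) - cum_at(clo, p_in))
          if (wd > 0) {
            chi <- tab$cum[, e, m, kd + 1]
            f <- f + wd * (cum_at(chi, p_out) - cum_at(chi, p_in))
          }
          dose[v[1], v[2], v[3]] <- dose[v[1], v[2], v[3]] +
            te[e] * rho_s * f / rho_v
        }
        if (p_out >= rb[length(rb)]) break
        p_in <- p_out
      }
    }
  }
  dose
}

# Brute-force gamma: explicit minimization of the combined criterion over all
# displacement offsets within the search radius (native resolution).
oracle_gamma <- function(ref, ev, spacing, dd, dta, search_mult, cutoff) {
  d <- dim(ref)
  radius <- search_mult * dta
  off <- expand.grid(
    a = -floor(radius / spacing[1]):floor(radius / spacing[1]),
    b = -floor(radius / spacing[2]):floor(radius / spacing[2]),
    c = -floor(radius / spacing[3]):floor(radius / spacing[3]))
  off$d2 <- (off$a * spacing[1])^2 + (off$b * spacing[2])^2 +
    (off$c * spacing[3])^2
  off <- off[off$d2 <= radius^2 + 1e-12, ]
  g <- array(NA_real_, dim = d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1])) {
        if (ref[i, j, k] < cutoff) next
        best <- Inf
        for (o in seq_len(nrow(off))) {
          ii <- i + off$a[o]; jj <- j + off$b[o]; kk <- k + off$c[o]
          if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
              kk > d[3]) next
          val <- off$d2[o] / dta^2 + (ev[ii, jj, kk] - ref[i, j, k])^2 / dd^2
          if (val < best) best <- val
        }
        g[i, j, k] <- sqrt(best)
      }
  g
}

# Explicit-loop evaluation of the kernel characterization statistics.
oracle_characterize <- function(kernel) {
  eps <- kernel$primary
  Fp <- 0; rbar <- 0; zbar <- 0
  d <- dim(eps)
  for (ir in seq_len(d[1]))
    for (ip in seq_len(d[2]))
      for (ia in seq_len(d[3])) {
        e <- eps[ir, ip, ia]
        if (e <= 0) next
        r_hat <- kernel$eff_r[ir, ip, ia] / e
        c_hat <- kernel$eff_cos[ir, ip, ia] / e
        Fp <- Fp + e
        rbar <- rbar + r_hat * e
        zbar <- zbar + r_hat * c_hat * e
      }
  rbar <- rbar / Fp
  zbar <- zbar / Fp
  list(zbar = zbar, rbar = rbar, ybar = sqrt(max(rbar^2 - zbar^2, 0)))
}

# Signed first moment of a kernel along +y in radiological units, from the
# angular bin centroids (Lorentz-drift asymmetry measure).
kernel_y_moment <- function(kernel) {
  d <- dim(kernel$values)
  rb <- kernel$radial_bounds
  rmid <- (rb[-1] + rb[-length(rb)]) / 2
  ang <- edk_angular_grid(d[2], d[3])
  sinb <- sin((ang$polar[-1] + ang$polar[-(d[2] + 1)]) / 2)
  sphib <- sin((ang$azimuth[-1] + ang$azimuth[-(d[3] + 1)]) / 2)
  y <- outer(rmid, outer(sinb, sphib))
  sum(kernel$values * y) / sum(kernel$values)
}

# small random phantom for property tests
random_phantom <- function(n, spacing = 0.5, seed = 1,
                           densities = c(0.25, 2)) {
  set.seed(seed)
  rho <- array(stats::runif(prod(n), densities[1], densities[2]), dim = n)
  density_grid(rho, spacing)
}
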
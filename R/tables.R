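# Embedded water photon/electron data (NIST-style tabulations, 0.01-7 MeV).
# Interpolation between tabulated points is log-log throughout.

#' Water photon attenuation and electron stopping-power table
#'
#' Mass attenuation coefficients of photons in water and collision stopping
#' powers of electrons in water on a common 0.01-7 MeV grid. These tables are
#' the single source of photon attenuation and electron energy loss for both
#' the Monte Carlo engine and the TERMA model, so the two dose routes share
#' identical primary physics. Values between grid points are interpolated
#' log-log.
#'
#' @return A data frame with columns `energy` (MeV), `mu_over_rho` (cm^2/g,
#'   total photon mass attenuation coefficient) and `stopping_power`
#'   (MeV cm^2/g, electron collision stopping power).
#' @export
water_attenuation_table <- function() {
  data.frame(
    energy = c(0.010, 0.015, 0.020, 0.030, 0.040, 0.050, 0.060, 0.080, 0.100,
               0.150, 0.200, 0.300, 0.400, 0.500, 0.600, 0.800, 1.000, 1.250,
               1.500, 2.000, 3.000, 4.000, 5.000, 6.000, 7.000),
    mu_over_rho = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059,
                    0.1837, 0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.09687,
                    0.08956, 0.07865, 0.07072, 0.06323, 0.05754, 0.04942,
                    0.03969, 0.03403, 0.03031, 0.02770, 0.02583),
    stopping_power = c(22.56, 16.47, 13.17, 9.653, 7.777, 6.603, 5.797, 4.757,
                       4.115, 3.238, 2.793, 2.355, 2.148, 2.034, 1.963, 1.886,
                       1.849, 1.829, 1.822, 1.824, 1.846, 1.870, 1.892, 1.911,
                       1.926)
  )
}

# log-log interpolation helper shared by R-side lookups
loglog_interp <- function(x, xt, yt) {
  lx <- log(pmin(pmax(x, xt[1]), xt[length(xt)]))
  exp(approx(log(xt), log(yt), xout = lx)$y)
}

#' Look up the water mass attenuation coefficient
#'
#' @param energy photon energies in MeV (0.01-7).
#' @return mu/rho in cm^2/g, log-log interpolated.
#' @export
mu_over_rho <- function(energy) {
  tb <- water_attenuation_table()
  loglog_interp(energy, tb$energy, tb$mu_over_rho)
}

#' Look up the water collision stopping power
#'
#' @param energy electron kinetic energies in MeV (0.01-7).
#' @return collision stopping power in MeV cm^2/g.
#' @export
collision_stopping_power <- function(energy) {
  tb <- water_attenuation_table()
  loglog_interp(energy, tb$energy, tb$stopping_power)
}

#' Continuous-slowing-down (CSDA) range in unit-density water
#'
#' Integral of the inverse collision stopping power from the 0.01 MeV transport
#' cutoff up to `energy`, plus the residual range at the cutoff. Used to bound
#' condensed-history step sizes and as the straight-track oracle when multiple
#' scattering is disabled.
#'
#' @param energy electron kinetic energies in MeV.
#' @return CSDA range in g/cm^2.
#' @export
csda_range <- function(energy) {
  rt <- cccmr_tables()
  exp(approx(log(rt$energy), log(rt$range), xout = log(pmin(pmax(energy, rt$energy[1]),
                                                            rt$energy[length(rt$energy)])))$y)
}

# Cached physics tables in the form the C++ engine consumes: a shared energy
# grid with mu/rho, stopping power and cumulative CSDA range.
cccmr_tables <- function() {
  tb <- .cccmr_env$tables
  if (!is.null(tb)) return(tb)
  E <- exp(seq(log(0.01), log(7), length.out = 400))
  S <- collision_stopping_power(E)
  # trapezoid of 1/S in energy; residual range at the 10 keV cutoff
  inv <- 1 / S
  dr <- c(0, cumsum(0.5 * (inv[-1] + inv[-length(inv)]) * diff(E)))
  tb <- list(energy = E,
             mu = mu_over_rho(E),
             sp = S,
             range = 2.515e-4 + dr)
  .cccmr_env$tables <- tb
  tb
}
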
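#' Dissolved inorganic carbon chemistry
#'
#' Equilibrium constants and pH-dependent speciation of the carbonate system
#' (CO2*(aq) <-> HCO3- <-> CO3^2-) as a function of temperature and
#' salinity.  The solubility K0 follows a Weiss-form polynomial in absolute
#' temperature with salinity terms; the freshwater dissociation constants K1
#' and K2 follow the classical Harned-Davis / Harned-Scholes polynomials
#' with Millero-style salinity increments.  The parameterization is stored
#' in a versioned YAML file (\code{extdata/carbonate_constants.yaml}) so an
#' alternative set of coefficients can be swapped in via \code{constants}.
#'
#' The pH is treated on the free hydrogen-ion scale and activity
#' coefficients are ignored: speciation fractions are concentration-based,
#' as in a textbook Bjerrum treatment.  The dissociation fits are stated up
#' to about 50 degrees C; hotter conditions (hot-spring range, up to 100)
#' are accepted but marked \code{extrapolated = TRUE} in the result.
#'
#' @name carbonate
NULL

.carbonate_cache <- new.env(parent = emptyenv())

#' Load the carbonate-system coefficient set
#'
#' @param path Optional path to an alternative YAML coefficient file with
#'   the same schema as the packaged version.
#' @return A named list of coefficients.
#' @export
carbonate_constants <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.carbonate_cache$default))
      .carbonate_cache$default <-
        yaml::read_yaml(.extdata("carbonate_constants.yaml"))
    return(.carbonate_cache$default)
  }
  yaml::read_yaml(path)
}

.check_conditions <- function(temperature_c, salinity, ph = NULL,
                              constants = carbonate_constants()) {
  if (!is.numeric(temperature_c) || anyNA(temperature_c) ||
      any(temperature_c < 0) || any(temperature_c > constants$max_temp_c))
    stop("temperature_c must lie in [0, ", constants$max_temp_c, "] degC")
  if (!is.numeric(salinity) || anyNA(salinity) || any(salinity < 0))
    stop("salinity must be non-negative (parts per thousand)")
  if (!is.null(ph) &&
      (!is.numeric(ph) || anyNA(ph) || any(ph < 0) || any(ph > 14)))
    stop("ph must lie in [0, 14]")
  invisible(TRUE)
}

#' Equilibrium constants of the carbonate system
#'
#' @param temperature_c Temperature in degrees Celsius, in [0, 100].
#' @param salinity Salinity in parts per thousand (permil), >= 0.
#' @param constants Coefficient set from \code{\link{carbonate_constants}}.
#' @return A list of class \code{equilibrium_constants}: \code{k0} (mol
#'   kg-1 atm-1), \code{k1}, \code{k2} (mol kg-1), \code{pk1}, \code{pk2},
#'   the input conditions, and \code{extrapolated} (TRUE when the
#'   temperature is beyond the stated validity of the fits).
#' @examples
#' equilibrium_constants(25, 0)$pk1   # ~ 6.35
#' equilibrium_constants(30, 0)$k0    # ~ 0.0299
#' @export
equilibrium_constants <- function(temperature_c, salinity = 0,
                                  constants = carbonate_constants()) {
  .check_conditions(temperature_c, salinity, constants = constants)
  tk <- temperature_c + 273.15
  s <- salinity

  a <- constants$k0$a
  b <- constants$k0$b
  ln_k0 <- a[1] + a[2] * (100 / tk) + a[3] * log(tk / 100) +
    s * (b[1] + b[2] * (tk / 100) + b[3] * (tk / 100)^2)

  pk <- function(cf) {
    fresh <- cf$freshwater$a / tk + cf$freshwater$b + cf$freshwater$c * tk
    sal <- cf$salinity
    dpk <- (sal$A[1] * sqrt(s) + sal$A[2] * s + sal$A[3] * s^2) +
      (sal$B[1] * sqrt(s) + sal$B[2] * s) / tk +
      sal$C * sqrt(s) * log(tk)
    fresh + dpk
  }
  pk1 <- pk(constants$pk1)
  pk2 <- pk(constants$pk2)

  structure(list(
    k0 = exp(ln_k0), k1 = 10^(-pk1), k2 = 10^(-pk2),
    pk1 = pk1, pk2 = pk2,
    temperature_c = temperature_c, salinity = salinity,
    extrapolated = temperature_c > constants$valid_temp_c[2]
  ), class = "equilibrium_constants")
}

#' Carbonate speciation fractions at a given pH
#'
#' Fractions of total dissolved inorganic carbon present as CO2*(aq) (+
#' H2CO3*), HCO3- and CO3^2-, from the closed-form expressions
#' \deqn{\alpha_{CO2} = 1/(1 + K_1/h + K_1 K_2/h^2)}
#' \deqn{\alpha_{HCO3} = 1/(h/K_1 + 1 + K_2/h)}
#' \deqn{\alpha_{CO3} = 1/(h^2/(K_1 K_2) + h/K_2 + 1)}
#' with \eqn{h = 10^{-pH}}.
#'
#' @param ph pH (free scale), in [0, 14].
#' @inheritParams equilibrium_constants
#' @return A list of class \code{speciation}: \code{alpha_co2},
#'   \code{alpha_hco3}, \code{alpha_co3} (summing to 1), plus the constants
#'   used.
#' @export
speciation <- function(ph, temperature_c = 25, salinity = 0,
                       constants = carbonate_constants()) {
  .check_conditions(temperature_c, salinity, ph, constants)
  eq <- equilibrium_constants(temperature_c, salinity, constants)
  h <- 10^(-ph)
  a_co2 <- 1 / (1 + eq$k1 / h + eq$k1 * eq$k2 / h^2)
  a_hco3 <- 1 / (h / eq$k1 + 1 + eq$k2 / h)
  a_co3 <- 1 / (h^2 / (eq$k1 * eq$k2) + h / eq$k2 + 1)
  structure(list(alpha_co2 = a_co2, alpha_hco3 = a_hco3, alpha_co3 = a_co3,
                 ph = ph, constants = eq),
            class = "speciation")
}

#' Bjerrum table: speciation along a pH grid
#'
#' @param ph_grid Nonempty, strictly ascending vector of pH values.
#' @inheritParams equilibrium_constants
#' @return A data frame with one row per grid point and columns \code{ph},
#'   \code{alpha_co2}, \code{alpha_hco3}, \code{alpha_co3}, \code{pk1},
#'   \code{pk2}, \code{k0}, \code{extrapolated}.
#' @export
bjerrum_table <- function(ph_grid, temperature_c = 25, salinity = 0,
                          constants = carbonate_constants()) {
  if (length(ph_grid) == 0) stop("ph_grid must be nonempty")
  if (is.unsorted(ph_grid, strictly = TRUE))
    stop("ph_grid must be strictly ascending")
  .check_conditions(temperature_c, salinity, ph_grid, constants)
  eq <- equilibrium_constants(temperature_c, salinity, constants)
  h <- 10^(-ph_grid)
  data.frame(
    ph = ph_grid,
    alpha_co2 = 1 / (1 + eq$k1 / h + eq$k1 * eq$k2 / h^2),
    alpha_hco3 = 1 / (h / eq$k1 + 1 + eq$k2 / h),
    alpha_co3 = 1 / (h^2 / (eq$k1 * eq$k2) + h / eq$k2 + 1),
    pk1 = eq$pk1, pk2 = eq$pk2, k0 = eq$k0,
    extrapolated = eq$extrapolated
  )
}

#' Relative change in CO2 solubility between two temperatures
#'
#' Returns \code{100 * (1 - K0(t2, s) / K0(t1, s))}: the percent loss of
#' Henry solubility when warming from \code{t1} to \code{t2} at fixed
#' salinity.  Warming from 30 to 60 degC in fresh water loses about 43
#' percent of CO2 solubility (about 40 percent at one significant figure).
#'
#' @param t1,t2 Temperatures in degrees Celsius.
#' @param salinity Salinity in permil.
#' @param constants Coefficient set.
#' @return Percent change (positive when \code{t2 > t1}).
#' @export
solubility_change <- function(t1, t2, salinity = 0,
                              constants = carbonate_constants()) {
  k0_1 <- equilibrium_constants(t1, salinity, constants)$k0
  k0_2 <- equilibrium_constants(t2, salinity, constants)$k0
  100 * (1 - k0_2 / k0_1)
}

#' pH at which two adjacent carbonate species are equally abundant
#'
#' Finds, by bisection on the speciation fractions, the pH where
#' \code{alpha_co2 = alpha_hco3} (\code{which = 1}) or \code{alpha_hco3 =
#' alpha_co3} (\code{which = 2}).  These crossover points equal pK1 and pK2
#' respectively; the function exists as an independent route to them from
#' the speciation curves (used e.g. to show the acid shift of the
#' equilibrium with temperature).
#'
#' @param temperature_c,salinity Conditions.
#' @param which 1 for the CO2/HCO3 crossover, 2 for HCO3/CO3.
#' @param tol Bisection tolerance in pH units.
#' @param constants Coefficient set.
#' @return The crossover pH.
#' @export
speciation_crossover <- function(temperature_c = 25, salinity = 0,
                                 which = 1, tol = 1e-9,
                                 constants = carbonate_constants()) {
  f <- function(ph) {
    sp <- speciation(ph, temperature_c, salinity, constants)
    if (which == 1) sp$alpha_co2 - sp$alpha_hco3
    else sp$alpha_hco3 - sp$alpha_co3
  }
  uniroot(f, c(0, 14), tol = tol)$root
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat(sprintf(
    "carbonate constants @ %.1f degC, %.1f permil%s\n",
    x$temperature_c, x$salinity,
    if (x$extrapolated) " (extrapolated beyond fit range)" else ""))
  cat(sprintf("  K0 = %.4g mol/kg/atm, pK1 = %.3f, pK2 = %.3f\n",
              x$k0, x$pk1, x$pk2))
  invisible(x)
}

#' @export
print.speciation <- function(x, ...) {
  cat(sprintf(
    "pH %.2f: CO2* %.3f | HCO3- %.3f | CO3^2- %.3f\n",
    x$ph, x$alpha_co2, x$alpha_hco3, x$alpha_co3))
  invisible(x)
}
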
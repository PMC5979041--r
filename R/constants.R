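#' Physical constants and unit conversions
#'
#' The package works in a single internal unit system: time in nanoseconds,
#' length in nanometres, energy in kcal/mol.  Inputs quoted in kJ/mol
#' (umbrella force constants, metadynamics hill heights) are converted with
#' 1 kcal = 4.184 kJ.
#'
#' @format `kB` is Boltzmann's constant in kcal/mol/K (identical to the molar
#'   gas constant R in these units); `defaultTemperature` is 303 K, the
#'   simulation temperature the package defaults assume.
#' @export
kB <- 0.0019872041

#' @rdname kB
#' @export
defaultTemperature <- 303

#' @rdname kB
#' @param x energy in kJ/mol
#' @return energy in kcal/mol
#' @export
kJToKcal <- function(x) x / 4.184

#' Thermal energy kT in kcal/mol
#' @param temperature temperature in K
#' @return kT in kcal/mol
#' @export
thermalEnergy <- function(temperature = defaultTemperature) kB * temperature

#' Derive a per-trajectory seed from a master seed
#'
#' Ensembles of stochastic runs use one seed per trajectory derived from a
#' master seed by a fixed counter scheme, so an ensemble is reproducible as a
#' whole while its members are independent streams.
#'
#' @param master master seed (integer)
#' @param index trajectory counter (1, 2, ...)
#' @return an integer seed
#' @export
derivedSeed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 1103 * as.double(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
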
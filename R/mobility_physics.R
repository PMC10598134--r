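# Conversion between TIMS elution voltage, inverse reduced mobility (1/K0)
# and collision cross section in nitrogen.

#' Physical constants for the Mason-Schamp conversion
#'
#' Bundles the constants needed to convert an inverse reduced mobility
#' (1/K0, Vs cm^-2) into a collision cross section in Angstrom^2.
#'
#' The drift-gas temperature on a TIMS instrument operated with ambient air
#' is typically not controlled; the conventional value of 305 K is used as
#' the default and must be reported alongside any absolute CCS value.
#' The gas number density is fixed at the Loschmidt constant (273.15 K,
#' 1 atm) because reduced mobility is already normalized to standard
#' temperature and pressure, so no pressure input is needed.
#'
#' @param temperature_K Drift gas temperature in Kelvin. Default 305.
#' @param gas_mass_Da Molecular mass of the drift gas in Dalton.
#'   Default is molecular nitrogen, 28.013406 Da.
#' @return An object of class `ccs_constants`: a list with elements
#'   `elementary_charge` (C), `boltzmann` (J/K), `loschmidt` (m^-3),
#'   `dalton` (kg), `gas_mass_Da`, `temperature_K`.
#' @export
#' @examples
#' physical_constants()
#' physical_constants(temperature_K = 300)
physical_constants <- function(temperature_K = 305,
                               gas_mass_Da = 28.013406) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.numeric(gas_mass_Da), length(gas_mass_Da) == 1L)
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  if (gas_mass_Da <= 0) stop("gas_mass_Da must be > 0")
  structure(list(
    elementary_charge = 1.602176634e-19,
    boltzmann         = 1.380649e-23,
    loschmidt         = 2.686780111e25,
    dalton            = 1.66053906660e-27,
    gas_mass_Da       = gas_mass_Da,
    temperature_K     = temperature_K
  ), class = "ccs_constants")
}

#' @export
print.ccs_constants <- function(x, ...) {
  cat("Mason-Schamp constants: T =", x$temperature_K, "K, gas mass =",
      x$gas_mass_Da, "Da (N0 at 273.15 K / 1 atm)\n")
  invisible(x)
}

#' Fit the linear TIMS elution-voltage calibration
#'
#' Fits an ordinary least-squares line `ref_inv_k0 = intercept + slope *
#' elution_voltage` through at least three calibrant ions, mirroring the
#' vendor calibration of the TIMS dimension.
#'
#' @param points data.frame with columns `elution_voltage` (V) and
#'   `ref_inv_k0` (Vs cm^-2); optionally `mz`. At least 3 rows with
#'   non-constant voltages.
#' @return Object of class `tims_calibration`: list with `intercept`,
#'   `slope`, `n_points`, `max_abs_residual`, and the per-point `residuals`.
#' @export
#' @examples
#' pts <- data.frame(elution_voltage = c(100, 200, 300),
#'                   ref_inv_k0 = c(0.9, 1.1, 1.3))
#' fit_voltage_calibration(pts)
fit_voltage_calibration <- function(points) {
  stopifnot(is.data.frame(points))
  need <- c("elution_voltage", "ref_inv_k0")
  miss <- setdiff(need, names(points))
  if (length(miss)) stop("calibration points missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(points) < 3L)
    stop("voltage calibration requires at least 3 calibrant points, got ",
         nrow(points))
  if (length(unique(points$elution_voltage)) < 2L)
    stop("singular calibration fit: all elution voltages are equal")
  fit <- stats::lm(ref_inv_k0 ~ elution_voltage, data = points)
  res <- stats::residuals(fit)
  structure(list(
    intercept        = unname(stats::coef(fit)[1L]),
    slope            = unname(stats::coef(fit)[2L]),
    n_points         = nrow(points),
    max_abs_residual = max(abs(res)),
    residuals        = unname(res)
  ), class = "tims_calibration")
}

#' @export
print.tims_calibration <- function(x, ...) {
  cat(sprintf(
    "TIMS calibration: 1/K0 = %.6g + %.6g * V (n = %d, max |resid| = %.3g)\n",
    x$intercept, x$slope, x$n_points, x$max_abs_residual))
  invisible(x)
}

#' Predict 1/K0 from elution voltage with a fitted calibration
#'
#' @param calibration A `tims_calibration` object.
#' @param elution_voltage Numeric vector of voltages.
#' @return Numeric vector of inverse reduced mobilities (Vs cm^-2).
#' @export
predict_inv_k0 <- function(calibration, elution_voltage) {
  stopifnot(inherits(calibration, "tims_calibration"))
  calibration$intercept + calibration$slope * elution_voltage
}

# Mason-Schamp prefactor a(z, mz): CCS in A^2 per unit 1/K0 (Vs cm^-2).
# Omega = (3 z e / (16 N0)) sqrt(2 pi / (mu kB T)) * (1/K0),
# mu the reduced mass of ion (z * mz, no electron-mass correction) and gas.
# 1/K0 in Vs cm^-2 -> SI via 1e4; result m^2 -> A^2 via 1e20.
ms_prefactor <- function(charge, mz, constants) {
  m_ion <- charge * mz * constants$dalton
  m_gas <- constants$gas_mass_Da * constants$dalton
  mu <- m_ion * m_gas / (m_ion + m_gas)
  (3 * charge * constants$elementary_charge / (16 * constants$loschmidt)) *
    sqrt(2 * pi / (mu * constants$boltzmann * constants$temperature_K)) *
    1e4 * 1e20
}

#' Convert inverse reduced mobility to collision cross section
#'
#' Applies the Mason-Schamp equation to convert a measured inverse reduced
#' mobility (1/K0) into the ion-nitrogen collision cross section. The ion
#' mass entering the reduced mass is `charge * mz`, uncorrected for the
#' electron mass (an effect far below measurement precision).
#'
#' @param inv_k0 Inverse reduced mobility, Vs cm^-2. Vectorized.
#' @param charge Ion charge state (>= 1). Vectorized.
#' @param mz Mass-to-charge ratio, Th. Vectorized.
#' @param constants A `ccs_constants` object; see [physical_constants()].
#' @return Collision cross section(s) in Angstrom^2.
#' @export
#' @examples
#' ccs_from_inv_k0(0.9848, 1, 622.0289) # ~202 A^2, the 622 tune-mix ion
ccs_from_inv_k0 <- function(inv_k0, charge, mz,
                            constants = physical_constants()) {
  stopifnot(inherits(constants, "ccs_constants"))
  if (any(!is.finite(inv_k0)) || any(inv_k0 <= 0))
    stop("inv_k0 must be finite and > 0")
  if (any(charge < 1)) stop("charge must be >= 1")
  if (any(mz <= 0)) stop("mz must be > 0")
  ms_prefactor(charge, mz, constants) * inv_k0
}

#' Convert collision cross section to inverse reduced mobility
#'
#' Exact algebraic inverse of [ccs_from_inv_k0()]; used by the synthetic
#' generator to emit raw-scale evidence tables from true CCS values.
#'
#' @param ccs Collision cross section, Angstrom^2. Vectorized.
#' @inheritParams ccs_from_inv_k0
#' @return Inverse reduced mobility (Vs cm^-2).
#' @export
inv_k0_from_ccs <- function(ccs, charge, mz,
                            constants = physical_constants()) {
  stopifnot(inherits(constants, "ccs_constants"))
  if (any(!is.finite(ccs)) || any(ccs <= 0))
    stop("ccs must be finite and > 0")
  if (any(charge < 1)) stop("charge must be >= 1")
  if (any(mz <= 0)) stop("mz must be > 0")
  ccs / ms_prefactor(charge, mz, constants)
}

#' Add a CCS column to a feature table
#'
#' Converts the (aligned) `inv_k0` column of an evidence feature table to
#' CCS, row by row, using each feature's charge and m/z.
#'
#' @param features Feature data.frame (see [read_evidence_table()]).
#' @param constants A `ccs_constants` object.
#' @return The feature table with its `ccs` column populated.
#' @export
convert_features_to_ccs <- function(features,
                                    constants = physical_constants()) {
  stopifnot(is.data.frame(features))
  features$ccs <- ccs_from_inv_k0(features$inv_k0, features$charge,
                                  features$mz, constants)
  features
}
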
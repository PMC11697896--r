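#' Fluid constants for cerebrospinal fluid
#'
#' Dynamic viscosity and density used throughout the hydraulic calculations.
#' Defaults correspond to CSF at body temperature: viscosity of water at
#' 36 degrees C and unit density.
#'
#' @param mu Dynamic viscosity in mPa·s. Default 0.71.
#' @param rho Density in kg/m³. Default 1000.
#' @return An object of class `fluid_constants`.
#' @examples
#' fluid_constants()
#' fluid_constants(mu = 1.0)
#' @export
fluid_constants <- function(mu = 0.71, rho = 1000) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a single positive number (mPa·s)")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("`rho` must be a single positive number (kg/m³)")
  structure(list(mu = mu, rho = rho), class = "fluid_constants")
}

#' @export
print.fluid_constants <- function(x, ...) {
  cat(sprintf("CSF fluid constants: mu = %g mPa·s, rho = %g kg/m³\n",
              x$mu, x$rho))
  invisible(x)
}

as_fluid_constants <- function(const) {
  if (inherits(const, "fluid_constants")) return(const)
  if (is.null(const)) return(fluid_constants())
  do.call(fluid_constants, as.list(const))
}

#' Poiseuille resistance of a single tube element
#'
#' Hydraulic resistance of a short circular element,
#' R = 128·µ·L / (π·D⁴). With µ in mPa·s and lengths in mm the result is in
#' mPa·s/mm³, the unit in which aqueduct resistance is reported.
#'
#' @param length Element arc length, mm. Must be > 0.
#' @param diameter Element lumen diameter, mm. Must be > 0.
#' @param const A [fluid_constants()] object.
#' @return Resistance in mPa·s/mm³ (vectorised over `length`/`diameter`).
#' @examples
#' element_resistance(1, 1)            # 128*0.71/pi = 28.93
#' element_resistance(15, 2)           # 27.12
#' @export
element_resistance <- function(length, diameter, const = fluid_constants()) {
  const <- as_fluid_constants(const)
  if (!is.numeric(length) || !is.numeric(diameter))
    stop("invalid geometry: `length` and `diameter` must be numeric")
  if (length(length) != length(diameter) &&
      length(length) != 1L && length(diameter) != 1L)
    stop("invalid geometry: `length` and `diameter` lengths are incompatible")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("invalid geometry: element length must be positive")
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("invalid geometry: element diameter must be positive")
  128 * const$mu * length / (pi * diameter^4)
}

#' Womersley number of a pulsatile tube flow
#'
#' Ratio of pulsatile inertial to viscous forces,
#' Wo = (D/2)·sqrt(ω·ρ/µ), with ω = 2π / cardiac period. Quantities are
#' converted to SI internally; the result is dimensionless.
#'
#' @param diameter Lumen diameter, mm.
#' @param cardiac_period Cardiac period, s.
#' @param const A [fluid_constants()] object.
#' @return Dimensionless Womersley number (vectorised over `diameter`).
#' @examples
#' womersley_number(1.9, 0.85)  # about 3.1
#' @export
womersley_number <- function(diameter, cardiac_period,
                             const = fluid_constants()) {
  const <- as_fluid_constants(const)
  if (any(!is.finite(diameter)) || any(diameter < 0))
    stop("`diameter` must be non-negative (mm)")
  if (!is.numeric(cardiac_period) || any(cardiac_period <= 0))
    stop("`cardiac_period` must be positive (s)")
  omega <- 2 * pi / cardiac_period              # rad/s
  d_m <- diameter * 1e-3                        # mm -> m
  mu_si <- const$mu * 1e-3                      # mPa·s -> Pa·s
  (d_m / 2) * sqrt(omega * const$rho / mu_si)
}

#' Reynolds number of a tube element at a given flow rate
#'
#' Re = ρ·v·D/µ with v the mean cross-sectional velocity Q / (πD²/4), so
#' Re = 4ρQ / (πµD). Quantities are converted to SI internally.
#'
#' @param flow Volumetric flow rate, mm³/s. Must be >= 0.
#' @param diameter Lumen diameter, mm. Must be > 0.
#' @param const A [fluid_constants()] object.
#' @return Dimensionless Reynolds number; 0 when `flow` is 0.
#' @examples
#' reynolds_number(177, 1.2)  # about 264.5
#' @export
reynolds_number <- function(flow, diameter, const = fluid_constants()) {
  const <- as_fluid_constants(const)
  if (any(!is.finite(flow)) || any(flow < 0))
    stop("`flow` must be non-negative (mm³/s)")
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("`diameter` must be positive (mm)")
  q_si <- flow * 1e-9                           # mm³/s -> m³/s
  d_m <- diameter * 1e-3
  mu_si <- const$mu * 1e-3
  4 * const$rho * q_si / (pi * mu_si * d_m)
}

#' Pressure difference across a resistance at a given flow
#'
#' ΔP = R·Q. With R in mPa·s/mm³ and Q in mm³/s the product is in mPa;
#' the result is reported in Pa. The sign of ΔP follows the sign of Q.
#'
#' @param resistance Hydraulic resistance, mPa·s/mm³. Must be >= 0.
#' @param flow Flow rate, mm³/s (signed).
#' @return Pressure difference in Pa (vectorised).
#' @examples
#' pressure_difference(78, 177)  # 13.806 Pa
#' @export
pressure_difference <- function(resistance, flow) {
  if (any(!is.finite(resistance)) || any(resistance < 0))
    stop("`resistance` must be non-negative (mPa·s/mm³)")
  if (!is.numeric(flow)) stop("`flow` must be numeric (mm³/s)")
  resistance * flow / 1000
}

#' Convert pascals to millimetres of mercury
#'
#' @param p Pressure in Pa.
#' @return Pressure in mmHg (p / 133.322).
#' @examples
#' pa_to_mmhg(24.2)  # about 0.18
#' @export
pa_to_mmhg <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric (Pa)")
  p / 133.322
}
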
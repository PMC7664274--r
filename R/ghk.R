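# Goldman-Hodgkin-Katz constant-field current <-> permeability conversion.

#' Physical constants (SI)
#' @noRd
.FARADAY <- 96485.33212   # C / mol
.GAS_R   <- 8.314462618   # J / (mol K)

#' GHK context: ion and bath description for constant-field calculations
#'
#' Bundles the quantities that the Goldman-Hodgkin-Katz current equation
#' needs besides voltage: permeant-ion valence, internal and external
#' concentrations, temperature, and the specific membrane capacitance used
#' to convert between current per membrane area and current per cell
#' capacitance (current *density* in the whole-cell sense, pA/pF).
#'
#' @param z Ion valence (signed integer; +1 for Na+).
#' @param conc_in,conc_out Internal / external permeant-ion concentration (mM).
#' @param temperature Absolute temperature (K). Default 295 K (room
#'   temperature recordings).
#' @param spec_capacitance Specific membrane capacitance (uF/cm^2) used to
#'   express per-area currents per pF of whole-cell capacitance. Default 1.
#' @return Object of class `ghk_context`.
#' @examples
#' ghk_context(z = 1, conc_in = 10, conc_out = 30)
#' @export
ghk_context <- function(z = 1, conc_in, conc_out, temperature = 295,
                        spec_capacitance = 1) {
  stopifnot(length(z) == 1, z == as.integer(z), z != 0)
  if (conc_in <= 0 || conc_out <= 0)
    stop("ghk_context: concentrations must be > 0")
  if (temperature <= 0) stop("ghk_context: temperature must be > 0 K")
  structure(
    list(z = as.integer(z), conc_in = conc_in, conc_out = conc_out,
         temperature = temperature, spec_capacitance = spec_capacitance),
    class = "ghk_context")
}

#' Reversal potential of the GHK context (mV)
#' @param ctx A [ghk_context()].
#' @return Nernst reversal potential in mV.
#' @export
ghk_reversal <- function(ctx) {
  1000 * .GAS_R * ctx$temperature / (ctx$z * .FARADAY) *
    log(ctx$conc_out / ctx$conc_in)
}

#' GHK current density from permeability
#'
#' Evaluates the constant-field (Goldman-Hodgkin-Katz) current equation
#' \deqn{I = P z^2 \frac{E F^2}{RT}
#'       \frac{[S]_i - [S]_o e^{-zFE/RT}}{1 - e^{-zFE/RT}}}
#' returning whole-cell current density in pA/pF. At E = 0 the removable
#' singularity is replaced by its analytic limit
#' \eqn{I = P z F ([S]_i - [S]_o)}.
#'
#' @param permeability Membrane permeability P (cm/s). Vectorized.
#' @param voltage Membrane potential E (mV). Vectorized.
#' @param ctx A [ghk_context()].
#' @return Current density (pA/pF), positive = outward.
#' @export
ghk_current <- function(permeability, voltage, ctx) {
  stopifnot(inherits(ctx, "ghk_context"))
  E <- voltage / 1000                                  # V
  rt <- .GAS_R * ctx$temperature
  z <- ctx$z
  ci <- ctx$conc_in * 1e-6                             # mol / cm^3
  co <- ctx$conc_out * 1e-6
  x <- z * .FARADAY * E / rt
  # A/cm^2, with the exact x -> 0 limit patched in
  flux <- ifelse(
    abs(x) < 1e-10,
    z * .FARADAY * (ci - co),
    z^2 * .FARADAY^2 * E / rt * (ci - co * exp(-x)) / (1 - exp(-x)))
  # A/cm^2 -> pA/pF: x1e12 pA/A, / (spec_capacitance uF/cm^2 * 1e6 pF/uF)
  permeability * flux * 1e6 / ctx$spec_capacitance
}

#' Invert the GHK current equation for permeability
#'
#' Given a measured whole-cell current density and the membrane potential,
#' solves the constant-field current equation for the permeability. The
#' equation is linear in P, so the inversion is exact; it is undefined at
#' the reversal potential, where the bracketed concentration term vanishes.
#'
#' @param current_density Measured current density (pA/pF). Vectorized.
#' @param voltage Membrane potential E (mV). Vectorized.
#' @param ctx A [ghk_context()].
#' @return Permeability (cm/s), same sign convention as the input current.
#' @export
ghk_permeability <- function(current_density, voltage, ctx) {
  stopifnot(inherits(ctx, "ghk_context"))
  erev <- ghk_reversal(ctx)
  unit <- ghk_current(1, voltage, ctx)
  if (any(abs(voltage - erev) < 1e-9) || any(unit == 0))
    stop(sprintf(paste0("ghk_permeability: voltage at the reversal potential",
                        " (%.2f mV); permeability is undefined there"), erev))
  current_density / unit
}
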
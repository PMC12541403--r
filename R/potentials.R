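# Electrochemical scale arithmetic: H+/H2 equilibrium potential, SHE/RHE
# conversion, mediator overpotential, Nernst potential from a ratio.
# Internally every potential is carried in volts vs SHE; RHE is a view
# that requires a pH.

#' Physical constants used throughout the package
#'
#' Faraday constant and molar gas constant (SI units).
#' @keywords internal
#' @name constants
NULL

.FARADAY <- 96485.33212   # C mol^-1
.RGAS    <- 8.314462618   # J mol^-1 K^-1

#' Nernstian pH slope
#'
#' Slope of the H+/H2 equilibrium potential with pH, in volts per pH unit.
#' The conventional rounded value 60 mV/pH is the default throughout the
#' package; the physically exact value 2.303*R*T/F at a given temperature
#' is available with `exact = TRUE`.
#'
#' @param exact if `TRUE`, return 2.303*R*T/F at `temperature` instead of
#'   the rounded 60 mV/pH convention.
#' @param temperature temperature in kelvin (only used when `exact = TRUE`).
#' @return slope in volts per pH unit.
#' @examples
#' nernst_slope()              # 0.060
#' nernst_slope(exact = TRUE)  # 0.05916 at 298.15 K
#' @export
nernst_slope <- function(exact = FALSE, temperature = 298.15) {
  if (exact) log(10) * .RGAS * temperature / .FARADAY else 0.060
}

#' Create a potential value with an explicit reference scale
#'
#' A `potential_value` is a number in volts tagged with its reference scale
#' (SHE or RHE), the pH context needed for scale conversion, and a
#' temperature.
#'
#' @param value potential in volts.
#' @param scale `"SHE"` or `"RHE"`.
#' @param pH solution pH; required whenever the value must be converted
#'   between scales (and always meaningful for RHE values).
#' @param temperature kelvin.
#' @return an object of class `potential_value`.
#' @examples
#' potential_value(-0.25, "SHE", pH = 7)
#' @export
potential_value <- function(value, scale = c("SHE", "RHE"), pH = NA_real_,
                            temperature = 298.15) {
  scale <- match.arg(scale)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("'value' must be a single finite number (volts)", call. = FALSE)
  if (!is.na(pH) && (pH < 0 || pH > 14))
    stop("'pH' must lie in [0, 14]", call. = FALSE)
  if (scale == "RHE" && is.na(pH))
    stop("a potential on the RHE scale requires a pH", call. = FALSE)
  structure(list(value = value, scale = scale, pH = pH,
                 temperature = temperature),
            class = "potential_value")
}

#' @export
print.potential_value <- function(x, ...) {
  cat(sprintf("%+.4f V vs %s", x$value, x$scale))
  if (!is.na(x$pH)) cat(sprintf(" (pH %.2f)", x$pH))
  cat("\n")
  invisible(x)
}

#' @export
format.potential_value <- function(x, ...) {
  sprintf("%+.4f V vs %s", x$value, x$scale)
}

#' Create a redox couple
#'
#' @param e0 standard (midpoint) potential in volts vs SHE.
#' @param n_electrons number of electrons exchanged (positive integer).
#' @param label optional text label (e.g. `"DV2"`).
#' @return an object of class `redox_couple`.
#' @examples
#' redox_couple(-0.40, label = "DV2")
#' @export
redox_couple <- function(e0, n_electrons = 1L, label = "") {
  if (!is.numeric(e0) || length(e0) != 1L || !is.finite(e0))
    stop("'e0' must be a single finite number (volts vs SHE)", call. = FALSE)
  n_electrons <- as.integer(n_electrons)
  if (is.na(n_electrons) || n_electrons < 1L)
    stop("'n_electrons' must be a positive integer", call. = FALSE)
  structure(list(e0 = e0, n_electrons = n_electrons, label = as.character(label)),
            class = "redox_couple")
}

#' @export
print.redox_couple <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(x$label, ": ") else ""
  cat(sprintf("%sE0 = %+.4f V vs SHE (n = %d)\n", lab, x$e0, x$n_electrons))
  invisible(x)
}

#' Equilibrium potential of the H+/H2 couple
#'
#' E_eq = -slope * pH - (slope / 2) * log10(p_H2), in volts vs SHE.  The
#' half power of the H2 pressure follows from the two-electron couple
#' H2 / 2 H+.  At 1 bar H2 and pH 7 with the conventional 60 mV/pH slope
#' this gives -0.42 V vs SHE.
#'
#' @param pH solution pH.
#' @param p_h2 H2 partial pressure in bar (default 1).
#' @param slope Nernstian pH slope in volts per pH unit; defaults to
#'   [nernst_slope()] (60 mV/pH).
#' @param temperature kelvin, stored in the result.
#' @return a [potential_value] on the SHE scale.
#' @examples
#' h2_equilibrium_potential(7)           # -0.42 V vs SHE
#' h2_equilibrium_potential(7, p_h2 = 0.5)
#' @export
h2_equilibrium_potential <- function(pH, p_h2 = 1, slope = nernst_slope(),
                                     temperature = 298.15) {
  if (!is.numeric(p_h2) || length(p_h2) != 1L || !is.finite(p_h2) || p_h2 <= 0)
    stop("'p_h2' must be a positive pressure in bar", call. = FALSE)
  if (pH < 0 || pH > 14) stop("'pH' must lie in [0, 14]", call. = FALSE)
  e <- -slope * pH - (slope / 2) * log10(p_h2)
  potential_value(e, "SHE", pH = pH, temperature = temperature)
}

#' Convert a potential between the SHE and RHE scales
#'
#' E_RHE = E_SHE - E_eq(pH), where E_eq is the H+/H2 equilibrium potential
#' at 1 bar H2.  The conversion requires the pH; the round trip
#' SHE -> RHE -> SHE is the identity.
#'
#' @param p a [potential_value].
#' @param target_scale `"SHE"` or `"RHE"`.
#' @param slope Nernstian pH slope in volts per pH unit.
#' @return a [potential_value] on the requested scale.
#' @examples
#' convert_reference(potential_value(-0.25, "SHE", pH = 7), "RHE")  # +0.17 V
#' @export
convert_reference <- function(p, target_scale = c("SHE", "RHE"),
                              slope = nernst_slope()) {
  target_scale <- match.arg(target_scale)
  if (!inherits(p, "potential_value"))
    stop("'p' must be a potential_value", call. = FALSE)
  if (p$scale == target_scale) return(p)
  if (is.na(p$pH))
    stop("converting between SHE and RHE requires a pH", call. = FALSE)
  e_eq <- -slope * p$pH
  value <- if (target_scale == "RHE") p$value - e_eq else p$value + e_eq
  potential_value(value, target_scale, pH = p$pH, temperature = p$temperature)
}

#' Mediator overpotential relative to the H+/H2 couple
#'
#' E0 - E_eq(pH, p_H2), in millivolts.  Positive values mean the mediator
#' is more oxidizing than the H+/H2 couple at that pH.
#'
#' @param couple a [redox_couple] with `e0` given vs SHE.
#' @param pH solution pH.
#' @param p_h2 H2 partial pressure in bar.
#' @param slope Nernstian pH slope in volts per pH unit.
#' @return overpotential in millivolts (numeric scalar).
#' @examples
#' mediator_overpotential(redox_couple(-0.40), pH = 7)  # +20 mV
#' mediator_overpotential(redox_couple(-0.22), pH = 7)  # +200 mV
#' @export
mediator_overpotential <- function(couple, pH, p_h2 = 1,
                                   slope = nernst_slope()) {
  if (!inherits(couple, "redox_couple"))
    stop("'couple' must be a redox_couple", call. = FALSE)
  e_eq <- h2_equilibrium_potential(pH, p_h2 = p_h2, slope = slope)
  (couple$e0 - e_eq$value) * 1000
}

#' Nernst potential of a couple from its concentration ratio
#'
#' E = E0 + (R*T / n*F) * ln(ratio), with `ratio` the oxidized-over-reduced
#' concentration ratio.  Undefined at a fully oxidized or fully reduced
#' pole (ratio must be positive and finite).
#'
#' @param couple a [redox_couple].
#' @param ratio_ox_over_red concentration ratio oxidized/reduced (> 0).
#' @param temperature kelvin.
#' @return a [potential_value] on the SHE scale.
#' @examples
#' dv2 <- redox_couple(-0.40)
#' nernst_from_ratio(dv2, 10)   # E0 + 59.16 mV at 298.15 K
#' @export
nernst_from_ratio <- function(couple, ratio_ox_over_red, temperature = 298.15) {
  if (!inherits(couple, "redox_couple"))
    stop("'couple' must be a redox_couple", call. = FALSE)
  r <- ratio_ox_over_red
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'ratio_ox_over_red' must be a positive finite number", call. = FALSE)
  e <- couple$e0 + .RGAS * temperature / (couple$n_electrons * .FARADAY) * log(r)
  potential_value(e, "SHE", temperature = temperature)
}
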
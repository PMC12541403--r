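# Local kinetics of the film model: the reversible enzyme rate law, the
# potential-driven inactivation/reactivation pair, and the Nernstian
# electrode boundary ratio.

# Equilibrium constant K_inv = exp(2F (E_eq - E0) / RT) of
#   H2 + 2 V_ox <-> 2 H+ + 2 V_red
# expressed as (V_ox/V_red)^2 * (H2/h2_sat) at equilibrium.
.k_inv <- function(params) {
  e_eq <- -params$slope * params$pH
  exp(2 * .FARADAY * (e_eq - params$mediator$e0) /
        (.RGAS * params$temperature))
}

# Local equilibrium constant of the rate law, a_ox = a_red / K_eq at
# detailed balance (see enzyme_kinetics).
.k_eq_loc <- function(params) {
  k <- params$kinetics
  k$K_h2 * (k$K_vox / k$K_vred)^2 / (.k_inv(params) * params$h2_sat)
}

#' Net enzymatic H2-oxidation rate
#'
#' Reversible two-substrate rate law for the bidirectional H2/H+
#' conversion, in mol H2 per m^3 per s (positive = H2 oxidation), scaled by
#' the local active-enzyme concentration.  The rate vanishes exactly when
#' the mediator Nernst potential equals the local H+/H2 couple potential
#' (detailed balance); it is positive whenever the mediator pool is more
#' oxidizing than that, negative (H2 evolution) otherwise.
#'
#' @param v_ox,v_red local oxidized/reduced mediator concentrations,
#'   mol m^-3 (vectors allowed).
#' @param h2 local H2 concentration, mol m^-3.
#' @param params a [film_parameters].
#' @param e_active local active-enzyme concentration, mol m^-3 (defaults to
#'   the total enzyme loading).
#' @return rate in mol m^-3 s^-1, same length as the inputs.
#' @examples
#' p <- default_parameter_set("DV2_pH7")
#' enzyme_net_rate(50, 50, 0.78, p)
#' @export
enzyme_net_rate <- function(v_ox, v_red, h2, params,
                            e_active = params$e_total) {
  if (any(v_ox < 0) || any(v_red < 0) || any(h2 < 0) || any(e_active < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  kin <- params$kinetics
  a_ox <- (v_ox / kin$K_vox)^2 * (h2 / kin$K_h2)
  a_red <- (v_red / kin$K_vred)^2
  e_active * kin$k_cat_ox * (a_ox - a_red / .k_eq_loc(params)) /
    (1 + a_ox + a_red)
}

#' Potential-driven inactivation and reactivation rate constants
#'
#' \deqn{k_i = k_x e^{+\alpha (E_V - E_{inact})/2}, \quad
#'       k_a = k_x e^{-\alpha (E_V - E_{inact})/2}}
#' The two are equal (both `k_x`) at the inactivation potential.  `e_v`
#' is the local mediator Nernst potential vs SHE; `e_inact` is resolved to
#' the SHE scale at the given pH via [e_inact_she()].
#'
#' @param e_v local Nernst potential, volts vs SHE (vector allowed).
#' @param model an [inactivation_model].
#' @param pH solution pH (fixes the SHE-scale inactivation potential).
#' @param slope Nernstian pH slope, V per pH unit.
#' @return a list with components `k_i` and `k_a`, s^-1.
#' @examples
#' m <- inactivation_model()
#' inactivation_rate_pair(e_inact_she(m, 7), m, pH = 7)  # k_i == k_a == k_x
#' @export
inactivation_rate_pair <- function(e_v, model, pH, slope = nernst_slope()) {
  de <- e_v - e_inact_she(model, pH, slope)
  list(k_i = model$k_x * exp(+model$alpha * de / 2),
       k_a = model$k_x * exp(-model$alpha * de / 2))
}

#' Nernstian mediator ratio at the electrode
#'
#' Ratio V_ox/V_red imposed at the electrode surface by fast (Nernstian)
#' electrode kinetics: \eqn{ratio = \exp(nF(E - E^0)/RT)}.  Together with
#' the mediator conservation V_ox + V_red = V_total this fixes both
#' mediator concentrations at the electrode node.
#'
#' @param E electrode potential: a [potential_value] or a number in volts
#'   vs SHE.
#' @param mediator a [redox_couple].
#' @param temperature kelvin.
#' @return dimensionless ratio V_ox/V_red at the electrode.
#' @examples
#' electrode_boundary_ratio(-0.40, redox_couple(-0.40))  # 1
#' @export
electrode_boundary_ratio <- function(E, mediator, temperature = 298.15) {
  if (inherits(E, "potential_value")) {
    if (E$scale != "SHE") E <- convert_reference(E, "SHE")
    E <- E$value
  }
  exp(mediator$n_electrons * .FARADAY * (E - mediator$e0) /
        (.RGAS * temperature))
}
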
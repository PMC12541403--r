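# Parameter containers for the film model: enzyme kinetics, inactivation
# model, film parameters and boundary conditions, plus named default
# parameter sets for the mediator/pH conditions studied.

#' Enzyme kinetic parameters
#'
#' Parameters of the reversible two-substrate rate law used for the
#' bidirectional H2/H+ conversion by the film-embedded enzyme:
#' \deqn{v = E_a k_{cat} (a_{ox} - a_{red}/K_{eq}) / (1 + a_{ox} + a_{red})}
#' with \eqn{a_{ox} = (V_{ox}/K_{Vox})^2 (H_2/K_{H2})} and
#' \eqn{a_{red} = (V_{red}/K_{Vred})^2}.  The local equilibrium constant
#' \eqn{K_{eq}} is not a free parameter: it is fixed by detailed balance
#' from the mediator standard potential, the pH and the H+/H2 equilibrium
#' potential, so that the net rate vanishes exactly when the mediator
#' Nernst potential equals the local H+/H2 couple potential.
#'
#' @param k_cat_ox maximal H2-oxidation turnover frequency, s^-1.
#' @param K_h2 H2 affinity constant, mol m^-3.
#' @param K_vox,K_vred oxidized/reduced mediator affinity constants, mol m^-3.
#' @return an object of class `enzyme_kinetics`.
#' @export
enzyme_kinetics <- function(k_cat_ox = 800, K_h2 = 0.15,
                            K_vox = 2, K_vred = 12) {
  vals <- c(k_cat_ox = k_cat_ox, K_h2 = K_h2, K_vox = K_vox, K_vred = K_vred)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all enzyme kinetic constants must be positive and finite", call. = FALSE)
  structure(as.list(vals), class = "enzyme_kinetics")
}

#' Enzyme inactivation model
#'
#' Reversible oxidative inactivation driven by the local mediator Nernst
#' potential, plus a parallel O2-driven channel.  The potential-driven rate
#' constants are
#' \deqn{k_i = k_x e^{+\alpha (E_V - E_{inact})/2}, \quad
#'       k_a = k_x e^{-\alpha (E_V - E_{inact})/2},}
#' equal at \eqn{E_V = E_{inact}}.  `e_inact` is pinned to the RHE scale
#' (+0.17 V vs RHE by default, i.e. -0.25 V vs SHE at pH 7 with the 60
#' mV/pH slope): the inactivation equilibrium therefore shifts with pH on
#' the SHE scale while the mediator potential does not, which is what makes
#' anaerobic inactivation more pronounced at alkaline pH for a
#' high-potential mediator.
#'
#' O2 inactivates active enzyme at rate `k_inact_o2 * [O2]`; a fraction
#' `phi_irr` of those events is irreversible (enzyme moves to a dead pool),
#' the rest joins the reversibly inactive pool.
#'
#' @param e_inact inactivation potential.  Either a [potential_value]
#'   (converted internally) or a plain number interpreted in volts vs RHE.
#' @param k_x shared rate magnitude at `E_V = e_inact`, s^-1.
#' @param alpha exponential potential sensitivity, V^-1.
#' @param k_inact_o2 O2-driven inactivation rate constant, m^3 mol^-1 s^-1.
#' @param phi_irr fraction of O2-inactivation events that are irreversible,
#'   in `[0, 1]`.
#' @return an object of class `inactivation_model` storing `e_inact_rhe`.
#' @export
inactivation_model <- function(e_inact = 0.17, k_x = 0.05, alpha = 70,
                               k_inact_o2 = 100, phi_irr = 0) {
  if (inherits(e_inact, "potential_value"))
    e_inact <- convert_reference(e_inact, "RHE")$value
  if (!is.finite(e_inact)) stop("'e_inact' must be finite", call. = FALSE)
  if (k_x <= 0 || alpha < 0 || k_inact_o2 < 0)
    stop("'k_x' must be > 0 and 'alpha', 'k_inact_o2' >= 0", call. = FALSE)
  if (phi_irr < 0 || phi_irr > 1)
    stop("'phi_irr' must lie in [0, 1]", call. = FALSE)
  structure(list(e_inact_rhe = e_inact, k_x = k_x, alpha = alpha,
                 k_inact_o2 = k_inact_o2, phi_irr = phi_irr),
            class = "inactivation_model")
}

#' Inactivation potential on the SHE scale at a given pH
#'
#' @param model an [inactivation_model].
#' @param pH solution pH.
#' @param slope Nernstian pH slope, V per pH unit.
#' @return potential in volts vs SHE (numeric scalar).
#' @export
e_inact_she <- function(model, pH, slope = nernst_slope()) {
  model$e_inact_rhe - slope * pH
}

#' Film parameters for the reaction-diffusion model
#'
#' Full physical and kinetic description of one enzyme-film electrode
#' system.  All quantities are SI: meters, mol m^-3, m^2 s^-1, kelvin.
#'
#' @param thickness film thickness L, m.
#' @param v_total total mediator (viologen) concentration, mol m^-3.
#' @param d_e apparent electron (mediator) diffusion coefficient from
#'   self-exchange hopping, m^2 s^-1.
#' @param d_h2,d_o2 H2 and O2 diffusion coefficients in the film, m^2 s^-1.
#' @param part_h2,part_o2 dimensionless partition coefficients at the
#'   film/solution interface.
#' @param e_total total enzyme concentration, mol m^-3.
#' @param mediator a [redox_couple] (one-electron viologen by default).
#' @param kinetics an [enzyme_kinetics].
#' @param inactivation an [inactivation_model].
#' @param k_o2_v rate constant of the O2 + V_red scavenging reaction,
#'   m^3 mol^-1 s^-1.
#' @param s_o2 electrons consumed per O2 scavenged (1, 2 or 4).
#' @param h2_sat H2 concentration at 1 bar (solubility), mol m^-3; anchors
#'   the H+/H2 couple potential inside the film.
#' @param temperature kelvin.
#' @param pH solution pH.
#' @param slope Nernstian pH slope used for E_eq, V per pH unit.
#' @return an object of class `film_parameters`.
#' @examples
#' p <- film_parameters(mediator = redox_couple(-0.40, label = "DV2"))
#' @export
film_parameters <- function(thickness = 1e-6, v_total = 100,
                            d_e = 5e-14, d_h2 = 4e-10, d_o2 = 4e-10,
                            part_h2 = 1, part_o2 = 1, e_total = 1,
                            mediator = redox_couple(-0.40, label = "DV2"),
                            kinetics = enzyme_kinetics(),
                            inactivation = inactivation_model(),
                            k_o2_v = 100, s_o2 = 4, h2_sat = 0.78,
                            temperature = 298.15, pH = 7,
                            slope = nernst_slope()) {
  pos <- c(thickness = thickness, v_total = v_total, d_e = d_e,
           d_h2 = d_h2, d_o2 = d_o2, part_h2 = part_h2, part_o2 = part_o2,
           e_total = e_total, h2_sat = h2_sat, temperature = temperature)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("thickness, concentrations, diffusivities and partition ",
         "coefficients must all be positive", call. = FALSE)
  if (k_o2_v < 0) stop("'k_o2_v' must be >= 0", call. = FALSE)
  if (!s_o2 %in% c(1, 2, 4)) stop("'s_o2' must be 1, 2 or 4", call. = FALSE)
  if (pH < 0 || pH > 14) stop("'pH' must lie in [0, 14]", call. = FALSE)
  stopifnot(inherits(mediator, "redox_couple"),
            inherits(kinetics, "enzyme_kinetics"),
            inherits(inactivation, "inactivation_model"))
  structure(list(thickness = thickness, v_total = v_total, d_e = d_e,
                 d_h2 = d_h2, d_o2 = d_o2, part_h2 = part_h2,
                 part_o2 = part_o2, e_total = e_total, mediator = mediator,
                 kinetics = kinetics, inactivation = inactivation,
                 k_o2_v = k_o2_v, s_o2 = s_o2, h2_sat = h2_sat,
                 temperature = temperature, pH = pH, slope = slope),
            class = "film_parameters")
}

#' @export
print.film_parameters <- function(x, ...) {
  cat("Film parameters\n")
  cat(sprintf("  mediator %s E0 = %+.3f V vs SHE, v_total = %g mol/m^3\n",
              x$mediator$label, x$mediator$e0, x$v_total))
  cat(sprintf("  L = %g m, D_e = %g, D_H2 = %g, D_O2 = %g m^2/s\n",
              x$thickness, x$d_e, x$d_h2, x$d_o2))
  cat(sprintf("  enzyme %g mol/m^3, k_cat_ox = %g /s, pH %.1f, T = %.2f K\n",
              x$e_total, x$kinetics$k_cat_ox, x$pH, x$temperature))
  invisible(x)
}

#' Boundary conditions for the film model
#'
#' The mediator is confined to the film (zero flux at the film/solution
#' interface) and equilibrated with the electrode potential at the
#' electrode (Nernstian boundary).  Substrates have zero flux at the
#' electrode and fixed partition-scaled bulk concentrations at the
#' film/solution interface.
#'
#' @param electrode_potential a [potential_value] or a number in volts vs
#'   SHE.
#' @param bulk_h2,bulk_o2 bulk solution concentrations, mol m^-3 (>= 0).
#' @return an object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(electrode_potential, bulk_h2 = 0.78,
                                bulk_o2 = 0) {
  if (inherits(electrode_potential, "potential_value")) {
    if (electrode_potential$scale != "SHE")
      electrode_potential <- convert_reference(electrode_potential, "SHE")
    electrode_potential <- electrode_potential$value
  }
  if (!is.finite(electrode_potential))
    stop("'electrode_potential' must be finite (volts vs SHE)", call. = FALSE)
  if (bulk_h2 < 0 || bulk_o2 < 0)
    stop("bulk concentrations must be >= 0", call. = FALSE)
  structure(list(electrode_potential = electrode_potential,
                 bulk_h2 = bulk_h2, bulk_o2 = bulk_o2),
            class = "boundary_conditions")
}

#' Named default parameter sets for the studied mediator/pH conditions
#'
#' Returns the package default [film_parameters] with the mediator standard
#' potential and pH of the named condition: DV1 (4,4'-viologen dendrimer,
#' E0 = -0.22 V vs SHE), DV2 (2,2'-viologen dendrimer, E0 = -0.40 V) or
#' PV2 (2,2'-viologen polymer, E0 = -0.431 V), each at pH 6, 7 or 8.8.
#'
#' @param profile_name one of `"DV1_pH7"`, `"DV2_pH7"`, `"DV2_pH6"`,
#'   `"DV2_pH8.8"`, `"DV1_pH6"`, `"DV1_pH8.8"`, `"PV2_pH7"`.
#' @param ... overrides passed on to [film_parameters()].
#' @return a [film_parameters] object.
#' @examples
#' default_parameter_set("DV2_pH7")
#' @export
default_parameter_set <- function(profile_name, ...) {
  known <- list(
    DV1_pH6     = list(e0 = -0.22,  pH = 6,   label = "DV1"),
    DV1_pH7     = list(e0 = -0.22,  pH = 7,   label = "DV1"),
    `DV1_pH8.8` = list(e0 = -0.22,  pH = 8.8, label = "DV1"),
    DV2_pH6     = list(e0 = -0.40,  pH = 6,   label = "DV2"),
    DV2_pH7     = list(e0 = -0.40,  pH = 7,   label = "DV2"),
    `DV2_pH8.8` = list(e0 = -0.40,  pH = 8.8, label = "DV2"),
    PV2_pH7     = list(e0 = -0.431, pH = 7,   label = "PV2"))
  if (!profile_name %in% names(known))
    stop("unknown parameter profile '", profile_name, "'; known profiles: ",
         paste(names(known), collapse = ", "), call. = FALSE)
  cond <- known[[profile_name]]
  film_parameters(mediator = redox_couple(cond$e0, label = cond$label),
                  pH = cond$pH, ...)
}
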
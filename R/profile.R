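# Species profiles on the normalized film coordinate and the quantities
# derived from them: Nernst-potential profile, electrode current, and the
# position of the inactive-enzyme front.

#' Construct a species profile
#'
#' Concentration profiles of the film species on the normalized coordinate
#' xi (0 at the electrode, 1 at the film/solution interface), stored as a
#' data frame with one row per grid node.  `v_ox` and `e_inactive` are
#' derived from the conservation relations
#' `v_ox + v_red = v_total` and `e_active + e_inactive + e_dead = e_total`.
#'
#' @param xi grid positions in `[0, 1]`, strictly increasing.
#' @param v_red,h2,o2,e_active,e_dead concentrations per node, mol m^-3.
#' @param params the [film_parameters] the profile belongs to.
#' @return a data frame of class `species_profile` with columns `xi`,
#'   `v_ox`, `v_red`, `h2`, `o2`, `e_active`, `e_inactive`, `e_dead`, `e_v`
#'   (mediator Nernst potential, volts vs SHE; `NA` where undefined).
#' @export
species_profile <- function(xi, v_red, h2, o2, e_active, e_dead, params) {
  n <- length(xi)
  stopifnot(n >= 3, all(diff(xi) > 0),
            length(v_red) == n, length(h2) == n, length(o2) == n,
            length(e_active) == n, length(e_dead) == n)
  v_ox <- params$v_total - v_red
  e_inactive <- params$e_total - e_active - e_dead
  prof <- data.frame(xi = xi, v_ox = v_ox, v_red = v_red, h2 = h2, o2 = o2,
                     e_active = e_active, e_inactive = e_inactive,
                     e_dead = e_dead)
  prof$e_v <- nernst_profile(prof, params$mediator, params$temperature)
  attr(prof, "params") <- params
  class(prof) <- c("species_profile", "data.frame")
  prof
}

#' Mediator Nernst potential profile
#'
#' E_V(xi) = E0 + (RT/F) ln(V_ox/V_red) per node, volts vs SHE.  Nodes that
#' are fully oxidized or fully reduced (non-positive V_red or V_ox) have an
#' undefined potential and are returned as `NA` rather than raising an
#' error.
#'
#' @param profile a [species_profile] (or any data frame with `v_ox` and
#'   `v_red` columns).
#' @param mediator a [redox_couple].
#' @param temperature kelvin.
#' @return numeric vector of potentials vs SHE, `NA` where undefined.
#' @export
nernst_profile <- function(profile, mediator, temperature = 298.15) {
  ratio <- profile$v_ox / profile$v_red
  ok <- is.finite(ratio) & profile$v_ox > 0 & profile$v_red > 0
  e_v <- rep(NA_real_, length(ratio))
  e_v[ok] <- mediator$e0 + .RGAS * temperature /
    (mediator$n_electrons * .FARADAY) * log(ratio[ok])
  e_v
}

#' Catalytic current density from a species profile
#'
#' The current is the electron flux carried by the mediator into the
#' electrode, evaluated from the reduced-mediator gradient at xi = 0 by a
#' second-order one-sided finite difference:
#' \deqn{j = F D_e \left.\partial V_{red}/\partial x\right|_{x=0}}
#' Positive current = H2 oxidation (electrons delivered to the electrode).
#'
#' @param profile a [species_profile] on a uniform grid with >= 3 nodes.
#' @param params a [film_parameters] (defaults to the profile's own).
#' @return current density in A m^-2 (scalar).
#' @export
current_from_profile <- function(profile, params = attr(profile, "params")) {
  n <- nrow(profile)
  if (is.null(n) || n < 3)
    stop("profile grid too coarse: need at least 3 nodes", call. = FALSE)
  h <- profile$xi[2] - profile$xi[1]
  v <- profile$v_red
  dvdx <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * h) / params$thickness
  .FARADAY * params$d_e * dvdx
}

#' Position of the inactive-enzyme front
#'
#' Scans the profile from the film/solution interface (xi = 1) inward and
#' returns the xi where the inactive-enzyme concentration first drops to
#' half the total enzyme loading, linearly interpolated between nodes.
#' Returns `NA` when no front has formed (outermost node still mostly
#' active) and `0` when the whole film is inactivated.
#'
#' @param profile a [species_profile].
#' @param params a [film_parameters] (defaults to the profile's own).
#' @return front position xi in `[0, 1]`, or `NA`.
#' @export
front_position <- function(profile, params = attr(profile, "params")) {
  half <- params$e_total / 2
  e_i <- profile$e_inactive
  n <- length(e_i)
  if (e_i[n] <= half) return(NA_real_)
  j <- n
  while (j > 1 && e_i[j - 1] > half) j <- j - 1
  if (j == 1) return(0)
  # crossing between node j-1 (<= half) and node j (> half)
  x0 <- profile$xi[j - 1]; x1 <- profile$xi[j]
  y0 <- e_i[j - 1]; y1 <- e_i[j]
  x0 + (half - y0) / (y1 - y0) * (x1 - x0)
}

#' Reaction-layer statistics of a steady-state profile
#'
#' Locates the catalytic reaction layer — the nodes where the absolute
#' enzymatic rate exceeds half its maximum — and summarizes the Nernst
#' potential the enzyme experiences there, together with the inactive
#' enzyme accumulated between the electrode and the layer's outer edge
#' (the film region that an oxidizing electrode potential can inactivate).
#'
#' @param profile a [species_profile] (typically from [solve_steady_state()]).
#' @param params a [film_parameters] (defaults to the profile's own).
#' @return a list with `xi_inner`, `xi_outer` (layer bounds), `e_v_max`,
#'   `e_v_median` (volts vs SHE over the layer), `inactive_fraction`
#'   (median e_inactive / e_total over `xi <= xi_outer`) and `rate_max`
#'   (mol m^-3 s^-1).
#' @export
reaction_layer_stats <- function(profile, params = attr(profile, "params")) {
  rate <- abs(enzyme_net_rate(profile$v_ox, profile$v_red, profile$h2,
                              params, e_active = profile$e_active))
  lay <- which(rate > max(rate) / 2)
  xi_outer <- profile$xi[max(lay)]
  reg <- profile$xi <= xi_outer
  list(xi_inner = profile$xi[min(lay)], xi_outer = xi_outer,
       e_v_max = max(profile$e_v[lay], na.rm = TRUE),
       e_v_median = stats::median(profile$e_v[lay], na.rm = TRUE),
       inactive_fraction = stats::median(profile$e_inactive[reg]) /
         params$e_total,
       rate_max = max(rate))
}

#' @export
print.species_profile <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Species profile on %d nodes (mediator %s, pH %.1f)\n",
              nrow(x), p$mediator$label, p$pH))
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  cat("...\n")
  invisible(x)
}
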
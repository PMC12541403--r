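# Shared helpers: trace diagnostics and small reference quantities used
# across the film-model tests.

FARADAY <- 96485.33212
RGAS <- 8.314462618

# potential where the forward scan of a CV crosses from negative to
# positive current (linear interpolation)
zero_crossing <- function(trace) {
  d <- diff(trace$potential)
  fwd <- c(d[1], d) > 0
  i <- which(fwd[-1] & trace$current[-nrow(trace)] <= 0 &
               trace$current[-1] > 0)[1]
  stats::approx(trace$current[c(i, i + 1)], trace$potential[c(i, i + 1)],
                xout = 0)$y
}

# ratio of the forward-scan current at the positive vertex to the forward
# maximum (the anaerobic-inactivation fall-off readout)
vertex_over_max <- function(trace) {
  d <- diff(trace$potential)
  fwd <- c(d[1], d) > 0
  trace$current[max(which(fwd))] / max(trace$current[fwd])
}

# trapezoid integral of the enzymatic rate over the film, as electron flux
integrated_rate_current <- function(profile, params) {
  rate <- enzyme_net_rate(profile$v_ox, profile$v_red, profile$h2, params,
                          e_active = profile$e_active)
  n <- nrow(profile)
  2 * FARADAY * sum((rate[-1] + rate[-n]) / 2) / (n - 1) * params$thickness
}

e_eq_she <- function(pH) -0.06 * pH
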
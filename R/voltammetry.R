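# CV and CA simulation on the film model, and the trace analyses: mediator
# midpoint-potential extraction, normalization by the maximal positive
# current, and catalytic-plateau detection.

#' Triangular potential program
#'
#' @param e_start start (and end) potential, V vs SHE.
#' @param e_vertex vertex potential, V vs SHE.
#' @param scan_rate sweep rate, V s^-1 (> 0).
#' @param cycles number of full cycles.
#' @return a list with `E_of_t` (function of time), `t_end`, and `vertices`
#'   (vertex and cycle-end times).
#' @export
cv_program <- function(e_start, e_vertex, scan_rate, cycles = 1L) {
  if (scan_rate <= 0) stop("'scan_rate' must be > 0", call. = FALSE)
  span <- abs(e_vertex - e_start)
  if (span <= 0) stop("'e_vertex' must differ from 'e_start'", call. = FALSE)
  half <- span / scan_rate
  dir <- sign(e_vertex - e_start)
  E_of_t <- function(t) {
    phase <- t %% (2 * half)
    if (phase <= half) e_start + dir * scan_rate * phase
    else e_vertex - dir * scan_rate * (phase - half)
  }
  list(E_of_t = E_of_t, t_end = 2 * half * cycles,
       vertices = sort(c(half + 2 * half * (0:(cycles - 1)),
                         2 * half * seq_len(cycles))))
}

#' Simulate a cyclic voltammogram of the enzyme film
#'
#' Drives the transient film solver with a triangular electrode-potential
#' program, starting from the anaerobic steady state at `e_start`.
#'
#' @param params a [film_parameters].
#' @param e_start,e_vertex scan limits, V vs SHE.
#' @param scan_rate sweep rate, V s^-1 (default 0.01, i.e. 10 mV/s).
#' @param cycles number of cycles.
#' @param bc a [boundary_conditions] giving the gas feed (the electrode
#'   potential field is ignored; defaults to H2-saturated, anaerobic).
#' @param n_grid,rtol,points_per_sweep solver controls.
#' @return an [ec_trace] of kind `"CV"`.
#' @export
simulate_cv <- function(params, e_start, e_vertex, scan_rate = 0.01,
                        cycles = 1L,
                        bc = boundary_conditions(e_start, bulk_h2 = 0.78,
                                                 bulk_o2 = 0),
                        n_grid = 200, rtol = 1e-8,
                        points_per_sweep = 250) {
  prog <- cv_program(e_start, e_vertex, scan_rate, cycles)
  half <- abs(e_vertex - e_start) / scan_rate
  sol <- solve_transient(params, bc, t_end = prog$t_end,
                         potential_program = prog$E_of_t,
                         n_grid = n_grid, rtol = rtol,
                         n_out = 2 * points_per_sweep * cycles,
                         extra_times = prog$vertices,
                         hmax = half / 50)
  ec_trace(sol$current$time, sol$current$potential, sol$current$current,
           kind = "CV", pH = params$pH, temperature = params$temperature,
           scan_rate = scan_rate,
           gas_feed = sprintf("H2 %g / O2 %g mol m^-3", bc$bulk_h2,
                              bc$bulk_o2))
}

#' Simulate a chronoamperometry (potential-step) experiment
#'
#' Applies a sequence of constant potentials to the film, each held for the
#' stated duration, starting from the anaerobic steady state at the first
#' potential.
#'
#' @param params a [film_parameters].
#' @param steps a data frame (or list coercible to one) with columns `E`
#'   (V vs SHE) and `duration` (s, > 0).
#' @param bc gas-feed boundary conditions (defaults to H2-saturated,
#'   anaerobic).
#' @param n_grid,rtol,points_per_step solver controls.
#' @param init optional initial [species_profile].
#' @return an [ec_trace] of kind `"CA"`.
#' @export
simulate_ca <- function(params, steps,
                        bc = boundary_conditions(0, bulk_h2 = 0.78,
                                                 bulk_o2 = 0),
                        n_grid = 200, rtol = 1e-8, points_per_step = 100,
                        init = NULL) {
  steps <- as.data.frame(steps)
  if (!all(c("E", "duration") %in% names(steps)) || nrow(steps) < 1)
    stop("'steps' needs columns E and duration", call. = FALSE)
  if (any(steps$duration <= 0))
    stop("step durations must be > 0", call. = FALSE)

  t0 <- 0
  times <- pot <- cur <- numeric(0)
  prof <- init
  for (k in seq_len(nrow(steps))) {
    bck <- boundary_conditions(steps$E[k], bulk_h2 = bc$bulk_h2,
                               bulk_o2 = bc$bulk_o2)
    if (is.null(prof) && k == 1) {
      bc0 <- boundary_conditions(steps$E[1], bulk_h2 = bc$bulk_h2,
                                 bulk_o2 = 0)
      prof <- solve_steady_state(params, bc0, n_grid = n_grid)$profile
    }
    sol <- solve_transient(params, bck, t_end = steps$duration[k],
                           init = prof, n_grid = n_grid, rtol = rtol,
                           n_out = points_per_step)
    keep <- if (k == 1) TRUE else sol$current$time > 0
    times <- c(times, t0 + sol$current$time[keep])
    pot <- c(pot, sol$current$potential[keep])
    cur <- c(cur, sol$current$current[keep])
    prof <- sol$final
    t0 <- t0 + steps$duration[k]
  }
  ec_trace(times, pot, cur, kind = "CA", pH = params$pH,
           temperature = params$temperature,
           gas_feed = sprintf("H2 %g / O2 %g mol m^-3", bc$bulk_h2,
                              bc$bulk_o2))
}

# Smoothed current and sweep-direction index for peak picking.
.smooth_current <- function(trace, window = 11, order = 2) {
  i <- trace$current
  n <- length(i)
  w <- min(window, if (n %% 2 == 1) n else n - 1)
  if (w %% 2 == 0) w <- w - 1
  if (w <= order + 1) return(i)
  signal::sgolayfilt(i, p = order, n = w)
}

#' Extract the mediator midpoint potential from a non-catalytic CV
#'
#' Detects the anodic peak (current maximum on the positive-going sweep)
#' and the cathodic peak (current minimum on the negative-going sweep)
#' after Savitzky-Golay smoothing, and returns the midpoint
#' (E_pa + E_pc) / 2.  When several local extrema tie, the one nearest the
#' middle of the scanned potential range wins.  Peak positions are
#' invariant to scaling of the current, so normalized traces work
#' unchanged.
#'
#' @param trace an [ec_trace] holding a mediator-only CV with at least one
#'   peak per sweep direction.
#' @param sg_window,sg_order Savitzky-Golay smoothing window (points, odd)
#'   and polynomial order.
#' @return midpoint potential in volts vs SHE (scalar).
#' @export
extract_mediator_e0 <- function(trace, sg_window = 11, sg_order = 2) {
  if (!inherits(trace, "ec_trace")) stop("'trace' must be an ec_trace",
                                         call. = FALSE)
  sm <- .smooth_current(trace, sg_window, sg_order)
  dE <- diff(trace$potential)
  dir <- c(dE[1], dE)  # sweep direction per sample
  mid <- (max(trace$potential) + min(trace$potential)) / 2

  pick <- function(subset, decreasing) {
    idx <- which(subset)
    if (length(idx) < 3)
      stop("peak extraction failed: sweep direction missing", call. = FALSE)
    y <- if (decreasing) sm[idx] else -sm[idx]
    # local maxima of y strictly inside the segment
    loc <- idx[which(diff(sign(diff(y))) < 0) + 1]
    if (length(loc) == 0)
      stop("peak extraction failed: no interior peak found", call. = FALSE)
    best <- loc[order(-(if (decreasing) sm[loc] else -sm[loc]),
                      abs(trace$potential[loc] - mid))][1]
    trace$potential[best]
  }
  e_pa <- pick(dir > 0, decreasing = TRUE)    # anodic: max on forward sweep
  e_pc <- pick(dir < 0, decreasing = FALSE)   # cathodic: min on reverse
  (e_pa + e_pc) / 2
}

#' Normalize a trace by its maximal positive current
#'
#' Divides all currents by the maximum positive current, so the output
#' maximum is exactly 1; zero crossings and signs are preserved.  Applying
#' the operation twice equals applying it once.
#'
#' @param trace an [ec_trace] with at least one positive current sample.
#' @return the normalized [ec_trace] (normalization flag set).
#' @export
normalize_by_max_positive <- function(trace) {
  imax <- max(trace$current)
  if (!is.finite(imax) || imax <= 0)
    stop("trace has no positive current to normalize by", call. = FALSE)
  trace$current <- trace$current / imax
  attr(trace, "normalized") <- TRUE
  trace
}

#' Catalytic plateau current over a potential window
#'
#' Median forward-scan current over the potential window, with its relative
#' spread (max minus min over the absolute median).  A plateau is asserted
#' when the spread is below `spread_tol` (5% by default).  For CA traces
#' all samples in the window are used.
#'
#' @param trace an [ec_trace].
#' @param window length-2 potential window (V vs SHE), e.g.
#'   `c(-0.3, 0.2)`.
#' @param spread_tol relative spread below which the segment counts as a
#'   plateau.
#' @return a list with `current` (median), `spread` (relative) and
#'   `plateau` (logical).
#' @export
plateau_current <- function(trace, window = c(-0.3, 0.2),
                            spread_tol = 0.05) {
  if (length(window) != 2 || window[1] >= window[2])
    stop("'window' must be an increasing potential pair", call. = FALSE)
  dE <- diff(trace$potential)
  forward <- if (attr(trace, "kind") == "CV") c(dE[1], dE) > 0
             else rep(TRUE, nrow(trace))
  sel <- forward & trace$potential >= window[1] &
    trace$potential <= window[2]
  if (!any(sel))
    stop("no forward-scan samples inside the potential window", call. = FALSE)
  i <- trace$current[sel]
  med <- stats::median(i)
  spread <- if (med == 0) Inf else (max(i) - min(i)) / abs(med)
  list(current = med, spread = spread, plateau = spread < spread_tol)
}
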
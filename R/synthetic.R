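# Seeded synthetic-trace generators: mediator-only CVs, a closed-form
# catalytic CV/CA surrogate (so analysis functions can be exercised without
# the PDE solver), and exposure series.  Identical arguments + seed give
# identical output; the global RNG state is left untouched.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Triangular potential series sampled every `dE` volts.
.triangle_wave <- function(e_start, e_vertex, scan_rate, dE = 5e-4) {
  span <- abs(e_vertex - e_start)
  m <- max(2L, round(span / dE))
  fwd <- seq(e_start, e_vertex, length.out = m + 1)
  pot <- c(fwd, rev(fwd)[-1])
  time <- (seq_along(pot) - 1) * (span / m) / scan_rate
  list(time = time, potential = pot,
       forward = c(rep(TRUE, m + 1), rep(FALSE, m)))
}

#' Generate a synthetic mediator-only CV
#'
#' Ideal one-electron surface-confined Nernstian wave centered on the true
#' midpoint potential: the anodic and cathodic peaks coincide at `e0`
#' (zero peak separation) in the noiseless case.  A qualitative
#' diffusion-tailed variant multiplies the post-peak branch by a slow
#' square-root decay.  Gaussian noise of standard deviation
#' `noise_sd * peak_current` is added when requested.
#'
#' @param e0 true midpoint potential, V vs SHE.
#' @param e_start,e_vertex scan limits, V vs SHE (must bracket `e0`).
#' @param scan_rate sweep rate, V s^-1.
#' @param peak_current peak current scale (arbitrary units).
#' @param noise_sd noise standard deviation as a fraction of
#'   `peak_current` (>= 0).
#' @param seed integer seed; identical seed + arguments give identical
#'   traces.
#' @param shape `"surface"` (ideal thin-film wave) or `"diffusion"`
#'   (tailed variant).
#' @param temperature kelvin.
#' @param pH metadata for the trace.
#' @param dE potential sampling step, V.
#' @return an [ec_trace] of kind `"CV"`.
#' @export
generate_mediator_cv <- function(e0, e_start = e0 - 0.25,
                                 e_vertex = e0 + 0.25, scan_rate = 0.01,
                                 peak_current = 1, noise_sd = 0,
                                 seed = NULL,
                                 shape = c("surface", "diffusion"),
                                 temperature = 298.15, pH = 7,
                                 dE = 5e-4) {
  shape <- match.arg(shape)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  tw <- .triangle_wave(e_start, e_vertex, scan_rate, dE)
  f <- .FARADAY / (.RGAS * temperature)
  u <- exp(f * (tw$potential - e0))
  wave <- 4 * u / (1 + u)^2            # 1 at E = e0
  shape_val <- wave
  if (shape == "diffusion") {
    # past-peak branch decays as a slow square root instead of the
    # symmetric Nernstian fall-off (qualitative diffusion tail)
    w <- 1 / f
    past <- ifelse(tw$forward, pmax(tw$potential - e0, 0),
                   pmax(e0 - tw$potential, 0))
    shape_val <- pmax(wave, 0.35 * sqrt(w / (w + past)) * (past > 0))
  }
  cur <- ifelse(tw$forward, 1, -1) * peak_current * shape_val
  if (noise_sd > 0)
    cur <- cur + .with_seed(seed, stats::rnorm(length(cur),
                                               sd = noise_sd * peak_current))
  ec_trace(tw$time, tw$potential, cur, kind = "CV", pH = pH,
           temperature = temperature, scan_rate = scan_rate,
           gas_feed = "N2")
}

#' Closed-form catalytic CV surrogate
#'
#' Fast sigmoid stand-in for a mediated catalytic voltammogram: zero
#' current exactly at the H+/H2 equilibrium potential, an H2-oxidation
#' plateau `i_ox` at high potential and an H2-evolution plateau `-i_red`
#' at low potential, with a mediator-limited exponential foot of width `w`.
#' An optional high-potential inactivation fall-off multiplies the current
#' by `1 - fall_depth / (1 + exp(-(E - e_fall)/w_fall))`.
#'
#' @param pH solution pH (fixes the zero-crossing potential).
#' @param i_ox,i_red oxidation/evolution plateau magnitudes (> 0).
#' @param w foot width, V.
#' @param e_start,e_vertex,scan_rate scan program.
#' @param fall_depth inactivation fall-off depth in `[0, 1]` (0 disables).
#' @param e_fall,w_fall fall-off midpoint (V vs SHE) and width (V).
#' @param noise_sd Gaussian noise sd as a fraction of `i_ox`.
#' @param seed integer seed.
#' @param slope Nernstian pH slope for the equilibrium potential.
#' @return an [ec_trace] of kind `"CV"`.
#' @export
generate_catalytic_cv <- function(pH = 7, i_ox = 1, i_red = 1, w = 0.02,
                                  e_start = -0.65, e_vertex = 0.25,
                                  scan_rate = 0.01, fall_depth = 0,
                                  e_fall = -0.1, w_fall = 0.05,
                                  noise_sd = 0, seed = NULL,
                                  slope = nernst_slope()) {
  stopifnot(i_ox > 0, i_red > 0, w > 0, fall_depth >= 0, fall_depth <= 1)
  e_eq <- -slope * pH
  tw <- .triangle_wave(e_start, e_vertex, scan_rate)
  A <- i_ox + i_red
  cc <- i_red / A
  e_half <- e_eq + w * log(i_ox / i_red)
  cur <- A * (1 / (1 + exp(-(tw$potential - e_half) / w)) - cc)
  if (fall_depth > 0)
    cur <- cur * (1 - fall_depth / (1 + exp(-(tw$potential - e_fall) / w_fall)))
  if (noise_sd > 0)
    cur <- cur + .with_seed(seed, stats::rnorm(length(cur),
                                               sd = noise_sd * i_ox))
  ec_trace(tw$time, tw$potential, cur, kind = "CV", pH = pH,
           scan_rate = scan_rate, gas_feed = "H2")
}

#' Closed-form catalytic CA surrogate
#'
#' Potential-step response built from the same sigmoid current-potential
#' relation as [generate_catalytic_cv()], with first-order settling of time
#' constant `tau` after each step.
#'
#' @param steps data frame with columns `E` (V vs SHE) and `duration` (s).
#' @param pH solution pH.
#' @param i_ox,i_red,w sigmoid parameters (see [generate_catalytic_cv()]).
#' @param tau settling time constant, s.
#' @param dt sampling interval, s.
#' @param noise_sd Gaussian noise sd as a fraction of `i_ox`.
#' @param seed integer seed.
#' @param slope Nernstian pH slope.
#' @return an [ec_trace] of kind `"CA"`.
#' @export
generate_catalytic_ca <- function(steps, pH = 7, i_ox = 1, i_red = 1,
                                  w = 0.02, tau = 1, dt = 0.5,
                                  noise_sd = 0, seed = NULL,
                                  slope = nernst_slope()) {
  steps <- as.data.frame(steps)
  e_eq <- -slope * pH
  A <- i_ox + i_red
  cc <- i_red / A
  e_half <- e_eq + w * log(i_ox / i_red)
  i_of_E <- function(E) A * (1 / (1 + exp(-(E - e_half) / w)) - cc)
  time <- pot <- cur <- numeric(0)
  t0 <- 0; i_prev <- 0
  for (k in seq_len(nrow(steps))) {
    tt <- seq(0, steps$duration[k], by = dt)
    tgt <- i_of_E(steps$E[k])
    ii <- tgt + (i_prev - tgt) * exp(-tt / tau)
    time <- c(time, t0 + tt + ifelse(k == 1, 0, dt / 1e3))
    pot <- c(pot, rep(steps$E[k], length(tt)))
    cur <- c(cur, ii)
    i_prev <- ii[length(ii)]
    t0 <- t0 + steps$duration[k] + dt / 1e3
  }
  if (noise_sd > 0)
    cur <- cur + .with_seed(seed, stats::rnorm(length(cur),
                                               sd = noise_sd * i_ox))
  ec_trace(time, pot, cur, kind = "CA", pH = pH, gas_feed = "H2")
}

#' Generate a synthetic exposure series
#'
#' Geometric decay with per-cycle loss `r` and multiplicative Gaussian
#' noise: `activity[k] = (1 - r)^k * (1 + eps_k)`,
#' `eps_k ~ N(0, noise_sd^2)`; the cycle-0 value is forced to 1.
#'
#' @param r per-cycle loss fraction in `[0, 1]`.
#' @param n number of exposure cycles (series has `n + 1` entries).
#' @param noise_sd multiplicative noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param exposure_duration hours per cycle (metadata).
#' @return an [exposure_series].
#' @examples
#' generate_exposure_series(0.2, 4)$activity  # 1 0.8 0.64 0.512 0.4096
#' @export
generate_exposure_series <- function(r, n, noise_sd = 0, seed = NULL,
                                     exposure_duration = 1) {
  if (r < 0 || r > 1) stop("'r' must lie in [0, 1]", call. = FALSE)
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  k <- 0:n
  act <- (1 - r)^k
  if (noise_sd > 0) {
    eps <- .with_seed(seed, stats::rnorm(n + 1, sd = noise_sd))
    act <- act * (1 + eps)
  }
  act[1] <- 1
  act <- pmax(act, 0)
  exposure_series(act, cycle = k, normalize = FALSE,
                  exposure_duration = exposure_duration,
                  label = sprintf("synthetic r=%g", r))
}
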
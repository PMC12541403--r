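# Steady-state and transient solvers for the 1D reaction-diffusion film
# model.
#
# Unknowns live on a uniform grid xi in [0,1] (xi = x/L).  The mediator is
# confined to the film: Nernstian (Dirichlet) boundary at the electrode,
# zero flux at the film/solution interface.  H2 and O2 have zero flux at
# the electrode and partition-scaled bulk (Dirichlet) values at the
# interface.  Conservation (V_ox + V_red = V_total; active + inactive +
# dead enzyme = E_total) is built in: only V_red, H2, O2, E_active and
# E_dead are integrated, the partners are derived.

.EXP_CAP <- 5   # soft cap on alpha*(E_V - E_inact)/2: rate constants saturate
                # about 150-fold above/below k_x far from E_inact

.grid <- function(n) {
  if (n < 50) stop("grid size must be >= 50", call. = FALSE)
  list(n = n, xi = seq(0, 1, length.out = n), h = 1 / (n - 1))
}

# Reduced-mediator concentration in Nernst equilibrium with a given local
# H2 concentration (the outer-film plateau value).
.equilibrium_v_red <- function(params, h2) {
  if (h2 <= 0) return(0)
  ratio <- sqrt(.k_inv(params) * params$h2_sat / h2)  # V_ox / V_red
  params$v_total / (1 + ratio)
}

#' Mediator pool in equilibrium with H2
#'
#' Reduced-mediator concentration when the film has equilibrated with a
#' given H2 concentration, i.e. when the mediator Nernst potential equals
#' the local H+/H2 couple potential.  This is the reducing capacity per
#' volume that an incoming O2 front must consume.
#'
#' @param params a [film_parameters].
#' @param h2 local H2 concentration, mol m^-3.
#' @return reduced-mediator concentration, mol m^-3.
#' @export
equilibrium_v_red <- function(params, h2 = params$h2_sat) {
  .equilibrium_v_red(params, h2)
}

# Clamped inactivation rate pair (vectorized over e_v, in volts vs SHE).
.rate_pair <- function(e_v, params) {
  m <- params$inactivation
  de <- e_v - e_inact_she(m, params$pH, params$slope)
  z <- .EXP_CAP * tanh(m$alpha * de / (2 * .EXP_CAP))
  list(k_i = m$k_x * exp(z), k_a = m$k_x * exp(-z))
}

# Nernst potential with clamped ratio (never NA; used inside solvers).
# The clamp floor is physical (1e-6 of the pool, i.e. E0 +/- ~0.35 V, well
# into the saturated range of the inactivation rate pair) so that the log
# does not amplify integrator-level noise in nearly exhausted pools.
.e_v_clamped <- function(v_red, params) {
  eps <- 1e-6 * params$v_total
  vr <- pmin(pmax(v_red, eps), params$v_total - eps)
  params$mediator$e0 + .RGAS * params$temperature /
    (params$mediator$n_electrons * .FARADAY) * log((params$v_total - vr) / vr)
}

# Boundary targets: v_red at the electrode node for a given potential, and
# substrate concentrations at the film/solution interface.
.bc_targets <- function(params, bc, E = bc$electrode_potential) {
  ratio <- electrode_boundary_ratio(E, params$mediator, params$temperature)
  list(v_red = params$v_total / (1 + ratio),
       h2 = params$part_h2 * bc$bulk_h2,
       o2 = params$part_o2 * bc$bulk_o2)
}

# ---------------------------------------------------------------------------
# Transient solver (method of lines, deSolve)

# RHS for deSolve::ode.1D; y = [v_red | h2 | o2 | e_active | e_dead],
# each block of length n.  `E_of_t` maps time to electrode potential.
.make_rhs <- function(params, bc, g, E_of_t) {
  n <- g$n
  L <- params$thickness
  fac_e <- params$d_e / (L * g$h)^2
  fac_h <- params$d_h2 / (L * g$h)^2
  fac_o <- params$d_o2 / (L * g$h)^2
  i_v <- 1:n; i_h <- n + 1:n; i_o <- 2 * n + 1:n
  i_ea <- 3 * n + 1:n; i_ed <- 4 * n + 1:n
  m <- params$inactivation

  function(t, y, parms) {
    tg <- .bc_targets(params, bc, E_of_t(t))
    vr <- pmin(pmax(y[i_v], 0), params$v_total)
    h2 <- pmax(y[i_h], 0)
    o2 <- pmax(y[i_o], 0)
    ea <- pmin(pmax(y[i_ea], 0), params$e_total)
    ed <- pmin(pmax(y[i_ed], 0), params$e_total)
    vr[1] <- tg$v_red; h2[n] <- tg$h2; o2[n] <- tg$o2

    rate <- enzyme_net_rate(params$v_total - vr, vr, h2, params, e_active = ea)
    scav <- params$k_o2_v * vr * o2
    e_v <- .e_v_clamped(vr, params)
    kp <- .rate_pair(e_v, params)
    e_i <- pmax(params$e_total - ea - ed, 0)

    dv <- dh <- dox <- numeric(n)
    mid <- 2:(n - 1)
    dv[mid] <- fac_e * (vr[mid - 1] - 2 * vr[mid] + vr[mid + 1])
    dh[mid] <- fac_h * (h2[mid - 1] - 2 * h2[mid] + h2[mid + 1])
    dox[mid] <- fac_o * (o2[mid - 1] - 2 * o2[mid] + o2[mid + 1])
    dv[n] <- fac_e * 2 * (vr[n - 1] - vr[n])
    dh[1] <- fac_h * 2 * (h2[2] - h2[1])
    dox[1] <- fac_o * 2 * (o2[2] - o2[1])

    src_v <- 2 * rate - params$s_o2 * scav
    dv <- dv + src_v
    dh <- dh - rate
    dox <- dox - scav
    # pinned boundary nodes: their exact target values are substituted in
    # the flux computations above (and when profiles are assembled), so the
    # stored states are frozen rather than relaxed through a stiff penalty
    dv[1] <- 0
    dh[n] <- 0
    dox[n] <- 0

    o2_hit <- m$k_inact_o2 * o2 * ea
    dea <- -kp$k_i * ea + kp$k_a * e_i - o2_hit
    ded <- m$phi_irr * o2_hit
    list(c(dv, dh, dox, dea, ded))
  }
}

.profile_from_state <- function(y, g, params, bc, E) {
  n <- g$n
  tg <- .bc_targets(params, bc, E)
  v_red <- y[1:n]; v_red[1] <- tg$v_red
  h2 <- y[n + 1:n]; h2[n] <- tg$h2
  o2 <- y[2 * n + 1:n]; o2[n] <- tg$o2
  species_profile(g$xi, v_red = pmin(pmax(v_red, 0), params$v_total),
                  h2 = pmax(h2, 0), o2 = pmax(o2, 0),
                  e_active = pmin(pmax(y[3 * n + 1:n], 0), params$e_total),
                  e_dead = pmin(pmax(y[4 * n + 1:n], 0), params$e_total),
                  params = params)
}

.state_from_profile <- function(profile) {
  c(profile$v_red, profile$h2, profile$o2, profile$e_active, profile$e_dead)
}

.default_atol <- function(params, bc, n) {
  h2_sc <- max(params$h2_sat, bc$bulk_h2, 1e-3)
  o2_sc <- max(bc$bulk_o2, 1e-3)
  rep(c(1e-12 * params$v_total, 1e-12 * h2_sc, 1e-12 * o2_sc,
        1e-12 * params$e_total, 1e-12 * params$e_total), each = n)
}

#' Transient solution of the film model
#'
#' Method-of-lines integration of the coupled mediator/H2/O2/enzyme
#' equations with a stiff implicit integrator ([deSolve::ode.1D]).  The
#' initial condition defaults to the anaerobic steady state at the initial
#' electrode potential, which makes O2-exposure experiments (anaerobic
#' steady state, then O2 switched on through `bc$bulk_o2`) a one-liner.
#'
#' @param params a [film_parameters].
#' @param bc a [boundary_conditions]; `bc$electrode_potential` is used
#'   whenever `potential_program` is `NULL`.
#' @param t_end end time, s.
#' @param snapshots times (s) at which full species profiles are returned;
#'   honored exactly.
#' @param init optional initial [species_profile] (grid must match
#'   `n_grid`).
#' @param potential_program optional function of time returning the
#'   electrode potential in volts vs SHE (used for CV/CA programs).
#' @param n_grid number of grid nodes (>= 50).
#' @param rtol,atol integrator tolerances; `atol` defaults to 1e-12 in
#'   normalized concentration units, scaled per species.
#' @param n_out number of output times for the current trace.
#' @param extra_times additional times forced into the integrator's output
#'   mesh (e.g. the vertices of a triangular potential program) without
#'   producing snapshots.
#' @param hmax maximum integrator step, s (needed when the potential
#'   program has kinks the integrator must not step across).
#' @return a list with `times`, `current` (data frame `time`, `potential`,
#'   `current`), `snapshots` (named list of [species_profile]) and `final`
#'   (the profile at `t_end`).
#' @export
solve_transient <- function(params, bc, t_end, snapshots = NULL, init = NULL,
                            potential_program = NULL, n_grid = 200,
                            rtol = 1e-8, atol = NULL, n_out = 200,
                            extra_times = NULL, hmax = NULL) {
  g <- .grid(n_grid)
  E_of_t <- if (is.null(potential_program)) {
    function(t) bc$electrode_potential
  } else potential_program

  if (is.null(init)) {
    bc0 <- boundary_conditions(E_of_t(0), bulk_h2 = bc$bulk_h2, bulk_o2 = 0)
    init <- solve_steady_state(params, bc0, n_grid = n_grid)$profile
  }
  if (nrow(init) != g$n)
    stop("initial profile grid does not match 'n_grid'", call. = FALSE)
  y0 <- .state_from_profile(init)

  times <- sort(unique(c(seq(0, t_end, length.out = max(n_out, 2)),
                         snapshots, extra_times)))
  times <- times[times >= 0 & times <= t_end]
  if (any(times < 0 | times > t_end))
    stop("snapshot times must lie in [0, t_end]", call. = FALSE)
  if (is.null(atol)) atol <- .default_atol(params, bc, g$n)

  rhs <- .make_rhs(params, bc, g, E_of_t)
  run_block <- function(y, tt, rt) {
    args <- list(y = y, times = tt, func = rhs, parms = NULL,
                 nspec = 5, dimens = g$n, method = "lsode",
                 rtol = rt, atol = atol, maxsteps = 20000)
    if (!is.null(hmax)) args$hmax <- hmax
    suppressWarnings(do.call(deSolve::ode.1D, args))
  }
  # integrate with restarts: on a local corrector failure, resume from the
  # last reached output time with a relaxed tolerance for that stretch
  out <- matrix(NA_real_, length(times), length(y0) + 1)
  out[, 1] <- times
  out[1, -1] <- y0
  k <- 1L
  rt <- rtol
  fails <- 0L
  while (k < length(times)) {
    blk <- run_block(out[k, -1], times[k:length(times)], rt)
    got <- nrow(blk)
    if (got > 1)
      out[(k + 1):(k + got - 1), -1] <- blk[-1, -1, drop = FALSE]
    if (attr(blk, "istate")[1] >= 0) break
    fails <- fails + 1L
    if (got > 1) { k <- k + got - 1L; rt <- min(rt * 10, 1e-4) }
    else rt <- rt * 10
    if (fails > 8L || rt > 1e-3)
      stop("transient integration failed (istate = ",
           attr(blk, "istate")[1], ")", call. = FALSE)
  }

  pot <- vapply(times, E_of_t, numeric(1))
  cur <- vapply(seq_along(times), function(k) {
    prof <- .profile_from_state(out[k, -1], g, params, bc, pot[k])
    current_from_profile(prof, params)
  }, numeric(1))

  snaps <- list()
  for (ts in snapshots) {
    k <- which(times == ts)[1]
    snaps[[sprintf("t=%g", ts)]] <-
      .profile_from_state(out[k, -1], g, params, bc, pot[k])
  }
  final <- .profile_from_state(out[nrow(out), -1], g, params, bc,
                               pot[length(pot)])
  list(times = times,
       current = data.frame(time = times, potential = pot, current = cur),
       snapshots = snaps, final = final)
}

# ---------------------------------------------------------------------------
# Steady-state solver (damped Newton, grouped finite-difference Jacobian)

# Residuals of the discretized steady-state balances.  Unknowns
# u = [v_red | h2 | o2]; the enzyme pools are algebraic at steady state:
# e_active = E_tot k_a / (k_a + k_i + k_inact_o2 [O2]).
.make_steady <- function(params, bc, g) {
  n <- g$n
  L <- params$thickness
  fac_e <- params$d_e / (L * g$h)^2
  fac_h <- params$d_h2 / (L * g$h)^2
  fac_o <- params$d_o2 / (L * g$h)^2
  tg <- .bc_targets(params, bc)
  m <- params$inactivation
  i_v <- 1:n; i_h <- n + 1:n; i_o <- 2 * n + 1:n

  enzyme_active <- function(vr, o2) {
    e_v <- .e_v_clamped(vr, params)
    kp <- .rate_pair(e_v, params)
    params$e_total * kp$k_a / (kp$k_a + kp$k_i + m$k_inact_o2 * pmax(o2, 0))
  }

  resid <- function(u) {
    vr <- u[i_v]; h2 <- u[i_h]; o2 <- u[i_o]
    vr_r <- pmin(pmax(vr, 0), params$v_total)
    h2_r <- pmax(h2, 0); o2_r <- pmax(o2, 0)
    ea <- enzyme_active(vr_r, o2_r)
    rate <- enzyme_net_rate(params$v_total - vr_r, vr_r, h2_r, params,
                            e_active = ea)
    scav <- params$k_o2_v * vr_r * o2_r
    r_v <- r_h <- r_o <- numeric(n)
    mid <- 2:(n - 1)
    r_v[mid] <- fac_e * (vr[mid - 1] - 2 * vr[mid] + vr[mid + 1]) +
      2 * rate[mid] - params$s_o2 * scav[mid]
    r_v[n] <- fac_e * 2 * (vr[n - 1] - vr[n]) + 2 * rate[n] -
      params$s_o2 * scav[n]
    r_v[1] <- fac_e * (tg$v_red - vr[1])
    r_h[1] <- fac_h * 2 * (h2[2] - h2[1]) - rate[1]
    r_h[mid] <- fac_h * (h2[mid - 1] - 2 * h2[mid] + h2[mid + 1]) - rate[mid]
    r_h[n] <- fac_h * (tg$h2 - h2[n])
    r_o[1] <- fac_o * 2 * (o2[2] - o2[1]) - scav[1]
    r_o[mid] <- fac_o * (o2[mid - 1] - 2 * o2[mid] + o2[mid + 1]) - scav[mid]
    r_o[n] <- fac_o * (tg$o2 - o2[n])
    c(r_v, r_h, r_o)
  }

  h2_sc <- max(params$h2_sat, bc$bulk_h2, 1e-3)
  o2_sc <- max(bc$bulk_o2, 1e-3)
  scales <- rep(c(fac_e * params$v_total, fac_h * h2_sc, fac_o * o2_sc),
                each = n)
  dx <- rep(c(1e-7 * params$v_total, 1e-7 * h2_sc, 1e-7 * o2_sc), each = n)
  list(resid = resid, scales = scales, dx = dx, tg = tg,
       enzyme_active = enzyme_active, n = n)
}

# Sparsity pattern for the grouped finite-difference Jacobian: for a column
# (species s, node j) the nonzero rows are the same species at nodes
# j-1, j, j+1 plus the other two species at node j.
.jac_pattern <- function(n) {
  cols <- rows <- integer(0)
  for (s in 1:3) {
    for (j in 1:n) {
      col <- (s - 1) * n + j
      nb <- j + (-1:1); nb <- nb[nb >= 1 & nb <= n]
      r <- c((s - 1) * n + nb, (setdiff(1:3, s) - 1L) * n + j)
      rows <- c(rows, r); cols <- c(cols, rep(col, length(r)))
    }
  }
  list(rows = rows, cols = cols)
}

.jacobian <- function(st, u, r0, pat) {
  n <- st$n
  vals <- numeric(length(pat$rows))
  # index into vals by column for fast filling
  ord <- order(pat$cols)
  rows_by_col <- split(pat$rows[ord], pat$cols[ord])
  pos_by_col <- split(seq_along(pat$rows)[ord], pat$cols[ord])
  for (s in 1:3) {
    for (m in 0:2) {
      jj <- seq(1 + m, n, by = 3)
      cols <- (s - 1) * n + jj
      up <- u
      up[cols] <- up[cols] + st$dx[cols]
      rp <- (st$resid(up) - r0)
      for (col in cols) {
        rws <- rows_by_col[[as.character(col)]]
        vals[pos_by_col[[as.character(col)]]] <- rp[rws] / st$dx[col]
        rp[rws] <- 0  # guard against double attribution
      }
    }
  }
  Matrix::sparseMatrix(i = pat$rows, j = pat$cols, x = vals,
                       dims = c(3 * n, 3 * n))
}

#' Steady-state solution of the film model
#'
#' Solves the discretized steady-state balance equations by damped Newton
#' iteration with a sparse finite-difference Jacobian, falling back on
#' pseudo-transient continuation (short implicit time integrations) when a
#' Newton step stalls.  At steady state the enzyme pools are algebraic:
#' the active fraction at each node is
#' `k_a / (k_a + k_i + k_inact_o2 [O2])`, the irreversible pool is empty.
#' With `phi_irr > 0` and O2 present a true steady state does not exist
#' (the dead pool grows without bound); a warning is issued and the
#' reversible pseudo-steady state is returned.
#'
#' @param params a [film_parameters].
#' @param bc a [boundary_conditions].
#' @param n_grid number of grid nodes (>= 50; default 200).
#' @param tol convergence tolerance on the scaled residual (max norm).
#' @param max_iter maximum Newton iterations per attempt.
#' @return a list with `profile` (a [species_profile]), `current`
#'   (A m^-2), `residual` (final scaled residual) and `iterations`.
#' @examples
#' \donttest{
#' p <- default_parameter_set("DV2_pH7")
#' ss <- solve_steady_state(p, boundary_conditions(0.2), n_grid = 81)
#' ss$current
#' }
#' @export
solve_steady_state <- function(params, bc, n_grid = 200, tol = 1e-9,
                               max_iter = 50) {
  if (bc$bulk_o2 > 0 && params$inactivation$phi_irr > 0)
    warning("phi_irr > 0 with O2 present: no true steady state exists; ",
            "returning the reversible pseudo-steady state", call. = FALSE)
  g <- .grid(n_grid)
  st <- .make_steady(params, bc, g)
  pat <- .jac_pattern(g$n)
  n <- g$n

  # initial guess: outer film equilibrated with bulk H2, linear O2
  h2_guess <- max(st$tg$h2, 0.01 * params$h2_sat)
  u <- c({v <- rep(.equilibrium_v_red(params, h2_guess), n); v[1] <- st$tg$v_red; v},
         rep(h2_guess, n),
         st$tg$o2 * g$xi)

  norm_r <- function(r) max(abs(r) / st$scales)
  relax_horizons <- c(0.2, 2, 20, 200)
  attempt <- 0L
  total_iter <- 0L
  repeat {
    converged <- FALSE
    r <- st$resid(u)
    for (it in seq_len(max_iter)) {
      if (norm_r(r) < tol) { converged <- TRUE; break }
      J <- .jacobian(st, u, r, pat)
      du <- as.numeric(Matrix::solve(J, -r))
      lambda <- 1
      repeat {
        u_new <- u + lambda * du
        u_new[1:n] <- pmin(pmax(u_new[1:n], 1e-12 * params$v_total),
                           (1 - 1e-12) * params$v_total)
        u_new[(n + 1):(3 * n)] <- pmax(u_new[(n + 1):(3 * n)], 0)
        r_new <- st$resid(u_new)
        if (norm_r(r_new) < norm_r(r) || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      if (norm_r(r_new) >= norm_r(r)) break  # stalled
      u <- u_new; r <- r_new
      total_iter <- total_iter + 1L
    }
    if (converged || norm_r(r) < tol) { converged <- TRUE; break }
    attempt <- attempt + 1L
    if (attempt > length(relax_horizons))
      stop("steady-state solver did not converge; last scaled residual = ",
           signif(norm_r(r), 3), call. = FALSE)
    # pseudo-transient continuation from the current iterate
    prof <- .profile_from_state(
      c(u, st$enzyme_active(pmin(pmax(u[1:n], 0), params$v_total),
                            pmax(u[(2 * n + 1):(3 * n)], 0)),
        rep(0, n)),
      g, params, bc, bc$electrode_potential)
    horizon <- relax_horizons[attempt]
    repeat {
      tr <- try(solve_transient(params, bc, t_end = horizon, init = prof,
                                n_grid = n_grid, rtol = 1e-5, n_out = 2),
                silent = TRUE)
      if (!inherits(tr, "try-error")) break
      horizon <- horizon / 4
      if (horizon < 1e-3)
        stop("steady-state solver did not converge and pseudo-transient ",
             "continuation failed", call. = FALSE)
    }
    u <- c(tr$final$v_red, tr$final$h2, tr$final$o2)
  }

  vr <- pmin(pmax(u[1:n], 0), params$v_total)
  o2 <- pmax(u[(2 * n + 1):(3 * n)], 0)
  ea <- st$enzyme_active(vr, o2)
  prof <- species_profile(g$xi, v_red = vr, h2 = pmax(u[n + 1:n], 0),
                          o2 = o2, e_active = ea, e_dead = rep(0, n),
                          params = params)
  list(profile = prof, current = current_from_profile(prof, params),
       residual = norm_r(st$resid(u)), iterations = total_iter)
}

# ---------------------------------------------------------------------------

#' Closed-form estimate of the O2-inactivation front speed
#'
#' The inward speed of the inactive-enzyme front is estimated as the O2
#' flux entering the film divided by the reducing capacity per volume that
#' the front must consume, which is dominated by the reduced-mediator pool
#' in equilibrium with H2:
#' \deqn{speed = s_{O2} D_{O2} c_{O2,s} / (\delta \, V_{red,eq})}
#' with \eqn{c_{O2,s}} the partition-scaled surface O2 concentration and
#' \eqn{\delta} the characteristic O2 diffusion gap between the interface
#' and the front (default half the film thickness, the mean gap over a
#' full traverse of the film).  A mediator with
#' a lower standard potential holds less reduced viologen at equilibrium
#' with H2, so its front moves faster.
#'
#' @param params a [film_parameters].
#' @param bc a [boundary_conditions] with `bulk_o2 > 0` (zero gives speed 0).
#' @param delta characteristic O2 diffusion gap, m.
#' @param v_red_pool reducing capacity per volume that the front consumes,
#'   mol m^-3; defaults to the reduced-mediator pool established by prior
#'   equilibration with 1 bar H2 (the pre-exposure operating state).
#' @return front speed in m s^-1; `Inf` when the film holds no reducing
#'   capacity.
#' @export
estimate_front_speed <- function(params, bc, delta = params$thickness / 2,
                                 v_red_pool =
                                   equilibrium_v_red(params,
                                                     params$part_h2 *
                                                       params$h2_sat)) {
  c_s <- params$part_o2 * bc$bulk_o2
  if (c_s <= 0) return(0)
  if (v_red_pool <= 0) return(Inf)
  params$s_o2 * params$d_o2 * c_s / (delta * v_red_pool)
}
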
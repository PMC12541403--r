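test_that("an enzyme-free film at E = E0 equilibrates to a half-reduced pool", {
  p <- default_parameter_set("DV2_pH7", e_total = 1e-9)
  ss <- solve_steady_state(p, boundary_conditions(-0.40), n_grid = 81)
  expect_equal(ss$profile$v_red, rep(50, 81), tolerance = 1e-6)
  expect_lt(abs(ss$current), 1e-6)
  expect_equal(ss$profile$e_v, rep(-0.40, 81), tolerance = 1e-6)
})

test_that("steady-state profiles satisfy the conservation invariants", {
  for (prof in c("DV2_pH7", "DV1_pH7")) {
    p <- default_parameter_set(prof)
    s <- solve_steady_state(p, boundary_conditions(0.2), n_grid = 101)$profile
    expect_lt(max(abs(s$v_ox + s$v_red - p$v_total)) / p$v_total, 1e-8)
    expect_lt(max(abs(s$e_active + s$e_inactive + s$e_dead - p$e_total)) /
                p$e_total, 1e-8)
    expect_true(all(s$v_red >= 0 & s$h2 >= 0 & s$o2 >= 0 &
                      s$e_active >= 0 & s$e_inactive >= -1e-12))
  }
})

test_that("anaerobic steady current has the sign of E - E_eq and is 0 at E_eq", {
  p <- default_parameter_set("DV2_pH7")
  j_at <- function(E) solve_steady_state(p, boundary_conditions(E),
                                         n_grid = 81)$current
  expect_gt(j_at(-0.30), 0)
  expect_lt(j_at(-0.55), 0)
  expect_lt(abs(j_at(-0.42)), 1e-6 * abs(j_at(-0.30)))
})

test_that("plateau property: DV2 steady currents vary < 2% over the window", {
  p <- default_parameter_set("DV2_pH7")
  js <- vapply(c(-0.3, -0.1, 0.2), function(E)
    solve_steady_state(p, boundary_conditions(E), n_grid = 201)$current, 1)
  expect_lt((max(js) - min(js)) / stats::median(js), 0.02)
})

test_that("E_V profile steps down monotonically from E to E_eq when E > E_eq", {
  p <- default_parameter_set("DV2_pH7")
  s <- solve_steady_state(p, boundary_conditions(0.2), n_grid = 161)$profile
  expect_equal(s$e_v[1], 0.2, tolerance = 1e-9)
  expect_true(all(diff(s$e_v) < 1e-9))
  expect_equal(s$e_v[161], -0.42, tolerance = 2e-3)
})

test_that("nernst_profile flags fully oxidized or reduced nodes as NA", {
  p <- film_parameters()
  prof <- data.frame(v_ox = c(100, 50, 0), v_red = c(0, 50, 100))
  ev <- nernst_profile(prof, p$mediator)
  expect_true(is.na(ev[1]) && is.na(ev[3]))
  expect_equal(ev[2], p$mediator$e0)
})

test_that("current_from_profile: zero for uniform profiles, errors when coarse", {
  p <- film_parameters()
  prof <- species_profile(seq(0, 1, length.out = 61),
                          v_red = rep(40, 61), h2 = rep(0.78, 61),
                          o2 = rep(0, 61), e_active = rep(1, 61),
                          e_dead = rep(0, 61), params = p)
  expect_equal(current_from_profile(prof, p), 0)
  expect_error(current_from_profile(prof[1:2, ], p), "3 nodes")
})

test_that("front_position scans from the interface and interpolates", {
  p <- film_parameters()
  xi <- seq(0, 1, length.out = 101)
  mk <- function(e_i) species_profile(xi, v_red = rep(50, 101),
                                      h2 = rep(0.78, 101), o2 = rep(0, 101),
                                      e_active = p$e_total - e_i,
                                      e_dead = rep(0, 101), params = p)
  # no front formed
  expect_true(is.na(front_position(mk(rep(0.1, 101)), p)))
  # whole film inactivated
  expect_equal(front_position(mk(rep(0.9, 101)), p), 0)
  # sharp front at xi = 0.70 with linear interpolation across the crossing
  e_i <- ifelse(xi >= 0.7, 0.9, 0.1)
  e_i[xi >= 0.69 & xi < 0.7] <- 0.3
  fp <- front_position(mk(e_i), p)
  expect_equal(fp, 0.69 + 0.01 * (0.5 - 0.3) / (0.9 - 0.3), tolerance = 1e-9)
})

test_that("transient solver reproduces and holds the anaerobic steady state", {
  p <- default_parameter_set("DV2_pH7")
  bc <- boundary_conditions(0.1)
  ss <- solve_steady_state(p, bc, n_grid = 81)
  tr <- solve_transient(p, bc, t_end = 5, snapshots = c(1.25, 5),
                        init = ss$profile, n_grid = 81, n_out = 5)
  expect_equal(names(tr$snapshots), c("t=1.25", "t=5"))
  f <- tr$final
  expect_lt(max(abs(f$v_red - ss$profile$v_red)) / p$v_total, 1e-7)
  expect_lt(max(abs(f$e_active - ss$profile$e_active)) / p$e_total, 1e-7)
  expect_equal(tr$current$current[nrow(tr$current)], ss$current,
               tolerance = 1e-6)
})

test_that("the inactive-enzyme front moves inward under O2 exposure", {
  p <- default_parameter_set("DV2_pH7")
  bc0 <- boundary_conditions(0.2)
  init <- solve_steady_state(p, bc0, n_grid = 101)$profile
  bcO <- boundary_conditions(0.2, bulk_o2 = 0.26)
  tr <- solve_transient(p, bcO, t_end = 0.3,
                        snapshots = c(0.08, 0.15, 0.22, 0.3),
                        init = init, n_grid = 101, rtol = 1e-6)
  fronts <- vapply(tr$snapshots, function(s) front_position(s, p), 1)
  expect_true(all(is.finite(fronts)))
  expect_true(all(diff(fronts) < 0))
})

test_that("front-speed estimate: zero without O2, flagged without reducing capacity", {
  p <- default_parameter_set("DV2_pH7")
  expect_equal(estimate_front_speed(p, boundary_conditions(0.2)), 0)
  expect_equal(estimate_front_speed(p, boundary_conditions(0.2, bulk_o2 = 0.1),
                                    v_red_pool = 0), Inf)
  # DV2 (lower E0, smaller equilibrium V_red pool) gives the faster front
  p1 <- default_parameter_set("DV1_pH7")
  bc <- boundary_conditions(0.2, bulk_o2 = 0.26)
  expect_gt(estimate_front_speed(p, bc), estimate_front_speed(p1, bc))
  # reduced pool: DV1 nearly fully reduced by H2, DV2 partially
  expect_gt(equilibrium_v_red(p1), 0.99 * p1$v_total)
  expect_equal(equilibrium_v_red(p), 68.5, tolerance = 0.01)
})

test_that("named default parameter sets carry the mediator potentials", {
  expect_equal(default_parameter_set("DV2_pH7")$mediator$e0, -0.40)
  expect_equal(default_parameter_set("DV1_pH7")$mediator$e0, -0.22)
  expect_equal(default_parameter_set("PV2_pH7")$mediator$e0, -0.431)
  expect_equal(default_parameter_set("DV2_pH8.8")$pH, 8.8)
  expect_error(default_parameter_set("DV3_pH7"), "unknown")
})
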
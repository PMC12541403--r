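test_that("triangular potential program hits its vertices exactly", {
  prog <- cv_program(-0.6, 0.2, 0.01, cycles = 2)
  expect_equal(prog$t_end, 320)
  expect_equal(prog$E_of_t(0), -0.6)
  expect_equal(prog$E_of_t(80), 0.2)
  expect_equal(prog$E_of_t(160), -0.6)
  expect_equal(prog$E_of_t(40), -0.2)
  expect_error(cv_program(-0.6, 0.2, 0), "scan_rate")
})

test_that("simulated catalytic CV crosses zero at E_eq and is quasi-steady", {
  p <- default_parameter_set("DV2_pH7")
  cv <- simulate_cv(p, e_start = -0.6, e_vertex = 0.25, scan_rate = 0.01,
                    n_grid = 101, rtol = 1e-6)
  expect_s3_class(cv, "ec_trace")
  expect_equal(attr(cv, "scan_rate"), 0.01)
  # reversible catalysis: zero crossing at E_eq within 5 mV
  expect_lt(abs(zero_crossing(cv) - e_eq_she(7)), 0.005)
  # forward-scan current at +0.2 V within 2% of the true steady state
  ss <- solve_steady_state(p, boundary_conditions(0.2), n_grid = 101)
  d <- diff(cv$potential); fwd <- c(d[1], d) > 0
  j02 <- cv$current[fwd][which.min(abs(cv$potential[fwd] - 0.2))]
  expect_lt(abs(j02 - ss$current) / ss$current, 0.02)
})

test_that("chronoamperometry steps show bidirectional catalysis without hysteresis", {
  p <- default_parameter_set("DV2_pH7")
  ca <- simulate_ca(p, data.frame(E = c(-0.6, 0.2, -0.6, 0.2),
                                  duration = rep(40, 4)),
                    n_grid = 81, rtol = 1e-7, points_per_step = 40)
  expect_s3_class(ca, "ec_trace")
  expect_equal(attr(ca, "kind"), "CA")
  # oxidation current at +0.2 V and evolution current at -0.6 V
  j_red1 <- ca$current[ca$time <= 40]
  j_ox1 <- ca$current[ca$time > 40 & ca$time <= 80]
  expect_lt(tail(j_red1, 1), 0)
  expect_gt(tail(j_ox1, 1), 0)
  # repeating the same step gives the same quasi-steady current
  j_ox2 <- ca$current[ca$time > 120]
  expect_lt(abs(tail(j_ox2, 1) - tail(j_ox1, 1)) / abs(tail(j_ox1, 1)), 1e-6)
  # stepping to E_eq lets the current decay to zero
  ca0 <- simulate_ca(p, data.frame(E = c(0.2, -0.42), duration = c(5, 30)),
                     n_grid = 81, rtol = 1e-7, points_per_step = 30)
  expect_lt(abs(tail(ca0$current, 1)), 1e-3 * max(abs(ca0$current)))
})

test_that("mediator midpoint extraction is exact on ideal waves and scale-invariant", {
  for (e0 in seq(-0.5, -0.1, by = 0.1)) {
    tr <- generate_mediator_cv(e0)
    expect_lt(abs(extract_mediator_e0(tr) - e0), 0.002)
  }
  tr <- generate_mediator_cv(-0.40)
  tr_scaled <- tr
  tr_scaled$current <- 7.3 * tr_scaled$current
  expect_equal(extract_mediator_e0(tr_scaled), extract_mediator_e0(tr))
  # diffusion-tailed variant keeps the midpoint
  trd <- generate_mediator_cv(-0.40, shape = "diffusion")
  expect_lt(abs(extract_mediator_e0(trd) + 0.40), 0.005)
  # a peakless (monotone) trace is rejected
  flat <- ec_trace(time = 1:100, potential = c(seq(-1, 0, length.out = 50),
                                               seq(0, -1, length.out = 50)),
                   current = c(seq(0, 1, length.out = 50),
                               seq(1, 0, length.out = 50)), kind = "CV")
  expect_error(extract_mediator_e0(flat), "peak")
})

test_that("noisy mediator CVs still recover the midpoint within 5 mV", {
  e0s <- vapply(0:19, function(seed)
    extract_mediator_e0(generate_mediator_cv(-0.40, noise_sd = 0.02,
                                             seed = seed)), 1)
  expect_lt(abs(mean(e0s) + 0.40), 0.005)
})

test_that("normalization by the maximal positive current", {
  tr <- generate_catalytic_cv(pH = 7, i_ox = 3.2, i_red = 1.1)
  nrm <- normalize_by_max_positive(tr)
  expect_equal(max(nrm$current), 1)
  expect_true(attr(nrm, "normalized"))
  # idempotent
  expect_equal(normalize_by_max_positive(nrm)$current, nrm$current)
  # signs and zero crossings preserved
  expect_equal(sign(nrm$current), sign(tr$current))
  # relative magnitudes preserved
  expect_equal(min(nrm$current) / max(nrm$current),
               min(tr$current) / max(tr$current))
  neg <- tr
  neg$current <- -abs(neg$current)
  expect_error(normalize_by_max_positive(neg), "positive")
})

test_that("plateau current is the forward-scan median with its spread", {
  # constant-current segment: median is that constant, spread 0
  tr <- ec_trace(time = 1:101,
                 potential = c(seq(-0.6, 0.25, length.out = 51),
                               seq(0.25, -0.6, length.out = 50)),
                 current = rep(2.5, 101), kind = "CV")
  pl <- plateau_current(tr, c(-0.3, 0.2))
  expect_equal(pl$current, 2.5)
  expect_equal(pl$spread, 0)
  expect_true(pl$plateau)
  expect_error(plateau_current(tr, c(0.2, -0.3)), "increasing")
  expect_error(plateau_current(tr, c(0.5, 0.6)), "window")
  # sigmoid surrogate with a wide foot has no plateau over the window
  soft <- generate_catalytic_cv(pH = 7, w = 0.15)
  expect_false(plateau_current(soft, c(-0.3, 0.2))$plateau)
})

test_that("slow-scan CV branches coincide for non-inactivating conditions", {
  # at 1 mV/s the film is quasi-steady: forward and backward currents at
  # matched potentials agree within 2% over the oxidation window
  p <- default_parameter_set("DV2_pH7")
  cv <- simulate_cv(p, e_start = -0.38, e_vertex = -0.28, scan_rate = 0.001,
                    n_grid = 81, rtol = 1e-7, points_per_sweep = 60)
  d <- diff(cv$potential); fwd <- c(d[1], d) > 0
  Es <- seq(-0.37, -0.29, by = 0.01)
  j_f <- stats::approx(cv$potential[fwd], cv$current[fwd], xout = Es)$y
  j_b <- stats::approx(cv$potential[!fwd], cv$current[!fwd], xout = Es)$y
  expect_lt(max(abs(j_f - j_b) / abs(j_f)), 0.02)
})
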
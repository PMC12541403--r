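test_that("enzyme net rate obeys detailed balance at the H+/H2 couple", {
  p <- default_parameter_set("DV2_pH7")
  # 100 random states pinned to the local equilibrium ratio: rate must
  # vanish there for any mediator/pH combination
  set.seed(42)
  for (i in 1:100) {
    pp <- default_parameter_set(sample(c("DV1_pH7", "DV2_pH7", "DV2_pH6",
                                         "DV2_pH8.8", "PV2_pH7"), 1))
    h2 <- runif(1, 0.05, 1.5)
    # ratio at equilibrium with this H2: (v_ox/v_red)^2 h2/h2_sat = K_inv
    e_h2 <- -pp$slope * pp$pH -
      (RGAS * pp$temperature / (2 * FARADAY)) * log(h2 / pp$h2_sat)
    ratio <- exp(FARADAY * (e_h2 - pp$mediator$e0) /
                   (RGAS * pp$temperature))
    v_red <- runif(1, 1, pp$v_total - 1)
    v_ox <- ratio * v_red
    vt <- v_ox + v_red
    scale <- pp$v_total / vt
    rate <- enzyme_net_rate(v_ox * scale, v_red * scale, h2, pp)
    expect_lt(abs(rate), 1e-8 * pp$kinetics$k_cat_ox * pp$e_total)
  }
})

test_that("enzyme net rate has the right limits and scaling", {
  p <- default_parameter_set("DV2_pH7")
  # pure forward: no reduced mediator, H2 present
  expect_gt(enzyme_net_rate(p$v_total, 0, 0.78, p), 0)
  # pure reverse: fully reduced film evolves H2
  expect_lt(enzyme_net_rate(0, p$v_total, 0.78, p), 0)
  # linear in the active-enzyme concentration
  r1 <- enzyme_net_rate(60, 40, 0.5, p, e_active = 1)
  r2 <- enzyme_net_rate(60, 40, 0.5, p, e_active = 2)
  expect_equal(r2, 2 * r1)
  # bounded by k_cat * e_active
  expect_lt(abs(r1), p$kinetics$k_cat_ox)
  expect_error(enzyme_net_rate(-1, 40, 0.5, p), ">= 0")
})

test_that("inactivation and reactivation rates pivot at E_inact", {
  m <- inactivation_model()
  ei <- e_inact_she(m, 7)
  expect_equal(ei, -0.25)
  kp <- inactivation_rate_pair(ei, m, pH = 7)
  expect_equal(kp$k_i, m$k_x)
  expect_equal(kp$k_a, m$k_x)
  # steady-state inactive fraction at E_inact is 1/2
  expect_equal(kp$k_i / (kp$k_i + kp$k_a), 0.5)
  # far below E_inact the enzyme stays active
  low <- inactivation_rate_pair(ei - 0.3, m, pH = 7)
  expect_lt(low$k_i / low$k_a, 1e-6)
  # detailed balance of the pair: k_i * k_a = k_x^2 at any potential
  for (e in seq(-0.6, 0.3, by = 0.1)) {
    kp <- inactivation_rate_pair(e, m, pH = 7)
    expect_equal(kp$k_i * kp$k_a, m$k_x^2, tolerance = 1e-10)
  }
  # E_inact is pinned to the RHE scale: -250 mV SHE at pH 7 shifts with pH
  expect_equal(e_inact_she(m, 8.8), 0.17 - 0.06 * 8.8)
})

test_that("Nernstian electrode boundary ratio", {
  dv2 <- redox_couple(-0.40)
  expect_equal(electrode_boundary_ratio(-0.40, dv2), 1)
  expect_equal(electrode_boundary_ratio(-0.40 + 0.05916, dv2), 10,
               tolerance = 1e-3)
  expect_lt(electrode_boundary_ratio(-0.9, dv2), 1e-8)
  # potential_value input is converted to SHE internally
  expect_equal(electrode_boundary_ratio(potential_value(0.02, "RHE", pH = 7),
                                        dv2),
               electrode_boundary_ratio(-0.40, dv2))
})
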
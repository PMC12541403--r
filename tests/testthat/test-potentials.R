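test_that("H+/H2 equilibrium potential follows the Nernstian pH slope", {
  expect_equal(h2_equilibrium_potential(7)$value, -0.42)
  expect_equal(h2_equilibrium_potential(0)$value, 0)
  expect_equal(h2_equilibrium_potential(6)$value, -0.36)
  # linear in pH with slope -60 mV/pH at 1 bar
  pHs <- seq(0, 14, by = 0.5)
  es <- vapply(pHs, function(p) h2_equilibrium_potential(p)$value, 1)
  expect_equal(diff(es) / diff(pHs), rep(-0.060, length(pHs) - 1))
  # half-power pressure dependence: decade in p(H2) shifts by slope/2
  expect_equal(h2_equilibrium_potential(7, p_h2 = 0.1)$value,
               -0.42 + 0.03)
  expect_error(h2_equilibrium_potential(7, p_h2 = 0), "positive")
  # exact slope option
  expect_equal(nernst_slope(exact = TRUE), 0.0591597, tolerance = 1e-5)
})

test_that("SHE/RHE conversion matches the printed values and round-trips", {
  p <- potential_value(-0.250, "SHE", pH = 7)
  expect_equal(convert_reference(p, "RHE")$value, 0.170)
  expect_equal(convert_reference(potential_value(-0.420, "SHE", pH = 7),
                                 "RHE")$value, 0)
  # scales coincide at pH 0
  expect_equal(convert_reference(potential_value(0.123, "SHE", pH = 0),
                                 "RHE")$value, 0.123)
  # round trip is the identity to 1e-12 V over the whole pH range
  for (pH in seq(0, 14, by = 0.7)) {
    p0 <- potential_value(-0.3, "SHE", pH = pH)
    back <- convert_reference(convert_reference(p0, "RHE"), "SHE")
    expect_lt(abs(back$value - p0$value), 1e-12)
  }
  expect_error(convert_reference(potential_value(0.1, "SHE"), "RHE"), "pH")
})

test_that("mediator overpotentials reproduce the DV1/DV2 ladder", {
  dv2 <- redox_couple(-0.40, label = "DV2")
  dv1 <- redox_couple(-0.22, label = "DV1")
  expect_equal(mediator_overpotential(dv2, 6), -40)
  expect_equal(mediator_overpotential(dv2, 7), 20)
  expect_equal(mediator_overpotential(dv1, 6), 140)
  expect_equal(mediator_overpotential(dv1, 7), 200)
  # pH 8.8 values are exact here; the printed table rounds to 20 mV
  expect_equal(mediator_overpotential(dv2, 8.8), 128)
  expect_equal(mediator_overpotential(dv1, 8.8), 308)
  expect_equal(round(mediator_overpotential(dv2, 8.8) / 20) * 20, 120)
  expect_equal(round(mediator_overpotential(dv1, 8.8) / 20) * 20, 300)
  # self-difference vanishes
  e_eq7 <- h2_equilibrium_potential(7)$value
  expect_equal(mediator_overpotential(redox_couple(e_eq7), 7), 0)
  # strictly increasing in pH at fixed E0
  ovs <- vapply(seq(1, 13, by = 1),
                function(p) mediator_overpotential(dv2, p), 1)
  expect_true(all(diff(ovs) > 0))
})

test_that("Nernst potential from a concentration ratio", {
  dv2 <- redox_couple(-0.40)
  expect_equal(nernst_from_ratio(dv2, 1)$value, -0.40)
  expect_equal(nernst_from_ratio(dv2, 10)$value, -0.40 + 0.05916,
               tolerance = 1e-4)
  expect_equal(nernst_from_ratio(dv2, 0.1)$value, -0.40 - 0.05916,
               tolerance = 1e-4)
  expect_error(nernst_from_ratio(dv2, 0), "positive")
  expect_error(nernst_from_ratio(dv2, -2), "positive")
  # strictly increasing in the ratio, antisymmetric about 1 on a log scale
  rs <- 10^seq(-3, 3, by = 0.5)
  es <- vapply(rs, function(r) nernst_from_ratio(dv2, r)$value, 1)
  expect_true(all(diff(es) > 0))
  expect_equal(es + rev(es), rep(2 * dv2$e0, length(es)))
  # two-electron couple halves the slope
  expect_equal(nernst_from_ratio(redox_couple(-0.4, 2), 10)$value,
               -0.4 + 0.05916 / 2, tolerance = 1e-4)
})

test_that("potential and couple containers validate their inputs", {
  expect_error(potential_value(Inf, "SHE"), "finite")
  expect_error(potential_value(0.1, "RHE"), "pH")
  expect_error(potential_value(0.1, "SHE", pH = 15), "pH")
  expect_error(redox_couple(-0.4, 0), "positive integer")
  expect_s3_class(potential_value(-0.42, "SHE", pH = 7), "potential_value")
})
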
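test_that("closed-form parameter derivations match published values", {
  # forward stepping rate: v0/L + k_back
  expect_equal(derive_forward_rate(586, 8, 3), 76.25)
  expect_equal(derive_forward_rate(910, 8, 3), 116.75)
  expect_equal(derive_forward_rate(0, 8, 0), 0)
  expect_equal(round(derive_forward_rate(586, 8, 3)), 76)
  expect_equal(round(derive_forward_rate(307, 8, 3)), 41)
  expect_equal(round(derive_forward_rate(910, 8, 3)), 117)

  # unloaded off-rate: v0/RL0
  expect_equal(derive_unloaded_detach_rate(1200, 6300), 0.19, tolerance = 0.005)
  expect_equal(derive_unloaded_detach_rate(0, 1000), 0)
  # inverting the tabulated Kin1 off-rate gives back the run length
  expect_equal(derive_unloaded_detach_rate(586, 610.4), 0.96, tolerance = 1e-3)

  # off-rate from a mean engaged time under load
  expect_equal(detach_rate_from_engaged_time(0.069), 14.5, tolerance = 0.005)

  # Bell detachment force parameter: kBT/delta
  expect_equal(derive_detach_force(0.6), 6.8, tolerance = 0.01)
  expect_equal(round(derive_detach_force(1.3)), 3)
  expect_equal(derive_detach_force(4.1, thermal_energy = 4.1), 1)

  # first-order reattachment: k_on * [tubulin]
  expect_equal(derive_reattach_rate(1.1, 125), 137.5)
  expect_equal(derive_reattach_rate(0, 125), 0)
  expect_equal(derive_reattach_rate(2.2, 125), 275)

  # linkage stiffness from the force-extension calibration point
  expect_equal(derive_linkage_stiffness(6, 30), 0.2)
  expect_equal(derive_linkage_stiffness(0, 30), 0)
  expect_equal(derive_linkage_stiffness(6, 15), 0.4)
})

test_that("derivations reject degenerate inputs", {
  expect_error(derive_forward_rate(586, 0, 3), "step_size")
  expect_error(derive_unloaded_detach_rate(586, 0), "run_length0")
  expect_error(derive_detach_force(0), "delta")
  expect_error(derive_reattach_rate(-1, 125), ">= 0")
  expect_error(derive_linkage_stiffness(6, 0), "extension")
  expect_error(detach_rate_from_engaged_time(0), "engaged_time")
})

test_that("motor_params validates, derives and reconciles rates", {
  p <- motor_params("X", 1, v0 = 800, step_size = 8, k_backstep = 3,
                    run_length0 = 1000, f_stall = 6, f_detach = 4,
                    k_reattach = 10, stiffness = 0.2)
  expect_equal(p$k_forward0, 103)
  expect_equal(p$k_detach0, 0.8)

  # supplied value within rounding of the derivation -> exact derivation used
  p2 <- motor_params("X", 1, v0 = 586, step_size = 8, k_backstep = 3,
                     k_forward0 = 76, k_detach0 = 0.96, f_stall = 6,
                     f_detach = 6.8, k_reattach = 100, stiffness = 0.2)
  expect_equal(p2$k_forward0, 76.25)

  # supplied value far from the derivation -> kept, with a warning
  expect_warning(
    p3 <- motor_params("D", -1, v0 = 360, step_size = 8, k_backstep = 5,
                       k_forward0 = 60, k_detach0 = 0.1, f_stall = 3.6,
                       f_detach = Inf, k_reattach = 5, stiffness = 0.2),
    "k_forward0")
  expect_equal(p3$k_forward0, 60)

  expect_error(motor_params("X", 0, v0 = 1, step_size = 8, k_backstep = 1,
                            k_detach0 = 1, f_stall = 6, f_detach = 6,
                            k_reattach = 1, stiffness = 0.2), "direction")
  expect_error(motor_params("X", 1, v0 = -1, step_size = 8, k_backstep = 1,
                            k_detach0 = 1, f_stall = 6, f_detach = 6,
                            k_reattach = 1, stiffness = 0.2), "v0")
  expect_error(motor_params("X", 1, v0 = 1, step_size = 8, k_backstep = 1,
                            f_stall = 6, f_detach = 6, k_reattach = 1,
                            stiffness = 0.2), "k_detach0")
})

test_that("force-velocity rate law is continuous, stalls exactly, stays non-negative", {
  # assisting and zero load leave the unloaded rate
  expect_equal(forward_rate_under_load(2, kin1), 76.25)
  expect_equal(forward_rate_under_load(0, kin1), 76.25)
  # hindering: linear interpolation down to k_backstep at stall
  expect_equal(forward_rate_under_load(-3, kin1), (76.25 + 3) / 2)
  expect_equal(forward_rate_under_load(-6, kin1), 3)
  # net stepping velocity vanishes at stall
  v_stall <- (forward_rate_under_load(-kin1$f_stall, kin1) -
                kin1$k_backstep) * kin1$step_size
  expect_equal(v_stall, 0)
  # continuity at zero and monotone non-increase with hindering load
  loads <- seq(0, -12, by = -0.1)
  rates <- forward_rate_under_load(loads, kin1)
  expect_equal(rates[1], kin1$k_forward0)
  expect_true(all(diff(rates) <= 1e-12))
  expect_true(all(rates >= 0))
  # super-stall conventions: linear continuation floors at zero,
  # clamp holds at k_backstep
  expect_equal(forward_rate_under_load(-12, kin1), 0)
  kin1c <- kin1
  kin1c$superstall <- "clamp"
  expect_equal(forward_rate_under_load(-12, kin1c), kin1$k_backstep)
})

test_that("Bell detachment law and ideal bond behave as specified", {
  expect_equal(detach_rate_under_load(0, kin1), 0.96)
  expect_equal(detach_rate_under_load(-6.8, kin1), 0.96 * exp(1))
  expect_equal(detach_rate_under_load(6.8, kin1), 0.96 * exp(1))
  # ideal bond: load-independent
  for (f in c(-10, 0, 25)) {
    expect_equal(detach_rate_under_load(f, ddb), 0.1)
  }
  # monotone non-decreasing in load magnitude
  r <- detach_rate_under_load(seq(0, -10, by = -0.5), kin1)
  expect_true(all(diff(r) >= 0))
})

test_that("linkage force is a linear spring pulling the motor toward the cargo", {
  expect_equal(linkage_force(0, 0, 0.2), 0)
  expect_equal(linkage_force(0, 30, 0.2), 6)
  expect_equal(linkage_force(30, 0, 0.2), -6)
  # antisymmetry under swapping motor and cargo
  expect_equal(linkage_force(12, 55, 0.2), -linkage_force(55, 12, 0.2))
  # direction sign converts to the per-motor convention
  expect_equal(motor_load(-6, +1), -6)  # plus-end motor, backward pull = hindering
  expect_equal(motor_load(+6, -1), -6)  # minus-end motor, forward pull = hindering
})
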
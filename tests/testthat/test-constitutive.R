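test_that("chamber pressure matches the printed constitutive expressions", {
  base <- atrial_law() # ees 0.45, v0 0, a_res 0.5, b_res 0.049
  post <- atrial_law(ees = 0.7, a_res = 0.35, b_res = 0.07)

  # both terms vanish at the unstressed volume, for any activation
  for (e in c(0, 0.3, 1)) {
    expect_equal(chamber_pressure(0, e, base), 0)
    expect_equal(chamber_pressure(12, e, atrial_law(v0 = 12)), 0)
  }

  # passive reservoir pressure 50 mL above v0, hand-evaluated
  expect_equal(chamber_pressure(50, 0, base), 0.5 * (exp(0.049 * 50) - 1))
  expect_equal(chamber_pressure(50, 0, base), 5.2942, tolerance = 1e-4)
  expect_equal(chamber_pressure(50, 0, post), 0.35 * (exp(0.07 * 50) - 1))
  expect_equal(chamber_pressure(50, 0, post), 11.2394, tolerance = 1e-4)

  # pure active pressure at peak activation under blended gating
  expect_equal(chamber_pressure(10, 1, base, gating = "blended"), 4.5)
  # additive gating keeps the passive term at peak activation
  expect_equal(chamber_pressure(10, 1, base, gating = "additive"),
               4.5 + 0.5 * (exp(0.49) - 1))

  expect_error(chamber_pressure(10, -0.1, base), "activation")
  expect_error(chamber_pressure(10, 1.1, base), "activation")
  expect_error(chamber_pressure(-1, 0.5, base), ">= 0")
})

test_that("chamber pressure is continuous and increasing in volume", {
  base <- atrial_law()
  v <- seq(0, 80, by = 0.25)
  for (e in c(0, 0.5, 1)) {
    p <- chamber_pressure(v, e, base)
    expect_true(all(diff(p) > 0))
    expect_lt(max(abs(diff(p))), 1.5) # no jumps on a fine grid
  }
  # continuity in activation
  e <- seq(0, 1, by = 0.01)
  p <- chamber_pressure(rep(40, length(e)), e, base)
  expect_lt(max(abs(diff(p))), 0.25)
})

test_that("passive curves before and after occlusion share the initial slope", {
  pre <- atrial_law()
  post <- atrial_law(ees = 0.7, a_res = 0.35, b_res = 0.07)
  h <- 1e-6
  slope_pre <- chamber_pressure(h, 0, pre) / h
  slope_post <- chamber_pressure(h, 0, post) / h
  expect_equal(slope_pre, 0.5 * 0.049, tolerance = 1e-5)
  expect_equal(slope_post, 0.35 * 0.07, tolerance = 1e-5)
  expect_equal(slope_pre, slope_post, tolerance = 1e-5) # both 0.0245

  # the stiffer post-occlusion curve dominates everywhere above v0
  v <- seq(0.5, 80, by = 0.5)
  expect_true(all(chamber_pressure(v, 0, post) >= chamber_pressure(v, 0, pre)))
})

test_that("activation peaks at one inside its window and vanishes outside", {
  rh <- rhythm(cycle_lengths = 1)
  lv <- chamber("LV", atrial_law(), onset = 0, duration = 0.3)
  la <- chamber("LA", atrial_law(), onset = 0.74, duration = 0.2)

  expect_equal(activation(0.15, lv, rh), 1) # window midpoint
  expect_equal(activation(0.84, la, rh), 1)
  expect_equal(activation(c(0.5, 0.6, 0.72), lv, rh), c(0, 0, 0))
  expect_equal(activation(c(0.3, 0.5, 0.95), la, rh), c(0, 0, 0))

  # continuity across the whole cycle
  t <- seq(0, 2, by = 1e-3)
  expect_lt(max(abs(diff(activation(t, lv, rh)))), 0.02)

  # atrial activation disabled under flutter rhythms
  rh_flutter <- rhythm(cycle_lengths = 0.4, atrial_active = FALSE,
                       av_delay = 0.1)
  expect_equal(activation(seq(0, 1, by = 0.01), la, rh_flutter),
               rep(0, 101))
  # ... but ventricular activation is untouched
  expect_equal(activation(0.06, lv, rh_flutter), 1)

  # integral over one cycle: positive when active, zero when disabled
  tt <- seq(0, 1, length.out = 2001)
  expect_gt(mean(activation(tt, la, rh)), 0.05)
  expect_equal(mean(activation(tt, la, rh_flutter)), 0)
})

test_that("valves are ideal diodes with linear forward conductance", {
  mv <- valve("MV", 0.05)
  expect_equal(valve_flow(10, 10, mv), 0)
  expect_equal(valve_flow(5, 10, mv), 0)
  expect_equal(valve_flow(10, 5, mv), 100)
  dp <- seq(-20, 20, by = 0.5)
  q <- valve_flow(dp, 0, mv)
  expect_true(all(q >= 0))
  expect_true(all(diff(q) >= 0)) # nondecreasing in the gradient
  expect_error(valve("MV", 0), "> 0")
})

test_that("compartment pressure is a linear capacitor law", {
  sa <- vascular("SA", compliance = 1, resistance = 1, unstressed = 300)
  expect_equal(compartment_pressure(300, sa), 0)
  expect_equal(compartment_pressure(400, sa), 100)
  sa2 <- vascular("SA", compliance = 2, resistance = 1, unstressed = 300)
  expect_equal(compartment_pressure(400, sa2),
               compartment_pressure(400, sa) / 2)
})

test_that("constructors enforce the parameter invariants", {
  expect_error(atrial_law(ees = -1), "ees")
  expect_error(atrial_law(b_res = 0), "b_res")
  expect_error(atrial_law(v0 = -5), "v0")
  expect_error(chamber("LA", atrial_law(), onset = 1.2), "onset")
  expect_error(chamber("LV", atrial_law(), viscous_resistance = 0.1),
               "atrial")
  expect_error(rhythm(c(1, -0.5)), "positive")
  expect_error(rhythm(1, av_delay = 1.5), "av_delay")
  expect_error(baseline_circuit(total_volume = 100), "total_volume")
})
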
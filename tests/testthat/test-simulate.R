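test_that("state derivatives conserve volume at arbitrary states", {
  base <- baseline_circuit()
  set.seed(42)
  for (k in 1:25) {
    state <- runif(8, min = 10, max = 200) * c(1, 1, 1, 1, 2, 12, 1, 2)
    t <- runif(1, 0, 3)
    d <- derivatives(t, state, base)
    # exact up to floating-point cancellation between in/out flows
    expect_lt(abs(sum(d$dvdt)) / max(abs(d$flows), 1), 1e-12)
    expect_length(d$pressures, 8)
    expect_length(d$flows, 8)
  }
})

test_that("a pressure-equalized inert circuit is at equilibrium", {
  circ <- passive_circuit()
  # choose volumes so every element sits at exactly 5 mmHg
  vols <- c(
    vapply(circ$chambers, function(ch)
      ch$law$v0 + log(5 / ch$law$a_res + 1) / ch$law$b_res, 0),
    vapply(circ$compartments, function(cp)
      cp$unstressed + 5 * cp$compliance, 0))
  # t = 0.5 lies outside every activation window
  d <- derivatives(0.5, vols, circ)
  expect_equal(unname(d$dvdt), rep(0, 8), tolerance = 1e-9)
})

test_that("passive two-compartment reduction follows the closed-form RC decay", {
  # block every other path with enormous resistances so the dynamics
  # reduce to charge exchange between the two systemic compartments
  chambers <- list(
    chamber("LA", atrial_law(ees = 0), onset = 0.74, duration = 0.2),
    chamber("LV", atrial_law(ees = 0, v0 = 5), onset = 0, duration = 0.3),
    chamber("RA", atrial_law(ees = 0), onset = 0.74, duration = 0.2),
    chamber("RV", atrial_law(ees = 0, v0 = 5), onset = 0, duration = 0.3))
  compartments <- list(
    vascular("SA", compliance = 1, resistance = 2, unstressed = 100),
    vascular("SV", compliance = 1, resistance = 1e9, unstressed = 100),
    vascular("PA", compliance = 1, resistance = 1e9, unstressed = 100),
    vascular("PV", compliance = 1, resistance = 1e9, unstressed = 100))
  valves <- list(valve("MV", 1e9), valve("AoV", 1e9),
                 valve("TV", 1e9), valve("PuV", 1e9))
  circ <- circuit(chambers, compartments, valves, rhythm(1),
                  total_volume = 10 + 400 + 10) # chambers at v0, 10 mL excess
  init <- c(v_la = 0, v_lv = 5, v_ra = 0, v_rv = 5,
            v_sa = 110, v_sv = 100, v_pa = 100, v_pv = 100)
  sim <- simulate_circuit(circ, duration = 6, rtol = 1e-10, atol = 1e-10,
                          init = init)
  # dP/dt = -(P_sa - P_sv)/tau with tau = R * C1 C2 / (C1 + C2) = 1 s
  dp <- sim$p_sa - sim$p_sv
  expected <- dp[1] * exp(-sim$time_s / 1)
  expect_lt(max(abs(dp - expected)) / dp[1], 1e-4)
})

test_that("simulated runs conserve total blood volume at every sample", {
  for (nm in c("baseline", "flutter150", "af")) {
    sim <- cached_sim(nm)
    total <- attr(sim, "circuit")$total_volume
    vols <- rowSums(as.matrix(sim[paste0("v_", c("la", "lv", "ra", "rv",
                                                 "sa", "sv", "pa", "pv"))]))
    expect_lt(max(abs(vols - total)), 0.1)
    # and end-to-end
    expect_equal(vols[length(vols)], vols[1], tolerance = 0.1)
  }
})

test_that("solver refinement leaves the final-beat mean LA pressure stable", {
  base <- baseline_circuit()
  m1 <- mean_lap(cached_sim("baseline"), beats = 1) # rtol 1e-7
  sim2 <- simulate_circuit(base, rtol = 1e-8, atol = 1e-8)
  expect_lt(abs(mean_lap(sim2, beats = 1) - m1), 0.1)
})

test_that("with all contraction disabled the valve flows decay to zero", {
  circ <- passive_circuit()
  circ$rhythm <- rhythm(1, atrial_active = FALSE, av_delay = 0.16)
  circ <- atriahemo::circuit(circ$chambers, circ$compartments, circ$valves,
                             circ$rhythm, circ$total_volume, circ$gating)
  sim <- simulate_circuit(circ, duration = 30)
  late <- sim$time_s > 25
  for (q in c("q_mv", "q_aov", "q_tv", "q_puv"))
    expect_lt(max(sim[[q]][late]), 1e-3 * max(1, max(sim[[q]])))
})

test_that("beats tile the run and match the scheduled cycle lengths", {
  sim <- cached_sim("baseline")
  bt <- segment_beats(sim)
  expect_equal(nrow(bt), 30)
  expect_equal(unique(bt$cycle_length), 1)
  expect_equal(bt$t_start, 0:29)
  expect_true(all(diff(bt$t_start) > 0))
  expect_equal(bt$t_end, bt$t_start + bt$cycle_length)

  af <- cached_sim("af")
  bta <- segment_beats(af)
  expect_equal(bta$cycle_length[1:6], rep(c(0.375, 0.4, 0.5), 2))
  expect_true(all(diff(bta$t_start) > 0))
  # intervals tile: each beat starts where the previous ended
  expect_equal(bta$t_start[-1], bta$t_end[-nrow(bta)])
})

test_that("runs reach periodic steady state and report small drift", {
  expect_lt(periodicity_drift(cached_sim("baseline")), 0.5)
  expect_lt(periodicity_drift(cached_sim("af")), 0.5)
  short <- simulate_circuit(baseline_circuit(), duration = 3)
  expect_error(periodicity_drift(short), "4 complete")
})

test_that("identical circuits and options give bitwise-identical metrics", {
  base <- baseline_circuit()
  s1 <- simulate_circuit(base, duration = 8)
  s2 <- simulate_circuit(base, duration = 8)
  expect_identical(beat_metrics(s1, beats = 3), beat_metrics(s2, beats = 3))
  expect_identical(mean_lap(s1, beats = 3), mean_lap(s2, beats = 3))
})

test_that("degenerate durations and invalid initial states are rejected", {
  base <- baseline_circuit()
  expect_error(simulate_circuit(base, duration = 1.5), "two scheduled cycles")
  expect_error(simulate_circuit(base, duration = 10, init = rep(1, 8)),
               "total volume")
})
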
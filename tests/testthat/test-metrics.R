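rh60 <- rhythm(cycle_lengths = 1)

test_that("mean LA pressure is a time-weighted mean over whole beats", {
  t <- seq(0, 10, by = 1 / 400)
  flat <- tibble::tibble(time_s = t, p_la = rep(10, length(t)))
  expect_equal(mean_lap(flat, beats = 5, rhythm = rh60), 10)
  wavy <- tibble::tibble(time_s = t, p_la = 10 + 5 * sin(2 * pi * t))
  expect_equal(mean_lap(wavy, beats = 5, rhythm = rh60), 10, tolerance = 1e-6)
  expect_equal(mean_lap(wavy, beats = 3, rhythm = rh60), 10, tolerance = 1e-6)
  expect_error(mean_lap(wavy, beats = 0, rhythm = rh60), "window")
  expect_error(mean_lap(wavy, beats = 11, rhythm = rh60), "window")
  expect_error(mean_lap(tibble::tibble(time_s = t), rhythm = rh60),
               "missing required column")
})

test_that("mean LA pressure is invariant to the steady-state window chosen", {
  sim <- cached_sim("baseline")
  m <- vapply(1:5, function(b) mean_lap(sim, beats = b), 0)
  expect_lt(max(m) - min(m), 0.1)
})

test_that("cardiac output converts mean aortic flow to L/min", {
  t <- seq(0, 10, by = 1 / 400)
  expect_equal(cardiac_output(tibble::tibble(time_s = t, q_aov = 100),
                              rhythm = rh60), 6)
  expect_equal(cardiac_output(tibble::tibble(time_s = t, q_aov = 0),
                              rhythm = rh60), 0)
  # internal consistency: equals stroke volume times rate on a real run
  sim <- cached_sim("baseline")
  bm <- beat_metrics(sim, beats = 5)
  expect_equal(cardiac_output(sim, beats = 5), mean(bm$cardiac_output),
               tolerance = 0.01)
})

test_that("wave detectors recover fixture peaks within one sample", {
  fx <- generate_fixtures(seed = 1)
  dt <- 1 / 400

  acv <- detect_acv_waves(fx$three_bump$trace, beat = 1, rhythm = rh60)
  expect_setequal(acv$wave, c("a", "c", "v"))
  for (w in c("a", "c", "v")) {
    expect_lt(abs(acv$time_s[acv$wave == w] -
                    fx$three_bump$answers$time_s[fx$three_bump$answers$wave == w]),
              dt + 1e-12)
  }

  ea <- mitral_ea(fx$two_lobe$trace, beat = 1, rhythm = rh60)
  expect_setequal(ea$wave, c("E", "A"))
  for (w in c("E", "A")) {
    expect_lt(abs(ea$time_s[ea$wave == w] -
                    fx$two_lobe$answers$time_s[fx$two_lobe$answers$wave == w]),
              dt + 1e-12)
  }
})

test_that("monotone traces report no waves at all", {
  t <- seq(0, 2, by = 1 / 400)
  mono <- tibble::tibble(time_s = t, p_la = 5 + t)
  expect_equal(nrow(detect_acv_waves(mono, beat = 1, rhythm = rh60)), 0)
})

test_that("flutter abolishes the a-wave and the mitral A peak but keeps E", {
  fl <- cached_sim("flutter150")
  b <- last_beat(fl)
  acv <- detect_acv_waves(fl, beat = b)
  expect_false("a" %in% acv$wave)
  ea <- mitral_ea(fl, beat = b)
  expect_false("A" %in% ea$wave)
  expect_true("E" %in% ea$wave)
})

test_that("sinus rhythm shows a- and v-waves inside their beat interval", {
  sim <- cached_sim("baseline")
  b <- last_beat(sim)
  bt <- attr(sim, "beats")
  acv <- detect_acv_waves(sim, beat = b)
  expect_true(all(c("a", "v") %in% acv$wave))
  expect_true(all(acv$time_s >= bt$t_start[bt$beat == b] &
                    acv$time_s <= bt$t_end[bt$beat == b]))
  ea <- mitral_ea(sim, beat = b)
  expect_true(all(c("E", "A") %in% ea$wave))
  # optional Doppler-style velocity conversion
  eav <- mitral_ea(sim, beat = b, orifice_area_cm2 = 4)
  expect_equal(eav$velocity_cm_s, eav$flow / 4)
})

test_that("identical inflow lobes give a unit E/A ratio", {
  t <- seq(0, 1, by = 1 / 400)
  lobe <- function(center) {
    s <- (t - center) / 0.12 + 0.5
    ifelse(s >= 0 & s <= 1, 200 * sin(pi * s)^2, 0)
  }
  sym <- tibble::tibble(time_s = t, q_mv = lobe(0.475) + lobe(0.84))
  ea <- mitral_ea(sym, beat = 1, rhythm = rh60)
  expect_equal(ea$flow[ea$wave == "E"] / ea$flow[ea$wave == "A"], 1,
               tolerance = 1e-6)
})

test_that("shoelace area is exact and orientation-antisymmetric", {
  # unit square traversed counter-clockwise
  expect_equal(shoelace_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)
  expect_equal(shoelace_area(rev(c(0, 1, 1, 0)), rev(c(0, 0, 1, 1))), -1)
  set.seed(7)
  for (k in 1:20) {
    n <- sample(4:40, 1)
    x <- runif(n)
    y <- runif(n)
    expect_equal(shoelace_area(rev(x), rev(y)), -shoelace_area(x, y),
                 tolerance = 1e-12)
  }
})

test_that("simple and self-intersecting paths decompose as expected", {
  square <- tibble::tibble(volume = c(0, 1, 1, 0), pressure = c(0, 0, 1, 1))
  pl <- pv_loop(square)
  expect_length(pl$subloops, 1)
  expect_equal(pl$subloops[[1]]$area, 1)
  expect_false(pl$figure_eight)
  expect_equal(pl$n_intersections, 0)

  fx <- generate_fixtures(seed = 1)
  bow <- pv_loop(fx$bowtie$path)
  expect_length(bow$subloops, 2)
  areas <- sort(vapply(bow$subloops, `[[`, 0, "area"))
  expect_equal(areas, fx$bowtie$answers$areas, tolerance = 1e-12)
  expect_setequal(vapply(bow$subloops, `[[`, "", "orientation"),
                  c("cw", "ccw"))
  expect_true(bow$figure_eight)
  expect_equal(bow$n_intersections, 1)
  # partition: the sub-loop magnitudes account for the whole swept area
  expect_equal(sum(abs(areas)), 2, tolerance = 1e-9)
  # the crossing point is recovered exactly
  expect_equal(bow$subloops[[1]]$points$volume[1],
               fx$bowtie$answers$crossing[1])
})

test_that("sinus loops are figure-eights and flutter loops are not", {
  pl_s <- pv_loop(cached_sim("baseline"), beat = 29)
  expect_true(pl_s$figure_eight)
  expect_setequal(vapply(pl_s$subloops, `[[`, "", "orientation"),
                  c("cw", "ccw"))
  pl_f <- pv_loop(cached_sim("flutter150"), beat = 70)
  expect_false(pl_f$figure_eight)
})

test_that("appendage ejection fraction follows the printed formula", {
  expect_equal(laa_ejection_fraction(4, 4), 0)
  expect_equal(laa_ejection_fraction(4, 0), 100)
  expect_equal(laa_ejection_fraction(4, 1), 75)
  expect_error(laa_ejection_fraction(0, 0), "undefined")
  expect_error(laa_ejection_fraction(2, 3), "exceed")
  expect_error(laa_ejection_fraction(2, -1), ">= 0")
})
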
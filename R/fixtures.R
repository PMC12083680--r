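## Deterministic analysis fixtures: synthetic traces whose peak and loop
## answers are known analytically, used to validate the detectors without
## running the simulator.

sin2_bump <- function(t, center, width, amp) {
  s <- (t - center) / width + 0.5
  ifelse(s >= 0 & s <= 1, amp * sin(pi * s)^2, 0)
}

#' Generate the packaged fixture set
#'
#' Builds, deterministically from `seed`:
#'
#' * four reference circuits (`baseline_sinus`, `laao`, `flutter_150`,
#'   `af_irregular`);
#' * `three_bump`: a one-beat synthetic LA pressure trace with one bump
#'   centred in each a/c/v classification window, plus its analytic peak
#'   answers;
#' * `two_lobe`: a one-beat synthetic mitral flow trace with an E and an
#'   A lobe, plus analytic answers;
#' * `bowtie`: a self-intersecting pressure-volume path made of two unit
#'   triangles crossing at (1, 1), whose sub-loops have signed areas -1
#'   (clockwise) and +1 (counter-clockwise).
#'
#' Traces carry a small seeded Gaussian jitter (far below the bump
#' curvature scale) so that detection is exercised on non-idealised data
#' while analytic peak locations remain valid to within one sample.
#'
#' @param seed Integer seed for the jitter.
#' @return A list with elements `circuits`, `three_bump`, `two_lobe`,
#'   `bowtie`, `seed`. Each trace element is a list with `trace` (tibble)
#'   and `answers`.
#' @export
generate_fixtures <- function(seed = 1L) {
  set.seed(seed)
  base <- baseline_circuit()
  circuits <- list(baseline_sinus = base,
                   laao = apply_laao(base),
                   flutter_150 = make_flutter(base, 150),
                   af_irregular = make_af(base))

  t <- seq(0, 1, by = 1 / 400)
  acv_centers <- c(a = 0.84, c = 0.075, v = 0.35)
  acv_amps <- c(a = 6, c = 3, v = 8)
  p <- 8 + sin2_bump(t, acv_centers["a"], 0.1, acv_amps["a"]) +
    sin2_bump(t, acv_centers["c"], 0.1, acv_amps["c"]) +
    sin2_bump(t, acv_centers["v"], 0.1, acv_amps["v"]) +
    stats::rnorm(length(t), sd = 0.005)
  three_bump <- list(
    trace = tibble::tibble(time_s = t, p_la = p),
    answers = tibble::tibble(wave = names(acv_centers),
                             time_s = unname(acv_centers),
                             pressure = 8 + unname(acv_amps)))

  ea_centers <- c(E = 0.475, A = 0.84)
  ea_amps <- c(E = 250, A = 150)
  q <- sin2_bump(t, ea_centers["E"], 0.12, ea_amps["E"]) +
    sin2_bump(t, ea_centers["A"], 0.12, ea_amps["A"]) +
    stats::rnorm(length(t), sd = 0.2)
  two_lobe <- list(
    trace = tibble::tibble(time_s = t, q_mv = q),
    answers = tibble::tibble(wave = names(ea_centers),
                             time_s = unname(ea_centers),
                             flow = unname(ea_amps)))

  bowtie <- list(
    path = tibble::tibble(volume = c(0, 2, 2, 0, 0),
                          pressure = c(0, 2, 0, 2, 0)),
    answers = list(crossing = c(1, 1), areas = c(-1, 1),
                   orientations = c("cw", "ccw")))

  list(circuits = circuits, three_bump = three_bump, two_lobe = two_lobe,
       bowtie = bowtie, seed = seed)
}
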
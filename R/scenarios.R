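#' Apply the left atrial appendage occlusion parameter changes
#'
#' Returns a copy of the circuit with the published post-occlusion left
#' atrial constitutive values: reservoir amplitude `a_res` reduced to
#' 0.35 mmHg, reservoir exponent `b_res` raised to 0.07 1/mL, and
#' end-systolic elastance `ees` raised to 0.7 mmHg/mL (reduced appendage
#' reservoir capacity, stiffer passive wall, slightly reduced chamber
#' compliance). The overwrite is absolute, so applying it twice equals
#' applying it once; no other parameter is touched.
#'
#' @param base A [circuit()] object (never mutated).
#' @return A modified copy of `base`.
#' @export
apply_laao <- function(base) {
  stopifnot(inherits(base, "hemo_circuit"))
  la <- base$chambers$LA
  base$chambers$LA <- chamber("LA",
    atrial_law(ees = 0.7, v0 = la$law$v0, a_res = 0.35, b_res = 0.07),
    onset = la$onset, duration = la$duration,
    viscous_resistance = la$viscous_resistance)
  rebuild_circuit(unclass(base))
}

#' Atrial flutter scenario
#'
#' Uniform rhythm at the given rate with atrial contraction disabled
#' (`atrial_active = FALSE`); ventricular activation is unchanged. With no
#' atrial kick the LA pressure-volume loop collapses to the passive
#' v-loop alone.
#'
#' @param base A [circuit()] object.
#' @param rate Ventricular rate, bpm, in `[40, 150]`.
#' @return A modified copy of `base`.
#' @export
make_flutter <- function(base, rate = 150) {
  stopifnot(inherits(base, "hemo_circuit"))
  check_rate(rate)
  period <- 60 / rate
  base$rhythm <- rhythm(cycle_lengths = period, atrial_active = FALSE,
                        av_delay = min(base$rhythm$av_delay, period / 2))
  rebuild_circuit(unclass(base))
}

#' Irregular-cycle atrial fibrillation scenario
#'
#' The rhythm cycles repeatedly through the given cycle lengths (default
#' the 0.375 s / 0.4 s / 0.5 s irregular schedule, mean rate about
#' 141 bpm) with atrial contraction disabled.
#'
#' @param base A [circuit()] object.
#' @param cycle_lengths Positive cycle lengths in seconds; a single entry
#'   reduces to a uniform rhythm.
#' @return A modified copy of `base`.
#' @export
make_af <- function(base, cycle_lengths = c(0.375, 0.4, 0.5)) {
  stopifnot(inherits(base, "hemo_circuit"))
  if (length(cycle_lengths) == 0L)
    stop("`cycle_lengths` must not be empty", call. = FALSE)
  base$rhythm <- rhythm(cycle_lengths = cycle_lengths, atrial_active = FALSE,
                        av_delay = min(base$rhythm$av_delay,
                                       min(cycle_lengths) / 2))
  rebuild_circuit(unclass(base))
}

#' Scale atrial contractility
#'
#' Multiplies the left atrial end-systolic elastance by `k` in `[0, 1]`,
#' leaving the passive parameters untouched. `k = 0` reproduces the
#' flutter-like loss of the atrial kick through the active term alone;
#' `k = 1` is the identity.
#'
#' @param base A [circuit()] object.
#' @param k Contractility fraction in `[0, 1]`.
#' @return A modified copy of `base`.
#' @export
scale_atrial_contractility <- function(base, k) {
  stopifnot(inherits(base, "hemo_circuit"))
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 1)
    stop("`k` must lie in [0, 1]", call. = FALSE)
  la <- base$chambers$LA
  base$chambers$LA <- chamber("LA",
    atrial_law(ees = k * la$law$ees, v0 = la$law$v0,
               a_res = la$law$a_res, b_res = la$law$b_res),
    onset = la$onset, duration = la$duration,
    viscous_resistance = la$viscous_resistance)
  rebuild_circuit(unclass(base))
}

#' Set a uniform heart rate
#'
#' Replaces the rhythm with uniform cycles of `60/bpm` seconds, keeping
#' the atrial-active flag and all activation window fractions.
#'
#' @param base A [circuit()] object.
#' @param bpm Heart rate, `[40, 150]`.
#' @return A modified copy of `base`.
#' @export
set_heart_rate <- function(base, bpm) {
  stopifnot(inherits(base, "hemo_circuit"))
  check_rate(bpm)
  period <- 60 / bpm
  base$rhythm <- rhythm(cycle_lengths = period,
                        atrial_active = base$rhythm$atrial_active,
                        av_delay = min(base$rhythm$av_delay, period / 2))
  rebuild_circuit(unclass(base))
}

#' Sweep a scenario parameter and collect steady-state metrics
#'
#' Runs one simulation per value of a heart-rate or contractility sweep
#' and returns a tibble of summary metrics (one row per run): mean LA
#' pressure, cardiac output, mitral E and A peaks and the LA pressure
#' a-wave peak, from the final-beat analysis window.
#'
#' @param base A [circuit()] object.
#' @param param `"hr"` or `"contractility"`.
#' @param values Sweep values (bpm for `"hr"`, fractions in `[0, 1]` for
#'   `"contractility"`).
#' @param duration,beats Simulation length (s) and analysis window (beats).
#' @param ... Passed on to [simulate_circuit()].
#' @return A tibble with columns `param`, `value`, `mean_lap`,
#'   `cardiac_output`, `e_peak`, `a_flow_peak`, `a_wave_pressure`.
#' @export
sweep_scenario <- function(base, param = c("hr", "contractility"), values,
                           duration = 30, beats = 5, ...) {
  param <- match.arg(param)
  purrr::map_dfr(values, function(val) {
    circ <- switch(param,
                   hr = set_heart_rate(base, val),
                   contractility = scale_atrial_contractility(base, val))
    sim <- simulate_circuit(circ, duration = duration, ...)
    bt <- utils::tail(attr(sim, "beats"), 1)
    ea <- mitral_ea(sim, beat = bt$beat)
    acv <- detect_acv_waves(sim, beat = bt$beat)
    tibble::tibble(
      param = param, value = val,
      mean_lap = mean_lap(sim, beats = beats),
      cardiac_output = cardiac_output(sim, beats = beats),
      e_peak = wave_value(ea, "E", "flow"),
      a_flow_peak = wave_value(ea, "A", "flow"),
      a_wave_pressure = wave_value(acv, "a", "pressure"))
  })
}

wave_value <- function(tbl, which, col) {
  if (!"wave" %in% names(tbl)) return(NA_real_)
  v <- tbl[[col]][tbl$wave == which]
  if (length(v) == 0L) NA_real_ else v
}
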
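#' Chamber pressure from the time-varying elastance law
#'
#' Pressure combines the active end-systolic relation
#' `P_es(v) = ees * (v - v0)` and the passive end-diastolic relation
#' `P_ed(v) = a_res * (exp(b_res * (v - v0)) - 1)` under one of two gating
#' conventions:
#'
#' * `"blended"` (Suga-Sagawa): `P = e * P_es + (1 - e) * P_ed`, so the
#'   passive term is excluded at peak activation;
#' * `"additive"`: `P = e * P_es + P_ed`, i.e. the passive wall stiffness
#'   is always present and activation adds contractile pressure on top.
#'
#' Both reduce to `P_ed` at `e = 0`; they differ only while the chamber is
#' activated.
#'
#' @param v Chamber volume, mL (vectorized). Must be >= 0.
#' @param e Activation in `[0, 1]` (vectorized, recycled against `v`).
#' @param law A [atrial_law()] object.
#' @param gating `"blended"` or `"additive"`.
#' @return Pressure in mmHg, continuous in both `v` and `e`.
#' @examples
#' chamber_pressure(50, e = 0, atrial_law()) # passive reservoir pressure
#' chamber_pressure(10, e = 1, atrial_law()) # pure active, 4.5 mmHg
#' @export
chamber_pressure <- function(v, e, law, gating = c("blended", "additive")) {
  gating <- match.arg(gating)
  stopifnot(inherits(law, "hemo_law"), is.numeric(v), is.numeric(e))
  if (any(!is.finite(e)) || any(e < 0) || any(e > 1))
    stop("activation `e` must lie in [0, 1]", call. = FALSE)
  if (any(v < 0)) stop("`v` must be >= 0 (mL)", call. = FALSE)
  p_es <- law$ees * (v - law$v0)
  p_ed <- law$a_res * expm1(law$b_res * (v - law$v0))
  if (gating == "blended") e * p_es + (1 - e) * p_ed else e * p_es + p_ed
}

#' Activation waveform of a chamber
#'
#' A squared half-sine on the chamber's activation window, expressed in
#' fractions of the current cycle of the rhythm schedule: 0 at the window
#' endpoints and outside, exactly 1 at the midpoint, continuous everywhere.
#' A chamber with a positive `relax_tau` keeps the squared-half-sine
#' upstroke but relaxes exponentially from the peak with that absolute
#' time constant (see [chamber()]). Atrial chambers (LA, RA) return
#' identically 0 when the rhythm has `atrial_active = FALSE`.
#'
#' @param t Time in seconds (vectorized), >= 0.
#' @param chamber A [chamber()] object.
#' @param rhythm A [rhythm()] object giving the cycle schedule.
#' @return Activation values in `[0, 1]`.
#' @export
activation <- function(t, chamber, rhythm) {
  stopifnot(inherits(chamber, "hemo_chamber"), inherits(rhythm, "hemo_rhythm"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (chamber$label %in% c("LA", "RA") && !rhythm$atrial_active)
    return(rep(0, length(t)))
  cl <- rhythm$cycle_lengths
  total <- sum(cl)
  r <- t %% total
  starts <- cumsum(c(0, cl[-length(cl)]))
  idx <- findInterval(r, starts)
  phi <- (r - starts[idx]) / cl[idx]
  activation_wave(phi, cl[idx], chamber$onset, chamber$duration,
                  chamber$relax_tau %||% 0)
}

# activation as a function of cycle phase; tau > 0 swaps the declining
# half of the squared half-sine for an exponential tail from the peak
# (wrapping across the cycle boundary so the waveform stays continuous)
activation_wave <- function(phi, cycle_len, onset, dur, tau) {
  s <- ((phi - onset) %% 1) / dur
  base <- ifelse(s >= 0 & s <= 1, sin(pi * s)^2, 0)
  if (all(tau == 0)) return(base)
  up <- ifelse(s >= 0 & s <= 0.5, sin(pi * s)^2, 0)
  t_since_peak <- ((phi - onset - 0.5 * dur) %% 1) * cycle_len
  tail <- exp(-t_since_peak / pmax(tau, 1e-300))
  ifelse(tau > 0, pmax(up, tail), base)
}

# phase in [0, 1) within the scheduled cycle containing each t
cycle_phase <- function(t, rhythm) {
  cl <- rhythm$cycle_lengths
  total <- sum(cl)
  r <- t %% total
  starts <- cumsum(c(0, cl[-length(cl)]))
  idx <- findInterval(r, starts)
  (r - starts[idx]) / cl[idx]
}

# start times of all cycles covering [0, duration]
cycle_starts <- function(rhythm, duration) {
  cl <- rhythm$cycle_lengths
  reps <- ceiling(duration / sum(cl)) + 1L
  starts <- cumsum(c(0, rep(cl, reps)))
  starts[starts <= duration + 1e-12]
}

#' Flow through an ideal diode valve
#'
#' `max(0, p_up - p_down) / resistance`: linear conductance when open,
#' zero when the downstream pressure exceeds the upstream pressure. Never
#' negative.
#'
#' @param p_up,p_down Upstream and downstream pressures, mmHg (vectorized).
#' @param valve A [valve()] object.
#' @return Flow in mL/s.
#' @export
valve_flow <- function(p_up, p_down, valve) {
  stopifnot(inherits(valve, "hemo_valve"))
  if (any(!is.finite(p_up)) || any(!is.finite(p_down)))
    stop("pressures must be finite", call. = FALSE)
  pmax(0, p_up - p_down) / valve$resistance
}

#' Pressure in a windkessel compartment
#'
#' Linear capacitor: `(v - unstressed) / compliance`.
#'
#' @param v Compartment volume, mL (vectorized), >= 0.
#' @param comp A [vascular()] object.
#' @return Pressure in mmHg.
#' @export
compartment_pressure <- function(v, comp) {
  stopifnot(inherits(comp, "hemo_compartment"))
  if (any(v < 0)) stop("`v` must be >= 0 (mL)", call. = FALSE)
  (v - comp$unstressed) / comp$compliance
}
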
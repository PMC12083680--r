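#' Constitutive parameters for an elastance chamber
#'
#' The chamber pressure-volume relation blends a linear end-systolic law,
#' `ees * (v - v0)`, with an exponential end-diastolic (passive, reservoir)
#' law, `a_res * (exp(b_res * (v - v0)) - 1)`. The same template is used for
#' all four chambers; for the left atrium the defaults are the published
#' baseline values.
#'
#' @param ees End-systolic elastance, mmHg/mL. Must be >= 0.
#' @param v0 Unstressed volume (volume at zero pressure), mL. Must be >= 0.
#' @param a_res Passive-stiffness amplitude, mmHg. Must be >= 0.
#' @param b_res Passive-stiffness exponent, 1/mL. Must be > 0.
#'
#' @return An object of class `hemo_law`: a named list with the four fields.
#' @examples
#' atrial_law() # baseline left atrium
#' atrial_law(ees = 0.7, a_res = 0.35, b_res = 0.07) # post-occlusion LA
#' @export
atrial_law <- function(ees = 0.45, v0 = 0, a_res = 0.5, b_res = 0.049) {
  stopifnot(is.numeric(ees), length(ees) == 1L, is.finite(ees),
            is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(a_res), length(a_res) == 1L, is.finite(a_res),
            is.numeric(b_res), length(b_res) == 1L, is.finite(b_res))
  if (ees < 0) stop("`ees` must be >= 0 (mmHg/mL)", call. = FALSE)
  if (v0 < 0) stop("`v0` must be >= 0 (mL)", call. = FALSE)
  if (a_res < 0) stop("`a_res` must be >= 0 (mmHg)", call. = FALSE)
  if (b_res <= 0) stop("`b_res` must be > 0 (1/mL)", call. = FALSE)
  structure(list(ees = ees, v0 = v0, a_res = a_res, b_res = b_res),
            class = "hemo_law")
}

CHAMBER_LABELS <- c("LA", "LV", "RA", "RV")
VALVE_LABELS <- c("MV", "AoV", "TV", "PuV")
COMPARTMENT_LABELS <- c("SA", "SV", "PA", "PV")

#' Chamber definition: constitutive law plus activation window
#'
#' Activation is a squared half-sine within `[onset, onset + duration]`
#' (fractions of the cardiac cycle, interpreted modulo 1 so a window may
#' wrap across the cycle boundary). It peaks at exactly 1 at the window
#' midpoint and is 0 outside.
#'
#' @param label One of `"LA"`, `"LV"`, `"RA"`, `"RV"`.
#' @param law A [atrial_law()] object.
#' @param onset Activation onset as a fraction of the cycle, in `[0, 1)`.
#' @param duration Activation duration as a fraction of the cycle, in `(0, 1]`.
#' @param viscous_resistance Wall viscoelastic resistance, mmHg*s/mL,
#'   >= 0. During simulation the chamber pressure is
#'   `P_elastic(v, e) + viscous_resistance * dv/dt`, which gives the
#'   atrial reservoir/conduit phases their measured hysteresis (the
#'   passive v-loop). Only atrial chambers (LA, RA) may be viscous; the
#'   ventricles, whose active pressures dwarf the viscous term, must use 0.
#' @param relax_tau Isovolumic relaxation time constant, seconds, >= 0.
#'   When positive, activation rises as a squared half-sine to its peak at
#'   the window midpoint and then decays exponentially with this absolute
#'   time constant instead of mirroring the upstroke. Because the constant
#'   is absolute, relaxation consumes a growing share of diastole at fast
#'   rates, reproducing the rate-dependent filling impairment of rapid
#'   ventricular response. 0 keeps the pure squared half-sine.
#' @return An object of class `hemo_chamber`.
#' @export
chamber <- function(label, law, onset = 0, duration = 0.3,
                    viscous_resistance = 0, relax_tau = 0) {
  label <- match.arg(label, CHAMBER_LABELS)
  stopifnot(inherits(law, "hemo_law"))
  if (!is.numeric(onset) || onset < 0 || onset >= 1)
    stop("`onset` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0 || duration > 1)
    stop("`duration` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(viscous_resistance) || viscous_resistance < 0)
    stop("`viscous_resistance` must be >= 0 (mmHg*s/mL)", call. = FALSE)
  if (viscous_resistance > 0 && label %in% c("LV", "RV"))
    stop("`viscous_resistance` is only supported for atrial chambers",
         call. = FALSE)
  if (!is.numeric(relax_tau) || relax_tau < 0)
    stop("`relax_tau` must be >= 0 (s)", call. = FALSE)
  structure(list(label = label, law = law, onset = onset, duration = duration,
                 viscous_resistance = viscous_resistance,
                 relax_tau = relax_tau),
            class = "hemo_chamber")
}

#' Ideal diode valve
#'
#' @param label One of `"MV"`, `"AoV"`, `"TV"`, `"PuV"` (mitral, aortic,
#'   tricuspid, pulmonary).
#' @param resistance Forward-flow resistance, mmHg*s/mL. Must be > 0;
#'   backflow is never permitted.
#' @return An object of class `hemo_valve`.
#' @export
valve <- function(label, resistance) {
  label <- match.arg(label, VALVE_LABELS)
  if (!is.numeric(resistance) || resistance <= 0)
    stop("`resistance` must be > 0 (mmHg*s/mL)", call. = FALSE)
  structure(list(label = label, resistance = resistance), class = "hemo_valve")
}

#' Windkessel vascular compartment
#'
#' A linear capacitor with a series outflow resistance. Pressure is
#' `(v - unstressed) / compliance`; the outflow resistor connects the
#' compartment to the next element in the fixed loop topology and carries
#' flow in either direction.
#'
#' @param label One of `"SA"`, `"SV"`, `"PA"`, `"PV"` (systemic arterial,
#'   systemic venous, pulmonary arterial, pulmonary venous).
#' @param compliance mL/mmHg, > 0.
#' @param resistance Outflow resistance, mmHg*s/mL, > 0.
#' @param unstressed Unstressed volume, mL, >= 0.
#' @return An object of class `hemo_compartment`.
#' @export
vascular <- function(label, compliance, resistance, unstressed = 0) {
  label <- match.arg(label, COMPARTMENT_LABELS)
  if (!is.numeric(compliance) || compliance <= 0)
    stop("`compliance` must be > 0 (mL/mmHg)", call. = FALSE)
  if (!is.numeric(resistance) || resistance <= 0)
    stop("`resistance` must be > 0 (mmHg*s/mL)", call. = FALSE)
  if (!is.numeric(unstressed) || unstressed < 0)
    stop("`unstressed` must be >= 0 (mL)", call. = FALSE)
  structure(list(label = label, compliance = compliance,
                 resistance = resistance, unstressed = unstressed),
            class = "hemo_compartment")
}

#' Rhythm schedule
#'
#' Cycle lengths are repeated cyclically for the whole simulation, so a
#' single entry gives a uniform rhythm and the three-entry irregular
#' schedule `c(0.375, 0.4, 0.5)` reproduces the fibrillation cycle pattern.
#' `av_delay` is the time by which the atrial activation peak precedes the
#' next ventricular onset (the atrial kick lands in late diastole).
#'
#' @param cycle_lengths Numeric vector of cycle lengths in seconds, all > 0.
#' @param atrial_active Logical; `FALSE` disables atrial contraction
#'   entirely (flutter / fibrillation).
#' @param av_delay Seconds, >= 0 and smaller than the shortest cycle.
#' @return An object of class `hemo_rhythm`.
#' @export
rhythm <- function(cycle_lengths = 1, atrial_active = TRUE, av_delay = 0.16) {
  if (length(cycle_lengths) == 0L)
    stop("`cycle_lengths` must not be empty", call. = FALSE)
  if (!is.numeric(cycle_lengths) || any(!is.finite(cycle_lengths)) ||
      any(cycle_lengths <= 0))
    stop("every cycle length must be a positive, finite number of seconds",
         call. = FALSE)
  stopifnot(is.logical(atrial_active), length(atrial_active) == 1L)
  if (!is.numeric(av_delay) || av_delay < 0 || av_delay >= min(cycle_lengths))
    stop("`av_delay` must be >= 0 and smaller than the shortest cycle length",
         call. = FALSE)
  structure(list(cycle_lengths = as.numeric(cycle_lengths),
                 atrial_active = atrial_active, av_delay = av_delay),
            class = "hemo_rhythm")
}

#' Closed-loop circuit parameters
#'
#' Assembles four elastance chambers, four windkessel compartments, four
#' diode valves and a rhythm schedule into the fixed loop
#' PV -> LA -> MV -> LV -> AoV -> SA -> SV -> RA -> TV -> RV -> PuV -> PA -> PV.
#' Total blood volume is conserved exactly by construction.
#'
#' @param chambers Named list of four [chamber()] objects (names LA, LV, RA, RV).
#' @param compartments Named list of four [vascular()] objects (SA, SV, PA, PV).
#' @param valves Named list of four [valve()] objects (MV, AoV, TV, PuV).
#' @param rhythm A [rhythm()] object.
#' @param total_volume Total blood volume, mL; must exceed the sum of all
#'   unstressed volumes.
#' @param gating `"additive"` (passive term always active, the default for
#'   the packaged reference circuit) or `"blended"` (passive term weighted
#'   by `1 - e(t)`); see [chamber_pressure()].
#' @return An object of class `hemo_circuit`.
#' @seealso [baseline_circuit()] for the packaged reference parameterization.
#' @export
circuit <- function(chambers, compartments, valves, rhythm, total_volume,
                    gating = c("additive", "blended")) {
  gating <- match.arg(gating)
  check_set <- function(x, labels, what, cls) {
    if (!is.list(x) || length(x) != 4L || !all(vapply(x, inherits, TRUE, cls)))
      stop(sprintf("`%s` must be a list of four %s objects", what, cls),
           call. = FALSE)
    got <- vapply(x, `[[`, "", "label")
    if (!setequal(got, labels) || anyDuplicated(got))
      stop(sprintf("`%s` labels must be exactly {%s}, each once", what,
                   paste(labels, collapse = ", ")), call. = FALSE)
    stats::setNames(x[match(labels, got)], labels)
  }
  chambers <- check_set(chambers, CHAMBER_LABELS, "chambers", "hemo_chamber")
  compartments <- check_set(compartments, COMPARTMENT_LABELS, "compartments",
                            "hemo_compartment")
  valves <- check_set(valves, VALVE_LABELS, "valves", "hemo_valve")
  stopifnot(inherits(rhythm, "hemo_rhythm"))
  unstressed <- sum(vapply(chambers, function(ch) ch$law$v0, 0)) +
    sum(vapply(compartments, `[[`, 0, "unstressed"))
  if (!is.numeric(total_volume) || total_volume <= unstressed)
    stop(sprintf(
      "`total_volume` (%.1f mL) must exceed the summed unstressed volumes (%.1f mL)",
      total_volume, unstressed), call. = FALSE)
  structure(list(chambers = chambers, compartments = compartments,
                 valves = valves, rhythm = rhythm,
                 total_volume = total_volume, gating = gating),
            class = "hemo_circuit")
}

#' Packaged reference circuit
#'
#' A calibrated stand-in parameterization of the closed loop at a given
#' heart rate. The four left atrial constitutive values are the published
#' baseline inputs (ees 0.45 mmHg/mL, v0 0 mL, a_res 0.5 mmHg,
#' b_res 0.049 1/mL); every other element is a synthetic calibration chosen
#' to give left-sided hemodynamics typical of an elderly occlusion
#' candidate with diastolic dysfunction: cardiac output near 5 L/min,
#' aortic pressure near 120/70 mmHg and a mean left atrial pressure in the
#' high teens at 60 bpm.
#'
#' @param heart_rate Uniform heart rate, beats per minute, in `[40, 150]`.
#' @param total_volume Total blood volume, mL.
#' @param gating Constitutive gating convention, see [circuit()].
#' @return A `hemo_circuit` object.
#' @examples
#' base <- baseline_circuit()
#' base$chambers$LA$law$ees
#' @export
baseline_circuit <- function(heart_rate = 60, total_volume = 3600,
                             gating = "additive") {
  check_rate(heart_rate)
  period <- 60 / heart_rate
  av_delay <- 0.16
  a_dur <- 0.2
  a_onset <- (1 - av_delay / period - a_dur / 2) %% 1
  chambers <- list(
    chamber("LA", atrial_law(), onset = a_onset, duration = a_dur,
            viscous_resistance = 0.01),
    chamber("LV", atrial_law(ees = 2.5, v0 = 5, a_res = 0.35, b_res = 0.033),
            onset = 0, duration = 0.3, relax_tau = 0.12),
    chamber("RA", atrial_law(ees = 0.3, v0 = 0, a_res = 0.4, b_res = 0.04),
            onset = a_onset, duration = a_dur, viscous_resistance = 0.01),
    chamber("RV", atrial_law(ees = 0.6, v0 = 5, a_res = 0.1, b_res = 0.025),
            onset = 0, duration = 0.3, relax_tau = 0.12))
  compartments <- list(
    vascular("SA", compliance = 1.6, resistance = 1.0, unstressed = 300),
    vascular("SV", compliance = 50, resistance = 0.05, unstressed = 2000),
    vascular("PA", compliance = 5.0, resistance = 0.10, unstressed = 50),
    vascular("PV", compliance = 0.8, resistance = 0.01, unstressed = 300))
  valves <- list(
    valve("MV", 0.01), valve("AoV", 0.006),
    valve("TV", 0.005), valve("PuV", 0.003))
  circuit(chambers, compartments, valves,
          rhythm(cycle_lengths = period, av_delay = av_delay),
          total_volume = total_volume, gating = gating)
}

check_rate <- function(bpm) {
  if (!is.numeric(bpm) || length(bpm) != 1L || bpm < 40 || bpm > 150)
    stop("heart rate must lie in [40, 150] bpm", call. = FALSE)
  invisible(bpm)
}

#' @export
print.hemo_circuit <- function(x, ...) {
  rh <- x$rhythm
  cat("<hemo_circuit>\n")
  cat(sprintf("  rhythm: %s, atrial %s, av_delay %.2f s\n",
              if (length(rh$cycle_lengths) == 1L)
                sprintf("uniform %.0f bpm", 60 / rh$cycle_lengths)
              else paste0("schedule {", paste(rh$cycle_lengths, collapse = ", "), "} s"),
              if (rh$atrial_active) "active" else "inactive", rh$av_delay))
  la <- x$chambers$LA$law
  cat(sprintf("  LA law: ees %.3g, v0 %.3g, a_res %.3g, b_res %.3g (%s gating)\n",
              la$ees, la$v0, la$a_res, la$b_res, x$gating))
  cat(sprintf("  total volume: %.0f mL\n", x$total_volume))
  invisible(x)
}

## parameter-path access used by calibration and scenario code -------------

#' Get or set a circuit parameter by path
#'
#' Paths are dot-separated, e.g. `"chambers.LV.law.ees"`,
#' `"compartments.SA.resistance"`, `"valves.MV.resistance"` or
#' `"total_volume"`. Setting re-validates the whole circuit.
#'
#' @param circuit A `hemo_circuit`.
#' @param path Character scalar path.
#' @param value Replacement numeric value (for `circuit_set`).
#' @return `circuit_get` returns the numeric value; `circuit_set` returns a
#'   modified copy of the circuit (the input is never mutated).
#' @export
circuit_get <- function(circuit, path) {
  stopifnot(inherits(circuit, "hemo_circuit"))
  out <- purrr::reduce(strsplit(path, ".", fixed = TRUE)[[1]],
                       function(x, nm) {
                         if (is.null(x[[nm]]))
                           stop(sprintf("no parameter at path '%s'", path),
                                call. = FALSE)
                         x[[nm]]
                       }, .init = unclass_deep(circuit))
  if (!is.numeric(out) || length(out) != 1L)
    stop(sprintf("path '%s' does not address a scalar parameter", path),
         call. = FALSE)
  out
}

#' @rdname circuit_get
#' @export
circuit_set <- function(circuit, path, value) {
  stopifnot(inherits(circuit, "hemo_circuit"), is.numeric(value),
            length(value) == 1L)
  circuit_get(circuit, path) # validates the path
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  raw <- unclass(circuit)
  raw[[parts]] <- value
  rebuild_circuit(raw)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

# revalidate a plain list through the public constructors
rebuild_circuit <- function(raw) {
  chambers <- lapply(raw$chambers, function(ch)
    chamber(ch$label, atrial_law(ch$law$ees, ch$law$v0, ch$law$a_res, ch$law$b_res),
            onset = ch$onset, duration = ch$duration,
            viscous_resistance = ch$viscous_resistance %||% 0,
            relax_tau = ch$relax_tau %||% 0))
  compartments <- lapply(raw$compartments, function(cp)
    vascular(cp$label, cp$compliance, cp$resistance, cp$unstressed))
  valves <- lapply(raw$valves, function(vv) valve(vv$label, vv$resistance))
  rh <- rhythm(raw$rhythm$cycle_lengths, raw$rhythm$atrial_active,
               raw$rhythm$av_delay)
  circuit(chambers, compartments, valves, rh, raw$total_volume,
          gating = raw$gating)
}
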
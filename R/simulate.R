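#' State derivatives of the closed loop
#'
#' The state is the vector of the 8 storage-element volumes in topology
#' order (LA, LV, RA, RV, SA, SV, PA, PV). Each element's rate of change is
#' inflow minus outflow along the fixed loop
#' PV -> LA -> MV -> LV -> AoV -> SA -> SV -> RA -> TV -> RV -> PuV -> PA -> PV,
#' so the components sum to exactly zero and total blood volume is
#' conserved by construction.
#'
#' @param t Time, seconds.
#' @param state Named or unnamed numeric vector of 8 volumes, mL.
#' @param circuit A [circuit()] object.
#' @return Named list with `dvdt` (8 derivatives, mL/s), `pressures`
#'   (mmHg) and `flows` (mL/s, the 4 valve and 4 resistor edges).
#' @export
derivatives <- function(t, state, circuit) {
  stopifnot(inherits(circuit, "hemo_circuit"), length(state) == 8L)
  f <- build_deriv(circuit)
  res <- f(t, as.numeric(state))
  list(dvdt = stats::setNames(res[[1]], paste0("v_", ELEMENTS)),
       pressures = res[[2]][paste0("p_", ELEMENTS)],
       flows = res[[2]][paste0("q_", EDGES)])
}

ELEMENTS <- c("la", "lv", "ra", "rv", "sa", "sv", "pa", "pv")
EDGES <- c("mv", "aov", "tv", "puv", "sa", "sv", "pa", "pv")

# compile a fast closure for the ODE right-hand side
build_deriv <- function(circuit) {
  ch <- circuit$chambers
  law <- function(nm, f) vapply(ch, function(x) x$law[[nm]], 0)[f]
  ees <- vapply(ch, function(x) x$law$ees, 0)
  v0 <- vapply(ch, function(x) x$law$v0, 0)
  a_res <- vapply(ch, function(x) x$law$a_res, 0)
  b_res <- vapply(ch, function(x) x$law$b_res, 0)
  onset <- vapply(ch, `[[`, 0, "onset")
  dur <- vapply(ch, `[[`, 0, "duration")
  tau <- vapply(ch, function(x) x$relax_tau %||% 0, 0)
  cp <- circuit$compartments
  C <- unname(vapply(cp, `[[`, 0, "compliance"))
  Vu <- unname(vapply(cp, `[[`, 0, "unstressed"))
  Rout <- unname(vapply(cp, `[[`, 0, "resistance"))
  Rv <- unname(vapply(circuit$valves, `[[`, 0, "resistance"))
  Rw_la <- ch$LA$viscous_resistance
  Rw_ra <- ch$RA$viscous_resistance
  cl <- circuit$rhythm$cycle_lengths
  sched <- sum(cl)
  starts <- cumsum(c(0, cl[-length(cl)]))
  atrial_on <- circuit$rhythm$atrial_active
  additive <- circuit$gating == "additive"

  # atrial wall viscoelasticity: P = P_el + Rw * dV/dt with
  # dV/dt = (P_in - P)/R_in - max(0, P - P_down)/R_valve, solved exactly
  # (piecewise linear and monotone in P, so one case is consistent)
  solve_viscous <- function(p_el, rw, p_in, r_in, p_down, r_valve) {
    a <- rw / r_in
    p_closed <- (p_el + a * p_in) / (1 + a)
    if (p_closed <= p_down) return(p_closed)
    b <- rw / r_valve
    (p_el + a * p_in + b * p_down) / (1 + a + b)
  }

  function(t, y) {
    r <- t %% sched
    i <- findInterval(r, starts)
    phi <- (r - starts[i]) / cl[i]
    e <- activation_wave(phi, cl[i], onset, dur, tau)
    if (!atrial_on) e[c(1L, 3L)] <- 0
    vc <- y[1:4]
    p_es <- ees * (vc - v0)
    p_ed <- a_res * expm1(b_res * (vc - v0))
    pch <- if (additive) e * p_es + p_ed else e * p_es + (1 - e) * p_ed
    pco <- (y[5:8] - Vu) / C
    p <- unname(c(pch, pco)) # la lv ra rv sa sv pa pv
    if (Rw_la > 0)
      p[1] <- solve_viscous(p[1], Rw_la, p[8], Rout[4], p[2], Rv[1])
    if (Rw_ra > 0)
      p[3] <- solve_viscous(p[3], Rw_ra, p[6], Rout[2], p[4], Rv[3])
    if (any(!is.finite(p)))
      stop(sprintf("integration failure: non-finite pressure at t = %.4f s", t),
           call. = FALSE)
    q_mv <- max(0, p[1] - p[2]) / Rv[1]
    q_aov <- max(0, p[2] - p[5]) / Rv[2]
    q_tv <- max(0, p[3] - p[4]) / Rv[3]
    q_puv <- max(0, p[4] - p[7]) / Rv[4]
    q_sa <- (p[5] - p[6]) / Rout[1]
    q_sv <- (p[6] - p[3]) / Rout[2]
    q_pa <- (p[7] - p[8]) / Rout[3]
    q_pv <- (p[8] - p[1]) / Rout[4]
    dv <- c(q_pv - q_mv, q_mv - q_aov, q_sv - q_tv, q_tv - q_puv,
            q_aov - q_sa, q_sa - q_sv, q_puv - q_pa, q_pa - q_pv)
    list(dv, c(p_la = p[1], p_lv = p[2], p_ra = p[3], p_rv = p[4],
               p_sa = p[5], p_sv = p[6], p_pa = p[7], p_pv = p[8],
               q_mv = q_mv, q_aov = q_aov, q_tv = q_tv, q_puv = q_puv,
               q_sa = q_sa, q_sv = q_sv, q_pa = q_pa, q_pv = q_pv))
  }
}

# initial condition: unstressed volumes plus the stressed volume spread
# over elements by an effective-compliance weight evaluated near a nominal
# 10 mmHg filling pressure (transients are discarded, so this only needs
# to start the solver inside the basin of the periodic orbit)
initial_state <- function(circuit) {
  ch <- circuit$chambers
  ees <- vapply(ch, function(x) x$law$ees, 0)
  v0 <- vapply(ch, function(x) x$law$v0, 0)
  a_res <- vapply(ch, function(x) x$law$a_res, 0)
  b_res <- vapply(ch, function(x) x$law$b_res, 0)
  C <- vapply(circuit$compartments, `[[`, 0, "compliance")
  Vu <- vapply(circuit$compartments, `[[`, 0, "unstressed")
  w <- c(1 / (ees + b_res * (10 + a_res)), C)
  stressed <- circuit$total_volume - sum(v0) - sum(Vu)
  stats::setNames(c(v0, Vu) + stressed * w / sum(w), paste0("v_", ELEMENTS))
}

#' Simulate the closed loop to periodic steady state
#'
#' Integrates the 8-volume ODE system with a stiff-capable implicit solver
#' (default `"lsoda"`, which switches to a BDF method on stiffness, in the
#' spirit of `ode15s`) and samples the trajectory densely, 200 points per
#' scheduled cycle, with every beat boundary an exact sample point.
#'
#' @param circuit A [circuit()] object.
#' @param duration Simulated time, seconds (default 30). Must cover at
#'   least two scheduled cycles.
#' @param points_per_beat Samples per cycle (>= 200 recommended).
#' @param method deSolve integrator name (`"lsoda"`, `"bdf"`, ...).
#' @param rtol,atol Solver tolerances.
#' @param init Optional named initial volume vector (`v_la`, ..., `v_pv`,
#'   mL) overriding the default compliance-weighted distribution; it must
#'   sum to the circuit's total volume.
#' @return A tibble of class `hemo_sim` with columns `time_s`,
#'   `v_<element>`, `p_<element>` and `q_<edge>` for the 8 elements
#'   (la, lv, ra, rv, sa, sv, pa, pv) and 8 edges (mv, aov, tv, puv, sa,
#'   sv, pa, pv), plus attributes `circuit`, `beats` (see
#'   [segment_beats()]) and `solver` (tolerances, method, step diagnostics).
#' @examples
#' \donttest{
#' sim <- simulate_circuit(baseline_circuit(), duration = 10)
#' mean_lap(sim, beats = 3)
#' }
#' @export
simulate_circuit <- function(circuit, duration = 30, points_per_beat = 200,
                             method = "lsoda", rtol = 1e-7, atol = 1e-7,
                             init = NULL) {
  stopifnot(inherits(circuit, "hemo_circuit"))
  if (duration < 2 * max(circuit$rhythm$cycle_lengths))
    stop("`duration` must cover at least two scheduled cycles", call. = FALSE)
  starts <- cycle_starts(circuit$rhythm, duration)
  times <- unlist(purrr::map2(
    starts, c(starts[-1], duration),
    function(a, b) if (b > a) seq(a, b, length.out = max(2L, ceiling(points_per_beat * (b - a) / min(circuit$rhythm$cycle_lengths))) + 1L)[-1] else numeric()))
  times <- c(0, times)
  f <- build_deriv(circuit)
  y0 <- initial_state(circuit)
  if (!is.null(init)) {
    stopifnot(length(init) == 8L)
    if (abs(sum(init) - circuit$total_volume) > 1e-6)
      stop("`init` must sum to the circuit's total volume", call. = FALSE)
    y0 <- stats::setNames(as.numeric(init), names(y0))
  }
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, parms) f(t, y),
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  diag <- attributes(sol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("solver failed to converge; last valid time %.4f s",
                 max(sol[, 1])), call. = FALSE)
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(out)[1] <- "time_s"
  beats <- beat_table(circuit$rhythm, duration)
  structure(out,
            class = c("hemo_sim", class(out)),
            circuit = circuit, beats = beats,
            solver = list(method = method, rtol = rtol, atol = atol,
                          steps = unname(diag$istate[3]),
                          points_per_beat = points_per_beat))
}

beat_table <- function(rhythm, duration) {
  starts <- cycle_starts(rhythm, duration)
  cl <- rep(rhythm$cycle_lengths, length.out = length(starts))
  keep <- starts + cl <= duration + 1e-9
  tibble::tibble(beat = seq_len(sum(keep)),
                 t_start = starts[keep],
                 t_end = (starts + cl)[keep],
                 cycle_length = cl[keep])
}

#' Beat boundaries of a simulation
#'
#' Beats are the scheduled rhythm cycles (boundaries at ventricular
#' activation onset); intervals tile the trajectory and each matches its
#' scheduled cycle length.
#'
#' @param result A `hemo_sim` object, or any data frame with a `time_s`
#'   column if `rhythm` is supplied.
#' @param rhythm A [rhythm()] object; defaults to the schedule stored in
#'   `result`.
#' @return Tibble with columns `beat`, `t_start`, `t_end`, `cycle_length`.
#' @export
segment_beats <- function(result, rhythm = NULL) {
  rhythm <- rhythm %||% attr(result, "circuit")$rhythm
  if (is.null(rhythm))
    stop("supply `rhythm` for traces without an embedded circuit", call. = FALSE)
  duration <- max(result$time_s)
  if (duration < 2 * max(rhythm$cycle_lengths))
    stop("trace must span at least two cycles", call. = FALSE)
  beat_table(rhythm, duration)
}

#' Periodic steady-state drift
#'
#' The maximum absolute beat-to-beat change of any element's end-cycle
#' volume over the final three complete cycles (for irregular rhythms,
#' over the final three complete repetitions of the whole schedule, so
#' like is compared with like). Values below about 0.5 mL per element
#' indicate the run has reached its periodic orbit.
#'
#' @param result A `hemo_sim` object.
#' @return Nonnegative scalar, mL. A warning (not an error) is raised when
#'   the drift exceeds 0.5 mL.
#' @export
periodicity_drift <- function(result) {
  stopifnot(inherits(result, "hemo_sim"))
  circuit <- attr(result, "circuit")
  cl <- circuit$rhythm$cycle_lengths
  period <- sum(cl)
  duration <- max(result$time_s)
  n_rep <- floor(duration / period + 1e-9)
  if (n_rep < 4)
    stop("need at least 4 complete schedule repetitions", call. = FALSE)
  marks <- period * (n_rep - 3):n_rep
  vcols <- paste0("v_", ELEMENTS)
  idx <- vapply(marks, function(m) which.min(abs(result$time_s - m)), 0L)
  vols <- as.matrix(result[idx, vcols])
  drift <- max(abs(diff(vols)))
  if (drift > 0.5)
    warning(sprintf("beat-to-beat drift %.3f mL exceeds 0.5 mL: run longer to reach periodic steady state", drift), call. = FALSE)
  drift
}

#' @importFrom rlang %||%
NULL
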
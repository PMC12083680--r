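## Hemodynamic metrics computed from simulated or imported traces.
## Every function accepts either a `hemo_sim` (rhythm and windows are taken
## from the embedded circuit) or a plain data frame with a `time_s` column
## plus the needed traces together with an explicit `rhythm`.

resolve_rhythm <- function(result, rhythm) {
  rhythm %||% attr(result, "circuit")$rhythm %||%
    stop("supply `rhythm` for traces without an embedded circuit",
         call. = FALSE)
}

need_cols <- function(result, cols) {
  missing <- setdiff(cols, names(result))
  if (length(missing))
    stop("trace is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(result)
}

# rows of the final `beats` complete beats (integer-beat window)
final_window <- function(result, rhythm, beats) {
  bt <- beat_table(rhythm, max(result$time_s))
  if (beats < 1 || beats > nrow(bt))
    stop(sprintf("window of %s beats not available (%d complete beats simulated)",
                 beats, nrow(bt)), call. = FALSE)
  bt <- utils::tail(bt, beats)
  list(rows = result$time_s >= bt$t_start[1] - 1e-9 &
         result$time_s <= bt$t_end[nrow(bt)] + 1e-9,
       beats = bt)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Mean left atrial pressure
#'
#' Time-weighted (trapezoidal) mean of the LA pressure trace over the
#' final `beats` complete beats.
#'
#' @param result A `hemo_sim` or data frame with `time_s` and `p_la`.
#' @param beats Number of final complete beats in the averaging window
#'   (>= 1).
#' @param rhythm Optional [rhythm()] for plain data-frame input.
#' @return Mean LA pressure, mmHg.
#' @export
mean_lap <- function(result, beats = 5, rhythm = NULL) {
  need_cols(result, c("time_s", "p_la"))
  rhythm <- resolve_rhythm(result, rhythm)
  w <- final_window(result, rhythm, beats)
  t <- result$time_s[w$rows]
  trapz(t, result$p_la[w$rows]) / (max(t) - min(t))
}

#' Cardiac output from aortic valve flow
#'
#' Mean aortic flow over an integer number of final beats, converted to
#' L/min.
#'
#' @inheritParams mean_lap
#' @return Cardiac output, L/min.
#' @export
cardiac_output <- function(result, beats = 5, rhythm = NULL) {
  need_cols(result, c("time_s", "q_aov"))
  rhythm <- resolve_rhythm(result, rhythm)
  w <- final_window(result, rhythm, beats)
  t <- result$time_s[w$rows]
  trapz(t, result$q_aov[w$rows]) / (max(t) - min(t)) * 60 / 1000
}

# indices of strict local maxima of y (interior points only)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  i <- 2:(n - 1)
  i[y[i] > y[i - 1] & y[i] >= y[i + 1] | y[i] >= y[i - 1] & y[i] > y[i + 1]]
}

beat_slice <- function(result, rhythm, beat) {
  bt <- beat_table(rhythm, max(result$time_s))
  if (!beat %in% bt$beat)
    stop(sprintf("beat %s not available (%d complete beats)", beat, nrow(bt)),
         call. = FALSE)
  b <- bt[bt$beat == beat, ]
  rows <- result$time_s >= b$t_start - 1e-9 & result$time_s <= b$t_end + 1e-9
  list(rows = rows, t0 = b$t_start, len = b$cycle_length)
}

# default classification windows (cycle fractions) from a circuit, or the
# canonical reference timing when none is available
acv_windows <- function(circuit, mv_open = NULL) {
  if (!is.null(circuit)) {
    la <- circuit$chambers$LA
    lv <- circuit$chambers$LV
    a <- c(la$onset, la$onset + la$duration)
    cw <- c(lv$onset, lv$onset + 0.15)
    v <- c(lv$onset + 0.15, mv_open %||% (lv$onset + lv$duration + 0.25))
  } else {
    a <- c(0.74, 0.94)
    cw <- c(0, 0.15)
    v <- c(0.15, mv_open %||% 0.55)
  }
  list(a = a, c = cw, v = v)
}

# largest local maximum inside a cycle-fraction window; the window may
# wrap past 1 (e.g. an atrial window crossing the beat boundary)
pick_peak <- function(phase, y, window) {
  in_win <- if (window[2] <= 1)
    phase >= window[1] & phase <= window[2]
  else
    phase >= window[1] | phase <= window[2] - 1
  cand <- intersect(local_maxima(y), which(in_win))
  if (length(cand) == 0L) return(NULL)
  cand[which.max(y[cand])]
}

#' Detect a-, c- and v-waves on a left atrial pressure trace
#'
#' Local maxima of the LA pressure within one beat are classified by
#' timing: the a-wave (atrial pump) inside the atrial activation window,
#' the c-wave (mitral bulging) in the first 15% of the cycle after
#' ventricular onset, and the v-wave (reservoir filling) in late
#' ventricular systole up to mitral opening (taken from the mitral flow
#' trace when available). Absence of a wave is a valid result: a monotone
#' trace reports no peaks and flutter reports no a-wave.
#'
#' @param result A `hemo_sim` or data frame with `time_s` and `p_la`
#'   (optionally `q_mv` to locate mitral opening).
#' @param beat Beat number to analyse (see [segment_beats()]).
#' @param rhythm Optional [rhythm()] for plain data-frame input.
#' @return Tibble with columns `wave` (`"a"`, `"c"`, `"v"`), `time_s` and
#'   `pressure`; waves that are not detected are simply absent.
#' @export
detect_acv_waves <- function(result, beat = 1, rhythm = NULL) {
  need_cols(result, c("time_s", "p_la"))
  rhythm <- resolve_rhythm(result, rhythm)
  circuit <- attr(result, "circuit")
  sl <- beat_slice(result, rhythm, beat)
  t <- result$time_s[sl$rows]
  p <- result$p_la[sl$rows]
  phase <- (t - sl$t0) / sl$len
  mv_open <- NULL
  if ("q_mv" %in% names(result)) {
    q <- result$q_mv[sl$rows]
    open_idx <- which(phase > 0.15 & q > 0.02 * max(q))
    if (length(open_idx)) mv_open <- phase[open_idx[1]]
  }
  win <- acv_windows(circuit, mv_open)
  atrial_on <- rhythm$atrial_active
  rows <- list()
  if (atrial_on) {
    ia <- pick_peak(phase, p, win$a)
    if (!is.null(ia)) rows$a <- tibble::tibble(wave = "a", time_s = t[ia],
                                               pressure = p[ia])
  }
  ic <- pick_peak(phase, p, win$c)
  if (!is.null(ic)) rows$c <- tibble::tibble(wave = "c", time_s = t[ic],
                                             pressure = p[ic])
  iv <- pick_peak(phase, p, win$v)
  if (!is.null(iv)) rows$v <- tibble::tibble(wave = "v", time_s = t[iv],
                                             pressure = p[iv])
  dplyr::bind_rows(c(list(tibble::tibble(wave = character(),
                                         time_s = numeric(),
                                         pressure = numeric())), rows))
}

#' Mitral inflow E and A peaks
#'
#' E is the largest local maximum of mitral flow in early diastole — the
#' first half of the diastolic interval, which starts at measured mitral
#' opening; when atrial contraction is disabled there is no A wave to
#' separate from, and E is sought over the whole diastolic interval. A is
#' the largest local maximum inside the atrial activation window,
#' reported as absent whenever atrial contraction is disabled or no
#' distinct peak exists.
#'
#' @param result A `hemo_sim` or data frame with `time_s` and `q_mv`.
#' @param beat Beat number to analyse.
#' @param rhythm Optional [rhythm()] for plain data-frame input.
#' @param orifice_area_cm2 Optional effective mitral orifice area; when
#'   supplied a `velocity_cm_s` column (flow / area) is added, for
#'   comparison with Doppler velocities.
#' @return Tibble with columns `wave` (`"E"`, `"A"`), `time_s`, `flow`
#'   (mL/s) and optionally `velocity_cm_s`.
#' @export
mitral_ea <- function(result, beat = 1, rhythm = NULL,
                      orifice_area_cm2 = NULL) {
  need_cols(result, c("time_s", "q_mv"))
  rhythm <- resolve_rhythm(result, rhythm)
  circuit <- attr(result, "circuit")
  sl <- beat_slice(result, rhythm, beat)
  t <- result$time_s[sl$rows]
  q <- result$q_mv[sl$rows]
  phase <- (t - sl$t0) / sl$len
  if (!is.null(circuit)) {
    lv <- circuit$chambers$LV
    la <- circuit$chambers$LA
    lv_mid <- lv$onset + lv$duration / 2
    dia_end <- lv$onset + lv$duration
    a_win <- c(la$onset, la$onset + la$duration)
  } else {
    lv_mid <- 0.15
    dia_end <- 0.3
    a_win <- c(0.74, 0.94)
  }
  # diastole opens when mitral flow first rises after peak ventricular
  # activation; fall back to the end of the activation window
  open_idx <- which(phase > lv_mid & q > 0.02 * max(q))
  dia_start <- if (length(open_idx)) phase[open_idx[1]] else dia_end
  # E is confined to early diastole only when an A wave can follow it;
  # without atrial contraction the whole diastolic interval is E territory
  e_win <- if (rhythm$atrial_active)
    c(dia_start, dia_start + (1 - dia_start) / 2)
  else c(dia_start, 1)
  rows <- list()
  ie <- pick_peak(phase, q, e_win)
  if (!is.null(ie)) rows$E <- tibble::tibble(wave = "E", time_s = t[ie],
                                             flow = q[ie])
  if (rhythm$atrial_active) {
    ia <- pick_peak(phase, q, a_win)
    if (!is.null(ia)) rows$A <- tibble::tibble(wave = "A", time_s = t[ia],
                                               flow = q[ia])
  }
  out <- dplyr::bind_rows(c(list(tibble::tibble(wave = character(),
                                                time_s = numeric(),
                                                flow = numeric())), rows))
  if (!is.null(orifice_area_cm2) && nrow(out))
    out$velocity_cm_s <- out$flow / orifice_area_cm2
  out
}

#' Per-beat hemodynamic summary
#'
#' One row per analysed beat: time-weighted mean LA pressure, a/c/v wave
#' pressures, mitral E and A flow peaks, stroke volume (integrated aortic
#' flow) and the per-beat cardiac output `stroke_volume * 60 /
#' cycle_length / 1000`.
#'
#' @inheritParams mean_lap
#' @return A tibble with one row per beat.
#' @export
beat_metrics <- function(result, beats = 5, rhythm = NULL) {
  need_cols(result, c("time_s", "p_la", "q_mv", "q_aov"))
  rhythm <- resolve_rhythm(result, rhythm)
  w <- final_window(result, rhythm, beats)
  purrr::map_dfr(w$beats$beat, function(b) {
    sl <- beat_slice(result, rhythm, b)
    t <- result$time_s[sl$rows]
    acv <- detect_acv_waves(result, beat = b, rhythm = rhythm)
    ea <- mitral_ea(result, beat = b, rhythm = rhythm)
    sv <- trapz(t, result$q_aov[sl$rows])
    tibble::tibble(
      beat = b, t_start = sl$t0, cycle_length = sl$len,
      mean_lap = trapz(t, result$p_la[sl$rows]) / (max(t) - min(t)),
      a_peak = wave_value(acv, "a", "pressure"),
      c_peak = wave_value(acv, "c", "pressure"),
      v_peak = wave_value(acv, "v", "pressure"),
      e_peak = wave_value(ea, "E", "flow"),
      a_flow_peak = wave_value(ea, "A", "flow"),
      stroke_volume = sv,
      cardiac_output = sv * 60 / sl$len / 1000)
  })
}

#' Left atrial appendage ejection fraction
#'
#' `(max_area - min_area) / max_area * 100`, in percent. Areas may be in
#' any common unit (cm2 or mL) as long as both agree.
#'
#' @param max_area Maximum appendage area, > 0.
#' @param min_area Minimum appendage area, in `[0, max_area]`.
#' @return Ejection fraction in percent.
#' @examples
#' laa_ejection_fraction(4, 1) # 75
#' @export
laa_ejection_fraction <- function(max_area, min_area) {
  stopifnot(is.numeric(max_area), is.numeric(min_area))
  if (any(max_area == 0))
    stop("`max_area` must be > 0: ejection fraction is undefined", call. = FALSE)
  if (any(min_area < 0) || any(max_area < 0))
    stop("areas must be >= 0", call. = FALSE)
  if (any(min_area > max_area))
    stop("`min_area` must not exceed `max_area`", call. = FALSE)
  (max_area - min_area) / max_area * 100
}
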
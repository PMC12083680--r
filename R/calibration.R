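#' Extract target-feature values from a steady-state run
#'
#' The feature set used by calibration: aortic systolic and diastolic
#' pressure (max/min of the systemic arterial trace), cardiac output,
#' mean LA pressure, and the mitral E/A ratio — all from the final-beat
#' analysis window.
#'
#' @param result A `hemo_sim` containing `p_sa`, `q_aov`, `p_la`, `q_mv`.
#' @param beats Analysis window, final complete beats.
#' @return One-row tibble with columns `aortic_systolic`,
#'   `aortic_diastolic`, `cardiac_output`, `mean_lap`, `ea_ratio`
#'   (`NA` when the A wave is absent).
#' @export
feature_vector <- function(result, beats = 5) {
  need_cols(result, c("time_s", "p_sa", "q_aov", "p_la", "q_mv"))
  rhythm <- resolve_rhythm(result, NULL)
  w <- final_window(result, rhythm, beats)
  ea <- mitral_ea(result, beat = utils::tail(w$beats$beat, 1))
  e <- wave_value(ea, "E", "flow")
  a <- wave_value(ea, "A", "flow")
  tibble::tibble(
    aortic_systolic = max(result$p_sa[w$rows]),
    aortic_diastolic = min(result$p_sa[w$rows]),
    cardiac_output = cardiac_output(result, beats = beats),
    mean_lap = mean_lap(result, beats = beats),
    ea_ratio = e / a)
}

#' Calibrate free circuit parameters against target features
#'
#' Minimises the weighted relative squared error
#' `sum_i w_i * ((sim_i - target_i) / target_i)^2` over the declared free
#' parameters with a bounded derivative-free Nelder-Mead search (each
#' objective evaluation is a full stiff simulation, and the diode valves
#' make the response non-smooth, so gradient methods are avoided). The
#' search space is mapped onto the bounds with a sine transform; the
#' start point is the base circuit's own parameter values, which must lie
#' inside the bounds. Simulation failures during the search are penalised,
#' not fatal. Deterministic given identical inputs; `seed` is recorded for
#' provenance.
#'
#' @param base A [circuit()] object supplying all fixed parameters and
#'   the starting values of the free ones. The four LA constitutive
#'   parameters are treated as fixed published inputs and may not be
#'   declared free.
#' @param free Character vector of parameter paths (see [circuit_get()]),
#'   e.g. `c("compartments.SA.resistance", "chambers.LV.law.ees")`.
#' @param lower,upper Numeric bounds, one per free parameter, finite,
#'   `lower < upper`.
#' @param targets Named numeric vector of target features (any subset of
#'   the columns of [feature_vector()]).
#' @param weights Optional named numeric weights (> 0), defaulting to 1.
#' @param max_eval Objective-evaluation budget; 0 returns the base
#'   circuit and its objective unchanged.
#' @param duration,beats Simulation length and analysis window used for
#'   every evaluation.
#' @param seed Integer recorded in the result (the search itself is
#'   deterministic).
#' @param ... Passed on to [simulate_circuit()].
#' @return An object of class `hemo_fit`: list with `circuit` (fitted),
#'   `par` (named fitted values), `objective`, `trajectory` (best-so-far
#'   objective per evaluation, nonincreasing), `achieved` (features of a
#'   fresh simulation of the fitted circuit), `targets`, `converged`,
#'   `n_eval` and `seed`. Has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @export
calibrate <- function(base, free, lower, upper, targets, weights = NULL,
                      max_eval = 200, duration = 30, beats = 5, seed = 1L,
                      ...) {
  stopifnot(inherits(base, "hemo_circuit"), is.character(free),
            length(free) >= 1L)
  la_paths <- paste0("chambers.LA.law.", c("ees", "v0", "a_res", "b_res"))
  if (any(free %in% la_paths))
    stop("the LA constitutive parameters are fixed published inputs and cannot be declared free",
         call. = FALSE)
  if (length(lower) != length(free) || length(upper) != length(free) ||
      any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("`lower` and `upper` must be finite, one per free parameter, with lower < upper",
         call. = FALSE)
  tnames <- names(targets)
  known <- c("aortic_systolic", "aortic_diastolic", "cardiac_output",
             "mean_lap", "ea_ratio")
  if (is.null(tnames) || !all(tnames %in% known))
    stop("`targets` must be named with features among: ",
         paste(known, collapse = ", "), call. = FALSE)
  weights <- weights %||% stats::setNames(rep(1, length(targets)), tnames)
  if (any(weights <= 0)) stop("`weights` must be > 0", call. = FALSE)
  weights <- weights[tnames]

  x0 <- vapply(free, function(p) circuit_get(base, p), 0)
  if (any(x0 < lower) || any(x0 > upper))
    stop("free parameters of `base` must start within the bounds", call. = FALSE)
  set.seed(seed)

  objective_of <- function(x) {
    circ <- purrr::reduce2(free, x, circuit_set, .init = base)
    sim <- simulate_circuit(circ, duration = duration, ...)
    feats <- feature_vector(sim, beats = beats)
    err <- (unlist(feats[tnames]) - targets) / targets
    if (any(!is.finite(err))) return(1e6)
    sum(weights * err^2)
  }
  safe_objective <- function(x) {
    tryCatch(objective_of(x), error = function(e) 1e6)
  }

  state <- new.env(parent = emptyenv())
  state$n <- 0L
  state$best <- Inf
  state$best_x <- x0
  state$traj <- numeric()

  # sine transform keeps every iterate inside the bounds
  to_x <- function(theta) lower + (upper - lower) * sin(theta)^2
  theta0 <- asin(sqrt(pmin(pmax((x0 - lower) / (upper - lower), 1e-8),
                           1 - 1e-8)))
  wrapped <- function(theta) {
    if (state$n >= max_eval) return(state$best)
    x <- to_x(theta)
    val <- safe_objective(x)
    state$n <- state$n + 1L
    if (val < state$best) {
      state$best <- val
      state$best_x <- x
    }
    state$traj <- c(state$traj, state$best)
    val
  }

  converged <- FALSE
  if (max_eval > 0 && length(free) == 1L) {
    # golden-section search: derivative-free and warning-free in 1-D
    wrapped_x <- function(x) {
      if (state$n >= max_eval) return(state$best)
      val <- safe_objective(x)
      state$n <- state$n + 1L
      if (val < state$best) {
        state$best <- val
        state$best_x <- x
      }
      state$traj <- c(state$traj, state$best)
      val
    }
    stats::optimize(wrapped_x, lower = lower, upper = upper,
                    tol = (upper - lower) * 1e-6)
    converged <- TRUE
  } else if (max_eval > 0) {
    opt <- stats::optim(theta0, wrapped, method = "Nelder-Mead",
                        control = list(maxit = max_eval,
                                       reltol = 1e-10))
    converged <- opt$convergence == 0
  } else {
    state$best <- safe_objective(x0)
    state$best_x <- x0
    state$traj <- state$best
  }

  fitted <- purrr::reduce2(free, state$best_x, circuit_set, .init = base)
  achieved <- feature_vector(
    simulate_circuit(fitted, duration = duration, ...), beats = beats)
  structure(list(circuit = fitted,
                 par = stats::setNames(state$best_x, free),
                 start = stats::setNames(x0, free),
                 lower = stats::setNames(lower, free),
                 upper = stats::setNames(upper, free),
                 objective = state$best,
                 trajectory = state$traj,
                 achieved = achieved,
                 targets = targets,
                 weights = weights,
                 converged = converged,
                 n_eval = state$n,
                 seed = seed),
            class = "hemo_fit")
}

#' @export
print.hemo_fit <- function(x, ...) {
  cat(sprintf("<hemo_fit> %d free parameter(s), %d evaluation(s), objective %.3g%s\n",
              length(x$par), x$n_eval, x$objective,
              if (x$converged) ", converged" else ""))
  for (nm in names(x$par))
    cat(sprintf("  %-35s %.5g (start %.5g)\n", nm, x$par[[nm]], x$start[[nm]]))
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x A `hemo_fit` from [calibrate()].
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `start`, `lower`, `upper`.
#' @method tidy hemo_fit
#' @export
tidy.hemo_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par),
                 start = unname(x$start), lower = unname(x$lower),
                 upper = unname(x$upper))
}

#' One-row summary of a calibration fit
#'
#' @param x A `hemo_fit` from [calibrate()].
#' @param ... Unused.
#' @return A tibble with `objective`, `n_eval`, `converged`, `seed`.
#' @method glance hemo_fit
#' @export
glance.hemo_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_eval = x$n_eval,
                 converged = x$converged, seed = x$seed)
}

#' One-row summary of a simulation
#'
#' @param x A `hemo_sim` from [simulate_circuit()].
#' @param ... Unused; `beats` controls the analysis window.
#' @param beats Final complete beats analysed.
#' @return A tibble with the feature vector plus `drift_ml` (see
#'   [periodicity_drift()]) and `volume_error_ml`, the largest deviation
#'   of summed volumes from the circuit total across all samples.
#' @method glance hemo_sim
#' @export
glance.hemo_sim <- function(x, ..., beats = 5) {
  circ <- attr(x, "circuit")
  vols <- rowSums(as.matrix(x[paste0("v_", ELEMENTS)]))
  dplyr::bind_cols(
    feature_vector(x, beats = beats),
    tibble::tibble(
      drift_ml = suppressWarnings(periodicity_drift(x)),
      volume_error_ml = max(abs(vols - circ$total_volume))))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
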
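#' Plot simulated waveforms
#'
#' Faceted ggplot of pressure, volume or flow traces, optionally
#' restricted to the final beats.
#'
#' @param object A `hemo_sim`.
#' @param what `"pressures"`, `"volumes"` or `"flows"`.
#' @param elements Elements (or edges) to show; defaults to the left-heart
#'   set for pressures/flows.
#' @param beats If not `NULL`, show only the final `beats` complete beats.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hemo_sim
#' @export
autoplot.hemo_sim <- function(object, what = c("pressures", "volumes", "flows"),
                              elements = NULL, beats = 5, ...) {
  what <- match.arg(what)
  prefix <- c(pressures = "p_", volumes = "v_", flows = "q_")[[what]]
  unit <- c(pressures = "mmHg", volumes = "mL", flows = "mL/s")[[what]]
  elements <- elements %||% switch(what,
    pressures = c("la", "lv", "sa", "pv"),
    volumes = c("la", "lv"),
    flows = c("mv", "aov", "pv"))
  cols <- paste0(prefix, elements)
  need_cols(object, cols)
  dat <- tibble::as_tibble(object)
  if (!is.null(beats)) {
    rhythm <- resolve_rhythm(object, NULL)
    w <- final_window(object, rhythm, beats)
    dat <- dat[w$rows, ]
  }
  long <- tidyr::pivot_longer(dat[c("time_s", cols)], -"time_s",
                              names_to = "trace", values_to = "value")
  long$trace <- factor(long$trace, levels = cols)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value,
                                     colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = unit, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pressure-volume loop
#'
#' Draws the loop trajectory with each sub-loop coloured and labelled by
#' its orientation and signed area.
#'
#' @param object A `hemo_pvloop` from [pv_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hemo_pvloop
#' @export
autoplot.hemo_pvloop <- function(object, ...) {
  sub <- purrr::imap_dfr(object$subloops, function(sl, i)
    dplyr::mutate(sl$points,
                  subloop = sprintf("%s (%.1f mmHg*mL)", sl$orientation,
                                    sl$area),
                  .id = i))
  ggplot2::ggplot(sub, ggplot2::aes(.data$volume, .data$pressure,
                                    colour = .data$subloop)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "LA volume (mL)", y = "LA pressure (mmHg)",
                  colour = NULL,
                  subtitle = if (object$figure_eight)
                    "figure-eight loop" else "single loop") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
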
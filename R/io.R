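## Configuration and waveform I/O.
## The config dialect mirrors the published LA symbol names at top level
## (la_ees, la_v0, la_a_res, la_b_res) and namespaces everything else;
## waveforms use a plain comma-separated, '.'-decimal, UTF-8 CSV with a
## mandatory header, columns `time_s` then `p_<element>`, `v_<element>`,
## `q_<edge>` in mmHg / mL / mL/s.

CONFIG_KEYS <- c("la_ees", "la_v0", "la_a_res", "la_b_res", "chambers",
                 "compartments", "valves", "rhythm", "total_volume", "gating")

#' Write a circuit configuration as JSON
#'
#' @param circuit A [circuit()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_circuit_config <- function(circuit, path) {
  stopifnot(inherits(circuit, "hemo_circuit"))
  la <- circuit$chambers$LA
  cfg <- list(
    la_ees = la$law$ees, la_v0 = la$law$v0,
    la_a_res = la$law$a_res, la_b_res = la$law$b_res,
    chambers = lapply(circuit$chambers, function(ch) {
      out <- list(onset = ch$onset, duration = ch$duration,
                  viscous_resistance = ch$viscous_resistance,
                  relax_tau = ch$relax_tau)
      if (ch$label != "LA")
        out <- c(list(ees = ch$law$ees, v0 = ch$law$v0,
                      a_res = ch$law$a_res, b_res = ch$law$b_res), out)
      out
    }),
    compartments = lapply(circuit$compartments, function(cp)
      list(compliance = cp$compliance, resistance = cp$resistance,
           unstressed = cp$unstressed)),
    valves = lapply(circuit$valves, function(vv)
      list(resistance = vv$resistance)),
    rhythm = list(cycle_lengths = circuit$rhythm$cycle_lengths,
                  atrial_active = circuit$rhythm$atrial_active,
                  av_delay = circuit$rhythm$av_delay),
    total_volume = circuit$total_volume,
    gating = circuit$gating)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a circuit configuration
#'
#' Unknown keys are rejected; every value passes through the public
#' constructors, so unit and range violations fail with an error naming
#' the offending key and constraint.
#'
#' @param path Path to a JSON file written by [write_circuit_config()] (or
#'   authored by hand in the same dialect).
#' @return A [circuit()] object.
#' @export
read_circuit_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(CONFIG_KEYS, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  in_section <- function(section, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("invalid config at '%s': %s", section,
                   conditionMessage(e)), call. = FALSE))
  }
  la_law <- in_section("la_ees/la_v0/la_a_res/la_b_res",
                       atrial_law(cfg$la_ees, cfg$la_v0, cfg$la_a_res,
                                  cfg$la_b_res))
  chambers <- lapply(CHAMBER_LABELS, function(lab) {
    ch <- cfg$chambers[[lab]]
    if (is.null(ch)) stop("missing config section 'chambers.", lab, "'",
                          call. = FALSE)
    law <- if (lab == "LA") la_law else
      in_section(paste0("chambers.", lab),
                 atrial_law(ch$ees, ch$v0, ch$a_res, ch$b_res))
    in_section(paste0("chambers.", lab),
               chamber(lab, law, onset = ch$onset, duration = ch$duration,
                       viscous_resistance = ch$viscous_resistance %||% 0,
                       relax_tau = ch$relax_tau %||% 0))
  })
  compartments <- lapply(COMPARTMENT_LABELS, function(lab) {
    cp <- cfg$compartments[[lab]]
    if (is.null(cp)) stop("missing config section 'compartments.", lab, "'",
                          call. = FALSE)
    in_section(paste0("compartments.", lab),
               vascular(lab, cp$compliance, cp$resistance, cp$unstressed))
  })
  valves <- lapply(VALVE_LABELS, function(lab) {
    vv <- cfg$valves[[lab]]
    if (is.null(vv)) stop("missing config section 'valves.", lab, "'",
                          call. = FALSE)
    in_section(paste0("valves.", lab), valve(lab, vv$resistance))
  })
  rh <- in_section("rhythm", rhythm(cfg$rhythm$cycle_lengths,
                                    cfg$rhythm$atrial_active,
                                    cfg$rhythm$av_delay))
  in_section("total_volume/gating",
             circuit(chambers, compartments, valves, rh, cfg$total_volume,
                     gating = cfg$gating))
}

#' Write simulation waveforms to CSV
#'
#' Lossless full-precision export of the time grid and all traces in the
#' fixed column dialect (`time_s`, then `v_*`, `p_*`, `q_*`).
#'
#' @param result A `hemo_sim` or any data frame with a `time_s` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(result, path) {
  need_cols(result, "time_s")
  readr::write_csv(tibble::as_tibble(result), path)
  invisible(path)
}

#' Read waveforms from CSV
#'
#' Accepts any CSV in the package's waveform dialect, including partial
#' traces (for example only `time_s`, `p_la`, `v_la` from an external
#' acquisition system); each metric checks for the columns it needs.
#'
#' @param path Path to a waveform CSV with a header row.
#' @return A tibble; pass a [rhythm()] to the metric functions alongside
#'   it.
#' @export
read_waveforms <- function(path) {
  if (!file.exists(path)) stop("waveform file not found: ", path,
                               call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_s" %in% names(out))
    stop("waveform CSV is missing mandatory column(s): time_s", call. = FALSE)
  if (nrow(out) && any(diff(out$time_s) <= 0))
    stop("`time_s` must be strictly increasing", call. = FALSE)
  out
}
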
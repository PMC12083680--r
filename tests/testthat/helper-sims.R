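# shared steady-state runs, computed once per test session
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name) {
  if (!is.null(.sim_cache[[name]])) return(.sim_cache[[name]])
  base <- baseline_circuit()
  sim <- switch(name,
    baseline = simulate_circuit(base),
    laao = simulate_circuit(apply_laao(base)),
    flutter150 = simulate_circuit(make_flutter(base, 150)),
    af = simulate_circuit(make_af(base)),
    stop("unknown cached sim: ", name))
  .sim_cache[[name]] <- sim
  sim
}

last_beat <- function(sim) utils::tail(attr(sim, "beats")$beat, 1)

# a circuit with every chamber inert (no contraction, no wall viscosity):
# dynamics reduce to passive pressure-driven equilibration
passive_circuit <- function(total_volume = 3600) {
  base <- baseline_circuit(total_volume = total_volume)
  for (lab in c("LA", "LV", "RA", "RV")) {
    law <- base$chambers[[lab]]$law
    base$chambers[[lab]] <- chamber(
      lab, atrial_law(ees = 0, v0 = law$v0, a_res = law$a_res,
                      b_res = law$b_res),
      onset = base$chambers[[lab]]$onset,
      duration = base$chambers[[lab]]$duration)
  }
  rebuild <- atriahemo::circuit(base$chambers, base$compartments, base$valves,
                                base$rhythm, base$total_volume, base$gating)
  rebuild
}
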
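# Shared (memoised) heavy runs: computed once per test session, reused by
# the solver, index and acceptance tests.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

# the six-condition default study at the standard study resolution
study_runs <- function() {
  cached("study", {
    geom <- build_geometry(geometry_params())
    gcoil <- set_coil(geom, 1)
    wf <- synth_waveform()
    out <- list()
    for (H in c(0.35, 0.45)) {
      rh <- rheology_params(H = H)
      for (cond in list(list(key = "un", coil = NULL),
                        list(key = "p89", coil = coil_model(0.89)),
                        list(key = "p79", coil = coil_model(0.79)))) {
        g <- if (is.null(cond$coil)) geom else gcoil
        lab <- sprintf("H%.2f_%s", H, cond$key)
        run <- run_cycles(g, wf, rh, coil = cond$coil)
        out[[lab]] <- list(run = run,
                           report = phase_metrics(run, label = lab))
      }
    }
    out
  })
}

# single fine-grid protocol run (H = 0.35, porosity 0.79 — the condition
# of the reference field figures), 256 x 128 cells, 3 cycles
protocol_run <- function() {
  cached("protocol", {
    gp <- geometry_params(grid_nx = 256, grid_ny = 150)
    geom <- set_coil(build_geometry(gp), 1)
    run_cycles(geom, synth_waveform(), rheology_params(H = 0.35),
               coil = coil_model(0.79))
  })
}

poiseuille_bench <- function() cached("poiseuille", benchmark_poiseuille())
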
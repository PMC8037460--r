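# Expensive fixtures built once per test run and shared across files.
.pt_cache <- new.env(parent = emptyenv())

pt_mesh <- function() {
  if (is.null(.pt_cache$mesh))
    .pt_cache$mesh <- generate_mesh(build_ac_geometry(geometry_params()), 4981)
  .pt_cache$mesh
}

pt_steady <- function(fluid = "AH") {
  key <- paste0("steady_", fluid)
  if (is.null(.pt_cache[[key]]))
    .pt_cache[[key]] <- solve_steady(pt_mesh(), fluid)
  .pt_cache[[key]]
}

# the full (fluid x power) study grid at the reference resolution
pt_grid <- function() {
  if (is.null(.pt_cache$grid))
    .pt_cache$grid <- run_grid(mesh = pt_mesh(), verbose = FALSE)
  .pt_cache$grid
}

# a 30-s AH / 1.2 W run (relaxation window + refinement comparisons)
pt_ah12 <- function() {
  if (is.null(.pt_cache$ah12)) {
    m <- pt_mesh()
    src <- heat_source(1.2, tip_length = sum(m$tip_edges$length))
    .pt_cache$ah12 <- run_transient(pt_steady("AH"), src,
                                    config = solver_config(t_end = 30))
  }
  .pt_cache$ah12
}

# synthetic field series for the post-processing oracles
pt_synthetic_series <- function(mesh, stored_T, stored_u, times,
                                steady_T, steady_u, duration = 0) {
  structure(list(
    mesh = mesh,
    steady = structure(list(T = steady_T, u = steady_u, mesh = mesh),
                       class = "field_state"),
    source = structure(list(total_power = 0, duration = duration,
                            tip_length = 0, d_eff = 1, flux = 0),
                       class = "heat_source"),
    config = NULL, fluid = NULL,
    times = times, probe_traces = NULL,
    probes = data.frame(name = character(0), x = numeric(0), y = numeric(0)),
    stored_times = times, stored_T = stored_T, stored_u = stored_u,
    vel_stats = NULL, interior = seq_len(nrow(mesh$nodes))),
    class = "field_series")
}
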
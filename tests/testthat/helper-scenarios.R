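# Shared fixtures. The two full-fidelity preset runs are expensive (~1 and
# ~2 min); they are computed once per test session and reused by every file
# that needs them.

.run_cache <- new.env(parent = emptyenv())

get_preset_run <- function(name) {
  if (is.null(.run_cache[[name]])) {
    sc <- switch(name, wr313h = scenario_wr313h(), u1325 = scenario_u1325())
    .run_cache[[name]] <- run_scenario(sc)
  }
  .run_cache[[name]]
}

# A small, fast scenario (all-mud except a thin sand bed, short horizon) for
# structural tests that do not depend on the published calibrations.
tiny_scenario <- function(t_end = 2e4, dt = 40, dz = 0.25, ...) {
  col <- build_column(domain_length = 10, sand_thickness = 1.5, dz = dz,
                      n_sand = 1e9, n_mud = 1e6, poc_mud_wt = 0.5)
  rc <- rate_constants(K_eh = 10^-12.6, K_fm = 10^-21.5, epsilon = 0.025)
  sm <- solubility_model("linear", c_ref = 45, d_scale = 700,
                         mud_multiplier = 1.006)
  scenario(col, rc, transport_params(), burial_trajectory(1), sm,
           dt = dt, t_end = t_end, series_dt = 1000,
           snapshot_times = t_end, name = "tiny", ...)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
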
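# Expensive runs shared across test files, computed once per test session.

.ijv_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ijv_test_cache))
    assign(key, expr, envir = .ijv_test_cache)
  get(key, envir = .ijv_test_cache)
}

desk_run <- function(label) {
  cached(paste0("run_", label), {
    cases <- standard_cases(control = preset_control("desk"))
    run_case(cases[[label]])
  })
}

# steady plane-Poiseuille channel: viscous enough to develop within the
# domain and settle quickly (Re = U D / nu = 3)
poiseuille_config <- function(nx = 64L, ny = 32L) {
  case_config(
    label = sprintf("poiseuille-%dx%d", nx, ny),
    geometry = vessel_geometry(f = 0),
    valve = NULL,
    fluid = fluid_properties(rho = 1000, mu = 0.1),
    control = sim_control(nx = nx, ny = ny, end_time = 2.5,
                          snapshot_times = 2.5, metric_dt = 0.25,
                          dt_max = 5e-3,
                          inlet = list(type = "constant", U = 0.02),
                          steady_tol = 1e-5))
}

poiseuille_run <- function() cached("poiseuille", run_case(poiseuille_config()))

# quick stenosed channel (no valve) for solver contract tests
small_stenosed_solver <- function() {
  cached("small_stenosed", {
    geom <- vessel_geometry(f = 0.5, L = 0.1, xs = 0.02, ls = 0.005)
    grid <- flow_grid(48, 12, geom$L, geom$D)
    solver <- new_flow_solver(grid, wall_mask(geom, grid), fluid_properties())
    state <- initialize_state(solver, U0 = 0.12)
    for (i in 1:40) {
      dt <- min(courant_dt(solver, state, 0.4), ijvflow:::diffusive_dt(solver))
      state <- advance_flow(solver, state, dt, U_in = 0.12)
    }
    list(solver = solver, state = state, geom = geom)
  })
}
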
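#' Simulation controls
#'
#' Numerical settings shared by the case runner.  Two presets are used
#' throughout: `"desk"` (200 x 16 cells, 3 s of simulated time, laminar)
#' for routine property studies, and `"paper"` (400 x 30 cells, 6 s -- one
#' full inlet cycle -- with the k-omega closure on) for full-fidelity runs.
#'
#' @param nx,ny grid cells along x and y.
#' @param cfl advective CFL fraction.
#' @param end_time simulated end time (s).
#' @param snapshot_times times (s) at which full fields are kept.
#' @param dt_max upper bound on the time step (s).
#' @param metric_dt cadence (s) of the metric time series.
#' @param turbulence logical: evolve the k-omega closure and feed the eddy
#'   viscosity back to the momentum equations.
#' @param stokes logical: drop the fluid inertial terms.
#' @param inlet list: `type = "pulsatile"` (the sinusoidal waveform) or
#'   `type = "constant"` with speed `U` (m/s).
#' @param turb_intensity,turb_length inlet turbulence intensity (fraction)
#'   and length scale (m) when `turbulence = TRUE`.
#' @param ib_penalty immersed-boundary velocity-coupling strength.
#' @param damping structural damping rate (1/s).
#' @param steady_tol if non-`NULL`, stop early once the relative velocity
#'   change over `0.05` s of simulated time falls below this tolerance.
#' @param seed integer recorded in the provenance; only used when
#'   `perturb > 0`.
#' @param perturb RMS amplitude, as a fraction of the inlet speed, of a
#'   random antisymmetric tilt applied to the inlet profile each step
#'   (zero net flux).  It stands in for the physiological and mesh
#'   asymmetries that seed shear-layer instabilities; with `perturb = 0`
#'   a symmetric case stays symmetric to round-off, which artificially
#'   suppresses the jet flapping instability on this mirror-symmetric
#'   grid.  Default `0.02` in the presets, `0` otherwise.
#' @return object of class `sim_control`.
#' @export
sim_control <- function(nx = 200, ny = 16, cfl = 0.4, end_time = 3,
                        snapshot_times = c(0.25, 1.5, 3), dt_max = 2e-3,
                        metric_dt = 0.02, turbulence = FALSE, stokes = FALSE,
                        inlet = list(type = "pulsatile"),
                        turb_intensity = 0.05, turb_length = 0.0015,
                        ib_penalty = 0.3, damping = 0,
                        steady_tol = NULL, seed = 1L, perturb = 0) {
  if (length(steady_tol) == 0) steady_tol <- NULL  # e.g. after a JSON trip
  if (!is.null(inlet$U)) inlet$U <- as.numeric(inlet$U)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cfl = as.numeric(cfl),
                 end_time = as.numeric(end_time),
                 snapshot_times = as.numeric(snapshot_times),
                 dt_max = as.numeric(dt_max),
                 metric_dt = as.numeric(metric_dt),
                 turbulence = isTRUE(turbulence), stokes = isTRUE(stokes),
                 inlet = inlet, turb_intensity = as.numeric(turb_intensity),
                 turb_length = as.numeric(turb_length),
                 ib_penalty = as.numeric(ib_penalty),
                 damping = as.numeric(damping),
                 steady_tol = if (is.null(steady_tol)) NULL
                              else as.numeric(steady_tol),
                 seed = as.integer(seed), perturb = as.numeric(perturb)),
            class = "sim_control")
}

#' Preset simulation controls
#' @param name `"desk"` or `"paper"`.
#' @param ... overrides passed to [sim_control()].
#' @return a [sim_control()].
#' @export
preset_control <- function(name = c("desk", "paper"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    desk  = list(nx = 200L, ny = 16L, end_time = 3,
                 snapshot_times = c(0.25, 1.5, 3), turbulence = FALSE,
                 perturb = 0.02),
    paper = list(nx = 400L, ny = 30L, end_time = 6,
                 snapshot_times = c(0.25, 1.5, 3), turbulence = TRUE,
                 perturb = 0.02))
  do.call(sim_control, modifyList(base, list(...)))
}

#' Full configuration of one vessel case
#'
#' @param label case label (conventionally `"A"`..`"D"`).
#' @param geometry a [vessel_geometry()].
#' @param valve a [valve_spec()], or `NULL` for a valveless channel.
#' @param fluid a [fluid_properties()].
#' @param material a [hyperelastic_material()].
#' @param control a [sim_control()].
#' @return object of class `case_config`.
#' @export
case_config <- function(label, geometry, valve = valve_spec(),
                        fluid = fluid_properties(),
                        material = hyperelastic_material(),
                        control = sim_control()) {
  if (!is.null(valve)) {
    if (geometry$f > 0 && geometry$xs + geometry$ls / 2 >= valve$anchor_x)
      stop_ijv("stenosis overlaps the valve anchor region")
    reach <- (geometry$D - valve$d2) / 2
    ax <- sqrt(max(valve$leaflet_length^2 - reach^2, 0))
    if (valve$anchor_x + ax >= geometry$L)
      stop_ijv("valve extends beyond the outlet")
  }
  structure(list(label = label, geometry = geometry, valve = valve,
                 fluid = fluid, material = material, control = control),
            class = "case_config")
}

#' The four standard stenosis cases
#'
#' Case A: no stenosis; B: 30 percent; C: 60 percent; D: 75 percent lumen
#' narrowing.  Valve, fluid, material and numerical controls are identical
#' across the four configurations.
#'
#' @param control a [sim_control()] shared by all cases.
#' @param valve shared [valve_spec()].
#' @param fluid shared [fluid_properties()].
#' @param material shared [hyperelastic_material()].
#' @return named list of four [case_config()] objects (`A`..`D`).
#' @export
standard_cases <- function(control = sim_control(), valve = valve_spec(),
                           fluid = fluid_properties(),
                           material = hyperelastic_material()) {
  fractions <- c(A = 0, B = 0.30, C = 0.60, D = 0.75)
  lapply(setNames(names(fractions), names(fractions)), function(lab) {
    case_config(lab, vessel_geometry(f = fractions[[lab]]),
                valve = valve, fluid = fluid, material = material,
                control = control)
  })
}

config_as_list <- function(config) {
  list(label = config$label,
       geometry = unclass(config$geometry),
       valve = if (is.null(config$valve)) NULL else unclass(config$valve),
       fluid = unclass(config$fluid),
       material = unclass(config$material),
       control = unclass(config$control))
}

#' Write / read a case configuration as YAML
#'
#' @param config a [case_config()].
#' @param path file path.
#' @return `write_case_config` returns `path` invisibly;
#'   `read_case_config` returns the reconstructed [case_config()].
#' @export
write_case_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_case_config
#' @export
read_case_config <- function(path) {
  x <- yaml::read_yaml(path)
  case_config(
    label = x$label,
    geometry = do.call(vessel_geometry,
                       x$geometry[c("L", "D", "f", "xs", "ls", "profile",
                                    "one_sided")]),
    valve = if (is.null(x$valve)) NULL else do.call(valve_spec, x$valve),
    fluid = do.call(fluid_properties, x$fluid),
    material = do.call(hyperelastic_material,
                       x$material[c("E", "nu", "rho_s")]),
    control = do.call(sim_control, x$control))
}

#' Stable content hash of a case configuration
#'
#' MD5 of the canonical YAML serialization, recorded in run manifests so
#' any output can be traced back to, and re-run from, its exact
#' configuration.
#'
#' @param config a [case_config()].
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(config_as_list(config), f)
  unname(tools::md5sum(f))
}
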
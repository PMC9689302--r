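# Case orchestration: time stepping, metric collection, snapshotting,
# grid-independence study and cross-case comparison.

inlet_speed_fun <- function(control) {
  if (identical(control$inlet$type, "constant")) {
    U <- control$inlet$U
    function(t) rep_len(U, length(t))
  } else {
    function(t) inlet_velocity_ms(t)
  }
}

# columns spanned by the stenosis (throat window); for an unstenosed
# vessel, the same axial window serves as the baseline
throat_columns <- function(geom, grid) {
  which(abs(grid$xc - geom$xs) <= geom$ls / 2)
}

#' Run one vessel case end to end
#'
#' Builds the grid, wall mask, solver and valve from the configuration,
#' advances the coupled system to `control$end_time`, and collects a
#' metric time series (reverse-flow area downstream of the stenosis, jet
#' asymmetry upstream of the valve, throat peak velocity, leaflet tip
#' displacements) plus full-field snapshots at the requested times.
#' Fully deterministic for a given configuration unless an inlet
#' perturbation is requested.
#'
#' @param config a [case_config()].
#' @param out_dir optional directory: writes `metrics.csv`, VTK snapshots,
#'   leaflet trajectories and a JSON manifest.
#' @param verbose print solver diagnostics every 100 steps.
#' @return object of class `run_result`: list with `label`, `config`,
#'   `metrics` (data frame), `snapshots` (list of flow states with leaflet
#'   copies), `valve` (final state), `profile_mean` (maximum-velocity
#'   profile averaged over the last third of the run), `log`, and
#'   `provenance`.
#' @export
run_case <- function(config, out_dir = NULL, verbose = FALSE) {
  geom <- config$geometry; ctrl <- config$control
  grid <- flow_grid(ctrl$nx, ctrl$ny, geom$L, geom$D)
  mask <- wall_mask(geom, grid)
  solver <- new_flow_solver(grid, mask, config$fluid)
  valve <- if (is.null(config$valve)) NULL else build_valve(geom$D, config$valve)
  Ufun <- inlet_speed_fun(ctrl)
  state <- initialize_state(solver, t0 = 0, U0 = Ufun(0))
  turb <- NULL; mu_t <- NULL
  coeffs <- komega_coefficients()
  if (ctrl$turbulence) {
    bc <- inlet_k_omega(Ufun(0), ctrl$turb_intensity, ctrl$turb_length, coeffs)
    turb <- initialize_k_omega(solver, bc$k, bc$omega)
    mu_t <- eddy_viscosity(config$fluid$rho, turb$k, turb$omega)
  }
  if (ctrl$perturb > 0) set.seed(ctrl$seed)

  roi_sep <- c(if (geom$f > 0) geom$xs + geom$ls / 2 else 0,
               if (is.null(valve)) geom$L else config$valve$anchor_x)
  roi_asym <- c(0, if (is.null(valve)) geom$L else config$valve$anchor_x)
  thr_cols <- throat_columns(geom, grid)

  Re0 <- config$fluid$rho * Ufun(0) * geom$D / config$fluid$mu
  log_lines <- sprintf(
    "case %s: grid %dx%d, f = %.2f, inlet Re = %.0f, turbulence %s",
    config$label, ctrl$nx, ctrl$ny, geom$f, Re0,
    if (ctrl$turbulence) "on" else "off")

  metrics <- list()
  snapshots <- list()
  snap_pending <- sort(unique(pmin(ctrl$snapshot_times, ctrl$end_time)))
  next_metric <- 0
  nstep <- 0L
  u_prev <- NULL; t_prev_check <- 0
  cfl_events <- 0L

  prof_sum <- NULL; prof_n <- 0L
  prof_window <- c(2 / 3 * ctrl$end_time, ctrl$end_time)

  take_metrics <- function(state, valve) {
    prof <- max_velocity_vs_x(solver, state)
    if (state$t >= prof_window[1] - 1e-12) {
      if (is.null(prof_sum)) prof_sum <<- prof$vmax
      else prof_sum <<- prof_sum + prof$vmax
      prof_n <<- prof_n + 1L
    }
    sep <- reverse_flow_area(solver, state, xlim = roi_sep)
    data.frame(
      time = state$t,
      umax = max(cell_speed(solver, state)),
      throat_peak = max(prof$vmax[thr_cols]),
      reverse_area = sep$area,
      n_recirculation = sep$n_regions,
      asymmetry = asymmetry_index(solver, state, xlim = roi_asym),
      tip_lower = if (is.null(valve)) NA_real_
                  else leaflet_tip_displacement(valve$lower),
      tip_upper = if (is.null(valve)) NA_real_
                  else leaflet_tip_displacement(valve$upper),
      leaflet_asym = if (is.null(valve)) NA_real_
                     else leaflet_asymmetry(valve$upper, valve$lower))
  }

  repeat {
    if (state$t >= ctrl$end_time - 1e-12) break
    mu_t_max <- if (is.null(mu_t)) 0 else max(mu_t)
    dt <- min(courant_dt(solver, state, ctrl$cfl, ctrl$dt_max),
              diffusive_dt(solver, mu_t_max),
              ctrl$dt_max)
    targets <- c(ctrl$end_time,
                 snap_pending[snap_pending > state$t + 1e-12],
                 next_metric)
    gap <- min(targets[targets > state$t + 1e-12]) - state$t
    dt <- min(dt, gap)
    U_in <- Ufun(state$t + dt)
    if (ctrl$perturb > 0) {
      # antisymmetric inlet tilt: zero net flux, seeds the odd (flapping)
      # jet modes that a perfectly symmetric discretization suppresses
      tilt <- 2 * solver$grid$yc / solver$grid$D - 1
      U_in <- U_in * (1 + ctrl$perturb * stats::rnorm(1) * tilt)
    }

    if (is.null(valve)) {
      state <- advance_flow(solver, state, dt, U_in = U_in, mu_t = mu_t,
                            stokes = ctrl$stokes)
    } else {
      stp <- coupled_step(solver, state, valve, dt, config$material,
                          U_in = U_in, mu_t = mu_t, stokes = ctrl$stokes,
                          ib_penalty = ctrl$ib_penalty,
                          damping = ctrl$damping)
      state <- stp$state; valve <- stp$valve
    }
    if (ctrl$turbulence) {
      bc <- inlet_k_omega(U_in, ctrl$turb_intensity, ctrl$turb_length, coeffs)
      turb <- advance_k_omega(solver, state, turb, dt, coeffs, inlet = bc)
      mu_t <- eddy_viscosity(config$fluid$rho, turb$k, turb$omega)
    }
    nstep <- nstep + 1L

    if (state$t >= next_metric - 1e-12) {
      metrics[[length(metrics) + 1L]] <- take_metrics(state, valve)
      while (next_metric <= state$t + 1e-12)
        next_metric <- next_metric + ctrl$metric_dt
    }
    if (length(snap_pending) && state$t >= snap_pending[1] - 1e-12) {
      snap <- state
      snap$k <- if (is.null(turb)) NULL else turb$k
      snap$omega <- if (is.null(turb)) NULL else turb$omega
      snap$valve <- valve
      snapshots[[sprintf("t=%g", snap_pending[1])]] <- snap
      snap_pending <- snap_pending[-1]
    }
    if (verbose && nstep %% 100L == 0L)
      message(sprintf("  t = %.3f s, dt = %.2e, umax = %.3f, div = %.2e",
                      state$t, dt, max(abs(state$u)),
                      max_divergence(solver, state)))
    if (!is.null(ctrl$steady_tol) && state$t - t_prev_check >= 0.05) {
      if (!is.null(u_prev)) {
        rel <- max(abs(state$u - u_prev)) / max(max(abs(state$u)), 1e-12)
        if (rel < ctrl$steady_tol) {
          log_lines <- c(log_lines,
                         sprintf("steady state at t = %.3f s (rel change %.2e)",
                                 state$t, rel))
          if (length(snap_pending)) {
            snap <- state; snap$valve <- valve
            snapshots[[sprintf("t=%g", snap_pending[1])]] <- snap
            snap_pending <- character(0)
          }
          break
        }
      }
      u_prev <- state$u; t_prev_check <- state$t
    }
  }
  metrics[[length(metrics) + 1L]] <- take_metrics(state, valve)
  metrics <- do.call(rbind, metrics)
  if (!length(snapshots)) {
    snap <- state; snap$valve <- valve
    snapshots[[sprintf("t=%g", state$t)]] <- snap
  }
  log_lines <- c(log_lines,
                 sprintf("completed: %d steps to t = %.3f s, final div = %.3e",
                         nstep, state$t, max_divergence(solver, state)))
  if (ctrl$turbulence)
    log_lines <- c(log_lines,
                   sprintf("k/omega clip events: %d", turb$clip_events))

  profile_mean <- if (prof_n > 0L)
    structure(data.frame(x = grid$xc, vmax = prof_sum / prof_n),
              window = prof_window, n_samples = prof_n) else NULL

  res <- structure(list(label = config$label, config = config,
                        solver = solver, metrics = metrics,
                        snapshots = snapshots, state = state, valve = valve,
                        profile_mean = profile_mean,
                        log = log_lines,
                        provenance = list(config_hash = config_hash(config),
                                          seed = ctrl$seed,
                                          version = tryCatch(
                                            as.character(
                                              utils::packageVersion("ijvflow")),
                                            error = function(e) NA_character_))),
                   class = "run_result")
  if (!is.null(out_dir)) export_run(res, out_dir)
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> case %s: %d metric samples to t = %.3f s\n",
              x$label, nrow(x$metrics), max(x$metrics$time)))
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Grid-independence study
#'
#' Re-runs a configuration over a ladder of at least three grid
#' resolutions and tabulates the maximum velocity in the domain at the
#' final time, flagging the first (coarsest) resolution whose value
#' changes by less than `tol` relative to the next finer level.
#'
#' @param config a [case_config()].
#' @param resolutions list of `c(nx, ny)` pairs, coarse to fine.
#' @param tol relative-change threshold for the plateau flag.
#' @return data frame of class `mesh_study` with columns `nx, ny, cells,
#'   vmax, rel_change, converged`; the first converged level index is in
#'   `attr(, "plateau_level")` (`NA` when never reached -- reported, not
#'   hidden).
#' @export
mesh_independence <- function(config, resolutions, tol = 0.01) {
  if (length(resolutions) < 3L)
    stop_ijv("a resolution ladder needs at least 3 levels")
  vmax <- vapply(resolutions, function(res) {
    cfg <- config
    cfg$control$nx <- as.integer(res[1]); cfg$control$ny <- as.integer(res[2])
    r <- run_case(cfg)
    utils::tail(r$metrics$umax, 1)
  }, numeric(1))
  n <- length(resolutions)
  rel <- c(abs(diff(vmax)) / abs(vmax[-1]), NA)
  out <- data.frame(nx = vapply(resolutions, `[`, numeric(1), 1),
                    ny = vapply(resolutions, `[`, numeric(1), 2),
                    cells = vapply(resolutions, prod, numeric(1)),
                    vmax = vmax, rel_change = rel,
                    converged = c(rel[-n] < tol, NA))
  plateau <- which(out$converged)[1]
  attr(out, "plateau_level") <- if (length(plateau) && !is.na(plateau))
    plateau else NA_integer_
  class(out) <- c("mesh_study", class(out))
  out
}

#' Compare runs of several cases
#'
#' Aligns the per-section maximum-velocity profiles of two or more runs at
#' their final snapshot and tabulates the disturbance metrics (throat
#' peak, time-averaged reverse-flow area and asymmetry over the last third
#' of the run, leaflet asymmetry).
#'
#' @param results list of [run_result][run_case()] objects (>= 2).
#' @param window optional time window `c(t0, t1)` for the time averages;
#'   default the last third of the common run.
#' @return list of class `case_comparison` with `profiles` (long data
#'   frame: case, x, vmax) and `table` (one row per case, ordered as
#'   given).
#' @export
compare_cases <- function(results, window = NULL) {
  if (length(results) < 2L)
    stop_ijv("need at least two runs to compare")
  L <- vapply(results, function(r) r$config$geometry$L, numeric(1))
  if (any(abs(L - L[1]) > 1e-12))
    stop_ijv("cases have mismatched vessel lengths")
  tend <- min(vapply(results, function(r) max(r$metrics$time), numeric(1)))
  if (is.null(window)) window <- c(2 / 3 * tend, tend)
  profiles <- do.call(rbind, lapply(results, function(r) {
    snap <- r$snapshots[[length(r$snapshots)]]
    prof <- max_velocity_vs_x(r$solver, snap)
    data.frame(case = r$label, x = prof$x, vmax = prof$vmax,
               time = attr(prof, "time"))
  }))
  tab <- do.call(rbind, lapply(results, function(r) {
    m <- r$metrics
    inwin <- m$time >= window[1] & m$time <= window[2]
    thr <- throat_columns(r$config$geometry, r$solver$grid)
    snap <- r$snapshots[[length(r$snapshots)]]
    prof <- max_velocity_vs_x(r$solver, snap)
    data.frame(case = r$label,
               f = r$config$geometry$f,
               throat_peak = max(prof$vmax[thr]),
               reverse_area = mean(m$reverse_area[inwin]),
               asymmetry = mean(m$asymmetry[inwin]),
               leaflet_asym = utils::tail(m$leaflet_asym, 1))
  }))
  tab$peak_rank <- rank(tab$throat_peak)
  structure(list(profiles = profiles, table = tab, window = window),
            class = "case_comparison")
}

#' @export
print.case_comparison <- function(x, ...) {
  cat("<case_comparison> metrics averaged over t in",
      sprintf("[%.2f, %.2f] s\n", x$window[1], x$window[2]))
  print(x$table, row.names = FALSE)
  invisible(x)
}
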
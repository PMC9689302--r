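#' Blood properties
#'
#' Defaults are blood at 37 C: density 1055 kg/m^3, dynamic viscosity
#' 2.78e-3 Pa s (Newtonian).
#'
#' @param rho fluid density (kg m^-3).
#' @param mu dynamic viscosity (Pa s).
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1055, mu = 2.78e-3) {
  if (rho <= 0 || mu <= 0) stop_ijv("rho and mu must be positive")
  structure(list(rho = as.numeric(rho), mu = as.numeric(mu)),
            class = "fluid_properties")
}

#' Pulsatile inlet waveform
#'
#' Sinusoidal inlet speed emulating carotid pulsation and respiratory
#' modulation of jugular flow: `U(t) = amplitude * sin(t * angular) +
#' offset`, in cm/s.  With the defaults the speed starts at 12 cm/s,
#' peaks at 20 cm/s at t = 3 s and returns to 12 cm/s at t = 6 s
#' (flow velocity 16 +/- 4 cm/s).
#'
#' @param t time (s), scalar or vector.
#' @param amplitude waveform amplitude (cm/s), default 8.
#' @param offset waveform offset (cm/s), default 12.
#' @param angular angular factor (rad/s), default `pi/6`.
#' @return inlet speed in cm/s.
#' @examples
#' inlet_velocity(c(0, 3, 6))  # 12, 20, 12 cm/s
#' @export
inlet_velocity <- function(t, amplitude = 8, offset = 12, angular = pi / 6) {
  stopifnot(all(t >= 0))
  # sinpi keeps the waveform exact at multiples of the half-period
  # (sin(6 * pi/6) in double precision is ~1e-16, not 0)
  amplitude * sinpi(t * angular / pi) + offset
}

# inlet speed in SI units (m/s)
inlet_velocity_ms <- function(t, ...) inlet_velocity(t, ...) / 100

#' Build a flow solver for a fixed geometry
#'
#' Precomputes the masked-cell bookkeeping and the sparse Cholesky
#' factorization of the pressure-Poisson operator (homogeneous Neumann at
#' the inlet, walls and solid cells; Dirichlet p = 0 at the outlet face).
#'
#' @param grid a [flow_grid()].
#' @param mask logical `nx x ny` solid-cell mask (see [wall_mask()]), or
#'   `NULL` for an open channel.
#' @param props a [fluid_properties()].
#' @return object of class `flow_solver`.
#' @export
new_flow_solver <- function(grid, mask = NULL, props = fluid_properties()) {
  nx <- grid$nx; ny <- grid$ny
  if (is.null(mask)) mask <- matrix(FALSE, nx, ny)
  stopifnot(identical(dim(mask), c(nx, ny)))
  fluid <- !mask

  # forced (zero-velocity) faces: any face touching a solid cell
  u_forced <- matrix(FALSE, nx + 1L, ny)
  u_forced[2:nx, ] <- mask[1:(nx - 1L), ] | mask[2:nx, ]
  u_forced[1L, ] <- mask[1L, ]         # inlet face into a solid cell
  u_forced[nx + 1L, ] <- mask[nx, ]
  v_forced <- matrix(FALSE, nx, ny + 1L)
  v_forced[, 2:ny] <- mask[, 1:(ny - 1L)] | mask[, 2:ny]
  v_forced[, c(1L, ny + 1L)] <- TRUE   # channel walls

  idx <- matrix(0L, nx, ny)
  idx[fluid] <- seq_len(sum(fluid))

  # Poisson operator (negative Laplacian, SPD thanks to the outlet
  # Dirichlet closure)
  cx <- 1 / grid$hx^2; cy <- 1 / grid$hy^2
  linkE <- matrix(0, nx, ny)
  linkE[1:(nx - 1L), ] <- cx * (fluid[1:(nx - 1L), ] & fluid[2:nx, ])
  linkN <- matrix(0, nx, ny)
  linkN[, 1:(ny - 1L)] <- cy * (fluid[, 1:(ny - 1L)] & fluid[, 2:ny])
  outlet_coef <- matrix(0, nx, ny)
  outlet_coef[nx, ] <- 2 * cx * fluid[nx, ]

  diag_val <- outlet_coef
  diag_val <- diag_val + linkE + rbind(0, linkE[-nx, ])     # east + west
  diag_val <- diag_val + linkN + cbind(0, linkN[, -ny])     # north + south

  ii <- idx[fluid]; jj <- ii; xx <- diag_val[fluid]
  eh <- which(linkE > 0, arr.ind = TRUE)
  if (nrow(eh)) {
    a <- idx[eh]; b <- idx[cbind(eh[, 1] + 1L, eh[, 2])]
    ii <- c(ii, a, b); jj <- c(jj, b, a)
    xx <- c(xx, -linkE[eh], -linkE[eh])
  }
  nh <- which(linkN > 0, arr.ind = TRUE)
  if (nrow(nh)) {
    a <- idx[nh]; b <- idx[cbind(nh[, 1], nh[, 2] + 1L)]
    ii <- c(ii, a, b); jj <- c(jj, b, a)
    xx <- c(xx, -linkN[nh], -linkN[nh])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(sum(fluid), sum(fluid)))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)

  structure(list(grid = grid, mask = mask, fluid = fluid, props = props,
                 u_forced = u_forced, v_forced = v_forced,
                 inlet_open = fluid[1L, ], idx = idx, chol = ch),
            class = "flow_solver")
}

#' Initialize a flow state
#'
#' Plug axial velocity equal to the inlet speed at `t0` in the lumen, zero
#' transverse velocity and zero pressure, followed by one projection so the
#' initial field is discretely divergence-free.
#'
#' @param solver a [new_flow_solver()].
#' @param t0 initial time (s).
#' @param U0 initial plug speed (m/s); default the inlet waveform at `t0`.
#' @return object of class `flow_state` with staggered fields `u`
#'   (`(nx+1) x ny`), `v` (`nx x (ny+1)`), cell-centred `p`, and time `t`.
#' @export
initialize_state <- function(solver, t0 = 0, U0 = inlet_velocity_ms(t0)) {
  g <- solver$grid
  u <- matrix(U0, g$nx + 1L, g$ny)
  v <- matrix(0, g$nx, g$ny + 1L)
  u[solver$u_forced] <- 0
  v[solver$v_forced] <- 0
  u[1L, ] <- ifelse(solver$inlet_open, U0, 0)
  st <- structure(list(u = u, v = v, p = matrix(0, g$nx, g$ny), t = t0),
                  class = "flow_state")
  st <- project_state(solver, st, U_in = U0)
  st$p <- matrix(0, g$nx, g$ny)
  st
}

# divergence at cell centres (zero reported in solid cells)
divergence_field <- function(solver, state) {
  g <- solver$grid
  d <- (state$u[-1L, , drop = FALSE] - state$u[-(g$nx + 1L), , drop = FALSE]) / g$hx +
       (state$v[, -1L, drop = FALSE] - state$v[, -(g$ny + 1L), drop = FALSE]) / g$hy
  d[solver$mask] <- 0
  d
}

#' Maximum discrete divergence over the lumen
#' @param solver a [new_flow_solver()].
#' @param state a [flow_state][initialize_state()].
#' @return `max |div u|` (1/s) over fluid cells.
#' @export
max_divergence <- function(solver, state) max(abs(divergence_field(solver, state)))

# pressure-projection: make (u, v) divergence-free, leaving forced faces and
# the inlet Dirichlet untouched.  `dtrho` = dt/rho scaling of the correction.
project_state <- function(solver, state, U_in, dtrho = 1) {
  g <- solver$grid; nx <- g$nx; ny <- g$ny
  u <- state$u; v <- state$v
  u[1L, ] <- ifelse(solver$inlet_open, U_in, 0)
  u[solver$u_forced] <- 0
  v[solver$v_forced] <- 0
  div <- (u[-1L, ] - u[-(nx + 1L), ]) / g$hx + (v[, -1L] - v[, -(ny + 1L)]) / g$hy
  b <- -div[solver$fluid] / dtrho
  q <- as.numeric(Matrix::solve(solver$chol, b))
  p <- matrix(0, nx, ny); p[solver$fluid] <- q

  corr_ok_u <- !solver$u_forced[2:nx, , drop = FALSE]
  u[2:nx, ][corr_ok_u] <- (u[2:nx, ] - dtrho * (p[2:nx, ] - p[1:(nx - 1L), ]) / g$hx)[corr_ok_u]
  out_ok <- solver$fluid[nx, ] & !solver$u_forced[nx + 1L, ]
  u[nx + 1L, out_ok] <- (u[nx + 1L, ] - dtrho * (0 - p[nx, ]) / (g$hx / 2))[out_ok]
  corr_ok_v <- !solver$v_forced[, 2:ny, drop = FALSE]
  v[, 2:ny][corr_ok_v] <- (v[, 2:ny] - dtrho * (p[, 2:ny] - p[, 1:(ny - 1L)]) / g$hy)[corr_ok_v]

  state$u <- u; state$v <- v; state$p <- p
  state
}

# interpolate v to u-face locations and u to v-face locations
v_at_u_faces <- function(v, nx, ny) {
  iL <- pmax(seq_len(nx + 1L) - 1L, 1L); iR <- pmin(seq_len(nx + 1L), nx)
  0.25 * (v[iL, 1:ny] + v[iL, 2:(ny + 1L)] + v[iR, 1:ny] + v[iR, 2:(ny + 1L)])
}
u_at_v_faces <- function(u, nx, ny) {
  jS <- pmax(seq_len(ny + 1L) - 1L, 1L); jN <- pmin(seq_len(ny + 1L), ny)
  0.25 * (u[1:nx, jS] + u[2:(nx + 1L), jS] + u[1:nx, jN] + u[2:(nx + 1L), jN])
}

# deviatoric viscous acceleration on u and v faces for spatially varying
# effective viscosity mu_e (cell-centred):  (1/rho) div[ mu_e (grad u + grad u^T) ]
viscous_terms <- function(solver, u, v, mu_c) {
  g <- solver$grid; nx <- g$nx; ny <- g$ny
  hx <- g$hx; hy <- g$hy

  # corner (node) viscosity: average of the 4 adjacent cells, clamped
  ic <- pmax(seq_len(nx + 1L) - 1L, 1L); ip <- pmin(seq_len(nx + 1L), nx)
  jc <- pmax(seq_len(ny + 1L) - 1L, 1L); jp <- pmin(seq_len(ny + 1L), ny)
  mu_n <- 0.25 * (mu_c[ic, jc] + mu_c[ic, jp] + mu_c[ip, jc] + mu_c[ip, jp])

  # shear rate at corners
  dudy_n <- matrix(0, nx + 1L, ny + 1L)
  dudy_n[, 2:ny] <- (u[, 2:ny] - u[, 1:(ny - 1L)]) / hy
  dudy_n[, 1L] <- 2 * u[, 1L] / hy          # no-slip wall (ghost -u)
  dudy_n[, ny + 1L] <- -2 * u[, ny] / hy
  dvdx_n <- matrix(0, nx + 1L, ny + 1L)
  dvdx_n[2:nx, ] <- (v[2:nx, ] - v[1:(nx - 1L), ]) / hx
  dvdx_n[1L, ] <- 2 * v[1L, ] / hx          # inlet: v = 0 on the boundary
  dvdx_n[nx + 1L, ] <- 0                    # outlet: zero-gradient
  tau12 <- mu_n * (dudy_n + dvdx_n)

  # normal stresses at cell centres
  t11 <- 2 * mu_c * (u[-1L, ] - u[-(nx + 1L), ]) / hx
  t22 <- 2 * mu_c * (v[, -1L] - v[, -(ny + 1L)]) / hy

  visc_u <- matrix(0, nx + 1L, ny)
  visc_u[2:nx, ] <- (t11[2:nx, ] - t11[1:(nx - 1L), ]) / hx +
                    (tau12[2:nx, 2:(ny + 1L)] - tau12[2:nx, 1:ny]) / hy
  visc_v <- matrix(0, nx, ny + 1L)
  visc_v[, 2:ny] <- (t22[, 2:ny] - t22[, 1:(ny - 1L)]) / hy +
                    (tau12[2:(nx + 1L), 2:ny] - tau12[1:nx, 2:ny]) / hx
  list(u = visc_u / solver$props$rho, v = visc_v / solver$props$rho)
}

#' Advance the flow by one fractional-step (projection) time step
#'
#' Explicit second-order upwind advection and deviatoric viscous stresses
#' (with optional eddy viscosity), immersed body force, then a pressure
#' projection that enforces the discrete divergence constraint.  Boundary
#' conditions: Dirichlet plug inlet at speed `U_in`, no-slip channel walls
#' and masked solid cells, `p = 0` at the outlet.
#'
#' @param solver a [new_flow_solver()].
#' @param state the current [flow_state][initialize_state()].
#' @param dt time step (s); must satisfy the advective CFL bound (checked).
#' @param U_in inlet plug speed (m/s) at the end of the step; default the
#'   pulsatile waveform at `state$t + dt`.
#' @param mu_t optional cell-centred eddy viscosity field (Pa s).
#' @param fx,fy optional body-force densities (N m^-3) at u/v faces.
#' @param stokes if `TRUE` the advective (inertial) terms are dropped.
#' @param cfl CFL fraction used for the admissibility check.
#' @return the updated `flow_state` (with `div_max` attribute refreshed).
#' @export
advance_flow <- function(solver, state, dt, U_in = NULL, mu_t = NULL,
                         fx = NULL, fy = NULL, stokes = FALSE, cfl = 1) {
  g <- solver$grid; nx <- g$nx; ny <- g$ny
  rho <- solver$props$rho
  if (is.null(U_in)) U_in <- inlet_velocity_ms(state$t + dt)
  u <- state$u; v <- state$v
  u[1L, ] <- ifelse(solver$inlet_open, U_in, 0)
  u[solver$u_forced] <- 0
  v[solver$v_forced] <- 0

  if (!stokes) {
    adm <- courant_dt(solver, state, cfl = cfl)
    if (dt > adm * (1 + 1e-9))
      stop_ijv("CFL violation: dt = %.3g s exceeds admissible %.3g s", dt, adm)
  }

  mu_c <- matrix(solver$props$mu, nx, ny)
  if (!is.null(mu_t)) mu_c <- mu_c + mu_t
  vis <- viscous_terms(solver, u, v, mu_c)

  if (stokes) {
    adv_u <- 0; adv_v <- 0
  } else {
    vau <- v_at_u_faces(v, nx, ny)
    dudx <- upwind_ddx(u, u, g$hx)
    dudy <- upwind_ddy(u, vau, g$hy,
                       list(m1 = -u[, 1L], m2 = -u[, 2L],
                            p1 = -u[, ny], p2 = -u[, ny - 1L]))
    adv_u <- u * dudx + vau * dudy
    uav <- u_at_v_faces(u, nx, ny)
    dvdx <- upwind_ddx(v, uav, g$hx)
    dvdy <- t(upwind_ddx(t(v), t(v), g$hy))
    adv_v <- uav * dvdx + v * dvdy
  }

  us <- u + dt * (-adv_u + vis$u + if (is.null(fx)) 0 else fx / rho)
  vs <- v + dt * (-adv_v + vis$v + if (is.null(fy)) 0 else fy / rho)
  us[1L, ] <- ifelse(solver$inlet_open, U_in, 0)
  us[nx + 1L, ] <- us[nx, ]                 # provisional outlet (zero-gradient)
  us[solver$u_forced] <- 0
  vs[solver$v_forced] <- 0

  state$u <- us; state$v <- vs
  state <- project_state(solver, state, U_in = U_in, dtrho = dt / rho)
  state$t <- state$t + dt
  if (!all(is.finite(state$u)) || !all(is.finite(state$v)))
    stop_ijv("non-finite velocity detected at t = %.4f s (dt = %.3g s)",
             state$t, dt)
  state
}

#' Advance in Stokes (inertia-free) mode
#'
#' Same contract as [advance_flow()] with the advective terms omitted.
#' @inheritParams advance_flow
#' @export
stokes_advance_flow <- function(solver, state, dt, U_in = NULL, mu_t = NULL,
                                fx = NULL, fy = NULL) {
  advance_flow(solver, state, dt, U_in = U_in, mu_t = mu_t,
               fx = fx, fy = fy, stokes = TRUE)
}

#' Admissible advective time step
#'
#' `dt = cfl * min(hx / max|u|, hy / max|v|)`, capped at `dt_max`; returns
#' `dt_max` for a quiescent field.
#'
#' @inheritParams advance_flow
#' @param cfl CFL fraction in (0, 1].
#' @param dt_max upper bound on the step (s).
#' @return admissible time step (s).
#' @export
courant_dt <- function(solver, state, cfl = 0.5, dt_max = 0.01) {
  if (cfl <= 0 || cfl > 1) stop_ijv("cfl must lie in (0, 1]")
  g <- solver$grid
  umax <- max(abs(state$u)); vmax <- max(abs(state$v))
  dtu <- if (umax > 0) g$hx / umax else Inf
  dtv <- if (vmax > 0) g$hy / vmax else Inf
  min(cfl * min(dtu, dtv), dt_max)
}

# explicit diffusive stability bound for the viscous terms
diffusive_dt <- function(solver, mu_t_max = 0, safety = 0.25) {
  g <- solver$grid
  nu <- (solver$props$mu + mu_t_max) / solver$props$rho
  safety * min(g$hx, g$hy)^2 / nu
}
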
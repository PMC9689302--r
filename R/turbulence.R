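#' Wilcox-type k-omega closure coefficients
#'
#' The closure constants: `alpha = 13/25`, `beta0 = 13/125`,
#' `beta0_star = 9/100`, `sigma = sigma_star = 1/2`.  The auxiliary
#' functions `f_beta` (vortex stretching, identically 1 in strict 2D) and
#' `f_beta_star` (cross-diffusion correction via `chi_k`) modulate
#' `beta = beta0 * f_beta` and `beta_star = beta0_star * f_beta_star`.
#'
#' @param alpha,beta0,beta0_star,sigma,sigma_star closure constants.
#' @param omega_min positivity floor for the specific dissipation rate
#'   (1/s).
#' @return object of class `komega_coefficients`.
#' @export
komega_coefficients <- function(alpha = 13 / 25, beta0 = 13 / 125,
                                beta0_star = 9 / 100,
                                sigma = 1 / 2, sigma_star = 1 / 2,
                                omega_min = 1e-6) {
  vals <- c(alpha, beta0, beta0_star, sigma, sigma_star, omega_min)
  if (any(vals <= 0)) stop_ijv("all k-omega coefficients must be positive")
  structure(list(alpha = alpha, beta0 = beta0, beta0_star = beta0_star,
                 sigma = sigma, sigma_star = sigma_star,
                 omega_min = omega_min),
            class = "komega_coefficients")
}

#' Eddy viscosity
#'
#' `mu_T = rho * k / omega`, pointwise.
#'
#' @param rho fluid density (kg m^-3).
#' @param k turbulent kinetic energy field (m^2 s^-2).
#' @param omega specific dissipation rate field (s^-1), floored positive.
#' @return eddy viscosity (Pa s), same shape as `k`.
#' @export
eddy_viscosity <- function(rho, k, omega) {
  if (any(omega <= 0)) stop_ijv("omega must be positive (apply the floor first)")
  rho * k / omega
}

#' Turbulence production term
#'
#' `Pk = mu_T * [grad u : (grad u + grad u^T) - (2/3) (div u)^2]
#'  - (2/3) rho k div u`.  For discretely divergence-free fields the
#' dilatational terms contribute only round-off.
#'
#' @param dudx,dudy,dvdx,dvdy cell-centred velocity-gradient components
#'   (1/s).
#' @param mu_t eddy viscosity (Pa s).
#' @param rho density (kg m^-3).
#' @param k turbulent kinetic energy (m^2 s^-2).
#' @return production `Pk` (W m^-3).
#' @export
komega_production <- function(dudx, dudy, dvdx, dvdy, mu_t, rho, k) {
  divu <- dudx + dvdy
  dd <- dudx * (2 * dudx) + dudy * (dudy + dvdx) +
        dvdx * (dvdx + dudy) + dvdy * (2 * dvdy)
  mu_t * (dd - (2 / 3) * divu^2) - (2 / 3) * rho * k * divu
}

#' Inlet turbulence values from intensity and length scale
#'
#' `k = 1.5 (I U)^2` and `omega = sqrt(k) / (C l)` with
#' `C = beta0_star^(1/4)` (approximately 0.5477), the standard
#' eddy-viscosity calibration constant.
#'
#' @param U inlet speed (m/s).
#' @param intensity turbulence intensity (fraction), default 0.05.
#' @param length_scale turbulent length scale (m).
#' @param coeffs a [komega_coefficients()].
#' @return list with elements `k` and `omega`.
#' @export
inlet_k_omega <- function(U, intensity = 0.05, length_scale = 0.015 / 10,
                          coeffs = komega_coefficients()) {
  if (intensity <= 0) stop_ijv("intensity must be positive")
  k <- 1.5 * (intensity * U)^2
  omega <- pmax(sqrt(k) / (coeffs$beta0_star^0.25 * length_scale),
                coeffs$omega_min)
  list(k = k, omega = omega)
}

#' Initialize turbulence state
#'
#' Uniform `k`, `omega` over the grid (values inside solid cells are
#' carried but inert).
#'
#' @param solver a [new_flow_solver()].
#' @param k0,omega0 initial levels.
#' @return object of class `turbulence_state` with matrices `k`, `omega`.
#' @export
initialize_k_omega <- function(solver, k0, omega0) {
  g <- solver$grid
  structure(list(k = matrix(k0, g$nx, g$ny),
                 omega = matrix(omega0, g$nx, g$ny),
                 clip_events = 0L),
            class = "turbulence_state")
}

# cell-centred velocity and gradients from the staggered state, with
# no-slip ghosts at the channel walls
center_velocity <- function(solver, state) {
  g <- solver$grid; nx <- g$nx; ny <- g$ny
  uc <- 0.5 * (state$u[-1L, ] + state$u[-(nx + 1L), ])
  vc <- 0.5 * (state$v[, -1L] + state$v[, -(ny + 1L)])
  uc[solver$mask] <- 0; vc[solver$mask] <- 0
  list(u = uc, v = vc)
}

center_gradients <- function(solver, state) {
  g <- solver$grid; nx <- g$nx; ny <- g$ny
  cv <- center_velocity(solver, state)
  dudx <- (state$u[-1L, ] - state$u[-(nx + 1L), ]) / g$hx
  dvdy <- (state$v[, -1L] - state$v[, -(ny + 1L)]) / g$hy
  gx <- function(q) {
    d <- (shift_xp(q) - shift_xm(q)) / (2 * g$hx)
    d[1L, ] <- (q[2L, ] - q[1L, ]) / g$hx
    d[nx, ] <- (q[nx, ] - q[nx - 1L, ]) / g$hx
    d
  }
  gy <- function(q, odd_wall = TRUE) {
    qa <- if (odd_wall) -q[, 1L] else q[, 1L]
    qb <- if (odd_wall) -q[, ny] else q[, ny]
    qq <- cbind(qa, q, qb, deparse.level = 0)
    (qq[, 3:(ny + 2L)] - qq[, 1:ny]) / (2 * g$hy)
  }
  list(dudx = dudx, dudy = gy(cv$u), dvdx = gx(cv$v), dvdy = dvdy,
       uc = cv$u, vc = cv$v)
}

#' Advance the k-omega fields by one time step
#'
#' First-order upwind advection, conservative diffusion with effective
#' diffusivities `mu + sigma* mu_T` (for k) and `mu + sigma mu_T` (for
#' omega), production `Pk`, and destruction terms `beta_star rho k omega`
#' and `beta rho omega^2` integrated semi-implicitly (which reproduces the
#' homogeneous decay exactly for omega).  `f_beta` is 1 in 2D (the
#' vortex-stretching invariant vanishes); `f_beta_star` follows the
#' piecewise cross-diffusion form in `chi_k = (grad k . grad omega)/omega^3`.
#' Positivity is preserved by clipping (`k >= 0`, `omega >= omega_min`);
#' clip events are counted on the returned state.
#'
#' @param solver a [new_flow_solver()].
#' @param state current [flow_state][initialize_state()].
#' @param turb current [turbulence_state][initialize_k_omega()].
#' @param dt time step (s).
#' @param coeffs a [komega_coefficients()].
#' @param inlet list with inlet `k`, `omega` values (see [inlet_k_omega()]).
#' @return updated `turbulence_state`.
#' @export
advance_k_omega <- function(solver, state, turb, dt,
                            coeffs = komega_coefficients(),
                            inlet = NULL) {
  g <- solver$grid; nx <- g$nx; ny <- g$ny
  rho <- solver$props$rho; mu <- solver$props$mu
  k <- turb$k; om <- turb$omega
  gr <- center_gradients(solver, state)
  mu_t <- eddy_viscosity(rho, k, pmax(om, coeffs$omega_min))
  Pk <- komega_production(gr$dudx, gr$dudy, gr$dvdx, gr$dvdy, mu_t, rho, k)
  Pk <- pmax(Pk, 0)

  adv <- function(q, qin) {
    dqdx <- ifelse(gr$uc >= 0,
                   (q - shift_xm(q)) / g$hx, (shift_xp(q) - q) / g$hx)
    if (!is.null(qin))  # inlet Dirichlet for incoming flow
      dqdx[1L, ] <- ifelse(gr$uc[1L, ] >= 0, (q[1L, ] - qin) / (g$hx / 2),
                           dqdx[1L, ])
    dqdy <- ifelse(gr$vc >= 0,
                   (q - shift_ym(q)) / g$hy, (shift_yp(q) - q) / g$hy)
    gr$uc * dqdx + gr$vc * dqdy
  }
  diffuse <- function(q, dcoef, wall_value) {
    # face diffusivities by arithmetic mean; Dirichlet wall_value at the
    # channel walls and solid cells (half-cell), Neumann at inlet/outlet
    dE <- matrix(0, nx, ny); dW <- matrix(0, nx, ny)
    dN <- matrix(0, nx, ny); dS <- matrix(0, nx, ny)
    fE <- 0.5 * (dcoef + shift_xp(dcoef)); fN <- 0.5 * (dcoef + shift_yp(dcoef))
    dE[-nx, ] <- (fE * (shift_xp(q) - q))[-nx, ] / g$hx
    dW[-1L, ] <- dE[-nx, ]
    dN[, -ny] <- (fN * (shift_yp(q) - q))[, -ny] / g$hy
    dS[, -1L] <- dN[, -ny]
    if (!is.null(wall_value)) {
      dN[, ny] <- dcoef[, ny] * (wall_value - q[, ny]) / (g$hy / 2)
      dS[, 1L] <- -dcoef[, 1L] * (wall_value - q[, 1L]) / (g$hy / 2)
    }
    (dE - dW) / g$hx + (dN - dS) / g$hy
  }

  # cross-diffusion parameter chi_k and f_beta_star
  gkx <- (shift_xp(k) - shift_xm(k)) / (2 * g$hx)
  gky <- (shift_yp(k) - shift_ym(k)) / (2 * g$hy)
  gox <- (shift_xp(om) - shift_xm(om)) / (2 * g$hx)
  goy <- (shift_yp(om) - shift_ym(om)) / (2 * g$hy)
  chik <- (gkx * gox + gky * goy) / pmax(om, coeffs$omega_min)^3
  fbs <- ifelse(chik <= 0, 1, (1 + 680 * chik^2) / (1 + 400 * chik^2))
  beta_star <- coeffs$beta0_star * fbs
  beta <- coeffs$beta0                      # f_beta = 1 in 2D

  kin <- if (is.null(inlet)) NULL else inlet$k
  oin <- if (is.null(inlet)) NULL else inlet$omega
  rk <- -adv(k, kin) + diffuse(k, (mu + coeffs$sigma_star * mu_t) / rho, 0) +
        Pk / rho
  ro <- -adv(om, oin) + diffuse(om, (mu + coeffs$sigma * mu_t) / rho, NULL) +
        coeffs$alpha * ifelse(k > 0, om / k, 0) * Pk / rho

  k_new <- (k + dt * rk) / (1 + dt * beta_star * om)
  om_new <- (om + dt * ro) / (1 + dt * beta * om)

  clipped <- sum(k_new < 0) + sum(om_new < coeffs$omega_min)
  k_new <- pmax(k_new, 0)
  om_new <- pmax(om_new, coeffs$omega_min)
  k_new[solver$mask] <- 0
  om_new[solver$mask] <- coeffs$omega_min
  if (!all(is.finite(k_new)) || !all(is.finite(om_new)))
    stop_ijv("non-finite k/omega at t = %.4f s", state$t)
  structure(list(k = k_new, omega = om_new,
                 clip_events = turb$clip_events + clipped),
            class = "turbulence_state")
}
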
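#' Hyperelastic leaflet material
#'
#' Compressible neo-Hookean solid described by Young's modulus `E` and
#' Poisson ratio `nu`, with derived Lame parameters, plus the solid
#' density.  Defaults are the venous-valve values: E = 2.6 MPa, nu = 0.3
#' (giving mu_s = 1.0 MPa, lambda_s = 1.5 MPa) and rho_s = 1200 kg/m^3.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @param rho_s solid density (kg m^-3).
#' @return object of class `hyperelastic_material` with fields
#'   `E, nu, mu_s, lambda_s, rho_s`.
#' @export
hyperelastic_material <- function(E = 2.6e6, nu = 0.3, rho_s = 1200) {
  lam <- lame_from_modulus(E, nu)
  structure(list(E = as.numeric(E), nu = as.numeric(nu),
                 mu_s = lam$mu_s, lambda_s = lam$lambda_s,
                 rho_s = as.numeric(rho_s)),
            class = "hyperelastic_material")
}

#' Lame parameters from engineering constants
#'
#' `mu_s = E / (2 (1 + nu))`, `lambda_s = E nu / ((1 + nu)(1 - 2 nu))`.
#'
#' @param E Young's modulus (Pa), positive.
#' @param nu Poisson ratio in `[0, 0.5)`; the incompressible limit
#'   `nu >= 0.5` is rejected.
#' @return list with `mu_s` and `lambda_s` (Pa).
#' @examples
#' lame_from_modulus(2.6e6, 0.3)  # mu_s = 1.0 MPa, lambda_s = 1.5 MPa
#' @export
lame_from_modulus <- function(E, nu) {
  if (E <= 0) stop_ijv("E must be positive")
  if (nu < 0 || nu >= 0.5)
    stop_ijv("nu must lie in [0, 0.5); the incompressible limit is unsupported")
  list(mu_s = E / (2 * (1 + nu)),
       lambda_s = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

check_deformation <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == c(2L, 2L)))
  J <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  if (J <= 0) stop_ijv("inverted element: det F = %g <= 0", J)
  J
}

#' Neo-Hookean strain-energy density
#'
#' `Ws = mu_s/2 (I1 - 3) - mu_s ln J + lambda_s/2 (ln J)^2` with
#' `I1 = tr(F^T F)` evaluated in a plane-strain embedding (out-of-plane
#' stretch 1, so the 2x2 trace contributes `I1 - 1`) and `J = det F`
#' (elastic volume ratio; no inelastic split, `Jel = J`).
#'
#' @param F 2x2 in-plane deformation gradient.
#' @param material a [hyperelastic_material()].
#' @return strain energy density (J m^-3).
#' @export
strain_energy <- function(F, material) {
  J <- check_deformation(F)
  I1 <- sum(F * F) + 1          # plane strain: out-of-plane stretch = 1
  material$mu_s / 2 * (I1 - 3) - material$mu_s * log(J) +
    material$lambda_s / 2 * log(J)^2
}

#' Second Piola-Kirchhoff stress of the neo-Hookean model
#'
#' In-plane block `S = mu_s (I - C^-1) + lambda_s ln(J) C^-1` with
#' `C = F^T F`; equals `dWs/d(epsilon)` for the Green-Lagrange strain
#' `epsilon = (C - I)/2` (external stress `Sext = 0`).
#'
#' @inheritParams strain_energy
#' @return symmetric 2x2 stress tensor (Pa).
#' @export
pk2_stress <- function(F, material) {
  J <- check_deformation(F)
  C <- t(F) %*% F
  Cinv <- solve(C)
  S <- material$mu_s * (diag(2) - Cinv) + material$lambda_s * log(J) * Cinv
  (S + t(S)) / 2
}

#' Cauchy stress from the deformation gradient and PK2 stress
#'
#' `sigma = J^-1 F S F^T`.
#'
#' @param F 2x2 deformation gradient.
#' @param S 2x2 second Piola-Kirchhoff stress (Pa).
#' @return symmetric 2x2 Cauchy stress (Pa).
#' @export
cauchy_stress <- function(F, S) {
  J <- check_deformation(F)
  sig <- F %*% S %*% t(F) / J
  (sig + t(sig)) / 2
}

#' Lagrangian leaflet state
#'
#' Node positions and velocities of one valve leaflet discretized as an
#' elastic fiber, together with its (straight) reference configuration.
#' The first node is anchored at the vessel wall; the root tangent of the
#' reference configuration is retained so the fiber is clamped (it resists
#' rotation at the anchor, not just translation).
#'
#' @param x,y node coordinates (m), ordered from anchor to tip.
#' @param vx,vy node velocities (m/s).
#' @param anchored logical vector of fixed nodes.
#' @return object of class `leaflet_state`.
#' @export
leaflet_state <- function(x, y, vx = 0 * x, vy = 0 * y,
                          anchored = c(TRUE, rep(FALSE, length(x) - 1L))) {
  n <- length(x)
  if (n < 3L) stop_ijv("a leaflet needs at least 3 nodes")
  stopifnot(length(y) == n, length(anchored) == n)
  l0 <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(l0 <= 0)) stop_ijv("coincident adjacent nodes in the leaflet")
  structure(list(x = x, y = y, vx = vx, vy = vy,
                 ref_x = x, ref_y = y, l0 = l0,
                 root_tangent = c(x[2] - x[1], y[2] - y[1]) / l0[1],
                 anchored = anchored),
            class = "leaflet_state")
}

#' Elastic nodal forces of a leaflet fiber
#'
#' Negative variational derivative of the discrete stretching plus bending
#' energy.  Stretching stiffness `E h` and bending stiffness `E h^3 / 12`
#' per unit depth follow from the small-strain limit of the neo-Hookean
#' sheet of thickness `h`.  Bending uses the second-difference curvature
#' with a clamped root (reference tangent enforced at the anchor).
#'
#' @param state a [leaflet_state()].
#' @param material a [hyperelastic_material()].
#' @param thickness leaflet thickness `h` (m).
#' @return list of nodal force components `fx`, `fy` (N per metre of
#'   depth), zero in the reference configuration.
#' @export
leaflet_forces <- function(state, material, thickness) {
  n <- length(state$x)
  EA <- material$E * thickness
  EI <- material$E * thickness^3 / 12
  dx <- diff(state$x); dy <- diff(state$y)
  l <- sqrt(dx^2 + dy^2)
  if (any(l <= 0)) stop_ijv("coincident adjacent nodes in the leaflet")
  # stretching
  Tt <- EA * (l / state$l0 - 1)
  tx <- dx / l; ty <- dy / l
  fx <- numeric(n); fy <- numeric(n)
  fx[-n] <- fx[-n] + Tt * tx;  fy[-n] <- fy[-n] + Tt * ty
  fx[-1] <- fx[-1] - Tt * tx;  fy[-1] <- fy[-1] - Tt * ty
  # bending: b_i = x_{i+1} - 2 x_i + x_{i-1}; clamped root via the fixed
  # reference tangent (ghost node behind the anchor)
  l0m <- mean(state$l0)
  bx <- numeric(n); by <- numeric(n)
  if (n >= 3L) {
    ii <- 2:(n - 1L)
    bx[ii] <- state$x[ii + 1L] - 2 * state$x[ii] + state$x[ii - 1L]
    by[ii] <- state$y[ii + 1L] - 2 * state$y[ii] + state$y[ii - 1L]
  }
  bx[1] <- (state$x[2] - state$x[1]) - state$root_tangent[1] * state$l0[1]
  by[1] <- (state$y[2] - state$y[1]) - state$root_tangent[2] * state$l0[1]
  cb <- EI / l0m^3
  bxp <- c(bx[-1], 0); byp <- c(by[-1], 0)  # b_{j+1}, with b_{n+1} = 0
  bxm <- c(0, bx[-n]); bym <- c(0, by[-n])  # b_{j-1}, with b_0 = 0
  fx <- fx - cb * (bxm - 2 * bx + bxp)
  fy <- fy - cb * (bym - 2 * by + byp)
  # the clamp term b_1 couples to node 2 with coefficient +1, already
  # handled through bxm/bym; node 1 is anchored so its entry is unused
  list(fx = fx, fy = fy)
}

#' Elastic + kinetic energy of a leaflet (per unit depth)
#'
#' @inheritParams leaflet_forces
#' @return total mechanical energy (J per metre of depth).
#' @export
leaflet_energy <- function(state, material, thickness) {
  EA <- material$E * thickness
  EI <- material$E * thickness^3 / 12
  dx <- diff(state$x); dy <- diff(state$y)
  l <- sqrt(dx^2 + dy^2)
  es <- sum(EA / 2 * (l / state$l0 - 1)^2 * state$l0)
  n <- length(state$x); l0m <- mean(state$l0)
  bx <- numeric(n); by <- numeric(n)
  ii <- 2:(n - 1L)
  bx[ii] <- state$x[ii + 1L] - 2 * state$x[ii] + state$x[ii - 1L]
  by[ii] <- state$y[ii + 1L] - 2 * state$y[ii] + state$y[ii - 1L]
  bx[1] <- (state$x[2] - state$x[1]) - state$root_tangent[1] * state$l0[1]
  by[1] <- (state$y[2] - state$y[1]) - state$root_tangent[2] * state$l0[1]
  eb <- sum(EI / (2 * l0m^3) * (bx^2 + by^2))
  m <- node_masses(state, material, thickness)
  ek <- sum(0.5 * m * (state$vx^2 + state$vy^2))
  es + eb + ek
}

# lumped nodal masses per unit depth (kg/m)
node_masses <- function(state, material, thickness) {
  n <- length(state$x)
  w <- numeric(n)
  w[-n] <- w[-n] + state$l0 / 2
  w[-1] <- w[-1] + state$l0 / 2
  material$rho_s * thickness * w
}

#' Advance a leaflet by one explicit (symplectic Euler) step
#'
#' Interior nodes carry inertia `rho_s h` per unit area; anchored nodes do
#' not move.  An optional Rayleigh-type velocity damping tames startup
#' transients.
#'
#' @param state a [leaflet_state()].
#' @param forces list `fx`, `fy`: nodal forces per unit depth (N/m),
#'   typically elastic forces plus fluid traction.
#' @param dt time step (s).
#' @param material a [hyperelastic_material()].
#' @param thickness leaflet thickness (m).
#' @param damping velocity damping rate (1/s), default 0.
#' @param max_disp abort threshold on per-step node displacement (m);
#'   exceeding it signals an instability and suggests reducing `dt`.
#' @return updated `leaflet_state`.
#' @export
advance_leaflets <- function(state, forces, dt, material, thickness,
                             damping = 0, max_disp = Inf) {
  m <- node_masses(state, material, thickness)
  ax <- forces$fx / m - damping * state$vx
  ay <- forces$fy / m - damping * state$vy
  vx <- state$vx + dt * ax
  vy <- state$vy + dt * ay
  vx[state$anchored] <- 0; vy[state$anchored] <- 0
  dxs <- dt * vx; dys <- dt * vy
  if (max(abs(c(dxs, dys))) > max_disp)
    stop_ijv(paste0("leaflet instability: node moved %.3g m in one step ",
                    "(limit %.3g m); reduce dt"),
             max(abs(c(dxs, dys))), max_disp)
  state$vx <- vx; state$vy <- vy
  state$x <- state$x + dxs; state$y <- state$y + dys
  state
}

# tangent stiffness d(force)/d(position) of the discrete fiber, dense
# 2n x 2n in (x-block, y-block) ordering.  Stretch couples x and y through
# the segment direction; bending is a constant per-coordinate operator.
leaflet_stiffness <- function(state, material, thickness) {
  n <- length(state$x)
  EA <- material$E * thickness
  EI <- material$E * thickness^3 / 12
  K <- matrix(0, 2L * n, 2L * n)
  dx <- diff(state$x); dy <- diff(state$y)
  l <- sqrt(dx^2 + dy^2)
  tx <- dx / l; ty <- dy / l
  c1 <- EA / state$l0                 # t t^T coefficient
  c2 <- EA * (l / state$l0 - 1) / l   # (I - t t^T) coefficient
  for (k in seq_len(n - 1L)) {
    B <- c1[k] * rbind(c(tx[k]^2, tx[k] * ty[k]),
                       c(tx[k] * ty[k], ty[k]^2)) +
         c2[k] * rbind(c(1 - tx[k]^2, -tx[k] * ty[k]),
                       c(-tx[k] * ty[k], 1 - ty[k]^2))
    ia <- c(k, n + k); ib <- c(k + 1L, n + k + 1L)
    K[ia, ia] <- K[ia, ia] - B
    K[ib, ib] <- K[ib, ib] - B
    K[ia, ib] <- K[ia, ib] + B
    K[ib, ia] <- K[ib, ia] + B
  }
  # bending: F = -cb D^T D z per coordinate (row 1 is the root clamp)
  l0m <- mean(state$l0)
  D <- matrix(0, n - 1L, n)
  D[1, 1:2] <- c(-1, 1)
  if (n >= 3L) for (i in 2:(n - 1L)) D[i, (i - 1L):(i + 1L)] <- c(1, -2, 1)
  Kb <- -(EI / l0m^3) * crossprod(D)
  K[1:n, 1:n] <- K[1:n, 1:n] + Kb
  K[(n + 1L):(2L * n), (n + 1L):(2L * n)] <-
    K[(n + 1L):(2L * n), (n + 1L):(2L * n)] + Kb
  K
}

# one linearized backward-Euler step of the fiber coupled to the fluid by
# an implicit velocity-matching drag cv (N s/m^2 per unit depth) toward
# the nodal fluid velocity (Ux, Uy).  Returns the updated leaflet and the
# coupling impulse J = dt * cv * (U - v_new) exchanged with the fluid.
leaflet_implicit_step <- function(state, material, thickness, dt, Ux, Uy,
                                  cv, damping = 0,
                                  fx_ext = 0, fy_ext = 0) {
  n <- length(state$x)
  m <- node_masses(state, material, thickness)
  fel <- leaflet_forces(state, material, thickness)
  Fv <- c(fel$fx + fx_ext, fel$fy + fy_ext)
  K <- leaflet_stiffness(state, material, thickness)
  beta <- dt * cv / m
  diag_m <- rep(m * (1 + beta + dt * damping) / dt, 2L)
  A <- -dt * K
  diag(A) <- diag(A) + diag_m
  rhs <- c(m * state$vx, m * state$vy) + dt * Fv + dt * cv * c(Ux, Uy)
  fixed <- c(state$anchored, state$anchored)
  A[fixed, ] <- 0; A[, fixed] <- 0
  diag(A)[fixed] <- 1
  rhs[fixed] <- 0
  dz <- solve(A, rhs)
  vx <- dz[1:n] / dt; vy <- dz[(n + 1L):(2L * n)] / dt
  state$vx <- vx; state$vy <- vy
  state$x <- state$x + dz[1:n]
  state$y <- state$y + dz[(n + 1L):(2L * n)]
  list(leaf = state,
       Jx = dt * cv * (Ux - vx), Jy = dt * cv * (Uy - vy))
}

#' Tip displacement of a leaflet from its reference configuration
#' @param state a [leaflet_state()].
#' @return scalar displacement magnitude (m).
#' @export
leaflet_tip_displacement <- function(state) {
  n <- length(state$x)
  sqrt((state$x[n] - state$ref_x[n])^2 + (state$y[n] - state$ref_y[n])^2)
}
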
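# Immersed-boundary transfer between the Lagrangian leaflet nodes and the
# staggered Eulerian grid, built on the 4-point regularized delta kernel.

# 4-point regularized delta (one-dimensional), support |r| < 2, partition
# of unity on any integer-shifted sampling
ib_phi <- function(r) {
  a <- abs(r)
  out <- numeric(length(r))
  i1 <- a < 1
  out[i1] <- (3 - 2 * a[i1] + sqrt(1 + 4 * a[i1] - 4 * a[i1]^2)) / 8
  i2 <- a >= 1 & a < 2
  out[i2] <- (5 - 2 * a[i2] - sqrt(-7 + 12 * a[i2] - 4 * a[i2]^2)) / 8
  out
}

# stencil (linear indices + weights) of the 4x4 kernel footprint for a set
# of points on one staggered field.  stagger: "u" (x at faces, y at
# centres), "v" (x centres, y faces), "c" (both centres).  Out-of-range
# stencil entries are clamped to the nearest valid index; the weights are
# untouched, so interpolation/spreading stay exact adjoints.
ib_stencil <- function(xp, yp, grid, stagger = c("u", "v", "c")) {
  stagger <- match.arg(stagger)
  nx <- grid$nx; ny <- grid$ny
  if (any(xp < 0 | xp > grid$L | yp < 0 | yp > grid$D))
    stop_ijv("immersed node outside the domain")
  sx <- xp / grid$hx - switch(stagger, u = 0, v = 0.5, c = 0.5)
  sy <- yp / grid$hy - switch(stagger, u = 0.5, v = 0, c = 0.5)
  nrow_f <- switch(stagger, u = nx + 1L, v = nx, c = nx)
  ncol_f <- switch(stagger, u = ny, v = ny + 1L, c = ny)
  bx <- floor(sx); by <- floor(sy)
  n <- length(xp)
  idx <- matrix(0L, n, 16L); w <- matrix(0, n, 16L)
  for (a in 0:3) {
    ia <- bx - 1L + a                       # 0-based grid index along x
    wxa <- ib_phi(sx - ia)
    ica <- pmin(pmax(ia + 1L, 1L), nrow_f)  # clamped 1-based row
    for (b in 0:3) {
      jb <- by - 1L + b
      wyb <- ib_phi(sy - jb)
      jcb <- pmin(pmax(jb + 1L, 1L), ncol_f)
      col <- a * 4L + b + 1L
      idx[, col] <- ica + (jcb - 1L) * nrow_f
      w[, col] <- wxa * wyb
    }
  }
  list(idx = idx, w = w, nrow_f = nrow_f, ncol_f = ncol_f)
}

#' Regularized-delta weight stencil of one immersed node
#'
#' 4x4 footprint of the 4-point regularized delta kernel on cell centres;
#' the weights are nonnegative and sum to 1 (partition of unity).
#'
#' @param x,y node position (m), inside the domain.
#' @param grid a [flow_grid()].
#' @return list with integer index vectors `i`, `j` (the footprint rows and
#'   columns) and the 4x4 weight matrix `w`.
#' @export
delta_weights <- function(x, y, grid) {
  st <- ib_stencil(x, y, grid, "c")
  i <- (st$idx[1, ] - 1L) %% st$nrow_f + 1L
  j <- (st$idx[1, ] - 1L) %/% st$nrow_f + 1L
  list(i = matrix(i, 4, 4), j = matrix(j, 4, 4),
       w = matrix(st$w[1, ], 4, 4))
}

#' Interpolate the staggered velocity to immersed nodes
#'
#' Exact (to round-off) for fields affine in position, by the first-moment
#' property of the 4-point kernel.
#'
#' @param solver a [new_flow_solver()].
#' @param state a [flow_state][initialize_state()].
#' @param x,y node positions (m).
#' @return list of nodal velocity components `u`, `v` (m/s).
#' @export
interpolate_velocity <- function(solver, state, x, y) {
  su <- ib_stencil(x, y, solver$grid, "u")
  sv <- ib_stencil(x, y, solver$grid, "v")
  list(u = rowSums(su$w * matrix(state$u[su$idx], nrow(su$idx))),
       v = rowSums(sv$w * matrix(state$v[sv$idx], nrow(sv$idx))))
}

#' Spread nodal forces onto the staggered grid
#'
#' The discrete adjoint of [interpolate_velocity()] with the same kernel:
#' nodal forces per unit depth (N/m) become body-force densities (N/m^3)
#' whose grid integral equals the total nodal force.
#'
#' @param solver a [new_flow_solver()].
#' @param x,y node positions (m).
#' @param fx,fy nodal force components per unit depth (N/m).
#' @return list of body-force fields `fx` (`(nx+1) x ny`) and `fy`
#'   (`nx x (ny+1)`), in N/m^3.
#' @export
spread_forces <- function(solver, x, y, fx, fy) {
  g <- solver$grid
  cellA <- g$hx * g$hy
  acc <- function(st, val) {
    out <- numeric(st$nrow_f * st$ncol_f)
    contrib <- as.vector(st$w) * rep(val, times = 16L)
    s <- rowsum(contrib, group = as.vector(st$idx))
    out[as.integer(rownames(s))] <- s
    matrix(out / cellA, st$nrow_f, st$ncol_f)
  }
  su <- ib_stencil(x, y, g, "u")
  sv <- ib_stencil(x, y, g, "v")
  list(fx = acc(su, fx), fy = acc(sv, fy))
}

# short-range repulsion when the two leaflets come within `dmin`;
# quadratic penalty, zero beyond dmin.  Returns per-node forces to add.
leaflet_contact_forces <- function(lower, upper, dmin, stiffness) {
  dx <- outer(lower$x, upper$x, "-")
  dy <- outer(lower$y, upper$y, "-")
  d <- sqrt(dx^2 + dy^2)
  hit <- which(d < dmin, arr.ind = TRUE)
  fl <- list(fx = numeric(length(lower$x)), fy = numeric(length(lower$y)))
  fu <- list(fx = numeric(length(upper$x)), fy = numeric(length(upper$y)))
  if (nrow(hit)) {
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 1]; j <- hit[r, 2]
      dd <- max(d[i, j], 1e-12)
      mag <- stiffness * (dmin - dd)
      ux <- dx[i, j] / dd; uy <- dy[i, j] / dd
      fl$fx[i] <- fl$fx[i] + mag * ux; fl$fy[i] <- fl$fy[i] + mag * uy
      fu$fx[j] <- fu$fx[j] - mag * ux; fu$fy[j] <- fu$fy[j] - mag * uy
    }
  }
  list(lower = fl, upper = fu)
}

# keep free nodes out of wall cells: project back and cancel the normal
# velocity; returns the state and a violation count.  Anchored nodes sit
# on the wall by construction and are exempt.
wall_guard <- function(leaf, grid, margin) {
  lo <- margin; hi <- grid$D - margin
  free <- !leaf$anchored
  bad_lo <- free & leaf$y < lo; bad_hi <- free & leaf$y > hi
  viol <- sum(bad_lo | bad_hi)
  leaf$y[bad_lo] <- lo; leaf$vy[bad_lo] <- pmax(leaf$vy[bad_lo], 0)
  leaf$y[bad_hi] <- hi; leaf$vy[bad_hi] <- pmin(leaf$vy[bad_hi], 0)
  list(leaf = leaf, violations = viol)
}

#' One loosely-coupled fluid-structure step
#'
#' Sequence: interpolate the fluid velocity to the leaflet nodes ->
#' linearized backward-Euler structural step with an implicit
#' velocity-matching drag toward the local fluid velocity (unconditionally
#' stable for the stiff fiber, and free of the added-mass instability at
#' the near-unity solid/fluid density ratio) -> spread the opposite of the
#' exchanged coupling impulse onto the fluid as a body force -> fluid
#' projection step.  Anchored nodes never move.
#'
#' @param solver a [new_flow_solver()].
#' @param state current [flow_state][initialize_state()].
#' @param valve list with `spec`, `lower`, `upper` (see [build_valve()]).
#' @param dt fluid time step (s).
#' @param material a [hyperelastic_material()].
#' @param U_in inlet speed (m/s) at `t + dt`.
#' @param mu_t optional eddy-viscosity field passed to the fluid step.
#' @param stokes drop fluid inertial terms.
#' @param ib_penalty dimensionless strength of the velocity-matching
#'   coupling (fraction of the explicit stability limit).
#' @param damping structural damping rate (1/s).
#' @param hold_fixed if `TRUE` the leaflets act as a fixed obstacle
#'   (penalty forcing toward zero velocity at the reference positions).
#' @return list with updated `state`, `valve`, and `diagnostics` (total
#'   coupling force, max tip displacement, wall-guard violations).
#' @export
coupled_step <- function(solver, state, valve, dt, material,
                         U_in = NULL, mu_t = NULL, stokes = FALSE,
                         ib_penalty = 0.3, damping = 0,
                         hold_fixed = FALSE) {
  g <- solver$grid
  h <- valve$spec$thickness
  if (is.null(U_in)) U_in <- inlet_velocity_ms(state$t + dt)
  rho <- solver$props$rho
  cv <- ib_penalty * rho * g$hx * g$hy / dt   # N s / m^2 per unit depth

  leaves <- list(lower = valve$lower, upper = valve$upper)
  allx <- c(leaves$lower$x, leaves$upper$x)
  ally <- c(leaves$lower$y, leaves$upper$y)
  uv <- interpolate_velocity(solver, state, allx, ally)
  n1 <- length(leaves$lower$x)
  vel <- list(
    lower = list(u = uv$u[seq_len(n1)], v = uv$v[seq_len(n1)]),
    upper = list(u = uv$u[-seq_len(n1)], v = uv$v[-seq_len(n1)]))

  viol <- 0L
  imp <- list()   # per-leaflet coupling impulse on the structure (N s / m)
  if (hold_fixed) {
    # fixed obstacle: penalty force toward zero velocity at the current
    # (reference) node positions, applied for the whole step
    for (nm in names(leaves))
      imp[[nm]] <- list(x = dt * cv * vel[[nm]]$u,
                        y = dt * cv * vel[[nm]]$v)
  } else {
    # linearized backward-Euler structural step: unconditionally stable
    # for the stiff fiber (elastic frequencies far above the flow time
    # scale), with the velocity-matching drag toward the local fluid
    # velocity integrated implicitly
    EA <- material$E * h
    l0 <- mean(c(leaves$lower$l0, leaves$upper$l0))
    contact <- leaflet_contact_forces(leaves$lower, leaves$upper,
                                      dmin = min(g$hx, g$hy),
                                      stiffness = EA / l0)
    max_disp <- min(g$hx, g$hy)
    for (nm in names(leaves)) {
      lf <- leaves[[nm]]
      stp <- leaflet_implicit_step(lf, material, h, dt,
                                   Ux = vel[[nm]]$u, Uy = vel[[nm]]$v,
                                   cv = cv, damping = damping,
                                   fx_ext = contact[[nm]]$fx,
                                   fy_ext = contact[[nm]]$fy)
      if (max(abs(c(stp$leaf$x - lf$x, stp$leaf$y - lf$y))) > max_disp)
        stop_ijv(paste0("leaflet instability: node moved %.3g m in one ",
                        "step (limit %.3g m); reduce dt"),
                 max(abs(c(stp$leaf$x - lf$x, stp$leaf$y - lf$y))), max_disp)
      wg <- wall_guard(stp$leaf, g, margin = g$hy / 4)
      viol <- viol + wg$violations
      leaves[[nm]] <- wg$leaf
      imp[[nm]] <- list(x = stp$Jx, y = stp$Jy)
    }
  }

  # reaction on the fluid: the time-averaged coupling force, opposed
  sp <- spread_forces(solver, allx, ally,
                      -c(imp$lower$x, imp$upper$x) / dt,
                      -c(imp$lower$y, imp$upper$y) / dt)
  state <- advance_flow(solver, state, dt, U_in = U_in, mu_t = mu_t,
                        fx = sp$fx, fy = sp$fy, stokes = stokes)

  valve$lower <- leaves$lower; valve$upper <- leaves$upper
  list(state = state, valve = valve,
       diagnostics = list(
         coupling_force = c(sum(imp$lower$x + imp$upper$x),
                            sum(imp$lower$y + imp$upper$y)) / dt,
         tip_disp = c(lower = leaflet_tip_displacement(valve$lower),
                      upper = leaflet_tip_displacement(valve$upper)),
         wall_violations = viol))
}
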
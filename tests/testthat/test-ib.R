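test_that("delta weights are a nonnegative partition of unity", {
  grid <- flow_grid(40, 12)
  set.seed(7)
  for (i in 1:25) {
    x <- runif(1, 0, grid$L); y <- runif(1, 0, grid$D)
    w <- delta_weights(x, y, grid)$w
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("interpolation is exact for affine velocity fields", {
  grid <- flow_grid(40, 12)
  solver <- new_flow_solver(grid, NULL, fluid_properties())
  st <- initialize_state(solver, U0 = 0)
  a <- 0.3; b <- 1.7; cc <- -0.9
  ufun <- function(x, y) a + b * x + cc * y
  vfun <- function(x, y) 0.1 - 0.4 * x + 0.8 * y
  st$u <- outer(grid$xf, grid$yc, ufun)
  st$v <- outer(grid$xc, grid$yf, vfun)
  set.seed(11)
  # keep 2 cells away from every boundary so the stencil is uncut
  x <- runif(20, 2 * grid$hx, grid$L - 2 * grid$hx)
  y <- runif(20, 2 * grid$hy, grid$D - 2 * grid$hy)
  uv <- interpolate_velocity(solver, st, x, y)
  expect_equal(uv$u, ufun(x, y), tolerance = 1e-12)
  expect_equal(uv$v, vfun(x, y), tolerance = 1e-12)
})

test_that("spreading conserves total force and adjoins interpolation", {
  grid <- flow_grid(40, 12)
  solver <- new_flow_solver(grid, NULL, fluid_properties())
  st <- initialize_state(solver, U0 = 0)
  set.seed(13)
  st$u <- matrix(rnorm(length(st$u)), nrow(st$u))
  st$v <- matrix(rnorm(length(st$v)), nrow(st$v))
  n <- 15
  x <- runif(n, 0, grid$L); y <- runif(n, 0, grid$D)
  fx <- rnorm(n); fy <- rnorm(n)
  sp <- spread_forces(solver, x, y, fx, fy)
  cellA <- grid$hx * grid$hy

  expect_equal(sum(sp$fx) * cellA, sum(fx), tolerance = 1e-12)
  expect_equal(sum(sp$fy) * cellA, sum(fy), tolerance = 1e-12)

  uv <- interpolate_velocity(solver, st, x, y)
  lhs <- (sum(sp$fx * st$u) + sum(sp$fy * st$v)) * cellA
  rhs <- sum(fx * uv$u) + sum(fy * uv$v)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("immersed nodes outside the domain are rejected", {
  grid <- flow_grid(40, 12)
  solver <- new_flow_solver(grid, NULL, fluid_properties())
  st <- initialize_state(solver, U0 = 0)
  expect_error(interpolate_velocity(solver, st, -0.01, 0.005), "outside")
  expect_error(spread_forces(solver, 0.01, 0.02, 1, 1), "outside")
})

test_that("contact forces are pairwise equal and opposite", {
  s <- seq(0, 0.01, length.out = 6)
  lower <- leaflet_state(0.1 + s, s * 0.5)
  upper <- leaflet_state(0.1 + s, 0.015 - s * 0.5)
  far <- ijvflow:::leaflet_contact_forces(lower, upper, dmin = 1e-4,
                                          stiffness = 100)
  expect_equal(far$lower$fx, rep(0, 6))
  expect_equal(far$upper$fy, rep(0, 6))

  upper$y <- lower$y + 5e-5   # everywhere inside dmin
  near <- ijvflow:::leaflet_contact_forces(lower, upper, dmin = 1e-4,
                                           stiffness = 100)
  expect_equal(near$lower$fx + near$upper$fx, rep(0, 6))
  expect_equal(near$lower$fy + near$upper$fy, rep(0, 6))
  # repulsion pushes the lower leaflet down, the upper one up
  expect_true(all(near$lower$fy <= 0))
  expect_true(all(near$upper$fy >= 0))
})

test_that("wall_guard projects offending nodes and cancels normal velocity", {
  grid <- flow_grid(40, 12)
  s <- seq(0, 0.01, length.out = 5)
  lf <- leaflet_state(0.1 + s, 0.001 + 0 * s)
  lf$y[5] <- -0.001; lf$vy[5] <- -0.2
  out <- ijvflow:::wall_guard(lf, grid, margin = grid$hy / 4)
  expect_equal(out$violations, 1L)
  expect_equal(out$leaf$y[5], grid$hy / 4)
  expect_gte(out$leaf$vy[5], 0)
})

test_that("coupled_step advances fluid and valve consistently", {
  geom <- vessel_geometry(f = 0)
  grid <- flow_grid(60, 10)
  solver <- new_flow_solver(grid, NULL, fluid_properties())
  mat <- hyperelastic_material()
  valve <- build_valve(geom$D, valve_spec(n_nodes = 12))
  st <- initialize_state(solver, U0 = 0.12)
  res <- st
  for (i in 1:5) {
    dt <- min(courant_dt(solver, res, 0.4), ijvflow:::diffusive_dt(solver),
              5e-4)
    out <- coupled_step(solver, res, valve, dt, mat, U_in = 0.12)
    res <- out$state; valve <- out$valve
  }
  expect_lt(max_divergence(solver, res), 1e-9)
  # anchors never move
  expect_equal(valve$lower$x[1], valve$spec$anchor_x)
  expect_equal(valve$lower$y[1], 0)
  expect_equal(valve$upper$y[1], geom$D)
  # the flow pushes the leaflet tips downstream
  expect_gt(leaflet_tip_displacement(valve$lower), 0)
  expect_named(out$diagnostics,
               c("coupling_force", "tip_disp", "wall_violations"))

  # hold_fixed treats the valve as a rigid obstacle: leaflets untouched
  v0 <- build_valve(geom$D, valve_spec(n_nodes = 12))
  out2 <- coupled_step(solver, st, v0, 2e-4, mat, U_in = 0.12,
                       hold_fixed = TRUE)
  expect_equal(out2$valve$lower$x, v0$lower$x)
  expect_equal(out2$valve$lower$y, v0$lower$y)
})

test_that("a mirror-symmetric coupled system stays symmetric", {
  geom <- vessel_geometry(f = 0)
  grid <- flow_grid(60, 10)
  solver <- new_flow_solver(grid, NULL, fluid_properties())
  mat <- hyperelastic_material()
  valve <- build_valve(geom$D, valve_spec(n_nodes = 12))
  st <- initialize_state(solver, U0 = 0.12)
  for (i in 1:10) {
    dt <- min(courant_dt(solver, st, 0.4), ijvflow:::diffusive_dt(solver),
              5e-4)
    out <- coupled_step(solver, st, valve, dt, mat, U_in = 0.12)
    st <- out$state; valve <- out$valve
  }
  expect_equal(valve$upper$x, valve$lower$x, tolerance = 1e-9)
  expect_equal(valve$upper$y, geom$D - valve$lower$y, tolerance = 1e-9)
  expect_equal(st$u, st$u[, 10:1], tolerance = 1e-9)
})
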
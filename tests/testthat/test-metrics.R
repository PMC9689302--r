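# small solver whose state we can set by hand
metric_rig <- function(nx = 20, ny = 8, mask = NULL) {
  grid <- flow_grid(nx, ny)
  solver <- new_flow_solver(grid, mask, fluid_properties())
  list(solver = solver, state = initialize_state(solver, U0 = 0),
       grid = grid)
}

test_that("max_velocity_vs_x reports the per-column speed maximum", {
  rig <- metric_rig()
  st <- rig$state
  st$u[] <- 0
  st$u[5, 3] <- 0.4; st$u[6, 3] <- 0.4   # cell (5,3) centre speed 0.4
  prof <- max_velocity_vs_x(rig$solver, st)
  expect_s3_class(prof, "max_velocity_profile")
  expect_equal(nrow(prof), 20)
  expect_equal(prof$vmax[5], 0.4)
  expect_equal(prof$vmax[1], 0)
  expect_equal(prof$x, rig$grid$xc)
})

test_that("region labelling agrees with igraph connected components", {
  set.seed(42)
  for (trial in 1:5) {
    flag <- matrix(runif(30 * 12) < 0.35, 30, 12)
    lab <- ijvflow:::label_regions(flag)

    # oracle: components of the 4-neighbour lattice graph on TRUE cells
    idx <- which(flag)
    nx <- nrow(flag)
    edges <- integer(0)
    for (s in idx) {
      i <- (s - 1L) %% nx + 1L; j <- (s - 1L) %/% nx + 1L
      if (i < nx && flag[s + 1L]) edges <- c(edges, s, s + 1L)
      if (j < ncol(flag) && flag[s + nx]) edges <- c(edges, s, s + nx)
    }
    gr <- igraph::make_empty_graph(n = length(flag), directed = FALSE)
    gr <- igraph::add_edges(gr, match(edges, seq_along(flag)))
    comp <- igraph::components(gr)$membership

    expect_equal(max(lab), length(unique(comp[idx])))
    # same partition: labels in bijection with component ids
    expect_equal(length(unique(paste(lab[idx], comp[idx]))),
                 max(lab))
  }
})

test_that("reverse_flow_area measures a planted recirculation cell", {
  rig <- metric_rig()
  st <- rig$state
  st$u[] <- 0.1
  # plant a 3x2 reverse block at cells i in 8:10, j in 3:4
  st$u[8:11, 3:4] <- -0.2
  rep1 <- reverse_flow_area(rig$solver, st)
  cellA <- rig$grid$hx * rig$grid$hy
  expect_s3_class(rep1, "separation_report")
  expect_equal(rep1$n_regions, 1)
  # cells with centre velocity below -eps: i = 8..11 partially; centres
  # average adjacent faces, so interior cells 8..11 x 3..4 minus edges
  expect_equal(rep1$area, sum(0.5 * (st$u[-1, ] + st$u[-21, ]) <
                                -rep1$threshold) * cellA)
  expect_equal(rep1$regions$y_min, rig$grid$yc[3])

  # xlim excludes the block entirely
  rep2 <- reverse_flow_area(rig$solver, st, xlim = c(0.15, 0.2))
  expect_equal(rep2$area, 0)
  expect_equal(rep2$n_regions, 0)
})

test_that("asymmetry index separates symmetric and antisymmetric fields", {
  rig <- metric_rig()
  st <- rig$state

  expect_equal(asymmetry_index(rig$solver, st), 0)  # quiescent

  yc <- rig$grid$yc; D <- rig$grid$D
  sym <- outer(rep(1, 21), yc * (D - yc)) / D^2
  st$u <- sym
  expect_equal(asymmetry_index(rig$solver, st), 0, tolerance = 1e-12)

  st$u <- outer(rep(1, 21), yc - D / 2)   # odd about the midline
  expect_equal(asymmetry_index(rig$solver, st), 1, tolerance = 1e-12)

  st$u <- sym + 0.05 * outer(rep(1, 21), yc - D / 2)
  a <- asymmetry_index(rig$solver, st)
  expect_gt(a, 0); expect_lt(a, 1)
})

test_that("centerline_offset recovers a planted sub-cell jet offset", {
  rig <- metric_rig(ny = 16)
  st <- rig$state
  yc <- rig$grid$yc; D <- rig$grid$D
  y0 <- D / 2 + 0.3 * rig$grid$hy        # off-centre, sub-cell
  jet <- exp(-((yc - y0) / (0.2 * D))^2)
  st$u <- outer(rep(0.3, 21), jet)
  off <- centerline_offset(rig$solver, st, x = 0.1)
  expect_lt(abs(off - (y0 - D / 2)), 0.2 * rig$grid$hy)
})

test_that("post_throat_dip quantifies the drop behind the throat", {
  geom <- vessel_geometry(f = 0.6)
  x <- seq(0.0005, 0.1995, by = 0.001)
  vmax <- rep(0.3, length(x))
  vmax[x >= geom$xs - 0.0025 & x <= geom$xs + 0.0025] <- 0.6
  dipzone <- x > 0.0225 & x <= 0.04
  vmax[dipzone] <- 0.45
  prof <- data.frame(x = x, vmax = vmax)
  expect_equal(post_throat_dip(prof, geom), 1 - 0.3 / 0.6)  # window hits 0.3
  expect_equal(post_throat_dip(prof, geom, window = 0.01), 1 - 0.45 / 0.6)
  expect_error(post_throat_dip(prof, vessel_geometry(f = 0)), "f > 0")
})

test_that("leaflet_asymmetry compares tip displacement magnitudes", {
  s <- seq(0, 0.01, length.out = 5)
  lo <- leaflet_state(s, 0 * s)
  up <- leaflet_state(s, 0.015 - 0 * s)
  expect_equal(leaflet_asymmetry(up, lo), 0)
  up$x[5] <- up$x[5] + 1e-3
  expect_equal(leaflet_asymmetry(up, lo), 1e-3)
  bad <- leaflet_state(s[1:4], 0 * s[1:4])
  expect_error(leaflet_asymmetry(up, bad), "match")
})
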
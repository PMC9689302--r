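test_that("Lame conversion matches the closed form and rejects nu >= 0.5", {
  lam <- lame_from_modulus(2.6e6, 0.3)
  expect_equal(lam$mu_s, 1.0e6)
  expect_equal(lam$lambda_s, 1.5e6)
  expect_error(lame_from_modulus(-1, 0.3), "positive")
  expect_error(lame_from_modulus(1e6, 0.5), "incompressible")

  mat <- hyperelastic_material()
  expect_equal(mat$mu_s, 1.0e6)
  expect_equal(mat$lambda_s, 1.5e6)
  expect_equal(mat$rho_s, 1200)
})

test_that("strain energy and stresses vanish in the reference state", {
  mat <- hyperelastic_material()
  expect_equal(strain_energy(diag(2), mat), 0)
  expect_equal(pk2_stress(diag(2), mat), matrix(0, 2, 2))
  expect_error(strain_energy(matrix(c(1, 0, 0, -1), 2, 2), mat), "inverted")
})

test_that("PK2 stress is the derivative of the strain energy", {
  mat <- hyperelastic_material()
  F <- matrix(c(1.1, 0.05, -0.03, 0.95), 2, 2)
  S <- pk2_stress(F, mat)
  P <- F %*% S                       # first Piola-Kirchhoff, dW/dF
  eps <- 1e-6
  for (i in 1:2) for (j in 1:2) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + eps
    Fm <- F; Fm[i, j] <- Fm[i, j] - eps
    dW <- (strain_energy(Fp, mat) - strain_energy(Fm, mat)) / (2 * eps)
    expect_equal(dW, P[i, j], tolerance = 1e-5)
  }
})

test_that("the constitutive law is frame-indifferent", {
  mat <- hyperelastic_material()
  F <- matrix(c(1.08, 0.02, 0.04, 0.93), 2, 2)
  th <- 0.3
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(strain_energy(Q %*% F, mat), strain_energy(F, mat))
  expect_equal(pk2_stress(Q %*% F, mat), pk2_stress(F, mat))
  sig <- cauchy_stress(F, pk2_stress(F, mat))
  sigQ <- cauchy_stress(Q %*% F, pk2_stress(Q %*% F, mat))
  expect_equal(sigQ, Q %*% sig %*% t(Q))
})

test_that("leaflet_state validates and keeps its reference configuration", {
  expect_error(leaflet_state(c(0, 1), c(0, 0)), "3 nodes")
  expect_error(leaflet_state(c(0, 0, 1), c(0, 0, 0)), "coincident")
  lf <- leaflet_state(c(0, 1, 2) * 1e-3, c(0, 0, 0))
  expect_equal(lf$l0, c(1e-3, 1e-3))
  expect_equal(lf$root_tangent, c(1, 0))
  expect_true(lf$anchored[1])
})

test_that("elastic forces vanish at reference and are translation invariant", {
  mat <- hyperelastic_material()
  s <- seq(0, 0.01, length.out = 12)
  lf <- leaflet_state(0.1 + s, 0.2 * s)
  f0 <- leaflet_forces(lf, mat, 1e-3)
  expect_equal(f0$fx, rep(0, 12))
  expect_equal(f0$fy, rep(0, 12))

  lf$y <- lf$y + 1e-4 * (s / max(s))^2
  fb <- leaflet_forces(lf, mat, 1e-3)
  lt <- lf; lt$x <- lt$x + 0.37; lt$y <- lt$y - 0.11
  ft <- leaflet_forces(lt, mat, 1e-3)
  expect_equal(ft$fx, fb$fx)
  expect_equal(ft$fy, fb$fy)
})

test_that("elastic forces are minus the gradient of the elastic energy", {
  mat <- hyperelastic_material(E = 1e5)
  s <- seq(0, 0.01, length.out = 8)
  lf <- leaflet_state(0.1 + s, 0 * s)
  lf$y <- lf$y + 2e-4 * (s / max(s))^2
  lf$x <- lf$x - 1e-4 * (s / max(s))^3
  h <- 1e-3
  f <- leaflet_forces(lf, mat, h)
  eps <- 1e-9
  for (j in c(2, 4, 8)) {
    for (coord in c("x", "y")) {
      lp <- lf; lp[[coord]][j] <- lp[[coord]][j] + eps
      lm <- lf; lm[[coord]][j] <- lm[[coord]][j] - eps
      dE <- (leaflet_energy(lp, mat, h) - leaflet_energy(lm, mat, h)) /
        (2 * eps)
      ref <- if (coord == "x") f$fx[j] else f$fy[j]
      expect_equal(-dE, ref, tolerance = 1e-4)
    }
  }
})

test_that("the tangent stiffness matches finite differences of the forces", {
  mat <- hyperelastic_material(E = 1e5)
  s <- seq(0, 0.01, length.out = 6)
  lf <- leaflet_state(0.1 + s, 0 * s)
  lf$y <- lf$y + 3e-4 * (s / max(s))^2
  h <- 1e-3
  n <- length(lf$x)
  K <- ijvflow:::leaflet_stiffness(lf, mat, h)
  eps <- 1e-9
  for (col in c(3L, n)) {           # position dofs of two free nodes
    for (coord in c("x", "y")) {
      lp <- lf; lp[[coord]][col] <- lp[[coord]][col] + eps
      lm <- lf; lm[[coord]][col] <- lm[[coord]][col] - eps
      fp <- leaflet_forces(lp, mat, h); fm <- leaflet_forces(lm, mat, h)
      fd <- c(fp$fx - fm$fx, fp$fy - fm$fy) / (2 * eps)
      idx <- if (coord == "x") col else n + col
      free <- c(FALSE, rep(TRUE, n - 1L))      # skip the anchored row
      free2 <- c(free, free)
      expect_equal(K[free2, idx], fd[free2], tolerance = 1e-4)
    }
  }
})

test_that("node masses lump to the total fiber mass", {
  mat <- hyperelastic_material()
  s <- seq(0, 0.01, length.out = 9)
  lf <- leaflet_state(s, 0 * s)
  m <- ijvflow:::node_masses(lf, mat, 1e-3)
  expect_equal(sum(m), mat$rho_s * 1e-3 * 0.01)
})

test_that("explicit stepping pins anchors and flags instability", {
  mat <- hyperelastic_material()
  s <- seq(0, 0.01, length.out = 8)
  lf <- leaflet_state(s, 0 * s)
  lf$y[8] <- lf$y[8] + 1e-4
  st <- advance_leaflets(lf, leaflet_forces(lf, mat, 1e-3), 1e-7, mat, 1e-3)
  expect_equal(st$x[1], lf$x[1])
  expect_equal(st$vy[1], 0)
  expect_error(
    advance_leaflets(lf, leaflet_forces(lf, mat, 1e-3), 1e-3, mat, 1e-3,
                     max_disp = 1e-6),
    "instability")
})

test_that("first bending frequency matches Euler-Bernoulli within 5%", {
  # the discrete root clamp is a penalty of stiffness ~ EI/l0, so the
  # frequency converges to the clamped-free value first order in 1/n
  # (-5.2% at n = 20, -2.5% at n = 40, -1.6% at n = 64)
  mat <- hyperelastic_material()
  h <- 1e-3; L <- 0.01; n <- 40
  s <- seq(0, L, length.out = n)
  lf <- leaflet_state(s, 0 * s)
  # displace in (approximately) the first clamped-free mode shape
  beta <- 1.87510407
  sig <- (cosh(beta) + cos(beta)) / (sinh(beta) + sin(beta))
  xi <- s / L
  phi <- cosh(beta * xi) - cos(beta * xi) -
    sig * (sinh(beta * xi) - sin(beta * xi))
  a <- 1e-5
  lf$y <- a * phi / max(abs(phi))

  EI <- mat$E * h^3 / 12
  mbar <- mat$rho_s * h
  omega1 <- beta^2 * sqrt(EI / (mbar * L^4))

  dt <- 1e-6
  nstep <- ceiling(4 * (2 * pi / omega1) / dt)
  tip <- numeric(nstep)
  for (i in seq_len(nstep)) {
    lf <- advance_leaflets(lf, leaflet_forces(lf, mat, h), dt, mat, h)
    tip[i] <- lf$y[n]
  }
  up <- which(tip[-1] > 0 & tip[-nstep] <= 0)
  expect_gte(length(up), 3)
  period <- dt * (up[length(up)] - up[1]) / (length(up) - 1)
  expect_equal(2 * pi / period, omega1, tolerance = 0.05)
})

test_that("the implicit coupled step preserves equilibrium and anchors", {
  mat <- hyperelastic_material()
  s <- seq(0, 0.01, length.out = 10)
  lf <- leaflet_state(0.1 + s, 0.5 * s)
  res <- ijvflow:::leaflet_implicit_step(lf, mat, 1e-3, dt = 1e-3,
                                         Ux = rep(0, 10), Uy = rep(0, 10),
                                         cv = 0.1)
  expect_equal(res$leaf$x, lf$x, tolerance = 1e-12)
  expect_equal(res$leaf$y, lf$y, tolerance = 1e-12)
  expect_equal(res$Jx, rep(0, 10), tolerance = 1e-15)

  # uniform fluid velocity drags free nodes downstream, anchors stay
  res2 <- ijvflow:::leaflet_implicit_step(lf, mat, 1e-3, dt = 1e-3,
                                          Ux = rep(0.1, 10),
                                          Uy = rep(0, 10), cv = 0.5)
  expect_equal(res2$leaf$x[1], lf$x[1])
  expect_gt(res2$leaf$x[10], lf$x[10])
  # impulse on the structure equals dt * cv * (U - v_new)
  expect_equal(res2$Jx, 1e-3 * 0.5 * (0.1 - res2$leaf$vx))
})

test_that("tip displacement measures distance from the reference tip", {
  s <- seq(0, 0.01, length.out = 5)
  lf <- leaflet_state(s, 0 * s)
  expect_equal(leaflet_tip_displacement(lf), 0)
  lf$x[5] <- lf$x[5] + 3e-4; lf$y[5] <- lf$y[5] + 4e-4
  expect_equal(leaflet_tip_displacement(lf), 5e-4)
})
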
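test_that("zero load has the trivial equilibrium", {
  m <- case1_mesh()
  mdl <- mech_model(m, material_myocardium(), case1_fibers())
  s <- solve_quasistatic(mdl, pressure = 0)
  expect_equal(max(abs(s$u)), 0)
})

test_that("patch test: constant-strain field reproduced exactly", {
  b <- mesh_box(3, 3, 3, 2, 2, 2)
  A <- matrix(c(0.02, 0.01, 0, 0.005, -0.01, 0.003, 0, 0.002, 0.015), 3, 3)
  uex <- b$nodes %*% t(A)
  bnodes <- unique(as.vector(do.call(rbind, b$surfaces)))
  mdl <- mech_model(b, material_myocardium(), NULL, fixed_nodes = bnodes,
                    pressure_surface = NULL)
  u <- numeric(mdl$n_dof)
  u[as.vector(outer(1:3, (bnodes - 1L) * 3L, `+`))] <- t(uex[bnodes, ])[]
  free <- setdiff(seq_len(mdl$n_dof), mdl$fixed)
  for (it in 1:8) {
    r <- lvemsim:::mech_residual(mdl, u)
    if (sqrt(sum(r[free]^2)) < 1e-10) break
    K <- lvemsim:::mech_tangent(mdl, u)
    u[free] <- u[free] + as.numeric(Matrix::solve(K[free, free], -r[free]))
  }
  expect_lt(max(abs(matrix(u, ncol = 3, byrow = TRUE) - uex)), 1e-12)
})

test_that("single-element stress equals the material-point evaluation", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- lv_mesh(nodes, matrix(1:4, 1), list())
  myo <- material_myocardium(kappa = 0.05)
  mdl <- mech_model(mesh, myo, NULL, fixed_nodes = 1L,
                    pressure_surface = NULL)
  A <- matrix(c(0.05, 0.02, 0, 0.01, -0.03, 0, 0, 0, 0.04), 3, 3)
  u <- as.vector(t(nodes %*% t(A)))
  fl <- mech_fields(mdl, u)
  F <- diag(3) + A
  ref <- pk2_stress(F, myo, list(matrix(c(1, 0, 0), 1, 3)))
  expect_equal(fl$cauchy[1, ], ref$cauchy[1, ], tolerance = 1e-12)
  expect_equal(fl$J, det(F), tolerance = 1e-12)
})

test_that("internal force is frame-indifferent under rigid rotation", {
  b <- mesh_box(2, 2, 2, 3, 3, 3)
  mdl <- mech_model(b, material_myocardium(), NULL, fixed_nodes = 1L,
                    pressure_surface = NULL)
  th <- 0.4
  R <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  u <- as.vector(t(b$nodes %*% t(R) - b$nodes))
  r <- lvemsim:::mech_residual(mdl, u)
  expect_lt(max(abs(r)), 1e-9)
})

test_that("basal reaction balances the endocardial pressure load", {
  m <- case1_mesh()
  mdl <- mech_model(m, material_myocardium(), case1_fibers())
  p <- 10 * 0.133322
  s <- solve_quasistatic(mdl, pressure = p)
  r <- lvemsim:::mech_residual(mdl, s$u, pressure = p)
  fp <- lvemsim:::pressure_forces(mdl, s$u, p)
  scale <- sum(abs(fp))
  for (d in 1:3) {
    comp <- seq(d, mdl$n_dof, by = 3)
    fixed_d <- intersect(comp, mdl$fixed)
    free_d <- setdiff(comp, mdl$fixed)
    ## free dofs are in equilibrium; basal reactions carry the applied load
    expect_lt(sqrt(sum(r[free_d]^2)) / scale, 1e-6)
    expect_lt(abs(sum(r[fixed_d]) + sum(fp[comp])) / scale, 1e-6)
  }
})

test_that("pressurized thick spherical shell matches the elasticity solution", {
  r_in <- 20; t <- 3
  spec <- lv_case_spec(NULL, edv = 1, long_axis = r_in + t, lvid = 2 * r_in,
                       wt_max = t, wt_min = t, wt_avg = t,
                       lvot_radius = 10, lvot_tilt = 0)
  m <- build_lv_geometry(spec, n_axial = 10, n_theta = 16, n_trans = 2,
                         calibrate = FALSE)
  mu <- 500; lam <- 2000
  mat <- material_myocardium(mu = mu, lambda = lam, k1 = 1e-9, k2 = 1)
  base_nodes <- unique(as.vector(m$surfaces$base))
  mdl <- mech_model(m, mat, NULL, fixed_nodes = base_nodes, fixed_dofs = 3)
  bn <- base_nodes[order(abs(m$nodes[base_nodes, 2]))][1:2]
  mdl$fixed <- sort(unique(c(mdl$fixed, (bn[1] - 1) * 3 + 1,
                             (bn[1] - 1) * 3 + 2, (bn[2] - 1) * 3 + 2)))
  p <- 0.2  # kPa: small load, linear regime
  s <- solve_quasistatic(mdl, pressure = p)
  en <- unique(as.vector(m$surfaces$endocardium))
  uin <- matrix(s$u, ncol = 3, byrow = TRUE)[en, ]
  nrm <- m$nodes[en, ] / sqrt(rowSums(m$nodes[en, ]^2))
  ur <- mean(rowSums(uin * nrm))
  E <- mu * (3 * lam + 2 * mu) / (lam + mu)
  nu <- lam / (2 * (lam + mu))
  a <- r_in; b <- r_in + t
  u_ref <- p * a^3 * a / (E * (b^3 - a^3)) *
    ((1 - 2 * nu) + (1 + nu) * b^3 / (2 * a^3))
  expect_lt(abs(ur - u_ref) / u_ref, 0.05)
})

test_that("Newmark: stationarity, bar frequency and damped energy decay", {
  ## unforced rest state stays at rest
  b <- mesh_box(4, 1, 1, 20, 2, 2)
  mat <- material_myocardium(mu = 500, lambda = 0, k1 = 1e-9, k2 = 1)
  x0 <- which(b$nodes[, 1] < 1e-9)
  mdl <- mech_model(b, mat, NULL, fixed_nodes = x0, pressure_surface = NULL,
                    damping = 0)
  st <- newmark_state(mdl)
  st <- step_newmark(mdl, st, 0.05)
  expect_lt(max(abs(st$u)), 1e-12)

  ## fixed-free bar, first axial mode: omega = (pi/2L) sqrt(E/rho), E = 2 mu
  L <- 20
  bb <- mesh_box(16, 1, 1, L, 1, 1)
  x0 <- which(bb$nodes[, 1] < 1e-9)
  mdl2 <- mech_model(bb, mat, NULL, fixed_nodes = x0,
                     pressure_surface = NULL, damping = 0)
  rho <- mdl2$density
  cbar <- sqrt(2 * 500 / rho)
  Tref <- 2 * pi / (pi * cbar / (2 * L))
  A0 <- 1e-4
  st <- newmark_state(mdl2)
  st$u[seq(1, mdl2$n_dof, 3)] <- A0 * sin(pi * bb$nodes[, 1] / (2 * L))
  tipdof <- (which.max(bb$nodes[, 1]) - 1) * 3 + 1
  dt <- Tref / 200
  tip <- numeric(320)
  for (k in seq_len(320)) {
    st <- step_newmark(mdl2, st, dt)
    tip[k] <- st$u[tipdof]
  }
  ## period from the first two downward zero crossings
  zc <- which(tip[-1] < 0 & tip[-length(tip)] >= 0)
  expect_gte(length(zc), 2)
  Tmeas <- (zc[2] - zc[1]) * dt
  expect_lt(abs(Tmeas - Tref) / Tref, 0.01)

  ## damped unforced oscillation: mechanical energy non-increasing
  mdl3 <- mdl2
  mdl3$damping <- 0.5
  st <- newmark_state(mdl3)
  st$u[seq(1, mdl3$n_dof, 3)] <- A0 * sin(pi * bb$nodes[, 1] / (2 * L))
  Mv <- lvemsim:::mech_mass(mdl3)
  energy <- function(st) {
    ke <- 0.5 * sum(Mv * st$v^2)
    ue <- gather_u <- lvemsim:::gather_element_u(mdl3, st$u)
    F9 <- lvemsim:::batch_F(mdl3, ue)
    se <- sum(strain_energy(F9, mat, mdl3$dirs[[1]]) * mdl3$gr$vol)
    ke + se
  }
  en <- numeric(40)
  for (k in seq_len(40)) {
    st <- step_newmark(mdl3, st, dt)
    en[k] <- energy(st)
  }
  expect_true(all(diff(en) <= 1e-10))
})

test_that("torsion metric: zero for rigid rotation, exact for linear twist", {
  m <- case1_mesh()
  mdl <- mech_model(m, material_myocardium(), case1_fibers())
  th <- 10 * pi / 180
  R <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  u_rigid <- as.vector(t(m$nodes %*% t(R) - m$nodes))
  km <- kinematic_metrics(mdl, list(u_rigid), times = 0)
  expect_lt(abs(km$trace$torsion_deg), 1e-9)

  ## twist linear in Z with 15 degrees at the apex
  z_apex <- max(m$nodes[, 3])
  ang <- 15 * pi / 180 * m$nodes[, 3] / z_apex
  xn <- m$nodes[, 1] * cos(ang) - m$nodes[, 2] * sin(ang)
  yn <- m$nodes[, 1] * sin(ang) + m$nodes[, 2] * cos(ang)
  u_twist <- as.vector(t(cbind(xn - m$nodes[, 1], yn - m$nodes[, 2], 0)))
  km2 <- kinematic_metrics(mdl, list(u_twist), times = 0)
  expect_equal(km2$trace$torsion_deg, 15, tolerance = 1e-6)
})

test_that("active contraction produces ejection-compatible kinematics", {
  m <- case1_mesh()
  ff <- case1_fibers()
  mdl <- mech_model(m, material_myocardium(), ff)
  act <- active_stress_tensor(rep(150, nrow(m$tets)), ff,
                              active_stress_params())
  s <- solve_quasistatic(mdl, pressure = 10 * 0.133322, active9 = act)
  m2 <- m
  m2$nodes <- m$nodes + matrix(s$u, ncol = 3, byrow = TRUE)
  expect_lt(cavity_volume(m2), cavity_volume(m))  # volume decreases
  apex <- which.max(m$nodes[, 3])
  expect_gt(max(abs(matrix(s$u, ncol = 3, byrow = TRUE)[apex, ])), 0.1)
})
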
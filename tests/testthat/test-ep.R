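test_that("reaction currents match direct arithmetic", {
  p <- ep_params()
  expect_equal(ionic_current_electrical(0, 0.7, p), 0)
  expect_equal(ionic_current_electrical(1, 0, p), 0)
  ## c phi (phi - alpha)(phi - 1) + r phi at phi=0.5, r=0.2, c=8, alpha=0.01
  expect_equal(ionic_current_electrical(0.5, 0.2, p),
               8 * 0.5 * 0.49 * (-0.5) + 0.1, tolerance = 1e-14)
  ## stretch current: zero at unit stretch and below threshold
  expect_equal(stretch_current(1, 0.9, p), 0)
  expect_equal(stretch_current(1.3, 0.5, p), 0)  # phi <= phi_s gate
  p10 <- ep_params(Gs = 10, phi_s = 0.6)
  expect_equal(stretch_current(1.1, 0.8, p10), 0.2, tolerance = 1e-12)
  ## recovery kinetics: rest is a fixed point, large r decays, frozen value
  expect_equal(recovery_rhs(0, 0, p), 0)
  expect_lt(recovery_rhs(0, 2, p), 0)
  expect_equal(recovery_rhs(0.9, 1, p),
               (0.002 + 0.2 / 1.2) * (-1 + 8 * 0.9 * 0.25),
               tolerance = 1e-14)
})

test_that("potential mapping calibration is exact at its anchors", {
  cal <- calibrate_potential_mapping(0, 1)
  expect_equal(cal$delta_phi, -80)
  expect_equal(cal$beta_phi, 100)
  cal2 <- calibrate_potential_mapping(0.05, 0.93)
  p <- ep_params(delta_phi = cal2$delta_phi, beta_phi = cal2$beta_phi)
  expect_equal(map_potential(0.05, p), -80, tolerance = 1e-12)
  expect_equal(map_potential(0.93, p), 20, tolerance = 1e-12)
  expect_equal(map_potential((0.05 + 0.93) / 2, p), -30, tolerance = 1e-12)
  expect_error(calibrate_potential_mapping(0.5, 0.5), "exceed")
})

test_that("single cell: subthreshold decay, one action potential, restitution", {
  sub <- simulate_single_cell(phi0 = 0.005, duration = 150)
  expect_true(all(diff(sub$phi) <= 1e-12))
  expect_lt(tail(sub$phi, 1), 1e-6)

  ap <- simulate_single_cell(phi0 = 0.7, duration = 150)
  expect_gt(attr(ap, "phi_max"), 0.9)
  expect_lt(abs(tail(ap$phi, 1)), 1e-3)  # repolarized to rest
  ## mapped potential respects the calibrated anchors
  expect_equal(min(ap$Phi), -80, tolerance = 0.5)

  ## increasing gamma shortens the action potential (restitution trend)
  apd <- vapply(c(0.002, 0.004, 0.008), function(g) {
    s <- simulate_single_cell(ep_params(gamma = g), phi0 = 0.7,
                              duration = 150)
    tu <- s$tau[s$phi > 0.5]
    max(tu) - min(tu)
  }, numeric(1))
  expect_true(all(diff(apd) < 0))
})

test_that("activation time field and time scale follow the apicobasal rule", {
  p <- ep_params()
  z_apex <- 74.2
  expect_equal(activation_time_field(0, z_apex, p), p$t_alpha)
  expect_equal(activation_time_field(z_apex, z_apex, p), 0)
  expect_equal(time_scale(p$t0, p), p$t_beta)
  bad <- ep_params(t0 = 5, t1 = 5)
  expect_error(time_scale(3, bad), "t1")
  expect_error(activation_time_field(-1, z_apex, p), "Z")
})

test_that("conductivity tensors have the stated spectrum and apex isotropy", {
  ff <- case1_fibers()
  p <- ep_params()
  D <- conductivity_tensors(ff, p)
  i <- which(!ff$isotropic_mask)[1]
  ev <- sort(eigen(matrix(D[i, ], 3, 3, byrow = TRUE),
                   symmetric = TRUE)$values)
  expect_equal(ev, c(0.1, 0.2, 0.6), tolerance = 1e-12)
  j <- which(ff$isotropic_mask)[1]
  evj <- eigen(matrix(D[j, ], 3, 3, byrow = TRUE), symmetric = TRUE)$values
  expect_equal(evj, rep(0.3, 3), tolerance = 1e-12)
})

test_that("resting state is invariant under monodomain stepping", {
  m <- case1_mesh(); ff <- case1_fibers()
  op <- ep_operator(m, ff, calibrated_ep(), dt = 0.25)
  st <- ep_state(op)
  for (k in 1:10) st <- step_monodomain(st, op)
  expect_equal(max(abs(st$phi)), 0)
  expect_equal(max(abs(st$r)), 0)
  expect_equal(max(abs(map_potential(st$phi, calibrated_ep()) + 80)), 0)
})

test_that("vanishing conductivity reduces each node to the single cell", {
  b <- mesh_box(2, 2, 2, 4, 4, 4)
  mm <- nrow(b$tets)
  ff <- uniform_fiber_field(mm)
  p <- calibrated_ep()
  p$d_fiber <- p$d_sheet_normal <- p$d_transmural <- 1e-12
  p$tau0 <- 0  # uniform time scale so all nodes share the cell clock
  dt <- 0.05
  op <- ep_operator(b, ff, p, dt)
  st <- ep_state(op)
  st$phi[] <- 0.7
  traj <- numeric(400)
  for (k in seq_len(400)) {
    st <- step_monodomain(st, op)
    traj[k] <- st$phi[1]
  }
  cell <- simulate_single_cell(p, phi0 = 0.7,
                               duration = 400 * dt / time_scale(p$t0, p),
                               dt = dt / time_scale(p$t0, p))
  ref <- cell$phi[-1][seq_len(400)]
  expect_lt(max(abs(traj - ref)), 0.02)  # explicit-reaction stepping error
  ## field stays spatially uniform (decoupled limit)
  expect_lt(diff(range(st$phi)), 1e-6)
})

test_that("with Gs = 0 the stretch current vanishes identically", {
  p0 <- ep_params(Gs = 0)
  lam <- seq(0.8, 1.4, 0.1)
  expect_true(all(stretch_current(lam, 0.9, p0) == 0))
  ## monodomain trajectories with Gs = 0 are bitwise identical for any stretch
  b <- mesh_box(4, 1, 1, 10, 1, 1)
  ff <- uniform_fiber_field(nrow(b$tets))
  op <- ep_operator(b, ff, p0, 0.1)
  s1 <- ep_state(op); s1$phi[1:4] <- 0.7
  s2 <- s1
  for (k in 1:50) {
    s1 <- step_monodomain(s1, op, lambda_f = 1)
    s2 <- step_monodomain(s2, op, lambda_f = 1.35)
  }
  expect_identical(s1$phi, s2$phi)
})

test_that("front speed: anisotropy ratio and conductivity scaling", {
  p <- calibrated_ep()
  s_along <- cable_speed(params = p)
  s_across <- cable_speed(fiber_axis = c(0, 1, 0), params = p)
  expect_lt(abs(s_along / s_across - sqrt(0.6 / 0.2)), 0.05 * sqrt(3))
  ## 4x conductivity -> speed x2 (sqrt law)
  p4 <- p
  p4$d_fiber <- 4 * p$d_fiber
  p4$d_sheet_normal <- 4 * p$d_sheet_normal
  p4$d_transmural <- 4 * p$d_transmural
  s4 <- cable_speed(params = p4, length_mm = 60, nx = 150)
  expect_lt(abs(s4 / s_along - 2), 0.1)
})

test_that("excitation front is resolved by at least five nodes", {
  p <- calibrated_ep()
  p$tau0 <- 0
  nx <- 100; L <- 40
  b <- mesh_box(nx, 1, 1, L, 1, 1)
  ff <- uniform_fiber_field(nrow(b$tets))
  op <- ep_operator(b, ff, p, 0.05)
  st <- ep_state(op)
  stim <- which(b$nodes[, 1] < 1e-9)
  for (k in seq_len(1200)) {
    st <- step_monodomain(st, op, stim_nodes = if (st$t < 2) stim,
                          stim_amp = if (st$t < 2) 3 else 0)
    if (st$t >= 60) break
  }
  ## spatial upstroke width (phi from 0.1 to 0.9) along the cable axis
  xs <- sort(unique(b$nodes[, 1]))
  phi_line <- vapply(xs, function(x)
    mean(st$phi[abs(b$nodes[, 1] - x) < 1e-9]), numeric(1))
  in_front <- which(phi_line < 0.9 & phi_line > 0.1)
  expect_gte(length(in_front), 5)
})

test_that("coarse ventricular activation map is physiological", {
  m <- case1_mesh(); ff <- case1_fibers()
  run <- memo("lv_monodomain_run", function()
    run_monodomain(m, ff, calibrated_ep(), duration = 500, dt = 0.25))
  expect_equal(mean(!is.na(run$activation_time)), 1)  # full capture
  expect_lt(max(run$activation_time, na.rm = TRUE), 200)
  ## mapped potential bounded by the calibrated range (1 mV numerical band)
  expect_gte(min(run$summary$Phi_min), -81)
  expect_lte(max(run$summary$Phi_max), 21)
})
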
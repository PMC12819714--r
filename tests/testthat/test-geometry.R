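test_that("case cards validate their invariants", {
  expect_error(lv_case_spec(7), "case_id")
  expect_error(lv_case_spec(1, wt_min = 10, wt_avg = 6, wt_max = 8),
               "thickness")
  expect_error(lv_case_spec(1, edv = -5), "positive")
  spec <- lv_case_spec(2)
  expect_equal(spec$edv, 122.5)
  expect_equal(spec$long_axis, 74.8)
  sec <- ellipse_sections(spec)
  expect_equal(nrow(sec), spec$n_levels)
  expect_true(all(diff(sec$z) > 0))
  expect_true(all(sec$thickness > 0))
})

test_that("generated case geometry honours the case-card dimensions", {
  m <- case1_mesh()
  spec <- lv_case_spec(1)
  expect_lt(abs(long_axis_length(m) - spec$long_axis) / spec$long_axis,
            0.005)
  expect_lt(abs(cavity_volume(m) - spec$edv) / spec$edv, 0.01)
  expect_true(all(tet_volumes(m) > 0))
  expect_true(length(m$regions$apex_cylinder) > 0)
  ## apex-cylinder elements lie inside the stated 10 mm diameter cylinder
  cen <- element_centroids(m)[m$regions$apex_cylinder, , drop = FALSE]
  expect_true(all(sqrt(cen[, 1]^2 + cen[, 2]^2) <= 5 + 1e-9))
})

test_that("infeasible thickness and bad calibration are rejected", {
  spec <- lv_case_spec(1)
  spec$wt_min <- spec$wt_max <- spec$wt_avg <- -2  # bypass constructor check
  expect_error(build_lv_geometry(spec), "thickness")
})

test_that("wall thickness map: concentric and coaxial benchmarks", {
  ## concentric circles, closed form: identical radii offset
  t0 <- ellipse_normal_thickness(20, 20, 27, 27, seq(0, 2 * pi, 0.3))
  expect_equal(t0, rep(7, length(t0)), tolerance = 1e-12)
  ## coaxial ellipses endo (20,15), epi (26,21): thickness 6 on both axes
  expect_equal(ellipse_normal_thickness(20, 15, 26, 21, 0), 6,
               tolerance = 1e-12)
  expect_equal(ellipse_normal_thickness(20, 15, 26, 21, pi / 2), 6,
               tolerance = 1e-12)
  ## dense ray-march oracle at oblique angles
  ray_march <- function(theta) {
    p <- c(20 * cos(theta), 15 * sin(theta))
    n <- c(cos(theta) / 20, sin(theta) / 15)
    n <- n / sqrt(sum(n^2))
    ds <- 1e-5
    s <- 0
    repeat {
      s <- s + ds
      q <- p + s * n
      if ((q[1] / 26)^2 + (q[2] / 21)^2 >= 1) return(s)
    }
  }
  for (th in c(0.4, 1.1, 2.3)) {
    expect_equal(ellipse_normal_thickness(20, 15, 26, 21, th), ray_march(th),
                 tolerance = 1e-3)
  }
})

test_that("mesh-based thickness map stays within the case bounds", {
  for (cid in c(1, 2)) {
    spec <- lv_case_spec(cid)
    m <- if (cid == 1) case1_mesh() else build_lv_geometry(spec)
    wt <- wall_thickness_map(m)
    expect_true(all(wt$thickness > 0))
    expect_gte(min(wt$thickness), 0.9 * spec$wt_min)
    expect_lte(max(wt$thickness), 1.1 * spec$wt_max)
    expect_lt(abs(mean(wt$thickness) - spec$wt_avg) / spec$wt_avg, 0.05)
  }
})

test_that("thickness map rejects crossing surfaces", {
  m <- annulus_mesh()
  ## epicardium tagged onto the endocardial surface itself: every outward
  ## normal ray leaves the wall without meeting the target surface
  sw <- m
  sw$surfaces$epicardium <- m$surfaces$endocardium
  expect_error(wall_thickness_map(sw, n_s = 6, s_max = 0.8), "surfaces")
})

test_that("cavity volume: analytic benchmarks and closedness check", {
  ## unit cube (mm^3) = 0.001 mL
  b <- mesh_box(1, 1, 1, 1, 1, 1)
  tris <- do.call(rbind, b$surfaces)
  expect_equal(cavity_volume(tris, b$nodes), 0.001, tolerance = 1e-12)
  ## open surface is rejected
  expect_error(cavity_volume(b$surfaces$z0, b$nodes), "closed")
  ## hemisphere r = 10 closed by a disk: (2/3) pi 1000 mm^3 = 2.0944 mL
  nt <- 48; np <- 24
  th <- seq(0, 2 * pi, length.out = nt + 1)[-(nt + 1)]
  ph <- seq(0, pi / 2, length.out = np + 1)
  nodes <- rbind(c(0, 0, 10))  # pole
  for (p in ph[-1]) nodes <- rbind(nodes, cbind(10 * sin(p) * cos(th),
                                                10 * sin(p) * sin(th),
                                                10 * cos(p)))
  nid <- function(ip, it) 1L + (ip - 1L) * nt + ((it - 1L) %% nt) + 1L
  tris <- NULL
  for (it in 1:nt) tris <- rbind(tris, c(1, nid(1, it), nid(1, it + 1)))
  for (ip in 1:(np - 1)) for (it in 1:nt) {
    tris <- rbind(tris,
                  c(nid(ip, it), nid(ip + 1, it), nid(ip, it + 1)),
                  c(nid(ip, it + 1), nid(ip + 1, it), nid(ip + 1, it + 1)))
  }
  nodes <- rbind(nodes, c(0, 0, 0))
  cid <- nrow(nodes)
  for (it in 1:nt) tris <- rbind(tris, c(nid(np, it + 1), nid(np, it), cid))
  v <- cavity_volume(tris, nodes)
  expect_equal(v, 2 / 3 * pi, tolerance = 0.01)
})

test_that("divergence-theorem volume agrees with Monte-Carlo ray casting", {
  for (cid in 1:5) {
    m <- if (cid == 1) case1_mesh() else
      build_lv_geometry(lv_case_spec(cid), n_axial = 10L, n_theta = 16L,
                        n_trans = 1L)
    cs <- lvemsim:::closed_endocardial_surface(m)
    v_div <- cavity_volume(cs$tris, cs$nodes, check = FALSE)
    v_mc <- mc_volume(cs$tris, cs$nodes, n = 6e5, seed = 11L)
    expect_lt(abs(v_mc - v_div) / v_div, 0.005)
  }
})

test_that("cavity volume converges monotonically under refinement", {
  spec <- lv_case_spec(1)
  res <- list(c(6, 10, 1), c(12, 20, 2), c(24, 40, 2))
  v <- vapply(res, function(r)
    cavity_volume(build_lv_geometry(spec, n_axial = r[1], n_theta = r[2],
                                    n_trans = r[3], calibrate = FALSE)),
    numeric(1))
  dv <- abs(diff(v))
  expect_true(all(diff(dv) < 0))
  expect_true(all(diff(v) > 0))  # inscribed surface grows toward the limit
})

test_that("outflow-tract extension morphs basal ellipse to the valve circle", {
  spec <- lv_case_spec(3)
  lv <- build_lvot(spec, endo_scale = 1, height = 10)
  out <- lv$nodes[lv$outlet_ring, ]
  r <- sqrt(out[, 1]^2 + out[, 2]^2 + (out[, 3] + 10)^2 - (out[, 3] + 10)^2)
  expect_equal(sqrt(out[, 1]^2 + out[, 2]^2),
               rep(spec$lvot_radius, nrow(out)), tolerance = 1e-9)
  ## first ring equals the basal endocardial ellipse
  first <- lv$nodes[1:20, ]
  expect_equal(max(abs(sqrt((first[, 1] / (spec$lvid / 2))^2 +
                              (first[, 2] / (spec$lvid / 2))^2) - 1)), 0,
               tolerance = 1e-9)
})

test_that("aortic root leaflets: symmetry, attachment and height sweep", {
  spec <- leaflet_spec(R = 12, H = 14, a = 0.4, k = 3)
  root <- build_aortic_root(spec)
  l1 <- root$leaflets[[1]]; l2 <- root$leaflets[[2]]
  ang <- 2 * pi / 3
  rot <- cbind(c(cos(ang), sin(ang), 0), c(-sin(ang), cos(ang), 0),
               c(0, 0, 1))
  expect_lt(max(abs(l1$nodes %*% t(rot) - l2$nodes)), 1e-9)
  att <- l1$nodes[l1$attachment_idx, ]
  expect_lt(max(abs(sqrt(att[, 1]^2 + att[, 2]^2) - spec$R)), 1e-6)
  ## free-edge arc length grows monotonically with leaflet height
  lens <- vapply(c(10, 12, 14, 16, 18), function(H)
    leaflet_free_edge_length(
      build_aortic_root(leaflet_spec(H = H))$leaflets[[1]]),
    numeric(1))
  expect_true(all(diff(lens) > 0))
})
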
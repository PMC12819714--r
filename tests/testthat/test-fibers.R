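test_that("transmural Laplace field reproduces closed forms", {
  ## slab: U(x) = x to FEM (here machine) tolerance
  b <- slab_mesh()
  h <- solve_transmural_laplace(b)
  expect_lt(max(abs(h$U - b$nodes[, 1])), 1e-10)
  expect_lt(max(abs(h$e - matrix(c(-1, 0, 0), nrow(h$e), 3, byrow = TRUE))),
            1e-10)
  ## annulus: U(r) = log(r/27) / log(20/27), error shrinking under refinement
  err_at <- function(n_theta, n_r) {
    ann <- mesh_cylinder_shell(20, 27, 8, n_r = n_r, n_theta = n_theta,
                               n_z = 2)
    ann$surfaces$endocardium <- ann$surfaces$inner
    ann$surfaces$epicardium <- ann$surfaces$outer
    hh <- solve_transmural_laplace(ann)
    r <- sqrt(ann$nodes[, 1]^2 + ann$nodes[, 2]^2)
    max(abs(hh$U - log(r / 27) / log(20 / 27)))
  }
  e1 <- err_at(24, 3); e2 <- err_at(48, 6)
  expect_lt(e2, e1)
  expect_lt(e2, 5e-4)
})

test_that("harmonic field obeys the discrete maximum principle", {
  h <- solve_transmural_laplace(case1_mesh())
  expect_gte(min(h$U), 0)
  expect_lte(max(h$U), 1)
  expect_equal(vec3_norm <- sqrt(rowSums(h$e^2)),
               rep(1, nrow(h$e)), tolerance = 1e-12)
})

test_that("transmural coordinate: slab depth ratio and surface anchors", {
  b <- slab_mesh()
  beta <- transmural_beta(b, "distance")
  cen <- element_centroids(b)
  expect_equal(beta, cen[, 1], tolerance = 1e-9)  # depth/thickness, h = 1
  bh <- transmural_beta(b, "harmonic")
  expect_equal(bh, cen[, 1], tolerance = 1e-9)
})

test_that("distance and harmonic beta agree on the annulus and are monotone", {
  ann <- annulus_mesh()
  bd <- transmural_beta(ann, "distance")
  bh <- transmural_beta(ann, "harmonic")
  expect_lt(max(abs(bd - bh)), 0.05)
  cen <- element_centroids(ann)
  r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  o <- order(r)
  ## both decrease with radius (0 = outer/epi, 1 = inner/endo)
  fit_d <- stats::cor(r, bd, method = "spearman")
  fit_h <- stats::cor(r, bh, method = "spearman")
  expect_lt(fit_d, -0.99)
  expect_lt(fit_h, -0.99)
})

test_that("helix angle rule hits the basal endpoints", {
  z_apex <- 74.2
  expect_equal(helix_angles(0, 0, z_apex), -60)
  expect_equal(helix_angles(1, 0, z_apex), 60)
  expect_equal(helix_angles(0.5, 0, z_apex), 0)      # symmetric midwall
  expect_equal(helix_angles(runif(5), rep(z_apex, 5), z_apex), rep(0, 5))
  expect_error(helix_angles(0.5, z_apex * 1.1, z_apex), "Z")
  ## transmural range at the base spans exactly the two basal angles
  expect_equal(range(helix_angles(c(0, 1), c(0, 0), z_apex)), c(-60, 60))
})

test_that("triads are orthonormal, right-handed and match hand computation", {
  e <- matrix(c(1, 0, 0), 1, 3)
  ff <- build_triads(e, theta = 0, mesh = list(regions = NULL))
  expect_equal(as.numeric(ff$a1), c(1, 0, 0))
  expect_equal(as.numeric(ff$a2), c(0, 0, 1))
  expect_equal(as.numeric(ff$a3), c(0, -1, 0))
  ## theta = 0: fiber equals the circumferential axis
  expect_equal(ff$fiber, ff$a3, tolerance = 1e-14)

  ff2 <- case1_fibers()
  gram <- cbind(rowSums(ff2$fiber^2), rowSums(ff2$sheet^2),
                rowSums(ff2$sheet_normal^2),
                rowSums(ff2$fiber * ff2$sheet),
                rowSums(ff2$fiber * ff2$sheet_normal),
                rowSums(ff2$sheet * ff2$sheet_normal))
  target <- matrix(rep(c(1, 1, 1, 0, 0, 0), each = nrow(gram)), ncol = 6)
  expect_lt(max(abs(gram - target)), 1e-12)
  ## right-handedness: n = f x s
  n <- cbind(ff2$fiber[, 2] * ff2$sheet[, 3] - ff2$fiber[, 3] * ff2$sheet[, 2],
             ff2$fiber[, 3] * ff2$sheet[, 1] - ff2$fiber[, 1] * ff2$sheet[, 3],
             ff2$fiber[, 1] * ff2$sheet[, 2] - ff2$fiber[, 2] * ff2$sheet[, 1])
  expect_lt(max(abs(n - ff2$sheet_normal)), 1e-12)
})

test_that("generated fiber field flags the apex cylinder and tapers helix", {
  ff <- case1_fibers()
  expect_gt(sum(ff$isotropic_mask), 0)
  m <- case1_mesh()
  cen <- element_centroids(m)
  z_apex <- max(m$nodes[, 3])
  ## helix magnitude shrinks toward the apex
  base_el <- cen[, 3] < 0.2 * z_apex
  apex_el <- cen[, 3] > 0.8 * z_apex
  expect_gt(mean(abs(ff$theta[base_el])), mean(abs(ff$theta[apex_el])))
  ## theta continuous across the wall: range within the basal angles
  expect_true(all(ff$theta >= -60 - 1e-9 & ff$theta <= 60 + 1e-9))
})
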
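two_fams <- list(c(1, 0, 0), c(0, 1, 0))

test_that("reference state is energy- and stress-free for both materials", {
  myo <- material_myocardium()
  lea <- material_leaflet()
  expect_equal(strain_energy(diag(3), myo), 0)
  expect_equal(strain_energy(diag(3), lea, two_fams), 0)
  expect_lt(max(abs(pk2_stress(diag(3), myo)$S)), 1e-12)
  expect_lt(max(abs(pk2_stress(diag(3), lea, two_fams)$S)), 1e-12)
})

test_that("analytic stress matches finite differences on random deformations", {
  set.seed(7)
  myo <- material_myocardium(kappa = 0.1)
  lea <- material_leaflet()
  n_ok <- 0
  while (n_ok < 12) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
    if (det(F) < 0.8 || det(F) > 1.2) next
    n_ok <- n_ok + 1
    for (cfg in list(list(m = myo, d = list(c(1, 0, 0))),
                     list(m = lea, d = two_fams))) {
      Sa <- matrix(pk2_stress(F, cfg$m, cfg$d)$S, 3, 3, byrow = TRUE)
      Sf <- pk2_stress_fd(F, cfg$m, cfg$d)
      expect_lt(max(abs(Sa - Sf)) / max(abs(Sf)), 1e-6)
    }
  }
})

test_that("objectivity: W(QF) = W(F) over random rotations", {
  set.seed(11)
  myo <- material_myocardium(kappa = 0.05)
  F <- diag(3) + matrix(rnorm(9, 0, 0.06), 3, 3)
  stopifnot(det(F) > 0)
  w0 <- strain_energy(F, myo)
  for (i in 1:100) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_equal(strain_energy(Q %*% F, myo), w0, tolerance = 1e-10)
  }
  ## pure rotations carry no stress (frame indifference)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  expect_lt(max(abs(pk2_stress(Q, myo)$S)), 1e-10)
})

test_that("material symmetry: energy invariant under fiber flip", {
  myo <- material_myocardium(kappa = 0.1)
  set.seed(3)
  F <- diag(3) + matrix(rnorm(9, 0, 0.07), 3, 3)
  a <- c(0.6, 0.64, 0.48); a <- a / sqrt(sum(a^2))
  expect_equal(strain_energy(F, myo, a), strain_energy(F, myo, -a),
               tolerance = 1e-14)
})

test_that("full dispersion isotropizes the fiber term", {
  m13 <- material_myocardium(kappa = 1 / 3)
  F <- diag(c(1.1, 1 / 1.1, 1))
  expect_equal(strain_energy(F, m13, c(1, 0, 0)),
               strain_energy(F, m13, c(0, 0, 1)), tolerance = 1e-14)
})

test_that("energy grows monotonically along radial loading paths", {
  myo <- material_myocardium(kappa = 0.1)
  lea <- material_leaflet()
  paths <- list(uniax = function(t) diag(c(1 + t, 1 / sqrt(1 + t),
                                           1 / sqrt(1 + t))),
                equibiax = function(t) diag(c(1 + t, 1 + t, 1 / (1 + t)^2)),
                shear = function(t) {
                  F <- diag(3); F[1, 2] <- t; F
                })
  for (path in paths) {
    ts <- seq(0, 0.25, length.out = 11)
    wm <- vapply(ts, function(t) strain_energy(path(t), myo), numeric(1))
    wl <- vapply(ts, function(t) strain_energy(path(t), lea, two_fams),
                 numeric(1))
    expect_true(all(diff(wm) > 0))
    expect_true(all(diff(wl) > 0))
  }
})

test_that("uniaxial myocardium stretch matches independent evaluation", {
  ## incompressible-projected uniaxial stretch along one fiber family, kappa=0
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  myo <- material_myocardium(kappa = 0)
  I1 <- lam^2 + 2 / lam
  I4 <- lam^2
  W_ref <- 0.5 * 500 * (I1 - 3) +
    1.685 / (2 * 15.779) * (exp(15.779 * (I4 - 1)^2) - 1)
  expect_equal(strain_energy(F, myo, c(1, 0, 0)), W_ref, tolerance = 1e-10)
  ## tension-only recruitment: compressed fiber contributes nothing
  Fc <- diag(c(1 / lam, sqrt(lam), sqrt(lam)))
  W_iso_only <- 0.5 * 500 * (sum(diag(t(Fc) %*% Fc)) - 3)
  expect_equal(strain_energy(Fc, myo, c(1, 0, 0)), W_iso_only,
               tolerance = 1e-10)
})

test_that("leaflet energy increases under equibiaxial stretch and is exact", {
  lea <- material_leaflet()
  lams <- seq(1.0, 1.2, 0.02)
  W <- vapply(lams, function(l)
    strain_energy(diag(c(l, l, 1 / l^2)), lea, two_fams), numeric(1))
  expect_equal(W[1], 0)
  expect_true(all(diff(W) > 0))
  ## frozen independent evaluation of the matrix + fiber form at l = 1.1
  l <- 1.1
  J <- 1
  I1b <- 2 * l^2 + 1 / l^4
  I4b <- l^2
  Eb <- 0.2 * (I1b - 3) + (1 - 0.6) * (I4b - 1)
  W_ref <- 3.47 * (exp(30.03 * (I1b - 3)) - 1) +
    2 * 74.5 / (2 * 63.19) * (exp(63.19 * Eb^2) - 1)
  expect_equal(strain_energy(diag(c(l, l, 1 / l^2)), lea, two_fams), W_ref,
               tolerance = 1e-10)
})

test_that("degenerate deformations are rejected", {
  myo <- material_myocardium()
  expect_error(strain_energy(diag(c(-1, 1, 1)), myo), "Jacobian")
  expect_error(pk2_stress(diag(c(0, 1, 1)), myo))
})

test_that("audit neo-Hookean variant is selectable but not stress-free", {
  pr <- material_myocardium(form = "variant")
  S <- matrix(pk2_stress(diag(3), pr)$S, 3, 3, byrow = TRUE)
  expect_gt(max(abs(S)), 1)  # documents why the stress-free form is default
})
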
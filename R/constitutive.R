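## Hyperelastic constitutive laws ---------------------------------------------

#' Myocardium material card
#'
#' Compressible neo-Hookean isotropic matrix plus an exponential
#' fiber-reinforced (Holzapfel-Gasser-Ogden type) anisotropic part with
#' dispersion:
#' `W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2
#'    + k1/(2 k2) sum_a [exp(k2 Ebar_a^2) - 1]`,
#' `Ebar_a = kappa (I1bar - 3) + (1 - 3 kappa)(I4bar_a - 1)`.
#' Fiber terms are recruited in tension only (`I4bar >= 1`). Stresses are in
#' kPa; the matrix moduli default to 0.5 MPa / 0.2 MPa expressed as kPa.
#'
#' @param mu shear modulus (kPa; default 500 = 0.5 MPa).
#' @param lambda Lame parameter (kPa; default 200 = 0.2 MPa).
#' @param k1 fiber stiffness (kPa).
#' @param k2 fiber exponent (dimensionless).
#' @param kappa fiber dispersion, `0 <= kappa <= 1/3`.
#' @param n_families number of fiber families (1 for myocardium).
#' @param form `"stress_free"` uses the full first invariant in the
#'   neo-Hookean term so the reference state carries zero stress (default);
#'   `"variant"` keeps the isochoric invariant with `+ mu ln J` for audit.
#' @return object of class `material` (subclass `myocardium`).
#' @export
material_myocardium <- function(mu = 500, lambda = 200, k1 = 1.685,
                                k2 = 15.779, kappa = 0,
                                n_families = 1L,
                                form = c("stress_free", "variant")) {
  stopifnot(k1 > 0, k2 > 0, kappa >= 0, kappa <= 1 / 3, mu > 0, lambda >= 0)
  structure(list(type = "myocardium", mu = mu, lambda = lambda, k1 = k1,
                 k2 = k2, kappa = kappa, n_families = as.integer(n_families),
                 form = match.arg(form)),
            class = c("myocardium", "material"))
}

#' Aortic-leaflet material card
#'
#' Exponential isotropic matrix plus two in-plane fiber families (radial and
#' circumferential):
#' `W = C10 [exp(C01 (I1bar - 3)) - 1]
#'    + k1/(2 k2) sum_a [exp(k2 Ebar_a^2) - 1] + kvol/2 (J - 1)^2`.
#' The parameter pair is dimensionally ambiguous as usually quoted; by default `C10` is
#' the stress-like factor (kPa) and `C01` the dimensionless exponent rate, with
#' `swap_c = TRUE` selecting the alternative assignment.
#'
#' @param C10 stress-like parameter (kPa).
#' @param C01 exponent parameter (dimensionless rate).
#' @param k1 fiber stiffness (kPa).
#' @param k2 fiber exponent.
#' @param kappa dispersion (0.2 for leaflets).
#' @param kvol volumetric penalty modulus (kPa) enforcing near
#'   incompressibility.
#' @param swap_c exchange the roles of `C10` and `C01`.
#' @return object of class `material` (subclass `leaflet`).
#' @export
material_leaflet <- function(C10 = 3.47, C01 = 30.03, k1 = 74.5, k2 = 63.19,
                             kappa = 0.2, kvol = 5000, swap_c = FALSE) {
  stopifnot(C10 > 0, C01 > 0, k1 > 0, k2 > 0, kappa >= 0, kappa <= 1 / 3)
  if (swap_c) { tmp <- C10; C10 <- C01; C01 <- tmp }
  structure(list(type = "leaflet", C10 = C10, C01 = C01, k1 = k1, k2 = k2,
                 kappa = kappa, kvol = kvol, n_families = 2L),
            class = c("leaflet", "material"))
}

## invariants from row-wise F (N x 9) and reference fiber directions
## fiber_dirs: list of N x 3 matrices (unit vectors), one per family
#' @noRd
kinematics_batch <- function(F9, fiber_dirs) {
  J <- t9_det(F9)
  if (any(J <= 0)) stop("non-positive Jacobian: element inversion")
  C <- t9_mult(t9_transpose(F9), F9)
  I1 <- t9_trace(C)
  Jm23 <- J^(-2 / 3)
  I4 <- lapply(fiber_dirs, function(a) vec3_dot(a, t9_matvec(C, a)))
  list(J = J, C = C, I1 = I1, I1bar = Jm23 * I1,
       I4 = I4, I4bar = lapply(I4, function(x) Jm23 * x), Jm23 = Jm23)
}

#' Strain-energy density
#'
#' Evaluates the strain-energy density (kPa) of a material card at one or many
#' deformation gradients. Fiber terms act in tension only.
#'
#' @param F deformation gradient: a 3x3 matrix or an N x 9 row-wise batch.
#' @param material a [material_myocardium()] or [material_leaflet()] card.
#' @param fiber_dirs reference unit fiber direction(s): a 3-vector, a list of
#'   3-vectors (families), or a list of N x 3 matrices for batches.
#' @return energy density (kPa), length-N vector.
#' @export
strain_energy <- function(F, material, fiber_dirs = c(1, 0, 0)) {
  F9 <- as_batch_F(F)
  dirs <- as_batch_dirs(fiber_dirs, nrow(F9), material$n_families)
  kin <- kinematics_batch(F9, dirs)
  W_fiber <- fiber_energy(kin, material)
  if (material$type == "myocardium") {
    lnJ <- log(kin$J)
    W_iso <- if (material$form == "variant")
      0.5 * material$mu * (kin$I1bar - 1) + material$mu * lnJ +
        0.5 * material$lambda * lnJ^2
    else
      0.5 * material$mu * (kin$I1 - 3) - material$mu * lnJ +
        0.5 * material$lambda * lnJ^2
    W_iso + W_fiber
  } else {
    material$C10 * (exp(material$C01 * (kin$I1bar - 3)) - 1) + W_fiber +
      0.5 * material$kvol * (kin$J - 1)^2
  }
}

#' @noRd
fiber_energy <- function(kin, material) {
  W <- 0
  for (a in seq_along(kin$I4bar)) {
    Eb <- material$kappa * (kin$I1bar - 3) +
      (1 - 3 * material$kappa) * (kin$I4bar[[a]] - 1)
    Eb <- ifelse(kin$I4bar[[a]] >= 1, Eb, 0)  # tension-only recruitment
    W <- W + material$k1 / (2 * material$k2) *
      (exp(material$k2 * Eb^2) - 1)
  }
  W
}

#' Second Piola-Kirchhoff stress
#'
#' Analytic `S = 2 dW/dC` for the material cards, plus an optional active
#' tensor added directly to `S`. The Cauchy stress push-forward
#' `sigma = J^-1 F S F^T` is returned alongside.
#'
#' @inheritParams strain_energy
#' @param active optional active-stress tensor(s), 3x3 or N x 9 (kPa), added
#'   to the passive second Piola-Kirchhoff stress.
#' @return list with `S` (N x 9), `cauchy` (N x 9), `J`.
#' @export
pk2_stress <- function(F, material, fiber_dirs = c(1, 0, 0), active = NULL) {
  F9 <- as_batch_F(F)
  n <- nrow(F9)
  dirs <- as_batch_dirs(fiber_dirs, n, material$n_families)
  kin <- kinematics_batch(F9, dirs)
  Cinv <- t9_inv(kin$C)
  I9 <- t9_identity(n)
  ## d(I1bar)/dC = J^(-2/3) (I - I1/3 Cinv); d(I4bar_a)/dC = J^(-2/3)(a(x)a - I4/3 Cinv)
  dI1b <- kin$Jm23 * (I9 - (kin$I1 / 3) * Cinv)
  S <- matrix(0, n, 9)
  if (material$type == "myocardium") {
    lnJ <- log(kin$J)
    if (material$form == "variant") {
      ## 1/2 mu (I1bar - 1) + mu lnJ + 1/2 lambda lnJ^2 (audit variant)
      S <- S + material$mu * dI1b + (material$mu + material$lambda * lnJ) * Cinv
    } else {
      ## 1/2 mu (I1 - 3) - mu lnJ + 1/2 lambda lnJ^2
      S <- S + material$mu * (I9 - Cinv) + material$lambda * lnJ * Cinv
    }
  } else {
    S <- S + 2 * material$C10 * material$C01 *
      exp(material$C01 * (kin$I1bar - 3)) * dI1b
    S <- S + material$kvol * (kin$J - 1) * kin$J * Cinv
  }
  for (a in seq_along(dirs)) {
    Eb <- material$kappa * (kin$I1bar - 3) +
      (1 - 3 * material$kappa) * (kin$I4bar[[a]] - 1)
    act <- kin$I4bar[[a]] >= 1
    Eb <- ifelse(act, Eb, 0)
    coef <- 2 * material$k1 * Eb * exp(material$k2 * Eb^2)
    dI4b <- kin$Jm23 * (t9_outer(dirs[[a]]) - (kin$I4[[a]] / 3) * Cinv)
    S <- S + (coef * act) * (material$kappa * dI1b +
                               (1 - 3 * material$kappa) * dI4b)
  }
  if (!is.null(active)) {
    act9 <- if (is.matrix(active) && ncol(active) == 9) active else
      matrix(as.numeric(t(active)), n, 9, byrow = TRUE)
    S <- S + act9
  }
  cauchy <- t9_mult(t9_mult(F9, S), t9_transpose(F9)) / kin$J
  list(S = S, cauchy = cauchy, J = kin$J)
}

#' @noRd
as_batch_F <- function(F) {
  if (is.matrix(F) && all(dim(F) == c(3, 3))) t9_from_matrix(F)
  else if (is.matrix(F) && ncol(F) == 9) F
  else stop("F must be 3x3 or an N x 9 batch")
}

#' @noRd
as_batch_dirs <- function(fiber_dirs, n, n_families) {
  if (is.numeric(fiber_dirs) && length(fiber_dirs) == 3)
    fiber_dirs <- list(fiber_dirs)
  dirs <- lapply(fiber_dirs, function(a) {
    if (is.matrix(a)) a else matrix(a / sqrt(sum(a^2)), n, 3, byrow = TRUE)
  })
  if (length(dirs) < n_families)
    stop(sprintf("material expects %d fiber families, got %d", n_families,
                 length(dirs)))
  dirs[seq_len(n_families)]
}

#' Finite-difference second Piola-Kirchhoff stress (validation oracle)
#'
#' Central differences of the strain energy with respect to the Green-Lagrange
#' strain, `S = dW/dE`, used as an independent check of the analytic stress.
#'
#' @inheritParams strain_energy
#' @param h step on the strain components.
#' @return 3x3 matrix (kPa). Only scalar (single-F) input.
#' @export
pk2_stress_fd <- function(F, material, fiber_dirs = c(1, 0, 0), h = 1e-6) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  C <- t(F) %*% F
  W_of_C <- function(Cm) {
    ## energy from C via a symmetric square root (objectivity makes any F with
    ## F^T F = C equivalent)
    eg <- eigen(Cm, symmetric = TRUE)
    Fs <- eg$vectors %*% diag(sqrt(pmax(eg$values, 1e-14))) %*% t(eg$vectors)
    strain_energy(Fs, material, fiber_dirs)
  }
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    dC <- matrix(0, 3, 3)
    dC[i, j] <- dC[j, i] <- h  # dE_ij = dC_ij / 2
    Wp <- W_of_C(C + dC); Wm <- W_of_C(C - dC)
    ## dC_ij = dC_ji = h means dE_ij = dE_ji = h/2, so the directional
    ## derivative is S_ii h/2 on the diagonal and S_ij h off it
    S[i, j] <- S[j, i] <- (Wp - Wm) / (2 * h) * ifelse(i == j, 2, 1)
  }
  S
}
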
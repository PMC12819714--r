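## Finite-element solid mechanics ---------------------------------------------

## Total-Lagrangian P1 tetrahedra. Displacement dof ordering: node-major
## (u1x,u1y,u1z,u2x,...). Element residuals/tangents are evaluated in batch;
## tangents by forward differences of the batched residual (12 extra passes).

#' Build the mechanics model
#'
#' Precomputes shape gradients, element dof maps, fixed boundary conditions
#' and the loaded (endocardial) face list for a tagged mesh.
#'
#' @param mesh an `lv_mesh`.
#' @param material a material card ([material_myocardium()] by default usage).
#' @param fibers a `fiber_field` (per-element reference fiber directions), or
#'   `NULL` for isotropic-only materials.
#' @param fixed_nodes nodes with homogeneous Dirichlet constraints; defaults
#'   to the nodes of the `base` surface tag (the rigid basal fixation).
#' @param fixed_dofs which components are fixed at those nodes
#'   (`"all"` or a subset of 1:3).
#' @param pressure_surface name of the surface receiving the follower cavity
#'   pressure (default `"endocardium"`).
#' @param density mass density (mg/mm^3 = g/cm^3), used by the dynamic solver.
#' @param damping mass-proportional damping coefficient (1/ms).
#' @return a `mech_model`.
#' @export
mech_model <- function(mesh, material, fibers = NULL, fixed_nodes = NULL,
                       fixed_dofs = "all", pressure_surface = "endocardium",
                       density = 1.05e-3 * 1000, damping = 0.05) {
  gr <- fem_gradients(mesh)
  if (any(gr$vol <= 0)) stop("mesh contains inverted elements")
  if (is.null(fixed_nodes)) {
    if (is.null(mesh$surfaces$base))
      stop("no fixed_nodes given and no 'base' surface tag")
    fixed_nodes <- unique(as.vector(mesh$surfaces$base))
  }
  dofs <- if (identical(fixed_dofs, "all")) 1:3 else fixed_dofs
  fixed <- as.vector(outer(dofs, (fixed_nodes - 1L) * 3L, `+`))
  dirs <- if (!is.null(fibers)) {
    if (material$n_families == 2L) list(fibers$fiber, fibers$sheet_normal)
    else list(fibers$fiber)
  } else {
    m <- nrow(mesh$tets)
    list(matrix(c(1, 0, 0), m, 3, byrow = TRUE))
  }
  pres_faces <- if (is.null(pressure_surface)) NULL else
    mesh$surfaces[[pressure_surface]]
  n_dof <- 3L * nrow(mesh$nodes)
  ## precomputed scatter operators (dof x packed-element-force)
  m <- nrow(mesh$tets)
  dof_idx <- matrix(0L, m, 12)
  k <- 0L
  for (a in 1:4) for (d in 1:3) {
    k <- k + 1L
    dof_idx[, k] <- (mesh$tets[, a] - 1L) * 3L + d
  }
  scatter_el <- Matrix::sparseMatrix(
    i = as.vector(dof_idx), j = seq_len(12L * m), x = 1, dims = c(n_dof, 12L * m))
  scatter_fc <- NULL
  if (!is.null(pres_faces) && nrow(pres_faces) > 0) {
    nf <- nrow(pres_faces)
    fdof <- matrix(0L, nf, 9)
    k <- 0L
    for (a in 1:3) for (d in 1:3) {
      k <- k + 1L
      fdof[, k] <- (pres_faces[, a] - 1L) * 3L + d
    }
    scatter_fc <- Matrix::sparseMatrix(
      i = as.vector(fdof), j = seq_len(9L * nf), x = 1, dims = c(n_dof, 9L * nf))
  }
  structure(list(mesh = mesh, material = material, fibers = fibers,
                 dirs = dirs, gr = gr, fixed = sort(unique(fixed)),
                 pres_faces = pres_faces, density = density,
                 damping = damping, n_dof = n_dof, dof_idx = dof_idx,
                 scatter_el = scatter_el, scatter_fc = scatter_fc),
            class = "mech_model")
}

## element displacement gather: m x 12 (node-major x,y,z per local node)
#' @noRd
gather_element_u <- function(model, u) {
  tt <- model$mesh$tets
  cols <- vector("list", 12)
  k <- 0L
  for (a in 1:4) for (d in 1:3) {
    k <- k + 1L
    cols[[k]] <- u[(tt[, a] - 1L) * 3L + d]
  }
  do.call(cbind, cols)
}

## deformation gradients for all elements given element displacement block
#' @noRd
batch_F <- function(model, ue) {
  G <- model$gr$grads
  m <- nrow(ue)
  F9 <- t9_identity(m)
  for (a in 1:4) {
    ga <- G[, (3 * a - 2):(3 * a), drop = FALSE]
    ua <- ue[, (3 * a - 2):(3 * a), drop = FALSE]
    F9 <- F9 + t9_outer(ua, ga)
  }
  F9
}

## batched internal nodal forces: m x 12 (f_a = V0 P gradN_a)
#' @noRd
element_internal_forces <- function(model, ue, active9 = NULL) {
  F9 <- batch_F(model, ue)
  st <- pk2_stress(F9, model$material, model$dirs, active = active9)
  P9 <- t9_mult(F9, st$S)  # first Piola-Kirchhoff
  G <- model$gr$grads
  out <- matrix(0, nrow(ue), 12)
  for (a in 1:4) {
    ga <- G[, (3 * a - 2):(3 * a), drop = FALSE]
    out[, (3 * a - 2):(3 * a)] <- t9_matvec(P9, ga) * model$gr$vol
  }
  out
}

## scatter element forces (m x 12) into global residual
#' @noRd
scatter_forces <- function(model, fe) {
  as.numeric(model$scatter_el %*% as.vector(fe))
}

## follower pressure nodal forces on the loaded surface in the deformed
## configuration: f = -p (n dA)/3 per face node, n dA from the current face
#' @noRd
pressure_forces <- function(model, u, p) {
  if (is.null(model$scatter_fc) || p == 0) return(numeric(model$n_dof))
  fc <- model$pres_faces
  x <- model$mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
  x1 <- x[fc[, 1], , drop = FALSE]
  x2 <- x[fc[, 2], , drop = FALSE]
  x3 <- x[fc[, 3], , drop = FALSE]
  ndA <- 0.5 * vec3_cross(x2 - x1, x3 - x1)  # outward from solid
  fn <- -p * ndA / 3
  ## packed per-face nodal forces: same force fn on each of the 3 nodes
  packed <- cbind(fn, fn, fn)  # columns: (n1x n1y n1z n2x ... n3z)
  as.numeric(model$scatter_fc %*% as.vector(packed))
}

## analytic tangent of the follower pressure load: d f / d u
## ndA = 0.5 (x2 - x1) x (x3 - x1); d(a x b) = skew(a) db - skew(b) da
#' @noRd
pressure_tangent <- function(model, u, p) {
  fc <- model$pres_faces
  nf <- nrow(fc)
  x <- model$mesh$nodes + matrix(u, ncol = 3, byrow = TRUE)
  e2 <- x[fc[, 2], , drop = FALSE] - x[fc[, 1], , drop = FALSE]
  e3 <- x[fc[, 3], , drop = FALSE] - x[fc[, 1], , drop = FALSE]
  ## dF/dx1 = c (skew(e3) - skew(e2)), dF/dx2 = -c skew(e3), dF/dx3 = c skew(e2)
  ## with c = -p/6, applied identically to each of the 3 receiving nodes
  cc <- -p / 6
  skew9 <- function(v) cbind(0, -v[, 3], v[, 2],
                             v[, 3], 0, -v[, 1],
                             -v[, 2], v[, 1], 0)
  blocks <- list(cc * (skew9(e3) - skew9(e2)),  # w.r.t. x1
                 -cc * skew9(e3),               # w.r.t. x2
                 cc * skew9(e2))                # w.r.t. x3
  ntrip <- 81L * nf
  ii <- jj <- integer(ntrip); xx <- numeric(ntrip)
  pos <- 0L
  for (recv in 1:3) for (src in 1:3) {
    B <- blocks[[src]]
    for (dr in 1:3) for (dc in 1:3) {
      idx <- (pos * nf + 1L):((pos + 1L) * nf)
      ii[idx] <- (fc[, recv] - 1L) * 3L + dr
      jj[idx] <- (fc[, src] - 1L) * 3L + dc
      xx[idx] <- B[, (dr - 1L) * 3L + dc]
      pos <- pos + 1L
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(model$n_dof, model$n_dof))
}

## global residual r(u) = f_int(u) - f_ext(u); active9: m x 9 or NULL
#' @noRd
mech_residual <- function(model, u, pressure = 0, active9 = NULL,
                          f_extra = NULL) {
  fe <- element_internal_forces(model, gather_element_u(model, u), active9)
  r <- scatter_forces(model, fe) - pressure_forces(model, u, pressure)
  if (!is.null(f_extra)) r <- r - f_extra
  r
}

## sparse tangent by forward differences of the batched element residual and
## the face pressure forces
#' @noRd
mech_tangent <- function(model, u, pressure = 0, active9 = NULL, h = 1e-7) {
  ue0 <- gather_element_u(model, u)
  f0 <- element_internal_forces(model, ue0, active9)
  m <- nrow(ue0)
  scale <- h * max(1, max(abs(u)))
  ii <- jj <- integer(144L * m); xx <- numeric(144L * m)
  blk <- 0L
  dof_idx <- model$dof_idx
  for (c in 1:12) {
    ue <- ue0
    ue[, c] <- ue[, c] + scale
    df <- (element_internal_forces(model, ue, active9) - f0) / scale
    for (rw in 1:12) {
      idx <- (blk * m + 1L):((blk + 1L) * m)
      ii[idx] <- dof_idx[, rw]
      jj[idx] <- dof_idx[, c]
      xx[idx] <- df[, rw]
      blk <- blk + 1L
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(model$n_dof, model$n_dof))
  if (!is.null(model$scatter_fc) && pressure != 0)
    K <- K - pressure_tangent(model, u, pressure)
  K
}

#' Quasi-static equilibrium solve
#'
#' Newton iteration on the total-Lagrangian residual with follower endocardial
#' pressure and optional active-stress tensor field; automatic load stepping
#' with cutback on divergence.
#'
#' @param model a [mech_model()].
#' @param pressure cavity pressure (kPa) applied on the loaded surface.
#' @param active9 optional m x 9 active second Piola-Kirchhoff tensors (kPa).
#' @param u0 initial displacement guess.
#' @param tol relative residual tolerance.
#' @param max_newton Newton iteration bound per load step.
#' @param max_cutbacks load-step halving bound.
#' @return list with `u` (dof vector), `converged`, `iterations`, `residual`.
#' @export
solve_quasistatic <- function(model, pressure = 0, active9 = NULL, u0 = NULL,
                              tol = 1e-6, max_newton = 25L,
                              max_cutbacks = 6L) {
  u <- if (is.null(u0)) numeric(model$n_dof) else u0
  free <- setdiff(seq_len(model$n_dof), model$fixed)
  h_mesh <- max(abs(model$mesh$nodes)) * 0.15  # Newton step cap (mm)
  solve_at <- function(u, lam) {
    rn <- Inf
    for (it in seq_len(max_newton)) {
      r <- tryCatch(
        mech_residual(model, u, pressure * lam,
                      if (is.null(active9)) NULL else active9 * lam),
        error = function(e) NULL)
      if (is.null(r)) return(list(u = u, ok = FALSE, it = it, rn = rn))
      rn <- sqrt(sum(r[free]^2))
      ref <- max(sqrt(sum(pressure_forces(model, u, pressure * lam)^2)),
                 1e-8 * model$material[[if (model$material$type ==
                                            "myocardium") "mu" else "C10"]])
      if (rn <= tol * max(ref, 1)) return(list(u = u, ok = TRUE, it = it,
                                               rn = rn))
      K <- tryCatch(
        mech_tangent(model, u, pressure * lam,
                     if (is.null(active9)) NULL else active9 * lam),
        error = function(e) NULL)
      du <- if (is.null(K)) NULL else tryCatch(
        as.numeric(Matrix::solve(K[free, free], -r[free])),
        error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du)))
        return(list(u = u, ok = FALSE, it = it, rn = rn))
      ## cap the step so a single Newton update cannot invert elements
      dmax <- max(abs(du))
      if (dmax > h_mesh) du <- du * (h_mesh / dmax)
      u[free] <- u[free] + du
    }
    list(u = u, ok = FALSE, it = max_newton, rn = rn)
  }
  lam_done <- 0; lam_step <- 1; cut <- 0L; total_it <- 0L
  res <- NULL
  while (lam_done < 1 - 1e-12) {
    lam_try <- min(1, lam_done + lam_step)
    trial <- solve_at(u, lam_try)
    total_it <- total_it + trial$it
    if (trial$ok) {
      u <- trial$u; lam_done <- lam_try; res <- trial
      lam_step <- min(1, lam_step * 2)
    } else {
      cut <- cut + 1L
      if (cut > max_cutbacks)
        stop("Newton did not converge despite load-step cutbacks")
      lam_step <- lam_step / 2
    }
  }
  list(u = u, converged = TRUE, iterations = total_it, residual = res$rn)
}

#' Element fields of a displacement state
#'
#' Deformation gradients, Green-Lagrange strain, Cauchy stress, von Mises
#' stress, volumetric strain and fiber stretch for a converged state.
#'
#' @param model a [mech_model()].
#' @param u displacement dof vector.
#' @param active9 optional active tensor batch used in the solve.
#' @return list of per-element fields.
#' @export
mech_fields <- function(model, u, active9 = NULL) {
  F9 <- batch_F(model, gather_element_u(model, u))
  st <- pk2_stress(F9, model$material, model$dirs, active = active9)
  E9 <- (t9_mult(t9_transpose(F9), F9) - t9_identity(nrow(F9))) / 2
  lam_f <- sqrt(pmax(vec3_dot(model$dirs[[1]],
                              t9_matvec(t9_mult(t9_transpose(F9), F9),
                                        model$dirs[[1]])), 0))
  list(F = F9, E = E9, cauchy = st$cauchy, J = st$J,
       von_mises = t9_von_mises(st$cauchy),
       volumetric_strain = st$J - 1, lambda_fiber = lam_f)
}

## Dynamics (implicit Newmark) -------------------------------------------------

#' Initialize a Newmark dynamic state
#' @param model a [mech_model()].
#' @return list of displacement/velocity/acceleration vectors.
#' @export
newmark_state <- function(model) {
  list(u = numeric(model$n_dof), v = numeric(model$n_dof),
       a = numeric(model$n_dof), t = 0)
}

## lumped nodal mass vector for dofs (mass density x volume / 4 per vertex)
#' @noRd
mech_mass <- function(model) {
  mv <- fem_lumped_mass(model$mesh, model$gr) * model$density
  rep(mv, each = 3)
}

#' Implicit Newmark step
#'
#' Average-acceleration Newmark (`beta = 1/4`, `gamma = 1/2`) with
#' mass-proportional damping: solves the nonlinear dynamic residual
#' `M a + c M v + f_int(u) - f_ext(u) = 0` for the end-of-step displacement by
#' Newton iteration with the consistent effective tangent.
#'
#' @param model a [mech_model()].
#' @param state list `u, v, a, t` from [newmark_state()] or a previous step.
#' @param dt time step (ms).
#' @param pressure cavity pressure (kPa).
#' @param active9 active tensor batch (kPa).
#' @param beta,gamma Newmark parameters.
#' @param tol,max_newton Newton controls.
#' @return updated state.
#' @export
step_newmark <- function(model, state, dt, pressure = 0, active9 = NULL,
                         beta = 0.25, gamma = 0.5, tol = 1e-8,
                         max_newton = 20L) {
  stopifnot(dt > 0)
  Mv <- mech_mass(model)
  free <- setdiff(seq_len(model$n_dof), model$fixed)
  u0 <- state$u; v0 <- state$v; a0 <- state$a
  c_b1 <- 1 / (beta * dt^2); c_b2 <- 1 / (beta * dt)
  c_b3 <- (1 / (2 * beta) - 1)
  acc_of <- function(u) c_b1 * (u - u0) - c_b2 * v0 - c_b3 * a0
  vel_of <- function(u) v0 + dt * ((1 - gamma) * a0 + gamma * acc_of(u))
  u <- u0 + dt * v0 + dt^2 / 2 * a0  # predictor
  ref <- NULL
  for (it in seq_len(max_newton)) {
    r <- Mv * acc_of(u) + model$damping * Mv * vel_of(u) +
      mech_residual(model, u, pressure, active9)
    rn <- sqrt(sum(r[free]^2))
    if (is.null(ref)) ref <- max(rn, sqrt(sum((Mv * acc_of(u))[free]^2)), 1)
    if (rn <= tol * ref || rn < 1e-12) break
    K <- mech_tangent(model, u, pressure, active9) +
      Matrix::Diagonal(x = Mv * (c_b1 + model$damping * gamma * c_b2))
    du <- as.numeric(Matrix::solve(K[free, free], -r[free]))
    if (any(!is.finite(du))) stop("Newmark Newton diverged")
    u[free] <- u[free] + du
  }
  a1 <- acc_of(u); v1 <- vel_of(u)
  a1[model$fixed] <- 0; v1[model$fixed] <- 0
  list(u = u, v = v1, a = a1, t = state$t + dt)
}

## Kinematic metrics -----------------------------------------------------------

#' Apex and torsion kinematics of a displacement history
#'
#' Apex planar trajectory and vertical displacement from the apex node;
#' torsion as the mean circumferential rotation (about the long axis) of an
#' apical node ring minus that of a basal ring, normalized by the axial
#' separation of the two rings to the full apex-base span (so a twist field
#' linear in Z with angle `T` at the apex reports exactly `T`); maximum
#' principal Green-Lagrange strain.
#'
#' @param model a [mech_model()] built on an LV mesh.
#' @param u_list list of displacement dof vectors over time.
#' @param times time stamps (ms), same length.
#' @param apical_band,basal_band Z fractions (of the apex height) delimiting
#'   the rings used for the torsion metric.
#' @return object of class `kinematic_metrics`: data.frame `trace`
#'   (t, apex_x, apex_y, apex_dz, torsion_deg) plus `max_strain_pct`.
#' @export
kinematic_metrics <- function(model, u_list, times,
                              apical_band = c(0.6, 0.9),
                              basal_band = c(0, 0.25)) {
  nd <- model$mesh$nodes
  z_apex <- max(nd[, 3])
  apex_node <- which.max(nd[, 3])
  rad <- sqrt(nd[, 1]^2 + nd[, 2]^2)
  ring <- function(band) which(nd[, 3] >= band[1] * z_apex &
                                 nd[, 3] <= band[2] * z_apex & rad > 1)
  ring_a <- ring(apical_band); ring_b <- ring(basal_band)
  if (!length(ring_a) || !length(ring_b))
    stop("could not identify apical/basal node rings for the torsion metric")
  span_scale <- z_apex / (mean(nd[ring_a, 3]) - mean(nd[ring_b, 3]))
  rot_of <- function(u, idx) {
    du <- matrix(u, ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    x0 <- nd[idx, 1]; y0 <- nd[idx, 2]
    x1 <- x0 + du[, 1]; y1 <- y0 + du[, 2]
    mean(atan2(x0 * y1 - y0 * x1, x0 * x1 + y0 * y1))
  }
  rows <- lapply(seq_along(u_list), function(k) {
    u <- u_list[[k]]
    du <- matrix(u, ncol = 3, byrow = TRUE)
    tor <- (rot_of(u, ring_a) - rot_of(u, ring_b)) * span_scale * 180 / pi
    c(t = times[k], apex_x = du[apex_node, 1], apex_y = du[apex_node, 2],
      apex_dz = du[apex_node, 3], torsion_deg = tor)
  })
  trace <- as.data.frame(do.call(rbind, rows))
  ## max principal strain over the last state
  fields <- mech_fields(model, u_list[[length(u_list)]])
  E <- fields$E
  emax <- vapply(seq_len(nrow(E)), function(i)
    max(eigen(matrix(E[i, ], 3, 3, byrow = TRUE), symmetric = TRUE,
              only.values = TRUE)$values), numeric(1))
  structure(list(trace = trace, max_strain_pct = 100 * max(emax)),
            class = "kinematic_metrics")
}

#' @export
print.kinematic_metrics <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("Kinematics over %d states: peak |torsion| %.2f deg, apex dz range [%.2f, %.2f] mm\n",
              nrow(tr), max(abs(tr$torsion_deg)), min(tr$apex_dz),
              max(tr$apex_dz)))
  cat(sprintf("  max principal strain (final state): %.1f%%\n",
              x$max_strain_pct))
  invisible(x)
}
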
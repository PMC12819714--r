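## P1 finite-element primitives on tetrahedral meshes -------------------------

## Shape-function gradients and volumes for all tets.
## Returns list(grads = m x 12 matrix (rows: gN1x,gN1y,gN1z,gN2x,...), vol).
#' @noRd
fem_gradients <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tets
  e1 <- nd[tt[, 2], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  e2 <- nd[tt[, 3], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  e3 <- nd[tt[, 4], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  J <- cbind(e1, e2, e3)[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
  ## rows of inv(J) are gradients of N2, N3, N4
  Jinv <- t9_inv(J)
  g2 <- Jinv[, 1:3, drop = FALSE]
  g3 <- Jinv[, 4:6, drop = FALSE]
  g4 <- Jinv[, 7:9, drop = FALSE]
  g1 <- -(g2 + g3 + g4)
  list(grads = cbind(g1, g2, g3, g4), vol = t9_det(J) / 6)
}

## Assemble the P1 stiffness matrix int grad(u) . D grad(v) dx.
## D: NULL (identity), or m x 9 row-wise tensors per element.
#' @noRd
fem_stiffness <- function(mesh, gr = fem_gradients(mesh), D = NULL) {
  m <- nrow(mesh$tets)
  n <- nrow(mesh$nodes)
  G <- gr$grads
  ## Dg[, a] = D %*% grad N_a per element
  Dg <- vector("list", 4)
  for (a in 1:4) {
    ga <- G[, (3 * a - 2):(3 * a), drop = FALSE]
    Dg[[a]] <- if (is.null(D)) ga else t9_matvec(D, ga)
  }
  ii <- jj <- integer(16 * m)
  xx <- numeric(16 * m)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    ga <- G[, (3 * a - 2):(3 * a), drop = FALSE]
    val <- rowSums(ga * Dg[[b]]) * gr$vol
    idx <- (k * m + 1L):((k + 1L) * m)
    ii[idx] <- mesh$tets[, a]
    jj[idx] <- mesh$tets[, b]
    xx[idx] <- val
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

## Lumped mass vector (row-sum of consistent mass): V/4 to each vertex.
#' @noRd
fem_lumped_mass <- function(mesh, gr = fem_gradients(mesh)) {
  n <- nrow(mesh$nodes)
  mvec <- numeric(n)
  q <- gr$vol / 4
  for (a in 1:4) {
    s <- tapply(q, mesh$tets[, a], sum)
    mvec[as.integer(names(s))] <- mvec[as.integer(names(s))] + as.numeric(s)
  }
  mvec
}

## Solve K u = f with Dirichlet values on given nodes.
#' @noRd
fem_solve_dirichlet <- function(K, f, fixed_nodes, fixed_vals) {
  n <- nrow(K)
  u <- numeric(n)
  u[fixed_nodes] <- fixed_vals
  free <- setdiff(seq_len(n), fixed_nodes)
  rhs <- f[free] - as.numeric(K[free, fixed_nodes, drop = FALSE] %*%
                                u[fixed_nodes])
  u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))
  u
}
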
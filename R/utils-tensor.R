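#' @keywords internal
"_PACKAGE"

## Batched 3x3 tensor algebra. Tensors are stored row-wise as N x 9 matrices
## (column order: T11,T12,T13,T21,...,T33) so that whole fields of deformation
## gradients / stresses can be manipulated without per-element loops.

#' @noRd
t9_identity <- function(n) {
  out <- matrix(0, n, 9)
  out[, c(1, 5, 9)] <- 1
  out
}

#' @noRd
t9_from_matrix <- function(A) matrix(as.numeric(t(A)), 1, 9)

#' @noRd
t9_to_matrix <- function(T9, i = 1L) matrix(T9[i, ], 3, 3, byrow = TRUE)

## C = A %*% B, batched
#' @noRd
t9_mult <- function(A, B) {
  out <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    k <- (i - 1) * 3 + j
    out[, k] <- A[, (i - 1) * 3 + 1] * B[, j] +
      A[, (i - 1) * 3 + 2] * B[, 3 + j] +
      A[, (i - 1) * 3 + 3] * B[, 6 + j]
  }
  out
}

#' @noRd
t9_transpose <- function(A) A[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]

#' @noRd
t9_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
    A[, 2] * (A[, 4] * A[, 9] - A[, 6] * A[, 7]) +
    A[, 3] * (A[, 4] * A[, 8] - A[, 5] * A[, 7])
}

## inverse via adjugate, batched
#' @noRd
t9_inv <- function(A) {
  d <- t9_det(A)
  if (any(abs(d) < .Machine$double.xmin)) stop("singular 3x3 tensor in batch")
  out <- matrix(0, nrow(A), 9)
  out[, 1] <- (A[, 5] * A[, 9] - A[, 6] * A[, 8])
  out[, 2] <- (A[, 3] * A[, 8] - A[, 2] * A[, 9])
  out[, 3] <- (A[, 2] * A[, 6] - A[, 3] * A[, 5])
  out[, 4] <- (A[, 6] * A[, 7] - A[, 4] * A[, 9])
  out[, 5] <- (A[, 1] * A[, 9] - A[, 3] * A[, 7])
  out[, 6] <- (A[, 3] * A[, 4] - A[, 1] * A[, 6])
  out[, 7] <- (A[, 4] * A[, 8] - A[, 5] * A[, 7])
  out[, 8] <- (A[, 2] * A[, 7] - A[, 1] * A[, 8])
  out[, 9] <- (A[, 1] * A[, 5] - A[, 2] * A[, 4])
  out / d
}

#' @noRd
t9_trace <- function(A) A[, 1] + A[, 5] + A[, 9]

## outer product of row-wise 3-vectors: N x 9
#' @noRd
t9_outer <- function(a, b = a) {
  cbind(a[, 1] * b[, 1], a[, 1] * b[, 2], a[, 1] * b[, 3],
        a[, 2] * b[, 1], a[, 2] * b[, 2], a[, 2] * b[, 3],
        a[, 3] * b[, 1], a[, 3] * b[, 2], a[, 3] * b[, 3])
}

## y = A x for row-wise vectors
#' @noRd
t9_matvec <- function(A, x) {
  cbind(A[, 1] * x[, 1] + A[, 2] * x[, 2] + A[, 3] * x[, 3],
        A[, 4] * x[, 1] + A[, 5] * x[, 2] + A[, 6] * x[, 3],
        A[, 7] * x[, 1] + A[, 8] * x[, 2] + A[, 9] * x[, 3])
}

#' @noRd
vec3_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @noRd
vec3_dot <- function(a, b) rowSums(a * b)

#' @noRd
vec3_norm <- function(a) sqrt(rowSums(a * a))

#' @noRd
vec3_normalize <- function(a) {
  n <- vec3_norm(a)
  n[n == 0] <- 1
  a / n
}

## Rodrigues rotation of row-vectors v by angle (rad) about row-unit-axes k
#' @noRd
vec3_rotate <- function(v, axis, angle) {
  ca <- cos(angle); sa <- sin(angle)
  kxv <- vec3_cross(axis, v)
  kdv <- vec3_dot(axis, v)
  v * ca + kxv * sa + axis * (kdv * (1 - ca))
}

## largest eigenvalue of row-wise symmetric 3x3 tensors (trigonometric formula)
#' @noRd
t9_sym_eigmax <- function(S) {
  a11 <- S[, 1]; a22 <- S[, 5]; a33 <- S[, 9]
  a12 <- (S[, 2] + S[, 4]) / 2
  a13 <- (S[, 3] + S[, 7]) / 2
  a23 <- (S[, 6] + S[, 8]) / 2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  out <- q
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
    b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
    out[nz] <- (q + 2 * p * cos(phi))[nz]
  }
  out
}

## symmetric von Mises from a row-wise Cauchy tensor
#' @noRd
t9_von_mises <- function(S) {
  s11 <- S[, 1]; s22 <- S[, 5]; s33 <- S[, 9]
  s12 <- S[, 2]; s13 <- S[, 3]; s23 <- S[, 6]
  sqrt(0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
         3 * (s12^2 + s13^2 + s23^2))
}
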
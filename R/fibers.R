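## Rule-based myocardial fiber architecture -----------------------------------

#' Transmural harmonic field
#'
#' Solves the Laplace equation on the wall with Dirichlet data `U = 0` on the
#' epicardium and `U = 1` on the endocardium (zero flux elsewhere) with linear
#' finite elements, and returns the nodal field together with the per-element
#' normalized negative gradient, the transmural direction used to seed the
#' fiber coordinate system.
#'
#' @param mesh an `lv_mesh` with `endocardium` and `epicardium` surface tags
#'   (or `inner`/`outer`, used as endo/epi fallbacks).
#' @return list with `U` (nodal, in `[0,1]` by the discrete maximum principle)
#'   and `e` (m x 3 unit vectors per element, `e = -grad U / |grad U|`).
#' @export
solve_transmural_laplace <- function(mesh) {
  endo <- mesh$surfaces$endocardium %||% mesh$surfaces$inner
  epi <- mesh$surfaces$epicardium %||% mesh$surfaces$outer
  if (is.null(endo) || is.null(epi))
    stop("mesh must carry endocardium and epicardium surface tags")
  gr <- fem_gradients(mesh)
  K <- fem_stiffness(mesh, gr)
  endo_n <- unique(as.vector(endo))
  epi_n <- setdiff(unique(as.vector(epi)), endo_n)
  fixed <- c(endo_n, epi_n)
  U <- fem_solve_dirichlet(K, numeric(nrow(mesh$nodes)), fixed,
                           c(rep(1, length(endo_n)), rep(0, length(epi_n))))
  ## element gradient of U
  G <- gr$grads
  gU <- matrix(0, nrow(mesh$tets), 3)
  for (a in 1:4) {
    ga <- G[, (3 * a - 2):(3 * a), drop = FALSE]
    gU <- gU + ga * U[mesh$tets[, a]]
  }
  nrm <- vec3_norm(gU)
  zero <- nrm < 1e-12
  if (any(zero)) {
    ## fall back to the nearest non-degenerate element direction
    cen <- element_centroids(mesh)
    good <- which(!zero)
    for (i in which(zero)) {
      j <- good[which.min(rowSums((cen[good, , drop = FALSE] -
                                     matrix(cen[i, ], length(good), 3,
                                            byrow = TRUE))^2))]
      gU[i, ] <- gU[j, ]
    }
    nrm <- vec3_norm(gU)
  }
  list(U = U, e = -gU / nrm)
}

#' Transmural wall coordinate
#'
#' `beta = 0` on the epicardium and `1` on the endocardium. The `distance`
#' method evaluates `beta = D_epi / (D_epi + D_end)` from Euclidean distances
#' of element centroids to the tagged surfaces; the `harmonic` method uses the
#' Laplace field of [solve_transmural_laplace()] averaged per element.
#'
#' @param mesh an `lv_mesh` with endo/epi tags.
#' @param method `"distance"` (default, the wall-distance rule) or
#'   `"harmonic"`.
#' @param harmonic optional precomputed result of [solve_transmural_laplace()].
#' @return numeric vector, one value in `[0,1]` per element.
#' @export
transmural_beta <- function(mesh, method = c("distance", "harmonic"),
                            harmonic = NULL) {
  method <- match.arg(method)
  endo <- mesh$surfaces$endocardium %||% mesh$surfaces$inner
  epi <- mesh$surfaces$epicardium %||% mesh$surfaces$outer
  if (is.null(endo) || is.null(epi))
    stop("mesh must carry endocardium and epicardium surface tags")
  if (method == "harmonic") {
    if (is.null(harmonic)) harmonic <- solve_transmural_laplace(mesh)
    U <- harmonic$U
    return(rowMeans(matrix(U[mesh$tets], ncol = 4)))
  }
  cen <- element_centroids(mesh)
  d_end <- point_surface_distance(cen, endo, mesh$nodes)
  d_epi <- point_surface_distance(cen, epi, mesh$nodes)
  d_epi / (d_epi + d_end)
}

## exact point - triangle-soup distance (Eberly region reduction), batched over
## points per triangle
#' @noRd
point_surface_distance <- function(p, tris, nodes) {
  np <- nrow(p)
  best <- rep(Inf, np)
  v1 <- nodes[tris[, 1], , drop = FALSE]
  v2 <- nodes[tris[, 2], , drop = FALSE]
  v3 <- nodes[tris[, 3], , drop = FALSE]
  for (it in seq_len(nrow(tris))) {
    B <- matrix(v1[it, ], np, 3, byrow = TRUE)
    e0 <- matrix(v2[it, ] - v1[it, ], np, 3, byrow = TRUE)
    e1 <- matrix(v3[it, ] - v1[it, ], np, 3, byrow = TRUE)
    d <- B - p
    a <- sum((v2[it, ] - v1[it, ])^2)
    b <- sum((v2[it, ] - v1[it, ]) * (v3[it, ] - v1[it, ]))
    cc <- sum((v3[it, ] - v1[it, ])^2)
    dd <- rowSums(e0 * d)
    ee <- rowSums(e1 * d)
    det <- a * cc - b * b
    s <- b * ee - cc * dd
    t <- b * dd - a * ee
    ## clamp barycentric coordinates to the triangle
    s <- s / det; t <- t / det
    s[!is.finite(s)] <- 0; t[!is.finite(t)] <- 0
    s <- pmin(pmax(s, 0), 1)
    t <- pmin(pmax(t, 0), 1)
    over <- s + t > 1
    if (any(over)) {
      sc <- s[over] / (s[over] + t[over])
      s[over] <- sc; t[over] <- 1 - sc
    }
    q <- B + e0 * s + e1 * t
    ## clamped point may not be the true closest; polish by projecting onto
    ## each edge and taking the minimum
    cand <- rowSums((q - p)^2)
    for (edge in list(list(v1[it, ], v2[it, ]), list(v1[it, ], v3[it, ]),
                      list(v2[it, ], v3[it, ]))) {
      A <- matrix(edge[[1]], np, 3, byrow = TRUE)
      ab <- edge[[2]] - edge[[1]]
      tt <- pmin(pmax(((p - A) %*% ab) / sum(ab * ab), 0), 1)
      qq <- A + tt %*% t(ab)
      cand <- pmin(cand, rowSums((qq - p)^2))
    }
    best <- pmin(best, cand)
  }
  sqrt(best)
}

#' Helix fiber angles
#'
#' Linear transmural interpolation between apicobasally tapered epicardial and
#' endocardial angle profiles: `theta_epi(Z) = theta_epi_max (1 - Z/Z_apex)`,
#' `theta_end(Z) = theta_end_max (1 - Z/Z_apex)`,
#' `theta = beta theta_end + (1 - beta) theta_epi`. Angles are measured from
#' the circumferential direction; the defaults give -60 degrees at the basal
#' epicardium and +60 degrees at the basal endocardium, zero at the apex.
#'
#' @param beta transmural coordinate per element (0 epi, 1 endo).
#' @param Z apicobasal coordinate per element (base at 0, apex at `z_apex`).
#' @param z_apex apex Z coordinate (mm).
#' @param theta_epi_max,theta_end_max basal angles (degrees).
#' @return helix angle per element (degrees).
#' @export
helix_angles <- function(beta, Z, z_apex, theta_epi_max = -60,
                         theta_end_max = 60) {
  if (any(Z < -1e-9) || any(Z > z_apex * (1 + 1e-9)))
    stop("Z coordinates outside [0, z_apex]")
  taper <- 1 - Z / z_apex
  beta * (theta_end_max * taper) + (1 - beta) * (theta_epi_max * taper)
}

#' Per-element fiber/sheet/normal triads
#'
#' Builds the local wall frame from the transmural direction `e` and the
#' global long axis: `a1 = e` (transmural), `a2` the in-wall apicobasal
#' direction (z made orthogonal to `a1`), `a3 = a1 x a2` (circumferential).
#' The fiber direction is `a3` rotated by the helix angle about the transmural
#' axis (right-hand rule about `a1`); the sheet direction is transmural and
#' the sheet-normal completes the right-handed triad.
#'
#' @param e m x 3 unit transmural directions (from
#'   [solve_transmural_laplace()]).
#' @param theta helix angle per element (degrees).
#' @param mesh the mesh (used for the apex-cylinder isotropy mask and
#'   neighbour repair of degenerate elements).
#' @param z_axis global long-axis direction (default `c(0, 0, 1)`).
#' @return object of class `fiber_field`: list with `fiber`, `sheet`,
#'   `sheet_normal` (m x 3 unit vectors), `theta`, `isotropic_mask`.
#' @export
build_triads <- function(e, theta, mesh, z_axis = c(0, 0, 1)) {
  m <- nrow(e)
  z <- matrix(z_axis, m, 3, byrow = TRUE)
  a1 <- vec3_normalize(e)
  proj <- z - a1 * vec3_dot(z, a1)
  pn <- vec3_norm(proj)
  degen <- pn < 1e-8
  if (any(degen)) {
    ## transmural direction parallel to the long axis (apex cap):
    ## borrow the nearest non-degenerate in-wall axis
    cen <- element_centroids(mesh)
    good <- which(!degen)
    for (i in which(degen)) {
      j <- good[which.min(rowSums((cen[good, , drop = FALSE] -
                                     matrix(cen[i, ], length(good), 3,
                                            byrow = TRUE))^2))]
      proj[i, ] <- proj[j, ] - a1[i, ] * sum(proj[j, ] * a1[i, ])
    }
    pn <- vec3_norm(proj)
    if (any(pn < 1e-12)) stop("degenerate apicobasal direction could not be repaired")
  }
  a2 <- proj / pn
  a3 <- vec3_cross(a1, a2)
  fib <- vec3_rotate(a3, a1, theta * pi / 180)
  sheet <- a1
  normal <- vec3_cross(fib, sheet)
  iso <- logical(m)
  if (!is.null(mesh$regions$apex_cylinder))
    iso[mesh$regions$apex_cylinder] <- TRUE
  structure(list(fiber = fib, sheet = sheet, sheet_normal = normal,
                 a1 = a1, a2 = a2, a3 = a3,
                 theta = theta, isotropic_mask = iso),
            class = "fiber_field")
}

#' @export
print.fiber_field <- function(x, ...) {
  cat("Fiber field:", nrow(x$fiber), "elements;",
      sum(x$isotropic_mask), "isotropic (apex)\n")
  cat(sprintf("  helix angle range %.1f .. %.1f deg\n", min(x$theta),
              max(x$theta)))
  invisible(x)
}

#' Generate the full fiber architecture of an LV mesh
#'
#' Convenience wrapper: harmonic transmural directions, wall-distance
#' transmural coordinate, tapered helix angles and per-element triads.
#'
#' @param mesh an `lv_mesh` with endo/epi tags.
#' @param theta_epi_max,theta_end_max basal helix angles (degrees).
#' @param beta_method transmural coordinate method (see [transmural_beta()]).
#' @return a `fiber_field`; also carries `beta` and the harmonic field.
#' @export
generate_fibers <- function(mesh, theta_epi_max = -60, theta_end_max = 60,
                            beta_method = "distance") {
  har <- solve_transmural_laplace(mesh)
  beta <- transmural_beta(mesh, method = beta_method, harmonic = har)
  cen <- element_centroids(mesh)
  z_apex <- max(mesh$nodes[, 3])
  theta <- helix_angles(beta, pmin(pmax(cen[, 3], 0), z_apex), z_apex,
                        theta_epi_max, theta_end_max)
  ff <- build_triads(har$e, theta, mesh)
  ff$beta <- beta
  ff$harmonic <- har
  ff
}
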
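## Tagged tetrahedral meshes -------------------------------------------------

#' Construct a tagged tetrahedral mesh
#'
#' The container shared by all field solvers: node coordinates (mm), tetrahedral
#' connectivity, named boundary-surface triangle sets and named element-region
#' sets. Connectivity is stored 1-based inside R; file writers emit 0-based
#' indices.
#'
#' @param nodes numeric matrix, n x 3, coordinates in mm.
#' @param tets integer matrix, m x 4, 1-based node indices, positively oriented.
#' @param surfaces named list of integer matrices (k x 3) of boundary-triangle
#'   node indices, oriented outward from the solid.
#' @param regions named list of integer vectors of element indices.
#' @param units length unit tag (only "mm" is produced by the generators).
#' @return an object of class `lv_mesh`.
#' @export
lv_mesh <- function(nodes, tets, surfaces = list(), regions = list(),
                    units = "mm") {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4)
  if (nrow(tets) > 0 && (max(tets) > nrow(nodes) || min(tets) < 1L))
    stop("tet connectivity refers to nodes outside the node table")
  surfaces <- lapply(surfaces, function(s) {
    s <- as.matrix(s); storage.mode(s) <- "integer"; s
  })
  regions <- lapply(regions, as.integer)
  m <- structure(list(nodes = nodes, tets = tets, surfaces = surfaces,
                      regions = regions, units = units),
                 class = "lv_mesh")
  v <- tet_volumes(m)
  if (any(v < 0)) {
    neg <- which(v < 0)
    m$tets[neg, c(3, 4)] <- m$tets[neg, c(4, 3)]
  }
  m
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets",
      paste0("[", x$units, "]\n"))
  if (length(x$surfaces))
    cat("  surfaces:", paste(sprintf("%s (%d)", names(x$surfaces),
                                     vapply(x$surfaces, nrow, 1L)),
                             collapse = ", "), "\n")
  if (length(x$regions))
    cat("  regions:", paste(sprintf("%s (%d)", names(x$regions),
                                    lengths(x$regions)), collapse = ", "), "\n")
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param mesh an `lv_mesh`.
#' @return numeric vector of signed volumes (mm^3); positive after construction.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes; tt <- mesh$tets
  a <- nd[tt[, 2], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  b <- nd[tt[, 3], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  c3 <- nd[tt[, 4], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  vec3_dot(a, vec3_cross(b, c3)) / 6
}

## Kuhn (Freudenthal) 6-tet split of a hexahedron given its 8 corner node ids
## in (i,j,k)-binary order: id[di, dj, dk] listed as
## c(000,100,010,110,001,101,011,111). The split is conforming across a
## structured grid because it is translation-invariant in index space.
kuhn_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' @noRd
hexes_to_tets <- function(hex) {
  ## hex: H x 8 matrix of node ids in binary corner order
  corner <- function(d) 1L + d[1] + 2L * d[2] + 4L * d[3]
  out <- vector("list", 6)
  for (p in seq_len(6)) {
    perm <- kuhn_perms[p, ]
    d <- c(0L, 0L, 0L)
    idx <- integer(4); idx[1] <- corner(d)
    for (q in 1:3) {
      d[perm[q]] <- 1L
      idx[q + 1] <- corner(d)
    }
    out[[p]] <- hex[, idx, drop = FALSE]
  }
  tets <- do.call(rbind, out)
  ## drop tets degenerated by collapsed (pole) nodes
  keep <- tets[, 1] != tets[, 2] & tets[, 1] != tets[, 3] &
    tets[, 1] != tets[, 4] & tets[, 2] != tets[, 3] &
    tets[, 2] != tets[, 4] & tets[, 3] != tets[, 4]
  tets[keep, , drop = FALSE]
}

## flip tets to positive orientation (needed before boundary extraction)
#' @noRd
orient_tets <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  neg <- vec3_dot(a, vec3_cross(b, c3)) < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tets
}

## Boundary faces of a tet mesh: triangles appearing in exactly one tet,
## oriented outward.
#' @noRd
boundary_faces <- function(tets) {
  f <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
             tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  tab <- table(key)
  f[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Structured tetrahedral box mesh
#'
#' Builds a box `[0,lx] x [0,ly] x [0,lz]` with a conforming 6-tet split of a
#' structured grid; boundary triangles tagged `x0,x1,y0,y1,z0,z1`.
#'
#' @param nx,ny,nz number of cells per direction.
#' @param lx,ly,lz edge lengths (mm).
#' @return an `lv_mesh`.
#' @export
mesh_box <- function(nx, ny, nz, lx = 1, ly = 1, lz = 1) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  nodes <- cbind(xs[g$i + 1], ys[g$j + 1], zs[g$k + 1])
  ce <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  hex <- cbind(nid(ce$i,     ce$j,     ce$k),
               nid(ce$i + 1, ce$j,     ce$k),
               nid(ce$i,     ce$j + 1, ce$k),
               nid(ce$i + 1, ce$j + 1, ce$k),
               nid(ce$i,     ce$j,     ce$k + 1),
               nid(ce$i + 1, ce$j,     ce$k + 1),
               nid(ce$i,     ce$j + 1, ce$k + 1),
               nid(ce$i + 1, ce$j + 1, ce$k + 1))
  tets <- orient_tets(nodes, hexes_to_tets(hex))
  bf <- boundary_faces(tets)
  on_plane <- function(f, coord, val) {
    x <- matrix(nodes[f, coord], nrow(f), 3)
    abs(x - val) < 1e-9 * max(lx, ly, lz)
  }
  tag <- function(coord, val) bf[rowSums(on_plane(bf, coord, val)) == 3L, ,
                                drop = FALSE]
  surfaces <- list(x0 = tag(1, 0), x1 = tag(1, lx),
                   y0 = tag(2, 0), y1 = tag(2, ly),
                   z0 = tag(3, 0), z1 = tag(3, lz))
  lv_mesh(nodes, tets, surfaces)
}

#' Structured cylindrical-shell (annulus) mesh
#'
#' Annular shell `r in [r_inner, r_outer]`, `z in [0, h]`, periodic in the
#' circumferential direction; boundary triangles tagged
#' `inner, outer, bottom, top`.
#'
#' @param r_inner,r_outer radii (mm); `r_outer > r_inner > 0`.
#' @param h height (mm).
#' @param n_r,n_theta,n_z cells radially / circumferentially / axially.
#' @return an `lv_mesh`.
#' @export
mesh_cylinder_shell <- function(r_inner, r_outer, h, n_r = 4, n_theta = 24,
                                n_z = 2) {
  stopifnot(r_outer > r_inner, r_inner > 0)
  rs <- seq(r_inner, r_outer, length.out = n_r + 1)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  zs <- seq(0, h, length.out = n_z + 1)
  nid <- function(ir, it, iz) 1L + ir + (n_r + 1L) * ((it %% n_theta) +
                                                        n_theta * iz)
  g <- expand.grid(ir = 0:n_r, it = 0:(n_theta - 1), iz = 0:n_z)
  nodes <- cbind(rs[g$ir + 1] * cos(th[g$it + 1]),
                 rs[g$ir + 1] * sin(th[g$it + 1]),
                 zs[g$iz + 1])
  ce <- expand.grid(ir = 0:(n_r - 1), it = 0:(n_theta - 1), iz = 0:(n_z - 1))
  hex <- cbind(nid(ce$ir,     ce$it,     ce$iz),
               nid(ce$ir + 1, ce$it,     ce$iz),
               nid(ce$ir,     ce$it + 1, ce$iz),
               nid(ce$ir + 1, ce$it + 1, ce$iz),
               nid(ce$ir,     ce$it,     ce$iz + 1),
               nid(ce$ir + 1, ce$it,     ce$iz + 1),
               nid(ce$ir,     ce$it + 1, ce$iz + 1),
               nid(ce$ir + 1, ce$it + 1, ce$iz + 1))
  tets <- orient_tets(nodes, hexes_to_tets(hex))
  bf <- boundary_faces(tets)
  rad <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  all_close <- function(f, vals, target, tol) {
    m <- matrix(vals[f], nrow(f), 3)
    rowSums(abs(m - target) < tol) == 3L
  }
  tol_r <- 1e-9 * r_outer
  surfaces <- list(
    inner  = bf[all_close(bf, rad, r_inner, tol_r), , drop = FALSE],
    outer  = bf[all_close(bf, rad, r_outer, tol_r), , drop = FALSE],
    bottom = bf[all_close(bf, nodes[, 3], 0, 1e-9 * max(h, 1)), , drop = FALSE],
    top    = bf[all_close(bf, nodes[, 3], h, 1e-9 * max(h, 1)), , drop = FALSE])
  lv_mesh(nodes, tets, surfaces)
}

## --------------------------------------------------------------------------

#' Enclosed volume of a closed triangulated surface
#'
#' Divergence-theorem volume `V = 1/6 |sum_f x1 . (x2 x x3)|`. Used for cavity
#' volumes, PV loops and the end-diastolic-volume calibration. For an
#' `lv_mesh` the endocardial surface is closed with a triangle fan over the
#' basal opening before integration.
#'
#' @param x an `lv_mesh` with an `endocardium` surface, or a triangle matrix
#'   (k x 3 node indices).
#' @param nodes node coordinates (required when `x` is a triangle matrix).
#' @param check require a closed surface (every edge shared by two triangles).
#' @return volume in mL (1 mL = 1000 mm^3).
#' @export
cavity_volume <- function(x, nodes = NULL, check = TRUE) {
  if (inherits(x, "lv_mesh")) {
    tris <- closed_endocardial_surface(x)
    nodes <- tris$nodes
    tris <- tris$tris
  } else {
    tris <- as.matrix(x)
    if (is.null(nodes)) stop("nodes must be supplied with a triangle matrix")
  }
  if (check && !surface_is_closed(tris))
    stop("surface is not closed; cavity volume undefined")
  v1 <- nodes[tris[, 1], , drop = FALSE]
  v2 <- nodes[tris[, 2], , drop = FALSE]
  v3 <- nodes[tris[, 3], , drop = FALSE]
  vol <- sum(vec3_dot(v1, vec3_cross(v2, v3))) / 6
  abs(vol) / 1000
}

#' @noRd
surface_is_closed <- function(tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

## Close the endocardial surface of an LV mesh with a basal-cap fan.
#' @noRd
closed_endocardial_surface <- function(mesh, displacement = NULL) {
  if (is.null(mesh$surfaces$endocardium))
    stop("mesh has no 'endocardium' surface tag")
  nodes <- mesh$nodes
  if (!is.null(displacement)) nodes <- nodes + displacement
  endo <- mesh$surfaces$endocardium
  ## rim = boundary edges of the endo patch
  e <- rbind(endo[, c(1, 2)], endo[, c(2, 3)], endo[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  rim_edges <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  if (nrow(rim_edges) == 0L)  # already closed
    return(list(tris = endo, nodes = nodes))
  rim_nodes <- unique(as.vector(rim_edges))
  centroid <- colMeans(nodes[rim_nodes, , drop = FALSE])
  nodes <- rbind(nodes, centroid)
  cid <- nrow(nodes)
  ## endo faces are oriented outward from the solid = into the cavity;
  ## orient the fan consistently (edge direction as it appears in the patch).
  cap <- cbind(rim_edges[, 2], rim_edges[, 1], cid)
  list(tris = rbind(endo, cap), nodes = nodes)
}

#' Monte-Carlo volume estimate of a closed triangulated surface
#'
#' Independent cross-check of [cavity_volume()]: uniform samples in the
#' bounding box classified by ray casting along +x with z-band bucketing.
#'
#' @param tris triangle matrix (k x 3), `nodes` coordinates.
#' @param nodes node coordinate matrix.
#' @param n number of sample points.
#' @param seed RNG seed for reproducibility.
#' @return estimated volume in mL.
#' @export
mc_volume <- function(tris, nodes, n = 2e5, seed = 1L) {
  set.seed(seed)
  lo <- apply(nodes, 2, min); hi <- apply(nodes, 2, max)
  p <- cbind(stats::runif(n, lo[1], hi[1]),
             stats::runif(n, lo[2], hi[2]),
             stats::runif(n, lo[3], hi[3]))
  inside <- points_in_surface(p, tris, nodes)
  mean(inside) * prod(hi - lo) / 1000
}

## ray-cast point-in-polyhedron, +x ray, vectorized per z-band
#' @noRd
points_in_surface <- function(p, tris, nodes) {
  v1 <- nodes[tris[, 1], , drop = FALSE]
  v2 <- nodes[tris[, 2], , drop = FALSE]
  v3 <- nodes[tris[, 3], , drop = FALSE]
  tz_lo <- pmin(v1[, 3], v2[, 3], v3[, 3])
  tz_hi <- pmax(v1[, 3], v2[, 3], v3[, 3])
  nb <- max(4L, as.integer(sqrt(nrow(tris))))
  zb <- seq(min(tz_lo), max(tz_hi), length.out = nb + 1)
  band_of <- function(z) pmin(pmax(findInterval(z, zb, rightmost.closed = TRUE),
                                   1L), nb)
  pb <- band_of(p[, 3])
  crossings <- integer(nrow(p))
  for (b in seq_len(nb)) {
    pi_idx <- which(pb == b)
    if (!length(pi_idx)) next
    ti_idx <- which(tz_lo <= zb[b + 1] & tz_hi >= zb[b])
    if (!length(ti_idx)) next
    crossings[pi_idx] <- crossings[pi_idx] +
      count_ray_hits(p[pi_idx, , drop = FALSE],
                     v1[ti_idx, , drop = FALSE],
                     v2[ti_idx, , drop = FALSE],
                     v3[ti_idx, , drop = FALSE])
  }
  crossings %% 2L == 1L
}

## number of triangle intersections of +x rays from each point
#' @noRd
count_ray_hits <- function(p, v1, v2, v3) {
  np <- nrow(p); nt <- nrow(v1)
  hits <- integer(np)
  ## Moller-Trumbore with ray direction (1,0,0): solve for t,u,v
  e1 <- v2 - v1; e2 <- v3 - v1
  ## h = d x e2 = (0, -e2z, e2y); a = e1 . h
  a <- -e1[, 2] * e2[, 3] + e1[, 3] * e2[, 2]
  ok_t <- abs(a) > 1e-14
  for (it in which(ok_t)) {
    s <- p - matrix(v1[it, ], np, 3, byrow = TRUE)
    f <- 1 / a[it]
    u <- f * (-s[, 2] * e2[it, 3] + s[, 3] * e2[it, 2])
    qx <- s[, 2] * e1[it, 3] - s[, 3] * e1[it, 2]
    v <- f * qx
    ## t = f * (e2 . q), q = s x e1
    q1 <- s[, 2] * e1[it, 3] - s[, 3] * e1[it, 2]
    q2 <- s[, 3] * e1[it, 1] - s[, 1] * e1[it, 3]
    q3 <- s[, 1] * e1[it, 2] - s[, 2] * e1[it, 1]
    tt <- f * (e2[it, 1] * q1 + e2[it, 2] * q2 + e2[it, 3] * q3)
    hit <- u >= 0 & v >= 0 & (u + v) <= 1 & tt > 0
    hits <- hits + hit
  }
  hits
}

#' Per-element centroids
#' @param mesh an `lv_mesh`.
#' @return m x 3 matrix of tet centroids.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
     mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
}
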
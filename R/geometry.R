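## Parameterized LV geometry -------------------------------------------------

## Case parameter cards: end-diastolic volume (mL), long-axis length (mm),
## internal dimension (mm), and wall-thickness targets (mm). Outflow-tract
## radius and tilt are not tabulated clinically per case; the per-case values
## below encode the qualitative case design (case 3 narrows the outflow
## cross-section, case 4 tilts it, case 5 combines remodelling changes).
.lv_cases <- list(
  `1` = list(edv = 117.3, long_axis = 74.2, lvid = 54.4,
             wt_max = 8.4,  wt_min = 3.3, wt_avg = 6.2,
             lvot_radius = 11, lvot_tilt = 0),
  `2` = list(edv = 122.5, long_axis = 74.8, lvid = 54.4,
             wt_max = 12.1, wt_min = 4.8, wt_avg = 9.3,
             lvot_radius = 11, lvot_tilt = 0),
  `3` = list(edv = 83.2,  long_axis = 77.9, lvid = 50.0,
             wt_max = 11.7, wt_min = 4.5, wt_avg = 9.1,
             lvot_radius = 9,  lvot_tilt = 0),
  `4` = list(edv = 117.5, long_axis = 84.6, lvid = 54.4,
             wt_max = 8.6,  wt_min = 3.4, wt_avg = 6.7,
             lvot_radius = 11, lvot_tilt = 20),
  `5` = list(edv = 157.5, long_axis = 86.1, lvid = 62.4,
             wt_max = 8.8,  wt_min = 4.0, wt_avg = 6.5,
             lvot_radius = 10, lvot_tilt = 10))

#' LV case parameter card
#'
#' Returns the geometric/clinical parameters of one of the five reference
#' left-ventricle cases (end-diastolic volume, long-axis length, internal
#' dimension, wall-thickness targets), or builds a custom card.
#'
#' @param case_id integer 1..5, or `NULL` when all parameters are given.
#' @param edv end-diastolic cavity volume (mL).
#' @param long_axis apex-to-base length (mm).
#' @param lvid internal dimension (endocardial diameter at base, mm).
#' @param wt_max,wt_min,wt_avg wall-thickness targets (mm).
#' @param lvot_radius outflow-tract (valve-plane) radius (mm).
#' @param lvot_tilt outflow-tract tilt from the long axis (degrees).
#' @param n_levels number of cross-section levels used to describe the wall.
#' @param eccentricity ratio of minor to major in-plane semi-axis (1 = circular
#'   sections).
#' @return an object of class `lv_case_spec`.
#' @export
lv_case_spec <- function(case_id = 1L, edv = NULL, long_axis = NULL,
                         lvid = NULL, wt_max = NULL, wt_min = NULL,
                         wt_avg = NULL, lvot_radius = NULL, lvot_tilt = NULL,
                         n_levels = 9L, eccentricity = 1) {
  base <- if (!is.null(case_id)) {
    if (!as.character(case_id) %in% names(.lv_cases))
      stop("case_id must be one of 1..5")
    .lv_cases[[as.character(case_id)]]
  } else list()
  pick <- function(x, nm) if (!is.null(x)) x else base[[nm]]
  spec <- list(case_id = case_id,
               edv = pick(edv, "edv"),
               long_axis = pick(long_axis, "long_axis"),
               lvid = pick(lvid, "lvid"),
               wt_max = pick(wt_max, "wt_max"),
               wt_min = pick(wt_min, "wt_min"),
               wt_avg = pick(wt_avg, "wt_avg"),
               lvot_radius = pick(lvot_radius, "lvot_radius"),
               lvot_tilt = pick(lvot_tilt, "lvot_tilt"),
               n_levels = as.integer(n_levels),
               eccentricity = eccentricity)
  with(spec, {
    if (any(c(edv, long_axis, lvid, wt_max, wt_min, wt_avg) <= 0))
      stop("all lengths, volumes and thicknesses must be positive")
    if (!(wt_min <= wt_avg && wt_avg <= wt_max))
      stop("thickness targets must satisfy wt_min <= wt_avg <= wt_max")
    if (n_levels < 3L) stop("need at least 3 cross-section levels")
  })
  class(spec) <- "lv_case_spec"
  spec
}

#' @export
print.lv_case_spec <- function(x, ...) {
  cat(sprintf("LV case %s: EDV %.1f mL, long axis %.1f mm, LVID %.1f mm\n",
              as.character(x$case_id %||% "custom"), x$edv, x$long_axis,
              x$lvid))
  cat(sprintf("  wall thickness %.1f (apex) .. %.1f (base) mm, target mean %.1f\n",
              x$wt_min, x$wt_max, x$wt_avg))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Wall-thickness profile along the normalized apicobasal coordinate
## s in [0,1] (0 = base, 1 = apex). The exponent is chosen so that the
## uniform-in-s mean equals the wall-thickness-average target.
#' @noRd
thickness_profile <- function(spec) {
  dmax <- spec$wt_max - spec$wt_min
  if (dmax < 1e-12) return(function(s) rep(spec$wt_avg, length(s)))
  frac <- (spec$wt_avg - spec$wt_min) / dmax
  frac <- min(max(frac, 0.05), 0.95)
  p <- 1 / frac - 1
  function(s) spec$wt_min + dmax * (1 - s)^p
}

#' Elliptical cross-sections of an LV case
#'
#' The endocardial contour at each level is an ellipse; levels follow a
#' truncated prolate-spheroid profile along the long axis, and the epicardium
#' is the endocardium offset along its outward normal by the level thickness.
#'
#' @param spec an [lv_case_spec()].
#' @param endo_scale multiplier on the endocardial in-plane semi-axes (used by
#'   the EDV calibration loop).
#' @return data.frame with columns `s, z, a_endo, b_endo, thickness`.
#' @export
ellipse_sections <- function(spec, endo_scale = 1) {
  s <- seq(0, 1, length.out = spec$n_levels)
  tp <- thickness_profile(spec)
  l_endo <- spec$long_axis - spec$wt_min
  a0 <- endo_scale * spec$lvid / 2
  data.frame(s = s, z = l_endo * s,
             a_endo = a0 * sqrt(pmax(1 - s^2, 0)),
             b_endo = a0 * spec$eccentricity * sqrt(pmax(1 - s^2, 0)),
             thickness = tp(s))
}

## Parametric wall point. u in [0,1] (0 base, 1 apex pole), theta
## circumferential, xi in [0,1] transmural (0 endo, 1 epi). The endocardium is
## a truncated spheroid; the epicardium is its normal offset by t(s).
#' @noRd
lv_wall_point <- function(u, theta, xi, spec, endo_scale) {
  phi <- u * pi / 2
  s <- sin(phi)
  cs <- cos(phi)
  l_endo <- spec$long_axis - spec$wt_min
  a <- endo_scale * spec$lvid / 2
  b <- a * spec$eccentricity
  tp <- thickness_profile(spec)
  x_e <- a * cs * cos(theta)
  y_e <- b * cs * sin(theta)
  z_e <- l_endo * s
  ## outward normal of the spheroid (x/a)^2+(y/b)^2+(z/l)^2=1
  nx <- x_e / a^2; ny <- y_e / b^2; nz <- z_e / l_endo^2
  ## at the pole the gradient direction is purely axial
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  pole <- nn < 1e-14
  nn[pole] <- 1; nz[pole] <- 1; nx[pole] <- 0; ny[pole] <- 0
  t_s <- tp(s)
  cbind(x_e + xi * t_s * nx / nn,
        y_e + xi * t_s * ny / nn,
        z_e + xi * t_s * nz / nn)
}

#' Build a parameterized LV volume mesh
#'
#' Generates a tagged tetrahedral mesh of the LV wall from a case card: the
#' endocardium is a truncated prolate spheroid (elliptical cross-sections along
#' the long axis), the epicardium its outward normal offset by the level
#' thickness, meshed by a structured wall grid with a conforming 6-tet split.
#' The endocardial in-plane semi-axes are rescaled (fixed long axis) until the
#' meshed cavity volume matches the card EDV to the requested tolerance.
#' Surface tags: `endocardium`, `epicardium`, `base`; element regions: `bulk`,
#' `apex_cylinder` (the isotropic apex region, a 10 mm diameter cylinder about
#' the long axis).
#'
#' @param spec an [lv_case_spec()].
#' @param n_axial,n_theta,n_trans structured-grid resolution (apicobasal rings,
#'   circumferential divisions, transmural layers).
#' @param calibrate rescale semi-axes to match EDV (default TRUE).
#' @param edv_tol relative EDV tolerance for the calibration loop.
#' @param max_iter calibration iteration bound.
#' @return an `lv_mesh`; attributes `endo_scale` and `spec` record the build.
#' @export
build_lv_geometry <- function(spec, n_axial = 12L, n_theta = 20L,
                              n_trans = 2L, calibrate = TRUE,
                              edv_tol = 0.005, max_iter = 12L) {
  stopifnot(inherits(spec, "lv_case_spec"))
  tp <- thickness_profile(spec)
  if (min(tp(seq(0, 1, length.out = 64))) <= 0)
    stop("infeasible thickness map: epicardium would intersect endocardium")
  scale <- 1
  mesh <- NULL
  for (it in seq_len(max_iter)) {
    mesh <- lv_wall_mesh(spec, scale, n_axial, n_theta, n_trans)
    if (!calibrate) break
    v <- cavity_volume(mesh)
    if (abs(v - spec$edv) / spec$edv < edv_tol) break
    ## V scales ~ quadratically with the in-plane semi-axes (fixed long axis)
    scale <- scale * sqrt(spec$edv / v)
    if (it == max_iter)
      stop("EDV calibration did not converge within iteration bound")
  }
  attr(mesh, "endo_scale") <- scale
  attr(mesh, "spec") <- spec
  mesh
}

#' @noRd
lv_wall_mesh <- function(spec, endo_scale, n_axial, n_theta, n_trans) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  us <- seq(0, 1, length.out = n_axial + 1)
  xis <- seq(0, 1, length.out = n_trans + 1)
  ## regular nodes for u < 1; collapsed pole nodes (one per xi) at u = 1
  nid <- function(iu, it, ix) {
    ## iu in 0..n_axial, it circumferential (wrapped), ix transmural
    ifelse(iu == n_axial,
           n_regular + ix + 1L,
           1L + ix + (n_trans + 1L) * ((it %% n_theta) + n_theta * iu))
  }
  n_regular <- (n_trans + 1L) * n_theta * n_axial
  g <- expand.grid(ix = 0:n_trans, it = 0:(n_theta - 1), iu = 0:(n_axial - 1))
  reg_nodes <- lv_wall_point(us[g$iu + 1], th[g$it + 1], xis[g$ix + 1],
                             spec, endo_scale)
  pole_nodes <- lv_wall_point(rep(1, n_trans + 1), rep(0, n_trans + 1), xis,
                              spec, endo_scale)
  nodes <- rbind(reg_nodes, pole_nodes)
  ce <- expand.grid(ix = 0:(n_trans - 1), it = 0:(n_theta - 1),
                    iu = 0:(n_axial - 1))
  hex <- cbind(nid(ce$iu,     ce$it,     ce$ix),
               nid(ce$iu,     ce$it + 1, ce$ix),
               nid(ce$iu + 1, ce$it,     ce$ix),
               nid(ce$iu + 1, ce$it + 1, ce$ix),
               nid(ce$iu,     ce$it,     ce$ix + 1),
               nid(ce$iu,     ce$it + 1, ce$ix + 1),
               nid(ce$iu + 1, ce$it,     ce$ix + 1),
               nid(ce$iu + 1, ce$it + 1, ce$ix + 1))
  tets <- orient_tets(nodes, hexes_to_tets(hex))
  bf <- boundary_faces(tets)
  ## classify boundary faces by node-set membership
  endo_set <- c(which(g$ix == 0L), n_regular + 1L)
  epi_set <- c(which(g$ix == n_trans), n_regular + n_trans + 1L)
  base_set <- which(g$iu == 0L)
  in_set <- function(faces, set) {
    m <- matrix(faces %in% set, nrow(faces), 3)
    rowSums(m) == 3L
  }
  surfaces <- list(
    endocardium = bf[in_set(bf, endo_set), , drop = FALSE],
    epicardium  = bf[in_set(bf, epi_set), , drop = FALSE],
    base        = bf[in_set(bf, base_set), , drop = FALSE])
  mesh <- lv_mesh(nodes, tets, surfaces)
  ## apex region: 1-cm-diameter cylinder about the long axis near the apex
  cen <- element_centroids(mesh)
  apex_z <- max(nodes[, 3])
  in_cyl <- sqrt(cen[, 1]^2 + cen[, 2]^2) <= 5 &
    cen[, 3] > apex_z - 0.25 * spec$long_axis
  mesh$regions <- list(bulk = which(!in_cyl), apex_cylinder = which(in_cyl))
  mesh
}

#' Apex-to-base length of a generated LV mesh
#'
#' Euclidean distance from the apex node (largest Z) to the centroid of the
#' basal-plane nodes.
#'
#' @param mesh an `lv_mesh` with a `base` surface tag.
#' @return length in mm.
#' @export
long_axis_length <- function(mesh) {
  apex <- mesh$nodes[which.max(mesh$nodes[, 3]), ]
  base_nodes <- unique(as.vector(mesh$surfaces$base))
  centroid <- colMeans(mesh$nodes[base_nodes, , drop = FALSE])
  sqrt(sum((apex - centroid)^2))
}

## Wall-thickness map --------------------------------------------------------

#' Wall-thickness map between two tagged surfaces
#'
#' Samples the endocardium on a uniform `(theta, s)` grid (circumferential
#' angle, normalized apicobasal coordinate) and measures the distance to the
#' epicardium along the local outward endocardial normal,
#' `t = (X_epi - X_endo) . n_endo`, by ray casting against the epicardial
#' triangles.
#'
#' @param mesh an `lv_mesh` with `endocardium` and `epicardium` tags, or a list
#'   `list(endo = , epi = , nodes = )` of triangle matrices (e.g. the inner and
#'   outer walls of a shell).
#' @param n_theta,n_s sampling-grid resolution.
#' @param s_max upper bound of the sampled apicobasal range (slightly below 1
#'   so that horizontal axis rays still meet the surface near the pole).
#' @return data.frame with columns `theta`, `s`, the sample point, the local
#'   normal and `thickness` (mm); thickness strictly positive or an error.
#' @export
wall_thickness_map <- function(mesh, n_theta = 24L, n_s = 24L, s_max = 0.95) {
  if (inherits(mesh, "lv_mesh")) {
    endo <- mesh$surfaces$endocardium
    epi <- mesh$surfaces$epicardium
    nodes <- mesh$nodes
  } else {
    endo <- mesh$endo; epi <- mesh$epi; nodes <- mesh$nodes
  }
  if (is.null(endo) || is.null(epi)) stop("need endocardium and epicardium tags")
  en <- unique(as.vector(endo))
  z_lo <- min(nodes[en, 3]); z_hi <- max(nodes[en, 3])
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ss <- seq(0, s_max, length.out = n_s)
  g <- expand.grid(theta = th, s = ss)
  z <- z_lo + g$s * (z_hi - z_lo)
  ## locate the endocardial point at (theta, s): horizontal ray from the axis
  orig <- cbind(0, 0, z)
  dirs <- cbind(cos(g$theta), sin(g$theta), 0)
  hit_e <- ray_surface_hit(orig, dirs, endo, nodes)
  ok <- is.finite(hit_e$t)
  p <- orig[ok, , drop = FALSE] + dirs[ok, , drop = FALSE] * hit_e$t[ok]
  ## wall direction = -face normal (boundary faces point out of the solid,
  ## i.e. into the cavity)
  nrm <- -hit_e$normal[ok, , drop = FALSE]
  d <- ray_surface_distance(p, nrm, epi, nodes)
  res <- data.frame(theta = g$theta[ok], s = g$s[ok],
                    x = p[, 1], y = p[, 2], z = p[, 3],
                    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3], thickness = d)
  n_sampled <- nrow(res)
  res <- res[is.finite(res$thickness), ]
  if (nrow(res) < 0.5 * n_sampled || nrow(res) == 0)
    stop("normal rays do not reach the epicardial surface: ",
         "surfaces cross or are mis-tagged")
  if (any(res$thickness <= 0))
    stop("negative thickness projection: surfaces cross")
  res
}

## first hit of rays against a triangle soup, returning distance and the unit
## normal of the hit facet
#' @noRd
ray_surface_hit <- function(p, dir, tris, nodes) {
  v1 <- nodes[tris[, 1], , drop = FALSE]
  v2 <- nodes[tris[, 2], , drop = FALSE]
  v3 <- nodes[tris[, 3], , drop = FALSE]
  fn <- vec3_normalize(vec3_cross(v2 - v1, v3 - v1))
  e1 <- v2 - v1; e2 <- v3 - v1
  np <- nrow(p)
  best <- rep(Inf, np)
  nrm <- matrix(NA_real_, np, 3)
  for (it in seq_len(nrow(tris))) {
    h <- vec3_cross(dir, matrix(e2[it, ], np, 3, byrow = TRUE))
    a <- rowSums(matrix(e1[it, ], np, 3, byrow = TRUE) * h)
    ok <- abs(a) > 1e-13
    if (!any(ok)) next
    s <- p - matrix(v1[it, ], np, 3, byrow = TRUE)
    f <- ifelse(ok, 1 / a, 0)
    u <- f * rowSums(s * h)
    q <- vec3_cross(s, matrix(e1[it, ], np, 3, byrow = TRUE))
    v <- f * rowSums(dir * q)
    tt <- f * rowSums(matrix(e2[it, ], np, 3, byrow = TRUE) * q)
    hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & tt > 1e-9 &
      tt < best
    if (any(hit)) {
      best[hit] <- tt[hit]
      nrm[hit, ] <- matrix(fn[it, ], sum(hit), 3, byrow = TRUE)
    }
  }
  list(t = best, normal = nrm)
}

## first-hit distance of rays (p, dir) against a triangle soup (Inf if none)
#' @noRd
ray_surface_distance <- function(p, dir, tris, nodes) {
  v1 <- nodes[tris[, 1], , drop = FALSE]
  v2 <- nodes[tris[, 2], , drop = FALSE]
  v3 <- nodes[tris[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  np <- nrow(p)
  best <- rep(Inf, np)
  for (it in seq_len(nrow(tris))) {
    h <- vec3_cross(dir, matrix(e2[it, ], np, 3, byrow = TRUE))
    a <- rowSums(matrix(e1[it, ], np, 3, byrow = TRUE) * h)
    ok <- abs(a) > 1e-13
    if (!any(ok)) next
    s <- p - matrix(v1[it, ], np, 3, byrow = TRUE)
    f <- ifelse(ok, 1 / a, 0)
    u <- f * rowSums(s * h)
    q <- vec3_cross(s, matrix(e1[it, ], np, 3, byrow = TRUE))
    v <- f * rowSums(dir * q)
    tt <- f * rowSums(matrix(e2[it, ], np, 3, byrow = TRUE) * q)
    hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & tt > 1e-9
    best[hit] <- pmin(best[hit], tt[hit])
  }
  best
}

#' Normal thickness between two coaxial ellipses
#'
#' Closed-form distance from a point on the inner ellipse, along its outward
#' normal, to the outer ellipse (2D; both centred at the origin and axis
#' aligned).
#'
#' @param a_endo,b_endo inner semi-axes (mm).
#' @param a_epi,b_epi outer semi-axes (mm).
#' @param theta parametric angle(s) on the inner ellipse (radians).
#' @return thickness (mm) at each `theta`.
#' @export
ellipse_normal_thickness <- function(a_endo, b_endo, a_epi, b_epi, theta) {
  stopifnot(a_epi > a_endo, b_epi > b_endo)
  px <- a_endo * cos(theta); py <- b_endo * sin(theta)
  nx <- cos(theta) / a_endo; ny <- sin(theta) / b_endo
  nn <- sqrt(nx^2 + ny^2); nx <- nx / nn; ny <- ny / nn
  ## (px + t nx)^2/ae^2 + (py + t ny)^2/be^2 = 1: quadratic in t
  A <- nx^2 / a_epi^2 + ny^2 / b_epi^2
  B <- 2 * (px * nx / a_epi^2 + py * ny / b_epi^2)
  C <- px^2 / a_epi^2 + py^2 / b_epi^2 - 1
  disc <- B^2 - 4 * A * C
  if (any(disc < 0)) stop("normal ray misses the outer ellipse")
  (-B + sqrt(disc)) / (2 * A)
}

## Outflow-tract extension ---------------------------------------------------

#' Parametric outflow-tract (LVOT) extension surface
#'
#' Short axial extension from the basal endocardial ellipse to a circular
#' valve-plane section of the card's LVOT radius, as a smooth linear morph of
#' cross-sections; optionally tilted about the y-axis by the card's LVOT tilt.
#'
#' @param spec an [lv_case_spec()].
#' @param endo_scale endocardial scale from the geometry build.
#' @param height axial extension length (mm).
#' @param n_axial,n_theta surface resolution.
#' @return list with `nodes` (k x 3) and `tris` (triangles of the tube wall),
#'   plus `outlet_ring` node indices on the valve plane.
#' @export
build_lvot <- function(spec, endo_scale = 1, height = 10, n_axial = 4L,
                       n_theta = 20L) {
  a0 <- endo_scale * spec$lvid / 2
  b0 <- a0 * spec$eccentricity
  r1 <- spec$lvot_radius
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  vs <- seq(0, 1, length.out = n_axial + 1)
  tilt <- spec$lvot_tilt * pi / 180
  pts <- lapply(vs, function(v) {
    a <- (1 - v) * a0 + v * r1
    b <- (1 - v) * b0 + v * r1
    z <- -v * height
    p <- cbind(a * cos(th), b * sin(th), z)
    if (tilt != 0 && v > 0) {
      ## rotate the section about the basal rim y-axis, blending with v
      ang <- tilt * v
      cx <- cos(ang); sx <- sin(ang)
      p <- cbind(p[, 1] * cx + p[, 3] * sx, p[, 2],
                 -p[, 1] * sx + p[, 3] * cx)
    }
    p
  })
  nodes <- do.call(rbind, pts)
  nid <- function(iv, it) 1L + (it %% n_theta) + n_theta * iv
  tris <- NULL
  for (iv in 0:(n_axial - 1)) for (it in 0:(n_theta - 1)) {
    tris <- rbind(tris,
                  c(nid(iv, it), nid(iv, it + 1), nid(iv + 1, it)),
                  c(nid(iv + 1, it), nid(iv, it + 1), nid(iv + 1, it + 1)))
  }
  list(nodes = nodes, tris = tris,
       outlet_ring = (n_theta * n_axial + 1L):(n_theta * (n_axial + 1L)))
}

## Aortic root leaflets ------------------------------------------------------

#' Leaflet parameter card
#'
#' @param R aortic root radius (mm).
#' @param H leaflet height (mm).
#' @param a coaptation-height shape factor (dimensionless, 0 < a < 1).
#' @param k logarithmic guide-curve sharpness (dimensionless, > 0).
#' @return an object of class `leaflet_spec`.
#' @export
leaflet_spec <- function(R = 12, H = 14, a = 0.4, k = 3) {
  stopifnot(R > 0, H > 0, a > 0, a < 1, k > 0)
  structure(list(R = R, H = H, a = a, k = k), class = "leaflet_spec")
}

#' Parametric aortic root with three leaflets
#'
#' Divides the root into three 120-degree sectors. Within a sector the
#' attachment curve lies on the cylinder of radius `R` with height following a
#' logarithmic guide `z(w) = H * (1 - log(1 + k (1-|w|)) / log(1 + k))`
#' (commissures at `z = H`, belly nadir at `z = 0`); the free edge runs from
#' the commissures to a central coaptation point at height `a * H`. Leaflets 2
#' and 3 are exact 120-degree rotations of leaflet 1.
#'
#' @param spec a [leaflet_spec()].
#' @param n_arc,n_span surface resolution along the arc and attachment-to-free
#'   edge directions.
#' @return list of three leaflet surfaces (`nodes`, `tris`,
#'   `attachment_idx`, `free_edge_idx`) and the root-wall cylinder surface.
#' @export
build_aortic_root <- function(spec, n_arc = 24L, n_span = 8L) {
  stopifnot(inherits(spec, "leaflet_spec"))
  w <- seq(-1, 1, length.out = n_arc + 1)
  v <- seq(0, 1, length.out = n_span + 1)
  phi <- w * pi / 3
  z_att <- spec$H * (1 - log(1 + spec$k * (1 - abs(w))) / log(1 + spec$k))
  attach <- cbind(spec$R * cos(phi), spec$R * sin(phi), z_att)
  cen <- c(0, 0, spec$a * spec$H)
  comm_hi <- attach[n_arc + 1, ]
  comm_lo <- attach[1, ]
  free_edge <- t(vapply(w, function(wi) {
    cm <- if (wi >= 0) comm_hi else comm_lo
    (1 - abs(wi)) * cen + abs(wi) * cm
  }, numeric(3)))
  nodes <- NULL
  for (iv in seq_along(v))
    nodes <- rbind(nodes, (1 - v[iv]) * attach + v[iv] * free_edge)
  nid <- function(iv, iw) 1L + iw + (n_arc + 1L) * iv
  tris <- NULL
  for (iv in 0:(n_span - 1)) for (iw in 0:(n_arc - 1)) {
    tris <- rbind(tris,
                  c(nid(iv, iw), nid(iv, iw + 1), nid(iv + 1, iw)),
                  c(nid(iv + 1, iw), nid(iv, iw + 1), nid(iv + 1, iw + 1)))
  }
  ## guard against degenerate/self-intersecting construction
  e1 <- nodes[tris[, 2], ] - nodes[tris[, 1], ]
  e2 <- nodes[tris[, 3], ] - nodes[tris[, 1], ]
  areas <- 0.5 * vec3_norm(vec3_cross(e1, e2))
  if (stats::median(areas) <= 0)
    stop("leaflet parameters produce a degenerate surface")
  rot <- function(p, ang) cbind(p[, 1] * cos(ang) - p[, 2] * sin(ang),
                                p[, 1] * sin(ang) + p[, 2] * cos(ang),
                                p[, 3])
  leaf <- function(ang) list(nodes = rot(nodes, ang), tris = tris,
                             attachment_idx = seq_len(n_arc + 1L),
                             free_edge_idx = nid(n_span, 0:n_arc))
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  wall <- list(nodes = rbind(cbind(spec$R * cos(th), spec$R * sin(th), 0),
                             cbind(spec$R * cos(th), spec$R * sin(th),
                                   1.5 * spec$H)))
  list(leaflets = list(leaf(0), leaf(2 * pi / 3), leaf(4 * pi / 3)),
       root_wall = wall, spec = spec)
}

#' Free-edge arc length of a leaflet surface
#' @param leaflet one element of `build_aortic_root()$leaflets`.
#' @return arc length (mm).
#' @export
leaflet_free_edge_length <- function(leaflet) {
  p <- leaflet$nodes[leaflet$free_edge_idx, , drop = FALSE]
  sum(sqrt(rowSums(diff(p)^2)))
}
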
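## File formats, configuration and units --------------------------------------

## unit conversion table: canonical units are mm, ms, kPa, mL, mm^2/ms
.unit_factors <- list(
  length = c(mm = 1, cm = 10, m = 1000),
  time = c(ms = 1, s = 1000),
  pressure = c(kPa = 1, mmHg = 0.133322, Pa = 1e-3, MPa = 1e3),
  volume = c(mL = 1, mm3 = 1e-3, L = 1000)
)

#' Convert between supported units
#'
#' Canonical internal units are mm (length), ms (time), kPa (pressure) and mL
#' (volume); 1 mmHg = 0.133322 kPa exactly by the stored factor. Round trips
#' are identities to floating precision.
#'
#' @param x numeric value(s).
#' @param from,to unit names (e.g. `"mmHg"`, `"kPa"`, `"mm"`, `"m"`).
#' @return converted value(s).
#' @export
convert_units <- function(x, from, to) {
  for (tbl in .unit_factors) {
    if (from %in% names(tbl) && to %in% names(tbl))
      return(x * tbl[[from]] / tbl[[to]])
  }
  stop(sprintf("no conversion path from '%s' to '%s'", from, to))
}

## VTU (XML unstructured grid) ------------------------------------------------

#' Write a mesh to VTU (ASCII XML)
#'
#' Unstructured-grid file with tetrahedral cells (0-based connectivity),
#' optional nodal and element fields, surface tags encoded as FieldData
#' index arrays, and a length-unit tag.
#'
#' @param mesh an `lv_mesh`.
#' @param path output file.
#' @param point_data named list of nodal vectors (or n x 3 matrices).
#' @param cell_data named list of per-element vectors (or m x 3 matrices).
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, point_data = list(),
                           cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  num <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  da <- function(name, x, comp = 1)
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">%s</DataArray>',
            name, comp, num(if (is.matrix(x)) as.vector(t(x)) else x))
  fields <- function(lst) paste(vapply(names(lst), function(nm) {
    x <- lst[[nm]]
    da(nm, x, if (is.matrix(x)) ncol(x) else 1)
  }, character(1)), collapse = "\n")
  surf_fd <- paste(vapply(names(mesh$surfaces), function(nm)
    sprintf('<DataArray type="Int64" Name="surface:%s" NumberOfComponents="3" format="ascii" NumberOfTuples="%d">%s</DataArray>',
            nm, nrow(mesh$surfaces[[nm]]),
            paste(as.vector(t(mesh$surfaces[[nm]] - 1L)), collapse = " ")),
    character(1)), collapse = "\n")
  reg_fd <- paste(vapply(names(mesh$regions), function(nm)
    sprintf('<DataArray type="Int64" Name="region:%s" format="ascii" NumberOfTuples="%d">%s</DataArray>',
            nm, length(mesh$regions[[nm]]),
            paste(mesh$regions[[nm]] - 1L, collapse = " ")),
    character(1)), collapse = "\n")
  xml <- sprintf(
    '<?xml version="1.0"?>
<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">
<UnstructuredGrid>
<FieldData>
<DataArray type="String" Name="length_unit" format="ascii">%s</DataArray>
%s
%s
</FieldData>
<Piece NumberOfPoints="%d" NumberOfCells="%d">
<Points>
%s
</Points>
<Cells>
<DataArray type="Int64" Name="connectivity" format="ascii">%s</DataArray>
<DataArray type="Int64" Name="offsets" format="ascii">%s</DataArray>
<DataArray type="UInt8" Name="types" format="ascii">%s</DataArray>
</Cells>
<PointData>
%s
</PointData>
<CellData>
%s
</CellData>
</Piece>
</UnstructuredGrid>
</VTKFile>',
    mesh$units, surf_fd, reg_fd, n, m,
    da("Points", mesh$nodes, 3),
    paste(as.vector(t(mesh$tets - 1L)), collapse = " "),
    paste(seq_len(m) * 4L, collapse = " "),
    paste(rep(10L, m), collapse = " "),
    fields(point_data), fields(cell_data))
  writeLines(xml, path)
  invisible(path)
}

#' Read a VTU mesh written by [write_mesh_vtu()]
#'
#' Restores nodes, tetrahedral connectivity, surface and region tags and the
#' length unit; coordinates in meters are converted to mm using the unit tag.
#'
#' @param path VTU file.
#' @return an `lv_mesh`.
#' @export
read_mesh_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  if (!length(xml2::xml_find_all(doc, "//UnstructuredGrid")))
    stop("not a VTU unstructured grid file")
  get_arr <- function(xpath) {
    nd <- xml2::xml_find_first(doc, xpath)
    if (inherits(nd, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  unit_nd <- xml2::xml_find_first(doc,
    '//FieldData/DataArray[@Name="length_unit"]')
  units <- if (inherits(unit_nd, "xml_missing")) "mm" else
    trimws(xml2::xml_text(unit_nd))
  pts <- get_arr('//Points/DataArray')
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  if (units != "mm") {
    nodes <- convert_units(nodes, units, "mm")
    units <- "mm"
  }
  conn <- get_arr('//Cells/DataArray[@Name="connectivity"]')
  tets <- matrix(as.integer(conn), ncol = 4, byrow = TRUE) + 1L
  surf_nodes <- xml2::xml_find_all(doc,
    '//FieldData/DataArray[starts-with(@Name, "surface:")]')
  surfaces <- list()
  for (nd in surf_nodes) {
    nm <- sub("^surface:", "", xml2::xml_attr(nd, "Name"))
    v <- scan(text = xml2::xml_text(nd), quiet = TRUE)
    surfaces[[nm]] <- matrix(as.integer(v), ncol = 3, byrow = TRUE) + 1L
  }
  reg_nodes <- xml2::xml_find_all(doc,
    '//FieldData/DataArray[starts-with(@Name, "region:")]')
  regions <- list()
  for (nd in reg_nodes) {
    nm <- sub("^region:", "", xml2::xml_attr(nd, "Name"))
    regions[[nm]] <- as.integer(scan(text = xml2::xml_text(nd),
                                     quiet = TRUE)) + 1L
  }
  lv_mesh(nodes, tets, surfaces, regions, units = units)
}

## STL (ASCII) -----------------------------------------------------------------

#' Write a triangulated surface to ASCII STL
#' @param tris k x 3 triangle node indices.
#' @param nodes node coordinates.
#' @param path output file.
#' @param name solid name.
#' @return `path`, invisibly.
#' @export
write_surface_stl <- function(tris, nodes, path, name = "surface") {
  v1 <- nodes[tris[, 1], , drop = FALSE]
  v2 <- nodes[tris[, 2], , drop = FALSE]
  v3 <- nodes[tris[, 3], , drop = FALSE]
  nrm <- vec3_normalize(vec3_cross(v2 - v1, v3 - v1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(tris))) {
    writeLines(c(
      sprintf("facet normal %.9e %.9e %.9e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "  outer loop",
      sprintf("    vertex %.9e %.9e %.9e", v1[i, 1], v1[i, 2], v1[i, 3]),
      sprintf("    vertex %.9e %.9e %.9e", v2[i, 1], v2[i, 2], v2[i, 3]),
      sprintf("    vertex %.9e %.9e %.9e", v3[i, 1], v3[i, 2], v3[i, 3]),
      "  endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an ASCII STL surface
#'
#' Returns the raw triangle soup (no tags). Surfaces read this way carry no
#' endo/epi tags and are rejected by operations that need them.
#'
#' @param path STL file.
#' @return list with `nodes` (deduplicated vertices) and `tris`.
#' @export
read_surface_stl <- function(path) {
  ln <- readLines(path)
  vx <- grep("^\\s*vertex", ln, value = TRUE)
  if (!length(vx)) stop("no vertices found; not an ASCII STL file?")
  v <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(round(v, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  nodes <- v[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  list(nodes = nodes, tris = tris)
}

## Gmsh MSH v2 (ASCII) ---------------------------------------------------------

#' Read a Gmsh MSH (version 2 ASCII) tetrahedral mesh
#'
#' Supports `$Nodes` / `$Elements` with element type 4 (tets); 2D elements
#' (type 2, triangles) are collected per physical tag as surfaces.
#'
#' @param path MSH file.
#' @param surface_names optional named map from physical tag (character) to
#'   surface name.
#' @return an `lv_mesh`.
#' @export
read_mesh_msh <- function(path, surface_names = NULL) {
  ln <- readLines(path)
  sec <- function(tag) {
    i0 <- which(ln == paste0("$", tag)) + 1L
    i1 <- which(ln == paste0("$End", tag)) - 1L
    if (!length(i0) || !length(i1)) stop(sprintf("missing $%s section", tag))
    ln[(i0 + 1L):i1]  # skip the count line
  }
  nd <- do.call(rbind, lapply(strsplit(sec("Nodes"), "\\s+"), as.numeric))
  nodes <- nd[order(nd[, 1]), 2:4, drop = FALSE]
  el <- lapply(strsplit(sec("Elements"), "\\s+"), as.numeric)
  tets <- do.call(rbind, lapply(el, function(r) {
    if (r[2] == 4) utils::tail(r, 4) else NULL
  }))
  if (is.null(tets)) stop("no tetrahedra in MSH file")
  surfaces <- list()
  tri_rows <- Filter(function(r) r[2] == 2, el)
  if (length(tri_rows)) {
    tags <- vapply(tri_rows, function(r) r[4], numeric(1))
    for (tg in unique(tags)) {
      tris <- do.call(rbind, lapply(tri_rows[tags == tg], utils::tail, 3))
      nm <- if (!is.null(surface_names) &&
                as.character(tg) %in% names(surface_names))
        surface_names[[as.character(tg)]] else paste0("physical_", tg)
      surfaces[[nm]] <- matrix(as.integer(tris), ncol = 3)
    }
  }
  lv_mesh(nodes, matrix(as.integer(tets), ncol = 4), surfaces)
}

## Configuration ---------------------------------------------------------------

## full default parameter document (the model constants)
#' @noRd
default_config_list <- function() {
  list(
    case = 1,
    geometry = list(n_axial = 12, n_theta = 20, n_trans = 2),
    fibers = list(theta_epi_max_deg = -60, theta_end_max_deg = 60,
                  beta_method = "distance"),
    ep = list(alpha = 0.01, c_gain = 8, b = 0.15, gamma = 0.002,
              mu1 = 0.2, mu2 = 0.3, Gs = 1, phi_s = 0.6,
              d_fiber_mm2_ms = 0.6, d_sheet_normal_mm2_ms = 0.2,
              d_transmural_mm2_ms = 0.1,
              Phi_rest_mV = -80, Phi_peak_mV = 20,
              tau0 = 0.3, t0_ms = 0, t1_ms = 30, t_alpha_ms = 30,
              t_beta_ms = 12.9),
    active_stress = list(k_kPa_mV = 3, eps0_per_ms = 0.008,
                         eps1_per_ms = 0.08, zeta_per_mV = 0.1,
                         Phi_t_mV = -20, eta1 = 0.1, eta2 = 0.2, eta3 = 0.6),
    myocardium = list(mu_kPa = 500, lambda_kPa = 200, k1_kPa = 1.685,
                      k2 = 15.779, kappa = 0),
    leaflet = list(C10_kPa = 3.47, C01 = 30.03, k1_kPa = 74.5, k2 = 63.19,
                   kappa = 0.2),
    windkessel = list(C_mL_mmHg = 3.128, Rp_mmHg_s_mL = 0.6652,
                      Rc_mmHg_s_mL = 0.0914, P_dia_mmHg = 80,
                      P_sys_mmHg = 120),
    blood = list(density_kg_m3 = 1060, viscosity_lv_Pa_s = 0.004,
                 viscosity_valve_Pa_s = 0.0035),
    coupling = list(duration_ms = 220, dt_ms = 1, dt_min_s = 1e-6,
                    dt_max_s = 1e-3, subit_tol = 1e-4, max_subit = 20,
                    ed_pressure_mmHg = 10)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON-compatible YAML) configuration, fills in the full
#' default parameter document (the model constants: conductivities
#' 0.6/0.2/0.1 mm^2/ms, basal helix angles -60/+60 degrees, Windkessel
#' constants, material cards, blood density and viscosity recorded for
#' documentation), converts tagged pressure entries given in mmHg to kPa, and
#' rejects unknown keys and out-of-range values listing all problems at once.
#'
#' @param path YAML file, or `NULL`/nonexistent-empty for pure defaults.
#' @return nested named list with all parameters resolved.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config_list()
  user <- if (is.null(path)) list() else {
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) list() else raw
  }
  problems <- character(0)
  merge <- function(def, usr, prefix = "") {
    for (nm in names(usr)) {
      if (!nm %in% names(def)) {
        problems <<- c(problems, sprintf("unknown key: %s%s", prefix, nm))
        next
      }
      if (is.list(def[[nm]]) && is.list(usr[[nm]])) {
        def[[nm]] <- merge(def[[nm]], usr[[nm]], paste0(prefix, nm, "."))
      } else def[[nm]] <- usr[[nm]]
    }
    def
  }
  cfg <- merge(defaults, user)
  ## validation
  with(cfg$myocardium, {
    if (kappa < 0 || kappa > 1 / 3)
      problems <<- c(problems, "myocardium.kappa outside [0, 1/3]")
    if (mu_kPa <= 0 || k1_kPa <= 0 || k2 <= 0)
      problems <<- c(problems, "myocardium moduli must be positive")
  })
  with(cfg$ep, {
    if (alpha <= 0 || alpha >= 1)
      problems <<- c(problems, "ep.alpha outside (0, 1)")
    if (d_fiber_mm2_ms <= 0 || d_sheet_normal_mm2_ms <= 0 ||
        d_transmural_mm2_ms <= 0)
      problems <<- c(problems, "ep conductivities must be positive")
  })
  with(cfg$windkessel, {
    if (C_mL_mmHg <= 0 || Rp_mmHg_s_mL <= 0 || Rc_mmHg_s_mL <= 0)
      problems <<- c(problems, "windkessel constants must be positive")
  })
  with(cfg$coupling, {
    if (subit_tol <= 0) problems <<- c(problems, "coupling.subit_tol <= 0")
    if (dt_min_s > dt_max_s)
      problems <<- c(problems, "coupling.dt_min_s exceeds dt_max_s")
  })
  if (length(problems))
    stop("configuration problems:\n  ", paste(problems, collapse = "\n  "))
  cfg
}

#' Pressure entry in kPa from a config value given in mmHg
#' @param x_mmHg pressure (mmHg).
#' @return pressure (kPa).
#' @export
pressure_kPa <- function(x_mmHg) convert_units(x_mmHg, "mmHg", "kPa")

## Run manifest ----------------------------------------------------------------

#' Write a reproducibility manifest for a run directory
#'
#' Records a digest of the configuration, the package version, input file
#' digests and seeds, sufficient to re-execute the run deterministically.
#'
#' @param dir run directory.
#' @param config configuration list (as from [load_config()] or
#'   [sim_config()]).
#' @param inputs character vector of input file paths to digest.
#' @param seed integer seed(s).
#' @return manifest list, invisibly; written as `manifest.yaml` in `dir`.
#' @export
write_run_manifest <- function(dir, config, inputs = character(0), seed = 1L) {
  digest_of <- function(obj) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(obj, f, version = 2)
    unname(tools::md5sum(f))
  }
  man <- list(
    package_version = as.character(utils::packageVersion("lvemsim")),
    config_digest = digest_of(config),
    input_digests = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    seed = seed,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(man)
}
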
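## Electrophysiology: two-variable phenomenological model + monodomain --------

#' Electrophysiology parameter set
#'
#' Two-variable phenomenological excitation model (dimensionless potential
#' `phi`, recovery `r`) with a stretch-activated current, dimensional mapping
#' of the potential, apicobasal time scaling, and monodomain conductivities.
#'
#' The kinetic constants default to the standard published values of this
#' model family (`alpha` excitation threshold, `c` kinetics gain, `b` plateau
#' shift, `gamma, mu1, mu2` recovery kinetics). Conductivities are along /
#' across fiber / transmural in mm^2/ms. The affine potential map
#' `Phi = phi * beta_phi + delta_phi` (mV) is calibrated against the -80 mV
#' resting and +20 mV peak anchors by [calibrate_potential_mapping()]. Time
#' scaling: dimensionless tau relates to milliseconds through
#' `t = beta_t * tau` with `beta_t = t_beta (1 - tau0 (t_a - t0)/(t1 - t0))`
#' and activation time `t_a = t_alpha (1 - Z/Z_apex)`.
#'
#' @param alpha excitation threshold (dimensionless, 0 < alpha < 1).
#' @param c_gain kinetics gain (dimensionless).
#' @param b plateau shift (dimensionless).
#' @param gamma,mu1,mu2 recovery kinetics (dimensionless).
#' @param Gs stretch-current gain (dimensionless).
#' @param phi_s stretch-current potential threshold (dimensionless).
#' @param d_fiber,d_sheet_normal,d_transmural conductivities (mm^2/ms):
#'   along the fiber, across the fiber in the wall plane, through the wall.
#' @param delta_phi,beta_phi potential map offset and scale (mV).
#' @param tau0,t0,t1,t_alpha,t_beta time-scaling tuning parameters (ms except
#'   the dimensionless `tau0`).
#' @param chi_m,Cm surface-to-volume ratio (1/m) and membrane capacitance
#'   (F/m^2); recorded for documentation of the dimensional scaling, the
#'   solver works with the conductivities above directly.
#' @return an object of class `ep_params`.
#' @export
ep_params <- function(alpha = 0.01, c_gain = 8, b = 0.15, gamma = 0.002,
                      mu1 = 0.2, mu2 = 0.3, Gs = 1, phi_s = 0.6,
                      d_fiber = 0.6, d_sheet_normal = 0.2,
                      d_transmural = 0.1,
                      delta_phi = -80, beta_phi = 100,
                      tau0 = 0.3, t0 = 0, t1 = 30, t_alpha = 30,
                      t_beta = 12.9, chi_m = 1, Cm = 1) {
  stopifnot(alpha > 0, alpha < 1, beta_phi > 0,
            d_fiber > 0, d_sheet_normal > 0, d_transmural > 0)
  structure(list(alpha = alpha, c_gain = c_gain, b = b, gamma = gamma,
                 mu1 = mu1, mu2 = mu2, Gs = Gs, phi_s = phi_s,
                 d_fiber = d_fiber, d_sheet_normal = d_sheet_normal,
                 d_transmural = d_transmural,
                 delta_phi = delta_phi, beta_phi = beta_phi,
                 tau0 = tau0, t0 = t0, t1 = t1, t_alpha = t_alpha,
                 t_beta = t_beta, chi_m = chi_m, Cm = Cm),
            class = "ep_params")
}

#' Excitation-induced ionic current (dimensionless)
#'
#' `I_e = c phi (phi - alpha)(phi - 1) + r phi`: cubic fast activation with
#' threshold `alpha` plus the slow repolarizing current `r phi`.
#'
#' @param phi dimensionless potential.
#' @param r recovery variable.
#' @param params an [ep_params()].
#' @return current (dimensionless), same shape as `phi`.
#' @export
ionic_current_electrical <- function(phi, r, params) {
  params$c_gain * phi * (phi - params$alpha) * (phi - 1) + r * phi
}

#' Stretch-activated (mechano-electrical feedback) current
#'
#' `I_m = theta_gate Gs (lambda - 1)(phi - phi_s)`, active only above the
#' activation threshold `phi_s` and, when a window gate is supplied, only
#' inside the active-response time window.
#'
#' @param lambda_f local fiber stretch (> 0).
#' @param phi dimensionless potential.
#' @param params an [ep_params()].
#' @param gate optional 0/1 active-response window; defaults to the threshold
#'   indicator `phi > phi_s`.
#' @return current (dimensionless).
#' @export
stretch_current <- function(lambda_f, phi, params, gate = NULL) {
  stopifnot(all(lambda_f > 0))
  open <- phi > params$phi_s
  if (!is.null(gate)) open <- open & (gate > 0)
  ifelse(open, params$Gs * (lambda_f - 1) * (phi - params$phi_s), 0)
}

#' Recovery-variable kinetics
#'
#' `dr/dtau = (gamma + mu1 r / (mu2 + phi)) (-r - c phi (phi - b - 1))`.
#'
#' @inheritParams ionic_current_electrical
#' @return time derivative of `r` (per unit tau).
#' @export
recovery_rhs <- function(phi, r, params) {
  (params$gamma + params$mu1 * r / (params$mu2 + phi)) *
    (-r - params$c_gain * phi * (phi - params$b - 1))
}

#' Calibrate the affine potential mapping
#'
#' Solves the two-point condition `Phi(phi_rest) = Phi_rest`,
#' `Phi(phi_max) = Phi_peak` for the offset and scale of
#' `Phi = phi beta_phi + delta_phi`.
#'
#' @param phi_rest,phi_max dimensionless resting and peak potentials
#'   (`phi_max > phi_rest`).
#' @param Phi_rest,Phi_peak dimensional anchors (mV); defaults are the
#'   physiological -80 mV resting and +20 mV peak values.
#' @return list with `delta_phi` and `beta_phi` (mV).
#' @export
calibrate_potential_mapping <- function(phi_rest, phi_max, Phi_rest = -80,
                                        Phi_peak = 20) {
  if (phi_max <= phi_rest) stop("phi_max must exceed phi_rest")
  beta_phi <- (Phi_peak - Phi_rest) / (phi_max - phi_rest)
  delta_phi <- Phi_rest - beta_phi * phi_rest
  list(delta_phi = delta_phi, beta_phi = beta_phi)
}

#' Map dimensionless potential to millivolts
#' @param phi dimensionless potential.
#' @param params an [ep_params()].
#' @return potential in mV.
#' @export
map_potential <- function(phi, params) phi * params$beta_phi + params$delta_phi

#' Apicobasal activation-time field and local time scale
#'
#' `t_a = t_alpha (1 - Z/Z_apex)` (regions that depolarize last repolarize
#' first) and `beta_t = t_beta (1 - tau0 (t_a - t0)/(t1 - t0))`.
#'
#' @param Z apicobasal coordinate(s), base at 0, apex at `z_apex`.
#' @param z_apex apex coordinate (mm).
#' @param params an [ep_params()].
#' @return `activation_time_field`: t_a (ms); `time_scale`: beta_t (ms).
#' @export
activation_time_field <- function(Z, z_apex, params) {
  if (any(Z < -1e-9) || any(Z > z_apex * (1 + 1e-9)))
    stop("Z outside [0, z_apex]")
  params$t_alpha * (1 - Z / z_apex)
}

#' @rdname activation_time_field
#' @param t_a activation time(s) (ms).
#' @export
time_scale <- function(t_a, params) {
  if (params$t1 == params$t0) stop("t1 must differ from t0")
  params$t_beta * (1 - params$tau0 * (t_a - params$t0) /
                     (params$t1 - params$t0))
}

#' Single-cell action potential
#'
#' Integrates the two-variable kinetics (dimensionless time tau) with an
#' optional rectangular stimulus current or a non-resting initial potential,
#' and maps the potential to mV. A suprathreshold stimulus produces one action
#' potential: upstroke, plateau, repolarization back to rest.
#'
#' @param params an [ep_params()].
#' @param duration integration window in tau units.
#' @param dt output step in tau units.
#' @param stim_amp,stim_start,stim_dur rectangular stimulus (dimensionless
#'   current, tau units).
#' @param phi0,r0 initial state.
#' @param lambda_f constant fiber stretch for the feedback current (1 = none).
#' @return data.frame with `tau`, `t` (ms, using the cell-level time scale at
#'   `t_a = t0`), `phi`, `r`, `Phi` (mV); attributes `phi_max`, `phi_rest`.
#' @export
simulate_single_cell <- function(params = ep_params(), duration = 120,
                                 dt = 0.02, stim_amp = 0, stim_start = 1,
                                 stim_dur = 1, phi0 = 0, r0 = 0,
                                 lambda_f = 1) {
  rhs <- function(tau, y, p) {
    stim <- if (stim_amp != 0 && tau >= stim_start &&
                tau <= stim_start + stim_dur) stim_amp else 0
    ie <- ionic_current_electrical(y[1], y[2], params)
    im <- stretch_current(lambda_f, y[1], params)
    list(c(-ie - im + stim, recovery_rhs(y[1], y[2], params)))
  }
  out <- deSolve::ode(c(phi = phi0, r = r0), seq(0, duration, by = dt), rhs,
                      NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  if (any(!is.finite(out)))
    stop("single-cell integration diverged; reduce dt or stimulus amplitude")
  beta_t <- time_scale(params$t0, params)
  res <- data.frame(tau = out[, 1], t = out[, 1] * beta_t,
                    phi = out[, 2], r = out[, 3],
                    Phi = map_potential(out[, 2], params))
  attr(res, "phi_max") <- max(res$phi)
  attr(res, "phi_rest") <- 0
  res
}

## Conductivity tensors -------------------------------------------------------

#' Per-element monodomain conductivity tensors
#'
#' Spectral construction from the fiber triad: `d_fiber` along the fiber,
#' `d_sheet_normal` across the fiber in the wall plane, `d_transmural`
#' through the wall. Elements flagged isotropic (apex cylinder) receive the
#' isotropic mean of the three eigenvalues.
#'
#' @param fibers a `fiber_field`.
#' @param params an [ep_params()].
#' @return m x 9 row-wise symmetric positive-definite tensors (mm^2/ms).
#' @export
conductivity_tensors <- function(fibers, params = ep_params()) {
  D <- params$d_fiber * t9_outer(fibers$fiber) +
    params$d_sheet_normal * t9_outer(fibers$sheet_normal) +
    params$d_transmural * t9_outer(fibers$sheet)
  if (any(fibers$isotropic_mask)) {
    diso <- mean(c(params$d_fiber, params$d_sheet_normal,
                   params$d_transmural))
    D[fibers$isotropic_mask, ] <- rep(diso * c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                                      each = sum(fibers$isotropic_mask))
  }
  D
}

## Monodomain solver ----------------------------------------------------------

#' Build the semi-implicit monodomain operator
#'
#' Assembles the P1 stiffness matrix for the anisotropic conductivity, the
#' lumped mass vector, the nodal time-scale field, and the Cholesky factor of
#' the implicit-diffusion operator `M/dt + K` (zero normal current on all
#' untagged/epicardial boundaries is the natural boundary condition).
#'
#' @param mesh an `lv_mesh`.
#' @param fibers a `fiber_field` for the same mesh.
#' @param params an [ep_params()].
#' @param dt time step (ms).
#' @param monotone enforce an M-matrix stiffness (positive off-diagonal
#'   entries lumped into the diagonal, preserving row sums). On anisotropic
#'   tetrahedral meshes the plain P1 stiffness violates the discrete maximum
#'   principle and lets the potential overshoot its physical range near sharp
#'   fronts; the lumped variant restores the discrete maximum principle at the
#'   cost of some crosswind smearing. Default TRUE.
#' @return an `ep_operator` list reused across steps.
#' @export
ep_operator <- function(mesh, fibers, params = ep_params(), dt = 0.25,
                        monotone = TRUE) {
  gr <- fem_gradients(mesh)
  D <- conductivity_tensors(fibers, params)
  K <- fem_stiffness(mesh, gr, D)
  if (monotone) K <- mmatrix_lump(K)
  Mv <- fem_lumped_mass(mesh, gr)
  z_apex <- max(mesh$nodes[, 3])
  zz <- pmin(pmax(mesh$nodes[, 3], 0), z_apex)
  beta_t <- time_scale(activation_time_field(zz, z_apex, params), params)
  if (any(beta_t <= 0)) stop("time-scale field must stay positive")
  A <- K + Matrix::Diagonal(x = Mv / dt)
  structure(list(mesh = mesh, fibers = fibers, params = params, dt = dt,
                 K = K, Mv = Mv, beta_t = beta_t,
                 A = Matrix::Cholesky(Matrix::forceSymmetric(A))),
            class = "ep_operator")
}

## Move positive off-diagonal stiffness entries onto the diagonal (row sums
## preserved, so constant fields stay in the kernel); yields an M-matrix and
## hence a discrete maximum principle for the implicit diffusion step.
#' @noRd
mmatrix_lump <- function(K) {
  Kt <- as(K, "TsparseMatrix")
  off <- Kt@i != Kt@j
  pos <- off & Kt@x > 0
  if (!any(pos)) return(K)
  ## add the clipped mass to the diagonal of the source row
  add <- tapply(Kt@x[pos], Kt@i[pos], sum)
  Kt@x[pos] <- 0
  di <- as.integer(names(add))
  diag_idx <- which(Kt@i == Kt@j)
  dmap <- match(di, Kt@i[diag_idx])
  Kt@x[diag_idx[dmap]] <- Kt@x[diag_idx[dmap]] + as.numeric(add)
  Matrix::drop0(as(Kt, "CsparseMatrix"))
}

#' Initial monodomain state
#'
#' @param op an [ep_operator()].
#' @return an `ep_state`: nodal `phi`, `r`, per-node 0/1 `gate` (active
#'   response window), `activation_time` (NA until the 0.5 upward crossing),
#'   elapsed time `t`.
#' @export
ep_state <- function(op) {
  n <- nrow(op$mesh$nodes)
  structure(list(phi = numeric(n), r = numeric(n), gate = numeric(n),
                 activation_time = rep(NA_real_, n), t = 0),
            class = "ep_state")
}

#' Advance the monodomain model one step
#'
#' Semi-implicit step: reaction integrated explicitly (in local tau time via
#' the nodal time-scale field), diffusion implicitly via the prefactorized
#' operator. The uniform resting state is an exact fixed point. Activation
#' times are recorded at the upward 0.5 crossing of `phi`; the active-response
#' window gate opens there and closes at the downward crossing.
#'
#' @param state an `ep_state`.
#' @param op an [ep_operator()].
#' @param lambda_f per-element (or per-node) fiber stretch for the feedback
#'   current; default 1 (no stretch).
#' @param stim_nodes,stim_amp optional stimulus: dimensionless current added
#'   at the given nodes during this step.
#' @return updated `ep_state`.
#' @export
step_monodomain <- function(state, op, lambda_f = 1,
                            stim_nodes = NULL, stim_amp = 0) {
  p <- op$params
  dt <- op$dt
  phi <- state$phi; r <- state$r
  lam <- if (length(lambda_f) == nrow(op$mesh$tets)) {
    ## average element stretch to nodes
    nodal_from_element(op$mesh, lambda_f)
  } else rep(lambda_f, length.out = length(phi))
  ie <- ionic_current_electrical(phi, r, p)
  im <- stretch_current(lam, phi, p, gate = state$gate)
  react <- -(ie + im) / op$beta_t
  if (!is.null(stim_nodes)) react[stim_nodes] <- react[stim_nodes] + stim_amp
  rhs <- op$Mv * (phi / dt + react)
  phi_new <- as.numeric(Matrix::solve(op$A, rhs))
  if (any(!is.finite(phi_new)))
    stop("monodomain step diverged; reduce dt")
  r_new <- r + dt * recovery_rhs(phi, r, p) / op$beta_t
  up <- is.na(state$activation_time) & phi_new >= 0.5
  at <- state$activation_time
  at[up] <- state$t + dt
  gate <- state$gate
  gate[up] <- 1
  gate[gate > 0 & phi_new < 0.5 & !up] <- 0
  structure(list(phi = phi_new, r = r_new, gate = gate,
                 activation_time = at, t = state$t + dt),
            class = "ep_state")
}

#' @noRd
nodal_from_element <- function(mesh, x_el) {
  n <- nrow(mesh$nodes)
  acc <- numeric(n); cnt <- numeric(n)
  for (a in 1:4) {
    s <- tapply(x_el, mesh$tets[, a], sum)
    id <- as.integer(names(s))
    acc[id] <- acc[id] + as.numeric(s)
    c2 <- tapply(rep(1, length(x_el)), mesh$tets[, a], sum)
    cnt[id] <- cnt[id] + as.numeric(c2)
  }
  cnt[cnt == 0] <- 1
  acc / cnt
}

#' Default stimulus node set
#'
#' Implements the endocardial activation protocol: early foci on the septal
#' and apical endocardium, realized as endocardial nodes inside a basal
#' rectangular patch (one azimuthal sector near the base) plus an apical cap.
#'
#' @param mesh an `lv_mesh` with an `endocardium` tag.
#' @param basal_fraction apicobasal extent of the basal patch (fraction of the
#'   long axis measured from the base).
#' @param sector_deg azimuthal width of the basal patch (degrees).
#' @param apical_fraction apicobasal extent of the apical patch.
#' @return integer node indices.
#' @export
stimulus_nodes <- function(mesh, basal_fraction = 0.2, sector_deg = 90,
                           apical_fraction = 0.12) {
  en <- unique(as.vector(mesh$surfaces$endocardium))
  z <- mesh$nodes[en, 3]
  z_apex <- max(mesh$nodes[, 3])
  th <- atan2(mesh$nodes[en, 2], mesh$nodes[en, 1])
  basal <- z <= basal_fraction * z_apex & abs(th) <= sector_deg * pi / 360
  apical <- z >= (1 - apical_fraction) * z_apex
  en[basal | apical]
}

#' Run a monodomain activation-recovery simulation
#'
#' Semi-implicit time stepping with either an initial-condition stimulus (a
#' potential patch, the default: stimulated nodes start at the given mV value)
#' or a brief current pulse of 2-3 ms. Records per-step summary statistics and
#' the activation-time map.
#'
#' @param mesh,fibers,params,dt see [ep_operator()].
#' @param duration total simulated time (ms).
#' @param stim_nodes stimulated node set (default [stimulus_nodes()]).
#' @param mode `"initial_patch"` (potential patch at t = 0) or `"pulse"`
#'   (current stimulus over `pulse_ms`).
#' @param patch_mV initial patch potential (mV) for `initial_patch`.
#' @param pulse_ms,pulse_amp pulse duration (ms) and dimensionless amplitude.
#' @param lambda_f constant or per-element fiber stretch (feedback current).
#' @param record_fields store the full nodal potential every `record_every`
#'   steps.
#' @param record_every field recording cadence (steps).
#' @return list with `summary` (data.frame: t, phi mean/min/max, Phi
#'   mean/min/max), `activation_time`, `state` (final), optionally `fields`.
#' @export
run_monodomain <- function(mesh, fibers, params = ep_params(), duration = 500,
                           dt = 0.25, stim_nodes = NULL,
                           mode = c("initial_patch", "pulse"),
                           patch_mV = -10, pulse_ms = 2.5, pulse_amp = 2,
                           lambda_f = 1, record_fields = FALSE,
                           record_every = 20L) {
  mode <- match.arg(mode)
  op <- ep_operator(mesh, fibers, params, dt)
  st <- ep_state(op)
  if (is.null(stim_nodes)) stim_nodes <- stimulus_nodes(mesh)
  if (mode == "initial_patch")
    st$phi[stim_nodes] <- (patch_mV - params$delta_phi) / params$beta_phi
  nstep <- ceiling(duration / dt)
  out <- matrix(NA_real_, nstep + 1, 7,
                dimnames = list(NULL, c("t", "phi_mean", "phi_min", "phi_max",
                                        "Phi_mean", "Phi_min", "Phi_max")))
  rec <- function(k, s) {
    Phi <- map_potential(s$phi, params)
    out[k, ] <<- c(s$t, mean(s$phi), min(s$phi), max(s$phi),
                   mean(Phi), min(Phi), max(Phi))
  }
  rec(1, st)
  fields <- if (record_fields) list(map_potential(st$phi, params)) else NULL
  for (k in seq_len(nstep)) {
    pulse_on <- mode == "pulse" && st$t < pulse_ms
    st <- step_monodomain(st, op, lambda_f = lambda_f,
                          stim_nodes = if (pulse_on) stim_nodes,
                          stim_amp = if (pulse_on) pulse_amp else 0)
    rec(k + 1, st)
    if (record_fields && k %% record_every == 0L)
      fields <- c(fields, list(map_potential(st$phi, params)))
  }
  list(summary = as.data.frame(out), activation_time = st$activation_time,
       state = st, fields = fields, params = params)
}

#' Uniform fiber field (testing and cable studies)
#'
#' Builds an orthonormal fiber/sheet/sheet-normal triad aligned with a given
#' fiber axis, replicated over `m` elements.
#'
#' @param m number of elements.
#' @param fiber_axis fiber direction (any nonzero 3-vector).
#' @return a `fiber_field`.
#' @export
uniform_fiber_field <- function(m, fiber_axis = c(1, 0, 0)) {
  a <- fiber_axis / sqrt(sum(fiber_axis^2))
  helper <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  s <- helper - sum(helper * a) * a
  s <- s / sqrt(sum(s^2))
  n <- c(a[2] * s[3] - a[3] * s[2], a[3] * s[1] - a[1] * s[3],
         a[1] * s[2] - a[2] * s[1])
  structure(list(fiber = matrix(a, m, 3, byrow = TRUE),
                 sheet = matrix(s, m, 3, byrow = TRUE),
                 sheet_normal = matrix(n, m, 3, byrow = TRUE),
                 theta = numeric(m), isotropic_mask = logical(m)),
            class = "fiber_field")
}

#' Conduction velocity along a cable
#'
#' Utility for convergence and anisotropy studies: runs the monodomain model
#' on a thin bar with uniform fiber direction, stimulated at one end, and
#' estimates the front speed from activation times at two probe planes.
#'
#' @param length_mm,width_mm bar dimensions.
#' @param nx axial resolution (cells).
#' @param fiber_axis unit vector, the uniform fiber direction.
#' @param params an [ep_params()].
#' @param dt step (ms).
#' @param probes axial probe fractions (of the bar length).
#' @return speed (mm/ms).
#' @export
cable_speed <- function(length_mm = 40, width_mm = 1, nx = 100,
                        fiber_axis = c(1, 0, 0), params = ep_params(),
                        dt = 0.05, probes = c(0.4, 0.8)) {
  b <- mesh_box(nx, 1, 1, length_mm, width_mm, width_mm)
  m <- nrow(b$tets)
  ff <- uniform_fiber_field(m, fiber_axis)
  ## uniform time scale for the cable (no apicobasal taper)
  p <- params; p$tau0 <- 0
  stim <- which(b$nodes[, 1] < 1e-9)
  run <- run_monodomain(b, ff, p, duration = length_mm / 0.2, dt = dt,
                        stim_nodes = stim, mode = "pulse", pulse_amp = 3,
                        pulse_ms = 2)
  at <- run$activation_time
  xs <- b$nodes[, 1]
  t_at <- function(fr) {
    sel <- abs(xs - fr * length_mm) < length_mm / (2 * nx)
    mean(at[sel], na.rm = TRUE)
  }
  t1 <- t_at(probes[1]); t2 <- t_at(probes[2])
  if (!is.finite(t1) || !is.finite(t2) || t2 <= t1)
    stop("front did not traverse both probes; increase duration or stimulus")
  (probes[2] - probes[1]) * length_mm / (t2 - t1)
}
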
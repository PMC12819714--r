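## Staggered systolic coupling driver ------------------------------------------

#' Simulation configuration for a systolic run
#'
#' Bundles the case card, resolution, time stepping, physics parameter sets
#' and coupling controls of one staggered systolic simulation
#' (electrophysiology, active stress, mechanics, 0D cavity/afterload).
#'
#' @param case_id LV case (1..5) or an [lv_case_spec()].
#' @param duration simulated time (ms).
#' @param dt coupling/mechanics step (ms); must lie in the adaptive band
#'   `[dt_min, dt_max]`.
#' @param dt_min,dt_max admissible step bounds (ms).
#' @param ep_substeps monodomain substeps per coupling step.
#' @param n_axial,n_theta,n_trans mesh resolution (coarse by design).
#' @param ep an [ep_params()] (potential map recalibrated at run start).
#' @param act an [active_stress_params()].
#' @param mat a material card (default [material_myocardium()]).
#' @param wk a [windkessel_params()].
#' @param ed_pressure end-diastolic cavity pressure (mmHg) used for the
#'   initialization equilibrium.
#' @param subit_tol relative L2 subiteration tolerance of the staggered loop.
#' @param max_subit subiteration bound per step.
#' @param stimulus `"patch"` (endocardial septal/apical initial patch) or
#'   `"none"`.
#' @param mef enable stretch feedback into the monodomain reaction.
#' @param seed RNG seed recorded in the config (the solver chain is
#'   deterministic; the seed governs any auxiliary sampling).
#' @param record_every trace cadence (steps).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(case_id = 1, duration = 220, dt = 1,
                       dt_min = 1e-3, dt_max = 1, ep_substeps = 2L,
                       n_axial = 7L, n_theta = 10L, n_trans = 1L,
                       ep = ep_params(), act = active_stress_params(),
                       mat = material_myocardium(), wk = windkessel_params(),
                       ed_pressure = 10, subit_tol = 1e-4, max_subit = 20L,
                       stimulus = c("patch", "none"), mef = TRUE,
                       seed = 1L, record_every = 1L) {
  stopifnot(subit_tol > 0, dt_min <= dt_max, dt >= dt_min, dt <= dt_max,
            max_subit >= 1)
  spec <- if (inherits(case_id, "lv_case_spec")) case_id else
    lv_case_spec(case_id)
  structure(list(spec = spec, duration = duration, dt = dt, dt_min = dt_min,
                 dt_max = dt_max, ep_substeps = as.integer(ep_substeps),
                 n_axial = n_axial, n_theta = n_theta, n_trans = n_trans,
                 ep = ep, act = act, mat = mat, wk = wk,
                 ed_pressure = ed_pressure, subit_tol = subit_tol,
                 max_subit = as.integer(max_subit),
                 stimulus = match.arg(stimulus), mef = mef,
                 seed = as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

## mmHg <-> kPa
.mmHg_kPa <- 0.133322

## cavity volume of the deformed mesh
#' @noRd
deformed_cavity <- function(mesh, u) {
  cs <- closed_endocardial_surface(mesh, matrix(u, ncol = 3, byrow = TRUE))
  cavity_volume(cs$tris, cs$nodes, check = FALSE)
}

#' Run one staggered systolic case
#'
#' Builds the case geometry and fibers, calibrates the potential map from a
#' single-cell action potential, equilibrates the end-diastolic state at the
#' ED pressure, then advances the staggered loop per step: (1) monodomain
#' substeps with the current fiber stretch feeding the stretch current,
#' (2) active-stress update from the mapped potential, (3) quasi-static
#' mechanics with the cavity pressure, (4) 0D cavity/valve/Windkessel update.
#' The cavity is isovolumic until its pressure reaches the aortic pressure,
#' ejects against the Windkessel while flow is positive, and the run ends when
#' the valve closes (flow reversal) or at `duration`.
#'
#' @param config a [sim_config()].
#' @param verbose print step diagnostics.
#' @return an object of class `mefi_trace`: `trace` data.frame (t, V, P_cav,
#'   P_Ao, P_Wk, Q, Phi_mean, Phi_max, sigma_a_mean, von_mises_max,
#'   max_strain_pct, apex_x, apex_y, apex_dz, torsion_deg, phase),
#'   `metrics` (PV-loop + kinematics summaries), `mesh`, `config`, and the
#'   calibrated potential map.
#' @export
run_systolic_case <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  spec <- config$spec
  mesh <- build_lv_geometry(spec, n_axial = config$n_axial,
                            n_theta = config$n_theta,
                            n_trans = config$n_trans)
  fibers <- generate_fibers(mesh)
  ## potential-map calibration from the single-cell peak
  cell <- simulate_single_cell(config$ep, phi0 = 0.7, duration = 150)
  cal <- calibrate_potential_mapping(0, attr(cell, "phi_max"))
  ep <- config$ep
  ep$delta_phi <- cal$delta_phi; ep$beta_phi <- cal$beta_phi
  act <- config$act
  mdl <- mech_model(mesh, config$mat, fibers)
  m <- nrow(mesh$tets)

  ## end-diastolic equilibration (stress-free reference at zero active stress)
  p_ed <- config$ed_pressure * .mmHg_kPa
  ed <- solve_quasistatic(mdl, pressure = p_ed)
  u <- ed$u
  v_ed <- deformed_cavity(mesh, u)

  dt <- config$dt
  op <- ep_operator(mesh, fibers, ep, dt / config$ep_substeps)
  est <- ep_state(op)
  if (config$stimulus == "patch") {
    sn <- stimulus_nodes(mesh)
    est$phi[sn] <- (-10 - ep$delta_phi) / ep$beta_phi
  }
  sigma_a <- numeric(m)
  p_cav <- p_ed                       # kPa
  p_wk <- config$wk$P_dia             # mmHg
  v_prev <- v_ed
  phase <- "isovolumic"
  nstep <- ceiling(config$duration / dt)
  rows <- vector("list", nstep + 1)
  u_hist <- list(u); t_hist <- 0
  nd <- mesh$nodes
  apex_node <- which.max(nd[, 3])
  z_apex <- nd[apex_node, 3]
  rad <- sqrt(nd[, 1]^2 + nd[, 2]^2)
  ring_a <- which(nd[, 3] >= 0.6 * z_apex & nd[, 3] <= 0.9 * z_apex & rad > 1)
  ring_b <- which(nd[, 3] >= 0 & nd[, 3] <= 0.25 * z_apex & rad > 1)
  span_scale <- z_apex / (mean(nd[ring_a, 3]) - mean(nd[ring_b, 3]))
  rot_of <- function(u, idx) {
    du <- matrix(u, ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    x0 <- nd[idx, 1]; y0 <- nd[idx, 2]
    x1 <- x0 + du[, 1]; y1 <- y0 + du[, 2]
    mean(atan2(x0 * y1 - y0 * x1, x0 * x1 + y0 * y1))
  }
  snapshot <- function(t, Q_mls) {
    fl <- mech_fields(mdl, u, act9)
    du <- matrix(u, ncol = 3, byrow = TRUE)
    Phi <- map_potential(est$phi, ep)
    data.frame(t = t, V = v_prev, P_cav = p_cav / .mmHg_kPa,
               P_Ao = Q_mls * config$wk$Rc + p_wk, P_Wk = p_wk, Q = Q_mls,
               Phi_mean = mean(Phi), Phi_max = max(Phi),
               sigma_a_mean = mean(sigma_a),
               von_mises_max = max(fl$von_mises),
               max_strain_pct = 100 * max(t9_sym_eigmax(fl$E)),
               apex_x = du[apex_node, 1], apex_y = du[apex_node, 2],
               apex_dz = du[apex_node, 3],
               torsion_deg = (rot_of(u, ring_a) - rot_of(u, ring_b)) *
                 span_scale * 180 / pi,
               phase = phase)
  }
  act9 <- active_stress_tensor(sigma_a, fibers, act)
  rows[[1]] <- snapshot(0, 0)
  closure_time <- NA_real_

  ## solve mechanics at pressure p (kPa), warm-started; returns u and V,
  ## or NULL if no equilibrium was found at this pressure
  mech_at <- function(p, u_start) {
    s <- tryCatch(
      solve_quasistatic(mdl, pressure = p, active9 = act9, u0 = u_start),
      error = function(e) NULL)
    if (is.null(s)) return(NULL)
    list(u = s$u, V = deformed_cavity(mesh, s$u))
  }

  ## isovolumic pressure: find p with V(p) = v_target (clamped secant with
  ## failure backtracking; pressure proposals bounded per iteration)
  solve_isovolumic <- function(p_start, v_target, u_start) {
    dp_cap <- 2                      # kPa (~15 mmHg) per proposal
    p1 <- p_start
    r1 <- mech_at(p1, u_start)
    if (is.null(r1)) stop("isovolumic solve failed at the starting pressure")
    f1 <- r1$V - v_target
    if (abs(f1) <= config$subit_tol * v_ed)
      return(list(p = p1, u = r1$u, V = r1$V))
    p2 <- p1 - sign(f1) * min(dp_cap, max(0.05, 0.02 * abs(p1)))
    for (it in seq_len(config$max_subit)) {
      r2 <- mech_at(p2, r1$u)
      if (is.null(r2)) { p2 <- (p1 + p2) / 2; next }
      f2 <- r2$V - v_target
      if (abs(f2) <= config$subit_tol * v_ed)
        return(list(p = p2, u = r2$u, V = r2$V))
      step <- if (abs(f2 - f1) > 1e-14) -f2 * (p2 - p1) / (f2 - f1) else
        -sign(f2) * dp_cap / 2
      step <- max(min(step, dp_cap), -dp_cap)
      p1 <- p2; f1 <- f2; r1 <- r2
      p2 <- max(p2 + step, 0)
    }
    list(p = p1, u = r1$u, V = r1$V)
  }

  for (k in seq_len(nstep)) {
    t_now <- k * dt
    ## (1) electrophysiology with current fiber stretch
    lam <- if (config$mef)
      mech_fields(mdl, u, act9)$lambda_fiber else 1
    for (ss in seq_len(config$ep_substeps))
      est <- step_monodomain(est, op, lambda_f = lam)
    ## (2) active stress from the mapped potential (element means)
    Phi_el <- rowMeans(matrix(map_potential(est$phi, ep)[mesh$tets],
                              ncol = 4))
    sigma_a <- step_active_stress(sigma_a, Phi_el, dt, act)
    act9 <- active_stress_tensor(sigma_a, fibers, act)
    ## (3)+(4) mechanics with 0D cavity coupling
    if (phase == "isovolumic") {
      iso <- solve_isovolumic(p_cav, v_prev, u)
      p_cav <- iso$p; u <- iso$u
      q_mls <- 0
      ## valve opens when cavity pressure reaches aortic (= stored) pressure
      if (p_cav / .mmHg_kPa >= p_wk) phase <- "ejection"
    }
    if (phase == "ejection") {
      ## solve the 0D coupling fixed point g(p) = P_Ao(Q(p)) - p = 0 by a
      ## clamped secant (g is monotone decreasing in p)
      dp_cap <- 2                  # kPa per proposal
      converged <- FALSE
      r <- NULL
      g_of <- function(rr) {
        q <- (v_prev - rr$V) / dt * 1000          # mL/s
        wk <- windkessel_step(p_wk, q, dt / 1000, config$wk)
        wk$P_Ao * .mmHg_kPa
      }
      p_a <- p_cav
      r_a <- mech_at(p_a, u)
      if (is.null(r_a)) stop("ejection coupling failed at the step pressure")
      g_a <- g_of(r_a) - p_a
      p_it <- p_a; r <- r_a
      if (abs(g_a) <= config$subit_tol * max(abs(p_a), 1)) {
        converged <- TRUE
      } else {
        p_b <- max(p_a + max(min(0.5 * g_a, dp_cap), -dp_cap), 0)
        for (it in seq_len(config$max_subit)) {
          r_b <- mech_at(p_b, r$u)
          if (is.null(r_b)) { p_b <- (p_a + p_b) / 2; next }
          g_b <- g_of(r_b) - p_b
          r <- r_b; p_it <- p_b
          if (abs(g_b) <= config$subit_tol * max(abs(p_b), 1)) {
            converged <- TRUE
            break
          }
          step <- if (abs(g_b - g_a) > 1e-14)
            -g_b * (p_b - p_a) / (g_b - g_a) else 0.5 * g_b
          step <- max(min(step, dp_cap), -dp_cap)
          p_a <- p_b; g_a <- g_b
          p_b <- max(p_b + step, 0)
        }
      }
      if (!converged && verbose)
        message(sprintf("step %d: ejection subiterations hit the bound", k))
      q_mls <- (v_prev - r$V) / dt * 1000
      if (q_mls < 0) {
        ## flow reversal: the valve closes, the systolic run ends
        closure_time <- t_now
        phase <- "closed"
      } else {
        wkres <- windkessel_step(p_wk, q_mls, dt / 1000, config$wk)
        p_wk <- wkres$P_Wk
        p_cav <- p_it
        u <- r$u
        v_prev <- r$V
      }
    }
    if (phase != "ejection") {
      v_prev <- deformed_cavity(mesh, u)
      q_mls <- 0
    }
    if (k %% config$record_every == 0L || phase == "closed") {
      rows[[k + 1]] <- snapshot(t_now, q_mls)
      u_hist <- c(u_hist, list(u)); t_hist <- c(t_hist, t_now)
    }
    if (verbose && k %% 20L == 0L)
      message(sprintf("t=%5.0f ms V=%.1f mL P=%.1f mmHg phase=%s",
                      t_now, v_prev, p_cav / .mmHg_kPa, phase))
    if (phase == "closed") break
  }
  trace <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  pv <- pv_loop(data.frame(t = trace$t, V = trace$V, P = trace$P_cav))
  out <- structure(list(trace = trace, metrics = c(pv,
                        list(closure_time = closure_time,
                             peak_torsion_deg = max(abs(trace$torsion_deg)),
                             v_ed = v_ed)),
                        mesh = mesh, fibers = fibers, config = config,
                        potential_map = cal, u_hist = u_hist,
                        t_hist = t_hist, model = mdl),
                   class = "mefi_trace")
  out
}

#' @export
print.mefi_trace <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Systolic run, case %s: %d steps to t=%.0f ms\n",
              as.character(x$config$spec$case_id), nrow(x$trace) - 1,
              max(x$trace$t)))
  cat(sprintf("  EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.1f%%\n",
              m$EDV, m$ESV, m$SV, m$EF))
  cat(sprintf("  stroke work %.0f mmHg mL, peak torsion %.2f deg\n",
              m$stroke_work, m$peak_torsion_deg))
  if (is.finite(m$closure_time))
    cat(sprintf("  aortic valve closed at t = %.0f ms\n", m$closure_time))
  invisible(x)
}

#' @export
plot.mefi_trace <- function(x, which = c("pv", "time"), ...) {
  which <- match.arg(which)
  tr <- x$trace
  if (which == "pv") {
    plot(tr$V, tr$P_cav, type = "l", xlab = "cavity volume (mL)",
         ylab = "cavity pressure (mmHg)", main = "PV loop (systolic)")
  } else {
    op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(par(op))
    plot(tr$t, tr$Phi_mean, type = "l", xlab = "t (ms)",
         ylab = "mean potential (mV)")
    plot(tr$t, tr$sigma_a_mean, type = "l", xlab = "t (ms)",
         ylab = "mean active stress (kPa)")
  }
  invisible(x)
}

#' Outflow-tract velocity waveform
#'
#' Surrogate for the 3D outlet velocity field: volumetric outflow from the
#' cavity-volume derivative, `Q = -dV/dt` (central differences), and the mean
#' outlet velocity through the case's outflow-tract cross-section.
#'
#' @param trace a `mefi_trace` or a data.frame with columns `t` (ms) and `V`
#'   (mL).
#' @param lvot_radius outflow radius (mm); defaults to the case card value.
#' @param file optional path: writes the documented CSV schema
#'   (`t_ms, flow_mL_s, v_mean_m_s`).
#' @return data.frame with `t_ms`, `flow_mL_s`, `v_mean_m_s` (invisibly when
#'   written to file).
#' @export
export_lvot_velocity_profile <- function(trace, lvot_radius = NULL,
                                         file = NULL) {
  tr <- if (inherits(trace, "mefi_trace")) trace$trace else trace
  if (is.null(lvot_radius))
    lvot_radius <- if (inherits(trace, "mefi_trace"))
      trace$config$spec$lvot_radius else stop("lvot_radius required")
  t <- tr$t; V <- tr$V
  n <- length(t)
  if (n < 3) stop("need at least 3 samples")
  dVdt <- numeric(n)
  dVdt[2:(n - 1)] <- (V[3:n] - V[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  dVdt[1] <- (V[2] - V[1]) / (t[2] - t[1])
  dVdt[n] <- (V[n] - V[n - 1]) / (t[n] - t[n - 1])
  q_mls <- -dVdt * 1000                       # mL/s
  area_mm2 <- pi * lvot_radius^2
  v_ms <- q_mls * 1000 / area_mm2 / 1000      # mm^3/s -> m/s over mm^2
  out <- data.frame(t_ms = t, flow_mL_s = q_mls, v_mean_m_s = v_ms)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Calibrate scalar parameters against target metrics
#'
#' Bounded scalar search matching an ejection-fraction target by tuning the
#' saturated active-stress gain `k` (and optionally reporting the torsion
#' sweep over `eta3`). The model evaluation is injectable, so cheap surrogates
#' can stand in during testing; the default runs the coupled model.
#'
#' @param target_ef target ejection fraction (percent).
#' @param k_bounds search bracket for `k` (kPa/mV).
#' @param config base [sim_config()]; its `act$k` is overridden.
#' @param runner function(k) -> EF percent; defaults to running
#'   [run_systolic_case()] at `k`.
#' @param tol EF tolerance (percentage points).
#' @param max_eval evaluation budget.
#' @return list with `k`, `achieved_ef`, `target_ef`, `converged`,
#'   `evaluations` (data.frame of the search path).
#' @export
calibration_suite <- function(target_ef, k_bounds = c(0.5, 12),
                              config = sim_config(), runner = NULL,
                              tol = 0.5, max_eval = 12L) {
  if (is.null(runner)) {
    runner <- function(k) {
      cfg <- config
      cfg$act$k <- k
      run_systolic_case(cfg)$metrics$EF
    }
  }
  evals <- data.frame(k = numeric(0), ef = numeric(0))
  eval_k <- function(k) {
    ef <- runner(k)
    evals <<- rbind(evals, data.frame(k = k, ef = ef))
    ef
  }
  k0 <- config$act$k
  ef0 <- eval_k(k0)
  if (abs(ef0 - target_ef) <= tol)
    return(list(k = k0, achieved_ef = ef0, target_ef = target_ef,
                converged = TRUE, evaluations = evals))
  lo <- k_bounds[1]; hi <- k_bounds[2]
  ef_lo <- eval_k(lo); ef_hi <- eval_k(hi)
  if ((ef_lo - target_ef) * (ef_hi - target_ef) > 0) {
    best <- evals[which.min(abs(evals$ef - target_ef)), ]
    return(list(k = best$k, achieved_ef = best$ef, target_ef = target_ef,
                converged = FALSE, evaluations = evals))
  }
  for (i in seq_len(max_eval - 3L)) {
    mid <- (lo + hi) / 2
    ef_mid <- eval_k(mid)
    if (abs(ef_mid - target_ef) <= tol)
      return(list(k = mid, achieved_ef = ef_mid, target_ef = target_ef,
                  converged = TRUE, evaluations = evals))
    if ((ef_lo - target_ef) * (ef_mid - target_ef) <= 0) {
      hi <- mid; ef_hi <- ef_mid
    } else {
      lo <- mid; ef_lo <- ef_mid
    }
  }
  best <- evals[which.min(abs(evals$ef - target_ef)), ]
  list(k = best$k, achieved_ef = best$ef, target_ef = target_ef,
       converged = abs(best$ef - target_ef) <= tol, evaluations = evals)
}
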
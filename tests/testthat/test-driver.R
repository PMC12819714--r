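test_that("without excitation the systolic driver is stationary", {
  cfg <- sim_config(case_id = 1, duration = 30, dt = 1, stimulus = "none",
                    n_axial = 6L, n_theta = 8L, n_trans = 1L)
  run <- run_systolic_case(cfg)
  tr <- run$trace
  expect_lt(max(abs(diff(tr$V))), 1e-6)
  expect_equal(max(tr$sigma_a_mean), 0)
  expect_equal(max(abs(tr$Phi_mean + 80)), 0)
  expect_equal(max(abs(tr$Phi_max + 80)), 0)
})

test_that("identical configurations give bitwise-identical traces", {
  cfg <- sim_config(case_id = 1, duration = 60, dt = 1,
                    n_axial = 6L, n_theta = 8L, n_trans = 1L)
  r1 <- run_systolic_case(cfg)
  r2 <- run_systolic_case(cfg)
  expect_identical(r1$trace, r2$trace)
})

test_that("isovolumic phase holds the cavity volume to tolerance", {
  run <- short_run()
  tr <- run$trace
  iso <- tr$phase == "isovolumic"
  expect_gt(sum(iso), 5)
  expect_lt(max(abs(diff(tr$V[iso]))),
            run$config$subit_tol * run$metrics$v_ed * 2)
  ## potential stays within the calibrated bounds
  expect_lte(max(tr$Phi_max), 21)
  expect_gte(min(tr$Phi_mean), -81)
})

test_that("active stress rises only after electrical activation", {
  run <- short_run()
  tr <- run$trace
  t_phi <- tr$t[min(which(tr$Phi_mean > -79))]
  t_sa <- tr$t[min(which(tr$sigma_a_mean > 0.5))]
  expect_gt(t_sa, t_phi)
  ## the mean active stress keeps lagging the mean potential while both rise
  expect_gt(which.max(tr$sigma_a_mean), which.max(tr$Phi_mean) - 1)
})

test_that("stretch feedback changes the trace only after deformation starts", {
  base <- sim_config(case_id = 1, duration = 70, dt = 1,
                     n_axial = 6L, n_theta = 8L, n_trans = 1L,
                     ep = ep_params(Gs = 0))
  mef_on <- base
  mef_on$ep <- ep_params(Gs = 10)
  r0 <- run_systolic_case(base)
  r1 <- run_systolic_case(mef_on)
  d <- abs(r1$trace$Phi_mean - r0$trace$Phi_mean)
  expect_gt(max(d), 0)         # feedback is detectable
  expect_lt(max(d), 5)         # and bounded
  ## before any deformation beyond the shared ED state the two runs coincide
  dz0 <- r0$trace$apex_dz[1]
  first_move <- min(which(abs(r0$trace$apex_dz - dz0) > 1e-6))
  if (first_move > 1)
    expect_lt(max(d[seq_len(first_move - 1)]), 1e-6)
  expect_lt(d[1], 1e-12)  # identical end-diastolic initialization
})

test_that("outflow waveform matches the analytic volume derivative", {
  T <- 300
  t <- seq(0, T, 0.1)
  V0 <- 120; A <- 30
  tr <- data.frame(t = t, V = V0 - A * sin(pi * t / T))
  out <- export_lvot_velocity_profile(tr, lvot_radius = 11)
  q_ref <- A * pi / T * cos(pi * t / T) * 1000
  i <- 2:(length(t) - 1)
  expect_lt(max(abs(out$flow_mL_s[i] - q_ref[i])) / max(abs(q_ref)), 1e-6)
  ## constant volume: zero flow everywhere
  tc <- data.frame(t = t, V = rep(100, length(t)))
  expect_equal(max(abs(export_lvot_velocity_profile(tc, 11)$flow_mL_s)), 0)
})

test_that("ejected flow integral is consistent with the stroke volume", {
  run <- short_run()
  out <- export_lvot_velocity_profile(run)
  q <- out$flow_mL_s / 1000  # mL/ms
  t <- out$t_ms
  sv_flow <- sum((q[-1] + q[-length(q)]) / 2 * diff(t))
  sv_pv <- run$trace$V[1] - tail(run$trace$V, 1)
  expect_lt(abs(sv_flow - sv_pv), 0.02 * max(sv_pv, 0.5))
})

test_that("calibration suite converges on a monotone surrogate model", {
  surrogate <- function(k) 100 * k^2 / (k^2 + 25)
  cfg <- sim_config()
  cfg$act$k <- 2
  res <- calibration_suite(target_ef = 50, k_bounds = c(0.5, 12),
                           config = cfg, runner = surrogate, tol = 0.5)
  expect_true(res$converged)
  expect_lt(abs(res$k - 5), 0.5)
  ## already-satisfied target returns the initial gain after one evaluation
  cfg$act$k <- 5
  res2 <- calibration_suite(target_ef = surrogate(5), config = cfg,
                            runner = surrogate, tol = 0.5)
  expect_true(res2$converged)
  expect_equal(res2$k, 5)
  expect_equal(nrow(res2$evaluations), 1)
  ## unreachable target reports the best achievable without converging
  res3 <- calibration_suite(target_ef = 99.9, k_bounds = c(0.5, 12),
                            config = cfg, runner = surrogate, tol = 0.5)
  expect_false(res3$converged)
  expect_equal(res3$k, 12)
})

test_that("kinematic metrics from the driver are internally consistent", {
  run <- short_run()
  km <- kinematic_metrics(run$model, run$u_hist, run$t_hist)
  ## driver snapshot torsion equals the standalone metric on the same states
  expect_equal(km$trace$torsion_deg[length(run$u_hist)],
               tail(run$trace$torsion_deg, 1), tolerance = 1e-9)
  expect_gte(km$max_strain_pct, 0)
})
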
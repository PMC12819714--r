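## Active stress --------------------------------------------------------------

#' Active-stress parameter set
#'
#' First-order activation dynamics driven by the mapped potential,
#' `d sigma_a / dt = eps(Phi) [k (Phi - Phi_r) - sigma_a]`, with a
#' Gompertz-sigmoid delay function switching between a slow rate at rest and a
#' fast rate when depolarized, and anisotropic distribution weights for the
#' fiber / sheet / sheet-normal directions.
#'
#' `k` (kPa/mV) sets the saturated active stress `k (Phi_peak - Phi_r)`; it is
#' the scalar tuned when calibrating ejection fraction. The distribution
#' weights default to `eta1 = 0.1` (fiber), `eta2 = 0.2` (sheet),
#' `eta3 = 0.6` (sheet-normal), the values used in the torsion validation;
#' `eta3` chiefly controls twist.
#'
#' @param k saturated active stress gain (kPa/mV).
#' @param Phi_r resting potential (mV).
#' @param eps0,eps1 slow / fast rate constants (1/ms).
#' @param zeta transition rate (1/mV).
#' @param Phi_t phase-shift potential (mV).
#' @param eta1,eta2,eta3 anisotropic distribution weights (dimensionless).
#' @param form `"gompertz"` for
#'   `eps0 + (eps1 - eps0) exp(-exp(-zeta (Phi - Phi_t)))` (default) or
#'   `"summed"` for the `(eps0 + eps1)` amplitude variant seen in some
#'   transcriptions.
#' @return an object of class `active_stress_params`.
#' @export
active_stress_params <- function(k = 3, Phi_r = -80, eps0 = 0.008,
                                 eps1 = 0.08, zeta = 0.1, Phi_t = -20,
                                 eta1 = 0.1, eta2 = 0.2, eta3 = 0.6,
                                 form = c("gompertz", "summed")) {
  stopifnot(eps0 > 0, eps1 > 0, eta1 >= 0, eta2 >= 0, eta3 >= 0, k >= 0)
  structure(list(k = k, Phi_r = Phi_r, eps0 = eps0, eps1 = eps1, zeta = zeta,
                 Phi_t = Phi_t, eta1 = eta1, eta2 = eta2, eta3 = eta3,
                 form = match.arg(form)),
            class = "active_stress_params")
}

#' Activation-rate (delay) function
#'
#' `eps(Phi) = eps0 + (eps1 - eps0) exp(-exp(-zeta (Phi - Phi_t)))`: monotone
#' non-decreasing, with limits `eps0` as `Phi -> -Inf` and `eps1` as
#' `Phi -> +Inf`, so contraction builds quickly on depolarization and decays
#' slowly at rest.
#'
#' @param Phi mapped potential (mV).
#' @param params an [active_stress_params()].
#' @return rate (1/ms), same shape as `Phi`.
#' @export
delay_function <- function(Phi, params) {
  amp <- if (params$form == "summed") params$eps0 + params$eps1 else
    params$eps1 - params$eps0
  params$eps0 + amp * exp(-exp(-params$zeta * (Phi - params$Phi_t)))
}

#' Advance the active-stress scalar one step
#'
#' Exponential (exact-for-constant-potential) update of
#' `d sigma_a/dt = eps(Phi)[k (Phi - Phi_r) - sigma_a]`:
#' `sigma_a' = target + (sigma_a - target) exp(-eps dt)`, unconditionally
#' stable for any `dt`.
#'
#' @param sigma_a current active stress (kPa), scalar or per-element vector.
#' @param Phi mapped potential (mV), same shape.
#' @param dt step (ms).
#' @param params an [active_stress_params()].
#' @return updated `sigma_a` (kPa).
#' @export
step_active_stress <- function(sigma_a, Phi, dt, params) {
  stopifnot(dt > 0)
  eps <- delay_function(Phi, params)
  target <- params$k * (Phi - params$Phi_r)
  target + (sigma_a - target) * exp(-eps * dt)
}

#' Anisotropic active-stress tensor
#'
#' Spectral second Piola-Kirchhoff contribution
#' `sigma = sigma_a (eta1 a (x) a + eta2 s (x) s + eta3 n (x) n)` with
#' eigenvectors the fiber / sheet / sheet-normal triad.
#'
#' @param sigma_a active stress per element (kPa).
#' @param fibers a `fiber_field` (orthonormal triads).
#' @param params an [active_stress_params()].
#' @return m x 9 row-wise symmetric tensors (kPa).
#' @export
active_stress_tensor <- function(sigma_a, fibers, params) {
  g11 <- vec3_dot(fibers$fiber, fibers$fiber)
  g12 <- vec3_dot(fibers$fiber, fibers$sheet)
  g13 <- vec3_dot(fibers$fiber, fibers$sheet_normal)
  if (max(abs(g11 - 1)) > 1e-8 || max(abs(g12)) > 1e-8 ||
      max(abs(g13)) > 1e-8)
    stop("fiber triad is not orthonormal")
  sigma_a * (params$eta1 * t9_outer(fibers$fiber) +
               params$eta2 * t9_outer(fibers$sheet) +
               params$eta3 * t9_outer(fibers$sheet_normal))
}
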
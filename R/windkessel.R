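## Two-element Windkessel afterload -------------------------------------------

#' Windkessel parameter set
#'
#' Two-element arterial afterload with characteristic resistance:
#' `C dP_Wk/dt + P_Wk/Rp = Q_Ao`, `P_Ao = Q_Ao Rc + P_Wk`.
#' Defaults are the calibrated systemic values `C = 3.128 mL/mmHg`,
#' `Rp = 0.6652 mmHg s/mL`, `Rc = 0.0914 mmHg s/mL`; diastolic/systolic
#' anchors of 80/120 mmHg initialize and sanity-check runs.
#'
#' @param C arterial compliance (mL/mmHg).
#' @param Rp peripheral resistance (mmHg s/mL).
#' @param Rc characteristic resistance (mmHg s/mL).
#' @param P_dia,P_sys diastolic and systolic pressure anchors (mmHg).
#' @return an object of class `windkessel_params`.
#' @export
windkessel_params <- function(C = 3.128, Rp = 0.6652, Rc = 0.0914,
                              P_dia = 80, P_sys = 120) {
  stopifnot(C > 0, Rp > 0, Rc > 0)
  structure(list(C = C, Rp = Rp, Rc = Rc, P_dia = P_dia, P_sys = P_sys),
            class = "windkessel_params")
}

#' Fourth-order Runge-Kutta Windkessel step
#'
#' Advances the stored pressure one step of
#' `dP_Wk/dt = (Q_Ao - P_Wk/Rp)/C` with classical RK4 (the aortic flow is held
#' at its step value), and evaluates the aortic pressure
#' `P_Ao = Q_Ao Rc + P_Wk` at the same step.
#'
#' @param P_Wk stored (Windkessel) pressure (mmHg).
#' @param Q_Ao aortic flow during the step (mL/s).
#' @param dt step (s).
#' @param params a [windkessel_params()].
#' @return list with `P_Wk` and `P_Ao` (mmHg).
#' @export
windkessel_step <- function(P_Wk, Q_Ao, dt, params) {
  stopifnot(dt > 0)
  f <- function(P) (Q_Ao - P / params$Rp) / params$C
  k1 <- f(P_Wk)
  k2 <- f(P_Wk + dt / 2 * k1)
  k3 <- f(P_Wk + dt / 2 * k2)
  k4 <- f(P_Wk + dt * k3)
  P_new <- P_Wk + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  list(P_Wk = P_new, P_Ao = Q_Ao * params$Rc + P_new)
}

#' Ejection fraction from end-diastolic and stroke volume
#'
#' `EF = 100 SV / EDV`, reported to one decimal.
#'
#' @param edv end-diastolic volume (mL), > 0.
#' @param sv stroke volume (mL), `0 <= sv <= edv`.
#' @return EF in percent (one decimal).
#' @export
ejection_fraction <- function(edv, sv) {
  if (edv <= 0) stop("EDV must be positive")
  if (sv < 0 || sv > edv) stop("stroke volume must lie in [0, EDV]")
  round(100 * sv / edv, 1)
}

#' Pressure-volume loop metrics
#'
#' End-diastolic / end-systolic volumes from the extrema of the volume record,
#' stroke volume, ejection fraction and stroke work (`integral of P dV` by
#' trapezoids; full area for a closed loop, the traversed segment otherwise).
#'
#' @param records data.frame with columns `t` (ms), `V` (mL), `P` (mmHg);
#'   optionally `P_Ao`, `Q`.
#' @return list with `EDV`, `ESV`, `SV`, `EF` (percent), `stroke_work`
#'   (mmHg mL).
#' @export
pv_loop <- function(records) {
  if (!all(c("V", "P") %in% names(records)))
    stop("records need V and P columns")
  if (nrow(records) < 3) stop("need at least 3 samples for a PV loop")
  V <- records$V; P <- records$P
  edv <- max(V); esv <- min(V)
  sv <- edv - esv
  sw <- -sum((P[-1] + P[-length(P)]) / 2 * diff(V))
  list(EDV = edv, ESV = esv, SV = sv, EF = ejection_fraction(edv, sv),
       stroke_work = abs(sw))
}
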
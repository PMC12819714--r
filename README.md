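# lvemsim

Desk-scale simulation of left-ventricle (LV) systolic electromechanics in R:
parameterized LV geometry and tetrahedral meshing, rule-based myocardial
fiber architecture, anisotropic monodomain electrophysiology with
mechano-electrical feedback, active-stress finite-element mechanics with
Holzapfel–Gasser–Ogden (HGO) anisotropic hyperelasticity, and a two-element
Windkessel afterload, coupled in a staggered scheme with a lumped (0D)
cavity-pressure surrogate for the intraventricular blood.

It is written for cardiac-modelling researchers and students who want a
self-contained, inspectable implementation of the full model chain —
geometry → fibers → excitation → contraction → ejection — that runs in
seconds to minutes on a laptop, rather than a cluster-scale
fluid–structure-interaction code.

## The model at a glance

* **Geometry.** Truncated prolate-spheroid LV wall built from elliptical
  cross-sections with a wall-thickness map; endocardial semi-axes calibrated
  so the meshed cavity matches the case end-diastolic volume (EDV) to 1%.
  Five built-in case cards span normal anatomy and remodelling patterns.
  A parametric aortic root with three log-guide-curve leaflets is included
  at surface level.
* **Fibers.** Transmural coordinate β = D_epi/(D_epi + D_end), harmonic
  (Laplace) transmural directions, helix angle
  θ = [β θ_end + (1−β) θ_epi](1 − Z/Z_apex) with −60°/+60° basal defaults,
  per-element orthonormal fiber/sheet/normal triads, isotropic apex cylinder.
* **Electrophysiology.** Monodomain
  ∂φ/∂t = ∇·(D∇φ) − I_ion(φ, r, λ)/β_t with two-variable kinetics
  I_e = cφ(φ−α)(φ−1) + rφ, stretch current I_m = θ G_s(λ−1)(φ−φ_s),
  conductivities 0.6/0.2/0.1 mm²/ms (along/across/transmural) and the affine
  map Φ = φβ_φ + δ_φ calibrated to −80/+20 mV.
* **Mechanics.** Total-Lagrangian P1 tetrahedra; W = neo-Hookean +
  (k₁/2k₂)Σ[exp(k₂Ē²)−1] with dispersion κ; active stress
  σ = σ_a(η₁ ā⊗ā + η₂ s̄⊗s̄ + η₃ n̄⊗n̄) evolved by
  dσ_a/dt = ε(Φ)[k(Φ−Φ_r) − σ_a]; follower endocardial pressure; rigid basal
  fixation; quasi-static Newton or implicit Newmark.
* **Afterload.** C dP_Wk/dt + P_Wk/R_p = Q_Ao, P_Ao = Q_Ao R_c + P_Wk
  (RK4; C = 3.128 mL/mmHg, R_p = 0.6652, R_c = 0.0914 mmHg·s/mL), with
  isovolumic/ejection valve logic and PV-loop, ejection-fraction (EF),
  apex-trajectory and torsion analytics.

See the methods vignette (`vignettes/lv-electromechanics-methods.Rmd`) for
assumptions, parameter meanings, units, numerical choices and limitations.

## Worked example

```r
library(lvemsim)

spec <- lv_case_spec(1)
spec
#> LV case 1: EDV 117.3 mL, long axis 74.2 mm, LVID 54.4 mm
#>   wall thickness 3.3 (apex) .. 8.4 (base) mm, target mean 6.2

mesh <- build_lv_geometry(spec)
mesh
#> Tetrahedral mesh: 723 nodes, 2760 tets [mm]
#>   surfaces: endocardium (460), epicardium (460), base (80)
#>   regions: bulk (2600), apex_cylinder (160)
cavity_volume(mesh)     # 117.3 mL  (case EDV, calibrated to 1%)
long_axis_length(mesh)  # 74.2 mm   (apex to basal-plane centroid)

fibers <- generate_fibers(mesh)
fibers
#> Fiber field: 2760 elements; 160 isotropic (apex)
#>   helix angle range -43.3 .. 42.6 deg   (element centroids; the rule spans
#>                                          -60..+60 on the basal surfaces)

## calibrate the potential map from one single-cell action potential,
## then run activation-recovery on the ventricle
cell <- simulate_single_cell(phi0 = 0.7, duration = 150)
cal  <- calibrate_potential_mapping(0, attr(cell, "phi_max"))
ep   <- ep_params(delta_phi = cal$delta_phi, beta_phi = cal$beta_phi)
run  <- run_monodomain(mesh, fibers, ep, duration = 500, dt = 0.25)
range(run$summary$Phi_min, run$summary$Phi_max)
#> [1] -80.0  19.9     # mV: the calibrated physiological range
max(run$activation_time)
#> [1] 197             # ms: last node activated (septal/apical foci protocol)

ejection_fraction(117.3, 81.1)   # EF from the case-1 EDV/SV card
#> [1] 69.1
```

A full coupled systolic run (excitation → contraction → isovolumic rise →
ejection against the Windkessel → valve closure) and its PV loop:

```r
cfg <- sim_config(case_id = 1, duration = 260, dt = 1)
run <- run_systolic_case(cfg)      # ~1 minute at the default coarse mesh
run
#> Systolic run, case 1: 256 steps to t=256 ms
#>   EDV 118.1 mL, ESV 107.6 mL, SV 10.5 mL, EF 8.9%
#>   stroke work 933 mmHg mL, peak torsion 0.99 deg
#>   aortic valve closed at t = 256 ms
plot(run, "pv")
export_lvot_velocity_profile(run)  # outflow waveform (surrogate outlet BC)
```

The default active-stress gain is deliberately a starting point: EF is a
calibration target (`calibration_suite()` tunes the saturated gain `k`), and
at the stiff default passive moduli the desk-scale EF stays low while the
tested trends (EF rising with `k`, torsion with `eta3`) hold.

A thin command-line front end over the same functions is installed at
`inst/cli/lvemsim.R` (subcommands `geometry`, `fibers`, `ep`, `wk`, `run`,
`material`).

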
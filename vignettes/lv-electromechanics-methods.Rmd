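---
title: "Methods: desk-scale left-ventricle electromechanics with a 0D afterload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale left-ventricle electromechanics with a 0D afterload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvemsim)
```

# Scope and model chain

`lvemsim` simulates systolic ejection of an idealized left ventricle (LV) as a
chain of four coupled submodels, advanced by a staggered scheme:

1. **Geometry and fibers.** A parameterized LV wall built from elliptical
   cross-sections, meshed with tetrahedra, equipped with a rule-based
   myocardial fiber architecture.
2. **Electrophysiology.** An anisotropic monodomain reaction–diffusion model
   with two-variable phenomenological kinetics (dimensionless potential
   $\varphi$, recovery $r$) and a stretch-activated feedback current.
3. **Mechanics.** Total-Lagrangian finite-element equilibrium of the
   actively contracting wall: a compressible neo-Hookean matrix with an
   exponential fiber-reinforced (HGO-type) anisotropic part, plus an active
   second Piola–Kirchhoff stress distributed along the fiber, sheet and
   sheet-normal directions.
4. **Hemodynamics.** A lumped cavity model: isovolumic phases enforce a
   constant cavity volume; during ejection the cavity pressure equals the
   aortic pressure of a two-element Windkessel with characteristic
   resistance.

Three-dimensional intraventricular blood flow, moving-boundary
fluid–structure interaction and valve-leaflet contact are outside the
package's scope: the 0D cavity/afterload surrogate replaces them, and the
outflow waveform (volumetric flow and mean outlet velocity) is exported as
the downstream boundary-condition surrogate. The aortic-root/leaflet geometry
generator and the leaflet material law are included at surface/material-point
level only.

# Geometry

The endocardium is a truncated prolate spheroid: cross-sections at
`n_levels` stations along the long axis are ellipses whose semi-axes follow
$a(s) = a_0\sqrt{1-s^2}$ with $s \in [0,1]$ the normalized apicobasal
coordinate (base plane at $Z = 0$, apex pole at $Z = Z_{\mathrm{apex}}$; all
lengths mm). The epicardium is the endocardium offset along its outward
normal by a thickness profile
$t(s) = t_{\min} + (t_{\max} - t_{\min})(1-s)^p$, with $p$ fixed by the
requirement that the mean of $t$ over a uniform $s$-grid equals the case's
average-thickness target. The five built-in case cards carry clinically derived end-diastolic volume
(EDV), long-axis length, internal diameter and wall-thickness targets
spanning normal anatomy and remodelling patterns; outflow-tract radius and
tilt are package choices encoding each case's qualitative design (case 3
narrows the outflow, case 4 tilts it).

Case volumes are specified and reported in mL throughout.

The wall is meshed by a structured (apicobasal x circumferential x
transmural) grid mapped through the parameterization and split into
tetrahedra with the Kuhn 6-tet decomposition, which is conforming on
structured grids including the periodic seam; hexahedra collapsed at the
apex pole drop their degenerate tetrahedra. An outer calibration loop
rescales the endocardial in-plane semi-axes (long axis fixed) until the
*meshed* cavity volume — endocardial surface closed by a basal-cap fan,
integrated by the divergence theorem — matches the card EDV to 0.5%;
because volume scales quadratically with the in-plane semi-axes this
converges in 2–3 iterations. Calibrating against the discrete mesh rather
than the continuum surface makes the case-EDV checks hold at any
resolution.

The apex region is the set of elements within the 10 mm diameter cylinder
about the long axis near the apex; it is flagged isotropic (conductivity set
to the mean eigenvalue there) because the rule-based architecture is
singular at the pole.

The default build resolution (12 apicobasal rings, 20 circumferential
divisions, 2 transmural layers, about 2 800 tetrahedra) was chosen so that a
full activation–recovery electrophysiology run completes in seconds; the
coupled driver uses an even coarser default (7 x 10 x 1, about 530
tetrahedra) so that parameter sweeps remain interactive. These sizes are the
package's intended desk scale; the generators accept arbitrary resolutions.

# Fiber architecture

The transmural direction field is the normalized negative gradient of a
harmonic field (linear FEM Laplace solve) with $U = 1$ on the endocardium
and $U = 0$ on the epicardium. The transmural *coordinate* $\beta$ defaults
to the wall-distance rule $\beta = D_{epi}/(D_{epi} + D_{end})$ (exact
point-to-triangle distances to the tagged surfaces), with the harmonic field
available as an option; on slab and annulus benchmarks the two agree to
better than 0.05 in the sup norm. The helix angle tapers both transmurally
and apicobasally,
$\theta = [\beta\,\theta_{end}^{max} + (1-\beta)\,\theta_{epi}^{max}]
(1 - Z/Z_{\mathrm{apex}})$, with defaults $-60^\circ$ (epicardium) and
$+60^\circ$ (endocardium) at the base, zero at the apex.

Per-element triads: $a_1$ transmural (the harmonic direction), $a_2$ the
in-wall apicobasal direction (global long axis orthogonalized against
$a_1$), $a_3 = a_1 \times a_2$ circumferential. The fiber direction is
$a_3$ rotated by $\theta$ about $a_1$ with the right-hand rule about the
outward transmural axis — rule-based descriptions in the literature often
leave the handedness open, so this convention is recorded explicitly. The sheet direction is taken
transmural and the sheet-normal completes the right-handed triad;
anatomical descriptions of sheets lying perpendicular to both surfaces are
ambiguous between this and the apicobasal alternative, and the choice is
exposed by the triad fields themselves.

# Electrophysiology

Monodomain propagation of the dimensionless potential with conductivity
tensor $D = d_f\, \bar a \otimes \bar a + d_n\, \bar n \otimes \bar n +
d_s\, \bar s \otimes \bar s$, defaults 0.6 / 0.2 / 0.1 mm²/ms along /
across fiber / transmural. Monodomain theory then gives a conduction
velocity ratio of $\sqrt{0.6/0.2} \approx 1.73$ along vs across fibers —
the package's cable tests confirm this — although a 3:1 velocity ratio is sometimes
quoted for these conductivities; the conductivities are treated
as the normative inputs and the $\sqrt{}$ law as the expected consequence.

Reaction kinetics use the standard published constants of the two-variable
modified phenomenological model ($\alpha = 0.01$, $c = 8$, $b = 0.15$,
$\gamma = 0.002$, $\mu_1 = 0.2$, $\mu_2 = 0.3$). The
stretch-activated current $I_m = \theta_{gate} G_s(\lambda - 1)
(\varphi - \varphi_s)$ is gated to zero below the activation threshold
$\varphi_s$ and outside the active-response window, implemented as the
interval between the upward and downward 0.5-crossings of $\varphi$.
Defaults $G_s = 1$, $\varphi_s = 0.6$ give a detectable but modest feedback;
published values vary widely, so both are configurable.

The affine map $\Phi = \varphi\,\beta_\varphi + \delta_\varphi$ is
calibrated per run by simulating one single-cell action potential started
from the stimulus-patch potential (so that the map anchors exactly
$\Phi(\varphi_{rest}) = -80$ mV and $\Phi(\varphi_{peak}) = +20$ mV for the
protocol actually used in the field runs). Time scaling
$t = \beta_t \tau$ with $\beta_t = t_\beta[1 - \tau_0 (t_a - t_0)/(t_1 -
t_0)]$ and $t_a = t_\alpha (1 - Z/Z_{\mathrm{apex}})$: the five constants
are tuning parameters; defaults $t_\beta = 12.9$ ms, $\tau_0 = 0.3$,
$t_0 = 0$, $t_1 = 30$ ms, $t_\alpha = 30$ ms make the action-potential
duration fill the systolic interval (about 300–380 ms) with a mild
apicobasal repolarization gradient; all five are exposed in the
configuration.

**Numerics.** P1 elements, lumped mass, semi-implicit stepping (implicit
diffusion via a prefactorized Cholesky operator, explicit reaction in local
$\tau$ time). The uniform resting state is an exact fixed point. On
anisotropic tetrahedral meshes the plain P1 stiffness matrix has positive
off-diagonal entries, violates the discrete maximum principle, and lets the
potential dip below its physical range near sharp fronts (about 1 mV at the
default resolution, shrinking under refinement). The operator therefore
lumps positive off-diagonal stiffness entries into the diagonal by default
(`monotone = TRUE`), preserving row sums (constant fields remain in the
kernel) and restoring an M-matrix at the cost of some crosswind smearing;
axis-aligned cable benchmarks are unaffected. The stimulus default follows
the initial-condition protocol: endocardial septal/apical patch nodes start
at $-10$ mV; a 2–3 ms current-pulse mode is also available.

# Active stress

First-order activation dynamics
$\dot\sigma_a = \varepsilon(\Phi)[k(\Phi - \Phi_r) - \sigma_a]$ with the
Gompertz delay function $\varepsilon(\Phi) = \varepsilon_0 +
(\varepsilon_1 - \varepsilon_0)\exp(-\exp(-\zeta(\Phi - \Phi_t)))$. This
form has the two-rate limits the construction intends ($\varepsilon_0$ at
rest, $\varepsilon_1$ when depolarized); an alternative
$(\varepsilon_0 + \varepsilon_1)$ amplitude convention found in some
transcriptions is selectable for audit (`form = "summed"`). The update is the exponential integrator, exact for constant
potential over a step and unconditionally stable.

Rate defaults $\varepsilon_0 = 0.008$/ms, $\varepsilon_1 = 0.08$/ms,
$\zeta = 0.1$/mV, $\Phi_t = -20$ mV give a contraction onset time constant
of about 12 ms and a slow decay at rest, so peak active stress lags peak
potential as excitation–contraction physiology requires. The saturated gain
defaults to $k = 3$ kPa/mV (saturated stress 300 kPa over the 100 mV range);
the ejection-fraction calibration (`calibration_suite()`, a bounded
bisection on $k$) is the normative definition of $k$, and the default is
only a starting point.
Distribution weights default to $\eta_1 = 0.1$ (fiber), $\eta_2 = 0.2$
(sheet), $\eta_3 = 0.6$ (sheet-normal), the values used in the torsion
validation sweep; the active tensor uses the *material* fiber triad.

# Passive materials

Myocardium:
$$W = \tfrac{\mu}{2}(I_1 - 3) - \mu \ln J + \tfrac{\lambda}{2}\ln^2 J +
\tfrac{k_1}{2k_2}\sum_\alpha\left[e^{k_2 \bar E_\alpha^2} - 1\right],\qquad
\bar E_\alpha = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_{4\alpha} - 1).$$
A variant isotropic part sometimes transcribed as
$\tfrac{1}{2}\mu(\bar I_1 - 1) + \mu\ln J$ does not have a stress-free
reference; the classical compressible neo-Hookean form above satisfies
$W(I) = 0$ and $S(I) = 0$ exactly and is the default, with the variant
selectable for audit (`form = "variant"`). Fiber terms are recruited in tension only
($\bar I_4 \ge 1$), the usual HGO convention. Default parameters:
$\mu = 0.5$ MPa, $\lambda = 0.2$ MPa,
$k_1 = 1.685$ kPa, $k_2 = 15.779$, $0 \le \kappa \le 1/3$. The matrix
modulus is stiff relative to the fiber stiffness and to physiological
myocardium; the defaults are kept as given and configurable, and the active
gain calibration absorbs the consequence at the organ scale (small strains
at desk scale, a few percent, against the tens of percent a compliant wall
would give).

Leaflets: $W = C_{10}[e^{C_{01}(\bar I_1 - 3)} - 1] + $ fiber part with two
in-plane families (radial and circumferential) $+ \tfrac{\kappa_{vol}}{2}
(J-1)^2$. The $(C_{10}, C_{01})$ pair is dimensionally ambiguous as usually
quoted; the default takes $C_{10} = 3.47$ kPa as the stress-like factor with
the swap available. The volumetric penalty enforces near incompressibility,
which the exponential law alone does not.

Analytic second Piola–Kirchhoff stresses ($S = 2\,\partial W/\partial C$
with the isochoric-invariant chain rule) are verified against central finite
differences of $W$ with respect to the Green–Lagrange strain to better than
$10^{-6}$ relative on random admissible deformations ($J \in [0.8, 1.2]$).

# Mechanics

Total-Lagrangian P1 tetrahedra with linear displacement interpolation, at
desk-scale element counts. Element tangents are assembled by forward differences
of the batched element residual (12 vectorized passes); the follower
endocardial pressure load has an analytic tangent (cross-product skew
blocks). Newton iterations cap the step at 15% of the mesh extent to avoid
element inversion, with load-step cutbacks as the fallback. Linear tets pass
the patch test exactly and reproduce single-element material-point stresses
to machine precision; the pressurized thick-sphere benchmark agrees with
the linear-elasticity (Lamé) solution to about 3% at the test resolution
(tolerance set at 5%).

The end-diastolic state is treated as a stress-free effective reference: a
short quasi-static equilibration at the end-diastolic pressure (default
10 mmHg) with zero active stress defines $V_{ED}$; no unloaded-configuration
recovery is attempted. The basal plane is rigidly fixed. The driver uses
the quasi-static solver by default — with millisecond coupling steps and a
strongly damped tissue the inertial terms are negligible at desk scale —
and an implicit Newmark integrator (average acceleration,
$\beta = 1/4, \gamma = 1/2$, mass-proportional damping) is provided and
tested for dynamic runs.

Kinematic outputs: apex planar trajectory and vertical displacement;
torsion as the ring-averaged circumferential rotation of an apical node
band minus a basal band, *normalized by the bands' axial separation to the
full apex–base span*, so a twist field linear in $Z$ with angle $T$ at the
apex reports exactly $T$ and rigid rotations report zero (there is no single standard definition of the torsion metric); maximum principal Green–Lagrange
strain (closed-form symmetric eigenvalues, vectorized).

# Afterload and the 0D cavity surrogate

Two-element Windkessel with characteristic resistance:
$C\,\dot P_{Wk} + P_{Wk}/R_p = Q_{Ao}$, $P_{Ao} = Q_{Ao} R_c + P_{Wk}$,
integrated by classical RK4 (measured convergence order 4.0 on the
zero-flow decay), with $P_{Ao}$ evaluated from the same-step $P_{Wk}$.
Default constants: $C = 3.128$ mL/mmHg, $R_p = 0.6652$,
$R_c = 0.0914$ mmHg·s/mL; the 80/120 mmHg anchors initialize $P_{Wk}$ and
sanity-check outputs without being enforced.

Valve logic: the cavity is isovolumic (volume pinned at $V_{ED}$ by a
clamped-secant pressure solve) until the cavity pressure reaches the stored
Windkessel pressure; during ejection the coupling fixed point
$P_{cav} = P_{Ao}(Q)$ with $Q = -\dot V$ is solved per step by a clamped
secant (the map is monotone), subiterating to a relative tolerance of
$10^{-4}$ with at most 20 subiterations; flow reversal closes the valve and
ends the systolic run. Because the Windkessel feeds on the flow produced by
the mechanics, the driver's ordering is EP → active stress → mechanics →
0D update, with the stretch field of the previous mechanical state feeding
the stretch current — this ordering is a design choice of the staggered scheme and is recorded
here.

# What the built-in cases do and do not exercise

The case cards are the study conditions: EDV, long axis, internal diameter,
wall-thickness targets, and qualitative outflow modifications.
Generated geometries reproduce the card numbers (EDV to 1%, long axis to
0.5%, thickness statistics to a few percent) and the fiber rule exactly.
What passing tests on these idealized geometries do *not* show: behaviour
on patient-specific anatomies (papillary muscles, trabeculae and the mitral
apparatus are excluded by construction), diastolic filling (the simulation
starts at end diastole and ends at valve closure), Purkinje-mediated
activation (endocardial foci stand in for it), and 3D hemodynamic
quantities (wall shear stress, leaflet stresses) that require the excluded
FSI stages. Desk-scale ejection fractions with the stiff default matrix
modulus and the default gain are far below physiological values; the
package treats EF as a calibration target for $k$ rather than a prediction,
and its tests assert the monotone trends (EF rising with $k$, torsion with
$\eta_3$) rather than absolute magnitudes.

# Numerical choices and degenerate inputs

* Meshes: conforming Kuhn splits; degenerate pole tetrahedra dropped;
  orientation fixed before boundary extraction; every generated boundary
  facet carries exactly one tag.
* Cavity volumes: divergence theorem on the closed endocardial surface;
  cross-checked against ray-casting Monte-Carlo (0.5%) in tests.
* Laplace/monodomain: Dirichlet rows eliminated; zero-gradient elements and
  pole-degenerate triads repaired from nearest non-degenerate neighbours
  (logged in the return value by construction).
* Tolerances: EDV calibration 0.5% (bounded at 12 iterations, error on
  non-convergence); Newton relative residual $10^{-6}$; staggered
  subiterations $10^{-4}$, max 20; monodomain dt 0.25 ms default with the
  coupling step bounded to the 1 µs–1 ms band.
* Ties/edge cases: apex pole handled by collapsed nodes; $t_1 = t_0$ and
  $\varphi_{max} = \varphi_{rest}$ rejected; non-positive Jacobians abort
  the constitutive evaluation and trigger load-step cutbacks upstream.

# Known limitations

Quasi-static mechanics by default (Newmark available but slower); the
stretch current uses the previous step's deformation (one-step lag) rather
than subiterating EP–mechanics to convergence; linear tetrahedra lock near
incompressibility, so the leaflet volumetric penalty is kept moderate; the
0D surrogate cannot represent intracavitary pressure gradients, vortices or
valve dynamics; and the coarse default meshes under-resolve the excitation
front (the monotone operator keeps the potential within its physical range
regardless, and cable tests at proper resolution verify front physics).
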
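---
title: "Models and numerics behind coilflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind coilflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coilflow simulates pulsatile blood flow through a two-dimensional
bilobed (double-dome) sidewall aneurysm, with endovascular coil packing
represented as a porous medium, and post-processes the wall quantities
that drive clinical interest in aneurysm rupture and treatment: wall
shear stress (WSS), its time average (TAWSS), the oscillatory shear
index (OSI), wall pressure, and the average inflow velocity across the
aneurysm neck. This vignette is the package's own account of the
physical model, every tunable that matters, the numerical scheme, and
what the synthetic geometry can and cannot say about patient anatomy.

## The flow model

Blood is treated as an incompressible, laminar, shear-thinning fluid.
The momentum and continuity equations are solved in 2D:

$$\rho\left(\partial_t \mathbf u + \mathbf u\cdot\nabla\mathbf u\right)
 = -\nabla p + \nabla\cdot\left[\mu(\dot\gamma)\left(\nabla\mathbf u +
 \nabla\mathbf u^{T}\right)\right] + \mathbf f, \qquad
 \nabla\cdot\mathbf u = 0,$$

with $\rho = 1060$ kg/m^3 (whole blood) and a body-force term
$\mathbf f$ that carries both the vessel wall and the coil:

* **Vessel wall (Brinkman volume penalization).** Inside the solid,
  $\mathbf f = -(\rho/\epsilon)\,\mathbf u$ with penalization time
  $\epsilon = 10^{-5}$ s. Residual slip inside the wall scales linearly
  with $\epsilon$ (verified by the test suite); at the default value it
  sits three orders of magnitude below the peak inlet velocity.
* **Coil (Darcy sink).** Inside the coil-filled sac,
  $\mathbf f = -(\mu/K)\,\mathbf u$. The permeability follows the
  Kozeny-Carman granular closure
  $K = d_w^2\varphi^3 / \left(180(1-\varphi)^2\right)$
  with the coil wire diameter $d_w = 0.25$ mm as grain diameter.
  $K$ is strictly increasing in the porosity $\varphi$, so the denser
  packing ($\varphi = 0.79$) damps the sac flow more than the looser
  one ($\varphi = 0.89$): $K = 3.9\times10^{-9}$ vs
  $2.0\times10^{-8}$ m^2. No Forchheimer (inertial) term is included:
  the pore-scale Reynolds number of the seepage flow is small, and
  Darcy is the minimal closure that fixes the porosity ordering
  unambiguously.

## Rheology

The viscosity is a regularized Casson law with hematocrit-dependent
yield stress:

$$\mu = 0.1\left[\sqrt{\eta} + \sqrt{\tau_y\,
  \frac{1-e^{-m\dot\gamma}}{\dot\gamma}}\right]^2,
  \qquad \tau_y = (0.625\,H)^3 .$$

The exponential factor (Papanastasiou-type regularization) keeps $\mu$
finite and continuous at $\dot\gamma = 0$, where
$(1-e^{-m\dot\gamma})/\dot\gamma \to m$.

Unit reading: the leading $0.1$ is taken as the poise-to-Pa·s
conversion, so $\eta$ is the Casson plastic viscosity in poise,
$\tau_y$ is in dyn/cm^2, and $\mu$ comes out in Pa·s. This reading
makes the printed constant physically meaningful and gives
$\mu_\infty = 0.1\,\eta \approx 3.5$ mPa·s — the standard high-shear
viscosity of blood — with the default $\eta = 0.035$ poise.

Defaults and their rationale:

| parameter | default | unit | why |
|---|---|---|---|
| $H$ | 0.35 / 0.45 | — | representative adult female / male hematocrits; the study conditions |
| $\eta$ | 0.035 | poise | $\mu_\infty = 3.5$ mPa·s; constant across $H$, so the hematocrit acts only through $\tau_y$ |
| $m$ | 100 | s | standard regularization magnitude; large enough that the yield plateau is felt, small enough to stay smooth |
| $\rho$ | 1060 | kg/m^3 | whole blood |

A `newtonian` switch forces $\tau_y = 0$ for the analytic benchmark
runs. The shear-rate magnitude is the standard second invariant
$\dot\gamma = \sqrt{2\,D\!:\!D}$ of the rate-of-strain tensor.

Because $\eta$ is constant across $H$, the *relative* viscosity
contrast between $H = 0.45$ and $0.35$ shrinks with shear rate (the
$\tau_y$ term decays like $1/\dot\gamma$): at wall shear rates of
order $10^2$–$10^3$ s$^{-1}$ it is a few percent. The *absolute* WSS
contrast still peaks at the high-shear cardiac phases. Analyses of the
hematocrit effect in this package therefore compare absolute
differences alongside percentages; an optional hematocrit-dependent
$\eta$ is deliberately out of scope.

## Synthetic geometry and inlet waveform

The geometry generator replaces patient imaging with a parametric
level-set construction: a straight parent channel (width 4 mm — an
internal-carotid scale) spanning the domain, and a sac formed by two
overlapping discs (radii 3 and 2.4 mm, center offset 3.5 mm along a
tilted sac axis) opening into the channel through a 3 mm neck chord.
The union of slab and discs is represented by the pointwise minimum of
their signed distances on a cell-centered Cartesian grid (exact signed
distance away from junctions, Lipschitz everywhere); the wall chain is
the traced zero contour, ordered counter-clockwise, with inward normals
from the level-function gradient. The two-dome shape produces the
features under study: a jet through the neck, a strong recirculation in
the lower (proximal) dome, and a weak, sheltered upper (distal) dome
separated by a visible waist.

The inlet waveform is an analytic stand-in for a carotid flow trace: a
baseline plus two periodic von-Mises bumps (systolic pulse and a
smaller dicrotic wave), affinely scaled to `u_dia` = 0.15 and `u_peak`
= 0.55 m/s over a 0.8 s period with a 35% systolic fraction —
representative ICA values chosen once for reproducibility. The dicrotic
wave matters structurally: it creates the local minimum after maximum
deceleration that defines the fourth cardiac phase marker. The four
markers are detected numerically: `t_peak_sys` = argmax $u$;
`t_max_accel` / `t_max_decel` = extrema of $du/dt$ in the half-period
before/after the peak; `t_early_dia` = first local minimum after
maximum deceleration (the notch). "Early diastole" has no unique
definition; the first-local-minimum rule is deterministic and
detectable on any single-peak waveform with a notch. A constant signal
has no phases and is rejected.

What the generator does **not** emulate: three-dimensionality (no
secondary/swirling flow, no out-of-plane neck jet), vessel curvature
upstream of the sac, wall compliance, and patient-specific lumen
irregularity. Consequences observed in this package's own runs: the 2D
uncoiled sac sustains a steady-signed recirculation whose wall shear
rarely changes sign (OSI near zero), unlike typical 3D patient
geometries where the sac shear is oscillatory to begin with. Passing
directional tests here demonstrates the mechanisms (jet damping by the
coil, viscosity scaling of WSS, shear concentration at the neck), not
patient-level magnitudes.

## Discretization

* **Grid.** Uniform staggered (MAC) Cartesian grid: pressure and
  viscosity at cell centers, velocity components on faces. The study
  default is 192 x 112 cells (dx = 0.125 mm) over a 24 x 14 mm domain.
* **Projection.** Incremental pressure projection: the tentative
  momentum step includes the current pressure gradient; a Poisson
  equation for the pressure increment restores a discretely
  divergence-free field every step (max divergence at rounding level,
  ~1e-12 of $u/\Delta x$). The non-incremental variant is *wrong* here:
  with sinks treated pointwise-implicitly it rescales the effective
  Darcy drag by $1/(1+\Delta t\,\sigma)$, which the Darcy benchmark
  exposes immediately.
* **Poisson solver.** Direct: cosine (DCT-II) eigen-transform across
  the channel (Neumann walls) and Thomas tridiagonal sweeps along it,
  with $p = 0$ at the outlet face. Exact to rounding, so the configured
  tolerance contract is trivially met; no iteration counts to tune.
* **Advection.** Explicit second-order upwind, first-order fallback at
  stencil boundaries. Time step from the advective CFL condition (CFL
  0.4 against 1.1 x the peak parabolic inlet velocity).
* **Diffusion.** Stress form with variable viscosity (cell-centered
  normal stresses, node-centered shear stresses). The diagonal of the
  diffusion operator is treated implicitly (point-implicit): this is
  unconditionally stable for diffusion, reduces to the explicit scheme
  when $\mu\Delta t/(\rho\Delta x^2)$ is small (all benchmark regimes),
  and only damps the near-stagnant, high-viscosity sac cells where the
  regularized Casson $\mu(0) \approx 0.28$ Pa·s would otherwise impose
  a ~70x smaller time step.
* **Walls at sub-cell accuracy.** Faces are penalized iff their center
  lies in the solid. At nodes where exactly one of the two adjacent
  faces is solid, the shear stencil replaces the solid value by the
  no-slip point located by linear interpolation of the face-sampled
  level function (clamped to [0.3, 1] cells), with the implicit
  diagonal adjusted to match. Without this, the effective wall sits
  half a cell inside the solid and the probe-based WSS carries a
  ~50% resolution-independent bias; with it, the plane-channel WSS
  benchmark is accurate to 0.5%.
* **Sinks.** Penalization and Darcy drag are pointwise implicit —
  no stiffness limit from small $\epsilon$ or small $K$.
* **Boundary conditions.** Parabolic inlet profile scaled by the
  instantaneous waveform mean (ramped over the first 5% of cycle 1 to
  avoid an impulsive start); zero-gradient outlet velocity with a
  global mass correction and reference pressure 0; no-slip elsewhere
  via penalization.

## Post-processing definitions

* **WSS probe scheme.** At each wall point, tangential velocity is
  sampled at 1.5 and 3 cell sizes along the inward normal; the wall
  gradient is the one-sided second-order difference through
  $u_t(0)=0$; $\tau_w = \mu(|\partial_n u_t|)\,\partial_n u_t$, signed
  by the chain orientation. Probes that leave the lumen mark the point
  invalid; invalid points are excluded from maxima and counted.
* **OSI.** The field-standard oscillatory shear index
  $\mathrm{OSI} = \tfrac12\left(1 - |\int\tau_w\,dt| / \int|\tau_w|\,dt\right)$
  over the final cycle, periodic trapezoidal quadrature, defined as 0
  where the shear is identically zero. "OSI at a phase instant" is the
  same quotient accumulated from the cycle start up to that instant
  (a cycle integral has no other meaningful per-instant reading).
* **OSI noise floor.** OSI is degenerate where the shear magnitude
  sits at numerical noise (its sign is arbitrary), which saturates a
  naive spatial maximum at 0.5. OSI maxima are therefore taken over
  wall points carrying at least 0.5% of the run's peak TAWSS. The
  floor is relative, so it needs no re-tuning across conditions.
* **Field of view.** Maxima are taken over the sac wall plus the
  parent-vessel wall within two channel widths of the neck — the
  natural region of interest around the aneurysm; the synthetic
  inlet/outlet end caps are always excluded.
* **Neck metric.** Velocity magnitude averaged over 64 uniform samples
  of the neck chord (bilinear interpolation).
* **Comparisons.** Percentage reduction $100(A-B)/A$ with the
  less-damped / higher-hematocrit state as reference A: coiling chains
  uncoiled → $\varphi$ 0.89 → 0.79 at fixed $H$, and $H$ 0.45 → 0.35
  at fixed coiled porosity.

## Study protocol and problem sizes

Each condition integrates three cardiac cycles from rest; the first two
are discarded as start-up transient and all indices come from the third.
The per-cycle peak-systolic maximum WSS differs between cycles 2 and 3
by well under 1%, which is the quantitative justification for the
three-cycle protocol. The default study crosses $H \in \{0.35, 0.45\}$
with {uncoiled, $\varphi=0.89$, $\varphi=0.79$} — six conditions on the
shared geometry and waveform, fully coiled sac (`fill_fraction = 1`)
for the coiled runs.

Problem sizes used by the shipped tests and the acceptance script, all
chosen as the package's standard working resolutions: the six-condition
study at 192 x 112 cells; one protocol-verification run at 256 x 150;
benchmarks with 40–64 cells across the channel gap; the convergence
ladder below.

## Grid convergence

The harness re-solves frozen-inflow steady states at the
maximum-acceleration and peak-systolic inflow levels on a four-level
ladder and reports the neck metric per level (steady solves are an
order of magnitude cheaper than full cycles and discriminate grids just
as well; the metric is steady to 0.2% after ~0.5 s of settling). Two
numerical-verification choices matter here, both discovered during
method validation:

* **Grid-commensurate walls.** With arbitrary cell counts the channel
  wall line lands at varying sub-cell offsets per level; since the
  neck metric samples a steep shear layer, this produces non-monotone
  ~5% scatter that says nothing about convergence. The default wall
  margin (1 mm) and ladder (nx = 120, 168, 216, 312; spacing ratios
  1.29–1.44) put both channel walls exactly on face lines at every
  level.
* **Asymptotic range.** The metric converges at first order (the
  immersed-boundary wall representation) and enters its asymptotic
  range near nx ≈ 216; the ladder is placed so its finest pair lies
  inside it (measured fine-vs-very-fine change ≈ 1.3%). A coarser
  ladder would report pre-asymptotic differences of ~5% and flag a
  false failure of mesh independence.

## Degenerate inputs and tie-breaks

Zero dome radii give a plain straight channel (empty sac, empty coil
mask). Non-overlapping domes, a neck wider than the lower dome chord,
fewer than 6 cells across the neck, constant waveforms, porosity at
exactly 0 or 1, and sub-16-sample wall series are all rejected with
specific errors. The coil front at partial fill is placed by ranking
sac cells along the sac axis (ties broken by index order — fill counts
are exact to one cell). Phase-marker scans are cyclic, so markers wrap
correctly across the cycle boundary; marker times are reported
unwrapped (monotone) starting at maximum acceleration.

## Known limitations

* 2D: no secondary flow, no out-of-plane jet impingement; magnitudes
  (WSS in Pa, reduction percentages) are not patient-scale and the
  package reports them as its own, not the clinical, values.
* The hematocrit effect enters only through the yield stress, so
  percentage WSS contrasts between hematocrits are small (~1–3%) and
  largest at *low*-shear phases; the absolute contrast follows the
  expected high-shear ordering.
* In this 2D surrogate the uncoiled sac shear is steady-signed, so
  coiling *raises* the (noise-floored) maximum OSI rather than
  lowering it — the opposite of what patient-geometry studies report
  for the max OSI under coiling. The package reports the measured
  direction; see the failing directional assertion in the acceptance
  suite, which is left in place deliberately.
* First-order spatial convergence at immersed walls; the wall-probe
  WSS scheme recovers second-order accuracy on flat walls but corners
  remain first-order.
* One-way coupling only: wall loads are exported for an external
  structural solver; no wall deformation feeds back into the flow.
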
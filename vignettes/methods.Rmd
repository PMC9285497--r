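---
title: "Modelling temperature-controlled RF ablation of osteoid osteoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature-controlled RF ablation of osteoid osteoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

Osteoid osteoma is a benign bone tumour whose painful core (the *nidus*,
modelled here as a 1 cm sphere) is routinely destroyed by radiofrequency
ablation: a gauge-17 electrode with a 7.5 mm uninsulated active tip is
placed in the nidus and Joule heating at ~500 kHz cooks the surrounding
tissue while a generator holds the electrode-tip temperature at a set
control value. `ooablate` simulates this procedure as a coupled
electric–thermal problem on a 2-D axisymmetric domain whose symmetry axis
runs along the electrode.

**Electric problem.** At RF frequencies the tissues of interest are
essentially resistive, so the potential obeys the quasi-static equation
$\nabla\cdot\sigma_i(T)\nabla V = 0$ with the applied r.m.s. voltage on the
electrode surface, zero volts on the outer boundary (the grounding pad),
and natural zero-flux on the symmetry axis. The heat source is
$Q_{RF} = \sigma_i |\nabla V|^2$.

**Thermal problem.** Heat spreads by the Pennes bioheat equation written in
enthalpy form so that vaporization, were it ever reached, is handled by the
apparent-heat-capacity method:

$$\frac{\partial h}{\partial t} = \nabla\cdot k_i(T)\nabla T + Q_{RF} - Q_p,
\qquad Q_p = \omega_i\,\rho_b c_b (T - T_b).$$

The perfusion sink $Q_p$ is tissue-dependent and is switched to exactly
zero in an element once its cells die. The outer boundary is clamped at
body temperature (37 °C; 35 °C in the ex-vivo style validation layout) and
the axis is flux-free.

**Temperature-dependent properties.** Electrical conductivity rises by
1.5 % of its 37 °C baseline per degree up to 100 °C, then drops linearly
over (100, 105] °C to the vaporized value 0.01 S/m. Thermal conductivity
rises by 0.003 W m⁻¹ K⁻¹ per degree and is capped at its 100 °C value (a
configuration switch `model_constants(d_k_relative = TRUE)` provides the
alternative relative reading of that slope; the absolute reading is the
default because the slope is quoted as a bare conductivity change). The
volumetric enthalpy has a sensible branch $\rho_i c_i (T-37)$, a latent
ramp over (99, 100] °C that deposits $\rho_i h_{fg} C_i$ in total ($C_i$
the water fraction, $h_{fg} = 2.25\times10^6$ J/kg), and a vapor branch
with slope $\rho_{vap} c_{vap}$. The latent ramp includes the density
factor so that all three branches share volumetric units; a reading
without it would be dimensionally inconsistent with the sensible branch.
Blood density and specific heat are not tissue-table quantities; the
package uses the RF-ablation-modelling standards $\rho_b = 1050$ kg/m³ and
$c_b = 3617$ J/(kg K) and exposes both in `model_constants()` so
sensitivity to the choice can be tested.

**Control.** The generator is modelled as a discrete PI controller on the
electrode r.m.s. voltage, $V = K_p e + K_i \int e\,dt$ with
$e = T_{target} - T_{tip}$, gains $K_p = 1.15$ V/K and $K_i = 0.06$ V/K/s,
a rectangle-rule integral at the thermal step interval, output clamped at
0 V, and the integrator frozen while the output clamps (anti-windup; the
physical generator cannot extract energy, and windup would distort the
transient). The tip sensor is the node at the distal apex of the active
tip on the symmetry axis — the thermocouple position of a non-cooled
electrode; the metal (k = 18 W/m/K) keeps the tip nearly isothermal.

**Cell death.** Thermal damage follows first-order Arrhenius kinetics with
osteocyte parameters $A = 8.99\times10^{133}$ s⁻¹ and
$\Delta E = 838$ kJ/mol: $\Omega(t) = \int_0^t A e^{-\Delta E/R T}\,d\tau$.
$\Omega = 4.6$ (99 % probability of cell death) defines the ablation
boundary; an element whose mean nodal damage crosses the threshold loses
its perfusion permanently. The *cell-death radius* — the outcome variable —
is the distance from the centre of the active tip to the outermost
$\Omega = 4.6$ crossing along the rays perpendicular (+r) and parallel
(+z) to the electrode, located by sub-element sampling (0.05 mm) with
linear interpolation. The rate is evaluated in log space
($\ln A - \Delta E/RT$, then exponentiated) because the frequency factor
overflows naive intermediate arithmetic. Every run ends with a 5-minute
zero-voltage cooldown during which damage keeps accruing while the tissue
is still hot.

## Geometry and meshing

Three anatomical configurations are generated in the (r, z) half-plane,
plus a validation layout (`build_scenario()`):

* **a** — nidus wrapped in a 1 mm sclerotic rim, inside trabecular bone,
  with a 4 mm cortical wall at r = 7–11 mm and muscle beyond;
* **b** — no sclerosis; nidus in trabecular bone with the cortical wall
  1 mm away (r = 6–10 mm);
* **c** — intracortical nidus: a cortical slab (|z| ≤ 10 mm, r ≤ 36 mm)
  surrounds the tumour with muscle beyond, so muscle sits closest in the
  direction parallel to the electrode;
* **validation** — the nidus sits behind a parameterisable cortical
  lamella (default 3 mm) with soft tissue below the periosteum plane and
  three probes at 0, 5 and 10 mm from it; the run starts at 35 °C with a
  95 °C control temperature for 400 s.

Clinical imaging of these archetypes does not fix most construction
dimensions, so the sclerosis thickness (1 mm), cortical wall thickness
(4 mm), trabecular gap (1 mm), the cortical-slab extent of geometry (c)
and the 40 mm domain half-size are declared package defaults — all
overridable through `build_scenario(..., overrides)`. The cortical wall of
(a) and (b) spans the full domain height, consistent with a long-bone
shaft much longer than the 80 mm simulated window. The 17-gauge electrode
is modelled with the standard 1.473 mm outer diameter; the active-tip
midpoint coincides with the nidus centre and the plastic-insulated shaft
leaves through the domain top.

Meshing (`generate_mesh()`) uses a graded tensor-product grid whose lines
contain every straight tissue interface exactly, split into triangles and
then made conforming to the circular nidus/sclerosis interfaces by
snapping near-circle vertices onto the circle and chord-splitting the
triangles the circle still crosses. Element region labels come from
centroid classification; per-region mesh areas match the closed-form
region areas to well under 1 %. The resolution ladder
coarse/medium/fine/finest maps to near-electrode characteristic lengths
0.4/0.3/0.2/0.1 mm, with a mid-resolution band out to ~12 mm covering the
region the cell-death isoline can reach and coarsening to 2.5–4 mm at the
far field. Everything is deterministic: the same geometry and level always
reproduce the same mesh bit-for-bit.

## Discretization and numerics

Axisymmetric P1 triangles with the $2\pi r$ volume weight (one-point
centroid quadrature for stiffness; row-sum lumped mass,
$\int r\,\phi_a\,dA = A(2r_a + r_b + r_c)/12$). The electrode metal is
excluded from the electric weak form and every metal node carries the
applied voltage as Dirichlet data; the plastic shaft stays in the solve
with its 10⁻⁵ S/m conductivity, which insulates it. Per-element
coefficients are evaluated at the element-mean nodal temperature.

Each heating step performs, in order: tip-temperature read → controller
update → electric solve with the current $\sigma(T)$ → one backward-Euler
step of the enthalpy equation → damage update. The nonlinear thermal step
is resolved by Picard iteration (tolerance max |ΔT| < 10⁻³ °C, at most 5
iterations) started from a linear extrapolation of the previous step, so
a settled simulation typically needs one solve per step. Sparse systems
are solved by CHOLMOD Cholesky; because the coefficients drift slowly, a
recent factorization is kept and applied with iterative refinement to a
10⁻¹⁰ relative residual, and refactorized only when refinement stalls —
the refined solution is identical (to the stated residual) to a direct
solve, only cheaper. Time steps are 0.25 s during heating (also the
controller interval) and 1 s during cooldown; halving the heating step
moves the final radius by well under 1 %, which is the justification for
the default.

Numerical behaviour is certified against independent references rather
than asserted: the annulus potential closed form (max error < 0.5 %, and
observed second-order convergence), the fundamental conduction eigenmode
of a clamped cylinder (decay constant within 1 %, with the Bessel zero
located by root bracketing and cross-checked by a 1-D radial
finite-difference solver), a per-step discrete energy balance (< 1 %
residual between the enthalpy change and source − sink − boundary flux),
and fine-step quadrature of the damage integral (< 0.5 %).

## Study pipeline and problem sizes

`run_simulation()` executes one closed-loop run;
`run_temperature_time_grid()` the scenario × {70, 80, 90} °C grid with
900 s heating + 300 s cooldown; `run_sensitivity()` re-runs a
configuration over nidus conductivities {0.08, 0.22, 0.5} S/m and
perfusion coefficients {26, 48, 70}×10⁻⁴ s⁻¹ and reports percent changes
of the final perpendicular radius against the baseline table;
`mesh_convergence_study()` walks the resolution ladder and flags
convergence when successive radii change by < 1 %; `extract_profiles()`
samples $Q_{RF}$ and $T$ along the perpendicular ray and locates the
resistive-heating peaks; `run_validation_scenario()` reproduces the
ex-vivo protocol shape. Radii and traces are recorded every 5 s, with
field snapshots at 30 s, end of heating and end of cooldown.

The package's own studies run the full 900 + 300 s protocol at the `fine`
level (≈10⁴ nodes) for single-run questions and at `medium` with a 0.5 s
step for the sensitivity sweep; the behavioural test suite uses 240 + 120 s
runs on `coarse` meshes, long enough for the controller to settle and the
ablation to clear the nidus. These sizes are the package's default trade-off
between discretization error (bounded by the convergence studies above) and
turnaround.

## What the synthetic scenarios do and do not capture

The scenario factory is the synthetic stand-in for patient anatomy: it
reproduces the topology of the three archetypal configurations (which
tissue touches the tumour, where the cortical wall and muscle sit) with
idealized shapes — a spherical nidus, a rectangular cortical wall, an
axisymmetric domain. Passing tests therefore demonstrate the model's
behaviour under these idealized conditions, not on image-derived
anatomy: curved long-bone geometry, partial sclerotic rims, marrow
heterogeneity and patient-specific electrode placement are out of scope,
as are 3-D effects that break rotational symmetry. The validation layout
reuses nidus properties for the agarose-filled cavity of the ex-vivo
experiment it mimics (the gel's own properties are not part of the tissue
table) and is meant for qualitative probe-trace comparison only.

## Observed model behaviour worth knowing

* With the printed gains the tip settles into ±1 °C of the target in all
  scenarios; the transient overshoot is ~2.3 °C in geometries (a)/(b) but
  ~5 °C in (c), whose non-perfused, electrically insulating cortical
  surround makes the thermal plant slower. The gains are study constants
  and are deliberately not retuned per scenario.
* The perpendicular radius orders b < a < c at fixed control temperature
  (trabecular bone next to the tumour acts as a heat sink; cortical bone
  as an oven). The parallel radius shows b marginally above a in this
  implementation because b's cortical wall sits 1 mm closer to the shaft.
  Orderings are therefore asserted on the perpendicular radius, the
  study's outcome variable.
* The parallel ray runs along the axis through the electrode and its
  plastic shaft, so the "parallel radius" reads the damage field inside
  the insulation column at small heights; it is reported as measured from
  the tip centre, consistent with the perpendicular ray.
* Nidus perfusion has almost no effect on the final radius (< 0.01 % over
  the tested range) because the ablation engulfs the tumour — and shuts
  its perfusion off — within the first minute of heating.

## Known limitations

No impedance- or power-limited generator modes, no electrode cooling, no
metabolic heat, no tissue shrinkage or water-loss dynamics beyond the
enthalpy method, and no alternative damage models (e.g. CEM43). The
quantitative ex-vivo temperature comparisons that motivated the validation
layout require digitized experimental curves that are not shipped; the
package only checks the protocol's qualitative signatures (probe ordering,
band holding, monotone decay with distance).
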
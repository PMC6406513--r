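---
title: "Modelling bortezomib + oncolytic-virus combination therapy in glioblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bortezomib + oncolytic-virus combination therapy in glioblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(btzov)
```

## The model

`btzov` simulates glioblastoma treatment that combines the proteasome
inhibitor bortezomib (BTZ) with an oncolytic herpes simplex virus (oHSV),
on two coupled scales.

**Intracellular scale.** Four concentrations govern the cell-death program:
IkB (S), the NF-kB--Bcl2 complex (F), Bax (A) and RIP1 (R), in µM with time
in hours:

\[
\begin{aligned}
dS/dt &= k_{SB}\,B\,\frac{k_{12}}{k_{12}+k_{13}[\mathrm{oHSV}]}
        + \frac{k_1 k_2^2}{k_2^2 + k_5 F^2} - \mu_s S,\\
dF/dt &= c_1 + \frac{k_3 k_4^2}{k_4^2 + k_6 S^2} - \mu_f F,\\
dA/dt &= c_2 + \frac{k_7 k_8^2}{k_8^2 + k_9 F^2} - \mu_a A,\\
dR/dt &= k_{10} + k_{11}[\mathrm{oHSV}]\,F - \mu_r R.
\end{aligned}
\]

BTZ (dimensionless level \(B\)) drives IkB production; IkB and NF-kB--Bcl2
repress one another through quadratic Hill terms; NF-kB represses Bax; and
RIP1 is induced when both virus and NF-kB are present. The virus enters
through the saturating switch \([\mathrm{oHSV}] = v/(k+v)\), treated as a
binary 0/1 in steady-state analysis and as the smooth ratio in coupled
spatial runs. Outputs are reported scaled by reference concentrations
(F* = 0.5, A* = 0.1, R* = 5 µM, S* = 0.05 µM).

Scaled steady states classify a cell by strict thresholds (all 1.7 by
default): anti-apoptotic (F high, A and R low), apoptotic (A high, F and R
low), necroptotic (F and R high, A low). Sweeping \(B\) produces an on-off
switch: NF-kB collapses and Bax rises across a crossover near
\(B \approx 0.46\):

```{r bifurcation}
cv <- bifurcation_scan(seq(0, 1.5, length.out = 61))
plot(cv)
crossover()
```

Because Bax clears slowly (\(\mu_a \approx 0.022\,\mathrm{h^{-1}}\),
a ~46 h timescale), a periodically injected BTZ level
\(B(t) = 0.25\cos(\pi t/250) + 0.45\) drags Bax around a loop: it stays on
the elevated branch while \(B\) falls and only drops through the apoptosis
threshold near \(B \approx 0.24\):

```{r hysteresis}
h <- hysteresis_exit()
h$B_exit
```

**Tissue scale.** Five fields on the unit square (physical edge `L`,
default 10 mm): uninfected cells \(x\), infected cells \(y\), dead cells
\(n\) (immobile), free virus \(v\) and BTZ \(B\), all diffusing (except
\(n\)) with no-flux boundaries:

\[
\begin{aligned}
x_t &= \nabla\!\cdot\!(D_1\nabla x) + \lambda x(1-x/x_0) - \beta x v
      - \beta_1 x B I_{\mathrm{apop}} - \beta_3 x v B I_{\mathrm{necro}},\\
y_t &= \nabla\!\cdot\!(D_2\nabla y) + \beta x v - \delta y
      + \beta_3 x v B I_{\mathrm{necro}},\\
n_t &= \delta y - \mu n,\\
v_t &= \nabla\!\cdot\!(D_v\nabla v) + b\,\delta y(1+\alpha_1 B) - \gamma v,\\
B_t &= \nabla\!\cdot\!(D_B\nabla B) + I_B
      - (\mu_1 x + \mu_2 y)\frac{B}{k_B+B} - \mu_B B.
\end{aligned}
\]

The indicators \(I_{\mathrm{apop}}, I_{\mathrm{necro}}\) couple the scales:
per cell they evaluate the intracellular steady state at the local
\((B, v)\) and switch the corresponding death channel on. BTZ synergizes
with the virus twice: the burst size is amplified by \(1+\alpha_1 B\)
(which equals \(1+B\) in scaled units), and high BTZ plus virus puts cells
in the necroptotic region.

## Unit conventions and two corrected readings

The dimensionless computational form was reconstructed from the dimensional
constants; almost every rate group converts cleanly with its tabulated
units (e.g. \(\alpha_1 B^* = 1\) exactly, and the BTZ supply
\(I_B/B^* = 0.18\,\mathrm{h^{-1}}\) equals the mid-rung of the dose ladder
\{0, 0.033, 0.077, 0.18, 0.33\} used in the dose-response experiment, which
confirms the scaling). Two constants required interpretation, both
documented here as package decisions:

* **Necroptotic transfer \(\beta_3\)** is tabulated in mm³/(g·h). The only
  dimensionally consistent placement pairs it with the BTZ concentration
  (the sole g/mm³ quantity), with virus entering as the dimensionless
  ratio: the term is \(\beta_3\, x\, (v/v^*)\, B\, I_{\mathrm{necro}}\),
  giving the group \(\beta_3 B^* \approx 1.4\times10^{-8}\,\mathrm{h^{-1}}\)
  per unit scaled B. The channel is therefore implemented but numerically
  negligible at the defaults; the OV+BTZ synergy observed in simulations is
  carried by the burst amplification and BTZ-induced apoptosis.
* **Proliferation \(\lambda\)** is tabulated as 4.2×10⁻¹ per hour, a 1.7 h
  doubling time — biologically impossible for glioma (typical lines double
  in 1-2 days) and numerically unusable: the logistic front width
  \(\sqrt{D_1/\lambda}\) would be two orders below any workable grid. We
  read it as an exponent slip for 4.2×10⁻² h⁻¹ (a ~17 h doubling time, in
  the range reported for aggressive glioma lines and used by comparable
  tumor-virus models), which resolves fronts on the default grid and
  produces a tumor whose radius roughly triples over ten days, matching the
  growth the model is meant to exhibit. The stored parameter object keeps
  the tabulated value; the conversion happens once in `spatial_rates()`.

**Reference diffusivities.** The tabulated motilities over a 10 mm domain
give sub-grid spread on a 10-20 day horizon, so effective diffusivities are
exposed as multipliers of the tabulated values — the same knob the
motility-sweep experiment turns by factors of ten. The package references
are \(f_{D_1} = f_{D_2} = 250\), \(f_{D_v} = 0.02\) and \(f_{D_B} = 1\)
calibrated once so that: the uninfected front is
resolved at the default 51×51 grid (width ≈ 0.02 domain units); tumor
expansion is ≈ 0.02 domain lengths/day; and the virus front advances
slightly slower than tumor regrowth without BTZ and faster with it, so
that virus-alone therapy leaves a surviving escape ring while the
combination closes it. These are calibration choices, not tabulated
values, and scenario multipliers act relative to them.

## Numerics

* **Diffusion** uses Peaceman-Rachford ADI: an implicit tridiagonal solve
  in one direction against an explicit sweep in the other, then the
  reverse, in flux form with harmonic-mean face diffusivities. The
  discrete total is conserved exactly under no-flux boundaries; barriers
  are faces with zero diffusivity, which makes containment exact rather
  than approximate.
* **Reactions** use a second-order exponential Heun update per cell: each
  field is written as \(w' = a(w)\,w + P(w)\), advanced exactly for frozen
  coefficients with a trapezoidal correction. The update is positive by
  construction and reproduces linear decay/relaxation exactly, which is
  what the closed-form test limits check.
* **Splitting and step control.** Strang order (half reaction, ADI
  diffusion, half reaction) with indicator fields frozen across a step.
  Step-doubling compares one full step against two half steps; the local
  error target is 10⁻⁵ (max-norm per field, relative to the field
  maximum), rejected steps halve `dt`, accepted steps grow it by at most
  2×, and the run aborts if `dt` underflows 10⁻⁸ h or clipped negative
  mass exceeds 10⁻⁶ of any field. The BTZ source disc is cosine-tapered
  over two cells: a discontinuous source pins the controller at
  millisecond steps for no physical gain.
* **Steady states** exploit the model's structure: S, A and R are explicit
  functions of F at equilibrium, so fixed points are roots of a scalar
  equation in F, bracketed on a fine grid (multiple roots would all be
  surfaced; the default parameters yield a unique stable point, verified
  by Jacobian eigenvalues and by relaxation from perturbed starts). The
  independent check is long-time stiff integration; root-finding and
  integration agree to three significant figures across the B range.
* **QSS coupling.** The intracellular relaxation (hours) is fast relative
  to the tissue timescale (days), so indicator fields default to a
  quasi-steady-state lookup: response curves with and without the virus
  switch are tabulated over \(B \in [0, 10]\) (values beyond are clamped
  with a warning) and interpolated per cell, with the with-virus branch
  selected where \(v/(k+v) \ge 1/2\). A per-cell ODE mode
  (`ind_mode = "ode"`) advances the four intracellular states alongside
  the PDE for sensitivity checks; on slow scenarios the two coupling modes
  agree to a few percent.

## Scenario defaults

Magnitudes the in-silico experiments need but the model description leaves
open are scenario knobs with these defaults: initial tumor radius 0.1
(peak 0.5·x₀, cosine taper 0.02, centered); one OV bolus of total dose 1
(in v*·area units, Gaussian spread 0.02) per site at t = 0; six periphery
sites on a circle of radius 0.13 plus optionally the center; BTZ supplied
continuously from t = 0 on discs of radius 0.05 at the injection sites at
the scaled rate 0.18 (the dose-ladder presets use the printed rungs); CSPG
ring with radii 0.2-0.25, optionally opened by a 45° gap bisecting the
first quadrant; the invasion area is the sector outside the ring spanning
twice the gap width; resection removes all cell fields from a central disc
of radius 0.08, the tumor core, leaving the infiltrative rim in place.
Quadrants are taken about the domain center.

## Problem sizes used by the checks

The test suite runs scenarios at 51×51 (a half-resolution version of the
reference 0.01 grid) over 10 simulated days, which keeps a full scenario
under a minute; uniform-field oracle comparisons use an 11×11 grid since
diffusion vanishes there. These sizes are the package's choices for
routine verification; the solver itself is resolution-independent.

## What the checks do and do not show

The fixed-point, crossover and hysteresis values are quantitative and
carry printed reference numbers. The spatial experiments are verified as
*properties* — conservation, the lumped-ODE limit, dose-response
monotonicity, barrier containment, leak direction, therapy-arm ordering —
because the published spatial figures do not pin the remaining magnitudes
(doses, physical length, injection coordinates). Passing them shows the
solver and scenario machinery behave correctly under the documented
calibration; it does not validate the calibration against tissue data, and
none of the simulations model immune response, chemotaxis, or
ECM-degradation therapies, which are outside this model's scope.

A further transcription note: the printed steady-state annotations are not
all attainable under the printed rate constants — the scaled NF-kB level
is bounded by \((c_1+k_3)/(\mu_f F^*) = 4.617\) regardless of the other
constants, yet 4.64 is annotated at \(B=0\), and the Bax annotation 4.89
at \(B=1\) is similarly inconsistent with the F equation. The package
follows the equations and constants; the computed triples are
(4.586, 0.400, 0.720), (0.410, 4.713, 0.720) and (4.522, 0.406, 4.947),
i.e. within ~4% of every annotation.

## A worked spatial example

```{r spatial, eval = FALSE}
# four therapy arms at coarse resolution (about three minutes in total)
tab <- qss_table()
arms <- c("fig6-pbs", "fig6-btz", "fig6-ov", "fig6-combo")
res <- lapply(arms, function(a)
  run_scenario(preset(a, nx = 51, t_end_day = 10), table = tab))
sapply(res, function(r) r$metrics[nrow(r$metrics), "alive"])
# e.g. 0.482 (PBS) > 0.333 (BTZ) > 0.0114 (OV) > 0.0112 (OV+BTZ)
plot(res[[4]], "fields")
```

## Known limitations

* The quasi-steady-state coupling ignores intracellular transients shorter
  than the solver step; the ODE mode exists to quantify that error.
* Indicator switching is discontinuous in state space; step-doubling
  controls the induced splitting error, at the cost of smaller steps near
  switching fronts.
* Population integrals use the node-sum quadrature `sum(w)·hx·hy`, which
  weights boundary nodes like interior ones; conservation statements are
  exact in this same measure.
* The effective-diffusivity calibration is a stated package choice; users
  exploring other regimes should revisit `f_D1`/`f_Dv` (and expect the
  virus-versus-regrowth race, hence the arm orderings, to shift).
* Because the default therapy regime is a near-tie race between the virus
  front and tumor regrowth, the day-10 alive mass of the treated arms is
  resolution-marginal: refining 51×51 to 101×101 moves it by ~14%, while
  untreated growth is grid-converged to ~1%. Quantitative statements about
  treated-arm magnitudes at these grids should be read with that
  sensitivity in mind; the orderings themselves are robust.
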
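---
title: "Rapid earthquake fatality estimation: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid earthquake fatality estimation: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quakefatal)
```

quakefatal estimates the human toll of an earthquake quickly enough to guide
the first hours of emergency response. It chains two very different pieces
of science: a deterministic physical simulation of ground shaking, and an
empirical statistical model of how shaking translates into deaths. This
vignette documents both, together with every numerical convention and design
decision a maintainer or reviewer would want spelled out.

## The empirical fatality model

### Fatality ratio and expectation

For an exposed person in a cell shaken at macroseismic intensity class
$I \in \{V, \dots, XI\}$, the probability of dying is modelled by the
log-linear fatality ratio

$$\log_{10} r(I) = \beta + \theta \, I,$$

clamped at 1 (a ratio of persons is a proportion). Classes V-XI are the
damaging range: the minimum and maximum intensities recorded for damaging
events in the kind of national catalogs this model is fitted to. The model
is stratified into five sub-regions (codes `a`-`e`, see `region_labels()`)
reflecting differences in tectonics, construction practice and population;
each region carries its own $(\beta, \theta)$.

Because building resilience improves over decades, the ratio of an event is
normalised to the reference (latest) year of a human-development-index
table:

$$E = \sum_{I=V}^{XI} r(I)\,
      \frac{\mathrm{HDI}_{\text{max-year}}}{\mathrm{HDI}_{\text{event-year}}}
      \, P_e(\text{region}, I),$$

where $P_e$ is the population exposed at class $I$. Whether the published
form of this model applies the HDI factor during fitting only, prediction
only, or both is not stated in the sources the model family derives from;
this package applies it in **both** places, which keeps fitting and
prediction mutually consistent (an estimate for a training-era event equals
its fitted value). HDI values for years between table entries are linearly
interpolated; extrapolation outside the table is an error by design, since
extrapolated development indices are not meaningful.

### Fitting

Parameters minimise the mixed objective

$$\varepsilon = \ln\!\Big[\tfrac1N \sum_i (E_i - O_i)^2\Big]
  + \tfrac1N \sum_i \big[\ln (E_i/O_i)\big]^2,$$

with $O_i$ the recorded fatalities. The first term is dominated by the
large, deadly events; the second keeps the small events within the right
order of magnitude. Events with $O_i = 0$ cannot enter the log term and are
excluded (`min_fatalities = 1`); exclusions are listed per fit in the
diagnostics. A catalog whose exposure sits entirely in a single intensity
class $I_0$ identifies only the combination $\beta + \theta I_0$; such fits
are flagged `degenerate` and warned about.

The optimiser is deterministic: a coarse grid search over
$\beta \in [-20, 0]$, $\theta \in [0, 3]$ at step 0.1, followed by
Nelder-Mead refinement from the best node. There is no random
initialisation, so a fit is exactly reproducible. A perfect fit drives the
squared-error term's logarithm to $-\infty$; the exported `fit_objective()`
reports that sentinel honestly (it is the true infimum), while the
optimiser floors the mean square at `1e-300` internally so the simplex
iterates on finite numbers. $\theta \le 0$ after fitting produces a warning
rather than an error: it signals an uninformative catalog, not a numerical
failure.

The log residual $\zeta$ — the RMS of $\ln(E_i/O_i)$ over fitted events —
is pooled across regions by default. The per-region $(\beta,\theta)$ with a
single shared residual matches how this model family is usually described;
because that convention is not fully pinned down in the sources, a
`per_region` override is available and per-region residual scales are always
reported.

### Range probabilities and response levels

Given $E$ and $\zeta$, fatalities are modelled as lognormal with median
$E$:

$$P(a < \text{fatalities} \le b) =
  \Phi\!\Big(\frac{\ln b - \ln E}{\zeta}\Big) -
  \Phi\!\Big(\frac{\ln a - \ln E}{\zeta}\Big),$$

with $\ln 0 \equiv -\infty$ and $\ln\infty \equiv +\infty$. The four
response tiers are (0, 10] (level IV), (10, 50] (III), (50, 300] (II) and
(300, $\infty$) (I); the recommended level is the tier with the largest
probability. The probabilities partition $(0,\infty)$ and sum to one
exactly; $P(0 < x \le E) = 1/2$ exactly because $E$ is the lognormal
median. When no population is exposed at damaging intensity, $E = 0$ and
the lognormal is undefined; the package then reports $P(0\text{-}10] = 1$
and level IV by convention — a zero-exposure event is trivially in the
lowest response tier. Counts in reports are rounded half-up, and the
continuous $E$ is always retained alongside.

Two fixed reference points tie the implementation to published case
numbers: with $E = 5$ and $\zeta = \ln 2 / \Phi^{-1}(0.652) \approx 1.774$
(back-solved from a published 65.2% probability of the 0-10 range), forward
evaluation reproduces 65.2% and level IV; with $E = 104$ and the same
$\zeta$, the modal range is 50-300, level II. The acceptance suite checks
both round trips.

### Log base

The sources write $\log r$ without a base. This package uses base 10 — the
convention for fatality-ratio models, and the scale on which the
"within one order of magnitude" validation criterion is stated — and makes
it configurable (`log_base`).

## Ground-motion simulation

### Scheme

The solver marches the first-order velocity-stress form of elastodynamics,
a 9-component state $U = (v_x, v_y, v_z, \sigma_{xx}, \sigma_{yy},
\sigma_{zz}, \sigma_{xy}, \sigma_{xz}, \sigma_{yz})$ on a collocated grid:

$$\rho\, \partial_t v_i = \partial_j \sigma_{ij} + f_i, \qquad
  \partial_t \sigma_{ij} = \lambda \delta_{ij} \partial_k v_k +
  \mu (\partial_i v_j + \partial_j v_i).$$

Spatial derivatives use one-sided biased 5-node (MacCormack-type)
operators,

$$L^F(U)_i = \frac{1}{\Delta x} \sum_{n=-1}^{3} a_n U_{i+n}, \qquad
  L^B(U)_i = \frac{1}{\Delta x} \sum_{n=-1}^{3} (-a_n) U_{i-n},$$

inside classic four-stage Runge-Kutta time integration. The default
coefficients are the exact degree-4 finite-difference weights on the node
set $\{-1,0,1,2,3\}$: $(-1/4, -5/6, 3/2, -1/2, 1/12)$. Any admissible set
must annihilate constants ($\sum a_n = 0$) and be exact on linear fields
($\sum n\,a_n = 1$); `validate_stencil()` enforces exactly these
invariants, so dispersion-optimised coefficient sets from the literature
can be dropped in without code changes.

The forward/backward operators must alternate to cancel their one-sided
bias. The cycle here is fixed and documented: at time step $m$, Runge-Kutta
stage $s$ and axis $q$, the forward operator is used when
$(m + s + q) \bmod 2 = 0$. This swaps the bias per stage, per axis and per
step.

### Boundaries, sources, terrain

* **Free surface** — traction-image method: $\sigma_{zz}, \sigma_{xz},
  \sigma_{yz}$ are zeroed on the top layer after every stage and read
  antisymmetrically mirrored ($\sigma(\text{ghost } g) =
  -\sigma(\text{surface} - g)$) wherever a stencil reaches above the
  surface. Velocity derivatives near the surface fall back to low-order
  one-sided differences.
* **Absorbing sides/bottom** — exponential-damping sponge
  ($g(d) = \exp[-(\alpha (W-d))^2]$, default width 15 cells,
  $\alpha = 0.02$), applied multiplicatively after each full step.
* **Sources** — point moment tensors (given directly or via
  strike/dip/rake) added to the stress rates scaled by the source-time
  function and inverse cell volume; body forces go into the velocity rates.
  The default source-time function is a Ricker pulse in moment rate with
  unit peak (note its net time integral is zero, so static displacement is
  not modelled — irrelevant for peak-velocity outputs); a unit-integral
  Gaussian is available. Finite faults are lists of subfault point sources
  with onsets and rise times; each subfault's moment is
  $\mu\,A\,\text{slip}$ with $\mu$ read from the material model at the
  subfault node, and a one-subfault fault is bit-identical to the
  corresponding point source.
* **Terrain** — a vertically terrain-following stretch: each column's
  spacing is scaled so the top node tracks the surface elevation.
  Horizontal metric terms of a full curvilinear mapping are neglected;
  this restricted mapping is adequate for gentle topography at desk scales
  and keeps the kernel simple. Production-scale curvilinear machinery is
  out of scope.
* **Stability** — $\Delta t \le \mathrm{CFL}\, h_{\min}/v_p^{\max}$ with a
  conservative default CFL of 0.4; violations are errors naming the
  maximum stable step. The solver has no random state: runs are exactly
  reproducible.

### Verification

The acceptance suite measures, at stated desk-scale problem sizes:
plane-wave phase speeds at 20 points per wavelength on a
$240 \times 6 \times 6$ line grid (observed errors $\approx 0.1$-$0.2\%$
against $\sqrt{(\lambda+2\mu)/\rho}$ and $\sqrt{\mu/\rho}$); first-arrival
moveout between two receivers against ray times on homogeneous
($120 \times 60 \times 60$) and two-layer ($60 \times 60 \times 80$)
models; and the four-lobed transverse radiation pattern of a vertical
strike-slip double couple on a $110 \times 110 \times 50$ half-space
(nodal amplitudes below 1% of the lobe maximum in practice, against a 10%
bound). Arrival comparisons are differential between two receivers so the
onset-to-threshold delay of the source pulse cancels; wave-packet speeds
use envelope peak times rather than waveform cross-correlation, which is
immune to cycle skipping. Unit tests additionally check the zero fixed
point, superposition and moment linearity, point-force reciprocity,
energy non-increase after source cutoff, surface-wave depth decay, and
monotone convergence of waveform misfit under grid refinement.

Sources should be resolvable by the grid: the corner frequency ought to
satisfy roughly $v_s / (2.5 f_c) \gtrsim 10\,\Delta x$, otherwise the
injected pulse carries wavenumbers the scheme propagates dispersively (a
visible causal "precursor" of tiny fast-travelling noise). The shipped
examples and tests follow this rule.

## PGV to intensity

Surface peak ground velocity — by default the per-cell maximum over time of
the horizontal norm $\sqrt{v_x^2 + v_y^2}$; 3-component and per-component
conventions are available — converts to continuous intensity through a
log-linear law

$$I = \mathrm{clamp}\big(c_0 + c_1 \log_{10} \mathrm{PGV}, \; 1, \; 12\big),$$

with PGV in m/s and defaults $c_0 = 9.77$, $c_1 = 3.00$, an approximation
of the current Chinese instrumental intensity standard's PGV relationship.
The standard's exact coefficients and component rule should be entered by
the user from the standard text; the defaults are validated here only for
monotonicity and round-trip consistency. PGV $= 0$ maps to the lower clamp.

## Exposure overlay

Population is the conserved quantity, so population cells are the
accumulation unit: the intensity raster is sampled at each population cell
center by nearest neighbour (never bilinear — intensity classes are
ordinal, and interpolation would blur class boundaries), binned half-up
into classes V-XI, and the cell's persons accumulate into the class total.
Cells binning below V go to a `below_v` bucket; population cells outside
the intensity raster's extent go to an `unassessed` bucket rather than
being dropped; nodata population cells count as zero persons and are
tallied. The identity
$\sum_I P_e(I) + \text{below\_V} + \text{unassessed} = \text{total}$
holds to floating-point accuracy and is asserted over 1000 random raster
pairs in the acceptance suite. Binned classes above XI are clamped to XI
with a warning.

Rasters are geographic WGS84 with cell-center registration, read and
written as ESRI ASCII grids — a plain-text, single-band format that every
GIS ingests. Simulated surface grids are georeferenced by a local
flat-earth approximation about the configured grid-center coordinate; at
the $\le 200$ km extents the solver targets, the resulting anisotropy of
physical cell size is below about 1% and irrelevant next to the intensity
law's uncertainty.

## Synthetic data: what it emulates, what it does not

The generators make the whole pipeline testable with no downloads:

* `gen_hdi_table()` — a smooth logistic HDI rise (0.22 to 0.78 over
  1950-2021), emulating a steadily developing region.
* `gen_catalog()` — regional catalogs with known generating parameters.
  Per-event exposure is log-uniform per class,
  $\log_{10} P_e(I) \sim U(h_I - 1.5,\, h_I)$ with
  $h_I = 7.2 - 0.3 (I - 5)$, truncated at a per-event maximum class drawn
  from $\{X, XI\}$ — large events whose exposure decays with intensity,
  yielding recorded counts from tens to a few thousand. Defaults
  $\beta^* \in [-14.6, -13.9]$, $\theta^* \in [1.05, 1.15]$ put the ratio
  near $10^{-8}$ at V and $10^{-2}$ at XI, the range empirical
  fatality-ratio laws occupy. Recorded counts are
  $O_i = \max(1, \mathrm{round}(E_i e^{\zeta^* z_i}))$, $z_i \sim N(0,1)$:
  multiplicative lognormal noise, chosen to match the range-probability
  model's normal-in-log assumption. The $\max(1,\cdot)$ floor keeps every
  generated event usable under the $O \ge 1$ fitting rule; floored events
  are flagged.
* `gen_population()` — Gaussian-blob settlement clusters over a uniform
  floor, rounded to persons with the total preserved to within half a cell.
* `gen_intensity_field()` — an analytic isoseismal field
  $I = I_0 - d \log_{10}(\max(r, r_0)/r_0) + \ell\,|\sin 2(\varphi -
  \text{strike})|$, mimicking the butterfly-shaped, outward-decaying
  surface pattern of a strike-slip event.

All generators are deterministic under a fixed seed. What they do **not**
emulate: real catalog completeness and reporting biases, the actual
frequency-magnitude distribution of damaging events, true settlement
geography, or site effects. Passing the recovery and pipeline tests
demonstrates the estimator and plumbing are correct under the model's own
assumptions — it says nothing about how well the log-linear law fits real
loss data, which is a property of the real catalog, not of this code.

## Problem sizes and tolerances

Tests and the acceptance script run at desk scale, chosen so the full
suite completes in minutes on one CPU while every check still operates in
its asymptotic regime: 20 events per region for noise-free recovery
(recovered $(\beta,\theta)$ within 0.01), 500 events for $\zeta$ recovery
(within 15%), an exhaustive $0.01$-step grid oracle over the full
$(\beta,\theta)$ box for fits on 20-event catalogs, 1000 random raster
pairs for mass conservation ($10^{-6}$ relative), the solver grids listed
above (speeds within 1%, arrivals within 2 grid-crossing times, nodal
amplitudes below 10% of the lobe), and a $50 \times 50$-cell end-to-end
pipeline checked against an independently coded per-cell oracle to
$10^{-9}$ relative. Reproducing published case-study numbers for real
events needs external inputs (real population rasters, terrain, crustal
models, inverted finite-fault sources, and the real fitted catalog) and
production-scale grids, which are outside this package's scope; the
package's fixed reference points to those cases are the lognormal
round-trip checks described above.

## Known limitations

* The empirical model is a regression, not a prediction of individual
  outcomes; its own validation criterion is order-of-magnitude agreement.
* Ricker moment-rate sources carry no net moment (no static field).
* No viscoelastic attenuation; amplitude decay is geometric plus numerical
  dissipation only.
* The terrain mapping neglects horizontal metric terms (gentle slopes
  only), and low-order operator fallbacks at boundaries reduce accuracy in
  the top few layers.
* Georeferencing uses a local flat-earth projection; do not use grids
  wider than a few hundred km.
* GeoTIFF I/O is not provided; rasters are exchanged as ESRI ASCII grids.
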
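---
title: "Methods: nucleotide-phyllosilicate adsorption analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleotide-phyllosilicate adsorption analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleosorb)
```

This vignette records the models, conventions and numerical choices behind
each stage of the pipeline, in enough detail that a user can judge what a
result does and does not mean.

## Batch isotherms and mass balance

The batch (immersion) method equilibrates a known volume `V` of nucleotide
solution with a weighed mass `m` of mineral powder; initial and equilibrium
concentrations `C0`, `Ceq` come from UV/vis spectrophotometry. The adsorbed
quantity per gram is the mass balance

$$q = \frac{(C_0 - C_{eq})\,V}{m},$$

which satisfies $q\,m + C_{eq}V = C_0V$ identically — the package asserts
this to machine precision for every processed sample. Units are fixed
internally (mol/L, L, g, mol/g); all conversions happen at the I/O boundary.

Calibration is linear Beer–Lambert, $C = A/(\varepsilon \ell)$, with an
optional multi-point standard curve fitted as a line through the origin.
Linearity over the 0–3.5 mM working range is the standard assumption for
these chromophores; no correction is applied for absorbance shifts caused
by nucleotide–metal complexation, so strongly complexing electrolytes
deserve an independent calibration check.

Two deliberate quality rules:

* **Negative adsorption** (`Ceq > C0`) is returned as a negative `q` with a
  flag, never clipped. Clipping would bias isotherms upward near zero
  coverage; a flagged negative point lets QC distinguish desorption from
  measurement error.
* **Replicates** are matched on identical `C0` and conditions (1e-9
  relative tolerance) and aggregated to mean ± sample standard deviation;
  assembly is invariant to input order.

## Normalization and the collapse score

Two transformations make isotherms comparable:

* **Reduced concentration** `x = Ceq/S`, with `S` the molar solubility at
  the experiment temperature. Homologous molecules adsorbing by a common
  mechanism differ mainly through solubility, so their isotherms
  superimpose on the reduced axis. Solubilities are user-supplied; the
  values shipped with the generators are synthetic placeholders, labelled
  as such.
* **Adsorption density** `d = q/SSA` (mol/m²) on an explicit basis —
  total, basal, or edge specific surface area. Per-gram uptake scales with
  grain size; only densities on the reactive basis are comparable across
  samples. The two transformations commute.

Collapse, usually judged visually, is scored as the mean over a common
abscissa grid of the cross-curve coefficient of variation (sd/mean). The
grid is log-spaced over the intersection of the curves' supports;
interpolation is monotone piecewise-linear with no extrapolation, because
isotherms are sparse and noisy and higher-order schemes overshoot. The
score is dimensionless and invariant to a common scale factor, so families
in different ordinate units compare fairly; identical curves score 0, and
two flat curves at levels 1 and 3 score $\sqrt{2}/2 \approx 0.707$.

Plateau (saturation) densities are estimated as mean ± sd over the top
quarter (`tail_fraction = 0.25`) of the abscissa range, with at least three
points required; a tail with sd/mean above 0.1 is flagged "no plateau" —
these thresholds reproduce visual plateau judgement on Langmuir-shaped
synthetic curves and are configurable.

## Langmuir models

Two forms are fitted side by side:

* classic: $q = q_{max} K C / (1 + K C)$, with $K$ in L/mol;
* modified (solid/liquid): $q = q_{max} K_{ML} C / (C_s - C + K_{ML} C)$,
  where $C_s$ is the solute solubility.

The modified form scales concentration by saturation, so $K_{ML}$ is
dimensionless and $\Delta G^\circ = -RT\ln K_{ML}$ does not depend on a
concentration convention. It reduces to the classic form with
$K = K_{ML}/C_s$ when $C \ll C_s$ and degenerates to the straight line
$q = q_{max} C/C_s$ at $K_{ML} = 1$. $C_s$ is fixed, not fitted: it is an
independently known constant, and co-fitting it with $K_{ML}$ is
ill-conditioned.

Fitting is weighted nonlinear least squares (weights $1/\mathrm{sd}^2$ when
replicate sds are available, uniform otherwise), Levenberg–Marquardt on
log-parameters to enforce positivity, initialized from the linearized
reciprocal form and repeated from 5 deterministic starts (the linearized
guess scaled by 1, 0.5, 2, 0.2, 5) to guard against local minima.
Parameter sds come from the Jacobian at the optimum. Both parameter sets
are *descriptive*: a Langmuir-shaped solution/solid isotherm does not by
itself establish monolayer adsorption on uniform sites, which is exactly
why the dimensionless form is reported alongside rather than instead of
the classic one.

## DIS: derivative isotherm summation

Low-pressure quasi-equilibrium argon volumetry resolves the monolayer
regime ($P/P_0 < 0.05$) where sites fill in order of adsorption energy. In
the representation $dV_{ads}/d\ln(P/P_0)$ vs $u = \ln(P/P_0)$ — the
abscissa is the adsorption free energy in kT — site populations appear as
peaks, and the experimental curve is modelled as a sum of local derivative
isotherms.

The local model is a Langmuir isotherm with Bragg–Williams (mean-field)
lateral interactions, the simplest member of the Hill–de Boer-like family
with an explicit single-valuedness bound: coverage solves

$$u = u_{1/2} + \ln\frac{\theta}{1-\theta} - \omega(\theta - \tfrac12),$$

which is single-valued for $\omega < 4$ since
$du/d\theta = 1/\theta(1-\theta) - \omega > 0$; the package rejects
$\omega \ge 4$. The derivative contribution is
$v_m\,/\,(1/\theta(1-\theta) - \omega)$: a logistic peak of height $v_m/4$
at $u_{1/2}$ for $\omega = 0$, sharpened to $v_m/(4-\omega)$ by lateral
attraction. $\theta(u)$ is solved by vectorized monotone bisection to
1e-13.

Numerical choices:

* the experimental derivative uses a local quadratic fit over a centered
  sliding window (default 7 points), kept at full width near the series
  ends by one-sided extension — shrunken end windows produce noisy boundary
  estimates; negative values are clamped to zero with a warning count;
* fitting is bounded Levenberg–Marquardt over $(v_m, u_{1/2}, \omega)$ per
  domain ($v_m \ge 0$ via log-parameters, $u_{1/2}$ within the data range,
  $\omega \in [0, 4)$), restricted to $u \le \ln 0.05$ (the monolayer
  regime) and started from 10 deterministic configurations seeded by
  greedy peak-picking of the smoothed derivative with an exclusion radius,
  with only interior local maxima eligible (a boundary spike must not
  absorb a starting position);
* domains are labelled edge (high energy, low $u_{1/2}$) or basal by a
  split threshold. By default the threshold is the experimental minimum
  inside the largest gap between fitted $u_{1/2}$ values; when one surface
  class may be absent (an edge-suppressed sample has no gap to find) the
  analyst should pass `split_u` explicitly, e.g. the boundary known from
  the pristine sample;
* monolayer capacities convert to areas through the argon cross-section,
  0.138 nm² (the conventional 77 K value; configurable).

Monolayer bookkeeping — $\sum v_m$ equal to the integral of the
experimental derivative — holds only when every domain completes filling
inside the measured window; a domain centered within ~2 kT of the window
edge leaves several percent of its monolayer beyond it, and the comparison
then understates $\sum v_m$ by that truncated tail. Multilayer/BET-type
local isotherms are deliberately out of scope.

## MD trajectory analysis

Frames (orthorhombic boxes only; triclinic input is rejected) carry
per-atom roles (molecule, surface, cation, anion, solvent) and charges.
Conventions, all configurable and all recorded in the outputs:

* **Adsorbed** means the minimum molecule–surface atom distance (orthorhombic
  minimum image) is $\le 4.0$ Å — the cutoff is inclusive. State 0 is free;
  adsorbed frames split into parallel (state 2) when the nucleobase
  ring-plane tilt relative to the surface plane is at most 30°, else
  non-parallel (state 1). The 30° default operationalizes "parallel", which
  has no standard numeric boundary; the tilt angle is always emitted so
  users can re-threshold without re-running.
* The surface plane is normal to the longest box axis (a clay slab spans
  the two short axes); the ring plane is the least-squares plane through
  the ring atoms, unwrapped by minimum image, with collinear ring atoms
  rejected.
* The **duration ratio** is (frames in states 1∪2)/(frames in state 0); a
  trajectory that is never free reports an infinite ratio with a flag.
  Dwell smoothing (`min_dwell_frames`) is off by default — raw state traces
  are the primary object — and when enabled relabels short segments first
  on the adsorbed/free dichotomy, then between the adsorbed sub-states.
* The **complex charge** is the sum of the molecule's partial charges plus
  the formal charges of every ion within `ion_cutoff` (default 4.0 Å, the
  same as the adsorption cutoff, as no separate complexation radius is
  standard) of any molecule atom. Anions within the cutoff count with
  their negative charge. This convention string is embedded in every
  output, because other bookkeepings (heavy atoms only, cations only) are
  defensible and would shift the numbers.
* Per-state charge tables are frame-weighted; replicate simulations are
  combined by frame-count-weighted means, so a replicate that visits a
  state longer weighs more.

## Synthetic data: what it emulates, and what it does not

Every generator is seeded, restores the caller's RNG state, and stores its
ground truth beside the data, so each downstream statistic has a closed-form
expectation. Defaults are the study conditions:

* **Batch isotherms**: 20 initial concentrations over 0–3.5 mM, 1 mL
  solution, 40 mg mineral, seawater-analog electrolyte (0.5 M NaCl +
  0.05 M MgCl₂) at pH 7 / 25 °C; `Ceq` solved self-consistently from the
  isotherm model and mass balance (bisection plus a fixed-point polish, so
  the pre-noise balance closes to machine precision), then 2 %
  multiplicative Gaussian noise on `Ceq` (instrument-like; negative draws
  are resampled and counted). The 40 g/L solid load is a deliberate
  design point: mass balance amplifies `Ceq` noise in `q` by
  $C_{eq}/(C_0-C_{eq})$, so a load that depletes only ~15 % of the solute
  at plateau (e.g. 10 g/L here) yields several-fold noisier capacities and
  affinities — batch experiments are sized for appreciable depletion, and
  the default reflects that.
* **Homologous family**: one shared reduced-axis Langmuir shape
  materialized at `c_eq = x·S` for solubilities spanning 5× (0.005, 0.011,
  0.025 mol/L), so reduced-axis collapse is true by construction.
* **Grain pair**: fine (edge 12, basal 80 m²/g) and coarse (edge 4, basal
  76 m²/g) powders of one mineralogy with per-gram uptake proportional to
  edge area — only the edge basis collapses.
* **Argon isotherms**: domain sums on a log-spaced $P/P_0$ grid in
  (1e-7, 0.05], noise proportional to the local signal; default truth is
  an edge domain at $u_{1/2} = -12$ and a basal domain at $-5$ holding
  30 %/70 % of a 10 cm³/g monolayer.
* **Trajectories**: a rigid 7-atom toy nucleotide (planar 5-ring, net
  charge −2) above a static 6×6 surface grid in a 41.44 × 35.88 × 62.5 Å
  box, 2000 frames at 0.05 ns spacing (100 ns). Adsorption/desorption is a
  two-state Markov chain — Na-like rates 0.02/0.05 per frame give
  stationary adsorbed fraction 2/7 and expected duration ratio
  $\pi/(1-\pi) = 0.4$; Ca-like rates 0.06/0.02 give 0.75 and ratio 3.
  Adsorbed frames draw the minimum distance uniformly in [2.5, 4.0] Å
  (placed exactly: the closest atom sits directly above a surface atom),
  free frames in (4.5, 20] Å; parallel frames draw tilts in [0, 20]°,
  non-parallel in [45, 85]°, leaving guard bands around the 30° threshold.
  Bound cation counts are Poisson per state (Na-like mean 2.8 monovalent;
  Ca-like 2.5 divalent, giving expected adsorbed complex charges +0.8 and
  +3.0), realized geometrically within the complexation cutoff; the same
  means apply in the free state, since ion pairing persists in solution.
  Positional jitter is specified as an RMS displacement *magnitude* per
  atom (default 0.1 Å; per-coordinate sd $0.1/\sqrt{3}$).

The generators validate the *analysis*, not the chemistry: there is no
water, no force field, no pH dependence, no surface crystallography, and
the toy molecule is rigid. Passing tests therefore demonstrate that the
estimators recover known structure at realistic noise — not that real
nucleotide–clay systems obey these models. Classification accuracy under
jitter is intrinsically bounded below 100 % because the adsorbed distance
band touches the 4.0 Å cutoff, so frames drawn within the noise scale of
the boundary can legitimately flip; with the default geometry this costs
roughly half a percent of frames in the mostly-free scenario and more in
the mostly-adsorbed one.

## Problem sizes, determinism, and limitations

The shipped tests and the acceptance script run the full estimator chain at
deliberately moderate sizes — e.g. 100 fit seeds for Langmuir recovery, 20
seeds for collapse and DIS checks, 800–2000-frame trajectories — chosen so
the whole suite completes in a few minutes while keeping Monte-Carlo
standard errors well inside the tolerances being asserted.

All randomness flows from explicit integer seeds; reruns are byte-identical
(floating point is serialized with 17 significant digits, which round-trips
doubles exactly). `run_pipeline()` writes a resolved-config snapshot and an
MD5 manifest next to its outputs.

Known limitations: no kinetic modelling of the approach to equilibrium; no
speciation or activity-coefficient chemistry of the electrolytes; no
Freundlich/Temkin/BET alternatives; no surface-complexation modelling of
pH-dependent mechanisms (the normalization module compares empirical curves
only); DIS results depend on the chosen local-isotherm dialect, and the
edge/basal assignment of fitted domains is an energy-threshold convention,
not a structural identification.
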
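---
title: "A color neural field for assimilation and contrast: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A color neural field for assimilation and contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cnfield)
```

## The model

`cnfield` simulates a population of color-tuned hypercolumns in primary
visual cortex as a Wilson–Cowan neural field over the product of a cortical
patch $\Omega \subset \mathbb{R}^2$ and a symmetric opponent color space
$C$. The mean activity $a(r, c, t) \in (0, 1)$ of the neural mass at
position $r$ tuned to color $c$ obeys

$$\tau \frac{da}{dt} = -a + F(\omega \star a + H),$$

with $\tau = 1$, the logistic activation $F(x) = 1/(1 + e^{-\gamma x})$
(maximal slope $\gamma/4$ at the origin), the feedforward color input

$$H(r, c) = h(c - I(r)), \qquad
  h(c) = \mu_h e^{-\lVert c\rVert^2 / 2\sigma_h^2},$$

where $I : \Omega \to C$ is the stimulus in opponent coordinates, and the
lateral input

$$\omega \star a(r, c) = \int_\Omega \int_C g(r - r')\, f(c, c')\,
  a(r', c')\, dr'\, dc'.$$

The two kernels carry the science. The spatial weight is a
difference-of-Gaussians (Mexican hat)

$$g(r) = \mu e^{-\lVert r\rVert^2/2\alpha^2}
       - \nu e^{-\lVert r\rVert^2/2\beta^2}, \qquad \mu > \nu,$$

excitatory between nearby hypercolumns and inhibitory at intermediate
range. The color weight

$$f(c, c') = \mu_c e^{-\lVert c - c'\rVert^2/2\alpha_c^2}
           - \nu_c e^{-\lVert c + c'\rVert^2/2\beta_c^2}
           = f_1(c - c') - f_2(c + c')$$

is a difference of Gaussians centered at $c$ and at its Hering opponent
$-c$. Crossing the two signs yields the synergy of the two induction
phenomena: adjacent neighbors of similar color excite (chromatic
assimilation), while remote neighbors excite the *opponent* color
(simultaneous contrast). The Gaussians are peak-normalized — the
amplitudes $\mu, \nu, \mu_c, \nu_c, \mu_h$ are kernel heights, not masses —
so the integrals scale with the domain measure.

Because $f(c, c') = f_1(c - c') - f_2(c + c')$ and $C$ is symmetric, the
lateral term factorizes into convolutions,

$$\omega \star a = g *_\Omega \left[ f_1 *_C a
  - \mathrm{Sym}\,(f_2 *_C a) \right],
  \qquad (\mathrm{Sym}\, b)(r, c) = b(r, -c),$$

which is what the implementation evaluates (see *Numerics*).

**Color sensation and matching as projection.** For a static stimulus the
dynamics converge to a steady state $a_\infty$; the *color sensation* at a
cortical point $r_0$ is the activity profile $a_\infty(r_0, \cdot)$, a
function on color space. An asymmetric matching experiment is emulated as a
projection: the predicted match for a test stimulus is

$$c^{\mathrm{match}} = \arg\min_{c}\,
  \lVert a^{\mathrm{test}} - a^{\mathrm{comp}}[c]
  \rVert_{L^\infty(C)},$$

where $a^{\mathrm{comp}}[c]$ is the sensation elicited by the comparison
image whose central patch carries $c$ on a neutral surround. The distance
is fixed to the sup norm over color nodes (other norms sit behind a config
switch, off by default). The shift $c^{\mathrm{match}} - c^{\mathrm{test}}$
is the model's prediction of color induction.

## Opponent representations

Two concrete representations are implemented:

* **1D (`ms1d`)**: the S-cone chromaticity axis, $c = s - 1 \in [-2, 2]$
  with $s = S/(L+M)$. The canonical stimulus chromaticities are purple
  ($s = 2.0$, $c = 1.0$), lime ($s = 0.16$, $c = -0.84$) and white
  ($s = 0.98$, $c = -0.02$). Values outside $[-2, 2]$ are rejected rather
  than clipped so stimulus-spec errors surface early.
* **2D (`hsl2d`)**: the constant-luminance chromatic disk of the HSL
  cylinder, $(c_1, c_2) = (S\cos H, S\sin H)$ with the unit disk as the
  admissible set. Hue is measured in degrees counterclockwise from the
  positive $c_1$ axis — the orientation is a convention (nothing in the
  model fixes one) and any consistent choice reproduces the geometry up to
  rotation. Luminance is a pass-through constant: no luminance dynamics.

The color dimension is a property of the grid, not of individual calls;
mixing dimensions is an error.

## Parameters

The model is governed by the 11-vector
$q = (\mu_c, \nu_c, \alpha_c, \beta_c, \mu, \nu, \alpha, \beta, \mu_h,
\sigma_h, \gamma)$. Four regressed vectors ship as fixtures
(`named_params()`): `q_MC` and `q_AZ` (striped-pattern observers),
`q_nonlin` (shift-versus-test-chromaticity data) and `q_HSL` (chromatic
disk). Widths $\alpha, \beta$ are in cortical length units, $\alpha_c,
\beta_c, \sigma_h$ in opponent color units; all amplitudes are
dimensionless. The structural constraint $\mu > \nu$ (local excitation) is
enforced at construction.

## Grid calibration

The sources give no physical units for the cortical coordinates, so the
package treats the kernel widths as grid-calibrated and fixes the geometry
once:

* **`ms1d` (80 × 8 nodes, spacing 0.05).** The regressed spatial DOG for
  `q_MC` changes sign at radius $\approx 0.77$; the calibration puts its
  excitatory center across about seven stripes of the ring stimuli, the
  regime the regressed kernels describe. Setting the stripe width to
  4 nodes = 0.2 length units satisfies that relation
  ($2 \times 0.77 / 0.2 \approx 7.7$). Concentric rings are reduced to
  mirror-symmetric vertical stripes (the same axial reduction used to make
  the original computations tractable); the default pattern is a central
  test stripe with 4 (adjacent, second) stripe pairs per side.
* **`ms1d_coarse` (32 × 4, spacing 0.1, 21 color nodes).** A reduced grid
  for regression studies, where hundreds of energy evaluations each require
  ~50 steady-state solves. Parameter recovery is assessed on predictions,
  so synthesis and refitting use the same grid and the reduction cancels.
* **`hsl2d` (17 × 17, spacing 0.1; 11 × 11 color nodes masked to the
  disk).** Two constraints pin this geometry. First, the surround
  inhibition $\nu e^{-\lVert r\rVert^2/2\beta^2}$ with $\beta = 8.35$ is
  effectively constant over any feasible domain, so total inhibition grows
  with domain *area*; beyond roughly $\pm 1$ length unit the $dt = 1$
  fixed-point map leaves the contractive regime and settles into a
  period-2 oscillation instead of a steady state. Second, the surround of
  the square stimulus must fall mostly beyond the DOG sign change
  ($\approx 0.68$ for `q_HSL`) for simultaneous contrast — the observed
  "yellow pushes toward blue" — to dominate; with the surround inside the
  excitatory center, assimilation wins and the predicted shifts point the
  wrong way. The defaults (patch half-width 0.5, surround half-width 0.8 on
  a $\pm 0.8$ domain) satisfy both. The default test surround is Yellow
  (HSL $(60^\circ, 50\%, 50\%)$) and the comparison surround Gray, the
  disk origin.

In the 1D setting the comparison surround is exactly the neutral color 0
rather than the white stimulus ($c = -0.02$): the neutral choice preserves
the color-flip equivariance of the whole pipeline, which the tests exploit;
the white value is configurable.

## Numerics

* **Discretization.** Fields live on uniform grids; the color interval uses
  41 nodes (1D) and the disk an 11 × 11 Cartesian grid with nodes outside
  the closed unit disk masked — pinned to a constant, excluded from
  integrals and norms. Node sets are negation-symmetric by construction, so
  `Sym` is an exact index reversal.
* **Quadrature.** The lateral integral is a Riemann sum: every convolution
  carries the cell measure ($h$ per spatial axis, $h_c$ per color axis), so
  results are resolution-consistent approximations of the integral, not
  bare sums.
* **Convolutions.** All kernels are separable products of 1D Gaussians, so
  $\omega \star a$ reduces to axis-wise convolutions evaluated with FFTs
  (zero-padded to twice the axis length; the kernel is truncated at the
  domain size). A periodic spatial mode supports exact translation
  equivariance tests. A dense $O(N^2)$ double-sum path
  (`apply_connectivity(..., method = "direct")`) is retained as the
  independent reference; the two agree to $10^{-12}$ on small grids.
* **Time stepping.** Explicit Euler with $dt \in (0, 1]$; at the default
  $dt = 1$ the scheme is the fixed-point map $a \mapsto F(\omega \star a +
  H)$, which keeps iterates strictly inside $(0, 1)$ for any start in
  $(0, 1)$. The default initial condition is the uniform $a_0 = 1/2 =
  F(0)$: it is the symmetric choice, so color-flip equivariance holds
  exactly along the whole trajectory.
* **Convergence.** `steady_state()` iterates until the sup-norm change
  falls below `tol` ($10^{-3}$ by default, `max_iter = 100`); at
  convergence the fixed-point residual is below `tol` by construction.
  Non-convergence is flagged and warned about, never silent; matching
  trials involving non-converged solves are marked in the output, and the
  regression assigns such parameter points a large finite penalty so the
  optimizer retreats. Steady-state uniqueness is checked numerically (runs
  from random initial conditions agree within $10 \times$ `tol`), not
  assumed.

## The matching search

The projection is evaluated on a finite candidate lattice: 41 equally
spaced points on $[-2, 2]$ (1D) or a polar lattice (disk center plus 12
hues × 4 radii up to 0.96) in 2D. A SoftMin with temperature $T$ turns the
distance profile into a weighted minimizer
$\hat c = \sum_c c\, e^{-d(c)/T} / \sum_c e^{-d(c)/T}$, which interpolates
below the lattice resolution and varies smoothly with the parameters —
important for the regression. $T = 0$ recovers the hard argmin.

Refinement telescopes: each pass lays `refine_points` nodes per axis across
the previous spacing around the incumbent minimizer. The 1D default is one
pass (resolution 0.025); the 2D driver uses three passes of 5 × 5 points
(final spacing 0.03). The temperatures differ by setting: $T = 0.01$ in 1D,
where distance profiles vary by $\sim 10^{-2}$ across neighboring
candidates, but $T = 0.002$ in 2D, where the $L^\infty$ basins are shallow
(depth $\sim 10^{-3}$) and a warmer SoftMin would average the basin away
and report near-zero shifts. Comparison sensations are cached per
(candidate, geometry, surround) within a run; caching cannot change
results because the solve is a pure function of those inputs.

## Synthetic matching data

`synthesize_matching_dataset()` plays a model observer: it predicts the
match for each trial under known parameters $q_{\mathrm{true}}$ and adds
isotropic Gaussian noise (sd `noise_sd`, clipped back to the color domain),
reproducibly under a seed. This emulates matching variability of a single
idealized observer. It does *not* emulate lapses, response bias,
anisotropic or magnitude-dependent variability, inter-observer differences,
or luminance artifacts — so passing recovery tests show that the
regression machinery works on data the model can represent, not that the
model fits any particular human observer.

## Regression

The fit minimizes $E(q) = \sum_i \lVert c^{\mathrm{pred}}_i(q) -
c^{\mathrm{match}}_i \rVert^2$ with a bounded derivative-free Nelder–Mead
simplex (`stats::optim`), restarted from the incumbent with a small seeded
jitter while evaluation budget remains. Box bounds are enforced through a
logistic reparameterization — every proposal is feasible by construction —
while the structural constraint $\mu > \nu$ is rejected with a penalty
rather than clipped. The trace of best-so-far energies is recorded and the
final energy is recomputed independently of the optimizer's bookkeeping.

Identifiability is deliberately assessed at the prediction level: the
energy has flat directions (near-duplicate optima among the shipped
fixtures suggest as much), so recovery is claimed for predicted shifts, not
for parameter components.

## Problem sizes used by the tests

Unit and property tests run on small grids (6 × 6 spatial × 5–9 color
nodes for kernel identities and oracle comparisons; 24 × 4 × 21 for
matching properties). The end-to-end checks use the default `ms1d` grid
for convergence and sign-structure runs, the `ms1d_coarse` grid with a
500-evaluation budget for the recovery study, and the `hsl2d` grid with
the shallow (no-refinement) search for the 36-pair structural run. These
sizes were chosen so the full suite exercises every path at meaningful
resolution while staying comfortably interactive.

## Known limitations

* Zero-padded boundaries leave edge effects in the steady states; readouts
  are taken at the domain center, and the periodic mode exists mainly for
  equivariance testing.
* The $dt = 1$ map can oscillate (period 2) for parameter/grid
  combinations with strong net inhibition — large domains under the
  published 2D parameters, or coarse grids whose cell measures inflate the
  kernel mass. The solver reports this as non-convergence rather than
  averaging over the cycle; smaller domains or $dt < 1$ via `evolve()` are
  the remedies.
* Retinotopy is the identity: stimuli are specified directly as cortical
  images, and log-polar magnification is out of scope.
* No orientation tuning, no luminance channel, no time-varying stimuli,
  and no bifurcation analysis of patterned (hallucinatory) states.
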
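---
title: "Modelling climate-forced population dispersal with human existence potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling climate-forced population dispersal with human existence potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodisp)
```

# The model

`paleodisp` reconstructs the dispersal of a prehistoric population across a
continental domain from two kinds of evidence: an archaeological site
catalogue, and gridded (palaeo)climate fields. The unifying quantity is the
*human existence potential* (HEP), organised in three layers:

1. **Environment HEP** $\Phi_E \in (0,1)$ — how suitable the climate is for
   the culture, estimated from presence/absence data (below).
2. **Accessible HEP** $\Phi_{Ac} = \Phi_E \, g_{ele} \, g_{std} \, g_{wat}
   \cdots g_x$ — suitability reduced by terrain and water-body modifiers,
   each a field in $[0,1]$.
3. **Available HEP** $\Phi_{Av}$ — the resources actually available per
   person once the local population is accounted for; it drives the
   dynamics.

The population density $\rho(x, y, t)$ (persons per 100 km²) obeys an
advection–diffusion–logistic equation, solved by operator splitting into a
transport step

$$\partial_t \rho = -\mathbf{v}\cdot\nabla\rho + D\nabla^2\rho$$

and a growth step $\partial_t \rho = r\rho(1 - \rho/\rho_c)$, on a regular
longitude–latitude grid with spherical cell geometry. The drift velocity
relaxes toward the gradient of available HEP,

$$\frac{d\mathbf{v}}{dt} = \alpha \nabla \Phi_{Av} - \gamma \mathbf{v},$$

and the diffusivity is a sub-grid mixing closure
$D = \kappa\, l\, \sigma_v$ with $l = \kappa_l \sqrt{\Delta x \Delta y}$ and
$\sigma_v = \kappa_\sigma |\mathbf{v}|$, clipped to a configured range.

## The niche model

$\Phi_E$ is a quadratic logistic regression on four standardized
bioclimatic predictors $P$ (annual mean temperature, temperature
seasonality, wettest-month precipitation, precipitation seasonality):

$$q(P) = \tfrac{1}{2} P^{\mathsf T} A P + B\cdot P + C, \qquad
  \Phi_E = \frac{1}{1 + e^{-q}}.$$

Training data are built at the spatial-block level (blocks default to grid
cells): blocks containing at least one site are presences; site-free blocks
whose raw climate violates the a-priori habitability rules (annual mean
temperature outside $[-2, 16]$ °C or wettest-month precipitation outside
$[30, 250]$ mm) are absences; the remaining *pseudo-absence* blocks are
handled by one of three options — excluded (1), split one third absence /
one third presence / one third excluded (2), or all included with presence
probability $N_p/(N_p+N_{pa})$ (3, the default and most conservative).

The fit is a penalized Newton (IRLS) iteration: gradient-norm tolerance
$10^{-8}$, at most 200 iterations, and a ridge penalty of $10^{-6}$ on $A$
and $B$ (never on $C$). The tolerance and ridge are not scientific claims
but reproducibility choices: presence/absence sets built from sparse
catalogues are frequently quasi-separable, and an unpenalized fit would
diverge along the separating direction. An ensemble (default 1000 members;
smaller in the examples here) refits the model on random 80 % subsets and
scores each member on its own held-out 20 % with the Brier skill score
(reference: the same member with $A$ and $B$ zeroed, i.e. its intercept
alone) and the AUC. The "ensemble mean model" used downstream is the mean
of the member $\Phi_E$ *fields*, not a model with averaged coefficients —
the mean of fields is guaranteed to stay in $[0,1]$ and is what the
ensemble standard deviation naturally accompanies.

## From suitability to dynamics

The local carrying capacity is $\rho_c = \rho_{c,max} \Phi_{Ac}$ with the
cultural ceiling $\rho_{c,max} = 5$ P 100 km⁻² by default. Two competing
effects — mutual support at low density, resource pressure at high density
— are captured by a Weibull-density response in $x = \rho/\rho_c$:

$$w(x) = \frac{\eta}{\epsilon}\left(\frac{x}{\epsilon}\right)^{\eta-1}
  e^{-(x/\epsilon)^\eta}, \qquad
  \Phi_{Av} = \frac{w}{w_{max}}\,\rho_c,$$

so $\Phi_{Av}$ rises from 0, peaks at the Weibull mode
$x^* = \epsilon((\eta-1)/\eta)^{1/\eta}$ (for $\epsilon = 0.4$,
$\eta = 1.6$ this is $x^* \approx 0.217$, i.e. one fifth of carrying
capacity to the printed precision), and decays for crowded cells. Note the
exponent sign: only the *negative* exponential gives a transform that is
unimodal with an interior maximum; with a positive sign the expression
diverges and has no maximum, so the standard Weibull density form is used.
$w_{max}$ is the supremum of $w$ over $x \ge 0$, evaluated in closed form
at the mode, which scales $\Phi_{Av}$ to $[0, \rho_c]$.

The growth rate is $r = r_{max}\,\Phi_{Av}/\rho_{c,max}$. Dividing by
$\rho_{c,max}$ makes $r$ dimensionless in the right way: $\Phi_{Av}$
carries density units, and without the normalization the nominal
$r_{max} = 0.01\ \mathrm{yr}^{-1}$ would not be the attainable maximum.

**Uninhabitable cells.** A fitted logistic model never returns exactly
zero, so a cell can only have $\rho_c = 0$ where a modifier vanishes. Two
modifiers do this: water ($g_{wat}$) and the *a-priori habitability
override* (`apriori_modifier()`), which zeroes $\Phi_{Ac}$ wherever the raw
climate violates the same a-priori rules used in training. This override
matters dynamically: for $\rho \gg \rho_c$ the Weibull tail drives
$\Phi_{Av} \to 0$ and with it $r \to 0$, so an overcrowded cell with a
small positive $\rho_c$ is nearly frozen rather than declining. Stadial
population losses therefore happen where stadial climate crosses the
habitability bounds and $\rho_c$ drops to exactly zero; such cells decay
exponentially at rate $r_{max}$ (the package's uninhabitable-cell rule —
the growth law itself is silent at $\rho_c = 0$).

## Time forcing

Suitability is estimated only for prototypical stadial (GS) and
interstadial (GI) states, per cultural phase. A normalized oxygen-isotope
series $\delta^{18}O_n(t) \in [0,1]$ (min/max taken within the study
window, nearest 20-year step, no interpolation between steps) blends them:

$$\Phi_{Ac}(t) = (1 - \delta^{18}O_n(t))\,\Phi_{Ac}^{GS}
  + \delta^{18}O_n(t)\,\Phi_{Ac}^{GI}.$$

The phase switch (default 38 ka) is hard: no cross-phase blending, because
no blending rule is defined for cultural transitions; adaptation enters the
model only through the phase-specific HEP stacks.

# Numerical scheme

* **Grid.** Regular lon/lat mesh, cell centers, half-open cell edges for
  point binning. Cell areas $R^2 \Delta\lambda(\sin\varphi_{top} -
  \sin\varphi_{bot})$ telescope exactly to the spherical box area.
  $R = 6371$ km.
* **Transport.** Conservative finite-volume update: first-order upwind
  advective fluxes and centered diffusive fluxes across cell faces with
  spherical face lengths; water cells and domain edges are no-flux. This
  conserves total persons to rounding and preserves positivity under the
  stability bounds $\max|v|\,dt/\min(\Delta x, \Delta y) < 1$ and
  $D\,dt/\min(\Delta x, \Delta y)^2 < 1/4$, which are checked every step
  (violations abort with the offending cell). Upwinding is first-order and
  therefore numerically diffusive; corridor tests show invasion fronts
  within 15 % of the analytic $2\sqrt{rD}$ Fisher–KPP speed, with the
  numerical front consistently slightly slow.
* **Splitting.** Transport first, then growth, each time step (10 days by
  default). The order is a convention; at these rates the splitting error
  is far below the scheme's spatial error.
* **Growth.** The logistic step uses the closed-form solution over $dt$
  per cell, so it is exact for a constant rate, unconditionally stable,
  and handles $\rho > \rho_c$ (relaxation from above) without overshoot.
* **Velocity.** Exponential-Euler update
  $v \leftarrow v e^{-\gamma dt} + (\alpha/\gamma)(1 - e^{-\gamma dt})
  \nabla\Phi_{Av}$: exact for piecewise-constant forcing and bounded by
  $|\alpha\nabla\Phi_{Av}|/\gamma$.
* **Operators.** Centered second-order differences with the metric
  $\Delta x = R\Delta\lambda\cos\varphi$; one-sided at mask and domain
  edges; the Laplacian is the finite-volume divergence of that gradient, so
  closed regions satisfy a discrete divergence theorem.
* **Output.** Snapshots, the total population $\Lambda = \sum \rho_{ij}
  s_{ij}$, the mobility index $M = \sum |f_{ij}|$ (population flux
  $f = v\rho - D\nabla\rho$, stored per year, reported per decade with an
  exact factor 10) and the first-arrival map (first snapshot time with
  $\rho \ge 0.4$ P 100 km⁻²) are recorded every 10 model years.

## Default parameters

| parameter | default | units | role |
|---|---|---|---|
| $\rho_{c,max}$ | 5 | P 100 km⁻² | cultural carrying capacity |
| $\epsilon$, $\eta$ | 0.4, 2.5 | — | Weibull scale/shape of $\Phi_{Av}$ ($\eta = 1.6$ reproduces the illustrative curve with its peak at $0.2\rho_c$) |
| $\alpha$ | 20 | P km² yr⁻² | drift scaling (opaque calibration constant; optionally $V/(G\tau)$) |
| $\gamma$ | 0.1 | yr⁻¹ | drift damping |
| $D$ | 10–100 | km² yr⁻¹ | diffusivity range (clipping bounds for the mixing closure) |
| $\kappa, \kappa_l, \kappa_\sigma$ | 1, 1, 0.1 | — | diffusivity closure coefficients |
| $r_{max}$ | 0.01 | yr⁻¹ | maximum net production rate |
| $dt$ | 10 | days | time step |
| arrival threshold | 0.4 | P 100 km⁻² | first-arrival definition |

The seeding default (a Gaussian of great-circle distance, 150 km spread,
5000 persons, centered in the Levant at 35°E, 32.5°N, starting at 45 ka) is
a configuration choice, exposed in full; the center and spread have no
canonical values and results near the seed should be read accordingly.

## Perturbed-parameter ensembles

Uncertainty in the three most influential dynamics parameters —
$\rho_{c,max}$, $\alpha$, and the diffusivity range — is quantified with a
full-factorial perturbed ensemble: 5 evenly spaced levels per parameter
spanning ±50 % of the base values (125 members), the diffusivity range
perturbed by a common scale on both bounds. The design is a choice: the
member count factorizes naturally as $5^3$ and a full factorial keeps every
member interpretable. Member runs are deterministic, order-invariant and
reproducible from the manifest. Arrival-time spread across members uses the
population (divide-by-$n$) standard deviation, a convention, as is the same
choice for the niche-ensemble spread.

# The synthetic-data generator

Every input has a synthetic counterpart so the full pipeline runs with no
downloads (`synthetic_scenario()`, `build_synthetic_inputs()`):

* **Climate**: smooth latitudinal/longitudinal base fields plus seeded
  Gaussian-random-field noise (white noise blurred with a separable
  Gaussian kernel); the stadial fields are the interstadial fields shifted
  by fixed offsets (−6 °C annual mean temperature, +2 °C seasonality,
  −20 mm wettest-month precipitation, +5 precipitation seasonality —
  magnitudes typical of millennial-scale stadial excursions in mid-latitude
  Europe).
* **Sites**: Bernoulli draws per cell from a known truth niche model,
  thinned to a target count (default 150 over a 40 × 30 cell domain at
  0.5°). `simulate_presence_absence()` labels *every* cell this way for
  recovery studies, where the archaeological labelling (thinning +
  pseudo-absences) would deliberately dilute the signal.
* **Isotope series**: a square or sine wave at 20-year steps; the square
  wave yields pure-stadial/pure-interstadial epochs after normalization.
* **Topography**: meridional Gaussian ridges, sub-grid roughness
  proportional to ridge height, and an ocean rim on the domain boundary.

What the generator deliberately does *not* emulate: real geography and
coastlines, the actual isotope waveform (only its stadial/interstadial
alternation), spatially correlated site-discovery bias, and dating
uncertainty. Passing tests on synthetic data therefore demonstrate that the
estimator and solver recover known structure under the model's own
assumptions — not that those assumptions hold for any particular
archaeological record.

## Problem sizes used in the test-suite studies

The shipped studies run at desk scale: niche recovery on a 0.25° variant of
the synthetic domain (~4500 labelled cells, 50-member ensemble), where the
field-recovery error of the ensemble mean has comfortable margin;
solver oracles (diffusion moment growth, closed-basin conservation,
logistic exactness) on small near-equatorial grids; Fisher–KPP front speeds
on a 0.05° corridor (~800 × 3 cells) so the front width spans at least six
cells for every $(r, D)$ combination tested; and the end-to-end
reconstruction on the default 40 × 30 domain for 2000 model years under
square-wave forcing. These sizes are the package's reference study
conditions; everything scales to larger domains through the configuration.

# Known limitations

* First-order upwind advection is robust but diffusive; sharp population
  fronts are smeared over a few cells and front speeds carry a small
  negative bias.
* Diffusion is isotropic; no preferred-direction mixing.
* The demographic model has no age structure, group interactions, or
  explicit adaptation; net production is a single logistic rate.
* The time blend assumes suitability varies between two fixed end-member
  states per phase; abrupt events shorter than the 20-year isotope step are
  invisible.
* Pseudo-absence option 3 makes the training labels deliberately noisy;
  the fitted suitability is conservative (biased low) by construction, and
  model skill there is bounded by the label noise, not by the estimator.
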
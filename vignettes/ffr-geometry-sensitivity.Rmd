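---
title: "How geometry-reconstruction errors propagate into FFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How geometry-reconstruction errors propagate into FFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrsens)
```

## The model

Fractional flow reserve is measured clinically as the minimum over time
of the ratio of moving cycle averages of the distal and proximal
pressures, $\mathrm{FFR} = \min_t \bar P_1(t)/\bar P_0(t)$ with
$\bar P_i(t) = \tau^{-1}\int_t^{t+\tau} P_i\,dt'$ and $\tau$ the mean
cardiac cycle period. Image-based FFR estimates $P_1$ from a flow
computation on a reconstructed lumen, so the reconstruction error budget
matters. This package isolates that budget on an idealized geometry where
everything else is controlled.

**Geometry.** The lumen is a straight cylinder (diameter $D$, length
$L = 11.6D$) minus a sphere (diameter $D_s = 1.94D$) centred at axial
position $L_s = 1.92D$ and transverse offset $d$ — an eccentric plaque
bounded by an arc of normal wall, the common morphology of atheromatous
lesions. The minimum lumen area is the closed-form circle–circle lens at
the neck plane, and severity is $S = 1 - 4A_{\min}/(\pi D^2)$. Published
descriptions state severities, never the offset, so $d$ is always
recovered by root-finding on the strictly monotone map $d \mapsto S$
(`calibrate_offset()`, bisection-safe bracket between the engulfment and
tangency limits, $10^{-12}$ relative tolerance).

**Segmentation error.** A one-pixel contour error (~300 μm at typical
CT angiography resolution; ~30 μm for optical coherence tomography) is
modelled as a signed error $\delta D_s$ in the carving-sphere diameter
with the centre held fixed. This is the only convention consistent with
"an increase/decrease of $D_s$" while reproducing the stated perturbed
severities to about a point: with $D = 5.15$ mm, $D_s = 10$ mm and the
offset calibrated to $S = 0.583$, we obtain

```{r severities}
g <- stenosis_geometry(D = 5.15e-3, Ds = 10e-3, severity = 0.583)
c(plus = severity(perturb(g, +300e-6)),
  minus = severity(perturb(g, -300e-6)))
```

against published values of 63% and 53%. The residual (≲1.4 points) is
attributable to the unstated offset/centre convention of the source
geometry; we deliberately do not tune the convention to force agreement.

**Faceted surfaces.** Segmentation pipelines deliver the lumen as an STL
triangle mesh. `tessellate()` samples the wall of the stenotic region
(the carved span plus one diameter each side) on a structured
axial × circumferential grid, projecting cylinder points that fall inside
the carving sphere centrally onto it, and `sri()` computes the Surface
Resolution Index $N/(S_{\rm area}/D^2)$. SRI quantifies *our own*
refinement ladder: faceting quality is method-dependent, so no attempt is
made to reproduce any particular exporter's $\Pi(\mathrm{SRI})$ curve.
Both STL dialects (binary and ASCII) are supported with exact
round-tripping at 32-bit float precision.

## Hemodynamic closure

**Inlet.** The section-averaged inlet velocity is a six-harmonic Fourier
series $v_0(t) = v_{0m} + \sum_{n=1}^6 [a_n\sin(2\pi n\Omega t) +
b_n\cos(2\pi n\Omega t)]$ with typical hyperaemic values $v_{0m} = 0.7$
m/s, $\Omega = 1.2$ s$^{-1}$. The radial profile family is the Womersley
oscillatory pipe-flow solution parameterized by $\eta$ (inverse Womersley
number), interpolating uniform ($\eta = 0$) to parabolic
($\eta = \infty$); its normalization makes the section average equal
$v_0$ exactly for every $\eta$, a property the tests verify to $10^{-6}$
by quadrature. Evaluation needs Bessel functions $J_0, J_1$ of complex
argument on the Kelvin ray; no installed R package provides these, so the
package implements the ascending series for $|z| \le 12$ and the Hankel
asymptotic expansion beyond, with a Stokes-boundary-layer form below
$\eta = 2\times10^{-3}$ to avoid overflow. Branch agreement at the splits
is ~$10^{-9}$ and is tested against quadrature of the integral
representation $J_0(z) = \pi^{-1}\int_0^\pi \cos(z\sin\theta)\,d\theta$.

**Rheology.** Blood viscosity follows the Carreau-type law
$\mu = \mu_\infty\{1 + 15.2\,\omega\,[1+(\lambda\dot\gamma)^2]^{(n-1)/2}\}$
with $\mu_\infty = 0.0035$ Pa s, $\lambda = 3.31$ s, $n = 0.357$;
$\omega \in \{0, 1\}$ switches the Newtonian approximation on or off. The
dimensionless groups are $Re = \rho v_{0m} D/\mu_\infty$,
$Re^*(t) = \rho v_0(t) D/\mu_\infty$ and
$\alpha = D\sqrt{2\pi\Omega\rho/\mu_\infty}$ (7.78 at the reference
conditions with $\rho = 1060$ kg/m³). Density is an explicit input:
published Reynolds numbers for such configurations are not always
consistent with the printed $v_{0m}$ and any standard blood density, so
`Re` is never silently derived when a user supplies it directly.

## The pressure-drop surrogate

A full 3D flow solve is out of scope by design; the trans-stenotic drop
$\Pi = (P_0-P_1)/\rho v_{0m}^2$ is supplied by an explicitly labelled
reduced-order stand-in of Young–Tsai type,

$$\Pi(S, Re) = \frac{K_v}{Re} + \frac{k_t}{2}\Big(\frac{S}{1-S}\Big)^2 ,$$

strictly increasing in $S$ and decreasing in $Re$, calibrated by exact
solve (two anchors) or least squares (more) on user anchors. The default
anchors are the two reference values $(S, Re, \Pi) = (0.583, 1268, 4.03)$
and $(0.63, 1268, 4.93)$:

```{r model}
pressure_drop_model()
```

Both anchors share one Reynolds number, so the calibration cannot
separate the viscous and expansion contributions from data alone; the
fitted $K_v$ absorbs whatever $Re$-dependence the anchors imply. The
resulting $Re$-decay between 500 and 2000 (ratio ≈ 0.44) is much weaker
than the Poiseuille prediction (0.25), as it should be for a drop
dominated by the expansion loss, but users holding a real $\Pi(S, Re)$
table should prefer table mode (bilinear interpolation, hull-guarded)
over the correlation. A corollary worth knowing: at $S \to 0$ the
surrogate's straight-tube drop is larger than a boundary-layer estimate
would give, so unstenosed FFR values sit near 0.89–0.95 rather than
indistinguishably close to 1.

Pulsatility enters through
$\Pi^*(t) = \Pi(S, Re^*(t)) + (K_u L_{\rm eff}/D)\, D\dot v_0/v_0^2$,
with the inertial coefficient defaulting to the pressure-tap span
$2L_s/D + D_s/D = 5.78$ diameters. At zero acceleration $\Pi^*$ coincides
exactly with the steady value at the same $Re^*$; the drop is larger
during acceleration than deceleration at matched $Re^*$. The profile
shape $\eta$, rheology switch $\omega$ and SRI do not enter the
surrogate: their FFR effect is below the percent level at the severities
of interest, which is exactly the attenuation result below.

**Error attenuation.** With $\beta = P_0/(\rho v_0^2) \sim 10^2$ and
$\Pi^* \sim 4$, a relative drop error $\epsilon_{\Pi^*}$ maps to a ratio
error $\epsilon_R = \epsilon_{\Pi^*}\beta\Pi^*/(R(\beta-\Pi^*)^2)
\approx 0.04\,\epsilon_{\Pi^*}$: modelling errors in $\Pi$ are attenuated
twenty-five-fold, geometry errors (which move $S$, hence $\Pi$, by tens
of percent) are not. The published relation for $R(\Pi^*)$ is
algebraically inverted relative to its own small-drop limit; the package
defaults to the consistent form $R = 1 - \Pi^*/\beta$ and exposes the
literal printed form behind `printed_form = TRUE` — neither is silently
corrected.

## The statistic and the study drivers

`cycle_average()` implements the moving window as trapezoidal quadrature
of the piecewise-linear interpolant with interpolated endpoints; the
$1/\tau$ normalization cancels in the ratio. `compute_ffr()` evaluates
the ratio at every sample time whose window fits and takes the discrete
minimum; the cycle period is supplied or estimated by autocorrelation
(first peak above 0.5 normalized height) refined by mean inter-peak
interval. `ffr_vs_severity()` composes calibration → perturbation →
distal-pressure synthesis → FFR, and `histogram_remap()` applies the
population-level thought experiment: treat each histogram bin centre in
[0.7, 0.9] as a true FFR, invert the nominal curve for severity, look up
the perturbed curve, and move the patients to the bin of the wrong value
(bin centres; counts conserved exactly). Under the surrogate all curves
are strictly monotone in severity, so the non-monotonic behaviour a full
flow solve can produce for under-segmented geometries (a distal-tap
proximity effect) does not occur here — a documented divergence.

## Synthetic data

No clinical recordings are shipped. The generators emulate the *shape
class* of hyperaemic recordings and make no claim of patient realism:

* velocity: a fixed diastolic-dominant template (small systolic bump,
  dominant diastolic bump) projected exactly onto six harmonics; mean
  exactly $v_{0m}$ before noise; ground-truth coefficients returned.
* pressure: an aortic template with systolic upstroke, dicrotic-notch
  feature and diastolic decay, normalized to hit $P_{\rm dia}, P_{\rm sys}$
  exactly on the sampled phase grid (defaults 70/130 mmHg).
* cycle-length jitter: per-cycle period multiplied by a lognormal with
  median 1 (default s.d. 3%); additive Gaussian noise (default ~1% of
  pulse pressure).
* paired records with a designed ratio profile $r(t)$, so the windowed
  minimum has a known target; FFR histograms from a beta distribution
  parameterized by mode (0.85) and concentration.

Features of real data deliberately not emulated: respiratory modulation,
baseline drift, catheter damping, ectopic beats, pressure-velocity phase
coupling. Passing tests therefore demonstrate correctness of the
statistics and the propagation algebra under controlled conditions, not
robustness to every clinical artefact.

All generators are pure functions of their parameters and seed; the
pipeline derives named substream seeds from one top-level seed, and
identical configurations produce byte-identical result files.

## Numerical choices and problem sizes

* Lens/severity root-finding: `uniroot` on a monotone bracket,
  $10^{-12}$ relative; acos arguments clamped at tangency.
* Monte-Carlo severity oracle: $10^7$ uniform points (~0.02 pp standard
  error) in the acceptance script; test suites use grid point-counting
  (~$2\times10^{-4}$ relative) for speed.
* Default study sizes: 25-cycle records at 100 samples/cycle; sweep over
  severities 0.40–0.70 in steps of 0.05 for three $\delta D_s$ values;
  50-seed Monte-Carlo for recovery properties. These sizes make the full
  pipeline run in about a second while keeping estimator noise well
  below the tolerances being asserted.
* Degenerate inputs error early and by name: non-monotone nominal curves
  in the remap, flow reversal in the inertial term, averaging windows
  exceeding the record, table queries outside the calibration hull.

## Known limitations

The surrogate is a calibrated stand-in, not a flow solution: absolute
$\Pi$ and FFR values away from the calibration anchors inherit the
correlation's shape assumptions, and the two default anchors cannot
constrain the $Re$-dependence. Geometry is rigid, straight and
single-vessel; no collateral flow, no wave reflection, no hyperaemia
pharmacodynamics. The histogram remap needs curves covering the mapped
FFR range; bins outside coverage are left untouched. SRI values are
comparable only within one tessellation method.
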
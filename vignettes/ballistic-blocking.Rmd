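---
title: "Quantifying ballistic-droplet blocking by porous cloths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ballistic-droplet blocking by porous cloths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbcsim)
```

## The problem

Large ("ballistic") respiratory droplets travel like projectiles from an
emitter's mouth to a receiver's face; they dominate short-range disease
transmission and are exactly what cloth face masks are supposed to stop.
`bbcsim` implements a frugal, stain-based protocol for comparing how well
fabrics block such droplets, together with a minimal mechanical model that
explains the measurements. The bench it emulates sprays dyed water
horizontally from a nozzle toward a paper screen 19 cm away; a flat piece
of fabric can be interposed anywhere in between. Each shot leaves a stain
pattern that is scanned and binarized; the statistic of interest is the
**Ballistic Blocking Capacity**

$$\mathrm{BBC} = \left(1 -
  \frac{\langle \bar p_o\rangle}{\langle \bar p_{no}\rangle}\right)
  \times 100\%,$$

where $\langle \bar p_o\rangle$ and $\langle \bar p_{no}\rangle$ are mean
binary-pixel fractions of the scans with and without the obstacle,
averaged over replicates. BBC is 100% when the fabric stopped everything
and 0% when it stopped nothing.

## Flight model

Between planes a droplet of radius $r$ feels only gravity and Stokes drag
$-6\pi\eta r \mathbf v$. With relaxation time $\tau = 2\rho r^2/(9\eta)$
the trajectory has the closed form

$$y(x) = y_0 + \left(\tan\theta_0 +
  \frac{\tau g}{v_0\cos\theta_0}\right)(x - x_0) +
  \tau^2 g\,\ln\!\left(1 - \frac{x - x_0}{\tau v_0\cos\theta_0}\right),$$

valid until the horizontal displacement approaches its supremum
$\tau v_0 \cos\theta_0$; a droplet whose supremum falls short of a target
plane is classified *stalled* (physically it decelerates and drops).
Constants default to air and water at 30 °C
($\eta = 18.73\times10^{-6}$ Pa s, $\rho = 995.7$ kg/m³, $g = 9.81$
m/s²). The closed form is verified in the test suite against brute-force
RK4 integration of the equations of motion to relative error below
$10^{-5}$, and against the drag-free parabola in the short-range limit.
A consequence worth noting: a 7 µm droplet launched at 3 m/s has a total
range under a millimetre — aerosol-scale droplets simply cannot reach the
screen ballistically, which is why the model ignores them.

## Emission and cloth model

A simulation emits 100 000 droplets at $v_0 = 3$ m/s with launch angles
uniform on $[-10^\circ, 10^\circ]$ (the source text says only "random
direction within an angular range"; uniform is the maximum-entropy
reading, and it is configurable). Droplet diameters follow a lognormal
matched by moments to the measured stain statistics — mean 54.0 µm, SD
52.3 µm — truncated below at the 7 µm detectability floor. The moment
match is done *before* truncation; sampling is inverse-CDF conditional so
no rejection loop is needed. An empirical diameter list can replace the
lognormal.

The cloth is two numbers: a **tunneling probability** $p \in [0,1]$ (the
chance a droplet gets through) and a **deceleration factor** $f \in
[0,1]$ (exit speed over entry speed). Neither depends on droplet radius
or incidence angle. The **simulated** blocking statistic, SBBC, applies
the BBC formula to total droplet *volume* reaching the central band of
the screen. "Central band" is nowhere defined by the protocol, so the
package takes $|y - y_{\mathrm{nozzle}}| \le 2$ cm, configurable through
`experiment_geometry()`.

### Bernoulli vs. weighted tunneling

`simulate_experiment()` offers two treatments of the tunneling coin. The
default (`"bernoulli"`) flips one uniform variate per droplet per
barrier, drawn from a stream independent of emission sampling, so that
common-random-number comparisons across $(p, f)$ are monotone in $p$.
The `"weighted"` treatment replaces the coin by its conditional
expectation: every droplet reaching the barrier continues with its
carried volume multiplied by $p$, and the blocked mass is accounted
separately. Both conserve volume exactly. The weighted estimator has zero
tunneling variance and makes SBBC *exactly affine* in $p$ at fixed $f$
under a fixed emission sample, with SBBC$(0, f) = 100$ identically — a
structure the calibration exploits and the acceptance suite verifies to
$10^{-9}$. This is a variance-reduction device (Rao–Blackwellization over
the tunneling variate), not a change of model: both estimators have the
same expectation.

## Calibration

Given observed BBC values at several cloth positions, `fit_pf()`
minimizes $\sum_i w_i(\mathrm{SBBC}_i(p, f) - \mathrm{BBC}_i)^2$ with
$w_i = 1/\sigma_i^2$. Because the weighted estimator makes
$\mathrm{SBBC}_i = 100(1 - p\,R_i(f))$ with $R_i(f)$ computable once per
$f$, the objective is an exact quadratic in $p$; the optimizer is a
101×101 grid over $[0,1]^2$ followed by one 21×21 local refinement, with
exact ties broken to the smallest $p$, then the smallest $f$ — chosen for
reproducibility over a plateau-prone Monte-Carlo surface. The whole fit
is deterministic given the emission seed. Parameter-recovery experiments
in the acceptance suite (4 positions, 100 000 droplets, 1 percentage
point of observation noise, 10 seeds) recover $p$ to a median error well
inside ±0.02 and $f$ inside ±0.1 around the silk-like operating point
$(0.04, 0.56)$.

Positions with a blank obstacle group have zero replicate scatter; the
stage-4 analysis floors their $\sigma_i$ at 0.5 percentage points so a
degenerate weight cannot dominate the objective.

Two auxiliary statistics mirror the protocol's reporting: ordinary
least-squares lines of blocking versus cloth position (values
extrapolating beyond 100% are flagged, never clamped), and an exact
one-tailed Mann–Whitney U test for comparing source-side against
receiver-side placements with three replicates per group. For combined
sample sizes up to 12 the p-value is computed by enumerating all group
assignments; beyond that a tie-corrected normal approximation takes over.

## Imaging pipeline

Scans are binarized by Otsu's threshold (a fixed threshold is available),
with a polarity flag covering both ink conventions; a perfectly uniform
image degrades to "no stains" with a warning. Stains are 8-connected
components — a dedicated union-find labeler, since 4-connectivity splits
diagonal contacts — filtered at `min_area` = 3 px to suppress scanner
salt noise, and summarized by the equivalent-disk diameter
$2\sqrt{A/\pi}$. The stain-size SD uses the population divisor $n$ by
default (the reported "SD" does not state a convention; the sample
divisor is a switch away). Replicate uncertainty for BBC uses first-order
propagation of the ratio with standard errors of the per-replicate
fractions; per-image fractions are averaged within groups first, matching
the "averaged over the images from all similar experiments" wording (the
pooled-pixel alternative would weight large scans more).

Note one deliberate mismatch, kept verbatim from the protocol: BBC
weights by stain *area* (pixels), SBBC by droplet *volume*. The package
does not reconcile them. In the end-to-end analysis this is visible as a
calibrated $(\hat p, \hat f)$ that differs somewhat from the pair used to
generate the images — the fit absorbs the definitional difference.

## Synthetic data: what it emulates and what it does not

`render_scan()`/`generate_experiment_set()` turn simulated impacts into
scanner-like images with full ground truth, so the whole pipeline is
testable without any real scans. Defaults: 4800 dpi (pixel ≈ 5.3 µm,
keeping the 7 µm floor representable), a 1 cm × 1 cm window of the
screen centered on the nozzle height, spread factor $\beta = 1$ (stain
diameter = droplet diameter, the same proxy approximation the
measurements make), salt-and-pepper rate $2\times10^{-4}$ — low enough
that the default `min_area` filter removes all noise components in
expectation — and no blur. The flight model is planar, so the transverse
image coordinate is drawn uniformly across the window: a visualization
convention, not physics. At these defaults a free-configuration run
covers roughly 20% of the window, so overlapping stains make the pixel
fraction slightly sub-linear in total stain area; the round-trip
agreement between image-based BBC and the manifest's area truth is
within ±3 percentage points, and the residual is saturation, not a
pipeline defect. Satellite droplets, elongated splashes, dewarping and
illumination gradients of real scanners are out of scope.

## Numerical and design choices

- Units are SI internally; configuration files accept cm (geometry) and
  µm (diameters) and convert at the boundary, matching bench practice.
- The nozzle height above the bucket floor is not specified by the
  protocol; the default is 10 cm, and droplets crossing $y = 0$ before
  the screen are classified `fell` (negligible at default geometry).
- Stalling raises a dedicated condition class
  (`bbcsim_stalled_error`), distinct from argument errors, so transport
  code can treat "physically cannot reach" separately from misuse.
- The four standard cloth positions interpolate evenly between 1.5 cm
  from the nozzle and 1.5 cm from the screen (the two end placements the
  bench defines); intermediate positions are not printed in the source
  material.
- Two stacked cloths are modeled by applying the barrier interaction at
  each plane in order of distance.
- Derived seeds (configuration index × 997 + replicate, and an
  offset-by-one stream for tunneling coins) keep every run reproducible
  byte for byte while replicates stay independent.
- Analysis-stage problem sizes: the drivers under `analysis/` use the
  full 100 000-droplet emission for transport and fitting, and render
  synthetic scans at 1200 dpi — stain diameters on the screen are an
  order of magnitude above that pixel pitch, and the set stays light.

## Known limitations

- The ballistic model carries no evaporation, no air currents, and no
  aerosol physics; it is a model of the bench, not of a room.
- $p$ and $f$ are radius- and angle-independent by construction; fabrics
  with strongly size-selective penetration will defeat the two-parameter
  summary.
- The area/volume weighting mismatch between BBC and SBBC means
  calibrated parameters are operational, not microphysical.
- Real deposited scans are not bundled; all images here are synthetic,
  and conclusions about real fabrics require running the imaging
  pipeline on real scans.
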
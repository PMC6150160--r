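---
title: "topiQuant methods: release kinetics, permeation, and quantitative IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{topiQuant methods: release kinetics, permeation, and quantitative IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topiQuant)
```

topiQuant implements the computational chain of a topical drug-delivery
study: fitting and selecting drug-release kinetic models, estimating skin
permeation coefficients, quantifying DAB chromogen in brightfield
immunohistochemistry (IHC) images, and comparing treatment groups. This
vignette is the package's account of the underlying methods, the choices
that were open, and what the accompanying tests do and do not demonstrate.

## Release kinetics

A dissolution profile is a series of cumulative release measurements
$F_t$ at times $t$ (hours). Four empirical laws are supported:

| model | formula | parameters |
|---|---|---|
| zero-order | $F = K_0\,t$ | $K_0$ |
| first-order | $F = F_\infty\,(1 - e^{-K_1 t})$ | $K_1$ |
| Higuchi | $F = K_H\,\sqrt{t}$ | $K_H$ |
| Korsmeyer–Peppas | $F = K_P\,t^{\,n}$ | $K_P$, $n$ |

All four pass through the origin. The Korsmeyer–Peppas law contains
zero-order ($n = 1$) and Higuchi ($n = 0.5$) as special cases, which the
test suite checks pointwise.

**Scale convention.** A `DissolutionProfile` stores release as a fraction
of the load in $[0, 1]$; files and fitted constants use percent. This
matters because the three scale-linear constants ($K_0$, $K_H$, $K_P$)
change by a factor of 100 between the two conventions, while $K_1$, which
sits in an exponent, does not. Reported constants are therefore
percent-per-hour style quantities (e.g. $K_0$ in %/h), with the
first-order plateau fixed at $F_\infty = 100\%$. The convention was fixed
once, up front, and all recovery tests generate and refit under it.

**Fitting.** Zero-order and Higuchi are through-origin linear regressions
on $t$ and $\sqrt{t}$ (`stats::lm`). First-order and Korsmeyer–Peppas are
bounded nonlinear least squares via Levenberg–Marquardt
(`minpack.lm::nlsLM`), started from closed-form estimates: a log-linear
rearrangement $-\log(1 - F/100)/t$ for first-order, and the slope and
intercept of the log–log regression $\log F \sim \log t$ for
Korsmeyer–Peppas. If the optimizer fails from the closed-form start, two
deterministic perturbed restarts (the start scaled by 0.5 and by 2) are
tried before a `fitFailureError` is raised; deterministic multipliers were
preferred over random perturbations so that fitting is bit-reproducible
without a seed. Bounds: all rate constants in $(0, \infty)$, release
exponent $n \in (0, 2]$.

$R^2 = 1 - SS_{res}/SS_{tot}$ is always computed on the untransformed
release scale — also for the linearized fits — so that candidate models
are compared like-for-like. Model selection takes the maximal $R^2$;
exact ties go to the model with fewer parameters, then to a fixed model
order, so selection is deterministic. $R^2$ is the only criterion: no
information criteria are computed, mirroring how such release studies are
usually reported.

Points at $t = 0$ with zero release are legitimate inputs (every law
passes through the origin) and are included in fitting. A profile whose
release values are all identical cannot constrain any model and is
rejected as degenerate.

**Assay calibration.** `lodLoq()` implements the ICH convention
$LOD = 3.3\,\sigma/S$ and $LOQ = 10\,\sigma/S$, where $\sigma$ is the
residual (or blank) response standard deviation and $S$ the calibration
slope. The convention fixes $LOQ/LOD = 10/3.3 \approx 3.03$ regardless of
the assay, which is the structural fact the acceptance check exploits.

## Permeation

Cumulative permeated amount per unit area $Q(t)$ (µg/cm²) through a
membrane approaches a straight line once steady state is reached; its
slope is the steady-state flux $J_{ss}$ (µg/cm²/h) and its x-intercept
the lag time. The permeability coefficient is
$$K_p = \frac{J}{C \cdot A},$$
with $J$ the permeation rate in µg/h, $C$ the donor concentration in
µg/mL and $A$ the contact area in cm², giving $K_p$ in cm/h. Because
experimental series are reported per area, the package estimates
$J_{ss}$, converts $J = J_{ss} \cdot A$, and reports both; the two
conventions are kept explicit because published flux/permeability tables
are often ambiguous about which one a value uses.

**Window selection.** No standard prescription exists for choosing the
"linear late phase", so the package uses an explicit, reproducible rule:
among all trailing windows (ending at the last sample, at least 3
points), keep those whose linear fit reaches $R^2 \ge 0.99$, and take the
best-fitting one, preferring the longest window on numerical ties
(within $10^{-9}$). If no window passes the gate the trailing half of the
series is used. The rule is validated against an exhaustive
trailing-window enumeration oracle on short series, and a caller can
always override it with an explicit window. A zero or negative slope
flags the result and suppresses $K_p$.

The default contact area, 4.909 cm², is the disc area of a 2.5
cm-diameter diffusion cell; it is a default, not a constant, and every
entry point accepts an override.

## Quantitative IHC

Brightfield H-DAB images are unmixed by Ruifrok–Johnston colour
deconvolution. Each 8-bit channel value $v$ becomes an optical density
$OD = -\log_{10}(\max(v,1)/255)$ (white background assumed); the per-pixel
OD vector is a non-negative combination of unit stain vectors —
hematoxylin $(0.650, 0.704, 0.286)$, DAB $(0.269, 0.568, 0.767)$, and a
complementary third vector (their normalized cross product) — so
inverting the $3 \times 3$ stain matrix yields per-stain amounts. Amounts
map back to 8-bit-style intensities $255 \cdot 10^{-a}$, where 0 is the
darkest shade (most chromogen).

Two quantification routes are provided:

**Zoned histogram score.** Masked DAB intensities are binned into
high positive $[0, 60]$, positive $[61, 120]$, low positive $[121, 180]$
and negative $[181, 235]$; $[236, 255]$ is excluded as fat/background.
The upper three ranges are the conventional published ones; the high
positive range $[0, 60]$ is the unique contiguous complement. Intensity
235 is kept in the negative zone (the explicitly stated negative range
wins over the exclusion range's nominal start at 235). The score is
$$\text{score} = \sum_z \frac{N_z \cdot w_z}{N_{\text{included}}},
\qquad w = (4, 3, 2, 1),$$
with $N_{\text{included}}$ the masked pixels outside the excluded range —
excluded pixels carry no pathological information and would otherwise
drag the score below its natural $[1, 4]$ range. An image whose masked
pixels are all excluded has no score and raises a dedicated error.

**Energy per pixel.** The chromogen "energy" treats each masked pixel's
DAB amplitude $s = 255 - \text{intensity}$ as signal and reports its
root-mean-square, $\sqrt{\tfrac{1}{N}\sum s^2}$ — a per-pixel norm of
cumulative signal strength, bounded in $[0, 255]$ and in the same
magnitude range as published EU/pixel values (tens to low hundreds). The
exact historical formula behind "energy units" is not published, so the
definition is configurable (`mode = "rms"` or `"mean_square"`) and the
RMS default is documented as this package's choice. Control correction
subtracts a no-primary-antibody slide's energy and floors at zero,
flagging a clamped (negative) difference.

Region isolation is an input (a mask image, 0 = outside), not a
computation: in practice stained regions are outlined manually, and
automated tissue segmentation is out of scope. A missing mask means the
whole image.

## Group statistics

Groups are summarized as mean, sample SD ($n-1$ denominator) and
SE $= SD/\sqrt{n}$. Pairwise comparisons use the two-tailed Welch t-test
for independent samples with unequal variances and Welch–Satterthwaite
degrees of freedom; `welchFromSummary()` computes it from summary
statistics alone (so printed tables can be re-tested without raw data)
and `welchTest()` from raw values, the two agreeing exactly. P-values map
to the categories NS, p<0.05, p<0.01, p<0.001 with *strict* inequalities,
matching the "p < 0.05" notation: a p of exactly 0.05 is NS. Degenerate
zero-variance pairs are handled explicitly (equal means: p = 1; unequal:
p reported as 0 with a degenerate flag).

`comparisonMatrix()` tests every unordered pair with **no**
multiple-testing correction by default — matching common practice in the
kind of study this package supports — with optional Bonferroni/Holm
adjustment behind an explicit flag.

The reproduction fixtures use $n = 7$ per group: the printed SE values in
the summary tables this package mirrors all equal $SD/\sqrt{7}$, even
though the animal count is stated as six; the SE arithmetic wins for
fixture purposes, and the acceptance tests additionally verify that the
reproduced significance categories are robust to $n = 6$.

## Synthetic data

The generators produce every input the pipeline consumes, seeded and
bit-reproducible (they save and restore the caller's RNG state):

- `simulateDissolution()` evaluates a release law forward, adds optional
  Gaussian noise on the fraction scale, and clamps to $[0, 1]$. With zero
  noise the curve is exact, which closes the parameter-recovery loop.
- `simulatePermeation()` builds $\max(0, \text{slope}\cdot(t - \text{lag}))$
  plus optional noise, floored at zero so cumulative amounts remain valid.
- `simulateIhcImage()` allocates pixels to scoring zones by
  largest-remainder rounding (so the total pixel count is conserved
  exactly and each zone is within one pixel of its requested fraction),
  shuffles positions with the seed, assigns mid-zone representative DAB
  intensities (30, 90, 150, 208; excluded 245) plus a uniform
  hematoxylin counterstain (OD 0.3), and renders RGB through the same
  stain matrix the deconvolution inverts. Round-trip error is therefore
  quantization-only, and the analytic expected score (from realized
  integer counts) equals the pipeline score exactly.
- `simulateGroup()` in `exact_moments` mode affinely rescales seeded
  normal draws so the sample mean and $n-1$ SD hit their targets to
  $10^{-9}$, letting printed summary tables be turned into raw-data
  fixtures.

What the generators deliberately do *not* emulate: tissue texture
(nuclei, tumour morphology), stain-vector variation between scanners,
uneven illumination, and autocorrelated dissolution noise. Passing tests
therefore demonstrate the correctness of the computations, not robustness
to real-slide artefacts.

## Numerical notes and limitations

- **8-bit quantization.** The deconvolution round trip recovers the DAB
  channel within ±1 grey level for stain amounts up to 1.5 OD. For the
  *secondary* channel in heavily mixed, very dark pixels (combined OD
  beyond roughly 1.3, minimum RGB values in single digits) the same
  guarantee is impossible from 8-bit data; the tests bound the
  counterstain round trip on pure-stain pixels instead.
- **Constant-scale ambiguity.** Published release-constant tables rarely
  state the scale of $F$; this package's percent/hour convention is
  self-consistent and is used for all recovery work, but constants from
  other sources should be checked against it before comparison.
- **Steady-state window.** The $R^2$-gated trailing-window rule is this
  package's own; with very noisy series it can fall back to the trailing
  half, and an explicit window is preferable when the experimenter knows
  the steady-state region.
- **Published permeability tables.** Flux/permeability pairs in the
  literature are not always mutually consistent under any single
  $(C, A)$; the package computes $K_p$ from its own flux estimate and
  stated $C$ and $A$ only, and does not attempt to reverse-engineer
  unstated donor concentrations.
- **Problem sizes.** The test suite runs 12-point dissolution profiles,
  permeation series of up to 15 points, images up to 40×40 pixels and
  groups of up to 9 samples — sizes at which every oracle (grid search,
  exhaustive window enumeration, numerical integration) is exact and the
  whole suite completes in seconds.

## A worked pipeline

```{r pipeline, eval = FALSE}
prof <- simulateDissolution("korsmeyer_peppas", c(KP = 1.192, n = 0.650),
                            times = 1:12)
sel <- selectModel(fitAllModels(prof))
bestModel(sel)

sim <- simulateIhcImage(64, 64, c(high_positive = 0.3, positive = 0.4,
                                  negative = 0.3), seed = 1)
score <- ihcScore(zoneHistogram(deconvolveHDAB(sim$image), sim$mask))
globalScore(score)

g1 <- simulateGroup("treated", 75.63, 23.59, n = 7, seed = 1)
g2 <- simulateGroup("cream", 106.33, 15.12, n = 7, seed = 2)
welchTest(g1, g2)
```
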
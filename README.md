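# topiQuant

topiQuant is an R package for the quantitative workflow of topical
drug-delivery studies — the kind of experiment in which a drug carrier
(for example a zeolite loaded with a chemotherapeutic) is characterised by
in-vitro dissolution, membrane permeation, and quantitative
immunohistochemistry (IHC) of treated tissue, with treatment groups
compared statistically. It is aimed at formulation scientists and image
analysts who want every number in such a study to come from tested,
scripted code rather than ad-hoc spreadsheets and point-and-click tools.

## What it computes

**Release kinetics.** Cumulative release profiles $F_t$ are fitted to the
four classical laws

- zero-order $F = K_0\,t$
- first-order $F = F_\infty(1 - e^{-K_1 t})$
- Higuchi $F = K_H\sqrt{t}$
- Korsmeyer–Peppas $F = K_P\,t^{\,n}$

by linear (zero-order, Higuchi) or bounded nonlinear (first-order,
Korsmeyer–Peppas) least squares, with $R^2$ always computed on the
untransformed release scale and the best model chosen by maximal $R^2$
(ties to fewer parameters). Time is in hours and constants follow a
percent-of-load convention. Assay helpers compute ICH detection limits
$LOD = 3.3\sigma/S$, $LOQ = 10\sigma/S$.

**Permeation.** The steady-state flux $J_{ss}$ (µg/cm²/h) is the slope of
the linear late phase of cumulative permeated amount per area, selected
by an $R^2$-gated trailing-window rule, and the permeability coefficient
is $K_p = J/(C\cdot A)$ (cm/h) with $J = J_{ss}\cdot A$.

**Quantitative IHC.** 8-bit RGB brightfield images are unmixed by
Ruifrok–Johnston H-DAB colour deconvolution; masked DAB intensities are
binned into high-positive/positive/low-positive/negative zones
([0,60]/[61,120]/[121,180]/[181,235], with [236,255] excluded) and scored
as $\sum_z N_z w_z / N_{included}$ with weights 4/3/2/1 (range 1–4).
A second route reports chromogen signal as RMS energy units per pixel,
control-corrected by subtracting a no-primary-antibody slide.

**Group statistics.** Mean/SD/SE summaries and pairwise two-tailed Welch
t-tests (unequal variances, Welch–Satterthwaite df) arranged into a
symmetric significance-category matrix (NS, p<0.05, p<0.01, p<0.001), by
default without multiplicity correction.

**Synthetic data.** Seeded generators produce dissolution curves from any
of the four laws, lagged permeation series, H-DAB images with exactly
known zone composition (rendered through the same stain matrix the
deconvolution inverts), and measurement groups whose sample mean and SD
hit targets exactly — so the full pipeline runs and is tested offline.

## Worked example

```r
library(topiQuant)

# release kinetics: simulate a Korsmeyer-Peppas curve and refit all models
prof <- simulateDissolution("korsmeyer_peppas", c(KP = 1.192, n = 0.650),
                            times = 1:12)
selectModel(fitAllModels(prof))
#> ModelSelection (criterion: max R² )
#>   zero_order         R² = 0.8644
#>   first_order        R² = 0.8772
#>   higuchi            R² = 0.9634
#>   korsmeyer_peppas   R² = 1.0000 <- best

# quantitative IHC on a synthetic image of known composition
sim <- simulateIhcImage(64, 64, c(high_positive = 0.3, positive = 0.4,
                                  negative = 0.3), seed = 1)
ihcScore(zoneHistogram(deconvolveHDAB(sim$image), sim$mask))
#> IhcScore: global = 2.7000 over 4096 included pixels

# Welch comparison of two groups matching published summary statistics
g1 <- simulateGroup("treated", 75.63, 23.59, n = 7, seed = 1)
g2 <- simulateGroup("cream",  106.33, 15.12, n = 7, seed = 2)
welchTest(g1, g2)
#> Welch comparison: t = -2.899, df = 10.2, p = 0.01553 -> p<0.05

# permeation: lagged series, steady-state flux and permeability
s <- simulatePermeation(slope = 5, lag = 1, times = 0:12,
                        donorConcentration = 4000)
analyzePermeation(s)
#> PermeationResult: Jss = 5 ug/cm^2/h, J = 24.54 ug/h, lag = 1 h, Kp = 0.00125 cm/h
```

The release selection shows the generating model winning with $R^2 = 1$
while the mis-specified laws trail it; the IHC global score 2.7 equals
the analytic expectation $0.3\cdot4 + 0.4\cdot3 + 0.3\cdot1$ of the
simulated zone fractions; the Welch p of 0.0155 falls in the p<0.05
category; and the permeation analysis recovers the simulated slope and
lag exactly, with $K_p = J_{ss}/C = 5/4000$ cm/h.

A thin command-line dispatcher over these functions ships at
`inst/scripts/topiquant.R` (subcommands `fit-release`, `permeation`,
`ihc-score`, `ihc-energy`, `compare-groups`, `simulate`, `run`), and
`runPipeline()` drives all stages from a YAML config. Input schemas are
plain delimited text (`time_h,release_pct`;
`time_h,cumulative_ug_per_cm2`; `group,value`) plus 8-bit PNG/TIFF
images; small ready-made fixtures live in `inst/extdata/`.

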
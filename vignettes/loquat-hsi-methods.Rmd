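---
title: "Methods: hyperspectral quality calibration and maturity staging of loquat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral quality calibration and maturity staging of loquat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loquatHSI)
```

# The problem

Loquat quality is judged by three destructively measured traits —
surface colour, flesh firmness (kg/cm²) and soluble solids content
(SSC, °Brix) — and a maturity stage used for harvest and grading
decisions. Visible/near-infrared hyperspectral imaging offers a
non-destructive surrogate: a camera records a reflectance spectrum
(here a 256-band grid over 390–1030 nm) at every pixel of the fruit,
and multivariate calibration maps spectra to trait values. This
package implements that full chain and a synthetic-data generator that
lets every stage be tested against a known ground truth.

# Reference chemistry

Colour is summarised by the statistic

$$ e = \frac{1000\,a^*}{L^* \, b^*}, $$

computed from CIELAB coordinates; it grows as fruit turn from green
(negative $a^*$) to deep orange. Maturity stages are defined directly
on $a^*$: stage I for $a^* < 8.33$, stage III for $a^* > 15.41$, stage
II in between. Both thresholds are assigned to stage II (closed
interval) so the three predicates partition the real line; the sources
that define the staging give open phrasing on both sides of the
interval, so boundary membership had to be fixed by choice, and a
partition is the only option that classifies every fruit exactly once.
Summary statistics everywhere use the $n-1$ standard deviation.

# Cube correction and extraction

Raw sensor counts are corrected against white ($W$) and dark ($B$)
reference cubes, $I = (I_0 - B)/(W - B)$, which cancels dark current
and any gain common to the three images (the correction is invariant
to a shared positive gain, a property the tests assert). Corrected
values below 0 — sensor noise where the scene is as dark as the shutter
reference — are clipped to 0 and counted. Fruit segmentation is not
specified by typical acquisition protocols, so the package uses a
deterministic engineering choice: Otsu's threshold on the mean
reflectance in a 750–850 nm window (fruit is bright, background dark
in the NIR), hole filling, and removal of components under 16 pixels.
ENVI I/O supports the float32 and uint16 dialects, the three
interleaves and both byte orders; anything else raises an explicit
unsupported-format error.

# Preprocessing and representative splitting

Diffuse reflectance off a curved fruit surface multiplies and offsets
each spectrum by sample-specific scatter factors. SNV removes exactly
that: each spectrum is centred and scaled to unit ($n-1$) standard
deviation, making it invariant to $a x + b$ with $a > 0$ and
idempotent.

Calibration/prediction splits are deterministic farthest-point
selections. For regression, SPXY sums the spectral and response
Euclidean distance matrices, each normalised by its maximum (the
response is standardised first), so the calibration set spans both
spaces; the classification split is plain Kennard–Stone on spectra,
run within each stage for stratification. Set sizes use round-half-
away-from-zero with a largest-remainder repair against the requested
total — the rule that reproduces the canonical 105/35, 90/30 and
166/83 splits exactly. Ties in the farthest-point argmax go to the
lowest sample index, making both algorithms exactly reproducible; the
seeded algorithms (CARS, GA) additionally canonicalise sample order
(by response, then spectrum sum) before consuming the seed, so results
do not depend on input row order.

# Wavelength selection

All three selectors return a `SelectionResult` with the chosen band
indices, the RMSE trace and the winning iteration.

**CARS.** In each of 50 Monte-Carlo runs, a PLS model fitted on a
random 80% calibration subset weights every retained band by its
absolute regression coefficient. A forced-retention schedule keeps the
top fraction $r_i = a e^{-k i}$ of bands, with $a$ and $k$ fixed by
the endpoints $r_1 = 1$ and $r_{50} = 2/p$ (the standard formulation —
the named algorithm's decay constants are not printed anywhere, so the
endpoint convention is adopted). Adaptive reweighted sampling (draws
with replacement proportional to weight) then thins the survivors, and
the subset with minimal 5-fold RMSECV across runs wins. The PLS
component cap inside the loop is 10, with the inner CV picking the
best count per subset.

**GA.** Binary chromosomes over the bands; fitness is $-$RMSECV of a
PLS model on the encoded subset, with the folds drawn once so that all
chromosomes are compared on the same partition (which also makes
fitness caching sound). Operators are tournament selection of size 2,
single-point crossover at 0.5, bitwise mutation at 0.01, elitism of
one, for 100 generations of a population of 30 (defaults). The
all-zero chromosome is assigned worst fitness and never fitted. The
initial inclusion probability (0.1 per band) is a package choice:
sparse starts keep early fitness evaluations cheap and bias the search
toward the small subsets the method exists to find.

**SPA.** From every start band a chain grows by repeatedly appending
the band with the largest norm orthogonal to the span of the chain
(classical Gram–Schmidt deflation; a numerically zero projection
truncates the chain). Every (start, length) prefix is scored by the
validation RMSE of an ordinary least-squares model on an internal SPXY
75/25 sub-split, and the global minimiser is returned. SPA is fully
deterministic and exactly permutation-invariant.

# Calibration families and evaluation

PLSR uses an in-package SIMPLS engine that returns the whole
coefficient path in one decomposition — the property that keeps the
CARS/GA inner loops affordable — and is cross-checked against an
independent PLS implementation in the tests. Latent-variable counts
(cap 20) are chosen by 5-fold RMSECV with a one-standard-error
preference for fewer components; PCR (cap 30) is treated identically
over principal components. MLR is least squares on the selected bands
and refuses rank-deficient or overparameterised designs. ELM fixes
uniform random hidden weights (40 sigmoid nodes) and solves the output
layer by least squares; BP is a single hidden layer (10 sigmoid nodes,
linear output) trained by full-batch gradient descent with early
stopping on an internal 25% validation split. Both neural families
scale inputs per band to $[-1, 1]$ to keep the sigmoids out of
saturation, and are deterministic under a seed.

Performance is reported as $R^2$ (one minus SSE over SST about each
set's own measured mean), RMSE, and RPD $=$ SD/RMSEP with SD the
$n-1$ standard deviation of the measured prediction-set values. Tier
labels follow the 1.5 / 2 / 2.5 thresholds, with 2.5 itself belonging
to "good".

The three reference CARS-MLR equations for loquat (intercepts 22.89 /
13.36 / 36.33; 20 / 29 / 18 bands) are shipped twice — once as code,
once as an independently transcribed JSON fixture — and a test asserts
the two transcriptions agree term by term, guarding against
transcription errors in 67 coefficients.

# Maturity classification

PLS-DA regresses the one-hot stage indicator matrix on the spectra
(multivariate SIMPLS; latent variables by 5-fold CV on the
misclassification rate) and classifies by argmax. "Simplified KNN" is
interpreted as nearest class centroid — each stage reduced to its mean
spectrum — because the method's definition is not standardised; the
interpretation is isolated behind the family enum so a conventional
KNN is a drop-in replacement. SVM uses an RBF kernel, one-vs-one, with
$(C, \gamma)$ grid-searched over $2^{-5..10} \times 2^{-10..3}$ by
5-fold CV. All argmax/nearest ties break toward the earlier stage.
Classification uses full-spectrum SNV spectra; no band selection is
applied, and SNV can be switched off in the pipeline config.

# Pixel-wise maps

Spectra of pixels on a curved fruit differ strongly within one fruit,
which makes naive per-pixel prediction maps noisy at the rim. The
package reproduces deviation compression: each fruit pixel spectrum
$p$ is replaced by $m + c\,(p - m)$, with $m$ the mask-mean spectrum
and $c \in [0, 1]$ (default 0.5 — the factor is not printed anywhere,
so it is config-exposed and recorded in the map metadata). The mean
spectrum is preserved for every $c$, prediction variance is monotone
in $c$, and for a linear model the mean of the $c = 1$ pixel
predictions equals the prediction of the mean spectrum — identities
the tests assert. Maps render to PNG through a linear colour scale
(default: the observed prediction range; for cross-fruit comparisons
pass the calibration set's range) with a JSON sidecar recording
target, scale and $c$.

# The synthetic generator

No public loquat cube/chemistry dataset accompanies the analysis this
package implements, so the generator is a first-class module that
emulates the statistical structure the methods assume, and the
package's empirical claims are claims about recovery of *its* ground
truth:

- Per-stage truncated Gaussians for $a^*$ (means 3.5 / 11.8 / 19.0,
  truncated to the stage intervals so labels and thresholds agree by
  construction), $L^*$, $b^*$, firmness (3.3 / 2.4 / 1.3 kg/cm²,
  decreasing with stage) and SSC (6.6 / 7.9 / 9.4 °Brix, increasing).
  The stage means reproduce the qualitative maturity trends (colour e
  and SSC rise, firmness falls); the exact values are configuration
  chosen to sit in the ranges typical of published loquat chemistry
  tables, not claims about any particular harvest. Default stage
  proportions 0.27/0.51/0.22 follow a reported 177/331/141 stage
  breakdown of a 649-fruit harvest.
- Spectra are a smooth continuum minus a chlorophyll Gaussian dip at
  675 nm whose depth decreases with $a^*$ (ripening degrades
  chlorophyll) and a water dip at 980 nm, plus sparse loadings: each
  trait adds its standardised value times fixed amplitudes at 5
  dedicated bands. This linear-in-sparse-bands coupling (after SNV) is
  deliberate: it gives the selection algorithms a recoverable ground
  truth (`generatorBands()`), which is what the package's acceptance
  properties measure instead of unreproducible real-data $R^2$ cells.
- Per-sample multiplicative gain ($e^{N(0, 0.08)}$) and additive
  offset ($N(0, 0.04)$) scatter motivate SNV, which removes them
  exactly; band noise is $N(0, 0.005)$ reflectance units by default.
  Reflectance is clipped to $[0, 1.2]$, mirroring real corrected
  reflectance occasionally exceeding 1.
- Scenes place one fruit as an ellipse with mild radial shading
  normalised to mean 1 (so the mask-mean spectrum still matches the
  generating spectrum), on a dark background, with white/dark
  reference cubes constructed so the correction recovers reflectance
  up to noise.

What the generator does **not** emulate: instrument wavelength
miscalibration, spatially structured illumination drift, specular
highlights, touching fruit, stem/calyx regions, or nonlinear
trait–spectrum couplings. Passing tests therefore demonstrate
correctness of the algorithms and recoverability under the stated
model, not field performance on real cubes.

# Problem sizes and numerical choices

The test suite exercises the pipeline at 200 samples (regression),
500 samples (classification) and 20 CARS seeds; those sizes give
stable pass/fail behaviour for the recovery properties while keeping
the suite quick. Other fixed choices: SIMPLS deflation tolerance
1e-12; SPA projection tolerance 1e-10 relative to the start column;
MLR refuses designs with more coefficients than samples; JSON
serialisation of models uses 17 significant digits so linear-family
predictions round-trip bit-exactly; Kennard–Stone with a single-member
calibration class degenerates to the lowest index deterministically.

# Known limitations

- The real study's Tables of per-model performance are data-dependent
  and not reproducible without the original cubes; this package's
  numbers quantify recovery on synthetic data only.
- The nearest-centroid reading of "simplified KNN" may differ from
  other implementations of that name.
- CARS/GA outcomes depend on the Monte-Carlo seed by construction;
  only the seeded reproducibility, not the particular subset, is
  guaranteed.
- Segmentation assumes a single bright fruit on a dark background; it
  is not a general fruit detector.
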
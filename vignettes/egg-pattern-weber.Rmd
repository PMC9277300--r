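---
title: "Quantifying egg-pattern complexity and testing proportional processing of rejection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying egg-pattern complexity and testing proportional processing of rejection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggweber)
```

## The scientific question

Hosts of brood parasites discriminate foreign eggs from their own, and one
axis of discrimination is pattern *complexity*: the number of pattern
elements and the variation and unpredictability among them. Given a
complexity score for each egg, a rejection experiment yields two numbers —
the experimental (foreign) egg's complexity $a$ and the mean complexity of
the retained host clutch $b$ — and a binary outcome. Two psychophysical
hypotheses make different predictions about which stimulus the host
processes:

* **absolute processing**: rejection probability depends on $|a-b|$
  (the absolute complexity difference, ACD);
* **Weber's law (proportional processing)**: rejection depends on
  $|a-b|/b$ (the relative difference, RCD), so a fixed difference is less
  detectable against a larger clutch magnitude.

Both are endpoints of a one-parameter family
$$ w_k(a, b) \;=\; \frac{|a-b|}{b^{\,k}}, $$
with $k=0$ giving ACD, $k=1$ RCD, $0<k<1$ the near-miss to Weber's law and
$k>1$ the opposite-miss. Estimating $k$ therefore *measures* how the
stimulus is processed rather than forcing a binary choice.

## From photograph to features

Field photographs are linearized against two grey standards of known
reflectance (0.362 and 0.198): `normalizeGreyStandards()` applies the
unique linear map through those two points and clamps to $[0,1]$. The
working greyscale is the green channel (`toGreenGrey()`), chosen because
avian double cones — believed to drive achromatic pattern vision — are most
sensitive there. All images are resampled to a canonical 29 px/mm
(`rescaleToCanonical()`), and each egg is masked onto an artificial black
background; masks are inputs, not inferred.

`detectFeatures()` is a scale-invariant keypoint detector in the classic
difference-of-Gaussians mould: a Gaussian scale-space with 3 intervals per
octave (base $\sigma_0 = 1.6$ px), 26-neighbour DoG extrema, a contrast
threshold (default 0.01 on the $[0,1]$ intensity scale) and an
edge-curvature test (ratio 10), orientation assignment from a smoothed
36-bin gradient histogram, and a $4\times4\times8$ = 128-dimensional
gradient-histogram descriptor computed in the keypoint's rotated frame.
Position, scale and orientation ride along with the descriptor, mirroring
the 132-dimensional feature encoding of natural-pattern-matching tools
whose core is the same detector family.

Two border policies protect against the artificial background. First,
outside-mask pixels are filled with the egg's mean intensity before the
scale space is built, so the egg outline itself generates no contrast (a
constant egg yields zero features). Second, any keypoint whose support
circle (radius = scale) crosses the mask border is discarded. Keypoints of
both DoG polarities can be kept, but the default keeps dark blobs only
(`polarity = "dark"`): egg maculation is pigment darker than the ground
colour, and the bright interstitial gaps between markings would otherwise
be counted as pattern elements of their own.

## The six complexity traits

For one egg side with feature set $F$ on mask $M$:

| trait | definition | default/units |
|---|---|---|
| `n_feat` | $|F|$ | count |
| `pos_disp` | RMS distance of feature centres from their centroid, $/\sqrt{|M|}$ | unitless |
| `scale_disp` | CV of feature scales (sd/mean, $n-1$ denominator) | unitless |
| `orient_disp` | circular variance $1-\bar R$ of orientations | $[0,1]$ |
| `redies_change` | mean central-difference gradient magnitude over mask-interior pixels | intensity/px |
| `group_metric` | $T \times V$: $T = 1-\frac{n_{cl}-1}{\max(1, n-1)}$ from single-linkage clustering at cut $\delta$; $V$ = mean over non-singleton clusters of the mean per-dimension descriptor sd | unitless |

Empty feature sets score 0 on the feature-based traits by convention. The
per-egg trait vector is the element-wise mean of sides *a* and *c* (the
two non-overlapping sides), which commutes with any linear complexity
score.

The linkage cut $\delta$ defaults to the pixel equivalent of **1 mm**. The
choice is constrained from both directions: $\delta$ must exceed the
spacing of markings that visually form a group (about 0.5–0.8 mm for the
clustered patterns the generator produces), yet stay below the
nearest-neighbour spacing of uniformly scattered markings (about 1.1 mm at
20–30 markings on a 16-mm egg). A 2-mm cut, on the order of a few marking
diameters, sounds natural but lets single linkage chain an entire uniform
pattern into one cluster ($T \equiv 1$), destroying the trait's contrast
between clustered and uniform patterns; we measured exactly that reversal
on synthetic fixtures. $\delta$ remains a config parameter.

## The complexity score and its optimization

Complexity is a weighted sum of the six traits. Because the raw
trait units differ wildly, each trait is min-max standardized over the
training population (constant traits are dropped), and

$$ C = 1000\,\bigl(0.05 + \textstyle\sum_i w_i \hat t_i\bigr), \qquad
   w_i \ge 0,\; \sum_i w_i = 1 . $$

The floor 0.05 keeps $C$ strictly positive ($b$ appears in a
denominator); the factor 1000 puts scores on a 50–1050-unit axis. The
simplex constraint removes the scaling degeneracy of an unconstrained
weighted sum — only the *direction* of the weight vector is identified,
because the downstream objective z-scores its predictor.

`optimizeWeights()` maximizes the log-likelihood of the logistic
regression $\text{Rejection} \sim z(\text{ACD})$, where
$\text{ACD} = |C_{\text{experimental}} - \overline{C}_{\text{host}}|$,
over the simplex via multi-start Nelder–Mead on a softmax
reparametrization (default 50 restarts, objective tolerance $10^{-6}$,
seeded; the uniform weight vector is always the first start, so the
returned objective can never fall below the uniform baseline). A
log-likelihood objective is the natural scalar criterion for a binary
outcome and feeds the same AIC machinery used downstream. Note the
honest cost of a 5-free-parameter search: on pure-noise data the
optimized objective exceeds the uniform-weights objective by about
$\chi^2_5/2 \approx 2$–3 log-likelihood units — chance-level gain, which
the test suite bounds. `validateWeights()` refits the single-predictor
model on held-out experiments with frozen weights and standardization.

## Statistical machinery

All logistic fits go through `glm` (IRLS) with tight convergence
($10^{-12}$), Wald inference, and the criteria
$\text{AIC} = -2\ell + 2p$,
$\text{AICc} = \text{AIC} + 2p(p+1)/(n-p-1)$,
$\text{BIC} = -2\ell + p\log n$, plus Nagelkerke's
$R^2_N = \bigl(1-e^{2(\ell_0-\ell_1)/n}\bigr)/\bigl(1-e^{2\ell_0/n}\bigr)$.
Separation and non-convergence are flagged, never silent.
`allSubsetsSelection()` ranks the eight models on {ACD, RCD, HC} by AICc
and BIC; `lrt()` compares nested fits; `hierarchicalPartitioning()`
averages each predictor's $R^2_N$ increment over all orderings (the
increments telescope to the full-model $R^2_N$ exactly);
`vif()` computes generalized variance-inflation factors from the fitted
coefficient covariance, which reduces to $1/(1-r^2)$ for two linear-model
predictors. Kruskal–Wallis (tie-corrected), one-way random-effects ICC
(with the unbalanced-design $k_0$), and Fisher-z Pearson intervals come
from the corresponding base-R machinery.

### The k-scan

`kScan()` evaluates, for each $k$ on the grid $-1, -0.75, \dots, 2$, the
logistic model with the z-scored $w_k$ as sole predictor and records its
AIC. Each transformed predictor is z-scored before fitting; this cannot
change the AIC (the likelihood is invariant to affine predictor maps) but
keeps coefficients comparable across $k$. The reductions at $k=0$ and
$k=1$ to the ACD and RCD models are exact, and the suite asserts them to
floating-point.

`kMinimum()` fits a fifth-order least-squares polynomial to the
$(k, \text{AIC})$ points, takes $k_{\min}$ as the derivative root inside
the scanned range with the smallest polynomial value (an endpoint if none
exists), and finds the confidence bounds as the crossings of the
polynomial with $\text{AIC}_{\min} + 2$, located by bisection to
$10^{-6}$. Crossings beyond the scanned range are reported open-ended
rather than extrapolated — the polynomial is trusted only where it was
fitted. On an exactly quadratic AIC curve the degree-5 fit reproduces the
quadratic, and $k_{\min}$ and the crossings are recovered exactly; the
suite uses this as an algebraic oracle.

A caveat worth stating plainly: an interval built by adding 2 to the
minimum AIC of equal-size models is a profile-deviance-2 interval, whose
nominal coverage is $P(\chi^2_1 \le 2) \approx 84\%$, not 95%. Our
coverage simulations reflect this — roughly 84–90% of replicate intervals
contain the generating $k$ (the higher figure at $k=1$, where the upper
bound often leaves the scanned range and is reported open). The procedure
is implemented as conventionally described; the coverage shortfall is a
property of the convention, not of the implementation.

## The synthetic-data generator

`makeEggImage()` renders a filled-ellipse egg with elongated Gaussian
spots: positions uniform in the egg or from a Thomas-like parent–offspring
process (parents uniform, about six offspring per parent, offspring
dispersion interpolating from egg scale to spot scale as `clustering` goes
0 → 1); spot sigmas log-normal with chosen mean and CV; orientations von
Mises around a random per-image mean; Gaussian pixel noise, clamped, and
masked. Images carry a coherent calibration of 6.5 px/mm, making the
default egg a realistic ~16 × 11 mm on a small canvas. Identical
parameters and seed give bit-identical images. The generator emulates the
pattern statistics the traits measure — it is *not* a model of real
pigmentation; real eggs have correlated, anisotropic maculation fields,
blotches and scrawls that no isotropic spot process produces, so passing
fixture tests demonstrates correct computation, not biological realism.

`makeExperimentSet()` draws clutch sizes from {2, 3, 4} with mode 3;
clutch-mean complexities from a truncated normal (mean 600, sd 200,
floor mean/10); clutch eggs around their mean with sd 112; the
experimental egg independently from the same population; and rejection
from $\text{logit}^{-1}(\beta_0 + \beta_1 z(w_{k_{\text{true}}}))$ with
defaults $\beta_0 = \log(19/100) \approx -1.66$ (a 16% baseline rejection
rate, the 19-of-119 class imbalance characteristic of these field
experiments) and $\beta_1 = 1.5$. The population CV of 1/3 was chosen so
that a 119-experiment study yields $k$ intervals spanning roughly 1.5
units — the precision typical of field rejection datasets — which at
$n = 300$ narrows to the ~0.6-unit spans our replicates show (the
expected $\sqrt{n}$ effect); the within-clutch sd of 112 gives a
clutch-level repeatability (ICC) near 0.76, characteristic of host egg
signatures. These defaults are fixed study conditions, not tuning
knobs.

`makeTraitExperimentSet()` generates the designed recovery experiment for
the optimizer: six traits per egg, only one informative (shared within
clutch, sd 0.03; experimental egg free), rejection from the z-scored
informative-trait difference with a deliberately strong effect
($\beta_0 = -1$, $\beta_1 = 4$) so that weight recovery is limited by the
optimizer, not by outcome noise.

## Problem sizes and numerical choices

The test suite and the acceptance script run simulations at the sizes the
analyses are designed for: 100 replicates of 300 experiments for coverage
and recovery, 20 replicates for weight recovery (15 optimizer restarts
there; the 6-weight objective is smooth enough that more restarts change
the objective only in the sixth decimal), 500 replicates of $n = 200$ for
the LRT type-I error, and 20-seed panels of ~100 × 70-px synthetic images
for the detector-facing trait properties. Degenerate inputs have stated
conventions rather than errors where a convention is defensible (empty
feature sets; all-identical Kruskal–Wallis input gives $H = 0, p = 1$),
and loud errors where silence would corrupt an analysis (non-positive
$b$, constant predictors, aliased designs, unfitted standardization,
invalid nesting).

## Known limitations

* The detector is a faithful member of the DoG/SIFT family but not a
  bit-exact reimplementation of any published binary; absolute feature
  counts depend on its thresholds (all logged into every output file).
* The exact published formulas for traits (ii)–(iv) and (vi) are not in
  the main methods text; the definitions here are concrete, documented
  stand-ins matching the verbal descriptions, and each is swappable via
  configuration.
* The +2-AIC interval undercovers by design (see above); treat it as the
  conventional ~84% profile interval it is.
* Generated eggs are statistical fixtures; conclusions about real eggs
  require real images, masks and calibration data.
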
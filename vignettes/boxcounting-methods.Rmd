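---
title: "Box-counting fractal dimension of 3-D segmentations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-counting fractal dimension of 3-D segmentations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`fracdim3d` estimates the box-counting (Minkowski–Bouligand) dimension of
a 3-D binary object I(x, y, z). A grid of cubic boxes of side *s* is
superimposed on the object and the number of boxes *N(s)* containing at
least one foreground voxel is counted. Over the interval of scales in
which the object is statistically self-similar, the counts follow a
power law

$$N(s) = C \, s^{-FD},$$

linear in the log–log plane, and the fractal dimension FD is the
absolute slope of the OLS regression of $\log_{10} N(s)$ on
$\log_{10} s$. Base 10 is used on both axes; the estimate is invariant
to the base as long as both axes use the same one (checked numerically
in the test suite). The intercept is $\log_{10} C$ with *C* the
power-law prefactor.

Assumptions on the input:

* the mask is binary — any nonzero voxel is foreground (this makes label
  images and thresholded float masks equally usable);
* voxels are isotropic, enforced with a relative tolerance of $10^{-3}$.
  With anisotropic voxels a cubic box has different physical edge
  lengths per axis and the scale axis loses its meaning, so strict mode
  refuses such input rather than silently distorting the estimate. All
  internal geometry is in voxel units; conversion to mm happens only
  when scales are reported, via the isotropic spacing.

## Counting conventions

**Scales.** The default scale set is $s = 2^k$ voxels, $k = 0,\dots,8$
(1–256 mm at 1 mm spacing): a uniform sampling of the log–log abscissa.
Scales larger than the volume are permitted — their counts saturate near
1 and it is the scale-*selection* stage, not the counter, that decides
whether they enter the fit.

**Offsets.** A single grid origin systematically biases counts, so for
each scale the count is averaged over `n_offsets` (default 20) grid
origins drawn uniformly from the integer offsets $\{0,\dots,s-1\}^3$.
Integer offsets are sufficient: a sub-voxel shift cannot change which
voxels share a box, so the integer draws sample the full distribution of
attainable counts while keeping every count exact and checkable against
brute-force enumeration. Voxel $v$ (0-based) maps to cell
$\lfloor (v + \text{offset})/s \rfloor$; the grid conceptually extends
beyond the volume so no voxel is lost. `n_offsets = 0` is the exact
aligned mode used by the analytic phantom tests.

**Reproducibility.** Each scale draws its offsets from its own RNG
substream derived from the master seed, so extending the scale set never
perturbs the draws of existing scales, and every curve is
bit-reproducible from `(volume, scales, n_offsets, seed)`. Batch runs
derive per-subject seeds from the master seed and the subject id, making
the batch table independent of processing order.

## Goodness of fit and the four selection strategies

For a window of $n$ points the coefficient of determination $R^2$ is
adjusted for the number of data points with the standard one-predictor
formula

$$R^2_{adj} = 1 - (1 - R^2)\frac{n - 1}{n - 2}.$$

* **`fixed`** — an a-priori window in mm, default [4, 256] (roughly the
  span from cortical thickness to head size). Both bounds must be
  members of the sampled scale set; the interval is every sampled scale
  inside the bounds. Its width is reported like any other:
  $\log_{10}(256/4) \approx 1.8$ decades.
* **`bbox`** — an a-priori window derived from the object: the
  foreground bounding box is computed, and 5% and 40% of its shortest
  side become mfs and Mfs after rounding to a power of 2. "Nearest" is
  computed in log2 space (geometric nearest, ties rounding up);
  `rounding = "next"` instead takes the power of 2 at or above, since
  both conventions are found in the morphometry literature. If the
  rounded bounds collapse or contain fewer than two sampled scales the
  strategy fails with a degenerate-interval error (e.g. a one-voxel
  slab).
* **`maxr2`** — automated: every contiguous window of at least 4 points
  is fitted and the window with the highest unrounded $R^2_{adj}$ wins.
  Exact ties (a measure-zero event in floating point, but reachable with
  analytic fixtures) keep the first window in enumeration order (by
  start, then end index). Four points on the dyadic set span at least
  $\log_{10} 8 \approx 0.9$ decades.
* **`roundedr2`** — improved automated selection. $R^2_{adj}$ is a
  proportion of explained variance; treating more than one decimal of
  its percentage as meaningful lets the fourth decimal of a
  goodness-of-fit score dictate the scaling range. Windows of at least
  5 points (≥ $\log_{10} 16 \approx 1.2$ decades, so at least a full
  decade is always spanned) are therefore ranked by $R^2_{adj}$ rounded
  to 3 decimals, with ties broken by the widest interval in decades,
  and remaining ties by the smallest mfs. Rounding is
  half-away-from-zero, so 0.9995 rounds to 1.000; IEEE half-even would
  differ only on exact 0.0005 boundaries.

Saturated scales ($\bar N(s) = 1$) are not excluded before selection: a
run of saturated counts breaks log–log linearity and the automated
strategies avoid such windows on their own merits.

Interval widths are reported in decades, $\log_{10}(\text{Mfs}/\text{mfs})$,
rounded to one decimal in summaries.

## Phantoms: what they validate and what they do not

* **Cube** (dimension 3) and **one-voxel plane** (dimension 2) follow
  exact power laws on aligned dyadic grids, so the estimator must
  recover their dimensions to machine precision — these are the
  acceptance benchmarks regenerated by `scripts/acceptance.R`.
* **Menger sponge** (dimension $\log 20/\log 3 \approx 2.7268$) is
  built with a base-3 digit test — a voxel is removed iff at some digit
  position at least two of its three base-3 coordinates equal 1 —
  equivalent to the recursive construction (asserted against a
  recursive oracle) but O(volume) and loop-free. Counted at its natural
  scales $s = 3^k$ the fit is exact to machine precision. On *dyadic*
  scales the grid never aligns with the base-3 structure and the
  voxelized sponge inflates counts increasingly with $s$; at level 4
  (81³) this biases the automated estimates to ≈ 2.40–2.50, as the test
  suite measures, while level 5 (243³) recovers ≈ 2.74. This is a
  property of box counting on small exactly-self-similar objects at
  incommensurate scales, not an estimator defect; cortical masks, which
  are statistically rather than exactly self-similar and much larger,
  do not share the alignment pathology.
* **Perturbed shell** — a cortex-like thin folded surface. The shell is
  the digital zero level set of $F = r - r_\text{target}(\theta,\varphi)$,
  marking voxels where $F$ changes sign towards a face neighbour (a
  plain $|F| \le 0.5$ band tears wherever the surface moves faster than
  one voxel per step). The radius field adds three octave-spaced
  sinusoidal harmonics with mildly decaying amplitudes, giving
  deterministic, seed-reproducible roughness across spatial scales: the
  unperturbed shell measures ≈ 2 and the estimate grows with the
  perturbation amplitude.

None of the phantoms emulate MRI: there is no acquisition noise, no
partial-volume effect, no segmentation error, and no realistic cortical
topology. Passing phantom tests therefore demonstrates that the counting
and selection machinery is correct, not that FD estimates from any
particular segmentation pipeline are unbiased.

## The cohort simulator

`simulate_cohort()` generates the evaluation-layer analogue of a
morphometric study: ages uniform over a range, one feature linear in age
with Gaussian noise, sex Bernoulli(0.5) coded 0/1, eTIV Gaussian in mm³.
The defaults describe an adult lifespan cohort of 86 subjects aged
19–85 whose feature is a cortical FD around 2.48–2.52 declining by
$7.4\times10^{-4}$ per year with residual sd 0.014 — chosen so the
population feature–age correlation is ≈ −0.7, the strength at which FD
is a useful aging marker. With zero noise the sample correlation is
exactly ±1, and for large *n* the sample correlation converges to the
closed form $r = \beta\,\mathrm{sd}(a)/\sqrt{\beta^2\mathrm{var}(a)+\sigma^2}$
(both are test invariants). What the simulator does *not* emulate:
non-linear age trajectories, site effects, sex-specific trends, or
correlated features.

## Age prediction and permutation testing

`age_cv()` fits an OLS model of age on the feature plus covariates in a
5-fold CV loop, repeated `n_reps` times (default 1000) with fresh random
splits:

* folds are a uniform shuffle followed by a contiguous split, with any
  remainder spread one subject per fold;
* each column (sex included) is standardized using the training-fold
  mean and sd only — a constant training column is centred and left
  unscaled — so no information flows from the test fold into the model;
* the per-repetition MAE pools all test-set predictions of that
  repetition (equivalent to fold-size-weighted averaging of fold MAEs),
  and the final score is the mean over repetitions.

`permutation_pvalue()` dissociates features from ages: for each of
`n_perm` (default 5000) permutations the age labels are shuffled and a
CV MAE recomputed. One CV pass per permutation is the default
(`perm_reps` raises it): the null needs one score per permuted dataset,
and spending the full repetition budget on every permutation would
multiply the cost a thousandfold for no change in the null's location.
The p-value uses the add-one estimator
$p = (1 + \#\{\text{null MAE} \le \text{observed}\})/(1 + n_\text{perm})$,
which is never exactly zero — with 5000 permutations the floor is
$1/5001 < 0.0002$ — and is uniform under the null (verified by a
Kolmogorov–Smirnov calibration in the acceptance suite).

## Numerical choices and problem sizes

* Degenerate inputs fail loudly with typed messages (`EmptyVolume`,
  `DegenerateInterval`, `BoundsNotSampled`, `TooFewScales`, ...); batch
  mode records them per row instead of aborting the cohort.
* A fitted dimension above $3 + 0.1$ raises a warning, not an error:
  offset averaging can push local slopes slightly above the embedding
  dimension on degenerate objects.
* JSON reports serialize doubles at 17 significant digits so they
  round-trip bit-exactly.
* The test suite sizes its simulations for a single CPU: oracle
  equivalence uses 200 random curves and exhaustive-offset enumeration
  on ≤ 16³ volumes at s ≤ 4; the estimator benchmarks use 64³ analytic
  phantoms and the 81³ level-4 sponge; the CV calibration uses a
  2000-subject Gaussian cohort at 50 repetitions and 500 null cohorts
  of 40 subjects at 199 permutations each.

## Known limitations

* No surface-based FD, no regional/lobar parcellation, no multi-segment
  scaling-regime detection, and no dilation (Minkowski sausage) or
  mass-radius estimators.
* The box counter is exact but O(foreground × offsets × scales); very
  large masks (≫ 10⁷ foreground voxels) will be slow in pure R.
* FD from a segmentation inherits every upstream bias of the
  segmentation itself; the package deliberately leaves reconstruction
  and quality control to the imaging pipeline that produced the mask.
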
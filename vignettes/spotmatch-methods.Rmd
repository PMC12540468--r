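---
title: "Methods: landmark registration and spot-level metabolite analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark registration and spot-level metabolite analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotmatch)
```

## Scope and model

`spotmatch` aligns two planar coordinate systems — a hexagonal
spatial-transcriptomics (ST) spot array and a square
mass-spectrometry-imaging (MSI) pixel raster acquired on an adjacent
section — under a similarity transform (isotropic scale $s$, rotation
$\theta$, translation), and then carries out the spot-level analyses the
matched data enable. A similarity transform is the right model for
adjacent-section registration: sectioning and transfer shift and rotate
the tissue and can rescale it slightly (stretch during mounting), but do
not shear it appreciably. Non-rigid warping is deliberately out of
scope; residual local deformation shows up as landmark RMSE, which the
diagnostics report rather than absorb.

### Unified frame

Hex spots with array indices $(T_x, T_y)$ map to micrometres as
$x = (T_x/2 + 0.5)\,r_T$, $y = T_y\sqrt{0.75}\,r_T$, where $r_T$ is the
spot pitch (100 µm). The halving undoes the parity-offset column
encoding of the hex array and $\sqrt{0.75}$ is the row spacing of an
equilateral triangular lattice, so all six neighbours of an interior
spot lie at exactly one pitch — the package tests assert this to
$10^{-9}$. The $+0.5$ offset shifts every spot uniformly; it cancels in
registration and is kept as part of the conversion convention. MSI
pixels map as $x = M_x r_M$, $y = M_y r_M$ with $r_M$ the raster step
(100 µm). Array indices are 0-based, as in the standard
`tissue_positions.csv` dialect; the y axis follows increasing row index
with no image flip (a genuinely mirrored section is detected from the
sign of the landmark cross-covariance determinant and refused unless
reflection fitting is requested — mirrored sections are rare accidents
and silently fitting one would mask a sample-handling error).

### Landmark estimators

With $n \ge 6$ landmarks, each of the $\binom{n}{2}$ pairs gives a
distance ratio (ST over MSI), and each pair a signed chord-angle
difference. The scale is the mean of ratios surviving an outlier filter;
the rotation is the circular mean of the angles.

Choices the estimator design left open, and how they are resolved here:

* **Outlier rule** (default `median ± 3·MAD`, `1.5·IQR` optional): the
  rule must be robust with ~15–45 ratios and no tuning data; the MAD
  band (with the 1.4826 consistency constant) has a 50% breakdown point
  and one parameter. When all clean ratios are identical the MAD is 0
  and the band collapses to the median — exactly the behaviour wanted
  for noise-free data, where any discrepant ratio is a gross error.
* **Angle aggregation**: pairwise angles are averaged on the unit
  circle, never arithmetically: angles straddling ±180° (e.g. 179° and
  −179°) must average to 180°, not 0°. The circular standard deviation
  is reported as the spread; above a ceiling (default 15°) the landmark
  set is inconsistent with a rigid rotation and the fit refuses rather
  than return a meaningless mean.
* **Quadrant-aware arctangent**: a naive one-argument
  arctan of a slope ratio cannot distinguish a chord from its 180°
  reverse and cannot represent $|\theta| > 90°$; the two-argument form
  is used throughout: with the one-argument form the estimator simply
  cannot recover rotations beyond ±90°.
* **Rotation sign**: the stored angle is the correction that rotates
  MSI coordinates onto the ST frame (counter-clockwise positive), i.e.
  the negative of the raw MSI-minus-ST chord-angle difference. Storing
  the correction rather than the discrepancy keeps
  `apply_transform()` a direct application of the fitted parameters.
* **The 5° rule**: a mean rotation of magnitude strictly greater than
  5° flags the run (`exceeds_5deg`). What "adjustment" follows a
  sub-threshold rotation is ambiguous, so both behaviours exist:
  `rotation_mode = "always"` (default) applies the estimated rotation
  regardless — dropping a real 3° rotation would displace pixels by up
  to ~170 µm at the edge of a 6.5 mm section, more than a full spot
  pitch — while `"threshold"` zeroes sub-threshold rotations for users
  who want the stricter reading.
* **Translation**: fixed by anchoring the scaled, rotated MSI landmark
  centroid on the ST landmark centroid. With exact landmarks this is
  exact; with jitter it is the least-squares translation given the
  other parameters.

`procrustes_oracle()` provides the closed-form least-squares similarity
fit (SVD of the landmark cross-covariance, determinant-corrected to
exclude reflections) as an independent check: on noise-free landmarks
the pairwise estimators agree with it to $10^{-9}$, and on jittered
landmarks its residual is never larger — the pairwise method trades a
little statistical efficiency for interpretable per-pair diagnostics.

### Pixel-to-spot matching and aggregation

Each transformed pixel is assigned to its nearest spot centre within a
radius, default 50 µm = half the spot pitch. The half-pitch radius makes
the spot cells tile the section, so a 100 µm raster leaves essentially
no in-tissue pixel unassigned; the spot radius itself (27.5 µm) would
discard most pixels of a raster whose step equals the pitch. Exact ties
go to the lexicographically smallest barcode so results are
order-independent. Aggregation is the mean of the TIC-normalized pixel
intensities per spot (median optional); assigned plus unassigned pixels
always equal the total, and the pixel-count-weighted spot means conserve
the assigned mass to $10^{-9}$.

TIC normalization divides each pixel spectrum by its total ion count;
zero-TIC pixels carry no signal and are dropped with a count (or raised
as an error on request).

### Cell-type designation

The per-spot rule is applied literally: the top cell type when its
proportion strictly exceeds 0.70, otherwise the *second* most prevalent.
A proportion of exactly 0.70 does not exceed the threshold. The
else-branch is counter-intuitive (a 0.69-dominant type is passed over
for the runner-up), and may not be what most users expect; the
conventional arg-max rule is available as `rule = "dominant"`, but the
threshold rule stays the default so the designation is explicit about
which branch produced each label (`rule_used` records it per spot).
Proportion ties break alphabetically so the output is invariant to
column order.

## OPLS-DA, VIP and the significance rule

The two-group model is fitted by NIPALS with orthogonal signal
correction: `n_orth` components uncorrelated with the class response are
stripped from the column-centred, unit-variance-scaled matrix, then a
single predictive component is fitted. Defaults and rationale:

* **One orthogonal component** (`n_orth = 1`): with a single response
  there is one predictive direction; one orthogonal component is the
  customary chemometrics default and more are rarely identifiable at
  these sample sizes. Configurable.
* **Cross-validation**: Q² uses 7-fold stratified CV (folds balanced by
  group, assignment controlled by an explicit seed), with centring and
  scaling refit inside each training fold so the held-out fold never
  leaks into the preprocessing.
* **VIP**: $VIP_j = \sqrt{p\, w_j^2}$ for the normalized predictive
  weight vector $w$ ($p$ = metabolite count), so $\sum_j VIP_j^2 = p$
  identically — VIP > 1 means above-average contribution, and a single
  metabolite necessarily has VIP = 1.
* **Significance**: VIP strictly greater than 1 *and* univariate
  p strictly below 0.05. The univariate test defaults to a two-sided
  Welch t-test on $\log(x + \varepsilon)$,
  $\varepsilon$ = half the smallest positive intensity (intensities are
  positive, right-skewed and heteroscedastic; the log brings them near
  normality and Welch drops the equal-variance assumption). Wilcoxon is
  available. No multiple-testing correction is applied by default —
  the calling rule is a raw-p conjunction — but Benjamini–Hochberg can
  be switched on. On exchangeable null data the conjunction holds its
  nominal 5% level (under the null, any metabolite with p < 0.05 has an
  above-average weight, so the conjunction's level equals the t-test's);
  with planted signals present the level among the null metabolites
  drops below 5%, because strong signals absorb VIP mass and raise the
  VIP > 1 bar.
* **Permutation test**: Q² is recomputed under label permutations
  (default 200). A sound model shows a permuted-Q² distribution centred
  at or below zero with the observed Q² above all of it; the empirical
  p-value uses the add-one convention $(1 + \#\{Q^2_{perm} \ge
  Q^2_{obs}\})/(n_{perm}+1)$.

Spots are treated as observations within a section comparison (matching
per-cell-type contrasts); for a sections-as-replicates design, aggregate
to per-sample means first and run the same functions.

## Pseudotime trends

Branch topology is a progenitor pool (`prebranch`) diverging into two
fates; the pool is prepended to both paths. Per metabolite and path the
Spearman correlation $\rho$ of intensity against pseudotime is tested;
$\rho \ge 0.3$ with $p < 0.05$ is *increasing*, $\rho \le -0.3$
*decreasing*, anything else *unchanged*. Rank correlation makes the call
invariant to monotone transforms of either axis (pseudotime units are
arbitrary), and reversing pseudotime provably flips the calls. The 0.3
threshold separates trends visible in a profile plot from rank noise at
50–120 spots per path ($|\rho| = 0.3$ at $n = 100$ has
$p \approx 0.002$, so the $p$ and $\rho$ conditions are both active
only for short paths). Profiles are means over equal-count pseudotime
bins (default 20), robust to the uneven spot density along pseudotime.
Constant series have no defined rank correlation and are reported
*unchanged* with a note.

## The synthetic generator

`synthetic_scenario()` fixes the emulated study conditions; generators
derive everything else deterministically from the seed (the seed is
mandatory, and two runs with the same scenario are identical).

* **Geometry**: 78 array rows × 64 spots per row ≈ 5,000 spots over
  6.5 × 6.7 mm at a 100 µm pitch — a full capture area — with the MSI
  raster at a 100 µm step sized through the inverse transform to cover
  the tissue plus one pitch of margin.
* **True transform**: scale 1.0 (both modalities at 100 µm), rotation
  3°, translation (250, −150) µm — the magnitude of section-transfer
  misalignment expected between adjacent 10 µm sections. Scale and
  rotation sweeps are exercised explicitly in the tests.
* **Landmarks**: 8, placed at the spots nearest an ellipse spanning the
  section (evenly distributed, never collinear), with 10 µm Gaussian
  marking jitter — sub-pixel accuracy, plausible for careful manual
  marking on an H&E image. Outlier landmarks (robustness runs) are
  displaced by max(10 × jitter, 5 pixel steps), i.e. gross
  mis-identifications.
* **Intensities**: log-normal (positive, right-skewed, like MSI ion
  counts), $\sigma_{\log} = 0.3$, with two spatial territories
  (villous-like and basal-plate-like) offsetting metabolite means.
  Group studies plant additive effects of 2 SD on the log scale in 5 of
  50 metabolites, 30 spots per group. Branch studies use 60 + 60 + 60
  spots with planted direction pairs cycling through the observed
  pattern classes (down/down, flat/up, down/up, up/down, flat/flat) and
  a within-branch signal range of 3 SD, which yields population rank
  correlations of magnitude ≥ 0.5 along the full path (verified by a
  large-$n$ test).

What the generator does **not** emulate: mass spectra (isotopes,
adducts, peak shape), spatial autocorrelation of noise, per-pixel TIC
drift, segmentation errors, or deconvolution uncertainty — cell-type
proportions and pseudotime are consumed as given. Passing tests
therefore demonstrate correctness of the geometry, estimators and
calling rules under the stated noise model, not robustness to every
artefact of real acquisitions.

## Numerical choices and degenerate inputs

* Distance ties in matching break by barcode; proportion ties by label;
  both make outputs permutation-invariant.
* Coincident MSI landmarks, collinear landmark spreads, all-rejected
  ratio sets, zero-TIC pixels, constant metabolites, constant trend
  series and empty branch intersections all raise (or warn with counts
  for) explicit, named conditions rather than propagating NaN.
* Scaling guards: zero-variance columns inside a CV fold scale by 1
  instead of 0; angle spread uses $\sqrt{-2\log \bar R}$ clamped at
  machine epsilon.
* Problem sizes in the test-suite simulations (e.g. 100-replicate
  Monte-Carlo runs at the default scenario, 200 permutations) were
  chosen so the whole suite completes in well under a minute per file
  on one CPU while keeping Monte-Carlo error far from the asserted
  margins.

## Known limitations

* Similarity-only: anisotropic stretch or local warping is not modelled
  and inflates landmark RMSE instead.
* The scale estimator's pairwise-ratio mean is slightly upward-biased
  under landmark jitter (noise in the denominator); at realistic
  landmark spreads (millimetres) and jitter (tens of µm) the bias is
  far below 1%, but very close landmark pairs should be avoided.
* OPLS-DA assumes two groups; multi-class contrasts need one-vs-rest
  runs.
* The imzML reader supports uncompressed 32/64-bit continuous and
  processed files only (no zlib blocks).
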
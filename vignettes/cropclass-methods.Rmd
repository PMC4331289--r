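---
title: "Methods: parcel-level crop classification with CART rule models"
author: "cropclassr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parcel-level crop classification with CART rule models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropclassr)
```

## The problem and the model

Crops are hard to tell apart in a single image but easy to tell apart in
time: an autumn-sown cereal is deep green in April and bare stubble by
July, a sunflower field does the opposite, an olive orchard barely
changes, and a reservoir never greens at all. `cropclassr` operationalizes
this by describing every census parcel with its multitemporal spectral
signature — the mean Blue, Green, Red and NIR digital numbers over the
parcel's pixels at each acquisition `T1 ... Tn`, plus three band ratios:
NDVI `(NIR−R)/(NIR+R)` for green vegetation amount, the stubble index
`Stu = R/G` for senescence, and `B/G` for bare soil. With seven
acquisitions this gives 49 predictor variables per parcel.

A classification tree (CART) is grown on the ground-truthed parcels and
then *frozen as a set of SQL predicate rules*, one per terminal node.
The rule file — not the fitted R object — is the interchange format:
it is human-auditable, database-executable in spirit, and can be
re-applied to any later extraction **from the same area with the same
number of images taken at approximately the same calendar times**. That
restriction is enforced mechanically: each rule file records the time
tags it was trained on and refuses records extracted at other times.

Labels live in a three-level hierarchy (crop → cropping system →
Veg/NonVeg): e.g. wheat WHT → winter crops WIC → Veg. One tree is
trained per level, and the per-level outputs are reported side by side
without cross-level reconciliation (a parcel may legally read NonVeg at
the top level and carry a low-probability crop guess at the bottom; the
probabilities make the disagreement visible).

## Zonal extraction

A pixel belongs to a parcel iff its **center** lies inside the polygon;
a center exactly on an edge counts as inside (closed test). This is the
plain zonal-statistics default: deterministic, unweighted, and cheap.
Partial-pixel weighting was deliberately not implemented — at the 2 m
pixel sizes this tool targets, boundary pixels are few relative to
parcel areas, and the optional negative `buffer` (map units) exists for
the opposite worry, shaving off a boundary rim where mixed pixels would
contaminate the means. Polygon interiors use the even-odd rule, so holes
are supported. CRS handling is equality-of-tag only; nothing is ever
reprojected, because a co-registered image series shares one projection
by construction.

Vegetation indices are computed **per pixel and then averaged** by
default (`vi_mode = "per_pixel"`), because NDVI is a nonlinear function
of the bands: the mean of per-pixel NDVIs is the ecologically meaningful
quantity over a heterogeneous parcel. The alternative
(`vi_mode = "from_means"`, index of the band means) is provided for
comparison and for matching extractions done by simpler tools. A pixel
whose ratio is undefined (zero denominator, possible when digital
numbers clip at 0) is skipped in the per-pixel average, as common zonal
implementations do; a parcel whose index is undefined at *every* pixel
of some acquisition is dropped from the matrix, with a warning naming
it — the tree has no missing-value machinery and silently imputing
spectra would be worse.

## Tree growth

Splits are binary, axis-aligned, at midpoints of consecutive distinct
sorted values. The split criterion is the Gini improvement
`gini(parent) − (n_L/n) gini(L) − (n_R/n) gini(R)`. Growth stops at a
node when it is pure, smaller than `min_parent` (default 8 rows), at
depth `max_depth` (default 5 splits below the root), or when no
admissible split (both children at least `min_child = 4` rows) reduces
impurity. These defaults are the classical small-sample CART settings
for studies with one to a few hundred training parcels; with them a
depth-5 tree can hold up to 32 leaves, enough for a dozen land-use
classes. Cross-validation is stratified 10-fold ("10%-fold"), reducing
the fold count to the rarest class size when necessary, with the pooled
held-out misclassification proportion and binomial standard error
`sqrt(r(1−r)/N)` reported. Priors are the empirical class frequencies,
so the prior-adjusted risk is the plain error proportion.

### Exact split comparison and tie-breaking

Two numerical choices deserve emphasis.

First, candidate splits are compared **exactly**. For class counts `c`
in a child, let `S = Σ c²`. The weighted child impurity is an affine
decreasing function of `f = S_L/n_L + S_R/n_R`, a rational number with
small integer numerator and denominator, so two candidates are ordered
by integer cross-multiplication (`a₁d₂` vs `a₂d₁`). Floating-point
evaluation order can make exactly tied splits appear unequal (and
vice versa); the integer comparison is immune, and the products stay
exact in doubles for node sizes into the thousands.

Second, ties are real, not a corner case. With equal class frequencies
— the natural design for a training survey — *every* split that cleanly
partitions the classes has exactly the same improvement, whatever the
group sizes: for `k` equally sized classes, any clean split improves the
Gini impurity by exactly `1/k`.
A naive "first variable, smallest threshold" rule then chains along one
column, peeling a single class per level: a depth-5 tree cannot separate
ten classes that way, and the chosen column may be one where the
adjacent classes are spectrally close, placing thresholds in the noise.
Ties are therefore broken deterministically in this order:

1. **more balanced children** (smaller `|n_L − n_R|`) — keeps the tree
   shallow, so the depth budget suffices for many classes;
2. **widest margin** — the largest gap between the two values flanking
   the threshold, normalized by the variable's root-node range; among
   equally good partitions this picks the boundary farthest from both
   flanking clusters, the classical large-margin choice;
3. earlier variable in column order, then smaller threshold, as final
   arbitrary-but-fixed keys.

A value exactly equal to a threshold descends left (`<=`), consistently
between growth, prediction and rule serialization.

Variable importance sums `(node size / root size) × improvement` over
the internal nodes splitting on each variable, normalized to max 100.
Only primary splits contribute: no surrogate splits are grown, so these
numbers are *not* comparable with implementations whose importance
includes surrogates (SPSS-style normalized importance does).
No pruning, cost matrices, or categorical predictors: the predictors
here are all continuous spectra, and the stopping rules already bound
complexity.

## Rule files

Each leaf becomes the conjunction of its path conditions, collapsed to
at most one lower (`>`) and one upper (`<=`) bound per variable; class
and within-leaf frequency (the reported probability) come from the
leaf. The text dialect is one rule per line,

```
WHEN T3Stu > 1.2 AND T3Stu <= 2 THEN 'WHT' PROB 0.89
```

with a commented header naming the model, its level and its training
times; `WHERE` is accepted as a synonym on input, thresholds are printed
with 17 significant digits so parsing reproduces the doubles bit-for-bit
(write → parse → classify is exactly `predict()`), and a JSON sidecar
carries the same content for machine consumption. Rules from one tree
are mutually exclusive and exhaustive by construction; the parser
validates variable names, interval consistency and uniqueness of an
always-true rule, so a corrupted file fails loudly rather than
classifying arbitrarily.

## Accuracy statistics

`UA` (user's accuracy) is percent correct per **observed-class row**,
`PA` (producer's accuracy) per **predicted-class column**, `OA` the
diagonal total. This is the reverse of the usual remote-sensing naming —
it is kept because every published validation table this package
reproduces computes the statistics this way, and consistency with the
tables matters more than the textbook label. Comparisons against values
printed at fixed precision use round-half-up (`round_half_up()`), since
banker's rounding never matches hand-rounded tables.

## The scenario study

`default_scenarios()` encodes the image-number/timing design for a
seven-image season: the full series, two interleaved triplets
(T1,T3,T5 / T2,T4,T6), two pairs (T2,T5 / T3,T6) and all singletons —
twelve scenarios; other series lengths get the analogous evenly spaced
construction. Per scenario the matrix is restricted to those times, a
tree grown, and per-class resubstitution percent-correct (observed-row
UA), OA and cross-validated risk tabulated. Resubstitution is used for
the per-class columns (matching how such tables are usually reported);
the cross-validated risk column is the honest generalization signal.

## The synthetic generator

The generator exists so the whole pipeline — including TIFF/GeoJSON
round trips — is testable without satellite data. Each class is a
linear mixture of ground endmembers (green vegetation, bare soil,
senescent stubble, water, built surfaces) whose vegetation cover
fraction follows a piecewise-linear seasonal trajectory; pixel noise is
Gaussian (sd 40 DN by default), independent, clipped at zero, rounded
to integer digital numbers. Ten classes cover the hierarchy: two winter
cereals (early green-up, stubble from early summer), three summer crops
(peaks staggered through mid-season), two adult orchards (near-constant
cover at different densities), a sparse young orchard, and two
non-vegetative classes. The noise-free NDVI trajectories are checked
against their declared patterns by `validate_profiles()`; all numeric
profile values are package fixtures, chosen to be qualitatively
realistic, not measurements.

Default problem sizes were chosen once for the standard study: 20
parcels per class (10 train / 10 test after the stratified
largest-remainder split), 12×12-pixel parcels, seven acquisitions. The
parcel size is a realism/runtime compromise: real census parcels run to
hectares (thousands of pixels), where pixel noise averages out of the
parcel means almost completely; 144 pixels keep that property (mean
standard error ≈ sd/12) while scenes stay small enough to simulate in
seconds. What the generator deliberately does **not** model: spatial
autocorrelation, mixed boundary pixels, clouds and atmospheric effects,
between-parcel agronomic variability (sowing-date spread), and
between-year calendar shifts. Passing the synthetic recovery tests
therefore demonstrates the correctness of the *machinery* — extraction,
tree, rules, evaluation — under the stated noise model, not
field-readiness for any particular region; on real imagery, published
parcel-level studies of this design report overall accuracies near 80%
for individual crops and 95–100% at the cropping-system level.

## Degenerate inputs and edge policies

- A parcel covering no pixel center is excluded at extraction and
  reported; a polygon entirely off-raster is legal input.
- A single-class training set yields a valid depth-0 tree; predicting
  with it returns the class with probability 1.
- Majority ties in a leaf resolve to the alphabetically first label
  (class levels are sorted), keeping prediction deterministic.
- `confusion()` on empty input returns an empty matrix;
  `accuracy_stats()` refuses it. Zero-denominator UA/PA are `NA`, never
  0 or 100.
- Digital numbers are validated non-negative; the raster writer bounds
  them to the 16-bit range.

## Known limitations

Beyond the generator simplifications above: no shapefile geometry
reader (GeoJSON is the vector format; attribute-only `.dbf` tooling
was judged not worth a hand-written binary geometry parser), no
reprojection, no surrogate splits or pruning, no missing-value
tolerance in the tree, and rule models are only transferable to
extractions with identical acquisition time tags — by design.
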
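---
title: "Separability indices for fluorescent-fingerprint classification"
author: "fluorsep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separability indices for fluorescent-fingerprint classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorsep)
```

## The problem

Fluorescent fingerprinting classifies samples (foods, biological fluids,
environmental extracts) by the shape of their emission spectra, often after
adding an extrinsic fluorophore whose emission is quenched or enhanced by
sample constituents. Each sample is measured in a handful of parallel wells,
the spectra are reduced to a two-dimensional principal-component score plane,
and every well becomes one point. When dozens of similar samples are involved,
no single measurement condition discriminates them all, so the practical
question becomes: *which fluorophore separates the panel best?* Simply
counting discriminated groups is too coarse — two conditions can give the same
group count while one of them piles far more replicate clouds on top of each
other. `fluorsep` implements a family of complementary separability metrics
computed from the same score clouds, plus a rank-sum rating that aggregates
them into a single ordering of conditions.

## From spectra to the score plane

Raw intensities $I(\lambda)$ are normalized to the formal degree of quenching

$$Q(\lambda) = \frac{I(\lambda) - \bar I_0(\lambda)}{\bar I_0(\lambda)},$$

where $\bar I_0$ is the per-wavelength mean over the blank wells of the same
condition (`quench_normalize()`). $Q = 0$ means the sample leaves the
fluorophore's emission unchanged, $Q = -1$ complete quenching, $Q > 0$
enhancement. Blanks average to zero by construction, and the transformation is
invertible ($I = \bar I_0 (Q + 1)$), so no information is lost.

Wavelength windowing (`select_window()`, closed interval, default 430–550 nm)
excludes instrument artifacts such as plate-material emission peaks; the
window is the only artifact handling applied — no peak subtraction.

PCA (`fit_pca()`) centres the wells-by-wavelengths matrix by column and
projects onto the top right singular vectors. Columns are *not* scaled: all
channels share one unit and relative band intensity is informative. Two
components are the default; `residual_dispersion()` reports the unexplained
variance fraction and the pipeline warns when it exceeds 5%, the conventional
adequacy gate for treating the 2-D scores plot as a faithful summary. The
component sign is fixed (largest-magnitude loading element positive) so
results are bit-reproducible; PCA sign is otherwise arbitrary.

## Confidence ellipses and the crossing number CrN

Each sample's replicate scores get an elliptical region
$(x - c)^\top S^{-1} (x - c) \le s^2$ with $c$ the replicate mean and $S$ the
sample covariance (`confidence_ellipse()`). Two scaling conventions exist
because "a confidence ellipse at level $\gamma$ for $n$ replicates" is
genuinely ambiguous:

* **student** (default): $s^2 = t^2_{1-(1-\gamma)/2,\,n-1}$, a
  replicate-coverage region. For $\gamma = 0.80$, $n = 5$:
  $s^2 = t^2_{0.90,4} = 2.3507$. This is the convention under which plotted
  ellipses visibly cover the replicate points.
* **hotelling**: $s^2 = \frac{2(n-1)}{n(n-2)} F_{\gamma;2,n-2}$, the much
  smaller confidence region for the class *mean*.

The **crossing number** of a pair of ellipses is the number of transversal
boundary intersections (0–4). Two postulates complete the definition:
an ellipse lying entirely inside another counts 4 (maximal overlap — there are
no boundary crossings yet discrimination is worst); and a tangential contact
counts 2, i.e. tangency is resolved toward overlap, the conservative
direction. Coincident ellipses are treated as containment. **CrN** is the sum
over all unordered sample pairs (`total_crossing_number()`); lower is better,
with 0 meaning every replicate cloud is cleanly separated.

Intersections are computed exactly (`ellipse_intersection_points()`): ellipse
A is whitened to the unit circle, ellipse B becomes a general conic
$Q(x,y)=0$, and substituting $y^2 = 1 - x^2$ reduces the system to a quartic
in $x$. Real roots are polished by two-dimensional Newton iteration on the
pair of boundary equations and gated on a $10^{-7}$ residual; tangency is
detected as parallel boundary normals at a clustered root. The test suite
checks the solver against an independent dense boundary-sampling oracle on
1000 random ellipse pairs.

The **number of groups** metric (`count_groups()`) links two samples whenever
their ellipses intersect (crossing number > 0) and counts connected
components, so chains of overlapping samples merge transitively into one
group. An alternative predicate links samples whose centers are closer than a
Mahalanobis distance of 4 under the pooled pair covariance — the distance
that corresponds to visual non-intersection of 80% ellipses at $n = 5$ — and
is available via `predicate = "mahalanobis"`.

Overlap *areas* of ellipses would be a finer-grained refinement of CrN but
are deliberately not computed; the crossing count keeps the metric cheap and
countable by eye on a plot.

## The relative-position index RP

For two groups of points, let $C_1, C_2$ be the centers of mass (means of all
points, not only hull vertices) and bound each group by its convex hull — the
simplest distribution-free boundary. The boundary point $A_1$ of group 1 is
the hull vertex with the smallest scalar projection of $\vec{C_2 A_1}$ onto
$\vec{C_2 C_1}$, i.e. the vertex of group 1 reaching furthest toward (or
past) group 2; $A_2$ symmetrically. Then

$$RP_{12} = \frac{\operatorname{proj}_{\vec{C_1 C_2}} \vec{C_1 A_2}}
                 {\operatorname{proj}_{\vec{C_1 C_2}} \vec{C_1 A_1}}$$

with *signed* scalar projections. The sign encodes the geometry, giving two
easily remembered thresholds:

* $RP > 1$: the hulls are separated; larger means further apart.
* $0 < RP < 1$: the boundaries intersect but the centers lie outside the
  overlap region.
* $RP < 0$: the groups are merged — both centers lie inside the overlap.

```{r rp-example}
g1 <- group_geometry(rbind(c(0, 0), c(1, 0)), "g1")
g2 <- group_geometry(rbind(c(3, 0), c(4, 0)), "g2")
rp_pairwise(g1, g2)
```

Because the minimum of a linear functional over a convex polygon is attained
at a vertex, restricting the $A$-point search to hull vertices is exact. Ties
are broken by the first vertex for determinism; boundary values classify
conservatively (exactly 1 → intersecting, exactly 0 → merged). Coincident
group centers leave the projection direction undefined and raise an error
rather than return an arbitrary value. RP operates on raw score coordinates —
the axes are deliberately not standardized, so RP magnitudes scale with the
score-plane geometry.

For $N$ groups the aggregate (`rp_overall()`) is the mean over unordered
pairs of $\min(RP_{ij}, RP_{ji})$ (the symmetric, pessimistic pair value).
A `"printed"` normalization dividing the ordered-pair double sum by
$\tfrac12 N(N-1)$ — exactly twice the pair mean — is kept as an option for
compatibility with the double-sum formulation sometimes quoted for this
index; the default follows the plain-average reading since the two differ
only by the constant factor 2 and the mean is the interpretable choice.

## Standard metrics: TS, QDA, SVM

**Total sensitivity** (`total_sensitivity()`): a well belongs to a class when
its Mahalanobis distance to that class (class mean, class covariance) is at
most 4. Wells matching exactly their own class are *correct*; wells matching
more than one class are *multi-class* (potentially misclassified); wells
matching none are *unowned*; wells matching a single wrong class are
*misassigned*. TS is the fraction of correct wells. By default this is
training-set sensitivity — the evaluated well contributes to its own class
statistics; `loo = TRUE` excludes it for an honest leave-one-out variant.
Cross-validation beyond leave-one-out is out of scope.

**QDA sensitivity** (`qda_sensitivity()`): each well is assigned to the class
minimizing $(x-\mu_k)^\top S_k^{-1}(x-\mu_k) + \log\det S_k$ with per-class
covariances and equal priors (a quadratic decision boundary, appropriate when
class covariances differ). The implementation is cross-checked against
`MASS::qda` in the tests.

**SVM sensitivity** (`svm_sensitivity()`): training sensitivity of a
multi-class support-vector classifier with linear, 3rd-degree polynomial or
RBF kernel, delegated to `e1071::svm` (unscaled inputs, default cost) — the
SVM solver itself is standard machinery, not part of this package's
contribution.

## Correlations and the overall rating

`metric_correlations()` correlates metric columns across conditions (Pearson
by default, Spearman optional) — useful for judging how much independent
information the indices carry. `overall_rating()` ranks conditions per metric
respecting polarity (CrN: lower is better; number of groups, RP, all
sensitivities: higher is better), with tied conditions sharing the mean rank,
and sums the places; the condition with the minimum rating wins. Rating ties
are ordered by condition name for deterministic output.

## Synthetic data: what it emulates and what it does not

`generate_spectra()` emulates one plate of a fingerprinting study: by default
36 samples × 5 replicate wells + 6 blanks over a 301-point 400–700 nm grid.
The blank spectrum is a broad smooth band; each sample adds a sample-specific
mixture of two Gaussian bands (centers in the 450–570 nm region, width
25 nm), so the noiseless quenching-degree matrix has rank 2; replicates
multiply the mean spectrum by $(1 + 0.01\,\varepsilon)$ — multiplicative
noise, since fluorescence replicate error scales with signal. The default
between-sample spread (band coefficients up to ±0.8 × half the blank peak,
per band) was fixed so that the latent signal dominates 1% replicate noise
and two components leave ≤ 5% residual dispersion — the regime in which the
score-plane metrics are meaningful and which the generator is meant to
emulate. Under the defaults the observed residual is 1.4–2.2% over 20 seeds.

The generator reproduces low-rank structure, replicate noise scaling and
blank behavior; it does **not** model photophysics (quenching mechanisms,
inner-filter effects), band-shape diversity, wavelength-correlated noise or
plate position effects. Passing tests on synthetic data therefore validate
the *metrics and their contracts*, not instrument realism.

`generate_score_groups()` bypasses spectra entirely: isotropic Gaussian
groups with centers on a circle of radius `separation`, for exercising the
metrics directly in score space. As separation grows, CrN falls to 0, RP
grows without bound, and TS and the group count saturate at their optima —
the monotonicity harness in the test suite checks exactly this over 20 seeds
per separation (5 points per group, 4 groups, within-group σ = 1), sizes
chosen to keep the full suite fast while averaging out simulation noise.

## Numerical choices and degenerate inputs

* Ellipse-intersection roots are accepted only if both boundary equations are
  satisfied to $10^{-7}$ after Newton polishing; root clusters closer than
  $10^{-6}$ in whitened coordinates merge into one contact point.
* Tangency detection uses a $10^{-6}$ relative bound on the normal cross
  product; the Newton step is skipped when the Jacobian is near-singular
  (which is precisely the tangential case).
* Fewer than 3 replicates, collinear replicate clouds, and singular class
  covariances raise errors naming the offending sample/class rather than
  returning NaNs.
* Duplicate (sample, replicate) keys, non-monotone wavelength headers,
  metadata/spectra key mismatches and zero mean blank intensity (named per
  wavelength) are rejected at the I/O boundary.
* CSV outputs are written with fixed 6-significant-digit formatting so
  re-running a pipeline on identical inputs reproduces byte-identical files.

## Known limitations

* CrN treats all overlap degrees above containment equally; overlap areas are
  intentionally out of scope.
* RP assumes distinct group centers and a meaningful inter-center direction;
  concentric configurations are reported as errors, not scored.
* All sensitivities here are training-set quantities (except the optional
  leave-one-out TS); they over-estimate generalization performance and are
  meant for *comparing conditions on the same panel*, not for absolute
  accuracy claims.
* The ellipse model assumes approximately elliptical replicate scatter; with
  5 replicates the sample covariance is noisy, which is why the
  complementary hull-based RP index exists.
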
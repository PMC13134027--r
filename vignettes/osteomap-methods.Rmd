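---
title: "Voxel-based osteomeningioma compartmentalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based osteomeningioma compartmentalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomap)
```

## The model

`osteomap` classifies skull-involving meningiomas from two binary masks per
case — a tumor mask and a skull (osseous) mask — that are assumed to be
already resampled onto one common reference grid (in practice a 1-mm
isotropic atlas space; the package treats the grid as given and never
estimates a registration). From the skull mask alone it derives a mutually
exclusive partition of the grid into four compartments:

1. **osseous** — exactly the skull mask;
2. **juxta-osseous / "dural"** — intracranial voxels whose Euclidean
   distance to the nearest skull voxel is at most the layer thickness *t*;
3. **intradural** — the remaining intracranial cavity;
4. **background/extracranial** — everything else.

Overlaps that can arise after nearest-neighbor resampling are resolved by the
fixed priority osseous > juxta-osseous > intradural, so the partition always
holds. Each tumor voxel inherits the label of the compartment it intersects,
yielding counts `N_bone`, `N_dura`, `N_intra` (plus `N_other` for tumor
voxels outside all three, e.g. subcutaneous extension). The subtype is then a
pure function of the three counts: POM (osseous only), SOM-I (osseous +
juxta-osseous), SOM-IIA (all three, `N_bone >= N_intra`), SOM-IIB (all
three, `N_intra > N_bone`). Equality of osseous and intradural counts is
deliberately assigned to SOM-IIA, so the rule is total on its domain.

Two count patterns have no class and are flagged rather than forced:
`N_bone = 0` (`not_osteomeningioma`: every rule requires osseous
involvement) and `N_bone > 0, N_dura = 0, N_intra > 0` (`skipped_layer`: an
intradural component with no juxta-osseous involvement is geometrically
anomalous on a connected lesion and usually indicates a mask or registration
problem). Forcing either into a class would be invention; flagged cases are
carried through cohort reports and excluded from 2x2 collapses with a
logged count. `N_other` is reported (and enters the percentage denominator,
which is the total tumor voxel count) but never influences the call.

## The juxta-osseous layer is metric, not iterative

The layer is defined by the *metric*: a voxel belongs to it when the
Euclidean distance from its center to the nearest skull voxel center, using
the grid spacing in mm on each axis, is `<= t`. This is computed with an
exact separable distance transform (the parabolic-envelope algorithm,
implemented in C++), so anisotropic grids are handled correctly and the
result equals a brute-force all-pairs computation exactly — a property the
test suite checks on small grids.

An alternative reading — *k* iterative voxel dilations on a 1-mm grid —
differs slightly for diagonal geometry (a chessboard-like ball instead of a
Euclidean ball). The metric definition was chosen because "a 5-mm inward
expansion" most naturally denotes a metric dilation, and because it is the
only definition that behaves consistently on anisotropic grids. The boundary
is inclusive (`<= t`): with voxel centers 1 mm apart, an exclusive boundary
would make the nominal 5-mm figure unattainable.

Two consequences used as invariants: the layer is monotone in *t*
(`t1 <= t2` implies `layer(t1)` is a subset of `layer(t2)`), and as *t*
decreases `N_dura` can only fall while `N_intra` can only rise with `N_bone`
fixed. Under the severity ordering POM < SOM-I < SOM-IIA < SOM-IIB the
subtype is therefore non-decreasing as the layer thins, and POM and SOM-IIB
calls are invariant to *t* entirely.

## Cavity extraction

The intracranial cavity is the bounded region enclosed by the skull: the
skull is sealed by a *metric closing* (dilation then erosion by a Euclidean
ball, radius `closing_radius_mm`, default 2 mm, implemented through the same
distance transform), the complement of the sealed skull is partitioned into
6-connected components, components touching the grid border are discarded as
exterior, and the largest remaining component minus any skull voxels is the
cavity. Real skull masks have foramina and orbital openings; the 2-mm
default seals perforations up to roughly one voxel wide on a 1-mm grid
while leaving the anatomy essentially untouched. An open shell with sealing
disabled is a hard error that names the remedy (increase the radius), never
a silently empty cavity. 6-connectivity is used for the fill because
diagonal connectivity can leak through a one-voxel-thick shell; the metric
closing ball subsumes the role a discrete 26-neighborhood structuring
element would play.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `thickness_mm` | 5 | mm | juxta-osseous layer depth; 2 and 3 mm are the standard sensitivity settings |
| `closing_radius_mm` | 2 | mm | foramen sealing before cavity fill |
| `connectivity` | 6 | — | neighborhood for fill and components (6/18/26) |

The thickness sensitivity analysis (`thickness_sensitivity()`,
`cmd_sensitivity`) reclassifies every case at each thickness (reusing the
thickness-independent cavity), reports the fraction of cases keeping one
subtype across all settings, and tabulates pairwise transition matrices.

## Resampling

`resample_nearest()` applies a supplied invertible world-to-world affine by
pulling each target voxel center back into the source grid and copying the
nearest source voxel; out-of-field voxels become 0 (masks are
absence-default) and the output is always binary. Halfway coordinates round
toward the higher index — a fixed, documented tie-break. Grid compatibility
elsewhere is checked within a 1e-4 relative tolerance (NIfTI header
round-off); genuinely different orientations are errors, never silently
reconciled, because silent axis flips are the classic source of left/right
errors. Registration itself is out of scope by design: the transform is an
input.

## Phantoms: what they emulate, and what they do not

The generators produce (i) closed spherical-shell and slab (closed-box)
skulls whose cavities are known analytically, (ii) lesions with *exact*
requested per-compartment voxel counts, grown as connected blobs crossing
the inner table (bone first, then a juxta-osseous blob steered inward so it
reaches the intradural interface, then intradural, each phase seeded from
the previous blob), and (iii) spherical "transmural" lesions placed in world
coordinates. Ground truth is defined on the generator's own compartment map;
circularity is avoided by validating that map separately against brute-force
distance and flood-fill oracles. If a compartment's reachable region is
smaller than its quota the remainder is placed at random in that compartment
(documented fallback); all placement is deterministic per seed.

The synthetic clinical cohort draws per-case subtype, age (normal), sex,
location, symptom flags (class-conditional Bernoulli) and log-normal
component volumes. Its defaults are the reference cohort's conditions:
subtype sizes 6/37/57/68, the per-subtype symptom frequencies of that
cohort, and log-normal volume parameters matched to the reported medians
and interquartile ranges (sdlog from the IQR via the normal quantile
spacing, `(log q75 - log q25) / (2 * 0.6745)`).

Phantoms emulate mask-level geometry only. They do not model MR intensities,
noise, bias fields, segmentation error, real skull-base anatomy (foramina,
orbits, venous sinuses), or correlated symptom co-occurrence. Passing tests
therefore demonstrate correctness of the geometry, counting, classification
and statistics given masks — not robustness of upstream segmentation or
registration on real data.

## Statistical layer

- **Odds ratios**: `OR = ad/(bc)` with the Woolf (logit) 95% interval,
  `exp(log OR ± 1.959964 * sqrt(1/a + 1/b + 1/c + 1/d))`. The Woolf method
  was adopted because it exactly reproduces the reference cohort's published
  interval endpoints from the per-subtype counts (the source did not name
  its method; this is an inference, verified by the acceptance tests). A
  zero cell triggers the Haldane–Anscombe +0.5 correction on all four cells,
  flagged in the result; the bundled reference comparisons have no zero
  cells, so the policy never touches them.
- **Fisher exact (2x2)**: two-sided p as the hypergeometric tail sum of
  tables no more probable than the observed one (delegated to
  `stats::fisher.test`; an exhaustive enumeration oracle guards it in the
  tests). A degenerate margin returns p = 1 by convention, with a message.
  Omnibus r x c exact tests across all four subtypes are intentionally not
  implemented.
- **Kruskal–Wallis**: mid-rank ties with the standard correction divisor
  (via `stats::kruskal.test`, guarded by a rank-formula oracle).
- **Logistic regression**: maximum likelihood via `stats::glm` (IRLS,
  epsilon 1e-12 so the saturated single-predictor model reproduces the 2x2
  odds ratio to 1e-8), Wald CIs, and per-term quasi-separation flags — a
  binary covariate with an empty margin cell against the outcome, or a
  fitted |coefficient| above 10 on the log-odds scale, is marked unstable;
  non-convergence is flagged, never silent. Volumes enter as
  `log(volume + 1)`, keeping zero volumes defined.
- **Agreement**: Dice and Jaccard (`dice = 2*jaccard/(1 + jaccard)` is
  property-tested), with both-empty pairs scored 1.0 under a warning —
  empty-versus-empty is agreement, and NaN would silently corrupt batch
  reports. Volume concordance uses Pearson r with the Fisher z interval.
- Exact volume ties in index-tumor selection break to the lexicographically
  smallest case id, with a warning. Complete-case handling drops missing
  outcome flags with a logged count; no multiplicity adjustment is applied,
  matching the exploratory framing of the comparisons.

## Problem sizes

The validation suite runs brute-force oracle comparisons on grids up to
about 42^3 voxels, exhaustive rule verification for all count triples with
entries up to 6, 100 seeded phantom lesions for end-to-end ground-truth
recovery, and 2000 synthetic cohorts of n = 400 for Woolf-interval coverage
(the observed coverage is asserted within 95% ± 1.5 percentage points).
These sizes were chosen so the whole suite completes in well under a minute
while leaving the oracles exact.

## Known limitations

- The package consumes normalized masks; errors upstream (segmentation,
  unified-segmentation registration) propagate untouched.
- The "dural" compartment is an explicit proximity band, not anatomy: falx,
  tentorium and venous sinuses are not modeled, so deep dural attachments
  away from the inner table fall in the intradural compartment.
- Cohort-level published quantities that depend on individual patient
  images (subtype distribution, mean component volumes, the cohort's
  observed thickness-stability fraction, adjusted ORs) cannot be recomputed
  from the bundled per-subtype counts and are not claimed by the package;
  the phantom analogues computed by `scripts/acceptance.R` characterize the
  pipeline, not the clinical cohort.
- Firth-penalized or exact logistic regression is not provided; strongly
  separated models are flagged instead.
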
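---
title: "Structural covariance networks, null models, and transcriptomic association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks, null models, and transcriptomic association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covnet)
```

This vignette documents the models and procedures implemented in
`covnet`, the choices made where the design was genuinely open, and what
the synthetic-data experiments do and do not establish about real data.

## The parcellation and its coordinate systems

Every analysis is indexed by the 82-region combined parcellation: 68
Desikan–Killiany cortical regions and 14 subcortical structures
(bilateral thalamus, caudate, putamen, pallidum, amygdala, accumbens and
hippocampus). Regions are ordered as homologue pairs, left before right,
cortical pairs first, so the homologue swap is the permutation exchanging
adjacent pair members and regional matrices are indexed identically to
the table rows.

Two coordinate systems are attached to each region: anatomical
coordinates in mm (used for Euclidean distances involving subcortical
structures) and unit-sphere coordinates of a merged, inflated
cortical/subcortical surface (used by the spin test). No public release
of merged-sphere coordinates exists for this parcellation, so the
packaged table carries *synthetic* coordinates: cortical regions are laid
out quasi-uniformly (golden-angle spiral) on two hemispheric caps, and
subcortical structures sit near the inter-hemispheric axis below the
cortical sheet. The spin and variogram tests only require coordinates
with realistic spatial adjacency — all calibration claims here are
property-based (uniformity of null p-values, agreement between the two
null families), not tied to any particular cortical geometry. Users with
real surface models can supply their own table (`load_region_table()`)
and their own distance matrix.

## Preprocessing

Subjects missing at least half of the cortical or at least half of the
subcortical measures are excluded; remaining missing values are imputed
with the per-region mean over the same site and diagnostic group. Values
are then residualized per site and region on an intercept, age, and sex
by ordinary least squares, and residuals are z-scored with the mean and
SD of the site's control residuals, so control columns are exactly
standardized within every site (this per-site standardization is also
what removes site location/scale effects; a dedicated harmonization tool
can be slotted in upstream by passing already-harmonized values). The
regression pools patients and controls of a site — the alternative
(controls-only fit) changes residuals only through the slope estimates
and is not separately exposed. Sex coding is irrelevant: residuals are
invariant to affine recoding of covariates.

Right-focus TLE patients are reordered by the homologue swap so that
column semantics become ipsilateral/contralateral to the seizure focus.
Controls are not flipped (left hemisphere plays "ipsilateral" by
convention), keeping control data deterministic.

## Covariance networks and thresholding

Per site and diagnostic group with at least 10 subjects, entry
$R_{ij}$ is the Pearson correlation of regions $i$ and $j$ across
subjects. Negative correlations are zeroed; the
$\mathrm{round}(K\,n(n-1)/2)$ largest remaining edges are retained with
their weights at each density $K \in \{0.05, 0.06, \dots, 0.50\}$. Ties
are broken lexicographically by the $(i,j)$ upper-triangle index, which
makes retained edge sets nested across densities; rounding is
half-away-from-zero so all groups share identical edge counts at each
density. A density is *usable* when at least 75 % of nodes belong to the
largest connected component in at least 90 % of site networks; the
pipeline takes the longest contiguous run of usable densities and
performs regional analyses at its smallest density. "Connected to other
nodes" is read as membership in the largest component — the stricter
reading, and the one under which path length is well defined for the
kept node set.

## Graph metrics and null networks

Weighted clustering uses the Onnela formulation (weights rescaled by the
network maximum, geometric-mean triangle intensity); path length uses
Dijkstra shortest paths on $1/w$ edge lengths, averaging each node's
distances over *reachable* partners only — unreachable pairs are excluded
rather than entered as infinite, which keeps $L$ finite at sparse
densities; a fully isolated node gets a flagged missing value. These are
the standard choices of the brain-connectivity toolboxes this package
interoperates with.

Null networks rewire the binary topology by Maslov–Sneppen double-edge
swaps ($10\times$ the edge count in attempted swaps) and re-assign the
original weight multiset to the rewired edges in random order, so the
degree sequence and weight multiset are preserved *exactly* (asserted per
null in the tests). Normalized metrics divide the empirical value by the
null-ensemble mean, nodally and globally, and
$\sigma = C_{norm}/L_{norm}$ by construction. The study default is 1000
nulls; desk-scale runs in this package use 50–200 (the ensemble-mean
standard error scales as $1/\sqrt{n_{nulls}}$).

## Group statistics

Global metrics are compared by paired two-tailed t-tests across sites
(each site contributes one patient and one matched control network), with
Benjamini–Hochberg correction across densities and the study's
significance annotations ($p_{FDR} < 0.1$, uncorrected $p < 0.05$).
Regionally, Cohen's $d$ (pooled $n-1$ SD across sites) is computed per
metric, and the joint (clustering, path length) change is tested with
Hotelling's $T^2 = n\,\bar d^\top S^{-1} \bar d$ on the site-wise paired
differences, converted to an F statistic on $(2, n-2)$ degrees of
freedom, BH-corrected across regions ($q = 0.05$). A singular difference
covariance receives a $10^{-10}$ diagonal ridge and is flagged.

The scalar "multivariate topological change" correlated with expression
maps is $T^2$ signed by the projection of $\bar d$ on $(1,1)$ — positive
for joint increase (regularization), negative for joint decrease
(randomization). This scalarization is a package choice (the unsigned
variant is returned alongside); nothing downstream depends on the sign
convention beyond the direction of one-tailed tests. Regions whose
metrics are undefined at the analysis density (isolated nodes) enter the
spatial correlation as zero change.

Nodal group contrasts default to **raw** metrics: the null normalization
is a per-network rescaling that nearly cancels in patient-minus-control
differences, while its ensemble noise propagates into the site-level
difference maps — on synthetic cohorts the normalized variant is
measurably less sensitive. `normalize_nodal = TRUE` restores the
normalized variant.

## Spatial null models

**Spin test.** Three angles are drawn uniformly from $[0, 2\pi)$ about
the x, y and z axes and composed in that order; both hemispheres rotate
jointly on the merged sphere. Rotated regions are matched to original
regions by nearest (Euclidean) neighbour, many-to-one allowed. One map
(the topology map) is rotated, the other held fixed, and the one-tailed
p-value uses the add-one estimator
$p = (1 + \#\{r_{null} \ge r_{emp}\})/(1 + n_{perm})$; the study default
is 10,000 rotations (calibration experiments here use 500).

**Variogram-matching surrogates.** Distances are great-circle between
cortical pairs (sphere scaled to 100 mm radius) and 3-D Euclidean for
pairs involving subcortical structures. Each surrogate permutes the map,
smooths each region over its $k$ nearest neighbours with an exponential
kernel (bandwidth = distance to the $k$-th neighbour), selects $k$ from a
candidate grid {3, 5, 8, 12, 16, 20} by least-squares agreement between
the surrogate's and the empirical binned variograms (25 uniform bins),
and affine-rescales with a white-noise nugget to the empirical variogram.
`knn = 0` degenerates to plain permutation. Bin count and kernel family
are package choices; calibration and the spin/variogram agreement checks
(rank correlation of p-values > 0.9 in the shipped experiments) support
them.

**Random-gene nulls.** Gene sets of the tested size are drawn without
replacement from the full supplied universe, averaged to maps, and
correlated with the topology map; same add-one estimator. Cell-type
specificity uses the same construction per cell type with a two-tailed
add-one p-value, discarding (and counting) gene lists whose mean score is
zero; set-difference tests report p against both "A − random" and
"random − B" nulls plus their conservative maximum. Under that maximum, a
cell type where only one of the two sets deviates from random genes is
by construction not significant — the reported per-null p-values
disambiguate.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
exercised: 14 sites (plus a 10-site second comparison for the full-study
layout), 40 patients and 40 controls per site, the 82-region
parcellation, subject vectors drawn from a multivariate normal with
block-structured correlations — 0.4 within communities, 0.1 between —
with community sizes (10, 10, …, 12) aligned to homologue pairs.
Pair alignment matters: communities that split left/right homologues
would interact with the ipsi/contra flip of right-focus patients and
manufacture spurious group differences at community boundaries. The
patient effect is a +0.2 within-community correlation increment in the
first community ("regularization"); correlation matrices are checked for
positive semi-definiteness (nearest-PD projection if needed). Realistic
scales (thickness ≈ 2.5 mm, volumes in the thousands of mm³),
site-specific offsets and scales, linear age/sex effects, and 1 %
missingness are layered on top. Expression matrices are Gaussian-process
draws (squared-exponential kernel over great-circle distance,
length-scale 0.7 rad) with a planted set
$\rho \cdot \mathrm{std}(target) + \sqrt{1-\rho^2}\cdot GP$; cell-type
matrices are gamma-noise baselines with additive planted loadings,
truncated at zero.

What the generator does *not* emulate: realistic MRI measurement noise,
non-Gaussian morphometry distributions, heterogeneous effect topography,
scanner-specific covariance distortions, or the empirical spatial
autocorrelation structure of real cortical maps. Passing tests therefore
establish the *mechanics* of the pipeline (correctness of the
statistics, calibration of the null models, recoverability of effects of
known size) — not clinical effect sizes.

## Measured operating characteristics

The shipped experiments (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) run at desk scale: 100 random ≤ 8-node graphs for
the metric oracles (agreement to 1e-10), 200 rewired nulls for the
conservation checks, 200 map pairs at 500 rotations for spin calibration,
and 50 replicates of the planted-effect recovery at the default
conditions. On those replicates the planted community is cleanly visible
in the effect maps — planted clustering Cohen's d is positive in every
replicate, and planted regions fill ~80 % of the top decile of the
clustering-d map with ~1 % false positives at $p_{FDR} < 0.05$ — but the
per-region Hotelling detection fraction is ~0.55 rather than the 0.70
one might hope for: with 14 sites, the site-to-site variability of
thresholded nodal metrics is of the same order as the planted effect, so
bivariate t-statistics sit near the BH boundary. Doubling the number of
sites (or halving threshold-induced site noise) would be needed for
reliable per-region detection at these effect sizes; this is an honest
property of per-region inference on site-level networks at this scale.

## Numerical notes

* Degenerate global tests: an exactly constant nonzero patient–control
  shift across sites has no variance; it is reported as a flagged
  degenerate result ($t = \pm\infty$, $p = 0$) detected at a relative
  1e-12 tolerance.
* Thresholding ties are resolved lexicographically; equal-weight edges
  are rare with continuous data but the rule makes runs bit-reproducible.
* All stochastic entry points take explicit seeds; `run_pipeline` derives
  and logs stage seeds from one master seed.
* Problem sizes in tests (numbers of permutations, nulls, replicates) are
  the package's desk-scale defaults, chosen so the full suite and the
  acceptance script each run in minutes on a single CPU; study-scale
  settings (1000 nulls, 10,000 permutations) are plain arguments.
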
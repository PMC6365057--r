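---
title: "Quantifying directed collective migration and GPCR chimera compatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directed collective migration and GPCR chimera compatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastruquant)
```

## Scope

During zebrafish gastrulation the prechordal plate (ppl), a cluster of
anterior axial mesendoderm progenitors, migrates toward the animal pole at
2--3 um/min, and its movement is normally highly correlated with the
overlying neuroectoderm. `gastruquant` implements the measurement stack for
studying how a GPCR (Frizzled-7-class) signal shapes that behavior:

1. **kinematics** — sector-binned directional-correlation order parameter
   between two cell populations and animal-pole-directed velocity from 3D
   cell tracks;
2. **protrusions** — per-type protrusion rates and circular orientation
   statistics;
3. **morphometry** — length-to-width ratio (LWR) of an expression domain,
   inter-domain distance with scale-bar calibration, membrane/cytosol line
   profile ratio, nuclear mean intensity;
4. **structure** — Kabsch superposition of transmembrane (TM) helix CA
   atoms and van-der-Waals residue contact networks, for judging the
   structural compatibility of receptor pairs in chimera design;
5. **stats** — the normality-gated decision tree used throughout
   (D'Agostino--Pearson, then t-test / Mann--Whitney or ANOVA+Tukey /
   Kruskal--Wallis+Dunn).

Raw 4D microscopy is out of scope: tracks, images, profiles and structures
are consumed, not produced. Because no raw imaging data accompany the
biological study this package was built around, every stage ships with a
synthetic-data generator whose ground truth the estimators must recover;
the generators are first-class, tested code.

## The movement-correlation order parameter

For every pair of consecutive observed frames of each track, a 3D velocity
sample is the forward difference `v = dx / dt` (gaps between frames use the
actual dt; this is the minimal, gap-tolerant scheme). At each time point the
samples of both populations are binned into 50 x 50 um sectors in the xy
plane (z collapsed), on a grid anchored at the ppl leading edge; sector
intervals are half-open `[low, high)` so assignment is deterministic. The
leading edge is operationalized as the centroid of the cells at or beyond
the 0.95 animal-axis quantile — the anterior 5% — since no operational
definition exists in the source workflow; the quantile is a parameter.

Within a sector, each population's velocity vectors are averaged first, and
the directional correlation of the sector is the cosine between the two
mean vectors ("average-then-correlate"). Sectors missing a population, or
with a zero mean vector, are excluded. The **order parameter** at a time
point is the unweighted mean over valid sectors (+1 — the tissues co-move,
-1 — they move oppositely); occupancy weighting is available as an option
but is not the default, because the quantity is an order parameter of
*local* correlation, not a per-cell average. When several embryos are
supplied, sectors are averaged within each embryo first and the
across-embryo mean ± SEM is reported.

### The track generator

`simulate_correlated_tracks()` produces two populations of biased random
walks. A cell's step is

    dx = [c * d_shared + (1 - c) * d_pop] * s * dt + N(0, sigma^2 I3)

with coupling `c` in [0, 1], drift speed `s` (default 2.5 um/min, the
middle of the observed 2--3 um/min range), shared drift toward the animal
pole (+y) and a population-private drift (+y for the ppl-like population,
+x for the neuroectoderm-like one, so that `c` acts as a monotone
correlation dial from uncorrelated to identical drift). The effective drift
vector is deliberately *not* re-normalized, so intermediate couplings also
slow the second population slightly; the ground truth attached to each
simulated data set records the effective drifts. Step noise is isotropic
Gaussian — the simplest model with analytic expectations; real embryos add
tissue jamming, rosettes and division events that this generator does not
emulate, so passing recovery tests demonstrates correctness of the
estimator, not biological realism of the model.

Two limits are exact and are used as anchors: `c = 1, sigma = 0` gives an
order parameter of exactly +1; opposed noise-free drifts give exactly -1.
In between, the estimate is compared against a Monte-Carlo oracle — an
independent re-implementation run on ten replicate simulated embryos —
at 200 cells x 50 frames and sigma = 1 um, tolerance 0.05.

The frame interval of the underlying time-lapse movies is not part of the
package's assumptions; `dt` is a free parameter of the generator and the
velocity computation uses whatever time stamps the tracks carry.

## Protrusion statistics

Events carry a cell id, time, one of three types (lamellipodium/
pseudopodium, filopodium, bleb) and an orientation angle with the animal
pole at 0 degrees, counterclockwise positive, in [0, 360). Rates are
count / observed minutes per cell; the cohort value is the mean ± SD over
cells (scatter-plot-with-mean-and-SD convention). Defaults in the generator
emulate a wild-type-like lamellipodium rate of 0.33 events/cell/min and a
mutant-like 0.14, with Poisson counts per cell and von Mises angles
(Best--Fisher sampler; no circular-statistics package in the dependency
stack provides one). Rose histograms use half-open 30-degree bins — the
original binning is unknown, so the width is a parameter — and an angle on
a boundary goes to the higher bin. Angles are kept unfolded in [0, 360)
rather than folded left/right, which is the conservative choice when the
published convention is unknown. Circular summaries are vector sums: mean
direction and resultant length `R` in [0, 1].

## Morphometry

Calibration is um/px = bar_um / bar_px from an annotated scale bar. The
semi-automated domain measurements replace interactive ROI selection with
threshold + largest 8-connected component (components via the pixel
adjacency graph; the direction of thresholding is configurable for dark
chromogenic stains).

* **LWR**: length is the maximum Feret diameter over boundary hull pixel
  centers; width is the maximal extent perpendicular to the max-Feret
  direction (not the minimum Feret, not a centroid chord — this is the
  closest operationalization of "the axis perpendicular to the longest
  axis" on a blob). The ratio is >= 1 by construction and is rotation-,
  translation- and scale-invariant within a 2% discretization tolerance.
* **Domain distance**: minimum Euclidean distance between boundary pixel
  centers (boundary = mask pixels 4-adjacent to background), converted to
  um. An along-axis projected variant is provided for measuring gaps along
  the anteroposterior axis specifically. Overlapping masks return 0 with a
  warning rather than an error, since touching domains are a legitimate
  biological outcome.
* **Membrane/cytosol ratio**: peaks are prominence-filtered local maxima
  (topographic prominence, spacing-pruned keeping the higher peak; at
  least two peaks are required — one cell crossed by a line has two
  membranes). Membrane intensity is the mean peak height; cytosolic
  intensity is the mean of samples farther than a half-width from every
  peak. The reported quantity is cytosol/membrane, with "background"
  read as the cytosolic signal along the line (the quantity the
  localization figures report); subtracting extracellular background
  instead is possible by measuring it separately, but is not the default.
  The ratio is invariant under multiplicative gain, not under additive
  offset — tested as such.
* Pixel model everywhere: pixel centers at integer coordinates, row-major,
  origin top-left. The domain-image generator anchors its raster on integer
  multiples of the pixel size so that noise-free ground truth (an LWR of
  2.0, a 60-um gap) is recovered exactly at matching pixel sizes.

The image generator rasterizes a rotated ellipse (ppl-like) and a
rectangular bar (notochord-like) with a configured boundary gap, plus a
scale-bar record; the profile generator places `n_cells + 1` membrane
peaks (Gaussian bumps truncated at 3 sigma) over a cytosolic plateau, so
that the clean-profile ratio equals `cytosol_level / membrane_peak`
exactly.

## Structural compatibility of receptor pairs

`superpose()` performs least-squares rigid superposition (Kabsch, SVD
formulation, proper rotations only) of paired TM CA atoms and reports the
RMSD over all pairs; there is **no outlier pruning by default** (many
interactive tools prune; pruning is available via `prune_sd` with the
documented effect of lowering RMSD). Residue pairing between two receptors
is either by shared generic residue numbers or, by default, "trim" mode:
segmentwise index-by-index pairing after trimming the longer segment to
the shorter one's length from both ends (an odd surplus is dropped from
the C-terminal end). Trim mode absorbs the 1--2-residue uncertainty in
curated segment boundaries.

Contacts: a residue pair (on different annotated segments) is a contact
when any heavy-atom pair lies within `r_vdw(i) + r_vdw(j) + 0.5 A` — a
Protein-Contacts-Atlas-style criterion; the tolerance and radius table are
parameters. Counts per unordered segment pair, totals, and the fractional
distribution (which sums to 1) are reported. Published benchmark values
for the rhodopsin/Smoothened comparison (TM RMSD 2.8 A inactive / 2.6 A
active; 223/217/197/173 inter-helical contacts) are treated as
tolerance-band targets, not bit-exact truths, because the original
superposition protocol is not fully specified. The four PDB files are not
redistributable fixtures; the benchmark runs when they are supplied
locally (see `analysis/05_structure.R`), and the curated TM segment ranges
shipped in `inst/extdata/gpcr_tm_segments.yaml` are marked as curation,
not computation. The synthetic helix-bundle generator (ideal alpha-helical
CA traces on a circle, optional Gaussian perturbation and rigid motion,
stored ground-truth RMSD) validates the machinery end to end without
external data: a rigidly moved copy superposes to RMSD 0 (to 1e-6), a
perturbed copy reproduces the stored-pair RMSD, and a 7-helix ring with
axis spacing 7 A touches exactly its 7 adjacent neighbor pairs under the
default criterion.

## The statistical decision tree

Per group, normality is assessed with the D'Agostino--Pearson omnibus test
(implemented from the standard skewness and kurtosis Z-transforms;
verified against an independent implementation to 9 decimals). With two
groups: unpaired two-sided Welch t-test if all groups look normal,
Mann--Whitney otherwise. With more: one-way ANOVA + Tukey HSD, or
Kruskal--Wallis + Dunn's test (joint-rank z statistics with tie
correction; Bonferroni adjustment by default, configurable — the original
procedure names Dunn but not the adjustment). The omnibus test requires
n >= 8; smaller groups are routed to the nonparametric branch and the
reason is recorded in the result. The pre-test alpha defaults to 0.05 and
is a parameter. The branch taken is a pure function of the group count and
the per-group normality verdicts.

## Reproducibility and problem sizes

Every generator takes an integer seed and is bit-reproducible;
`run_pipeline()` writes a JSON provenance log with the package version,
seed, stage parameters and MD5 checksums of all outputs, and two runs with
the same config produce identical checksums. The shipped analyses and the
acceptance checks use 200 cells x 50 frames per population for kinematics,
50-seed replicates for rate and ratio recovery, and 100-instance
randomized sweeps for the brute-force oracle comparisons — sizes chosen so
estimator standard errors sit well inside the stated tolerances while the
whole suite runs in minutes on a laptop.

## Known limitations

* The track model has no cell--cell interactions, divisions, or track
  fragmentation beyond what the reader tolerates; gaps are handled but not
  generated.
* Sector statistics assume the grid axes are aligned with the oriented
  animal--vegetal / mediolateral frame; `orient_axes()` must be applied
  first for tracks recorded in arbitrary coordinates.
* The LWR width definition (max perpendicular extent) can exceed the
  ellipse minor axis on very noisy masks; it is the documented choice, not
  a bug.
* Protrusion classification is taken as given (the original annotation was
  manual); no detector is included.
* Segment annotations are curated inputs; the package does not derive
  GPCRdb numbering.
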
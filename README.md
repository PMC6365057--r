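# gastruquant

Quantification toolkit for studying how GPCR signaling directs collective
cell migration during zebrafish gastrulation, and for assessing the
structural compatibility of receptor pairs in optogenetic chimera design.

During gastrulation the prechordal plate (ppl) — a cluster of anterior
axial mesendoderm progenitors — migrates toward the animal pole at
2–3 μm/min, normally in tight coordination with the overlying
neuroectoderm. `gastruquant` implements the full measurement stack for
that system:

- **Movement correlation.** From 3D cell tracks, per-interval velocity
  vectors are averaged in 50 × 50 μm sectors (z collapsed) on a grid
  anchored at the ppl leading edge; each sector's directional correlation
  is the cosine between the two populations' mean velocity vectors, and
  the **order parameter** is the sector average: +1 when the tissues
  co-move, −1 when they move oppositely. Animal-pole-directed velocity
  time series use the same leading-edge rule.
- **Protrusion dynamics.** Rates in events/cell/min per protrusion type
  (lamellipodium/pseudopodium, filopodium, bleb), rose histograms of
  orientation (0° = animal pole), and circular summaries (mean direction,
  resultant length R).
- **Expression-domain morphometry.** Length-to-width ratio (maximum Feret
  diameter over the perpendicular extent), minimum boundary distance
  between two domains with scale-bar calibration, membrane/cytosol line
  profile ratios via prominence-based peak finding, and per-nucleus mean
  intensities.
- **Structure.** Kabsch superposition of transmembrane-helix CA atoms
  (RMSD, no default outlier pruning) and van-der-Waals residue contact
  networks (vdW-sum + 0.5 Å criterion), with per-helix-pair counts and
  distributions — the compatibility evidence behind rhodopsin/Frizzled
  chimera design.
- **Statistics.** The normality-gated decision tree: D'Agostino–Pearson
  omnibus per group, then t-test / Mann–Whitney (2 groups) or one-way
  ANOVA + Tukey / Kruskal–Wallis + Dunn (> 2 groups).

No raw imaging data are required: every stage has a synthetic-data
generator (`simulate_correlated_tracks()`, `simulate_protrusion_events()`,
`make_domain_image()`, `make_membrane_profile()`, `make_helix_bundle()`)
that writes the same file formats the readers consume and carries the
ground truth its estimator must recover.

## Worked example

Simulate two populations with known movement coupling, then recover the
order parameter and the animal-pole velocity:

```r
library(gastruquant)

cfg <- track_sim_config(n_cells_per_population = 200, n_frames = 50,
                        drift_speed = 2.5, coupling = 0.75,
                        noise_sigma = 1, seed = 1075)
tracks <- simulate_correlated_tracks(cfg)

op <- correlate_tracks(tracks, popA = "ppl", popB = "neuroectoderm",
                       sector_um = 50)
mean(op$order_parameter)
#> [1] 0.8379516

av <- ap_velocity(tracks, "ppl", edge_quantile = 0.95)
mean(av$v_ap)
#> [1] 2.569433
```

An order parameter of ~0.84 says the two tissues' local movement
directions agree strongly (a fully coupled, noise-free pair gives exactly
1.0; opposed drifts give −1.0); the leading-edge cells advance animally at
~2.5 μm/min, the configured drift. Sweeping the coupling dial
(`analysis/01`–`02`) gives the expected monotone response:

```
 coupling order_parameter ap_velocity
     0.00           0.005       2.482
     0.25           0.280       2.472
     0.50           0.624       2.476
     0.75           0.838       2.569
     1.00           0.910       2.543
```

Comparing two protrusion-rate cohorts runs the decision tree end to end:

```r
wt  <- simulate_protrusion_events(c(lamellipodium_pseudopodium = 0.33),
                                  n_cells = 15, duration = 60, seed = 11)
mut <- simulate_protrusion_events(c(lamellipodium_pseudopodium = 0.14),
                                  n_cells = 15, duration = 60, seed = 12)
compare_groups(list(
  wt     = protrusion_rate(wt$events,  wt$windows)$per_cell$rate,
  mutant = protrusion_rate(mut$events, mut$windows)$per_cell$rate))
#> Group comparison: unpaired t-test
#>   statistic = 7.62, p = 5.719e-08
#>   normality (D'Agostino-Pearson, alpha = 0.05 ):
#>   group  n   p.value normal testable
#>      wt 15 0.8355738   TRUE     TRUE
#>  mutant 15 0.7246830   TRUE     TRUE
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
package's study-style analyses, writing tidy CSVs under `results/`:

| script | what it does |
|---|---|
| `01_simulate_tracks.R` | track data across a coupling grid |
| `02_correlation.R` | order parameter + AP velocity per coupling |
| `03_protrusions.R` | per-type rates, rose histograms, circular stats |
| `04_morphometry.R` | LWR, domain distances, profile ratios |
| `05_structure.R` | helix-bundle validation; published PDB benchmark if `analysis/pdb/` holds 1u19/4jkv/3pqr/6d32 |
| `06_statistics.R` | decision-tree comparisons of the above |

`run_pipeline()` offers the same stages config-driven (YAML) with a JSON
provenance log (seed, parameters, output checksums).

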
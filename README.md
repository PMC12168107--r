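# bioregshift

Bipartite-network bioregionalisation and climate-driven region shifts for
marine species assemblages.

Communities, not single species, set the large-scale structure of ocean
biogeography: assemblages separated by climatic barriers (sharp temperature
fronts) form regions whose boundaries should be predictable under climate
change. `bioregshift` implements the full "group first, then predict"
workflow for testing that idea on gridded occurrence compilations:

1. **Occurrences** — coordinate cleaning (equal lon/lat, (0,0), on-land,
   duplicates), a 1950–2019 October–March window, species retention by a
   10-occurrence cut-off OR a >50% endemism rule, and rasterisation to a
   binary species × 1°-cell presence matrix.
2. **Regions** — the presence matrix becomes a bipartite species–site
   network clustered by minimising the two-level map equation

   *L(M) = q H(Q) + Σᵢ (qᵢ + pᵢ∘) H(Pᵢ)*

   with a greedy optimiser (Louvain-style aggregation plus fine- and
   coarse-tuning, best of 100 seeded restarts, written in C++). Clusters
   with fewer than 20 nodes are discarded; species fidelity
   *Fᵢ = occurrences in region / total occurrences* characterises cohesion.
3. **Barrier test** — kernel densities of each region's cells along the
   temperature gradient; the overlap coefficient ∫min(f₁, f₂) quantifies
   separation, with the gap interval between the colder region's 90th and
   the warmer region's 10th percentile.
4. **Region models** — each major region (≥ 30 presences) is a
   presence–absence target modelled by five techniques (GLM, GAM, neural
   network, discriminant analysis, adaptive hinge splines) under 4-fold
   spatial block cross-validation; variables pass Spearman-0.7 collinearity
   grouping and permutation importance (*Imp = 1 − r*, median > 10%);
   members are accepted iff Jaccard *J = TP/(TP+FP+FN)* ≥ 0.5 on held-out
   blocks.
5. **Projection** — delta-corrected warming fields
   (*baseline + future − historical*), ensembles of 20 baseline and 200
   future runs (5 techniques × 4 folds × 10 pseudo-GCMs), hard
   classification maps, the normalised transition index
   *TI = −Σ (pᵢ/P) log(pᵢ/P) / log N*, and equal-area gains/losses across
   five probability classes with paired t- or sign tests.

A first-class synthetic-data module (`make_default_scene()` and friends)
plants two thermal guilds across an 8 °C barrier with known ground truth, so
the entire pipeline is testable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic scene; each step prints its findings and writes tables under
`results/`:

```sh
Rscript analysis/01_simulate_scene.R
Rscript analysis/02_delineate_regions.R
Rscript analysis/03_climatic_barrier.R
Rscript analysis/04_region_models.R
Rscript analysis/05_project_shifts.R
```

Output from a run of steps 1–2 (seed 42):

```
Scene: 16200 cells (14662 ocean), 70 species, 159609 occurrence records
Planted barrier: 8.0 degC; isotherm latitude -52.5 deg
<bg_bipartite> 70 species + 14119 sites, 93561 edges
<bg_partition> 11 modules, L = 9.6290 bits (best of 100 runs)
<bg_regions> 2 regions (node counts: 7272, 6879); 38 unassigned nodes
Region 1: 7272 nodes, 7242 cells, mean temperature 15.5 degC
Region 2: 6879 nodes, 6848 cells, mean temperature 0.5 degC
```

Eleven modules are found; after the <20-node filter exactly the two planted
regions survive — a warm (subtropical-like) region and a cold (southern)
region — and the nine minor clusters (widespread transition species and the
localised endemics with their few cells) are set aside. Step 3 then reports

```
<bg_barrier_report> temperature @ 200 m: overlap = 0.0083 (threshold 0.05) -> barrier supported
  gap interval: [2.61, 13.24] degC
```

the planted barrier: the two regions' temperature densities barely overlap
and the gap spans the 8 °C isotherm. Step 4 fits the ensembles
(`selected predictors: temp_200m`; 20 members per region, median Jaccard
0.992, all accepted — temperature alone explains the region boundary), and
step 5 projects them under the +2 ± 0.5 °C pseudo-GCM set:

```
Region 1 (20 baseline runs, 200 future runs):
       class    delta test  p_value significant
5 (0.8, 1.0]  1713290 sign 1.24e-60        TRUE   # warm region gains
Region 2:
5 (0.8, 1.0] -1632002 sign 1.24e-60        TRUE   # cold region loses
Transition zone mean latitude: -52.5 -> -53.5 deg (poleward shift yes)
```

Under uniform warming the very-high-probability area (km²) of the warm
region expands significantly, the cold region's contracts by a matching
amount, and the transition zone (normalised transition index ≥ 0.9) moves
poleward — the qualitative fingerprint of a climatic barrier tracking its
isotherm.

## Layout

```
R/                  package code: grid/fields, synthetic scene, occurrences,
                    network + map equation (src/ holds the C++ core),
                    barrier diagnostics, region models, projection
analysis/           numbered workflow scripts (the study, step by step)
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (models, assumptions, design choices)
```
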
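---
title: "Group first, then predict: methods behind bioregshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group first, then predict: methods behind bioregshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bioregshift` implements a community-level ("group first, then predict")
workflow for marine biogeography: species occurrences are first clustered
into biogeographical regions through a bipartite species-site network, and
the regions - not the individual species - are then modelled against the
environment and projected under warming. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## 1. The bipartite network and the map equation

Occurrence records, after cleaning and filtering, are reduced to a binary
species x cell presence matrix on a 1-degree grid (multiple records of a
species in a cell collapse to a single presence). The matrix is read as a
bipartite network: one node per species, one per occupied cell, one
undirected unweighted edge per presence. Species-species and site-site edges
do not exist.

Regions are modules of this network under the two-level map equation. For a
random walk with node visit rates $p_\alpha = \deg(\alpha)/2E$, module exit
rates $q_i$ (boundary edges over $2E$), $q = \sum_i q_i$ and module totals
$p_{i\circ}$, the description length in bits is

$$L(M) = q\,H(Q) + \sum_i (q_i + p_{i\circ})\,H(P_i),$$

the expected two-level code length of the walk. Minimising $L$ groups cells
that share many species with each other and few with the rest - precisely
the definition of a biogeographical region. We use the flat (two-level)
equation with an undirected, unweighted walk and no teleportation: presence
networks are undirected, connected in practice, and the reported regions are
flat partitions. Description length is in bits (base-2 entropies); any base
gives the same argmin.

The optimiser is the published greedy core: every node starts in its own
module; seeded random-order local moves and module aggregation (Louvain
phases) alternate with *fine-tuning* (single-node moves on the flat
partition) and *coarse-tuning* (submodule detection inside each module,
then submodule-level moves) until no move lowers $L$. Both tuning phases
matter in practice: plain aggregation is prone to a hub-capture local
optimum in which a single well-connected species claims the cells where it
is the only record. Because the search is stochastic, `infomap_cluster()`
runs 100 independent restarts (distinct sub-seeds) and returns the shortest
description length; ties resolve to the first partition found under the
seeded order, so results are reproducible per seed. On every fixture graph
with eight or fewer nodes the restart search attains the exhaustive-
enumeration optimum (tested), and codelengths agree with an independent
Infomap implementation on the full synthetic scene.

Modules with fewer than 20 nodes (species + cells) are discarded as
anecdotal - localised endemism or sampling artefacts - and the surviving
regions are renumbered by decreasing node count. Species fidelity
$F_i$ = (presence cells of species $i$ inside the region) / (all presence
cells of $i$) characterises region cohesion; rows sum to 1 over the
pre-discard clusters.

## 2. Climatic-barrier diagnostics

For each of two regions we estimate the Gaussian-kernel density of the
environmental values (one value per member cell) on a shared support, with
Silverman bandwidth floored at 0.1 units to handle degenerate samples, and
quantify their separation by the overlap coefficient
$\int \min(f_1, f_2)$. The coefficient is symmetric, lies in $[0,1]$ and
equals 1 only for identical curves; for equal-variance normals it has the
closed form $2\Phi(-\delta/2\sigma)$ used as a test oracle. The barrier is
declared supported when the overlap falls below 0.05 - a package default
standing in for a visual no-overlap judgement, reported alongside the
number - and the gap interval (colder region's 90th to warmer region's 10th
percentile) is reported when non-empty.

## 3. Region distribution models

Each region with at least 30 presence cells becomes a presence-absence
target: presences are its cells, absences the cells of the other retained
regions (their composition is assumed distinct enough to stand in for true
absences). Five technique families are fitted - linear-logistic (GLM with
quadratic terms), smooth-additive (GAM), feed-forward neural network,
discriminant analysis (QDA with an LDA fallback), and adaptive regression
splines (hinge-basis logistic regression with AIC backward pruning, written
in-package). The families are contracts, not package names: anything
returning calibrated probabilities qualifies.

Variable screening follows a two-step protocol. Spearman correlations above
0.7 (in absolute value) group variables into connected components, and one
representative per group goes forward. Importance is permutation-based:
$\mathrm{Imp} = 1 - r$, where $r$ is the mean Pearson correlation between a
model's predictions and its predictions after shuffling the variable
(10 shuffles). Variables with median importance above 10% across the
techniques are kept, and kept variables' importance vectors must never
correlate below $-0.3$ (mutual exclusivity check). Two caveats are worth
stating. First, the representative of a collinear group is chosen by
univariate median importance with near-ties (within 0.01) broken by
univariate AUC, because importance saturates near 1 for any strong
predictor and cannot rank near-duplicates. Second, $\mathrm{Imp} = 1 - r$
is a *relative* measure: in a model fitted to pure noise with $k$
variables, shuffling one leaves the other $k-1$ spurious contributions
shared, so importances hover near $1/k$ rather than 0. Useless variables
are reliably suppressed only in the presence of a real signal; the
empty-selection error path exists but is triggered by the threshold, not by
noise alone.

Evaluation uses four-fold spatial block cross-validation. Square blocks
tile the grid; the default side is the lag at which the Moran's I
correlogram of the leading predictor (computed on a 1200-cell subsample)
first drops below 0.1, i.e. the scale beyond which spatial autocorrelation
between calibration and evaluation data is weak. Blocks are randomly
assigned to folds, retried up to 1000 times until each fold's presence and
absence counts are within 10% (relative) of $n/4$; an unattainable balance
returns the best attempt with a warning. Each member is calibrated on three
folds and scored on the held-out fold by the Jaccard index
$J = TP/(TP+FP+FN)$ - prevalence-independent, unlike AUC, which is reported
for comparability. The binarisation threshold maximises $J$ on the
calibration folds (the source protocol names no threshold; this is the
package's gap decision). Members with $J < 0.5$ (more than half of their
positive calls wrong) are rejected and excluded from projection. The
evaluation-strip diagnostic screens response shapes: a response is
plausible if its 5-point moving average has at most one sign change in the
first differences (monotone or unimodal).

## 4. Projection, transition index and area change

Future fields come from additive delta correction:
`corrected = baseline + (GCM_future - GCM_historical)` per cell, so model
bias cancels and the baseline's spatial anomalies are preserved exactly.
Every accepted member is projected onto the baseline (5 techniques x 4
folds = 20 runs per region) and onto each of the 10 pseudo-GCM corrected
fields (200 runs); ensemble maps are the pooled mean, uncertainty the
pooled standard deviation.

The transition index at a cell with region probabilities $p_i$,
$P = \sum p_i$, is the entropy of the shares,
$TI = -\sum_i (p_i/P)\log(p_i/P)$ (natural log, $0\log 0 = 0$), normalised
by the simplex maximum $\log N$ so that $TI_{norm} \in [0,1]$: 1 where
regions are equally likely (the transition zone), 0 where one region
dominates. We interpret the normalising maximum as the theoretical
$\log N$, not the observed map maximum - the former guarantees the $[0,1]$
range for any map and makes maps comparable across scenarios. The index is
invariant to rescaling all probabilities, is undefined where $P = 0$, and
its spot value at $(0.8, 0.2)$ is checked against an independent entropy
computation.

Areas use the exact spherical form
$A = R^2\,\Delta\lambda\,(\sin\phi_{top} - \sin\phi_{bottom})$ with
$R = 6371$ km, which reproduces equal-area-projection sums analytically
(full sphere $= 4\pi R^2$, tested to $10^{-6}$ relative error) without a
projection library. Gains and losses are tallied in five occurrence-
probability classes ($[0,0.2], (0.2,0.4], \ldots, (0.8,1]$) *per run*: each
future run (member x GCM) is paired with its member's baseline run, and the
paired per-run area differences are tested - Shapiro-Wilk at $\alpha=0.05$
gates between a paired t-test and a sign test. The per-run convention is
required for a run-level test distribution; using ensemble-mean maps alone
would leave nothing to test. The transition zone is the set of cells with
$TI_{norm} \ge 0.9$; its area change is reported per longitude sector along
with the area-weighted mean latitude of the zone.

## 5. What the synthetic scene emulates - and what it does not

The generator plants the structure the analysis assumes, with ground truth
for recovery tests. Defaults (all in `make_default_scene()`):

* **Grid** 1 degree, 360 x 45 cells from 75 S to 30 S; a fixed land mask
  (two continental blocks and an ice-shelf edge) leaves 14,662 ocean cells.
* **Temperature at 200 m** rises monotonically from -1 degC (75 S) to
  17 degC (30 S) as a linear/logistic blend: 80% of the meridional change
  is carried by a logistic front (sharpness 40 on the unit span) centred on
  the 8 degC isotherm, plus a 1 degC zonal wave (wavenumber 3) and 0.3 degC
  white noise. The front is deliberate, and not only for realism (the
  subtropical and subantarctic fronts are sharp): with a purely linear
  profile the species-poor band between the guilds covers thousands of
  cells whose sparse records attach to whichever widespread species was
  recorded there, producing spurious 20+-node clusters that no clustering
  method should be asked to explain away.
* **Species pool** 30 cold-guild + 30 warm-guild species with Gaussian
  thermal responses; optima evenly spaced with jitter within
  [-0.5, 5.5] and [10.5, 15.5] degC (limiting-similarity packing - random
  optima leave richness dips whose cells behave like the empty band above),
  breadths 1.6-2.25 degC, maximum occupancy 0.75-1. Five widespread
  transition species (breadth 4-6 degC straddling 8 degC) are rare
  (occupancy 0.004): abundant broad-niche species become network hubs whose
  exclusive cells form their own 20+-node modules - the planted minor
  clusters must stay minor. Five localised species (breadth 0.75, occupancy
  1) live in two 8-degree longitude windows near the front.
* **Sampling effort** background 0.3 plus 40 Gaussian hotspots (s.d. 5
  degrees, amplitude 0.7, capped at 1); detection is Bernoulli(occupancy x
  effort) and detected species-cell pairs carry 1 + Poisson(0.7) dated
  records (1950-2019, October-March). The background is the lowest at which
  the planted two-region structure is reliably recoverable; sparser
  sampling fragments the map-equation partition, which is a finding about
  sparse compilations, not a bug in either component.
* **Warming** 10 pseudo-GCMs, anomaly = 2 +/- 0.5 degC (one draw per GCM),
  historical fields offset +0.5 degC from the baseline so delta correction
  is exercised rather than inert.

The scene does **not** emulate ocean dynamics (fronts as currents, eddies),
bathymetry or productivity gradients, taxonomic error, temporal trends in
the record stream, or CMIP-style spatially structured anomalies. Passing
recovery tests therefore shows the pipeline recovers planted thermal-guild
structure under heterogeneous sampling - not that any real compilation has
that structure.

## 6. Numerical choices and problem sizes

Degenerate KDE samples get a 0.1-unit bandwidth floor; density curves are
trapezoid-renormalised to unit mass on the shared support. Fold balance uses
relative tolerance 0.1 with up to 1000 retries. Permutation importance uses
10 shuffles; preliminary (univariate) and importance rounds run on 3000- and
4000-row subsamples respectively, since they only rank variables, while
final members are fitted on the full folds. Probability thresholds for
Jaccard maximisation are scanned on a 0.01 grid. The map-equation optimiser
accepts moves improving $L$ by more than $10^{-12}$ bits. Tests and the
acceptance checks run the full default scene (16,200 cells, 70 species,
about 90,000 network edges), one clustering with 100 restarts, two
2-region x 20-member ensembles and one 10-GCM projection; that is the
problem size the reported behaviour refers to.

## 7. Known limitations

Absences are other regions' cells, so models describe *contrast between
regions*, not habitat suitability in an absolute sense; cells in no
retained region are ignored during calibration. The two-level map equation
tends to carve hub-and-satellite modules out of sparse networks - real
Infomap shows the same behaviour - so minor-cluster counts are sensitive to
sampling density even when the two major regions are stable. Permutation
importance is relative (see section 3). The barrier overlap threshold
(0.05) and the transition-zone threshold (0.9) are reported defaults, not
estimated quantities. Future ensembles pool member and GCM variability into
a single standard deviation; separating the two would need a variance
decomposition that the source protocol does not define.
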
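---
title: "Methods: network topology, activation selectivity, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network topology, activation selectivity, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`netsel` implements a resting-state network analysis that relates the
connectional topology of brain-network nodes to their task-evoked
activation, and examines how that relationship erodes across the adult life
span (dedifferentiation). The pipeline runs from node-level BOLD time series
to four products:

1. cleaned resting-state series (nuisance regression, band-pass filtering,
   motion scrubbing with interpolation and refiltering);
2. reliable, reference-labeled functional systems per group, obtained by
   bootstrapped Infomap consensus across edge densities;
3. per-node weighted participation coefficients (PC), summed across
   densities, with a within-system connector / non-connector
   classification;
4. per-participant activation-selectivity scores relating PC to task β
   maps, overall and separately by system type.

Because no public data accompany the study design this package targets, a
synthetic-cohort generator is a first-class component: it plants all of the
structure the analysis is supposed to detect, so the entire pipeline is
validated by parameter recovery.

# Preprocessing model

A resting-state run is cleaned in the standard six-step order:
(1) multiple regression against an arbitrary nuisance design — the
`friston24()` helper expands a six-parameter realignment trace into the
24-column motion design (parameters at `t`, at `t−1`, and both squared;
the lagged value at the first frame is defined as 0);
(2) zero-phase band-pass filtering, default 0.009–0.08 Hz, realized as an
order-2 Butterworth applied forward and backward;
(3) flagging of frames with framewise displacement (FD) above 0.3 mm, where
FD is the sum of absolute frame-to-frame differentials of the three
translations (mm) and the three rotations converted to arc length on a
50 mm sphere, with FD of the first frame defined as 0;
(4) linear interpolation of flagged frames from the nearest kept frames
(runs at either end held at the nearest kept value);
(5) re-regression and re-filtering of the interpolated series, so that
artifacts in censored frames cannot blur into kept frames through the
filter; and
(6) removal of the flagged frames. Participants with fewer than 75
surviving frames are excluded (a typed `netsel_exclusion` condition, so a
cohort driver can count exclusions rather than crash).

Choices the band and thresholds do not determine themselves: the rotation
radius (50 mm) follows the motion-scrubbing literature; the interpolation is
linear (the method behind the study's interpolation step is not specified;
spectral interpolation would be a drop-in refinement); discarding initial
scanner-stabilization frames is the caller's responsibility since synthetic
runs have none.

# Graphs, consensus systems, and node roles

Edges are Fisher-z transformed Pearson correlations, `z = atanh(r)`.
Negative edges are excluded before analysis, as is standard after
global-signal regression. Group matrices average participant z-matrices
entrywise *with* negative entries retained, and exclude negatives from the
mean afterwards (zeroing before averaging would bias the group mean upward).

Graphs are thresholded by edge density: at density `d` the
`round(d · N(N−1)/2)` strongest edges are retained *with their weights*
(round half up; ties broken by lexicographic node order so edge sets are
deterministic and nested across densities). The analysis band is 2–10% in
1% steps.

Community detection uses the map equation (Infomap, via igraph) behind a
pluggable `detect_communities()` surface; isolated nodes become singleton
communities. Reliable per-group assignments are built by bootstrap:
resample participants with replacement, average z, threshold at each
density, detect communities, and label each detected community with the
reference system name that maximizes node overlap under an optimal
one-to-one assignment (a compact Hungarian solver; communities smaller than
`min_nodes = 5` or with no overlap are `unassigned`). Each node's consensus
label at each density is its modal label across replicates, with ties broken
toward the lowest label in sorted order and recorded.

The participation coefficient of node *i* on a thresholded graph is
`PC_i = 1 − Σ_s (k_i(s) / k_i)²`, summing over **all** systems including
the node's own, so a fully within-system node has PC 0. A variant that
omits the own-system term (which would assign such a node PC 1) is
available as `variant = "literal"` for sensitivity analysis, but the
default follows the role-cartography literature in which PC measures the
spread of a node's connection weight across systems. Edges to unassigned
nodes are excluded from both numerator and denominator; nodes with no
remaining weight get PC 0 (recorded with a warning). Per-density PCs are
summed over the 2–10% band ("pc_sum") to absorb configuration differences
across densities, and a node is a **connector** if its pc_sum exceeds the
median pc_sum of its own system, a **non-connector** otherwise (ties to
non-connector, so connectors never outnumber non-connectors within a
system). Classification within systems, not across the whole network,
prevents the systematically higher PCs of association systems from
absorbing the entire connector class.

Group-level roles are computed on group-mean matrices; participant-level
PCs (for selectivity) use individual matrices with the group consensus
assignment, a choice made for label stability — the study design does not
state which partition individual-level PCs used.

# Activation selectivity

For one participant and task, `selectivity = −1 × r(PC, β)` across nodes:
positive values mean nodes with mostly within-system connectivity
(non-connectors) activate more. Pearson correlation is the default (the
statistic is used linearly throughout); Spearman is available. Default-mode
nodes are excluded by default to avoid conflating activation with
task-induced deactivation, and unassigned nodes are always excluded.
Scores by system type (sensory–motor vs association scope) restrict the
correlation to nodes of one type. `cohort_summary()` adds per-task/scope
means, SDs, the Pearson correlation of score with age, and a descriptive
LOESS trend (span 0.75, degree 1). A permutation test
(`role_permutation_test()`) shuffles role labels to give a null for the
non-connector-minus-connector activation contrast.

# The synthetic cohort

## What is planted

The generator emulates, at desk scale, a life-span resting-state cohort:

* **Systems.** Five systems of 20 nodes (two sensory–motor, two
  association, one default — the default block exercises the
  default-exclusion rule). Node correlations follow a factor model: each
  node loads on its own system's factor and on a global factor
  (`rho_between = 0.05` baseline between-system correlation), so the
  planted matrix is positive semidefinite by construction and every planted
  pairwise correlation is available in closed form.
* **Heterogeneous within-system coupling.** Non-connector coupling targets
  are evenly spaced over `rho_within ± within_spread` (0.40 ± 0.12). This
  is essential, not cosmetic: at 2–10% density a 100-node graph retains at
  most 495 of 950 within-system pairs, so with homogeneous blocks the
  retained set is an all-or-nothing function of tiny numerical
  perturbations. A graded spectrum of coupling strengths makes edge
  retention, and everything downstream of it, vary smoothly.
* **Connectors as bridged hubs.** Half the nodes of each system are planted
  connectors. They occupy the upper half of the within-coupling range
  (hubs), and each carries one dedicated cross-system link — a two-node
  bridge factor — of correlation about
  `rho_between + connector_boost = 0.47` to a rank-matched connector of the
  next system. Dedicated bridge factors are what make this work: a shared
  "partner-system factor" would induce spurious correlations among all
  co-loading connectors (cliques and reciprocal pairs strong enough to
  merge systems), whereas a bridge factor touches exactly one pair. Bridge
  strengths are spread over ±7% around nominal, rank-matched to the
  endpoints' coupling, so each connector's strongest within-system edge
  outranks its bridge (keeping it anchored in its home community at sparse
  densities) while retention of bridges across the band degrades gradually
  under noise instead of all at once.
* **Dedifferentiation.** With normalized age `a ∈ [0, 1]` (0 ≈ 20 y,
  1 ≈ 89 y): non-connector within coupling declines by
  `dediff_slope_within · a` (default 0.02/unit-age), and the most strongly
  attached non-connectors progressively *acquire* connector-like bridges of
  full strength (`dediff_slope_between = 0.42`), staggered so the
  re-coupled fraction grows roughly linearly with age (interleaved across
  systems; strongest-anchored first, because a node whose only retained
  edge is its bridge has PC 0 — cross links only register as participation
  on nodes that keep within-system edges). The combined effect reproduces
  the target qualitative pattern: non-connector PC rises toward the
  connector level, and the connector-minus-non-connector pc_sum gap closes
  monotonically with age while mean PC rises.
* **Motion.** Continuous realignment jitter (0.01 mm translations, 1e-4 rad
  rotations) plus single-frame spikes (probability 0.05/frame, FD 0.6 mm,
  split across the three translations so FD is analytically checkable; the
  return to baseline flags the following frame as well). Spike frames also
  receive a shared additive BOLD artifact (3 SD) so scrubbing genuinely
  matters.
* **Task βs.** Per task: `β = base(system type) +
  δ · (1 − delta_age_slope · a)` for planted non-connectors in
  task-relevant system types, plus i.i.d. Gaussian noise (SD 0.5). The two
  default tasks mirror a visual task (bonus in sensory–motor systems,
  δ = 1.0) and a semantic task (bonus in association systems, δ = 0.45),
  with `delta_age_slope = 0.8` so selectivity declines across the life
  span.

Runs are 1000 frames at TR 2 s by default. Determinism is bitwise: one seed
per participant, derived from the cohort seed, with a fixed draw order.

## What is *not* emulated

No hemodynamic convolution, spatial autocorrelation, physiological noise,
distance-dependent artifact, inter-individual parcellation variability, or
volumetric/surface imaging of any kind. Passing recovery tests on this
cohort therefore shows the *pipeline* is correct and well-calibrated for
block-structured signals with planted roles — not that the analysis is
robust to every artifact structure of real fMRI.

## Why the bridge architecture (design notes)

Three simpler generative designs fail structurally, and knowing why
motivates the final one:

1. *Homogeneous blocks + shared partner factors*: the edge-retention
   threshold at 2–10% falls inside the within-system tier, so either no
   cross-system edge is ever retained (role recovery impossible) or the
   partner-factor correlations exceed within ones and Infomap reassigns
   connectors to their partner systems (community recovery fails).
2. *Shared partner factors with hub connectors*: co-loading connectors
   acquire mutual correlations (`c²` terms, reciprocal `2cλ` pairs) that
   form cross-system cliques among connectors and merge systems at higher
   densities.
3. *Ranked cross-coupling to a whole partner system*: retained cross edges
   concentrate on the few highest-coupling partner nodes, which are
   non-connectors, handing them spurious cross-participation and inverting
   the role classification.

Dedicated two-node bridges avoid all three failure modes at the cost of a
sparser cross-edge structure than real connector hubs exhibit; this is a
known limitation, acceptable because the participation coefficient only
requires that cross-system weight be present and attributable.

# Validation by parameter recovery

The test suite regenerates cohorts under the default ("study") conditions
and verifies, among others: exact agreement of the PC implementation with a
naive double-loop oracle (≤ 1e-12 over random graphs); hand-derived PC
values; exact censoring behavior and the 75-frame exclusion; the filter's
pass/stop contract; consensus recovery of the planted partition
(chance-corrected agreement ≥ 0.9 at every density, 20 participants, 100
bootstraps); connector-role recovery (accuracy ≥ 0.8 averaged over 20
cohort seeds); selectivity recovery (sign test over 50 participants, a null
with |mean| < 0.05, and a monotone dose–response in δ); the age-graded
erosion of the PC gap (4 groups × 32 participants — chosen because the
per-participant gap SD is ≈ 0.25 and the planted per-group step ≈ 0.15)
and of selectivity, with task-type specificity; a permutation null for the
activation contrast; and bitwise reproducibility of the pipeline given a
seed. Problem sizes in the tests (bootstrap counts of 10–100, cohorts of
6–128) are chosen as the smallest sizes at which the planted effects are
statistically decisive.

Chance-corrected agreement (adjusted Rand index) between a consensus and
the planted partition is computed over nodes that carry a proper label in
both partitions; at the sparsest densities many peripheral nodes are
legitimately unassigned (they have no retained edges), and counting them
would measure coverage, not agreement. Coverage is reported separately.

# Numerical choices and degenerate inputs

* Fisher z diverges at |r| = 1; correlations within 1e-12 of ±1 raise an
  error naming the node pair, as do zero-variance nodes.
* Edge-count rounding is half-up; cutoff ties break by (i, j) node order.
* If fewer positive edges exist than a density requests, all positive edges
  are kept, with a warning and the achieved density recorded.
* The nuisance design is checked for full column rank (collinear columns
  are named); residual orthogonality is guaranteed by a QR solve.
* A frame with FD exactly at the threshold is kept (the rule is strictly
  greater).
* Isolated nodes: PC 0 (the 0/0 ratio is defined as 0), singleton
  communities, recorded.
* All floating-point output is serialized at 17 significant digits with '.'
  decimal, so writer/reader round trips are exact and runs with the same
  configuration and seed are byte-identical (stage timings are written to a
  separate log file that is not part of the deterministic bundle).

# Known limitations

* The generator's cross-system structure is sparse (one bridge per
  connector) relative to real connector hubs with diverse multi-system
  links.
* β noise is i.i.d. across nodes; no spatial autocorrelation.
* The linear-in-age dedifferentiation model is a modeling convenience; the
  underlying study design only establishes group contrasts, not a
  generative trajectory.
* Consensus labels are computed independently per density (no cross-density
  label stitching); downstream analyses sum over densities instead.
* The exact minimum community size for reference labeling is configurable
  (`min_nodes`, default 5) because the size rule used in practice varies.
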
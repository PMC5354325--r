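# netsel

Resting-state network topology and task activation selectivity, across the
adult life span.

## The problem

Brain areas differ in how their resting-state functional connectivity
(RSFC) is distributed: **non-connector** nodes connect mostly within their
own functional system, while **connector** nodes bridge systems. A
recurring observation in cognitive neuroscience is that non-connector nodes
of task-relevant systems activate more strongly during tasks, and that this
*activation selectivity* erodes with age as network topology
dedifferentiates — within-system connectivity falls, between-system
connectivity rises, and the connector/non-connector contrast shrinks.

`netsel` is for researchers who have node-level BOLD time series (any
parcellation, extracted upstream), head-realignment traces, and per-node
task β estimates, and who want a tested, reproducible implementation of
this analysis — plus a synthetic-cohort generator that plants the whole
causal structure, so the pipeline can be validated end-to-end by parameter
recovery rather than taken on faith.

## The statistics at the core

* Edges: Fisher-z Pearson correlations, `z = atanh(r)`, negative edges
  excluded; graphs thresholded at edge densities 2–10% (top
  `round(d·N(N−1)/2)` edges, kept weighted).
* Systems: Infomap communities on bootstrapped group-mean matrices
  (resampling participants, 1000 replicates by default), labeled against a
  reference partition by optimal overlap assignment; each node's reliable
  assignment is its modal label across replicates, per density.
* Node topology: weighted participation coefficient
  `PC_i = 1 − Σ_m (k_i(m)/k_i)²` per density, summed over the 2–10% band;
  a node is a connector iff its summed PC exceeds the median of its own
  system.
* Activation selectivity, per participant and task:
  `selectivity = −1 × r(PC, β)` across nodes (default-system nodes
  excluded) — positive when low-PC (non-connector) nodes activate more.
* Preprocessing: Friston-24 nuisance regression, 0.009–0.08 Hz zero-phase
  band-pass, framewise-displacement scrubbing at 0.3 mm with interpolation
  and refiltering, and exclusion of participants with fewer than 75
  surviving frames.

## Worked example

Simulate a small young-adult cohort with planted systems and roles, run the
full pipeline, and look at what it recovers:

```r
library(netsel)

spec <- cohort_spec(n_participants = 12, age_grid = rep(0, 12))
cfg  <- pipeline_config(cohort = spec, out_dir = "demo_out",
                        n_boot = 50, seed = 42)
res  <- run_pipeline(cfg)

head(res$topology[, c("node_id", "system", "system_type", "pc_sum", "role")])
#>   node_id     system   system_type    pc_sum          role
#> 1    n001 unassigned          <NA> 0.0000000      excluded
#> 2    n002        S01 sensory-motor 0.0000000 non-connector
#> 3    n003 unassigned          <NA> 0.0000000      excluded
#> 4    n004        S01 sensory-motor 0.3082262 non-connector
#> 5    n005 unassigned          <NA> 0.0000000      excluded
#> 6    n006        S01 sensory-motor 0.4009733     connector

aggregate(score ~ task + scope, data = res$scores,
          FUN = function(x) round(mean(x), 3))
#>       task         scope  score
#> 1 semantic           all  0.057
#> 2   visual           all  0.109
#> 3 semantic   association  0.123
#> 4   visual   association -0.033
#> 5 semantic sensory-motor  0.036
#> 6   visual sensory-motor  0.342
```

The bootstrap consensus recovers the five planted systems (weakly coupled
peripheral nodes stay `unassigned` and are excluded from role analysis),
summed PC separates planted connectors from non-connectors, and the
selectivity table shows exactly the planted task-type specificity: the
"visual" task's selectivity is concentrated in sensory–motor systems
(0.342 vs −0.033), the "semantic" task's in association systems (0.123 vs
0.036). `res$consensus`, `res$scores` and the written TSV/JSON artifacts in
`demo_out/` carry the full detail; reruns with the same config and seed are
byte-identical.

With an age-graded cohort (`age_grid` spanning 0 to 1, i.e. ~20 to ~89
years), `cohort_summary()` additionally reports the negative correlation of
selectivity with age and its restriction to task-relevant system types.

## Layout

* `R/synthetic.R` — cohort specification and generator (factor-model
  covariance with bridge factors, motion spikes, task βs, planted truth)
* `R/preprocess.R` — FD, Friston-24 design, nuisance regression, band-pass,
  scrubbing
* `R/graph.R` — Fisher-z matrices, density thresholding, node strength
* `R/communities.R` — Infomap wrapper, Hungarian label matching, bootstrap
  consensus, partition agreement
* `R/topology.R` — participation coefficients, density-summed PC, connector
  classification
* `R/selectivity.R` — selectivity scores, node-type activation contrasts,
  permutation null, cohort summaries
* `R/pipeline.R`, `R/io.R` — end-to-end driver, configuration, TSV/JSON
  readers and writers
* `vignettes/netsel-methods.Rmd` — the full methods account: model,
  parameters, generator design rationale, numerical choices, limitations
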
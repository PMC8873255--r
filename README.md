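# mobimark

Digital mobility biomarkers from outdoor GPS navigation traces.

`mobimark` is for researchers studying real-world spatial navigation in
small case-control cohorts — typically Alzheimer's disease patients and
matched healthy controls tracked with a pocket GPS unit over a couple of
weeks. It turns raw timestamped latitude/longitude traces into
participant-level features of everyday navigation, compares the groups,
and runs the two classification protocols that go with those features. A
seeded synthetic cohort generator makes the whole pipeline runnable and
testable without access to any private tracking data.

## What it computes

The unit of analysis is the **return-loop segment**: a contiguous
sub-trajectory that returns to within 10 m of its start, lasts 1–20 min
and covers ≥ 100 m of path. Segments are extracted greedily (maximum path
length per start, no temporal overlap, never across recording gaps) and
characterised on a 100 m grid:

* **Segment entropy** — Shannon entropy of grid-cell visit counts pooled
  over a participant's segments, `H = −Σ_c P(c) log P(c)` (natural log);
  low when movement concentrates on few places.
* **Segment similarity** — per segment, the fraction of the participant's
  other segments whose cell-set Jaccard similarity `|A∩B| / |A∪B|`
  exceeds 0.5.
* **Distance from home** — Euclidean distance from the estimated home
  (centroid of daily first/last positions) to each segment's centroid.
* **Shape** — segment complexity (number of points where the averaged
  absolute first/second-order turning angle `(|θ¹| + |θ²|)/2` exceeds
  120°), total turning angle `Σ sin θ¹` (signed; negative for
  clockwise-majority turning), radius of gyration.
* **Stops** — durations of periods static within 10 m for ≥ 60 s.
* **Mobility graph** — grid cells dwelt in ≥ 5 min as nodes, observed
  transitions as edges, transit cells removed with their neighbours
  clique-reconnected; closeness, betweenness and degree centrality per
  node.

Groups are compared feature-wise by two-sample Kolmogorov–Smirnov tests
with Cohen's `d` effect sizes on the pooled per-segment values.
Patient-vs-control classification is leave-one-participant-out logistic
regression trained by stochastic gradient descent (10,000 steps, repeated
50× to quantify uncertainty), with features as 10-bin normalised
histograms; sensitivity is the fraction of true patients among
participants *predicted* patient, specificity the analogue for controls.
Alone-vs-accompanied movement is classified per segment with an
RBF-kernel SVM on raw shape/temporal features.

## Worked example

```r
library(mobimark)

co <- generate_cohort(cohort_config(n_controls = 2, n_patients = 2,
                                    days = 7, master_seed = 11))
tr <- co$traces[["P001"]]
tr
#> <mm_trace> participant P001 (patient): 6284 samples, 1.5e+02 h span

prep <- prepare_participant(tr, co$annotations)
nrow(prep$segments)
#> [1] 17

pf <- participant_features(prep)
round(pf$entropy, 3)
#> [1] 3.018
head(pf$seg[, c("companionship", "similarity", "distance_from_home",
                "complexity", "total_turning_angle", "n_stops")], 5)
#>   companionship similarity distance_from_home complexity total_turning_angle n_stops
#> 1   accompanied      0.000                258          3                2.16       0
#> 2   accompanied      0.000                415          4                5.82       2
#> 3   accompanied      0.000                619          7                8.80       2
#> 4   accompanied      0.312                205          3                4.32       3
#> 5         alone      0.000                709          2               -1.73       1
```

This patient made 17 return loops in a week; their visit entropy of 3.02
nats reflects a moderate spread of visited cells, and the accompanied
loops show the higher turning-angle complexity and extra stops that the
alone/accompanied classifier exploits. `run_pipeline()` runs the full
analysis (segments → features → graphs → statistics → both classifiers)
and writes CSV tables plus a JSON summary; `exec/mobimark` exposes the
same stages as shell subcommands (`simulate`, `segment`, `features`,
`graph`, `stats`, `classify`, `run-all`, `bin-sweep`).

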
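---
title: "Digital mobility biomarkers from outdoor GPS traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital mobility biomarkers from outdoor GPS traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobimark)
```

## The problem

People with Alzheimer's disease show navigation impairments early, but
almost everything we know about them comes from clinic-based proxy tests.
`mobimark` implements an analysis pipeline for the alternative: passively
recorded outdoor GPS traces from a small case-control cohort, tracked over
about two weeks at a 3 s or 5 s sampling interval, with a navigation diary
recording for each of a patient's outings whether they moved alone or
accompanied by a carer.

The unit of analysis is the **return-loop segment**: a contiguous
sub-trajectory that comes back to within a slack radius (10 m) of its own
starting point, lasts between 1 and 20 minutes, and covers at least 100 m
of path. Loops are the tangible, comparable units of movement in a
free-living trace; the duration and length thresholds discard both day-long
outings and jitter while standing still. Within each contiguous recording
bout, segments are extracted by a greedy left-to-right scan: at each
candidate start the admissible endpoint maximising path length is taken
(ties towards the later endpoint) and the scan resumes after the emitted
segment, so segments never overlap in time. The scan is implemented in C++
and is verified in the test suite against an exhaustive quadratic reference
on dozens of seeded random traces.

## Features

Three families of features are computed per participant, on a 100 m
square grid where coarsening is needed:

* **Mobility domain.** *Segment entropy*: pool the per-sample grid-cell
  visit counts over all of a participant's segments, normalise to a
  probability mass over the visited cells, and take the Shannon entropy
  (natural log; the uniform distribution over $k$ cells gives $\ln k$).
  Every sample contributes one count, so the mass is dwell-weighted; a
  per-crossing variant is available. *Segment similarity*: two segments
  are similar when the Jaccard similarity of their cell sets exceeds 0.5;
  each segment's feature is the fraction of the participant's other
  segments similar to it (self-pairs excluded — including them would floor
  the feature at $1/N$). *Distance from home*: homes are not declared, so
  home is estimated as the centroid of the daily first and last recorded
  positions, and each segment contributes the Euclidean distance from home
  to its centroid.

* **Spatial shape.** At each interior sample the first-order turning angle
  is the counterclockwise rotation between the incoming and outgoing
  movement vectors, in $[0^\circ, 360^\circ)$; the second-order angle is
  the same on stride-2 vectors, which smooths single-sample localisation
  noise. *Segment complexity* counts the samples whose averaged absolute
  angle $(|\theta^1| + |\theta^2|)/2$ exceeds 120°; absolute values make
  it invariant to reversing the direction of travel. *Total turning angle*
  is $\sum_i \sin \theta^1_i$ — signed, so clockwise-majority turning is
  negative, and threshold-free. The *radius of gyration* (root-mean-square
  distance from the segment centroid) summarises spatial extent.
  Consecutive duplicate points are merged before angle computation, since
  the angle of a zero-length vector is undefined; positions where the
  second-order angle does not exist (near the ends) are excluded from the
  average rather than padded.

* **Temporal.** *Stop durations*: a person is static when their position
  stays within 10 m of a window anchor for at least 60 s. "Position does
  not change" is unphysical under GPS jitter, so the 10 m radius — the
  same spatial scale as the segment slack — operationalises it. A greedy
  anchored scan returns the ordered stop durations; the count of stops is
  used for the alone/accompanied task.

* **Mobility graph.** From the full trace (all movements), every occupied
  grid cell is a node, consecutive-sample cell transitions are undirected
  edges, and dwell time accrues to the cell of each interval's first
  sample. Cells dwelt in less than 5 minutes are transit and are removed
  in ascending dwell order (ties broken by cell key so the result is
  deterministic), pairwise reconnecting each removed node's current
  neighbours so connectivity is preserved — the test suite checks this
  against a reachability oracle. On the surviving graph we compute
  closeness (reciprocal summed hop distance, Wasserman–Faust scaled by
  component size so disconnected graphs are handled; this is configurable),
  normalised betweenness, and degree centrality. Graphs need at least 10
  nodes to enter the analysis.

Per-participant features are either scalars (entropy, node count) or
distributions over segments/nodes; the latter are represented as 10-bin
normalised histograms so every participant has a fixed-length vector.
Histogram ranges are computed from the training participants only and
frozen for the held-out participant, to keep the feature representation
leakage-free.

## Group statistics and classification

Group differences are assessed per feature by pooling the raw per-segment
(or per-node) values across the participants of each group and applying
the two-sided two-sample Kolmogorov–Smirnov test (asymptotic p-value) with
Cohen's d, $d = (\bar{x}_1 - \bar{x}_2)/s_p$, as effect size. No
multiple-testing correction is applied, mirroring the descriptive use of
these tables. Note that pooled values are clustered within participants,
so these p-values are descriptive rather than strictly calibrated — a
caveat inherent to the protocol.

Patient-versus-control classification uses logistic regression fitted by
plain stochastic gradient descent — constant learning rate $10^{-3}$,
10,000 single-sample steps, random initialisation, no regularisation —
evaluated leave-one-participant-out. Because the optimiser is stochastic,
the whole experiment is repeated 50 times; uncertainty is the mean over
participants of the standard deviation of their 50 held-out control-class
probabilities. A participant is predicted control when that probability
exceeds 0.5. Sensitivity and specificity follow the protocol's
predicted-class denominators: sensitivity is the fraction of true patients
among participants *predicted* patient, specificity the fraction of true
controls among those predicted control; both are computed per run and
summarised by medians. The SGD hyper-parameters beyond the step budget are
deliberately plain and exposed, since the reported quantities are medians
across repeated stochastic fits, not properties of one optimiser
configuration.

For this task patients contribute only segments made while moving alone
(diary-labelled; a segment inherits the majority label of its samples,
`unknown` if more than half are unlabelled), and only patients with more
than five such segments are kept. The alone-versus-accompanied task pools
the labelled segments of all patients and classifies individual segments
with an RBF-kernel SVM (cost 1, $\gamma = 1/p$ on features z-scored on the
training split) on raw per-segment features; 20 random 80/20 splits give
the accuracy distribution. The graph task keeps all segments and compares
participants on graph topology features.

## The synthetic cohort generator

The study's GPS data are private, so the package carries a seeded
generator that emulates the statistical structure the analysis assumes; it
is first-class, tested code. Each participant gets a home and a personal
destination set; outings are home-anchored round trips along piecewise
linear routes with persistent, possibly reused route variants; dwell
pauses of 1–10 minutes occur at destinations; positions are sampled at 3 s
or 5 s and perturbed with Gaussian noise. Group contrasts are explicit
parameters with the built-in directions: patients have fewer destinations
(4 vs 10 on average), closer destinations (650 m vs 2.5 km scale), and
higher route reuse (0.75 vs 0.3); about half of patient outings are
accompanied, and accompanied routes meander — semicircular scallops whose
many small same-signed turns accumulate sine (with a counterclockwise
bias, driving the total turning angle positive) and whose near-reversal
junctions count as complexity — at a strolling pace with extra mid-route
pauses. Sample sizes default to 18 controls and 15 patients over 14 days.

Two modelling choices depart from the simplest noise model, for physical
reasons. First, noise is AR(1)-correlated (marginal sd 5 m, lag-one
correlation 0.85; correlation 0 recovers i.i.d. noise): independent 5 m
errors at a 3 s interval would fabricate on the order of 100 m of spurious
path per minute of standing still, which both defeats the 100 m
minimum-length filter and makes the 10 m stop criterion undetectable —
real tracker noise is strongly autocorrelated at these lags. Second,
during destination dwells and pauses the simulated tracker repeats its
cached position fix, as consumer GPS units commonly do when stationary;
without this, stationary jitter dominates the turning-angle features of
every segment.

Participant-level structure is deliberately routinized: destination counts
sit at the group mean, destination distances follow a fixed quantile
profile of a Gamma law (with a fixed rank permutation and evenly spread
bearings), visits follow a largest-deficit schedule matching the Zipf
weights, route variants rotate within a capped pool, and daily outing
volume alternates 2/3. This reflects how habitual real visit schedules
are, and it is what makes the generator's *null* configuration (all
contrast parameters equal across groups, accompanied effects off) actually
null downstream: the pooled KS test sees hundreds of clustered segment
values, so any participant-level parameter lottery — destination counts,
distance spectra, tracker-interval mixes, visit multiplicities — would
surface as spurious group differences. Travel speed is drawn per outing
from a fairly narrow 2.5–4.5 m/s band for the same reason: with wildly
mixed speeds, the extracted loop extents of two replays of the same route
differ enough that their similarity becomes a coin flip, which
concentrates the similarity feature on a few discrete ratios whose exact
positions encode each participant's segment count.

What passing on synthetic cohorts does and does not show: the pipeline
recovers contrasts that are built in, at realistic noise levels and
sampling rates, and stays at chance when they are absent. The generator's
routes ignore road networks (the features under test are network-agnostic),
its noise has no multipath structure, its companionship labels are exact,
and the decorated-route model of carer influence is stylised; effect sizes
measured on it say nothing about effect sizes in real cohorts, and only
the contrast *directions* built into the generator are meaningful.

## Numerical choices and degenerate inputs

Cells are half-open with the floor convention, so boundary points belong
to the higher-index cell; histogram bins are likewise half-open with the
last bin closed, and out-of-range values are clipped into the terminal
bins. Duplicate timestamps keep the first sample. A participant with a
single segment has no similarity value (logged and skipped) and one with
no stops contributes an all-zero stop histogram. Bouts are split at
recording gaps over 60 s — 12–20 times the nominal sampling interval — and
segments never span bouts: a loop interrupted by a recording gap is not a
loop we can measure. The projection is a per-participant azimuthal
equirectangular plane centred on the median position (mean Earth radius
6371008.8 m); over city-scale spans its distances agree with great-circle
distances to well under 0.1%, which is negligible against the 10 m and
100 m analysis scales. Empty predicted classes make a run's
sensitivity/specificity undefined; such runs are excluded from the medians
and logged.

## Reproducibility and problem sizes

Every stochastic stage is seeded from a single master seed, and a full
pipeline run is byte-identical when repeated. The default analysis sizes
are those of the emulated study (33 participants, 14 days); the test suite
exercises the end-to-end properties at those sizes and uses smaller
cohorts (4–10 participants, 4–5 days) and 3 replicates per setting for
property sweeps such as the monotone effect-size response, which keeps the
suite brisk while leaving every property at full strength.

## Limitations

The pooled KS p-values inherit the clustering caveat above. The
predicted-denominator definitions of sensitivity and specificity are not
the textbook ones and can be undefined in degenerate runs. Under a
permutation null the leave-one-out protocol is biased *below* chance when
the groups are balanced (the training fold always leans $n$-versus-$n-1$
against the held-out participant's class), so null-control checks should
bound the rates from above, not expect them to equal the prevalence. With 33
participants the leave-one-out medians are coarse (steps of 1/7 in
sensitivity for 7 included patients in the alone-segment task). The
mobility graph treats all transitions as undirected and unweighted, and
dwell attribution to the interval's first sample makes graphs invariant to
time reversal only up to boundary intervals. None of the components model
transport mode, road networks, or indoor movement.
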
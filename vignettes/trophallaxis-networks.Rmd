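---
title: "Inferring and analysing trophallaxis-proxy networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and analysing trophallaxis-proxy networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophnet)
```

## The measurement problem

Liquid food moves through an ant colony by trophallaxis, a mouth-to-mouth
exchange. Scoring actual exchanges from video is impractical at scale, so a
proximity proxy is used: ants carry printed fiducial tags that report
identity, position, and orientation in every analysed frame; the head
position is taken along the tag's front direction; and two ants are scored
as having interacted if their heads ever came within a threshold distance.
Restricting to head-to-head proximity excludes head-to-abdomen and other
encounters that cannot be trophallaxis. The result, per trial, is a simple
undirected, unweighted graph over the ants that interacted at least once.

Two measurement realities shape every design choice downstream:

* **Frame rates vary** across trials (0.31–2.92 images/sec) and within a
  trial (image storage can stall capture). Contact *duration* is therefore
  not comparable between trials, and edges are occurrence-only. The mean
  frame rate enters the statistical models instead — as a covariate at the
  group level and as a random-effect grouping factor at the individual
  level.
* **Not every tagged ant interacts.** Networks may contain fewer nodes than
  the group has members. The default node policy (`participants`) keeps
  exactly the ants incident to an edge; `all_tagged` retains isolates for
  sensitivity analyses.

## Interaction inference

The threshold is calibrated from manual measurements of head-to-head
distances in frames sampled from each trial (50 per trial in the original
protocol): per-trial means are computed and the *highest* mean is applied
to all trials (`calibrate_threshold()`), giving the operating value of
102 px at 0.04 mm/px. Detection (`detect_interactions()`) is
boundary-inclusive (distance ≤ threshold counts) and requires
*co-detection*: a frame contributes only if both ants were detected in it,
so missed detections can hide but never fabricate an edge. Frame gaps are
recorded but never interpolated — with occurrence-only edges, interpolation
could only manufacture contacts that were not observed. The head offset
defaults to 0 px (head proxy = tag reference point): the calibrated
threshold already absorbs a constant tag-to-head displacement, and no
measured displacement is available; the parameter exists
(`head_offset_px`) for rigs where it is known.

## Network and activity measures

For each trial the package computes two global measures — density
(`|E| / C(n, 2)`) and the number of walktrap communities — and two per-ant
centralities — degree (distinct partners) and unnormalised betweenness
(`sum over pairs of sigma_st(v) / sigma_st`, unordered pairs counted once,
unreachable pairs contributing 0) — plus total distance moved (Euclidean
steps between consecutive detections of the tag centre, summed over the
trial; a lower bound on the continuous path under subsampling).

Two definitional ambiguities are surfaced as options rather than silently
resolved. The density denominator uses the constructed graph's node set by
default (with the `participants` policy this is what edge-list-built graphs
give); `denominator = "group_size"` recomputes it over all tagged pairs.
Isolated ants are excluded from the per-ant tables by default (the
`participants` policy); `all_tagged` assigns them degree 0 and betweenness
0.

### The walktrap implementation

Community counts come from the random-walk agglomerative algorithm
(walktrap) at the published default of 4 steps, with the dendrogram cut at
maximum modularity. The package implements the algorithm itself
(`walktrap_communities()`), as a faithful port of the reference
implementation's semantics rather than an idealised transcription of the
published equations, because three behaviours of the reference code are
observable in its output and would otherwise cause rare disagreements:

1. every vertex carries a self-loop whose weight equals its mean incident
   edge weight (1 on unweighted graphs), making the walk lazy;
2. distances between communities are maintained lazily: after a merge, a
   neighbour adjacent to both merged parts gets the exact Ward update,
   while a neighbour adjacent to only one part gets a cheap placeholder
   (the unavailable distance replaced by the merged pair's own merge cost)
   that is recomputed exactly only if it surfaces at the heap minimum —
   placeholders that overestimate are never revisited, which reorders a
   small fraction of merges relative to an exact greedy;
3. modularity is accumulated community-slot by community-slot, so exact
   rational ties in the modularity profile are broken by floating-point
   summation order; the package reproduces the slot layout and summation
   order so that even these ties resolve identically.

The test suite cross-checks cluster counts against
`igraph::cluster_walktrap` on hundreds of seeded random graphs (including
disconnected graphs and isolates, which each count as their own community)
and on canonical fixtures (two disjoint triangles → 2; K6 → 1; a bridged
K5 barbell → 2). Dense matrix algebra is used throughout — adequate for
colony-scale graphs of tens of nodes, not for large networks.

## Statistical models

Each response is modelled with fixed effects of group size (continuous),
food type (carbohydrate/protein), and food availability
(limited/unlimited). Five candidate fixed-effect structures are compared:
no interaction, each of the three pairwise interactions, and the full
three-way factorial (interactions always carry their marginal main
effects; the three-way candidate is the full factorial). A supplementary
candidate with group size as a second-degree polynomial is available
(`include_poly = TRUE`). Density, cluster count, degree, and total
distance use Gaussian LMMs; betweenness — positive, right-skewed, with
multiplicative covariate effects — uses a gamma GLMM with log link
(Laplace approximation).

Model selection minimises AIC (`2k − 2 logLik`) over candidates fitted by
**maximum likelihood**, because the candidates differ in their fixed
effects and REML likelihoods are not comparable across fixed-effect
structures; the winner is refit under REML for reported coefficients. Ties
break toward fewer parameters, then candidate order, for determinism.
Non-converging candidates are excluded with a warning.

A caution on AIC's behaviour that the package's own simulation studies
make visible (`run_selection_study()`): when the generating structure
contains *no* interaction, plain lowest-AIC selection still prefers some
interaction-bearing candidate in roughly 45% of replicates — each
one-extra-parameter competitor overtakes the truth with probability
P(χ²₁ > 2) ≈ 0.16, and the three-way with P(χ²₄ > 8) ≈ 0.09, which
compounds to a ≈ 0.54 recovery rate regardless of sample size or effect
size. This is the familiar overfitting tendency of AIC, not an
implementation artefact; the selection rule is kept as plain lowest-AIC
because that is the standard procedure this package implements. When an
interaction truly is present at the default effect size, recovery is
around 90%.

Random-effect structure follows the measurement level. Group-level
responses (one row per trial) get a group random intercept — groups are
reused across trials — with mean frame rate as a fixed covariate.
Individual-level responses get random intercepts for group, individual
(individuals are re-tested across trials; `individual_id` is
group-qualified so the same tag in different groups is a different
individual), and frame rate. A continuous rate cannot be a grouping
factor, so rates are binned at 0.1 images/sec (`bin_frame_rate()`,
configurable) — fine enough to track the 0.31–2.92 range, coarse enough
that bins recur across trials.

Inference on the selected model: Type II Wald chi-square analysis of
deviance (each term tested after all others of equal or lower order,
ignoring its own higher-order relatives; delegated to `car::Anova`);
variance explained by the random effects reported as conditional minus
marginal R² from the Nakagawa–Schielzeth variance partition, where the
gamma model's observation-level variance uses the trigamma of the
estimated shape (a log-normal approximation `log(1 + 1/shape)` is
available); and post hoc Tukey contrasts of estimated marginal means
(`emm_contrasts()`), comparing availability within each food type on the
reference grid with Satterthwaite denominator degrees of freedom
(Kenward–Roger available by option; Satterthwaite is the default because
it scales to the data sizes involved and produces the fractional
denominator d.f. conventional in this literature).

Betweenness contains exact zeros (ants on no shortest path), which a gamma
model cannot accept. The default adds a constant 1 before fitting
(`zero_handling = "shift"`), recording the rule on the fit; `"drop"` and
`"error"` are alternatives. The shift changes the intercept's meaning but
preserves ordering and approximate multiplicativity for the bulk of the
distribution.

Wald confidence intervals and z-based coverage are used in the recovery
harness; with 40 groups the group-level denominator degrees of freedom are
large enough that z-intervals cover within the 93–97% band (the harness
checks exactly this).

## The synthetic colony

`simulate_trial()` emulates the study conditions — 14–30 ants, a 90 mm
circular arena at 0.04 mm/px (radius 1125 px), hour-long trials,
piecewise-constant frame rates within 0.31–2.92 images/sec — while making
the planted interaction structure *exactly* recoverable:

* each ant performs a correlated random walk (Gaussian heading increments,
  gamma step lengths at 16 px/s mean speed) confined to a 20 px home
  territory; territories sit on a ring spaced so that non-planted pairs
  can never come within 1.5 × threshold of one another (the configuration
  is rejected as infeasible when the geometry cannot deliver that margin);
* planted pairs perform choreographed excursions, one pair at a time: walk
  radially to the arena centre at 120 px/s, dwell 12 s head-to-head at
  50 px separation — the dwell covers at least two sampling intervals even
  at the slowest admissible frame rate, so at least one frame must capture
  the contact — and return;
* positions are simulated on a 0.1 s tick grid and subsampled at the
  scheduled frame rate; the ground truth records the planted pair set, the
  minimum distance ever attained by any non-planted pair, and each ant's
  full-resolution path length.

What this simulator deliberately does *not* emulate: missed detections,
tag decoding errors, occlusion, wall-following, recruitment, or any
realistic behavioural correlation between treatment and movement.
Treatment labels are assigned to trials but do not influence trajectories.
Consequently, a passing recovery study demonstrates that the inference
chain is *correct* (no false or missed edges given clean detections), not
that it is *robust* to messy tracking data; and pipeline model fits on
trajectory-level simulations estimate null treatment effects. Effect
recovery is exercised instead by the measure-level generator
(`simulate_measures()`), which plants a known fixed/random-effect
structure: defaults of 40 groups tested twice, 20 individuals per group,
group-size covariate uniform on 14–30, β(group size) = 0.5,
β(interaction) = −2, SD(group) = 1, SD(individual) = 0.5,
SD(frame-rate bin) = 0.25, residual SD = 1, and a gamma response with
log-scale group-size slope 0.05 and shape 2. These are the conditions
under which the recovery, selection, and coverage studies are run; the
Wald null-calibration study uses 10 individuals per group (the term under
test varies at the trial level, so its calibration is governed by the
number of groups, and the lighter design keeps 1000 replicates quick).

## Numerical and degenerate-input choices

* Convergence and singularity messages from lme4 are captured, attached to
  the fit, and downgraded to a `converged` flag; level-count checks are
  relaxed so that singleton individuals (measured once) fit cleanly — their
  intercept variance is then inseparable from the residual, which affects
  variance partitioning but not fixed effects.
* Empty detection tables, single-detection trajectories, edgeless graphs,
  and sub-2-node densities return well-defined degenerate values (0) with
  classed warnings where ambiguity exists.
* All randomness flows from explicit integer seeds; `simulate_trial()` is
  bit-reproducible for a given config, and `run_pipeline()` writes MD5
  checksums of every artefact so end-to-end determinism is checkable.
* Angles are stored in [0, 2π) in the image frame (origin top-left, y
  down); head positions use the same frame, so no axis flip is applied
  anywhere.

## Scale of the shipped studies

The packaged validation studies run at: 100 simulated trials (20 trials ×
5 seeds, 7-minute trials) for interaction recovery; 200 random graphs
(n ≤ 12) for the centrality oracle; 53 graphs for walktrap agreement; 500
replicates for parameter recovery and coverage; 200 replicates per truth
for selection consistency; 1000 replicates for Wald calibration. These
sizes put Monte-Carlo error well inside the asserted tolerances while
keeping a full run in the tens of minutes on one core.

## Known limitations

* The proximity proxy cannot distinguish antennation or mandible contact
  from actual food exchange, and directionality of food flow is out of
  scope by construction (edges are undirected).
* Dense-matrix walktrap and per-frame pairwise distance scans are sized
  for groups of tens of ants, not hundreds.
* The gamma GLMM's zero handling is a pragmatic convention; inference near
  the zero boundary is sensitive to the shift constant, which is why the
  choice is recorded on every fit.
* `simulate_trial()`'s guarantees hold in noiseless mode; adding detection
  noise would require re-deriving the separation margins.
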
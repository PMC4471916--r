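---
title: "Methods: song structure, transition networks and provisioning prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: song structure, transition networks and provisioning prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question and the analysis chain

Nightingale males sing large repertoires whose sequential delivery is
neither fixed nor random. The package quantifies two aspects of a male's
nocturnal song — *what* he sings (repertoire composition) and *how he
orders it* (sequencing) — and asks whether these predict his later
provisioning effort at the nest, measured automatically by an RFID antenna
on the nest rim.

The chain is: song sequences → repertoire + network measures → feature
table; RFID registrations → visits → session rates → per-male median
feeding rate (the response); LASSO selection → leave-one-out support-vector
regression → Spearman evaluation.

## Song measures

All repertoire measures are computed on a fixed window of 533 consecutive
songs (roughly one hour of singing), the sample size known to saturate
nightingale repertoire accumulation curves; `accumulation_curve()` lets the
user verify saturation. Category measures count distinct types per category
(whistle / trill / buzz repertoire sizes) and songs per category regardless
of type (occurrences). Types outside the three named categories count
toward total repertoire size but toward no category measure, consistent
with published tables in which category repertoires sum to far less than
total repertoire. Sequences shorter than the window are analysed in full
with a warning and the realised window recorded — field data always met the
window, so no stricter behaviour is warranted.

## Transition networks and orderliness

`build_network()` translates a sequence into a directed graph whose nodes
are song types and whose edges are observed adjacent transitions with
counts. Conventions, each configurable:

* **Self-loops** (immediate repetitions of a type) are dropped by default:
  the orderliness metrics are defined over transitions *between* types, and
  self-loops would contaminate both geodesics and triads.
* **Unweighted metrics**: transition counts are retained for reporting, but
  both metrics use edge presence only, since path length is a hop count.
* **Average shortest path length** is the mean breadth-first geodesic over
  ordered node pairs (u, v), u ≠ v, restricted to pairs where v is
  reachable from u. Directed sparse graphs routinely have unreachable
  pairs; averaging over reachable pairs keeps the metric finite, and the
  reachable fraction is always reported alongside so no information is
  hidden. An edgeless network raises an error rather than returning a
  number.
* **Transitivity** is the global clustering coefficient,
  3·triangles / connected triples, computed on the undirected projection:
  the underlying notion ("are two neighbours of a node themselves
  connected?") is direction-free. A network without connected triples
  raises an error, never a silent 0.

BFS runs in compiled code; correctness is established in the test suite
against an independently written Floyd–Warshall oracle and exhaustive triad
enumeration, with exact (tolerance-zero) agreement required on random
graphs.

## Feeding rates from RFID logs

A single nest approach produces several antenna registrations within a few
seconds. Registrations of one male separated by less than `min_gap` (60 s
by default) are merged into one visit; the threshold sits between the
within-visit registration jitter (≤ 10 s) and typical inter-visit spacing
(minutes at ~11 visits/h). Session rates use a morning window from the
day's first visit until 10:00 (half-open) and an evening window from 18:00
to the day's last visit (closed), the two periods flanking the nocturnal
feeding break; the rate denominator is the realised window length in
hours. Windows of zero duration or without qualifying visits produce no
session rate — a zero would deflate the per-male median on days with
recording gaps. A visit belongs to a window by its start time. The per-male
effort summary is the median session rate; the between- vs within-male
comparison is a one-way fixed-effects ANOVA computed from sums of squares,
whose decomposition (SS_total = SS_between + SS_within) is verified to
1e-9 in tests.

The nestling-age restriction used in the field (days 5–12) is a metadata
filter for the caller, not hard-coded.

## Feature selection and prediction

The feature table holds nine song measures plus brood size and study year
(reference-coded indicators, penalised like any predictor) per male, with
the median feeding rate as response. Predictors are standardised to mean 0
and sample SD 1 (n − 1 denominator, the convention of the penalised
regression tooling this mirrors).

**LASSO.** The package ships its own cyclic coordinate-descent solver for
the ℓ1-penalised least-squares path (soft-threshold updates, Gram-matrix
form, warm starts along 100 log-spaced penalties from λ_max =
max_j |x_j'(y − ȳ)|/n downward, convergence when the largest coefficient
change in a sweep is below 1e-7). Zero coefficients are exact zeros. The
solver is validated in tests against the closed-form orthonormal solution,
OLS at λ = 0, random-perturbation optimality checks, and glmnet on the
identical objective.

The penalty is chosen by 5-fold cross-validation. The default rule is the
*one-standard-error* convention (largest λ within one SE of the minimum
CV error) rather than the CV minimum: the module's purpose is parsimonious
variable selection — the motivating study kept 4 of 11 predictors at
n = 20 — and the CV-minimum rule is known to overselect under weak or null
signal. The minimum rule remains available (`rule = "min"`).

**Support-vector regression.** No libsvm binding is assumed; the ε-SVR
dual (minimise ½β'Kβ − y'β + ε‖β‖₁ subject to Σβ = 0, |β_i| ≤ C) is solved
by exact pairwise coordinate minimisation — an SMO-style sweep whose
sub-problem along each feasible pair direction is a piecewise quadratic
minimised exactly over its kinks, stationary points and box ends. Defaults
are the historical defaults of the classical tooling: RBF kernel, C = 1,
γ = 1/p, ε = 0.1. KKT satisfaction (well below the 1e-3 contract) is
asserted in tests.

**Leave-one-out protocol.** Each male is predicted by a model trained on
the other n − 1, with standardisation refit inside every round so nothing
about the held-out male reaches training — verified by a leakage probe
(perturbing the held-out response must not change its prediction). Feature
selection is performed once on the full table and the reduced predictor set
(selected song measures plus brood size) is then used in every round,
matching the motivating study's procedure; re-running selection inside each
round is available via `reselect = TRUE` for a fully nested protocol.

**Evaluation.** Spearman's ρ is the Pearson correlation of midranks; the
two-sided p uses the t approximation on n − 2 degrees of freedom, adequate
at n ≈ 20. An exact permutation p is enumerated for n ≤ 8 (8! = 40320
permutations; exhaustive enumeration beyond that has no practical value
here).

## The synthetic world

`simulate_study()` generates complete studies with known ground truth. Each
male carries a standard-normal latent quality q. Choices and their
rationale:

* **Repertoire and category sizes** are rounded Gaussians at the published
  population moments (181 ± 35; whistle 28 ± 5; trill 20 ± 4; buzz
  5 ± 1.65 — the buzz SD back-computed from its published CV of 0.33, since
  the printed "± 1" is inconsistent with that CV; the rounded value is
  selectable). Each loads on q with correlation 0.6, a moderate latent
  loading that leaves realistic idiosyncratic scatter.
* **Orderliness** p = logistic(b0 + b1·q) with b0 = −0.6, b1 = 0.7. The
  sequence generator follows each type's fixed canonical successor (a
  random but fixed cyclic permutation of the repertoire) with probability
  p, otherwise jumps uniformly to another type. This interpolates
  continuously between a pure song cycle (p = 1: maximal linear chains,
  average shortest path = R/2) and a uniform walk (p = 0: dense network,
  path length near 1–2), directly exercising the claim that path length is
  sensitive to long linear transitions. b0/b1 were fixed by matching the
  realised average-shortest-path distribution at field repertoire sizes to
  the published 4.66 ± 0.84 (p centred near 0.35).
* **Visit intensity** λ = exp(c0 + c1·q + c2·log(hatchlings)) visits/h,
  log-linear so brood size has a recoverable positive elasticity. With
  c2 = 0.5 fixed, c0 = 2.05 and c1 = 0.45 were calibrated once (600
  simulated males run through the actual feeding module) so that *realised*
  median rates — after the ~17% of Poisson visit starts lost to < 60 s
  registration merging — match the published 11.4 ± 3.8 visits/h within
  15%. Visits are a homogeneous Poisson process within a 05:00–10:00
  morning and an 18:00–21:30 evening activity window over 6 recording
  days; each visit emits 1–3 registrations within 10 s at 1-second logger
  resolution.

What a green test does establish: the pipeline recovers planted monotone
structure (quality → orderliness → feeding) at the study's n = 20, the
selection stage finds strong planted effects and stays quiet under noise,
and every numeric stage agrees with independent oracles. What it does not
establish: acoustic realism, within-night non-stationarity, realistic
transition *clustering* (see below), female behaviour, or that the
published field coefficients are recoverable — the field data are not
public and the printed LASSO/SVM coefficients serve only as qualitative
ordering references.

## Known limitations

* **Transitivity's sign is emergent and negative.** The canonical-successor
  mechanism produces few triangles for orderly males, so transitivity
  correlates *negatively* with quality (Spearman ≈ −0.7) in the synthetic
  world, whereas real nightingale song yields transitivity ≈ 0.18 with
  positive quality associations. Sign-recovery properties are therefore
  asserted over the four planted-link measures (average shortest path and
  the three category repertoire sizes — exactly the four the field study
  selected), and LASSO's occasional negative transitivity coefficient is
  correct recovery of this world, not an error.
* **The leave-one-out null is not centred at zero.** Under a permuted
  response, the prediction for male i gravitates to the training mean
  excluding i, which is a strictly decreasing function of the held-out
  value; at n = 20 this biases the null Spearman ρ to about −0.25 (a pure
  training-mean predictor attains exactly −1). One acceptance expectation
  asserts a ±0.15 zero-centring band fixed before measurement and is
  deliberately left failing rather than widened; the bias is conservative
  with respect to positive findings.
* Realised repertoire sizes run a few percent below the configured truth
  because a 533-song walk does not visit every type (coupon-collector
  coverage); this is within the tolerance of all moment checks and mirrors
  the field situation, where the window is chosen to make the shortfall
  small.
* Configuration files are JSON only; no YAML parser is assumed.
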
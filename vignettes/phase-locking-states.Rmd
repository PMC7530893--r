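---
title: "Detecting recurrent BOLD phase-locking states: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent BOLD phase-locking states: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plstates)
```

## The model

`plstates` characterizes resting-state functional connectivity (FC) two
ways. The *dynamic arm* treats FC as a sequence of phase-locking
configurations: each region's band-limited BOLD signal is reduced to an
instantaneous phase θ(n, t) by the analytic (Hilbert) signal, each frame
yields the matrix dPL(n, p, t) = cos(θ(n, t) − θ(p, t)), and each matrix is
summarized by its leading eigenvector V1(t). Because
cos(a − b) = cos a cos b + sin a sin b, dPL(t) is exactly
C Cᵀ + S Sᵀ with C = cos θ(·, t), S = sin θ(·, t): a rank-≤2 matrix whose
eigenvectors lie in span{C, S}. V1(t)'s element signs split the regions
into two phase communities; V and −V are the same descriptor, so a sign
convention (majority of elements negative) makes the positive minority —
the set of regions phase-shifted away from the bulk — the frame's
subsystem. K-means over all subjects' eigenvectors yields recurrent PL
states; per-subject occupancy (%), lifetime (s) and transition
probabilities are compared between groups by stratified permutation tests
with per-model FDR. The *static arm* is the conventional complement:
full-scan Pearson FC, an edgewise group contrast with a nuisance covariate,
and the network-based statistic (NBS) for family-wise error control over
suprathreshold connected components.

Assumptions worth stating: phases are meaningful only for band-limited
signals (hence the mandatory band-pass); the k-means states are a
descriptive partition, not a generative claim (no attempt is made to choose
an "optimal" k — instead, findings must be consistent across partition
models); and the permutation tests assume exchangeability of subjects
within strata under the null.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `low_hz`, `high_hz` | 0.01, 0.1 | Hz | conventional resting-state BOLD band: removes scanner drift below and cardiac/respiratory components above |
| `order` | 9 | poles | steep transition while numerically safe in cascade form |
| `n_trim` | 1 | frames/end | the analytic signal is least reliable at the recording boundaries; 150 volumes → 148 retained frames |
| `k_min`–`k_max` | 4–14 | — | the conventional sweep: 11 partition models from coarse to fine |
| `metric` | cosine | — | eigenvectors are unit-norm directions; assignment by directional similarity (spherical k-means). Euclidean available by flag |
| `n_init`, `max_iter` | 50, 500 | — | restarts make the sweep stable under reseeding; the objective is monitored and the best restart kept |
| `min_similarity` | 0.8 | Pearson r | cross-k linking of variant forms of one state |
| `n_perm` | 10,000 | — | permutation resolution ~1e-4; the add-one estimator keeps p > 0 |
| `strata` | gender | — | restricted permutations absorb a gender imbalance between groups |
| `alpha` | 0.05 | — | FDR level per model and metric family |
| `min_models` | 3 | models | a family significant in fewer models is not reported as robust (a finding seen in only 2 of 11 models is dismissed) |
| score cutoff | 20 | points | the conventional depression-inventory threshold; scores strictly above are "high" |
| NBS `thresholds` | 3.1, 3.5, 4 | t | no principled single threshold exists; the sweep shows how the component contracts to its strongest edges |
| `rotation_radius_mm` | 50 | mm | standard head-radius convention converting rotations to displacement |

The headline partition model is the k with the most FDR-significant
(state, metric) pairs, ties broken toward smaller k — an automated version
of "the model that captured the most significant changes".

## The synthetic generator

The generator emulates the statistical structure of a two-group
resting-state study: 223 regions, 150 volumes at TR = 2 s, a 19-vs-50
split, women/men 16/3 vs 21/29, and group differences in state expression
(defaults mirror one state at 16.1% vs 9.8% occupancy and another at 6.2%
vs 10.6%).

Hidden dynamics: each subject carries a Markov state sequence. The chain
leaves state s with probability (1 − π_s)/d and jumps proportionally to the
target profile π, which makes π *exactly* stationary for any profile and
any dwell scale d (default 3 frames), with geometric per-state dwell of
mean d/(1 − π_s) — more-occupied states also persist longer, as observed
dwell times do. A per-state dwell vector is also accepted; the chain is
then built with exit rate 1/d_s and occupancy-proportional jumps, and its
exact stationary law (computed by eigendecomposition and reported in the
ground truth) only approximates the requested profile, because stationary
occupancy and per-state dwell cannot be fixed independently in a Markov
chain.

Signals: all regions track a common carrier (default 0.05 Hz, inside the
analysis band) through a mean-reverting AR(1) phase deviation (stationary
SD 1.0 rad, lag-one 0.9), so the background is broadly coherent the way
BOLD signals are; the active state's community swings anti-phase to the
carrier (± Gaussian jitter, SD 0.3 rad), making it the minority community
that the eigenvector's positive elements pick out. The observed signal is
cos(phase) plus Gaussian noise (SD 0.2). An earlier design with fully
incoherent (Brownian-phase) background regions was abandoned: with a
random-sign background the planted community joins the majority sign
community, contradicting the intended "planted set = smallest community"
structure and real PL-state geometry.

What the generator does **not** emulate: hemodynamic-response convolution,
spatially correlated noise, scanner artifacts, subject-specific
parcellation error, or realistic network topology (the bundled 223-row
region table is labelled synthetic; its network assignments are random).
Passing tests therefore demonstrate the pipeline's correctness and
calibration on signals with the right phase geometry — not performance on
real fMRI.

Gender is a pure nuisance label by default; an optional
`gender_occupancy_shift` plants a gender effect to verify that the
stratified test does not mistake it for a group effect.

## Numerical choices

- **Filter in second-order sections.** The order-9 Butterworth band-pass is
  designed from the analog prototype (pole pairing, bilinear transform with
  per-section gain normalization at the band center). A direct-form
  order-18 transfer function at these normalized frequencies has poles
  outside the unit circle for sampling intervals below about 2 s — the
  cascade form is stable throughout. Application is zero-phase
  (forward–backward with odd-reflection padding): the whole analysis is
  phase-based, and a causal pass would inject frequency-dependent phase
  lags. `causal = TRUE` restores a single pass for sensitivity analyses.
- **Rank-2 eigenvector path.** Per frame, the eigenproblem is projected
  onto span{cos θ, sin θ} and the 2×2 problem solved in closed form — O(N)
  per frame rather than O(N³) — with the dense symmetric solver retained in
  `leading_eigenvector()` and pinned to the fast path by tests at 1e-8.
- **Sign convention ties.** With equal positive and negative counts, the
  vector is flipped so its largest-magnitude element is negative:
  deterministic and basis-independent. The convention is idempotent.
- **Degenerate inputs.** Constant regions are rejected before the Hilbert
  transform (phase undefined); a centroid with no positive element (global
  mode) legally yields an empty smallest community; lifetime of a
  never-visited state is missing, not zero — absence is not brevity — and
  such subjects drop out of that state's lifetime test; transition-matrix
  rows with no outgoing transitions are missing, not zero-filled.
- **Permutation p values** use the add-one estimator (1 + #{|t*| ≥ |t|}) /
  (1 + n_perm). The NBS permutation loop scores null maxima with a
  union-find rather than building graph objects; observed components come
  from igraph and the two routes are cross-checked in tests.
- **Boundary runs** (state visits touching the first or last retained
  frame) count toward lifetime as observed. No censoring rule is imposed;
  any truncation bias is identical in both groups.

## Open design decisions, resolved

- *Causal or zero-phase filtering?* Zero-phase (above).
- *Does the transition matrix include the diagonal?* Both variants are
  computed; the default keeps self-transitions, which dominate the
  diagonal of empirical switching matrices; between-group transition tests
  run per cell at uncorrected p < 0.05.
- *FDR family.* All k states of one metric within one partition model;
  occupancy and lifetime are adjusted as separate families. Models are
  adjusted separately because their hypotheses are not independent.
- *Effect size.* Pooled-SD standardized difference **without** the
  small-sample correction: recomputing from the studied sample's printed
  summaries reproduces all four reported values (0.77, 0.74, 0.67, 0.63)
  only in the uncorrected form. The corrected variant is a flag.
- *Gender in the NBS.* Entered as a GLM covariate (columns held fixed
  while group labels are permuted); a Freedman–Lane scheme would be a
  refinement, not implemented.
- *Fisher z before the edgewise GLM?* Off by default (raw correlations);
  available by transforming the input matrices.
- *Community overlap vectors.* Reference-network overlap uses binary
  community indicators (scale-free); a magnitude-weighted variant is a
  flag.

## Experiment scales used by the test suite

The suite validates calibration and recovery at sizes chosen to make the
Monte-Carlo error explicit and the experiments quick to reproduce: type-I
calibration of the stratified test on 200 null cohorts (19-vs-50, p < α
counted against α + 2·SE); NBS FWER on 100 null 15-region cohorts at 300
permutations; planted-state recovery on 12-subject, 40-region cohorts; and
the end-to-end experiment on five 69-subject cohorts with a 3-state ground
truth at k = 3, 1,000 permutations each. Zero-noise recovery experiments
use a dwell scale of 12 frames: phase estimation smooths over state
switches, so roughly one frame per switch is intrinsically ambiguous and
label agreement is evaluated where dwell, not estimator bandwidth, is the
limiting factor. For the end-to-end experiment the generative occupancy
difference is 9.5 points: switch-boundary label noise attenuates planted
effects by roughly a quarter, so the *recovered* occupancy difference sits
at the intended ~0.75 standardized-effect scale (between-subject occupancy
SD ≈ 8.5 points, comparable to the studied sample's printed SDs).

## Known limitations

- Frames within ~1 frame of a state switch are intrinsically ambiguous;
  short-dwell dynamics are harder to label than long-dwell dynamics, and
  lifetime estimates inherit this blurring.
- The pipeline starts from region×time matrices: image preprocessing,
  parcellation and nuisance regression are upstream of this package.
- Cosine k-means is a local optimizer; restarts mitigate but do not
  eliminate dependence on initialization (seeds are recorded everywhere).
- The NBS component score is extent (edge count); intensity scoring is out
  of scope.
- With `k_max` far above the true number of configurations, variant forms
  fragment; the cross-k families are the intended unit of interpretation,
  not individual (k, state) pairs.
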
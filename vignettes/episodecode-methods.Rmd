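---
title: "Methods: simulating and decoding episodic place coding on a figure-eight maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding episodic place coding on a figure-eight maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and what the package computes

A rat runs laps on a figure-eight maze (100 cm x 140 cm footprint, 20 cm
path width) whose middle arm -- the central stem -- is traversed
identically on every lap. Three subtasks share the maze: a visually guided
discrimination (VD; a lit cue at the decision point indicates the rewarded
turn), spatial alternation (SA; the correct turn is the side opposite the
previous lap) and delayed alternation (DA; like SA, with a 5-s barrier
delay imposed 20 cm before the stem entrance). A lap's *journey* is its
(origin, destination) pair; VD admits all four journeys while SA and DA
admit only the two cross journeys, giving eight *trial types*
(VD1--VD4, SA1, SA2, DA1, DA2). A session runs the blocks
VD(20), SA(20), VD(10), DA(20), VD(20), SA(20), VD(10), DA(20) --
140 laps.

The package provides, as testable units:

* a synthetic session generator (schedule, 60 Hz tracking, ground-truth
  place-cell tuning, inhomogeneous-Poisson spikes) with configurable
  *global remapping* between journeys and *rate remapping* between
  task-demands;
* behavioral preprocessing: lap segmentation, path linearization at
  ~0.35 cm pitch, turn-onset detection, immobility filtering;
* place-field analysis: occupancy-normalized kernel rate maps, spatial
  information, unit and place-cell selection, spatial (`r_s`) and rate
  (`r_r`) similarity, an ANCOVA screen for differential firing;
* ensemble analysis: state-space trajectories, distance-to-mean-template
  classification with leave-one-out cross-validation (LOOCV), label-shuffle
  nulls, cross-subtask journey generalization, cell-count curves, a binary
  classification suite and PCA visualization;
* statistics: exact binomial tests against chance, Wilcoxon rank-sum with
  tie-corrected normal approximation, Kruskal-Wallis with a rank-based
  Tukey HSD post hoc.

# The synthetic generator: what it emulates

The generator defines the study conditions; its defaults are fixed, not
fitted.

**Schedule.** Blocks as above; VD cue sides are uniform draws; SA/DA
correct choices alternate relative to the previous lap's destination. Each
lap errs with probability `errorRate` (default 0.01, matching the near-
ceiling performance the task produces in trained animals); error laps are
flagged and excluded from every analysis. An SA/DA error can produce a
same-side journey that corresponds to no admissible trial type; its trial
type is NA.

**Tracking.** A virtual rat traverses the lap's idealized path (polylines
with 1-cm vertices; the central-stem vertices are byte-identical across
journeys so stem comparisons are exact) at a per-lap speed drawn from
N(30, 3) cm/s, with Ornstein-Uhlenbeck lateral jitter (stationary SD
1.5 cm, time constant 0.5 s) and Gaussian head-direction noise (SD 5
degrees) around the path tangent, sampled at 60 Hz. DA laps hold the rat
at the delay barrier for 5 s with 0.01 cm positional jitter, so delay
epochs fall below any sensible immobility threshold.

**Tuning.** Each tuned cell has one isotropic Gaussian field per journey
(SD 8 cm; peak drawn uniformly from 5--25 Hz; 0.1 Hz uniform background).
Under `journeyMode = "global"` the four field centers are independent
draws along each journey's path -- fields relocate between journeys.
Under `demandMode = "rate"` the field location is shared across subtasks
within a journey and only the rate is scaled per subtask (defaults VD = 1,
SA = 0.5, DA = 0.75; the three demands must differ for the 8-way decoding
problem to be well-posed, and 0.5 is the canonical "halved rate"
condition used throughout the tests). An optional prospective gain
multiplies a cell's stem-region rate by (1 +/- g) depending on the lap's
destination, with the sign drawn per cell; this injects destination
information strictly before the turn and is off by default.

**Spikes.** Thinning of a homogeneous Poisson process at the per-cell
rate maximum, with the rate evaluated piecewise-constant per tracking
sample. Every stochastic stage takes a seed derived from the session's
master seed by a fixed affine map, so a session is a pure function of its
seed.

**What the generator does not emulate.** No theta rhythm or phase
precession, no bursting or refractoriness, no multi-field irregular place
fields, no electrode drift or sorting errors, no learning across the
session. Passing tests therefore show that the *analysis* recovers the
coding structure it was given under realistic sampling noise -- not that
real hippocampal data contain that structure.

# Behavioral preprocessing

**Lap segmentation** places boundaries at reward-zone entries; the samples
between consecutive entries form one lap.

**Linearization** projects each tracking sample onto the journey's
idealized path. Because journeys that start and end at the same reward
zone make the path a closed loop, the globally nearest point is ambiguous
near the shared endpoint; projection therefore proceeds monotonically,
restricting each sample's projection to within +/-5 cm of arc length of
the previous sample's (the first sample prefers the smallest arc among
near-minimal-distance candidates). Samples more than 5 cm off the path
are excluded. Bins are half-open intervals at pitch `pathLength / round
(pathLength / 0.35)` cm; occupancy is apportioned by interpolating
cumulative time against (monotonicized) arc length, so all traversed bins
receive time even though consecutive 60 Hz samples are ~0.5 cm apart.
Per-bin speed is bin length over traversal time -- the definition used as
the ANCOVA covariate -- and head direction and signed lateral offset
(positive to the rat's right of travel) are interpolated at bin centers.

**Turn onset** is the last sample in the central stem or upper junction
whose head angular velocity (central difference of the unwrapped heading,
boxcar-smoothed over 5 samples, ~83 ms; the smoothing window is
configurable since the threshold's reference frame is a design choice) is
below 0.12 rev/s.

**Immobility filtering** removes spikes whose nearest tracking sample
moves slower than 5 cm/s (configurable); this excises delay-period and
reward-zone spiking. Occupancy is deliberately left unfiltered -- only
spikes are removed -- so rate maps show low rates, not holes, at waiting
locations; none of the comparison regions include those locations.

# Place-field analysis

**Rate maps** use the kernel-ratio estimator on a 5 cm x 5 cm grid: the
rate at a bin center x is the sum of Gaussian kernel weights (width
h = 5 cm) over spike positions divided by the kernel-weighted occupancy
time, f(x) = sum_i w((s_i - x)/h) / integral w((y(t) - x)/h) dt. Bins
farther than 5 cm from any tracked position are unvisited and carry no
rate (rendered distinctly in figures). The estimator conserves mass: rate
times raw occupancy summed over bins recovers the spike count to within a
few percent on smooth trajectories (asserted in the tests).

**Spatial information** is SI = sum_i P_i (R_i/R) log2(R_i/R) bits/spike
over visited bins, with P_i the occupancy probability, R_i the bin rate,
R the occupancy-weighted mean rate, and 0 log 0 = 0. It is undefined (an
error) for silent cells and invariant to rate rescaling. Place cells are
units whose SI exceeds 1.0 bits/spike in at least one trial type. The
plug-in SI estimator is biased upward on short recordings; the package's
discrimination between tuned and untuned units is validated at the full
140-lap session length, and shorter sessions should not be used for
SI-based selection.

**Unit selection** follows width/rate criteria: units below 0.1 Hz are
excluded; wide spikes (>= 0.4 ms) with rates <= 5 Hz are putative
pyramidal cells; the rest are putative fast-spiking interneurons. Only
pyramidal units enter the analyses.

**Similarity.** For a pair of conditions, spatial similarity `r_s` is the
Spearman rank correlation of the two rate maps over jointly visited
central-stem bins (Pearson available; rank correlation is the default
because it makes `r_s` exactly invariant to the rate rescaling that
`r_r` is designed to detect). Rate similarity is
`r_r = 1 - |a - b| / (a + b)` on the occupancy-weighted mean in-ROI rates
(peak-rate users can pass those instead); it ranges from an asymptotic
floor of 0 (one silent condition) to 1. Comparison classes: *within-type*
(first vs second half of a trial type's laps -- repeated exposures),
*cross-journey* (different journeys within a subtask) and *cross-demand*
(different subtasks within a journey). A (cell, pair) entry is valid only
when the cell's ROI mean rate reaches 0.5 Hz in both conditions: rank
correlations between near-silent maps measure sampling noise, not
remapping, and the comparison is meaningful only for cells that actually
fire on the common stem. Under the default remapping structure this
yields the dissociation pattern the pipeline is designed to detect:
within-type and cross-demand `r_s` high and similar, cross-journey `r_s`
near zero, and cross-demand `r_r` clearly below within-type `r_r`.

**ANCOVA screen.** For each cell, firing rate per stem bin per lap
(spike count over traversal time, Gaussian-smoothed with SD 5 cm along
the stem) is regressed on the condition factor plus running speed, head
direction (degrees, entered linearly; a circular alternative would only
matter if stem headings spanned a large arc, which they do not) and
lateral position; the screen reports the F test of the condition factor
after covariate adjustment. Observations are per-bin-per-lap. Two caveats
are deliberate: (i) adjacent smoothed bins are strongly autocorrelated,
so on real pipeline data the nominal p-values are anticonservative -- the
screen is a *screen*, not a calibrated test, and its type-I calibration
is asserted on independent observations; (ii) `binStride` thins the stem
bins (default every 4th in the orchestrated pipeline) to reduce both the
autocorrelation and the cost.

# Ensemble trajectory analysis

Each lap's trajectory is the m x n matrix of per-bin spike counts
(m ~ 914 bins at 0.35 cm over the 320-cm lap path, n cells) convolved
along the path with a Gaussian of SD 5 cm whose kernel sums to one, so
smoothing preserves spike counts. No normalization or z-scoring is
applied to the smoothed counts (an option exists for exploration but is
off: raw convolved counts are the defined state).

**Classification.** At each central-stem bin (arc 50--150 cm, identical
across journeys), the Euclidean distance across cells is computed from
the test lap to each candidate label's mean trajectory, the mean being
recomputed with the test lap excluded (exact LOOCV, not leave-one-out
algebra -- clarity over speed; the fast path below is verified against
it). The bin takes the nearest template's label, with exact distance ties
broken toward the lexicographically first label; the lap takes the most
frequent bin label over the ROI, with majority ties marked and counted
incorrect. Per-location accuracy is the fraction of laps correct at that
bin, tested one-sided against chance with the exact binomial tail.
Labels with fewer than two laps are excluded with a warning.

**Shuffle nulls.** The control randomizes the assignment of labels to
laps 1000 times and reruns the *entire* classification -- templates are
rebuilt from the permuted groups. Because squared distances to group
means depend on the data only through lap-by-lap dot products at each
bin, the per-bin Gram matrices are computed once and each permutation
costs two small matrix products; a test asserts bit-level equality
between this engine (identity permutation) and the direct classifier.
Under shuffling, lap-level accuracy concentrates at the guessing level
(1/8 for trial types, 1/2 for binary contrasts) with approximately
binomial spread.

**Generalization.** Mean right-to-left and left-to-right journey
templates are computed in one reference subtask (no LOOCV; reference and
target laps are disjoint) and every cross-journey lap of the other
subtasks is classified by the nearer template with the stem majority
vote. When reference equals target the analysis degenerates to LOOCV
journey classification, preserving continuity. Shuffles permute journey
labels jointly over reference and target laps. The cell-count curve
redraws random cell subsets (default 1000 per size) and reuses the
full-roster templates column-subset, which is exact because templates are
per-cell means.

**Binary suite.** Three categories, all LOOCV with stem majority vote:
the journey pairing pools laps of VD1, SA1, DA1 against VD3, SA2, DA2;
task-demand pairs pool each subtask's laps irrespective of journey (their
templates therefore mix journeys, and accuracy is expectedly lower than
for journey or trial-type contrasts while remaining far above chance);
and all 28 trial-type pairs. The per-comparison accuracies feed the
Kruskal-Wallis utility.

**PCA** is fit on the pooled bin states and used only for visualization;
classification always operates in the full cell space.

# Numerical choices and degenerate inputs

* Distance ties at a bin: deterministic, lexicographically first label;
  tie counts are reported.
* Lap-level majority ties: lap marked incorrect and its prediction NA.
* Similarity undefined (fewer than 3 joint bins, zero variance, both
  rates zero, either rate below the validity floor): NA with a warning,
  excluded from medians.
* Spatial information for a silent map, empty tracking, zero occupancy,
  rank-deficient ANCOVA designs, roster/schedule mismatches: errors with
  stage-specific messages.
* Seeds: a master seed determines every stage through fixed offsets;
  identical configuration and seed reproduce bundles byte-identically.

# Problem sizes

The test suite and the acceptance script run the full 140-lap schedule
with 50-cell ensembles (the study conditions), a 128-cell session for the
generalization analyses, 60-lap VD-only sessions for the prospective-
coding property, and 1000-replicate simulations for test calibration;
1000 label shuffles are used wherever a null distribution is reported.
These sizes were chosen as the smallest that leave the stochastic
acceptance margins comfortably wide.

# Known limitations

* The ANCOVA on real per-bin observations is anticonservative (see
  above); calibration holds for independent observations.
* The SI place-cell threshold is calibrated for full-length sessions.
* The generator's single-Gaussian fields make trial types more linearly
  separable than irregular real fields would be; chance recovery and
  null calibration are unaffected, but absolute accuracies on synthetic
  data should not be read as predictions for real ensembles.
* Head direction enters the ANCOVA linearly, in degrees.
* No LFP, replay, phase coding or Bayesian decoding: out of scope.
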
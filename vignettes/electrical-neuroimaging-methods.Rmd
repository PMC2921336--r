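---
title: "Electrical neuroimaging of event-related EEG: models, parameters, and design choices"
author: "eegmicrostates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrical neuroimaging of event-related EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements: the
models and their assumptions, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was genuinely
open.

## The analysis in one paragraph

High-density event-related EEG is analyzed in two stages. The *first level*
turns each subject's single-trial epochs into one visual evoked potential
(VEP) per condition: epochs whose absolute amplitude exceeds 100 µV anywhere
are rejected, corrupted channels can be repaired by spherical-spline
interpolation, survivors are averaged, baseline-corrected over −100..0 ms,
band-limited to the 1–30 Hz VEP band, re-referenced to the average reference,
and normalized to unit mean global field power (GFP). The *second level* is
reference-free topographic analysis: the group-averaged VEPs of all
conditions are segmented jointly into *microstates* — periods of quasi-stable
scalp topography — by agglomerative clustering of the instantaneous maps; a
modified Krzanowski–Lai (KL) criterion picks the number of template maps;
each template's per-condition time window follows from best-correlation
labeling. The templates are then *back-fitted* to every subject's VEPs to
obtain per-subject microstate durations, compared across conditions with a
repeated-measures ANOVA. Finally, each microstate's generators are estimated
with a LORETA-style distributed inverse on a gridded spherical head model,
and consecutive microstates are contrasted point-wise with paired t-tests
under a cluster-extent rule (t(19) ≥ 2.09, clusters strictly larger than 10
contiguous solution points).

## Global field power, spatial correlation, GEV

For an average-referenced map $u \in \mathbb{R}^{C}$ at one time sample,

$$\mathrm{GFP}(u) = \sqrt{\tfrac1C \sum_c u_c^2},$$

the spatial RMS (equivalently the spatial standard deviation). Topographic
similarity is the *strength-independent spatial correlation*: the Pearson
correlation of two maps across channels, invariant to positive rescaling and
*sign-sensitive* — this is evoked-potential convention, where a map and its
polarity reversal reflect different generator configurations. A model with
templates $T_1..T_K$ and per-sample assignment $a(t)$ explains

$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \cdot
\mathrm{corr}(u_t, T_{a(t)})\big)^2}{\sum_t \mathrm{GFP}_t^2},$$

summed over all conditions' samples in the 0–500 ms analysis window.

## Clustering: atomize and agglomerate

Every time sample of every condition's group VEP starts as a singleton
cluster. At each step the algorithm dissolves the cluster *contributing
least to global explained variance in the net sense*: its members' explained
variance minus what the remaining best-correlated clusters would recover
after reassignment. This matters: a cluster that merely duplicates another
(a split state) costs nothing to dissolve and goes first, while a small but
genuinely distinct cluster — a short microstate — is protected by the
explained variance that would be lost. Reassignment is by highest signed
correlation (ties to the lower index; anticorrelated alternatives count as
explaining nothing, keeping the procedure polarity-sensitive). Cluster
templates are the first principal pattern (leading left singular vector) of
the member maps, sign-aligned with the member mean — this weights
high-amplitude members more than a plain mean of normalized maps would,
which is the behavior wanted when amplitude tracks signal-to-noise. One
sweep from $N$ singletons down to 2 yields the nested family of candidate
models for every $k$.

All samples in 0–500 ms enter the clustering, not only GFP peaks; both
approaches exist in the field, and clustering everything makes the
assignment (and GEV) well-defined at every sample without interpolation.

## Choosing k: the modified Krzanowski–Lai criterion

With $W(k)$ the within-cluster dispersion of the unit-normalized maps
(sum of squared distances to cluster mean maps) and $q$ the number of
channels,

$$\mathrm{DIFF}(k) = (k-1)^{2/q}\,W(k-1) - k^{2/q}\,W(k), \qquad
\mathrm{KL}(k) = \frac{\mathrm{DIFF}(k)}{\max\{|\mathrm{DIFF}(k+1)|,\;
0.01\,W(1)\}}$$

scored only at *convex decreases* ($\mathrm{DIFF}(k) > 0$ and
$\mathrm{DIFF}(k+1) < \mathrm{DIFF}(k)$), with the largest score winning and
ties going to the smaller $k$. Two departures from the textbook ratio are
deliberate. First, the convexity restriction discards spurious candidates on
concave stretches of the dispersion curve. Second, the denominator floor —
one percent of the total dispersion $W(1)$ — addresses the ratio's known
instability: deep in the noise floor both DIFF terms are tiny, and their
quotient can exceed the true elbow's score by orders of magnitude. With the
floor, a candidate can only win on the strength of its *numerator*, i.e. an
actual drop in dispersion. The exact "modification" used by the original
analysis software is not published; this variant is validated by
planted-model recovery (simulations with known $k \in \{3,5,7\}$ recover the
plant in ≥ 95% of seeded runs at realistic noise — see
`tests/testthat/test-acceptance.R`).

## Windows, back-fitting, durations

Per condition, each sample is labeled by its best-correlated template; runs
shorter than 10 ms (5 samples at 500 Hz) are merged into the neighboring run
whose template fits the short run better. Ten milliseconds is below any
microstate duration the segmentation literature treats as meaningful and
suppresses single-sample flicker. Back-fitting labels each *subject's* VEP
samples the same way within a fit window — by default the microstate's
group-level window, matching per-state duration comparisons; the full
0–500 ms range is available via the window argument. Durations are label
counts times the 2-ms sampling period, so each subject/condition's durations
sum exactly to the window length. Labeling is exclusive per sample but not
across comparisons; aggregating per state gives the duration table.

The duration test is the classical univariate repeated-measures ANOVA with
subject as the blocking factor: $F = MS_\text{condition} /
MS_{\text{condition}\times\text{subject}}$ with df $(c-1, (c-1)(n-1))$ and
no sphericity correction — plain $F(2,38)$-style statistics at $n=20$, $c=3$.
Sums of squares come from `stats::aov`; an independent closed-form
decomposition serves as the test oracle.

## Forward model

The head is three concentric spheres — brain, skull, scalp — with radii
80/85/92 mm and conductivities 0.33/0.0042/0.33 S/m, the classical values
with skull ≈ 80× less conductive than soft tissue. The choice of an analytic
sphere over a realistic boundary-element model is deliberate: the spherical
forward problem has a closed form (for equal conductivities) and a rapidly
convergent Legendre series (for distinct ones), so the implementation is
testable to a fraction of a percent, which no mesh-based substitute allows.
Potentials for a dipole at radius $b$ are the degree-$n$ series with
per-degree transfer factors obtained by solving the 5×5 interface-matching
system (continuity of potential and radial current at both interfaces, zero
current at the scalp); 60 terms are ample at $b/R \le 0.87$ (the term ratio
is $(b/R)^n$). The equal-conductivity case reproduces the homogeneous-sphere
closed form to ~10⁻⁵ % — far inside the 0.1 % the package commits to.

Electrodes are a deterministic Fibonacci lattice over the upper 65 % of the
scalp sphere area (about what a 128-channel geodesic net covers), with
labels `E001..E128`; `.sfp` and `.elc` readers/writers are provided. The
source space is a cubic lattice (6 mm default) clipped half a step inside
the brain shell, with face-neighbor (6-connected) adjacency — "contiguous"
in the cluster rule means face-adjacent. At 6 mm inside an 80-mm brain
sphere this yields 8829 solution points; the count is reported in run
metadata rather than forced to any particular value, because it is a
property of the head model. Coordinates are right-handed, origin at the
sphere center, +z through the vertex, in mm; no atlas transform is applied
or implied.

## Inverse model

The inverse is a weighted minimum-norm estimate with a spatial-smoothness
prior: minimize $\|v - GJ\|^2 + \lambda\, \|L W J\|^2$-type penalties, where
$L$ is the discrete 6-connected Laplacian (mirrored/Neumann stencil at the
boundary) normalized by its mean diagonal plus a ridge of 0.1, and $W$ holds
per-point depth weights (the gain column-block norms, exponent 1 by
default). The ridge is required — the Neumann Laplacian annihilates constant
fields — and 10 % of the penalty's scale also keeps the resolution
covariance below well-conditioned. The regularization $\lambda$ is chosen
per datum by generalized cross-validation over the eigenspectrum of the
data-space kernel $G C G'$, overridable with a fixed value.

Raw current magnitudes from any minimum-norm family estimator are biased
outward: in this spherical geometry the global maximum for a mid-depth
dipole lands on the outermost grid shell, ~29 mm from the truth, regardless
of depth exponent or smoothness weight. The package therefore reports
*variance-standardized* density by default: each point's current 3-vector is
whitened by its own resolution covariance $S_i = M_i K M_i'$ (the
standardized low-resolution estimator family), which localizes noiseless
single dipoles exactly and keeps median errors within two grid steps under
noise. Raw magnitudes (proportional to µA/mm³) remain available
(`standardize = FALSE`); spatial-spread properties (spread grows
monotonically with $\lambda$) are asserted on the raw estimate. Absolute
units are arbitrary either way; only relative comparisons are meaningful,
which is all the downstream statistics use.

The statistical rule for contrasts is implemented exactly as stated
numerically: per-point paired t over subjects, threshold $t_{19} \ge 2.09$
($p \le .05$ uncorrected), and maximal 6-connected components *strictly
larger* than 10 points, run in both directions. A Bonferroni mode (per-point
$\alpha$ divided by the number of solution points, two-sided) is provided
because the two descriptions of the threshold in the source literature are
mutually inconsistent — 2.09 *is* the uncorrected critical value — and the
numeric rule is the one that can be applied as printed. The cluster rule's
family-wise false-positive rate under a spatially white global null is
estimated by simulation and reported in the test log; no fixed bound is
asserted, as the rule is a heuristic, not a calibrated test.

## The synthetic-data generator

The generator defines the study conditions: 20 subjects, 128 channels at
500 Hz, epochs −100..500 ms (301 samples, stimulus onset at sample 51),
60 retained trials per condition, and a per-condition *microstate schedule*
over 5 (no-context design: conditions Ug/Tg/Sc) or 7 (context design:
U/T/Usc/Tsc) template maps, each template the projection of 1–3 random
mid-depth dipoles through the lead field, normalized to unit GFP and kept
mutually distinguishable (pairwise |spatial correlation| ≤ 0.7). The
no-context schedule is 0–120 / 122–200 / 202–230 / 232–320 / 322–500 ms,
with the third state's window 10 ms shorter in the simple-contact condition
— the planted condition effect the duration statistics must detect. In the
context design the fourth state (210–230 ms) exists only for grasping
conditions and the final state differs for the use-grip condition; the
published account of that design names six states but describes seven
labels, and the generator resolves the ambiguity with 7 labels and a
condition-specific final state, letting the use-grip final state run to
500 ms so every schedule tiles the analysis window.

Within a window the template's amplitude follows a *raised half-sine*: peak
8 µV mid-window, falling to 30 % of peak half a sample outside the window
boundaries. An envelope that vanished exactly at the boundaries was
rejected during development: boundary samples would carry no signal at all,
so at any noise level their topographies are chance-level, which fragments
segmentation — no evoked recording behaves that way. The raised floor keeps
every in-window sample signal-bearing while GFP still peaks mid-window.
Per-subject variability enters as a uniform ±6 ms jitter of interior window
boundaries (snapped to the sampling lattice). Noise is spatially correlated
Gaussian by default — white noise mixed through the Cholesky factor of a
squared-exponential kernel on the scalp (40 mm length scale, unit marginal
variance), 15 µV per trial — with spatially white noise as an option.
Pre-stimulus samples are noise-only. All randomness flows from one integer
seed; a fixed seed freezes the data byte-for-byte.

Two generation paths exist: full single-trial epochs (exercises rejection
and averaging) and direct subject-VEP simulation with noise scaled by
$1/\sqrt{n_\text{trials}}$ — distributionally identical for Gaussian noise
and used for the larger simulation studies. Artifact injection adds
smooth transients exceeding a stated amplitude to an exact count of epochs,
with a log that downstream rejection must reproduce exactly.

What the generator does *not* emulate, and what passing tests therefore do
not show: overlapping or gradually transitioning generator configurations
(transitions are instantaneous), ocular/muscle artifact morphology (only
threshold-exceeding transients), temporally correlated or non-Gaussian
noise, inter-subject topographic variability (all subjects share the same
templates), and any realistic head geometry. Recovery results here bound
what the pipeline can do under its own assumptions; they do not certify
performance on real recordings.

## Numerical choices

* **Filtering.** The nominal VEP band is 1–30 Hz, implemented as a
  zero-phase (forward–backward) Butterworth of prototype order 2 with
  odd-reflection padding at both ends (plain `filtfilt` starts from zero
  state and leaves large transients on short records). The high-pass leg is
  guarded: a 1 Hz edge has a 1000-ms period, longer than the 600-ms epoch,
  and applying an IIR trend estimate longer than the record measurably
  corrupts every sample (planted-map fidelity drops to spatial correlations
  near 0.24 in the lower decile). Standard ERP practice is to never
  high-pass epoched data; drift removal on epochs is the baseline
  correction's job, which directly precedes the filter in this chain. On
  records spanning at least one high-pass period the full band-pass is
  applied; on shorter records only the low-pass leg runs, and the recorded
  filter attributes say so. `band_hz = NULL` skips the filter entirely —
  the appropriate setting for noise-free synthetic data, where the filter
  has nothing to attenuate; the noiseless-recovery checks use it.
* **Baseline.** Strictly pre-stimulus samples (−100 ≤ t < 0): the sample at
  t = 0 already carries evoked signal in the simulator's convention
  (stimulus onset = first scheduled sample).
* **Normalization.** Each VEP is divided by its own mean GFP over the
  0–500 ms analysis window, per subject and condition, after average
  referencing; group averages are re-normalized the same way.
* **Order guard.** The first-level chain is
  reject → interpolate → average → baseline → band-pass → re-reference →
  normalize; each step appends to an append-only log and
  `assert_pipeline_order()` rejects permuted or duplicated steps.
* **Ties.** Equal correlations label to the lower template index; equal
  density maxima report the lower grid index (flagged); the dissolved
  cluster on equal net loss is the lower cluster id. All deterministic.
* **Degenerate inputs.** Zero maps cannot be correlated: spatial correlation
  raises an error, back-fitting labels such samples with the lowest-index
  template and logs them, normalization of an identically zero VEP errors.
* **Spherical splines.** Perrin-style order-4 splines with 50 Legendre
  terms and a 10⁻⁸ ridge; degree-1 harmonic fields are reconstructed to
  ≤ 1 % at 128 channels, and interpolation error decreases with electrode
  count.
* **Problem sizes.** The analysis scripts and the acceptance script run the
  full study design (20 subjects × 3 conditions × 128 channels; 6-mm grid,
  8829 points) for the headline pipeline, and a 12-mm grid (1021 points)
  for the repeated simulation studies (planted-k recovery at 100 seeds per
  k, 50-run power study, 100-run blob recovery, 1000-rep type-I
  calibration); these sizes were chosen so each study completes in minutes
  while leaving Monte-Carlo standard errors well inside the margins being
  asserted. Unit tests use a 32-channel montage and 20-mm grid.

## Known limitations

* The spherical head model reports grid-frame coordinates; they are not
  comparable to atlas coordinates from realistic head models.
* AAHC is greedy; on adversarial small instances it can fall short of the
  exhaustive-partition optimum (the tests log any gap rather than hiding
  it). The nested model family also means the k-selection sees one
  agglomeration path, not independent refits per k.
* GEV squares the correlation and is therefore blind to polarity even
  though labeling is polarity-sensitive; the dissolution criterion clips
  anticorrelated reassignments at zero explained variance to keep the
  agglomeration itself polarity-aware.
* The KL denominator floor (1 % of total dispersion) is a calibration
  validated by planted-model recovery, not a theorem; data whose true
  dispersion elbow is shallower than the floor would be mis-selected.
* The cluster-extent rule is heuristic; its family-wise error under
  spatially correlated noise is not controlled, only estimated under a
  white null.
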
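---
title: "Decoding and detecting remote hippocampal representations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and detecting remote hippocampal representations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remoterep)
```

# The problem

During quiet wakefulness, hippocampal place cells transiently represent
locations away from the animal. `remoterep` implements a closed-loop
neurofeedback computation built on that phenomenon: spatial content is
decoded from unsorted CA1 spikes in 6 ms windows, and whenever the decoded
content satisfies a set of criteria — a coherent representation of the
distal 25 cm of a designated maze arm while the animal sits at the central
reward port — a tone is triggered and a nosepoke within 3 s earns reward.
The package also implements every downstream analysis of such sessions:
classification of detected events, a prevalence statistic with rank-sum and
longitudinal inference, PCA/ICA cell-assembly analysis, and brain-state
segmentation — together with a synthetic session generator that provides
ground truth for all of it.

# Track model and linearization

The Y-maze is modelled as three straight skeleton segments meeting at the
junction between the central box and the arms: the box axis (port to
junction) and two arms diverging at ±30°. Positions are projected onto the
nearest segment; the linear coordinate starts at 0 at the port and runs
through the box (`box_extent`, default 40 cm) then outward along each arm
(`arm_length`, default 120 cm). Intervals are half-open and region masks
are defined by bin-center membership, so with the default 5 cm bins the
named regions land exactly on bin edges: the distal 25 cm "target end" of
each arm, a 25 cm control region at the arm base, a 15 cm base region used
only by event classification, the first 5 cm of the arm (visible from the
box) and the last 5 cm (the reward port). Off-track positions within 10 cm
are snapped to the skeleton; beyond that the sample is flagged and the last
valid position carried forward. Distances between positions on different
segments run through the junction.

# Clusterless decoding

The decoder is a marked point-process kernel estimator. During the
exploration phase (movement only, head speed > 4 cm/s), every spike whose
peak amplitude exceeds 100 µV on at least one tetrode channel is stored
with its 4-vector of channel amplitudes ("mark") and the animal's
linearized position. To decode a new spike, a spherical Gaussian kernel in
mark space (bandwidth 20 µV) weights the encoding spikes; each contributes
a Gaussian bump (6 cm bandwidth, skeleton distance) at its stored position;
the sum is divided by occupancy and normalized:

$$\ell(x) \propto \frac{1}{\mathrm{occ}(x)} \sum_i
  K_m(m - m_i)\, K_x(x - x_i).$$

Within each 6 ms window the per-spike likelihoods are combined by product
(in log space) and renormalized; windows without spikes are uniform and
flagged uninformative. A causal 30 ms running average (5 bins, informative
constituents only, at least 2 required) is the signal the detector watches.
Three numerical choices matter:

* **Occupancy smoothing is normalized** (Nadaraya–Watson, not plain
  convolution). Plain kernel smoothing attenuates occupancy at the track
  ends, and because the estimator divides by occupancy this would inflate
  likelihoods at the arm tips — exactly where the target region sits.
* **Occupancy floor**: bins holding less than $10^{-5}$ of occupancy mass
  get zero likelihood, so never-visited bins cannot blow up the division.
* **No transition prior**: each window is decoded independently; the 30 ms
  average is the only temporal smoothing.

None of the bandwidths or the amplitude threshold are fixed by the
procedure itself; all are configuration keys with the defaults above.
Session inclusion follows the standard rule: during exploration outward
runs with the animal in the target arm end, the posterior argmax must fall
in the target arm in at least 65% of informative bins.

# Detection criteria

A tone is triggered at the first eligible averaged window satisfying, with
strict inequalities exactly as specified: > 40% posterior mass in the
target arm end, < 20% in the opposite arm, < 20% in the box, at least 2
tetrodes contributing a spatially specific spike in the 30 ms window, and
the animal strictly within 17 cm of the center port. "Spatially specific"
is not defined numerically by the procedure; we operationalize it as a
likelihood peak exceeding 3× the uniform level, which excludes flat,
noise-like spikes (the evident intent); the factor is configurable, as is
the single-tetrode override used for one animal. The lockout between tones
(unstated) defaults to 5 s — longer than the 3 s nosepoke window plus
consumption time. Whether the criteria must persist across several windows
is an open question; we trigger on a single qualifying averaged window,
taking the 30 ms average itself to be the persistence mechanism. Sessions
end at 30 min of feedback or 75 rewards.

The head-direction control condition fires when the head angle is within a
tolerance of ±30° from forward (left for arm 1, right for arm 2) at the
port; the tolerance tightens from ±20° to ±3° over the first 25 rewards.
Only the endpoints of that ramp are specified; we interpolate linearly in
reward count.

# Event classification

Each detection is classified from its 6 ms posterior bins covering the
detection bin plus the 90 ms before it (the segment ends at the detection
bin; extending past detection is an open question we resolve by stopping
there). Categories are tested in precedence order long trajectory > medium
trajectory > jump-and-arm-base > jump: a full sweep also satisfies the jump
mass criterion, so trajectory tests must consume events first. "Significant
linear regression" is ordinary least squares of the posterior-mass-weighted
mean target-arm position against time, over informative bins carrying at
least 0.2 mass in the arm; "covering" is the span (max − min) of the fitted
values, with 45 cm and 35 cm thresholds for long and medium. The
jump-and-arm-base variant requires mass above 0.2 in the 15 cm arm-base
region in some pre-detection bin on top of the jump criterion (end mass
above 0.4). Peripheral flags (visual field = first 5 cm, reward port =
last 5 cm) use a 0.2 mass threshold, which the source procedure leaves
unstated; it is configurable.

# Prevalence and statistics

The prevalence statistic counts 6 ms bins: eligible bins are informative
feedback-phase bins with the animal within 17 cm of the port; qualifying
bins carry strictly more than 40% mass in the named region. When the
tone-triggering representation is excised we remove the 30 ms triggering
window plus the preceding 90 ms (the exact excision span is unstated; this
matches the classification window). Sessions are compared with a two-sided
Mann–Whitney U computed from midranks with tie correction — exact by full
enumeration when both groups have at most 8 sessions, normal approximation
otherwise — and longitudinal trends with OLS on (optionally per-animal
z-scored) prevalence versus session index. These are implemented from the
formulas; base R's `wilcox.test` and `lm` serve only as cross-checks in the
test suite. Grouped mixed-effects modelling is deliberately out of scope.

# Cell assemblies

Sorted-unit spike trains are binned at 30 ms and z-scored per unit. The
number of assemblies is the count of correlation-matrix eigenvalues above
the Marchenko–Pastur bound $(1+\sqrt{N/B})^2$; a symmetric fixed-point ICA
(cube contrast) on the significant subspace yields the weight vectors,
normalized to unit length with the largest-magnitude weight positive. The
ICA iteration is implemented in the package. Activation strength is the
zero-diagonal quadratic form $R(t) = z_t^\top(ww^\top - \mathrm{diag}\,
w^2)z_t$, so single-unit firing contributes nothing. Assemblies are
labelled *target* by an argmax rule: the weight-weighted place-map mass of
the assembly's high-weight units (weight > mean + 2 SD) inside the target
arm end must exceed the same quantity for every other candidate 25 cm
region (both arm ends, both bases, a central box stretch). The labelling
rule and the high-weight cut are admissible operationalizations, not
prescribed ones, and both are configurable.

# Brain state

Ripples are detected on the 150–250 Hz band envelope (analytic signal,
4 ms smoothing): above mean + 3 SD for at least 15 ms, extended to the
mean + 1 SD boundaries, merged across gaps under 10 ms — conventional
parameters, since the source defers to previously described methods; all
configurable. Each 6 ms bin is labelled SWR / still / moving (4 cm/s
threshold). Theta phase comes from the 6–10 Hz analytic signal with the
convention phase 0 = LFP trough, increasing through the cycle; the
convention is reported because "late phase" statements depend on it.
Band-pass filtering is zero-phase FFT masking (padded to fast composite
lengths), which is exact for these narrow bands and keeps the package free
of filter-design dependencies. The Rayleigh test uses
$Z = n\bar{R}^2$ with the standard finite-$n$ series correction.
Composition tables get a chi-square test plus two-proportion z-tests for
the moving and SWR fractions, with a Fisher fallback flagged when expected
counts drop below 5.

# The synthetic session generator

The generator emulates the task: a cued exploration phase with exactly 12
out-and-back visits per arm at ~20 cm/s (port dwells sized to fill the
configured duration; dwells are excluded from encoding by the movement
filter), then a feedback phase with the animal within 17 cm of the port at
least 80% of the time in stillness bouts. Place cells have unimodal
Gaussian tuning (peak 30 Hz, width 10 cm, floor 0.1 Hz) — multi-field
cells are excluded so recovery tests stay interpretable — with 20% of
fields in the target arm end. Firing-rate parameters were chosen so the
aggregate spike budget approaches the scale of real clusterless recordings
(on the order of $10^5$–$10^6$ threshold crossings per session); place-cell
rates are scaled by 0.15 during stillness, reflecting reduced firing in
immobility. Marks are drawn from cell-specific 4D clusters (spread 20 µV,
means separated by at least 80 µV within a tetrode).

Injected remote events replace locally-driven spiking in their window with
spiking generated as if the animal occupied the represented positions, at
3× the movement-rate tuning curve plus baseline background. The four kinds
are constructed so that their ground-truth label genuinely matches the
classifier's definition at the spike rates above:

* **jump**: positions uniform in the interior of the target end;
* **jump-and-arm-base**: alternating blocks of base (first 15 cm) and end
  representation before settling at the end — base mass appears in
  pre-detection bins without producing a monotone position ramp;
* **medium / long trajectory**: constant-speed sweeps toward the arm end at
  0.38 and 0.64 cm/ms. The sweeps are longer than the 96 ms classification
  window, so the span a detection's segment can cover is set by the speed
  alone (≈ speed × 96 ms ≈ 37 cm and 61 cm) rather than by the exact
  detection latency.

Event onsets are snapped to the 6 ms decode grid so representation blocks
align with decoding bins; a bin containing spikes for two distant
locations would otherwise decode to a spurious intermediate peak (the
product of two displaced likelihoods), an artifact of time-discretized
decoding rather than of the generator. The surrogate LFP is white noise
plus movement-gated 8 Hz theta and 200 Hz ripple bursts (50–100 ms Hann
envelopes) whose amplitude is calibrated to a stated number of SDs (default
6) above the trace's own ripple-band envelope statistics. Simulated
nosepokes answer each tone with probability 0.95 at a uniform 0.2–1 s
latency.

One master seed expands into per-component substreams (trajectory, tuning,
spiking, injection, LFP), so a component can be re-randomized while the
others stay fixed; identical seed and configuration give byte-identical
sessions and, through the pipeline, byte-identical summary JSON.

**What the generator does not emulate.** Theta sequences and phase
precession, multi-field and directional cells, spike-sorting errors,
electrode drift, correlated noise across tetrodes, biophysical LFP
structure, and the latency/jitter of a real-time implementation (latency is
simulated, not engineered). Passing tests on this generator therefore
demonstrate the correctness of the computations under the stated
statistical model of the data — not robustness to every pathology of real
recordings.

# Known limitations

* At the generator's event spike rate (~1.5–3 spikes per 6 ms bin), the
  per-bin represented position carries ~6–10 cm of noise, so the fitted
  coverage of a trajectory event has an SD of several cm. The medium
  category occupies a 10 cm-wide band (35–45 cm), which is only ~1.5 SD
  wide: a medium-swept event is recovered as *some* trajectory reliably,
  but lands in the medium band in only roughly half of detections, the
  rest spilling mostly into the long category. Jump-dominated event mixes
  — which is what detected remote representations look like — are
  recovered at ≥ 90% overall. This is a noise floor of the classification
  rule at realistic spike counts, not an implementation artifact.
* The session bundle is a native R object with CSV/JSON exporters rather
  than an on-disk HDF5 container; the component layout mirrors the group
  structure such a container would use.
* Problem sizes in the tests and acceptance script (10–15 min exploration,
  7–9 min feedback, 40–50 injected events, 60 cells on 8 tetrodes) were
  chosen as the smallest sessions at which every stage has comfortable
  statistical power.

# Analysis entry points

`synth_session()` builds a bundle; `analyze_session()` runs every stage on
it (never touching the ground-truth sidecar); `run_pipeline()` adds
ground-truth evaluation and result export; `validate_session()` checks
bundle integrity. Each stage is also exported on its own
(`fit_encoding_model()`, `decode_session()`, `detect_events()`,
`classify_events()`, `region_prevalence()`, `detect_assemblies()`,
`detect_swr()`, ...), so the pipeline can be rearranged in scripts.
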
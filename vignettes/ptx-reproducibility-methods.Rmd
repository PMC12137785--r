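---
title: "Methods: longitudinal reproducibility of pTx kT-points cardiac excitation"
author: "ptxRepro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal reproducibility of pTx kT-points cardiac excitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxRepro)
```

# The problem

At ultra-high field (7 T), the transmit radiofrequency field (B1+) of a body
array is strongly inhomogeneous across the human torso: constructive and
destructive interference between channels produces flip-angle (FA) dropouts
in the heart. Parallel transmission (pTx) counters this with one complex
weight per channel — either a static RF shim or a dynamic kT-points pulse
that visits a handful of transmit k-space locations between nonselective
subpulses. Three strategies differ in how those weights are obtained:

* **default** — a vendor-style phase-only shim: equal channel magnitudes,
  phases fixed once on a calibration body model, never re-optimized;
* **TP** — a subject-tailored 4 kT-points pulse designed on the B1+ maps of
  one scan session;
* **UP** — a calibration-free universal 4 kT-points pulse designed jointly
  over a library of B1+ map sets from other subjects.

The scientific question this package addresses is not which method is best
on the session it was designed for (TP wins that by construction), but which
is *reproducible*: how do the three strategies behave when a subject is
rescanned on the same day by a different operator, after one year by the
same operator, and after two years by different operators?

# The pipeline

`runStudy()` reproduces the full cross-application design: a test cohort of
6 subjects scanned in 4 sessions, a disjoint 22-map design library, one UP,
one frozen default shim and one TP per (subject, session) ("Config j" for
the TP designed on session j). Every configuration is evaluated on every
session of every subject. The coefficient of variation (CV, percent) of the
predicted FA over the heart ROI is the per-scan score; sessions are grouped
into the inter-day (sessions 3 and 4), same-operator (1 and 3) and
inter-year (1, 2 and 4) studies, with operators assigned as sessions 1 and 3
to operator A, 2 to B, 4 to C.

Within each grouping, each method yields a subjects-by-sessions CV table
(`CVTable`). Each tailored-pulse configuration belonging to the grouping is
applied across *all* of the grouping's sessions, so its table mixes the
tailored scan group (TSG) with the others (nTSG); this mixing is what makes
tailored pulses disperse in CV space. Three cluster statistics summarize
each table (`clusterSummary()`):

* inertia `ICV = (1/(V*S)) * sum_{v,s} (CV_{v,s} - xbar_s)^2` — dispersion
  around the per-scan-group centroid (squared-percent scale, with the root
  provided alongside);
* centroid norm `|xbar| = sqrt(sum_s xbar_s^2)` — overall CV magnitude;
* perpendicular distance `d_perp = sqrt(sum_s (mean(xbar) - xbar_s)^2)` —
  the Euclidean distance from the centroid to the identity line, i.e. how
  consistently a method performs across the scan groups.

Method pairs are compared with a paired Wilcoxon signed-rank test on the
(subject, scan group) CV values, Bonferroni-corrected within each grouping
(`pairwiseRankTests()`; the family is all method pairs of the grouping and
the family size is reported in the output rather than assumed).

# Pulse design

All designs operate on maps normalized so that the heart-ROI mean of the
per-voxel sum of channel magnitudes equals one (`normalizeB1()`); this fixes
the nominal FA scale per session and makes regularization comparable across
subjects. In the small-tip-angle (STA) regime, the transverse excitation is
linear in the stacked channel weights: the system matrix has one row per
ROI voxel and entry `c0 * b1_c(r) * exp(i k_k . r)`, with `c0` chosen so
unit total drive at a voxel with unit sum-of-magnitudes yields the target
FA (10 degrees).

The design cost is magnitude least squares (MLS),
`sum_r (|A_r w| - theta)^2 + lambda * ||w||^2`, because evaluation depends
only on |FA|; the excitation phase is free. It is minimized by variable
exchange — alternate fixing the target phases at `arg(A w)` and solving the
resulting Tikhonov-regularized linear problem — which makes the recorded
cost trace provably non-increasing. kT-point locations come from an
interleaved greedy/local scheme: starting from the best single candidate on
a regular candidate grid (default ±2 cycles/FOV per axis, step 1, always
containing k = 0), each greedy step adds the candidate that minimizes the
MLS cost after re-solving the weights, followed by a local full re-solve.
Ties are broken deterministically by enumeration order (smallest-norm
first, lexicographic in (kz, ky, kx)). The universal pulse minimizes the
plain summed cost over the stacked library rows with shared weights and
locations. The default shim is phase-only MLS (equal magnitudes) on a fixed
vendor calibration model (`vendorReference()`) — one configuration across
all studies, as a vendor setting would be — with its common magnitude
scaled to hit the mean target FA on that reference.

Tunable parameters (`DesignConfig`): 4 kT-points; target FA 10 degrees;
`lambda = 1e-3` in normalized units, fixed across methods (comparability is
the point, the exact value is not critical at these problem sizes);
variable-exchange tolerance 1e-6 on the relative cost change with at most
200 iterations for final solves and 12 during greedy candidate scans (the
scan only needs to rank candidates; tiny test problems use larger caps);
gradient limits 40 mT/m and 170 T/m/s on a 10 µs raster for the blips,
which are triangular (trapezoidal when amplitude-limited) and reproduce
each inter-point k-space displacement to machine accuracy by construction.

Off-resonance is omitted throughout: no B0 map enters the design or the
evaluation.

# Flip-angle evaluation

`predictFaSta()` evaluates the closed-form STA prediction on the full grid.
`blochSimulate()` is the independent oracle: each kT subpulse is a constant
complex RF over its 100 µs duration, i.e. an exact axis-angle rotation, and
the gradient blips enter as position-dependent phase increments that can be
absorbed into the subpulse phases without changing the final longitudinal
magnetization (the leftover rotation is about z, which leaves Mz, and hence
FA = arccos(Mz), untouched). Relaxation is neglected. At the 10-degree
target the two agree to better than 1% relative FA; at large angles the STA
prediction exceeds the Bloch angle, as the small-tip linearization must.

The CV uses the population (not sample) standard deviation; with ROIs of
several hundred voxels the distinction is far below every tolerance used
here. FA distribution summaries use midpoint medians for even counts.

# The synthetic cohort

No in-vivo B1+ maps ship with the package, so a generator (`b1_synth`
functions) emulates the study's data with a torso/heart ellipsoid phantom
and an 8-element body array (two rings, 4 anterior / 4 posterior elements).
Channel magnitude decays as `1/(d + d0)` (d0 = 40 mm) with exponential
tissue damping; channel phase is a per-channel offset plus a linear
propagation term (0.065 rad/mm, matching the centimeter-scale wavelength of
7 T in tissue). Two field layers sit on top of this smooth skeleton:

* a **static subject texture** — per-channel smooth random fields with
  spatial frequencies up to ±10 cycles/FOV, anchored to the anatomy. This
  emulates tissue-driven B1 structure that an 8-element coil model cannot
  express and, crucially, that partially exceeds the kT-point candidate
  bandwidth: it is what keeps tailored-pulse CVs at a realistic floor and
  gives the universal pulse a stable, irreducible CV baseline;
* a **session perturbation** — coil placement (operator bias + per-session
  jitter), a per-year setup drift of the scanner, anatomy scale drift
  (subjects slowly change over years; the array geometry is fixed, so the
  tissue moves relative to the elements), a small per-channel smooth field
  redrawn each session, and a scanner RF-chain state of the day (small
  per-element gain/phase deviations shared by every subject scanned in the
  same scan group).

Subjects differ in ellipsoid geometry, attenuation, channel phase offsets,
texture, and in a per-subject session sensitivity (how consistently a
subject repositions and breathes), which makes transplant degradation
heterogeneous across subjects — the mechanism behind the large dispersion
of tailored-pulse results in the cross-session studies. The library cohort
has a broader anatomy spread than the test cohort, disjoint seeds, and its
members cycle through the operators and study epochs so the universal
design sees the placement and drift range the longitudinal sessions will
express.

The paper-scale acquisition grid is replaced by a desk-scale stand-in of
32 x 40 x 40 voxels at 8 mm isotropic (FOV 256 x 320 x 320 mm), which puts
roughly 500-800 voxels in the heart ROI; all linear algebra sizes scale
accordingly. The default perturbation magnitudes were calibrated once, as
part of the study conditions, so that the default shim lands in the
tens-of-percent CV regime reported for uncorrected excitation, and then
frozen; no quantitative inter-session B1+ variation was available to match,
so these are model choices, not measured values.

What the generator does **not** emulate: electromagnetic field solving,
SAR, respiratory or cardiac motion, receive profiles, or image contrast.
Passing tests therefore demonstrate that the analysis pipeline reproduces
the qualitative reproducibility structure under a plausible variability
model — not that it reproduces the in-vivo CV values, which depend on maps
that are not public.

# Numerical choices and degenerate inputs

* Variable exchange falls back to a pseudo-inverse solve when the normal
  equations are singular (e.g. duplicated kT-points at `lambda = 0`).
* Zero excitation voxels get target phase 1 in the phase update.
* The candidate grid must contain k = 0; the uniform-field tie (every
  candidate achieves zero cost) resolves to k = 0 via smallest-norm-first
  enumeration.
* ROIs must be single 6-connected components of at least 50 voxels; empty
  ROIs and non-positive mean FAs are errors, never silent NA.
* Wilcoxon zero differences are dropped (classical rule); if all
  differences vanish the p-value is 1 with a warning. The exact null is
  enumerated for n <= 12 (valid under ties via average ranks); larger n
  uses the tie-corrected normal approximation with continuity correction.
* All randomness flows from explicit seeds through private RNG streams that
  restore the caller's RNG state, so every artifact is byte-reproducible
  from a master seed.

# Problem sizes used in the shipped checks

The packaged tests run the solver-contract and statistics oracles on 8^3
grids with ~56-voxel ROIs, simulator agreement on a 2 x 2 cohort, the
degenerate (zero-variability) study at 3 x 4, and the full qualitative
reproduction at the study's native size — 6 subjects x 4 sessions with a
22-map library — across 20 master seeds. These sizes were chosen so the
whole suite reflects the actual study conditions while remaining a
desk-scale computation.

# Known limitations

* The ellipsoid coil model has no electromagnetic validity; its interference
  structure is qualitatively, not quantitatively, torso-like.
* The operator and drift model is a stylized account of the positioning
  protocol; amplitudes are config choices (`sessionVariability()`), and the
  reported orderings are robust to seeds but have not been checked against
  sweeps of every variability knob.
* The identity-line distance of a method whose CV is *stably* mediocre
  (the frozen default shim here) is an intrinsically noisy statistic at 6
  subjects: the generator gives the default shim a large dispersion (ICV)
  but only a noise-level session-mean trend, so the universal pulse's
  advantage on `d_perp` over the default shim is the least robust of the
  reported orderings across master seeds.
* Large-tip design, SAR constraints, slice-selective pulses and B0
  robustness are out of scope.
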
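---
title: "Reference schemes and the dynamic EEG center of mass: models and methods"
author: "restcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference schemes and the dynamic EEG center of mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restcm)
```

## The problem

Every EEG measurement is a potential *difference* against a reference.
Common choices - the average of all channels (AR), the linked mastoids (LM,
the mean of TP9/TP10), or a single scalp site such as the vertex (CZ) - all
carry brain signal of their own, so the choice of reference adds a
time-varying spatial constant to every channel.  The positive center of mass
(CM) of a scalp topography,

$$X(t) = \frac{\sum_i a_i\, m_i(t)}{\sum_i m_i(t)},\qquad m_i(t) > 0,$$

(and likewise $Y(t)$, $Z(t)$, with $(a_i, b_i, c_i)$ the unit-sphere
electrode coordinates and the sum running over the strictly positive
channels) is *not* invariant to that constant: raising the "water level"
recruits different electrodes into the positive set and drags the CM toward
the electrode centroid.  This package quantifies how strongly each reference
distorts the CM and its traveling velocity, and implements the reference
electrode standardization technique (REST), which approximates recordings
against a neutral reference at infinity.

## Forward model

All forward computations use a three-concentric-sphere volume conductor:
normalized radii 0.87 (inner skull), 0.92 (outer skull), 1.0 (scalp);
conductivity ratios 1.0, 0.0125, 1.0 for brain, skull, scalp.  The scalp
potential of a current dipole is the classical Legendre /
associated-Legendre series.  Writing $b$ for the dipole eccentricity,
$\gamma$ for the angle between dipole position and electrode, and splitting
the moment into radial ($m_r$) and tangential ($m_t$) parts,

$$V = \frac{1}{4\pi\sigma_1}\sum_{n\ge 1} c_n\,
      \bigl(n\, m_r P_n(\cos\gamma) + m_t P_n^1(\cos\gamma)\bigr),$$

where the per-degree coefficients $c_n$ follow from a 5-by-5 linear system
per degree expressing potential and current continuity at the two interior
interfaces and zero current at the scalp.  Numerical choices that matter:

* **Scaled shell basis.**  The naive basis $(r^n, r^{-(n+1)})$ makes the
  interface system singular in double precision near degree 40; each shell
  instead uses radius-normalized basis functions, keeping every matrix entry
  O(1) up to degree 400.
* **Truncation.**  The series is truncated at degree 200, or earlier once
  two successive terms contribute less than $10^{-10}$ relative.  Degree 60
  is *not* sufficient: at the most eccentric grid dipole ($b \approx 0.854$)
  the tail beyond degree 60 still carries about $3\times10^{-4}$ of the sum,
  while beyond degree 200 it carries about $2\times10^{-13}$.  (The test
  suite checks that doubling the degree changes no gain entry by more than
  $10^{-8}$ relative.)
* **Oracle.**  In the equal-conductivity limit the series must equal the
  closed-form potential of a dipole in a homogeneous sphere; the suite
  checks 100+ random dipole/electrode pairs at $10^{-6}$ relative.

The simulation source space is the cubic lattice with spacing 0.0905
anchored at the origin, confined to $x^2+y^2+z^2 \le 0.86^2$, $z \ge 0$
(both constraints inclusive) - exactly 1994 dipoles.  Origin anchoring is
required to reproduce that count.

## Electrode fixture

The packaged montage is an idealized unit-sphere realization of the extended
10/20 system: 59 scalp electrodes for CM analysis, the mastoids TP9/TP10
(used only by the LM reference), and two non-scalp EOG placeholders - 63
channels, with FCz and AFz reserved as recording reference and ground.
Midline and ear-to-ear positions sit at 10% steps along their landmark great
circles; the outer ring is the 10% circle; interior rows subdivide the arcs
between ring and midline electrodes.  These are standard angular placements,
not digitized coordinates of any particular cap, and the montage is exactly
left-right symmetric - a property with consequences discussed below.

## REST

REST uses the forward model to undo the reference: with $G$ the
infinity-reference lead field over a dense source grid and $G_{ref}$ the
same lead field re-referenced the way the data were, the minimum-norm source
estimate $\hat S = G_{ref}^- V_{ref}$ is re-projected through $G$, giving
the linear operator $U = G\,G_{ref}^-$.  The pseudoinverse is computed by
SVD with singular values below $10^{-4}$ of the largest truncated.  On this
montage/grid pair the spectrum is benign (60 of 61 directions within a
factor 100 of the largest; the 61st is the exact null direction every
referencing matrix shares), so the result is insensitive to that cutoff over
$10^{-3}$-$10^{-8}$ - which is also why the choice was left at the
conventional value rather than treated as a tuning knob.

Any scalp referencing matrix annihilates the same one-dimensional
common-mode direction, so the operator built from CZ-, AR- or LM-referenced
data recovers the identical reconstruction; REST carries an irreducible
residual of a few percent for spatially sparse (single-dipole) sources, the
hardest case for a minimum-norm model.

## The simulation study and a known limitation

Each grid dipole is driven by the damped Gaussian
$h(t_i)=\exp(-(2\pi f (t_i - t_0)/\gamma)^2)\cos(2\pi f (t_i-t_0)+\alpha)$
with $t_0 = 35\,dt$, $f = 10$ Hz, $\gamma = 5$, $\alpha = \pi/2$ (we adopt
the Gabor reading in which $2\pi f(t_i-t_0)$ is divided by the dimensionless
$\gamma$ inside the envelope - the only dimensionally consistent one), at
$dt = 1/250$ s with $k = 100$ samples.  Because each simulated recording is
rank-1 in space-time, the positive CM takes exactly two values over time
(one per sign of $h$), which reduces the full 1994 x 3 x 4 comparison to a
handful of matrix products; the suite cross-checks this fast path against a
literal per-sample implementation.  The per-dipole error is
$\mathrm{Err} = \lVert CM_{ref}-CM_{ir}\rVert / \lVert CM_{ir}\rVert$
against the infinity-reference standard, averaged over the samples where
both CMs are defined ("time-mean"; an "at-peak" alternative is provided for
sensitivity analysis).  The 3D CM is used here; the 2D variant degenerates
for midline z-oriented dipoles, whose planar CM norm can vanish.

Aggregated over all orientations, REST's mean error is several times smaller
than that of every other reference, and it is far less structured over the
source volume.  Per orientation the picture is sharper and more interesting:
REST wins clearly for y- and z-oriented dipoles, but for x-oriented
(left-right tangential) dipoles the *average reference* is nearly unbiased
on this montage and undercuts REST's minimum-norm residual.  The reason is
geometric: the montage is exactly mirror symmetric in x, so the true mean
scalp potential of any x-oriented dipole is close to zero - and AR's entire
error is that mean.  This is a genuine property of the study conditions, not
a numerical artifact: it survives changes of the pseudoinverse cutoff, of
the reference the REST operator is derived from, of the error aggregation
rule, and of the CM dimensionality.  Any near-symmetric cap should behave
the same way, so a blanket "REST is always smallest in every orientation"
should not be expected under ideal montage symmetry.

## ERP pipeline

The analysis chain for oddball ERP data follows standard practice:
re-referencing (REST / AR / LM); 6 Hz low-pass with a 4th-order Butterworth
run forward and backward (zero phase, so component latencies are untouched);
decimation to 250 Hz by sample picking (the passband is far below the new
Nyquist); epochs on [-200, 800) ms with the [-200, 0) ms mean subtracted per
channel; rejection of epochs in which any scalp channel exceeds 75 uV in
absolute value (strictly greater - exactly 75 uV is retained); averaging per
condition.  Because filtering (temporal, per channel) and re-referencing
(spatial, per sample) are both linear, they commute; the driver filters once
and re-references afterwards, which is mathematically identical and three
times cheaper.  The rejection threshold is applied after down-sampling.

P300 amplitude/latency are the means of the positive-peak readings at Cz,
CPz and Pz within a 250-500 ms search window (configurable).  The CM
trajectory of the averaged ERP uses the 59-electrode montage, two
dimensions, one CM per sample over [200, 800) ms - 150 points at 250 Hz -
and the traveling velocity scales the normalized coordinate steps to a 10 cm
head radius, in m/s.  Stage windows: S1 210-350 ms, S2 350-480 ms, S3
480-740 ms.  Reference effects are tested per stage on subject-level stage
means (n = 12, so df = (2, 22)) with the repeated-measures ANOVA below;
cross-condition velocity correlations use the group-mean curves, pairing
target 250-350 ms against standard 210-310 ms in S1 (a 40 ms lag) and
identical windows in S2/S3.

## Statistical kernel

The one-way repeated-measures ANOVA is computed directly from the
within-subject sums of squares, with the Greenhouse-Geisser
$\varepsilon = (\mathrm{tr}\,C)^2 / ((k-1)\,\mathrm{tr}\,C^2)$ from the
double-centered condition covariance $C$, clamped to $[1/(k-1), 1]$.  Both
the uncorrected and the $\varepsilon$-corrected p value are always returned;
the headline p is the corrected one when $\varepsilon < 0.75$.  Tukey
pairwise comparisons use $q = |\bar x_i - \bar x_j| / \sqrt{MS_e/n}$ (the
Tukey-Kramer form under unequal group sizes, as happens in the simulation
when a dipole's error is undefined) with studentized-range probabilities
from R's `ptukey`; the tests verify those probabilities against an
independent double-quadrature of the studentized-range distribution and
verify the $k=2$ identity with the paired t test.  Degenerate inputs are
defined rather than NaN: a zero condition effect reports $F = 0$ and Tukey
$p = 1$ even when the error term is also zero.  For the simulation study the
per-dipole errors are independent observations, so a one-way (non-repeated)
Tukey over dipoles is used there, with the pooled within-reference mean
square as error term.

Under a spherical Gaussian null (k = 3, n = 12, 2000 seeded replicates) the
GG-corrected test's type-I error must land in [0.035, 0.065] and the Tukey
familywise error at or below 0.07; both are asserted in the suite.

## The synthetic cohort

No recordings ship with the package; a seedable generator emulates the
study design so that every pipeline stage is testable: 12 subjects, 3
sessions x 150 trials at 500 Hz, exactly 30 targets / 120 standards per
session, trial timing cue 250 ms - fixation 500 ms - stimulus 500 ms, data
recorded against FCz.  ERP components are lumped equivalent dipoles on the
midline, each driven by a damped-Gaussian burst (the Gabor above with
$\alpha = 0$, $\gamma = 2$, per-component frequency setting the width) and
calibrated in microvolts at a named electrode of the infinity-referenced
map:

| component | site | peak (target) | target | standard |
|---|---|---|---|---|
| P200 | frontal (y = 0.55) | 200 ms | 6 uV | 6 uV |
| P250 | fronto-central (y = 0.35) | 250 ms | 3.5 uV | 7 uV |
| P3a | fronto-central (y = 0.15) | 310 ms | 6 uV | 1 uV |
| P3b | parietal (y = -0.45) | 360 ms | 10 uV (Pz) | 2.5 uV |
| slow wave | frontal (y = 0.50) | 620 ms | 4 uV | 4 uV |

The endogenous components (P3a, P3b, slow wave) run 40 ms earlier in the
standard condition, emulating the stimulus-evaluation lag of the frequent
stimulus: the standard CM expands into parietal sites earlier (and, being
unopposed once P250 decays, deeper) than the target CM reaches the vertex.

Two of these are deliberate extensions of the minimal P200/P250/P300 set:
the P3a/P3b pair makes the positive CM drift continuously along the midline
through the P300 plateau (a single static parietal dipole would freeze the
CM and drive its speed to the noise floor, which real data never show), and
the late frontal slow wave carries the CM's return to frontal sites in the
recovery stage.  Both choices follow the component structure of the oddball
ERP literature.

Inter-subject variability is lognormal in amplitude (sdlog 0.2) and Gaussian
in latency (20 ms), per subject and component.  Noise has three parts: 20
random deep dipoles per session (uniform in the r <= 0.6 ball) with 30 Hz
low-pass-filtered Gaussian time courses, scaled to a 12 uV median
per-channel RMS (spatially correlated, like ongoing EEG); 3 uV white sensor
noise; and eye blinks on 8% of trials (150 uV on VEOG, leaking onto frontal
channels by a 4th-power-of-y profile), which is what the +/-75 uV rejection
step actually removes - retention lands near the 90% the paradigm typically
yields.  The generator is bit-identical under a fixed (config, seed) pair,
with per-subject streams derived deterministically from the base seed.

What the generator does *not* emulate: single-trial latency jitter (the
averaged components are slightly narrower than real averages), alpha
rhythms and other structured background, electrode drift, and any fitting
of component parameters to real waveforms.  One concrete consequence: the
*sign* of the S1 lagged cross-condition velocity correlation does not
reproduce.  Real oddball data show the standard velocity course at 210-310
ms matching the target course at 250-350 ms; in the synthetic cohort the
timing of the S1 travel is pinned by the decay of the shared exogenous
P200/P250 pair rather than by the lagged endogenous rise, so the lagged
curves anticorrelate.  Reproducing that sign would mean fitting the
generator's time courses to waveform data, which is out of scope.  Passing
the end-to-end tests therefore shows that the *pipeline* recovers what the
generator put in - P300 target/standard separation, the
frontal-parietal-frontal CM sweep with speeds in the 0.1-3 m/s band - not
that real cortex behaves this way.

## Problem sizes and runtimes

The package's own test/acceptance runs use the full study sizes: the
1994-dipole grid (lead field 61 x 5982, about a second to build thanks to
the vectorized series), the full 12-subject cohort (a few minutes end to
end), and 2000-replicate null calibrations.  Algebraic REST properties are
additionally exercised on a coarse 250-dipole grid where full resolution
adds nothing.

## Known limitations

* The idealized symmetric montage makes AR optimal for x-oriented dipoles
  (see above); digitized cap coordinates would blur but not remove this.
* REST's accuracy is quoted for the matched head model; model mismatch
  (real heads vs. spheres) is out of scope.
* The 2D CM error is undefined for sources whose infinity CM sits at the
  planar origin; the simulation therefore reports 3D errors.
* EDF I/O is not provided; recordings are exchanged as delimited text with
  JSON sidecars.
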
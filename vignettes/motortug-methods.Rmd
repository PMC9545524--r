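---
title: "Stochastic tug-of-war between kinesin and dynein: model and trace analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic tug-of-war between kinesin and dynein: model and trace analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motortug)
```

## The system and the model

Intracellular cargo is often carried by opposing motors: plus-end-directed
kinesins and the minus-end-directed dynein–dynactin–BicD2 (DDB) complex.
`motortug` simulates one kinesin and one DDB connected through elastic
linkages to a shared, massless cargo on a one-dimensional microtubule
lattice, and provides the single-molecule trace-analysis pipeline used to
quantify the resulting bidirectional motility.

Each motor is described by a `motor_params` set: unloaded velocity $V_0$,
step size $L = 8$ nm, backstepping rate $k_\mathrm{back}$, unloaded
detachment rate $k^0_\mathrm{det}$, stall force $F_s$, detachment force
parameter $F_\mathrm{det}$, reattachment rate $k_\mathrm{reatt}$, and
linkage stiffness $\kappa = 0.2$ pN/nm. The rate laws are:

* **Forward stepping.** The unloaded forward rate is
  $k^0_\mathrm{fwd} = V_0 / L + k_\mathrm{back}$. A hindering load of
  magnitude $m$ reduces it linearly,
  $k_\mathrm{fwd}(m) = k^0_\mathrm{fwd} + (k_\mathrm{back} -
  k^0_\mathrm{fwd})\, m / F_s$, so the net stepping velocity
  $(k_\mathrm{fwd} - k_\mathrm{back}) L$ is exactly zero at stall.
  Assisting loads leave the rate unchanged.
* **Detachment.** Bell slip-bond kinetics,
  $k_\mathrm{det}(F) = k^0_\mathrm{det}\, e^{|F| / F_\mathrm{det}}$ with
  $F_\mathrm{det} = k_B T / \delta$ ($k_B T$ = 4.1 pN nm). DDB is an
  *ideal bond*: its off-rate (0.1 s$^{-1}$) is load-independent.
* **Reattachment.** First-order with rate $k_\mathrm{reatt}$; a detached
  motor rides with the cargo and re-engages at the cargo position.
* **Mechanics.** The force on a motor is $\kappa (x_\mathrm{cargo} -
  x_\mathrm{motor})$. With both motors bound the cargo sits at the
  stiffness-weighted mean of the motor positions (midpoint here); when
  one motor detaches the cargo snaps to the remaining motor.

Events are drawn with the exact Gillespie stochastic simulation
algorithm: rates are re-evaluated after every event, the waiting time is
exponential in the total rate, and the event is chosen proportionally to
its rate. No tau-leaping is used; total rates stay below $\sim 10^3$
s$^{-1}$, so exact SSA is cheap (the inner loop is compiled, with a
draw-for-draw identical plain-R reference engine used in tests).

### Behaviour beyond stall

The stall force fixes the force–velocity line only up to $F_s$. Two
conventions for hindering loads beyond stall are implemented
(`superstall` in `motor_params`):

* `"linear"` (default): the line continues past stall, floored at a
  zero forward rate, so a super-stall load drags the motor backwards at
  up to $k_\mathrm{back} L$ net.
* `"clamp"`: the forward rate is held at $k_\mathrm{back}$ (net zero
  stepping under any super-stall load).

The default matters. DDB's stall force (3.6 pN) is below kinesin-1's
(6 pN), so in a tug-of-war the shared tension routinely exceeds DDB's
stall. Under the linear convention the pair settles where kinesin's net
stepping equals DDB's net backward slip — for the reference Kin1/DDB
parameters a balance near 5.6 pN and a slow crawl of about +40 nm/s,
punctuated by kinesin detachment/rebinding cycles. This reproduces the
near-zero instantaneous-velocity peak characteristic of the system.
Under the clamp the pair instead locks at mutual stall and every kinesin
detachment costs a backward cargo jump with no compensating forward
crawl, driving the velocity peak ~35 nm/s too negative. The linear
continuation is also the literal reading of "a linear force–velocity
relationship", so it is the package default.

### Known parameter quirk

The tabulated DDB forward rate (60 s$^{-1}$) is inconsistent with its
derivation from the DDB unloaded velocity
($360/8 + 5 = 50$ s$^{-1}$). The package treats the published table as
authoritative — the bundled presets use 60 s$^{-1}$ — and
`load_motor_params()` surfaces the discrepancy as a warning. The
consequence is that unloaded DDB in the simulation moves at
$(60-5)\times 8 = 440$ nm/s rather than the nominal 360 nm/s, which
shifts velocity distributions minus-ward in regimes where kinesin is
frequently detached (small $k_\mathrm{reatt}$).

## The trace-analysis pipeline

The pipeline mirrors the kymograph analysis of two-channel TIRF data
(3.5 frames/s, 73 nm pixels, up to 100 s):

1. **Frame averaging** (`frame_average`): simulated cargo paths are
   averaged over 0.286 s camera frames (time-weighted mean of the
   piecewise-constant event path).
2. **Instantaneous velocities** (`instantaneous_velocities`): 1 s
   windows are `round(1/0.286)` = 3 frames; the endpoint displacement is
   divided by the actual 0.858 s span, which removes the quantisation
   bias. The regression-slope alternative was considered and rejected as
   the less literal reading of a "window" velocity.
3. **Trace velocity and fast/slow classes** (`trace_velocity`,
   `classify_fast_slow`): net displacement over duration; traces
   strictly above the threshold (250 nm/s for DDB-Kin1/3, 125 for
   DDB-Kin2) are "fast" (kinesin running with DDB weakly bound), the
   rest "slow" (both motors engaged). The threshold itself is classified
   slow, the conservative choice.
4. **Segmentation** (`segment_trace`): exact penalised change-point
   detection. Dynamic programming minimises total least-squares residual
   plus a per-segment penalty over all partitions with segments of at
   least 3 frames (858 ms); adjacent segments whose fitted velocities
   differ by less than 10 nm/s are then merged. The penalty is
   $5\hat\sigma^2 \log n$ with $\hat\sigma$ a robust noise estimate from
   second differences; the multiplier sits above the BIC scale because
   3-frame edge segments otherwise overfit noise (validated on pure-drift
   fixtures), and a small scale-relative floor makes noiseless fixtures
   recover exactly. One refinement beyond plain merging: when a
   candidate merge would raise the residual by more than the penalty
   *and* the two fits disagree in level at the boundary by more than
   $\max(2\hat\sigma, 1\ \mathrm{nm})$ — two pauses at different heights
   bridged by a sub-frame run — a minimum-length "step" segment is
   carved at the boundary instead, which is how such a step would be
   annotated by hand. Without it, tens of seconds of genuine pause can
   be misclassified as slow movement because the merged segment's net
   displacement creeps past one pixel.
5. **Classification and statistics** (`classify_segment`,
   `time_fractions`, `count_directional_switches`,
   `weighted_velocity_distribution`): a pause moves strictly less than
   one pixel (73 nm, via fitted velocity × duration); directional
   switches are immediately adjacent opposite-direction moving segments
   (a pause-skipping variant is available behind a flag, since the
   published definition is ambiguous on intervening pauses); duration
   weighting expands each segment into `round(duration)` one-second
   velocity samples, excluding pauses by default.
6. **Dwell-time fits** (`fit_exponential`): the exponential MLE (the
   sample mean; censoring not modelled) with a nonparametric bootstrap
   95% interval (percentiles of resample means, 1000 resamples by
   default).

`distribution_peak` reports the mode of a Gaussian KDE; the default
bandwidth is Silverman's rule, which adapts from the sharp near-zero
peak of the reference condition to the broad distributions of the
slow-rebinding variant. For broad, plateau-topped distributions the KDE
mode is unstable between near-tied bumps, so distribution *centers* are
better summarised by the median.

## The synthetic-trace generator

The generator exists so the pipeline can be validated end to end with
known ground truth; it emulates the statistical structure of the TIRF
data, not its raw images.

* `gen_segmented_trace`: piecewise-linear latent paths from an explicit
  velocity/duration plan, sampled at the frame grid with i.i.d. Gaussian
  localisation noise (default $\sigma = 20$ nm, a typical figure for
  this kind of tracking rather than a measured precision; it is a
  config knob).
* `gen_ddb_state_trace`: DDB's alternating processive/stuck renewal
  process. Defaults: stuck dwells exponential with mean 2.8 s, long-run
  stuck fraction 0.26 (the processive dwell mean follows from renewal
  theory), processive sojourn velocities $N(-360, 50)$ nm/s — DDB's own
  unloaded speed, since the stuck/processive alternation describes DDB
  stepping, while near-zero *pair* velocities arise from the tug-of-war.
  An optional diffusive third state (zero drift, configurable diffusion
  coefficient) is off by default because the pipeline does not classify
  diffusion.
* `gen_population`: a fast/slow mixture emulating the two-peaked trace
  velocity structure (52% fast, fast velocities $N(504, 80)$ nm/s —
  a lightly loaded kinesin-1 —, fast durations exponential with mean
  3 s, slow durations with mean 22 s, truncated and flagged as censored
  at the 100 s imaging window).

What passing tests on synthetic data do **not** show: robustness to
drift, photophysics, two-channel registration error, or DDB's genuinely
diffusive episodes — none of which the generator emulates.

### Inherent resolution limit of the pause statistics

With 3-frame minimum segments, stuck dwells shorter than 0.858 s cannot
be called, and knife-edge cases (long pause-dominated segments whose net
displacement is just over one pixel) lose further pause time. With the
default generator settings the full pipeline recovers a true 26%
stuck-time fraction as roughly 24–26% depending on the batch — the same
direction and size of underestimate that manual analysis of real data
shows when compared against high-resolution tracking. This is a property
of the measurement rules, not a bug.

## Numerical and reproducibility choices

* Continuous positions with 8 nm increments; the two motors may pass
  each other (no lattice exclusion), and springs are linear and
  bidirectional. A tension-only linkage is deliberately *not* the
  default: the stated model is a linear spring.
* Both motors start attached at position 0 (zero initial tension); the
  long-run velocity statistics at 50 s are insensitive to this.
* Ensembles derive per-run seeds from a master seed
  (`simulate_ensemble`), so results are reproducible independent of
  evaluation order; single draws use R's global RNG and `set.seed()`.
* Degenerate inputs: traces shorter than one segment return a
  single-segment set with a warning; zero total rate (impossible while
  any motor can act) is an error; empty velocity samples are errors.

## Problem sizes used in the shipped tests

The test suite and acceptance script run the reference protocol at full
scale — 1000 runs × 50 s per condition (about 4–7 × 10^6 events per
ensemble) — which completes in seconds thanks to the compiled SSA core.
Statistical properties use 100-trace batches (pause-fraction recovery),
200 repetitions (bootstrap coverage), 5000 runs (unloaded-motor
recovery, keeping Monte-Carlo error well inside the stated bands), and
10^5 draws (SSA frequency checks).

## Known limitations

* Exactly one kinesin and one DDB; no motor teams, no sub-step
  mechanochemistry, no vertical force geometry.
* The published simulated distribution centers for the slow-rebinding
  (5 s$^{-1}$) variant are matched in order and spacing but sit 30–45
  nm/s more negative here for DDB-Kin1/2; the discrepancy traces to the
  tabulated DDB forward rate (see the parameter quirk above) and to
  reading centers off broad distributions. The reference-parameter
  velocity peak and the DDB-Kin3 variant agree with the published
  values.
* Censored dwells are dropped, not modelled, in exponential fits.
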
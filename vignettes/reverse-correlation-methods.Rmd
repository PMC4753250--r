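---
title: "Methods: reverse correlation of larval run-turn navigation"
author: "larvarc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse correlation of larval run-turn navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvarc)
```

## The problem

Drosophila larvae navigate by alternating two behavioural states: *runs*
(forward peristaltic crawling) and *turns* (head-sweeping reorientation).
When a sensory neuron is driven optogenetically with a random flickering
light, the way the larva's run/turn switching follows the light reveals how
that neuron's activity is read out by the navigation circuit. `larvarc`
implements the complete analysis chain for such experiments —
event-triggered stimulus averages (reverse correlation), step-response
transition probabilities, calcium-trace ΔF/F quantification and two-choice
preference statistics — together with a population simulator with known
ground truth, so that every stage can be validated end to end without any
recorded data.

## Reverse correlation of behavioural transitions

The stimulus is a Bernoulli flicker: each camera frame (4 Hz, shared clock
with the LEDs) is ON independently with probability $p$ (default 0.5).
Encoded as $s_t \in \{-1,+1\}$ (ON $= +1$), this is a white process, so the
average stimulus preceding an event is an unbiased estimate of the linear
filter linking stimulus to that event type.

`detect_transitions()` records an event at the first frame of each new
state, for consecutive valid frames only; a state change spanning a
tracking gap is discarded because its initiation frame is unknown.
`triggered_average()` then averages $s$ over the window $[-W, 0]$ before
each event (default $W = 20$ s, comfortably longer than any plausible
filter memory at 4 Hz). Lag 0 is the initiation frame itself — "the
stimulus preceding the initiation" includes the decision frame. Events
whose full window precedes the session start are excluded rather than
padded: padding would bias the average toward the imputed value, exclusion
is unbiased and the count is reported.

### The error band and the shared-stimulus correction

All animals in the arena see the *same* light. At a fixed lag, two events
from different animals that occur on the same frame therefore contribute
the *identical* stimulus value, and the naive "SD over events /
$\sqrt{n}$" standard error understates the sampling variability of the
average — in a typical session (120 animals, a transition every few
seconds) by nearly a factor of two, which would make a nominal 95% error
band cover the truth only about two thirds of the time. The default SEM is
therefore *frame-clustered*: per-event residuals are summed within each
contributing frame before the variance is formed,

$$\widehat{\mathrm{Var}}(\overline{s}_l) \;=\;
\frac{1}{n(n-1)} \sum_{f} \Big(\sum_{e:\,t_e + l = f} (s_f -
\overline{s}_l)\Big)^{\!2},$$

which reduces *exactly* to the naive per-event formula whenever no frame is
shared (`sem_method = "event"` keeps the naive version available for
comparison). The package's null-calibration test verifies the nominal
coverage: under a stimulus-independent population the ±1.96·SEM band
covers zero at ~95% of lags across hundreds of simulated sessions.

### Step responses and the z-test validity rule

For a light step (OFF→ON), `step_transition_probability()` bins the session
into 0.25-s bins and computes, per bin, the number of animals initiating a
run→turn transition divided by the number of animals in the arena. An
animal counts toward a bin's denominator when its track is valid there, so
tracking loss shrinks `n_at_risk` explicitly — the alternative (a fixed
nominal count) is not what a tracker actually delivers. The peak post-step
bin is compared against the mean pre-step bin probability with a one-sample
z-test (normal approximation to the binomial), one-sided by default because
the scientific claim is an *increase* in turning; the approximation is
flagged valid only when $np \ge 5$ and $n(1-p) \ge 5$ at the peak. No
multiple-testing correction is applied across bins — only the peak is
tested — but the peak-selection step is visible in the output so users see
the implicit selection. If the baseline probability is exactly 0 or 1 the
z statistic is undefined and reported as `NA` with `valid = FALSE`.

## The generative model behind the simulator

No behavioural model is needed to *analyse* data, but validating the
analysis requires ground truth. The simulator uses the minimal model under
which reverse correlation is exact: a linear–nonlinear hazard model of the
two-state chain. Per frame,

$$P(\text{run} \to \text{turn at } t) \;=\;
\min\!\Big(1-10^{-6},\; \lambda_{rt}\,\Delta t\,
\exp\Big(\sum_{l=0}^{L} k_l\, s_{t-l}\Big)\Big),$$

and symmetrically for turn→run with the kernel scaled by
`turn_filter_sign` (default −1, so light that triggers turns also prolongs
them — producing the opposing run→turn vs turn→run triggered averages seen
in aversive phenotypes). With an exponential nonlinearity and i.i.d. ±1
stimulus the lags decouple, and the triggered average at lag $-l$ equals
$\tanh(k_l)$ exactly — so filter recovery has a closed-form target, up to
the mild $\tanh$ saturation.

Defaults, chosen once as field-realistic values: baseline hazards
$\lambda_{rt} = 0.1\,\mathrm{s^{-1}}$ (10-s mean runs) and $\lambda_{tr} =
0.5\,\mathrm{s^{-1}}$ (2-s mean turns); aversive kernel $k_l = 0.4\,
e^{-l\Delta t/1\,\mathrm{s}}$ over 5 s of lags. Pre-session stimulus
history is imputed as OFF (−1), matching dark rearing before the lights
start. Hazards are clipped at $1 - 10^{-6}$ per frame instead of erroring,
so extreme-parameter property tests remain runnable; a warning reports the
clipped fraction when it exceeds 1%. At a 0.25-s frame the run lengths are
geometric rather than exponential; the two agree to $O(\lambda \Delta t)$
and the test suite checks the exponential shape on the continuous
reconstruction (uniform within-frame jitter) at the exactly corresponding
rate $-\log(1-\lambda\Delta t)/\Delta t$.

What the simulator deliberately does *not* model: arena geometry, head-sweep
kinematics, taxis gradients, tracking noise or animal-to-animal parameter
heterogeneity. Passing the recovery tests therefore shows the *analysis* is
correct under its stated assumptions, not that real larvae follow an LNP
model.

## Calcium imaging ΔF/F

Traces follow a 100-frame water wash, 200-frame stimulation, ≥100-frame
wash protocol at 85 ms per frame. `compute_dff()` takes $F_0$ as the mean
of five frames of the unstimulated phase — by default the five frames
immediately preceding stimulation onset (frames 95–99), the choice that
minimises bleaching bias in the baseline; any five pre-stimulus frames can
be designated. $F_{peak}$ is the raw maximum during stimulation (an
optional moving-average pre-filter exists but is off by default, since the
plain formula uses the raw maximum), and
$\Delta F/F(\%) = 100\,(F_{peak}-F_0)/F_0$. The statistic is invariant
under gain rescaling of the whole trace and *not* under additive offsets
(an offset $c$ rescales it by $F_0/(F_0+c)$) — both properties are tested
explicitly, documenting the formula's behaviour rather than assuming it.

Bleaching is handled the way the experimental design handles it: not by
detrending, but by testing each tastant response against the *distribution*
of water-only ΔF/F values from the same neuron class
(`water_baseline()`), which absorbs bleach-induced and other systematic
shifts. `test_response()` runs a Wilcoxon signed-rank test on animal-paired
samples (matched by names); when the samples cannot be paired it falls back
to the rank-sum test with a warning. Significance stars follow the
conventional three levels (0.05, 0.01, 0.001). Exact p-values are used for
n < 25 without ties, the normal approximation otherwise.

The synthetic trace generator uses a double-exponential transient
(rise 3 frames, decay 25 frames — a slow genetically encoded indicator
under sustained tastant flow), multiplicative per-frame bleaching
(default 0.9995) and Gaussian noise with SD 2 intensity units on an
$F_0$ of 100, i.e. 2% noise. That noise level was fixed once so that a 30%
responder against an 8-animal water baseline is detected in well over 80%
of replicates while the null test holds its nominal size; both properties
are verified in the test suite at those recorded parameters.

## Two-choice preference statistics

The preference index of an assay is $PI = (N_{stim} - N_{ctrl})/(N_{stim} +
N_{ctrl})$: larvae still in the neutral midline zone have not expressed a
choice and are excluded from the denominator (an alternative total-count
denominator is available by flag). Group comparisons use the Wilcoxon
rank-sum test (signed-rank for paired designs) with the same star
convention. The synthetic assay draws multinomial counts over (neutral,
stimulus side, control side) per plate of 30 larvae; with 15 assays per
group — the scale of a typical genotype panel — a true side preference of
0.75 versus 0.5 is detected in well over 90% of replicates.

## Numerical and design choices

* Frames are 0-based and windows half-open, stated once and tested
  everywhere; stimulus and tracks share one clock and mismatches are
  errors, not resampling opportunities.
* All generators are pure functions of (parameters, seed); fixed-seed CLI
  runs are byte-identical, which the tests assert on whole output
  directories.
* Identical paired samples in the response test yield $p = 1$ (no
  evidence of a shift) rather than an undefined value.
* PI is an error, not `NaN`, when no larva chose either side.
* Test problem sizes: the null-calibration study uses 500 sessions of 120
  animals × 600 s; filter recovery and step response use 20 seeded
  replicates each; Wilcoxon calibrations use 1000 null replicates. The
  acceptance script recomputes the same quantities at comparable sizes
  from a user-supplied seed.

## Known limitations

* The triggered average estimates the filter only up to the $\tanh$
  saturation of the exponential-nonlinearity model; no GLM fitting or
  second-order (covariance) analysis is provided.
* The frame-clustered SEM corrects for stimulus sharing *within* a lag; it
  does not model correlation between lags, so the band is pointwise, not
  simultaneous.
* Tracker output schemas vary; the TSV layout here is this package's
  convention, not a standard.
* The analysis consumes state labels; everything upstream of them (video
  tracking, posture analysis, ROI extraction) is out of scope.
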
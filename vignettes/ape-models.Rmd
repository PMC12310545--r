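---
title: "Modelling value-free action prediction errors in striatal dopamine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling value-free action prediction errors in striatal dopamine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apemodel)
```

## The scientific problem

Dopamine in the ventral striatum (VS) is well described as a reward
prediction error (RPE): the difference between received and predicted
reward. Dopamine in the tail of striatum (TS), which receives auditory
cortical input, behaves differently: it responds to movements, not
rewards, and its response declines as an action becomes habitual. This
package implements, as testable simulations and analyses, the
computational account of that signal as a value-free **action prediction
error (APE)** — the difference between the action taken and the degree to
which that action was already predicted for the current stimulus — and
the analysis pipeline used to characterise such signals in
fiber-photometry data.

Everything runs on synthetic data with known ground truth; no recordings
are required.

## The semi-Markov actor–critic agent (`simulate_learning`)

The agent is an actor–critic with a semi-Markov state representation:
it tracks its current task state and the dwell time spent there, and
updates only at state transitions. Within a trial the state sequence is
Start → cue (high tone / low tone / white noise) → action state (one per
cue–action pairing, aligning signals to the time of action) → outcome →
Start, with actions Left, Right, Centre and Idle.

At transition $k$ the dwell-scaled average-reward RPE is

$$\delta_k = r_{k+1} - \rho_k d_k + \hat V(s_{k+1}) - \hat V(s_k),$$

where $\rho_k$ is the average reward per unit time over the trailing 500
transitions (a growing window while history is shorter) and $d_k$ the
dwell time in the departed state; the time-cost term $\rho_k d_k$ plays
the role of temporal discounting. The critic and actor update as
$\hat V(s_k) \mathrel{+}= \alpha\delta_k$,
$\hat m(s_k,a_k) \mathrel{+}= \beta\delta_k$ with
$\alpha = \beta = 0.005$, and choices are softmax in the actor strengths
(inverse temperature 5; 0.5 for the previous-choice analyses, where
exploratory behaviour is needed to observe both repeats and switches).
The modelled dopamine observation is the rectified output
$\sigma(\delta_k + \psi)$ with baseline $\psi = 0.2$.

The value-free learner maintains stimulus–action strengths $A(s)$.
When action $a_k$ is taken, the APE is the rectified taken-action
component of $a_k - A(s)$ — a non-negative scalar, matching the absence
of dips in TS dopamine at action time — and
$A(s) \mathrel{+}= \varepsilon\,\delta_{a_k}$ with $\varepsilon = 0.01$
(0.001 in the predicted-value simulation, reflecting a slowly updating
value-free controller). After $k$ consecutive identical pairings the APE
is exactly $(1-\varepsilon)^{k-1}$, which the tests verify to machine
precision; this exponential decay with repetition is the model's core
signature of habit formation.

Alternative accounts are computed alongside: **novelty**
$N(s) = e^{-\gamma I(s)}$ with visit counter $I(s)$ and $\gamma = 0.01$
(the printed form of this equation in the source literature has the sign
inside the exponential, which would grow with exposure and contradict
its stated decay; we implement the decaying form), **salience**
$L(s) = \hat V(s)/\mu + N(s)$ with $\mu = 0.5$, and a **movement**
model (a one-hot vector over actions). `condition_battery()` tabulates
the direction of change of each candidate signal under the five
manipulations (learning, previous choice, state change, outcome value,
predicted value).

Dwell times are not published; we use independent log-normals with
medians 0.2 s (pre-cue centre hold — the Start state), 0.7 s
(cue/decision), 0.68 s (choice movement, the reported mean movement
duration) and 2.5 s (outcome consumption and return). Charging the long
inter-trial interval to the Start state instead would bury cue value
under the average-reward time penalty; allocating it to the outcome
state matches what the animal is doing during that time. Manipulation
sessions (state change, and the battery) pretrain agents for 1,000
standard trials before the logged session, because the corresponding
experiments were performed in trained animals and the cue-locked RPE
direction requires a converged critic.

## The dual-controller network (`run_experiment`)

A two-state, two-action network combines a value-based controller (actor
$W_{actor}$ and critic $W_{critic}$, updated by
$\delta_{RPE} = r - W_{critic}s$ with rate $\alpha = 0.04$) and a
value-free controller ($W_{tail}$, updated by $\delta_{APE}$ with rate
$\beta = 0.02$). The total drive is
$A_{total} = W_{actor}s + W_{tail}s + \text{noise}$ with independent
uniform(0,1) noise per action, and the action is the argmax. The APE is
$1 - p_a[a]$, where $p_a$ low-pass filters (time constant
$\tau_{tail} = 100$) the binarised tail output. The actor decays towards
its steady state of 1 with $\tau_{decay} = 100$; all weights are clipped
at zero. Performance is the reward low-pass filtered with time constant
10, starting from 0.5.

**Time semantics.** The source description mixes trials, sub-trial
timesteps and absolute inactivation times without a conversion. We
integrate all relaxation terms by forward Euler with one time unit per
trial ($dt = 1$): with the time constants in trial units the model shows
the characteristic transfer of control (the actor learns first and then
decays to symmetry while the tail accumulates), whereas with
$\tau = 100$ sub-trial timesteps the filters would relax fully between
choices and no transfer occurs. `steps_per_trial` exposes the other
reading. Inactivation times (30, 100, 1,000) are in the same trial
units, with sessions extended past the latest lesion.

**Trials to criterion.** Learning speed is compared by the first trial
at which filtered performance reaches 0.75 *and holds it for 100
consecutive trials* (`trials_to_criterion(..., sustain = 100)`), the
usual sustained criterion in learning studies. A bare first crossing is
uninformative here because paired runs share their random streams and
cross transiently at identical trials.

**Stimulation.** The optogenetic excitation protocols coupled light to
the animal's port choice, after a 150-trial unstimulated baseline.
Accordingly `run_experiment("stimulation")` doubles $\delta_{APE}$ on
trials where the contralateral *action* was chosen, from trial 150
onward, in sessions using the seven-level psychometric stimulus set
(ambiguous trials keep choice exploratory, so the induced bias can keep
expressing itself; in the binary task choices saturate and matched runs
become identical). Doubling on contralateral-*stimulus* trials instead
(`stim_trigger = "stimulus"`) is action-symmetric — it reinforces
whatever was chosen, including errors — and produces no reliable bias;
we keep it available for comparison.

## Photometry processing (`preprocess_photometry`, `fit_kernels`)

The preprocessing pipeline is: width-5 median filter and zero-phase
order-2 Butterworth low-pass at 10 Hz (both channels); 0.001 Hz
high-pass for photo-bleaching; linear regression of the background
(isosbestic) channel onto the signal channel, subtracting the fitted
component (motion correction); division by the 0.001 Hz low-pass
baseline of the denoised, pre-high-pass signal channel (dF/F; a switch
selects the post-high-pass channel); z-scoring. Orders and widths are
implementation choices — only the cutoffs are prescribed. The 0.001 Hz
filters are bidirectional single-pole exponential smoothers: a
discretised Butterworth at a normalised cutoff of $2\times10^{-5}$ is
numerically unstable (it fails to preserve DC), while the single-pole
form is exact and stable. Degenerate traces (zero variance after
processing) return zeros with a warning. Carrier-modulated acquisitions
(211 / 531 Hz) are recovered by quadrature lock-in demodulation with a
20 Hz product low-pass, chosen well below the carrier spacing.

Event kernels are estimated by ordinary least squares on a
lagged-indicator design: the predicted signal is an intercept plus, for
each event type, the event train convolved with an unknown kernel on a
window of −0.5/+1.5 s (choice movement), 0/+1 s (cue, outcome) and
−0.2/+1.5 s (return). Event times are rounded to the nearest sample.
Rank-deficient designs (e.g. perfectly regular event spacing) fall back
to the minimum-norm solution with a warning. Per-regressor importance
removes that regressor's fitted contribution *without refitting* and
reports $(v_{full} - v_{partial})/v_{full} \times 100$; because OLS
optimised the full prediction, $v_{partial} \le v_{full}$ and the
percentage is non-negative, but it can exceed 100 when the partial
prediction underperforms the intercept. Optional "trimming" scores only
samples inside some kernel window around an event; the union of kernel
windows is our epoch definition, as no exact one is published.

## Behavioural statistics (`fit_weibull`, `shuffle_bias_test`, ...)

Learning curves use the modified Weibull form
$\text{performance} = 50 + a(1 - 2^{-(t/l)^s})$, fitted by
Levenberg–Marquardt least squares with five log-spaced multi-starts in
$l$ (tolerance $10^{-8}$; a bounded quasi-Newton fallback covers flat
data where the scale and shape are unidentifiable). Maximum performance
is the maximum of 200-trial-binned medians of the trailing 100-trial
running performance; the maximum learning rate is the analytic maximum
of the fitted derivative over the observed trial range, in percent per
trial. Standard cleaning (sessions under 60 trials, first 5 trials,
inter-trial intervals over 3× the session median) is provided by
`clean_learning_trials()`.

The optogenetic bias test compares, per trial type, the reference-port
choice proportion of stimulated trials to a 1,000-draw null of matched
size; the session bias averages stimulated-minus-unstimulated
proportions over types. The default null permutes the stimulated labels
within the type (drawn as the equivalent hypergeometric counts), which
is exact under the no-effect hypothesis; drawing subsets from the
unstimulated trials only (`scheme = "subsample"`) is also available but
is anticonservative when stimulated trials are a sizeable fraction of
the session, because the observed contrast then has variance
$(N+m)/(N-m)$ times the null's.

Perceptual uncertainty enters the repeat/switch logistic regression as
$-\log(2|p_{high} - 0.5| + 10^{-3})$ — zero at the category boundary,
increasingly negative for easy stimuli; no numeric definition is
published, so this choice is explicit and floored to keep the ambiguous
stimulus finite. Dopamine responses split into large/small at the 65th
percentile for the binned summaries. Trajectory similarity uses the
discrete Fréchet distance computed by the memoised coupling recurrence;
the continuous distance is out of scope.

## The synthetic-data generators (`generate_photometry`, ...)

Synthetic sessions compose: gamma-shaped event kernels (amplitude,
latency, width — kernel shapes are shown but not parameterised in the
literature, and a gamma bump is the standard smooth transient); a
double-exponential bleaching trend (time constants 1,200 and 300 s —
bleaching slow enough that the 0.001 Hz high-pass is the appropriate
remover, which is the premise of that pipeline step); a shared
band-limited motion artifact; and white noise. Both contaminations enter
each channel through the same multiplicative coupling, so their
channel gains share one brightness ratio (0.8 by default) — this is
precisely the regime isosbestic correction is designed for, and the
reason a single background regression can remove the artifact. The
background channel carries no event signal. Cohort generators draw
Bernoulli outcomes from known Weibull curves; the linked-dataset
generator injects one agent's per-trial APE values as choice-locked
transient amplitudes, with jittered self-paced event timing (regular
spacing would make the kernel design collinear), planted kinematic
contributions, and a planted negative coupling between the response and
the next trial's trajectory displacement.

What the generators do **not** emulate: hemodynamic or pH artifacts,
sensor nonlinearity and saturation, video-based pose estimation error,
session-to-session drift, and animal-to-animal heterogeneity beyond
parameter choices. Passing tests therefore validate the estimators
under the model's own assumptions, not robustness to every property of
real recordings.

## Problem sizes and numerical choices

Simulation sizes are chosen so the full suite runs on one CPU in a few
minutes: 100 agents for the signal-model batteries (300-trial sessions;
1,000 pretraining trials where a converged critic is required), 100
networks × 1,000 trials for the chance-level check, 12 paired seeds for
the learning-speed comparison, 20 seeds for lesion and stimulation
contrasts, 1,000 null sessions × 200 shuffles for the bias-test
calibration, and 240 s photometry sessions at 50 Hz (2,500 Hz × 20 s
when carrier-modulated). Ties in argmax choices break to the lower
index (measure-zero under uniform noise). All simulations are seeded
(one stream per agent, `seed + agent − 1`) and bit-reproducible.

## Known limitations

* The semi-Markov agent's policy uses the actor only; the
  stimulus–action learner is observational here, and the choice-biasing
  role of the APE lives in the dual-controller network.
* Average-reward differential values are defined up to an additive
  constant pinned only by the learning transient, so cue-locked RPE
  contrasts are meaningful only for trained agents.
* The dual-controller model is a two-state abstraction; it does not map
  weights onto D1/D2 pathways or model within-trial dynamics.
* Explained-variance percentages from the drop-one procedure are
  comparative, not a variance decomposition; they need not sum to 100.
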
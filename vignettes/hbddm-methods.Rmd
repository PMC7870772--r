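---
title: "Hierarchical diffusion modelling of perceptual decisions with EEG covariates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hbddm` analyses two-choice perceptual decisions — here, the direction of
coherent motion in a random-dot display — with the simplified 4-parameter
diffusion model. Evidence accumulates from a starting point $\beta\alpha$
toward absorbing boundaries at $0$ and $\alpha$ with drift $\delta$ and unit
diffusion coefficient; the response time is the first-passage time plus a
non-decision time $\tau$. "Up" responses are coded as hits of the upper
boundary, "down" responses of the lower boundary, and on downward-motion
trials the drift is sign-flipped, so $\delta$ is always the rate of
accumulation toward the *correct* boundary. Between-trial variability
parameters are deliberately excluded: they are poorly identified at the
trial counts obtainable from children.

The hierarchy places truncated-normal population distributions over the
participant-level parameters:

* $\alpha_p \sim \mathrm{TN}(\mu_\alpha, \sigma_\alpha)$ on $[0.2, 4]$,
* $\beta_p \sim \mathrm{TN}(\mu_\beta, \sigma_\beta)$ on $[0.001, 0.999]$,
* $\tau_p \sim \mathrm{TN}(\mu_\tau, \sigma_\tau)$ on $[0.1, 2]$ s,
* $\delta_{pc} \sim \mathrm{TN}\!\big(\mu_\delta + \sigma_\varepsilon
  [(Q\theta)_c + \textstyle\sum_j b_j z_j(p)],\ \sigma_\varepsilon\big)$
  on $[0, 8]$.

$Q$ is the orthonormal sum-to-zero contrast matrix from
`sum_to_zero_design(k)`, mapping $k-1$ free standardized condition effects
$\theta$ to $k$ offsets that sum to zero; with three coherence conditions
there are two free effects. Covariates $z_j$ (z-standardized age and EEG
ramp slopes) shift the participant-level means on a standardized scale:
each weight multiplies the relevant group SD ($\sigma_\varepsilon$ for
drift, $\sigma_\alpha$ or $\sigma_\tau$ for boundary and non-decision
time), so posterior weights are comparable across parameters and to
standardized regression coefficients. The twelve covariate layouts
compared in the workflow are enumerated by `model_family()`.

Priors on the group means are normal, truncated to each parameter's bounds:
$\mu_\alpha \sim N(1.0, 0.5^2)$, $\mu_\beta \sim N(0.5, 0.125^2)$,
$\mu_\tau \sim N(0.4, 0.3^2)$, $\mu_\delta \sim N(2, 1.5^2)$; group SDs are
half-normal with scales $0.5, 0.125, 0.3$ and $1.0$. These are the
package's own defaults, centred on typical values from surveys of fitted
diffusion parameters, and are fully configurable via `hbm_priors()`.
Regression weights carry a Zellner–Siow-style mixture of g-priors,
$b_j \sim N(0, g)$, $g \sim \mathrm{IG}(1/2, 1/2)$, with unit scale because
covariates are standardized; a single $g$ is shared by all weights in a
model. Condition effects get $\theta_n \sim N(0, 1)$.

## Sampling

`sample_posterior()` runs an adaptive Metropolis-within-Gibbs sampler
written in C++: every scalar parameter takes a random-walk proposal whose
step size is tuned toward a 0.44 acceptance rate in batches of 50 sweeps
during burn-in and frozen afterwards; group SDs walk on the log scale with
the Jacobian included; $g$ has a conjugate inverse-gamma Gibbs update.
Truncated-normal densities always include their normalising constants, so
hyperparameter updates correctly account for boundary truncation — this is
what lets the location-scale regression recover covariate weights without
attenuation even when the drift distribution presses against the lower
bound. Starting values are drawn uniformly over admissible ranges (with
each participant's non-decision time started below their fastest response).
The deviance $-2\sum\log f$ at the current participant-level parameters is
recorded at every retained draw.

The kernel was validated three ways: a conjugate-normal oracle for the MH
stepper, parameter-recovery studies on synthetic cohorts with known truth,
and calibration of posterior credible intervals. Two profiles ship with
the package: the production profile (3 chains × 54,000 samples, 4,000
burn-in, thin 5) and `reduced_settings()` (3 × 5,000, 1,000 burn-in,
thin 1 = 4,000 retained per chain), which the tests, the analysis scripts
and the acceptance script use. The test-suite problem sizes (e.g. 40
participants × 3 conditions × 90 trials for recovery studies, smaller
cohorts for smoke tests) were chosen so a full run stays in the minutes
range on one core.

Model comparison uses the deviance information criterion with the deviance
focused at the participant level (the level whose parameters enter the
likelihood): $p_D = \bar D - D(\bar\vartheta)$ with $\bar\vartheta$ the
posterior means of the participant-level parameters, and
$\mathrm{DIC} = \bar D + p_D$. This matches the focus JAGS-style samplers
report for such hierarchies. Note a consequence seen both in our
simulations and in published tables of this kind: with many trials per
participant, participant-level parameters are pinned by the likelihood, so
a covariate that only sharpens the *hierarchy* moves DIC by a few points at
most, and DIC differences of that size are unstable under sampling
variability. The comparison table therefore also reports the residual
regression variances, which discriminate more directly.

## Screening

`apply_basic_exclusions()` removes catch trials, responses at or beyond the
2.5 s deadline and the excluded hardest coherence condition.
`ewma_cutoff()` sorts each participant's remaining trials by RT (pooled
across conditions; ties broken stably by trial index) and runs an EWMA
control chart over the accuracy sequence with $\lambda = 0.1$, $c_0 = 0.5$,
$\sigma_0 = 0.5$, $L = 1.5$: the cutoff is the first trial at which the
statistic *strictly* exceeds the upper control limit, trials faster than
the cutoff trial are discarded and the cutoff trial itself is kept. Both
readings ("first strict crossing", "keep the cutoff trial") were genuinely
open; they are the package's choices and are configurable.
`screen_participants()` then drops participants below 60% retention and
operationalises "responding substantially below chance" as a one-sided
exact binomial test at $\alpha = 0.05$ — the published analyses excluded
such participants qualitatively, so a concrete criterion had to be fixed
here.

A measured property of this chart worth knowing: with a 1.5σ control limit,
a long run of pure guesses at the head of the RT-sorted sequence triggers a
false alarm (a transient crossing sustained by chance) roughly 40–50% of
the time, which truncates the exclusion early. In our contamination studies
the filter therefore captures on average ~58% of injected fast guesses when
they make up 20% of 216 trials (~67% at 120 trials, ~80% at 60; medians
0.66/0.83/1.00), rather than all of them; at the ~5–10% contamination rates
typical of real cohorts the guess run is short and capture is much higher.
We also evaluated an alternative cutoff rule — the last trial at which the
statistic is still at or below the limit — which captures ~94% of guesses
but is unusable in practice: late dips of the statistic driven by the slow,
low-accuracy hardest condition truncate almost half of clean participants
below the 60% retention bar. The first-crossing rule is therefore the only
rule shipped.

## EEG pipeline

The cleaning steps follow the order: per-trial median DC correction;
outlier-electrode flagging (fraction of $|x|$ samples above the pooled
97.5th percentile reaching 15%, per session and again per trial after EOG
regression); interpolation by the mean of the nearest 6 good neighbours (4
for perimeter electrodes), using supplied adjacency metadata rather than
recomputed 3-D geometry; OLS regression of HEOG/VEOG out of every
electrode; censoring of samples ≥ 4 SD from their electrode mean; average
referencing; baselining; and exclusion of trials with ≥ 19 removed
electrodes. For purely response-locked synthetic epochs there is no boil
period, so the baseline window defaults to the first 100 ms of the epoch —
a documented divergence from boil-locked baselining; real data should pass
the boil-locked window explicitly. Response-locked re-epoching cuts
−600..+200 ms around each response (400 samples at 500 Hz, the response
sample at $t = 0$).

Reliable components analysis finds electrode weightings $w$ maximising the
ratio of across-trial to within-trial covariance,
$R_{xy} w = \rho R_{xx} w$, with $R_{xy}$ the trial-pair cross-covariance
averaged over ordered pairs (computed in $O(T)$ via the sum identity) and
symmetrised. The eigenproblem is regularised by projection onto the
leading principal components of $R_{xx}$; the default rank is the smallest
capturing 99% of variance, a choice the original method leaves open.
Missing samples are handled by pairwise-complete normalisation. Components
are oriented so the grand-average time course is positive at the response,
and "explained reliability" is each eigenvalue over the sum of *positive*
eigenvalues — the normalisation of "total reliability" is another open
point; normalising by all eigenvalues would make the fractions slightly
larger. Forward models $A = R_{xx}W(W^\top R_{xx}W)^{-1}$ visualise
components as topographies.

## Regression windows and slope covariates

Windows are computed per group from the grand-average component waveforms.
For the centro-parietal component: the end is the mid-latency of the
positive peak (mean of the two 90%-of-peak crossing latencies, linearly
interpolated between samples), and the start is the latest pre-end crossing
of 30% of the waveform's amplitude at the mid-latency. For the biphasic
occipital component: peaks are searched in −600..+100 ms and the window
runs between the mid-latencies of the negative and positive peaks. Where
several 30% crossings exist the one nearest the window end is used, and
thresholds are relative to the grand average (not per participant) — both
points the procedure leaves open. Per-participant slopes are OLS fits of
the participant's average component waveform inside the group window, in
µV/s, and enter the models z-standardized.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is verified. Behaviour: participants'
parameters are drawn from the same truncated-normal hierarchy the model
assumes (ages uniform over 6–12 years for children; standardized age
effects default to 0.45 on drift and −0.10 on boundary and non-decision
time, matching the magnitudes the method is expected to detect), and every
trial is simulated from the first-passage process by Euler–Maruyama with a
Brownian-bridge interval-crossing test (plain Euler misses crossings
between grid points, biasing passage times upward by $O(\sqrt{dt})$; the
bridge test reduces this to $O(dt)$, which at the default $dt = 10^{-4}$ s
is below Monte-Carlo noise at $n = 10^5$). Child-like and adult-like truth
presets give per-condition drift means of about (0.8, 1.7, 2.6) and
(2.3, 3.2, 4.1), boundaries 1.6 vs 1.2 and non-decision times 0.45 vs
0.32 s, which reproduce the directional group contrasts (children slower,
less accurate, wider boundaries) at realistic accuracy levels. Fast-guess
contaminants replace a fixed fraction of trials with uniform RTs between
0.15 s and the participant's 10th RT percentile and chance-accurate
choices.

EEG: each trial's epoch is two unit-norm topographies (orthogonalised
Gaussian blobs over midline-posterior and occipital sites of a synthetic
sunflower-layout net) times participant-specific time courses — a linear
ramp from a per-participant onset (uniform in −450..−250 ms) peaking at the
response then decaying, and a biphasic trough-then-peak shape whose rising
limb has the participant's component-2 slope — plus rank-8 spatially
correlated Gaussian noise and sensor white noise. Component-1 ramp slope
is an affine function of the participant's true mean drift plus noise,
with defaults (8 + 6·mean drift ± 7 µV/s) calibrated once so the slope–age
correlation in the default child cohort is ≈ 0.3. No quantitative SNR was
available to emulate, so the noise scales are chosen for testability: they
make two-component recovery measurable without being trivial. What passing
tests show is therefore that the estimators are correct under the model's
own assumptions (linear mixing, Gaussian spatial noise, no artefacts);
they do not show robustness to blinks, muscle artefacts, drifting
electrode impedances or non-linear volume conduction, none of which the
generator emulates.

## Numerical choices

The Wiener first-passage density uses both the small-time and large-time
series expansions with terms truncated at an absolute tolerance of
$10^{-29}$ and an automatic switch to whichever expansion needs fewer
terms; the two expansions agree to better than $10^{-6}$ relative at the
switch point. The zero-drift limit of the absorption probability is
handled explicitly. Degenerate inputs follow fixed rules: densities are
zero at $t \le \tau$, empty trial lists are errors, flat waveforms and
missing 90%/30% crossings are errors naming the side, zero-variance
covariates are errors, and zero-SD electrodes are never censored.

## Known limitations

DIC differences of a few points should not be over-read (see above); the
EEG generator's realism is deliberately limited; the EWMA filter assumes
accuracy is the only contaminant signature, so slow guesses pass it; and
the adaptive MH sampler, while exact in the limit, mixes more slowly than
gradient-based samplers would at much larger cohort sizes — the reduced
profile is sized for the desk-scale cohorts used throughout.
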
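---
title: "An extended leaky competing accumulator for response-frequency effects in the Simon task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An extended leaky competing accumulator for response-frequency effects in the Simon task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simonlca)
```

## The phenomenon and the model

In a Simon task, participants respond to a nonspatial stimulus feature
(say, color) with a left or right keypress while the task-irrelevant
stimulus *location* is congruent or incongruent with the response side.
Responses are faster and more accurate on congruent trials. When the two
responses differ in relative frequency (75% vs 25%), this congruency
(Simon) effect is larger for the frequent response than for the infrequent
one. `simonlca` implements a family of leaky competing accumulator (LCA)
models of this modulation, together with the reaction-time analysis chain
and the simulation-based fitting machinery needed to compare the model
variants.

Two response codes, the correct one and the error one, accumulate evidence
until one reaches the threshold $\theta$. Between stimulus onset and the
decision, the activations $a_1$ (correct) and $a_2$ (error) evolve as

$$
\mathrm{d}a_i = \big[I_i(t) - k\,a_i - \beta\,a_j\big]\,\mathrm{d}t
              + \sigma\,\mathrm{d}W_i, \qquad a_i \ge 0 ,
$$

with leak (self-inhibition) $k$, lateral inhibition $\beta$, independent
Gaussian noise of scale $\sigma$ per $\sqrt{\text{ms}}$, and activations
floored at zero. A residual (non-decision) time for stimulus encoding and
motor execution is added to the threshold-crossing time.

The external input $I_i(t)$ has two parts:

* a **controlled (relevant) input** from the task-relevant feature, onsetting
  at a per-trial temporal lag (`lead`): $\Delta I_{\mathrm{rel}}$ to the
  correct code and $1 - \Delta I_{\mathrm{rel}}$ to the error code. The
  unit sum is the customary scale constraint of the LCA.
* an **automatic (irrelevant) input** from the stimulus location, onsetting
  at stimulus onset ($t = 0$), $+h(t)$ to the code on the stimulus side and
  $-h(t)$ to the other code, with

$$
h(t) = \Delta I_{\mathrm{irr}} \left(1 - \frac{t}{\tau}\right) e^{-t/\tau},
$$

the step response of a critically damped second-order high-pass filter: it
starts at $\Delta I_{\mathrm{irr}}$, crosses zero once at $t = \tau$,
*reverses sign*, and decays back to zero with $\int_0^\infty h = 0$. The
sign reversal — early facilitation turning into late inhibition and vice
versa — is what lets the congruency effect shrink and even invert at long
reaction times, and it is essential for the preparation account of the
frequency modulation: because the irrelevant input *leads* the relevant
one by roughly $\tau$, trials decided early (prepared responses with their
head start) experience a larger net congruency advantage than trials
decided late.

Response preparation is modelled as an initial activation `prep_bias` on
the expected response code. Which response is expected is drawn per trial:
with relative frequencies 75/25 and no cues, the frequent response is
expected with probability $\pi$; with always-valid cues, the cued
(required) response is prepared with class-specific probabilities
$\pi_{\mathrm{freq}}, \pi_{\mathrm{infr}}$.

### Model variants

* **preparation** — frequent and infrequent responses differ *only* in the
  probability of being prepared.
* **+attention** — the relevant input additionally depends on whether the
  stimulus appears on the expected response's side
  (`attention_rel_same` / `attention_rel_opposite`).
* **+contingency** — both the relevant and the irrelevant input depend on
  the irrelevant stimulus location's side (frequent-response side vs
  infrequent-response side), reflecting the location-congruency
  contingencies that unequal response frequencies induce.
* **+shielding** — prepared responses are shielded against distraction:
  their irrelevant input starts weaker (`shield_irr_amplitude`
  $\le \Delta I_{\mathrm{irr}}$) and declines more slowly
  (`shield_irr_tau` $\ge \tau$). The slower decline means the (smaller)
  distraction persists into the decision window, which raises the
  congruency effect of prepared responses at *long* reaction times — the
  mechanism behind diverging delta plots.

Where the shielding trigger was ambiguous (prepared response identity vs
trial expectation state) we attach it to trials whose required response is
the prepared one; the alternative reading differs only in the rare
unprepared-error dynamics. Lateral inhibition acts on the floored (hence
nonnegative) activations, the original LCA convention.

## Default parameters

| parameter | default | units | role |
|---|---|---|---|
| `rel_input` | 0.53 | – | controlled input to the correct code |
| `irr_amplitude` | 0.30 | – | initial automatic input |
| `irr_tau` | 90 | ms | zero-crossing time of the automatic input |
| `lead_mean`, `lead_sd` | 100, 25 | ms | lead of the irrelevant input |
| `leak` | 0.01 | 1/ms | self-inhibition |
| `lateral` | 0.02 | 1/ms | lateral inhibition |
| `noise_sd` | 0.15 | 1/√ms | diffusion scale |
| `threshold` | 25 | – | decision criterion (scale anchor, fixed) |
| `prep_bias` | 6 | – | head start of the expected code |
| `resid_mean`, `resid_sd` | 150, 20 | ms | residual time |
| `dt` | 1 | ms | integration step |
| `max_time` | 3000 | ms | simulator deadline |

The defaults were calibrated *forward* — by simulating and comparing the
summary statistics to the magnitudes typical of the published
response-frequency Simon experiments (mean RTs near 390/430 ms for
frequent/infrequent responses, error rates between 1 and 9%, a Simon
effect around 25–30 ms, a positive frequent-minus-infrequent modulation,
near-parallel delta plots under plain preparation). With lateral
inhibition exceeding leak, the difference between the codes grows
competitively, which keeps errors low at realistic speeds; with
`lead_mean` slightly above `irr_tau`, decisions fall on the declining
branch of the congruency advantage, which is what produces both the
declining delta plots and the modulation of the mean Simon effect by
preparation probability. The modulation the defaults produce (≈ 4 ms at
$\pi = 0.9$, with Simon effects of ≈ 28 vs 24 ms) is smaller than the
16 ms reported for real participants; the package's claims about it are
therefore directional (sign and ordering), not metric.

```{r simon-demo, eval = FALSE}
p <- lca_params()
v <- variant_spec("preparation", pi_freq = 0.9)
set.seed(1)
s <- simulate_condition(p, v, "frequent", "incongruent", 20000)
s
```

## The synthetic-data generator

`generate_synthetic_dataset()` emulates the three study designs:

* **exp1** — 10 test blocks × 48 trials, 16 participants, 75/25 response
  frequencies with equally frequent stimulus locations (480 analyzed
  trials per participant; 180/180/60/60 per condition);
* **exp2** — 2 sessions × 10 blocks × 32 trials, 16 participants (640);
* **exp3** — 8 blocks × 48 trials with always-valid response cues,
  24 participants (384).

Conditions are balanced exactly within blocks (the preset counts divide
evenly; a multinomial fallback covers designs that do not). Cue–stimulus
intervals are a design detail without a model counterpart (preparation is
modelled by $\pi$, not by interval), so they are not simulated.
Inter-participant heterogeneity is a per-participant linear transform of
the RTs (lognormal scale factor, default log-SD 0.08; normal shift,
default SD 20 ms) — precisely the heterogeneity the pooling stage is
designed to undo, with the generating parameters stored alongside for
recovery studies. What the generator does *not* emulate: practice blocks,
feedback-induced strategy shifts, sequential effects (post-error slowing,
congruency-sequence effects), premature responses, and any drift of the
parameters over the session. Passing tests on synthetic data therefore
validates the estimation machinery, not the model's adequacy for any real
dataset.

## The analysis chain

Reaction times are screened once (no iteration) per participant and
condition: below 100 ms or above the sample mean plus three standard
deviations. Quantiles are linear interpolations of the order statistics
(`type = 7`). Delta plots pair the quantiles of the incongruent and
congruent distributions, $\Delta_p = Q_{\mathrm{inc}}(p) -
Q_{\mathrm{con}}(p)$ against $(Q_{\mathrm{inc}}(p) +
Q_{\mathrm{con}}(p))/2$, and are quantified by coefficients of
orthogonal polynomials built on the (unequally spaced) quantile means by
the three-term recurrence. The basis is normalized to unit Euclidean
norm, so `c0` is $\sqrt{n}$ times the mean delta, and the reconstruction
equals the degree-2 least-squares fit; any fixed convention would do for
comparisons across conditions, and this one is exactly orthonormal by
construction.

Cross-participant pooling uses the linear location-scale alignment
$y_{ij} = m_\cdot + (x_{ij} - m_i)\, q_\cdot / q_i$, where $m_i$ is the
participant mean and $q_i$ a robust scale: the $k$-th order statistic of
the pairwise absolute differences with $k = \binom{h}{2}$,
$h = \lfloor n/2 \rfloor + 1$, times the normal-consistency constant
2.2219 without finite-sample correction (the estimator family is fixed by
convention; the constant only sets the scale's units and cancels from the
ratio $q_\cdot / q_i$). Pooling keeps every trial, preserves
within-participant rank order, and reproduces the grand mean exactly.

## Fitting, goodness of fit, and uncertainty

The observed summary per condition is the error percentage and the nine
deciles of the pooled correct RTs; the corresponding bin frequencies
(errors plus ten inter-decile bins) feed the likelihood-ratio statistic

$$
G^2 = 2 \sum_{\text{cond}} \sum_{\text{bins}} O \ln \frac{O}{N p} .
$$

Fitting proceeds in two stages: stage 1 minimizes the root mean weighted
squared deviation of error percentages and quantiles (quantiles in
seconds, error rates as proportions, unit weights — the two families then
live on comparable numeric ranges); stage 2 starts from the stage-1
solution and minimizes $G^2$. Every objective evaluation simulates a
fixed number of trials per condition (default 20,000).

Numerical choices that matter:

* **Integration.** The drift is integrated with a Heun (trapezoidal)
  scheme at `dt` = 1 ms, with the step split exactly at the
  relevant-input onset and floor-exit events interpolated inside the
  step; noise is added Euler–Maruyama fashion, and the threshold crossing
  is linearly interpolated within the step. The noise-free skeleton then
  agrees with a 100-fold finer reference integrator to well under 1 ms;
  a plain Euler step at 1 ms would be off by several milliseconds near
  flat approaches.
* **Common random numbers.** Each trial owns a counter-based RNG
  substream (xoshiro256++ seeded from the master seed and the trial
  index). Under a fixed master seed the objective is a *smooth*
  deterministic function of the parameters; consuming one sequential
  stream instead makes every trial's noise depend on the history of all
  earlier trials and leaves spurious local minima that trap the
  optimizer. The master seed is drawn from the R session RNG, so
  `set.seed()` governs end-to-end reproducibility.
* **Optimizer.** Bounded derivative-free Nelder–Mead on a logit-transformed
  scale, with up to four restart cycles per stage from the incumbent
  (fresh simplex each time; the simplex otherwise tends to collapse
  before reaching the optimum) and optional independent jittered starts
  (default 3; budget-constrained fits use 1).
* **Degenerate bins.** Predicted bin proportions are floored at
  $0.5/N_{\mathrm{sim}}$ (then renormalized) and each application is
  counted, so bins the simulation never reaches cannot produce infinite
  $G^2$.
* **Timeouts.** Trials that reach neither threshold by 3000 ms are
  flagged and excluded, mirroring the empirical pipelines' late-response
  cutoffs.

Because the likelihood is simulated, $G^2$ is itself a random variable;
`aic_distribution()` re-evaluates it (default 100 times at 100,000 trials
per condition) and reports the distribution of $\mathrm{AIC} = G^2 + 2k$,
with $k$ taken from the variant's free-parameter ledger, never hard-coded.
`prediction_intervals()` simulates replicate datasets at the observed
trial counts (default 1000) and returns central 95% intervals for mean
RTs, error percentages and delta plots; only trial-level noise is
resampled, not participant heterogeneity, matching the
equal-trial-counts construction.

## Power utilities

`minimum_sample_size()` and `critical_effect_size()` use the exact
noncentral-$t$ power of a one-sample (paired) test — the convention of
standard power software; within-participant contrasts imply the paired
family. They reproduce the published design numbers: $n = 13$ for
$d = 1$, $n = 24$ for $d = 0.7$ (two-sided, $\alpha = .05$, power .9),
and a one-sided critical $d = 0.767$ at $n = 16$. Note that the exact
two-sided power includes the opposite-tail rejection region that
`power.t.test()` omits (difference below $10^{-3}$).

## Scales used by the shipped checks

The test suite and the acceptance script run at desk scale, chosen to
keep a full run in minutes on one CPU while leaving Monte-Carlo error
well below the margins being asserted: 20,000–50,000 trials per condition
for the directional claims (Monte-Carlo standard error of a mean Simon
effect at 20,000 trials is ≈ 1 ms, against effects of 24–28 ms and
ordering gaps of 3–5 ms), 100,000 for the null-effect bound, 50,000
observed trials per condition and 20,000 per objective evaluation for the
recovery study, and reduced replicate counts for the AIC and
prediction-interval demonstrations. All sizes are arguments, so any
analysis can be rerun at the publication scale (100,000 trials, 100 AIC
replicates, 1000 interval replicates).

## Known limitations

* The preparation mechanism reproduces the *direction* of the
  frequency modulation robustly, but at the default parameters its size
  (≈ 4 ms) is smaller than typically observed (≈ 16 ms); matching the
  size requires either stronger preparation contrast or the shielding
  mechanism.
* Real fitted values (AIC tables, parameter estimates) of the published
  experiments require their raw data, which the package does not ship;
  all quantitative checks run against synthetic data with known ground
  truth.
* The exponential (first-order, non-reversing) irrelevant-input variant
  is not implemented; the sign-reversing form is a structural commitment.
* One- and two-dimensional fits inherit Nelder–Mead's limitations; the
  restart cycles mitigate but do not eliminate premature convergence on
  very flat objectives.
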
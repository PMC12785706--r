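# simonlca

Leaky competing accumulator (LCA) models of the Simon effect and its
modulation by relative response frequency, for cognitive modellers who
want to simulate conflict-task behaviour, analyse reaction-time
distributions, and compare model variants by simulation-based fitting.

## The problem

In a Simon task the irrelevant stimulus location speeds congruent and
slows incongruent responses. When one response is required on 75% of
trials and the other on 25%, the Simon effect is larger for the frequent
response — even though the frequent response is *faster*. Three candidate
mechanisms can produce such a modulation: biased response preparation,
preparation-linked shifts of visual attention, and the location-congruency
contingencies that unequal response frequencies induce. `simonlca`
implements all of them as variants of one accumulator model, plus a
*shielding* variant in which prepared responses are partially protected
against distraction.

## The model

Two response codes accumulate evidence until one crosses the threshold
θ:

    da_i = [ I_i(t) − k·a_i − β·a_j ] dt + σ dW_i ,   a_i ≥ 0

The external input combines a controlled (relevant) input ΔI_rel to the
correct code (1 − ΔI_rel to the error code), onsetting at a variable lag,
with a transient automatic (irrelevant) input from the stimulus location,

    h(t) = ΔI_irr (1 − t/τ) e^(−t/τ) ,

which starts at ΔI_irr, reverses sign at t = τ, and integrates to zero —
early facilitation becomes late inhibition and vice versa. Preparation
gives the expected response code a head start; which response is expected
is drawn per trial with probability π (or set by response cues). The
analysis chain provides outlier screening, quantiles, delta plots with
orthogonal-polynomial coefficients, and cross-participant pooling via a
location/robust-scale alignment; model fitting minimizes an RMS
quantile/error discrepancy and then a G² statistic over quantile-bin
frequencies, both on simulated predictions under common random numbers,
and model comparison uses AIC = G² + 2k over repeated simulations.

## Worked example

Simulate the four frequency-by-congruency conditions of a 75/25 design
under the preparation model with π = 0.9:

```r
library(simonlca)
p <- lca_params()
v <- variant_spec("preparation", pi_freq = 0.9)
set.seed(1)
for (fc in c("frequent", "infrequent"))
  for (cg in c("congruent", "incongruent"))
    print(simulate_condition(p, v, fc, cg, 20000))
```

Output (one CPU, a few seconds):

```
frequent-congruent     mean RT 366.9 ms   errors 1.64 %
frequent-incongruent   mean RT 394.4 ms   errors 2.17 %
infrequent-congruent   mean RT 404.9 ms   errors 5.67 %
infrequent-incongruent mean RT 428.2 ms   errors 9.10 %
Simon effect: 27.5 ms (frequent) vs 23.3 ms (infrequent); modulation 4.2 ms
```

Frequent responses are ~38 ms faster and less error-prone than infrequent
ones (they are prepared on 90% of trials), and their Simon effect is
larger — the modulation the preparation mechanism is meant to produce.
The frequent-response delta plot declines across the RT range, the
signature of a leading, sign-reversing irrelevant input:

```
    p mean_ms delta_ms
1 0.1   310.7    78.80
2 0.3   343.6    55.69
3 0.5   370.2    34.15
4 0.7   401.0     8.24
5 0.9   459.0   -38.44
  c0 = 61.911  c1 = -90.458  c2 = -1.892
```

`c0`, `c1`, `c2` are level, slope and curvature coefficients of the
orthonormal-polynomial fit to the delta plot; the strongly negative slope
quantifies the decline, and under the +shielding variant the frequent and
infrequent slopes diverge instead of staying parallel.

The `analysis/` scripts chain these steps: `01_simulate.R` writes
synthetic datasets for the three experiment presets, `02_descriptives.R`
produces condition summaries and delta plots, `03_power.R` the
noncentral-t design computations, `04_recovery.R` a parameter-recovery
study, and `05_model_comparison.R` an AIC comparison of the preparation
and +shielding variants on shielding-generated data. Outputs (CSV plus a
provenance record with the master seed) land under `results/`.

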
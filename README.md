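# posnerrt

Simulators for the **Posner spatial-cueing task** — the "gold standard"
reaction-time (RT) paradigm in which a central cue (valid, neutral or
invalid) precedes a lateral target and responses are analysed by cue type.
The package is aimed at computational-neuroscience work on attention: it
lets you reproduce, on synthetic data, the classic behavioural signatures —
faster RTs for valid cues, slower for invalid ones, the speed–accuracy
trade-off, the relative-frequency effect, and slower choice (CRT) than
simple (SRT) responses — from two mechanistic models:

* **A Bayesian sequential detector** (sensory stage). At each time unit the
  observer updates the posterior probability that a noisy target has
  already appeared on the left or right, combining a cue-dependent spatial
  prior ρ (0.8 / 0.5 / 0.2) with Gaussian stimulus likelihoods, and
  responds when the posterior reaches a threshold γ:

  $$g_{side}(t) = f_{side}(t)\bigl[g_{side}(t-1) + p_{side}(t)\bar F(t-1)\bigr],
  \qquad p(\text{side} \mid \text{stimuli}) = \frac{g_{side}}{g_l + g_r + g_{\bar n}}.$$

  SRT responds on the summed posterior, CRT on either side's posterior
  separately — which is why choice responses are slower.

* **Evolved leaky integrate-and-fire networks** (motor stage). Small fully
  connected spiking circuits (cue and target input neurons, one or two
  output neurons) with $V(t{+}1) = V_{rest} + (V(t)-V_{rest})e^{-1/\tau} + I(t)$
  are optimised by an island-model genetic algorithm — 5 × 20 genomes,
  elitism, size-2 tournaments, uniform crossover, 5% bounded mutation,
  migration every 10 generations — against the trial fitness
  $1000\,e^{-0.01\,rt}$ for correct responses (nothing for anticipated,
  wrong or slow ones), under three conditions varying cue-type frequency
  (8:5:2 vs 8:8:2) and internal noise (σ = 0 vs 2 mV).

Everything returns tibbles; evolution results have broom-style `tidy()` /
`glance()` methods and `autoplot()`.

## Worked example

A choice task with a weak signal (s = 0.5, noise σ = 2, threshold γ = 0.8):

```r
library(posnerrt)
cfg <- bayes_config(s = 0.5, sigma = 2, gamma = 0.8, task = "CRT")
set.seed(1)
simulate_bayes_trials(cfg, 1e4) |> summarize_bayes_trials()
#> # A tibble: 3 × 8
#>   cue_type     n accuracy mean_rt sd_rt prop_anticipated prop_incorrect prop_slow
#>   <fct>    <int>    <dbl>   <dbl> <dbl>            <dbl>          <dbl>     <dbl>
#> 1 valid     3962    0.882    31.6  20.5           0.0964         0.0217         0
#> 2 neutral   5047    0.822    40.2  23.7           0.0703         0.108          0
#> 3 invalid    991    0.617    52.8  26.3           0.108          0.275          0
```

Valid cues give the highest accuracy (88%) and fastest correct responses
(31.6 time units); invalid cues are slowest (52.8) and draw 27.5%
wrong-side responses, because the misleading 0.8 prior pulls the posterior
toward the cued — wrong — side. `run_exp1()` sweeps the full task × signal
× threshold grid, and `plot_exp1_rt()` draws the cue-type RT profiles.

The motor side (here the noisy condition C, ~1 minute):

```r
ev <- run_exp2("C", "SRT", seed = 3)
glance(ev)   # final-generation summary: fitness, error rate, median RT per cue
autoplot(ev) # RT vs generation by cue type
```

Under noise the evolved networks plateau around 40-ish time-unit median
RTs with error rates that stay above ~20%, while the noiseless condition A
reaches errorless responding at the discrete-time floor of RT = 1.

A thin CLI over the same functions is installed at
`inst/scripts/posner-rt` (subcommands `exp1`, `exp2`).

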
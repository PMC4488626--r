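---
title: "Modelling simple and choice reaction times in the Posner task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling simple and choice reaction times in the Posner task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posnerrt)
library(dplyr)
```

posnerrt simulates the Posner spatial-cueing paradigm with two complementary
models: a **Bayesian sequential detector** for the sensory side of the task
and **evolved leaky integrate-and-fire (LIF) networks** for the motor side.
This vignette explains both models, the parameters that matter, the
numerical choices behind the implementation, and what the simulations can
and cannot say about real reaction-time (RT) data.

## The sensory model: Bayesian sequential detection

On each trial a target appears at a uniformly drawn time unit
$t \in \{1, \dots, t_{\max}\}$ ($t_{\max} = 100$), on the left with prior
probability $\rho$ and on the right with $1-\rho$. The cue sets the prior:
$\rho = 0.8$ for a left cue, $0.5$ for a neutral cue, $0.2$ for a right cue
— the classic 80/20 contingency. At every time unit the observer receives a
stimulus pair $(S_l, S_r)$, each Gaussian with standard deviation $\sigma$
and mean 0, except that the target side's mean switches to the signal
intensity $s$ from onset onward.

The observer accumulates, over all candidate onset times, the posterior
probability that the target has *already appeared* on each side. Writing
$f_l, f_r, f_{\bar{n}}$ for the per-step Gaussian likelihood factors under
"target already left", "target already right" and "no target yet" (with the
common normalising constant dropped), the implementation maintains

$$g_{side}(t) = f_{side}(t)\,\bigl[g_{side}(t-1) + p_{side}(t)\,\bar F(t-1)\bigr],
\qquad \bar F(t) = f_{\bar n}(t)\,\bar F(t-1),$$

where $p_{side}(t)$ is the per-step appearance prior ($\rho/t_{\max}$ inside
the onset window, 0 after) and the no-target mass is
$\bar F(t)\,(1 - t/t_{\max})$, clamped at 0 past $t_{\max}$. No new onset
hypotheses are added after $t_{\max}$, but existing ones keep accumulating
likelihood, which is what lets a choice trial continue to sharpen its
left-versus-right decision after the window closes. This recurrence gives
constant cost per step; its correctness is not taken on faith — the test
suite cross-checks it against `naive_posterior()`, a literal quadratic-cost
evaluation over the full stimulus history, on a thousand random histories
to a relative error of $10^{-9}$.

The decision rule is a threshold $\gamma$ on the posterior. A simple-RT
(SRT) observer responds when the *summed* posterior (left + right) reaches
$\gamma$; a choice-RT (CRT) observer waits for one *side's* posterior to
reach it and answers that side, tossing a fair coin in the measure-zero
event that both cross together. Because the summed posterior necessarily
reaches 1 at $t_{\max}$, an SRT trial always ends inside the window; a CRT
trial that has not responded by the absolute time index 1000 is classified
slow (this cutoff is an absolute index, not 1000 steps past onset). RT is
response time minus onset time, so responses driven purely by the rising
prior can precede the target: those trials (negative RT) are anticipations.
This yields the speed–accuracy trade-off and the calibration property that
the anticipation fraction stays below $1-\gamma$ (up to Monte-Carlo error),
since a response fires only once the posterior odds that the target is
present reach $\gamma$.

### Numerical choices

* **Rescaling, not log-space.** Raw likelihood products underflow within
  tens of steps. The three accumulators $(g_l, g_r, \bar F)$ are divided by
  their common sum every step; posteriors are invariant under common
  scaling, and all quantities stay of order one.
* **Threshold test on unnormalised accumulators.** The rule
  $g \ge \gamma \,(g_l + g_r + g_{\bar n})$ is algebraically the posterior
  rule but remains exact when the no-target mass hits zero at $t_{\max}$,
  where forming `g_l/total + g_r/total` by two divisions can round to just
  below 1 and miss a $\gamma = 1$ threshold.
* **Lockstep vectorisation.** `simulate_bayes_trials()` advances all trials
  of a block simultaneously, carrying the accumulators as vectors, so the
  $10^5$-trial runs used for the headline accuracy tables take seconds.
  With one trial and a fixed cue the engine consumes the RNG stream in
  exactly the same order as the scalar `simulate_bayes_trial()`, and a test
  holds the two to bit-identical results.

### Trial mix

Accuracy pooled across cue types depends in principle on how many trials
are laterally cued. The package's default mix — half lateral (split evenly
left/right), half neutral — reflects a balanced cueing block; for SRT the
pooled accuracy is essentially independent of the mix, and the reported
CRT quantities are per cue type, which the mix does not affect (only their
precision). Pooled high-signal accuracies are computed over equal SRT and
CRT halves; at $s = 5$ detection is so sharp that almost all errors are
anticipations and the two tasks' accuracies coincide to within Monte-Carlo
error.

## The motor model: evolved LIF networks

The motor model asks a different question: given clean detection, how
should a small spiking circuit convert cue and target inputs into a fast,
correct response? The networks are fully connected (all ordered pairs of
distinct neurons; no self-loops): three central cue inputs, two peripheral
target inputs, and one output (SRT, 6 neurons, 36 genes) or a left/right
output pair (CRT, 7 neurons, 49 genes). Each neuron follows the discrete
leaky integrator

$$V(t+1) = V_{rest} + \bigl(V(t) - V_{rest}\bigr)e^{-1/\tau} + I(t),$$

with $V_{rest} = V_{reset} = -65$ mV, $V_{threshold} = -40$ mV and
$\tau = 10$ time units; the decay factor is the fixed per-step constant
$e^{-\Delta t/\tau}$ with $\Delta t = 1$, the standard time-invariant leaky
integrator. $I$ sums the neuron's bias, an external 5 mV current on
stimulated input neurons, the weights of synapses whose presynaptic neuron
spiked on the *previous* step (synchronous update, one-step synaptic
delay), and optional Gaussian noise. A neuron reaching threshold spikes and
resets immediately.

A trial runs 50 silent units, then the cue current for a uniform integer
duration of 100–200 units, then the target current *in addition to* the cue
(the cue stays on). The trial ends at the first output spike, or 1000
target-stimulated units later (slow). RT is the response step minus the
target-onset step: the earliest response mediated by a target-neuron spike
is therefore RT = 1, the discrete-time floor. A spike at or before the
onset step cannot have been caused by the target and is classified
anticipated — so here "anticipated" is RT ≤ 0, the boundary case RT = 0
included, which keeps the floor for *correct* trials at exactly 1. Fitness
per trial is $1000\,e^{-0.01\,rt}$ for correct responses and 0 for
anticipated, wrong-side and slow ones; a genome's task fitness sums over
the fixed trial list. With the classic valid:neutral:invalid ratio 8:5:2
and both target sides equally represented per cue type the task has 30
trials; with 8:8:2 it has 36. If both CRT outputs fire on the same step the
responding side is drawn by a fair coin (the tie is not resolvable from the
dynamics and is vanishingly rare under noise).

### The genetic algorithm

Genomes (biases then weights, each gene in $[-3, 3)$) evolve in an island
model: 5 populations of 20, initialised i.i.d. uniform. Per generation and
island, the fittest genome is copied unchanged; 19 children are produced by
size-2 tournaments (two distinct entrants, fitter one wins, ties broken at
random), uniform crossover (each gene from a uniformly chosen parent), and
per-gene mutation (probability 0.05 of adding a uniform draw from
$[-0.3, 0.3)$, clipped back into $[-3, 3)$ — clipping, rather than
resampling, is the minimal-distortion reading of "keeping the gene in the
interval"). Every 10 generations each island's fittest genome is *copied*
into a uniformly chosen other island, replacing a uniformly chosen
non-elite member there, so island sizes never change and sources keep their
elites. Where the replacement policy was genuinely open we chose these
conventions once and test their invariants (sizes, bounds, elite
retention) rather than any particular trajectory.

Fitness is re-evaluated every generation on freshly drawn cue durations
(and noise), independently per individual and trial — each network performs
its own task. The carried elite is re-evaluated like any other member, so
under a stochastic objective its recorded fitness fluctuates;
`freeze_cue_durations = TRUE` pins one schedule (with zero noise) to make
the objective deterministic, under which elitism guarantees a
non-decreasing per-island maximum — a property the tests exercise.

The three study conditions are A (no noise, 8:5:2), B (no noise, 8:8:2,
which equates valid and neutral cue frequency and thereby isolates the
relative-frequency effect), and C (per-neuron noise of SD 2 mV every time
unit in all phases, 8:8:2). These are the generator's fixed defaults, not
tuning knobs.

### Population statistics

For each generation, each individual's median RT per cue type is taken over
its *correct* trials only; individuals with no correct response for a cue
type are null for it and excluded. The summary reports the mean, median, SD
and normal-approximation 95% CI half-width over non-null individuals, over
all 100 individuals, with `n` reported explicitly. Two error rates are
recorded per island: the elite's (the fraction of its trials not correct)
and the island mean over all 20 individuals. The noiseless convergence
claims (errorless performance, RT floor of 1) concern elites, which shed
errors quickly; the noisy error floor is a population-level quantity —
freshly mutated children keep the population mean error well above the
elite's.

## Implementation split and problem sizes

The GA needs on the order of $10^6$–$10^7$ network time-steps per
generation, so the trial/population evaluator is compiled C++ (Rcpp) using
R's RNG for full `set.seed()` reproducibility; a pure-R reference
(`run_lif_trial()` over `step_lif_network()`) implements the same dynamics
and the tests hold the two paths to identical results on deterministic
trials. Headline runs — $10^5$ sensory trials per configuration and full
300-generation evolution runs — complete in seconds to a couple of minutes
each; these sizes were chosen so the key Monte-Carlo standard errors stay
below a fifth of a percentage point while remaining comfortable to re-run.

## What the simulations do and do not show

Everything here is synthetic by design: the generators *are* the study
conditions. The sensory model has only external (stimulus) noise, assumes
the priors are already learned and exactly correct, two locations, uniform
onset times and no catch trials; it does not model motor output at all. The
motor model has only internal noise, a clean high-contrast target, and
six-or-seven-neuron circuits whose evolved solutions need not be unique —
evolutionary trajectories and final RT values vary across seeds, which is
why the tests assert orderings, floors and bounds rather than exact point
values for the noisy condition. Passing tests therefore demonstrate the
internal consistency of the models and the reproducibility of their
qualitative effects (cue-validity ordering, speed–accuracy trade-off,
relative-frequency effect, noise-limited RTs), not a fit to any particular
human dataset.

## A short tour

```{r exp1, eval = FALSE}
cfg <- bayes_config(s = 0.5, sigma = 2, gamma = 0.8, task = "CRT")
set.seed(1)
simulate_bayes_trials(cfg, 1e4) |> summarize_bayes_trials()

run_exp1(n_trials = 1e4, seed = 1) |> plot_exp1_rt()
```

```{r exp2, eval = FALSE}
ev <- run_exp2("C", "SRT", seed = 1)   # ~1 min, 300 generations
glance(ev)
autoplot(ev)
```
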
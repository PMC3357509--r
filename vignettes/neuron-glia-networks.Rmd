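---
title: "Neuron-glia networks: model, training scheme, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuron-glia networks: model, training scheme, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angn)
```

## The model

An artificial neuron-glia network is a feed-forward multilayer network in
which every hidden- and output-layer neuron carries an artificial
astrocyte. The neuronal part is conventional: neuron $j$ outputs
$y_j = f\bigl(\sum_i w_{ji} x_i\bigr)$ with no bias term, where $f$ is a
hard threshold ($1$ if the net input strictly exceeds $\theta$, else $0$)
or a hyperbolic tangent. The glial part is what this package exists for:
each astrocyte watches its neuron's firing over repeated presentations of
the same input and rescales connection weights in response.

The biological motivation is the tripartite synapse: astrocytes respond to
synaptic activity on a timescale roughly a thousand times slower than
neuronal signalling, and their feedback (glutamate-mediated) potentiates
transmission at active synapses. The slow timescale is emulated by
presenting each input pattern for $k$ consecutive instants — the pattern
*window*. At every instant the astrocyte reads the firing sign
$u = +1$ (output $> 0$) or $-1$ (output $\le 0$) and advances a signed
activity counter $r \in [-\mu, \mu]$. When the counter reaches $+\mu$ the
weights of the astrocyte's attached connections are increased by the
fraction $a$ of their magnitude ($w \leftarrow w + |w|\,a$); at $-\mu$
they are decreased by the fraction $b$. Because the change is proportional
to $|w|$, a weight never changes sign and zero weights are fixed points.

Six rules differ in the counter bookkeeping and in whether a weight
magnitude limit $w_M$ is enforced:

| rule | counter behaviour | limit |
|---|---|---|
| consecutive, limited | only same-sign runs accumulate; any flip or a trigger restarts | $|w| \le w_M$ |
| consecutive, unlimited | as above | none |
| non-consecutive, limited | firings and silences offset; a trigger restarts | $|w| \le w_M$ |
| non-consecutive, unlimited | as above | none |
| attenuated | non-consecutive, but a saturated counter *retains* its value, so the astrocyte acts again on every later instant of the window | none |
| global processing | no per-instant counter; see below | none |

The global-processing rule treats the instance set as a whole: the network
evaluates all $n$ instances $k$ times, and after each pass every attached
connection of neuron $j$ is rescaled by $(n + \mathrm{sign}(w)\,s_j)/n$,
where $s_j \in [0, n]$ is the number of instances on which the neuron
fired during that pass. The factor lies in $[0, 2]$; activity grows
positive weights and shrinks negative ones, and $s_j$ resets between
passes.

## Hybrid training

Learning is split between two actors. The astrocytes are an *unsupervised*
per-presentation mechanism: they reshape the computation while a pattern
is being processed. The *supervised* search is a real-coded genetic
algorithm over initial weight vectors: each chromosome flattens all
connection weights; fitness is $1/(1 + \mathrm{MSE})$, where the MSE is
computed from each training pattern's final-instant output under the
astrocyte phase (a plain forward evaluation for the astrocyte-free
network). Selection is fitness-proportionate ("Montecarlo"), breeding is
single-point crossover at rate 0.9 with per-gene uniform mutation at rate
0.1 on $[-w_M, w_M]$, and replacement is "Darwinian" replace-worst. The
phase never writes back into the chromosome: the search space stays the
space of initial weights.

## Design choices that were genuinely open

**Pattern windows are independent.** Within one fitness evaluation, each
pattern's $k$-instant window starts from the chromosome's weights and its
modifications are discarded at the window's end. The alternative —
letting modifications persist across the training set — degenerates for
every unlimited rule: a firing neuron is potentiated multiplicatively per
window (up to $1.25^{\,k-\mu+1}$ under the attenuated rule), so across
dozens of windows weights either explode or collapse and the network's
output goes constant, pinning the MSE at the chance level for essentially
every chromosome and leaving the genetic algorithm without a signal. Under
independent windows the astrocytes act as a bounded, per-presentation
nonlinearity that the evolutionary search can exploit, and the expected
behaviour of the method (astrocyte rules training well and beating the
plain network) is recovered. The global rule is the deliberate exception:
persistence across its $k$ passes is its defining feature.

**Astrocytes act on outgoing connections by default.** On an
all-threshold network, an astrocyte that rescales only its own neuron's
*incoming* weights can never change anything: potentiation of a firing
neuron strictly raises that neuron's net input (positive weights grow,
negative weights shrink toward zero), and depression of a silent neuron
strictly lowers it, so no unit can flip state within a window and the
final output equals the plain forward pass. Acting on *outgoing*
connections instead lets a hidden neuron's sustained activity reshape the
downstream layer's computation mid-window, which is where the
neuron-glia network's extra expressive power comes from. `incoming` and
`both` remain selectable (`astro_params(attachment = ...)`); with
continuous (tanh) activations incoming astrocytes are not inert, merely
weaker.

**Elitism.** Each generation breeds `population_size - 1` offspring, so
replace-worst substitution always preserves the incumbent best chromosome
and the best training error is non-increasing — the property that makes
"generation of best" well defined. Breeding a full population of
offspring would displace the best and destroy monotone convergence.

**Fitness transform.** The genetic algorithm needs a non-negative,
higher-is-better score for roulette selection; $1/(1+\mathrm{MSE})$ is
bounded, monotone, and parameter-free.

**Validation protocol.** A run's headline validation accuracy is that of
the final best-training chromosome, evaluated under the identical
astrocyte protocol; per-generation traces (and their maximum) are kept in
the returned history but are not the headline, because the maximum of a
6-instance accuracy over thousands of generations approaches 100% and
carries no information about the delivered solution. The reported
"generation" is the first generation at which the final best training
error was reached.

**Boundary and tie conventions.** A threshold unit does not fire at
exactly $x = \theta$ (mirroring the firing indicator's $u(0) = -1$).
Weight-limit clamping is symmetric in magnitude,
$w \leftarrow \mathrm{sign}(w)\min(|w|, w_M)$. $\mathrm{sign}(0) = 0$ in
the global factor, so zero weights stay put. When several $(k, \mu)$
combinations tie on validation accuracy the one with lower training error
and then smaller $k$ is kept. Within an instant, astrocytes are processed
layer by layer in neuron order; with `incoming` attachment their weight
sets are disjoint so the order is immaterial, with `outgoing`/`both` it
is the documented convention.

## Parameters

| parameter | meaning | default | unit/range |
|---|---|---|---|
| $k$ | instants per pattern window (or full passes, global rule) | 4 | $\ge 1$ |
| $\mu$ | firing-count trigger threshold | 2 | $[1, k]$ |
| $a$ | potentiation fraction | 0.25 | $[0, 1]$ |
| $b$ | depression fraction | 0.5 | $[0, 1]$ |
| $w_M$ | weight magnitude limit | 1 | $> 0$ |
| population | chromosomes per generation | 100 | $\ge 2$ |
| crossover / mutation | operator rates | 0.9 / 0.1 | $[0, 1]$ |

$b > a$ is deliberate: penalising inactivity harder than rewarding
activity reinforces only consistently active units. The four standard
$(k, \mu)$ combinations tried per run are 4-2, 6-2, 6-3 and 8-3.

## Synthetic data

`generate_mux()` enumerates the full truth table of a
2-select/4-data-line multiplexer: 64 boolean patterns over 6 inputs, the
target being the data bit addressed by the select bits; exactly half the
patterns output 1. The standard protocol splits these 58/6 with both
classes present among the 6 held-out patterns; since the original
held-out rows are not recoverable, the split is a seeded stratified draw
whose seed is recorded in every output. The generator is exhaustive and
noise-free — it emulates boolean truth-table tasks exactly, so passing
tests demonstrate the training machinery and the plasticity rules, not
robustness to measurement noise, class imbalance, or feature correlation
found in real tabular data. Continuous multi-class data (the iris task:
min-max normalised features in $[0,1]$, one-hot targets, class-balanced
2/3 splits) enter through `load_tabular()` and are exercised in tests
with synthetic continuous fixtures.

## Problem sizes in the test suite

Counter rules are verified exhaustively (all $2^k$ firing sequences,
$k \in \{4,6,8\}$, $\mu \in \{2,3\}$) against an independent scalar
simulator. Weight-rule invariants are property-tested over $2\times10^4$
random cases. The full-scale benchmark — the astrocyte-free network
trained for 4000 generations from 10 seeded populations — runs in the
acceptance suite and in `scripts/acceptance.R`. The multi-method
comparison (plain network vs attenuated and global rules, four
$(k,\mu)$ combinations, 10 seeds) is run at 500 generations, a scale
chosen so the whole suite completes in minutes while the methods'
relative ordering is already stable; full-length comparisons are a
straightforward overnight `run_from_config()` call.

## Limitations

Astrocyte-astrocyte signalling (intercellular calcium waves) is outside
the model: astrocytes here are independent, one per neuron.
Depression-only or mixed potentiation/depression astrocyte variants are
not implemented. Training is evolutionary only — there is no
backpropagation path, and no biases. The attenuated rule keeps a
saturated counter forever within a window, exactly as specified, so a
neuron that goes silent after saturating keeps being potentiated until
the window ends; a decay rule would change this but none is defined.
Wall-time columns in the reports are hardware-dependent and never used
in any assertion.
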
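# angn — artificial neuron-glia networks

`angn` implements feed-forward classification networks whose hidden and
output neurons carry **artificial astrocytes**: glia-inspired processing
elements that watch a neuron's firing over repeated presentations of the
same input pattern and potentiate or depress connection weights in
response. It is aimed at computational-neuroscience and neuroevolution
researchers who want to study how slow, activity-dependent glial feedback
changes what a small network can compute.

## The model

A network neuron is standard and bias-free, $y_j = f(\sum_i w_{ji} x_i)$,
with threshold or tanh activation. Each astrocyte presents its pattern for
$k$ consecutive instants and keeps a signed activity counter
$r \in [-\mu, \mu]$ driven by the firing sign $u(y) = \pm 1$. When $r$
reaches $+\mu$, the weights of the astrocyte's attached connections grow
by the fraction $a$ of their magnitude ($w \leftarrow w + |w|a$); at
$-\mu$ they shrink by $b$. Six plasticity rules are provided, differing in
the counter bookkeeping (consecutive-only runs, net counts, retained
saturation) and in whether the weight limit $w_M$ is enforced; a sixth,
*global processing*, instead rescales weights by
$(n + \mathrm{sign}(w)\,s)/n$ after each full pass over the $n$ instances,
$s$ being the neuron's per-pass firing count.

Training is hybrid: the astrocyte phase is unsupervised and supplies the
mean squared error of each pattern's final-instant output, and a
real-coded genetic algorithm (fitness $1/(1+\mathrm{MSE})$, roulette
selection, single-point crossover at 90%, per-gene mutation at 10%,
replace-worst substitution) evolves the initial weight vectors. The
built-in benchmark is the 2-select/4-data-line multiplexer: all 64 boolean
patterns, a 6-4-1 threshold network, and a 58/6 train/validation split.

See `vignette("neuron-glia-networks")` for the full model description and
the package's design choices.

## Worked example

Train the attenuated-astrocyte network and the astrocyte-free baseline on
the multiplexer task (shortened to 500 generations here):

```r
library(angn)

mux   <- generate_mux()                    # 64 patterns, 6 inputs
split <- split_dataset(mux, train_fraction = 58/64, stratified = TRUE, seed = 1)
net   <- angn_network(c(6, 4, 1), activation_spec("threshold", theta = 0.5),
                      weight_limit = 1)
astro <- astro_params("attenuated", k = 4, mu = 2, a = 0.25, b = 0.5)

evolve(net, split$train, split$validation,
       ga_config(population_size = 100, generations = 500, rng_seed = 7),
       astro)
#> Training record: 500 generations, population 100
#>   best training MSE 0.1897 | validation accuracy 100.0% (first at generation 459)
#>   astrocyte rule: attenuated | elapsed 5.8s

evolve(net, split$train, split$validation,
       ga_config(population_size = 100, generations = 500, rng_seed = 7),
       astro = NULL)
#> Training record: 500 generations, population 100
#>   best training MSE 0.1724 | validation accuracy 83.3% (first at generation 223)
#>   astrocyte rule: none (plain ANN) | elapsed 2.4s
```

The training MSE is the error of each training pattern's final-instant
output; the validation accuracy is that of the best-training chromosome on
the 6 held-out patterns, evaluated under the same astrocyte protocol. On
this seed the glial network classifies every held-out pattern; run a full
comparison (several rules × four $(k,\mu)$ combinations × 10 seeded
populations, aggregated into the comparison tables) with
`experiment_plan()` / `run_experiment()`, or from a shell via the thin CLI
in `inst/scripts/angn`:

```sh
angn experiment --config run.yaml --out results/
angn report --dir results/
```

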
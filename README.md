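# netbite

Network-biased tree ensembles for drug-sensitivity regression and
biomarker screening.

## What problem this solves

Predicting IC50 drug sensitivity of cancer cell lines from basal gene
expression is a small-n / large-m regression with a nonlinear response
that usually depends on a handful of genes. When a drug's protein targets
are known, `netbite` injects that prior directly into a random-forest
style ensemble: every gene gets a selection weight, and the candidate
features considered at each tree node are drawn **without replacement
with probability proportional to the remaining weights**. Uniform weights
recover the classic random forest (RF); weights concentrated on the drug
targets give a *biased tree ensemble* (BiTE); weights first smoothed over
a protein-protein interaction network give the network-based variant
(NetBiTE). Comparing the biased model against the uniform baseline on
shared cross-validation folds turns the ensemble into a biomarker test:
if biasing toward a gene set helps, that set is predictive.

The weight vector is built in two steps:

1. **Initial weights** `W0`: high weight `W` (e.g. 1 or 0.6) on each
   reported target, a small floor `epsilon = 1e-5` everywhere else.
2. **Network propagation** (random walk with restart) on a
   confidence-weighted PPI graph with adjacency `A`, degree matrix `D`:

   ```
   W_{t+1} = alpha * A' W_t + (1 - alpha) * W0,   A' = D^{-1/2} A D^{-1/2}
   ```

   iterated to a fixed point (max-norm tolerance 1e-6). `alpha` in (0,1)
   sets the diffusion depth; 0.7 is the default. The fixed point equals
   `(1-alpha) (I - alpha A')^{-1} W0`, which the tests use as an
   independent oracle.

Trees are exact variance-reduction CART regressors (midpoint thresholds,
minimum leaf size `TPS`, no depth cap), fitted on bootstrap draws;
accuracy is reported as `rho`, the Pearson correlation between pooled
out-of-fold predictions and the truth under repeated 30–40-fold
cross-validation, clamped to [0, 1].

## Worked example

Everything below runs on synthetic data generated by the package — a
200 x 200 standardized expression matrix whose response is a
deterministic 5th-degree polynomial of two planted target genes.

```r
library(netbite)

bench <- make_benchmark(n_samples = 200, n_genes = 200, seed = 1)
bench
#> synthetic_benchmark: 200 samples x 200 genes; targets: g022, g104

# NetBiTE weights: full weight on the targets, diffused over a planted
# PPI fixture standing in for a STRING download
fx <- make_ppi_fixture(colnames(bench$expression), bench$targets,
                       effectors_per_target = 3, background_density = 0.02,
                       seed = 1)
ws <- propagate_weights(initial_weights(bench$targets,
                                        colnames(bench$expression)),
                        fx$graph, propagation_config(alpha = 0.7))
ws
#> bias_weights (propagated) over 200 genes
#>   range [3e-06, 0.4453646]
#>   propagation: alpha=0.7, 26 iterations, residual=5.244605e-07

neighborhood_of_influence(ws, 4)
#>   gene    weight
#> 1 g104 0.4453646
#> 2 g022 0.4275074
#> 3 g014 0.1571388
#> 4 g044 0.1479239

# paired BiTE-vs-RF comparison, identical folds, 3 repeats
w0 <- initial_weights(bench$targets, colnames(bench$expression),
                      high_weight = 0.6, epsilon = 1e-5)
tab <- compare_models(bench$expression, as.numeric(bench$ic50_scaled),
                      bias = w0, n_tree_grid = c(10L, 100L), mtry = 2,
                      repeats = 3, seed = 1)
print(tab, digits = 3)
#>   n_tree rho_biased  rho_rf delta_rho  p_value
#> 1     10      0.723 0.01474     0.708 1.30e-04
#> 2    100      0.728 0.00424     0.724 9.53e-06
```

Reading the output: after propagation the two targets keep the largest
weights (0.43–0.45) and their planted interaction partners (`g014`,
`g044`, ...) are pulled well above the 1e-5 background — the
"neighborhood of influence" of the targets. In the comparison table a
biased ensemble that sees only `mtry = 2` candidate genes per split
reaches `rho ≈ 0.72` with as few as 10 trees, while a uniform random
forest restricted to the same `mtry` is no better than chance
(`rho ≈ 0.01`): with 200 genes and 2 random candidates per node it
essentially never meets the informative genes. `delta_rho` is the
biased-minus-uniform accuracy difference on shared folds and `p_value` a
paired two-sided t-test across repeats.

## Command-line interface

A thin launcher (`inst/cli/netbite.R`) exposes the pipeline as
subcommands:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "netbite.R", package = "netbite"))')" \
    make-fixtures --out-dir fixtures --seed 1
# then: propagate | fit-predict | benchmark | compare
```

Flags mirror the configuration keys (`--config FILE` loads a flat
`key = value` file; explicit flags win). Exit codes: 0 ok, 1 user error,
2 internal error.

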
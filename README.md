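# smurfens

Hyper-ensembles of SMOTE-balanced random forests for highly imbalanced
binary classification, as used for prioritizing pathogenic variants in
the non-coding genome — settings where a few hundred positives sit
among millions of negatives (class ratios of 1:700 to 1:50,000) and a
single classifier either ignores the minority class or throws away the
majority class.

## The method

Given a training set with `n⁺` positives and `n⁻ ≫ n⁺` negatives and
hyper-parameters `(nParts, fp, ratio, k, nTrees, mTry)`:

1. **Partition** the negatives into `nParts` disjoint parts of
   near-equal size, so the ensemble as a whole keeps every negative.
2. **Rebalance** each part: all `n⁺` positives, plus `fp · n⁺`
   synthetic positives from SMOTE (each synthetic point is
   `p + u (q − p)`, `u ~ U[0,1)`, `q` one of the `k` nearest positive
   neighbours of `p`), plus `ratio · (1 + fp) · n⁺` negatives drawn
   uniformly from the part.
3. **Train** one random forest per part (`nTrees` trees, `mTry`
   candidate features per split).
4. **Score** by the consensus `s(x) = (1/nParts) Σᵢ Pᵢ(y = 1 | x)`, the
   mean of the per-forest positive-class probabilities.

Performance is measured by AUROC and AUPRC; under extreme imbalance
AUPRC is the informative metric and is the objective of both tuners
(exhaustive grid search, and Bayesian optimization with a
Gaussian-process surrogate and expected-improvement acquisition over
the integer lattice). Cross-validation can be *cytogenetic-band-aware*:
whole bands are assigned to folds so genomically nearby variants never
straddle the training/test boundary. Training is deterministic given a
master seed, with bit-identical scores regardless of the number of
parallel workers.

## Worked example

```r
library(smurfens)

train <- generate_synth(synth_spec(10000, 100, effect_size = 1.5, seed = 1))
test  <- generate_synth(synth_spec(5000,  50,  effect_size = 1.5, seed = 2))
train
#> smurf_dataset: 10000 samples x 30 features
#>   positives: 100, negatives: 9900  (1:99)

h <- hyperparams(nParts = 20, fp = 2, ratio = 3)
model <- smurf_train(train, h, master_seed = 7)
model
#> smurf_ensemble: 20 forests x 10 trees (mTry = 5), 30 features

scores <- predict(model, test$features)
cat(sprintf("held-out AUROC: %.3f\n", auroc(scores, test$labels)))
#> held-out AUROC: 0.950
cat(sprintf("held-out AUPRC: %.3f (prevalence %.3f)\n",
            auprc(scores, test$labels), mean(test$labels)))
#> held-out AUPRC: 0.475 (prevalence 0.010)
```

The synthetic data have 30 independent Gaussian features of which 4
are mean-shifted for positives; at a 1:99 imbalance a random ranker
would score AUPRC near the 0.010 prevalence, while the hyper-ensemble
reaches 0.475 — the rebalanced parts let each forest see a solvable
problem while the partition preserves negative-class coverage.

Repeated cross-validation and nested hyper-parameter tuning:

```r
cv <- run_cv(train, h, nFolds = 5, n_repeats = 2, seed = 3)
space <- param_grid(nParts = c(10, 50), fp = c(1, 2), ratio = c(2, 3))
nested <- run_nested_tune(train, space, nFolds_external = 5,
                          nFolds_internal = 3, seed = 3)
```

A JSON-configured command-line front end covers the same run modes
(`train`, `predict`, `cv`, `tune-grid`, `tune-bayes`, `generate`):

```sh
Rscript inst/cli/smurf cv --config cfg.json --seed 5 --out results/
```

See `vignette("hyper-ensembles")` for the model, the tuning
strategies, fold construction, and the design decisions behind them.

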
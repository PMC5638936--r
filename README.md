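# spaft — semi-supervised survival analysis with self-paced AFT pseudo-labelling

`spaft` is an R package for gene selection and survival prediction on
high-dimensional expression data (samples × genes with observed time
*t<sub>i</sub>* and event indicator *δ<sub>i</sub>* ∈ {0,1}) when a large
fraction of patients is censored. Supervised penalized Cox models use
censored samples only through the risk sets of the partial likelihood;
`spaft` additionally *pseudo-labels* them:

1. **Cox stage** — a penalized Cox model (MCP by default; lasso and elastic
   net available),
   β\* = argmin { −(1/n) Σ δ<sub>i</sub> [x<sub>i</sub>ᵀβ − log Σ<sub>j∈R<sub>i</sub></sub> e^{x<sub>j</sub>ᵀβ}] + Σ P(β<sub>j</sub>; λ) },
   ranks all patients by prognostic index x<sup>T</sup>β and median-splits
   them into high- and low-risk groups.
2. **SP-AFT stage** — per group, an accelerated failure time regression
   log t = μ + x<sup>T</sup>β + ε is trained under self-paced learning:
   censored samples carry binary weights v<sub>j</sub>, the loss is
   (y<sub>j</sub> − x<sub>j</sub>ᵀβ)² but +∞ whenever the prediction falls
   below the censor log-time, weights are v<sub>j</sub> = 1{loss ≤ α}, and
   the age parameter α grows each round so the model learns easy samples
   first.
3. **Promotion** — censored samples retained by the SPL weights, whose
   imputed time strictly exceeds their censor time, become labelled
   (time = exp(pseudo log-time), δ = 1) and the loop repeats.

The package also ships the matching simulation generator (correlated
Gaussian expression, Gompertz-hazard times, exact-fraction censoring, ground
truth retained), evaluation metrics (concordance index, log-time MSE,
gene-selection counts), a multi-seed benchmark harness over five methods
(`cox-sp-aft`, `semi-cox`, `cox-mcp`, `cox-lasso`, `cox-en`), and a CLI.
See the methods vignette (`vignettes/spaft-methods.Rmd`) for the model
details, numerical choices and known limitations.

## Worked example

```r
library(spaft)
study <- simulate_study(simulation_config(p = 500, n = 250, n_true = 20, seed = 42))
study
#> <simulated_study> n=250, p=500, |true support|=20, 125 censored (seed 42)

sp  <- split_train_test(study$data, 200, seed = 1)
res <- run_cox_sp_aft(sp$train, pipeline_config(seed = 1))
res
#> <pipeline_result> 3 outer round(s); 80 censored sample(s) promoted; 26 genes selected
res$audit[, c("round", "n_labeled", "n_new_promoted")]
#>   round n_labeled n_new_promoted
#> 1     1       161             60
#> 2     2       181             20
#> 3     3       181              0

sel <- selection_metrics(match(names(res$final_cox$beta)[res$final_cox$support],
                               names(study$truth$beta_true)),
                         study$truth$true_support)
sprintf("correct %d / selected %d (accuracy %.2f)", sel$correct, sel$total, sel$accuracy)
#> [1] "correct 15 / selected 26 (accuracy 0.58)"

pi_test <- prognostic_index(res$final_cox,
                            apply_standardization(sp$test$X, res$std_record))
concordance_index(-pi_test, sp$test$time, sp$test$status)
#> [1] 0.8994083
```

Reading: of 100 censored training samples, 80 were confidently
pseudo-labelled and promoted across three outer rounds (the third promoted
nothing, so the loop stopped); the final Cox fit selected 26 genes of which
15 are in the true 20-gene support; the negated prognostic index orders
~90% of comparable test pairs correctly.

The same run from the shell:

```sh
Rscript inst/cli/spaft simulate --out sim/ --seed 42
Rscript inst/cli/spaft fit --expression sim/expression.tsv --survival sim/survival.tsv \
    --method cox-sp-aft --out fit/ --seed 1
Rscript inst/cli/spaft evaluate --coefficients fit/coefficients.tsv \
    --expression sim/expression.tsv --survival sim/survival.tsv \
    --truth sim/truth.tsv --out report.json
```

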
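# tcglm

Differential expression analysis for **RNA-seq time courses** by two-step
polynomial regression with **negative binomial generalized linear models**,
together with a negative binomial simulator with known truth and an FDR/FNR
benchmarking harness.

It is aimed at analysts with gene × sample count matrices from experiments
where time is a quantitative covariate — one or several treatment series
measured over ordered time points — who want genes whose expression changes
along time or differs between series, with per-gene models that retain only
significant coefficients.

## The method

For a gene measured at times $t_i$ across $S$ series, expression is modeled
by polynomial regression with series dummies $z$; with two series and a
quadratic fit:

$$y_i = \beta_0 + \beta_1 t_i + \beta_2 t_i^2 + \beta_3 z_i + \beta_4 t_i z_i + \beta_5 t_i^2 z_i + \varepsilon_i$$

Counts follow a negative binomial GLM with log link,
$Y_i \sim \mathrm{NB}(\mu_i, \theta)$,
$\mathrm{Var}(Y_i) = \mu_i + \mu_i^2/\theta$ (default $\theta = 10$, held
fixed); the gaussian family recovers the classical linear model for
continuous data. The procedure has two regression steps:

1. **Screen** — each gene's full polynomial model is tested against the
   intercept-only model with the deviance likelihood-ratio statistic
   $\Delta = D_0 - D_1 \sim \chi^2_p$; Benjamini–Hochberg adjustment
   controls the FDR across genes (default $\alpha = 0.05$).
2. **Model selection** — backward stepwise regression per screened gene
   keeps only coefficients significant at `step_alpha`, and the optimised
   model's *deviance-explained*
   $R^2 = (D_0 - D_{\mathrm{final}})/D_0$ filters the final selection
   (cutoffs of 0.5–0.7 are typical).

Counts should be normalized beforehand; TMM scaling-factor and low-count
filtering utilities are included, and likelihoods are evaluated via
log-gamma functions so non-integer normalized values are handled exactly.

## Worked example

Simulate a two-series course (6 time points, 3 replicates, 2000 genes, 5%
DE genes rising linearly), normalize, run both steps, and score against the
known truth:

```r
library(tcglm)

sim    <- tc_simulate(tc_sim_spec("A", series = 2, replicates = 3,
                                  n_genes = 2000, seed = 11))
counts <- apply_normalization(sim$counts, tmm_factors(sim$counts))
scr    <- tc_screen(counts, sim$design, degree = 2,
                    family = tc_family("nb", theta = 10), alpha = 0.05)
glance(scr)
#> # A tibble: 1 × 7
#>   n_genes n_selected n_fit_failed n_skipped alpha family            degree
#>     <int>      <int>        <int>     <int> <dbl> <chr>              <int>
#> 1    2000         72            0         0  0.05 negative_binomial      2

mods <- tc_stepwise(counts, scr)       # backward elimination per gene
sel  <- tc_select(mods, rsq = 0.5)     # deviance-explained filter
head(tidy(mods), 5)
#> # A tibble: 5 × 5
#>   gene_id term          estimate   p_value r_squared
#>   <chr>   <chr>            <dbl>     <dbl>     <dbl>
#> 1 g0006   Intercept       2.13   NA            0.268
#> 2 g0006   time:series2   -0.600   0.000112     0.268
#> 3 g0006   time2:series2   0.0942  0.00106      0.268
#> 4 g0062   Intercept       1.54   NA            0.591
#> 5 g0062   time            0.175   0.000853     0.591

tc_score(sel, sim$truth)
#> # A tibble: 1 × 7
#>   selected false_positives false_negatives   fdr    fnr n_genes  n_de
#>      <int>           <int>           <int> <dbl>  <dbl>   <int> <int>
#> 1       26               0              74     0 0.0375    2000   100
```

Of 2000 genes, 72 pass the screen; the $R^2 \ge 0.5$ filter keeps 26, all
of them true positives (empirical FDR 0, FNR 3.75%). Coefficients read
directly against the model: `g0006` differs between series (`time:series2`,
`time2:series2` retained), `g0062` follows a time trend shared with the
reference series. `tc_rsq_sweep(mods, sim$truth)` tabulates FDR/FNR across
cutoffs (`autoplot()` draws it), and `plot_gene_trends()` overlays fitted
profiles on the observed counts.

A thin command-line front end wraps the same functions
(`exec/tcglm`, or `tc_cli()` from R): `simulate`, `fit`, `evaluate` and
`sweep` subcommands read and write plain TSV/JSON artifacts.

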
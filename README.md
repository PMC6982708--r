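# bcproxy

Input-adaptive proxy imputation for gappy air-quality time series — a
"virtual sensor" for exposure variables such as black carbon (BC).

## The problem

Long-term air-quality records are rarely complete: instruments fail, get
serviced, or are deployed late, and key exposure variables such as black
carbon are measured at far fewer sites than routine pollutants. A
*proxy* (virtual sensor) estimates the target pollutant from co-measured
variables with a regression model. The *traditional* proxy uses only the
single best model — so whenever one of that model's inputs is itself
missing, the estimate is unavailable and the gap survives. The
*input-adaptive* proxy developed here keeps the full ranking of all
acceptable models and, hour by hour, falls back to the best model whose
inputs are actually present, until every fillable gap is filled.

## The method

For an output variable $Y$ (log-transformed concentration) and candidate
inputs $X_1,\dots,X_k$, the package:

1. **Screens** candidates by absolute Pearson correlation with the log
   output, discarding $|R| < 0.1$;
2. **Enumerates** every subset of at most three inputs ($\sum_{p\le3}\binom{k}{p}$
   models; 1159 for $k=19$) and fits each by robust regression
   $Y = \beta_0 + \sum_{i=1}^{p}\beta_i X_i + \varepsilon$, using
   iteratively reweighted least squares with the Tukey bisquare weight
   $w(r) = (1-(r/c)^2)^2$ for $|r|\le c$, $c = 4.685$, on
   leverage-adjusted standardized residuals
   $r_i = e_i/(s\sqrt{1-h_i})$, $s = \mathrm{MAD}/0.6745$;
3. **Averages** coefficients and evaluation attributes over five random
   80% subsets of the data (bootstrap multiple imputation);
4. **Rejects** models with variance inflation
   $\mathrm{VIF}_p = 1/(1-R_p^2) \ge 5$ (multicollinearity) or residuals
   failing the Lilliefors normality test at $\alpha = 0.05$;
5. **Ranks** the survivors by adjusted
   $\mathrm{adj}R^2 = 1 - (1-r^2_{y\hat y})\frac{N-1}{N-p-1}$
   (descending, at 2-decimal granularity), then MAE, then RMSE, then
   sample size — separately for each of eight classes (four thermal
   seasons × workday/weekend, with thermal seasons cut where the
   smoothed daily temperature crosses 0 °C and 10 °C);
6. **Imputes** each missing hour with
   $\hat Y = \exp(\beta_0 + \sum_i \beta_i X_i)$ from the best-ranked
   feasible model of that hour's class, cascading down the ranking when
   inputs are missing.

## Worked example

Everything is runnable without any external data via the built-in
synthetic generator, which emulates correlated log-normal pollutant
series with diurnal/weekly harmonics, an annual temperature cycle, and
missing-at-random block gaps:

```r
library(bcproxy)
cfg <- synth_config(start = "2017-01-01", end = "2017-06-30", n_predictors = 5,
                    true_inputs = c("X1", "X2"), beta = c(X1 = 0.6, X2 = 0.3),
                    seed = 42)
g <- generate_synthetic(cfg)                      # $table is gappy, $truth is not
proxy <- train_proxy(g$table, synth_specs(cfg), temp_var = "Temp", seed = 42)
proxy
#> <bc_proxy> output BC, 5 features, 6 class(es)
#>   spring.weekend     rank 1: X1+X2 (adjR2 0.946, 24 accepted)
#>   spring.workday     rank 1: X1+X2+X3 (adjR2 0.942, 25 accepted)
#>   summer.weekend     rank 1: X1+X2+X5 (adjR2 0.944, 24 accepted)
#>   summer.workday     rank 1: X1+X2+X4 (adjR2 0.940, 25 accepted)
#>   winter.weekend     rank 1: X1+X2+X3 (adjR2 0.939, 25 accepted)
#>   winter.workday     rank 1: X1+X2+X5 (adjR2 0.944, 25 accepted)
```

Every class's top model contains the generating inputs `X1+X2`; with six
months of data a third accessory input sometimes ties at the 2-decimal
adjusted-$R^2$ granularity, exactly the near-equivalence of top models
the ranking is designed to tolerate. Imputation:

```r
adaptive    <- impute_proxy(proxy, g$table)
traditional <- impute_proxy(proxy, g$table, mode = "traditional")
sprintf("coverage: traditional %.1f%%, adaptive %.1f%%",
        100 * traditional$coverage, 100 * adaptive$coverage)
#> "coverage: traditional 91.0%, adaptive 100.0%"
masked <- is.na(as.data.frame(g$table)$BC)
cor(adaptive$filled[masked], as.data.frame(g$truth)$BC[masked])
#> 0.929
```

The traditional proxy leaves 9% of hours unexplained (its inputs are
gappy too); the cascade fills every hour, and the filled values
correlate 0.93 with the held-out truth on the masked hours.
`rank_usage(adaptive$records)` tabulates, per class, the fraction of gap
hours served by the rank-1 model, rank 2, ranks 3–10, and beyond —
the cascade's fallback behaviour at a glance.

## Command line

A thin front end wraps the same functions:

```sh
Rscript inst/cli/proxy.R train  --data data.csv --config config.yml --out run/
Rscript inst/cli/proxy.R impute --data data.csv --models run/ --mode adaptive --out filled.csv
Rscript inst/cli/proxy.R report --records filled.csv --out report/
```

See `inst/extdata/example_config.yml` for the configuration format.

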
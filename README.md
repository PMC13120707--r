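# gwcrash

Zonal analysis of overdispersed event counts with spatial heterogeneity:
global and local Moran statistics, covariate screening, global count-model
baselines, and **geographically weighted negative binomial regression
(GWNBR)** with data-driven bandwidth selection.

## Who this is for

Analysts modelling counts aggregated to administrative zones — road crashes
per district, disease cases per county — where two things are usually true
at once: the counts are overdispersed (variance far above the mean), and the
covariate effects are not constant over the map. A single global coefficient
for, say, road density then misrepresents most places. This package
implements the standard workflow for that situation end-to-end, plus a
synthetic-data generator with known spatially varying truth so the whole
chain can be validated without access to any particular dataset.

## The model

The global baseline is NB2 negative binomial regression with log link:

    ln(mu_j) = ln(t_j) + sum_k beta_k x_jk,     Var(y_j) = mu_j + alpha mu_j^2

GWNBR lets both the coefficients and the dispersion vary with the zone's
location (u_j, v_j):

    y_j ~ NB[ t_j exp( sum_k beta_k(u_j, v_j) x_jk ),  alpha(u_j, v_j) ]

Each zone gets its own fit, obtained by maximizing a kernel-weighted local
log-likelihood (adaptive bisquare kernel by default, whose bandwidth is a
nearest-neighbor count). The bandwidth is chosen by golden-section search
minimizing either the model's AIC (with a trace-based effective number of
parameters) or a leave-one-out cross-validation score. Model comparison uses
AIC, MAD and RMSE, plus Moran tests on the deviance residuals — a
well-fitting spatial model should leave no significant positive residual
clustering.

## Worked example

Simulate a 196-zone study in the regime of district-level crash counts
(overdispersed, spatially clustered response, known truth), then run the
chain:

```r
library(gwcrash)

study <- simulate_preset("paper_like", seed = 1)
units <- study$units                       # spatial_units: counts + covariates
W <- row_standardize(contiguity_weights(units, "queen"))

global_moran(units$crashes, W, n_permutations = 999, seed = 1)
#> Global Moran's I
#>   I = 0.1951   E[I] = -0.0051   Var[I] = 0.00131 (randomization)
#>   z = 5.5325   (two-sided 99% critical value 2.58)   p = 3.157e-08
#>   permutation p = 0.001 (999 permutations)
```

The response clusters strongly (I = 0.195 against a null expectation of
−1/195 = −0.0051; z = 5.5 far beyond 2.58), so a spatial model is worth the
trouble. The global NB fit confirms heavy overdispersion:

```r
nbr <- fit_negbin(units, crashes ~ x1 + x2 + x3)
nbr
#> <count_fit> family = negbin, n = 196, logLik = -716.329, AIC = 1442.657
#>   dispersion alpha = 0.8459
#>         term estimate      se statistic         p
#>  (Intercept)   2.6192 0.06889    38.021 0.000e+00
#>           x1   0.3762 0.07029     5.352 8.704e-08
#>           x2   0.2266 0.06930     3.270 1.074e-03
#>           x3   0.3145 0.06955     4.521 6.148e-06
```

Select the bandwidth and fit GWNBR; the local coefficients are summarized in
the conventional five-number format (minimum, quartiles, maximum) with the
share of zones where the local t-statistic is significant:

```r
bw <- select_bandwidth(units, crashes ~ x1 + x2 + x3, criterion = "aic")
bw
#> Bandwidth search (aic): optimum 20 with score 1394.6426 (13 evaluations)

gw <- fit_gwnbr(units, crashes ~ x1 + x2 + x3,
                kernel_spec("adaptive_bisquare", bw$optimum))
summary(gw)
#> Local coefficient summary (AIC 1394.643, effective params 104.41)
#>         term    min       lq median     uq   max pct_significant
#>  (Intercept) -2.101  1.82839 2.3477 2.9780 5.450          73.469
#>           x1 -1.123  0.25261 0.6888 0.9785 2.796          36.735
#>           x2 -1.422 -0.01620 0.2575 0.7045 2.617           8.163
#>           x3 -1.040 -0.09723 0.2150 0.5263 2.090          13.776
```

The x1 effect, generated as a west-east gradient from 0.2 to 0.8, comes back
with a local median of 0.69 and wide legitimate spread — exactly the
heterogeneity a single global coefficient (0.38 above) averages away.
Finally, the side-by-side comparison:

```r
compare_models(list(NBR = nbr, GWNBR = gw), W)
#> Model comparison (deviance residual Moran)
#>  model                      type bandwidth likelihood  aic  rmse   mad
#>    NBR         Negative binomial        NA       -716 1443 16.21 10.93
#>  GWNBR GWNBR (adaptive_bisquare)        20       -593 1395  7.29  5.34
#>  residual_moran_I residual_moran_p best_aic
#>             0.161          0.00001
#>            -0.126          0.00144        *
```

GWNBR wins on every criterion (AIC 1395 vs 1443, RMSE 7.3 vs 16.2) and
removes the significant *positive* clustering of the NB residuals
(I = 0.161 → −0.126; the small negative remainder is a symptom of local
smoothing, not of unmodeled structure).

`run_full_analysis(analysis_config(...))` executes the same chain —
descriptives, Moran + LISA, screening, global fits, both AIC- and
CV-selected GWNBR fits, comparison, local maps — and writes every table as
CSV/GeoJSON with a JSON run manifest. A thin command-line wrapper lives at
`inst/cli/gwcrash.R`.

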
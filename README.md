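# mpratools

Differential activity analysis for massively parallel reporter assays
(MPRAs), built on precision-weighted linear models with empirical-Bayes
moderation.

MPRA experiments couple thousands of candidate regulatory elements to
barcodes, transfect the library into replicate cell populations, and
sequence both plasmid DNA (element copy number) and transcribed RNA.  The
activity of an element is the log2 ratio of its RNA to DNA abundance, and
the scientific questions are comparative: does an element's activity differ
between alleles, cell types, or conditions?  Analyses in the literature
have mostly used ad-hoc tests (pooled Fisher exact tests, plain t-tests)
that are either badly miscalibrated on overdispersed count data or waste
power.  This package implements a calibrated, flexible alternative for
statisticians and computational biologists analyzing such data.

## The model

Barcode counts are summarized per element and sample into a log2 activity
measure, either by aggregation

```
a_hat = log2( (1 + (L/N_r) * sum_b R_b) / (1 + (L/N_d) * sum_b D_b) )
```

or by averaging per-barcode log-ratios (aggregation has roughly `1/B` of
the averaging bias; both Taylor approximations are available as
`bias_aggregate()` / `bias_average()`).  Activities are modeled per element
with a weighted linear model `y_es = x_s' beta_e + eps_es`, where the
observation weights come from a lowess fit of sqrt(residual SD) against
log2 DNA abundance — low-copy elements are noisier and are down-weighted.
Residual variances are shrunk towards a scaled inverse-chi-square prior
fitted across elements, giving moderated t statistics with augmented
degrees of freedom.  Paired (allelic) designs are handled by a consensus
within-block correlation and generalized least squares.  A negative
binomial generator, an 8-step null-resampling procedure for empirical type
I error estimation, FDR utilities, t-test/Fisher-exact baselines, and a
Taylor-theory power calculator round out the toolkit.

## Worked example

```r
library(mpratools)

# synthetic study: 500 elements, 10% with a true log2 effect of 1, 4 vs 4
sim <- generate_mpra(simulation_spec(
  n_elements = 500, effect_fraction = 0.1, effect_size = 1,
  phi_dna = 0.2, phi_rna = 0.2,
  dna_lib_size = 1e6, rna_lib_size = 1e6, seed = 42))

fit <- mpralm(sim$counts, ~ condition)
fit
#> mpralm fit: 500 elements, 8 samples, 2 coefficients ( aggregate estimator )
#>   prior df d0 = 46.14  prior variance s0^2 = 1.083

head(top_elements(fit), 5)
#>   element_id    logFC        t df_total      p_value  adj_p_value
#> 1  elem_0090 1.311684 6.453394  52.1393 3.639268e-08 1.819634e-05
#> 2  elem_0284 1.290512 6.180397  52.1393 9.886615e-08 2.471654e-05
#> 3  elem_0476 1.085742 5.560989  52.1393 9.347184e-07 9.640654e-05
#> 4  elem_0204 1.172186 5.560410  52.1393 9.366640e-07 9.640654e-05
#> 5  elem_0176 1.101842 5.552385  52.1393 9.640654e-07 9.640654e-05
```

`logFC` is the estimated log2 activity difference between the groups, `t`
the moderated statistic on `df_total = d0 + d` degrees of freedom, and
`adj_p_value` the Benjamini-Hochberg adjusted p value.  At BH 0.05 this run
reports 50 elements, 41 of them true positives from the generator's truth
table.  The fitted d0 of about 46 means each element's variance estimate
borrows the equivalent of 46 extra degrees of freedom from its peers.

Design questions are answered by the power engine; with a log2 effect of 1,
10 barcodes, a 5M-read library and the default Bonferroni correction for
5000 tests:

```r
power_two_group(4, 1, dna_lib_size = 5e6)
#> [1] 0.4634974
```

`plot(fit)` shows the fitted copy-number–variance trend;
`make_fixture()` and `run_pipeline()` provide file-based entry points.

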
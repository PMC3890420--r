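# immunopolar

Model-based inference of immune-cell polarization from bulk tumor gene
expression, with the surrounding cohort workflow: clustering, infiltration
scoring, PCA, survival statistics with a random-signature null, contingency
statistics, and immunohistochemistry stain quantification.

## The problem

Bulk expression profiles of homogenized tumor tissue mix malignant,
stromal, and immune cells. Whether the immune infiltrate is biased toward
type 1 cell-mediated cytotoxic immunity (Th1 helper cells, M1
macrophages) or toward type 2 / regulatory states matters for prognosis —
particularly in triple-negative breast cancer, where no targeted therapy
applies — but cell-level polarization cannot be observed directly in bulk
data. `immunopolar` treats polarization as Bayesian model selection among
K mutually exclusive signature models. For a sample with per-gene cohort
z-scores *z*, subset model *M<sub>k</sub>* predicts its own exclusive
signature genes at a target z-score of +*a* and the other subsets' genes
at −*a*, with a product-of-Gaussian-kernels likelihood:

    L_k = exp( -1/2 * sum_{g in E_k} (z_g - a)^2
               -1/2 * sum_{j != k} sum_{g in E_j} (z_g + a)^2 )

    p(M_k | z) = L_k pi_k / sum_j L_j pi_j

with uniform priors pi_k = 1/K by default. Cohort-level polarization is
the mean posterior over samples; its significance is assessed against an
empirical null built by bootstrap resampling of the pooled expression
values (B = 1000 synthetic cohorts of n = 200). The prognostic value of
the Th1 posterior is judged against a second null: Cox hazard ratios from
1000 random signature families of identical subset sizes drawn from the
same gene panel.

## Worked example

```r
library(immunopolar)

# a synthetic cohort: 50 normal-like, 50 group-1-like (type 2/17 bias),
# 50 group-2-like samples (planted Th1 amplitude 1.5, M1 bias)
cc <- generate_cohort(synthetic_cohort_config(seed = 1))

zm <- zscore(cc$expression)
th <- reduce_to_exclusive(load_panel()$Thelper)
round(cohort_mean_posterior(zm, th, membership = cc$clinical$group), 3)
#>          Th1   Th2  Th17 iTreg
#> group1 0.038 0.280 0.440 0.243
#> group2 0.710 0.025 0.093 0.173
#> normal 0.067 0.497 0.125 0.311
```

The group-2 cohort is called Th1-polarized (mean posterior 0.71), group 1
shows a mixed Th2/Th17 bias, and normal tissue is Th2-biased. Against the
bootstrap null (B = 1000), the group-2 Th1 mean has empirical p = 1/1001
< 0.001. The full pipeline adds clustering, infiltration, PCA, and
survival:

```r
res <- run_pipeline(cc$expression, cc$clinical, B = 1000, seed = 7)
res$cox$coefficients
#>             term    hr  lower upper        p
#> 1          p_th1 0.215  0.101 0.459 7.11e-05
#> ...
```

The Th1 posterior is protective (HR 0.215 per unit posterior) independent
of molecular pathology, and `res$hr_ensemble` shows it beats the random
signatures of identical size.

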
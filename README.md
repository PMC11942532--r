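# metrotwas

Multi-ancestry transcriptome-wide association testing and Bayesian gene
fine-mapping from GWAS summary statistics.

## The problem

A transcriptome-wide association study (TWAS) asks whether the genetically
regulated component of a gene's expression (GReX) is associated with a
complex trait. Classical TWAS builds a cis-SNP expression prediction model in
a single reference population; that limits power and generalizability when
the GWAS population and the expression panel differ in allele frequencies,
LD, and eQTL effect sizes. `metrotwas` implements a joint-likelihood
multi-ancestry TWAS for analysts who have:

* per-ancestry expression panels (or prediction weights with uncertainty),
  e.g. an African-ancestry and a European-ancestry panel of roughly
  1032 and 801 individuals;
* GWAS summary statistics as marginal z-scores with an LD reference matrix;
* LD block definitions for post-hoc fine-mapping.

## The model

Per ancestry *m* ∈ {1, …, M}, expression follows the cis-eQTL model

```
z_m = G_m β_m + ε_m,        ε_m ~ N(0, σ²_m I)
```

and the trait acts only through genetically regulated expression

```
y = α (G β) + ε_y,          β = Σ_m w_m β_m,   Σ_m w_m = 1,  w_m ≥ 0.
```

`metro_test()` profiles `α` over a simplex grid of contribution weights `w`,
using the projected statistic `T(w) = b(w)ᵀz` with `b(w) = Σ_m w_m β̂_m`,
propagating the prediction-weight covariance into the likelihood's variance
and de-attenuating the GReX variance for estimation noise. Because `w` is
unidentified under `α = 0`, the grid-maximized likelihood-ratio statistic is
calibrated against a parametric empirical null (`calibrate_null()`), giving
well-controlled type-I error where a naive 1-df χ² reference is
anticonservative.

Significant genes (Bonferroni, `0.05 / n_genes`; at the study scale of
17,238 genes this is 2.90 × 10⁻⁶) are fine-mapped per LD block with
`focus_pip()`: every causal configuration of up to `max_causal` genes plus a
null (no causal gene) model is scored by its multivariate-normal marginal
likelihood under the GReX correlation matrix, yielding per-gene posterior
inclusion probabilities and a 90% credible set that may include the null
model.

A fully generative synthetic-data module (latent-Gaussian AR(1) haplotypes
thresholded at ancestry-specific allele frequencies, sparse
cross-ancestry-correlated eQTL architectures, traits generated through GReX)
makes every stage testable without access to restricted genotype or
expression data.

## Worked example

```r
library(metrotwas)

cfg <- sim_config(panel_sizes = c(1032, 801), n_snps = 30, n_gwas = 5000,
                  expr_h2 = 0.5, true_alpha = 0.5,
                  true_weights = c(0.5, 0.5), seed = 42)

panels <- lapply(1:2, function(m)
  simulate_expression(simulate_genotypes(cfg, m), cfg))
models <- lapply(panels, fit_expression_model, method = "ridge")
models[[1]]
#> <prediction_model> ANC1 (ridge): 30 SNPs, 30 nonzero, cv R2 = 0.473

beta <- 0.5 * panels[[1]]$true_betas + 0.5 * panels[[2]]$true_betas
gwas <- simulate_gwas_summary(cfg, composite_beta = beta)

fit <- metro_test(models, gwas, null_reps = 300, gene_id = "geneX")
tidy(fit)
#> # A tibble: 1 × 8
#>   gene  alpha   w_1   w_2   lrt         p   p_naive dominant_ancestry
#>   <chr> <dbl> <dbl> <dbl> <dbl>     <dbl>     <dbl> <chr>
#> 1 geneX 0.493  0.54  0.46 1138. 1.13e-292 1.62e-249 ANC1
```

The fitted `alpha` (0.493) recovers the simulated GReX effect (0.5) and the
contribution weights land near the simulated equal split, with the
empirically calibrated p-value far below any family-wise threshold. Regions
with several genes sharing eQTLs are then fine-mapped:

```r
region <- simulate_region(cfg, n_genes = 5, causal_gene = 2)
fm <- finemap_region(region)
fm
#> <finemap_result> 5 genes; null posterior = 3.25e-261;
#>   90% credible set: {gene_02, gene_03, gene_04}
tidy(fm)
#> # A tibble: 5 × 4
#>   gene_id       z    pip in_credible_set
#>   <chr>     <dbl>  <dbl> <lgl>
#> 1 gene_01 -0.0787 0.0372 FALSE
#> 2 gene_02 35.2    1      TRUE
#> 3 gene_03 24.2    0.0786 TRUE
#> 4 gene_04 -3.14   0.0765 TRUE
#> 5 gene_05 -1.21   0.0765 FALSE
```

The causal gene (`gene_02`) gets posterior inclusion probability 1; its
cis-window-sharing neighbours retain small probabilities and pad the
credible set to the 90% level. `plot_manhattan()`, `plot_qq()` and the
`autoplot()` methods render the standard figures;
`contribution_summary()`, `overlap_counts()`, `canonicalize()` and
`enrich_hypergeometric()` cover downstream reporting.

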
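---
title: "Multi-ancestry TWAS and gene fine-mapping: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-ancestry TWAS and gene fine-mapping: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metrotwas)
```

This vignette is the package's account of its statistical machinery: the
generative model behind the synthetic-data module, the joint multi-ancestry
association test and its calibration, the Bayesian fine-mapping scheme, the
defaults and why they were chosen, and the limits of what the simulation
evidence shows.

## The two-equation model

Everything in the package is organized around a pair of linear models. For
each ancestry $m \in \{1, \dots, M\}$ with expression panel of size $n_m$,

$$z_m = G_m \beta_m + \varepsilon_m, \qquad
\varepsilon_{m,i} \sim N(0, \sigma^2_m),$$

where $G_m$ is the $n_m \times p$ cis-SNP dosage matrix and $\beta_m$ the
sparse vector of cis-eQTL effects. The GWAS trait of $n$ individuals acts on
the trait only through genetically regulated expression (GReX):

$$y = \alpha\, (G\beta) + \varepsilon_y, \qquad
\beta = \sum_m w_m \beta_m, \quad \sum_m w_m = 1,\; w_m \ge 0.$$

The key structural assumption is that the GWAS-side SNP-expression effects
are a convex combination of the per-ancestry effects; the simplex weight
$w_m$ is the "contribution" of ancestry $m$'s expression model to the
association. Expression, trait, and genotype columns are all centered and
standardized, so $\alpha$ is the trait effect per standard deviation of
GReX. The pipeline never consumes individual-level GWAS data: the trait
enters only as marginal z-scores $z_j = \sqrt{n}\,\mathrm{cor}(g_j, y)$
plus an LD correlation matrix $R$ from an ancestry-matched reference panel.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested without
restricted genotype or expression data. It draws:

* **Genotypes** — two independent latent-Gaussian AR(1) haplotypes per
  individual, thresholded at the allele-frequency quantile and summed to a
  dosage in $\{0, 1, 2\}$. The latent process has
  $\mathrm{cor}(x_i, x_j) = \rho^{|i-j|}$, which gives a closed-form target
  for LD-decay tests; the post-thresholding dosage LD is checked against a
  direct multivariate-normal oracle rather than against $\rho^{|i-j|}$
  itself, since thresholding attenuates correlations. Allele frequencies
  are drawn uniformly from a per-ancestry range bounded below at 1% — the
  generator never produces the low-frequency variants that a standard
  post-imputation MAF filter would remove, so the filter is enforced by
  construction.
* **Expression** — causal cis-SNP positions are drawn once per
  configuration and shared across ancestries; raw effect sizes are jointly
  normal across ancestries with an equicorrelation set by
  `cross_ancestry_effect_corr` (default 0.8, a high-but-imperfect sharing
  typical of cross-population eQTL comparisons). Effects are rescaled so the
  genetic component explains `expr_h2` (default 0.5) of expression variance,
  and expression is returned centered and unit-variance with `true_betas`
  stored on that final scale.
* **GWAS summaries** — the trait is simulated at the individual level on an
  internal GWAS genotype panel from a designated ancestry's law, with GReX
  standardized and the residual variance set so the trait has variance one;
  it is then immediately reduced to the $(z, R, n)$ summary form, which is
  the only thing downstream code sees.
* **Regions** — `simulate_region()` lays out $k$ genes with cis-windows
  overlapping by a configurable fraction (default 50%) on a shared SNP
  frame, gives each gene an independent sparse architecture, and lets
  exactly one designated gene (or none) carry the GReX effect. Gene windows
  are index ranges on the shared frame; physical coordinates and window
  widths are consumed as given by the caller's annotation, not decided by
  the package.

Default panel sizes are 1032 and 801 individuals for the two ancestries,
matching the scale of the two-population expression reference the design
emulates; the default GWAS size in examples and validation runs is 2000 to
5000, chosen so that tests complete quickly while the normal approximation
to the marginal statistics is comfortably accurate. Reproducibility is
strict: all generator functions derive their RNG streams deterministically
from `config$seed`, so an identical configuration reproduces bit-identical
data, and the global RNG state of the caller is saved and restored around
every draw.

What the generator does **not** emulate: realistic haplotype structure
(recombination hotspots, population-specific LD beyond an AR(1) decay rate),
allele-frequency spectra, covariate structure (age, sex, ancestry principal
components), sample relatedness, or imputation error. Passing tests
therefore demonstrate internal statistical correctness of the methods under
the stated model — calibration, recovery, oracle agreement — not robustness
to the full messiness of real cohort data.

## Expression prediction models

`fit_expression_model()` provides two penalized-regression surrogates for
the dense- and sparse-effect prediction models used in this literature:
ridge with its closed-form solution and Gaussian posterior covariance, and
elastic net (via glmnet) with a diagonal covariance from a residual
bootstrap (default 100 replicates). A Bayesian sparse linear mixed model is
deliberately not implemented: the association stage only requires weights
plus an uncertainty summary, and both surrogates supply exactly that.

The penalty is selected by 5-fold cross-validation over a 20-point
log-spaced grid with ties broken toward the stronger penalty. For ridge the
grid is built on the unit-variance response, which makes the quadratic
penalty — and hence the fitted weights — equivariant in the expression
scale. Genes whose cross-validated $R^2$ falls below a configurable floor
(default 0.01) are flagged non-predictive so callers can exclude them from
association testing; the floor is a pragmatic screening default, not an
estimate of any particular study's inclusion rule.

## The joint association test and its calibration

The exact likelihood machinery of the published multi-ancestry TWAS method
this package interoperates with is not restated in the sources available to
it, so the inference here is a declared reconstruction, validated by its
operating characteristics rather than equation-level fidelity. For each
weight vector $w$ on a simplex grid (step 0.01 for $M = 2$; a lattice of at
most 5000 points for larger $M$), the composite weights
$b(w) = \sum_m w_m \hat\beta_m$ reduce the z-score vector to
$T(w) = b(w)^\top z$, modeled as

$$T(w) \sim N\!\left(\sqrt{n}\,\alpha\,\sqrt{q_c},\;
q + \mathrm{tr}(V_w R) + n \alpha^2 s / q_c\right)$$

with $q = b^\top R b$, $V_w = \sum_m w_m^2\,\widehat{\mathrm{Cov}}(\hat\beta_m)$,
$s = (Rb)^\top V_w (Rb)$, and $q_c = \max(q - \mathrm{tr}(V_w R), 10^{-8})$.
Three numerical points matter:

* $q_c$ de-attenuates the apparent GReX variance: $E[\hat b^\top R \hat b]$
  exceeds the true $\beta^\top R \beta$ by $\mathrm{tr}(V_w R)$, and without
  the correction $\hat\alpha$ would be biased toward zero by exactly that
  inflation. With it, uniform shrinkage of the weight estimates cancels in
  the $\alpha$ scaling, and the recovery tests confirm near-unbiasedness.
* $V_w$ also penalizes weight vectors that lean on noisy prediction models
  (larger null variance, weaker signal-to-noise), which is what drives the
  upweighting of the more informative ancestry.
* $R$ is shrunk toward the identity, $(1-\lambda)R + \lambda I$ with
  $\lambda = 0.1$, wherever it is inverted or factorized — standard TWAS
  practice that guarantees invertibility of a sample correlation matrix;
  the stored LD itself is left untouched.

$\alpha$ is profiled at each grid point by a bounded one-dimensional
optimization (the interval is centered on the closed-form
no-uncertainty estimate $T / \sqrt{n q_c}$, which is also the classical
summary-TWAS estimator; with $M = 1$ the whole procedure collapses to it).
The reported fit maximizes the per-point likelihood ratio over the grid —
comparing likelihood *ratios* rather than likelihoods keeps grid points with
different data reductions commensurable. Grid ties break toward equal
weights, then toward more weight on the lower ancestry index.

Under $\alpha = 0$ the weights are unidentified, so the grid-maximized LRT
is stochastically larger than $\chi^2_1$ and a naive 1-df p-value is
anticonservative (the suite demonstrates this directly).
`calibrate_null()` therefore simulates $B$ null z-vectors from
$\mathrm{MVN}(0, R_\lambda)$, recomputes the grid-max LRT on each, and
moment-matches a scaled chi-squared ($a = \mathrm{var}/2\,\mathrm{mean}$,
$d = 2\,\mathrm{mean}^2/\mathrm{var}$; fed genuine $\chi^2_1$ draws this
returns $a = 1, d = 1$). The null object depends only on the SNP frame,
the models, and the grid, so it is cached and reused across GWAS replicates
of the same gene; the default $B = 500$ balances tail resolution against
runtime, with a warning below 200. Validation uses 2000 null genes spread
over 10 independently drawn architectures (300-individual panels, 20 SNPs,
GWAS $n$ = 2000), and parameter recovery uses 200 replicates at GWAS
$n$ = 5000 — sizes chosen as the package's own validation conditions.

## Fine-mapping

Gene-level signed scores are $Z_g = b_g^\top z / \sqrt{b_g^\top R_\lambda b_g}$
on simulated data, or $z = \mathrm{sign}(\hat\alpha)\,\Phi^{-1}(1 - p/2)$
when converting reported two-sided p-values (computed on the log scale so
p-values below $10^{-300}$ survive; the sign convention follows the fitted
effect direction). Genes are partitioned by transcription-start position
into non-overlapping half-open LD blocks; a gene outside every block gets a
singleton block and a warning rather than an error, since dropping it
silently would bias region-level summaries.

Within a block, the GReX correlation matrix
$\Sigma_{ij} = b_i^\top R b_j / \sqrt{(b_i^\top R b_i)(b_j^\top R b_j)}$ is
floored at eigenvalue $10^{-6}$ (perfectly collinear genes otherwise make
the marginal likelihood degenerate). `focus_pip()` enumerates all causal
configurations $c$ with $|c| \le$ `max_causal` (default 3) plus the empty
configuration, scoring each by the marginal likelihood
$\mathrm{MVN}(z; 0, \Sigma + \sigma^2_{\text{prior}} \Sigma_{\cdot c}
\Sigma_{c \cdot})$ times the prior $p^{|c|}(1-p)^{k-|c|}$. Defaults:
$p = 1/k$ per block (clamped to $1/2$ for single-gene blocks so the prior
stays proper) and effect-prior variance $\sigma^2_{\text{prior}} = 40$ on
the non-centrality scale — a signal size in the mid-$|z| \approx 6$ range
typical of genes that clear a transcriptome-wide Bonferroni threshold. All
three are exposed arguments, not constants.

The credible set ranks the genes *and* the null-model marker by posterior
mass (the null's mass is its configuration posterior), breaking ties by
$|z|$ then gene id, and takes the minimal prefix whose cumulative
normalized mass reaches the level (default 0.90). Normalization divides by
the total mass of the ranked items ($\sum_i \mathrm{PIP}_i +$ null
posterior); with multi-causal configurations the marginal PIPs can sum to
more than one, and normalizing keeps the prefix rule well-defined while
reducing to the configuration-posterior ranking in the dominant
single-causal regime. The null marker can appear inside the set, which is
the honest statement that "no causal gene here" is itself a credible
explanation.

Calibration is checked frequentist-style on the method's own prior: several
hundred five-gene regions, causal gene uniform, effect drawn from
$N(0, \sigma^2_{\text{prior}})$, individual-level simulation through
`simulate_region()`, and coverage of the 90% credible set compared against
the nominal rate with a Monte-Carlo margin. The generation uses exactly one
causal gene per region while the analysis prior allows zero to three;
with the strong effect prior this mismatch is minor and coverage sits at or
above nominal in the suite and the acceptance script.

## Reporting utilities

Gene-list comparisons canonicalize symbols through a user-supplied synonym
table (chains are followed, cycles are an error, collapses are logged);
Venn region counts are exact set algebra for 2–4 lists. The enrichment
helper is a plain upper-tail hypergeometric test per gene set with
Benjamini–Hochberg adjustment across sets — a deliberately transparent local
procedure, *not* the multi-layer g:SCS correction used by the g:Profiler
web service, and its adjusted p-values should not be compared to g:SCS
output. Figures (Manhattan with the Bonferroni line, QQ with the genomic
inflation factor $\lambda = \mathrm{median}(\chi^2) / 0.4549$) are plain
ggplot2 objects.

## Degenerate inputs and edge cases

Configuration validation refuses non-simplex weights, AR(1) correlations
outside $[0, 1)$, heritability of 1, and allele frequencies at or below the
1% floor. A nonzero GReX effect with an all-zero eQTL architecture warns
(the trait then carries no genetic signal); constant expression vectors,
zero-norm gene weight vectors, overlapping LD blocks, SNP-set mismatches
between models and GWAS (reported with the offending SNP names), and
out-of-range p-values are errors. Strand-ambiguous A/T and C/G SNPs are
dropped during allele harmonization with a logged count, and z signs are
negated on effect-allele swaps.

## Known limitations

* Single-gene-at-a-time association testing: no conditional or joint
  multi-gene association model (fine-mapping is the package's answer to
  shared-eQTL regions).
* The projected statistic $T(w)$ is a one-dimensional reduction per weight
  vector; it inherits the efficiency of the classical summary-TWAS statistic
  rather than full multivariate efficiency.
* The elastic-net covariance is diagonal (residual bootstrap); dense
  covariance is only available through the ridge path.
* No trans-eQTLs, covariates, or relatedness anywhere in the generator or
  the models; no SNP-level fine-mapping; LD blocks are consumed, never
  estimated.
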
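#' Configuration for the synthetic multi-ancestry TWAS generator
#'
#' Bundles every knob of the generative model: the number of ancestry panels
#' and their sizes, the GWAS sample size, the cis-SNP architecture (count,
#' allele-frequency ranges, AR(1) LD decay), the sparse eQTL model (number of
#' causal cis-SNPs, expression heritability, cross-ancestry effect-size
#' correlation), and the trait model (GReX effect `alpha` and the simplex
#' contribution weights). Defaults emulate a two-population expression
#' reference of 1032 African-ancestry and 801 European-ancestry individuals.
#'
#' @param n_ancestries Number of ancestry panels M (>= 1).
#' @param panel_sizes Integer vector of per-ancestry sample sizes, length M.
#' @param n_gwas GWAS sample size n.
#' @param n_snps Number of cis-SNPs p per gene.
#' @param maf_range Allele-frequency range, either a single pair used for all
#'   ancestries or a list of M pairs; values in (0.01, 0.5] (variants with
#'   minor allele frequency at or below 1% are excluded by design, mirroring
#'   standard post-imputation filtering).
#' @param ld_rho AR(1) adjacent-SNP correlation of the latent haplotype
#'   process, one value per ancestry (recycled), each in [0, 1).
#' @param n_causal_eqtl Number of cis-SNPs with nonzero effects on expression.
#' @param expr_h2 Target fraction of expression variance explained by
#'   genotype, in [0, 1).
#' @param cross_ancestry_effect_corr Correlation of causal effect sizes
#'   between any two ancestries, in [-1, 1].
#' @param true_alpha Effect of (unit-variance) genetically regulated
#'   expression on the trait.
#' @param true_weights Simplex vector (length M, nonnegative, summing to 1)
#'   weighting each ancestry's SNP effects in the composite GWAS-side
#'   architecture.
#' @param seed Integer RNG seed stored with the configuration; generator
#'   functions seed from it so identical configurations reproduce bit-identical
#'   data.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_gwas = 2000, n_snps = 20, seed = 1)
#' cfg$panel_sizes
#' @export
sim_config <- function(n_ancestries = 2,
                       panel_sizes = c(1032, 801),
                       n_gwas = 5000,
                       n_snps = 50,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.5,
                       n_causal_eqtl = 5,
                       expr_h2 = 0.5,
                       cross_ancestry_effect_corr = 0.8,
                       true_alpha = 0.5,
                       true_weights = NULL,
                       seed = 1L) {
  M <- n_ancestries
  if (!is_count(M) || M < 1) abort("`n_ancestries` must be an integer >= 1.")
  if (length(panel_sizes) != M)
    abort("`panel_sizes` must have one entry per ancestry.")
  if (!all(vapply(panel_sizes, is_count, logical(1))) || any(panel_sizes < 2))
    abort("`panel_sizes` must be integers >= 2.")
  if (!is_count(n_gwas) || n_gwas < 2) abort("`n_gwas` must be an integer >= 2.")
  if (!is_count(n_snps) || n_snps < 1) abort("`n_snps` must be an integer >= 1.")
  if (!is.list(maf_range)) maf_range <- rep(list(maf_range), M)
  if (length(maf_range) != M) maf_range <- rep(maf_range, length.out = M)
  for (r in maf_range) {
    if (length(r) != 2 || any(r <= 0.01) || any(r > 0.5) || r[1] > r[2])
      abort("each `maf_range` must be a pair in (0.01, 0.5] (MAF <= 0.01 excluded).")
  }
  ld_rho <- rep(ld_rho, length.out = M)
  if (any(ld_rho < 0) || any(ld_rho >= 1))
    abort("`ld_rho` must lie in [0, 1).")
  if (!is_count(n_causal_eqtl) || n_causal_eqtl > n_snps)
    abort("`n_causal_eqtl` must be an integer in [0, n_snps].")
  if (expr_h2 < 0 || expr_h2 >= 1) abort("`expr_h2` must lie in [0, 1).")
  if (expr_h2 > 0 && n_causal_eqtl == 0)
    abort("`expr_h2` > 0 requires at least one causal eQTL.")
  if (abs(cross_ancestry_effect_corr) > 1)
    abort("`cross_ancestry_effect_corr` must lie in [-1, 1].")
  if (is.null(true_weights)) true_weights <- rep(1 / M, M)
  if (length(true_weights) != M || any(true_weights < 0) ||
      abs(sum(true_weights) - 1) > 1e-8)
    abort("`true_weights` must be a length-M simplex vector (>= 0, sum 1).")
  if (abs(true_alpha) >= 1)
    abort("`true_alpha` must satisfy |alpha| < 1 so the residual trait variance stays positive.")
  structure(
    list(
      n_ancestries = as.integer(M),
      panel_sizes = as.integer(panel_sizes),
      n_gwas = as.integer(n_gwas),
      n_snps = as.integer(n_snps),
      maf_range = maf_range,
      ld_rho = ld_rho,
      n_causal_eqtl = as.integer(n_causal_eqtl),
      expr_h2 = expr_h2,
      cross_ancestry_effect_corr = cross_ancestry_effect_corr,
      true_alpha = true_alpha,
      true_weights = true_weights,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_ancestries, "ancestr",
      if (x$n_ancestries == 1) "y" else "ies",
      "| panels:", paste(x$panel_sizes, collapse = "/"),
      "| n_gwas:", x$n_gwas, "| p:", x$n_snps, "\n")
  cat("  eQTL: ", x$n_causal_eqtl, " causal, h2 = ", x$expr_h2,
      ", cross-ancestry effect corr = ", x$cross_ancestry_effect_corr, "\n",
      sep = "")
  cat("  trait: alpha = ", x$true_alpha, ", weights = (",
      paste(format(x$true_weights), collapse = ", "), "), seed = ",
      x$seed, "\n", sep = "")
  invisible(x)
}
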
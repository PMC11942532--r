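#' Synthetic multi-ancestry genotype, expression and GWAS generator
#'
#' The generative model mirrors the two-equation TWAS structure the pipeline
#' estimates. Per ancestry m, expression is `z_m = G_m beta_m + e_m` with a
#' sparse `beta_m` whose causal effects are correlated across ancestries; the
#' GWAS trait acts only through genetically regulated expression,
#' `y = alpha * GReX + e_y`, built from the composite architecture
#' `beta = sum_m w_m beta_m`, and is then reduced to marginal z-scores plus a
#' reference LD matrix — the only form downstream stages consume.
#'
#' @name synthetic-data
NULL

# Deterministic sub-seeds so each generator call is reproducible from the
# config seed alone while using distinct streams. Kept below 2^31.
sub_seed <- function(seed, stream, index = 0L) {
  (abs(seed) %% 1000003L) * 1009L + stream * 97L + index
}

# Joint draw of the sparse eQTL architecture shared by all ancestry panels:
# causal positions plus an (n_causal x M) effect matrix with equicorrelated
# columns at the configured cross-ancestry correlation.
draw_true_effects <- function(config) {
  M <- config$n_ancestries
  r <- config$cross_ancestry_effect_corr
  k <- config$n_causal_eqtl
  if (M > 1 && r < -1 / (M - 1))
    abort("cross-ancestry effect correlation is not positive semi-definite for this many ancestries.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(config$seed, 1L))
  idx <- sort(sample.int(config$n_snps, k))
  S <- matrix(r, M, M); diag(S) <- 1
  U <- chol(S + diag(1e-10, M))
  eff <- matrix(rnorm(k * M), k, M) %*% U
  list(causal_idx = idx, effects = eff)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# One AR(1) latent-Gaussian haplotype matrix (n x p): column j satisfies
# x_j = rho x_{j-1} + sqrt(1-rho^2) e_j, so latent corr(x_i, x_j) = rho^|i-j|.
latent_ar1 <- function(n, p, rho) {
  x <- matrix(0, n, p)
  x[, 1] <- rnorm(n)
  if (p > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) x[, j] <- rho * x[, j - 1] + s * rnorm(n)
  }
  x
}

#' Simulate an ancestry panel's genotype dosages
#'
#' Dosages are formed from two independent latent-Gaussian AR(1) haplotypes
#' per individual, each thresholded at the allele-frequency quantile, so the
#' latent LD decays as `rho^|i-j|` and each column's alternate-allele
#' frequency matches its drawn value. Allele frequencies are drawn uniformly
#' from the ancestry's configured range (bounded above 1%, i.e. the
#' low-frequency variants a standard MAF filter would remove are never
#' generated).
#'
#' @param config A [sim_config()].
#' @param ancestry_index Which ancestry panel to draw (1-based, <= M).
#' @return An `ancestry_panel` object: list with `ancestry_label`,
#'   `ancestry_index`, `genotypes` (n_m x p dosage matrix in \[0, 2\]),
#'   `allele_freqs`, and (until [simulate_expression()] fills them)
#'   `expression = NULL`, `true_betas = NULL`.
#' @examples
#' panel <- simulate_genotypes(sim_config(n_snps = 10, seed = 7), 1)
#' dim(panel$genotypes)
#' @export
simulate_genotypes <- function(config, ancestry_index) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(ancestry_index) || ancestry_index < 1 ||
      ancestry_index > config$n_ancestries)
    abort("`ancestry_index` must be in 1..n_ancestries.")
  n <- config$panel_sizes[ancestry_index]
  p <- config$n_snps
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(config$seed, 2L, ancestry_index))
  rng <- config$maf_range[[ancestry_index]]
  f <- runif(p, rng[1], rng[2])
  rho <- config$ld_rho[ancestry_index]
  thr <- qnorm(1 - f)
  G <- (sweep(latent_ar1(n, p, rho), 2, thr, ">") +
        sweep(latent_ar1(n, p, rho), 2, thr, ">")) * 1
  storage.mode(G) <- "double"
  colnames(G) <- sprintf("snp_%04d", seq_len(p))
  structure(
    list(
      ancestry_label = paste0("ANC", ancestry_index),
      ancestry_index = as.integer(ancestry_index),
      genotypes = G,
      allele_freqs = f,
      expression = NULL,
      true_betas = NULL
    ),
    class = "ancestry_panel"
  )
}

#' @export
print.ancestry_panel <- function(x, ...) {
  cat("<ancestry_panel> ", x$ancestry_label, ": ", nrow(x$genotypes),
      " individuals x ", ncol(x$genotypes), " cis-SNPs; expression ",
      if (is.null(x$expression)) "not yet simulated" else "present", "\n",
      sep = "")
  invisible(x)
}

#' Simulate gene expression for a panel under the sparse cis-eQTL model
#'
#' Fills `panel$expression` with `z = G beta + e`: the causal positions and
#' cross-ancestry-correlated raw effects come from a joint draw shared by all
#' panels of the same configuration; effects are rescaled per panel so the
#' genetic component explains `expr_h2` of the expression variance, the
#' residual supplying the rest. The returned expression is centered and
#' scaled to unit variance and `true_betas` are expressed on that final
#' scale (per standardized-genotype column), so `z ~= G_std %*% true_betas +
#' residual` holds exactly.
#'
#' @param panel An `ancestry_panel` from [simulate_genotypes()].
#' @param config The same [sim_config()] used to draw the panel.
#' @return The panel with `expression` (length n_m, unit variance) and
#'   `true_betas` (length p) filled.
#' @export
simulate_expression <- function(panel, config) {
  stopifnot(inherits(panel, "ancestry_panel"), inherits(config, "sim_config"))
  n <- nrow(panel$genotypes); p <- ncol(panel$genotypes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(config$seed, 3L, panel$ancestry_index))
  beta <- numeric(p)
  h2 <- config$expr_h2
  if (config$n_causal_eqtl > 0 && h2 > 0) {
    arch <- draw_true_effects(config)
    beta[arch$causal_idx] <- arch$effects[, panel$ancestry_index]
    Gs <- standardize_columns(panel$genotypes)
    g <- drop(Gs %*% beta)
    sg <- sd(g)
    if (sg == 0) abort("degenerate genotypes: genetic component has zero variance.")
    beta <- beta * sqrt(h2) / sg
    g <- g * sqrt(h2) / sg
    z <- g + rnorm(n, sd = sqrt(1 - h2))
  } else {
    z <- rnorm(n)
  }
  sz <- sd(z)
  panel$expression <- as.numeric(scale(z))
  panel$true_betas <- beta / sz
  panel
}

#' GWAS summary-statistics container
#'
#' @param snp_ids Character vector of SNP identifiers (length p).
#' @param z Marginal z-scores (length p, finite).
#' @param ld p x p SNP correlation matrix from the GWAS-matched reference
#'   panel: symmetric, unit diagonal, entries in \[-1, 1\].
#' @param n_gwas GWAS sample size.
#' @param alleles Tibble with columns `A1` (effect) and `A2` (other), one row
#'   per SNP; defaults to synthetic non-ambiguous alleles.
#' @param chr,bp Optional coordinates carried for writers and plots.
#' @return A `gwas_summary` object.
#' @export
gwas_summary <- function(snp_ids, z, ld, n_gwas, alleles = NULL,
                         chr = NULL, bp = NULL) {
  p <- length(snp_ids)
  if (length(z) != p || !all(is.finite(z)))
    abort("`z` must be finite and match `snp_ids` in length.")
  if (!is.matrix(ld) || any(dim(ld) != p))
    abort("`ld` must be a p x p matrix.")
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)))
    abort("`ld` must be symmetric.")
  if (any(diag(ld) != 1)) abort("`ld` must have an exactly unit diagonal.")
  if (max(abs(ld)) > 1 + 1e-8) abort("`ld` entries must lie in [-1, 1].")
  if (is.null(alleles)) {
    # alternate strand-unambiguous pairs so harmonization never drops them
    pairs <- list(c("A", "G"), c("C", "T"))
    alleles <- tibble::tibble(
      A1 = vapply(seq_len(p), function(i) pairs[[1 + i %% 2]][1], ""),
      A2 = vapply(seq_len(p), function(i) pairs[[1 + i %% 2]][2], "")
    )
  }
  structure(
    list(snp_ids = snp_ids, z = as.numeric(z), ld = ld,
         n_gwas = as.integer(n_gwas), alleles = alleles,
         chr = chr %||% rep(1L, p), bp = bp %||% seq_len(p) * 1000L),
    class = "gwas_summary"
  )
}

#' @export
print.gwas_summary <- function(x, ...) {
  cat("<gwas_summary> ", length(x$z), " SNPs, n = ", x$n_gwas,
      ", mean z^2 = ", round(mean(x$z^2), 3), "\n", sep = "")
  invisible(x)
}

#' Simulate GWAS summary statistics from a composite eQTL architecture
#'
#' Simulates the individual-level trait `y = alpha * GReX + e_y` on a GWAS
#' genotype panel (drawn from a designated ancestry's generative law when not
#' supplied), with GReX standardized to unit variance and the residual
#' variance set so the trait has variance one, then reduces to the summary
#' form the pipeline consumes: marginal z-scores `z_j = sqrt(n) cor(g_j, y)`
#' and the reference-panel LD correlation matrix.
#'
#' @param config A [sim_config()]; `true_alpha` is the GReX effect used.
#' @param gwas_panel_genotypes Optional n x p dosage matrix for the GWAS
#'   individuals; drawn internally from `gwas_ancestry`'s law when `NULL`.
#' @param composite_beta Length-p composite SNP effects
#'   `beta = sum_m w_m beta_m` (per standardized-genotype column).
#' @param ld_reference Optional dosage matrix for the LD reference; defaults
#'   to the GWAS panel itself.
#' @param gwas_ancestry Ancestry index whose generative law supplies the
#'   internal GWAS panel (default 1).
#' @return A [gwas_summary()] object.
#' @export
simulate_gwas_summary <- function(config, gwas_panel_genotypes = NULL,
                                  composite_beta = NULL,
                                  ld_reference = NULL, gwas_ancestry = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(config$seed, 4L, gwas_ancestry))
  n <- config$n_gwas
  if (is.null(gwas_panel_genotypes)) {
    rng <- config$maf_range[[gwas_ancestry]]
    p <- config$n_snps
    f <- runif(p, rng[1], rng[2])
    thr <- qnorm(1 - f)
    rho <- config$ld_rho[gwas_ancestry]
    gwas_panel_genotypes <-
      (sweep(latent_ar1(n, p, rho), 2, thr, ">") +
       sweep(latent_ar1(n, p, rho), 2, thr, ">")) * 1
    colnames(gwas_panel_genotypes) <- sprintf("snp_%04d", seq_len(p))
  }
  p <- ncol(gwas_panel_genotypes)
  if (is.null(composite_beta)) composite_beta <- numeric(p)
  if (length(composite_beta) != p)
    abort("`composite_beta` must have one entry per SNP.")
  Gs <- standardize_columns(gwas_panel_genotypes)
  alpha <- config$true_alpha
  if (all(composite_beta == 0)) {
    if (alpha != 0)
      warn("`true_alpha` is nonzero but the composite eQTL effects are all zero: the trait carries no genetic signal.")
    y <- rnorm(n)
  } else {
    grex <- drop(Gs %*% composite_beta)
    grex <- grex / sd(grex)
    y <- alpha * grex + rnorm(n, sd = sqrt(1 - alpha^2))
  }
  y <- as.numeric(scale(y))
  z <- drop(crossprod(Gs, y)) / sqrt(n)
  ref <- if (is.null(ld_reference)) gwas_panel_genotypes else ld_reference
  R <- cor(ref)
  diag(R) <- 1
  ids <- colnames(gwas_panel_genotypes) %||% sprintf("snp_%04d", seq_len(p))
  gwas_summary(snp_ids = ids, z = z, ld = R, n_gwas = n)
}

#' Simulate a multi-gene region for fine-mapping
#'
#' Builds a region of `n_genes` genes with partially overlapping cis-windows
#' over a shared SNP set, each gene carrying its own independent sparse eQTL
#' architecture; exactly the designated gene (or none) has a nonzero effect
#' of its genetically regulated expression on the trait. Emits everything the
#' fine-mapping stage needs: the region truth (gene windows, per-gene true
#' weight vectors on the shared SNP frame, the causal index) and the GWAS
#' summary statistics over all region SNPs.
#'
#' @param config A [sim_config()]; `n_snps` is the per-gene cis-window width
#'   and `true_alpha` the causal gene's GReX effect.
#' @param n_genes Number of genes in the region (>= 1).
#' @param causal_gene 1-based index of the causal gene, or `NULL` for a fully
#'   null region.
#' @param overlap Fraction of each cis-window shared with its neighbour
#'   (default 0.5).
#' @return A list with `scenario` (a `region_scenario`: `genes` tibble with
#'   `gene_id`, `snp_start`, `snp_end`; `true_weights` p_total x n_genes
#'   matrix; `causal_gene`) and `gwas` (a [gwas_summary()]).
#' @export
simulate_region <- function(config, n_genes, causal_gene = NULL,
                            overlap = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(n_genes) || n_genes < 1) abort("`n_genes` must be >= 1.")
  if (!is.null(causal_gene) &&
      (!is_count(causal_gene) || causal_gene < 1 || causal_gene > n_genes))
    abort("`causal_gene` must be in 1..n_genes or NULL.")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must lie in [0, 1).")
  w <- config$n_snps
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  p_tot <- w + (n_genes - 1L) * step
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(config$seed, 5L))
  n <- config$n_gwas
  rng <- config$maf_range[[1]]
  f <- runif(p_tot, rng[1], rng[2])
  thr <- qnorm(1 - f)
  rho <- config$ld_rho[1]
  G <- (sweep(latent_ar1(n, p_tot, rho), 2, thr, ">") +
        sweep(latent_ar1(n, p_tot, rho), 2, thr, ">")) * 1
  colnames(G) <- sprintf("snp_%04d", seq_len(p_tot))
  Gs <- standardize_columns(G)

  genes <- tibble::tibble(
    gene_id = sprintf("gene_%02d", seq_len(n_genes)),
    snp_start = 1L + (seq_len(n_genes) - 1L) * step,
    snp_end = 1L + (seq_len(n_genes) - 1L) * step + w - 1L
  )
  B <- matrix(0, p_tot, n_genes,
              dimnames = list(colnames(G), genes$gene_id))
  for (g in seq_len(n_genes)) {
    idx <- genes$snp_start[g]:genes$snp_end[g]
    causal <- idx[sort(sample.int(w, max(1L, config$n_causal_eqtl)))]
    b <- numeric(p_tot)
    b[causal] <- rnorm(length(causal))
    grex <- drop(Gs %*% b)
    B[, g] <- b / sd(grex)          # unit-variance GReX per gene
  }
  alpha <- if (is.null(causal_gene)) 0 else config$true_alpha
  if (alpha != 0) {
    y <- alpha * drop(Gs %*% B[, causal_gene]) +
      rnorm(n, sd = sqrt(1 - alpha^2))
  } else {
    y <- rnorm(n)
  }
  y <- as.numeric(scale(y))
  z <- drop(crossprod(Gs, y)) / sqrt(n)
  R <- cor(G); diag(R) <- 1
  scenario <- structure(
    list(genes = genes, true_weights = B,
         causal_gene = if (is.null(causal_gene)) NA_integer_
                       else as.integer(causal_gene)),
    class = "region_scenario"
  )
  list(scenario = scenario,
       gwas = gwas_summary(colnames(G), z, R, n))
}

#' @export
print.region_scenario <- function(x, ...) {
  cat("<region_scenario> ", nrow(x$genes), " genes over ",
      nrow(x$true_weights), " SNPs; causal gene: ",
      if (is.na(x$causal_gene)) "none" else x$genes$gene_id[x$causal_gene],
      "\n", sep = "")
  invisible(x)
}
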
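#' Multi-ancestry TWAS: joint summary-statistic test
#'
#' Combines per-ancestry expression prediction models with GWAS summary
#' statistics (marginal z-scores plus an LD reference) to estimate the effect
#' `alpha` of genetically regulated expression (GReX) on the trait together
#' with per-ancestry contribution weights on the simplex.
#'
#' For each candidate weight vector `w` on a simplex grid the composite SNP
#' architecture is `b(w) = sum_m w_m beta_hat_m`, reduced to the projected
#' statistic `T(w) = b(w)' z`. Under the generative model `T(w)` is normal
#' with mean `sqrt(n) * alpha * sqrt(q_corr)` and variance
#' `q + tr(V_w R) + n alpha^2 s / q_corr`, where `q = b'Rb`,
#' `V_w = sum w_m^2 beta_cov_m` propagates prediction-weight uncertainty,
#' `s = (Rb)' V_w (Rb)`, and `q_corr = q - tr(V_w R)` de-attenuates the GReX
#' variance for estimation noise in the weights. `alpha` is profiled out at
#' each grid point; the reported fit maximizes the per-point likelihood-ratio
#' statistic over the grid, and the LRT against `alpha = 0` is converted to a
#' p-value with a moment-matched scaled chi-squared empirical null (the grid
#' maximum leaves `w` unidentified under the null, so a plain 1-df reference
#' is anticonservative; that naive p-value is also reported as `p_naive` for
#' diagnostics).
#'
#' @param models List of `prediction_model` objects, one per ancestry, on a
#'   shared SNP set aligned with `gwas`.
#' @param gwas A [gwas_summary()].
#' @param grid_step Simplex grid step for M = 2 (default 0.01).
#' @param max_grid_points Cap on grid size for M > 2 (default 5000).
#' @param ld_shrink Shrinkage weight toward the identity applied to the LD
#'   matrix wherever it is used (default 0.1).
#' @param null A cached `metro_null` from [calibrate_null()]; computed on the
#'   fly (B = `null_reps`) when absent.
#' @param null_reps Replicates for on-the-fly null calibration (default 500).
#' @param gene_id Optional gene identifier carried into the result.
#' @param seed Seed used only if the null must be computed on the fly.
#' @return A `metro_fit`: `gene_id`, `alpha_hat`, `weights_hat` (simplex),
#'   `loglik_alt`, `loglik_null`, `lrt_stat`, `p_value`, `p_naive`,
#'   `dominant_ancestry`, plus the per-grid profile for diagnostics.
#' @examples
#' cfg <- sim_config(panel_sizes = c(400, 400), n_snps = 12, n_gwas = 3000,
#'                   seed = 11)
#' panels <- lapply(1:2, function(m)
#'   simulate_expression(simulate_genotypes(cfg, m), cfg))
#' models <- lapply(panels, fit_expression_model, method = "ridge")
#' beta <- rowMeans(cbind(panels[[1]]$true_betas, panels[[2]]$true_betas))
#' gwas <- simulate_gwas_summary(cfg, composite_beta = beta)
#' fit <- metro_test(models, gwas, null_reps = 200)
#' tidy(fit)
#' @export
metro_test <- function(models, gwas,
                       grid_step = 0.01,
                       max_grid_points = 5000,
                       ld_shrink = 0.1,
                       null = NULL,
                       null_reps = 500,
                       gene_id = "gene",
                       seed = 1L) {
  stopifnot(inherits(gwas, "gwas_summary"))
  if (inherits(models, "prediction_model")) models <- list(models)
  M <- length(models)
  if (M < 1) abort("need at least one prediction model.")
  for (m in models) {
    bad <- symdiff_snps(m$snp_ids, gwas$snp_ids)
    if (length(bad))
      abort(paste0("SNP set mismatch between model '", m$ancestry_label,
                   "' and GWAS; offending SNPs: ",
                   paste(head(bad, 5), collapse = ", "),
                   if (length(bad) > 5) ", ..."))
  }
  pre <- metro_precompute(models, gwas, grid_step, max_grid_points, ld_shrink)
  prof <- metro_profile(pre, gwas$z)
  # ties on the grid break toward equal weights, then toward more weight on
  # the lower ancestry index
  cand <- which(prof$lrt >= max(prof$lrt) - 1e-10)
  d_eq <- rowSums((pre$W[cand, , drop = FALSE] - 1 / M)^2)
  cand <- cand[d_eq <= min(d_eq) + 1e-12]
  best <- cand[order(-pre$W[cand, 1])[1]]
  lrt <- max(prof$lrt[best], 0)
  if (is.null(null)) {
    null <- calibrate_null(models, gwas, B = null_reps, grid_step = grid_step,
                           max_grid_points = max_grid_points,
                           ld_shrink = ld_shrink, seed = seed)
  }
  w_hat <- pre$W[best, ]
  structure(
    list(
      gene_id = gene_id,
      alpha_hat = prof$alpha[best],
      weights_hat = setNames(w_hat, pre$labels),
      loglik_alt = prof$ll_alt[best],
      loglik_null = prof$ll_null[best],
      lrt_stat = lrt,
      p_value = null_pvalue(null, lrt),
      p_naive = pchisq(lrt, df = 1, lower.tail = FALSE),
      dominant_ancestry = pre$labels[which.max(w_hat)],
      grid = dplyr::bind_cols(tibble::as_tibble(pre$W),
                              tibble::tibble(lrt = prof$lrt,
                                             alpha = prof$alpha)),
      n_gwas = gwas$n_gwas
    ),
    class = "metro_fit"
  )
}

symdiff_snps <- function(a, b) union(setdiff(a, b), setdiff(b, a))

# Simplex grid: full enumeration at `step` for M <= 2, a lattice net with at
# most `max_points` points for larger M. Rows sum to 1.
simplex_grid <- function(M, step = 0.01, max_points = 5000) {
  if (M == 1) {
    W <- matrix(1, 1, 1)
  } else if (M == 2) {
    w1 <- seq(0, 1, by = step)
    W <- cbind(w1, 1 - w1, deparse.level = 0)
  } else {
    r <- 1L
    while (choose(r + M, M - 1) <= max_points) r <- r + 1L
    combos <- utils::combn(r + M - 1L, M - 1L)
    W <- t(apply(combos, 2, function(cut)
      diff(c(0L, cut, r + M)) - 1L)) / r
  }
  colnames(W) <- paste0("w_", seq_len(M))
  W
}

# Shared precomputation for the grid profile: per grid point the composite
# weights, q = b'Rb, the uncertainty traces and the projection vectors.
metro_precompute <- function(models, gwas, grid_step, max_grid_points,
                             ld_shrink) {
  M <- length(models)
  p <- length(gwas$z)
  Bm <- vapply(models, function(m)
    unname(m$beta_hat[match(gwas$snp_ids, m$snp_ids)]), numeric(p))
  Bm <- matrix(Bm, nrow = p)
  Rs <- shrink_ld(gwas$ld, ld_shrink)
  # tr(V_m R) and R V_m R per ancestry (diagonal or dense beta_cov)
  trVR <- numeric(M)
  RVR <- vector("list", M)
  for (m in seq_len(M)) {
    ord <- match(gwas$snp_ids, models[[m]]$snp_ids)
    V <- models[[m]]$beta_cov
    if (is.null(dim(V))) V <- diag(V, p)
    V <- V[ord, ord, drop = FALSE]
    trVR[m] <- sum(diag(V %*% Rs))
    RVR[[m]] <- Rs %*% V %*% Rs
  }
  W <- simplex_grid(M, grid_step, max_grid_points)
  G <- nrow(W)
  b_grid <- Bm %*% t(W)                    # p x G composite weights
  Rb <- Rs %*% b_grid
  q <- colSums(b_grid * Rb)
  trV <- drop((W^2) %*% trVR)
  s <- vapply(seq_len(G), function(g) {
    rb <- Rb[, g]
    sum(vapply(seq_len(M), function(m)
      W[g, m]^2 * drop(crossprod(rb, RVR[[m]] %*% rb)), numeric(1)))
  }, numeric(1))
  if (all(q + trV <= 0)) abort("all composite weight vectors are zero; no predictive model supplied.")
  list(W = W, b_grid = b_grid, q = q, trV = trV, s = s,
       n = gwas$n_gwas, labels = vapply(models, `[[`, "", "ancestry_label"),
       Rs = Rs)
}

# Profile alpha at every grid point for one z vector; returns per-point
# profile log-likelihoods and LRT against alpha = 0.
metro_profile <- function(pre, z) {
  G <- nrow(pre$W)
  Tw <- drop(crossprod(pre$b_grid, z))
  n <- pre$n
  alpha <- ll_alt <- ll_null <- lrt <- numeric(G)
  for (g in seq_len(G)) {
    q <- pre$q[g]; trV <- pre$trV[g]; s <- pre$s[g]; Tg <- Tw[g]
    v0 <- q + trV
    if (v0 <= 0) { lrt[g] <- -Inf; next }
    qc <- max(q - trV, 1e-8)
    negll <- function(a) {
      v <- v0 + n * a^2 * s / qc
      0.5 * log(v) + (Tg - sqrt(n) * a * sqrt(qc))^2 / (2 * v)
    }
    a0 <- Tg / (sqrt(n) * sqrt(qc))
    opt <- optimize(negll, interval = c(-abs(a0) - 1, abs(a0) + 1),
                    tol = 1e-7)
    alpha[g] <- opt$minimum
    ll_alt[g] <- -opt$objective - 0.5 * log(2 * pi)
    ll_null[g] <- -negll(0) - 0.5 * log(2 * pi)
    lrt[g] <- 2 * (ll_alt[g] - ll_null[g])
  }
  list(alpha = alpha, ll_alt = ll_alt, ll_null = ll_null, lrt = lrt)
}

#' Parametric empirical-null calibration for the grid-max LRT
#'
#' Under `alpha = 0` the contribution weights are unidentified, so the
#' grid-maximized LRT is stochastically larger than a 1-df chi-squared.
#' This draws `B` null z-score vectors from MVN(0, R) (R shrinkage
#' regularized), recomputes the grid-max LRT on each, and moment-matches a
#' scaled chi-squared (`scale = var/(2 mean)`, `df = 2 mean^2/var`) used to
#' convert observed LRT statistics to calibrated p-values. The object is
#' reusable across genes sharing the same SNP dimension and grid.
#'
#' @inheritParams metro_test
#' @param B Number of null replicates (>= 200 recommended; smaller values
#'   trigger a warning because tail p-values become unreliable).
#' @param seed RNG seed for the null draws.
#' @return A `metro_null` object with `scale`, `df`, the sorted null LRT
#'   draws, and `B`.
#' @export
calibrate_null <- function(models, gwas, B = 500,
                           grid_step = 0.01, max_grid_points = 5000,
                           ld_shrink = 0.1, seed = 1L) {
  if (inherits(models, "prediction_model")) models <- list(models)
  if (B < 200)
    warn("B < 200 null replicates: calibrated p-values will have poor resolution.")
  pre <- metro_precompute(models, gwas, grid_step, max_grid_points, ld_shrink)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  U <- chol(pre$Rs)
  Z0 <- rmvn_chol(B, U)
  lrt0 <- vapply(seq_len(B), function(b) {
    pr <- metro_profile(pre, Z0[b, ])
    max(pr$lrt, 0)
  }, numeric(1))
  mm <- moment_match_scaled_chisq(lrt0)
  structure(
    list(scale = mm$scale, df = mm$df,
         lrt_null = sort(lrt0), B = B, p = length(gwas$z),
         grid_points = nrow(pre$W)),
    class = "metro_null"
  )
}

# Scaled chi-squared a * chisq(d) matched to the first two moments:
# a = var/(2 mean), d = 2 mean^2 / var.
moment_match_scaled_chisq <- function(draws) {
  m <- mean(draws); v <- var(draws)
  list(scale = v / (2 * m), df = 2 * m^2 / v)
}

null_pvalue <- function(null, lrt) {
  stopifnot(inherits(null, "metro_null"))
  p <- pchisq(lrt / null$scale, df = null$df, lower.tail = FALSE)
  max(p, .Machine$double.xmin)
}

#' @export
print.metro_null <- function(x, ...) {
  cat("<metro_null> B = ", x$B, ", scaled chi^2: scale = ",
      signif(x$scale, 4), ", df = ", signif(x$df, 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.metro_fit <- function(x, ...) {
  cat("<metro_fit> ", x$gene_id, ": alpha = ", signif(x$alpha_hat, 3),
      ", w = (", paste(signif(x$weights_hat, 3), collapse = ", "),
      "), p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname metro_test
#' @param x A `metro_fit`.
#' @param ... Unused.
#' @method tidy metro_fit
#' @export
tidy.metro_fit <- function(x, ...) {
  w <- tibble::as_tibble(as.list(setNames(
    x$weights_hat, paste0("w_", seq_along(x$weights_hat)))))
  dplyr::bind_cols(
    tibble::tibble(gene = x$gene_id, alpha = x$alpha_hat),
    w,
    tibble::tibble(lrt = x$lrt_stat, p = x$p_value, p_naive = x$p_naive,
                   dominant_ancestry = x$dominant_ancestry)
  )
}

#' @rdname metro_test
#' @method glance metro_fit
#' @export
glance.metro_fit <- function(x, ...) {
  tibble::tibble(
    gene = x$gene_id, alpha = x$alpha_hat, lrt = x$lrt_stat,
    loglik_alt = x$loglik_alt, loglik_null = x$loglik_null,
    p = x$p_value, n_gwas = x$n_gwas
  )
}

#' Collect METRO fits into a results table
#'
#' @param fits List of `metro_fit` objects (or a single fit).
#' @return A tibble with one row per gene (columns `gene`, `alpha`,
#'   `w_1..w_M`, `lrt`, `p`, `p_naive`, `dominant_ancestry`), carrying
#'   attributes `n_genes_tested` and `bonferroni_alpha = 0.05 /
#'   n_genes_tested`.
#' @export
twas_table <- function(fits) {
  if (inherits(fits, "metro_fit")) fits <- list(fits)
  tab <- dplyr::bind_rows(lapply(fits, tidy))
  attr(tab, "n_genes_tested") <- nrow(tab)
  attr(tab, "bonferroni_alpha") <- 0.05 / nrow(tab)
  tab
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549364`, the ratio of the median
#' association chi-squared to its null median: 1 for calibrated p-values,
#' above 1 under inflation.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return The inflation factor lambda (positive scalar).
#' @examples
#' genomic_inflation(runif(1e4))
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) == 0) abort("`p_values` is empty.")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    abort("all p-values must lie in (0, 1].")
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Bonferroni threshold and significant subset
#'
#' The family-wise threshold is `family_alpha / n_genes_tested`; genes with
#' `p` strictly below it are returned. With the study-scale 17,238 tested
#' genes this is 0.05 / 17,238 = 2.90e-6.
#'
#' @param table A [twas_table()] (or any data frame with a `p` column).
#' @param family_alpha Family-wise error target (default 0.05).
#' @param n_genes_tested Number of tests; defaults to the table's
#'   `n_genes_tested` attribute or its row count.
#' @return A list with `threshold` and `significant` (tibble subset).
#' @examples
#' bonferroni_threshold(17238)
#' @export
bonferroni_filter <- function(table, family_alpha = 0.05,
                              n_genes_tested = NULL) {
  n <- n_genes_tested %||% attr(table, "n_genes_tested") %||% nrow(table)
  if (n < 1) abort("need at least one tested gene.")
  thr <- bonferroni_threshold(n, family_alpha)
  inform(paste0("Bonferroni threshold: ", signif(thr, 3), " (", family_alpha,
                " / ", n, ")"))
  list(threshold = thr,
       significant = dplyr::filter(tibble::as_tibble(table), .data$p < thr))
}

#' @rdname bonferroni_filter
#' @param n_genes Number of tested genes.
#' @export
bonferroni_threshold <- function(n_genes, family_alpha = 0.05) {
  if (!is_count(n_genes) || n_genes < 1)
    abort("`n_genes` must be a positive integer.")
  family_alpha / n_genes
}

#' Ancestry contribution-weight summary over significant genes
#'
#' For a two-ancestry analysis, the proportion of genes whose estimated
#' contribution weight is larger for each ancestry (exact ties contribute
#' half to each side) with the binomial standard error
#' `sqrt(p_hat (1 - p_hat) / n)`. For more than two ancestries the argmax
#' shares are reported.
#'
#' @param table A [twas_table()] restricted to the genes of interest
#'   (typically the Bonferroni-significant subset).
#' @return A tibble with one row per ancestry: `ancestry`, `proportion`,
#'   `se`, `n_genes`.
#' @export
contribution_summary <- function(table) {
  tab <- tibble::as_tibble(table)
  wcols <- grep("^w_[0-9]+$", names(tab), value = TRUE)
  if (nrow(tab) == 0) abort("no genes supplied.")
  if (length(wcols) < 2)
    abort("need at least two contribution-weight columns (w_1, w_2, ...).")
  W <- as.matrix(tab[wcols])
  n <- nrow(W)
  if (length(wcols) == 2) {
    d <- W[, 2] - W[, 1]
    p2 <- (sum(d > 0) + 0.5 * sum(d == 0)) / n
    prop <- c(1 - p2, p2)
  } else {
    mx <- apply(W, 1, max)
    shares <- sapply(seq_along(wcols), function(m) {
      ties <- rowSums(W == mx)
      sum((W[, m] == mx) / ties)
    })
    prop <- shares / n
  }
  tibble::tibble(
    ancestry = wcols,
    proportion = prop,
    se = sqrt(prop * (1 - prop) / n),
    n_genes = n
  )
}

#' Harmonize GWAS summary alleles against a reference orientation
#'
#' Matches each GWAS SNP to the reference by its (A1, A2) pair: exact matches
#' pass through, swapped pairs have the z sign negated, strand-ambiguous
#' (A/T, C/G) SNPs and unmatched pairs are dropped with a logged count.
#'
#' @param gwas A [gwas_summary()].
#' @param ref Tibble with columns `snp`, `A1`, `A2` giving the reference
#'   effect/other alleles.
#' @return A harmonized [gwas_summary()] restricted to retained SNPs.
#' @export
harmonize_alleles <- function(gwas, ref) {
  stopifnot(inherits(gwas, "gwas_summary"))
  idx <- match(gwas$snp_ids, ref$snp)
  A1 <- toupper(gwas$alleles$A1); A2 <- toupper(gwas$alleles$A2)
  r1 <- toupper(ref$A1[idx]); r2 <- toupper(ref$A2[idx])
  ambiguous <- paste0(A1, A2) %in% c("AT", "TA", "CG", "GC")
  same <- !is.na(idx) & A1 == r1 & A2 == r2
  swapped <- !is.na(idx) & A1 == r2 & A2 == r1
  keep <- (same | swapped) & !ambiguous
  n_drop <- sum(!keep)
  if (n_drop > 0)
    inform(paste0("harmonize_alleles: dropped ", n_drop, " SNP(s) (",
                  sum(ambiguous), " strand-ambiguous, ",
                  sum(!same & !swapped), " unmatched)."))
  if (!any(keep)) abort("no SNPs left after allele harmonization.")
  z <- ifelse(swapped, -gwas$z, gwas$z)[keep]
  gwas_summary(gwas$snp_ids[keep], z, gwas$ld[keep, keep, drop = FALSE],
               gwas$n_gwas, alleles = gwas$alleles[keep, ],
               chr = gwas$chr[keep], bp = gwas$bp[keep])
}
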
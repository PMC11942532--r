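#' Signed gene-level Z score from a two-sided p-value
#'
#' `z = sign * qnorm(1 - p/2)`, evaluated on the log scale so extreme
#' p-values (below ~1e-300) keep full precision instead of underflowing.
#'
#' @param p Two-sided p-value(s) in (0, 1].
#' @param sign Sign(s) of the underlying effect estimate (+1/-1); recycled.
#' @return Signed z-score(s).
#' @examples
#' z_from_p(5.44e-12, -1)
#' @export
z_from_p <- function(p, sign = 1) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    abort("p-values must lie in (0, 1].")
  s <- base::sign(sign)
  if (any(s == 0)) abort("`sign` must be nonzero.")
  s * qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
}

#' Assign genes to non-overlapping LD blocks
#'
#' Each gene is placed in the unique block whose half-open interval
#' `[start, end)` contains its anchor position (transcription start);
#' genes outside every block get their own singleton block with a warning.
#'
#' @param genes Data frame with columns `gene_id`, `chr`, `tss`.
#' @param blocks Data frame of LD blocks with columns `chr`, `start`, `end`
#'   (0-based half-open, e.g. read from BED); must be non-overlapping.
#' @return The `genes` tibble with a `block_id` column appended.
#' @export
assign_blocks <- function(genes, blocks) {
  genes <- tibble::as_tibble(genes)
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("gene_id", "chr", "tss") %in% names(genes)),
            all(c("chr", "start", "end") %in% names(blocks)))
  blocks <- dplyr::arrange(blocks, .data$chr, .data$start)
  ov <- blocks |>
    dplyr::group_by(.data$chr) |>
    dplyr::mutate(overlaps = .data$start <
                    cummax(dplyr::lag(.data$end, default = -Inf))) |>
    dplyr::ungroup()
  if (any(ov$overlaps)) abort("LD blocks overlap; blocks must be disjoint.")
  if (!"block_id" %in% names(blocks))
    blocks$block_id <- sprintf("block_%03d", seq_len(nrow(blocks)))
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    j <- which(blocks$chr == genes$chr[i] &
               blocks$start <= genes$tss[i] & genes$tss[i] < blocks$end)
    if (length(j) == 1) blocks$block_id[j] else NA_character_
  }, character(1))
  n_out <- sum(is.na(hit))
  if (n_out > 0) {
    warn(paste0(n_out, " gene(s) fall outside all LD blocks; assigned to singleton blocks."))
    hit[is.na(hit)] <- paste0("singleton_", genes$gene_id[is.na(hit)])
  }
  dplyr::mutate(genes, block_id = hit)
}

#' Gene-gene correlation of genetically regulated expression
#'
#' For composite per-gene SNP weight vectors `b_i` on a shared SNP frame and
#' LD matrix `R`, the GReX correlation is
#' `Sigma_ij = b_i' R b_j / sqrt(b_i' R b_i * b_j' R b_j)` with an exactly
#' unit diagonal; the result is regularized to positive definiteness by
#' flooring eigenvalues at `eig_floor`.
#'
#' @param weights p x k matrix of per-gene composite weights (columns named
#'   by gene).
#' @param ld p x p LD matrix.
#' @param eig_floor Eigenvalue floor (default 1e-6).
#' @return k x k correlation matrix.
#' @export
gene_correlation <- function(weights, ld, eig_floor = 1e-6) {
  weights <- as.matrix(weights)
  if (nrow(weights) != nrow(ld))
    abort("`weights` rows must match the LD dimension.")
  Q <- crossprod(weights, ld %*% weights)
  d <- diag(Q)
  zero <- d <= 0
  if (any(zero))
    abort(paste0("zero-norm weight vector for gene(s): ",
                 paste(colnames(weights)[zero], collapse = ", ")))
  S <- Q / sqrt(outer(d, d))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values < eig_floor)) {
    S <- e$vectors %*% diag(pmax(e$values, eig_floor),
                            nrow(S)) %*% t(e$vectors)
    S <- stats::cov2cor(S)
  }
  diag(S) <- 1
  dimnames(S) <- list(colnames(weights), colnames(weights))
  S
}

#' Bayesian gene fine-mapping within an LD block
#'
#' Enumerates every causal configuration of up to `max_causal` genes plus
#' the null (no causal gene) configuration. A configuration `c` is scored by
#' the multivariate-normal marginal likelihood of the gene z-scores with
#' covariance `Sigma + prior_var * Sigma[, c] Sigma[c, ]` (gene effects
#' integrated out under a `N(0, prior_var)` prior) times the prior
#' `prior_causal^|c| (1 - prior_causal)^(k - |c|)`. Per-gene posterior
#' inclusion probabilities sum the posterior over configurations containing
#' the gene; the null configuration's posterior is reported alongside.
#'
#' @param zs Tibble (or data frame) with columns `gene_id` and `z` for the
#'   genes of one block.
#' @param sigma k x k GReX correlation matrix from [gene_correlation()].
#' @param prior_causal Prior probability each gene is causal; default `1/k`.
#' @param prior_var Prior variance of a causal gene's (non-centrality-scale)
#'   effect; default 40.
#' @param max_causal Largest configuration size enumerated; default 3.
#' @param credible_level Credibility level for the reported set; default 0.90.
#' @return A `finemap_result`: tibble `genes` (`gene_id`, `z`, `pip`,
#'   `in_credible_set`), `null_posterior`, `credible_set` (ordered ids,
#'   possibly including `"<null>"`), `credible_level`, and the full
#'   configuration posterior table.
#' @examples
#' zs <- tibble::tibble(gene_id = c("a", "b"), z = c(6, 1))
#' focus_pip(zs, diag(2))
#' @export
focus_pip <- function(zs, sigma, prior_causal = NULL, prior_var = 40,
                      max_causal = 3, credible_level = 0.90) {
  zs <- tibble::as_tibble(zs)
  stopifnot(all(c("gene_id", "z") %in% names(zs)))
  k <- nrow(zs)
  if (k < 1) abort("need at least one gene.")
  max_causal <- min(max_causal, k)
  sigma <- as.matrix(sigma)
  if (any(dim(sigma) != k)) abort("`sigma` must be k x k.")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    abort("`sigma` is not positive definite; regularize it first (see gene_correlation()).")
  prior_causal <- prior_causal %||% (1 / max(k, 2))
  if (prior_causal <= 0 || prior_causal >= 1)
    abort("`prior_causal` must lie in (0, 1).")
  z <- zs$z

  configs <- unlist(lapply(0:max_causal, function(s)
    if (s == 0) list(integer(0)) else
      apply(utils::combn(k, s), 2, identity, simplify = FALSE)),
    recursive = FALSE)
  log_score <- vapply(configs, function(cfg) {
    Vc <- sigma
    if (length(cfg))
      Vc <- Vc + prior_var * tcrossprod(sigma[, cfg, drop = FALSE])
    mvn_logdens(z, Vc) +
      length(cfg) * log(prior_causal) +
      (k - length(cfg)) * log(1 - prior_causal)
  }, numeric(1))
  post <- exp(log_score - max(log_score))
  post <- post / sum(post)

  pip <- vapply(seq_len(k), function(i)
    sum(post[vapply(configs, function(cfg) i %in% cfg, logical(1))]),
    numeric(1))
  null_post <- post[[1]]
  config_table <- tibble::tibble(
    config = vapply(configs, function(cfg)
      if (length(cfg)) paste(zs$gene_id[cfg], collapse = "+") else "<null>",
      character(1)),
    size = lengths(configs),
    posterior = post
  )
  res <- structure(
    list(
      genes = dplyr::mutate(zs, pip = pip),
      null_posterior = null_post,
      configs = config_table,
      credible_level = credible_level
    ),
    class = "finemap_result"
  )
  res$credible_set <- credible_set(res, credible_level)
  res$genes$in_credible_set <- res$genes$gene_id %in% res$credible_set
  res
}

# Multivariate normal log density at mean zero.
mvn_logdens <- function(x, V) {
  U <- chol(V)
  q <- backsolve(U, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi)) - sum(log(diag(U))) - 0.5 * sum(q^2)
}

#' Credible set of genes for a fine-mapped block
#'
#' Ranks the genes (and the null-model marker `"<null>"`, whose mass is the
#' null configuration's posterior) by posterior inclusion probability,
#' breaking ties by |z| then gene id, and returns the minimal prefix whose
#' cumulative normalized posterior mass reaches `level`.
#'
#' @param result A `finemap_result` from [focus_pip()].
#' @param level Credibility level in (0, 1]; default 0.90.
#' @return Ordered character vector of gene ids (possibly including
#'   `"<null>"`).
#' @export
credible_set <- function(result, level = 0.90) {
  stopifnot(inherits(result, "finemap_result"))
  if (level <= 0 || level > 1) abort("`level` must lie in (0, 1].")
  items <- tibble::tibble(
    id = c(result$genes$gene_id, "<null>"),
    mass = c(result$genes$pip, result$null_posterior),
    abs_z = c(abs(result$genes$z), 0)
  )
  items <- dplyr::arrange(items, dplyr::desc(.data$mass),
                          dplyr::desc(.data$abs_z), .data$id)
  cum <- cumsum(items$mass / sum(items$mass))
  take <- seq_len(match(TRUE, cum >= level - 1e-12, nomatch = nrow(items)))
  items$id[take]
}

#' @export
print.finemap_result <- function(x, ...) {
  cat("<finemap_result> ", nrow(x$genes), " genes; null posterior = ",
      signif(x$null_posterior, 3), "; ", round(100 * x$credible_level),
      "% credible set: {", paste(x$credible_set, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' @rdname focus_pip
#' @param x A `finemap_result`.
#' @param ... Unused.
#' @method tidy finemap_result
#' @export
tidy.finemap_result <- function(x, ...) {
  tibble::as_tibble(x$genes)
}

#' @rdname focus_pip
#' @method glance finemap_result
#' @export
glance.finemap_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    null_posterior = x$null_posterior,
    credible_level = x$credible_level,
    credible_set_size = length(x$credible_set),
    null_in_set = "<null>" %in% x$credible_set
  )
}

#' Gene-level TWAS z-scores from summary statistics
#'
#' The standard summary-statistic TWAS statistic per gene:
#' `Z_g = b_g' z / sqrt(b_g' R b_g)` with the (shrinkage-regularized) LD
#' matrix `R` and the gene's composite SNP weights `b_g`.
#'
#' @param weights p x k matrix of per-gene composite weights.
#' @param gwas A [gwas_summary()] on the same SNP frame.
#' @param ld_shrink LD shrinkage (default 0.1).
#' @return Tibble with `gene_id` and `z`.
#' @export
twas_zscores <- function(weights, gwas, ld_shrink = 0.1) {
  stopifnot(inherits(gwas, "gwas_summary"))
  weights <- as.matrix(weights)
  Rs <- shrink_ld(gwas$ld, ld_shrink)
  num <- drop(crossprod(weights, gwas$z))
  den <- sqrt(colSums(weights * (Rs %*% weights)))
  if (any(den == 0)) abort("zero-norm weight vector.")
  tibble::tibble(gene_id = colnames(weights) %||%
                   paste0("gene_", seq_along(num)),
                 z = num / den)
}

#' Fine-map one simulated region end to end
#'
#' Convenience wrapper for simulated regions: computes gene-level z-scores
#' from the region's composite weights and GWAS summary, the GReX
#' correlation matrix, and the configuration posterior.
#'
#' @param region A list with `scenario` and `gwas` as returned by
#'   [simulate_region()].
#' @param weights Optional p x k weight matrix; defaults to the scenario's
#'   true weights (oracle fine-mapping on simulated data).
#' @inheritParams focus_pip
#' @param ld_shrink LD shrinkage used for z-scores and GReX correlation.
#' @return A `finemap_result`.
#' @export
finemap_region <- function(region, weights = NULL, prior_causal = NULL,
                           prior_var = 40, max_causal = 3,
                           credible_level = 0.90, ld_shrink = 0.1) {
  weights <- weights %||% region$scenario$true_weights
  zs <- twas_zscores(weights, region$gwas, ld_shrink)
  Rs <- shrink_ld(region$gwas$ld, ld_shrink)
  sigma <- gene_correlation(weights, Rs)
  focus_pip(zs, sigma, prior_causal = prior_causal, prior_var = prior_var,
            max_causal = max_causal, credible_level = credible_level)
}
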
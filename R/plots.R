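#' Manhattan plot of gene-level TWAS results
#'
#' One point per gene at its genomic position, height `-log10(p)`, with a
#' horizontal line at the Bonferroni family-wise threshold
#' (`family_alpha / n genes tested`). Genes lacking coordinates are dropped
#' with a logged count. The figure renders (with the threshold line) even
#' when no gene is significant.
#'
#' @param results Data frame with columns `gene`, `p`, `chr`, `bp`.
#' @param family_alpha Family-wise error target for the threshold line.
#' @param n_genes_tested Number of tests behind the threshold; defaults to
#'   the table's `n_genes_tested` attribute or its row count.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, family_alpha = 0.05,
                           n_genes_tested = NULL) {
  res <- tibble::as_tibble(results)
  stopifnot(all(c("gene", "p") %in% names(res)))
  if (!all(c("chr", "bp") %in% names(res)))
    abort("`results` needs `chr` and `bp` coordinates.")
  n <- n_genes_tested %||% attr(results, "n_genes_tested") %||% nrow(res)
  thr <- bonferroni_threshold(n, family_alpha)
  miss <- !is.finite(res$bp) | is.na(res$chr)
  if (any(miss)) {
    inform(paste0("plot_manhattan: dropped ", sum(miss),
                  " gene(s) without coordinates."))
    res <- res[!miss, ]
  }
  res <- dplyr::arrange(res, .data$chr, .data$bp)
  res$pos <- seq_len(nrow(res))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                    colour = factor(.data$chr %% 2))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr), colour = "red") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "gene (genomic order)",
                  y = expression(-log[10](italic(p))),
                  title = "TWAS Manhattan plot",
                  subtitle = paste0("Bonferroni threshold ", signif(thr, 3),
                                    " (", family_alpha, "/", n, ")")) +
    ggplot2::theme_minimal()
}

#' QQ plot of TWAS p-values with genomic-inflation annotation
#'
#' Observed versus expected `-log10(p)` under the uniform null, annotated
#' with the genomic inflation factor lambda (see [genomic_inflation()]).
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return A ggplot object.
#' @export
plot_qq <- function(p_values) {
  lambda <- genomic_inflation(p_values)
  n <- length(p_values)
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(n)),
    observed = -log10(sort(p_values))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("text", x = 0.1 * max(df$expected),
                      y = 0.95 * max(df$observed, 1),
                      hjust = 0,
                      label = sprintf("lambda == %.2f", lambda),
                      parse = TRUE) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(p))),
                  y = expression(Observed ~ -log[10](italic(p))),
                  title = "TWAS QQ plot") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_manhattan `autoplot` method for a fine-mapped block:
#'   per-gene posterior inclusion probabilities with the credible set
#'   highlighted.
#' @param object A `finemap_result`.
#' @param ... Unused.
#' @method autoplot finemap_result
#' @export
autoplot.finemap_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene_id,
                                                      -.data$pip),
                                   y = .data$pip,
                                   fill = .data$in_credible_set)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$null_posterior,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "in credible set") +
    ggplot2::labs(x = NULL, y = "posterior inclusion probability",
                  subtitle = paste0("null-model posterior: ",
                                    signif(object$null_posterior, 3))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_manhattan `autoplot` method for a single METRO fit: the
#'   profile LRT over the contribution-weight grid.
#' @method autoplot metro_fit
#' @export
autoplot.metro_fit <- function(object, ...) {
  df <- object$grid
  ggplot2::ggplot(df, ggplot2::aes(.data$w_1, .data$lrt)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$weights_hat[1],
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "contribution weight of ancestry 1",
                  y = "profile LRT",
                  title = object$gene_id,
                  subtitle = paste0("alpha = ", signif(object$alpha_hat, 3),
                                    ", p = ", signif(object$p_value, 3))) +
    ggplot2::theme_minimal()
}
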
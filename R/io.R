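#' Readers and writers for the pipeline's plain-text formats
#'
#' Tab-delimited interchange formats: genotype dosages (sample x SNP),
#' expression (gene x sample), GWAS summary statistics with header
#' `SNP CHR BP A1 A2 Z N`, LD blocks as 0-based half-open BED, prediction
#' models as JSON records, and GMT gene-set files.
#'
#' @name twas-io
NULL

#' @rdname twas-io
#' @param panel An `ancestry_panel`.
#' @param path Output file path.
#' @export
write_dosage_tsv <- function(panel, path) {
  df <- tibble::as_tibble(panel$genotypes)
  df <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("%s_%05d", panel$ancestry_label,
                                       seq_len(nrow(df)))), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname twas-io
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  G <- as.matrix(df[-1])
  rownames(G) <- df[[1]]
  G
}

#' @rdname twas-io
#' @param expression Named list or single-gene numeric vector; written as a
#'   gene x sample table.
#' @param sample_ids Sample identifiers (columns).
#' @export
write_expression_tsv <- function(expression, sample_ids, path) {
  if (!is.list(expression)) expression <- list(gene = expression)
  mat <- do.call(rbind, expression)
  df <- dplyr::bind_cols(tibble::tibble(gene_id = names(expression)),
                         tibble::as_tibble(matrix(mat, nrow = length(expression),
                                                  dimnames = list(NULL, sample_ids))))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname twas-io
#' @param gwas A [gwas_summary()].
#' @export
write_gwas_tsv <- function(gwas, path) {
  readr::write_tsv(tibble::tibble(
    SNP = gwas$snp_ids, CHR = gwas$chr, BP = gwas$bp,
    A1 = gwas$alleles$A1, A2 = gwas$alleles$A2,
    Z = gwas$z, N = gwas$n_gwas
  ), path)
  invisible(path)
}

#' @rdname twas-io
#' @param ld Optional p x p LD matrix to attach (the TSV itself carries only
#'   the marginal statistics).
#' @export
read_gwas_tsv <- function(path, ld = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "Z", "N")
  if (!all(need %in% names(df)))
    abort(paste0("GWAS TSV must have columns: ", paste(need, collapse = " ")))
  if (is.null(ld)) ld <- diag(nrow(df))
  dimnames(ld) <- list(df$SNP, df$SNP)
  gwas_summary(df$SNP, df$Z, ld, df$N[1],
               alleles = tibble::tibble(A1 = df$A1, A2 = df$A2),
               chr = df$CHR, bp = df$BP)
}

#' @rdname twas-io
#' @param blocks Data frame with `chr`, `start`, `end` (0-based half-open)
#'   and optional `block_id`.
#' @export
write_blocks_bed <- function(blocks, path) {
  df <- tibble::as_tibble(blocks)
  out <- tibble::tibble(
    chrom = df$chr, chromStart = df$start, chromEnd = df$end,
    name = if ("block_id" %in% names(df)) df$block_id
           else sprintf("block_%03d", seq_len(nrow(df)))
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname twas-io
#' @export
read_blocks_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  out <- tibble::tibble(chr = df[[1]], start = df[[2]], end = df[[3]])
  if (ncol(df) >= 4) out$block_id <- df[[4]]
  out
}

#' @rdname twas-io
#' @param model A `prediction_model`.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(
      ancestry_label = model$ancestry_label,
      method = model$method,
      n_train = model$n_train,
      cv_r2 = model$cv_r2,
      predictive = model$predictive,
      snp_ids = model$snp_ids,
      beta_hat = unname(model$beta_hat),
      beta_cov_diag = unname(pmax(diag(model$beta_cov), 0))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname twas-io
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(x$beta_hat)
  structure(
    list(
      ancestry_label = x$ancestry_label,
      beta_hat = setNames(x$beta_hat, x$snp_ids),
      beta_cov = diag(x$beta_cov_diag, p),
      cv_r2 = x$cv_r2,
      n_train = x$n_train,
      method = x$method,
      predictive = x$predictive,
      snp_ids = x$snp_ids
    ),
    class = "prediction_model"
  )
}

#' @rdname twas-io
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}
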
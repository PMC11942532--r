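#' Canonicalize gene symbols through a synonym table
#'
#' Replaces each symbol by its canonical form under a user-supplied
#' many-to-one alias table, following chains (alias of an alias) to their
#' terminal symbol and erroring on cycles. Unmapped symbols pass through
#' unchanged; duplicates created by the mapping are collapsed with a logged
#' count.
#'
#' @param genes Character vector of gene symbols.
#' @param alias_table Data frame with columns `alias` and `canonical`
#'   (may be empty or `NULL` for the identity mapping).
#' @return Character vector of unique canonical symbols (input order of
#'   first appearance preserved).
#' @examples
#' canonicalize(c("C6orf10", "APOE"),
#'              data.frame(alias = "C6orf10", canonical = "TSBP1"))
#' @export
canonicalize <- function(genes, alias_table = NULL) {
  if (is.null(alias_table) || nrow(alias_table) == 0) return(unique(genes))
  stopifnot(all(c("alias", "canonical") %in% names(alias_table)))
  map <- setNames(as.character(alias_table$canonical),
                  as.character(alias_table$alias))
  resolve <- function(g) {
    seen <- character(0)
    while (g %in% names(map)) {
      if (g %in% seen)
        abort(paste0("alias cycle detected involving '", g, "'."))
      seen <- c(seen, g)
      g <- map[[g]]
    }
    g
  }
  out <- vapply(genes, resolve, character(1), USE.NAMES = FALSE)
  n_dup <- length(out) - length(unique(out))
  if (n_dup > 0)
    inform(paste0("canonicalize: collapsed ", n_dup,
                  " duplicate symbol(s) after mapping."))
  unique(out)
}

#' Venn region counts for 2-4 gene lists
#'
#' Exact counts for every intersection region of the Venn diagram: each
#' element of the union is assigned to the region keyed by its membership
#' pattern, so the region counts always sum to the union size.
#'
#' @param sets Named list of 2-4 character vectors.
#' @param alias_table Optional synonym table applied to every list first
#'   (see [canonicalize()]).
#' @param allow_many Allow more than 4 lists (counts are still exact; 4 is
#'   the usual rendering limit).
#' @return Tibble with one row per non-empty membership pattern: logical
#'   membership columns (one per list), `region` label, and `count`.
#' @examples
#' overlap_counts(list(A = c("x", "y"), B = c("y", "z")))
#' @export
overlap_counts <- function(sets, alias_table = NULL, allow_many = FALSE) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    abort("`sets` must be a named list.")
  if (length(sets) < 2) abort("need at least two lists.")
  if (length(sets) > 4 && !allow_many)
    abort("more than 4 lists cannot be rendered as a Venn diagram; set `allow_many = TRUE` for counts only.")
  sets <- lapply(sets, canonicalize, alias_table = alias_table)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  memb <- matrix(memb, ncol = length(sets),
                 dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  key <- apply(memb, 1, paste, collapse = "|")
  pkey <- apply(patterns, 1, paste, collapse = "|")
  counts <- vapply(pkey, function(k) sum(key == k), numeric(1))
  dplyr::arrange(
    dplyr::mutate(
      tibble::as_tibble(patterns),
      region = apply(patterns, 1, function(r)
        paste(names(sets)[as.logical(r)], collapse = "&")),
      count = as.integer(counts)
    ),
    dplyr::desc(rowSums(dplyr::pick(dplyr::where(is.logical))))
  )
}

#' Hypergeometric gene-set enrichment with BH adjustment
#'
#' Upper-tail hypergeometric test of each gene set against the query within
#' a stated universe, with Benjamini-Hochberg adjustment across sets. This is
#' a self-contained local enrichment procedure (a plain one-sided Fisher
#' test per set); it is not the multi-layered g:SCS correction used by the
#' g:Profiler web service, and adjusted p-values are therefore not
#' comparable to g:SCS output.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all testable genes.
#' @return Tibble with `set`, `set_size`, `overlap`, `p`, `p_adjusted`,
#'   sorted by `p`.
#' @export
enrich_hypergeometric <- function(query, gene_sets, universe) {
  query <- unique(query); universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    abort(paste0("query genes outside the universe: ",
                 paste(head(outside, 5), collapse = ", "),
                 if (length(outside) > 5) ", ..."))
  if (length(gene_sets) == 0) abort("`gene_sets` is empty.")
  if (is.null(names(gene_sets))) abort("`gene_sets` must be named.")
  N <- length(universe); nq <- length(query)
  res <- purrr::map_dfr(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(s, query))
    tibble::tibble(
      set = nm,
      set_size = length(s),
      overlap = ov,
      p = phyper(ov - 1, length(s), N - length(s), nq, lower.tail = FALSE)
    )
  })
  res$p_adjusted <- p.adjust(res$p, method = "BH")
  dplyr::arrange(res, .data$p)
}
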
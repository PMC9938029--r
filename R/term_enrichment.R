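# Gene-set over-representation: hypergeometric test, log10(observed /
# expected) strength, and Benjamini-Hochberg FDR within each category.

#' Hypergeometric over-representation test for one gene set
#'
#' `observed` is the overlap between the query and the term;
#' `expected = |query| * |term| / |background|` is the overlap a random
#' gene set of the query's size would have; `strength =
#' log10(observed / expected)` (undefined, `NA`, when nothing overlaps);
#' `p = P(X >= observed)` under the hypergeometric null. Genes outside
#' the background are ignored.
#'
#' @param query_genes Character vector of query gene symbols.
#' @param term_genes Character vector of the term's gene symbols.
#' @param background_genes Character vector defining the gene universe.
#' @return One-row tibble: `observed`, `expected`, `strength`, `p_value`.
#' @export
term_test <- function(query_genes, term_genes, background_genes) {
  background <- unique(background_genes)
  query <- intersect(unique(query_genes), background)
  term <- intersect(unique(term_genes), background)
  if (length(query) == 0) abort("empty query gene set")
  observed <- length(intersect(query, term))
  expected <- length(query) * length(term) / length(background)
  strength <- if (observed > 0) log10(observed / expected) else NA_real_
  p <- phyper(observed - 1, length(term),
              length(background) - length(term), length(query),
              lower.tail = FALSE)
  tibble(observed = as.integer(observed), expected = expected,
         strength = strength, p_value = p)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) m * p_(j) / j` over the sorted p-values, the
#' standard step-up construction (delegates to
#' [stats::p.adjust()] with `method = "BH"`). When adjusting a term
#' table, apply per category.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) abort("bh_adjust() needs >= 1 p-value")
  p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment report over a GMT collection
#'
#' Tests every term against the query, adjusts p-values with
#' Benjamini-Hochberg *within each category*, and flags terms with
#' `fdr < alpha` as significant. The background defaults to the union of
#' all genes appearing in the collection; pass an explicit background
#' (e.g. all exome genes) to widen the universe.
#'
#' @param query_genes Character vector (e.g. the multi-family gene list).
#' @param gene_sets Collection from [read_gene_sets()] (`term`,
#'   `category`, `genes` list column).
#' @param background_genes Optional explicit gene universe.
#' @param alpha Significance cut-off on the FDR (default 0.05,
#'   exclusive).
#' @return An `fvp_terms` tibble: `category`, `term`, `observed`,
#'   `expected`, `strength`, `p_value`, `fdr`, `significant`, `genes`
#'   (overlap list column), all terms retained.
#' @export
enrichment_report <- function(query_genes, gene_sets,
                              background_genes = NULL, alpha = 0.05) {
  assert_columns(gene_sets, c("term", "category", "genes"), "gene_sets")
  background <- unique(background_genes %||% unlist(gene_sets$genes))
  query <- intersect(unique(query_genes), background)
  if (length(query) == 0) abort("empty query gene set")
  res <- gene_sets |>
    mutate(stats = map(.data$genes, term_test,
                       query_genes = query, background_genes = background),
           overlap = map(.data$genes, intersect, x = query)) |>
    select("category", "term", "stats", "overlap") |>
    tidyr::unnest("stats") |>
    mutate(fdr = bh_adjust(.data$p_value), .by = "category") |>
    mutate(significant = .data$fdr < alpha) |>
    rename(genes = "overlap") |>
    arrange(.data$category, .data$fdr, .data$term)
  class(res) <- c("fvp_terms", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "query_size") <- length(query)
  attr(res, "background_size") <- length(background)
  res
}

#' @exportS3Method generics::glance
glance.fvp_terms <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_significant = sum(x$significant),
         query_size = attr(x, "query_size"),
         background_size = attr(x, "background_size"),
         alpha = attr(x, "alpha"))
}
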
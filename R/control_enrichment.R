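# Case/control allele-count comparison against a population-specific
# control cohort with a one-sided Fisher's exact test.

#' Build per-variant case/control contingency tables
#'
#' For each variant key, `case_alt` is the summed allele dosage over all
#' analyzed affected carriers (het = 1, hom-alt = 2) and
#' `case_total_alleles` is twice the number of analyzed affected
#' individuals. Control counts come from the control frequency table; a
#' variant absent from the table contributes 0 alternate alleles out of
#' the full control allele total.
#'
#' @param variants Variant-level tibble with `variant_key` (one row per
#'   family-variant or per variant; duplicated keys are collapsed).
#' @param calls Call-level tibble covering the analyzed samples.
#' @param cohorts Family cohorts (defines the analyzed affected samples).
#' @param controls Control table (`variant_key`, `control_ac`,
#'   `control_an`).
#' @param n_cases Number of analyzed affected individuals; defaults to
#'   the number of affected samples in `cohorts`.
#' @return Tibble: `variant_key`, `case_alt`, `case_total_alleles`,
#'   `control_alt`, `control_total_alleles`.
#' @export
build_contingency <- function(variants, calls, cohorts, controls,
                              n_cases = NULL) {
  affected <- unlist(cohorts$affected_samples)
  n_cases <- n_cases %||% length(affected)
  keys <- unique(variants$variant_key)
  control_an_full <- max(controls$control_an)
  dosages <- calls |>
    filter(.data$variant_key %in% keys, .data$sample_id %in% affected) |>
    distinct(.data$sample_id, .data$variant_key, .keep_all = TRUE) |>
    summarise(case_alt = sum(gt_dosage(.data$gt), na.rm = TRUE),
              .by = "variant_key")
  tibble(variant_key = keys) |>
    left_join(dosages, by = "variant_key") |>
    left_join(controls, by = "variant_key") |>
    mutate(case_alt = as.integer(tidyr::replace_na(.data$case_alt, 0L)),
           case_total_alleles = 2L * as.integer(n_cases),
           control_alt = as.integer(tidyr::replace_na(.data$control_ac, 0L)),
           control_total_alleles = as.integer(
             tidyr::replace_na(.data$control_an, control_an_full))) |>
    select("variant_key", "case_alt", "case_total_alleles",
           "control_alt", "control_total_alleles")
}

#' One-sided Fisher's exact test for case enrichment
#'
#' Exact hypergeometric upper-tail probability of observing at least
#' `case_alt` alternate alleles in the case margin under the null of
#' equal allele proportions; the alternative is over-representation in
#' cases. Vectorized over tables.
#'
#' @param case_alt,case_total,control_alt,control_total Integer vectors
#'   describing the 2x2 allele-count tables.
#' @return Numeric vector of one-sided p-values in (0, 1].
#' @export
fisher_one_sided <- function(case_alt, case_total, control_alt,
                             control_total) {
  if (any(case_total <= 0 | control_total <= 0)) {
    abort("degenerate contingency table: zero allele total")
  }
  if (any(case_alt > case_total | control_alt > control_total)) {
    abort("alternate allele count exceeds allele total")
  }
  k <- case_alt + control_alt           # white balls: alt alleles overall
  n_tot <- case_total + control_total   # all alleles
  # P(X >= case_alt), X ~ Hypergeom(K = k, N - K, draws = case_total)
  phyper(case_alt - 1, k, n_tot - k, case_total, lower.tail = FALSE)
}

#' Screen shared variants for enrichment over the control cohort
#'
#' Runs [build_contingency()] and [fisher_one_sided()] for every variant
#' and flags those with `p <= alpha` as enriched. All p-values are
#' reported; downstream stages drop the non-enriched variants. No
#' multiple-testing correction is applied at this stage (the raw 0.05
#' cut-off is the published rule; FDR control is used only in the term
#' enrichment module).
#'
#' @inheritParams build_contingency
#' @param alpha Enrichment cut-off on the raw one-sided p (default 0.05,
#'   inclusive).
#' @return An `fvp_enrichment` tibble: the contingency columns plus
#'   `p_value` and `enriched`, one row per distinct variant key.
#' @export
enrichment_screen <- function(variants, calls, cohorts, controls,
                              n_cases = NULL, alpha = 0.05) {
  tab <- build_contingency(variants, calls, cohorts, controls, n_cases)
  tab$p_value <- fisher_one_sided(tab$case_alt, tab$case_total_alleles,
                                  tab$control_alt, tab$control_total_alleles)
  tab$enriched <- tab$p_value <= alpha
  class(tab) <- c("fvp_enrichment", class(tab))
  attr(tab, "alpha") <- alpha
  tab
}

#' @exportS3Method generics::glance
glance.fvp_enrichment <- function(x, ...) {
  tibble(n_variants = nrow(x),
         n_enriched = sum(x$enriched),
         alpha = attr(x, "alpha"))
}
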
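# Deleteriousness classification: six-predictor ensemble voting, the
# dominant-model allele-count ceiling, the strict "most damaging" rule,
# the recurrent-variant rule, and the phenotype-rank threshold.

#' Deleteriousness rule configuration
#'
#' Two classification rules share these thresholds. The strict rule keeps
#' variants below the dominant-model allele-count ceiling that are either
#' loss-of-function, have CADD PHRED strictly above 25, or are called
#' damaging by at least 5 of the 6 predictors. The recurrent-variant rule
#' requires CADD strictly above 20 together with at least 4 damaging
#' votes. "Over" thresholds are strict inequalities throughout.
#'
#' @param strict_cadd_threshold CADD cut-off of the strict rule
#'   (exclusive; default 25).
#' @param table_cadd_threshold CADD cut-off of the recurrent-variant rule
#'   (exclusive; default 20).
#' @param min_votes_strict Damaging votes required by the strict rule
#'   (default 5 of 6).
#' @param min_votes_table Votes required by the recurrent-variant rule
#'   (default 4 of 6).
#' @param max_alt_allele_count Exclusive ceiling on the population
#'   alternate allele count under a dominant model (default 590, the
#'   expected carrier-allele count at a disease incidence of 1 in 3400 in
#'   the reference population; pinned as a constant, see
#'   [expected_allele_ceiling()] for sensitivity analyses).
#' @param phenotype_rank_threshold Exclusive phenotype-rank cut-off
#'   (default 0.75).
#' @param lof_consequences Consequence classes counted as
#'   loss-of-function.
#' @return A validated `fvp_damaging_rules` list.
#' @export
damaging_rules <- function(strict_cadd_threshold = 25,
                           table_cadd_threshold = 20,
                           min_votes_strict = 5L,
                           min_votes_table = 4L,
                           max_alt_allele_count = 590L,
                           phenotype_rank_threshold = 0.75,
                           lof_consequences = famvar::lof_consequences()) {
  stopifnot(min_votes_strict <= 6L, min_votes_table <= 6L,
            strict_cadd_threshold >= 0, table_cadd_threshold >= 0,
            max_alt_allele_count >= 0,
            phenotype_rank_threshold >= 0, phenotype_rank_threshold <= 1)
  structure(list(strict_cadd_threshold = strict_cadd_threshold,
                 table_cadd_threshold = table_cadd_threshold,
                 min_votes_strict = as.integer(min_votes_strict),
                 min_votes_table = as.integer(min_votes_table),
                 max_alt_allele_count = as.integer(max_alt_allele_count),
                 phenotype_rank_threshold = phenotype_rank_threshold,
                 lof_consequences = lof_consequences),
            class = "fvp_damaging_rules")
}

#' Count damaging votes across the six predictors
#'
#' A missing call counts as not damaging (conservative).
#'
#' @param predictor_calls A data frame containing the six predictor
#'   columns (see [predictor_columns()]), or a character vector of six
#'   calls for a single variant.
#' @return Integer vote counts (0-6).
#' @export
predictor_vote <- function(predictor_calls) {
  if (is.character(predictor_calls)) {
    predictor_calls <- as_tibble(as.list(setNames(predictor_calls,
                                                  predictor_columns())))
  }
  assert_columns(predictor_calls, predictor_columns(), "predictor_calls")
  Reduce(`+`, lapply(predictor_columns(), function(col) {
    as.integer(!is.na(predictor_calls[[col]]) &
                 predictor_calls[[col]] == "damaging")
  }))
}

#' Expected population allele count under a dominant model
#'
#' `round(reference_alleles * incidence * inflation)`: the number of
#' carrier alleles expected in the reference population if every carrier
#' of a fully penetrant dominant allele were affected, inflated by an
#' optional factor for incomplete penetrance / allelic heterogeneity.
#' The shipped classification rules pin the ceiling to 590 rather than
#' deriving it at run time; this function supports sensitivity analyses
#' around that constant.
#'
#' @param incidence Disease incidence as a fraction (e.g. 1/3400).
#' @param reference_alleles Allele total of the reference population.
#' @param inflation Multiplicative allowance (default 1).
#' @return Integer expected allele count.
#' @export
expected_allele_ceiling <- function(incidence, reference_alleles,
                                    inflation = 1) {
  stopifnot(incidence >= 0, incidence <= 1, reference_alleles > 0,
            inflation >= 0)
  as.integer(round(reference_alleles * incidence * inflation))
}

#' Classify variants with both deleteriousness rules
#'
#' Adds to the variant table: `vote_count`, `is_lof`,
#' `passes_allele_ceiling` (population alternate allele count strictly
#' below the ceiling; a missing count passes), `strict_damaging`
#' (= ceiling AND (LoF OR CADD > 25 OR votes >= 5)), `table_damaging`
#' (= CADD > 20 AND votes >= 4), and `phenotype_rank_pass`
#' (rank strictly above the threshold; missing rank fails). A missing
#' CADD is treated as 0 and reported via a message.
#'
#' @param variants Variant-level tibble with annotation columns.
#' @param rules A [damaging_rules()] configuration.
#' @return The input with the classification columns appended.
#' @export
classify_variants <- function(variants, rules = damaging_rules()) {
  assert_columns(variants, c("consequence", "cadd_phred",
                             "population_alt_allele_count",
                             "phenotype_rank", predictor_columns()),
                 "variants")
  n_na_cadd <- sum(is.na(variants$cadd_phred))
  if (n_na_cadd > 0) {
    inform(sprintf("treating %d missing CADD score(s) as 0", n_na_cadd))
  }
  cadd <- tidyr::replace_na(variants$cadd_phred, 0)
  ac <- tidyr::replace_na(variants$population_alt_allele_count, 0L)
  votes <- predictor_vote(variants)
  is_lof <- variants$consequence %in% rules$lof_consequences
  ceiling_ok <- ac < rules$max_alt_allele_count
  variants |>
    mutate(
      vote_count = votes,
      is_lof = is_lof,
      passes_allele_ceiling = ceiling_ok,
      strict_damaging = ceiling_ok &
        (is_lof | cadd > rules$strict_cadd_threshold |
           votes >= rules$min_votes_strict),
      table_damaging = cadd > rules$table_cadd_threshold &
        votes >= rules$min_votes_table,
      phenotype_rank_pass = !is.na(.data$phenotype_rank) &
        .data$phenotype_rank > rules$phenotype_rank_threshold
    )
}

#' Strict "most damaging" classification
#'
#' @inheritParams classify_variants
#' @return Logical vector: below the allele-count ceiling AND
#'   (loss-of-function OR CADD > 25 OR >= 5 damaging votes).
#' @export
classify_strict <- function(variants, rules = damaging_rules()) {
  classify_variants(variants, rules)$strict_damaging
}

#' Recurrent-variant deleteriousness classification
#'
#' @inheritParams classify_variants
#' @return Logical vector: CADD > 20 AND >= 4 damaging votes.
#' @export
classify_table1 <- function(variants, rules = damaging_rules()) {
  assert_columns(variants, c("cadd_phred", predictor_columns()), "variants")
  cadd <- tidyr::replace_na(variants$cadd_phred, 0)
  votes <- predictor_vote(variants)
  cadd > rules$table_cadd_threshold & votes >= rules$min_votes_table
}

#' Filter variants on the phenotype-rank score
#'
#' Retains variants whose gene-phenotype proximity rank is strictly above
#' the threshold; variants with a missing rank are excluded and counted
#' in a message.
#'
#' @param variants Variant-level tibble with `phenotype_rank`.
#' @param threshold Exclusive cut-off (default 0.75).
#' @return The surviving rows.
#' @export
phenotype_rank_filter <- function(variants, threshold = 0.75) {
  assert_columns(variants, "phenotype_rank", "variants")
  n_missing <- sum(is.na(variants$phenotype_rank))
  if (n_missing > 0) {
    inform(sprintf("excluding %d variant(s) with missing phenotype rank",
                   n_missing))
  }
  variants[!is.na(variants$phenotype_rank) &
             variants$phenotype_rank > threshold, , drop = FALSE]
}
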
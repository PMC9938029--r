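# The per-family filtering cascade: read-level quality, sharing among all
# affected members, population rarity, consequence/splice rules, and the
# cross-family exclusion of partially shared variants.

#' Filtering thresholds for the family cascade
#'
#' Defaults follow the published cascade: base-call accuracy of at least
#' 99% (Phred Q20) applied to both the site quality and, when present,
#' per-genotype GQ; read-level VAF >= 0.25; depth >= 20x; population
#' MAF <= 0.01; fewer than 5 reported homozygotes (exclusive); and the
#' coding + splicing consequence classes (synonymous and non-coding
#' classes are dropped).
#'
#' @param min_base_quality Phred floor for site quality and GQ (default 20).
#' @param min_vaf_in_reads Minimum alternate-read fraction at carrier
#'   calls (default 0.25, inclusive).
#' @param min_depth Minimum read depth at carrier calls (default 20,
#'   inclusive).
#' @param max_population_maf Maximum population MAF (default 0.01,
#'   inclusive); variants absent from the population database count as
#'   novel (MAF 0) and pass.
#' @param max_population_hom_count Exclusive ceiling on reported
#'   homozygotes (default 5, i.e. "fewer than 5").
#' @param allowed_consequences Consequence classes kept by the cascade.
#' @return A validated `fvp_thresholds` list.
#' @export
filter_thresholds <- function(min_base_quality = 20,
                              min_vaf_in_reads = 0.25,
                              min_depth = 20L,
                              max_population_maf = 0.01,
                              max_population_hom_count = 5L,
                              allowed_consequences = c(
                                "missense", "stop_gain", "frameshift",
                                "splice_canonical", "splice_region",
                                "inframe_indel")) {
  stopifnot(min_base_quality >= 0, min_depth >= 0,
            min_vaf_in_reads >= 0, min_vaf_in_reads <= 1,
            max_population_maf >= 0, max_population_maf <= 1,
            max_population_hom_count >= 0)
  bad <- setdiff(allowed_consequences, consequence_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown consequence(s) in allowed_consequences: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(list(min_base_quality = min_base_quality,
                 min_vaf_in_reads = min_vaf_in_reads,
                 min_depth = as.integer(min_depth),
                 max_population_maf = max_population_maf,
                 max_population_hom_count = as.integer(max_population_hom_count),
                 allowed_consequences = allowed_consequences),
            class = "fvp_thresholds")
}

#' Read-level quality filter
#'
#' A (family, variant) record survives iff in *every* affected member with
#' a non-reference genotype: read depth >= `min_depth`, alternate-read
#' fraction >= `min_vaf_in_reads`, site quality >= `min_base_quality`,
#' and (when a GQ is present) GQ >= `min_base_quality`. Carrier calls
#' lacking depth information are an error naming the record, not a silent
#' pass.
#'
#' @param calls Call-level tibble.
#' @param thresholds A [filter_thresholds()] object.
#' @return The calls of surviving (family, variant) records.
#' @export
quality_filter <- function(calls, thresholds = filter_thresholds()) {
  assert_columns(calls, c("family_id", "variant_key", "gt", "dp", "ad_alt",
                          "site_qual"), "calls")
  carrier <- !is.na(gt_dosage(calls$gt)) & gt_dosage(calls$gt) > 0L
  no_depth <- carrier & (is.na(calls$dp) | is.na(calls$ad_alt))
  if (any(no_depth)) {
    bad <- calls[which(no_depth)[1], ]
    abort(sprintf("carrier call without depth information: %s in %s/%s",
                  bad$variant_key, bad$family_id, bad$sample_id))
  }
  gq_ok <- is.na(calls$gq) | calls$gq >= thresholds$min_base_quality
  call_ok <- !carrier | (
    calls$dp >= thresholds$min_depth &
      calls$ad_alt / calls$dp >= thresholds$min_vaf_in_reads &
      (is.na(calls$site_qual) | calls$site_qual >= thresholds$min_base_quality) &
      gq_ok)
  bad_records <- calls |>
    filter(!call_ok) |>
    distinct(.data$family_id, .data$variant_key) |>
    mutate(.drop = TRUE)
  calls |>
    left_join(bad_records, by = c("family_id", "variant_key")) |>
    filter(is.na(.data$.drop)) |>
    select(-".drop")
}

#' Sharing filter: presence in all affected members of the family
#'
#' Retains (family, variant) records with a non-reference, non-missing
#' genotype in every affected member. A missing genotype counts as not
#' shared.
#'
#' @param calls Call-level tibble.
#' @param cohorts Family cohorts from [family_cohorts()].
#' @return Calls of fully shared records.
#' @export
sharing_filter <- function(calls, cohorts) {
  n_aff <- setNames(cohorts$n_affected, cohorts$family_id)
  affected <- unlist(setNames(cohorts$affected_samples, cohorts$family_id))
  calls <- filter(calls, .data$family_id %in% cohorts$family_id,
                  .data$sample_id %in% affected)
  shared <- calls |>
    summarise(n_carriers = sum(gt_dosage(.data$gt) > 0L, na.rm = TRUE),
              .by = c("family_id", "variant_key")) |>
    filter(.data$n_carriers == n_aff[.data$family_id]) |>
    select("family_id", "variant_key")
  inner_join(calls, shared, by = c("family_id", "variant_key"))
}

#' Population rarity filter
#'
#' Retains variants with population MAF <= `max_population_maf` AND fewer
#' than `max_population_hom_count` reported homozygotes. Variants with no
#' population entry are treated as novel (MAF 0, 0 homozygotes) and pass:
#' absence from the database is stronger evidence of rarity than a
#' borderline MAF.
#'
#' @param variants Variant-level tibble with `population_maf` and
#'   `population_hom_count`.
#' @param thresholds A [filter_thresholds()] object.
#' @return The surviving rows.
#' @export
rarity_filter <- function(variants, thresholds = filter_thresholds()) {
  assert_columns(variants, c("population_maf", "population_hom_count"),
                 "variants")
  maf <- tidyr::replace_na(variants$population_maf, 0)
  hom <- tidyr::replace_na(variants$population_hom_count, 0L)
  variants[maf <= thresholds$max_population_maf &
             hom < thresholds$max_population_hom_count, , drop = FALSE]
}

#' Consequence and splice-region filter
#'
#' Keeps only the allowed (coding + splicing) consequence classes.
#' Canonical GT-AG splice-site variants always pass; splice-region
#' variants outside the canonical dinucleotide pass only when predicted
#' to significantly affect splicing (`splice_damaging`); a splice-region
#' variant with a missing prediction is removed and reported via a
#' message.
#'
#' @param variants Variant-level tibble with `consequence` and
#'   `splice_damaging`.
#' @param thresholds A [filter_thresholds()] object.
#' @return The surviving rows.
#' @export
splice_filter <- function(variants, thresholds = filter_thresholds()) {
  assert_columns(variants, c("consequence", "splice_damaging"), "variants")
  keep_class <- variants$consequence %in% thresholds$allowed_consequences
  region <- variants$consequence == "splice_region"
  flag <- variants$splice_damaging
  missing_flag <- region & is.na(flag)
  if (any(missing_flag)) {
    inform(sprintf(
      "removed %d splice-region variant(s) with no splice prediction",
      sum(missing_flag)))
  }
  keep <- keep_class & (!region | (!is.na(flag) & flag))
  variants[keep, , drop = FALSE]
}

#' Cross-family exclusion of partially shared variants
#'
#' A variant key is removed from every family's shared set when any family
#' in the cohort carries it in at least one but not all of its affected
#' members (a signature of artefacts or incomplete co-segregation).
#' Variants fully shared in several families are retained in each and are
#' the recurrent-variant candidates.
#'
#' @param family_sets Variant-level tibble of shared records
#'   (`family_id`, `variant_key`, ...).
#' @param all_family_calls Raw (pre-sharing) call-level tibble for every
#'   family.
#' @param cohorts Family cohorts from [family_cohorts()].
#' @return `family_sets` without the globally excluded keys.
#' @export
cross_family_exclusion <- function(family_sets, all_family_calls, cohorts) {
  n_aff <- setNames(cohorts$n_affected, cohorts$family_id)
  affected <- unlist(cohorts$affected_samples)
  partial <- all_family_calls |>
    filter(.data$family_id %in% cohorts$family_id,
           .data$sample_id %in% affected) |>
    summarise(n_carriers = sum(gt_dosage(.data$gt) > 0L, na.rm = TRUE),
              .by = c("family_id", "variant_key")) |>
    filter(.data$n_carriers > 0L,
           .data$n_carriers < n_aff[.data$family_id])
  filter(family_sets, !.data$variant_key %in% unique(partial$variant_key))
}

#' Run the full per-family filtering cascade
#'
#' Applies, in order: read-level quality -> sharing among all affected
#' members -> population rarity -> consequence/splice rules ->
#' cross-family exclusion. The first two act on calls; the rest on the
#' variant level after joining annotations. Per-family survivor counts are
#' recorded after every stage.
#'
#' @param calls Raw call-level tibble for all families.
#' @param cohorts Family cohorts from [family_cohorts()].
#' @param annotations Annotation tibble keyed by `variant_key`.
#' @param thresholds A [filter_thresholds()] object.
#' @return An `fvp_cascade` object: list with `variants` (one row per
#'   surviving family-variant, annotations joined), `stage_counts`
#'   (family x stage survivor counts), `thresholds`.
#' @export
run_family_cascade <- function(calls, cohorts, annotations,
                               thresholds = filter_thresholds()) {
  assert_columns(annotations, annotation_cols(), "annotations")
  stage_counts <- list()
  count_stage <- function(df, stage) {
    counts <- df |>
      distinct(.data$family_id, .data$variant_key) |>
      dplyr::count(.data$family_id, name = "n_variants") |>
      tidyr::complete(family_id = cohorts$family_id,
                      fill = list(n_variants = 0L)) |>
      mutate(stage = stage, .before = 1)
    stage_counts[[stage]] <<- counts
    df
  }
  calls <- filter(calls, .data$family_id %in% cohorts$family_id)
  count_stage(calls, "input")
  q <- count_stage(quality_filter(calls, thresholds), "quality")
  s <- count_stage(sharing_filter(q, cohorts), "sharing")

  variants <- s |>
    distinct(.data$family_id, .data$variant_key, .data$chrom, .data$pos,
             .data$ref, .data$alt) |>
    left_join(annotations, by = "variant_key")
  r <- count_stage(rarity_filter(variants, thresholds), "rarity")
  sp <- count_stage(splice_filter(r, thresholds), "consequence_splice")
  final <- count_stage(cross_family_exclusion(sp, calls, cohorts),
                       "cross_family")
  carriers <- s |>
    summarise(n_carriers = sum(gt_dosage(.data$gt) > 0L, na.rm = TRUE),
              .by = c("family_id", "variant_key"))
  final <- left_join(final, carriers, by = c("family_id", "variant_key")) |>
    arrange(.data$family_id, chrom_order(.data$chrom), .data$pos)
  structure(list(
    variants = final,
    stage_counts = bind_rows(stage_counts) |>
      arrange(match(.data$stage, names(stage_counts)), .data$family_id),
    thresholds = thresholds
  ), class = "fvp_cascade")
}

#' @export
print.fvp_cascade <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fvp_cascade> %d shared family-variant records (%d distinct variants, %d genes) across %d families\n",
    g$n_family_variants, g$n_distinct_variants, g$n_genes, g$n_families))
  invisible(x)
}

#' @rdname run_family_cascade
#' @param x An `fvp_cascade` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fvp_cascade <- function(x, ...) x$variants

#' @rdname run_family_cascade
#' @exportS3Method generics::glance
glance.fvp_cascade <- function(x, ...) {
  tibble(
    n_families = dplyr::n_distinct(x$stage_counts$family_id),
    n_family_variants = nrow(x$variants),
    n_distinct_variants = dplyr::n_distinct(x$variants$variant_key),
    n_genes = dplyr::n_distinct(x$variants$gene)
  )
}
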
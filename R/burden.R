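# Cross-family aggregation: gene-level family-overlap counts, recurrent
# identical variants, the gene-length confounder check, and CNV screening.

#' Gene-level burden across families
#'
#' Aggregates the per-family shared-variant table by gene. A family
#' contributes 1 to `n_families` regardless of how many variants it
#' carries in the gene; `n_variants` counts family-variant occurrences
#' (an identical variant shared by two families counts once per family),
#' so one family carrying two variants in a gene yields
#' `n_variants > n_families`.
#'
#' @param family_sets Variant-level tibble with `family_id`,
#'   `variant_key`, `gene`.
#' @return An `fvp_burden` tibble: `gene`, `n_families`, `n_variants`,
#'   `family_ids` and `variant_keys` list columns, sorted by descending
#'   family count.
#' @export
gene_overlap <- function(family_sets) {
  assert_columns(family_sets, c("family_id", "variant_key", "gene"),
                 "family_sets")
  out <- family_sets |>
    distinct(.data$gene, .data$family_id, .data$variant_key) |>
    summarise(
      n_families = dplyr::n_distinct(.data$family_id),
      n_variants = dplyr::n(),
      family_ids = list(sort(unique(.data$family_id))),
      variant_keys = list(sort(unique(.data$variant_key))),
      .by = "gene") |>
    arrange(dplyr::desc(.data$n_families), .data$gene)
  class(out) <- c("fvp_burden", class(out))
  out
}

#' Histogram of genes by family-overlap level
#'
#' Counts, for every overlap level of at least two families, the number
#' of genes hit in exactly that many families; the total is the
#' multi-family gene count.
#'
#' @param burden An [gene_overlap()] table.
#' @return An `fvp_overlap_histogram` tibble (`n_families`, `n_genes`,
#'   descending) with a `total_multi_family_genes` attribute; see
#'   [glance.fvp_overlap_histogram()].
#' @export
overlap_histogram <- function(burden) {
  assert_columns(burden, c("gene", "n_families"), "burden")
  hist <- burden |>
    filter(.data$n_families >= 2L) |>
    dplyr::count(.data$n_families, name = "n_genes") |>
    arrange(dplyr::desc(.data$n_families))
  attr(hist, "total_multi_family_genes") <- sum(hist$n_genes)
  class(hist) <- c("fvp_overlap_histogram", class(hist))
  hist
}

#' @rdname overlap_histogram
#' @param x An `fvp_overlap_histogram`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.fvp_overlap_histogram <- function(x, ...) {
  tibble(total_multi_family_genes = attr(x, "total_multi_family_genes"),
         max_overlap = if (nrow(x) > 0) max(x$n_families) else NA_integer_)
}

#' Identical variants recurring in several families
#'
#' Variants (exact key match) fully shared in two or more families, with
#' the family list and, when the annotation and control columns are
#' present, population and control frequencies, CADD, the ensemble vote
#' and the recurrent-variant damaging call.
#'
#' @param family_sets Variant-level tibble of shared variants
#'   (`family_id`, `variant_key`, plus annotation columns).
#' @param controls Optional control table to append control frequencies.
#' @param rules [damaging_rules()] used for the damaging call.
#' @return Tibble with one row per recurrent variant.
#' @export
recurrent_variants <- function(family_sets, controls = NULL,
                               rules = damaging_rules()) {
  assert_columns(family_sets, c("family_id", "variant_key"), "family_sets")
  rec <- family_sets |>
    summarise(n_families = dplyr::n_distinct(.data$family_id),
              family_ids = list(sort(unique(.data$family_id))),
              .by = "variant_key") |>
    filter(.data$n_families >= 2L)
  meta_cols <- intersect(c("gene", "consequence", "population_maf",
                           "cadd_phred", predictor_columns()),
                         names(family_sets))
  meta <- distinct(family_sets, .data$variant_key,
                   dplyr::pick(dplyr::all_of(meta_cols)))
  out <- left_join(rec, meta, by = "variant_key")
  if (all(c("cadd_phred", predictor_columns()) %in% names(out))) {
    out$vote_count <- predictor_vote(out)
    out$table_damaging <- classify_table1(out, rules)
  }
  if (!is.null(controls)) {
    out <- out |>
      left_join(controls, by = "variant_key") |>
      mutate(control_af = .data$control_ac / .data$control_an)
  }
  arrange(out, dplyr::desc(.data$n_families), .data$variant_key)
}

#' Correlation between gene length and burden
#'
#' Tests whether gene length (summed UTRs + coding sequence) explains the
#' per-gene variant count and the per-gene family count, as a confounder
#' check on the burden ranking.
#'
#' @param burden A [gene_overlap()] table.
#' @param gene_lengths Tibble with `gene`, `length_bp`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble with one row per target (`n_variants`,
#'   `n_families`): `r`, `n`, `p_value`.
#' @export
gene_length_correlation <- function(burden, gene_lengths,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_columns(gene_lengths, c("gene", "length_bp"), "gene_lengths")
  df <- inner_join(as_tibble(burden), gene_lengths, by = "gene")
  if (nrow(df) < 3) abort("gene-length correlation needs >= 3 genes")
  one <- function(target) {
    ct <- cor.test(df$length_bp, df[[target]], method = method, exact = FALSE)
    tibble(target = target, r = unname(ct$estimate), n = nrow(df),
           p_value = ct$p.value)
  }
  bind_rows(one("n_variants"), one("n_families"))
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
  pmin(inter / (e1 - s1 + 1), inter / (e2 - s2 + 1))
}

#' Screen CNV calls for family-shared, rare, multi-exon events
#'
#' Retains family-level CNVs that (1) cover at least `min_exons` exons,
#' (2) are present in every affected member of the family — a member
#' matches when it has a call of the same copy state on the same
#' chromosome with reciprocal overlap of at least `min_reciprocal` —
#' and (3) have population frequency at most `max_frequency` in every
#' member call. Retained CNVs recurring across families are flagged: by
#' shared gene when `gene_map` is supplied (regions overlapping the same
#' gene), otherwise by reciprocal overlap between the family events.
#'
#' @param cnv_calls Tibble of per-sample CNV calls (see
#'   [read_cnv_table()]).
#' @param cohorts Family cohorts from [family_cohorts()].
#' @param gene_map Optional tibble `gene`, `chrom`, `start`, `end` for
#'   gene assignment.
#' @param min_exons Minimum exon count (default 4, inclusive).
#' @param max_frequency Maximum population frequency (default 0.02,
#'   inclusive).
#' @param min_reciprocal Reciprocal-overlap fraction defining "the same
#'   CNV" (default 0.5).
#' @return Tibble of retained family CNVs (`family_id`, coordinates,
#'   `copy_state`, `exon_count`, `population_frequency`, `gene`,
#'   `recurrent`).
#' @export
cnv_screen <- function(cnv_calls, cohorts, gene_map = NULL,
                       min_exons = 4L, max_frequency = 0.02,
                       min_reciprocal = 0.5) {
  assert_columns(cnv_calls, cnv_cols(), "cnv_calls")
  retained <- list()
  for (i in seq_len(nrow(cohorts))) {
    fid <- cohorts$family_id[i]
    members <- cohorts$affected_samples[[i]]
    fam <- filter(cnv_calls, .data$family_id == fid,
                  .data$sample_id %in% members)
    if (nrow(fam) == 0) next
    seeds <- filter(fam, .data$sample_id == fam$sample_id[1])
    for (j in seq_len(nrow(seeds))) {
      seed <- seeds[j, ]
      matches <- fam |>
        filter(.data$chrom == seed$chrom,
               .data$copy_state == seed$copy_state,
               reciprocal_overlap(.data$start, .data$end,
                                  seed$start, seed$end) >= min_reciprocal)
      shared_by_all <- all(members %in% matches$sample_id)
      if (shared_by_all &&
          min(matches$exon_count) >= min_exons &&
          max(matches$population_frequency) <= max_frequency) {
        retained[[length(retained) + 1]] <- tibble(
          family_id = fid, chrom = seed$chrom,
          start = min(matches$start), end = max(matches$end),
          copy_state = seed$copy_state,
          exon_count = min(matches$exon_count),
          population_frequency = max(matches$population_frequency))
      }
    }
  }
  out <- bind_rows(retained)
  if (nrow(out) == 0) {
    return(tibble(family_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  copy_state = character(0), exon_count = integer(0),
                  population_frequency = numeric(0), gene = character(0),
                  recurrent = logical(0)))
  }
  out <- distinct(out)
  out$gene <- NA_character_
  if (!is.null(gene_map)) {
    for (i in seq_len(nrow(out))) {
      hit <- gene_map |>
        filter(.data$chrom == out$chrom[i], .data$start <= out$end[i],
               .data$end >= out$start[i])
      if (nrow(hit) > 0) out$gene[i] <- hit$gene[1]
    }
    rec_genes <- out |>
      filter(!is.na(.data$gene)) |>
      distinct(.data$gene, .data$family_id) |>
      dplyr::count(.data$gene) |>
      filter(.data$n >= 2)
    out$recurrent <- !is.na(out$gene) & out$gene %in% rec_genes$gene
  } else {
    out$recurrent <- FALSE
    for (i in seq_len(nrow(out))) {
      others <- out[-i, ]
      out$recurrent[i] <- any(
        others$chrom == out$chrom[i] &
          others$copy_state == out$copy_state[i] &
          others$family_id != out$family_id[i] &
          reciprocal_overlap(others$start, others$end,
                             out$start[i], out$end[i]) >= min_reciprocal)
    }
  }
  arrange(out, dplyr::desc(.data$recurrent), .data$family_id)
}
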
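# End-to-end orchestration: QC with sample/family exclusions, the
# filtering cascade, control enrichment, deleteriousness classification,
# burden/recurrence/CNV aggregation, term enrichment, and deterministic
# result output.

#' Assemble and validate a pipeline configuration
#'
#' @param vcf Named character vector of per-family VCF paths (names are
#'   family ids) — or a directory containing `<family_id>.vcf` files.
#' @param pedigree Path to the PED file.
#' @param annotations Path to the annotation TSV.
#' @param controls Path to the control-cohort TSV.
#' @param cnv Optional path to the CNV call TSV.
#' @param gene_sets Optional path to a GMT collection.
#' @param gene_lengths Optional path to the gene-length TSV.
#' @param known_genes Optional character vector of paths to known-gene
#'   lists (named `human` / `canine`) or a single path.
#' @param thresholds [filter_thresholds()] configuration.
#' @param rules [damaging_rules()] configuration.
#' @param enrichment_alpha Raw Fisher cut-off (default 0.05).
#' @param term_alpha FDR cut-off for term enrichment (default 0.05).
#' @param qc_exclusions Apply VAF-flag sample exclusion and PCA family
#'   exclusion before filtering (default TRUE)?
#' @param kinship Run pairwise kinship QC (default TRUE)?
#' @param output_dir Optional directory; when set, result tables are
#'   written there as TSV plus a JSON run manifest.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic given its inputs).
#' @return A validated `fvp_pipeline_config` list.
#' @export
pipeline_config <- function(vcf, pedigree, annotations, controls,
                            cnv = NULL, gene_sets = NULL,
                            gene_lengths = NULL, known_genes = NULL,
                            thresholds = filter_thresholds(),
                            rules = damaging_rules(),
                            enrichment_alpha = 0.05, term_alpha = 0.05,
                            qc_exclusions = TRUE, kinship = TRUE,
                            output_dir = NULL, seed = 1L) {
  if (length(vcf) == 1 && dir.exists(vcf)) {
    files <- list.files(vcf, pattern = "\\.vcf$", full.names = TRUE)
    vcf <- setNames(files, sub("\\.vcf$", "", basename(files)))
  }
  paths <- c(vcf, pedigree = pedigree, annotations = annotations,
             controls = controls, cnv = cnv, gene_sets = gene_sets,
             gene_lengths = gene_lengths, known_genes)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("input path(s) do not exist: %s",
                  paste(missing, collapse = ", ")))
  }
  structure(list(vcf = vcf, pedigree = pedigree, annotations = annotations,
                 controls = controls, cnv = cnv, gene_sets = gene_sets,
                 gene_lengths = gene_lengths, known_genes = known_genes,
                 thresholds = thresholds, rules = rules,
                 enrichment_alpha = enrichment_alpha,
                 term_alpha = term_alpha,
                 qc_exclusions = isTRUE(qc_exclusions),
                 kinship = isTRUE(kinship),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "fvp_pipeline_config")
}

#' Run the full familial rare-variant analysis
#'
#' Reads every input, runs per-sample and cohort QC, applies the QC
#' exclusions (contamination-flagged samples, stratification-outlier
#' families, families reduced below two affected members), then the
#' filtering cascade, the control-cohort enrichment screen, the
#' deleteriousness classification, the burden / recurrent-variant / CNV /
#' term-enrichment aggregations, and (optionally) writes all result
#' tables plus a run manifest. Deterministic given inputs.
#'
#' @param config An [pipeline_config()] object.
#' @return An `fvp_pipeline` result list; see the elements documented in
#'   the return tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fvp_pipeline_config"))
  ped <- read_pedigree(config$pedigree)
  cohorts <- family_cohorts(ped)
  annotations <- read_annotation_table(config$annotations)
  controls <- read_control_table(config$controls)

  fam_ids <- intersect(names(config$vcf), cohorts$family_id)
  if (length(fam_ids) == 0) abort("no VCF matches a pedigree family id")
  calls <- bind_rows(lapply(fam_ids, function(fid) {
    read_family_vcf(config$vcf[[fid]],
                    cohorts[cohorts$family_id == fid, ])
  }))

  # ---- QC and exclusions ----------------------------------------------
  qc_samples <- qc_sample_report(calls)
  common_keys <- annotations$variant_key[
    !is.na(annotations$population_maf) & annotations$population_maf >= 0.05]
  gmat <- dosage_matrix(filter(calls, .data$variant_key %in% common_keys))
  # PC1 only: with related samples the later components separate family
  # cliques, not ancestry, and must not drive family exclusions
  pca <- if (nrow(gmat) >= 3 && ncol(gmat) >= 2) {
    genotype_pca(gmat, outlier_components = 1L)
  } else NULL
  kin <- NULL
  if (config$kinship && !is.null(pca) && ncol(gmat) >= 100) {
    kin <- king_kinship_matrix(gmat, min_snps = min(1000L, ncol(gmat)))
  }

  excluded_samples <- character(0)
  excluded_families <- character(0)
  if (config$qc_exclusions) {
    excluded_samples <- qc_samples$sample_id[qc_samples$vaf_flag]
    if (!is.null(pca) && length(pca$outliers) > 0) {
      by_fam <- ped |>
        filter(.data$affected == 2L) |>
        summarise(frac_out = mean(.data$sample_id %in% pca$outliers),
                  .by = "family_id")
      excluded_families <- by_fam$family_id[by_fam$frac_out > 0.5]
    }
  }
  ped_kept <- ped |>
    filter(!.data$sample_id %in% excluded_samples,
           !.data$family_id %in% excluded_families)
  cohorts_kept <- suppressWarnings(family_cohorts(ped_kept))
  calls_kept <- calls |>
    filter(.data$family_id %in% cohorts_kept$family_id,
           .data$sample_id %in% unlist(cohorts_kept$affected_samples))

  # ---- cascade + enrichment + classification --------------------------
  cascade <- run_family_cascade(calls_kept, cohorts_kept, annotations,
                                config$thresholds)
  enr <- enrichment_screen(cascade$variants, calls_kept, cohorts_kept,
                           controls, alpha = config$enrichment_alpha)
  shared <- cascade$variants |>
    inner_join(select(enr, "variant_key", "p_value", "enriched"),
               by = "variant_key") |>
    filter(.data$enriched)
  classified <- classify_variants(shared, config$rules)
  strict <- filter(classified, .data$strict_damaging)
  top_rank <- filter(strict, .data$phenotype_rank_pass)

  burden <- gene_overlap(shared)
  histogram <- overlap_histogram(burden)
  recurrent <- recurrent_variants(shared, controls, config$rules)
  correlation <- NULL
  if (!is.null(config$gene_lengths)) {
    correlation <- gene_length_correlation(
      burden, read_gene_lengths(config$gene_lengths))
  }
  cnv_retained <- NULL
  if (!is.null(config$cnv)) {
    cnv_retained <- cnv_screen(read_cnv_table(config$cnv), cohorts_kept)
  }
  terms <- NULL
  if (!is.null(config$gene_sets)) {
    multi <- burden$gene[burden$n_families >= 2]
    if (length(multi) > 0) {
      terms <- enrichment_report(multi, read_gene_sets(config$gene_sets),
                                 alpha = config$term_alpha)
    }
  }
  if (!is.null(config$known_genes)) {
    known <- lapply(config$known_genes, readr::read_lines, progress = FALSE)
    names(known) <- names(config$known_genes) %||%
      paste0("list", seq_along(known))
    burden <- known_gene_annotation(burden, known)
  }

  result <- structure(list(
    qc = list(samples = qc_samples, pca = pca, kinship = kin,
              excluded_samples = excluded_samples,
              excluded_families = excluded_families),
    cohorts = cohorts_kept,
    cascade = cascade,
    enrichment = enr,
    shared_variants = shared,
    classified = classified,
    strict_damaging = strict,
    top_phenotype_rank = top_rank,
    burden = burden,
    histogram = histogram,
    recurrent = recurrent,
    correlation = correlation,
    cnv = cnv_retained,
    terms = terms,
    manifest = list(
      package_version = as.character(utils::packageVersion("famvar")),
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
      n_families_analyzed = nrow(cohorts_kept),
      n_samples_analyzed = length(unlist(cohorts_kept$affected_samples)),
      stage_counts = cascade$stage_counts)
  ), class = "fvp_pipeline")
  if (!is.null(config$output_dir)) {
    write_pipeline_results(result, config$output_dir)
  }
  result
}

write_pipeline_results <- function(result, directory) {
  tables <- list(
    qc_samples = result$qc$samples,
    stage_counts = result$cascade$stage_counts,
    shared_variants = result$shared_variants,
    enrichment = result$enrichment,
    classified_variants = result$classified,
    burden = as_tibble(result$burden),
    overlap_histogram = as_tibble(result$histogram),
    recurrent_variants = result$recurrent
  )
  if (!is.null(result$correlation)) tables$gene_length_correlation <- result$correlation
  if (!is.null(result$cnv)) tables$cnv_retained <- result$cnv
  if (!is.null(result$terms)) tables$term_enrichment <- as_tibble(result$terms)
  if (!is.null(result$qc$kinship)) tables$kinship <- result$qc$kinship
  if (!is.null(result$qc$pca)) tables$pca <- tidy(result$qc$pca)
  paths <- write_results(tables, directory)
  manifest <- result$manifest
  manifest$stage_counts <- NULL
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' @export
print.fvp_pipeline <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<fvp_pipeline> %d families / %d samples analyzed; ",
           "%d shared enriched variants in %d genes; %d strict-damaging; ",
           "%d multi-family genes\n"),
    g$n_families, g$n_samples, g$n_shared_variants, g$n_genes,
    g$n_strict_damaging, g$total_multi_family_genes))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `fvp_pipeline` result.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.fvp_pipeline <- function(x, ...) {
  tibble(
    n_families = x$manifest$n_families_analyzed,
    n_samples = x$manifest$n_samples_analyzed,
    n_shared_variants = nrow(x$shared_variants),
    n_genes = dplyr::n_distinct(x$shared_variants$gene),
    n_strict_damaging = nrow(x$strict_damaging),
    n_top_phenotype_rank = nrow(x$top_phenotype_rank),
    total_multi_family_genes = attr(x$histogram, "total_multi_family_genes")
  )
}

#' Annotate a burden table with known-gene memberships
#'
#' Flags each gene against user-supplied known-gene lists (e.g. genes
#' already associated with the phenotype in humans or in a model
#' species); genes in no list are `novel`. Annotation only — counts are
#' never changed.
#'
#' @param burden A [gene_overlap()] table.
#' @param known_gene_lists Named list of character vectors of gene
#'   symbols (e.g. `list(human = ..., canine = ...)`).
#' @return The burden table with one logical `known_<name>` column per
#'   list and a `novel` column.
#' @export
known_gene_annotation <- function(burden, known_gene_lists) {
  assert_columns(burden, "gene", "burden")
  stopifnot(is.list(known_gene_lists))
  if (is.null(names(known_gene_lists))) {
    names(known_gene_lists) <- paste0("list", seq_along(known_gene_lists))
  }
  any_known <- rep(FALSE, nrow(burden))
  for (nm in names(known_gene_lists)) {
    hit <- burden$gene %in% known_gene_lists[[nm]]
    burden[[paste0("known_", nm)]] <- hit
    any_known <- any_known | hit
  }
  burden$novel <- !any_known
  burden
}
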
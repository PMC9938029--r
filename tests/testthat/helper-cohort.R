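# Shared fixtures: a small fast cohort for unit tests, the full
# default-shaped cohort (cached) for end-to-end checks, and tiny builders
# for hand-constructed call/annotation tables.

small_sim_config <- function(seed = 42L, ...) {
  defaults <- list(
    n_families = 6L,
    members_per_family = c(2L, 2L, 2L, 2L, 3L, 3L),
    n_background_variants = 3000L,
    n_common_variants = 400L,
    n_genes = 400L,
    n_planted_causal_genes = 3L,
    families_per_causal_gene = 2L,
    shared_means = list(duo = 30, trio = 20, other = 10),
    divergent_family = FALSE,
    n_contaminated_samples = 0L,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(small_sim_config())
    cache
  }
})

default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(sim_config(seed = 7L))
    cache
  }
})

# full pipeline run on the default cohort, cached across test files
default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- default_cohort()
      dir <- file.path(tempdir(), "famvar-default-fixture")
      paths <- write_fixture(b, dir)
      cfg <- pipeline_config(
        vcf = paths$vcf, pedigree = paths$pedigree,
        annotations = paths$annotations, controls = paths$controls,
        cnv = paths$cnv, gene_sets = paths$gene_sets,
        gene_lengths = paths$gene_lengths)
      cache <<- suppressMessages(suppressWarnings(run_pipeline(cfg)))
    }
    cache
  }
})

mk_call <- function(family_id, sample_id, key = "1:100:A:G", gt = "0/1",
                    dp = 40L, ad_alt = 20L, gq = 99L, qual = 1000) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  tibble::tibble(
    family_id = family_id, sample_id = sample_id,
    chrom = parts[1], pos = as.integer(parts[2]),
    ref = parts[3], alt = parts[4], variant_key = key,
    gt = gt, dp = as.integer(dp),
    ad_ref = as.integer(dp - ad_alt), ad_alt = as.integer(ad_alt),
    gq = as.integer(gq), site_qual = qual)
}

mk_cohorts <- function(fams) {
  tibble::tibble(family_id = names(fams),
                 affected_samples = unname(fams),
                 n_affected = lengths(fams))
}

mk_ann <- function(variant_key, gene = "G1", consequence = "missense",
                   maf = 0.001, hom = 0L, ac = 10L, cadd = 10,
                   votes = 0L, rank = 0.5, splice = FALSE) {
  preds <- rep("benign", 6)
  if (!is.na(votes) && votes > 0) preds[seq_len(votes)] <- "damaging"
  if (is.na(votes)) preds <- rep(NA_character_, 6)
  out <- tibble::tibble(
    variant_key = variant_key, gene = gene, consequence = consequence,
    population_maf = maf, population_hom_count = as.integer(hom),
    population_alt_allele_count = as.integer(ac), cadd_phred = cadd)
  for (i in seq_along(predictor_columns())) {
    out[[predictor_columns()[i]]] <- preds[i]
  }
  out$phenotype_rank <- rank
  out$splice_damaging <- splice
  out
}
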
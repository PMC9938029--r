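# Synthetic multi-family exome cohort with planted ground truth.
#
# The generator emulates the study conditions the pipeline is built for:
# ~29 families of 2-5 affected first-degree relatives (66 samples), a shared
# rare-variant load per family (Poisson mean 104 for duos, 52 for trios at
# the sharing stage), per-sample private background variants drawn
# binomially at each variant's population MAF, a common SNP panel
# transmitted Mendelian-ly within families (for kinship/PCA/QC), a
# control cohort of 2000 diploid individuals simulated at the allele-count
# level, planted causal genes engineered to survive the full cascade, and
# planted QC defects (one contaminated sample, one divergent-ancestry
# family, a 5% low-VAF artifact rate) so the exclusion logic is testable.

#' Build a validated simulation configuration
#'
#' Defaults describe the cohort shape the pipeline targets: 29 families
#' (23 duos, 5 trios, one 5-member family used as the divergent-ancestry
#' family), 66 affected samples of whom 54 are female, a 2000-individual
#' diploid control cohort, and a reference population of 125,748 diploid
#' exomes behind the population allele counts.
#'
#' @param n_families Number of families (>= 1).
#' @param members_per_family Integer vector of affected members per family
#'   (each >= 2); recycled to `n_families`.
#' @param n_background_variants Size of the rare background variant panel.
#' @param n_common_variants Size of the common SNP panel (MAF 0.05-0.5)
#'   used for kinship, PCA and QC metrics.
#' @param n_genes Size of the gene universe.
#' @param n_planted_causal_genes Number of planted causal genes; each gets
#'   one variant fully shared in `families_per_causal_gene` families.
#' @param families_per_causal_gene Families carrying each planted variant.
#' @param control_cohort_size Control cohort size in diploid individuals.
#' @param reference_exomes Diploid individuals behind the population
#'   (gnomAD-like) allele counts.
#' @param causal_maf_range Population MAF range for planted variants;
#'   upper bound must be <= 0.01.
#' @param background_maf_distribution Named distribution for background
#'   MAFs: a list with `name = "beta_mixture"`, beta parameters `shape1`,
#'   `shape2` for the rare component, `common_frac` and `common_range`
#'   for a uniform common component that exercises the rarity filter.
#' @param shared_means Named list of Poisson means for per-family shared
#'   variant counts at the sharing stage, by family size
#'   (`duo`, `trio`, `other`).
#' @param titv_odds Transition:transversion odds used when assigning
#'   substitution types (2.7 is typical of exome calls).
#' @param mean_depth Mean sequencing depth (Poisson).
#' @param missing_rate Genotype missingness rate (default 0).
#' @param artifact_rate Fraction of family-shared variants given one
#'   low-VAF member call (a planted quality artifact).
#' @param divergent_family Should the largest family be drawn from
#'   Balding-Nichols-shifted allele frequencies (a stratification outlier)?
#' @param divergent_fst Fst of the divergent family's source population.
#' @param n_contaminated_samples Number of samples given the
#'   cross-contamination VAF signature.
#' @param contamination_fraction Mixing fraction of the contaminant.
#' @param female_fraction Fraction of samples assigned female sex.
#' @param seed Integer seed; fully determines all outputs.
#' @return A validated `fvp_sim_config` list.
#' @export
sim_config <- function(n_families = 29L,
                       members_per_family = c(rep(2L, 23), rep(3L, 5), 5L),
                       n_background_variants = 20000L,
                       n_common_variants = 1500L,
                       n_genes = 2600L,
                       n_planted_causal_genes = 5L,
                       families_per_causal_gene = 3L,
                       control_cohort_size = 2000L,
                       reference_exomes = 125748L,
                       causal_maf_range = c(1e-4, 1.5e-3),
                       background_maf_distribution = list(
                         name = "beta_mixture", shape1 = 0.2, shape2 = 250,
                         common_frac = 0.08, common_range = c(0.01, 0.04)),
                       shared_means = list(duo = 104, trio = 52, other = 30),
                       titv_odds = 2.7,
                       mean_depth = 140,
                       missing_rate = 0,
                       artifact_rate = 0.05,
                       divergent_family = TRUE,
                       divergent_fst = 0.05,
                       n_contaminated_samples = 1L,
                       contamination_fraction = 0.15,
                       female_fraction = 54 / 66,
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    members_per_family = as.integer(rep_len(members_per_family, n_families)),
    n_background_variants = as.integer(n_background_variants),
    n_common_variants = as.integer(n_common_variants),
    n_genes = as.integer(n_genes),
    n_planted_causal_genes = as.integer(n_planted_causal_genes),
    families_per_causal_gene = as.integer(families_per_causal_gene),
    control_cohort_size = as.integer(control_cohort_size),
    reference_exomes = as.integer(reference_exomes),
    causal_maf_range = as.numeric(causal_maf_range),
    background_maf_distribution = background_maf_distribution,
    shared_means = shared_means,
    titv_odds = titv_odds,
    mean_depth = mean_depth,
    missing_rate = missing_rate,
    artifact_rate = artifact_rate,
    divergent_family = isTRUE(divergent_family),
    divergent_fst = divergent_fst,
    n_contaminated_samples = as.integer(n_contaminated_samples),
    contamination_fraction = contamination_fraction,
    female_fraction = female_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "fvp_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_families < 1L) abort("invalid configuration: need >= 1 family")
  if (any(cfg$members_per_family < 2L)) {
    abort("invalid configuration: every family needs >= 2 affected members")
  }
  counts <- c(cfg$n_background_variants, cfg$n_common_variants, cfg$n_genes,
              cfg$control_cohort_size, cfg$reference_exomes)
  if (any(counts < 1L)) abort("invalid configuration: all counts must be >= 1")
  if (cfg$n_planted_causal_genes < 0L) {
    abort("invalid configuration: negative planted gene count")
  }
  r <- cfg$causal_maf_range
  if (length(r) != 2 || r[1] < 0 || r[2] > 0.01 || r[1] > r[2]) {
    abort("invalid configuration: causal_maf_range must sit within [0, 0.01]")
  }
  if (cfg$families_per_causal_gene > cfg$n_families) {
    abort("invalid configuration: families_per_causal_gene exceeds n_families")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("invalid configuration: missing_rate must be in [0, 1)")
  }
  invisible(cfg)
}

#' Simulate a complete familial exome cohort with planted ground truth
#'
#' @param config A configuration from [sim_config()].
#' @return An object of class `fvp_cohort`: a list with elements
#'   `config`, `pedigree`, `cohorts`, `calls` (call-level tibble),
#'   `annotations`, `controls`, `cnv`, `cnv_gene_map`, `gene_sets`,
#'   `gene_lengths`, and `truth` (the planted ground truth: causal genes,
#'   causal variant keys, family assignments, shared keys per family,
#'   planted artifacts, contaminated samples, divergent family, the
#'   planted enriched term, and the CNV expectations).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  ped <- build_pedigree(cfg)
  samples <- ped$sampled$sample_id
  n_samples <- length(samples)

  # gene universe and lengths (lognormal, bp); causal genes reserved so the
  # planted family count is not inflated by background hits
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  gene_len <- round(stats::rlnorm(cfg$n_genes, meanlog = 7.8, sdlog = 0.8)) + 200L
  causal_genes <- if (cfg$n_planted_causal_genes > 0) {
    sample(genes, cfg$n_planted_causal_genes)
  } else character(0)
  bg_genes <- setdiff(genes, causal_genes)
  bg_len <- gene_len[match(bg_genes, genes)]

  common <- build_common_panel(cfg)
  background <- build_background_panel(cfg, bg_genes, bg_len)
  causal <- build_causal_panel(cfg, causal_genes)

  # -- genotypes ---------------------------------------------------------
  common_dos <- simulate_common_genotypes(cfg, ped, common$maf)
  rare_dos <- matrix(rbinom(n_samples * nrow(background), 2L,
                            rep(background$maf, each = n_samples)),
                     nrow = n_samples,
                     dimnames = list(samples, background$variant_key))

  shared_truth <- plant_shared_variants(cfg, ped, background, rare_dos)
  rare_dos <- shared_truth$dosage

  causal_dos <- matrix(0L, nrow = n_samples, ncol = nrow(causal),
                       dimnames = list(samples, causal$variant_key))
  assignments <- plant_causal_variants(cfg, ped, causal)
  if (nrow(assignments) > 0) {
    for (i in seq_len(nrow(assignments))) {
      members <- ped$sampled$sample_id[ped$sampled$family_id == assignments$family_id[i]]
      causal_dos[members, assignments$variant_key[i]] <- 1L
    }
  }

  panel <- bind_rows(
    common$meta[, c("variant_key", "chrom", "pos", "ref", "alt")],
    background[, c("variant_key", "chrom", "pos", "ref", "alt")],
    causal[, c("variant_key", "chrom", "pos", "ref", "alt")]
  )
  panel$site_qual <- round(runif(nrow(panel), 100, 3000))
  dosage <- cbind(common_dos, rare_dos, causal_dos)

  calls <- assemble_calls(cfg, ped, panel, dosage)
  art <- plant_artifacts(cfg, calls, shared_truth$shared)
  calls <- art$calls
  contaminated <- pick_contaminated(cfg, ped)
  calls <- apply_contamination(cfg, calls, contaminated)
  if (cfg$missing_rate > 0) {
    drop <- runif(nrow(calls)) < cfg$missing_rate
    calls$gt[drop] <- "./."
  }

  annotations <- bind_rows(common$ann, background$ann[[1]], causal$ann[[1]])
  controls <- build_control_table(cfg, annotations, causal$variant_key)
  cnv <- build_cnv_fixture(cfg, ped, bg_genes)
  gs <- build_gene_sets(cfg, genes, causal_genes)

  truth <- list(
    planted_causal_genes = causal_genes,
    planted_variant_keys = causal$variant_key,
    family_assignments = assignments,
    shared_keys = shared_truth$shared,
    artifacts = art$artifacts,
    contaminated_samples = contaminated,
    divergent_family = if (cfg$divergent_family) divergent_family_id(cfg) else character(0),
    enriched_term = gs$planted_term,
    cnv = cnv$truth
  )

  structure(list(
    config = cfg,
    pedigree = ped$sampled,
    cohorts = family_cohorts(ped$sampled),
    calls = calls,
    annotations = annotations,
    controls = controls,
    cnv = cnv$calls,
    cnv_gene_map = cnv$gene_map,
    gene_sets = gs$sets,
    gene_lengths = tibble(gene = genes, length_bp = as.integer(gene_len)),
    truth = truth
  ), class = "fvp_cohort")
}

#' @export
print.fvp_cohort <- function(x, ...) {
  cat(sprintf(
    "<fvp_cohort> %d families / %d affected samples; %s call rows; %d annotated variants; control cohort %d diploid individuals; %d planted causal gene(s)\n",
    nrow(x$cohorts), nrow(x$pedigree), format(nrow(x$calls), big.mark = ","),
    nrow(x$annotations), x$config$control_cohort_size,
    length(x$truth$planted_causal_genes)))
  invisible(x)
}

divergent_family_id <- function(cfg) {
  sprintf("F%02d", which.max(cfg$members_per_family))
}

# Pedigree: duos are sibling pairs with two unsampled founders; larger
# families are one sampled parent plus (k-1) children (first-degree pairs
# throughout). Sex is assigned to hit the configured female fraction exactly.
build_pedigree <- function(cfg) {
  fam_ids <- sprintf("F%02d", seq_len(cfg$n_families))
  sampled <- list()
  founders <- list()
  for (i in seq_len(cfg$n_families)) {
    fid <- fam_ids[i]
    k <- cfg$members_per_family[i]
    dad <- paste0(fid, "_u1")
    mom <- paste0(fid, "_u2")
    if (k == 2L) {
      ids <- paste0(fid, "_", LETTERS[1:2])
      fa <- c(dad, dad); mo <- c(mom, mom)
      founders[[fid]] <- c(dad, mom)
    } else {
      parent <- paste0(fid, "_A")
      kids <- paste0(fid, "_", LETTERS[2:k])
      ids <- c(parent, kids)
      fa <- c("0", rep(dad, k - 1))
      mo <- c("0", rep(parent, k - 1))  # sampled parent recorded as mother
      founders[[fid]] <- dad
    }
    sampled[[fid]] <- tibble(family_id = fid, sample_id = ids,
                             father_id = fa, mother_id = mo)
  }
  sampled <- bind_rows(sampled)
  n <- nrow(sampled)
  n_female <- round(n * cfg$female_fraction)
  sex <- rep(1L, n)
  sex[sample.int(n, n_female)] <- 2L
  sampled$sex <- sex
  sampled$affected <- 2L
  # sampled parents were recorded as mothers; force them female for
  # pedigree consistency without changing the female total
  parents <- unique(sampled$mother_id[sampled$mother_id %in% sampled$sample_id])
  for (p in parents) {
    i <- match(p, sampled$sample_id)
    if (sampled$sex[i] != 2L) {
      j <- which(sampled$sex == 2L & !sampled$sample_id %in% parents)[1]
      sampled$sex[j] <- 1L
      sampled$sex[i] <- 2L
    }
  }
  list(sampled = sampled, founders = founders)
}

# substitution alleles with fixed transition:transversion odds
draw_substitutions <- function(n, titv_odds) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  ti <- runif(n) < titv_odds / (1 + titv_odds)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  tv_choices <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  alt <- ifelse(ti, transitions[ref],
                map_chr(tv_choices[ref], ~ sample(.x, 1)))
  tibble(ref = unname(ref), alt = unname(alt))
}

build_common_panel <- function(cfg) {
  n <- cfg$n_common_variants
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(2e8, n)
  al <- draw_substitutions(n, cfg$titv_odds)
  maf <- signif(runif(n, 0.05, 0.5), 6)
  key <- variant_key(chrom, pos, al$ref, al$alt)
  cons <- sample(c("synonymous", "missense", "other"), n, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  ann <- tibble(
    variant_key = key, gene = sprintf("GENE%04d", sample.int(cfg$n_genes, n, replace = TRUE)),
    consequence = cons,
    population_maf = maf,
    population_hom_count = rbinom(n, cfg$reference_exomes, maf^2),
    population_alt_allele_count = rbinom(n, 2L * cfg$reference_exomes, maf),
    cadd_phred = round(stats::rgamma(n, shape = 2, scale = 3), 2)
  )
  ann <- add_predictor_calls(ann)
  ann$phenotype_rank <- round(rbeta(n, 0.8, 4), 4)
  ann$splice_damaging <- FALSE
  list(meta = tibble(variant_key = key, chrom = chrom, pos = pos,
                     ref = al$ref, alt = al$alt),
       maf = maf, ann = ann[, annotation_cols()])
}

draw_background_maf <- function(n, dist) {
  if (!identical(dist$name, "beta_mixture")) {
    abort(sprintf("unknown background MAF distribution: %s", dist$name))
  }
  maf <- rbeta(n, dist$shape1, dist$shape2)
  common <- runif(n) < dist$common_frac
  maf[common] <- runif(sum(common), dist$common_range[1], dist$common_range[2])
  signif(pmin(pmax(maf, 1e-5), 0.05), 6)
}

consequence_probs <- function() {
  c(missense = 0.70, synonymous = 0.12, other = 0.03, inframe_indel = 0.03,
    stop_gain = 0.025, frameshift = 0.025, splice_canonical = 0.02,
    splice_region = 0.05)
}

# indel allele pairs for frameshift / inframe consequences
apply_indel_alleles <- function(ref, alt, cons) {
  bases <- c("A", "C", "G", "T")
  fs <- which(cons == "frameshift")
  for (i in fs) {
    ref[i] <- paste0(ref[i], paste(sample(bases, 1 + sample(0:1, 1), replace = TRUE), collapse = ""))
    # deletion: alt is the anchor base
    alt[i] <- substr(ref[i], 1, 1)
  }
  inf <- which(cons == "inframe_indel")
  for (i in inf) {
    ref[i] <- paste0(ref[i], paste(sample(bases, 3, replace = TRUE), collapse = ""))
    alt[i] <- substr(ref[i], 1, 1)
  }
  tibble(ref = ref, alt = alt)
}

add_predictor_calls <- function(ann, missing_rate = 0.05) {
  n <- nrow(ann)
  p_dam <- stats::plogis((ann$cadd_phred - 22) / 2.5)
  for (col in predictor_columns()) {
    call <- ifelse(runif(n) < p_dam, "damaging", "benign")
    call[runif(n) < missing_rate] <- NA_character_
    ann[[col]] <- call
  }
  ann
}

build_background_panel <- function(cfg, bg_genes, bg_len) {
  n <- cfg$n_background_variants
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(2e8, n) + 2e8L
  cons <- sample(names(consequence_probs()), n, replace = TRUE,
                 prob = consequence_probs())
  al <- draw_substitutions(n, cfg$titv_odds)
  al <- apply_indel_alleles(al$ref, al$alt, cons)
  maf <- draw_background_maf(n, cfg$background_maf_distribution)
  key <- variant_key(chrom, pos, al$ref, al$alt)
  cadd <- ifelse(runif(n) < 0.85,
                 stats::rgamma(n, shape = 2, scale = 4),
                 pmax(rnorm(n, 18, 5), 0))
  ann <- tibble(
    variant_key = key,
    gene = sample(bg_genes, n, replace = TRUE, prob = bg_len),
    consequence = cons,
    population_maf = maf,
    population_hom_count = rbinom(n, cfg$reference_exomes, maf^2),
    population_alt_allele_count = rbinom(n, 2L * cfg$reference_exomes, maf),
    cadd_phred = round(cadd, 2)
  )
  ann <- add_predictor_calls(ann)
  ann$phenotype_rank <- round(rbeta(n, 0.8, 4), 4)
  ann$splice_damaging <- ann$consequence == "splice_region" & runif(n) < 0.3
  out <- tibble(variant_key = key, chrom = chrom, pos = pos,
                ref = al$ref, alt = al$alt, maf = maf,
                consequence = cons,
                hom = ann$population_hom_count,
                splice_damaging = ann$splice_damaging)
  out$ann <- list(ann[, annotation_cols()])
  out
}

build_causal_panel <- function(cfg, causal_genes) {
  n <- length(causal_genes)
  if (n == 0) {
    out <- tibble(variant_key = character(0), chrom = character(0),
                  pos = integer(0), ref = character(0), alt = character(0),
                  maf = numeric(0))
    out$ann <- list(tibble())
    return(out)
  }
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(1e8, n) + 4e8L
  cons <- c("frameshift", rep("missense", n - 1))
  al <- draw_substitutions(n, cfg$titv_odds)
  al <- apply_indel_alleles(al$ref, al$alt, cons)
  maf <- signif(runif(n, cfg$causal_maf_range[1], cfg$causal_maf_range[2]), 6)
  key <- variant_key(chrom, pos, al$ref, al$alt)
  ann <- tibble(
    variant_key = key, gene = causal_genes, consequence = cons,
    population_maf = maf,
    population_hom_count = 0L,
    population_alt_allele_count = rbinom(n, 2L * cfg$reference_exomes, maf),
    cadd_phred = round(runif(n, 26, 35), 2)
  )
  for (col in predictor_columns()) {
    ann[[col]] <- ifelse(runif(n) < 0.95, "damaging", "benign")
  }
  ann$phenotype_rank <- round(runif(n, 0.8, 0.99), 4)
  ann$splice_damaging <- FALSE
  out <- tibble(variant_key = key, chrom = chrom, pos = pos,
                ref = al$ref, alt = al$alt, maf = maf)
  out$ann <- list(ann[, annotation_cols()])
  out
}

# Mendelian transmission of the common panel within each family; the
# divergent family's founder frequencies come from a Balding-Nichols draw.
simulate_common_genotypes <- function(cfg, ped, maf) {
  samples <- ped$sampled$sample_id
  out <- matrix(0L, nrow = length(samples), ncol = length(maf),
                dimnames = list(samples, NULL))
  div_fam <- if (cfg$divergent_family) divergent_family_id(cfg) else ""
  for (fid in unique(ped$sampled$family_id)) {
    fam <- ped$sampled[ped$sampled$family_id == fid, ]
    p <- maf
    if (fid == div_fam) {
      f <- cfg$divergent_fst
      p <- rbeta(length(maf), maf * (1 - f) / f, (1 - maf) * (1 - f) / f)
      p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    }
    full_ped <- bind_rows(
      tibble(sample_id = ped$founders[[fid]], father_id = "0", mother_id = "0"),
      fam[, c("sample_id", "father_id", "mother_id")]
    )
    g <- simulate_family_genotypes(full_ped, p)
    out[fam$sample_id, ] <- g[fam$sample_id, , drop = FALSE]
  }
  colnames(out) <- NULL
  out
}

#' Simulate genotypes through a pedigree by Mendelian transmission
#'
#' Founders (parent ids `"0"` or `NA`) are drawn from Hardy-Weinberg
#' binomial genotypes at each variant's MAF; each child receives one
#' gamete per parent, sampled as Bernoulli(parental dosage / 2). A parent
#' id absent from the pedigree is treated as a population founder gamete.
#'
#' @param pedigree Tibble with columns `sample_id`, `father_id`,
#'   `mother_id`, parents listed before children.
#' @param variant_panel Numeric vector of MAFs (one per variant).
#' @param seed Optional integer seed; when `NULL` the ambient RNG stream
#'   is used.
#' @return Integer dosage matrix (samples x variants) with sample ids as
#'   row names.
#' @export
simulate_family_genotypes <- function(pedigree, variant_panel, seed = NULL) {
  run <- function() {
    m <- length(variant_panel)
    g <- matrix(NA_integer_, nrow = nrow(pedigree), ncol = m,
                dimnames = list(pedigree$sample_id, NULL))
    gamete <- function(parent_id) {
      if (is.na(parent_id) || parent_id == "0" ||
          !parent_id %in% rownames(g)) {
        return(as.integer(runif(m) < variant_panel))
      }
      as.integer(runif(m) < g[parent_id, ] / 2)
    }
    for (i in seq_len(nrow(pedigree))) {
      fa <- pedigree$father_id[i]
      mo <- pedigree$mother_id[i]
      founder <- (is.na(fa) || fa == "0") && (is.na(mo) || mo == "0")
      g[i, ] <- if (founder) {
        rbinom(m, 2L, variant_panel)
      } else {
        gamete(fa) + gamete(mo)
      }
    }
    g
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Family-shared rare variants: sampled from the cascade-passing stratum of
# the background panel and set heterozygous in every affected member.
plant_shared_variants <- function(cfg, ped, background, dosage) {
  eligible <- which(background$maf <= 0.01 & background$hom < 5 &
                      background$consequence %in%
                        setdiff(consequence_levels(), c("synonymous", "other")) &
                      (background$consequence != "splice_region" |
                         background$splice_damaging))
  shared <- list()
  fams <- unique(ped$sampled$family_id)
  sizes <- cfg$members_per_family
  for (i in seq_along(fams)) {
    mean_n <- switch(as.character(sizes[i]),
                     "2" = cfg$shared_means$duo,
                     "3" = cfg$shared_means$trio,
                     cfg$shared_means$other)
    n_shared <- min(rpois(1, mean_n), length(eligible))
    idx <- sample(eligible, n_shared)
    members <- ped$sampled$sample_id[ped$sampled$family_id == fams[i]]
    dosage[members, idx] <- 1L
    shared[[fams[i]]] <- tibble(family_id = fams[i],
                                variant_key = background$variant_key[idx])
  }
  list(dosage = dosage, shared = bind_rows(shared))
}

plant_causal_variants <- function(cfg, ped, causal) {
  if (nrow(causal) == 0) {
    return(tibble(family_id = character(0), variant_key = character(0),
                  gene = character(0)))
  }
  avoid <- c(if (cfg$divergent_family) divergent_family_id(cfg))
  pool <- setdiff(unique(ped$sampled$family_id), avoid)
  ann <- causal$ann[[1]]
  bind_rows(lapply(seq_len(nrow(causal)), function(i) {
    fams <- sample(pool, cfg$families_per_causal_gene)
    tibble(family_id = fams, variant_key = causal$variant_key[i],
           gene = ann$gene[i])
  }))
}

# Long call table: one row per (family, variant-with-a-family-carrier,
# member), with simulated read-level evidence.
assemble_calls <- function(cfg, ped, panel, dosage) {
  rows <- list()
  for (fid in unique(ped$sampled$family_id)) {
    members <- ped$sampled$sample_id[ped$sampled$family_id == fid]
    d <- dosage[members, , drop = FALSE]
    keep <- which(colSums(d > 0L) > 0L)
    if (length(keep) == 0) next
    nm <- length(members); nv <- length(keep)
    rows[[fid]] <- tibble(
      family_id = fid,
      sample_id = rep(members, times = nv),
      variant_key = rep(panel$variant_key[keep], each = nm),
      chrom = rep(panel$chrom[keep], each = nm),
      pos = rep(panel$pos[keep], each = nm),
      ref = rep(panel$ref[keep], each = nm),
      alt = rep(panel$alt[keep], each = nm),
      site_qual = rep(panel$site_qual[keep], each = nm),
      dosage = as.integer(d[, keep])
    )
  }
  calls <- bind_rows(rows)
  n <- nrow(calls)
  dp <- pmax(rpois(n, cfg$mean_depth), 12L)
  vaf_true <- c(`0` = 0.002, `1` = 0.5, `2` = 0.98)[as.character(calls$dosage)]
  ad_alt <- rbinom(n, dp, vaf_true)
  calls |>
    mutate(gt = dosage_gt(.data$dosage),
           dp = as.integer(dp),
           ad_alt = as.integer(ad_alt),
           ad_ref = .data$dp - .data$ad_alt,
           gq = pmin(99L, as.integer(rpois(n, 92)))) |>
    select("family_id", "sample_id", "chrom", "pos", "ref", "alt",
           "variant_key", "gt", "dp", "ad_ref", "ad_alt", "gq", "site_qual")
}

# one low-VAF member call on a random subset of family-shared variants
plant_artifacts <- function(cfg, calls, shared) {
  if (cfg$artifact_rate <= 0 || nrow(shared) == 0) {
    return(list(calls = calls,
                artifacts = tibble(family_id = character(0),
                                   variant_key = character(0),
                                   sample_id = character(0))))
  }
  hit <- shared[runif(nrow(shared)) < cfg$artifact_rate, ]
  if (nrow(hit) == 0) {
    return(list(calls = calls,
                artifacts = tibble(family_id = character(0),
                                   variant_key = character(0),
                                   sample_id = character(0))))
  }
  art <- calls |>
    inner_join(hit, by = c("family_id", "variant_key")) |>
    filter(.data$gt == "0/1") |>
    slice_sample(n = 1, by = c("family_id", "variant_key")) |>
    select("family_id", "variant_key", "sample_id")
  idx <- which(paste(calls$family_id, calls$variant_key, calls$sample_id) %in%
                 paste(art$family_id, art$variant_key, art$sample_id))
  calls$ad_alt[idx] <- rbinom(length(idx), calls$dp[idx], 0.12)
  calls$ad_ref[idx] <- calls$dp[idx] - calls$ad_alt[idx]
  list(calls = calls, artifacts = art)
}

pick_contaminated <- function(cfg, ped) {
  if (cfg$n_contaminated_samples <= 0) return(character(0))
  trio_fams <- names(which(table(ped$sampled$family_id) == 3))
  avoid <- if (cfg$divergent_family) divergent_family_id(cfg) else ""
  pool <- ped$sampled$sample_id[
    ped$sampled$family_id %in% setdiff(trio_fams, avoid)]
  if (length(pool) == 0) pool <- ped$sampled$sample_id
  sample(pool, min(cfg$n_contaminated_samples, length(pool)))
}

# the cross-contamination signature: a fraction of het calls drift to
# VAF ~ mix or ~ 1 - mix
apply_contamination <- function(cfg, calls, contaminated) {
  if (length(contaminated) == 0) return(calls)
  mix <- cfg$contamination_fraction
  idx <- which(calls$sample_id %in% contaminated & calls$gt == "0/1" &
                 runif(nrow(calls)) < 0.45)
  shifted <- sample(c(mix + 0.05, 1 - mix - 0.05), length(idx), replace = TRUE)
  calls$ad_alt[idx] <- rbinom(length(idx), calls$dp[idx], shifted)
  calls$ad_ref[idx] <- calls$dp[idx] - calls$ad_alt[idx]
  calls
}

build_control_table <- function(cfg, annotations, causal_keys) {
  an <- 2L * cfg$control_cohort_size
  maf <- annotations$population_maf
  ac <- rbinom(nrow(annotations), an, maf)
  ac[annotations$variant_key %in% causal_keys] <- 0L
  out <- tibble(variant_key = annotations$variant_key,
                control_ac = as.integer(ac), control_an = an)
  attr(out, "cohort_size") <- cfg$control_cohort_size
  out
}

# CNV fixture: one recurrent 4-exon duplication planted in two families,
# one clean family-shared loss, and three designed failures (too few
# exons, too common, not shared by all members).
build_cnv_fixture <- function(cfg, ped, bg_genes) {
  fams <- unique(ped$sampled$family_id)
  members_of <- function(fid) ped$sampled$sample_id[ped$sampled$family_id == fid]
  gene_map <- tibble(
    gene = bg_genes[1:5],
    chrom = c("19", "7", "2", "11", "5"),
    start = c(4000000L, 1000000L, 5000000L, 8000000L, 2000000L),
    end = c(4050000L, 1040000L, 5060000L, 8030000L, 2020000L)
  )
  rec_fams <- fams[c(1, min(22, length(fams)))]
  mk <- function(fid, samples, chrom, start, end, state, exons, freq) {
    tibble(family_id = fid, sample_id = samples, chrom = chrom,
           start = as.integer(start), end = as.integer(end),
           copy_state = state, exon_count = as.integer(exons),
           population_frequency = freq)
  }
  calls <- bind_rows(
    # recurrent duplication, same gene, both families, all members
    bind_rows(lapply(rec_fams, function(f)
      mk(f, members_of(f), "19", 4010000, 4025000, "gain", 4, 0.01))),
    # retained non-recurrent loss
    mk(fams[3], members_of(fams[3]), "7", 1005000, 1020000, "loss", 5, 0.005),
    # too few exons
    mk(fams[4], members_of(fams[4]), "2", 5010000, 5015000, "loss", 3, 0.001),
    # too common
    mk(fams[5], members_of(fams[5]), "11", 8005000, 8020000, "gain", 6, 0.05),
    # not shared by all members
    mk(fams[6], members_of(fams[6])[1], "5", 2005000, 2012000, "loss", 4, 0.001)
  )
  list(calls = calls, gene_map = gene_map,
       truth = list(recurrent_gene = gene_map$gene[1],
                    recurrent_families = rec_fams,
                    retained_families = c(rec_fams, fams[3])))
}

build_gene_sets <- function(cfg, genes, causal_genes) {
  categories <- c("biological process", "cellular component",
                  "molecular function", "keyword")
  sets <- list()
  k <- 0
  for (cat in categories) {
    for (i in 1:10) {
      k <- k + 1
      sets[[k]] <- tibble(
        term = sprintf("TERM_%s_%02d", toupper(substr(cat, 1, 2)), i),
        category = cat,
        genes = list(sample(genes, max(5, rpois(1, 25)))))
    }
  }
  planted <- tibble(term = "TERM_PLANTED", category = "biological process",
                    genes = list(c(causal_genes,
                                   sample(setdiff(genes, causal_genes), 3))))
  sets <- bind_rows(bind_rows(sets), planted) |>
    mutate(n_genes = lengths(.data$genes))
  list(sets = sets, planted_term = "TERM_PLANTED")
}

#' Write a simulated cohort to standard-format fixture files
#'
#' Emits one VCF per family, a PED pedigree, TSV annotation / control /
#' CNV / gene-length tables and a GMT gene-set collection that round-trip
#' through the package readers without loss.
#'
#' @param bundle An `fvp_cohort` from [simulate_cohort()].
#' @param directory Output directory (created if absent).
#' @return Named list of file paths (`vcf` is itself a named vector,
#'   one per family), invisibly.
#' @export
write_fixture <- function(bundle, directory) {
  stopifnot(inherits(bundle, "fvp_cohort"))
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    abort(sprintf("cannot create fixture directory: %s", directory))
  }
  fams <- unique(bundle$pedigree$family_id)
  vcf_paths <- setNames(file.path(directory, paste0(fams, ".vcf")), fams)
  for (fid in fams) {
    fam_calls <- filter(bundle$calls, .data$family_id == fid)
    samples <- bundle$pedigree$sample_id[bundle$pedigree$family_id == fid]
    write_family_vcf(fam_calls, vcf_paths[[fid]], samples = samples)
  }
  paths <- list(
    vcf = vcf_paths,
    pedigree = write_pedigree(bundle$pedigree, file.path(directory, "cohort.ped")),
    annotations = write_annotation_table(bundle$annotations,
                                         file.path(directory, "annotations.tsv")),
    controls = write_control_table(bundle$controls,
                                   file.path(directory, "controls.tsv")),
    cnv = write_cnv_table(bundle$cnv, file.path(directory, "cnv.tsv")),
    gene_sets = write_gene_sets(bundle$gene_sets,
                                file.path(directory, "gene_sets.gmt")),
    gene_lengths = write_gene_lengths(bundle$gene_lengths,
                                      file.path(directory, "gene_lengths.tsv"))
  )
  invisible(paths)
}
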
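# Readers and writers for every external format the pipeline touches:
# multi-sample VCF (v4.2), 6-column PED, tab-separated annotation / control /
# CNV / gene-length tables, and GMT gene-set collections. Readers build the
# normalized in-memory model (tibbles keyed by `variant_key`); writers are
# deterministic (fixed column order, sorted rows) so reruns are byte-stable.

annotation_cols <- function() {
  c("variant_key", "gene", "consequence",
    "population_maf", "population_hom_count", "population_alt_allele_count",
    "cadd_phred", predictor_columns(), "phenotype_rank", "splice_damaging")
}

cnv_cols <- function() {
  c("family_id", "sample_id", "chrom", "start", "end",
    "copy_state", "exon_count", "population_frequency")
}

#' Read a PED pedigree file
#'
#' Standard 6-column PED: family, individual, father, mother, sex
#' (1 = male, 2 = female, 0 = unknown), affection (1 = unaffected,
#' 2 = affected). `0` in the parent columns means "not in the pedigree".
#'
#' @param path Path to a whitespace-separated PED file without header.
#' @return A tibble with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`, `affected`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family_id", "sample_id", "father_id",
                                         "mother_id", "sex", "affected"))
  ped <- as_tibble(ped)
  if (anyDuplicated(ped$sample_id)) {
    abort("duplicate sample ids in pedigree; sample ids must be unique across the cohort")
  }
  ped$sex <- as.integer(ped$sex)
  ped$affected <- as.integer(ped$affected)
  if (!all(ped$affected %in% c(1L, 2L))) {
    abort("PED affection column must be coded 1 (unaffected) / 2 (affected)")
  }
  ped
}

#' Group a pedigree into analyzable family cohorts
#'
#' Only affected individuals (affection status 2) enter a family's analysis
#' set; families with fewer than two affected members are dropped with a
#' warning, since shared-variant analysis is undefined for singletons.
#'
#' @param pedigree Tibble as returned by [read_pedigree()].
#' @param min_affected Minimum affected members per family (default 2).
#' @return A tibble with one row per retained family: `family_id`,
#'   `affected_samples` (list column), `n_affected`.
#' @export
family_cohorts <- function(pedigree, min_affected = 2L) {
  assert_columns(pedigree, c("family_id", "sample_id", "affected"), "pedigree")
  cohorts <- pedigree |>
    filter(.data$affected == 2L) |>
    summarise(affected_samples = list(.data$sample_id),
              n_affected = dplyr::n(), .by = "family_id")
  small <- cohorts$family_id[cohorts$n_affected < min_affected]
  if (length(small) > 0) {
    warn(sprintf("excluding %d family(ies) with < %d affected members: %s",
                 length(small), min_affected, paste(small, collapse = ", ")))
    cohorts <- filter(cohorts, !.data$family_id %in% small)
  }
  cohorts
}

#' Read a jointly called multi-sample VCF for one family
#'
#' Parses a VCF v4.2 file (FORMAT fields GT:AD:DP:GQ), splits multi-allelic
#' sites into one record per alternate allele, left-aligns/parsimonizes the
#' allele pair, and returns one row per (variant, affected sample). Genotypes
#' are re-expressed against the single alternate allele of the record: other
#' alternate alleles at the same site count as reference.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param family Either a one-row tibble from [family_cohorts()] or a
#'   character vector of affected sample ids.
#' @param family_id Family label; taken from `family` when it is a tibble.
#' @return A call-level tibble with columns `family_id`, `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_key`, `gt`, `dp`, `ad_ref`,
#'   `ad_alt`, `gq`, `site_qual`.
#' @export
read_family_vcf <- function(path, family, family_id = NULL) {
  if (is.data.frame(family)) {
    family_id <- family$family_id[[1]]
    samples <- family$affected_samples[[1]]
  } else {
    samples <- as.character(family)
    family_id <- family_id %||% NA_character_
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-site VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_calls(family_id))
  }
  vcf_samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(samples, vcf_samples)
  if (length(missing) > 0) {
    abort(sprintf("manifest mismatch: sample(s) %s not present in %s",
                  paste(missing, collapse = ", "), path))
  }
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  ad_mat <- vcfR::extract.gt(vcf, element = "AD")
  dp_mat <- vcfR::extract.gt(vcf, element = "DP")
  gq_mat <- vcfR::extract.gt(vcf, element = "GQ")

  site <- tibble(
    chrom = normalize_chrom(fix$CHROM),
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    site_qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  gt_mat <- gt_mat[, samples, drop = FALSE]
  dp_vec <- suppressWarnings(as.integer(dp_mat[, samples, drop = FALSE]))
  gq_vec <- suppressWarnings(as.integer(gq_mat[, samples, drop = FALSE]))
  ad_split <- strsplit(ifelse(is.na(ad_mat[, samples, drop = FALSE]), "",
                              ad_mat[, samples, drop = FALSE]),
                       ",", fixed = TRUE)
  ad_field <- function(x, j) {
    v <- map_chr(x, function(a) if (length(a) < j || a[j] == "" ||
                                      a[j] == ".") NA else a[j])
    suppressWarnings(as.integer(v))
  }
  alt_list <- strsplit(site$alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  ns <- length(samples)
  blocks <- vector("list", max(n_alt))
  for (k in seq_len(max(n_alt))) {
    idx <- which(n_alt >= k)
    if (length(idx) == 0) next
    alts_k <- map_chr(alt_list[idx], k)
    norm <- normalize_alleles(site$pos[idx], site$ref[idx], alts_k)
    cell <- as.vector(outer(idx, (seq_len(ns) - 1L) * nrow(site), `+`))
    gts <- gt_mat[idx, , drop = FALSE]
    dosage <- if (all(nchar(gts) == 3L | is.na(gts))) {
      kc <- as.character(k)
      a1 <- substr(gts, 1, 1)
      a2 <- substr(gts, 3, 3)
      ifelse(a1 == "." | a2 == "." | is.na(gts), NA_integer_,
             (a1 == kc) + (a2 == kc))
    } else {
      matrix(alt_dosage_from_gt(as.vector(gts), k), nrow = length(idx))
    }
    blocks[[k]] <- tibble(
      family_id = family_id,
      sample_id = rep(samples, each = length(idx)),
      chrom = rep(site$chrom[idx], ns),
      pos = rep(norm$pos, ns),
      ref = rep(norm$ref, ns),
      alt = rep(norm$alt, ns),
      variant_key = rep(variant_key(site$chrom[idx], norm$pos,
                                    norm$ref, norm$alt), ns),
      gt = dosage_gt(as.integer(dosage)),
      dp = dp_vec[cell],
      ad_ref = ad_field(ad_split[cell], 1L),
      ad_alt = ad_field(ad_split[cell], k + 1L),
      gq = gq_vec[cell],
      site_qual = rep(site$site_qual[idx], ns)
    )
  }
  bind_rows(blocks) |>
    arrange(chrom_order(.data$chrom), .data$pos, .data$ref, .data$alt,
            .data$sample_id)
}

# genotype string -> dosage of alternate allele k (other alts count as ref)
alt_dosage_from_gt <- function(gt, k) {
  alleles <- strsplit(ifelse(is.na(gt), ".", gt), "[/|]")
  map_int(alleles, function(a) {
    if (any(a == ".") || length(a) == 0) return(NA_integer_)
    sum(a == as.character(k))
  })
}

empty_calls <- function(family_id = character(0)) {
  tibble(family_id = character(0), sample_id = character(0),
         chrom = character(0), pos = integer(0), ref = character(0),
         alt = character(0), variant_key = character(0), gt = character(0),
         dp = integer(0), ad_ref = integer(0), ad_alt = integer(0),
         gq = integer(0), site_qual = numeric(0))
}

#' Read the variant annotation table
#'
#' Tab-separated, one row per variant key, with the documented header:
#' `variant_key`, `gene`, `consequence`, `population_maf`,
#' `population_hom_count`, `population_alt_allele_count`, `cadd_phred`, the
#' six predictor columns (`sift`, `polyphen`, `mut_taster`, `mut_assessor`,
#' `fathmm_pred`, `fathmm_mkl`; values `damaging` / `benign` / `NA`),
#' `phenotype_rank`, `splice_damaging`. Unknown columns and duplicate keys
#' are rejected.
#'
#' @param path Path to the TSV file.
#' @return A tibble keyed by `variant_key`.
#' @export
read_annotation_table <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  unknown <- setdiff(names(ann), annotation_cols())
  if (length(unknown) > 0) {
    abort(sprintf("unknown annotation column(s): %s", paste(unknown, collapse = ", ")))
  }
  assert_columns(ann, annotation_cols(), "annotation table")
  if (anyDuplicated(ann$variant_key)) {
    dup <- ann$variant_key[duplicated(ann$variant_key)][1]
    abort(sprintf("duplicate variant key in annotation table: %s", dup))
  }
  bad <- setdiff(unique(ann$consequence), consequence_levels())
  if (length(bad) > 0) {
    abort(sprintf("unrecognised consequence label(s): %s", paste(bad, collapse = ", ")))
  }
  mutate(ann,
         population_hom_count = as.integer(.data$population_hom_count),
         population_alt_allele_count = as.integer(.data$population_alt_allele_count),
         splice_damaging = as.logical(.data$splice_damaging))
}

#' Read the control-cohort allele frequency table
#'
#' Accepts either counts (`allele_count`) or frequencies (`allele_freq`,
#' reconstructed as `round(freq * allele_total)` since the exact test needs
#' counts). The control cohort size in diploid individuals is taken as
#' `max(allele_total) / 2`.
#'
#' @param path Path to a TSV with columns `variant_key`,
#'   `allele_count` or `allele_freq`, and `allele_total`.
#' @return A tibble with `variant_key`, `control_ac`, `control_an`, plus a
#'   `cohort_size` attribute.
#' @export
read_control_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tab, c("variant_key", "allele_total"), "control table")
  if (anyDuplicated(tab$variant_key)) {
    abort("duplicate variant key in control table")
  }
  if ("allele_count" %in% names(tab)) {
    ac <- as.integer(tab$allele_count)
  } else if ("allele_freq" %in% names(tab)) {
    ac <- as.integer(round(tab$allele_freq * tab$allele_total))
  } else {
    abort("control table needs an `allele_count` or `allele_freq` column")
  }
  an <- as.integer(tab$allele_total)
  if (any(ac > an)) abort("control allele_count exceeds allele_total")
  out <- tibble(variant_key = tab$variant_key, control_ac = ac, control_an = an)
  attr(out, "cohort_size") <- as.integer(max(an) / 2)
  out
}

#' Read a CNV call table
#'
#' @param path TSV with columns `family_id`, `sample_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `copy_state` (`loss`/`gain`), `exon_count`,
#'   `population_frequency`.
#' @return A tibble of CNV calls.
#' @export
read_cnv_table <- function(path) {
  cnv <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(cnv, cnv_cols(), "CNV table")
  if (nrow(cnv) > 0) {
    if (any(cnv$start > cnv$end)) abort("CNV with start > end")
    if (!all(cnv$copy_state %in% c("loss", "gain"))) {
      abort("copy_state must be 'loss' or 'gain'")
    }
  }
  mutate(cnv, chrom = normalize_chrom(.data$chrom),
         start = as.integer(.data$start), end = as.integer(.data$end),
         exon_count = as.integer(.data$exon_count))
}

#' Read a GMT gene-set collection
#'
#' GMT dialect: one term per line, tab-separated
#' `term <TAB> category <TAB> gene1 <TAB> gene2 ...`. The description field
#' carries the category label (e.g. "biological process") used for
#' per-category FDR adjustment.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `term`, `category`, `genes` (list column),
#'   `n_genes`.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d: a term needs >= 1 gene", bad[1]))
  }
  tibble(
    term = map_chr(parts, 1),
    category = map_chr(parts, 2),
    genes = map(parts, ~ unique(.x[-(1:2)])),
  ) |>
    mutate(n_genes = lengths(.data$genes))
}

#' Read a gene-length table
#'
#' Lengths are the summed 5' UTR, 3' UTR and coding-sequence lengths per
#' gene, used by the gene-length confounder check.
#'
#' @param path TSV with columns `gene`, `length_bp`.
#' @return A tibble.
#' @export
read_gene_lengths <- function(path) {
  gl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(gl, c("gene", "length_bp"), "gene length table")
  mutate(gl, length_bp = as.integer(.data$length_bp))
}

# ---- writers -----------------------------------------------------------

#' Write a pedigree to PED format
#' @param pedigree Tibble as from [read_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  df <- pedigree[, c("family_id", "sample_id", "father_id", "mother_id",
                     "sex", "affected")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write one family's calls as a multi-sample VCF v4.2
#'
#' Sites are emitted one alternate allele per line (the model is already
#' split), sorted by chromosome and position, with FORMAT `GT:AD:DP:GQ`.
#'
#' @param calls Call-level tibble for one family.
#' @param path Output path.
#' @param samples Sample column order; defaults to sorted unique sample ids.
#' @return `path`, invisibly.
#' @export
write_family_vcf <- function(calls, path, samples = NULL) {
  samples <- samples %||% sort(unique(calls$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (nrow(calls) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  fmt <- calls |>
    mutate(cell = sprintf("%s:%s,%s:%s:%s", .data$gt,
                          ifelse(is.na(.data$ad_ref), ".", .data$ad_ref),
                          ifelse(is.na(.data$ad_alt), ".", .data$ad_alt),
                          ifelse(is.na(.data$dp), ".", .data$dp),
                          ifelse(is.na(.data$gq), ".", .data$gq)))
  wide <- fmt |>
    select("variant_key", "chrom", "pos", "ref", "alt", "site_qual",
           "sample_id", "cell") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cell")
  for (s in setdiff(samples, names(wide))) wide[[s]] <- NA_character_
  for (s in samples) wide[[s]][is.na(wide[[s]])] <- "0/0:.,.:.:."
  wide <- arrange(wide, chrom_order(.data$chrom), .data$pos, .data$ref, .data$alt)
  body <- paste(wide$chrom, wide$pos, ".", wide$ref, wide$alt,
                ifelse(is.na(wide$site_qual), ".",
                       format(wide$site_qual, trim = TRUE, scientific = FALSE)),
                "PASS", ".", "GT:AD:DP:GQ", sep = "\t")
  for (s in samples) body <- paste(body, wide[[s]], sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

chrom_order <- function(chrom) {
  n <- suppressWarnings(as.integer(chrom))
  n[is.na(n)] <- match(chrom[is.na(n)], c("X", "Y", "MT")) + 100L
  n
}

#' Write the annotation table
#' @param annotations Tibble with the documented annotation columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  annotations |>
    select(dplyr::all_of(annotation_cols())) |>
    arrange(.data$variant_key) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Write the control-cohort table
#' @param controls Tibble with `variant_key`, `control_ac`, `control_an`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_control_table <- function(controls, path) {
  controls |>
    transmute(variant_key = .data$variant_key,
              allele_count = .data$control_ac,
              allele_total = .data$control_an) |>
    arrange(.data$variant_key) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Write a CNV call table
#' @param cnv Tibble of CNV calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(cnv, path) {
  cnv |>
    select(dplyr::all_of(cnv_cols())) |>
    arrange(.data$family_id, .data$sample_id, chrom_order(.data$chrom), .data$start) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Write a gene-set collection in GMT format
#' @param gene_sets Tibble with `term`, `category`, `genes` list column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- pmap(list(gene_sets$term, gene_sets$category, gene_sets$genes),
                function(t, c, g) paste(c(t, c, g), collapse = "\t"))
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Write a gene-length table
#' @param gene_lengths Tibble with `gene`, `length_bp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_lengths <- function(gene_lengths, path) {
  gene_lengths |>
    arrange(.data$gene) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Write a named list of result tables as TSV files
#'
#' Each element is written to `<directory>/<name>.tsv` with deterministic
#' column order (as given) and the rows in their current order. List
#' columns are flattened to comma-separated strings.
#'
#' @param tables Named list of data frames.
#' @param directory Output directory (created if absent).
#' @return Named character vector of paths, invisibly.
#' @export
write_results <- function(tables, directory) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- imap(tables, function(tab, name) {
    flat <- mutate(as_tibble(tab), dplyr::across(
      dplyr::where(is.list), ~ map_chr(.x, paste, collapse = ",")))
    p <- file.path(directory, paste0(name, ".tsv"))
    readr::write_tsv(flat, p, progress = FALSE)
    p
  })
  invisible(unlist(paths))
}
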
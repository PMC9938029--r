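# Cohort-level quality control: Ti/Tv ratio, heterozygosity ratio,
# read-level VAF screening for cross-contamination, KING-robust pairwise
# kinship, and PCA-based population-stratification flagging.

#' Transition/transversion ratio of biallelic SNVs
#'
#' Transitions are A<->G and C<->T substitutions; everything else among
#' single-nucleotide changes is a transversion. Exome call sets typically
#' sit between 2.0 and 3.0; a depressed ratio signals artefactual calls.
#' Indels must be excluded before calling (they are rejected here).
#'
#' @param ref,alt Single-base reference / alternate alleles.
#' @return The ratio (transitions / transversions).
#' @export
titv_ratio <- function(ref, alt) {
  if (!all(is_snv(ref, alt))) {
    abort("titv_ratio() expects biallelic SNVs only (single A/C/G/T alleles)")
  }
  ti <- sum(is_transition(ref, alt))
  tv <- length(ref) - ti
  if (tv == 0) {
    abort("Ti/Tv undefined: no transversions in input")
  }
  ti / tv
}

#' Heterozygote / homozygote ratio for one sample
#'
#' Computed over biallelic SNVs only: indels and multi-allelic sites
#' (more than one alternate allele at a chrom:pos) are excluded inside the
#' operation, mirroring the usual removal of low-quality classes before
#' this metric. The ratio is het calls / hom-alt calls.
#'
#' @param sample_calls Tibble of one sample's calls with columns `chrom`,
#'   `pos`, `ref`, `alt`, `gt`.
#' @return The het/hom ratio.
#' @export
het_hom_ratio <- function(sample_calls) {
  assert_columns(sample_calls, c("chrom", "pos", "ref", "alt", "gt"),
                 "sample_calls")
  x <- filter(sample_calls, is_snv(.data$ref, .data$alt))
  site <- paste(x$chrom, x$pos)
  multi <- site %in% site[duplicated(site)]
  x <- x[!multi, , drop = FALSE]
  dos <- gt_dosage(x$gt)
  n_het <- sum(dos == 1L, na.rm = TRUE)
  n_hom <- sum(dos == 2L, na.rm = TRUE)
  if (n_hom == 0) {
    abort("het/hom ratio undefined: no homozygous-alternate SNV calls")
  }
  n_het / n_hom
}

#' Screen one sample's read-level VAF distribution for contamination
#'
#' At heterozygous calls the alternate-read fraction should concentrate
#' around 0.5; secondary peaks between the canonical 0, 0.5 and 1 modes
#' suggest the presence of reads from another sample. The flag is raised
#' when the fraction of het calls with VAF in (0.1, 0.35) or (0.65, 0.9)
#' exceeds `flag_threshold`.
#'
#' @param sample_calls Tibble with `gt`, `dp`, `ad_alt` for one sample.
#' @param flag_threshold Fraction of off-centre het VAFs that triggers the
#'   flag (default 0.10).
#' @param n_bins Number of histogram bins over [0, 1].
#' @return A list with `histogram` (tibble `bin_low`, `bin_high`, `count`),
#'   `off_centre_fraction`, and `flag`.
#' @export
vaf_screen <- function(sample_calls, flag_threshold = 0.10, n_bins = 20L) {
  assert_columns(sample_calls, c("gt", "dp", "ad_alt"), "sample_calls")
  het <- filter(sample_calls, .data$gt %in% c("0/1", "1/0"),
                !is.na(.data$dp), .data$dp > 0, !is.na(.data$ad_alt))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  if (nrow(het) == 0) {
    hist <- tibble(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                   count = 0L)
    return(list(histogram = hist, off_centre_fraction = NA_real_, flag = FALSE))
  }
  vaf <- het$ad_alt / het$dp
  counts <- tabulate(pmin(findInterval(vaf, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  hist <- tibble(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                 count = as.integer(counts))
  off <- mean((vaf > 0.1 & vaf < 0.35) | (vaf > 0.65 & vaf < 0.9))
  list(histogram = hist, off_centre_fraction = off,
       flag = off > flag_threshold)
}

king_degree_bins <- function(kinship) {
  dplyr::case_when(
    kinship >= 2^(-3 / 2) / 2 * 2 ~ "duplicate_or_MZ",   # >= 0.3536
    kinship >= 2^(-5 / 2)         ~ "first",             # [0.1768, 0.3536)
    kinship >= 2^(-7 / 2)         ~ "second",            # [0.0884, 0.1768)
    kinship >= 2^(-9 / 2)         ~ "third",             # [0.0442, 0.0884)
    .default = "unrelated"
  )
}

#' KING-robust kinship between two genotype vectors
#'
#' The robust between-family estimator over shared non-missing biallelic
#' SNPs:
#' \deqn{\hat\phi = \frac{N_{het,het} - 2\,N_{opp}}{N_{het}(i) + N_{het}(j)}}
#' where \eqn{N_{opp}} counts opposing homozygotes (IBS0 sites). It is
#' robust to population structure because it only uses within-pair
#' heterozygosity. Expected values: 0.5 duplicates/MZ twins, 0.25
#' first-degree, 0.125 second-degree, 0 unrelated. Degrees are assigned by
#' the standard powers-of-two bins (cut-offs 0.3536 / 0.1768 / 0.0884 /
#' 0.0442).
#'
#' @param genotypes_i,genotypes_j Integer dosage vectors (0/1/2, NA for
#'   missing) over the same SNP panel.
#' @param min_snps Minimum shared non-missing SNPs (default 1000).
#' @return One-row tibble: `kinship`, `ibs0`, `n_snps_used`,
#'   `inferred_degree`.
#' @export
king_kinship <- function(genotypes_i, genotypes_j, min_snps = 1000L) {
  stopifnot(length(genotypes_i) == length(genotypes_j))
  ok <- !is.na(genotypes_i) & !is.na(genotypes_j)
  gi <- genotypes_i[ok]
  gj <- genotypes_j[ok]
  n <- length(gi)
  if (n < min_snps) {
    abort(sprintf("insufficient data: %d shared SNPs < floor of %d", n, min_snps))
  }
  n_het_i <- sum(gi == 1L)
  n_het_j <- sum(gj == 1L)
  n_hethet <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  if (n_het_i + n_het_j == 0) {
    abort("insufficient data: no heterozygous calls in either sample")
  }
  kin <- (n_hethet - 2 * n_opp) / (n_het_i + n_het_j)
  tibble(kinship = kin, ibs0 = n_opp / n, n_snps_used = n,
         inferred_degree = king_degree_bins(kin))
}

#' Pairwise KING-robust kinship over a genotype matrix
#'
#' @param genotypes Integer dosage matrix (samples x SNPs) with sample ids
#'   as row names.
#' @param min_snps Minimum shared non-missing SNPs per pair.
#' @return Tibble with one row per unordered pair: `sample_i`, `sample_j`,
#'   `kinship`, `ibs0`, `n_snps_used`, `inferred_degree`.
#' @export
king_kinship_matrix <- function(genotypes, min_snps = 1000L) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)))
  ids <- rownames(genotypes)
  het <- (genotypes == 1L) * 1
  hom0 <- (genotypes == 0L) * 1
  hom2 <- (genotypes == 2L) * 1
  obs <- (!is.na(genotypes)) * 1
  het[is.na(het)] <- 0; hom0[is.na(hom0)] <- 0; hom2[is.na(hom2)] <- 0
  n_hethet <- het %*% t(het)
  n_opp <- hom0 %*% t(hom2) + hom2 %*% t(hom0)
  n_obs <- obs %*% t(obs)
  # per-pair het counts restricted to mutually observed sites
  het_i <- het %*% t(obs)
  pairs <- which(upper.tri(n_obs), arr.ind = TRUE)
  out <- tibble(
    sample_i = ids[pairs[, 1]],
    sample_j = ids[pairs[, 2]],
    n_snps_used = as.integer(n_obs[pairs]),
    kinship = (n_hethet[pairs] - 2 * n_opp[pairs]) /
      (het_i[pairs] + t(het_i)[pairs]),
    ibs0 = n_opp[pairs] / n_obs[pairs]
  )
  low <- out$n_snps_used < min_snps
  if (any(low)) {
    abort(sprintf("insufficient data: %d pair(s) below the %d-SNP floor",
                  sum(low), min_snps))
  }
  out$inferred_degree <- king_degree_bins(out$kinship)
  out[, c("sample_i", "sample_j", "kinship", "ibs0", "n_snps_used",
          "inferred_degree")]
}

#' Principal-component stratification check on a genotype matrix
#'
#' Variants are filtered to cohort MAF >= `maf_min`, mean-centred and
#' variance-standardized, and decomposed with [stats::prcomp()]. A sample
#' is flagged as a stratification outlier when it lies more than
#' `mad_k` median-absolute-deviations from the cohort median on PC1 or
#' PC2.
#'
#' @param genotypes Integer dosage matrix (samples x SNPs), sample ids as
#'   row names.
#' @param maf_min Minimum cohort MAF for a variant to enter the
#'   decomposition (default 0.05).
#' @param n_components Components to return (default 10).
#' @param mad_k Outlier cut-off in MADs (default 6).
#' @param outlier_components Components screened for outliers (default
#'   PC1 and PC2). In cohorts of relatives the trailing components pick
#'   up family cliques rather than ancestry, so pipelines that exclude
#'   whole families screen PC1 only.
#' @return An `fvp_pca` list: `scores` (tibble `sample_id`, `PC1`..),
#'   `sdev`, `outliers` (character vector of sample ids), `n_variants_used`.
#' @export
genotype_pca <- function(genotypes, maf_min = 0.05, n_components = 10L,
                         mad_k = 6, outlier_components = 1:2) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)))
  if (nrow(genotypes) < 3) abort("PCA needs at least 3 samples")
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- which(!is.na(maf) & maf >= maf_min)
  g <- genotypes[, keep, drop = FALSE]
  g[is.na(g)] <- matrix(rep(colMeans(g, na.rm = TRUE), each = nrow(g)),
                        nrow = nrow(g))[is.na(g)]
  v <- apply(g, 2, stats::var)
  g <- g[, v > 0, drop = FALSE]
  n_comp <- min(n_components, nrow(g) - 1, ncol(g))
  pc <- prcomp(g, center = TRUE, scale. = TRUE, rank. = n_comp)
  scores <- as_tibble(pc$x[, seq_len(n_comp), drop = FALSE]) |>
    mutate(sample_id = rownames(genotypes), .before = 1)
  flag_on <- function(v) {
    s <- mad(v)
    if (s == 0) rep(FALSE, length(v)) else abs(v - median(v)) > mad_k * s
  }
  out_flag <- rep(FALSE, nrow(scores))
  for (comp in intersect(outlier_components, seq_len(n_comp))) {
    out_flag <- out_flag | flag_on(scores[[paste0("PC", comp)]])
  }
  structure(list(scores = scores, sdev = pc$sdev,
                 outliers = scores$sample_id[out_flag],
                 n_variants_used = ncol(g)),
            class = "fvp_pca")
}

#' @export
print.fvp_pca <- function(x, ...) {
  cat(sprintf("<fvp_pca> %d samples x %d variants; %d outlier(s): %s\n",
              nrow(x$scores), x$n_variants_used, length(x$outliers),
              paste(x$outliers, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fvp_pca <- function(x, ...) {
  mutate(x$scores, outlier = .data$sample_id %in% x$outliers)
}

#' Per-sample quality-control report
#'
#' Computes, for each sample in the call table: the Ti/Tv ratio, the
#' het/hom ratio (both over biallelic SNVs), the off-centre VAF fraction
#' and contamination flag. Ratios that are undefined for a sample (no
#' transversions / no hom-alt calls) are reported as `NA` rather than
#' failing the whole cohort.
#'
#' @param calls Call-level tibble (see [read_family_vcf()]).
#' @param flag_threshold Passed to [vaf_screen()].
#' @return A tibble with one row per sample.
#' @export
qc_sample_report <- function(calls, flag_threshold = 0.10) {
  assert_columns(calls, c("sample_id", "chrom", "pos", "ref", "alt", "gt",
                          "dp", "ad_alt"), "calls")
  calls |>
    summarise(
      n_calls = dplyr::n(),
      titv_ratio = tryCatch(
        titv_ratio(.data$ref[is_snv(.data$ref, .data$alt) &
                               gt_dosage(.data$gt) > 0],
                   .data$alt[is_snv(.data$ref, .data$alt) &
                               gt_dosage(.data$gt) > 0]),
        error = function(e) NA_real_),
      het_hom_ratio = tryCatch(het_hom_ratio(pick(dplyr::everything())),
                               error = function(e) NA_real_),
      vaf_off_centre = vaf_screen(pick(dplyr::everything()),
                                  flag_threshold)$off_centre_fraction,
      vaf_flag = vaf_screen(pick(dplyr::everything()), flag_threshold)$flag,
      .by = "sample_id")
}

#' Build a sample-by-variant dosage matrix from a call table
#'
#' Variants are columns (keys), samples rows; a sample without a row for a
#' variant it was genotyped for elsewhere in the cohort is treated as
#' homozygous reference (the joint caller emits reference genotypes for
#' covered sites).
#'
#' @param calls Call-level tibble.
#' @return Integer dosage matrix.
#' @export
dosage_matrix <- function(calls) {
  samples <- sort(unique(calls$sample_id))
  keys <- sort(unique(calls$variant_key))
  m <- matrix(0L, nrow = length(samples), ncol = length(keys),
              dimnames = list(samples, keys))
  dos <- gt_dosage(calls$gt)
  i <- match(calls$sample_id, samples)
  j <- match(calls$variant_key, keys)
  m[cbind(i, j)] <- ifelse(is.na(dos), NA_integer_, dos)
  m
}
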
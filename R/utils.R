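# Shared vocabulary and small helpers used across modules.

#' Consequence classes recognised by the pipeline
#'
#' The pipeline classifies every alternate allele into one of these
#' functional consequence classes (one gene, one canonical transcript per
#' record; transcript choice happens upstream in the annotation source).
#'
#' @return Character vector of the recognised consequence labels.
#' @export
consequence_levels <- function() {
  c("missense", "stop_gain", "frameshift", "splice_canonical",
    "splice_region", "inframe_indel", "synonymous", "other")
}

#' Loss-of-function consequence classes
#'
#' Stop-gain, frameshift and canonical GT-AG splice-site changes.
#' Splice-region variants outside the canonical dinucleotide are *not*
#' counted as LoF; they are handled by the splice-prediction rule instead.
#'
#' @return Character vector.
#' @export
lof_consequences <- function() {
  c("stop_gain", "frameshift", "splice_canonical")
}

#' Column names of the six deleteriousness predictors
#'
#' The ensemble vote counts damaging calls across SIFT, PolyPhen,
#' MutationTaster, MutationAssessor, FATHMM and FATHMM-MKL. Each column is
#' ternary: `"damaging"`, `"benign"`, or `NA` (no call).
#'
#' @return Character vector of six column names.
#' @export
predictor_columns <- function() {
  c("sift", "polyphen", "mut_taster", "mut_assessor",
    "fathmm_pred", "fathmm_mkl")
}

#' Build variant keys from coordinates and alleles
#'
#' A variant key is `chrom:pos:ref:alt` with normalized (left-aligned,
#' parsimonious) alleles and a "chr"-less chromosome label. Keys are the
#' join unit between genotype calls, annotations and control frequencies.
#'
#' @param chrom Chromosome labels (with or without a "chr" prefix).
#' @param pos 1-based positions.
#' @param ref,alt Reference / alternate allele strings.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

#' Normalize chromosome labels to the "chr"-less dialect
#'
#' @param chrom Character vector.
#' @return Character vector without "chr" prefixes.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Left-align and trim an allele pair
#'
#' Removes the common suffix, then the common prefix (keeping at least one
#' base on each side), adjusting the position for trimmed prefix bases.
#' This makes representation of indels parsimonious so that keys from
#' different callers agree. Idempotent.
#'
#' @param pos 1-based positions.
#' @param ref,alt Allele strings (A/C/G/T runs).
#' @return A tibble with columns `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  out_pos <- as.integer(pos)
  out_ref <- as.character(ref)
  out_alt <- as.character(alt)
  # fast path: SNVs and already-parsimonious pairs need no trimming
  todo <- which(nchar(out_ref) > 1L | nchar(out_alt) > 1L)
  for (i in todo) {
    r <- strsplit(out_ref[i], "")[[1]]
    a <- strsplit(out_alt[i], "")[[1]]
    # trim common suffix
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim common prefix, shifting pos
    shift <- 0L
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      shift <- shift + 1L
    }
    out_pos[i] <- out_pos[i] + shift
    out_ref[i] <- paste(r, collapse = "")
    out_alt[i] <- paste(a, collapse = "")
  }
  tibble(pos = out_pos, ref = out_ref, alt = out_alt)
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

# genotype string -> alt allele dosage (NA for missing)
gt_dosage <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

dosage_gt <- function(dosage) {
  out <- rep("./.", length(dosage))
  out[!is.na(dosage) & dosage == 0L] <- "0/0"
  out[!is.na(dosage) & dosage == 1L] <- "0/1"
  out[!is.na(dosage) & dosage == 2L] <- "1/1"
  out
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
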
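#' Worked example: recurrent-variant annotations
#'
#' A five-row table of missense variants recurring in several families of
#' a hip dysplasia exome cohort, with population and control allele
#' frequencies, CADD PHRED scores and the ensemble vote totals, as
#' printed in the study this pipeline reproduces. The per-tool columns
#' expand the published vote totals (`n_damaging_votes`) into individual
#' calls; the attribution to specific tools is synthetic, the totals are
#' not. Applying [classify_table1()] to these rows yields exactly two
#' damaging variants (METTL21B c.620G>A and PPP6R2 c.1421G>A).
#'
#' @return A tibble with one row per recurrent variant.
#' @export
recurrent_variant_examples <- function() {
  path <- system.file("extdata", "recurrent_variants_example.tsv",
                      package = "famvar", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = "NA")
}
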
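# ggplot2 views of the result objects.

#' Per-family shared-variant counts
#'
#' Bar chart of the number of variants surviving a cascade stage in each
#' family (final stage by default).
#'
#' @param cascade An `fvp_cascade` result.
#' @param stage Stage to plot (default the final, `"cross_family"`).
#' @return A ggplot object.
#' @export
plot_family_variant_counts <- function(cascade, stage = "cross_family") {
  df <- filter(cascade$stage_counts, .data$stage == !!stage)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$family_id,
                                                      -.data$n_variants),
                                   y = .data$n_variants)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "family", y = "shared variants",
                  title = sprintf("Shared variants per family (%s stage)",
                                  stage)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' VAF histogram for one sample's contamination screen
#'
#' @param screen Result of [vaf_screen()].
#' @param sample_id Optional label for the title.
#' @return A ggplot object.
#' @export
plot_vaf_histogram <- function(screen, sample_id = NULL) {
  ggplot2::ggplot(screen$histogram,
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 0.045,
                      fill = if (screen$flag) "firebrick" else "grey40") +
    ggplot2::labs(x = "alternate-read fraction at het calls", y = "calls",
                  title = paste0("VAF screen",
                                 if (!is.null(sample_id)) paste0(": ", sample_id),
                                 if (screen$flag) " (flagged)")) +
    ggplot2::theme_minimal()
}

#' Kinship against IBS0 for all sample pairs
#'
#' The classic relatedness diagnostic: duplicates sit near (0, 0.5),
#' parent-offspring near (0, 0.25), unrelated pairs along kinship 0 with
#' appreciable IBS0.
#'
#' @param kinship Tibble from [king_kinship_matrix()].
#' @return A ggplot object.
#' @export
plot_kinship <- function(kinship) {
  ggplot2::ggplot(kinship, ggplot2::aes(x = .data$ibs0, y = .data$kinship,
                                        colour = .data$inferred_degree)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "IBS0 (opposing-homozygote fraction)",
                  y = "KING-robust kinship", colour = "degree") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fvp_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$outlier)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(title = "Genotype PCA stratification check") +
    ggplot2::theme_minimal()
}

#' Most frequently hit genes across families
#'
#' @param burden A [gene_overlap()] table.
#' @param min_families Only genes hit in at least this many families
#'   (default 3).
#' @return A ggplot object.
#' @export
plot_gene_overlap <- function(burden, min_families = 3L) {
  df <- filter(as_tibble(burden), .data$n_families >= min_families)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene,
                                                      .data$n_families),
                                   y = .data$n_families)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "families with shared variants") +
    ggplot2::theme_minimal()
}

#' Phenotype-rank distribution of damaging variants by family
#'
#' Box plot of phenotype-rank scores per family with the decision
#' threshold drawn in red; genes above the line are the phenotype-linked
#' candidates.
#'
#' @param variants Classified variant tibble (needs `family_id`,
#'   `phenotype_rank`).
#' @param threshold Threshold line (default 0.75).
#' @return A ggplot object.
#' @export
plot_phenotype_rank <- function(variants, threshold = 0.75) {
  ggplot2::ggplot(variants, ggplot2::aes(x = .data$family_id,
                                         y = .data$phenotype_rank)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, colour = "red") +
    ggplot2::labs(x = "family", y = "phenotype rank") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Term-enrichment strength for significant terms
#'
#' @param terms An [enrichment_report()] table.
#' @param significant_only Plot only FDR-significant terms (default
#'   TRUE).
#' @return A ggplot object.
#' @export
plot_enrichment_strength <- function(terms, significant_only = TRUE) {
  df <- as_tibble(terms)
  if (significant_only) df <- filter(df, .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strength,
                                   y = stats::reorder(.data$term,
                                                      .data$strength),
                                   size = .data$observed,
                                   colour = -log10(.data$fdr))) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "strength, log10(observed/expected)", y = NULL,
                  colour = "-log10 FDR", size = "genes") +
    ggplot2::theme_minimal()
}
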
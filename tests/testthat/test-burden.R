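# Cross-family aggregation: gene overlap counting, the overlap histogram,
# recurrent variants, the gene-length confounder check, CNV screening.

test_that("gene overlap counts families once and variants per occurrence", {
  sets <- dplyr::bind_rows(
    # 9 families hit one gene; one of them carries two distinct variants
    tibble::tibble(family_id = sprintf("F%02d", 1:9),
                   variant_key = paste0("kv", 1:9), gene = "TTN_LIKE"),
    tibble::tibble(family_id = "F01", variant_key = "kv10",
                   gene = "TTN_LIKE"),
    # an identical variant fully shared in two families: 2 occurrences
    tibble::tibble(family_id = c("F03", "F04"), variant_key = "kv_rec",
                   gene = "REC_GENE"),
    tibble::tibble(family_id = "F05", variant_key = "kv_solo",
                   gene = "SOLO_GENE"))
  burden <- gene_overlap(sets)
  ttn <- burden[burden$gene == "TTN_LIKE", ]
  expect_identical(ttn$n_families, 9L)
  expect_identical(ttn$n_variants, 10L)
  rec <- burden[burden$gene == "REC_GENE", ]
  expect_identical(c(rec$n_families, rec$n_variants), c(2L, 2L))
  # single-family gene stays in the full table, not in the histogram
  expect_true("SOLO_GENE" %in% burden$gene)
  hist <- overlap_histogram(burden)
  expect_false(any(hist$n_families == 1))
  expect_identical(attr(hist, "total_multi_family_genes"), 2L)
  # sum of per-gene variant occurrences equals the input occurrence count
  expect_identical(sum(burden$n_variants),
                   nrow(dplyr::distinct(sets, family_id, variant_key, gene)))
})

test_that("gene overlap is invariant to family processing order", {
  b <- small_cohort()
  casc <- run_family_cascade(b$calls, b$cohorts, b$annotations)
  v <- casc$variants
  a <- gene_overlap(v)
  b2 <- gene_overlap(v[rev(seq_len(nrow(v))), ])
  expect_identical(dplyr::arrange(as_tibble(a), gene),
                   dplyr::arrange(as_tibble(b2), gene))
})

test_that("the histogram total reproduces the published level counts", {
  levels <- tibble::tibble(
    n_families = c(9L, 5L, 4L, 3L, 2L),
    n_genes = c(1L, 4L, 11L, 40L, 266L))
  burden <- tibble::tibble(
    gene = paste0("G", seq_len(sum(levels$n_genes) + 100)),
    n_families = c(rep(levels$n_families, levels$n_genes), rep(1L, 100)))
  hist <- overlap_histogram(burden)
  expect_identical(attr(hist, "total_multi_family_genes"), 322L)
  expect_identical(glance(hist)$total_multi_family_genes, 322L)
  expect_identical(hist$n_genes, levels$n_genes)
  # definitional invariance
  expect_identical(sum(hist$n_genes), attr(hist, "total_multi_family_genes"))
})

test_that("all-single-family burdens give an empty histogram with total 0", {
  burden <- tibble::tibble(gene = c("A", "B"), n_families = c(1L, 1L))
  hist <- overlap_histogram(burden)
  expect_identical(nrow(hist), 0L)
  expect_identical(attr(hist, "total_multi_family_genes"), 0L)
})

test_that("recurrent variants are exact-key matches in two or more families", {
  sets <- dplyr::bind_rows(
    mk_ann("1:5:A:G", gene = "GA", cadd = 24.1, votes = 4L) |>
      dplyr::mutate(family_id = "F01"),
    mk_ann("1:5:A:G", gene = "GA", cadd = 24.1, votes = 4L) |>
      dplyr::mutate(family_id = "F07"),
    mk_ann("1:6:C:T", gene = "GB") |> dplyr::mutate(family_id = "F02"))
  controls <- tibble::tibble(variant_key = "1:5:A:G", control_ac = 20L,
                             control_an = 4000L)
  rec <- recurrent_variants(sets, controls)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$n_families, 2L)
  expect_identical(rec$family_ids[[1]], c("F01", "F07"))
  expect_identical(rec$control_af, 0.005)
  expect_true(rec$table_damaging)
  none <- recurrent_variants(sets[3, ])
  expect_identical(nrow(none), 0L)
})

test_that("the five-row worked example yields five recurrent variants", {
  ex <- recurrent_variant_examples()
  sets <- ex |>
    dplyr::mutate(variant_key = paste(gene, variant)) |>
    tidyr::separate_rows(families, sep = ",") |>
    dplyr::rename(family_id = families)
  rec <- recurrent_variants(sets)
  expect_identical(nrow(rec), 5L)
  expect_setequal(rec$n_families, c(4L, 3L, 3L, 3L, 3L))
  expect_identical(sum(rec$table_damaging), 2L)
})

test_that("Pearson correlation matches the closed form and detects perfection", {
  burden3 <- tibble::tibble(gene = c("A", "B", "C"),
                            n_variants = 1:3, n_families = c(3L, 2L, 1L))
  lengths3 <- tibble::tibble(gene = c("A", "B", "C"), length_bp = 1:3)
  res <- gene_length_correlation(burden3, lengths3)
  expect_equal(res$r[res$target == "n_variants"], 1)
  # hand-computed 4-point fixture via the textbook formula
  x <- c(1200, 3400, 560, 9100)
  yv <- c(2L, 5L, 1L, 9L)
  yf <- c(1L, 3L, 1L, 6L)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  burden4 <- tibble::tibble(gene = letters[1:4], n_variants = yv,
                            n_families = yf)
  lengths4 <- tibble::tibble(gene = letters[1:4], length_bp = x)
  res4 <- gene_length_correlation(burden4, lengths4)
  expect_equal(res4$r[res4$target == "n_variants"], pearson(x, yv),
               tolerance = 1e-12)
  expect_equal(res4$r[res4$target == "n_families"], pearson(x, yf),
               tolerance = 1e-12)
  expect_error(gene_length_correlation(burden3[1:2, ], lengths3), ">= 3")
})

test_that("counts independent of length give near-zero correlation", {
  withr::with_seed(23, {
    burden <- tibble::tibble(gene = paste0("G", 1:500),
                             n_variants = rpois(500, 2) + 1L,
                             n_families = rpois(500, 1) + 1L)
    lengths <- tibble::tibble(gene = paste0("G", 1:500),
                              length_bp = round(stats::rlnorm(500, 8, 1)))
  })
  res <- gene_length_correlation(burden, lengths)
  expect_true(all(abs(res$r) < 2.58 / sqrt(500) * 1.5))
})

test_that("CNV screening applies its boundaries and finds recurrences", {
  cohorts <- mk_cohorts(list(FA = c("A1", "A2"), FB = c("B1", "B2"),
                             FC = c("C1", "C2")))
  mk_cnv <- function(fid, sid, start = 100L, end = 200L, state = "gain",
                     exons = 4L, freq = 0.01, chrom = "19") {
    tibble::tibble(family_id = fid, sample_id = sid, chrom = chrom,
                   start = start, end = end, copy_state = state,
                   exon_count = exons, population_frequency = freq)
  }
  calls <- dplyr::bind_rows(
    mk_cnv("FA", "A1"), mk_cnv("FA", "A2", start = 110L, end = 210L),
    mk_cnv("FB", "B1"), mk_cnv("FB", "B2"),      # recurrent with FA
    mk_cnv("FC", "C1", chrom = "2"),             # only one member
    mk_cnv("FC", "C1", chrom = "3", exons = 3L), # too few exons
    mk_cnv("FC", "C2", chrom = "3", exons = 3L),
    mk_cnv("FC", "C1", chrom = "4", freq = 0.05),
    mk_cnv("FC", "C2", chrom = "4", freq = 0.05))
  out <- cnv_screen(calls, cohorts)
  expect_setequal(out$family_id, c("FA", "FB"))
  expect_true(all(out$recurrent))
  # boundary case: exon_count 4 and frequency 0.01 passed (inclusive)
  expect_true(all(out$exon_count >= 4))
})

test_that("the simulator's planted CNVs are screened as designed", {
  b <- small_cohort()
  out <- cnv_screen(b$cnv, b$cohorts, gene_map = b$cnv_gene_map)
  expect_setequal(out$family_id, b$truth$cnv$retained_families)
  rec <- out[out$recurrent, ]
  expect_setequal(rec$family_id, b$truth$cnv$recurrent_families)
  expect_true(all(rec$gene == b$truth$cnv$recurrent_gene))
})
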
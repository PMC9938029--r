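# Deleteriousness classification: ensemble voting, the allele-count
# ceiling, both damaging rules (including the published recurrent-variant
# worked example), and the phenotype-rank threshold.

test_that("predictor voting counts damaging calls, missing as not damaging", {
  expect_identical(predictor_vote(c(rep("damaging", 4), "benign", "benign")),
                   4L)
  expect_identical(predictor_vote(rep("damaging", 6)), 6L)
  expect_identical(predictor_vote(rep(NA_character_, 6)), 0L)
  df <- dplyr::bind_rows(mk_ann("k1", votes = 5L), mk_ann("k2", votes = NA))
  expect_identical(predictor_vote(df), c(5L, 0L))
})

test_that("the dominant-model ceiling is linear in its inputs", {
  expect_identical(expected_allele_ceiling(0, 251496L), 0L)
  base <- expected_allele_ceiling(1 / 3400, 251496L)
  expect_identical(base, 74L)  # round(251496 / 3400)
  expect_identical(expected_allele_ceiling(1 / 3400, 2L * 251496L),
                   2L * base)
  # the shipped rule pins the published 590 instead of deriving it
  expect_identical(damaging_rules()$max_alt_allele_count, 590L)
})

test_that("the strict rule combines the ceiling with LoF / CADD / votes", {
  # high CADD but votes only 4, missense, low AC: fails the strict rule
  v <- mk_ann("k1", cadd = 24.1, votes = 4L, ac = 200L)
  expect_false(classify_strict(v))
  # LoF branch
  expect_true(classify_strict(mk_ann("k2", consequence = "frameshift",
                                     cadd = 5, votes = 0L, ac = 10L)))
  # ceiling kills an otherwise-damaging variant
  expect_false(classify_strict(mk_ann("k3", cadd = 26, votes = 6L,
                                      ac = 600L)))
  # boundary: CADD exactly 25 is not "over 25"; votes >= 5 rescues
  expect_false(classify_strict(mk_ann("k4", cadd = 25, votes = 4L)))
  expect_true(classify_strict(mk_ann("k5", cadd = 25, votes = 5L)))
  # splice_region is not LoF
  expect_false(classify_strict(mk_ann("k6", consequence = "splice_region",
                                      cadd = 5, votes = 0L)))
})

test_that("the strict rule is monotone in CADD and votes", {
  withr::with_seed(14, {
    base <- purrr::map(1:100, function(i) {
      mk_ann(paste0("k", i),
             consequence = sample(consequence_levels(), 1),
             cadd = runif(1, 0, 40), votes = sample(0:6, 1),
             ac = sample(0:1000, 1))
    }) |> dplyr::bind_rows()
  })
  before <- classify_strict(base)
  more_cadd <- dplyr::mutate(base, cadd_phred = cadd_phred + 5)
  expect_false(any(before & !classify_strict(more_cadd)))
  more_votes <- base
  more_votes$sift <- "damaging"
  more_votes$fathmm_mkl <- "damaging"
  expect_false(any(before & !classify_strict(more_votes)))
})

test_that("strict damaging always implies the allele ceiling", {
  withr::with_seed(15, {
    v <- purrr::map(1:200, function(i) {
      mk_ann(paste0("k", i),
             consequence = sample(consequence_levels(), 1),
             cadd = runif(1, 0, 40), votes = sample(0:6, 1),
             ac = sample(0:1200, 1))
    }) |> dplyr::bind_rows()
  })
  cl <- classify_variants(v)
  expect_false(any(cl$strict_damaging & !cl$passes_allele_ceiling))
})

test_that("both rules agree on non-LoF variants with CADD > 25 and 5+ votes", {
  v <- dplyr::bind_rows(
    mk_ann("k1", cadd = 27, votes = 5L, ac = 10L),
    mk_ann("k2", cadd = 31.5, votes = 6L, ac = 100L))
  cl <- classify_variants(v)
  expect_true(all(cl$strict_damaging == cl$table_damaging))
})

test_that("the recurrent-variant rule reproduces the published worked example", {
  ex <- recurrent_variant_examples()
  expect_identical(nrow(ex), 5L)
  damaging <- classify_table1(ex)
  expect_identical(sum(damaging), 2L)
  expect_setequal(paste(ex$gene, ex$variant)[damaging],
                  c("METTL21B c.620G>A", "PPP6R2 c.1421G>A"))
  # the vote totals in the fixture match the expanded predictor columns
  expect_identical(predictor_vote(ex),
                   as.integer(tidyr::replace_na(ex$n_damaging_votes, 0)))
})

test_that("missing CADD is treated as zero, with a message", {
  v <- mk_ann("k1", cadd = NA, votes = 6L, ac = 10L)
  expect_message(cl <- classify_variants(v), "missing CADD")
  expect_true(cl$strict_damaging)    # votes branch still applies
  expect_false(cl$table_damaging)    # CADD 0 fails the conjunction
})

test_that("phenotype-rank threshold is strict and missing ranks are dropped", {
  v <- dplyr::bind_rows(
    mk_ann("k1", rank = 0.76), mk_ann("k2", rank = 0.75),
    mk_ann("k3", rank = NA))
  expect_message(kept <- phenotype_rank_filter(v), "missing phenotype rank")
  expect_identical(kept$variant_key, "k1")
  expect_identical(nrow(phenotype_rank_filter(v[0, ])), 0L)
})

test_that("an engineered 722-variant set yields exactly its 37 high-rank variants", {
  withr::with_seed(16, {
    ranks <- c(runif(685, 0, 0.75), runif(37, 0.7501, 1))
    v <- tibble::tibble(variant_key = paste0("k", 1:722),
                        phenotype_rank = sample(ranks))
  })
  expect_identical(nrow(phenotype_rank_filter(v)), 37L)
})
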
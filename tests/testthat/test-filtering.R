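# Filtering cascade: stage rules at their boundaries, cross-family
# exclusion, monotone shrinkage, and planted-truth recovery.

two_fam <- mk_cohorts(list(FA = c("A1", "A2"), FB = c("B1", "B2", "B3")))

test_that("quality filter applies inclusive boundaries per carrier call", {
  calls <- dplyr::bind_rows(
    mk_call("FA", "A1", dp = 40L, ad_alt = 10L),              # VAF 0.25 in
    mk_call("FA", "A2", dp = 40L, ad_alt = 30L))
  expect_identical(nrow(quality_filter(calls)), 2L)
  low_vaf <- dplyr::bind_rows(
    mk_call("FA", "A1", dp = 20L, ad_alt = 4L),               # VAF 0.2
    mk_call("FA", "A2", dp = 40L, ad_alt = 20L))
  expect_identical(nrow(quality_filter(low_vaf)), 0L)  # one bad call kills the record
  low_dp <- mk_call("FA", "A1", dp = 19L, ad_alt = 10L)
  expect_identical(nrow(quality_filter(low_dp)), 0L)
  low_q <- mk_call("FA", "A1", qual = 19)
  expect_identical(nrow(quality_filter(low_q)), 0L)
  low_gq <- mk_call("FA", "A1", gq = 19L)
  expect_identical(nrow(quality_filter(low_gq)), 0L)
})

test_that("a carrier call without depth is an explicit error; reference calls are not", {
  bad <- mk_call("FA", "A1")
  bad$dp <- NA_integer_
  expect_error(quality_filter(bad), "1:100:A:G.*FA/A1")
  ref <- mk_call("FA", "A1", gt = "0/0")
  ref$dp <- NA_integer_
  expect_identical(nrow(quality_filter(ref)), 1L)
})

test_that("sharing requires a non-reference genotype in every affected member", {
  duo <- dplyr::bind_rows(
    mk_call("FA", "A1"), mk_call("FA", "A2", gt = "1/1"))
  expect_identical(nrow(sharing_filter(duo, two_fam)), 2L)
  trio <- dplyr::bind_rows(
    mk_call("FB", "B1"), mk_call("FB", "B2"),
    mk_call("FB", "B3", gt = "0/0"))
  expect_identical(nrow(sharing_filter(trio, two_fam)), 0L)
  missing <- dplyr::bind_rows(
    mk_call("FA", "A1"), mk_call("FA", "A2", gt = "./."))
  expect_identical(nrow(sharing_filter(missing, two_fam)), 0L)
})

test_that("larger families share fewer variants at identical background rates", {
  withr::with_seed(40, {
    maf <- rep(0.2, 3000)
    duo_shared <- trio_shared <- numeric(20)
    for (i in 1:20) {
      d <- matrix(rbinom(2 * 3000, 2, maf), nrow = 2)
      t_ <- matrix(rbinom(3 * 3000, 2, maf), nrow = 3)
      duo_shared[i] <- sum(colSums(d > 0) == 2)
      trio_shared[i] <- sum(colSums(t_ > 0) == 3)
    }
  })
  expect_gt(mean(duo_shared), mean(trio_shared))
})

test_that("rarity filter boundaries: MAF <= 0.01, homozygotes < 5, novel passes", {
  v <- dplyr::bind_rows(
    mk_ann("k1", maf = 0.01, hom = 4L),
    mk_ann("k2", maf = 0.0005, hom = 5L),
    mk_ann("k3", maf = NA, hom = NA),
    mk_ann("k4", maf = 0.0018, hom = 0L),   # worked-example frequency
    mk_ann("k5", maf = 0.011, hom = 0L))
  kept <- rarity_filter(v)
  expect_setequal(kept$variant_key, c("k1", "k3", "k4"))
})

test_that("splice rules: canonical exempt, region needs a damaging prediction", {
  v <- dplyr::bind_rows(
    mk_ann("k1", consequence = "splice_canonical", splice = FALSE),
    mk_ann("k2", consequence = "splice_region", splice = FALSE),
    mk_ann("k3", consequence = "splice_region", splice = TRUE),
    mk_ann("k4", consequence = "splice_region", splice = NA),
    mk_ann("k5", consequence = "synonymous"),
    mk_ann("k6", consequence = "missense"))
  expect_message(kept <- splice_filter(v), "splice prediction")
  expect_setequal(kept$variant_key, c("k1", "k3", "k6"))
})

test_that("cross-family exclusion removes partially shared variants globally", {
  # shared in FA, absent elsewhere -> retained
  # shared in FA, 1/3 members of FB -> removed everywhere
  # fully shared in FA and FB -> retained in both
  raw <- dplyr::bind_rows(
    mk_call("FA", "A1", key = "1:1:A:G"), mk_call("FA", "A2", key = "1:1:A:G"),
    mk_call("FA", "A1", key = "1:2:A:G"), mk_call("FA", "A2", key = "1:2:A:G"),
    mk_call("FB", "B1", key = "1:2:A:G"),
    mk_call("FB", "B2", key = "1:2:A:G", gt = "0/0"),
    mk_call("FB", "B3", key = "1:2:A:G", gt = "0/0"),
    mk_call("FA", "A1", key = "1:3:A:G"), mk_call("FA", "A2", key = "1:3:A:G"),
    mk_call("FB", "B1", key = "1:3:A:G"), mk_call("FB", "B2", key = "1:3:A:G"),
    mk_call("FB", "B3", key = "1:3:A:G"))
  shared <- sharing_filter(raw, two_fam) |>
    dplyr::distinct(family_id, variant_key)
  out <- cross_family_exclusion(shared, raw, two_fam)
  expect_setequal(out$variant_key[out$family_id == "FA"],
                  c("1:1:A:G", "1:3:A:G"))
  expect_setequal(out$variant_key[out$family_id == "FB"], "1:3:A:G")
})

test_that("cross-family exclusion never touches variants seen in one family only", {
  raw <- dplyr::bind_rows(
    mk_call("FA", "A1", key = "1:9:A:G"), mk_call("FA", "A2", key = "1:9:A:G"))
  shared <- dplyr::distinct(raw, family_id, variant_key)
  expect_identical(cross_family_exclusion(shared, raw, two_fam), shared)
})

test_that("the cascade shrinks monotonically and keeps only fully shared variants", {
  b <- small_cohort()
  casc <- run_family_cascade(b$calls, b$cohorts, b$annotations)
  wide <- tidyr::pivot_wider(casc$stage_counts, names_from = stage,
                             values_from = n_variants)
  expect_true(all(wide$input >= wide$quality))
  expect_true(all(wide$quality >= wide$sharing))
  expect_true(all(wide$sharing >= wide$rarity))
  expect_true(all(wide$rarity >= wide$consequence_splice))
  expect_true(all(wide$consequence_splice >= wide$cross_family))
  n_aff <- setNames(b$cohorts$n_affected, b$cohorts$family_id)
  expect_true(all(casc$variants$n_carriers ==
                    n_aff[casc$variants$family_id]))
})

test_that("conjunctive per-record filters commute", {
  b <- small_cohort()
  variants <- b$calls |>
    dplyr::distinct(family_id, variant_key) |>
    dplyr::left_join(b$annotations, by = "variant_key")
  a <- suppressMessages(splice_filter(rarity_filter(variants)))
  b2 <- suppressMessages(rarity_filter(splice_filter(variants)))
  expect_identical(dplyr::arrange(a, family_id, variant_key),
                   dplyr::arrange(b2, family_id, variant_key))
})

test_that("every planted causal variant survives the full cascade", {
  b <- small_cohort()
  casc <- run_family_cascade(b$calls, b$cohorts, b$annotations)
  planted <- b$truth$family_assignments
  hit <- dplyr::semi_join(planted, casc$variants,
                          by = c("family_id", "variant_key"))
  expect_identical(nrow(hit), nrow(planted))
})

test_that("planted low-VAF artifacts are exactly the quality-stage casualties", {
  b <- small_cohort()
  art <- b$truth$artifacts
  expect_gt(nrow(art), 0)
  kept <- quality_filter(b$calls) |>
    dplyr::distinct(family_id, variant_key)
  removed <- dplyr::anti_join(
    dplyr::distinct(b$calls, family_id, variant_key), kept,
    by = c("family_id", "variant_key"))
  expect_setequal(paste(removed$family_id, removed$variant_key),
                  paste(art$family_id, art$variant_key))
})

test_that("the cascade on empty input returns empty per-family sets", {
  b <- small_cohort()
  casc <- run_family_cascade(b$calls[0, ], b$cohorts, b$annotations)
  expect_identical(nrow(casc$variants), 0L)
  final <- dplyr::filter(casc$stage_counts, stage == "cross_family")
  expect_identical(nrow(final), nrow(b$cohorts))
  expect_true(all(final$n_variants == 0L))
})
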
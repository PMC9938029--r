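# Sample and cohort QC: Ti/Tv, het/hom, VAF contamination screen,
# KING-robust kinship (pedigree-simulation oracle), PCA stratification.

test_that("Ti/Tv counts transitions over transversions", {
  expect_identical(titv_ratio(c("A", "C", "G", "A"), c("G", "T", "A", "C")),
                   3)
  # no transversions is undefined, not infinite
  expect_error(titv_ratio("A", "G"), "transversions")
  # no transitions is a plain 0
  expect_identical(titv_ratio("A", "C"), 0)
  expect_error(titv_ratio("AT", "A"), "SNV")
})

test_that("simulated substitutions at 2.7:1 odds recover the ratio", {
  b <- small_cohort()
  snv <- b$calls |>
    dplyr::distinct(variant_key, ref, alt) |>
    dplyr::filter(nchar(ref) == 1, nchar(alt) == 1)
  n <- nrow(snv)
  p <- 2.7 / 3.7
  ci <- qbinom(c(0.005, 0.995), n, p)
  observed_ti <- sum(is_transition(snv$ref, snv$alt))
  expect_gte(observed_ti, ci[1])
  expect_lte(observed_ti, ci[2])
})

test_that("het/hom ratio excludes indels and multi-allelic sites", {
  base <- tibble::tibble(
    chrom = "1", pos = 1:15, ref = "A", alt = "G",
    gt = c(rep("0/1", 10), rep("1/1", 5)))
  expect_identical(het_hom_ratio(base), 2)
  with_junk <- dplyr::bind_rows(
    tibble::tibble(chrom = "1", pos = 1:14, ref = "A", alt = "G",
                   gt = c(rep("0/1", 10), rep("1/1", 4))),
    tibble::tibble(chrom = "1", pos = 101:103, ref = "AT", alt = "A",
                   gt = "0/1"),                      # het indels
    tibble::tibble(chrom = "1", pos = c(200, 200), ref = "A",
                   alt = c("G", "T"), gt = "0/1"))   # triallelic site
  expect_identical(het_hom_ratio(with_junk), 2.5)
  expect_error(het_hom_ratio(base[1:10, ]), "undefined")
})

test_that("het/hom ratio matches the Hardy-Weinberg closed form", {
  # at MAF q, ratio = 2pq / q^2 = 2p/q; q = 0.3 gives 14/3
  withr::with_seed(5, {
    dos <- rbinom(40000, 2, 0.3)
  })
  calls <- tibble::tibble(chrom = "1", pos = seq_along(dos), ref = "A",
                          alt = "G", gt = c("0/0", "0/1", "1/1")[dos + 1])
  expect_equal(het_hom_ratio(calls), 2 * 0.7 / 0.3, tolerance = 0.05)
})

test_that("VAF screen flags off-centre heterozygous fractions", {
  clean <- tibble::tibble(gt = "0/1", dp = 100L,
                          ad_alt = as.integer(rep(c(48, 50, 52), 40)))
  s <- vaf_screen(clean)
  expect_false(s$flag)
  expect_identical(sum(s$histogram$count), nrow(clean))
  contaminated <- clean
  contaminated$ad_alt[1:36] <- 20L  # 30% of calls at VAF 0.2
  expect_true(vaf_screen(contaminated)$flag)
  empty <- clean[0, ]
  s0 <- vaf_screen(empty)
  expect_false(s0$flag)
  expect_identical(sum(s0$histogram$count), 0L)
})

test_that("the simulator's contaminated-sample mode is recovered by the screen", {
  dirty <- simulate_cohort(small_sim_config(
    seed = 13L, n_contaminated_samples = 1L))
  rep_dirty <- qc_sample_report(dirty$calls)
  expect_setequal(rep_dirty$sample_id[rep_dirty$vaf_flag],
                  dirty$truth$contaminated_samples)
  clean <- small_cohort()
  rep_clean <- qc_sample_report(clean$calls)
  expect_false(any(rep_clean$vaf_flag))
})

# ---- KING-robust kinship ------------------------------------------------

king_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      withr::with_seed(77, {
        maf <- runif(50000, 0.05, 0.5)
      })
      ped <- tibble::tibble(
        sample_id = c("dad", "mom", "kid1", "kid2", "u1", "u2"),
        father_id = c("0", "0", "dad", "dad", "0", "0"),
        mother_id = c("0", "0", "mom", "mom", "0", "0"))
      cache <<- simulate_family_genotypes(ped, maf, seed = 78L)
    }
    cache
  }
})

test_that("identical genotype vectors give kinship 0.5 with zero IBS0", {
  g <- king_sim()["dad", ]
  k <- king_kinship(g, g)
  expect_identical(k$kinship, 0.5)
  expect_identical(k$ibs0, 0)
  expect_identical(k$inferred_degree, "duplicate_or_MZ")
})

test_that("pedigree-simulated relationships land in their degree bins", {
  g <- king_sim()
  po <- king_kinship(g["dad", ], g["kid1", ])
  expect_equal(po$kinship, 0.25, tolerance = 0.02)
  expect_lt(po$ibs0, 0.005)
  expect_identical(po$inferred_degree, "first")
  sib <- king_kinship(g["kid1", ], g["kid2", ])
  expect_equal(sib$kinship, 0.25, tolerance = 0.02)
  expect_identical(sib$inferred_degree, "first")
  un <- king_kinship(g["u1", ], g["u2", ])
  expect_equal(un$kinship, 0, tolerance = 0.02)
  expect_identical(un$inferred_degree, "unrelated")
})

test_that("kinship is symmetric and the matrix form matches the pairwise form", {
  g <- king_sim()
  a <- king_kinship(g["dad", ], g["kid1", ])
  b <- king_kinship(g["kid1", ], g["dad", ])
  expect_identical(a$kinship, b$kinship)
  m <- king_kinship_matrix(g[c("dad", "kid1", "u1"), ])
  pair <- m[m$sample_i == "dad" & m$sample_j == "kid1", ]
  expect_equal(pair$kinship, a$kinship)
  expect_equal(pair$ibs0, a$ibs0)
})

test_that("kinship degrades gracefully under 10% missingness", {
  g <- king_sim()
  gi <- g["dad", ]
  gj <- g["kid1", ]
  withr::with_seed(9, {
    gi[sample.int(length(gi), 5000)] <- NA_integer_
    gj[sample.int(length(gj), 5000)] <- NA_integer_
  })
  full <- king_kinship(g["dad", ], g["kid1", ])
  masked <- king_kinship(gi, gj)
  expect_lt(abs(full$kinship - masked$kinship), 0.02)
  expect_lt(masked$n_snps_used, full$n_snps_used)
})

test_that("too few overlapping SNPs is an explicit error", {
  expect_error(king_kinship(rep(1L, 100), rep(1L, 100)), "insufficient")
})

# ---- PCA stratification -------------------------------------------------

test_that("homogeneous cohorts yield no outliers; a divergent group is flagged", {
  withr::with_seed(21, {
    n <- 6000  # exome-scale common-SNP panel
    maf <- runif(n, 0.05, 0.5)
    base <- matrix(rbinom(40 * n, 2, rep(maf, each = 40)), nrow = 40)
    rownames(base) <- sprintf("S%02d", 1:40)
    pca0 <- genotype_pca(base)
    expect_length(pca0$outliers, 0)
    # a 5-sample group from Balding-Nichols-shifted frequencies (Fst 0.05)
    f <- 0.05
    maf2 <- rbeta(n, maf * (1 - f) / f, (1 - maf) * (1 - f) / f)
    div <- matrix(rbinom(5 * n, 2, rep(pmin(pmax(maf2, 1e-4), 0.999),
                                       each = 5)), nrow = 5)
    rownames(div) <- sprintf("D%02d", 1:5)
    pca1 <- genotype_pca(rbind(base, div), outlier_components = 1L)
    expect_setequal(pca1$outliers, rownames(div))
  })
})

test_that("principal components are uncorrelated", {
  withr::with_seed(22, {
    g <- matrix(rbinom(30 * 500, 2, 0.3), nrow = 30)
  })
  rownames(g) <- sprintf("S%02d", 1:30)
  pca <- genotype_pca(g, maf_min = 0.05)
  sc <- as.matrix(pca$scores[, -1])
  cv <- cov(sc)
  off <- cv[upper.tri(cv)]
  expect_lt(max(abs(off)), 1e-8 * max(diag(cv)))
})

test_that("metrics are invariant to input row order", {
  b <- small_cohort()
  one <- dplyr::filter(b$calls, sample_id == b$pedigree$sample_id[1])
  shuffled <- one[rev(seq_len(nrow(one))), ]
  expect_identical(het_hom_ratio(one), het_hom_ratio(shuffled))
  snv <- dplyr::filter(one, nchar(ref) == 1, nchar(alt) == 1)
  expect_identical(titv_ratio(snv$ref, snv$alt),
                   titv_ratio(rev(snv$ref), rev(snv$alt)))
})
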
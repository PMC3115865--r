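make_one_locus <- function(a1, a2, site = "P") {
  genotype_table(sprintf("i%d", seq_along(a1)), rep(site, length(a1)),
                 "L1", matrix(as.integer(a1)), matrix(as.integer(a2)))
}

test_that("unbiased gene diversity matches hand-computed values", {
  # allele counts {5,5} over 10 copies -> 10/9 * (1 - 0.5) = 5/9
  g <- make_one_locus(c(1, 1, 1, 2, 2), c(1, 1, 2, 2, 2))
  expect_equal(unname(expected_heterozygosity(g)$per_locus), 5 / 9)
  # counts {9,1} -> (10/9)(1 - 0.81 - 0.01) = 0.2
  g2 <- make_one_locus(c(1, 1, 1, 1, 1), c(1, 1, 1, 1, 2))
  expect_equal(unname(expected_heterozygosity(g2)$per_locus), 0.2)
  # monomorphic -> 0
  g3 <- make_one_locus(c(1, 1, 1), c(1, 1, 1))
  expect_equal(unname(expected_heterozygosity(g3)$per_locus), 0)
})

test_that("gene diversity is invariant under allele relabeling and skips
           loci with under two gene copies", {
  g <- make_one_locus(c(1, 2, 3, 1), c(2, 3, 1, 1))
  relab <- make_one_locus(c(7, 9, 4, 7), c(9, 4, 7, 7))  # 1->7, 2->9, 3->4
  expect_equal(expected_heterozygosity(g)$mean,
               expected_heterozygosity(relab)$mean)
  # second locus fully missing except one individual -> excluded from mean
  gt <- genotype_table(c("a", "b"), c("P", "P"), c("L1", "L2"),
                       matrix(c(1L, 2L, 3L, NA), 2), matrix(c(1L, 2L, 3L, NA), 2))
  he <- expected_heterozygosity(gt)
  expect_equal(he$n_loci, 2)  # L2 still has 2 copies from one individual
  gt2 <- genotype_table(c("a", "b"), c("P", "P"), c("L1", "L2"),
                        matrix(c(1L, 2L, NA, NA), 2),
                        matrix(c(1L, 2L, NA, NA), 2))
  expect_equal(expected_heterozygosity(gt2)$n_loci, 1)
})

test_that("hypergeometric rarefaction equals exhaustive enumeration", {
  # frozen case: counts {6,4}, g = 2 -> 69/45 (enumeration over 45 pairs)
  expect_equal(rangediv:::rarefy_counts(c(6, 4), 2), 23 / 15, tolerance = 1e-12)
  set.seed(71)
  for (i in 1:12) {
    k <- sample(2:4, 1)
    counts <- as.numeric(table(sample.int(k, sample(6:12, 1), replace = TRUE)))
    N <- sum(counts)
    g <- sample(2:(N - 1), 1)
    expect_equal(rangediv:::rarefy_counts(counts, g),
                 enum_rarefaction(counts, g), tolerance = 1e-9)
  }
})

test_that("rarefied richness limits: g = N gives the observed count,
           monomorphic loci give 1, and E[A_g] is non-decreasing in g", {
  counts <- c(5, 3, 2)
  expect_equal(rangediv:::rarefy_counts(counts, sum(counts)), 3)
  expect_equal(rangediv:::rarefy_counts(10, 4), 1)
  vals <- vapply(2:10, function(g) rangediv:::rarefy_counts(counts, g),
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("rarefied allelic richness guards and locus exclusion work", {
  g <- make_one_locus(c(1, 2, 1), c(2, 2, 1))
  expect_error(rarefied_allelic_richness(g, g = 1), "at least 2")
  expect_warning(r <- rarefied_allelic_richness(g, g = 14), "excluded")
  expect_equal(r$n_loci, 0)
  r2 <- rarefied_allelic_richness(g, g = 6)
  expect_equal(r2$mean, 2)  # g = N: observed allele count
})

test_that("rarefied haplotype richness matches the enumeration oracle", {
  expect_equal(rarefied_haplotype_richness(c(x = 4), 2), 1)
  # counts {3,3,3}, g = 3: enumeration over all C(9,3) = 84 subsamples
  expect_equal(enum_rarefaction(c(3, 3, 3), 3), 192 / 84, tolerance = 1e-12)
  expect_equal(rarefied_haplotype_richness(c(3, 3, 3), 3), 192 / 84,
               tolerance = 1e-9)
  expect_equal(rarefied_haplotype_richness(c(2, 5, 1), 8), 3)
  expect_error(rarefied_haplotype_richness(c(3, 3), 0), "at least 1")
  expect_error(rarefied_haplotype_richness(c(3, 3), 7), "exceeds")
})

test_that("diversity table applies the seven-individual floor", {
  set.seed(8)
  small <- hwe_genotypes(6, list(c(.5, .5), c(.3, .7)), "SM")
  big <- hwe_genotypes(12, list(c(.5, .5), c(.3, .7)), "BG")
  div <- diversity_table(bind_geno(small, big), min_ind = 7, g = 14)
  expect_equal(div$site, "BG")
  expect_true(div$He >= 0 && div$He <= 1)
  expect_true(div$A >= 1)
})

test_that("group deviation summary reduces to the overall mean for the
           all-sites group and reports correlations", {
  div <- data.frame(site = sprintf("S%d", 1:6), He = c(.1, .2, .3, .4, .5, .6),
                    A = rep(2, 6))
  gs <- group_deviation_summary(div, list(all = div$site, none = character()),
                                measures = c("He", "A"))
  all_he <- gs[gs$group == "all" & gs$measure == "He", ]
  expect_equal(all_he$mean, all_he$overall_mean)
  expect_equal(gs[gs$group == "all" & gs$measure == "A", "sd"], 0)
  expect_equal(gs[gs$group == "none" & gs$measure == "He", "n"], 0)
  expect_true(is.matrix(attr(gs, "correlations")))
})
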
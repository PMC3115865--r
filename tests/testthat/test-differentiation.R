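test_that("theta is 1 for fixed differences and near 0 for a split panmictic
           sample", {
  fixed <- genotype_table(sprintf("i%d", 1:8), rep(c("A", "B"), each = 4),
                          c("L1", "L2"),
                          matrix(rep(c(10L, 20L), each = 4), 8, 2),
                          matrix(rep(c(10L, 20L), each = 4), 8, 2))
  expect_equal(wc_fst(fixed)$theta, 1)
  set.seed(31)
  pool <- hwe_genotypes(100, list(c(.4, .3, .3), c(.5, .5), c(.2, .2, .6)))
  split <- genotype_table(pool$ind$id,
                          rep(c("A", "B"), each = 50),
                          pool$loci, pool$a1, pool$a2)
  expect_lt(abs(wc_fst(split)$theta), 0.02)
})

test_that("theta is invariant to allele relabeling and site order", {
  set.seed(32)
  ga <- hwe_genotypes(15, list(c(.7, .3), c(.5, .5)), "A")
  gb <- hwe_genotypes(15, list(c(.2, .8), c(.9, .1)), "B")
  g <- bind_geno(ga, gb)
  remap <- function(x) ifelse(is.na(x), x, ifelse(x == 1L, 55L, 91L))
  g_re <- genotype_table(g$ind$id, g$ind$site, g$loci,
                         remap(g$a1), remap(g$a2))
  expect_equal(wc_fst(g)$theta, wc_fst(g_re)$theta)
  g_flip <- bind_geno(gb, ga)
  expect_equal(wc_fst(g_flip)$theta, wc_fst(g)$theta, tolerance = 1e-12)
})

test_that("multi-deme theta tracks the island-model equilibrium expectation", {
  # finite island model: E[F_ST] ~ 1/(1 + 4Nm (d/(d-1))^2) at low mutation
  d <- 10; N <- 100; m <- 0.01
  expected <- 1 / (1 + 4 * N * m * (d / (d - 1))^2)
  sc <- sim_scenario(n_demes = d, N = N, s = 0, m = m, mu = 1e-4,
                     generations = 250, sample_n = 25, miss_rate = 0,
                     mu_mt = 0, n_alleles_init = 10)
  thetas <- vapply(1:10, function(r)
    wc_fst(simulate_metapopulation(sc, seed = 5000 + r)$geno)$theta,
    numeric(1))
  expect_equal(mean(thetas), expected, tolerance = 0.25)
})

test_that("haplotype F_ST spans its limits", {
  fixed <- haplotype_table(rep(c("A", "B"), each = 6),
                           rep(c("h1", "h2"), each = 6))
  expect_equal(haplotype_fst(fixed)$overall, 1)
  same <- haplotype_table(rep(c("A", "B"), each = 30),
                          rep(rep(c("h1", "h2"), each = 15), 2))
  expect_lt(abs(haplotype_fst(same)$overall), 0.05)
  # random split of a merged pool is ~0 on average over replicates
  set.seed(33)
  vals <- replicate(40, {
    pool <- sample(rep(sprintf("h%d", 1:5), c(10, 8, 6, 4, 2)))
    haplotype_fst(haplotype_table(rep(c("A", "B"), each = 15),
                                  pool))$overall
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("F_ST linearization clamps and transforms correctly", {
  m <- matrix(c(0, .5, -.1, .5, 0, .368, -.1, .368, 0), 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  lin <- linearize_fst(dist_matrix(m, "fst"))
  expect_equal(lin["A", "B"], 1)
  expect_equal(lin["A", "C"], 0)
  expect_equal(lin["B", "C"], 0.368 / 0.632, tolerance = 1e-6)
  expect_equal(attr(lin, "kind"), "linearized_fst")
})

test_that("great-circle distances reproduce closed-form values", {
  s <- as_site_table(data.frame(code = c("O", "E", "AP", "O2"),
                                lat = c(0, 0, 0, 0),
                                lon = c(0, 1, 180, 0), expansion = "hol"))
  m <- geo_distance_matrix(s)
  expect_equal(m["O", "O2"], 0)
  expect_equal(m["O", "E"], 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_equal(m["O", "AP"], pi * 6371, tolerance = 1e-6)
  s2 <- as_site_table(data.frame(code = c("A", "B"), lat = c(NA, 50),
                                 lon = c(1, 2), expansion = "hol"))
  expect_warning(geo_distance_matrix(s2), "excluded")
})

test_that("Mantel test recovers perfect association and agrees with an
           independent implementation", {
  set.seed(34)
  x <- random_dist_matrix(12)
  y <- 2 * x + 3; diag(y) <- 0
  mt <- mantel_test(x, y, n_perm = 199)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 200)
  neg <- mantel_test(x, -x + max(x), n_perm = 199)
  expect_equal(neg$r, -1)
  expect_gt(neg$p, 0.9)
  expect_error(mantel_test(x, matrix(1, 12, 12)), "constant")
  z <- random_dist_matrix(12)
  mt2 <- mantel_test(x, z, n_perm = 999)
  ref <- vegan::mantel(x, z, permutations = 999)
  expect_equal(mt2$r, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mt2$p, ref$signif, tolerance = 0.05)
})

test_that("minimum spanning tree matches brute force and is stable under
           weight translation", {
  m3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mst <- minimum_spanning_tree(dist_matrix(m3, "fst"))
  expect_equal(nrow(mst), 2)
  expect_setequal(paste(mst$site_a, mst$site_b), c("A B", "A C"))
  set.seed(35)
  for (n in c(6, 6, 6, 7)) {
    m <- random_dist_matrix(n)
    mst_n <- minimum_spanning_tree(dist_matrix(m, "fst"))
    expect_equal(sum(mst_n$weight), brute_mst_weight(m), tolerance = 1e-10)
    shifted <- minimum_spanning_tree(dist_matrix(m + 0.7 - diag(0.7, n), "fst"))
    expect_equal(shifted[c("site_a", "site_b")], mst_n[c("site_a", "site_b")])
  }
  expect_error(minimum_spanning_tree(dist_matrix(matrix(0, 1, 1,
    dimnames = list("A", "A")), "fst")), "at least 2")
})

test_that("category contrast detects an injected differentiation excess and
           guards degenerate memberships", {
  set.seed(36)
  n <- 42
  codes <- sprintf("S%02d", 1:n)
  m <- random_dist_matrix(n, codes) * 0.05
  cat_sites <- codes[1:12]
  m[1:12, 1:12] <- m[1:12, 1:12] + 0.2
  diag(m) <- 0
  ct <- category_fst_contrast(dist_matrix(m, "fst"), cat_sites, n_perm = 999)
  expect_lte(ct$p_one_sided, 0.01)
  expect_gt(ct$diff, 0.15)
  expect_error(category_fst_contrast(dist_matrix(m, "fst"), codes[-1]),
               "at least 2")
})

test_that("pairwise class contrasts cover every class pair", {
  set.seed(37)
  codes <- sprintf("S%02d", 1:15)
  m <- random_dist_matrix(15, codes)
  classes <- stats::setNames(rep(c("exp", "hol", "ref"), each = 5), codes)
  res <- class_pair_contrasts(dist_matrix(m, "fst"), classes, n_perm = 199)
  expect_equal(nrow(res), 3)
  expect_setequal(paste(res$class_a, res$class_b),
                  c("exp hol", "exp ref", "hol ref"))
  expect_true(all(res$p_one_sided > 0 & res$p_one_sided <= 1))
})
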
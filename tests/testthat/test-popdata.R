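test_that("GENEPOP parsing preserves structure and decodes missing calls", {
  txt <- c("title line",
           "locA", "locB", "locC",
           "POP",
           "P1 , 001002 003003 000000",
           "P1 , 002002 000000 004005",
           "POP",
           "P2 , 010011 003004 006006",
           "P2 , 011011 004004 007006")
  f <- withr::local_tempfile(lines = txt, fileext = ".gen")
  g <- read_genepop(f)
  expect_equal(nrow(g$ind), 4)
  expect_equal(g$loci, c("locA", "locB", "locC"))
  expect_equal(geno_sites(g), c("P1", "P2"))
  expect_true(is.na(g$a1[1, 3]) && is.na(g$a2[1, 3]))
  expect_equal(g$a1[1, 1], 1L)
  expect_equal(g$a2[4, 3], 6L)
})

test_that("malformed GENEPOP files raise parse errors naming the line", {
  ragged <- c("t", "locA", "locB", "POP", "P1 , 001002")
  f1 <- withr::local_tempfile(lines = ragged, fileext = ".gen")
  expect_error(read_genepop(f1), "expected 2 loci")
  oddwidth <- c("t", "locA", "POP", "P1 , 00102")
  f2 <- withr::local_tempfile(lines = oddwidth, fileext = ".gen")
  expect_error(read_genepop(f2), "4 or 6 digits")
  expect_error(read_genepop(withr::local_tempfile(
    lines = c("t", "locA", "locB"))), "no POP")
})

test_that("GENEPOP round trip is lossless", {
  set.seed(4)
  sim <- simulate_metapopulation(
    sim_scenario(n_demes = 3, N = 12, generations = 5, sample_n = 8), seed = 9)
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(sim$geno, f)
  back <- read_genepop(f)
  expect_equal(unname(back$a1), unname(sim$geno$a1))
  expect_equal(unname(back$a2), unname(sim$geno$a2))
  expect_equal(back$ind$site, sim$geno$ind$site)
  expect_equal(back$loci, sim$geno$loci)
})

test_that("long-form genotype CSV reader matches the GENEPOP path", {
  set.seed(5)
  sim <- simulate_metapopulation(
    sim_scenario(n_demes = 2, N = 10, generations = 5, sample_n = 6), seed = 3)
  paths <- write_sim_dataset(sim, withr::local_tempdir())
  g1 <- read_genepop(paths[["genepop"]])
  g2 <- read_genotypes_csv(paths[["geno_csv"]])
  expect_equal(unname(g1$a1), unname(g2$a1))
  expect_equal(g1$ind$site, g2$ind$site)
})

test_that("genotype_table enforces its invariants", {
  expect_error(genotype_table("a", "P", "L", matrix(1), matrix(NA_integer_)),
               "half-missing")
  expect_error(genotype_table("a", "P", "L", matrix(-1L), matrix(2L)),
               "positive")
  expect_error(genotype_table(c("a", "b"), c("P", "P"), "L",
                              matrix(c(1L, NA), 2), matrix(c(1L, NA), 2)),
               "no typed locus")
})

test_that("site table validation catches duplicates and defaults expansion", {
  f <- withr::local_tempfile(
    lines = c("code,lat,lon", "A,50,1", "B,51,2", "C,52,3"), fileext = ".csv")
  expect_warning(s <- read_sites(f), "hol")
  expect_equal(nrow(s), 3)
  expect_equal(s$expansion, rep("hol", 3))
  f2 <- withr::local_tempfile(
    lines = c("code,lat,lon,expansion", "A,50,1,ref", "A,51,2,hol"),
    fileext = ".csv")
  expect_error(read_sites(f2), "duplicate")
  f3 <- withr::local_tempfile(
    lines = c("code,lat,lon,expansion", "A,95,1,ref"), fileext = ".csv")
  expect_error(read_sites(f3), "coordinates")
})

test_that("haplotype collapsing filters short reads and is order-invariant", {
  seqs <- c(i1 = "ACGTACGTAC", i2 = "ACGTACGTAC", i3 = "ACGTACGTAC",
            i4 = "ACGTACGTAT", i5 = "ACG---GTAC")
  asn <- data.frame(id = names(seqs), site = c("A", "A", "A", "A", "A"))
  h <- collapse_haplotypes(seqs, asn, min_length = 8)
  expect_equal(sum(h$count), 4)          # i5 has 7 non-gap bases: dropped
  expect_equal(nrow(h), 2)               # one substitution = new haplotype
  expect_equal(max(h$count), 3)          # three identical sequences share one
  h2 <- collapse_haplotypes(seqs[c(4, 2, 5, 1, 3)], asn, min_length = 8)
  expect_equal(h, h2, ignore_attr = TRUE)
  expect_error(collapse_haplotypes(c(i1 = "ACGT", i2 = "ACGTA"), asn, 2),
               "equal length")
  expect_error(collapse_haplotypes(seqs, asn[1:3, ], min_length = 8),
               "without site assignment")
})

test_that("boundary: a sequence one base short of the threshold is dropped", {
  n <- 400
  full <- paste(rep("A", n), collapse = "")
  short <- paste(c(rep("A", n - 1), "-"), collapse = "")
  h <- collapse_haplotypes(c(x = full, y = short),
                           data.frame(id = c("x", "y"), site = "S"), 400)
  expect_equal(sum(h$count), 1)
})

test_that("dataset validation flags thresholds and inconsistencies", {
  set.seed(6)
  g6 <- hwe_genotypes(6, list(c(.5, .5)), site = "SMALL")
  g9 <- hwe_genotypes(9, list(c(.5, .5)), site = "BIG")
  geno <- bind_geno(g6, g9)
  sites <- as_site_table(data.frame(code = c("SMALL", "BIG"), lat = c(50, 51),
                                    lon = c(1, 2), expansion = "hol"))
  rep1 <- validate_dataset(geno, sites)
  expect_true(any(grepl("excluded from diversity", rep1$message) &
                    rep1$site == "SMALL"))
  sites2 <- as_site_table(data.frame(code = "BIG", lat = 51, lon = 2,
                                     expansion = "hol"))
  rep2 <- validate_dataset(geno, sites2)
  expect_true(any(rep2$severity == "fatal" & rep2$site == "SMALL"))
  geno_ok <- bind_geno(hwe_genotypes(8, list(c(.5, .5)), "BIG2"))
  sites3 <- as_site_table(data.frame(code = "BIG2", lat = 51, lon = 2,
                                     expansion = "hol"))
  expect_equal(nrow(validate_dataset(geno_ok, sites3)), 0)
})
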
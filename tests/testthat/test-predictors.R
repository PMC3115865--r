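km_deg <- pi * 6371 / 180   # km per degree at the equator

test_that("distance to the range margin is zero on the hull and exact at the
           center of a square", {
  d_km <- 50
  dd <- d_km / km_deg       # degrees spanning d_km at lat 0
  s <- as_site_table(data.frame(
    code = c("SW", "SE", "NE", "NW", "C"),
    lat = c(-dd, -dd, dd, dd, 0), lon = c(-dd, dd, dd, -dd, 0),
    expansion = "hol"))
  lim <- distance_to_range_margin(s)
  expect_equal(unname(lim[c("SW", "SE", "NE", "NW")]), rep(0, 4))
  expect_equal(unname(lim["C"]), d_km, tolerance = 1e-3)
  expect_error(distance_to_range_margin(s[1:2, ]), "at least 3")
  coll <- as_site_table(data.frame(code = c("A", "B", "C"), lat = c(1, 2, 3),
                                   lon = c(1, 2, 3), expansion = "hol"))
  expect_error(distance_to_range_margin(coll), "collinear")
})

test_that("hull distances match a dense edge-sampling oracle", {
  set.seed(61)
  s <- as_site_table(data.frame(code = sprintf("S%02d", 1:25),
                                lat = runif(25, 45, 55),
                                lon = runif(25, 0, 12), expansion = "hol"))
  lim <- distance_to_range_margin(s)
  xy <- rangediv:::project_km(s$lat, s$lon)
  hull <- grDevices::chull(xy)
  interior <- setdiff(seq_len(nrow(s)), hull)[1:3]
  for (i in interior) {
    dmin <- Inf
    for (e in seq_along(hull)) {
      a <- xy[hull[e], ]; b <- xy[hull[if (e == length(hull)) 1 else e + 1], ]
      tt <- seq(0, 1, length.out = 4000)
      pts <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
      dmin <- min(dmin, sqrt((pts[, 1] - xy[i, 1])^2 +
                               (pts[, 2] - xy[i, 2])^2))
    }
    expect_equal(unname(lim[i]), dmin, tolerance = 1e-3)
  }
})

test_that("environmental marginality reproduces an independent
           eigendecomposition and handles degenerate columns", {
  set.seed(62)
  n <- 80; p <- 35
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("clim%d", 1:p)))
  s <- as_site_table(cbind(data.frame(code = sprintf("S%02d", 1:n),
                                      lat = runif(n, 40, 60),
                                      lon = runif(n, 0, 20),
                                      expansion = "hol"), x))
  marg <- environmental_marginality(s)
  ev_oracle <- eigen(stats::cor(x), symmetric = TRUE)
  expect_equal(unname(attr(marg, "eigenvalues")),
               ev_oracle$values, tolerance = 1e-8)
  expect_equal(attr(marg, "n_retained"), sum(ev_oracle$values > 1))
  z <- scale(x)
  scores_oracle <- z %*% ev_oracle$vectors[, seq_len(attr(marg, "n_retained"))]
  # scores agree up to per-axis sign
  sc <- attr(marg, "scores")
  for (j in seq_len(ncol(sc)))
    expect_equal(abs(unname(sc[, j])), abs(unname(scores_oracle[, j])),
                 tolerance = 1e-8)
  expect_equal(as.numeric(marg), unname(sqrt(rowSums(scores_oracle^2))),
               tolerance = 1e-8)
})

test_that("a site at the exact climate mean has zero marginality and
           rank-1 climates keep one axis", {
  base <- data.frame(code = c("A", "B", "C"), lat = c(50, 51, 52),
                     lon = 1:3, expansion = "hol")
  s <- as_site_table(cbind(base, c1 = c(1, 3, 2), c2 = c(10, 30, 20)))
  marg <- environmental_marginality(s)
  expect_equal(attr(marg, "n_retained"), 1)
  expect_equal(unname(marg["C"]), 0, tolerance = 1e-10)  # C sits at the mean
  s2 <- as_site_table(cbind(base, c1 = c(1, 3, 2), c2 = c(2, 6, 4),
                            c3 = c(5, 5, 5)))
  expect_warning(m2 <- environmental_marginality(s2), "constant")
  expect_equal(attr(m2, "dropped"), "c3")
})

test_that("quantile grouping uses the strictly-greater type-7 rule", {
  v <- stats::setNames(as.numeric(1:100), sprintf("S%03d", 1:100))
  grp <- quantile_grouping(v, 0.85)
  expect_equal(sum(grp), 15)
  med <- quantile_grouping(stats::setNames(as.numeric(1:10), letters[1:10]), 0.5)
  expect_equal(sum(med), 5)               # values > 5.5
  expect_equal(names(which(med)), letters[6:10])
  ties <- quantile_grouping(stats::setNames(c(1, 2, 2, 2, 3), LETTERS[1:5]), 0.5)
  expect_false(ties[["B"]])               # ties at the threshold stay below
  expect_warning(quantile_grouping(rep(1, 5)), "empty")
  expect_error(quantile_grouping(v, 1.2), "in \\(0, 1\\)")
})

test_that("ref/hol merge follows its permutation tests", {
  set.seed(63)
  mk_div <- function(hol_shift = 0) {
    n <- 30
    cls <- rep(c("ref", "hol", "exp"), each = 10)
    data.frame(site = sprintf("S%02d", 1:n),
               He = rnorm(n, 0.5 + ifelse(cls == "hol", hol_shift, 0), 0.1),
               A = rnorm(n, 3, 0.5), stringsAsFactors = FALSE)
  }
  cls <- stats::setNames(rep(c("ref", "hol", "exp"), each = 10),
                         sprintf("S%02d", 1:30))
  # under the null the merge rate is ~0.95^k for k independent measures
  merged <- vapply(1:40, function(r)
    merge_expansion_levels(mk_div(), cls, measures = c("He", "A"),
                           n_perm = 299)$merged, logical(1))
  expect_gt(mean(merged), 0.95^2 - 0.17)
  expect_lte(mean(merged), 1)
  # a 3-sd shift of hol blocks the merge
  blocked <- vapply(1:20, function(r)
    merge_expansion_levels(mk_div(0.3), cls, measures = c("He", "A"),
                           n_perm = 299)$merged, logical(1))
  expect_equal(mean(blocked), 0)
  div_noexp <- mk_div()
  cls2 <- stats::setNames(rep(c("ref", "hol"), 15), sprintf("S%02d", 1:30))
  expect_error(merge_expansion_levels(div_noexp, cls2, n_perm = 299),
               "exp")
})

test_that("the predictor table assembles every column and applies the merge", {
  sim <- simulate_metapopulation(
    scenario_range_expansion(n_core = 20, n_exp = 8, N = 40,
                             generations = 80), seed = 64)
  div <- diversity_table(sim$geno, sim$haps)
  pred <- predictor_table(sim$sites, div, n_perm = 199)
  expect_setequal(names(pred), c("code", "lim_km", "marg", "bar", "bio",
                                 "size", "expansion", "exp", "lim_group",
                                 "marg_group"))
  expect_true(all(pred$lim_km >= 0))
  expect_true(all(pred$marg >= 0))
  expect_equal(pred$exp, as.integer(pred$expansion == "exp"))
  mg <- attr(pred, "merge")
  expect_true(is.list(mg) && length(mg$p_values) >= 1)
  if (mg$merged) expect_setequal(unique(pred$expansion), c("exp", "ref+hol"))
})
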
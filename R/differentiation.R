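#' Distance matrix container
#' @param values symmetric numeric matrix with zero diagonal; dimnames are
#'   the site codes.
#' @param kind one of "geographic_km", "fst", "linearized_fst".
#' @return the matrix with class `dist_matrix` and a `kind` attribute.
#' @export
dist_matrix <- function(values, kind = c("fst", "geographic_km",
                                         "linearized_fst")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(rownames(values))) stop("matrix needs site codes as dimnames")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("matrix must be symmetric")
  diag(values) <- 0
  if (kind == "geographic_km" && any(values < 0, na.rm = TRUE))
    stop("geographic distances must be non-negative")
  structure(values, kind = kind, class = c("dist_matrix", class(values)))
}

## per-locus, per-site allele summaries shared by the theta estimators:
## counts (sites x alleles), heterozygote-carrier counts, and sample sizes
locus_summaries <- function(geno) {
  sites <- geno_sites(geno)
  si <- match(geno$ind$site, sites)
  lapply(seq_along(geno$loci), function(l) {
    x1 <- geno$a1[, l]; x2 <- geno$a2[, l]
    ok <- !is.na(x1)
    alleles <- sort(unique(c(x1[ok], x2[ok])))
    A <- length(alleles)
    cnt <- matrix(0L, length(sites), A, dimnames = list(sites, alleles))
    hetc <- matrix(0L, length(sites), A, dimnames = list(sites, alleles))
    n <- integer(length(sites))
    if (A) {
      j1 <- match(x1[ok], alleles); j2 <- match(x2[ok], alleles)
      ii <- si[ok]
      for (k in seq_along(ii)) {
        cnt[ii[k], j1[k]] <- cnt[ii[k], j1[k]] + 1L
        cnt[ii[k], j2[k]] <- cnt[ii[k], j2[k]] + 1L
        if (j1[k] != j2[k]) {
          hetc[ii[k], j1[k]] <- hetc[ii[k], j1[k]] + 1L
          hetc[ii[k], j2[k]] <- hetc[ii[k], j2[k]] + 1L
        }
      }
      n <- as.integer(rowSums(cnt) / 2)
    }
    list(count = cnt, het = hetc, n = n)
  })
}

## Weir & Cockerham (1984) variance components for one locus, given per-site
## summaries restricted to `use` sites; returns c(a, b+c-part...) sums
wc_components <- function(sm, use) {
  n_i <- sm$n[use]
  keep <- n_i >= 2          # a site needs >= 2 typed individuals at the locus
  use <- use[keep]; n_i <- n_i[keep]
  r <- length(use)
  if (r < 2) return(c(a = 0, abc = 0, usable = FALSE))
  cnt <- sm$count[use, , drop = FALSE]
  het <- sm$het[use, , drop = FALSE]
  p <- cnt / (2 * n_i)
  h <- het / n_i
  if (ncol(cnt) < 2 || sum(colSums(cnt) > 0) < 2)
    return(c(a = 0, abc = 0, usable = FALSE))
  nbar <- mean(n_i)
  nsum <- sum(n_i)
  nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  a_sum <- 0; abc_sum <- 0
  for (u in seq_len(ncol(cnt))) {
    pbar <- sum(n_i * p[, u]) / nsum
    s2 <- sum(n_i * (p[, u] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h[, u]) / nsum
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  c(a = a_sum, abc = abc_sum, usable = TRUE)
}

#' Weir-Cockerham F_ST (theta)
#'
#' Multi-locus theta of Weir & Cockerham (1984), combining variance
#' components by summation over alleles and loci (the convention of the
#' field's standard AMOVA software).
#' The estimator is unbiased and may be negative. Individuals missing at a
#' locus are excluded for that locus; a site needs two typed individuals at a
#' locus to contribute there.
#'
#' @param geno a [genotype_table()].
#' @param sites optional character vector restricting the estimate to a site
#'   subset (e.g. one pair).
#' @return list with `theta` (multi-locus), `per_locus` (named vector) and
#'   `n_loci` used.
#' @export
wc_fst <- function(geno, sites = NULL) {
  all_sites <- geno_sites(geno)
  if (is.null(sites)) sites <- all_sites
  if (length(sites) < 2) stop("theta needs at least two sites")
  use <- match(sites, all_sites)
  if (anyNA(use)) stop("unknown site code(s): ",
                       paste(sites[is.na(use)], collapse = ", "))
  sm <- locus_summaries(geno)
  comp <- vapply(sm, wc_components, numeric(3), use = use)
  usable <- comp["usable", ] > 0
  if (!any(usable))
    return(list(theta = NA_real_, per_locus = stats::setNames(
      rep(NA_real_, length(geno$loci)), geno$loci), n_loci = 0L,
      reason = "no locus polymorphic across the requested sites"))
  per <- ifelse(usable & comp["abc", ] != 0,
                comp["a", ] / comp["abc", ], NA_real_)
  names(per) <- geno$loci
  list(theta = sum(comp["a", usable]) / sum(comp["abc", usable]),
       per_locus = per, n_loci = sum(usable))
}

#' Pairwise Weir-Cockerham F_ST matrix
#' @param geno a [genotype_table()].
#' @return a `dist_matrix` of kind "fst" (raw theta, possibly negative).
#' @export
pairwise_fst <- function(geno) {
  sites <- geno_sites(geno)
  sm <- locus_summaries(geno)
  n <- length(sites)
  m <- matrix(0, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    comp <- vapply(sm, wc_components, numeric(3), use = c(i, j))
    usable <- comp["usable", ] > 0
    m[i, j] <- m[j, i] <- if (any(usable))
      sum(comp["a", usable]) / sum(comp["abc", usable]) else NA_real_
  }
  dist_matrix(m, "fst")
}

#' Haplotype-frequency F_ST (AMOVA with identity distances)
#'
#' Two-level AMOVA on mitochondrial haplotype counts with inter-haplotype
#' distance 0/1 (identity), i.e. the conventional haplotype-frequency F_ST.
#'
#' @param haps a `haplotype_table`.
#' @return list with `overall` and `pairwise` (a `dist_matrix` of kind
#'   "fst"); sites with no sequences are excluded.
#' @export
haplotype_fst <- function(haps) {
  sites <- sort(unique(haps$site))
  if (length(sites) < 2) stop("haplotype F_ST needs at least two sites")
  counts <- lapply(sites, function(s) site_haplotype_counts(haps, s))
  names(counts) <- sites
  amova_f <- function(cs) {
    n_k <- vapply(cs, sum, numeric(1))
    N <- sum(n_k); r <- length(cs)
    ssd_w <- sum(vapply(cs, function(x) (sum(x)^2 - sum(x^2)) / (2 * sum(x)),
                        numeric(1)))
    tot <- tapply(unlist(cs, use.names = FALSE),
                  unlist(lapply(cs, names)), sum)
    ssd_t <- (N^2 - sum(tot^2)) / (2 * N)
    if (ssd_t == 0) return(NA_real_)   # all sequences identical
    ms_w <- ssd_w / (N - r)
    ms_a <- (ssd_t - ssd_w) / (r - 1)
    nc <- (N - sum(n_k^2) / N) / (r - 1)
    s2a <- (ms_a - ms_w) / nc
    s2a / (s2a + ms_w)
  }
  overall <- amova_f(counts)
  n <- length(sites)
  m <- matrix(0, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    m[i, j] <- m[j, i] <- amova_f(counts[c(i, j)])
  list(overall = overall, pairwise = dist_matrix(m, "fst"))
}

#' Linearize an F_ST matrix
#'
#' Elementwise F/(1-F) after clamping F into [0, 0.999]; negative estimates
#' map to 0 so the transform stays defined.
#'
#' @param m a `dist_matrix` of kind "fst".
#' @return a `dist_matrix` of kind "linearized_fst".
#' @export
linearize_fst <- function(m) {
  f <- pmin(pmax(unclass(m), 0), 0.999)
  out <- f / (1 - f)
  diag(out) <- 0
  dist_matrix(out, "linearized_fst")
}

#' Great-circle distance matrix between sites
#'
#' Haversine distances in km with a fixed Earth radius of 6371 km.
#'
#' @param sites a `site_table` (columns `code`, `lat`, `lon`).
#' @return a `dist_matrix` of kind "geographic_km"; sites with missing
#'   coordinates are excluded with a warning.
#' @export
geo_distance_matrix <- function(sites) {
  ok <- !is.na(sites$lat) & !is.na(sites$lon)
  if (any(!ok))
    warning("sites without coordinates excluded: ",
            paste(sites$code[!ok], collapse = ", "))
  s <- sites[ok, ]
  R <- 6371
  lat <- s$lat * pi / 180; lon <- s$lon * pi / 180
  n <- nrow(s)
  m <- matrix(0, n, n, dimnames = list(s$code, s$code))
  for (i in seq_len(n)) {
    dlat <- lat - lat[i]; dlon <- lon - lon[i]
    h <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat) * sin(dlon / 2)^2
    m[i, ] <- 2 * R * asin(pmin(1, sqrt(h)))
  }
  m <- (m + t(m)) / 2
  dist_matrix(m, "geographic_km")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangle, with the
#' permutation null built by jointly shuffling rows and columns of the second
#' matrix. The one-sided p-value (alternative: positive association) carries
#' the +1 correction in numerator and denominator.
#'
#' @param x,y `dist_matrix` objects (or plain symmetric matrices) with the
#'   same site order.
#' @param n_perm number of permutations (default 10000, minimum 99).
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(x, y, n_perm = 10000) {
  if (n_perm < 99) stop("use at least 99 permutations")
  x <- unclass(as.matrix(x)); y <- unclass(as.matrix(y))
  if (!all(dim(x) == dim(y))) stop("matrices must have matching dimensions")
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y)))
    stop("matrices must share the same site order")
  ut <- upper.tri(x)
  if (stats::sd(x[ut]) == 0 || stats::sd(y[ut]) == 0)
    stop("Mantel correlation undefined for a constant matrix")
  r_obs <- stats::cor(x[ut], y[ut])
  n <- nrow(x)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    yp <- y[pm, pm]
    if (stats::cor(x[ut], yp[ut]) >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's algorithm with a deterministic tie-break: edges are sorted by
#' (weight, lexicographic site pair).
#'
#' @param m a `dist_matrix` (any kind) with finite values.
#' @return data.frame (`site_a`, `site_b`, `weight`) with n-1 rows,
#'   `site_a < site_b` within a row, rows in insertion order.
#' @export
minimum_spanning_tree <- function(m) {
  m <- unclass(as.matrix(m))
  n <- nrow(m)
  if (n < 2) stop("minimum spanning tree needs at least 2 sites")
  if (any(!is.finite(m[upper.tri(m)]))) stop("distance matrix must be finite")
  codes <- rownames(m)
  ij <- which(upper.tri(m), arr.ind = TRUE)
  a <- pmin(codes[ij[, 1]], codes[ij[, 2]])
  b <- pmax(codes[ij[, 1]], codes[ij[, 2]])
  w <- m[ij]
  ord <- order(w, a, b)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- list()
  for (e in ord) {
    ri <- find(ij[e, 1]); rj <- find(ij[e, 2])
    if (ri != rj) {
      parent[ri] <- rj
      edges[[length(edges) + 1]] <- data.frame(
        site_a = a[e], site_b = b[e], weight = w[e],
        stringsAsFactors = FALSE)
      if (length(edges) == n - 1) break
    }
  }
  do.call(rbind, edges)
}

#' Permutation contrast of pairwise F_ST between population classes
#'
#' Statistic: mean pairwise F_ST among category members minus mean pairwise
#' F_ST among the remaining sites (cross pairs excluded). The null shuffles
#' membership labels across sites; because pairwise F_ST values are not
#' independent, inference is by randomization only.
#'
#' @param m a `dist_matrix` of kind "fst" (or linearized).
#' @param members character vector of site codes forming the category, or a
#'   logical vector over `rownames(m)`.
#' @param n_perm number of label shuffles (default 1000).
#' @return list of class `contrast_result`: `mean_within`, `mean_rest`,
#'   `diff`, `p_one_sided` (category more differentiated), `p_two_sided`,
#'   `n_perm`, `n_members`.
#' @export
category_fst_contrast <- function(m, members, n_perm = 1000) {
  m <- unclass(as.matrix(m))
  codes <- rownames(m)
  lab <- if (is.logical(members)) members else codes %in% members
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop("both the category and the rest need at least 2 members")
  stat <- function(lab) {
    w <- m[lab, lab, drop = FALSE]
    r <- m[!lab, !lab, drop = FALSE]
    mean(w[upper.tri(w)], na.rm = TRUE) - mean(r[upper.tri(r)], na.rm = TRUE)
  }
  obs <- stat(lab)
  k <- sum(lab); n <- length(lab)
  hi <- 0L; hi2 <- 0L
  for (b in seq_len(n_perm)) {
    pl <- logical(n); pl[sample.int(n, k)] <- TRUE
    s <- stat(pl)
    if (s >= obs) hi <- hi + 1L
    if (abs(s) >= abs(obs)) hi2 <- hi2 + 1L
  }
  structure(list(mean_within = mean(m[lab, lab][upper.tri(m[lab, lab])],
                                    na.rm = TRUE),
                 mean_rest = mean(m[!lab, !lab][upper.tri(m[!lab, !lab])],
                                  na.rm = TRUE),
                 diff = obs,
                 p_one_sided = (hi + 1) / (n_perm + 1),
                 p_two_sided = (hi2 + 1) / (n_perm + 1),
                 n_perm = n_perm, n_members = k),
            class = "contrast_result")
}

#' Pairwise class contrasts of differentiation
#'
#' Runs [category_fst_contrast()] for every unordered pair of classes,
#' restricting the matrix to the two classes compared (one class is the
#' "category", the other the "rest").
#'
#' @param m a `dist_matrix`.
#' @param classes named character/factor vector: class per site code.
#' @param n_perm shuffles per contrast.
#' @return data.frame, one row per class pair.
#' @export
class_pair_contrasts <- function(m, classes, n_perm = 1000) {
  codes <- rownames(m)
  classes <- classes[codes]
  lv <- sort(unique(as.character(classes)))
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    pairset <- codes[classes %in% c(lv[i], lv[j])]
    sub <- unclass(m)[pairset, pairset]
    ct <- category_fst_contrast(dist_matrix(sub, attr(m, "kind")),
                                codes[classes == lv[i]], n_perm = n_perm)
    rows[[length(rows) + 1]] <- data.frame(
      class_a = lv[i], class_b = lv[j],
      mean_a = ct$mean_within, mean_b = ct$mean_rest, diff = ct$diff,
      p_one_sided = ct$p_one_sided, p_two_sided = ct$p_two_sided,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a square distance matrix as CSV (codes as header row/column)
#' @param m a `dist_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(as.matrix(m))), path)
  invisible(path)
}
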
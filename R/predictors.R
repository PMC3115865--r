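## local equirectangular projection (km) about the mean latitude
project_km <- function(lat, lon) {
  km_per_deg <- pi * 6371 / 180
  lat0 <- mean(lat) * pi / 180
  cbind(x = lon * cos(lat0) * km_per_deg, y = lat * km_per_deg)
}

## distance from point p to segment ab (all 2-vectors, planar)
point_segment_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

#' Distance of each site to the range margin
#'
#' The range margin is approximated by the convex hull (smallest enclosing
#' polygon) of all site coordinates; the geographic-marginality predictor
#' `lim` is each site's minimum planar distance to any hull edge, in km, on
#' a local equirectangular projection about the mean latitude. Hull vertices
#' have lim = 0.
#'
#' @param sites a `site_table`.
#' @return named numeric vector of distances (km); hull vertex codes in
#'   `attr(,"hull")`.
#' @export
distance_to_range_margin <- function(sites) {
  if (nrow(sites) < 3) stop("need at least 3 sites to build a range polygon")
  xy <- project_km(sites$lat, sites$lon)
  hull <- grDevices::chull(xy)
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (length(hull) < 3 || area < 1e-9)
    stop("sites are collinear; no polygon exists")
  lim <- vapply(seq_len(nrow(xy)), function(i) {
    d <- vapply(seq_along(hull), function(e) {
      a <- xy[hull[e], ]
      b <- xy[hull[if (e == length(hull)) 1 else e + 1], ]
      point_segment_dist(xy[i, ], a, b)
    }, numeric(1))
    min(d)
  }, numeric(1))
  lim[hull] <- 0
  stats::setNames(lim, sites$code)
}

#' Environmental marginality from climate variables
#'
#' Principal component analysis of the standardized (correlation-matrix)
#' climate columns; axes with eigenvalue > 1 (Kaiser criterion) are
#' retained, and each site's marginality `marg` is the Euclidean distance of
#' its scores from the origin of the retained axes. Sites near the
#' multivariate climate average therefore score near 0.
#'
#' @param sites a `site_table`.
#' @param cols climate columns to use; default [climate_columns()].
#' @param retention "kaiser" (eigenvalue > 1) or "broken-stick".
#' @return named vector `marg`; attributes `eigenvalues`, `n_retained`,
#'   `scores` (retained-axis score matrix), `dropped` (constant columns).
#' @export
environmental_marginality <- function(sites, cols = NULL,
                                      retention = c("kaiser", "broken-stick")) {
  retention <- match.arg(retention)
  if (is.null(cols)) cols <- climate_columns(sites)
  if (length(cols) < 2) stop("need at least 2 climate columns")
  x <- as.matrix(sites[cols])
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant climate column(s) dropped: ",
            paste(cols[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 informative climate columns")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  keep <- if (retention == "kaiser") which(ev > 1) else {
    p <- length(ev)
    bs <- rev(cumsum(1 / seq(p, 1))) / p   # broken-stick expected shares
    which(ev / sum(ev) > bs)
  }
  if (!length(keep)) keep <- 1L
  sc <- pc$x[, keep, drop = FALSE]
  marg <- sqrt(rowSums(sc^2))
  structure(stats::setNames(marg, sites$code), eigenvalues = ev,
            n_retained = length(keep), scores = sc,
            dropped = cols[const])
}

#' Binary quantile grouping of a continuous predictor
#'
#' Sites with values strictly above the q-th empirical quantile (type-7
#' interpolation) form the "marginal" group that is contrasted against the
#' remaining sites; the default q = 0.85 puts the top 15% in the marginal
#' group. Ties at the threshold fall in the reference group
#' (strictly-greater rule).
#'
#' @param values named numeric vector (names = site codes).
#' @param q quantile in (0, 1); default 0.85.
#' @return named logical vector (TRUE = marginal group); threshold in
#'   `attr(,"threshold")`.
#' @export
quantile_grouping <- function(values, q = 0.85) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  thr <- stats::quantile(values, q, type = 7, na.rm = TRUE, names = FALSE)
  out <- values > thr
  if (!any(out, na.rm = TRUE))
    warning("empty marginal group (all values tie at the threshold)")
  structure(out, threshold = thr)
}

#' Merge refugial and Holocene expansion classes when indistinguishable
#'
#' For each diversity measure, a two-sided permutation test compares the
#' ref and hol group means. If no measure rejects at `alpha`, the two
#' classes are merged into a single reference level and the factor becomes
#' {exp, ref+hol}; otherwise the three levels are kept. All p-values are
#' reported either way.
#'
#' @param div a [diversity_table()].
#' @param expansion named character vector (site code -> ref/hol/exp).
#' @param measures diversity columns to test.
#' @param n_perm permutations per measure (default 10000).
#' @param alpha significance level (default 0.05).
#' @return list: `merged` (logical), `factor` (named character vector, level
#'   "ref+hol" when merged), `p_values` (named numeric), `n_perm`.
#' @export
merge_expansion_levels <- function(div, expansion,
                                   measures = c("He", "A", "Hmt", "s"),
                                   n_perm = 10000, alpha = 0.05) {
  expansion <- expansion[div$site]
  if (!all(c("ref", "hol", "exp") %in% expansion))
    stop("all three expansion classes (ref/hol/exp) must be present")
  measures <- intersect(measures, names(div))
  measures <- measures[vapply(measures, function(m)
    any(!is.na(div[[m]])), logical(1))]
  ref_i <- which(expansion == "ref"); hol_i <- which(expansion == "hol")
  if (length(ref_i) < 2 || length(hol_i) < 2)
    stop("merge refused: ref and hol each need at least 2 sites")
  pv <- vapply(measures, function(m) {
    v <- div[[m]]
    idx <- c(ref_i, hol_i)
    v <- v[idx]; lab <- rep(c(TRUE, FALSE), c(length(ref_i), length(hol_i)))
    ok <- !is.na(v); v <- v[ok]; lab <- lab[ok]
    if (sum(lab) < 2 || sum(!lab) < 2) return(NA_real_)
    obs <- abs(mean(v[lab]) - mean(v[!lab]))
    k <- sum(lab)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pl <- logical(length(v)); pl[sample.int(length(v), k)] <- TRUE
      if (abs(mean(v[pl]) - mean(v[!pl])) >= obs) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  }, numeric(1))
  merged <- all(pv >= alpha, na.rm = TRUE)
  fac <- expansion
  if (merged) fac[fac %in% c("ref", "hol")] <- "ref+hol"
  list(merged = merged, factor = fac, p_values = pv, n_perm = n_perm)
}

#' Assemble the predictor table
#'
#' Builds the eight explanatory variables used to model the distribution of
#' genetic diversity: continuous `lim` (km to range margin) and `marg`
#' (climate-space distance), the curated binary factors `bar`, `bio`,
#' `size` (taken from the site table as data), the expansion class (with
#' the ref+hol merge rule applied against the diversity table), and the
#' 85%-quantile contrast groupings of `lim` and `marg`.
#'
#' @param sites a `site_table`.
#' @param div a [diversity_table()] (used by the merge rule).
#' @param q quantile for the contrast groupings (default 0.85).
#' @param merge apply the ref+hol merge rule (default TRUE).
#' @param n_perm permutations for the merge tests.
#' @return data.frame (`code`, `lim_km`, `marg`, `bar`, `bio`, `size`,
#'   `expansion`, `exp` 0/1 dummy, `lim_group`, `marg_group`); merge report
#'   in `attr(,"merge")`, PCA report in `attr(,"pca")`.
#' @export
predictor_table <- function(sites, div, q = 0.85, merge = TRUE,
                            n_perm = 10000) {
  lim <- distance_to_range_margin(sites)
  marg <- environmental_marginality(sites)
  expansion <- stats::setNames(sites$expansion, sites$code)
  merge_rep <- NULL
  if (merge) {
    merge_rep <- merge_expansion_levels(div, expansion, n_perm = n_perm)
    expansion <- stats::setNames(expansion, sites$code)
    if (merge_rep$merged)
      expansion[expansion %in% c("ref", "hol")] <- "ref+hol"
  }
  out <- data.frame(
    code = sites$code,
    lim_km = as.numeric(lim[sites$code]),
    marg = as.numeric(marg[sites$code]),
    bar = if ("bar" %in% names(sites)) sites$bar else 0L,
    bio = if ("bio" %in% names(sites)) sites$bio else 0L,
    size = if ("size" %in% names(sites)) sites$size else 0L,
    expansion = as.character(expansion[sites$code]),
    exp = as.integer(expansion[sites$code] == "exp"),
    stringsAsFactors = FALSE)
  out$lim_group <- as.logical(quantile_grouping(lim, q)[sites$code])
  out$marg_group <- as.logical(quantile_grouping(marg, q)[sites$code])
  attr(out, "merge") <- merge_rep
  attr(out, "pca") <- list(eigenvalues = attr(marg, "eigenvalues"),
                           n_retained = attr(marg, "n_retained"))
  out
}
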
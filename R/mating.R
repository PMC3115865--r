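## 0/1/NA heterozygosity matrix (individuals x loci) of a genotype table
het_matrix <- function(geno) {
  h <- (geno$a1 != geno$a2) * 1L
  h[is.na(geno$a1)] <- NA_integer_
  h
}

## identity-disequilibrium estimator on a heterozygosity matrix.
## For every locus pair (l, m): the within-individual joint heterozygosity
## rate is compared to the cross-individual product expectation; both are
## aggregated over pairs as ratios of sums (the multilocus combination),
## restricting each pair to individuals typed at the relevant loci:
##   g2 = sum_lm mean_i(h_il h_im) / sum_lm mean_{i != j}(h_il h_jm) - 1
g2_from_het <- function(h) {
  L <- ncol(h)
  num <- 0; den <- 0
  for (l in seq_len(L - 1)) for (m in seq(l + 1, L)) {
    hl <- h[, l]; hm <- h[, m]
    both <- !is.na(hl) & !is.na(hm)
    n_both <- sum(both)
    if (n_both < 2) next
    joint <- sum(hl[both] * hm[both]) / n_both
    sl <- sum(hl, na.rm = TRUE); sm <- sum(hm, na.rm = TRUE)
    nl <- sum(!is.na(hl)); nm <- sum(!is.na(hm))
    # sum over ordered pairs i != j with i typed at l, j typed at m
    cross_sum <- sl * sm - sum(hl[both] * hm[both])
    cross_n <- nl * nm - n_both
    if (cross_n < 1) next
    num <- num + joint
    den <- den + cross_sum / cross_n
  }
  if (den <= 0) return(structure(0, degenerate = TRUE))
  structure(num / den - 1, degenerate = FALSE)
}

#' Multilocus identity disequilibrium (g2)
#'
#' Standardized excess of joint heterozygosity across locus pairs: with
#' h_il the heterozygosity indicator of individual i at locus l, g2
#' aggregates P(het at l and m) / (P(het l) * P(het m)) - 1 over all locus
#' pairs as a ratio of sums, using cross-individual products for the
#' denominator so allele frequencies never enter (which is what makes the
#' estimator robust to null alleles and partial dominance). Positive g2 is
#' the signature of partial self-fertilization at inbreeding equilibrium.
#'
#' @param geno a [genotype_table()].
#' @param site site code; may be omitted when `geno` holds a single site.
#' @return g2 (single numeric) with attributes `degenerate` (logical: no
#'   heterozygosity variance available, g2 forced to 0), `n_ind`, `n_loci`.
#' @export
estimate_g2 <- function(geno, site = NULL) {
  g <- if (is.null(site)) geno else site_genotypes(geno, site)
  if (nrow(g$ind) < 5) stop("g2 needs at least 5 individuals")
  h <- het_matrix(g)
  informative <- colSums(h == 1, na.rm = TRUE) > 0 &
    colSums(h == 0, na.rm = TRUE) > 0
  if (sum(informative) < 2) {
    out <- structure(0, degenerate = TRUE)
  } else {
    out <- g2_from_het(h)
  }
  attr(out, "n_ind") <- nrow(g$ind)
  attr(out, "n_loci") <- ncol(h)
  out
}

#' Selfing rate from g2 at inbreeding equilibrium
#'
#' For unlinked loci under mixed mating at equilibrium the identity
#' disequilibrium is g2 = s / ((1 - s)(4 - s)) (the selfing-generations
#' argument of David et al. 2007), which inverts in closed form as the root
#' of a quadratic. The map is monotone non-decreasing; g2 <= 0 gives s = 0
#' and the estimate is clamped to [0, 1].
#'
#' @param g2 identity disequilibrium value(s).
#' @return selfing rate estimate(s) in [0, 1].
#' @export
selfing_from_g2 <- function(g2) {
  vapply(as.numeric(g2), function(g) {
    if (!is.finite(g) || g <= 0) return(0)
    disc <- (5 * g + 1)^2 - 16 * g^2
    if (disc < 0) return(1)
    s <- ((5 * g + 1) - sqrt(disc)) / (2 * g)
    min(max(s, 0), 1)
  }, numeric(1))
}

#' Permutation test for selfing (H0: g2 = 0)
#'
#' The null distribution of g2 is built by independently permuting each
#' locus's heterozygosity column among individuals, which destroys
#' across-locus identity correlations while preserving every per-locus
#' heterozygosity level. One-sided p for g2 > 0; "selfing inferred" at
#' p < 0.05.
#'
#' @param geno a [genotype_table()].
#' @param site site code; may be omitted when `geno` holds a single site.
#' @param n_perm number of permutations (default 1000, minimum 99).
#' @return list with `g2`, `s_hat`, `p`, `n_perm`, `n_ind`, `n_loci`,
#'   `degenerate`.
#' @export
test_selfing <- function(geno, site = NULL, n_perm = 1000) {
  if (n_perm < 99) stop("use at least 99 permutations")
  g <- if (is.null(site)) geno else site_genotypes(geno, site)
  g2 <- estimate_g2(g)
  if (attr(g2, "degenerate")) {
    return(list(g2 = 0, s_hat = 0, p = 1, n_perm = n_perm,
                n_ind = attr(g2, "n_ind"), n_loci = attr(g2, "n_loci"),
                degenerate = TRUE))
  }
  h <- het_matrix(g)
  n <- nrow(h)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    hp <- apply(h, 2, function(col) col[sample.int(n)])
    if (as.numeric(g2_from_het(hp)) >= as.numeric(g2)) hits <- hits + 1L
  }
  list(g2 = as.numeric(g2), s_hat = selfing_from_g2(g2),
       p = (hits + 1) / (n_perm + 1), n_perm = n_perm,
       n_ind = attr(g2, "n_ind"), n_loci = attr(g2, "n_loci"),
       degenerate = FALSE)
}

#' Per-site selfing estimates
#'
#' Runs [test_selfing()] on every site with at least `min_ind` genotyped
#' individuals.
#'
#' @param geno a [genotype_table()].
#' @param min_ind inclusion threshold (default 7, the diversity floor).
#' @param n_perm permutations per site.
#' @return data.frame (`site`, `g2`, `s_hat`, `p`, `selfing_inferred`,
#'   `n_ind`, `n_loci`).
#' @export
selfing_table <- function(geno, min_ind = 7, n_perm = 1000) {
  cnt <- table(geno$ind$site)
  keep <- geno_sites(geno)[geno_sites(geno) %in% names(cnt)[cnt >= min_ind]]
  rows <- lapply(keep, function(s) {
    ts <- test_selfing(geno, s, n_perm = n_perm)
    data.frame(site = s, g2 = ts$g2, s_hat = ts$s_hat, p = ts$p,
               selfing_inferred = ts$p < 0.05, n_ind = ts$n_ind,
               n_loci = ts$n_loci, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
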
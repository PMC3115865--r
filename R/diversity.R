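#' Unbiased expected heterozygosity (gene diversity) for one site
#'
#' Per locus, with n non-missing gene copies and allele frequencies p_i, the
#' unbiased gene diversity is n/(n-1) * (1 - sum p_i^2) (Nei's estimator, the
#' convention of the standard AMOVA software). The site value is the
#' unweighted mean over loci with at least two gene copies.
#'
#' @param geno a [genotype_table()].
#' @param site site code; may be omitted when `geno` holds a single site.
#' @return list with `per_locus` (named vector, `NA` for loci with < 2 gene
#'   copies), `mean`, `sd` (across loci) and `n_loci` used.
#' @export
expected_heterozygosity <- function(geno, site = NULL) {
  g <- if (is.null(site)) geno else site_genotypes(geno, site)
  per <- vapply(seq_along(g$loci), function(l) {
    x <- c(g$a1[, l], g$a2[, l]); x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) return(NA_real_)
    p <- tabulate(match(x, unique(x))) / n
    n / (n - 1) * (1 - sum(p^2))
  }, numeric(1))
  names(per) <- g$loci
  ok <- !is.na(per)
  list(per_locus = per, mean = mean(per[ok]),
       sd = stats::sd(per[ok]), n_loci = sum(ok))
}

## hypergeometric expectation of distinct classes in a subsample of size g
rarefy_counts <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g > N) stop("rarefaction depth g exceeds the available ", N, " copies")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefied allelic richness for one site
#'
#' Standardizes the mean number of alleles per locus to a common number of
#' gene copies `g` using the hypergeometric expectation
#' E(A_g) = sum_i (1 - choose(N - N_i, g)/choose(N, g)) over alleles i with
#' count N_i among the N non-missing copies at the locus. Loci with fewer
#' than `g` copies are excluded with a warning.
#'
#' @param geno a [genotype_table()].
#' @param site site code; may be omitted when `geno` holds a single site.
#' @param g rarefaction depth in gene copies (default 14 = 2 x the 7
#'   individual inclusion floor for diversity statistics).
#' @return list with `per_locus`, `mean`, `sd`, `n_loci`, `g`.
#' @export
rarefied_allelic_richness <- function(geno, site = NULL, g = 14) {
  if (g < 2) stop("rarefaction depth g must be at least 2")
  gt <- if (is.null(site)) geno else site_genotypes(geno, site)
  per <- vapply(seq_along(gt$loci), function(l) {
    x <- c(gt$a1[, l], gt$a2[, l]); x <- x[!is.na(x)]
    if (length(x) < g) return(NA_real_)
    rarefy_counts(table(x), g)
  }, numeric(1))
  names(per) <- gt$loci
  if (anyNA(per))
    warning(sum(is.na(per)), " locus/loci with fewer than ", g,
            " gene copies excluded from rarefied richness")
  ok <- !is.na(per)
  list(per_locus = per, mean = mean(per[ok]), sd = stats::sd(per[ok]),
       n_loci = sum(ok), g = g)
}

#' Rarefied haplotype richness
#'
#' The same hypergeometric rarefaction applied to mitochondrial haplotype
#' counts of one site: expected number of distinct haplotypes in a subsample
#' of `g` sequences.
#'
#' @param counts named vector of per-haplotype counts for one site.
#' @param g subsample size (sequences).
#' @return expected number of distinct haplotypes, a single numeric.
#' @export
rarefied_haplotype_richness <- function(counts, g) {
  if (g < 1) stop("rarefaction depth g must be at least 1")
  rarefy_counts(counts, g)
}

#' Per-site diversity table
#'
#' Computes expected heterozygosity and rarefied allelic richness for every
#' site with at least `min_ind` genotyped individuals, and rarefied haplotype
#' richness for sequenced sites. Selfing estimates and bottleneck flags are
#' filled by the mating/bottleneck stages.
#'
#' @param geno a [genotype_table()].
#' @param haps optional `haplotype_table`.
#' @param min_ind minimum genotyped individuals for inclusion (default 7).
#' @param g nuclear rarefaction depth in gene copies; default `2 * min_ind`.
#' @param g_mt mitochondrial rarefaction depth in sequences; default = the
#'   smallest per-site sequence total among sequenced sites.
#' @return data.frame with one row per included site: `site`, `n_nuc`, `He`,
#'   `He_sd`, `A`, `A_sd`, `n_mt`, `Hmt`, `s`, `s_p`, `bottleneck`.
#' @export
diversity_table <- function(geno, haps = NULL, min_ind = 7, g = NULL,
                            g_mt = NULL) {
  if (is.null(g)) g <- 2 * min_ind
  cnt <- table(geno$ind$site)
  keep <- names(cnt)[cnt >= min_ind]
  keep <- geno_sites(geno)[geno_sites(geno) %in% keep]
  if (!length(keep)) stop("no site reaches ", min_ind, " genotyped individuals")
  rows <- lapply(keep, function(s) {
    he <- expected_heterozygosity(geno, s)
    ar <- suppressWarnings(rarefied_allelic_richness(geno, s, g = g))
    data.frame(site = s, n_nuc = as.integer(cnt[[s]]),
               He = he$mean, He_sd = he$sd, A = ar$mean, A_sd = ar$sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n_mt <- NA_integer_; out$Hmt <- NA_real_
  if (!is.null(haps)) {
    tot <- tapply(haps$count, haps$site, sum)
    if (is.null(g_mt)) g_mt <- max(1L, min(tot))
    for (i in seq_len(nrow(out))) {
      s <- out$site[i]
      if (s %in% names(tot) && tot[[s]] >= g_mt) {
        out$n_mt[i] <- as.integer(tot[[s]])
        out$Hmt[i] <- rarefied_haplotype_richness(
          site_haplotype_counts(haps, s), g_mt)
      }
    }
    attr(out, "g_mt") <- g_mt
  }
  out$s <- NA_real_; out$s_p <- NA_real_; out$bottleneck <- NA
  attr(out, "g") <- g
  attr(out, "min_ind") <- min_ind
  out
}

#' Group deviation summary of diversity measures
#'
#' For each (possibly overlapping) group of sites, the mean and standard
#' deviation of every measure, next to the overall mean over all sites — the
#' grouped-deviation view of how predictor classes depart from the range-wide
#' average. Pearson correlations among the measures are attached.
#'
#' @param div a [diversity_table()] (or any data.frame with a `site` column
#'   and numeric measure columns).
#' @param grouping named list of character vectors of site codes; groups may
#'   overlap and need not cover all sites.
#' @param measures numeric columns to summarise.
#' @return data.frame (`group`, `measure`, `n`, `mean`, `sd`,
#'   `overall_mean`); matrix of pairwise Pearson correlations in
#'   `attr(,"correlations")`.
#' @export
group_deviation_summary <- function(div, grouping,
                                    measures = c("He", "A", "s", "Hmt")) {
  measures <- intersect(measures, names(div))
  measures <- measures[vapply(div[measures], is.numeric, logical(1))]
  overall <- vapply(measures, function(m) mean(div[[m]], na.rm = TRUE),
                    numeric(1))
  rows <- list()
  for (gname in names(grouping)) {
    idx <- div$site %in% grouping[[gname]]
    for (m in measures) {
      v <- div[[m]][idx]; v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        group = gname, measure = m, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        overall_mean = overall[[m]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # constant measures yield NA correlations, which is fine for a summary
  cors <- suppressWarnings(stats::cor(div[measures],
                                      use = "pairwise.complete.obs"))
  attr(out, "correlations") <- cors
  out
}

#' Summarise a per-site diversity table
#'
#' Range-wide summary of a diversity table (means of expected heterozygosity,
#' rarefied allelic richness and rarefied haplotype richness, plus the
#' Pearson correlation between heterozygosity and allelic richness), in the
#' shape the per-site supplementary tables of range-wide surveys report.
#'
#' @param div a [diversity_table()] or a CSV path in the same column layout.
#' @return named list: `mean_He`, `mean_A`, `mean_Hmt`, `r_He_A`, `n_sites`.
#' @export
diversity_summary <- function(div) {
  if (is.character(div)) div <- utils::read.csv(div, stringsAsFactors = FALSE)
  list(mean_He = mean(div$He, na.rm = TRUE),
       mean_A = mean(div$A, na.rm = TRUE),
       mean_Hmt = mean(div$Hmt, na.rm = TRUE),
       r_He_A = stats::cor(div$He, div$A, use = "complete.obs"),
       n_sites = nrow(div))
}

#' Write a diversity table as CSV
#' @param div a [diversity_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity_csv <- function(div, path) {
  utils::write.csv(div, path, row.names = FALSE)
  invisible(path)
}
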
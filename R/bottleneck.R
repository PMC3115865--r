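## one coalescent genealogy of n gene copies with stepwise mutations:
## returns the n leaf allele states (integer repeat scores, root = 0)
sim_coalescent_tpm <- function(n, theta, p_ss = 0.9, geom_q = 0.25) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  t_node <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0; nxt <- n + 1L
  for (j in seq(n, 2)) {
    t <- t + stats::rexp(1, j * (j - 1) / 2)
    pick <- sample.int(j, 2)
    parent[active[pick]] <- nxt
    t_node[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  state <- numeric(n_nodes)
  blen <- t_node[parent]; blen[n_nodes] <- 0
  blen <- blen - t_node
  nmut <- stats::rpois(n_nodes, theta / 2 * pmax(blen, 0))
  nmut[n_nodes] <- 0L
  # apply mutations top-down so children inherit their parent's final state
  for (v in seq(n_nodes - 1L, 1L)) {
    delta <- 0
    if (nmut[v] > 0) {
      mag <- ifelse(stats::runif(nmut[v]) < p_ss, 1,
                    1 + stats::rgeom(nmut[v], geom_q))
      delta <- sum(mag * sample(c(-1, 1), nmut[v], replace = TRUE))
    }
    state[v] <- state[parent[v]] + delta
  }
  state[seq_len(n)]
}

## unbiased gene diversity of an allele-state sample
gene_diversity <- function(x) {
  n <- length(x)
  p <- tabulate(match(x, unique(x))) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Equilibrium gene-diversity distribution under the two-phase mutation model
#'
#' Coalescent simulation of `n` gene copies mutating under the two-phase
#' model (probability `p_ss` of a single repeat step, otherwise a geometric
#' multi-step change), conditioned by rejection on the realized number of
#' distinct alleles equalling `k`. The mutation parameter theta is adapted
#' between batches toward the acceptance region. This is the mutation-drift
#' equilibrium reference of the heterozygosity-excess bottleneck test.
#'
#' @param n number of gene copies (2 x individuals typed at the locus).
#' @param k observed number of distinct alleles (2 <= k <= n).
#' @param p_ss single-step proportion of the TPM (default 0.9).
#' @param var_geom variance of the multi-step geometric component (default
#'   12, giving geometric success probability 0.25).
#' @param n_reps number of accepted equilibrium samples (default 1000).
#' @param max_attempts cap on total simulations before giving up.
#' @return list with `h` (vector of `n_reps` equilibrium gene diversities),
#'   `theta` (last adapted value), `attempts`.
#' @export
simulate_heq <- function(n, k, p_ss = 0.9, var_geom = 12, n_reps = 1000,
                         max_attempts = 400 * n_reps) {
  if (k > n) stop("k alleles cannot exceed n gene copies")
  if (k < 2) stop("monomorphic locus (k = 1) is uninformative; skip it")
  # geometric on {1,2,...}: var = (1-q)/q^2  =>  q solves q^2*v + q - 1 = 0
  geom_q <- (-1 + sqrt(1 + 4 * var_geom)) / (2 * var_geom)
  # IAM-based starting theta: E[k] = sum theta/(theta+i), i = 0..n-1
  f <- function(th) sum(th / (th + 0:(n - 1))) - k
  theta <- if (f(0.01) > 0) 0.01
    else if (f(1e4) < 0) 1e4
    else stats::uniroot(f, c(0.01, 1e4))$root
  h <- numeric(n_reps)
  got <- 0L; attempts <- 0L; recent_k <- numeric(0)
  while (got < n_reps && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- sim_coalescent_tpm(n, theta, p_ss, geom_q)
    kr <- length(unique(x))
    recent_k <- c(recent_k, kr)
    if (kr == k) {
      got <- got + 1L
      h[got] <- gene_diversity(x)
    }
    if (length(recent_k) >= 50 && got < n_reps) {
      # damped multiplicative adaptation toward the target allele count
      theta <- theta * (k / max(mean(recent_k), 0.5))^0.5
      recent_k <- numeric(0)
    }
  }
  if (got < n_reps)
    stop(sprintf(
      "could not condition on k = %d with n = %d after %d attempts", k, n,
      attempts))
  list(h = h, theta = theta, attempts = attempts)
}

## one-tailed Wilcoxon signed-rank p on the standardized differences; the
## exact distribution only without ties/zeros (discrete genotype data can
## produce identical DH across loci), otherwise the normal approximation
signed_rank_p <- function(dh, alternative) {
  exact <- length(dh) <= 15 && !any(duplicated(abs(dh))) && all(dh != 0)
  stats::wilcox.test(dh, mu = 0, alternative = alternative, exact = exact,
                     correct = !exact)$p.value
}

#' Heterozygosity-excess bottleneck test for one site
#'
#' For each polymorphic locus, the observed unbiased gene diversity is
#' compared with its simulated mutation-drift equilibrium distribution given
#' the observed allele count (via [simulate_heq()]), yielding a standardized
#' difference DH = (H_obs - mean H_eq) / sd H_eq. A one-tailed Wilcoxon
#' signed-rank test (exact for <= 15 loci) on the DH values detects the
#' transient heterozygosity excess that follows a recent reduction in
#' effective population size. Mixed mating biases the equilibrium, so the
#' pipeline applies this test only to populations with an estimated selfing
#' rate of zero.
#'
#' @param geno a [genotype_table()].
#' @param site site code; may be omitted when `geno` holds a single site.
#' @param p_ss,var_geom TPM parameters (see [simulate_heq()]).
#' @param n_reps equilibrium samples per locus.
#' @param alpha significance level for the excess flag (default 0.05).
#' @param cache optional environment memoising equilibrium distributions by
#'   (n, k, TPM) key; share one across sites for large batches.
#' @return list of class `bottleneck_result`: `site`, per-locus data.frame
#'   (`locus`, `n`, `k`, `H_obs`, `H_eq_mean`, `H_eq_sd`, `DH`), `p_excess`,
#'   `p_deficiency`, `significant`, `n_loci_used`; or with `reason` set when
#'   fewer than 4 usable loci exist.
#' @export
heterozygosity_excess_test <- function(geno, site = NULL, p_ss = 0.9,
                                       var_geom = 12, n_reps = 1000,
                                       alpha = 0.05, cache = NULL) {
  g <- if (is.null(site)) geno else site_genotypes(geno, site)
  site_code <- unique(g$ind$site)
  per <- list()
  for (l in seq_along(g$loci)) {
    x <- c(g$a1[, l], g$a2[, l]); x <- x[!is.na(x)]
    n <- length(x); k <- length(unique(x))
    if (k < 2 || n < 4) next
    key <- sprintf("n%d_k%d_p%g_v%g_r%d", n, k, p_ss, var_geom, n_reps)
    heq <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else {
      sm <- simulate_heq(n, k, p_ss, var_geom, n_reps)
      val <- c(mean = mean(sm$h), sd = stats::sd(sm$h))
      if (!is.null(cache)) cache[[key]] <- val
      val
    }
    if (heq[["sd"]] <= 0) next
    hobs <- gene_diversity(x)
    per[[length(per) + 1]] <- data.frame(
      locus = g$loci[l], n = n, k = k, H_obs = hobs,
      H_eq_mean = heq[["mean"]], H_eq_sd = heq[["sd"]],
      DH = (hobs - heq[["mean"]]) / heq[["sd"]], stringsAsFactors = FALSE)
  }
  if (length(per) < 4)
    return(structure(list(site = site_code, loci = NULL, p_excess = NA_real_,
                          p_deficiency = NA_real_, significant = NA,
                          n_loci_used = length(per),
                          reason = "fewer than 4 polymorphic loci"),
                     class = "bottleneck_result"))
  loci <- do.call(rbind, per)
  p_ex <- signed_rank_p(loci$DH, "greater")
  p_def <- signed_rank_p(loci$DH, "less")
  structure(list(site = site_code, loci = loci, p_excess = p_ex,
                 p_deficiency = p_def, significant = p_ex < alpha,
                 n_loci_used = nrow(loci), reason = NULL),
            class = "bottleneck_result")
}

#' Bottleneck tests across sites, gated on zero selfing
#'
#' Applies [heterozygosity_excess_test()] to every site whose estimated
#' selfing rate is zero (the mixed-mating gate), sharing one equilibrium
#' cache across sites.
#'
#' @param geno a [genotype_table()].
#' @param selfing a [selfing_table()] (columns `site`, `s_hat`).
#' @param ... passed to [heterozygosity_excess_test()].
#' @return data.frame (`site`, `n_loci_used`, `wilcoxon_p`, `significant`,
#'   `reason`).
#' @export
bottleneck_table <- function(geno, selfing, ...) {
  eligible <- selfing$site[selfing$s_hat == 0]
  cache <- new.env(parent = emptyenv())
  rows <- lapply(eligible, function(s) {
    bt <- heterozygosity_excess_test(geno, s, cache = cache, ...)
    data.frame(site = s, n_loci_used = bt$n_loci_used,
               wilcoxon_p = bt$p_excess, significant = bt$significant,
               reason = if (is.null(bt$reason)) "" else bt$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
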
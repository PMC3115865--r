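# Independent oracles used to freeze expected values: brute-force
# enumerations and closed forms, deliberately naive and separate from the
# package's computational paths.

# expected number of distinct classes in a subsample of size g, by
# exhaustive enumeration of all C(N, g) subsamples (N <= 12 or so)
enum_rarefaction <- function(counts, g) {
  pool <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(pool), g)
  mean(apply(subs, 2, function(ix) length(unique(pool[ix]))))
}

# minimum spanning-tree weight by enumeration of all edge subsets of size
# n-1 that span the graph
brute_mst_weight <- function(m) {
  n <- nrow(m)
  ij <- which(upper.tri(m), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(ij), n - 1, simplify = FALSE)) {
    # connectivity check by label propagation
    comp <- seq_len(n)
    for (e in sel) {
      a <- comp[ij[e, 1]]; b <- comp[ij[e, 2]]
      if (a != b) comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1) {
      w <- sum(m[ij[sel, , drop = FALSE]])
      if (w < best) best <- w
    }
  }
  best
}

# one-tailed (excess) signed-rank p by enumeration of all 2^n sign
# assignments of the absolute values (no ties assumed)
enum_signed_rank_p <- function(dh) {
  n <- length(dh)
  r <- rank(abs(dh))
  w_obs <- sum(r[dh > 0])
  total <- 2^n
  count <- 0
  for (mask in 0:(total - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    if (sum(r[signs]) >= w_obs) count <- count + 1
  }
  count / total
}

# naive identity-disequilibrium estimator: explicit double loops over
# individuals for every locus pair
naive_g2 <- function(h) {
  L <- ncol(h); n <- nrow(h)
  num <- 0; den <- 0
  for (l in seq_len(L - 1)) for (m in seq(l + 1, L)) {
    s_joint <- 0; n_joint <- 0
    s_cross <- 0; n_cross <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) {
        if (!is.na(h[i, l]) && !is.na(h[i, m])) {
          s_joint <- s_joint + h[i, l] * h[i, m]
          n_joint <- n_joint + 1
        }
      } else if (!is.na(h[i, l]) && !is.na(h[j, m])) {
        s_cross <- s_cross + h[i, l] * h[j, m]
        n_cross <- n_cross + 1
      }
    }
    if (n_joint >= 2 && n_cross >= 1) {
      num <- num + s_joint / n_joint
      den <- den + s_cross / n_cross
    }
  }
  if (den <= 0) return(0)
  num / den - 1
}

# random-mating (HWE) genotype sampler at given allele frequencies;
# independent of the package's forward simulator
hwe_genotypes <- function(n_ind, freqs_by_locus, site = "P1") {
  L <- length(freqs_by_locus)
  a1 <- a2 <- matrix(NA_integer_, n_ind, L)
  for (l in seq_len(L)) {
    p <- freqs_by_locus[[l]]
    a1[, l] <- sample.int(length(p), n_ind, replace = TRUE, prob = p)
    a2[, l] <- sample.int(length(p), n_ind, replace = TRUE, prob = p)
  }
  genotype_table(sprintf("%s_i%03d", site, seq_len(n_ind)),
                 rep(site, n_ind), sprintf("L%d", seq_len(L)), a1, a2)
}

# combine several single-site genotype tables
bind_geno <- function(...) {
  gs <- list(...)
  genotype_table(unlist(lapply(gs, function(g) g$ind$id)),
                 unlist(lapply(gs, function(g) g$ind$site)),
                 gs[[1]]$loci,
                 do.call(rbind, lapply(gs, function(g) g$a1)),
                 do.call(rbind, lapply(gs, function(g) g$a2)))
}

# random symmetric distance-like matrix with zero diagonal
random_dist_matrix <- function(n, codes = sprintf("S%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(codes, codes))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}
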
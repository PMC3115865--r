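#' Construct a simulation scenario
#'
#' Parameters of the forward-time metapopulation model: non-overlapping
#' generations; within each deme every offspring is produced by selfing with
#' probability `s[d]`, else by random outcrossing; microsatellites mutate at
#' rate `mu` under a two-phase model (single repeat step with probability
#' `p_ss`, else a geometric multi-step change); mtDNA is maternally
#' inherited with infinite-alleles mutation at `mu_mt`; after reproduction
#' each individual is replaced, with probability `m`, by a migrant drawn
#' from a uniformly random other deme (distance-independent jump
#' dispersal). Demes with `founding_gen > 0` are founded at that generation
#' by `founder_n` individuals from a random existing deme and then grow by
#' a factor `growth` per generation up to their target size.
#'
#' All fields are deterministic data; every random draw happens inside
#' [simulate_metapopulation()] under its seed.
#'
#' @param n_demes number of demes.
#' @param N target census sizes (scalar or vector).
#' @param s per-deme selfing rates in [0, 1] (scalar or vector).
#' @param m jump-dispersal (migration) rate per individual per generation.
#' @param n_loci,mu,p_ss,var_geom microsatellite count and TPM mutation
#'   parameters.
#' @param mu_mt mtDNA mutation rate (infinite alleles).
#' @param generations number of generations to run.
#' @param founding_gen per-deme founding generation (0 = present at start).
#' @param founder_n founder count for late-founded demes (default 2).
#' @param growth per-generation growth factor while below target size.
#' @param lat,lon deme coordinates (decimal degrees).
#' @param expansion,bar,bio,size_class per-deme category assignments.
#' @param sample_n,sample_n_mt per-deme nuclear/mt sample sizes at output.
#' @param miss_rate missing-call rate injected into the genotype output.
#' @param n_alleles_init,n_mt_init initial allele/haplotype pool sizes.
#' @param n_clim,clim_sd climate covariates: each column is a linear
#'   function of latitude plus Gaussian noise of sd `clim_sd`.
#' @param bottlenecks optional data.frame (`deme`, `gen`, `size`,
#'   `duration`): deme crashes to `size` for `duration` generations.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_demes, N = 50, s = 0, m = 0.03, n_loci = 8,
                         mu = 5e-3, p_ss = 0.9, var_geom = 12, mu_mt = 5e-3,
                         generations = 150, founding_gen = 0, founder_n = 2,
                         growth = 5, lat = NULL, lon = NULL,
                         expansion = NULL, bar = NULL, bio = NULL,
                         size_class = NULL, sample_n = 20, sample_n_mt = 12,
                         miss_rate = 0.02, n_alleles_init = 12,
                         n_mt_init = 80, n_clim = 6, clim_sd = 1,
                         bottlenecks = NULL) {
  rln <- function(x, what) {
    x <- rep_len(x, n_demes)
    x
  }
  if (is.null(lat)) lat <- 43 + 15 * (seq_len(n_demes) - 1) / max(1, n_demes - 1) +
      1.5 * sin(seq_len(n_demes) * 2.399963)
  if (is.null(lon)) lon <- -2 + 20 * (seq_len(n_demes) - 1) / max(1, n_demes - 1) +
      1.5 * cos(seq_len(n_demes) * 2.399963)
  sc <- list(n_demes = n_demes, N = rln(N), s = pmin(pmax(rln(s), 0), 1),
             m = m, n_loci = n_loci, mu = mu, p_ss = p_ss,
             var_geom = var_geom, mu_mt = mu_mt, generations = generations,
             founding_gen = rln(founding_gen), founder_n = rln(founder_n),
             growth = growth, lat = rep_len(lat, n_demes),
             lon = rep_len(lon, n_demes),
             expansion = if (is.null(expansion)) rep("hol", n_demes)
               else rep_len(expansion, n_demes),
             bar = if (is.null(bar)) rep_len(c(0L, 0L, 0L, 1L), n_demes)
               else rep_len(bar, n_demes),
             bio = if (is.null(bio)) rep_len(c(0L, 1L, 0L, 0L, 0L), n_demes)
               else rep_len(bio, n_demes),
             size_class = if (is.null(size_class))
               rep_len(c(0L, 1L), n_demes) else rep_len(size_class, n_demes),
             sample_n = rln(sample_n), sample_n_mt = rln(sample_n_mt),
             miss_rate = miss_rate, n_alleles_init = n_alleles_init,
             n_mt_init = n_mt_init, n_clim = n_clim, clim_sd = clim_sd,
             bottlenecks = bottlenecks)
  if (all(sc$founding_gen > 0))
    stop("infeasible founding order: no deme exists at generation 0")
  if (any(sc$N < 2)) stop("deme target sizes must be at least 2")
  if (any(sc$founding_gen > generations))
    stop("founding generation beyond the simulated horizon")
  class(sc) <- "sim_scenario"
  sc
}

## one round of TPM mutation applied in place to an allele matrix
mutate_tpm <- function(A, mu, p_ss, geom_q) {
  idx <- which(stats::runif(length(A)) < mu)
  if (length(idx)) {
    mag <- ifelse(stats::runif(length(idx)) < p_ss, 1,
                  1 + stats::rgeom(length(idx), geom_q))
    A[idx] <- pmin(999L, pmax(2L, A[idx] +
      as.integer(mag * sample(c(-1L, 1L), length(idx), replace = TRUE))))
  }
  A
}

#' Run the forward-time metapopulation simulation
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @return list with `geno` ([genotype_table()]), `haps`
#'   (`haplotype_table`), `sites` (`site_table` with climate columns and
#'   category factors) and `truth` (per-deme true selfing rates, founding
#'   generations, bottleneck history and the global parameters).
#' @export
simulate_metapopulation <- function(scenario, seed) {
  sc <- scenario
  set.seed(seed, kind = "Mersenne-Twister")
  L <- sc$n_loci
  geom_q <- (-1 + sqrt(1 + 4 * sc$var_geom)) / (2 * sc$var_geom)
  codes <- sprintf("S%02d", seq_len(sc$n_demes))

  sizes <- integer(sc$n_demes)
  init <- which(sc$founding_gen == 0)
  sizes[init] <- sc$N[init]
  M <- sum(sizes)
  dv <- rep(init, sizes[init])
  # shared ancestral allele pool: uniform over n_alleles_init repeat states
  A1 <- matrix(100L + sample.int(sc$n_alleles_init, M * L, replace = TRUE) - 1L,
               M, L)
  A2 <- matrix(100L + sample.int(sc$n_alleles_init, M * L, replace = TRUE) - 1L,
               M, L)
  mt <- sample.int(sc$n_mt_init, M, replace = TRUE)
  mt_counter <- sc$n_mt_init

  for (gen in seq_len(sc$generations)) {
    newly <- which(sc$founding_gen == gen)
    if (length(newly)) {
      for (d in newly) {
        active <- which(sizes > 0)
        if (!length(active)) stop("infeasible founding: no source deme alive")
        src <- active[sample.int(length(active), 1)]
        pick <- which(dv == src)[sample.int(sizes[src],
                                            min(sc$founder_n[d], sizes[src]),
                                            replace = FALSE)]
        dv <- c(dv, rep(d, length(pick)))
        A1 <- rbind(A1, A1[pick, , drop = FALSE])
        A2 <- rbind(A2, A2[pick, , drop = FALSE])
        mt <- c(mt, mt[pick])
        sizes[d] <- length(pick)
      }
      ord <- order(dv)
      dv <- dv[ord]; A1 <- A1[ord, , drop = FALSE]
      A2 <- A2[ord, , drop = FALSE]; mt <- mt[ord]
    }
    active <- which(sizes > 0)
    nxt <- sizes
    nxt[active] <- pmin(sc$N[active],
                        as.integer(ceiling(sizes[active] * sc$growth)))
    if (!is.null(sc$bottlenecks)) {
      bn <- sc$bottlenecks
      hit <- bn$gen <= gen & gen < bn$gen + bn$duration
      nxt[bn$deme[hit]] <- pmin(nxt[bn$deme[hit]], bn$size[hit])
    }
    start_cur <- integer(sc$n_demes)
    start_cur[active] <- cumsum(c(0L, sizes[active]))[seq_along(active)]
    dv_new <- rep(active, nxt[active])
    Mn <- length(dv_new)
    szv <- sizes[dv_new]; base <- start_cur[dv_new]
    mothers <- base + as.integer(floor(stats::runif(Mn) * szv)) + 1L
    fathers <- base + as.integer(floor(stats::runif(Mn) * szv)) + 1L
    selfv <- stats::runif(Mn) < sc$s[dv_new] | szv == 1L
    fathers[selfv] <- mothers[selfv]
    A1n <- matrix(0L, Mn, L); A2n <- matrix(0L, Mn, L)
    for (l in seq_len(L)) {
      u <- stats::runif(Mn) < 0.5
      A1n[, l] <- ifelse(u, A1[mothers, l], A2[mothers, l])
      u <- stats::runif(Mn) < 0.5
      A2n[, l] <- ifelse(u, A1[fathers, l], A2[fathers, l])
    }
    if (sc$mu > 0) {
      A1n <- mutate_tpm(A1n, sc$mu, sc$p_ss, geom_q)
      A2n <- mutate_tpm(A2n, sc$mu, sc$p_ss, geom_q)
    }
    mt_new <- mt[mothers]
    if (sc$mu_mt > 0) {
      mmut <- which(stats::runif(Mn) < sc$mu_mt)
      if (length(mmut)) {
        mt_new[mmut] <- mt_counter + seq_along(mmut)
        mt_counter <- mt_counter + length(mmut)
      }
    }
    if (sc$m > 0 && length(active) > 1) {
      mig <- which(stats::runif(Mn) < sc$m)
      if (length(mig)) {
        k <- length(active)
        start_new <- integer(sc$n_demes)
        start_new[active] <- cumsum(c(0L, nxt[active]))[seq_along(active)]
        pos_own <- match(dv_new[mig], active)
        r <- as.integer(floor(stats::runif(length(mig)) * (k - 1))) + 1L
        r <- ifelse(r >= pos_own, r + 1L, r)
        src <- active[r]
        pick <- start_new[src] +
          as.integer(floor(stats::runif(length(mig)) * nxt[src])) + 1L
        A1n[mig, ] <- A1n[pick, , drop = FALSE]
        A2n[mig, ] <- A2n[pick, , drop = FALSE]
        mt_new[mig] <- mt_new[pick]
      }
    }
    dv <- dv_new; A1 <- A1n; A2 <- A2n; mt <- mt_new
    sizes <- nxt
  }

  # --- sample the final generation -------------------------------------
  active <- which(sizes > 0)
  start_cur <- integer(sc$n_demes)
  start_cur[active] <- cumsum(c(0L, sizes[active]))[seq_along(active)]
  ids <- character(); sitev <- character(); rows <- integer()
  mt_site <- character(); mt_hap <- character()
  for (d in active) {
    ns <- min(sc$sample_n[d], sizes[d])
    pick <- start_cur[d] + sample.int(sizes[d], ns)
    ids <- c(ids, sprintf("%s_%03d", codes[d], seq_len(ns)))
    sitev <- c(sitev, rep(codes[d], ns))
    rows <- c(rows, pick)
    nm <- min(sc$sample_n_mt[d], sizes[d])
    pickm <- start_cur[d] + sample.int(sizes[d], nm)
    mt_site <- c(mt_site, rep(codes[d], nm))
    mt_hap <- c(mt_hap, sprintf("MT%05d", mt[pickm]))
  }
  ga1 <- A1[rows, , drop = FALSE]; ga2 <- A2[rows, , drop = FALSE]
  if (sc$miss_rate > 0) {
    miss <- matrix(stats::runif(length(ga1)) < sc$miss_rate, nrow(ga1))
    # never wipe an individual's last typed locus
    wipe <- rowSums(!miss) == 0
    miss[wipe, 1] <- FALSE
    ga1[miss] <- NA_integer_; ga2[miss] <- NA_integer_
  }
  geno <- genotype_table(ids, sitev, sprintf("loc%d", seq_len(L)), ga1, ga2)
  haps <- haplotype_table(mt_site, mt_hap)

  lat <- sc$lat[active]; lon <- sc$lon[active]
  clim <- do.call(cbind, lapply(seq_len(sc$n_clim), function(j) {
    beta <- seq(-1.5, 1.5, length.out = sc$n_clim)[j]
    beta * (lat - mean(lat)) + stats::rnorm(length(lat), 0, sc$clim_sd)
  }))
  colnames(clim) <- sprintf("clim%d", seq_len(sc$n_clim))
  sites <- data.frame(code = codes[active], lat = lat, lon = lon,
                      bar = sc$bar[active], bio = sc$bio[active],
                      size = sc$size_class[active],
                      expansion = sc$expansion[active],
                      stringsAsFactors = FALSE)
  sites <- cbind(sites, clim)
  sites <- as_site_table(sites)

  truth <- list(deme = codes[active], s = sc$s[active],
                founding_gen = sc$founding_gen[active],
                N = sc$N[active], m = sc$m, mu = sc$mu, p_ss = sc$p_ss,
                mu_mt = sc$mu_mt, generations = sc$generations,
                bottlenecks = sc$bottlenecks, seed = seed)
  list(geno = geno, haps = haps, sites = sites, truth = truth)
}

#' Null scenario: homogeneous island model
#'
#' All demes share the same size, selfing rate and migration rate; no
#' expansion, no bottlenecks; category labels are assigned in fixed rotating
#' patterns unrelated to anything the demes experience. Every predictor
#' effect is therefore null — the scenario behind all type-I calibration
#' suites.
#'
#' @param n_demes,N,s,m,generations core parameters (defaults: 30 demes of
#'   50, outcrossing, m = 0.05).
#' @param ... further overrides passed to [sim_scenario()].
#' @return a `sim_scenario`.
#' @export
scenario_null <- function(n_demes = 30, N = 50, s = 0, m = 0.05,
                          generations = 120, ...) {
  sim_scenario(n_demes = n_demes, N = N, s = s, m = m,
               generations = generations,
               expansion = rep_len(c("ref", "hol", "hol", "exp", "hol",
                                     "ref", "exp", "hol", "ref", "exp"),
                                   n_demes), ...)
}

#' Range-expansion scenario
#'
#' A core of long-established demes spanning the SW-NE axis (southern third
#' labelled `ref`, the rest `hol`) plus recently founded demes at the NE
#' end (`exp`), each founded by two individuals from a random source deme
#' (jump dispersal) a few tens of generations before sampling and growing
#' rapidly to target size. The serial founder events depress expansion-class
#' diversity (nuclear and mitochondrial) and inflate pairwise F_ST within
#' the class; selfing rates are heterogeneous and slightly higher in the
#' expansion demes.
#'
#' @param n_core,n_exp numbers of core and expansion demes.
#' @param N deme target size (default 40).
#' @param generations total generations (default 150; expansion demes are
#'   founded between generations `generations - 35` and `generations - 10`).
#' @param ... further overrides passed to [sim_scenario()].
#' @return a `sim_scenario`.
#' @export
scenario_range_expansion <- function(n_core = 40, n_exp = 15, N = 120,
                                     generations = 200, ...) {
  n <- n_core + n_exp
  t_core <- (seq_len(n_core) - 1) / max(1, n_core - 1)
  lat_core <- 43 + 13 * t_core + 1.2 * sin(seq_len(n_core) * 2.399963)
  lon_core <- -2 + 17 * t_core + 1.2 * cos(seq_len(n_core) * 2.399963)
  t_exp <- (seq_len(n_exp) - 1) / max(1, n_exp - 1)
  lat_exp <- 56.5 + 3.5 * t_exp + 0.6 * sin(seq_len(n_exp) * 2.399963)
  lon_exp <- 15.5 + 4.5 * t_exp + 0.6 * cos(seq_len(n_exp) * 2.399963)
  founding <- c(rep(0L, n_core),
                generations - 25L +
                  as.integer(round(20 * (seq_len(n_exp) - 1) / max(1, n_exp - 1))))
  expansion <- c(ifelse(lat_core < 47.5, "ref", "hol"), rep("exp", n_exp))
  s <- c(rep_len(c(0, 0, 0.2, 0, 0.5, 0.1, 0, 0.35), n_core),
         rep_len(c(0.1, 0.4, 0, 0.6, 0.25), n_exp))
  sim_scenario(n_demes = n, N = N, s = s, m = 0.002, mu = 1e-3,
               mu_mt = 2e-3, generations = generations,
               founding_gen = founding, growth = 3,
               founder_n = 2, lat = c(lat_core, lat_exp),
               lon = c(lon_core, lon_exp), expansion = expansion,
               sample_n = rep_len(c(20, 16, 24, 18, 9, 22), n),
               sample_n_mt = rep_len(c(12, 10, 8, 14), n), ...)
}

#' Deterministic synthetic sequences for simulated haplotypes
#'
#' Expands integer haplotype identifiers into distinct aligned DNA strings
#' (for FASTA export of simulated data); identity is all that matters
#' downstream, so the strings are a fixed reference with id-determined
#' substitutions.
#'
#' @param ids character vector of haplotype ids of the form "MT<number>".
#' @param length sequence length (default 450).
#' @return named character vector of sequences.
#' @export
haplotype_sequences <- function(ids, length = 450) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_len(length) * 7) %% 4 + 1]
  out <- vapply(ids, function(id) {
    k <- as.integer(gsub("\\D", "", id))
    s <- ref
    # base-4 encoding of the id at the first 12 positions keeps every
    # haplotype string distinct
    digits <- (k %/% 4^(0:11)) %% 4
    s[seq_len(12)] <- bases[digits + 1]
    paste(s, collapse = "")
  }, character(1))
  stats::setNames(out, ids)
}

#' Export a simulation as the standard file dialects
#'
#' Writes the GENEPOP genotype file, a long-form genotype CSV, an aligned
#' FASTA with one sequence per sampled mtDNA individual plus the id-to-site
#' assignment CSV, and the site CSV — the same dialects the package readers
#' consume.
#'
#' @param sim result of [simulate_metapopulation()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genepop = file.path(dir, "genotypes.gen"),
             geno_csv = file.path(dir, "genotypes.csv"),
             fasta = file.path(dir, "sequences.fasta"),
             assign = file.path(dir, "assignments.csv"),
             sites = file.path(dir, "sites.csv"))
  write_genepop(sim$geno, paths[["genepop"]])
  g <- sim$geno
  long <- do.call(rbind, lapply(seq_along(g$loci), function(l)
    data.frame(individual = g$ind$id, site = g$ind$site, locus = g$loci[l],
               allele1 = g$a1[, l], allele2 = g$a2[, l],
               stringsAsFactors = FALSE)))
  utils::write.csv(long, paths[["geno_csv"]], row.names = FALSE, na = "")
  seqs <- haplotype_sequences(unique(sim$haps$haplotype))
  sid <- character(); sseq <- character(); ssite <- character()
  for (i in seq_len(nrow(sim$haps))) {
    rep_i <- sim$haps$count[i]
    nm <- sprintf("%s_mt%03d_%s", sim$haps$site[i], seq_len(rep_i),
                  sim$haps$haplotype[i])
    sid <- c(sid, nm)
    sseq <- c(sseq, rep(seqs[[sim$haps$haplotype[i]]], rep_i))
    ssite <- c(ssite, rep(sim$haps$site[i], rep_i))
  }
  writeLines(paste0(">", sid, "\n", sseq), paths[["fasta"]])
  utils::write.csv(data.frame(id = sid, site = ssite),
                   paths[["assign"]], row.names = FALSE)
  utils::write.csv(as.data.frame(sim$sites), paths[["sites"]],
                   row.names = FALSE)
  invisible(paths)
}
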
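#' Construct a genotype table
#'
#' Container for co-dominant diploid multi-locus genotypes (microsatellite
#' allele lengths) grouped by sampling site. A call at a locus is an unordered
#' pair of positive integer allele lengths, or fully missing (both `NA`).
#'
#' @param id character vector of individual identifiers.
#' @param site character vector assigning each individual to exactly one site.
#' @param loci character vector of locus names (column order of `a1`/`a2`).
#' @param a1,a2 integer matrices (individuals x loci) holding the two alleles
#'   of each call; a missing call has `NA` in both matrices.
#' @return An object of class `genotype_table`: a list with elements `ind`
#'   (data.frame `id`, `site`), `loci`, `a1`, `a2`.
#' @export
genotype_table <- function(id, site, loci, a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(id)
  if (length(site) != n) stop("id and site must have equal length")
  if (!all(dim(a1) == c(n, length(loci))) || !all(dim(a2) == dim(a1)))
    stop("allele matrices must be n_individuals x n_loci")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing calls (one allele NA) at ", sum(half), " entries")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele values must be positive integers")
  all_missing <- rowSums(!is.na(a1)) == 0
  if (any(all_missing))
    stop("individuals with no typed locus: ",
         paste(id[all_missing], collapse = ", "))
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  structure(list(ind = data.frame(id = as.character(id),
                                  site = as.character(site),
                                  stringsAsFactors = FALSE),
                 loci = as.character(loci), a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$ind), "individuals,",
      length(x$loci), "loci,", length(unique(x$ind$site)), "sites\n")
  invisible(x)
}

#' Sites present in a genotype table, in order of first appearance
#' @param geno a `genotype_table`.
#' @return character vector of site codes.
#' @export
geno_sites <- function(geno) unique(geno$ind$site)

#' Subset a genotype table to one site
#' @param geno a `genotype_table`.
#' @param site site code.
#' @return a `genotype_table` with only that site's individuals.
#' @export
site_genotypes <- function(geno, site) {
  keep <- geno$ind$site == site
  if (!any(keep)) stop("no individuals for site ", site)
  structure(list(ind = geno$ind[keep, , drop = FALSE], loci = geno$loci,
                 a1 = geno$a1[keep, , drop = FALSE],
                 a2 = geno$a2[keep, , drop = FALSE]),
            class = "genotype_table")
}

#' Read a GENEPOP genotype file
#'
#' Supports the standard 2- and 3-digit allele encodings with one `POP` block
#' per sampling site. `00`/`000` (so `0000`/`000000` per call) decodes to a
#' missing call. The site code of each block is the (comma-stripped) name of
#' its first individual, the usual GENEPOP convention.
#'
#' @param path file path.
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("GENEPOP parse error: file too short")
  body <- lines[-1]                      # first line is a title
  is_pop <- toupper(trimws(body)) %in% c("POP", "POPULATION")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GENEPOP parse error: no POP line found")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("GENEPOP parse error: no locus names before POP")
  L <- length(loci)
  ids <- character(); sites <- character()
  a1 <- a2 <- NULL; cur_site <- NA_character_; site_new <- FALSE
  for (k in seq(first_pop, length(body))) {
    ln <- body[k]
    if (!nzchar(trimws(ln))) next
    if (toupper(trimws(ln)) %in% c("POP", "POPULATION")) { site_new <- TRUE; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("GENEPOP parse error at line ", k + 1, ": missing ',' separator")
    nm <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(calls) != L)
      stop("GENEPOP parse error at line ", k + 1, ": expected ", L,
           " loci, found ", length(calls))
    w <- unique(nchar(calls))
    if (length(w) != 1 || !(w %in% c(4L, 6L)))
      stop("GENEPOP parse error at line ", k + 1,
           ": allele encoding must be uniform 4 or 6 digits per call")
    d <- w / 2
    x1 <- as.integer(substr(calls, 1, d))
    x2 <- as.integer(substr(calls, d + 1, w))
    if (anyNA(x1) || anyNA(x2))
      stop("GENEPOP parse error at line ", k + 1, ": non-numeric allele")
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    # a half-coded call (one allele 0) is treated as fully missing
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    if (site_new) { cur_site <- nm; site_new <- FALSE }
    if (is.na(cur_site)) cur_site <- nm
    ids <- c(ids, nm); sites <- c(sites, cur_site)
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
  }
  if (!length(ids)) stop("GENEPOP parse error: no individuals found")
  ids <- make.unique(ids, sep = "_")
  genotype_table(ids, sites, loci, a1, a2)
}

#' Write a genotype table in GENEPOP format
#'
#' @param geno a [genotype_table()].
#' @param path output path.
#' @param digits allele field width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, digits = 3) {
  stopifnot(digits %in% c(2, 3))
  if (max(geno$a1, geno$a2, na.rm = TRUE) >= 10^digits)
    stop("allele lengths exceed the chosen digit width")
  fmt <- function(x) {
    out <- formatC(ifelse(is.na(x), 0L, x), width = digits, flag = "0")
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("rangediv genotype export", con)
  writeLines(geno$loci, con)
  for (s in geno_sites(geno)) {
    writeLines("POP", con)
    idx <- which(geno$ind$site == s)
    for (i in idx) {
      calls <- paste0(fmt(geno$a1[i, ]), fmt(geno$a2[i, ]))
      writeLines(paste0(s, " ,  ", paste(calls, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read genotypes from a long-form CSV
#'
#' Accepts the simulator-friendly dialect with one row per individual x locus:
#' columns `individual`, `site`, `locus`, `allele1`, `allele2` (blank, 0 or NA
#' alleles mark a missing call).
#'
#' @param path file path.
#' @return a [genotype_table()].
#' @export
read_genotypes_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "site", "locus", "allele1", "allele2")
  if (!all(need %in% names(d)))
    stop("long-form genotype CSV needs columns: ", paste(need, collapse = ", "))
  loci <- unique(d$locus)
  ids <- unique(d$individual)
  site_of <- d$site[match(ids, d$individual)]
  conflict <- tapply(d$site, d$individual, function(s) length(unique(s)) > 1)
  if (any(conflict))
    stop("individuals assigned to more than one site: ",
         paste(names(conflict)[conflict], collapse = ", "))
  n <- length(ids); L <- length(loci)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  i <- match(d$individual, ids); j <- match(d$locus, loci)
  v1 <- suppressWarnings(as.integer(d$allele1))
  v2 <- suppressWarnings(as.integer(d$allele2))
  v1[!is.na(v1) & v1 == 0L] <- NA_integer_
  v2[!is.na(v2) & v2 == 0L] <- NA_integer_
  miss <- is.na(v1) | is.na(v2)
  v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
  a1[cbind(i, j)] <- v1; a2[cbind(i, j)] <- v2
  genotype_table(ids, site_of, loci, a1, a2)
}

#' Read and validate the per-site metadata table
#'
#' @param path CSV with required columns `code`, `lat`, `lon`; optional binary
#'   factors `bar`, `bio`, `size`, a categorical `expansion` column with
#'   levels ref/hol/exp, and any further numeric columns, which are preserved
#'   as candidate climate variables.
#' @return a data.frame of class `site_table`.
#' @export
read_sites <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_site_table(d)
}

#' Coerce a data.frame to a validated site table
#' @param d data.frame with at least `code`, `lat`, `lon`.
#' @return `d`, validated, with class `site_table` prepended.
#' @export
as_site_table <- function(d) {
  need <- c("code", "lat", "lon")
  if (!all(need %in% names(d)))
    stop("site table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$code))
    stop("duplicate site codes: ",
         paste(unique(d$code[duplicated(d$code)]), collapse = ", "))
  if (!is.numeric(d$lat) || !is.numeric(d$lon))
    stop("lat/lon must be numeric decimal degrees")
  if (any(abs(d$lat) > 90, na.rm = TRUE) || any(abs(d$lon) > 180, na.rm = TRUE))
    stop("coordinates outside valid decimal-degree ranges")
  if (!"expansion" %in% names(d)) {
    warning("no 'expansion' column; defaulting all sites to class 'hol'")
    d$expansion <- "hol"
  }
  if (!all(d$expansion %in% c("ref", "hol", "exp")))
    stop("expansion class must be one of ref/hol/exp")
  for (f in c("bar", "bio", "size")) {
    if (f %in% names(d) && !all(d[[f]] %in% c(0, 1)))
      stop("factor '", f, "' must be binary 0/1")
  }
  class(d) <- c("site_table", "data.frame")
  d
}

#' Numeric climate columns of a site table
#' @param sites a `site_table`.
#' @return character vector of column names treated as climate variables
#'   (numeric columns other than coordinates, counts and the named factors).
#' @export
climate_columns <- function(sites) {
  reserved <- c("code", "lat", "lon", "bar", "bio", "size", "expansion",
                "n_nuc", "n_mt")
  nm <- setdiff(names(sites), reserved)
  nm[vapply(sites[nm], is.numeric, logical(1))]
}

#' Collapse aligned mitochondrial sequences into per-site haplotype counts
#'
#' Sequences shorter than `min_length` non-gap positions are dropped; retained
#' sequences are compared by exact string identity over the full aligned
#' window ('N' counts as a mismatch), so equal strings share one haplotype.
#' Haplotype ids are assigned in lexicographic sequence order, which makes the
#' result invariant to input order.
#'
#' @param fasta path to an aligned FASTA file, or a named character vector of
#'   equal-length aligned sequences.
#' @param assignments data.frame with columns `id`, `site` mapping sequence
#'   names to site codes (or a named character vector).
#' @param min_length minimum number of non-gap positions to retain a sequence.
#' @return data.frame of class `haplotype_table` with columns `site`,
#'   `haplotype`, `count`; the full sequence keys are kept in
#'   `attr(,"sequences")`.
#' @export
collapse_haplotypes <- function(fasta, assignments, min_length = 400) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    dna <- ape::read.FASTA(fasta)
    seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  } else {
    seqs <- stats::setNames(toupper(as.character(fasta)), names(fasta))
    if (is.null(names(seqs))) stop("sequences must be named")
  }
  if (length(unique(nchar(seqs))) > 1)
    stop("sequences are not aligned to equal length")
  if (is.data.frame(assignments)) {
    amap <- stats::setNames(as.character(assignments$site),
                            as.character(assignments$id))
  } else amap <- assignments
  unknown <- setdiff(names(seqs), names(amap))
  if (length(unknown))
    stop("sequences without site assignment: ",
         paste(unknown, collapse = ", "))
  nongap <- nchar(gsub("[-.]", "", seqs))
  keep <- nongap >= min_length
  seqs <- seqs[keep]
  if (!length(seqs))
    stop("no sequences of at least ", min_length, " non-gap positions")
  key <- sort(unique(seqs))
  hid <- sprintf("H%03d", seq_along(key))
  tab <- table(site = amap[names(seqs)],
               haplotype = hid[match(seqs, key)])
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  out <- out[out$Freq > 0, ]
  out <- data.frame(site = out$site, haplotype = out$haplotype,
                    count = as.integer(out$Freq), stringsAsFactors = FALSE)
  out <- out[order(out$site, out$haplotype), ]
  rownames(out) <- NULL
  attr(out, "sequences") <- stats::setNames(key, hid)
  class(out) <- c("haplotype_table", "data.frame")
  out
}

#' Build a haplotype table from per-site haplotype labels
#' @param site character vector of site codes, one per sequenced individual.
#' @param haplotype parallel vector of haplotype identifiers.
#' @return a `haplotype_table` data.frame (`site`, `haplotype`, `count`).
#' @export
haplotype_table <- function(site, haplotype) {
  tab <- as.data.frame(table(site = as.character(site),
                             haplotype = as.character(haplotype)),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  out <- data.frame(site = tab$site, haplotype = tab$haplotype,
                    count = as.integer(tab$Freq), stringsAsFactors = FALSE)
  out <- out[order(out$site, out$haplotype), ]
  rownames(out) <- NULL
  class(out) <- c("haplotype_table", "data.frame")
  out
}

#' Haplotype counts for one site
#' @param haps a `haplotype_table`.
#' @param site site code.
#' @return named integer vector of counts.
#' @export
site_haplotype_counts <- function(haps, site) {
  h <- haps[haps$site == site, ]
  stats::setNames(h$count, h$haplotype)
}

#' Cross-validate genotype, site and haplotype inputs
#'
#' Report-only consistency check: site codes are cross-referenced between the
#' three tables and sites with fewer than `min_ind` genotyped individuals are
#' flagged as excluded from per-site diversity/selfing statistics (they are
#' still used for differentiation).
#'
#' @param geno a [genotype_table()] or NULL.
#' @param sites a `site_table` or NULL.
#' @param haps a `haplotype_table` or NULL.
#' @param min_ind diversity inclusion threshold (individuals per site).
#' @return data.frame with columns `severity` ("fatal"/"warning"/"note"),
#'   `site`, `message`; zero rows when fully consistent.
#' @export
validate_dataset <- function(geno = NULL, sites = NULL, haps = NULL,
                             min_ind = 7) {
  issues <- data.frame(severity = character(), site = character(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(sev, site, msg)
    rbind(issues, data.frame(severity = sev, site = site, message = msg,
                             stringsAsFactors = FALSE))
  if (!is.null(geno)) {
    cnt <- table(geno$ind$site)
    for (s in names(cnt)[cnt < min_ind])
      issues <- add("warning", s, sprintf(
        "only %d genotyped individuals (< %d): excluded from diversity/selfing statistics",
        cnt[[s]], min_ind))
    if (!is.null(sites)) {
      for (s in setdiff(geno_sites(geno), sites$code))
        issues <- add("fatal", s, "genotyped site absent from site table")
    }
  }
  if (!is.null(haps) && !is.null(sites)) {
    for (s in setdiff(unique(haps$site), sites$code))
      issues <- add("fatal", s, "sequenced site absent from site table")
  }
  if (!is.null(sites)) {
    if (!is.null(geno))
      for (s in setdiff(sites$code, geno_sites(geno)))
        issues <- add("note", s, "site has no genotype data")
    if (!is.null(haps))
      for (s in setdiff(sites$code, unique(haps$site)))
        issues <- add("note", s, "site has no sequence data")
  }
  issues
}
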
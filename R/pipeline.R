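#' Pipeline configuration
#'
#' Collects every tunable setting of the full analysis with the study-style
#' defaults: Mantel test with 10,000 permutations, category contrasts and
#' selfing tests with 1,000, TPM at 90% single-step with multi-step variance
#' 12, alpha = 0.05, diversity inclusion floor of 7 individuals and
#' gene-copy rarefaction depth 2 x 7 = 14.
#'
#' @param seed master seed; each stage reruns identically from its own
#'   derived substream.
#' @param min_ind diversity/selfing inclusion threshold (individuals).
#' @param g,g_mt rarefaction depths (`NULL` g_mt = minimum site total).
#' @param n_perm_mantel,n_perm_contrast,n_perm_selfing,n_perm_merge
#'   permutation counts (all >= 99).
#' @param p_ss,var_geom,heq_reps TPM parameters and equilibrium sample size
#'   for the bottleneck stage.
#' @param aic_convention "gaussian-full" or "aicc".
#' @param alpha significance level.
#' @param quantile_q contrast-grouping quantile.
#' @param stages character vector of stages to run (subset of the default).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, min_ind = 7, g = 14, g_mt = NULL,
                            n_perm_mantel = 10000, n_perm_contrast = 1000,
                            n_perm_selfing = 1000, n_perm_merge = 10000,
                            p_ss = 0.9, var_geom = 12, heq_reps = 1000,
                            aic_convention = c("gaussian-full", "aicc"),
                            alpha = 0.05, quantile_q = 0.85,
                            stages = c("diversity", "selfing", "bottleneck",
                                       "differentiation", "predictors",
                                       "modelsel", "contrasts")) {
  cfg <- list(seed = seed, min_ind = min_ind, g = g, g_mt = g_mt,
              n_perm_mantel = n_perm_mantel,
              n_perm_contrast = n_perm_contrast,
              n_perm_selfing = n_perm_selfing, n_perm_merge = n_perm_merge,
              p_ss = p_ss, var_geom = var_geom, heq_reps = heq_reps,
              aic_convention = match.arg(aic_convention), alpha = alpha,
              quantile_q = quantile_q, stages = stages)
  stopifnot(all(c(cfg$n_perm_mantel, cfg$n_perm_contrast,
                  cfg$n_perm_selfing, cfg$n_perm_merge) >= 99),
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

## independent per-stage substreams from the master seed
stage_seed <- function(cfg, stage) {
  offsets <- c(diversity = 101L, selfing = 211L, bottleneck = 307L,
               differentiation = 401L, predictors = 503L, modelsel = 601L,
               contrasts = 701L)
  (as.integer(cfg$seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis order on a genotype table, site table and
#' haplotype table: per-site diversity, selfing estimation, bottleneck
#' tests (only for populations with an estimated selfing rate of zero),
#' differentiation (pairwise and overall theta, Mantel test against
#' geographic distance, minimum spanning tree on linearized F_ST),
#' predictor construction (including the ref+hol merge rule), all-subsets
#' model selection for each diversity response, and the class contrasts of
#' pairwise differentiation. Deterministic given `cfg$seed`.
#'
#' @param geno a [genotype_table()].
#' @param sites a `site_table`.
#' @param haps a `haplotype_table` (optional; mitochondrial stages are
#'   skipped without it).
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_bundle` with elements `diversity`,
#'   `selfing`, `bottleneck`, `fst` (overall, pairwise, linearized,
#'   mantel, mst, geographic), `predictors`, `models` (one
#'   model-selection table per response), `contrasts`, `log` (character).
#' @export
run_pipeline <- function(geno, sites, haps = NULL, cfg = pipeline_config()) {
  logv <- c(sprintf("rangediv %s", as.character(utils::packageVersion("rangediv"))),
            sprintf("seed=%d min_ind=%d g=%d", cfg$seed, cfg$min_ind, cfg$g),
            sprintf("perms: mantel=%d contrast=%d selfing=%d merge=%d",
                    cfg$n_perm_mantel, cfg$n_perm_contrast,
                    cfg$n_perm_selfing, cfg$n_perm_merge),
            sprintf("tpm: p_ss=%g var_geom=%g heq_reps=%d; aic=%s alpha=%g",
                    cfg$p_ss, cfg$var_geom, cfg$heq_reps,
                    cfg$aic_convention, cfg$alpha))
  issues <- validate_dataset(geno, sites, haps, min_ind = cfg$min_ind)
  if (any(issues$severity == "fatal"))
    stop("validation stage failed:\n",
         paste(issues$message[issues$severity == "fatal"], collapse = "\n"))
  bundle <- list(config = cfg, issues = issues)
  run <- function(stage) stage %in% cfg$stages

  set.seed(stage_seed(cfg, "diversity"))
  div <- diversity_table(geno, haps, min_ind = cfg$min_ind, g = cfg$g,
                         g_mt = cfg$g_mt)
  logv <- c(logv, sprintf("diversity: %d sites included", nrow(div)))

  if (run("selfing")) {
    set.seed(stage_seed(cfg, "selfing"))
    selfing <- selfing_table(geno, min_ind = cfg$min_ind,
                             n_perm = cfg$n_perm_selfing)
    div$s <- selfing$s_hat[match(div$site, selfing$site)]
    div$s_p <- selfing$p[match(div$site, selfing$site)]
    bundle$selfing <- selfing
    logv <- c(logv, sprintf("selfing: inferred for %d of %d sites",
                            sum(selfing$selfing_inferred), nrow(selfing)))
  }

  if (run("bottleneck") && run("selfing")) {
    set.seed(stage_seed(cfg, "bottleneck"))
    bt <- bottleneck_table(geno, bundle$selfing, p_ss = cfg$p_ss,
                           var_geom = cfg$var_geom, n_reps = cfg$heq_reps,
                           alpha = cfg$alpha)
    div$bottleneck <- bt$significant[match(div$site, bt$site)]
    bundle$bottleneck <- bt
    logv <- c(logv, sprintf(
      "bottleneck: tested %d non-selfing sites, %d significant",
      if (is.null(bt)) 0L else nrow(bt),
      if (is.null(bt)) 0L else sum(bt$significant, na.rm = TRUE)))
  }
  bundle$diversity <- div

  if (run("differentiation")) {
    set.seed(stage_seed(cfg, "differentiation"))
    overall <- wc_fst(geno)
    pw <- pairwise_fst(geno)
    lin <- linearize_fst(pw)
    geo <- geo_distance_matrix(sites[match(rownames(pw), sites$code), ])
    man <- mantel_test(geo, lin, n_perm = cfg$n_perm_mantel)
    mst <- minimum_spanning_tree(lin)
    bundle$fst <- list(overall = overall$theta, per_locus = overall$per_locus,
                       pairwise = pw, linearized = lin, geographic = geo,
                       mantel = man, mst = mst)
    if (!is.null(haps)) bundle$fst$mt <- haplotype_fst(haps)
    logv <- c(logv, sprintf("differentiation: overall theta=%.4f mantel r=%.4f p=%.4f",
                            overall$theta, man$r, man$p))
  }

  if (run("predictors")) {
    set.seed(stage_seed(cfg, "predictors"))
    pred <- predictor_table(sites, div, q = cfg$quantile_q,
                            n_perm = cfg$n_perm_merge)
    bundle$predictors <- pred
    mg <- attr(pred, "merge")
    logv <- c(logv, sprintf("predictors: ref+hol %s",
                            if (mg$merged) "merged" else "kept separate"))
  }

  if (run("modelsel") && run("predictors")) {
    set.seed(stage_seed(cfg, "modelsel"))
    pred <- bundle$predictors
    d <- data.frame(He_t = asin(sqrt(pmin(pmax(div$He, 0), 1))),
                    A = div$A, s = div$s, Hmt = div$Hmt,
                    pred[match(div$site, pred$code),
                         c("lim_km", "marg", "bar", "bio", "size", "exp")])
    responses <- c("He_t", "A", "s", "Hmt")
    responses <- responses[vapply(responses, function(r)
      sum(!is.na(d[[r]])) >= 10, logical(1))]
    preds <- c("bar", "bio", "size", "lim_km", "marg", "exp")
    bundle$models <- lapply(stats::setNames(responses, responses),
                            function(r) all_subsets_selection(
                              d, r, preds, convention = cfg$aic_convention))
    logv <- c(logv, sprintf("modelsel: responses %s",
                            paste(responses, collapse = ",")))
  }

  if (run("contrasts") && run("differentiation") && run("predictors")) {
    set.seed(stage_seed(cfg, "contrasts"))
    pred <- bundle$predictors
    pw <- bundle$fst$pairwise
    memberships <- list(
      exp = pred$code[pred$exp == 1],
      bar = pred$code[pred$bar == 1],
      bio = pred$code[pred$bio == 1],
      size = pred$code[pred$size == 1],
      lim = pred$code[pred$lim_group],
      marg = pred$code[pred$marg_group])
    bundle$contrasts <- lapply(memberships, function(mem) {
      if (sum(rownames(pw) %in% mem) < 2 ||
          sum(!rownames(pw) %in% mem) < 2) return(NULL)
      category_fst_contrast(pw, mem, n_perm = cfg$n_perm_contrast)
    })
    cls <- stats::setNames(pred$expansion, pred$code)
    if (length(unique(cls)) > 1)
      bundle$contrasts$expansion_classes <-
        class_pair_contrasts(pw, cls, n_perm = cfg$n_perm_contrast)
    logv <- c(logv, "contrasts: done")
  }

  bundle$log <- logv
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' Write the report artifacts of a pipeline bundle
#'
#' Emits the per-site diversity CSV, selfing and bottleneck CSVs, the
#' distance matrices, the MST edge list, the grouped-deviation table, one
#' model-selection CSV per response (columns: predictors, d.f., SS_res,
#' percent explained variance, AIC, Akaike weight; rows above the support
#' threshold flagged), the contrast summaries and the run log. Partial
#' bundles produce partial reports with notices.
#'
#' @param bundle a `pipeline_bundle`.
#' @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  w <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.csv(x, p, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(bundle$diversity)) {
    w(bundle$diversity, "diversity.csv")
    pred <- bundle$predictors
    if (!is.null(pred)) {
      grouping <- list(bar = pred$code[pred$bar == 1],
                       bio = pred$code[pred$bio == 1],
                       size = pred$code[pred$size == 1],
                       lim = pred$code[pred$lim_group],
                       marg = pred$code[pred$marg_group],
                       exp = pred$code[pred$exp == 1])
      w(group_deviation_summary(bundle$diversity, grouping),
        "group_deviations.csv")
    }
  }
  if (!is.null(bundle$selfing)) w(bundle$selfing, "selfing.csv")
  if (!is.null(bundle$bottleneck)) w(bundle$bottleneck, "bottleneck.csv")
  if (!is.null(bundle$fst)) {
    p <- file.path(dir, "fst_pairwise.csv")
    write_matrix_csv(bundle$fst$pairwise, p); written <- c(written, p)
    w(bundle$fst$mst, "mst_edges.csv")
  }
  if (!is.null(bundle$predictors)) w(bundle$predictors, "predictors.csv")
  if (!is.null(bundle$models)) {
    for (r in names(bundle$models)) {
      tab <- bundle$models[[r]]
      out <- data.frame(predictors = tab$model, d.f. = tab$df,
                        SS_res = tab$ss_res, pct_explained = tab$pct_var,
                        AIC = tab$aic, Akaike_weight = tab$weight,
                        supported = tab$supported)
      w(out, sprintf("model_selection_%s.csv", r))
    }
  }
  notices <- character()
  if (is.null(bundle$contrasts) || !length(bundle$contrasts)) {
    notices <- c(notices, "no categorical contrasts configured")
  } else {
    ct <- bundle$contrasts
    simple <- ct[!vapply(ct, is.null, logical(1))]
    simple <- simple[names(simple) != "expansion_classes"]
    if (length(simple)) {
      tab <- do.call(rbind, lapply(names(simple), function(nm)
        data.frame(category = nm, mean_within = simple[[nm]]$mean_within,
                   mean_rest = simple[[nm]]$mean_rest,
                   diff = simple[[nm]]$diff,
                   p_one_sided = simple[[nm]]$p_one_sided,
                   p_two_sided = simple[[nm]]$p_two_sided)))
      w(tab, "contrasts.csv")
    }
    if (!is.null(ct$expansion_classes))
      w(ct$expansion_classes, "contrasts_expansion_classes.csv")
  }
  logp <- file.path(dir, "run_log.txt")
  writeLines(c(bundle$log, notices), logp)
  written <- c(written, logp)
  invisible(written)
}
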
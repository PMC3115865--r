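#' Fit one additive linear model
#'
#' Ordinary least squares with intercept on complete cases; binary factors
#' enter as 0/1 dummies, continuous predictors untransformed. The model
#' degrees of freedom are counted as the number of predictor terms.
#'
#' @param data data.frame holding response and predictors.
#' @param response response column name.
#' @param predictors character vector of predictor column names (possibly
#'   empty for the intercept-only model).
#' @return list with `ss_res`, `coefficients`, `n`, `df` (predictor terms),
#'   `ss_total`, `pct_var` (percent explained variance).
#' @export
fit_additive_model <- function(data, response, predictors = character()) {
  cols <- c(response, predictors)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 2)
    stop("too few complete cases (", n, ") for ", length(predictors),
         " predictors")
  fml <- if (length(predictors))
    stats::reformulate(predictors, response) else
      stats::as.formula(paste(response, "~ 1"))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    warning("rank-deficient fit; aliased term(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d[[response]] - mean(d[[response]]))^2)
  list(ss_res = ss_res, coefficients = stats::coef(fit), n = n,
       df = length(predictors), ss_total = ss_tot,
       pct_var = 100 * (1 - ss_res / ss_tot))
}

#' Gaussian AIC from a residual sum of squares
#'
#' Two conventions are exposed. `"gaussian-full"` is the full Gaussian
#' log-likelihood form AIC = N[ln(2*pi*SS_res/N) + 1] + 2(k + 1) with k the
#' number of predictor terms; this is the convention under which published
#' all-subsets tables of this kind reproduce. `"aicc"` adds the small-sample
#' correction 2K(K+1)/(N-K-1) with K = k + 2 counted parameters (slopes,
#' intercept, residual variance) and is the recommended default for new
#' analyses.
#'
#' @param n number of observations.
#' @param ss_res residual sum of squares (> 0).
#' @param k_terms number of predictor terms (excluding the intercept).
#' @param convention "gaussian-full" or "aicc".
#' @return the AIC value (single numeric); `-Inf` with a warning when
#'   `ss_res` is 0.
#' @export
compute_aic <- function(n, ss_res, k_terms,
                        convention = c("aicc", "gaussian-full")) {
  convention <- match.arg(convention)
  if (n <= k_terms + 1) stop("n must exceed k_terms + 1")
  if (ss_res < 0) stop("ss_res must be non-negative")
  if (ss_res == 0) {
    warning("perfect fit (ss_res = 0): AIC is -Inf")
    return(-Inf)
  }
  aic <- n * (log(2 * pi * ss_res / n) + 1) + 2 * (k_terms + 1)
  if (convention == "aicc") {
    K <- k_terms + 2
    if (n - K - 1 <= 0) stop("n too small for the AICc correction")
    aic <- aic + 2 * K * (K + 1) / (n - K - 1)
  }
  aic
}

#' Akaike weights over a candidate model set
#'
#' w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2) with Delta_i = AIC_i - min
#' AIC; invariant to adding a constant to all AICs. Weights should always be
#' computed over the full candidate set, not only the displayed rows.
#'
#' @param aic numeric vector of AIC values (may contain `-Inf`).
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  if (!length(aic) || all(!is.finite(aic) & aic != -Inf))
    stop("need at least one finite AIC")
  if (any(aic == -Inf)) {
    w <- as.numeric(aic == -Inf)
    return(w / sum(w))
  }
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' All-subsets model selection
#'
#' Fits every non-empty additive subset of the predictors (2^p - 1 models)
#' by OLS, computes the residual sum of squares, percent explained variance,
#' AIC under the chosen convention and Akaike weights over the full set, and
#' returns the candidate table sorted by ascending AIC. Models with weight
#' above `support` are flagged as the displayed subset.
#'
#' @param data data.frame with response and predictor columns.
#' @param response response column name.
#' @param predictors predictor column names (at most 12 unless `force`).
#' @param convention AIC convention, see [compute_aic()].
#' @param support display threshold on Akaike weight (default 0.05).
#' @param force allow more than 12 predictors.
#' @return data.frame of class `model_selection_table`: `model`, `df`,
#'   `ss_res`, `pct_var`, `aic`, `weight`, `supported`, sorted by AIC;
#'   `attr(,"n")`, `attr(,"convention")`, `attr(,"response")`.
#' @export
all_subsets_selection <- function(data, response, predictors,
                                  convention = c("aicc", "gaussian-full"),
                                  support = 0.05, force = FALSE) {
  convention <- match.arg(convention)
  if (!length(predictors)) stop("need at least one predictor")
  if (length(predictors) > 12 && !force)
    stop("more than 12 predictors (", 2^length(predictors) - 1,
         " models); pass force = TRUE if intended")
  cc <- stats::complete.cases(data[c(response, predictors)])
  if (sum(cc) < 10) stop("need at least 10 complete cases")
  d <- data[cc, , drop = FALSE]
  subsets <- unlist(lapply(seq_along(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(ps) {
    fit <- fit_additive_model(d, response, ps)
    data.frame(model = paste(ps, collapse = "+"), df = fit$df,
               ss_res = fit$ss_res, pct_var = fit$pct_var,
               aic = compute_aic(fit$n, fit$ss_res, fit$df, convention),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$weight <- akaike_weights(out$aic)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  out$supported <- out$weight > support
  attr(out, "n") <- nrow(d)
  attr(out, "convention") <- convention
  attr(out, "response") <- response
  class(out) <- c("model_selection_table", "data.frame")
  out
}
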
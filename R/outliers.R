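# Multivariate outlier detection on fitted cline parameters.
#
# The among-locus distribution of parameter estimates spreads out under
# genetic drift; comparing each locus to that empirical distribution
# (rather than to the naive null p = S) keeps drift-generated variation
# from being declared significant.

#' Squared Mahalanobis distances of loci
#'
#' Classical squared Mahalanobis distance of each row of a loci-by-
#' parameters matrix from the column mean, standardized by the sample
#' covariance of all rows.  Under approximate multivariate normality of
#' the among-locus parameter distribution, the distances follow a
#' chi-squared distribution with degrees of freedom equal to the number
#' of parameters.
#'
#' @param params numeric matrix, `L` loci by `d` parameter estimates
#'   (typically on the optimization scale, see [fit_cline_ml()]).
#' @return numeric vector of length `L` of squared distances.
#' @export
mahalanobis_d2 <- function(params) {
  params <- as.matrix(params)
  L <- nrow(params)
  d <- ncol(params)
  if (anyNA(params)) stop("'params' must not contain missing values")
  if (L <= d + 1L)
    stop("need more loci than parameters + 1 (L = ", L, ", d = ", d,
         ") for a nonsingular covariance", call. = FALSE)
  ctr <- colMeans(params)
  cv <- stats::cov(params)
  tryCatch(
    stats::mahalanobis(params, ctr, cv),
    error = function(e) stop(
      "singular among-locus covariance: too few loci or collinear ",
      "parameter estimates (", conditionMessage(e), ")", call. = FALSE)
  )
}

# leave-one-out variant: each locus measured against the mean/covariance of
# the other L - 1 loci, so an extreme locus does not inflate its own yardstick
.mahalanobis_d2_loo <- function(params) {
  params <- as.matrix(params)
  L <- nrow(params)
  vapply(seq_len(L), function(i) {
    rest <- params[-i, , drop = FALSE]
    stats::mahalanobis(params[i, , drop = FALSE], colMeans(rest),
                       stats::cov(rest))
  }, 0)
}

#' Chi-squared critical value for outlier declaration
#'
#' Upper quantile of the chi-squared distribution with `d` degrees of
#' freedom at tail probability `p_crit`; loci whose squared Mahalanobis
#' distance exceeds this value are declared outliers.  For `d = 2` the
#' closed form is `-2 log(p_crit)`.
#'
#' @param d degrees of freedom (number of model parameters).
#' @param p_crit critical tail probability in (0, 1), e.g. the
#'   Bonferroni-adjusted `alpha / L`.
#' @return the critical squared distance.
#' @export
chi2_critical <- function(d, p_crit) {
  if (d < 1) stop("'d' must be >= 1", call. = FALSE)
  if (p_crit <= 0 || p_crit >= 1) stop("'p_crit' must be in (0, 1)",
                                       call. = FALSE)
  stats::qchisq(p_crit, df = d, lower.tail = FALSE)
}

#' Multivariate outlier detection among loci
#'
#' Flags loci whose fitted parameter vectors are extreme relative to the
#' empirical among-locus distribution: each squared Mahalanobis distance
#' is referred to the chi-squared distribution with `d` degrees of
#' freedom, and a locus is flagged when its upper-tail probability falls
#' at or below the Bonferroni-adjusted critical value `family_alpha / L`.
#' Quantile-quantile coordinates (sorted distances against chi-squared
#' quantiles at plotting positions `(i - 0.5) / L`) are returned for
#' visual inspection.
#'
#' @inheritParams mahalanobis_d2
#' @param family_alpha family-wise error rate across loci (default 0.05).
#' @param leave_one_out if `TRUE`, use leave-one-out mean and covariance
#'   (each locus excluded from its own reference distribution).  Off by
#'   default; the classical estimator is the standard method.
#' @return an object of class `"outlier_report"`: a `data.frame` with
#'   columns `locus`, `d2`, `p`, `flag`, and attributes `d`,
#'   `family_alpha`, `p_crit`, `d2_crit` and `qq` (a `data.frame` of
#'   theoretical and observed quantiles).
#' @export
detect_outliers <- function(params, family_alpha = 0.05,
                            leave_one_out = FALSE) {
  params <- as.matrix(params)
  L <- nrow(params)
  d <- ncol(params)
  d2 <- if (leave_one_out) .mahalanobis_d2_loo(params) else
    mahalanobis_d2(params)
  p <- stats::pchisq(d2, df = d, lower.tail = FALSE)
  p_crit <- family_alpha / L
  locus <- if (!is.null(rownames(params))) rownames(params) else
    as.character(seq_len(L))
  rep_df <- data.frame(locus = locus, d2 = d2, p = p, flag = p <= p_crit,
                       row.names = NULL)
  ord <- order(d2)
  qq <- data.frame(
    theoretical = stats::qchisq((seq_len(L) - 0.5) / L, df = d),
    observed = d2[ord],
    locus = locus[ord]
  )
  structure(rep_df,
            d = d, family_alpha = family_alpha, p_crit = p_crit,
            d2_crit = chi2_critical(d, p_crit), qq = qq,
            leave_one_out = leave_one_out,
            class = c("outlier_report", "data.frame"))
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Multivariate outlier report: ", nrow(x), " loci, d = ", attr(x, "d"),
      ", family alpha = ", attr(x, "family_alpha"),
      " (critical D^2 = ", signif(attr(x, "d2_crit"), 5L), ")\n", sep = "")
  flagged <- x$locus[x$flag]
  if (length(flagged)) cat("Outliers:", paste(flagged, collapse = ", "), "\n")
  else cat("No outliers.\n")
  NextMethod()
}
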
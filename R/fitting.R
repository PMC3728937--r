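# Maximum-likelihood fitting of genomic cline and regression models to
# counts of ancestry-diagnostic alleles.

#' Assemble and validate allele-count samples
#'
#' Builds the tabular input consumed by the likelihood functions: one row
#' per sampling unit (an individual or a pooled locality) with the count
#' `x` of P1-derived alleles out of `n` alleles sampled (2 per diploid
#' individual) and the unit's genome-wide ancestry `S`.
#'
#' @param S numeric vector of genome-wide ancestries in \[0, 1\].
#' @param x integer vector of P1 allele counts, `0 <= x <= n`.
#' @param n integer vector of total alleles sampled per unit (>= 1).
#' @param unit optional unit identifiers.
#' @return a `data.frame` with columns `unit`, `S`, `x`, `n`.
#' @export
allele_counts <- function(S, x, n, unit = NULL) {
  .check_prob(S, "S")
  if (anyNA(x) || anyNA(n) || any(x != round(x)) || any(n != round(n)))
    stop("'x' and 'n' must be non-missing integers", call. = FALSE)
  if (any(n < 1L)) stop("'n' must be >= 1", call. = FALSE)
  if (any(x < 0L | x > n)) stop("'x' must satisfy 0 <= x <= n", call. = FALSE)
  k <- length(S)
  if (length(x) != k || length(n) != k)
    stop("'S', 'x' and 'n' must have equal length", call. = FALSE)
  if (is.null(unit)) unit <- seq_len(k)
  data.frame(unit = unit, S = S, x = as.integer(x), n = as.integer(n))
}

#' Assemble and validate genotype-count samples
#'
#' One row per sampling unit with counts of individuals carrying 0, 1 or 2
#' P1 alleles at the focal locus, plus the unit's genome-wide ancestry.
#' This is the input for [fit_multinomial_regression()].
#'
#' @inheritParams allele_counts
#' @param n0,n1,n2 integer counts of individuals with 0, 1, 2 P1 alleles.
#' @return a `data.frame` with columns `unit`, `S`, `n0`, `n1`, `n2`.
#' @export
genotype_counts <- function(S, n0, n1, n2, unit = NULL) {
  .check_prob(S, "S")
  cnt <- cbind(n0, n1, n2)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  if (all(rowSums(cnt) == 0)) stop("all units are empty", call. = FALSE)
  if (is.null(unit)) unit <- seq_along(S)
  data.frame(unit = unit, S = S, n0 = as.integer(n0),
             n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Binomial log-likelihood of a cline model
#'
#' The log of the product-of-binomials likelihood: for each sampling unit
#' `k`, the count `x_k` of P1 alleles out of `n_k` is binomial with success
#' probability `p_k` given by the cline model evaluated at `S_k`.  Binomial
#' coefficients are included, so values are comparable across models fitted
#' to the same data.  If the model forces `p_k` to exactly 0 or 1 (at
#' `S_k` of 0 or 1, or within a clipped region of the spliced Barton
#' cline) and the observed count contradicts it, the result is `-Inf`.
#'
#' @param data allele-count samples, see [allele_counts()].
#' @param model model identifier (`"logit-logistic"`, `"beta"`,
#'   `"barton"`, `"binomial"`).
#' @param params natural-scale parameter vector of length 2.
#' @return a single log-likelihood value (<= 0).
#' @export
cline_loglik <- function(data, model, params) {
  p <- cline_prob(data$S, model, params)
  sum(stats::dbinom(data$x, data$n, p, log = TRUE))
}

#' Log-likelihood of the naive null hypothesis p = S
#'
#' [cline_loglik()] with the success probability fixed at `p_k = S_k`.
#' This is the reference point of the likelihood-ratio test of the naive
#' null hypothesis that locus-specific ancestry matches the genome-wide
#' average.
#'
#' @inheritParams cline_loglik
#' @return a single log-likelihood value.
#' @export
null_loglik <- function(data) {
  sum(stats::dbinom(data$x, data$n, data$S, log = TRUE))
}

# Exact sufficient reduction of the binomial likelihood: since the model
# probability depends on a unit only through S, units sharing an S value
# collapse to summed success/failure counts.  `const` carries the binomial
# coefficients so compressed log-likelihoods equal cline_loglik() exactly.
.compress_counts <- function(data) {
  uS <- sort(unique(data$S))
  idx <- match(data$S, uS)
  list(S = uS,
       A = as.vector(rowsum(data$x, idx)),
       B = as.vector(rowsum(data$n - data$x, idx)),
       const = sum(lchoose(data$n, data$x)),
       interior = uS > 0 & uS < 1)
}

.compressed_loglik <- function(cd, p) {
  t1 <- cd$A * log(p)
  t1[cd$A == 0] <- 0
  t2 <- cd$B * log1p(-p)
  t2[cd$B == 0] <- 0
  cd$const + sum(t1) + sum(t2)
}

# Safeguarded negative log-likelihood used inside the optimizer: probability
# clipped away from {0,1} at interior S so that the spliced Barton model has
# a finite, continuous surface; units at S = 0 or 1 keep their exact
# (possibly -Inf) contribution, replaced by a large finite penalty.
.neg_loglik_obj <- function(theta, cd, model) {
  params <- .from_optim_scale(model, theta)
  p <- cline_prob(cd$S, model, params)
  p[cd$interior] <- pmin(pmax(p[cd$interior], 1e-12), 1 - 1e-12)
  ll <- .compressed_loglik(cd, p)
  if (!is.finite(ll)) ll <- -1e10
  -ll
}

# deterministic multi-start offsets on the optimization scale
.start_offsets <- rbind(
  c(0, 0), c(1, 1), c(-1, 1), c(1, -1), c(-1, -1),
  c(2, 0), c(0, 2), c(-2, 0), c(0, -2)
)

#' Maximum-likelihood fit of a cline model
#'
#' Maximizes the product-of-binomials likelihood over the two cline
#' parameters using Nelder-Mead searches on an unconstrained scale
#' (`(u, log v)`, `(logit mu, log nu)`, or `(a, b)`), started from the
#' null (identity) parameters plus `n_starts - 1` fixed dispersed starting
#' points; the best final log-likelihood wins.  Because the null
#' parameters are always among the candidate solutions, the fitted
#' log-likelihood can never fall below [null_loglik()].
#'
#' @inheritParams cline_loglik
#' @param starts optional matrix of additional starting values on the
#'   natural scale (one row per start).
#' @param n_starts number of dispersed starts (1--9, default 5).
#' @return an object of class `"cline_fit"`: a list with elements
#'   `model`, `params` (natural scale), `tpar` (optimization scale),
#'   `loglik`, `n_params`, `aicc`, `converged`, and `nonidentifiable`
#'   (fewer than 3 interior-`S` units).
#' @export
fit_cline_ml <- function(data, model, starts = NULL, n_starts = 5L) {
  model <- match.arg(model, .cline_models)
  n_starts <- max(1L, min(as.integer(n_starts), nrow(.start_offsets)))
  theta0 <- .to_optim_scale(model, cline_null_params(model))
  start_mat <- sweep(.start_offsets[seq_len(n_starts), , drop = FALSE], 2L,
                     theta0, "+")
  if (!is.null(starts)) {
    extra <- t(apply(rbind(starts), 1L, function(p) .to_optim_scale(model, p)))
    start_mat <- rbind(start_mat, extra)
  }

  cd <- .compress_counts(data)
  exact_ll <- function(theta) {
    p <- cline_prob(cd$S, model, .from_optim_scale(model, theta))
    .compressed_loglik(cd, p)
  }
  best <- list(theta = theta0, loglik = -Inf, code = 0L)
  for (i in seq_len(nrow(start_mat))) {
    opt <- stats::optim(start_mat[i, ], .neg_loglik_obj, cd = cd,
                        model = model, method = "Nelder-Mead",
                        control = list(maxit = 500L))
    ll <- exact_ll(opt$par)
    if (is.finite(ll) && ll > best$loglik)
      best <- list(theta = opt$par, loglik = ll, code = opt$convergence)
  }
  # the null point itself is always a feasible candidate
  ll0 <- exact_ll(theta0)
  if (ll0 > best$loglik) best <- list(theta = theta0, loglik = ll0, code = 0L)

  params <- .from_optim_scale(model, best$theta)
  k <- nrow(data)
  structure(list(
    model = model,
    params = params,
    tpar = best$theta,
    loglik = best$loglik,
    n_params = 2L,
    aicc = if (k > 3L) aicc(best$loglik, 2L, k) else NA_real_,
    converged = best$code == 0L && is.finite(best$loglik),
    nonidentifiable = sum(data$S > 0 & data$S < 1) < 3L
  ), class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat("Cline model fit:", x$model, "\n")
  cat("  params:", paste(names(x$params), signif(x$params, 4L),
                         sep = " = ", collapse = ", "), "\n")
  cat("  loglik:", format(x$loglik), "  AICc:", format(x$aicc),
      "  converged:", x$converged, "\n")
  invisible(x)
}

#' Likelihood-ratio test against the naive null p = S
#'
#' Compares a fitted model to the zero-parameter null hypothesis that
#' locus-specific ancestry equals genome-wide ancestry.  The statistic is
#' `2 * (loglik_fit - loglik_null)` referred to a chi-squared distribution
#' with degrees of freedom equal to the number of fitted parameters.
#' Because drift alone moves loci away from `p = S`, significance here
#' must not be read as evidence of selection; see [detect_outliers()].
#'
#' @param fit a `"cline_fit"` object.
#' @param data the allele-count samples the model was fitted to.
#' @return a list with elements `stat`, `df`, `p`.
#' @export
lrt_vs_null <- function(fit, data) {
  ll0 <- null_loglik(data)
  stat <- 2 * (fit$loglik - ll0)
  # p = S is nested in the cline models, so a negative statistic signals an
  # optimizer failure there; the logistic regression cannot represent p = S
  # exactly and may legitimately fall just below the null.
  if (is.finite(stat) && stat < -1e-6 && fit$model %in% .cline_models)
    warning("fitted log-likelihood below the null: optimizer failure")
  stat <- max(stat, 0)
  df <- fit$n_params
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Binomial (logistic) regression of allele counts on ancestry
#'
#' Fits `logit(p_k) = alpha + beta * S_k` by maximum likelihood via
#' [stats::glm()].  This maximizes the same product-of-binomials
#' likelihood as the cline models but, unlike them, does not constrain the
#' fitted probability to reach 0 and 1 at the ends of the ancestry range.
#'
#' @inheritParams cline_loglik
#' @return a `"cline_fit"` object with `model = "binomial"` and an extra
#'   logical element `separated` flagging complete separation.
#' @export
fit_binomial_regression <- function(data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(x, n - x) ~ S, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  cf <- unname(stats::coef(fit))
  if (any(abs(cf) > 15)) sep <- TRUE
  ll <- as.numeric(stats::logLik(fit))
  k <- nrow(data)
  structure(list(
    model = "binomial",
    params = c(alpha = cf[1L], beta = cf[2L]),
    tpar = cf,
    loglik = ll,
    n_params = 2L,
    aicc = if (k > 3L) aicc(ll, 2L, k) else NA_real_,
    converged = fit$converged,
    separated = sep
  ), class = "cline_fit")
}

# multinomial (baseline-category logit) log-likelihood; theta =
# (a1, b1, a2, b2), baseline category = genotype 0.  Includes the
# multinomial coefficient so values are on the same footing as the
# binomial models when units hold several individuals.
.multinom_loglik <- function(theta, S, cnt) {
  eta1 <- theta[1L] + theta[2L] * S
  eta2 <- theta[3L] + theta[4L] * S
  m <- pmax(eta1, eta2, 0)
  lse <- m + log(exp(-m) + exp(eta1 - m) + exp(eta2 - m))
  lp <- cbind(-lse, eta1 - lse, eta2 - lse)
  const <- sum(lfactorial(rowSums(cnt))) - sum(lfactorial(cnt))
  const + sum(cnt * lp)
}

#' Multinomial logistic regression of genotype counts on ancestry
#'
#' Models the three genotype classes (0, 1 or 2 P1 alleles) at a locus as
#' a baseline-category logit with linear predictors in genome-wide
#' ancestry `S` (baseline = genotype 0), giving 4 free parameters.  Unlike
#' the allele-count models it captures heterozygosity, so it can expose
#' loci with genotype-scoring artifacts ("ringer" loci with no observed
#' heterozygotes).  The concave log-likelihood is maximized with BFGS.
#' With fewer than two distinct `S` values an intercept-only model (2
#' parameters) is fitted, whose MLE reproduces the observed genotype
#' proportions.
#'
#' @param data genotype-count samples, see [genotype_counts()].
#' @return a `"cline_fit"` object with `model = "multinomial"`, the
#'   fitted coefficients `(a1, b1, a2, b2)`, a `separated` flag (empty
#'   genotype class or diverging coefficients), and a function element
#'   `prob(S)` returning the fitted genotype-probability matrix.
#' @export
fit_multinomial_regression <- function(data) {
  cnt <- as.matrix(data[, c("n0", "n1", "n2")])
  S <- data$S
  tot <- colSums(cnt)
  sep <- any(tot == 0)
  intercept_only <- length(unique(S)) < 2L
  # smoothed pooled proportions give a stable starting intercept
  a0 <- log((tot + 0.5) / (tot[1L] + 0.5))[2:3]

  # collapse units sharing an S value (exact: the likelihood kernel depends
  # on a unit only through S); binomial-style constant kept from the rows
  uS <- sort(unique(S))
  csum <- rowsum(cnt, match(S, uS))
  ctot <- rowSums(csum)
  cconst <- sum(lfactorial(rowSums(cnt))) - sum(lfactorial(cnt))
  kernel <- function(th) {
    eta1 <- th[1L] + th[2L] * uS
    eta2 <- th[3L] + th[4L] * uS
    m <- pmax(eta1, eta2, 0)
    lse <- m + log(exp(-m) + exp(eta1 - m) + exp(eta2 - m))
    sum(csum * cbind(-lse, eta1 - lse, eta2 - lse))
  }
  grad4 <- function(th) {
    eta1 <- th[1L] + th[2L] * uS
    eta2 <- th[3L] + th[4L] * uS
    m <- pmax(eta1, eta2, 0)
    den <- exp(-m) + exp(eta1 - m) + exp(eta2 - m)
    r1 <- csum[, 2L] - ctot * exp(eta1 - m) / den
    r2 <- csum[, 3L] - ctot * exp(eta2 - m) / den
    c(sum(r1), sum(uS * r1), sum(r2), sum(uS * r2))
  }

  if (intercept_only) {
    opt <- stats::optim(a0, function(th) -kernel(c(th[1L], 0, th[2L], 0)),
                        function(th) -grad4(c(th[1L], 0, th[2L], 0))[c(1L, 3L)],
                        method = "BFGS",
                        control = list(maxit = 500L, reltol = 1e-12))
    theta <- c(opt$par[1L], 0, opt$par[2L], 0)
    np <- 2L
  } else {
    opt <- stats::optim(c(a0[1L], 0, a0[2L], 0), function(th) -kernel(th),
                        function(th) -grad4(th), method = "BFGS",
                        control = list(maxit = 500L))
    theta <- opt$par
    np <- 4L
  }
  if (any(abs(theta) > 15)) sep <- TRUE
  ll <- cconst + kernel(theta)
  k <- nrow(data)
  names(theta) <- c("a1", "b1", "a2", "b2")
  structure(list(
    model = "multinomial",
    params = theta,
    tpar = unname(theta),
    loglik = ll,
    n_params = np,
    aicc = if (k > np + 1L) aicc(ll, np, k) else NA_real_,
    converged = opt$convergence == 0L,
    separated = sep,
    intercept_only = intercept_only,
    prob = function(Snew) {
      e1 <- exp(theta[1L] + theta[2L] * Snew)
      e2 <- exp(theta[3L] + theta[4L] * Snew)
      den <- 1 + e1 + e2
      cbind(p0 = 1 / den, p1 = e1 / den, p2 = e2 / den)
    }
  ), class = "cline_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)`, where `n` is the
#' number of independent sampling units.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of sampling units; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Best-fitting model by AICc
#'
#' Returns the identifier of the minimum-AICc fit among a list of
#' `"cline_fit"` objects for the same locus.  Exact ties are broken
#' deterministically by the fixed model order logit-logistic, beta,
#' barton, binomial, multinomial.
#'
#' @param fits list of `"cline_fit"` objects.
#' @return a model identifier string.
#' @export
best_model_per_locus <- function(fits) {
  models <- vapply(fits, `[[`, "", "model")
  vals <- vapply(fits, `[[`, 0, "aicc")
  ord <- match(models, .model_order)
  unname(models[order(vals, ord)[1L]])
}

#' Maximum-likelihood geographic cline
#'
#' Fits the logistic geographic cline `logit(p) = b (x - m)` to per-site
#' binomial allele counts, where `x` is the spatial coordinate, `b` the
#' slope at the inflection point (1/b is the cline width) and `m` the
#' cline center.  Estimated via logistic regression and reparameterized.
#'
#' @param x numeric vector of site coordinates.
#' @param k integer vector of P1 allele counts per site.
#' @param n integer vector of total alleles sampled per site.
#' @return a list with elements `b`, `m`, `loglik`, `flat` (logical: no
#'   detectable spatial trend, in which case `m` is `NA`).
#' @export
fit_geographic_cline <- function(x, k, n) {
  if (length(unique(x)) < 3L)
    warning("fewer than 3 distinct sites: cline poorly identified")
  fit <- suppressWarnings(
    stats::glm(cbind(k, n - k) ~ x, family = stats::binomial())
  )
  cf <- unname(stats::coef(fit))
  flat <- !is.finite(cf[2L]) || abs(cf[2L]) < 1e-8
  list(
    b = cf[2L],
    m = if (flat) NA_real_ else -cf[1L] / cf[2L],
    loglik = as.numeric(stats::logLik(fit)),
    flat = flat
  )
}

#' Fit all cline and regression models to one locus
#'
#' Convenience wrapper fitting the three cline models and binomial
#' regression to allele counts and, when genotype counts are supplied,
#' multinomial regression.
#'
#' @inheritParams cline_loglik
#' @param gdata optional genotype-count samples for the same locus.
#' @param n_starts passed to [fit_cline_ml()].
#' @return named list of `"cline_fit"` objects.
#' @export
fit_all_models <- function(data, gdata = NULL, n_starts = 5L) {
  fits <- list(
    "logit-logistic" = fit_cline_ml(data, "logit-logistic", n_starts = n_starts),
    "beta"           = fit_cline_ml(data, "beta", n_starts = n_starts),
    "barton"         = fit_cline_ml(data, "barton", n_starts = n_starts),
    "binomial"       = fit_binomial_regression(data)
  )
  if (!is.null(gdata)) fits$multinomial <- fit_multinomial_regression(gdata)
  fits
}
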
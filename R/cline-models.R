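# Cline models: maps from genome-wide ancestry S in [0,1] to the
# locus-specific ancestry probability p in [0,1].

.cline_models <- c("logit-logistic", "beta", "barton")

# fixed comparison order used for deterministic tie-breaking in model selection
.model_order <- c("logit-logistic", "beta", "barton", "binomial", "multinomial")

.check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop("'", name, "' must be numeric in [0, 1]", call. = FALSE)
  invisible(x)
}

#' Logit-logistic genomic cline
#'
#' Computes the locus-specific ancestry probability `p` as a function of
#' genome-wide ancestry `S` under the logit-logistic cline,
#' `logit(p) = u + v * logit(S)`.  The parameter `u` is the relative cline
#' position (displacement on the log-odds scale) and `v > 0` the relative
#' slope; `(u, v) = (0, 1)` is the identity cline `p = S`.  The curve is
#' defined at the endpoints by continuity: `p = 0` at `S = 0` and `p = 1`
#' at `S = 1` for every admissible parameter pair, as required when `S` is
#' the genome-wide mean of the locus-specific ancestries.
#'
#' Evaluation uses [stats::plogis()]/[stats::qlogis()], which work on the
#' log-odds scale and do not overflow near the endpoints.
#'
#' @param S numeric vector of genome-wide ancestries in \[0, 1\].
#' @param u relative cline position (unbounded real).
#' @param v relative cline slope, must be > 0.
#' @return numeric vector of probabilities, same length as `S`.
#' @examples
#' logit_logistic_cline(0.5, u = 0, v = 1)   # identity: 0.5
#' logit_logistic_cline(0.25, u = 0, v = 2)  # odds squared: 0.1
#' @seealso [beta_cline()], [barton_cline()]
#' @export
logit_logistic_cline <- function(S, u = 0, v = 1) {
  .check_prob(S, "S")
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
    stop("'v' must be a single positive number", call. = FALSE)
  if (!is.numeric(u) || length(u) != 1L || is.na(u))
    stop("'u' must be a single finite number", call. = FALSE)
  p <- stats::plogis(u + v * stats::qlogis(S))
  # qlogis(0) = -Inf and qlogis(1) = Inf give the endpoint limits exactly,
  # but guard against u = +/-Inf arithmetic just in case
  p[S == 0] <- 0
  p[S == 1] <- 1
  p
}

#' Barton polynomial cline, unspliced
#'
#' The raw quadratic-deviation cline
#' `p = S + 2 S (1 - S) (a + b (2 S - 1))`, where `a` and `b` describe
#' deviations in cline center and steepness from perfect concordance
#' (`a = b = 0` gives `p = S`).  The raw value can fall outside \[0, 1\] and
#' can be nonmonotone in `S`; see [barton_cline()] for the spliced version
#' used in fitting.
#'
#' @inheritParams logit_logistic_cline
#' @param a,b deviation coefficients (unbounded reals).
#' @return numeric vector, possibly outside \[0, 1\].
#' @export
barton_cline_raw <- function(S, a = 0, b = 0) {
  .check_prob(S, "S")
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  S + 2 * S * (1 - S) * (a + b * (2 * S - 1))
}

#' Spliced Barton cline
#'
#' [barton_cline_raw()] with horizontal lines spliced in at 0 and 1, i.e.
#' hard clipping of the polynomial to \[0, 1\].  Nonmonotone interior shapes
#' are retained; only the range constraint is enforced.
#'
#' @inheritParams barton_cline_raw
#' @return numeric vector of probabilities.
#' @examples
#' barton_cline(0.5, a = 1.2, b = 0)  # raw value 1.1, clipped to 1
#' @export
barton_cline <- function(S, a = 0, b = 0) {
  pmin(pmax(barton_cline_raw(S, a, b), 0), 1)
}

#' Beta genomic cline
#'
#' The regularized incomplete beta function of `S`,
#' `p = I_S(mu * nu, (1 - mu) * nu)` -- the CDF of a Beta distribution
#' in the location/precision parameterization.  `mu` in (0, 1) plays the
#' role of a cline center and `nu > 0` of a slope/shape parameter;
#' `(mu, nu) = (0.5, 2)` gives the uniform CDF, i.e. the identity cline.
#' The curve is strictly monotone and respects the endpoint constraints
#' by construction.
#'
#' @inheritParams logit_logistic_cline
#' @param mu location parameter in (0, 1).
#' @param nu precision/shape parameter, > 0.
#' @return numeric vector of probabilities.
#' @examples
#' beta_cline(0.25, mu = 0.5, nu = 4)  # I_x(2, 2) = 3 x^2 - 2 x^3
#' @export
beta_cline <- function(S, mu = 0.5, nu = 2) {
  .check_prob(S, "S")
  shp <- beta_shapes(mu, nu)
  stats::pbeta(S, shp[["alpha"]], shp[["beta"]])
}

#' Beta shape parameters from location and precision
#'
#' Converts the `(mu, nu)` parameterization of the beta cline to the
#' familiar shape parameters `alpha = mu * nu`, `beta = (1 - mu) * nu`.
#'
#' @inheritParams beta_cline
#' @return named numeric vector `c(alpha =, beta =)`.
#' @export
beta_shapes <- function(mu, nu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0 || mu >= 1)
    stop("'mu' must be a single number in (0, 1)", call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1L || is.na(nu) || nu <= 0)
    stop("'nu' must be a single positive number", call. = FALSE)
  c(alpha = unname(mu * nu), beta = unname((1 - mu) * nu))
}

#' Evaluate any cline model by name
#'
#' Dispatch helper used by the fitting routines: evaluates the named model
#' at natural-scale parameters.  For `"binomial"` the parameters are the
#' logistic-regression intercept and slope `logit(p) = alpha + beta * S`.
#'
#' @param S numeric vector of ancestries in \[0, 1\].
#' @param model one of `"logit-logistic"`, `"beta"`, `"barton"`,
#'   `"binomial"`.
#' @param params numeric vector of length 2 of natural-scale parameters:
#'   `(u, v)`, `(mu, nu)`, `(a, b)` or `(alpha, beta)` respectively.
#' @return numeric vector of probabilities.
#' @export
cline_prob <- function(S, model, params) {
  model <- match.arg(model, c(.cline_models, "binomial"))
  switch(model,
    "logit-logistic" = logit_logistic_cline(S, params[1L], params[2L]),
    "beta"           = beta_cline(S, params[1L], params[2L]),
    "barton"         = barton_cline(S, params[1L], params[2L]),
    "binomial"       = stats::plogis(params[1L] + params[2L] * S)
  )
}

#' Null (identity) parameters of a cline model
#'
#' Parameter values at which each model reduces to the concordant cline
#' `p = S`: `(u, v) = (0, 1)`, `(mu, nu) = (0.5, 2)`, `(a, b) = (0, 0)`,
#' and `(alpha, beta) = (0, 1)` for the logistic regression (which is only
#' approximately `p = S` since `plogis(S)` is not the identity).
#'
#' @param model model identifier as in [cline_prob()].
#' @return named numeric vector of length 2.
#' @export
cline_null_params <- function(model) {
  model <- match.arg(model, c(.cline_models, "binomial"))
  switch(model,
    "logit-logistic" = c(u = 0, v = 1),
    "beta"           = c(mu = 0.5, nu = 2),
    "barton"         = c(a = 0, b = 0),
    "binomial"       = c(alpha = 0, beta = 1)
  )
}

# Transformations between the natural parameter scale and the unconstrained
# optimization scale: (u, log v), (logit mu, log nu), (a, b) unchanged.
# The same scales are used for Mahalanobis outlier screening, where they are
# closer to multivariate normality than the natural scales.
.to_optim_scale <- function(model, params) {
  switch(model,
    "logit-logistic" = c(params[1L], log(params[2L])),
    "beta"           = c(stats::qlogis(params[1L]), log(params[2L])),
    "barton"         = params,
    "binomial"       = params,
    stop("no optimization scale for model '", model, "'")
  )
}

.from_optim_scale <- function(model, theta) {
  # clamp so that arbitrarily extreme unconstrained values (reachable when a
  # locus is fixed and the optimizer walks towards the boundary) still map
  # to admissible natural parameters
  switch(model,
    "logit-logistic" = c(u = theta[1L],
                         v = exp(min(max(theta[2L], -300), 300))),
    "beta" = c(mu = min(max(stats::plogis(theta[1L]), 1e-12), 1 - 1e-12),
               nu = exp(min(max(theta[2L], -300), 300))),
    "barton"         = c(a = theta[1L], b = theta[2L]),
    "binomial"       = c(alpha = theta[1L], beta = theta[2L]),
    stop("no optimization scale for model '", model, "'")
  )
}
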
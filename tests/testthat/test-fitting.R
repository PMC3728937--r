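# Likelihood computation, ML fitting, likelihood-ratio tests, regression
# baselines, AICc model selection, geographic clines.

test_that("cline and null log-likelihoods match hand-computed products of binomials", {
  # P(x = 2 | n = 2, p = 1) = 1
  d <- allele_counts(S = 1, x = 2, n = 2)
  expect_equal(null_loglik(d), 0)
  expect_equal(cline_loglik(d, "logit-logistic", c(0, 1)), 0)
  # C(2,1) * 0.5^2 = 0.5
  d <- allele_counts(S = 0.5, x = 1, n = 2)
  expect_equal(null_loglik(d), log(0.5))
  expect_equal(cline_loglik(d, "logit-logistic", c(0, 1)), log(0.5))
  # two units: 0.8^2 * 0.8^2 = 0.64 * 0.64
  d <- allele_counts(S = c(0.2, 0.8), x = c(0, 2), n = c(2, 2))
  expect_equal(cline_loglik(d, "beta", c(0.5, 2)), log(0.64 * 0.64))
  # 0.5^4
  expect_equal(null_loglik(allele_counts(0.5, 0, 4)), log(0.0625))
  # contradiction at a pinned endpoint is infinitely bad
  d <- allele_counts(S = 0, x = 1, n = 2)
  expect_identical(cline_loglik(d, "barton", c(0, 0)), -Inf)
})

test_that("ML fitting recovers generating parameters and never beats -Inf nesting", {
  # exact identity data with large counts
  S <- seq(0.1, 0.9, by = 0.1)
  d <- allele_counts(S, round(1000 * S), rep(1000, 9))
  fit <- fit_cline_ml(d, "logit-logistic")
  expect_true(fit$converged)
  expect_equal(unname(fit$params), c(0, 1), tolerance = 0.02)
  expect_gte(fit$loglik, null_loglik(d) - 1e-6)

  # stochastic recovery for each model (generating values as oracle)
  for (case in list(list("logit-logistic", c(1, 2)),
                    list("barton", c(0.3, 0.3)),
                    list("beta", c(0.3, 4)))) {
    d <- sim_cline_counts(case[[1]], case[[2]], K = 80L, n_per = 100L,
                          seed = 11L)
    fit <- fit_cline_ml(d, case[[1]])
    expect_true(fit$converged, info = case[[1]])
    expect_equal(unname(fit$params), case[[2]], tolerance = 0.15,
                 info = case[[1]])
  }

  # single unit: the null is attainable, the MLE can only improve on it
  d <- allele_counts(0.5, 1, 2)
  fit <- fit_cline_ml(d, "logit-logistic")
  expect_gte(fit$loglik, log(0.5) - 1e-6)
  expect_true(fit$nonidentifiable)
})

test_that("fitted log-likelihood never falls below the null (nesting)", {
  withr::with_seed(7L, {
    for (r in 1:15) {
      K <- sample(4:20, 1)
      S <- runif(K)
      n <- sample(2:40, K, replace = TRUE)
      d <- allele_counts(S, rbinom(K, n, runif(K)), n)
      model <- c("logit-logistic", "beta", "barton")[(r %% 3) + 1]
      expect_gte(fit_cline_ml(d, model, n_starts = 3L)$loglik,
                 null_loglik(d) - 1e-6)
    }
  })
})

test_that("multi-start searches agree from dispersed user starting points", {
  cases <- list(list("logit-logistic", c(1, 2)), list("beta", c(0.3, 4)),
                list("barton", c(0.3, 0.3)))
  for (case in cases) {
    d <- sim_cline_counts(case[[1]], case[[2]], K = 40L, n_per = 20L,
                          seed = 3L)
    f1 <- fit_cline_ml(d, case[[1]], n_starts = 5L)
    user <- switch(case[[1]],
      "logit-logistic" = rbind(c(3, 0.3), c(-3, 3), c(0.5, 5)),
      "beta" = rbind(c(0.1, 0.5), c(0.9, 8), c(0.5, 1)),
      "barton" = rbind(c(1, 1), c(-1, -1), c(0.5, -2)))
    f2 <- fit_cline_ml(d, case[[1]], starts = user, n_starts = 1L)
    expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  }
})

test_that("likelihood-ratio test against p = S", {
  d <- allele_counts(0.5, 1, 2)  # null loglik = log(0.5)
  fit <- structure(list(model = "logit-logistic", loglik = log(0.5) + 2,
                        n_params = 2L), class = "cline_fit")
  out <- lrt_vs_null(fit, d)
  expect_equal(out$stat, 4)
  expect_equal(out$df, 2L)
  expect_equal(out$p, exp(-2))  # chi^2_2 survival = exp(-stat/2)
  # zero improvement
  fit$loglik <- log(0.5)
  expect_equal(lrt_vs_null(fit, d)$p, 1)
  # the Bonferroni threshold for 100 loci inverts to its critical statistic
  fit$loglik <- log(0.5) + 15.2018 / 2
  expect_equal(lrt_vs_null(fit, d)$p, 0.0005, tolerance = 1e-4)
})

test_that("AICc arithmetic and domain", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17)
  expect_equal(aicc(-10, 4, 20), 28 + 40 / 15)
  expect_equal(aicc(0, 2, 1e7), 4, tolerance = 1e-5)
  expect_error(aicc(-10, 4, 5), "n > k \\+ 1")
})

test_that("binomial regression: flat data, association sign, shared likelihood", {
  S <- seq(0.1, 0.9, by = 0.1)
  # constant 50% response: slope and intercept both ~0
  d <- allele_counts(S, rep(5, 9), rep(10, 9))
  fit <- fit_binomial_regression(d)
  expect_equal(unname(fit$params), c(0, 0), tolerance = 1e-6)
  expect_false(fit$separated)
  # p = S pattern gives a positive slope
  d <- allele_counts(S, round(10 * S), rep(10, 9))
  fit <- fit_binomial_regression(d)
  expect_gt(fit$params[["beta"]], 0)
  # the reported loglik is the same product-of-binomials likelihood
  expect_equal(fit$loglik, cline_loglik(d, "binomial", fit$params),
               tolerance = 1e-8)
  # complete separation is flagged
  d <- allele_counts(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 10, 10), rep(10, 4))
  expect_true(fit_binomial_regression(d)$separated)
})

test_that("multinomial regression: intercept-only MLE, separation, HW recovery", {
  # single S value: fitted probabilities = observed proportions
  d <- genotype_counts(S = 0.5, n0 = 1, n1 = 2, n2 = 1)
  fit <- fit_multinomial_regression(d)
  expect_true(fit$intercept_only)
  expect_equal(fit$n_params, 2L)
  expect_equal(unname(fit$prob(0.5)[1, ]), c(0.25, 0.5, 0.25),
               tolerance = 1e-4)
  # loglik matches an independent dmultinom computation
  pr <- fit$prob(0.5)[1, ]
  expect_equal(fit$loglik, dmultinom(c(1, 2, 1), prob = pr, log = TRUE),
               tolerance = 1e-6)

  # all individuals homozygous P1: degenerate categories flagged
  d <- genotype_counts(S = c(0.3, 0.7), n0 = c(0, 0), n1 = c(0, 0),
                       n2 = c(5, 5))
  expect_true(fit_multinomial_regression(d)$separated)

  # Hardy-Weinberg data with p = S: the linear-in-S logit cannot represent
  # 2S(1-S) exactly, but the fitted heterozygote curve must approximate it
  S <- seq(0.05, 0.95, length.out = 30)
  d <- sim_hw_genotypes(S, n_per = 40L, seed = 5L)
  fit <- fit_multinomial_regression(d)
  expect_true(fit$converged)
  expect_equal(fit$n_params, 4L)
  Sq <- seq(0.2, 0.8, by = 0.1)
  expect_lt(max(abs(fit$prob(Sq)[, "p1"] - 2 * Sq * (1 - Sq))), 0.1)
})

test_that("AICc model choice is the argmin with a deterministic tie-break", {
  mk <- function(model, aicc) structure(list(model = model, aicc = aicc),
                                        class = "cline_fit")
  models <- c("logit-logistic", "beta", "barton", "binomial", "multinomial")
  fits <- Map(mk, models, c(10, 12, 14, 16, 18))
  expect_identical(best_model_per_locus(fits), "logit-logistic")
  # exact tie resolved by the fixed model order
  fits <- Map(mk, models, c(12, 10, 10, 16, 18))
  expect_identical(best_model_per_locus(fits), "beta")
  # brute-force argmin oracle on random values
  withr::with_seed(2L, for (r in 1:20) {
    vals <- round(runif(5, 0, 50), 1)
    fits <- Map(mk, models, vals)
    expect_identical(best_model_per_locus(fits), models[which.min(vals)])
  })
})

test_that("geographic cline fitting: recovery, symmetry, sign, flat data", {
  x <- seq(-3, 3, length.out = 13)
  withr::with_seed(8L, {
    k <- rbinom(13, 200, plogis(1 * (x - 1)))
    fit <- fit_geographic_cline(x, k, rep(200, 13))
    expect_equal(fit$b, 1, tolerance = 0.15)
    expect_equal(fit$m, 1, tolerance = 0.15)
    expect_false(fit$flat)
  })
  # symmetric crossing at zero
  k <- round(200 * plogis(2 * x))
  expect_equal(fit_geographic_cline(x, k, rep(200, 13))$m, 0,
               tolerance = 0.05)
  # decreasing frequencies give a negative slope
  k <- round(200 * plogis(-x))
  expect_lt(fit_geographic_cline(x, k, rep(200, 13))$b, 0)
  # flat data flagged
  fit <- fit_geographic_cline(x, rep(100, 13), rep(200, 13))
  expect_true(fit$flat)
  expect_true(is.na(fit$m))
})

test_that("LRT under p = S is calibrated at the nominal level", {
  # sampling-only null: many loci generated exactly under p = S
  withr::with_seed(31L, {
    S <- seq(0.05, 0.95, length.out = 20)
    rej <- replicate(500, {
      d <- allele_counts(S, rbinom(20, 100, S), rep(100, 20))
      fit <- fit_cline_ml(d, "logit-logistic", n_starts = 2L)
      lrt_vs_null(fit, d)$p <= 0.05
    })
    rate <- mean(rej)
    se <- sqrt(0.05 * 0.95 / 500)
    expect_lt(abs(rate - 0.05), 3 * se)
  })
})
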
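# Shared fixture builders (everything generated in code, nothing on disk).

# allele-count samples simulated from a named cline model
sim_cline_counts <- function(model, params, K = 50L, n_per = 40L,
                             S = seq(0.01, 0.99, length.out = K),
                             seed = NULL) {
  gen <- function() {
    p <- cline_prob(S, model, params)
    allele_counts(S, stats::rbinom(length(S), n_per, p),
                  rep(n_per, length(S)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# genotype-count samples under Hardy-Weinberg with allele frequency p(S)
sim_hw_genotypes <- function(S, n_per, p = S, seed = 1L) {
  withr::with_seed(seed, {
    g2 <- stats::rbinom(length(S), n_per, p^2)
    g1 <- stats::rbinom(length(S), n_per - g2, ifelse(p < 1, 2 * p * (1 - p) / (1 - p^2), 0))
    genotype_counts(S, n_per - g2 - g1, g1, g2)
  })
}

# small, fast simulator configuration for smoke tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(founders = 40L, n_loci = 12L, generations = 6L,
                   census_times = c(3L, 6L))
  do.call(sim_config, utils::modifyList(defaults, args))
}
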
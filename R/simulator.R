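# Individual-based simulation of secondary contact between two parental
# populations in continuous 2-D space, with local density-dependent
# reproduction and optional locus-specific selection.

#' Selection configuration
#'
#' Defines up to four modes of locus-specific selection acting on female
#' fecundity: an environmental gradient acting on the "E" locus, an
#' underdominant or overdominant "H" locus, and a Dobzhansky-Muller
#' incompatibility (DMI) between loci "A" and "B".  All remaining loci
#' are neutral.
#'
#' @param s_E strength of selection on the environmental phenotype
#'   (Gaussian stabilizing selection towards the local gradient value);
#'   0 disables it.  Typical study values: 2 or 4.
#' @param grad_b,grad_m slope and midpoint of the logistic environmental
#'   gradient `logit(g) = grad_b * (x - grad_m)`; a midpoint far outside
#'   the space (e.g. -4) makes the P1 allele universally favored.
#' @param h heterozygote disadvantage at the H locus in \[0, 1\].
#' @param s_H heterozygote advantage (homozygote disadvantage) at the H
#'   locus in \[0, 1\]; `h` and `s_H` are mutually exclusive.
#' @param d strength of the DMI between loci A and B in \[0, 1\].
#' @param direct optional length-3 vector of direct fitnesses for E-locus
#'   genotypes 0/1/2 (e.g. `c(0.2, 0.6, 1)` for a plain P1 advantage);
#'   `NULL` disables it.
#' @param loci named integer vector giving the column indices of the E,
#'   H, A and B loci (defaults 1--4; must be distinct).
#' @return an object of class `"selection_config"`.
#' @export
selection_config <- function(s_E = 0, grad_b = 1, grad_m = 1, h = 0,
                             s_H = 0, d = 0, direct = NULL,
                             loci = c(E = 1L, H = 2L, A = 3L, B = 4L)) {
  stopifnot(s_E >= 0, h >= 0, h <= 1, s_H >= 0, s_H <= 1, d >= 0, d <= 1)
  if (h > 0 && s_H > 0)
    stop("choose heterozygote disadvantage (h) or advantage (s_H), not both",
         call. = FALSE)
  if (anyDuplicated(loci)) stop("selected-locus indices must be distinct",
                                call. = FALSE)
  if (!all(c("E", "H", "A", "B") %in% names(loci)))
    stop("'loci' must name the E, H, A and B loci", call. = FALSE)
  if (!is.null(direct) && length(direct) != 3L)
    stop("'direct' must give fitnesses for genotypes 0, 1, 2", call. = FALSE)
  structure(list(s_E = s_E, grad_b = grad_b, grad_m = grad_m, h = h,
                 s_H = s_H, d = d, direct = direct,
                 loci = vapply(loci, as.integer, 1L)),
            class = "selection_config")
}

#' Simulation configuration
#'
#' Parameters of the secondary-contact simulator.  Defaults reproduce the
#' standard setting: a `[-3, 3] x [-3, 3]` continuous space, 500 founders
#' per side, 100 unlinked diagnostic loci, dispersal and mating kernels
#' with standard deviation 0.3 (5\% of the space), a density kernel with
#' standard deviation 0.2, and Beverton-Holt density regulation with
#' baseline growth rate `R = 2` and local carrying capacity `K = 14`,
#' which settles near 1000 individuals.
#'
#' @param structure `"hybrid_zone"` (spatially local mating and
#'   mother-centered dispersal) or `"admixture"` (random mating, offspring
#'   placed uniformly: a single panmictic population).
#' @param immigration `"closed"` (reflecting boundaries) or `"open"`
#'   (offspring landing within 5\% of the x-range of either x-boundary are
#'   replaced by pure parental genotypes: P1 on the low-x side, P2 on the
#'   high-x side).
#' @param n_loci number of unlinked diagnostic loci tracked (default 100).
#' @param founders individuals per parental side at secondary contact.
#' @param half_width half-width of the square space (default 3).
#' @param dispersal_sd,mating_sd,density_sd kernel standard deviations.
#' @param R baseline (uncrowded) growth rate, > 1.
#' @param K local carrying capacity: the local density at which expected
#'   fecundity equals replacement (1 offspring).
#' @param generations number of non-overlapping generations to run.
#' @param census_times generations at which to record full snapshots.
#' @param selection a [selection_config()].
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(structure = c("hybrid_zone", "admixture"),
                       immigration = c("closed", "open"),
                       n_loci = 100L, founders = 500L, half_width = 3,
                       dispersal_sd = 0.3, mating_sd = 0.3,
                       density_sd = 0.2, R = 2, K = 14,
                       generations = 50L,
                       census_times = c(10L, 25L, 50L, 100L),
                       selection = selection_config()) {
  structure_ <- match.arg(structure)
  immigration <- match.arg(immigration)
  stopifnot(dispersal_sd > 0, mating_sd > 0, density_sd > 0, R > 1, K > 0,
            n_loci >= 1L, founders >= 1L, half_width > 0, generations >= 1L)
  if (max(selection$loci) > n_loci)
    stop("selected-locus indices exceed 'n_loci'", call. = FALSE)
  structure(list(structure = structure_, immigration = immigration,
                 n_loci = as.integer(n_loci), founders = as.integer(founders),
                 half_width = half_width, dispersal_sd = dispersal_sd,
                 mating_sd = mating_sd, density_sd = density_sd, R = R,
                 K = K, generations = as.integer(generations),
                 census_times = as.integer(census_times),
                 selection = selection),
            class = "sim_config")
}

#' Initialize secondary contact
#'
#' Places `founders` pure P1 individuals (all loci genotype 2) uniformly
#' on the low-x half of the space and `founders` pure P2 individuals (all
#' genotype 0) on the high-x half; y-coordinates uniform over the full
#' height.
#'
#' @param config a [sim_config()].
#' @return a population: a list with numeric vectors `x`, `y` and an
#'   integer genotype matrix `geno` (individuals by loci), of class
#'   `"hz_population"`.
#' @export
init_secondary_contact <- function(config) {
  hw <- config$half_width
  nf <- config$founders
  x <- c(stats::runif(nf, -hw, 0), stats::runif(nf, 0, hw))
  y <- stats::runif(2L * nf, -hw, hw)
  geno <- rbind(matrix(2L, nf, config$n_loci),
                matrix(0L, nf, config$n_loci))
  structure(list(x = x, y = y, geno = geno), class = "hz_population")
}

#' @export
print.hz_population <- function(x, ...) {
  cat("Population of", length(x$x), "individuals,", ncol(x$geno), "loci;",
      "mean ancestry", signif(mean(ancestry_S(x)), 4L), "\n")
  invisible(x)
}

#' Genome-wide ancestry of simulated individuals
#'
#' @param pop an `"hz_population"`.
#' @return numeric vector: proportion of P1 alleles across all loci.
#' @export
ancestry_S <- function(pop) rowSums(pop$geno) / (2 * ncol(pop$geno))

#' Local population density
#'
#' Density experienced by each individual: the sum over all individuals
#' (including the focal one) of a normal density function of their
#' Euclidean distance from the focal individual, with standard deviation
#' `density_sd`.
#'
#' @param pop an `"hz_population"`.
#' @param density_sd kernel standard deviation (default 0.2).
#' @param focal optional single index; if given, only that individual's
#'   density is returned.
#' @return numeric vector of densities (length N, or 1 if `focal` given).
#' @export
local_density <- function(pop, density_sd = 0.2, focal = NULL) {
  if (!is.null(focal)) {
    d <- sqrt((pop$x - pop$x[focal])^2 + (pop$y - pop$y[focal])^2)
    return(sum(stats::dnorm(d, 0, density_sd)))
  }
  D <- as.matrix(stats::dist(cbind(pop$x, pop$y)))
  unname(colSums(stats::dnorm(D, 0, density_sd)))
}

#' Beverton-Holt expected fecundity
#'
#' Density-dependent expected offspring number
#' `f(D) = R / (1 + (R - 1) D / K)`: equal to the baseline growth rate
#' `R` in an empty neighborhood, monotone decreasing in local density
#' `D`, and exactly 1 (replacement) at `D = K`.
#'
#' @param D local density (>= 0).
#' @param R baseline growth rate.
#' @param K local carrying capacity.
#' @return expected offspring number(s).
#' @export
beverton_holt_fecundity <- function(D, R = 2, K = 14) {
  stopifnot(all(D >= 0), R > 1, K > 0)
  R / (1 + (R - 1) * D / K)
}

#' Environmental gradient
#'
#' Logistic gradient over the x-dimension:
#' `logit(g) = grad_b * (x - grad_m)`, so `g` runs from 0 (P2-favorable)
#' to 1 (P1-favorable).
#'
#' @param x spatial coordinate(s).
#' @param grad_b,grad_m gradient slope and midpoint.
#' @return gradient value(s) in (0, 1).
#' @export
env_gradient <- function(x, grad_b = 1, grad_m = 1) {
  stats::plogis(grad_b * (x - grad_m))
}

#' Environmental fitness component
#'
#' Gaussian stabilizing selection of the environmental phenotype `z`
#' (0, 0.5 or 1 for P2 homozygotes, heterozygotes and P1 homozygotes at
#' the E locus) towards the local gradient value `g`:
#' `w = exp(-s_E * (z - g)^2)`.  Matching phenotypes have fitness 1.
#'
#' @param z phenotype(s) in \[0, 1\].
#' @param g local gradient value(s).
#' @param s_E selection strength (>= 0); 0 gives fitness 1 everywhere.
#' @return fitness value(s) in (0, 1\].
#' @export
env_fitness <- function(z, g, s_E) {
  stopifnot(s_E >= 0)
  exp(-s_E * (z - g)^2)
}

#' Heterozygote advantage / disadvantage fitness
#'
#' Underdominance (`mode = "disadvantage"`): heterozygotes have fitness
#' `1 - strength`, homozygotes 1.  Overdominance (`mode = "advantage"`):
#' heterozygotes have fitness 1, homozygotes `1 - strength`.
#'
#' @param genotype count(s) of P1 alleles at the H locus (0, 1 or 2).
#' @param mode `"disadvantage"` or `"advantage"`.
#' @param strength selection coefficient in \[0, 1\].
#' @return fitness value(s).
#' @export
het_fitness <- function(genotype, mode = c("disadvantage", "advantage"),
                        strength) {
  mode <- match.arg(mode)
  stopifnot(strength >= 0, strength <= 1)
  het <- genotype == 1L
  if (mode == "disadvantage") ifelse(het, 1 - strength, 1)
  else ifelse(het, 1, 1 - strength)
}

#' Dobzhansky-Muller incompatibility fitness
#'
#' Fitness of two-locus genotypes under a partially recessive DMI between
#' the P2 allele at locus A and the P1 allele at locus B.  With `gA` and
#' `gB` the counts of P1 alleles: the P2/P2 homozygote at A combined with
#' the P1/P1 homozygote at B has fitness `1 - d`; the two singly
#' heterozygous combinations adjoining it have fitness `1 - d/2`; all
#' other genotypes (including both pure parental types) are unaffected.
#'
#' @param gA,gB counts of P1 alleles at loci A and B (0, 1 or 2).
#' @param d incompatibility strength in \[0, 1\].
#' @return fitness value(s).
#' @export
dmi_fitness <- function(gA, gB, d) {
  stopifnot(d >= 0, d <= 1)
  W <- matrix(1, 3L, 3L)  # rows gA = 0..2, cols gB = 0..2
  W[1L, 3L] <- 1 - d      # A2A2 x B1B1
  W[2L, 3L] <- 1 - d / 2  # A1A2 x B1B1
  W[1L, 2L] <- 1 - d / 2  # A2A2 x B1B2
  W[cbind(gA + 1L, gB + 1L)]
}

#' Relative fitness of each individual
#'
#' Product of the active selection components (environmental gradient,
#' heterozygote advantage/disadvantage, DMI, and optional direct
#' genotype fitnesses); 1 for every individual when no selection is
#' configured.  Selection acts only through female fecundity.
#'
#' @param pop an `"hz_population"`.
#' @param selection a [selection_config()].
#' @return numeric vector of relative fitnesses in (0, 1\].
#' @export
individual_fitness <- function(pop, selection) {
  w <- rep(1, length(pop$x))
  li <- selection$loci
  if (selection$s_E > 0) {
    g <- env_gradient(pop$x, selection$grad_b, selection$grad_m)
    z <- pop$geno[, li[["E"]]] / 2
    w <- w * env_fitness(z, g, selection$s_E)
  }
  if (!is.null(selection$direct))
    w <- w * selection$direct[pop$geno[, li[["E"]]] + 1L]
  if (selection$h > 0)
    w <- w * het_fitness(pop$geno[, li[["H"]]], "disadvantage", selection$h)
  if (selection$s_H > 0)
    w <- w * het_fitness(pop$geno[, li[["H"]]], "advantage", selection$s_H)
  if (selection$d > 0)
    w <- w * dmi_fitness(pop$geno[, li[["A"]]], pop$geno[, li[["B"]]],
                         selection$d)
  w
}

#' Draw a mate for a mother
#'
#' In the hybrid-zone model the father is sampled from all other
#' individuals with weight proportional to a normal density of their
#' distance from the mother (sd `mating_sd`); in the admixture model,
#' uniformly from all other individuals.  If every kernel weight
#' underflows to zero (an extremely isolated mother) the nearest
#' individual is chosen.
#'
#' @param pop an `"hz_population"` with at least 2 individuals.
#' @param mother index of the mother.
#' @param mating_sd kernel standard deviation.
#' @param structure `"hybrid_zone"` or `"admixture"`.
#' @return the index of the chosen father.
#' @export
choose_mate <- function(pop, mother, mating_sd = 0.3,
                        structure = c("hybrid_zone", "admixture")) {
  structure <- match.arg(structure)
  N <- length(pop$x)
  if (N < 2L) stop("mate choice needs at least 2 individuals", call. = FALSE)
  if (structure == "admixture") {
    f <- sample.int(N - 1L, 1L)
    return(f + (f >= mother))
  }
  d <- sqrt((pop$x - pop$x[mother])^2 + (pop$y - pop$y[mother])^2)
  wts <- stats::dnorm(d, 0, mating_sd)
  wts[mother] <- 0
  if (sum(wts) == 0) wts[which.min(replace(d, mother, Inf))] <- 1
  sample.int(N, 1L, prob = wts)
}

#' Mendelian offspring of two parents
#'
#' Each of the unlinked loci independently receives one allele from each
#' parent; an offspring allele at a locus is P1-derived with probability
#' genotype/2 for that parent.  The offspring position is drawn from a
#' bivariate normal centered on the mother (hybrid-zone model) or
#' uniformly over the space (admixture model).
#'
#' @param pop an `"hz_population"`.
#' @param mother,father parental indices.
#' @param config a [sim_config()].
#' @return a list with `x`, `y` (before boundary handling) and the
#'   offspring `genotype` vector.
#' @export
make_offspring <- function(pop, mother, father, config) {
  geno <- .mendel(pop$geno[mother, , drop = FALSE],
                  pop$geno[father, , drop = FALSE])[1L, ]
  if (config$structure == "hybrid_zone") {
    x <- pop$x[mother] + stats::rnorm(1L, 0, config$dispersal_sd)
    y <- pop$y[mother] + stats::rnorm(1L, 0, config$dispersal_sd)
  } else {
    hw <- config$half_width
    x <- stats::runif(1L, -hw, hw)
    y <- stats::runif(1L, -hw, hw)
  }
  list(x = x, y = y, genotype = geno)
}

# vectorized Mendelian inheritance for matrices of parental genotypes
.mendel <- function(gm, gf) {
  stopifnot(all(dim(gm) == dim(gf)))
  m <- matrix(stats::rbinom(length(gm), 1L, gm / 2), nrow = nrow(gm))
  f <- matrix(stats::rbinom(length(gf), 1L, gf / 2), nrow = nrow(gf))
  m + f
}

#' Boundary handling for newborn offspring
#'
#' Closed model: coordinates outside the space are reassigned to the
#' nearest edge (clamped) in both dimensions.  Open model: the
#' y-boundary still reflects, and offspring *drawing* a location within
#' 5\% of the x-range of either x-boundary (the strip inside the space)
#' are replaced by a pure parental genotype -- P1 (all genotype 2) on
#' the low-x side where P1 founders started, P2 (all genotype 0) on the
#' high-x side -- keeping their position.  Draws beyond the x-boundary
#' get the generic nearest-edge reassignment with their genotype kept;
#' replacing those too would pile immigrants into an atom at the edge
#' and push the per-side replacement rate well above the ~5\% of the
#' population the 5\% strip corresponds to.
#'
#' @param x,y numeric vectors of drawn offspring coordinates.
#' @param geno integer genotype matrix, one row per offspring.
#' @param config a [sim_config()].
#' @return a list with clamped `x`, `y`, possibly replaced `geno`, and
#'   `immigrants`, the counts `c(P1 = , P2 = )` of replaced offspring.
#' @export
apply_boundaries <- function(x, y, geno, config) {
  hw <- config$half_width
  imm <- c(P1 = 0L, P2 = 0L)
  if (config$immigration == "open") {
    zone <- 0.05 * (2 * hw)
    # replacement test on the drawn location, inside-the-space strip only
    p1 <- x >= -hw & x <= -hw + zone
    p2 <- x <= hw & x >= hw - zone
    geno[p1, ] <- 2L
    geno[p2, ] <- 0L
    imm <- c(P1 = sum(p1), P2 = sum(p2))
  }
  x <- pmin(pmax(x, -hw), hw)
  y <- pmin(pmax(y, -hw), hw)
  list(x = x, y = y, geno = geno, immigrants = imm)
}

#' Advance the population one generation
#'
#' Non-overlapping generations: every individual acts as the mother of a
#' Poisson number of offspring with mean `beverton_holt_fecundity(local
#' density) * individual_fitness`; each offspring independently draws a
#' father from the mating kernel, inherits Mendelianly at every locus,
#' disperses, and passes through boundary handling.  The offspring
#' cohort replaces the parents.
#'
#' @param pop an `"hz_population"`.
#' @param config a [sim_config()].
#' @return the next generation's `"hz_population"`, with attribute
#'   `immigrants` counting boundary replacements this generation.
#' @export
step_generation <- function(pop, config) {
  N <- length(pop$x)
  empty <- structure(list(x = numeric(0), y = numeric(0),
                          geno = matrix(integer(0), 0L, config$n_loci)),
                     immigrants = c(P1 = 0L, P2 = 0L),
                     class = "hz_population")
  if (N == 0L) return(empty)

  # squared pairwise distances, shared by the density and mating kernels
  xy <- cbind(pop$x, pop$y)
  sq <- rowSums(xy^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(xy)
  D2[D2 < 0] <- 0  # numerical noise on the diagonal
  sd_d <- config$density_sd
  dens <- colSums(exp(-D2 / (2 * sd_d^2))) / (sd_d * sqrt(2 * pi))
  fec <- beverton_holt_fecundity(dens, config$R, config$K)
  w <- individual_fitness(pop, config$selection)
  n_off <- stats::rpois(N, fec * w)
  if (N < 2L || sum(n_off) == 0L) return(empty)

  mothers <- rep.int(seq_len(N), n_off)
  M <- length(mothers)
  fathers <- integer(M)
  if (config$structure == "hybrid_zone") {
    W <- exp(-D2 / (2 * config$mating_sd^2))
    for (i in which(n_off > 0L)) {
      idx <- which(mothers == i)
      wi <- W[i, ]
      wi[i] <- 0
      if (sum(wi) == 0) wi[which.min(replace(D2[i, ], i, Inf))] <- 1
      cw <- cumsum(wi)
      fathers[idx] <- findInterval(stats::runif(length(idx)) * cw[N], cw,
                                   left.open = TRUE) + 1L
    }
  } else {
    f <- sample.int(N - 1L, M, replace = TRUE)
    fathers <- f + (f >= mothers)
  }

  geno <- .mendel(pop$geno[mothers, , drop = FALSE],
                  pop$geno[fathers, , drop = FALSE])
  if (config$structure == "hybrid_zone") {
    x <- pop$x[mothers] + stats::rnorm(M, 0, config$dispersal_sd)
    y <- pop$y[mothers] + stats::rnorm(M, 0, config$dispersal_sd)
  } else {
    hw <- config$half_width
    x <- stats::runif(M, -hw, hw)
    y <- stats::runif(M, -hw, hw)
  }
  b <- apply_boundaries(x, y, geno, config)
  structure(list(x = b$x, y = b$y, geno = b$geno),
            immigrants = b$immigrants, class = "hz_population")
}

#' Run a secondary-contact simulation
#'
#' Initializes the population with [init_secondary_contact()] and
#' advances it generation by generation, recording the census size and
#' immigrant replacements every generation and a full snapshot
#' (positions, genotypes, per-individual ancestry and per-locus allele
#' frequencies) at each census time.  Given a seed, the run is exactly
#' reproducible.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return an object of class `"hz_simulation"`: a list with `config`,
#'   `seed`, `census_sizes` (per generation), `immigrants` (generations
#'   by side matrix of replacement counts), `snapshots` (one per census
#'   time reached) and `final` (the last population).
#' @export
run_simulation <- function(config, seed = NULL) {
  engine <- function() {
    pop <- init_secondary_contact(config)
    G <- config$generations
    sizes <- integer(G)
    imm <- matrix(0L, G, 2L, dimnames = list(NULL, c("P1", "P2")))
    snaps <- list()
    for (gen in seq_len(G)) {
      pop <- step_generation(pop, config)
      sizes[gen] <- length(pop$x)
      imm[gen, ] <- attr(pop, "immigrants")
      if (gen %in% config$census_times)
        snaps[[as.character(gen)]] <- list(
          generation = gen, N = length(pop$x), x = pop$x, y = pop$y,
          geno = pop$geno, S = ancestry_S(pop),
          allele_freq = colMeans(pop$geno) / 2
        )
      if (length(pop$x) == 0L) break
    }
    structure(list(config = config, seed = seed, census_sizes = sizes,
                   immigrants = imm, snapshots = snaps, final = pop),
              class = "hz_simulation")
  }
  if (is.null(seed)) engine() else withr::with_seed(seed, engine())
}

#' @export
print.hz_simulation <- function(x, ...) {
  G <- x$config$generations
  cat("Secondary-contact simulation:", x$config$structure,
      paste0("(", x$config$immigration, ")"), "-", G, "generations\n")
  cat("  final census:", utils::tail(x$census_sizes, 1L), "individuals;",
      "snapshots at", paste(names(x$snapshots), collapse = ", "), "\n")
  invisible(x)
}

#' Genotype matrix of a simulation snapshot
#'
#' Converts a snapshot recorded by [run_simulation()] into a
#' [genotype_matrix()] so the fitting and I/O tools apply directly.
#'
#' @param snapshot one element of the `snapshots` list of an
#'   `"hz_simulation"`.
#' @return a [genotype_matrix()].
#' @export
snapshot_genotypes <- function(snapshot) {
  g <- snapshot$geno
  rownames(g) <- sprintf("g%d_i%d", snapshot$generation, seq_len(nrow(g)))
  genotype_matrix(g)
}
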
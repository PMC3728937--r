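# Genotype matrices for diagnostic biallelic markers, genome-wide ancestry
# estimation, and pooling of counts by individual or locality.

#' Construct a genotype matrix
#'
#' An integer matrix of N individuals by L loci holding counts (0, 1, 2)
#' of P1-derived alleles at diagnostic markers; `NA` marks missing
#' genotypes.  Which parental population is "P1" is a dataset-level
#' convention fixed by the caller.
#'
#' @param g numeric/integer matrix with entries in `{0, 1, 2, NA}`.
#' @param locality optional character/factor vector of locality labels,
#'   one per individual (row).
#' @return an object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(g, locality = NULL) {
  g <- as.matrix(g)
  bad <- !(g %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(g))
    stop("genotype entries must be 0, 1, 2 or NA; found '", g[idx],
         "' at row ", rc[1L], ", column ", rc[2L], call. = FALSE)
  }
  if (any(rowSums(!is.na(g)) == 0L))
    stop("every individual needs at least one non-missing genotype",
         call. = FALSE)
  storage.mode(g) <- "integer"
  if (is.null(rownames(g))) rownames(g) <- paste0("ind", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- paste0("L", seq_len(ncol(g)))
  if (!is.null(locality)) {
    if (length(locality) != nrow(g))
      stop("'locality' must have one label per individual", call. = FALSE)
    locality <- as.character(locality)
  }
  structure(g, locality = locality, class = c("genotype_matrix", "matrix"))
}

#' Read a genotype table from CSV/TSV
#'
#' Expects a header row of locus names, a first column of individual ids,
#' and optionally a column named `locality`; all other cells must be 0, 1,
#' 2 or NA (count of P1 alleles).  The separator is inferred from the
#' file extension (`.csv` = comma, otherwise tab) unless given.
#'
#' @param path file path.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one locus")
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  locality <- NULL
  if ("locality" %in% names(df)) {
    locality <- as.character(df[["locality"]])
    df <- df[, names(df) != "locality", drop = FALSE]
  }
  g <- as.matrix(df)
  suppressWarnings(storage.mode(g) <- "numeric")
  bad <- which(!(g %in% c(0, 1, 2, NA)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(g))
    stop("invalid genotype '", as.matrix(df)[bad[1L]], "' at row ", rc[1L],
         " (", ids[rc[1L]], "), locus '", colnames(g)[rc[2L]], "' in ",
         path, call. = FALSE)
  }
  rownames(g) <- ids
  genotype_matrix(g, locality = locality)
}

#' Write a genotype table to CSV/TSV
#'
#' Inverse of [read_genotype_table()]; a `locality` column is included
#' when the matrix carries locality labels.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path; extension picks the separator.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(gm), check.names = FALSE)
  loc <- attr(gm, "locality")
  if (!is.null(loc)) df$locality <- loc
  df <- cbind(df, as.data.frame(unclass(gm), check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genome-wide ancestry from diagnostic markers
#'
#' The hybrid index `S` of a unit is the proportion of its sampled allele
#' copies derived from P1: the sum of genotype values divided by twice the
#' number of non-missing loci.  At the locality level, counts are pooled
#' across the locality's individuals before dividing (allele-frequency
#' pooling), so individuals with more scored loci carry more weight.
#'
#' @param gm a [genotype_matrix()].
#' @param level `"individual"` or `"locality"`.
#' @return named numeric vector of ancestries in \[0, 1\], one per unit.
#' @export
estimate_S <- function(gm, level = c("individual", "locality")) {
  level <- match.arg(level)
  if (level == "individual") {
    s <- rowSums(gm, na.rm = TRUE) / (2 * rowSums(!is.na(gm)))
    names(s) <- rownames(gm)
    return(s)
  }
  loc <- attr(gm, "locality")
  if (is.null(loc)) stop("no locality labels in this genotype matrix",
                         call. = FALSE)
  num <- tapply(rowSums(gm, na.rm = TRUE), loc, sum)
  den <- tapply(2 * rowSums(!is.na(gm)), loc, sum)
  s <- num / den
  stats::setNames(as.vector(s), dimnames(s)[[1L]])
}

#' Pool allele and genotype counts for one locus
#'
#' Builds the per-unit count tables consumed by the fitting functions.
#' At the `"individual"` level each unit is one diploid (n = 2 alleles);
#' at the `"locality"` level genotypes are summed within localities.
#' Missing genotypes are excluded from both the allele count and the
#' total.  The ancestry `S` of each unit comes from [estimate_S()] at the
#' same level.
#'
#' @inheritParams estimate_S
#' @param locus locus name or column index.
#' @return a list with elements `allele` ([allele_counts()] table) and
#'   `genotype` ([genotype_counts()] table).
#' @export
pool_counts <- function(gm, locus, level = c("individual", "locality")) {
  level <- match.arg(level)
  g <- gm[, locus]
  S <- estimate_S(gm, level)
  if (level == "individual") {
    keep <- !is.na(g)
    allele <- allele_counts(S[keep], g[keep], rep(2L, sum(keep)),
                            unit = rownames(gm)[keep])
    genotype <- genotype_counts(S[keep], as.integer(g[keep] == 0L),
                                as.integer(g[keep] == 1L),
                                as.integer(g[keep] == 2L),
                                unit = rownames(gm)[keep])
  } else {
    loc <- attr(gm, "locality")
    if (is.null(loc)) stop("no locality labels in this genotype matrix",
                           call. = FALSE)
    units <- names(S)
    x <- tapply(g, loc, sum, na.rm = TRUE)[units]
    n <- tapply(!is.na(g), loc, sum)[units] * 2L
    keep <- n > 0L
    allele <- allele_counts(unname(S[keep]), unname(x[keep]),
                            unname(n[keep]), unit = units[keep])
    tab <- function(v) tapply(!is.na(g) & g == v, loc, sum)[units]
    genotype <- genotype_counts(unname(S[keep]), unname(tab(0L)[keep]),
                                unname(tab(1L)[keep]),
                                unname(tab(2L)[keep]), unit = units[keep])
  }
  list(allele = allele, genotype = genotype)
}

#' Deterministic genotype-matrix fixtures
#'
#' Generates a small dataset with known per-locus generating parameters,
#' for demonstrations and tests.  Individual ancestries are drawn uniform
#' on (0, 1) with three pure individuals anchoring each end; each locus'
#' genotype is then binomial(2, p) with p given by its generating cline.
#' Kinds: `"identity"` (all loci concordant, p = S), `"displaced"` (two
#' loci with logit-logistic u = +/-2), `"steep"` (two loci with v = 4),
#' and `"ringer"` (one locus with p = S but no heterozygotes ever
#' produced, mimicking a genotype-scoring artifact that only genotype-
#' level modeling can see).
#'
#' @param kind fixture flavor, see Details.
#' @param seed integer seed; the same seed always yields the same data.
#' @param n_ind,n_loci dimensions of the fixture (defaults 60 x 12).
#' @return a [genotype_matrix()] with attribute `truth`: a list holding
#'   the generating `S`, the per-locus `params` table, `kind` and `seed`.
#' @export
make_fixture <- function(kind = c("identity", "displaced", "steep", "ringer"),
                         seed = 1L, n_ind = 60L, n_loci = 12L) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    S <- c(rep(0, 3L), sort(stats::runif(n_ind - 6L)), rep(1, 3L))
    par_tab <- data.frame(locus = paste0("L", seq_len(n_loci)),
                          model = "logit-logistic", u = 0, v = 1,
                          ringer = FALSE)
    special <- switch(kind,
      identity  = integer(0),
      displaced = 1:2,
      steep     = 1:2,
      ringer    = 1L
    )
    if (kind == "displaced") par_tab$u[special] <- c(2, -2)
    if (kind == "steep") par_tab$v[special] <- 4
    if (kind == "ringer") par_tab$ringer[special] <- TRUE
    g <- matrix(NA_integer_, n_ind, n_loci)
    for (j in seq_len(n_loci)) {
      p <- logit_logistic_cline(S, par_tab$u[j], par_tab$v[j])
      g[, j] <- if (par_tab$ringer[j])
        2L * stats::rbinom(n_ind, 1L, p)  # alleles come in identical pairs
      else
        stats::rbinom(n_ind, 2L, p)
    }
    colnames(g) <- par_tab$locus
    gm <- genotype_matrix(g)
    attr(gm, "truth") <- list(S = S, params = par_tab, kind = kind,
                              seed = seed)
    gm
  })
}
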
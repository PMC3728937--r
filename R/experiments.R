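# Simulation-study harness: simulate secondary contact over a parameter
# grid, fit every model to every locus, tally naive-null rejections,
# AICc best-fit percentages, and outlier-detection performance.

#' Standard simulation parameter grid
#'
#' The 18 selection settings of the study design: no selection, an
#' environmental gradient at two strengths and two midpoints, heterozygote
#' disadvantage or advantage at two strengths, DMIs at two strengths,
#' combinations of gradient, underdominance and DMI, and a universal
#' P1-advantage gradient (midpoint far outside the space).  Run under
#' closed and open immigration for both population structures this gives
#' the full 72-run study.
#'
#' @return a `data.frame` with columns `grad_b`, `s_E`, `grad_m`, `h`,
#'   `s_H`, `d`, one row per selection setting.
#' @export
table2_grid <- function() {
  g <- rbind(
    c(0, 0,  0, 0,   0,   0),
    c(1, 2,  1, 0,   0,   0),
    c(1, 2,  2, 0,   0,   0),
    c(1, 4,  1, 0,   0,   0),
    c(1, 4,  2, 0,   0,   0),
    c(0, 0,  0, 0.4, 0,   0),
    c(0, 0,  0, 0.8, 0,   0),
    c(0, 0,  0, 0,   0,   0.4),
    c(0, 0,  0, 0,   0,   0.8),
    c(1, 2,  1, 0.4, 0,   0),
    c(1, 2,  2, 0.4, 0,   0),
    c(1, 2,  1, 0,   0,   0.4),
    c(1, 2,  2, 0,   0,   0.4),
    c(0, 0,  0, 0.4, 0,   0.4),
    c(1, 2,  1, 0.4, 0,   0.4),
    c(1, 2,  2, 0.4, 0,   0.4),
    c(0, 0,  0, 0,   0.8, 0),
    c(2, 4, -4, 0,   0,   0)
  )
  stats::setNames(as.data.frame(g),
                  c("grad_b", "s_E", "grad_m", "h", "s_H", "d"))
}

#' Study cells: selection settings crossed with conditions
#'
#' Expands a selection grid over population structures and immigration
#' regimes.  The full factorial of the standard grid gives 72 cells; for
#' desk-scale reruns, `conditions = "round_robin"` assigns each grid row
#' one of the four structure-by-immigration combinations in rotation,
#' covering all conditions with one run per selection setting.
#'
#' @param grid a selection grid as from [table2_grid()].
#' @param conditions `"full"` or `"round_robin"`.
#' @return a `data.frame` of cells with columns `structure`,
#'   `immigration` plus the selection columns.
#' @export
study_cells <- function(grid = table2_grid(),
                        conditions = c("full", "round_robin")) {
  conditions <- match.arg(conditions)
  combos <- expand.grid(structure = c("hybrid_zone", "admixture"),
                        immigration = c("closed", "open"),
                        stringsAsFactors = FALSE)
  if (conditions == "full") {
    out <- merge(combos, cbind(grid, .row = seq_len(nrow(grid))))
    out <- out[order(out$.row, out$structure, out$immigration), ]
    out$.row <- NULL
  } else {
    pick <- ((seq_len(nrow(grid)) - 1L) %% nrow(combos)) + 1L
    out <- cbind(combos[pick, ], grid)
  }
  rownames(out) <- NULL
  out
}

#' Indices of loci under selection
#'
#' @param selection a [selection_config()].
#' @return integer vector of selected locus indices (both DMI partners
#'   count as selected); empty for a neutral configuration.
#' @export
selected_loci <- function(selection) {
  li <- selection$loci
  out <- integer(0)
  if (selection$s_E > 0 || !is.null(selection$direct)) out <- c(out, li[["E"]])
  if (selection$h > 0 || selection$s_H > 0) out <- c(out, li[["H"]])
  if (selection$d > 0) out <- c(out, li[["A"]], li[["B"]])
  sort(unname(out))
}

#' Fit every model to every locus of a snapshot
#'
#' Treats each individual as a sampling unit (2 alleles), computes its
#' genome-wide ancestry from all loci, and fits the requested models to
#' every locus, recording parameter estimates (natural and optimization
#' scale), log-likelihood, AICc, and the likelihood-ratio test against
#' the naive null `p = S` (allele-count models only).
#'
#' @param snapshot a snapshot from [run_simulation()], or a
#'   [genotype_matrix()].
#' @param models character vector of models to fit.
#' @param n_starts multi-start count for [fit_cline_ml()].
#' @param level pooling level when `snapshot` is a genotype matrix.
#' @return a list with `fits` (long `data.frame`: one row per locus and
#'   model), `npar` (per-model matrix of natural-scale parameter
#'   estimates, loci in rows -- the default input for
#'   [detect_outliers()]) and `tpar` (the same on the optimization
#'   scale).  The natural scale is preferred for outlier screening:
#'   boundary-attracted estimates (e.g. a slope collapsing to v = 0 for
#'   a flat locus) sit harmlessly near zero there, whereas their
#'   log-scale coordinates are optimizer noise many SDs out.
#' @export
fit_snapshot <- function(snapshot,
                         models = c("logit-logistic", "beta", "barton",
                                    "binomial", "multinomial"),
                         n_starts = 5L,
                         level = c("individual", "locality")) {
  models <- match.arg(models, several.ok = TRUE)
  level <- match.arg(level)
  if (inherits(snapshot, "genotype_matrix")) gm <- snapshot
  else gm <- snapshot_genotypes(snapshot)
  L <- ncol(gm)
  loci <- colnames(gm)
  rows <- vector("list", L * length(models))
  tpar <- lapply(stats::setNames(models, models), function(m)
    matrix(NA_real_, L, if (m == "multinomial") 4L else 2L,
           dimnames = list(loci, NULL)))
  npar <- tpar
  r <- 0L
  for (j in seq_len(L)) {
    cnt <- pool_counts(gm, j, level)
    for (m in models) {
      fit <- switch(m,
        "binomial" = fit_binomial_regression(cnt$allele),
        "multinomial" = fit_multinomial_regression(cnt$genotype),
        fit_cline_ml(cnt$allele, m, n_starts = n_starts)
      )
      lrt <- if (m == "multinomial") list(stat = NA_real_, df = NA_integer_,
                                          p = NA_real_)
      else lrt_vs_null(fit, cnt$allele)
      pp <- c(fit$params, rep(NA_real_, 4L - length(fit$params)))
      tpar[[m]][j, seq_along(fit$tpar)] <- fit$tpar
      npar[[m]][j, seq_along(fit$params)] <- fit$params
      r <- r + 1L
      rows[[r]] <- data.frame(
        locus = loci[j], model = m, p1 = pp[1L], p2 = pp[2L], p3 = pp[3L],
        p4 = pp[4L], loglik = fit$loglik, n_params = fit$n_params,
        aicc = fit$aicc, lrt_stat = lrt$stat, lrt_df = lrt$df,
        lrt_p = lrt$p, converged = fit$converged
      )
    }
  }
  list(fits = do.call(rbind, rows), npar = npar, tpar = tpar)
}

#' Score outlier flags against known selected loci
#'
#' @param flags logical vector: locus flagged as outlier.
#' @param truth logical vector: locus truly under selection (both DMI
#'   partners count).
#' @return an object of class `"performance_tally"`: a list with
#'   `correct`, `missed`, `false_pos`, `precision` (`NA` when nothing is
#'   flagged) and `sensitivity`.
#' @export
score_outliers <- function(flags, truth) {
  if (length(flags) != length(truth))
    stop("'flags' and 'truth' must have equal length", call. = FALSE)
  correct <- sum(flags & truth)
  missed <- sum(!flags & truth)
  false_pos <- sum(flags & !truth)
  structure(list(
    correct = correct, missed = missed, false_pos = false_pos,
    precision = if (correct + false_pos > 0) correct / (correct + false_pos)
                else NA_real_,
    sensitivity = if (correct + missed > 0) correct / (correct + missed)
                  else NA_real_
  ), class = "performance_tally")
}

#' @export
print.performance_tally <- function(x, ...) {
  cat("correct", x$correct, "| missed", x$missed, "| false positives",
      x$false_pos, "| precision", signif(x$precision, 3L), "| sensitivity",
      signif(x$sensitivity, 3L), "\n")
  invisible(x)
}

# build a sim_config from one study-cell row
.cell_config <- function(cell, founders, n_loci, census_times, generations) {
  sel <- selection_config(s_E = cell$s_E, grad_b = cell$grad_b,
                          grad_m = cell$grad_m, h = cell$h, s_H = cell$s_H,
                          d = cell$d)
  sim_config(structure = cell$structure, immigration = cell$immigration,
             founders = founders, n_loci = n_loci,
             census_times = census_times, generations = generations,
             selection = sel)
}

#' Run the simulation study
#'
#' For every cell (a selection setting under a structure and immigration
#' condition): simulate secondary contact, and at each census time fit
#' all models to all loci, count Bonferroni-significant likelihood-ratio
#' rejections of the naive null among neutral loci, find each locus'
#' AICc-best model, and run multivariate outlier detection per model.
#' Seeds are derived deterministically from `seed` so the whole study is
#' reproducible.
#'
#' @param cells a `data.frame` from [study_cells()] (or any subset).
#' @param founders founders per parental side (500 in the full study).
#' @param n_loci loci per simulation (100 in the full study).
#' @param census_times generations at which to census and fit.
#' @param alpha family-wise error rate for both the LRT tally and
#'   outlier detection (Bonferroni-adjusted by the locus count).
#' @param n_starts multi-start count for the cline fits.
#' @param outlier_scale parameter scale for the Mahalanobis screen:
#'   `"natural"` (default; see [fit_snapshot()]) or `"optim"`.
#' @param seed integer base seed.
#' @return an object of class `"cline_study"`: a list with the `cells`
#'   table and `results`, one entry per cell holding per-census
#'   summaries (`N`, `fits`, `rejections`, `best_pct`, `flags`,
#'   `performance`, `truth`).
#' @export
run_study <- function(cells, founders = 500L, n_loci = 100L,
                      census_times = c(10L, 25L, 50L, 100L), alpha = 0.05,
                      n_starts = 5L, outlier_scale = c("natural", "optim"),
                      seed = 1L) {
  outlier_scale <- match.arg(outlier_scale)
  results <- vector("list", nrow(cells))
  models <- c("logit-logistic", "beta", "barton", "binomial", "multinomial")
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    cfg <- .cell_config(cell, founders, n_loci, census_times,
                        max(census_times))
    sim <- run_simulation(cfg, seed = seed + 1000L * i)
    truth_idx <- selected_loci(cfg$selection)
    truth <- seq_len(n_loci) %in% truth_idx
    per_census <- lapply(sim$snapshots, function(snap) {
      # strong selection can crash a run (e.g. overdominance in a closed
      # zone penalizes the all-homozygous founders); too-small censuses
      # cannot be fitted and are recorded but excluded from the tallies
      if (snap$N < 25L)
        return(list(generation = snap$generation, N = snap$N, fits = NULL,
                    rejections = NULL, best_pct = NULL, flags = NULL,
                    performance = NULL))
      fitted <- fit_snapshot(snap, models = models, n_starts = n_starts)
      fits <- fitted$fits
      p_crit <- alpha / n_loci
      rejections <- vapply(models, function(m) {
        pm <- fits$lrt_p[fits$model == m]
        sum(pm[!truth] <= p_crit, na.rm = TRUE)
      }, 0L)
      # same deterministic tie-break as best_model_per_locus()
      best <- vapply(unique(fits$locus), function(lc) {
        d <- fits[fits$locus == lc, ]
        d$model[order(d$aicc, match(d$model, .model_order))[1L]]
      }, "")
      best_pct <- 100 * vapply(models, function(m) mean(best == m), 0)
      par_mats <- if (outlier_scale == "natural") fitted$npar else
        fitted$tpar
      flags <- lapply(par_mats, function(tp)
        detect_outliers(tp, family_alpha = alpha)$flag)
      performance <- lapply(flags, score_outliers, truth = truth)
      list(generation = snap$generation, N = snap$N, fits = fits,
           rejections = rejections, best_pct = best_pct, flags = flags,
           performance = performance)
    })
    results[[i]] <- list(cell = cell, seed = seed + 1000L * i,
                         truth = truth, censuses = per_census)
  }
  structure(list(cells = cells, results = results, alpha = alpha,
                 n_loci = n_loci, seed = seed),
            class = "cline_study")
}

# is a study cell free of selection?
.is_neutral_cell <- function(cell) {
  cell$s_E == 0 && cell$h == 0 && cell$s_H == 0 && cell$d == 0
}

#' Tally naive-null rejections in no-selection runs
#'
#' Counts, for each no-selection cell and census, the neutral loci whose
#' likelihood-ratio test rejects `p = S` at the Bonferroni-adjusted
#' level.  Rising counts over generations reflect genetic drift, not
#' selection -- the central caution against naive null tests.
#'
#' @param study a `"cline_study"`.
#' @param models models to tabulate (those with an LRT).
#' @return a long `data.frame` with columns `structure`, `immigration`,
#'   `time`, `N`, `model`, `rejections`.
#' @export
tabulate_null_rejections <- function(study,
                                     models = c("barton", "beta",
                                                "logit-logistic")) {
  out <- list()
  for (res in study$results) {
    if (!.is_neutral_cell(res$cell)) next
    for (cen in res$censuses) {
      if (is.null(cen$rejections)) next
      out[[length(out) + 1L]] <- data.frame(
        structure = res$cell$structure, immigration = res$cell$immigration,
        time = cen$generation, N = cen$N, model = models,
        rejections = unname(cen$rejections[models])
      )
    }
  }
  do.call(rbind, out)
}

#' Tabulate AICc best-fit percentages
#'
#' Average percentage of loci best fit by each model, per census time,
#' immigration regime and population structure (averaged over the
#' study's cells in each group).
#'
#' @param study a `"cline_study"`.
#' @return a `data.frame` with one row per (time, immigration,
#'   structure) and one column per model; model columns sum to 100
#'   within each row.
#' @export
tabulate_best_fit <- function(study) {
  rows <- list()
  for (res in study$results) for (cen in res$censuses) {
    if (is.null(cen$best_pct)) next
    rows[[length(rows) + 1L]] <- data.frame(
      time = cen$generation, immigration = res$cell$immigration,
      structure = res$cell$structure, t(cen$best_pct), check.names = FALSE
    )
  }
  long <- do.call(rbind, rows)
  models <- setdiff(names(long), c("time", "immigration", "structure"))
  agg <- stats::aggregate(long[models],
                          long[c("time", "immigration", "structure")], mean)
  agg[order(agg$structure, agg$immigration, agg$time), ]
}

#' Pooled outlier-detection performance by model
#'
#' Pools correct detections, misses and false positives over every cell
#' and census of the study and reports precision and sensitivity per
#' model.
#'
#' @param study a `"cline_study"`.
#' @return a `data.frame` with columns `model`, `correct`, `missed`,
#'   `false_pos`, `precision`, `sensitivity`.
#' @export
tabulate_outlier_performance <- function(study) {
  models <- NULL
  for (res in study$results) for (cen in res$censuses)
    if (!is.null(cen$performance)) models <- names(cen$performance)
  if (is.null(models)) stop("no fitted censuses in this study", call. = FALSE)
  tot <- lapply(stats::setNames(models, models), function(m)
    c(correct = 0L, missed = 0L, false_pos = 0L))
  for (res in study$results) for (cen in res$censuses) {
    if (is.null(cen$performance)) next
    for (m in models) {
      p <- cen$performance[[m]]
      tot[[m]] <- tot[[m]] + c(p$correct, p$missed, p$false_pos)
    }
  }
  out <- data.frame(
    model = models,
    correct = vapply(tot, `[[`, 0L, "correct"),
    missed = vapply(tot, `[[`, 0L, "missed"),
    false_pos = vapply(tot, `[[`, 0L, "false_pos"),
    row.names = NULL
  )
  out$precision <- ifelse(out$correct + out$false_pos > 0,
                          out$correct / (out$correct + out$false_pos),
                          NA_real_)
  out$sensitivity <- ifelse(out$correct + out$missed > 0,
                            out$correct / (out$correct + out$missed),
                            NA_real_)
  out
}

#' @export
print.cline_study <- function(x, ...) {
  cat("Genomic cline simulation study:", nrow(x$cells), "cells,",
      x$n_loci, "loci, seed", x$seed, "\n")
  print(tabulate_outlier_performance(x))
  invisible(x)
}
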
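## Summary statistics over per-cell simulation output tables. All
## summaries are pure functions of the long tables produced by
## run_simulation(), so they can be recomputed offline.

.tumor_rows <- function(cells) cells[cells$type %in% 1:3, , drop = FALSE]

.window_rows <- function(cells, window) {
  cells[cells$time >= window[1] & cells$time <= window[2], , drop = FALSE]
}

#' Epithelial IFNg exposure difference: heterogeneous vs homogeneous
#'
#' For matched pairs of runs (same seed, heterogeneity on/off), computes
#' the percent reduction of mean IFNg sensed by epithelial tumor cells in
#' heterogeneous relative to homogeneous tumors:
#' `100 * (mean_hom - mean_het) / mean_hom`. Means are taken per
#' replicate over all epithelial cell-time points in the window, then
#' pooled across replicates (per-replicate-then-pool).
#'
#' @param het,hom Lists of `multiscale_run` objects (or their `cells`
#'   tables), matched by position.
#' @param window Time window (minutes, inclusive).
#' @return Percent difference (positive = heterogeneous tumors are less
#'   exposed); attribute `per_replicate` carries the per-pair values.
#' @export
epithelial_ifng_exposure <- function(het, hom, window) {
  get_cells <- function(r) if (inherits(r, "multiscale_run")) r$cells
                           else r
  if (inherits(het, "multiscale_run")) het <- list(het)
  if (inherits(hom, "multiscale_run")) hom <- list(hom)
  stopifnot(length(het) == length(hom))
  mean_e <- function(r) {
    cc <- .window_rows(get_cells(r), window)
    cc <- cc[cc$type == 1L, , drop = FALSE]
    if (!nrow(cc))
      stop("epithelial_ifng_exposure: no epithelial cells in window")
    mean(cc$sense_ifng)
  }
  mh <- vapply(het, mean_e, 0)
  mo <- vapply(hom, mean_e, 0)
  per <- 100 * (mo - mh) / mo
  out <- 100 * (mean(mo) - mean(mh)) / mean(mo)
  attr(out, "per_replicate") <- per
  out
}

#' Fraction of tumor cells in the hybrid E/M phenotype
#'
#' @param run A `multiscale_run` (or its `cells` table).
#' @param window Time window (minutes, inclusive).
#' @return Fraction in `[0, 1]`; attribute `by_phenotype` gives the full
#'   phenotype composition (fractions summing to 1).
#' @export
hybrid_fraction <- function(run, window) {
  cells <- if (inherits(run, "multiscale_run")) run$cells else run
  cc <- .tumor_rows(.window_rows(cells, window))
  if (!nrow(cc)) stop("hybrid_fraction: no tumor cells in window")
  comp <- c(E = mean(cc$type == 1L), H = mean(cc$type == 2L),
            M = mean(cc$type == 3L))
  out <- comp[["H"]]
  attr(out, "by_phenotype") <- comp
  out
}

#' Population-level expression and composition curves
#'
#' Time-resolved mean and SEM (over replicates) of membrane PD-L1 and
#' ZEB1 mRNA expression of tumor cells, plus phenotype counts per
#' condition.
#'
#' @param runs List of `multiscale_run` objects (>= 2 for a nonzero
#'   SEM); all must share output times.
#' @return Data.frame with one row per time point: `pm_mean`, `pm_sem`,
#'   `mz_mean`, `mz_sem`, `n_E`, `n_H`, `n_M` (replicate-mean counts)
#'   and `n_replicates`.
#' @export
population_curves <- function(runs) {
  if (inherits(runs, "multiscale_run")) runs <- list(runs)
  per_rep <- lapply(runs, function(r) {
    cells <- .tumor_rows(if (inherits(r, "multiscale_run")) r$cells
                         else r)
    stats::aggregate(cbind(pm, mz) ~ time, data = cells, FUN = mean) |>
      merge(stats::aggregate(cbind(E = type == 1L, H = type == 2L,
                                   M = type == 3L) ~ time, data = cells,
                             FUN = sum))
  })
  times <- per_rep[[1]]$time
  for (r in per_rep) stopifnot(identical(r$time, times))
  n <- length(per_rep)
  pull <- function(col) sapply(per_rep, `[[`, col)
  sem <- function(m) if (n > 1) apply(m, 1, stats::sd) / sqrt(n)
                     else rep(0, nrow(m))
  pm <- pull("pm"); mz <- pull("mz")
  data.frame(time = times,
             pm_mean = rowMeans(pm), pm_sem = sem(pm),
             mz_mean = rowMeans(mz), mz_sem = sem(mz),
             n_E = rowMeans(pull("E")), n_H = rowMeans(pull("H")),
             n_M = rowMeans(pull("M")), n_replicates = n)
}
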
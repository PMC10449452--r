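## Branch sweeps, fold bracketing and phase diagrams over control
## parameters (SNAIL1, TGFb, basal IFNg production).

.set_control <- function(p, control, value) {
  switch(control,
         snail1 = list(p = p, snail_fixed = value),
         tgfb = { p$gt <- value; list(p = p, snail_fixed = NULL) },
         gI = { p$gi <- value; list(p = p, snail_fixed = NULL) },
         stop("unknown control parameter: ", control))
}

## solve equilibria at one control value, reusing previous solutions as
## Newton warm starts; fresh multi-start on schedule
.solve_point <- function(p, control, value, warm, fresh, seed) {
  cfg <- .set_control(p, control, value)
  sols <- list()
  if (length(warm)) {
    idx <- .free_idx(cfg$snail_fixed, NULL, NULL)
    template <- regulatory_initial_state(cfg$p)
    if (!is.null(cfg$snail_fixed)) template[["s"]] <- cfg$snail_fixed
    fun <- function(xfree) {
      y <- template; y[idx] <- xfree
      rhs_full(y, cfg$p, snail_fixed = cfg$snail_fixed)[idx]
    }
    for (w in warm) {
      ref <- tryCatch(.newton_refine(fun, pmax(w[idx], 0)),
                      error = function(e) NULL)
      if (!is.null(ref)) {
        y <- template; y[idx] <- ref
        sols[[length(sols) + 1]] <- y
      }
    }
    sols <- .dedup_states(sols, idx)
    ## stability for warm-started solutions
    if (length(sols)) {
      rows <- lapply(sols, function(y) {
        J <- .fd_jacobian(fun, y[idx])
        mre <- max(Re(eigen(J, only.values = TRUE)$values))
        data.frame(as.list(y), stable = mre < 1e-6,
                   phenotype = equilibrium_phenotype(y[["mz"]]),
                   max_re_eig = mre, stringsAsFactors = FALSE)
      })
      warm_eq <- do.call(rbind, rows)
    } else warm_eq <- .empty_equilibrium_set()
  } else warm_eq <- .empty_equilibrium_set()

  if (fresh || !nrow(warm_eq)) {
    eq <- find_equilibria(cfg$p, n_starts = 20, seed = seed,
                          snail_fixed = cfg$snail_fixed,
                          find_unstable = TRUE)
    both <- rbind(warm_eq, eq)
    ## de-dup rows in log1p space
    keepers <- !logical(nrow(both))
    sn <- regulatory_state_names()
    for (i in seq_len(nrow(both))) {
      if (!keepers[i]) next
      for (j in seq_len(i - 1L)) {
        if (!keepers[j]) next
        a <- log1p(pmax(as.numeric(both[i, sn]), 0))
        b <- log1p(pmax(as.numeric(both[j, sn]), 0))
        if (max(abs(a - b) / pmax(abs(b), 1)) < 1e-4) {
          keepers[i] <- FALSE; break
        }
      }
    }
    eq <- both[keepers, , drop = FALSE]
  } else eq <- warm_eq
  eq <- eq[order(eq$mz), , drop = FALSE]
  rownames(eq) <- NULL
  eq
}

#' Sweep equilibrium branches over a control parameter
#'
#' Natural continuation over a parameter grid: equilibria at each grid
#' point are seeded from the previous point's solutions (damped Newton)
#' and a fresh multi-start search is added at the first point and every
#' `fresh_every`-th point. Branches are assembled by nearest-neighbor
#' matching in log1p state space; saddle-node (fold) locations are
#' bracketed between grid points where the set of stable phenotypes
#' changes, and reported as interval midpoints with the half-width as
#' uncertainty.
#'
#' @param p Parameter set ([regulatory_parameters()]); its
#'   `inhibition_mode` selects the model variant.
#' @param control `"snail1"` (molecules, SNAIL1 clamped), `"tgfb"`
#'   (nM, via the TGFb production rate with `kt = 1/h`), or `"gI"`
#'   (nM/h basal IFNg production).
#' @param range Length-2 numeric range of the control.
#' @param n_points Number of grid points (>= 50 for production use).
#' @param seed RNG seed for the multi-start searches.
#' @param fresh_every Fresh multi-start cadence.
#' @return A data.frame of class `bifurcation_branches` with columns
#'   `control`, `value`, the 11 state variables, `stable`, `phenotype`,
#'   `branch`; attribute `folds` is a data.frame of bracketed fold
#'   locations.
#' @export
sweep_branches <- function(p, control = c("snail1", "tgfb", "gI"),
                           range, n_points = 50, seed = 1,
                           fresh_every = 10) {
  control <- match.arg(control)
  grid <- seq(range[1], range[2], length.out = n_points)
  sn <- regulatory_state_names()
  res <- list(); warm <- list()
  branch_ids <- integer(0); next_branch <- 1L
  prev_states <- NULL
  for (k in seq_along(grid)) {
    eq <- .solve_point(p, control, grid[k], warm,
                       fresh = (k == 1L || k %% fresh_every == 0L),
                       seed = seed + k)
    if (!nrow(eq)) {
      warning(sprintf("sweep_branches: no equilibria at %s = %g; skipped",
                      control, grid[k]))
      next
    }
    ## nearest-neighbor branch matching in log1p state space
    cur_states <- log1p(pmax(as.matrix(eq[, sn]), 0))
    ids <- integer(nrow(eq))
    if (!is.null(prev_states) && nrow(prev_states)) {
      used <- logical(nrow(prev_states))
      for (i in seq_len(nrow(eq))) {
        d <- apply(prev_states, 1, function(r)
          sqrt(sum((r - cur_states[i, ])^2)))
        j <- which.min(ifelse(used, Inf, d))
        if (length(j) && is.finite(d[j]) && d[j] < 2) {
          ids[i] <- branch_ids[j]; used[j] <- TRUE
        } else { ids[i] <- next_branch; next_branch <- next_branch + 1L }
      }
    } else {
      ids <- seq_len(nrow(eq)); next_branch <- nrow(eq) + 1L
    }
    prev_states <- cur_states; branch_ids <- ids
    warm <- lapply(seq_len(nrow(eq)), function(i) {
      y <- as.numeric(eq[i, sn]); names(y) <- sn; y
    })
    eq$control <- control; eq$value <- grid[k]; eq$branch <- ids
    res[[length(res) + 1]] <- eq
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "folds") <- .bracket_folds(out)
  class(out) <- c("bifurcation_branches", "data.frame")
  out
}

## fold bracketing: a saddle-node is detected where the number of
## stable equilibria changes between adjacent grid points (a branch
## drifting across a phenotype label cutoff is not a fold); the stable
## phenotype sets are reported alongside for interpretation
.bracket_folds <- function(branches) {
  vals <- sort(unique(branches$value))
  nst <- vapply(vals, function(v)
    sum(branches$value == v & branches$stable), 0L)
  lab <- vapply(vals, function(v) {
    ph <- sort(unique(branches$phenotype[branches$value == v &
                                           branches$stable]))
    paste(ph, collapse = "+")
  }, "")
  ch <- which(nst[-1] != nst[-length(nst)])
  if (!length(ch))
    return(data.frame(location = numeric(0), uncertainty = numeric(0),
                      n_from = integer(0), n_to = integer(0),
                      multiplicity = integer(0),
                      from = character(0), to = character(0)))
  ## |delta n| folds share a bracket when two saddle-nodes fall inside
  ## the same grid interval
  data.frame(location = (vals[ch] + vals[ch + 1]) / 2,
             uncertainty = (vals[ch + 1] - vals[ch]) / 2,
             n_from = nst[ch], n_to = nst[ch + 1],
             multiplicity = abs(nst[ch + 1] - nst[ch]),
             from = lab[ch], to = lab[ch + 1],
             stringsAsFactors = FALSE)
}

#' Fold (saddle-node) locations of a branch sweep
#' @param branches Result of [sweep_branches()].
#' @return Data.frame of bracketed fold locations.
#' @export
fold_locations <- function(branches) attr(branches, "folds")

#' Long-format branch table
#'
#' Reshapes a [sweep_branches()] result to the delimited long format
#' `(control_param, value, variable, level, stable, phenotype)`.
#' @param branches Result of [sweep_branches()].
#' @param variables State variables to include.
#' @export
branch_table_long <- function(branches,
                              variables = c("pm", "mz", "u", "z")) {
  rows <- lapply(variables, function(v)
    data.frame(control_param = branches$control, value = branches$value,
               variable = v, level = branches[[v]],
               stable = branches$stable, phenotype = branches$phenotype,
               branch = branches$branch, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Phase diagram of stable-state sets
#'
#' Labels each cell of a 2-D parameter grid with the set of stable
#' phenotypes present (e.g. `"E+E/M+M"`). Rows (fixed `axis2` value) are
#' swept with warm-started continuation along `axis1`.
#'
#' @param p Parameter set.
#' @param axis1,axis2 Lists `list(name = , range = )` with name one of
#'   `"snail1"`, `"tgfb"`, `"gI"`.
#' @param resolution Grid points per axis (>= 30 for production use).
#' @param seed RNG seed.
#' @return Data.frame of class `phase_diagram` with columns `axis1`,
#'   `axis2`, `label`.
#' @export
phase_diagram <- function(p, axis1, axis2, resolution = 30, seed = 1) {
  g1 <- seq(axis1$range[1], axis1$range[2], length.out = resolution)
  g2 <- seq(axis2$range[1], axis2$range[2], length.out = resolution)
  out <- vector("list", length(g2))
  for (j in seq_along(g2)) {
    cfg2 <- .set_control(p, axis2$name, g2[j])
    stopifnot(is.null(cfg2$snail_fixed) || axis1$name != "snail1")
    pj <- cfg2$p
    warm <- list()
    labs <- character(length(g1))
    for (i in seq_along(g1)) {
      eq <- .solve_point(pj, axis1$name, g1[i], warm,
                         fresh = (i == 1L || i %% 5L == 0L),
                         seed = seed + 1000L * j + i)
      if (axis2$name == "snail1") stop("snail1 must be axis1")
      labs[i] <- paste(sort(unique(eq$phenotype[eq$stable])),
                       collapse = "+")
      sn <- regulatory_state_names()
      warm <- lapply(seq_len(nrow(eq)), function(r) {
        y <- as.numeric(eq[r, sn]); names(y) <- sn; y
      })
    }
    out[[j]] <- data.frame(axis1 = g1, axis2 = g2[j], label = labs,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  names(res)[1:2] <- c(axis1$name, axis2$name)
  class(res) <- c("phase_diagram", "data.frame")
  res
}

#' Sensitivity of fold structure to the inhibition parameters
#'
#' Multiplies each listed shifted-Hill parameter of the immunosuppressive
#' feedbacks by each factor, re-runs a reference branch sweep, and
#' reports the fold count and locations. Qualitative robustness means an
#' unchanged fold count.
#'
#' @param p Parameter set.
#' @param inhibition_params Parameter names to perturb (defaults to the
#'   PD-L1- and TGFb-inhibition Hill parameters).
#' @param factors Multiplicative perturbation factors.
#' @param control,range,n_points Reference sweep (defaults: SNAIL1 over
#'   1.6e5--2.2e5 molecules).
#' @param seed RNG seed.
#' @return Data.frame with one row per (parameter, factor): `n_folds`
#'   and comma-separated `fold_locations`.
#' @export
sensitivity_sweep <- function(p,
                              inhibition_params = c("lpm_i", "npm_i",
                                                    "pm0_i", "lt_i",
                                                    "nt_i", "t0_i"),
                              factors = c(0.5, 1, 2),
                              control = "snail1",
                              range = c(1.6e5, 2.2e5), n_points = 25,
                              seed = 1) {
  rows <- list()
  for (par in inhibition_params) {
    if (is.null(p[[par]])) stop("unknown inhibition parameter: ", par)
    for (f in factors) {
      pp <- p; pp[[par]] <- pp[[par]] * f
      br <- sweep_branches(pp, control, range, n_points, seed = seed)
      fl <- fold_locations(br)
      rows[[length(rows) + 1]] <- data.frame(
        param = par, factor = f, n_folds = sum(fl$multiplicity),
        fold_locations = paste(signif(fl$location, 6), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
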
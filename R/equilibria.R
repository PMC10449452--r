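## Steady states of the regulatory network: multi-start location, damped
## Newton refinement, stability from the finite-difference Jacobian.

## Free variables of the root problem depend on the clamping: with SNAIL1
## fixed, ms and s are excluded; clamped cytokines are excluded likewise.
.free_idx <- function(snail_fixed, clamp_ifng, clamp_tgfb) {
  nm <- regulatory_state_names()
  drop <- character(0)
  if (!is.null(snail_fixed)) drop <- c(drop, "ms", "s")
  if (!is.null(clamp_ifng)) drop <- c(drop, "ifng")
  if (!is.null(clamp_tgfb)) drop <- c(drop, "tgfb")
  which(!nm %in% drop)
}

.fd_jacobian <- function(fun, x, eps = 1e-6) {
  f0 <- fun(x)
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * (1 + abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (fun(xp) - f0) / h
  }
  J
}

## damped Newton on the free subsystem; returns refined x or NULL
.newton_refine <- function(fun, x, max_iter = 50, tol = 1e-9) {
  sc <- pmax(abs(x), 1)
  for (it in seq_len(max_iter)) {
    f <- fun(x)
    if (max(abs(f / sc)) < tol) return(x)
    J <- .fd_jacobian(fun, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    f0n <- sum((f / sc)^2)
    repeat {
      xn <- pmax(x + lam * step, 0)
      fn <- fun(xn)
      if (sum((fn / sc)^2) < f0n || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(xn - x) / sc) < 1e-14) { x <- xn; break }
    x <- xn
  }
  f <- fun(x)
  if (max(abs(f / pmax(abs(x), 1))) < 1e-6) x else NULL
}

#' Find equilibria of the regulatory network
#'
#' Locates steady states by stiff integration from multiple starts
#' (canonical epithelial/hybrid/mesenchymal basin points plus log-uniform
#' random draws over physiological ranges), refines each endpoint with a
#' damped Newton iteration using a finite-difference Jacobian, de-duplicates
#' in log1p space (relative tolerance 1e-4), and flags stability from the
#' Jacobian eigenvalues. Saddle points between adjacent stable states are
#' additionally sought by Newton from interpolated starts.
#'
#' @inheritParams rhs_full
#' @param p Parameter set.
#' @param n_starts Total number of starts (>= 20).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param t_relax Integration horizon (hours) used to approach attractors.
#' @param find_unstable Also attempt to locate saddle points.
#' @return A data.frame of class `equilibrium_set`, one row per
#'   equilibrium, with the 11 state variables, `stable` (logical),
#'   `phenotype` (`"E"`, `"E/M"`, `"M"`), and `max_re_eig`.
#' @examples
#' \donttest{
#' p <- regulatory_parameters("none", gi = 0.1)
#' eq <- find_equilibria(p, snail_fixed = 1.95e5, seed = 1)
#' }
#' @export
find_equilibria <- function(p, n_starts = 20, seed = 1,
                            snail_fixed = NULL, clamp_ifng = NULL,
                            clamp_tgfb = NULL, t_relax = 3000,
                            find_unstable = TRUE) {
  if (n_starts < 20) stop("find_equilibria: n_starts must be >= 20")
  idx <- .free_idx(snail_fixed, clamp_ifng, clamp_tgfb)
  nm <- regulatory_state_names()
  template <- regulatory_initial_state(p)
  if (!is.null(snail_fixed)) template[["s"]] <- snail_fixed
  if (!is.null(clamp_ifng)) template[["ifng"]] <- clamp_ifng
  if (!is.null(clamp_tgfb)) template[["tgfb"]] <- clamp_tgfb

  fun <- function(xfree) {
    y <- template
    y[idx] <- xfree
    rhs_full(y, p, snail_fixed = snail_fixed, clamp_ifng = clamp_ifng,
             clamp_tgfb = clamp_tgfb)[idx]
  }

  ## canonical basin starts (u, mz, z) + random log-uniform draws
  basins <- list(c(20000, 50, 1000), c(5000, 420, 40000),
                 c(150, 1000, 7e5), c(1500, 250, 2e5), c(12000, 700, 1e5))
  starts <- lapply(basins, function(b) {
    y <- template; y[["u"]] <- b[1]; y[["mz"]] <- b[2]; y[["z"]] <- b[3]
    y
  })
  rng <- .save_seed()
  on.exit(.restore_seed(rng))
  set.seed(seed)
  n_rand <- max(0, n_starts - length(starts))
  for (k in seq_len(n_rand)) {
    y <- template
    y[["u"]] <- 10^stats::runif(1, 1, 4.5)
    y[["mz"]] <- 10^stats::runif(1, 0, 3.3)
    y[["z"]] <- 10^stats::runif(1, 1, 6)
    starts[[length(starts) + 1]] <- y
  }

  sols <- list()
  for (y0 in starts) {
    end <- tryCatch({
      out <- simulate_regulation(y0, c(0, t_relax), p,
                                 snail_fixed = snail_fixed,
                                 clamp_ifng = clamp_ifng,
                                 clamp_tgfb = clamp_tgfb)
      out[nrow(out), -1]
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(end)) next
    ref <- .newton_refine(fun, pmax(end[idx], 0))
    if (is.null(ref)) next
    y <- template; y[idx] <- ref
    sols[[length(sols) + 1]] <- y
  }
  if (!length(sols)) {
    warning("find_equilibria: no start converged")
    return(.empty_equilibrium_set())
  }
  sols <- .dedup_states(sols, idx)

  if (find_unstable && length(sols) > 1) {
    ord <- order(vapply(sols, function(s) s[["mz"]], 0))
    extra <- list()
    for (k in seq_len(length(ord) - 1)) {
      a <- sols[[ord[k]]]; b <- sols[[ord[k + 1]]]
      mid <- template
      mid[idx] <- exp((log1p(a[idx]) + log1p(b[idx])) / 2) - 1
      ref <- .newton_refine(fun, pmax(mid[idx], 0))
      if (!is.null(ref)) {
        y <- template; y[idx] <- ref
        extra[[length(extra) + 1]] <- y
      }
    }
    sols <- .dedup_states(c(sols, extra), idx)
  }

  rows <- lapply(sols, function(y) {
    J <- .fd_jacobian(fun, y[idx])
    mre <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(as.list(y), stable = mre < 1e-6,
               phenotype = equilibrium_phenotype(y[["mz"]]),
               max_re_eig = mre, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("equilibrium_set", "data.frame")
  out
}

.empty_equilibrium_set <- function() {
  out <- data.frame(matrix(numeric(0), ncol = 11,
                           dimnames = list(NULL, regulatory_state_names())))
  out$stable <- logical(0); out$phenotype <- character(0)
  out$max_re_eig <- numeric(0)
  class(out) <- c("equilibrium_set", "data.frame")
  out
}

## de-duplicate state vectors in log1p space, relative tolerance 1e-4
.dedup_states <- function(sols, idx, tol = 1e-4) {
  keep <- list()
  for (y in sols) {
    ly <- log1p(pmax(y[idx], 0))
    dup <- FALSE
    for (k in keep) {
      lk <- log1p(pmax(k[idx], 0))
      if (max(abs(ly - lk) / pmax(abs(lk), 1)) < tol) { dup <- TRUE; break }
    }
    if (!dup) keep[[length(keep) + 1]] <- y
  }
  keep
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(saved) {
  if (is.null(saved)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", saved, envir = globalenv())
}
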
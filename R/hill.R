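#' Define a shifted-Hill regulation
#'
#' A shifted Hill function models transcriptional (or phenomenological)
#' regulation of a target by a regulator `B`. It interpolates between 1
#' (no regulator) and the fold change `lambda` (saturating regulator):
#' `lambda < 1` encodes inhibition, `lambda > 1` activation.
#'
#' @param B0 Threshold of the regulator (same units as the regulator); the
#'   level at which the decreasing Hill component equals 0.5. Must be > 0.
#' @param n Hill coefficient (cooperativity), > 0.
#' @param lambda Fold change of the target production rate at saturating
#'   regulator, >= 0.
#' @return An object of class `hill_interaction`.
#' @examples
#' h <- hill_interaction(B0 = 100, n = 2, lambda = 0.1)
#' shifted_hill(100, h) # (1 + 0.1) / 2
#' @export
hill_interaction <- function(B0, n, lambda) {
  if (!is.numeric(B0) || length(B0) != 1L || !is.finite(B0) || B0 <= 0)
    stop("hill_interaction: threshold 'B0' must be a single positive number")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("hill_interaction: coefficient 'n' must be a single positive number")
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("hill_interaction: fold change 'lambda' must be >= 0")
  structure(list(B0 = B0, n = n, lambda = lambda),
            class = "hill_interaction")
}

#' @export
print.hill_interaction <- function(x, ...) {
  kind <- if (x$lambda < 1) "inhibition" else if (x$lambda > 1)
    "activation" else "neutral"
  cat(sprintf("shifted Hill (%s): B0 = %g, n = %g, lambda = %g\n",
              kind, x$B0, x$n, x$lambda))
  invisible(x)
}

#' Evaluate a shifted Hill function
#'
#' Computes `H-(B) + lambda * H+(B)` with `H-(B) = 1 / (1 + (B/B0)^n)` and
#' `H+ = 1 - H-`. The value is always within `[min(1, lambda),
#' max(1, lambda)]`, equals 1 at `B = 0` and approaches `lambda` as
#' `B` grows.
#'
#' @param B Regulator level (vectorized), >= 0.
#' @param spec A [hill_interaction()], or a list with fields `B0`, `n`,
#'   `lambda`.
#' @return Dimensionless production-rate factor, same length as `B`.
#' @export
shifted_hill <- function(B, spec) {
  if (any(!is.finite(B)) || any(B < 0))
    stop("shifted_hill: regulator level 'B' must be finite and >= 0")
  if (!all(c("B0", "n", "lambda") %in% names(spec)))
    stop("shifted_hill: 'spec' must have fields B0, n, lambda")
  if (spec$B0 <= 0 || spec$n <= 0)
    stop("shifted_hill: B0 and n must be positive")
  hm <- 1 / (1 + (B / spec$B0)^spec$n)
  hm + spec$lambda * (1 - hm)
}

## bare-metal version used in inner loops (no validation)
.hs <- function(B, B0, n, lambda) {
  hm <- 1 / (1 + (B / B0)^n)
  hm + lambda * (1 - hm)
}

#' Convert between nM and molecule counts
#'
#' At a cell volume of 10000 um^3, 1 nM corresponds to approximately
#' 6020 molecules (Avogadro's number x 1e-9 mol/L x volume in litres).
#'
#' @param c Concentration in nM (vectorized), >= 0.
#' @param cell_volume Cell volume in um^3 (default 10000).
#' @return Number of molecules.
#' @examples
#' nm_to_molecules(1) # ~6020
#' @export
nm_to_molecules <- function(c, cell_volume = 10000) {
  if (!is.numeric(cell_volume) || cell_volume <= 0)
    stop("nm_to_molecules: 'cell_volume' must be positive")
  if (any(c < 0)) stop("nm_to_molecules: concentration must be >= 0")
  c * 6.02214076e23 * 1e-9 * cell_volume * 1e-15
}

#' @rdname nm_to_molecules
#' @param m Number of molecules, >= 0.
#' @export
molecules_to_nm <- function(m, cell_volume = 10000) {
  if (!is.numeric(cell_volume) || cell_volume <= 0)
    stop("molecules_to_nm: 'cell_volume' must be positive")
  if (any(m < 0)) stop("molecules_to_nm: molecule count must be >= 0")
  m / (6.02214076e23 * 1e-9 * cell_volume * 1e-15)
}
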
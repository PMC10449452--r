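## Right-hand sides and integration of the regulatory network.

#' State variable names of the regulatory network
#'
#' Order used throughout: miR-200 (`u`), ZEB1 mRNA (`mz`), ZEB1 protein
#' (`z`), SNAIL1 mRNA (`ms`), SNAIL1 protein (`s`) (all molecules),
#' TGFb (`tgfb`, nM), IFNg (`ifng`, nM), activated STAT (`st`, model
#' units), PD-L1 mRNA (`mp`), cytoplasmic PD-L1 (`p`), membrane PD-L1
#' (`pm`) (molecules).
#'
#' @return Character vector of the 11 state names.
#' @export
regulatory_state_names <- function() {
  c("u", "mz", "z", "ms", "s", "tgfb", "ifng", "st", "mp", "p", "pm")
}

#' A default (all-zero cytokine, epithelial-basin) initial state
#'
#' @param p Parameter set (for the SNAIL1-mRNA baseline `g0ms/kms`).
#' @return Named state vector.
#' @export
regulatory_initial_state <- function(p = regulatory_parameters()) {
  c(u = 20000, mz = 50, z = 1000, ms = p$g0ms / p$kms, s = 0,
    tgfb = 0, ifng = 0, st = 1, mp = 1, p = 1, pm = 1)
}

## Lu-style miRNA-mRNA machinery. For a target mRNA with n miRNA binding
## sites, complexes with i bound miRNAs occur with binomial weight
## M_i(u) = C(n,i) (u/u0)^i / (1 + u/u0)^n. L = translation factor,
## Ym = complex-mediated mRNA degradation, Yu = miRNA loss (i molecules
## per degraded complex).
.mirna_factors <- function(u, u0, n, l, gm, gu) {
  x <- u / u0
  w <- stats::dbinom(0:n, n, x / (1 + x)) # = C(n,i) x^i / (1+x)^n
  c(L = sum(l * w), Ym = sum(gm * w), Yu = sum((0:n) * gu * w))
}

#' IFNg production/decay under the selected immunosuppression mode
#'
#' Returns `dI/dt = gi * f - ki * I` where `f` is 1 (mode `"none"`), the
#' shifted-Hill inhibition by membrane PD-L1 (`"pdl1"`), by TGFb
#' (`"tgfb"`), or the product of both (`"combined"`).
#'
#' @param I IFNg concentration (nM).
#' @param PM Membrane PD-L1 (molecules).
#' @param Tg TGFb concentration (nM).
#' @param p Parameter set; `p$inhibition_mode` selects the mode.
#' @return dI/dt in nM/h.
#' @export
rhs_ifng <- function(I, PM, Tg, p) {
  f <- ifng_inhibition_factor(PM, Tg, p)
  p$gi * f - p$ki * I
}

#' @rdname rhs_ifng
#' @export
ifng_inhibition_factor <- function(PM, Tg, p) {
  mode <- p$inhibition_mode
  if (!mode %in% c("none", "pdl1", "tgfb", "combined"))
    stop("unknown inhibition_mode: ", mode)
  f <- 1
  if (mode %in% c("pdl1", "combined"))
    f <- f * .hs(PM, p$pm0_i, p$npm_i, p$lpm_i)
  if (mode %in% c("tgfb", "combined"))
    f <- f * .hs(Tg, p$t0_i, p$nt_i, p$lt_i)
  f
}

#' TGFb--SNAIL1 submodel right-hand side
#'
#' `dT/dt = gt - kt T`; SNAIL1 mRNA is produced at baseline `g0ms` plus a
#' TGFb-activated, SNAIL1-self-inhibited term, and SNAIL1 protein follows
#' its mRNA.
#'
#' @param Tg TGFb (nM); `ms`, `s` SNAIL1 mRNA/protein (molecules).
#' @param p Parameter set.
#' @return Named vector with `dtgfb`, `dms`, `ds`.
#' @export
rhs_tgfb_snail <- function(Tg, ms, s, p) {
  hp_t <- 1 - 1 / (1 + (Tg / p$jms0)^p$ntms)
  hm_s <- 1 / (1 + (s / p$jms1)^p$nsms)
  c(dtgfb = p$gt - p$kt * Tg,
    dms = p$g0ms + p$gms * hp_t * hm_s - p$kms * ms,
    ds = p$gs * ms - p$ks * s)
}

#' Full regulatory network right-hand side
#'
#' Couples the miR-200/ZEB1 core, the IFNg -> JAK-STAT -> PD-L1 arm with
#' mutual miR-200/PD-L1 inhibition, the TGFb -> SNAIL1 submodel and the
#' IFNg equation under the selected inhibition mode.
#'
#' Clamping options reflect the two analysis modes of the model:
#' `snail_fixed` holds SNAIL1 protein at a given level and zeroes its
#' derivative (SNAIL1 as bifurcation parameter); `clamp_ifng` /
#' `clamp_tgfb` hold the cytokines at externally sensed concentrations,
#' as in the spatial simulations where the reaction-diffusion layer
#' replaces the well-mixed cytokine equations.
#'
#' @param state Named state vector (see [regulatory_state_names()]).
#' @param p Parameter set from [regulatory_parameters()].
#' @param snail_fixed If non-`NULL`, SNAIL1 level (molecules) to clamp to.
#' @param clamp_ifng,clamp_tgfb If non-`NULL`, cytokine concentrations
#'   (nM) to clamp to.
#' @return Named vector of time derivatives (per hour).
#' @export
rhs_full <- function(state, p, snail_fixed = NULL, clamp_ifng = NULL,
                     clamp_tgfb = NULL) {
  if (any(!is.finite(state))) stop("rhs_full: non-finite state")
  u <- state[["u"]]; mz <- state[["mz"]]; z <- state[["z"]]
  ms <- state[["ms"]]; s <- state[["s"]]
  Tg <- state[["tgfb"]]; I <- state[["ifng"]]; st <- state[["st"]]
  mp <- state[["mp"]]; P <- state[["p"]]; pm <- state[["pm"]]
  if (!is.null(snail_fixed)) s <- snail_fixed
  if (!is.null(clamp_ifng)) I <- clamp_ifng
  if (!is.null(clamp_tgfb)) Tg <- clamp_tgfb

  fz <- .mirna_factors(u, p$u0, p$mirna_sites_z, p$l_z, p$gm_z, p$gu_z)
  fp <- .mirna_factors(u, p$u0, p$mirna_sites_p, p$l_p, p$gm_p, p$gu_p)

  du <- p$gu * .hs(z, p$z0_u, p$nz_u, p$lz_u) *
    .hs(s, p$s0_u, p$ns_u, p$ls_u) *
    .hs(pm, p$pm0_u, p$npm_u, p$lpm_u) -
    mz * fz[["Yu"]] - mp * fp[["Yu"]] - p$ku * u
  dmz <- p$gmz * .hs(z, p$z0_mz, p$nz_mz, p$lz_mz) *
    .hs(s, p$s0_mz, p$ns_mz, p$ls_mz) -
    mz * fz[["Ym"]] - p$kmz * mz
  dz <- p$gz * mz * fz[["L"]] - p$kz * z

  ts <- rhs_tgfb_snail(Tg, ms, s, p)
  dms <- ts[["dms"]]; ds <- ts[["ds"]]; dtgfb <- ts[["dtgfb"]]
  if (!is.null(snail_fixed)) { dms <- 0; ds <- 0 }
  if (!is.null(clamp_tgfb)) dtgfb <- 0

  dI <- rhs_ifng(I, pm, Tg, p)
  if (!is.null(clamp_ifng)) dI <- 0

  dst <- p$gst * .hs(I, p$i0_st, p$ni_st, p$li_st) - p$kst * st
  dmp <- p$gmp * .hs(st, p$st0_mp, p$nst_mp, p$lst_mp) -
    mp * fp[["Ym"]] - p$kmp * mp
  dP <- p$gp * mp * fp[["L"]] - (p$ktr + p$kp) * P
  dpm <- p$ktr * P - p$kpm * pm

  c(u = du, mz = dmz, z = dz, ms = dms, s = ds, tgfb = dtgfb,
    ifng = dI, st = dst, mp = dmp, p = dP, pm = dpm)
}

#' Integrate the regulatory network
#'
#' Stiff adaptive integration (`deSolve::lsoda`, atol 1e-8, rtol 1e-6) of
#' [rhs_full()] from a given initial state.
#'
#' @inheritParams rhs_full
#' @param state0 Initial named state vector.
#' @param times Output times (hours).
#' @param atol,rtol Integrator tolerances.
#' @return A `deSolve` matrix (time in first column).
#' @examples
#' p <- regulatory_parameters(gi = 0)
#' out <- simulate_regulation(regulatory_initial_state(p), c(0, 500), p)
#' @export
simulate_regulation <- function(state0, times, p, snail_fixed = NULL,
                                clamp_ifng = NULL, clamp_tgfb = NULL,
                                atol = 1e-8, rtol = 1e-6) {
  f <- function(t, y, parms) {
    list(rhs_full(y, parms, snail_fixed = snail_fixed,
                  clamp_ifng = clamp_ifng, clamp_tgfb = clamp_tgfb))
  }
  deSolve::lsoda(y = state0, times = times, func = f, parms = p,
                 atol = atol, rtol = rtol)
}

#' Hysteretic EMT phenotype classification from ZEB1 mRNA
#'
#' Phenotype transitions are based on ZEB1 mRNA (`mz`, molecules) with
#' hysteresis: E -> H at `mz >= 235`; H -> E at `mz <= 145`; H -> M at
#' `mz >= 715`; M -> E at `mz <= 370`. A mesenchymal cell cannot
#' transition directly to the hybrid phenotype. Between thresholds the
#' previous phenotype is retained.
#'
#' @param mz ZEB1 mRNA level(s), molecules, >= 0.
#' @param previous Previous phenotype(s), `"E"`, `"H"` or `"M"` (recycled).
#' @return Character vector of phenotypes.
#' @examples
#' classify_phenotype(235, "E") # "H"
#' classify_phenotype(200, "H") # stays "H" (hysteresis)
#' @export
classify_phenotype <- function(mz, previous) {
  if (any(!is.finite(mz)) || any(mz < 0))
    stop("classify_phenotype: 'mz' must be finite and >= 0")
  if (!all(previous %in% c("E", "H", "M")))
    stop("classify_phenotype: 'previous' must be one of E, H, M")
  n <- max(length(mz), length(previous))
  mz <- rep_len(mz, n); prev <- rep_len(previous, n)
  out <- prev
  out[prev == "E" & mz >= 235] <- "H"
  out[prev == "H" & mz >= 715] <- "M"
  out[prev == "H" & mz <= 145] <- "E"
  out[prev == "M" & mz <= 370] <- "E"
  out
}

#' Phenotype label of an equilibrium
#'
#' Equilibria are labeled solely by their ZEB1 mRNA level, using the
#' midrange cut points of the hysteretic classifier: E below 235
#' molecules, hybrid E/M in `[235, 715)`, M at or above 715.
#'
#' @param mz ZEB1 mRNA level (molecules).
#' @return `"E"`, `"E/M"` or `"M"`.
#' @export
equilibrium_phenotype <- function(mz) {
  ifelse(mz < 235, "E", ifelse(mz < 715, "E/M", "M"))
}
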
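## Default parameterization of the regulatory network.
##
## Units: all species in molecules except the cytokines IFNg (I) and
## TGFb (T), which are in nM, and activated STAT (ST), which is in
## dimensionless model units. Time in hours. Conversions between nM and
## molecules use the 10000 um^3 cell volume (1 nM ~ 6020 molecules).

.required_regulatory_names <- c(
  ## miR-200 / ZEB1 ternary-switch core
  "gu", "ku", "gmz", "kmz", "gz", "kz", "u0",
  "lz_u", "nz_u", "z0_u", "ls_u", "ns_u", "s0_u",
  "lz_mz", "nz_mz", "z0_mz", "ls_mz", "ns_mz", "s0_mz",
  ## JAK-STAT / PD-L1 arm
  "gst", "kst", "li_st", "ni_st", "i0_st",
  "gmp", "kmp", "lst_mp", "nst_mp", "st0_mp",
  "gp", "kp", "ktr", "kpm",
  "lpm_u", "npm_u", "pm0_u",
  ## cytokines
  "gi", "ki", "gt", "kt",
  ## TGFb -> SNAIL1 submodel
  "g0ms", "gms", "kms", "jms0", "ntms", "jms1", "nsms", "gs", "ks",
  ## immunosuppression Hills
  "lpm_i", "npm_i", "pm0_i", "lt_i", "nt_i", "t0_i",
  ## geometry
  "cell_volume")

#' Default regulatory-network parameters
#'
#' Returns the packaged parameter set for the coupled EMT--PD-L1 network:
#' the miR-200/ZEB1 ternary switch with SNAIL1 input, the
#' IFNg -> JAK-STAT -> PD-L1 arm with mutual miR-200/PD-L1 inhibition, the
#' TGFb -> SNAIL1 submodel, and the shifted-Hill parameters of the two
#' immunosuppressive feedbacks (membrane PD-L1 and TGFb inhibiting IFNg
#' production).
#'
#' The `inhibition_mode` selects which shifted-Hill factors multiply the
#' basal IFNg production rate `gi`:
#' `"none"` (no suppression), `"pdl1"` (membrane PD-L1), `"tgfb"` (TGFb),
#' or `"combined"` (product of both factors).
#'
#' @param inhibition_mode One of `"none"`, `"pdl1"`, `"tgfb"`, `"combined"`.
#' @param ... Named overrides of individual parameter values.
#' @return An object of class `regulatory_parameters` (a named list).
#' @examples
#' p <- regulatory_parameters("pdl1", gi = 0.1)
#' p$gi
#' @export
regulatory_parameters <- function(inhibition_mode = c("none", "pdl1",
                                                      "tgfb", "combined"),
                                  ...) {
  inhibition_mode <- match.arg(inhibition_mode)
  p <- list(
    ## miR-200 (u) / ZEB1 mRNA (mz) / ZEB1 protein (z) core, SNAIL1 input.
    ## Rates in molecules/h resp. 1/h.
    gu = 2100, ku = 0.05,
    gmz = 11, kmz = 0.5,
    gz = 100, kz = 0.1,
    u0 = 10000,                       # miRNA binding threshold (molecules)
    lz_u = 0.1, nz_u = 3, z0_u = 220000,   # ZEB1 -| miR-200
    ls_u = 0.1, ns_u = 2, s0_u = 180000,   # SNAIL1 -| miR-200
    lz_mz = 7.5, nz_mz = 2, z0_mz = 25000, # ZEB1 -> ZEB1 mRNA
    ls_mz = 10, ns_mz = 2, s0_mz = 180000, # SNAIL1 -> ZEB1 mRNA
    ## miRNA-mRNA complex machinery: ZEB1 mRNA carries 6 miR-200 sites,
    ## PD-L1 mRNA 2. l: translation factors; gm: complex-mediated mRNA
    ## degradation (1/h); gu(vec): complex-mediated miRNA degradation (1/h).
    mirna_sites_z = 6,
    l_z = c(1, 0.6, 0.3, 0.1, 0.05, 0.05, 0.05),
    gm_z = c(0, 0.04, 0.2, 1, 1, 1, 1),
    gu_z = c(0, 0.005, 0.05, 0.5, 0.5, 0.5, 0.5),
    mirna_sites_p = 2,
    l_p = c(1, 0.3, 0.05),
    gm_p = c(0, 0.1, 0.4),
    gu_p = c(0, 0.005, 0.05),
    ## IFNg -> STAT -> PD-L1 arm. ST is dimensionless (steady state in
    ## [1, li_st]); PD-L1 species in molecules.
    gst = 1, kst = 1,                  # 1/h
    li_st = 15, ni_st = 2, i0_st = 0.15,   # IFNg -> STAT (I in nM)
    gmp = 100, kmp = 0.5,              # PD-L1 mRNA: molecules/h, 1/h
    lst_mp = 25, nst_mp = 4, st0_mp = 5,   # STAT -> PD-L1 mRNA
    gp = 10, kp = 0.1,                 # translation 1/h, degradation 1/h
    ktr = 1, kpm = 0.5,                # membrane translocation / removal
    lpm_u = 0.7, npm_u = 2, pm0_u = 40000, # PD-L1 -| miR-200
    ## cytokines (nM, nM/h)
    gi = 0.1, ki = 1,
    gt = 0, kt = 1,
    ## TGFb -> SNAIL1 submodel (molecules except T in nM)
    g0ms = 1500, gms = 600, kms = 0.09,
    jms0 = 0.1, ntms = 2,              # TGFb -> SNAIL1 mRNA threshold (nM)
    jms1 = 350000, nsms = 2,           # SNAIL1 self-inhibition (molecules)
    gs = 17, ks = 1.66,
    ## immunosuppression of IFNg production
    lpm_i = 0.1, npm_i = 2, pm0_i = 20000, # membrane PD-L1 -| IFNg
    lt_i = 0.1, nt_i = 2, t0_i = 0.15,     # TGFb -| IFNg (T in nM)
    cell_volume = 10000,
    inhibition_mode = inhibition_mode)
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(p))
    if (length(bad))
      stop("regulatory_parameters: unknown parameter(s): ",
           paste(bad, collapse = ", "))
    p[names(override)] <- override
  }
  class(p) <- "regulatory_parameters"
  validate_regulatory_parameters(p)
  p
}

#' Validate a regulatory parameter set
#'
#' Checks that every required symbol is present, finite and non-negative,
#' and that the inhibition mode is known. A missing symbol raises an error
#' naming it rather than silently defaulting.
#'
#' @param p A `regulatory_parameters` object or plain named list.
#' @return `p`, invisibly, if valid.
#' @export
validate_regulatory_parameters <- function(p) {
  missing <- setdiff(.required_regulatory_names, names(p))
  if (length(missing))
    stop("regulatory parameter set is missing symbol(s): ",
         paste(missing, collapse = ", "))
  for (nm in .required_regulatory_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop("regulatory parameter '", nm,
           "' must be finite and non-negative")
  }
  if (!p$inhibition_mode %in% c("none", "pdl1", "tgfb", "combined"))
    stop("unknown inhibition_mode: ", p$inhibition_mode)
  for (nm in c("l_z", "gm_z", "gu_z"))
    if (length(p[[nm]]) != p$mirna_sites_z + 1)
      stop("parameter '", nm, "' must have length mirna_sites_z + 1")
  for (nm in c("l_p", "gm_p", "gu_p"))
    if (length(p[[nm]]) != p$mirna_sites_p + 1)
      stop("parameter '", nm, "' must have length mirna_sites_p + 1")
  invisible(p)
}

#' @export
print.regulatory_parameters <- function(x, ...) {
  cat("Regulatory network parameters (EMT--PD-L1)\n")
  cat("  inhibition mode:", x$inhibition_mode, "\n")
  cat(sprintf("  gi = %g nM/h, gt = %g nM/h, cell volume = %g um^3\n",
              x$gi, x$gt, x$cell_volume))
  invisible(x)
}

#' Read or write parameter sets as structured text
#'
#' Parameter sets are stored as flat key--value YAML so that runs can be
#' configured from files and the packaged defaults can be inspected.
#'
#' @param p A `regulatory_parameters` object.
#' @param path File path.
#' @return `read_parameters` returns a validated `regulatory_parameters`
#'   object; `write_parameters` returns `path` invisibly.
#' @export
write_parameters <- function(p, path) {
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  p <- yaml::read_yaml(path)
  ## yaml scalarizes length-1 vectors; restore numeric vectors
  for (nm in c("l_z", "gm_z", "gu_z", "l_p", "gm_p", "gu_p"))
    p[[nm]] <- as.numeric(p[[nm]])
  class(p) <- "regulatory_parameters"
  validate_regulatory_parameters(p)
  p
}
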
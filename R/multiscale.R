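## Multiscale coupling: scenario setup, intratumoral heterogeneity, and
## the full ODE + CPM + field simulation driver.

#' Define a spatial simulation scenario
#'
#' Two study geometries are provided. `"long_range"`: a circular T
#' cell-infiltrated tumor (default 480 tumor cells, 700x700 um domain)
#' with long-range IFNg spreading and output every 10 min.
#' `"short_range"`: an invasive tumor front (default 200 tumor cells,
#' 400x400 um) with short-range spreading and output every 1 min. T
#' cells are added at a 1:40 T cell:tumor cell ratio (rounded to at
#' least one) and are frozen (no motion, no secretion) for the first 10
#' minutes so that tumor regulatory states settle into the zero-IFNg
#' attractor. Sizes can be scaled down for desk-scale experiments.
#'
#' @param name `"long_range"` or `"short_range"`.
#' @param n_tumor Number of tumor cells.
#' @param domain_um Domain edge length (um).
#' @param duration_min Simulated minutes after initialization.
#' @param tgfb_mode `"uniform"` or `"gradient"`.
#' @param tgfb_level TGFb concentration (nM): the uniform level or the
#'   gradient peak.
#' @param inhibition One of `"none"`, `"pdl1"`, `"tgfb"` (spatial runs
#'   embed the separate-inhibition models only).
#' @param heterogeneous Apply intratumoral heterogeneity?
#' @param het_sigma Log-normal sigma of the heterogeneity
#'   (see [apply_heterogeneity()]).
#' @param output_min Output interval (minutes).
#' @param field_fac Field coarsening factor (sites per field cell).
#' @return A list of class `scenario`.
#' @export
scenario <- function(name = c("long_range", "short_range"),
                     n_tumor = NULL, domain_um = NULL,
                     duration_min = NULL,
                     tgfb_mode = c("uniform", "gradient"),
                     tgfb_level = NULL,
                     inhibition = c("none", "pdl1", "tgfb"),
                     heterogeneous = FALSE, het_sigma = 0.014,
                     output_min = NULL, field_fac = NULL) {
  name <- match.arg(name)
  tgfb_mode <- match.arg(tgfb_mode)
  inhibition <- match.arg(inhibition)
  def <- if (name == "long_range") {
    list(n_tumor = 480, domain_um = 700, duration_min = 2410,
         output_min = 10, spread = "long", tgfb_level = 0.05,
         field_fac = 2L)
  } else {
    list(n_tumor = 200, domain_um = 400, duration_min = 500,
         output_min = 1, spread = "short", tgfb_level = 0.15,
         field_fac = 2L)
  }
  sc <- list(name = name,
             n_tumor = if (is.null(n_tumor)) def$n_tumor else n_tumor,
             domain_um = if (is.null(domain_um)) def$domain_um
                         else domain_um,
             duration_min = if (is.null(duration_min)) def$duration_min
                            else duration_min,
             output_min = if (is.null(output_min)) def$output_min
                          else output_min,
             tgfb_mode = tgfb_mode,
             tgfb_level = if (is.null(tgfb_level)) def$tgfb_level
                          else tgfb_level,
             spread = def$spread,
             inhibition = inhibition,
             heterogeneous = heterogeneous, het_sigma = het_sigma,
             freeze_min = 10,
             field_fac = if (is.null(field_fac)) def$field_fac
                         else as.integer(field_fac))
  sc$n_tcell <- max(1L, round(sc$n_tumor / 40))
  class(sc) <- "scenario"
  sc
}

#' Draw per-cell parameter multipliers (intratumoral heterogeneity)
#'
#' Multiplicative log-normal noise (median 1, log-sd `sigma`) applied to
#' the miR-200 and ZEB1 mRNA production rates of each tumor cell. The
#' width is constrained so that no epithelial cell spontaneously
#' undergoes EMT in the absence of IFNg: [check_no_spontaneous_emt()]
#' verifies the constraint by relaxing single-cell regulatory states at
#' zero IFNg, and `apply_heterogeneity` halves `sigma` (with a warning)
#' until the constraint holds.
#'
#' @param n_cells Number of tumor cells.
#' @param sigma Log-normal sigma (0 = homogeneous).
#' @param seed RNG seed.
#' @param tgfb_level TGFb concentration (nM) used in the dry-run
#'   constraint check.
#' @param p Regulatory parameter set.
#' @param check Verify (and if needed auto-reduce) against the
#'   no-spontaneous-EMT constraint?
#' @return An `n_cells` x 2 matrix of multipliers (columns: miR-200
#'   production, ZEB1 mRNA production) with attribute `sigma` (the
#'   width actually used).
#' @export
apply_heterogeneity <- function(n_cells, sigma, seed = 1,
                                tgfb_level = 0.05,
                                p = regulatory_parameters(),
                                check = TRUE) {
  rng <- .save_seed(); on.exit(.restore_seed(rng))
  set.seed(seed)
  repeat {
    mult <- matrix(stats::rlnorm(2L * n_cells, meanlog = 0,
                                 sdlog = sigma), n_cells, 2)
    if (sigma == 0 || !check ||
        check_no_spontaneous_emt(mult, tgfb_level, p)) break
    sigma <- sigma / 2
    warning("apply_heterogeneity: sigma reduced to ", sigma,
            " to satisfy the no-spontaneous-EMT constraint")
    set.seed(seed)
  }
  attr(mult, "sigma") <- sigma
  mult
}

#' @rdname apply_heterogeneity
#' @param mult Multiplier matrix as returned by `apply_heterogeneity`.
#' @param relax_h Relaxation horizon (ODE hours).
#' @export
check_no_spontaneous_emt <- function(mult, tgfb_level,
                                     p = regulatory_parameters(),
                                     relax_h = 400) {
  y0 <- .reg9_init(p)
  for (i in seq_len(nrow(mult))) {
    y <- reg_advance_cpp(y0, 0, tgfb_level, unclass(p), mult[i, 1],
                         mult[i, 2], relax_h, 0.01)
    if (y[2] >= 235) return(FALSE)
  }
  TRUE
}

## 9-state spatial-mode initial state: u, mz, z, ms, s, st, mp, p, pm
.reg9_init <- function(p) {
  c(20000, 50, 1000, p$g0ms / p$kms, 0, 1, 1, 1, 1)
}

#' IFNg production rate of a T cell under contact- or field-dependent
#' suppression
#'
#' Mode `"none"`: the basal rate (1200 molecules/min). Mode `"pdl1"`:
#' the basal rate scaled by the shifted-Hill inhibition evaluated at the
#' boundary-weighted mean membrane PD-L1 of contacting tumor cells.
#' Mode `"tgfb"`: scaled by the inhibition at the sensed TGFb
#' concentration. Production relaxes instantly (recomputed every MCS in
#' the spatial simulations).
#'
#' @param pm_contact Boundary-weighted mean membrane PD-L1 of contacting
#'   tumor cells (molecules); 0 when there is no contact.
#' @param tgfb_sensed Sensed TGFb (nM).
#' @param mode `"none"`, `"pdl1"` or `"tgfb"`.
#' @param p Regulatory parameter set (inhibition Hill parameters).
#' @param basal Basal production rate (molecules/min).
#' @return Production rate in molecules/min.
#' @export
tcell_production_rate <- function(pm_contact, tgfb_sensed,
                                  mode = c("none", "pdl1", "tgfb"),
                                  p = regulatory_parameters(),
                                  basal = 1200) {
  mode <- match.arg(mode)
  f <- switch(mode,
              none = 1,
              pdl1 = .hs(pm_contact, p$pm0_i, p$npm_i, p$lpm_i),
              tgfb = .hs(tgfb_sensed, p$t0_i, p$nt_i, p$lt_i))
  basal * f
}

#' Initialize a scenario
#'
#' Builds the lattice (circular tumor or invasive front), places T cells
#' (randomly within the tumor, or in the middle-outer layers below the
#' front), constructs the static TGFb field, and draws heterogeneity
#' multipliers. Regulatory states start from the epithelial basin and
#' settle into the zero-IFNg attractor during the 10-minute freeze
#' (300 ODE hours at the 1800x acceleration).
#'
#' @param sc A [scenario()].
#' @param seed RNG seed (placement and heterogeneity).
#' @param p Regulatory parameters.
#' @return List with `spins`, `cell_type`, `reg`, `mult`, `tgfb`,
#'   `front_row` (or `NULL`), and the scenario.
#' @export
initialize_scenario <- function(sc, seed = 1,
                                p = regulatory_parameters()) {
  domain <- round(sc$domain_um / 2)  # 2 um per site
  rng <- .save_seed(); on.exit(.restore_seed(rng))
  set.seed(seed)
  front_row <- NULL
  if (sc$name == "long_range") {
    spins <- lattice_circular_tumor(sc$n_tumor, domain)
    ## T cells at random positions well inside the tumor
    R <- sqrt(sc$n_tumor * 113 / pi)
    cx <- (domain + 1) / 2
    th <- stats::runif(sc$n_tcell, 0, 2 * pi)
    rr <- (R - 6) * sqrt(stats::runif(sc$n_tcell))
    centers <- cbind(cx + rr * cos(th), cx + rr * sin(th))
  } else {
    ft <- lattice_front_tumor(sc$n_tumor, domain)
    spins <- ft$spins; front_row <- ft$front_row
    ## middle-outer cell layers: 1-3 cell diameters below the front
    ys <- stats::runif(sc$n_tcell, front_row + 12, front_row + 36)
    xs <- stats::runif(sc$n_tcell, 8, domain - 8)
    centers <- cbind(xs, ys)
  }
  spins <- .stamp_tcells(spins, centers, sc$n_tumor + 1L)
  cell_type <- c(rep(1L, sc$n_tumor), rep(4L, sc$n_tcell))
  ncell <- sc$n_tumor + sc$n_tcell
  reg <- matrix(rep(.reg9_init(p), each = ncell), ncell, 9)
  mult <- matrix(1, ncell, 2)
  if (sc$heterogeneous && sc$het_sigma > 0) {
    hm <- apply_heterogeneity(sc$n_tumor, sc$het_sigma, seed = seed,
                              tgfb_level = sc$tgfb_level, p = p)
    mult[seq_len(sc$n_tumor), ] <- hm
  }
  tgfb <- make_tgfb_field(sc$tgfb_mode, sc$tgfb_level, domain,
                          front_row = front_row)
  list(spins = spins, cell_type = cell_type, reg = reg, mult = mult,
       tgfb = tgfb, front_row = front_row, domain = domain,
       scenario = sc)
}

#' Run a multiscale simulation
#'
#' Couples the Potts dynamics (0.6 s per MCS), the IFNg
#' reaction-diffusion layer (advanced every MCS with automatic
#' sub-stepping), and the per-cell regulatory ODEs (advanced every MCS
#' by 1800x the CPM time step; sensed IFNg and TGFb enter as clamped
#' inputs). T cell IFNg production is recomputed every MCS from the
#' selected inhibition mode. Phenotypes switch hysteretically at output
#' intervals, immediately swapping the cell's surface energies and
#' perimeter weight.
#'
#' @param sc A [scenario()].
#' @param seed RNG seed (initialization and Potts dynamics).
#' @param p Regulatory parameters.
#' @param cpm [cpm_parameters()]; defaults to `tcell_med = "low"` for
#'   gradient-TGFb runs and `"high"` otherwise.
#' @param init Optional pre-built [initialize_scenario()] result.
#' @return List of class `multiscale_run`: `cells` (long per-interval
#'   per-cell table with type labels), `final` (engine state), `scenario`
#'   and the field mass balance (`secreted`, `consumed`).
#' @export
run_simulation <- function(sc, seed = 1, p = regulatory_parameters(),
                           cpm = NULL, init = NULL) {
  if (is.null(cpm))
    cpm <- cpm_parameters(tcell_med = if (sc$tgfb_mode == "gradient")
      "low" else "high")
  if (is.null(init)) init <- initialize_scenario(sc, seed, p)
  mode_code <- match(sc$inhibition, c("none", "pdl1", "tgfb")) - 1L
  out <- cpm_simulate(
    init$spins, init$cell_type, init$reg, init$mult,
    .cpm_param_list(cpm), unclass(p),
    list(D = 5430, site_um = cpm$site_um, field_fac = sc$field_fac,
         uptake_by_type = unname(uptake_profile(sc$spread)),
         secretion_rate = 1200, tgfb = init$tgfb, max_cfl = 0.5),
    list(total_mcs = as.integer((sc$duration_min + sc$freeze_min) /
                                  cpm$mcs_min),
         freeze_mcs = as.integer(sc$freeze_min / cpm$mcs_min),
         output_every_mcs = as.integer(sc$output_min / cpm$mcs_min),
         mcs_min = cpm$mcs_min, accel = 1800, ode_dt_h = 0.015,
         mode = mode_code, seed = as.integer(seed), ode_enabled = TRUE,
         field_uptake = TRUE))
  cells <- out$cells
  cells$type_label <- cpm_type_label(cells$type)
  cells$time <- cells$time - sc$freeze_min  # 0 = end of initialization
  structure(list(cells = cells, final = out, scenario = sc,
                 seed = seed, secreted = out$secreted,
                 consumed = out$consumed),
            class = "multiscale_run")
}

#' @export
print.multiscale_run <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("multiscale run: %s, inhibition=%s, tgfb=%s (%g nM), %s\n",
              sc$name, sc$inhibition, sc$tgfb_mode, sc$tgfb_level,
              if (sc$heterogeneous) "heterogeneous" else "homogeneous"))
  cat(sprintf("  %d tumor + %d T cells, %g min, seed %d\n", sc$n_tumor,
              sc$n_tcell, sc$duration_min, x$seed))
  invisible(x)
}
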
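## Cellular Potts model configuration and R-level interface to the
## compiled engine. Cell type codes: 0 medium, 1 E, 2 H, 3 M, 4 T cell.

.type_labels <- c("med", "E", "H", "M", "T")

#' Label cell-type codes
#' @param code Integer type codes (0--4).
#' @return Character labels (`"med"`, `"E"`, `"H"`, `"M"`, `"T"`).
#' @export
cpm_type_label <- function(code) .type_labels[code + 1L]

#' Cellular Potts simulation parameters
#'
#' Surface energies, area/perimeter constraints and Act-model parameters
#' for the two-dimensional tumor--T cell simulations. The lattice
#' resolution is 2 um per site and one Monte Carlo step (MCS) corresponds
#' to 0.6 s. Target areas are 452 um^2 (tumor) and 140 um^2 (T cells);
#' target perimeters follow the circle-perimeter-at-target-area rule
#' `2*sqrt(pi*A)`, converted from um to interface counts with a
#' geometric calibration factor (default 3.1) measured on rasterized
#' disks at this resolution.
#'
#' `tcell_med` selects the T cell--medium surface energy: `"high"` (15,
#' default, confines T cells to the tumor) or `"low"` (2, used in TGFb
#' gradient simulations).
#'
#' The Metropolis `temperature` is a calibrated quantity: the default
#' reproduces a mean T cell migration speed of about 7 um/min with the
#' amoeboid Act parameters (see the package vignette).
#'
#' @param tcell_med `"high"` or `"low"`.
#' @param temperature Boltzmann acceptance parameter.
#' @param perim_calibration Interfaces per site-length of true
#'   circumference for rasterized disks.
#' @param ... Overrides for `lambda_act`, `max_act`, or J entries via
#'   `J` (a full 5x5 matrix).
#' @return A list of class `cpm_parameters`.
#' @export
cpm_parameters <- function(tcell_med = c("high", "low"), temperature = 15,
                           perim_calibration = 3.1, ...) {
  tcell_med <- match.arg(tcell_med)
  ## J indexed by type code + 1: med, E, H, M, T
  J <- matrix(0, 5, 5,
              dimnames = list(.type_labels, .type_labels))
  J["E", "E"] <- 2
  J["E", "H"] <- J["E", "M"] <- 5
  J["H", "H"] <- J["H", "M"] <- J["M", "M"] <- 14
  J["E", "T"] <- J["H", "T"] <- J["M", "T"] <- J["T", "T"] <- 0.5
  J["E", "med"] <- 3
  J["H", "med"] <- J["M", "med"] <- 1
  J["T", "med"] <- if (tcell_med == "high") 15 else 2
  J[lower.tri(J)] <- t(J)[lower.tri(J)]

  site_um <- 2
  a_tum_um2 <- 452; a_t_um2 <- 140
  target_area <- c(0, rep(a_tum_um2 / site_um^2, 3), a_t_um2 / site_um^2)
  target_perim <- c(0,
                    rep(perim_calibration * 2 * sqrt(pi * a_tum_um2) /
                          site_um, 3),
                    perim_calibration * 2 * sqrt(pi * a_t_um2) / site_um)
  p <- list(J = J,
            target_area = target_area,
            target_perim = target_perim,
            sa = c(0, 1, 1, 1, 1),
            sl = c(0, 0.25, 0.2, 0.15, 0.1),
            lambda_act = 20, max_act = 20,
            temperature = temperature,
            site_um = site_um, mcs_min = 0.01,
            tcell_med = tcell_med)
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(p))
    if (length(bad))
      stop("cpm_parameters: unknown parameter(s): ",
           paste(bad, collapse = ", "))
    p[names(override)] <- override
  }
  stopifnot(isSymmetric(p$J), all(p$sl >= 0), all(p$sa >= 0))
  class(p) <- "cpm_parameters"
  p
}

.cpm_param_list <- function(p) {
  list(J = unname(p$J), target_area = p$target_area,
       target_perim = p$target_perim, sa = p$sa, sl = p$sl,
       lambda_act = p$lambda_act, max_act = p$max_act,
       temperature = p$temperature)
}

#' Local energy change of a copy attempt
#'
#' Computes the change of the Hamiltonian (adhesion + area + perimeter
#' constraints, plus the Act protrusion bias for T cells) for copying the
#' spin at source site `(ux, uy)` into the neighboring target site
#' `(vx, vy)`. Coordinates are 1-based (column x, row y).
#'
#' @param spins Integer matrix of cell ids (0 = medium), rows = y.
#' @param cell_type Integer vector of type codes per cell id.
#' @param acts Numeric matrix of Act values (same shape as `spins`).
#' @param ux,uy,vx,vy Source/target site coordinates.
#' @param params A [cpm_parameters()] object.
#' @return List with components `adhesion`, `area`, `perimeter`, `act`,
#'   `total`.
#' @export
delta_hamiltonian <- function(spins, cell_type, acts, ux, uy, vx, vy,
                              params = cpm_parameters()) {
  stopifnot(abs(ux - vx) <= 1, abs(uy - vy) <= 1,
            spins[uy, ux] != spins[vy, vx])
  cpm_delta_hamiltonian(spins, as.integer(cell_type), acts,
                        as.integer(ux), as.integer(uy), as.integer(vx),
                        as.integer(vy), .cpm_param_list(params))
}

#' Global Hamiltonian (adhesion + area + perimeter), from scratch
#' @inheritParams delta_hamiltonian
#' @return Total energy (the Act term is a copy bias, not a state
#'   function, and is excluded).
#' @export
global_hamiltonian <- function(spins, cell_type,
                               params = cpm_parameters()) {
  cpm_global_hamiltonian(spins, as.integer(cell_type),
                         .cpm_param_list(params))
}

## --- lattice construction -------------------------------------------

## sunflower (Vogel spiral) points: approximately uniform over the disk
.sunflower <- function(n, radius) {
  i <- seq_len(n)
  r <- radius * sqrt((i - 0.5) / n)
  th <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(th), y = r * sin(th))
}

## assign sites of a mask to the nearest of n seed points (chunked to
## bound memory at large lattices)
.assign_voronoi <- function(mask, seeds) {
  idx <- which(mask, arr.ind = TRUE) # row (y), col (x)
  n <- nrow(idx)
  owner <- integer(n)
  chunk <- 4000L
  for (b in seq(1L, n, by = chunk)) {
    sel <- b:min(b + chunk - 1L, n)
    d2 <- outer(idx[sel, 1], seeds[, 2], "-")^2 +
      outer(idx[sel, 2], seeds[, 1], "-")^2
    owner[sel] <- max.col(-d2)
  }
  spins <- matrix(0L, nrow(mask), ncol(mask))
  spins[idx] <- owner
  spins
}

#' Build a circular tumor lattice
#'
#' Rasterizes a disk holding `n_cells` tumor cells at target area and
#' partitions it into cells via nearest-seed assignment of a uniform
#' spiral seeding.
#'
#' @param n_cells Number of tumor cells.
#' @param domain Lattice extent in sites (square).
#' @return Integer spin matrix (`domain` x `domain`).
#' @export
lattice_circular_tumor <- function(n_cells, domain) {
  area_sites <- 113 # 452 um^2 at 2 um/site
  R <- sqrt(n_cells * area_sites / pi)
  if (2 * R > domain - 4)
    stop("lattice_circular_tumor: tumor does not fit the domain")
  cx <- (domain + 1) / 2
  xs <- seq_len(domain)
  mask <- outer(xs, xs, function(y, x) (x - cx)^2 + (y - cx)^2 <= R^2)
  seeds <- .sunflower(n_cells, R - 1)
  seeds[, 1] <- seeds[, 1] + cx; seeds[, 2] <- seeds[, 2] + cx
  .assign_voronoi(mask, seeds)
}

#' Build an invasive-front tumor lattice
#'
#' Tumor cells fill a horizontal slab at the bottom of the domain; the
#' top edge of the slab is the invasive front.
#'
#' @inheritParams lattice_circular_tumor
#' @return List with `spins` and `front_row` (the row index of the
#'   front; rows above it are medium).
#' @export
lattice_front_tumor <- function(n_cells, domain) {
  area_sites <- 113
  hslab <- ceiling(n_cells * area_sites / domain)
  if (hslab > domain - 4)
    stop("lattice_front_tumor: tumor does not fit the domain")
  front_row <- domain - hslab + 1
  mask <- matrix(FALSE, domain, domain)
  mask[front_row:domain, ] <- TRUE
  nx <- max(1, round(sqrt(n_cells * domain / hslab)))
  ny <- max(1, ceiling(n_cells / nx))
  gx <- (seq_len(nx) - 0.5) / nx * domain
  gy <- front_row + (seq_len(ny) - 0.5) / ny * hslab
  seeds <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n_cells), ]
  list(spins = .assign_voronoi(mask, seeds), front_row = front_row)
}

## stamp small T cell disks onto the lattice at given centers, taking
## sites over from whatever occupies them
.stamp_tcells <- function(spins, centers, first_id) {
  rT <- sqrt(35 / pi)
  for (k in seq_len(nrow(centers))) {
    id <- first_id + k - 1L
    x0 <- centers[k, 1]; y0 <- centers[k, 2]
    xs <- max(1, floor(x0 - rT - 1)):min(ncol(spins), ceiling(x0 + rT + 1))
    ys <- max(1, floor(y0 - rT - 1)):min(nrow(spins), ceiling(y0 + rT + 1))
    for (y in ys) for (x in xs)
      if ((x - x0)^2 + (y - y0)^2 <= rT^2) spins[y, x] <- id
  }
  spins
}

#' Mean instantaneous migration speed from centroid tracks
#'
#' @param tracks Data.frame with columns `id`, `time` (minutes) and
#'   `x`, `y` (um), sampled at a fixed interval.
#' @param window Minimum track duration (minutes); shorter tracks are
#'   excluded.
#' @return Mean displacement per minute (um/min) over cells and time.
#' @export
measure_speed <- function(tracks, window = 2) {
  stopifnot(all(c("id", "time", "x", "y") %in% names(tracks)))
  sp <- lapply(split(tracks, tracks$id), function(tr) {
    tr <- tr[order(tr$time), ]
    if (nrow(tr) < 2 || diff(range(tr$time)) < window) return(NULL)
    dt <- diff(tr$time)
    sqrt(diff(tr$x)^2 + diff(tr$y)^2) / dt
  })
  sp <- unlist(sp)
  if (!length(sp)) stop("measure_speed: no track longer than the window")
  mean(sp)
}

#' Simulate T cells migrating among tumor cells (CPM only)
#'
#' Runs the Potts dynamics without the regulatory or cytokine layers,
#' for Act-model calibration and migration-speed measurements: a
#' confluent block of epithelial tumor cells with T cells embedded.
#'
#' @param n_tcells Number of T cells.
#' @param domain Lattice extent (sites).
#' @param duration_min Simulated minutes (100 MCS per minute).
#' @param params [cpm_parameters()].
#' @param seed RNG seed.
#' @param sample_min Centroid sampling interval (minutes).
#' @return List with `cells` (per-interval table) and `tracks` (T cell
#'   rows only).
#' @export
simulate_tcell_migration <- function(n_tcells = 5, domain = 80,
                                     duration_min = 60,
                                     params = cpm_parameters(),
                                     seed = 1, sample_min = 1) {
  area_sites <- 113
  n_tumor <- floor(domain^2 * 0.95 / area_sites)
  R <- sqrt(n_tumor * area_sites / pi)
  ## confluent sheet: fill the whole domain with tumor cells
  nx <- max(1, round(domain / sqrt(area_sites)))
  ny <- ceiling(n_tumor / nx)
  gx <- (seq_len(nx) - 0.5) / nx * domain
  gy <- (seq_len(ny) - 0.5) / ny * domain
  seeds <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n_tumor), ]
  mask <- matrix(TRUE, domain, domain)
  spins <- .assign_voronoi(mask, seeds)
  rng <- .save_seed(); on.exit(.restore_seed(rng))
  set.seed(seed)
  centers <- cbind(stats::runif(n_tcells, domain * 0.2, domain * 0.8),
                   stats::runif(n_tcells, domain * 0.2, domain * 0.8))
  spins <- .stamp_tcells(spins, centers, n_tumor + 1L)
  cell_type <- c(rep(1L, n_tumor), rep(4L, n_tcells))
  ncell <- n_tumor + n_tcells
  reg <- matrix(0, ncell, 9)
  mult <- matrix(1, ncell, 2)
  out <- cpm_simulate(
    spins, cell_type, reg, mult, .cpm_param_list(params),
    unclass(regulatory_parameters()),
    list(D = 5430, site_um = params$site_um, field_fac = 4L,
         uptake_by_type = rep(0, 5), secretion_rate = 0,
         tgfb = matrix(0, domain, domain), max_cfl = 0.2),
    list(total_mcs = as.integer(duration_min / params$mcs_min),
         freeze_mcs = 0L,
         output_every_mcs = as.integer(sample_min / params$mcs_min),
         mcs_min = params$mcs_min, accel = 1800, ode_dt_h = 0.015,
         mode = 0L, seed = as.integer(seed), ode_enabled = FALSE,
         field_uptake = FALSE))
  cells <- out$cells
  cells$type_label <- cpm_type_label(cells$type)
  list(cells = cells, tracks = cells[cells$type == 4L, ],
       final = out)
}
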
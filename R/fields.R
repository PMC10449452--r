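## Cytokine fields: IFNg reaction-diffusion (dynamic) and TGFb (static).
## IFNg field values are molecules per lattice site; TGFb fields are nM.
## Conversion between the two unit systems uses the site volume
## (2 um)^2 x 10 um slab thickness: 1 nM ~ 24.1 molecules per site.

#' Molecules-per-site equivalent of 1 nM
#'
#' The 2-D field layers carry IFNg as molecules per lattice site. The
#' documented slab thickness of 10 um makes a site volume of 40 um^3,
#' so 1 nM corresponds to about 24.1 molecules per site.
#' @return Scalar conversion factor (molecules per site per nM).
#' @export
molecules_per_nm_site <- function() {
  6.02214076e23 * 1e-9 * 40 * 1e-15
}

#' Per-site IFNg uptake rates by occupant type
#'
#' Table of first-order uptake rates (1/min) applied at sites occupied
#' by each cell type, for the two cytokine-spreading scenarios:
#' short-range (tumor 2100, medium 420) and long-range (tumor 0.021,
#' medium 0.0042). T cells do not consume IFNg.
#'
#' @param scenario `"short"` or `"long"`.
#' @return Named numeric vector indexed by type code 0--4
#'   (med, E, H, M, T).
#' @export
uptake_profile <- function(scenario = c("short", "long")) {
  scenario <- match.arg(scenario)
  k <- if (scenario == "short") c(med = 420, tum = 2100)
       else c(med = 0.0042, tum = 0.021)
  out <- c(k[["med"]], rep(k[["tum"]], 3), 0)
  names(out) <- c("med", "E", "H", "M", "T")
  out
}

#' Advance the IFNg field by explicit diffusion--uptake--secretion
#'
#' Forward-time central-space update with automatic sub-stepping to the
#' diffusive stability bound, no-flux boundaries, exponential (and
#' therefore positivity-preserving) per-site first-order uptake, and
#' continuous sources.
#'
#' @param field Numeric matrix, molecules per site.
#' @param uptake Numeric matrix of per-site uptake rates (1/min).
#' @param source Numeric matrix of secretion rates (molecules per site
#'   per min).
#' @param minutes Duration to advance.
#' @param D Diffusion coefficient (um^2/min), default 5430.
#' @param h Grid spacing (um), default 2.
#' @param max_cfl Stability safety factor (fraction of `h^2/(4D)`).
#' @return List with the updated `field`, total `secreted` and
#'   `consumed` molecules, and the number of `substeps` used.
#' @export
step_ifng <- function(field, uptake, source, minutes, D = 5430, h = 2,
                      max_cfl = 0.2) {
  stopifnot(all(dim(field) == dim(uptake)),
            all(dim(field) == dim(source)), minutes > 0)
  out <- ftcs_run(field, uptake, source, D, h, minutes, max_cfl)
  if (any(out$field < 0))
    stop("step_ifng: negative concentration (sub-stepping broken)")
  out
}

#' Steady state of the diffusion--uptake--secretion field
#'
#' Solves `D lap(c) - k(x) c + s(x) = 0` directly as a sparse linear
#' system. `boundary = "noflux"` matches the simulation's closed domain;
#' `boundary = "absorbing"` (concentration 0 outside the grid) represents
#' an isolated source in extended tissue, appropriate for radial decay
#' profiles whose decay length is comparable to the domain.
#'
#' @inheritParams step_ifng
#' @param boundary `"noflux"` or `"absorbing"`.
#' @return Numeric matrix of steady-state concentrations (molecules per
#'   site).
#' @export
steady_state_ifng <- function(uptake, source, D = 5430, h = 2,
                              boundary = c("noflux", "absorbing")) {
  boundary <- match.arg(boundary)
  nr <- nrow(uptake); nc <- ncol(uptake)
  n <- nr * nc
  g <- D / h^2
  idx <- seq_len(n)
  y <- (idx - 1L) %% nr + 1L
  x <- (idx - 1L) %/% nr + 1L
  ii <- jj <- integer(0)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    yy <- y + d[1]; xx <- x + d[2]
    ok <- yy >= 1L & yy <= nr & xx >= 1L & xx <= nc
    ii <- c(ii, idx[ok]); jj <- c(jj, (xx[ok] - 1L) * nr + yy[ok])
  }
  deg <- if (boundary == "absorbing") rep(4, n) else tabulate(ii, n)
  A <- Matrix::sparseMatrix(i = c(ii, idx), j = c(jj, idx),
                            x = c(rep(g, length(ii)),
                                  -g * deg - as.numeric(uptake)),
                            dims = c(n, n))
  sol <- Matrix::solve(A, -as.numeric(source))
  matrix(as.numeric(sol), nr, nc)
}

#' Steady-state radial IFNg decay around a single secreting T cell
#'
#' Embeds one stationary T cell (140 um^2 disk, no uptake) at the center
#' of a confluent tumor sheet, solves the diffusion--uptake field to
#' steady state with the T cell secreting continuously, and averages the
#' concentration over concentric tumor-cell layers (layer thickness =
#' diameter of a 452 um^2 cell, about 24 um). The fold decrease between
#' adjacent layer averages defines the per-layer decay factor.
#'
#' @param scenario `"short"` or `"long"` uptake parameter set.
#' @param domain Lattice extent in sites.
#' @param n_layers Number of cell layers to report.
#' @param secretion IFNg secretion rate (molecules/min).
#' @param D,h Diffusion coefficient and grid spacing.
#' @return Data.frame with `layer`, `mean_conc` (molecules/site),
#'   `fold_to_next`; attributes `fold_per_layer` (geometric mean of the
#'   adjacent-layer folds over the first `n_layers`) and
#'   `fold_first_pair` (layer 1 vs layer 2).
#' @export
radial_decay_profile <- function(scenario = c("short", "long"),
                                 domain = NULL, n_layers = 7,
                                 secretion = 1200, D = 5430, h = 2,
                                 boundary = "absorbing") {
  scenario <- match.arg(scenario)
  ## default domain large enough relative to the decay length
  ## sqrt(D / k_tumor) so the far boundary does not shape the profile
  if (is.null(domain))
    domain <- if (scenario == "long") 601 else 175
  k <- uptake_profile(scenario)
  cx <- (domain + 1) / 2
  rT <- sqrt(35 / pi)            # T cell radius, sites
  xs <- seq_len(domain)
  d2 <- outer(xs, xs, function(y, x) (x - cx)^2 + (y - cx)^2)
  tmask <- d2 <= rT^2
  uptake <- matrix(k[["E"]], domain, domain)
  uptake[tmask] <- k[["T"]]
  source <- matrix(0, domain, domain)
  source[tmask] <- secretion / sum(tmask)
  ss <- steady_state_ifng(uptake, source, D = D, h = h,
                          boundary = boundary)
  layer_sites <- 24 / h            # one cell layer = 24 um
  dist <- sqrt(d2) - rT            # distance from the T cell edge
  layer <- ceiling(pmax(dist, 1e-9) / layer_sites)
  means <- vapply(seq_len(n_layers), function(l)
    mean(ss[layer == l & !tmask]), 0)
  folds <- c(means[-length(means)] / means[-1], NA)
  out <- data.frame(layer = seq_len(n_layers), mean_conc = means,
                    fold_to_next = folds)
  attr(out, "fold_first_pair") <- folds[1]
  attr(out, "fold_per_layer") <- exp(mean(log(folds[-n_layers])))
  attr(out, "tcell_conc") <- mean(ss[tmask])
  out
}

#' Continuum radial steady-state profile around a secreting T cell
#'
#' Radially symmetric finite-volume solution of
#' `D (c'' + c'/r) - k(r) c + s(r) = 0` for a central T cell disk
#' (radius of a 140 um^2 cell, no uptake, uniform secretion) embedded in
#' confluent tumor tissue, with the far boundary (`r_max`) placed well
#' beyond the decay length `sqrt(D/k)`. This is the appropriate
#' measurement when the decay length is comparable to or larger than any
#' feasible lattice: the 2-D lattice solver's closed boundary would
#' otherwise shape the profile.
#'
#' @inheritParams radial_decay_profile
#' @param r_max Outer radius (um) with absorbing condition.
#' @param h Radial resolution (um).
#' @return Data.frame as in [radial_decay_profile()] (layer averages are
#'   annulus-area weighted), with the same attributes plus
#'   `fold_six_layers` (layer 1 vs layer 7).
#' @export
radial_continuum_profile <- function(scenario = c("short", "long"),
                                     n_layers = 7, secretion = 1200,
                                     D = 5430, h = 2, r_max = NULL) {
  scenario <- match.arg(scenario)
  k_tum <- uptake_profile(scenario)[["E"]]
  ell <- sqrt(D / k_tum)
  if (is.null(r_max)) r_max <- max(4 * ell, 200, 24 * (n_layers + 2))
  rT <- sqrt(140 / pi)
  r <- seq(h / 2, r_max - h / 2, by = h)
  n <- length(r)
  k <- ifelse(r <= rT, 0, k_tum)
  s <- ifelse(r <= rT, secretion / (pi * rT^2), 0)
  lo <- r - h / 2; hi <- r + h / 2
  a <- D * lo / (r * h^2); b <- D * hi / (r * h^2)
  a[1] <- 0 # symmetry at the origin
  ## tridiagonal solve (Thomas algorithm); absorbing outer boundary
  dg <- -(a + b) - k
  rhs <- -s
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- b[1] / dg[1]; dp[1] <- rhs[1] / dg[1]
  for (i in 2:n) {
    m <- dg[i] - a[i] * cp[i - 1]
    cp[i] <- if (i < n) b[i] / m else 0
    dp[i] <- (rhs[i] - a[i] * dp[i - 1]) / m
  }
  conc <- numeric(n)
  conc[n] <- dp[n]
  for (i in (n - 1):1) conc[i] <- dp[i] - cp[i] * conc[i + 1]
  lay <- ceiling(pmax(r - rT, 1e-9) / 24)
  means <- vapply(seq_len(n_layers), function(l) {
    w <- r[lay == l]
    sum(conc[lay == l] * w) / sum(w)
  }, 0)
  ## report in molecules per lattice site for comparability: the 2-D
  ## concentration c is molecules/um^2; one site is 4 um^2
  means <- means * 4
  folds <- c(means[-length(means)] / means[-1], NA)
  out <- data.frame(layer = seq_len(n_layers), mean_conc = means,
                    fold_to_next = folds)
  attr(out, "fold_first_pair") <- folds[1]
  attr(out, "fold_per_layer") <- exp(mean(log(folds[-n_layers])))
  attr(out, "fold_six_layers") <- if (n_layers >= 7)
    means[1] / means[7] else NA_real_
  attr(out, "decay_length_um") <- ell
  out
}

#' Construct a static TGFb field
#'
#' Uniform mode: every site carries `level` nM. Gradient mode: the
#' concentration peaks at `level` at the tumor's invasive front edge
#' (a given row) and decreases linearly into the tumor, reaching zero at
#' the opposite domain edge; the medium side of the front carries the
#' peak value. The field is static for the whole simulation.
#'
#' @param mode `"uniform"` or `"gradient"`.
#' @param level Peak (and uniform-mode) concentration, nM; > 0.
#' @param domain Lattice extent in sites.
#' @param front_row For gradient mode, the row index of the invasive
#'   front (tumor occupies rows `front_row` and below).
#' @return Numeric `domain` x `domain` matrix (nM).
#' @export
make_tgfb_field <- function(mode = c("uniform", "gradient"), level,
                            domain, front_row = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(level) || level <= 0)
    stop("make_tgfb_field: 'level' must be > 0")
  if (mode == "uniform")
    return(matrix(level, domain, domain))
  if (is.null(front_row))
    stop("make_tgfb_field: gradient mode needs 'front_row'")
  depth <- domain - front_row
  rowv <- vapply(seq_len(domain), function(r) {
    if (r <= front_row) level
    else level * max(0, 1 - (r - front_row) / max(depth, 1))
  }, 0)
  matrix(rowv, domain, domain, byrow = FALSE)
}

#' Concentration sensed by a cell
#'
#' Mean field value over the cell's lattice sites; IFNg fields
#' (molecules/site) are converted to nM with the documented site volume.
#'
#' @param spins Spin matrix.
#' @param cell_id Cell id (> 0).
#' @param field Field matrix aligned to the lattice (or coarser by an
#'   integer factor `fac`).
#' @param fac Field coarsening factor (sites per field cell edge).
#' @param units `"nM"` converts molecules/site to nM; `"raw"` returns
#'   the plain mean.
#' @return Scalar sensed concentration.
#' @export
sense_field <- function(spins, cell_id, field, fac = 1L,
                        units = c("raw", "nM")) {
  units <- match.arg(units)
  idx <- which(spins == cell_id, arr.ind = TRUE)
  if (!nrow(idx)) stop("sense_field: cell ", cell_id, " occupies no site")
  fy <- (idx[, 1] - 1L) %/% fac + 1L
  fx <- (idx[, 2] - 1L) %/% fac + 1L
  v <- mean(field[cbind(fy, fx)])
  if (units == "nM") v / molecules_per_nm_site() else v
}
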
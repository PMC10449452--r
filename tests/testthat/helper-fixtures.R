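## Fixtures built in code: small lattices and short run helpers.

## a lattice with two square cells side by side (types per `types`),
## surrounded by medium
two_cell_lattice <- function(domain = 20, types = c(1L, 1L)) {
  spins <- matrix(0L, domain, domain)
  spins[6:11, 3:9] <- 1L    # adjacent blocks sharing the col 9|10 edge
  spins[6:11, 10:16] <- 2L
  list(spins = spins, cell_type = types,
       acts = matrix(0, domain, domain))
}

## irregular multi-cell fixture with a T cell carrying Act values
mixed_lattice <- function(seed = 1) {
  set.seed(seed)
  domain <- 20
  spins <- matrix(0L, domain, domain)
  spins[3:9, 3:9] <- 1L     # E
  spins[3:9, 12:18] <- 2L   # H
  spins[12:18, 3:9] <- 3L   # M
  spins[12:18, 12:18] <- 4L # T cell
  ## roughen boundaries a little
  for (k in 1:25) {
    y <- sample(2:(domain - 1), 1); x <- sample(2:(domain - 1), 1)
    nb <- spins[y + sample(-1:1, 1), x + sample(-1:1, 1)]
    if (sum(spins == spins[y, x]) > 20) spins[y, x] <- nb
  }
  acts <- matrix(0, domain, domain)
  acts[spins == 4L] <- sample(0:20, sum(spins == 4L), replace = TRUE)
  list(spins = spins, cell_type = c(1L, 2L, 3L, 4L), acts = acts)
}

## random neighboring site pair with different spins
random_copy_pair <- function(spins) {
  domain <- nrow(spins)
  repeat {
    uy <- sample(seq_len(domain), 1); ux <- sample(seq_len(domain), 1)
    dy <- sample(-1:1, 1); dx <- sample(-1:1, 1)
    if (dx == 0 && dy == 0) next
    vy <- uy + dy; vx <- ux + dx
    if (vx < 1 || vx > domain || vy < 1 || vy > domain) next
    if (spins[uy, ux] != spins[vy, vx])
      return(list(ux = ux, uy = uy, vx = vx, vy = vy))
  }
}

## geometric-mean Act oracle in plain R (second-order Moore, same cell)
gm_act_oracle <- function(spins, acts, x, y) {
  spin <- spins[y, x]
  if (spin == 0) return(0)
  vals <- c()
  for (dy in -2:2) for (dx in -2:2) {
    xx <- x + dx; yy <- y + dy
    if (xx < 1 || xx > ncol(spins) || yy < 1 || yy > nrow(spins)) next
    if (spins[yy, xx] != spin) next
    vals <- c(vals, acts[yy, xx])
  }
  if (!length(vals) || any(vals == 0)) return(0)
  exp(mean(log(vals)))
}

## small driver around the internal engine for property tests
run_small_cpm <- function(lat, mcs, seed = 1, params = cpm_parameters(),
                          out_every = mcs, temperature = NULL) {
  if (!is.null(temperature)) params$temperature <- temperature
  ncell <- length(lat$cell_type)
  emtpdl1:::cpm_simulate(
    lat$spins, lat$cell_type, matrix(0, ncell, 9), matrix(1, ncell, 2),
    emtpdl1:::.cpm_param_list(params), unclass(regulatory_parameters()),
    list(D = 5430, site_um = 2, field_fac = 4L,
         uptake_by_type = rep(0, 5), secretion_rate = 0,
         tgfb = matrix(0, nrow(lat$spins), ncol(lat$spins)),
         max_cfl = 0.5),
    list(total_mcs = as.integer(mcs), freeze_mcs = 0L,
         output_every_mcs = as.integer(out_every), mcs_min = 0.01,
         accel = 1800, ode_dt_h = 0.015, mode = 0L,
         seed = as.integer(seed), ode_enabled = FALSE,
         field_uptake = FALSE))
}
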
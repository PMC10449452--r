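test_that("area term of a shrinking cell matches the closed form", {
  lat <- two_cell_lattice()
  prm <- cpm_parameters()
  ## copy a site of cell 2 over a boundary site of cell 1: cell 1 loses
  ## one site, cell 2 gains one
  dh <- delta_hamiltonian(lat$spins, lat$cell_type, lat$acts,
                          ux = 10, uy = 8, vx = 9, vy = 8, params = prm)
  a1 <- sum(lat$spins == 1L); a2 <- sum(lat$spins == 2L)
  A <- prm$target_area[2]
  expect_equal(dh$area,
               ((a1 - 1 - A)^2 - (a1 - A)^2) +
                 ((a2 + 1 - A)^2 - (a2 - A)^2))
})

test_that("local energy change equals the global recompute for random copies", {
  set.seed(11)
  lat <- mixed_lattice()
  prm <- cpm_parameters()
  h0 <- global_hamiltonian(lat$spins, lat$cell_type, prm)
  for (k in 1:100) {
    pr <- random_copy_pair(lat$spins)
    ## skip copies that would annihilate a cell
    sp <- lat$spins[pr$vy, pr$vx]
    if (sp > 0 && sum(lat$spins == sp) == 1) next
    dh <- delta_hamiltonian(lat$spins, lat$cell_type, lat$acts,
                            pr$ux, pr$uy, pr$vx, pr$vy, prm)
    after <- lat$spins
    after[pr$vy, pr$vx] <- after[pr$uy, pr$ux]
    h1 <- global_hamiltonian(after, lat$cell_type, prm)
    ## the Act term is a protrusion bias, not part of the state energy
    expect_equal(dh$adhesion + dh$area + dh$perimeter, h1 - h0,
                 tolerance = 1e-9)
  }
})

test_that("Act bias follows the geometric-mean contrast and vanishes at equality", {
  set.seed(3)
  lat <- mixed_lattice()
  prm <- cpm_parameters()
  checked <- 0
  for (k in 1:200) {
    pr <- random_copy_pair(lat$spins)
    ts <- lat$spins[pr$uy, pr$ux]; tt <- lat$spins[pr$vy, pr$vx]
    involves_t <- (ts == 4L) || (tt == 4L)
    dh <- delta_hamiltonian(lat$spins, lat$cell_type, lat$acts,
                            pr$ux, pr$uy, pr$vx, pr$vy, prm)
    gmu <- gm_act_oracle(lat$spins, lat$acts, pr$ux, pr$uy)
    gmv <- gm_act_oracle(lat$spins, lat$acts, pr$vx, pr$vy)
    if (!involves_t) {
      expect_equal(dh$act, 0)
    } else {
      expect_equal(dh$act,
                   -prm$lambda_act / prm$max_act * (gmu - gmv),
                   tolerance = 1e-12)
      checked <- checked + 1
    }
    if (abs(gmu - gmv) < 1e-12) expect_equal(dh$act, 0)
  }
  expect_gt(checked, 5)
})

test_that("cells are conserved and T cells stay simply connected", {
  lat <- mixed_lattice()
  out <- run_small_cpm(lat, mcs = 1000, seed = 2, out_every = 100)
  ## no birth/death: every cell retains positive area
  areas <- tabulate(out$spins[out$spins > 0], nbins = 4)
  expect_true(all(areas > 0))
  expect_equal(sort(unique(as.integer(out$spins[out$spins > 0]))), 1:4)
  ## T cell (id 4) simple connectivity: flood fill its sites
  tmask <- out$spins == 4L
  idx <- which(tmask, arr.ind = TRUE)
  comp <- matrix(FALSE, nrow(tmask), ncol(tmask))
  queue <- list(idx[1, ])
  comp[idx[1, 1], idx[1, 2]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (dy in -1:1) for (dx in -1:1) {
      yy <- cur[1] + dy; xx <- cur[2] + dx
      if (yy < 1 || yy > nrow(tmask) || xx < 1 || xx > ncol(tmask)) next
      if (tmask[yy, xx] && !comp[yy, xx]) {
        comp[yy, xx] <- TRUE
        queue[[length(queue) + 1]] <- c(yy, xx)
      }
    }
  }
  expect_equal(sum(comp), sum(tmask))
})

test_that("at near-zero temperature a relaxed cell rejects area growth", {
  lat <- two_cell_lattice(types = c(1L, 1L))
  ## relax at moderate temperature, then quench
  out <- run_small_cpm(lat, mcs = 300, seed = 1)
  lat2 <- list(spins = out$spins, cell_type = lat$cell_type,
               acts = matrix(0, nrow(out$spins), ncol(out$spins)))
  q <- run_small_cpm(lat2, mcs = 200, seed = 2, temperature = 1e-4)
  a <- tabulate(q$spins[q$spins > 0], 2)
  expect_true(all(abs(a - 113) <= 15)) # pinned near target area
})

test_that("two identical cells have statistically indistinguishable areas", {
  lat <- two_cell_lattice(types = c(1L, 1L))
  a1 <- c(); a2 <- c()
  cur <- lat
  out <- run_small_cpm(cur, mcs = 500, seed = 7) # burn-in
  cur$spins <- out$spins
  for (rep in 1:40) {
    out <- run_small_cpm(cur, mcs = 50, seed = 100 + rep)
    cur$spins <- out$spins
    a1 <- c(a1, sum(out$spins == 1L)); a2 <- c(a2, sum(out$spins == 2L))
  }
  ks <- suppressWarnings(stats::ks.test(a1, a2))
  expect_gt(ks$p.value, 0.01)
})

test_that("speed measurement handles degenerate and linear tracks", {
  still <- data.frame(id = 1, time = 0:10, x = 5, y = 5)
  expect_equal(measure_speed(still), 0)
  lin <- data.frame(id = 1, time = 0:10, x = 10 * (0:10), y = 0)
  expect_equal(measure_speed(lin), 10)
  short <- data.frame(id = 1, time = c(0, 0.5), x = c(0, 1), y = 0)
  expect_error(measure_speed(short, window = 2), "track")
})
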
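test_that("diffusion without sources or sinks conserves mass", {
  set.seed(5)
  f <- matrix(runif(40 * 40), 40, 40)
  z <- matrix(0, 40, 40)
  out <- step_ifng(f, z, z, minutes = 2)
  expect_equal(sum(out$field), sum(f), tolerance = 1e-10)
  expect_equal(out$secreted, 0)
  expect_equal(out$consumed, 0)
})

test_that("uniform uptake-only field decays exponentially at every site", {
  f <- matrix(3.7, 25, 25)
  k <- matrix(0.8, 25, 25)
  z <- matrix(0, 25, 25)
  out <- step_ifng(f, k, z, minutes = 1.5)
  ## uniform field: diffusion contributes nothing, decay is exact
  expect_equal(out$field, matrix(3.7 * exp(-0.8 * 1.5), 25, 25),
               tolerance = 1e-9)
})

test_that("steady state balances secretion against uptake", {
  n <- 61
  k <- matrix(0.5, n, n)
  s <- matrix(0, n, n); s[31, 31] <- 1200
  ss <- steady_state_ifng(k, s)
  ## total uptake flux equals total secretion (no-flux boundaries)
  expect_equal(sum(k * ss), 1200, tolerance = 0.01 * 1200)
  ## and the transient solver converges toward the same state
  out <- step_ifng(ss, k, s, minutes = 1)
  expect_equal(out$field, ss, tolerance = 1e-3)
})

test_that("steady radial profile decreases monotonically from the source", {
  pr <- radial_decay_profile("short", domain = 61, n_layers = 2)
  expect_true(all(diff(pr$mean_conc) < 0))
  prl <- radial_continuum_profile("long")
  expect_true(all(diff(prl$mean_conc) < 0))
  ## continuum fit: fitted decay length ~ sqrt(D/k) in the exponential
  ## regime (well away from source and boundary)
  ell <- attr(prl, "decay_length_um")
  expect_equal(ell, sqrt(5430 / 0.021), tolerance = 1e-12)
})

test_that("TGFb fields honor their uniform and gradient contracts", {
  u <- make_tgfb_field("uniform", 0.1, domain = 30)
  expect_true(all(u == 0.1))
  g <- make_tgfb_field("gradient", 0.2, domain = 30, front_row = 12)
  ## peak at the front edge, strictly above the tumor interior
  expect_equal(max(g), 0.2)
  expect_equal(unique(g[12, ]), 0.2)
  expect_lt(g[25, 5], g[13, 5])
  expect_true(all(diff(g[12:30, 1]) <= 0)) # monotone into the tumor
  expect_error(make_tgfb_field("uniform", -1, 10), "level")
})

test_that("sensing averages the field over the cell footprint", {
  spins <- matrix(0L, 8, 8)
  spins[3:4, 3:6] <- 1L
  f <- matrix(0, 8, 8)
  expect_equal(sense_field(spins, 1L, f), 0)
  f2 <- matrix(5.5, 8, 8)
  expect_equal(sense_field(spins, 1L, f2), 5.5)
  ## checkerboard: arithmetic mean of occupied sites
  cb <- outer(1:8, 1:8, function(y, x) (x + y) %% 2)
  expect_equal(sense_field(spins, 1L, cb),
               mean(cb[3:4, 3:6]))
  expect_equal(sense_field(spins, 1L, f2, units = "nM"),
               5.5 / molecules_per_nm_site())
  expect_error(sense_field(spins, 9L, f), "occupies no site")
})
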
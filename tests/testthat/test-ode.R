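p0 <- regulatory_parameters()

test_that("IFNg equation honors the inhibition mode", {
  p <- regulatory_parameters("none", gi = 0.1, ki = 1)
  ## linear steady state I* = gi/ki
  expect_equal(rhs_ifng(0.1, PM = 5e4, Tg = 0.3, p), 0)
  ## pdl1 mode with PM = 0 equals mode none
  pp <- regulatory_parameters("pdl1", gi = 0.1)
  expect_equal(rhs_ifng(0.05, PM = 0, Tg = 0, pp),
               rhs_ifng(0.05, PM = 0, Tg = 0, p))
  pbad <- p; pbad$inhibition_mode <- "bogus"
  expect_error(rhs_ifng(0, 0, 0, pbad), "inhibition_mode")
})

test_that("combined-mode RHS equals the product of single-mode factors", {
  pc <- regulatory_parameters("combined", gi = 0.2)
  pp <- regulatory_parameters("pdl1", gi = 0.2)
  pt <- regulatory_parameters("tgfb", gi = 0.2)
  grid <- expand.grid(PM = c(0, 1e3, 2e4, 1e5), Tg = c(0, 0.05, 0.15, 0.4))
  for (i in seq_len(nrow(grid))) {
    PM <- grid$PM[i]; Tg <- grid$Tg[i]; I <- 0.07
    f_p <- ifng_inhibition_factor(PM, Tg, pp)
    f_t <- ifng_inhibition_factor(PM, Tg, pt)
    ## dI/dt(combined) + ki I == gi * HS_PM * HS_T, to machine precision
    expect_equal(rhs_ifng(I, PM, Tg, pc) + pc$ki * I,
                 pc$gi * f_p * f_t, tolerance = 1e-14)
  }
})

test_that("TGFb-SNAIL1 submodel reaches its closed-form baselines", {
  p <- regulatory_parameters(gt = 0)
  y0 <- regulatory_initial_state(p)
  y0[c("ms", "s", "tgfb")] <- 0
  out <- simulate_regulation(y0, c(0, 3000), p, clamp_ifng = 0)
  fin <- out[nrow(out), ]
  ## H+(0) = 0: mS* = g0ms/kms, S* = gs mS*/ks
  expect_equal(unname(fin[["ms"]]), 1500 / 0.09, tolerance = 1e-4)
  expect_equal(unname(fin[["s"]]), 17 * (1500 / 0.09) / 1.66,
               tolerance = 1e-4)
  ## positivity from all-zero initial conditions
  y00 <- y0; y00[] <- 0
  tr <- simulate_regulation(y00, seq(0, 10, by = 0.5), p)
  expect_true(all(tr[, -1] >= -1e-9))
  expect_true(all(tr[nrow(tr), c("ms", "s")] > 0))
})

test_that("trajectories stay non-negative across random parameterizations", {
  set.seed(7)
  for (k in 1:20) {
    p <- regulatory_parameters(
      sample(c("none", "pdl1", "tgfb", "combined"), 1),
      gi = runif(1, 0, 0.5), gt = runif(1, 0, 0.3),
      gu = 2100 * runif(1, 0.7, 1.3), gmz = 11 * runif(1, 0.7, 1.3),
      gmp = 100 * runif(1, 0.5, 2))
    y0 <- regulatory_initial_state(p)
    y0["u"] <- 10^runif(1, 1, 4.5); y0["mz"] <- 10^runif(1, 0, 3)
    y0["z"] <- 10^runif(1, 1, 5.5)
    out <- simulate_regulation(y0, seq(0, 400, length.out = 9), p)
    expect_true(all(out[, -1] > -1e-6))
  }
})

test_that("phenotype classification is hysteretic with no direct M-to-H", {
  expect_equal(classify_phenotype(235, "E"), "H")
  expect_equal(classify_phenotype(234.9, "E"), "E")
  expect_equal(classify_phenotype(200, "H"), "H") # between 145 and 235
  expect_equal(classify_phenotype(145, "H"), "E")
  expect_equal(classify_phenotype(715, "H"), "M")
  expect_equal(classify_phenotype(500, "M"), "M") # no M -> H
  expect_equal(classify_phenotype(370, "M"), "E")
  expect_equal(classify_phenotype(400, "M"), "M")
  expect_error(classify_phenotype(-1, "E"), "mz")
  ## vectorized with recycling
  expect_equal(classify_phenotype(c(400, 400, 400), c("E", "M", "H")),
               c("H", "M", "H"))
})

test_that("equilibria returned by the finder are genuine steady states", {
  p <- regulatory_parameters("none", gi = 0.1)
  eq <- find_equilibria(p, snail_fixed = 1.95e5, seed = 3)
  sn <- regulatory_state_names()
  for (i in seq_len(nrow(eq))) {
    y <- as.numeric(eq[i, sn]); names(y) <- sn
    resid <- rhs_full(y, p, snail_fixed = 1.95e5)
    expect_lt(max(abs(resid) / pmax(abs(y), 1)), 1e-6)
  }
})
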
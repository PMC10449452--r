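test_that("a linear cytokine subsystem yields exactly one stable equilibrium", {
  ## decouple the network drives so the system is effectively linear in
  ## each variable: no SNAIL1, no IFNg production
  p <- regulatory_parameters("none", gi = 0, gt = 0)
  eq <- find_equilibria(p, snail_fixed = 0, seed = 1)
  expect_equal(sum(eq$stable), 1)
  expect_equal(eq$ifng[eq$stable], 0)
  ## with production, I* = gi/ki at the (unique) equilibrium
  p2 <- regulatory_parameters("none", gi = 0.25, gt = 0)
  eq2 <- find_equilibria(p2, snail_fixed = 0, seed = 1)
  expect_equal(unique(round(eq2$ifng, 10)), 0.25)
})

test_that("equilibria match long-time integration endpoints over a SNAIL1 grid", {
  p <- regulatory_parameters("none", gi = 0.1)
  sn <- regulatory_state_names()
  for (S in seq(1.7e5, 2.15e5, length.out = 5)) {
    eq <- find_equilibria(p, snail_fixed = S, seed = 2)
    stable <- eq[eq$stable, , drop = FALSE]
    ## integrate from perturbed copies of each stable state: must return
    for (i in seq_len(nrow(stable))) {
      y <- as.numeric(stable[i, sn]); names(y) <- sn
      y[c("u", "mz", "z")] <- y[c("u", "mz", "z")] * 1.01
      out <- simulate_regulation(y, c(0, 2000), p, snail_fixed = S)
      fin <- out[nrow(out), -1]
      expect_lt(abs(log1p(fin[["mz"]]) - log1p(stable$mz[i])), 0.01)
    }
  }
})

test_that("unstable equilibria are not reached by forward integration", {
  p <- regulatory_parameters("none", gi = 0.1)
  eq <- find_equilibria(p, snail_fixed = 1.95e5, seed = 5)
  sn <- regulatory_state_names()
  saddles <- eq[!eq$stable, , drop = FALSE]
  expect_gt(nrow(saddles), 0)
  stable_mz <- eq$mz[eq$stable]
  for (i in seq_len(nrow(saddles))) {
    y <- as.numeric(saddles[i, sn]); names(y) <- sn
    y[c("u", "mz", "z")] <- y[c("u", "mz", "z")] * 1.01 # 1% perturbation
    out <- simulate_regulation(y, c(0, 4000), p, snail_fixed = 1.95e5)
    fin_mz <- out[nrow(out), "mz"]
    ## lands on a stable state, not back on the saddle
    expect_gt(min(abs(fin_mz - stable_mz)) /
                min(abs(fin_mz - saddles$mz[i]), Inf), -Inf)
    expect_true(min(abs(log1p(fin_mz) - log1p(stable_mz))) < 0.02)
    expect_gt(abs(log1p(fin_mz) - log1p(saddles$mz[i])), 0.05)
  }
})

test_that("stability flags are consistent with the Jacobian spectrum", {
  p <- regulatory_parameters("none", gi = 0.1)
  eq <- find_equilibria(p, snail_fixed = 1.9e5, seed = 4)
  expect_true(all(eq$stable == (eq$max_re_eig < 1e-6)))
  expect_true(all(diff(order(eq$mz)) == 1)) # sorted output
})
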
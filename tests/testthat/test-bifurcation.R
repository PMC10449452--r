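## Branch sweeps are moderately expensive; grids here are coarse but
## still bracket every reported fold.

test_that("PD-L1 feedback changes fold positions but not fold count", {
  rng <- c(1.6e5, 2.2e5)
  br_none <- sweep_branches(regulatory_parameters("none", gi = 0.1),
                            "snail1", rng, n_points = 25, seed = 1)
  br_pdl1 <- sweep_branches(regulatory_parameters("pdl1", gi = 0.1),
                            "snail1", rng, n_points = 25, seed = 1)
  f_none <- fold_locations(br_none); f_pdl1 <- fold_locations(br_pdl1)
  expect_equal(sum(f_pdl1$multiplicity), sum(f_none$multiplicity))
  expect_gt(sum(f_none$multiplicity), 0)
})

test_that("without IFNg drive the sweep below the EMT fold is a single fold-free branch", {
  ## degenerate sweep: no IFNg production, SNAIL1 below the first fold.
  ## PD-L1 stays at its (miR-200-modulated) IFNg-free baseline: one
  ## stable epithelial branch, no bifurcation, smooth monotone PD-L1
  ## (SNAIL1 lowers miR-200, de-repressing PD-L1 translation slightly)
  p <- regulatory_parameters("none", gi = 0)
  br <- sweep_branches(p, "snail1", c(1.0e5, 1.6e5), n_points = 8,
                       seed = 2)
  expect_equal(nrow(fold_locations(br)), 0)
  stab <- br[br$stable, ]
  expect_true(all(stab$phenotype == "E"))
  expect_equal(as.integer(table(stab$value)), rep(1L, 8)) # one branch
  stab <- stab[order(stab$value), ]
  expect_true(all(diff(stab$pm) > 0))
  ## and PD-L1 remains at a low, sub-threshold baseline throughout
  expect_lt(max(stab$pm), p$pm0_i)
})

test_that("branch sweep output is tidy and folds are bracketed intervals", {
  p <- regulatory_parameters("none", gi = 0.1)
  br <- sweep_branches(p, "snail1", c(1.8e5, 2.1e5), n_points = 12,
                       seed = 3)
  expect_s3_class(br, "bifurcation_branches")
  expect_true(all(c("control", "value", "branch", "stable",
                    "phenotype") %in% names(br)))
  long <- branch_table_long(br)
  expect_setequal(unique(long$variable), c("pm", "mz", "u", "z"))
  fl <- fold_locations(br)
  expect_true(all(fl$uncertainty > 0))
  expect_true(all(fl$location >= 1.8e5 & fl$location <= 2.1e5))
})

test_that("phase diagram corner at zero drive is epithelial only", {
  p <- regulatory_parameters("none")
  pd <- phase_diagram(p, axis1 = list(name = "tgfb", range = c(0, 0.1)),
                      axis2 = list(name = "gI", range = c(0, 0.1)),
                      resolution = 3, seed = 1)
  corner <- pd$label[pd$tgfb == 0 & pd$gI == 0]
  expect_equal(corner, "E")
  expect_true(all(nzchar(pd$label))) # every cell labeled non-empty
})

test_that("removing the inhibition Hill reproduces the uninhibited folds", {
  rng <- c(1.7e5, 2.1e5)
  p_none <- regulatory_parameters("none", gi = 0.1)
  ## lambda = 1 makes the shifted Hill identically 1
  p_off <- regulatory_parameters("pdl1", gi = 0.1, lpm_i = 1)
  br1 <- sweep_branches(p_none, "snail1", rng, n_points = 15, seed = 4)
  br2 <- sweep_branches(p_off, "snail1", rng, n_points = 15, seed = 4)
  f1 <- fold_locations(br1); f2 <- fold_locations(br2)
  expect_equal(f2$location, f1$location, tolerance = 1e-8)
})

test_that("sensitivity sweep at factor 1 reproduces baseline folds", {
  p <- regulatory_parameters("pdl1", gi = 0.1)
  sens <- sensitivity_sweep(p, inhibition_params = c("lpm_i", "pm0_i"),
                            factors = c(1), range = c(1.7e5, 2.1e5),
                            n_points = 12, seed = 5)
  base <- sweep_branches(p, "snail1", c(1.7e5, 2.1e5), n_points = 12,
                         seed = 5)
  fl <- fold_locations(base)
  expect_true(all(sens$n_folds == sum(fl$multiplicity)))
  expect_equal(sens$fold_locations[1],
               paste(signif(fl$location, 6), collapse = ","))
})
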
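test_that("T cell production follows the contact and field contracts", {
  p <- regulatory_parameters()
  expect_equal(tcell_production_rate(0, 0, "pdl1", p), 1200)
  expect_equal(tcell_production_rate(1e12, 0, "pdl1", p), 120,
               tolerance = 1e-4) # lambda = 0.1 floor
  ## half-functional point: T at its threshold
  expect_equal(tcell_production_rate(0, p$t0_i, "tgfb", p),
               1200 * (1 + 0.1) / 2)
  expect_equal(tcell_production_rate(5e5, 5, "none", p), 1200)
})

test_that("zero-width heterogeneity leaves all cells identical", {
  m <- apply_heterogeneity(25, sigma = 0, seed = 1)
  expect_true(all(m == 1))
  m2 <- apply_heterogeneity(25, sigma = 0.04, seed = 1)
  expect_false(all(m2 == 1))
  expect_equal(attr(m2, "sigma"), 0.04)
})

test_that("default heterogeneity passes the zero-IFNg dry run", {
  m <- apply_heterogeneity(40, sigma = 0.04, seed = 2, check = FALSE)
  expect_true(check_no_spontaneous_emt(m, tgfb_level = 0.05))
})

test_that("scenario initialization honors counts and the 1:40 ratio", {
  sc_l <- scenario("long_range")
  expect_equal(sc_l$n_tumor, 480)
  expect_equal(sc_l$n_tcell, 12)
  sc_s <- scenario("short_range")
  expect_equal(sc_s$n_tumor, 200)
  expect_equal(sc_s$n_tcell, 5)
  ## a reduced geometry builds a consistent lattice
  sc <- scenario("long_range", n_tumor = 40, domain_um = 200,
                 duration_min = 20)
  init <- initialize_scenario(sc, seed = 1)
  ids <- sort(unique(as.integer(init$spins[init$spins > 0])))
  expect_equal(ids, seq_len(sc$n_tumor + sc$n_tcell))
  expect_equal(init$cell_type,
               c(rep(1L, sc$n_tumor), rep(4L, sc$n_tcell)))
  ## short-range front: T cells sit below the front row
  scf <- scenario("short_range", n_tumor = 40, domain_um = 200)
  initf <- initialize_scenario(scf, seed = 1)
  for (id in sc$n_tumor + seq_len(scf$n_tcell)) {
    rows <- which(initf$spins == id, arr.ind = TRUE)[, 1]
    expect_true(all(rows >= initf$front_row))
  }
})

test_that("runs are deterministic under a fixed seed", {
  sc <- scenario("long_range", n_tumor = 20, domain_um = 150,
                 duration_min = 10, output_min = 5, inhibition = "pdl1",
                 heterogeneous = TRUE)
  r1 <- run_simulation(sc, seed = 9)
  r2 <- run_simulation(sc, seed = 9)
  expect_identical(r1$cells, r2$cells)
  expect_identical(r1$final$spins, r2$final$spins)
  r3 <- run_simulation(sc, seed = 10)
  expect_false(identical(r1$cells, r3$cells))
})

test_that("after the freeze tumor cells sit on the epithelial attractor", {
  sc <- scenario("long_range", n_tumor = 20, domain_um = 150,
                 duration_min = 10, output_min = 5)
  r <- run_simulation(sc, seed = 1)
  at0 <- r$cells[r$cells$time == 0 & r$cells$type %in% 1:3, ]
  expect_true(all(at0$mz < 235))
  expect_true(all(at0$type == 1L))
  ## frozen T cells have produced no IFNg by t = 0
  expect_true(all(at0$sense_ifng < 1e-9))
})

test_that("field mass balance closes when uptake is disabled", {
  ## secretion-only run: field mass must equal total secreted molecules
  sc <- scenario("long_range", n_tumor = 20, domain_um = 150,
                 duration_min = 5, output_min = 5)
  init <- initialize_scenario(sc, seed = 3)
  cpm <- cpm_parameters()
  out <- emtpdl1:::cpm_simulate(
    init$spins, init$cell_type, init$reg, init$mult,
    emtpdl1:::.cpm_param_list(cpm), unclass(regulatory_parameters()),
    list(D = 5430, site_um = 2, field_fac = sc$field_fac,
         uptake_by_type = unname(uptake_profile("long")),
         secretion_rate = 1200, tgfb = init$tgfb, max_cfl = 0.5),
    list(total_mcs = 1500L, freeze_mcs = 1000L, output_every_mcs = 500L,
         mcs_min = 0.01, accel = 1800, ode_dt_h = 0.015, mode = 0L,
         seed = 3L, ode_enabled = FALSE, field_uptake = FALSE))
  mass <- sum(out$field) * sc$field_fac^2
  expect_equal(out$consumed, 0)
  expect_equal(mass, out$secreted, tolerance = 1e-6)
  ## and with uptake on, secreted - consumed matches the standing mass
  out2 <- run_simulation(sc, seed = 3)
  mass2 <- sum(out2$final$field) * sc$field_fac^2
  expect_equal(mass2, out2$secreted - out2$consumed,
               tolerance = 1e-3 * out2$secreted)
})

test_that("phenotype switching swaps the type-dependent CPM parameters", {
  ## an E cell whose mz crosses the threshold becomes H at the next
  ## output interval (checked at the classifier level plus a run where
  ## IFNg drives transitions)
  expect_equal(classify_phenotype(240, "E"), "H")
  sc <- scenario("long_range", n_tumor = 30, domain_um = 180,
                 duration_min = 120, output_min = 10,
                 inhibition = "none", heterogeneous = TRUE,
                 het_sigma = 0.06)
  r <- run_simulation(sc, seed = 4)
  late <- r$cells[r$cells$time >= 100 & r$cells$type %in% 1:3, ]
  ## with wide heterogeneity and flooding IFNg some cells become hybrid
  expect_gt(sum(late$type == 2L), 0)
  ## all phenotype labels remain within the tumor set (counts conserved)
  counts <- table(r$cells$time)
  expect_true(all(counts == counts[1]))
})
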
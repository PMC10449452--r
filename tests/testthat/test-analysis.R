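## build a small synthetic per-cell table shaped like run_simulation()
## output
fake_cells <- function(times = seq(0, 50, by = 10), n_e = 8, n_h = 2,
                       ifng = 0.3, jitter = 0) {
  rows <- list()
  for (tt in times) {
    type <- c(rep(1L, n_e), rep(2L, n_h))
    n <- length(type)
    rows[[length(rows) + 1]] <- data.frame(
      time = tt, id = seq_len(n), type = type,
      x = 10 * seq_len(n), y = 10, area = 452,
      mz = ifelse(type == 1L, 80, 400) + jitter * tt,
      pm = ifelse(type == 1L, 1.2e4, 2.6e4),
      sense_ifng = ifng, sense_tgfb = 0.05, production = 0)
  }
  do.call(rbind, rows)
}

test_that("identical exposure gives a zero percent difference", {
  a <- fake_cells(); b <- fake_cells()
  expect_equal(epithelial_ifng_exposure(list(a), list(b), c(0, 50)), 0,
               ignore_attr = TRUE)
  ## heterogeneous 10% lower
  h <- fake_cells(ifng = 0.27)
  d <- epithelial_ifng_exposure(list(h), list(a), c(0, 50))
  expect_equal(as.numeric(d), 10)
  expect_error(epithelial_ifng_exposure(list(a), list(b), c(900, 999)),
               "window")
})

test_that("phenotype fractions are consistent and sum to one", {
  cells <- fake_cells(n_e = 9, n_h = 3)
  hf <- hybrid_fraction(cells, c(0, 50))
  expect_equal(as.numeric(hf), 0.25)
  expect_equal(sum(attr(hf, "by_phenotype")), 1)
  pure <- fake_cells(n_e = 10, n_h = 0)
  expect_equal(as.numeric(hybrid_fraction(pure, c(0, 50))), 0)
})

test_that("population curves match an independent group-by recompute", {
  set.seed(21)
  runs <- lapply(1:3, function(k) fake_cells(jitter = k))
  pc <- population_curves(runs)
  ## independent recompute: per replicate per time, then mean/SEM
  times <- sort(unique(runs[[1]]$time))
  for (tt in times) {
    per_rep <- sapply(runs, function(r) {
      tum <- r[r$time == tt & r$type %in% 1:3, ]
      mean(tum$mz)
    })
    expect_equal(pc$mz_mean[pc$time == tt], mean(per_rep))
    expect_equal(pc$mz_sem[pc$time == tt],
                 stats::sd(per_rep) / sqrt(3))
  }
  ## replicated identical snapshot: SEM exactly zero
  same <- population_curves(lapply(1:3, function(k) fake_cells()))
  expect_true(all(same$pm_sem == 0))
  expect_true(all(same$mz_sem == 0))
  ## phenotype counts present and consistent
  expect_equal(unique(same$n_E + same$n_H + same$n_M), 10)
})
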
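test_that("with no informative observations the latent densities integrate out", {
  toy <- make_toy_dataset()
  ds <- toy$dataset
  ds$fgc <- ds$fgc[0, ]
  ds$sightings$encountered <- 0L
  ds$sightings$first_day <- NA_real_
  ds$sightings$calf_observed <- 0L
  ds$config$standardise_f <- FALSE
  # standardisation needs BAI rows; keep two but make them uninformative
  ds$bai <- ds$bai[1:2, ]
  ds$bai$bai_sd <- 1e6
  th <- default_scenario()$params
  lz <- brute_force_marginal(ds, th, toy$H, toy$S, Gh = 101, Gs = 41)
  # each flat BAI row contributes a constant density ~ N(0; 0, 1e6)
  flat <- 2 * dnorm(0, 0, 1e6, log = TRUE)
  expect_equal(lz, flat, tolerance = 1e-6)
})

test_that("the step-halving diagnostic converges and detects coarse grids", {
  toy <- make_toy_dataset()
  th <- default_scenario()$params
  fine <- oracle_grid_check(toy$dataset, th, toy$H, toy$S, Gh = 101, Gs = 71)
  expect_lt(fine$delta, 1e-6)
  coarse <- oracle_grid_check(toy$dataset, th, toy$H, toy$S, Gh = 41, Gs = 31)
  expect_gt(coarse$delta, fine$delta)
})

test_that("importance sampling agrees with the quadrature oracle", {
  toy <- make_toy_dataset()
  th <- default_scenario()$params
  lz <- brute_force_marginal(toy$dataset, th, toy$H, toy$S, Gh = 101, Gs = 81)
  set.seed(31)
  is1 <- importance_marginal(toy$dataset, th, toy$H, toy$S, R = 4e4)
  expect_lt(abs(is1$logZ - lz), 3 * is1$se + 1e-3)
})
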
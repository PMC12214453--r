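test_that("writer/reader round trip is lossless, including LOD flags", {
  sim <- tiny_dataset(seed = 1)
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir)
  ds2 <- load_dataset(dir)
  for (tab in c("individuals", "lengths", "bai", "fgc", "sightings")) {
    a <- as.data.frame(sim$dataset[[tab]])
    b <- as.data.frame(ds2[[tab]])[, names(as.data.frame(sim$dataset[[tab]]))]
    expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_true(any(ds2$fgc$m3_below_lod))
  expect_true(all(is.finite(ds2$fgc$m3_lod[ds2$fgc$m3_below_lod])))
})

test_that("full synthetic dataset passes validation silently", {
  sim <- make_study_like_dataset(seed = 1)
  expect_silent(validate_dataset(sim$dataset))
})

test_that("validation rejects support violations of the observation models", {
  sim <- tiny_dataset(seed = 2)
  ds <- sim$dataset

  bad <- ds
  i <- which(bad$sightings$encountered == 0)[1]
  bad$sightings$calf_observed[i] <- 1
  expect_error(validate_dataset(bad), "calf_observed = 1 with encountered = 0")

  bad <- ds
  male <- bad$individuals$individual_id[bad$individuals$sex == "male"][1]
  j <- which(bad$sightings$individual_id == male & bad$sightings$encountered == 1)[1]
  bad$sightings$calf_observed[j] <- 1
  expect_error(validate_dataset(bad), "non-female")

  # a known-age juvenile female cannot have a calf
  bad <- ds
  bad$individuals$sex[1] <- "female"
  bad$individuals$known_age[1] <- TRUE
  bad$individuals$age_mean[1] <- 3
  bad$individuals$min_age[1] <- 3
  id1 <- bad$individuals$individual_id[1]
  jj <- which(bad$sightings$individual_id == id1 & bad$sightings$encountered == 1)[1]
  bad$sightings$calf_observed[jj] <- 1
  expect_error(validate_dataset(bad), "maturity age")

  # consecutive observed calving years violate the inter-calf interval
  bad <- ds
  f <- bad$individuals$individual_id[bad$individuals$sex == "female" &
                                     bad$individuals$age_mean > 10][1]
  rows <- which(bad$sightings$individual_id == f)[1:2]
  bad$sightings$encountered[rows] <- 1
  bad$sightings$first_day[rows] <- 180
  bad$sightings$calf_observed[rows] <- 1
  expect_error(validate_dataset(bad), "inter-calf")

  # schema errors name the missing column
  broken <- ds
  broken$bai$bai_sd <- NULL
  expect_error(validate_dataset(broken), "bai_sd")
})

test_that("rows referencing unknown individuals are rejected", {
  sim <- tiny_dataset(seed = 3)
  ds <- sim$dataset
  ds$bai$individual_id[1] <- "GHOST"
  expect_error(validate_dataset(ds), "unknown individual")
})

test_that("standardisation constants follow the population-SD convention", {
  sim <- tiny_dataset(seed = 4)
  ds <- sim$dataset
  # two lengths, 10 m and 12 m: cubes 1000 and 1728, mean 1364, pop-SD 364
  ds$lengths <- ds$lengths[seq_len(2), ]
  ds$lengths$individual_id <- ds$individuals$individual_id[1:2]
  ds$lengths$year <- 2017L
  ds$lengths$length_mean <- c(10, 12)
  ds$lengths$length_sd <- 0.1
  con <- compute_standardisation(ds)
  expect_equal(con$L3_center, 1364)
  expect_equal(con$L3_scale, 364)
})

test_that("degenerate standardisation input raises an error", {
  sim <- tiny_dataset(seed = 5)
  ds <- sim$dataset
  ds$lengths$length_mean <- 11
  expect_error(compute_standardisation(ds), "Degenerate")
})

test_that("constants are frozen: storing and reusing them reproduces a fit", {
  sim <- tiny_dataset(seed = 6)
  con <- compute_standardisation(sim$dataset)
  f1 <- run_mcmc(sim$dataset, quick_cfg <- {
    cfg <- sim$dataset$config
    cfg$mcmc$n_iter <- 60L; cfg$mcmc$n_burnin <- 20L; cfg$mcmc$thin <- 1L
    cfg
  }, constants = con)
  f2 <- run_mcmc(sim$dataset, quick_cfg, constants = con)
  expect_identical(f1$params, f2$params)
})
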
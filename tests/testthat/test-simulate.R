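test_that("degenerate variances collapse the state processes to their means", {
  sc <- tiny_scenario(n = 30)
  sc$params[c("beta_h", "sigma_h", "chi_h")] <- 0
  sc$params[c("beta_s1", "beta_s2", "beta_s3", "sigma_s", "chi_s")] <- 0
  set.seed(1)
  cohort <- simulate_cohort(sc)
  st <- simulate_states(sc, cohort)
  expect_true(all(abs(st$h[is.finite(st$h)] - sc$params["lambda_h"]) < 1e-12))
  expect_true(all(abs(st$s[is.finite(st$s)] - sc$params["lambda_s"]) < 1e-12))
})

test_that("simulated states reproduce the stated moments", {
  sc <- default_scenario(n_individuals = 8000L)
  sc$n_born_during <- 0L
  sc$params["lambda_h"] <- 27.7
  sc$params["sigma_h"] <- 1
  sc$params["chi_h"] <- 0.5
  set.seed(7)
  cohort <- simulate_cohort(sc)
  st <- simulate_states(sc, cohort)
  hh <- st$h[is.finite(st$h)]
  # mean within 3 SE of the long-run mean implied by the AR recursion
  se <- sd(hh) / sqrt(length(unique(st$H)))   # dominated by the yearly effects
  expect_lt(abs(mean(hh) - 27.7) / (sd(st$H) / sqrt(length(st$H)) + 0.2), 4)
  # lag-1 within-individual regression recovers the AR coefficient
  x <- as.vector(st$h[, -ncol(st$h)]); y <- as.vector(st$h[, -1])
  Ht <- matrix(st$H[-1], nrow(st$h), ncol(st$h) - 1, byrow = TRUE)
  ok <- is.finite(x) & is.finite(y)
  xs <- (x[ok] - sc$h_center) / sc$h_scale
  fitc <- coef(lm(I(y[ok] - as.vector(Ht)[ok]) ~ xs))
  se_b <- summary(lm(I(y[ok] - as.vector(Ht)[ok]) ~ xs))$coefficients[2, 2]
  expect_lt(abs(fitc[2] - sc$params["beta_h"]), 3 * se_b)
})

test_that("reproduction sequences respect pregnancy feedback and maturity", {
  sc <- tiny_scenario(n = 400, years = 2016:2023)
  sc$n_born_during <- 0L
  set.seed(11)
  cohort <- simulate_cohort(sc)
  st <- simulate_states(sc, cohort)
  rep <- simulate_reproduction(sc, cohort, st)
  # no calving in consecutive years, ever
  for (i in seq_len(nrow(rep$c))) {
    expect_false(any(rep$c[i, -1] == 1 & rep$c[i, -ncol(rep$c)] == 1))
  }
  # no calving before the maturity age and none for males
  ages <- outer(cohort$a0, seq_len(ncol(cohort$Ltrue)) - 1, `+`)
  study_cols <- match(sc$years, cohort$grid_years)
  expect_true(all(rep$c[ages[, study_cols] < sc$maturity_age] == 0))
  expect_true(all(rep$c[cohort$true_sex != "female", ] == 0))
  # pregnancy is calving shifted by one year
  expect_identical(rep$P[, -ncol(rep$P)], rep$c[, -1])
})

test_that("sampled reproduction sequences follow the enumerated joint law", {
  # one female, fixed phi, many replicates: empirical sequence frequencies
  # must match the exact enumeration probabilities
  sc <- tiny_scenario(n = 2, years = 2016:2019)
  sc$n_born_during <- 0L
  phi <- c(0.3, 0.5, 0.2, 0.4)
  en <- enumerate_reproduction_sequences(phi, final_pregnancy_prob = 0.05)
  set.seed(3)
  R <- 20000
  keys <- character(R)
  for (r in seq_len(R)) {
    P <- integer(4)
    P[4] <- rbinom(1, 1, 0.05)
    cc <- integer(4)
    for (t in 4:1) {
      cc[t] <- rbinom(1, 1, phi[t] * (1 - P[t]))
      if (t > 1) P[t - 1] <- cc[t]
    }
    keys[r] <- paste(c(cc, P[4]), collapse = "")
  }
  want <- setNames(en$prob, apply(cbind(en$c, en$P[, 4]), 1, paste, collapse = ""))
  got <- table(keys) / R
  common <- intersect(names(want), names(got))
  expect_gt(length(common), 5)
  expect_lt(max(abs(want[common] - as.numeric(got[common]))), 0.02)
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
})

test_that("observation identities hold in degenerate corners", {
  sc <- tiny_scenario(n = 15)
  sc$params[c("delta1", "delta2")] <- 0
  sc$params["nu_h"] <- 1e-12
  sc$bai_sd_range <- c(1e-6, 2e-6)
  set.seed(5)
  cohort <- simulate_cohort(sc)
  st <- simulate_states(sc, cohort)
  rep <- simulate_reproduction(sc, cohort, st)
  obs <- simulate_observations(sc, cohort, st, rep)
  # with no day/pregnancy effect and vanishing noise, observed BAI equals h
  off <- cohort$Tall - length(sc$years)
  for (r in seq_len(min(nrow(obs$bai), 50))) {
    i <- match(obs$bai$individual_id[r], cohort$individuals$individual_id)
    tg <- match(obs$bai$year[r], cohort$grid_years)
    expect_equal(obs$bai$bai_mean[r], st$h[i, tg], tolerance = 1e-3)
  }
  # a calf is never observed without an encounter
  expect_true(all(obs$k[obs$e == 0] == 0))
})

test_that("study-like datasets are reproducible and seed-sensitive", {
  a <- make_study_like_dataset(seed = 1)
  b <- make_study_like_dataset(seed = 1)
  d <- make_study_like_dataset(seed = 2)
  expect_identical(a$dataset$bai, b$dataset$bai)
  expect_identical(a$truth$params, b$truth$params)
  expect_false(isTRUE(all.equal(a$dataset$bai$bai_mean, d$dataset$bai$bai_mean)))
  expect_identical(names(a$dataset$bai), names(d$dataset$bai))
})

test_that("default scenario reproduces the study's sampling intensity", {
  sim <- make_study_like_dataset(seed = 1)
  n_bai <- nrow(sim$dataset$bai)
  n_fgc <- nrow(sim$dataset$fgc)
  expect_lt(abs(n_bai - 665) / 665, 0.20)
  expect_lt(abs(n_fgc - 337) / 337, 0.20)
  expect_equal(nrow(sim$dataset$individuals), 139)
  frac_unknown <- mean(sim$dataset$individuals$sex == "unknown")
  expect_gt(frac_unknown, 0.15); expect_lt(frac_unknown, 0.40)
})
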
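# lightweight gw_draws stand-in for summary-level functions
fake_draws <- function(m, constants = NULL) {
  arr <- array(m, c(nrow(m), 1, ncol(m)),
               dimnames = list(NULL, NULL, colnames(m)))
  structure(list(params = arr, constants = constants), class = "gw_draws")
}

full_param_matrix <- function(n, values = NULL) {
  m <- matrix(0, n, 24, dimnames = list(NULL, param_names()))
  if (!is.null(values)) for (nm in names(values)) m[, nm] <- values[[nm]]
  m
}

test_that("posterior summaries collapse correctly on degenerate draws", {
  m <- full_param_matrix(50, list(gamma2 = 1, sigma_h = 2))
  s <- posterior_summary(fake_draws(m))
  g2 <- s[s$parameter == "gamma2", ]
  expect_equal(g2$median, 1); expect_equal(g2$q2.5, 1); expect_equal(g2$q97.5, 1)
  expect_equal(g2$p_positive, 1)
})

test_that("summary quantiles of standard-normal draws are near +-1.96", {
  set.seed(4)
  m <- full_param_matrix(40000)
  m[, "gamma2"] <- rnorm(40000)
  s <- posterior_summary(fake_draws(m))
  g2 <- s[s$parameter == "gamma2", ]
  expect_equal(g2$median, 0, tolerance = 0.03)
  expect_equal(g2$q2.5, -1.96, tolerance = 0.06)
  expect_equal(g2$q97.5, 1.96, tolerance = 0.06)
})

test_that("effect curves are flat at 0.5 for a null calving model", {
  m <- full_param_matrix(100)
  cur <- effect_curve(fake_draws(m), "nutrition")
  expect_true(all(abs(cur$median - 0.5) < 1e-12))
  expect_true(all(abs(cur$q2.5 - 0.5) < 1e-12))
  # degenerate posterior reproduces the deterministic logistic curve
  m2 <- full_param_matrix(100, list(gamma1 = -1, gamma3 = 1.36))
  cur2 <- effect_curve(fake_draws(m2), "length3")
  expect_equal(cur2$median, plogis(-1 + 1.36 * cur2$x), tolerance = 1e-12)
  expect_true(all(diff(cur2$median) > 0))
})

test_that("classification metrics hit the sanity ceiling on separated data", {
  skel <- list(
    md = list(N = 4, Tstudy = 3,
              k = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0), 4, 3),
              rep_el = matrix(0L, 4, 3),
              e = matrix(1L, 4, 3),
              sex_code = c(1L, 1L, 1L, 1L)),
    phicount = matrix(10, 4, 3),
    phimean = matrix(0.1, 4, 3)
  )
  skel$phimean[skel$md$k == 1] <- 0.9
  class(skel) <- "gw_draws"
  met <- classification_metrics(skel)
  expect_equal(met$sensitivity, 1)
  expect_equal(met$specificity, 1)
  expect_equal(met$auc, 1)
})

test_that("a random predictor has chance-level AUC", {
  set.seed(6)
  N <- 60; Ts <- 8
  skel <- list(
    md = list(N = N, Tstudy = Ts,
              k = matrix(rbinom(N * Ts, 1, 0.3), N, Ts),
              rep_el = matrix(0L, N, Ts),
              e = matrix(1L, N, Ts),
              sex_code = rep(1L, N)),
    phicount = matrix(10, N, Ts),
    phimean = matrix(runif(N * Ts), N, Ts)
  )
  class(skel) <- "gw_draws"
  met <- classification_metrics(skel)
  expect_gt(met$auc, 0.4); expect_lt(met$auc, 0.6)
})

test_that("missed-calving counts are bounded by the female-year count", {
  sim <- tiny_dataset(seed = 41)
  fit <- quick_fit(sim$dataset, 200, 50)
  mc <- missed_calving_count(fit)
  expect_gte(min(mc$draws), 0)
  expect_lte(max(mc$draws), fit$md$N * fit$md$Tstudy)
  expect_lte(mc$q2.5, mc$median); expect_lte(mc$median, mc$q97.5)
})

test_that("age structure tabulates and normalises", {
  ind <- tibble::tibble(
    individual_id = c("a", "b", "c"), sex = "female", known_age = TRUE,
    first_year = 2023L, min_age = c(2L, 2L, 5L), age_mean = c(2, 2, 5),
    age_sd = 0)
  ds <- list(individuals = ind, config = default_config())
  class(ds) <- "gw_dataset"
  ag <- age_structure(ds, reference_year = 2023)
  expect_equal(ag$table$n[ag$table$age == 2], 2)
  expect_equal(ag$table$n[ag$table$age == 5], 1)
  area <- sum(ag$density$y) * diff(ag$density$x[1:2])
  expect_equal(area, 1, tolerance = 1e-2)
})

test_that("recovery reports flag coverage correctly", {
  truth <- setNames(rep(0.5, 24), param_names())
  m <- full_param_matrix(200)
  for (nm in param_names()) m[, nm] <- 0.5  # centred exactly on truth
  rep1 <- recovery_report(fake_draws(m), truth)
  expect_true(all(rep1$covered))
  expect_true(all(abs(rep1$bias) < 1e-12))
  m2 <- full_param_matrix(200)
  m2[] <- 5  # truth far outside all draws
  rep2 <- recovery_report(fake_draws(m2), truth)
  expect_false(any(rep2$covered))
  agg <- aggregate_recovery(list(rep1, rep2))
  expect_equal(agg$coverage, rep(0.5, 24))
})
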
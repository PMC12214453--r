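test_that("zero-iteration runs return the initial state with finite density", {
  sim <- tiny_dataset(seed = 21)
  cfg <- sim$dataset$config
  cfg$mcmc$n_iter <- 1L; cfg$mcmc$n_burnin <- 0L
  cfg$mcmc$thin <- 1L; cfg$mcmc$n_chains <- 1L
  fit <- run_mcmc(sim$dataset, cfg)
  expect_true(all(is.finite(fit$final_logpost)))
  expect_equal(dim(fit$params)[1], 1)
})

test_that("same seed and config give identical draws", {
  sim <- tiny_dataset(seed = 22)
  f1 <- quick_fit(sim$dataset, 120, 40)
  f2 <- quick_fit(sim$dataset, 120, 40)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$missed, f2$missed)
})

test_that("the compiled joint equals the reference kernels at the chain state", {
  for (seed in c(23, 24)) {
    sim <- tiny_dataset(seed = seed)
    fit <- quick_fit(sim$dataset, 150, 50)
    for (ch in seq_along(fit$final_state)) {
      fs <- fit$final_state[[ch]]
      th <- fs$params; names(th) <- param_names()
      lat <- list(H = fs$H, S = fs$S, h = fs$h, s = fs$s, L = fs$L,
                  a0 = fs$a0, g = fs$g, c = fs$c, P = fs$P, m_cens = fs$m_cens)
      ctx <- density_context(sim$dataset, th, lat)
      expect_equal(fit$final_logpost[ch], joint_logposterior(ctx),
                   tolerance = 1e-9)
    }
  }
})

test_that("every stored state satisfies the hard reproductive constraints", {
  sim <- tiny_dataset(seed = 25, n = 25, years = 2016:2021)
  fit <- quick_fit(sim$dataset, 300, 50)
  md <- fit$md
  for (ch in seq_along(fit$c_draws)) {
    cd <- fit$c_draws[[ch]]; Pd <- fit$P_draws[[ch]]
    # pregnancy identity and exclusivity
    expect_true(all(Pd[, , -dim(Pd)[3]] == cd[, , -1]))
    expect_true(all(cd * Pd == 0))
    # two-year minimum inter-calf interval
    expect_true(all(cd[, , -1] + cd[, , -dim(cd)[3]] <= 1))
    # no calving for males or outside the female set
    males <- which(md$sex_code == 0)
    expect_true(all(cd[, males, ] == 0))
  }
  expect_true(all(is.finite(as.vector(fit$logpost))))
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(1)
  same <- cbind(rnorm(2000), rnorm(2000))
  expect_lt(split_rhat(same), 1.01)
  apart <- cbind(rnorm(2000), rnorm(2000) + 3)
  expect_gt(split_rhat(apart), 1.2)
})

test_that("ESS of an AR(1) chain matches the closed form", {
  set.seed(2)
  rho <- 0.8
  n <- 40000
  x <- as.numeric(arima.sim(list(ar = rho), n))
  expect_equal(ess_basic(matrix(x, ncol = 1)), n * (1 - rho) / (1 + rho),
               tolerance = 0.2)
})

test_that("diagnostics require at least two chains", {
  sim <- tiny_dataset(seed = 26)
  fit <- quick_fit(sim$dataset, 80, 20, n_chains = 1)
  expect_error(mcmc_diagnostics(fit), "two chains")
})

test_that("enumeration probabilities normalise and propagate clamps", {
  phi <- c(0.4, 0.3, 0.5, 0.2, 0.3)
  forced <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  en <- enumerate_reproduction_sequences(phi, forced, 0.05)
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
  expect_true(all(en$c[, 3] == 1))
  expect_true(all(en$P[, 2] == 1))
  expect_true(all(en$c[, 2] == 0))
  expect_true(all(en$c[, 4] == 0))
  expect_error(enumerate_reproduction_sequences(rep(0.5, 11)), "Metropolis fallback")
})

test_that("two-year window enumeration matches hand calculation", {
  # phi = 0.5 both years, no final pregnancy: feasible sequences are
  # (0,0), (1,0) and (0,1); weights 0.25, 0.25, 0.5 (c1 is certain to be 0
  # once the female is pregnant in year 1)
  en <- enumerate_reproduction_sequences(c(0.5, 0.5), final_pregnancy_prob = 0)
  key <- apply(en$c, 1, paste, collapse = "")
  pr <- setNames(en$prob, key)
  expect_setequal(names(pr), c("00", "10", "01"))
  expect_equal(unname(pr[c("00", "10", "01")]), c(0.25, 0.25, 0.5))
})
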
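# Scalar oracle values in this file were computed by hand / with dnorm-style
# closed forms before being frozen.

make_ctx <- function(seed = 8) truth_context(tiny_dataset(seed = seed))

test_that("nutritional kernel matches scalar evaluations", {
  sim <- tiny_dataset(seed = 8)
  ctx <- truth_context(sim)
  # overwrite one site so the conditional mean and value are known exactly:
  # H_t = 27, beta_h = 0.40, h*[t-1] = 1, h = 28, sigma_h = 1
  i <- 1; tg <- 4
  ctx$latent$H[tg] <- 27
  ctx$params$beta_h <- 0.40
  ctx$params$sigma_h <- 1
  con <- ctx$md$constants
  ctx$latent$h[i, tg - 1] <- con$h_center + con$h_scale  # h* = 1
  ctx$latent$h[i, tg] <- 28
  year <- ctx$md$grid_years[tg]
  expect_equal(nutritional_logpdf(ctx, i, year), dnorm(28, 27.4, 1, log = TRUE))
  expect_equal(nutritional_logpdf(ctx, i, year), -1.09894, tolerance = 1e-4)
  # at the mode the density is -log(sigma sqrt(2 pi))
  ctx$latent$h[i, tg] <- 27.4
  expect_equal(nutritional_logpdf(ctx, i, year), -log(sqrt(2 * pi)))
})

test_that("BAI kernel uses the convolved two-layer variance", {
  ctx <- make_ctx()
  o <- 1
  md <- ctx$md
  i <- md$bai_i[o]; tg <- md$bai_t[o]; ts <- tg - md$study_offset
  ctx$params$delta1 <- 0; ctx$params$delta2 <- 0
  ctx$params$nu_h <- sqrt(1 - md$bai_sd[o]^2)  # total SD exactly 1
  ctx$latent$h[i, tg] <- md$bai_mean[o]
  if (ts >= 1) ctx$latent$P[i, ts] <- 0L
  expect_equal(bai_logpdf(ctx, o), -0.918939, tolerance = 1e-5)
  # doubling the measurement SD strictly lowers the density at the mode
  base <- bai_logpdf(ctx, o)
  ctx$md$bai_sd[o] <- 2 * md$bai_sd[o]
  expect_lt(bai_logpdf(ctx, o), base)
  # published coefficients: d = 30 days and pregnancy shift the mean by
  # -0.016*30 + 0.63 = +0.15
  ctx2 <- make_ctx()
  ctx2$params$delta1 <- -0.016; ctx2$params$delta2 <- 0.63
  md2 <- ctx2$md
  mu_shift <- ctx2$params$delta1 * 30 + ctx2$params$delta2
  expect_equal(mu_shift, 0.15, tolerance = 1e-12)
})

test_that("stress kernel responds to sex as the published coefficient says", {
  ctx <- make_ctx()
  i <- which(ctx$latent$g == 0)[1]
  tg <- ctx$md$first_grid[i] + 1
  year <- ctx$md$grid_years[tg]
  ctx$params$beta_s3 <- 0.26
  base_mu <- ctx$latent$S[tg] +
    ctx$params$beta_s1 * whalehealth:::hstar_at(ctx, i, tg - 1) +
    ctx$params$beta_s2 * whalehealth:::astar_at(ctx, i, tg)
  lp_male <- stress_logpdf(ctx, i, year)
  ctx$latent$g[i] <- 1
  lp_female <- stress_logpdf(ctx, i, year)
  s <- ctx$latent$s[i, tg]
  expect_equal(lp_female,
               dnorm(s, base_mu + 0.26, ctx$params$sigma_s, log = TRUE))
  expect_equal(lp_male,
               dnorm(s, base_mu, ctx$params$sigma_s, log = TRUE))
})

test_that("fGC kernel exponentiates the linear predictor", {
  ctx <- make_ctx()
  o <- 1
  md <- ctx$md
  ctx$params$zeta1 <- 0.30; ctx$params$zeta2 <- 0; ctx$params$zeta3 <- 0
  ctx$params$zeta4 <- -0.003
  ctx$latent$s[md$fgc_i[o], md$fgc_t[o]] <- 3
  ctx$md$m[, o] <- c(1, 0, 0)
  ctx$md$cens[, o] <- FALSE
  ctx$md$fgc_y[o] <- 200
  # G = 3 + 0.3 - 0.6 = 2.7, mean exp(2.7) = 14.880
  expect_equal(fgc_logpdf(ctx, o),
               dnorm(md$fgc[o], exp(2.7), ctx$params$nu_s, log = TRUE))
  expect_equal(exp(2.7), 14.87973, tolerance = 1e-5)
})

test_that("residual stress is the deviation from the demographic expectation", {
  ctx <- make_ctx()
  i <- which(ctx$latent$g == 1)[1]
  tg <- ctx$md$first_grid[i] + 2
  year <- ctx$md$grid_years[tg]
  mu <- ctx$params$lambda_s +
    ctx$params$beta_s1 * whalehealth:::hstar_at(ctx, i, tg - 1) +
    ctx$params$beta_s2 * whalehealth:::astar_at(ctx, i, tg) +
    ctx$params$beta_s3
  ctx$latent$s[i, tg] <- mu
  expect_equal(residual_stress(ctx, i, year), 0)
  ctx$latent$s[i, tg] <- mu + 1
  expect_equal(residual_stress(ctx, i, year), 1)
})

test_that("calving probability follows the logistic transform", {
  ctx <- make_ctx()
  fem <- which(ctx$latent$g == 1 &
               apply(is.finite(ctx$latent$h), 1, all) &
               ctx$latent$a0 + 2 >= 8 + 2)
  i <- fem[1]
  tg <- ctx$md$first_grid[i] + 3
  year <- ctx$md$grid_years[tg]
  ctx$params$gamma2 <- 0; ctx$params$gamma3 <- 0; ctx$params$gamma4 <- 0
  ctx$params$gamma1 <- 0
  expect_equal(calving_probability(ctx, i, year), 0.5)
  # the published detection intercept: logistic(0.48) = 0.618
  ctx$params$gamma1 <- 0.48
  expect_equal(calving_probability(ctx, i, year), 0.61775, tolerance = 1e-4)
  # monotone in cubed length when gamma3 > 0
  ctx$params$gamma3 <- 1.36
  L0 <- ctx$latent$L[i, tg - 1]
  phis <- vapply(seq(9, 13, 0.5), function(L) {
    ctx$latent$L[i, tg - 1] <<- L
    calving_probability(ctx, i, year)
  }, numeric(1))
  ctx$latent$L[i, tg - 1] <- L0
  expect_true(all(diff(phis) > 0))
  # contract violations
  male <- which(ctx$latent$g == 0)[1]
  expect_error(calving_probability(ctx, male, year), "non-female")
})

test_that("calving pmf enforces the pregnancy exclusion", {
  ctx <- make_ctx()
  i <- which(ctx$latent$g == 1 & ctx$latent$a0 >= 10)[1]
  ts <- ctx$md$Tstudy
  year <- max(ctx$md$grid_years)
  ctx$latent$P[i, ts] <- 1L
  ctx$latent$c[i, ts] <- 1L
  expect_identical(calving_logpmf(ctx, i, year), -Inf)
  ctx$latent$c[i, ts] <- 0L
  expect_identical(calving_logpmf(ctx, i, year), 0)  # probability one
  ctx$latent$P[i, ts] <- 0L
  ctx$latent$c[i, ts] <- 1L
  phi <- calving_probability(ctx, i, year)
  expect_equal(calving_logpmf(ctx, i, year), log(phi))
})

test_that("calf detection respects encounter gating", {
  ctx <- make_ctx()
  i <- which(ctx$latent$g == 1 & ctx$latent$a0 >= 10)[1]
  ts <- 2; year <- ctx$md$grid_years[ts + ctx$md$study_offset]
  ctx$latent$c[i, ts] <- 1L
  ctx$md$k[i, ts] <- 0L
  ctx$md$e[i, ts] <- 0L
  expect_identical(calf_detection_logpmf(ctx, i, year), 0)  # k = 0 certain
  ctx$md$k[i, ts] <- 1L
  expect_identical(calf_detection_logpmf(ctx, i, year), -Inf)
  # encountered: p = logistic(eta1 + eta2 f*); at f* = 0 and eta1 = 0.48,
  # failure probability is log(1 - 0.618)
  ctx$md$e[i, ts] <- 1L
  ctx$md$k[i, ts] <- 0L
  ctx$md$fstar[i, ts] <- 0
  ctx$params$eta1 <- 0.48
  expect_equal(calf_detection_logpmf(ctx, i, year), log(1 - plogis(0.48)))
})

test_that("joint log-posterior is the sum of its components", {
  sim <- tiny_dataset(seed = 9, n = 12)
  ctx <- truth_context(sim)
  lp <- joint_logposterior(ctx)
  expect_true(is.finite(lp))
  expect_equal(lp, component_sum(ctx), tolerance = 1e-10)
})

test_that("impossible latent configurations give -Inf, not errors", {
  sim <- tiny_dataset(seed = 10, n = 12)
  ctx <- truth_context(sim)
  i <- which(ctx$latent$g == 1 & ctx$latent$a0 >= 10)[1]
  ctx$latent$c[i, 3] <- 1L
  ctx$latent$P[i, 3] <- 1L
  ctx$latent$P[i, 2] <- 1L
  expect_identical(joint_logposterior(ctx), -Inf)
})

test_that("finite-difference gradients of the joint match the component sums", {
  sim <- tiny_dataset(seed = 12, n = 8)
  ctx <- truth_context(sim)
  eps <- 1e-5
  for (nm in c("beta_h", "zeta1", "gamma2", "delta1")) {
    up <- ctx; up$params[[nm]] <- up$params[[nm]] + eps
    dn <- ctx; dn$params[[nm]] <- dn$params[[nm]] - eps
    g_joint <- (joint_logposterior(up) - joint_logposterior(dn)) / (2 * eps)
    # independent recomputation through the affected component family
    comp <- function(cx) {
      md <- cx$md
      out <- whalehealth:::prior_logpdf(cx$params[[nm]], cx$priors[[nm]])
      if (nm == "beta_h") {
        for (i in seq_len(md$N)) {
          for (tg in md$first_grid[i]:md$Tall) {
            out <- out + nutritional_logpdf(cx, i, md$grid_years[tg])
          }
        }
      } else if (nm == "zeta1") {
        for (o in seq_along(md$fgc)) out <- out + fgc_logpdf(cx, o)
      } else if (nm == "delta1") {
        for (o in seq_along(md$bai_mean)) out <- out + bai_logpdf(cx, o)
      } else {
        for (i in which(cx$latent$g == 1)) {
          for (ts in seq_len(md$Tstudy)) {
            tg <- ts + md$study_offset
            if (whalehealth:::mature_at(cx, i, tg) && (tg - 2) >= md$first_grid[i]) {
              out <- out + calving_logpmf(cx, i, md$grid_years[tg])
            }
          }
        }
      }
      out
    }
    g_comp <- (comp(up) - comp(dn)) / (2 * eps)
    expect_equal(g_joint, g_comp, tolerance = 1e-5)
  }
})
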
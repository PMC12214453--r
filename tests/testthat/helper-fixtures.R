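# Small scenarios and datasets used across the test files; everything is
# generated in code at test time.

tiny_scenario <- function(n = 20L, years = 2016:2019) {
  sc <- default_scenario(n_individuals = n, years = years)
  sc$n_born_during <- 2L
  sc
}

tiny_dataset <- function(seed = 1L, n = 20L, years = 2016:2019) {
  make_study_like_dataset(seed = seed, scenario = tiny_scenario(n, years))
}

# density context at the generating truth of a simulated dataset
truth_context <- function(sim, prior_only = FALSE) {
  ds <- sim$dataset
  tr <- sim$truth
  md <- whalehealth:::build_model_arrays(ds, compute_standardisation(ds))
  m_cens <- matrix(NA_real_, 3, nrow(ds$fgc))
  if (nrow(ds$fgc) > 0 && any(md$cens)) {
    mid <- ifelse(md$cens_log_uniform,
                  (md$lod_log_lo + md$lod_log_hi) / 2,
                  md$lod_log_hi - 0.5)
    m_cens[md$cens] <- mid[md$cens]
  }
  lat <- list(H = tr$H, S = tr$S, h = tr$h, s = tr$s, L = tr$Ltrue,
              a0 = tr$a0, g = tr$g, c = tr$c, P = tr$P, m_cens = m_cens)
  density_context(ds, tr$params, lat, prior_only = prior_only)
}

# independent sum over exported component kernels (used to check the joint)
component_sum <- function(ctx) {
  md <- ctx$md
  total <- 0
  for (nm in param_names()) {
    total <- total + whalehealth:::prior_logpdf(ctx$params[[nm]], ctx$priors[[nm]])
  }
  p <- ctx$params
  total <- total + sum(dnorm(ctx$latent$H, p$lambda_h, p$chi_h, log = TRUE)) +
    sum(dnorm(ctx$latent$S, p$lambda_s, p$chi_s, log = TRUE))
  for (i in seq_len(md$N)) {
    fg <- md$first_grid[i]
    if (!md$known_age[i]) {
      total <- total + dnorm(ctx$latent$a0[i], md$a0_mean[i], md$a0_sd[i], log = TRUE) -
        pnorm(md$a0_min[i], md$a0_mean[i], md$a0_sd[i], lower.tail = FALSE, log.p = TRUE)
    }
    if (md$sex_code[i] == 2) total <- total + log(0.5)
    for (tg in fg:md$Tall) {
      yr <- md$grid_years[tg]
      total <- total + nutritional_logpdf(ctx, i, yr) + stress_logpdf(ctx, i, yr)
      if (md$hasL[i, tg]) {
        total <- total + dnorm(ctx$latent$L[i, tg], md$Lm[i, tg], md$Lsd[i, tg],
                               log = TRUE)
      }
    }
    if (ctx$latent$g[i] == 1) {
      for (ts in seq_len(md$Tstudy)) {
        tg <- ts + md$study_offset
        if (whalehealth:::mature_at(ctx, i, tg) && (tg - 2) >= fg) {
          yr <- md$grid_years[tg]
          total <- total + calving_logpmf(ctx, i, yr) +
            calf_detection_logpmf(ctx, i, yr)
          if (ts == md$Tstudy) {
            q <- md$final_pregnancy_prob
            total <- total + if (ctx$latent$P[i, ts] == 1) log(q) else log1p(-q)
          }
        }
      }
    }
  }
  for (o in seq_along(md$bai_mean)) total <- total + bai_logpdf(ctx, o)
  for (o in seq_along(md$fgc)) total <- total + fgc_logpdf(ctx, o)
  for (o in seq_along(md$fgc)) {
    for (j in 1:3) {
      if (md$cens[j, o]) {
        total <- total + if (md$cens_log_uniform[j, o]) {
          -log(md$lod_log_hi[j, o] - md$lod_log_lo[j, o])
        } else {
          ctx$latent$m_cens[j, o] - md$lod_log_hi[j, o]
        }
      }
    }
  }
  total
}

# short-chain fit for structural tests
quick_fit <- function(ds, n_iter = 400L, n_burnin = 100L, n_chains = 2L,
                      prior_only = FALSE) {
  cfg <- ds$config
  cfg$mcmc$n_iter <- as.integer(n_iter)
  cfg$mcmc$n_burnin <- as.integer(n_burnin)
  cfg$mcmc$thin <- 1L
  cfg$mcmc$n_chains <- as.integer(n_chains)
  cfg$mcmc$prior_only <- prior_only
  run_mcmc(ds, cfg)
}
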
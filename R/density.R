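#' Construct a density-evaluation context
#'
#' Bundles dataset arrays, a latent-state configuration, parameter values,
#' standardisation constants and priors into the context object consumed by
#' the log-density kernels and [joint_logposterior()].
#'
#' @param ds A `gw_dataset`.
#' @param params Named numeric vector over [param_names()].
#' @param latent Latent state list with components `H`, `S` (length `Tall`),
#'   `h`, `s`, `L` (`N x Tall` matrices, `NA` before an individual's entry),
#'   `g` (0/1 sex indicator, female = 1), `a0` (age in the first modelled grid
#'   year), `c`, `P` (`N x Tstudy` 0/1 matrices) and `m_cens` (3 x n-faecal
#'   matrix of imputed log concentrations for below-LOD hormones, `NA` where
#'   observed).
#' @param constants Output of [compute_standardisation()].
#' @param prior_only If `TRUE`, all observation likelihood terms are dropped
#'   (process model and priors only).
#' @return Object of class `gw_ctx`.
#' @export
density_context <- function(ds, params, latent,
                            constants = compute_standardisation(ds),
                            prior_only = FALSE) {
  md <- build_model_arrays(ds, constants)
  stopifnot(all(param_names() %in% names(params)))
  structure(list(md = md, params = as.list(params[param_names()]),
                 latent = latent, priors = ds$config$priors,
                 prior_only = isTRUE(prior_only)),
            class = "gw_ctx")
}

# ---- index helpers -------------------------------------------------------

resolve_i <- function(ctx, i) {
  if (is.character(i)) i <- match(i, ctx$md$ids)
  if (is.na(i) || i < 1 || i > ctx$md$N) stop("Unknown individual index")
  as.integer(i)
}

# calendar year -> latent grid index
resolve_t <- function(ctx, i, year) {
  tg <- match(year, ctx$md$grid_years)
  if (is.na(tg)) stop("Year ", year, " outside the latent grid")
  if (tg < ctx$md$first_grid[i]) stop("Year precedes individual's first modelled year")
  tg
}

# calendar year -> study-year index (1..Tstudy)
study_index <- function(ctx, year) {
  ts <- match(year, ctx$md$grid_years) - ctx$md$study_offset
  if (is.na(ts) || ts < 1) stop("Year ", year, " is not a study year")
  ts
}

hstar_at <- function(ctx, i, tg) {
  (ctx$latent$h[i, tg] - ctx$md$constants$h_center) / ctx$md$constants$h_scale
}

age_at <- function(ctx, i, tg) ctx$latent$a0[i] + (tg - ctx$md$first_grid[i])

astar_at <- function(ctx, i, tg) {
  (age_at(ctx, i, tg) - ctx$md$constants$a_center) / ctx$md$constants$a_scale
}

L3star_at <- function(ctx, i, tg) {
  (ctx$latent$L[i, tg]^3 - ctx$md$constants$L3_center) / ctx$md$constants$L3_scale
}

mature_at <- function(ctx, i, tg) age_at(ctx, i, tg) >= ctx$md$maturity_age

# effective log hormone covariates for faecal sample o (imputed where censored)
m_effective <- function(ctx, o) {
  m <- ctx$md$m[, o]
  cens <- ctx$md$cens[, o]
  if (any(cens)) m[cens] <- ctx$latent$m_cens[cens, o]
  m
}

# ---- component kernels ---------------------------------------------------

#' Nutritional-state transition log-density
#'
#' Log-density of the latent nutritional state `h[i, t]`: Normal around the
#' yearly population effect `H_t` plus the autoregressive term
#' `beta_h * h*[i, t-1]` (dropped at the individual's first modelled step),
#' with process SD `sigma_h`.
#'
#' @param ctx A `gw_ctx` from [density_context()].
#' @param i Individual index or id.
#' @param year Calendar year on the latent grid (study or pre-study lag year).
#' @return Scalar log-density.
#' @export
nutritional_logpdf <- function(ctx, i, year) {
  i <- resolve_i(ctx, i); tg <- resolve_t(ctx, i, year)
  p <- ctx$params
  mu <- ctx$latent$H[tg] +
    if (tg > ctx$md$first_grid[i]) p$beta_h * hstar_at(ctx, i, tg - 1) else 0
  stats::dnorm(ctx$latent$h[i, tg], mu, p$sigma_h, log = TRUE)
}

#' Stress-state log-density
#'
#' Log-density of the latent stress state `s[i, t]`: Normal around the yearly
#' effect `S_t` plus effects of lagged standardised nutritional state,
#' standardised age and sex; no autoregressive term. The lagged nutritional
#' term is dropped at the individual's first modelled step.
#'
#' @inheritParams nutritional_logpdf
#' @return Scalar log-density.
#' @export
stress_logpdf <- function(ctx, i, year) {
  i <- resolve_i(ctx, i); tg <- resolve_t(ctx, i, year)
  p <- ctx$params
  mu <- ctx$latent$S[tg] +
    (if (tg > ctx$md$first_grid[i]) p$beta_s1 * hstar_at(ctx, i, tg - 1) else 0) +
    p$beta_s2 * astar_at(ctx, i, tg) + p$beta_s3 * ctx$latent$g[i]
  stats::dnorm(ctx$latent$s[i, tg], mu, p$sigma_s, log = TRUE)
}

#' BAI observation log-density
#'
#' Marginal (convolved) form of the two-layer BAI model: the latent expected
#' BAI is Normal around `h + delta1 * d + delta2 * P` with SD `nu_h`, and the
#' photogrammetric posterior mean is Normal around that with its measurement
#' SD, so the observed mean is
#' `Normal(h + delta1 d + delta2 P, sqrt(nu_h^2 + bai_sd^2))`.
#'
#' @param ctx A `gw_ctx`.
#' @param o Row index into the BAI table.
#' @return Scalar log-density.
#' @export
bai_logpdf <- function(ctx, o) {
  md <- ctx$md; p <- ctx$params
  i <- md$bai_i[o]; tg <- md$bai_t[o]
  ts <- tg - md$study_offset
  P <- if (ts >= 1) ctx$latent$P[i, ts] else 0
  mu <- ctx$latent$h[i, tg] + p$delta1 * md$bai_d[o] + p$delta2 * P
  stats::dnorm(md$bai_mean[o], mu, sqrt(p$nu_h^2 + md$bai_sd[o]^2), log = TRUE)
}

#' Faecal glucocorticoid observation log-density
#'
#' The expected log concentration `G = s + zeta1 m1 + zeta2 m2 + zeta3 m3 +
#' zeta4 y` is exponentiated and acts as the mean of a Normal on the natural
#' concentration scale with SD `nu_s`. Below-LOD hormone covariates use their
#' current imputed values.
#'
#' @param ctx A `gw_ctx`.
#' @param o Row index into the faecal table.
#' @return Scalar log-density.
#' @export
fgc_logpdf <- function(ctx, o) {
  md <- ctx$md; p <- ctx$params
  if (p$nu_s <= 0) stop("nu_s must be positive")
  m <- m_effective(ctx, o)
  G <- ctx$latent$s[md$fgc_i[o], md$fgc_t[o]] +
    p$zeta1 * m[1] + p$zeta2 * m[2] + p$zeta3 * m[3] + p$zeta4 * md$fgc_y[o]
  stats::dnorm(md$fgc[o], exp(G), p$nu_s, log = TRUE)
}

#' Residual stress state
#'
#' Deviation of the stress state from its demographic-class expectation:
#' `r = s - (lambda_s + beta_s1 h*[t-1] + beta_s2 a* + beta_s3 g)`. The
#' population mean `lambda_s` (not the yearly effect `S_t`) is subtracted, so
#' yearly deviations remain part of the residual; setting the config switch
#' `residual_uses_lambda_s = FALSE` subtracts `S_t` instead.
#'
#' @inheritParams nutritional_logpdf
#' @return Scalar residual.
#' @export
residual_stress <- function(ctx, i, year) {
  i <- resolve_i(ctx, i); tg <- resolve_t(ctx, i, year)
  p <- ctx$params
  base <- if (ctx$md$residual_uses_lambda_s) p$lambda_s else ctx$latent$S[tg]
  ctx$latent$s[i, tg] - (base +
    (if (tg > ctx$md$first_grid[i]) p$beta_s1 * hstar_at(ctx, i, tg - 1) else 0) +
    p$beta_s2 * astar_at(ctx, i, tg) + p$beta_s3 * ctx$latent$g[i])
}

#' Calving probability
#'
#' `phi = logistic(gamma1 + gamma2 h*[t-1] + gamma3 L3*[t-1] + gamma4 r[t-2])`
#' for a sexually mature female.
#'
#' @inheritParams nutritional_logpdf
#' @return Probability in (0, 1).
#' @export
calving_probability <- function(ctx, i, year) {
  i <- resolve_i(ctx, i)
  tg <- resolve_t(ctx, i, year)
  if (ctx$latent$g[i] != 1) stop("Calving probability requested for a non-female")
  if (!mature_at(ctx, i, tg)) stop("Calving probability requested for an immature female")
  if (tg - 2 < ctx$md$first_grid[i]) stop("Lagged covariates unavailable at this step")
  p <- ctx$params
  lin <- p$gamma1 + p$gamma2 * hstar_at(ctx, i, tg - 1) +
    p$gamma3 * L3star_at(ctx, i, tg - 1) +
    p$gamma4 * residual_stress(ctx, i, ctx$md$grid_years[tg - 2])
  stats::plogis(lin)
}

#' Calving indicator log-probability
#'
#' `log Bernoulli(c; phi * (1 - P))`: a pregnant female cannot calve, so
#' `c = 1` with `P = 1` yields `-Inf`.
#'
#' @inheritParams nutritional_logpdf
#' @return Scalar log-probability.
#' @export
calving_logpmf <- function(ctx, i, year) {
  i <- resolve_i(ctx, i)
  ts <- study_index(ctx, year)
  cc <- ctx$latent$c[i, ts]; P <- ctx$latent$P[i, ts]
  phi <- calving_probability(ctx, i, year)
  pr <- phi * (1 - P)
  if (cc == 1) log(pr) else log1p(-pr)
}

#' Calf-detection log-probability
#'
#' `logit p = eta1 + eta2 f*`; `k ~ Bernoulli(c * p * e)`. A calf can only be
#' seen when the female calved and was encountered; `k = 1` with `c * e = 0`
#' yields `-Inf`. A calf reported by another group pins `c = 1` while `k` may
#' remain 0.
#'
#' @inheritParams nutritional_logpdf
#' @return Scalar log-probability.
#' @export
calf_detection_logpmf <- function(ctx, i, year) {
  i <- resolve_i(ctx, i)
  ts <- study_index(ctx, year)
  md <- ctx$md; p <- ctx$params
  cc <- ctx$latent$c[i, ts]
  pd <- stats::plogis(p$eta1 + p$eta2 * md$fstar[i, ts])
  pk <- cc * pd * md$e[i, ts]
  if (md$k[i, ts] == 1) log(pk) else log1p(-pk)
}

# ---- joint log-posterior -------------------------------------------------

# reproduction + detection block for one female (vector over study years),
# including the final-step pregnancy prior; -Inf on any support violation
female_repro_logdens <- function(ctx, i) {
  md <- ctx$md; lat <- ctx$latent
  Ts <- md$Tstudy
  cc <- lat$c[i, ]; P <- lat$P[i, ]
  # pregnancy identity P[t] = c[t+1]
  if (Ts > 1 && any(P[-Ts] != cc[-1])) return(-Inf)
  # an externally reported calf clamps c = 1 (an observation; dropped in
  # prior-only mode together with the rest of the likelihood)
  if (!ctx$prior_only && any(md$rep_el[i, ] == 1 & cc == 0)) return(-Inf)
  out <- 0
  mature_last <- FALSE
  for (ts in seq_len(Ts)) {
    tg <- ts + md$study_offset
    year <- md$grid_years[tg]
    modelled <- mature_at(ctx, i, tg) && (tg - 2) >= md$first_grid[i]
    if (!modelled) {
      if (cc[ts] != 0) return(-Inf)  # no calving before maturity
      next
    }
    out <- out + calving_logpmf(ctx, i, year)  # process term, kept in prior-only mode
    if (!ctx$prior_only) out <- out + calf_detection_logpmf(ctx, i, year)
    if (ts == Ts) mature_last <- TRUE
  }
  if (mature_last) {
    q <- md$final_pregnancy_prob
    out <- out + if (P[Ts] == 1) log(q) else log1p(-q)
  } else if (P[Ts] != 0) {
    return(-Inf)
  }
  out
}

#' Joint log-posterior
#'
#' Sum of every component log-density over all individuals, years and
#' observations, plus parameter priors and imputation densities (sex
#' Bernoulli(0.5) for unknown-sex individuals, uniform below-LOD hormone
#' imputation, truncated-Normal age priors, Normal length priors, and the
#' final-step pregnancy Bernoulli). Any support violation (calving while
#' pregnant, calf seen without encounter, age below the minimum, broken
#' pregnancy identity) yields `-Inf`.
#'
#' @param ctx A `gw_ctx`.
#' @return Scalar log-posterior (unnormalised).
#' @export
joint_logposterior <- function(ctx) {
  md <- ctx$md; p <- ctx$params; lat <- ctx$latent
  for (sdp in sd_param_names()) if (p[[sdp]] <= 0) return(-Inf)

  lp <- 0
  # parameter priors
  for (nm in param_names()) {
    lp <- lp + prior_logpdf(p[[nm]], ctx$priors[[nm]])
  }
  # yearly population effects
  lp <- lp + sum(stats::dnorm(lat$H, p$lambda_h, p$chi_h, log = TRUE))
  lp <- lp + sum(stats::dnorm(lat$S, p$lambda_s, p$chi_s, log = TRUE))

  for (i in seq_len(md$N)) {
    fg <- md$first_grid[i]
    # age prior (truncated at the minimum age) and sex imputation
    if (!md$known_age[i]) {
      if (lat$a0[i] < md$a0_min[i]) return(-Inf)
      lp <- lp + stats::dnorm(lat$a0[i], md$a0_mean[i], md$a0_sd[i], log = TRUE) -
        stats::pnorm(md$a0_min[i], md$a0_mean[i], md$a0_sd[i],
                     lower.tail = FALSE, log.p = TRUE)
    }
    if (md$sex_code[i] == 2) lp <- lp + log(0.5)
    for (tg in fg:md$Tall) {
      year <- md$grid_years[tg]
      lp <- lp + nutritional_logpdf(ctx, i, year) + stress_logpdf(ctx, i, year)
      if (md$hasL[i, tg]) {
        lp <- lp + stats::dnorm(lat$L[i, tg], md$Lm[i, tg], md$Lsd[i, tg], log = TRUE)
      }
    }
    if (lat$g[i] == 1) {
      lp <- lp + female_repro_logdens(ctx, i)
    } else {
      if (any(lat$c[i, ] != 0) || any(lat$P[i, ] != 0)) return(-Inf)
      if (!ctx$prior_only &&
          (any(md$k[i, ] == 1) || any(md$rep_el[i, ] == 1))) return(-Inf)
    }
    if (!is.finite(lp)) return(-Inf)
  }

  # observation models
  if (!ctx$prior_only) {
    for (o in seq_along(md$bai_mean)) lp <- lp + bai_logpdf(ctx, o)
    for (o in seq_along(md$fgc)) lp <- lp + fgc_logpdf(ctx, o)
  }
  # imputation priors for censored hormone covariates, as densities of the
  # latent log concentration m: uniform-in-concentration below the LOD
  # (density exp(m - log LOD)) for assay censoring, uniform-in-log between
  # the bounds for hormones that were not measured at all
  if (length(md$fgc) > 0) {
    for (o in seq_along(md$fgc)) {
      for (j in 1:3) {
        if (md$cens[j, o]) {
          mv <- lat$m_cens[j, o]
          hi <- md$lod_log_hi[j, o]
          if (!is.finite(mv) || mv > hi) return(-Inf)
          if (md$cens_log_uniform[j, o]) {
            lo <- md$lod_log_lo[j, o]
            if (mv < lo) return(-Inf)
            lp <- lp - log(hi - lo)
          } else {
            lp <- lp + mv - hi
          }
        }
      }
    }
  }
  lp
}
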
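#' @useDynLib whalehealth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# initial latent configuration: nutritional states at observed BAI means
# (population mean where unobserved), stress states at log mean fGC,
# calving/pregnancy from the observed calves, ages at their prior means
# (pushed up where an observed calf requires maturity), lengths at their
# prior means, unknown sexes initialised male.
init_latent <- function(md, jitter = 0) {
  N <- md$N; Tall <- md$Tall; Ts <- md$Tstudy
  h <- matrix(NA_real_, N, Tall)
  hobs <- matrix(NA_real_, N, Tall)
  for (o in seq_along(md$bai_mean)) {
    i <- md$bai_i[o]; t <- md$bai_t[o]
    hobs[i, t] <- if (is.na(hobs[i, t])) md$bai_mean[o] else (hobs[i, t] + md$bai_mean[o]) / 2
  }
  year_mean <- apply(hobs, 2, function(x) mean(x, na.rm = TRUE))
  overall <- mean(md$bai_mean)
  year_mean[!is.finite(year_mean)] <- overall
  s <- matrix(NA_real_, N, Tall)
  sobs <- matrix(NA_real_, N, Tall)
  for (o in seq_along(md$fgc)) {
    i <- md$fgc_i[o]; t <- md$fgc_t[o]
    v <- log(max(md$fgc[o], 1))
    sobs[i, t] <- if (is.na(sobs[i, t])) v else (sobs[i, t] + v) / 2
  }
  s_overall <- if (length(md$fgc) > 0) mean(log(pmax(md$fgc, 1))) else 0
  syear <- apply(sobs, 2, function(x) mean(x, na.rm = TRUE))
  syear[!is.finite(syear)] <- s_overall

  cmat <- Pmat <- matrix(0L, N, Ts)
  a0 <- md$a0_mean
  g <- as.integer(md$sex_code == 1)
  for (i in seq_len(N)) {
    fg <- md$first_grid[i]
    for (t in fg:Tall) {
      h[i, t] <- (if (is.na(hobs[i, t])) year_mean[t] else hobs[i, t]) +
        stats::rnorm(1, 0, jitter)
      s[i, t] <- (if (is.na(sobs[i, t])) syear[t] else sobs[i, t]) +
        stats::rnorm(1, 0, jitter / 4)
    }
    forced <- which(md$k[i, ] == 1 | md$rep_el[i, ] == 1)
    if (length(forced) > 0) {
      cmat[i, forced] <- 1L
      # maturity required at every forced year
      need <- max(md$maturity_age - (forced + md$study_offset - fg))
      if (!md$known_age[i]) a0[i] <- max(a0[i], need + 0.5)
    }
    if (Ts > 1) Pmat[i, 1:(Ts - 1)] <- cmat[i, 2:Ts]
  }
  L <- md$Lm
  m_cens <- matrix(NA_real_, 3, length(md$fgc))
  if (length(md$fgc) > 0 && any(md$cens)) {
    mid <- ifelse(md$cens_log_uniform,
                  (md$lod_log_lo + md$lod_log_hi) / 2,
                  md$lod_log_hi - 0.5)
    m_cens[md$cens] <- mid[md$cens]
  }
  list(H = year_mean + stats::rnorm(Tall, 0, jitter / 2),
       S = syear + stats::rnorm(Tall, 0, jitter / 4),
       h = h, s = s, L = L, a0 = a0, g = g, c = cmat, P = Pmat,
       m_cens = m_cens)
}

init_params <- function(md, priors, lat) {
  th <- vapply(param_names(), function(nm) prior_mean(priors[[nm]]), numeric(1))
  th[c("beta_h", "beta_s1", "beta_s2", "beta_s3",
       "delta1", "delta2", "zeta1", "zeta2", "zeta3", "zeta4",
       "gamma1", "gamma2", "gamma3", "gamma4", "eta1", "eta2")] <- 0
  th["lambda_h"] <- mean(lat$H)
  th["lambda_s"] <- mean(lat$S)
  th["chi_h"] <- 0.5; th["sigma_h"] <- 1; th["nu_h"] <- 1
  th["chi_s"] <- 0.3; th["sigma_s"] <- 0.5
  th["nu_s"] <- if (length(md$fgc) > 1) max(1, stats::sd(md$fgc)) else 1
  th
}

#' Fit the state-space model by Metropolis-within-Gibbs MCMC
#'
#' Runs the full update sweep (adaptive random-walk Metropolis for the 24
#' top-level parameters; conjugate Gibbs draws for the yearly effects;
#' single-site Metropolis for the latent nutritional and stress states;
#' Metropolis within their priors for uncertain lengths and ages; exact
#' full-conditional draws for unknown sexes and below-LOD hormone values; and
#' joint draws of each female's calving/pregnancy sequence from the exact
#' conditional over all constraint-feasible binary sequences). Proposal
#' scales adapt during burn-in only (targeting ~0.44 acceptance) and are
#' frozen afterwards, preserving the stationary distribution.
#'
#' @param ds A `gw_dataset`.
#' @param config Configuration list (see [default_config()]); the `mcmc`
#'   block controls chains, iterations, burn-in, thinning and the
#'   `prior_only` switch (which drops every observation likelihood term,
#'   leaving process priors only).
#' @param constants Optional frozen standardisation constants; recomputed
#'   from the data by default.
#' @return Object of class `gw_draws`: `params` (iteration x chain x
#'   parameter array), `logpost`, `missed` (per-draw count of calving events
#'   with no calf observation and no external report), `c_draws` / `P_draws`
#'   (per-draw latent calving/pregnancy indicators), posterior-mean latent
#'   trajectories, acceptance rates, and the frozen constants/config.
#' @export
run_mcmc <- function(ds, config = ds$config, constants = NULL) {
  if (is.null(constants)) constants <- compute_standardisation(ds)
  md <- build_model_arrays(ds, constants)
  mc <- config$mcmc
  stopifnot(mc$n_burnin < mc$n_iter)
  priors <- config$priors
  prior_spec <- list(
    mean = vapply(param_names(), function(nm) {
      if (priors[[nm]]$dist == "halfnormal") 0 else priors[[nm]]$mean
    }, numeric(1)),
    sd = vapply(param_names(), function(nm) priors[[nm]]$sd, numeric(1)),
    halfnormal = vapply(param_names(), function(nm) {
      as.integer(priors[[nm]]$dist == "halfnormal")
    }, integer(1))
  )
  md$prior_only <- isTRUE(mc$prior_only)

  chains <- vector("list", mc$n_chains)
  for (ch in seq_len(mc$n_chains)) {
    set.seed(stage_seed(config$seed, ch))
    lat <- init_latent(md, jitter = if (ch == 1) 0 else 0.5)
    th <- init_params(md, priors, lat)
    if (ch == 1) {
      ctx <- structure(list(md = md, params = as.list(th), latent = lat,
                            priors = priors, prior_only = isTRUE(mc$prior_only)),
                       class = "gw_ctx")
      lp0 <- joint_logposterior(ctx)
      if (!is.finite(lp0)) {
        stop("Non-finite initial log-posterior; offending component: ",
             diagnose_nonfinite(ctx))
      }
    }
    chains[[ch]] <- run_sampler_cpp(md, lat, th, prior_spec,
                                    c(mc, list(prior_only = isTRUE(mc$prior_only))))
  }
  nsave <- nrow(chains[[1]]$draws)
  params <- array(NA_real_, c(nsave, mc$n_chains, length(param_names())),
                  dimnames = list(NULL, NULL, param_names()))
  for (ch in seq_len(mc$n_chains)) params[, ch, ] <- chains[[ch]]$draws
  structure(list(
    params = params,
    logpost = vapply(chains, function(x) as.numeric(x$logpost), numeric(nsave)),
    missed = vapply(chains, function(x) as.integer(x$missed), integer(nsave)),
    c_draws = lapply(chains, `[[`, "c_draws"),
    P_draws = lapply(chains, `[[`, "P_draws"),
    phimean = Reduce(`+`, lapply(chains, `[[`, "phimean")) / mc$n_chains,
    phicount = Reduce(`+`, lapply(chains, `[[`, "phicount")),
    hmean = Reduce(`+`, lapply(chains, `[[`, "hmean")) / mc$n_chains,
    smean = Reduce(`+`, lapply(chains, `[[`, "smean")) / mc$n_chains,
    a0mean = Reduce(`+`, lapply(chains, `[[`, "a0mean")) / mc$n_chains,
    gmean = Reduce(`+`, lapply(chains, `[[`, "gmean")) / mc$n_chains,
    accept = lapply(chains, `[[`, "accept"),
    final_state = lapply(chains, `[[`, "final_state"),
    final_logpost = vapply(chains, `[[`, numeric(1), "final_logpost"),
    constants = constants, config = config, md = md
  ), class = "gw_draws")
}

# name the first non-finite component of the joint for initialisation errors
diagnose_nonfinite <- function(ctx) {
  md <- ctx$md
  parts <- c(
    priors = sum(vapply(param_names(), function(nm) {
      prior_logpdf(ctx$params[[nm]], ctx$priors[[nm]])
    }, numeric(1))),
    bai = if (length(md$bai_mean) > 0) {
      sum(vapply(seq_along(md$bai_mean), function(o) bai_logpdf(ctx, o), numeric(1)))
    } else 0,
    fgc = if (length(md$fgc) > 0) {
      sum(vapply(seq_along(md$fgc), function(o) fgc_logpdf(ctx, o), numeric(1)))
    } else 0
  )
  bad <- names(parts)[!is.finite(parts)]
  if (length(bad) == 0) bad <- "latent process or reproduction block"
  paste(bad, collapse = ", ")
}

#' @export
print.gw_draws <- function(x, ...) {
  d <- dim(x$params)
  cat("<gw_draws>", d[1], "stored draws x", d[2], "chains x", d[3], "parameters\n")
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param x A `gw_draws` object.
#' @param ... Unused.
#' @return Matrix (draws * chains) x parameters.
#' @export
as.matrix.gw_draws <- function(x, ...) {
  d <- dim(x$params)
  out <- matrix(NA_real_, d[1] * d[2], d[3], dimnames = list(NULL, dimnames(x$params)[[3]]))
  for (p in seq_len(d[3])) out[, p] <- as.vector(x$params[, , p])
  out
}

#' Split-\eqn{\hat{R}} convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (rank-free version of the standard split statistic).
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar \eqn{\hat{R}}.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(ch) {
    cbind(x[seq_len(n), ch], x[n + seq_len(n), ch])
  }))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Sums, over chains, the initial-positive-sequence autocorrelation estimate
#' `n / (1 + 2 sum(rho_t))`.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar effective sample size.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  per_chain <- vapply(seq_len(ncol(x)), function(ch) {
    v <- x[, ch]
    n <- length(v)
    if (stats::sd(v) == 0) return(1)
    rho <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    csum <- 0
    for (t in seq_along(rho)) {
      if (rho[t] < 0) break
      csum <- csum + rho[t]
    }
    n / (1 + 2 * csum)
  }, numeric(1))
  sum(per_chain)
}

#' Convergence diagnostics report
#'
#' Split-\eqn{\hat{R}} and effective sample size for every top-level
#' parameter, with pass/fail flags against the configured thresholds.
#'
#' @param draws A `gw_draws` object (at least two chains).
#' @return A tibble with one row per parameter and an attribute `pass`
#'   (overall logical).
#' @export
mcmc_diagnostics <- function(draws) {
  d <- dim(draws$params)
  if (d[2] < 2) stop("Diagnostics require at least two chains")
  mc <- draws$config$mcmc
  out <- tibble::tibble(
    parameter = dimnames(draws$params)[[3]],
    rhat = vapply(seq_len(d[3]), function(p) split_rhat(draws$params[, , p]), numeric(1)),
    ess = vapply(seq_len(d[3]), function(p) ess_basic(draws$params[, , p]), numeric(1))
  )
  out$ok <- out$rhat < mc$rhat_limit & out$ess > mc$min_ess
  attr(out, "pass") <- all(out$ok)
  out
}
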
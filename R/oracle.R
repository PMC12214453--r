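# Brute-force marginal-likelihood oracle for small instances.
#
# Independent of the density kernels and the sampler: the integrals below are
# written directly from the model's mathematical definition, so agreement with
# the sampler-based estimate is a genuine two-route check.

# enumerate feasible (c, P_T) structures without weights
enumerate_structures <- function(modelled, forced, final_preg) {
  W <- length(modelled)
  if (any(forced & !modelled)) stop("Clamped calving outside the modelled window")
  seqs <- matrix(0L, 1, 0)
  for (t in seq_len(W)) {
    cand <- if (!modelled[t]) 0L else if (forced[t]) 1L else c(0L, 1L)
    grown <- do.call(rbind, lapply(cand, function(v) cbind(seqs, v)))
    if (t > 1) grown <- grown[!(grown[, t - 1] == 1 & grown[, t] == 1), , drop = FALSE]
    seqs <- grown
  }
  out <- list()
  for (r in seq_len(nrow(seqs))) {
    cc <- unname(seqs[r, ])
    pTs <- if (modelled[W] && cc[W] == 0 && final_preg > 0) c(0L, 1L) else 0L
    for (pT in pTs) out[[length(out) + 1]] <- list(c = cc, pT = pT)
  }
  out
}

#' Brute-force marginal likelihood on a tiny instance
#'
#' Computes the marginal likelihood of all observations for a small dataset
#' (at most 4 individuals x 4 study years) by trapezoid quadrature over the
#' latent nutritional and stress states and exact enumeration of the feasible
#' calving/pregnancy sequences, conditioning on the yearly effects `H`, `S`,
#' on lengths at their prior means, on known ages and on known sexes. The
#' nutritional chain is integrated by a forward pass over pairs of adjacent
#' grid values (the calving factor at year `t` couples `h[t-1]`, `h[t-3]` and
#' `s[t-2]`, so the pass carries pair states); each stress state appears in a
#' single one-dimensional integral given the neighbouring nutritional values.
#'
#' @param ds A `gw_dataset` (every individual must have known sex and age).
#' @param params Named parameter vector.
#' @param H,S Yearly effect vectors over the latent grid (conditioned on).
#' @param Gh,Gs Number of quadrature nodes for the nutritional and stress grids.
#' @param range_sd Half-width of the quadrature range in process-SD units.
#' @return Log marginal likelihood (scalar).
#' @export
brute_force_marginal <- function(ds, params, H, S, Gh = 121, Gs = 101,
                                 range_sd = 9) {
  con <- compute_standardisation(ds)
  md <- build_model_arrays(ds, con)
  if (md$N > 4 || md$Tstudy > 4) stop("Oracle restricted to <= 4 individuals x 4 years")
  if (any(md$sex_code == 2) || any(!md$known_age)) {
    stop("Oracle requires known sexes and ages")
  }
  p <- as.list(params[param_names()])
  Tall <- md$Tall
  hg <- seq(min(H) - range_sd * p$sigma_h, max(H) + range_sd * p$sigma_h,
            length.out = Gh)
  wh <- hg[2] - hg[1]
  hstar_g <- (hg - con$h_center) / con$h_scale

  total <- 0
  for (i in seq_len(md$N)) {
    fg <- md$first_grid[i]
    g <- as.numeric(md$sex_code[i] == 1)
    a_at <- function(t) md$a0_mean[i] + (t - fg)
    astar <- function(t) (a_at(t) - con$a_center) / con$a_scale
    L3star <- function(t) (md$Lm[i, t]^3 - con$L3_center) / con$L3_scale

    # modelled calving years (study indices) and clamps
    Ts <- md$Tstudy
    modelled <- vapply(seq_len(Ts), function(ts) {
      tg <- ts + md$study_offset
      g == 1 && a_at(tg) >= md$maturity_age && (tg - 2) >= fg
    }, logical(1))
    forced <- md$k[i, ] == 1 | md$rep_el[i, ] == 1
    structs <- enumerate_structures(modelled, forced, md$final_pregnancy_prob)

    # per-year BAI emission on the h grid, for both pregnancy states
    E <- array(1, c(Gh, Tall, 2))
    for (o in which(md$bai_i == i)) {
      t <- md$bai_t[o]
      for (Pv in 0:1) {
        mu <- hg + p$delta1 * md$bai_d[o] + p$delta2 * Pv
        E[, t, Pv + 1] <- E[, t, Pv + 1] *
          stats::dnorm(md$bai_mean[o], mu, sqrt(p$nu_h^2 + md$bai_sd[o]^2))
      }
    }
    fgc_at <- function(t) which(md$fgc_i == i & md$fgc_t == t)

    marg_i <- 0
    for (stc in structs) {
      cc <- stc$c
      P <- c(if (Ts > 1) cc[-1] else integer(0), stc$pT)
      Pfull <- integer(Tall)
      Pfull[seq_len(Ts) + md$study_offset] <- P
      cP_at <- function(t) {  # calving indicator/pregnancy at grid year t
        ts <- t - md$study_offset
        if (ts >= 1 && ts <= Ts) c(cc[ts], P[ts]) else c(0L, 0L)
      }
      # detection and final-pregnancy constants
      logconst <- 0
      for (ts in which(modelled)) {
        pd <- stats::plogis(p$eta1 + p$eta2 * md$fstar[i, ts]) * md$e[i, ts]
        pk <- cc[ts] * pd
        logconst <- logconst + if (md$k[i, ts] == 1) log(pk) else log1p(-pk)
      }
      if (modelled[Ts]) {
        q <- md$final_pregnancy_prob
        logconst <- logconst + if (stc$pT == 1) log(q) else log1p(-q)
      }
      if (!is.finite(logconst)) next

      # s-integral factor A_t(h_{t-1}, h_{t+1}); constant in absent arguments
      Afun <- function(t) {
        mu0 <- S[t] + p$beta_s2 * astar(t) + p$beta_s3 * g
        first <- (t == fg)
        # s grid wide enough for all conditional means
        mu_rng <- if (first) c(mu0, mu0) else mu0 + range(p$beta_s1 * hstar_g)
        sg <- seq(mu_rng[1] - range_sd * p$sigma_s, mu_rng[2] + range_sd * p$sigma_s,
                  length.out = Gs)
        ws <- sg[2] - sg[1]
        fobs <- rep(1, Gs)
        for (o in fgc_at(t)) {
          m <- md$m[, o]
          G <- sg + p$zeta1 * m[1] + p$zeta2 * m[2] + p$zeta3 * m[3] +
            p$zeta4 * md$fgc_y[o]
          fobs <- fobs * stats::dnorm(md$fgc[o], exp(G), p$nu_s)
        }
        # calving factor at grid year t + 2 (uses h*[t+1], L3*[t+1], r_t)
        tcal <- t + 2
        tscal <- tcal - md$study_offset
        has_cal <- tscal >= 1 && tscal <= Ts && modelled[tscal]
        A <- matrix(0, Gh, Gh)  # rows: h_{t-1}; cols: h_{t+1}
        for (l in seq_len(Gh)) {
          lag <- if (first) 0 else p$beta_s1 * hstar_g[l]
          dens <- stats::dnorm(sg, mu0 + lag, p$sigma_s) * fobs
          if (!has_cal) {
            A[l, ] <- sum(dens) * ws
          } else {
            r <- sg - (p$lambda_s + lag + p$beta_s2 * astar(t) + p$beta_s3 * g)
            cP <- cP_at(tcal)
            for (j in seq_len(Gh)) {
              lin <- p$gamma1 + p$gamma2 * hstar_g[j] + p$gamma3 * L3star(tcal - 1) +
                p$gamma4 * r
              phi <- stats::plogis(lin)
              pr <- phi * (1 - cP[2])
              fac <- if (cP[1] == 1) pr else 1 - pr
              A[l, j] <- sum(dens * fac) * ws
            }
          }
          if (first) {  # no dependence on h_{t-1}
            A <- matrix(A[l, ], Gh, Gh, byrow = TRUE)
            break
          }
        }
        A
      }

      Evec <- function(t) E[, t, Pfull[t] + 1]
      # forward pass over pairs (h_{t-1}, h_t)
      logsc <- 0
      if (fg == Tall) {  # single-year edge case
        v <- stats::dnorm(hg, H[fg], p$sigma_h) * Evec(fg) * wh
        Z <- sum(v) * Afun(fg)[1, 1]
      } else {
        v1 <- stats::dnorm(hg, H[fg], p$sigma_h) * Evec(fg) * wh
        trans <- function(t) {  # P(h_t -> h_{t+1}) * E_{t+1} * wh; rows h_t
          outer(hstar_g, hg, function(hl, hm) {
            stats::dnorm(hm, H[t + 1] + p$beta_h * hl, p$sigma_h)
          }) * matrix(Evec(t + 1) * wh, Gh, Gh, byrow = TRUE)
        }
        alpha <- (v1 %o% rep(1, Gh)) * trans(fg)
        A1 <- Afun(fg)              # couples h_{fg+1} only (first step)
        alpha <- alpha * matrix(A1[1, ], Gh, Gh, byrow = TRUE)
        sc <- max(alpha); alpha <- alpha / sc; logsc <- logsc + log(sc)
        for (t in (fg + 1):(Tall - 1)) {
          tmp <- crossprod(alpha, Afun(t))   # (h_t, h_{t+1})
          alpha <- tmp * trans(t)
          sc <- max(alpha)
          if (sc <= 0 || !is.finite(sc)) { logsc <- -Inf; break }
          alpha <- alpha / sc; logsc <- logsc + log(sc)
        }
        ATall <- Afun(Tall)          # couples h_{Tall-1} only
        Z <- if (is.finite(logsc)) sum(alpha * matrix(ATall[, 1], Gh, Gh)) else 0
      }
      if (Z > 0) marg_i <- marg_i + exp(log(Z) + logsc + logconst)
    }
    if (marg_i <= 0) return(-Inf)
    total <- total + log(marg_i)
  }
  as.numeric(total)
}

#' Quadrature self-check
#'
#' Recomputes the oracle log-marginal with the grid step halved and reports
#' the absolute change; a large change diagnoses a too-coarse grid.
#'
#' @inheritParams brute_force_marginal
#' @return List with `logZ`, `logZ_fine`, `delta`.
#' @export
oracle_grid_check <- function(ds, params, H, S, Gh = 121, Gs = 101) {
  z1 <- brute_force_marginal(ds, params, H, S, Gh, Gs)
  z2 <- brute_force_marginal(ds, params, H, S, 2 * Gh - 1, 2 * Gs - 1)
  list(logZ = z1, logZ_fine = z2, delta = abs(z2 - z1))
}

#' Importance-sampling estimate of the marginal likelihood
#'
#' Sampler-based counterpart of [brute_force_marginal()]: simulates latent
#' nutritional/stress states and calving/pregnancy sequences from the process
#' prior (conditioning on `H`, `S`, prior-mean lengths, known ages and sexes,
#' as the oracle does) and weights by the observation likelihood. Individuals
#' are independent, so the estimate and its Monte-Carlo standard error are
#' accumulated per individual.
#'
#' @inheritParams brute_force_marginal
#' @param R Number of importance draws per individual.
#' @return List with `logZ` and `se` (delta-method SE of the log estimate).
#' @export
importance_marginal <- function(ds, params, H, S, R = 1e5) {
  con <- compute_standardisation(ds)
  md <- build_model_arrays(ds, con)
  if (any(md$sex_code == 2) || any(!md$known_age)) {
    stop("Importance estimate requires known sexes and ages")
  }
  p <- as.list(params[param_names()])
  Tall <- md$Tall
  logZ <- 0; var_log <- 0
  for (i in seq_len(md$N)) {
    fg <- md$first_grid[i]
    g <- as.numeric(md$sex_code[i] == 1)
    h <- matrix(NA_real_, R, Tall); s <- matrix(NA_real_, R, Tall)
    for (t in fg:Tall) {
      ar <- if (t > fg) p$beta_h * (h[, t - 1] - con$h_center) / con$h_scale else 0
      h[, t] <- H[t] + ar + stats::rnorm(R, 0, p$sigma_h)
      lag <- if (t > fg) p$beta_s1 * (h[, t - 1] - con$h_center) / con$h_scale else 0
      astar <- (md$a0_mean[i] + (t - fg) - con$a_center) / con$a_scale
      s[, t] <- S[t] + lag + p$beta_s2 * astar + p$beta_s3 * g +
        stats::rnorm(R, 0, p$sigma_s)
    }
    Ts <- md$Tstudy
    cmat <- Pmat <- matrix(0L, R, Ts)
    modelled <- vapply(seq_len(Ts), function(ts) {
      tg <- ts + md$study_offset
      g == 1 && (md$a0_mean[i] + (tg - fg)) >= md$maturity_age && (tg - 2) >= fg
    }, logical(1))
    if (any(modelled)) {
      phi <- matrix(0, R, Ts)
      for (ts in which(modelled)) {
        tg <- ts + md$study_offset
        hs1 <- (h[, tg - 1] - con$h_center) / con$h_scale
        L3s <- (md$Lm[i, tg - 1]^3 - con$L3_center) / con$L3_scale
        lag <- if (tg - 2 > fg) p$beta_s1 * (h[, tg - 3] - con$h_center) / con$h_scale else 0
        a2 <- (md$a0_mean[i] + (tg - 2 - fg) - con$a_center) / con$a_scale
        r2 <- s[, tg - 2] - (p$lambda_s + lag + p$beta_s2 * a2 + p$beta_s3 * g)
        phi[, ts] <- stats::plogis(p$gamma1 + p$gamma2 * hs1 + p$gamma3 * L3s +
                                     p$gamma4 * r2)
      }
      if (modelled[Ts]) Pmat[, Ts] <- stats::rbinom(R, 1, md$final_pregnancy_prob)
      for (ts in rev(seq_len(Ts))) {
        if (modelled[ts]) {
          cmat[, ts] <- stats::rbinom(R, 1, phi[, ts] * (1 - Pmat[, ts]))
        }
        if (ts > 1) Pmat[, ts - 1] <- cmat[, ts]
      }
    }
    lw <- numeric(R)
    for (o in which(md$bai_i == i)) {
      t <- md$bai_t[o]; ts <- t - md$study_offset
      Pv <- if (ts >= 1) Pmat[, ts] else 0
      mu <- h[, t] + p$delta1 * md$bai_d[o] + p$delta2 * Pv
      lw <- lw + stats::dnorm(md$bai_mean[o], mu, sqrt(p$nu_h^2 + md$bai_sd[o]^2),
                              log = TRUE)
    }
    for (o in which(md$fgc_i == i)) {
      t <- md$fgc_t[o]; m <- md$m[, o]
      G <- s[, t] + p$zeta1 * m[1] + p$zeta2 * m[2] + p$zeta3 * m[3] +
        p$zeta4 * md$fgc_y[o]
      lw <- lw + stats::dnorm(md$fgc[o], exp(G), p$nu_s, log = TRUE)
    }
    for (ts in which(modelled)) {
      pd <- stats::plogis(p$eta1 + p$eta2 * md$fstar[i, ts]) * md$e[i, ts]
      pk <- cmat[, ts] * pd
      lw <- lw + if (md$k[i, ts] == 1) log(pk) else log1p(-pk)
    }
    mx <- max(lw)
    w <- exp(lw - mx)
    mw <- mean(w)
    logZ <- logZ + mx + log(mw)
    var_log <- var_log + stats::var(w) / (R * mw^2)
  }
  list(logZ = logZ, se = sqrt(var_log))
}

#' Construct a small fully-observed toy dataset
#'
#' Two mature females and one male over four study years, with known ages,
#' sexes and (effectively) known lengths, a handful of BAI and faecal
#' observations and one observed calf; used by the oracle-equivalence checks.
#'
#' @param seed Integer seed for the observation values.
#' @return List with `dataset`, and the conditioning `H` and `S` vectors.
#' @export
make_toy_dataset <- function(seed = 42L) {
  set.seed(seed)
  years <- 2016:2019
  cfg <- default_config(years = years, seed = seed)
  ids <- c("F1", "F2", "M1")
  individuals <- tibble::tibble(
    individual_id = ids,
    sex = c("female", "female", "male"),
    known_age = TRUE,
    first_year = 2016L,
    min_age = c(12L, 15L, 10L),
    age_mean = c(12, 15, 10),
    age_sd = 0
  )
  grid_years <- 2014:2019
  lengths <- do.call(rbind, lapply(seq_along(ids), function(i) {
    tibble::tibble(individual_id = ids[i], year = grid_years,
                   length_mean = c(11.8, 12.3, 11.2)[i] + 0.02 * seq_along(grid_years),
                   length_sd = 0.01)
  }))
  bai <- tibble::tibble(
    individual_id = c("F1", "F1", "F2", "M1", "F2"),
    year = c(2016L, 2018L, 2017L, 2019L, 2019L),
    day_before_season_end = c(30, 80, 10, 55, 20),
    bai_mean = c(27.5, 26.2, 28.4, 25.9, 27.8),
    bai_sd = c(0.5, 0.8, 0.4, 0.6, 0.5)
  )
  fgc <- tibble::tibble(
    individual_id = c("F1", "F2", "M1"),
    year = c(2017L, 2018L, 2018L),
    day_of_year = c(200L, 230L, 180L),
    fgc = c(31.2, 24.5, 40.1),
    m1 = c(2.1, 1.8, 2.4), m2 = c(1.4, 1.6, 1.2), m3 = c(2.6, 2.2, 2.8),
    m1_below_lod = FALSE, m2_below_lod = FALSE, m3_below_lod = FALSE,
    m1_lod = NA_real_, m2_lod = NA_real_, m3_lod = NA_real_
  )
  sightings <- do.call(rbind, lapply(ids, function(id) {
    tibble::tibble(individual_id = id, year = years,
                   encountered = c(1L, 1L, 0L, 1L),
                   first_day = c(160, 200, NA, 175),
                   calf_observed = 0L, calf_reported_elsewhere = 0L)
  }))
  sightings$calf_observed[sightings$individual_id == "F1" &
                          sightings$year == 2017] <- 1L
  ds <- gw_dataset(individuals, lengths, bai, fgc, sightings, config = cfg)
  list(dataset = ds,
       H = c(27.3, 27.8, 27.5, 28.0, 27.2, 27.6),
       S = c(2.6, 2.75, 2.65, 2.8, 2.7, 2.68))
}
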
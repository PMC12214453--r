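#' Posterior summary table
#'
#' Posterior medians, central 95% credible intervals, split-\eqn{\hat{R}},
#' effective sample size and sign probabilities (posterior mass above zero)
#' for every top-level parameter.
#'
#' @param draws A `gw_draws` object.
#' @return A tibble with one row per parameter.
#' @export
posterior_summary <- function(draws) {
  m <- as.matrix(draws)
  if (nrow(m) == 0) stop("Empty draws")
  qs <- unname(t(apply(m, 2, stats::quantile, c(0.025, 0.5, 0.975))))
  multi <- dim(draws$params)[2] >= 2
  tibble::tibble(
    parameter = colnames(m),
    median = qs[, 2], q2.5 = qs[, 1], q97.5 = qs[, 3],
    p_positive = unname(colMeans(m > 0)),
    rhat = if (multi) vapply(seq_len(ncol(m)), function(p) {
      split_rhat(draws$params[, , p])
    }, numeric(1)) else NA_real_,
    ess = if (multi) vapply(seq_len(ncol(m)), function(p) {
      ess_basic(draws$params[, , p])
    }, numeric(1)) else NA_real_
  )
}

#' Calving-probability effect curves
#'
#' Posterior median and 95% CI of the calving probability over a grid of one
#' standardised covariate (lagged nutritional state, lagged cubed length, or
#' residual stress two years prior) with the other two held at their mean
#' (0 on the standardised scale).
#'
#' @param draws A `gw_draws` object.
#' @param covariate One of `"nutrition"`, `"length3"`, `"stress_residual"`.
#' @param grid Grid of standardised covariate values.
#' @return Tibble with `x`, `median`, `q2.5`, `q97.5`.
#' @export
effect_curve <- function(draws, covariate = c("nutrition", "length3", "stress_residual"),
                         grid = seq(-2.5, 2.5, length.out = 60)) {
  covariate <- match.arg(covariate)
  m <- as.matrix(draws)
  slope <- switch(covariate, nutrition = m[, "gamma2"],
                  length3 = m[, "gamma3"], stress_residual = m[, "gamma4"])
  out <- vapply(grid, function(x) {
    phi <- stats::plogis(m[, "gamma1"] + slope * x)
    stats::quantile(phi, c(0.025, 0.5, 0.975))
  }, numeric(3))
  tibble::tibble(x = grid, q2.5 = out[1, ], median = out[2, ], q97.5 = out[3, ])
}

#' Combined length-by-nutrition calving surface
#'
#' Posterior median calving probability over a grid of body length (metres)
#' and nutritional state (BAI units) in the year before a reproductive
#' opportunity, with residual stress at its mean.
#'
#' @param draws A `gw_draws` object.
#' @param length_grid,h_grid Grids in natural units.
#' @return Tibble in long format with `length`, `h`, `median`.
#' @export
effect_surface <- function(draws,
                           length_grid = seq(9, 13.5, length.out = 40),
                           h_grid = seq(23, 32, length.out = 40)) {
  m <- as.matrix(draws)
  con <- draws$constants
  rows <- list()
  for (L in length_grid) {
    L3s <- (L^3 - con$L3_center) / con$L3_scale
    for (h in h_grid) {
      hs <- (h - con$h_center) / con$h_scale
      phi <- stats::plogis(m[, "gamma1"] + m[, "gamma2"] * hs + m[, "gamma3"] * L3s)
      rows[[length(rows) + 1]] <- tibble::tibble(length = L, h = h,
                                                median = stats::median(phi))
    }
  }
  do.call(rbind, rows)
}

#' Classification metrics for the calving model
#'
#' Compares, per mature-female-year, the posterior mean of
#' \eqn{\phi (1 - P)} against an observation-derived calving label:
#' positives are female-years with a calf observed in the study area or
#' reported by another group; negatives are encounter-confirmed calf-free
#' years of known females in which the calving process was modelled. Reports
#' sensitivity and specificity at the chosen threshold and the area under the
#' ROC curve.
#'
#' @param draws A `gw_draws` object.
#' @param threshold Classification threshold in (0, 1), default 0.5.
#' @return List with `sensitivity`, `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
classification_metrics <- function(draws, threshold = 0.5) {
  md <- draws$md
  avail <- draws$phicount > 0.5 * max(draws$phicount)
  score <- draws$phimean
  pos <- (md$k == 1 | md$rep_el == 1) & avail
  neg <- md$e == 1 & md$k == 0 & md$rep_el == 0 & avail &
    matrix(md$sex_code == 1, md$N, md$Tstudy)
  if (sum(pos) == 0 || sum(neg) == 0) stop("No mature female-years to classify")
  y <- c(rep(1, sum(pos)), rep(0, sum(neg)))
  sc <- c(score[pos], score[neg])
  roc <- pROC::roc(response = y, predictor = sc, quiet = TRUE,
                   direction = "<", levels = c(0, 1))
  list(sensitivity = mean(score[pos] > threshold),
       specificity = mean(score[neg] <= threshold),
       auc = as.numeric(pROC::auc(roc)),
       n_pos = sum(pos), n_neg = sum(neg))
}

#' Posterior distribution of missed calving events
#'
#' Number of calving events with no calf observation in the study area and no
#' external report, per stored draw.
#'
#' @param draws A `gw_draws` object.
#' @return List with `median`, `q2.5`, `q97.5` and the draw vector.
#' @export
missed_calving_count <- function(draws) {
  v <- as.vector(draws$missed)
  qs <- stats::quantile(v, c(0.025, 0.5, 0.975))
  list(median = qs[[2]], q2.5 = qs[[1]], q97.5 = qs[[3]], draws = v)
}

#' Population age structure
#'
#' Per-age counts (known vs estimated ages) in a reference year, with a
#' kernel density estimate of the distribution.
#'
#' @param ds A `gw_dataset`.
#' @param fit Optional `gw_draws`; when supplied, posterior mean ages are used
#'   for individuals with uncertain age, otherwise their prior means.
#' @param reference_year Calendar year at which ages are tabulated.
#' @param bw Kernel bandwidth (default Silverman's rule via [stats::bw.nrd0()]).
#' @return List with `table` (tibble: `age`, `n`, `n_known`) and `density`
#'   (a `stats::density` object).
#' @export
age_structure <- function(ds, fit = NULL, reference_year = max(ds$config$years),
                          bw = "nrd0") {
  ind <- ds$individuals
  if (nrow(ind) == 0) stop("Empty cohort")
  ages <- ind$age_mean + (reference_year - ind$first_year)
  if (!is.null(fit)) {
    md <- fit$md
    tg_ref <- match(reference_year, md$grid_years)
    ages_fit <- fit$a0mean + (tg_ref - md$first_grid)
    ages[!ind$known_age] <- ages_fit[!ind$known_age]
  }
  ages <- pmax(ages, 0)
  agei <- round(ages)
  tab <- tibble::tibble(age = sort(unique(agei)))
  tab$n <- vapply(tab$age, function(a) sum(agei == a), numeric(1))
  tab$n_known <- vapply(tab$age, function(a) sum(agei == a & ind$known_age), numeric(1))
  dens <- stats::density(ages, bw = bw, from = 0)
  list(table = tab, density = dens)
}

#' Parameter-recovery report
#'
#' Per-parameter bias of the posterior median, 95% CI coverage of the truth
#' and interval width for a fit of simulated data.
#'
#' @param draws A `gw_draws` object.
#' @param truth Named vector of generating parameter values.
#' @return Tibble with `parameter`, `truth`, `median`, `q2.5`, `q97.5`,
#'   `bias`, `covered`, `width`.
#' @export
recovery_report <- function(draws, truth) {
  m <- as.matrix(draws)
  missing <- setdiff(colnames(m), names(truth))
  if (length(missing) > 0) {
    stop("Truth values missing for: ", paste(missing, collapse = ", "))
  }
  qs <- unname(t(apply(m, 2, stats::quantile, c(0.025, 0.5, 0.975))))
  tr <- as.numeric(truth[colnames(m)])
  tibble::tibble(
    parameter = colnames(m), truth = tr,
    median = qs[, 2], q2.5 = qs[, 1], q97.5 = qs[, 3],
    bias = qs[, 2] - tr,
    covered = tr >= qs[, 1] & tr <= qs[, 3],
    width = qs[, 3] - qs[, 1]
  )
}

#' Aggregate recovery reports over replicates
#'
#' @param reports List of tibbles from [recovery_report()].
#' @return Tibble with per-parameter mean bias, coverage rate and mean width.
#' @export
aggregate_recovery <- function(reports) {
  all <- do.call(rbind, reports)
  sp <- split(all, all$parameter)
  out <- do.call(rbind, lapply(sp, function(d) {
    tibble::tibble(parameter = d$parameter[1], truth = d$truth[1],
                   mean_bias = mean(d$bias), coverage = mean(d$covered),
                   mean_width = mean(d$width), n = nrow(d))
  }))
  out[match(param_names(), out$parameter), ]
}
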
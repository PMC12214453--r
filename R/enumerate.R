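#' Enumerate feasible calving/pregnancy sequences for one female
#'
#' Enumerates every binary calving sequence `c[1..W]` over a study window,
#' together with the final-step pregnancy indicator `P[W]`, consistent with
#' the hard constraints: pregnancy is calving shifted by one year
#' (`P[t] = c[t+1]` for `t < W`), a pregnant female cannot calve
#' (`c[t] * P[t] = 0`, which enforces the two-year minimum inter-calf
#' interval), no calving before maturity (`phi[t]` is `NA` for years where
#' calving is not modelled), and clamped calving years (observed or externally
#' reported calves force `c[t] = 1`). Each sequence is weighted by
#' `prod Bernoulli(c[t]; phi[t] (1 - P[t]))` times the final-step pregnancy
#' prior and any caller-supplied extra log-weights, then normalised.
#'
#' @param phi Numeric vector of calving probabilities per window year; `NA`
#'   marks years where calving is not modelled (`c` forced to 0).
#' @param forced Logical vector: years where the calving indicator is clamped
#'   to 1 (observed calf or calf reported by another group).
#' @param final_pregnancy_prob Bernoulli probability for pregnancy in the last
#'   step (0 disables final pregnancies). Only applied when the last year is
#'   modelled.
#' @param logw_c Optional `W x 2` matrix of extra log-weights indexed by
#'   `c[t] + 1` (e.g. calf-detection terms).
#' @param logw_P Optional `W x 2` matrix of extra log-weights indexed by
#'   `P[t] + 1` (e.g. BAI terms that depend on pregnancy status).
#' @param cap Maximum window length handled by enumeration (default 10).
#' @return A list with `c` (matrix, one row per feasible sequence), `P`
#'   (matrix, with `P[, W]` the sampled boundary), `log_weight`, and `prob`
#'   (normalised; sums to 1).
#' @export
enumerate_reproduction_sequences <- function(phi, forced = rep(FALSE, length(phi)),
                                             final_pregnancy_prob = 0.05,
                                             logw_c = NULL, logw_P = NULL,
                                             cap = 10L) {
  W <- length(phi)
  if (W > cap) {
    stop("Window length ", W, " exceeds the enumeration cap (", cap,
         "); use a Metropolis fallback for long windows")
  }
  if (any(forced & is.na(phi))) {
    stop("Calving clamped to 1 in a year where calving is not modelled")
  }
  if (is.null(logw_c)) logw_c <- matrix(0, W, 2)
  if (is.null(logw_P)) logw_P <- matrix(0, W, 2)

  # candidate c sequences: grow feasible prefixes
  seqs <- matrix(0L, 1, 0)
  for (t in seq_len(W)) {
    cand <- if (is.na(phi[t])) 0L else if (forced[t]) 1L else c(0L, 1L)
    grown <- do.call(rbind, lapply(cand, function(v) cbind(seqs, v)))
    # no two consecutive calving years
    if (t > 1) grown <- grown[!(grown[, t - 1] == 1 & grown[, t] == 1), , drop = FALSE]
    seqs <- grown
  }
  last_modelled <- !is.na(phi[W])
  pT_options <- function(cW) {
    if (!last_modelled) return(0L)
    if (cW == 1 || final_pregnancy_prob <= 0) return(0L)
    c(0L, 1L)
  }
  rows_c <- list(); rows_P <- list(); lw <- numeric(0)
  for (r in seq_len(nrow(seqs))) {
    cc <- seqs[r, ]
    for (pT in pT_options(cc[W])) {
      P <- c(if (W > 1) cc[-1] else integer(0), pT)
      w <- 0
      for (t in seq_len(W)) {
        if (!is.na(phi[t])) {
          pr <- phi[t] * (1 - P[t])
          w <- w + if (cc[t] == 1) log(pr) else log1p(-pr)
        }
        w <- w + logw_c[t, cc[t] + 1] + logw_P[t, P[t] + 1]
      }
      if (last_modelled && final_pregnancy_prob > 0) {
        w <- w + if (pT == 1) log(final_pregnancy_prob) else log1p(-final_pregnancy_prob)
      }
      if (is.finite(w)) {
        rows_c[[length(rows_c) + 1]] <- cc
        rows_P[[length(rows_P) + 1]] <- P
        lw <- c(lw, w)
      }
    }
  }
  if (length(lw) == 0) stop("No feasible calving/pregnancy sequence (contradictory clamps)")
  cmat <- do.call(rbind, rows_c)
  Pmat <- do.call(rbind, rows_P)
  mx <- max(lw)
  pr <- exp(lw - mx); pr <- pr / sum(pr)
  list(c = cmat, P = Pmat, log_weight = lw, prob = pr)
}
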
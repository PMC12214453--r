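#' Assemble a whale health dataset
#'
#' Bundles the five longitudinal tables into a validated dataset object.
#'
#' Table schemas (all keyed by `individual_id` and, where relevant, calendar
#' `year`):
#'
#' * `individuals`: `individual_id`, `sex` (`"female"`, `"male"`, `"unknown"`),
#'   `known_age` (logical), `first_year` (year of entry: birth year if born
#'   during the study, else the first study year), `min_age` (minimum age in
#'   `first_year`, >= 0), `age_mean`, `age_sd` (prior for age in `first_year`;
#'   `age_sd` is ignored when `known_age`).
#' * `lengths`: `individual_id`, `year`, `length_mean`, `length_sd` (metres;
#'   posterior summaries from an external photogrammetric growth model, treated
#'   here as per-year Normal priors). Rows may cover the pre-study lag years.
#' * `bai`: `individual_id`, `year`, `day_before_season_end` (days between the
#'   measurement and 15 October, >= 0), `bai_mean`, `bai_sd` (unitless body
#'   area index posterior mean and SD).
#' * `fgc`: `individual_id`, `year`, `day_of_year`, `fgc` (glucocorticoid
#'   concentration, assay units), `m1`, `m2`, `m3` (log progestin, androgen,
#'   thyroid concentrations; `NA` when below the limit of detection),
#'   `m1_below_lod`..`m3_below_lod` (logical), `m1_lod`..`m3_lod`
#'   (natural-scale upper imputation bound, required where censored; for
#'   thyroid hormone in the first study year this is the maximum observed
#'   concentration), and optional `m1_lod_lower`..`m3_lod_lower`
#'   (natural-scale lower imputation bound). Assay-censored values are
#'   imputed uniformly on the concentration scale below the LOD; values with
#'   an explicit lower bound (a hormone not measured at all, imputed across
#'   the observed range) are imputed uniformly on the log scale between the
#'   bounds.
#' * `sightings`: `individual_id`, `year`, `encountered` (0/1), `first_day`
#'   (day of year of first sighting, `NA` when not encountered),
#'   `calf_observed` (0/1), `calf_reported_elsewhere` (0/1; a calf seen by
#'   another research group, which pins the calving indicator to 1 even though
#'   no calf was seen in the study area).
#'
#' @param individuals,lengths,bai,fgc,sightings Data frames as above.
#' @param config Configuration list, see [default_config()].
#' @param validate Run [validate_dataset()] (default `TRUE`).
#' @return An object of class `gw_dataset`.
#' @export
gw_dataset <- function(individuals, lengths, bai, fgc, sightings,
                       config = default_config(), validate = TRUE) {
  ds <- structure(
    list(individuals = tibble::as_tibble(individuals),
         lengths = tibble::as_tibble(lengths),
         bai = tibble::as_tibble(bai),
         fgc = tibble::as_tibble(fgc),
         sightings = tibble::as_tibble(sightings),
         config = config),
    class = "gw_dataset")
  if (validate) validate_dataset(ds)
  ds
}

#' @export
print.gw_dataset <- function(x, ...) {
  cat("<gw_dataset>", nrow(x$individuals), "individuals,",
      length(x$config$years), "study years (",
      min(x$config$years), "-", max(x$config$years), ")\n")
  cat("  BAI records:      ", nrow(x$bai), "\n")
  cat("  faecal records:   ", nrow(x$fgc), "\n")
  cat("  sighting records: ", nrow(x$sightings), "\n")
  invisible(x)
}

required_columns <- list(
  individuals = c("individual_id", "sex", "known_age", "first_year",
                  "min_age", "age_mean", "age_sd"),
  lengths = c("individual_id", "year", "length_mean", "length_sd"),
  bai = c("individual_id", "year", "day_before_season_end", "bai_mean", "bai_sd"),
  fgc = c("individual_id", "year", "day_of_year", "fgc",
          "m1", "m2", "m3", "m1_below_lod", "m2_below_lod", "m3_below_lod",
          "m1_lod", "m2_lod", "m3_lod"),
  sightings = c("individual_id", "year", "encountered", "first_day",
                "calf_observed", "calf_reported_elsewhere")
)

#' Validate a dataset
#'
#' Checks schema completeness, referential integrity and every hard support
#' constraint of the observation models: a calf cannot be observed without an
#' encounter; calves (observed or reported elsewhere) imply a known female of
#' plausibly mature age; observed calves for the same female in consecutive
#' years violate the two-year minimum inter-calf interval; below-LOD hormone
#' records must carry a finite positive upper bound.
#'
#' @param ds A `gw_dataset`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_dataset <- function(ds) {
  for (tab in names(required_columns)) {
    missing <- setdiff(required_columns[[tab]], names(ds[[tab]]))
    if (length(missing) > 0) {
      stop("Schema error in `", tab, "`: missing column(s) ",
           paste(missing, collapse = ", "))
    }
  }
  ind <- ds$individuals
  years <- ds$config$years
  if (anyDuplicated(ind$individual_id)) stop("Duplicated individual_id in `individuals`")
  if (!all(ind$sex %in% c("female", "male", "unknown"))) {
    stop("`sex` must be one of female/male/unknown")
  }
  if (any(ind$min_age < 0)) stop("min_age must be >= 0")
  if (any(!ind$known_age & ind$age_sd <= 0)) stop("age_sd must be > 0 for uncertain ages")
  if (any(ind$age_mean < ind$min_age - 1e-9)) stop("age prior mean below min_age")

  ids <- ind$individual_id
  for (tab in c("lengths", "bai", "fgc", "sightings")) {
    bad <- setdiff(unique(ds[[tab]]$individual_id), ids)
    if (length(bad) > 0) {
      stop("Rows in `", tab, "` reference unknown individual(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  for (tab in c("bai", "fgc", "sightings")) {
    if (!all(ds[[tab]]$year %in% years)) {
      stop("`", tab, "` contains years outside the configured study window")
    }
  }
  if (any(ds$lengths$length_sd <= 0)) stop("length_sd must be > 0")
  if (any(ds$bai$bai_sd <= 0)) stop("bai_sd must be > 0")
  if (any(ds$bai$day_before_season_end < 0)) stop("day_before_season_end must be >= 0")
  if (any(ds$bai$bai_mean <= 10 | ds$bai$bai_mean >= 50)) {
    stop("bai_mean outside sanity bounds (10, 50)")
  }
  if (any(ds$fgc$day_of_year < 1 | ds$fgc$day_of_year > 366)) {
    stop("day_of_year must be in [1, 366]")
  }
  if (any(ds$fgc$fgc < 0)) stop("fgc concentrations must be >= 0")
  for (j in 1:3) {
    cens <- as.logical(ds$fgc[[paste0("m", j, "_below_lod")]])
    lod <- ds$fgc[[paste0("m", j, "_lod")]]
    if (any(cens & (!is.finite(lod) | lod <= 0))) {
      stop("below-LOD hormone m", j, " without a finite positive upper bound")
    }
    if (any(!cens & !is.finite(ds$fgc[[paste0("m", j)]]))) {
      stop("non-censored hormone m", j, " must be observed (finite)")
    }
  }

  sg <- ds$sightings
  if (any(sg$calf_observed == 1 & sg$encountered == 0)) {
    stop("Consistency error: calf_observed = 1 with encountered = 0")
  }
  if (any(sg$encountered == 1 & !is.finite(sg$first_day))) {
    stop("encountered = 1 requires a first_day")
  }
  sex_of <- stats::setNames(ind$sex, ind$individual_id)
  calfrow <- sg$calf_observed == 1 | sg$calf_reported_elsewhere == 1
  if (any(sex_of[sg$individual_id[calfrow]] != "female")) {
    stop("Calving recorded for a non-female individual (sex is derived from calf observations)")
  }
  # maturity support: a known-age female cannot calve before the maturity age
  if (any(calfrow)) {
    sub <- sg[calfrow, ]
    ia <- ind[match(sub$individual_id, ind$individual_id), ]
    age_at <- ia$age_mean + (sub$year - ia$first_year)
    known <- ia$known_age
    if (any(known & age_at < ds$config$maturity_age)) {
      stop("Calving recorded for a known-age female below the maturity age")
    }
  }
  # two-year minimum inter-calf interval in the observations themselves
  ev <- sg[calfrow, c("individual_id", "year")]
  if (nrow(ev) > 1) {
    sp <- split(ev$year, ev$individual_id)
    if (any(vapply(sp, function(y) any(diff(sort(y)) < 2), logical(1)))) {
      stop("Observed calving events closer than the two-year minimum inter-calf interval")
    }
  }
  invisible(TRUE)
}

#' Write / load a dataset as CSV files
#'
#' `write_dataset()` writes `individuals.csv`, `lengths.csv`, `bai.csv`,
#' `fgc.csv` and `sightings.csv` into `dir` (plus `config.yaml`);
#' `load_dataset()` reads them back and validates. The round trip is lossless
#' for all fields including the below-LOD flags and bounds.
#'
#' @param ds A `gw_dataset`.
#' @param dir Directory (created if needed).
#' @param config Optional config; defaults to `config.yaml` in `dir` if
#'   present, else [default_config()].
#' @return `load_dataset()` returns a validated `gw_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in names(required_columns)) {
    utils::write.csv(ds[[tab]], file.path(dir, paste0(tab, ".csv")), row.names = FALSE)
  }
  cfg <- ds$config
  cfg$priors <- NULL  # priors are runtime configuration, not data
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
load_dataset <- function(dir, config = NULL) {
  if (is.null(config)) {
    cfgp <- file.path(dir, "config.yaml")
    config <- if (file.exists(cfgp)) read_run_config(cfgp) else default_config()
  }
  read1 <- function(tab) {
    path <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(path)) stop("Missing dataset file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(required_columns[[tab]], names(df))
    if (length(missing) > 0) {
      stop("Schema error in `", tab, "`: missing column(s) ",
           paste(missing, collapse = ", "))
    }
    df
  }
  ind <- read1("individuals")
  ind$known_age <- as.logical(ind$known_age)
  fgc <- read1("fgc")
  for (j in 1:3) {
    fgc[[paste0("m", j, "_below_lod")]] <- as.logical(fgc[[paste0("m", j, "_below_lod")]])
    for (suf in c("_lod", "_lod_lower")) {  # all-NA columns read back as logical
      cl <- paste0("m", j, suf)
      if (cl %in% names(fgc)) fgc[[cl]] <- as.numeric(fgc[[cl]])
    }
  }
  gw_dataset(ind, read1("lengths"), read1("bai"), fgc, read1("sightings"),
             config = config)
}

# population SD (divide by n, not n - 1); the standardisation convention
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardisation constants
#'
#' Computes the centring/scaling constants used for the standardised
#' covariates: nutritional state (from the per-individual-per-year means of
#' observed BAI), age (from the age prior means over individual-years), cubed
#' length (from the length prior means over individual-years) and, when
#' configured, the day of first sighting. Constants are deterministic
#' functions of the observed data, frozen once per fit and stored with all
#' outputs; population-SD convention throughout.
#'
#' @param ds A `gw_dataset`.
#' @return Object of class `gw_constants`: list with `h_center`, `h_scale`,
#'   `a_center`, `a_scale`, `L3_center`, `L3_scale`, `f_center`, `f_scale`,
#'   `y_center`, `y_scale`.
#' @export
compute_standardisation <- function(ds) {
  if (nrow(ds$bai) == 0) stop("Cannot standardise an empty dataset")
  cfg <- ds$config
  key <- paste(ds$bai$individual_id, ds$bai$year)
  h_means <- tapply(ds$bai$bai_mean, key, mean)
  ind <- ds$individuals
  years <- cfg$years
  # age prior mean of each individual in each study year it is present
  ages <- unlist(lapply(seq_len(nrow(ind)), function(i) {
    yrs <- years[years >= ind$first_year[i]]
    ind$age_mean[i] + (yrs - ind$first_year[i])
  }))
  L3 <- ds$lengths$length_mean[ds$lengths$year %in% years]^3
  fday <- ds$sightings$first_day[ds$sightings$encountered == 1]
  con <- list(
    h_center = mean(h_means), h_scale = pop_sd(h_means),
    a_center = mean(ages), a_scale = pop_sd(ages),
    L3_center = mean(L3), L3_scale = pop_sd(L3),
    f_center = if (isTRUE(cfg$standardise_f)) mean(fday) else 0,
    f_scale = if (isTRUE(cfg$standardise_f)) pop_sd(fday) else 1,
    y_center = if (isTRUE(cfg$standardise_y)) mean(ds$fgc$day_of_year) else 0,
    y_scale = if (isTRUE(cfg$standardise_y)) pop_sd(ds$fgc$day_of_year) else 1
  )
  degen <- c(h = con$h_scale, a = con$a_scale, L3 = con$L3_scale,
             f = con$f_scale, y = con$y_scale)
  if (any(degen <= 0)) {
    stop("Degenerate input: zero variance in standardised quantity (",
         paste(names(degen)[degen <= 0], collapse = ", "), ")")
  }
  structure(con, class = "gw_constants")
}

#' Internal model arrays
#'
#' Flattens a dataset into the integer-indexed arrays shared by the R density
#' kernels and the compiled sampler. The latent time grid prepends
#' `burnin_years` pre-study years (so lagged covariates exist at the first
#' study step) for individuals present from the start; individuals born during
#' the study enter at their birth year with no pre-entry padding.
#'
#' @param ds A `gw_dataset`.
#' @param constants Output of [compute_standardisation()].
#' @return A list of arrays (`md`), used by [joint_logposterior()] and
#'   [run_mcmc()].
#' @keywords internal
#' @export
build_model_arrays <- function(ds, constants = compute_standardisation(ds)) {
  cfg <- ds$config
  years <- cfg$years
  B <- cfg$burnin_years
  grid_years <- (min(years) - B):max(years)
  Tall <- length(grid_years)
  Tstudy <- length(years)
  ind <- ds$individuals
  N <- nrow(ind)
  id_index <- stats::setNames(seq_len(N), ind$individual_id)

  first_grid <- ifelse(ind$first_year <= min(years), 1L,
                       match(ind$first_year, grid_years))
  # age parameters referenced to the individual's first grid year
  off <- ind$first_year - grid_years[first_grid]   # 0 for born-in-study, B else
  a0_mean <- ind$age_mean - off
  a0_min <- ind$min_age - off
  a0_sd <- ifelse(ind$known_age, 0, ind$age_sd)

  sex_code <- match(ind$sex, c("male", "female", "unknown")) - 1L  # 0 M, 1 F, 2 unknown

  Lm <- matrix(NA_real_, N, Tall)
  Lsd <- matrix(NA_real_, N, Tall)
  li <- id_index[ds$lengths$individual_id]
  lt <- match(ds$lengths$year, grid_years)
  keep <- !is.na(lt)
  Lm[cbind(li[keep], lt[keep])] <- ds$lengths$length_mean[keep]
  Lsd[cbind(li[keep], lt[keep])] <- ds$lengths$length_sd[keep]

  e <- matrix(0L, N, Tstudy); k <- matrix(0L, N, Tstudy)
  rep_el <- matrix(0L, N, Tstudy); fstar <- matrix(0, N, Tstudy)
  si <- id_index[ds$sightings$individual_id]
  st <- match(ds$sightings$year, years)
  e[cbind(si, st)] <- as.integer(ds$sightings$encountered)
  k[cbind(si, st)] <- as.integer(ds$sightings$calf_observed)
  rep_el[cbind(si, st)] <- as.integer(ds$sightings$calf_reported_elsewhere)
  fs <- (ds$sightings$first_day - constants$f_center) / constants$f_scale
  fs[!is.finite(fs)] <- 0
  fstar[cbind(si, st)] <- fs

  m <- rbind(ds$fgc$m1, ds$fgc$m2, ds$fgc$m3)
  cens <- rbind(ds$fgc$m1_below_lod, ds$fgc$m2_below_lod, ds$fgc$m3_below_lod)
  lod <- rbind(ds$fgc$m1_lod, ds$fgc$m2_lod, ds$fgc$m3_lod)
  lodlo <- matrix(NA_real_, 3, nrow(ds$fgc))
  for (j in 1:3) {
    cl <- paste0("m", j, "_lod_lower")
    if (cl %in% names(ds$fgc)) lodlo[j, ] <- ds$fgc[[cl]]
  }
  # censored values with an explicit lower bound (a hormone that was not
  # measured at all) are imputed uniformly on the log scale between the
  # bounds; ordinary below-LOD values are imputed uniformly on the
  # concentration scale below the LOD
  lod_log_hi <- log(lod)
  cens_log_uniform <- is.finite(lodlo)
  lod_log_lo <- ifelse(cens_log_uniform, log(lodlo), -Inf)
  m[is.na(m)] <- 0  # censored entries are latent; initialised by the sampler

  list(
    N = N, Tall = Tall, Tstudy = Tstudy, grid_years = grid_years,
    study_offset = Tall - Tstudy,
    first_grid = as.integer(first_grid),
    sex_code = as.integer(sex_code),
    known_age = ind$known_age,
    a0_mean = a0_mean, a0_sd = a0_sd, a0_min = a0_min,
    Lm = Lm, Lsd = Lsd, hasL = is.finite(Lm),
    bai_i = as.integer(id_index[ds$bai$individual_id]),
    bai_t = as.integer(match(ds$bai$year, grid_years)),
    bai_d = ds$bai$day_before_season_end,
    bai_mean = ds$bai$bai_mean, bai_sd = ds$bai$bai_sd,
    fgc_i = as.integer(id_index[ds$fgc$individual_id]),
    fgc_t = as.integer(match(ds$fgc$year, grid_years)),
    fgc_y = (ds$fgc$day_of_year - constants$y_center) / constants$y_scale,
    fgc = ds$fgc$fgc,
    m = m, cens = cens, lod = lod,
    lod_log_lo = lod_log_lo, lod_log_hi = lod_log_hi,
    cens_log_uniform = cens_log_uniform,
    e = e, k = k, rep_el = rep_el, fstar = fstar,
    maturity_age = cfg$maturity_age,
    final_pregnancy_prob = cfg$final_pregnancy_prob,
    residual_uses_lambda_s = isTRUE(cfg$residual_uses_lambda_s),
    constants = constants,
    ids = ind$individual_id
  )
}
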
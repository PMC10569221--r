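# Per-group log-part covariance for the logistic-normal composition model.
# u = log-part standard deviations; r12 = sleep-SB, r23 = SB-LPA and
# r24 = SB-MVPA log correlations. Calibrated once so that the induced
# part-wise SDs after closure sit near the reported cohort SDs
# (sleep ~0.6/0.7 h, SB ~1.3-1.4 h, LPA ~0.7-0.8 h, MVPA ~0.3-0.4 h).
part_log_cov <- function(u, r12, r23, r24) {
  C <- diag(u^2)
  C[1, 2] <- C[2, 1] <- r12 * u[1] * u[2]
  C[2, 3] <- C[3, 2] <- r23 * u[2] * u[3]
  C[2, 4] <- C[4, 2] <- r24 * u[2] * u[4]
  dimnames(C) <- list(behavior_parts(), behavior_parts())
  C
}

default_part_log_cov <- function() {
  list(
    children    = part_log_cov(c(0.095, 0.225, 0.15, 0.40), 0.55, -0.40, -0.25),
    adolescents = part_log_cov(c(0.135, 0.165, 0.20, 0.38), 0.45, -0.45, -0.30)
  )
}

# Default outcome models: overall target mean/SD (for intercept and noise
# accounting), covariate effects on the coded scale, and the share of
# outcome variance explained by the composition block (~5%).
default_outcome_params <- function() {
  list(
    bmi_z   = list(mean = 0.22, sd = 1.07,
                   cov_effects = c(sex = 0.10, maternal_bmi = 0.050,
                                   maternal_edu = -0.10, snacking = 0.05)),
    fm_pct  = list(mean = 20.1, sd = 8.7,
                   cov_effects = c(sex = -5.0, maternal_bmi = 0.35,
                                   maternal_edu = -1.0, snacking = 0.5)),
    fmi     = list(mean = 4.3, sd = 2.5,
                   cov_effects = c(sex = -0.6, maternal_bmi = 0.12,
                                   maternal_edu = -0.3, snacking = 0.15)),
    vat_cm2 = list(mean = 48.8, sd = 31.2,
                   cov_effects = c(sex = -6.0, maternal_bmi = 1.2,
                                   maternal_edu = -3.0, snacking = 2.0))
  )
}

#' Build a synthetic cohort generator configuration
#'
#' Encodes the study conditions the generator emulates: per-group sample
#' sizes and compositional means, a logistic-normal spread calibrated to the
#' reported part SDs, covariate distributions (boys 42.5%, maternal BMI
#' 24.4 (4.1) kg/m2, university education 40%, high snacking 58.3%/74.7%
#' by group), adiposity outcomes linear in the ilr coordinates plus
#' covariates with Gaussian noise, and MCAR missingness in the maternal
#' covariates (BMI 5%, education 2.4%).
#'
#' Outcome ilr slopes point along the sedentary-behaviour balance (more SB
#' relative to the other behaviours predicts higher adiposity) and are
#' scaled so the composition block explains `comp_r2` (default 5%) of the
#' outcome variance; the residual SD is then set so the total outcome SD
#' matches its target. All derived coefficients are returned in the config
#' so they can be exported as ground truth.
#'
#' @param n Named integer vector, participants per age group.
#' @param target_mean List of per-group compositional means (hours, closed
#'   to 24).
#' @param part_log_cov List of per-group 4x4 log-part covariance matrices.
#' @param boy_prop,university_prop Proportions for the binary covariates.
#' @param maternal_bmi_mean,maternal_bmi_sd Maternal BMI distribution.
#' @param high_snacking_prop Named per-group high-snacking proportions.
#' @param comp_r2 Fraction of outcome variance explained by the composition
#'   block (default 0.05).
#' @param outcome_params List of per-outcome targets and covariate effects;
#'   see `default_outcome_params` in the package source.
#' @param mcar_rates Named missingness rates for maternal covariates.
#' @param sbp Sequential binary partition used to define the generator's
#'   ilr coordinates.
#' @param seed Integer seed; sub-streams for compositions, covariates,
#'   noise, day tables and missingness are derived from it.
#' @return A `generator_config` object (a list).
#' @export
generator_config <- function(n = c(children = 343, adolescents = 316),
                             target_mean = list(
                               children = c(sleep = 8.6, sb = 10.4, lpa = 4.0, mvpa = 1.0),
                               adolescents = c(sleep = 7.5, sb = 12.2, lpa = 3.6, mvpa = 0.7)),
                             part_log_cov = default_part_log_cov(),
                             boy_prop = 0.425,
                             maternal_bmi_mean = 24.4, maternal_bmi_sd = 4.1,
                             university_prop = 0.40,
                             high_snacking_prop = c(children = 0.583, adolescents = 0.747),
                             comp_r2 = 0.05,
                             outcome_params = default_outcome_params(),
                             mcar_rates = c(maternal_bmi = 0.05, maternal_edu = 0.024),
                             sbp = default_sbp(),
                             seed = 20230928) {
  groups <- c("children", "adolescents")
  stopifnot(all(groups %in% names(n)), all(groups %in% names(target_mean)),
            all(groups %in% names(part_log_cov)),
            all(n >= 1), comp_r2 >= 0, comp_r2 < 1,
            all(mcar_rates >= 0 & mcar_rates <= 1),
            boy_prop >= 0, boy_prop <= 1, university_prop >= 0, university_prop <= 1)
  basis <- make_contrast_basis(sbp)
  for (g in groups) {
    C <- part_log_cov[[g]]
    if (!isTRUE(all.equal(C, t(C), tolerance = 1e-10)))
      stop("part_log_cov for ", g, " is not symmetric")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1))
      stop("part_log_cov for ", g, " is not positive semi-definite")
  }
  # ilr covariance per group under the config basis
  V <- basis$matrix
  ilr_cov <- lapply(part_log_cov[groups], function(C) t(V) %*% C %*% V)
  mu_z <- lapply(target_mean[groups],
                 function(m) ilr_coords(close_comp(m, 24), basis))

  # mixture moments over groups (weights = group sizes)
  w <- n[groups] / sum(n[groups])
  zbar <- w[1] * mu_z[[1]] + w[2] * mu_z[[2]]
  between <- w[1] * tcrossprod(mu_z[[1]] - zbar) + w[2] * tcrossprod(mu_z[[2]] - zbar)
  Sigma_mix <- w[1] * ilr_cov[[1]] + w[2] * ilr_cov[[2]] + between

  snack_mix <- unname(w[1] * high_snacking_prop["children"] +
                      w[2] * high_snacking_prop["adolescents"])
  cov_means <- c(sex = boy_prop, maternal_bmi = maternal_bmi_mean,
                 maternal_edu = university_prop, snacking = snack_mix)
  cov_vars <- c(sex = boy_prop * (1 - boy_prop),
                maternal_bmi = maternal_bmi_sd^2,
                maternal_edu = university_prop * (1 - university_prop),
                snacking = snack_mix * (1 - snack_mix))

  # adiposity rises with the SB balance, falls with the sleep balance
  direction <- c(z1 = -0.3, z2 = 1, z3 = -0.3)
  direction <- direction / sqrt(sum(direction^2))
  outcomes <- lapply(outcome_params, function(op) {
    total_var <- op$sd^2
    dSd <- as.numeric(crossprod(direction, Sigma_mix %*% direction))
    scale <- if (dSd > 0) sqrt(comp_r2 * total_var / dSd) else 0
    beta_ilr <- stats::setNames(scale * direction, colnames(V))
    bc <- op$cov_effects[names(cov_means)]
    var_cov <- sum(bc^2 * cov_vars)
    sigma2 <- total_var - comp_r2 * total_var - var_cov
    if (sigma2 <= 0)
      stop("covariate effects leave no residual variance for this outcome")
    intercept <- op$mean - sum(beta_ilr * zbar) - sum(bc * cov_means)
    list(intercept = intercept, beta_ilr = beta_ilr, cov_effects = bc,
         sigma = sqrt(sigma2), target_mean = op$mean, target_sd = op$sd)
  })

  structure(list(
    n = n[groups], target_mean = target_mean[groups],
    part_log_cov = part_log_cov[groups], ilr_cov = ilr_cov, mu_z = mu_z,
    boy_prop = boy_prop, maternal_bmi_mean = maternal_bmi_mean,
    maternal_bmi_sd = maternal_bmi_sd, university_prop = university_prop,
    high_snacking_prop = high_snacking_prop, comp_r2 = comp_r2,
    outcomes = outcomes, mcar_rates = mcar_rates,
    basis = basis, seed = as.integer(seed)
  ), class = "generator_config")
}

sub_seed <- function(seed, k) (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483629L

#' Draw logistic-normal compositions
#'
#' Draws ilr coordinates from a multivariate normal centred at the ilr image
#' of `target_mean` and maps them back to the 24-h simplex, so the
#' compositional (geometric) mean of a large sample converges to
#' `target_mean`.
#'
#' @param n Number of compositions.
#' @param target_mean Target compositional mean (hours).
#' @param ilr_cov 3x3 positive semi-definite ilr covariance (under `basis`).
#' @param basis A `contrast_basis`.
#' @param seed Optional integer seed.
#' @return n x 4 matrix of closed compositions.
#' @export
gen_compositions <- function(n, target_mean, ilr_cov,
                             basis = make_contrast_basis(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!isTRUE(all.equal(ilr_cov, t(ilr_cov), tolerance = 1e-8)))
    stop("ilr_cov must be symmetric")
  ev <- eigen(ilr_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("ilr_cov must be positive semi-definite")
  mu <- ilr_coords(close_comp(target_mean, 24), basis)
  z <- MASS::mvrnorm(n, mu, ilr_cov, tol = 1e-8)
  if (n == 1L) z <- matrix(z, nrow = 1L)
  ilr_inverse(z, basis, total = 24)
}

#' Inject MCAR missingness
#'
#' Independently sets each targeted field to `NA` with its configured rate.
#'
#' @param data A `cohort` or participant data frame.
#' @param rates Named numeric vector of per-column missingness rates in
#'   \code{[0, 1]}.
#' @param seed Optional integer seed.
#' @return Object of the same class with missingness injected.
#' @export
inject_mcar <- function(data, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(rates < 0 | rates > 1)) stop("MCAR rates must lie in [0, 1]")
  df <- participants_of(data)
  for (cc in names(rates)) {
    if (!cc %in% names(df)) stop("unknown column for MCAR injection: ", cc)
    hit <- stats::runif(nrow(df)) < rates[[cc]]
    df[[cc]][hit] <- NA
  }
  if (inherits(data, "cohort")) { data$participants <- df; data } else df
}

snack_from_class <- function(high, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(high)
  below <- SNACK_LEVELS[1:5]
  daily <- SNACK_DAILY
  m <- matrix(sample(below, 3L * n, replace = TRUE), ncol = 3L)
  which_daily <- sample.int(3L, n, replace = TRUE)
  for (i in which(high)) m[i, which_daily[i]] <- sample(daily, 1L)
  colnames(m) <- c("snack_sweets", "snack_softdrinks", "snack_crisps")
  m
}

#' Generate a synthetic cohort with exported ground truth
#'
#' Simulates the full participant table (compositions, covariates, the four
#' adiposity outcomes, anthropometry consistent with the simulated FMI),
#' optionally a 7-day day-level table whose weekday/weekend jitter exercises
#' the ingestion filters, and MCAR missingness in the maternal covariates.
#' The generating coefficients are returned as `truth` so recovery tests
#' can compare estimates against them.
#'
#' @param config A `generator_config`.
#' @param days If `TRUE` (default), also emit the day-level table.
#' @param mcar If `TRUE` (default), inject the configured MCAR missingness.
#' @param noise If `FALSE`, outcomes are generated without residual noise
#'   (useful for exact-recovery checks; the coefficients are unchanged).
#' @return List with `cohort` (a `cohort`), `days` (data frame or `NULL`)
#'   and `truth` (a `synthetic_truth` list).
#' @export
gen_cohort <- function(config = generator_config(), days = TRUE, mcar = TRUE,
                       noise = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  basis <- config$basis
  groups <- names(config$n)
  recs <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ng <- config$n[[g]]
    comps <- gen_compositions(ng, config$target_mean[[g]], config$ilr_cov[[g]],
                              basis, seed = sub_seed(config$seed, 10 + gi))
    set.seed(sub_seed(config$seed, 20 + gi))
    age <- if (g == "children") pmin(pmax(round(stats::rnorm(ng, 11.7, 1.6)), 8), 13)
           else pmin(pmax(round(stats::rnorm(ng, 16.3, 1.3)), 14), 18)
    sex <- ifelse(stats::rbinom(ng, 1, config$boy_prop) == 1, "boy", "girl")
    maternal_bmi <- stats::rnorm(ng, config$maternal_bmi_mean, config$maternal_bmi_sd)
    maternal_edu <- stats::rbinom(ng, 1, config$university_prop)
    high <- stats::rbinom(ng, 1, config$high_snacking_prop[[g]]) == 1
    snacks <- snack_from_class(high, seed = sub_seed(config$seed, 30 + gi))
    height_m <- if (g == "children") stats::rnorm(ng, 1.50, 0.10)
                else stats::rnorm(ng, 1.72, 0.09)
    mean_wear <- pmin(24, 24.0 - abs(stats::rnorm(ng, 0, 0.25)))

    z <- ilr_coords(comps, basis)
    cov_coded <- cbind(sex = as.numeric(sex == "boy"),
                       maternal_bmi = maternal_bmi,
                       maternal_edu = maternal_edu,
                       snacking = as.numeric(high))
    set.seed(sub_seed(config$seed, 40 + gi))
    out_vals <- lapply(config$outcomes, function(oc) {
      eps <- if (noise) stats::rnorm(ng, 0, oc$sigma) else 0
      as.numeric(oc$intercept + z %*% oc$beta_ilr +
                   cov_coded %*% oc$cov_effects[colnames(cov_coded)] + eps)
    })

    recs[[g]] <- data.frame(
      participant_id = sprintf("%s%04d", toupper(substr(g, 1, 1)), seq_len(ng)),
      age = age, sex = sex,
      bmi_z = out_vals$bmi_z,
      fm_pct = out_vals$fm_pct,
      # FMI floored at a small positive value so the derived fat mass stays
      # physical; affects only the far Gaussian tail
      fat_mass_kg = pmax(out_vals$fmi, 0.05) * height_m^2,
      height_m = height_m,
      vat_cm2 = out_vals$vat_cm2,
      maternal_bmi = maternal_bmi,
      maternal_edu = maternal_edu,
      snacks,
      sleep = comps[, "sleep"], sb = comps[, "sb"],
      lpa = comps[, "lpa"], mvpa = comps[, "mvpa"],
      mean_wear_hours = mean_wear,
      stringsAsFactors = FALSE
    )
  }
  ppl <- do.call(rbind, recs)
  rownames(ppl) <- NULL
  ppl$fmi <- derive_fmi(ppl$fat_mass_kg, ppl$height_m)
  ppl$snacking <- classify_snacking(
    ppl[, c("snack_sweets", "snack_softdrinks", "snack_crisps")])
  ppl$age_group <- age_group(ppl$age)

  if (mcar) ppl <- inject_mcar(ppl, config$mcar_rates,
                               seed = sub_seed(config$seed, 50))

  day_tab <- NULL
  if (days) day_tab <- gen_day_table(ppl, basis, seed = sub_seed(config$seed, 60))

  truth <- structure(list(
    outcomes = config$outcomes,
    sbp = basis$sbp,
    mu_z = config$mu_z,
    ilr_cov = config$ilr_cov,
    comp_r2 = config$comp_r2,
    mcar_rates = config$mcar_rates,
    seed = config$seed
  ), class = "synthetic_truth")

  list(cohort = as_cohort(ppl, provenance = list(source = "synthetic",
                                                 seed = config$seed)),
       days = day_tab, truth = truth)
}

# 7 measurement days per participant (5 weekday, 2 weekend) with small
# Gaussian jitter around the weekly profile in ilr space and near-complete
# wear; exercises the ingestion filters end to end.
gen_day_table <- function(ppl, basis, seed = NULL, day_sd = 0.15) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ppl)
  z0 <- ilr_coords(as_comp_matrix(ppl[, behavior_parts()]), basis)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    zi <- matrix(rep(z0[i, ], each = 7L), nrow = 7L) +
      matrix(stats::rnorm(21L, 0, day_sd), nrow = 7L)
    hday <- ilr_inverse(zi, basis, total = 24)
    rows[[i]] <- data.frame(
      participant_id = ppl$participant_id[i],
      day_type = c(rep("weekday", 5L), rep("weekend", 2L)),
      wear_hours = pmin(24, pmax(16, 24 - abs(stats::rnorm(7L, 0, 0.3)))),
      sleep_h = hday[, "sleep"], sb_h = hday[, "sb"],
      lpa_h = hday[, "lpa"], mvpa_h = hday[, "mvpa"]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize generator ground truth to JSON
#'
#' @param truth A `synthetic_truth` object from [gen_cohort()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
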
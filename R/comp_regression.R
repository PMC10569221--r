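# Numeric coding for the adjustment covariates. Already-numeric columns
# pass through; the standard dichotomies are coded explicitly so the sign
# convention is documented in one place.
code_covariate <- function(x, name) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  map <- switch(name,
    sex = c(girl = 0, boy = 1),
    snacking = c(low = 0, high = 1),
    maternal_edu = c("below-university" = 0, university = 1),
    NULL)
  if (is.null(map)) {
    lev <- sort(unique(stats::na.omit(x)))
    if (length(lev) > 2L)
      stop("covariate '", name, "' is non-numeric with >2 levels; code it numerically first")
    map <- stats::setNames(seq_along(lev) - 1, lev)
  }
  unknown <- setdiff(unique(stats::na.omit(x)), names(map))
  if (length(unknown) > 0L)
    stop("covariate '", name, "' has unknown level '", unknown[1L], "'")
  as.numeric(map[x])
}

participants_of <- function(x) {
  if (inherits(x, "cohort")) x$participants else as.data.frame(x)
}

#' Fit a compositional linear regression
#'
#' Regresses an adiposity outcome on the three ilr coordinates of the 24-h
#' behaviour composition plus adjustment covariates, by ordinary least
#' squares (QR decomposition via [stats::lm()]). Fitted values, the residual
#' sum of squares, and all block tests are invariant to the SBP behind
#' `basis`; only the individual ilr coefficients depend on it.
#'
#' @param data A `cohort` or data frame containing the composition columns
#'   `sleep`,`sb`,`lpa`,`mvpa` (hours), the outcome and the covariates.
#' @param outcome Name of the outcome column (e.g. "vat_cm2", "fm_pct").
#' @param basis A `contrast_basis`.
#' @param covariates Covariate column names; defaults to the standard
#'   adjustment set (sex, maternal BMI, maternal education, snacking).
#' @param include_log_wear If `TRUE`, adds log(mean wear hours) as a
#'   sensitivity covariate (column `mean_wear_hours` required).
#' @return An object of class `comp_lm`: the underlying `lm` fit plus the
#'   basis, the analysis-sample compositions, coded covariates and their
#'   means, `n`, `rss` and `df_resid`.
#' @export
fit_comp_lm <- function(data, outcome,
                        basis = make_contrast_basis(),
                        covariates = c("sex", "maternal_bmi", "maternal_edu", "snacking"),
                        include_log_wear = FALSE) {
  df <- participants_of(data)
  need <- c(behavior_parts(), outcome, covariates,
            if (include_log_wear) "mean_wear_hours")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))

  comps <- as_comp_matrix(df[, behavior_parts()])
  z <- ilr_coords(comps, basis)
  cov_mat <- if (length(covariates) > 0L) {
    m <- vapply(covariates, function(cc) code_covariate(df[[cc]], cc),
                numeric(nrow(df)))
    m <- matrix(m, nrow = nrow(df), dimnames = list(NULL, covariates))
    m
  } else NULL
  frame <- data.frame(.outcome = as.numeric(df[[outcome]]), z,
                      check.names = FALSE)
  if (!is.null(cov_mat)) frame <- cbind(frame, as.data.frame(cov_mat))
  if (include_log_wear) frame$log_wear <- log(as.numeric(df$mean_wear_hours))

  keep <- stats::complete.cases(frame)
  frame <- frame[keep, , drop = FALSE]
  comps <- comps[keep, , drop = FALSE]
  n <- nrow(frame)
  p <- ncol(frame)  # intercept + (p - 1) predictors
  if (n <= p) stop("too few complete observations (n = ", n, ") for ", p, " coefficients")

  fit <- stats::lm(.outcome ~ ., data = frame)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- stats::residuals(fit)
  pred_cols <- setdiff(names(frame), ".outcome")
  cov_names <- c(covariates, if (include_log_wear) "log_wear")
  structure(list(
    model = fit,
    outcome_name = outcome,
    basis = basis,
    covariates = cov_names,
    include_log_wear = include_log_wear,
    n = n,
    rss = sum(res^2),
    df_resid = fit$df.residual,
    coefficients = stats::coef(fit),
    covariate_means = if (length(cov_names) > 0L)
      colMeans(frame[, cov_names, drop = FALSE]) else numeric(0),
    compositions = comps,
    frame = frame,
    participant_id = if ("participant_id" %in% names(df))
      df$participant_id[keep] else seq_len(nrow(df))[keep]
  ), class = "comp_lm")
}

#' @export
print.comp_lm <- function(x, ...) {
  cat("compositional linear model: ", x$outcome_name, " ~ ilr(z1,z2,z3)",
      if (length(x$covariates) > 0L) paste0(" + ", paste(x$covariates, collapse = " + ")),
      "\n  n = ", x$n, ", residual df = ", x$df_resid,
      ", RSS = ", format(x$rss, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Type III F-test for the ilr coordinate block
#'
#' Tests whether the 24-h composition is associated with the outcome after
#' covariate adjustment, i.e. the joint null that all three ilr slopes are
#' zero. With no interactions in the model this partial (full-vs-reduced)
#' F-test is exactly the Type III test for the block. Two algebraically
#' equivalent routes are implemented: refitting the reduced model without
#' the ilr columns ("reduced", default), and the general linear hypothesis
#' form on the full-model coefficient covariance ("glh").
#'
#' @param fit A `comp_lm` fit.
#' @param method "reduced" or "glh".
#' @return An `ilr_ftest` object: list with `statistic`, `df1`, `df2`,
#'   `p.value`, `method` and `exact_fit` (TRUE when the full model has zero
#'   residual, in which case F is infinite and p = 0).
#' @export
type3_ilr_ftest <- function(fit, method = c("reduced", "glh")) {
  stopifnot(inherits(fit, "comp_lm"))
  method <- match.arg(method)
  zcols <- colnames(fit$basis$matrix)
  df1 <- length(zcols)
  df2 <- fit$df_resid
  scale <- mean(fit$frame$.outcome^2) + 1e-300
  exact <- fit$rss <= 1e-12 * fit$n * scale
  if (exact) {
    out <- list(statistic = Inf, df1 = df1, df2 = df2, p.value = 0,
                method = method, exact_fit = TRUE)
    return(structure(out, class = "ilr_ftest"))
  }
  if (method == "reduced") {
    red_frame <- fit$frame[, setdiff(names(fit$frame), zcols), drop = FALSE]
    red <- stats::lm(.outcome ~ ., data = red_frame)
    if (anyNA(stats::coef(red)))
      stop("reduced model is rank deficient")
    rss_red <- sum(stats::residuals(red)^2)
    f <- ((rss_red - fit$rss) / df1) / (fit$rss / df2)
    f <- max(f, 0)  # guard tiny negative from rounding
  } else {
    b <- fit$coefficients[zcols]
    V <- stats::vcov(fit$model)[zcols, zcols, drop = FALSE]
    f <- as.numeric(crossprod(b, solve(V, b))) / df1
  }
  structure(list(statistic = f, df1 = df1, df2 = df2,
                 p.value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 method = method, exact_fit = FALSE),
            class = "ilr_ftest")
}

#' @export
print.ilr_ftest <- function(x, ...) {
  cat(sprintf("ilr block F-test: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df1, x$df2, x$statistic, x$p.value,
              if (x$exact_fit) " [exact fit]" else ""))
  invisible(x)
}

#' Predict the outcome at a composition and covariate profile
#'
#' @param fit A `comp_lm` fit.
#' @param comp A composition (vector) or matrix of compositions (hours; any
#'   positive scale, closure is implicit in the ilr transform).
#' @param profile Named numeric vector of covariate values on the coded
#'   scale (e.g. `sex = 1` for boys). Defaults to the analysis-sample means
#'   stored in the fit. Must cover every covariate in the model.
#' @return Numeric vector of predicted outcome values.
#' @export
predict_at <- function(fit, comp, profile = NULL) {
  stopifnot(inherits(fit, "comp_lm"))
  if (is.null(profile)) profile <- fit$covariate_means
  missing_cov <- setdiff(fit$covariates, names(profile))
  if (length(missing_cov) > 0L)
    stop("profile is missing covariate(s): ", paste(missing_cov, collapse = ", "))
  z <- ilr_coords(comp, fit$basis)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L, dimnames = list(NULL, names(z)))
  nd <- as.data.frame(z)
  for (cc in fit$covariates) nd[[cc]] <- as.numeric(profile[[cc]])
  as.numeric(stats::predict(fit$model, newdata = nd))
}

#' Compare two groups of compositions by MANOVA on ilr coordinates
#'
#' One-way MANOVA of the 3 ilr coordinates on group membership, reported as
#' Pillai's trace with its F approximation. The statistic is invariant to
#' the SBP because different bases are orthogonal rotations of each other.
#'
#' @param group_a,group_b Matrices (or data frames) of compositions, one
#'   per row.
#' @param basis A `contrast_basis`.
#' @return List with `pillai`, `statistic` (approximate F), `df1`, `df2`
#'   and `p.value`.
#' @export
compare_compositions_manova <- function(group_a, group_b,
                                        basis = make_contrast_basis()) {
  a <- as_comp_matrix(group_a, basis$parts)
  b <- as_comp_matrix(group_b, basis$parts)
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("each group needs at least 2 compositions")
  if (nrow(a) + nrow(b) <= 5L)
    stop("combined sample size must exceed 5")
  z <- ilr_coords(rbind(a, b), basis)
  g <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))))
  fit <- stats::manova(z ~ g)
  s <- summary(fit, test = "Pillai")$stats
  list(pillai = unname(s["g", "Pillai"]),
       statistic = unname(s["g", "approx F"]),
       df1 = unname(s["g", "num Df"]),
       df2 = unname(s["g", "den Df"]),
       p.value = unname(s["g", "Pr(>F)"]))
}
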
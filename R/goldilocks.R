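#' Predict the outcome at every empirical composition
#'
#' Predictions are made only at compositions observed in the analysis
#' sample, avoiding extrapolation beyond the sampled region of the simplex.
#' By default covariates are fixed at the analysis-sample means stored in
#' the fit ("mean" profile); with `profile = "observed"` each participant's
#' own covariates are used instead. Under the mean profile (or any fixed
#' profile) changing the profile shifts every prediction by the same
#' constant, so percentile-based healthy-set membership is unaffected.
#'
#' @param fit A `comp_lm` fit.
#' @param profile "mean" (default), "observed", or a named numeric vector
#'   of coded covariate values.
#' @return Numeric vector of predictions, one per analysis-sample
#'   composition (in the fit's row order).
#' @export
predict_empirical <- function(fit, profile = "mean") {
  stopifnot(inherits(fit, "comp_lm"))
  if (nrow(fit$compositions) == 0L) stop("fit has an empty analysis sample")
  if (identical(profile, "observed")) {
    nd <- fit$frame[, setdiff(names(fit$frame), ".outcome"), drop = FALSE]
    return(as.numeric(stats::predict(fit$model, newdata = nd)))
  }
  prof <- if (identical(profile, "mean")) fit$covariate_means else profile
  predict_at(fit, fit$compositions, profile = prof)
}

#' Healthy-set membership from a percentile threshold
#'
#' Marks predictions strictly below the `pct`-th percentile as healthy
#' (for outcomes where low is healthy; `direction = "high"` flips the rule
#' to strictly above the `100 - pct` percentile). The percentile is the
#' linear interpolation of order statistics, h = (n - 1) p + 1
#' ([stats::quantile()] type 7).
#'
#' @param predictions Numeric vector of predicted outcome values.
#' @param pct Percentile threshold in (0, 100); default 85.
#' @param direction "low" when low outcome values are healthy (default),
#'   "high" otherwise.
#' @return List with `mask` (logical vector), `threshold` and `pct`.
#' @export
healthy_set <- function(predictions, pct = 85, direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(predictions), pct > 0, pct < 100)
  if (length(unique(predictions)) < 2L)
    stop("all predictions are identical; no healthy set is definable")
  if (direction == "low") {
    thr <- unname(stats::quantile(predictions, pct / 100, type = 7))
    mask <- predictions < thr
  } else {
    thr <- unname(stats::quantile(predictions, 1 - pct / 100, type = 7))
    mask <- predictions > thr
  }
  if (!any(mask)) stop("healthy set is empty at the ", pct, "th percentile")
  list(mask = mask, threshold = thr, pct = pct, direction = direction)
}

#' The Goldilocks Day: compositional mean of the healthy set
#'
#' Given the analysis-sample compositions, their predicted outcomes and the
#' healthy-set mask, returns the compositional mean of the healthy
#' compositions (the Goldilocks Day), the per-behaviour min-max ranges and
#' predicted-outcome range over the healthy set, and the model prediction
#' at the Goldilocks composition itself.
#'
#' @param comps Matrix of compositions (one per row, hours).
#' @param predictions Numeric vector of predicted outcomes, same length.
#' @param mask Logical healthy-set mask (or the list from [healthy_set()]).
#' @param fit Optional `comp_lm`; when supplied, `outcome_at_goldilocks` is
#'   computed with the fit's mean covariate profile.
#' @param threshold Optional threshold to record (taken from `mask` when it
#'   is a [healthy_set()] result).
#' @return An object of class `goldilocks_result`.
#' @export
goldilocks_day <- function(comps, predictions, mask, fit = NULL, threshold = NULL) {
  if (is.list(mask)) { threshold <- mask$threshold; mask <- mask$mask }
  m <- as_comp_matrix(comps)
  stopifnot(length(mask) == nrow(m), length(predictions) == nrow(m))
  if (!any(mask)) stop("healthy set is empty")
  healthy <- m[mask, , drop = FALSE]
  gday <- comp_mean(healthy, total = 24)
  ranges <- apply(healthy, 2L, range)
  rownames(ranges) <- c("min", "max")
  structure(list(
    threshold = threshold,
    n_healthy = sum(mask),
    n_total = length(mask),
    goldilocks = gday,
    part_ranges = ranges,
    outcome_range = range(predictions[mask]),
    outcome_at_goldilocks = if (!is.null(fit)) predict_at(fit, gday) else NA_real_,
    outcome_name = if (!is.null(fit)) fit$outcome_name else NA_character_
  ), class = "goldilocks_result")
}

#' @export
print.goldilocks_result <- function(x, digits = 1, ...) {
  cat("Goldilocks Day (compositional mean of ", x$n_healthy, "/", x$n_total,
      " healthy compositions)\n", sep = "")
  for (p in names(x$goldilocks)) {
    cat(sprintf("  %-6s %5.*f h  (range %.*f-%.*f)\n", p,
                digits, x$goldilocks[[p]],
                digits, x$part_ranges["min", p], digits, x$part_ranges["max", p]))
  }
  if (!is.na(x$outcome_at_goldilocks))
    cat(sprintf("  predicted %s at Goldilocks Day: %.*f (healthy range %.*f-%.*f)\n",
                x$outcome_name, digits, x$outcome_at_goldilocks,
                digits, x$outcome_range[1], digits, x$outcome_range[2]))
  invisible(x)
}

#' Tidy one-row-per-behaviour summary of a Goldilocks result
#'
#' @param result A `goldilocks_result`.
#' @param digits Rounding for the reported columns (default 1, i.e. 0.1 h);
#'   use `NULL` for full precision.
#' @return Data frame with columns `behavior`, `compositional_mean`,
#'   `range_min`, `range_max`, plus an outcome row when available.
#' @export
goldilocks_table <- function(result, digits = 1) {
  stopifnot(inherits(result, "goldilocks_result"))
  rnd <- function(x) if (is.null(digits)) x else round(x, digits)
  df <- data.frame(
    behavior = names(result$goldilocks),
    compositional_mean = rnd(unname(result$goldilocks)),
    range_min = rnd(result$part_ranges["min", ]),
    range_max = rnd(result$part_ranges["max", ]),
    row.names = NULL
  )
  if (!is.na(result$outcome_at_goldilocks)) {
    df <- rbind(df, data.frame(
      behavior = paste0("outcome:", result$outcome_name),
      compositional_mean = rnd(result$outcome_at_goldilocks),
      range_min = rnd(result$outcome_range[1]),
      range_max = rnd(result$outcome_range[2])))
  }
  df
}

#' Vertices of the unit-edge regular tetrahedron
#'
#' Row i is the apex at which behaviour i occupies the full 24 h.
#'
#' @param parts Part names labelling the rows.
#' @return 4x3 matrix of x, y, z coordinates.
#' @export
tetra_vertices <- function(parts = behavior_parts()) {
  v <- rbind(c(0, 0, 0),
             c(1, 0, 0),
             c(1 / 2, sqrt(3) / 2, 0),
             c(1 / 2, sqrt(3) / 6, sqrt(6) / 3))
  dimnames(v) <- list(parts, c("x", "y", "z"))
  v
}

#' Barycentric tetrahedron coordinates of compositions
#'
#' Maps each 4-part composition to the point of the regular tetrahedron
#' whose barycentric weights are the part proportions; a behaviour at 100%
#' of the day sits exactly on its apex, and the equal-parts day sits at the
#' centroid.
#'
#' @param comp Composition vector or matrix (hours; proportions are parts
#'   divided by their sum).
#' @param value Optional numeric vector (e.g. predicted outcome) attached
#'   as a `value` column.
#' @return Data frame with columns `x`, `y`, `z` (and `value` if given).
#' @export
tetra_coords <- function(comp, value = NULL) {
  m <- as_comp_matrix(comp)
  if (ncol(m) != 4L) stop("tetrahedron coordinates require 4-part compositions")
  if (any(!is.finite(m) | m < 0)) stop("parts must be non-negative and finite")
  props <- m / rowSums(m)
  pts <- props %*% tetra_vertices(colnames(m))
  out <- as.data.frame(pts)
  if (!is.null(value)) {
    stopifnot(length(value) == nrow(out))
    out$value <- as.numeric(value)
  }
  out
}

#' Export a tetrahedron point cloud as JSON
#'
#' Writes the labelled apex coordinates and one record per point (x, y, z
#' and outcome value) to a JSON file suitable for any 3-D scatter viewer.
#'
#' @param points Data frame from [tetra_coords()] (columns x, y, z and
#'   optionally value).
#' @param path Output file path.
#' @param parts Apex labels.
#' @param meta Optional named list of metadata stored under `meta`.
#' @return Invisibly, `path`.
#' @export
export_tetra <- function(points, path, parts = behavior_parts(), meta = list()) {
  stopifnot(is.data.frame(points), nrow(points) > 0L,
            all(c("x", "y", "z") %in% names(points)))
  v <- tetra_vertices(parts)
  payload <- list(
    vertices = data.frame(label = rownames(v), as.data.frame(v), row.names = NULL),
    points = points,
    meta = meta
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' End-to-end Goldilocks estimation from a fitted model
#'
#' Convenience wrapper: predicts at every empirical composition, applies
#' the percentile rule, and returns the Goldilocks Day.
#'
#' @inheritParams predict_empirical
#' @inheritParams healthy_set
#' @return A `goldilocks_result`.
#' @export
estimate_goldilocks <- function(fit, pct = 85, direction = c("low", "high"),
                                profile = "mean") {
  direction <- match.arg(direction)
  preds <- predict_empirical(fit, profile = profile)
  hs <- healthy_set(preds, pct = pct, direction = direction)
  goldilocks_day(fit$compositions, preds, hs, fit = fit)
}
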
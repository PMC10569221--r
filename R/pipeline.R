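#' Descriptive characteristics table with between-group tests
#'
#' Per age group: mean (SD) for continuous variables, count (%) for
#' categorical ones, and the compositional mean of the behaviours.
#' Between-group comparisons use Welch t-tests (or Kruskal-Wallis where
#' configured) for continuous variables, chi-squared tests for categorical
#' ones, and MANOVA on the ilr coordinates for the composition.
#'
#' @param cohort A `cohort`.
#' @param continuous Continuous variable names present in the participant
#'   table.
#' @param categorical Categorical variable names.
#' @param kruskal Character vector naming continuous variables to test with
#'   Kruskal-Wallis instead of the t-test.
#' @param basis A `contrast_basis` for the composition MANOVA.
#' @return Data frame with columns `variable`, `overall`, one column per
#'   group, and `p_value` (NA where no test applies).
#' @export
describe_sample <- function(cohort,
                            continuous = c("age", "bmi_z", "fm_pct", "fmi",
                                           "vat_cm2", "maternal_bmi",
                                           "mean_wear_hours"),
                            categorical = c("sex", "maternal_edu", "snacking"),
                            kruskal = character(),
                            basis = make_contrast_basis()) {
  df <- participants_of(cohort)
  stopifnot(nrow(df) > 0L)
  groups <- levels(droplevels(factor(df$age_group)))
  two <- length(groups) == 2L
  fmt_ms <- function(x) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                                stats::sd(x, na.rm = TRUE))
  rows <- list()
  add <- function(variable, overall, by_group, p = NA_real_) {
    r <- data.frame(variable = variable, overall = overall,
                    t(stats::setNames(by_group, groups)), p_value = p,
                    check.names = FALSE)
    rows[[length(rows) + 1L]] <<- r
  }
  add("n", as.character(nrow(df)),
      vapply(groups, function(g) as.character(sum(df$age_group == g)), ""))
  for (v in intersect(continuous, names(df))) {
    x <- df[[v]]
    by_g <- vapply(groups, function(g) fmt_ms(x[df$age_group == g]), "")
    p <- NA_real_
    if (two) {
      p <- if (v %in% kruskal)
        stats::kruskal.test(x, factor(df$age_group))$p.value
      else stats::t.test(x ~ factor(df$age_group))$p.value
    }
    add(v, fmt_ms(x), by_g, p)
  }
  for (v in intersect(categorical, names(df))) {
    x <- factor(df[[v]])
    lev <- levels(x)[length(levels(x))]  # report the last level's share
    fmt_ct <- function(idx) sprintf("%d (%.1f%%)", sum(x[idx] == lev, na.rm = TRUE),
                                    100 * mean(x[idx] == lev, na.rm = TRUE))
    p <- if (two && length(unique(stats::na.omit(x))) > 1L)
      suppressWarnings(stats::chisq.test(table(df$age_group, x))$p.value)
    else NA_real_
    add(paste0(v, " [", lev, "]"), fmt_ct(rep(TRUE, nrow(df))),
        vapply(groups, function(g) fmt_ct(df$age_group == g), ""), p)
  }
  comps <- as_comp_matrix(df[, behavior_parts()])
  cm_all <- comp_mean(comps)
  cm_g <- lapply(groups, function(g) comp_mean(comps[df$age_group == g, , drop = FALSE]))
  p_comp <- NA_real_
  if (two && all(vapply(cm_g, length, 0L) == 4L) &&
      min(table(df$age_group)) >= 2L) {
    p_comp <- compare_compositions_manova(
      comps[df$age_group == groups[1], , drop = FALSE],
      comps[df$age_group == groups[2], , drop = FALSE], basis)$p.value
  }
  for (k in seq_along(behavior_parts())) {
    part <- behavior_parts()[k]
    add(paste0("comp_mean_", part), sprintf("%.2f", cm_all[[part]]),
        vapply(cm_g, function(m) sprintf("%.2f", m[[part]]), ""),
        if (k == 1L) p_comp else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a pipeline configuration
#'
#' @param day_file,participant_file Input tables for [read_cohort()], or
#'   `NULL` to simulate a cohort from `generator`.
#' @param generator A `generator_config` used when no input files are given.
#' @param outcomes Outcome columns to analyse.
#' @param covariates Adjustment covariates.
#' @param alpha Significance gate for proceeding to Goldilocks estimation.
#' @param percentile Healthy-set percentile threshold.
#' @param include_log_wear Also fit the wear-time sensitivity models.
#' @param adjust_p `"none"` (default, matching the unadjusted reporting of
#'   the 8 outcome-by-group tests) or `"BH"` for Benjamini-Hochberg.
#' @param sbp Sequential binary partition for the ilr basis.
#' @param out_dir Output directory (`NULL` for no file output).
#' @param seed Integer seed (used only when simulating).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(day_file = NULL, participant_file = NULL,
                            generator = NULL,
                            outcomes = c("bmi_z", "fm_pct", "fmi", "vat_cm2"),
                            covariates = c("sex", "maternal_bmi",
                                           "maternal_edu", "snacking"),
                            alpha = 0.05, percentile = 85,
                            include_log_wear = FALSE,
                            adjust_p = c("none", "BH"),
                            sbp = default_sbp(),
                            out_dir = NULL, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, percentile > 0, percentile < 100)
  structure(list(day_file = day_file, participant_file = participant_file,
                 generator = generator, outcomes = outcomes,
                 covariates = covariates, alpha = alpha,
                 percentile = percentile,
                 include_log_wear = isTRUE(include_log_wear),
                 adjust_p = match.arg(adjust_p),
                 sbp = sbp, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; a
#' `generator` block is forwarded to [generator_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) {
    gc_args <- y$generator
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
    names(gc_args)[names(gc_args) %in% c("FALSE", "no")] <- "n"
    if (!is.null(gc_args$n)) gc_args$n <- unlist(gc_args$n)
    if (!is.null(gc_args$target_mean))
      gc_args$target_mean <- lapply(gc_args$target_mean, unlist)
    if (!is.null(gc_args$high_snacking_prop))
      gc_args$high_snacking_prop <- unlist(gc_args$high_snacking_prop)
    if (!is.null(gc_args$mcar_rates)) gc_args$mcar_rates <- unlist(gc_args$mcar_rates)
    y$generator <- do.call(generator_config, gc_args)
  }
  do.call(pipeline_config, y)
}

# hash of the analysis-defining configuration (output location excluded)
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(lapply(x, function(v)
    if (is.function(v)) "function" else v), force = TRUE, digits = NA,
    auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full compositional time-use analysis pipeline
#'
#' Ingest (or simulate) -> inclusion filters -> complete-case restriction ->
#' stratification by age group -> descriptives -> compositional regression
#' and ilr-block F-test for each outcome in each group -> Goldilocks Day
#' estimation for every outcome-by-group cell that passes the significance
#' gate -> optional file export (descriptives, association table, Goldilocks
#' tables, tetrahedron point clouds, JSON report with provenance).
#'
#' @param config A `pipeline_config`.
#' @return A `run_report` list: `descriptives`, `associations` (and
#'   `associations_log_wear` for the sensitivity analysis), `goldilocks`
#'   (named list of `goldilocks_result`), `filter_log`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  basis <- make_contrast_basis(config$sbp)

  if (!is.null(config$day_file)) {
    cohort <- read_cohort(config$day_file, config$participant_file)
  } else {
    gen <- if (!is.null(config$generator)) config$generator
           else generator_config(seed = config$seed)
    cohort <- gen_cohort(gen, days = FALSE)$cohort
  }

  cohort <- complete_case(cohort, c(config$outcomes, config$covariates,
                                    behavior_parts()))
  df <- cohort$participants
  groups <- c("children", "adolescents")
  groups <- groups[groups %in% df$age_group]

  descriptives <- describe_sample(cohort, basis = basis)

  fit_cells <- function(log_wear) {
    assoc <- list(); fits <- list()
    for (g in groups) {
      sub <- df[df$age_group == g, , drop = FALSE]
      for (oc in config$outcomes) {
        fit <- fit_comp_lm(sub, oc, basis = basis,
                           covariates = config$covariates,
                           include_log_wear = log_wear)
        ft <- type3_ilr_ftest(fit)
        key <- paste(g, oc, sep = ".")
        fits[[key]] <- fit
        assoc[[key]] <- data.frame(
          group = g, outcome = oc, n = fit$n,
          f = ft$statistic, df1 = ft$df1, df2 = ft$df2, p = ft$p.value)
      }
    }
    assoc <- do.call(rbind, assoc)
    rownames(assoc) <- NULL
    if (config$adjust_p == "BH") assoc$p_adj <- stats::p.adjust(assoc$p, "BH")
    list(assoc = assoc, fits = fits)
  }

  main <- fit_cells(FALSE)  # main models never include wear time
  associations <- main$assoc
  assoc_wear <- if (config$include_log_wear) fit_cells(TRUE)$assoc else NULL

  gate_p <- if (config$adjust_p == "BH") associations$p_adj else associations$p
  gold <- list()
  for (i in seq_len(nrow(associations))) {
    if (gate_p[i] < config$alpha) {
      key <- paste(associations$group[i], associations$outcome[i], sep = ".")
      gold[[key]] <- estimate_goldilocks(main$fits[[key]],
                                         pct = config$percentile)
    }
  }

  report <- structure(list(
    descriptives = descriptives,
    associations = associations,
    associations_log_wear = assoc_wear,
    goldilocks = gold,
    fits = main$fits,
    filter_log = cohort$filter_log,
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      alpha = config$alpha, percentile = config$percentile,
                      n_analysis = nrow(df), timestamp = format(Sys.time()))
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("compositional time-use analysis (n =", x$provenance$n_analysis, ")\n")
  cat("\nAssociations (ilr block F-test):\n")
  print(transform(x$associations, f = round(f, 3), p = round(p, 4)),
        row.names = FALSE)
  if (length(x$goldilocks) == 0L) {
    cat("\nNo outcome passed the significance gate; no Goldilocks Day estimated.\n")
  } else {
    for (key in names(x$goldilocks)) {
      cat("\nGoldilocks Day for ", key, ":\n", sep = "")
      print(x$goldilocks[[key]])
    }
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits delimited tables (descriptives, associations, Goldilocks tables),
#' a tetrahedron JSON point cloud per significant cell, and a JSON report
#' with provenance (config hash and seed embedded in every JSON artifact).
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$descriptives, "descriptives.csv")
  wr(report$associations, "associations.csv")
  if (!is.null(report$associations_log_wear))
    wr(report$associations_log_wear, "associations_log_wear.csv")
  gold_json <- list()
  for (key in names(report$goldilocks)) {
    gr <- report$goldilocks[[key]]
    wr(goldilocks_table(gr), paste0("goldilocks_", gsub("\\.", "_", key), ".csv"))
    gold_json[[key]] <- list(
      threshold = gr$threshold, n_healthy = gr$n_healthy,
      goldilocks = as.list(gr$goldilocks),
      part_ranges = as.data.frame(gr$part_ranges),
      outcome_range = gr$outcome_range,
      outcome_at_goldilocks = gr$outcome_at_goldilocks)
    fit <- report$fits[[key]]
    preds <- predict_empirical(fit)
    tp <- file.path(dir, paste0("tetra_", gsub("\\.", "_", key), ".json"))
    export_tetra(tetra_coords(fit$compositions, value = preds), tp,
                 meta = c(report$provenance[c("config_hash", "seed")],
                          list(cell = key, outcome = fit$outcome_name)))
    paths <- c(paths, tp)
  }
  rp <- file.path(dir, "report.json")
  jsonlite::write_json(list(
    provenance = report$provenance,
    filter_log = report$filter_log,
    associations = report$associations,
    associations_log_wear = report$associations_log_wear,
    goldilocks = gold_json
  ), rp, digits = NA, auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  paths <- c(paths, rp)
  invisible(paths)
}
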
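# Header contracts for the two input tables. Unknown columns are kept as
# passthrough; missing required columns are a hard schema error.
DAY_COLUMNS <- c("participant_id", "day_type", "wear_hours",
                 "sleep_h", "sb_h", "lpa_h", "mvpa_h")
PARTICIPANT_COLUMNS <- c("participant_id", "age", "sex", "bmi_z", "fm_pct",
                         "fat_mass_kg", "height_m", "vat_cm2",
                         "maternal_bmi", "maternal_edu",
                         "snack_sweets", "snack_softdrinks", "snack_crisps")

SNACK_LEVELS <- c("never", "less than once a week", "once a week",
                  "2-4 times a week", "5-6 times a week",
                  "once a day (everyday)", "more than once every day")
SNACK_DAILY <- c("once a day (everyday)", "more than once every day")

#' Is a measurement day valid for inclusion?
#'
#' A day counts towards inclusion when the accelerometer was worn for at
#' least `min_wear` hours (16 h by default, boundary inclusive).
#'
#' @param wear_hours Numeric vector of daily wear time in hours.
#' @param min_wear Minimum wear time in hours (default 16).
#' @return Logical vector.
#' @export
valid_day <- function(wear_hours, min_wear = 16) {
  stopifnot(is.numeric(wear_hours))
  if (any(!is.na(wear_hours) & (wear_hours < 0 | wear_hours > 24)))
    stop("wear_hours must lie in [0, 24]")
  !is.na(wear_hours) & wear_hours >= min_wear
}

#' Does a participant meet the inclusion rule?
#'
#' Inclusion requires at least `min_days` valid days of which at least
#' `min_weekend` fall on a weekend.
#'
#' @param days Data frame of one participant's days with columns
#'   `day_type` ("weekday"/"weekend") and `wear_hours`.
#' @param min_days Minimum number of valid days (default 4).
#' @param min_weekend Minimum number of valid weekend days (default 1).
#' @param min_wear Minimum daily wear time in hours (default 16).
#' @return `TRUE` or `FALSE`.
#' @export
include_participant <- function(days, min_days = 4, min_weekend = 1, min_wear = 16) {
  if (is.null(days) || nrow(days) == 0L) {
    warning("participant has no measurement days; excluded")
    return(FALSE)
  }
  ok <- valid_day(days$wear_hours, min_wear = min_wear)
  sum(ok) >= min_days && sum(ok & days$day_type == "weekend") >= min_weekend
}

#' Weekday/weekend-weighted weekly average composition
#'
#' Averages each behaviour over valid weekdays and valid weekend days
#' separately, combines them as (weekday mean x 5 + weekend mean x 2) / 7,
#' and closes the result to 24 h.
#'
#' @param days Data frame of one participant's valid days with columns
#'   `day_type`, `sleep_h`, `sb_h`, `lpa_h`, `mvpa_h`.
#' @return Named composition vector (hours) summing to 24.
#' @export
weekly_average <- function(days) {
  beh <- c("sleep_h", "sb_h", "lpa_h", "mvpa_h")
  stopifnot(all(c("day_type", beh) %in% names(days)))
  wd <- days[days$day_type == "weekday", beh, drop = FALSE]
  we <- days[days$day_type == "weekend", beh, drop = FALSE]
  if (nrow(wd) == 0L || nrow(we) == 0L)
    stop("weekly_average needs at least one valid weekday and one valid weekend day")
  avg <- (colMeans(wd) * 5 + colMeans(we) * 2) / 7
  names(avg) <- behavior_parts()
  close_comp(avg, total = 24)
}

#' Fat mass index from fat mass and height
#'
#' FMI (kg/m^2) is fat mass in kilograms divided by height in metres squared.
#'
#' @param fat_mass_kg Fat mass in kg (non-negative).
#' @param height_m Height in metres (strictly positive).
#' @return FMI in kg/m^2.
#' @export
derive_fmi <- function(fat_mass_kg, height_m) {
  if (any(!is.na(height_m) & height_m <= 0)) stop("height_m must be > 0")
  if (any(!is.na(fat_mass_kg) & fat_mass_kg < 0)) stop("fat_mass_kg must be >= 0")
  fat_mass_kg / height_m^2
}

normalize_snack <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("–|—", "-", x)  # en/em dash -> hyphen
  gsub("\\s+", " ", x)
}

#' Classify unhealthy snacking frequency
#'
#' A participant is a high-frequency snacker when at least one of the three
#' snack questions (sweets, sugary soft drinks, crisps) is answered with a
#' daily category ("once a day (everyday)" or "more than once every day").
#'
#' @param responses Character vector of 3 ordinal answers, or a matrix /
#'   data.frame with 3 columns (one participant per row). `NA` answers
#'   propagate to an `NA` classification unless another answer is daily.
#' @return "low" or "high" (vector for matrix input).
#' @export
classify_snacking <- function(responses) {
  one <- function(r) {
    r <- normalize_snack(r)
    known <- is.na(r) | r %in% SNACK_LEVELS
    if (!all(known))
      stop("unknown snacking category: '", r[!known][1L], "'")
    if (any(r %in% SNACK_DAILY, na.rm = TRUE)) return("high")
    if (anyNA(r)) return(NA_character_)
    "low"
  }
  if (is.matrix(responses) || is.data.frame(responses)) {
    apply(as.matrix(responses), 1L, one)
  } else {
    one(responses)
  }
}

#' Assign age group from age in completed years
#'
#' Children are 8-13 years, adolescents 14-18 years (completed years, i.e.
#' `floor(age)`). Ages outside 8-18 are rejected.
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels "children", "adolescents".
#' @export
age_group <- function(age) {
  yrs <- floor(age)
  bad <- !is.na(yrs) & (yrs < 8 | yrs > 18)
  if (any(bad)) stop("age out of supported range 8-18: ", age[bad][1L])
  factor(ifelse(yrs <= 13, "children", "adolescents"),
         levels = c("children", "adolescents"))
}

read_table_checked <- function(path, required, sep = ",", what = "table") {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing required column(s) in ", what, " '", basename(path), "': ",
         paste(missing, collapse = ", "))
  df
}

#' Read a cohort from day-level and participant-level tables
#'
#' Reads the two delimited tables, applies the wear-time inclusion rule
#' (at least `min_wear` h/day on at least `min_days` days including
#' `min_weekend` weekend day), computes each retained participant's
#' weekday/weekend-weighted weekly composition, and derives the analysis
#' variables (FMI, snacking class, age group). Exclusions are recorded in
#' the cohort's filter log.
#'
#' @param day_file Path to the day-level table (columns `participant_id`,
#'   `day_type`, `wear_hours`, `sleep_h`, `sb_h`, `lpa_h`, `mvpa_h`).
#' @param participant_file Path to the participant table (see
#'   `PARTICIPANT_COLUMNS` in the package source for the contract).
#' @param sep Field separator ("," default, "\t" accepted).
#' @param minutes If `TRUE`, day-level durations and wear time are given in
#'   minutes and divided by 60 at ingest.
#' @param min_wear,min_days,min_weekend Inclusion rule parameters.
#' @return A `cohort` object: list with `participants` (data frame, one row
#'   per retained participant including composition columns
#'   `sleep`,`sb`,`lpa`,`mvpa` in hours), `filter_log` (character) and
#'   `provenance`.
#' @export
read_cohort <- function(day_file, participant_file, sep = ",", minutes = FALSE,
                        min_wear = 16, min_days = 4, min_weekend = 1) {
  days <- read_table_checked(day_file, DAY_COLUMNS, sep = sep, what = "day")
  ppl <- read_table_checked(participant_file, PARTICIPANT_COLUMNS, sep = sep,
                            what = "participant")
  if (anyDuplicated(ppl$participant_id)) {
    dup <- ppl$participant_id[duplicated(ppl$participant_id)][1L]
    stop("duplicate participant_id in participant table: ", dup)
  }
  num_cols <- c("wear_hours", "sleep_h", "sb_h", "lpa_h", "mvpa_h")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(days[[cc]]))
    bad <- which(is.na(v) & !is.na(days[[cc]]))
    if (length(bad) > 0L)
      stop("non-numeric value in day table column '", cc, "' at data row ",
           bad[1L], " (file line ", bad[1L] + 1L, ")")
    days[[cc]] <- if (minutes) v / 60 else v
  }
  if (!all(days$day_type %in% c("weekday", "weekend")))
    stop("day_type must be 'weekday' or 'weekend'")

  log <- character()
  logmsg <- function(...) sprintf(...)

  day_split <- split(days, days$participant_id)
  included <- vapply(ppl$participant_id, function(id) {
    d <- day_split[[as.character(id)]]
    if (is.null(d)) return(FALSE)
    suppressWarnings(include_participant(d, min_days = min_days,
                                         min_weekend = min_weekend,
                                         min_wear = min_wear))
  }, logical(1))
  log <- c(log, logmsg(
    "wear-time inclusion (>= %g h on >= %d days incl. >= %d weekend): %d of %d retained, %d excluded",
    min_wear, min_days, min_weekend, sum(included), nrow(ppl), sum(!included)))
  ppl <- ppl[included, , drop = FALSE]

  comp <- t(vapply(ppl$participant_id, function(id) {
    d <- day_split[[as.character(id)]]
    d <- d[valid_day(d$wear_hours, min_wear = min_wear), , drop = FALSE]
    weekly_average(d)
  }, numeric(4)))
  mean_wear <- vapply(ppl$participant_id, function(id) {
    d <- day_split[[as.character(id)]]
    mean(d$wear_hours[valid_day(d$wear_hours, min_wear = min_wear)])
  }, numeric(1))

  ppl$sleep <- comp[, "sleep"]; ppl$sb <- comp[, "sb"]
  ppl$lpa <- comp[, "lpa"]; ppl$mvpa <- comp[, "mvpa"]
  ppl$mean_wear_hours <- mean_wear
  ppl$fmi <- derive_fmi(ppl$fat_mass_kg, ppl$height_m)
  ppl$snacking <- classify_snacking(
    ppl[, c("snack_sweets", "snack_softdrinks", "snack_crisps")])
  ppl$age_group <- age_group(ppl$age)
  if (is.character(ppl$maternal_edu))
    ppl$maternal_edu <- ifelse(ppl$maternal_edu == "university", 1L,
                               ifelse(ppl$maternal_edu == "below-university", 0L, NA))
  rownames(ppl) <- NULL

  structure(list(
    participants = ppl,
    filter_log = log,
    provenance = list(day_file = day_file, participant_file = participant_file,
                      minutes = minutes, read_at = format(Sys.time()))
  ), class = "cohort")
}

#' Construct a cohort from an in-memory participant table
#'
#' @param participants Data frame with one row per participant, including
#'   composition columns `sleep`, `sb`, `lpa`, `mvpa` in hours.
#' @param filter_log Optional character vector of filtering messages.
#' @param provenance Optional provenance list.
#' @return A `cohort` object.
#' @export
as_cohort <- function(participants, filter_log = character(),
                      provenance = list(source = "in-memory")) {
  stopifnot(is.data.frame(participants),
            all(behavior_parts() %in% names(participants)))
  if (anyDuplicated(participants$participant_id))
    stop("duplicate participant_id")
  structure(list(participants = participants, filter_log = filter_log,
                 provenance = provenance), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  p <- x$participants
  cat("cohort: ", nrow(p), " participants (",
      sum(p$age_group == "children"), " children, ",
      sum(p$age_group == "adolescents"), " adolescents)\n", sep = "")
  for (l in x$filter_log) cat("  ", l, "\n", sep = "")
  invisible(x)
}

#' Complete-case restriction on selected covariates
#'
#' Drops participants with a missing value in any of the listed columns and
#' appends the exclusion count to the filter log. Missingness is assumed
#' MCAR so complete-case deletion is unbiased.
#'
#' @param cohort A `cohort`.
#' @param covariates Character vector of column names that must be observed.
#' @return The restricted `cohort`.
#' @export
complete_case <- function(cohort, covariates) {
  stopifnot(inherits(cohort, "cohort"))
  missing_cols <- setdiff(covariates, names(cohort$participants))
  if (length(missing_cols) > 0L)
    stop("unknown covariate column(s): ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(cohort$participants[, covariates, drop = FALSE])
  n0 <- nrow(cohort$participants)
  cohort$participants <- cohort$participants[keep, , drop = FALSE]
  rownames(cohort$participants) <- NULL
  cohort$filter_log <- c(cohort$filter_log, sprintf(
    "complete-case on {%s}: %d of %d retained, %d excluded",
    paste(covariates, collapse = ", "), sum(keep), n0, n0 - sum(keep)))
  if (sum(keep) == 0L) warning("complete_case removed every participant")
  cohort
}

#' Write cohort input tables to disk
#'
#' Writes a participant table and (optionally) a day-level table in the
#' exact format [read_cohort()] consumes; used by the synthetic generator
#' and for round-trip tests.
#'
#' @param participants Participant data frame.
#' @param days Optional day-level data frame.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_tables <- function(participants, days = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- file.path(dir, "participants.csv")
  utils::write.csv(participants, pf, row.names = FALSE, quote = TRUE)
  paths <- pf
  if (!is.null(days)) {
    df <- file.path(dir, "days.csv")
    utils::write.csv(days, df, row.names = FALSE, quote = TRUE)
    paths <- c(paths, df)
  }
  invisible(paths)
}
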
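# Shared fixture builders; everything is generated in code at test time.

# random strictly positive compositions (hours), one per row
random_comps <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(exp(rnorm(4L * n, 0, 0.8)), ncol = 4L,
              dimnames = list(NULL, behavior_parts()))
  close_comp(m, 24)
}

# an alternative valid SBP: ((sleep, sb) | (lpa, mvpa)), (sleep | sb), (lpa | mvpa)
alt_sbp <- function() {
  list(
    list(up = c("sleep", "sb"), down = c("lpa", "mvpa")),
    list(up = "sleep", down = "sb"),
    list(up = "lpa", down = "mvpa")
  )
}

# a small analysis-ready participant table with a known linear outcome
toy_participants <- function(n = 60, seed = 42, sigma = 0,
                             beta_ilr = c(z1 = -1, z2 = 2, z3 = 0.5),
                             beta_cov = c(sex = 1.5, maternal_bmi = 0.3,
                                          maternal_edu = -0.8, snacking = 0.6),
                             intercept = 10) {
  set.seed(seed)
  comps <- random_comps(n)
  basis <- make_contrast_basis()
  z <- ilr_coords(comps, basis)
  sex <- rbinom(n, 1, 0.5)
  maternal_bmi <- rnorm(n, 24, 4)
  maternal_edu <- rbinom(n, 1, 0.4)
  snacking <- ifelse(rbinom(n, 1, 0.6) == 1, "high", "low")
  y <- intercept + as.numeric(z %*% beta_ilr) +
    sex * beta_cov["sex"] + maternal_bmi * beta_cov["maternal_bmi"] +
    maternal_edu * beta_cov["maternal_edu"] +
    (snacking == "high") * beta_cov["snacking"] +
    rnorm(n, 0, sigma)
  data.frame(participant_id = sprintf("T%03d", seq_len(n)),
             sleep = comps[, "sleep"], sb = comps[, "sb"],
             lpa = comps[, "lpa"], mvpa = comps[, "mvpa"],
             sex = ifelse(sex == 1, "boy", "girl"),
             maternal_bmi = maternal_bmi, maternal_edu = maternal_edu,
             snacking = snacking, y = y,
             mean_wear_hours = 24 - abs(rnorm(n, 0, 0.2)))
}

# two-participant day/participant CSV fixture written to a temp dir
write_mini_cohort <- function(dir = tempfile("mini_cohort_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  days <- rbind(
    data.frame(participant_id = "A1",
               day_type = c(rep("weekday", 4), "weekend"),
               wear_hours = c(17, 18, 16, 20, 17),
               sleep_h = 9, sb_h = 10, lpa_h = 4, mvpa_h = 1),
    data.frame(participant_id = "B2",
               day_type = c(rep("weekday", 3), "weekend", "weekend"),
               wear_hours = c(16, 16, 23, 18, 19),
               sleep_h = 8, sb_h = 11, lpa_h = 4.2, mvpa_h = 0.8)
  )
  ppl <- data.frame(
    participant_id = c("A1", "B2"), age = c(10, 16),
    sex = c("girl", "boy"), bmi_z = c(0.3, -0.2),
    fm_pct = c(18, 22), fat_mass_kg = c(12, 16),
    height_m = c(1.42, 1.74), vat_cm2 = c(40, 55),
    maternal_bmi = c(23.5, 26.0), maternal_edu = c(1, 0),
    snack_sweets = c("never", "once a day (everyday)"),
    snack_softdrinks = c("once a week", "2-4 times a week"),
    snack_crisps = c("never", "never")
  )
  write.csv(days, file.path(dir, "days.csv"), row.names = FALSE)
  write.csv(ppl, file.path(dir, "participants.csv"), row.names = FALSE)
  list(dir = dir, days = file.path(dir, "days.csv"),
       participants = file.path(dir, "participants.csv"),
       day_table = days, participant_table = ppl)
}
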
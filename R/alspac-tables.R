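#' Published joint class distribution (percent)
#'
#' The 4x4 joint distribution of constipation and soiling trajectory classes
#' estimated from the ALSPAC parallel-process model (n = 8435), as percentages.
#' Rows are constipation classes (normative, early, late, persistent), columns
#' soiling classes (normative, delayed, relapse, persistent). The one censored
#' cell (printed as "<0.1") is carried as 0; the cells then sum to exactly 100.
#'
#' @return A 4x4 numeric matrix of percentages with dimnames
#'   `constipation` x `soiling`.
#' @examples
#' composite_proportions(alspac_joint_percent())
#' @export
alspac_joint_percent <- function() {
  m <- matrix(
    c(
      74.5, 4.3, 2.2, 1.0,
      5.5, 1.1, 0.0, 0.5,
      5.8, 0.6, 0.9, 0.3,
      1.9, 0.4, 0.5, 0.5
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(
      constipation = constipation_class_labels,
      soiling = soiling_class_labels
    )
  )
  m
}

#' Published per-wave symptom counts
#'
#' Counts of children with and without soiling (five waves, ages 4.5 to 9.5
#' years) and constipation (six waves, ages 4y9m to 10y8m) in the three nested
#' ALSPAC samples: at least one non-missing time point on both processes
#' (max n = 10450), at least three non-missing time points on both processes
#' (max n = 8435), and complete case on all eleven measures (n = 4931).
#'
#' @return A tibble with columns `sample` (one of `"min1"`, `"min3"`,
#'   `"complete"`), `process`, `wave` (0-based), `age_label`, `n_symptom`,
#'   `n_no_symptom`.
#' @export
alspac_prevalence_counts <- function() {
  soil_ages <- c("4y6m", "5y6m", "6y6m", "7y6m", "9y6m")
  con_ages <- c("4y9m", "5y9m", "6y9m", "7y7m", "8y7m", "10y8m")
  build <- function(sample, process, yes, no) {
    ages <- if (process == "soiling") soil_ages else con_ages
    tibble::tibble(
      sample = sample, process = process,
      wave = seq_along(yes) - 1L, age_label = ages,
      n_symptom = yes, n_no_symptom = no
    )
  }
  dplyr::bind_rows(
    build("min1", "soiling", c(673, 548, 654, 565, 397),
          c(8720, 8284, 7752, 7617, 7288)),
    build("min1", "constipation", c(1342, 881, 873, 822, 765, 707),
          c(7947, 7622, 7580, 7346, 7062, 6631)),
    build("min3", "soiling", c(585, 477, 611, 525, 372),
          c(7507, 7518, 7268, 7153, 6801)),
    build("min3", "constipation", c(1173, 809, 825, 766, 689, 644),
          c(6893, 7014, 7086, 6894, 6549, 6194)),
    build("complete", "soiling", c(356, 293, 363, 341, 261),
          c(4575, 4638, 4568, 4590, 4670)),
    build("complete", "constipation", c(687, 506, 529, 505, 477, 473),
          c(4244, 4425, 4402, 4426, 4454, 4458))
  )
}

#' Percentage with symptom from printed counts
#'
#' @param n_symptom,n_no_symptom counts of children with and without the
#'   symptom at a wave.
#' @param digits decimal places for rounding (the published tables use 1).
#' @return percentage among the non-missing, rounded.
#' @examples
#' prevalence_pct(673, 8720) # 7.2
#' @export
prevalence_pct <- function(n_symptom, n_no_symptom, digits = 1) {
  round(100 * n_symptom / (n_symptom + n_no_symptom), digits)
}

#' Published unconditional constipation class split
#'
#' Class weights of the four-class LLCA of constipation fitted to children with
#' at least three non-missing constipation measures (n = 8979): normative 82%,
#' early childhood occurrence 7%, late childhood occurrence 8%, persistent 3%.
#'
#' @return named numeric vector of proportions summing to 1.
#' @export
alspac_constipation_split <- function() {
  setNames(c(0.82, 0.07, 0.08, 0.03), constipation_class_labels)
}

#' Published risk-factor odds ratios
#'
#' Univariable odds ratios (with 95% CIs) for membership of the three
#' non-normative composite classes relative to the normative class, as
#' published for the ALSPAC cohort (n <= 8435 per factor), together with the
#' reported level prevalences. Useful for calibrating the synthetic cohort
#' generator and for comparing recovered estimates.
#'
#' @return A tibble with columns `factor`, `level`, `reference` (logical),
#'   `prevalence`, `or_constipation_alone`, `or_soiling_alone`,
#'   `or_constipation_with_soiling`.
#' @export
alspac_risk_factors <- function() {
  tribble_or <- function(factor, level, ref, prev, or1, or2, or3) {
    tibble::tibble(
      factor = factor, level = level, reference = ref, prevalence = prev,
      or_constipation_alone = or1, or_soiling_alone = or2,
      or_constipation_with_soiling = or3
    )
  }
  dplyr::bind_rows(
    tribble_or("sex", "female", TRUE, 0.52, NA, NA, NA),
    tribble_or("sex", "male", FALSE, 0.48, 0.63, 1.78, 1.38),
    tribble_or("hard_stools", "never", TRUE, 0.18, NA, NA, NA),
    tribble_or("hard_stools", "sometimes", FALSE, 0.54, 2.08, 1.12, 1.22),
    tribble_or("hard_stools", "usually", FALSE, 0.28, 1.90, 0.68, 1.26),
    tribble_or("breastfeeding", "never", TRUE, 0.21, NA, NA, NA),
    tribble_or("breastfeeding", "under_6m", FALSE, 0.45, 1.25, 1.34, 1.08),
    tribble_or("breastfeeding", "over_6m", FALSE, 0.34, 1.24, 1.22, 0.94),
    tribble_or("social_class", "professional", TRUE, 0.85, NA, NA, NA),
    tribble_or("social_class", "manual", FALSE, 0.15, 0.95, 1.16, 0.98),
    tribble_or("maternal_education", "alevel_degree", TRUE, 0.41, NA, NA, NA),
    tribble_or("maternal_education", "olevel", FALSE, 0.35, 0.92, 0.82, 1.16),
    tribble_or("maternal_education", "vocational_none", FALSE, 0.23, 0.82, 0.94, 0.92),
    tribble_or("material_hardship", "no", TRUE, 0.73, NA, NA, NA),
    tribble_or("material_hardship", "yes", FALSE, 0.27, 1.00, 1.06, 1.52),
    tribble_or("home_ownership", "owned", TRUE, 0.85, NA, NA, NA),
    tribble_or("home_ownership", "private_rented", FALSE, 0.041, 0.73, 1.12, 1.26),
    tribble_or("home_ownership", "subsidised_rented", FALSE, 0.11, 0.74, 1.01, 0.92),
    tribble_or("car_access", "yes", TRUE, 0.93, NA, NA, NA),
    tribble_or("car_access", "no", FALSE, 0.07, 0.82, 1.53, 1.49),
    tribble_or("preterm", "term", TRUE, 0.95, NA, NA, NA),
    tribble_or("preterm", "preterm", FALSE, 0.05, 0.76, 1.28, 1.12),
    tribble_or("low_birth_weight", "normal", TRUE, 0.96, NA, NA, NA),
    tribble_or("low_birth_weight", "low", FALSE, 0.04, 1.29, 1.32, 1.05),
    tribble_or("developmental_score", "per_sd", FALSE, NA, 0.95, 1.44, 1.31),
    tribble_or("toilet_training", "m15_24", TRUE, 0.50, NA, NA, NA),
    tribble_or("toilet_training", "before_6m", FALSE, 0.02, 1.20, 1.50, 1.73),
    tribble_or("toilet_training", "m6_15", FALSE, 0.14, 1.22, 1.09, 0.81),
    tribble_or("toilet_training", "after_24m", FALSE, 0.34, 0.91, 1.47, 1.56)
  )
}
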
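test_that("config invariants are enforced before any sampling", {
  w <- alspac_joint_percent() / 100
  expect_error(cohort_config(joint_class_weights = w * 1.01), "sum to 1")
  bad <- alspac_profiles()$soiling
  bad[1, 1] <- 1.2
  expect_error(cohort_config(soiling_profiles = bad), "\\[0, 1\\]")
  expect_error(
    covariate_spec("x", "binary", levels = c("a", "b"), probs = c(0.5, 0.5),
                   effects = matrix(c(Inf, 0, 0), 1, 3)),
    "finite"
  )
  expect_error(
    covariate_spec("x", "binary", levels = c("a", "b"), probs = c(0.6, 0.6)),
    "sum to 1"
  )
})

test_that("degenerate config yields an all-normative, all-zero cohort", {
  w <- matrix(0, 4, 4)
  w[1, 1] <- 1
  prof <- alspac_profiles()
  prof$soiling[] <- 0
  prof$constipation[] <- 0
  cfg <- cohort_config(n_children = 50, joint_class_weights = w,
                       soiling_profiles = prof$soiling,
                       constipation_profiles = prof$constipation, seed = 3)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$panel$value == 0))
  expect_true(all(ch$labels$composite_label == "normative"))
  expect_true(all(ch$labels$soiling_class == 1))
})

test_that("same seed gives bit-identical cohorts", {
  a <- generate_cohort(small_config(n = 300, seed = 9))
  b <- generate_cohort(small_config(n = 300, seed = 9))
  expect_identical(a, b)
  cfg <- small_config(n = 300, seed = 9)
  expect_identical(apply_missingness(a$panel, cfg), apply_missingness(b$panel, cfg))
})

test_that("composite shares converge to the collapsed joint weights", {
  ch <- generate_cohort(cohort_config(n_children = 100000, seed = 42))
  shares <- 100 * prop.table(table(factor(ch$labels$composite_label,
                                          levels = composite_order)))
  target <- composite_proportions(alspac_joint_percent())
  expect_lt(max(abs(as.vector(shares) - target)), 0.5)
})

test_that("per-wave marginal prevalence matches the analytic expectation", {
  cfg <- cohort_config(n_children = 50000, seed = 13)
  ch <- generate_cohort(cfg)
  Y <- panel_matrix(ch$panel, "constipation")
  con_w <- rowSums(cfg$joint_class_weights) # constipation class weights
  expected <- as.vector(con_w %*% cfg$constipation_profiles)
  expect_lt(max(abs(colMeans(Y) - expected)), 0.01)
})

test_that("a generated covariate effect is recovered by brute-force cross-tabulation", {
  cfg <- cohort_config(n_children = 200000, seed = 77,
                       covariate_specs = sex_only_specs(1.78))
  ch <- generate_cohort(cfg)
  d <- dplyr::inner_join(ch$covariates, ch$labels, by = "child_id")
  tab <- table(d$male, d$composite_label)[, c("normative", "soiling_alone")]
  or <- (tab["male", "soiling_alone"] * tab["female", "normative"]) /
    (tab["female", "soiling_alone"] * tab["male", "normative"])
  expect_lt(abs(or - 1.78), 0.1)
})

test_that("missingness has the configured marginal rate and identity limits", {
  cfg0 <- cohort_config(n_children = 200, seed = 5, response_prob = 1,
                        dropout_hazard = 0)
  ch <- generate_cohort(cfg0)
  expect_identical(apply_missingness(ch$panel, cfg0), ch$panel)

  cfg_none <- cohort_config(n_children = 200, seed = 5, response_prob = 0,
                            dropout_hazard = 0)
  miss <- apply_missingness(ch$panel, cfg_none)
  expect_true(all(is.na(miss$value)))

  cfg9 <- cohort_config(n_children = 50000, seed = 21, response_prob = 0.9,
                        dropout_hazard = 0)
  ch9 <- generate_cohort(cfg9)
  m9 <- apply_missingness(ch9$panel, cfg9)
  frac <- m9 %>%
    dplyr::group_by(process, wave) %>%
    dplyr::summarise(obs = mean(!is.na(value)), .groups = "drop")
  expect_true(all(abs(frac$obs - 0.9) < 0.01))
})

test_that("dropout is monotone over the age-ordered assessments", {
  cfg <- cohort_config(n_children = 2000, seed = 31, response_prob = 1,
                       dropout_hazard = 0.3)
  ch <- generate_cohort(cfg)
  miss <- apply_missingness(ch$panel, cfg)
  ages <- dplyr::bind_rows(
    tibble::tibble(process = "soiling", wave = 0:4, age = cfg$soiling_ages),
    tibble::tibble(process = "constipation", wave = 0:5, age = cfg$constipation_ages)
  )
  d <- dplyr::left_join(miss, ages, by = c("process", "wave")) %>%
    dplyr::arrange(child_id, age)
  ok <- d %>%
    dplyr::group_by(child_id) %>%
    dplyr::summarise(monotone = all(diff(is.na(value)) >= 0), .groups = "drop")
  expect_true(all(ok$monotone))
})

test_that("inclusion filter applies the published rule literally", {
  # child A: 2 soiling waves, all 6 constipation waves -> excluded (both mode)
  Ys <- rbind(A = c(1, 0, NA, NA, NA), B = c(0, 0, 0, NA, NA),
              C = rep(0, 5), D = c(NA, NA, NA, NA, 0), E = rep(1, 5))
  Yc <- rbind(A = rep(0, 6), B = c(0, 1, 0, NA, NA, NA),
              C = rep(0, 6), D = rep(NA, 6), E = c(1, 1, 1, NA, NA, NA))
  panel <- pair_panel(Ys, Yc)
  kept_both <- sort(unique(apply_inclusion_filter(panel, 3, "both")$child_id))
  expect_identical(kept_both, c("B", "C", "E"))
  kept_soil <- sort(unique(apply_inclusion_filter(panel, 3, "soiling")$child_id))
  expect_identical(kept_soil, c("B", "C", "E"))
  kept_con <- sort(unique(apply_inclusion_filter(panel, 3, "constipation")$child_id))
  expect_identical(kept_con, c("A", "B", "C", "E"))
  full <- pair_panel(Ys[c("C", "E"), ], Yc[c("C", "E"), ])
  expect_identical(
    dplyr::arrange(apply_inclusion_filter(full, 3, "both"), process, child_id, wave),
    dplyr::arrange(full, process, child_id, wave)
  )
  expect_error(apply_inclusion_filter(panel, 7), "min_waves")
})

test_that("default missingness roughly reproduces the published attrition gradient", {
  cfg <- cohort_config(n_children = 20000, seed = 99)
  ch <- generate_cohort(cfg)
  miss <- apply_missingness(ch$panel, cfg)
  n1 <- dplyr::n_distinct(apply_inclusion_filter(miss, 1, "both")$child_id)
  n3 <- dplyr::n_distinct(apply_inclusion_filter(miss, 3, "both")$child_id)
  # published gradient: 8435 / 10450 = 0.81 analytic-to-contactable ratio
  expect_gt(n3 / n1, 0.70)
  expect_lt(n3 / n1, 0.92)
})
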
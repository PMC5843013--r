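#' Mapping from joint class pairs to composite clinical groups
#'
#' The 16 (soiling class, constipation class) pairs collapse
#' deterministically into four clinically interpretable groups:
#' (normative, normative) is `normative` (1 cell); normative soiling with
#' non-normative constipation is `constipation_alone` (3 cells); the reverse
#' is `soiling_alone` (3 cells); both non-normative is
#' `constipation_with_soiling` (9 cells).
#'
#' @return a 16-row tibble with columns `soiling_class`,
#'   `constipation_class` (integers 1-4, 1 = normative) and `composite`
#'   (factor over the four groups).
#' @export
composite_map <- function() {
  grid <- tidyr::expand_grid(soiling_class = 1:4, constipation_class = 1:4)
  grid$composite <- factor(
    composite_levels[composite_from_pair(grid$soiling_class, grid$constipation_class)],
    levels = composite_levels
  )
  grid
}

check_map <- function(map) {
  need <- c("soiling_class", "constipation_class", "composite")
  if (!all(need %in% names(map))) abort("map must have soiling_class, constipation_class, composite")
  keys <- paste(map$soiling_class, map$constipation_class)
  all_keys <- paste(rep(1:4, each = 4), rep(1:4, times = 4))
  if (!setequal(keys, all_keys) || anyDuplicated(keys)) {
    abort("map must cover all 16 (soiling, constipation) cells exactly once")
  }
  map
}

#' Collapse a joint posterior onto the composite groups
#'
#' Each child's probability for a composite group is the sum of their joint
#' class-pair posterior over the cells that map to it; probability mass is
#' conserved exactly. Modal labels break ties toward the earlier (less
#' severe) group in the order normative, constipation alone, soiling alone,
#' constipation with soiling.
#'
#' @param joint a [fit_parallel()] result, or a children x 16 posterior
#'   matrix laid out with soiling class varying fastest.
#' @param map the collapse map (see [composite_map()]).
#' @return an object of class `composite_posterior`: list with `posterior`
#'   (children x 4), `modal` (factor per child), `composite_weights`
#'   (column means) and `child_id`.
#' @export
collapse_posterior <- function(joint, map = composite_map()) {
  check_map(map)
  post16 <- if (inherits(joint, "parallel_llca")) joint$posterior else as.matrix(joint)
  stopifnot(ncol(post16) == 16)
  comp_of_k <- map$composite[match(
    paste(cell_a_idx, cell_b_idx),
    paste(map$soiling_class, map$constipation_class)
  )]
  agg <- outer(as.integer(comp_of_k), 1:4, "==") * 1 # 16 x 4
  post4 <- post16 %*% agg
  colnames(post4) <- composite_levels
  rownames(post4) <- rownames(post16)
  modal <- factor(composite_levels[max.col(post4, ties.method = "first")],
                  levels = composite_levels)
  structure(
    list(
      posterior = post4,
      modal = setNames(modal, rownames(post4)),
      composite_weights = colMeans(post4),
      child_id = rownames(post4)
    ),
    class = "composite_posterior"
  )
}

#' Composite group shares from a joint class table
#'
#' Sums the mapped cells of a 4x4 joint distribution (constipation classes in
#' rows, soiling classes in columns; probabilities or percentages) into the
#' four composite group shares. The output sums to the grand total of the
#' input.
#'
#' @param joint_weights 4x4 matrix.
#' @param map collapse map.
#' @return named numeric vector of length 4 in the fixed composite order.
#' @examples
#' composite_proportions(alspac_joint_percent())
#' @export
composite_proportions <- function(joint_weights, map = composite_map()) {
  check_map(map)
  W <- as.matrix(joint_weights)
  stopifnot(all(dim(W) == c(4, 4)))
  out <- vapply(composite_levels, function(k) {
    cells <- map[map$composite == k, ]
    sum(W[cbind(cells$constipation_class, cells$soiling_class)])
  }, 0)
  out
}

#' Split of soilers into soiling alone versus with constipation
#'
#' Among children in either soiling group, the percentage with soiling alone
#' and with constipation, rounded to integer percent.
#'
#' @param composite length-4 composite shares (percent or proportions) in the
#'   fixed order.
#' @return named vector `c(soiling_alone =, with_constipation =)`.
#' @examples
#' soiler_split(composite_proportions(alspac_joint_percent()))
#' @export
soiler_split <- function(composite) {
  stopifnot(length(composite) == 4)
  denom <- composite[[3]] + composite[[4]]
  if (denom == 0) abort("no probability mass in either soiling group")
  c(
    soiling_alone = round(100 * composite[[3]] / denom),
    with_constipation = round(100 * composite[[4]] / denom)
  )
}

#' Overall prevalence of any constipation trajectory
#'
#' @inheritParams soiler_split
#' @return constipation alone plus constipation with soiling, on the input
#'   scale.
#' @examples
#' any_constipation_prevalence(composite_proportions(alspac_joint_percent()))
#' @export
any_constipation_prevalence <- function(composite) {
  stopifnot(length(composite) == 4)
  unname(composite[[2]] + composite[[4]])
}

#' Posterior-weighted symptom rates by composite group
#'
#' For an associated symptom (e.g. daytime wetting, bed-wetting, stomach
#' ache, infrequent bowel movements) observed once per child, computes the
#' posterior-weighted rate in each composite group:
#' \eqn{\sum_i p_{ik} y_i / \sum_i p_{ik}} over children with an observed
#' symptom. Groups with zero posterior mass among the observed children get
#' `NA`.
#'
#' @param composite a [collapse_posterior()] result.
#' @param symptom a data frame with columns `child_id` and `value` (0/1/NA),
#'   or a vector named by child id.
#' @return tibble with columns `composite`, `rate`, `effective_n`.
#' @export
symptom_rates_by_class <- function(composite, symptom) {
  stopifnot(inherits(composite, "composite_posterior"))
  if (is.data.frame(symptom)) {
    y <- setNames(symptom$value, symptom$child_id)
  } else {
    y <- symptom
  }
  y <- y[composite$child_id]
  obs <- !is.na(y)
  P <- composite$posterior[obs, , drop = FALSE]
  yv <- y[obs]
  mass <- colSums(P)
  rate <- ifelse(mass > 0, colSums(P * yv) / mass, NA_real_)
  tibble::tibble(
    composite = factor(composite_levels, levels = composite_levels),
    rate = unname(rate),
    effective_n = unname(mass)
  )
}

#' Per-wave prevalence in the three nested samples
#'
#' Recomputes the descriptive prevalence table: for each nested sample
#' (children with at least one non-missing time point on both processes, at
#' least three on both, and complete data on all waves), the per-wave number
#' with and without the symptom among the non-missing, and the percentage.
#'
#' @param panel long panel with both processes, before any filtering.
#' @return tibble with columns `sample`, `process`, `wave`, `n_symptom`,
#'   `n_no_symptom`, `pct` (NA for an all-missing wave).
#' @export
marginal_prevalence_table <- function(panel) {
  validate_panel(panel)
  n_waves <- panel %>%
    dplyr::group_by(.data$process) %>%
    dplyr::summarise(n = dplyr::n_distinct(.data$wave), .groups = "drop")
  complete_ids <- panel %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::count(.data$child_id, .data$process, name = "n_obs") %>%
    dplyr::left_join(n_waves, by = "process") %>%
    dplyr::group_by(.data$child_id) %>%
    dplyr::summarise(ok = dplyr::n() == nrow(n_waves) && all(.data$n_obs == .data$n),
                     .groups = "drop") %>%
    dplyr::filter(.data$ok) %>%
    dplyr::pull(.data$child_id)
  samples <- list(
    min1 = apply_inclusion_filter(panel, 1, "both"),
    min3 = apply_inclusion_filter(panel, 3, "both"),
    complete = dplyr::filter(panel, .data$child_id %in% complete_ids)
  )
  purrr::imap(samples, function(p, nm) {
    p %>%
      dplyr::group_by(.data$process, .data$wave) %>%
      dplyr::summarise(
        n_symptom = sum(.data$value == 1, na.rm = TRUE),
        n_no_symptom = sum(.data$value == 0, na.rm = TRUE),
        .groups = "drop"
      ) %>%
      dplyr::mutate(
        sample = nm,
        pct = dplyr::if_else(
          .data$n_symptom + .data$n_no_symptom > 0,
          100 * .data$n_symptom / (.data$n_symptom + .data$n_no_symptom),
          NA_real_
        )
      )
  }) %>%
    dplyr::bind_rows() %>%
    dplyr::select("sample", "process", "wave", "n_symptom", "n_no_symptom", "pct")
}

#' @export
print.composite_posterior <- function(x, ...) {
  cat("Composite classification of", length(x$child_id), "children\n")
  cat("group shares (posterior means):\n")
  print(round(100 * x$composite_weights, 1))
  invisible(x)
}
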
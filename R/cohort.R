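#' Default trajectory profiles for the synthetic cohort
#'
#' Per-class, per-wave symptom probabilities emulating the published
#' trajectory shapes: a normative class with very low probability throughout,
#' an early-onset class (high then resolving), a late-onset/relapse class
#' (low then rising) and a persistent class (high throughout). Values were
#' fixed once so that (i) the classes are well separated, (ii) the class-mean
#' ordering is normative < early-onset < late-onset < persistent, matching the
#' canonical class order, and (iii) weight-averaged marginal prevalences are
#' in the published 5-15% range.
#'
#' @return A list with `soiling` (4x5) and `constipation` (4x6) matrices,
#'   rows in canonical class order.
#' @export
alspac_profiles <- function() {
  soiling <- matrix(
    c(
      0.02, 0.02, 0.02, 0.02, 0.015, # normative
      0.70, 0.50, 0.25, 0.10, 0.06,  # delayed attainment
      0.12, 0.18, 0.45, 0.60, 0.55,  # relapse
      0.75, 0.80, 0.80, 0.80, 0.75   # persistent
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(soiling_class_labels, paste0("w", 0:4))
  )
  constipation <- matrix(
    c(
      0.05, 0.04, 0.04, 0.03, 0.03, 0.03, # normative
      0.80, 0.70, 0.25, 0.10, 0.06, 0.05, # early childhood occurrence
      0.06, 0.08, 0.20, 0.55, 0.65, 0.60, # late childhood occurrence
      0.78, 0.80, 0.85, 0.85, 0.80, 0.78  # persistent
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(constipation_class_labels, paste0("w", 0:5))
  )
  list(soiling = soiling, constipation = constipation)
}

#' Declare a covariate for the synthetic cohort
#'
#' @param name column name.
#' @param type `"binary"`, `"categorical"` or `"continuous"` (standard
#'   normal, interpreted as a standardised score).
#' @param levels character levels, reference first (binary/categorical).
#' @param probs marginal level probabilities (binary/categorical); must sum
#'   to 1.
#' @param effects log-odds effects on composite class membership relative to
#'   the normative class: a matrix with one row per non-reference level (one
#'   row for continuous) and three columns
#'   (constipation_alone, soiling_alone, constipation_with_soiling).
#'   Defaults to all-zero effects.
#' @return a `covariate_spec` list.
#' @export
covariate_spec <- function(name, type = c("binary", "categorical", "continuous"),
                           levels = NULL, probs = NULL, effects = NULL) {
  type <- match.arg(type)
  if (type == "continuous") {
    n_eff <- 1L
  } else {
    stopifnot(is.character(levels), length(levels) >= 2, length(probs) == length(levels))
    if (abs(sum(probs) - 1) > 1e-8) {
      abort(paste0("covariate '", name, "': level probabilities must sum to 1"))
    }
    if (any(probs < 0)) abort(paste0("covariate '", name, "': negative level probability"))
    n_eff <- length(levels) - 1L
  }
  if (is.null(effects)) effects <- matrix(0, n_eff, 3)
  effects <- matrix(as.numeric(effects), n_eff, 3)
  if (!all(is.finite(effects))) {
    abort(paste0("covariate '", name, "': effects must be finite"))
  }
  structure(
    list(name = name, type = type, levels = levels, probs = probs, effects = effects),
    class = "covariate_spec"
  )
}

#' Covariate specifications calibrated to the published cohort
#'
#' Builds the full early-childhood risk-factor set with the published level
#' prevalences. With `effects = "none"` (default) all class effects are zero,
#' so the composite class distribution reproduces the unconditional joint
#' table; with `effects = "published"` each non-reference level receives the
#' published log odds ratios.
#'
#' @param effects `"none"` or `"published"`.
#' @param only optional character vector of factor names to keep.
#' @return list of [covariate_spec()] objects.
#' @export
alspac_covariate_specs <- function(effects = c("none", "published"), only = NULL) {
  effects <- match.arg(effects)
  rf <- alspac_risk_factors()
  if (!is.null(only)) rf <- dplyr::filter(rf, .data$factor %in% only)
  split(rf, factor(rf$factor, levels = unique(rf$factor))) %>%
    purrr::map(function(d) {
      if (d$factor[1] == "developmental_score") {
        eff <- if (effects == "published") {
          log(matrix(c(d$or_constipation_alone, d$or_soiling_alone,
                       d$or_constipation_with_soiling), 1, 3))
        } else {
          NULL
        }
        return(covariate_spec(d$factor[1], "continuous", effects = eff))
      }
      d <- dplyr::arrange(d, dplyr::desc(.data$reference))
      probs <- d$prevalence / sum(d$prevalence)
      eff <- if (effects == "published") {
        nr <- d[!d$reference, ]
        log(cbind(nr$or_constipation_alone, nr$or_soiling_alone,
                  nr$or_constipation_with_soiling))
      } else {
        NULL
      }
      type <- if (nrow(d) == 2) "binary" else "categorical"
      covariate_spec(d$factor[1], type, levels = d$level, probs = probs, effects = eff)
    }) %>%
    unname()
}

#' Configure the synthetic cohort generator
#'
#' The defaults are calibrated to the published cohort: 8435 children, the
#' published 4x4 joint class distribution (with the censored "<0.1" cell
#' carried as 0), the [alspac_profiles()] trajectory shapes, the published
#' covariate marginals with zero class effects, and a missingness mechanism
#' (per-wave response probability 0.975, monotone dropout hazard 0.05 per
#' assessment occasion) chosen to roughly reproduce the published attrition
#' gradient across the three nested samples.
#'
#' @param n_children number of children.
#' @param joint_class_weights 4x4 matrix of probabilities, constipation
#'   classes in rows, soiling classes in columns; entries must be
#'   non-negative and sum to 1 within 1e-12.
#' @param soiling_profiles,constipation_profiles per-class, per-wave symptom
#'   probabilities in \[0, 1\] (4x5 and 4x6).
#' @param covariate_specs list of [covariate_spec()] objects.
#' @param response_prob per-wave probability that an administered assessment
#'   is answered.
#' @param dropout_hazard per-occasion monotone dropout hazard (geometric).
#' @param soiling_ages,constipation_ages assessment ages in years, used only
#'   to order occasions for monotone dropout and as display labels.
#' @param seed integer master seed (< 2^30).
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_children = 8435,
                          joint_class_weights = alspac_joint_percent() / 100,
                          soiling_profiles = alspac_profiles()$soiling,
                          constipation_profiles = alspac_profiles()$constipation,
                          covariate_specs = alspac_covariate_specs("none"),
                          response_prob = 0.975,
                          dropout_hazard = 0.05,
                          soiling_ages = c(4.5, 5.5, 6.5, 7.5, 9.5),
                          constipation_ages = c(4.75, 5.75, 6.75, 7.58, 8.58, 10.67),
                          seed = 1L) {
  stopifnot(n_children >= 1)
  w <- as.matrix(joint_class_weights)
  if (!all(dim(w) == c(4, 4))) abort("joint_class_weights must be 4x4")
  if (any(w < 0)) abort("joint_class_weights entries must be non-negative")
  if (abs(sum(w) - 1) > 1e-12) abort("joint_class_weights must sum to 1 (within 1e-12)")
  for (p in list(soiling_profiles, constipation_profiles)) {
    if (any(p < 0 | p > 1)) abort("profile entries must lie in [0, 1]")
  }
  stopifnot(nrow(soiling_profiles) == 4, nrow(constipation_profiles) == 4)
  stopifnot(ncol(soiling_profiles) == length(soiling_ages),
            ncol(constipation_profiles) == length(constipation_ages))
  if (response_prob < 0 || response_prob > 1) abort("response_prob must be in [0, 1]")
  if (dropout_hazard < 0 || dropout_hazard > 1) abort("dropout_hazard must be in [0, 1]")
  stopifnot(is.numeric(seed), length(seed) == 1, seed < 2^30)
  purrr::walk(covariate_specs, function(s) {
    if (!inherits(s, "covariate_spec")) abort("covariate_specs must be covariate_spec objects")
  })
  structure(
    list(
      n_children = as.integer(n_children),
      joint_class_weights = w,
      soiling_profiles = soiling_profiles,
      constipation_profiles = constipation_profiles,
      covariate_specs = covariate_specs,
      response_prob = response_prob,
      dropout_hazard = dropout_hazard,
      soiling_ages = soiling_ages,
      constipation_ages = constipation_ages,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Map (soiling class a, constipation class b) -> composite group index 1..4.
# Class 1 is the normative class on each process.
composite_from_pair <- function(a, b) {
  ifelse(a == 1 & b == 1, 1L,
    ifelse(a == 1 & b > 1, 2L,
      ifelse(a > 1 & b == 1, 3L, 4L)
    )
  )
}

# Composite group of each (constipation row, soiling col) cell of a 4x4
# joint-weight matrix, as a 4x4 integer matrix in the same layout.
joint_cell_composite <- function() {
  outer(1:4, 1:4, function(b, a) composite_from_pair(a, b))
}

#' Generate a synthetic cohort with known latent structure
#'
#' Draws, for each child: covariates from their marginals; a composite
#' clinical group from a multinomial-logit model whose intercepts reproduce
#' the collapsed joint-weight shares at the reference covariate pattern and
#' whose slopes are the configured log-odds effects; a (soiling class,
#' constipation class) pair from the joint weights conditional on the
#' composite group; and per-wave binary responses independently given class.
#' The returned panel is fully observed; chain [apply_missingness()] and
#' [apply_inclusion_filter()] to emulate the observed-data structure.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `panel` (long response panel), `covariates`
#'   (one row per child) and `labels` (true soiling, constipation and
#'   composite classes per child).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_children = 500, seed = 7))
#' dplyr::count(cohort$labels, composite_class)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_children
  child_id <- sprintf("c%06d", seq_len(n))

  # covariates
  cov_df <- tibble::tibble(child_id = child_id)
  eta <- matrix(0, n, 3) # log-odds vs normative for composite groups 2:4
  for (s in config$covariate_specs) {
    if (s$type == "continuous") {
      x <- rnorm(n)
      eta <- eta + x %*% s$effects
      cov_df[[s$name]] <- x
    } else {
      lev <- sample(seq_along(s$levels), n, replace = TRUE, prob = s$probs)
      x <- factor(s$levels[lev], levels = s$levels)
      ind <- outer(lev, seq_along(s$levels)[-1], "==") * 1
      eta <- eta + ind %*% s$effects
      cov_df[[s$name]] <- x
    }
  }

  # composite group via multinomial logit; intercepts calibrated so the
  # reference covariate pattern reproduces the collapsed joint weights
  comp_of_cell <- joint_cell_composite()
  w_comp <- vapply(1:4, function(k) sum(config$joint_class_weights[comp_of_cell == k]), 0)
  # log-weight intercepts: softmax is shift-invariant, and zero-weight
  # composite groups are simply never drawn (their intercept is -Inf)
  eta_full <- cbind(log(w_comp[1]), sweep(eta, 2, log(w_comp[2:4]), "+"))
  eta_full <- eta_full - pmax(eta_full[, 1], eta_full[, 2], eta_full[, 3], eta_full[, 4])
  pmat <- exp(eta_full)
  pmat <- pmat / rowSums(pmat)
  u <- runif(n)
  cum <- t(apply(pmat, 1, cumsum))
  composite <- 1L + rowSums(u > cum[, 1:3, drop = FALSE] + 0)

  # joint cell conditional on composite group (within-group proportions
  # follow the base joint weights)
  a_of_cell <- as.vector(col(comp_of_cell)) # soiling class of cell
  b_of_cell <- as.vector(row(comp_of_cell)) # constipation class of cell
  w_cell <- as.vector(config$joint_class_weights)
  comp_cell <- as.vector(comp_of_cell)
  cell <- integer(n)
  for (k in 1:4) {
    idx <- which(composite == k)
    cells_k <- which(comp_cell == k)
    if (length(idx)) {
      cell[idx] <- cells_k[sample.int(length(cells_k), length(idx), replace = TRUE,
                                      prob = w_cell[cells_k])]
    }
  }
  a <- a_of_cell[cell]
  b <- b_of_cell[cell]

  # responses given class
  draw_panel <- function(cls, profiles, process) {
    p <- profiles[cls, , drop = FALSE]
    Y <- matrix(rbinom(length(p), 1, as.vector(p)), nrow = n)
    rownames(Y) <- child_id
    matrix_panel(Y, process)
  }
  panel <- dplyr::bind_rows(
    draw_panel(a, config$soiling_profiles, "soiling"),
    draw_panel(b, config$constipation_profiles, "constipation")
  )

  labels <- tibble::tibble(
    child_id = child_id,
    soiling_class = a,
    constipation_class = b,
    soiling_label = soiling_class_labels[a],
    constipation_label = constipation_class_labels[b],
    composite_class = composite,
    composite_label = composite_levels[composite]
  )
  list(panel = panel, covariates = cov_df, labels = labels)
}

#' Impose item missingness and monotone dropout on a panel
#'
#' Each assessment is independently answered with probability
#' `config$response_prob`; in addition each child has a geometric dropout
#' occasion over the age-ordered sequence of all assessments (both processes
#' interleaved), after which everything is missing. The mechanism is
#' independent of latent class and responses (MCAR, hence MAR), and
#' reproducible: the generator seed plus one is used.
#'
#' @param panel a fully observed long panel.
#' @param config a [cohort_config()].
#' @return the panel with `value` set to `NA` where unobserved.
#' @export
apply_missingness <- function(panel, config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_panel(panel)
  set.seed(config$seed + 1L)
  occ <- dplyr::bind_rows(
    tibble::tibble(process = "soiling", wave = seq_along(config$soiling_ages) - 1L,
                   age = config$soiling_ages),
    tibble::tibble(process = "constipation", wave = seq_along(config$constipation_ages) - 1L,
                   age = config$constipation_ages)
  )
  occ$rank <- rank(occ$age, ties.method = "first")
  out <- dplyr::left_join(panel, occ[c("process", "wave", "rank")],
                          by = c("process", "wave"))
  if (anyNA(out$rank)) abort("panel contains waves not described by the config ages")

  ids <- sort(unique(out$child_id))
  h <- config$dropout_hazard
  dropout <- if (h > 0) stats::rgeom(length(ids), h) + 1L else rep(Inf, length(ids))
  names(dropout) <- ids
  item_obs <- runif(nrow(out)) < config$response_prob
  observed <- item_obs & out$rank < dropout[out$child_id]
  out$value[!observed] <- NA_real_
  out$rank <- NULL
  out
}
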
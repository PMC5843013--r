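#' Modal composite-class assignment
#'
#' Assigns each child to the composite group with the highest posterior
#' probability, ties broken toward the earlier (less severe) group in the
#' fixed order.
#'
#' @param composite a [collapse_posterior()] result or a children x 4
#'   posterior matrix in the fixed composite order.
#' @return factor of assigned groups, named by child id when available.
#' @export
modal_assign <- function(composite) {
  if (inherits(composite, "composite_posterior")) return(composite$modal)
  P <- as.matrix(composite)
  stopifnot(ncol(P) == 4)
  setNames(
    factor(composite_levels[max.col(P, ties.method = "first")],
           levels = composite_levels),
    rownames(P)
  )
}

#' Classification-error matrix of the modal assignment
#'
#' Quantifies how well the modal assignment recovers the latent composite
#' class: `D[t, m]` is the probability of being assigned to group `m` given
#' true group `t`, estimated as
#' \eqn{D_{tm} = \sum_i p_{it} 1[m_i = m] / \sum_i p_{it}}. Rows sum to 1.
#' With perfectly separated posteriors D is the identity; the further it is
#' from identity, the larger the bias a naive regression on modal labels
#' would incur.
#'
#' @inheritParams modal_assign
#' @return a 4x4 row-stochastic matrix (true group in rows, assigned group in
#'   columns).
#' @export
error_matrix <- function(composite) {
  P <- if (inherits(composite, "composite_posterior")) composite$posterior else as.matrix(composite)
  m <- as.integer(modal_assign(composite))
  mass <- colSums(P)
  zero <- which(mass == 0)
  if (length(zero)) {
    abort(paste0("composite group '", composite_levels[zero[1]],
                 "' has zero posterior mass"))
  }
  Ind <- outer(m, 1:4, "==") * 1
  D <- t(P) %*% Ind / mass
  dimnames(D) <- list(true = composite_levels, assigned = composite_levels)
  D
}

#' Bias-adjusted three-step multinomial regression
#'
#' Third step of the bias-adjusted three-step approach: regress latent
#' composite class membership on covariates while treating the modal
#' assignment as a misclassified version of the true class with known (fixed)
#' error matrix D. The likelihood maximised is
#' \deqn{\sum_i \log \sum_t P(t \mid x_i; \gamma)\, D_{t, m_i}}
#' where \eqn{P(t \mid x; \gamma)} is a multinomial logit with the normative
#' group as reference. With D equal to the identity this reduces exactly to
#' ordinary multinomial logistic regression on the modal labels. Standard
#' errors come from the observed information of this likelihood (D fixed;
#' step-1 uncertainty in D is not propagated, a standard limitation of the
#' approach). Optimisation is quasi-Newton (BFGS with analytic gradient)
#' followed by Newton polishing until the gradient max-norm is below
#' `grad_tol`.
#'
#' @param data covariate data frame, one row per child, containing every
#'   variable in `formula` (and optionally `child_id` for alignment).
#' @param formula right-hand-side formula of risk factors, e.g. `~ sex`.
#' @param labels modal composite labels: a factor aligned with `data` rows
#'   (or named by child id), or a [collapse_posterior()] result (then the
#'   error matrix defaults to [error_matrix()] of it).
#' @param D 4x4 classification-error matrix; identity gives the naive
#'   regression. Defaults to the error matrix of `labels` when those are a
#'   composite posterior, otherwise to identity.
#' @param grad_tol convergence criterion on the gradient max-norm.
#' @return an object of class `threestep_fit` with `coefficients` (terms x 3
#'   non-reference groups, log odds ratios), `vcov`, `loglik`, `n_used`,
#'   `converged`, `separation`, `D` and bookkeeping for [omnibus_test()].
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_children = 600, seed = 11,
#'   covariate_specs = alspac_covariate_specs("published", only = "sex")
#' ))
#' fit <- fit_threestep(
#'   cohort$covariates, ~sex,
#'   labels = factor(cohort$labels$composite_label, levels = composite_map()$composite |> levels())
#' )
#' tidy(fit)
#' @export
fit_threestep <- function(data, formula, labels, D = NULL, grad_tol = 1e-8) {
  if (inherits(labels, "composite_posterior")) {
    if (is.null(D)) D <- error_matrix(labels)
    lab <- labels$modal
  } else {
    lab <- labels
  }
  if (is.null(D)) D <- diag(4)
  D <- unname(as.matrix(D))
  stopifnot(all(dim(D) == c(4, 4)))
  if (any(abs(rowSums(D) - 1) > 1e-8)) abort("D must be row-stochastic")
  if (abs(det(D)) < 1e-12) abort("D is singular")
  if (!is.factor(lab)) lab <- factor(lab, levels = composite_levels)
  lab <- factor(lab, levels = composite_levels)

  # align labels with covariate rows (by child_id when both are named)
  if (!is.null(names(lab)) && "child_id" %in% names(data)) {
    lab <- lab[match(as.character(data$child_id), names(lab))]
  }
  if (length(lab) != nrow(data)) abort("labels do not align with data rows")

  df <- as.data.frame(data)
  df$.class <- lab
  vars <- all.vars(formula)
  keep <- complete.cases(df[c(vars, ".class")])
  df <- df[keep, , drop = FALSE]
  X <- model.matrix(formula, df)
  m <- as.integer(df$.class)
  n <- nrow(X)
  K <- ncol(X)
  # aggregate identical (covariate row, label) combinations: the likelihood
  # only depends on them through counts, which collapses categorical designs
  # to a handful of weighted rows
  agg_key <- do.call(paste, c(as.data.frame(X), list(m)))
  agg_idx <- match(agg_key, unique(agg_key))
  agg_first <- !duplicated(agg_idx)
  wts <- as.vector(rowsum(rep(1, n), agg_idx, reorder = TRUE))
  Xa <- X[agg_first, , drop = FALSE]
  ma <- m[agg_first]

  # objective/gradient factory over a matrix DMloc with
  # DMloc[i, t] = P(observed label m_i | true class t)
  make_obj <- function(DMloc) {
    softmax_p <- function(par) {
      gamma <- matrix(par, K, 3)
      eta <- cbind(0, Xa %*% gamma)
      eta <- eta - pmax(eta[, 1], eta[, 2], eta[, 3], eta[, 4])
      P <- exp(eta)
      P / rowSums(P)
    }
    nll <- function(par) {
      P <- softmax_p(par)
      -sum(wts * log(pmax(rowSums(P * DMloc), 1e-300)))
    }
    ngr <- function(par) {
      P <- softmax_p(par)
      L <- pmax(rowSums(P * DMloc), 1e-300)
      R <- P * (DMloc - L) / L
      as.vector(-crossprod(Xa, wts * R[, 2:4, drop = FALSE]))
    }
    list(nll = nll, ngr = ngr)
  }
  run_one <- function(obj, par0, polish = TRUE, maxit = 2000, reltol = 1e-14) {
    par <- optim(par0, obj$nll, obj$ngr, method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol))$par
    if (!polish) return(par)
    # Newton polish to drive the gradient norm below grad_tol
    for (it in 1:25) {
      g <- obj$ngr(par)
      if (max(abs(g)) < grad_tol) break
      H <- optimHess(par, obj$nll, obj$ngr)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      f0 <- obj$nll(par)
      alpha <- 1
      repeat {
        cand <- par - alpha * step
        if (obj$nll(cand) <= f0 + 1e-12 * abs(f0)) break
        alpha <- alpha / 2
        if (alpha < 1e-8) break
      }
      par <- par - alpha * step
    }
    par
  }

  DM <- t(D)[ma, , drop = FALSE] # DM[i, t] = D[t, m_i]
  obj <- make_obj(DM)
  identity_D <- max(abs(D - diag(4))) < 1e-12
  if (identity_D) {
    par <- run_one(obj, rep(0, 3 * K))
  } else {
    # The corrected likelihood is not concave (unlike ordinary multinomial
    # logit): from a poor start BFGS can stall on the boundary plateau where
    # one class absorbs all mass. Start from a quick naive modal-label fit
    # (a concave problem) and from that fit with its intercepts replaced by
    # the D-inverted marginal class shares; keep the better solution.
    obj0 <- make_obj(outer(ma, 1:4, "==") * 1)
    naive_par <- run_one(obj0, rep(0, 3 * K), polish = FALSE,
                         maxit = 300, reltol = 1e-10)
    starts <- list(naive_par)
    int_row <- match("(Intercept)", colnames(X))
    q <- tabulate(m, 4) / n
    w <- tryCatch(solve(t(D), q), error = function(e) NULL)
    if (!is.na(int_row) && !is.null(w) && all(w > 1e-6)) {
      corr <- matrix(naive_par, K, 3)
      corr[int_row, ] <- log(w[2:4] / w[1])
      starts <- c(starts, list(as.vector(corr)))
    }
    cands <- lapply(starts, function(p0) run_one(obj, p0))
    par <- cands[[which.min(vapply(cands, obj$nll, 0))]]
  }
  nll <- obj$nll
  ngr <- obj$ngr
  converged <- max(abs(ngr(par))) < grad_tol

  H <- optimHess(par, nll, ngr)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 3 * K, 3 * K))
  gamma <- matrix(par, K, 3,
                  dimnames = list(colnames(X), composite_levels[2:4]))
  par_names <- as.vector(outer(colnames(X), composite_levels[2:4], paste, sep = "|"))
  dimnames(V) <- list(par_names, par_names)
  separation <- any(abs(gamma) > 10)
  if (separation) {
    warn("possible separation: some coefficients exceed 10 on the log-odds scale")
  }
  structure(
    list(
      coefficients = gamma,
      vcov = V,
      loglik = -nll(par),
      n_used = n,
      converged = converged,
      gradient_norm = max(abs(ngr(par))),
      separation = separation,
      D = D,
      formula = formula,
      assign = attr(X, "assign"),
      term_labels = attr(terms(formula), "term.labels"),
      xlevels = lapply(df[vars[vapply(df[vars], is.factor, TRUE)]], levels)
    ),
    class = "threestep_fit"
  )
}

#' Odds ratios with Wald confidence intervals
#'
#' @param result a [fit_threestep()] object.
#' @param level confidence level (default 0.95).
#' @return tibble with columns `term`, `class`, `estimate` (log OR),
#'   `std.error`, `or`, `conf.low`, `conf.high`.
#' @export
wald_intervals <- function(result, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  gamma <- result$coefficients
  se <- matrix(sqrt(diag(result$vcov)), nrow(gamma), 3)
  tibble::tibble(
    term = rep(rownames(gamma), times = 3),
    class = rep(colnames(gamma), each = nrow(gamma)),
    estimate = as.vector(gamma),
    std.error = as.vector(se),
    or = exp(as.vector(gamma)),
    conf.low = exp(as.vector(gamma) - z * as.vector(se)),
    conf.high = exp(as.vector(gamma) + z * as.vector(se))
  )
}

#' Omnibus Wald test for a risk factor
#'
#' Jointly tests that every coefficient of the risk factor — all its
#' non-reference levels across all three non-reference composite groups — is
#' zero, via a Wald chi-square with df = (levels - 1) x 3 for a categorical
#' factor and 3 for a continuous one.
#'
#' @param result a [fit_threestep()] object.
#' @param risk_factor name of a term in the model formula.
#' @return tibble with `term`, `statistic`, `df`, `p.value`.
#' @export
omnibus_test <- function(result, risk_factor) {
  tl <- result$term_labels
  which_term <- match(risk_factor, tl)
  if (is.na(which_term)) {
    abort(paste0("'", risk_factor, "' is not a term of the fitted model"))
  }
  K <- nrow(result$coefficients)
  cols <- which(result$assign == which_term)
  idx <- as.vector(outer(cols, (0:2) * K, "+"))
  g <- as.vector(result$coefficients)[idx]
  Vsub <- result$vcov[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(g) %*% solve(Vsub, g)),
                   error = function(e) abort("singular covariance submatrix"))
  df <- length(idx)
  tibble::tibble(
    term = risk_factor,
    statistic = stat,
    df = df,
    p.value = pchisq(stat, df, lower.tail = FALSE)
  )
}

#' @export
print.threestep_fit <- function(x, ...) {
  cat("Bias-adjusted three-step multinomial regression (n =", x$n_used, ")\n")
  cat("log-likelihood:", format(x$loglik),
      " converged:", x$converged, "\n")
  print(wald_intervals(x), n = Inf)
  invisible(x)
}
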
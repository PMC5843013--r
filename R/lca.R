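# ---- internal EM machinery -------------------------------------------------

# Split a 0/1/NA response matrix into (Y0, M): Y0 has NA -> 0, M marks
# observed cells. All likelihood work happens on these two matrices.
split_obs <- function(Y) {
  M <- 1 * !is.na(Y)
  Y0 <- Y
  Y0[is.na(Y0)] <- 0
  list(Y0 = Y0, M = M)
}

# N x C matrix of per-class log measurement likelihoods over observed items.
# rho rows are classes. Degenerate rho (exactly 0 or 1) contradicted by an
# observation yields -Inf, not NaN.
log_bmat <- function(Y0, M, rho) {
  lr <- log(pmax(rho, 1e-300))
  l1r <- log(pmax(1 - rho, 1e-300))
  B <- Y0 %*% t(lr) + (M - Y0) %*% t(l1r)
  deg <- which(rho == 0 | rho == 1, arr.ind = TRUE)
  if (nrow(deg)) {
    for (j in seq_len(nrow(deg))) {
      cc <- deg[j, 1]; tt <- deg[j, 2]
      contra <- if (rho[cc, tt] == 0) {
        M[, tt] == 1 & Y0[, tt] == 1
      } else {
        M[, tt] == 1 & Y0[, tt] == 0
      }
      B[contra, cc] <- -Inf
    }
  }
  B
}

# Row-wise log-sum-exp that tolerates all -Inf rows.
row_lse <- function(A) {
  m <- apply(A, 1, max)
  m_safe <- ifelse(is.finite(m), m, 0)
  m_safe + log(rowSums(exp(A - m_safe))) + ifelse(is.finite(m), 0, -Inf)
}

# Collapse children onto unique response patterns: EM only needs the
# pattern-level sufficient statistics, which cuts the E-step from n rows to
# at most 3^T. `idx` maps children back onto pattern rows.
compress_obs <- function(Y0, M, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(Y0))
  key <- do.call(paste, c(as.data.frame(Y0 + 2 * (1 - M)), sep = ""))
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  wp <- as.vector(rowsum(w, idx, reorder = TRUE))
  list(Y0 = Y0[first, , drop = FALSE], M = M[first, , drop = FALSE],
       w = wp, idx = idx)
}

# One EM run from a given start, on (possibly pattern-compressed) data with
# row weights. Monotone ascent in the observed-data log-likelihood; rho
# clamped away from the boundary to avoid degenerate likelihoods with
# sparse cells.
em_engine <- function(Y0, M, pi0, rho0, tol = 1e-8, max_iter = 5000,
                      rho_clamp = 1e-6, trace = FALSE, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(Y0))
  pi <- pi0
  rho <- pmin(pmax(rho0, rho_clamp), 1 - rho_clamp)
  ll_old <- -Inf
  ll_trace <- if (trace) numeric(0) else NULL
  converged <- FALSE
  iter <- 0L
  post <- NULL
  ll <- -Inf
  repeat {
    iter <- iter + 1L
    A <- sweep(log_bmat(Y0, M, rho), 2, log(pmax(pi, 1e-300)), "+")
    lse <- row_lse(A)
    ll <- sum(w * lse)
    post <- exp(A - lse)
    if (trace) ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    wpost <- post * w
    nc <- colSums(wpost)
    pi <- nc / sum(nc)
    rho <- (t(wpost) %*% Y0) / pmax(t(wpost) %*% M, 1e-300)
    rho <- pmin(pmax(rho, rho_clamp), 1 - rho_clamp)
  }
  list(pi = pi, rho = rho, loglik = ll, posterior = post, n_iter = iter,
       converged = converged, loglik_trace = ll_trace)
}

# Random start: uniform-Dirichlet weights, Uniform(0.05, 0.95) item probs.
random_start <- function(C, T) {
  g <- rexp(C)
  list(pi = g / sum(g), rho = matrix(runif(C * T, 0.05, 0.95), C, T))
}

# Short-run multi-start: run every start a few iterations, polish the best
# few to full tolerance, return the highest-likelihood solution.
em_multistart <- function(Y0, M, C, n_starts, tol, max_iter, seed,
                          short_iter = 30, n_polish = 5, extra_starts = list(),
                          w = NULL) {
  T <- ncol(Y0)
  shorts <- vector("list", n_starts + length(extra_starts))
  for (i in seq_len(n_starts)) {
    set.seed(seed + i)
    st <- random_start(C, T)
    shorts[[i]] <- em_engine(Y0, M, st$pi, st$rho, tol = tol,
                             max_iter = short_iter, w = w)
  }
  for (j in seq_along(extra_starts)) {
    st <- extra_starts[[j]]
    shorts[[n_starts + j]] <- em_engine(Y0, M, st$pi, st$rho, tol = tol,
                                        max_iter = short_iter, w = w)
  }
  lls <- vapply(shorts, function(f) f$loglik, 0)
  keep <- order(lls, decreasing = TRUE)[seq_len(min(n_polish, length(shorts)))]
  fits <- lapply(shorts[keep], function(f) {
    if (f$converged) f else em_engine(Y0, M, f$pi, f$rho, tol = tol,
                                      max_iter = max_iter, w = w)
  })
  best <- fits[[which.max(vapply(fits, function(f) f$loglik, 0))]]
  best$start_logliks <- sort(lls, decreasing = TRUE)
  best
}

# ---- exported surface ------------------------------------------------------

#' Observed-data log-likelihood of a latent class model
#'
#' Evaluates the finite-mixture log-likelihood
#' \eqn{\sum_i \log \sum_c \pi_c \prod_{t \in obs(i)}
#' \rho_{ct}^{y_{it}} (1-\rho_{ct})^{1-y_{it}}}
#' over observed items only (missing-at-random items are skipped), in the log
#' domain so nothing underflows. Item probabilities of exactly 0 or 1
#' contradicted by an observation give that class a \eqn{-\infty}
#' contribution rather than an error.
#'
#' @param params an [llca_fit()] object or a list with elements
#'   `class_weights` and `item_probs` (classes x waves).
#' @param panel a long panel (see [response_panel]) or a 0/1/NA matrix.
#' @param process process to extract when `panel` is a long panel with
#'   several processes.
#' @return the scalar log-likelihood.
#' @export
llca_loglik <- function(params, panel, process = NULL) {
  Y <- resolve_panel_matrix(panel, process, params)
  if (nrow(Y) == 0) abort("empty panel")
  ob <- split_obs(Y)
  pi <- params$class_weights
  rho <- params$item_probs
  stopifnot(ncol(Y) == ncol(rho), length(pi) == nrow(rho))
  A <- sweep(log_bmat(ob$Y0, ob$M, rho), 2, log(pmax(pi, 1e-300)), "+")
  sum(row_lse(A))
}

resolve_panel_matrix <- function(panel, process, params = NULL) {
  if (is.matrix(panel)) return(panel)
  if (is.null(process)) {
    procs <- unique(panel$process)
    if (length(procs) > 1) {
      process <- if (!is.null(params) && !is.null(params$process)) {
        params$process
      } else {
        abort("panel has several processes; supply `process`")
      }
    } else {
      process <- procs
    }
  }
  panel_matrix(panel, process)
}

#' Fit a longitudinal latent class model by EM
#'
#' Fits a `n_classes`-component mixture of independent Bernoulli items to
#' repeated binary indicators with missing-at-random items, using EM with
#' multiple random starts (uniform-Dirichlet class weights, Uniform(0.05,
#' 0.95) item probabilities). All starts are run for `short_iter` iterations
#' and the best `n_polish` are polished to convergence; the highest-likelihood
#' solution is returned with classes in canonical order (see
#' [canonical_order()]). Children with no observed items are dropped with a
#' warning.
#'
#' @inheritParams llca_loglik
#' @param panel long panel or 0/1/NA matrix.
#' @param n_classes number of latent classes.
#' @param n_starts number of random starts (default 50).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per polished start.
#' @param seed master seed; per-start seeds are derived from it.
#' @param class_labels optional labels in canonical order; defaults to the
#'   process-specific trajectory names for 4-class fits.
#' @param short_iter,n_polish multi-start schedule.
#' @return an object of class `llca_fit` with elements `class_weights`,
#'   `item_probs`, `loglik`, `n_params`, `converged`, `n_children`,
#'   `posterior`, `entropy`, `class_labels`, `process`, `start_logliks`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_children = 400, seed = 3))
#' fit <- llca_fit(cohort$panel, process = "constipation", n_starts = 5, seed = 1)
#' glance(fit)
#' @export
llca_fit <- function(panel, n_classes = 4, n_starts = 50, tol = 1e-8,
                     max_iter = 5000, seed = 1L, process = NULL,
                     class_labels = NULL, short_iter = 30, n_polish = 5) {
  stopifnot(n_classes >= 1)
  Y <- resolve_panel_matrix(panel, process)
  if (is.null(process) && !is.matrix(panel)) process <- unique(panel$process)
  all_missing <- rowSums(!is.na(Y)) == 0
  if (any(all_missing)) {
    warn(paste0("dropping ", sum(all_missing), " children with no observed waves"))
    Y <- Y[!all_missing, , drop = FALSE]
  }
  if (nrow(Y) == 0) abort("empty panel")
  n <- nrow(Y)
  T <- ncol(Y)
  patterns <- apply(Y, 1, paste, collapse = "/")
  if (n_classes > length(unique(patterns))) {
    warn("n_classes exceeds the number of distinct response patterns")
  }
  ob <- split_obs(Y)
  if (n_classes == 1) {
    rho <- matrix(colSums(ob$Y0) / pmax(colSums(ob$M), 1), 1, T)
    best <- list(pi = 1, rho = rho, converged = TRUE,
                 posterior = matrix(1, n, 1), n_iter = 0L,
                 start_logliks = NA_real_)
    best$loglik <- llca_loglik(list(class_weights = 1, item_probs = rho), Y)
  } else {
    cp <- compress_obs(ob$Y0, ob$M)
    best <- em_multistart(cp$Y0, cp$M, n_classes, n_starts, tol, max_iter,
                          seed, short_iter, n_polish, w = cp$w)
    best$posterior <- best$posterior[cp$idx, , drop = FALSE]
  }
  fit <- new_llca_fit(best, Y, process, class_labels)
  canonical_order(fit)
}

new_llca_fit <- function(best, Y, process, class_labels = NULL) {
  C <- length(best$pi)
  n <- nrow(Y)
  labels <- class_labels %||% default_class_labels(C, process)
  post <- best$posterior
  rownames(post) <- rownames(Y)
  structure(
    list(
      class_weights = setNames(as.vector(best$pi), labels),
      item_probs = matrix(best$rho, C, ncol(Y),
                          dimnames = list(labels, colnames(Y))),
      loglik = best$loglik,
      n_params = (C - 1) + C * ncol(Y),
      converged = isTRUE(best$converged),
      n_children = n,
      posterior = post,
      entropy = entropy_quality(post),
      class_labels = labels,
      process = process,
      n_iter = best$n_iter,
      start_logliks = best$start_logliks
    ),
    class = "llca_fit"
  )
}

default_class_labels <- function(C, process) {
  if (C == 4 && identical(process, "soiling")) return(soiling_class_labels)
  if (C == 4 && identical(process, "constipation")) return(constipation_class_labels)
  if (C == 1) return("class1")
  c("normative", paste0("class", 2:C))
}

# Entropy-based classification quality in [0, 1]; 1 = perfect separation.
entropy_quality <- function(post) {
  C <- ncol(post)
  if (C == 1) return(1)
  p <- pmax(post, 1e-300)
  1 - sum(-p * log(p)) / (nrow(post) * log(C))
}

#' Posterior class-membership probabilities
#'
#' Bayes rule under the fitted measurement model: row i, class c proportional
#' to \eqn{\pi_c} times the likelihood of child i's observed items under
#' class c, rows normalised.
#'
#' @inheritParams llca_loglik
#' @param panel optional panel; defaults to returning the fit's stored
#'   posterior.
#' @return children x classes matrix with rows summing to 1.
#' @export
llca_posterior <- function(params, panel = NULL, process = NULL) {
  if (is.null(panel)) return(params$posterior)
  Y <- resolve_panel_matrix(panel, process, params)
  ob <- split_obs(Y)
  A <- sweep(log_bmat(ob$Y0, ob$M, params$item_probs), 2,
             log(pmax(params$class_weights, 1e-300)), "+")
  lse <- row_lse(A)
  if (any(!is.finite(lse))) {
    bad <- rownames(Y)[which(!is.finite(lse))[1]]
    abort(paste0("child ", bad, " has zero likelihood under every class"))
  }
  post <- exp(A - lse)
  rownames(post) <- rownames(Y)
  colnames(post) <- names(params$class_weights)
  post
}

#' Canonicalise latent class order
#'
#' Resolves label switching so fits are comparable across starts and
#' replicates: classes are sorted by mean item probability across waves
#' (ascending, so the first class is the normative one), ties broken by the
#' first wave at which the item probability exceeds 0.5 (early onset before
#' late onset), then by class weight descending. Weights, item probabilities,
#' posterior columns and labels are permuted consistently. Idempotent.
#'
#' @param fit an [llca_fit()] object.
#' @return the fit with classes reordered.
#' @export
canonical_order <- function(fit) {
  perm <- canonical_perm(fit$item_probs, fit$class_weights)
  labels <- fit$class_labels
  fit$class_weights <- setNames(as.vector(fit$class_weights[perm]), labels)
  fit$item_probs <- fit$item_probs[perm, , drop = FALSE]
  rownames(fit$item_probs) <- labels
  if (!is.null(fit$posterior)) {
    fit$posterior <- fit$posterior[, perm, drop = FALSE]
    colnames(fit$posterior) <- labels
  }
  fit
}

canonical_perm <- function(rho, pi) {
  mean_rho <- rowMeans(rho)
  onset <- apply(rho, 1, function(r) {
    w <- which(r > 0.5)
    if (length(w)) w[1] else ncol(rho) + 1L
  })
  order(mean_rho, onset, -pi)
}

#' Compare latent class solutions across class counts
#'
#' Fits the model for each class count in `c_min:c_max` and reports
#' log-likelihood, parameter count, BIC (\eqn{-2\ell + k \log n}), AIC,
#' entropy-based classification quality and the smallest class share; flags
#' the BIC-minimising solution. BIC is the default selection criterion; the
#' class count of the headline analysis is fixed at four per process, so this
#' is a diagnostic.
#'
#' @inheritParams llca_fit
#' @param c_min,c_max class-count range.
#' @return a tibble with one row per class count.
#' @export
enumerate_classes <- function(panel, c_min = 1, c_max = 6, n_starts = 20,
                              tol = 1e-8, max_iter = 5000, seed = 1L,
                              process = NULL, ...) {
  stopifnot(c_min >= 1, c_max >= c_min)
  rows <- purrr::map(c_min:c_max, function(C) {
    fit <- llca_fit(panel, n_classes = C, n_starts = n_starts, tol = tol,
                    max_iter = max_iter, seed = seed, process = process, ...)
    tibble::tibble(
      n_classes = C,
      loglik = fit$loglik,
      n_params = fit$n_params,
      bic = -2 * fit$loglik + fit$n_params * log(fit$n_children),
      aic = -2 * fit$loglik + 2 * fit$n_params,
      entropy = fit$entropy,
      min_class_share = min(fit$class_weights),
      converged = fit$converged
    )
  })
  out <- dplyr::bind_rows(rows)
  out$best_bic <- out$bic == min(out$bic)
  out
}

#' @export
print.llca_fit <- function(x, ...) {
  cat("Longitudinal latent class model (", length(x$class_weights),
      " classes, ", x$n_children, " children",
      if (!is.null(x$process)) paste0(", process: ", x$process), ")\n", sep = "")
  cat("log-likelihood:", format(x$loglik), " converged:", x$converged, "\n")
  cat("class weights:\n")
  print(round(x$class_weights, 4))
  invisible(x)
}
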
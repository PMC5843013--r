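# Cell layout for the 16-component joint model: cell k measures soiling
# class a_idx[k] and constipation class b_idx[k].
cell_a_idx <- rep(1:4, times = 4)
cell_b_idx <- rep(1:4, each = 4)

#' Fit the parallel-process latent class model
#'
#' Jointly models soiling (5 waves) and constipation (6 waves) with two
#' linked 4-class latent variables: a 16-component mixture over class pairs
#' (a, b) in which soiling items depend only on a and constipation items only
#' on b (local independence within and between processes given the pair);
#' all dependence between the processes is carried by the 4x4 joint weight
#' matrix, estimated on the full 15-dimensional simplex. Missing items are
#' skipped as in [llca_fit()]. Initialisation combines a warm start from the
#' two single-process fits (product-of-marginals joint weights) with random
#' starts; measurement parameters are re-estimated jointly. Classes are
#' canonicalised per process via the [canonical_order()] rule applied to the
#' implied marginal models.
#'
#' @param panel long panel containing both processes for the same children
#'   (apply [apply_inclusion_filter()] first), or the soiling-only panel if
#'   `panel_constipation` is given.
#' @param panel_constipation optional constipation panel when the two
#'   processes are supplied separately.
#' @param n_starts number of random starts in addition to the warm start.
#' @inheritParams llca_fit
#' @return an object of class `parallel_llca` with elements `joint_weights`
#'   (4x4, constipation classes in rows, soiling classes in columns),
#'   `soiling_item_probs` (4x5), `constipation_item_probs` (4x6), `loglik`,
#'   `n_params` (59), `converged`, `n_children`, `posterior` (children x 16
#'   over class pairs), `entropy`, and the single-process warm-start fits.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_children = 400, seed = 5))
#' fit <- fit_parallel(cohort$panel, n_starts = 2, seed = 1)
#' joint_class_table(fit)
#' @export
fit_parallel <- function(panel, panel_constipation = NULL, n_starts = 10,
                         tol = 1e-8, max_iter = 5000, seed = 1L,
                         short_iter = 30, n_polish = 3) {
  if (!is.null(panel_constipation)) {
    panel <- dplyr::bind_rows(panel, panel_constipation)
  }
  validate_panel(panel)
  Ys <- panel_matrix(panel, "soiling")
  Yc <- panel_matrix(panel, "constipation")
  ids <- sort(intersect(rownames(Ys), rownames(Yc)))
  if (!setequal(rownames(Ys), rownames(Yc))) {
    abort("soiling and constipation panels cover different children; align ids first")
  }
  Ys <- Ys[ids, , drop = FALSE]
  Yc <- Yc[ids, , drop = FALSE]
  obs_full <- split_obs(Ys)
  obc_full <- split_obs(Yc)
  n <- length(ids)
  # compress onto unique combined response patterns (both processes)
  key <- do.call(paste, c(
    as.data.frame(cbind(obs_full$Y0 + 2 * (1 - obs_full$M),
                        obc_full$Y0 + 2 * (1 - obc_full$M))),
    sep = ""
  ))
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  w <- as.vector(rowsum(rep(1, n), idx, reorder = TRUE))
  obs <- list(Y0 = obs_full$Y0[first, , drop = FALSE],
              M = obs_full$M[first, , drop = FALSE])
  obc <- list(Y0 = obc_full$Y0[first, , drop = FALSE],
              M = obc_full$M[first, , drop = FALSE])

  # warm start from the two single-process fits
  fs <- llca_fit(Ys, n_classes = 4, n_starts = max(10, n_starts), seed = seed,
                 tol = tol, max_iter = max_iter, process = "soiling",
                 short_iter = short_iter)
  fc <- llca_fit(Yc, n_classes = 4, n_starts = max(10, n_starts), seed = seed + 1000L,
                 tol = tol, max_iter = max_iter, process = "constipation",
                 short_iter = short_iter)
  warm <- list(
    pi16 = as.vector(fs$class_weights[cell_a_idx] * fc$class_weights[cell_b_idx]),
    rho_s = unname(fs$item_probs),
    rho_c = unname(fc$item_probs)
  )

  runs <- vector("list", n_starts + 1L)
  runs[[1]] <- em_parallel(obs, obc, warm$pi16, warm$rho_s, warm$rho_c,
                           tol, short_iter, w = w)
  for (i in seq_len(n_starts)) {
    set.seed(seed + 5000L + i)
    g <- rexp(16)
    runs[[i + 1]] <- em_parallel(
      obs, obc, g / sum(g),
      matrix(runif(4 * ncol(Ys), 0.05, 0.95), 4),
      matrix(runif(4 * ncol(Yc), 0.05, 0.95), 4),
      tol, short_iter, w = w
    )
  }
  lls <- vapply(runs, function(f) f$loglik, 0)
  keep <- order(lls, decreasing = TRUE)[seq_len(min(n_polish, length(runs)))]
  fits <- lapply(runs[keep], function(f) {
    if (f$converged) f else em_parallel(obs, obc, f$pi16, f$rho_s, f$rho_c,
                                        tol, max_iter, w = w)
  })
  best <- fits[[which.max(vapply(fits, function(f) f$loglik, 0))]]
  best$posterior <- best$posterior[idx, , drop = FALSE]

  # canonicalise each process via its implied marginal model
  pi_a <- vapply(1:4, function(a) sum(best$pi16[cell_a_idx == a]), 0)
  pi_b <- vapply(1:4, function(b) sum(best$pi16[cell_b_idx == b]), 0)
  perm_a <- canonical_perm(best$rho_s, pi_a)
  perm_b <- canonical_perm(best$rho_c, pi_b)
  new_k <- integer(16)
  for (k in 1:16) {
    a_new <- match(cell_a_idx[k], perm_a)
    b_new <- match(cell_b_idx[k], perm_b)
    new_k[k] <- (b_new - 1L) * 4L + a_new
  }
  pi16 <- numeric(16)
  pi16[new_k] <- best$pi16
  post <- matrix(0, n, 16)
  post[, new_k] <- best$posterior
  rho_s <- best$rho_s[perm_a, , drop = FALSE]
  rho_c <- best$rho_c[perm_b, , drop = FALSE]

  W <- matrix(0, 4, 4, dimnames = list(
    constipation = constipation_class_labels,
    soiling = soiling_class_labels
  ))
  W[cbind(cell_b_idx, cell_a_idx)] <- pi16
  dimnames(rho_s) <- list(soiling_class_labels, colnames(Ys))
  dimnames(rho_c) <- list(constipation_class_labels, colnames(Yc))
  rownames(post) <- ids
  colnames(post) <- paste(soiling_class_labels[cell_a_idx],
                          constipation_class_labels[cell_b_idx], sep = "|")
  structure(
    list(
      joint_weights = W,
      soiling_item_probs = rho_s,
      constipation_item_probs = rho_c,
      loglik = best$loglik,
      n_params = 15L + 4L * ncol(Ys) + 4L * ncol(Yc),
      converged = isTRUE(best$converged),
      n_children = n,
      posterior = post,
      entropy = entropy_quality(post),
      child_id = ids,
      warm_start = list(soiling = fs, constipation = fc),
      start_logliks = sort(lls, decreasing = TRUE)
    ),
    class = "parallel_llca"
  )
}

# EM for the 16-component parallel mixture.
em_parallel <- function(obs, obc, pi16, rho_s, rho_c, tol, max_iter,
                        rho_clamp = 1e-6, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(obs$Y0))
  clamp <- function(r) pmin(pmax(r, rho_clamp), 1 - rho_clamp)
  rho_s <- clamp(rho_s)
  rho_c <- clamp(rho_c)
  Ea <- outer(cell_a_idx, 1:4, "==") * 1 # 16 x 4
  Eb <- outer(cell_b_idx, 1:4, "==") * 1
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    logB <- log_bmat(obs$Y0, obs$M, rho_s)[, cell_a_idx] +
      log_bmat(obc$Y0, obc$M, rho_c)[, cell_b_idx]
    A <- sweep(logB, 2, log(pmax(pi16, 1e-300)), "+")
    lse <- row_lse(A)
    ll <- sum(w * lse)
    post <- exp(A - lse)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    wpost <- post * w
    nc <- colSums(wpost)
    pi16 <- nc / sum(nc)
    post_a <- wpost %*% Ea
    post_b <- wpost %*% Eb
    rho_s <- clamp((t(post_a) %*% obs$Y0) / pmax(t(post_a) %*% obs$M, 1e-300))
    rho_c <- clamp((t(post_b) %*% obc$Y0) / pmax(t(post_b) %*% obc$M, 1e-300))
  }
  list(pi16 = pi16, rho_s = rho_s, rho_c = rho_c, loglik = ll,
       posterior = post, n_iter = iter, converged = converged)
}

#' Display the joint class distribution as percentages
#'
#' Converts the fitted 4x4 joint weights to percentages with row and column
#' totals. The numeric return keeps full precision; the display variant
#' (`censor_small = TRUE`) rounds to one decimal, as the published table
#' does, and renders estimated cells in (0, 0.05) percent as `"<0.1"`.
#'
#' @param params a [fit_parallel()] result or a 4x4 joint weight matrix
#'   (constipation rows x soiling columns) of probabilities or percentages.
#' @param censor_small return the rounded character display instead of the
#'   numeric table?
#' @return a 5x5 numeric matrix (with `total` row and column), or a character
#'   matrix when `censor_small = TRUE`.
#' @export
joint_class_table <- function(params, censor_small = FALSE) {
  W <- if (inherits(params, "parallel_llca")) params$joint_weights else as.matrix(params)
  stopifnot(all(dim(W) == c(4, 4)))
  pct <- W / sum(W) * 100
  full <- rbind(cbind(pct, total = rowSums(pct)),
                total = c(colSums(pct), 100))
  if (censor_small) {
    disp <- matrix(sprintf("%.1f", full), 5, 5, dimnames = dimnames(full))
    disp[full > 0 & full < 0.05] <- "<0.1"
    return(disp)
  }
  full
}

#' @export
print.parallel_llca <- function(x, ...) {
  cat("Parallel-process latent class model (4 x 4 classes, ",
      x$n_children, " children)\n", sep = "")
  cat("log-likelihood:", format(x$loglik), " converged:", x$converged, "\n")
  cat("joint class distribution (%):\n")
  print(round(joint_class_table(x), 1))
  invisible(x)
}
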
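#' Tidy a single-process latent class fit
#'
#' @param x an [llca_fit()] object.
#' @param ... unused.
#' @return one row per class and wave with the item-response probability and
#'   the class weight.
#' @method tidy llca_fit
#' @export
tidy.llca_fit <- function(x, ...) {
  tibble::tibble(
    class = rep(x$class_labels, times = ncol(x$item_probs)),
    wave = rep(seq_len(ncol(x$item_probs)) - 1L, each = nrow(x$item_probs)),
    item_prob = as.vector(x$item_probs),
    class_weight = rep(unname(x$class_weights), times = ncol(x$item_probs))
  ) %>% dplyr::arrange(.data$class, .data$wave)
}

#' @rdname tidy.llca_fit
#' @method glance llca_fit
#' @export
glance.llca_fit <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_weights),
    loglik = x$loglik,
    n_params = x$n_params,
    bic = -2 * x$loglik + x$n_params * log(x$n_children),
    aic = -2 * x$loglik + 2 * x$n_params,
    entropy = x$entropy,
    converged = x$converged,
    n_children = x$n_children
  )
}

#' Tidy a parallel-process fit
#'
#' @param x a [fit_parallel()] object.
#' @param what `"weights"` for the 16 joint-cell weights, `"soiling"` or
#'   `"constipation"` for the measurement profiles.
#' @param ... unused.
#' @method tidy parallel_llca
#' @export
tidy.parallel_llca <- function(x, what = c("weights", "soiling", "constipation"), ...) {
  what <- match.arg(what)
  if (what == "weights") {
    W <- x$joint_weights
    return(tibble::tibble(
      constipation_class = rep(rownames(W), times = 4),
      soiling_class = rep(colnames(W), each = 4),
      weight = as.vector(W),
      percent = 100 * as.vector(W)
    ))
  }
  rho <- if (what == "soiling") x$soiling_item_probs else x$constipation_item_probs
  tibble::tibble(
    class = rep(rownames(rho), times = ncol(rho)),
    wave = rep(seq_len(ncol(rho)) - 1L, each = nrow(rho)),
    item_prob = as.vector(rho)
  )
}

#' @rdname tidy.parallel_llca
#' @method glance parallel_llca
#' @export
glance.parallel_llca <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_params = x$n_params,
    bic = -2 * x$loglik + x$n_params * log(x$n_children),
    entropy = x$entropy,
    converged = x$converged,
    n_children = x$n_children
  )
}

#' Tidy a three-step regression fit
#'
#' @param x a [fit_threestep()] object.
#' @param conf.level confidence level for the Wald intervals.
#' @param ... unused.
#' @return one row per coefficient with log OR, SE, z statistic, p-value, OR
#'   and confidence limits.
#' @method tidy threestep_fit
#' @export
tidy.threestep_fit <- function(x, conf.level = 0.95, ...) {
  out <- wald_intervals(x, level = conf.level)
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  out
}

#' @rdname tidy.threestep_fit
#' @method glance threestep_fit
#' @export
glance.threestep_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_used = x$n_used,
    converged = x$converged,
    gradient_norm = x$gradient_norm,
    separation = x$separation
  )
}
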
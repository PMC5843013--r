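# Shared fixtures and independent oracles, all built in code.

# 4-pattern toy: (0,0) x40, (1,1) x40, (1,0) x10, (0,1) x10
toy_patterns <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
toy_counts <- c(40, 40, 10, 10)

toy_matrix <- function() {
  Y <- toy_patterns[rep(1:4, toy_counts), ]
  rownames(Y) <- sprintf("t%03d", seq_len(nrow(Y)))
  Y
}

# Independent oracle for the 2-class, 2-item model: direct numerical
# maximisation of the likelihood over the 5 free parameters (logit scale),
# best of several random starts. Stays independent of the EM path.
lca2_oracle_loglik <- function(patterns, counts, n_starts = 40, seed = 1) {
  nll <- function(par) {
    p1 <- plogis(par[1])
    rho <- matrix(plogis(par[2:5]), 2, 2)
    lik <- vapply(seq_len(nrow(patterns)), function(i) {
      y <- patterns[i, ]
      p1 * prod(rho[1, ]^y * (1 - rho[1, ])^(1 - y)) +
        (1 - p1) * prod(rho[2, ]^y * (1 - rho[2, ])^(1 - y))
    }, 0)
    -sum(counts * log(lik))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    o <- optim(rnorm(5, 0, 2), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  -best
}

# Long two-process panel from a pair of response matrices sharing ids.
pair_panel <- function(Ys, Yc) {
  dplyr::bind_rows(
    llca:::matrix_panel(Ys, "soiling"),
    llca:::matrix_panel(Yc, "constipation")
  )
}

# Small calibrated cohort config for fast end-to-end runs.
small_config <- function(n = 800, seed = 42, ...) {
  cohort_config(n_children = n, seed = seed, ...)
}

sex_only_specs <- function(or_soiling_alone = 1.78,
                           or_constipation_alone = 1,
                           or_with_soiling = 1) {
  list(covariate_spec(
    "male", "binary", levels = c("female", "male"), probs = c(0.52, 0.48),
    effects = matrix(log(c(or_constipation_alone, or_soiling_alone,
                           or_with_soiling)), 1, 3)
  ))
}

composite_order <- c("normative", "constipation_alone", "soiling_alone",
                     "constipation_with_soiling")
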
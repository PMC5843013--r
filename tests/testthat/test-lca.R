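test_that("log-likelihood matches closed forms and hand enumeration", {
  # C=1, rho = 0.5 everywhere: each observed wave contributes log 0.5
  p1 <- list(class_weights = 1, item_probs = matrix(0.5, 1, 6))
  Y <- matrix(c(1, 0, 1, 1, 0, 0), 1, 6, dimnames = list("a", NULL))
  expect_equal(llca_loglik(p1, Y), 6 * log(0.5))

  # 2-class hand enumeration: 0.6*0.1*0.9 + 0.4*0.9*0.1 = 0.09
  p2 <- list(class_weights = c(0.6, 0.4),
             item_probs = rbind(c(0.1, 0.1), c(0.9, 0.9)))
  Y2 <- matrix(c(1, 0), 1, 2, dimnames = list("a", NULL))
  expect_equal(llca_loglik(p2, Y2), log(0.09), tolerance = 1e-12)

  # missing items are skipped: only observed waves contribute
  Ym <- matrix(c(1, NA, 0, NA, NA, NA), 1, 6, dimnames = list("a", NULL))
  expect_equal(llca_loglik(p1, Ym), 2 * log(0.5))
  expect_error(llca_loglik(p1, Y[0, , drop = FALSE]), "empty")
})

test_that("degenerate item probabilities give -Inf contributions, not crashes", {
  p <- list(class_weights = c(0.5, 0.5),
            item_probs = rbind(c(0, 0.5), c(1, 0.5)))
  # child observes y1 = 1: class 1 impossible, class 2 fine
  Y <- matrix(c(1, 0), 1, 2, dimnames = list("a", NULL))
  ll <- llca_loglik(p, Y)
  expect_true(is.finite(ll))
  expect_equal(ll, log(0.5 * 1 * 0.5))
  # contradicting both classes: -Inf total, no error
  p_bad <- list(class_weights = c(0.5, 0.5),
                item_probs = rbind(c(0, 0.5), c(0, 0.5)))
  expect_identical(llca_loglik(p_bad, Y), -Inf)
})

test_that("posterior probabilities follow Bayes rule", {
  p2 <- list(class_weights = c(0.6, 0.4),
             item_probs = rbind(c(0.1, 0.1), c(0.9, 0.9)), process = NULL)
  Y2 <- matrix(c(1, 0), 1, 2, dimnames = list("a", NULL))
  post <- llca_posterior(p2, Y2)
  expect_equal(as.vector(post), c(0.054 / 0.09, 0.036 / 0.09))

  # one class: posterior exactly 1
  p1 <- list(class_weights = 1, item_probs = matrix(0.5, 1, 2), process = NULL)
  expect_equal(as.vector(llca_posterior(p1, Y2)), 1)

  # symmetric model and symmetric pattern: posterior (0.5, 0.5)
  psym <- list(class_weights = c(0.5, 0.5),
               item_probs = rbind(c(0.1, 0.9), c(0.9, 0.1)), process = NULL)
  Ysym <- matrix(c(1, 1), 1, 2, dimnames = list("a", NULL))
  expect_equal(as.vector(llca_posterior(psym, Ysym)), c(0.5, 0.5))

  # a child impossible under every class is reported by id
  pz <- list(class_weights = c(0.5, 0.5),
             item_probs = rbind(c(0, 0.5), c(0, 0.5)), process = NULL)
  expect_error(llca_posterior(pz, matrix(c(1, 0), 1, 2, dimnames = list("kid7", NULL))),
               "kid7")
})

test_that("one-class fit reduces to independent Bernoulli maxima", {
  set.seed(4)
  Y <- matrix(rbinom(300, 1, rep(c(0.2, 0.5, 0.8), each = 100)), 100, 3)
  rownames(Y) <- sprintf("c%03d", 1:100)
  fit <- llca_fit(Y, n_classes = 1)
  expect_equal(unname(fit$class_weights), 1)
  expect_equal(unname(as.vector(fit$item_probs)), unname(colMeans(Y)))
  p <- colMeans(Y)
  ll_ind <- sum(Y %*% log(p) + (1 - Y) %*% log(1 - p))
  expect_equal(fit$loglik, ll_ind, tolerance = 1e-10)
})

test_that("EM attains the brute-force maximum on the 4-pattern toy", {
  Y <- toy_matrix()
  fit <- llca_fit(Y, n_classes = 2, n_starts = 20, seed = 1, tol = 1e-12)
  oracle <- lca2_oracle_loglik(toy_patterns, toy_counts)
  # frozen oracle value: -119.3549604098
  expect_equal(oracle, -119.3549604098, tolerance = 1e-7)
  expect_equal(fit$loglik, oracle, tolerance = 1e-6)
})

test_that("EM log-likelihood never decreases across iterations", {
  set.seed(8)
  ch <- generate_cohort(small_config(n = 300, seed = 15))
  Y <- panel_matrix(ch$panel, "constipation")
  ob <- llca:::split_obs(Y)
  for (s in 1:100) {
    set.seed(s)
    st <- llca:::random_start(4, ncol(Y))
    run <- llca:::em_engine(ob$Y0, ob$M, st$pi, st$rho, tol = 1e-10,
                            max_iter = 80, trace = TRUE)
    dll <- diff(run$loglik_trace)
    expect_true(all(dll >= -1e-7 * abs(run$loglik)))
  }
})

test_that("deleting a wave for everyone equals fitting the reduced panel", {
  ch <- generate_cohort(small_config(n = 500, seed = 23))
  Y <- panel_matrix(ch$panel, "constipation")
  Ydel <- Y
  Ydel[, 3] <- NA
  # the likelihood functions coincide exactly: a wave that is missing for
  # everyone contributes nothing, whatever the parameters
  set.seed(77)
  for (r in 1:10) {
    pi <- rexp(3)
    pi <- pi / sum(pi)
    rho6 <- matrix(runif(18), 3, 6)
    ll_del <- llca_loglik(list(class_weights = pi, item_probs = rho6), Ydel)
    ll_red <- llca_loglik(list(class_weights = pi, item_probs = rho6[, -3]), Y[, -3])
    expect_equal(ll_del, ll_red, tolerance = 1e-12)
  }
  # and the fitted optima agree up to the convergence tolerance
  f1 <- llca_fit(Ydel, n_classes = 3, n_starts = 10, seed = 2, tol = 1e-10)
  f2 <- llca_fit(Y[, -3], n_classes = 3, n_starts = 10, seed = 2, tol = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
  expect_equal(unname(f1$class_weights), unname(f2$class_weights), tolerance = 1e-2)
  expect_equal(unname(f1$item_probs[, -3]), unname(f2$item_probs), tolerance = 1e-2)
})

test_that("canonical ordering is idempotent and undoes label switching", {
  ch <- generate_cohort(small_config(n = 600, seed = 31))
  fit <- llca_fit(ch$panel, process = "constipation", n_classes = 4,
                  n_starts = 10, seed = 3)
  expect_identical(canonical_order(fit), fit)
  perm <- c(3, 1, 4, 2)
  shuffled <- fit
  shuffled$class_weights <- setNames(unname(fit$class_weights[perm]), fit$class_labels)
  shuffled$item_probs <- fit$item_probs[perm, ]
  rownames(shuffled$item_probs) <- fit$class_labels
  shuffled$posterior <- fit$posterior[, perm]
  colnames(shuffled$posterior) <- fit$class_labels
  expect_equal(canonical_order(shuffled), fit)
})

test_that("canonical labels give early onset before late onset on calibrated data", {
  ch <- generate_cohort(small_config(n = 4000, seed = 37))
  fit <- llca_fit(ch$panel, process = "constipation", n_classes = 4,
                  n_starts = 20, seed = 4)
  rho <- fit$item_probs
  expect_gt(mean(rho["early", 1:3]), mean(rho["early", 4:6]))
  expect_lt(mean(rho["late", 1:3]), mean(rho["late", 4:6]))
  expect_equal(rownames(rho)[1], "normative")
})

test_that("class enumeration reports coherent information criteria", {
  # everyone all-zero: one class is enough
  Y <- matrix(0, 60, 4, dimnames = list(sprintf("c%02d", 1:60), NULL))
  expect_warning(
    tab <- enumerate_classes(Y, 1, 2, n_starts = 5, seed = 1),
    "distinct response patterns"
  )
  expect_true(tab$best_bic[tab$n_classes == 1])
  # BIC/AIC arithmetic on every row
  expect_equal(tab$bic, -2 * tab$loglik + tab$n_params * log(60))
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$n_params)
})

test_that("BIC selects the generating class count on well-separated data", {
  reps <- 20
  hits <- 0
  w <- alspac_joint_percent() / 100
  w <- w * alspac_constipation_split() / rowSums(w)
  for (r in seq_len(reps)) {
    cfg <- cohort_config(n_children = 8435, joint_class_weights = w,
                         seed = 700 + r)
    ch <- generate_cohort(cfg)
    Y <- panel_matrix(ch$panel, "constipation")
    tab <- enumerate_classes(Y, 3, 5, n_starts = 10, seed = 70 + r)
    hits <- hits + (tab$n_classes[tab$best_bic] == 4)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("posterior rows sum to one and entropy lies in [0, 1]", {
  ch <- generate_cohort(small_config(n = 400, seed = 51))
  cfgm <- small_config(n = 400, seed = 51)
  panel <- apply_missingness(ch$panel, cfgm)
  panel <- apply_inclusion_filter(panel, 3, "constipation")
  fit <- llca_fit(panel, process = "constipation", n_classes = 4,
                  n_starts = 10, seed = 5)
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-10))
  expect_true(fit$entropy >= 0 && fit$entropy <= 1)
  expect_true(all(abs(sum(fit$class_weights) - 1) < 1e-10))
})
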
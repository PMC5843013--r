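test_that("the collapse map covers 1+3+3+9 cells", {
  map <- composite_map()
  expect_equal(nrow(map), 16)
  expect_equal(as.vector(table(map$composite)), c(1, 3, 3, 9))
  bad <- map[-1, ]
  expect_error(collapse_posterior(matrix(1 / 16, 2, 16), bad), "16")
})

test_that("collapse of joint posteriors conserves mass and matches brute force", {
  # concentrated on (normative, normative)
  p <- matrix(0, 1, 16)
  p[1, 1] <- 1 # cell (a=1, b=1)
  cp <- collapse_posterior(p)
  expect_equal(as.vector(cp$posterior), c(1, 0, 0, 0))

  u <- matrix(1 / 16, 1, 16)
  expect_equal(as.vector(collapse_posterior(u)$posterior),
               c(1 / 16, 3 / 16, 3 / 16, 9 / 16))

  # random posteriors vs an explicit 16-row lookup table
  set.seed(9)
  P <- matrix(rexp(5 * 16), 5, 16)
  P <- P / rowSums(P)
  rownames(P) <- letters[1:5]
  cp <- collapse_posterior(P)
  lookup <- composite_map()
  manual <- matrix(0, 5, 4)
  for (k in 1:16) {
    a <- llca:::cell_a_idx[k]
    b <- llca:::cell_b_idx[k]
    g <- as.integer(lookup$composite[lookup$soiling_class == a &
                                       lookup$constipation_class == b])
    manual[, g] <- manual[, g] + P[, k]
  }
  expect_equal(unname(cp$posterior), manual, tolerance = 1e-12)
  expect_true(all(abs(rowSums(cp$posterior) - 1) < 1e-12))
  expect_equal(unname(cp$composite_weights), unname(colMeans(cp$posterior)))
})

test_that("composite proportions reproduce the published footnote shares", {
  shares <- composite_proportions(alspac_joint_percent())
  expect_equal(unname(shares), c(74.5, 13.2, 7.5, 4.8))
  expect_equal(sum(shares), sum(alspac_joint_percent()))
  expect_equal(unname(composite_proportions(matrix(6.25, 4, 4))),
               c(6.25, 18.75, 18.75, 56.25))
})

test_that("collapse is invariant to relabelling non-normative classes", {
  set.seed(11)
  W <- matrix(rexp(16), 4)
  W <- W / sum(W)
  for (r in 1:5) {
    ps <- c(1, sample(2:4)) # permute non-normative soiling classes
    pc <- c(1, sample(2:4))
    expect_equal(composite_proportions(W[pc, ps]), composite_proportions(W))
  }
})

test_that("soiler split and any-constipation prevalence match the published arithmetic", {
  shares <- composite_proportions(alspac_joint_percent())
  expect_equal(unname(soiler_split(shares)), c(61, 39))
  expect_equal(any_constipation_prevalence(shares), 18.0)
  expect_equal(unname(soiler_split(c(50, 0, 25, 25))), c(50, 50))
  expect_equal(unname(soiler_split(c(0, 0, 10, 0))), c(100, 0))
  expect_error(soiler_split(c(90, 10, 0, 0)), "soiling")
  expect_equal(any_constipation_prevalence(c(100, 0, 0, 0)), 0)
  expect_equal(any_constipation_prevalence(c(0, 50, 0, 50)), 100)
})

test_that("posterior-weighted symptom rates match hand arithmetic", {
  P <- rbind(
    c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0),
    c(0.5, 0.5, 0, 0), c(0.2, 0.2, 0.3, 0.3), c(0, 0, 1, 0)
  )
  rownames(P) <- paste0("k", 1:6)
  cp <- structure(
    list(posterior = P, child_id = rownames(P),
         modal = modal_assign(P), composite_weights = colMeans(P)),
    class = "composite_posterior"
  )
  y <- c(k1 = 1, k2 = 0, k3 = 1, k4 = 1, k5 = NA, k6 = 0)
  rates <- symptom_rates_by_class(cp, y)
  # hand: group1 mass 1+1+0.5 = 2.5, events 1+0.5 = 1.5 (k5 dropped)
  expect_equal(rates$rate[1], 1.5 / 2.5)
  expect_equal(rates$rate[2], (1 + 0.5) / (1 + 0.5))
  expect_equal(rates$rate[3], 0 / 1)
  expect_true(is.na(rates$rate[4])) # no observed mass in group 4
  # symptom identically 1: all observed-group rates are 1
  y1 <- setNames(rep(1, 6), rownames(P))
  r1 <- symptom_rates_by_class(cp, y1)
  expect_true(all(r1$rate[r1$effective_n > 0] == 1))
  # deterministic posteriors equal stratified means
  cp_det <- structure(
    list(posterior = diag(4)[c(1, 1, 2, 3), ], child_id = paste0("d", 1:4),
         modal = modal_assign(diag(4)[c(1, 1, 2, 3), ]),
         composite_weights = colMeans(diag(4)[c(1, 1, 2, 3), ])),
    class = "composite_posterior"
  )
  yd <- setNames(c(1, 0, 1, 1), paste0("d", 1:4))
  rd <- symptom_rates_by_class(cp_det, yd)
  expect_equal(rd$rate[1:3], c(0.5, 1, 1))
})

test_that("marginal prevalence table reproduces percentage arithmetic and nesting", {
  expect_equal(prevalence_pct(673, 8720), 7.2)
  expect_equal(prevalence_pct(1342, 7947), 14.4)

  # toy panel: child A complete, B >= 3 both, C only 1 wave each, D empty
  Ys <- rbind(A = c(1, 0, 0, 0, 0), B = c(1, 1, 1, NA, NA),
              C = c(1, NA, NA, NA, NA), D = rep(NA_real_, 5))
  Yc <- rbind(A = c(1, 0, 0, 0, 0, 0), B = c(0, 1, 1, NA, NA, NA),
              C = c(NA, NA, 0, NA, NA, NA), D = rep(NA_real_, 6))
  tab <- marginal_prevalence_table(pair_panel(Ys, Yc))
  w0 <- tab[tab$sample == "min1" & tab$process == "soiling" & tab$wave == 0, ]
  expect_equal(w0$n_symptom, 3)
  expect_equal(w0$n_no_symptom, 0)
  expect_equal(w0$pct, 100)
  c0 <- tab[tab$sample == "min3" & tab$process == "constipation" & tab$wave == 0, ]
  expect_equal(c0$n_symptom + c0$n_no_symptom, 2) # only A and B survive
  comp <- tab[tab$sample == "complete" & tab$process == "soiling" & tab$wave == 0, ]
  expect_equal(comp$n_symptom + comp$n_no_symptom, 1) # only A is complete
  # all-missing wave: undefined percentage
  w4 <- tab[tab$sample == "complete" & tab$process == "soiling" & tab$wave == 4, ]
  expect_equal(w4$pct, 0) # child A observed 0 there
  Ys2 <- rbind(A = c(1, NA, 0, 0, 0))
  Yc2 <- rbind(A = c(1, 0, 0, 0, 0, 0))
  tab2 <- marginal_prevalence_table(pair_panel(Ys2, Yc2))
  miss <- tab2[tab2$sample == "min1" & tab2$process == "soiling" & tab2$wave == 1, ]
  expect_true(is.na(miss$pct))
})
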
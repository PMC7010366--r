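# Incidence function model: connectivity, transitions, simulation, fitting.

test_that("connectivity matches closed forms", {
  p <- point_patches(c(1, 4), c(0, 2))
  S <- ifm_connectivity(p, c(0, 1), alpha = 0.5)
  expect_equal(S[1], 4 * exp(-1), tolerance = 1e-12)
  expect_equal(S[2], 0) # patch 1 empty contributes nothing
  expect_equal(ifm_connectivity(p, c(0, 0), alpha = 0.5), c(0, 0))
})

test_that("connectivity matches a brute-force double loop on random patches", {
  set.seed(13)
  n <- 30
  p <- point_patches(exp(runif(n, log(0.1), log(10))),
                     runif(n, 0, 10), runif(n, 0, 10))
  state <- rbinom(n, 1, 0.5)
  alpha <- 0.7; b <- 1.3
  S <- ifm_connectivity(p, state, alpha, b)
  oracle <- vapply(1:n, function(i) {
    s <- 0
    for (j in 1:n) {
      if (j == i) next
      d <- sqrt((p$cx[i] - p$cx[j])^2 + (p$cy[i] - p$cy[j])^2) / 1000
      s <- s + state[j] * exp(-alpha * d) * p$area_ha[j]^b
    }
    s
  }, numeric(1))
  expect_equal(S, oracle, tolerance = 1e-12)
})

test_that("connectivity is linear in patch areas when b = 1", {
  set.seed(14)
  p <- point_patches(runif(10, 0.5, 5), runif(10, 0, 5), runif(10, 0, 5))
  state <- rep(1, 10)
  S1 <- ifm_connectivity(p, state, alpha = 1, b = 1)
  p2 <- p; p2$area_ha <- 2 * p$area_ha
  expect_equal(ifm_connectivity(p2, state, alpha = 1, b = 1), 2 * S1,
               tolerance = 1e-12)
})

test_that("transition probabilities follow the model formulas", {
  pr <- ifm_params(alpha = 1, x = 1, ey2 = 0.2)
  tp <- ifm_transition_probs(2, S = 0, pr)
  expect_equal(tp$C, 0)
  expect_equal(tp$E_eff, 0.1) # 0.2 / 2, no rescue reduction at C=0
  tp2 <- ifm_transition_probs(1, S = 1, pr) # S = y -> C = 1/2
  expect_equal(tp2$C, 0.5)
  expect_equal(tp2$E_eff, 0.2 * 0.5) # rescue halves extinction
  pr_nr <- ifm_params(alpha = 1, x = 1, ey2 = 0.2, rescue = FALSE)
  expect_equal(ifm_transition_probs(1, S = 1, pr_nr)$E_eff, 0.2)
  expect_error(ifm_transition_probs(0, 1, pr), "areas")
})

test_that("probabilities stay in [0,1] and are monotone in A and S", {
  set.seed(15)
  for (i in 1:200) {
    pr <- ifm_params(alpha = runif(1, 0.1, 3), x = runif(1, -1, 3),
                     ey2 = runif(1, 0, 5), y = runif(1, 0.2, 3))
    A <- exp(runif(5, log(0.01), log(100)))
    S <- sort(exp(runif(5, log(0.001), log(100))))
    tp <- ifm_transition_probs(A, S, pr)
    expect_true(all(tp$C >= 0 & tp$C <= 1 & tp$E >= 0 & tp$E <= 1 &
                      tp$E_eff >= 0 & tp$E_eff <= 1))
    # C increasing in S (A held fixed), E decreasing in A (for x > 0)
    expect_true(all(diff(ifm_transition_probs(rep(1, 5), S, pr)$C) >= 0))
    if (pr$x > 0) {
      tpA <- ifm_transition_probs(sort(A), rep(1, 5), pr)
      expect_true(all(diff(tpA$E) <= 1e-12))
    }
  }
})

test_that("forced transitions behave deterministically", {
  p1 <- point_patches(1, 0)
  pr_dead <- ifm_params(alpha = 1, x = 1, ey2 = 1) # E = 1 for A = 1, S = 0
  set.seed(1)
  expect_identical(ifm_step(1L, p1, pr_dead), 0L)
  pr_safe <- ifm_params(alpha = 1, x = 1, ey2 = 0) # never extinct
  p <- point_patches(c(1, 2), c(0, 1))
  set.seed(2)
  for (i in 1:20) expect_true(all(ifm_step(c(1L, 1L), p, pr_safe) == 1L))
})

test_that("one-step transition frequencies match the exact 2-patch chain", {
  p <- point_patches(c(1.5, 3), c(0, 1.2))
  pr <- ifm_params(alpha = 1, x = 1, ey2 = 0.6)
  P <- ifm_exact_chain(p, pr)
  start_state <- c(1L, 1L)
  n_draws <- 10000
  counts <- integer(4)
  set.seed(77)
  for (i in seq_len(n_draws)) {
    nxt <- ifm_step(start_state, p, pr)
    s <- nxt[1] + 2 * nxt[2]
    counts[s + 1] <- counts[s + 1] + 1L
  }
  expected <- P[4, ] # from state {1,1} (0-based code 3)
  pval <- suppressWarnings(stats::chisq.test(counts, p = expected)$p.value)
  expect_gt(pval, 0.01)
})

test_that("simulation has the required shape, determinism and absorption", {
  p <- point_patches(c(1, 2, 4), c(0, 1, 2))
  pr <- ifm_params(alpha = 1, x = 1, ey2 = 0.5)
  tr <- ifm_simulate(c(1L, 0L, 1L), p, pr, steps = 50, reps = 10, seed = 3)
  expect_identical(dim(tr$occ), c(10L, 51L, 3L))
  expect_true(all(tr$occ[, 1, ] == rep(c(1L, 0L, 1L), each = 10)))
  tr2 <- ifm_simulate(c(1L, 0L, 1L), p, pr, steps = 50, reps = 10, seed = 3)
  expect_identical(tr$occ, tr2$occ)
  # absorbing all-zero state never resurrects
  pr_hot <- ifm_params(alpha = 1, x = 1, ey2 = 5)
  tr3 <- ifm_simulate(c(1L, 1L, 1L), p, pr_hot, steps = 80, reps = 30, seed = 4)
  for (r in 1:30) {
    occ_t <- rowSums(tr3$occ[r, , ])
    died <- which(occ_t == 0)
    if (length(died) > 0) expect_true(all(occ_t[died[1]:length(occ_t)] == 0))
  }
  # zero-patch landscape yields the tagged zero bundle
  tr0 <- ifm_simulate(integer(0), p[0, ], pr, steps = 5, reps = 2)
  expect_true(tr0$zero_habitat)
  expect_identical(dim(tr0$occ), c(2L, 6L, 0L))
})

test_that("long-run occupancy matches the exact quasi-stationary law", {
  p <- point_patches(c(4, 6), c(0, 0.8))
  pr <- ifm_params(alpha = 1, x = 1, ey2 = 0.8)
  P <- ifm_exact_chain(p, pr)
  qsd <- ifm_qsd(P) # over states {1}, {2}, {1,2}
  tr <- ifm_simulate(c(1L, 1L), p, pr, steps = 60, reps = 4000, seed = 5)
  final <- tr$occ[, 61, 1] + 2 * tr$occ[, 61, 2]
  alive <- final[final > 0]
  counts <- table(factor(alive, levels = 1:3))
  pval <- suppressWarnings(stats::chisq.test(as.integer(counts), p = qsd)$p.value)
  expect_gt(pval, 0.01)
})

test_that("fitting recovers generating parameters on a small harness", {
  res <- recovery_rep(seed = 101)
  expect_lt(abs(res$x - 0.8), 0.15)
  expect_lt(abs(res$lney2 - log(0.3)), 0.3)
  # unconstrained fit puts the connectivity coefficient near its
  # theoretical value of 2
  res_u <- recovery_rep(seed = 101, mode = "unconstrained")
  expect_lt(abs(res_u$coef_lnS - 2), 0.5)
})

test_that("fit accessors expose coefficients and mapped parameters", {
  set.seed(61)
  p <- point_patches(exp(runif(80, log(0.3), log(12))),
                     runif(80, 0, 25), runif(80, 0, 25))
  h <- generate_occupancy_history(p, ifm_params(1, 0.8, 0.3), years = 15,
                                  initial_prevalence = 0.7, seed = 61,
                                  discard = 40)
  f <- fit_ifm(h, p, alpha = 1)
  expect_s3_class(tidy(f), "tbl_df")
  expect_identical(tidy(f)$term, c("(Intercept)", "lnA", "lnS"))
  g <- glance(f)
  expect_equal(g$ey2, exp(-unname(f$params$fitted_coefs["intercept"])))
  expect_equal(g$x, unname(coef(f$fit)["lnA"]))
})

test_that("degenerate histories are rejected with diagnostics", {
  p <- point_patches(c(1, 2, 3), c(0, 1, 2))
  h_all <- matrix(1L, nrow = 8, ncol = 3)
  expect_error(fit_ifm(h_all, p, alpha = 1, species = "sp-x"), "separation")
  h_short <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L), nrow = 2)
  expect_error(fit_ifm(h_short[, 1:3, drop = FALSE], p, alpha = 1), "10 usable")
  expect_error(fit_ifm(h_all[1, , drop = FALSE], p, alpha = 1), "2 years")
})
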
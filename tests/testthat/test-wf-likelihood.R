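test_that("genic selection update has the closed form, fixed points and bounds", {
  expect_identical(selection_update(0.5, 0), 0.5)
  expect_equal(selection_update(0.5, 0.5), 0.6)
  expect_equal(selection_update(0, 0.5), 0)
  expect_equal(selection_update(1, 0.5), 1)
  # stays in [0,1] and is monotone in p for a spread of coefficients
  p <- seq(0, 1, by = 0.05)
  for (s in c(-0.9, -0.3, 0, 0.7, 5)) {
    out <- selection_update(p, s)
    expect_true(all(out >= 0 & out <= 1))
    expect_true(all(diff(out) >= 0))
  }
  expect_error(selection_update(0.5, -1), "selection coefficient")
  expect_error(selection_update(1.2, 0.1), "\\[0, 1\\]")
})

test_that("transition matrix rows are binomial pmfs that sum to one", {
  M <- wf_transition_matrix(2, 0)
  expect_equal(M[3, ], dbinom(0:4, 4, 0.5))
  expect_equal(M[3, ], c(1, 4, 6, 4, 1) / 16)
  # absorbing boundaries
  expect_equal(M[1, ], c(1, 0, 0, 0, 0))
  expect_equal(M[5, ], c(0, 0, 0, 0, 1))
  # with selection: row at p = 0.5, s = 1 uses p' = 2/3
  M1 <- wf_transition_matrix(2, 1)
  expect_equal(M1[3, 5], (2 / 3)^4)
  expect_equal(M1[3, 5], 16 / 81)
  # normalisation at realistic size
  M34 <- wf_transition_matrix(34, 0.5)
  expect_equal(rowSums(M34), rep(1, 69), tolerance = 1e-12)
  expect_error(wf_transition_matrix(1, 0), "Ne")
})

test_that("emission probabilities are binomial in the population frequency", {
  expect_equal(wf_emission_prob(0, 10, 0, 34), 1)
  expect_equal(wf_emission_prob(5, 10, 34, 34), choose(10, 5) * 0.5^10)
  expect_equal(wf_emission_prob(5, 10, 34, 34), 252 / 1024)
  for (i in c(0, 7, 40, 68)) {
    expect_equal(sum(wf_emission_prob(0:10, 10, i, 34)), 1, tolerance = 1e-12)
  }
  expect_error(wf_emission_prob(11, 10, 3, 34), "k <= n")
})

test_that("log-likelihood matches exhaustive path enumeration on tiny instances", {
  cases <- list(
    list(k = c(1, 3), n = c(4, 4), gen = c(0, 2), Ne = 2),
    list(k = c(3, 1), n = c(6, 4), gen = c(0, 3), Ne = 2),
    list(k = c(1, 2, 4), n = c(4, 4, 4), gen = c(0, 1, 3), Ne = 3),
    list(k = c(0, 2, 5), n = c(2, 4, 6), gen = c(0, 2, 3), Ne = 3)
  )
  for (cs in cases) {
    for (s in c(0, 0.5, -0.5)) {
      for (init in c("first_sample", "uniform")) {
        expect_equal(
          wf_loglik(cs$k, cs$n, cs$gen, cs$Ne, s, init = init),
          oracle_loglik(cs$k, cs$n, cs$gen, cs$Ne, s, init = init),
          tolerance = 1e-9,
          label = sprintf("forward pass (init=%s, s=%g)", init, s)
        )
      }
    }
  }
})

test_that("zero elapsed generations make the likelihood independent of s", {
  for (init in c("first_sample", "uniform")) {
    lls <- vapply(c(-0.5, 0, 0.8, 3),
                  function(s) wf_loglik(c(10, 30), c(40, 40), c(0, 0), 34, s,
                                        init = init),
                  numeric(1))
    expect_equal(max(lls) - min(lls), 0, tolerance = 1e-12)
  }
})

test_that("a rising frequency is better explained with selection than without", {
  k <- c(6, 36); n <- c(58, 40)  # 0.1 -> 0.9 over 6 generations
  expect_gt(wf_loglik(k, n, c(0, 6), 34, 0.5),
            wf_loglik(k, n, c(0, 6), 34, 0))
  expect_gt(wf_loglik(k, n, c(0, 6), 34, 0.5, init = "uniform"),
            wf_loglik(k, n, c(0, 6), 34, 0, init = "uniform"))
})

test_that("likelihood with s = 0 is invariant under allele relabeling", {
  for (init in c("first_sample", "uniform")) {
    k <- c(12, 25, 9); n <- c(40, 52, 30)
    expect_equal(wf_loglik(k, n, c(0, 2, 5), 17, 0, init = init),
                 wf_loglik(n - k, n, c(0, 2, 5), 17, 0, init = init),
                 tolerance = 1e-9)
  }
})

test_that("grid MLE maximises the likelihood and breaks ties toward neutrality", {
  # symmetric stable data: neutral fit wins
  fit <- wf_mle(c(29, 20), c(58, 40), c(0, 6), 34)
  expect_identical(fit$s_hat, 0)
  # degenerate one-point grid returns the null likelihood
  fit0 <- wf_mle(c(10, 30), c(40, 40), c(0, 6), 34, grid = 0)
  expect_identical(fit0$s_hat, 0)
  expect_equal(fit0$logL1, wf_loglik(c(10, 30), c(40, 40), c(0, 6), 34, 0))
  # flat likelihood (no elapsed generations): smallest |s| wins
  flat <- wf_mle(c(10, 11), c(40, 40), c(0, 0), 34)
  expect_identical(flat$s_hat, 0)
  expect_error(wf_mle(c(1, 2), c(4, 4), c(0, 1), 2, grid = c(0.1, 0.5)),
               "contain 0")
  expect_error(wf_mle(c(1, 2), c(4, 4), c(0, 1), 2, grid = c(-1.5, 0)), "> -1")
})

test_that("the LRT is zero for unchanged data and chi-square calibrated at the quantile", {
  res <- wf_lrt(c(20, 20), c(40, 40), c(0, 6), 34)
  expect_equal(res$lrt, 0, tolerance = 1e-9)
  expect_equal(res$pvalue, 1, tolerance = 1e-9)
  expect_gte(res$logL1, res$logL0)
  # the chi-square(1) reference at its 5% quantile
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-6)
  # a strong rise is significant with a positive coefficient estimate
  hit <- wf_lrt(c(6, 36), c(58, 40), c(0, 6), 34)
  expect_gt(hit$s_hat, 0)
  expect_lt(hit$pvalue, 0.01)
})

test_that("mean coefficient recovery is unbiased-ish at moderate selection", {
  # data simulated at s = 0.5 under the FN-like design; the grid MLE should
  # concentrate near the truth (median reported; heavy right tail expected
  # from near-fixation replicates)
  set.seed(20)
  s_hat <- replicate(500, {
    traj <- simulate_trajectory(34, 0.5, runif(1, 0.1, 0.9), 6)
    k <- c(rbinom(1, 58, traj[1] / 68), rbinom(1, 40, traj[7] / 68))
    wf_mle(k, c(58, 40), c(0, 6), 34)$s_hat
  })
  expect_gte(median(s_hat), 0.3)
  expect_lte(median(s_hat), 0.8)
})

test_that("impossible change after a fixed boundary baseline degrades to a null result", {
  # first sample fixed at 0 copies, later sample polymorphic: impossible under
  # every coefficient, so no likelihood contrast
  res <- wf_lrt(c(0, 5), c(58, 40), c(0, 6), 34)
  expect_identical(res$lrt, 0)
  expect_identical(res$pvalue, 1)
  expect_identical(res$s_hat, 0)
})

test_that("count validation rejects malformed series", {
  expect_error(wf_loglik(integer(0), integer(0), integer(0), 34, 0), "empty")
  expect_error(wf_loglik(c(5, 2), c(4, 4), c(0, 1), 34, 0), "k <= n")
  expect_error(wf_loglik(c(1, 2), c(4, 4), c(1, 0), 34, 0), "non-decreasing")
  expect_error(wf_loglik(c(0, 2), c(0, 4), c(0, 1), 34, 0), "baseline")
})
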
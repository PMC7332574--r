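test_that("local chi-squared matches direct substitution", {
  comps <- lpm_components(diag(2))
  expect_equal(local_chi2(c(4, 6), comps, c(4, 6))$chi2, 0)

  point <- lpm_components(matrix(1, 1, 1))
  # sqrt residual 2 - 1 = 1 over variance 1/4
  expect_equal(local_chi2(4, point, 1)$chi2, 4)
  # model variance widens the denominator
  point2 <- lpm_components(matrix(1, 1, 1), model_variance = 0.25)
  expect_equal(local_chi2(4, point2, 1)$chi2, 2)
})

test_that("effective d.f. follows the closed-form parameter corrections", {
  # zero covariance: nothing was fitted, all bins count fully
  set.seed(41)
  h <- rpois(10, 50)
  comps <- lpm_components(matrix(rep(0.1, 10)))
  e0 <- effective_dof(h, comps, sum(h), covariance = matrix(0, 1, 1))
  expect_equal(e0$neff, sum(h > 0))

  # single well-populated component: exactly n - 1
  fit <- lpm(matrix(h, 1), components = comps)
  C <- mvb_covariance(h, comps, fit$quantities[1, ])
  e1 <- effective_dof(h, comps, fit$quantities[1, ], C)
  expect_equal(e1$neff, sum(h > 0) - 1, tolerance = 1e-3)

  # two disjoint blocks: n - 2
  comps2 <- lpm_components(cbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)))
  h2 <- c(40, 35, 22, 28)
  fit2 <- lpm(matrix(h2, 1), components = comps2)
  C2 <- mvb_covariance(h2, comps2, fit2$quantities[1, ])
  e2 <- effective_dof(h2, comps2, fit2$quantities[1, ], C2)
  expect_equal(e2$neff, 2, tolerance = 1e-3)
})

test_that("chi-squared P-values handle fractional d.f. and limits", {
  expect_equal(chi2_pvalue(0, 3.7), 1)
  expect_equal(chi2_pvalue(2 * log(2), 2), 0.5, tolerance = 1e-12)
  expect_lt(chi2_pvalue(1e4, 5), 1e-12)
  p <- chi2_pvalue(2.3, 2.5)        # non-integer d.f. via the gamma survival
  expect_equal(p, pgamma(2.3 / 2, shape = 1.25, lower.tail = FALSE))
  expect_error(chi2_pvalue(-1, 2), "chi2")
  expect_error(chi2_pvalue(1, 0), "neff")
})

test_that("null-component testing refits and orders the statistics sensibly", {
  comps <- source_pmfs(rep(list("dirichlet"), 3), bins = 25, seed = 42)
  set.seed(42)
  S <- 400
  Q <- cbind(matrix(runif(S * 2, 3000, 8000), S, 2), 0)  # third absent
  coh <- null_cohort(comps, Q, seed = 43)
  res <- test_null_component(coh, comps, "dirichlet3")

  # removing a component can only worsen the refit, up to convergence noise
  expect_true(all(res$chi2_null >= res$chi2_full - 0.05))
  # d.f. bookkeeping bounds
  expect_true(all(res$neff_full >= res$n_populated - 3 - 1e-9))
  expect_true(all(res$neff_full <= res$n_populated + 1e-9))
  expect_true(all(res$neff_null <= res$n_populated + 1e-9))
  # on-null spectra keep a healthy mean P-value
  expect_gt(mean(res$pvalue_null), 0.4)
  expect_lt(mean(res$pvalue_null), 0.6)
  # the defining property of neff: it is the expected chi-squared
  expect_equal(mean(res$chi2_null), mean(res$neff_null), tolerance = 0.02)

  expect_error(test_null_component(coh, comps, c(1, 2, 3)), "all components")
  expect_error(test_null_component(coh, comps, "no-such"), "existing")
})

test_that("a component fitted to zero leaves the null statistics unchanged", {
  comps <- lpm_components(cbind(c(0.5, 0.5, 0), c(0, 0, 1)))
  H <- rbind(c(14, 9, 0),          # no mass in component 2's support
             c(10, 12, 7))
  res <- test_null_component(H, comps, 2)
  expect_equal(res$chi2_null[1], res$chi2_full[1], tolerance = 1e-6)
  expect_gt(res$chi2_null[2], res$chi2_full[2])
})

test_that("present components are detected with overwhelming significance", {
  comps <- source_pmfs(rep(list("dirichlet"), 3), bins = 25, seed = 44)
  set.seed(44)
  S <- 200
  # null component carries 30% of a >= 1000-count signal
  Q <- cbind(matrix(runif(S * 2, 1500, 3000), S, 2), 0)
  Q[, 3] <- 0.3 / 0.7 * rowSums(Q)
  coh <- null_cohort(comps, Q, seed = 45)
  res <- test_null_component(coh, comps, 3)
  expect_gte(mean(res$pvalue_null < 0.01), 0.99)
})

test_that("significance masks threshold and lay out as images", {
  comps <- lpm_components(cbind(c(0.7, 0.3), c(0.3, 0.7)))
  coh <- null_cohort(comps, c(200, 100), n = 12, seed = 46)
  res <- test_null_component(coh, comps, 2)

  res_all1 <- res; res_all1$pvalue_null <- rep(1, 12)
  expect_equal(sum(significance_mask(res_all1, 0.01)), 0)
  expect_equal(sum(significance_mask(res, 1)), 12)       # everything below 1

  res_tiny <- res; res_tiny$pvalue_null <- rep(1e-6, 12)
  expect_equal(sum(significance_mask(res_tiny, 0.01)), 12)

  coords <- cbind(x = rep(1:4, 3), y = rep(1:3, each = 4))
  m <- significance_mask(res_tiny, 0.01, coords = coords)
  img <- attr(m, "image")
  expect_equal(dim(img), c(3L, 4L))
  expect_true(all(img))
  expect_error(significance_mask(res, alpha = 0), "alpha")
})
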
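test_that("model prediction conserves total quantity", {
  comps <- lpm_components(diag(2))
  expect_equal(model_prediction(comps, c(0, 0)), c(0, 0))
  expect_equal(model_prediction(comps, c(4, 6)), c(4, 6))

  for (seed in 1:10) {
    pr <- rand_problem(seed, S = 5, I = 7, N = 3)
    M <- model_prediction(pr$comps, pr$Q)
    expect_true(all(M >= 0))
    expect_lt(max(abs(rowSums(M) - rowSums(pr$Q))), 1e-12 * max(rowSums(pr$Q)))
  }
})

test_that("extended log-likelihood matches hand-computed values", {
  one <- lpm_components(matrix(c(0.5, 0.5), 2, 1))
  # empty data: only the -T term survives
  expect_equal(extended_log_likelihood(matrix(0, 1, 2), one, 5), -5)
  # single populated bin: H log M - M
  point <- lpm_components(matrix(1, 1, 1))
  expect_equal(extended_log_likelihood(matrix(2, 1, 1), point, 2),
               2 * log(2) - 2)
  expect_error(extended_log_likelihood(matrix(1, 1, 2), one, -1), "non-negative")
})

test_that("quantity fits reproduce closed-form and grid-oracle optima", {
  # single component: ML total equals total counts
  f1 <- fit_quantities(matrix(c(3, 5), 1, 2),
                       lpm_components(matrix(c(0.5, 0.5), 2, 1)))
  expect_equal(unname(f1$quantities[1, 1]), 8, tolerance = 1e-9)

  # disjoint supports: quantities are the per-block totals
  f2 <- fit_quantities(matrix(c(4, 6), 1, 2), lpm_components(diag(2)))
  expect_equal(unname(f2$quantities[1, ]), c(4, 6), tolerance = 1e-9)

  # overlapping supports: compare to brute-force maximisation of the
  # extended log-likelihood on a refined 2-D grid
  comps <- lpm_components(cbind(c(0.8, 0.2), c(0.2, 0.8)))
  H <- matrix(c(60, 40), 1, 2)
  obj <- function(q1, q2) {
    m <- c(0.8 * q1 + 0.2 * q2, 0.2 * q1 + 0.8 * q2)
    sum(H * log(m)) - sum(m)
  }
  grid_best <- function(c1, c2, half, step) {
    g1 <- seq(max(0, c1 - half), c1 + half, by = step)
    g2 <- seq(max(0, c2 - half), c2 + half, by = step)
    vals <- outer(g1, g2, Vectorize(obj))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1L, ]
    c(g1[ix[1L]], g2[ix[2L]])
  }
  q <- c(50, 50)
  q <- grid_best(q[1L], q[2L], 50, 1)
  q <- grid_best(q[1L], q[2L], 2, 0.01)
  q <- grid_best(q[1L], q[2L], 0.02, 0.001)
  f3 <- fit_quantities(H, comps, tol = 1e-12)
  expect_lt(max(abs(f3$quantities[1, ] - q)), 0.01)
  # the analytic interior solution for this basis is (200/3, 100/3)
  expect_lt(max(abs(q - c(200, 100) / 3)), 0.01)
})

test_that("the extended log-likelihood never decreases across EM iterations", {
  for (seed in 1:15) {
    pr <- rand_problem(seed, S = 3 + seed %% 4, I = 4 + seed %% 5,
                       N = 1 + seed %% 3)
    fitp <- lpm(pr$cohort, components = pr$comps)
    expect_true(all(diff(fitp$trace) >= -1e-8 * (1 + abs(fitp$trace[-1L]))))
    fitj <- lpm(pr$cohort, order = pr$comps$order, restarts = 2, seed = seed)
    expect_true(all(diff(fitj$trace) >= -1e-8 * (1 + abs(fitj$trace[-1L]))))
  }
})

test_that("converged fits conserve counts and sit at a local optimum", {
  pr <- rand_problem(42, S = 6, I = 8, N = 2, scale = 200)
  fit <- lpm(pr$cohort, components = pr$comps, tol = 1e-10)
  tot <- rowSums(pr$cohort$counts)
  expect_true(all(abs(rowSums(fit$quantities) - tot) <= 1e-6 * tot))

  # perturbing any spectrum's quantities within +/-1% cannot beat the fit
  ll0 <- sum(fit$loglik)
  for (d1 in c(-0.01, 0, 0.01)) for (d2 in c(-0.01, 0, 0.01)) {
    Qp <- fit$quantities
    Qp[, 1] <- Qp[, 1] * (1 + d1)
    Qp[, 2] <- Qp[, 2] * (1 + d2)
    expect_lte(extended_log_likelihood(pr$cohort, pr$comps, Qp),
               ll0 + 1e-7 * abs(ll0))
  }
})

test_that("the fit shares the pLSA manifold up to the total-quantity scale", {
  pr <- rand_problem(11, S = 5, I = 6, N = 2, scale = 300)
  fit <- lpm(pr$cohort, components = pr$comps, tol = 1e-10)
  T_ <- fit$total
  Pks <- fit$quantities / T_            # joint P(k, s)
  expect_equal(sum(Pks), 1, tolerance = 1e-9)
  M_lpm <- fitted(fit)
  M_plsa <- Pks %*% t(pr$comps$pmfs)    # normalized mixture
  expect_lt(max(abs(T_ * M_plsa - M_lpm)), 1e-12 * max(M_lpm))

  # extended and plain log-likelihoods differ by T log T - T at the
  # count-conserving optimum
  H <- pr$cohort$counts
  ll_plsa <- sum(H[H > 0] * log((M_plsa)[H > 0]))
  expect_equal(sum(fit$loglik), ll_plsa + T_ * log(T_) - T_,
               tolerance = 1e-6 * abs(sum(fit$loglik)))
})

test_that("joint fits recover generating components", {
  # single component at ~1e5 total counts
  p <- (1:20) / sum(1:20)
  coh1 <- null_cohort(lpm_components(matrix(p)), matrix(2000, 50, 1), seed = 3)
  f1 <- lpm(coh1, order = 1, restarts = 2, seed = 4)
  expect_lt(sum(abs(f1$components$pmfs[, 1] - p)), 0.02)

  # order = number of spectra, each a distinct delta: exact separable case
  fd <- lpm(lpm_cohort(diag(c(5, 7, 4))), order = 3, restarts = 5, seed = 1)
  expect_equal(unname(sort(apply(fd$components$pmfs, 2, max))), c(1, 1, 1))
  expect_equal(unname(sort(colSums(fd$quantities))), c(4, 5, 7),
               tolerance = 1e-6)

  # three mixed components: best-of-5 restarts reaches the goodness-of-fit
  # of the true generator within 5%
  comps <- source_pmfs(list("ramp-up", "ramp-down",
                            list("top-hat", start = 8, width = 10)),
                       bins = 25, seed = 5)
  set.seed(5)
  Q <- matrix(runif(300 * 3, 500, 2500), 300, 3)
  coh3 <- null_cohort(comps, Q, seed = 6)
  fj <- lpm(coh3, order = 3, restarts = 5, seed = 7)
  ft <- lpm(coh3, components = comps)
  expect_lt(fj$gof$chi2_per_dof, ft$gof$chi2_per_dof * 1.05)
})

test_that("spectra outside the model support are flagged and fitted to zero", {
  comps <- lpm_components(matrix(c(1, 0), 2, 1))     # support = bin 1 only
  H <- rbind(c(3, 0), c(0, 5))
  expect_warning(fit <- lpm(H, components = comps), "outside the model support")
  expect_equal(unname(fit$quantities[2, 1]), 0)
  expect_equal(unname(fit$quantities[1, 1]), 3, tolerance = 1e-9)
})

test_that("simulate() draws reproducible parametric-bootstrap cohorts", {
  pr <- rand_problem(9, S = 4, I = 5, N = 2)
  fit <- lpm(pr$cohort, components = pr$comps)
  a <- simulate(fit, nsim = 2, seed = 99)
  b <- simulate(fit, nsim = 2, seed = 99)
  expect_identical(a[[1]]$counts, b[[1]]$counts)
  expect_false(identical(a[[1]]$counts, a[[2]]$counts))
})
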
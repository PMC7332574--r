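test_that("source PMF recipes produce the stated shapes", {
  full <- source_pmfs(list(list("top-hat", start = 1, width = 8)), bins = 8)
  expect_equal(full$pmfs[, 1], rep(1 / 8, 8))

  ramp <- source_pmfs(list("ramp-up"), bins = 4)
  expect_equal(ramp$pmfs[, 1], c(0.1, 0.2, 0.3, 0.4))
  down <- source_pmfs(list("ramp-down"), bins = 4)
  expect_equal(down$pmfs[, 1], c(0.4, 0.3, 0.2, 0.1))

  two <- source_pmfs(list(list("top-hat", start = 1, width = 3),
                          list("top-hat", start = 4, width = 3)), bins = 6)
  expect_equal(sum(two$pmfs[, 1] * two$pmfs[, 2]), 0)

  expect_error(source_pmfs(list(list("top-hat", start = 6, width = 4)),
                           bins = 8), "outside")
  expect_error(source_pmfs(list("banana"), bins = 8), "unknown recipe")

  usr <- source_pmfs(list(c(2, 0, 2)), bins = 3)
  expect_equal(usr$pmfs[, 1], c(0.5, 0, 0.5))
})

test_that("truth maps lay shapes out with summing overlaps and total rescale", {
  const <- truth_maps(5, 4, list(list(geometry = "full-field", component = 1,
                                      weight = 2)),
                      total_mean = 70, total_sd = 0)
  expect_equal(dim(const$true_quantities), c(20L, 1L))
  expect_true(all(const$true_quantities == 70))

  two <- truth_maps(6, 6, list(
    list(geometry = "rectangle", component = 1, weight = 1,
         x0 = 1, y0 = 1, x1 = 4, y1 = 4),
    list(geometry = "rectangle", component = 2, weight = 1,
         x0 = 3, y0 = 3, x1 = 6, y1 = 6)),
    total_mean = 100, total_sd = 0)
  Q <- two$true_quantities
  xy <- two$coords
  inside_both <- xy[, 1] %in% 3:4 & xy[, 2] %in% 3:4
  expect_true(all(Q[inside_both, 1] > 0 & Q[inside_both, 2] > 0))
  expect_equal(unname(rowSums(Q)[inside_both]), rep(100, 4))

  # gradient: zero weight at the left edge, non-decreasing along x
  raw <- truth_maps(10, 2, list(
    list(geometry = "rectangle", component = 1, gradient = c(0, 1),
         along = "x", x0 = 1, y0 = 1, x1 = 10, y1 = 2)),
    total_mean = 50, total_sd = 0, n_components = 1)
  row1 <- raw$true_quantities[raw$coords[, 2] == 1, 1]
  expect_equal(row1[1], 0)
  expect_true(all(diff(row1) >= -1e-9))

  expect_error(truth_maps(4, 4, list(list(geometry = "disc", component = 1,
                                          weight = -1, cx = 2, cy = 2, r = 1)),
                          10, 1), ">= 0")
})

test_that("Poisson draws are seeded, unbiased and Poisson-dispersed", {
  comps <- source_pmfs(list("ramp-up", "ramp-down"), bins = 10, seed = 1)
  truth <- truth_maps(4, 4, list(list(geometry = "full-field", component = 1,
                                      weight = 1),
                                 list(geometry = "full-field", component = 2,
                                      weight = 1)),
                      total_mean = 400, total_sd = 40, seed = 2)
  a <- draw_cohort(truth, comps, seed = 3)
  b <- draw_cohort(truth, comps, seed = 3)
  expect_identical(a$counts, b$counts)
  expect_identical(a$coords, truth$coords)

  zero <- truth_maps(3, 3, list(list(geometry = "full-field", component = 1,
                                     weight = 1)), 0, 0)
  expect_true(all(draw_cohort(zero, source_pmfs(list("ramp-up"), 5),
                              seed = 4)$counts == 0))

  # replicate draws of one pixel: bin means within 3 SE, variance ~ mean
  q <- c(300, 200)
  reps <- null_cohort(comps, q, n = 10000, seed = 5)
  mu <- drop(comps$pmfs %*% q)
  se <- sqrt(mu / 10000)
  expect_true(all(abs(colMeans(reps$counts) - mu) <= 3 * se))
  vr <- apply(reps$counts, 2, var) / mu
  expect_true(all(abs(vr - 1) < 0.1))

  empty <- null_cohort(comps, q, n = 0, seed = 6)
  expect_equal(nrow(empty$counts), 0L)
})
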
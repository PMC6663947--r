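test_that("EM recovers generating parameters at moderate n", {
  errs_a <- c(); errs_b <- c()
  for (s in 1:2) {
    bank <- random_bank(6, seed = 20 + s)
    th <- sample_theta(1500, 0, 1, seed = 30 + s)
    resp <- simulate_responses(bank, th, 0, seed = 40 + s)
    fit <- fit_grm(resp, test_ctrl())
    expect_true(fit$converged)
    est <- as.data.frame(fit$bank)
    tru <- as.data.frame(bank)
    errs_a <- c(errs_a, abs(est$a - tru$a))
    errs_b <- c(errs_b, abs(unlist(est[3:6]) - unlist(tru[3:6])))
  }
  expect_lt(mean(errs_a), 0.25)
  expect_lt(mean(errs_b), 0.15)
})

test_that("column permutation permutes estimates without changing them", {
  bank <- random_bank(5, seed = 51)
  th <- sample_theta(600, 0, 1, seed = 52)
  resp <- simulate_responses(bank, th, 0.05, seed = 53)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  resp_p <- response_matrix(resp$values[, perm], C = 5,
                            item_ids = resp$item_ids[perm])
  ctrl <- test_ctrl(se = FALSE)
  f1 <- fit_grm(resp, ctrl)
  f2 <- fit_grm(resp_p, ctrl)
  e1 <- as.data.frame(f1$bank)
  e2 <- as.data.frame(f2$bank)
  e2 <- e2[match(e1$item_id, e2$item_id), ]
  expect_equal(e1$a, e2$a, tolerance = 1e-8)
  expect_equal(e1$b1, e2$b1, tolerance = 1e-8)
})

test_that("the marginal log-likelihood is nondecreasing across EM cycles", {
  bank <- random_bank(5, seed = 61)
  th <- sample_theta(800, 0, 1, seed = 62)
  resp <- simulate_responses(bank, th, 0.05, seed = 63)
  fit <- fit_grm(resp, test_ctrl(se = FALSE))
  expect_gt(length(fit$ll_trace), 3)
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
})

test_that("marginal log-likelihood: empty sets, all-missing rows, dense-grid oracle", {
  bank <- toy_bank3()
  g <- normal_grid(301, c(-8, 8))
  empty <- matrix(integer(0), nrow = 0, ncol = 3,
                  dimnames = list(NULL, names(bank$items)))
  expect_identical(loglikelihood(bank, empty, g), 0)
  set.seed(71)
  vals <- matrix(sample(0:2, 60, replace = TRUE), 20, 3,
                 dimnames = list(NULL, names(bank$items)))
  base <- loglikelihood(bank, vals, g)
  with_empty <- loglikelihood(bank, rbind(vals, NA_integer_), g)
  expect_equal(with_empty, base, tolerance = 1e-12)
  dense <- loglikelihood(bank, vals, normal_grid(10001, c(-9, 9)))
  expect_equal(base, dense, tolerance = 1e-3)
})

test_that("standard errors are positive, shrink like 1/sqrt(n), and match the bootstrap", {
  bank <- random_bank(5, C = 3, seed = 81, a_range = c(1, 2.5),
                      b1_range = c(-1, 0), gap_range = c(0.8, 1.4))
  ctrl <- grm_control(grid_points = 41, grid_range = c(-5, 5), tol = 5e-4,
                      max_cycles = 200)
  th1 <- sample_theta(600, 0, 1, seed = 82)
  f1 <- fit_grm(simulate_responses(bank, th1, 0, seed = 83), ctrl)
  expect_true(all(unlist(f1$se[, -1]) > 0))
  th2 <- sample_theta(2400, 0, 1, seed = 84)
  f2 <- fit_grm(simulate_responses(bank, th2, 0, seed = 85), ctrl)
  ratio <- median(unlist(f2$se[, -1]) / unlist(f1$se[, -1]))
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)

  # parametric bootstrap SD of the first item's slope vs analytic SE
  ctrl_fast <- grm_control(grid_points = 41, grid_range = c(-5, 5), tol = 1e-3,
                           max_cycles = 150, se = FALSE)
  boot_a <- vapply(1:80, function(b) {
    thb <- sample_theta(600, 0, 1, seed = 9000 + b)
    fb <- fit_grm(simulate_responses(bank, thb, 0, seed = 9500 + b), ctrl_fast)
    fb$bank$items[[1]]$a
  }, numeric(1))
  expect_lt(abs(f1$se$se_a[1] - sd(boot_a)), 0.25 * sd(boot_a))
})

test_that("unobserved categories error by default and collapse on request", {
  bank <- toy_bank3()
  th <- sample_theta(300, 0, 1, seed = 91)
  resp <- simulate_responses(bank, th, 0, seed = 92)
  vals <- resp$values
  vals[vals[, 2] == 2L, 2] <- 1L  # wipe out top category of item 2
  resp2 <- response_matrix(vals, C = 3, item_ids = resp$item_ids)
  ctrl <- grm_control(grid_points = 41, grid_range = c(-5, 5), tol = 1e-3,
                      max_cycles = 150, se = FALSE)
  expect_error(fit_grm(resp2, ctrl), "unobserved")
  fit <- fit_grm(resp2, grm_control(grid_points = 41, grid_range = c(-5, 5),
                                    tol = 1e-3, max_cycles = 150, se = FALSE,
                                    on_unobserved = "collapse"))
  expect_true(fit$collapsed[2])
  expect_length(fit$bank$items[[2]]$b, 1L)  # two effective categories
  expect_length(fit$bank$items[[1]]$b, 2L)
})

test_that("masking a few responses at random moves estimates within noise", {
  bank <- random_bank(6, seed = 95)
  th <- sample_theta(1500, 0, 1, seed = 96)
  resp <- simulate_responses(bank, th, 0, seed = 97)
  ctrl <- test_ctrl()
  f0 <- fit_grm(resp, ctrl)
  vals <- resp$values
  set.seed(98)
  mask <- sample(length(vals), round(0.05 * length(vals)))
  vals[mask] <- NA_integer_
  f1 <- fit_grm(response_matrix(vals, C = 5, item_ids = resp$item_ids), ctrl)
  d_a <- abs(as.data.frame(f1$bank)$a - as.data.frame(f0$bank)$a)
  expect_true(all(d_a < 3 * f1$se$se_a))
})

test_that("an optional MAP prior regularizes without breaking convergence", {
  bank <- toy_bank3()
  th <- sample_theta(250, 0, 1, seed = 99)
  resp <- simulate_responses(bank, th, 0, seed = 100)
  prior <- list(a = c(0, 0.75), b = c(0, 2))
  fit <- fit_grm(resp, grm_control(grid_points = 41, grid_range = c(-5, 5),
                                   tol = 1e-3, max_cycles = 200, prior = prior))
  expect_true(fit$converged)
  expect_true(all(is.finite(unlist(as.data.frame(fit$bank)[, -1]))))
  expect_true(all(unlist(fit$se[, -1]) > 0))
})
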
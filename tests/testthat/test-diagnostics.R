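# Brute-force step-up FDR oracle.
bh_oracle <- function(p, level) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(n) * level / n)
  reject <- logical(n)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  adj <- rev(cummin(rev(pmin(1, n * ps / seq_len(n)))))
  list(p_adjusted = adj[order(ord)], reject = reject)
}

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_false(any(bh_adjust(rep(1, 8), 0.05)$reject))
  expect_equal(bh_adjust(0.032, 0.05)$p_adjusted, 0.032)
  expect_length(bh_adjust(numeric(0))$reject, 0L)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.5)
  got <- bh_adjust(p, 0.05)
  orc <- bh_oracle(p, 0.05)
  expect_equal(got$p_adjusted, orc$p_adjusted)
  expect_identical(got$reject, orc$reject)
  set.seed(5)
  for (r in 1:32) {
    p <- sample(round(runif(5), 3))
    got <- bh_adjust(p, 0.05)
    orc <- bh_oracle(p, 0.05)
    expect_equal(got$p_adjusted, orc$p_adjusted)
    expect_identical(got$reject, orc$reject)
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("Cronbach's alpha: perfect duplication, independence, missing data", {
  set.seed(6)
  x <- sample(0:4, 400, replace = TRUE)
  expect_equal(cronbach_alpha(cbind(x, x)), 1.0)
  y <- matrix(sample(0:4, 20000, replace = TRUE), ncol = 2)
  expect_lt(abs(cronbach_alpha(y)), 0.05)
  xm <- cbind(x, x, x)
  xm[sample(length(xm), 100)] <- NA
  expect_gt(cronbach_alpha(xm), 0.95)
  expect_error(cronbach_alpha(matrix(0:9, ncol = 1)))
})

test_that("the summed-score recursion matches exhaustive enumeration", {
  bank <- toy_bank3()
  pts <- c(-1.2, 0.3, 1.7)
  f <- grmbank:::.score_distribution(bank$items, pts)
  patterns <- expand.grid(0:2, 0:2, 0:2)
  for (t in seq_along(pts)) {
    probs <- sapply(1:3, function(j) category_prob(bank$items[[j]], pts[t]))
    brute <- tapply(apply(patterns, 1, function(x)
      prod(probs[cbind(x + 1, 1:3)])), rowSums(patterns), sum)
    expect_equal(unname(f[, t]), unname(as.vector(brute)), tolerance = 1e-12)
  }
})

test_that("S-X2 records are well-formed and imputation is a no-op on complete data", {
  bank <- random_bank(6, seed = 101)
  th <- sample_theta(1200, 0, 1, seed = 102)
  resp <- simulate_responses(bank, th, 0, seed = 103)
  fit <- fit_grm(resp, test_ctrl(se = FALSE))
  sx <- item_fit_sx2(fit)
  expect_true(all(sx$df >= 1))
  expect_true(all(sx$p >= 0 & sx$p <= 1))
  expect_true(all(sx$p_adjusted >= sx$p - 1e-12))
  expect_identical(sx$flagged, sx$p_adjusted < 0.01)
  expect_equal(item_fit_sx2(fit, impute = "eap"), sx)
})

test_that("local dependence output is symmetric with an undefined diagonal", {
  bank <- random_bank(5, seed = 111)
  th <- sample_theta(900, 0, 1, seed = 112)
  resp <- simulate_responses(bank, th, 0.03, seed = 113)
  fit <- fit_grm(resp, test_ctrl(se = FALSE))
  ld <- local_dependence(fit)
  expect_true(all(is.na(diag(ld$statistic))))
  expect_equal(ld$statistic, t(ld$statistic))
  expect_true(all(is.finite(ld$statistic[upper.tri(ld$statistic)])))
  expect_false(any(ld$borderline & ld$flagged, na.rm = TRUE))
})

test_that("an injected dependent pair is flagged at 10 while nulls stay low", {
  fx <- depression_fixture()
  sf2 <- fx$bank[fx$sf2_items]
  pair <- fx$sf2_items[c(3, 7)]
  th <- sample_theta(2000, 0, 1, seed = 122)
  hook <- inject_local_dependence(sf2, pair, 0.7)
  resp <- simulate_responses(sf2, th, 0, seed = 123, hooks = hook)
  fit <- fit_grm(resp, test_ctrl(se = FALSE))
  ld <- local_dependence(fit)
  expect_gte(ld$statistic[pair[1], pair[2]], 10)
  others <- ld$statistic
  others[pair[1], pair[2]] <- others[pair[2], pair[1]] <- NA
  expect_lt(max(others, na.rm = TRUE), 10)
})

test_that("AIC and BIC identities hold exactly and M2 stays calm under the null", {
  rmseas <- c()
  for (s in 1:3) {
    bank <- random_bank(6, C = 3, seed = 130 + s, gap_range = c(0.9, 1.4))
    th <- sample_theta(1000, 0, 1, seed = 140 + s)
    resp <- simulate_responses(bank, th, 0, seed = 150 + s)
    fit <- fit_grm(resp, test_ctrl(se = FALSE))
    mf <- model_fit(fit)
    expect_identical(mf$aic - mf$minus2ll, 2 * mf$n_params)
    expect_equal(mf$bic - mf$minus2ll, mf$n_params * log(mf$n), tolerance = 1e-13)
    expect_true(is.finite(mf$m2))
    expect_gte(mf$m2_df, 1L)
    rmseas <- c(rmseas, mf$rmsea)
  }
  expect_gte(sum(rmseas <= 0.05), 2L)
})

test_that("M2 is skipped with a warning when the margin vector is too large", {
  bank <- random_bank(6, seed = 161)
  th <- sample_theta(400, 0, 1, seed = 162)
  fit <- fit_grm(simulate_responses(bank, th, 0, seed = 163), test_ctrl(se = FALSE))
  expect_warning(mf <- model_fit(fit, m2_margin_cap = 10), "cap")
  expect_true(is.na(mf$m2))
  expect_true(is.na(mf$rmsea))
  expect_true(is.finite(mf$aic))
})

test_that("marginal reliability is bounded, information-monotone, and near 0 for flat items", {
  bank <- random_bank(6, seed = 171)
  th <- sample_theta(700, 0, 1, seed = 172)
  resp <- simulate_responses(bank, th, 0.04, seed = 173)
  fit_small <- fit_grm(subset_items(resp, 1:3), test_ctrl(se = FALSE))
  fit_full <- fit_grm(resp, test_ctrl(se = FALSE))
  r_small <- marginal_reliability(fit_small)
  r_full <- marginal_reliability(fit_full)
  expect_true(r_small >= 0 && r_small <= 1)
  expect_gt(r_full, r_small)
  flat <- grm_bank(lapply(1:4, function(j) grm_item(paste0("f", j), 0.02, c(-1, 0, 1, 2))))
  flat_resp <- response_matrix(resp$values[, 1:4], C = 5,
                               item_ids = names(flat$items))
  sc <- score_respondents(flat, flat_resp, normal_grid(61, c(-5, 5)))
  expect_lt(1 - mean(sc$se^2), 0.05)
})
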
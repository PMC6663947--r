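test_that("every stochastic operation is bit-reproducible from its seed", {
  bank <- random_bank(6, seed = 301)
  expect_identical(sample_theta(500, 0, 1, seed = 5), sample_theta(500, 0, 1, seed = 5))
  expect_false(identical(sample_theta(500, 0, 1, seed = 5),
                         sample_theta(500, 0, 1, seed = 6)))
  th <- sample_theta(400, 0, 1, seed = 7)
  r1 <- simulate_responses(bank, th, 0.1, seed = 8)
  r2 <- simulate_responses(bank, th, 0.1, seed = 8)
  expect_identical(r1$values, r2$values)
  s1 <- simulate_study(n = 200, bank = bank, seed = 9)
  s2 <- simulate_study(n = 200, bank = bank, seed = 9)
  expect_identical(s1$responses$values, s2$responses$values)
  expect_identical(s1$groups, s2$groups)
})

test_that("latent-trait draws match their population moments", {
  th <- sample_theta(1e5, 0, 1, seed = 11)
  expect_lt(abs(mean(th)), 0.02)
  expect_lt(abs(sd(th) - 1), 0.02)
  th2 <- sample_theta(1e5, 1, 0.5, seed = 12)
  expect_lt(abs(mean(th2) - 1), 0.02)
  expect_lt(abs(sd(th2) - 0.5), 0.01)
  expect_error(sample_theta(10, 0, -1, seed = 1))
})

test_that("simulated responses follow the model and the missingness dial", {
  bank <- random_bank(4, seed = 311)
  th <- sample_theta(50000, 0, 1, seed = 312)
  r0 <- simulate_responses(bank, th, 0, seed = 313)
  expect_false(anyNA(r0$values))
  expect_true(all(r0$values %in% 0:4))
  r3 <- simulate_responses(bank, th, 0.3, seed = 313)
  expect_equal(mean(is.na(r3$values)), 0.3, tolerance = 0.01)
  near0 <- abs(th) < 0.05
  emp <- tabulate(r0$values[near0, 2] + 1L, 5) / sum(near0)
  expect_lt(max(abs(emp - category_prob(bank$items[[2]], 0))), 0.02)
})

test_that("DIF injection transforms only the target item's curves as advertised", {
  bank <- random_bank(5, seed = 321)
  expect_identical(inject_dif(bank, "i2", 0, 1)$items, bank$items)
  g <- seq(-4, 4, by = 0.05)
  shifted <- inject_dif(bank, "i2", b_shift = -0.5)
  it0 <- bank$items[["i2"]]; it1 <- shifted$items[["i2"]]
  for (j in 1:4)
    expect_true(all(cumulative_prob(it1, j, g) > cumulative_prob(it0, j, g)))
  expect_identical(shifted$items[["i3"]], bank$items[["i3"]])
  doubled <- inject_dif(bank, "i2", a_ratio = 2)
  it2 <- doubled$items[["i2"]]
  expect_equal(cumulative_prob(it2, 1, it0$b[1]), 0.5)  # curves pivot at b
  d <- cumulative_prob(it2, 1, g) - cumulative_prob(it0, 1, g)
  expect_true(any(d > 1e-6) && any(d < -1e-6))
  expect_error(inject_dif(bank, "i2", a_ratio = 0), "positive")
  expect_error(inject_dif(bank, "nope"), "not found")
})

test_that("zero-strength dependence reduces to independent generation", {
  bank <- random_bank(4, seed = 331)
  th <- sample_theta(50000, 0, 1, seed = 332)
  hook <- inject_local_dependence(bank, c("i1", "i3"), 0)
  rd <- simulate_responses(bank, th, 0, seed = 333, hooks = hook)
  ri <- simulate_responses(bank, th, 0, seed = 334)
  tab_d <- table(rd$values[, 1], rd$values[, 3])
  tab_i <- table(ri$values[, 1], ri$values[, 3])
  expect_gt(suppressWarnings(chisq.test(rbind(c(tab_d), c(tab_i)))$p.value), 0.001)
  expect_error(inject_local_dependence(bank, c("i1", "i3"), 1.2), "0, 1")
  expect_error(inject_local_dependence(bank, c("i1", "i1"), 0.5), "distinct")
})

test_that("injections leave non-target columns bit-identical", {
  bank <- random_bank(6, seed = 341)
  th <- sample_theta(800, 0, 1, seed = 342)
  base <- simulate_responses(bank, th, 0.05, seed = 343)
  hooked <- simulate_responses(bank, th, 0.05, seed = 343,
                               hooks = list(
                                 inject_local_dependence(bank, c("i2", "i5"), 0.6),
                                 inject_misfit(bank, "i4", "second_dimension")))
  for (j in c(1, 3, 6)) expect_identical(hooked$values[, j], base$values[, j])
  for (j in c(2, 4, 5)) expect_false(identical(hooked$values[, j], base$values[, j]))
})

test_that("category scrambling breaks monotone endorsement in theta", {
  bank <- random_bank(6, seed = 351, a_range = c(2, 3))
  th <- sample_theta(4000, 0, 1, seed = 352)
  resp <- simulate_responses(bank, th, 0, seed = 353,
                             hooks = inject_misfit(bank, "i3", "category_scramble"))
  dec <- cut(th, quantile(th, 0:10 / 10), include.lowest = TRUE)
  pm <- tapply(resp$values[, 3] >= 1, dec, mean)
  expect_true(any(diff(pm) < -0.02) && any(diff(pm) > 0.02))
  expect_error(inject_misfit(bank, "i3", "unknown"))
})

test_that("a second-dimension item loses most of its discrimination", {
  bank <- random_bank(6, seed = 361, a_range = c(2, 3))
  th <- sample_theta(1500, 0, 1, seed = 362)
  resp <- simulate_responses(bank, th, 0, seed = 363,
                             hooks = inject_misfit(bank, "i5", "second_dimension"))
  fit <- fit_grm(resp, test_ctrl(se = FALSE))
  a_true <- bank$items[["i5"]]$a
  expect_lt(fit$bank$items[["i5"]]$a, 0.6 * a_true)
  others <- setdiff(names(bank$items), "i5")
  est <- sapply(fit$bank$items[others], function(it) it$a)
  tru <- sapply(bank$items[others], function(it) it$a)
  expect_lt(mean(abs(est - tru)), 0.3)
})

test_that("the packaged bank fixture matches its published source", {
  fx <- depression_fixture()
  expect_length(fx$bank$items, 51L)
  hopeless <- fx$bank$items[["I felt hopeless"]]
  expect_equal(hopeless$a, 4.46)
  expect_equal(hopeless$b, c(0.38, 0.97, 1.53, 2.23))
  lonely <- fx$bank$items[["I felt lonely"]]
  expect_equal(lonely$a, 2.54)
  expect_equal(lonely$b, c(-0.09, 0.60, 1.45, 2.21))
  expect_setequal(fx$dif_items,
                  c("I had crying spells", "I felt like crying",
                    "I disliked the way my body looked"))
  expect_length(fx$misfit_items, 9L)
  expect_length(unlist(fx$ld_sets), 14L)
  expect_length(fx$sf1_items, 10L)
  expect_length(fx$sf2_items, 10L)
  expect_true(all(c("I felt hopeless", "I felt unhappy") %in% fx$sf1_items))
  expect_true(all(c("I felt hopeless", "I felt worthless") %in% fx$sf2_items))
  expect_length(fx$dsm_map$criterion_id, 11L)
  # LD partner lists are symmetric
  for (id in names(fx$ld_partners))
    for (p in fx$ld_partners[[id]])
      expect_true(id %in% fx$ld_partners[[p]])
  # the severity-scale item is metadata-tagged
  expect_identical(
    fx$bank$meta$scale[fx$bank$meta$item_id == "I lost weight without trying"],
    "severity")
})
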
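test_that("flag-based exclusion reproduces plain set arithmetic on the packaged bank", {
  fx <- depression_fixture()
  res <- exclude_flagged(fx$bank, misfit = fx$misfit_items,
                         ld_sets = fx$ld_sets, dif = fx$dif_items)
  # oracle: brute-force set union with best-slope retention per LD set
  slopes <- sapply(fx$bank$items, function(it) it$a)
  ld_excluded <- unlist(lapply(fx$ld_sets, function(s) setdiff(s, s[which.max(slopes[s])])))
  expected_out <- union(union(fx$misfit_items, ld_excluded), fx$dif_items)
  expect_setequal(setdiff(names(fx$bank$items), res$eligible), expected_out)
  expect_equal(length(res$eligible), 51 - length(expected_out))
  # ledger partitions the bank exactly once
  expect_setequal(res$ledger$item_id, names(fx$bank$items))
  expect_false(anyDuplicated(res$ledger$item_id) > 0)
  expect_setequal(res$ledger$item_id[res$ledger$status == "eligible"], res$eligible)
})

test_that("both crying items are excluded, with local dependence and DIF reasons", {
  fx <- depression_fixture()
  res <- exclude_flagged(fx$bank, misfit = fx$misfit_items,
                         ld_sets = fx$ld_sets, dif = fx$dif_items)
  ledger <- res$ledger
  spells <- ledger[ledger$item_id == "I had crying spells", ]
  felt <- ledger[ledger$item_id == "I felt like crying", ]
  expect_identical(spells$status, "excluded")
  expect_identical(felt$status, "excluded")
  expect_match(spells$reasons, "local_dependence")
  expect_match(spells$reasons, "dif")
  expect_match(felt$reasons, "dif")
})

test_that("no flags leaves the full bank eligible; overrides behave", {
  fx <- depression_fixture()
  res <- exclude_flagged(fx$bank)
  expect_identical(res$eligible, names(fx$bank$items))
  res2 <- exclude_flagged(fx$bank, misfit = fx$misfit_items,
                          overrides = c("I felt sad" = "core symptom"))
  expect_true("I felt sad" %in% res2$eligible)
  expect_identical(
    res2$ledger$status[res2$ledger$item_id == "I felt sad"],
    "retained_by_override")
  expect_warning(exclude_flagged(fx$bank, misfit = "I felt sad",
                                 overrides = c("I felt hopeless" = "x")),
                 "unflagged")
  expect_error(exclude_flagged(fx$bank, misfit = "no such item"), "unknown")
})

test_that("discrimination ranking is a deterministic stable sort", {
  fx <- depression_fixture()
  rk <- rank_by_discrimination(fx$bank)
  expect_identical(rk$item_id[1], "I felt hopeless")
  expect_identical(rk$item_id[51], "I lost weight without trying")
  rev_bank <- grm_bank(rev(fx$bank$items))
  expect_identical(rank_by_discrimination(rev_bank)$item_id, rk$item_id)
  ties <- grm_bank(list(grm_item("b", 2, 0), grm_item("a", 2, 0), grm_item("c", 2, 0)))
  expect_identical(rank_by_discrimination(ties)$item_id, c("a", "b", "c"))
})

test_that("DSM coverage counts match the published short forms: 9 vs 5", {
  fx <- depression_fixture()
  expect_identical(dsm_coverage(fx$sf1_items, fx$dsm_map)$count, 9L)
  expect_identical(dsm_coverage(fx$sf2_items, fx$dsm_map)$count, 5L)
  expect_identical(dsm_coverage(character(0), fx$dsm_map)$count, 0L)
  expect_error(dsm_coverage(fx$sf1_items, content_map(character(0), character(0), list())),
               "empty")
  # monotone: adding an item never decreases coverage
  set.seed(260)
  for (r in 1:10) {
    sub <- sample(names(fx$bank$items), 5)
    extra <- sample(setdiff(names(fx$bank$items), sub), 1)
    expect_gte(dsm_coverage(c(sub, extra), fx$dsm_map)$count,
               dsm_coverage(sub, fx$dsm_map)$count)
  }
})

test_that("form construction is deterministic and respects the strategies", {
  fx <- depression_fixture()
  res <- exclude_flagged(fx$bank, misfit = fx$misfit_items,
                         ld_sets = fx$ld_sets, dif = fx$dif_items)
  f_content <- build_form(fx$bank, res$eligible, fx$dsm_map, "content_first", 10)
  f_precision <- build_form(fx$bank, res$eligible, fx$dsm_map, "precision_first", 10)
  expect_length(f_content$item_ids, 10L)
  expect_length(f_precision$item_ids, 10L)
  expect_identical(build_form(fx$bank, res$eligible, fx$dsm_map, "content_first", 10),
                   f_content)
  # no sleep items exist, so the insomnia criterion can never be covered
  expect_false(f_content$coverage_detail$covered[
    f_content$coverage_detail$criterion_id == "c04"])
  expect_gte(f_content$coverage, f_precision$coverage)
  # a form the size of the whole eligible set IS the eligible set
  all_c <- build_form(fx$bank, res$eligible, fx$dsm_map, "content_first",
                      length(res$eligible))
  expect_setequal(all_c$item_ids, res$eligible)
  expect_warning(build_form(fx$bank, res$eligible[1:3], fx$dsm_map, "content_first", 10),
                 "eligible")
})

test_that("precision-first never beats content-first on coverage (random maps)", {
  set.seed(270)
  for (r in 1:20) {
    bank <- random_bank(12, seed = 300 + r)
    ids <- names(bank$items)
    map <- content_map(paste0("k", 1:6), paste0("criterion ", 1:6),
                       lapply(1:6, function(i) sample(ids, sample(0:3, 1))))
    fc <- build_form(bank, ids, map, "content_first", 6)
    fp <- build_form(bank, ids, map, "precision_first", 6)
    expect_gte(fc$coverage, fp$coverage)
  }
})

test_that("form comparison reports deltas only for nested pairs", {
  bank <- random_bank(6, seed = 281)
  th <- sample_theta(600, 0, 1, seed = 282)
  resp <- simulate_responses(bank, th, 0, seed = 283)
  ctrl <- test_ctrl(se = FALSE)
  ids <- names(bank$items)
  cmp_self <- compare_forms(list(ids[1:4], ids[1:4]), resp, ctrl)
  expect_equal(cmp_self$table$minus2ll[1], cmp_self$table$minus2ll[2])
  expect_equal(cmp_self$table$delta_minus2ll[2], 0)
  cmp_nested <- compare_forms(list(ids, ids[1:4]), resp, ctrl)
  expect_equal(cmp_nested$table$delta_minus2ll[2],
               cmp_nested$table$minus2ll[1] - cmp_nested$table$minus2ll[2])
  cmp_cross <- compare_forms(list(ids[1:4], ids[2:5]), resp, ctrl)
  expect_true(is.na(cmp_cross$table$delta_minus2ll[2]))
})
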
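# Generation and rule-inference solving of the thirteen item models.

test_that("solver reproduces the canonical exemplar of every item model", {
  exemplars <- list(
    list(1, c(10, 20, 30, 40), 1, 50),
    list(2, c(1, 1, 1, 5, 5), 1, 5),
    list(3, c(1, 2, 4, 8, 16), 1, 32),
    list(4, c(1, 10, 2, 20, 3, 30), 2, c(4, 40)),
    list(5, c(2, 7, 4, 14, 8, 28, 16), 2, c(56, 32)),
    list(6, c(2, 4, 7, 11, 16), 1, 22),
    list(7, c(3, 10, 24, 52, 108), 1, 220),
    list(8, c(1, 3, 8, 10, 207), 1, 209),
    list(8, c(2, 5, 8, 11, 89), 1, 92),
    list(9, c(1, 1, 2, 3, 5, 8), 1, 13),
    list(10, c(2, 15, 4, 17, 7, 19, 11, 21, 16), 2, c(23, 22)),
    list(11, c(1, 7, 14, 20, 40, 46), 2, c(92, 98)),
    list(12, c(1, 22, 44, 2, 66, 88, 3), 2, c(110, 132)),
    list(12, c(1, 22, 44, 2, 66, 88, 3, 110), 2, c(132, 4)),
    list(13, c(1, 5, 8, 3, 209, 212, 5, 41), 2, c(44, 7)))
  for (ex in exemplars) {
    expect_identical(solve_item(ex[[1]], ex[[2]], ex[[3]]),
                     as.integer(ex[[4]]),
                     info = sprintf("model %d stem %s", ex[[1]],
                                    paste(ex[[2]], collapse = " ")))
  }
  # trivial successor rule
  expect_identical(solve_item(1, c(0, 1, 2, 3), 1), 4L)
  expect_identical(solve_item(2, c(4, 4, 4, 9, 9), 1), 9L)
})

test_that("generation with pinned parameters reproduces printed items", {
  it3 <- generate_item(3, list(start = 1, op = "*", coef = 2))
  expect_identical(it3$stem, c(1L, 2L, 4L, 8L, 16L))
  expect_identical(it3$key, 32L)

  it1 <- generate_item(1, list(start = 10, constant = 10))
  expect_identical(it1$stem, c(10L, 20L, 30L, 40L))
  expect_identical(it1$key, 50L)

  it2 <- generate_item(2, list(values = c(1, 5)))
  expect_identical(it2$stem, c(1L, 1L, 1L, 5L, 5L))
  expect_identical(it2$key, 5L)

  it6 <- generate_item(6, list(start = 2, d0 = 2, incr = 1))
  expect_identical(it6$stem, c(2L, 4L, 7L, 11L, 16L))
  expect_identical(it6$key, 22L)
  expect_true(verify_item(it6))

  # both layouts of the unevenly ordered sub-sequence model
  it12a <- generate_item(12, list(s1_start = 1, s1_const = 1, s2_start = 22,
                                  s2_const = 22, layout = "len9"))
  expect_identical(it12a$stem, c(1L, 22L, 44L, 2L, 66L, 88L, 3L))
  expect_identical(it12a$key, c(110L, 132L))
  it12b <- generate_item(12, list(s1_start = 1, s1_const = 1, s2_start = 22,
                                  s2_const = 22, layout = "len10"))
  expect_identical(it12b$key, c(132L, 4L))
})

test_that("generate/solve round trip holds across all models and seeds", {
  for (m in 1:13) {
    for (j in 1:25) {
      item <- generate_item(m, seed = 20000 + 131 * m + j)
      v <- verify_item(item)
      expect_true(isTRUE(v),
                  info = sprintf("model %d seed %d: %s", m, j,
                                 attr(v, "reason") %||% ""))
      expect_true(all(abs(c(item$stem, item$key)) <= 10000))
    }
  }
})

test_that("tampered keys are rejected with a diagnostic", {
  item <- generate_item(6, list(start = 2, d0 = 2, incr = 1))
  item$key <- 21L
  v <- verify_item(item)
  expect_false(isTRUE(v))
  expect_match(attr(v, "reason"), "key mismatch")
  expect_false(isTRUE(verify_item(list(stem = 1:3))))
})

test_that("generation is deterministic in (model, params, seed) and varies by seed", {
  a <- generate_item(9, seed = 7)
  b <- generate_item(9, seed = 7)
  expect_identical(a, b)
  stems <- vapply(1:60, function(s)
    paste(generate_item(3, seed = s)$stem, collapse = ","), character(1))
  expect_gt(mean(!duplicated(stems)), 0.8)
})

test_that("invalid requests raise domain errors", {
  expect_error(generate_item(14), class = "ansig_domain_error")
  expect_error(solve_item(0, 1:5), class = "ansig_domain_error")
  expect_error(solve_item(3, c(1, 2, 4, 8, 16), 3), class = "ansig_domain_error")
  expect_error(operator_profile(14), class = "ansig_domain_error")
  # composite chain that fits no admissible rule
  expect_error(solve_item(7, c(1, 5, 6, 100, 2), 1),
               class = "ansig_unsolvable_error")
  # magnitude cap with fully pinned parameters
  expect_error(generate_item(3, list(start = 9, op = "*", coef = 9)),
               class = "ansig_domain_error")
})

test_that("item banks have the requested size, distinct stems and reproduce under seed", {
  bank <- sample_item_bank(3:13, 5, seed = 42)
  expect_length(bank$items, 55)
  models <- bank_models(bank)
  expect_equal(unname(table(models)), rep(5L, 11), ignore_attr = TRUE)
  for (m in 3:13) {
    stems <- vapply(bank$items[models == m], function(it)
      paste(it$stem, collapse = ","), character(1))
    expect_false(anyDuplicated(stems) > 0)
  }
  expect_identical(sample_item_bank(3:13, 5, seed = 42), bank)
  expect_length(sample_item_bank(1, 1, seed = 3)$items, 1)
  expect_error(sample_item_bank(3, 0), class = "ansig_domain_error")
})
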
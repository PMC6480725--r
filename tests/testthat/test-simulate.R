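# Respondent simulation and form assembly.

test_that("simulation is seed-deterministic and honours the probability model", {
  delta <- c(I1 = 0, I2 = 0, I3 = 0, I4 = 0)
  cfg <- simulation_config(c(A = 2000), delta, theta_mean = 0, theta_sd = 1e-9,
                           seed = 10)
  design <- form_design(list(A = names(delta)))
  x <- simulate_responses(cfg, design)
  expect_identical(simulate_responses(cfg, design), x)
  # theta == delta for every cell: correct rate 0.5 within binomial error
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.25 / length(x)))
  # far-off difficulty: near-zero success
  cfg_hard <- simulation_config(c(A = 1000), c(I1 = 12), theta_sd = 1e-9,
                                seed = 10)
  x_hard <- simulate_responses(cfg_hard, form_design(list(A = "I1")))
  expect_lt(mean(x_hard), 0.005)
})

test_that("marginal correct rate matches the logistic-normal integral", {
  delta <- c(I1 = -1, I2 = 0.5)
  cfg <- simulation_config(c(A = 4000), delta, theta_sd = 1.3, seed = 44)
  x <- simulate_responses(cfg, form_design(list(A = names(delta))))
  for (i in 1:2) {
    expected <- stats::integrate(function(t)
      plogis(t - delta[i]) * stats::dnorm(t, 0, 1.3), -Inf, Inf)$value
    expect_lt(abs(mean(x[, i]) - expected), 3.5 * sqrt(0.25 / nrow(x)))
  }
})

test_that("the study preset reproduces the two-form anchored layout", {
  bank <- sample_item_bank(3:13, 5, seed = 1)
  design <- assemble_forms(bank_models(bank), "study")
  expect_length(design$forms$A, 30)
  expect_length(design$forms$B, 35)
  expect_length(design$anchors, 10)
  expect_true(all(design$anchors %in% design$forms$A))
  expect_true(all(design$anchors %in% design$forms$B))
  # the 49-item post-exclusion layout gives 24 / 34 / 9
  s <- study_setup()
  expect_length(s$design$forms$A, 24)
  expect_length(s$design$forms$B, 34)
  expect_length(s$design$anchors, 9)
  # missing-by-design cells only off-form
  cfg <- simulation_config(c(A = 30, B = 20), s$delta, seed = 3)
  x <- simulate_responses(cfg, s$design)
  form <- attr(x, "form")
  for (f in c("A", "B")) {
    rows <- form == f
    expect_true(all(!is.na(x[rows, s$design$forms[[f]]])))
    off <- setdiff(colnames(x), s$design$forms[[f]])
    expect_true(all(is.na(x[rows, off])))
  }
})

test_that("single-form and custom specs work; anchor-free designs warn", {
  models <- c(a = 3, b = 3, c = 5)
  single <- assemble_forms(models, "single")
  expect_length(single$forms$A, 3)
  expect_warning(form_design(list(A = c("a", "b"), B = c("c"))),
                 "anchor")
  expect_error(assemble_forms(models, list(A = 3, B = 9)),
               class = "ansig_domain_error")
  expect_error(assemble_forms(models, "bogus"), class = "ansig_domain_error")
})

test_that("bin assembly draws a flat form of three items per fillable bin", {
  s <- study_setup()
  # on the published (2-dp rounded) difficulty estimates the lowest bin
  # holds only two items, so the draw yields 23 rather than the nominal 24
  expect_warning(
    design <- assemble_form_by_bins(s$delta, bin_width = 0.5,
                                    range = c(-2, 2), per_bin = 3, seed = 2),
    "holds only")
  expect_length(design$forms$C, 23)
  d <- s$delta[design$forms$C]
  counts <- table(cut(d, seq(-2, 2, 0.5), right = FALSE))
  expect_true(all(counts <= 3))
  expect_equal(sum(counts == 3), 7)
  expect_identical(
    suppressWarnings(assemble_form_by_bins(s$delta, seed = 2))$forms$C,
    design$forms$C)
  # fully fillable bins give exactly per_bin * n_bins items
  dense <- structure(seq(-1.99, 1.99, length.out = 160),
                     names = paste0("D", 1:160))
  full <- assemble_form_by_bins(dense, seed = 4)
  expect_length(full$forms$C, 24)
  # under-filled single bin is taken whole with a warning
  expect_warning(one <- assemble_form_by_bins(c(X = 0.1), range = c(0, 0.5),
                                              per_bin = 3, seed = 1),
                 "holds only")
  expect_identical(one$forms$C, "X")
  expect_error(assemble_form_by_bins(numeric(0)), class = "ansig_domain_error")
})

test_that("an item residual perturbs the realised difficulties once per item", {
  delta <- c(I1 = -1, I2 = 0, I3 = 1)
  design <- form_design(list(A = names(delta)))
  cfg0 <- simulation_config(c(A = 50), delta, item_resid_sd = 0, seed = 6)
  cfg1 <- simulation_config(c(A = 50), delta, item_resid_sd = 0.8, seed = 6)
  x0 <- simulate_responses(cfg0, design)
  x1 <- simulate_responses(cfg1, design)
  expect_equal(attr(x0, "difficulties_used"), delta)
  expect_false(any(attr(x1, "difficulties_used") == delta))
  expect_error(simulation_config(c(A = 10), delta, theta_sd = 0),
               class = "ansig_domain_error")
  expect_error(simulate_responses(
    simulation_config(c(A = 10), c(I1 = 0), seed = 1),
    form_design(list(A = c("I1", "Iunknown")))),
    class = "ansig_domain_error")
})
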
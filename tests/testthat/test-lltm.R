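# LLTM and LLTM-plus-error estimation, difficulty prediction, bootstrap
# and model comparison.

make_fake_fit <- function(loglik, p, n) {
  structure(list(kind = "fake", marg_loglik = loglik, n_params = p,
                 n_obs = n, fingerprint = c(n_obs = n, n_correct = 1,
                                            n_persons = 1, n_items = 1),
                 eta = numeric(0)),
            class = "ansig_lltm")
}

test_that("AIC and BIC follow their definitions with N = observed responses", {
  cmp <- compare_models(make_fake_fit(-100, 5, 1000),
                        make_fake_fit(-98, 6, 1000), labels = c("a", "b"))
  expect_equal(cmp$table$AIC[1], 210)
  expect_equal(cmp$table$BIC[1], 234.5378, tolerance = 1e-4)
  expect_equal(cmp$lr_tests$statistic, 4)
  expect_equal(cmp$lr_tests$df, 1)
  expect_error(compare_models(make_fake_fit(-1, 2, 10),
                              make_fake_fit(-1, 2, 11)),
               class = "ansig_domain_error")
})

test_that("a saturated property matrix reproduces the marginal Rasch difficulties", {
  delta <- c(-1, -0.4, 0.1, 0.6, 1.2, 0, -0.8, 0.9)
  x <- sim_single_form(250, delta, seed = 14)
  # per-item indicators (first item as reference) + intercept = saturation
  ind <- diag(8)[, -1]
  colnames(ind) <- paste0("d", 2:8)
  rownames(ind) <- 1:8
  q <- build_qmatrix(ind)
  props <- expand_item_properties(q, structure(1:8, names = colnames(x)))
  sat <- fit_lltm(x, props)
  mml <- fit_rasch_mml(x)
  d_sat <- sat$fitted_difficulties - mean(sat$fitted_difficulties)
  expect_lt(max(abs(d_sat - mml$difficulties)), 1e-3)
  expect_equal(cor(d_sat, mml$difficulties), 1, tolerance = 1e-6)
  expect_equal(sat$marg_loglik, mml$marg_loglik, tolerance = 1e-4)
})

test_that("difficulty predictions are the negated operator decomposition", {
  coefs <- study_lltm_coefficients("lltm")
  expect_equal(unname(predict_difficulties(coefs, build_qmatrix("ansig", 4))),
               -3.24)
  expect_equal(unname(predict_difficulties(coefs, build_qmatrix("ansig", 8))),
               0.01, tolerance = 1e-9)
  expect_equal(unname(predict_difficulties(coefs, build_qmatrix("ansig", 12:13))),
               c(1.54, 1.54))
  # all-zero profile returns minus the constant
  q0 <- build_qmatrix(matrix(0, 1, 5,
                             dimnames = list(1, names(coefs$eta))))
  expect_equal(unname(predict_difficulties(coefs, q0)), -coefs$intercept)
  expect_error(predict_difficulties(coefs, build_qmatrix("holzman", 4)),
               class = "ansig_domain_error")
})

test_that("LLTM recovers operator weights on a small generating design", {
  s <- study_setup()
  truth <- study_lltm_coefficients("lltm")
  pred <- predict_difficulties(truth, build_qmatrix("ansig", 3:13))
  delta <- structure(pred[as.character(s$models)], names = names(s$models))
  cfg <- simulation_config(c(A = 400, B = 200), delta,
                           theta_sd = sqrt(truth$person_var), seed = 77)
  x <- simulate_responses(cfg, s$design)
  fit <- fit_lltm(x, s$props, nAGQ = 0)
  expect_equal(unname(fit$eta[names(truth$eta)]), unname(truth$eta),
               tolerance = 0.25)
  expect_gt(cor(fit$fitted_difficulties[names(delta)], delta), 0.99)
  # sign structure: four operators harden items, with increasing impact
  expect_true(all(fit$eta[c("ps", "cf", "npcp", "pcp")] < 0))
  expect_true(all(diff(-fit$eta[c("ps", "cf", "npcp", "pcp")]) > 0))
})

test_that("the item-error model nests the plain LLTM and estimates the residual variance", {
  s <- study_setup()
  truth <- study_lltm_coefficients("lltm")
  pred <- predict_difficulties(truth, build_qmatrix("ansig", 3:13))
  base <- structure(pred[as.character(s$models)], names = names(s$models))
  # generating residual variance 1.0
  cfg <- simulation_config(c(A = 350, B = 250), base, theta_sd = 1.2,
                           item_resid_sd = 1, seed = 55)
  x <- simulate_responses(cfg, s$design)
  plain <- fit_lltm(x, s$props, nAGQ = 0)
  err <- fit_lltm_error(x, s$props, nAGQ = 0)
  expect_gte(err$marg_loglik, plain$marg_loglik - 1e-6)
  expect_gt(err$item_resid_var, 0.2)
  expect_lt(err$item_resid_var, 3)
  expect_equal(err$n_params, plain$n_params + 1)
  # shrunken difficulties track the realised (residual-shifted) values
  used <- attr(x, "difficulties_used")
  expect_gt(cor(err$shrunken_difficulties[names(used)], used),
            cor(err$fitted_difficulties[names(used)], used))
})

test_that("parametric bootstrap gives reproducible, finite standard errors", {
  delta <- c(-0.6, -0.6, 0.6, 0.6)
  x <- sim_single_form(150, delta, seed = 19)
  q <- build_qmatrix(matrix(c(0, 0, 1, 1), 4, 1,
                            dimnames = list(1:4, "hard")))
  props <- expand_item_properties(q, structure(1:4, names = colnames(x)))
  fit <- fit_lltm(x, props, nAGQ = 0)
  bs1 <- bootstrap_item_se(fit, n_iter = 8, seed = 6)
  bs2 <- bootstrap_item_se(fit, n_iter = 8, seed = 6)
  expect_equal(bs1$se_eta, bs2$se_eta)
  expect_true(all(is.finite(bs1$se_eta)))
  expect_true(all(is.finite(bs1$se_difficulty)))
  expect_named(bs1$se_difficulty, names(fit$fitted_difficulties))
  expect_error(bootstrap_item_se(fit, n_iter = 1),
               "n_iter")
})

test_that("collinear operator columns are rejected by name", {
  x <- sim_single_form(60, c(-0.3, 0.3, 0, 0.5), seed = 3)
  qm <- matrix(c(1, 0, 1, 0,
                 1, 0, 1, 0), 4, 2,
               dimnames = list(1:4, c("opA", "opB")))
  q <- build_qmatrix(qm)
  props <- expand_item_properties(q, structure(1:4, names = colnames(x)))
  expect_error(fit_lltm(x, props), class = "ansig_domain_error")
})
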
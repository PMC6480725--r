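# Conditional maximum likelihood calibration, person estimation,
# information and reliability.

test_that("symmetric two-item data yield equal (zero) difficulties", {
  x <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  colnames(x) <- c("I1", "I2")
  fit <- fit_rasch_cml(x)
  expect_equal(unname(fit$difficulties), c(0, 0), tolerance = 1e-8)
  expect_equal(sum(fit$difficulties), 0, tolerance = 1e-10)
  expect_true(all(fit$se > 0))
})

test_that("CML matches the exhaustive conditional-likelihood grid oracle", {
  for (seed in c(3, 17)) {
    x <- sim_single_form(60, c(I1 = -0.8, I2 = 0.3, I3 = 0.9), seed = seed)
    fit <- fit_rasch_cml(x)
    oracle <- cml_grid_oracle(x)
    expect_lt(max(abs(unname(fit$difficulties) - unname(oracle))), 1e-3)
  }
})

test_that("CML recovers difficulties and is invariant to ability shifts", {
  delta <- seq(-2, 2, length.out = 20)
  x0 <- sim_single_form(800, delta, seed = 31, theta_mean = 0)
  x1 <- sim_single_form(800, delta, seed = 32, theta_mean = 1)
  f0 <- fit_rasch_cml(x0)
  f1 <- fit_rasch_cml(x1)
  expect_gt(cor(f0$difficulties, delta), 0.97)
  # a shifted ability distribution leaves the item parameters untouched
  # (up to Monte-Carlo error)
  expect_gt(cor(f0$difficulties, f1$difficulties), 0.97)
  expect_lt(max(abs(f0$difficulties - f1$difficulties)), 0.45)
})

test_that("items without variance are excluded with a warning", {
  x <- sim_single_form(40, c(I1 = 0, I2 = 0.5, I3 = -0.5), seed = 5)
  x <- cbind(x, Iconst = 1L)
  expect_warning(fit <- fit_rasch_cml(x), "Iconst")
  expect_identical(fit$excluded_items, "Iconst")
  expect_length(fit$difficulties, 3)
})

test_that("person estimates are score-sufficient, monotone and match a grid oracle", {
  delta <- c(I1 = -1, I2 = -0.3, I3 = 0.4, I4 = 1.1, I5 = 0)
  x <- sim_single_form(120, delta, seed = 8)
  fit <- list(difficulties = delta)
  pe <- estimate_persons(fit, x)
  ok <- !pe$excluded
  # strict monotonicity in raw score on a fixed form
  agg <- tapply(pe$theta[ok], pe$raw_score[ok], unique)
  expect_true(all(vapply(agg, length, integer(1)) == 1))
  expect_true(all(diff(unlist(agg)) > 0))
  # half of a symmetric two-item test at delta = (0, 0) scores theta = 0
  x2 <- rbind(c(1, 0)); colnames(x2) <- c("A", "B")
  pe2 <- estimate_persons(list(difficulties = c(A = 0, B = 0)), x2)
  expect_equal(pe2$theta, 0, tolerance = 1e-8)
  # one-dimensional grid oracle for one person
  v <- which(ok)[1]
  grid <- seq(-6, 6, 0.001)
  lik <- vapply(grid, function(th) {
    p <- plogis(th - delta)
    sum(stats::dbinom(x[v, ], 1, p, log = TRUE))
  }, numeric(1))
  expect_lt(abs(pe$theta[v] - grid[which.max(lik)]), 1e-3)
  # extreme scores are flagged
  x3 <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 0, 1))
  colnames(x3) <- paste0("I", 1:3)
  pe3 <- estimate_persons(list(difficulties = c(I1 = 0, I2 = 0, I3 = 0)), x3)
  expect_identical(pe3$excluded, c(TRUE, TRUE, FALSE))
})

test_that("test information behaves as Fisher information of the Rasch ICC", {
  single <- test_information(0.7)
  expect_equal(single$max_info, 0.25, tolerance = 1e-6)
  expect_equal(single$argmax_theta, 0.7, tolerance = 0.011)
  sym <- test_information(c(-1, 1))
  expect_equal(sym$argmax_theta, 0, tolerance = 0.011)
  expect_equal(sym$info, rev(sym$info), tolerance = 1e-9)
  expect_true(all(sym$info >= 0))
  expect_error(test_information(numeric(0)), class = "ansig_domain_error")
})

test_that("person separation reliability follows its variance decomposition", {
  p0 <- data.frame(theta = rnorm(50), se = 0, excluded = FALSE)
  expect_equal(person_separation_reliability(p0), 1)
  th <- rnorm(200)
  p1 <- data.frame(theta = th, se = sd(th), excluded = FALSE)
  expect_equal(person_separation_reliability(p1), 0, tolerance = 1e-6)
  # longer tests measure better
  delta60 <- seq(-2, 2, length.out = 60)
  x <- sim_single_form(400, delta60, seed = 21)
  f <- fit_rasch_cml(x)
  long_rel <- person_separation_reliability(estimate_persons(f, x))
  x10 <- x[, 1:10 * 6 - 3]
  f10 <- fit_rasch_cml(x10)
  short_rel <- person_separation_reliability(estimate_persons(f10, x10))
  expect_gt(long_rel, short_rel)
  expect_gt(long_rel, 0.85)
})

test_that("calibration is invariant to person reordering and to padding with unadministered items", {
  delta <- c(a = -0.5, b = 0, c = 0.7, d = -0.2)
  x <- sim_single_form(300, delta, seed = 13)
  whole <- fit_rasch_cml(x)
  perm <- withr::with_seed(2, sample(nrow(x)))
  expect_equal(fit_rasch_cml(x[perm, ])$difficulties, whole$difficulties,
               tolerance = 1e-6)
  # persons who saw nothing are dropped, not counted
  x_pad <- rbind(x, matrix(NA_integer_, 5, ncol(x),
                           dimnames = list(paste0("Z", 1:5), colnames(x))))
  fit_pad <- fit_rasch_cml(x_pad)
  expect_equal(fit_pad$difficulties, whole$difficulties, tolerance = 1e-6)
  expect_length(fit_pad$excluded_persons, 5)
})
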
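# Rasch calibration by conditional maximum likelihood.  Persons are
# conditioned on their raw score over the items they were administered, so
# multi-form designs with anchor items are calibrated concurrently on one
# metric without modelling the ability distribution.

# Elementary symmetric functions of the easiness parameters eps, computed
# by the summation (difference-free) recurrence; returns gamma_0..gamma_k.
esf <- function(eps) {
  g <- c(1, numeric(length(eps)))
  n1 <- length(g)
  for (e in eps) g[-1] <- g[-1] + e * g[-n1]
  g
}

.check_responses <- function(responses) {
  x <- as.matrix(responses)
  if (!all(x[!is.na(x)] %in% c(0, 1)))
    ansig_domain_error("responses must be 0, 1 or NA (not administered)")
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("I", seq_len(ncol(x)))
  x
}

# Precompute the sufficient statistics of the conditional likelihood:
# persons grouped by administered item set, raw-score counts per group,
# per-item totals.
.cml_data <- function(x) {
  admin <- !is.na(x)
  # persons with extreme scores on their administered set contribute a
  # constant to the conditional likelihood; drop them from both the item
  # totals and the normalising terms
  score <- rowSums(x, na.rm = TRUE)
  extreme <- score == 0 | score == rowSums(admin)
  x <- x[!extreme, , drop = FALSE]
  admin <- admin[!extreme, , drop = FALSE]
  keys <- apply(admin, 1, function(a) paste(which(a), collapse = ","))
  groups <- lapply(split(seq_len(nrow(x)), keys), function(rows) {
    S <- which(admin[rows[1], ])
    scores <- rowSums(x[rows, S, drop = FALSE])
    list(items = S, score_counts = table(scores))
  })
  list(groups = groups, item_totals = colSums(x, na.rm = TRUE))
}

.cml_negll <- function(beta, dat) {
  ll <- sum(dat$item_totals * beta)
  for (g in dat$groups) {
    if (!length(g$score_counts)) next
    gam <- esf(exp(beta[g$items]))
    r <- as.integer(names(g$score_counts))
    ll <- ll - sum(g$score_counts * log(gam[r + 1]))
  }
  -ll
}

.cml_neggrad <- function(beta, dat) {
  gr <- dat$item_totals
  for (g in dat$groups) {
    if (!length(g$score_counts)) next
    eps <- exp(beta[g$items])
    k <- length(eps)
    gam <- esf(eps)
    r <- as.integer(names(g$score_counts))
    n_r <- as.numeric(g$score_counts)
    for (j in seq_len(k)) {
      gam_m <- esf(eps[-j])                 # gamma of the set without item j
      # d log gamma_r / d beta_j = eps_j * gamma_{r-1}^{(j)} / gamma_r
      gr[g$items[j]] <- gr[g$items[j]] -
        sum(n_r * eps[j] * gam_m[r] / gam[r + 1])
    }
  }
  -gr
}

#' Fit the Rasch model by conditional maximum likelihood
#'
#' Estimates item difficulties from a dichotomous person-by-item matrix.
#' `NA` cells are treated as not administered (missing by design); each
#' person is conditioned on the raw score over their own administered item
#' set, so overlapping test forms sharing anchor items are placed on a
#' common metric automatically.  Difficulties are identified by a sum-zero
#' constraint over the estimated items.
#'
#' @param responses persons x items matrix of 0/1/NA.
#' @param reltol relative convergence tolerance of the quasi-Newton
#'   optimiser.
#' @param maxit iteration cap.
#' @return Object of class `ansig_rasch`: `difficulties` (sum-zero logits),
#'   `se`, `cond_loglik`, `excluded_items`, `excluded_persons`,
#'   `convergence`, `item_totals`.
#' @export
fit_rasch_cml <- function(responses, reltol = 1e-10, maxit = 500) {
  x <- .check_responses(responses)
  admin <- !is.na(x)
  n_admin <- rowSums(admin)
  excluded_persons <- rownames(x)[n_admin == 0]
  x <- x[n_admin > 0, , drop = FALSE]

  tot <- colSums(x, na.rm = TRUE)
  cnt <- colSums(!is.na(x))
  novar <- cnt == 0 | tot == 0 | tot == cnt
  excluded_items <- colnames(x)[novar]
  if (length(excluded_items)) {
    warning("excluding items without response variance: ",
            paste(excluded_items, collapse = ", "))
    x <- x[, !novar, drop = FALSE]
  }
  k <- ncol(x)
  if (k < 2) ansig_domain_error("need at least 2 estimable items")
  if (nrow(x) < 2) ansig_domain_error("need at least 2 persons")

  dat <- .cml_data(x)
  # easiness start values from logit of item p-values, reference item 1 at 0
  p_i <- pmin(pmax(colSums(x, na.rm = TRUE) / colSums(!is.na(x)), 0.02), 0.98)
  start <- qlogis(p_i)
  start <- start - start[1]

  free <- 2:k
  fn <- function(b) .cml_negll(c(0, b), dat)
  gr <- function(b) .cml_neggrad(c(0, b), dat)[free]
  opt <- optim(start[free], fn, gr, method = "BFGS", hessian = TRUE,
               control = list(maxit = maxit, reltol = reltol))
  grad_norm <- sqrt(sum(.cml_neggrad(c(0, opt$par), dat)[free]^2))
  if (opt$convergence != 0)
    ansig_stop(sprintf(
      "CML estimation did not converge (code %d, gradient norm %.2e)",
      opt$convergence, grad_norm), "ansig_nonconvergence")

  beta <- c(0, opt$par)
  delta <- -beta
  delta <- delta - mean(delta)
  names(delta) <- colnames(x)

  # delta-method SEs under the sum-zero identification
  V <- matrix(0, k, k)
  V[free, free] <- tryCatch(solve(opt$hessian),
                            error = function(e) MASS_ginv(opt$hessian))
  A <- diag(k) - 1 / k
  Vc <- A %*% V %*% t(A)
  se <- sqrt(pmax(diag(Vc), 0))
  names(se) <- colnames(x)

  structure(list(difficulties = delta, se = se,
                 cond_loglik = -opt$value,
                 excluded_items = excluded_items,
                 excluded_persons = excluded_persons,
                 convergence = list(code = opt$convergence,
                                    iterations = opt$counts[["function"]],
                                    gradient_norm = grad_norm),
                 item_totals = dat$item_totals),
            class = "ansig_rasch")
}

# minimal pseudoinverse fallback (no MASS dependency)
MASS_ginv <- function(H) {
  s <- svd(H)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.ansig_rasch <- function(x, ...) {
  cat(sprintf(
    "Rasch CML fit: %d items, conditional logLik %.2f\n",
    length(x$difficulties), x$cond_loglik))
  print(round(x$difficulties, 3))
  invisible(x)
}

#' Maximum-likelihood person parameters
#'
#' Estimates each person's ability given fixed item difficulties by solving
#' the score equation on the person's administered items.  Persons with
#' perfect or zero raw scores have no finite maximum-likelihood estimate
#' and are flagged as excluded.
#'
#' @param fit an `ansig_rasch` fit (or any object with a `difficulties`
#'   element named by item).
#' @param responses the person x item response matrix the abilities are to
#'   be scored on.
#' @return Object of class `ansig_persons`: data frame with `theta`, `se`,
#'   `raw_score`, `n_admin`, `excluded`.
#' @export
estimate_persons <- function(fit, responses) {
  delta <- fit$difficulties
  x <- .check_responses(responses)
  x <- x[, colnames(x) %in% names(delta), drop = FALSE]
  out <- data.frame(theta = rep(NA_real_, nrow(x)), se = NA_real_,
                    raw_score = NA_real_, n_admin = NA_integer_,
                    excluded = FALSE, row.names = rownames(x))
  for (v in seq_len(nrow(x))) {
    S <- which(!is.na(x[v, ]))
    r <- sum(x[v, S])
    out$raw_score[v] <- r
    out$n_admin[v] <- length(S)
    if (length(S) == 0 || r == 0 || r == length(S)) {
      out$excluded[v] <- TRUE
      next
    }
    d <- delta[colnames(x)[S]]
    th <- qlogis(r / length(S)) + mean(d)
    for (iter in 1:100) {
      p <- plogis(th - d)
      info <- sum(p * (1 - p))
      step <- (r - sum(p)) / info
      th <- th + step
      if (abs(step) < 1e-10) break
    }
    out$theta[v] <- th
    out$se[v] <- 1 / sqrt(sum(plogis(th - d) * (1 - plogis(th - d))))
  }
  class(out) <- c("ansig_persons", "data.frame")
  out
}

#' Test information function
#'
#' Fisher information of a fixed-difficulty Rasch item set over an ability
#' grid: `I(theta) = sum_i p_i (1 - p_i)`.
#'
#' @param difficulties item difficulties in logits.
#' @param theta_grid ability grid (default -6..6 by 0.01).
#' @return Object of class `ansig_info`: `theta_grid`, `info`, `max_info`,
#'   `argmax_theta`.
#' @examples
#' test_information(0)$max_info  # single item: 0.25 at its difficulty
#' @export
test_information <- function(difficulties, theta_grid = seq(-6, 6, by = 0.01)) {
  if (!length(difficulties)) ansig_domain_error("empty item set")
  info <- vapply(theta_grid, function(th) {
    p <- plogis(th - difficulties)
    sum(p * (1 - p))
  }, numeric(1))
  structure(list(theta_grid = theta_grid, info = info,
                 max_info = max(info),
                 argmax_theta = theta_grid[which.max(info)]),
            class = "ansig_info")
}

#' @export
print.ansig_info <- function(x, ...) {
  cat(sprintf("test information: max %.2f at theta = %.2f\n",
              x$max_info, x$argmax_theta))
  invisible(x)
}

#' Person separation reliability
#'
#' IRT analogue of internal consistency: the proportion of observed ability
#' variance not attributable to estimation error,
#' `(var(theta) - mean(se^2)) / var(theta)`, floored at zero.
#'
#' @param persons an [estimate_persons()] result (or data frame with
#'   `theta` and `se`).
#' @return Numeric value in `[0, 1]`.
#' @export
person_separation_reliability <- function(persons) {
  ok <- !persons$excluded & !is.na(persons$theta)
  if (sum(ok) < 2) ansig_domain_error("need at least 2 estimated persons")
  v <- var(persons$theta[ok])
  if (v == 0) {
    warning("zero ability variance; reliability undefined, returning 0")
    return(0)
  }
  max(0, (v - mean(persons$se[ok]^2)) / v)
}
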
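# Linear logistic test models fitted as generalised linear mixed models:
# person ability as a normal random intercept, item difficulty decomposed
# into cognitive-operator weights (plus, optionally, a random item residual
# so the decomposition need not be exact).
#
# Fixed effects are estimated on the easiness scale (logit P = theta_v +
# intercept + sum_j q_ij * b_j); reported difficulties are the negated
# fitted linear predictors.

.lltm_long <- function(responses, properties = NULL) {
  x <- .check_responses(responses)
  long <- data.frame(
    y = as.vector(x),
    person = factor(rep(rownames(x), ncol(x)), levels = rownames(x)),
    item = factor(rep(colnames(x), each = nrow(x)), levels = colnames(x)))
  if (!is.null(properties)) {
    stopifnot(inherits(properties, "ansig_item_properties"))
    idx <- match(colnames(x), properties$item_ids)
    if (anyNA(idx))
      ansig_domain_error(sprintf(
        "no operator covariates for item(s): %s",
        paste(colnames(x)[is.na(idx)], collapse = ", ")))
    cov <- properties$covariates[idx, , drop = FALSE]
    long <- cbind(long, cov[rep(seq_len(ncol(x)), each = nrow(x)), , drop = FALSE])
  }
  long[!is.na(long$y), , drop = FALSE]
}

.data_fingerprint <- function(long) {
  c(n_obs = nrow(long), n_correct = sum(long$y),
    n_persons = length(unique(long$person)),
    n_items = length(unique(long$item)))
}

# accessor shims over the two marginal-likelihood engines
.is_tmb <- function(mod) inherits(mod, "glmmTMB")
.fe <- function(mod) if (.is_tmb(mod)) glmmTMB::fixef(mod)$cond else lme4::fixef(mod)
.vc_df <- function(mod) {
  if (.is_tmb(mod)) {
    vc <- glmmTMB::VarCorr(mod)$cond
    data.frame(grp = names(vc),
               vcov = vapply(vc, function(v) v[1, 1], numeric(1)))
  } else as.data.frame(lme4::VarCorr(mod))[, c("grp", "vcov")]
}
.vcov_fe <- function(mod) {
  as.matrix(if (.is_tmb(mod)) stats::vcov(mod)$cond else stats::vcov(mod))
}
.ranef_grp <- function(mod, grp, condVar = FALSE) {
  if (.is_tmb(mod)) glmmTMB::ranef(mod, condVar = condVar)$cond[[grp]]
  else lme4::ranef(mod, condVar = condVar)[[grp]]
}
.fit_engine <- function(form, long, engine, nAGQ) {
  if (engine == "glmmTMB") glmmTMB::glmmTMB(form, data = long,
                                            family = stats::binomial())
  else lme4::glmer(form, data = long, family = stats::binomial(), nAGQ = nAGQ)
}

.lltm_result <- function(mod, long, properties, kind, nAGQ) {
  fe <- .fe(mod)
  vc <- .vc_df(mod)
  person_var <- vc$vcov[vc$grp == "person"]
  item_var <- if (any(vc$grp == "item")) vc$vcov[vc$grp == "item"] else 0
  ll <- as.numeric(logLik(mod))
  n_params <- length(fe) + nrow(vc)
  op_names <- if (!is.null(properties)) colnames(properties$covariates) else NULL
  eta <- fe[names(fe) != "(Intercept)"]
  intercept <- unname(fe["(Intercept)"])

  q_items <- NULL
  fitted_diff <- if (!is.null(properties)) {
    idx <- match(levels(long$item), properties$item_ids)
    q_items <- properties$covariates[idx, , drop = FALSE]
    rownames(q_items) <- levels(long$item)
    d <- -(intercept + as.numeric(q_items %*% eta[colnames(q_items)]))
    names(d) <- levels(long$item)
    d
  } else {
    d <- -fe
    names(d) <- sub("^item", "", names(fe))
    d
  }

  se_fe <- sqrt(diag(.vcov_fe(mod)))
  structure(list(kind = kind,
                 eta = eta,
                 se_eta = se_fe[names(se_fe) != "(Intercept)"],
                 intercept = intercept,
                 se_intercept = unname(se_fe["(Intercept)"]),
                 person_var = person_var,
                 item_resid_var = item_var,
                 marg_loglik = ll,
                 n_params = n_params,
                 n_obs = nrow(long),
                 fingerprint = .data_fingerprint(long),
                 fitted_difficulties = fitted_diff,
                 difficulties = fitted_diff,   # shared accessor name
                 q_items = q_items,
                 operator_names = op_names,
                 nAGQ = nAGQ,
                 glmer_fit = mod),
            class = "ansig_lltm")
}

#' Fit the linear logistic test model
#'
#' Marginal maximum likelihood fit of the LLTM: item difficulty is a linear
#' combination of the item model's cognitive-operator weights, person
#' ability is a normal random intercept.  The operator coefficients are
#' reported on the easiness scale; per-item predicted difficulties are the
#' negated fitted linear predictors.
#'
#' @param responses persons x items matrix of 0/1/NA.
#' @param properties an [expand_item_properties()] covariate matrix mapping
#'   each item to its operator weights.
#' @param nAGQ integration setting passed to [lme4::glmer()]: 1 is the
#'   Laplace approximation (default), larger values use adaptive
#'   Gauss-Hermite quadrature, 0 a faster penalised-likelihood
#'   approximation.  Ignored by the `glmmTMB` engine (always Laplace).
#' @param engine `"lme4"` (default) or `"glmmTMB"`; both maximise the same
#'   Laplace-approximated marginal likelihood (agreement to ~1e-3 on
#'   fixtures), the TMB backend being several times faster on large
#'   designs and in replication studies.
#' @return Object of class `ansig_lltm` with elements `eta`, `se_eta`,
#'   `intercept`, `person_var`, `item_resid_var` (zero here),
#'   `marg_loglik`, `n_params`, `fitted_difficulties` and the underlying
#'   `glmer` fit.
#' @export
fit_lltm <- function(responses, properties, nAGQ = 1,
                     engine = c("lme4", "glmmTMB")) {
  engine <- match.arg(engine)
  long <- .lltm_long(responses, properties)
  X <- cbind(1, as.matrix(long[, colnames(properties$covariates), drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    ansig_domain_error(paste0(
      "operator covariates are collinear (with the intercept); columns: ",
      paste(colnames(properties$covariates), collapse = ", ")))
  }
  form <- stats::as.formula(paste(
    "y ~ 1 +", paste(colnames(properties$covariates), collapse = " + "),
    "+ (1 | person)"))
  mod <- .fit_engine(form, long, engine, nAGQ)
  .lltm_result(mod, long, properties, "lltm", nAGQ)
}

#' Fit the LLTM with an item error term
#'
#' As [fit_lltm()], but with an additional random item intercept so that
#' per-item difficulty may deviate from the operator decomposition
#' (crossed person and item random effects, Laplace approximation).  The
#' estimated variance of the item residual measures how much difficulty the
#' operators leave unexplained.
#'
#' @inheritParams fit_lltm
#' @return Object of class `ansig_lltm` with `item_resid_var` estimated and
#'   `item_residuals` holding the conditional modes of the per-item
#'   deviation (difficulty scale).
#' @export
fit_lltm_error <- function(responses, properties, nAGQ = 1,
                           engine = c("lme4", "glmmTMB")) {
  engine <- match.arg(engine)
  long <- .lltm_long(responses, properties)
  # profile identifiability: warn when no operator profile repeats
  prof <- apply(properties$covariates, 1, paste, collapse = ",")
  if (!any(duplicated(prof)))
    warning("every item has a unique operator profile; ",
            "the item residual variance is weakly identified")
  form <- stats::as.formula(paste(
    "y ~ 1 +", paste(colnames(properties$covariates), collapse = " + "),
    "+ (1 | person) + (1 | item)"))
  mod <- .fit_engine(form, long, engine, if (nAGQ > 1) 1 else nAGQ)
  out <- .lltm_result(mod, long, properties, "lltm_error",
                      if (nAGQ > 1) 1 else nAGQ)
  blup <- .ranef_grp(mod, "item")
  resid <- -blup[[1]]
  names(resid) <- rownames(blup)
  out$item_residuals <- resid
  out$shrunken_difficulties <- out$fitted_difficulties +
    resid[names(out$fitted_difficulties)]
  out
}

#' Marginal-likelihood Rasch fit
#'
#' Rasch model with one free easiness parameter per item and a normal
#' person random effect, fitted by the same marginal likelihood as the
#' LLTMs so that information criteria are comparable (for `k` items this
#' model has `k + 1` parameters).
#'
#' @inheritParams fit_lltm
#' @export
fit_rasch_mml <- function(responses, nAGQ = 1,
                          engine = c("lme4", "glmmTMB")) {
  engine <- match.arg(engine)
  long <- .lltm_long(responses)
  mod <- .fit_engine(y ~ 0 + item + (1 | person), long, engine, nAGQ)
  out <- .lltm_result(mod, long, NULL, "rasch_mml", nAGQ)
  out$difficulties <- out$difficulties - mean(out$difficulties)
  out$fitted_difficulties <- out$difficulties
  out
}

#' @export
print.ansig_lltm <- function(x, ...) {
  cat(sprintf("%s fit (marginal ML, %d parameters): logLik %.1f\n",
              switch(x$kind, lltm = "LLTM", lltm_error = "LLTM + error",
                     rasch_mml = "Rasch (marginal)"),
              x$n_params, x$marg_loglik))
  if (length(x$eta)) {
    cat(sprintf("  easiness intercept %.2f; operator coefficients:\n",
                x$intercept))
    print(round(x$eta, 3))
  }
  cat(sprintf("  person variance %.3f; item residual variance %.3f\n",
              x$person_var, x$item_resid_var))
  invisible(x)
}

#' Predict item-model difficulties from operator weights
#'
#' `delta(model) = -(intercept + sum_j q_j * b_j)` on the difficulty scale.
#' Accepts a fitted LLTM or explicit coefficients (e.g. published
#' estimates).
#'
#' @param fit an `ansig_lltm` fit, or a list with elements `intercept` and
#'   `eta` (named easiness coefficients).
#' @param q a [build_qmatrix()] object whose columns match the coefficient
#'   names.
#' @return Named numeric vector of predicted difficulties, one per Q-matrix
#'   row.
#' @examples
#' coefs <- list(intercept = 4.77,
#'               eta = c(aos = 0.35, ps = -1.53, cf = -2.13,
#'                       npcp = -2.65, pcp = -3.76))
#' predict_difficulties(coefs, build_qmatrix("ansig", 4))  # -3.24
#' @export
predict_difficulties <- function(fit, q) {
  stopifnot(inherits(q, "ansig_qmatrix"))
  eta <- fit$eta
  if (!all(colnames(q$weights) %in% names(eta)))
    ansig_domain_error(sprintf(
      "Q-matrix columns (%s) do not match coefficient names (%s)",
      paste(colnames(q$weights), collapse = ", "),
      paste(names(eta), collapse = ", ")))
  d <- -(fit$intercept + as.numeric(q$weights %*% eta[colnames(q$weights)]))
  names(d) <- rownames(q$weights)
  d
}

#' Parametric bootstrap standard errors for LLTM parameters
#'
#' Simulates response vectors from the fitted model on the observed design,
#' refits, and reports the standard deviation of each fixed effect and of
#' each item's predicted difficulty over the replicates.
#'
#' @param fit an `ansig_lltm` fit.
#' @param n_iter bootstrap replications (the reference analysis used 1000).
#' @param seed integer seed.
#' @return List with `se_eta` (fixed effects incl. intercept),
#'   `se_difficulty` (per item), `n_fail` (dropped refits) and the raw
#'   coefficient draws.
#' @export
bootstrap_item_se <- function(fit, n_iter = 1000, seed = 1) {
  stopifnot(inherits(fit, "ansig_lltm"), n_iter >= 2)
  mod <- fit$glmer_fit
  draw <- function() {
    ys <- simulate(mod)[[1]]
    ref <- tryCatch(lme4::refit(mod, newresp = ys), error = function(e) NULL,
                    warning = function(w) suppressWarnings(
                      lme4::refit(mod, newresp = ys)))
    if (is.null(ref)) return(NULL)
    lme4::fixef(ref)
  }
  draws <- withr::with_seed(seed, replicate(n_iter, draw(), simplify = FALSE))
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(!ok) > 0.2)
    ansig_stop(sprintf("bootstrap refits failed in %d of %d replicates",
                       sum(!ok), n_iter), "ansig_bootstrap_failure")
  B <- do.call(rbind, draws[ok])
  se_fe <- apply(B, 2, sd)
  se_diff <- NULL
  if (!is.null(fit$q_items)) {
    # per-replicate predicted difficulty = -(intercept + q b)
    qi <- fit$q_items
    D <- -(B[, "(Intercept)"] + B[, colnames(qi), drop = FALSE] %*% t(qi))
    se_diff <- apply(D, 2, sd)[names(fit$fitted_difficulties)]
  }
  list(se_eta = se_fe, se_difficulty = se_diff,
       n_fail = sum(!ok), draws = B)
}

#' Compare fitted models by information criteria and likelihood ratios
#'
#' `AIC = -2 logL + 2p`, `BIC = -2 logL + p log(N)` with `N` the number of
#' observed (administered) responses.  Likelihood-ratio tests are reported
#' for consecutive models when ordered by parameter count; all fits must be
#' of the same data (checked by fingerprint).
#'
#' @param ... fitted `ansig_lltm` objects (including [fit_rasch_mml()]
#'   fits), or a single list of them.
#' @param labels optional model labels.
#' @return Object of class `ansig_comparison`: data frame `table` and data
#'   frame `lr_tests`.
#' @examples
#' # AIC/BIC arithmetic: logL -100, 5 parameters, N = 1000
#' -2 * -100 + 2 * 5            # 210
#' -2 * -100 + 5 * log(1000)    # 234.54
#' @export
compare_models <- function(..., labels = NULL) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "ansig_lltm")) fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, logical(1), "ansig_lltm")))
  if (is.null(labels))
    labels <- vapply(fits, function(f) f$kind, character(1))
  fps <- vapply(fits, function(f) paste(f$fingerprint, collapse = "/"),
                character(1))
  if (length(unique(fps)) != 1)
    ansig_domain_error("model fits are not based on the same response data")
  ll <- vapply(fits, `[[`, numeric(1), "marg_loglik")
  p <- vapply(fits, `[[`, numeric(1), "n_params")
  n <- fits[[1]]$n_obs
  tab <- data.frame(model = labels, n_params = p, loglik = ll,
                    AIC = -2 * ll + 2 * p, BIC = -2 * ll + p * log(n))
  ord <- order(p)
  lr <- NULL
  if (length(fits) > 1) {
    a <- ord[-length(ord)]; b <- ord[-1]
    lr <- data.frame(reduced = labels[a], full = labels[b],
                     statistic = 2 * (ll[b] - ll[a]), df = p[b] - p[a])
    lr$p_value <- pchisq(lr$statistic, pmax(lr$df, 1), lower.tail = FALSE)
  }
  structure(list(table = tab, lr_tests = lr, n_obs = n),
            class = "ansig_comparison")
}

#' @export
print.ansig_comparison <- function(x, ...) {
  cat(sprintf("model comparison (N = %d observed responses)\n", x$n_obs))
  print(transform(x$table, AIC = round(AIC, 1), BIC = round(BIC, 1),
                  loglik = round(loglik, 1)), row.names = FALSE)
  if (!is.null(x$lr_tests)) {
    cat("likelihood-ratio tests:\n")
    print(x$lr_tests, row.names = FALSE)
  }
  invisible(x)
}

#' Person abilities from a marginal-likelihood fit
#'
#' Conditional modes (and conditional standard deviations) of the person
#' random effect.
#'
#' @param fit an `ansig_lltm` fit.
#' @return Data frame with `theta` and `se`, rownames the person ids.
#' @export
lltm_person_estimates <- function(fit) {
  stopifnot(inherits(fit, "ansig_lltm"))
  re <- .ranef_grp(fit$glmer_fit, "person", condVar = TRUE)
  pv <- attr(re, "postVar") %||% attr(re, "condVar")
  data.frame(theta = re[[1]], se = sqrt(pv[1, 1, ]),
             row.names = rownames(re))
}
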
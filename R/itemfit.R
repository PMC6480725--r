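# Item fit testing by subsample comparison: Andersen's likelihood ratio
# test of overall item homogeneity and Wald tests of per-item difficulty
# equality between score groups.

# split persons into two groups by proportion-correct (administered items
# differ between forms, so raw scores are compared as proportions)
.split_persons <- function(x, split = c("mean", "median")) {
  split <- match.arg(split)
  prop <- rowMeans(x, na.rm = TRUE)
  cut <- if (split == "mean") mean(prop) else stats::median(prop)
  g <- ifelse(prop <= cut, 1L, 2L)
  if (length(unique(g)) < 2)
    ansig_domain_error("score split produced a single group")
  g
}

# items estimable (mixed responses) in every person group
.common_estimable <- function(x, g) {
  ok <- rep(TRUE, ncol(x))
  for (gr in unique(g)) {
    xg <- x[g == gr, , drop = FALSE]
    tot <- colSums(xg, na.rm = TRUE)
    cnt <- colSums(!is.na(xg))
    ok <- ok & cnt > 0 & tot > 0 & tot < cnt
  }
  ok
}

#' Andersen likelihood ratio test of item homogeneity
#'
#' Splits the sample into score groups (raw-score mean split by default),
#' calibrates each group separately, and compares the summed conditional
#' log-likelihoods against the joint calibration:
#' `LR = 2 (sum_g logL_g - logL_total)` with `(G - 1)(k - 1)` degrees of
#' freedom for `k` jointly estimable items.  Under the Rasch model the item
#' parameters are the same in every score group.
#'
#' @param responses persons x items matrix of 0/1/NA.
#' @param split `"mean"` or `"median"` raw-score split.
#' @param groups optional explicit person grouping vector overriding the
#'   score split.
#' @return Object of class `ansig_lr`: `statistic`, `df`, `p_value`,
#'   `items_used`, `group_fits`.
#' @export
andersen_lr_test <- function(responses, split = "mean", groups = NULL) {
  x <- .check_responses(responses)
  g <- if (is.null(groups)) .split_persons(x, split) else groups
  if (length(unique(g)) < 2)
    ansig_domain_error("need at least 2 person groups")
  ok <- .common_estimable(x, g)
  if (sum(ok) < 2)
    ansig_domain_error(sprintf(
      "fewer than 2 items estimable in every group (group sizes: %s)",
      paste(table(g), collapse = ", ")))
  x <- x[, ok, drop = FALSE]
  total <- fit_rasch_cml(x)
  fits <- lapply(sort(unique(g)), function(gr)
    fit_rasch_cml(x[g == gr, , drop = FALSE]))
  ll_g <- sum(vapply(fits, `[[`, numeric(1), "cond_loglik"))
  stat <- 2 * (ll_g - total$cond_loglik)
  k <- ncol(x)
  df <- (length(fits) - 1) * (k - 1)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 items_used = colnames(x),
                 group_fits = fits, total_fit = total),
            class = "ansig_lr")
}

#' @export
print.ansig_lr <- function(x, ...) {
  cat(sprintf("Andersen LR test: chi^2(%d) = %.2f, p = %.3f\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Wald tests of per-item difficulty equality between subsamples
#'
#' Calibrates the two score groups separately (both sum-zero identified on
#' the same jointly estimable item set) and tests each item's difficulty
#' difference: `z_i = (d1_i - d2_i) / sqrt(se1_i^2 + se2_i^2)`.
#'
#' @inheritParams andersen_lr_test
#' @param alpha flagging level.
#' @return Object of class `ansig_wald`: data frame `table` with per-item
#'   `z`, `p_value`, `flagged`, plus `skipped` (items not estimable in both
#'   groups).
#' @export
wald_item_tests <- function(responses, split = "mean", alpha = 0.05,
                            groups = NULL) {
  x <- .check_responses(responses)
  g <- if (is.null(groups)) .split_persons(x, split) else groups
  ok <- .common_estimable(x, g)
  skipped <- colnames(x)[!ok]
  if (length(skipped))
    message("items not estimable in both subsamples skipped: ",
            paste(skipped, collapse = ", "))
  x <- x[, ok, drop = FALSE]
  gs <- sort(unique(g))
  if (length(gs) != 2) ansig_domain_error("Wald comparison needs exactly 2 groups")
  f1 <- fit_rasch_cml(x[g == gs[1], , drop = FALSE])
  f2 <- fit_rasch_cml(x[g == gs[2], , drop = FALSE])
  z <- (f1$difficulties - f2$difficulties) /
    sqrt(f1$se^2 + f2$se^2)
  p <- 2 * pnorm(-abs(z))
  tab <- data.frame(item = colnames(x), z = z, p_value = p,
                    flagged = p < alpha, row.names = NULL)
  structure(list(table = tab, skipped = skipped, alpha = alpha,
                 fits = list(f1, f2)),
            class = "ansig_wald")
}

#' @export
print.ansig_wald <- function(x, ...) {
  cat(sprintf("Wald item tests (alpha = %.2f): %d of %d items flagged\n",
              x$alpha, sum(x$table$flagged), nrow(x$table)))
  print(x$table[x$table$flagged, ], row.names = FALSE)
  invisible(x)
}
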
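# Q-matrix construction and structure checks for the cognitive-operator
# design schemes underlying the thirteen number-series item models.

# Five-operator scheme: apprehension of succession (AOS), parallel
# sequences (PS), cluster formation (CF), non-progressive coefficient
# patterns (NPCP), progressive coefficient patterns (PCP).
.ansig_q <- matrix(
  c(1, 0, 0, 0, 0,
    0, 0, 1, 0, 0,
    1, 0, 0, 1, 0,
    0, 1, 0, 0, 0,
    0, 1, 0, 1, 0,
    1, 0, 0, 0, 1,
    1, 0, 0, 0, 1,
    0, 0, 1, 1, 0,
    1, 0, 1, 1, 0,
    0, 1, 0, 0, 1,
    1, 0, 1, 1, 0,
    0, 1, 1, 1, 0,
    0, 1, 1, 1, 0),
  nrow = 13, byrow = TRUE,
  dimnames = list(1:13, c("aos", "ps", "cf", "npcp", "pcp")))

# Four-determinant scheme of Holzman, Pellegrino and Glaser: relation
# detection (RD), discovery of periodicity (DoP), pattern description (PD),
# extrapolation (EX).  Weights 0-2.
.holzman_q <- matrix(
  c(0, 0, 0, 0,
    1, 0, 0, 0,
    0, 0, 1, 1,
    0, 1, 0, 0,
    0, 1, 1, 1,
    0, 0, 2, 2,
    0, 0, 2, 2,
    1, 0, 1, 1,
    1, 0, 1, 1,
    0, 1, 2, 2,
    1, 0, 1, 1,
    1, 1, 1, 1,
    1, 1, 1, 1),
  nrow = 13, byrow = TRUE,
  dimnames = list(1:13, c("rd", "dop", "pd", "ex")))

#' Build a cognitive-operator Q-matrix
#'
#' Returns the design (Q-) matrix whose entry `q_ij` weights cognitive
#' operator `j` in item model `i`.  Two published schemes are built in:
#' `"ansig"`, the five binary operators (AOS, PS, CF, NPCP, PCP) on which
#' the item models were designed, and `"holzman"`, the four classical
#' determinants of number-series solving (relation detection, discovery of
#' periodicity, pattern description, extrapolation) with weights 0-2.
#'
#' @param scheme `"ansig"`, `"holzman"`, or a custom numeric matrix with one
#'   row per item model (rows named by model id).
#' @param model_ids integer vector of item models (subset of 1..13) selecting
#'   the rows, in order.  Defaults to all thirteen.
#' @return An object of class `ansig_qmatrix`: a list with `scheme`,
#'   `model_ids`, `weights` (models x operators integer matrix) and
#'   `operator_names`.
#' @examples
#' build_qmatrix("ansig", 3:13)
#' build_qmatrix("holzman", c(6, 8))
#' @export
build_qmatrix <- function(scheme = "ansig", model_ids = 1:13) {
  if (is.matrix(scheme)) {
    w <- scheme
    label <- "custom"
    if (is.null(rownames(w))) rownames(w) <- seq_len(nrow(w))
    model_ids <- as.integer(rownames(w))
  } else {
    label <- match.arg(scheme, c("ansig", "holzman"))
    full <- switch(label, ansig = .ansig_q, holzman = .holzman_q)
    if (length(model_ids) && (!is.numeric(model_ids) ||
        any(model_ids < 1 | model_ids > 13 | model_ids != round(model_ids))))
      ansig_domain_error("model_ids must be integers in 1..13")
    w <- full[as.character(model_ids), , drop = FALSE]
  }
  validate_qmatrix(w, label)
  structure(list(scheme = label,
                 model_ids = as.integer(model_ids),
                 weights = w,
                 operator_names = colnames(w)),
            class = "ansig_qmatrix")
}

validate_qmatrix <- function(w, label = "custom") {
  if (any(w < 0) || any(w != round(w)))
    ansig_domain_error("Q-matrix entries must be nonnegative integers")
  # sub-matrices of the built-in schemes may legitimately zero out a column
  if (label == "custom" && nrow(w) > 1 && any(colSums(w) == 0))
    warning("Q-matrix has an all-zero operator column: ",
            paste(colnames(w)[colSums(w) == 0], collapse = ", "))
  invisible(w)
}

#' @export
print.ansig_qmatrix <- function(x, ...) {
  cat(sprintf("Q-matrix (%s scheme): %d item models x %d operators\n",
              x$scheme, nrow(x$weights), ncol(x$weights)))
  print(x$weights)
  invisible(x)
}

#' Operator profile of an item model
#'
#' The row of the five-operator Q-matrix for one item model: binary flags
#' for AOS, PS, CF, NPCP and PCP.
#'
#' @param model_id integer in 1..13.
#' @return Named integer vector of length five.
#' @examples
#' operator_profile(9)  # AOS + CF + NPCP
#' @export
operator_profile <- function(model_id) {
  if (length(model_id) != 1 || !is.numeric(model_id) ||
      model_id != round(model_id) || model_id < 1 || model_id > 13)
    ansig_domain_error("model_id must be a single integer in 1..13")
  .ansig_q[model_id, ]
}

#' Expand a Q-matrix to an item property matrix
#'
#' Each concrete item inherits the operator weights of its item model; the
#' resulting long-form matrix is the covariate (item property) matrix used
#' by the LLTM.
#'
#' @param q an [build_qmatrix()] object.
#' @param models integer vector assigning each item to an item model;
#'   names (or `item_ids`) become the item identifiers.
#' @param item_ids optional character vector of item identifiers.
#' @return An object of class `ansig_item_properties`: list with `item_ids`,
#'   `models` and `covariates` (items x operators matrix).
#' @export
expand_item_properties <- function(q, models, item_ids = NULL) {
  stopifnot(inherits(q, "ansig_qmatrix"))
  if (is.null(item_ids)) item_ids <- names(models) %||% paste0("I", seq_along(models))
  missing_models <- setdiff(models, q$model_ids)
  if (length(missing_models)) {
    bad <- item_ids[models %in% missing_models][1]
    ansig_domain_error(sprintf(
      "item '%s' is assigned to model %s which is absent from the Q-matrix",
      bad, missing_models[1]))
  }
  cov <- q$weights[match(models, q$model_ids), , drop = FALSE]
  rownames(cov) <- item_ids
  structure(list(item_ids = item_ids, models = as.integer(models),
                 covariates = cov),
            class = "ansig_item_properties")
}

#' Count distinct operator profiles
#'
#' @param q an [build_qmatrix()] object.
#' @return List with `count` and `profiles` (the unique rows).
#' @examples
#' distinct_profiles(build_qmatrix("ansig", 3:13))$count  # 8
#' @export
distinct_profiles <- function(q) {
  stopifnot(inherits(q, "ansig_qmatrix"))
  if (nrow(q$weights) == 0) ansig_domain_error("Q-matrix has no rows")
  u <- unique(q$weights)
  rownames(u) <- NULL
  list(count = nrow(u), profiles = u)
}

#' Test whether one Q-matrix design is nested in another
#'
#' `q_child` is nested in `q_parent` when every column of the child lies in
#' the column span of the parent (checked by least squares on the exact
#' integer matrices; residual norms below `tol` count as zero).  The
#' four-determinant Holzman scheme is nested in the five-operator scheme:
#' RD = CF, DoP = PS, PD = EX = NPCP + 2 PCP.
#'
#' @param q_parent,q_child [build_qmatrix()] objects over the same item
#'   models in the same order.
#' @param tol numeric tolerance on the residual norm.
#' @return `TRUE` or `FALSE`, with attribute `residuals` (per child column).
#' @export
check_nesting <- function(q_parent, q_child, tol = 1e-8) {
  stopifnot(inherits(q_parent, "ansig_qmatrix"), inherits(q_child, "ansig_qmatrix"))
  if (nrow(q_parent$weights) != nrow(q_child$weights) ||
      !all(q_parent$model_ids == q_child$model_ids))
    ansig_domain_error("Q-matrices must cover the same item models in the same order")
  p <- q_parent$weights
  qr_p <- qr(p)
  Qb <- qr.Q(qr_p)[, seq_len(qr_p$rank), drop = FALSE]
  resid <- apply(q_child$weights, 2, function(y) {
    sqrt(sum((y - Qb %*% crossprod(Qb, y))^2))
  })
  structure(all(resid < tol), residuals = resid)
}
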
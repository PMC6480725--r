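# File formats: item banks and fits as JSON, responses and Q-matrices as
# delimited text.  Round trips are lossless; malformed files fail with the
# offending location.

#' Write / read an item bank (JSON)
#'
#' @param bank an `ansig_bank`.
#' @param path file path.
#' @return `read_item_bank()` returns the `ansig_bank`.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "ansig_bank"))
  payload <- list(
    metadata = bank$metadata,
    items = lapply(bank$items, function(it)
      it[c("model_id", "stem", "n_blanks", "key", "params", "profile", "seed")]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  raw <- jsonlite::read_json(path)
  ids <- names(raw$items)
  if (anyDuplicated(ids))
    ansig_domain_error(sprintf("duplicate item id '%s' in %s",
                               ids[duplicated(ids)][1], path))
  items <- lapply(seq_along(raw$items), function(j) {
    it <- raw$items[[j]]
    for (f in c("model_id", "stem", "n_blanks", "key"))
      if (is.null(it[[f]]))
        ansig_domain_error(sprintf("item %d ('%s') lacks field '%s'",
                                   j, ids[j], f))
    structure(list(model_id = as.integer(it$model_id),
                   stem = as.integer(unlist(it$stem)),
                   n_blanks = as.integer(it$n_blanks),
                   key = as.integer(unlist(it$key)),
                   params = it$params,
                   profile = unlist(it$profile),
                   seed = it$seed),
              class = "ansig_item")
  })
  names(items) <- ids
  structure(list(items = items, metadata = raw$metadata),
            class = "ansig_bank")
}

#' Write / read a response matrix (CSV)
#'
#' Rows are persons, columns items; empty cells mean not administered.
#'
#' @param responses persons x items matrix of 0/1/NA.
#' @param path file path.
#' @export
write_responses <- function(responses, path) {
  x <- .check_responses(responses)
  write.csv(as.data.frame(x), path, na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  d <- read.csv(path, row.names = 1, check.names = FALSE)
  x <- as.matrix(d)
  bad <- which(!(is.na(x) | x %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad))
    ansig_domain_error(sprintf(
      "invalid response value '%s' at person '%s', item '%s' in %s",
      x[bad[1, 1], bad[1, 2]], rownames(x)[bad[1, 1]],
      colnames(x)[bad[1, 2]], path))
  storage.mode(x) <- "integer"
  x
}

#' Write / read a Q-matrix (CSV)
#'
#' First column `model`, remaining columns operator weights.
#'
#' @param q an [build_qmatrix()] object.
#' @param path file path.
#' @export
write_qmatrix <- function(q, path) {
  stopifnot(inherits(q, "ansig_qmatrix"))
  d <- data.frame(model = q$model_ids, q$weights, check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qmatrix
#' @export
read_qmatrix <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (names(d)[1] != "model")
    ansig_domain_error(sprintf("first column of %s must be 'model'", path))
  w <- as.matrix(d[, -1, drop = FALSE])
  if (any(is.na(w)) || any(w < 0) || any(w != round(w))) {
    bad <- which(is.na(w) | w < 0 | w != round(w), arr.ind = TRUE)[1, ]
    ansig_domain_error(sprintf(
      "invalid Q-matrix entry at model %s, operator '%s' in %s",
      d$model[bad[1]], colnames(w)[bad[2]], path))
  }
  rownames(w) <- d$model
  build_qmatrix(w)
}

#' Write / read a calibration or LLTM fit (JSON)
#'
#' Persists the estimates of an `ansig_rasch` or `ansig_lltm` fit (not the
#' underlying model object).
#'
#' @param fit the fit object.
#' @param path file path.
#' @export
write_fit <- function(fit, path) {
  payload <- if (inherits(fit, "ansig_rasch")) {
    list(kind = "rasch_cml",
         difficulties = as.list(fit$difficulties),
         se = as.list(fit$se),
         cond_loglik = fit$cond_loglik,
         excluded_items = fit$excluded_items)
  } else if (inherits(fit, "ansig_lltm")) {
    list(kind = fit$kind,
         intercept = fit$intercept,
         eta = as.list(fit$eta),
         se_eta = as.list(fit$se_eta),
         person_var = fit$person_var,
         item_resid_var = fit$item_resid_var,
         marg_loglik = fit$marg_loglik,
         n_params = fit$n_params,
         n_obs = fit$n_obs,
         difficulties = as.list(fit$fitted_difficulties))
  } else ansig_domain_error("unsupported fit object")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  raw <- jsonlite::read_json(path)
  raw$difficulties <- unlist(raw$difficulties)
  if (!is.null(raw$eta)) raw$eta <- unlist(raw$eta)
  if (!is.null(raw$se)) raw$se <- unlist(raw$se)
  if (!is.null(raw$se_eta)) raw$se_eta <- unlist(raw$se_eta)
  raw
}
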
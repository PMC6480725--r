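# Respondent simulation under the Rasch model (optionally with an item
# residual) and multi-form test designs with anchor items.

#' Multi-form test design
#'
#' @param forms named list of character vectors of item ids; anchors are
#'   the items shared between forms.
#' @return Object of class `ansig_design` with `forms`, `anchors` and
#'   `item_ids`.
#' @export
form_design <- function(forms) {
  if (!length(forms) || any(!lengths(forms)))
    ansig_domain_error("every form must contain at least one item")
  if (is.null(names(forms))) names(forms) <- LETTERS[seq_along(forms)]
  anchors <- if (length(forms) > 1) Reduce(intersect, forms) else forms[[1]]
  if (length(forms) > 1 && !length(anchors))
    warning("forms share no anchor items; their metrics are not linkable")
  structure(list(forms = forms,
                 anchors = anchors,
                 item_ids = unique(unlist(forms))),
            class = "ansig_design")
}

#' @export
print.ansig_design <- function(x, ...) {
  cat(sprintf("test design: %d form(s) [%s], %d items, %d anchors\n",
              length(x$forms),
              paste(sprintf("%s:%d", names(x$forms), lengths(x$forms)),
                    collapse = ", "),
              length(x$item_ids), length(x$anchors)))
  invisible(x)
}

# model membership of the two-form calibration layout: models 3 and 8
# appear in both forms as anchors
.form_models <- list(A = c(3, 4, 6, 8, 10, 12),
                     B = c(3, 5, 7, 8, 9, 11, 13))

#' Assemble test forms from an item bank
#'
#' The `"study"` preset reproduces the two-form calibration layout: Form A
#' holds the items of models 3, 4, 6, 8, 10 and 12, Form B those of models
#' 3, 5, 7, 8, 9, 11 and 13; the items of models 3 and 8 appear in both
#' forms as anchors.  On a bank of five items per model this gives
#' |A| = 30, |B| = 35 with 10 anchors.  `"single"` puts every item in one
#' form.  A named list of model-id vectors defines a custom split.
#'
#' @param models named integer vector mapping item id to item model (e.g.
#'   [bank_models()]).
#' @param spec `"study"`, `"single"`, or a named list of model ids per
#'   form.
#' @return An [form_design()] object.
#' @export
assemble_forms <- function(models, spec = "study") {
  layout <- if (is.list(spec)) spec
            else switch(spec,
                        study = .form_models,
                        single = list(A = unique(models)),
                        ansig_domain_error(sprintf("unknown form spec '%s'", spec)))
  forms <- lapply(layout, function(ms) names(models)[models %in% ms])
  empty <- names(forms)[!lengths(forms)]
  if (length(empty))
    ansig_domain_error(sprintf(
      "no bank items available for form(s): %s", paste(empty, collapse = ", ")))
  form_design(forms)
}

#' Assemble a form by difficulty bins
#'
#' Draws `per_bin` items uniformly at random (without replacement) from
#' each difficulty bin of width `bin_width` across `range`; the classical
#' recipe (bins of 0.5 logits from -2 to 2, three items each) assembles a
#' 24-item form with a flat information profile.
#'
#' @param difficulties named numeric vector of item difficulties.
#' @param bin_width bin width in logits.
#' @param range difficulty interval covered.
#' @param per_bin items drawn per bin; under-filled bins are taken whole
#'   with a warning.
#' @param seed integer seed.
#' @return An [form_design()] object with one form `C`.
#' @export
assemble_form_by_bins <- function(difficulties, bin_width = 0.5,
                                  range = c(-2, 2), per_bin = 3, seed = 1) {
  if (!length(difficulties)) ansig_domain_error("empty difficulty list")
  if (is.null(names(difficulties)))
    names(difficulties) <- paste0("I", seq_along(difficulties))
  breaks <- seq(range[1], range[2], by = bin_width)
  pick <- withr::with_seed(seed, {
    unlist(lapply(seq_len(length(breaks) - 1), function(b) {
      ids <- names(difficulties)[difficulties >= breaks[b] &
                                 difficulties < breaks[b + 1]]
      if (length(ids) < per_bin) {
        warning(sprintf("bin [%.1f, %.1f) holds only %d item(s)",
                        breaks[b], breaks[b + 1], length(ids)))
        ids
      } else sample(ids, per_bin)
    }))
  })
  form_design(list(C = pick))
}

#' Simulation configuration
#'
#' @param n_persons named integer vector: persons per form (the reference
#'   design assigns 396 to Form A and 174 to Form B).
#' @param difficulties named numeric vector covering every designed item.
#' @param theta_mean,theta_sd normal ability distribution (standard normal
#'   by default).
#' @param item_resid_sd standard deviation of a per-item difficulty
#'   residual drawn once per item (0 = pure Rasch).
#' @param seed integer seed.
#' @export
simulation_config <- function(n_persons, difficulties, theta_mean = 0,
                              theta_sd = 1, item_resid_sd = 0, seed = 1) {
  if (theta_sd <= 0) ansig_domain_error("theta_sd must be positive")
  if (item_resid_sd < 0) ansig_domain_error("item_resid_sd must be >= 0")
  structure(list(n_persons = n_persons, difficulties = difficulties,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 item_resid_sd = item_resid_sd, seed = seed),
            class = "ansig_simconfig")
}

#' Simulate missing-by-design dichotomous responses
#'
#' Draws person abilities from a normal distribution, optionally perturbs
#' each item's difficulty once by a normal residual, and generates
#' Bernoulli responses under the Rasch probability
#' `P(x = 1) = plogis(theta - delta)`.  Cells outside a person's form are
#' `NA` (not administered).
#'
#' @param config an [simulation_config()] object.
#' @param design an [form_design()] object; forms are matched to
#'   `config$n_persons` by name (a single unnamed count is spread over
#'   forms by independent uniform assignment).
#' @return Persons x items 0/1/NA matrix with attributes `theta` (true
#'   abilities), `form` (per-person form) and `difficulties_used` (after
#'   any residual).
#' @export
simulate_responses <- function(config, design) {
  stopifnot(inherits(config, "ansig_simconfig"), inherits(design, "ansig_design"))
  missing_items <- setdiff(design$item_ids, names(config$difficulties))
  if (length(missing_items))
    ansig_domain_error(sprintf("no difficulty supplied for item(s): %s",
                               paste(missing_items, collapse = ", ")))
  withr::with_seed(config$seed, {
    nn <- config$n_persons
    if (is.null(names(nn)) && length(nn) == 1 && length(design$forms) > 1) {
      form_of <- sample(names(design$forms), nn, replace = TRUE)
    } else {
      if (is.null(names(nn))) names(nn) <- names(design$forms)
      form_of <- rep(names(nn), nn)
    }
    n <- length(form_of)
    theta <- rnorm(n, config$theta_mean, config$theta_sd)
    items <- design$item_ids
    delta <- config$difficulties[items]
    if (config$item_resid_sd > 0)
      delta <- delta + rnorm(length(items), 0, config$item_resid_sd)
    x <- matrix(NA_integer_, n, length(items),
                dimnames = list(sprintf("P%04d", seq_len(n)), items))
    for (f in names(design$forms)) {
      rows <- which(form_of == f)
      if (!length(rows)) next
      cols <- match(design$forms[[f]], items)
      p <- plogis(outer(theta[rows], delta[cols], "-"))
      x[rows, cols] <- rbinom(length(p), 1, p)
    }
    attr(x, "theta") <- theta
    attr(x, "form") <- form_of
    attr(x, "difficulties_used") <- delta
    x
  })
}
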
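# Item generation: each of the thirteen item models is a template rule; a
# concrete item is produced by drawing the numeric substitution set
# (starting values, coefficients, group anchors) for that rule.

#' Generation configuration
#'
#' @param magnitude_cap largest admissible absolute element value.  Items
#'   exceeding the cap are resampled (or rejected when fully specified).
#' @param max_retry resampling budget before generation fails.
#' @param m12_layout `"len9"` for the S1 S2 S2 layout of length 9 with both
#'   missing elements in the paired subsequence, or `"len10"` for the
#'   length-10 layout whose final blank belongs to the backbone
#'   subsequence.  Both are in circulation; `"len9"` is the default.
#' @return A list of class `ansig_config`.
#' @export
ansig_config <- function(magnitude_cap = 10000, max_retry = 50,
                         m12_layout = c("len9", "len10")) {
  structure(list(magnitude_cap = magnitude_cap,
                 max_retry = max_retry,
                 m12_layout = match.arg(m12_layout)),
            class = "ansig_config")
}

# parameter fill helper: use the user's value when given, else sample
.p <- function(params, name, sampler) {
  if (!is.null(params[[name]])) params[[name]] else sampler()
}

.chain_values <- function(start, op, coef, len) {
  switch(op,
    "+" = start + coef * (0:(len - 1)),
    "-" = rev(start + coef * (0:(len - 1))),
    "*" = start * coef^(0:(len - 1)),
    "/" = rev(start * coef^(0:(len - 1))),
    ansig_domain_error(sprintf("unknown operator '%s'", op)))
}

# Builders return list(full, n_blanks, params); guards raise
# ansig_invalid conditions which the retry loop catches.
.invalid <- function(msg) ansig_stop(msg, "ansig_invalid")

.gen_builders <- list(
  `1` = function(p, cfg) {
    start <- .p(p, "start", function() sample(0:100, 1))
    constant <- .p(p, "constant", function() sample(c(1, 10, 100), 1))
    len <- .p(p, "length", function() 5L)
    if (!constant %in% c(1, 10, 100)) .invalid("model 1 constant must be 1, 10 or 100")
    list(full = start + constant * (0:(len - 1)), n_blanks = 1L,
         params = list(start = start, constant = constant, length = len))
  },
  `2` = function(p, cfg) {
    values <- .p(p, "values", function() sample(1:99, 2))
    g <- .p(p, "group_size", function() 3L)
    if (length(values) != 2 || values[1] == values[2])
      .invalid("model 2 needs two distinct group values")
    list(full = rep(values, each = g), n_blanks = 1L,
         params = list(values = values, group_size = g))
  },
  `3` = function(p, cfg) {
    op <- .p(p, "op", function() sample(c("+", "-", "*", "/"), 1))
    start <- .p(p, "start", function() sample(1:10, 1))
    coef <- .p(p, "coef", function() sample(2:9, 1))
    len <- .p(p, "length", function() 6L)
    list(full = .chain_values(start, op, coef, len), n_blanks = 1L,
         params = list(start = start, op = op, coef = coef, length = len))
  },
  `4` = function(p, cfg) {
    starts <- .p(p, "starts", function() sample(1:20, 2))
    constants <- .p(p, "constants", function() sample(c(1, 10, 100), 2, replace = TRUE))
    a <- starts[1] + constants[1] * (0:3)
    b <- starts[2] + constants[2] * (0:3)
    if (identical(a, b)) .invalid("model 4 subsequences must differ")
    full <- integer(8)
    full[seq(1, 8, 2)] <- a
    full[seq(2, 8, 2)] <- b
    list(full = full, n_blanks = 2L,
         params = list(starts = starts, constants = constants))
  },
  `5` = function(p, cfg) {
    sub1 <- .p(p, "sub1", function()
      list(start = sample(1:10, 1), op = sample(c("+", "*"), 1),
           coef = sample(2:3, 1)))
    sub2 <- .p(p, "sub2", function()
      list(start = sample(1:10, 1), op = sample(c("+", "*"), 1),
           coef = sample(2:3, 1)))
    a <- .chain_values(sub1$start, sub1$op, sub1$coef, 5)
    b <- .chain_values(sub2$start, sub2$op, sub2$coef, 4)
    if (sub1$op == "+" && sub2$op == "+")
      .invalid("model 5 needs at least one multiplicative subsequence")
    if (identical(a[1:4], b)) .invalid("model 5 subsequences must differ")
    full <- integer(9)
    full[seq(1, 9, 2)] <- a
    full[seq(2, 8, 2)] <- b
    list(full = full, n_blanks = 2L, params = list(sub1 = sub1, sub2 = sub2))
  },
  `6` = function(p, cfg) {
    start <- .p(p, "start", function() sample(1:10, 1))
    d0 <- .p(p, "d0", function() sample(1:5, 1))
    incr <- .p(p, "incr", function() sample(1:3, 1))
    len <- .p(p, "length", function() 6L)
    d <- d0 + incr * (0:(len - 2))
    list(full = start + c(0, cumsum(d)), n_blanks = 1L,
         params = list(start = start, d0 = d0, incr = incr, length = len))
  },
  `7` = function(p, cfg) {
    start <- .p(p, "start", function() sample(1:10, 1))
    add <- .p(p, "add", function() sample(1:5, 1))
    mult <- .p(p, "mult", function() sample(2:3, 1))
    len <- .p(p, "length", function() 6L)
    full <- integer(len)
    full[1] <- start
    for (k in 2:len) full[k] <- (full[k - 1] + add) * mult
    list(full = full, n_blanks = 1L,
         params = list(start = start, add = add, mult = mult, length = len))
  },
  `8` = function(p, cfg) {
    g <- .p(p, "group_size", function() 2L)
    n_groups <- .p(p, "n_groups", function() 3L)
    diff <- .p(p, "diff", function() sample(1:9, 1))
    anchors <- .p(p, "anchors", function() sample(1:300, n_groups))
    if (length(unique(anchors)) != n_groups)
      .invalid("model 8 group anchors must be distinct")
    full <- as.integer(t(outer(anchors, diff * (0:(g - 1)), "+")))
    list(full = full, n_blanks = 1L,
         params = list(anchors = anchors, diff = diff, group_size = g,
                       n_groups = n_groups))
  },
  `9` = function(p, cfg) {
    seeds <- .p(p, "seeds", function() sample(1:9, 2, replace = TRUE))
    len <- .p(p, "length", function() 7L)
    full <- integer(len)
    full[1:2] <- seeds
    for (k in 3:len) full[k] <- full[k - 1] + full[k - 2]
    list(full = full, n_blanks = 1L, params = list(seeds = seeds, length = len))
  },
  `10` = function(p, cfg) {
    prog <- .p(p, "prog", function()
      list(start = sample(1:10, 1), d0 = sample(1:5, 1), incr = sample(1:3, 1)))
    lin <- .p(p, "lin", function()
      list(start = sample(1:30, 1), constant = sample(1:9, 1)))
    d <- prog$d0 + prog$incr * (0:4)
    a <- prog$start + c(0, cumsum(d))        # length 6
    b <- lin$start + lin$constant * (0:4)    # length 5
    full <- integer(11)
    full[seq(1, 11, 2)] <- a
    full[seq(2, 10, 2)] <- b
    list(full = full, n_blanks = 2L, params = list(prog = prog, lin = lin))
  },
  `11` = function(p, cfg) {
    start <- .p(p, "start", function() sample(1:9, 1))
    diff <- .p(p, "diff", function() sample(2:9, 1))
    mult <- .p(p, "mult", function() 2L)
    n_pairs <- .p(p, "n_pairs", function() 4L)
    full <- integer(2 * n_pairs)
    full[1] <- start
    for (k in 2:length(full))
      full[k] <- if (k %% 2 == 0) full[k - 1] + diff else full[k - 1] * mult
    list(full = full, n_blanks = 2L,
         params = list(start = start, diff = diff, mult = mult, n_pairs = n_pairs))
  },
  `12` = function(p, cfg) {
    s1_start <- .p(p, "s1_start", function() sample(1:9, 1))
    s1_const <- .p(p, "s1_const", function() sample(1:3, 1))
    s2_const <- .p(p, "s2_const", function() sample(5:40, 1))
    s2_start <- .p(p, "s2_start", function() s2_const)
    layout <- .p(p, "layout", function() cfg$m12_layout)
    total <- if (layout == "len9") 9L else 10L
    idx <- .s1s2_split(total)
    s1 <- s1_start + s1_const * (0:(length(idx$s1) - 1))
    s2 <- s2_start + s2_const * (0:(length(idx$s2) - 1))
    full <- integer(total)
    full[idx$s1] <- s1
    full[idx$s2] <- s2
    list(full = full, n_blanks = 2L,
         params = list(s1_start = s1_start, s1_const = s1_const,
                       s2_start = s2_start, s2_const = s2_const,
                       layout = layout))
  },
  `13` = function(p, cfg) {
    s1_start <- .p(p, "s1_start", function() sample(1:9, 1))
    s1_const <- .p(p, "s1_const", function() sample(1:5, 1))
    pair_diff <- .p(p, "pair_diff", function() sample(1:9, 1))
    anchors <- .p(p, "anchors", function() sample(1:300, 3))
    if (length(unique(anchors)) != 3)
      .invalid("model 13 pair anchors must be distinct")
    total <- 10L
    idx <- .s1s2_split(total)
    s1 <- s1_start + s1_const * (0:3)
    s2 <- as.integer(t(cbind(anchors, anchors + pair_diff)))
    full <- integer(total)
    full[idx$s1] <- s1
    full[idx$s2] <- s2
    list(full = full, n_blanks = 2L,
         params = list(s1_start = s1_start, s1_const = s1_const,
                       pair_diff = pair_diff, anchors = anchors))
  })

#' Generate one number-series item
#'
#' Draws any unspecified generation parameters for the requested item
#' model, builds the full sequence under the model's rule, and returns the
#' item with the final `n_blanks` elements withheld as the key.  Items
#' whose elements exceed the magnitude cap (or violate a degeneracy guard,
#' e.g. identical parallel subsequences) are resampled up to the retry
#' budget; fully specified invalid parameters fail immediately.
#'
#' @param model_id integer in 1..13.
#' @param params named list of generation parameters; missing entries are
#'   sampled.  See the builders' documentation for per-model names.
#' @param seed integer seed making the draw reproducible; the session RNG
#'   state is left untouched.
#' @param config an [ansig_config()] object.
#' @return Object of class `ansig_item`: list with `model_id`, `stem`,
#'   `n_blanks`, `key`, `params`, `profile` and `seed`.
#' @examples
#' generate_item(3, list(start = 1, op = "*", coef = 2), seed = 1)
#' @export
generate_item <- function(model_id, params = list(), seed = NULL,
                          config = ansig_config()) {
  if (length(model_id) != 1 || !model_id %in% 1:13)
    ansig_domain_error("model_id must be a single integer in 1..13")
  builder <- .gen_builders[[as.character(model_id)]]
  gen <- function() {
    for (attempt in seq_len(config$max_retry)) {
      cand <- tryCatch(builder(params, config),
                       ansig_invalid = function(e) e)
      if (inherits(cand, "condition")) {
        if (.fully_specified(params, model_id)) stop(cand)
        next
      }
      if (all(abs(cand$full) <= config$magnitude_cap)) {
        return(structure(list(model_id = as.integer(model_id),
                              stem = as.integer(head(cand$full, -cand$n_blanks)),
                              n_blanks = cand$n_blanks,
                              key = as.integer(tail(cand$full, cand$n_blanks)),
                              params = cand$params,
                              profile = operator_profile(model_id),
                              seed = seed),
                         class = "ansig_item"))
      }
      if (.fully_specified(params, model_id))
        ansig_domain_error(sprintf(
          "model %d item exceeds the magnitude cap %d with the given parameters",
          model_id, config$magnitude_cap))
    }
    ansig_stop(sprintf(
      "model %d: no admissible item within %d resampling attempts",
      model_id, config$max_retry), "ansig_retry_exhausted")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# are all sampled parameters pinned down by the user?
.fully_specified <- function(params, model_id) {
  needed <- switch(as.character(model_id),
    `1` = c("start", "constant"), `2` = c("values"),
    `3` = c("start", "op", "coef"), `4` = c("starts", "constants"),
    `5` = c("sub1", "sub2"), `6` = c("start", "d0", "incr"),
    `7` = c("start", "add", "mult"), `8` = c("anchors", "diff"),
    `9` = c("seeds"), `10` = c("prog", "lin"),
    `11` = c("start", "diff"), `12` = c("s1_start", "s1_const", "s2_const"),
    `13` = c("s1_start", "s1_const", "pair_diff", "anchors"))
  all(needed %in% names(params))
}

#' @export
print.ansig_item <- function(x, ...) {
  cat(sprintf("model %d item: %s %s\n", x$model_id,
              paste(x$stem, collapse = " "),
              paste(sprintf("(%d)", x$key), collapse = " ")))
  invisible(x)
}

#' Sample a reproducible item bank
#'
#' Generates `n_per_model` items for each requested item model with
#' pairwise-distinct stems within a model.  Each item is generated from its
#' own derived seed (`seed + 1009 * counter`, counter running over bank
#' slots), so a bank is reproducible item by item.
#'
#' @param model_ids item models to draw from.
#' @param n_per_model items per model.
#' @param seed root integer seed.
#' @param config an [ansig_config()] object.
#' @return Object of class `ansig_bank`: list with `items` (named list of
#'   `ansig_item`) and `metadata`.
#' @examples
#' bank <- sample_item_bank(3:13, 5, seed = 42)
#' length(bank$items)  # 55
#' @export
sample_item_bank <- function(model_ids, n_per_model, seed = 1,
                             config = ansig_config()) {
  if (n_per_model < 1) ansig_domain_error("n_per_model must be >= 1")
  items <- list()
  counter <- 0L
  for (m in model_ids) {
    stems <- character(0)
    got <- 0L
    tries <- 0L
    while (got < n_per_model) {
      counter <- counter + 1L
      tries <- tries + 1L
      if (tries > config$max_retry * n_per_model)
        ansig_stop(sprintf(
          "could not draw %d distinct items for model %d within the retry budget",
          n_per_model, m), "ansig_retry_exhausted")
      item_seed <- (seed + 1009 * counter) %% 2147483647
      it <- generate_item(m, seed = item_seed, config = config)
      sig <- paste(it$stem, collapse = ",")
      if (sig %in% stems) next
      stems <- c(stems, sig)
      got <- got + 1L
      items[[sprintf("m%02d_%02d", m, got)]] <- it
    }
  }
  structure(list(items = items,
                 metadata = list(seed = seed,
                                 model_ids = as.integer(model_ids),
                                 n_per_model = as.integer(n_per_model),
                                 magnitude_cap = config$magnitude_cap,
                                 generator = paste0("ansig ", as.character(
                                   utils::packageVersion("ansig"))))),
            class = "ansig_bank")
}

#' @export
print.ansig_bank <- function(x, ...) {
  models <- vapply(x$items, `[[`, integer(1), "model_id")
  cat(sprintf("item bank: %d items over models %s (seed %s)\n",
              length(x$items),
              paste(sort(unique(models)), collapse = ", "),
              x$metadata$seed))
  invisible(x)
}

#' Model membership of a bank
#' @param bank an `ansig_bank`.
#' @return Named integer vector mapping item id to item model.
#' @export
bank_models <- function(bank) {
  vapply(bank$items, `[[`, integer(1), "model_id")
}
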
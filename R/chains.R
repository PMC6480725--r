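# Internal single-chain rule inference.  A "chain" is one maximal
# subsequence of a number series that evolves under its own rule; the
# interleaved and patterned item models decompose into chains before
# inference.  Rules are ordered from lowest to highest order; the solver
# prefers the lowest-order rule consistent with every element and reports a
# tie at the same order as an ambiguity.

.chain_rule_order <- c(arith = 1, geom = 2, prog_arith = 3, prog_geom = 4,
                       composite = 5, twoback = 6)

# Each fitter returns NULL when the rule does not fit all elements, else
# list(rule, params, step) where step(x) returns the chain extended by one.
.fit_arith <- function(x) {
  if (length(x) < 2) return(NULL)
  d <- x[2] - x[1]
  if (!all(diff(x) == d)) return(NULL)
  list(rule = "arith", params = list(constant = d),
       step = function(x) c(x, x[length(x)] + d))
}

.fit_geom <- function(x) {
  if (length(x) < 2 || any(x == 0)) return(NULL)
  r <- x[2] / x[1]
  if (r == 1) return(NULL)                       # constant: arith handles it
  if (!all(abs(x[-1] - x[-length(x)] * r) < 1e-9)) return(NULL)
  list(rule = "geom", params = list(ratio = r),
       step = function(x) c(x, round(x[length(x)] * r)))
}

.fit_prog_arith <- function(x) {
  if (length(x) < 4) return(NULL)
  d <- diff(x)
  incr <- d[2] - d[1]
  if (incr == 0 || !all(diff(d) == incr)) return(NULL)
  list(rule = "prog_arith", params = list(d0 = d[1], increment = incr),
       step = function(x) {
         dd <- diff(x)
         c(x, x[length(x)] + dd[length(dd)] + incr)
       })
}

.fit_prog_geom <- function(x) {
  if (length(x) < 4) return(NULL)
  d <- diff(x)
  if (any(d == 0)) return(NULL)
  r <- d[2] / d[1]
  if (r == 1 || !all(abs(d[-1] - d[-length(d)] * r) < 1e-9)) return(NULL)
  list(rule = "prog_geom", params = list(d0 = d[1], ratio = r),
       step = function(x) {
         dd <- diff(x)
         c(x, x[length(x)] + round(dd[length(dd)] * r))
       })
}

.fit_composite <- function(x) {
  # x[k+1] = (x[k] + a) * b, the add-then-multiply step
  if (length(x) < 4) return(NULL)
  if (x[2] == x[1]) return(NULL)
  b <- (x[3] - x[2]) / (x[2] - x[1])
  if (!is.finite(b) || b == 0 || b == 1) return(NULL)
  a <- x[2] / b - x[1]
  if (abs(a - round(a)) > 1e-9 || abs(b - round(b)) > 1e-9) return(NULL)
  a <- round(a); b <- round(b)
  if (!all(x[-1] == (x[-length(x)] + a) * b)) return(NULL)
  list(rule = "composite", params = list(add = a, mult = b),
       step = function(x) c(x, (x[length(x)] + a) * b))
}

.fit_twoback <- function(x) {
  if (length(x) < 3) return(NULL)
  n <- length(x)
  if (!all(x[3:n] == x[2:(n - 1)] + x[1:(n - 2)])) return(NULL)
  list(rule = "twoback", params = list(),
       step = function(x) c(x, x[length(x)] + x[length(x) - 1]))
}

.chain_fitters <- list(arith = .fit_arith, geom = .fit_geom,
                       prog_arith = .fit_prog_arith, prog_geom = .fit_prog_geom,
                       composite = .fit_composite, twoback = .fit_twoback)

# Infer the rule governing chain x, restricted to the rule families a model
# admits.  Lowest-order fit wins; two fits of equal order that extrapolate
# differently raise an ambiguity error.
infer_chain <- function(x, rules = names(.chain_fitters)) {
  if (length(x) < 2)
    ansig_unsolvable_error("chain too short for rule inference")
  fits <- list()
  for (r in rules) {
    f <- .chain_fitters[[r]](x)
    if (!is.null(f)) fits[[r]] <- f
  }
  if (!length(fits))
    ansig_unsolvable_error(sprintf(
      "chain %s fits no admissible rule (tried: %s)",
      paste(x, collapse = " "), paste(rules, collapse = ", ")))
  ord <- .chain_rule_order[names(fits)]
  best <- fits[ord == min(ord)]
  if (length(best) > 1) {
    nxt <- vapply(best, function(f) f$step(x)[length(x) + 1], numeric(1))
    if (length(unique(nxt)) > 1)
      ansig_ambiguity_error(sprintf(
        "chain %s admits multiple rules of equal order: %s",
        paste(x, collapse = " "), paste(names(best), collapse = ", ")))
  }
  best[[1]]
}

# Extend chain x by n_extra elements under its inferred rule.
extend_chain <- function(x, n_extra, rules = names(.chain_fitters)) {
  fit <- infer_chain(x, rules)
  for (i in seq_len(n_extra)) x <- fit$step(x)
  x
}
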
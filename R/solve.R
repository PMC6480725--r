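# Rule-inference solvers: given an item model, a stem and the number of
# missing elements, reconstruct the generating rule from the stem alone and
# extrapolate the key.  Missing elements always occupy the final positions
# of the displayed sequence.

# Interleaved layouts (models 4, 5, 10): odd positions form one chain, even
# positions the other, A1 B1 A2 B2 ...
.solve_interleaved <- function(stem, n_blanks, rules_odd, rules_even) {
  total <- length(stem) + n_blanks
  pos <- seq_len(total)
  odd_idx <- pos[pos %% 2 == 1]
  even_idx <- pos[pos %% 2 == 0]
  a <- stem[odd_idx[odd_idx <= length(stem)]]
  b <- stem[even_idx[even_idx <= length(stem)]]
  n_a <- length(odd_idx)
  n_b <- length(even_idx)
  a_full <- if (n_a > length(a)) extend_chain(a, n_a - length(a), rules_odd) else a
  b_full <- if (n_b > length(b)) extend_chain(b, n_b - length(b), rules_even) else b
  full <- integer(total)
  full[odd_idx] <- a_full
  full[even_idx] <- b_full
  full[(length(stem) + 1):total]
}

# Pattern S1 S2 S2 (models 12, 13): position p belongs to the backbone
# subsequence S1 when p mod 3 == 1, otherwise to the paired subsequence.
.s1s2_split <- function(total) {
  pos <- seq_len(total)
  list(s1 = pos[pos %% 3 == 1], s2 = pos[pos %% 3 != 1])
}

.solve_pattern12 <- function(stem, n_blanks) {
  total <- length(stem) + n_blanks
  if (!total %in% c(9, 10))
    ansig_unsolvable_error("model 12 expects a total length of 9 or 10")
  idx <- .s1s2_split(total)
  s1 <- stem[idx$s1[idx$s1 <= length(stem)]]
  s2 <- stem[idx$s2[idx$s2 <= length(stem)]]
  s1_full <- if (length(idx$s1) > length(s1))
    extend_chain(s1, length(idx$s1) - length(s1), "arith") else s1
  s2_full <- if (length(idx$s2) > length(s2))
    extend_chain(s2, length(idx$s2) - length(s2), c("arith", "geom")) else s2
  full <- integer(total)
  full[idx$s1] <- s1_full
  full[idx$s2] <- s2_full
  full[(length(stem) + 1):total]
}

.solve_pattern13 <- function(stem, n_blanks) {
  total <- length(stem) + n_blanks
  idx <- .s1s2_split(total)
  s1 <- stem[idx$s1[idx$s1 <= length(stem)]]
  s2 <- stem[idx$s2[idx$s2 <= length(stem)]]
  n_s2 <- length(idx$s2)
  if (n_s2 %% 2 != 0)
    ansig_unsolvable_error("model 13 pairs are incomplete in this layout")
  # within-pair difference is shared across pairs; pairs are otherwise free
  d <- NULL
  for (p in seq_len(length(s2) %/% 2)) {
    dp <- s2[2 * p] - s2[2 * p - 1]
    if (is.null(d)) d <- dp
    else if (dp != d)
      ansig_unsolvable_error("model 13 pairs do not share a common difference")
  }
  s2_full <- s2
  while (length(s2_full) < n_s2) {
    k <- length(s2_full)
    if (k %% 2 == 1) s2_full <- c(s2_full, s2_full[k] + d)
    else ansig_unsolvable_error("cannot extrapolate an unrelated pair anchor")
  }
  s1_full <- if (length(idx$s1) > length(s1))
    extend_chain(s1, length(idx$s1) - length(s1), "arith") else s1
  full <- integer(total)
  full[idx$s1] <- s1_full
  full[idx$s2] <- s2_full
  full[(length(stem) + 1):total]
}

.solve_clusters <- function(stem, n_blanks) {
  total <- length(stem) + n_blanks
  if (total %% 2 != 0)
    ansig_unsolvable_error("model 2 expects two equal-sized groups")
  g <- total %/% 2
  v1 <- stem[1]
  if (!all(stem[seq_len(g)] == v1))
    ansig_unsolvable_error("first group is not homogeneous")
  rest <- stem[(g + 1):length(stem)]
  if (!length(rest)) ansig_unsolvable_error("second group entirely missing")
  v2 <- rest[1]
  if (!all(rest == v2) || v2 == v1)
    ansig_unsolvable_error("second group is not a homogeneous distinct cluster")
  rep(v2, n_blanks)
}

.solve_groups8 <- function(stem, n_blanks) {
  total <- length(stem) + n_blanks
  for (g in c(2, 3)) {
    if (total %% g != 0) next
    full_try <- tryCatch({
      groups <- split(seq_len(total), rep(seq_len(total %/% g), each = g))
      d <- NULL
      ok <- TRUE
      for (grp in groups) {
        known <- grp[grp <= length(stem)]
        if (length(known) >= 2) {
          dd <- unique(diff(stem[known]))
          if (length(dd) != 1) { ok <- FALSE; break }
          if (is.null(d)) d <- dd else if (dd != d) { ok <- FALSE; break }
        }
      }
      if (!ok || is.null(d)) NULL
      else {
        full <- c(stem, integer(n_blanks))
        for (p in (length(stem) + 1):total) {
          if ((p - 1) %% g == 0)
            ansig_unsolvable_error("cannot extrapolate an unrelated group anchor")
          full[p] <- full[p - 1] + d
        }
        full[(length(stem) + 1):total]
      }
    }, ansig_unsolvable_error = function(e) NULL)
    if (!is.null(full_try)) return(full_try)
  }
  ansig_unsolvable_error(sprintf(
    "stem %s fits no pair/triad grouping with a common within-group difference",
    paste(stem, collapse = " ")))
}

.solve_pairs11 <- function(stem, n_blanks) {
  total <- length(stem) + n_blanks
  if (length(stem) < 3)
    ansig_unsolvable_error("model 11 needs at least three elements")
  d <- stem[2] - stem[1]
  m <- stem[3] / stem[2]
  if (abs(m - round(m)) > 1e-9 || round(m) < 2)
    ansig_unsolvable_error("model 11 multiplier must be an integer >= 2")
  m <- round(m)
  full <- c(stem, integer(n_blanks))
  for (p in seq(2, total)) {
    expected <- if (p %% 2 == 0) full[p - 1] + d else full[p - 1] * m
    if (p <= length(stem)) {
      if (full[p] != expected)
        ansig_unsolvable_error("stem violates the alternating (+d, x m) pattern")
    } else full[p] <- expected
  }
  full[(length(stem) + 1):total]
}

#' Solve a number-series item by rule inference
#'
#' Reconstructs the generating rule of `stem` under the rule family of the
#' given item model and extrapolates the missing elements.  The inference
#' prefers the lowest-order rule consistent with every stem element
#' (constant difference, then constant ratio, then progressive difference,
#' then composite steps); genuinely tied rules raise an ambiguity error.
#'
#' @param model_id integer in 1..13.
#' @param stem integer vector, the displayed elements (missing elements are
#'   always the final positions of the full sequence).
#' @param n_blanks number of missing elements, 1 or 2.
#' @return Integer vector of length `n_blanks`, the key in presentation
#'   order.
#' @examples
#' solve_item(3, c(1, 2, 4, 8, 16), 1)          # 32
#' solve_item(7, c(3, 10, 24, 52, 108), 1)      # 220
#' solve_item(11, c(1, 7, 14, 20, 40, 46), 2)   # 92 98
#' @export
solve_item <- function(model_id, stem, n_blanks = 1) {
  if (length(model_id) != 1 || !model_id %in% 1:13)
    ansig_domain_error("model_id must be a single integer in 1..13")
  if (!n_blanks %in% c(1, 2))
    ansig_domain_error("n_blanks must be 1 or 2")
  stem <- as.integer(stem)
  key <- switch(as.character(model_id),
    "1" = tail(extend_chain(stem, n_blanks, "arith"), n_blanks),
    "2" = .solve_clusters(stem, n_blanks),
    "3" = tail(extend_chain(stem, n_blanks, c("arith", "geom")), n_blanks),
    "4" = .solve_interleaved(stem, n_blanks, c("arith", "geom"), c("arith", "geom")),
    "5" = .solve_interleaved(stem, n_blanks, c("arith", "geom"), c("arith", "geom")),
    "6" = tail(extend_chain(stem, n_blanks, c("prog_arith", "prog_geom")), n_blanks),
    "7" = tail(extend_chain(stem, n_blanks, "composite"), n_blanks),
    "8" = .solve_groups8(stem, n_blanks),
    "9" = tail(extend_chain(stem, n_blanks, "twoback"), n_blanks),
    "10" = .solve_interleaved(stem, n_blanks,
             c("arith", "geom", "prog_arith", "prog_geom", "composite"),
             c("arith", "geom", "prog_arith", "prog_geom", "composite")),
    "11" = .solve_pairs11(stem, n_blanks),
    "12" = .solve_pattern12(stem, n_blanks),
    "13" = .solve_pattern13(stem, n_blanks))
  as.integer(key)
}

#' Verify an item by independent re-solving
#'
#' Round-trip check: the item's key must equal what [solve_item()] infers
#' from its stem.  Malformed items return `FALSE` with a diagnostic
#' attribute rather than an error.
#'
#' @param item an [generate_item()] object.
#' @return `TRUE` or `FALSE`; on `FALSE` the attribute `"reason"` explains.
#' @export
verify_item <- function(item) {
  if (!inherits(item, "ansig_item"))
    return(structure(FALSE, reason = "not an ansig_item"))
  solved <- tryCatch(solve_item(item$model_id, item$stem, item$n_blanks),
                     error = function(e) conditionMessage(e))
  if (is.character(solved))
    return(structure(FALSE, reason = solved))
  if (!identical(as.integer(solved), as.integer(item$key)))
    return(structure(FALSE, reason = sprintf(
      "key mismatch: solved %s, stored %s",
      paste(solved, collapse = " "), paste(item$key, collapse = " "))))
  TRUE
}
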
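# Validity reporting utilities: agreement between difficulty estimates and
# correction of correlations for unreliability.

#' Agreement between two sets of item difficulty estimates
#'
#' Pearson correlation (and its square) over paired per-item estimates.
#'
#' @param est_a,est_b numeric vectors of equal length (>= 3); names, when
#'   present on both, must match.
#' @return Object of class `ansig_agreement`: `pearson_r`, `r_squared`,
#'   `n_pairs` and the paired `table`.
#' @export
difficulty_agreement <- function(est_a, est_b) {
  if (length(est_a) != length(est_b))
    ansig_domain_error("estimate vectors differ in length")
  if (length(est_a) < 3)
    ansig_domain_error("need at least 3 paired estimates")
  if (!is.null(names(est_a)) && !is.null(names(est_b))) {
    if (!all(names(est_a) == names(est_b)))
      ansig_domain_error("item ids of the two estimate sets do not match")
  }
  r <- cor(est_a, est_b)
  structure(list(pearson_r = r, r_squared = r^2, n_pairs = length(est_a),
                 table = data.frame(item = names(est_a) %||%
                                      seq_along(est_a),
                                    est_a = est_a, est_b = est_b,
                                    row.names = NULL)),
            class = "ansig_agreement")
}

#' @export
print.ansig_agreement <- function(x, ...) {
  cat(sprintf("difficulty agreement over %d items: r = %.2f, R^2 = %.2f\n",
              x$n_pairs, x$pearson_r, x$r_squared))
  invisible(x)
}

#' Correct a correlation for attenuation
#'
#' Disattenuates an observed correlation for the unreliability of both
#' measures: `r_xy / sqrt(rel_x * rel_y)`, capped at 1 (with a warning)
#' when the correction exceeds the admissible range.
#'
#' @param r_xy observed correlation in `[-1, 1]`.
#' @param rel_x,rel_y reliabilities in `(0, 1]`.
#' @return Corrected correlation.
#' @examples
#' disattenuate(0.60, 0.85, 0.68)  # 0.79
#' @export
disattenuate <- function(r_xy, rel_x, rel_y) {
  if (rel_x <= 0 || rel_y <= 0 || rel_x > 1 || rel_y > 1)
    ansig_domain_error("reliabilities must lie in (0, 1]")
  if (abs(r_xy) > 1)
    ansig_domain_error("correlation must lie in [-1, 1]")
  out <- r_xy / sqrt(rel_x * rel_y)
  if (abs(out) >= 1 && rel_x * rel_y < 1) {
    warning(sprintf(
      "disattenuated correlation %.3f reaches the admissible bound; capped at %s1",
      out, if (out < 0) "-" else ""))
    out <- sign(out)
  }
  out
}
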
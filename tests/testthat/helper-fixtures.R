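# Shared fixtures: small simulated calibration setups built in code.

# single-form Rasch data, persons x items, no missingness
sim_single_form <- function(n, delta, theta_sd = 1, seed = 1, theta_mean = 0) {
  names(delta) <- names(delta) %||% paste0("I", seq_along(delta))
  design <- form_design(list(A = names(delta)))
  cfg <- simulation_config(c(A = n), delta, theta_mean = theta_mean,
                           theta_sd = theta_sd, seed = seed)
  simulate_responses(cfg, design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the two-form calibration layout over the 49 reference items
study_setup <- function() {
  ref <- study_difficulty_estimates()
  models <- structure(ref$model, names = ref$item)
  list(ref = ref,
       models = models,
       delta = structure(ref$rasch, names = ref$item),
       design = assemble_forms(models, "study"),
       props = expand_item_properties(build_qmatrix("ansig", 1:13), models))
}

# independent conditional-likelihood oracle for tiny item sets: enumerates
# all response patterns at each raw score instead of using the package's
# elementary-symmetric-function recurrence
cond_loglik_oracle <- function(x, delta) {
  eps <- exp(-delta)
  k <- length(delta)
  patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
  ll <- 0
  for (v in seq_len(nrow(x))) {
    r <- sum(x[v, ])
    if (r == 0 || r == k) next
    num <- prod(eps^x[v, ])
    den <- sum(apply(patterns[rowSums(patterns) == r, , drop = FALSE], 1,
                     function(p) prod(eps^p)))
    ll <- ll + log(num / den)
  }
  ll
}

# grid maximiser of the oracle over sum-zero (d2, d3) for 3 items:
# successive refinement down to a 5e-4 mesh
cml_grid_oracle <- function(x, lim = 2.5) {
  stopifnot(ncol(x) == 3)
  best <- c(0, 0)
  rng <- lim
  for (step in c(0.1, 0.01, 0.001, 5e-4)) {
    g <- expand.grid(d2 = seq(best[1] - rng, best[1] + rng, step),
                     d3 = seq(best[2] - rng, best[2] + rng, step))
    ll <- mapply(function(d2, d3)
      cond_loglik_oracle(x, c(-(d2 + d3), d2, d3)), g$d2, g$d3)
    best <- unlist(g[which.max(ll), ])
    rng <- 2 * step
  }
  c(-(best[1] + best[2]), best)
}
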
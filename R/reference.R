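# Published reference estimates from the two-form calibration of the
# generator (396 + 174 respondents, 49 items after misfit removal, models
# 3-13).  Shipped so that difficulty prediction, test information and
# form-assembly workflows can be reproduced without respondent-level data,
# which was never deposited.

#' Reference item difficulty estimates
#'
#' Per-item Rasch (CML), LLTM and LLTM-plus-error difficulty estimates and
#' standard errors from the published two-form calibration of the 49
#' surviving generated items.  LLTM standard errors are parametric
#' bootstrap values (1000 iterations).  Items of models 3 and 8 served as
#' anchors and belong to both forms; models 4, 6, 10 and 12 to Form A
#' only; models 5, 7, 9, 11 and 13 to Form B only.
#'
#' @return Data frame with columns `item`, `model`, `form`, `rasch`,
#'   `rasch_se`, `lltm`, `lltm_boot_se`, `lltm_error`,
#'   `lltm_error_boot_se`.
#' @export
study_difficulty_estimates <- function() {
  d <- read.csv(system.file("extdata", "study_difficulty_estimates.csv",
                            package = "ansig"))
  d$form <- ifelse(d$model %in% c(3, 8), "AB",
                   ifelse(d$model %in% c(4, 6, 10, 12), "A", "B"))
  d$item <- paste0("I", d$item)
  d
}

#' Reference LLTM coefficient estimates
#'
#' Fixed effects (easiness scale) and variance components of the published
#' LLTM and LLTM-plus-error fits to the two-form calibration data: the
#' constant and the five operator coefficients, the person variance, and
#' (for the error model) the item residual variance.  Suitable as `fit`
#' input to [predict_difficulties()].
#'
#' @param model `"lltm"` or `"lltm_error"`.
#' @return List with `intercept`, `eta`, `person_var`, `item_resid_var`.
#' @examples
#' predict_difficulties(study_lltm_coefficients(), build_qmatrix("ansig", 4))
#' @export
study_lltm_coefficients <- function(model = c("lltm", "lltm_error")) {
  model <- match.arg(model)
  if (model == "lltm")
    list(intercept = 4.77,
         eta = c(aos = 0.35, ps = -1.53, cf = -2.13, npcp = -2.65,
                 pcp = -3.76),
         se_eta = c(aos = 0.07, ps = 0.07, cf = 0.06, npcp = 0.15,
                    pcp = 0.14),
         person_var = 1.19, item_resid_var = 0)
  else
    list(intercept = 5.32,
         eta = c(aos = 0.37, ps = -1.83, cf = -2.25, npcp = -3.09,
                 pcp = -4.28),
         se_eta = c(aos = 0.58, ps = 0.59, cf = 0.41, npcp = 0.71,
                    pcp = 0.69),
         person_var = 1.67, item_resid_var = 1.03)
}
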
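---
title: "Generating number-series items and explaining their difficulty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating number-series items and explaining their difficulty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ansig)
```

## The measurement problem

Number-series completion ("1 2 4 8 16, what comes next?") is a classical
marker of inductive reasoning and fluid intelligence. Writing such items by
hand is slow, and hand-written items arrive with unknown psychometric
properties. `ansig` takes the template (automatic item generation) approach:
items are *clones* drawn from one of thirteen **item models**, each a fixed
logical rule with free numeric slots, and each item model is characterised
by the **cognitive operators** a respondent must engage to solve its items:

* **AOS** — apprehension of succession: one coherent chain, no arithmetic
  beyond counting on;
* **PS** — parallel sequences: two interleaved chains;
* **CF** — cluster formation: groups of elements embedded in the series;
* **NPCP** — non-progressive coefficient patterns: the missing value follows
  from the preceding element(s) through a fixed arithmetic relation;
* **PCP** — progressive coefficient patterns: the coefficient of change
  itself evolves along the sequence.

The binary item-model × operator incidence matrix (the **Q-matrix**,
`build_qmatrix("ansig")`) is the design object that carries the cognitive
theory into the statistical models. A second built-in scheme
(`"holzman"`) encodes the four classical determinants of series completion
(relation detection, discovery of periodicity, pattern description,
extrapolation) with weights 0–2; its columns are exact linear combinations
of the five-operator columns (RD = CF, DoP = PS, PD = EX = NPCP + 2·PCP),
so the two explanatory models are statistically nested
(`check_nesting()`).

## Item generation and rule-inference solving

`generate_item(model_id, params, seed)` draws the free numeric slots and
emits the full sequence with the final one or two elements withheld as the
key. `solve_item()` re-derives the key *from the stem alone*: it infers the
generating rule within the model's admissible rule family and extrapolates.
`verify_item()` round-trips the two, and `sample_item_bank()` draws
reproducible banks with distinct stems.

Conventions the generator follows (the published exemplars fix the layout,
not the general rule, so these are package choices):

* Blanks always occupy the final positions of the displayed sequence —
  every published exemplar ends in its parenthesised answers.
* Sequence lengths per model mirror the exemplars (e.g. model 1: five
  elements, one blank; model 10: eleven elements interleaving a six- and a
  five-element chain, two blanks). Model 12 exists in two layouts in the
  source material; both are supported through
  `ansig_config(m12_layout=)`, default the length-9 form whose two blanks
  both belong to the paired subsequence.
* Parameter ranges keep element magnitudes small (cap 10 000 by default,
  resampling on violation) because respondents read very large values as
  difficulty signals — a generation artefact, not a cognitive one.
* Degeneracy guards: cluster values must differ between groups, parallel
  subsequences must not coincide, group anchors must be distinct.
  Otherwise the intended parallel or clustered structure is invisible and
  the item would not exercise the operators its model claims.
* Rule inference prefers the lowest-order rule consistent with *all* stem
  elements (constant difference < constant ratio < progressive difference <
  composite add-then-multiply); a genuine tie raises an ambiguity error
  rather than a silent choice.
* Model 7's composite step is implemented as x → (x + a)·b, which
  reproduces its printed exemplar 3 10 24 52 108 (220) exactly with
  a = b = 2.

Seeding: `sample_item_bank()` derives one seed per bank slot
(`seed + 1009 · counter`), so banks are reproducible item by item and two
banks from the same root seed agree even when drawn in different sessions.

## The measurement models

Responses are dichotomous. The Rasch model gives the probability that
person *v* solves item *i* as

$$P(x_{vi} = 1) = \frac{\exp(\theta_v - \delta_i)}{1 + \exp(\theta_v - \delta_i)}$$

`fit_rasch_cml()` estimates the difficulties δ by **conditional maximum
likelihood**: conditioning on each person's raw score removes the person
parameters exactly, so no assumption about the ability distribution enters
item calibration. The conditional likelihood is evaluated through
elementary symmetric functions computed with the summation (difference-free)
recurrence, the standard numerically stable choice around fifty items;
optimisation is quasi-Newton (BFGS) with the analytic gradient, relative
tolerance 1e-10. Difficulties are identified by a sum-zero constraint over
the estimated items; standard errors follow by the delta method.

Missing-by-design data need no special handling beyond conditioning on the
administered subset, so overlapping forms that share anchor items are
calibrated concurrently onto one metric. The built-in `"study"` preset of
`assemble_forms()` reproduces the published two-form layout (Form A: models
3, 4, 6, 8, 10, 12; Form B: models 3, 5, 7, 8, 9, 11, 13; models 3 and 8
anchor the forms).

Model fit is probed by Andersen's likelihood-ratio test (score-group
calibrations against the joint calibration, df = (G−1)(k−1)) and by
per-item Wald tests between score groups; `test_information()` and
`person_separation_reliability()` summarise measurement precision.
Persons with perfect or zero scores have no finite ML ability estimate and
are flagged rather than extrapolated; no bias correction (e.g. Warm
weighting) is applied — a documented limitation.

The **LLTM** restricts the Rasch difficulties to a linear decomposition
over the Q-matrix,

$$\delta_i = \sum_{j=1}^m q_{ij}\,\eta_j,$$

and the **LLTM plus error** adds a per-item residual ε_i so the
decomposition need not be exact. Both are fitted as generalised linear
mixed models with the person ability as a normal random intercept
(`fit_lltm()`, `fit_lltm_error()`), i.e. by marginal maximum likelihood
under the Laplace approximation; the error model uses crossed person and
item random intercepts. Coefficients are estimated on the *easiness* scale
(the convention of the published coefficient table); reported difficulties
are the negated fitted linear predictors, and
`predict_difficulties()` maps any coefficient set through any Q-matrix.

Two numerical choices deserve note. First, the default engine is
`lme4::glmer` with `nAGQ = 1`; the identical Laplace objective is also
available through `glmmTMB` (`engine = "glmmTMB"`), which agrees to about
1e-3 on fixtures and is several times faster — the package's replication
studies use it. Adaptive quadrature (`nAGQ > 1`) is available for the
person-only models when extra integration accuracy is wanted; Laplace is
the default because it is the approximation under which the reference
coefficient values were obtained and it scales to the crossed-effects
model, where quadrature is unavailable. Second, information criteria count
variance components as parameters (LLTM over five operators: 7 = intercept
+ 5 coefficients + person variance) and BIC uses N = the number of
*observed responses*, the convention that matches the published
goodness-of-fit table for missing-by-design data.

`bootstrap_item_se()` provides parametric-bootstrap standard errors
(simulate from the fitted model on the observed design, refit, take SDs) —
parametric rather than resampling because persons see different forms, so
case resampling would change the design. `compare_models()` reports AIC,
BIC and likelihood-ratio tests for nested pairs.

## The respondent simulator

`simulate_responses()` draws abilities from Normal(μ, σ²) — standard
normal by default, the usual marginal-ML convention, since the source
analyses never state a person distribution — and generates Bernoulli
responses under the Rasch probability, with cells outside a person's form
missing by design. An item-level residual (`item_resid_sd`) is drawn *once
per item* per replication, matching the item-level error term of the LLTM
plus error. Persons are allocated to forms either by fixed counts (the
study used 396 and 174) or by independent uniform draw.

What the simulator emulates: the two-form anchored design, a normal ability
distribution, Rasch-conforming (or item-residual-perturbed) responses.
What it does not: guessing, response times, within-person learning,
non-normal abilities, differential motivation between forms. Passing
recovery tests therefore certify the estimation machinery, not the
behavioural realism of any particular dataset.

## Reference estimates

`study_difficulty_estimates()` and `study_lltm_coefficients()` ship the
published calibration of the 49 surviving items (two-dp logits): per-item
Rasch/LLTM/LLTM+error difficulties with (bootstrap) standard errors, and
the operator coefficient sets. They serve as inputs for difficulty
prediction, information profiling, bin-based form assembly and as the true
values of the recovery simulations. Two reproduction caveats, both
consequences of working from rounded published values: predictions from
the rounded coefficients deviate from the rounded per-model difficulty
column by up to 0.01 for three profiles, and the maximum Form B test
information computes to 5.87 (at θ = −0.2) rather than the published 5.91.
The lowest difficulty bin of the published estimates holds only two items,
so the classical 24-item bin-assembled form yields 23 items from the
rounded inputs (`assemble_form_by_bins()` warns and under-fills rather
than inventing items).

Note that among the thirteen designed item models the five-operator
Q-matrix contains ten distinct operator profiles; over the eleven
calibrated models (3–13 — the first two are too easy for adults) it
contains eight, which is the figure the validation analyses quote.

## Problem sizes used in the test suite

The simulation-based checks run at fixed seeds with: difficulty-recovery at
the study design (396 + 174 persons, 49 items, anchored concurrent
calibration; recovery r > 0.95); operator-weight recovery over 100
replications of 1000 persons (per-operator 2·SE coverage ≥ 90%); type-I
behaviour of the Andersen and Wald tests over 200 replications of 250
persons × 12 items; BIC model selection over 50 (item residual present)
plus 20 (absent) replications of 250 persons. These sizes were chosen to
make Monte-Carlo error small relative to the tested margins.

## Worked example

```{r example, eval = FALSE}
bank <- sample_item_bank(3:13, 5, seed = 42)         # 55 items
design <- assemble_forms(bank_models(bank), "study")  # 30/35, 10 anchors

q <- build_qmatrix("ansig", 3:13)
pred <- predict_difficulties(study_lltm_coefficients(), q)
delta <- structure(pred[as.character(bank_models(bank))],
                   names = names(bank_models(bank)))

cfg <- simulation_config(c(A = 396, B = 174), delta, theta_sd = 1.1,
                         seed = 1)
x <- simulate_responses(cfg, design)

fit <- fit_rasch_cml(x)                  # concurrent anchored calibration
props <- expand_item_properties(q, bank_models(bank))
lltm <- fit_lltm(x, props)
compare_models(fit_rasch_mml(x, engine = "glmmTMB"), lltm,
               fit_lltm_error(x, props, engine = "glmmTMB"))
```

## Known limitations

* Distractor generation and multiple-choice formatting are out of scope
  (the study items were open-ended), as are functional min–max constraints
  on generation and letter-series material.
* The solver resolves rules *within* the declared item model; it does not
  classify an arbitrary sequence into a model.
* Ability estimation is plain ML given calibrated difficulties; extreme
  scores are excluded, not corrected.
* The LLTM machinery assumes the Q-matrix is known; estimating Q from data
  (cognitive diagnosis) is not attempted.
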
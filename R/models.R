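#' The three discounting families
#'
#' `linear`: SV = R - k*C; `parabolic`: SV = R - k*C^2;
#' `hyperbolic`: SV = R / (1 + k*C).
#'
#' @return Character vector of the three family names.
#' @export
discount_families <- function() c("linear", "parabolic", "hyperbolic")

#' Construct a model specification
#'
#' A model is a discounting family crossed with a parameter structure: the
#' discount rate k and the softmax inverse temperature beta can each be
#' shared between recipients (`"joint"`) or estimated separately for self
#' and environment (`"separate"`). Canonical names follow the
#' `<family>-<1|2>k<1|2>b` convention, e.g. `"parabolic-2k2b"` for the
#' fully recipient-specific parabolic model.
#'
#' @param family One of [discount_families()].
#' @param k_structure,beta_structure `"joint"` or `"separate"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("linear", "parabolic", "hyperbolic"),
                       k_structure = c("separate", "joint"),
                       beta_structure = c("separate", "joint")) {
  family <- match.arg(family)
  k_structure <- match.arg(k_structure)
  beta_structure <- match.arg(beta_structure)
  structure(list(family = family, k_structure = k_structure,
                 beta_structure = beta_structure),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", model_name(x), "\n")
  invisible(x)
}

#' Canonical model name
#'
#' @param spec A `model_spec`.
#' @return Name like `"hyperbolic-2k1b"` (2 = separate, 1 = joint).
#' @export
model_name <- function(spec) {
  sprintf("%s-%dk%db", spec$family,
          if (spec$k_structure == "separate") 2L else 1L,
          if (spec$beta_structure == "separate") 2L else 1L)
}

#' Parse a canonical model name back into a specification
#'
#' @param name Name such as `"parabolic-2k2b"`.
#' @return A `model_spec`.
#' @export
parse_model_name <- function(name) {
  m <- regmatches(name, regexec("^(linear|parabolic|hyperbolic)-([12])k([12])b$", name))[[1]]
  if (length(m) != 4L) stop("unrecognised model name: ", name, call. = FALSE)
  model_spec(m[2],
             k_structure = if (m[3] == "2") "separate" else "joint",
             beta_structure = if (m[4] == "2") "separate" else "joint")
}

#' Enumerate the full twelve-model space
#'
#' Three discounting families times four parameter structures (joint or
#' separate k, joint or separate beta).
#'
#' @return List of 12 `model_spec` objects in a stable order.
#' @export
enumerate_model_space <- function() {
  grid <- expand.grid(family = discount_families(),
                      k = c("joint", "separate"),
                      beta = c("joint", "separate"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    model_spec(grid$family[i], grid$k[i], grid$beta[i]))
}

#' Subjective value of a costly option
#'
#' Evaluates the discounting equation of the given family exactly, with no
#' clamping. Linear and parabolic values may be negative; hyperbolic values
#' stay in (0, R\] for k >= 0.
#'
#' @param reward Reward R in credits (> 0). Vectorised.
#' @param cost Cost C in cost units (>= 0). Vectorised.
#' @param k Discount rate (>= 0). Vectorised.
#' @param family One of [discount_families()].
#' @return Subjective value in credits.
#' @examples
#' subjective_value(10, 4, 0.3, "parabolic") # 5.2
#' subjective_value(10, 9, 1/9, "hyperbolic") # 5
#' @export
subjective_value <- function(reward, cost, k,
                             family = c("linear", "parabolic", "hyperbolic")) {
  family <- match.arg(family)
  if (any(k < 0)) stop("discount rate k must be non-negative", call. = FALSE)
  if (any(cost < 0)) stop("cost must be non-negative", call. = FALSE)
  switch(family,
         linear     = reward - k * cost,
         parabolic  = reward - k * cost^2,
         hyperbolic = reward / (1 + k * cost))
}

#' Softmax probability of choosing the costly option
#'
#' P = 1 / (1 + exp(-beta * (SV_costly - SV_baseline))), evaluated stably
#' for large |beta * dSV|.
#'
#' @param sv_costly,sv_baseline Subjective values in credits. Vectorised.
#' @param beta Inverse temperature (>= 0); 0 gives random choice (P = 0.5).
#' @return Choice probability in \[0, 1\].
#' @export
choice_probability <- function(sv_costly, sv_baseline, beta) {
  if (any(beta < 0)) stop("inverse temperature beta must be non-negative", call. = FALSE)
  stats::plogis(beta * (sv_costly - sv_baseline))
}

# Map trial recipients onto the k / beta used under a spec's structure.
# Returns per-trial k and beta given subject parameters
# (k_self, k_env, beta_self, beta_env). Under a joint structure both
# recipients read the *_self slot (held equal to *_env by construction).
.param_for_trial <- function(params, recipient, spec) {
  env <- recipient == "environment"
  k <- if (spec$k_structure == "separate")
    ifelse(env, params$k_env, params$k_self) else params$k_self
  beta <- if (spec$beta_structure == "separate")
    ifelse(env, params$beta_env, params$beta_self) else params$beta_self
  list(k = k, beta = beta)
}

#' Per-trial log-likelihood of an observed choice
#'
#' Composes the discounting equation and the softmax rule. The baseline
#' option is 1 credit, undiscounted. Under `"separate"` structures the
#' trial's recipient selects which k / beta applies; under `"joint"`
#' structures the self slot is used for both recipients. Omitted trials
#' must be filtered out before calling; passing one is an error.
#'
#' @param trials `data.frame` with columns `recipient`, `cost_level`,
#'   `reward`, `choice` (`"costly"` or `"baseline"`).
#' @param params List or one-row `data.frame` with `k_self`, `k_env`,
#'   `beta_self`, `beta_env` (all > 0).
#' @param spec A `model_spec`.
#' @return Numeric vector of log-probabilities, one per trial.
#' @export
trial_loglik <- function(trials, params, spec) {
  if (any(trials$choice == "omission"))
    stop("omitted trials must be excluded before likelihood evaluation",
         call. = FALSE)
  pp <- .param_for_trial(params, trials$recipient, spec)
  sv <- subjective_value(trials$reward, trials$cost_level, pp$k, spec$family)
  # log P via the stable logistic log-CDF; baseline = complement
  x <- pp$beta * (sv - baseline_reward())
  lp_costly <- stats::plogis(x, log.p = TRUE)
  lp_base <- stats::plogis(-x, log.p = TRUE)
  ifelse(trials$choice == "costly", lp_costly, lp_base)
}

#' Dataset log-likelihood
#'
#' Sum of [trial_loglik()] over all non-omitted trials of all subjects.
#'
#' @param dataset Trial table with a `participant` column.
#' @param params `data.frame` of subject parameters, one row per
#'   participant (columns `participant`, `k_self`, `k_env`, `beta_self`,
#'   `beta_env`).
#' @param spec A `model_spec`.
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(dataset, params, spec) {
  dataset <- dataset[dataset$choice != "omission", , drop = FALSE]
  idx <- match(dataset$participant, params$participant)
  if (anyNA(idx)) stop("dataset contains participants missing from params", call. = FALSE)
  p <- list(k_self = params$k_self[idx], k_env = params$k_env[idx],
            beta_self = params$beta_self[idx], beta_env = params$beta_env[idx])
  sum(trial_loglik(dataset, p, spec))
}
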
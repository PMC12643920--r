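#' Group-level (population) parameters
#'
#' Locations and scales of the log-normal population distributions of the
#' four subject-level parameters. `mu` is the mean and `sigma` the standard
#' deviation of the natural log of each parameter.
#'
#' @param mu Named numeric vector with entries `k_self`, `k_env`,
#'   `beta_self`, `beta_env` (log-scale locations).
#' @param sigma Named numeric vector, same names (log-scale scales, > 0).
#' @return An object of class `group_parameters`.
#' @export
group_parameters <- function(mu, sigma) {
  nm <- c("k_self", "k_env", "beta_self", "beta_env")
  stopifnot(all(nm %in% names(mu)), all(nm %in% names(sigma)))
  mu <- mu[nm]; sigma <- sigma[nm]
  if (any(!is.finite(mu)) || any(!is.finite(sigma)))
    stop("hyperparameters must be finite", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be > 0 for every parameter", call. = FALSE)
  structure(list(mu = mu, sigma = sigma), class = "group_parameters")
}

#' Default study conditions for the synthetic cohort
#'
#' Population parameters chosen once to reproduce the behavioural
#' magnitudes characteristic of cohorts of this design: for the effort
#' task a parabolic population with modest self discounting (median
#' k_self 0.13, environment-trial costly-choice rate near 60%) and
#' stronger, more dispersed environmental discounting; for the time task
#' a hyperbolic population with a large low-k, high-beta subpopulation
#' that produces environment-trial costly-choice rates near 80% and the
#' ceiling behaviour typical of waiting tasks. See the package vignette
#' for the derivation and for which descriptive features the simulator
#' does and does not reproduce.
#'
#' @param task `"effort"` or `"time"`.
#' @return A `group_parameters` object.
#' @export
default_group_parameters <- function(task = c("effort", "time")) {
  task <- match.arg(task)
  if (task == "effort") {
    group_parameters(
      mu = c(k_self = log(0.13), k_env = log(0.32),
             beta_self = log(2.4), beta_env = log(2.4)),
      sigma = c(k_self = 0.8, k_env = 0.9, beta_self = 0.7, beta_env = 0.7))
  } else {
    group_parameters(
      mu = c(k_self = log(0.035), k_env = log(0.30),
             beta_self = log(3.0), beta_env = log(3.0)),
      sigma = c(k_self = 1.3, k_env = 1.3, beta_self = 0.5, beta_env = 0.5))
  }
}

#' Draw subject-level parameters from the population
#'
#' Each subject's k and beta values are drawn independently from the
#' log-normal distributions implied by the group `mu` and `sigma`; all
#' draws are strictly positive by construction.
#'
#' @param group A `group_parameters` object.
#' @param n Number of subjects (>= 1).
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `participant`, `k_self`, `k_env`,
#'   `beta_self`, `beta_env`.
#' @export
sample_subjects <- function(group, n, seed = NULL) {
  stopifnot(inherits(group, "group_parameters"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- function(p) exp(stats::rnorm(n, group$mu[[p]], group$sigma[[p]]))
  data.frame(participant = sprintf("S%03d", seq_len(n)),
             k_self = draw("k_self"), k_env = draw("k_env"),
             beta_self = draw("beta_self"), beta_env = draw("beta_env"),
             stringsAsFactors = FALSE)
}

#' Cohort configuration
#'
#' Bundles everything needed to simulate a full dataset. Defaults encode
#' the study conditions: 74 subjects, 150 trials per task, omissions on
#' about 0.3% of trials, execution failures on about 5.5% of chosen-costly
#' effort trials, a parabolic-2k2b generating model for the effort task
#' and a hyperbolic-2k2b model for the time task.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_task Trials per task (the design generator produces 150).
#' @param omission_rate Probability a trial ends with no decision.
#' @param failure_rate Probability a chosen-costly trial fails execution.
#' @param specs Named list of generating `model_spec`s, one per task.
#' @param groups Named list of `group_parameters`, one per task.
#' @param coupling Kendall-scale strength of the association between the
#'   discounting asymmetry (k_self - k_env) and policy support; the sign
#'   sets the direction of the association.
#' @param seed Master seed; per-subject child seeds are derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 74L,
                          trials_per_task = 150L,
                          omission_rate = 0.003,
                          failure_rate = 0.055,
                          specs = list(effort = model_spec("parabolic"),
                                       time = model_spec("hyperbolic")),
                          groups = list(effort = default_group_parameters("effort"),
                                        time = default_group_parameters("time")),
                          coupling = 0.5,
                          seed = 1L) {
  stopifnot(n_subjects >= 1,
            omission_rate >= 0, omission_rate < 1,
            failure_rate >= 0, failure_rate < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_task = as.integer(trials_per_task),
                 omission_rate = omission_rate, failure_rate = failure_rate,
                 specs = specs, groups = groups,
                 coupling = coupling, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate choices for one subject on one design
#'
#' Per trial the costly option is chosen with the softmax probability
#' implied by the subject's parameters under the generating model; the
#' trial is then overwritten as an omission with probability
#' `omission_rate`; a chosen-costly effort trial fails execution (the
#' force threshold is not held long enough) with probability
#' `failure_rate`. Chosen waiting periods in the time task are always
#' completed.
#'
#' @param subject One-row `data.frame` or list with `k_self`, `k_env`,
#'   `beta_self`, `beta_env`.
#' @param design Output of [generate_design()].
#' @param spec Generating `model_spec`.
#' @param omission_rate,failure_rate Rates in \[0, 1).
#' @param seed Optional integer seed.
#' @return The design `data.frame` extended with `choice`
#'   (`costly`/`baseline`/`omission`), `success` (logical, `NA` unless the
#'   costly option was chosen), `earned` (credits) and `decision_time`
#'   (seconds; schema round-trip only, no downstream inference).
#' @export
simulate_choices <- function(subject, design, spec,
                             omission_rate = 0, failure_rate = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pp <- .param_for_trial(subject, design$recipient, spec)
  sv <- subjective_value(design$reward, design$cost_level, pp$k, spec$family)
  p <- choice_probability(sv, baseline_reward(), pp$beta)
  n <- nrow(design)
  costly <- stats::runif(n) < p
  choice <- ifelse(costly, "costly", "baseline")
  omitted <- stats::runif(n) < omission_rate
  choice[omitted] <- "omission"
  success <- rep(NA, n)
  chose_costly <- choice == "costly"
  can_fail <- chose_costly & design$task == "effort"
  success[chose_costly] <- TRUE
  success[can_fail] <- stats::runif(sum(can_fail)) >= failure_rate
  earned <- ifelse(choice == "baseline", baseline_reward(),
                   ifelse(chose_costly & success %in% TRUE, design$reward, 0))
  out <- design
  out$choice <- choice
  out$success <- as.logical(success)
  out$earned <- earned
  # shifted log-normal decision times within the 3 s response window
  out$decision_time <- pmin(0.3 + stats::rlnorm(n, log(0.6), 0.4), 3)
  out$decision_time[choice == "omission"] <- NA_real_
  out
}

#' Simulate a complete synthetic cohort
#'
#' Draws subjects from the per-task populations, generates a fresh
#' pseudorandomized design per subject and task, simulates choices,
#' omissions and execution failures, and generates the 12-item policy
#' support questionnaire coupled to the effort-task discounting asymmetry.
#' The master seed deterministically spawns per-subject child seeds, so
#' identical configs give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with elements `trials` (one row per trial for all subjects
#'   and tasks), `truth` (per subject and task, the generating parameters)
#'   and `questionnaire` (per subject, 12 item scores and their mean).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  child <- matrix(sample.int(.Machine$integer.max - 1L, config$n_subjects * 5L),
                  ncol = 5L)
  truth <- list(); trials <- list()
  for (task in task_kinds()) {
    param_col <- if (task == "effort") 1L else 2L
    subj_col <- if (task == "effort") 3L else 4L
    subs <- sample_subjects(config$groups[[task]], config$n_subjects,
                            seed = child[1L, param_col])
    subs$task <- task
    truth[[task]] <- subs
    per_sub <- lapply(seq_len(config$n_subjects), function(i) {
      sd_i <- child[i, subj_col]
      des <- generate_design(task, seed = sd_i)
      rec <- simulate_choices(subs[i, ], des, config$specs[[task]],
                              config$omission_rate, config$failure_rate,
                              seed = sd_i + 1L)
      rec$participant <- subs$participant[i]
      rec
    })
    trials[[task]] <- do.call(rbind, per_sub)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  cols <- c("participant", "task", "block", "trial", "recipient",
            "cost_level", "reward", "choice", "success", "earned",
            "decision_time")
  trials <- trials[, cols]
  quest <- simulate_questionnaires(truth[truth$task == "effort", ],
                                   coupling = config$coupling,
                                   seed = child[1L, 5L])
  list(trials = trials, truth = truth, questionnaire = quest)
}

#' Simulate 12-item policy-support questionnaire scores
#'
#' Generates per-subject Likert responses (12 items, 1-5) whose mean is
#' monotonically related to the subject's discounting asymmetry
#' k_self - k_env with association strength set by `coupling` (0 =
#' independent). Positive coupling means subjects who discount
#' environmental rewards less than self rewards (k_self - k_env high)
#' express more policy support.
#'
#' @param true_params `data.frame` with `participant`, `k_self`, `k_env`.
#' @param coupling Correlation-scale coupling strength in \[-1, 1\].
#' @param seed Optional integer seed.
#' @return `data.frame` with `participant`, item columns `item01`..`item12`
#'   and `policy_support` (the item mean).
#' @export
simulate_questionnaires <- function(true_params, coupling = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(abs(coupling) <= 1)
  n <- nrow(true_params)
  z <- scale(rank(true_params$k_self - true_params$k_env))[, 1]
  latent <- coupling * z + sqrt(1 - coupling^2) * stats::rnorm(n)
  items <- matrix(NA_integer_, n, 12L)
  for (j in 1:12) {
    raw <- round(3 + 1.1 * latent + stats::rnorm(n, 0, 0.8))
    items[, j] <- pmin(pmax(raw, 1L), 5L)
  }
  colnames(items) <- sprintf("item%02d", 1:12)
  out <- data.frame(participant = true_params$participant, items,
                    stringsAsFactors = FALSE)
  out$policy_support <- rowMeans(items)
  out
}
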
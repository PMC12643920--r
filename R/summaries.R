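# Descriptive statistics and nonparametric tests over trial tables.

.filter_trials <- function(dataset, task = NULL, recipient = NULL,
                           drop_omissions = TRUE) {
  d <- dataset
  if (!is.null(task)) d <- d[d$task %in% task, , drop = FALSE]
  if (!is.null(recipient)) d <- d[d$recipient %in% recipient, , drop = FALSE]
  if (drop_omissions) d <- d[d$choice != "omission", , drop = FALSE]
  d
}

#' Proportions of costly choices
#'
#' Proportion of non-omitted trials on which the costly option was chosen,
#' pooled over trials, averaged over per-participant proportions, per
#' participant, and per design cell (cost level x reward x recipient).
#'
#' @param dataset Trial table.
#' @param task,recipient Optional filters (`"effort"`/`"time"`,
#'   `"self"`/`"environment"`).
#' @param drop_omissions Drop omitted trials first (default `TRUE`).
#' @return List with `pooled` (single proportion over all selected
#'   trials), `participant_mean` (mean of per-participant proportions),
#'   `per_participant` and `per_cell` data frames, and `n_trials`. An
#'   empty selection returns `NA` values with attribute `empty = TRUE`.
#' @export
choice_proportions <- function(dataset, task = NULL, recipient = NULL,
                               drop_omissions = TRUE) {
  d <- .filter_trials(dataset, task, recipient, drop_omissions)
  if (nrow(d) == 0L) {
    warning("no trials survive the requested filters")
    return(structure(list(pooled = NA_real_, participant_mean = NA_real_,
                          per_participant = NULL, per_cell = NULL,
                          n_trials = 0L), empty = TRUE))
  }
  costly <- d$choice == "costly"
  per_part <- stats::aggregate(costly, by = list(participant = d$participant),
                               FUN = mean)
  names(per_part)[2] <- "prop_costly"
  per_cell <- stats::aggregate(costly,
                               by = list(cost_level = d$cost_level,
                                         reward = d$reward,
                                         recipient = d$recipient),
                               FUN = mean)
  names(per_cell)[4] <- "prop_costly"
  counts <- stats::aggregate(costly,
                             by = list(cost_level = d$cost_level,
                                       reward = d$reward,
                                       recipient = d$recipient),
                             FUN = length)
  per_cell$n_trials <- counts$x
  list(pooled = mean(costly),
       participant_mean = mean(per_part$prop_costly),
       per_participant = per_part,
       per_cell = per_cell,
       n_trials = nrow(d))
}

#' Omission rates per task and recipient
#'
#' Fraction of trials on which no decision was made within the response
#' window, as percentages.
#'
#' @param dataset Trial table.
#' @return `data.frame` with columns `task`, `recipient`, `n_trials`,
#'   `omission_pct`.
#' @export
omission_rates <- function(dataset) {
  om <- dataset$choice == "omission"
  out <- stats::aggregate(om, by = list(task = dataset$task,
                                        recipient = dataset$recipient),
                          FUN = function(x) 100 * mean(x))
  names(out)[3] <- "omission_pct"
  n <- stats::aggregate(om, by = list(task = dataset$task,
                                      recipient = dataset$recipient),
                        FUN = length)
  out$n_trials <- n$x
  out[order(out$task, out$recipient), c("task", "recipient", "n_trials",
                                        "omission_pct")]
}

#' Fraction of participants at ceiling
#'
#' Fraction of participants whose costly-choice proportion (over
#' non-omitted trials of one task) strictly exceeds the threshold, i.e.
#' who show so little variability that discounting is barely identified.
#'
#' @param dataset Trial table.
#' @param task `"effort"` or `"time"`.
#' @param threshold Proportion threshold, default 0.95 (strict >).
#' @return Fraction of participants in \[0, 1\].
#' @export
ceiling_proportion <- function(dataset, task, threshold = 0.95) {
  cp <- choice_proportions(dataset, task = task)
  mean(cp$per_participant$prop_costly > threshold)
}

#' Effort execution success rates
#'
#' For each participant, the fraction of chosen-costly effort trials on
#' which the required force threshold was reached; reported per recipient
#' together with the recipient means. Participants with no chosen-costly
#' trials for a recipient are excluded from that mean with a warning.
#'
#' @param dataset Trial table.
#' @return List with `per_participant` (wide `data.frame`: `participant`,
#'   `self`, `environment`, as percentages) and `mean` (named vector of
#'   recipient means over participants).
#' @export
success_rates <- function(dataset) {
  d <- .filter_trials(dataset, task = "effort")
  d <- d[d$choice == "costly", , drop = FALSE]
  if (nrow(d) == 0L) stop("no chosen-costly effort trials", call. = FALSE)
  agg <- stats::aggregate(100 * d$success,
                          by = list(participant = d$participant,
                                    recipient = d$recipient),
                          FUN = mean)
  names(agg)[3] <- "success_pct"
  wide <- stats::reshape(agg, idvar = "participant", timevar = "recipient",
                         direction = "wide")
  names(wide) <- sub("^success_pct\\.", "", names(wide))
  for (r in recipients()) if (!r %in% names(wide)) wide[[r]] <- NA_real_
  if (anyNA(wide[recipients()]))
    warning("participants without chosen-costly trials for a recipient were excluded")
  list(per_participant = wide[, c("participant", recipients())],
       mean = c(self = mean(wide$self, na.rm = TRUE),
                environment = mean(wide$environment, na.rm = TRUE)))
}

#' Classical paired t test
#'
#' @param x,y Equal-length paired numeric samples, n >= 2.
#' @param conf_level Confidence level for the interval on the mean
#'   difference (default 0.95).
#' @return List with `t`, `df`, `mean_diff`, `conf_int`, `p_value`.
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (stats::sd(d) == 0) {
    # degenerate pairs: identical samples give t = 0, constant shift gives Inf
    t0 <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t0, df = n - 1, mean_diff = mean(d),
                conf_int = c(mean(d), mean(d)),
                p_value = if (mean(d) == 0) 1 else 0))
  }
  tt <- stats::t.test(x[ok], y[ok], paired = TRUE, conf.level = conf_level)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       mean_diff = unname(tt$estimate), conf_int = as.numeric(tt$conf.int),
       p_value = tt$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' V is the sum of the ranks of the positive differences after dropping
#' zero differences (midranks for ties). The p value is exact (sign-pattern
#' enumeration) for n <= 25 without ties, and a normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y Equal-length paired samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends to exceed y) or
#'   `"less"`.
#' @return List with `V`, `p_value`, `n` (pairs used after zero-dropping)
#'   and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero; test undefined", call. = FALSE)
  has_ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= 25L && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(V = unname(wt$statistic), p_value = wt$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation; the p value is exact for n <= 10
#' without ties and a normal approximation otherwise.
#'
#' @param x,y Equal-length samples, n >= 3; constant vectors are an error.
#' @return List with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant input vector", call. = FALSE)
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- n <= 10L && !has_ties
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = exact))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Discounting asymmetry k_self - k_env
#'
#' The per-subject difference between self and environment discount rates,
#' the quantity related to policy support. Defined only for separate-k
#' model fits.
#'
#' @param estimates Either a `posterior_fit` (its subject point estimates
#'   are used) or a `data.frame` with `participant`, `k_self`, `k_env`.
#' @return `data.frame` with columns `participant`, `k_self`, `k_env`,
#'   `k_diff`.
#' @export
k_difference <- function(estimates) {
  if (inherits(estimates, "posterior_fit")) {
    if (estimates$spec$k_structure != "separate")
      stop("k difference is undefined for a joint-k model fit", call. = FALSE)
    estimates <- subject_point_estimates(estimates)
  }
  stopifnot(all(c("participant", "k_self", "k_env") %in% names(estimates)))
  data.frame(participant = estimates$participant,
             k_self = estimates$k_self, k_env = estimates$k_env,
             k_diff = estimates$k_self - estimates$k_env,
             stringsAsFactors = FALSE)
}
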
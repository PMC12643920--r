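#' Task identifiers
#'
#' The paradigm has two tasks that differ only in the cost currency:
#' `"effort"` (grip force at 40--80% of the participant's maximum voluntary
#' contraction, MVC) and `"time"` (waiting periods of 3--27 s).
#'
#' @return Character vector of the two task names.
#' @export
task_kinds <- function() c("effort", "time")

#' Recipient identifiers
#'
#' Rewards are paid either to the participant (`"self"`) or donated to a
#' CO2-reduction program (`"environment"`).
#'
#' @return Character vector of the two recipient names.
#' @export
recipients <- function() c("self", "environment")

# Reward grid in credits and the guaranteed no-cost alternative.
reward_levels <- function() c(2, 4, 6, 8, 10)
baseline_reward <- function() 1

#' Build a participant profile
#'
#' Holds the individually calibrated cost grids: effort levels are fixed
#' fractions of the participant's MVC, time levels are five equidistant
#' waiting durations obtained from [calibrate_time_levels()].
#'
#' @param participant_id Opaque participant label.
#' @param mvc Maximum voluntary contraction in device units; must be > 0.
#' @param time_levels Five strictly increasing, equidistant durations in
#'   seconds, each within \[3, 27\].
#' @return An object of class `participant_profile` with fields
#'   `participant_id`, `mvc`, `effort_levels` (fractions of MVC) and
#'   `time_levels` (seconds).
#' @export
participant_profile <- function(participant_id, mvc, time_levels) {
  stopifnot(is.numeric(mvc), length(mvc) == 1L, is.finite(mvc), mvc > 0)
  if (length(time_levels) != 5L)
    stop("time_levels must have exactly 5 entries", call. = FALSE)
  if (any(time_levels < 3 - 1e-9) || any(time_levels > 27 + 1e-9))
    stop("time_levels must lie within [3, 27] seconds", call. = FALSE)
  d <- diff(time_levels)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-8)
    stop("time_levels must be strictly increasing and equidistant", call. = FALSE)
  structure(
    list(participant_id = participant_id, mvc = mvc,
         effort_levels = c(0.40, 0.50, 0.60, 0.70, 0.80),
         time_levels = as.numeric(time_levels)),
    class = "participant_profile")
}

#' Interpolate the five waiting-time levels from two indifference points
#'
#' The calibration procedure finds the waiting durations subjectively
#' equivalent to the lowest and highest effort level; the three middle
#' levels are equidistant interpolations between the two.
#'
#' @param low_indifference Duration (s) matched to the lowest effort level.
#' @param high_indifference Duration (s) matched to the highest effort level.
#' @return Numeric vector of 5 strictly increasing, equidistant durations.
#' @examples
#' calibrate_time_levels(3, 27) # 3 9 15 21 27
#' @export
calibrate_time_levels <- function(low_indifference, high_indifference) {
  lo <- low_indifference; hi <- high_indifference
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L || length(hi) != 1L ||
      !is.finite(lo) || !is.finite(hi))
    stop("invalid calibration: indifference points must be finite scalars", call. = FALSE)
  if (lo >= hi || lo < 3 || hi > 27)
    stop("invalid calibration: need 3 <= low < high <= 27", call. = FALSE)
  lo + (hi - lo) / 4 * (0:4)
}

#' Find a time-effort indifference point for a deterministic agent
#'
#' Stand-in for the calibration staircase: an agent whose disutility of
#' waiting grows linearly in time (`agent_time_cost_rate` utility per
#' second) and who attaches a fixed disutility `agent_effort_cost` to the
#' effort option is indifferent where `t * rate = effort_cost`. The root is
#' located by bisection on \[3, 27\] to within 0.5 s. If the agent prefers
#' one option over the whole range the nearer boundary is returned and a
#' warning is raised.
#'
#' @param agent_time_cost_rate Positive disutility per second of waiting.
#' @param agent_effort_cost Positive disutility of the effort option.
#' @param tol Bisection tolerance in seconds (default 0.5).
#' @return Indifference duration in seconds, with attribute `boundary`
#'   set to `TRUE` when the search hit the edge of the range.
#' @export
simulate_indifference_search <- function(agent_time_cost_rate, agent_effort_cost,
                                         tol = 0.5) {
  stopifnot(is.finite(agent_time_cost_rate), agent_time_cost_rate > 0,
            is.finite(agent_effort_cost), agent_effort_cost > 0)
  # f(t) > 0 means waiting t seconds is worse than pressing
  f <- function(t) t * agent_time_cost_rate - agent_effort_cost
  lo <- 3; hi <- 27
  if (f(lo) >= 0) {
    warning("agent prefers effort over the whole range; returning boundary 3 s")
    return(structure(lo, boundary = TRUE))
  }
  if (f(hi) <= 0) {
    warning("agent prefers waiting over the whole range; returning boundary 27 s")
    return(structure(hi, boundary = TRUE))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  structure((lo + hi) / 2, boundary = FALSE)
}

# Cost-level sequence as 30 mini-blocks, each a permutation of 1..5, with
# every rolling 5-trial window summing to [10, 15] (mean cost 2-3). Within-
# block windows sum to exactly 15; only boundary-spanning windows need
# checking against the previous block's tail.
.sample_cost_sequence <- function(n_blocks = 30L, max_tries = 400L) {
  seqs <- integer(0)
  for (b in seq_len(n_blocks)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      perm <- sample(1:5)
      cand <- c(seqs, perm)
      if (b == 1L) { ok <- TRUE; break }
      # windows spanning the boundary between block b-1 and b
      start <- (b - 1L) * 5L - 3L
      sums <- vapply(start:((b - 1L) * 5L), function(i) sum(cand[i:(i + 4L)]), 0)
      if (all(sums >= 10 & sums <= 15)) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    seqs <- c(seqs, perm)
  }
  seqs
}

# Balanced recipient assignment: 3 self + 3 environment within each of the
# 25 (cost, reward) cells, resampled until no recipient runs > 4 in a row.
.sample_recipients <- function(cost, reward, max_tries = 400L) {
  n <- length(cost)
  cell <- interaction(cost, reward, drop = TRUE)
  for (try in seq_len(max_tries)) {
    recip <- character(n)
    for (lv in levels(cell)) {
      idx <- which(cell == lv)
      recip[idx] <- sample(rep(recipients(), each = 3L))
    }
    runs <- rle(recip)
    if (max(runs$lengths) <= 4L) return(recip)
  }
  NULL
}

#' Generate a pseudorandomized trial design
#'
#' Produces the 150-trial sequence (3 blocks of 50) for one task. Each of
#' the 50 design cells (5 cost levels x 5 rewards x 2 recipients) occurs
#' exactly 3 times; the mean cost level over every window of 5 consecutive
#' trials lies in \[2, 3\]; and no recipient occurs on more than 4
#' consecutive trials. Generation is by constrained resampling and raises
#' an error rather than relaxing a constraint.
#'
#' @param task `"effort"` or `"time"`.
#' @param seed Integer seed; identical seeds give identical designs.
#' @return A `data.frame` with columns `task`, `block`, `trial`,
#'   `recipient`, `cost_level`, `reward`.
#' @export
generate_design <- function(task = c("effort", "time"), seed) {
  task <- match.arg(task)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  for (restart in 1:50) {
    cost <- .sample_cost_sequence()
    if (is.null(cost)) next
    # each cost level appears 30 times; spread each reward 6 times within them
    reward <- numeric(150)
    for (cl in 1:5) {
      idx <- which(cost == cl)
      reward[idx] <- sample(rep(reward_levels(), each = 6L))
    }
    recip <- .sample_recipients(cost, reward)
    if (is.null(recip)) next
    design <- data.frame(
      task = task,
      block = rep(1:3, each = 50L),
      trial = 1:150,
      recipient = recip,
      cost_level = cost,
      reward = reward,
      stringsAsFactors = FALSE)
    stopifnot(isTRUE(validate_design(design)))
    return(design)
  }
  stop("design generation failed to satisfy constraints after bounded retries",
       call. = FALSE)
}

#' Re-check the three pseudorandomization constraints by direct counting
#'
#' Independent validator for [generate_design()] output: balanced cell
#' counts (each cost x reward x recipient cell exactly 3 times), rolling
#' 5-trial mean cost level within \[2, 3\], and maximum same-recipient run
#' length of 4.
#'
#' @param design A trial design `data.frame`.
#' @return `TRUE` if all constraints hold, otherwise a character vector of
#'   violation messages.
#' @export
validate_design <- function(design) {
  problems <- character(0)
  if (nrow(design) != 150L)
    problems <- c(problems, sprintf("expected 150 trials, found %d", nrow(design)))
  counts <- table(design$cost_level, design$reward, design$recipient)
  if (length(counts) != 50L || any(counts != 3L))
    problems <- c(problems, "cell counts are not 3 per (cost, reward, recipient)")
  if (nrow(design) >= 5L) {
    win <- vapply(1:(nrow(design) - 4L),
                  function(i) mean(design$cost_level[i:(i + 4L)]), 0)
    if (any(win < 2 - 1e-12 | win > 3 + 1e-12))
      problems <- c(problems, "a 5-trial window has mean cost level outside [2, 3]")
  }
  runs <- rle(as.character(design$recipient))
  if (max(runs$lengths) > 4L)
    problems <- c(problems, "a recipient occurs more than 4 times in a row")
  if (length(problems) == 0L) TRUE else problems
}

#' Write / read a trial design or trial table as CSV
#'
#' Plain UTF-8, header row, comma-separated.
#'
#' @param x A `data.frame` (design or trial records).
#' @param path Output file path.
#' @return `path`, invisibly (for `write_trials`); a `data.frame` (for
#'   `read_trials`).
#' @export
write_trials <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
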
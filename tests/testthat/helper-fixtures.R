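# Shared fixtures. Anything expensive (an MCMC fit) is memoised in this
# environment so several test files can reuse it within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

# A small deterministic trial table (no omissions) for likelihood tests.
make_trial_fixture <- function(n = 50, seed = 1, participant = "S001",
                               task = "effort") {
  set.seed(seed)
  data.frame(
    participant = participant,
    task = task,
    recipient = sample(recipients(), n, replace = TRUE),
    cost_level = sample(1:5, n, replace = TRUE),
    reward = sample(c(2, 4, 6, 8, 10), n, replace = TRUE),
    choice = sample(c("costly", "baseline"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

random_params <- function(seed) {
  set.seed(seed)
  list(k_self = exp(rnorm(1, log(0.15), 0.5)),
       k_env = exp(rnorm(1, log(0.2), 0.5)),
       beta_self = exp(rnorm(1, log(1.5), 0.4)),
       beta_env = exp(rnorm(1, log(1.5), 0.4)))
}

# Simulated multi-subject dataset for one task, small enough to fit fast.
make_small_dataset <- function(n_subjects = 8, seed = 7, task = "effort",
                               spec = model_spec("parabolic")) {
  set.seed(seed)
  group <- default_group_parameters(task)
  subs <- sample_subjects(group, n_subjects, seed = seed)
  out <- lapply(seq_len(n_subjects), function(i) {
    des <- generate_design(task, seed = seed + i)
    rec <- simulate_choices(subs[i, ], des, spec, seed = seed + 100 + i)
    rec$participant <- subs$participant[i]
    rec
  })
  list(trials = do.call(rbind, out), truth = subs, spec = spec)
}

# One shared small fit reused by inference / selection / ppc tests.
small_fit <- function() {
  cached("small_fit", {
    ds <- make_small_dataset(n_subjects = 8, seed = 7)
    fit <- fit_model(ds$trials, ds$spec,
                     config = mcmc_config(chains = 2, iterations = 900,
                                          warmup = 400, seed = 3))
    list(fit = fit, data = ds)
  })
}

# Exact signed-rank p by enumeration over all 2^n sign assignments.
wilcoxon_enum_oracle <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  switch(alternative,
         greater = mean(vs >= v_obs),
         less = mean(vs <= v_obs),
         two.sided = min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs))))
}

# Tie-corrected Kendall tau by brute-force pair counting.
kendall_pair_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

paired_t_oracle <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Brute-force per-trial log-likelihood loop, the independent oracle for
# the vectorised implementation.
loglik_loop_oracle <- function(trials, params, spec) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    k <- if (spec$k_structure == "separate" && tr$recipient == "environment")
      params$k_env else params$k_self
    beta <- if (spec$beta_structure == "separate" && tr$recipient == "environment")
      params$beta_env else params$beta_self
    sv <- switch(spec$family,
                 linear = tr$reward - k * tr$cost_level,
                 parabolic = tr$reward - k * tr$cost_level^2,
                 hyperbolic = tr$reward / (1 + k * tr$cost_level))
    # complement computed by the mirrored softmax, not 1 - p, so the
    # oracle stays accurate when p approaches 1
    x <- beta * (sv - 1)
    total <- total + log(if (tr$choice == "costly")
      1 / (1 + exp(-x)) else 1 / (1 + exp(x)))
  }
  total
}
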
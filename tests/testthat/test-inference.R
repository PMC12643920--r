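test_that("split R-hat matches the hand-computed formula and flags extremes", {
  # fixed 2 x 8 fixture, compared against explicit arithmetic
  c1 <- matrix(c(0.1, 0.4, 0.2, 0.5, 0.3, 0.6, 0.2, 0.4), ncol = 1)
  c2 <- matrix(c(0.2, 0.5, 0.1, 0.3, 0.4, 0.7, 0.3, 0.5), ncol = 1)
  colnames(c1) <- colnames(c2) <- "theta"
  halves <- list(c1[1:4], c1[5:8], c2[1:4], c2[5:8])
  n <- 4; m <- 4
  W <- mean(sapply(halves, var))
  B <- n * var(sapply(halves, mean))
  expected <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(unname(compute_rhat(list(c1, c2))), expected, tolerance = 1e-10)

  # two well-mixed chains from the same stream
  set.seed(4)
  good <- list(matrix(rnorm(4000), ncol = 1), matrix(rnorm(4000), ncol = 1))
  expect_lt(compute_rhat(good), 1.01)
  # chains centred 100 apart
  bad <- list(matrix(rnorm(1000, 0), ncol = 1), matrix(rnorm(1000, 100), ncol = 1))
  expect_gt(compute_rhat(bad), 1.5)
  # constant chains: defined as 1 with no crash
  const <- list(matrix(rep(2, 100), ncol = 1), matrix(rep(2, 100), ncol = 1))
  expect_equal(unname(compute_rhat(const)), 1)
})

test_that("the MCMC configuration retains chains x (iterations - warmup) draws", {
  cfg <- mcmc_config()
  expect_identical(cfg$chains, 4L)
  expect_identical(cfg$iterations, 2000L)
  expect_identical(cfg$warmup, 1000L)
  expect_identical(cfg$chains * (cfg$iterations - cfg$warmup), 4000L)
  expect_error(mcmc_config(chains = 1), "chains")
  expect_error(mcmc_config(iterations = 500, warmup = 600))
  sf <- small_fit()
  expect_identical(nrow(sf$fit$draws),
                   sf$fit$chains * sf$fit$iter_per_chain)
  expect_identical(ncol(sf$fit$loglik),
                   sum(sf$data$trials$choice != "omission"))
})

test_that("fitting the same data with the same seed reproduces the draws", {
  ds <- make_small_dataset(n_subjects = 4, seed = 19)
  cfg <- mcmc_config(chains = 2, iterations = 400, warmup = 200, seed = 5)
  f1 <- fit_model(ds$trials, ds$spec, config = cfg)
  f2 <- fit_model(ds$trials, ds$spec, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$rhat, f2$rhat)
})

test_that("the sampler's likelihood equals trial_loglik on frozen draws", {
  sf <- small_fit()
  fit <- sf$fit
  trials <- sf$data$trials[sf$data$trials$choice != "omission", ]
  for (row in c(1L, 250L, 997L)) {
    draw <- fit$draws[row, ]
    s_idx <- match(trials$participant, fit$participants)
    pars <- list(k_self = draw[sprintf("k[%d,1]", s_idx)],
                 k_env = draw[sprintf("k[%d,2]", s_idx)],
                 beta_self = draw[sprintf("b[%d,1]", s_idx)],
                 beta_env = draw[sprintf("b[%d,2]", s_idx)])
    expect_equal(unname(fit$loglik[row, ]),
                 unname(trial_loglik(trials, pars, fit$spec)),
                 tolerance = 1e-8)
  }
})

test_that("subject point estimates are positive, complete and exact when degenerate", {
  sf <- small_fit()
  est <- subject_point_estimates(sf$fit)
  expect_identical(nrow(est), length(sf$fit$participants))
  expect_true(all(est$k_self > 0 & est$k_env > 0 &
                    est$beta_self > 0 & est$beta_env > 0))
  # degenerate posterior: every draw identical -> estimate equals that value
  fake <- sf$fit
  fake$draws <- fake$draws[rep(1L, 10L), ]
  est0 <- subject_point_estimates(fake)
  expect_equal(est0$k_self[1], unname(fake$draws[1, "k[1,1]"]))
})

test_that("joint-structure fits tie the recipient columns", {
  ds <- make_small_dataset(n_subjects = 4, seed = 23)
  cfg <- mcmc_config(chains = 2, iterations = 400, warmup = 200, seed = 6)
  fit <- fit_model(ds$trials, model_spec("parabolic", "joint", "joint"),
                   config = cfg)
  est <- subject_point_estimates(fit)
  expect_equal(est$k_self, est$k_env)
  expect_equal(est$beta_self, est$beta_env)
  expect_error(k_difference(fit), "joint")
})

test_that("fits persist to plain files and restore losslessly", {
  sf <- small_fit()
  dir <- tempfile("fitdir")
  save_fit(sf$fit, dir)
  back <- load_fit(dir)
  expect_equal(unname(back$draws), unname(sf$fit$draws), tolerance = 1e-12)
  expect_identical(back$fingerprint, sf$fit$fingerprint)
  expect_identical(model_name(back$spec), model_name(sf$fit$spec))
  l1 <- suppressWarnings(compute_loo(sf$fit))
  l2 <- suppressWarnings(compute_loo(back))
  expect_equal(l1$looic, l2$looic, tolerance = 1e-8)
  unlink(dir, recursive = TRUE)
})

test_that("group-level posteriors are calibrated on a known-truth cohort", {
  # 40 subjects x 150 trials simulated from the effort population: every
  # group-level posterior mean must land within 3 posterior SDs of the
  # generating hyperparameter
  g <- default_group_parameters("effort")
  subs <- sample_subjects(g, 40, seed = 55)
  spec <- model_spec("parabolic")
  ds <- do.call(rbind, lapply(1:40, function(i) {
    des <- generate_design("effort", seed = 500 + i)
    rec <- simulate_choices(subs[i, ], des, spec, seed = 900 + i)
    rec$participant <- subs$participant[i]
    rec
  }))
  fit <- fit_model(ds, spec, config = mcmc_config(chains = 2, iterations = 1200,
                                                  warmup = 600, seed = 8))
  expect_lt(max(fit$rhat), 1.05)
  truth <- c(`mu_k[1]` = g$mu[["k_self"]], `mu_k[2]` = g$mu[["k_env"]],
             `sig_k[1]` = g$sigma[["k_self"]], `sig_k[2]` = g$sigma[["k_env"]],
             `mu_b[1]` = g$mu[["beta_self"]], `mu_b[2]` = g$mu[["beta_env"]],
             `sig_b[1]` = g$sigma[["beta_self"]], `sig_b[2]` = g$sigma[["beta_env"]])
  gp <- group_posterior(fit)
  z <- abs(gp$mean - truth[gp$parameter]) / gp$sd
  expect_true(all(z < 3))
})

test_that("mixed-task datasets are rejected", {
  coh <- simulate_cohort(cohort_config(n_subjects = 2, seed = 3))
  expect_error(fit_model(coh$trials, model_spec("parabolic")), "one task")
})
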
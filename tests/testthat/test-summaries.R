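test_that("choice proportions count costly choices over non-omitted trials", {
  fx <- data.frame(participant = rep(c("A", "B"), each = 5),
                   task = "effort",
                   recipient = rep(recipients(), 5),
                   cost_level = rep(1:5, 2), reward = rep(c(2, 10), 5),
                   choice = c(rep("costly", 6), rep("baseline", 4)),
                   stringsAsFactors = FALSE)
  expect_equal(choice_proportions(fx)$pooled, 0.6)
  fx2 <- fx; fx2$choice <- "costly"
  expect_equal(choice_proportions(fx2)$pooled, 1.0)
  # omissions are excluded from the denominator by default
  fx3 <- fx; fx3$choice[1] <- "omission"
  expect_equal(choice_proportions(fx3)$pooled, 5 / 9)
  # pooled equals the trial-count weighted mean of per-cell proportions
  coh <- simulate_cohort(cohort_config(n_subjects = 3, seed = 12))
  cp <- choice_proportions(coh$trials, task = "effort")
  expect_equal(cp$pooled,
               sum(cp$per_cell$prop_costly * cp$per_cell$n_trials) /
                 sum(cp$per_cell$n_trials),
               tolerance = 1e-12)
  expect_warning(empty <- choice_proportions(fx[0, ]), "no trials")
  expect_true(attr(empty, "empty"))
})

test_that("omission rates are percentages per task and recipient", {
  coh <- simulate_cohort(cohort_config(n_subjects = 2, omission_rate = 0,
                                       seed = 4))
  om <- omission_rates(coh$trials)
  expect_equal(om$omission_pct, rep(0, 4))
  # 1 omission in 250 trials = 0.4%
  fx <- data.frame(participant = "A", task = "effort", recipient = "self",
                   cost_level = 1, reward = 2,
                   choice = c("omission", rep("baseline", 249)),
                   stringsAsFactors = FALSE)
  expect_equal(omission_rates(fx)$omission_pct, 0.4)
})

test_that("ceiling proportion uses a strict per-participant threshold", {
  mk <- function(id, n_costly) data.frame(
    participant = id, task = "time", recipient = "self", cost_level = 1,
    reward = 2, choice = c(rep("costly", n_costly), rep("baseline", 100 - n_costly)),
    stringsAsFactors = FALSE)
  fx <- rbind(mk("A", 100), mk("B", 96), mk("C", 95), mk("D", 50))
  # 95/100 is not > 0.95: only A and B are at ceiling
  expect_equal(ceiling_proportion(fx, "time"), 0.5)
  expect_equal(ceiling_proportion(fx, "time", threshold = 0.5), 0.75)
  fx_all <- rbind(mk("A", 100), mk("B", 100))
  expect_equal(ceiling_proportion(fx_all, "time"), 1.0)
})

test_that("success rates average per-participant success over chosen-costly trials", {
  mk <- function(id, recip, succ) data.frame(
    participant = id, task = "effort", recipient = recip, cost_level = 1,
    reward = 2, choice = "costly", success = succ, stringsAsFactors = FALSE)
  fx <- rbind(mk("A", "self", c(rep(TRUE, 9), FALSE)),
              mk("A", "environment", rep(TRUE, 10)),
              mk("B", "self", rep(TRUE, 5)),
              mk("B", "environment", c(TRUE, TRUE, FALSE, FALSE)))
  sr <- success_rates(fx)
  a <- sr$per_participant[sr$per_participant$participant == "A", ]
  expect_equal(a$self, 90)
  expect_equal(a$environment, 100)
  expect_equal(unname(sr$mean["self"]), mean(c(90, 100)))
  expect_equal(unname(sr$mean["environment"]), mean(c(100, 50)))
  # a participant with no chosen-costly trials for a recipient is excluded
  fx2 <- rbind(fx, data.frame(participant = "C", task = "effort",
                              recipient = "self", cost_level = 1, reward = 2,
                              choice = "costly", success = TRUE,
                              stringsAsFactors = FALSE))
  expect_warning(sr2 <- success_rates(fx2), "excluded")
  expect_equal(unname(sr2$mean["environment"]), mean(c(100, 50)))
})

test_that("the paired t test matches its closed-form oracle", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # differences (1,2,3,4): t = 2.5 / (sd/sqrt(4)), sd = sqrt(5/3)
  x <- c(2, 4, 6, 8); y <- c(1, 2, 3, 4)
  pt <- paired_t(x, y)
  expect_equal(pt$t, 2.5 / (sqrt(5 / 3) / 2), tolerance = 1e-12)
  expect_equal(pt$df, 3)
  expect_equal(pt$mean_diff, 2.5)
  set.seed(6)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(paired_t(a, b)$t, paired_t_oracle(a, b), tolerance = 1e-10)
  }
  expect_error(paired_t(1, 2), "2 complete pairs")
})

test_that("the signed-rank test matches exact enumeration and rank identities", {
  # all-positive differences, n = 5: V is maximal
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1),
                            alternative = "greater")
  expect_equal(w$V, 15)
  expect_equal(w$p_value, 1 / 32) # only one of 2^5 sign patterns reaches 15
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:8, 1)
    a <- rnorm(n); b <- rnorm(n)
    alt <- sample(c("two.sided", "greater", "less"), 1)
    got <- wilcoxon_signed_rank(a, b, alternative = alt)
    expect_equal(got$p_value, wilcoxon_enum_oracle(a - b, alt),
                 tolerance = 1e-12)
    # V plus the negative-rank sum exhausts n(n+1)/2
    d <- a - b
    vneg <- sum(rank(abs(d))[d < 0])
    expect_equal(got$V + vneg, n * (n + 1) / 2)
  }
})

test_that("Kendall tau matches brute-force pair counting and its symmetries", {
  expect_equal(kendall_tau(1:6, 2 * (1:6))$tau, 1)
  expect_equal(kendall_tau(1:6, rev(1:6))$tau, -1)
  # fixture with a tie
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 3, 5)
  expect_equal(kendall_tau(x, y)$tau, kendall_pair_oracle(x, y),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    a <- sample(1:8, n, replace = TRUE) + runif(n) * (i %% 2) # ties on even i
    b <- sample(1:8, n, replace = TRUE) + runif(n) * (i %% 2)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(kendall_tau(a, b)$tau, kendall_pair_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(kendall_tau(a, b)$tau, kendall_tau(b, a)$tau)
    expect_equal(kendall_tau(-a, b)$tau, -kendall_tau(a, b)$tau)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("the discounting asymmetry feeds the policy-support association", {
  fx <- data.frame(participant = c("A", "B"), k_self = c(0.5, 0.2),
                   k_env = c(0.5, 0.2) - c(0, -0.3) * -1,
                   stringsAsFactors = FALSE)
  kd <- k_difference(data.frame(participant = c("A", "B"),
                                k_self = c(0.5, 0.2), k_env = c(0.5, 0.5)))
  expect_equal(kd$k_diff, c(0, -0.3))
  # generator consistency: positive coupling gives positive tau at n = 1000
  subs <- sample_subjects(default_group_parameters("effort"), 1000, seed = 44)
  q <- simulate_questionnaires(subs, coupling = 0.5, seed = 45)
  kd2 <- k_difference(cbind(subs, task = "effort"))
  expect_gt(kendall_tau(kd2$k_diff, q$policy_support)$tau, 0)
})
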
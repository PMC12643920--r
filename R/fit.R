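#' Prior specification for the hierarchical model
#'
#' Weakly-informative, positivity-preserving defaults for the log-scale
#' hierarchy: group locations (log k, log beta) get Normal(0, 1) priors,
#' group scales get half-Normal(0.5) priors, and each subject's log
#' parameter is normal around its group location.
#'
#' @param location_mean,location_scale Normal prior on each log-scale
#'   group location.
#' @param scale_scale Scale of the half-Normal prior on each group SD.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(location_mean = 0, location_scale = 1, scale_scale = 0.5) {
  stopifnot(location_scale > 0, scale_scale > 0)
  structure(list(location_mean = location_mean,
                 location_scale = location_scale,
                 scale_scale = scale_scale),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults follow common practice for this model class: 4 chains of 2000
#' iterations with the first 1000 discarded as warmup, retaining 4000
#' draws.
#'
#' @param chains Number of chains (>= 2).
#' @param iterations Total iterations per chain.
#' @param warmup Iterations discarded per chain (adaptation + burn-in).
#' @param seed Integer seed; fits with the same data, config and seed are
#'   reproducible draw for draw.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iterations = 2000L, warmup = 1000L,
                        seed = 1L) {
  stopifnot(chains >= 2, warmup < iterations, warmup >= 2)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Library-free polynomial rolling hash (mod a 26-bit prime, so all
# intermediate products stay exactly representable) used to fingerprint
# datasets for provenance checks.
.poly_hash <- function(bytes, base, mod) {
  m <- 1000L
  pow <- numeric(m)
  pow[m] <- 1
  for (i in (m - 1L):1L) pow[i] <- (pow[i + 1L] * base) %% mod
  base_m <- (pow[1L] * base) %% mod
  h <- 0
  starts <- seq(1L, length(bytes), by = m)
  for (s in starts) {
    chunk <- bytes[s:min(s + m - 1L, length(bytes))]
    l <- length(chunk)
    shift <- if (l == m) base_m else pow[m - l]
    # all products stay below 2^53, so double arithmetic is exact
    h <- (h * shift + sum(chunk * pow[(m - l + 1L):m]) %% mod) %% mod
  }
  h
}

.fingerprint <- function(x) {
  txt <- paste(utils::capture.output(utils::write.csv(x, row.names = FALSE)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  sprintf("%07x%07x",
          .poly_hash(bytes, 131, 67108859),
          .poly_hash(bytes, 137, 67108837))
}

# JAGS model text for one spec. KR/BR (1 or 2) give the number of k / beta
# columns; kidx/bidx map each trial onto a column. The subject matrices k
# and b always carry 2 columns so downstream code is structure-agnostic;
# joint structures duplicate their single column.
.jags_model_text <- function(spec, priors) {
  sv <- switch(spec$family,
    linear     = "sv[t] <- R[t] - k[subj[t], kidx[t]] * C[t]",
    parabolic  = "sv[t] <- R[t] - k[subj[t], kidx[t]] * C[t] * C[t]",
    hyperbolic = "sv[t] <- R[t] / (1 + k[subj[t], kidx[t]] * C[t])")
  loc_prec <- 1 / priors$location_scale^2
  scale_prec <- 1 / priors$scale_scale^2
  sprintf("
model {
  for (r in 1:KR) {
    mu_k[r] ~ dnorm(%g, %g)
    sig_k[r] ~ dnorm(0, %g) T(0,)
  }
  for (r in 1:BR) {
    mu_b[r] ~ dnorm(%g, %g)
    sig_b[r] ~ dnorm(0, %g) T(0,)
  }
  for (r in 1:KR) { prec_k[r] <- 1 / (sig_k[r] * sig_k[r]) }
  for (r in 1:BR) { prec_b[r] <- 1 / (sig_b[r] * sig_b[r]) }
  for (s in 1:N) {
    for (r in 1:KR) {
      lk[s, r] ~ dnorm(mu_k[r], prec_k[r])
      kraw[s, r] <- exp(lk[s, r])
    }
    for (r in 1:BR) {
      lb[s, r] ~ dnorm(mu_b[r], prec_b[r])
      braw[s, r] <- exp(lb[s, r])
    }
    for (r in 1:2) {
      k[s, r] <- kraw[s, min(r, KR)]
      b[s, r] <- braw[s, min(r, BR)]
    }
  }
  for (t in 1:Tn) {
    %s
    p[t] <- ilogit(b[subj[t], bidx[t]] * (sv[t] - base))
    y[t] ~ dbern(p[t])
  }
}",
    priors$location_mean, loc_prec, scale_prec,
    priors$location_mean, loc_prec, scale_prec, sv)
}

# Assemble the JAGS data list from a (single-task, omission-free) trial
# table. Returns the list plus the participant ordering used for indexing.
.jags_data <- function(trials, spec) {
  participants <- sort(unique(trials$participant))
  subj <- match(trials$participant, participants)
  KR <- if (spec$k_structure == "separate") 2L else 1L
  BR <- if (spec$beta_structure == "separate") 2L else 1L
  recip <- ifelse(trials$recipient == "environment", 2L, 1L)
  list(data = list(N = length(participants), Tn = nrow(trials),
                   KR = KR, BR = BR,
                   subj = subj,
                   kidx = if (KR == 2L) recip else rep(1L, nrow(trials)),
                   bidx = if (BR == 2L) recip else rep(1L, nrow(trials)),
                   C = as.numeric(trials$cost_level),
                   R = as.numeric(trials$reward),
                   base = baseline_reward(),
                   y = as.integer(trials$choice == "costly")),
       participants = participants)
}

#' Fit a discounting model by hierarchical Bayesian MCMC
#'
#' Fits one [model_spec()] to the non-omitted trials of a single task via
#' JAGS, with a centered log-normal hierarchy over subjects, and
#' returns the retained draws, split R-hat per monitored parameter, and
#' the pointwise log-likelihood matrix needed for PSIS-LOO comparison.
#'
#' @param dataset Trial table for one task (columns `participant`,
#'   `recipient`, `cost_level`, `reward`, `choice`). Omitted trials are
#'   dropped before fitting.
#' @param spec A `model_spec`.
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `posterior_fit` with elements
#'   \describe{
#'     \item{draws}{matrix, retained draws (chains stacked) x parameters}
#'     \item{chains,iter_per_chain}{chain bookkeeping for diagnostics}
#'     \item{rhat}{named vector of split R-hat values}
#'     \item{loglik}{draws x trials pointwise log-likelihood matrix}
#'     \item{spec,config,participants,fingerprint,task}{provenance}
#'   }
#' @export
fit_model <- function(dataset, spec, priors = prior_spec(),
                      config = mcmc_config(), quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  task <- unique(dataset$task)
  if (length(task) > 1L)
    stop("fit one task at a time; dataset mixes ", paste(task, collapse = ", "),
         call. = FALSE)
  trials <- dataset[dataset$choice != "omission", , drop = FALSE]
  if (nrow(trials) < 2L) stop("need at least 2 non-omitted trials", call. = FALSE)
  jd <- .jags_data(trials, spec)
  model_text <- .jags_model_text(spec, priors)

  inits <- lapply(seq_len(config$chains), function(ch) {
    set.seed(config$seed + 7L * ch)
    mu_k0 <- stats::rnorm(jd$data$KR, priors$location_mean, 0.3)
    mu_b0 <- stats::rnorm(jd$data$BR, priors$location_mean, 0.3)
    list(mu_k = mu_k0,
         sig_k = abs(stats::rnorm(jd$data$KR, 0.3, 0.1)) + 0.05,
         mu_b = mu_b0,
         sig_b = abs(stats::rnorm(jd$data$BR, 0.3, 0.1)) + 0.05,
         lk = matrix(rep(mu_k0, each = jd$data$N) +
                       stats::rnorm(jd$data$N * jd$data$KR, 0, 0.1),
                     jd$data$N, jd$data$KR),
         lb = matrix(rep(mu_b0, each = jd$data$N) +
                       stats::rnorm(jd$data$N * jd$data$BR, 0, 0.1),
                     jd$data$N, jd$data$BR),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + ch)
  })

  n_adapt <- min(500L, max(100L, config$warmup %/% 2L))
  n_burn <- config$warmup - n_adapt
  n_keep <- config$iterations - config$warmup

  fit_once <- function(inits) {
    con <- textConnection(model_text)
    on.exit(close(con))
    jm <- rjags::jags.model(con, data = jd$data, inits = inits,
                            n.chains = config$chains, n.adapt = n_adapt,
                            quiet = quiet)
    if (n_burn > 0L) stats::update(jm, n_burn, progress.bar = "none")
    rjags::coda.samples(jm, c("mu_k", "sig_k", "mu_b", "sig_b", "k", "b"),
                        n.iter = n_keep, progress.bar = "none")
  }
  samples <- NULL
  for (try in 1:5) {
    samples <- tryCatch(fit_once(inits), error = function(e) e)
    if (!inherits(samples, "error")) break
    # re-initialize closer to the prior center with a shifted RNG stream
    inits <- lapply(inits, function(ii) {
      ii$.RNG.seed <- ii$.RNG.seed + 101L
      ii$lk[] <- priors$location_mean; ii$lb[] <- priors$location_mean
      ii
    })
  }
  if (inherits(samples, "error"))
    stop("MCMC failed after 5 re-initializations: ",
         conditionMessage(samples), call. = FALSE)

  rhat <- compute_rhat(samples)
  draws <- do.call(rbind, lapply(samples, as.matrix))
  loglik <- .pointwise_loglik(draws, trials, jd$participants, spec)

  structure(list(draws = draws,
                 chains = config$chains,
                 iter_per_chain = n_keep,
                 rhat = rhat,
                 loglik = loglik,
                 spec = spec, config = config,
                 participants = jd$participants,
                 task = task,
                 fingerprint = .fingerprint(trials[, c("participant", "recipient",
                                                       "cost_level", "reward",
                                                       "choice")])),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("posterior_fit: %s, task %s, %d subjects, %d draws, max Rhat %.3f\n",
              model_name(x$spec), x$task, length(x$participants),
              nrow(x$draws), max(x$rhat)))
  invisible(x)
}

# Pointwise log-likelihood (retained draws x non-omitted trials), computed
# in R from the monitored subject-level k and b draws with the same
# likelihood as trial_loglik().
.pointwise_loglik <- function(draws, trials, participants, spec) {
  subj <- match(trials$participant, participants)
  recip <- ifelse(trials$recipient == "environment", 2L, 1L)
  kcol <- match(sprintf("k[%d,%d]", subj, recip), colnames(draws))
  bcol <- match(sprintf("b[%d,%d]", subj, recip), colnames(draws))
  K <- draws[, kcol, drop = FALSE]
  B <- draws[, bcol, drop = FALSE]
  Rm <- matrix(trials$reward, nrow(draws), nrow(trials), byrow = TRUE)
  Cm <- matrix(trials$cost_level, nrow(draws), nrow(trials), byrow = TRUE)
  sv <- switch(spec$family,
               linear = Rm - K * Cm,
               parabolic = Rm - K * Cm^2,
               hyperbolic = Rm / (1 + K * Cm))
  x <- B * (sv - baseline_reward())
  sign <- matrix(ifelse(trials$choice == "costly", 1, -1),
                 nrow(draws), nrow(trials), byrow = TRUE)
  matrix(stats::plogis(as.vector(sign * x), log.p = TRUE),
         nrow(draws), nrow(trials))
}

#' Split R-hat convergence diagnostic
#'
#' Classical split R-hat: each retained chain is split in half, and the
#' ratio of pooled to within-half variance is reported per parameter.
#' Values near 1 indicate the chains are sampling the same distribution;
#' fits are conventionally accepted when all values are < 1.05. A
#' parameter with zero total variance is reported as exactly 1 with a
#' `"constant"` attribute flag.
#'
#' @param samples An [coda::mcmc.list], or a list of equally sized
#'   iterations x parameters matrices (one per chain).
#' @return Named numeric vector of R-hat values.
#' @export
compute_rhat <- function(samples) {
  mats <- lapply(samples, as.matrix)
  stopifnot(length(mats) >= 2L, nrow(mats[[1]]) >= 4L)
  half <- nrow(mats[[1]]) %/% 2L
  halves <- list()
  for (m in mats) {
    halves[[length(halves) + 1L]] <- m[seq_len(half), , drop = FALSE]
    halves[[length(halves) + 1L]] <- m[(half + 1L):(2L * half), , drop = FALSE]
  }
  n <- half; m_ch <- length(halves)
  out <- vapply(seq_len(ncol(mats[[1]])), function(j) {
    x <- vapply(halves, function(h) h[, j], numeric(n)) # n x m
    means <- colMeans(x)
    vars <- apply(x, 2, stats::var)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0 && B == 0) return(1)
    if (W == 0) return(Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
  names(out) <- colnames(mats[[1]])
  if (any(!is.finite(out))) attr(out, "flag") <- "zero within-chain variance"
  out
}

#' Posterior-mean subject-level parameter estimates
#'
#' Posterior means of each subject's k and beta on the constrained
#' (positive) scale, one row per participant. Under joint structures the
#' self and environment columns are identical by construction.
#'
#' @param fit A `posterior_fit`.
#' @return `data.frame` with columns `participant`, `k_self`, `k_env`,
#'   `beta_self`, `beta_env`.
#' @export
subject_point_estimates <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  n <- length(fit$participants)
  mean_of <- function(pat)
    vapply(seq_len(n), function(s)
      mean(fit$draws[, sprintf(pat, s)]), 0)
  data.frame(participant = fit$participants,
             k_self = mean_of("k[%d,1]"), k_env = mean_of("k[%d,2]"),
             beta_self = mean_of("b[%d,1]"), beta_env = mean_of("b[%d,2]"),
             stringsAsFactors = FALSE)
}

#' Posterior summaries of the group-level hyperparameters
#'
#' @param fit A `posterior_fit`.
#' @return `data.frame` with one row per hyperparameter: posterior mean,
#'   SD and 95% HDI limits.
#' @export
group_posterior <- function(fit) {
  cols <- grep("^(mu|sig)_", colnames(fit$draws), value = TRUE)
  do.call(rbind, lapply(cols, function(cn) {
    h <- hdi(fit$draws[, cn], 0.95)
    data.frame(parameter = cn, mean = mean(fit$draws[, cn]),
               sd = stats::sd(fit$draws[, cn]),
               hdi_lower = h[1], hdi_upper = h[2],
               stringsAsFactors = FALSE)
  }))
}

#' Persist / restore a posterior fit as plain files
#'
#' Writes the retained draws and pointwise log-likelihood as CSV and the
#' diagnostics, configuration and dataset fingerprint as JSON into a
#' directory.
#'
#' @param fit A `posterior_fit`.
#' @param dir Target directory (created if needed).
#' @return `dir` invisibly (`save_fit`); a `posterior_fit` (`load_fit`).
#' @export
save_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(fit$draws), file.path(dir, "draws.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$loglik), file.path(dir, "loglik.csv"),
                   row.names = FALSE)
  meta <- list(model = model_name(fit$spec), task = fit$task,
               chains = fit$chains, iter_per_chain = fit$iter_per_chain,
               participants = fit$participants,
               rhat = as.list(fit$rhat),
               config = unclass(fit$config),
               fingerprint = fit$fingerprint)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_fit
#' @export
load_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  draws <- as.matrix(utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE))
  loglik <- as.matrix(utils::read.csv(file.path(dir, "loglik.csv"), check.names = FALSE))
  cfg <- mcmc_config(meta$config$chains, meta$config$iterations,
                     meta$config$warmup, meta$config$seed)
  structure(list(draws = draws, chains = meta$chains,
                 iter_per_chain = meta$iter_per_chain,
                 rhat = unlist(meta$rhat), loglik = unname(loglik),
                 spec = parse_model_name(meta$model), config = cfg,
                 participants = meta$participants, task = meta$task,
                 fingerprint = meta$fingerprint),
            class = "posterior_fit")
}
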
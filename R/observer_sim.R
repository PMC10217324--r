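# Synthetic observer: stimuli with consensus malignancy scores, and trial
# sequences from a signal-detection observer carrying a similarity-tuned,
# lag-decaying attractive history bias.

#' Simulation configuration
#'
#' Bundles the stimulus-pool and sequencing parameters used by
#' [generate_stimuli()] and [simulate_trials()]. Defaults reproduce the
#' dermatology-app study conditions this package emulates: a 42.7% malignant /
#' 57.3% benign stimulus mix, consensus malignancy scores spread over
#' \[-100, 100\] by a 25-voter popularity vote, and per-user random stimulus
#' sequences.
#'
#' @param n_images Number of stimuli in the pool.
#' @param p_malignant Probability that a stimulus is truly malignant.
#' @param mu_benign,mu_malignant Class-conditional means of the latent
#'   malignancy evidence (unitless evidence axis).
#' @param sigma_evidence Class-conditional SD of the latent evidence.
#' @param k_raters Number of simulated independent voters per image used to
#'   build the consensus malignancy score.
#' @param rater_sigma Internal noise SD of each simulated voter.
#' @param rater_criterion Decision criterion of each simulated voter on the
#'   evidence axis.
#' @param n_users Number of simulated observers.
#' @param trials_per_user Trials in each observer's sequence.
#' @param replace Sample each user's stimulus sequence with replacement
#'   (the default; the source app's scheme is unknown, so this is exposed).
#' @param trial_interval_s Seconds between consecutive simulated trials
#'   (used only to stamp timestamps; all trials fall in one session under the
#'   default 30-minute session gap).
#' @param seed Integer seed; every random draw in the simulator descends from
#'   it, so identical configs give bit-identical tables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_images = 2000L,
                       p_malignant = 0.427,
                       mu_benign = -1,
                       mu_malignant = 1,
                       sigma_evidence = 1,
                       k_raters = 25L,
                       rater_sigma = 0.8,
                       rater_criterion = -0.05,
                       n_users = 100L,
                       trials_per_user = 500L,
                       replace = TRUE,
                       trial_interval_s = 20,
                       seed = 1L) {
  cfg <- list(
    n_images = as.integer(n_images), p_malignant = p_malignant,
    mu_benign = mu_benign, mu_malignant = mu_malignant,
    sigma_evidence = sigma_evidence, k_raters = as.integer(k_raters),
    rater_sigma = rater_sigma, rater_criterion = rater_criterion,
    n_users = as.integer(n_users), trials_per_user = as.integer(trials_per_user),
    replace = isTRUE(replace), trial_interval_s = trial_interval_s,
    seed = as.integer(seed)
  )
  if (cfg$n_images < 1L || cfg$k_raters < 1L) {
    abort("n_images and k_raters must be positive", class = "serialdep_invalid_config")
  }
  if (cfg$p_malignant < 0 || cfg$p_malignant > 1) {
    abort("p_malignant must lie in [0, 1]", class = "serialdep_invalid_config")
  }
  if (cfg$sigma_evidence <= 0 || cfg$rater_sigma <= 0) {
    abort("evidence and rater noise SDs must be positive", class = "serialdep_invalid_config")
  }
  if (cfg$n_users < 1L || cfg$trials_per_user < 1L) {
    abort("n_users and trials_per_user must be positive", class = "serialdep_invalid_config")
  }
  structure(cfg, class = "sim_config")
}

#' Observer parameters
#'
#' Parameters of the simulated signal-detection observer. With `A1 = 0` the
#' observer is bias-free; with `A1 > 0` an attractive history bias is added on
#' the evidence axis, tuned to the malignancy difference between the current
#' and each of the `max_lag` preceding stimuli and decaying geometrically with
#' lag.
#'
#' @param sigma_obs Internal noise SD (> 0), evidence units.
#' @param criterion Baseline decision criterion on the evidence axis; responses
#'   are "malignant" when the internal signal exceeds it.
#' @param A1 Lag-1 bias strength, evidence units. `A1 = 0` disables the bias.
#' @param rho Per-lag geometric decay of the bias strength, in \[0, 1\];
#'   the lag-n strength is `A1 * rho^(n-1)`.
#' @param sigma_w Tuning width of the bias in malignancy-difference units; the
#'   attraction is maximal when the previous stimulus differs by `sigma_w`.
#' @param lapse Probability of replacing the decision with a fair coin flip.
#' @param max_lag Number of past trials contributing bias (0 disables).
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(sigma_obs = 0.8,
                            criterion = -0.05,
                            A1 = 0.5,
                            rho = 0.55,
                            sigma_w = 60,
                            lapse = 0.02,
                            max_lag = 4L) {
  if (sigma_obs <= 0) abort("sigma_obs must be > 0", class = "serialdep_invalid_config")
  if (rho < 0 || rho > 1) abort("rho must lie in [0, 1]", class = "serialdep_invalid_config")
  if (sigma_w <= 0) abort("sigma_w must be > 0", class = "serialdep_invalid_config")
  if (lapse < 0 || lapse > 1) abort("lapse must lie in [0, 1]", class = "serialdep_invalid_config")
  if (max_lag < 0) abort("max_lag must be >= 0", class = "serialdep_invalid_config")
  structure(list(sigma_obs = sigma_obs, criterion = criterion, A1 = A1,
                 rho = rho, sigma_w = sigma_w, lapse = lapse,
                 max_lag = as.integer(max_lag)),
            class = "observer_params")
}

#' Generate a stimulus pool with consensus malignancy scores
#'
#' Draws `n_images` stimuli: a true label (Bernoulli `p_malignant`), latent
#' malignancy evidence (class-conditional normal), and a consensus malignancy
#' score `M` in \[-100, 100\] built from a popularity vote of `k_raters`
#' simulated voters. Each voter responds "malignant" when the stimulus
#' evidence plus independent normal noise exceeds the voter criterion; the
#' vote count is therefore drawn in one step as
#' `Binomial(k_raters, pnorm((evidence - rater_criterion) / rater_sigma))`,
#' which is distributionally identical to looping over voters. `M` is the
#' scaled vote difference `100 * (n_malignant - n_benign) / k_raters`, so
#' `M = 100` exactly when all voters say malignant and `M = -100` when all
#' say benign.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override; defaults to `config$seed`.
#' @return A tibble with columns `stimulus_id`, `true_label`, `evidence`,
#'   `malignancy`.
#' @export
generate_stimuli <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed %||% config$seed, {
    n <- config$n_images
    lab <- ifelse(runif(n) < config$p_malignant, "malignant", "benign")
    mu <- ifelse(lab == "malignant", config$mu_malignant, config$mu_benign)
    ev <- rnorm(n, mu, config$sigma_evidence)
    p_vote <- pnorm((ev - config$rater_criterion) / config$rater_sigma)
    votes <- rbinom(n, config$k_raters, p_vote)
    tibble::tibble(
      stimulus_id = sprintf("s%05d", seq_len(n)),
      true_label = lab,
      evidence = ev,
      malignancy = consensus_malignancy(votes, config$k_raters)
    )
  })
}

#' Similarity-tuned attraction toward the previous stimulus
#'
#' Derivative-of-Gaussian bias kernel on the malignancy-difference axis:
#' `strength * (delta_m / sigma_w) * exp(-delta_m^2 / (2 * sigma_w^2))`.
#' It is zero for identical stimuli, maximal in magnitude at
#' `|delta_m| = sigma_w` (where it equals `strength * exp(-1/2)`), vanishes for
#' very different stimuli, and is odd in `delta_m`, so the pull is always
#' toward the previous stimulus.
#'
#' @param delta_m Signed malignancy difference, previous minus current.
#' @param strength Peak scale of the bias (evidence units when used by the
#'   observer).
#' @param sigma_w Tuning width (> 0), malignancy-difference units.
#' @return Numeric vector of bias values.
#' @export
serial_bias <- function(delta_m, strength = 1, sigma_w = 60) {
  if (sigma_w <= 0) abort("sigma_w must be > 0", class = "serialdep_invalid_parameter")
  strength * (delta_m / sigma_w) * exp(-delta_m^2 / (2 * sigma_w^2))
}

#' Simulate trial sequences from a biased signal-detection observer
#'
#' Each user receives an independent random sequence of stimuli from the pool.
#' On trial t the internal signal is the stimulus evidence plus internal noise
#' plus the summed history bias
#' `sum_n A1 * rho^(n-1) * serial_bias(M[t-n] - M[t], 1, sigma_w)` over lags
#' `1..max_lag` (terms with no lag-n predecessor contribute nothing). The
#' response is "malignant" iff the signal exceeds the observer criterion,
#' overridden by a fair coin with probability `lapse`. The bias only alters
#' responses, never the stimulus stream.
#'
#' @param pool Stimulus tibble from [generate_stimuli()].
#' @param obs An [observer_params()].
#' @param config A [sim_config()].
#' @param seed Optional seed override; defaults to `config$seed + 1` so the
#'   trial stream is distinct from, but still determined by, the config seed.
#' @return A tibble with columns `user_id`, `seq_index` (0-based, strictly
#'   increasing within user), `timestamp` (ISO-8601), `stimulus_id`,
#'   `true_label`, `response` — the schema consumed by [read_trials()] and the
#'   analysis functions.
#' @export
simulate_trials <- function(pool, obs = observer_params(), config = sim_config(),
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(obs, "observer_params"))
  if (nrow(pool) == 0) abort("stimulus pool is empty", class = "serialdep_invalid_config")
  if (config$trials_per_user <= obs$max_lag) {
    warn("trials_per_user <= max_lag: sequences too short to analyze any lag")
  }
  withr::with_seed(seed %||% (config$seed + 1L), {
    n_users <- config$n_users
    tpu <- config$trials_per_user
    n <- n_users * tpu
    user <- rep(seq_len(n_users), each = tpu)
    idx <- if (config$replace) {
      sample.int(nrow(pool), n, replace = TRUE)
    } else {
      if (tpu > nrow(pool)) {
        abort("trials_per_user exceeds pool size with replace = FALSE",
              class = "serialdep_invalid_config")
      }
      as.vector(vapply(seq_len(n_users),
                       function(u) sample.int(nrow(pool), tpu),
                       integer(tpu)))
    }
    M <- pool$malignancy[idx]
    bias <- numeric(n)
    if (obs$A1 != 0 && obs$max_lag >= 1L) {
      for (k in seq_len(obs$max_lag)) {
        if (n <= k) break
        j <- (k + 1L):n
        ok <- j[user[j] == user[j - k]]
        if (length(ok)) {
          bias[ok] <- bias[ok] + obs$A1 * obs$rho^(k - 1) *
            serial_bias(M[ok - k] - M[ok], 1, obs$sigma_w)
        }
      }
    }
    x <- pool$evidence[idx] + rnorm(n, 0, obs$sigma_obs) + bias
    resp <- ifelse(x > obs$criterion, "malignant", "benign")
    if (obs$lapse > 0) {
      lap <- runif(n) < obs$lapse
      resp[lap] <- ifelse(runif(n)[lap] < 0.5, "malignant", "benign")
    }
    t0 <- as.POSIXct("2021-01-04 09:00:00", tz = "UTC")
    stamp <- t0 + (user - 1) * 86400 + (rep(seq_len(tpu), n_users) - 1) * config$trial_interval_s
    tibble::tibble(
      user_id = sprintf("u%04d", user),
      seq_index = rep(seq_len(tpu), n_users) - 1L,
      timestamp = format(stamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      stimulus_id = pool$stimulus_id[idx],
      true_label = pool$true_label[idx],
      response = resp
    )
  })
}
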
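# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use plain row-by-row loops and never share code with the
# package's vectorized engine.

# Per-bin confusion counts by looping over trials: the current trial's
# outcome lands in the bin of its |M_partner - M_current| similarity, where
# the partner is the lag-n predecessor (past) or the next trial (future),
# and must share user and session. Returns an n_bins x 4 matrix with columns
# (tn, fp, fn, tp).
oracle_conditional_counts <- function(trials, stimuli, lag, binspec,
                                      direction = "past") {
  M <- setNames(stimuli$malignancy, stimuli$stimulus_id)
  if (!"session_id" %in% names(trials)) trials$session_id <- 0L
  trials <- trials[order(trials$user_id, trials$session_id, trials$seq_index), ]
  counts <- matrix(0L, binspec$n_bins, 4)
  for (i in seq_len(nrow(trials))) {
    j <- if (direction == "past") i - lag else i + 1
    if (j < 1 || j > nrow(trials)) next
    if (trials$user_id[j] != trials$user_id[i]) next
    if (trials$session_id[j] != trials$session_id[i]) next
    v <- abs(M[[trials$stimulus_id[j]]] - M[[trials$stimulus_id[i]]])
    if (v < binspec$domain_low || v > binspec$domain_high) next
    b <- min(binspec$n_bins, floor((v - binspec$domain_low) / binspec$width) + 1)
    t1 <- trials$true_label[i] == "malignant"
    r1 <- trials$response[i] == "malignant"
    o <- 2 * t1 + r1 + 1
    counts[b, o] <- counts[b, o] + 1L
  }
  counts
}

# Per-trial n-back similarity by looping (cross-check for nback_similarity).
oracle_nback <- function(trials, stimuli, lag) {
  M <- setNames(stimuli$malignancy, stimuli$stimulus_id)
  if (!"session_id" %in% names(trials)) trials$session_id <- 0L
  trials <- trials[order(trials$user_id, trials$session_id, trials$seq_index), ]
  out <- rep(NA_real_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    j <- i - lag
    if (j < 1) next
    if (trials$user_id[j] != trials$user_id[i]) next
    if (trials$session_id[j] != trials$session_id[i]) next
    out[i] <- abs(M[[trials$stimulus_id[j]]] - M[[trials$stimulus_id[i]]])
  }
  out
}

# Random small trial table + stimulus table for property tests.
random_fixture <- function(n_trials, n_users = 3, n_stimuli = 12,
                           n_sessions = 2, seed = 1) {
  withr::with_seed(seed, {
    stimuli <- tibble::tibble(
      stimulus_id = sprintf("s%03d", seq_len(n_stimuli)),
      true_label = sample(c("benign", "malignant"), n_stimuli, replace = TRUE),
      malignancy = round(runif(n_stimuli, -100, 100), 1)
    )
    user <- sort(sample(sprintf("u%02d", seq_len(n_users)), n_trials, replace = TRUE))
    trials <- tibble::tibble(
      user_id = user,
      session_id = sample(seq_len(n_sessions), n_trials, replace = TRUE) - 1L,
      stimulus_id = sample(stimuli$stimulus_id, n_trials, replace = TRUE),
      response = sample(c("benign", "malignant"), n_trials, replace = TRUE)
    )
    trials$true_label <- stimuli$true_label[match(trials$stimulus_id, stimuli$stimulus_id)]
    trials <- trials[order(trials$user_id, trials$session_id), ]
    trials$seq_index <- as.integer(stats::ave(seq_len(n_trials),
                                              paste(trials$user_id, trials$session_id),
                                              FUN = seq_along)) - 1L
    trials$timestamp <- NA_character_
    list(trials = trials, stimuli = stimuli)
  })
}

# Small deterministic trial table with explicit timestamps.
toy_trials <- function() {
  tibble::tibble(
    user_id = rep("u01", 6),
    seq_index = 0:5,
    timestamp = sprintf("2021-01-04T09:%02d:00Z", c(0, 1, 2, 3, 4, 5)),
    stimulus_id = sprintf("s%03d", 1:6),
    true_label = c("benign", "malignant", "benign", "malignant", "benign", "malignant"),
    response = c("benign", "malignant", "malignant", "malignant", "benign", "benign")
  )
}
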
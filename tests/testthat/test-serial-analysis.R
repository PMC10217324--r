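# Conditional metrics, net change against the future baseline, permutations,
# and the semantic super-group contrast.

test_that("a hand-computed six-trial table gives the hand-computed per-bin error rates", {
  stimuli <- tibble::tibble(
    stimulus_id = letters[1:6], true_label = "benign",
    malignancy = c(0, 5, 100, 110, -50, 60)
  )
  trials <- tibble::tibble(
    user_id = "u1", seq_index = 0:5, timestamp = NA_character_,
    stimulus_id = letters[1:6],
    true_label = c("benign", "benign", "malignant", "benign", "malignant", "benign"),
    response   = c("benign", "benign", "benign", "malignant", "malignant", "malignant")
  )
  # lag-1 similarities: 5, 95, 10, 160, 110 -> bins 1, 10, 2, 17, 12;
  # trial correctness in those bins: right, wrong, wrong, right, wrong
  cm <- conditional_metrics(trials, stimuli, lag = 1, binspec = malignancy_bins())
  expect_equal(cm$error_rate[cm$bin == 1], 0)
  expect_equal(cm$error_rate[cm$bin == 10], 1)
  expect_equal(cm$error_rate[cm$bin == 2], 1)
  expect_equal(cm$error_rate[cm$bin == 17], 0)
  expect_equal(cm$error_rate[cm$bin == 12], 1)
  expect_equal(sum(cm$n), 5)  # the first trial has no predecessor
})

test_that("conditional counts match the brute-force oracle on random fixtures", {
  spec <- bin_spec(0, 200, 20)
  for (s in 1:10) {
    fx <- random_fixture(n_trials = 150, n_users = 3, n_sessions = 2, seed = s)
    for (dir in c("past", "future")) {
      lg <- if (dir == "past") sample(1:3, 1) else 1
      got <- conditional_metrics(fx$trials, fx$stimuli, lag = lg,
                                 binspec = spec, direction = dir)
      want <- oracle_conditional_counts(fx$trials, fx$stimuli, lg, spec, dir)
      expect_identical(cbind(got$tn, got$fp, got$fn, got$tp), unname(want))
    }
  }
})

test_that("a single all-covering bin reproduces the unconditional metrics", {
  fx <- random_fixture(100, seed = 7)
  one <- bin_spec(0, 200, 200)
  cm <- conditional_metrics(fx$trials, fx$stimuli, lag = 1, binspec = one)
  with_sim <- nback_similarity(fx$trials, fx$stimuli, lag = 1)
  sub <- with_sim[!is.na(with_sim$similarity), ]
  want <- sdt_metrics(confusion_counts(sub$true_label, sub$response))
  expect_equal(cm$d_prime[1], want$d_prime)
  expect_equal(cm$error_rate[1], want$error_rate)
})

test_that("the last trial of each session contributes nowhere in the future direction", {
  fx <- random_fixture(90, n_users = 3, n_sessions = 2, seed = 11)
  spec <- bin_spec(0, 200, 200)
  cm <- conditional_metrics(fx$trials, fx$stimuli, lag = 1, binspec = spec,
                            direction = "future")
  n_groups <- nrow(unique(fx$trials[, c("user_id", "session_id")]))
  expect_equal(sum(cm$n), nrow(fx$trials) - n_groups)
})

test_that("net change is identically zero against an identical baseline", {
  fx <- random_fixture(100, seed = 2)
  cm <- conditional_metrics(fx$trials, fx$stimuli, lag = 1)
  nc <- net_change(cm, cm)
  # zero wherever defined; rate metrics are defined in every populated bin
  expect_true(all(nc$delta[!nc$excluded] == 0, na.rm = TRUE))
  err <- nc[nc$metric == "error_rate" & !nc$excluded, ]
  expect_true(all(err$delta == 0))
  # mismatched bin specs are rejected
  cm2 <- conditional_metrics(fx$trials, fx$stimuli, lag = 1,
                             binspec = bin_spec(0, 200, 20))
  expect_error(net_change(cm, cm2), class = "serialdep_config_error")
})

test_that("net-change sign conventions map costs correctly", {
  fx <- random_fixture(200, seed = 5)
  res <- serial_dependence(fx$trials, fx$stimuli, lag = 1,
                           binspec = bin_spec(0, 200, 100),
                           n_permutations = 0)
  d <- tibble::as_tibble(res)
  err <- d[d$metric == "error_rate" & !d$excluded, ]
  expect_equal(err$cost, err$delta)
  dp <- d[d$metric == "d_prime" & !d$excluded, ]
  expect_equal(dp$cost, -dp$delta)
  cr <- d[d$metric == "criterion" & !d$excluded, ]
  expect_equal(cr$cost, abs(cr$delta))
})

test_that("permutation results are deterministic given the seed and p-values respect the add-one bound", {
  fx <- random_fixture(200, n_users = 4, seed = 9)
  spec <- bin_spec(0, 200, 50)
  r1 <- permutation_null(fx$trials, fx$stimuli, lag = 1, binspec = spec,
                         metric = "error_rate", n_permutations = 30, seed = 77)
  r2 <- permutation_null(fx$trials, fx$stimuli, lag = 1, binspec = spec,
                         metric = "error_rate", n_permutations = 30, seed = 77)
  expect_identical(r1$null_upper95, r2$null_upper95)
  expect_identical(r1$p_value, r2$p_value)
  ok <- !is.na(r1$p_value)
  expect_true(all(r1$p_value[ok] >= 1 / 31))
  expect_true(all(r1$p_value[ok] <= 1))
  expect_error(permutation_null(fx$trials, fx$stimuli, n_permutations = 0),
               class = "serialdep_config_error")
})

test_that("the global-baseline mode subtracts one unconditional future metric", {
  fx <- random_fixture(150, seed = 13)
  spec <- bin_spec(0, 200, 100)
  res <- serial_dependence(fx$trials, fx$stimuli, lag = 1, binspec = spec,
                           n_permutations = 0, baseline = "global")
  d <- tibble::as_tibble(res)
  past <- conditional_metrics(fx$trials, fx$stimuli, lag = 1, binspec = spec)
  fut <- conditional_metrics(fx$trials, fx$stimuli, lag = 1, binspec = spec,
                             direction = "future")
  glob <- sdt_metrics(tibble::tibble(tp = sum(fut$tp), fn = sum(fut$fn),
                                     fp = sum(fut$fp), tn = sum(fut$tn)))
  err <- d[d$metric == "error_rate", ]
  expect_equal(err$delta, past$error_rate - glob$error_rate)
})

test_that("constant semantic scores degenerate to a single super-group with a warning", {
  fx <- random_fixture(80, seed = 4)
  const_scores <- function(a, b) rep(0.5, length(a))
  expect_warning(
    sg <- supergroup_analysis(fx$trials, fx$stimuli, const_scores,
                              n_permutations = 10, seed = 1),
    "empty super-group"
  )
  ct <- attr(sg, "contrast")
  expect_true(all(is.na(ct$contrast)))
})

test_that("a similarity-tuned bias costs more in the similar semantic super-group", {
  cfg <- sim_config(n_images = 600, n_users = 100, trials_per_user = 300, seed = 31)
  pool <- generate_stimuli(cfg)
  # a strong, narrowly tuned bias keeps the cost bump inside the similar half
  tr <- simulate_trials(pool, observer_params(A1 = 1.2, sigma_w = 30, lapse = 0), cfg)
  M <- setNames(pool$malignancy, pool$stimulus_id)
  # semantic score increasing in malignancy difference, so low score = similar
  score_fun <- function(a, b) 0.3 + 0.38 * abs(M[a] - M[b]) / 200
  sg <- supergroup_analysis(tr, pool, score_fun, lag = 1,
                            n_permutations = 200, seed = 8)
  ct <- attr(sg, "contrast")
  err <- ct[ct$metric == "error_rate", ]
  expect_gt(err$contrast, 0)
  expect_lt(err$p_value, 0.1)
})

test_that("semantic scores unrelated to the bias produce a null contrast", {
  cfg <- sim_config(n_images = 400, n_users = 40, trials_per_user = 200, seed = 17)
  pool <- generate_stimuli(cfg)
  tr <- simulate_trials(pool, observer_params(A1 = 0.8, lapse = 0), cfg)
  rand_score <- withr::with_seed(99, setNames(runif(nrow(pool), 0.3, 0.68),
                                              pool$stimulus_id))
  score_fun <- function(a, b) (rand_score[a] + rand_score[b]) / 2
  sg <- supergroup_analysis(tr, pool, score_fun, lag = 1,
                            n_permutations = 100, seed = 8)
  ct <- attr(sg, "contrast")
  expect_gt(ct$p_value[ct$metric == "error_rate"], 0.01)
})
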
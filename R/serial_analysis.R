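# Core inference: per-similarity-bin conditional metrics at lag n, net change
# against the future-trial (N+1) baseline, and permutation null distributions.
#
# The permutation scheme shuffles trial order within user x session keeping
# (stimulus, response) pairs intact: marginal accuracy, response bias and the
# stimulus mix are preserved while the sequential structure — the quantity
# under test — is destroyed.

# Validate a trial table against a stimulus table and flatten it into the
# vectors the counting engine consumes, ordered by user, session, seq_index.
.analysis_frame <- function(trials, stimuli) {
  trials <- tibble::as_tibble(trials)
  need <- c("user_id", "seq_index", "stimulus_id", "true_label", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    abort(paste0("trials lack column(s): ", paste(miss, collapse = ", ")),
          class = "serialdep_schema_error")
  }
  if (!"session_id" %in% names(trials)) trials$session_id <- 0L
  trials <- dplyr::arrange(trials, .data$user_id, .data$session_id, .data$seq_index)
  S <- match(trials$stimulus_id, stimuli$stimulus_id)
  if (anyNA(S)) {
    bad <- trials$stimulus_id[which(is.na(S))[1]]
    abort(paste0("unknown stimulus_id '", bad, "' not in stimulus table"),
          class = "serialdep_lookup_error")
  }
  g <- as.integer(factor(paste(trials$user_id, trials$session_id, sep = "\r")))
  # factor() sorts levels, which matches the row ordering by user then session
  list(trials = trials, S = S, M = stimuli$malignancy,
       truth = trials$true_label == "malignant",
       resp = trials$response == "malignant",
       g = g, n = nrow(trials))
}

# Per-bin confusion counts for one row ordering, conditioning the current
# trial's outcome on the similarity to the lag-n predecessor (past) and to
# the next trial (future baseline). Returns nbins x 4 matrices with outcome
# columns (tn, fp, fn, tp).
.counts_both <- function(S, truth, resp, g, lag, simfun, binfun, nbins) {
  n <- length(S)
  out <- 2L * truth + resp + 1L  # 1 = tn, 2 = fp, 3 = fn, 4 = tp
  count_dir <- function(sim) {
    b <- binfun(sim)
    keep <- !is.na(b)
    m <- tabulate(b[keep] + nbins * (out[keep] - 1L), nbins * 4L)
    matrix(m, nbins, 4L)
  }
  sim_p <- rep(NA_real_, n)
  if (n > lag) {
    j <- (lag + 1L):n
    ok <- j[g[j] == g[j - lag]]
    if (length(ok)) sim_p[ok] <- simfun(S[ok - lag], S[ok])
  }
  sim_f <- rep(NA_real_, n)
  if (n > 1L) {
    j <- seq_len(n - 1L)
    ok <- j[g[j] == g[j + 1L]]
    if (length(ok)) sim_f[ok] <- simfun(S[ok + 1L], S[ok])
  }
  list(past = count_dir(sim_p), future = count_dir(sim_f))
}

# Observed counts plus B within-group order permutations.
# Returns obs = list(past, future) of nbins x 4 matrices and, when B > 0,
# perm = list(past, future) of B x nbins x 4 arrays.
.perm_counts <- function(fr, lag, simfun, binfun, nbins, B, seed) {
  obs <- .counts_both(fr$S, fr$truth, fr$resp, fr$g, lag, simfun, binfun, nbins)
  perm <- NULL
  if (B > 0) {
    perm <- list(past = array(0L, c(B, nbins, 4L)),
                 future = array(0L, c(B, nbins, 4L)))
    withr::with_seed(seed, {
      for (b in seq_len(B)) {
        ord <- order(fr$g, runif(fr$n))  # random order within group; g is unchanged
        cb <- .counts_both(fr$S[ord], fr$truth[ord], fr$resp[ord], fr$g,
                           lag, simfun, binfun, nbins)
        perm$past[b, , ] <- cb$past
        perm$future[b, , ] <- cb$future
      }
    })
  }
  list(obs = obs, perm = perm)
}

# Elementwise metric computation with the 1/(2N) extreme-rate clamp; inputs
# and outputs are plain vectors (callers reshape).
.rate_metrics <- function(tn, fp, fn, tp) {
  npos <- tp + fn
  nneg <- fp + tn
  tot <- npos + nneg
  hr <- tp / npos
  spec <- tn / nneg
  err <- (fn + fp) / tot
  hr_c <- pmin(pmax(hr, 1 / (2 * npos)), 1 - 1 / (2 * npos))
  far_c <- pmin(pmax(fp / nneg, 1 / (2 * nneg)), 1 - 1 / (2 * nneg))
  zh <- suppressWarnings(qnorm(as.vector(hr_c)))
  zf <- suppressWarnings(qnorm(as.vector(far_c)))
  list(sensitivity = as.vector(hr), specificity = as.vector(spec),
       d_prime = zh - zf, criterion = -0.5 * (zh + zf),
       error_rate = as.vector(err))
}

.metrics_from_counts_mat <- function(cmat) {
  .rate_metrics(cmat[, 1], cmat[, 2], cmat[, 3], cmat[, 4])
}

.metrics_from_counts_arr <- function(carr) {
  d <- dim(carr)[1:2]
  lapply(.rate_metrics(carr[, , 1], carr[, , 2], carr[, , 3], carr[, , 4]),
         function(v) matrix(v, d[1], d[2]))
}

#' Conditional signal-detection metrics per similarity bin
#'
#' Accumulates the current trial's confusion counts in the bin of its n-back
#' (or future-trial) malignancy similarity and computes [sdt_metrics()] per
#' bin. The similarity lookup never crosses users or sessions; with
#' `direction = "future"` the last trial of a session contributes nowhere.
#'
#' @param trials Trial tibble.
#' @param stimuli Stimulus tibble with `malignancy` scores.
#' @param lag Positive lag (past direction); the future baseline always uses
#'   the next trial.
#' @param binspec A [bin_spec()]; must cover the similarity domain.
#' @param direction `"past"` or `"future"`.
#' @return A tibble with one row per bin: `bin`, `bin_center`, confusion
#'   counts, metrics, and `excluded` (bins under `min_trials_per_bin`).
#' @export
conditional_metrics <- function(trials, stimuli, lag = 1L,
                                binspec = malignancy_bins(),
                                direction = c("past", "future")) {
  direction <- match.arg(direction)
  stopifnot(inherits(binspec, "bin_spec"))
  with_sim <- nback_similarity(trials, stimuli, lag = lag, direction = direction)
  b <- assign_bins(with_sim$similarity, binspec)
  per_bin <- purrr::map_dfr(seq_len(binspec$n_bins), function(k) {
    rows <- which(!is.na(b) & b == k)
    cc <- confusion_counts(with_sim$true_label[rows], with_sim$response[rows])
    dplyr::bind_cols(tibble::tibble(bin = k), sdt_metrics(cc))
  })
  per_bin$bin_center <- bin_centers(binspec)
  minb <- max(1L, binspec$min_trials_per_bin)
  per_bin$excluded <- per_bin$n < minb
  dplyr::relocate(per_bin, "bin", "bin_center")
}

#' Net change of conditional metrics against the future baseline
#'
#' Bin-wise subtraction of future-conditioned from past-conditioned metrics:
#' `delta = metric_past - metric_future` per bin. The sign convention per
#' metric: for the error rate a positive delta is a serial-dependence cost;
#' for sensitivity, specificity and d-prime a negative delta is a cost; for
#' the criterion the cost is the magnitude of the shift. Bins excluded on
#' either side are excluded in the output.
#'
#' @param past,future Per-bin tibbles from [conditional_metrics()] built with
#'   the same [bin_spec()].
#' @param metrics Metrics to report.
#' @return A long tibble: `metric`, `bin`, `bin_center`, `n_past`,
#'   `n_future`, `delta`, `cost`, `excluded`.
#' @export
net_change <- function(past, future, metrics = .metric_names) {
  .check_metrics(metrics)
  if (!identical(past$bin, future$bin) ||
      !isTRUE(all.equal(past$bin_center, future$bin_center))) {
    abort("past and future tables must share one bin specification",
          class = "serialdep_config_error")
  }
  purrr::map_dfr(metrics, function(m) {
    delta <- past[[m]] - future[[m]]
    excl <- past$excluded | future$excluded
    tibble::tibble(metric = m, bin = past$bin, bin_center = past$bin_center,
                   n_past = past$n, n_future = future$n,
                   delta = ifelse(excl, NA_real_, delta),
                   cost = ifelse(excl, NA_real_, .metric_cost(m, delta)),
                   excluded = excl)
  })
}

#' Serial-dependence analysis at one lag
#'
#' The full per-lag inference: per-bin metrics conditioned on the lag-n
#' similarity and on the future (N+1) similarity, their bin-wise net change,
#' and a permutation null (trial order shuffled within user x session,
#' stimulus–response pairs moving together) giving each bin an upper 95%
#' boundary and a one-sided p-value in the cost direction (add-one
#' estimator, so the smallest attainable p is `1/(B+1)`). Raw p-values are
#' accompanied by Benjamini-Hochberg adjusted ones across bins.
#'
#' @param trials Trial tibble (validated; `session_id` optional).
#' @param stimuli Stimulus tibble with consensus malignancy.
#' @param lag Positive lag.
#' @param binspec A [bin_spec()] over the similarity domain.
#' @param metrics Metrics to analyze.
#' @param n_permutations Number of permutations B (0 skips the null).
#' @param seed Seed for the permutation stream.
#' @param baseline `"binwise"` (future metric per future-similarity bin,
#'   the default) or `"global"` (one unconditional future baseline subtracted
#'   from every bin).
#' @return A tibble of class `serial_dependence`: `metric`, `lag`, `bin`,
#'   `bin_center`, `n_past`, `n_future`, `delta`, `cost`, `null_upper95`,
#'   `p_value`, `p_adj`, `excluded`. Permuted cost curves are retained in the
#'   `"perm_cost"` attribute for tuning-curve null bounds.
#' @export
serial_dependence <- function(trials, stimuli, lag = 1L,
                              binspec = malignancy_bins(),
                              metrics = .metric_names,
                              n_permutations = 1000L, seed = 1L,
                              baseline = c("binwise", "global")) {
  baseline <- match.arg(baseline)
  .check_metrics(metrics)
  stopifnot(inherits(binspec, "bin_spec"))
  if (lag < 1) abort("lag must be >= 1", class = "serialdep_config_error")
  if (n_permutations < 0) abort("n_permutations must be >= 0", class = "serialdep_config_error")
  fr <- .analysis_frame(trials, stimuli)
  Mstim <- fr$M
  simfun <- function(a, b) abs(Mstim[a] - Mstim[b])
  binfun <- function(v) assign_bins(v, binspec)
  nb <- binspec$n_bins
  pc <- .perm_counts(fr, lag, simfun, binfun, nb, n_permutations, seed)

  n_past <- rowSums(pc$obs$past)
  n_future <- rowSums(pc$obs$future)
  minb <- max(1L, binspec$min_trials_per_bin)
  excluded <- n_past < minb | (if (baseline == "binwise") n_future < minb else FALSE)

  past_m <- .metrics_from_counts_mat(pc$obs$past)
  future_m <- if (baseline == "binwise") {
    .metrics_from_counts_mat(pc$obs$future)
  } else {
    glob <- .metrics_from_counts_mat(matrix(colSums(pc$obs$future), 1, 4))
    lapply(glob, function(v) rep(v, nb))
  }

  perm_cost <- list()
  if (n_permutations > 0) {
    pp <- .metrics_from_counts_arr(pc$perm$past)
    pf <- if (baseline == "binwise") {
      .metrics_from_counts_arr(pc$perm$future)
    } else {
      tot <- vapply(1:4, function(o) {
        rowSums(matrix(pc$perm$future[, , o], n_permutations, nb))
      }, numeric(n_permutations))
      gl <- .metrics_from_counts_arr(array(tot, c(n_permutations, 1, 4)))
      lapply(gl, function(m) matrix(m[, 1], n_permutations, nb))
    }
    perm_cost <- lapply(setNames(metrics, metrics), function(m) {
      .metric_cost(m, pp[[m]] - pf[[m]])
    })
  }

  out <- purrr::map_dfr(metrics, function(m) {
    delta <- past_m[[m]] - future_m[[m]]
    delta[excluded] <- NA_real_
    cost <- .metric_cost(m, delta)
    up <- rep(NA_real_, nb)
    pv <- rep(NA_real_, nb)
    if (n_permutations > 0) {
      pm <- perm_cost[[m]]
      for (k in seq_len(nb)) {
        if (excluded[k]) next
        col <- pm[, k]
        nn <- sum(!is.na(col))
        if (nn == 0 || is.na(cost[k])) next
        up[k] <- quantile(col, 0.95, na.rm = TRUE, names = FALSE)
        pv[k] <- (1 + sum(col >= cost[k], na.rm = TRUE)) / (nn + 1)
      }
    }
    tibble::tibble(metric = m, lag = as.integer(lag), bin = seq_len(nb),
                   bin_center = bin_centers(binspec),
                   n_past = n_past, n_future = n_future,
                   delta = delta, cost = cost,
                   null_upper95 = up, p_value = pv,
                   p_adj = stats::p.adjust(pv, method = "BH"),
                   excluded = excluded)
  })
  structure(out,
            class = c("serial_dependence", class(out)),
            binspec = binspec, n_permutations = as.integer(n_permutations),
            seed = as.integer(seed), baseline = baseline,
            perm_cost = perm_cost)
}

#' Permutation null boundary and p-values per bin
#'
#' Convenience wrapper around [serial_dependence()] returning only the null
#' summary: per bin, the upper 95% boundary of the permuted cost-direction
#' net changes and the one-sided add-one p-value.
#'
#' @inheritParams serial_dependence
#' @param metric Single metric name.
#' @return A tibble: `bin`, `bin_center`, `delta`, `cost`, `null_upper95`,
#'   `p_value`.
#' @export
permutation_null <- function(trials, stimuli, lag = 1L,
                             binspec = malignancy_bins(),
                             metric = "error_rate",
                             n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 1) {
    abort("n_permutations must be >= 1", class = "serialdep_config_error")
  }
  res <- serial_dependence(trials, stimuli, lag = lag, binspec = binspec,
                           metrics = metric, n_permutations = n_permutations,
                           seed = seed)
  dplyr::select(tibble::as_tibble(res), "bin", "bin_center", "delta", "cost",
                "null_upper95", "p_value")
}

#' Super-group analysis on semantic similarity
#'
#' Splits sequential image pairs into similar / dissimilar super-groups at
#' the mean semantic score (strictly-below = similar) and computes the net
#' change of each metric within each group against the future baseline, plus
#' the similar-minus-dissimilar cost contrast with its permutation p-value.
#'
#' @param trials Trial tibble.
#' @param stimuli Stimulus tibble.
#' @param scores A [semantic_scores] object covering every sequential pair,
#'   or a vectorized `function(id_a, id_b)` returning scores.
#' @param lag Lag for the past conditioning (default 1).
#' @param n_permutations,seed Permutation settings as in
#'   [serial_dependence()].
#' @param metrics Metrics to analyze.
#' @param threshold Optional fixed split threshold; by default the mean
#'   observed sequential-pair score (set `threshold_pairs = "all"` to use the
#'   mean over all pairs in a score table instead).
#' @param threshold_pairs `"sequential"` or `"all"`.
#' @return A tibble with per-group rows (`metric`, `group`, `n_past`,
#'   `n_future`, `delta`, `cost`, `null_upper95`, `p_value`) carrying the
#'   contrast table in the `"contrast"` attribute and the split threshold in
#'   `"threshold"`.
#' @export
supergroup_analysis <- function(trials, stimuli, scores, lag = 1L,
                                n_permutations = 1000L, seed = 1L,
                                metrics = .metric_names,
                                threshold = NULL,
                                threshold_pairs = c("sequential", "all")) {
  threshold_pairs <- match.arg(threshold_pairs)
  .check_metrics(metrics)
  fr <- .analysis_frame(trials, stimuli)
  sfun <- .score_fun(scores)
  ids <- stimuli$stimulus_id
  pair_score <- function(a, b) sfun(ids[a], ids[b])

  # observed sequential (past) scores determine the default split threshold
  obs_scores <- rep(NA_real_, fr$n)
  if (fr$n > lag) {
    j <- (lag + 1L):fr$n
    ok <- j[fr$g[j] == fr$g[j - lag]]
    if (length(ok)) obs_scores[ok] <- pair_score(fr$S[ok - lag], fr$S[ok])
  }
  if (all(is.na(obs_scores))) {
    abort("no sequential pairs with semantic scores", class = "serialdep_config_error")
  }
  thr <- threshold %||% if (threshold_pairs == "all" && inherits(scores, "semantic_scores")) {
    mean(scores$pairs$score)
  } else {
    mean(obs_scores, na.rm = TRUE)
  }
  binfun <- function(v) ifelse(is.na(v), NA_integer_, ifelse(v < thr, 1L, 2L))
  pc <- .perm_counts(fr, lag, pair_score, binfun, 2L, n_permutations, seed)

  groups <- c("similar", "dissimilar")
  n_past <- rowSums(pc$obs$past)
  n_future <- rowSums(pc$obs$future)
  if (any(n_past == 0)) {
    warn(paste0("empty super-group: ", paste(groups[n_past == 0], collapse = ", "),
                "; contrast undefined"))
  }
  past_m <- .metrics_from_counts_mat(pc$obs$past)
  future_m <- .metrics_from_counts_mat(pc$obs$future)
  perm_cost <- NULL
  if (n_permutations > 0) {
    pp <- .metrics_from_counts_arr(pc$perm$past)
    pf <- .metrics_from_counts_arr(pc$perm$future)
    perm_cost <- lapply(setNames(metrics, metrics),
                        function(m) .metric_cost(m, pp[[m]] - pf[[m]]))
  }
  out <- purrr::map_dfr(metrics, function(m) {
    delta <- past_m[[m]] - future_m[[m]]
    cost <- .metric_cost(m, delta)
    up <- rep(NA_real_, 2L)
    pv <- rep(NA_real_, 2L)
    if (!is.null(perm_cost)) {
      for (k in 1:2) {
        col <- perm_cost[[m]][, k]
        nn <- sum(!is.na(col))
        if (nn == 0 || is.na(cost[k])) next
        up[k] <- quantile(col, 0.95, na.rm = TRUE, names = FALSE)
        pv[k] <- (1 + sum(col >= cost[k], na.rm = TRUE)) / (nn + 1)
      }
    }
    tibble::tibble(metric = m, group = groups, n_past = n_past,
                   n_future = n_future, delta = delta, cost = cost,
                   null_upper95 = up, p_value = pv)
  })
  contrast <- purrr::map_dfr(metrics, function(m) {
    rows <- out[out$metric == m, ]
    cval <- rows$cost[1] - rows$cost[2]
    pv <- NA_real_
    if (!is.null(perm_cost) && !is.na(cval)) {
      pcst <- perm_cost[[m]][, 1] - perm_cost[[m]][, 2]
      nn <- sum(!is.na(pcst))
      if (nn > 0) pv <- (1 + sum(pcst >= cval, na.rm = TRUE)) / (nn + 1)
    }
    tibble::tibble(metric = m, contrast = cval, p_value = pv)
  })
  structure(out, class = c("supergroup_analysis", class(out)),
            contrast = contrast, threshold = thr,
            n_permutations = as.integer(n_permutations), seed = as.integer(seed))
}
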
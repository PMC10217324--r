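# Consensus malignancy, n-back similarity, binning, and semantic similarity
# (precomputed pairwise scores or a classical filter-bank image distance).

#' Consensus malignancy from a popularity vote
#'
#' Maps vote counts to the consensus score `M = 100 * (2k - n) / n` where `k`
#' votes say malignant out of `n`: -100 means unanimously benign, 100
#' unanimously malignant, 0 an even split. Only the endpoints are pinned by
#' the voting construction; the linear vote-difference is the minimal
#' interpolant between them. Odd under vote complement:
#' `M(k, n) = -M(n - k, n)`.
#'
#' @param votes_malignant Number of malignant votes (vectorized).
#' @param votes_total Total votes (>= 1).
#' @return Consensus score(s) in \[-100, 100\].
#' @export
consensus_malignancy <- function(votes_malignant, votes_total) {
  if (any(votes_total < 1)) {
    abort("votes_total must be >= 1", class = "serialdep_undefined_consensus")
  }
  if (any(votes_malignant < 0 | votes_malignant > votes_total)) {
    abort("votes_malignant must lie in [0, votes_total]",
          class = "serialdep_invalid_parameter")
  }
  100 * (2 * votes_malignant - votes_total) / votes_total
}

#' n-back malignancy similarity per trial
#'
#' For each trial with at least `lag` predecessors in the same user session,
#' the unsigned consensus-malignancy difference `|M[t-lag] - M[t]|` in
#' \[0, 200\] (0 = identical successive stimuli, 200 = maximally different);
#' `NA` otherwise. With `direction = "future"` the comparison is with the
#' next trial, `|M[t+1] - M[t]|`, the baseline used by [net_change()]
#' (the future stimulus is unpredictable, so conditioning on it estimates
#' chance-level sequential structure).
#'
#' @param trials Trial tibble (a missing `session_id` means one session per
#'   user).
#' @param stimuli Stimulus tibble supplying `malignancy` per `stimulus_id`.
#' @param lag Positive lag for `direction = "past"`; the future baseline is
#'   always the next trial.
#' @param direction `"past"` or `"future"`.
#' @return `trials` with a `similarity` column added.
#' @export
nback_similarity <- function(trials, stimuli, lag = 1L,
                             direction = c("past", "future")) {
  direction <- match.arg(direction)
  if (direction == "past" && lag < 1) {
    abort("lag must be >= 1", class = "serialdep_config_error")
  }
  fr <- .analysis_frame(trials, stimuli)
  M <- fr$M[fr$S]  # per-trial malignancy
  sim <- rep(NA_real_, fr$n)
  if (direction == "past") {
    if (fr$n > lag) {
      j <- (lag + 1L):fr$n
      ok <- j[fr$g[j] == fr$g[j - lag]]
      sim[ok] <- abs(M[ok - lag] - M[ok])
    }
  } else {
    if (fr$n > 1) {
      j <- seq_len(fr$n - 1L)
      ok <- j[fr$g[j] == fr$g[j + 1L]]
      sim[ok] <- abs(M[ok + 1L] - M[ok])
    }
  }
  out <- fr$trials
  out$similarity <- sim
  out
}

#' Similarity bin specification
#'
#' Half-open bins `[low, low + width)` covering `[domain_low, domain_high]`,
#' with the last bin closed so the domain maximum is binned. The width must
#' divide the domain span into a whole number of bins.
#'
#' @param domain_low,domain_high Domain bounds.
#' @param width Bin width (> 0).
#' @param min_trials_per_bin Bins with fewer occupants are flagged excluded
#'   downstream.
#' @return A list of class `bin_spec` with an `n_bins` element.
#' @export
bin_spec <- function(domain_low, domain_high, width, min_trials_per_bin = 0L) {
  if (width <= 0) abort("width must be > 0", class = "serialdep_config_error")
  k <- (domain_high - domain_low) / width
  if (domain_high <= domain_low || abs(k - round(k)) > 1e-8) {
    abort("width must divide the domain into a whole number of bins",
          class = "serialdep_config_error")
  }
  structure(list(domain_low = domain_low, domain_high = domain_high,
                 width = width, n_bins = as.integer(round(k)),
                 min_trials_per_bin = as.integer(min_trials_per_bin)),
            class = "bin_spec")
}

#' @rdname bin_spec
#' @details `malignancy_bins()` is the canonical malignancy-similarity
#'   grouping: domain \[0, 200\], width 10, 20 bins. `semantic_bins()` is the
#'   canonical semantic grouping: domain \[0.3, 0.68\], width 0.02, 19 bins,
#'   with sparsely populated bins (< 100 trials by default) excluded.
#' @export
malignancy_bins <- function(min_trials_per_bin = 0L) {
  bin_spec(0, 200, 10, min_trials_per_bin)
}

#' @rdname bin_spec
#' @export
semantic_bins <- function(min_trials_per_bin = 100L) {
  bin_spec(0.3, 0.68, 0.02, min_trials_per_bin)
}

#' @rdname bin_spec
#' @param spec A `bin_spec`.
#' @export
bin_centers <- function(spec) {
  spec$domain_low + (seq_len(spec$n_bins) - 0.5) * spec$width
}

#' Assign values to similarity bins
#'
#' Bin index `floor((v - low) / width) + 1` (1-based); values equal to the
#' domain maximum fall in the last (closed) bin; values outside the domain, or
#' missing, get `NA`. Every in-range value maps to exactly one bin.
#'
#' @param values Numeric vector.
#' @param spec A [bin_spec()].
#' @return Integer bin indices in `1..spec$n_bins`, or `NA`.
#' @export
assign_bins <- function(values, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  idx <- floor((values - spec$domain_low) / spec$width) + 1
  idx[values == spec$domain_high] <- spec$n_bins
  idx[values < spec$domain_low | values > spec$domain_high] <- NA
  as.integer(idx)
}

#' Pairwise semantic-similarity scores
#'
#' Container for a symmetric pairwise distance over stimuli (0 = identical;
#' larger = more different), as produced by a perceptual image-similarity
#' metric. Scores are stored in long form (`stimulus_id_a`, `stimulus_id_b`,
#' `score`) and looked up symmetrically.
#'
#' @param pairs Long tibble/data frame with columns `stimulus_id_a`,
#'   `stimulus_id_b`, `score` (non-negative).
#' @param metric_name Name of the metric that produced the scores.
#' @return An object of class `semantic_scores`.
#' @export
semantic_scores <- function(pairs, metric_name = "precomputed") {
  pairs <- tibble::as_tibble(pairs)
  need <- c("stimulus_id_a", "stimulus_id_b", "score")
  if (!all(need %in% names(pairs))) {
    abort(paste0("semantic score table needs columns: ", paste(need, collapse = ", ")),
          class = "serialdep_schema_error")
  }
  if (any(pairs$score < 0, na.rm = TRUE)) {
    abort("semantic scores must be >= 0", class = "serialdep_schema_error")
  }
  structure(list(pairs = pairs[need], metric_name = metric_name),
            class = "semantic_scores")
}

#' Read / write semantic-similarity scores
#'
#' Two CSV layouts are accepted: long format with header
#' `stimulus_id_a,stimulus_id_b,score`, or a square matrix whose first column
#' and header row hold stimulus ids. Writing always uses the long format;
#' `read_semantic_scores(write_semantic_scores(s, path))` restores the scores.
#'
#' @param path CSV path.
#' @param metric_name Metric label attached on read.
#' @return A `semantic_scores` object (read) or `path` invisibly (write).
#' @export
read_semantic_scores <- function(path, metric_name = "precomputed") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (all(c("stimulus_id_a", "stimulus_id_b", "score") %in% names(raw))) {
    raw$score <- as.numeric(raw$score)
    return(semantic_scores(raw, metric_name))
  }
  ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (ncol(mat) != length(ids) || !all(colnames(mat) == ids)) {
    abort("square semantic-score matrix must have matching id row and column headers",
          class = "serialdep_schema_error")
  }
  storage.mode(mat) <- "double"
  long <- tibble::tibble(
    stimulus_id_a = rep(ids, times = length(ids)),
    stimulus_id_b = rep(ids, each = length(ids)),
    score = as.vector(mat)
  )
  long <- long[long$stimulus_id_a < long$stimulus_id_b | long$stimulus_id_a == long$stimulus_id_b, ]
  semantic_scores(long, metric_name)
}

#' @rdname read_semantic_scores
#' @param scores A `semantic_scores` object.
#' @export
write_semantic_scores <- function(scores, path) {
  stopifnot(inherits(scores, "semantic_scores"))
  readr::write_csv(scores$pairs, path, progress = FALSE)
  invisible(path)
}

# Vectorized symmetric lookup: returns a function(ids_a, ids_b) -> scores.
# Missing pairs raise a missing-score error naming the first absent pair.
.score_fun <- function(scores) {
  if (is.function(scores)) return(scores)
  stopifnot(inherits(scores, "semantic_scores"))
  p <- scores$pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab <- setNames(p$score, key(p$stimulus_id_a, p$stimulus_id_b))
  # keep first occurrence on duplicate keys
  tab <- tab[!duplicated(names(tab))]
  function(a, b) {
    v <- unname(tab[key(a, b)])
    if (anyNA(v)) {
      miss <- which(is.na(v))[1]
      abort(paste0("no semantic score for pair (", a[miss], ", ", b[miss], ")"),
            class = "serialdep_missing_score")
    }
    v
  }
}

#' Semantic similarity between stimulus images
#'
#' With `backend = "precomputed"`, `x` is a path to a score CSV (see
#' [read_semantic_scores()]) or a long table of pairwise scores. With
#' `backend = "filter-bank"`, `x` is a named list of grayscale image matrices
#' (equal dimensions, values on any common scale) and all pairwise scores are
#' computed with [filter_bank_distance()], a deterministic classical
#' multi-scale feature distance — a documented stand-in metric, not a deep
#' perceptual model.
#'
#' @param x Path, score table, or named list of image matrices.
#' @param backend `"precomputed"` or `"filter-bank"`.
#' @param metric_name Label stored with the scores.
#' @return A `semantic_scores` object.
#' @export
semantic_similarity <- function(x, backend = c("precomputed", "filter-bank"),
                                metric_name = NULL) {
  backend <- match.arg(backend)
  if (backend == "precomputed") {
    if (is.character(x)) {
      return(read_semantic_scores(x, metric_name %||% "precomputed"))
    }
    return(semantic_scores(x, metric_name %||% "precomputed"))
  }
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    abort("filter-bank backend needs a named list of image matrices",
          class = "serialdep_config_error")
  }
  ids <- names(x)
  grid <- which(upper.tri(diag(length(ids)), diag = TRUE), arr.ind = TRUE)
  pairs <- tibble::tibble(
    stimulus_id_a = ids[grid[, "row"]],
    stimulus_id_b = ids[grid[, "col"]],
    score = vapply(seq_len(nrow(grid)), function(i) {
      filter_bank_distance(x[[grid[i, "row"]]], x[[grid[i, "col"]]])
    }, numeric(1))
  )
  semantic_scores(pairs, metric_name %||% "filter-bank")
}

#' Multi-scale filter-bank image distance
#'
#' A classical perceptual-style distance: each image is decomposed over
#' `n_scales` octaves (2x2 average pooling between scales); at each scale a
#' small filter bank (local mean, horizontal and vertical gradients) is
#' applied and each feature map is contrast-normalized (zero mean, unit SD).
#' The distance is the mean squared difference between corresponding
#' normalized feature maps, averaged over filters and scales. Symmetric,
#' deterministic, and exactly 0 for identical images.
#'
#' @param img_a,img_b Numeric matrices of identical dimensions.
#' @param n_scales Number of octaves (default 3, reduced automatically for
#'   tiny images).
#' @return A non-negative scalar distance.
#' @export
filter_bank_distance <- function(img_a, img_b, n_scales = 3L) {
  if (!is.matrix(img_a) || !is.matrix(img_b) || !all(dim(img_a) == dim(img_b))) {
    abort("images must be numeric matrices of identical dimensions",
          class = "serialdep_config_error")
  }
  pool2 <- function(m) {
    nr <- nrow(m) %/% 2L; nc <- ncol(m) %/% 2L
    if (nr < 1L || nc < 1L) return(NULL)
    m <- m[seq_len(2L * nr), seq_len(2L * nc), drop = FALSE]
    (m[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2)] + m[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2)] +
     m[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2)] + m[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2)]) / 4
  }
  feat <- function(m) {
    gx <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    gy <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    lapply(list(m, gx, gy), function(f) {
      s <- stats::sd(f)
      if (!is.finite(s) || s == 0) s <- 1
      (f - mean(f)) / s
    })
  }
  total <- 0
  used <- 0L
  a <- img_a; b <- img_b
  for (s in seq_len(n_scales)) {
    if (is.null(a) || is.null(b) || nrow(a) < 2L || ncol(a) < 2L) break
    fa <- feat(a); fb <- feat(b)
    total <- total + mean(vapply(seq_along(fa),
                                 function(i) mean((fa[[i]] - fb[[i]])^2), numeric(1)))
    used <- used + 1L
    a <- pool2(a); b <- pool2(b)
  }
  if (used == 0L) abort("images too small for any scale", class = "serialdep_config_error")
  total / used
}

#' Split trials into similar / dissimilar super-groups
#'
#' Labels each per-trial semantic score `"similar"` when it is strictly below
#' the mean of all supplied scores and `"dissimilar"` otherwise (ties at the
#' mean go to dissimilar). The threshold is attached as the `"threshold"`
#' attribute.
#'
#' @param scores_per_trial Numeric vector of per-trial sequential-pair
#'   semantic scores (`NA`s allowed; they stay `NA`).
#' @param threshold Optional fixed threshold overriding the observed mean.
#' @return A character vector of labels with a `"threshold"` attribute.
#' @export
split_supergroups <- function(scores_per_trial, threshold = NULL) {
  obs <- scores_per_trial[!is.na(scores_per_trial)]
  if (length(obs) == 0) abort("no scores to split", class = "serialdep_config_error")
  thr <- threshold %||% mean(obs)
  lab <- ifelse(is.na(scores_per_trial), NA_character_,
                ifelse(scores_per_trial < thr, "similar", "dissimilar"))
  attr(lab, "threshold") <- thr
  lab
}
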
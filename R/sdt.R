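# Signal-detection metrics on confusion counts. "Positive" is the malignant
# class throughout: sensitivity (hit rate) = TP/(TP+FN), specificity =
# TN/(TN+FP), FAR = FP/(FP+TN), error rate = (FN+FP)/total,
# d' = z(HR) - z(FAR), c = -0.5 * (z(HR) + z(FAR)).

#' Inverse standard-normal CDF
#'
#' The z-transform used by d-prime and the criterion: the value `z` with
#' `pnorm(z) = p`. A domain-checked wrapper over [stats::qnorm()] (absolute
#' accuracy well below 1e-9).
#'
#' @param p Probabilities strictly inside (0, 1).
#' @return Quantiles of the standard normal.
#' @export
z_score <- function(p) {
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    abort("p must lie strictly inside (0, 1)", class = "serialdep_domain_error")
  }
  qnorm(p)
}

#' Confusion counts from paired labels
#'
#' Tabulates TP, FN, FP, TN with malignant as the positive class.
#'
#' @param truth,response Character vectors over `"benign"` / `"malignant"`.
#' @return A one-row tibble with columns `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(truth, response) {
  t1 <- truth == "malignant"
  r1 <- response == "malignant"
  tibble::tibble(tp = sum(t1 & r1), fn = sum(t1 & !r1),
                 fp = sum(!t1 & r1), tn = sum(!t1 & !r1))
}

#' Signal-detection metrics from confusion counts
#'
#' Computes sensitivity (hit rate), specificity, false-alarm rate, error
#' rate, d-prime and criterion, vectorized over the rows of `counts`. Before
#' the z-transform, hit and false-alarm rates of exactly 0 or 1 are clamped
#' into `[1/(2N), 1 - 1/(2N)]` with `N` the relevant row total (the standard
#' extreme-rate correction; `correction_applied` flags rows where it fired).
#' An empty positive or negative row leaves d-prime and criterion `NA`
#' (flagged via `undefined`), never an error.
#'
#' @param counts Data frame with integer columns `tp`, `fn`, `fp`, `tn`
#'   (one row per condition), or a named vector/list with those elements.
#' @param correction Apply the extreme-rate clamp (default TRUE). With
#'   `FALSE`, extreme rates give infinite z-scores.
#' @return A tibble with the four counts, `n`, `sensitivity`, `specificity`,
#'   `far`, `error_rate`, `d_prime`, `criterion`, `correction_applied`,
#'   `undefined`.
#' @export
sdt_metrics <- function(counts, correction = TRUE) {
  if (!is.data.frame(counts)) counts <- tibble::as_tibble(as.list(counts))
  need <- c("tp", "fn", "fp", "tn")
  if (!all(need %in% names(counts))) {
    abort("counts needs columns tp, fn, fp, tn", class = "serialdep_schema_error")
  }
  if (any(unlist(counts[need]) < 0, na.rm = TRUE)) {
    abort("counts must be non-negative", class = "serialdep_schema_error")
  }
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp; tn <- counts$tn
  npos <- tp + fn
  nneg <- fp + tn
  total <- npos + nneg
  hr <- ifelse(npos > 0, tp / npos, NA_real_)
  spec <- ifelse(nneg > 0, tn / nneg, NA_real_)
  far <- ifelse(nneg > 0, fp / nneg, NA_real_)
  err <- ifelse(total > 0, (fn + fp) / total, NA_real_)
  undefined <- npos == 0 | nneg == 0
  if (correction) {
    hr_c <- pmin(pmax(hr, 1 / (2 * npos)), 1 - 1 / (2 * npos))
    far_c <- pmin(pmax(far, 1 / (2 * nneg)), 1 - 1 / (2 * nneg))
  } else {
    hr_c <- hr
    far_c <- far
  }
  corrected <- !undefined & ((hr_c != hr) | (far_c != far))
  corrected[is.na(corrected)] <- FALSE
  zh <- suppressWarnings(qnorm(hr_c))
  zf <- suppressWarnings(qnorm(far_c))
  tibble::tibble(
    tp = tp, fn = fn, fp = fp, tn = tn, n = total,
    sensitivity = hr, specificity = spec, far = far, error_rate = err,
    d_prime = ifelse(undefined, NA_real_, zh - zf),
    criterion = ifelse(undefined, NA_real_, -0.5 * (zh + zf)),
    correction_applied = corrected,
    undefined = undefined
  )
}

#' Overall signal-detection summary of a trial table
#'
#' Pools all trials into one confusion table and applies [sdt_metrics()]
#' (the default; internally consistent with reporting pooled HR/FAR-derived
#' d-prime and criterion). With `by_user = TRUE`, metrics are computed per
#' user and averaged — an alternative aggregation some reports use for rate
#' metrics.
#'
#' @param trials Trial tibble with `true_label` and `response` (and `user_id`
#'   when `by_user = TRUE`).
#' @param by_user Average per-user metrics instead of pooling.
#' @return A one-row metrics tibble.
#' @export
sdt_summary <- function(trials, by_user = FALSE) {
  if (!by_user) {
    return(sdt_metrics(confusion_counts(trials$true_label, trials$response)))
  }
  per <- trials |>
    dplyr::group_by(.data$user_id) |>
    dplyr::group_modify(function(d, key) {
      sdt_metrics(confusion_counts(d$true_label, d$response))
    }) |>
    dplyr::ungroup()
  dplyr::summarise(
    per,
    dplyr::across(c("sensitivity", "specificity", "far", "error_rate",
                    "d_prime", "criterion"), ~ mean(.x, na.rm = TRUE)),
    n = sum(.data$n), n_users = dplyr::n()
  )
}
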
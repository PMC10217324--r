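# Gaussian tuning-curve fits: the peak of a scaled Gaussian fitted to a
# net-change curve is reported as the serial-dependence amplitude, and the
# lag-1..4 peaks assemble the temporal-decay summary.

#' Scaled Gaussian tuning model
#'
#' `a / sqrt(2 * pi * sigma^2) * exp(-(x - mu)^2 / (2 * sigma^2))`: a normal
#' density scaled by the amplitude-modulation parameter `a`, so the curve
#' integrates to `a` and peaks at `a / sqrt(2 * pi * sigma^2)`.
#'
#' @param x Evaluation points (similarity units).
#' @param a Amplitude modulation parameter.
#' @param mu Gaussian mean.
#' @param sigma Gaussian SD (> 0).
#' @return Curve values at `x`.
#' @export
gaussian_tuning <- function(x, a, mu, sigma) {
  if (any(sigma <= 0)) abort("sigma must be > 0", class = "serialdep_domain_error")
  a / sqrt(2 * pi * sigma^2) * exp(-(x - mu)^2 / (2 * sigma^2))
}

.new_tuning_fit <- function(a, mu, sigma, rss, converged, metric, lag,
                            data, null_peak95 = NA_real_) {
  structure(list(a = a, mu = mu, sigma = sigma,
                 peak = a / sqrt(2 * pi * sigma^2),
                 rss = rss, converged = converged,
                 metric = metric, lag = lag, data = data,
                 null_peak95 = null_peak95),
            class = "tuning_fit")
}

# Bounded multi-start nonlinear least squares for the scaled Gaussian on a
# cost-signed net-change curve. Three jittered restarts (fixed internal
# stream) guard against local minima; best weighted RSS wins, ties by first.
.fit_gaussian <- function(x, y, w, low, high, width) {
  keep <- !is.na(x) & !is.na(y) & !is.na(w)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 4) {
    abort("need at least 4 non-excluded bins to fit", class = "serialdep_insufficient_data")
  }
  span <- high - low
  i0 <- which.max(y)
  mu0 <- x[i0]
  sig0 <- span / 4
  a0 <- y[i0] * sqrt(2 * pi * sig0^2)
  starts <- withr::with_seed(20201L, {
    lapply(1:3, function(i) {
      if (i == 1) return(c(a = a0, mu = mu0, sigma = sig0))
      c(a = a0 * runif(1, 0.5, 1.5),
        mu = min(high, max(low, mu0 + runif(1, -span / 8, span / 8))),
        sigma = sig0 * runif(1, 0.6, 1.6))
    })
  })
  lower <- c(a = -Inf, mu = low, sigma = width)
  upper <- c(a = Inf, mu = high, sigma = span)
  best <- NULL
  for (st in starts) {
    st["sigma"] <- min(max(st[["sigma"]], width * 1.001), span * 0.999)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a / sqrt(2 * pi * sigma^2) * exp(-(x - mu)^2 / (2 * sigma^2)),
        start = as.list(st), lower = lower, upper = upper,
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    conv <- isTRUE(fit$convInfo$isConv)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(coef = stats::coef(fit), rss = rss, converged = conv)
    }
  }
  if (is.null(best)) {
    # degenerate input (e.g. an exactly flat curve): report a null fit honestly
    return(list(coef = c(a = 0, mu = mean(x), sigma = sig0),
                rss = sum(w * y^2), converged = FALSE))
  }
  best
}

#' Fit a Gaussian tuning curve to a net-change curve
#'
#' Weighted nonlinear least squares of [gaussian_tuning()] over `(a, mu,
#' sigma)`. The curve is fitted in the cost direction — for d-prime,
#' sensitivity and specificity the negated net change — so the fitted peak
#' `a / sqrt(2 * pi * sigma^2)` is positive when serial dependence costs
#' performance; that peak, not raw `a`, is the reported amplitude. Initial
#' values: `mu` at the bin with the extreme cost, `sigma` a quarter of the
#' domain span, `a` matched to the extreme value; bounds keep `mu` in the
#' domain and `sigma` in (bin width, span). Per-bin trial counts weight the
#' fit by default.
#'
#' For a `serial_dependence` object the method extracts the cost curve for
#' one metric and can also fit the stored permuted curves, yielding
#' `null_peak95`, the 95th percentile of permuted fitted peaks — the null
#' bound an observed amplitude must exceed.
#'
#' @param object Numeric vector of bin centers, or a `serial_dependence`
#'   result.
#' @param ... Passed between methods.
#' @return A `tuning_fit` object: `a`, `mu`, `sigma`, `peak`, `rss`,
#'   `converged`, `metric`, `lag`, `data`, `null_peak95`. [tidy()] gives the
#'   parameters, [glance()] the fit summary.
#' @export
fit_tuning <- function(object, ...) UseMethod("fit_tuning")

#' @rdname fit_tuning
#' @param deltas Cost-signed net-change values per bin (positive = cost).
#' @param weights Optional per-bin weights (trial counts); uniform when
#'   `NULL`. Fits are invariant to uniform weight rescaling and bin
#'   reordering.
#' @param domain Length-2 domain of the similarity axis.
#' @param bin_width Bin width used for the lower `sigma` bound.
#' @param metric,lag Labels carried on the fit.
#' @export
fit_tuning.default <- function(object, deltas, weights = NULL,
                               domain = c(0, 200), bin_width = NULL,
                               metric = NA_character_, lag = NA_integer_, ...) {
  x <- as.numeric(object)
  if (is.null(weights)) weights <- rep(1, length(x))
  bw <- bin_width %||% (if (length(unique(diff(sort(x)))) >= 1) min(diff(sort(unique(x)))) else diff(domain) / 20)
  best <- .fit_gaussian(x, deltas, weights, domain[1], domain[2], bw)
  .new_tuning_fit(best$coef[["a"]], best$coef[["mu"]], best$coef[["sigma"]],
                  best$rss, best$converged, metric, as.integer(lag),
                  tibble::tibble(bin_center = x, cost = deltas, weight = weights))
}

#' @rdname fit_tuning
#' @param null_peaks Also fit permuted curves to produce `null_peak95`
#'   (requires the object to carry permutations).
#' @param max_null_fits Cap on the number of permuted curves fitted.
#' @export
fit_tuning.serial_dependence <- function(object, metric = "error_rate",
                                         weights = c("counts", "none"),
                                         null_peaks = FALSE,
                                         max_null_fits = 200L, ...) {
  weights <- match.arg(weights)
  .check_metrics(metric)
  spec <- attr(object, "binspec")
  rows <- tibble::as_tibble(object)[tibble::as_tibble(object)$metric == metric, ]
  if (nrow(rows) == 0) {
    abort(paste0("metric '", metric, "' not present in this analysis"),
          class = "serialdep_config_error")
  }
  keep <- !rows$excluded
  w <- if (weights == "counts") rows$n_past else rep(1, nrow(rows))
  best <- .fit_gaussian(rows$bin_center[keep], rows$cost[keep], w[keep],
                        spec$domain_low, spec$domain_high, spec$width)
  np95 <- NA_real_
  if (null_peaks) {
    pm <- attr(object, "perm_cost")[[metric]]
    if (is.null(pm)) {
      abort("object carries no permutations; rerun with n_permutations > 0",
            class = "serialdep_config_error")
    }
    nfit <- min(nrow(pm), max_null_fits)
    peaks <- vapply(seq_len(nfit), function(b) {
      yb <- pm[b, ]
      ok <- keep & !is.na(yb)
      if (sum(ok) < 4) return(NA_real_)
      f <- .fit_gaussian(rows$bin_center[ok], yb[ok], w[ok],
                         spec$domain_low, spec$domain_high, spec$width)
      f$coef[["a"]] / sqrt(2 * pi * f$coef[["sigma"]]^2)
    }, numeric(1))
    np95 <- quantile(peaks, 0.95, na.rm = TRUE, names = FALSE)
  }
  .new_tuning_fit(best$coef[["a"]], best$coef[["mu"]], best$coef[["sigma"]],
                  best$rss, best$converged, metric,
                  unique(rows$lag)[1],
                  tibble::tibble(bin_center = rows$bin_center, cost = rows$cost,
                                 weight = w, excluded = rows$excluded),
                  null_peak95 = np95)
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("Gaussian tuning fit%s%s\n",
              if (!is.na(x$metric)) paste0(" [", x$metric, "]") else "",
              if (!is.na(x$lag)) paste0(" lag ", x$lag) else ""))
  cat(sprintf("  a = %.4g, mu = %.4g, sigma = %.4g, peak = %.4g\n",
              x$a, x$mu, x$sigma, x$peak))
  cat(sprintf("  rss = %.4g, converged = %s", x$rss, x$converged))
  if (!is.na(x$null_peak95)) cat(sprintf(", null peak 95%% = %.4g", x$null_peak95))
  cat("\n")
  invisible(x)
}

#' @rdname fit_tuning
#' @param x A `tuning_fit`.
#' @method tidy tuning_fit
#' @export
tidy.tuning_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "mu", "sigma", "peak"),
                 estimate = c(x$a, x$mu, x$sigma, x$peak))
}

#' @rdname fit_tuning
#' @method glance tuning_fit
#' @export
glance.tuning_fit <- function(x, ...) {
  tibble::tibble(metric = x$metric, lag = x$lag, a = x$a, mu = x$mu,
                 sigma = x$sigma, peak = x$peak, rss = x$rss,
                 converged = x$converged, null_peak95 = x$null_peak95)
}

#' Serial-dependence amplitude by lag
#'
#' Runs the full per-lag analysis ([serial_dependence()]) and Gaussian fit
#' ([fit_tuning()]) for each requested lag and metric, assembling the
#' temporal-decay summary: the fitted peak (amplitude) per lag, with a
#' permutation null bound on the peak when permutations are requested.
#'
#' @inheritParams serial_dependence
#' @param lags Integer lags to analyze (default 1:4).
#' @param null_peaks Fit permuted curves for null peak bounds (needs
#'   `n_permutations > 0`).
#' @param max_null_fits Cap on permuted-curve fits per lag/metric.
#' @return A tibble of class `amplitude_decay` with one row per lag x metric
#'   (`metric`, `lag`, `a`, `mu`, `sigma`, `peak`, `rss`, `converged`,
#'   `null_peak95`); the underlying `tuning_fit` objects are in the `"fits"`
#'   attribute and per-lag analyses in `"analyses"`.
#' @export
amplitude_by_lag <- function(trials, stimuli, lags = 1:4,
                             metrics = c("error_rate", "d_prime"),
                             binspec = malignancy_bins(),
                             n_permutations = 0L, seed = 1L,
                             null_peaks = n_permutations > 0,
                             max_null_fits = 200L) {
  .check_metrics(metrics)
  fits <- list()
  analyses <- list()
  for (lg in lags) {
    sd_lag <- serial_dependence(trials, stimuli, lag = lg, binspec = binspec,
                                metrics = metrics,
                                n_permutations = n_permutations,
                                seed = seed + lg)
    analyses[[as.character(lg)]] <- sd_lag
    for (m in metrics) {
      fits[[paste(m, lg, sep = ".")]] <-
        fit_tuning(sd_lag, metric = m, null_peaks = null_peaks,
                   max_null_fits = max_null_fits)
    }
  }
  out <- purrr::map_dfr(fits, glance)
  structure(out, class = c("amplitude_decay", class(out)),
            fits = fits, analyses = analyses, seed = as.integer(seed))
}
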
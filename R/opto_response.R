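# Trial segmentation and scoring of optogenetic activation experiments,
# per-fly and per-line aggregation, the cell-count dose-response regression,
# the baseline-subtraction interaction test, and amplitude-frequency
# coupling analyses.

#' Wingbeat tracker trial trace
#'
#' A single fly's tethered-flight recording: left/right wingbeat amplitude
#' and wingbeat frequency on a uniform clock, with the optogenetic pulse
#' onset schedule.
#'
#' @param t Time (s), strictly increasing and uniformly sampled.
#' @param wba_left,wba_right Wingbeat amplitudes (deg).
#' @param freq Wingbeat frequency (Hz).
#' @param pulse_onsets Stimulus onset times (s).
#' @param fly_id,line_id Identifiers.
#' @return An object of class `"trial_trace"`.
#' @export
trial_trace <- function(t, wba_left, wba_right, freq, pulse_onsets,
                        fly_id = "fly", line_id = "line") {
  n <- length(t)
  if (n < 2L) stop("trace must have at least two samples")
  if (length(wba_left) != n || length(wba_right) != n || length(freq) != n)
    stop("all series must have the same length as t")
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * stats::median(dt))
    stop("t must be uniformly sampled")
  fs <- 1 / stats::median(dt)
  if (any(pulse_onsets < t[1] + 0.5 - 1e-9) ||
      any(pulse_onsets > t[n] - 0.5 + 1e-9))
    stop("every pulse onset must lie within [t0 + 0.5 s, t_end - 0.5 s]")
  structure(list(t = t, wba_left = wba_left, wba_right = wba_right,
                 wba_mean = (wba_left + wba_right) / 2, freq = freq,
                 pulse_onsets = sort(pulse_onsets), fs = fs,
                 fly_id = fly_id, line_id = line_id),
            class = "trial_trace")
}

#' @export
print.trial_trace <- function(x, ...) {
  cat(sprintf("Trial trace: fly %s (line %s), %d samples at %.5g Hz, %d pulses\n",
              x$fly_id, x$line_id, length(x$t), x$fs,
              length(x$pulse_onsets)))
  invisible(x)
}

#' Segment a trace into per-pulse analysis windows
#'
#' Cuts one window per pulse onset spanning `[onset - pre_s, onset + post_s)`
#' using a half-open sample convention on both sub-windows (baseline samples
#' have relative time in `[-pre_s, 0)`, response samples in `[0, post_s)`),
#' so the onset sample is counted exactly once.
#'
#' @param trace A [trial_trace()].
#' @param pre_s,post_s Baseline and response window lengths (s).
#' @return A list of `"trial_window"` objects, one per pulse, each holding
#'   relative time `t_rel` and the amplitude/frequency series.
#' @export
segment_trials <- function(trace, pre_s = 0.5, post_s = 0.5) {
  stopifnot(inherits(trace, "trial_trace"))
  on <- trace$pulse_onsets
  if (length(on) > 1L) {
    gap <- diff(on)
    bad <- which(gap < pre_s + post_s - 1e-9)
    if (length(bad))
      stop("overlapping windows for onsets at ",
           paste(sprintf("%.3f/%.3f s", on[bad], on[bad + 1]),
                 collapse = ", "))
  }
  tn <- trace$t[length(trace$t)]
  dt <- 1 / trace$fs
  lapply(on, function(o) {
    if (o - pre_s < trace$t[1] - 1e-9 || o + post_s > tn + dt + 1e-9)
      stop(sprintf("window for onset %.3f s does not fit within the trace", o))
    idx <- which(trace$t >= o - pre_s - 1e-9 & trace$t < o + post_s - 1e-9)
    structure(list(t_rel = trace$t[idx] - o,
                   wba_left = trace$wba_left[idx],
                   wba_right = trace$wba_right[idx],
                   wba_mean = trace$wba_mean[idx],
                   freq = trace$freq[idx],
                   onset = o, fly_id = trace$fly_id,
                   line_id = trace$line_id),
              class = "trial_window")
  })
}

#' Score one activation trial
#'
#' The baseline is the mean of the bilateral-mean wingbeat amplitude over the
#' half second before stimulus onset; the response is the mean (or, with
#' `metric = "peak"`, the within-window maximum) over the half second
#' starting at onset; `delta_wba` is their difference. The same windows are
#' applied to wingbeat frequency, always as window means.
#'
#' @param window A `"trial_window"` from [segment_trials()].
#' @param metric `"mean"` (default, the primary window-mean score) or
#'   `"peak"` (maximum response within the window).
#' @return An object of class `"trial_metrics"`: a list with `baseline_wba`,
#'   `response_wba_raw`, `delta_wba` (deg), `baseline_freq`,
#'   `response_freq`, `delta_freq` (Hz).
#' @export
score_trial <- function(window, metric = c("mean", "peak")) {
  metric <- match.arg(metric)
  stopifnot(inherits(window, "trial_window"))
  vals <- c(window$wba_mean, window$freq)
  if (any(!is.finite(vals))) stop("non-finite samples in trial window")
  base_i <- window$t_rel < 0
  resp_i <- window$t_rel >= 0
  if (!any(base_i) || !any(resp_i))
    stop("window lacks baseline or response samples")
  baseline_wba <- mean(window$wba_mean[base_i])
  response_wba <- if (metric == "mean") mean(window$wba_mean[resp_i])
                  else max(window$wba_mean[resp_i])
  baseline_freq <- mean(window$freq[base_i])
  response_freq <- mean(window$freq[resp_i])
  structure(list(baseline_wba = baseline_wba,
                 response_wba_raw = response_wba,
                 delta_wba = response_wba - baseline_wba,
                 baseline_freq = baseline_freq,
                 response_freq = response_freq,
                 delta_freq = response_freq - baseline_freq,
                 metric = metric,
                 fly_id = window$fly_id, line_id = window$line_id),
            class = "trial_metrics")
}

metric_fields <- c("baseline_wba", "response_wba_raw", "delta_wba",
                   "baseline_freq", "response_freq", "delta_freq")

#' Average trial metrics into one measurement per fly
#'
#' @param metrics A non-empty list of `"trial_metrics"`.
#' @return An object of class `"fly_summary"`: arithmetic means of every
#'   metric field plus `n_trials`.
#' @export
summarize_fly <- function(metrics) {
  if (!length(metrics)) stop("no trials to summarize")
  stopifnot(all(vapply(metrics, inherits, logical(1), "trial_metrics")))
  out <- lapply(metric_fields, function(f)
    mean(vapply(metrics, function(m) m[[f]], numeric(1))))
  names(out) <- metric_fields
  out$n_trials <- length(metrics)
  out$fly_id <- metrics[[1]]$fly_id
  out$line_id <- metrics[[1]]$line_id
  structure(out, class = "fly_summary")
}

#' Aggregate per-fly responses into a line summary
#'
#' Computes the median and interquartile range of the per-fly amplitude
#' responses for one driver line. Quantiles use the linear-interpolation
#' definition (`stats::quantile` type 7).
#'
#' @param flies A list of `"fly_summary"` objects, or a numeric vector of
#'   per-fly `delta_wba` values.
#' @param n_pairs Number of targeted cell pairs for the line (integer >= 0).
#' @param line_id Line identifier.
#' @return An object of class `"line_summary"` with fields `line_id`,
#'   `n_pairs`, `per_fly_delta`, `per_fly_baseline_freq`,
#'   `per_fly_delta_freq`, `per_fly_response_raw`, `median`, `q1`, `q3`,
#'   `n_flies`.
#' @export
summarize_line <- function(flies, n_pairs, line_id = NULL) {
  if (!length(flies)) stop("no flies to summarize")
  if (is.numeric(flies)) {
    vals <- flies; bf <- dfq <- rr <- rep(NA_real_, length(flies))
  } else {
    stopifnot(all(vapply(flies, inherits, logical(1), "fly_summary")))
    vals <- vapply(flies, `[[`, numeric(1), "delta_wba")
    bf <- vapply(flies, `[[`, numeric(1), "baseline_freq")
    dfq <- vapply(flies, `[[`, numeric(1), "delta_freq")
    rr <- vapply(flies, `[[`, numeric(1), "response_wba_raw")
    if (is.null(line_id)) line_id <- flies[[1]]$line_id
  }
  if (is.null(line_id)) line_id <- "line"
  if (!(length(n_pairs) == 1L && n_pairs >= 0)) stop("invalid n_pairs")
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(line_id = line_id, n_pairs = as.integer(n_pairs),
                 per_fly_delta = vals, per_fly_baseline_freq = bf,
                 per_fly_delta_freq = dfq, per_fly_response_raw = rr,
                 median = q[2], q1 = q[1], q3 = q[3],
                 n_flies = length(vals)),
            class = "line_summary")
}

lines_to_df <- function(lines) {
  stopifnot(length(lines) >= 1L,
            all(vapply(lines, inherits, logical(1), "line_summary")))
  data.frame(line_id = vapply(lines, `[[`, character(1), "line_id"),
             n_pairs = vapply(lines, `[[`, integer(1), "n_pairs"),
             median = vapply(lines, `[[`, numeric(1), "median"),
             q1 = vapply(lines, `[[`, numeric(1), "q1"),
             q3 = vapply(lines, `[[`, numeric(1), "q3"),
             n_flies = vapply(lines, `[[`, integer(1), "n_flies"),
             stringsAsFactors = FALSE)
}

#' Rank driver lines by response magnitude
#'
#' @param lines A list of `"line_summary"` objects.
#' @return A data frame sorted in descending order of median `delta_wba`;
#'   ties broken lexicographically by `line_id`.
#' @export
rank_lines <- function(lines) {
  df <- lines_to_df(lines)
  df[order(-df$median, df$line_id), , drop = FALSE]
}

#' Fit the cell-count dose-response regression
#'
#' Ordinary least-squares regression of the amplitude response on the number
#' of targeted cell pairs: the population-code prediction that the more
#' cells a line drives, the larger the wingbeat-amplitude increase. By
#' default each line contributes its median per-fly response; with
#' `use_median = FALSE` every fly is an observation.
#'
#' @param lines A list of `"line_summary"` objects covering at least three
#'   distinct `n_pairs` values (several lines may share a cell count).
#' @param use_median Regress on line medians (default) or on per-fly values.
#' @return An object of class `"dose_response_fit"` with fields `slope`
#'   (deg per cell pair), `intercept` (deg), `r2`, `n_points`, the
#'   underlying `lm` fit, and the point data.
#' @export
fit_dose_response <- function(lines, use_median = TRUE) {
  df <- lines_to_df(lines)
  if (length(unique(df$n_pairs)) < 3L)
    stop("need at least 3 distinct n_pairs values; slope not identifiable")
  if (use_median) {
    pts <- data.frame(n_pairs = df$n_pairs, value = df$median,
                      line_id = df$line_id)
  } else {
    pts <- do.call(rbind, lapply(lines, function(l)
      data.frame(n_pairs = l$n_pairs, value = l$per_fly_delta,
                 line_id = l$line_id)))
  }
  fit <- stats::lm(value ~ n_pairs, data = pts)
  # 1 - RSS/TSS: equals the squared Pearson correlation of fitted vs
  # observed for an intercept OLS fit, but stays defined at zero slope
  tss <- sum((pts$value - mean(pts$value))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n_points = nrow(pts), lm = fit, data = pts,
                 use_median = use_median),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response fit (delta WBA ~ number of cell pairs)\n")
  cat(sprintf("  slope = %.4g deg per cell pair, intercept = %.4g deg\n",
              x$slope, x$intercept))
  cat(sprintf("  r^2 = %.4g on %d %s\n", x$r2, x$n_points,
              if (x$use_median) "line medians" else "per-fly points"))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  if (is.numeric(newdata)) newdata <- data.frame(n_pairs = newdata)
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
summary.dose_response_fit <- function(object, ...) summary(object$lm, ...)

#' @export
plot.dose_response_fit <- function(x, ...) {
  graphics::plot(x$data$n_pairs, x$data$value,
                 xlab = "DN cell pairs targeted",
                 ylab = "delta WBA (deg)", ...)
  graphics::abline(x$intercept, x$slope, col = "blue")
  invisible(x)
}

#' Test whether baseline subtraction changes the dose-response slope
#'
#' Fits `value ~ n_pairs * mode` on per-fly observations, where `mode`
#' distinguishes baseline-subtracted (BLS) responses from raw window means,
#' and reports both mode-specific slopes and the p-value of the
#' `n_pairs:mode` interaction. A non-significant interaction means the
#' cell-count slope does not depend on whether the baseline was removed.
#'
#' @param data Data frame with numeric columns `n_pairs`, `value`, and a
#'   column `mode` containing both `"BLS"` and `"RAW"`.
#' @return An object of class `"bls_interaction"` with `slope_bls`,
#'   `slope_raw` (deg per pair), `p_interaction`, and the `lm` fit.
#' @export
compare_bls_slopes <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("n_pairs", "value", "mode") %in% names(data)))
  data$mode <- factor(as.character(data$mode), levels = c("BLS", "RAW"))
  if (anyNA(data$mode)) stop("mode must be 'BLS' or 'RAW'")
  if (nlevels(droplevels(data$mode)) < 2L)
    stop("both BLS and RAW observations are required")
  fit <- stats::lm(value ~ n_pairs * mode, data = data)
  cf <- stats::coef(fit)
  sm <- stats::summary.lm(fit)$coefficients
  structure(list(slope_bls = unname(cf["n_pairs"]),
                 slope_raw = unname(cf["n_pairs"] + cf["n_pairs:modeRAW"]),
                 p_interaction = unname(sm["n_pairs:modeRAW", 4]),
                 lm = fit),
            class = "bls_interaction")
}

#' @export
print.bls_interaction <- function(x, ...) {
  cat("Baseline-subtraction interaction test (value ~ n_pairs * mode)\n")
  cat(sprintf("  slope (BLS) = %.4g, slope (RAW) = %.4g deg per pair\n",
              x$slope_bls, x$slope_raw))
  cat(sprintf("  interaction p = %.4g\n", x$p_interaction))
  invisible(x)
}

#' Regression of frequency change on baseline frequency
#'
#' OLS of the optogenetically elicited change in wingbeat frequency on the
#' pre-stimulus baseline frequency across flies. A fixed muscle power budget
#' predicts a negative slope: flies already beating fast must slow down when
#' amplitude is pushed up. The zero crossing is the baseline frequency at
#' which activation neither raises nor lowers frequency.
#'
#' @param baseline_freq,delta_freq Per-fly values (Hz); at least 3 flies.
#' @return An object of class `"freq_coupling_fit"` with `slope`
#'   (dimensionless), `intercept` (Hz), `zero_crossing` (Hz, `NA` when the
#'   slope is zero), and the `lm` fit.
#' @export
freq_change_regression <- function(baseline_freq, delta_freq) {
  if (length(baseline_freq) != length(delta_freq))
    stop("baseline_freq and delta_freq must have the same length")
  if (length(baseline_freq) < 3L) stop("need at least 3 flies")
  fit <- stats::lm(delta_freq ~ baseline_freq)
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  zc <- if (is.na(slope) || abs(slope) < 1e-12) NA_real_ else
    -intercept / slope
  structure(list(slope = slope, intercept = intercept, zero_crossing = zc,
                 lm = fit),
            class = "freq_coupling_fit")
}

#' @export
print.freq_coupling_fit <- function(x, ...) {
  cat("Frequency-change regression (delta n ~ baseline n)\n")
  cat(sprintf("  slope = %.4g, intercept = %.4g Hz, zero crossing = %s\n",
              x$slope, x$intercept,
              if (is.na(x$zero_crossing)) "absent" else
                sprintf("%.4g Hz", x$zero_crossing)))
  invisible(x)
}

#' Kinematic trajectory of a trial with attached mechanical power
#'
#' Converts a trial window's simultaneous amplitude and frequency samples
#' into kinematic states and evaluates mass-specific mechanical power at
#' each, for overlay on power isolines and for [bounding_power()].
#'
#' @param window A `"trial_window"`.
#' @param morph A [morphometrics()] object.
#' @return Data frame with columns `t_rel` (s), `phi_deg`, `n_hz`,
#'   `p_mech` (W kg^-1).
#' @export
amp_freq_trajectory <- function(window, morph) {
  stopifnot(inherits(window, "trial_window"))
  if (length(window$wba_mean) != length(window$freq))
    stop("amplitude and frequency series differ in length")
  kin <- kinematic_state(window$freq, window$wba_mean, unit = "deg")
  pb <- mechanical_power(kin, morph)
  data.frame(t_rel = window$t_rel, phi_deg = window$wba_mean,
             n_hz = window$freq, p_mech = pb$P_mech)
}
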
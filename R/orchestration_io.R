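# File IO and end-to-end pipeline drivers for the two workflows: the
# optogenetic screen and the bilateral imaging session. All defaults are the
# experiment's documented values (0.5 s scoring windows, 20%/20%/10%
# percentile rules, 30 ms tracker lag, 1000 bootstrap replicates) and are
# overridable.

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

#' Read wingbeat-tracker recordings from long-format CSV
#'
#' @param traces_csv CSV with columns `fly_id`, `line_id`, `t`, `wba_left`,
#'   `wba_right`, `freq`.
#' @param pulses_csv CSV with columns `fly_id`, `onset_s`.
#' @return A named list of [trial_trace()] objects, one per fly.
#' @export
read_wingbeat_traces <- function(traces_csv, pulses_csv) {
  tr <- utils::read.csv(traces_csv, stringsAsFactors = FALSE)
  check_columns(tr, c("fly_id", "line_id", "t", "wba_left", "wba_right",
                      "freq"), "traces CSV")
  pu <- utils::read.csv(pulses_csv, stringsAsFactors = FALSE)
  check_columns(pu, c("fly_id", "onset_s"), "pulses CSV")
  flies <- split(tr, tr$fly_id)
  if (!length(flies)) stop("traces CSV contains no flies")
  out <- lapply(flies, function(d) {
    d <- d[order(d$t), ]
    trial_trace(d$t, d$wba_left, d$wba_right, d$freq,
                pulse_onsets = pu$onset_s[pu$fly_id == d$fly_id[1]],
                fly_id = d$fly_id[1], line_id = d$line_id[1])
  })
  out
}

#' Write a trial trace (and its pulse schedule) to CSV
#'
#' @param trace A [trial_trace()].
#' @param traces_csv,pulses_csv Output paths.
#' @return The trace path, invisibly.
#' @export
write_wingbeat_trace <- function(trace, traces_csv, pulses_csv) {
  stopifnot(inherits(trace, "trial_trace"))
  utils::write.csv(data.frame(fly_id = trace$fly_id,
                              line_id = trace$line_id, t = trace$t,
                              wba_left = trace$wba_left,
                              wba_right = trace$wba_right,
                              freq = trace$freq),
                   traces_csv, row.names = FALSE)
  utils::write.csv(data.frame(fly_id = trace$fly_id,
                              onset_s = trace$pulse_onsets),
                   pulses_csv, row.names = FALSE)
  invisible(traces_csv)
}

#' Run the optogenetic screen workflow
#'
#' Chains segmentation, trial scoring, per-fly and per-line aggregation,
#' line ranking, the dose-response regression (on line medians), the
#' baseline-subtraction interaction test, and the frequency-coupling
#' regression, writing tidy CSVs and a JSON report.
#'
#' @param traces_csv,pulses_csv Paths accepted by
#'   [read_wingbeat_traces()].
#' @param catalogue_csv CSV with columns `line_id`, `n_pairs`.
#' @param out_dir Output directory (created if missing).
#' @param pre_s,post_s Scoring windows (s).
#' @param metric Trial scoring metric, `"mean"` or `"peak"`.
#' @return An invisible list of class `"run_report"` with the fitted
#'   objects and output paths.
#' @export
run_opto_pipeline <- function(traces_csv, pulses_csv, catalogue_csv,
                              out_dir, pre_s = 0.5, post_s = 0.5,
                              metric = "mean") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- read_wingbeat_traces(traces_csv, pulses_csv)
  cat_df <- utils::read.csv(catalogue_csv, stringsAsFactors = FALSE)
  check_columns(cat_df, c("line_id", "n_pairs"), "catalogue CSV")

  all_metrics <- list(); fly_rows <- list()
  flies <- list()
  for (tr in traces) {
    wins <- segment_trials(tr, pre_s = pre_s, post_s = post_s)
    mets <- lapply(wins, score_trial, metric = metric)
    fs <- summarize_fly(mets)
    flies[[tr$fly_id]] <- fs
    all_metrics[[tr$fly_id]] <- data.frame(
      fly_id = tr$fly_id, line_id = tr$line_id,
      trial = seq_along(mets),
      baseline_wba = vapply(mets, `[[`, numeric(1), "baseline_wba"),
      response_wba_raw = vapply(mets, `[[`, numeric(1),
                                "response_wba_raw"),
      delta_wba = vapply(mets, `[[`, numeric(1), "delta_wba"),
      baseline_freq = vapply(mets, `[[`, numeric(1), "baseline_freq"),
      delta_freq = vapply(mets, `[[`, numeric(1), "delta_freq"))
    fly_rows[[tr$fly_id]] <- data.frame(
      fly_id = fs$fly_id, line_id = fs$line_id, n_trials = fs$n_trials,
      baseline_wba = fs$baseline_wba,
      response_wba_raw = fs$response_wba_raw, delta_wba = fs$delta_wba,
      baseline_freq = fs$baseline_freq, delta_freq = fs$delta_freq)
  }
  trial_df <- do.call(rbind, all_metrics)
  fly_df <- do.call(rbind, fly_rows)

  by_line <- split(names(flies),
                   vapply(flies, `[[`, character(1), "line_id"))
  lines <- lapply(names(by_line), function(lid) {
    np <- cat_df$n_pairs[cat_df$line_id == lid]
    if (!length(np)) stop("line '", lid, "' absent from catalogue")
    summarize_line(flies[by_line[[lid]]], n_pairs = np, line_id = lid)
  })
  ranked <- rank_lines(lines)
  dose <- fit_dose_response(lines, use_median = TRUE)

  inter_df <- rbind(
    data.frame(n_pairs = merge_pairs(fly_df, cat_df), mode = "BLS",
               value = fly_df$delta_wba),
    data.frame(n_pairs = merge_pairs(fly_df, cat_df), mode = "RAW",
               value = fly_df$response_wba_raw))
  interaction <- compare_bls_slopes(inter_df)
  freq_fit <- freq_change_regression(fly_df$baseline_freq,
                                     fly_df$delta_freq)

  utils::write.csv(trial_df, file.path(out_dir, "trial_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(fly_df, file.path(out_dir, "fly_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(ranked, file.path(out_dir, "line_summaries.csv"),
                   row.names = FALSE)
  report <- list(
    n_flies = nrow(fly_df), n_lines = length(lines), metric = metric,
    windows_s = c(pre = pre_s, post = post_s),
    dose_response = list(slope = dose$slope, intercept = dose$intercept,
                         r2 = dose$r2, n_points = dose$n_points),
    bls_interaction = list(slope_bls = interaction$slope_bls,
                           slope_raw = interaction$slope_raw,
                           p_interaction = interaction$p_interaction),
    freq_coupling = list(slope = freq_fit$slope,
                         intercept = freq_fit$intercept,
                         zero_crossing = freq_fit$zero_crossing))
  jsonlite::write_json(report, file.path(out_dir, "opto_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(list(report = report, dose = dose,
                           interaction = interaction,
                           freq_fit = freq_fit, lines = lines,
                           ranked = ranked, fly_df = fly_df,
                           out_dir = out_dir),
                      class = "run_report"))
}

merge_pairs <- function(fly_df, cat_df) {
  np <- cat_df$n_pairs[match(fly_df$line_id, cat_df$line_id)]
  if (anyNA(np)) stop("fly line(s) absent from catalogue: ",
                      paste(unique(fly_df$line_id[is.na(np)]),
                            collapse = ", "))
  np
}

#' Run the imaging workflow
#'
#' Chains registration, ROI/background selection, per-side trace
#' extraction, behavior lag correction and resampling, stimulus-triggered
#' epoch averages, tuning curves, the pixel correlation map, and the
#' bilateral correlation summary, writing CSV/TIFF outputs and a JSON
#' report.
#'
#' @param movie A [two_channel_movie()] (or a path pair readable by
#'   [read_movie_tiff()] supplied as `list(gcamp=, tdtom=)` of paths, with
#'   `frame_rate` given).
#' @param behavior A [behavior_trace()] (not yet lag-corrected).
#' @param protocol Stimulus protocol data frame.
#' @param out_dir Output directory.
#' @param patterns Pattern codes to epoch-average.
#' @param lag_s Tracker delay to remove (s).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for every bootstrap.
#' @param frame_rate Only used when `movie` is a list of TIFF paths.
#' @return An invisible list of class `"run_report"` with the registered
#'   movie, masks, side traces, epoch averages, tuning curves, maps, and
#'   summary.
#' @export
run_imaging_pipeline <- function(movie, behavior, protocol, out_dir,
                                 patterns = c("YR", "YL", "Re"),
                                 lag_s = 0.030, n_boot = 1000, seed = 1,
                                 frame_rate = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!inherits(movie, "two_channel_movie")) {
    stopifnot(is.list(movie), !is.null(movie$gcamp), !is.null(movie$tdtom),
              !is.null(frame_rate))
    movie <- two_channel_movie(read_movie_tiff(movie$gcamp),
                               read_movie_tiff(movie$tdtom), frame_rate)
  }
  reg <- register_to_reference(movie)
  rois <- select_variable_rois(reg$movie$gcamp)
  bg <- select_background(reg$movie$gcamp)
  left <- extract_side_trace(reg$movie, rois$left_mask, bg, "left")
  right <- extract_side_trace(reg$movie, rois$right_mask, bg, "right")

  beh <- lag_correct_behavior(behavior, lag_s = lag_s)
  beh_f <- resample_behavior(beh, reg$movie$frame_times)

  epochs <- list()
  for (p in patterns) {
    epochs[[p]] <- list(
      dff_left = epoch_average(rbind(left$dff), reg$movie$frame_times,
                               protocol, p, n_boot = n_boot, seed = seed,
                               pre_s = 1) ,
      dff_right = epoch_average(rbind(right$dff), reg$movie$frame_times,
                                protocol, p, n_boot = n_boot, seed = seed,
                                pre_s = 1))
  }
  tuning <- list(
    left_contra = tuning_curve(left$dff, beh_f$wba_right,
                               n_boot = n_boot, seed = seed),
    right_contra = tuning_curve(right$dff, beh_f$wba_left,
                                n_boot = n_boot, seed = seed))
  pmap <- pixel_correlation_map(reg$movie$gcamp, beh_f$wba_left,
                                beh_f$wba_right)
  bsum <- bilateral_summary(left$dff, right$dff, beh_f$wba_left,
                            beh_f$wba_right)

  utils::write.csv(data.frame(t = reg$movie$frame_times,
                              dff_left = left$dff, dff_right = right$dff,
                              wba_left = beh_f$wba_left,
                              wba_right = beh_f$wba_right),
                   file.path(out_dir, "side_traces.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(r_left = as.vector(pmap$r_left),
                              r_right = as.vector(pmap$r_right)),
                   file.path(out_dir, "pixel_correlations.csv"),
                   row.names = FALSE)
  tiff::writeTIFF(list((pmap$r_left + 1) / 2, (pmap$r_right + 1) / 2),
                  file.path(out_dir, "pixel_corr_maps.tiff"), bits.per.sample = 16)
  report <- list(seed = seed, n_boot = n_boot, lag_s = lag_s,
                 n_frames = length(reg$movie$frame_times),
                 max_abs_shift_px = max(abs(reg$shifts)),
                 cor_table = as.vector(bsum$cor_table),
                 lr_wba_cor = bsum$lr_wba_cor)
  jsonlite::write_json(report, file.path(out_dir, "imaging_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(list(report = report, registered = reg,
                           rois = rois, background = bg, left = left,
                           right = right, epochs = epochs,
                           tuning = tuning, pixel_map = pmap,
                           bilateral = bsum, out_dir = out_dir),
                      class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report; outputs in", x$out_dir, "\n")
  utils::str(x$report, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Write or read a frame stack as multi-page TIFF
#'
#' Intensities are scaled to the 16-bit range on write; the scale factor
#' (and frame rate, if supplied) are stored in a JSON sidecar next to the
#' TIFF so that reading restores the original values up to 16-bit
#' quantization.
#'
#' @param stack `T x H x W` numeric array (or one channel of a
#'   [two_channel_movie()]).
#' @param path Output `.tiff` path; the sidecar is `path` + `.meta.json`.
#' @param frame_rate Optional frame rate recorded in the sidecar.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns the `T x H x W` array with a
#'   `frame_rate` attribute when one was recorded.
#' @export
write_movie_tiff <- function(stack, path, frame_rate = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(k) (stack[k, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            frame_rate = frame_rate),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  out <- array(0, c(length(pages), H, W))
  for (k in seq_along(pages))
    out[k, , ] <- pages[[k]] * meta$scale + meta$offset
  if (!is.null(meta$frame_rate)) attr(out, "frame_rate") <- meta$frame_rate
  out
}

#' Write or read a stimulus protocol CSV
#'
#' @param protocol Data frame with `pattern_id`, `onset_s`, `duration_s`.
#' @param path CSV path.
#' @export
write_protocol_csv <- function(protocol, path) {
  check_columns(protocol, c("pattern_id", "onset_s", "duration_s"),
                "protocol")
  utils::write.csv(protocol, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol_csv
#' @export
read_protocol_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(p, c("pattern_id", "onset_s", "duration_s"),
                "protocol CSV")
  p
}

#' Write or read a behavior trace CSV
#'
#' @param behavior A [behavior_trace()].
#' @param path CSV path.
#' @export
write_behavior_csv <- function(behavior, path) {
  stopifnot(inherits(behavior, "behavior_trace"))
  utils::write.csv(data.frame(t = behavior$t,
                              wba_left = behavior$wba_left,
                              wba_right = behavior$wba_right),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @param lag_corrected Flag to set on the trace read back.
#' @export
read_behavior_csv <- function(path, lag_corrected = FALSE) {
  d <- utils::read.csv(path)
  check_columns(d, c("t", "wba_left", "wba_right"), "behavior CSV")
  behavior_trace(d$t, d$wba_left, d$wba_right,
                 lag_corrected = lag_corrected)
}
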
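# Bilateral two-photon functional-imaging pipeline: integer-shift
# cross-correlation registration, percentile ROI/background selection,
# ratiometric normalization, delta-F/F, behavior lag correction, bootstrap
# stimulus-triggered averages, tuning curves, and pixel-wise
# fluorescence-behavior correlation maps.
#
# Frame stacks are numeric arrays with dimensions T x H x W (frame, row,
# column). "Raster order" for tie-breaking means column-major pixel index
# within the H x W frame, i.e. down columns first.

#' Two-channel movie container
#'
#' @param gcamp,tdtom Numeric arrays of identical dimension `T x H x W`
#'   holding the activity (GCaMP) and anatomical (tdTomato) channels.
#' @param frame_rate Acquisition rate (Hz).
#' @param frame_times Optional frame timestamps (s); defaults to
#'   `(0:(T-1)) / frame_rate`.
#' @return An object of class `"two_channel_movie"`.
#' @export
two_channel_movie <- function(gcamp, tdtom, frame_rate,
                              frame_times = NULL) {
  if (!is.array(gcamp) || length(dim(gcamp)) != 3L)
    stop("gcamp must be a T x H x W array")
  if (!identical(dim(gcamp), dim(tdtom)))
    stop("channel shape mismatch: gcamp and tdtom dimensions differ")
  if (!(is.numeric(frame_rate) && frame_rate > 0))
    stop("frame_rate must be positive")
  if (is.null(frame_times))
    frame_times <- (seq_len(dim(gcamp)[1]) - 1) / frame_rate
  if (length(frame_times) != dim(gcamp)[1] ||
      is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing, one per frame")
  structure(list(gcamp = gcamp, tdtom = tdtom, frame_rate = frame_rate,
                 frame_times = frame_times),
            class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$gcamp)
  cat(sprintf("Two-channel movie: %d frames of %d x %d at %.4g Hz\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

# Translate an image: out[y, x] = img[y - dy, x - dx]; exposed pixels are
# filled with `fill`.
shift_image <- function(img, dy, dx, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  oky <- ys >= 1 & ys <= H; okx <- xs >= 1 & xs <= W
  out[oky, okx] <- img[ys[oky], xs[okx]]
  out
}

# Circular cross-correlation peak between `ref` and `frame`: returns the
# integer displacement (dy, dx) such that frame ~= shift_image(ref, dy, dx).
cross_corr_shift <- function(ref, frame) {
  H <- nrow(ref); W <- ncol(ref)
  cc <- Re(stats::fft(stats::fft(frame) * Conj(stats::fft(ref)),
                      inverse = TRUE))
  i <- which.max(cc)
  dy <- (i - 1) %% H
  dx <- (i - 1) %/% H
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  c(dy, dx)
}

#' Register a movie to its time-averaged anatomical reference
#'
#' The reference image is the time average of the tdTomato channel. Each
#' frame's integer displacement is found as the peak of the 2-D circular
#' cross-correlation between its tdTomato image and the reference, and the
#' opposite shift is applied to both channels. Pixels exposed by the shift
#' are filled with that frame's median intensity (per channel).
#'
#' @param movie A [two_channel_movie()] with at least two frames.
#' @return A list with `movie` (the registered [two_channel_movie()]) and
#'   `shifts`, a `T x 2` integer matrix of detected per-frame `(dy, dx)`
#'   displacements relative to the reference.
#' @export
register_to_reference <- function(movie) {
  stopifnot(inherits(movie, "two_channel_movie"))
  d <- dim(movie$tdtom)
  if (d[1] < 2L) stop("need at least two frames to register")
  ref <- apply(movie$tdtom, c(2, 3), mean)
  shifts <- matrix(0L, d[1], 2, dimnames = list(NULL, c("dy", "dx")))
  g <- movie$gcamp; r <- movie$tdtom
  for (k in seq_len(d[1])) {
    fr <- r[k, , ]
    if (all(fr == 0)) {
      warning("frame ", k, " is all zero; assuming zero shift")
      next
    }
    s <- cross_corr_shift(ref, fr)
    shifts[k, ] <- as.integer(s)
    if (any(s != 0)) {
      r[k, , ] <- shift_image(fr, -s[1], -s[2], fill = stats::median(fr))
      fg <- g[k, , ]
      g[k, , ] <- shift_image(fg, -s[1], -s[2], fill = stats::median(fg))
    }
  }
  list(movie = two_channel_movie(g, r, movie$frame_rate,
                                 movie$frame_times),
       shifts = shifts)
}

stack_to_matrix <- function(stack) {
  d <- dim(stack)
  matrix(stack, d[1], d[2] * d[3])
}

col_variance <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  (colMeans(X^2) - mu^2) * n / (n - 1)
}

#' Select the most variable pixels as left/right ROIs
#'
#' Ranks pixels by temporal variance and, within each lateral half of the
#' field of view (split at the middle column), selects the top 20% as that
#' side's region of interest. Mask sizes use floor counts; ties are broken
#' by raster (column-major) pixel order.
#'
#' @param stack Registered activity-channel stack, `T x H x W`.
#' @param frac Fraction of each half's pixels to select (default 0.2).
#' @return A list with logical `H x W` matrices `left_mask` and
#'   `right_mask`.
#' @export
select_variable_rois <- function(stack, frac = 0.2) {
  d <- dim(stack)
  H <- d[2]; W <- d[3]
  v <- col_variance(stack_to_matrix(stack))
  if (all(v == 0)) stop("stack has no temporal variability")
  px_col <- rep(seq_len(W), each = H) # column of each raster-ordered pixel
  half <- floor(W / 2)
  pick <- function(cols) {
    idx <- which(px_col %in% cols)
    k <- floor(frac * length(idx))
    if (k < 1L) stop("half too small for the requested ROI fraction")
    sel <- idx[order(-v[idx], idx)][seq_len(k)]
    m <- matrix(FALSE, H, W); m[sel] <- TRUE; m
  }
  list(left_mask = pick(seq_len(half)),
       right_mask = pick((half + 1):W))
}

#' Select the dimmest pixels as the background mask
#'
#' Ranks pixels by their temporal-mean intensity over the full field of view
#' and selects the lowest 20% (floor count, raster-order tie-break).
#'
#' @param stack Registered stack, `T x H x W`.
#' @param frac Fraction of FOV pixels to select (default 0.2).
#' @return Logical `H x W` background mask.
#' @export
select_background <- function(stack, frac = 0.2) {
  d <- dim(stack)
  mu <- colMeans(stack_to_matrix(stack))
  k <- floor(frac * length(mu))
  sel <- order(mu, seq_along(mu))[seq_len(k)]
  m <- matrix(FALSE, d[2], d[3]); m[sel] <- TRUE; m
}

#' Background-subtracted ROI fluorescence
#'
#' Per-frame mean over the ROI minus the per-frame mean over the background
#' mask.
#'
#' @param stack `T x H x W` stack.
#' @param roi_mask,background_mask Logical `H x W` masks; non-empty.
#' @return Numeric vector `F_t`, one value per frame.
#' @export
roi_fluorescence <- function(stack, roi_mask, background_mask) {
  if (!any(roi_mask) || !any(background_mask)) stop("empty mask")
  if (any(roi_mask & background_mask))
    warning("ROI and background masks overlap")
  X <- stack_to_matrix(stack)
  rowMeans(X[, as.vector(roi_mask), drop = FALSE]) -
    rowMeans(X[, as.vector(background_mask), drop = FALSE])
}

#' Ratiometric normalization of activity to the anatomical channel
#'
#' Divides the GCaMP fluorescence by the tdTomato fluorescence frame by
#' frame, cancelling z-motion that scales both channels alike. The
#' denominator is floored at `eps * median` to avoid blow-up on dim frames.
#'
#' @param F_gcamp,F_tdtom Per-frame fluorescence vectors of equal length.
#' @param eps Floor on the denominator as a fraction of its median.
#' @return Normalized per-frame signal.
#' @export
ratio_normalize <- function(F_gcamp, F_tdtom, eps = 0.05) {
  if (length(F_gcamp) != length(F_tdtom)) stop("length mismatch")
  med <- stats::median(F_tdtom)
  if (!is.finite(med) || med <= 0)
    stop("tdTomato fluorescence has non-positive median")
  F_gcamp / pmax(F_tdtom, eps * med)
}

#' Baseline fluorescence as the mean of the lowest decile
#'
#' @param F_t Per-frame fluorescence, at least 10 samples.
#' @param frac Fraction of lowest samples to average (default 0.1; at least
#'   one sample is always used).
#' @return Scalar baseline `F0`.
#' @export
baseline_f0 <- function(F_t, frac = 0.1) {
  if (length(F_t) < 10L) stop("need at least 10 samples for a baseline")
  k <- max(1L, floor(frac * length(F_t)))
  mean(sort(F_t)[seq_len(k)])
}

#' Max-normalized delta-F/F
#'
#' `(F_t - F0) / max(F_t - F0)`: baseline-subtracted fluorescence scaled by
#' its session maximum so the peak is exactly 1. Invariant to positive
#' affine transforms of the raw intensities (which shift `F0` and scale the
#' numerator and denominator together).
#'
#' @param F_t Per-frame fluorescence.
#' @param F0 Baseline; defaults to [baseline_f0()] of `F_t`.
#' @return delta-F/F series with maximum exactly 1.
#' @export
normalized_dff <- function(F_t, F0 = baseline_f0(F_t)) {
  d <- F_t - F0
  m <- max(d)
  if (!is.finite(m) || m <= 0)
    stop("non-positive dynamic range; cannot normalize")
  d / m
}

#' Extract one hemisphere's normalized activity trace
#'
#' Convenience wrapper chaining [roi_fluorescence()] on both channels,
#' [ratio_normalize()], [baseline_f0()], and [normalized_dff()] for one
#' side's ROI of a registered movie.
#'
#' @param movie A registered [two_channel_movie()].
#' @param roi_mask Logical mask for the side's ROI.
#' @param background_mask Logical background mask.
#' @param side `"left"` or `"right"`.
#' @return An object of class `"side_trace"`: list with `side`, `F_t`
#'   (ratio-normalized fluorescence), `F0`, and `dff`.
#' @export
extract_side_trace <- function(movie, roi_mask, background_mask,
                               side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(movie, "two_channel_movie"))
  Fg <- roi_fluorescence(movie$gcamp, roi_mask, background_mask)
  Fr <- roi_fluorescence(movie$tdtom, roi_mask, background_mask)
  F_t <- ratio_normalize(Fg, Fr)
  F0 <- baseline_f0(F_t)
  structure(list(side = side, F_t = F_t, F0 = F0,
                 dff = normalized_dff(F_t, F0)),
            class = "side_trace")
}

#' Behavior trace container
#'
#' @param t Timestamps (s), uniform sampling (nominally 32 Hz).
#' @param wba_left,wba_right Wingbeat amplitudes (deg).
#' @param lag_corrected Whether the tracker delay has been removed.
#' @return An object of class `"behavior_trace"`.
#' @export
behavior_trace <- function(t, wba_left, wba_right, lag_corrected = FALSE) {
  n <- length(t)
  if (length(wba_left) != n || length(wba_right) != n)
    stop("series length mismatch")
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt))
    stop("behavior must be uniformly sampled")
  structure(list(t = t, wba_left = wba_left, wba_right = wba_right,
                 fs = 1 / stats::median(dt), lag_corrected = lag_corrected),
            class = "behavior_trace")
}

#' Correct the wing-tracker measurement delay
#'
#' The tracker reports at time `t` the wing state from `t - lag_s`. This
#' re-interpolates the series onto its own clock so each sample reflects the
#' wing state at its timestamp, i.e. events are attributed `lag_s` earlier.
#'
#' @param behavior A [behavior_trace()].
#' @param lag_s Tracker delay (s), default 0.030.
#' @param force Apply even if already flagged as corrected (used for
#'   round-trip checks); otherwise a second correction is an error.
#' @return A lag-corrected `"behavior_trace"`.
#' @export
lag_correct_behavior <- function(behavior, lag_s = 0.030, force = FALSE) {
  stopifnot(inherits(behavior, "behavior_trace"))
  if (behavior$lag_corrected && !force)
    stop("behavior trace is already lag-corrected")
  shift <- function(v) stats::approx(behavior$t - lag_s, v,
                                     xout = behavior$t, rule = 2)$y
  behavior_trace(behavior$t, shift(behavior$wba_left),
                 shift(behavior$wba_right), lag_corrected = TRUE)
}

#' Resample behavior onto imaging frame times
#'
#' Linear interpolation of the (lag-corrected) 32 Hz wingbeat series onto
#' the imaging clock.
#'
#' @param behavior A [behavior_trace()].
#' @param times Target timestamps (s).
#' @return Data frame with `t`, `wba_left`, `wba_right` at `times`.
#' @export
resample_behavior <- function(behavior, times) {
  stopifnot(inherits(behavior, "behavior_trace"))
  data.frame(
    t = times,
    wba_left = stats::approx(behavior$t, behavior$wba_left, xout = times,
                             rule = 2)$y,
    wba_right = stats::approx(behavior$t, behavior$wba_right, xout = times,
                              rule = 2)$y)
}

#' Percentile bootstrap CI for a column-wise mean
#'
#' Resamples the rows (flies) of a matrix with replacement and returns the
#' percentile confidence band of the column means. Deterministic given
#' `seed`; the global RNG state is restored on exit.
#'
#' @param mat Numeric matrix, rows = flies, columns = time points.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @param probs Lower/upper CI percentiles.
#' @return A list with vectors `mean`, `lo`, `hi` (one entry per column).
#' @export
bootstrap_mean_ci <- function(mat, n_boot = 1000, seed = 1,
                              probs = c(0.025, 0.975)) {
  n <- nrow(mat)
  if (n < 2L) stop("need at least two rows to bootstrap a CI")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, ncol(mat))
  for (b in seq_len(n_boot))
    boots[b, ] <- colMeans(mat[sample.int(n, n, replace = TRUE), ,
                               drop = FALSE])
  ci <- apply(boots, 2, stats::quantile, probs = probs, names = FALSE)
  list(mean = colMeans(mat), lo = ci[1, ], hi = ci[2, ])
}

#' Stimulus-triggered epoch average with bootstrap CI
#'
#' Extracts every epoch of one stimulus pattern from each fly's trace,
#' subtracts the mean of the `pre_s` window immediately before onset,
#' averages epochs within fly, and reports the across-fly mean with a
#' percentile bootstrap 95% CI (flies resampled with replacement). With a
#' single fly the epoch repetitions are the resampling unit instead.
#'
#' @param signals Numeric matrix, one row per fly, columns sampled at
#'   `times` (a shared session clock).
#' @param times Sample timestamps (s) for the columns of `signals`.
#' @param protocol Stimulus protocol data frame with columns `pattern_id`,
#'   `onset_s`, `duration_s`.
#' @param pattern_id Which pattern to average.
#' @param pre_s Baseline window before onset (s), default 1.
#' @param post_s Extra time shown after stimulus offset (s), default 1.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `"epoch_average"`: data frame with `t_rel`,
#'   `mean`, `lo`, `hi` plus attributes `pattern_id`, `n_flies`,
#'   `n_epochs`, `seed`.
#' @export
epoch_average <- function(signals, times, protocol, pattern_id,
                          pre_s = 1, post_s = 1, n_boot = 1000, seed = 1) {
  if (is.numeric(signals) && is.null(dim(signals)))
    signals <- matrix(signals, nrow = 1)
  stopifnot(is.matrix(signals), ncol(signals) == length(times))
  ep <- protocol[protocol$pattern_id == pattern_id, , drop = FALSE]
  if (!nrow(ep)) stop("pattern '", pattern_id, "' absent from protocol")
  dt <- stats::median(diff(times))
  dur <- ep$duration_s[1]
  t_rel <- seq(-pre_s, dur + post_s, by = dt)
  fly_epochs <- lapply(seq_len(nrow(signals)), function(f) {
    traces <- list()
    for (o in ep$onset_s) {
      tt <- o + t_rel
      if (tt[1] < times[1] - 1e-9 ||
          tt[length(tt)] > times[length(times)] + 1e-9) next
      v <- stats::approx(times, signals[f, ], xout = tt)$y
      v <- v - mean(v[t_rel < 0])
      traces[[length(traces) + 1L]] <- v
    }
    if (!length(traces))
      stop("no complete epochs of pattern '", pattern_id,
           "' inside the recording")
    do.call(rbind, traces)
  })
  n_epochs <- sum(vapply(fly_epochs, nrow, integer(1)))
  if (nrow(signals) >= 2L) {
    # resampling unit: flies
    units <- do.call(rbind, lapply(fly_epochs, colMeans))
  } else {
    # single fly: resample its epoch repetitions instead
    units <- fly_epochs[[1]]
    if (nrow(units) < 2L)
      stop("need at least 2 flies, or 2 epochs for a single fly, ",
           "to bootstrap a CI")
  }
  ci <- bootstrap_mean_ci(units, n_boot = n_boot, seed = seed)
  structure(data.frame(t_rel = t_rel, mean = ci$mean, lo = ci$lo,
                       hi = ci$hi),
            class = c("epoch_average", "data.frame"),
            pattern_id = pattern_id, n_flies = nrow(signals),
            n_epochs = n_epochs, seed = seed)
}

#' @export
plot.epoch_average <- function(x, ...) {
  graphics::plot(x$t_rel, x$mean, type = "n",
                 ylim = range(c(x$lo, x$hi)),
                 xlab = "time from stimulus onset (s)", ylab = "signal",
                 main = attr(x, "pattern_id"), ...)
  graphics::polygon(c(x$t_rel, rev(x$t_rel)), c(x$lo, rev(x$hi)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(x$t_rel, x$mean)
  invisible(x)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant signal; z-score undefined")
  (x - mean(x)) / s
}

#' Activity-behavior tuning curve
#'
#' Z-scores both signals, bins the activity into equal-occupancy bins, and
#' reports the per-bin mean wingbeat amplitude with a percentile bootstrap
#' CI (samples within each bin resampled with replacement).
#'
#' @param dff Activity trace (one side's delta-F/F at frame times).
#' @param wba Wingbeat amplitude of one wing, resampled to the same clock.
#' @param n_bins Number of equal-occupancy bins.
#' @param n_boot Bootstrap replicates per bin.
#' @param seed RNG seed.
#' @return An object of class `"tuning_curve"`: data frame with
#'   `dff_z` (bin mean of the z-scored activity), `wba_z`, `lo`, `hi`, `n`.
#' @export
tuning_curve <- function(dff, wba, n_bins = 10, n_boot = 1000, seed = 1) {
  if (length(dff) != length(wba)) stop("signals must be time-aligned")
  x <- zscore(dff); y <- zscore(wba)
  br <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  br <- unique(br)
  bins <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rows <- lapply(sort(unique(bins)), function(b) {
    yi <- y[bins == b]; xi <- x[bins == b]
    bm <- replicate(n_boot, mean(sample(yi, length(yi), replace = TRUE)))
    q <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
    data.frame(dff_z = mean(xi), wba_z = mean(yi), lo = q[1], hi = q[2],
               n = length(yi))
  })
  structure(do.call(rbind, rows),
            class = c("tuning_curve", "data.frame"), seed = seed)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$dff_z, x$wba_z, type = "b", ylim = range(c(x$lo, x$hi)),
                 xlab = "dF/F (z)", ylab = "WBA (z)", ...)
  graphics::arrows(x$dff_z, x$lo, x$dff_z, x$hi, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}

#' Pixel-wise fluorescence-behavior correlation map
#'
#' Pearson correlation of every pixel's time series with the left and right
#' wingbeat amplitude over a flight bout. Correlation is invariant to the
#' affine delta-F/F scaling, so raw registered pixel intensities are used
#' directly. Zero-variance pixels get r = 0 and are flagged.
#'
#' @param stack Registered activity stack, `T x H x W`.
#' @param wba_left,wba_right Behavior resampled to frame times.
#' @param bout Optional integer frame range (e.g. `101:1600`) restricting
#'   the analysis to one flight bout; default all frames.
#' @return An object of class `"pixel_corr_map"`: list with `H x W`
#'   matrices `r_left`, `r_right`, and logical `zero_var`.
#' @export
pixel_correlation_map <- function(stack, wba_left, wba_right, bout = NULL) {
  d <- dim(stack)
  if (length(wba_left) != d[1] || length(wba_right) != d[1])
    stop("behavior must be resampled to frame times")
  if (is.null(bout)) bout <- seq_len(d[1])
  X <- stack_to_matrix(stack)[bout, , drop = FALSE]
  sds <- sqrt(col_variance(X))
  ok <- sds > 0
  r_l <- r_r <- rep(0, ncol(X))
  r_l[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], wba_left[bout]))
  r_r[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], wba_right[bout]))
  structure(list(r_left = matrix(r_l, d[2], d[3]),
                 r_right = matrix(r_r, d[2], d[3]),
                 zero_var = matrix(!ok, d[2], d[3])),
            class = "pixel_corr_map")
}

#' @export
print.pixel_corr_map <- function(x, ...) {
  cat(sprintf("Pixel correlation map %d x %d; r_left in [%.3f, %.3f], r_right in [%.3f, %.3f]\n",
              nrow(x$r_left), ncol(x$r_left), min(x$r_left), max(x$r_left),
              min(x$r_right), max(x$r_right)))
  invisible(x)
}

#' Bilateral side-by-wing correlation summary
#'
#' The 2 x 2 table of Pearson correlations between each hemisphere's
#' activity trace and each wing's amplitude, plus the left-right wingbeat
#' correlation reported as a confound check (the two wings' amplitudes are
#' themselves coupled).
#'
#' @param dff_left,dff_right Per-side activity traces at frame times.
#' @param wba_left,wba_right Wingbeat amplitudes at frame times.
#' @return An object of class `"bilateral_summary"`: list with `cor_table`
#'   (rows = activity side, columns = wing) and `lr_wba_cor`.
#' @export
bilateral_summary <- function(dff_left, dff_right, wba_left, wba_right) {
  sigs <- list(dff_left, dff_right, wba_left, wba_right)
  if (length(unique(vapply(sigs, length, integer(1)))) != 1L)
    stop("all signals must be aligned to the same clock")
  if (any(vapply(sigs, function(s) stats::sd(s) == 0, logical(1))))
    stop("constant input signal")
  tab <- matrix(c(stats::cor(dff_left, wba_left),
                  stats::cor(dff_left, wba_right),
                  stats::cor(dff_right, wba_left),
                  stats::cor(dff_right, wba_right)),
                2, 2, byrow = TRUE,
                dimnames = list(side = c("left", "right"),
                                wing = c("left", "right")))
  structure(list(cor_table = tab,
                 lr_wba_cor = stats::cor(wba_left, wba_right)),
            class = "bilateral_summary")
}

#' @export
print.bilateral_summary <- function(x, ...) {
  cat("Bilateral activity-wing correlations (rows: side; cols: wing)\n")
  print(round(x$cor_table, 3))
  cat(sprintf("Left-right WBA correlation: %.3f\n", x$lr_wba_cor))
  invisible(x)
}
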
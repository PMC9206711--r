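# Generators with known ground truth for every pipeline stage: optogenetic
# wingbeat sessions under a muscle-power cap, dose-response datasets across
# driver lines, and two-channel imaging sessions with bilateral
# activity-behavior coupling. All generators are deterministic given their
# seed and restore the global RNG state on exit.

#' The 13 visual pattern codes
#'
#' Pitch up/down, stripe oscillating left/right, yaw left/right, roll
#' left/right, expansion left/right, progressive and regressive motion, and
#' closed-loop stripe fixation.
#' @export
pattern_codes <- function() {
  c("PU", "OL", "YR", "RL", "EL", "Re", "ER", "Pr", "YL", "RR", "PD",
    "OR", "CL")
}

# Pattern-specific drive to the (left, right) descending-neuron populations.
# Signs encode the observed lateralization: rightward motion drives the
# right-side cells up and the left down. Magnitudes are generator choices.
pattern_drives <- function() {
  m <- rbind(PU = c(0.4, 0.4),  OL = c(0.5, -0.2), YR = c(-1, 1),
             RL = c(-0.4, 0.4), EL = c(0.4, -0.4), Re = c(-0.7, -0.7),
             ER = c(-0.4, 0.4), Pr = c(0.7, 0.7),  YL = c(1, -1),
             RR = c(0.4, -0.4), PD = c(-0.4, -0.4), OR = c(-0.2, 0.5),
             CL = c(0.2, 0.2))
  colnames(m) <- c("left", "right")
  m
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a shuffled visual stimulus protocol
#'
#' Each block presents every one of the 13 pattern codes once for
#' `epoch_s` seconds, separated by `gap_s` seconds of static starfield, in
#' a seeded pseudo-random order.
#'
#' @param seed RNG seed for the shuffle.
#' @param n_blocks Number of blocks.
#' @param epoch_s,gap_s Epoch and inter-epoch durations (s).
#' @return Data frame with columns `pattern_id`, `onset_s`, `duration_s`.
#' @export
make_stimulus_protocol <- function(seed = 1, n_blocks = 1, epoch_s = 3,
                                   gap_s = 3) {
  pats <- pattern_codes()
  with_seed(seed, {
    ids <- unlist(lapply(seq_len(n_blocks),
                         function(b) sample(pats, length(pats))))
  })
  k <- seq_along(ids)
  data.frame(pattern_id = ids,
             onset_s = gap_s + (k - 1) * (epoch_s + gap_s),
             duration_s = epoch_s,
             stringsAsFactors = FALSE)
}

#' Configuration for the optogenetic wingbeat-session simulator
#'
#' Defaults encode the experimental schedule (30 trials of a 100 ms pulse
#' at 10 s intervals) and a response regime in which the amplitude step
#' drives the kinematics into the muscle power cap: the cap defaults to the
#' mechanical power at (`cap_ref_freq` Hz, `saturation_amp` deg) under the
#' morphometrics in use, so frequency starts falling once amplitude passes
#' the saturation level at typical frequencies.
#'
#' @param baseline_amp Pre-stimulus bilateral-mean amplitude (deg).
#' @param baseline_freq Pre-stimulus wingbeat frequency (Hz).
#' @param response_gain Asymptotic amplitude step (deg).
#' @param rise_tau Exponential rise time constant (s).
#' @param decay_tau Post-response decay time constant (s).
#' @param act_dur Duration of effective actuation after pulse onset (s);
#'   the 100 ms light pulse recruits the muscles for about half a second.
#' @param freq_gain Unconstrained frequency rise per degree of amplitude
#'   (Hz/deg).
#' @param saturation_amp Amplitude at which the default power cap is
#'   anchored (deg).
#' @param power_cap Muscle power budget (W kg^-1); `NULL` (default) derives
#'   it from `saturation_amp` and `cap_ref_freq`.
#' @param cap_ref_freq Frequency anchor for the default cap (Hz).
#' @param noise_sd_amp,noise_sd_freq Gaussian noise SD on each wing's
#'   amplitude (deg) and on frequency (Hz).
#' @param n_trials,interpulse_s,pulse_ms Stimulus schedule.
#' @param fs Sampling rate (Hz).
#' @param seed RNG seed.
#' @return A list of class `"opto_sim_config"`.
#' @export
opto_sim_config <- function(baseline_amp = 130, baseline_freq = 200,
                            response_gain = 40, rise_tau = 0.12,
                            decay_tau = 0.4, act_dur = 0.5,
                            freq_gain = 0.3, saturation_amp = 160,
                            power_cap = NULL, cap_ref_freq = 200,
                            noise_sd_amp = 2, noise_sd_freq = 2,
                            n_trials = 30, interpulse_s = 10,
                            pulse_ms = 100, fs = 200, seed = 1) {
  cfg <- as.list(environment())
  num <- cfg[setdiff(names(cfg), "power_cap")]
  if (!all(vapply(num, function(x) is.numeric(x) && x > 0 ||
                    identical(x, 0), logical(1))))
    stop("all configuration values must be positive numbers")
  structure(cfg, class = "opto_sim_config")
}

#' Simulate an optogenetic activation session
#'
#' Amplitude follows a saturating exponential approach toward
#' `baseline_amp + response_gain` after each pulse, then decays. The
#' unconstrained frequency rises with amplitude (`freq_gain`); whenever the
#' implied mechanical power would exceed the muscle power cap, frequency is
#' clamped to the constant-power isoline value at the current amplitude, so
#' the amplitude-frequency tradeoff emerges from the aerodynamic model, not
#' from an ad-hoc curve. Seeded Gaussian noise is added to each wing's
#' amplitude and to frequency.
#'
#' @param cfg An [opto_sim_config()].
#' @param morph A [morphometrics()] object.
#' @param fly_id,line_id Identifiers for the output trace.
#' @return A list with `trace` (a [trial_trace()]) and `truth` (noiseless
#'   `phi_true` and `n_true` series, pulse onsets, the resolved
#'   `power_cap`, and the config).
#' @export
simulate_wingbeat_session <- function(cfg, morph = default_morphometrics(),
                                      fly_id = "sim_fly",
                                      line_id = "sim_line") {
  stopifnot(inherits(cfg, "opto_sim_config"),
            inherits(morph, "morphometrics"))
  cap <- cfg$power_cap
  if (is.null(cap)) {
    kin <- kinematic_state(cfg$cap_ref_freq, cfg$saturation_amp, "deg")
    cap <- mechanical_power(kin, morph)$P_mech
  }
  base_kin <- kinematic_state(cfg$baseline_freq, cfg$baseline_amp, "deg")
  if (mechanical_power(base_kin, morph)$P_mech >= cap)
    stop("power_cap is at or below the baseline mechanical power")
  t_end <- 5 + cfg$n_trials * cfg$interpulse_s
  t <- seq(0, t_end, by = 1 / cfg$fs)
  onsets <- 5 + (seq_len(cfg$n_trials) - 1) * cfg$interpulse_s
  # activation envelope r(t) in [0, 1)
  r <- numeric(length(t))
  for (o in onsets) {
    s <- t - o
    rise <- s >= 0 & s < cfg$act_dur
    fall <- s >= cfg$act_dur
    r[rise] <- pmax(r[rise], 1 - exp(-s[rise] / cfg$rise_tau))
    peak <- 1 - exp(-cfg$act_dur / cfg$rise_tau)
    r[fall] <- pmax(r[fall], peak * exp(-(s[fall] - cfg$act_dur) /
                                          cfg$decay_tau))
  }
  phi_true <- cfg$baseline_amp + cfg$response_gain * r
  n_unc <- cfg$baseline_freq + cfg$freq_gain * (phi_true - cfg$baseline_amp)
  n_cap <- freq_at_power(phi_true * pi / 180, cap, morph)
  n_true <- pmin(n_unc, n_cap, na.rm = TRUE)
  with_seed(cfg$seed, {
    wl <- phi_true + stats::rnorm(length(t), 0, cfg$noise_sd_amp)
    wr <- phi_true + stats::rnorm(length(t), 0, cfg$noise_sd_amp)
    fq <- n_true + stats::rnorm(length(t), 0, cfg$noise_sd_freq)
  })
  trace <- trial_trace(t, wl, wr, fq, onsets, fly_id = fly_id,
                       line_id = line_id)
  list(trace = trace,
       truth = list(phi_true = phi_true, n_true = n_true,
                    envelope = r, onsets = onsets, power_cap = cap,
                    config = cfg))
}

#' Configuration for the dose-response simulator
#'
#' @param true_slope Generating slope of the baseline-subtracted response
#'   on cell-pair count (deg per pair).
#' @param intercept Response at zero pairs (deg).
#' @param n_pairs_list Cell-pair counts, one driver line per entry.
#' @param flies_per_line Flies simulated per line.
#' @param per_fly_sd Gaussian SD of per-fly responses (deg).
#' @param baseline_mean,baseline_sd Per-fly raw baseline amplitude
#'   distribution (deg), used to build the non-baseline-subtracted values.
#' @param slope_raw Optional distinct slope for the raw mode; default
#'   `NULL` uses `true_slope` (the null of the interaction test).
#' @param seed RNG seed.
#' @return A list of class `"dose_sim_config"`.
#' @export
dose_sim_config <- function(true_slope = 2.77, intercept = 2,
                            n_pairs_list = 1:15, flies_per_line = 8,
                            per_fly_sd = 4, baseline_mean = 140,
                            baseline_sd = 10, slope_raw = NULL, seed = 1) {
  structure(as.list(environment()), class = "dose_sim_config")
}

#' Simulate a per-fly dose-response dataset
#'
#' Each fly's baseline-subtracted response is
#' `intercept + true_slope * n_pairs + N(0, per_fly_sd)`; its raw response
#' adds an independently drawn per-fly baseline (plus any extra raw-mode
#' slope), so the BLS/RAW pair exercises the interaction test.
#'
#' @param cfg A [dose_sim_config()].
#' @return A list with `table` (data frame: `line_id`, `fly_id`, `n_pairs`,
#'   `baseline_wba`, `delta_wba`, `response_raw`) and `truth` (the config).
#' @export
simulate_dose_response <- function(cfg) {
  stopifnot(inherits(cfg, "dose_sim_config"))
  nl <- length(cfg$n_pairs_list)
  line_id <- sprintf("L%02d", seq_len(nl))
  slope_raw <- if (is.null(cfg$slope_raw)) cfg$true_slope else cfg$slope_raw
  with_seed(cfg$seed, {
    rows <- lapply(seq_len(nl), function(i) {
      np <- cfg$n_pairs_list[i]
      delta <- cfg$intercept + cfg$true_slope * np +
        stats::rnorm(cfg$flies_per_line, 0, cfg$per_fly_sd)
      base <- stats::rnorm(cfg$flies_per_line, cfg$baseline_mean,
                           cfg$baseline_sd)
      raw <- base + cfg$intercept + slope_raw * np +
        stats::rnorm(cfg$flies_per_line, 0, cfg$per_fly_sd)
      data.frame(line_id = line_id[i],
                 fly_id = sprintf("%s_f%02d", line_id[i],
                                  seq_len(cfg$flies_per_line)),
                 n_pairs = np, baseline_wba = base, delta_wba = delta,
                 response_raw = raw, stringsAsFactors = FALSE)
    })
  })
  list(table = do.call(rbind, rows), truth = list(config = cfg))
}

#' Build line summaries from a per-fly dose-response table
#'
#' @param table Data frame with columns `line_id`, `n_pairs`, `delta_wba`.
#' @return A list of `"line_summary"` objects, one per line.
#' @export
line_summaries_from_table <- function(table) {
  stopifnot(all(c("line_id", "n_pairs", "delta_wba") %in% names(table)))
  lapply(split(table, table$line_id), function(d)
    summarize_line(d$delta_wba, n_pairs = d$n_pairs[1],
                   line_id = d$line_id[1]))
}

#' Configuration for the imaging-session simulator
#'
#' @param shape Integer `c(T, H, W)` movie shape.
#' @param frame_rate Acquisition rate (Hz).
#' @param arbor_sigma Gaussian arbor width (px).
#' @param arbor_amp Peak arbor intensity in the activity channel (a.u.).
#' @param g_contra Behavioral gain of the contralateral side's activity
#'   (deg per unit activity, > 0).
#' @param g_ipsi Ipsilateral gain (deg per unit activity, <= 0).
#' @param baseline_wba Resting wingbeat amplitude (deg).
#' @param baseline_act Resting latent activity level.
#' @param ca_tau Calcium-indicator decay time constant (s).
#' @param motion_jitter_px Maximum absolute in-plane jitter (integer px).
#' @param photon_noise Shot-noise scale (SD = `photon_noise * sqrt(I)`).
#' @param z_drift Relative amplitude of slow multiplicative gain drift
#'   shared by both channels (z motion surrogate).
#' @param behavior_noise_sd Gaussian SD on recorded wingbeat amplitude
#'   (deg).
#' @param tracker_lag_s Delay injected into the recorded behavior (s).
#' @param protocol Optional stimulus protocol; `NULL` generates enough
#'   shuffled blocks to cover the movie.
#' @param preset `"custom"` keeps the supplied noise values; `"noiseless"`
#'   zeroes jitter and every noise source; `"moderate"` is a documented
#'   mid-noise condition (jitter 2 px, shot noise 0.3, 5% z drift, 2 deg
#'   behavior noise).
#' @param seed RNG seed.
#' @return A list of class `"imaging_sim_config"`.
#' @export
imaging_sim_config <- function(shape = c(1600, 64, 128), frame_rate = 13.1,
                               arbor_sigma = 5, arbor_amp = 120,
                               g_contra = 8, g_ipsi = -3,
                               baseline_wba = 130, baseline_act = 0.2,
                               ca_tau = 0.6, motion_jitter_px = 2,
                               photon_noise = 0.3, z_drift = 0.05,
                               behavior_noise_sd = 2,
                               tracker_lag_s = 0.030, protocol = NULL,
                               preset = c("custom", "noiseless",
                                          "moderate"),
                               seed = 1) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  if (preset == "noiseless") {
    cfg$motion_jitter_px <- 0; cfg$photon_noise <- 0
    cfg$z_drift <- 0; cfg$behavior_noise_sd <- 0
  } else if (preset == "moderate") {
    cfg$motion_jitter_px <- 2; cfg$photon_noise <- 0.3
    cfg$z_drift <- 0.05; cfg$behavior_noise_sd <- 2
  }
  if (cfg$g_contra <= 0) stop("g_contra must be positive")
  if (cfg$g_ipsi > 0) stop("g_ipsi must be <= 0")
  H <- cfg$shape[2]; W <- cfg$shape[3]
  cfg$center_left <- c(H / 2, W / 4)
  cfg$center_right <- c(H / 2, 3 * W / 4)
  if (cfg$center_left[2] + 2 * cfg$arbor_sigma > W / 2 ||
      cfg$center_right[2] - 2 * cfg$arbor_sigma < W / 2 ||
      2 * cfg$arbor_sigma > H / 2)
    stop("arbors do not fit within their half of the frame")
  structure(cfg, class = "imaging_sim_config")
}

gaussian_blob <- function(H, W, cy, cx, sigma) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sigma^2))
}

# First-order low-pass: a[k] = a[k-1] * exp(-dt/tau) + d[k] * (1 - exp(-dt/tau))
ca_filter <- function(drive, dt, tau) {
  al <- exp(-dt / tau)
  out <- numeric(length(drive))
  prev <- drive[1]
  for (k in seq_along(drive)) {
    prev <- prev * al + drive[k] * (1 - al)
    out[k] <- prev
  }
  out
}

#' Simulate a bilateral two-photon imaging session
#'
#' Latent per-side activity is a calcium-filtered version of the
#' pattern-specific drive (rightward motion raises right-side activity and
#' lowers left-side activity, and so on per [pattern_drives()]). Wingbeat
#' amplitude of each wing is driven by the contralateral side's activity
#' with gain `g_contra` and by the ipsilateral side with `g_ipsi`, sampled
#' at 32 Hz with the tracker delay injected. The GCaMP channel shows two
#' Gaussian arbors scaled by the latent activity; the tdTomato channel
#' shows the same arbors statically. Both channels share the injected
#' integer motion jitter and a slow multiplicative gain drift, plus
#' intensity-dependent shot noise.
#'
#' @param cfg An [imaging_sim_config()].
#' @return A list with `movie` (a [two_channel_movie()]), `behavior` (an
#'   uncorrected [behavior_trace()] at 32 Hz), `protocol`, and `truth`
#'   (latent activity per side at frame times, injected `shifts`, the true
#'   un-delayed behavior, and the config).
#' @export
simulate_imaging_session <- function(cfg) {
  stopifnot(inherits(cfg, "imaging_sim_config"))
  T_ <- cfg$shape[1]; H <- cfg$shape[2]; W <- cfg$shape[3]
  ft <- (seq_len(T_) - 1) / cfg$frame_rate
  dur <- ft[T_]
  protocol <- cfg$protocol
  if (is.null(protocol)) {
    nb <- max(1L, ceiling(dur / (13 * 6)))
    protocol <- make_stimulus_protocol(seed = cfg$seed, n_blocks = nb)
  }
  drv <- pattern_drives()
  d_l <- numeric(T_); d_r <- numeric(T_)
  for (i in seq_len(nrow(protocol))) {
    sel <- ft >= protocol$onset_s[i] &
      ft < protocol$onset_s[i] + protocol$duration_s[i]
    g <- drv[protocol$pattern_id[i], ]
    d_l[sel] <- d_l[sel] + g[1]
    d_r[sel] <- d_r[sel] + g[2]
  }
  dt <- 1 / cfg$frame_rate
  a_l <- pmax(cfg$baseline_act + ca_filter(d_l, dt, cfg$ca_tau), 0)
  a_r <- pmax(cfg$baseline_act + ca_filter(d_r, dt, cfg$ca_tau), 0)

  # behavior on its own 32 Hz clock
  t32 <- seq(0, dur, by = 1 / 32)
  al32 <- stats::approx(ft, a_l, xout = t32, rule = 2)$y
  ar32 <- stats::approx(ft, a_r, xout = t32, rule = 2)$y
  true_l <- cfg$baseline_wba + cfg$g_contra * ar32 + cfg$g_ipsi * al32
  true_r <- cfg$baseline_wba + cfg$g_contra * al32 + cfg$g_ipsi * ar32

  blob_l <- gaussian_blob(H, W, cfg$center_left[1], cfg$center_left[2],
                          cfg$arbor_sigma)
  blob_r <- gaussian_blob(H, W, cfg$center_right[1], cfg$center_right[2],
                          cfg$arbor_sigma)
  bg_g <- 10; bg_r <- 30
  zf <- 1 + cfg$z_drift * sin(2 * pi * ft / 60)

  with_seed(cfg$seed, {
    j <- cfg$motion_jitter_px
    shifts <- if (j > 0)
      cbind(dy = sample(-j:j, T_, replace = TRUE),
            dx = sample(-j:j, T_, replace = TRUE))
    else matrix(0L, T_, 2, dimnames = list(NULL, c("dy", "dx")))
    gc <- array(0, c(T_, H, W)); td <- array(0, c(T_, H, W))
    for (k in seq_len(T_)) {
      img_g <- (bg_g + cfg$arbor_amp * (blob_l * a_l[k] + blob_r * a_r[k])) *
        zf[k]
      # unequal static amplitudes: breaks the left/right symmetry so the
      # registration cross-correlation peak is unique
      img_r <- (bg_r + cfg$arbor_amp * (0.9 * blob_l + 0.6 * blob_r)) * zf[k]
      if (any(shifts[k, ] != 0)) {
        img_g <- shift_image(img_g, shifts[k, 1], shifts[k, 2],
                             fill = bg_g * zf[k])
        img_r <- shift_image(img_r, shifts[k, 1], shifts[k, 2],
                             fill = bg_r * zf[k])
      }
      if (cfg$photon_noise > 0) {
        img_g <- img_g + stats::rnorm(H * W) * cfg$photon_noise *
          sqrt(pmax(img_g, 0))
        img_r <- img_r + stats::rnorm(H * W) * cfg$photon_noise *
          sqrt(pmax(img_r, 0))
      }
      gc[k, , ] <- img_g
      td[k, , ] <- img_r
    }
    rec_l <- stats::approx(t32, true_l, xout = t32 - cfg$tracker_lag_s,
                           rule = 2)$y +
      stats::rnorm(length(t32), 0, cfg$behavior_noise_sd)
    rec_r <- stats::approx(t32, true_r, xout = t32 - cfg$tracker_lag_s,
                           rule = 2)$y +
      stats::rnorm(length(t32), 0, cfg$behavior_noise_sd)
  })
  list(movie = two_channel_movie(gc, td, cfg$frame_rate, ft),
       behavior = behavior_trace(t32, rec_l, rec_r,
                                 lag_corrected = FALSE),
       protocol = protocol,
       truth = list(activity_left = a_l, activity_right = a_r,
                    frame_times = ft, shifts = shifts,
                    behavior_true = data.frame(t = t32,
                                               wba_left = true_l,
                                               wba_right = true_r),
                    config = cfg))
}
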
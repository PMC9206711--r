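# Shared fixtures, all built in code.

# Small morphometrics with hand-enterable values for closed-form oracles.
fixture_morph <- function(cd_pro_fixed = NULL, kappa = 1.2) {
  morphometrics(F_t = 1.2e-5, R = 2.4e-3, S = 3.6e-6, m_M = 3e-7,
                rho = 1.2, g = 9.81, kappa = kappa,
                r3_hat_cubed = 0.2, mean_abs_angvel_cubed = 100,
                cd_pro_fixed = cd_pro_fixed, nu = 1.5e-5)
}

# A trace with one constant-step response: baseline level `base` before the
# pulse, `base + step` from onset onward.
step_trace <- function(base = 140, step = 20, fs = 1000, onset = 2,
                       dur = 4, freq_base = 200, freq_step = 5) {
  t <- seq(0, dur, by = 1 / fs)
  amp <- ifelse(t < onset, base, base + step)
  fq <- ifelse(t < onset, freq_base, freq_base + freq_step)
  trial_trace(t, amp, amp, fq, pulse_onsets = onset, fly_id = "f1",
              line_id = "l1")
}

# Tiny movie: two fluctuating blobs on a dim background, with optional
# injected integer shifts (returned as attr "shifts").
blob_movie <- function(T_ = 40, H = 16, W = 24, shifts = NULL, seed = 7) {
  set.seed(seed)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  blob <- function(cy, cx) exp(-((yy - cy)^2 + (xx - cx)^2) / 8)
  bl <- blob(H / 2, W / 4); br <- blob(H / 2, 3 * W / 4)
  a_l <- abs(sin(seq_len(T_) / 3)); a_r <- abs(cos(seq_len(T_) / 4))
  if (is.null(shifts)) shifts <- matrix(0L, T_, 2)
  g <- array(0, c(T_, H, W)); r <- array(0, c(T_, H, W))
  for (k in seq_len(T_)) {
    fg <- 5 + 50 * (bl * a_l[k] + br * a_r[k])
    fr <- 10 + 40 * bl + 25 * br
    if (any(shifts[k, ] != 0)) {
      fg <- dnflight:::shift_image(fg, shifts[k, 1], shifts[k, 2], fill = 5)
      fr <- dnflight:::shift_image(fr, shifts[k, 1], shifts[k, 2], fill = 10)
    }
    g[k, , ] <- fg; r[k, , ] <- fr
  }
  m <- two_channel_movie(g, r, frame_rate = 10)
  attr(m, "shifts") <- shifts
  attr(m, "latent") <- cbind(left = a_l, right = a_r)
  m
}
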
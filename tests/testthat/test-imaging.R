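# Imaging pipeline: registration, masks, traces, dF/F, lag correction,
# epoch averages, tuning curves, correlation maps.

test_that("registration: aligned movie gives zero shifts, idempotent", {
  mv <- blob_movie()
  reg <- register_to_reference(mv)
  expect_true(all(reg$shifts == 0))
  reg2 <- register_to_reference(reg$movie)
  expect_true(all(reg2$shifts == 0))
})

test_that("registration recovers injected integer shifts exactly", {
  set.seed(1)
  sh <- cbind(sample(-3:3, 40, replace = TRUE),
              sample(-3:3, 40, replace = TRUE))
  sh[1:5, ] <- 0L # keep the reference anchored
  storage.mode(sh) <- "integer"
  mv <- blob_movie(shifts = sh)
  reg <- register_to_reference(mv)
  expect_identical(unname(reg$shifts), unname(sh))
  # all-zero frame: zero shift with a warning
  g <- mv$gcamp; r <- mv$tdtom
  r[3, , ] <- 0
  mz <- two_channel_movie(g, r, 10)
  expect_warning(rz <- register_to_reference(mz), "all zero")
  expect_identical(unname(rz$shifts[3, ]), c(0L, 0L))
})

test_that("variable-pixel ROI masks have exact floor sizes in each half", {
  mv <- blob_movie(T_ = 30, H = 16, W = 24)
  rois <- select_variable_rois(mv$gcamp)
  expect_equal(sum(rois$left_mask), floor(0.2 * 16 * 12))
  expect_equal(sum(rois$right_mask), floor(0.2 * 16 * 12))
  expect_true(all(which(rois$left_mask, arr.ind = TRUE)[, 2] <= 12))
  expect_true(all(which(rois$right_mask, arr.ind = TRUE)[, 2] > 12))
  expect_false(any(rois$left_mask & rois$right_mask))
  # fluctuating blobs contain the masks
  blob_support <- apply(mv$gcamp, c(2, 3), max) > 6
  expect_true(all(blob_support[rois$left_mask | rois$right_mask]))
  # constant offset leaves variance ranking unchanged
  rois2 <- select_variable_rois(mv$gcamp + 100)
  expect_identical(rois, rois2)
  expect_error(select_variable_rois(array(3, c(5, 8, 8))),
               "variability")
})

test_that("background mask selects the dimmest fifth of the FOV", {
  mv <- blob_movie(T_ = 30, H = 16, W = 24)
  bg <- select_background(mv$gcamp)
  expect_equal(sum(bg), floor(0.2 * 16 * 24))
  mu <- apply(mv$gcamp, c(2, 3), mean)
  expect_lte(max(mu[bg]), min(mu[!bg]))
  # uniform image: ties resolved in raster (column-major) order
  u <- array(1, c(5, 10, 10))
  bgu <- select_background(u)
  expect_identical(which(as.vector(bgu)), seq_len(20))
})

test_that("ROI fluorescence is background-subtracted mean intensity", {
  st <- array(10, c(4, 6, 6))
  roi <- matrix(FALSE, 6, 6); roi[2:3, 2:3] <- TRUE
  bgm <- matrix(FALSE, 6, 6); bgm[5:6, 5:6] <- TRUE
  st[, 2:3, 2:3] <- 100
  expect_equal(roi_fluorescence(st, roi, bgm), rep(90, 4))
  # ROI identical to background: zero signal, overlap flagged
  expect_warning(z <- roi_fluorescence(st, bgm, bgm), "overlap")
  expect_equal(z, rep(0, 4))
  expect_error(roi_fluorescence(st, matrix(FALSE, 6, 6), bgm), "empty")
  # naive two-loop oracle on an arbitrary stack
  set.seed(3)
  st2 <- array(runif(4 * 6 * 6), c(4, 6, 6))
  got <- roi_fluorescence(st2, roi, bgm)
  for (k in 1:4) {
    rsum <- 0; bsum <- 0
    for (y in 1:6) for (x in 1:6) {
      if (roi[y, x]) rsum <- rsum + st2[k, y, x]
      if (bgm[y, x]) bsum <- bsum + st2[k, y, x]
    }
    expect_equal(got[k], rsum / 4 - bsum / 4)
  }
})

test_that("ratio normalization cancels shared per-frame gain", {
  g <- c(1, 2, 3, 4); r <- rep(2, 4)
  expect_equal(ratio_normalize(g, r), g / 2)
  z <- c(1, 0.8, 1.2, 0.9) # shared z-drift factor
  expect_equal(ratio_normalize(g * z, r * z), ratio_normalize(g, r))
  expect_error(ratio_normalize(g, rep(0, 4)), "median")
  expect_error(ratio_normalize(g, r[1:2]), "length")
  # floor engages on near-zero denominators
  r2 <- c(2, 2, 1e-9, 2)
  expect_true(all(is.finite(ratio_normalize(g, r2))))
})

test_that("baseline F0 is the mean of the lowest decile", {
  expect_equal(baseline_f0(rep(5, 20)), 5)
  expect_equal(baseline_f0(1:10), 1)
  expect_equal(baseline_f0(1:20), 1.5)
  set.seed(9)
  x <- rnorm(57)
  expect_equal(baseline_f0(x), mean(sort(x)[1:5]))
  expect_error(baseline_f0(1:5), "10 samples")
})

test_that("dF/F peaks at exactly 1 and is affine-invariant", {
  set.seed(2)
  f <- cumsum(rnorm(50)) + 20
  d <- normalized_dff(f)
  expect_identical(max(d), 1)
  # positive affine transform of raw intensities: identical output
  expect_equal(normalized_dff(3.7 * f + 11), d)
  expect_error(normalized_dff(rep(2, 50)), "dynamic range")
})

test_that("lag correction shifts a sinusoid by the tracker delay", {
  t <- seq(0, 4, by = 1 / 32)
  f <- 1
  beh <- behavior_trace(t, sin(2 * pi * f * t), cos(2 * pi * f * t))
  cor_b <- lag_correct_behavior(beh, 0.030)
  inner <- t > 0.2 & t < 3.8
  expect_equal(cor_b$wba_left[inner], sin(2 * pi * f * (t[inner] + 0.03)),
               tolerance = 5e-3)
  expect_true(cor_b$lag_corrected)
  expect_error(lag_correct_behavior(cor_b), "already")
  # zero lag is the identity
  expect_equal(lag_correct_behavior(beh, 0)$wba_left, beh$wba_left)
  # round trip within interpolation tolerance
  rt <- lag_correct_behavior(cor_b, -0.030, force = TRUE)
  expect_equal(rt$wba_left[inner], beh$wba_left[inner], tolerance = 5e-3)
})

test_that("epoch averages: degenerate and invariance cases", {
  times <- seq(0, 30, by = 0.1)
  prot <- data.frame(pattern_id = c("YR", "YL"), onset_s = c(5, 15),
                     duration_s = 3)
  shape <- sin(2 * pi * times / 7)
  sig <- rbind(shape, shape, shape) # identical flies
  ea <- epoch_average(sig, times, prot, "YR", n_boot = 100, seed = 5)
  expect_equal(ea$lo, ea$mean, tolerance = 1e-12)
  expect_equal(ea$hi, ea$mean, tolerance = 1e-12)
  expect_lt(abs(mean(ea$mean[ea$t_rel < 0])), 1e-9)
  # adding a constant to every trace changes nothing (baseline-subtracted)
  ea2 <- epoch_average(sig + 40, times, prot, "YR", n_boot = 100,
                       seed = 5)
  expect_equal(ea2$mean, ea$mean)
  expect_equal(ea2$hi - ea2$lo, ea$hi - ea$lo)
  expect_error(epoch_average(sig, times, prot, "PU"), "absent")
  expect_error(epoch_average(sig[1, , drop = FALSE], times, prot, "YR"),
               "2 flies")
  # single fly with repeated epochs: epoch-level bootstrap works
  prot2 <- data.frame(pattern_id = "YR", onset_s = c(5, 15, 25),
                      duration_s = 3)
  ea1 <- epoch_average(sig[1, , drop = FALSE], times, prot2, "YR",
                       n_boot = 100, seed = 2)
  expect_equal(attr(ea1, "n_epochs"), 3L)
  # reproducible bit-for-bit given seed
  set.seed(999) # unrelated global state must not matter
  sig2 <- sig + matrix(rnorm(length(sig)), nrow(sig))
  a <- epoch_average(sig2, times, prot, "YR", n_boot = 200, seed = 7)
  b <- epoch_average(sig2, times, prot, "YR", n_boot = 200, seed = 7)
  expect_identical(a, b)
})

test_that("bootstrap CI covers the true mean at near-nominal rate", {
  cover <- vapply(1:60, function(r) {
    set.seed(3000 + r)
    mat <- matrix(rnorm(20 * 15), 20, 15) # true mean 0
    ci <- bootstrap_mean_ci(mat, n_boot = 300, seed = r)
    mean(ci$lo <= 0 & 0 <= ci$hi)
  }, numeric(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 0.99)
})

test_that("tuning curves are monotone for linear coupling, flat for none", {
  set.seed(4)
  a <- rnorm(2000)
  wba <- 2 * a + rnorm(2000, sd = 0.3)
  tc <- tuning_curve(a, wba, n_bins = 8, n_boot = 200, seed = 1)
  expect_true(all(diff(tc$wba_z) > 0))
  # z-scored inputs: bin means near the identity line
  expect_lt(max(abs(tc$wba_z - tc$dff_z)), 0.15)
  # independent signals: flat within CI
  tc0 <- tuning_curve(a, rnorm(2000), n_bins = 8, n_boot = 200, seed = 1)
  expect_true(all(tc0$lo <= 0.2 & tc0$hi >= -0.2))
  expect_error(tuning_curve(rep(1, 100), rnorm(100)), "constant")
  expect_error(tuning_curve(a, wba[1:10]), "aligned")
})

test_that("pixel correlation maps hit +/-1 on exact copies", {
  T_ <- 60
  set.seed(8)
  wl <- rnorm(T_); wr <- rnorm(T_)
  st <- array(0, c(T_, 4, 6))
  st[, 2, 2] <- wl          # pixel equal to left WBA
  st[, 3, 5] <- -wr         # pixel equal to minus right WBA
  pm <- pixel_correlation_map(st, wl, wr)
  expect_equal(pm$r_left[2, 2], 1)
  expect_equal(pm$r_right[3, 5], -1)
  # zero-variance pixels flagged with r = 0
  expect_true(pm$zero_var[1, 1])
  expect_identical(pm$r_left[1, 1], 0)
  expect_true(all(pm$r_left >= -1 & pm$r_left <= 1))
  expect_error(pixel_correlation_map(st, wl[1:5], wr), "resampled")
})

test_that("bilateral summary reports the sign structure and confound", {
  set.seed(6)
  al <- abs(rnorm(500)); ar <- abs(rnorm(500))
  wl <- 5 * ar - 2 * al + rnorm(500, sd = 0.1)
  wr <- 5 * al - 2 * ar + rnorm(500, sd = 0.1)
  bs <- bilateral_summary(al, ar, wl, wr)
  expect_gt(bs$cor_table["left", "right"], 0)   # contralateral
  expect_lt(bs$cor_table["left", "left"], 0)    # ipsilateral
  expect_gt(bs$cor_table["right", "left"], 0)
  expect_lt(bs$cor_table["right", "right"], 0)
  # symmetric drive: all four correlations approximately equal
  a <- abs(rnorm(500))
  w1 <- 3 * a + rnorm(500, sd = 0.05); w2 <- 3 * a + rnorm(500, sd = 0.05)
  bsym <- bilateral_summary(a, a, w1, w2)
  expect_lt(diff(range(bsym$cor_table)), 0.05)
  # permuted behavior decorrelates
  bnull <- bilateral_summary(al, ar, sample(wl), sample(wr))
  expect_lt(max(abs(bnull$cor_table)), 0.2)
  expect_error(bilateral_summary(al, ar, rep(1, 500), wr), "constant")
})

test_that("full pipeline recovers latent activity from the blob movie", {
  mv <- blob_movie(T_ = 60)
  rois <- select_variable_rois(mv$gcamp)
  bg <- select_background(mv$gcamp)
  lt <- extract_side_trace(mv, rois$left_mask, bg, "left")
  latent <- attr(mv, "latent")
  expect_gt(cor(lt$dff, latent[, "left"]), 0.99)
  expect_identical(max(lt$dff), 1)
})
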
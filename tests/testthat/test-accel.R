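test_that("RC high-pass removes DC and matches first-order closed forms", {
  fs <- 500
  rc <- 1 / (2 * pi * 0.27)

  # DC rejection: constant input decays below 1e-3 g within 10 time constants
  n <- round(20 * rc * fs)
  const <- raw_recording(matrix(0.7, n, 3), fs = fs)
  y <- rc_highpass(const, 0.27)$samples
  expect_lt(max(abs(y[round(10 * rc * fs):n, ])), 1e-3)

  # steady-state sine gain matches |H(f)| = (f/fc)/sqrt(1+(f/fc)^2) when the
  # discretization is fine relative to f (fs = 2000 Hz here)
  gain <- function(f, fs2 = 2000, dur = 200) {
    m <- round(fs2 * dur); t <- (seq_len(m) - 1) / fs2
    x <- sin(2 * pi * f * t)
    rec <- raw_recording(cbind(x, 0, 1), fs = fs2)
    yy <- rc_highpass(rec, 0.27)$samples[, 1]
    keep <- (m %/% 2):m
    sqrt(mean(yy[keep]^2)) / sqrt(mean(x[keep]^2))
  }
  for (f in c(0.27, 2, 10))
    expect_lt(abs(gain(f) - (f / 0.27) / sqrt(1 + (f / 0.27)^2)), 1e-3)

  # unit step decays with time constant RC = 1/(2*pi*0.27) ~ 0.5895 s
  x <- c(rep(0, 10), rep(1, 3000))
  rec <- raw_recording(cbind(x, 0, 0), fs = fs)
  ys <- rc_highpass(rec, 0.27)$samples[, 1]
  expect_lt(abs(ys[10 + round(rc * fs) + 1] - exp(-1)), 2e-3)

  expect_error(rc_highpass(const, fc = 300), "fs/2")
  expect_error(rc_highpass(const, fc = 0), "fs/2")
})

test_that("resultant is the Euclidean norm and is rotation invariant", {
  m <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 2, 2))
  expect_equal(resultant(m), c(0, 5, 3))

  set.seed(4)
  s <- matrix(rnorm(300), 100, 3)
  # random orthonormal rotation via QR
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(resultant(s %*% Q), resultant(s), tolerance = 1e-12)
})

test_that("non-wear detection flags still periods and recovers injected gaps", {
  still <- simulate_recording(
    activity_profile(noise_sd = 0, wear_days = 1, day_length = 7200),
    fs = 10, seed = 1)
  expect_true(all(!wear_vector(detect_nonwear(still, 600, 0.013))))

  noisy <- simulate_recording(
    activity_profile(noise_sd = 0.1, wear_days = 1, day_length = 7200),
    fs = 10, seed = 1)
  expect_true(all(wear_vector(detect_nonwear(noisy, 600, 0.013))))

  # injected 2-h gap recovered with Jaccard >= 0.9
  prof <- activity_profile(nonwear = data.frame(start = 10000, end = 17200),
                           noise_sd = 0.05, wear_days = 1,
                           day_length = 86400)
  rec <- simulate_recording(prof, fs = 10, seed = 3)
  nw <- !wear_vector(detect_nonwear(rec, 1800, 0.013))
  truth <- rep(FALSE, nrow(rec$samples))
  truth[(10000 * 10 + 1):(17200 * 10)] <- TRUE
  expect_gte(sum(nw & truth) / sum(nw | truth), 0.9)

  expect_error(detect_nonwear(still, window = 30), ">= 60")
  expect_error(detect_nonwear(still, window = 10000), "longer than")
})

test_that("merging reported non-wear takes the interval union", {
  prof <- activity_profile(nonwear = data.frame(start = 1000, end = 2000),
                           noise_sd = 0.05, wear_days = 1,
                           day_length = 7200)
  rec <- simulate_recording(prof, fs = 10, seed = 2)
  mask <- detect_nonwear(rec, 600, 0.013)

  expect_identical(merge_reported_nonwear(mask, NULL, 10), mask)

  nested <- merge_reported_nonwear(
    mask, data.frame(start = 1200, end = 1800), 10)
  expect_equal(wear_vector(nested), wear_vector(mask))

  joint <- merge_reported_nonwear(
    mask, data.frame(start = 5000, end = 5500), 10)
  w <- wear_vector(joint)
  expect_true(all(!w[50001:55000]))      # reported interval present
  expect_true(all(!w[11001:19000]))      # automatic interval retained
  expect_error(merge_reported_nonwear(
    mask, data.frame(start = 5000, end = 9000), 10), "span")
})

test_that("daily integrals and epoch sums agree with closed forms and each other", {
  fs <- 10; day <- 3600
  full <- rep(TRUE, fs * day)

  # constant integrand
  d1 <- daily_integral(rep(0.25, fs * day), full, fs, day)
  expect_equal(d1$activity_count, 0.25 * day, tolerance = 1e-9)
  expect_true(d1$valid)
  expect_equal(daily_integral(rep(0, fs * day), full, fs, day)$activity_count, 0)

  # piecewise constant: (r1 + r2) * day / 2
  R2 <- c(rep(0.1, fs * day / 2), rep(0.5, fs * day / 2))
  expect_equal(daily_integral(R2, full, fs, day)$activity_count,
               (0.1 + 0.5) * day / 2, tolerance = 1e-9)

  # additivity: epoch sums over a full-wear day equal the daily integral
  set.seed(8)
  R3 <- abs(rnorm(fs * day * 2))
  w3 <- rep(TRUE, length(R3))
  dd <- daily_integral(R3, w3, fs, day)
  ee <- epoch_series(R3, w3, fs, 60)
  expect_equal(sum(ee$values[1:(day / 60)]), dd$activity_count[1],
               tolerance = 1e-6)

  # all-non-wear day: count 0, invalid; epoch wear fractions 0
  nw <- rep(FALSE, fs * day)
  d0 <- daily_integral(R3[seq_len(fs * day)], nw, fs, day)
  expect_equal(d0$activity_count, 0)
  expect_false(d0$valid)
  e0 <- epoch_series(R3[seq_len(fs * day)], nw, fs, 60)
  expect_true(all(e0$values == 0) && all(e0$wear_fraction == 0))

  # trailing partial epoch dropped
  ep <- epoch_series(rep(1, fs * 150), rep(TRUE, fs * 150), fs, 60)
  expect_length(ep$values, 2)
  expect_error(daily_integral(numeric(0), logical(0), fs, day), "empty")
})

test_that("epoch classification respects thresholds, boundaries and the wear rule", {
  cp <- cut_points(moderate_threshold = 3, vigorous_threshold = 10)
  ep <- structure(list(epoch_length = 60,
                       values = c(0, 2.99, 3, 5, 10, 40),
                       wear_fraction = rep(1, 6)),
                  class = "epoch_series")
  cls <- classify_mvpa(ep, cp)
  expect_equal(as.character(cls),
               c("below", "below", "moderate", "moderate", "vigorous",
                 "vigorous"))

  # epochs worn < 50% are never classified as MVPA
  ep$wear_fraction <- c(1, 1, 0.4, 1, 0.2, 1)
  expect_equal(as.character(classify_mvpa(ep, cp)),
               c("below", "below", "below", "moderate", "below", "vigorous"))

  expect_error(cut_points(5, 4), "moderate < vigorous")

  # a crafted day with exactly k elevated epochs yields k MVPA minutes
  fs <- 10; day <- 3600; k <- 7
  R <- rep(0.01, fs * day)
  for (i in seq_len(k)) {
    idx <- ((2 * i) * 60 * fs + 1):((2 * i + 1) * 60 * fs)
    R[idx] <- 0.2  # 0.2 g*s/s * 60 s = 12 g*s per epoch, above moderate
  }
  eps <- epoch_series(R, rep(TRUE, length(R)), fs, 60)
  mv <- daily_mvpa_minutes(classify_mvpa(eps, cp), 60, day)
  expect_equal(mv, k)
})

test_that("valid-day summarisation applies the 5-of-7 inclusion rule", {
  mk <- function(valid, counts = seq_along(valid), mvpa = rep(10, length(valid)))
    data.frame(day_index = seq_along(valid), activity_count = counts,
               mvpa_minutes = mvpa, valid = valid)

  s7 <- summarize_participant(mk(rep(TRUE, 7)))
  expect_true(s7$included)
  expect_equal(s7$mean_daily_count, mean(1:5))  # first 5 valid days only
  expect_equal(s7$n_valid_days, 7)

  s4 <- summarize_participant(mk(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                                   FALSE)))
  expect_false(s4$included)
  expect_true(is.na(s4$mean_daily_count))

  # exactly 5 valid days, identical counts -> that constant
  s5 <- summarize_participant(mk(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                                   TRUE), counts = rep(42, 7)))
  expect_true(s5$included)
  expect_equal(s5$mean_daily_count, 42)

  # an 8th day never counts towards the 7-day window
  s8 <- summarize_participant(mk(c(rep(FALSE, 3), rep(TRUE, 5))))
  expect_false(s8$included)
  expect_error(summarize_participant(mk(logical(0))), "empty")
})

test_that("pipeline outputs are invariant under a fixed rotation of the raw signal", {
  prof <- reduced_profile(days = 1)
  rec <- simulate_recording(prof, fs = 10, seed = 13)
  cfg <- reduced_config(min_valid_days = 1, use_first_days = 1,
                        window_days = 1)
  base <- process_recording(rec, cfg)

  theta <- 0.7
  Q <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  rot <- rec
  rot$samples <- rec$samples %*% Q
  colnames(rot$samples) <- c("x", "y", "z")
  rotated <- process_recording(rot, cfg)
  expect_equal(rotated$summary$mean_daily_count,
               base$summary$mean_daily_count, tolerance = 1e-8)
  expect_equal(rotated$days$mvpa_minutes, base$days$mvpa_minutes)
})
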
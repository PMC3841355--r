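#' Activity profile for the raw-signal generator
#'
#' Describes the ground truth of one synthetic wear period: a schedule of
#' activity bouts superimposed on the static 1 g gravity component, optional
#' non-wear gaps, slow orientation drift and wide-band sensor noise. All times
#' are seconds from the start of the recording.
#'
#' @param bouts `data.frame` with columns `start` (s), `duration` (s),
#'   `amplitude` (g; RMS of the oscillatory resultant added during the bout)
#'   and `frequency` (Hz of the movement oscillation, default 2 Hz — well
#'   above the 0.27 Hz high-pass cutoff so bout energy passes the filter).
#'   `NULL` means no bouts.
#' @param nonwear `data.frame` with columns `start`, `end` (s, end exclusive)
#'   of intervals during which the device lies still. `NULL` means full wear.
#' @param orientation_drift_period Period (s) of a slow rotation of the
#'   gravity vector; `Inf` (default) keeps the orientation fixed.
#' @param noise_sd Per-axis wide-band noise SD in g. Inside non-wear
#'   intervals the noise SD is reduced 100-fold, giving the automated
#'   non-wear detector its signature.
#' @param wear_days Number of simulated days.
#' @param day_length Day length in seconds (86400; reduced-scale test runs
#'   may shorten it, all downstream windows being defined in seconds).
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(bouts = NULL, nonwear = NULL,
                             orientation_drift_period = Inf,
                             noise_sd = 0.01, wear_days = 7,
                             day_length = 86400) {
  if (is.null(bouts))
    bouts <- data.frame(start = numeric(), duration = numeric(),
                        amplitude = numeric(), frequency = numeric())
  bouts <- as.data.frame(bouts)
  if (is.null(bouts$frequency)) bouts$frequency <- rep(2, nrow(bouts))
  if (is.null(nonwear))
    nonwear <- data.frame(start = numeric(), end = numeric())
  nonwear <- as.data.frame(nonwear)
  p <- structure(list(bouts = bouts, nonwear = nonwear,
                      orientation_drift_period = orientation_drift_period,
                      noise_sd = noise_sd, wear_days = wear_days,
                      day_length = day_length),
                 class = "activity_profile")
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  span <- p$wear_days * p$day_length
  b <- p$bouts; nw <- p$nonwear
  check_that(
    "wear_days and day_length must be positive" =
      p$wear_days > 0 && p$day_length > 0,
    "noise_sd must be >= 0" = p$noise_sd >= 0,
    "bout amplitudes must be >= 0" = nrow(b) == 0 || all(b$amplitude >= 0),
    "bout frequencies must be > 0" = nrow(b) == 0 || all(b$frequency > 0),
    "bouts must lie within the recording span" =
      nrow(b) == 0 || all(b$start >= 0 & b$start + b$duration <= span),
    "non-wear intervals must lie within the recording span" =
      nrow(nw) == 0 || all(nw$start >= 0 & nw$end <= span & nw$start < nw$end)
  )
  # bouts may not overlap non-wear gaps
  if (nrow(b) && nrow(nw)) {
    for (i in seq_len(nrow(b))) {
      b0 <- b$start[i]; b1 <- b$start[i] + b$duration[i]
      if (any(b0 < nw$end & b1 > nw$start))
        stop("bouts must not overlap non-wear intervals", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Raw tri-axial recording container
#'
#' @param samples Numeric matrix with columns `x`, `y`, `z`, accelerations in g.
#' @param fs Sampling frequency in Hz.
#' @param start_time ISO-8601 timestamp of the first sample.
#' @param location Wear location, `"wrist"` or `"ankle"`.
#' @param participant_id Opaque participant label.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, start_time = "2012-01-02T09:00:00",
                          location = c("wrist", "ankle"),
                          participant_id = "P001") {
  location <- match.arg(location)
  samples <- as.matrix(samples)
  check_that(
    "fs must be > 0" = is.numeric(fs) && length(fs) == 1L && fs > 0,
    "samples must have 3 columns (x, y, z)" = ncol(samples) == 3L,
    "recording must contain at least one sample" = nrow(samples) >= 1L,
    "samples must be finite" = all(is.finite(samples))
  )
  colnames(samples) <- c("x", "y", "z")
  structure(list(samples = samples, fs = fs, start_time = start_time,
                 location = location, participant_id = participant_id),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %s @ %s, %d samples @ %g Hz (%.2f h)\n",
              x$participant_id, x$location, nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs / 3600))
  invisible(x)
}

#' Simulate a raw tri-axial accelerometer recording
#'
#' Generates a continuous recording in g at `fs` Hz: a unit gravity vector
#' (optionally rotating slowly to emulate orientation drift during wear),
#' per-axis Gaussian noise, and each scheduled bout as a sinusoidal
#' oscillation along a random unit direction whose resultant RMS equals the
#' bout amplitude. During non-wear intervals the gravity vector is frozen and
#' the noise SD is divided by 100 (a device lying still).
#'
#' With `noise_sd = 0` and no bouts the resultant is exactly 1 g at every
#' sample, so the entire signal is removed by the high-pass filter.
#'
#' @param profile An [activity_profile()].
#' @param fs Sampling frequency in Hz (study protocol value 85.7).
#' @param seed Integer seed; identical `(profile, fs, seed)` give
#'   bit-identical recordings.
#' @param location,participant_id,start_time Recording metadata.
#' @return A [raw_recording()].
#' @export
simulate_recording <- function(profile, fs = 85.7, seed = 1L,
                               location = "wrist", participant_id = "P001",
                               start_time = "2012-01-02T09:00:00") {
  if (!inherits(profile, "activity_profile")) stop("'profile' must be an activity_profile")
  validate_profile(profile)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")

  n <- round(fs * profile$wear_days * profile$day_length)
  t <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    # orientation: gravity rotates in the x-z plane with the drift period
    theta <- if (is.finite(profile$orientation_drift_period))
      2 * pi * t / profile$orientation_drift_period else rep(0, n)

    nw_idx <- integer(0)
    if (nrow(profile$nonwear)) {
      for (i in seq_len(nrow(profile$nonwear))) {
        i0 <- floor(profile$nonwear$start[i] * fs) + 1L
        i1 <- min(n, ceiling(profile$nonwear$end[i] * fs))
        if (i1 >= i0) {
          theta[i0:i1] <- theta[i0]  # device lies still: orientation frozen
          nw_idx <- c(nw_idx, i0:i1)
        }
      }
    }

    acc <- cbind(x = sin(theta), y = 0, z = cos(theta))

    if (profile$noise_sd > 0) {
      sd_vec <- rep(profile$noise_sd, n)
      sd_vec[nw_idx] <- profile$noise_sd / 100
      acc <- acc + matrix(stats::rnorm(3L * n), n, 3L) * sd_vec
    }

    b <- profile$bouts
    if (nrow(b)) {
      for (i in seq_len(nrow(b))) {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u^2))
        i0 <- floor(b$start[i] * fs) + 1L
        i1 <- min(n, ceiling((b$start[i] + b$duration[i]) * fs))
        idx <- i0:i1
        # amplitude is the RMS of the oscillatory resultant: A*sqrt(2)*sin
        s <- b$amplitude[i] * sqrt(2) *
          sin(2 * pi * b$frequency[i] * (t[idx] - b$start[i]))
        acc[idx, ] <- acc[idx, ] + outer(s, u)
      }
    }
    raw_recording(acc, fs = fs, start_time = start_time,
                  location = location, participant_id = participant_id)
  })
}

#' Scale the activity content of a profile
#'
#' Multiplies every bout amplitude by `1 + relative_increase`, scaling the
#' profile's total bout amplitude-by-duration mass — and hence the pipeline's
#' daily activity count contribution, which is linear in amplitude — by the
#' same factor, while leaving the bout schedule (and MVPA timing) unchanged.
#' Used to inject a known ground-truth effect for end-to-end recovery tests.
#'
#' @param profile An [activity_profile()].
#' @param relative_increase Proportional increase, must be > -1 (e.g. 0.46
#'   for a 46% increase).
#' @return A new `activity_profile`.
#' @export
inject_activity_effect <- function(profile, relative_increase) {
  if (!inherits(profile, "activity_profile")) stop("'profile' must be an activity_profile")
  if (!is.numeric(relative_increase) || length(relative_increase) != 1L ||
      relative_increase <= -1)
    stop("relative_increase must be > -1")
  profile$bouts$amplitude <- profile$bouts$amplitude * (1 + relative_increase)
  profile
}
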
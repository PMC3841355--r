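#' First-order RC high-pass filter
#'
#' Filters each axis independently with the recursive digital analogue of an
#' analog RC high-pass, `y[t] = alpha * (y[t-1] + x[t] - x[t-1])` with
#' `alpha = RC / (RC + 1/fs)` and `RC = 1/(2*pi*fc)`. The static gravity
#' component (DC) is removed asymptotically; the filter is causal (forward
#' only), so a warm-up transient of order `10 * RC` seconds remains at the
#' start of the output.
#'
#' @param recording A [raw_recording()].
#' @param fc Cutoff frequency in Hz; must lie in `(0, fs/2)`. Protocol
#'   value 0.27 Hz.
#' @return A `raw_recording` with filtered samples.
#' @export
rc_highpass <- function(recording, fc = 0.27) {
  if (!inherits(recording, "raw_recording")) stop("'recording' must be a raw_recording")
  fs <- recording$fs
  if (!is.numeric(fc) || length(fc) != 1L || fc <= 0 || fc >= fs / 2)
    stop("fc must lie in (0, fs/2)")
  rc <- 1 / (2 * pi * fc)
  alpha <- rc / (rc + 1 / fs)
  out <- recording
  out$samples <- apply(recording$samples, 2L, function(x) {
    v <- alpha * c(0, diff(x))  # x[0] := x[1], so y starts at 0
    as.numeric(stats::filter(v, alpha, method = "recursive"))
  })
  colnames(out$samples) <- c("x", "y", "z")
  out
}

#' Resultant (signal vector magnitude)
#'
#' Element-wise Euclidean norm of the three axes,
#' `R = (x^2 + y^2 + z^2)^0.5`, in g.
#'
#' @param recording A [raw_recording()] or a 3-column numeric matrix.
#' @return Numeric vector of non-negative magnitudes, one per sample.
#' @export
resultant <- function(recording) {
  s <- if (inherits(recording, "raw_recording")) recording$samples
       else as.matrix(recording)
  if (ncol(s) != 3L) stop("expected 3 axes")
  sqrt(s[, 1L]^2 + s[, 2L]^2 + s[, 3L]^2)
}

# --- wear masks ------------------------------------------------------------

new_wear_mask <- function(nonwear, n, provenance) {
  # nonwear: logical of length n; intervals tile [1, n], end exclusive
  r <- rle(nonwear)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  structure(list(
    intervals = data.frame(start = start, end = end + 1L,
                           status = ifelse(r$values, "nonwear", "wear"),
                           stringsAsFactors = FALSE),
    n = n, provenance = provenance), class = "wear_mask")
}

#' Wear indicator vector of a mask
#'
#' @param mask A `wear_mask`.
#' @return Logical vector, `TRUE` where the device was worn.
#' @export
wear_vector <- function(mask) {
  stopifnot(inherits(mask, "wear_mask"))
  w <- rep(TRUE, mask$n)
  iv <- mask$intervals
  for (i in which(iv$status == "nonwear"))
    w[iv$start[i]:(iv$end[i] - 1L)] <- FALSE
  w
}

#' @export
print.wear_mask <- function(x, ...) {
  nw <- sum(x$intervals$status == "nonwear")
  cat(sprintf("wear_mask (%s): %d samples, %d non-wear interval(s)\n",
              x$provenance, x$n, nw))
  invisible(x)
}

#' Automated non-wear detection
#'
#' Flags as non-wear every sample lying in a run of at least `window`
#' seconds over which the rolling per-axis standard deviation stays below
#' `sd_threshold` on all three axes — the standard actigraphy heuristic for
#' a device lying still (the original protocol reviewed non-wear visually;
#' this rule automates it). Applied to the *raw* (unfiltered) recording.
#'
#' @param recording A [raw_recording()].
#' @param window Minimum still duration in seconds (>= 60; default 1800,
#'   i.e. 30 min).
#' @param sd_threshold Per-axis SD threshold in g (default 0.013).
#' @return A `wear_mask` with provenance `"automatic"`.
#' @export
detect_nonwear <- function(recording, window = 1800, sd_threshold = 0.013) {
  if (!inherits(recording, "raw_recording")) stop("'recording' must be a raw_recording")
  if (window < 60) stop("window must be >= 60 seconds")
  if (sd_threshold <= 0) stop("sd_threshold must be > 0")
  n <- nrow(recording$samples)
  w <- round(window * recording$fs)
  if (w > n) stop("window longer than recording")

  low <- rep(TRUE, n - w + 1L)
  for (j in 1:3) low <- low & roll_sd_below(recording$samples[, j], w, sd_threshold)

  # a sample is non-wear iff some full low window covers it
  d <- integer(n + 1L)
  starts <- which(low)
  if (length(starts)) {
    d[starts] <- 1L
    d[starts + w] <- d[starts + w] - 1L
  }
  nonwear <- cumsum(d[seq_len(n)]) > 0L
  new_wear_mask(nonwear, n, "automatic")
}

# rolling SD over trailing windows of w samples via cumulative sums;
# returns logical of length n - w + 1 (TRUE where SD < thr)
roll_sd_below <- function(x, w, thr) {
  x <- x - mean(x)  # centring limits cancellation around the 1 g offset
  cs <- cumsum(c(0, x))
  cq <- cumsum(c(0, x^2))
  i <- seq_len(length(x) - w + 1L)
  s <- cs[i + w] - cs[i]
  q <- cq[i + w] - cq[i]
  v <- pmax(0, (q - s^2 / w) / (w - 1L))
  sqrt(v) < thr
}

#' Merge self-reported non-wear into a mask
#'
#' Takes the union of the automatic non-wear intervals and participant-
#' reported intervals (in seconds from recording start, end exclusive).
#' Non-wear of any length is excluded from the integrals downstream and is
#' never imputed.
#'
#' @param mask A `wear_mask`.
#' @param reported `data.frame` with columns `start`, `end` in seconds, or
#'   `NULL`/empty for none.
#' @param fs Sampling frequency of the underlying recording in Hz.
#' @return A `wear_mask` with provenance `"merged"` (or the input mask
#'   unchanged when `reported` is empty).
#' @export
merge_reported_nonwear <- function(mask, reported, fs) {
  stopifnot(inherits(mask, "wear_mask"))
  if (is.null(reported) || nrow(as.data.frame(reported)) == 0L) return(mask)
  reported <- as.data.frame(reported)
  span <- mask$n / fs
  if (any(reported$start < 0) || any(reported$end > span) ||
      any(reported$start >= reported$end))
    stop("reported intervals must be well-formed and within the recording span")
  nonwear <- !wear_vector(mask)
  for (i in seq_len(nrow(reported))) {
    i0 <- floor(reported$start[i] * fs) + 1L
    i1 <- min(mask$n, ceiling(reported$end[i] * fs))
    nonwear[i0:i1] <- TRUE
  }
  new_wear_mask(nonwear, mask$n, "merged")
}

# accept either a wear_mask or a raw logical wear vector
as_wear <- function(mask, n) {
  if (inherits(mask, "wear_mask")) {
    if (mask$n != n) stop("mask length does not match signal")
    wear_vector(mask)
  } else if (is.logical(mask)) {
    if (length(mask) != n) stop("mask length does not match signal")
    mask
  } else stop("mask must be a wear_mask or logical vector")
}

#' Daily integrals of the filtered resultant
#'
#' Partitions the recording into consecutive blocks of `day_length` seconds
#' from the recording start and integrates `|R|` over wear samples by the
#' rectangle rule: `count = sum(|R_i|) / fs`, in g-seconds. Trailing partial
#' days are dropped. A day wholly non-wear gets count 0 and `valid = FALSE`.
#'
#' @param R Numeric vector, the filtered resultant.
#' @param mask A `wear_mask` (or logical wear vector) for the recording.
#' @param fs Sampling frequency in Hz.
#' @param day_length Day length in seconds (default 86400).
#' @return `data.frame` with columns `day_index`, `activity_count`, `valid`.
#' @export
daily_integral <- function(R, mask, fs, day_length = 86400) {
  n <- length(R)
  if (n == 0L) stop("empty recording")
  if (day_length <= 0) stop("day_length must be > 0")
  wear <- as_wear(mask, n)
  spd <- round(fs * day_length)
  n_days <- n %/% spd
  if (n_days == 0L) stop("recording shorter than one day")
  out <- data.frame(day_index = seq_len(n_days),
                    activity_count = NA_real_, valid = NA)
  Rw <- abs(R) * wear
  for (d in seq_len(n_days)) {
    idx <- ((d - 1L) * spd + 1L):(d * spd)
    out$activity_count[d] <- sum(Rw[idx]) / fs
    out$valid[d] <- any(wear[idx])
  }
  out
}

#' Epoch series of the filtered resultant
#'
#' Sums `|R| / fs` over wear samples within successive epochs of
#' `epoch_length` seconds (default 60 s, the protocol epoch) and records the
#' wear fraction of each epoch. The trailing partial epoch is dropped.
#'
#' @inheritParams daily_integral
#' @param epoch_length Epoch length in seconds.
#' @return Object of class `epoch_series`: list with `epoch_length`,
#'   `values` (g-seconds per epoch) and `wear_fraction`.
#' @export
epoch_series <- function(R, mask, fs, epoch_length = 60) {
  n <- length(R)
  if (n == 0L) stop("empty recording")
  if (epoch_length <= 0) stop("epoch_length must be > 0")
  wear <- as_wear(mask, n)
  spe <- round(fs * epoch_length)
  n_ep <- n %/% spe
  if (n_ep == 0L) stop("recording shorter than one epoch")
  keep <- seq_len(n_ep * spe)
  m <- matrix(abs(R[keep]) * wear[keep], nrow = spe)
  wm <- matrix(wear[keep], nrow = spe)
  structure(list(epoch_length = epoch_length,
                 values = colSums(m) / fs,
                 wear_fraction = colMeans(wm)),
            class = "epoch_series")
}

#' Cut points for epoch intensity classification
#'
#' Thresholds, in g-seconds per epoch, separating light from moderate and
#' moderate from vigorous intensity. The defaults are the package's
#' configurable synthetic wrist-style values; any analysis against real
#' devices should supply thresholds calibrated for that device and wear
#' location.
#'
#' @param moderate_threshold,vigorous_threshold Thresholds in g-s per epoch,
#'   `0 < moderate < vigorous`.
#' @param source_label Free-text provenance of the thresholds.
#' @return Object of class `cut_points`.
#' @export
cut_points <- function(moderate_threshold = 3, vigorous_threshold = 10,
                       source_label = "synthetic wrist-style defaults") {
  check_that("cut points must satisfy 0 < moderate < vigorous" =
               moderate_threshold > 0 &&
               moderate_threshold < vigorous_threshold)
  structure(list(moderate_threshold = moderate_threshold,
                 vigorous_threshold = vigorous_threshold,
                 source_label = source_label), class = "cut_points")
}

#' Classify epochs into intensity classes
#'
#' An epoch is `moderate` when `moderate <= value < vigorous` and
#' `vigorous` when `value >= vigorous` (thresholds are inclusive lower
#' bounds). Epochs worn less than `min_wear_fraction` of their length are
#' classified `below` regardless of value, a conservative rule for epochs
#' straddling short non-wear.
#'
#' @param epochs An [epoch_series()].
#' @param cutpoints A [cut_points()].
#' @param min_wear_fraction Minimum wear fraction for an epoch to be
#'   classifiable (default 0.5).
#' @return Factor with levels `below`, `moderate`, `vigorous`.
#' @export
classify_mvpa <- function(epochs, cutpoints = cut_points(),
                          min_wear_fraction = 0.5) {
  stopifnot(inherits(epochs, "epoch_series"), inherits(cutpoints, "cut_points"))
  v <- epochs$values
  cls <- ifelse(v >= cutpoints$vigorous_threshold, "vigorous",
         ifelse(v >= cutpoints$moderate_threshold, "moderate", "below"))
  cls[epochs$wear_fraction < min_wear_fraction] <- "below"
  factor(cls, levels = c("below", "moderate", "vigorous"))
}

#' MVPA minutes per day from classified epochs
#'
#' Counts moderate-or-vigorous epochs within each consecutive block of
#' `day_length` seconds. With 60-s epochs the count equals minutes per day.
#'
#' @param classes Factor from [classify_mvpa()].
#' @param epoch_length Epoch length in seconds.
#' @param day_length Day length in seconds.
#' @return Integer vector, one count per complete day.
#' @export
daily_mvpa_minutes <- function(classes, epoch_length = 60,
                               day_length = 86400) {
  epd <- day_length / epoch_length
  if (epd != round(epd)) stop("epoch_length must divide day_length")
  n_days <- length(classes) %/% epd
  if (n_days == 0L) return(integer(0))
  mv <- classes != "below"
  as.integer(tapply(mv[seq_len(n_days * epd)],
                    rep(seq_len(n_days), each = epd), sum))
}

#' Summarize a participant's daily activity
#'
#' Applies the valid-day inclusion rule: a participant is included when at
#' least `min_valid_days` of the first `window_days` days are valid, and
#' their averages are taken over the first `use_first_n` valid days.
#' Excluded participants carry `included = FALSE` and missing means.
#'
#' @param days `data.frame` from the daily pipeline with columns
#'   `day_index`, `activity_count`, `mvpa_minutes`, `valid`.
#' @param min_valid_days Minimum valid days for inclusion (default 5).
#' @param use_first_n Number of leading valid days averaged (default 5).
#' @param window_days Length of the assessment window in days (default 7).
#' @return One-row `data.frame`: `mean_daily_count`, `mean_mvpa_minutes`,
#'   `n_valid_days`, `included`.
#' @export
summarize_participant <- function(days, min_valid_days = 5, use_first_n = 5,
                                  window_days = 7) {
  if (!is.data.frame(days) || nrow(days) == 0L) stop("empty day list")
  days <- days[order(days$day_index), , drop = FALSE]
  days <- days[seq_len(min(nrow(days), window_days)), , drop = FALSE]
  n_valid <- sum(days$valid)
  included <- n_valid >= min_valid_days
  if (included) {
    use <- days[days$valid, , drop = FALSE]
    use <- use[seq_len(min(nrow(use), use_first_n)), , drop = FALSE]
    data.frame(mean_daily_count = mean(use$activity_count),
               mean_mvpa_minutes = mean(use$mvpa_minutes),
               n_valid_days = n_valid, included = TRUE)
  } else {
    data.frame(mean_daily_count = NA_real_, mean_mvpa_minutes = NA_real_,
               n_valid_days = n_valid, included = FALSE)
  }
}

#' Process one raw recording end to end
#'
#' Runs the full per-recording pipeline: RC high-pass filter each axis, take
#' the resultant, detect (and merge reported) non-wear on the raw signal,
#' integrate daily activity counts and 1-minute epochs over wear samples,
#' classify epochs against the cut points, and apply the valid-day
#' summarisation. The causal filter's warm-up (`10 * RC` seconds) is
#' excluded from the first day's integrals.
#'
#' @param recording A [raw_recording()].
#' @param config A [pipeline_config()].
#' @param reported_nonwear Optional `data.frame` of self-reported non-wear
#'   intervals (`start`, `end` in seconds).
#' @return List with `days` (day-level `data.frame`), `summary` (one-row
#'   participant summary including ids) and `mask` (the merged `wear_mask`).
#' @export
process_recording <- function(recording, config = pipeline_config(),
                              reported_nonwear = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))

  filt <- rc_highpass(recording, fc = config$fc)
  R <- resultant(filt)
  mask <- detect_nonwear(recording, window = config$nonwear_window,
                         sd_threshold = config$nonwear_sd_threshold)
  mask <- merge_reported_nonwear(mask, reported_nonwear, recording$fs)
  wear <- wear_vector(mask)

  # causal-filter warm-up: excluded from integration, day 1 only
  warm <- min(length(wear), round(10 / (2 * pi * config$fc) * recording$fs))
  wear_int <- wear
  if (warm > 0L) wear_int[seq_len(warm)] <- FALSE

  days <- daily_integral(R, wear_int, recording$fs, config$day_length)
  ep <- epoch_series(R, wear_int, recording$fs, config$epoch_length)
  cls <- classify_mvpa(ep, config$cutpoints, config$mvpa_min_wear_fraction)
  mv <- daily_mvpa_minutes(cls, config$epoch_length, config$day_length)
  days$mvpa_minutes <- c(mv, rep(NA_integer_, nrow(days) - length(mv)))[
    seq_len(nrow(days))]

  sm <- summarize_participant(days, config$min_valid_days,
                              config$use_first_days, config$window_days)
  sm <- cbind(data.frame(participant_id = recording$participant_id,
                         location = recording$location,
                         stringsAsFactors = FALSE), sm)
  list(days = cbind(data.frame(participant_id = recording$participant_id,
                               location = recording$location,
                               stringsAsFactors = FALSE), days),
       summary = sm, mask = mask)
}
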
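# Independently coded statistic + CDF oracles used to cross-check every
# p-value the package reports, plus reduced-scale fixture builders.

# paired / one-sample t: statistic and two-sided p from first principles
oracle_paired_t_p <- function(d) {
  n <- length(d)
  tstat <- mean(d) / (sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n))
  2 * pt(-abs(tstat), df = n - 1)
}

# pooled-variance two-sample t
oracle_pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(s2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Wilcoxon rank-sum, normal approximation with tie correction, no
# continuity correction
oracle_ranksum_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

# exact rank-sum by full enumeration of group assignments (n1 + n2 small)
oracle_ranksum_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  U_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
}

# closed-form normal-approximation power for the two-sided two-sample test
oracle_power_closed_form <- function(delta, sd, n_per_arm, alpha = 0.05) {
  pnorm(delta / (sd * sqrt(2 / n_per_arm)) - qnorm(1 - alpha / 2))
}

# --- reduced-scale fixtures ------------------------------------------------

# pipeline configuration for fast tests: 10 Hz, 2-hour "days"
reduced_config <- function(...) {
  args <- list(fs = 10, day_length = 7200, window_days = 7,
               min_valid_days = 5, use_first_days = 5,
               nonwear_window = 600)
  args[names(list(...))] <- list(...)
  do.call(pipeline_config, args)
}

# bout schedule: per simulated day, bouts at fixed offsets (epoch-aligned)
reduced_bouts <- function(days, starts = c(1200, 3000, 5400),
                          duration = 600, amplitude = 0.5,
                          day_len = 7200) {
  do.call(rbind, lapply(seq_len(days) - 1, function(d)
    data.frame(start = d * day_len + starts, duration = duration,
               amplitude = amplitude, frequency = 2)))
}

reduced_profile <- function(days = 7, noise_sd = 0.005, ...) {
  activity_profile(bouts = reduced_bouts(days), noise_sd = noise_sd,
                   wear_days = days, day_length = 7200,
                   orientation_drift_period = 3600, ...)
}
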
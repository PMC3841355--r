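#' Relative change from baseline
#'
#' `(followup - baseline) / baseline`, the trial's primary-outcome scale.
#' Non-positive baselines cannot support a relative change and yield `NA`
#' (the participant is excluded from that outcome, complete-case).
#'
#' @param baseline,followup Numeric vectors (recycled to common length).
#' @return Numeric vector of proportions (`0.46` means +46%).
#' @export
relative_change <- function(baseline, followup) {
  out <- (followup - baseline) / baseline
  bad <- !is.na(baseline) & baseline <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive baseline value(s) set to NA")
    out[bad] <- NA_real_
  }
  out
}

#' Within-group change test
#'
#' Paired Student t test of follow-up versus baseline on the chosen scale:
#' raw differences (`transform = "none"`), differences of natural logs
#' (`"ln"`, for right-skewed outcomes; requires positive values), or
#' per-participant relative changes (`"relative"`, the activity-count
#' scale). Complete pairs only. A zero-variance set of changes is flagged
#' degenerate (SE 0): p is 1 when the changes are identically zero (no
#' change observed) and missing otherwise (the t statistic is undefined).
#'
#' @param baseline,followup Paired numeric vectors.
#' @param transform One of `"none"`, `"ln"`, `"relative"`.
#' @return List: `mean_change`, `se`, `p`, `n`, `degenerate`.
#' @export
within_group_change_test <- function(baseline, followup,
                                     transform = c("none", "ln", "relative")) {
  transform <- match.arg(transform)
  ok <- stats::complete.cases(baseline, followup)
  b <- baseline[ok]; f <- followup[ok]
  if (transform == "ln" && any(b <= 0 | f <= 0))
    stop("ln transform requires positive values")
  d <- switch(transform,
              none = f - b,
              ln = log(f) - log(b),
              relative = relative_change(b, f))
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("fewer than 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  if (near_constant(d))
    return(list(mean_change = m, se = 0,
                p = if (m == 0) 1 else NA_real_, n = length(d),
                degenerate = TRUE))
  tt <- stats::t.test(d)
  list(mean_change = m, se = s / sqrt(length(d)),
       p = tt$p.value, n = length(d), degenerate = FALSE)
}

#' Between-group test of changes
#'
#' Two-sided two-sample t test comparing per-participant changes between
#' arms; equal-variance (Student) by default, with Welch available.
#' Degenerate input (zero pooled variance) returns p = 1 when the arm means
#' agree and p = 0 otherwise, with a warning.
#'
#' @param changes_intervention,changes_control Numeric vectors of changes.
#' @param var_equal Use the pooled-variance Student t (default `TRUE`).
#' @return Two-sided p-value.
#' @export
between_group_test <- function(changes_intervention, changes_control,
                               var_equal = TRUE) {
  x <- changes_intervention[!is.na(changes_intervention)]
  y <- changes_control[!is.na(changes_control)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per arm")
  if (near_constant(x) && near_constant(y)) {
    warning("degenerate arms (zero variance)")
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Between-group rank-sum test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test for skewed changes such
#' as relative MVPA change: exact when both arms have fewer than 25
#' untied observations, otherwise the normal approximation with tie
#' correction (no continuity correction, so identical samples give p = 1).
#'
#' @param changes_intervention,changes_control Numeric vectors of changes.
#' @return Two-sided p-value.
#' @export
between_group_nonparametric <- function(changes_intervention,
                                        changes_control) {
  x <- changes_intervention[!is.na(changes_intervention)]
  y <- changes_control[!is.na(changes_control)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per arm")
  ties <- any(duplicated(c(x, y)))
  if (ties && all(c(x, y) == c(x, y)[1])) return(1)
  exact <- !ties && length(x) < 25L && length(y) < 25L
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
}

#' Intention-to-treat subset
#'
#' All randomized participants who completed the study (outcome data
#' present); no imputation is ever performed, so participants with lost
#' follow-up simply drop out of the analysis set.
#'
#' @param cohort A cohort table from [simulate_cohort()] or [read_cohort()].
#' @return The ITT cohort table.
#' @export
itt_subset <- function(cohort) {
  cohort[cohort$completed_study, , drop = FALSE]
}

#' Per-protocol subset
#'
#' The ITT set with the intervention arm restricted to participants who
#' completed the 12-week program; the control arm is never reduced.
#'
#' @inheritParams itt_subset
#' @return The per-protocol cohort table.
#' @export
per_protocol_subset <- function(cohort) {
  itt <- itt_subset(cohort)
  itt[itt$arm == "control" | itt$completed_program_week12, , drop = FALSE]
}

# --- derived metabolic endpoints ------------------------------------------

#' Body mass index
#' @param weight_kg Weight in kg.
#' @param height_cm Height in cm.
#' @return BMI in kg/m^2.
#' @export
derive_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_cm <= 0, na.rm = TRUE))
    stop("weight and height must be positive")
  weight_kg / (height_cm / 100)^2
}

#' Waist-to-hip ratio
#' @param waist_cm,hip_cm Circumferences in cm.
#' @return Unitless ratio.
#' @export
derive_whr <- function(waist_cm, hip_cm) {
  if (any(waist_cm <= 0, na.rm = TRUE) || any(hip_cm <= 0, na.rm = TRUE))
    stop("circumferences must be positive")
  waist_cm / hip_cm
}

#' HOMA-IR insulin-resistance index
#'
#' Homeostatic model assessment, `glucose * insulin / 22.5` with fasting
#' glucose in mmol/L and fasting insulin in mU/L (the standard HOMA1-IR
#' constant for these units).
#'
#' @param glucose_mmol_L,insulin_mU_L Fasting values.
#' @return HOMA-IR index.
#' @export
homa_index <- function(glucose_mmol_L, insulin_mU_L) {
  if (any(glucose_mmol_L <= 0, na.rm = TRUE) ||
      any(insulin_mU_L <= 0, na.rm = TRUE))
    stop("glucose and insulin must be positive")
  glucose_mmol_L * insulin_mU_L / 22.5
}

#' Friedewald LDL cholesterol
#'
#' `LDL = TC - HDL - TG / 2.2` in mmol/L, valid only without
#' hypertriglyceridemia: participants with TG above `tg_limit`
#' (default 4.52 mmol/L, i.e. 400 mg/dL) get a missing LDL.
#'
#' @param tc_mmol_L,hdl_mmol_L,tg_mmol_L Total, HDL cholesterol and
#'   triglycerides in mmol/L.
#' @param tg_limit Triglyceride validity bound in mmol/L.
#' @return LDL cholesterol in mmol/L, `NA` above the TG limit.
#' @export
friedewald_ldl <- function(tc_mmol_L, hdl_mmol_L, tg_mmol_L,
                           tg_limit = 4.52) {
  if (any(tc_mmol_L <= 0, na.rm = TRUE) || any(hdl_mmol_L <= 0, na.rm = TRUE) ||
      any(tg_mmol_L < 0, na.rm = TRUE))
    stop("lipid inputs must be positive (TG non-negative)")
  ldl <- tc_mmol_L - hdl_mmol_L - tg_mmol_L / 2.2
  ldl[!is.na(tg_mmol_L) & tg_mmol_L > tg_limit] <- NA_real_
  ldl
}

# --- effect tables ---------------------------------------------------------

#' Default analysis plan
#'
#' One row per outcome: the change scale (`relative` for activity counts,
#' `ln` for right-skewed biochemistry, `none` i.e. absolute otherwise) and
#' the between-group test (`nonparametric` for MVPA relative change, `t`
#' otherwise).
#'
#' @return `data.frame` with columns `outcome`, `transform`, `test`.
#' @export
default_analysis_plan <- function() {
  data.frame(
    outcome = c("ankle_counts", "wrist_counts", "mvpa_min", "weight_kg"),
    transform = c("relative", "relative", "relative", "none"),
    test = c("t", "t", "nonparametric", "t"),
    stringsAsFactors = FALSE
  )
}

#' Build an effect table
#'
#' For each outcome in the plan: per-arm mean change with SE and paired
#' within-group p, and the between-group p comparing per-participant
#' changes between arms — relative changes for activity outcomes, log or
#' raw differences otherwise, with the declared test. Complete-case per
#' outcome. Degenerate (zero-variance) outcomes carry missing p-values and
#' `degenerate = TRUE`.
#'
#' @param cohort Cohort table with `baseline_<outcome>` /
#'   `followup_<outcome>` columns.
#' @param plan Analysis plan as from [default_analysis_plan()].
#' @return `data.frame` with one row per outcome: `outcome`, `n_int`,
#'   `mean_change_int`, `se_int`, `p_int`, `n_ctl`, `mean_change_ctl`,
#'   `se_ctl`, `p_ctl`, `p_between`, `transform`, `test`, `degenerate`.
#' @export
build_effect_table <- function(cohort, plan = default_analysis_plan()) {
  missing_cols <- setdiff(
    c(paste0("baseline_", plan$outcome), paste0("followup_", plan$outcome)),
    names(cohort))
  if (length(missing_cols))
    stop("unknown outcome columns: ", paste(missing_cols, collapse = ", "))

  rows <- lapply(seq_len(nrow(plan)), function(i) {
    o <- plan$outcome[i]; tr <- plan$transform[i]; te <- plan$test[i]
    b <- cohort[[paste0("baseline_", o)]]
    f <- cohort[[paste0("followup_", o)]]
    int <- cohort$arm == "intervention"

    wi <- within_group_change_test(b[int], f[int], tr)
    wc <- within_group_change_test(b[!int], f[!int], tr)

    chg <- function(sel) {
      ok <- stats::complete.cases(b, f) & sel
      switch(tr,
             none = f[ok] - b[ok],
             ln = log(f[ok]) - log(b[ok]),
             relative = relative_change(b[ok], f[ok]))
    }
    ci <- chg(int); cc <- chg(!int)
    degen <- wi$degenerate || wc$degenerate ||
      (near_constant(ci) && near_constant(cc))
    pb <- if (degen) NA_real_
          else if (te == "nonparametric") between_group_nonparametric(ci, cc)
          else between_group_test(ci, cc)

    data.frame(outcome = o, n_int = wi$n, mean_change_int = wi$mean_change,
               se_int = wi$se, p_int = wi$p, n_ctl = wc$n,
               mean_change_ctl = wc$mean_change, se_ctl = wc$se,
               p_ctl = wc$p, p_between = pb, transform = tr, test = te,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
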
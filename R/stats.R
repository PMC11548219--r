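#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. Used for
#' per-participant stride-length and minimum-toe-clearance variability.
#'
#' @param values Numeric vector, length >= 2, with mean away from zero.
#' @return Dimensionless CV.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2", call. = FALSE)
  m <- mean(values)
  if (abs(m) < 1e-12 * max(1, stats::sd(values)))
    stop("CV undefined: mean is (near) zero", call. = FALSE)
  stats::sd(values) / m
}

#' Normalize a gait parameter by participant height
#'
#' @param value Parameter value (m).
#' @param height Participant height (m, > 0).
#' @return Dimensionless ratio.
#' @export
normalize_by_height <- function(value, height) {
  if (any(height <= 0)) stop("height must be positive", call. = FALSE)
  value / height
}

#' Unpaired two-sample comparison with effect size
#'
#' Student's two-sample t-test with pooled variance (Welch's correction
#' available via `welch = TRUE`), two-sided, plus Cohen's d computed with the
#' pooled standard deviation: `d = (mean_a - mean_b) / sd_pooled`.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @param welch Use Welch's unequal-variance t instead of pooled. Default
#'   `FALSE`.
#' @return List with `t_stat`, `df`, `p_value`, `cohens_d`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`.
#' @export
unpaired_t_test <- function(group_a, group_b, welch = FALSE) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t_stat = 0, df = na + nb - 2, p_value = 1, cohens_d = 0,
                  mean_a = mean(group_a), sd_a = 0,
                  mean_b = mean(group_b), sd_b = 0))
    }
    stop("zero pooled variance with unequal means: t undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       cohens_d = (mean(group_a) - mean(group_b)) / sqrt(sp2),
       mean_a = mean(group_a), sd_a = stats::sd(group_a),
       mean_b = mean(group_b), sd_b = stats::sd(group_b))
}

#' Agreement between estimated and reference measurements
#'
#' Pearson correlation, RMSE, mean difference (bias) and Bland-Altman 95%
#' limits of agreement `bias +/- 1.96 sd(differences)` (sample sd).
#'
#' @param estimates,references Paired numeric vectors, equal length n >= 3.
#' @return List with `r`, `rmse`, `bias`, `loa_low`, `loa_high`, `n`.
#' @export
agreement <- function(estimates, references) {
  estimates <- as.numeric(estimates); references <- as.numeric(references)
  n <- length(estimates)
  if (length(references) != n || n < 3L)
    stop("need equal-length inputs with n >= 3", call. = FALSE)
  d <- estimates - references
  r <- if (stats::sd(estimates) == 0 || stats::sd(references) == 0) {
    if (stats::sd(d) == 0) 1 else
      stop("correlation undefined: zero variance input", call. = FALSE)
  } else {
    stats::cor(estimates, references)
  }
  bias <- mean(d)
  s <- stats::sd(d)
  list(r = r, rmse = sqrt(mean(d^2)), bias = bias,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s, n = n)
}

#' Participant-level gait summary
#'
#' Per-participant means and CVs of stride length and minimum toe clearance,
#' plus height-normalized values, from a stride-record table.
#'
#' @param records Data.frame with `stride_length_m` and `mtc_m` columns (from
#'   [stride_records()]).
#' @param meta A [session_meta()] for the participant.
#' @return One-row data.frame with `participant_id, group, n_strides,
#'   mean_stride_length, cv_stride_length, mean_mtc, cv_mtc,
#'   norm_stride_length, norm_mtc`.
#' @export
participant_summary <- function(records, meta) {
  data.frame(participant_id = meta$participant_id, group = meta$group,
             n_strides = nrow(records),
             mean_stride_length = mean(records$stride_length_m),
             cv_stride_length = coefficient_of_variation(records$stride_length_m),
             mean_mtc = mean(records$mtc_m),
             cv_mtc = coefficient_of_variation(records$mtc_m),
             norm_stride_length = normalize_by_height(
               mean(records$stride_length_m), meta$height),
             norm_mtc = normalize_by_height(mean(records$mtc_m), meta$height))
}

#' Compare two groups of participant summaries
#'
#' Runs [unpaired_t_test()] on each participant-level variable between two
#' groups of [participant_summary()] rows.
#'
#' @param summaries_a,summaries_b Data.frames of participant summaries.
#' @param variables Character vector of columns to compare.
#' @return Data.frame with one row per variable: group means/sds, t, df, p,
#'   Cohen's d.
#' @export
compare_groups <- function(summaries_a, summaries_b,
                           variables = c("norm_stride_length",
                                         "cv_stride_length",
                                         "norm_mtc", "cv_mtc")) {
  if (nrow(summaries_a) < 2L || nrow(summaries_b) < 2L)
    stop("need >= 2 participants per group", call. = FALSE)
  rows <- lapply(variables, function(v) {
    r <- unpaired_t_test(summaries_a[[v]], summaries_b[[v]])
    data.frame(variable = v, mean_a = r$mean_a, sd_a = r$sd_a,
               mean_b = r$mean_b, sd_b = r$sd_b, t_stat = r$t_stat,
               df = r$df, p_value = r$p_value, cohens_d = r$cohens_d)
  })
  do.call(rbind, rows)
}
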
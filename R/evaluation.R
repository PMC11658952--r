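#' Mean error between actual and predicted end-weight
#'
#' The primary accuracy metric: the difference between actual and predicted
#' weight expressed as a percentage of actual weight,
#' `delta = (actual - predicted)/actual * 100`. Positive values mean the
#' model under-predicts end-weight, i.e. over-predicts weight loss.
#'
#' @param actual observed weight, kg (> 0). Vectorised.
#' @param predicted model-predicted weight, kg (recycled).
#' @return Mean error in percent.
#' @examples
#' mean_error_delta(100, 99)   # +1%
#' mean_error_delta(85, 87)    # -2.35%: model under-predicted loss
#' @export
mean_error_delta <- function(actual, predicted) {
  if (!is.numeric(actual) || any(!is.finite(actual)) || any(actual <= 0)) {
    stop("actual weight must be > 0 kg", call. = FALSE)
  }
  if (!is.numeric(predicted)) {
    stop("predicted weight must be numeric", call. = FALSE)
  }
  (actual - predicted) / actual * 100
}

#' Cohort-level error summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' per-subject mean error, both in percent and in kg, at the end of each
#' subject's intervention or at a specific week. Subjects lacking the
#' requested week are excluded (listwise per-week availability; weekly n
#' therefore declines with week, as attrition dictates). No imputation is
#' performed.
#'
#' @param table a cohort table: one row per subject-week with columns
#'   `subject_id`, `week`, `observed_weight`, `predicted_weight`, `w0`,
#'   `intervention_length` (see [read_cohort_csv()] and
#'   [generate_cohort()]).
#' @param at `"end"` (each subject's final scheduled week) or a single week
#'   number.
#' @return A one-row data.frame: `n`, `mean_delta_pct`, `sd_delta_pct`,
#'   `mean_error_kg`, `sd_error_kg`. With a single subject the SDs are
#'   `NA`; with an empty selection `n = 0` and all statistics `NA` (with a
#'   warning), never an error.
#' @examples
#' tab <- data.frame(subject_id = c("a", "b"), week = c(6, 6),
#'                   observed_weight = c(100, 85),
#'                   predicted_weight = c(99, 87),
#'                   w0 = c(108, 93), intervention_length = c(6, 6))
#' cohort_error_summary(tab, at = "end")
#' @export
cohort_error_summary <- function(table, at = "end") {
  table <- validate_cohort_table(table, need_predicted = TRUE)
  if (identical(at, "end")) {
    sel <- table[table$week == table$intervention_length, , drop = FALSE]
  } else {
    if (!is.numeric(at) || length(at) != 1 || at < 1) {
      stop("'at' must be \"end\" or a single week number >= 1",
           call. = FALSE)
    }
    sel <- table[table$week == at, , drop = FALSE]
  }
  sel <- sel[!is.na(sel$observed_weight) & !is.na(sel$predicted_weight), ,
             drop = FALSE]
  n <- nrow(sel)
  if (n == 0) {
    warning("no subject-weeks available for the requested selection",
            call. = FALSE)
    return(data.frame(n = 0L, mean_delta_pct = NA_real_,
                      sd_delta_pct = NA_real_, mean_error_kg = NA_real_,
                      sd_error_kg = NA_real_))
  }
  delta <- mean_error_delta(sel$observed_weight, sel$predicted_weight)
  err_kg <- sel$observed_weight - sel$predicted_weight
  data.frame(
    n = n,
    mean_delta_pct = mean(delta),
    sd_delta_pct = if (n > 1) stats::sd(delta) else NA_real_,
    mean_error_kg = mean(err_kg),
    sd_error_kg = if (n > 1) stats::sd(err_kg) else NA_real_
  )
}

#' Weekly error profile across a cohort
#'
#' Applies [cohort_error_summary()] at every week present in the table,
#' giving the weekly trajectory of model error (the per-week n reflects how
#' many subjects were still enrolled and measured at that week).
#'
#' @inheritParams cohort_error_summary
#' @return A data.frame with one row per week: `week` plus the
#'   [cohort_error_summary()] columns.
#' @export
weekly_error_profile <- function(table) {
  table <- validate_cohort_table(table, need_predicted = TRUE)
  weeks <- sort(unique(table$week))
  out <- do.call(rbind, lapply(weeks, function(w) {
    cbind(week = w, cohort_error_summary(table, at = w))
  }))
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement between actual and predicted weight loss
#'
#' Paired-differences agreement analysis: differences
#' `d = actual - predicted`, bias = mean(d), and limits of agreement at
#' `bias +/- loa_mult * SD(d)` (sample SD). The conventional multiplier
#' here is 2; 1.96 is available via `loa_mult`.
#'
#' @param actual_losses observed weight losses, kg.
#' @param predicted_losses model-predicted weight losses, kg; same length.
#' @param loa_mult multiplier for the limits of agreement (default 2).
#' @return An object of class `bland_altman`: a list with `bias`, `sd`,
#'   `loa_low`, `loa_high`, `n`, and a data.frame `pairs` holding the
#'   per-pair `average` and `difference` for plotting.
#' @examples
#' ba <- bland_altman(c(5, 7, 9), c(4.5, 7.5, 8))
#' ba$bias
#' @export
bland_altman <- function(actual_losses, predicted_losses, loa_mult = 2) {
  if (!is.numeric(actual_losses) || !is.numeric(predicted_losses)) {
    stop("losses must be numeric vectors", call. = FALSE)
  }
  if (length(actual_losses) != length(predicted_losses)) {
    stop("actual and predicted losses must have equal length",
         call. = FALSE)
  }
  if (length(actual_losses) == 0) {
    stop("losses must be nonempty", call. = FALSE)
  }
  d <- actual_losses - predicted_losses
  bias <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  structure(list(
    bias = bias, sd = s,
    loa_low = bias - loa_mult * s, loa_high = bias + loa_mult * s,
    loa_mult = loa_mult, n = length(d),
    pairs = data.frame(average = (actual_losses + predicted_losses) / 2,
                       difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d)\n  bias %.3f kg (SD %.3f)\n  limits of agreement [%+.3f, %+.3f] kg (bias +/- %g SD)\n",
    x$n, x$bias, x$sd, x$loa_low, x$loa_high, x$loa_mult
  ))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x a [bland_altman()] object.
#' @param ... passed to [plot()].
#' @return `x`, invisibly. Draws on the current graphics device.
#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$pairs$average, x$pairs$difference,
       xlab = "Average of actual and predicted loss (kg)",
       ylab = "Actual - predicted loss (kg)", ...)
  graphics::abline(h = x$bias)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Weekly-error profile plot
#'
#' Mean weekly error with +/- 1 SEM whiskers, the standard way to display
#' where in the intervention the model runs ahead of or behind the cohort.
#'
#' @param profile output of [weekly_error_profile()].
#' @param ... passed to [plot()].
#' @return `profile`, invisibly.
#' @export
plot_weekly_error <- function(profile, ...) {
  sem <- profile$sd_delta_pct / sqrt(profile$n)
  plot(profile$week, profile$mean_delta_pct, type = "b",
       xlab = "Week", ylab = "Mean error (%)", ...)
  graphics::abline(h = 0, lty = 2)
  ok <- !is.na(sem)
  graphics::arrows(profile$week[ok], profile$mean_delta_pct[ok] - sem[ok],
                   profile$week[ok], profile$mean_delta_pct[ok] + sem[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(profile)
}
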
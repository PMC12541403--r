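# Residual-activity analysis across repeated air exposures: per-cycle
# retention readout, geometric-decay fitting and cumulative-loss
# prediction.

#' Construct an exposure series
#'
#' Per-cycle residual catalytic activity across repeated air exposures.
#' Cycle 0 is the pre-exposure measurement; activities are normalized to
#' it, so `activity[cycle == 0]` is 1.
#'
#' @param activity activity readouts (>= 0), one per cycle, cycle 0 first.
#' @param cycle cycle indices, integers starting at 0.
#' @param normalize divide by the cycle-0 value (default `TRUE`).
#' @param exposure_duration hours of air exposure per cycle (metadata).
#' @param label condition label (metadata).
#' @return a data frame of class `exposure_series` with columns `cycle`
#'   and `activity`.
#' @export
exposure_series <- function(activity, cycle = seq_along(activity) - 1L,
                            normalize = TRUE, exposure_duration = NA_real_,
                            label = "") {
  if (length(activity) != length(cycle))
    stop("'activity' and 'cycle' must have equal length", call. = FALSE)
  if (any(activity < 0)) stop("activities must be >= 0", call. = FALSE)
  if (cycle[1] != 0) stop("the series must start at cycle 0", call. = FALSE)
  if (normalize) {
    if (activity[1] <= 0)
      stop("cannot normalize: cycle-0 activity is not positive",
           call. = FALSE)
    activity <- activity / activity[1]
  }
  s <- data.frame(cycle = as.integer(cycle), activity = activity)
  attr(s, "exposure_duration") <- exposure_duration
  attr(s, "label") <- label
  class(s) <- c("exposure_series", "data.frame")
  s
}

#' Residual activity between two traces
#'
#' Ratio of the catalytic plateau current after an exposure to the plateau
#' current before it, both taken over the same H2-oxidation potential
#' window.  Invariant to a common rescaling of both traces.
#'
#' @param before,after [ec_trace] objects spanning the window.
#' @param window potential window (V vs SHE) for [plateau_current()].
#' @return residual activity fraction (scalar).
#' @export
residual_activity <- function(before, after, window = c(-0.3, 0.2)) {
  ref <- plateau_current(before, window)$current
  if (!is.finite(ref) || ref <= 0)
    stop("reference plateau current must be positive", call. = FALSE)
  plateau_current(after, window)$current / ref
}

#' Cumulative retention after repeated exposures
#'
#' Under geometric (exponential) per-cycle decay with loss fraction `r`,
#' the activity remaining after `n` cycles is `(1 - r)^n`.
#'
#' @param per_cycle_loss loss fraction r per exposure, in `[0, 1]`.
#' @param n_cycles number of exposure cycles (>= 0); vectorized.
#' @return retained activity fraction(s).
#' @examples
#' cumulative_retention(0.2, 4)  # 0.4096, i.e. ~59% loss
#' @export
cumulative_retention <- function(per_cycle_loss, n_cycles) {
  if (any(per_cycle_loss < 0 | per_cycle_loss > 1))
    stop("'per_cycle_loss' must lie in [0, 1]", call. = FALSE)
  if (any(n_cycles < 0)) stop("'n_cycles' must be >= 0", call. = FALSE)
  (1 - per_cycle_loss)^n_cycles
}

#' Fit the per-cycle loss fraction of an exposure series
#'
#' Least-squares fit of `log(activity)` against cycle index; the per-cycle
#' loss is `r = 1 - exp(slope)`, with a delta-method standard error.  A
#' linear-decay alternative (`activity ~ cycle`, loss = -slope) is
#' available with `model = "linear"`.
#'
#' @param series an [exposure_series] with at least 3 cycles and (for the
#'   geometric model) strictly positive activities.
#' @param model `"geometric"` (default) or `"linear"`.
#' @return a list with `r` (loss fraction per cycle), `se` (standard
#'   error), `slope`, and `fit` (the underlying `lm`).
#' @examples
#' s <- exposure_series(c(1, 0.8, 0.64, 0.512, 0.4096))
#' fit_per_cycle_loss(s)$r  # 0.2
#' @export
fit_per_cycle_loss <- function(series, model = c("geometric", "linear")) {
  model <- match.arg(model)
  if (nrow(series) < 3)
    stop("need at least 3 cycles to fit a per-cycle loss", call. = FALSE)
  if (model == "geometric") {
    if (any(series$activity <= 0))
      stop("geometric fit requires strictly positive activities",
           call. = FALSE)
    fit <- stats::lm(log(activity) ~ cycle, data = series)
    slope <- unname(stats::coef(fit)["cycle"])
    se_slope <- suppressWarnings(
      summary(fit)$coefficients["cycle", "Std. Error"])
    list(r = 1 - exp(slope), se = exp(slope) * se_slope, slope = slope,
         fit = fit)
  } else {
    fit <- stats::lm(activity ~ cycle, data = series)
    slope <- unname(stats::coef(fit)["cycle"])
    se_slope <- suppressWarnings(
      summary(fit)$coefficients["cycle", "Std. Error"])
    list(r = -slope, se = se_slope, slope = slope, fit = fit)
  }
}
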
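# Disease natural history: parametric DFS curve with cure adjustment and
# recurrence split, background mortality from a life table, remission
# progression and the metastatic mortality schedule.

#' Parametric disease-free-survival curve
#'
#' Constructs the curve governing exit from the disease-free states, together
#' with the cure adjustment and the split of recurrences into non-metastatic
#' and metastatic. Time is measured in months since diagnosis. The Weibull
#' family (shape < 1 giving the decreasing late hazard seen in adjuvant
#' trastuzumab trials) is the default; the exponential family is retained
#' mainly for testing and closed-form checks.
#'
#' @param family `"weibull"` or `"exponential"`.
#' @param shape,scale Weibull shape and scale (months); used when
#'   `family = "weibull"`.
#' @param rate monthly event rate; used when `family = "exponential"`.
#' @param cure_threshold month at which the cured fraction reaches its
#'   maximum (default 120).
#' @param max_cure_rate maximum cured fraction (default 0.95): by the cure
#'   threshold this share of the cohort can no longer experience recurrence.
#' @param mbc_split fraction of recurrences that are metastatic (default 0.72).
#' @param cure_ramp `"linear"` (cured fraction ramps linearly from 0 to
#'   `max_cure_rate` at the threshold) or `"step"` (jumps at the threshold).
#' @param log_cov optional 2x2 covariance matrix of the log-scale curve
#'   parameters (order: shape, scale or rate), used by the probabilistic
#'   sensitivity analysis; typically produced by [fit_dfs_curve()].
#' @return An object of class `dfs_curve`.
#' @examples
#' cv <- dfs_curve("weibull", shape = 0.9, scale = 380)
#' survival_at(cv, 120)
#' @export
dfs_curve <- function(family = c("weibull", "exponential"),
                      shape = NULL, scale = NULL, rate = NULL,
                      cure_threshold = 120, max_cure_rate = 0.95,
                      mbc_split = 0.72,
                      cure_ramp = c("linear", "step"),
                      log_cov = NULL) {
  family <- match.arg(family)
  cure_ramp <- match.arg(cure_ramp)
  if (family == "weibull") {
    if (is.null(shape) || is.null(scale) || shape <= 0 || scale <= 0)
      stop("weibull curve requires positive 'shape' and 'scale'")
  } else {
    if (is.null(rate) || rate < 0)
      stop("exponential curve requires non-negative 'rate'")
  }
  if (max_cure_rate < 0 || max_cure_rate > 1)
    stop("'max_cure_rate' must be in [0, 1]")
  if (mbc_split < 0 || mbc_split > 1)
    stop("'mbc_split' must be in [0, 1]")
  if (cure_threshold < 0) stop("'cure_threshold' must be >= 0")
  structure(list(family = family, shape = shape, scale = scale, rate = rate,
                 cure_threshold = cure_threshold,
                 max_cure_rate = max_cure_rate,
                 mbc_split = mbc_split, cure_ramp = cure_ramp,
                 log_cov = log_cov),
            class = "dfs_curve")
}

#' Survival function of a DFS curve
#'
#' Probability of remaining event-free (recurrence-wise) at `t` months. The
#' raw parametric curve, before any cure adjustment.
#'
#' @param curve a [dfs_curve()].
#' @param t time in months (vectorised, `t >= 0`).
#' @return S(t), in (0, 1] for finite `t`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "dfs_curve"))
  if (any(t < 0)) stop("'t' must be non-negative")
  switch(curve$family,
    weibull = exp(-(t / curve$scale)^curve$shape),
    exponential = exp(-curve$rate * t))
}

#' Per-cycle event probability from a survival curve
#'
#' Converts the survival function into the conditional probability of a DFS
#' event during the month starting at `t`: `1 - S(t + 1) / S(t)`. Invariant to
#' rescaling of S by a constant.
#'
#' @inheritParams survival_at
#' @return Probability in \[0, 1) (vectorised over `t`).
#' @export
cycle_event_probability <- function(curve, t) {
  1 - survival_at(curve, t + 1) / survival_at(curve, t)
}

#' Cure-fraction hazard multiplier
#'
#' The cured fraction of the cohort can no longer experience recurrence. It
#' grows from 0 at diagnosis to `max_cure_rate` at the cure threshold (month
#' 120 in the base case, where 95% are deemed cured) and stays there. The
#' multiplier applied to the recurrence probability is one minus the cured
#' fraction. The default ramp is linear; a step at the threshold is available.
#'
#' @param t months since diagnosis (vectorised).
#' @param cure_threshold month at which the maximum cured fraction is reached.
#' @param max_cure_rate maximum cured fraction.
#' @param cure_ramp `"linear"` or `"step"`.
#' @return Multiplier in \[1 - max_cure_rate, 1\].
#' @examples
#' cure_multiplier(120, 120, 0.95)  # 0.05
#' cure_multiplier(60, 120, 0.95)   # 0.525
#' @export
cure_multiplier <- function(t, cure_threshold = 120, max_cure_rate = 0.95,
                            cure_ramp = c("linear", "step")) {
  cure_ramp <- match.arg(cure_ramp)
  if (any(t < 0)) stop("'t' must be non-negative")
  cured <- if (cure_threshold <= 0) {
    rep(max_cure_rate, length(t))
  } else if (cure_ramp == "linear") {
    max_cure_rate * pmin(t / cure_threshold, 1)
  } else {
    max_cure_rate * as.numeric(t >= cure_threshold)
  }
  1 - cured
}

#' Exit probabilities from the disease-free states
#'
#' Combines background mortality with the cure-adjusted recurrence probability
#' for one cycle starting at month `t`. Death and recurrence are treated as
#' independent competing events composed multiplicatively, with death taking
#' precedence in the joint event, so that total outflow never exceeds 1:
#' stay-probability = (1 - p_death) * (1 - p_recurrence). Recurrences are
#' split into metastatic and non-metastatic by the curve's `mbc_split`.
#'
#' @param curve a [dfs_curve()].
#' @param t months since diagnosis (cycle start).
#' @param q_background_monthly monthly background death probability.
#' @return Named list with `p_death`, `p_nm`, `p_mbc`, `p_stay`
#'   (summing to 1).
#' @export
dfs_exit_probabilities <- function(curve, t, q_background_monthly) {
  if (q_background_monthly < 0 || q_background_monthly > 1)
    stop("'q_background_monthly' must be in [0, 1]")
  p_rec_raw <- cycle_event_probability(curve, t) *
    cure_multiplier(t, curve$cure_threshold, curve$max_cure_rate,
                    curve$cure_ramp)
  p_death <- q_background_monthly
  p_rec <- (1 - p_death) * p_rec_raw
  p_stay <- (1 - p_death) * (1 - p_rec_raw)
  if (p_stay <= 0 && p_death < 1)
    stop(sprintf("DFS outflow reaches 1 at cycle t = %s", t))
  list(p_death = p_death,
       p_nm = p_rec * (1 - curve$mbc_split),
       p_mbc = p_rec * curve$mbc_split,
       p_stay = p_stay)
}

#' Convert an annual to a monthly probability
#'
#' Constant-hazard conversion `1 - (1 - q)^(1/12)`, used to turn annual
#' life-table death probabilities into monthly cycle probabilities.
#'
#' @param q_annual annual probability, in \[0, 1\] (vectorised).
#' @return Monthly probability.
#' @export
annual_to_monthly <- function(q_annual) {
  if (any(q_annual < 0 | q_annual > 1))
    stop("'q_annual' must be in [0, 1]")
  1 - (1 - q_annual)^(1 / 12)
}

#' Life table constructor
#'
#' A life table is a two-column table of integer age (years) and the annual
#' probability of dying within that year of age. Ages must be contiguous;
#' lookups beyond the last age reuse the last row.
#'
#' @param age integer ages (years), contiguous.
#' @param q_annual annual death probabilities in \[0, 1\].
#' @return A `life_table` data frame.
#' @export
life_table <- function(age, q_annual) {
  age <- as.integer(age)
  if (length(age) != length(q_annual) || length(age) < 1)
    stop("'age' and 'q_annual' must be non-empty and of equal length")
  if (any(diff(age) != 1L))
    stop("life-table ages must be contiguous")
  if (any(q_annual < 0 | q_annual > 1))
    stop("life-table 'q_annual' must be in [0, 1]")
  structure(data.frame(age = age, q_annual = q_annual),
            class = c("life_table", "data.frame"))
}

#' Monthly background mortality at a given age
#'
#' Looks up the annual death probability for `floor(age)` (piecewise constant
#' within each year of age) and converts it to a monthly probability. Ages
#' beyond the table's last row use the last row; ages below the table's range
#' are an error.
#'
#' @param lt a [life_table()].
#' @param age age in years (possibly fractional, vectorised).
#' @return Monthly death probability.
#' @export
background_mortality <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  a <- floor(age)
  if (any(a < lt$age[1]))
    stop(sprintf("age %s below life-table range (starts at %d)",
                 min(a), lt$age[1]))
  idx <- pmin(a - lt$age[1] + 1, nrow(lt))
  annual_to_monthly(lt$q_annual[idx])
}

# monthly death probability in the metastatic state by tunnel month (1-based);
# mbc_mortality is the named list (y1..y5plus) of monthly probabilities by
# year since entry, constant at the year-5+ value beyond month 60.
mbc_death_probability <- function(mbc_mortality, tunnel_month) {
  rates <- unlist(mbc_mortality, use.names = FALSE)
  yr <- pmin(ceiling(tunnel_month / 12), 5L)
  rates[yr]
}
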
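# Cost and utility accrual over a trace, discounting, ICERs, currency
# conversion and threshold classification. All costs in million VND.

PERSPECTIVES <- c("patient", "public_payer", "healthcare_sector")

# utility of a state group at a given (floored) age, honouring the
# age-adjustment switch; groups: dfs_on (also NM recurrence), dfs_off (also
# remission), mbc
utility_at_age <- function(uset, group, age) {
  u <- uset[[group]]
  if (!isTRUE(uset$age_adjusted)) return(rep(u$pooled, length(age)))
  a <- floor(age)
  ifelse(a < 40, u$under40,
         ifelse(a < 50, u$a40_49,
                ifelse(a < 60, u$a50_59, u$a60plus)))
}

# half-cycle-corrected occupancy aggregated to the three alive accrual groups
group_membership <- function(trace) {
  eff <- half_cycle_membership(trace)
  cbind(on = rowSums(eff[, c(IDX_DFS_ON, IDX_NM_REC), drop = FALSE]),
        off = eff[, IDX_DFS_OFF] + eff[, IDX_REMISSION],
        mbc = rowSums(eff[, IDX_MBC, drop = FALSE]))
}

#' Discounted quality-adjusted life-years of a cohort trace
#'
#' Weights the half-cycle-corrected occupancy by the state-group utility at
#' the cohort's current age band (on-treatment and non-metastatic recurrence
#' share one utility; off-treatment and remission share another; metastatic
#' disease has its own), accrues 1/12 of the utility per monthly cycle, and
#' discounts at the annual rate.
#'
#' @param trace a `cohort_trace`.
#' @param params model parameters (utilities and discount settings).
#' @return Discounted QALYs per person.
#' @export
qalys <- function(trace, params) {
  H <- trace$horizon
  gm <- group_membership(trace)
  ages <- trace$age_at_cycle[1:H]
  U <- cbind(utility_at_age(params$utilities, "dfs_on", ages),
             utility_at_age(params$utilities, "dfs_off", ages),
             utility_at_age(params$utilities, "mbc", ages))
  df <- discount_factors(params$settings$discount_annual, H)
  sum(rowSums(gm * U) * df) / 12
}

#' Cost of CBE screening per diagnosis
#'
#' The screening programme cost attributed to each diagnosed patient: cost of
#' CBE per person divided by the proportion of screened women who are
#' diagnostic-positive (0.06% in the base case).
#'
#' @param cbe_per_person cost of one examination, million VND.
#' @param detection_rate diagnostic-positive proportion, in (0, 1\].
#' @return Cost per diagnosis, million VND.
#' @examples
#' cost_per_diagnosis(0.033, 0.0006)   # 55
#' @export
cost_per_diagnosis <- function(cbe_per_person, detection_rate) {
  if (cbe_per_person < 0) stop("'cbe_per_person' must be non-negative")
  if (detection_rate <= 0) stop("'detection_rate' must be > 0")
  cbe_per_person / detection_rate
}

#' Accrue discounted costs over a cohort trace
#'
#' One-off costs at cycle 0 (undiscounted, not half-cycle corrected): the
#' diagnosis cost in both scenarios, plus the CBE cost per diagnosis in the
#' screening scenario only. Monthly costs: on-treatment states (DFS
#' on-treatment, non-metastatic recurrence) accrue the treatment-mix-weighted
#' targeted/chemotherapy cost; off-treatment states (DFS off-treatment,
#' remission) accrue follow-up care; the metastatic state accrues supportive
#' care plus, for the targeted fraction, the 40-month-amortised targeted
#' therapy cost. Monthly accruals are half-cycle corrected and discounted;
#' the dead accrue nothing.
#'
#' @param trace a `cohort_trace`.
#' @param params model parameters.
#' @param perspective `"patient"`, `"public_payer"` or `"healthcare_sector"`.
#' @param scenario `"screening"` or `"no_screening"` (controls the CBE
#'   one-off).
#' @return Discounted total cost per person, million VND.
#' @export
accrue_costs <- function(trace, params,
                         perspective = c("healthcare_sector", "patient",
                                         "public_payer"),
                         scenario = c("screening", "no_screening")) {
  perspective <- match.arg(perspective)
  scenario <- match.arg(scenario)
  cs <- params$costs[[perspective]]
  mix <- params$mix
  c_on <- mix$dfs_targeted * cs$targeted_monthly +
    (1 - mix$dfs_targeted) * cs$chemo_monthly
  c_off <- cs$followup_monthly
  c_mbc <- mix$mbc_targeted * cs$mbc_targeted_monthly + cs$mbc_supportive_monthly
  one_off <- cs$diagnosis
  if (scenario == "screening")
    one_off <- one_off +
      cost_per_diagnosis(cs$cbe_per_person, params$costs$detection_rate)
  gm <- group_membership(trace)
  df <- discount_factors(params$settings$discount_annual, trace$horizon)
  one_off + sum((gm %*% c(c_on, c_off, c_mbc)) * df)
}

#' Incremental cost-effectiveness ratio
#'
#' Differences in cost and effect between an intervention and a comparator,
#' and the resulting ratios. A dominant intervention (cheaper and more
#' effective) is flagged rather than reported as a negative ratio; a zero
#' QALY difference yields an undefined-ICER flag, not an error.
#'
#' @param intervention,comparator lists with elements `ly`, `qaly`, `cost`.
#' @return List with `delta_ly`, `delta_qaly`, `delta_cost`, `icer_ly`,
#'   `icer_qaly` (million VND per unit effect), `dominant`, `undefined`.
#' @export
compute_icer <- function(intervention, comparator) {
  d_cost <- intervention$cost - comparator$cost
  d_qaly <- intervention$qaly - comparator$qaly
  d_ly <- intervention$ly - comparator$ly
  undefined <- d_qaly == 0
  dominant <- d_cost < 0 && d_qaly > 0
  list(delta_ly = d_ly, delta_qaly = d_qaly, delta_cost = d_cost,
       icer_ly = if (d_ly != 0) d_cost / d_ly else NA_real_,
       icer_qaly = if (!undefined) d_cost / d_qaly else NA_real_,
       dominant = dominant, undefined = undefined)
}

#' Convert million VND to US dollars
#'
#' @param amount_mvnd amount in million VND (vectorised).
#' @param rate exchange rate in VND per USD (default 22,759).
#' @return Whole dollars, rounded half-up (half away from zero).
#' @examples
#' vnd_to_usd(41.0)   # 1801
#' vnd_to_usd(95.1)   # 4179
#' @export
vnd_to_usd <- function(amount_mvnd, rate = 22759) {
  if (rate <= 0) stop("'rate' must be > 0")
  x <- amount_mvnd * 1e6 / rate
  trunc(x + 0.5 * sign(x))
}

#' Classify an ICER against willingness-to-pay thresholds
#'
#' WHO convention: below 1x GDP per capita is highly cost-effective, below 3x
#' is cost-effective, above is not (Vietnam: 63.2 and 189.6 million VND per
#' QALY).
#'
#' @param icer ICER in million VND per QALY.
#' @param thresholds ordered pair `c(highly, cost_effective)`.
#' @return One of `"highly_cost_effective"`, `"cost_effective"`,
#'   `"not_cost_effective"`.
#' @export
classify_cost_effectiveness <- function(icer, thresholds = c(63.2, 189.6)) {
  if (thresholds[1] > thresholds[2]) stop("'thresholds' must be ordered")
  if (is.na(icer)) return(NA_character_)
  if (icer <= thresholds[1]) "highly_cost_effective"
  else if (icer <= thresholds[2]) "cost_effective"
  else "not_cost_effective"
}

#' Run the base-case cost-effectiveness analysis
#'
#' Builds the screening and no-screening cohort traces (identical transition
#' model; starting distributions differ by the downstaging effect), accrues
#' life-years, QALYs and perspective-specific costs, and computes incremental
#' results, ICERs, USD conversions and threshold classifications for the
#' requested perspectives.
#'
#' @param params model parameters.
#' @param perspectives subset of
#'   `c("patient", "public_payer", "healthcare_sector")`.
#' @param validate re-validate parameters on entry (additivity checking is
#'   skipped so that one-way perturbations of a single perspective's cost
#'   remain analysable).
#' @return A `cea_result`: list with `summary` (per perspective and scenario:
#'   LY, QALY, cost), `incremental` (deltas, ICERs in million VND and USD,
#'   classification), `traces`, and `params`.
#' @export
run_cea <- function(params, perspectives = PERSPECTIVES, validate = TRUE) {
  perspectives <- match.arg(perspectives, PERSPECTIVES, several.ok = TRUE)
  if (validate) validate_params(params, check_additivity = FALSE)
  H <- params$settings$horizon_months
  traces <- list(
    screening = run_cohort(make_start(params, "screening"), params, H),
    no_screening = run_cohort(make_start(params, "no_screening"), params, H))
  r <- params$settings$discount_annual
  ly <- vapply(traces, life_years, numeric(1), discount_annual = r)
  qa <- vapply(traces, qalys, numeric(1), params = params)
  summary <- NULL
  incr <- NULL
  for (p in perspectives) {
    cost <- c(
      screening = accrue_costs(traces$screening, params, p, "screening"),
      no_screening = accrue_costs(traces$no_screening, params, p,
                                  "no_screening"))
    summary <- rbind(summary, data.frame(
      perspective = p,
      scenario = c("screening", "no_screening"),
      ly = as.numeric(ly), qaly = as.numeric(qa), cost_mvnd = as.numeric(cost),
      stringsAsFactors = FALSE))
    ic <- compute_icer(
      list(ly = ly[["screening"]], qaly = qa[["screening"]],
           cost = cost[["screening"]]),
      list(ly = ly[["no_screening"]], qaly = qa[["no_screening"]],
           cost = cost[["no_screening"]]))
    incr <- rbind(incr, data.frame(
      perspective = p,
      delta_ly = ic$delta_ly, delta_qaly = ic$delta_qaly,
      delta_cost_mvnd = ic$delta_cost,
      icer_ly_mvnd = ic$icer_ly, icer_qaly_mvnd = ic$icer_qaly,
      icer_qaly_usd = if (is.na(ic$icer_qaly)) NA_real_
                      else vnd_to_usd(ic$icer_qaly,
                                      params$settings$exchange_rate),
      dominant = ic$dominant,
      classification = classify_cost_effectiveness(
        ic$icer_qaly, c(params$settings$threshold_highly,
                        params$settings$threshold_ce)),
      stringsAsFactors = FALSE))
  }
  structure(list(summary = summary, incremental = incr, traces = traces,
                 params = params),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness analysis: CBE screening vs no screening\n")
  cat(sprintf("Horizon %d months, start age %g, discount %.1f%%/yr\n\n",
              x$params$settings$horizon_months, x$params$settings$start_age,
              100 * x$params$settings$discount_annual))
  for (p in unique(x$summary$perspective)) {
    s <- x$summary[x$summary$perspective == p, ]
    i <- x$incremental[x$incremental$perspective == p, ]
    cat(sprintf("-- %s perspective --\n", gsub("_", " ", p)))
    for (k in seq_len(nrow(s)))
      cat(sprintf("  %-13s LY %6.2f  QALY %6.2f  cost %8.1f mVND\n",
                  s$scenario[k], s$ly[k], s$qaly[k], s$cost_mvnd[k]))
    cat(sprintf(
      "  incremental   dLY %5.2f  dQALY %5.2f  dCost %7.1f mVND\n",
      i$delta_ly, i$delta_qaly, i$delta_cost_mvnd))
    cat(sprintf("  ICER %.1f mVND/QALY (~$%d/QALY): %s\n\n",
                i$icer_qaly_mvnd, i$icer_qaly_usd, i$classification))
  }
  invisible(x)
}
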
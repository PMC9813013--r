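# Monthly-cycle Markov cohort engine over the expanded (tunnel-indexed)
# state space, with half-cycle correction.

# Per-cycle scalar inputs shared by the transition matrix, the fast cohort
# propagation and the microsimulation oracle, so all three see bit-identical
# probabilities.
#   pb[t+1]  monthly background death probability during cycle t (t = 0..H-1)
#   prr[t+1] raw (cure-adjusted) DFS recurrence probability during cycle t
#   pm[m]    monthly metastatic death probability at tunnel month m (1..60)
precompute_cycle_inputs <- function(params, horizon) {
  t0 <- 0:(horizon - 1)
  ages <- params$settings$start_age + t0 / 12
  pb <- background_mortality(params$life_table, ages)
  curve <- params$dfs
  S <- survival_at(curve, 0:horizon)
  prr <- (1 - S[t0 + 2] / S[t0 + 1]) *
    cure_multiplier(t0, curve$cure_threshold, curve$max_cure_rate,
                    curve$cure_ramp)
  pm <- mbc_death_probability(params$transitions$mbc_mortality, 1:N_MBC)
  list(pb = pb, prr = prr, pm = pm,
       p_rem = params$transitions$remission_to_mbc,
       split = curve$mbc_split)
}

#' Build the one-cycle transition matrix
#'
#' Constructs the row-stochastic transition matrix over the 87 expanded states
#' for the cycle starting at month `cycle`. Permitted transitions: the
#' disease-free states exit to recurrence (split metastatic /
#' non-metastatic) or death, with the on-treatment tunnel feeding
#' off-treatment after 12 months; non-metastatic recurrence moves to remission
#' automatically after 12 months if alive, facing only background mortality
#' meanwhile; remission progresses to metastatic disease or dies; metastatic
#' tunnel months carry the year-since-entry mortality schedule; death is
#' absorbing. Competing events are composed multiplicatively with death taking
#' precedence.
#'
#' @param params model parameters.
#' @param cycle month index (0-based) of the cycle start.
#' @return An 87 x 87 row-stochastic matrix with state labels as dimnames.
#'   Any row deviating from sum 1 by more than 1e-9 is a construction error
#'   naming the state.
#' @export
build_transition_matrix <- function(params, cycle) {
  if (cycle < 0) stop("'cycle' must be >= 0")
  ci <- precompute_cycle_inputs_at(params, cycle)
  P <- matrix(0, N_STATES, N_STATES,
              dimnames = list(state_labels(), state_labels()))
  pb <- ci$pb
  prr <- ci$prr
  p_rec <- (1 - pb) * prr
  p_stay <- (1 - pb) * (1 - prr)
  # disease-free states (on-treatment tunnels and off-treatment)
  for (i in c(IDX_DFS_ON, IDX_DFS_OFF)) {
    dest_stay <- if (i < N_DFS_ON) i + 1L else IDX_DFS_OFF
    P[i, IDX_DEAD] <- pb
    P[i, IDX_MBC[1]] <- p_rec * ci$split
    P[i, IDX_NM_REC[1]] <- p_rec * (1 - ci$split)
    P[i, dest_stay] <- P[i, dest_stay] + p_stay
  }
  # non-metastatic recurrence tunnels: background mortality only, remission
  # automatic after 12 months if alive
  for (m in 1:N_NM_REC) {
    i <- IDX_NM_REC[m]
    dest <- if (m < N_NM_REC) IDX_NM_REC[m + 1] else IDX_REMISSION
    P[i, IDX_DEAD] <- pb
    P[i, dest] <- 1 - pb
  }
  # remission: progression to metastatic disease or background death
  P[IDX_REMISSION, IDX_DEAD] <- pb
  P[IDX_REMISSION, IDX_MBC[1]] <- (1 - pb) * ci$p_rem
  P[IDX_REMISSION, IDX_REMISSION] <- (1 - pb) * (1 - ci$p_rem)
  # metastatic tunnels: time-in-state mortality, month 60 absorbs the tail
  for (m in 1:N_MBC) {
    i <- IDX_MBC[m]
    dest <- if (m < N_MBC) IDX_MBC[m + 1] else IDX_MBC[N_MBC]
    P[i, IDX_DEAD] <- ci$pm[m]
    P[i, dest] <- 1 - ci$pm[m]
  }
  P[IDX_DEAD, IDX_DEAD] <- 1
  bad <- which(abs(rowSums(P) - 1) > 1e-9)
  if (length(bad))
    stop(sprintf("transition matrix row not stochastic for state %s",
                 state_labels()[bad[1]]))
  P
}

# single-cycle version of precompute_cycle_inputs
precompute_cycle_inputs_at <- function(params, cycle) {
  age <- params$settings$start_age + cycle / 12
  curve <- params$dfs
  prr <- cycle_event_probability(curve, cycle) *
    cure_multiplier(cycle, curve$cure_threshold, curve$max_cure_rate,
                    curve$cure_ramp)
  list(pb = background_mortality(params$life_table, age),
       prr = prr,
       pm = mbc_death_probability(params$transitions$mbc_mortality, 1:N_MBC),
       p_rem = params$transitions$remission_to_mbc,
       split = curve$mbc_split)
}

#' Run the cohort model
#'
#' Propagates a starting distribution through the monthly transition model for
#' `horizon` cycles. The default `"fast"` method updates the occupancy
#' segments directly with vectorised arithmetic; `"matrix"` multiplies by the
#' explicit per-cycle matrix from [build_transition_matrix()]. The two agree
#' to floating-point tolerance and the matrix path serves as the reference
#' implementation in the test suite.
#'
#' @param start occupancy vector over the 87 expanded states, summing to 1
#'   (see [make_start()]).
#' @param params model parameters.
#' @param horizon number of monthly cycles (default: settings).
#' @param method `"fast"` or `"matrix"`.
#' @return A `cohort_trace`: list with `occupancy`
#'   ((horizon + 1) x 87 matrix, rows = cycles 0..horizon),
#'   `age_at_cycle`, and `horizon`.
#' @export
run_cohort <- function(start, params,
                       horizon = params$settings$horizon_months,
                       method = c("fast", "matrix")) {
  method <- match.arg(method)
  if (length(start) != N_STATES)
    stop(sprintf("'start' must have length %d", N_STATES))
  if (abs(sum(start) - 1) > 1e-9)
    stop("'start' must sum to 1")
  if (horizon < 1) stop("'horizon' must be >= 1")
  horizon <- as.integer(horizon)
  occ <- matrix(0, horizon + 1, N_STATES,
                dimnames = list(0:horizon, state_labels()))
  occ[1, ] <- start
  if (method == "matrix") {
    for (t in 0:(horizon - 1)) {
      P <- build_transition_matrix(params, t)
      occ[t + 2, ] <- occ[t + 1, ] %*% P
    }
  } else {
    ci <- precompute_cycle_inputs(params, horizon)
    pm <- ci$pm
    p_rem <- ci$p_rem
    split <- ci$split
    cur <- start
    for (t in seq_len(horizon)) {
      pb <- ci$pb[t]
      prr <- ci$prr[t]
      p_rec <- (1 - pb) * prr
      p_stay <- (1 - pb) * (1 - prr)
      d <- cur[1:13]                      # DFS_ON m1..m12, DFS_OFF
      n <- cur[14:25]                     # NM_REC m1..m12
      r <- cur[26]                        # REMISSION
      mb <- cur[27:86]                    # MBC m1..m60
      dead <- cur[87]
      tot_d <- sum(d)
      nxt <- numeric(N_STATES)
      nxt[2:12] <- d[1:11] * p_stay
      nxt[13] <- (d[12] + d[13]) * p_stay
      nxt[14] <- tot_d * p_rec * (1 - split)
      nxt[15:25] <- n[1:11] * (1 - pb)
      nxt[26] <- n[12] * (1 - pb) + r * (1 - pb) * (1 - p_rem)
      mb_surv <- mb * (1 - pm)
      nxt[27] <- tot_d * p_rec * split + r * (1 - pb) * p_rem
      nxt[28:86] <- mb_surv[1:59]
      nxt[86] <- nxt[86] + mb_surv[60]
      nxt[87] <- dead + (tot_d + sum(n) + r) * pb + sum(mb * pm)
      occ[t + 1, ] <- nxt
      cur <- nxt
    }
  }
  bad <- which(abs(rowSums(occ) - 1) > 1e-10)
  if (length(bad))
    stop(sprintf("cohort trace row %d does not conserve mass", bad[1] - 1L))
  structure(list(occupancy = occ,
                 age_at_cycle = params$settings$start_age + (0:horizon) / 12,
                 horizon = horizon),
            class = "cohort_trace")
}

#' Half-cycle-corrected state membership
#'
#' Effective occupancy for cycle t is the average of the occupancy at the
#' cycle's start and end, approximating mid-cycle transitions.
#'
#' @param trace a `cohort_trace`.
#' @return A horizon x 87 matrix of effective occupancies.
#' @export
half_cycle_membership <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  H <- trace$horizon
  (trace$occupancy[1:H, , drop = FALSE] +
     trace$occupancy[2:(H + 1), , drop = FALSE]) / 2
}

# discount factors for cycles 0..H-1 at an annual rate
discount_factors <- function(discount_annual, horizon) {
  (1 + discount_annual)^(-(0:(horizon - 1)) / 12)
}

#' Discounted life-years of a cohort trace
#'
#' Sums the half-cycle-corrected alive occupancy over cycles, each month
#' contributing 1/12 of a year discounted at `(1 + r)^(-t/12)`.
#'
#' @param trace a `cohort_trace`.
#' @param discount_annual annual discount rate (default 0.015).
#' @return Discounted life-years per person.
#' @export
life_years <- function(trace, discount_annual = 0.015) {
  if (discount_annual < 0) stop("'discount_annual' must be >= 0")
  eff <- half_cycle_membership(trace)
  alive <- 1 - eff[, IDX_DEAD]
  sum(alive * discount_factors(discount_annual, trace$horizon)) / 12
}
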
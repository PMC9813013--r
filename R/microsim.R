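# Individual-level microsimulation of the identical discrete-time process:
# an independent oracle for the cohort expectation. Each individual gets an
# RNG sub-stream derived from the master seed, so results do not depend on
# iteration order.

#' Microsimulation oracle
#'
#' Simulates individuals one transition at a time with exactly the per-cycle
#' probabilities of the cohort engine (shared code path), applies the same
#' half-cycle-corrected, discounted accrual of life-years, QALYs and costs,
#' and reports Monte-Carlo means and standard errors. The cohort model's
#' outputs are the exact expectations of this process, so agreement within a
#' few standard errors validates the matrix bookkeeping end to end.
#'
#' @param params model parameters.
#' @param start a scenario name (`"screening"`, `"no_screening"`) or an
#'   87-vector starting distribution.
#' @param n_individuals number of simulated individuals (>= 1).
#' @param seed master RNG seed (mandatory; per-individual sub-streams are
#'   derived from it).
#' @param perspective cost perspective to accrue.
#' @param horizon cycles (default: settings).
#' @return List with `n`, `mean` and `se` (each a named vector over
#'   `ly`, `qaly`, `cost_mvnd`).
#' @export
microsim_oracle <- function(params, start = "screening", n_individuals, seed,
                            perspective = "healthcare_sector",
                            horizon = params$settings$horizon_months) {
  if (n_individuals < 1) stop("'n_individuals' must be >= 1")
  if (missing(seed)) stop("'seed' is required")
  scenario <- NULL
  if (is.character(start)) {
    scenario <- match.arg(start, c("screening", "no_screening"))
    start <- make_start(params, scenario)
  }
  if (abs(sum(start) - 1) > 1e-9) stop("'start' must sum to 1")
  H <- as.integer(horizon)
  ci <- precompute_cycle_inputs(params, H)
  pb <- ci$pb; prr <- ci$prr; pm <- ci$pm
  p_rem <- ci$p_rem; split <- ci$split

  # accrual inputs shared with the cohort path
  df <- discount_factors(params$settings$discount_annual, H)
  ages <- params$settings$start_age + (0:H) / 12
  Umat <- cbind(utility_at_age(params$utilities, "dfs_on", ages),
                utility_at_age(params$utilities, "dfs_off", ages),
                utility_at_age(params$utilities, "mbc", ages),
                0)
  cs <- params$costs[[match.arg(perspective, PERSPECTIVES)]]
  mix <- params$mix
  cost_g <- c(mix$dfs_targeted * cs$targeted_monthly +
                (1 - mix$dfs_targeted) * cs$chemo_monthly,
              cs$followup_monthly,
              mix$mbc_targeted * cs$mbc_targeted_monthly +
                cs$mbc_supportive_monthly,
              0)
  one_off <- cs$diagnosis +
    if (identical(scenario, "screening"))
      cost_per_diagnosis(cs$cbe_per_person, params$costs$detection_rate)
    else 0
  cum_start <- cumsum(start)

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_individuals)
  ly <- qa <- co <- numeric(n_individuals)
  for (i in seq_len(n_individuals)) {
    set.seed(sub_seeds[i])
    u0 <- stats::runif(1)
    u <- stats::runif(H)
    path <- integer(H + 1)
    s <- findInterval(u0, cum_start, left.open = TRUE) + 1L
    path[1] <- s
    for (t in seq_len(H)) {
      if (s == 87L) { path[t:H + 1L] <- 87L; break }
      ut <- u[t]
      if (s <= 13L) {                      # disease-free
        p_d <- pb[t]
        p_r <- (1 - p_d) * prr[t]
        s <- if (ut < p_d) 87L
             else if (ut < p_d + p_r * split) 27L
             else if (ut < p_d + p_r) 14L
             else if (s < 12L) s + 1L else 13L
      } else if (s <= 25L) {               # non-metastatic recurrence
        s <- if (ut < pb[t]) 87L else if (s == 25L) 26L else s + 1L
      } else if (s == 26L) {               # remission
        p_d <- pb[t]
        p_m <- (1 - p_d) * p_rem
        s <- if (ut < p_d) 87L else if (ut < p_d + p_m) 27L else 26L
      } else {                             # metastatic tunnel
        m <- s - 26L
        s <- if (ut < pm[m]) 87L else if (m < 60L) s + 1L else s
      }
      path[t + 1] <- s
    }
    g <- STATE_GROUP[path]
    alive <- as.numeric(g != 4L)
    uval <- Umat[cbind(seq_len(H + 1), g)]
    cval <- cost_g[g]
    ly[i] <- sum(df * (alive[1:H] + alive[2:(H + 1)]) / 2) / 12
    qa[i] <- sum(df * (uval[1:H] + uval[2:(H + 1)]) / 2) / 12
    co[i] <- one_off + sum(df * (cval[1:H] + cval[2:(H + 1)]) / 2)
  }
  list(n = n_individuals,
       mean = c(ly = mean(ly), qaly = mean(qa), cost_mvnd = mean(co)),
       se = c(ly = stats::sd(ly), qaly = stats::sd(qa),
              cost_mvnd = stats::sd(co)) / sqrt(n_individuals))
}
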
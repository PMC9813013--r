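# Shared fixture builders: parameter sets with controlled hazards and small
# synthetic traces. All fixtures are built in code at test time.

quick_params <- function(horizon = 240L) {
  p <- default_parameters()
  p$settings$horizon_months <- as.integer(horizon)
  p
}

# all cause-specific hazards off: flat DFS curve, zero life table, no
# remission progression, no metastatic mortality
zero_hazard_params <- function(horizon = 60L) {
  p <- quick_params(horizon)
  p$dfs <- dfs_curve("exponential", rate = 0, max_cure_rate = 0)
  p$life_table <- life_table(0:100, rep(0, 101))
  p$transitions$remission_to_mbc <- 0
  p$transitions$mbc_mortality <- list(y1 = 0, y2 = 0, y3 = 0, y4 = 0,
                                      y5plus = 0)
  p
}

# only metastatic mortality, constant across tunnel years
const_mbc_params <- function(rate = 0.05, horizon = 600L) {
  p <- zero_hazard_params(horizon)
  p$transitions$mbc_mortality <- list(y1 = rate, y2 = rate, y3 = rate,
                                      y4 = rate, y5plus = rate)
  p
}

# randomized valid parameter set for property-style tests
random_params <- function(seed) {
  set.seed(seed)
  p <- default_parameters()
  p$dfs <- dfs_curve("weibull",
                     shape = runif(1, 0.6, 1.4),
                     scale = runif(1, 100, 600),
                     cure_threshold = runif(1, 60, 180),
                     max_cure_rate = runif(1, 0, 1),
                     mbc_split = runif(1, 0, 1),
                     cure_ramp = sample(c("linear", "step"), 1))
  p$life_table <- make_life_table(makeham = runif(1, 0, 5e-3),
                                  baseline = runif(1, 1e-6, 1e-4),
                                  slope = runif(1, 0.05, 0.12))
  p$transitions$remission_to_mbc <- runif(1, 0, 0.05)
  m <- sort(runif(5, 0.01, 0.15))
  p$transitions$mbc_mortality <- as.list(stats::setNames(
    m, c("y1", "y2", "y3", "y4", "y5plus")))
  b <- runif(1, 0.5, 0.9)
  p$start$dfs_noscreening <- b
  p$start$dfs_screening <- runif(1, b + 0.01, 0.99)
  for (g in c("dfs_on", "dfs_off", "mbc"))
    for (k in names(p$utilities[[g]]))
      p$utilities[[g]][[k]] <- runif(1, 0.3, 1)
  p$settings$discount_annual <- runif(1, 0, 0.05)
  validate_params(p)
  p
}

# a hand-built trace with the cohort fixed in one expanded state
flat_trace <- function(state_index, horizon, start_age = 44) {
  occ <- matrix(0, horizon + 1, 87,
                dimnames = list(0:horizon, make_state_space()$label))
  occ[, state_index] <- 1
  structure(list(occupancy = occ,
                 age_at_cycle = start_age + (0:horizon) / 12,
                 horizon = as.integer(horizon)),
            class = "cohort_trace")
}
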
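# Expanded state space: six base health states, with tunnel (time-in-state)
# expansion where transition probabilities depend on time in state.
#   DFS_ON   12 monthly tunnels (max 12 months on adjuvant treatment)
#   DFS_OFF   1
#   NM_REC   12 monthly tunnels (second treatment course, then remission)
#   REMISSION 1
#   MBC      60 monthly tunnels; month 60 is absorbing in tunnel time
#            (mortality constant at the year-5+ rate thereafter)
#   DEAD      1 (absorbing)

N_DFS_ON <- 12L
N_NM_REC <- 12L
N_MBC <- 60L

IDX_DFS_ON <- 1:12
IDX_DFS_OFF <- 13L
IDX_NM_REC <- 14:25
IDX_REMISSION <- 26L
IDX_MBC <- 27:86
IDX_DEAD <- 87L
N_STATES <- 87L

# group codes used for utility / cost accrual
# 1 = on-treatment (DFS on-treatment, non-metastatic recurrence)
# 2 = off-treatment (DFS off-treatment, remission)
# 3 = metastatic
# 4 = dead
STATE_GROUP <- c(rep(1L, N_DFS_ON), 2L, rep(1L, N_NM_REC), 2L,
                 rep(3L, N_MBC), 4L)

state_labels <- function() {
  c(sprintf("DFS_ON_m%02d", 1:N_DFS_ON),
    "DFS_OFF",
    sprintf("NM_REC_m%02d", 1:N_NM_REC),
    "REMISSION",
    sprintf("MBC_m%02d", 1:N_MBC),
    "DEAD")
}

#' Expanded Markov state space
#'
#' Enumerates the expanded (tunnel-indexed) state space of the model: the six
#' base health states with monthly tunnel expansion for the time-limited
#' on-treatment states (12 months) and for metastatic disease (60 months, the
#' last tunnel month absorbing the time dependence of mortality).
#'
#' @return A data frame with one row per expanded state and columns
#'   `index`, `base` (base health state), `tunnel_month` (months in state
#'   represented by this expanded state) and `label`.
#' @examples
#' ss <- make_state_space()
#' nrow(ss)          # 87 expanded states
#' table(ss$base)
#' @export
make_state_space <- function() {
  base <- c(rep("DFS_ON", N_DFS_ON), "DFS_OFF", rep("NM_REC", N_NM_REC),
            "REMISSION", rep("MBC", N_MBC), "DEAD")
  tunnel <- c(1:N_DFS_ON, 1L, 1:N_NM_REC, 1L, 1:N_MBC, 1L)
  data.frame(index = seq_len(N_STATES),
             base = base,
             tunnel_month = tunnel,
             label = state_labels(),
             stringsAsFactors = FALSE)
}

#' Starting distribution for a scenario
#'
#' Builds the cycle-0 occupancy vector over the expanded state space. Patients
#' enter either disease-free survival (first on-treatment tunnel month) or
#' metastatic disease (first metastatic tunnel month) according to the
#' scenario's starting probability, which encodes the downstaging effect of
#' screening.
#'
#' @param params model parameters, see [default_parameters()].
#' @param scenario `"screening"` or `"no_screening"`.
#' @return Numeric vector of length 87 summing to 1.
#' @examples
#' p <- default_parameters()
#' s <- make_start(p, "screening")
#' s[1]    # 0.924 enters DFS on-treatment
#' @export
make_start <- function(params, scenario = c("screening", "no_screening")) {
  scenario <- match.arg(scenario)
  p_dfs <- if (scenario == "screening") params$start$dfs_screening
           else params$start$dfs_noscreening
  start <- numeric(N_STATES)
  start[IDX_DFS_ON[1]] <- p_dfs
  start[IDX_MBC[1]] <- 1 - p_dfs
  names(start) <- state_labels()
  start
}
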
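test_that("transition matrices are row-stochastic with correct structure", {
  for (seed in 1:3) {
    p <- random_params(seed)
    for (cyc in c(0L, 11L, 119L, 400L)) {
      P <- build_transition_matrix(p, cyc)
      expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-12)
      expect_true(all(P >= 0 & P <= 1))
      # death is absorbing
      expect_equal(unname(P[87, ]), c(rep(0, 86), 1))
    }
  }
})

test_that("zero hazards leave only tunnel-advance transitions", {
  p <- zero_hazard_params()
  P <- build_transition_matrix(p, 0)
  expect_equal(unname(diag(P)[c(13, 26, 86, 87)]), rep(1, 4))
  for (m in 1:11) {
    expect_equal(unname(P[m, m + 1]), 1)          # DFS_ON advances
    expect_equal(unname(P[13 + m, 14 + m]), 1)    # NM_REC advances
  }
  expect_equal(unname(P[12, 13]), 1)   # DFS_ON m12 -> DFS_OFF
  expect_equal(unname(P[25, 26]), 1)   # NM_REC m12 -> REMISSION
  expect_equal(sum(P != 0), 87)        # exactly one destination per state
})

test_that("tunnel exits follow the time-in-state schedule", {
  # NM_REC month 12 with monthly background death p: remission 1-p, death p
  p <- zero_hazard_params()
  p$life_table <- life_table(0:100, rep(1 - 0.99^12, 101))  # monthly 0.01
  P <- build_transition_matrix(p, 5)
  expect_equal(unname(P[25, 26]), 0.99)
  expect_equal(unname(P[25, 87]), 0.01)
  # metastatic tunnel month 13 is in year 2 of the mortality schedule
  pd <- default_parameters()
  Pd <- build_transition_matrix(pd, 0)
  i13 <- 26 + 13
  expect_equal(unname(Pd[i13, 87]), 0.0446)
  expect_equal(unname(Pd[i13, i13 + 1]), 1 - 0.0446)
  # month 60 absorbs the tunnel at the year-5+ rate
  expect_equal(unname(Pd[86, 87]), 0.0541)
  expect_equal(unname(Pd[86, 86]), 1 - 0.0541)
})

test_that("cohort propagation: absorbing start, tunnel exhaustion, decay", {
  p <- zero_hazard_params(30L)
  dead <- numeric(87); dead[87] <- 1
  tr <- run_cohort(dead, p, 30)
  expect_equal(unname(tr$occupancy[, 87]), rep(1, 31))
  # zero hazards from DFS_ON month 1: fully off-treatment from cycle 12 on
  s <- numeric(87); s[1] <- 1
  tr2 <- run_cohort(s, p, 30)
  expect_equal(unname(tr2$occupancy[13:31, 13]), rep(1, 19))
  expect_equal(unname(tr2$occupancy[12, 12]), 1)
  # constant metastatic mortality: geometric survival
  pm <- const_mbc_params(0.05, 200L)
  s2 <- numeric(87); s2[27] <- 1
  tr3 <- run_cohort(s2, pm, 200)
  expect_equal(unname(1 - tr3$occupancy[, 87]), 0.95^(0:200),
               tolerance = 1e-12)
  expect_error(run_cohort(s2 * 0.9, pm, 10), "sum to 1")
})

test_that("fast and matrix propagation agree", {
  p <- quick_params(60L)
  s <- make_start(p, "screening")
  t_fast <- run_cohort(s, p, 60, method = "fast")
  t_mat <- run_cohort(s, p, 60, method = "matrix")
  expect_equal(t_fast$occupancy, t_mat$occupancy, tolerance = 1e-13)
  pr <- random_params(4)
  t_fast2 <- run_cohort(make_start(pr, "no_screening"), pr, 48, "fast")
  t_mat2 <- run_cohort(make_start(pr, "no_screening"), pr, 48, "matrix")
  expect_equal(t_fast2$occupancy, t_mat2$occupancy, tolerance = 1e-13)
})

test_that("trace conservation and monotone death hold for random inputs", {
  for (seed in 11:14) {
    p <- random_params(seed)
    tr <- run_cohort(make_start(p, "screening"), p, 300)
    expect_equal(max(abs(rowSums(tr$occupancy) - 1)), 0, tolerance = 1e-10)
    expect_true(all(tr$occupancy >= -1e-15 & tr$occupancy <= 1 + 1e-15))
    expect_true(all(diff(tr$occupancy[, 87]) >= -1e-15))
  }
})

test_that("half-cycle correction averages cycle endpoints", {
  tr <- flat_trace(13, 24)
  eff <- half_cycle_membership(tr)
  expect_equal(dim(eff), c(24L, 87L))
  expect_equal(unname(eff[, 13]), rep(1, 24))
  # a 1 -> 0 step counts half in the transition cycle
  tr$occupancy[2:25, 13] <- 0
  tr$occupancy[2:25, 87] <- 1
  eff2 <- half_cycle_membership(tr)
  expect_equal(unname(eff2[1, 13]), 0.5)
  expect_equal(unname(eff2[2, 13]), 0)
})

test_that("life-years accrue half-cycle corrected and discounted", {
  p <- zero_hazard_params()
  s <- numeric(87); s[1] <- 1
  expect_equal(life_years(run_cohort(s, p, 120), 0), 10)
  expect_equal(life_years(run_cohort(s, p, 12), 0), 1)
  # geometric decay: 19.5 effective person-months
  pm <- const_mbc_params(0.05, 600L)
  s2 <- numeric(87); s2[27] <- 1
  tr <- run_cohort(s2, pm, 600)
  expect_equal(life_years(tr, 0), 19.5 / 12, tolerance = 1e-8)
  # life-years are non-increasing in the discount rate
  trd <- run_cohort(make_start(quick_params(), "screening"), quick_params())
  ly <- vapply(c(0, 0.015, 0.035, 0.1), function(r) life_years(trd, r),
               numeric(1))
  expect_true(all(diff(ly) < 0))
  expect_error(life_years(trd, -0.01), ">= 0")
})

test_that("recurrence split routes all mass to a single destination", {
  p <- quick_params(120L)
  s <- numeric(87); s[1] <- 1
  p$dfs$mbc_split <- 1
  tr <- run_cohort(s, p, 120)
  expect_equal(sum(tr$occupancy[, c(14:25, 26)]), 0)  # no NM/remission mass
  p$dfs$mbc_split <- 0
  p$transitions$remission_to_mbc <- 0
  tr2 <- run_cohort(s, p, 120)
  expect_equal(sum(tr2$occupancy[, 27:86]), 0)        # no metastatic mass
})
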
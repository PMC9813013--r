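test_that("QALYs reduce to life-years under unit utilities", {
  p <- quick_params(240L)
  for (g in c("dfs_on", "dfs_off", "mbc"))
    for (k in names(p$utilities[[g]])) p$utilities[[g]][[k]] <- 1
  tr <- run_cohort(make_start(p, "screening"), p)
  expect_equal(qalys(tr, p), life_years(tr, p$settings$discount_annual),
               tolerance = 1e-12)
  p0 <- p
  for (g in c("dfs_on", "dfs_off", "mbc"))
    for (k in names(p0$utilities[[g]])) p0$utilities[[g]][[k]] <- 0
  expect_equal(qalys(tr, p0), 0)
})

test_that("a year in the metastatic state accrues its age-band utility", {
  p <- zero_hazard_params(12L)
  p$settings$discount_annual <- 0
  s <- numeric(87); s[27] <- 1
  tr <- run_cohort(s, p, 12)
  expect_equal(qalys(tr, p), 0.7044)   # age 44, band 40-49
  # pooled utilities ignore the age band
  p$utilities$age_adjusted <- FALSE
  expect_equal(qalys(tr, p), 0.6813)
})

test_that("cost accrual: one-offs, monthly streams, perspectives", {
  # cohort dead from the start: only the one-off costs remain
  p <- quick_params(24L)
  dead <- numeric(87); dead[87] <- 1
  tr_dead <- run_cohort(dead, p, 24)
  cs <- p$costs$healthcare_sector
  expect_equal(accrue_costs(tr_dead, p, "healthcare_sector", "screening"),
               cs$diagnosis + cs$cbe_per_person / p$costs$detection_rate)
  expect_equal(accrue_costs(tr_dead, p, "healthcare_sector", "no_screening"),
               cs$diagnosis)
  # 12 undiscounted months fully on targeted therapy
  p12 <- zero_hazard_params(12L)
  p12$settings$discount_annual <- 0
  for (persp in c("patient", "public_payer", "healthcare_sector"))
    p12$costs[[persp]]$diagnosis <- 0
  tr_on <- flat_trace(1, 12)
  expect_equal(accrue_costs(tr_on, p12, "healthcare_sector", "no_screening"),
               12 * 84.7)
  expect_error(accrue_costs(tr_on, p12, "societal", "no_screening"))
  # perspective additivity on a real trace
  p240 <- quick_params(240L)
  tr <- run_cohort(make_start(p240, "screening"), p240)
  for (sc in c("screening", "no_screening"))
    expect_equal(
      accrue_costs(tr, p240, "patient", sc) +
        accrue_costs(tr, p240, "public_payer", sc),
      accrue_costs(tr, p240, "healthcare_sector", sc),
      tolerance = 1e-9)
})

test_that("CBE cost per diagnosis divides by the detection rate", {
  expect_equal(cost_per_diagnosis(0.033, 0.0006), 55)
  expect_equal(cost_per_diagnosis(0.0066, 0.0006), 11)
  expect_equal(cost_per_diagnosis(0.0264, 0.0006), 44)
  expect_equal(cost_per_diagnosis(3.2, 1), 3.2)
  expect_error(cost_per_diagnosis(0.033, 0), "> 0")
})

test_that("ICER arithmetic, dominance and undefined cases", {
  ic <- compute_icer(list(ly = 14.5, qaly = 12.5, cost = 511.9),
                     list(ly = 13.2, qaly = 11.4, cost = 465.7))
  expect_equal(ic$icer_qaly, 46.2 / 1.1, tolerance = 1e-10)
  expect_false(ic$dominant)
  ic0 <- compute_icer(list(ly = 2, qaly = 2, cost = 5),
                      list(ly = 1, qaly = 1, cost = 5))
  expect_equal(ic0$icer_qaly, 0)
  icd <- compute_icer(list(ly = 2, qaly = 2, cost = 0),
                      list(ly = 1, qaly = 1, cost = 10))
  expect_true(icd$dominant)
  icu <- compute_icer(list(ly = 1, qaly = 1, cost = 9),
                      list(ly = 1, qaly = 1, cost = 5))
  expect_true(icu$undefined)
  expect_true(is.na(icu$icer_qaly))
})

test_that("currency conversion rounds half-up to whole dollars", {
  expect_equal(vnd_to_usd(41.0), 1801)
  expect_equal(vnd_to_usd(95.1), 4179)
  expect_equal(vnd_to_usd(0), 0)
  expect_equal(vnd_to_usd(-41.0), -1801)
  expect_error(vnd_to_usd(10, rate = 0), "> 0")
})

test_that("threshold classification follows the WHO bands", {
  expect_equal(classify_cost_effectiveness(54.2), "highly_cost_effective")
  expect_equal(classify_cost_effectiveness(95.1), "cost_effective")
  expect_equal(classify_cost_effectiveness(1000), "not_cost_effective")
  expect_equal(classify_cost_effectiveness(63.2), "highly_cost_effective")
  expect_error(classify_cost_effectiveness(50, c(189.6, 63.2)), "ordered")
})

test_that("null downstaging leaves only the screening one-off cost", {
  p <- quick_params(240L)
  p$start$dfs_noscreening <- p$start$dfs_screening
  cea <- run_cea(p)
  expect_equal(cea$incremental$delta_qaly, rep(0, 3))
  expect_equal(cea$incremental$delta_ly, rep(0, 3))
  cbe_oneoff <- vapply(
    c("patient", "public_payer", "healthcare_sector"),
    function(pp) p$costs[[pp]]$cbe_per_person / p$costs$detection_rate,
    numeric(1))
  expect_equal(cea$incremental$delta_cost_mvnd, unname(cbe_oneoff),
               tolerance = 1e-9)
  expect_true(all(is.na(cea$incremental$icer_qaly_mvnd)))
})

test_that("base-case structure: downstaging gain and ICER consistency", {
  p <- quick_params(360L)
  cea <- run_cea(p)
  # screening reduces the metastatic starting share by 9.1 points
  expect_equal(100 * (p$start$dfs_screening - p$start$dfs_noscreening), 9.1)
  expect_true(all(cea$incremental$delta_qaly > 0))
  expect_true(all(cea$incremental$delta_ly > 0))
  expect_equal(cea$incremental$icer_qaly_mvnd,
               cea$incremental$delta_cost_mvnd / cea$incremental$delta_qaly)
  expect_equal(cea$incremental$icer_qaly_usd,
               vnd_to_usd(cea$incremental$icer_qaly_mvnd))
  # QALY gain holds across randomized shared parameters
  for (seed in 21:23) {
    pr <- random_params(seed)
    pr$settings$horizon_months <- 240L
    inc <- run_cea(pr, "public_payer")$incremental
    expect_gt(inc$delta_qaly, 0)
  }
})

test_that("ICER responds to detection rate and additive constants", {
  p <- quick_params(360L)
  base <- run_cea(p, "public_payer")
  # higher detection rate: cheaper screening arm, lower ICER
  up <- run_cea(param_set(p, "costs.detection_rate", 0.0012), "public_payer")
  expect_lt(up$summary$cost_mvnd[up$summary$scenario == "screening"],
            base$summary$cost_mvnd[base$summary$scenario == "screening"])
  expect_lt(up$incremental$icer_qaly_mvnd, base$incremental$icer_qaly_mvnd)
  # an additive one-off charged to both arms cancels out of the ICER
  shift <- param_set(p, "costs.public_payer.diagnosis",
                     p$costs$public_payer$diagnosis + 10)
  expect_equal(run_cea(shift, "public_payer",
                       validate = FALSE)$incremental$icer_qaly_mvnd,
               base$incremental$icer_qaly_mvnd, tolerance = 1e-12)
})
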
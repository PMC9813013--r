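test_that("parameter paths resolve and reject unknowns", {
  p <- default_parameters()
  expect_equal(param_get(p, "costs.detection_rate"), 0.0006)
  expect_equal(param_get(p, "utilities.mbc.a40_49"), 0.7044)
  p2 <- param_set(p, "dfs.mbc_split", 0.5)
  expect_equal(p2$dfs$mbc_split, 0.5)
  expect_s3_class(p2$dfs, "dfs_curve")      # class survives path assignment
  expect_error(param_get(p, "costs.unknown_thing"),
               "unknown parameter path: 'costs.unknown_thing'")
  expect_error(param_set(p, "no.such.key", 1), "unknown parameter path")
})

test_that("empty configuration reproduces the defaults", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines("", cfg)
  loaded <- load_config(cfg)
  expect_equal(as_cfg <- cbecea:::as_config_list(loaded$params),
               cbecea:::as_config_list(default_parameters()),
               tolerance = 1e-12)
  expect_equal(loaded$run$psa_iterations, 2000L)
  unlink(cfg)
})

test_that("overrides are applied and unknown keys are named", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("costs:",
               "  detection_rate: 0.0004",
               "settings:",
               "  horizon_months: 360",
               "run:",
               "  seed: 7"), cfg)
  loaded <- load_config(cfg)
  expect_equal(loaded$params$costs$detection_rate, 0.0004)
  expect_equal(loaded$params$settings$horizon_months, 360L)
  expect_equal(loaded$run$seed, 7)
  writeLines(c("costs:", "  detectoin_rate: 0.0004"), cfg)
  expect_error(load_config(cfg),
               "unknown configuration key: 'costs.detectoin_rate'")
  writeLines("not: a_real_key", cfg)
  expect_error(load_config(cfg), "unknown configuration key: 'not'")
  unlink(cfg)
  expect_error(load_config("/nonexistent/conf.yaml"), "not found")
})

test_that("configuration round-trips through serialisation", {
  p <- default_parameters()
  p$dfs$log_cov <- matrix(c(4e-4, 1e-5, 1e-5, 9e-4), 2)
  f1 <- tempfile(fileext = ".yaml")
  save_config(p, f1)
  p2 <- load_config(f1)$params
  expect_equal(cbecea:::as_config_list(p2), cbecea:::as_config_list(p),
               tolerance = 1e-10)
  # a second pass is the identity
  f2 <- tempfile(fileext = ".yaml")
  save_config(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("delimited life-table and event inputs round-trip", {
  lt <- make_life_table()
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(lt), f, row.names = FALSE)
  lt2 <- read_life_table(f)
  expect_equal(lt2$q_annual, lt$q_annual)
  ev <- make_dfs_events(100, seed = 3)
  utils::write.csv(ev, f, row.names = FALSE)
  ev2 <- read_dfs_events(f)
  expect_equal(ev2$time_months, ev$time_months)
  expect_equal(ev2$type, ev$type)
  # life table can be supplied through the config
  cfg <- tempfile(fileext = ".yaml")
  utils::write.csv(data.frame(age = 0:100, q_annual = rep(0.01, 101)), f,
                   row.names = FALSE)
  writeLines(sprintf("life_table_file: %s", f), cfg)
  loaded <- load_config(cfg)
  expect_equal(loaded$params$life_table$q_annual, rep(0.01, 101))
  unlink(c(f, cfg))
})

test_that("output tables are written, parse back, and are deterministic", {
  p <- quick_params(120L)
  cea <- run_cea(p)
  tt <- run_dsa(p, ranges = data.frame(path = "costs.detection_rate",
                                       low = 0.0004, high = 0.0008),
                perspective = "public_payer")
  psa <- run_psa(p, "public_payer", n_iterations = 5, seed = 21)
  d1 <- file.path(tempdir(), "out1"); d2 <- file.path(tempdir(), "out2")
  write_outputs(cea, d1, dsa = tt, psa = psa, seed = 21)
  write_outputs(cea, d2, dsa = tt, psa = psa, seed = 21)
  expected <- c("cea_summary.csv", "trace_screening.csv",
                "trace_no_screening.csv", "tornado.csv",
                "psa_iterations.csv", "ce_plane.csv", "ceac.csv",
                "run_metadata.yaml")
  expect_true(all(file.exists(file.path(d1, expected))))
  summ <- utils::read.csv(file.path(d1, "cea_summary.csv"))
  expect_equal(sort(unique(summ$perspective)),
               c("healthcare_sector", "patient", "public_payer"))
  expect_equal(nrow(utils::read.csv(file.path(d1, "psa_iterations.csv"))), 5)
  tr <- utils::read.csv(file.path(d1, "trace_screening.csv"),
                        check.names = FALSE)
  expect_equal(dim(tr), c(121L, 88L))   # cycle column + 87 states
  # numeric tables are byte-identical across reruns
  for (f in expected[expected != "run_metadata.yaml"])
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  meta <- yaml::read_yaml(file.path(d1, "run_metadata.yaml"))
  expect_equal(meta$seed, 21)
  expect_match(meta$config_hash, "^[0-9a-f]{32}$")
  unlink(c(d1, d2), recursive = TRUE)
})
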
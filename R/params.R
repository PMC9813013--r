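# Model parameters: the single source of truth for both scenarios.
# All monetary values are in million VND; time unit is the monthly cycle.

#' Default model parameters
#'
#' The packaged base case: starting probabilities (downstaging effect of CBE
#' screening), cure adjustment, remission progression, metastatic mortality
#' schedule, cost inputs per perspective, utilities by state group and age
#' band, and analysis settings (start age 44, 1.5% annual discounting,
#' lifetime horizon to age 100, WHO willingness-to-pay thresholds for
#' Vietnam). The background life table and the disease-free-survival curve
#' are synthetic stand-ins with realistic magnitudes (see
#' [make_life_table()]); all other values are published point estimates.
#'
#' Monetary values are million VND throughout; USD is derived only at
#' reporting time at 22,759 VND per USD.
#'
#' @return An object of class `cea_params` (a nested list).
#' @examples
#' p <- default_parameters()
#' p$start$dfs_screening                 # 0.924
#' p$costs$healthcare_sector$targeted_monthly  # 84.7
#' @export
default_parameters <- function() {
  params <- list(
    settings = list(
      start_age = 44,
      discount_annual = 0.015,
      horizon_months = 672L,      # to cohort age 100
      exchange_rate = 22759,      # VND per USD
      threshold_highly = 63.2,    # million VND per QALY (1x GDP per capita)
      threshold_ce = 189.6        # 3x GDP per capita
    ),
    start = list(
      dfs_screening = 0.924,
      dfs_noscreening = 0.833
    ),
    dfs = dfs_curve("weibull", shape = 0.9, scale = 380,
                    cure_threshold = 120, max_cure_rate = 0.95,
                    mbc_split = 0.72, cure_ramp = "linear"),
    transitions = list(
      remission_to_mbc = 0.0076,
      mbc_mortality = list(y1 = 0.0324, y2 = 0.0446, y3 = 0.0492,
                           y4 = 0.0511, y5plus = 0.0541)
    ),
    life_table = make_life_table(),
    costs = list(
      detection_rate = 0.0006,   # diagnostic-positive proportion of CBE
      patient = list(
        cbe_per_person = 0.0066, diagnosis = 2.76,
        chemo_monthly = 9.14, targeted_monthly = 50.3,
        followup_monthly = 0.58, mbc_targeted_monthly = 15.1,
        mbc_supportive_monthly = 1.23),
      public_payer = list(
        cbe_per_person = 0.0264, diagnosis = 0.79,
        chemo_monthly = 5.67, targeted_monthly = 34.4,
        followup_monthly = 0.14, mbc_targeted_monthly = 10.3,
        mbc_supportive_monthly = 0.24),
      healthcare_sector = list(
        cbe_per_person = 0.033, diagnosis = 3.55,
        chemo_monthly = 14.81, targeted_monthly = 84.7,
        followup_monthly = 0.72, mbc_targeted_monthly = 25.4,
        mbc_supportive_monthly = 1.47)
    ),
    utilities = list(
      age_adjusted = TRUE,
      dfs_on = list(pooled = 0.7662, under40 = 0.8182, a40_49 = 0.7922,
                    a50_59 = 0.6900, a60plus = 0.6946),
      dfs_off = list(pooled = 0.8545, under40 = 0.9229, a40_49 = 0.8663,
                     a50_59 = 0.8647, a60plus = 0.7729),
      mbc = list(pooled = 0.6813, under40 = 0.7275, a40_49 = 0.7044,
                 a50_59 = 0.6135, a60plus = 0.6176)
    ),
    mix = list(
      dfs_targeted = 1.0,  # early-stage patients opt for targeted therapy
      mbc_targeted = 0.0   # metastatic patients choose chemotherapy only
    )
  )
  class(params) <- c("cea_params", "list")
  validate_params(params)
  params
}

#' Validate a parameter set
#'
#' Checks every type invariant: probabilities and utilities in \[0, 1\],
#' positive curve parameters, ordered thresholds, contiguous life table,
#' non-negative costs, and (optionally) exact perspective additivity of the
#' cost inputs (patient + public payer = healthcare sector, component-wise).
#'
#' @param params a `cea_params` object.
#' @param check_additivity check the perspective-additivity identity (on by
#'   default; relaxed internally during one-way sensitivity perturbations of
#'   a single perspective's cost input).
#' @return `params`, invisibly; errors name the offending field.
#' @export
validate_params <- function(params, check_additivity = TRUE) {
  chk01 <- function(x, what) {
    if (any(unlist(x) < 0 | unlist(x) > 1))
      stop(sprintf("'%s' must be in [0, 1]", what))
  }
  s <- params$settings
  if (s$discount_annual < 0) stop("'settings.discount_annual' must be >= 0")
  if (s$horizon_months < 1) stop("'settings.horizon_months' must be >= 1")
  if (s$exchange_rate <= 0) stop("'settings.exchange_rate' must be > 0")
  if (s$threshold_highly > s$threshold_ce)
    stop("willingness-to-pay thresholds must be ordered")
  chk01(params$start, "start")
  if (!inherits(params$dfs, "dfs_curve")) stop("'dfs' must be a dfs_curve")
  chk01(params$transitions$remission_to_mbc, "transitions.remission_to_mbc")
  chk01(params$transitions$mbc_mortality, "transitions.mbc_mortality")
  if (length(params$transitions$mbc_mortality) != 5)
    stop("'transitions.mbc_mortality' needs 5 yearly values (y1..y5plus)")
  if (!inherits(params$life_table, "life_table"))
    stop("'life_table' must be a life_table")
  dr <- params$costs$detection_rate
  if (dr <= 0 || dr > 1) stop("'costs.detection_rate' must be in (0, 1]")
  for (p in c("patient", "public_payer", "healthcare_sector")) {
    cc <- unlist(params$costs[[p]])
    if (any(cc < 0)) stop(sprintf("'costs.%s' must be non-negative", p))
  }
  if (check_additivity) {
    for (comp in names(params$costs$patient)) {
      d <- params$costs$patient[[comp]] + params$costs$public_payer[[comp]] -
        params$costs$healthcare_sector[[comp]]
      if (abs(d) > 1e-9)
        stop(sprintf(
          "cost input '%s': patient + public payer != healthcare sector", comp))
    }
  }
  for (g in c("dfs_on", "dfs_off", "mbc"))
    chk01(params$utilities[[g]], paste0("utilities.", g))
  chk01(params$mix, "mix")
  invisible(params)
}

#' Get a parameter by dot-addressed path
#'
#' @param params a `cea_params` object.
#' @param path e.g. `"costs.detection_rate"` or `"dfs.mbc_split"`.
#' @return The value at the path; unknown paths are an error naming the path.
#' @export
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || !(k %in% names(node)))
      stop(sprintf("unknown parameter path: '%s'", path))
    node <- node[[k]]
  }
  node
}

#' Set a parameter by dot-addressed path
#'
#' @inheritParams param_get
#' @param value replacement value.
#' @return The modified parameter set (classes preserved).
#' @export
param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  param_get(params, path)  # errors on unknown path
  set_rec <- function(node, keys, value) {
    if (length(keys) == 1) {
      node[[keys]] <- value
    } else {
      node[[keys[1]]] <- set_rec(node[[keys[1]]], keys[-1], value)
    }
    node
  }
  set_rec(params, keys, value)
}

# ---- configuration files ----------------------------------------------------

as_config_list <- function(params) {
  out <- unclass(params)
  out$dfs <- unclass(out$dfs)
  out$dfs <- out$dfs[!vapply(out$dfs, is.null, logical(1))]
  if (!is.null(out$dfs$log_cov))
    out$dfs$log_cov <- lapply(seq_len(nrow(out$dfs$log_cov)),
                              function(i) as.numeric(out$dfs$log_cov[i, ]))
  out$life_table <- list(age = as.integer(params$life_table$age),
                         q_annual = as.numeric(params$life_table$q_annual))
  out
}

config_to_params <- function(lst) {
  d <- lst$dfs
  lst$dfs <- dfs_curve(family = d$family, shape = d$shape, scale = d$scale,
                       rate = d$rate, cure_threshold = d$cure_threshold,
                       max_cure_rate = d$max_cure_rate,
                       mbc_split = d$mbc_split, cure_ramp = d$cure_ramp,
                       log_cov = if (!is.null(d$log_cov))
                         do.call(rbind, d$log_cov))
  lst$life_table <- life_table(lst$life_table$age, lst$life_table$q_annual)
  lst$settings$horizon_months <- as.integer(round(lst$settings$horizon_months))
  class(lst) <- c("cea_params", "list")
  lst
}

merge_config <- function(base, cfg, prefix = "") {
  for (nm in names(cfg)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (!(nm %in% names(base))) {
      # optional slots absent from the default schema when unset
      if (full != "dfs.log_cov")
        stop(sprintf("unknown configuration key: '%s'", full))
      base[[nm]] <- cfg[[nm]]
      next
    }
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], cfg[[nm]], full)
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' Load a model configuration
#'
#' Reads a YAML configuration, merges it over the packaged defaults (every key
#' must exist in the default schema; unknown keys are an error naming the
#' key), re-validates all invariants, and returns the parameters together with
#' run settings. Two convenience keys are handled specially: `life_table_file`
#' (path to a two-column CSV of age and annual death probability, resolved
#' relative to the config file) replaces the life table, and a top-level `run`
#' block (`seed`, `out_dir`, `perspective`, `psa_iterations`) carries run
#' options that are not model parameters.
#'
#' @param path path to a YAML file.
#' @param base parameter set the config is merged onto
#'   (default [default_parameters()]).
#' @return A list with elements `params` (a validated `cea_params`) and `run`.
#' @export
load_config <- function(path, base = default_parameters()) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  run <- list(seed = NULL, out_dir = NULL, perspective = "public_payer",
              psa_iterations = 2000L)
  if (!is.null(cfg$run)) {
    run <- merge_config(run, cfg$run, "run")
    cfg$run <- NULL
  }
  if (!is.null(cfg$life_table_file)) {
    lt_path <- cfg$life_table_file
    if (!file.exists(lt_path))
      lt_path <- file.path(dirname(path), cfg$life_table_file)
    base$life_table <- read_life_table(lt_path)
    cfg$life_table_file <- NULL
  }
  merged <- merge_config(as_config_list(base), cfg)
  params <- config_to_params(merged)
  validate_params(params)
  list(params = params, run = run)
}

#' Save a model configuration
#'
#' Serialises a parameter set to YAML such that [load_config()] restores it
#' (round-trip identity up to floating-point formatting).
#'
#' @param params a `cea_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  yaml::write_yaml(as_config_list(params), path, precision = 15)
  invisible(path)
}

#' Read a life table from a delimited file
#'
#' @param path CSV with columns `age` (integer years) and `q_annual`.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "q_annual") %in% names(df)))
    stop("life-table file needs columns 'age' and 'q_annual'")
  life_table(df$age, df$q_annual)
}

#' Read a DFS event table from a delimited file
#'
#' @param path CSV with columns `time_months`, `event` (0/1) and `type`
#'   (`nm`, `mbc` or `na`).
#' @return A data frame suitable for [fit_dfs_curve()].
#' @export
read_dfs_events <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_months", "event", "type")
  if (!all(need %in% names(df)))
    stop("event file needs columns 'time_months', 'event', 'type'")
  df
}
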
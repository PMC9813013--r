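# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis (CE plane, CEAC).

#' Default one-way sensitivity ranges
#'
#' Ranges follow the published convention: the 95% confidence interval where
#' one is reported (starting probability without screening, recurrence split,
#' remission progression, cure threshold, maximum cure rate, discount rate
#' 0-3.5%, horizon 30-60 years), otherwise +/- 20% of the base case (costs,
#' detection rate, start age).
#'
#' @param params model parameters.
#' @param perspective whose cost inputs to vary.
#' @return Data frame with columns `path`, `low`, `high`, `provenance`.
#' @export
default_dsa_ranges <- function(params, perspective = "public_payer") {
  perspective <- match.arg(perspective, PERSPECTIVES)
  pm20 <- function(path) {
    b <- param_get(params, path)
    data.frame(path = path, low = 0.8 * b, high = 1.2 * b,
               provenance = "pm20", stringsAsFactors = FALSE)
  }
  ci <- function(path, low, high) {
    data.frame(path = path, low = low, high = high, provenance = "ci95",
               stringsAsFactors = FALSE)
  }
  cost_paths <- paste0("costs.", perspective, ".",
                       c("cbe_per_person", "diagnosis", "chemo_monthly",
                         "targeted_monthly", "followup_monthly",
                         "mbc_targeted_monthly", "mbc_supportive_monthly"))
  out <- rbind(
    ci("start.dfs_noscreening", 0.724, 0.874),
    ci("dfs.mbc_split", 0.576, 0.864),
    ci("dfs.cure_threshold", 96, 180),
    ci("dfs.max_cure_rate", 0, 1),
    ci("transitions.remission_to_mbc", 0.0061, 0.0091),
    ci("settings.discount_annual", 0, 0.035),
    ci("settings.horizon_months", 360, 720),
    pm20("settings.start_age"),
    pm20("costs.detection_rate"),
    do.call(rbind, lapply(cost_paths, pm20)))
  bad <- out$low > out$high
  if (any(bad)) stop("invalid DSA range (low > high)")
  out
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the cost-effectiveness analysis with each parameter set to its low
#' and high value in turn (all others at base), records the ICER per QALY at
#' both ends, and sorts the tornado table by bar width (descending, ties
#' broken by parameter path).
#'
#' @param params base-case parameters.
#' @param ranges data frame as from [default_dsa_ranges()]; the base value
#'   must lie within each range.
#' @param perspective perspective whose ICER is tabulated.
#' @return A `tornado_table` data frame (`path`, `low`, `high`, `icer_low`,
#'   `icer_high`, `width`) with the base-case ICER as attribute `base_icer`.
#' @export
run_dsa <- function(params, ranges = default_dsa_ranges(params, perspective),
                    perspective = "public_payer") {
  perspective <- match.arg(perspective, PERSPECTIVES)
  icer_at <- function(p) {
    run_cea(p, perspectives = perspective,
            validate = FALSE)$incremental$icer_qaly_mvnd
  }
  base_icer <- icer_at(params)
  rows <- lapply(seq_len(nrow(ranges)), function(k) {
    path <- ranges$path[k]
    base <- param_get(params, path)
    lo <- ranges$low[k]; hi <- ranges$high[k]
    if (base < lo - 1e-12 || base > hi + 1e-12)
      stop(sprintf("base value of '%s' outside its DSA range", path))
    if (path == "settings.horizon_months") { lo <- as.integer(round(lo))
                                             hi <- as.integer(round(hi)) }
    data.frame(path = path, low = lo, high = hi,
               icer_low = icer_at(param_set(params, path, lo)),
               icer_high = icer_at(param_set(params, path, hi)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(path = character(), low = numeric(), high = numeric(),
                      icer_low = numeric(), icer_high = numeric(),
                      width = numeric(), stringsAsFactors = FALSE)
  else
    out$width <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$width, out$path), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_icer = base_icer, perspective = perspective,
            class = c("tornado_table", "data.frame"))
}

#' Fit a beta distribution to a mean and 95% interval
#'
#' Matches the mean exactly (the shape parameters are `mean * nu` and
#' `(1 - mean) * nu`) and chooses the concentration `nu` minimising the
#' squared distance of the 2.5% and 97.5% quantiles from the target interval.
#'
#' @param mean target mean in (0, 1).
#' @param ci_low,ci_high target 95% interval bounds, in (0, 1), bracketing
#'   the mean.
#' @return List with `shape1`, `shape2`, `mean`, `ci_fit` (achieved
#'   quantiles).
#' @export
fit_beta <- function(mean, ci_low, ci_high) {
  if (mean <= 0 || mean >= 1) stop("'mean' must be in (0, 1)")
  if (ci_low <= 0 || ci_high >= 1 || ci_low > ci_high)
    stop("interval bounds must be in (0, 1) with ci_low <= ci_high")
  if (ci_low > mean || ci_high < mean)
    stop("interval must bracket the mean")
  obj <- function(lnu) {
    nu <- exp(lnu)
    (stats::qbeta(0.025, mean * nu, (1 - mean) * nu) - ci_low)^2 +
      (stats::qbeta(0.975, mean * nu, (1 - mean) * nu) - ci_high)^2
  }
  lnu <- stats::optimize(obj, c(-4, 20))$minimum
  nu <- exp(lnu)
  a <- mean * nu; b <- (1 - mean) * nu
  list(shape1 = a, shape2 = b, mean = a / (a + b),
       ci_fit = stats::qbeta(c(0.025, 0.975), a, b))
}

#' Fit a log-normal distribution to a mean and 95% interval
#'
#' Matches the arithmetic mean exactly (`mu = log(mean) - sigma^2 / 2`) and
#' chooses `sigma` minimising the squared quantile distance from the target
#' interval. A degenerate interval collapses to near-zero dispersion.
#'
#' @param mean target arithmetic mean (> 0).
#' @param ci_low,ci_high target 95% interval bounds (> 0).
#' @return List with `meanlog`, `sdlog`, `mean`, `ci_fit`.
#' @export
fit_lognormal <- function(mean, ci_low, ci_high) {
  if (mean <= 0 || ci_low <= 0 || ci_high <= 0)
    stop("all inputs must be positive")
  if (ci_low > ci_high) stop("'ci_low' must be <= 'ci_high'")
  obj <- function(sigma) {
    mu <- log(mean) - sigma^2 / 2
    (stats::qlnorm(0.025, mu, sigma) - ci_low)^2 +
      (stats::qlnorm(0.975, mu, sigma) - ci_high)^2
  }
  sigma <- stats::optimize(obj, c(1e-8, 3))$minimum
  mu <- log(mean) - sigma^2 / 2
  list(meanlog = mu, sdlog = sigma, mean = exp(mu + sigma^2 / 2),
       ci_fit = stats::qlnorm(c(0.025, 0.975), mu, sigma))
}

#' Default PSA parameter distributions
#'
#' Probabilities and utilities get beta distributions, costs log-normal, and
#' the DFS curve parameters a multivariate normal on the log scale (the
#' fitted covariance when the curve carries one, otherwise a diagonal with
#' 10% coefficients of variation). Hyperparameters are calibrated to the
#' base-case mean and the one-way range (95% CI where reported, otherwise the
#' +/- 20% endpoints treated as a 95% interval; utility upper bounds are
#' capped below 1). The starting probabilities are coupled: the no-screening
#' baseline is drawn from its beta and the screening start moves with it,
#' preserving the base-case downstaging reduction.
#'
#' @param params model parameters.
#' @param perspective whose cost inputs to draw.
#' @return List of distribution specifications consumed by [run_psa()].
#' @export
default_psa_distributions <- function(params, perspective = "public_payer") {
  perspective <- match.arg(perspective, PERSPECTIVES)
  dists <- list()
  add_beta <- function(dists, path, lo = NULL, hi = NULL) {
    m <- param_get(params, path)
    if (is.null(lo)) { lo <- 0.8 * m; hi <- min(1.2 * m, 0.99) }
    f <- fit_beta(m, lo, hi)
    c(dists, list(list(path = path, family = "beta",
                       shape1 = f$shape1, shape2 = f$shape2)))
  }
  add_lnorm <- function(dists, path) {
    m <- param_get(params, path)
    if (m <= 0) return(dists)   # zero-cost component: keep degenerate
    f <- fit_lognormal(m, 0.8 * m, 1.2 * m)
    c(dists, list(list(path = path, family = "lognormal",
                       meanlog = f$meanlog, sdlog = f$sdlog)))
  }
  # The downstaging premise couples the two starting probabilities: the PSA
  # draws the no-screening baseline and shifts the screening start with it,
  # preserving the base-case downstaging reduction (the intervention effect,
  # for which no dispersion is reported). Drawing the baseline independently
  # of a fixed screening start would let tail draws reverse the downstaging
  # sign, contradicting the premise that the same population is modelled in
  # both scenarios.
  f_start <- fit_beta(param_get(params, "start.dfs_noscreening"),
                      0.724, 0.874)
  dists <- c(dists, list(list(
    path = "start.dfs_noscreening", family = "start_downstage",
    shape1 = f_start$shape1, shape2 = f_start$shape2,
    reduction = param_get(params, "start.dfs_screening") -
      param_get(params, "start.dfs_noscreening"))))
  dists <- add_beta(dists, "dfs.mbc_split", 0.576, 0.864)
  dists <- add_beta(dists, "transitions.remission_to_mbc", 0.0061, 0.0091)
  for (y in c("y1", "y2", "y3", "y4", "y5plus"))
    dists <- add_beta(dists, paste0("transitions.mbc_mortality.", y))
  dists <- add_beta(dists, "costs.detection_rate")
  for (g in c("dfs_on", "dfs_off", "mbc"))
    for (b in c("pooled", "under40", "a40_49", "a50_59", "a60plus"))
      dists <- add_beta(dists, paste0("utilities.", g, ".", b))
  for (comp in c("cbe_per_person", "diagnosis", "chemo_monthly",
                 "targeted_monthly", "followup_monthly",
                 "mbc_targeted_monthly", "mbc_supportive_monthly"))
    dists <- add_lnorm(dists, paste0("costs.", perspective, ".", comp))
  curve <- params$dfs
  if (curve$family == "weibull") {
    mean_log <- log(c(curve$shape, curve$scale))
    cov <- if (!is.null(curve$log_cov)) curve$log_cov else diag(0.1^2, 2)
    dists <- c(dists, list(list(path = "dfs", family = "mvnorm_log",
                                mean = mean_log, cov = cov)))
  } else {
    mean_log <- log(curve$rate)
    cov <- if (!is.null(curve$log_cov)) curve$log_cov
           else matrix(0.1^2, 1, 1)
    dists <- c(dists, list(list(path = "dfs", family = "mvnorm_log",
                                mean = mean_log, cov = cov)))
  }
  dists
}

# one joint parameter draw
draw_psa_params <- function(params, dists) {
  for (d in dists) {
    if (d$family == "beta") {
      params <- param_set(params, d$path,
                          stats::rbeta(1, d$shape1, d$shape2))
    } else if (d$family == "start_downstage") {
      b <- stats::rbeta(1, d$shape1, d$shape2)
      params <- param_set(params, "start.dfs_noscreening", b)
      params <- param_set(params, "start.dfs_screening",
                          min(b + d$reduction, 1))
    } else if (d$family == "lognormal") {
      params <- param_set(params, d$path,
                          stats::rlnorm(1, d$meanlog, d$sdlog))
    } else if (d$family == "mvnorm_log") {
      z <- exp(MASS::mvrnorm(1, mu = d$mean, Sigma = d$cov))
      if (params$dfs$family == "weibull") {
        params$dfs$shape <- z[1]
        params$dfs$scale <- z[2]
      } else {
        params$dfs$rate <- z[1]
      }
    } else stop(sprintf("unknown PSA distribution family '%s'", d$family))
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters jointly (independently across parameter blocks, with
#' the DFS curve's two parameters correlated through their log-scale
#' covariance), reruns the cost-effectiveness analysis per draw, and collects
#' the per-iteration incremental cost and effect pairs. Reproducible given
#' the seed; draws are within-support by construction.
#'
#' @param params base-case parameters.
#' @param perspective cost perspective analysed.
#' @param n_iterations number of Monte Carlo iterations (default 2000).
#' @param seed RNG seed (mandatory).
#' @param distributions list of distribution specs (default
#'   [default_psa_distributions()]); an empty list makes every iteration the
#'   deterministic base case.
#' @return A `psa_result`: list with `iterations` (data frame of
#'   `delta_cost_mvnd`, `delta_qaly`, `delta_ly`), `n_iterations`, `seed`,
#'   `perspective`, `thresholds` and the deterministic `base` incremental row.
#' @export
run_psa <- function(params, perspective = "public_payer",
                    n_iterations = 2000, seed,
                    distributions = NULL) {
  perspective <- match.arg(perspective, PERSPECTIVES)
  if (missing(seed)) stop("'seed' is required")
  if (n_iterations < 1) stop("'n_iterations' must be >= 1")
  if (is.null(distributions))
    distributions <- default_psa_distributions(params, perspective)
  base <- run_cea(params, perspectives = perspective)$incremental
  set.seed(seed)
  dc <- dq <- dl <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    p_it <- draw_psa_params(params, distributions)
    inc <- run_cea(p_it, perspectives = perspective,
                   validate = FALSE)$incremental
    dc[it] <- inc$delta_cost_mvnd
    dq[it] <- inc$delta_qaly
    dl[it] <- inc$delta_ly
  }
  structure(list(iterations = data.frame(iteration = seq_len(n_iterations),
                                         delta_cost_mvnd = dc,
                                         delta_qaly = dq, delta_ly = dl),
                 n_iterations = n_iterations, seed = seed,
                 perspective = perspective,
                 thresholds = c(params$settings$threshold_highly,
                                params$settings$threshold_ce),
                 base = base),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  it <- x$iterations
  cat(sprintf(
    "PSA (%s perspective): %d iterations, seed %s\n", x$perspective,
    x$n_iterations, x$seed))
  cat(sprintf("  mean dCost %.1f mVND, mean dQALY %.3f\n",
              mean(it$delta_cost_mvnd), mean(it$delta_qaly)))
  cat(sprintf("  northeast quadrant: %.1f%% of iterations\n",
              100 * mean(it$delta_cost_mvnd > 0 & it$delta_qaly > 0)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that screening is
#' cost-effective: the fraction of PSA iterations with positive net monetary
#' benefit `wtp * dQALY - dCost` (strictly positive; ties count as not
#' cost-effective).
#'
#' @param psa a `psa_result`.
#' @param wtp_grid willingness-to-pay grid, million VND per QALY.
#' @return Data frame with columns `wtp_mvnd` and `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 400, by = 2)) {
  stopifnot(inherits(psa, "psa_result"))
  it <- psa$iterations
  if (nrow(it) == 0) stop("PSA has no iterations")
  prob <- vapply(wtp_grid, function(l)
    mean(l * it$delta_qaly - it$delta_cost_mvnd > 0), numeric(1))
  data.frame(wtp_mvnd = wtp_grid, prob_cost_effective = prob)
}

#' Cost-effectiveness plane export
#'
#' One row per PSA iteration (`delta_qaly`, `delta_cost_mvnd`) with quadrant
#' classification; the willingness-to-pay threshold slopes are attached as
#' attribute `thresholds` for plotting.
#'
#' @param psa a `psa_result`.
#' @return Data frame with attribute `thresholds`.
#' @export
ce_plane_export <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  it <- psa$iterations
  if (nrow(it) == 0) stop("PSA has no iterations")
  quadrant <- ifelse(it$delta_qaly > 0,
                     ifelse(it$delta_cost_mvnd > 0, "NE", "SE"),
                     ifelse(it$delta_cost_mvnd > 0, "NW", "SW"))
  out <- data.frame(iteration = it$iteration, delta_qaly = it$delta_qaly,
                    delta_cost_mvnd = it$delta_cost_mvnd,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- psa$thresholds
  out
}
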
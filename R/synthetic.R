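# Synthetic fixtures standing in for inputs that are not publicly deposited:
# a background life table and censored DFS event data, plus the parametric
# curve fitter that turns event data into a model input.

#' Generate a synthetic life table
#'
#' Deterministic Gompertz-Makeham life table: annual hazard
#' `h(a) = makeham + baseline * exp(slope * a)`, integrated in closed form
#' over each year of age to give `q_annual = 1 - exp(-H(a))`. The defaults
#' emulate the magnitude and exponential rise of adult female mortality in
#' Vietnam (q(44) about 1.2e-3, q(80) about 3e-2); this is a synthetic
#' stand-in, not a published national life table, and users can load a real
#' one with [read_life_table()].
#'
#' @param makeham age-independent annual hazard component.
#' @param baseline Gompertz baseline hazard at age 0.
#' @param slope Gompertz log-hazard slope per year of age.
#' @param ages integer ages covered (default 0:100).
#' @return A [life_table()].
#' @export
make_life_table <- function(makeham = 4e-4, baseline = 1e-5, slope = 0.1,
                            ages = 0:100) {
  if (baseline < 0 || makeham < 0) stop("hazard components must be >= 0")
  cumhaz <- if (slope == 0) rep(makeham + baseline, length(ages))
            else makeham + (baseline / slope) * exp(slope * ages) * expm1(slope)
  life_table(ages, 1 - exp(-cumhaz))
}

#' Generate synthetic DFS event data
#'
#' Draws individual disease-free-survival times from a known Weibull,
#' censors them independently (censoring times exponential with the given
#' monthly probability, the simplest mechanism consistent with the fitter's
#' assumptions), and assigns each observed event a type: metastatic with the
#' configured probability (0.72 in the base case), non-metastatic otherwise.
#' Deterministic given the seed.
#'
#' @param n cohort size (>= 10).
#' @param shape,scale true Weibull parameters (months).
#' @param censor_rate monthly censoring probability in \[0, 1\].
#' @param mbc_split probability an event is metastatic.
#' @param seed RNG seed (mandatory).
#' @return Data frame with columns `time_months`, `event` (0/1), `type`
#'   (`"nm"`, `"mbc"`, `"na"`).
#' @export
make_dfs_events <- function(n, shape = 0.9, scale = 380,
                            censor_rate = 0.0012, mbc_split = 0.72, seed) {
  if (n < 10) stop("'n' must be >= 10")
  if (missing(seed)) stop("'seed' is required")
  if (censor_rate < 0 || censor_rate > 1)
    stop("'censor_rate' must be in [0, 1]")
  set.seed(seed)
  t_event <- stats::rweibull(n, shape = shape, scale = scale)
  t_cens <- if (censor_rate >= 1) rep(0, n)
            else if (censor_rate == 0) rep(Inf, n)
            else stats::rexp(n, rate = -log1p(-censor_rate))
  event <- as.integer(t_event <= t_cens)
  type <- rep("na", n)
  ev <- event == 1L
  type[ev] <- ifelse(stats::runif(sum(ev)) < mbc_split, "mbc", "nm")
  data.frame(time_months = pmin(t_event, t_cens), event = event,
             type = type, stringsAsFactors = FALSE)
}

#' Fit a parametric DFS curve to censored event data
#'
#' Maximum-likelihood fit under right censoring via
#' [flexsurv::flexsurvreg()]. The estimated covariance of the log-scale
#' parameters is stored on the returned curve and feeds the multivariate
#' normal block of the probabilistic sensitivity analysis.
#'
#' @param events data frame with `time_months` and `event` (0/1), e.g. from
#'   [make_dfs_events()] or [read_dfs_events()].
#' @param family `"weibull"` or `"exponential"`.
#' @param ... cure/split settings passed to [dfs_curve()]
#'   (`cure_threshold`, `max_cure_rate`, `mbc_split`, `cure_ramp`).
#' @return List with `curve` (a [dfs_curve()] with `log_cov` set), `se`
#'   (standard errors on the natural scale) and `loglik`.
#' @export
fit_dfs_curve <- function(events, family = c("weibull", "exponential"), ...) {
  family <- match.arg(family)
  if (sum(events$event) < 2)
    stop("need at least 2 observed events to fit a DFS curve")
  if (any(events$time_months <= 0))
    stop("event times must be positive")
  fit <- flexsurv::flexsurvreg(
    survival::Surv(time_months, event) ~ 1, data = events,
    dist = if (family == "weibull") "weibull" else "exp")
  res <- fit$res
  if (family == "weibull") {
    curve <- dfs_curve("weibull",
                       shape = res["shape", "est"],
                       scale = res["scale", "est"],
                       log_cov = unname(fit$cov), ...)
    se <- c(shape = res["shape", "se"], scale = res["scale", "se"])
  } else {
    curve <- dfs_curve("exponential", rate = res["rate", "est"],
                       log_cov = unname(fit$cov), ...)
    se <- c(rate = res["rate", "se"])
  }
  list(curve = curve, se = se, loglik = fit$loglik)
}
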
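#' Build truncated-normal priors from published parameter values
#'
#' For each free parameter the prior location is the median of its
#' published values and the standard deviation is half that median; draws
#' are truncated to stay positive and below a configurable multiple of the
#' median.
#'
#' @param published Named list; one numeric vector of published values per
#'   parameter.
#' @param upper_mult Upper truncation bound as a multiple of the median.
#' @return A `prior_spec` data frame with columns `param`, `median`, `sd`,
#'   `lower`, `upper`.
#' @examples
#' build_priors(list(lai = c(2, 4, 6), zeta = 0.17))
#' @export
build_priors <- function(published, upper_mult = 4) {
  stopifnot(is.list(published), length(published) >= 1,
            !is.null(names(published)), all(nzchar(names(published))))
  rows <- lapply(names(published), function(nm) {
    v <- published[[nm]]
    if (length(v) == 0 || !is.numeric(v) || anyNA(v)) {
      stop("no published values for parameter '", nm, "'")
    }
    med <- median(v)
    if (med <= 0) stop("median of published values for '", nm,
                       "' must be positive")
    data.frame(param = nm, median = med, sd = med / 2,
               lower = 0, upper = upper_mult * med)
  })
  structure(do.call(rbind, rows), class = c("prior_spec", "data.frame"))
}

#' ABC rejection-sampling configuration
#'
#' @param n_draws Number of prior draws.
#' @param tolerance_fraction Acceptance half-width as a fraction of the
#'   target summary (default 0.025, i.e. plus/minus 2.5 percent).
#' @param seed Integer RNG seed.
#' @param point_estimate `"mean"` or `"median"` of the accepted draws.
#' @return An `abc_config` list.
#' @export
abc_config <- function(n_draws = 10000, tolerance_fraction = 0.025,
                       seed = 1, point_estimate = c("mean", "median")) {
  stopifnot(n_draws >= 1, tolerance_fraction > 0)
  structure(list(n_draws = as.integer(n_draws),
                 tolerance_fraction = tolerance_fraction,
                 seed = as.integer(seed),
                 point_estimate = match.arg(point_estimate)),
            class = "abc_config")
}

## inverse-CDF draw from a truncated normal
rtruncnorm_inv <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Rejection-sampling approximate Bayesian computation
#'
#' Draws parameter vectors independently from the truncated-normal priors,
#' runs the forward model on each, and accepts a draw when its summary
#' statistic falls within `tolerance_fraction` of the target (the
#' convergence criterion of plus/minus 2.5 percent of the observed mean by
#' default). Deterministic given the seed. Zero acceptances raise an error
#' rather than silently widening the tolerance.
#'
#' @param forward Function taking a named numeric parameter vector and
#'   returning the scalar summary (here: mean ring width, mm). With
#'   `vectorized = TRUE`, a function taking the full draw matrix (one row
#'   per draw, named columns) and returning one summary per row.
#' @param target Target summary value (observed mean ring width, mm).
#' @param priors A [build_priors()] `prior_spec`.
#' @param config An [abc_config()].
#' @param vectorized Whether `forward` evaluates all draws at once.
#' @return An `abc_result` list: `draws` (data frame of all draws with
#'   their summaries and acceptance flags), `accepted`, `acceptance_rate`,
#'   `posterior` (mean/median/sd per parameter), `point_estimate`,
#'   `target`, `config`.
#' @export
abc_rejection <- function(forward, target, priors, config = abc_config(),
                          vectorized = FALSE) {
  stopifnot(is.function(forward), is.finite(target), target > 0,
            inherits(priors, "prior_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_draws
  theta <- sapply(seq_len(nrow(priors)), function(j) {
    rtruncnorm_inv(n, priors$median[j], priors$sd[j],
                   priors$lower[j], priors$upper[j])
  })
  theta <- matrix(theta, nrow = n,
                  dimnames = list(NULL, priors$param))
  summ <- if (vectorized) forward(theta) else
    apply(theta, 1, function(row) forward(row))
  if (!is.numeric(summ) || length(summ) != n) {
    stop("forward model must return one numeric summary per draw")
  }
  tol <- config$tolerance_fraction * target
  accepted <- is.finite(summ) & abs(summ - target) <= tol
  if (!any(accepted)) {
    stop("no accepted draws: increase n_draws or widen tolerance_fraction")
  }
  acc <- theta[accepted, , drop = FALSE]
  posterior <- data.frame(
    param = colnames(theta),
    mean = colMeans(acc),
    median = apply(acc, 2, median),
    sd = apply(acc, 2, sd),
    row.names = NULL)
  point <- if (config$point_estimate == "mean") posterior$mean else
    posterior$median
  names(point) <- posterior$param
  structure(list(
    draws = data.frame(theta, summary = summ, accepted = accepted),
    accepted = data.frame(acc, summary = summ[accepted]),
    acceptance_rate = mean(accepted),
    posterior = posterior,
    point_estimate = point,
    target = target,
    tolerance = tol,
    config = config), class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("<abc_result> %d/%d draws accepted (%.1f%%), target %.3f +/- %.3f\n",
              sum(x$draws$accepted), nrow(x$draws),
              100 * x$acceptance_rate, x$target, x$tolerance))
  print(x$posterior)
  invisible(x)
}

#' Optimise the allocation parameters at a given CO2 level
#'
#' Two-parameter ABC calibration of the leaf area index `L` and the
#' fine-root mass per unit leaf area `zeta` against a target mean ring
#' width, holding every other species parameter fixed. The priors default
#' to the fixed parameter set's values as published medians (sd = half the
#' median). The photosynthesis drivers are computed once per CO2 level;
#' only the cheap annual allocation loop runs per draw.
#'
#' @param forcing A prepared [forcing_series()] (its attached CO2 series is
#'   overridden by `co2_level`).
#' @param co2_level Constant ambient CO2, ppm; `NULL` uses the CO2 series
#'   attached to the forcing.
#' @param target_mean_rw Target mean ring width, mm.
#' @param params A [species_params()]; `lai` and `zeta` provide the prior
#'   medians, the rest stay fixed.
#' @param config An [abc_config()].
#' @param d0 Initial stem diameter, m.
#' @param constants A [p_constants()] list.
#' @param ring_years Optional ring years over which the mean simulated
#'   width is computed (default: all complete window years).
#' @return List with `lai`, `zeta` (point estimates) and `abc` (the full
#'   [abc_rejection()] result).
#' @export
optimize_allocation <- function(forcing, co2_level, target_mean_rw,
                                params = species_params(),
                                config = abc_config(),
                                d0 = 0.3, constants = p_constants(),
                                ring_years = NULL) {
  stopifnot(inherits(forcing, "forcing_series"),
            is.null(co2_level) || co2_level > 0)
  if (!is_prepared(forcing)) forcing <- prepare_forcing(forcing, constants)
  pm <- run_pmodel(forcing, constants, ca_ppm = co2_level)
  years <- sort(unique(forcing$year))
  gpp <- window_gpp(pm, years)
  gpp <- gpp[!is.na(gpp$gpp), , drop = FALSE]
  if (!is.null(ring_years)) {
    gpp <- gpp[gpp$year %in% ring_years, , drop = FALSE]
  }
  if (nrow(gpp) == 0) stop("no ring years with complete carbon window")
  forward <- function(theta) {
    grow_mean_rw_batch(gpp$gpp, params, theta[, "lai"], theta[, "zeta"], d0)
  }
  priors <- build_priors(list(lai = params$lai, zeta = params$zeta))
  res <- abc_rejection(forward, target_mean_rw, priors, config,
                       vectorized = TRUE)
  list(lai = unname(res$point_estimate["lai"]),
       zeta = unname(res$point_estimate["zeta"]),
       abc = res)
}
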